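#!/usr/bin/env Rscript
# Simulate one treatment arm and write the volume curve and run manifest.
#
# Usage:
#   Rscript scripts/simulate.R --arm NC_CD --cancer lung --seed 1 \
#       --t-end 17 --out run/

suppressMessages({
  library(optparse)
  library(nanotarget)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--arm", type = "character", default = "V",
              help = "treatment arm: V, NC_D, L_C, L_CD, NC_CD, NC_CD_mod"),
  make_option("--cancer", type = "character", default = "lung",
              help = "parameter set: lung or melanoma"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--t-end", type = "double", default = 17, dest = "t_end",
              help = "end of simulation, days"),
  make_option("--npts", type = "integer", default = 50L,
              help = "grid points per side"),
  make_option("--h", type = "double", default = 0.5,
              help = "dimensionless grid spacing"),
  make_option("--out", type = "character", default = "run",
              help = "output directory")
)))

params <- paper_defaults(opts$cancer)
grid <- sim_grid(opts$npts, opts$h)
message(sprintf("arm %s (%s), %d^3 grid, h = %g, seed = %d",
                opts$arm, opts$cancer, opts$npts, opts$h, opts$seed))
curve <- run_arm(opts$arm, params, grid, seed = opts$seed,
                 t_end_days = opts$t_end)

dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
utils::write.csv(as.data.frame(curve),
                 file.path(opts$out, "volumes.csv"), row.names = FALSE)
jsonlite::write_json(attr(curve, "manifest"),
                     file.path(opts$out, "manifest.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message(sprintf("final volume at day %.1f: %.1f mm^3",
                max(curve$day), curve$volume_mm3[nrow(curve)]))
message("wrote ", file.path(opts$out, "volumes.csv"))
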