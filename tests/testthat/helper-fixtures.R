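# Shared fixtures: small grids and cheap run settings used across tests.
# The published production grid is 50^3; unit tests use coarser grids whose
# voxel count keeps a single 17-day integration near a second.

lung <- paper_defaults("lung")

smoke_grid <- function() sim_grid(25, h = 1.0)   # arm-comparison scale
tiny_grid  <- function() sim_grid(12, h = 1.5)   # fastest qualitative scale

# A uniform state at a homogeneous fixed point (drug-free), for
# stationarity checks.
uniform_state <- function(grid, n0, m0) {
  np <- grid$npts
  arr <- function(v) array(v, dim = c(np, np, np))
  structure(list(t = 0, n = arr(n0), m = arr(m0), c = arr(0), d = arr(0),
                 carriers = list(), rng_seed = 0L),
            class = "nt_state")
}

final_volume <- function(curve) curve$volume_mm3[nrow(curve)]
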