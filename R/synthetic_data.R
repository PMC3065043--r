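#' Generate synthetic tumour-volume datasets
#'
#' Emulates per-arm caliper measurements: the model is run at known
#' ground-truth parameters, sampled daily over the treatment window, and
#' perturbed by multiplicative lognormal observation noise
#' (`obs = model * exp(eps)`, `eps ~ N(0, noise_rel^2)`). Volumes are
#' positive and measurement error grows with size, which the lognormal model
#' captures; replicates differ by the initial vessel-field seed and by the
#' noise draw, and the whole dataset is reproducible from `seed`.
#'
#' @param truth ground-truth [model_params()].
#' @param arms arm names to generate.
#' @param noise_rel relative observation noise (default 0.05).
#' @param n_replicates replicates per arm.
#' @param seed master seed; per-replicate simulation seeds and noise streams
#'   are derived from it.
#' @param days sampling days (default daily over the treatment window,
#'   8 to 17).
#' @param grid an [sim_grid()].
#' @param ... passed to [run_arm()].
#' @return object of class `nt_dataset`: list with `data` (`data.frame` of
#'   `day`, `volume_mm3`, `arm`, `replicate`), `truth`, `noise_rel`,
#'   `seed`, and `sim_seeds` (the per-replicate simulation seeds).
#' @export
generate_volumes <- function(truth = paper_defaults("lung"),
                             arms = c("V", "L_C", "NC_D"),
                             noise_rel = 0.05, n_replicates = 3, seed = 1,
                             days = 8:17, grid = sim_grid(), ...) {
  stopifnot(noise_rel >= 0, n_replicates >= 1)
  rows <- list()
  sim_seeds <- integer(0)
  for (r in seq_len(n_replicates)) {
    sim_seed <- (seed * 1009L + r) %% 2147483647L
    sim_seeds[r] <- sim_seed
    for (a in arms) {
      cur <- run_arm(a, truth, grid, seed = sim_seed,
                     t_end_days = max(days), ...)
      vol <- stats::approx(cur$day, cur$volume_mm3, xout = days,
                           rule = 2)$y
      set.seed((seed * 7919L + r * 131L + match(a, arm_names())) %%
                 2147483647L)
      eps <- stats::rnorm(length(days), 0, noise_rel)
      rows[[paste(a, r)]] <- data.frame(
        day = days, volume_mm3 = vol * exp(eps), arm = a, replicate = r)
    }
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  structure(list(data = data, truth = truth, noise_rel = noise_rel,
                 seed = seed, sim_seeds = sim_seeds),
            class = "nt_dataset")
}

#' Write / read a volume dataset as CSV
#'
#' Schema: columns `day`, `volume_mm3`, `arm`, `replicate` -- identical to
#' the calibration input. The round trip is lossless to full double
#' precision.
#'
#' @param data a `data.frame` with the schema above (or an `nt_dataset`,
#'   whose `$data` is written).
#' @param path CSV file path.
#' @return `write_volume_csv()` returns `path` invisibly;
#'   `read_volume_csv()` returns the `data.frame`.
#' @export
write_volume_csv <- function(data, path) {
  if (inherits(data, "nt_dataset")) data <- data$data
  need <- c("day", "volume_mm3", "arm", "replicate")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(data[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_volume_csv
#' @export
read_volume_csv <- function(path) {
  data <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e)))
  need <- c("day", "volume_mm3", "arm", "replicate")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (k in c("day", "volume_mm3")) {
    if (!is.numeric(data[[k]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(data[[k]]))))[1]
      stop("non-numeric value in column ", k, " at data line ", bad)
    }
  }
  data
}
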