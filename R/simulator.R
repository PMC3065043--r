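#' Simulation grid
#'
#' A cubic finite-difference grid with `npts` points per side and uniform
#' dimensionless spacing `h`, integrated with no-flux (zero-gradient)
#' boundaries. The physical voxel volume is `(h * length_scale)^3` mm^3
#' where `length_scale = sqrt(D1 / rho)` comes from the unit system in use.
#'
#' The default spacing `h = 0.5` gives a 25-unit (about 24 mm for lung
#' parameters) domain side: wide enough that the untreated tumour front does
#' not reach the boundary within the 17-day protocol, so day-17 arm
#' comparisons are not confounded by domain saturation (see the vignette).
#'
#' @param npts points per side (default 50).
#' @param h dimensionless grid spacing, `> 0`.
#' @return object of class `nt_grid`.
#' @export
sim_grid <- function(npts = 50, h = 0.5) {
  stopifnot(npts >= 3, h > 0)
  structure(list(npts = as.integer(npts), h = h), class = "nt_grid")
}

#' @rdname sim_grid
#' @param grid an `nt_grid`.
#' @param units an [unit_system()].
#' @return `voxel_volume_mm3()`: physical volume of one voxel, mm^3.
#' @export
voxel_volume_mm3 <- function(grid, units) (grid$h * units$length_scale)^3

#' Discrete Laplacian with no-flux boundaries
#'
#' 7-point stencil on a 3D array; boundary faces use zero-gradient (mirror)
#' ghost values, so the discrete divergence theorem holds exactly: the
#' output sums to zero for any input.
#'
#' @param field 3D numeric array.
#' @param h grid spacing.
#' @return array of the same shape.
#' @export
laplacian_noflux <- function(field, h) {
  if (length(dim(field)) != 3) stop("laplacian_noflux expects a 3D array")
  cpp_laplacian_noflux(field, h)
}

#' Initial simulation state
#'
#' Tumour cells start as a unit-peak Gaussian of width `sigma0` centred on
#' the grid (the avascular seed); vessels start i.i.d. uniform on (0, 1) per
#' voxel, which the cubic dynamics quickly sharpens into vascular and
#' avascular islands; all drug and carrier fields start at zero.
#'
#' @param grid an [sim_grid()].
#' @param params an [model_params()] object (uses `sigma0`).
#' @param seed integer RNG seed for the vessel field; the state is bitwise
#'   reproducible from it.
#' @return object of class `nt_state`: list with dimensionless time `t`,
#'   fields `n`, `m`, `c`, `d`, carrier list `carriers`, and `rng_seed`.
#' @export
initialize_state <- function(grid, params, seed = 1) {
  np <- grid$npts
  ax <- (seq_len(np) - (np + 1) / 2) * grid$h
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  n <- exp(-r2 / (2 * params$sigma0^2))
  set.seed(seed)
  m <- array(stats::runif(np^3), dim = c(np, np, np))
  # c and d must be distinct arrays: the integrator updates them in place
  structure(list(t = 0, n = n, m = m,
                 c = array(0, dim = c(np, np, np)),
                 d = array(0, dim = c(np, np, np)),
                 carriers = list(), rng_seed = as.integer(seed)),
            class = "nt_state")
}

#' Explicit-Euler stability bound on the time step
#'
#' `0.9 * h^2 / (6 * max(1, D2_t, D3_t, D4_t))`: the diffusive stability
#' limit of the 7-point stencil with a 10% safety margin (the tumour field
#' has unit dimensionless diffusivity).
#'
#' @param grid an [sim_grid()].
#' @param params an [model_params()] object.
#' @return scalar dimensionless time step.
#' @export
stable_dt <- function(grid, params) {
  0.9 * grid$h^2 / (6 * max(1, params$D2_t, params$D3_t, params$D4_t))
}

default_dt <- function(grid, params) min(0.002, stable_dt(grid, params))

#' One forward-Euler step of the full model
#'
#' Advances every field by `dt` (dimensionless): reaction terms of
#' [rhs_n()], [rhs_m()], [rhs_c()], [rhs_d()] plus diffusion, carrier uptake
#' at the current vascular concentration, and drug release at the current
#' normalized profile values. Negative values arising from the explicit
#' update are clipped to zero. Carrier fields must already exist for every
#' past dose ([run_arm()] allocates them as doses are administered).
#'
#' @param state an [initialize_state()] state.
#' @param dt dimensionless time step; refused above the stability bound
#'   unless `override_stability = TRUE`.
#' @param spec an [build_arm()] treatment arm.
#' @param params an [model_params()] object.
#' @param grid an [sim_grid()].
#' @param tau_D vascular clearance time of carriers, days.
#' @param form delivery-efficiency variant, see [delivery_efficiency()].
#' @param override_stability allow `dt` above the stability bound.
#' @return the advanced state.
#' @export
step <- function(state, dt, spec, params, grid, tau_D = 15,
                 form = c("as_printed", "max_at_one"),
                 override_stability = FALSE) {
  form <- match.arg(form)
  bound <- stable_dt(grid, params)
  if (dt > bound) {
    if (!override_stability) {
      stop(sprintf("dt = %g exceeds the stability bound %g; pass override_stability = TRUE to force", dt, bound))
    }
    warning(sprintf("dt = %g exceeds the stability bound %g", dt, bound))
  }
  units <- unit_system(params$rho, params$D1)
  day <- dimensionless_to_days(state$t, units)
  k <- length(state$carriers)
  dose_days <- spec$schedule$dose_times[seq_len(k)]
  sc <- step_scalars(spec, day, dose_days, tau_D)
  new <- state
  new$n <- state$n + 0; new$m <- state$m + 0
  new$c <- state$c + 0; new$d <- state$d + 0
  new$carriers <- lapply(state$carriers, function(x) x + 0)
  cpp_step_inplace(new$n, new$m, new$carriers, new$c, new$d,
                   grid$h, dt, unclass(params),
                   sc$gamma, sc$rpC, sc$rpD,
                   spec$chemo_active, spec$anti_active,
                   if (form == "as_printed") 0L else 1L)
  new$t <- state$t + dt
  new
}

# Gamma_i(t) and normalized release-profile values for the first k doses.
step_scalars <- function(spec, day, dose_days, tau_D) {
  k <- length(dose_days)
  if (k == 0) {
    return(list(gamma = numeric(0), rpC = numeric(0), rpD = numeric(0)))
  }
  gam <- vapply(dose_days, function(ti) vessel_concentration(day, ti, tau_D),
                numeric(1))
  rp <- function(profile) {
    if (is.null(profile)) return(numeric(k))
    vapply(dose_days, function(ti) profile_value(profile, day, ti),
           numeric(1))
  }
  list(gamma = gam, rpC = rp(spec$profile_C), rpD = rp(spec$profile_D))
}

#' Detectable tumour volume
#'
#' Physical volume of the voxels whose tumour-cell density reaches the
#' detectability threshold: `count(n >= c_th) * (h * length_scale)^3` mm^3.
#' This is the quantity compared with caliper measurements.
#'
#' @param n tumour-cell field.
#' @param c_th detectability threshold on the dimensionless density.
#' @param grid an [sim_grid()].
#' @param units an [unit_system()].
#' @return volume in mm^3.
#' @export
tumor_volume <- function(n, c_th, grid, units = unit_system()) {
  sum(n >= c_th) * voxel_volume_mm3(grid, units)
}

#' Simulate one treatment arm and record the volume curve
#'
#' Integrates the full model from `t = 0` (implantation) to `t_end_days`,
#' administering carriers at the scheduled dose days (a fresh zero carrier
#' field is added at the start of the step containing each dose time) and
#' recording the detectable tumour volume every `record_every` days.
#'
#' @param arm arm name (see [arm_names()]) or an `nt_arm` from
#'   [build_arm()].
#' @param params an [model_params()] object.
#' @param grid an [sim_grid()].
#' @param schedule an [administration_schedule()]; defaults to the arm's.
#' @param seed RNG seed for the initial vessel field.
#' @param t_end_days end of the simulation, days; must reach the last dose.
#' @param dt dimensionless time step; default
#'   `min(0.002, stability bound)` (see the vignette on accuracy).
#' @param record_every recording cadence, days.
#' @param tau_D carrier vascular clearance time, days.
#' @param form delivery-efficiency variant.
#' @return a `volume curve`: `data.frame(day, volume_mm3, arm, seed)` of
#'   class `nt_volume_curve`, with a `manifest` attribute holding the fully
#'   resolved run configuration.
#' @export
#' @examples
#' \donttest{
#' curve <- run_arm("V", paper_defaults("lung"), sim_grid(25, h = 1),
#'                  seed = 1, t_end_days = 6)
#' tail(curve, 3)
#' }
run_arm <- function(arm, params = paper_defaults("lung"), grid = sim_grid(),
                    schedule = NULL, seed = 1, t_end_days = 17, dt = NULL,
                    record_every = 0.1, tau_D = 15,
                    form = c("as_printed", "max_at_one")) {
  form <- match.arg(form)
  if (is.character(arm)) arm <- build_arm(arm)
  stopifnot(inherits(arm, "nt_arm"))
  if (is.null(schedule)) schedule <- arm$schedule
  has_doses <- !is.null(arm$profile_C) || !is.null(arm$profile_D)
  if (has_doses && t_end_days < max(schedule$dose_times)) {
    stop("t_end_days must reach the last scheduled dose")
  }
  if (is.null(dt)) dt <- default_dt(grid, params)
  if (dt > stable_dt(grid, params)) {
    stop(sprintf("dt = %g exceeds the stability bound %g", dt,
                 stable_dt(grid, params)))
  }
  units <- unit_system(params$rho, params$D1)
  t_end <- days_to_dimensionless(t_end_days, units)
  nsteps <- ceiling(t_end / dt - 1e-9)
  dts <- rep(dt, nsteps)
  if (nsteps > 0) dts[nsteps] <- max(t_end - (nsteps - 1) * dt, 0)
  # recording times: nominal days mapped to the step grid (one record per
  # distinct step; reported at the nominal day, within one step of it)
  rec_days <- seq(0, t_end_days, by = record_every)
  idx_all <- pmin(nsteps, ceiling(days_to_dimensionless(rec_days, units) /
                                    dt - 1e-9))
  keep <- !duplicated(idx_all)
  rec_idx <- idx_all[keep]
  rec_days <- rec_days[keep]
  rec_idx_pos <- rec_idx[rec_idx > 0]

  state <- initialize_state(grid, params, seed)
  pars <- unclass(params)
  form_i <- if (form == "as_printed") 0L else 1L
  K <- if (has_doses) length(schedule$dose_times) else 0L

  # per-step carrier scalars, evaluated at the step start; all three vanish
  # before each dose time, so carriers can be allocated up front
  day_vec <- dimensionless_to_days((seq_len(nsteps) - 1) * dt, units)
  per_dose <- function(fun) {
    if (K == 0) return(matrix(0, 0, nsteps))
    do.call(rbind, lapply(schedule$dose_times[seq_len(K)],
                          function(ti) fun(ti)))
  }
  gammaM <- per_dose(function(ti) vessel_concentration(day_vec, ti, tau_D))
  rpM <- function(profile) {
    if (is.null(profile)) return(matrix(0, K, max(nsteps, 0)))
    per_dose(function(ti) profile_value(profile, day_vec, ti))
  }
  v0 <- tumor_volume(state$n, params$c_th, grid, units)
  out <- cpp_run(state$n, state$m, state$c, state$d, K, grid$h, dts, pars,
                 gammaM, rpM(arm$profile_C), rpM(arm$profile_D),
                 arm$chemo_active, arm$anti_active, form_i,
                 as.integer(rec_idx_pos), params$c_th)
  if (out$aborted_step > 0) {
    stop(sprintf("instability: non-finite fields at day %.2f (dt = %g)",
                 dimensionless_to_days(out$aborted_step * dt, units), dt))
  }
  vox <- voxel_volume_mm3(grid, units)
  days <- rec_days
  vols <- out$counts * vox
  if (0 %in% rec_idx) vols <- c(v0, vols)

  curve <- data.frame(day = days, volume_mm3 = vols, arm = arm$name,
                      seed = seed)
  class(curve) <- c("nt_volume_curve", "data.frame")
  attr(curve, "manifest") <- list(
    arm = arm_manifest(arm), npts = grid$npts, h = grid$h, dt = dt,
    seed = seed, t_end_days = t_end_days, record_every = record_every,
    tau_D = tau_D, form = form, params = lapply(pars, as.numeric),
    length_scale_mm = units$length_scale,
    voxel_mm3 = voxel_volume_mm3(grid, units))
  curve
}

#' First day a volume curve crosses a threshold
#'
#' Linearly interpolates between recorded points; returns `NA` if the curve
#' never reaches the threshold.
#'
#' @param curve a volume curve (`data.frame` with `day`, `volume_mm3`).
#' @param threshold_mm3 threshold volume, mm^3.
#' @return day of first crossing, or `NA_real_`.
#' @export
crossing_day <- function(curve, threshold_mm3) {
  stopifnot(nrow(curve) > 0)
  v <- curve$volume_mm3; d <- curve$day
  hit <- which(v >= threshold_mm3)
  if (length(hit) == 0) return(NA_real_)
  i <- hit[1]
  if (i == 1) return(d[1])
  d[i - 1] + (threshold_mm3 - v[i - 1]) * (d[i] - d[i - 1]) /
    (v[i] - v[i - 1])
}

#' Tune the grid spacing against the 50 mm^3 growth anchor
#'
#' The only absolute volume anchor available is that untreated tumours reach
#' 50 mm^3 about 8 days after implantation. This helper scans grid spacings
#' and reports the one whose untreated volume curve crosses the threshold
#' closest to the target day. Note that the continuum dynamics are fixed by
#' `(D1, rho)` -- the crossing day is largely insensitive to `h` (see the
#' vignette) -- so the helper also reports whether the anchor was actually
#' met within `tol`.
#'
#' @param params an [model_params()] object.
#' @param npts grid points per side.
#' @param h_values candidate spacings to scan.
#' @param target_day,threshold_mm3,tol the anchor: crossing of
#'   `threshold_mm3` at `target_day +/- tol` days.
#' @param seed RNG seed for the vessel field.
#' @param t_end_days length of the scan runs, days.
#' @param ... passed to [run_arm()].
#' @return list with the selected `h`, its `crossing_day`, `converged`
#'   (anchor met within `tol`), and the full scan `table`.
#' @export
calibrate_grid <- function(params = paper_defaults("lung"), npts = 50,
                           h_values = c(0.3, 0.5, 0.8, 1.1),
                           target_day = 8, threshold_mm3 = 50, tol = 0.5,
                           seed = 1, t_end_days = 10, ...) {
  rows <- lapply(h_values, function(h) {
    cur <- run_arm("V", params, sim_grid(npts, h), seed = seed,
                   t_end_days = t_end_days, ...)
    data.frame(h = h, crossing_day = crossing_day(cur, threshold_mm3))
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$crossing_day)
  if (!any(ok)) {
    return(list(h = NA_real_, crossing_day = NA_real_, converged = FALSE,
                table = tab))
  }
  best <- which.min(abs(tab$crossing_day - target_day) + ifelse(ok, 0, Inf))
  list(h = tab$h[best], crossing_day = tab$crossing_day[best],
       converged = isTRUE(abs(tab$crossing_day[best] - target_day) <= tol),
       table = tab)
}

#' @export
print.nt_volume_curve <- function(x, ...) {
  man <- attr(x, "manifest")
  cat(sprintf("<volume curve> arm %s, seed %d, %d records to day %.1f\n",
              man$arm$name, man$seed, nrow(x), max(x$day)))
  print.data.frame(utils::tail(as.data.frame(x), 5))
  invisible(x)
}

#' Plot volume curves
#'
#' @param x a volume curve or a list of them (e.g. one per arm).
#' @param log plot volumes on a log axis.
#' @param ... further arguments to [graphics::matplot()].
#' @export
plot_volume_curves <- function(x, log = FALSE, ...) {
  curves <- if (inherits(x, "nt_volume_curve")) list(x) else x
  days <- curves[[1]]$day
  vols <- vapply(curves, function(cu) cu$volume_mm3, numeric(length(days)))
  labs <- vapply(curves, function(cu) as.character(cu$arm[1]), "")
  graphics::matplot(days, vols, type = "l", lty = 1, col = seq_along(curves),
                    xlab = "day", ylab = "tumour volume (mm^3)",
                    log = if (log) "y" else "", ...)
  graphics::legend("topleft", legend = labs, col = seq_along(curves),
                   lty = 1, bty = "n")
  invisible(x)
}
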