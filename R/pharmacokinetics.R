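#' Administration schedule
#'
#' Dose times and the horizon over which release profiles are normalized.
#' The published protocol administers at days 8, 10, 12, 14, 16 and follows
#' tumours to day 17.
#'
#' @param dose_times strictly increasing administration times, days.
#' @param horizon last time considered, days; all doses must precede it.
#' @return object of class `nt_schedule`.
#' @export
administration_schedule <- function(dose_times = c(8, 10, 12, 14, 16),
                                    horizon = 17) {
  if (length(dose_times) == 0) stop("empty schedule")
  if (any(diff(dose_times) <= 0)) {
    stop("dose_times must be strictly increasing")
  }
  if (any(dose_times >= horizon)) {
    stop("all dose_times must be earlier than the horizon")
  }
  structure(list(dose_times = as.numeric(dose_times),
                 horizon = as.numeric(horizon)),
            class = "nt_schedule")
}

#' Gamma-type release kernel
#'
#' Un-normalized release kernel of a single administration:
#' `theta(t - t_i) (t - t_i)^p exp(-(t - t_i) / tau)`, i.e. zero before the
#' dose, a power-law onset and an exponential tail. The step function is
#' right-continuous (`theta(0) = 1`). Its maximum over `t` lies at
#' `t_i + p * tau`.
#'
#' @param t time(s), days; vectorized.
#' @param t_i administration time, days.
#' @param p power-law exponent, `p >= 0`.
#' @param tau decay time, days, `tau > 0`.
#' @return nonnegative numeric of the same length as `t`.
#' @export
gamma_kernel <- function(t, t_i, p, tau) {
  stopifnot(p >= 0, tau > 0)
  s <- t - t_i
  out <- numeric(length(s))
  on <- s >= 0
  out[on] <- s[on]^p * exp(-s[on] / tau)
  if (p == 0) out[on & s == 0] <- 1  # 0^0 = 1: pure exponential kernel
  out
}

#' Normalization constant of a release profile over a schedule
#'
#' `N = sum_i integral_0^horizon kernel(t, t_i, p, tau) dt`, computed by
#' adaptive quadrature (relative tolerance 1e-10, one integral per dose so
#' the integrable power-law onset at each `t_i` sits at an interval
#' endpoint). Dividing the summed kernels by `N` makes the total release
#' over the horizon equal one. For a single untruncated window the closed
#' form is `tau^(p+1) * Gamma(p+1)`, used as an independent oracle in the
#' tests.
#'
#' @param schedule an [administration_schedule()].
#' @param p,tau kernel parameters (days for `tau`).
#' @return scalar `N > 0` in units of days^(p+1).
#' @export
normalization_constant <- function(schedule, p, tau) {
  stopifnot(inherits(schedule, "nt_schedule"))
  contribs <- vapply(schedule$dose_times, function(ti) {
    stats::integrate(function(s) s^p * exp(-s / tau),
                     lower = 0, upper = schedule$horizon - ti,
                     rel.tol = 1e-10, abs.tol = 0)$value
  }, numeric(1))
  sum(contribs)
}

#' Release profile of one agent under one treatment
#'
#' A gamma-type kernel shared by every dose of a schedule, with a single
#' normalization constant per treatment so that the summed release over all
#' doses integrates to one over the horizon.
#'
#' @param p,tau kernel parameters (`tau` in days).
#' @param label free-text tag, e.g. `"nanocell core (D)"`.
#' @return object of class `nt_profile` with `N = NA` until normalized.
#' @export
release_profile <- function(p, tau, label = "") {
  stopifnot(p >= 0, tau > 0)
  structure(list(p = p, tau = tau, N = NA_real_, label = label),
            class = "nt_profile")
}

#' @rdname release_profile
#' @param profile an `nt_profile`.
#' @param schedule an [administration_schedule()].
#' @export
normalize_profile <- function(profile, schedule) {
  stopifnot(inherits(profile, "nt_profile"))
  profile$N <- normalization_constant(schedule, profile$p, profile$tau)
  profile
}

#' Evaluate a normalized release profile
#'
#' @param profile a normalized `nt_profile`.
#' @param t time(s), days.
#' @param t_i administration time, days.
#' @return release rate per day; the sum over doses integrates to one over
#'   the schedule horizon.
#' @export
profile_value <- function(profile, t, t_i) {
  if (is.na(profile$N)) stop("profile is not normalized; see normalize_profile()")
  gamma_kernel(t, t_i, profile$p, profile$tau) / profile$N
}

#' Carrier concentration in the blood vessels after one dose
#'
#' `Gamma_i(t) = theta(t - t_i) exp(-(t - t_i)/tau_D)`: unit concentration at
#' the moment of administration, decaying exponentially. The same clearance
#' is used for liposomes and nanocells, with `tau_D` equal to the nanocell
#' release time (15 days).
#'
#' @param t time(s), days; vectorized.
#' @param t_i administration time, days.
#' @param tau_D vascular clearance time, days.
#' @return numeric in `[0, 1]`.
#' @export
vessel_concentration <- function(t, t_i, tau_D = 15) {
  stopifnot(tau_D > 0)
  s <- t - t_i
  ifelse(s >= 0, exp(-s / tau_D), 0)
}

#' Carrier uptake rate into the tissue
#'
#' Right-hand side of the carrier equation: `delta_t * Gamma_i(t) *
#' delivery_efficiency(m)`. Uptake requires vasculature (zero where `m = 0`)
#' and is maximal near normalized vessel density.
#'
#' @param m vessel-density field (nonnegative).
#' @param gamma_val scalar `Gamma_i(t)` in `[0, 1]`.
#' @param params an [model_params()] object.
#' @param form delivery-efficiency variant, see [delivery_efficiency()].
#' @return field of the same shape as `m`.
#' @export
uptake_rate <- function(m, gamma_val, params,
                        form = c("as_printed", "max_at_one")) {
  stopifnot(gamma_val >= 0, gamma_val <= 1)
  params$delta_t * gamma_val * delivery_efficiency(m, params$m_lim, form)
}

#' Local drug-release rate from accumulated carriers
#'
#' `R(x, t) = sum_i RP_i(t) C_i(x, t)`: each past administration's carrier
#' field releases drug at the (normalized) profile rate for that dose. A
#' profile of `NULL` (agent not carried by this treatment) contributes
#' exactly zero.
#'
#' @param t time, days.
#' @param carriers list of carrier fields `C_i`, one per past dose, in dose
#'   order.
#' @param profile a normalized `nt_profile`, or `NULL` for an absent agent.
#' @param schedule an [administration_schedule()]; its first
#'   `length(carriers)` dose times are used.
#' @return a field of the same shape as the carriers (0 if `profile` is
#'   `NULL` or no carriers exist yet).
#' @export
release_rate <- function(t, carriers, profile, schedule) {
  if (length(carriers) > length(schedule$dose_times)) {
    stop("more carrier fields than scheduled doses")
  }
  if (length(carriers) == 0) return(0)
  acc <- 0 * carriers[[1]]
  if (is.null(profile)) return(acc)
  for (i in seq_along(carriers)) {
    acc <- acc + profile_value(profile, t, schedule$dose_times[i]) *
      carriers[[i]]
  }
  acc
}

#' Reaction term of the free antiangiogenic agent
#'
#' `lambdaC_t * R_C - nuC_t * c`: release from carriers minus natural decay.
#' There is no vessel-reabsorption term for this agent (it acts on normal
#' and abnormal vessels alike, preventing reuptake).
#'
#' @param cc free-agent field.
#' @param R_C release-rate field (per day).
#' @param params an [model_params()] object.
#' @return field.
#' @export
rhs_c <- function(cc, R_C, params) {
  params$lambdaC_t * R_C - params$nuC_t * cc
}

#' Reaction term of the free chemotherapeutic agent
#'
#' `lambdaD_t * R_D - mu_t * m * d - nuD_t * d`: release, reabsorption into
#' blood vessels (the trapping term, proportional to local vessel density),
#' and natural decay. Vascular collapse (`m -> 0`) removes the reabsorption
#' sink and traps the drug in the tissue.
#'
#' @param d free-agent field.
#' @param R_D release-rate field (per day).
#' @param m vessel-density field.
#' @param params an [model_params()] object.
#' @return field.
#' @export
rhs_d <- function(d, R_D, m, params) {
  params$lambdaD_t * R_D - params$mu_t * m * d - params$nuD_t * d
}

#' Sample release and vessel-concentration curves as a table
#'
#' Convenience writer for plotting: samples the normalized release profiles
#' and the vascular carrier concentration of a treatment arm on a daily (or
#' finer) time grid.
#'
#' @param spec a treatment spec from [build_arm()].
#' @param schedule an [administration_schedule()].
#' @param times sample times, days.
#' @param tau_D vascular clearance time, days.
#' @return data.frame with columns `day`, `value`, `agent`, `arm`.
#' @export
sample_release_curves <- function(spec, schedule,
                                  times = seq(0, schedule$horizon, by = 0.1),
                                  tau_D = 15) {
  rows <- list()
  agents <- list(C = spec$profile_C, D = spec$profile_D)
  for (ag in names(agents)) {
    prof <- agents[[ag]]
    if (is.null(prof)) next
    val <- rowSums(vapply(schedule$dose_times,
                          function(ti) profile_value(prof, times, ti),
                          numeric(length(times))))
    rows[[ag]] <- data.frame(day = times, value = val, agent = ag,
                             arm = spec$name)
  }
  gam <- rowSums(vapply(schedule$dose_times,
                        function(ti) vessel_concentration(times, ti, tau_D),
                        numeric(length(times))))
  rows[["Gamma"]] <- data.frame(day = times, value = gam, agent = "Gamma",
                                arm = spec$name)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
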