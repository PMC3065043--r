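#' Treatment arms
#'
#' Builds the specification of one treatment arm of the comparison:
#' \describe{
#'   \item{`V`}{untreated control; no agents active.}
#'   \item{`NC_D`}{nanocells carrying only doxorubicin (chemotherapy only);
#'     slow nanocell-core release `(p_nc, tau_nc)`.}
#'   \item{`L_C`}{liposomes carrying only combretastatin (antiangiogenic
#'     only); fast liposomal release `(p_l, tau_l)`.}
#'   \item{`L_CD`}{one liposome carrying both agents: both released with the
#'     liposomal profile.}
#'   \item{`NC_CD`}{nanocell: combretastatin from the lipid envelope
#'     (liposomal profile), doxorubicin from the core (slow profile).}
#'   \item{`NC_CD_mod`}{nanocell with delayed core release (`p_nc = 0.8`),
#'     renormalized so the same total amount of each drug is released.}
#' }
#' Because the nanocell envelope is itself a liposome, the envelope profile
#' equals the `L_C` profile and shares its normalization constant; every
#' active profile is normalized over the schedule, so all combination arms
#' release the same total amount of each agent.
#'
#' @param name arm name (see above).
#' @param schedule an [administration_schedule()].
#' @param p_nc,tau_nc nanocell-core release exponent and decay time (days);
#'   published values 0.3 and 15.
#' @param p_l,tau_l liposomal release exponent and decay time (days);
#'   published values 0.1 and 2.
#' @param p_nc_mod core exponent of the modified (delayed-release) nanocell.
#' @return object of class `nt_arm`: list with fields `name`, `j` (arm index
#'   1-4, 0 for control), `modified`, `chemo_active`, `anti_active`,
#'   `profile_C`, `profile_D` (normalized `nt_profile` or `NULL`).
#' @export
#' @examples
#' arm <- build_arm("NC_CD")
#' arm$profile_D$p   # 0.3
#' arm$profile_C$tau # 2
build_arm <- function(name = c("V", "NC_D", "L_C", "L_CD", "NC_CD",
                               "NC_CD_mod"),
                      schedule = administration_schedule(),
                      p_nc = 0.3, tau_nc = 15, p_l = 0.1, tau_l = 2,
                      p_nc_mod = 0.8) {
  name <- match.arg(name)
  lipo <- normalize_profile(release_profile(p_l, tau_l, "liposome"), schedule)
  core <- normalize_profile(release_profile(p_nc, tau_nc, "nanocell core"),
                            schedule)
  spec <- switch(name,
    V = list(j = 0L, chemo_active = FALSE, anti_active = FALSE,
             profile_C = NULL, profile_D = NULL, modified = FALSE),
    NC_D = list(j = 1L, chemo_active = TRUE, anti_active = FALSE,
                profile_C = NULL, profile_D = core, modified = FALSE),
    L_C = list(j = 2L, chemo_active = FALSE, anti_active = TRUE,
               profile_C = lipo, profile_D = NULL, modified = FALSE),
    L_CD = list(j = 3L, chemo_active = TRUE, anti_active = TRUE,
                profile_C = lipo, profile_D = lipo, modified = FALSE),
    NC_CD = list(j = 4L, chemo_active = TRUE, anti_active = TRUE,
                 profile_C = lipo, profile_D = core, modified = FALSE),
    NC_CD_mod = list(j = 4L, chemo_active = TRUE, anti_active = TRUE,
                     profile_C = lipo,
                     profile_D = normalize_profile(
                       release_profile(p_nc_mod, tau_nc,
                                       "nanocell core (delayed)"), schedule),
                     modified = TRUE)
  )
  spec$name <- name
  spec$schedule <- schedule
  class(spec) <- "nt_arm"
  spec
}

#' @export
print.nt_arm <- function(x, ...) {
  cat("<nt_arm>", x$name, " (j =", x$j, ")\n")
  cat("  chemo:", x$chemo_active, " anti:", x$anti_active,
      " modified:", x$modified, "\n")
  for (ag in c("profile_C", "profile_D")) {
    pr <- x[[ag]]
    if (is.null(pr)) cat(" ", ag, ": absent\n")
    else cat(sprintf("  %s: p=%.3g tau=%.3g d N=%.6g (%s)\n",
                     ag, pr$p, pr$tau, pr$N, pr$label))
  }
  invisible(x)
}

#' All arm names in the canonical comparison order
#' @export
arm_names <- function() c("V", "NC_D", "L_C", "L_CD", "NC_CD", "NC_CD_mod")

#' Unit system of the nondimensionalization
#'
#' The model is integrated in dimensionless variables related to laboratory
#' units by `t_tilde = rho * t` and `x_tilde = x * sqrt(rho / D1)`, so the
#' characteristic time is `1 / rho` days and the characteristic length is
#' `sqrt(D1 / rho)` mm.
#'
#' @param rho net proliferation rate, 1/day.
#' @param D1 tumour-cell diffusivity, mm^2/day.
#' @return object of class `nt_units` with `rho`, `D1`, `length_scale` (mm),
#'   `time_scale` (days).
#' @export
unit_system <- function(rho = 0.35, D1 = 0.32) {
  stopifnot(rho > 0, D1 > 0)
  structure(list(rho = rho, D1 = D1,
                 length_scale = sqrt(D1 / rho),
                 time_scale = 1 / rho),
            class = "nt_units")
}

#' @rdname unit_system
#' @param t time in days.
#' @param units an `nt_units` object.
#' @export
days_to_dimensionless <- function(t, units) t * units$rho

#' @rdname unit_system
#' @param t_tilde dimensionless time.
#' @export
dimensionless_to_days <- function(t_tilde, units) t_tilde / units$rho

#' @rdname unit_system
#' @param x length in mm.
#' @export
mm_to_dimensionless <- function(x, units) x / units$length_scale

#' @rdname unit_system
#' @param x_tilde dimensionless length.
#' @export
dimensionless_to_mm <- function(x_tilde, units) x_tilde * units$length_scale

#' Serialize an arm to a run-manifest list
#'
#' @param spec an `nt_arm`.
#' @return plain list suitable for [jsonlite::write_json()].
#' @export
arm_manifest <- function(spec) {
  prof <- function(p) if (is.null(p)) NULL else
    list(p = p$p, tau = p$tau, N = p$N, label = p$label)
  list(name = spec$name, j = spec$j, modified = spec$modified,
       chemo_active = spec$chemo_active, anti_active = spec$anti_active,
       profile_C = prof(spec$profile_C), profile_D = prof(spec$profile_D),
       dose_times = spec$schedule$dose_times,
       horizon = spec$schedule$horizon)
}
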