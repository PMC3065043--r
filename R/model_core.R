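#' Reaction term of the tumour-cell field
#'
#' The local (non-diffusive) part of the tumour-cell dynamics: logistic
#' growth `n(1 - n)`, enhancement by vasculature `alpha1_t * m * n`, and --
#' when chemotherapy is active -- the kill term `-AD_t * d * n`. Diffusion is
#' handled by the simulator.
#'
#' @param n,m,d numeric arrays on a common grid: tumour-cell density, vessel
#'   density, free chemotherapeutic concentration (all dimensionless,
#'   nonnegative).
#' @param params an [model_params()] object.
#' @param chemo_active logical; include the chemotherapy kill term.
#' @return array of the same shape as `n`.
#' @export
rhs_n <- function(n, m, d = 0 * n, params = paper_defaults("lung"),
                  chemo_active = FALSE) {
  check_fields(n = n, m = m, d = d)
  out <- n * (1 - n) + params$alpha1_t * m * n
  if (chemo_active) out <- out - params$AD_t * d * n
  out
}

#' Reaction term of the vessel-density field
#'
#' The local part of the vasculature dynamics: the cubic self-interaction
#' `m (alpha_t + beta_t m + gamma_t m^2)`, the pro-angiogenic drive by tumour
#' cells `alpha2_t * n * m`, and -- when antiangiogenic therapy is active --
#' the vessel-disruption term `-AC_t * c * m`.
#'
#' @param n,m,cc numeric arrays: tumour-cell density, vessel density, free
#'   antiangiogenic concentration.
#' @param params an [model_params()] object.
#' @param anti_active logical; include the antiangiogenic term.
#' @return array of the same shape as `m`.
#' @export
rhs_m <- function(n, m, cc = 0 * m, params = paper_defaults("lung"),
                  anti_active = FALSE) {
  check_fields(n = n, m = m, cc = cc)
  out <- m * (params$alpha_t + params$beta_t * m + params$gamma_t * m^2) +
    params$alpha2_t * n * m
  if (anti_active) out <- out - params$AC_t * cc * m
  out
}

check_fields <- function(...) {
  fields <- list(...)
  dims <- lapply(fields, function(f) dim(f) %||% length(f))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
    stop("field shape mismatch: ",
         paste(names(fields), vapply(dims, paste, "", collapse = "x"),
               sep = "=", collapse = ", "))
  }
  for (nm in names(fields)) {
    if (any(fields[[nm]] < 0)) {
      stop("field ", nm, " contains negative values")
    }
  }
  invisible(NULL)
}

#' Homogeneous fixed points of the coupled tumour--vasculature system
#'
#' For the published cubic coefficients (-1, 3, -2) the nontrivial uniform
#' steady states of the vessel field, with the tumour field slaved to
#' `n* = 1 + alpha1_t m*`, solve the quadratic
#' `-2 m^2 + (3 + alpha1_t alpha2_t) m + (alpha2_t - 1) = 0`, giving
#' `m* = (3 + a12 +/- sqrt(8 (alpha2_t - 1) + (3 + a12)^2)) / 4` with
#' `a12 = alpha1_t alpha2_t`. For any other cubic coefficients the steady
#' state is found numerically from the polynomial
#' `alpha_t + alpha2_t + (beta_t + alpha1_t alpha2_t) m + gamma_t m^2 = 0`.
#'
#' @param params an [model_params()] object.
#' @return numeric vector of the two nonnegative roots in increasing order.
#'   A root of the quadratic that falls below zero (possible for
#'   `alpha2_t > 1`) is reported as 0, the vessel-free branch, which is a
#'   fixed point of the full dynamics in its own right. A negative
#'   discriminant (no real uniform fixed points) raises a condition of
#'   class `nt_no_fixed_points`.
#' @seealso [tumor_fixed_point()], [fixed_point_stability()]
#' @export
#' @examples
#' round(vasculature_fixed_points(paper_defaults("lung")), 2) # 0.02 1.97
vasculature_fixed_points <- function(params) {
  a1 <- params$alpha1_t; a2 <- params$alpha2_t
  canonical <- isTRUE(all.equal(
    c(params$alpha_t, params$beta_t, params$gamma_t), c(-1, 3, -2)))
  if (canonical) {
    disc <- 8 * (a2 - 1) + (3 + a1 * a2)^2
    if (disc < 0) {
      stop(errorCondition("no real fixed points: negative discriminant",
                          class = c("nt_no_fixed_points", "error",
                                    "condition")))
    }
    roots <- ((3 + a1 * a2) + c(-1, 1) * sqrt(disc)) / 4
  } else {
    # general cubic coefficients: numeric root-finding on the steady state
    z <- polyroot(c(params$alpha_t + a2, params$beta_t + a1 * a2,
                    params$gamma_t))
    re <- Re(z)[abs(Im(z)) < 1e-9]
    if (length(re) < 2) {
      stop(errorCondition("no real fixed points for these cubic coefficients",
                          class = c("nt_no_fixed_points", "error",
                                    "condition")))
    }
    roots <- sort(re)
  }
  sort(pmax(roots, 0))
}

#' Tumour-cell density at a uniform vessel fixed point
#'
#' The carrying capacity of the tumour field shifts with local vasculature:
#' the stable uniform tumour state is `n* = 1 + alpha1_t m*`.
#'
#' @param m_star nonnegative vessel density at the fixed point.
#' @param alpha1_t vasculature -> tumour coupling.
#' @return `1 + alpha1_t * m_star`.
#' @export
tumor_fixed_point <- function(m_star, alpha1_t) {
  stopifnot(all(m_star >= 0))
  1 + alpha1_t * m_star
}

#' Linear stability of the uniform fixed points
#'
#' Evaluates the 2x2 reaction Jacobian of `(n, m)` at each uniform fixed
#' point (including the vessel-free state `(1, 0)`) and classifies each by
#' the sign of the leading eigenvalue.
#'
#' @param params an [model_params()] object.
#' @return data.frame with columns `m_star`, `n_star`, `lambda1`, `lambda2`
#'   (eigenvalues, decreasing real part) and `stable`.
#' @export
fixed_point_stability <- function(params) {
  ms <- c(0, vasculature_fixed_points(params))
  rows <- lapply(ms, function(m) {
    n <- tumor_fixed_point(m, params$alpha1_t)
    J <- reaction_jacobian(n, m, params)
    ev <- eigen(J, only.values = TRUE)$values
    ev <- ev[order(-Re(ev))]
    data.frame(m_star = m, n_star = n,
               lambda1 = Re(ev[1]), lambda2 = Re(ev[2]),
               stable = all(Re(ev) < 0))
  })
  do.call(rbind, rows)
}

#' Reaction Jacobian of the drug-free (n, m) subsystem at a uniform state
#'
#' @param n,m scalars: the uniform state.
#' @param params an [model_params()] object.
#' @return 2x2 matrix, rows/cols ordered (n, m).
#' @export
reaction_jacobian <- function(n, m, params) {
  matrix(c(
    1 - 2 * n + params$alpha1_t * m,                      params$alpha1_t * n,
    params$alpha2_t * m,
    params$alpha_t + 2 * params$beta_t * m + 3 * params$gamma_t * m^2 +
      params$alpha2_t * n
  ), nrow = 2, byrow = TRUE)
}

#' Vascular delivery-efficiency factor
#'
#' Carrier extravasation is limited by the quality of the local vasculature:
#' absent vessels deliver nothing, and the dense, abnormal vessels of an
#' untreated tumour (m around 2) deliver poorly, so efficiency is a unimodal
#' function of vessel density. Two published variants of the kernel are
#' provided:
#' \describe{
#'   \item{`as_printed`}{`m * exp(-(m / m_lim)^2)`, with maximum at
#'     `m_lim / sqrt(2)`.}
#'   \item{`max_at_one`}{`m * exp(-m^2 / m_lim)`, whose maximum sits exactly
#'     at `m = 1` when `m_lim = 2`, matching the interpretation that normal
#'     vasculature (m = 1) delivers best.}
#' }
#' The two variants disagree on where the peak lies (see the package
#' vignette); `as_printed` is the default everywhere.
#'
#' @param m vessel density, scalar or array, nonnegative.
#' @param m_lim positive scale of the kernel.
#' @param form `"as_printed"` (default) or `"max_at_one"`.
#' @return same shape as `m`.
#' @export
#' @examples
#' delivery_efficiency(1, 2)               # exp(-1/4)
#' optimize(function(m) -delivery_efficiency(m, 2), c(0, 4))$minimum # ~1.414
delivery_efficiency <- function(m, m_lim,
                                form = c("as_printed", "max_at_one")) {
  form <- match.arg(form)
  stopifnot(m_lim > 0, all(m >= 0))
  if (form == "as_printed") {
    m * exp(-(m / m_lim)^2)
  } else {
    m * exp(-m^2 / m_lim)
  }
}
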