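#' Model parameters for the tumour--vasculature--therapy system
#'
#' Constructs the full parameter set of the coupled model: the dimensionless
#' reaction--diffusion coefficients of the tumour-cell field `n` and the
#' vessel-density field `m`, the carrier-uptake and drug-release coefficients,
#' the therapy strengths, and the dimensionful scales (`D1`, `rho`) used to
#' convert between days/millimetres and dimensionless units.
#'
#' `paper_defaults()` returns the published calibration for either Lewis lung
#' carcinoma or B16/F10 melanoma; the two cancers differ only in the
#' tumour-cell diffusivity `D1` and the two therapy strengths `AC_t`, `AD_t`.
#' By construction `lambdaC_t = 100 * lambdaD_t` (a hundred times more
#' combretastatin than doxorubicin is administered) and `D4_t = D3_t` (both
#' free agents diffuse like small nutrient molecules).
#'
#' @param cancer `"lung"` or `"melanoma"`: selects the published defaults.
#' @param ... named overrides for any field below.
#'
#' @return An object of class `nt_params`: a named list with fields
#' \describe{
#'   \item{alpha1_t}{vasculature -> tumour growth coupling (dimensionless).}
#'   \item{D2_t}{vessel diffusivity (dimensionless).}
#'   \item{alpha_t, beta_t, gamma_t}{cubic self-interaction coefficients of
#'     the vessel field; defaults (-1, 3, -2) give stable states at m = 0
#'     and m = 1 and an unstable state at 1/2.}
#'   \item{alpha2_t}{tumour -> vasculature coupling (dimensionless).}
#'   \item{delta_t}{carrier uptake coefficient (dimensionless).}
#'   \item{m_lim}{scale of the vascular delivery-efficiency factor.}
#'   \item{D3_t, D4_t}{free-drug diffusivities (dimensionless).}
#'   \item{lambdaC_t, lambdaD_t}{release amplitudes of the antiangiogenic (C)
#'     and chemotherapeutic (D) agents.}
#'   \item{nuC_t, nuD_t}{natural decay rates of the free agents.}
#'   \item{mu_t}{reabsorption rate of free chemotherapeutic drug into
#'     vessels (the trapping term).}
#'   \item{AC_t, AD_t}{therapy strengths: kill rates per unit free drug.}
#'   \item{D1}{tumour-cell diffusivity, mm^2/day.}
#'   \item{rho}{net proliferation rate, 1/day.}
#'   \item{c_th}{detectability threshold on the dimensionless cell density.}
#'   \item{sigma0}{width of the Gaussian initial tumour seed (dimensionless).}
#' }
#' @export
#' @examples
#' p <- paper_defaults("lung")
#' p$alpha1_t
#' vasculature_fixed_points(p)
paper_defaults <- function(cancer = c("lung", "melanoma"), ...) {
  cancer <- match.arg(cancer)
  base <- list(
    alpha1_t  = 1.1,
    D2_t      = 0.005,
    alpha_t   = -1,
    beta_t    = 3,
    gamma_t   = -2,
    alpha2_t  = 0.9,
    delta_t   = 0.8,
    m_lim     = 2,
    D3_t      = 0.02,
    D4_t      = 0.02,
    lambdaD_t = 13,
    lambdaC_t = 1300,
    nuC_t     = 3,
    nuD_t     = 0.1,
    mu_t      = 8,
    rho       = 0.35,
    c_th      = 0.09,
    sigma0    = 0.35
  )
  if (cancer == "lung") {
    base$D1 <- 0.32; base$AC_t <- 0.1; base$AD_t <- 1.65
  } else {
    base$D1 <- 0.46; base$AC_t <- 0.3; base$AD_t <- 3
  }
  model_params(.defaults = base, ...)
}

#' @rdname paper_defaults
#' @param .defaults internal: a complete base list to override.
#' @export
model_params <- function(..., .defaults = paper_defaults("lung")) {
  over <- list(...)
  over <- over[nzchar(names(over) %||% character(0))]
  p <- unclass(.defaults)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown) > 0) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  }
  p[names(over)] <- over
  p <- lapply(p, as.numeric)
  class(p) <- "nt_params"
  validate_params(p)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a parameter set
#'
#' Checks the sign constraints the model requires: rates, diffusivities and
#' amplitudes nonnegative; `m_lim`, `rho`, `D1` strictly positive.
#'
#' @param p an `nt_params` object.
#' @return `p`, invisibly; errors on violation.
#' @export
validate_params <- function(p) {
  nonneg <- c("alpha1_t", "D2_t", "alpha2_t", "delta_t", "D3_t", "D4_t",
              "lambdaC_t", "lambdaD_t", "nuC_t", "nuD_t", "mu_t",
              "AC_t", "AD_t", "c_th", "sigma0")
  for (k in nonneg) {
    if (is.na(p[[k]]) || p[[k]] < 0) {
      stop("parameter ", k, " must be nonnegative")
    }
  }
  for (k in c("m_lim", "rho", "D1")) {
    if (is.na(p[[k]]) || p[[k]] <= 0) {
      stop("parameter ", k, " must be strictly positive")
    }
  }
  invisible(p)
}

#' @export
print.nt_params <- function(x, ...) {
  cat("<nt_params> coupled tumour-vasculature-therapy parameters\n")
  flat <- unlist(unclass(x))
  print(flat)
  invisible(x)
}

#' Serialize / restore a parameter set
#'
#' Parameter sets round-trip through a flat key-value document. The format is
#' chosen from the file extension: `.json` uses JSON, `.yaml`/`.yml` uses
#' YAML.
#'
#' @param p an `nt_params` object.
#' @param path file to write or read.
#' @return `read_params()` returns an `nt_params` object; `write_params()`
#'   returns `path` invisibly.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "nt_params"))
  flat <- lapply(unclass(p), as.numeric)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(flat, path, precision = 15)
  } else {
    stop("unsupported extension for parameter file: ", path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  flat <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported extension for parameter file: ", path)
  }
  do.call(model_params, c(flat, list(.defaults = paper_defaults("lung"))))
}
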