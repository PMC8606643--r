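#' Structural and variability parameters of the Emax time-course model
#'
#' Bundles the fixed effects of the drug-effect time course with the
#' variability terms of the mixed-effects meta-analysis model:
#' the maximal placebo-adjusted change `emax` (percent of baseline BMI,
#' negative for weight loss), the treatment duration `et50` (weeks) at which
#' half of `emax` is reached, the inter-study standard deviations
#' `omega_emax` and `omega_et50` of the study-level random effects, and the
#' residual scale `sigma`. `sigma` is the residual standard deviation for an
#' arm of 100 subjects; an observation backed by `n` subjects has residual
#' variance `sigma^2 / (n / 100)`.
#'
#' @param emax Maximal placebo-adjusted BMI change, percent of baseline
#'   (negative = loss).
#' @param et50 Treatment duration to half-maximal effect, weeks; must be
#'   positive.
#' @param omega_emax,omega_et50 Inter-study variability magnitudes
#'   (standard deviations of the study-level random effects); nonnegative.
#' @param sigma Residual scale for an arm of N = 100 subjects; nonnegative.
#'
#' @return An object of class `emax_params`.
#' @examples
#' emax_params(emax = -1.51, et50 = 0.5, sigma = 0.414)
#' @export
emax_params <- function(emax, et50, omega_emax = 0, omega_et50 = 0, sigma = 0) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    as.double(x)
  }
  emax <- num1(emax, "emax")
  et50 <- num1(et50, "et50")
  if (et50 <= 0) stop("'et50' must be positive (weeks)", call. = FALSE)
  omega_emax <- num1(omega_emax, "omega_emax")
  omega_et50 <- num1(omega_et50, "omega_et50")
  sigma <- num1(sigma, "sigma")
  if (omega_emax < 0 || omega_et50 < 0 || sigma < 0)
    stop("variability magnitudes ('omega_emax', 'omega_et50', 'sigma') must be >= 0",
         call. = FALSE)
  structure(
    list(emax = emax, et50 = et50, omega_emax = omega_emax,
         omega_et50 = omega_et50, sigma = sigma),
    class = "emax_params"
  )
}

#' @export
print.emax_params <- function(x, ...) {
  cat("Emax time-course parameters\n")
  cat(sprintf("  emax       %8.4g %% (maximal BMI change)\n", x$emax))
  cat(sprintf("  et50       %8.4g weeks (half-maximal duration)\n", x$et50))
  cat(sprintf("  omega_emax %8.4g (inter-study SD)\n", x$omega_emax))
  cat(sprintf("  omega_et50 %8.4g (inter-study SD)\n", x$omega_et50))
  cat(sprintf("  sigma      %8.4g (residual scale, N = 100)\n", x$sigma))
  invisible(x)
}

#' Declare a covariate effect on a structural parameter
#'
#' A covariate submodel maps a study-level covariate value onto the typical
#' value of `emax` or `et50`. Three forms are supported: `linear_shift`
#' (`p + (cov - ref) * theta`), `power` (`p * (cov / ref)^theta`), and
#' `categorical_shift` (`p + cov * theta` with `cov` coded 0/1). Continuous
#' forms are centred at a reference value `reference`, conventionally the
#' population median; when `NULL` it is resolved to the median of the
#' covariate across studies at fit time.
#'
#' @param target Parameter the covariate acts on, `"emax"` or `"et50"`.
#' @param name Name of the covariate column in the study-level covariate
#'   table.
#' @param form One of `"linear_shift"`, `"power"`, `"categorical_shift"`.
#' @param theta Coefficient; estimated during fitting (this value is the
#'   starting value, or the generating value in simulation configs).
#' @param reference Reference (median) covariate value for the continuous
#'   forms; must be `NULL` for `categorical_shift`.
#'
#' @return An object of class `covariate_spec`.
#' @seealso [apply_covariate()], [covariate_search()]
#' @export
covariate_spec <- function(target = c("emax", "et50"), name,
                           form = c("linear_shift", "power", "categorical_shift"),
                           theta = 0, reference = NULL) {
  target <- match.arg(target)
  form <- match.arg(form)
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stop("'name' must be a non-empty string", call. = FALSE)
  if (!is.numeric(theta) || length(theta) != 1 || !is.finite(theta))
    stop("'theta' must be a single finite number", call. = FALSE)
  if (form == "categorical_shift" && !is.null(reference))
    stop("'reference' must be NULL for a categorical_shift covariate", call. = FALSE)
  if (!is.null(reference)) {
    if (!is.numeric(reference) || length(reference) != 1 || !is.finite(reference))
      stop("'reference' must be a single finite number or NULL", call. = FALSE)
    reference <- as.double(reference)
  }
  structure(
    list(target = target, name = name, form = form,
         theta = as.double(theta), reference = reference),
    class = "covariate_spec"
  )
}

#' @export
print.covariate_spec <- function(x, ...) {
  ref <- if (is.null(x$reference)) "median at fit time" else format(x$reference)
  cat(sprintf("covariate '%s' on %s (%s), theta = %g, reference = %s\n",
              x$name, x$target, x$form, x$theta,
              if (x$form == "categorical_shift") "-" else ref))
  invisible(x)
}

re_forms <- c("exponential", "additive", "none")

#' Model specification for the Emax meta-analysis model
#'
#' Combines initial structural parameter values, the functional form of the
#' inter-study random effects on `emax` and `et50` (`"exponential"`:
#' `p * exp(eta)`; `"additive"`: `p + eta`; `"none"`), and any covariate
#' submodels.
#'
#' @param init An [emax_params()] object with starting values.
#' @param re_emax,re_et50 Random-effect form for each parameter.
#' @param covariates A list of [covariate_spec()] objects.
#'
#' @return An object of class `model_spec`.
#' @seealso [fit_emax()], [read_model_spec()]
#' @export
model_spec <- function(init = emax_params(-1, 1, 0.1, 0.1, 0.3),
                       re_emax = c("exponential", "additive", "none"),
                       re_et50 = c("exponential", "additive", "none"),
                       covariates = list()) {
  if (!inherits(init, "emax_params"))
    stop("'init' must be an emax_params object", call. = FALSE)
  re_emax <- match.arg(re_emax)
  re_et50 <- match.arg(re_et50)
  if (!is.list(covariates) ||
      !all(vapply(covariates, inherits, logical(1), "covariate_spec")))
    stop("'covariates' must be a list of covariate_spec objects", call. = FALSE)
  structure(
    list(init = init, re_emax = re_emax, re_et50 = re_et50,
         covariates = covariates),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Emax MBMA model specification\n")
  cat(sprintf("  random effects: emax = %s, et50 = %s\n", x$re_emax, x$re_et50))
  cat(sprintf("  covariates: %d\n", length(x$covariates)))
  for (cv in x$covariates) {
    cat("   - "); print(cv)
  }
  cat("  initial values:\n")
  print(x$init)
  invisible(x)
}

#' Serialize a model specification to YAML
#'
#' @param spec A [model_spec()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  obj <- list(
    init = unclass(spec$init),
    re_emax = spec$re_emax,
    re_et50 = spec$re_et50,
    covariates = lapply(spec$covariates, unclass)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a model specification from YAML
#'
#' @param path Path to a YAML file written by [write_model_spec()] (or
#'   hand-authored with the same fields).
#' @return A [model_spec()] object.
#' @export
read_model_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  init <- do.call(emax_params, obj$init)
  covs <- lapply(obj$covariates %||% list(), function(cv) {
    covariate_spec(target = cv$target, name = cv$name, form = cv$form,
                   theta = cv$theta %||% 0, reference = cv$reference)
  })
  model_spec(init = init,
             re_emax = obj$re_emax %||% "none",
             re_et50 = obj$re_et50 %||% "none",
             covariates = covs)
}
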