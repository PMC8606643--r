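#' Emax time-course drug effect
#'
#' The structural model of the meta-analysis: the placebo-adjusted effect at
#' treatment duration `time` is `emax * time / (et50 + time)`. The effect is
#' 0 at time 0, monotone in time, and approaches `emax` asymptotically;
#' `et50` is the duration at which half the maximal effect is reached.
#'
#' @param emax Maximal effect (percent BMI change; negative = loss).
#' @param et50 Half-maximal treatment duration, weeks (> 0).
#' @param time Treatment duration(s), weeks (>= 0); vectorized.
#'
#' @return Effect(s) at `time`, same units as `emax`.
#' @examples
#' emax_effect(-1.51, 0.5, c(0.5, 2, 4.5, 9.5)) / -1.51  # fractions of emax
#' @seealso [time_to_fraction()] for the inverse problem.
#' @export
emax_effect <- function(emax, et50, time) {
  if (!is.numeric(et50) || length(et50) != 1 || !is.finite(et50) || et50 <= 0)
    stop("'et50' must be a single positive number (weeks)", call. = FALSE)
  if (any(!is.finite(time)) || any(time < 0))
    stop("'time' must be finite and nonnegative (weeks)", call. = FALSE)
  emax * time / (et50 + time)
}

#' Treatment duration needed to reach a fraction of the maximal effect
#'
#' Closed-form inversion of the Emax time course: solving
#' `f = t / (et50 + t)` for `t` gives `t = f * et50 / (1 - f)`. By
#' construction `emax_effect(emax, et50, time_to_fraction(f, et50))` equals
#' `f * emax` exactly, for any `emax`.
#'
#' @param fraction Target fraction(s) of the maximal effect, in (0, 1);
#'   vectorized.
#' @param et50 Half-maximal treatment duration, weeks (> 0).
#'
#' @return Duration(s) in weeks.
#' @examples
#' time_to_fraction(c(0.5, 0.8, 0.9, 0.95), et50 = 0.5)
#' @export
time_to_fraction <- function(fraction, et50) {
  if (!is.numeric(et50) || length(et50) != 1 || !is.finite(et50) || et50 <= 0)
    stop("'et50' must be a single positive number (weeks)", call. = FALSE)
  if (any(!is.finite(fraction)) || any(fraction <= 0) || any(fraction >= 1))
    stop("'fraction' must lie strictly between 0 and 1", call. = FALSE)
  fraction * et50 / (1 - fraction)
}

#' Apply a study-level random effect to a parameter
#'
#' The inter-study variability model: `exponential` multiplies the typical
#' value by `exp(eta)` (sign-preserving, keeps a positive parameter
#' positive), `additive` adds `eta` (can change sign), `none` returns the
#' value unchanged.
#'
#' @param value Typical parameter value.
#' @param eta Random deviate (study-level).
#' @param form `"exponential"`, `"additive"`, or `"none"`.
#' @return The study-level parameter value.
#' @export
apply_random_effect <- function(value, eta,
                                form = c("exponential", "additive", "none")) {
  form <- match.arg(form)
  switch(form,
         exponential = value * exp(eta),
         additive = value + eta,
         none = value)
}

#' Apply a covariate submodel to a typical parameter value
#'
#' Evaluates the declared covariate relationship at a covariate value:
#' `linear_shift` gives `p + (cov - ref) * theta`, `power` gives
#' `p * (cov / ref)^theta` (requires `cov > 0`), `categorical_shift` gives
#' `p + cov * theta` with `cov` coded 0/1. At the reference value (or at
#' category 0) every form is the identity.
#'
#' @param p_t Typical parameter value.
#' @param cov_value Covariate value for the study.
#' @param spec A [covariate_spec()]; its `reference` must be resolved
#'   (non-`NULL`) for the continuous forms.
#' @return The covariate-adjusted parameter value.
#' @export
apply_covariate <- function(p_t, cov_value, spec) {
  stopifnot(inherits(spec, "covariate_spec"))
  if (!is.numeric(cov_value) || length(cov_value) != 1 || !is.finite(cov_value))
    stop("'cov_value' must be a single finite number", call. = FALSE)
  switch(spec$form,
    linear_shift = {
      if (is.null(spec$reference))
        stop("covariate '", spec$name, "': unresolved reference value", call. = FALSE)
      p_t + (cov_value - spec$reference) * spec$theta
    },
    power = {
      if (is.null(spec$reference))
        stop("covariate '", spec$name, "': unresolved reference value", call. = FALSE)
      if (cov_value <= 0)
        stop("power-form covariate '", spec$name,
             "' requires a positive covariate value", call. = FALSE)
      p_t * (cov_value / spec$reference)^spec$theta
    },
    categorical_shift = p_t + cov_value * spec$theta
  )
}

# Compose all covariate submodels targeting one parameter, in declaration
# order (power forms multiply, shift forms add; the order is part of the
# model definition so that multi-covariate models are reproducible).
apply_covariates <- function(p_t, target, specs, cov_row) {
  for (sp in specs) {
    if (sp$target != target) next
    cv <- cov_row[[sp$name]]
    if (is.null(cv) || is.na(cv))
      stop("missing value for covariate '", sp$name, "'", call. = FALSE)
    p_t <- apply_covariate(p_t, as.numeric(cv), sp)
  }
  p_t
}
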