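# Synthetic aggregate-trial generator with stored ground truth, so every
# stage of the pipeline is testable end to end: the per-study BMI time
# courses behind published aggregate meta-analyses are generally not
# deposited, only the arm-level summaries.

# design template mirroring the packaged carnitine fixture: per-arm sizes
# 23-132, endpoint durations 12 weeks to 12 months
design_template <- function() {
  data.frame(
    n_intervention = c(31L, 132L, 129L, 40L, 41L, 38L, 46L, 23L),
    n_control = c(27L, 126L, 125L, 40L, 40L, 37L, 48L, 23L),
    time_weeks = c(26, 52, 52, 12, 13, 52 / 3, 26, 12),
    dose_g_per_day = c(2, 2, 2, 2, 2, 2, 2, 3))
}

#' Configuration of a synthetic aggregate-trial experiment
#'
#' Collects everything that defines a simulated two-arm trial set: the
#' generating ("truth") parameters, random-effect forms, the per-study
#' design (arm sizes, measurement times, baseline BMI distribution, dose
#' as inert metadata), an optional placebo time course for the control
#' arms (its own small Emax curve; it cancels in the placebo adjustment but
#' exercises the subtraction step), optional generating covariate effects,
#' and the seed. Regenerating with the same configuration reproduces the
#' dataset bit-identically.
#'
#' @param n_studies Number of studies; used only when `design` is `NULL`,
#'   in which case a realistic 8-study template (arm sizes 23-132, endpoint
#'   durations 12-52 weeks) is recycled to length.
#' @param truth Generating [emax_params()].
#' @param re_emax,re_et50 Random-effect forms used in generation.
#' @param design Optional data.frame with columns `study_id`,
#'   `n_intervention`, `n_control`, `time_weeks` (one row per study and
#'   measurement time), and optionally `dose_g_per_day`, `baseline_mean`,
#'   `baseline_sd`.
#' @param placebo List with `emax` and `et50` for the control-arm drift;
#'   default is no placebo response.
#' @param covariate_effects List of [covariate_spec()] objects with
#'   generating `theta` (continuous forms need a resolved `reference`;
#'   study values are drawn around it unless supplied via a `values`
#'   element added to the declaration).
#' @param baseline_mean,baseline_sd Defaults for the per-arm baseline BMI
#'   distribution (kg/m^2); arm baselines are drawn Normal and floored at
#'   15. The default mean of 30 reflects the obese type-2-diabetes
#'   population the model was built for.
#' @param seed Integer seed stored in the configuration.
#' @return A `sim_config` object.
#' @seealso [simulate_trials()], [carnitine_design()]
#' @export
sim_config <- function(n_studies = 8L,
                       truth = emax_params(-1.51, 0.5, 0, 0, 0.414),
                       re_emax = c("exponential", "additive", "none"),
                       re_et50 = c("exponential", "additive", "none"),
                       design = NULL,
                       placebo = list(emax = 0, et50 = 4),
                       covariate_effects = list(),
                       baseline_mean = 30, baseline_sd = 2,
                       seed = 1L) {
  re_emax <- match.arg(re_emax)
  re_et50 <- match.arg(re_et50)
  if (!inherits(truth, "emax_params"))
    stop("'truth' must be an emax_params object", call. = FALSE)
  if (is.null(design)) {
    if (!is_count(n_studies))
      stop("'n_studies' must be a positive integer", call. = FALSE)
    tpl <- design_template()
    rows <- ((seq_len(n_studies) - 1L) %% nrow(tpl)) + 1L
    design <- tpl[rows, , drop = FALSE]
    design$study_id <- sprintf("sim%02d", seq_len(n_studies))
  }
  req <- c("study_id", "n_intervention", "n_control", "time_weeks")
  missing <- setdiff(req, names(design))
  if (length(missing))
    stop("design lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"dose_g_per_day" %in% names(design)) design$dose_g_per_day <- 2
  if (!"baseline_mean" %in% names(design)) design$baseline_mean <- baseline_mean
  if (!"baseline_sd" %in% names(design)) design$baseline_sd <- baseline_sd
  bad <- character()
  if (any(design$n_intervention < 2) || any(design$n_control < 2))
    bad <- c(bad, "arm sizes must be >= 2")
  if (any(design$time_weeks <= 0))
    bad <- c(bad, "measurement times must be > 0 weeks")
  if (any(design$baseline_mean <= 0))
    bad <- c(bad, "baseline BMI mean must be > 0")
  if (!is.list(placebo) || !all(c("emax", "et50") %in% names(placebo)) ||
      placebo$et50 <= 0)
    bad <- c(bad, "placebo model needs 'emax' and a positive 'et50'")
  if (!all(vapply(covariate_effects, inherits, logical(1), "covariate_spec")))
    bad <- c(bad, "covariate_effects must be covariate_spec objects")
  if (length(bad))
    stop("invalid simulation config: ", paste(bad, collapse = "; "),
         call. = FALSE)
  design <- design[order(design$study_id, design$time_weeks), , drop = FALSE]
  rownames(design) <- NULL
  structure(
    list(n_studies = length(unique(design$study_id)), truth = truth,
         re_emax = re_emax, re_et50 = re_et50, design = design,
         placebo = placebo, covariate_effects = covariate_effects,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Synthetic trial configuration: %d studies, seed %d\n",
              x$n_studies, x$seed))
  cat(sprintf("  random effects: emax = %s, et50 = %s; %d covariate effect(s)\n",
              x$re_emax, x$re_et50, length(x$covariate_effects)))
  print(x$truth)
  invisible(x)
}

#' Simulation design matching the packaged carnitine trials
#'
#' Builds a [sim_config()] whose design is the 8 l-carnitine studies of the
#' packaged fixture — exact per-arm sample sizes, doses, and endpoint
#' durations — and whose generating parameters default to the published
#' final-model estimates (Emax -1.51%, ET50 0.5 weeks, omega_Emax 1.345,
#' omega_ET50 0.003, sigma 0.414).
#'
#' @param truth Generating [emax_params()].
#' @param re_emax,re_et50 Random-effect forms for generation.
#' @param seed Integer seed.
#' @param ... Passed on to [sim_config()] (e.g. `placebo`,
#'   `covariate_effects`).
#' @return A `sim_config` with 8 studies.
#' @export
carnitine_design <- function(truth = emax_params(-1.51, 0.5, 1.345, 0.003, 0.414),
                             re_emax = "exponential", re_et50 = "exponential",
                             seed = 1L, ...) {
  tab <- carnitine_trials()
  tab <- tab[tab$drug == "l-carnitine", , drop = FALSE]
  ints <- tab[tab$arm == "intervention", , drop = FALSE]
  ctls <- tab[tab$arm == "control", , drop = FALSE]
  design <- data.frame(
    study_id = ints$study_id,
    n_intervention = ints$n,
    n_control = ctls$n[match(ints$study_id, ctls$study_id)],
    time_weeks = ints$time_weeks,
    dose_g_per_day = ints$dose_g_per_day,
    stringsAsFactors = FALSE)
  sim_config(truth = truth, re_emax = re_emax, re_et50 = re_et50,
             design = design, seed = seed, ...)
}

#' Simulate an aggregate two-arm trial dataset
#'
#' Forward simulation under the model's own assumptions. Per study: draw
#' the random effects, apply generating covariate effects to the typical
#' Emax/ET50, then per arm draw a baseline BMI and, at each design time,
#' a change rate — the placebo curve for the control arm, placebo plus the
#' study-level drug-effect curve for the intervention arm — with residual
#' noise of standard deviation `sigma / sqrt(n / 100)` (arm of `n`
#' subjects). Raw BMI values are back-computed from the baseline so that
#' the change-rate preprocessing recovers the generated rates exactly.
#'
#' @param config A [sim_config()].
#' @return A `sim_bundle`: `table` (a raw `study_table` with both arms and
#'   time-0 rows), `truth` (the config), and `noiseless_adjusted` (an
#'   `effect_series` of the generating placebo-adjusted effects with no
#'   residual and no random effects).
#' @export
simulate_trials <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- config$truth
  des <- config$design
  studies <- unique(des$study_id)

  with_seed(config$seed, {
    rows <- list()
    noiseless <- list()
    cov_tab <- NULL
    for (s in studies) {
      d <- des[des$study_id == s, , drop = FALSE]
      eta1 <- if (config$re_emax != "none" && truth$omega_emax > 0)
        stats::rnorm(1, 0, truth$omega_emax) else 0
      eta2 <- if (config$re_et50 != "none" && truth$omega_et50 > 0)
        stats::rnorm(1, 0, truth$omega_et50) else 0

      cov_row <- list(study_id = s)
      for (ce in config$covariate_effects) {
        val <- if (!is.null(ce$values)) {
          ce$values[[match(s, studies)]]
        } else if (ce$form == "categorical_shift") {
          stats::rbinom(1, 1, 0.5)
        } else {
          if (is.null(ce$reference))
            stop("generating covariate '", ce$name,
                 "' needs a resolved reference value", call. = FALSE)
          stats::rnorm(1, ce$reference, 0.15 * max(abs(ce$reference), 1))
        }
        cov_row[[ce$name]] <- val
      }
      emax_typ <- apply_covariates(truth$emax, "emax",
                                   config$covariate_effects, cov_row)
      et50_typ <- apply_covariates(truth$et50, "et50",
                                   config$covariate_effects, cov_row)
      emax_s <- if (config$re_emax == "none") emax_typ else
        apply_random_effect(emax_typ, eta1, config$re_emax)
      et50_s <- if (config$re_et50 == "none") et50_typ else
        apply_random_effect(et50_typ, eta2, config$re_et50)
      et50_s <- max(et50_s, 1e-6)

      base_int <- max(15, stats::rnorm(1, d$baseline_mean[1], d$baseline_sd[1]))
      base_ctl <- max(15, stats::rnorm(1, d$baseline_mean[1], d$baseline_sd[1]))

      mk_row <- function(arm, dose, n, t, bmi) {
        c(list(study_id = s, arm = arm, dose_g_per_day = dose, n = n,
               time = t, time_unit = "weeks", bmi = bmi),
          cov_row[setdiff(names(cov_row), "study_id")])
      }
      rws <- list(
        mk_row("intervention", d$dose_g_per_day[1], d$n_intervention[1], 0,
               base_int),
        mk_row("control", 0, d$n_control[1], 0, base_ctl))
      for (j in seq_len(nrow(d))) {
        t <- d$time_weeks[j]
        pl <- emax_effect(config$placebo$emax, config$placebo$et50, t)
        rate_ctl <- pl +
          stats::rnorm(1, 0, truth$sigma / sqrt(d$n_control[j] / 100))
        rate_int <- pl + emax_effect(emax_s, et50_s, t) +
          stats::rnorm(1, 0, truth$sigma / sqrt(d$n_intervention[j] / 100))
        rws <- c(rws, list(
          mk_row("intervention", d$dose_g_per_day[j], d$n_intervention[j], t,
                 base_int * (1 + rate_int / 100)),
          mk_row("control", 0, d$n_control[j], t,
                 base_ctl * (1 + rate_ctl / 100))))
        noiseless[[paste(s, j)]] <- data.frame(
          study_id = s, time_weeks = t,
          effect_pct = emax_effect(emax_typ, et50_typ, t),
          n_eff = min(d$n_intervention[j], d$n_control[j]),
          adjusted = TRUE, stringsAsFactors = FALSE)
      }
      rows <- c(rows, rws)
      if (length(cov_row) > 1)
        cov_tab <- rbind(cov_tab,
                         as.data.frame(cov_row, stringsAsFactors = FALSE))
    }
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    df$change_rate_pct <- NA_real_
    first <- c("study_id", "arm", "dose_g_per_day", "n", "time", "time_unit",
               "bmi", "change_rate_pct")
    df <- df[, c(first, setdiff(names(df), first)), drop = FALSE]
    df$time_weeks <- df$time
    df$time <- NULL
    df$time_unit <- NULL
    df <- df[order(df$study_id, df$arm, df$time_weeks), , drop = FALSE]
    rownames(df) <- NULL
    first2 <- c("study_id", "arm", "dose_g_per_day", "n", "time_weeks",
                "bmi", "change_rate_pct")
    df <- df[, c(first2, setdiff(names(df), first2)), drop = FALSE]

    structure(
      list(table = new_study_table(df), truth = config,
           noiseless_adjusted = new_effect_series(
             do.call(rbind, noiseless), cov_tab)),
      class = "sim_bundle")
  })
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("Synthetic trial bundle: %d studies (seed %d)\n",
              x$truth$n_studies, x$truth$seed))
  cat("  generating parameters:\n")
  print(x$truth$truth)
  cat(sprintf("  table: %d rows; noiseless adjusted series: %d points\n",
              nrow(x$table), nrow(x$noiseless_adjusted)))
  invisible(x)
}
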