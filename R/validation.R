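# Bootstrap uncertainty, prediction-corrected VPC, Monte-Carlo prediction.

# flat named vector of estimated quantities for bootstrap summaries
param_vector <- function(fit) {
  p <- fit$params
  out <- c(emax = p$emax, et50 = p$et50)
  if (fit$spec$re_emax != "none") out <- c(out, omega_emax = p$omega_emax)
  if (fit$spec$re_et50 != "none") out <- c(out, omega_et50 = p$omega_et50)
  out <- c(out, sigma = p$sigma)
  if (!is.null(fit$thetas) && length(fit$thetas))
    out <- c(out, stats::setNames(as.numeric(fit$thetas),
                                  paste0("theta_", names(fit$thetas))))
  out
}

# build a resampled effect series from a vector of (possibly repeated)
# study ids; repeats get unique labels so they enter the likelihood as
# distinct studies
resample_series <- function(data, ids) {
  covs <- attr(data, "covariates")
  pieces <- vector("list", length(ids))
  cov_pieces <- if (!is.null(covs)) vector("list", length(ids))
  for (k in seq_along(ids)) {
    blk <- as.data.frame(data[data$study_id == ids[k], , drop = FALSE])
    new_id <- paste0(ids[k], "#", k)
    blk$study_id <- new_id
    pieces[[k]] <- blk
    if (!is.null(covs)) {
      cv <- covs[covs$study_id == ids[k], , drop = FALSE]
      if (nrow(cv)) {
        cv$study_id <- new_id
        cov_pieces[[k]] <- cv
      }
    }
  }
  new_covs <- if (!is.null(covs)) do.call(rbind, cov_pieces)
  new_effect_series(do.call(rbind, pieces), new_covs)
}

#' Study-level bootstrap of the fitted model
#'
#' Nonparametric bootstrap with the study as the resampling unit (the level
#' at which the model's heterogeneity lives): studies are resampled with
#' replacement `n_reps` times, each replicate is refitted starting from the
#' original estimates, and percentile summaries are computed over the
#' converged replicates. Replicates that fail to converge are dropped and
#' counted. Deterministic given `seed`.
#'
#' @param data An `effect_series`.
#' @param spec A [model_spec()].
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param init Optional starting values for the original fit.
#' @param n_starts Optimizer starts for the original fit (replicate refits
#'   use a single start from the original estimates).
#' @param .resample Optional function `(study_ids, replicate_index) ->
#'   study_ids` overriding the resampling mechanism (used for testing,
#'   e.g. an identity resample).
#' @return An `emax_bootstrap` object: a summary data.frame (`parameter`,
#'   `estimate`, `median`, `ci_low`, `ci_high`, `bias_pct`) plus counts.
#'   `bias_pct` is `(median - estimate) / estimate * 100`, `NA` when the
#'   estimate is 0. More than 50% failed replicates flags the summary as
#'   unreliable.
#' @export
bootstrap_emax <- function(data, spec, n_reps = 1000, seed = 1L,
                           init = NULL, n_starts = 3L, .resample = NULL) {
  stopifnot(inherits(data, "effect_series"), inherits(spec, "model_spec"))
  if (!is_count(n_reps)) stop("'n_reps' must be a positive integer", call. = FALSE)
  base <- fit_emax(spec, data, init = init, seed = derive_seed(seed, 0L),
                   n_starts = n_starts)
  if (!base$converged)
    stop("fit on the original data did not converge", call. = FALSE)
  est <- param_vector(base)
  studies <- unique(data$study_id)

  draw <- if (is.null(.resample)) {
    idx <- with_seed(derive_seed(seed, 1L),
                     matrix(sample.int(length(studies),
                                       n_reps * length(studies),
                                       replace = TRUE),
                            nrow = n_reps))
    function(r) studies[idx[r, ]]
  } else {
    function(r) .resample(studies, r)
  }

  reps <- matrix(NA_real_, n_reps, length(est),
                 dimnames = list(NULL, names(est)))
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    bdata <- resample_series(data, draw(r))
    f <- tryCatch(
      suppressWarnings(
        fit_emax(spec, bdata, init = base$params,
                 seed = derive_seed(seed, 100L + r), n_starts = 1L)),
      error = function(e) NULL)
    if (is.null(f) || !f$converged) {
      n_failed <- n_failed + 1L
      next
    }
    pv <- param_vector(f)
    reps[r, ] <- pv[names(est)]
  }
  ok <- stats::complete.cases(reps)
  if (!any(ok)) stop("all bootstrap replicates failed", call. = FALSE)
  med <- apply(reps[ok, , drop = FALSE], 2, stats::median)
  lo <- apply(reps[ok, , drop = FALSE], 2, stats::quantile, probs = 0.025)
  hi <- apply(reps[ok, , drop = FALSE], 2, stats::quantile, probs = 0.975)
  bias <- ifelse(est != 0, (med - est) / est * 100, NA_real_)
  structure(
    list(summary = data.frame(parameter = names(est), estimate = unname(est),
                              median = unname(med), ci_low = unname(lo),
                              ci_high = unname(hi), bias_pct = unname(bias),
                              stringsAsFactors = FALSE),
         replicates = reps[ok, , drop = FALSE],
         n_replicates = n_reps, n_failed = n_failed,
         unreliable = n_failed > n_reps / 2, seed = seed, fit = base),
    class = "emax_bootstrap")
}

#' @export
print.emax_bootstrap <- function(x, ...) {
  cat(sprintf("Study-level bootstrap: %d replicates (%d failed%s)\n",
              x$n_replicates, x$n_failed,
              if (x$unreliable) "; UNRELIABLE: >50% failures" else ""))
  df <- x$summary
  df[, -1] <- lapply(df[, -1], signif, 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

# Simulate one replicate effect series at the observed design from a fitted
# model (draws eta per study, residual per observation). Uses the current
# RNG stream; callers seed it.
simulate_effects <- function(fit, data = fit$data) {
  params <- fit$params
  spec <- fit$spec
  covspecs <- effective_covspecs(spec, fit$thetas)
  tv <- typical_values(params, covspecs, data)
  v <- params$sigma^2 / (data$n_eff / 100)
  y <- numeric(nrow(data))
  for (k in seq_along(tv$studies)) {
    idx <- which(data$study_id == tv$studies[k])
    e1 <- tv$emax[k]
    t5 <- tv$et50[k]
    if (spec$re_emax != "none" && params$omega_emax > 0)
      e1 <- apply_random_effect(e1, stats::rnorm(1, 0, params$omega_emax),
                                spec$re_emax)
    if (spec$re_et50 != "none" && params$omega_et50 > 0)
      t5 <- apply_random_effect(t5, stats::rnorm(1, 0, params$omega_et50),
                                spec$re_et50)
    t5 <- max(t5, 1e-6)
    t <- data$time_weeks[idx]
    y[idx] <- e1 * t / (t5 + t) + stats::rnorm(length(idx), 0, sqrt(v[idx]))
  }
  out <- as.data.frame(data)
  out$effect_pct <- y
  new_effect_series(out, attr(data, "covariates"))
}

#' Prediction-corrected visual predictive check
#'
#' Simulates `n_sims` replicate datasets at the observed design from the
#' fitted model, prediction-corrects every observation (observed and
#' simulated) by the ratio of its time-bin's median population prediction
#' to its own population prediction, and compares observed bin medians with
#' the simulated 2.5th-97.5th percentile envelope of bin medians. By
#' default each distinct design time is its own bin (aggregate-trial data
#' are too sparse for automatic binning); custom bin edges can be supplied.
#'
#' @param data Observed `effect_series`.
#' @param fit A converged `emax_fit`.
#' @param n_sims Number of Monte-Carlo replicates.
#' @param seed Integer seed.
#' @param bins Optional numeric vector of bin edges covering the observed
#'   times; `NULL` means one bin per distinct design time.
#' @return An `emax_pcvpc` object: per-bin table (`time`, `n_obs`,
#'   `obs_median`, `sim_median`, `sim_lo`, `sim_hi`, `inside`) plus the
#'   fraction of observed bin medians inside the envelope (`coverage`).
#' @export
pcvpc <- function(data, fit, n_sims = 500, seed = 1L, bins = NULL) {
  stopifnot(inherits(data, "effect_series"), inherits(fit, "emax_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  data <- new_effect_series(as.data.frame(data), attr(data, "covariates"))
  covspecs <- effective_covspecs(fit$spec, fit$thetas)
  tv <- typical_values(fit$params, covspecs, data)
  ki <- match(data$study_id, tv$studies)
  pred <- tv$emax[ki] * data$time_weeks / (tv$et50[ki] + data$time_weeks)

  if (is.null(bins)) {
    bin_id <- match(round(data$time_weeks, 6),
                    sort(unique(round(data$time_weeks, 6))))
    bin_time <- sort(unique(round(data$time_weeks, 6)))
  } else {
    if (min(bins) > min(data$time_weeks) || max(bins) < max(data$time_weeks))
      stop("'bins' must cover the observed time range", call. = FALSE)
    cutf <- cut(data$time_weeks, bins, include.lowest = TRUE)
    keep_lv <- levels(cutf)[tabulate(cutf, nbins = nlevels(cutf)) > 0]
    if (length(keep_lv) < nlevels(cutf))
      warning("empty bin(s) dropped", call. = FALSE)
    bin_id <- match(as.character(cutf), keep_lv)
    bin_time <- vapply(split(data$time_weeks, bin_id), stats::median,
                       numeric(1))
  }
  nb <- length(unique(bin_id))

  correct <- function(y, prd) {
    med_prd <- vapply(split(prd, bin_id), stats::median, numeric(1))
    ratio <- med_prd[bin_id] / prd
    ratio[!is.finite(ratio)] <- 1
    y * ratio
  }
  bin_medians <- function(y) {
    vapply(split(y, bin_id), stats::median, numeric(1))
  }

  obs_med <- bin_medians(correct(data$effect_pct, pred))
  sims <- with_seed(derive_seed(seed, 2L), {
    m <- matrix(NA_real_, n_sims, nb)
    for (s in seq_len(n_sims)) {
      ysim <- simulate_effects(fit, data)$effect_pct
      m[s, ] <- bin_medians(correct(ysim, pred))
    }
    m
  })
  lo <- apply(sims, 2, stats::quantile, probs = 0.025)
  mid <- apply(sims, 2, stats::median)
  hi <- apply(sims, 2, stats::quantile, probs = 0.975)
  inside <- obs_med >= lo & obs_med <= hi
  tab <- data.frame(time = bin_time, n_obs = as.integer(table(bin_id)),
                    obs_median = unname(obs_med), sim_median = unname(mid),
                    sim_lo = unname(lo), sim_hi = unname(hi),
                    inside = unname(inside))
  structure(list(table = tab, coverage = mean(inside), n_sims = n_sims,
                 bins = bins, seed = seed),
            class = "emax_pcvpc")
}

#' @export
print.emax_pcvpc <- function(x, ...) {
  cat(sprintf(
    "Prediction-corrected VPC: %d simulations, %d bins, %.0f%% of observed bin medians inside the 95%% envelope\n",
    x$n_sims, nrow(x$table), 100 * x$coverage))
  df <- x$table
  df[] <- lapply(df, function(col) if (is.numeric(col)) signif(col, 4) else col)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.emax_pcvpc <- function(x, ...) {
  tab <- x$table
  ylim <- range(tab$obs_median, tab$sim_lo, tab$sim_hi)
  plot(tab$time, tab$sim_median, type = "l", ylim = ylim,
       xlab = "time (weeks)", ylab = "prediction-corrected effect (%)",
       main = "Prediction-corrected VPC", ...)
  graphics::lines(tab$time, tab$sim_lo, lty = 2)
  graphics::lines(tab$time, tab$sim_hi, lty = 2)
  graphics::points(tab$time, tab$obs_median, pch = 19,
                   col = ifelse(tab$inside, "black", "red"))
  invisible(x)
}

#' Monte-Carlo prediction of the efficacy time course
#'
#' Simulates the population effect curve under inter-study variability:
#' `n_sims` random-effect draws produce a band of Emax time courses, summarized
#' by the median and 2.5th/97.5th percentiles over a time grid. With both
#' omegas zero the median curve equals [emax_effect()] exactly. The
#' parameter-free fraction of maximal effect, `t / (et50 + t)`, is returned
#' alongside, with milestone annotations at 50, 80, 90, and 95% of Emax.
#'
#' @param params An [emax_params()] object.
#' @param horizon Prediction horizon, weeks (> 0).
#' @param n_sims Number of Monte-Carlo draws.
#' @param seed Integer seed.
#' @param re_emax,re_et50 Random-effect forms used for the draws.
#' @param times Optional explicit time grid (weeks).
#' @return An `emax_prediction`: data.frame `time`, `median`, `lo`, `hi`,
#'   `fraction_of_emax`, with a `milestones` attribute (fractions 0.5, 0.8,
#'   0.9, 0.95 and the weeks at which they are reached).
#' @export
predict_efficacy <- function(params, horizon, n_sims = 1000, seed = 1L,
                             re_emax = c("exponential", "additive", "none"),
                             re_et50 = c("exponential", "additive", "none"),
                             times = NULL) {
  stopifnot(inherits(params, "emax_params"))
  re_emax <- match.arg(re_emax)
  re_et50 <- match.arg(re_et50)
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon <= 0)
    stop("'horizon' must be a single positive number of weeks", call. = FALSE)
  if (is.null(times)) times <- seq(0, horizon, length.out = 201)
  fr_marks <- c(0.5, 0.8, 0.9, 0.95)

  curves <- with_seed(derive_seed(seed, 3L), {
    m <- matrix(NA_real_, n_sims, length(times))
    for (s in seq_len(n_sims)) {
      e1 <- params$emax
      t5 <- params$et50
      if (re_emax != "none" && params$omega_emax > 0)
        e1 <- apply_random_effect(e1, stats::rnorm(1, 0, params$omega_emax),
                                  re_emax)
      if (re_et50 != "none" && params$omega_et50 > 0)
        t5 <- apply_random_effect(t5, stats::rnorm(1, 0, params$omega_et50),
                                  re_et50)
      t5 <- max(t5, 1e-6)
      m[s, ] <- e1 * times / (t5 + times)
    }
    m
  })
  out <- data.frame(
    time = times,
    median = apply(curves, 2, stats::median),
    lo = apply(curves, 2, stats::quantile, probs = 0.025),
    hi = apply(curves, 2, stats::quantile, probs = 0.975),
    fraction_of_emax = times / (params$et50 + times))
  milestones <- data.frame(
    fraction = fr_marks,
    time_weeks = time_to_fraction(fr_marks, params$et50),
    effect = fr_marks * params$emax)
  structure(out, milestones = milestones, params = params,
            class = c("emax_prediction", "data.frame"))
}

#' @export
print.emax_prediction <- function(x, ...) {
  cat(sprintf("Monte-Carlo efficacy prediction over %d time points\n", nrow(x)))
  ms <- attr(x, "milestones")
  cat("  milestones (fraction of Emax -> weeks):\n")
  for (i in seq_len(nrow(ms)))
    cat(sprintf("    %2.0f%% at %.3g weeks (effect %.3g%%)\n",
                100 * ms$fraction[i], ms$time_weeks[i], ms$effect[i]))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' @export
plot.emax_prediction <- function(x, ...) {
  plot(x$time, x$median, type = "l",
       ylim = range(x$lo, x$hi), xlab = "time (weeks)",
       ylab = "BMI change (%)", main = "Predicted efficacy time course", ...)
  graphics::lines(x$time, x$lo, lty = 2)
  graphics::lines(x$time, x$hi, lty = 2)
  ms <- attr(x, "milestones")
  graphics::abline(v = ms$time_weeks, col = "grey", lty = 3)
  invisible(x)
}
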