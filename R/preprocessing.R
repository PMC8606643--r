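#' Percent change from baseline
#'
#' The unit of effect throughout the analysis: the BMI change rate
#' `(e_t - e_b) / e_b * 100`, in percent of the baseline value. Signs are
#' preserved (weight loss is negative).
#'
#' @param e_t Outcome value(s) at time t.
#' @param e_b Baseline outcome value(s); must be positive.
#' @return Percent change(s) from baseline.
#' @examples
#' change_rate(24.5, 25)  # -2
#' @export
change_rate <- function(e_t, e_b) {
  if (any(!is.finite(e_b)) || any(e_b <= 0))
    stop("baseline value 'e_b' must be positive", call. = FALSE)
  (e_t - e_b) / e_b * 100
}

new_effect_series <- function(df, covariates = NULL) {
  df <- df[order(df$study_id, df$time_weeks), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, covariates = covariates,
            class = c("effect_series", "data.frame"))
}

#' Construct an effect series directly
#'
#' Builds the canonical estimation input — one row per (study, time) with a
#' placebo-adjusted percent effect and an effective sample size — from
#' vectors. Mostly useful in tests and simulations; real tables go through
#' [assemble_effect_series()].
#'
#' @param study_id Study labels.
#' @param time_weeks Times in weeks (> 0 for adjusted points).
#' @param effect_pct Placebo-adjusted percent change from baseline.
#' @param n_eff Effective sample sizes (>= 1).
#' @param adjusted Logical; whether the control arm has been subtracted.
#' @param covariates Optional study-level covariate data.frame with a
#'   `study_id` column.
#' @return An `effect_series` data.frame.
#' @export
effect_series <- function(study_id, time_weeks, effect_pct, n_eff,
                          adjusted = TRUE, covariates = NULL) {
  df <- data.frame(study_id = as.character(study_id),
                   time_weeks = as.numeric(time_weeks),
                   effect_pct = as.numeric(effect_pct),
                   n_eff = as.numeric(n_eff),
                   adjusted = rep_len(as.logical(adjusted), length(study_id)),
                   stringsAsFactors = FALSE)
  if (any(df$n_eff < 1)) stop("'n_eff' must be >= 1", call. = FALSE)
  if (any(df$time_weeks <= 0 & df$adjusted))
    stop("adjusted effect points must have time > 0", call. = FALSE)
  new_effect_series(df, covariates)
}

#' @export
print.effect_series <- function(x, ...) {
  cat(sprintf("Placebo-adjusted effect series: %d studies, %d points\n",
              length(unique(x$study_id)), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Subtract the control-arm time course from the intervention arm
#'
#' Removes shared trial effects (placebo response, co-medication, regression
#' to the mean) by differencing the two arms of one study at matched times:
#' the adjusted effect is `intervention - control`. Times are matched to
#' within 0.5 week after unit normalization — a tolerance that absorbs
#' floating error, not month/week rounding (13.0 weeks and 12 weeks remain
#' distinct). The effective sample size of an adjusted point is
#' `min(n_intervention, n_control)`, a conservative choice for the
#' sample-size-based residual weighting.
#'
#' @param intervention,control Data.frames with columns `study_id`,
#'   `time_weeks`, `effect_pct`, `n` (unadjusted per-arm change rates), both
#'   from the same study.
#' @param tol Time-matching tolerance in weeks.
#' @return An `effect_series` of adjusted points at the shared times.
#' @export
placebo_adjust <- function(intervention, control, tol = 0.5) {
  su_i <- unique(intervention$study_id)
  su_c <- unique(control$study_id)
  if (length(su_i) != 1 || length(su_c) != 1 || su_i != su_c)
    stop("arms must come from a single common study (got '",
         paste(su_i, collapse = ","), "' vs '",
         paste(su_c, collapse = ","), "')", call. = FALSE)
  out <- NULL
  for (k in seq_len(nrow(intervention))) {
    dt <- abs(control$time_weeks - intervention$time_weeks[k])
    m <- which.min(dt)
    if (length(m) == 0 || dt[m] > tol) next
    out <- rbind(out, data.frame(
      study_id = su_i,
      time_weeks = intervention$time_weeks[k],
      effect_pct = intervention$effect_pct[k] - control$effect_pct[m],
      n_eff = min(intervention$n[k], control$n[m]),
      adjusted = TRUE,
      stringsAsFactors = FALSE
    ))
  }
  if (is.null(out) || nrow(out) == 0)
    stop("no overlapping time points between arms of study '", su_i, "'",
         call. = FALSE)
  new_effect_series(out)
}

# per-arm change rates at t > 0 for one (study, arm) block
arm_change_rates <- function(block) {
  has_bmi <- any(!is.na(block$bmi))
  if (has_bmi) {
    b0 <- block[block$time_weeks == 0 & !is.na(block$bmi), , drop = FALSE]
    if (nrow(b0) != 1)
      stop("study '", block$study_id[1], "', arm '", block$arm[1],
           "': raw outcomes require exactly one time-0 (baseline) row",
           call. = FALSE)
    post <- block[block$time_weeks > 0, , drop = FALSE]
    data.frame(study_id = post$study_id, time_weeks = post$time_weeks,
               effect_pct = change_rate(post$bmi, b0$bmi), n = post$n,
               stringsAsFactors = FALSE)
  } else {
    post <- block[block$time_weeks > 0 & !is.na(block$change_rate_pct), ,
                  drop = FALSE]
    data.frame(study_id = post$study_id, time_weeks = post$time_weeks,
               effect_pct = post$change_rate_pct, n = post$n,
               stringsAsFactors = FALSE)
  }
}

#' Assemble placebo-adjusted effect series from an arm-level table
#'
#' Runs the preprocessing pipeline study by study: per-arm percent change
#' rates from baseline (skipped for rows that already carry
#' `change_rate_pct`), then control-arm subtraction at matched times.
#' Studies without a control arm are excluded with a warning. Baseline
#' (time-0) points are identically zero by construction, carry no
#' information for a model that passes through the origin, and are excluded.
#' Any non-canonical columns of the table are collected into a study-level
#' covariate table (first intervention-arm value per study).
#'
#' @param table A `study_table` with outcome data.
#' @return An `effect_series`; its `covariates` attribute holds the
#'   study-level covariate data.frame.
#' @export
assemble_effect_series <- function(table) {
  stopifnot(inherits(table, "study_table"))
  if (nrow(table) == 0) stop("empty study table", call. = FALSE)
  if (all(is.na(table$bmi)) && all(is.na(table$change_rate_pct)))
    stop("no outcome columns: table carries neither 'bmi' nor 'change_rate_pct'",
         call. = FALSE)

  studies <- unique(table$study_id)
  dropped <- 0L
  pieces <- list()
  for (s in studies) {
    st <- table[table$study_id == s, , drop = FALSE]
    if (!all(c("intervention", "control") %in% st$arm)) {
      dropped <- dropped + 1L
      next
    }
    int <- arm_change_rates(st[st$arm == "intervention", , drop = FALSE])
    ctl <- arm_change_rates(st[st$arm == "control", , drop = FALSE])
    pieces[[s]] <- placebo_adjust(int, ctl)
  }
  if (dropped > 0)
    warning(dropped, " study/studies without a control arm excluded",
            call. = FALSE)
  if (length(pieces) == 0)
    stop("no study with both arms and outcome data", call. = FALSE)
  df <- do.call(rbind, lapply(pieces, as.data.frame))

  extra <- setdiff(names(table), c(canonical_cols, "time_weeks"))
  covs <- NULL
  if (length(extra)) {
    ints <- table[table$arm == "intervention", , drop = FALSE]
    ints <- ints[!duplicated(ints$study_id), , drop = FALSE]
    covs <- ints[ints$study_id %in% df$study_id,
                 c("study_id", extra), drop = FALSE]
    rownames(covs) <- NULL
  }
  new_effect_series(df, covs)
}

#' Write an effect series to CSV
#'
#' Emits the tidy canonical estimation input: `study_id`, `time_weeks`,
#' `effect_pct`, `n_eff`, `adjusted` (plus study-level covariates joined
#' back on, when present).
#'
#' @param series An `effect_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_effect_series <- function(series, path) {
  stopifnot(inherits(series, "effect_series"))
  out <- as.data.frame(series)
  covs <- attr(series, "covariates")
  if (!is.null(covs)) out <- merge(out, covs, by = "study_id", sort = FALSE)
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]))
      out[[nm]] <- ifelse(is.na(out[[nm]]), "", sprintf("%.17g", out[[nm]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
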