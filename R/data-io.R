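#' @title Arm-level aggregate trial tables
#'
#' @description
#' The input to the meta-analysis is a long-format table with one row per
#' (study, arm, time point): columns `study_id`, `arm`
#' (`"intervention"`/`"control"`), `dose_g_per_day`, `n` (arm sample size),
#' `time` + `time_unit` (`"weeks"` or `"months"`), and at most one of `bmi`
#' (raw outcome, kg/m^2) or `change_rate_pct` (pre-computed percent change
#' from baseline). Any further columns are carried along as study-level
#' covariates / metadata. Times are normalized to weeks on read.
#'
#' @name study_table
NULL

canonical_cols <- c("study_id", "arm", "dose_g_per_day", "n",
                    "time", "time_unit", "bmi", "change_rate_pct")

default_colmap <- function() {
  stats::setNames(as.list(canonical_cols), canonical_cols)
}

new_study_table <- function(df) {
  class(df) <- c("study_table", "data.frame")
  df
}

#' Convert durations to weeks
#'
#' Published trial durations mix weeks and months; all internal times are in
#' weeks. Months are converted at 52/12 weeks per month (calendar-consistent:
#' 12 months = 52 weeks), so e.g. 3 months = 13.0 weeks — deliberately not
#' merged with a 12-week duration.
#'
#' @param value Duration value(s), nonnegative; vectorized.
#' @param unit `"weeks"` or `"months"` (scalar or vector recycled to
#'   `value`).
#' @return Duration(s) in weeks.
#' @examples
#' normalize_time(6, "months")  # 26
#' @export
normalize_time <- function(value, unit) {
  if (any(!is.finite(value)) || any(value < 0))
    stop("durations must be finite and nonnegative", call. = FALSE)
  unit <- rep_len(as.character(unit), length(value))
  bad <- !unit %in% c("weeks", "months")
  if (any(bad))
    stop("unknown time unit(s): ", paste(unique(unit[bad]), collapse = ", "),
         " (use 'weeks' or 'months')", call. = FALSE)
  ifelse(unit == "months", value * 52 / 12, value)
}

#' Read an arm-level aggregate trial table
#'
#' Reads a delimited text file (comma-separated, or tab-separated for
#' `.tsv`) of aggregate trial arms, validates it, and normalizes all times
#' to weeks. Rows may carry raw `bmi` outcomes or pre-computed
#' `change_rate_pct` values, but never both in one row; tables with neither
#' (study metadata only) are accepted and flagged, and can be used for
#' bookkeeping but not for effect assembly.
#'
#' @param path Path to the file.
#' @param format_spec Optional column mapping: a named list (or path to a
#'   YAML file containing one) mapping canonical column names (`study_id`,
#'   `arm`, `dose_g_per_day`, `n`, `time`, `time_unit`, `bmi`,
#'   `change_rate_pct`) to the names used in the file.
#'
#' @return A `study_table`: a data.frame with the canonical columns
#'   `study_id`, `arm`, `dose_g_per_day`, `n`, `time_weeks`, `bmi`,
#'   `change_rate_pct` plus any covariate columns from the file.
#' @seealso [write_study_table()], [carnitine_trials()]
#' @export
read_study_table <- function(path, format_spec = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(format_spec) && length(format_spec) == 1)
    format_spec <- yaml::read_yaml(format_spec)
  map <- utils::modifyList(default_colmap(), as.list(format_spec %||% list()))

  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.csv(path, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE)

  # rename mapped columns to canonical names
  for (canon in canonical_cols) {
    src <- map[[canon]]
    if (!is.null(src) && src %in% names(raw) && src != canon)
      names(raw)[names(raw) == src] <- canon
  }

  required <- c("study_id", "arm", "n", "time")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  if (nrow(raw) == 0) {
    warning("empty study table (header only): ", path, call. = FALSE)
    df <- data.frame(study_id = character(), arm = character(),
                     dose_g_per_day = numeric(), n = integer(),
                     time_weeks = numeric(), bmi = numeric(),
                     change_rate_pct = numeric(), stringsAsFactors = FALSE)
    return(new_study_table(df))
  }

  raw$study_id <- as.character(raw$study_id)
  raw$arm <- as.character(raw$arm)
  bad_arm <- !raw$arm %in% c("intervention", "control")
  if (any(bad_arm))
    stop("invalid arm value(s): ", paste(unique(raw$arm[bad_arm]), collapse = ", "),
         " (must be 'intervention' or 'control')", call. = FALSE)

  if (!all(is.finite(raw$n)) || any(raw$n < 1) || any(raw$n != round(raw$n)))
    stop("'n' must be positive integers (arm sample sizes)", call. = FALSE)
  if (any(!is.finite(raw$time)) || any(raw$time < 0))
    stop("'time' must be finite and nonnegative", call. = FALSE)

  unit <- if ("time_unit" %in% names(raw)) raw$time_unit else "weeks"
  raw$time_weeks <- normalize_time(raw$time, unit)

  has_bmi <- "bmi" %in% names(raw)
  has_cr <- "change_rate_pct" %in% names(raw)
  if (!has_bmi) raw$bmi <- NA_real_
  if (!has_cr) raw$change_rate_pct <- NA_real_
  raw$bmi <- as.numeric(raw$bmi)
  raw$change_rate_pct <- as.numeric(raw$change_rate_pct)
  both <- !is.na(raw$bmi) & !is.na(raw$change_rate_pct)
  if (any(both))
    stop("row(s) with both 'bmi' and 'change_rate_pct' present (studies: ",
         paste(unique(raw$study_id[both]), collapse = ", "),
         "); supply exactly one outcome per row", call. = FALSE)
  if (any(!is.na(raw$bmi) & raw$bmi <= 0))
    stop("'bmi' must be positive where present", call. = FALSE)

  if (!"dose_g_per_day" %in% names(raw)) raw$dose_g_per_day <- NA_real_
  raw$dose_g_per_day <- as.numeric(raw$dose_g_per_day)
  if (any(!is.na(raw$dose_g_per_day) & raw$dose_g_per_day < 0))
    stop("'dose_g_per_day' must be nonnegative", call. = FALSE)

  key <- paste(raw$study_id, raw$arm, signif(raw$time_weeks, 10), sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (study, arm, time) row(s): ",
         paste(unique(raw$study_id[duplicated(key)]), collapse = ", "),
         call. = FALSE)

  extra <- setdiff(names(raw), c(canonical_cols, "time_weeks"))
  df <- raw[, c("study_id", "arm", "dose_g_per_day", "n", "time_weeks",
                "bmi", "change_rate_pct", extra), drop = FALSE]
  df <- df[order(df$study_id, df$arm, df$time_weeks), , drop = FALSE]
  rownames(df) <- NULL
  new_study_table(df)
}

#' Write an arm-level trial table
#'
#' Writes a `study_table` back to CSV in the same long dialect read by
#' [read_study_table()] (times in weeks). Numeric fields are written with
#' 17 significant digits so that a write/read round trip reproduces them
#' exactly.
#'
#' @param table A `study_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(table, path) {
  stopifnot(inherits(table, "study_table"))
  out <- as.data.frame(table)
  out$time <- out$time_weeks
  out$time_unit <- "weeks"
  out$time_weeks <- NULL
  first <- c("study_id", "arm", "dose_g_per_day", "n", "time", "time_unit",
             "bmi", "change_rate_pct")
  out <- out[, c(first, setdiff(names(out), first)), drop = FALSE]
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      v <- out[[nm]]
      out[[nm]] <- ifelse(is.na(v), "", sprintf("%.17g", v))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Total enrollment of a study table
#'
#' Sums arm sample sizes across the table, counting each (study, arm) once
#' even when an arm contributes several time points.
#'
#' @param table A `study_table`.
#' @return Total number of subjects (integer).
#' @examples
#' total_enrollment(carnitine_trials())  # 1239
#' @export
total_enrollment <- function(table) {
  stopifnot(inherits(table, "study_table"))
  if (nrow(table) == 0) return(0L)
  arms <- !duplicated(paste(table$study_id, table$arm, sep = "\r"))
  as.integer(sum(table$n[arms]))
}

#' Packaged fixture: carnitine RCTs in type 2 diabetes
#'
#' The aggregate metadata of the ten randomized controlled trials of
#' l-carnitine (8 studies), acetyl-l-carnitine (1), and propionyl-l-carnitine
#' (1) in type 2 diabetes patients that motivate this package: per-arm sample
#' sizes, doses, endpoint durations, mean age, and country, transcribed from
#' the published study table. Outcome columns are absent — the per-study BMI
#' time courses were never deposited — so this table supports design
#' bookkeeping and simulation design (see [carnitine_design()]) but not
#' effect assembly.
#'
#' @return A `study_table` with 20 arms from 10 studies; covariate columns
#'   `drug`, `country`, `treatment`, `age_mean`, `age_sd`.
#' @export
carnitine_trials <- function() {
  path <- system.file("extdata", "carnitine_trials.csv", package = "embma",
                      mustWork = TRUE)
  read_study_table(path)
}

#' @export
print.study_table <- function(x, ...) {
  n_st <- length(unique(x$study_id))
  cat(sprintf("Aggregate trial table: %d studies, %d arms, %d rows\n",
              n_st, length(unique(paste(x$study_id, x$arm))), nrow(x)))
  has_out <- any(!is.na(x$bmi)) || any(!is.na(x$change_rate_pct))
  if (!has_out && nrow(x) > 0) cat("  (study metadata only: no outcome columns)\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
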