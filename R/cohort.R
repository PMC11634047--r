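#' Read a cohort assessment table
#'
#' One row per assessment. The delimiter (comma or tab) is detected from the
#' header line. Canonical columns: `resident_id`, `date`, `app_version`,
#' `age`, `gender`, `frs`, `gait_speed`, `dementia`, `walking_aid`,
#' `fall_history`, `n_diseases`, `falls_since_last`, `mode`. A column map
#' (named character vector or JSON file `{"canonical": "file_column", ...}`)
#' renames non-standard headers.
#'
#' @param path Path to a delimited text file with a header row.
#' @param col_map Optional named character vector (`canonical = file_column`)
#'   or path to a JSON file with the same mapping.
#' @return data.frame of assessments, `date` parsed as `Date`.
#' @export
read_cohort <- function(path, col_map = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    if (is.character(col_map) && length(col_map) == 1 && file.exists(col_map)) {
      col_map <- unlist(jsonlite::read_json(col_map, simplifyVector = TRUE))
    }
    for (canonical in names(col_map)) {
      src <- col_map[[canonical]]
      if (!src %in% names(x)) {
        stop("column map refers to missing column: ", src, call. = FALSE)
      }
      names(x)[names(x) == src] <- canonical
    }
  }
  if (!all(c("resident_id", "date", "frs") %in% names(x))) {
    stop("cohort table must provide resident_id, date and frs columns",
         call. = FALSE)
  }
  x$date <- as.Date(x$date)
  validate_assessments(x)
  x
}

validate_assessments <- function(x) {
  chk <- function(col, ok, what) {
    if (col %in% names(x)) {
      bad <- !is.na(x[[col]]) & !ok(x[[col]])
      if (any(bad)) stop("invalid assessment record(s): ", what, call. = FALSE)
    }
  }
  chk("age", function(v) v >= 0, "negative age")
  chk("gait_speed", function(v) v >= 0, "negative gait speed")
  chk("falls_since_last", function(v) v >= 0 & v == round(v),
      "falls must be non-negative integers")
  chk("frs", function(v) v >= 0 & v <= 100, "FRS outside [0, 100]")
  invisible(x)
}

#' Apply study eligibility rules to assessment records
#'
#' Retains residents aged at least `min_age` with more than one assessment
#' recorded under a compatible app version. Excluded records are returned in
#' a per-record exclusion log rather than silently dropped; a missing age
#' excludes the record with reason `"missing-field"` instead of failing.
#'
#' @param assessments data.frame of assessments (see [read_cohort()]).
#' @param min_age Minimum age in years at assessment; default 60.
#' @param versions Optional character vector of compatible `app_version`
#'   tags; `NULL` skips the version rule.
#' @param min_assessments Minimum number of assessments per resident after
#'   the record-level rules; default 2 (repeat assessment required).
#' @return A list with elements `retained` (data.frame) and `exclusions`
#'   (data.frame with columns `resident_id`, `date`, `rule`).
#' @export
filter_eligible <- function(assessments, min_age = 60, versions = NULL,
                            min_assessments = 2) {
  x <- assessments
  rule <- rep(NA_character_, nrow(x))

  if (!"age" %in% names(x)) x$age <- NA_real_
  rule[is.na(rule) & is.na(x$age)] <- "missing-field"
  rule[is.na(rule) & x$age < min_age] <- "age"
  if (!is.null(versions)) {
    v <- x$app_version %||% rep(NA_character_, nrow(x))
    rule[is.na(rule) & (is.na(v) | !v %in% versions)] <- "version"
  }

  keep <- is.na(rule)
  counts <- table(x$resident_id[keep])
  few <- names(counts)[counts < min_assessments]
  rule[keep & x$resident_id %in% few] <- "repeat-assessment"
  keep <- is.na(rule)

  exclusions <- data.frame(
    resident_id = x$resident_id[!keep],
    date = x$date[!keep],
    rule = rule[!keep],
    stringsAsFactors = FALSE
  )
  list(retained = x[keep, , drop = FALSE], exclusions = exclusions)
}

#' Form consecutive (T1, T2) observation pairs
#'
#' Every pair of consecutive assessments of the same resident whose interval
#' lies within `interval_range` days becomes one observation; consecutive
#' gaps outside the window are dropped and logged in the `"dropped"`
#' attribute. Falls are taken from the T2 record's `falls_since_last` and
#' normalized to daily and weekly rates; covariates are carried from T1.
#'
#' @param assessments Eligibility-filtered assessments.
#' @param interval_range Length-2 numeric, inclusive interval window in
#'   days; default `c(45, 180)`.
#' @return data.frame of observation pairs (class `frs_pairs`) with columns
#'   `resident_id`, `t1_date`, `t2_date`, `interval_days`, `falls`,
#'   `frs_t1`, `frs_t2`, `rate_day`, `rate_week` plus any available T1
#'   covariates.
#' @export
build_pairs <- function(assessments, interval_range = c(45, 180)) {
  x <- assessments[order(assessments$resident_id, assessments$date), ,
                   drop = FALSE]
  dup <- duplicated(x[, c("resident_id", "date")])
  if (any(dup)) {
    d <- x[dup, c("resident_id", "date")]
    stop("ambiguous records: duplicate (resident, date) for ",
         paste(paste(d$resident_id, d$date, sep = "@"), collapse = ", "),
         call. = FALSE)
  }

  same <- x$resident_id[-1] == x$resident_id[-nrow(x)]
  i1 <- which(same)           # T1 row indices
  i2 <- i1 + 1L               # T2 row indices
  interval <- as.numeric(x$date[i2] - x$date[i1])
  inside <- interval >= interval_range[1] & interval <= interval_range[2]

  dropped <- data.frame(
    resident_id = x$resident_id[i1[!inside]],
    t1_date = x$date[i1[!inside]],
    t2_date = x$date[i2[!inside]],
    interval_days = interval[!inside],
    reason = rep("interval", sum(!inside)),
    stringsAsFactors = FALSE
  )
  i1 <- i1[inside]; i2 <- i2[inside]; interval <- interval[inside]

  falls <- if ("falls_since_last" %in% names(x)) {
    x$falls_since_last[i2]
  } else {
    rep(NA_integer_, length(i2))
  }
  rates <- normalize_falls(falls, interval)

  pairs <- data.frame(
    resident_id = x$resident_id[i1],
    t1_date = x$date[i1],
    t2_date = x$date[i2],
    interval_days = interval,
    falls = falls,
    frs_t1 = x$frs[i1],
    frs_t2 = x$frs[i2],
    rate_day = rates$rate_day,
    rate_week = rates$rate_week,
    stringsAsFactors = FALSE
  )
  for (cov in c("age", "gender", "gait_speed", "dementia", "walking_aid",
                "fall_history", "n_diseases", "mode")) {
    if (cov %in% names(x)) pairs[[cov]] <- x[[cov]][i1]
  }
  attr(pairs, "dropped") <- dropped
  class(pairs) <- c("frs_pairs", "data.frame")
  pairs
}

#' Normalize reported falls to daily and weekly rates
#'
#' Reported fall counts cover observation windows of unequal length, so they
#' are divided by the interval in days; the per-week rate (x 7) is the unit
#' used throughout the analysis.
#'
#' @param falls Non-negative fall counts (vectorised).
#' @param interval_days Positive interval lengths in days.
#' @return data.frame with columns `rate_day` and `rate_week`.
#' @examples
#' normalize_falls(2, 100)  # 0.02 per day, 0.14 per week
#' @export
normalize_falls <- function(falls, interval_days) {
  if (any(interval_days <= 0, na.rm = TRUE)) {
    stop("invalid pair: interval must be positive", call. = FALSE)
  }
  if (any(falls < 0, na.rm = TRUE)) {
    stop("invalid pair: negative fall count", call. = FALSE)
  }
  data.frame(rate_day = falls / interval_days,
             rate_week = 7 * falls / interval_days)
}
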