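#' Built-in stratification schemes
#'
#' Names of the stratifiers used in the subgroup analyses: assessment
#' interval binned to the nearest of 60/90/120 days (ties rounded down),
#' reported disease count (0, 1, 2, 3, >=4 over the 15-disease list), age
#' band (<65, 65-74, 75-85, >85 years), gait speed (>= vs < 0.6 m/s, the
#' boundary assigned to the closed upper bin), dementia, the joint
#' gait-speed/dementia extremes, fall history and walking-aid use.
#'
#' @return Character vector of scheme names accepted by [stratify()].
#' @export
subgroup_schemes <- function() {
  c("interval", "diseases", "age", "gait_speed", "dementia",
    "gait_dementia", "fall_history", "walking_aid")
}

yes_no <- function(x) ifelse(is.na(x), NA_character_,
                             ifelse(as.logical(x), "yes", "no"))

scheme_labels <- function(pairs, scheme) {
  switch(scheme,
    interval = {
      anchors <- c(60, 90, 120)
      vapply(pairs$interval_days, function(d) {
        if (is.na(d)) return(NA_character_)
        dist <- abs(anchors - d)
        # round-half-down: ties go to the smaller anchor
        paste0(anchors[which.min(dist)], " days")
      }, character(1))
    },
    diseases = {
      k <- pairs$n_diseases
      ifelse(is.na(k), NA_character_, ifelse(k >= 4, ">=4", as.character(k)))
    },
    age = {
      a <- pairs$age
      ifelse(is.na(a), NA_character_,
        ifelse(a < 65, "<65",
          ifelse(a < 75, "65-74", ifelse(a <= 85, "75-85", ">85"))))
    },
    gait_speed = {
      g <- pairs$gait_speed
      ifelse(is.na(g), NA_character_, ifelse(g >= 0.6, ">=0.6", "<0.6"))
    },
    dementia = yes_no(pairs$dementia),
    gait_dementia = {
      g <- pairs$gait_speed; d <- pairs$dementia
      ifelse(is.na(g) | is.na(d), NA_character_,
        ifelse(g >= 0.6 & !d, ">=0.6 & no dementia",
          ifelse(g < 0.6 & d, "<0.6 & dementia", NA_character_)))
    },
    fall_history = yes_no(pairs$fall_history),
    walking_aid = yes_no(pairs$walking_aid),
    stop("unknown stratification scheme: ", scheme, call. = FALSE)
  )
}

#' Partition observation pairs into strata
#'
#' Deterministically assigns each pair to at most one stratum of a scheme;
#' pairs whose required covariate is missing (or which fall outside the
#' scheme's defined strata, as in the joint gait/dementia scheme) are routed
#' to the `"unassigned"` attribute with their row indices rather than
#' silently dropped.
#'
#' @param pairs Observation pairs from [build_pairs()].
#' @param scheme A scheme name from [subgroup_schemes()], or a function
#'   mapping the pairs data.frame to a character vector of stratum labels
#'   (`NA` = unassigned).
#' @return Named list of pair subsets, one per stratum, with an
#'   `"unassigned"` attribute holding the unassigned rows.
#' @export
stratify <- function(pairs, scheme) {
  labels <- if (is.function(scheme)) scheme(pairs)
            else scheme_labels(pairs, scheme)
  assigned <- !is.na(labels)
  out <- split(pairs[assigned, , drop = FALSE], labels[assigned])
  attr(out, "unassigned") <- pairs[!assigned, , drop = FALSE]
  out
}

#' Run the smoothing/fit/association pipeline per stratum
#'
#' For every stratum of every requested scheme: smooths the weekly fall
#' rates over the FRS axis, fits the candidate models, selects by RMSE and
#' computes the Spearman association, tabulating RMSE, rho, p, mean (SD)
#' FRS at T1 and the observation count. Strata whose smoothed curve has
#' fewer than `min_points` points are reported with the `"insufficient"`
#' note and no fit is attempted.
#'
#' @param pairs Observation pairs from [build_pairs()].
#' @param schemes `"all"` or a character vector of scheme names.
#' @param window Running-average window (FRS points); default 2.
#' @param families Model families passed to [fit_models()].
#' @param min_points Minimum smoothed points required for fitting;
#'   default 10.
#' @return data.frame of class `frs_subgroup_report` with columns `scheme`,
#'   `stratum`, `rmse`, `rho`, `p`, `frs_mean`, `frs_sd`, `n`, `note`.
#' @export
subgroup_pipeline <- function(pairs, schemes = "all", window = 2,
                              families = c("linear", "quadratic",
                                           "exponential"),
                              min_points = 10) {
  if (identical(schemes, "all")) schemes <- subgroup_schemes()
  rows <- list()
  for (scheme in schemes) {
    strata <- stratify(pairs, scheme)
    for (label in names(strata)) {
      sub <- strata[[label]]
      row <- data.frame(scheme = scheme, stratum = label, rmse = NA_real_,
                        rho = NA_real_, p = NA_real_,
                        frs_mean = mean(sub$frs_t1),
                        frs_sd = safe_sd(sub$frs_t1),
                        n = nrow(sub), note = "", stringsAsFactors = FALSE)
      res <- tryCatch({
        curve <- running_average(sub, window = window)
        if (nrow(curve) < min_points) {
          row$note <- "insufficient"
        } else {
          best <- select_model(fit_models(curve, families = families))
          assoc <- spearman_on_curve(curve)
          row$rmse <- best$rmse
          row$rho <- assoc$rho
          row$p <- assoc$p
          row$note <- best$family
        }
        row
      }, error = function(e) {
        row$note <- paste0("error: ", conditionMessage(e))
        row
      })
      rows[[length(rows) + 1]] <- res
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scheme = character(0), stratum = character(0),
               rmse = numeric(0), rho = numeric(0), p = numeric(0),
               frs_mean = numeric(0), frs_sd = numeric(0), n = integer(0),
               note = character(0), stringsAsFactors = FALSE)
  rownames(report) <- NULL
  attr(report, "boundary_rules") <- c(
    gait_speed = "0.6 m/s assigned to >=0.6",
    interval = "ties between anchors rounded down",
    age = "bands [65,75), [75,85], (85, Inf)"
  )
  class(report) <- c("frs_subgroup_report", "data.frame")
  report
}
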