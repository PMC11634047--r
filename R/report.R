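#' Descriptive statistics for an observation-pair table
#'
#' Means and sample SDs (n-1 denominator) for age, gait speed, FRS at T1
#' and T2 and the assessment interval; counts for gender, dementia, fallers
#' (fall history at T1) and walking-aid use. With a single observation the
#' SDs are reported as `NA` markers.
#'
#' @param pairs Observation pairs from [build_pairs()].
#' @return data.frame with columns `characteristic`, `mean`, `sd`, `count`.
#' @export
describe_cohort <- function(pairs) {
  if (NROW(pairs) == 0) stop("need at least one observation", call. = FALSE)
  num <- function(name, x) data.frame(
    characteristic = name, mean = mean(x, na.rm = TRUE),
    sd = safe_sd(x[!is.na(x)]), count = NA_real_,
    stringsAsFactors = FALSE)
  cnt <- function(name, k) data.frame(
    characteristic = name, mean = NA_real_, sd = NA_real_,
    count = as.numeric(k), stringsAsFactors = FALSE)
  opt <- function(col) col %in% names(pairs)

  rows <- list(
    cnt("residents", length(unique(pairs$resident_id))),
    cnt("observations", nrow(pairs))
  )
  if (opt("gender")) {
    rows <- c(rows, list(
      cnt("women", sum(pairs$gender == "female", na.rm = TRUE)),
      cnt("men", sum(pairs$gender == "male", na.rm = TRUE))))
  }
  if (opt("age")) rows <- c(rows, list(num("age_years", pairs$age)))
  if (opt("dementia")) rows <- c(rows, list(
    cnt("dementia", sum(pairs$dementia, na.rm = TRUE))))
  if (opt("fall_history")) rows <- c(rows, list(
    cnt("fallers_t1", sum(pairs$fall_history, na.rm = TRUE))))
  if (opt("gait_speed")) rows <- c(rows, list(
    num("gait_speed_m_s", pairs$gait_speed)))
  if (opt("walking_aid")) rows <- c(rows, list(
    cnt("walking_aids", sum(pairs$walking_aid, na.rm = TRUE))))
  rows <- c(rows, list(
    num("frs_t1", pairs$frs_t1),
    num("frs_t2", pairs$frs_t2),
    num("interval_days", pairs$interval_days),
    num("falls_per_week", pairs$rate_week)
  ))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

stage <- function(manifest, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  manifest$timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  list(result = res, manifest = manifest)
}

#' Run the full prognostic-validity analysis
#'
#' Orchestrates every stage end to end: eligibility filtering, consecutive
#' (T1, T2) pairing with fall-rate normalization, running-average smoothing,
#' model fitting and RMSE-based selection, Spearman association, threshold
#' inversion, distribution-based MCIDs with bootstrap CIs, descriptive
#' statistics and the subgroup report. A run manifest records the seed,
#' configuration, decision flags and per-stage timings, so a rerun with the
#' same manifest reproduces the analytical outputs exactly.
#'
#' @param assessments Assessment table (see [read_cohort()] /
#'   [generate_cohort()]).
#' @param min_age,versions Eligibility rules (see [filter_eligible()]).
#' @param window Running-average window in FRS points; default 2.
#' @param families Candidate model families.
#' @param horizons Threshold horizons in weeks; default `c(26, 52, 104)`.
#' @param effect_sizes MCID effect-size anchors.
#' @param replicates,level Bootstrap settings.
#' @param schemes Subgroup schemes (`"all"` or a subset).
#' @param seed Integer seed for the bootstrap.
#' @return List of class `frs_report` with elements `status`,
#'   `descriptives`, `model`, `models`, `association`, `thresholds`,
#'   `mcid`, `subgroups`, `exclusions` and `manifest`. A cohort with no
#'   eligible pairs yields `status = "no-observations"` instead of an
#'   error.
#' @export
run_full_analysis <- function(assessments, min_age = 60, versions = NULL,
                              window = 2,
                              families = c("linear", "quadratic",
                                           "exponential"),
                              horizons = c(26, 52, 104),
                              effect_sizes = c(0.2, 0.5, 0.8),
                              replicates = 10000, level = 0.95,
                              schemes = "all", seed = NULL) {
  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("fallrisk")),
    n_input_records = nrow(assessments),
    params = list(min_age = min_age, versions = versions, window = window,
                  families = families, horizons = horizons,
                  effect_sizes = effect_sizes, replicates = replicates,
                  level = level, schemes = schemes),
    decisions = list(window_mode = "fixed-width",
                     threshold_rounding = "round-up",
                     rmse_tie_break = "fewer parameters, then linear < quadratic < exponential",
                     bootstrap_unit = "observation",
                     sd_denominator = "n-1",
                     alpha = 0.05),
    timings = list()
  )

  s <- stage(manifest, "filter", filter_eligible(assessments,
                                                 min_age = min_age,
                                                 versions = versions))
  manifest <- s$manifest; elig <- s$result
  manifest$n_excluded <- nrow(elig$exclusions)

  s <- stage(manifest, "pair", build_pairs(elig$retained))
  manifest <- s$manifest; pairs <- s$result
  manifest$n_pairs <- nrow(pairs)

  if (nrow(pairs) == 0) {
    return(structure(list(status = "no-observations",
                          exclusions = elig$exclusions,
                          manifest = manifest), class = "frs_report"))
  }

  s <- stage(manifest, "describe", describe_cohort(pairs))
  manifest <- s$manifest; descriptives <- s$result

  s <- stage(manifest, "smooth", running_average(pairs, window = window))
  manifest <- s$manifest; curve <- s$result

  s <- stage(manifest, "fit", fit_models(curve, families = families))
  manifest <- s$manifest; models <- s$result

  s <- stage(manifest, "select", select_model(models))
  manifest <- s$manifest; best <- s$result

  s <- stage(manifest, "associate", spearman_on_curve(curve))
  manifest <- s$manifest; assoc <- s$result

  thresholds <- if (best$family == "quadratic" &&
                    best$coefficients[["a"]] > 0) {
    s <- stage(manifest, "thresholds", threshold_frs(best, horizons))
    manifest <- s$manifest
    s$result
  } else {
    NULL
  }

  s <- stage(manifest, "mcid",
             mcid_bootstrap(pairs$frs_t1, pairs$frs_t2,
                            effect_sizes = effect_sizes,
                            replicates = replicates, level = level,
                            seed = seed))
  manifest <- s$manifest; mcid <- s$result

  s <- stage(manifest, "subgroups",
             subgroup_pipeline(pairs, schemes = schemes, window = window,
                               families = families))
  manifest <- s$manifest; subgroups <- s$result

  structure(list(status = "ok", descriptives = descriptives, curve = curve,
                 models = models, model = best, association = assoc,
                 thresholds = thresholds, mcid = mcid,
                 subgroups = subgroups, exclusions = elig$exclusions,
                 manifest = manifest),
            class = "frs_report")
}

#' @export
print.frs_report <- function(x, ...) {
  cat("<frs_report> status:", x$status, "\n")
  if (x$status != "ok") return(invisible(x))
  cat(sprintf("  observations: %d (excluded records: %d)\n",
              x$manifest$n_pairs, x$manifest$n_excluded))
  cat(sprintf("  selected model: %s (RMSE %.4g)\n", x$model$family,
              x$model$rmse))
  if (!x$association$degenerate) {
    cat(sprintf("  Spearman rho on smoothed curve: %.3f (p = %.3g)\n",
                x$association$rho, x$association$p))
  }
  if (!is.null(x$thresholds)) {
    cat("  thresholds (weeks -> FRS):",
        paste(names(x$thresholds), x$thresholds, sep = " -> ",
              collapse = ", "), "\n")
  }
  cat("  MCID (effect size -> points):",
      paste(x$mcid$effect_size, round(x$mcid$mcid, 1), sep = " -> ",
            collapse = ", "), "\n")
  invisible(x)
}
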