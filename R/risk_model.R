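#' Default fall-risk-factor catalog
#'
#' The multifactorial Fall Risk Score (FRS) aggregates intrinsic and extrinsic
#' fall-risk factors collected by gait analysis and questionnaire. Nine
#' factors known to carry high prognostic weight in established inpatient
#' fall-risk instruments (e.g. STRATIFY, Hendrich II, Downton) receive double
#' weight; the remaining factors receive single weight. "Visual and auditory
#' impairments" is counted as one double-weighted factor, preserving the
#' instrument's count of nine.
#'
#' @return A data.frame with columns `factor` (character) and `weight`
#'   (numeric, here 2 or 1). Total weight of the default catalog is 24.
#' @examples
#' cat <- frs_catalog()
#' sum(cat$weight)  # 24
#' @export
frs_catalog <- function() {
  data.frame(
    factor = c(
      # double-weighted
      "limited_mobility", "dizziness", "visual_auditory_impairment",
      "medication_use", "cognitive_impairment", "depression",
      "urge_incontinence", "fall_history", "restlessness",
      # single-weighted
      "comorbidities_limiting_mobility", "foot_disorders",
      "syncope_conditions", "fear_of_falling", "walking_aids",
      "environmental_hazards"
    ),
    weight = c(rep(2, 9), rep(1, 6)),
    stringsAsFactors = FALSE
  )
}

validate_catalog <- function(catalog) {
  if (!is.data.frame(catalog) || !all(c("factor", "weight") %in% names(catalog))) {
    stop("catalog must be a data.frame with columns 'factor' and 'weight'",
         call. = FALSE)
  }
  if (nrow(catalog) == 0) {
    stop("invalid weight configuration: empty factor catalog", call. = FALSE)
  }
  if (anyDuplicated(catalog$factor)) {
    stop("invalid weight configuration: duplicated factor names", call. = FALSE)
  }
  if (any(!is.finite(catalog$weight)) || any(catalog$weight <= 0)) {
    stop("invalid weight configuration: all weights must be positive",
         call. = FALSE)
  }
  invisible(catalog)
}

#' Read a weight configuration from JSON
#'
#' Expects a document of the form
#' `{"factors": [{"name": "...", "weight": 2}, ...]}`.
#'
#' @param path Path to a JSON file.
#' @return A catalog data.frame as returned by [frs_catalog()].
#' @export
read_weight_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$factors)) {
    stop("weight configuration must contain a 'factors' array", call. = FALSE)
  }
  catalog <- data.frame(
    factor = as.character(doc$factors$name),
    weight = as.numeric(doc$factors$weight),
    stringsAsFactors = FALSE
  )
  validate_catalog(catalog)
}

#' Compute the Fall Risk Score for one risk-factor profile
#'
#' The FRS is the weighted fraction of catalog factors present, on a 0-100
#' scale: 0 means no factor present, 100 means every factor present. The
#' score is invariant under a common positive rescaling of the weights and is
#' monotone non-decreasing in factor presence.
#'
#' @param present Either a character vector of present factor names, or a
#'   named logical vector over catalog factors (`NA` entries are treated as
#'   absent, with a warning).
#' @param catalog Factor catalog; defaults to [frs_catalog()].
#' @return FRS as a single numeric in `[0, 100]`.
#' @examples
#' compute_frs(character(0))          # 0
#' compute_frs(frs_catalog()$factor)  # 100
#' compute_frs("fall_history")        # 100 * 2 / 24
#' @export
compute_frs <- function(present, catalog = frs_catalog()) {
  validate_catalog(catalog)
  if (is.logical(present)) {
    if (is.null(names(present))) {
      stop("logical profiles must be named by factor", call. = FALSE)
    }
    if (anyNA(present)) {
      warning("unknown (NA) factor flags treated as absent", call. = FALSE)
      present[is.na(present)] <- FALSE
    }
    present <- names(present)[present]
  }
  present <- as.character(present)
  unknown <- setdiff(present, catalog$factor)
  if (length(unknown) > 0) {
    stop("catalog mismatch: unknown factor(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  100 * sum(catalog$weight[catalog$factor %in% present]) / sum(catalog$weight)
}

#' Score a table of boolean factor flags
#'
#' Vectorised scoring for a data.frame with one logical column per catalog
#' factor (the cohort-table representation of profiles).
#'
#' @param flags data.frame of logical columns named after catalog factors.
#' @inheritParams compute_frs
#' @return Numeric vector of FRS values, one per row.
#' @export
frs_from_flags <- function(flags, catalog = frs_catalog()) {
  validate_catalog(catalog)
  unknown <- setdiff(names(flags), catalog$factor)
  if (length(unknown) > 0) {
    stop("catalog mismatch: unknown factor column(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(flags)
  if (anyNA(m)) {
    warning("unknown (NA) factor flags treated as absent", call. = FALSE)
    m[is.na(m)] <- FALSE
  }
  storage.mode(m) <- "numeric"
  w <- catalog$weight[match(colnames(m), catalog$factor)]
  as.numeric(100 * (m %*% w) / sum(catalog$weight))
}

#' Flag limited mobility from gait speed
#'
#' Default mapping of the video-derived gait parameter into the catalog:
#' gait speed below 0.6 m/s (the habitual-speed cut used throughout the
#' subgroup analyses) flags the "limited_mobility" factor.
#'
#' @param gait_speed Gait speed in m/s.
#' @param cutoff Cut point in m/s; default 0.6.
#' @return Logical vector.
#' @export
flag_limited_mobility <- function(gait_speed, cutoff = 0.6) {
  gait_speed < cutoff
}
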