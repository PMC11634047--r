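#' Running-average smoothing of fall rates over the FRS axis
#'
#' For each distinct integer FRS value observed at T1, averages the weekly
#' fall rate over all observations whose T1 FRS lies within half a window of
#' that value (closed interval). The default window is 2 FRS percentage
#' points of the 0-100 scale, centered; `adaptive = TRUE` instead widens the
#' window proportionally to the local FRS value (2% of FRS), which
#' degenerates to zero width near FRS 0 and is provided for comparison only.
#'
#' @param pairs Observation pairs from [build_pairs()], or any data.frame
#'   with `frs_t1` and `rate_week` columns.
#' @param window Window width in FRS percentage points (fixed mode) or in
#'   percent of the local FRS value (adaptive mode); default 2.
#' @param adaptive Use the locally proportional window; default `FALSE`.
#' @return data.frame of class `frs_curve` with columns `frs` (grid value),
#'   `rate` (mean weekly rate) and `n` (observations in the window), ordered
#'   by `frs`.
#' @export
running_average <- function(pairs, window = 2, adaptive = FALSE) {
  if (NROW(pairs) == 0) stop("empty input: no observations to smooth",
                             call. = FALSE)
  if (window <= 0) stop("window must be positive", call. = FALSE)
  frs <- pairs$frs_t1
  rate <- pairs$rate_week
  grid <- sort(unique(round(frs)))
  half <- if (adaptive) (window / 100) * grid / 2 else rep(window / 2,
                                                           length(grid))
  stats <- vapply(seq_along(grid), function(i) {
    inside <- abs(frs - grid[i]) <= half[i]
    c(mean(rate[inside]), sum(inside))
  }, numeric(2))
  keep <- stats[2, ] >= 1
  curve <- data.frame(frs = grid[keep], rate = stats[1, keep],
                      n = as.integer(stats[2, keep]))
  attr(curve, "window") <- window
  attr(curve, "adaptive") <- adaptive
  class(curve) <- c("frs_curve", "data.frame")
  curve
}

model_n_params <- c(linear = 2L, quadratic = 3L, exponential = 3L)

new_frs_model <- function(family, coefficients, rmse, converged = TRUE,
                          note = NULL) {
  structure(
    list(family = family, coefficients = coefficients, rmse = rmse,
         n_params = model_n_params[[family]], converged = converged,
         note = note),
    class = "frs_model"
  )
}

#' @export
print.frs_model <- function(x, ...) {
  cat(sprintf("<frs_model> family: %s%s\n", x$family,
              if (!x$converged) " (NOT converged)" else ""))
  cat("  coefficients:",
      paste(sprintf("%s = %.8g", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  cat(sprintf("  RMSE: %s\n", format(x$rmse)))
  invisible(x)
}

#' Predict the weekly fall rate from a fitted model
#'
#' @param object An `frs_model`.
#' @param frs FRS values at which to evaluate the model.
#' @param ... Unused.
#' @return Numeric vector of predicted weekly fall rates.
#' @export
predict.frs_model <- function(object, frs, ...) {
  co <- object$coefficients
  switch(object$family,
    linear = co[["intercept"]] + co[["slope"]] * frs,
    quadratic = co[["a"]] * frs^2 + co[["b"]] * frs + co[["c"]],
    exponential = co[["a"]] * exp(co[["b"]] * frs) + co[["c"]],
    stop("unknown model family: ", object$family, call. = FALSE)
  )
}

rmse_of <- function(model, curve) {
  sqrt(mean((curve$rate - predict(model, curve$frs))^2))
}

#' Fit candidate fall-rate models to a smoothed curve
#'
#' Fits, in ascending order of complexity, a linear and a quadratic model by
#' ordinary least squares and an exponential model `a * exp(b * FRS) + c` by
#' Levenberg-Marquardt nonlinear least squares (initialised at
#' `a = range of rates`, `b = 0.01`, `c = min rate`). A nonlinear fit that
#' fails to converge is returned flagged as non-converged, never silently
#' omitted. Each model carries its RMSE against the smoothed points.
#'
#' @param curve An `frs_curve` from [running_average()] (at least one more
#'   point than the largest requested parameter count).
#' @param families Model families to fit.
#' @return List of `frs_model` objects, one per requested family.
#' @export
fit_models <- function(curve,
                       families = c("linear", "quadratic", "exponential")) {
  families <- match.arg(families, c("linear", "quadratic", "exponential"),
                        several.ok = TRUE)
  needed <- max(model_n_params[families]) + 1L
  if (nrow(curve) < needed) {
    stop("insufficient data: need at least ", needed, " smoothed points",
         call. = FALSE)
  }
  out <- list()
  if ("linear" %in% families) {
    fit <- stats::lm(rate ~ frs, data = curve)
    m <- new_frs_model("linear",
                       c(intercept = unname(stats::coef(fit)[1]),
                         slope = unname(stats::coef(fit)[2])), NA)
    m$rmse <- rmse_of(m, curve)
    out$linear <- m
  }
  if ("quadratic" %in% families) {
    fit <- stats::lm(rate ~ frs + I(frs^2), data = curve)
    m <- new_frs_model("quadratic",
                       c(a = unname(stats::coef(fit)[3]),
                         b = unname(stats::coef(fit)[2]),
                         c = unname(stats::coef(fit)[1])), NA)
    m$rmse <- rmse_of(m, curve)
    out$quadratic <- m
  }
  if ("exponential" %in% families) {
    out$exponential <- fit_exponential(curve)
  }
  structure(out, class = "frs_model_set")
}

fit_exponential <- function(curve) {
  if (stats::sd(curve$rate) == 0) {
    # constant curve: exact degenerate fit, no iteration needed
    m <- new_frs_model("exponential",
                       c(a = 0, b = 0, c = curve$rate[1]), NA,
                       note = "degenerate constant fit")
    m$rmse <- rmse_of(m, curve)
    return(m)
  }
  start <- list(a = max(diff(range(curve$rate)), 1e-8), b = 0.01,
                c = min(curve$rate))
  fit <- tryCatch(
    minpack.lm::nlsLM(rate ~ a * exp(b * frs) + c, data = curve,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(new_frs_model("exponential", c(a = NA_real_, b = NA_real_,
                                          c = NA_real_),
                         NA_real_, converged = FALSE,
                         note = conditionMessage(fit)))
  }
  co <- stats::coef(fit)
  m <- new_frs_model("exponential", c(a = unname(co["a"]),
                                      b = unname(co["b"]),
                                      c = unname(co["c"])), NA)
  m$rmse <- rmse_of(m, curve)
  m
}

#' Select the best-fitting model by RMSE
#'
#' Returns the converged model with the lowest RMSE. Exact ties are broken
#' toward the family with fewer parameters, then by the declared order
#' linear < quadratic < exponential; an applied tie-break is recorded in the
#' returned model's `note`.
#'
#' @param models List of `frs_model` objects (e.g. from [fit_models()]).
#' @return The selected `frs_model`.
#' @export
select_model <- function(models) {
  models <- Filter(function(m) isTRUE(m$converged), models)
  if (length(models) == 0) {
    stop("model selection failed: no converged model", call. = FALSE)
  }
  family_rank <- c(linear = 1L, quadratic = 2L, exponential = 3L)
  rmse <- vapply(models, function(m) m$rmse, numeric(1))
  np <- vapply(models, function(m) m$n_params, integer(1))
  fr <- family_rank[vapply(models, function(m) m$family, character(1))]
  ord <- order(rmse, np, fr)
  best <- models[[ord[1]]]
  if (sum(rmse == min(rmse)) > 1) {
    best$note <- paste0("tie on RMSE broken toward ", best$family)
  }
  best
}

#' Spearman association over the smoothed curve
#'
#' Spearman rank correlation (average ranks for ties) with a two-sided
#' p-value between the FRS grid and the smoothed weekly fall rate. A
#' constant rate vector makes the rank correlation undefined; this is
#' returned as a flagged degenerate result rather than propagating `NaN`.
#' Because neighbouring windows overlap, the smoothed points are not
#' independent and the p-value should be read descriptively.
#'
#' @param curve An `frs_curve` with at least 3 points.
#' @return List of class `frs_association` with `rho`, `p`, `n` and
#'   `degenerate`.
#' @export
spearman_on_curve <- function(curve) {
  if (nrow(curve) < 3) stop("need at least 3 smoothed points", call. = FALSE)
  if (stats::sd(curve$rate) == 0) {
    return(structure(list(rho = NA_real_, p = NA_real_, n = nrow(curve),
                          degenerate = TRUE), class = "frs_association"))
  }
  ct <- suppressWarnings(
    stats::cor.test(curve$frs, curve$rate, method = "spearman",
                    exact = FALSE)
  )
  structure(list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(curve),
                 degenerate = FALSE), class = "frs_association")
}

#' @export
print.frs_association <- function(x, ...) {
  if (x$degenerate) {
    cat("<frs_association> degenerate (constant rates), rho undefined\n")
  } else {
    cat(sprintf("<frs_association> rho = %.3f, p = %.3g (n = %d points)\n",
                x$rho, x$p, x$n))
  }
  invisible(x)
}

#' Published quadratic fall-rate model
#'
#' The reference quadratic relating the FRS at baseline to the expected
#' number of falls per week over the follow-up interval:
#' `rate = 2.02977245e-5 * FRS^2 + 3.1456122e-5 * FRS - 2.34295251e-3`,
#' with a reported RMSE of 0.015 against its smoothed curve. Useful as a
#' data-generating model and for threshold computations.
#'
#' @return An `frs_model` of family `"quadratic"`.
#' @export
reference_fall_model <- function() {
  new_frs_model("quadratic",
                c(a = 2.02977245e-5, b = 3.1456122e-5, c = -2.34295251e-3),
                rmse = 0.015, note = "published reference model")
}

#' FRS threshold for an expected fall within a time horizon
#'
#' Inverts a quadratic fall-rate model: solves
#' `rate(FRS) * horizon_weeks = 1` for the positive root and returns the
#' smallest integer FRS at or above it (a score "starting at" which one fall
#' is expected within the horizon). Horizons of 26, 52 and 104 weeks
#' correspond to 6, 12 and 24 months.
#'
#' @param model An `frs_model` of family `"quadratic"` with positive leading
#'   coefficient.
#' @param horizon_weeks Positive horizon(s) in weeks (vectorised).
#' @return Integer vector of thresholds, named by horizon; `NA` (with a
#'   `"no-threshold"` attribute) where the expected falls never reach 1 on
#'   the 0-100 scale.
#' @examples
#' threshold_frs(reference_fall_model(), c(26, 52, 104))  # 45, 32, 24
#' @export
threshold_frs <- function(model, horizon_weeks) {
  if (any(horizon_weeks <= 0)) {
    stop("invalid argument: horizon must be positive", call. = FALSE)
  }
  if (model$family != "quadratic" || model$coefficients[["a"]] <= 0) {
    stop("threshold inversion requires a quadratic model with positive ",
         "leading coefficient", call. = FALSE)
  }
  a <- model$coefficients[["a"]]
  b <- model$coefficients[["b"]]
  cc <- model$coefficients[["c"]]
  out <- vapply(horizon_weeks, function(h) {
    disc <- b^2 - 4 * a * (cc - 1 / h)
    if (disc < 0) return(NA_real_)
    root <- (-b + sqrt(disc)) / (2 * a)
    if (root > 100) return(NA_real_)
    max(ceiling(root), 0)
  }, numeric(1))
  res <- as.integer(out)
  names(res) <- as.character(horizon_weeks)
  if (anyNA(res)) attr(res, "no-threshold") <- horizon_weeks[is.na(res)]
  res
}
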