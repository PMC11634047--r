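pairs_df <- function(frs, rate) {
  data.frame(frs_t1 = frs, rate_week = rate)
}

test_that("running average reproduces degenerate cases exactly", {
  # constant input: every smoothed point equals the shared rate
  cv <- running_average(pairs_df(c(10, 11, 12, 20), rep(0.3, 4)), window = 2)
  expect_true(all(cv$rate == 0.3))

  # window smaller than spacing: curve equals the raw points
  cv <- running_average(pairs_df(c(10, 20, 30), c(0.1, 0.2, 0.3)),
                        window = 2)
  expect_equal(cv$rate, c(0.1, 0.2, 0.3))
  expect_equal(cv$n, rep(1L, 3))

  # two neighbouring values share both observations under a width-2 window
  cv <- running_average(pairs_df(c(30, 31), c(0.1, 0.3)), window = 2)
  expect_equal(cv$rate, c(0.2, 0.2))

  expect_error(running_average(pairs_df(numeric(0), numeric(0))), "empty")
})

test_that("running average matches the brute-force window oracle", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    frs <- runif(n, 1, 71)
    rate <- rexp(n, 50)
    w <- sample(c(1, 2, 4), 1)
    got <- running_average(pairs_df(frs, rate), window = w)
    want <- brute_running_average(frs, rate, w)
    expect_equal(got$frs, want$frs)
    expect_equal(got$rate, want$rate)
    expect_equal(got$n, want$n)
    # a mean stays within the raw range
    expect_true(all(got$rate >= min(rate) - 1e-12 &
                    got$rate <= max(rate) + 1e-12))
  }
})

test_that("noiseless quadratic points are recovered to high precision", {
  ref <- reference_fall_model()
  curve <- make_curve(1:71, predict(ref, 1:71))
  fits <- fit_models(curve)
  co <- fits$quadratic$coefficients
  expect_equal(co[["a"]], ref$coefficients[["a"]], tolerance = 1e-8)
  expect_equal(co[["b"]], ref$coefficients[["b"]], tolerance = 1e-8)
  expect_equal(co[["c"]], ref$coefficients[["c"]], tolerance = 1e-8)
  expect_lt(fits$quadratic$rmse, 1e-12)
})

test_that("nested and constant limits behave as expected", {
  curve <- make_curve(1:20, 0.001 + 0.002 * (1:20))
  fits <- fit_models(curve)
  expect_lt(abs(fits$quadratic$coefficients[["a"]]), 1e-10)
  expect_lt(fits$linear$rmse, 1e-12)
  expect_lt(fits$quadratic$rmse, 1e-12)

  const <- make_curve(1:10, rep(0.05, 10))
  fits <- fit_models(const)
  for (m in fits) expect_lt(m$rmse, 1e-12)
  expect_true(fits$exponential$converged)
})

test_that("exponential fits recover a known exponential curve", {
  frs <- seq(5, 70, by = 5)
  curve <- make_curve(frs, 0.002 * exp(0.04 * frs) + 0.005)
  m <- fit_models(curve, families = "exponential")$exponential
  expect_true(m$converged)
  expect_lt(m$rmse, 1e-8)
  expect_equal(m$coefficients[["b"]], 0.04, tolerance = 1e-4)
})

test_that("quadratic RMSE never exceeds linear RMSE (nested least squares)", {
  set.seed(31)
  for (i in 1:15) {
    frs <- sort(sample(1:71, sample(6:30, 1)))
    curve <- make_curve(frs, pmax(0, rnorm(length(frs), 0.02, 0.02)))
    fits <- fit_models(curve, families = c("linear", "quadratic"))
    expect_lte(fits$quadratic$rmse, fits$linear$rmse + 1e-12)
  }
})

test_that("model selection minimises RMSE with declared tie-breaks", {
  models <- list(make_model("linear", 0.017),
                 make_model("quadratic", 0.015),
                 make_model("exponential", 0.016))
  expect_equal(select_model(models)$family, "quadratic")

  ties <- list(make_model("exponential", 0.01), make_model("linear", 0.01),
               make_model("quadratic", 0.01))
  expect_equal(select_model(ties)$family, "linear")

  expect_equal(select_model(list(make_model("exponential", 0.5)))$family,
               "exponential")
  expect_error(select_model(list(make_model("exponential", NA,
                                            converged = FALSE))),
               "no converged")
})

test_that("insufficient smoothed points raise an error", {
  expect_error(fit_models(make_curve(1:3, c(0.1, 0.2, 0.3))),
               "insufficient")
})

test_that("Spearman on the curve matches rank arithmetic", {
  up <- make_curve(c(10, 20, 30, 40, 50), c(1, 2, 3, 4, 5) / 100)
  expect_equal(spearman_on_curve(up)$rho, 1)
  down <- make_curve(c(10, 20, 30, 40, 50), c(5, 4, 3, 2, 1) / 100)
  expect_equal(spearman_on_curve(down)$rho, -1)
  # one adjacent swap among five points: rho = 1 - 6*2/120 = 0.9
  swap <- make_curve(c(10, 20, 30, 40, 50), c(1, 2, 4, 3, 5) / 100)
  expect_equal(spearman_on_curve(swap)$rho, 0.9)

  set.seed(41)
  for (i in 1:10) {
    cv <- make_curve(1:12, runif(12))
    expect_equal(spearman_on_curve(cv)$rho, rank_rho(cv$frs, cv$rate))
  }
})

test_that("constant rates yield a flagged degenerate association", {
  res <- spearman_on_curve(make_curve(1:5, rep(0.1, 5)))
  expect_true(res$degenerate)
  expect_true(is.na(res$rho))
  expect_error(spearman_on_curve(make_curve(1:2, c(0.1, 0.2))), "3")
})

test_that("threshold inversion reproduces the published values", {
  th <- threshold_frs(reference_fall_model(), c(26, 52, 104))
  expect_equal(unname(th), c(45L, 32L, 24L))
})

test_that("thresholds are monotone in the horizon and signal absence", {
  ref <- reference_fall_model()
  horizons <- c(10, 26, 40, 52, 80, 104, 150)
  th <- threshold_frs(ref, horizons)
  expect_true(all(diff(th) <= 0))

  tiny <- make_model("quadratic", 0,
                     coefficients = c(a = 1e-9, b = 0, c = 0))
  none <- threshold_frs(tiny, 26)
  expect_true(is.na(none))
  expect_equal(attr(none, "no-threshold"), 26)

  expect_error(threshold_frs(ref, -1), "positive")
  expect_error(threshold_frs(make_model("linear", 0.1,
                                        c(intercept = 0, slope = 1)), 26),
               "quadratic")
})

test_that("analytic thresholds round-trip through refitted curve points", {
  ref <- reference_fall_model()
  curve <- make_curve(1:71, predict(ref, 1:71))
  refit <- select_model(fit_models(curve,
                                   families = c("linear", "quadratic")))
  expect_equal(threshold_frs(refit, c(26, 52, 104)),
               threshold_frs(ref, c(26, 52, 104)))
})
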