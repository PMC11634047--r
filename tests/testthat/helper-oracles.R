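# Independent brute-force oracles and small fixture builders.

brute_frs <- function(present, catalog) {
  total <- 0
  got <- 0
  for (i in seq_len(nrow(catalog))) {
    total <- total + catalog$weight[i]
    if (catalog$factor[i] %in% present) got <- got + catalog$weight[i]
  }
  100 * got / total
}

brute_running_average <- function(frs, rate, window) {
  grid <- sort(unique(round(frs)))
  out <- data.frame(frs = grid, rate = NA_real_, n = NA_integer_)
  for (i in seq_along(grid)) {
    vals <- c()
    for (j in seq_along(frs)) {
      if (abs(frs[j] - grid[i]) <= window / 2) vals <- c(vals, rate[j])
    }
    out$rate[i] <- mean(vals)
    out$n[i] <- length(vals)
  }
  out
}

# Spearman rho as Pearson correlation of average ranks, computed from the
# definition rather than through cor.test.
rank_rho <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# loop-based percentile bootstrap of effect_size * pooled SD, independent of
# the vectorised implementation
reference_mcid_ci <- function(t1, t2, effect_size, replicates, level, seed) {
  set.seed(seed)
  n <- length(t1)
  stat <- numeric(replicates)
  for (r in seq_len(replicates)) {
    idx <- sample.int(n, n, replace = TRUE)
    stat[r] <- sqrt((sd(t1[idx])^2 + sd(t2[idx])^2) / 2)
  }
  effect_size * quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2),
                         names = FALSE)
}

make_assessments <- function(resident_id, day, age = 80, frs = 30,
                             falls = 0, version = "10.8.0", ...) {
  data.frame(resident_id = resident_id,
             date = as.Date("2022-01-01") + day,
             app_version = version, age = age, frs = frs,
             falls_since_last = falls, ...,
             stringsAsFactors = FALSE)
}

make_curve <- function(frs, rate, n = 1L) {
  curve <- data.frame(frs = frs, rate = rate, n = n)
  class(curve) <- c("frs_curve", "data.frame")
  curve
}

make_model <- function(family, rmse, coefficients = c(a = 1, b = 0, c = 0),
                       converged = TRUE) {
  structure(list(family = family, coefficients = coefficients, rmse = rmse,
                 n_params = c(linear = 2L, quadratic = 3L,
                              exponential = 3L)[[family]],
                 converged = converged, note = NULL),
            class = "frs_model")
}

# analytic mean and SD of a truncated normal
truncnorm_mean <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

truncnorm_sd <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- pnorm(b) - pnorm(a)
  delta <- (dnorm(a) - dnorm(b)) / z
  sd * sqrt(1 + (a * dnorm(a) - b * dnorm(b)) / z - delta^2)
}
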