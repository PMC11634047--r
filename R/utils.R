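# Internal helpers shared across modules.

# Truncated-normal sampler via inverse-CDF; exact, no rejection loop.
# sd = 0 collapses to the (bounds-checked) mean.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (lower > upper) {
    stop("infeasible truncation bounds: lower > upper", call. = FALSE)
  }
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop("degenerate distribution (sd = 0) falls outside truncation bounds",
           call. = FALSE)
    }
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo <= 0) {
    stop("truncation bounds leave no probability mass", call. = FALSE)
  }
  u <- stats::runif(n, plo, phi)
  pmin(pmax(stats::qnorm(u, mean, sd), lower), upper)
}

# Sample SD (n-1 denominator) that returns NA for n < 2 instead of erroring.
safe_sd <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
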