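#' Synthetic cohort generator configuration
#'
#' Defaults emulate the study population the analysis is designed for:
#' residents of German long-term-care facilities assessed roughly every
#' three months. FRS at baseline is truncated-normal with mean 29.7 and SD
#' 11.8 on [1, 71]; follow-up FRS has mean 29.2 and SD 11.5 and correlates
#' 0.9 with baseline; assessment intervals are truncated-normal with mean
#' 108.5 and SD 31.6 days on [45, 180]; fall counts between assessments are
#' Poisson with weekly rate given by the reference quadratic model (clamped
#' at 0, since it is negative at low FRS), scaled by the interval length.
#' Covariate prevalences follow the study's descriptives: walking aids
#' 622/857, dementia 277/857, fall history 125/857, women 615/857, gait
#' speed 0.49 (SD 0.19) m/s, age 83.3 (SD 8.7) years (minimum 60), disease
#' count Poisson(2.1). By default low gait speed and walking-aid use are
#' coupled; all other covariates are sampled independently.
#'
#' @param n_residents Number of residents; the default 617 yields about 857
#'   observation pairs.
#' @param obs_lambda Poisson mean of additional pairs per resident beyond
#'   the first (857/617 pairs per resident on average).
#' @param frs_t1 List: `mean`, `sd`, `range` for baseline FRS.
#' @param frs_t2 List: `mean`, `sd`, `cor` (correlation with baseline).
#' @param interval List: `mean`, `sd`, `range` (days).
#' @param rate_model An `frs_model` giving the weekly fall rate as a
#'   function of FRS (clamped at 0 before use), or `NULL` for a zero-rate
#'   (no falls) cohort.
#' @param overdispersion `NULL` for Poisson fall counts, or a positive
#'   negative-binomial size parameter (smaller = more overdispersed).
#' @param p_walking_aid,p_dementia,p_fall_history,p_female Prevalences.
#' @param gait List: `mean`, `sd`, `min` for gait speed (m/s).
#' @param age List: `mean`, `sd`, `min` for age (years).
#' @param disease_lambda Poisson mean of the reported disease count.
#' @param couple_gait_aid Couple walking-aid use to slow gait (below 0.6
#'   m/s) so that the marginal prevalence stays near `p_walking_aid`.
#' @param start_date First possible assessment date.
#' @return List of class `frs_generator_config`.
#' @export
cohort_config <- function(n_residents = 617,
                          obs_lambda = 857 / 617 - 1,
                          frs_t1 = list(mean = 29.7, sd = 11.8,
                                        range = c(1, 71)),
                          frs_t2 = list(mean = 29.2, sd = 11.5, cor = 0.9),
                          interval = list(mean = 108.5, sd = 31.6,
                                          range = c(45, 180)),
                          rate_model = reference_fall_model(),
                          overdispersion = NULL,
                          p_walking_aid = 622 / 857,
                          p_dementia = 277 / 857,
                          p_fall_history = 125 / 857,
                          p_female = 615 / 857,
                          gait = list(mean = 0.49, sd = 0.19, min = 0),
                          age = list(mean = 83.3, sd = 8.7, min = 60),
                          disease_lambda = 2.1,
                          couple_gait_aid = TRUE,
                          start_date = as.Date("2021-06-01")) {
  cfg <- list(n_residents = n_residents, obs_lambda = obs_lambda,
              frs_t1 = frs_t1, frs_t2 = frs_t2, interval = interval,
              rate_model = rate_model, overdispersion = overdispersion,
              p_walking_aid = p_walking_aid, p_dementia = p_dementia,
              p_fall_history = p_fall_history, p_female = p_female,
              gait = gait, age = age, disease_lambda = disease_lambda,
              couple_gait_aid = couple_gait_aid, start_date = start_date)
  probs <- c(p_walking_aid, p_dementia, p_fall_history, p_female)
  if (any(probs < 0 | probs > 1)) {
    stop("config error: prevalences must lie in [0, 1]", call. = FALSE)
  }
  sds <- c(frs_t1$sd, frs_t2$sd, interval$sd, gait$sd, age$sd)
  if (any(sds < 0)) stop("config error: SDs must be non-negative",
                         call. = FALSE)
  if (frs_t1$range[1] > frs_t1$range[2] ||
      interval$range[1] > interval$range[2]) {
    stop("config error: truncation bounds crossed", call. = FALSE)
  }
  if (n_residents < 1 || obs_lambda < 0) {
    stop("config error: need >= 1 resident and non-negative obs_lambda",
         call. = FALSE)
  }
  if (abs(frs_t2$cor) > 1) stop("config error: |cor| must be <= 1",
                                call. = FALSE)
  class(cfg) <- "frs_generator_config"
  cfg
}

#' Generate a synthetic assessment cohort
#'
#' Draws a reproducible roster of residents, each with one baseline and at
#' least one follow-up assessment. Follow-up FRS follows a stationary
#' bivariate-normal step from the previous assessment; falls reported at
#' each follow-up are Poisson (or negative-binomial when overdispersion is
#' configured) with mean `max(0, rate(FRS_prev)) * interval_days / 7`. The
#' output is an assessment table in the same dialect [read_cohort()] reads,
#' ready for [filter_eligible()] and [build_pairs()].
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer seed; fixed seed implies an identical
#'   cohort.
#' @return data.frame of assessments with the generator config and seed as
#'   attributes. `falls_since_last` is `NA` at each resident's first
#'   assessment (nothing precedes it).
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "frs_generator_config"))
  if (!is.null(seed)) set.seed(seed)
  nr <- config$n_residents
  n_pairs <- 1L + stats::rpois(nr, config$obs_lambda)
  n_assess <- n_pairs + 1L
  max_depth <- max(n_assess)

  # resident-level covariates
  age <- rtruncnorm(nr, config$age$mean, config$age$sd,
                    lower = config$age$min)
  gait <- rtruncnorm(nr, config$gait$mean, config$gait$sd,
                     lower = config$gait$min)
  gender <- ifelse(stats::runif(nr) < config$p_female, "female", "male")
  dementia <- stats::runif(nr) < config$p_dementia
  p_aid <- if (config$couple_gait_aid) {
    ifelse(gait < 0.6, 0.9, 0.35)
  } else {
    rep(config$p_walking_aid, nr)
  }
  walking_aid <- stats::runif(nr) < p_aid
  fall_history0 <- stats::runif(nr) < config$p_fall_history
  n_diseases <- stats::rpois(nr, config$disease_lambda)

  # FRS sequences: baseline, then an AR(1)-type step matched to the
  # configured follow-up mean/SD/correlation
  t1 <- config$frs_t1; t2 <- config$frs_t2
  frs <- matrix(NA_real_, nrow = nr, ncol = max_depth)
  frs[, 1] <- rtruncnorm(nr, t1$mean, t1$sd, t1$range[1], t1$range[2])
  innov_sd <- t2$sd * sqrt(max(0, 1 - t2$cor^2))
  for (d in 2:max_depth) {
    active <- n_assess >= d
    if (!any(active)) next
    prev <- frs[active, d - 1]
    step <- t2$mean + t2$cor * (t2$sd / t1$sd) * (prev - t1$mean) +
      stats::rnorm(sum(active), 0, innov_sd)
    # every assessment can serve as the baseline of the next pair, so all
    # scores live on the same truncated scale as the configured baseline
    frs[active, d] <- pmin(pmax(step, t1$range[1]), t1$range[2])
  }

  # intervals and dates
  iv <- config$interval
  intervals <- matrix(NA_real_, nrow = nr, ncol = max_depth - 1L)
  for (d in seq_len(max_depth - 1L)) {
    active <- n_assess >= d + 1L
    intervals[active, d] <- round(
      rtruncnorm(sum(active), iv$mean, iv$sd, iv$range[1], iv$range[2]))
  }
  first_date <- config$start_date +
    floor(stats::runif(nr, 0, 730))

  # falls reported at each follow-up, driven by the previous FRS
  rate_at <- function(f) {
    if (is.null(config$rate_model)) rep(0, length(f))
    else pmax(0, predict(config$rate_model, f))
  }
  falls <- matrix(NA_integer_, nrow = nr, ncol = max_depth)
  for (d in 2:max_depth) {
    active <- which(n_assess >= d)
    if (!length(active)) next
    mu <- rate_at(frs[active, d - 1]) * intervals[active, d - 1] / 7
    falls[active, d] <- if (is.null(config$overdispersion)) {
      stats::rpois(length(active), mu)
    } else {
      stats::rnbinom(length(active), size = config$overdispersion, mu = mu)
    }
  }

  # assemble long table
  rid <- rep(seq_len(nr), n_assess)
  depth <- unlist(lapply(n_assess, seq_len), use.names = FALSE)
  flat <- cbind(rid, depth)
  date <- first_date[rid]
  offs <- t(apply(cbind(0, intervals), 1, function(r) cumsum(ifelse(is.na(r), 0, r))))
  date <- date + offs[flat]

  fall_hist <- matrix(FALSE, nrow = nr, ncol = max_depth)
  fall_hist[, 1] <- fall_history0
  for (d in 2:max_depth) {
    fall_hist[, d] <- fall_hist[, d - 1] |
      (!is.na(falls[, d]) & falls[, d] > 0)
  }

  out <- data.frame(
    resident_id = sprintf("R%05d", rid),
    date = date,
    app_version = "10.8.0",
    age = round(age[rid], 1),
    gender = gender[rid],
    frs = frs[flat],
    gait_speed = round(gait[rid], 3),
    dementia = dementia[rid],
    walking_aid = walking_aid[rid],
    fall_history = fall_hist[flat],
    n_diseases = n_diseases[rid],
    falls_since_last = falls[flat],
    mode = ifelse(dementia[rid], "external", "self"),
    stringsAsFactors = FALSE
  )
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  out
}

#' Generate risk-factor profiles matching a target FRS distribution
#'
#' Draws a target score from the configured (truncated-normal) FRS
#' distribution, proposes factor flags as independent Bernoulli draws with
#' presence probability `target / 100` (so the expected score equals the
#' target), and accepts the proposal only if its computed FRS falls within
#' `tol` of the target (acceptance-rejection). After `max_tries` the last
#' proposal is kept and counted; a high miss rate triggers a warning
#' reporting the achieved moments, which signals that the catalog is too
#' coarse for the requested distribution.
#'
#' @param n Number of profiles.
#' @param catalog Factor catalog; default [frs_catalog()].
#' @param target List: `mean`, `sd`, `range` of the target FRS
#'   distribution.
#' @param tol Acceptance tolerance in FRS points; defaults to the catalog's
#'   granularity (one minimal weight step).
#' @param max_tries Proposal attempts per profile; default 50.
#' @param seed Optional integer seed.
#' @return data.frame with one logical column per catalog factor plus the
#'   computed `frs` column.
#' @export
generate_profiles <- function(n, catalog = frs_catalog(),
                              target = list(mean = 29.7, sd = 11.8,
                                            range = c(1, 71)),
                              tol = NULL, max_tries = 50, seed = NULL) {
  validate_catalog(catalog)
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(catalog)
  w <- catalog$weight
  total <- sum(w)
  if (is.null(tol)) tol <- 100 * min(w) / total
  goals <- rtruncnorm(n, target$mean, target$sd, target$range[1],
                      target$range[2])
  flags <- matrix(FALSE, nrow = n, ncol = k,
                  dimnames = list(NULL, catalog$factor))
  frs <- numeric(n)
  misses <- 0L
  for (i in seq_len(n)) {
    p <- min(max(goals[i] / 100, 0), 1)
    for (try in seq_len(max_tries)) {
      f <- stats::runif(k) < p
      s <- 100 * sum(w[f]) / total
      if (abs(s - goals[i]) <= tol) break
    }
    if (abs(s - goals[i]) > tol) misses <- misses + 1L
    flags[i, ] <- f
    frs[i] <- s
  }
  if (misses > 0.05 * n) {
    warning(sprintf(
      "target FRS distribution unreachable at catalog granularity for %d/%d profiles; achieved mean %.2f, sd %.2f",
      misses, n, mean(frs), stats::sd(frs)), call. = FALSE)
  }
  out <- as.data.frame(flags)
  out$frs <- frs
  out
}
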