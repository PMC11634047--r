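test_that("eligibility boundary cases follow the age and repeat rules", {
  under <- make_assessments(rep("A", 3), c(0, 90, 180), age = 59)
  res <- filter_eligible(under)
  expect_equal(nrow(res$retained), 0)
  expect_true(all(res$exclusions$rule == "age"))

  single <- make_assessments("B", 0, age = 60)
  res <- filter_eligible(single)
  expect_equal(nrow(res$retained), 0)
  expect_equal(res$exclusions$rule, "repeat-assessment")
})

test_that("a mixed roster retains exactly the eligible residents", {
  rows <- do.call(rbind, lapply(1:10, function(i) {
    n <- if (i == 3) 1 else 2
    make_assessments(paste0("R", i), seq(0, by = 90, length.out = n),
                     age = if (i <= 2) 58 else 72)
  }))
  res <- filter_eligible(rows)
  expect_equal(length(unique(res$retained$resident_id)), 7)
  # every excluded record appears exactly once in the log
  expect_equal(nrow(res$retained) + nrow(res$exclusions), nrow(rows))
  expect_equal(anyDuplicated(res$exclusions[, c("resident_id", "date")]), 0)
})

test_that("missing age excludes the record instead of crashing", {
  rows <- make_assessments(c("A", "A"), c(0, 90), age = c(NA, 70))
  res <- filter_eligible(rows)
  expect_true("missing-field" %in% res$exclusions$rule)
})

test_that("incompatible app versions are excluded when versions are given", {
  rows <- make_assessments(c("A", "A", "A"), c(0, 90, 180),
                           version = c("10.8.0", "9.0.0", "10.8.0"))
  res <- filter_eligible(rows, versions = c("10.8.0"))
  expect_equal(nrow(res$retained), 2)
  expect_equal(res$exclusions$rule, "version")
})

test_that("consecutive pairing respects the interval window", {
  p <- build_pairs(make_assessments(rep("A", 3), c(0, 100, 200)))
  expect_equal(nrow(p), 2)
  expect_equal(p$interval_days, c(100, 100))

  p <- build_pairs(make_assessments(c("A", "A"), c(0, 30)))
  expect_equal(nrow(p), 0)
  expect_equal(attr(p, "dropped")$interval_days, 30)

  # residents with gaps {100}, {30, 170}, {200}: only 100 and 170 qualify
  rows <- rbind(make_assessments(c("A", "A"), c(0, 100)),
                make_assessments(c("B", "B", "B"), c(0, 30, 200)),
                make_assessments(c("C", "C"), c(0, 200)))
  p <- build_pairs(rows)
  expect_equal(nrow(p), 2)
  expect_setequal(p$interval_days, c(100, 170))
})

test_that("duplicate (resident, date) records raise an ambiguity error", {
  rows <- make_assessments(c("A", "A", "A"), c(0, 0, 90))
  expect_error(build_pairs(rows), "duplicate")
})

test_that("pairing is order-independent and conserves fall counts", {
  set.seed(3)
  coh <- generate_cohort(cohort_config(n_residents = 60), seed = 5)
  shuffled <- coh[sample.int(nrow(coh)), ]
  p1 <- build_pairs(coh)
  p2 <- build_pairs(shuffled)
  expect_equal(p1, p2, ignore_attr = TRUE)
  # all generated intervals lie in the window, so the paired falls must
  # account for every reported fall
  expect_equal(sum(p1$falls), sum(coh$falls_since_last, na.rm = TRUE))
})

test_that("fall counts normalize to daily and weekly rates", {
  r <- normalize_falls(c(2, 0, 1), c(100, 90, 70))
  expect_equal(r$rate_day, c(0.02, 0, 1 / 70))
  expect_equal(r$rate_week, c(0.14, 0, 0.1))
  expect_error(normalize_falls(1, 0), "interval")
  expect_error(normalize_falls(-1, 10), "negative")
})

test_that("cohort tables round-trip through delimited text", {
  coh <- generate_cohort(cohort_config(n_residents = 20), seed = 1)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(coh, path, row.names = FALSE)
  back <- read_cohort(path)
  expect_equal(back$frs, coh$frs)
  expect_s3_class(back$date, "Date")

  # tab dialect with a column map
  names(coh)[names(coh) == "frs"] <- "score"
  path2 <- tempfile(fileext = ".tsv")
  utils::write.table(coh, path2, sep = "\t", row.names = FALSE)
  back2 <- read_cohort(path2, col_map = c(frs = "score"))
  expect_equal(back2$frs, back$frs)
})

test_that("invalid assessment records are rejected on read", {
  coh <- generate_cohort(cohort_config(n_residents = 5), seed = 2)
  coh$frs[1] <- 130
  path <- tempfile(fileext = ".csv")
  utils::write.csv(coh, path, row.names = FALSE)
  expect_error(read_cohort(path), "FRS")
})
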