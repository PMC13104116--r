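tidy_series <- function(values_by_animal, days, modality = "m") {
  do.call(rbind, lapply(names(values_by_animal), function(a)
    data.frame(animal = a, modality = modality, day = days,
               value = values_by_animal[[a]])))
}

test_that("baseline normalization maps the day-1 cross-animal mean to 1", {
  s <- tidy_series(list(A1 = c(2, 3), A2 = c(2, 5), A3 = c(2, 4)),
                   days = c(1, 10))
  n <- normalize_to_baseline(s)
  expect_equal(n$value[n$day == 1], rep(1, 3))
  expect_equal(n$value[n$animal == "A1" & n$day == 10], 1.5)

  s2 <- tidy_series(list(A1 = c(1, 2), A2 = c(3, 4)), days = c(1, 10))
  n2 <- normalize_to_baseline(s2)
  expect_equal(n2$value[n2$day == 1], c(0.5, 1.5))
  expect_equal(mean(n2$value[n2$day == 1]), 1)

  s3 <- tidy_series(list(A1 = c(7, 7), A2 = c(7, 7)), days = c(1, 10))
  expect_equal(normalize_to_baseline(s3)$value, rep(1, 4))
})

test_that("baseline normalization rejects missing or zero baselines", {
  s <- data.frame(animal = c("A1", "A1", "A2"), modality = "m",
                  day = c(1, 10, 10), value = c(1, 2, 3))
  expect_error(normalize_to_baseline(s), "A2")
  z <- tidy_series(list(A1 = c(1, 2), A2 = c(-1, 2)), days = c(1, 10))
  expect_error(normalize_to_baseline(z), "zero baseline")
})

test_that("daily interpolation is linear between knots and exact at them", {
  d <- interpolate_daily(c(1, 4), c(1, 4))
  expect_equal(d$value, c(1, 2, 3, 4))
  expect_equal(d$measured, c(TRUE, FALSE, FALSE, TRUE))
  d2 <- interpolate_daily(c(1, 8), c(0, 14))
  expect_equal(d2$value[d2$day == 5], 8)
  # measured days exact, no extrapolation outside the measured span
  days <- c(3, 7, 20, 41)
  vals <- c(2.5, -1, 7, 0.3)
  d3 <- interpolate_daily(days, vals)
  expect_equal(d3$value[match(days, d3$day)], vals)
  expect_equal(range(d3$day), c(3, 41))
  expect_error(interpolate_daily(c(1, 1, 4), c(1, 2, 3)), "duplicate")
  expect_error(interpolate_daily(4, 1), "at least 2")
})

test_that("a constructed 5-day shift is recovered with R = 1 at every width", {
  f <- function(d) 1 + sin(d / 4) + 0.3 * cos(d / 9)
  fixed <- interpolate_daily(1:56, f(1:56))
  sliding <- interpolate_daily(1:56, f((1:56) - 5))
  res <- lag_correlation(fixed, sliding)
  b <- best_lag(res)
  expect_equal(b$lag, 5)
  expect_equal(b$r, 1.0)
  at5 <- res$grid[res$grid$lag == 5, ]
  expect_equal(at5$r, rep(1, nrow(at5)))
  expect_true(all(res$grid$p[res$grid$lag == 5] < 1e-6))
})

test_that("anti-correlated series give R = -1 at zero lag", {
  f <- interpolate_daily(1:56, sin(1:56 / 4))
  s <- interpolate_daily(1:56, -sin(1:56 / 4))
  res <- lag_correlation(f, s)
  r0 <- res$grid[res$grid$lag == 0, "r"]
  expect_equal(r0, rep(-1, length(r0)))
})

test_that("independent series leave most grid cells non-significant", {
  set.seed(3)
  f <- interpolate_daily(1:56, rnorm(56))
  s <- interpolate_daily(1:56, rnorm(56))
  res <- lag_correlation(f, s)
  avail <- res$grid[res$grid$available, ]
  expect_gt(mean(avail$p > 0.05), 0.5)
  wide <- avail[avail$width >= 21, ]
  expect_lt(max(abs(wide$r)), 0.8)
})

test_that("ties break toward the smallest lag, then the smallest width", {
  # constant-correlation construction: linear series correlate perfectly
  # at every lag and width, so the reported best must be lag 0, width 7
  f <- interpolate_daily(1:56, 1:56)
  s <- interpolate_daily(1:56, 2 * (1:56) + 3)
  b <- best_lag(lag_correlation(f, s))
  expect_equal(b$lag, 0)
  expect_equal(b$width, 7)
})

test_that("grid cells beyond series coverage are unavailable, not errors", {
  f <- interpolate_daily(1:30, sin(1:30 / 3))
  s <- interpolate_daily(1:30, sin((1:30 - 2) / 3))
  res <- lag_correlation(f, s, widths = c(7, 14, 21, 28, 35), max_lag = 10)
  expect_true(any(!res$grid$available))
  expect_true(all(is.na(res$grid$r[!res$grid$available])))
  expect_equal(best_lag(res)$lag, 2)
  short <- interpolate_daily(1:5, 1:5)
  expect_error(lag_correlation(short, short, widths = 35, max_lag = 40),
               "unavailable")
})

test_that("normalization and interpolation commute", {
  days <- c(1, 4, 10, 21)
  s <- tidy_series(list(A1 = c(2, 3, 6, 4), A2 = c(4, 1, 5, 2)), days)
  mean_daily <- function(df) {
    agg <- aggregate(value ~ day, df, mean)
    interpolate_daily(agg$day, agg$value)
  }
  a <- mean_daily(normalize_to_baseline(s))
  b <- mean_daily(s)
  b$value <- b$value / mean(s$value[s$day == 1])
  expect_equal(a$value, b$value)
})

test_that("timepoint comparison keeps its null rate on exchangeable data", {
  rejections <- vapply(1:60, function(s) {
    set.seed(s)
    m <- matrix(rnorm(8 * 4), 4, 8,
                dimnames = list(paste0("A", 1:4), paste0("d", 1:8)))
    compare_timepoints(m)$p < 0.05
  }, logical(1))
  expect_gte(mean(!rejections), 0.9)
})

test_that("a strongly shifted day is detected with flagged post hoc pairs", {
  set.seed(2)
  m <- matrix(rnorm(8 * 4), 4, 8,
              dimnames = list(paste0("A", 1:4), paste0("d", 1:8)))
  m[, 3] <- m[, 3] + 10
  rep_ <- compare_timepoints(m)
  expect_lt(rep_$p, 0.05)
  hits <- grepl("d3", rep_$posthoc$comparison) & rep_$posthoc$p_adj < 0.05
  expect_gt(sum(hits), 0)
})

test_that("skewed data routes to the Friedman test with Dunn post hoc", {
  set.seed(4)
  m <- matrix(rlnorm(8 * 5, sdlog = 3), 5, 8,
              dimnames = list(paste0("A", 1:5), paste0("d", 1:8)))
  rep_ <- compare_timepoints(m)
  expect_match(rep_$test, "Friedman")
  expect_false(all(rep_$normality$normal))
  # Friedman statistic reproduced by the base test
  fr <- friedman.test(m)
  expect_equal(rep_$statistic, unname(fr$statistic))
  expect_equal(rep_$df, 7)
})

test_that("paired comparison demands a complete table", {
  df <- data.frame(animal = c("A1", "A1", "A2", "A3", "A2", "A3"),
                   day = c(1, 4, 1, 1, 4, 4), value = rnorm(6))
  expect_silent(compare_timepoints(df))
  expect_error(compare_timepoints(df[-2, ]), "missing cells")
})
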