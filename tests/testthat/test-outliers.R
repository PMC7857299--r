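test_that("null thresholds use inclusive linear interpolation", {
  vals <- seq(0.0001, 1, by = 0.0001)  # 10,000 evenly spaced values
  nd <- build_null(vals, percentiles = 99)
  thr <- nd$thresholds$threshold
  expect_gt(thr, 0.99)
  expect_lt(thr, 1.00)
  expect_equal(thr, unname(quantile(vals, 0.99, type = 7)))
})

test_that("thresholds are monotone in the percentile", {
  set.seed(2)
  nd <- build_null(rbeta(2e6, 1, 20))
  expect_equal(nd$thresholds$percentile, c(99.9, 99.99, 99.999))
  expect_true(all(diff(nd$thresholds$threshold) >= 0))
})

test_that("a null that is too small for the percentile errors", {
  expect_error(build_null(runif(5000), percentiles = 99.9), "null too small")
  expect_error(build_null(runif(50000), percentiles = 99.99),
               "null too small")
  expect_silent(build_null(runif(11000), percentiles = 99.9))
})

test_that("calling a continuous null against itself is self-calibrating", {
  set.seed(8)
  n <- 2e5
  vals <- rbeta(n, 2, 30)
  nd <- build_null(vals, percentiles = c(99.9, 99.99))
  w <- tibble::tibble(start = seq_len(n) * 10 - 10, end = seq_len(n) * 10,
                      fst = vals)
  # exactly n * (1 - q) values exceed the type-7 quantile of distinct values
  expect_equal(nrow(call_outliers(w, nd, 99.99)), 20)
  expect_equal(nrow(call_outliers(w, nd, 99.9)), 200)

  # held-out draws from the same distribution exceed at rate ~ 1e-4
  held <- rbeta(n, 2, 30)
  k <- sum(held > nd$thresholds$threshold[2])
  expect_gte(k, qbinom(5e-4, n, 1e-4))
  expect_lte(k, qbinom(1 - 5e-4, n, 1e-4))
})

test_that("call_outliers respects thresholds and missing percentiles", {
  nd <- build_null(runif(20000), percentiles = 99.9)
  w <- tibble::tibble(start = c(0, 10), end = c(10, 20),
                      fst = c(0.1, NA))
  expect_equal(nrow(call_outliers(w, nd, 99.9)), 0)   # all below
  expect_error(call_outliers(w, nd, 99.99), "not present")
})

test_that("classification follows the lag/bierne/drift definitions", {
  call <- tibble::tibble(start = 45000, end = 55000, n_snps = 5L,
                         fst = 0.9, threshold = 0.5, percentile = 99.9,
                         class = "unclassified",
                         distance_to_selected = NA_real_,
                         nearest_mutation = NA_real_)
  base_sample <- list(
    generation = 1000L,
    params = list(mode = "global", n_per_deme = 200),
    selected = tibble::tibble(
      mutation = 1, position = 50000, kind = "beneficial",
      freq_deme1 = 0.9, freq_deme2 = 0.1, fix_gen = NA_integer_))

  # segregating beneficial at metapopulation frequency 0.5 inside window
  expect_equal(classify_outliers(call, base_sample)$class, "lag")

  # fixed 0.1 N generations ago, 2 kb away, nothing segregating
  s2 <- base_sample
  s2$selected <- tibble::tibble(
    mutation = 2, position = 52000, kind = "beneficial",
    freq_deme1 = 1, freq_deme2 = 1,
    fix_gen = 1000L - as.integer(0.1 * 400))
  cl2 <- classify_outliers(call, s2)
  expect_equal(cl2$class, "bierne")
  expect_equal(cl2$distance_to_selected, 2000)

  # fixation older than the horizon is not attributed to the sweep
  s3 <- s2
  s3$selected$fix_gen <- 0L
  expect_equal(classify_outliers(call, s3)$class, "unclassified")

  # neutral simulations: everything is drift
  s4 <- base_sample
  s4$params$mode <- "neutral"
  s4$selected <- s4$selected[0, ]
  expect_equal(classify_outliers(call, s4)$class, "drift")

  # outside the classification radius
  s5 <- base_sample
  s5$selected$position <- 90000
  expect_equal(classify_outliers(call, s5, radius = 10000)$class,
               "unclassified")
})

test_that("outlier rate is per 10,000 windows with a dataset bootstrap", {
  w <- tibble::tibble(start = rep(0, 10000), end = rep(10, 10000),
                      fst = runif(10000),
                      dataset = rep(1:100, each = 100))
  calls <- w[1:13, ]
  r <- outlier_rate(calls, w, n_boot = 500, seed = 1)
  expect_equal(r$rate, 13)

  # zero outliers: rate 0, degenerate bootstrap
  r0 <- outlier_rate(calls[0, ], w, n_boot = 100, seed = 1)
  expect_equal(r0$rate, 0)
  expect_true(all(r0$boot == 0))

  # bootstrap consistency: mean of resampled rates ~ point estimate
  expect_lt(abs(mean(r$boot) - r$rate) / r$rate, 0.15)
  expect_error(outlier_rate(calls, w[0, ]), "no tested windows")
})

test_that("profile aggregation bins symmetrically and flags truncation", {
  w <- tibble::tibble(start = seq(0, 99000, by = 1000),
                      end = seq(1000, 100000, by = 1000),
                      n_snps = 5L, fst = 0.1,
                      pi_w_deme1 = 2e-4, pi_w_deme2 = 2e-4,
                      pi_w_mean = 2e-4, d_xy = 3e-4)
  # two outliers: one centered, one at the genome edge (truncated flank)
  pr <- aggregate_profiles(list(w, w), centers = c(50000, 5000),
                           scenario = "neutral", flank = 4e4, bin = 1e4,
                           n_boot = 50, seed = 1)
  expect_true(all(c("scenario", "stat", "bin_mid", "mean", "lo", "hi", "n")
                  %in% names(pr)))
  bins <- sort(unique(pr$bin_mid))
  expect_equal(bins, -bins[length(bins):1])  # symmetric about 0
  # the edge outlier cannot contribute to the far-left bins
  left <- pr[pr$bin_mid == min(bins) & pr$stat == "fst", ]
  expect_lt(left$n, 2)
  # constant input gives back the constant
  expect_equal(unique(pr$mean[pr$stat == "d_xy"]), 3e-4)
})
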