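test_that("identical seed and params give a bit-identical sample", {
  p <- tiny_params()
  s1 <- wf_run(p, seed = 4)
  s2 <- wf_run(p, seed = 4)
  expect_identical(s1$positions, s2$positions)
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(s1$deme, s2$deme)
  s3 <- wf_run(p, seed = 5)
  expect_false(identical(s1$positions, s3$positions))
})

test_that("samples have the advertised shape and invariants", {
  p <- tiny_params()
  s <- wf_run(p, seed = 1)
  expect_equal(nrow(s$matrix), 2 * p$sample_size)
  expect_equal(s$deme, rep(1:2, each = p$sample_size))
  expect_equal(ncol(s$matrix), length(s$positions))
  expect_false(is.unsorted(s$positions))
  expect_true(all(s$positions >= 0 & s$positions < p$genome_length))
  # every column segregates in the sample
  cs <- colSums(s$matrix)
  expect_true(all(cs > 0 & cs < nrow(s$matrix)))
})

test_that("neutral diversity is near the structured-coalescent expectation", {
  # pi within a deme ~ 2 mu * 4N (mean within-deme pair coalescence 4N
  # generations in the symmetric two-deme model, any migration rate)
  p <- tiny_params()   # N = 30/deme, mu = 2e-6, L = 1e5
  expected_pi <- 2 * p$mu * 4 * p$n_per_deme
  pis <- vapply(1:6, function(r) {
    s <- wf_run(p, seed = 100 + r)
    mean(c(pi_within(s$matrix[s$deme == 1, , drop = FALSE],
                     p$genome_length),
           pi_within(s$matrix[s$deme == 2, , drop = FALSE],
                     p$genome_length)))
  }, numeric(1))
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - expected_pi), 3 * se + 0.2 * expected_pi)
})

test_that("beneficial fixation fraction matches the diffusion prediction", {
  # cross-module oracle: all gene-region mutations beneficial with
  # exponential effects; with Nm large the metapopulation is effectively
  # panmictic with 2N = 200 haploids
  # beneficial input kept to ~0.04 mutations/generation so sweeps are
  # rare enough to fix (or be lost) almost independently
  p <- sim_params(n_per_deme = 50, Nm = 25, genome_length = 1e5,
                  gene_regions = cbind(0, 1e5), mu = 2e-9, rec = 1e-4,
                  dfe = dfe_config(1, 0.2), mode = "global",
                  burn_in = 200, sample_size = 10)
  s <- wf_run(p, stop_after(30000), seed = 8, cap = 40000)
  arose <- unique(s$trajectories$mutation)
  fixed <- s$substitutions$mutation[s$substitutions$kind == "beneficial"]
  expect_gt(length(arose), 500)
  # expected fixation prob averaged over the DFE (heterozygous effect s/2)
  u_bar <- integrate(function(x)
    fixation_prob(x / 2, 2 * p$n_per_deme) * dexp(x, 1 / 0.2),
    0, Inf)$value
  phat <- length(fixed) / length(arose)
  se <- sqrt(u_bar * (1 - u_bar) / length(arose))
  # 3 SE plus a margin for residual interference among concurrent sweeps
  expect_lt(abs(phat - u_bar), 3 * se + 0.25 * u_bar)
})

test_that("sweeps reduce diversity near the selected site", {
  p <- sim_params(n_per_deme = 50, Nm = 1, genome_length = 4e5,
                  gene_regions = cbind(195000, 205000),
                  mu = 2e-6, rec = 2e-6,
                  dfe = dfe_config(0.05, 0.3), mode = "global",
                  burn_in = 2000, sample_size = 10)
  signs <- vapply(1:6, function(r) {
    s <- wf_run(p, stop_at_fixation(0.99), seed = 200 + r, cap = 30000)
    w <- window_scan(s, size = 2e4, step = 2e4)
    mid <- (w$start + w$end) / 2
    focal <- which.min(abs(mid - 2e5))
    w$pi_w_mean[focal] < median(w$pi_w_mean[abs(mid - 2e5) > 1e5])
  }, logical(1))
  expect_gte(sum(signs), 5)  # sign test across replicates
})

test_that("stop conditions hold at the sampled generation", {
  p <- sim_params(n_per_deme = 50, Nm = 1, genome_length = 2e5,
                  gene_regions = cbind(75000, 125000),
                  mu = 2e-6, rec = 2e-6,
                  dfe = dfe_config(0.05, 0.3), mode = "global",
                  burn_in = 1000, sample_size = 10)
  # lag: metapopulation frequency of the trigger inside the band
  s <- wf_run(p, stop_at_lag(0.5, 0.15), seed = 31, cap = 30000)
  tr <- s$trajectories[s$trajectories$mutation == s$trigger, ]
  last <- tr[which.max(tr$generation), ]
  f <- (last$freq_deme1 + last$freq_deme2) / 2
  expect_gte(f, 0.35); expect_lte(f, 0.65)

  # fixation: trigger above 0.99 in both demes
  s2 <- wf_run(p, stop_at_fixation(0.99), seed = 32, cap = 30000)
  tr2 <- s2$trajectories[s2$trajectories$mutation == s2$trigger, ]
  last2 <- tr2[which.max(tr2$generation), ]
  expect_gte(last2$freq_deme1, 0.99)
  expect_gte(last2$freq_deme2, 0.99)

  # at least one lag-phase replicate shows a between-deme frequency gap
  gaps <- abs(s$trajectories$freq_deme1 - s$trajectories$freq_deme2)
  expect_gt(max(gaps), 0.3)
})

test_that("a stop condition that cannot be met times out explicitly", {
  p <- tiny_params()  # neutral: no beneficial mutation can ever trigger
  expect_error(wf_run(p, stop_at_lag(0.5, 0.1), seed = 1, cap = 50),
               "timeout")
})

test_that("trajectories stay in [0,1] and end at loss, fixation or sampling", {
  p <- sim_params(n_per_deme = 40, Nm = 1, genome_length = 2e5,
                  gene_regions = cbind(50000, 150000),
                  mu = 2e-6, rec = 2e-6, dfe = dfe_config(0.05, 0.2),
                  mode = "global", burn_in = 500, sample_size = 10)
  s <- wf_run(p, stop_after(2000), seed = 77)
  tr <- s$trajectories
  expect_gt(nrow(tr), 0)
  expect_true(all(tr$freq_deme1 >= 0 & tr$freq_deme1 <= 1))
  expect_true(all(tr$freq_deme2 >= 0 & tr$freq_deme2 <= 1))
  ends <- dplyr::summarise(dplyr::group_by(tr, .data$mutation),
                           f = (dplyr::last(.data$freq_deme1) +
                                dplyr::last(.data$freq_deme2)) / 2,
                           g = max(.data$generation))
  expect_true(all(ends$f == 0 | ends$f == 1 | ends$g == s$generation))
})

test_that("local mode maintains the antagonistic allele for the set time", {
  p <- sim_params(n_per_deme = 40, Nm = 1, genome_length = 1e5,
                  gene_regions = cbind(45000, 55000),
                  mu = 1e-6, rec = 1e-6, mode = "local_antagonistic",
                  s_local = 0.5, burn_in = 500, sample_size = 10)
  s <- wf_run(p, stop_local_established(300), seed = 9, cap = 100000)
  foc <- s$selected[s$selected$kind == "antagonistic", ]
  expect_equal(nrow(foc), 1)
  f <- (foc$freq_deme1 + foc$freq_deme2) / 2
  expect_gt(f, 0); expect_lt(f, 1)
  # favored in deme 1: frequency higher there
  expect_gt(foc$freq_deme1, foc$freq_deme2)
  tr <- s$trajectories[s$trajectories$mutation == foc$mutation, ]
  expect_gte(max(tr$generation) - min(tr$generation), 300 - 1)
})

test_that("neutral F_ST is insensitive to population rescaling", {
  mean_fst <- function(n, seed) {
    p <- sim_params(n_per_deme = n, Nm = 1, genome_length = 2e5,
                    mu = 5e-7 * 100 / n, rec = 5e-7 * 100 / n,
                    mode = "neutral", sample_size = 16)
    bs <- wf_burn_in(p, derive_seed(seed, "rb", 0))
    f <- unlist(lapply(1:6, function(r) {
      s <- wf_run(p, stop_after(4 * n), seed = derive_seed(seed, "rf", r),
                  burn_in_state = bs)
      window_scan(s, 2e4, 2e4)$fst
    }))
    mean(f, na.rm = TRUE)
  }
  f100 <- mean_fst(100, 21)
  f50 <- mean_fst(50, 22)
  expect_lt(abs(f100 - f50), 0.06)
  expect_lt(abs(f100 - 1 / 9), 0.05)
})
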