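test_that("fixation probability has the right limits and shape", {
  expect_equal(fixation_prob(0, 1000), 1 / 2000)
  # closed form evaluated independently
  expect_equal(fixation_prob(0.01, 1000),
               (1 - exp(-0.02)) / (1 - exp(-40)), tolerance = 1e-12)
  # continuous at 0
  expect_equal(fixation_prob(1e-10, 1000), 1 / 2000, tolerance = 1e-4)
  # strong-selection asymptote u -> 2 s_het (rel. error < 5% at 4Ns = 40)
  expect_lt(abs(fixation_prob(0.01, 1000) - 0.02) / 0.02, 0.05)
  # bounded and monotone increasing
  s <- seq(0, 0.05, by = 0.005)
  u <- fixation_prob(s, 500)
  expect_true(all(u > 0 & u < 1))
  expect_true(all(diff(u) > 0))
})

test_that("sweep durations match the logistic and diffusion forms", {
  d <- sweep_duration(1.25e-4, 1e6)
  expect_equal(d$t_intermediate, log(16) / 1.25e-4, tolerance = 1e-12)
  expect_equal(d$t_fix, (2 / 1.25e-4) * (log(250) - digamma(1)),
               tolerance = 1e-12)

  # logistic transit symmetry: p -> 1/2 takes as long as 1/2 -> 1-p
  a <- sweep_duration(0.01, 1e4, p_lo = 0.1, p_hi = 0.5)$t_intermediate
  b <- sweep_duration(0.01, 1e4, p_lo = 0.5, p_hi = 0.9)$t_intermediate
  expect_equal(a, b)

  # monotone decreasing in s
  t1 <- sweep_duration(0.001, 1e5)
  t2 <- sweep_duration(0.01, 1e5)
  expect_gt(t1$t_intermediate, t2$t_intermediate)
  expect_gt(t1$t_fix, t2$t_fix)

  expect_error(sweep_duration(0, 100), "`s`")
})

test_that("sojourn-time quadrature matches a Wright-Fisher oracle", {
  # frozen oracle: mean conditional fixation time from 300 WF replicates at
  # N = 500, s_het = 0.01 (semidominant) was 696.5 with SE 11.6
  tq <- sweep_duration(0.01, 500, fixation_method = "quadrature")$t_fix
  expect_lt(abs(tq - 696.5), 3 * 11.6)
})

test_that("adaptive substitution rate and waiting time follow alpha*L*d/T", {
  r <- adaptive_substitution_rate(0.5, 15e6, 0.0067, 14e6)
  expect_equal(r$rate, 0.5 * 15e6 * 0.0067 / 14e6)
  expect_equal(r$waiting_time, 1 / r$rate)
  expect_identical(adaptive_substitution_rate(0, 1e6, 0.01, 1e6)$waiting_time,
                   Inf)
  expect_error(adaptive_substitution_rate(0.5, 1e6, 0.01, 0), "T_gen")
})

test_that("incomplete sweep count is rate x duration", {
  expect_equal(n_incomplete_sweeps(1 / 280, 22200), 22200 / 280)
  expect_equal(n_incomplete_sweeps(0, 5000), 0)
  expect_equal(n_incomplete_sweeps(0.01, 500),
               2 * n_incomplete_sweeps(0.01, 250))
})

test_that("predicted alpha matches a Monte-Carlo DFE average", {
  expect_equal(predict_alpha(dfe_config(0, 0.1), 1000), 0)
  expect_equal(predict_alpha(dfe_config(1, 0.5), 5000), 1)

  # Monte-Carlo oracle: average fixation prob over 1e6 exponential draws
  set.seed(7)
  N <- 5000; p_a <- 1e-4; sbar <- 0.02
  u_mc <- mean(fixation_prob(rexp(1e6, 1 / sbar) / 2, N))
  alpha_mc <- p_a * u_mc / (p_a * u_mc + (1 - p_a) / (2 * N))
  a <- predict_alpha(dfe_config(p_a, sbar), N)
  expect_lt(abs(a - alpha_mc) / alpha_mc, 0.01)

  # monotone in p_a and mean_s
  a2 <- predict_alpha(dfe_config(2e-4, sbar), N)
  a3 <- predict_alpha(dfe_config(p_a, 2 * sbar), N)
  expect_gt(a2, a)
  expect_gt(a3, a)
})

test_that("the Drosophila-style summary chains the pieces consistently", {
  s <- sweep_theory_summary(0.5, 15e6, 0.0067, 14e6, N = 1e6, two_Ns = 250)
  expect_equal(s$s, 1.25e-4)
  expect_equal(s$n_incomplete_sweeps, s$rate * s$t_intermediate)
  g <- glance(s)
  expect_named(g, c("rate", "waiting_time", "t_intermediate", "t_fix",
                    "n_incomplete_sweeps"))
})
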