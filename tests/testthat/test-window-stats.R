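test_that("Weir-Cockerham theta matches hand-derivable cases", {
  # fixed difference between demes: maximal differentiation
  expect_equal(wc_fst(1, 0, 10, 10), 1)
  # identical intermediate frequencies: theta = -1/9 (direct evaluation)
  expect_equal(wc_fst(0.5, 0.5, 10, 10), -1 / 9, tolerance = 1e-12)
  # no polymorphism: undefined, not zero
  expect_true(is.na(wc_fst(0, 0, 10, 10)))
  expect_true(is.na(wc_fst(numeric(0), numeric(0), 10, 10)))
})

test_that("theta equals the brute-force variance-component oracle", {
  set.seed(11)
  for (k in 1:100) {
    nsite <- sample(1:8, 1)
    n1 <- sample(4:20, 1); n2 <- sample(4:20, 1)
    p1 <- sample(0:n1, nsite, replace = TRUE) / n1
    p2 <- sample(0:n2, nsite, replace = TRUE) / n2
    got <- wc_fst(p1, p2, n1, n2)
    want <- oracle_wc_theta(p1, p2, n1, n2)
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("theta is invariant under allele-label swap at every site", {
  set.seed(3)
  p1 <- runif(10); p2 <- runif(10)
  expect_equal(wc_fst(p1, p2, 12, 14), wc_fst(1 - p1, 1 - p2, 12, 14),
               tolerance = 1e-12)
})

test_that("pi_within matches pair enumeration", {
  # all identical haplotypes
  expect_equal(pi_within(matrix(1, 4, 3), 100), 0)
  # two haplotypes differing at one site out of 10 kb
  expect_equal(pi_within(rbind(c(0, 1), c(0, 0)), 1e4), 1e-4)
  # n = 4 with derived count 2: 4 of 6 pairs differ
  m <- rbind(1, 1, 0, 0)
  expect_equal(pi_within(m, 1e4), (4 / 6) / 1e4)
  expect_error(pi_within(matrix(0, 1, 3), 100), ">= 2")

  set.seed(5)
  for (k in 1:100) {
    n <- sample(2:8, 1); s <- sample(1:10, 1)
    m <- matrix(rbinom(n * s, 1, runif(1)), n, s)
    expect_equal(pi_within(m, 1000), oracle_pi(m, 1000), tolerance = 1e-12)
  }
})

test_that("d_xy matches pair enumeration and self-comparison identity", {
  expect_equal(d_xy(matrix(0, 3, 2), matrix(0, 4, 2), 100), 0)
  expect_equal(d_xy(rbind(c(1, 0)), rbind(c(0, 0)), 1e4), 1e-4)
  expect_error(d_xy(matrix(0, 0, 2), matrix(0, 3, 2), 100), ">= 1")

  set.seed(6)
  for (k in 1:100) {
    s <- sample(1:10, 1)
    m1 <- matrix(rbinom(4 * s, 1, 0.4), 4, s)
    m2 <- matrix(rbinom(6 * s, 1, 0.6), 6, s)
    expect_equal(d_xy(m1, m2, 500), oracle_dxy(m1, m2, 500),
                 tolerance = 1e-12)
  }

  # comparing a deme with itself: d_xy equals pooled pi up to n/(n-1)
  m <- matrix(rbinom(6 * 8, 1, 0.5), 6, 8)
  n <- 2 * nrow(m)
  expect_equal(d_xy(m, m, 100),
               pi_within(rbind(m, m), 100) * (n - 1) / n, tolerance = 1e-12)
})

test_that("window_scan lays out windows correctly", {
  s <- random_sample(n_hap = 20, n_site = 40, L = 20000)
  w <- window_scan(s, size = 10000, step = 500)
  expect_equal(nrow(w), 21)
  expect_equal(w$start[1], 0)
  expect_equal(c(w$start[21], w$end[21]), c(10000, 20000))

  g <- window_scan(s, size = 10000, centering = "gene_centered",
                   gene_regions = cbind(47500, 52500),
                   genome_length = 20000)
  expect_equal(nrow(g), 1)
  expect_equal(c(g$start, g$end), c(45000, 55000))

  expect_error(window_scan(s, size = 0), "> 0")
  expect_error(window_scan(s, step = -1), "> 0")
})

test_that("window statistics are invariant to haplotype row order", {
  s <- random_sample(n_hap = 16, n_site = 60, L = 50000)
  w1 <- window_scan(s, size = 10000, step = 5000)
  set.seed(9)
  perm <- c(sample(1:8), sample(9:16))  # permute within demes
  s2 <- s
  s2$matrix <- s$matrix[perm, ]
  s2$deme <- s$deme[perm]
  w2 <- window_scan(s2, size = 10000, step = 5000)
  expect_equal(w1, w2)
})

test_that("empty windows are reported with undefined F_ST", {
  s <- random_sample(n_hap = 8, n_site = 5, L = 1e5, seed = 2)
  s$positions <- seq(1000, 5000, length.out = 5)  # all sites in [0, 10kb)
  w <- window_scan(s, size = 10000, step = 10000)
  expect_true(is.na(w$fst[w$n_snps == 0][1]))
  expect_true(all(w$pi_w_mean[w$n_snps == 0] == 0))
  expect_true(all(w$d_xy[w$n_snps == 0] == 0))
  # windowed stats agree with direct per-window computation
  in1 <- s$positions < 10000
  expect_equal(w$fst[1],
               wc_fst(colMeans(s$matrix[s$deme == 1, in1, drop = FALSE]),
                      colMeans(s$matrix[s$deme == 2, in1, drop = FALSE]),
                      4, 4))
})
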