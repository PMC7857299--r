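# Independent brute-force oracles used across tests. These deliberately
# re-derive each statistic from first principles (pair enumeration, literal
# variance components) rather than reusing the package's closed forms.

# mean pairwise differences per site within a haplotype matrix, by
# enumerating all C(n,2) pairs
oracle_pi <- function(mat, L) {
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      tot <- tot + sum(mat[i, ] != mat[j, ])
  tot / choose(n, 2) / L
}

# mean pairwise differences per site across demes, enumerating all pairs
oracle_dxy <- function(m1, m2, L) {
  tot <- 0
  for (i in seq_len(nrow(m1)))
    for (j in seq_len(nrow(m2)))
      tot <- tot + sum(m1[i, ] != m2[j, ])
  tot / (nrow(m1) * nrow(m2)) / L
}

# literal Weir-Cockerham theta for haploid counts: variance components
# computed step by step per site, combined as a ratio of sums
oracle_wc_theta <- function(p1, p2, n1, n2) {
  r <- 2
  num <- den <- 0
  for (s in seq_along(p1)) {
    ni <- c(n1, n2); pi <- c(p1[s], p2[s])
    nbar <- sum(ni) / r
    pw <- sum(ni * pi) / sum(ni)
    msa <- sum(ni * (pi - pw)^2) / (r - 1)
    msw <- sum(ni * pi * (1 - pi)) / sum(ni - 1)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    num <- num + (msa - msw)
    den <- den + (msa + (nc - 1) * msw)
  }
  if (den <= 0) return(NA_real_)
  num / den
}

# single-locus Wright-Fisher fixation fraction (diploid, semidominant:
# genotype fitnesses 1, 1+s_het, 1+2*s_het), vectorised over replicates
oracle_wf_fix_fraction <- function(N, s_het, n_rep, seed = 1) {
  set.seed(seed)
  p <- rep(1 / (2 * N), n_rep)
  alive <- rep(TRUE, n_rep)
  while (any(alive)) {
    q <- p[alive]
    wbar <- q^2 * (1 + 2 * s_het) + 2 * q * (1 - q) * (1 + s_het) +
      (1 - q)^2
    qq <- (q^2 * (1 + 2 * s_het) + q * (1 - q) * (1 + s_het)) / wbar
    q <- rbinom(sum(alive), 2 * N, qq) / (2 * N)
    p[alive] <- q
    alive[alive] <- q > 0 & q < 1
  }
  mean(p == 1)
}

# tiny fast neutral parameter set for simulator tests
tiny_params <- function(...) {
  sim_params(n_per_deme = 30, Nm = 1, genome_length = 1e5,
             mu = 2e-6, rec = 2e-6, mode = "neutral",
             burn_in = 600, sample_size = 10, ...)
}

# random haplotype sample in the shape window_scan() expects
random_sample <- function(n_hap = 20, n_site = 50, L = 1e5, seed = 1) {
  set.seed(seed)
  list(positions = sort(runif(n_site, 0, L)),
       matrix = matrix(rbinom(n_hap * n_site, 1, 0.3), n_hap, n_site),
       deme = rep(1:2, each = n_hap / 2),
       generation = 0L,
       params = list(genome_length = L))
}
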