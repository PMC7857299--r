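test_that("the sweep time course keeps tables consistent", {
  p <- sim_params(n_per_deme = 40, Nm = 1, genome_length = 2e5,
                  gene_regions = cbind(c(40000, 140000), c(60000, 160000)),
                  mu = 2e-6, rec = 2e-6, dfe = dfe_config(0.05, 0.2),
                  mode = "global", burn_in = 500, sample_size = 10)
  tc <- experiment_single_sweep(p, total_generations = 600,
                                sample_every = 200, seed = 3,
                                size = 2e4, step = 1e4)
  expect_equal(sort(unique(tc$scans$generation)), 500 + c(200, 400, 600))
  # referential integrity: selected mutations in each sample's metadata
  # appear in the trajectory table
  for (smp in tc$samples) {
    seg <- smp$segregating_selected
    if (nrow(seg) > 0)
      expect_true(all(seg$mutation %in% tc$trajectories$mutation))
  }
  # scans carry the full window grid each time point
  expect_equal(nrow(tc$scans) %% 3, 0)
})

test_that("a post-fixation F_ST peak dissipates under continued migration", {
  p <- sim_params(n_per_deme = 50, Nm = 1, genome_length = 2e5,
                  gene_regions = cbind(75000, 125000), mu = 2e-6, rec = 2e-6,
                  dfe = dfe_config(0.05, 0.5), mode = "global",
                  burn_in = 2000, sample_size = 30)
  # find a replicate whose sweep left a real F_ST peak at fixation, then
  # let migration act for 400 generations (m t >> 1) and re-scan
  found <- FALSE
  for (r in 1:8) {
    s <- tryCatch(wf_run(p, stop_at_fixation(0.99), seed = 900 + r,
                         cap = 50000), error = function(e) NULL)
    if (is.null(s)) next
    ctr <- s$selected$position[match(s$trigger, s$selected$mutation)]
    w1 <- window_scan(s, 2e4, 1e4)
    near <- abs((w1$start + w1$end) / 2 - ctr) <= 2e4
    f1 <- max(w1$fst[near], na.rm = TRUE)
    if (f1 < 0.45) next
    found <- TRUE
    s2 <- wf_run(p, stop_after(400), seed = 1400 + r,
                 burn_in_state = list(state = s$state,
                                      generation = s$generation))
    w2 <- window_scan(s2, 2e4, 1e4)
    f2 <- max(w2$fst[abs((w2$start + w2$end) / 2 - ctr) <= 2e4],
              na.rm = TRUE)
    expect_lt(f2, f1)
    expect_lt(f2, 0.45)
    break
  }
  expect_true(found)
})

test_that("profile scenario labels propagate and bins are well-formed", {
  pr <- experiment_profiles(n_outliers = 2, seed = 12,
                            scenarios = c("lag", "neutral"),
                            n_per_deme = 80, genome_length = 4e5,
                            flank = 5e4, bin = 1e4)
  expect_setequal(unique(pr$profiles$scenario), c("lag", "neutral"))
  expect_true(all(pr$profiles$n >= 1))
  expect_equal(pr$n_found[["lag"]], 2)
  bins <- sort(unique(pr$profiles$bin_mid))
  expect_equal(bins, -rev(bins))
  expect_true(all(c("fst", "pi_w", "d_xy") %in% pr$profiles$stat))
})

test_that("grid experiment produces calibrated neutral-free rates", {
  grid <- tibble::tibble(mean_s = 0.3, p_a = 0.1, Nm = 1, n_per_deme = 80)
  res <- experiment_outlier_rates(grid, replicates = 8, null_forks = 8,
                                  percentiles = 99.9,
                                  main_generations = 200,
                                  n_burn_in = 1, seed = 6,
                                  n_boot = 100)
  r <- res$rates
  expect_equal(nrow(r), 1)
  # 10 gene windows x 8 datasets, minus any windows without SNPs
  expect_lte(r$n_windows, 80)
  expect_gte(r$n_windows, 40)
  expect_true(is.na(r$alpha_realized) ||
                (r$alpha_realized >= 0 && r$alpha_realized <= 1))
  expect_s3_class(res$nulls[[1]], "null_distribution")
})
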