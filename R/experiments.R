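#' Standard desk-scale parameter set
#'
#' The package's default "desk world": two demes of 200 diploids, a 1 Mbp
#' chromosome with ten 5 kb gene-like regions (5% functional, mirroring a
#' 25/500 Mbp ratio), `mu = rec = 2.5e-7` per bp per generation (per-site
#' `4 Ne mu = 4e-4` with `Ne = 400` metapopulation diploids), burn-in
#' `10 * 2 Ne` generations. Experiments at this scale reproduce orderings
#' and qualitative signatures; full-scale runs (5000 per deme, 500 Mbp)
#' use the same code with different parameters.
#'
#' @param Nm Migrants received per deme per generation.
#' @param mode Selection regime.
#' @param p_a,mean_s DFE of beneficial mutations in gene regions.
#' @param n_per_deme Diploids per deme.
#' @param genome_length Chromosome length (bp).
#' @param s_local Antagonistic-allele effect for local mode.
#' @param rec Recombination rate per bp per generation.
#' @param ... Passed on to [sim_params()].
#' @return A [sim_params()] object.
#' @export
desk_params <- function(Nm = 1, mode = "neutral", p_a = 0, mean_s = 0,
                        n_per_deme = 200, genome_length = 1e6,
                        s_local = 0.05, rec = 2.5e-7, ...) {
  sim_params(n_per_deme = n_per_deme, Nm = Nm,
             genome_length = genome_length,
             mu = 2.5e-7, rec = rec,
             dfe = dfe_config(p_a, mean_s), mode = mode,
             s_local = s_local, ...)
}

#' Time course of a genome scan during recurrent sweeps
#'
#' Runs one replicate under recurrent globally beneficial mutations,
#' sampling and scanning the genome every `sample_every` generations: the
#' Manhattan-plot-over-time experiment. Returns the sliding-window F_ST
#' (and diversity) time series, the per-generation allele-frequency
#' trajectories of every beneficial mutation, and the substitution record.
#'
#' @param params A [sim_params()] with `mode = "global"`.
#' @param total_generations Length of the selection phase.
#' @param sample_every Generations between genome scans.
#' @param seed Integer seed.
#' @param size,step Window size/step for the sliding scan.
#' @return A list of class `sweep_timecourse`: `scans` (tibble with
#'   `generation` + window columns), `trajectories`, `substitutions`,
#'   `samples` (list of `hap_sample`s), `params`.
#' @export
experiment_single_sweep <- function(params, total_generations = NULL,
                                    sample_every = NULL, seed = 1L,
                                    size = 10000, step = 500) {
  stopifnot(params$mode == "global")
  ne <- 2 * params$n_per_deme
  total_generations <- total_generations %||% (10L * ne)
  sample_every <- sample_every %||% max(1L, ne %/% 4L)
  bs <- wf_burn_in(params, derive_seed(seed, "fig1_burnin", 0L))
  state <- bs$state
  scans <- list(); samples <- list()
  traj <- list(); subs <- list()
  n_chunk <- ceiling(total_generations / sample_every)
  for (k in seq_len(n_chunk)) {
    res <- run_phase(state, params,
                     list(type = "generations", T = sample_every,
                          cap = sample_every, selection = TRUE,
                          record = TRUE),
                     derive_seed(seed, "fig1_chunk", k))
    state <- res$state
    traj[[k]] <- res$traj; subs[[k]] <- res$subs
    smp <- wf_sample(state, params, derive_seed(seed, "fig1_sample", k))
    smp$params <- params
    w <- window_scan(smp, size = size, step = step)
    w$generation <- smp$generation
    scans[[k]] <- w
    samples[[k]] <- smp
  }
  structure(list(
    scans = dplyr::bind_rows(scans),
    trajectories = dplyr::bind_rows(traj),
    substitutions = dplyr::bind_rows(subs),
    samples = samples, params = params),
    class = "sweep_timecourse")
}

#' Outlier rates across a DFE x migration grid
#'
#' The grid experiment: for each cell (`mean_s`, `p_a`, `Nm`,
#' `n_per_deme`), simulate `replicates` datasets under recurrent global
#' adaptation, scan gene-centered windows, call outliers against a
#' matched neutral null (same demography, windows pooled over neutral
#' forks of shared burn-ins), and report rates per 10,000 windows with a
#' dataset bootstrap, the realized adaptive proportion of substitutions
#' (alpha), and the lag/Bierne classification mix.
#'
#' @param grid Tibble with columns `mean_s`, `p_a`, `Nm` (and optionally
#'   `n_per_deme`).
#' @param replicates Simulated datasets per cell.
#' @param null_forks Neutral replicates per demography for the null
#'   (sliding windows are pooled, so each fork contributes many windows).
#' @param percentiles Outlier thresholds (percent).
#' @param main_generations Selection-phase length before sampling
#'   (default `2 * 2 Ne`, decorrelating forks of a shared burn-in).
#' @param n_burn_in Independent burn-ins per demography that forks are
#'   spread over.
#' @param seed Master seed.
#' @param size Window size (bp).
#' @param n_boot Bootstrap resamples for rates.
#' @return A list of class `outlier_rate_grid`: `rates` (tibble: cell,
#'   percentile, rate, CI, n_outliers, n_windows, alpha_realized,
#'   lag_fraction), `nulls` (per demography), `calls`, `windows`.
#' @export
experiment_outlier_rates <- function(grid, replicates = 50, null_forks = 60,
                                     percentiles = c(99.9, 99.99),
                                     main_generations = NULL,
                                     n_burn_in = 2, seed = 1L,
                                     size = 10000, n_boot = 1000) {
  grid <- tibble::as_tibble(grid)
  if (!"n_per_deme" %in% names(grid)) grid$n_per_deme <- 200L
  demos <- dplyr::distinct(grid[, c("Nm", "n_per_deme")])

  # shared neutral burn-ins + neutral null per demography
  nulls <- list(); burns <- list()
  for (i in seq_len(nrow(demos))) {
    dm <- demos[i, ]
    key <- paste(dm$Nm, dm$n_per_deme)
    p0 <- desk_params(Nm = dm$Nm, mode = "neutral",
                      n_per_deme = dm$n_per_deme)
    mg <- main_generations %||% (2L * 2L * 2L * p0$n_per_deme)
    burns[[key]] <- lapply(seq_len(n_burn_in), function(b)
      wf_burn_in(p0, derive_seed(seed, paste0("null_burnin_", key), b)))
    nw <- lapply(seq_len(null_forks), function(r) {
      bs <- burns[[key]][[1 + (r - 1) %% n_burn_in]]
      s <- wf_run(p0, stop_after(mg),
                  seed = derive_seed(seed, paste0("null_fork_", key), r),
                  burn_in_state = bs)
      window_scan(s, size = size, step = 500)
    })
    nulls[[key]] <- build_null(nw, percentiles = percentiles)
  }

  all_windows <- list(); all_calls <- list(); rates <- list()
  for (ci in seq_len(nrow(grid))) {
    cf <- grid[ci, ]
    key <- paste(cf$Nm, cf$n_per_deme)
    p <- desk_params(Nm = cf$Nm, mode = "global", p_a = cf$p_a,
                     mean_s = cf$mean_s, n_per_deme = cf$n_per_deme)
    mg <- main_generations %||% (2L * 2L * 2L * p$n_per_deme)
    lab <- sprintf("cell%d", ci)
    wins <- list(); calls <- list()
    n_ben_subs <- 0L; n_gene_subs <- 0L
    for (r in seq_len(replicates)) {
      bs <- burns[[key]][[1 + (r - 1) %% n_burn_in]]
      s <- wf_run(p, stop_after(mg),
                  seed = derive_seed(seed, paste0("fork_", lab), r),
                  burn_in_state = bs)
      w <- window_scan(s, size = size, centering = "gene_centered")
      w$dataset <- r
      wins[[r]] <- w
      sub_gene <- dplyr::filter(
        s$substitutions,
        in_gene_region(.data$position, p$gene_regions))
      n_gene_subs <- n_gene_subs + nrow(sub_gene)
      n_ben_subs <- n_ben_subs + sum(sub_gene$kind == "beneficial")
      for (q in percentiles) {
        cl <- call_outliers(w, nulls[[key]], q)
        if (nrow(cl)) {
          cl <- classify_outliers(cl, s, radius = size)
          cl$dataset <- r
          calls[[length(calls) + 1L]] <- cl
        }
      }
    }
    wins <- dplyr::bind_rows(wins)
    calls <- dplyr::bind_rows(calls)
    all_windows[[ci]] <- dplyr::mutate(wins, cell = ci)
    all_calls[[ci]] <- if (nrow(calls)) dplyr::mutate(calls, cell = ci)
    for (q in percentiles) {
      cq <- if (nrow(calls)) calls[calls$percentile == q, ] else calls
      rt <- outlier_rate(cq, wins, n_boot = n_boot,
                         seed = derive_seed(seed, paste0("boot_", lab),
                                            round(q * 1000)))
      lagf <- if (nrow(cq) > 0)
        mean(cq$class == "lag") else NA_real_
      rates[[length(rates) + 1L]] <- tibble::tibble(
        cell = ci, mean_s = cf$mean_s, p_a = cf$p_a, Nm = cf$Nm,
        n_per_deme = cf$n_per_deme, percentile = q,
        rate = rt$rate, ci_lo = rt$ci[1], ci_hi = rt$ci[2],
        n_outliers = rt$n_outliers, n_windows = rt$n_windows,
        alpha_realized = if (n_gene_subs > 0) n_ben_subs / n_gene_subs
                         else NA_real_,
        lag_fraction = lagf)
    }
  }
  structure(list(rates = dplyr::bind_rows(rates), nulls = nulls,
                 calls = dplyr::bind_rows(all_calls),
                 windows = dplyr::bind_rows(all_windows), grid = grid),
            class = "outlier_rate_grid")
}

in_gene_region <- function(pos, gene_regions) {
  if (length(pos) == 0) return(logical(0))
  if (nrow(gene_regions) == 0) return(rep(FALSE, length(pos)))
  i <- findInterval(pos, gene_regions[, 1])
  i > 0 & pos < gene_regions[cbind(pmax(i, 1), 2)]
}

#' Diversity profiles around outliers for four evolutionary scenarios
#'
#' The scenario-comparison experiment: collects `n_outliers` F_ST outlier
#' regions under each of four processes -- `lag` (sampled mid-sweep),
#' `bierne` (sampled just after fixation), `local` (spatially
#' antagonistic allele maintained `5 Ne` generations) and `neutral`
#' (drift only) -- and aggregates F_ST, pi_W and d_XY in distance bins
#' around the causal site (outlier window center for neutral).
#'
#' @param n_outliers Outliers to collect per scenario.
#' @param seed Master seed.
#' @param scenarios Subset of `c("lag", "bierne", "local", "neutral")`.
#' @param Nm Migration level (default 1, as in the scenario comparison).
#' @param s_a Selection coefficient scale: DFE mean for the global-sweep
#'   scenarios and the antagonistic allele's effect in the local scenario.
#'   The desk default 0.5 keeps the barrier strength `s/m` large (50, so
#'   sweeping alleles lag visibly between demes) while the hitchhiking
#'   footprint `~s/(rec ln 4Ns)` stays well under the flank width.
#' @param p_a Beneficial fraction for the global-sweep scenarios, set so
#'   that condition-triggered sweeps arrive within a few thousand
#'   generations but rarely overlap.
#' @param percentile Outlier threshold percentile (default 99; at desk
#'   sample sizes the F_ST null tail is wide, so this plays the role the
#'   99.99th percentile plays on half-million-window genomes at full scale).
#'   The null is built from neutral sliding windows of the same demography.
#' @param flank,bin Profile extent and bin width (bp).
#' @param max_attempts Replicate budget per scenario; if exhausted a
#'   partial result is returned with a warning.
#' @param n_per_deme,genome_length Desk-world demography.
#' @param rec Recombination rate (default 2.5e-6/bp, ten times the mutation
#'   rate, so sweep troughs are localized relative to the 1 Mbp genome).
#' @param sample_size Haplotypes sampled per deme (50: window F_ST noise,
#'   and hence the null tail, shrinks with sample size).
#' @return A list of class `profile_experiment`: `profiles` (binned
#'   [aggregate_profiles()] tibble over scenarios), `n_found`, `null`,
#'   `threshold`, `background` (genome-median stats from the neutral
#'   forks).
#' @export
experiment_profiles <- function(n_outliers = 20, seed = 1L,
                                scenarios = c("lag", "bierne", "local",
                                              "neutral"),
                                Nm = 1, s_a = 0.5, p_a = 0.02,
                                percentile = 99,
                                flank = 1e5, bin = 1e4,
                                max_attempts = NULL,
                                n_per_deme = 200, genome_length = 1e6,
                                rec = 2.5e-6, sample_size = 50L) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  max_attempts <- max_attempts %||% (20L * n_outliers)
  p_neut <- desk_params(Nm = Nm, mode = "neutral", n_per_deme = n_per_deme,
                        genome_length = genome_length, rec = rec,
                        sample_size = sample_size)
  ne <- 2L * n_per_deme
  mg <- 2L * 2L * ne

  # neutral null from shared-burn-in forks; also the background level
  n_null_forks <- max(10L, ceiling(2e4 / (genome_length / 500)))
  bs <- lapply(1:2, function(b)
    wf_burn_in(p_neut, derive_seed(seed, "prof_null_burnin", b)))
  null_scans <- lapply(seq_len(n_null_forks), function(r) {
    s <- wf_run(p_neut, stop_after(mg),
                seed = derive_seed(seed, "prof_null_fork", r),
                burn_in_state = bs[[1 + (r - 1) %% 2]])
    window_scan(s, size = 1e4, step = 500)
  })
  null <- build_null(null_scans, percentiles = percentile)
  thr <- null_threshold(null, percentile)
  pooled <- dplyr::bind_rows(null_scans)
  background <- tibble::tibble(
    fst = stats::median(pooled$fst, na.rm = TRUE),
    pi_w = stats::median(pooled$pi_w_mean),
    d_xy = stats::median(pooled$d_xy))

  profiles <- list(); n_found <- integer(0)
  for (sc in scenarios) {
    scans <- list(); centers <- numeric(0)
    attempts <- 0L
    r <- 0L
    while (length(centers) < n_outliers && attempts < max_attempts) {
      attempts <- attempts + 1L; r <- r + 1L
      got <- collect_profile_outlier(
        sc, p_neut, bs[[1 + (r - 1) %% 2]], thr, s_a, p_a, Nm, mg,
        n_per_deme, genome_length, rec, sample_size,
        derive_seed(seed, paste0("prof_", sc), r))
      for (g in got) {
        if (length(centers) >= n_outliers) break
        scans[[length(scans) + 1L]] <- g$scan
        centers <- c(centers, g$center)
      }
    }
    if (length(centers) < n_outliers)
      warning(sprintf(
        "scenario %s: only %d of %d outliers found in %d attempts",
        sc, length(centers), n_outliers, attempts))
    n_found[sc] <- length(centers)
    if (length(centers) > 0)
      profiles[[sc]] <- aggregate_profiles(
        scans, centers, scenario = sc, flank = flank, bin = bin,
        seed = derive_seed(seed, paste0("prof_boot_", sc), 0L))
  }
  per_outlier <- dplyr::bind_rows(
    lapply(profiles, function(p) attr(p, "per_outlier")))
  structure(list(profiles = dplyr::bind_rows(profiles), n_found = n_found,
                 per_outlier = per_outlier,
                 null = null, threshold = thr, background = background),
            class = "profile_experiment")
}

# one replicate of a profile scenario; returns list of list(scan, center)
collect_profile_outlier <- function(sc, p_neut, bs, thr, s_a, p_a, Nm, mg,
                                    n_per_deme, genome_length, rec,
                                    sample_size, seed) {
  if (sc == "neutral") {
    s <- wf_run(p_neut, stop_after(mg), seed = seed, burn_in_state = bs)
    w <- window_scan(s, size = 1e4, step = 500)
    hits <- which(!is.na(w$fst) & w$fst > thr)
    if (!length(hits)) return(list())
    # merge runs of overlapping outlier windows into distinct regions
    grp <- cumsum(c(1, diff(hits) > 20))
    centers <- vapply(split(hits, grp), function(ii) {
      i <- ii[which.max(w$fst[ii])]
      (w$start[i] + w$end[i]) / 2
    }, numeric(1))
    return(lapply(centers, function(cc) list(scan = w, center = cc)))
  }

  if (sc == "local") {
    p <- desk_params(Nm = Nm, mode = "local_antagonistic", s_local = s_a,
                     n_per_deme = n_per_deme, genome_length = genome_length,
                     rec = rec, sample_size = sample_size)
    s <- tryCatch(
      wf_run(p, stop_local_established(), seed = seed, burn_in_state = bs,
             cap = 200L * 2L * n_per_deme),
      error = function(e) NULL)
  } else {
    p <- desk_params(Nm = Nm, mode = "global", p_a = p_a, mean_s = s_a,
                     n_per_deme = n_per_deme, genome_length = genome_length,
                     rec = rec, sample_size = sample_size)
    stop_cond <- if (sc == "lag") stop_at_lag(0.5, 0.1)
                 else stop_at_fixation(0.99)
    s <- tryCatch(
      wf_run(p, stop_cond, seed = seed, burn_in_state = bs,
             cap = 500L * 2L * n_per_deme),
      error = function(e) NULL)
  }
  if (is.null(s) || is.na(s$trigger)) return(list())
  center <- s$selected$position[match(s$trigger, s$selected$mutation)]
  w <- window_scan(s, size = 1e4, step = 500)
  d <- abs((w$start + w$end) / 2 - center)
  near <- d <= 1e4 & !is.na(w$fst)
  if (!any(near) || max(w$fst[near]) <= thr) return(list())
  list(list(scan = w, center = center))
}
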