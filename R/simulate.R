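#' Stop conditions for the forward simulator
#'
#' Constructors for the conditions under which [wf_run()] stops the main
#' (selection) phase and draws its haplotype sample:
#' \itemize{
#'   \item `stop_after(generations)`: run exactly that many generations.
#'   \item `stop_at_lag(target, tol)`: stop the first generation a globally
#'     beneficial mutation's metapopulation frequency enters
#'     `[target - tol, target + tol]` (the mid-sweep "lag" protocol).
#'   \item `stop_at_fixation(freq)`: stop when a beneficial mutation exceeds
#'     frequency `freq` in the metapopulation and in both demes (the
#'     post-sweep "Bierne" protocol).
#'   \item `stop_local_established(duration)`: local-adaptation protocol; a
#'     spatially antagonistic allele is introduced (reintroduced on loss,
#'     which restarts the clock) and the run stops once it has segregated
#'     `duration` generations (default `5 * Ne` with `Ne = 2 * n_per_deme`
#'     metapopulation diploids).
#' }
#'
#' @param generations,target,tol,freq,duration See above.
#' @return A `wf_stop` condition object.
#' @name stop_conditions
NULL

#' @rdname stop_conditions
#' @export
stop_after <- function(generations) {
  stopifnot(generations >= 0)
  structure(list(type = "generations", T = as.integer(generations)),
            class = "wf_stop")
}

#' @rdname stop_conditions
#' @export
stop_at_lag <- function(target = 0.5, tol = 0.1) {
  stopifnot(target > 0, target < 1, tol > 0)
  structure(list(type = "lag", lag_target = target, lag_tol = tol),
            class = "wf_stop")
}

#' @rdname stop_conditions
#' @export
stop_at_fixation <- function(freq = 0.99) {
  stopifnot(freq > 0.5, freq <= 1)
  structure(list(type = "fixed", fixed_freq = freq), class = "wf_stop")
}

#' @rdname stop_conditions
#' @export
stop_local_established <- function(duration = NULL) {
  structure(list(type = "local", T = duration), class = "wf_stop")
}

par_for_cpp <- function(params) {
  list(
    n_per_deme = params$n_per_deme,
    genome_length = as.numeric(params$genome_length),
    Nm = params$Nm, mu = params$mu, rec = params$rec,
    p_a = params$dfe$p_a, mean_s = params$dfe$mean_s,
    s_local = params$s_local,
    mode = switch(params$mode, neutral = 0L, global = 1L,
                  local_antagonistic = 2L),
    gene_start = as.numeric(params$gene_regions[, 1]),
    gene_end = as.numeric(params$gene_regions[, 2])
  )
}

default_phase <- function() {
  list(type = "generations", T = 0L, cap = 0L, selection = FALSE,
       record = FALSE, lag_target = 0.5, lag_tol = 0.1, fixed_freq = 0.99,
       local_pos = 0)
}

run_phase <- function(state, params, phase, seed) {
  ph <- utils::modifyList(default_phase(), phase)
  ph$T <- as.integer(ph$T); ph$cap <- as.integer(ph$cap)
  res <- cpp_wf_run(state, par_for_cpp(params), ph, as.integer(seed))
  res$traj <- tibble::as_tibble(res$traj)
  res$subs <- tibble::as_tibble(res$subs)
  res$subs$kind <- kind_label(res$subs$kind)
  res
}

kind_label <- function(k) {
  c("neutral", "beneficial", "antagonistic")[k + 1L]
}

#' Neutral burn-in
#'
#' Runs `params$burn_in` generations of purely neutral evolution from an
#' initially monomorphic population, returning an opaque population state
#' that selection-phase runs can continue from. A single burn-in state may
#' be shared across replicates that then diverge under different seeds
#' (trajectories decorrelate over the main phase).
#'
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @return A list with `state` (opaque), `params`, `generation`.
#' @export
wf_burn_in <- function(params, seed) {
  stopifnot(inherits(params, "sim_params"))
  res <- run_phase(NULL, params,
                   list(type = "generations", T = params$burn_in,
                        cap = params$burn_in, selection = FALSE,
                        record = FALSE),
                   seed)
  list(state = res$state, params = params, generation = res$stop_gen)
}

#' Run the two-deme Wright-Fisher simulation and draw a haplotype sample
#'
#' Runs (optionally) a neutral burn-in, then the main phase under the
#' selection regime of `params$mode` until `stop` is satisfied, then samples
#' `params$sample_size` haplotypes per deme. Fully deterministic given
#' (`params`, `stop`, `seed`).
#'
#' @param params A [sim_params()].
#' @param stop A stop condition from [stop_conditions]; default
#'   `stop_after(0)` samples immediately after burn-in.
#' @param seed Integer seed.
#' @param burn_in_state Optional result of [wf_burn_in()] with identical
#'   demography, to skip the burn-in.
#' @param cap Generation cap for condition-triggered stops; exceeding it is
#'   an explicit timeout error. Default `2000 * n_per_deme`.
#' @param local_pos Introduction position of the antagonistic allele in
#'   local mode (default: midpoint of the central gene region).
#' @return A `hap_sample` object: list with `positions` (bp, sorted),
#'   `matrix` (haplotypes x sites, 0/1), `deme` (1/2 per row), `generation`,
#'   `params`, `selected` (tibble of selected mutations segregating or fixed
#'   during the run, with per-deme frequencies), `trajectories` (per
#'   generation per selected mutation), `substitutions`, `trigger`
#'   (mutation id that satisfied the stop condition, or `NA`), and `state`
#'   (for continuation).
#' @examples
#' p <- sim_params(20, 1, 5e4, mu = 1e-6, rec = 1e-6, mode = "neutral",
#'                 burn_in = 400, sample_size = 10)
#' s <- wf_run(p, seed = 1)
#' dim(s$matrix)
#' @export
wf_run <- function(params, stop = stop_after(0), seed = 1L,
                   burn_in_state = NULL, cap = NULL, local_pos = NULL) {
  stopifnot(inherits(params, "sim_params"), inherits(stop, "wf_stop"))
  if (is.null(cap)) cap <- 2000L * params$n_per_deme
  seed <- as.integer(seed)

  if (is.null(burn_in_state)) {
    burn_in_state <- wf_burn_in(params, derive_seed(seed, "burn_in", 0L))
  }
  state <- burn_in_state$state
  burn_gen <- burn_in_state$generation

  if (stop$type == "local" && params$mode != "local_antagonistic")
    stop("stop_local_established() requires mode = 'local_antagonistic'",
         call. = FALSE)
  if (is.null(local_pos)) {
    gr <- params$gene_regions
    if (nrow(gr) == 0) local_pos <- params$genome_length / 2
    else {
      mid <- (gr[, 1] + gr[, 2]) / 2
      local_pos <- mid[which.min(abs(mid - params$genome_length / 2))]
    }
  }
  phase <- list(type = stop$type,
                T = if (!is.null(stop$T)) stop$T
                    else if (stop$type == "local") 5L * 2L * params$n_per_deme
                    else 0L,
                cap = if (stop$type == "generations")
                        max(cap, stop$T %||% 0L) else cap,
                selection = params$mode == "global" && params$dfe$p_a > 0,
                record = TRUE,
                lag_target = stop$lag_target %||% 0.5,
                lag_tol = stop$lag_tol %||% 0.1,
                fixed_freq = stop$fixed_freq %||% 0.99,
                local_pos = local_pos)
  res <- run_phase(state, params, phase, derive_seed(seed, "main", 0L))
  if (res$status == 2L)
    stop("stop condition `", stop$type, "` not met within ", cap,
         " generations (timeout)", call. = FALSE)

  out <- wf_sample(res$state, params, derive_seed(seed, "sample", 0L))
  out$params <- params
  out$burn_in_generation <- burn_gen
  out$trajectories <- res$traj
  out$substitutions <- res$subs
  out$trigger <- res$trigger_uid
  out$seed <- seed
  # selected-mutation metadata: segregating now, plus fixed during main phase
  fixed_sel <- dplyr::filter(res$subs, .data$kind != "neutral")
  out$selected <- dplyr::bind_rows(
    dplyr::mutate(out$segregating_selected, fix_gen = NA_integer_),
    dplyr::mutate(fixed_sel, freq_deme1 = 1, freq_deme2 = 1)
  )
  out$segregating_selected <- NULL
  class(out) <- "hap_sample"
  out
}

wf_sample <- function(state, params, seed) {
  raw <- cpp_sample_haplotypes(state, par_for_cpp(params),
                               params$sample_size, as.integer(seed))
  sel <- tibble::as_tibble(raw$segregating_selected)
  sel$kind <- kind_label(sel$kind)
  list(positions = raw$positions, matrix = raw$matrix, deme = raw$deme,
       generation = raw$generation, segregating_selected = sel,
       state = state)
}

#' @export
print.hap_sample <- function(x, ...) {
  cat(sprintf(
    "Haplotype sample: %d haplotypes (%d per deme) x %d segregating sites\n",
    nrow(x$matrix), sum(x$deme == 1), ncol(x$matrix)))
  cat(sprintf("  generation %d; %d selected mutations tracked; trigger: %s\n",
              x$generation, nrow(x$selected),
              ifelse(is.na(x$trigger), "none", format(x$trigger))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
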