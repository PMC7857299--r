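#' Distribution of fitness effects for new functional-site mutations
#'
#' A fraction `p_a` of mutations arising in gene-like regions is beneficial;
#' their homozygous selection coefficients are drawn from an exponential
#' distribution with mean `mean_s`. All other mutations are neutral.
#' Dominance is semidominant throughout (`h = 0.5`), so a heterozygote
#' carries advantage `s/2`.
#'
#' @param p_a Proportion of new functional-site mutations that are
#'   beneficial, in `[0, 1]`.
#' @param mean_s Mean homozygous selection coefficient of beneficial
#'   mutations (>= 0).
#' @return An object of class `"dfe_config"` (a named list).
#' @examples
#' dfe_config(p_a = 1e-4, mean_s = 0.1)
#' @export
dfe_config <- function(p_a, mean_s) {
  if (!is.numeric(p_a) || length(p_a) != 1L || is.na(p_a) ||
      p_a < 0 || p_a > 1)
    stop("`p_a` must be a single number in [0, 1]", call. = FALSE)
  if (!is.numeric(mean_s) || length(mean_s) != 1L || is.na(mean_s) ||
      mean_s < 0)
    stop("`mean_s` must be a single number >= 0", call. = FALSE)
  structure(list(p_a = p_a, mean_s = mean_s), class = "dfe_config")
}

as_dfe_config <- function(x) {
  if (inherits(x, "dfe_config")) return(x)
  if (is.list(x) && all(c("p_a", "mean_s") %in% names(x)))
    return(dfe_config(x$p_a, x$mean_s))
  stop("cannot interpret `dfe` as a dfe_config", call. = FALSE)
}

#' @export
print.dfe_config <- function(x, ...) {
  cat(sprintf("DFE: beneficial fraction p_a = %g, Exp(mean s = %g), h = 0.5\n",
              x$p_a, x$mean_s))
  invisible(x)
}

#' Draw a selection coefficient from the DFE
#'
#' With probability `p_a` returns a beneficial homozygous coefficient
#' `s ~ Exponential(mean = mean_s)`; otherwise returns 0 (the neutral
#' marker). Vectorised over `n` draws.
#'
#' @param dfe A [dfe_config()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`; entries are 0 (neutral) or
#'   positive selection coefficients.
#' @examples
#' set.seed(1)
#' mean(sample_effect(dfe_config(1, 0.1), 1e4))  # ~0.1
#' @export
sample_effect <- function(dfe, n = 1L) {
  dfe <- as_dfe_config(dfe)
  s <- numeric(n)
  hit <- stats::runif(n) < dfe$p_a
  if (any(hit)) s[hit] <- stats::rexp(sum(hit), rate = 1 / dfe$mean_s)
  s
}

default_gene_regions <- function(genome_length, gene_length = 5000,
                                 spacing = 100000) {
  # gene-like regions of `gene_length` bp centered every `spacing` bp
  if (genome_length - 1 < spacing / 2)
    return(matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("start", "end"))))
  centers <- seq(spacing / 2, genome_length - 1, by = spacing)
  m <- cbind(start = centers - gene_length / 2,
             end = centers + gene_length / 2)
  m[m[, 1] >= 0 & m[, 2] <= genome_length, , drop = FALSE]
}

#' Simulation parameters for the two-deme Wright-Fisher model
#'
#' Full specification of one simulation replicate: two demes of
#' `n_per_deme` diploids exchanging migrants so that each deme receives an
#' expected `Nm` immigrants per generation (implemented as `Poisson(Nm)`
#' individual pair-swaps; this calibrates the mean neutral Weir-Cockerham
#' window F_ST to about `1/(1 + 8 Nm)`, i.e. 0.11 at `Nm = 1` and 0.012 at
#' `Nm = 10`), a linear chromosome of
#' `genome_length` bp with uniform per-bp mutation (`mu`) and recombination
#' (`rec`) rates, and gene-like regions (half-open, 0-based intervals) in
#' which new mutations can be beneficial according to `dfe`.
#'
#' `mode` selects the selection regime: `"global"` (beneficial mutations are
#' favored equally in both demes), `"local_antagonistic"` (a single allele
#' with homozygous advantage `s_local` in deme 1 and disadvantage `-s_local`
#' in deme 2 is introduced and maintained), or `"neutral"` (the beneficial
#' fraction is forced to 0).
#'
#' @param n_per_deme Diploid individuals per deme (>= 2).
#' @param Nm Expected migrants exchanged between the pair per generation.
#' @param genome_length Chromosome length in bp.
#' @param gene_regions Two-column matrix (`start`, `end`) of half-open
#'   functional intervals; defaults to 5 kb regions every 100 kb (5% of the
#'   genome functional).
#' @param mu Per-bp per-generation mutation rate.
#' @param rec Per-bp per-generation recombination rate.
#' @param dfe A [dfe_config()].
#' @param mode One of `"global"`, `"local_antagonistic"`, `"neutral"`.
#' @param s_local Homozygous advantage of the locally adapted allele in its
#'   favored deme (used only in local mode).
#' @param burn_in Generations of neutral burn-in before the selection phase;
#'   default `10 * 2 * (2 * n_per_deme)` i.e. ten times the haploid
#'   metapopulation size.
#' @param sample_size Haplotypes drawn per deme at sampling.
#' @return An object of class `"sim_params"`.
#' @examples
#' sim_params(n_per_deme = 100, Nm = 1, genome_length = 1e5,
#'            dfe = dfe_config(1e-4, 0.1))
#' @export
sim_params <- function(n_per_deme, Nm, genome_length,
                       gene_regions = default_gene_regions(genome_length),
                       mu = 2.5e-7, rec = 2.5e-7,
                       dfe = dfe_config(0, 0),
                       mode = c("global", "local_antagonistic", "neutral"),
                       s_local = 0, burn_in = NULL,
                       sample_size = 20L) {
  mode <- match.arg(mode)
  dfe <- as_dfe_config(dfe)
  if (n_per_deme < 2) stop("`n_per_deme` must be >= 2", call. = FALSE)
  if (Nm < 0) stop("`Nm` must be >= 0", call. = FALSE)
  if (mu < 0 || rec < 0) stop("`mu` and `rec` must be >= 0", call. = FALSE)
  if (genome_length <= 0) stop("`genome_length` must be > 0", call. = FALSE)
  gene_regions <- validate_gene_regions(gene_regions, genome_length)
  if (mode == "neutral") dfe <- dfe_config(0, dfe$mean_s)
  if (is.null(burn_in)) burn_in <- 10 * 2 * (2 * n_per_deme)
  structure(list(
    n_per_deme = as.integer(round(n_per_deme)), n_demes = 2L, Nm = Nm,
    genome_length = genome_length, gene_regions = gene_regions,
    mu = mu, rec = rec, dfe = dfe, mode = mode, s_local = s_local,
    burn_in = as.integer(burn_in), sample_size = as.integer(sample_size)
  ), class = "sim_params")
}

validate_gene_regions <- function(gr, genome_length) {
  if (is.null(gr) || (is.matrix(gr) && nrow(gr) == 0))
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("start", "end"))))
  gr <- as.matrix(gr)
  if (ncol(gr) != 2) stop("`gene_regions` needs columns start, end",
                          call. = FALSE)
  colnames(gr) <- c("start", "end")
  gr <- gr[order(gr[, 1]), , drop = FALSE]
  if (any(gr[, 1] < 0) || any(gr[, 2] > genome_length) ||
      any(gr[, 2] <= gr[, 1]))
    stop("gene regions must be non-empty half-open intervals within ",
         "[0, genome_length)", call. = FALSE)
  if (nrow(gr) > 1 && any(gr[-1, 1] < gr[-nrow(gr), 2]))
    stop("gene regions must be disjoint", call. = FALSE)
  gr
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "Two-deme Wright-Fisher parameters (%s mode)\n", x$mode))
  cat(sprintf("  N per deme %d, Nm = %g, genome %g bp (%d gene regions)\n",
              x$n_per_deme, x$Nm, x$genome_length, nrow(x$gene_regions)))
  cat(sprintf("  mu = %g, rec = %g per bp; burn-in %d generations\n",
              x$mu, x$rec, x$burn_in))
  print(x$dfe)
  if (x$mode == "local_antagonistic")
    cat(sprintf("  local allele: s = +/-%g (favored in deme 1)\n", x$s_local))
  invisible(x)
}

#' Rescale simulation parameters to a smaller (or larger) population
#'
#' Applies the standard population-genetic rescaling by a factor `lambda`:
#' `N -> round(lambda * N)`, `s -> s / lambda` (both the DFE mean and
#' `s_local`), `mu -> mu / lambda`, `rec -> rec / lambda`, with the
#' migration rate chosen so `Nm` is unchanged; the genome layout is
#' untouched and `burn_in` is rescaled to keep `burn_in / (2N)` fixed.
#' This preserves `2Ns`, `Nm` and per-window `4Nmu` / `4Nrec`, so diversity,
#' differentiation and sweep dynamics match in rescaled time units.
#'
#' @param params A [sim_params()].
#' @param lambda Scaling factor (> 0); `lambda < 1` shrinks the population.
#' @return A rescaled `sim_params` object.
#' @examples
#' p <- sim_params(5000, 1, 1e6, dfe = dfe_config(1e-4, 0.02))
#' rescale_params(p, 0.04)   # N = 200 per deme, mean s = 0.5
#' @export
rescale_params <- function(params, lambda) {
  stopifnot(inherits(params, "sim_params"), lambda > 0)
  n_new <- round(lambda * params$n_per_deme)
  if (n_new < 2) stop("rescaled `n_per_deme` < 2", call. = FALSE)
  sim_params(
    n_per_deme = n_new, Nm = params$Nm,
    genome_length = params$genome_length, gene_regions = params$gene_regions,
    mu = params$mu / lambda, rec = params$rec / lambda,
    dfe = dfe_config(params$dfe$p_a, params$dfe$mean_s / lambda),
    mode = params$mode, s_local = params$s_local / lambda,
    burn_in = max(1L, round(params$burn_in * lambda)),
    sample_size = params$sample_size
  )
}
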