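#' Weir-Cockerham F_ST for haplotype data, combined across sites
#'
#' Computes Weir and Cockerham's theta for two demes from per-site allele
#' frequencies, using the haploid (haplotype-count) variance components
#' \deqn{MSA = \sum_i n_i (p_i - \bar p_w)^2 / (r - 1)}
#' \deqn{MSW = \sum_i n_i p_i (1 - p_i) / \sum_i (n_i - 1)}
#' \deqn{n_c = (\sum n_i - \sum n_i^2 / \sum n_i) / (r - 1)}
#' with `r = 2` demes, combined across sites as a ratio of sums:
#' \deqn{\theta = \frac{\sum_s (MSA_s - MSW_s)}
#'                     {\sum_s (MSA_s + (n_c - 1) MSW_s)}}
#' The estimator may be negative; with no polymorphic site it is undefined
#' and `NA` is returned (never silently 0).
#'
#' @param p1,p2 Allele frequencies per site in deme 1 and deme 2 (vectors of
#'   equal length).
#' @param n1,n2 Haplotype sample sizes (scalars or per-site vectors, >= 2).
#' @return Single numeric theta (<= 1), or `NA` if undefined.
#' @examples
#' wc_fst(1, 0, 10, 10)        # 1: fixed difference
#' wc_fst(0.5, 0.5, 10, 10)    # -1/9
#' @export
wc_fst <- function(p1, p2, n1, n2) {
  stopifnot(length(p1) == length(p2))
  if (length(p1) == 0) return(NA_real_)
  comp <- wc_components(p1, p2, n1, n2)
  den <- sum(comp$den)
  if (!is.finite(den) || den <= 0) return(NA_real_)
  sum(comp$num) / den
}

# per-site numerator/denominator of Weir-Cockerham theta (haploid form)
wc_components <- function(p1, p2, n1, n2) {
  n <- n1 + n2
  pbar <- (n1 * p1 + n2 * p2) / n
  msa <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2          # r - 1 = 1
  msw <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n - 2)
  nc <- (n - (n1^2 + n2^2) / n)                            # / (r - 1)
  list(num = msa - msw, den = msa + (nc - 1) * msw)
}

#' Within-deme nucleotide diversity (pi_W)
#'
#' Mean number of pairwise differences per site among the haplotypes of one
#' deme, normalised by the full window length `L` (monomorphic sites
#' included). Equivalent to \eqn{\sum_s 2 p_s (1 - p_s) n / (n - 1) / L}.
#'
#' @param mat 0/1 haplotype matrix (rows = haplotypes) of one deme, or a
#'   vector of per-site derived-allele frequencies (then give `n`).
#' @param L Window length in bp.
#' @param n Haplotype count (required when `mat` is a frequency vector).
#' @return Per-site diversity (numeric scalar, >= 0).
#' @examples
#' pi_within(rbind(c(0, 1), c(0, 0)), L = 1e4)  # one diff in one pair
#' @export
pi_within <- function(mat, L, n = NULL) {
  if (is.matrix(mat)) {
    n <- nrow(mat)
    p <- colMeans(mat)
  } else p <- mat
  if (is.null(n) || n < 2)
    stop("pi_within needs >= 2 haplotypes", call. = FALSE)
  sum(2 * p * (1 - p)) * n / (n - 1) / L
}

#' Between-deme nucleotide diversity (d_XY)
#'
#' Mean number of pairwise differences per site between haplotypes drawn
#' from different demes, normalised by window length `L`:
#' \eqn{\sum_s [p_{1s}(1 - p_{2s}) + p_{2s}(1 - p_{1s})] / L}.
#'
#' @param mat1,mat2 0/1 haplotype matrices (or per-site frequency vectors)
#'   for demes 1 and 2.
#' @param L Window length in bp.
#' @return Per-site divergence (numeric scalar, >= 0).
#' @examples
#' d_xy(rbind(c(1, 0)), rbind(c(0, 0)), L = 1e4)
#' @export
d_xy <- function(mat1, mat2, L) {
  p1 <- if (is.matrix(mat1)) colMeans(mat1) else mat1
  p2 <- if (is.matrix(mat2)) colMeans(mat2) else mat2
  if (length(p1) != length(p2))
    stop("demes must be scored at the same sites", call. = FALSE)
  if ((is.matrix(mat1) && nrow(mat1) == 0) ||
      (is.matrix(mat2) && nrow(mat2) == 0))
    stop("d_xy needs >= 1 haplotype per deme", call. = FALSE)
  sum(p1 * (1 - p2) + p2 * (1 - p1)) / L
}

#' Windowed genome scan of F_ST, pi_W and d_XY
#'
#' Computes the three summary statistics in windows over a haplotype
#' sample: either sliding windows (`size` bp advancing by `step` bp, fully
#' inside the genome) or one window per gene-like region, centered on the
#' region midpoint. Windows are 0-based half-open intervals. Windows
#' without SNPs report `fst = NA` and zero diversity.
#'
#' @param sample A `hap_sample` from [wf_run()], or a list with elements
#'   `positions`, `matrix`, `deme` (1/2), and (for gene-centered mode
#'   without `gene_regions`) `params`.
#' @param size Window size in bp (default 10,000).
#' @param step Step size in bp for sliding windows (default 500).
#' @param centering `"sliding"` or `"gene_centered"`.
#' @param genome_length Genome length (defaults to `sample$params`).
#' @param gene_regions Two-column matrix for gene-centered mode (defaults
#'   to `sample$params$gene_regions`).
#' @return A tibble with columns `start`, `end`, `n_snps`, `fst`,
#'   `pi_w_deme1`, `pi_w_deme2`, `pi_w_mean`, `d_xy`; class `window_scan`
#'   so `autoplot()` works.
#' @examples
#' p <- sim_params(20, 1, 5e4, mu = 2e-6, rec = 2e-6, mode = "neutral",
#'                 burn_in = 400, sample_size = 10)
#' window_scan(wf_run(p, seed = 1), size = 10000, step = 10000)
#' @export
window_scan <- function(sample, size = 10000, step = 500,
                        centering = c("sliding", "gene_centered"),
                        genome_length = NULL, gene_regions = NULL) {
  centering <- match.arg(centering)
  if (size <= 0 || step <= 0)
    stop("`size` and `step` must be > 0", call. = FALSE)
  genome_length <- genome_length %||% sample$params$genome_length
  if (is.null(genome_length))
    stop("supply `genome_length` for samples without params", call. = FALSE)

  if (centering == "sliding") {
    if (genome_length < size)
      stop("genome shorter than window size", call. = FALSE)
    starts <- seq(0, genome_length - size, by = step)
    ends <- starts + size
  } else {
    gene_regions <- gene_regions %||% sample$params$gene_regions
    if (is.null(gene_regions) || nrow(gene_regions) == 0)
      stop("gene-centered scan needs gene regions", call. = FALSE)
    mid <- (gene_regions[, 1] + gene_regions[, 2]) / 2
    starts <- mid - size / 2
    ends <- mid + size / 2
  }

  pos <- sample$positions
  ord <- order(pos)
  pos <- pos[ord]
  m <- sample$matrix[, ord, drop = FALSE]
  d1 <- sample$deme == 1
  n1 <- sum(d1); n2 <- sum(!d1)
  if (n1 < 2 || n2 < 2)
    stop("need >= 2 haplotypes per deme", call. = FALSE)

  if (length(pos)) {
    p1 <- colMeans(m[d1, , drop = FALSE])
    p2 <- colMeans(m[!d1, , drop = FALSE])
    comp <- wc_components(p1, p2, n1, n2)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    site <- cbind(
      snp = as.numeric(pbar > 0 & pbar < 1),
      num = comp$num, den = comp$den,
      pi1 = 2 * p1 * (1 - p1) * n1 / (n1 - 1),
      pi2 = 2 * p2 * (1 - p2) * n2 / (n2 - 1),
      dxy = p1 * (1 - p2) + p2 * (1 - p1))
    cs <- rbind(0, apply(site, 2, cumsum))
    lo <- findInterval(starts - 1e-9, pos)
    hi <- findInterval(ends - 1e-9, pos)
    win <- cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]
  } else {
    win <- matrix(0, length(starts), 6,
                  dimnames = list(NULL, c("snp", "num", "den",
                                          "pi1", "pi2", "dxy")))
  }

  fst <- ifelse(win[, "den"] > 0, win[, "num"] / win[, "den"], NA_real_)
  fst[win[, "snp"] == 0] <- NA_real_
  out <- tibble::tibble(
    start = starts, end = ends,
    n_snps = as.integer(win[, "snp"]),
    fst = fst,
    pi_w_deme1 = win[, "pi1"] / size,
    pi_w_deme2 = win[, "pi2"] / size,
    pi_w_mean = (win[, "pi1"] + win[, "pi2"]) / 2 / size,
    d_xy = win[, "dxy"] / size)
  class(out) <- c("window_scan", class(out))
  out
}
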