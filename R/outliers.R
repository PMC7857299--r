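#' Build the neutral null distribution of window F_ST
#'
#' Pools window F_ST values from neutral simulations and computes empirical
#' percentile thresholds. Quantiles use R's type-7 (inclusive linear
#' interpolation on the sorted values), fixed so thresholds are
#' bit-reproducible. A percentile `q` requires at least `10 / (1 - q/100)`
#' windows with defined F_ST.
#'
#' @param windows A window table (tibble with an `fst` column), a list of
#'   such tables, or a bare numeric vector of F_ST values. Windows with
#'   undefined (`NA`) F_ST are excluded.
#' @param percentiles Percentiles (in percent) at which to compute
#'   thresholds; default `c(99.9, 99.99, 99.999)`.
#' @return A `null_distribution` object: list with sorted `values`, `n`, and
#'   a tibble `thresholds` (`percentile`, `threshold`).
#' @examples
#' build_null(runif(20000), percentiles = 99.9)
#' @export
build_null <- function(windows, percentiles = c(99.9, 99.99, 99.999)) {
  if (is.list(windows) && !is.data.frame(windows))
    windows <- dplyr::bind_rows(windows)
  values <- if (is.numeric(windows)) windows else windows$fst
  values <- sort(values[is.finite(values)])
  n <- length(values)
  stopifnot(all(percentiles > 0), all(percentiles < 100))
  need <- 10 / (1 - percentiles / 100)
  if (any(n < need))
    stop(sprintf(
      "null too small: %d F_ST windows, need >= %.0f for the %.5gth percentile",
      n, max(need), percentiles[which.max(need)]), call. = FALSE)
  thr <- stats::quantile(values, percentiles / 100, type = 7, names = FALSE)
  structure(list(
    values = values, n = n,
    thresholds = tibble::tibble(percentile = percentiles, threshold = thr)
  ), class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Neutral F_ST null: %d windows\n", x$n))
  print(x$thresholds)
  invisible(x)
}

#' @export
tidy.null_distribution <- function(x, ...) x$thresholds

#' @export
glance.null_distribution <- function(x, ...) {
  tibble::tibble(n = x$n, min = x$values[1], max = x$values[x$n],
                 mean = mean(x$values))
}

null_threshold <- function(null, percentile) {
  stopifnot(inherits(null, "null_distribution"))
  i <- match(percentile, null$thresholds$percentile)
  if (is.na(i))
    stop("percentile ", percentile, " not present in the null (available: ",
         paste(null$thresholds$percentile, collapse = ", "), ")",
         call. = FALSE)
  null$thresholds$threshold[i]
}

#' Call F_ST outlier windows against a neutral null
#'
#' Flags windows whose F_ST is strictly above the empirical null threshold
#' at the given percentile. Windows with undefined F_ST are never called
#' (and are excluded from the denominator when rates are computed).
#'
#' @param windows A window table (from [window_scan()], typically
#'   gene-centered, optionally with extra grouping columns such as
#'   `dataset`).
#' @param null A [build_null()] result.
#' @param percentile Percentile (must be one the null was built with).
#' @return The outlier rows of `windows` plus columns `threshold`,
#'   `percentile`, `class` (`"unclassified"` until [classify_outliers()]),
#'   `distance_to_selected` and `nearest_mutation` (`NA` until classified).
#' @export
call_outliers <- function(windows, null, percentile = 99.99) {
  thr <- null_threshold(null, percentile)
  out <- dplyr::filter(windows, !is.na(.data$fst), .data$fst > thr)
  dplyr::mutate(out, threshold = thr, percentile = percentile,
                class = "unclassified",
                distance_to_selected = NA_real_,
                nearest_mutation = NA_real_)
}

#' Classify outlier calls as lag, Bierne or drift
#'
#' Uses simulation metadata to attribute each outlier window to a process:
#' \itemize{
#'   \item `lag`: a segregating globally beneficial mutation at
#'     metapopulation frequency in `(0.05, 0.95)` lies within `radius` of
#'     the window center at sampling;
#'   \item `bierne`: otherwise, a beneficial mutation that fixed within the
#'     last `horizon` generations lies within `radius`;
#'   \item `drift`: the simulation was neutral;
#'   \item `unclassified`: none of the above (or no metadata, e.g. field
#'     data).
#' }
#'
#' @param calls Output of [call_outliers()].
#' @param sample The `hap_sample` the windows came from (supplies selected
#'   mutations, sampling generation and mode); `NULL` leaves calls
#'   unclassified.
#' @param radius Classification radius in bp from the window center
#'   (default one window size, 10 kb).
#' @param horizon Look-back horizon in generations for Bierne-type fixation
#'   (default `0.5 * Ne` with `Ne = 2 * n_per_deme` metapopulation
#'   diploids).
#' @return `calls` with `class`, `distance_to_selected` and
#'   `nearest_mutation` filled in.
#' @export
classify_outliers <- function(calls, sample, radius = 10000, horizon = NULL) {
  if (nrow(calls) == 0) return(calls)
  if (is.null(sample)) return(calls)
  mode <- sample$params$mode
  if (is.null(horizon)) horizon <- 0.5 * 2 * sample$params$n_per_deme
  sel <- sample$selected
  gen <- sample$generation
  centers <- (calls$start + calls$end) / 2

  if (!is.null(sel) && nrow(sel) > 0) {
    d <- abs(outer(centers, sel$position, "-"))
    nearest <- apply(d, 1, which.min)
    calls$distance_to_selected <- d[cbind(seq_along(centers), nearest)]
    calls$nearest_mutation <- sel$mutation[nearest]
  }

  cls <- function(center) {
    if (!is.null(sel) && nrow(sel) > 0) {
      dd <- abs(sel$position - center)
      fmeta <- (sel$freq_deme1 + sel$freq_deme2) / 2
      seg_lag <- sel$kind == "beneficial" & is.na(sel$fix_gen) &
        fmeta > 0.05 & fmeta < 0.95 & dd <= radius
      if (any(seg_lag)) return("lag")
      fixed_recent <- sel$kind == "beneficial" & !is.na(sel$fix_gen) &
        (gen - sel$fix_gen) <= horizon & dd <= radius
      if (any(fixed_recent)) return("bierne")
    }
    if (mode == "neutral") return("drift")
    "unclassified"
  }
  calls$class <- vapply(centers, cls, character(1))
  calls
}

#' Outlier rate per 10,000 windows with dataset bootstrap
#'
#' Point estimate `1e4 * n_outliers / n_windows` over the pooled windows,
#' with a bootstrap that resamples whole simulated datasets (replicates)
#' with replacement, mirroring how replicate simulations are the unit of
#' sampling error. Windows with undefined F_ST do not count toward the
#' denominator.
#'
#' @param calls Outlier calls (must carry a `dataset` column if `windows`
#'   does).
#' @param windows The pooled tested window table (with `dataset` column for
#'   the bootstrap; without one, the bootstrap resamples windows).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return An `outlier_rate` object: list with `rate`, `n_outliers`,
#'   `n_windows`, `boot` (bootstrap rates) and `ci` (2.5/97.5 percentiles).
#' @export
outlier_rate <- function(calls, windows, n_boot = 1000, seed = 1L) {
  tested <- dplyr::filter(windows, !is.na(.data$fst))
  n_windows <- nrow(tested)
  if (n_windows == 0) stop("no tested windows", call. = FALSE)
  n_out <- nrow(calls)
  rate <- 1e4 * n_out / n_windows

  if (!"dataset" %in% names(tested)) {
    # no replicate structure: fall back to resampling windows
    tested$dataset <- seq_len(n_windows)
    if (n_out > 0)
      calls$dataset <- match(paste(calls$start, calls$end),
                             paste(tested$start, tested$end))
  }
  ds <- unique(tested$dataset)
  out_by <- if (n_out > 0)
    as.numeric(table(factor(calls$dataset, levels = ds)))
  else rep(0, length(ds))
  win_by <- as.numeric(table(factor(tested$dataset, levels = ds)))

  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  boot <- withr_seed({
    k <- length(ds)
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(k, k, replace = TRUE)
      1e4 * sum(out_by[idx]) / sum(win_by[idx])
    }, numeric(1))
  })
  structure(list(rate = rate, n_outliers = n_out, n_windows = n_windows,
                 boot = boot,
                 ci = stats::quantile(boot, c(0.025, 0.975), names = FALSE)),
            class = "outlier_rate")
}

#' @export
print.outlier_rate <- function(x, ...) {
  cat(sprintf(
    "Outlier rate: %.3g per 10,000 windows (%d / %d; bootstrap CI %.3g-%.3g)\n",
    x$rate, x$n_outliers, x$n_windows, x$ci[1], x$ci[2]))
  invisible(x)
}

#' @export
tidy.outlier_rate <- function(x, ...) {
  tibble::tibble(rate = x$rate, n_outliers = x$n_outliers,
                 n_windows = x$n_windows,
                 ci_lo = x$ci[1], ci_hi = x$ci[2])
}

#' Aggregate F_ST / pi_W / d_XY profiles around outliers
#'
#' Bins sliding-window statistics by distance from each outlier's center
#' (the causal selected site for selection scenarios, the outlier window
#' center for drift) and returns per-bin means with a bootstrap band taken
#' over outliers.
#'
#' @param scans List of sliding [window_scan()] tables, one per outlier.
#' @param centers Numeric vector (same length) of center positions in bp.
#' @param scenario Scenario label stored in the output (e.g. `"lag"`).
#' @param flank Flank width in bp on each side of the center (default 100
#'   kb); bins extending beyond a scan are simply missing for that outlier
#'   and are flagged by their lower `n`.
#' @param bin Bin width in bp (default 10 kb).
#' @param n_boot Bootstrap resamples over outliers (default 200).
#' @param seed Integer seed.
#' @return A `profile_aggregate` tibble: `scenario`, `stat`, `bin_mid`,
#'   `mean`, `lo`, `hi`, `n`.
#' @export
aggregate_profiles <- function(scans, centers, scenario, flank = 1e5,
                               bin = 1e4, n_boot = 200, seed = 1L) {
  stopifnot(length(scans) == length(centers), length(scans) >= 1)
  breaks <- seq(-flank, flank, by = bin)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  long <- purrr::imap_dfr(scans, function(w, i) {
    d <- (w$start + w$end) / 2 - centers[[i]]
    keep <- d >= -flank & d < flank
    w <- w[keep, ]
    tibble::tibble(outlier = i,
                   bin_mid = mids[findInterval(d[keep], breaks,
                                               rightmost.closed = TRUE)],
                   fst = w$fst, pi_w = w$pi_w_mean, d_xy = w$d_xy)
  })
  long <- tidyr::pivot_longer(long, c("fst", "pi_w", "d_xy"),
                              names_to = "stat", values_to = "value")
  # per-outlier per-bin mean first, so each outlier contributes once per bin
  per <- dplyr::summarise(
    dplyr::group_by(long, .data$outlier, .data$stat, .data$bin_mid),
    value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  # matrix outliers x (stat, bin) so bootstrap rows align across resamples
  wide <- tidyr::pivot_wider(per, names_from = c("stat", "bin_mid"),
                             values_from = "value", names_sep = "@")
  M <- as.matrix(wide[, -1, drop = FALSE])
  set.seed(seed)
  boots <- replicate(n_boot, {
    colMeans(M[sample(nrow(M), nrow(M), replace = TRUE), , drop = FALSE],
             na.rm = TRUE)
  })
  key <- do.call(rbind, strsplit(colnames(M), "@", fixed = TRUE))
  qs <- apply(boots, 1, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  agg <- tibble::tibble(
    stat = key[, 1], bin_mid = as.numeric(key[, 2]),
    mean = colMeans(M, na.rm = TRUE),
    n = colSums(!is.na(M)),
    lo = qs[1, ], hi = qs[2, ])
  agg <- dplyr::arrange(agg, .data$stat, .data$bin_mid)
  out <- dplyr::mutate(agg, scenario = scenario, .before = 1)
  # per-outlier central vs flank means, for sign tests across outliers
  per_outlier <- dplyr::summarise(
    dplyr::group_by(long, .data$outlier, .data$stat),
    central = mean(.data$value[abs(.data$bin_mid) <= bin], na.rm = TRUE),
    flank = mean(.data$value[abs(.data$bin_mid) >= flank / 2], na.rm = TRUE),
    .groups = "drop")
  per_outlier$scenario <- scenario
  attr(out, "per_outlier") <- per_outlier
  class(out) <- c("profile_aggregate", class(out))
  out
}
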