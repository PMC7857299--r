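open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
}
open_in <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
}
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Read and write window tables as BED-like TSV
#'
#' Tab-delimited, dot-decimal, full-precision text with columns `chrom`,
#' `start`, `end`, `n_snps`, `fst`, `pi_w_mean`, `pi_w_deme1`,
#' `pi_w_deme2`, `d_xy` (plus any extra columns such as `dataset`).
#' Intervals are 0-based half-open. Round trips are lossless for all
#' numeric fields.
#'
#' @param windows A window table from [window_scan()].
#' @param path Output path (`.gz` for gzip).
#' @param chrom Chromosome label written in the first column.
#' @return `write_window_tsv` returns `path` invisibly; `read_window_tsv`
#'   returns a `window_scan` tibble.
#' @export
write_window_tsv <- function(windows, path, chrom = "1") {
  df <- dplyr::mutate(tibble::as_tibble(windows), chrom = chrom, .before = 1)
  con <- open_out(path)
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- lapply(df, function(x) if (is.double(x)) fmt_num(x)
                   else as.character(x))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' @rdname write_window_tsv
#' @export
read_window_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = NA, check.names = FALSE)
  df <- tibble::as_tibble(df)
  if (!all(c("start", "end", "fst") %in% names(df)))
    stop("malformed window table: ", path, call. = FALSE)
  if (any(df$end <= df$start))
    stop("coordinate violation (end <= start) at row ",
         which(df$end <= df$start)[1], " of ", path, call. = FALSE)
  if ("n_snps" %in% names(df)) df$n_snps <- as.integer(df$n_snps)
  class(df) <- c("window_scan", class(df))
  df
}

#' Read and write selected-mutation trajectories as TSV
#'
#' Columns `generation`, `mutation`, `freq_deme1`, `freq_deme2`, one row
#' per generation per tracked mutation.
#'
#' @param traj Trajectory tibble (from `wf_run()$trajectories`).
#' @param path File path (`.gz` for gzip).
#' @export
write_trajectory_tsv <- function(traj, path) {
  df <- traj[, c("generation", "mutation", "freq_deme1", "freq_deme2")]
  con <- open_out(path)
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    writeLines(paste(df$generation, fmt_num(df$mutation),
                     fmt_num(df$freq_deme1), fmt_num(df$freq_deme2),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_trajectory_tsv
#' @export
read_trajectory_tsv <- function(path) {
  df <- tibble::as_tibble(utils::read.delim(path, sep = "\t"))
  if (!all(c("generation", "mutation", "freq_deme1", "freq_deme2")
           %in% names(df)))
    stop("malformed trajectory table: ", path, call. = FALSE)
  if (any(df$freq_deme1 < 0 | df$freq_deme1 > 1 |
          df$freq_deme2 < 0 | df$freq_deme2 > 1))
    stop("frequency outside [0,1] in ", path, call. = FALSE)
  df
}

#' Export and import haplotype samples
#'
#' Three plain-text formats:
#' \itemize{
#'   \item `"ms"`: an ms-style block (`segsites:`, `positions:`, one 0/1
#'     string per haplotype) with an `ms`-like command line recording the
#'     two-deme sample configuration (`-I 2 n1 n2`) and genome length.
#'     Positions are written in bp at full precision (not rescaled to
#'     `[0,1]`), so round trips are exact.
#'   \item `"vcf"`: VCF 4.2 with haploid genotypes, one sample column per
#'     haplotype (named `deme<d>_hap<i>`); integer `POS` is
#'     `floor(bp) + 1` and the exact bp position is kept in `INFO/BP`.
#'   \item `"tsv"`: a site table (`position`, then one 0/1 column per
#'     haplotype).
#' }
#'
#' @param sample A `hap_sample` (or a list with `positions`, `matrix`,
#'   `deme`, `generation`).
#' @param path Output path (`.gz` supported).
#' @param format `"ms"`, `"vcf"` or `"tsv"`.
#' @return `export_sample` returns `path` invisibly. `read_sample_ms` /
#'   `read_sample_vcf` return a list with `positions`, `matrix`, `deme`,
#'   `genome_length`.
#' @export
export_sample <- function(sample, path, format = c("ms", "vcf", "tsv")) {
  format <- match.arg(format)
  switch(format,
         ms = write_sample_ms(sample, path),
         vcf = write_sample_vcf(sample, path),
         tsv = write_sample_tsv(sample, path))
}

write_sample_ms <- function(sample, path) {
  m <- sample$matrix
  n1 <- sum(sample$deme == 1); n2 <- sum(sample$deme == 2)
  L <- sample$params$genome_length %||% NA
  con <- open_out(path)
  on.exit(close(con))
  writeLines(c(
    sprintf("ms %d 1 -I 2 %d %d -L %s", n1 + n2, n1, n2, fmt_num(L)),
    sprintf("%d", sample$generation %||% 0L),
    "", "//",
    sprintf("segsites: %d", ncol(m))), con)
  if (ncol(m) > 0) {
    writeLines(paste("positions:",
                     paste(fmt_num(sample$positions), collapse = " ")), con)
    writeLines(apply(m, 1, paste, collapse = ""), con)
  }
  invisible(path)
}

#' @rdname export_sample
#' @export
read_sample_ms <- function(path) {
  con <- open_in(path)
  on.exit(close(con))
  lines <- readLines(con)
  hdr <- strsplit(lines[1], "\\s+")[[1]]
  iI <- match("-I", hdr)
  n1 <- as.integer(hdr[iI + 2]); n2 <- as.integer(hdr[iI + 3])
  iL <- match("-L", hdr)
  L <- if (is.na(iL)) NA_real_ else as.numeric(hdr[iL + 1])
  iseg <- grep("^segsites:", lines)[1]
  S <- as.integer(sub("^segsites:\\s*", "", lines[iseg]))
  if (S == 0) {
    return(list(positions = numeric(0),
                matrix = matrix(0L, n1 + n2, 0), deme = rep(1:2, c(n1, n2)),
                genome_length = L))
  }
  pos <- as.numeric(strsplit(sub("^positions:\\s*", "", lines[iseg + 1]),
                             "\\s+")[[1]])
  rows <- lines[(iseg + 2):(iseg + 1 + n1 + n2)]
  m <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
  list(positions = pos, matrix = m, deme = rep(1:2, c(n1, n2)),
       genome_length = L)
}

write_sample_vcf <- function(sample, path) {
  m <- sample$matrix
  deme <- sample$deme
  idx <- stats::ave(seq_along(deme), deme, FUN = seq_along)
  snames <- sprintf("deme%d_hap%d", deme, idx)
  con <- open_out(path)
  on.exit(close(con))
  L <- sample$params$genome_length %||% max(sample$positions, 1)
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=1,length=%d>", ceiling(L)),
    "##INFO=<ID=BP,Number=1,Type=Float,Description=\"Exact position in bp\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", snames), collapse = "\t")), con)
  if (ncol(m) > 0) {
    gt <- apply(m, 2, function(col) paste(col, collapse = "\t"))
    writeLines(sprintf("1\t%d\tsite%d\tA\tT\t.\tPASS\tBP=%s\tGT\t%s",
                       floor(sample$positions) + 1L, seq_len(ncol(m)),
                       fmt_num(sample$positions), gt), con)
  }
  invisible(path)
}

#' @rdname export_sample
#' @export
read_sample_vcf <- function(path) {
  con <- open_in(path)
  on.exit(close(con))
  lines <- readLines(con)
  hdr <- lines[grepl("^#CHROM", lines)]
  cols <- strsplit(hdr, "\t")[[1]]
  snames <- cols[-(1:9)]
  deme <- as.integer(sub("^deme(\\d+)_hap\\d+$", "\\1", snames))
  body <- lines[!grepl("^#", lines)]
  clen <- sub(".*length=(\\d+).*", "\\1", lines[grepl("^##contig", lines)][1])
  if (length(body) == 0) {
    return(list(positions = numeric(0),
                matrix = matrix(0L, length(snames), 0), deme = deme,
                genome_length = as.numeric(clen)))
  }
  parts <- strsplit(body, "\t")
  pos <- vapply(parts, function(p) as.numeric(sub("^BP=", "", p[8])),
                numeric(1))
  m <- vapply(parts, function(p) as.integer(p[-(1:9)]),
              integer(length(snames)))
  dim(m) <- c(length(snames), length(parts))
  list(positions = pos, matrix = m, deme = deme,
       genome_length = as.numeric(clen))
}

write_sample_tsv <- function(sample, path) {
  m <- sample$matrix
  df <- tibble::as_tibble(t(m), .name_repair = "minimal")
  idx <- stats::ave(seq_along(sample$deme), sample$deme, FUN = seq_along)
  names(df) <- sprintf("deme%d_hap%d", sample$deme, idx)
  con <- open_out(path)
  on.exit(close(con))
  writeLines(paste(c("position", names(df)), collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(list(fmt_num(sample$positions)),
                                as.list(df), list(sep = "\t"))), con)
  invisible(path)
}

#' Run manifest: reproducible record of a simulation run
#'
#' Captures everything needed to re-execute a run bit-for-bit: the full
#' parameter set, the master seed, the stop condition, the package version,
#' a timestamp and (optionally) md5 checksums of written artifacts.
#' [rerun_manifest()] re-executes the run from the manifest and returns the
#' resulting sample, which is identical to the original.
#'
#' @param params A [sim_params()].
#' @param seed Master seed used.
#' @param stop The stop condition used.
#' @param files Optional character vector of artifact paths to checksum.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(params, seed, stop = stop_after(0), files = NULL) {
  man <- list(
    package = "sweepscan",
    version = as.character(utils::packageVersion("sweepscan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    stop = unclass(stop),
    params = params_to_list(params),
    checksums = if (!is.null(files))
      as.list(tools::md5sum(files)) else NULL)
  class(man) <- "run_manifest"
  man
}

params_to_list <- function(params) {
  p <- unclass(params)
  p$gene_regions <- list(start = as.numeric(p$gene_regions[, 1]),
                         end = as.numeric(p$gene_regions[, 2]))
  p$dfe <- unclass(p$dfe)
  p
}

params_from_list <- function(p) {
  sim_params(
    n_per_deme = p$n_per_deme, Nm = p$Nm,
    genome_length = p$genome_length,
    gene_regions = cbind(start = unlist(p$gene_regions$start),
                         end = unlist(p$gene_regions$end)),
    mu = p$mu, rec = p$rec,
    dfe = dfe_config(p$dfe$p_a, p$dfe$mean_s),
    mode = p$mode, s_local = p$s_local, burn_in = p$burn_in,
    sample_size = p$sample_size)
}

#' @rdname run_manifest
#' @param path JSON path.
#' @export
write_manifest <- function(man, path) {
  jsonlite::write_json(unclass(man), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname run_manifest
#' @export
read_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(man) <- "run_manifest"
  man
}

#' @rdname run_manifest
#' @param man A `run_manifest`.
#' @export
rerun_manifest <- function(man) {
  params <- params_from_list(man$params)
  stop_cond <- structure(man$stop, class = "wf_stop")
  stop_cond$T <- if (!is.null(stop_cond$T)) as.integer(stop_cond$T)
  wf_run(params, stop_cond, seed = man$seed)
}
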