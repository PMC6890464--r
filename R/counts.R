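#' Count fragments per region by midpoint membership
#'
#' Assigns each paired-end fragment to the unique region containing its
#' midpoint `floor((start + end) / 2)` (0-based), so adjacent merged peaks
#' never double-count a fragment. Fragments whose midpoint falls in no
#' region are ignored. With `mode = "any"` a fragment is instead counted
#' for every region it overlaps.
#'
#' @param fragments an [interval_set] of fragment intervals.
#' @param regions an [interval_set] of non-overlapping (pre-merged)
#'   regions.
#' @param mode `"midpoint"` (default) or `"any"`.
#' @return Named integer vector of counts, one per region id, in region
#'   order.
#' @export
count_fragments <- function(fragments, regions, mode = c("midpoint", "any")) {
  mode <- match.arg(mode)
  stopifnot_interval_set(fragments)
  stopifnot_interval_set(regions)
  gr_r <- as_granges(regions)
  if (mode == "midpoint" && !GenomicRanges::isDisjoint(gr_r, ignore.strand = TRUE))
    stop("regions overlap; merge them first (see merge_intervals)")
  counts <- integer(nrow(regions))
  names(counts) <- regions$id
  if (nrow(fragments) == 0L || nrow(regions) == 0L) return(counts)
  if (mode == "midpoint") {
    mid <- floor((fragments$start + fragments$end) / 2)
    gr_m <- GenomicRanges::GRanges(fragments$chrom,
                                   IRanges::IRanges(mid + 1L, mid + 1L))
    n <- GenomicRanges::countOverlaps(gr_r, gr_m, ignore.strand = TRUE)
  } else {
    n <- GenomicRanges::countOverlaps(gr_r, as_granges(fragments),
                                      ignore.strand = TRUE)
  }
  counts[] <- n
  counts
}

#' Split fragments into length classes
#'
#' Partitions fragments by length into inclusive `[min_len, max_len]`
#' classes; the defaults separate subnucleosomal (0-100 bp) from
#' mononucleosomal (180-250 bp) fragments. Fragments matching no class
#' are dropped.
#'
#' @param fragments an [interval_set].
#' @param classes named list of `c(min_len, max_len)` pairs;
#'   classes must not overlap.
#' @return Named list of [interval_set]s, one per class.
#' @export
split_by_fragment_size <- function(fragments,
                                   classes = list(subnucleosomal = c(0, 100),
                                                  mononucleosome = c(180, 250))) {
  stopifnot_interval_set(fragments)
  if (length(classes) == 0L) stop("at least one class required")
  b <- do.call(rbind, lapply(classes, function(x) as.numeric(x[1:2])))
  if (any(b[, 2] < b[, 1])) stop("each class needs min_len <= max_len")
  ord <- order(b[, 1])
  if (nrow(b) > 1L && any(b[ord, 1][-1] <= b[ord, 2][-nrow(b)]))
    stop("fragment size classes overlap")
  len <- fragments$end - fragments$start
  out <- lapply(seq_along(classes), function(i) {
    keep <- len >= b[i, 1] & len <= b[i, 2]
    s <- fragments[keep, , drop = FALSE]
    rownames(s) <- NULL
    class(s) <- class(fragments)
    attr(s, "genome") <- attr(fragments, "genome")
    s
  })
  names(out) <- names(classes)
  out
}

# TMM factor for one sample against the reference column.
# Trimmed (by M and by A), inverse-variance weighted mean of per-region
# log-ratios, as published for the trimmed-mean-of-M-values method.
tmm_one <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  if (length(m) == 0L)
    stop("sample shares no region with positive counts with the reference")
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep)) {
    warning("all regions trimmed; falling back to factor 1")
    return(1)
  }
  f <- sum(m[keep] / w[keep], na.rm = TRUE) / sum(1 / w[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values scaling factors for a region-by-sample count
#' matrix. The reference sample is the one whose 75th percentile of
#' count/library-size is closest to the mean of those percentiles. For
#' each sample, per-region log2 ratios against the reference (M) are
#' trimmed by `trim_m` on M and `trim_a` on average abundance (A), and the
#' survivors combined by an inverse-variance (delta-method) weighted mean.
#' Factors are rescaled so their geometric mean is 1.
#'
#' @param counts region-by-sample matrix of non-negative integer counts.
#' @param lib_size optional per-sample library sizes; defaults to column
#'   sums.
#' @param trim_m,trim_a tail fractions trimmed on M and A (defaults 0.30
#'   and 0.05, the published method's defaults).
#' @return List with `lib_size` and `factors` (geometric mean 1), both
#'   named by sample.
#' @export
tmm_factors <- function(counts, lib_size = NULL, trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("at least 2 samples required")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (length(lib_size) != ncol(counts))
    stop("lib_size length must match the number of samples")
  if (any(lib_size <= 0)) stop("library sizes must be positive")
  keep <- rowSums(counts > 0) > 0
  x <- counts[keep, , drop = FALSE]
  q75 <- apply(x, 2, stats::quantile, probs = 0.75) / lib_size
  ref <- which.min(abs(q75 - mean(q75)))
  f <- vapply(seq_len(ncol(x)), function(k)
    tmm_one(x[, k], x[, ref], lib_size[k], lib_size[ref], trim_m, trim_a),
    numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  ls <- as.numeric(lib_size)
  names(ls) <- colnames(counts)
  list(lib_size = ls, factors = f)
}

#' Log2 counts per million with TMM effective library sizes
#'
#' `log2((Y + prior) / (N * f + 2 * prior) * 1e6)` for count `Y`, library
#' size `N` and TMM factor `f`; the half-count prior keeps zeros finite.
#'
#' @param counts region-by-sample count matrix.
#' @param norm result of [tmm_factors()].
#' @param prior prior count added to the numerator (default 0.5).
#' @return Real matrix of the same dimension as `counts`.
#' @export
log2_cpm <- function(counts, norm, prior = 0.5) {
  counts <- as.matrix(counts)
  eff <- norm$lib_size * norm$factors
  if (length(eff) != ncol(counts))
    stop("normalization factors do not match the count matrix")
  log2(sweep(counts + prior, 2, eff + 2 * prior, "/") * 1e6)
}

#' CPM on the natural scale with TMM effective library sizes
#'
#' @param counts region-by-sample count matrix.
#' @param norm result of [tmm_factors()].
#' @return Matrix of `Y / (N * f) * 1e6`.
#' @export
cpm_tmm <- function(counts, norm) {
  counts <- as.matrix(counts)
  eff <- norm$lib_size * norm$factors
  if (length(eff) != ncol(counts))
    stop("normalization factors do not match the count matrix")
  sweep(counts, 2, eff, "/") * 1e6
}

#' Read / write a region-by-sample count table (TSV)
#'
#' The table has region ids in the first column (`region_id`) and one
#' integer column per sample.
#'
#' @param path TSV path.
#' @return Integer matrix with region-id rownames.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "region_id") stop("first column must be region_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$region_id
  storage.mode(m) <- "double"
  m
}

#' @rdname read_count_table
#' @param counts matrix to write.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(region_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample sheet (TSV)
#'
#' Columns: `sample_id`, `condition`, `replicate_batch`, and optionally
#' `phase` (EG1/LG1/S/SG2), `time_hr`, `library_size`.
#'
#' @param path TSV path.
#' @return Data frame, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "condition", "replicate_batch")
  if (!all(req %in% names(df)))
    stop("sample sheet must contain columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("sample_id must be unique")
  df
}

#' @rdname read_sample_sheet
#' @param samples data frame to write.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
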