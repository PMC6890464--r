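#' Construct an interval set
#'
#' An `interval_set` is the package's container for ordered genomic regions:
#' a data frame with columns `chrom`, `start`, `end`, `id` and `strand`,
#' using 0-based half-open (BED) coordinates throughout. Rows are kept
#' sorted by (chrom, start, end) and region ids must be unique.
#'
#' @param chrom character vector of chromosome names (exact string match is
#'   used everywhere; no "chr" prefix normalization).
#' @param start,end numeric vectors of 0-based half-open coordinates;
#'   `end > start >= 0` is required.
#' @param id optional character vector of unique region identifiers.
#'   Defaults to `"chrom:start-end"`.
#' @param strand optional strand (`"+"`, `"-"` or `"."`; default `"."`).
#' @param genome optional named numeric vector of chromosome lengths; when
#'   supplied, no interval may exceed its chromosome length.
#' @return An `interval_set` (a sorted data frame with a `genome` attribute).
#' @examples
#' interval_set(c("chr1", "chr1"), c(10, 100), c(20, 200))
#' @export
interval_set <- function(chrom = character(), start = numeric(),
                         end = numeric(), id = NULL, strand = NULL,
                         genome = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(start) != n || length(end) != n)
    stop("chrom, start and end must have equal length")
  if (any(start < 0)) stop("start coordinates must be >= 0")
  if (any(end <= start)) stop("all intervals must satisfy end > start")
  if (is.null(id)) id <- sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
  id <- as.character(id)
  if (anyDuplicated(id)) stop("region ids must be unique within an interval_set")
  if (is.null(strand)) strand <- rep(".", n)
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-", "."))) stop("strand must be one of '+', '-', '.'")
  if (!is.null(genome)) {
    if (is.null(names(genome))) stop("genome must be a named vector of chromosome lengths")
    bad <- chrom %in% names(genome) & end > genome[chrom]
    if (any(bad)) stop("interval(s) exceed chromosome length: ", id[which(bad)[1]])
  }
  x <- data.frame(chrom = chrom, start = start, end = end, id = id,
                  strand = strand, stringsAsFactors = FALSE)
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  attr(x, "genome") <- genome
  class(x) <- c("interval_set", "data.frame")
  x
}

#' @export
print.interval_set <- function(x, ...) {
  cat("interval_set with", nrow(x), "intervals on",
      length(unique(x$chrom)), "chromosome(s)\n")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

is_interval_set <- function(x) inherits(x, "interval_set")

stopifnot_interval_set <- function(x, arg = deparse(substitute(x))) {
  if (!is_interval_set(x)) stop(arg, " must be an interval_set")
  invisible(x)
}

# GRanges bridge: interval_set is 0-based half-open, GRanges 1-based closed
as_granges <- function(x) {
  stopifnot_interval_set(x)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = ifelse(x$strand == ".", "*", x$strand)
  )
}

granges_to_interval_set <- function(gr, id = NULL, genome = NULL) {
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  interval_set(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    id = id, strand = strand, genome = genome
  )
}

#' Read a BED file into an interval_set
#'
#' Parses BED3/BED6 (tab-separated, 0-based half-open). Column 4, when
#' present, provides region ids; otherwise ids are generated as
#' `"chrom:start-end"`. Gzip-compressed files are accepted. Lines are
#' re-sorted by (chrom, start, end) on read.
#'
#' @param path path to a BED file (optionally gzipped).
#' @param genome optional named vector of chromosome lengths.
#' @return An [interval_set].
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(interval_set(genome = genome))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1], ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", bad[1], ": non-numeric coordinates")
  bad <- which(end <= start)
  if (length(bad))
    stop("invalid BED line ", bad[1], ": end <= start")
  id <- if (all(nf >= 4L)) vapply(fields, `[[`, "", 4L) else NULL
  strand <- if (all(nf >= 6L)) vapply(fields, `[[`, "", 6L) else NULL
  interval_set(chrom, start, end, id = id, strand = strand, genome = genome)
}

#' Write an interval_set to a BED file
#'
#' @param x an [interval_set].
#' @param path output path.
#' @param score score column for BED6 output (default 0).
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, score = 0) {
  stopifnot_interval_set(x)
  df <- data.frame(x$chrom, as.integer(x$start), as.integer(x$end),
                   x$id, score, x$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge overlapping or book-ended intervals
#'
#' Overlapping intervals, and intervals separated by at most `gap` bases,
#' are replaced by their union (per chromosome). With the default `gap = 0`
#' book-ended intervals (end == next start) are merged, matching the
#' default behaviour of BEDTools merge. Merged regions get fresh
#' `"chrom:start-end"` ids.
#'
#' @param x an [interval_set].
#' @param gap non-negative integer; intervals at distance <= `gap` merge.
#' @return An [interval_set] of merged regions.
#' @export
merge_intervals <- function(x, gap = 0) {
  stopifnot_interval_set(x)
  if (gap < 0) stop("gap must be non-negative")
  if (nrow(x) == 0L) return(x)
  gr <- GenomicRanges::reduce(as_granges(x), min.gapwidth = gap + 1L,
                              ignore.strand = TRUE)
  granges_to_interval_set(gr, genome = attr(x, "genome"))
}

#' Drop intervals longer than a maximum length
#'
#' Removes intervals whose length (`end - start`) exceeds `max_len`;
#' the default 5000 reproduces the "peaks larger than 5 kb are removed"
#' preprocessing rule. Length exactly `max_len` is retained.
#'
#' @param x an [interval_set].
#' @param max_len maximum retained length in bp (> 0).
#' @return The filtered [interval_set].
#' @export
filter_by_length <- function(x, max_len = 5000) {
  stopifnot_interval_set(x)
  if (max_len <= 0) stop("max_len must be positive")
  keep <- (x$end - x$start) <= max_len
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(x)
  attr(out, "genome") <- attr(x, "genome")
  out
}

#' Remove intervals overlapping an exclusion set
#'
#' Drops every `target` interval sharing at least one base with any
#' interval of `exclusion` (the blacklist / Input-peak removal rule).
#' Coordinates are half-open: `[10,20)` and `[20,30)` do not overlap.
#'
#' @param target,exclusion [interval_set]s.
#' @return The filtered target [interval_set].
#' @export
remove_overlapping <- function(target, exclusion) {
  stopifnot_interval_set(target)
  stopifnot_interval_set(exclusion)
  if (nrow(target) == 0L || nrow(exclusion) == 0L) return(target)
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(as_granges(target), as_granges(exclusion),
                                 ignore.strand = TRUE))
  out <- target[hits == 0L, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(target)
  attr(out, "genome") <- attr(target, "genome")
  out
}

#' Expand intervals symmetrically
#'
#' Pads each interval by `pad` bases on both sides, clipping at 0 and at
#' the chromosome length when a genome is attached (the +/-500 bp
#' H3K27ac expansion rule). The result is re-sorted but not merged.
#'
#' @param x an [interval_set].
#' @param pad non-negative pad in bp.
#' @return The expanded [interval_set].
#' @export
expand_intervals <- function(x, pad) {
  stopifnot_interval_set(x)
  if (pad < 0) stop("pad must be non-negative")
  if (nrow(x) == 0L || pad == 0) return(x)
  genome <- attr(x, "genome")
  start <- pmax(0, x$start - pad)
  end <- x$end + pad
  if (!is.null(genome)) {
    lim <- genome[x$chrom]
    end <- ifelse(!is.na(lim), pmin(end, lim), end)
  }
  interval_set(x$chrom, start, end, id = x$id, strand = x$strand,
               genome = genome)
}

#' Distance from each region to its nearest TSS
#'
#' For every region, reports the closest transcription-start site:
#' distance 0 when a TSS falls inside the region, otherwise the number of
#' bases between the TSS and the nearest region edge. Ties (equidistant
#' TSS on both sides) are broken toward the smaller genomic coordinate.
#' Regions on chromosomes absent from the annotation get `NA` distance
#' with a warning. Output rows are ordered by region id.
#'
#' @param regions an [interval_set].
#' @param tss an [interval_set] of single-base TSS positions (`end ==
#'   start + 1`), ids interpreted as gene ids.
#' @return data frame with columns `region_id`, `gene_id`, `distance`.
#' @export
nearest_tss <- function(regions, tss) {
  stopifnot_interval_set(regions)
  stopifnot_interval_set(tss)
  if (nrow(tss) == 0L) stop("tss annotation is empty")
  if (any(tss$end - tss$start != 1))
    stop("tss intervals must be single-base (end == start + 1)")
  out <- data.frame(region_id = regions$id,
                    gene_id = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  gr_r <- as_granges(regions)
  gr_t <- as_granges(tss)
  dtn <- suppressWarnings(
    GenomicRanges::distanceToNearest(gr_r, gr_t, ignore.strand = TRUE))
  if (length(dtn)) {
    dvec <- rep(NA_real_, nrow(regions))
    dvec[S4Vectors::queryHits(dtn)] <- S4Vectors::mcols(dtn)$distance
    # collect every TSS at the minimal distance (distanceToNearest picks
    # an arbitrary one among ties), then take the smallest coordinate
    pad <- ifelse(is.na(dvec), 0, dvec + 1)
    ex <- gr_r
    GenomicRanges::start(ex) <- pmax(1, GenomicRanges::start(gr_r) - pad)
    GenomicRanges::end(ex) <- GenomicRanges::end(gr_r) + pad
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(ex, gr_t, ignore.strand = TRUE))
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    dd <- suppressWarnings(GenomicRanges::distance(gr_r[qh], gr_t[sh]))
    keep <- !is.na(dvec[qh]) & dd == dvec[qh]
    qh <- qh[keep]; sh <- sh[keep]
    ord <- order(qh, tss$start[sh])
    qh <- qh[ord]; sh <- sh[ord]
    first <- !duplicated(qh)
    out$gene_id[qh[first]] <- tss$id[sh[first]]
    out$distance <- dvec
  }
  if (anyNA(out$distance))
    warning(sum(is.na(out$distance)),
            " region(s) on chromosomes absent from the TSS annotation")
  out <- out[order(out$region_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify regions as TSS-distal or promoter-proximal
#'
#' Distance > `threshold` bp from the nearest TSS is "distal", <=
#' `threshold` "proximal" (default 1 kb). Missing distances are labelled
#' "unassigned".
#'
#' @param distances data frame from [nearest_tss()].
#' @param threshold distance threshold in bp.
#' @return data frame with columns `region_id`, `class`.
#' @export
classify_proximity <- function(distances, threshold = 1000) {
  if (!all(c("region_id", "distance") %in% names(distances)))
    stop("distances must contain region_id and distance columns")
  cls <- ifelse(is.na(distances$distance), "unassigned",
                ifelse(distances$distance > threshold, "distal", "proximal"))
  data.frame(region_id = distances$region_id, class = cls,
             stringsAsFactors = FALSE)
}

#' Fraction of intervals overlapping another set
#'
#' Fraction of `a`'s intervals sharing at least one base with any interval
#' of `b` (the statistic behind binding-overlap summaries such as "89% of
#' SOX2-dependent sites overlap an OCT4 peak").
#'
#' @param a,b [interval_set]s; `a` must be non-empty.
#' @return A fraction in \[0, 1\].
#' @export
overlap_fraction <- function(a, b) {
  stopifnot_interval_set(a)
  stopifnot_interval_set(b)
  if (nrow(a) == 0L) stop("overlap_fraction: 'a' is empty")
  if (nrow(b) == 0L) return(0)
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(as_granges(a), as_granges(b),
                                 ignore.strand = TRUE))
  mean(hits > 0L)
}

#' Subset an interval_set by region id
#'
#' @param x an [interval_set].
#' @param ids character vector of region ids to keep.
#' @return The subset [interval_set] (in sorted order).
#' @export
subset_by_id <- function(x, ids) {
  stopifnot_interval_set(x)
  out <- x[x$id %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(x)
  attr(out, "genome") <- attr(x, "genome")
  out
}
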