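#' Direction-consistent significant changes across two comparisons
#'
#' Reproduces the two-comparison consistency filter used when calling
#' factor-dependent loci: a region is a candidate when it is significant
#' (`q < fdr`) in at least one comparison (`mode = "any"`, the default) or
#' in both (`mode = "both"`), and is retained only when its log2
#' fold-change has the same non-zero sign in both comparisons. Retained
#' regions are split into `decreased` and `increased` by that shared sign.
#'
#' @param res_a,res_b `diff_result` data frames over the same region
#'   universe (e.g. the 26 h and 40 h depletion contrasts).
#' @param fdr FDR threshold (default 0.05).
#' @param mode `"any"` or `"both"` (see above).
#' @param tf optional factor name recorded in the output.
#' @return A `change_set`: list with `tf`, `decreased`, `increased`
#'   (character vectors of region ids) and `evidence` (per-candidate q and
#'   log2FC in both comparisons).
#' @export
consistent_changes <- function(res_a, res_b, fdr = 0.05,
                               mode = c("any", "both"), tf = NA_character_) {
  mode <- match.arg(mode)
  if (!setequal(res_a$region_id, res_b$region_id))
    stop("the two results cover different region universes")
  b <- res_b[match(res_a$region_id, res_b$region_id), ]
  sig <- if (mode == "any") res_a$q < fdr | b$q < fdr else
    res_a$q < fdr & b$q < fdr
  same_dir <- sign(res_a$log2FC) == sign(b$log2FC) &
    res_a$log2FC != 0 & b$log2FC != 0
  keep <- sig & same_dir
  structure(list(
    tf = tf,
    decreased = res_a$region_id[keep & res_a$log2FC < 0],
    increased = res_a$region_id[keep & res_a$log2FC > 0],
    evidence = data.frame(region_id = res_a$region_id[keep],
                          log2FC_a = res_a$log2FC[keep], q_a = res_a$q[keep],
                          log2FC_b = b$log2FC[keep], q_b = b$q[keep],
                          stringsAsFactors = FALSE)
  ), class = "change_set")
}

#' Baseline-difference exclusion
#'
#' Regions already differing strongly between untreated baseline
#' conditions (cell lines or culture media) are excluded from dependency
#' classification: a region is excluded when, in any baseline comparison,
#' it is significant (`q < fdr`) and `|log2FC| > log2(fold)` (the
#' "discard loci with FC > 4 among significantly different loci" rule;
#' equality is retained).
#'
#' @param baseline_results list of `diff_result` data frames.
#' @param fdr FDR threshold (default 0.05).
#' @param fold fold-change threshold (> 1; default 4).
#' @return Character vector of excluded region ids.
#' @export
baseline_exclusion <- function(baseline_results, fdr = 0.05, fold = 4) {
  if (fold <= 1) stop("fold must be > 1")
  if (inherits(baseline_results, "data.frame"))
    baseline_results <- list(baseline_results)
  excluded <- character(0)
  for (res in baseline_results) {
    hit <- res$q < fdr & abs(res$log2FC) > log2(fold)
    excluded <- union(excluded, res$region_id[hit])
  }
  excluded
}

#' Classify regions into factor-dependency groups
#'
#' Labels every region of the universe with exactly one of: `OD`
#' (accessibility lost on OCT4 depletion only), `SD` (SOX2 only), `CD`
#' (either factor), `gained_on_OCT4_loss` / `gained_on_SOX2_loss`,
#' `excluded_baseline`, `excluded_unbound`, or `unclassified`.
#'
#' A region with a consistent accessibility decrease is labelled
#' `excluded_baseline` when in the baseline-exclusion set, then
#' `excluded_unbound` when not overlapping any OCT4/SOX2 ChIP peak, and
#' otherwise OD/SD/CD by which factor's depletion it responded to.
#' Decreases take precedence over increases; gained labels (OCT4 before
#' SOX2 when gained under both) are subject to the baseline exclusion but
#' not to the binding gate, since gained loci are largely unbound.
#'
#' @param oct4,sox2 `change_set`s from [consistent_changes()] for the two
#'   depletions.
#' @param universe character vector of all region ids under study.
#' @param excluded region ids from [baseline_exclusion()].
#' @param bound region ids overlapping the merged OCT4/SOX2 ChIP peak
#'   universe.
#' @return A `dependency_call`: list with `labels` (data frame
#'   `region_id`, `label`) and `counts` (table of label counts).
#' @export
classify_dependency <- function(oct4, sox2, universe, excluded, bound) {
  if (!inherits(oct4, "change_set") || !inherits(sox2, "change_set"))
    stop("oct4 and sox2 must be change_sets from consistent_changes()")
  lab <- stats::setNames(rep("unclassified", length(universe)), universe)
  dec_o <- intersect(oct4$decreased, universe)
  dec_s <- intersect(sox2$decreased, universe)
  inc_o <- intersect(oct4$increased, universe)
  inc_s <- intersect(sox2$increased, universe)

  lab[setdiff(inc_s, dec_o)] <- "gained_on_SOX2_loss"
  lab[setdiff(inc_o, dec_s)] <- "gained_on_OCT4_loss"

  both <- intersect(dec_o, dec_s)
  lab[setdiff(dec_o, dec_s)] <- "OD"
  lab[setdiff(dec_s, dec_o)] <- "SD"
  lab[both] <- "CD"

  dec_any <- union(dec_o, dec_s)
  lab[setdiff(dec_any, bound)] <- "excluded_unbound"
  changed <- union(dec_any, union(inc_o, inc_s))
  lab[intersect(changed, excluded)] <- "excluded_baseline"

  labels <- data.frame(region_id = universe, label = unname(lab[universe]),
                       stringsAsFactors = FALSE)
  structure(list(labels = labels, counts = table(labels$label)),
            class = "dependency_call")
}

#' @export
print.dependency_call <- function(x, ...) {
  cat("dependency_call over", nrow(x$labels), "regions:\n")
  print(x$counts)
  invisible(x)
}

#' Per-label ChIP-peak overlap fractions
#'
#' For each dependency label, the fraction of its regions overlapping at
#' least one OCT4 peak and at least one SOX2 peak (the "89% of SD sites
#' overlap an OCT4 peak"-style summary). Empty label classes get `NA`.
#'
#' @param call a `dependency_call`.
#' @param oct4_peaks,sox2_peaks [interval_set]s of ChIP peaks.
#' @param regions [interval_set] of the region universe (ids matching the
#'   call).
#' @param labels labels to report (default the dependency and gained
#'   classes).
#' @return Data frame: `label`, `n`, `frac_oct4`, `frac_sox2`.
#' @export
binding_overlap_report <- function(call, oct4_peaks, sox2_peaks, regions,
                                   labels = c("OD", "SD", "CD",
                                              "gained_on_OCT4_loss",
                                              "gained_on_SOX2_loss")) {
  if (!inherits(call, "dependency_call")) stop("call must be a dependency_call")
  out <- lapply(labels, function(l) {
    ids <- call$labels$region_id[call$labels$label == l]
    if (length(ids) == 0L)
      return(data.frame(label = l, n = 0L, frac_oct4 = NA_real_,
                        frac_sox2 = NA_real_))
    sub <- subset_by_id(regions, ids)
    data.frame(label = l, n = length(ids),
               frac_oct4 = overlap_fraction(sub, oct4_peaks),
               frac_sox2 = overlap_fraction(sub, sox2_peaks))
  })
  do.call(rbind, out)
}

#' Region ids bound by a peak universe
#'
#' Convenience gate for [classify_dependency()]: ids of `regions`
#' overlapping (>= 1 bp) the union of the supplied peak sets.
#'
#' @param regions [interval_set] of the region universe.
#' @param ... one or more [interval_set]s of ChIP peaks.
#' @return Character vector of bound region ids.
#' @export
bound_region_ids <- function(regions, ...) {
  peaks <- list(...)
  if (length(peaks) == 0L) stop("supply at least one peak set")
  gr_r <- as_granges(regions)
  hit <- rep(FALSE, nrow(regions))
  for (p in peaks) {
    stopifnot_interval_set(p)
    if (nrow(p) == 0L) next
    hit <- hit | GenomicRanges::countOverlaps(gr_r, as_granges(p),
                                              ignore.strand = TRUE) > 0L
  }
  regions$id[hit]
}
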