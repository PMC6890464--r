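#' Assemble a region-by-phase fold-change matrix
#'
#' Builds the matrix clustered in the cell-cycle analysis: one row per
#' (typically OCT4-bound, accessible) region, one column per cell-cycle
#' phase in fixed order EG1, LG1, S, SG2, holding the per-phase contrast
#' log2 fold-change (e.g. degron versus control within each sorted
#' fraction). Regions missing from any phase are dropped with a message.
#'
#' @param per_phase_results named list of `diff_result` data frames, one
#'   per phase; names must cover `phases`.
#' @param regions character vector of region ids to include.
#' @param phases column order (default `c("EG1","LG1","S","SG2")`).
#' @return Real matrix (regions x phases) with region-id rownames.
#' @export
build_fc_matrix <- function(per_phase_results, regions,
                            phases = c("EG1", "LG1", "S", "SG2")) {
  if (!all(phases %in% names(per_phase_results)))
    stop("missing phase result(s): ",
         paste(setdiff(phases, names(per_phase_results)), collapse = ", "))
  if (length(regions) == 0L) stop("empty region set")
  cols <- lapply(phases, function(ph) {
    res <- per_phase_results[[ph]]
    res$log2FC[match(regions, res$region_id)]
  })
  fc <- do.call(cbind, cols)
  dimnames(fc) <- list(regions, phases)
  keep <- stats::complete.cases(fc)
  if (any(!keep))
    message(sum(!keep), " region(s) missing from at least one phase; dropped")
  fc[keep, , drop = FALSE]
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (i in seq_len(k - 1L) + 1L) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[i, ] <- x[sample.int(n, 1L, prob = prob), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[i, ])^2))
  }
  centers
}

#' K-means clustering of fold-change profiles
#'
#' Euclidean k-means (Lloyd iterations) with k-means++ initialization and
#' `n_init` restarts, keeping the solution with the lowest total
#' within-cluster sum of squares. Clusters are then relabelled with
#' [order_clusters()] so that cluster 1 has the lowest (most negative)
#' mean log2 fold-change in `order_phase`. Results are deterministic for
#' a fixed seed.
#'
#' @param fc matrix from [build_fc_matrix()]; must have at least `k`
#'   distinct rows.
#' @param k number of clusters (default 4).
#' @param seed integer seed for the restarts.
#' @param n_init number of k-means++ restarts (default 10).
#' @param order_phase column used for the ordering rule (default "EG1").
#' @return A `cluster_model`: list with `k`, `assignments` (named integer
#'   vector), `centers` (k x phases), `inertia`, `seed`.
#' @export
kmeans_cluster <- function(fc, k = 4, seed = 1L, n_init = 10,
                           order_phase = "EG1") {
  fc <- as.matrix(fc)
  if (nrow(fc) < k) stop("need at least k rows")
  if (nrow(unique(fc)) < k) stop("fewer distinct rows than clusters")
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_init)) {
    init <- kmeanspp_centers(fc, k)
    km <- suppressWarnings(
      stats::kmeans(fc, centers = init, iter.max = 200L, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  model <- structure(list(k = k,
                          assignments = stats::setNames(best$cluster, rownames(fc)),
                          centers = best$centers,
                          inertia = best$tot.withinss,
                          seed = seed),
                     class = "cluster_model")
  order_clusters(model, fc, phase = order_phase)
}

#' Relabel clusters by ascending mean fold-change in one phase
#'
#' Bijective relabelling so that the cluster with the lowest mean log2
#' fold-change in `phase` becomes cluster 1, the next lowest cluster 2,
#' and so on ("ordered according to the lowest mean log2 fold-change in
#' EG1"). Ties are broken by cluster size, larger first. The partition
#' and inertia are unchanged.
#'
#' @param model a `cluster_model`.
#' @param fc the matrix the model was fitted on.
#' @param phase column name used for ordering (default "EG1").
#' @return The relabelled `cluster_model`.
#' @export
order_clusters <- function(model, fc, phase = "EG1") {
  if (!inherits(model, "cluster_model")) stop("model must be a cluster_model")
  fc <- as.matrix(fc)
  if (!phase %in% colnames(fc)) stop("phase '", phase, "' is not a column of fc")
  k <- model$k
  if (k == 1L) return(model)
  assign <- model$assignments[rownames(fc)]
  means <- vapply(seq_len(k), function(cl)
    mean(fc[assign == cl, phase]), numeric(1))
  sizes <- tabulate(assign, nbins = k)
  ord <- order(means, -sizes) # old labels in ascending order of phase mean
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  model$assignments <- stats::setNames(relabel[model$assignments],
                                       names(model$assignments))
  model$centers <- model$centers[ord, , drop = FALSE]
  rownames(model$centers) <- seq_len(k)
  model
}

#' Per-cluster normalized accessibility time courses
#'
#' For an inhibitor time-course count matrix: TMM-normalize, average the
#' per-region CPM over replicate samples at each time point, then average
#' over each cluster's regions, yielding one time course per cluster
#' (normalize, then average replicates, then average regions).
#'
#' @param counts region-by-sample count matrix over the time course.
#' @param samples sample sheet with a numeric `time_hr` column.
#' @param norm result of [tmm_factors()] for `counts`.
#' @param model a `cluster_model` whose assignment names are a subset of
#'   the count regions.
#' @return Data frame `cluster`, `time_hr`, `value` (one row per cluster
#'   and time point), of class `time_course_set`.
#' @export
cluster_timecourse <- function(counts, samples, norm, model) {
  counts <- as.matrix(counts)
  if (is.null(samples$time_hr) || anyNA(samples$time_hr))
    stop("samples must carry a complete numeric time_hr column")
  times <- sort(unique(samples$time_hr))
  regions <- intersect(names(model$assignments), rownames(counts))
  if (length(regions) == 0L)
    stop("no cluster regions present in the count matrix")
  cpm <- cpm_tmm(counts, norm)[regions, , drop = FALSE]
  assign <- model$assignments[regions]
  per_time <- vapply(times, function(t) {
    idx <- which(samples$time_hr == t)
    if (length(idx) == 0L) stop("time point without samples: ", t)
    rowMeans(cpm[, idx, drop = FALSE])
  }, numeric(length(regions)))
  per_time <- matrix(per_time, nrow = length(regions))
  out <- do.call(rbind, lapply(sort(unique(assign)), function(cl) {
    data.frame(cluster = cl, time_hr = times,
               value = colMeans(per_time[assign == cl, , drop = FALSE]))
  }))
  rownames(out) <- NULL
  class(out) <- c("time_course_set", "data.frame")
  out
}
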