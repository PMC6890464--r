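#' Default pipeline configuration
#'
#' All thresholds used by the end-to-end analysis, with the defaults of
#' the supported study design: FDR 0.05, baseline fold-change exclusion
#' at 4, TSS-proximity threshold 1000 bp, maximum peak length 5000 bp,
#' k = 4 clusters, TMM trim fractions 0.30 / 0.05, significance mode
#' "any", kinetics fitting window 4 hr.
#'
#' @param ... overrides of the default keys; unknown keys are rejected.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(fdr = 0.05, baseline_fold = 4, proximity_bp = 1000,
              max_peak_len = 5000, k = 4, trim_m = 0.30, trim_a = 0.05,
              prior_count = 0.5, significance_mode = "any",
              kinetics_max_time = 4, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(structure(cfg, class = "pipeline_config"))
}

#' Validate a pipeline configuration
#'
#' @param cfg a `pipeline_config`.
#' @return `cfg`, invisibly, or an error describing the invalid key.
#' @export
validate_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stop("invalid configuration: ", msg)
  chk(cfg$fdr > 0 && cfg$fdr < 1, "fdr must be in (0, 1)")
  chk(cfg$baseline_fold > 1, "baseline_fold must be > 1")
  chk(cfg$proximity_bp > 0, "proximity_bp must be positive")
  chk(cfg$max_peak_len > 0, "max_peak_len must be positive")
  chk(cfg$k >= 1, "k must be >= 1")
  chk(cfg$trim_m >= 0 && cfg$trim_m < 0.5, "trim_m must be in [0, 0.5)")
  chk(cfg$trim_a >= 0 && cfg$trim_a < 0.5, "trim_a must be in [0, 0.5)")
  chk(cfg$significance_mode %in% c("any", "both"),
      "significance_mode must be 'any' or 'both'")
  chk(cfg$kinetics_max_time > 0, "kinetics_max_time must be positive")
  invisible(cfg)
}

#' Run the end-to-end synthetic analysis
#'
#' Orchestrates the full chain on generator output: simulate the
#' depletion design, TMM-normalize, fit the moderated model, call the
#' four depletion and two baseline contrasts, apply the
#' consistency/baseline/binding filters, classify dependency, and report
#' binding-overlap fractions; then the cell-cycle design through
#' clustering; then the inhibitor time course through per-cluster decay
#' fits. Results (TSV/BED/JSON, plus the resolved configuration) are
#' written under `out_dir` when given; reruns with the same
#' configuration and seed produce identical reports.
#'
#' @param cfg a [pipeline_config()].
#' @param params a [sim_params()]; its seed is taken from `cfg$seed`
#'   unless supplied explicitly.
#' @param out_dir optional output directory.
#' @param steps subset of `c("classify", "cluster", "kinetics")` to run
#'   (default all).
#' @return List with `dependency` (call, overlap report, contrasts),
#'   `clusters` (`cluster_model`), `kinetics` (per-cluster fits and time
#'   courses), and `report` (the aggregated summary list).
#' @export
run_pipeline <- function(cfg = pipeline_config(), params = NULL,
                         out_dir = NULL,
                         steps = c("classify", "cluster", "kinetics")) {
  validate_config(cfg)
  steps <- match.arg(steps, several.ok = TRUE)
  if (is.null(params)) params <- sim_params(seed = cfg$seed)
  report <- list(config = unclass(cfg))
  out <- list()

  if ("classify" %in% steps) {
    sim <- simulate_depletion_experiment(params)
    norm <- tmm_factors(sim$counts, trim_m = cfg$trim_m, trim_a = cfg$trim_a)
    logcpm <- log2_cpm(sim$counts, norm, prior = cfg$prior_count)
    fit <- ebayes_moderate(fit_linear_model(logcpm, make_design(sim$samples)))
    res_oct4 <- list(
      SL = contrast_fit(fit, "ZHBTc4_SL_dox", "ZHBTc4_SL_untr"),
      S2iL = contrast_fit(fit, "ZHBTc4_S2iL_dox", "ZHBTc4_S2iL_untr"))
    res_sox2 <- list(
      h26 = contrast_fit(fit, "2TS22C_S2iL_dox26", "2TS22C_S2iL_untr"),
      h40 = contrast_fit(fit, "2TS22C_S2iL_dox40", "2TS22C_S2iL_untr"))
    res_base <- list(
      culture = contrast_fit(fit, "ZHBTc4_SL_untr", "ZHBTc4_S2iL_untr"),
      line = contrast_fit(fit, "ZHBTc4_S2iL_untr", "2TS22C_S2iL_untr"))
    oct4 <- consistent_changes(res_oct4$SL, res_oct4$S2iL, fdr = cfg$fdr,
                               mode = cfg$significance_mode, tf = "OCT4")
    sox2 <- consistent_changes(res_sox2$h26, res_sox2$h40, fdr = cfg$fdr,
                               mode = cfg$significance_mode, tf = "SOX2")
    excluded <- baseline_exclusion(res_base, fdr = cfg$fdr,
                                   fold = cfg$baseline_fold)
    bound <- bound_region_ids(sim$regions, sim$oct4_peaks, sim$sox2_peaks)
    call <- classify_dependency(oct4, sox2, universe = sim$regions$id,
                                excluded = excluded, bound = bound)
    overlap <- binding_overlap_report(call, sim$oct4_peaks, sim$sox2_peaks,
                                      sim$regions)
    out$dependency <- list(call = call, overlap = overlap,
                           contrasts = c(res_oct4, res_sox2, res_base),
                           sim = sim)
    report$dependency <- list(label_counts = as.list(call$counts),
                              overlap = overlap)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(call$labels, file.path(out_dir, "dependency_labels.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_simulation(sim, file.path(out_dir, "simulated_input"))
    }
  }

  if ("cluster" %in% steps) {
    cc <- simulate_cellcycle_experiment(params)
    norm_cc <- tmm_factors(cc$counts, trim_m = cfg$trim_m, trim_a = cfg$trim_a)
    logcpm_cc <- log2_cpm(cc$counts, norm_cc, prior = cfg$prior_count)
    fit_cc <- ebayes_moderate(fit_linear_model(logcpm_cc, make_design(cc$samples)))
    phases <- colnames(params$cc_templates)
    per_phase <- lapply(stats::setNames(phases, phases), function(ph)
      contrast_fit(fit_cc, paste0("MD_", ph), paste0("MDstar_", ph)))
    fc <- build_fc_matrix(per_phase, regions = cc$regions$id, phases = phases)
    model <- kmeans_cluster(fc, k = cfg$k, seed = cfg$seed)
    out$clusters <- list(model = model, fc = fc, sim = cc)
    report$clusters <- list(
      sizes = as.list(table(model$assignments)),
      centers = apply(model$centers, 1, function(r) as.list(r),
                      simplify = FALSE))
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(
        data.frame(region_id = names(model$assignments),
                   cluster = unname(model$assignments)),
        file.path(out_dir, "clusters.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("kinetics" %in% steps) {
    tcs <- simulate_timecourse(params)
    norm_tc <- tmm_factors(tcs$counts, trim_m = cfg$trim_m, trim_a = cfg$trim_a)
    responsive <- tcs$truth$region_id[tcs$truth$responsive]
    model_tc <- structure(
      list(k = 1L,
           assignments = stats::setNames(rep(1L, length(responsive)), responsive),
           centers = NULL, inertia = NA_real_, seed = cfg$seed),
      class = "cluster_model")
    tc <- cluster_timecourse(tcs$counts, tcs$samples, norm_tc, model_tc)
    fits <- cluster_kinetics(tc, max_time = cfg$kinetics_max_time)
    traces <- simulate_traces(params)
    trace_fit <- fit_trace_halflife(traces$traces)
    out$kinetics <- list(timecourse = tc, fits = fits,
                         trace_fit = trace_fit, sim = tcs)
    report$kinetics <- list(
      accessibility = lapply(fits, function(f)
        if (is.null(f)) NULL else
          list(a = f$a, b = f$b, c = f$c, half_life_hr = f$half_life,
               rss = f$rss, converged = f$converged, n_points = f$n_points)),
      protein = list(half_life_hr = trace_fit$population$half_life,
                     b = trace_fit$population$b,
                     converged = trace_fit$population$converged))
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(tc, file.path(out_dir, "timecourse.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  out$report <- report
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  out
}
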