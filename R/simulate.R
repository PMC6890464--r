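#' Simulation parameters
#'
#' Bundles the knobs of the synthetic-data generator. Defaults emulate
#' the supported experimental designs at desk scale: negative-binomial
#' ATAC fragment counts over a 2 x 10 Mb toy genome, factor-dependency
#' classes with planted depletion effects, hidden per-sample composition
#' factors for TMM to estimate, replicate-batch structure for the paired
#' design, and first-order decay kinetics for degron time courses and
#' single-cell fluorescence traces.
#'
#' @param n_regions number of regions (default 5000).
#' @param class_proportions named fractions over
#'   `c(OD, SD, CD, gained, null)` summing to 1.
#' @param baseline_mean,baseline_sd normal distribution of per-region
#'   baseline log2-CPM.
#' @param effect_log2fc planted depletion effect: accessibility loss of
#'   this magnitude (log2) for OD/SD/CD under the relevant depletion,
#'   gain for "gained" regions.
#' @param nb_dispersion negative-binomial dispersion phi
#'   (`var = mu + phi mu^2`).
#' @param n_replicates replicate batches per condition.
#' @param lib_size_mean,lib_size_cv log-normal library-size distribution.
#' @param composition_sd sd of the hidden log-normal per-sample
#'   composition factor absorbed by normalization.
#' @param batch_sd sd of per-region replicate-batch effects (log2).
#' @param baseline_shift_prop,baseline_shift_log2 fraction of regions
#'   carrying a culture/cell-line baseline difference and its magnitude
#'   (log2), exercised by the baseline-exclusion filter.
#' @param chip_overlap named list of per-class binding rates for the
#'   planted OCT4 and SOX2 ChIP peaks. The defaults plant complete
#'   binding of each factor at its own dependent and co-dependent sites,
#'   89% OCT4 binding at SOX2-dependent sites and 65% SOX2 binding at
#'   OCT4-dependent sites, with background rates elsewhere.
#' @param cc_templates 4 x 4 matrix of cell-cycle log2FC templates
#'   (clusters x EG1/LG1/S/SG2): strong early-G1 loss with partial
#'   recovery, moderate loss with full recovery, small persistent loss,
#'   and unaffected.
#' @param cc_proportions cluster proportions for the cell-cycle design.
#' @param cc_jitter per-region sd around the cluster template.
#' @param cc_dispersion NB dispersion for the sorted-fraction libraries.
#' @param decay_rate accessibility-loss rate constant (per hour).
#' @param plateau_fraction residual signal fraction after complete
#'   factor loss.
#' @param responsive_frac fraction of time-course regions that respond.
#' @param trace_rate protein-degradation rate constant (per hour).
#' @param trace_noise_cv multiplicative Gaussian noise cv on traces.
#' @param n_cells number of simulated cells (default 45).
#' @param trace_interval,trace_duration trace sampling grid (hours).
#' @param seed integer seed; all outputs are reproducible from it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_regions = 5000,
                       class_proportions = c(OD = 0.10, SD = 0.03, CD = 0.05,
                                             gained = 0.12, null = 0.70),
                       baseline_mean = 5, baseline_sd = 1,
                       effect_log2fc = 1.5,
                       nb_dispersion = 0.05,
                       n_replicates = 2,
                       lib_size_mean = 3e6, lib_size_cv = 0.2,
                       composition_sd = 0.1,
                       batch_sd = 0.1,
                       baseline_shift_prop = 0.02, baseline_shift_log2 = 2.5,
                       chip_overlap = list(
                         oct4 = c(OD = 1, SD = 0.89, CD = 1,
                                  gained = 0.20, null = 0.25),
                         sox2 = c(OD = 0.65, SD = 1, CD = 1,
                                  gained = 0.10, null = 0.15)),
                       cc_templates = rbind(
                         c(-2.8, -1.8, -1.2, -1.0),
                         c(-1.6, -0.8, -0.3, 0.0),
                         c(-0.7, -0.7, -0.7, -0.7),
                         c(0.0, 0.0, 0.0, 0.0)),
                       cc_proportions = c(0.25, 0.25, 0.25, 0.25),
                       cc_jitter = 0.1,
                       cc_dispersion = 0.02,
                       decay_rate = 1.386,
                       plateau_fraction = 0.30,
                       responsive_frac = 0.10,
                       trace_rate = 2.166,
                       trace_noise_cv = 0.10,
                       n_cells = 45,
                       trace_interval = 0.1, trace_duration = 2,
                       seed = 1L) {
  p <- as.list(environment())
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  if (any(class_proportions < 0)) stop("class_proportions must be non-negative")
  if (nb_dispersion <= 0 || cc_dispersion <= 0) stop("dispersion must be positive")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  colnames(p$cc_templates) <- c("EG1", "LG1", "S", "SG2")
  class(p) <- "sim_params"
  p
}

# Non-overlapping regions on a 2 x 10 Mb toy genome, widths 200-1000 bp.
toy_genome <- c(chr1 = 1e7, chr2 = 1e7)

place_regions <- function(n, genome = toy_genome) {
  per_chr <- diff(round(seq(0, n, length.out = length(genome) + 1)))
  sets <- mapply(function(chrom, len, m) {
    if (m == 0L) return(NULL)
    w <- round(stats::runif(m, 200, 1000))
    gaps <- stats::runif(m, 0.2, 1)
    avail <- len - sum(w) - 1000
    if (avail <= 0) stop("too many regions for the toy genome")
    gaps <- floor(gaps / sum(gaps) * avail * 0.9) + 1
    start <- cumsum(gaps) + cumsum(c(0, w[-m]))
    data.frame(chrom = chrom, start = start, end = start + w)
  }, names(genome), genome, per_chr, SIMPLIFY = FALSE)
  df <- do.call(rbind, sets)
  interval_set(df$chrom, df$start, df$end,
               id = sprintf("region_%05d", seq_len(nrow(df))),
               genome = genome)
}

# ChIP peaks overlapping selected regions (peak centered on the region
# midpoint, width 200-600 bp).
plant_peaks <- function(regions, bound_idx, prefix) {
  if (length(bound_idx) == 0L)
    return(interval_set(genome = attr(regions, "genome")))
  mid <- floor((regions$start[bound_idx] + regions$end[bound_idx]) / 2)
  w <- round(stats::runif(length(bound_idx), 200, 600))
  start <- pmax(0, mid - floor(w / 2))
  interval_set(regions$chrom[bound_idx], start, start + w,
               id = sprintf("%s_peak_%05d", prefix, seq_along(bound_idx)),
               genome = attr(regions, "genome"))
}

# NB counts for a regions x samples grid of log2-CPM means.
nb_counts <- function(log2cpm_mean, eff_lib, dispersion) {
  mu <- sweep(2^log2cpm_mean, 2, eff_lib / 1e6, "*")
  n <- length(mu)
  counts <- matrix(stats::rnbinom(n, size = 1 / dispersion, mu = mu),
                   nrow = nrow(mu), dimnames = dimnames(log2cpm_mean))
  counts
}

draw_lib_sizes <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  round(stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog))
}

#' Simulate the dual-depletion ATAC experiment
#'
#' Emulates the factor-depletion design: ZHBTc4 (Tet-Off *Pou5f1*) with
#' and without dox in two culture settings (SL and S2iL) and 2TS22C
#' (Tet-Off *Sox2*) with and without dox for two durations (26 h / 40 h),
#' with replicate batches shared across conditions (the paired design).
#' OD regions lose accessibility only under OCT4 depletion, SD only
#' under SOX2 depletion, CD under either, and "gained" regions gain
#' accessibility under OCT4 depletion. A configurable fraction of
#' regions carries a baseline culture/cell-line difference, and ChIP
#' peaks are planted at the per-class binding rates in `p$chip_overlap`.
#'
#' @param p a [sim_params()] object.
#' @return List with `regions` ([interval_set]), `samples` (sample
#'   sheet), `counts` (regions x samples matrix), `oct4_peaks`,
#'   `sox2_peaks` ([interval_set]s), and `truth` (per-region class,
#'   binding and planted-effect table).
#' @export
simulate_depletion_experiment <- function(p = sim_params()) {
  stopifnot(inherits(p, "sim_params"))
  set.seed(p$seed)
  n <- p$n_regions
  regions <- place_regions(n)
  classes <- sample(rep(names(p$class_proportions),
                        times = round_proportions(p$class_proportions, n)))
  base <- stats::rnorm(n, p$baseline_mean, p$baseline_sd)

  conditions <- c("ZHBTc4_SL_untr", "ZHBTc4_SL_dox",
                  "ZHBTc4_S2iL_untr", "ZHBTc4_S2iL_dox",
                  "2TS22C_S2iL_untr", "2TS22C_S2iL_dox26", "2TS22C_S2iL_dox40")
  oct4_dox <- c("ZHBTc4_SL_dox", "ZHBTc4_S2iL_dox")
  sox2_dox <- c("2TS22C_S2iL_dox26", "2TS22C_S2iL_dox40")
  samples <- expand.grid(replicate_batch = paste0("b", seq_len(p$n_replicates)),
                         condition = conditions, stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = paste(samples$condition, samples$replicate_batch, sep = "."),
    condition = samples$condition,
    replicate_batch = samples$replicate_batch,
    stringsAsFactors = FALSE)
  ns <- nrow(samples)

  # planted effects: regions x conditions (log2)
  eff <- matrix(0, n, length(conditions), dimnames = list(regions$id, conditions))
  eff[classes == "OD", oct4_dox] <- -p$effect_log2fc
  eff[classes == "SD", sox2_dox] <- -p$effect_log2fc
  eff[classes == "CD", c(oct4_dox, sox2_dox)] <- -p$effect_log2fc
  eff[classes == "gained", oct4_dox] <- p$effect_log2fc

  # baseline culture / cell-line shifts
  shifted <- stats::runif(n) < p$baseline_shift_prop
  shift_sign <- sample(c(-1, 1), n, replace = TRUE)
  sl_shift <- shifted & stats::runif(n) < 0.5
  cl_shift <- shifted & !sl_shift
  sl_cols <- c("ZHBTc4_SL_untr", "ZHBTc4_SL_dox")
  cl_cols <- c("2TS22C_S2iL_untr", "2TS22C_S2iL_dox26", "2TS22C_S2iL_dox40")
  eff[sl_shift, sl_cols] <- eff[sl_shift, sl_cols] +
    shift_sign[sl_shift] * p$baseline_shift_log2
  eff[cl_shift, cl_cols] <- eff[cl_shift, cl_cols] +
    shift_sign[cl_shift] * p$baseline_shift_log2

  # per-region batch effects (batch 1 is the reference)
  batch_eff <- matrix(0, n, p$n_replicates)
  if (p$n_replicates > 1)
    batch_eff[, -1] <- stats::rnorm(n * (p$n_replicates - 1), 0, p$batch_sd)

  lib <- draw_lib_sizes(ns, p$lib_size_mean, p$lib_size_cv)
  comp <- stats::rlnorm(ns, -p$composition_sd^2 / 2, p$composition_sd)
  bi <- match(samples$replicate_batch, paste0("b", seq_len(p$n_replicates)))
  mean_log2cpm <- base + eff[, samples$condition, drop = FALSE] +
    batch_eff[, bi, drop = FALSE]
  counts <- nb_counts(mean_log2cpm, lib * comp, p$nb_dispersion)
  colnames(counts) <- samples$sample_id

  oct4_idx <- which(stats::runif(n) < p$chip_overlap$oct4[classes])
  sox2_idx <- which(stats::runif(n) < p$chip_overlap$sox2[classes])

  truth <- data.frame(region_id = regions$id, class = classes,
                      baseline_log2cpm = base,
                      oct4_bound = seq_len(n) %in% oct4_idx,
                      sox2_bound = seq_len(n) %in% sox2_idx,
                      baseline_shifted = shifted,
                      true_log2fc_oct4 = eff[, "ZHBTc4_S2iL_dox"] -
                        eff[, "ZHBTc4_S2iL_untr"],
                      true_log2fc_sox2 = eff[, "2TS22C_S2iL_dox40"] -
                        eff[, "2TS22C_S2iL_untr"],
                      stringsAsFactors = FALSE)

  list(regions = regions, samples = samples, counts = counts,
       oct4_peaks = plant_peaks(regions, oct4_idx, "oct4"),
       sox2_peaks = plant_peaks(regions, sox2_idx, "sox2"),
       truth = truth)
}

# largest-remainder rounding of n * proportions to integers summing to n
round_proportions <- function(prop, n) {
  raw <- prop * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  k
}

#' Simulate the cell-cycle (mitotic-degron) ATAC experiment
#'
#' Emulates sorted cell-cycle fractions (EG1, LG1, S, SG2) of cells
#' expressing a mitotic-degron factor fusion (MD) versus its inactive
#' mutant control (MD*): each region follows one of four planted
#' phase-profile templates (with per-region jitter), applied to the MD
#' conditions only.
#'
#' @param p a [sim_params()] object (`cc_*` fields and the shared count
#'   model are used).
#' @return List with `regions`, `samples`, `counts`, and `truth`
#'   (per-region `cluster` and planted profile columns).
#' @export
simulate_cellcycle_experiment <- function(p = sim_params()) {
  stopifnot(inherits(p, "sim_params"))
  set.seed(p$seed + 1L)
  n <- p$n_regions
  phases <- colnames(p$cc_templates)
  regions <- place_regions(n)
  cluster <- sample(rep(seq_len(nrow(p$cc_templates)),
                        times = round_proportions(p$cc_proportions, n)))
  profile <- p$cc_templates[cluster, , drop = FALSE] +
    matrix(stats::rnorm(n * length(phases), 0, p$cc_jitter), n)
  dimnames(profile) <- list(regions$id, phases)
  base <- stats::rnorm(n, p$baseline_mean, p$baseline_sd)

  conditions <- c(paste0("MD_", phases), paste0("MDstar_", phases))
  samples <- expand.grid(replicate_batch = paste0("b", seq_len(p$n_replicates)),
                         condition = conditions, stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = paste(samples$condition, samples$replicate_batch, sep = "."),
    condition = samples$condition,
    replicate_batch = samples$replicate_batch,
    phase = sub("^MD(star)?_", "", samples$condition),
    stringsAsFactors = FALSE)
  ns <- nrow(samples)
  eff <- matrix(0, n, length(conditions), dimnames = list(regions$id, conditions))
  eff[, paste0("MD_", phases)] <- profile

  batch_eff <- matrix(0, n, p$n_replicates)
  if (p$n_replicates > 1)
    batch_eff[, -1] <- stats::rnorm(n * (p$n_replicates - 1), 0, p$batch_sd)
  bi <- match(samples$replicate_batch, paste0("b", seq_len(p$n_replicates)))
  lib <- draw_lib_sizes(ns, p$lib_size_mean, p$lib_size_cv)
  comp <- stats::rlnorm(ns, -p$composition_sd^2 / 2, p$composition_sd)
  mean_log2cpm <- base + eff[, samples$condition, drop = FALSE] +
    batch_eff[, bi, drop = FALSE]
  counts <- nb_counts(mean_log2cpm, lib * comp, p$cc_dispersion)
  colnames(counts) <- samples$sample_id

  truth <- data.frame(region_id = regions$id, cluster = cluster,
                      baseline_log2cpm = base, stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(profile))
  rownames(truth) <- NULL
  list(regions = regions, samples = samples, counts = counts, truth = truth)
}

#' Simulate the degron inhibitor time course
#'
#' Emulates ATAC libraries collected at increasing times of
#' auxin-induced factor degradation: responsive regions' mean
#' accessibility decays as `m(t) = (m0 - c) exp(-b t) + c` with plateau
#' `c = plateau_fraction * m0`; non-responsive regions stay constant.
#' Counts are negative-binomial around the decayed means.
#'
#' @param p a [sim_params()] object (`decay_rate`, `plateau_fraction`,
#'   `responsive_frac`, `nb_dispersion`, `n_replicates` are used).
#' @param times sampling times in hours, increasing from 0 (default
#'   `c(0, 0.5, 1, 2, 3, 4, 6, 10)`).
#' @return List with `regions`, `samples` (with `time_hr`), `counts`,
#'   `truth` (per-region `responsive`, `rate`, `plateau`).
#' @export
simulate_timecourse <- function(p = sim_params(),
                                times = c(0, 0.5, 1, 2, 3, 4, 6, 10)) {
  stopifnot(inherits(p, "sim_params"))
  if (is.unsorted(times, strictly = TRUE) || times[1] != 0)
    stop("times must be strictly increasing and start at 0")
  set.seed(p$seed + 2L)
  n <- p$n_regions
  regions <- place_regions(n)
  responsive <- stats::runif(n) < p$responsive_frac
  base <- stats::rnorm(n, p$baseline_mean, p$baseline_sd)

  conditions <- paste0("t", times)
  samples <- expand.grid(replicate_batch = paste0("b", seq_len(p$n_replicates)),
                         condition = conditions, stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = paste(samples$condition, samples$replicate_batch, sep = "."),
    condition = samples$condition,
    replicate_batch = samples$replicate_batch,
    time_hr = rep(times, each = p$n_replicates),
    stringsAsFactors = FALSE)
  ns <- nrow(samples)

  # decay factor on the natural scale, applied to responsive regions
  decay <- p$plateau_fraction +
    (1 - p$plateau_fraction) * exp(-p$decay_rate * samples$time_hr)
  logfc <- outer(as.numeric(responsive), log2(decay))
  lib <- draw_lib_sizes(ns, p$lib_size_mean, p$lib_size_cv)
  comp <- stats::rlnorm(ns, -p$composition_sd^2 / 2, p$composition_sd)
  mean_log2cpm <- base + logfc
  dimnames(mean_log2cpm) <- list(regions$id, samples$sample_id)
  counts <- nb_counts(mean_log2cpm, lib * comp, p$nb_dispersion)

  truth <- data.frame(region_id = regions$id, responsive = responsive,
                      rate = ifelse(responsive, p$decay_rate, NA_real_),
                      plateau = ifelse(responsive, p$plateau_fraction, NA_real_),
                      baseline_log2cpm = base, stringsAsFactors = FALSE)
  list(regions = regions, samples = samples, counts = counts, truth = truth)
}

#' Simulate single-cell fluorescence degradation traces
#'
#' Emulates time-lapse imaging of a fluorescently tagged degron fusion
#' after inducer addition: each cell's background-subtracted signal
#' follows `y_i(t) = A_i exp(-b t) (1 + eps)` with cell-specific
#' amplitude `A_i` (log-normal) and i.i.d. multiplicative Gaussian noise
#' of coefficient of variation `trace_noise_cv`.
#'
#' @param p a [sim_params()] object (`trace_*`, `n_cells` fields used).
#' @return List with `traces` (data frame `time_hr`, `signal`, `cell`)
#'   and `truth` (`rate`, per-cell amplitudes).
#' @export
simulate_traces <- function(p = sim_params()) {
  stopifnot(inherits(p, "sim_params"))
  if (p$n_cells < 1) stop("n_cells must be >= 1")
  set.seed(p$seed + 3L)
  times <- seq(0, p$trace_duration, by = p$trace_interval)
  sdlog <- sqrt(log(1 + 0.3^2))
  amp <- stats::rlnorm(p$n_cells, log(1000) - sdlog^2 / 2, sdlog)
  traces <- do.call(rbind, lapply(seq_len(p$n_cells), function(i) {
    eps <- stats::rnorm(length(times), 0, p$trace_noise_cv)
    data.frame(time_hr = times,
               signal = amp[i] * exp(-p$trace_rate * times) * (1 + eps),
               cell = sprintf("cell_%02d", i))
  }))
  list(traces = traces,
       truth = list(rate = p$trace_rate, half_life = log(2) / p$trace_rate,
                    amplitudes = amp))
}

#' Write a simulated depletion experiment to disk
#'
#' Emits the plain-text files the pipeline consumes: `regions.bed`,
#' `oct4_peaks.bed`, `sox2_peaks.bed`, `counts.tsv`, `samples.tsv`,
#' `truth.tsv`.
#'
#' @param sim result of [simulate_depletion_experiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(sim$regions, file.path(dir, "regions.bed"))
  write_bed(sim$oct4_peaks, file.path(dir, "oct4_peaks.bed"))
  write_bed(sim$sox2_peaks, file.path(dir, "sox2_peaks.bed"))
  write_count_table(sim$counts, file.path(dir, "counts.tsv"))
  write_sample_sheet(sim$samples, file.path(dir, "samples.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
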