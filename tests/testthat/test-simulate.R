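test_that("simulation parameters are validated", {
  expect_error(sim_params(class_proportions = c(OD = 0.5, SD = 0.1, CD = 0.1,
                                                gained = 0.1, null = 0.1)),
               "sum to 1")
  expect_error(sim_params(nb_dispersion = 0), "positive")
  expect_s3_class(sim_params(), "sim_params")
})

test_that("depletion simulation has the documented structure and truth", {
  p <- sim_params(n_regions = 800, seed = 301)
  sim <- simulate_depletion_experiment(p)
  expect_equal(nrow(sim$regions), 800)
  expect_equal(dim(sim$counts), c(800, 7 * p$n_replicates))
  expect_equal(rownames(sim$counts), sim$regions$id)
  expect_equal(colnames(sim$counts), sim$samples$sample_id)
  expect_true(all(sim$counts >= 0) && all(sim$counts == round(sim$counts)))
  expect_equal(as.vector(table(sim$truth$class)[c("OD", "SD", "CD")]),
               as.vector(round(800 * p$class_proportions[c("OD", "SD", "CD")])))
  # regions do not overlap and respect the toy genome
  expect_equal(nrow(merge_intervals(sim$regions)), nrow(sim$regions))

  # identical seed -> identical output; different seed -> different counts
  sim2 <- simulate_depletion_experiment(sim_params(n_regions = 800, seed = 301))
  expect_identical(sim$counts, sim2$counts)
  sim3 <- simulate_depletion_experiment(sim_params(n_regions = 800, seed = 302))
  expect_false(identical(sim$counts, sim3$counts))
})

test_that("simulated counts satisfy the NB moment identity", {
  # var = mu + phi mu^2 at high mean
  p <- sim_params(seed = 303)
  set.seed(303)
  mu <- 200; phi <- 0.05
  draws <- rnbinom(1e4, size = 1 / phi, mu = mu)
  expect_equal(mean(draws), mu, tolerance = 0.02)
  expect_equal(var(draws), mu + phi * mu^2, tolerance = 0.1)

  # in the generator itself: a null region's counts across samples
  pn <- sim_params(n_regions = 2000,
                   class_proportions = c(OD = 0, SD = 0, CD = 0,
                                         gained = 0, null = 1),
                   baseline_shift_prop = 0, composition_sd = 0,
                   lib_size_cv = 0, batch_sd = 0, seed = 304)
  sim <- simulate_depletion_experiment(pn)
  cpm <- sweep(sim$counts, 2, colSums(sim$counts), "/") * 1e6
  disp <- apply(cpm, 1, var) / rowMeans(cpm)^2 - 1 / rowMeans(sim$counts)
  expect_equal(median(disp[rowMeans(sim$counts) > 100]), pn$nb_dispersion,
               tolerance = 0.35)
})

test_that("planted ChIP overlap rates are recovered by the overlap report", {
  p <- sim_params(n_regions = 4000, seed = 305)
  sim <- simulate_depletion_experiment(p)
  sd_regions <- subset_by_id(sim$regions,
                             sim$truth$region_id[sim$truth$class == "SD"])
  od_regions <- subset_by_id(sim$regions,
                             sim$truth$region_id[sim$truth$class == "OD"])
  # binomial error at n ~ 120-400 planted sites
  expect_equal(overlap_fraction(sd_regions, sim$oct4_peaks), 0.89,
               tolerance = 0.08)
  expect_equal(overlap_fraction(od_regions, sim$sox2_peaks), 0.65,
               tolerance = 0.08)
  expect_equal(overlap_fraction(od_regions, sim$oct4_peaks), 1.0)
})

test_that("cell-cycle simulation plants the four template profiles", {
  p <- sim_params(n_regions = 600, seed = 306)
  sim <- simulate_cellcycle_experiment(p)
  expect_equal(sort(unique(sim$truth$cluster)), 1:4)
  # cluster 4 template: no effect in any phase
  c4 <- sim$truth[sim$truth$cluster == 4, c("EG1", "LG1", "S", "SG2")]
  expect_equal(mean(as.matrix(c4)), 0, tolerance = 0.05)
  # cluster 1 loses more in EG1 than cluster 2, by construction
  expect_lt(mean(sim$truth$EG1[sim$truth$cluster == 1]),
            mean(sim$truth$EG1[sim$truth$cluster == 2]))
  expect_equal(ncol(sim$counts), 8 * p$n_replicates)
})

test_that("time-course simulation decays toward the plateau", {
  p <- sim_params(n_regions = 500, seed = 307)
  sim <- simulate_timecourse(p)
  expect_true(all(c("time_hr") %in% names(sim$samples)))
  # noiseless mean model: fitted rate equals the planted rate
  t <- c(0, 0.5, 1, 2, 3, 4)
  m <- (1 - p$plateau_fraction) * exp(-p$decay_rate * t) + p$plateau_fraction
  fit <- fit_exponential_decay(t, m)
  expect_equal(fit$b, p$decay_rate, tolerance = 1e-6)
  # plateau 0 -> signal vanishes at late times
  m0 <- exp(-p$decay_rate * c(0, 5, 10))
  expect_lt(m0[3], 1e-5)
  # responsive regions lose counts, non-responsive do not
  late <- sim$samples$time_hr == 10
  early <- sim$samples$time_hr == 0
  ratio <- rowMeans(sim$counts[, late]) / pmax(1, rowMeans(sim$counts[, early]))
  expect_lt(median(ratio[sim$truth$responsive]), 0.5)
  expect_gt(median(ratio[!sim$truth$responsive]), 0.7)
  expect_error(simulate_timecourse(p, times = c(1, 2)), "start at 0")
})

test_that("simulated files round-trip through the package readers", {
  p <- sim_params(n_regions = 300, seed = 308)
  sim <- simulate_depletion_experiment(p)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  regions <- read_bed(file.path(dir, "regions.bed"))
  expect_equal(regions$id, sim$regions$id)
  expect_equal(regions$start, sim$regions$start)
  counts <- read_count_table(file.path(dir, "counts.tsv"))
  expect_equal(counts, sim$counts + 0, ignore_attr = TRUE)
  expect_equal(rownames(counts), rownames(sim$counts))
  samples <- read_sample_sheet(file.path(dir, "samples.tsv"))
  expect_equal(samples$sample_id, sim$samples$sample_id)
})
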