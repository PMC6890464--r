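two_group_design <- function(n_per = 3) {
  samples <- data.frame(
    sample_id = sprintf("s%d", seq_len(2 * n_per)),
    condition = rep(c("ctrl", "trt"), each = n_per),
    replicate_batch = rep("b1", 2 * n_per))
  make_design(samples)
}

test_that("design matrix has one column per condition plus batch indicators", {
  samples <- data.frame(sample_id = sprintf("s%d", 1:8),
                        condition = rep(c("A", "B"), 4),
                        replicate_batch = rep(c("b1", "b2"), each = 4))
  X <- make_design(samples)
  expect_equal(colnames(X), c("A", "B", "batch_b2"))
  expect_equal(unname(rowSums(X[, c("A", "B")])), rep(1, 8))

  # condition confounded with batch -> rank deficiency reported
  bad <- data.frame(sample_id = sprintf("s%d", 1:4),
                    condition = c("A", "A", "B", "B"),
                    replicate_batch = c("b1", "b1", "b2", "b2"))
  expect_error(make_design(bad), "rank deficient")
})

test_that("OLS reproduces condition means and exact residual identities", {
  X <- two_group_design(2)
  y <- matrix(c(1, 1, 5, 5,
                2, 4, 1, 9), nrow = 2, byrow = TRUE)
  fit <- fit_linear_model(y, X)
  # duplicate values within condition: zero residual variance, beta = means
  expect_equal(unname(fit$coefficients[1, ]), c(1, 5))
  expect_equal(fit$sigma2[[1]], 0)
  expect_equal(fit$df_residual, 2)
  # fitted + residuals reconstruct the input
  fitted <- fit$coefficients %*% t(X)
  expect_equal(unname(fitted[2, ] + (y[2, ] - fitted[2, ])), y[2, ])
})

test_that("OLS estimates are unbiased under simulated Gaussian noise", {
  set.seed(61)
  X <- two_group_design(3)
  beta <- c(ctrl = 2, trt = 3.5)
  y <- matrix(rnorm(1000 * 6, mean = rep(X %*% beta, each = 1000), sd = 1),
              1000, 6)
  fit <- fit_linear_model(y, X)
  expect_equal(unname(colMeans(fit$coefficients)), unname(beta),
               tolerance = 0.05)
})

test_that("empirical-Bayes moderation matches limma and its formula limits", {
  skip_if_not_installed("limma")
  set.seed(62)
  X <- two_group_design(3)
  y <- matrix(rnorm(3000 * 6, sd = sqrt(rchisq(3000, 4) / 4)), 3000)
  y[1:150, 4:6] <- y[1:150, 4:6] + 2
  fit <- ebayes_moderate(fit_linear_model(y, X))
  res <- contrast_fit(fit, "trt", "ctrl")

  lf <- limma::lmFit(y, X)
  lf <- limma::eBayes(limma::contrasts.fit(
    lf, limma::makeContrasts(trt - ctrl, levels = X)))
  expect_equal(fit$d0, lf$df.prior, tolerance = 1e-10)
  expect_equal(fit$s0sq, lf$s2.prior, tolerance = 1e-10)
  expect_equal(res$t, unname(lf$t[, 1]), tolerance = 1e-12)
  expect_equal(res$p, unname(lf$p.value[, 1]), tolerance = 1e-12)

  # complete-shrinkage limit: equal variances force infinite prior df
  same <- matrix(rnorm(50 * 6), 50)
  f2 <- fit_linear_model(same, X)
  f2$sigma2 <- rep(f2$sigma2[1], 50)
  eb2 <- ebayes_moderate(f2)
  expect_true(is.infinite(eb2$d0))
  expect_equal(unname(eb2$sigma2_moderated), rep(eb2$s0sq, 50))

  expect_error(ebayes_moderate(structure(list(sigma2 = rep(0, 40),
                                              df_residual = 4),
                                         class = "acc_fit")),
               "degenerate")
})

test_that("prior recovery from the scaled-F variance model", {
  set.seed(63)
  n <- 10000; dg <- 3; d0 <- 4; s0sq <- 1
  s2 <- s0sq * (rchisq(n, dg) / dg) * (d0 / rchisq(n, d0))
  eb <- ebayes_moderate(structure(list(sigma2 = s2, df_residual = dg),
                                  class = "acc_fit"))
  expect_lt(abs(eb$d0 - d0) / d0, 0.25)
  expect_lt(abs(eb$s0sq - s0sq) / s0sq, 0.10)
})

test_that("BH FDR matches its hand-computed and brute-force values", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(64)
  for (i in 1:5) {
    p <- runif(sample(10:500, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), oracle_bh(p))
    expect_equal(bh_fdr(p), p.adjust(p, "BH"))  # independent reference
    # q >= p and order invariance
    expect_true(all(bh_fdr(p) >= p))
    perm <- sample(length(p))
    expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  }
})

test_that("contrasts behave under self-contrast and direction swap", {
  set.seed(65)
  X <- two_group_design(3)
  y <- matrix(rnorm(200 * 6), 200)
  fit <- ebayes_moderate(fit_linear_model(y, X))
  self <- contrast_fit(fit, "trt", "trt")
  expect_equal(self$log2FC, rep(0, 200))
  expect_equal(self$p, rep(1, 200))

  fwd <- contrast_fit(fit, "trt", "ctrl")
  rev <- contrast_fit(fit, "ctrl", "trt")
  expect_equal(fwd$log2FC, -rev$log2FC)
  expect_equal(fwd$p, rev$p)
  expect_error(contrast_fit(fit, "nope", "ctrl"), "available")
})

test_that("a planted depletion effect is detected with high power", {
  # OD-like regions (true log2FC -1.5, NB dispersion 0.05, 2 replicates
  # per condition) under the two-comparison detection rule the
  # classifier uses: significant in at least one of the two depletion
  # contrasts with a consistent negative direction in both
  p <- sim_params(n_regions = 2000,
                  class_proportions = c(OD = 0.25, SD = 0, CD = 0,
                                        gained = 0, null = 0.75),
                  baseline_shift_prop = 0, seed = 66)
  sim <- simulate_depletion_experiment(p)
  norm <- tmm_factors(sim$counts)
  fit <- ebayes_moderate(fit_linear_model(log2_cpm(sim$counts, norm),
                                          make_design(sim$samples)))
  res_sl <- contrast_fit(fit, "ZHBTc4_SL_dox", "ZHBTc4_SL_untr")
  res_s2 <- contrast_fit(fit, "ZHBTc4_S2iL_dox", "ZHBTc4_S2iL_untr")
  cs <- consistent_changes(res_sl, res_s2, fdr = 0.05, mode = "any")
  od_ids <- sim$truth$region_id[sim$truth$class == "OD"]
  expect_gte(mean(od_ids %in% cs$decreased), 0.9)
  # single-contrast detection is necessarily weaker but still substantial
  od <- sim$truth$class == "OD"
  expect_gte(mean(res_s2$q[od] < 0.05 & res_s2$log2FC[od] < 0), 0.7)
})
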