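#' Build a no-intercept condition + batch design matrix
#'
#' One indicator column per condition plus indicator columns for replicate
#' batches (first batch as reference), i.e. the `~ 0 + Condition +
#' Replicate` parameterization used for paired depletion designs. When
#' only one batch is present the batch columns are omitted
#' (`~ 0 + Condition`).
#'
#' @param samples sample sheet data frame with `condition` and
#'   `replicate_batch` columns; row order defines sample order.
#' @param batch logical; include replicate-batch columns (default TRUE).
#' @return Numeric design matrix with named columns; condition columns
#'   carry the condition name, batch columns are prefixed `"batch_"`.
#' @export
make_design <- function(samples, batch = TRUE) {
  cond <- factor(samples$condition)
  X <- stats::model.matrix(~ 0 + cond)
  colnames(X) <- levels(cond)
  if (batch && length(unique(samples$replicate_batch)) > 1L) {
    b <- factor(samples$replicate_batch)
    Xb <- stats::model.matrix(~b)[, -1, drop = FALSE]
    colnames(Xb) <- paste0("batch_", levels(b)[-1])
    X <- cbind(X, Xb)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; confounded column(s): ",
         paste(dropped, collapse = ", "))
  }
  rownames(X) <- samples$sample_id
  X
}

#' Per-region ordinary least squares fit
#'
#' Fits the same linear model to every region (row) of a log2-CPM matrix:
#' coefficient estimates, residual variance `s2 = RSS / df`, residual
#' degrees of freedom, and the unscaled coefficient covariance
#' `(X'X)^-1` shared across regions.
#'
#' @param logcpm region-by-sample real matrix (e.g. from [log2_cpm()]).
#' @param design design matrix from [make_design()]; must have more rows
#'   than columns and full column rank.
#' @return An object of class `acc_fit`: list with `coefficients`
#'   (regions x coefficients), `sigma2`, `df_residual`, `cov_unscaled`,
#'   `ave_log2cpm`, `design`.
#' @export
fit_linear_model <- function(logcpm, design) {
  logcpm <- as.matrix(logcpm)
  if (nrow(design) != ncol(logcpm))
    stop("design rows must match logcpm columns")
  if (is.null(rownames(logcpm)))
    rownames(logcpm) <- sprintf("region_%05d", seq_len(nrow(logcpm)))
  p <- ncol(design)
  n <- nrow(design)
  if (n <= p) stop("need more samples than coefficients")
  qrX <- qr(design)
  if (qrX$rank < p) {
    dropped <- colnames(design)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; confounded column(s): ",
         paste(dropped, collapse = ", "))
  }
  cov_unscaled <- chol2inv(chol(crossprod(design)))
  dimnames(cov_unscaled) <- list(colnames(design), colnames(design))
  beta <- t(qr.coef(qrX, t(logcpm)))
  colnames(beta) <- colnames(design)
  fitted <- beta %*% t(design)
  rss <- rowSums((logcpm - fitted)^2)
  df <- n - p
  structure(list(coefficients = beta,
                 sigma2 = rss / df,
                 df_residual = df,
                 cov_unscaled = cov_unscaled,
                 ave_log2cpm = rowMeans(logcpm),
                 design = design),
            class = "acc_fit")
}

# Inverse of the trigamma function by Newton iteration on
# trigamma(x) = target, solved on x > 0.
trigamma_inverse <- function(target, start = 5, tol = 1e-8, maxit = 50) {
  if (target <= 0) return(Inf)
  x <- start
  for (i in seq_len(maxit)) {
    f <- trigamma(x) - target
    step <- f / psigamma(x, deriv = 2)
    x_new <- x - step
    if (x_new <= 0) x_new <- x / 2
    if (abs(x_new - x) < tol * x) return(x_new)
    x <- x_new
  }
  warning("trigamma inverse did not converge; treating prior df as infinite")
  Inf
}

#' Empirical-Bayes variance moderation
#'
#' Estimates a scaled inverse-chi-square prior (`d0`, `s0^2`) for the
#' per-region residual variances by moment matching on `e_g = log(s_g^2) -
#' digamma(d_g/2) + log(d_g/2)`: `trigamma(d0/2) = var(e) -
#' trigamma(d_g/2)` (Newton on the trigamma inverse) and `s0^2 =
#' exp(mean(e) + digamma(d0/2) - log(d0/2))`. If `var(e) <=
#' trigamma(d_g/2)` the prior df is infinite and every moderated variance
#' equals `s0^2`. Moderated variances are `(d0 s0^2 + d_g s_g^2) / (d0 +
#' d_g)`.
#'
#' @param fit an `acc_fit` from [fit_linear_model()].
#' @return The fit augmented with `d0`, `s0sq`, `sigma2_moderated` and
#'   `df_total` (class `acc_fit_eb`).
#' @export
ebayes_moderate <- function(fit) {
  if (!inherits(fit, "acc_fit")) stop("fit must come from fit_linear_model")
  s2 <- fit$sigma2
  d <- fit$df_residual
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) stop("all residual variances are zero; data are degenerate")
  if (sum(ok) < 30)
    warning("fewer than 30 regions with positive residual variance; ",
            "prior estimates may be unstable")
  e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
  ve <- stats::var(e)
  target <- ve - trigamma(d / 2)
  if (is.na(target) || target <= 0) {
    d0 <- Inf
    s0sq <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(target)
    s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  s2_mod <- if (is.infinite(d0)) rep(s0sq, length(s2)) else
    (d0 * s0sq + d * s2) / (d0 + d)
  out <- fit
  out$d0 <- d0
  out$s0sq <- s0sq
  out$sigma2_moderated <- s2_mod
  out$df_total <- d0 + d
  class(out) <- c("acc_fit_eb", "acc_fit")
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: on sorted p-values, `q_(i) = min_{j >= i}
#' min(1, p_(j) * m / j)`, returned in the original order.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] and contain no NA")
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[ord] * m / (m:1)))
  q[order(ord)]
}

#' Moderated contrast between two condition coefficients
#'
#' Computes `log2FC = beta_a - beta_b`, its moderated t statistic using
#' the empirical-Bayes variances, a two-sided p-value on `d0 + d_g`
#' degrees of freedom, and BH-adjusted FDR across all regions.
#'
#' @param fit an `acc_fit_eb` from [ebayes_moderate()].
#' @param numerator,denominator coefficient (condition) names; the
#'   contrast is numerator minus denominator. When `denominator` is
#'   `NULL` the single coefficient is tested against zero.
#' @return A `diff_result` data frame: `region_id`, `log2FC`, `t`, `p`,
#'   `q`, `mean_log2cpm`.
#' @export
contrast_fit <- function(fit, numerator, denominator = NULL) {
  if (!inherits(fit, "acc_fit_eb"))
    stop("fit must be moderated first (see ebayes_moderate)")
  cn <- colnames(fit$coefficients)
  for (nm in c(numerator, denominator))
    if (!nm %in% cn)
      stop("unknown coefficient '", nm, "'; available: ",
           paste(cn, collapse = ", "))
  cvec <- stats::setNames(numeric(length(cn)), cn)
  cvec[numerator] <- cvec[numerator] + 1
  if (!is.null(denominator)) cvec[denominator] <- cvec[denominator] - 1
  lfc <- drop(fit$coefficients %*% cvec)
  vc <- drop(t(cvec) %*% fit$cov_unscaled %*% cvec)
  if (vc <= 0) {
    # contrast of a coefficient with itself: no variance, no effect
    tstat <- rep(0, length(lfc))
    p <- rep(1, length(lfc))
  } else {
    tstat <- lfc / sqrt(vc * fit$sigma2_moderated)
    p <- 2 * stats::pt(-abs(tstat), df = fit$df_total)
  }
  res <- data.frame(region_id = rownames(fit$coefficients),
                    log2FC = lfc, t = tstat, p = p, q = bh_fdr(p),
                    mean_log2cpm = fit$ave_log2cpm,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("diff_result", "data.frame")
  res
}

#' Write / read a differential-accessibility result table
#'
#' @param res a `diff_result` data frame.
#' @param path TSV path.
#' @export
write_diff_result <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diff_result
#' @export
read_diff_result <- function(path) {
  res <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("region_id", "log2FC", "t", "p", "q")
  if (!all(req %in% names(res)))
    stop("diff result must contain columns: ", paste(req, collapse = ", "))
  class(res) <- c("diff_result", "data.frame")
  res
}
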