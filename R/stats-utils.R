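#' Normality-gated two-sample test
#'
#' Implements the testing policy used throughout the analyses: each
#' sample is screened with the Shapiro-Wilk test; if either has
#' `p < 0.05` a non-parametric test is used (Wilcoxon signed-rank when
#' the samples are matched and `n >= 5`, otherwise Mann-Whitney U), and
#' otherwise a t-test (paired when matched, Welch unequal-variance when
#' not). All tests are two-tailed.
#'
#' Degenerate matched data (all pairwise differences zero) are reported
#' with `p = 1` and statistic 0, since no test can be computed.
#'
#' @param x,y numeric vectors, each of length >= 3; equal lengths
#'   required when `matched = TRUE`.
#' @param matched logical; were the observations paired?
#' @param alpha normality-screen level (default 0.05).
#' @return A `test_report`: list with `test_name` (`"t"`,
#'   `"mann_whitney"` or `"wilcoxon_signed_rank"`), `paired`, `p`,
#'   `statistic`, `normality_p` (length-2 vector).
#' @export
select_and_test <- function(x, y, matched = FALSE, alpha = 0.05) {
  if (length(x) < 3L || length(y) < 3L) stop("each sample needs >= 3 values")
  if (matched && length(x) != length(y))
    stop("matched samples must have equal length")
  sw <- c(x = stats::shapiro.test(x)$p.value,
          y = stats::shapiro.test(y)$p.value)
  nonparam <- any(sw < alpha)
  if (matched && all(x == y)) {
    test_name <- if (nonparam) "wilcoxon_signed_rank" else "t"
    return(structure(list(test_name = test_name, paired = TRUE, p = 1,
                          statistic = 0, normality_p = sw),
                     class = "test_report"))
  }
  if (nonparam) {
    use_signed_rank <- matched && length(x) >= 5L
    if (use_signed_rank) {
      ht <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)
      test_name <- "wilcoxon_signed_rank"
      paired <- TRUE
    } else {
      ht <- stats::wilcox.test(x, y, paired = FALSE,
                               exact = length(x) <= 50 && length(y) <= 50)
      test_name <- "mann_whitney"
      paired <- FALSE
    }
  } else {
    ht <- stats::t.test(x, y, paired = matched, var.equal = FALSE)
    test_name <- "t"
    paired <- matched
  }
  structure(list(test_name = test_name, paired = paired,
                 p = unname(ht$p.value), statistic = unname(ht$statistic),
                 normality_p = sw),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("%s test (%s): statistic = %.4g, p = %.4g\n",
              x$test_name, if (x$paired) "paired" else "unpaired",
              x$statistic, x$p))
  invisible(x)
}

#' Fisher's exact test on a 2x2 enrichment table
#'
#' Two-sided exact test (hypergeometric) with the conditional
#' maximum-likelihood odds ratio, as used for comparing the number of
#' regions in a category of interest between two groups. A zero cell
#' yields an infinite or zero odds-ratio estimate, flagged in the result.
#'
#' @param table 2x2 matrix (or 4-vector, column-major) of non-negative
#'   integer counts with at least one positive margin.
#' @return List with `odds_ratio`, `p`, `degenerate` (TRUE when the
#'   odds-ratio estimate is 0 or infinite).
#' @export
fisher_enrichment <- function(table) {
  m <- matrix(as.numeric(table), 2, 2)
  if (any(is.na(m)) || any(m < 0)) stop("counts must be non-negative")
  if (any(m != round(m))) stop("counts must be integers")
  if (sum(m) == 0) stop("at least one margin must be positive")
  ht <- stats::fisher.test(m, alternative = "two.sided")
  or <- unname(ht$estimate)
  list(odds_ratio = or, p = unname(ht$p.value),
       degenerate = !is.finite(or) || or == 0)
}

#' Z-transform enrichment scores within categories
#'
#' Standardizes user-supplied enrichment scores (e.g. -log10 p-values)
#' within each annotation category: `z = (score - mean) / sd` per
#' category. Categories with zero spread get all-zero z-scores with a
#' warning; singleton categories are an error.
#'
#' @param scores numeric vector of enrichment scores, one per term.
#' @param category vector (same length) assigning each term to a
#'   category.
#' @return Numeric vector of z-scores in the input order, named like
#'   `scores` when it has names.
#' @export
zscore_within_category <- function(scores, category) {
  if (length(scores) != length(category))
    stop("scores and category must have the same length")
  sizes <- table(category)
  if (any(sizes < 2L))
    stop("singleton category: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  z <- numeric(length(scores))
  for (cat in unique(category)) {
    idx <- which(category == cat)
    s <- stats::sd(scores[idx])
    if (s == 0) {
      warning("category '", cat, "' has zero spread; z set to 0")
      z[idx] <- 0
    } else {
      z[idx] <- (scores[idx] - mean(scores[idx])) / s
    }
  }
  names(z) <- names(scores)
  z
}
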