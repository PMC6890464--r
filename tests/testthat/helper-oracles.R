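# Brute-force oracles, independent of the implementation paths they check.

# Merge by marking covered bases (plus bridged gaps) on a logical array.
oracle_merge <- function(x, gap = 0) {
  out <- list()
  for (chrom in sort(unique(x$chrom))) {
    s <- x[x$chrom == chrom, ]
    lim <- max(s$end) + gap + 2
    covered <- logical(lim)
    for (i in seq_len(nrow(s))) covered[(s$start[i] + 1):s$end[i]] <- TRUE
    if (gap > 0) { # bridge gaps of length <= gap between covered runs
      r <- rle(covered)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (j in seq_along(r$values))
        if (!r$values[j] && r$lengths[j] <= gap &&
            j > 1 && j < length(r$values))
          covered[starts[j]:ends[j]] <- TRUE
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    if (length(keep))
      out[[chrom]] <- data.frame(chrom = chrom, start = starts[keep] - 1,
                                 end = ends[keep])
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# All-pairs overlap test (half-open intervals).
oracle_overlaps_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

# All-pairs nearest TSS: distance 0 inside, else bases between; ties to
# the smaller TSS coordinate.
oracle_nearest <- function(regions, tss) {
  t(vapply(seq_len(nrow(regions)), function(i) {
    cand <- tss[tss$chrom == regions$chrom[i], ]
    if (nrow(cand) == 0L) return(c(NA_real_, NA_real_))
    pos <- cand$start
    d <- ifelse(pos >= regions$start[i] & pos < regions$end[i], 0,
                ifelse(pos < regions$start[i], regions$start[i] - pos - 1,
                       pos - regions$end[i]))
    j <- which(d == min(d))
    j <- j[which.min(pos[j])]
    c(d[j], pos[j])
  }, numeric(2)))
}

# BH step-up from first principles: sort, scale, cumulative min from the
# largest p down, cap at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[ord] <- pmin(1, q_sorted)
  q
}

# Two-sided Fisher exact p by full enumeration over tables with the
# observed margins.
oracle_fisher_p <- function(m) {
  a <- m[1, 1]; r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, function(x) {
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1)
  }, numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Plain-data.frame view of an interval_set's coordinates.
iv_df <- function(x) data.frame(chrom = x$chrom, start = x$start, end = x$end)

# Random interval_set on a compact coordinate range.
random_intervals <- function(n, max_pos = 1e5, max_len = 500, chroms = c("chrA", "chrB")) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  interval_set(sample(chroms, n, replace = TRUE), start, start + len,
               id = sprintf("iv%05d", seq_len(n)))
}
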