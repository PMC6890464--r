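#' Fit a three-parameter exponential decay
#'
#' Nonlinear least squares for `y = a * exp(-b * t) + c` with the rate
#' constrained positive through an internal log parameterization
#' (`b = exp(lb)`). Starting values are derived from the data: the offset
#' starts at `min(y) - 0.05 * range(y)` and a log-linear regression of
#' `y - c0` on `t` supplies the initial amplitude and rate. Data whose
#' initialization implies a non-positive rate (no decay) raise an error.
#'
#' @param times numeric vector of time points (hours), strictly
#'   increasing, at least 4 points spanning a positive range.
#' @param values matched numeric vector of signal (background-subtracted
#'   fluorescence, normalized accessibility, ...).
#' @param max_iter maximum optimizer iterations (default 500).
#' @return A `decay_fit`: list with `a`, `b` (per hour), `c`,
#'   `half_life` (`log(2)/b`, hours), `rss`, `converged`, `n_points`,
#'   `fitted`.
#' @export
fit_exponential_decay <- function(times, values, max_iter = 500L) {
  if (length(times) != length(values)) stop("times and values lengths differ")
  ok <- is.finite(times) & is.finite(values)
  times <- times[ok]; values <- values[ok]
  if (length(times) < 4L) stop("need at least 4 finite points")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (diff(range(times)) <= 0) stop("times must span a positive range")

  rng <- diff(range(values))
  if (rng == 0) stop("no decay detected: constant signal")
  c0 <- min(values) - 0.05 * rng
  z <- values - c0
  ll <- stats::lm(log(z) ~ times)
  b0 <- -unname(stats::coef(ll)[2])
  if (!is.finite(b0) || b0 <= 0) stop("no decay detected")
  a0 <- exp(unname(stats::coef(ll)[1]))

  residual_fn <- function(par)
    values - (par[1] * exp(-exp(par[2]) * times) + par[3])
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(a0, log(b0), c0), fn = residual_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = max_iter, ftol = 1e-12, ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) {
    a <- a0; b <- b0; cc <- c0
    converged <- FALSE
  } else {
    a <- fit$par[1]; b <- exp(fit$par[2]); cc <- fit$par[3]
    # info 1-3: ftol/ptol convergence; 5: iteration limit hit
    converged <- fit$info %in% 1:4
  }
  fitted <- a * exp(-b * times) + cc
  structure(list(a = a, b = b, c = cc,
                 half_life = half_life(b),
                 rss = sum((values - fitted)^2),
                 converged = converged,
                 n_points = length(times),
                 fitted = fitted),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay_fit: y = %.4g * exp(-%.4g t) + %.4g\n", x$a, x$b, x$c))
  cat(sprintf("  half-life %.3f hr | rss %.4g | %d points | converged: %s\n",
              x$half_life, x$rss, x$n_points, x$converged))
  invisible(x)
}

#' Half-life of an exponential decay
#'
#' `log(2) / b` for a first-order rate constant `b` (per hour).
#'
#' @param b positive rate constant.
#' @return Half-life in hours.
#' @export
half_life <- function(b) {
  if (!is.numeric(b) || any(b <= 0)) stop("rate constant must be positive")
  log(2) / b
}

#' Read a single-cell trace table
#'
#' Long-format TSV with columns `Time` (hours), `Signal`
#' (background-subtracted mean intensity), `Cell` (cell identifier) and
#' optionally `Treatment`; the layout of time-lapse source-data exports.
#'
#' @param path TSV (or CSV) path.
#' @param treatment optional value to filter the `Treatment` column on.
#' @return Data frame with columns `time_hr`, `signal`, `cell`.
#' @export
read_trace_table <- function(path, treatment = NULL) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  req <- c("time", "signal", "cell")
  if (!all(req %in% names(df)))
    stop("trace table must contain columns Time, Signal, Cell")
  if (!is.null(treatment)) {
    if (!"treatment" %in% names(df)) stop("no Treatment column to filter on")
    df <- df[df$treatment == treatment, ]
  }
  data.frame(time_hr = df$time, signal = df$signal, cell = df$cell,
             stringsAsFactors = FALSE)
}

#' Population-average decay fit of single-cell traces
#'
#' Averages the signal over cells at each time point, fits the
#' three-parameter exponential to the population average, and (optionally)
#' fits each cell individually.
#'
#' @param traces data frame with `time_hr`, `signal`, `cell` (see
#'   [read_trace_table()] / [simulate_traces()]).
#' @param per_cell also fit each single-cell trace (default FALSE).
#' @return List with `population` (a `decay_fit`), `mean_trace` (data
#'   frame `time_hr`, `signal`), and when requested `per_cell` (list of
#'   `decay_fit` by cell) with `per_cell_half_life` summary.
#' @export
fit_trace_halflife <- function(traces, per_cell = FALSE) {
  req <- c("time_hr", "signal", "cell")
  if (!all(req %in% names(traces)))
    stop("traces must contain columns time_hr, signal, cell")
  agg <- stats::aggregate(signal ~ time_hr, data = traces, FUN = mean)
  agg <- agg[order(agg$time_hr), ]
  pop <- fit_exponential_decay(agg$time_hr, agg$signal)
  out <- list(population = pop, mean_trace = agg)
  if (per_cell) {
    cells <- split(traces, traces$cell)
    fits <- lapply(cells, function(d) {
      d <- d[order(d$time_hr), ]
      tryCatch(fit_exponential_decay(d$time_hr, d$signal),
               error = function(e) NULL)
    })
    fits <- fits[!vapply(fits, is.null, logical(1))]
    out$per_cell <- fits
    out$per_cell_half_life <- vapply(fits, `[[`, numeric(1), "half_life")
  }
  out
}

#' Fit decay kinetics for each cluster time course
#'
#' Applies [fit_exponential_decay()] to every cluster of a
#' [cluster_timecourse()] result, restricted to `max_time` (clusters whose
#' signal does not decay are reported with an `NA` fit, mirroring loci
#' insensitive to factor loss).
#'
#' @param tc a `time_course_set` data frame.
#' @param max_time latest time point used for fitting (default 4 hr, the
#'   window before indirect effects dominate).
#' @return Named list of `decay_fit` (or `NULL` for non-decaying
#'   clusters), one per cluster.
#' @export
cluster_kinetics <- function(tc, max_time = 4) {
  stopifnot(all(c("cluster", "time_hr", "value") %in% names(tc)))
  tc <- tc[tc$time_hr <= max_time, ]
  out <- lapply(split(tc, tc$cluster), function(d) {
    d <- d[order(d$time_hr), ]
    tryCatch(fit_exponential_decay(d$time_hr, d$value),
             error = function(e) NULL)
  })
  out
}
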