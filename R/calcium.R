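#' Annotated recording trace
#'
#' A fluorescence (AU) or firing-rate (Hz) series with named analysis
#' windows. Windows are `(start, end)` pairs in seconds, interpreted as
#' half-open `[start, end)` when selecting samples.
#'
#' @param times_s strictly increasing sample times, seconds.
#' @param values finite sample values.
#' @param windows named list of `(start, end)` pairs; typically `baseline`,
#'   `response` (and `response2` for a second concentration step), `highK`.
#' @return An object of class `trace`.
#' @export
trace <- function(times_s, values, windows = list()) {
  times_s <- as.numeric(times_s); values <- as.numeric(values)
  if (length(times_s) != length(values) || length(times_s) < 2L)
    stop("times and values must be of equal length >= 2")
  if (any(diff(times_s) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(values))) stop("values must be finite")
  rng <- range(times_s)
  for (nm in names(windows)) {
    w <- windows[[nm]]
    if (length(w) != 2L || w[1] >= w[2])
      stop("window '", nm, "' must be an ordered (start, end) pair")
    if (w[1] < rng[1] - 1e-9 || w[2] > rng[2] + max(diff(times_s)) + 1e-9)
      stop("window '", nm, "' lies outside the recording")
  }
  structure(list(times_s = times_s, values = values, windows = windows),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("Trace: %d samples over [%g, %g] s; windows: %s\n",
              length(x$times_s), min(x$times_s), max(x$times_s),
              if (length(x$windows)) paste(names(x$windows), collapse = ", ")
              else "none"))
  invisible(x)
}

window_values <- function(tr, window) {
  if (is.character(window)) {
    if (!window %in% names(tr$windows))
      stop("trace has no window named '", window, "'")
    window <- tr$windows[[window]]
  }
  sel <- tr$times_s >= window[1] & tr$times_s < window[2]
  if (!any(sel)) stop("window [", window[1], ", ", window[2],
                      ") contains no samples")
  tr$values[sel]
}

window_bounds <- function(tr, window) {
  if (is.character(window)) tr$windows[[window]] else window
}

#' Photobleaching correction by baseline fit and subtraction
#'
#' Fits a mono-exponential-plus-constant model `c + a exp(-b t)` to the
#' samples of the baseline window (no agonist present), extends the fitted
#' trend over the whole recording, and subtracts it. If the exponential fit
#' fails to converge, a straight-line fit to the baseline is used instead.
#' After correction the baseline mean is approximately zero.
#'
#' @param tr a [trace()].
#' @param baseline_window window name or `(start, end)` seconds; needs at
#'   least 10 samples.
#' @return The corrected [trace()] (windows preserved), with attribute
#'   `"bleach_model"` naming the model used (`"exponential"` or `"linear"`).
#' @export
correct_bleaching <- function(tr, baseline_window = "baseline") {
  stopifnot(inherits(tr, "trace"))
  bw <- window_bounds(tr, baseline_window)
  sel <- tr$times_s >= bw[1] & tr$times_s < bw[2]
  if (sum(sel) < 10L)
    stop("baseline window must contain at least 10 samples, has ", sum(sel))
  tb <- tr$times_s[sel]; yb <- tr$values[sel]
  t0 <- tb[1]
  # exponential-plus-constant y = cc + a exp(-b (t - t0)), fitted by
  # Levenberg-Marquardt from several candidate rates (the rate is poorly
  # conditioned on short windows); best converged fit by RSS wins
  span <- max(diff(range(tb)), 1)
  a0 <- yb[1] - yb[length(yb)]
  resid_fn <- function(th) yb - (th[1] + th[2] * exp(-th[3] * (tb - t0)))
  best <- NULL
  for (b0 in c(0.2 / span, 1 / span, 5 / span, 1e-4)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(yb[length(yb)], a0, b0),
                         lower = c(-Inf, -Inf, 0), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$info %in% 1:3 &&
        (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (!is.null(best)) {
    th <- best$par
    trend <- th[1] + th[2] * exp(-th[3] * (tr$times_s - t0))
    model <- "exponential"
  } else {
    lf <- stats::lm(yb ~ tb)
    trend <- stats::coef(lf)[1] + stats::coef(lf)[2] * tr$times_s
    model <- "linear"
  }
  out <- trace(tr$times_s, tr$values - trend, tr$windows)
  attr(out, "bleach_model") <- model
  out
}

#' Windowed response quantification
#'
#' The response is the mean over the response window minus the mean over the
#' baseline window (the 4-minute intervals immediately before and at the end
#' of an agonist application); sigma is the sample SD of the baseline
#' samples.
#'
#' @param tr a [trace()].
#' @param baseline_window,response_window window names or `(start, end)`
#'   pairs in seconds; they must not overlap.
#' @return A list with `response` (mean difference), `sigma` (baseline SD),
#'   `baseline_mean`, `n_baseline`, `n_response`.
#' @export
quantify_response <- function(tr, baseline_window = "baseline",
                              response_window = "response") {
  stopifnot(inherits(tr, "trace"))
  bw <- window_bounds(tr, baseline_window)
  rw <- window_bounds(tr, response_window)
  if (max(bw[1], rw[1]) < min(bw[2], rw[2]))
    stop("baseline and response windows overlap")
  yb <- window_values(tr, bw)
  yr <- window_values(tr, rw)
  list(response = mean(yr) - mean(yb), sigma = stats::sd(yb),
       baseline_mean = mean(yb), n_baseline = length(yb),
       n_response = length(yr))
}

#' 3-sigma responder classification
#'
#' A cell is called a responder when its response is *strictly greater* than
#' `threshold_multiple` times the baseline standard deviation (the 3-sigma
#' criterion, a z-score of 3). A response of exactly `3 * sigma` is not a
#' responder. Negative responses (inhibition) are never called responders
#' unless `signed = TRUE`, in which case the criterion is applied to the
#' magnitude.
#'
#' @param response mean response (AU or Hz).
#' @param sigma baseline standard deviation, > 0.
#' @param threshold_multiple criterion multiple, default 3.
#' @param signed apply the criterion to `abs(response)`.
#' @return A list of class `response_call`: `z_score`, `responder`,
#'   `response_abs`, `threshold_multiple`.
#' @examples
#' classify_responder(3.5, 1)$responder   # TRUE
#' classify_responder(3.0, 1)$responder   # FALSE (strict)
#' @export
classify_responder <- function(response, sigma, threshold_multiple = 3,
                               signed = FALSE) {
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be > 0 (z-score undefined for a flat baseline)")
  z <- response / sigma
  crit <- if (signed) abs(z) else z
  structure(list(z_score = z, responder = crit > threshold_multiple,
                 response_abs = response,
                 threshold_multiple = threshold_multiple),
            class = "response_call")
}

#' @export
print.response_call <- function(x, ...) {
  cat(sprintf("%s (z = %.2f, threshold %g)\n",
              if (x$responder) "RESPONDER" else "non-responder",
              x$z_score, x$threshold_multiple))
  invisible(x)
}

#' Normalize a response to the high-K+ deflection
#'
#' Expresses a response as a percentage of the fluorescence evoked by high
#' (40 mM) potassium saline -- the fluorescence at maximal voltage-activated
#' calcium influx, a per-cell reference for indicator expression. Cells
#' without a positive high-K+ response lack a functional indicator readout
#' and are excluded (error).
#'
#' @param response response magnitude, AU.
#' @param highK_response high-K+ response magnitude, must be > 0.
#' @return `100 * response / highK_response` (percent).
#' @export
normalize_to_highK <- function(response, highK_response) {
  if (!is.finite(highK_response) || highK_response <= 0)
    stop("highK_response must be > 0; cell lacks a functional indicator ",
         "response and must be excluded")
  100 * response / highK_response
}

#' Population response with one-sample t-test
#'
#' Mean and SEM of the per-cell normalized responses, with a two-tailed
#' one-sample t-test against zero.
#'
#' @param normalized_responses numeric vector, n >= 2.
#' @return A list with `mean`, `sem`, `n`, `t`, `p`, `df`.
#' @export
population_response <- function(normalized_responses) {
  x <- as.numeric(normalized_responses)
  n <- length(x)
  if (n < 2L) stop("need at least two cells for a population test")
  m <- mean(x); s <- stats::sd(x); sem <- s / sqrt(n)
  if (s == 0) {
    tv <- if (m == 0) 0 else sign(m) * Inf
    pv <- if (m == 0) 1 else 0
  } else {
    tv <- m / sem
    pv <- 2 * stats::pt(-abs(tv), n - 1)
  }
  list(mean = m, sem = sem, n = n, t = tv, p = pv, df = n - 1)
}

#' Firing-rate responder classification
#'
#' Bins a spike-rate series into `bin_s`-second data points, takes the mean
#' and SD of the first `n_baseline_bins` points (24 bins of 10 s = the
#' 4-minute baseline), computes the change in frequency as the response-window
#' bin mean minus the baseline mean, and applies the strict 3-sigma
#' criterion.
#'
#' @param tr a [trace()] whose values are instantaneous firing rates (Hz),
#'   or already-binned rates at `bin_s` spacing.
#' @param response_window window name or `(start, end)` seconds.
#' @param bin_s bin width, seconds.
#' @param n_baseline_bins number of baseline data points, default 24.
#' @param threshold_multiple criterion multiple, default 3.
#' @return A list: `call` (a `response_call`), `delta_frequency` (Hz),
#'   `baseline_mean`, `baseline_sd`.
#' @export
classify_firing_responder <- function(tr, response_window = "response",
                                      bin_s = 10, n_baseline_bins = 24,
                                      threshold_multiple = 3) {
  stopifnot(inherits(tr, "trace"))
  t0 <- tr$times_s[1]
  bins <- floor((tr$times_s - t0) / bin_s)
  rate_bins <- tapply(tr$values, bins, mean)
  bin_start <- as.numeric(names(rate_bins)) * bin_s + t0
  if (length(rate_bins) < n_baseline_bins + 1L)
    stop("need at least ", n_baseline_bins, " baseline bins plus one ",
         "response bin, have ", length(rate_bins))
  base <- rate_bins[seq_len(n_baseline_bins)]
  rw <- window_bounds(tr, response_window)
  resp_sel <- bin_start >= rw[1] & bin_start < rw[2]
  if (!any(resp_sel)) stop("response window contains no bins")
  if (rw[1] < t0 + n_baseline_bins * bin_s)
    stop("response window overlaps the baseline bins")
  delta <- mean(rate_bins[resp_sel]) - mean(base)
  call <- classify_responder(delta, stats::sd(base), threshold_multiple)
  list(call = call, delta_frequency = delta, baseline_mean = mean(base),
       baseline_sd = stats::sd(base))
}

#' Population change-in-frequency test (Wilcoxon signed rank)
#'
#' Two-tailed one-sample Wilcoxon signed-rank test of the per-neuron
#' frequency changes against zero, the population test used for
#' firing-rate data.
#'
#' @param delta_frequencies numeric vector of per-neuron frequency changes.
#' @return A list with `median`, `n`, `V` (signed-rank statistic), `p`.
#' @export
population_delta_frequency <- function(delta_frequencies) {
  x <- as.numeric(delta_frequencies)
  if (length(x) < 2L) stop("need at least two neurons")
  wt <- stats::wilcox.test(x, mu = 0, alternative = "two.sided",
                           exact = FALSE, correct = TRUE)
  list(median = stats::median(x), n = length(x),
       V = unname(wt$statistic), p = wt$p.value)
}
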