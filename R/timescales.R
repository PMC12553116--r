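#' Biased sample autocorrelation function
#'
#' Autocorrelation at lags `0..max_lag` as the autocovariance divided by the
#' variance, both with divisor `N` (the biased estimator) and with the mean
#' taken once over the whole input. The biased form guarantees
#' `|acf[m]| <= 1` at every lag.
#'
#' @param series A [uniform_series()] or numeric vector (then `fs` applies).
#' @param max_lag Largest lag in samples; `1 <= max_lag <= N - 1`.
#' @param fs Sampling rate when `series` is a bare vector.
#' @return An `acf_result`: list with `acf` (length `max_lag + 1`, `acf[1]`
#'   is lag 0) and `fs`.
#' @examples
#' acf_biased(uniform_series(c(1, 2, 3, 4)), max_lag = 1)$acf  # 1, 0.25
#' @export
acf_biased <- function(series, max_lag, fs = 1) {
  x <- as_series_values(series)
  if (inherits(series, "uniform_series")) fs <- series$fs
  n <- length(x)
  if (max_lag < 1 || max_lag > n - 1)
    stop("`max_lag` must be between 1 and N - 1 = ", n - 1)
  if (var(x) == 0)
    stop("constant input: autocorrelation is undefined for zero variance")
  structure(list(acf = as.numeric(acf_biased_cpp(x, as.integer(max_lag))),
                 fs = fs),
            class = "acf_result")
}

#' @export
print.acf_result <- function(x, ...) {
  cat(sprintf("<acf_result> lags 0..%d @ %g Hz\n", length(x$acf) - 1, x$fs))
  invisible(x)
}

acw_threshold <- function(kind = c("acw0", "acw50", "acwe")) {
  switch(match.arg(kind), acw0 = 0, acw50 = 0.5, acwe = exp(-1))
}

#' Autocorrelation window (ACW)
#'
#' The first lag at which the ACF reaches or drops below a threshold: 0 for
#' ACW-0, 0.5 for ACW-50 and 1/e for ACW-e. Reported in seconds. When no
#' crossing occurs within the available lags the maximum lag is returned and
#' the result is flagged as censored.
#'
#' @param acf An `acf_result` from [acf_biased()].
#' @param kind One of `"acw0"`, `"acw50"`, `"acwe"`.
#' @param interpolate Return the continuous crossing point instead of the
#'   integer lag: log-linear interpolation between the bracketing lags when
#'   threshold and values are positive (exact for exponentially decaying
#'   ACFs), linear otherwise. Useful for parameter recovery against analytic
#'   timescales, which are not lag-quantized; the pipeline default is the
#'   plain first crossing.
#' @return Duration in seconds, with a logical attribute `censored`.
#' @examples
#' r <- structure(list(acf = c(1, 0.6, 0.2, -0.1), fs = 1), class = "acf_result")
#' acw(r, "acw0")   # 3 s
#' acw(r, "acw50")  # 2 s
#' @export
acw <- function(acf, kind = c("acw0", "acw50", "acwe"), interpolate = FALSE) {
  if (!inherits(acf, "acf_result") || length(acf$acf) < 2)
    stop("`acf` must be an acf_result with at least one positive lag")
  thr <- acw_threshold(kind)
  r <- acf$acf
  hit <- which(r[-1] <= thr)
  if (length(hit) > 0) {
    m <- hit[1]
    cross <- as.numeric(m)
    if (interpolate) {
      r_prev <- r[m]; r_m <- r[m + 1]  # r[1] is lag 0
      cross <- if (r_m > 0 && thr > 0 && r_prev > thr)
        (m - 1) + (log(r_prev) - log(thr)) / (log(r_prev) - log(r_m))
      else if (r_prev > r_m)
        (m - 1) + (r_prev - thr) / (r_prev - r_m)
      else as.numeric(m)
    }
    out <- cross / acf$fs
    attr(out, "censored") <- FALSE
  } else {
    out <- (length(r) - 1) / acf$fs
    attr(out, "censored") <- TRUE
  }
  out
}

#' Remove a least-squares linear trend
#'
#' Fits one line over the full series and subtracts it; the output is
#' mean-zero.
#'
#' @param series A [uniform_series()].
#' @return A detrended [uniform_series()].
#' @export
linear_detrend <- function(series) {
  stopifnot(inherits(series, "uniform_series"))
  x <- series$values
  t <- seq_along(x)
  fit <- stats::lm.fit(cbind(1, t), x)
  uniform_series(fit$residuals, fs = series$fs, t0 = series$t0)
}

#' Band-pass filter specification
#'
#' A zero-phase (forward-backward) Butterworth band-pass. The canonical
#' band for 1-Hz BOLD signals is 0.05-0.5 Hz with a third-order filter per
#' pass (effectively sixth-order).
#'
#' @param low_hz Lower passband edge in Hz.
#' @param high_hz Upper passband edge in Hz; at most the Nyquist frequency.
#'   When it equals Nyquist the filter reduces to a high-pass at `low_hz`.
#' @param order Filter order per pass.
#' @param zero_phase Apply forward and backward (doubling the order).
#' @return An object of class `bandpass_spec`.
#' @export
bandpass_spec <- function(low_hz = 0.05, high_hz = 0.5, order = 3,
                          zero_phase = TRUE) {
  if (!(low_hz > 0 && low_hz < high_hz))
    stop("need 0 < low_hz < high_hz")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order,
                 zero_phase = zero_phase),
            class = "bandpass_spec")
}

# Zero-phase filtering with odd (point-reflection) edge padding, so the
# forward and backward passes start near the local signal level rather than
# at zero. `pad` is clamped to n - 1.
filtfilt_padded <- function(b, a, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  ext <- c(left, x, right)
  y <- signal::filter(b, a, ext)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applied to the complete series before any windowing. With
#' `high_hz >= fs/2` (the Nyquist frequency) only the high-pass half is
#' applied, since the upper edge carries no constraint.
#'
#' @param series A [uniform_series()].
#' @param spec A [bandpass_spec()].
#' @return The filtered [uniform_series()].
#' @export
bandpass <- function(series, spec = bandpass_spec()) {
  stopifnot(inherits(series, "uniform_series"), inherits(spec, "bandpass_spec"))
  fs <- series$fs
  nyq <- fs / 2
  if (spec$high_hz > nyq + 1e-12)
    stop("high_hz = ", spec$high_hz, " Hz exceeds the Nyquist frequency ",
         nyq, " Hz")
  if (spec$high_hz >= nyq - 1e-12) {
    filt <- signal::butter(spec$order, spec$low_hz / nyq, type = "high")
  } else {
    filt <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / nyq,
                           type = "pass")
  }
  # padding long enough for the slow edge transient at the low cutoff
  pad <- max(3 * (spec$order * 2 + 1), ceiling(3 * fs / spec$low_hz))
  if (spec$zero_phase) {
    y <- filtfilt_padded(filt$b, filt$a, series$values, pad)
  } else {
    y <- as.numeric(signal::filter(filt$b, filt$a, series$values))
  }
  uniform_series(y, fs = fs, t0 = series$t0)
}

#' Sliding-window (dynamic) autocorrelation window
#'
#' For each window position the ACW of that window's slice, with
#' `max_lag = window length - 1`, indexed by window start time. Constant
#' slices yield a missing value; slices whose ACF never crosses the threshold
#' are censored at the maximum lag.
#'
#' @param series A [uniform_series()].
#' @param window A [window_spec()]; the window must be an integer number of
#'   samples.
#' @param kind ACW variant, as in [acw()].
#' @param interpolate Continuous crossing, as in [acw()].
#' @return A [dynamic_series()] of ACW values in seconds.
#' @examples
#' s <- gen_ar1(phi = 0.8, n = 300, seed = 1)
#' d <- dynamic_acw(s, window_spec(60, 1), "acw50")
#' mean(d$values)
#' @export
dynamic_acw <- function(series, window = window_spec(), kind = "acw0",
                        interpolate = FALSE) {
  stopifnot(inherits(series, "uniform_series"))
  ws <- window_samples(window, series$fs)
  n <- length(series$values)
  if (n < ws$L)
    stop("series (", n, " samples) shorter than the window (", ws$L, " samples)")
  thr <- acw_threshold(kind)
  res <- dynamic_acw_cpp(series$values, ws$L, ws$step, thr, interpolate)
  vals <- res$lag / series$fs
  starts <- series$t0 + (seq_along(vals) - 1) * ws$step / series$fs
  dynamic_series(vals, starts, window$length_s, statistic_name = kind,
                 censored = res$censored)
}

#' Welch power spectral density
#'
#' Averaged modified periodogram over Hann-tapered, overlapping,
#' per-segment demeaned segments; one-sided density scaled so that the
#' integral over frequency approximates the signal variance.
#'
#' @param series A [uniform_series()].
#' @param segment_s Segment length in seconds.
#' @param overlap_fraction Fractional overlap between consecutive segments.
#' @return List with `freq_hz` and `psd` (power per Hz).
#' @export
welch_psd <- function(series, segment_s = 60, overlap_fraction = 0.5) {
  stopifnot(inherits(series, "uniform_series"))
  x <- series$values
  fs <- series$fs
  L <- as.integer(round(segment_s * fs))
  n <- length(x)
  if (L > n) stop("segment (", L, " samples) longer than the series (", n, ")")
  if (L < 8) stop("segment too short for a meaningful periodogram")
  hop <- max(1L, L - as.integer(round(L * overlap_fraction)))
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))  # Hann
  u <- sum(w^2)
  starts <- seq(1L, n - L + 1L, by = hop)
  nfreq <- L %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + L - 1)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[1:nfreq]
    p <- (Mod(X)^2) / (fs * u)
    # one-sided: double all bins except DC and (for even L) Nyquist
    scale2 <- rep(2, nfreq); scale2[1] <- 1
    if (L %% 2 == 0) scale2[nfreq] <- 1
    acc <- acc + p * scale2
  }
  list(freq_hz = (0:(nfreq - 1)) * fs / L, psd = acc / length(starts))
}
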