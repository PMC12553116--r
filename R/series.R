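#' Evenly sampled time-series
#'
#' The common container of every analysis stage: a real-valued signal sampled
#' at a fixed rate. Brain signals are conventionally sampled at 1 Hz here
#' (one sample per fMRI repetition time), as are the semantic series derived
#' from a transcript.
#'
#' @param values Numeric vector of samples; at least two, no missing values.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `uniform_series` with fields `values`, `fs`,
#'   `t0`.
#' @examples
#' s <- uniform_series(sin(2 * pi * 0.1 * (0:99)), fs = 1)
#' series_time(s)[1:5]
#' @export
uniform_series <- function(values, fs = 1, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 2)
    stop("a uniform_series needs at least 2 samples")
  if (anyNA(values) || any(!is.finite(values)))
    stop("a uniform_series must not contain missing or non-finite values")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("`fs` must be a single positive sampling rate in Hz")
  structure(list(values = values, fs = fs, t0 = as.numeric(t0)),
            class = "uniform_series")
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %d samples @ %g Hz, t0 = %g s\n",
              length(x$values), x$fs, x$t0))
  invisible(x)
}

#' @export
length.uniform_series <- function(x) length(x$values)

#' Sample times of a uniform series
#'
#' @param series A [uniform_series()].
#' @return Numeric vector of sample times in seconds.
#' @export
series_time <- function(series) {
  stopifnot(inherits(series, "uniform_series"))
  series$t0 + (seq_along(series$values) - 1) / series$fs
}

as_series_values <- function(x) {
  if (inherits(x, "uniform_series")) x$values else as.numeric(x)
}

#' Read a series (or a matrix of series) from TSV/CSV
#'
#' Expects a one-line header. A single column yields one series; several
#' columns yield a named list of series, one per column label.
#'
#' @param path File path; tab- or comma-separated, sniffed from the header.
#' @param fs Sampling rate in Hz (default 1 Hz); overridden by a `t_s`
#'   column when one is present (the format [write_series_tsv()] emits).
#' @param t0 Time of the first row in seconds (likewise overridden).
#' @return A `uniform_series` or a named list of them.
#' @export
read_series_tsv <- function(path, fs = 1, t0 = 0) {
  header <- readLines(path, n = 1)
  sep <- if (grepl(",", header, fixed = TRUE) && !grepl("\t", header)) "," else "\t"
  df <- read.delim(path, sep = sep, check.names = FALSE)
  if ("t_s" %in% names(df)) {
    steps <- diff(df$t_s)
    if (length(steps) > 0 && max(abs(steps - steps[1])) > 1e-9)
      stop("t_s column is not evenly spaced")
    fs <- 1 / steps[1]
    t0 <- df$t_s[1]
    df <- df[setdiff(names(df), "t_s")]
  }
  if (ncol(df) == 1) return(uniform_series(df[[1]], fs = fs, t0 = t0))
  out <- lapply(df, uniform_series, fs = fs, t0 = t0)
  names(out) <- names(df)
  out
}

#' Write a series to TSV
#'
#' Columns `t_s` and `value` with a header line.
#'
#' @param series A [uniform_series()].
#' @param path Output file path.
#' @export
write_series_tsv <- function(series, path) {
  stopifnot(inherits(series, "uniform_series"))
  df <- data.frame(t_s = series_time(series), value = series$values)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-window statistic series
#'
#' Output of a sliding-window stage: one value per window position, indexed
#' by window start time. Missing values mark windows where the statistic was
#' undefined (e.g. a constant slice).
#'
#' @param values Numeric vector, one value per window (NA allowed).
#' @param window_starts_s Window start times in seconds.
#' @param window_length_s Window length in seconds.
#' @param statistic_name Label for the statistic (e.g. `"acw0"`).
#' @param censored Logical vector marking windows whose statistic was
#'   right-censored at the maximum lag.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(values, window_starts_s, window_length_s,
                           statistic_name = "stat",
                           censored = rep(FALSE, length(values))) {
  stopifnot(length(values) == length(window_starts_s),
            length(censored) == length(values))
  structure(list(values = as.numeric(values),
                 window_starts_s = as.numeric(window_starts_s),
                 window_length_s = as.numeric(window_length_s),
                 statistic_name = statistic_name,
                 censored = as.logical(censored)),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  cat(sprintf("<dynamic_series> %s: %d windows of %g s (%d censored, %d missing)\n",
              x$statistic_name, length(x$values), x$window_length_s,
              sum(x$censored), sum(is.na(x$values))))
  invisible(x)
}

#' @export
length.dynamic_series <- function(x) length(x$values)

#' Convert a dynamic series to a uniform series
#'
#' Valid when the windows advance by a fixed step; the result is sampled at
#' `1/step` Hz and starts at the first window's start time. Missing windows
#' are not allowed here (drop or impute first).
#'
#' @param dyn A [dynamic_series()].
#' @return A [uniform_series()].
#' @export
as_uniform_series <- function(dyn) {
  stopifnot(inherits(dyn, "dynamic_series"))
  steps <- diff(dyn$window_starts_s)
  if (length(steps) == 0) stop("need at least two windows")
  if (max(abs(steps - steps[1])) > 1e-9)
    stop("window starts are not evenly spaced")
  if (anyNA(dyn$values))
    stop("dynamic series contains missing windows; handle them first")
  uniform_series(dyn$values, fs = 1 / steps[1], t0 = dyn$window_starts_s[1])
}

#' Block-average a uniform series
#'
#' Replaces each run of `d` consecutive samples by its mean (a trailing
#' partial block is dropped), producing a series at `fs / d`. Used to embed
#' heavily oversampled sliding-window statistics on a grid matched to their
#' innovation timescale.
#'
#' @param series A [uniform_series()].
#' @param d Block size in samples (>= 1).
#' @return A [uniform_series()] of block means.
#' @export
bin_series <- function(series, d) {
  stopifnot(inherits(series, "uniform_series"), d >= 1)
  d <- as.integer(d)
  if (d == 1) return(series)
  v <- series$values
  nb <- length(v) %/% d
  if (nb < 2) stop("series too short to bin by ", d)
  uniform_series(colMeans(matrix(v[1:(nb * d)], d)), fs = series$fs / d,
                 t0 = series$t0)
}

#' Sliding-window specification
#'
#' @param length_s Window length in seconds (> 0).
#' @param step_s Step between window starts in seconds (> 0). The canonical
#'   analysis uses a 60-s window advancing 1 s at a time.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length_s = 60, step_s = 1) {
  if (length_s <= 0 || step_s <= 0)
    stop("window length and step must be positive")
  structure(list(length_s = length_s, step_s = step_s), class = "window_spec")
}

# window length/step in samples for a given sampling rate; checks that the
# window is an integer number of samples.
window_samples <- function(window, fs) {
  L <- window$length_s * fs
  step <- window$step_s * fs
  if (abs(L - round(L)) > 1e-8 || abs(step - round(step)) > 1e-8)
    stop("window length and step must be integer numbers of samples at fs = ",
         fs, " Hz")
  list(L = as.integer(round(L)), step = as.integer(round(step)))
}
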