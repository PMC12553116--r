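#' Subjects-by-regions-by-time panel
#'
#' Container for group analyses: one aligned series per subject and region.
#'
#' @param data 3-d numeric array, `subject x region x time`.
#' @param subject_ids,region_labels Dimension labels; defaults are generated.
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `subject_region_panel`.
#' @export
subject_region_panel <- function(data, subject_ids = NULL,
                                 region_labels = NULL, fs = 1, t0 = 0) {
  if (length(dim(data)) != 3) stop("`data` must be subject x region x time")
  d <- dim(data)
  if (is.null(subject_ids)) subject_ids <- paste0("sub", seq_len(d[1]))
  if (is.null(region_labels)) region_labels <- paste0("R", seq_len(d[2]))
  stopifnot(length(subject_ids) == d[1], length(region_labels) == d[2])
  dimnames(data) <- list(subject_ids, region_labels, NULL)
  structure(list(data = data, subject_ids = subject_ids,
                 region_labels = region_labels, fs = fs, t0 = t0),
            class = "subject_region_panel")
}

#' @export
print.subject_region_panel <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<subject_region_panel> %d subjects x %d regions x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' Extract one subject/region series from a panel
#'
#' @param panel A [subject_region_panel()].
#' @param subject,region Index or label.
#' @return A [uniform_series()].
#' @export
panel_series <- function(panel, subject, region) {
  stopifnot(inherits(panel, "subject_region_panel"))
  uniform_series(panel$data[subject, region, ], fs = panel$fs, t0 = panel$t0)
}

# window start indices (1-based) for a series of n samples
window_starts_idx <- function(n, L, step) {
  if (n < L) stop("series shorter than the window")
  seq(1L, n - L + 1L, by = step)
}

#' Sliding-window inter-subject correlation (ISC)
#'
#' For each window, the Pearson correlation of every unordered subject pair
#' on that window's slice; the window ISC is the median over pairs, and the
#' summary is the mean over windows. Pairs with a zero-variance slice are
#' dropped for that window and counted.
#'
#' @param panel A [subject_region_panel()] (>= 2 subjects).
#' @param region Region label or index.
#' @param window A [window_spec()].
#' @return An `isc_result`: `per_window`, `window_starts_s`, `summary`,
#'   `n_dropped_pairs`.
#' @export
sliding_isc <- function(panel, region, window = window_spec()) {
  stopifnot(inherits(panel, "subject_region_panel"))
  m <- panel$data[, region, , drop = TRUE]
  if (is.null(dim(m))) stop("need at least 2 subjects")
  ws <- window_samples(window, panel$fs)
  starts <- window_starts_idx(ncol(m), ws$L, ws$step)
  n_dropped <- 0L
  per_window <- vapply(starts, function(s) {
    slice <- m[, s:(s + ws$L - 1), drop = FALSE]
    sds <- apply(slice, 1, sd)
    ok <- sds > 0
    if (sum(ok) < 2) { n_dropped <<- n_dropped + choose(nrow(slice), 2); return(NA_real_) }
    n_dropped <<- n_dropped + (choose(nrow(slice), 2) - choose(sum(ok), 2))
    cm <- cor(t(slice[ok, , drop = FALSE]))
    median(cm[upper.tri(cm)])
  }, numeric(1))
  structure(list(per_window = per_window,
                 window_starts_s = panel$t0 + (starts - 1) / panel$fs,
                 summary = mean(per_window, na.rm = TRUE),
                 window = window, n_dropped_pairs = n_dropped),
            class = "isc_result")
}

#' @export
print.isc_result <- function(x, ...) {
  cat(sprintf("<isc_result> mean ISC = %.4f over %d windows\n",
              x$summary, length(x$per_window)))
  invisible(x)
}

#' Region-by-region inter-subject correlation matrix
#'
#' For each region pair, the per-window median cross-subject Pearson
#' correlation (subject `i`'s series in one region against subject `j`'s in
#' the other, over all ordered pairs `i != j`), averaged over windows. The
#' result is symmetric with unit diagonal. Feed a raw panel or a
#' dynamic-ACW panel (see [dynamic_acw_panel()]) for side-by-side comparison.
#'
#' @param panel A [subject_region_panel()] (>= 2 regions, >= 2 subjects).
#' @param window A [window_spec()].
#' @return `region x region` numeric matrix.
#' @export
roi_correlation_matrices <- function(panel, window = window_spec()) {
  stopifnot(inherits(panel, "subject_region_panel"))
  d <- dim(panel$data)
  S <- d[1]; R <- d[2]; n <- d[3]
  if (R < 2) stop("need at least 2 regions")
  if (S < 2) stop("need at least 2 subjects")
  ws <- window_samples(window, panel$fs)
  starts <- window_starts_idx(n, ws$L, ws$step)
  acc <- matrix(0, R, R)
  cnt <- matrix(0, R, R)
  pair_i <- rep(seq_len(S), each = S)
  pair_j <- rep(seq_len(S), times = S)
  cross <- pair_i != pair_j
  for (s in starts) {
    # rows = (subject, region) flattened; columns = time
    flat <- matrix(aperm(panel$data[, , s:(s + ws$L - 1), drop = FALSE],
                         c(3, 1, 2)), nrow = ws$L)
    sds <- apply(flat, 2, sd)
    cm <- suppressWarnings(cor(flat))
    for (a in seq_len(R)) for (b in seq_len(a)) {
      ia <- (a - 1) * S + pair_i[cross]
      ib <- (b - 1) * S + pair_j[cross]
      vals <- cm[cbind(ia, ib)]
      vals <- vals[!is.na(vals)]
      if (length(vals) > 0) {
        acc[a, b] <- acc[a, b] + median(vals)
        cnt[a, b] <- cnt[a, b] + 1
      }
    }
  }
  out <- acc / pmax(cnt, 1)
  out[upper.tri(out)] <- t(out)[upper.tri(out)]
  diag(out) <- 1
  dimnames(out) <- list(panel$region_labels, panel$region_labels)
  out
}

#' Dynamic-ACW panel
#'
#' Applies [dynamic_acw()] to every subject/region series of a panel,
#' returning a new panel whose time axis is the window index (sampled at
#' `1/step` Hz, starting at the first window's start time). Censored windows
#' keep their censored value; constant windows yield `NA` and are counted.
#'
#' @param panel A [subject_region_panel()].
#' @param window A [window_spec()].
#' @param kind ACW variant, as in [acw()].
#' @return A [subject_region_panel()] of ACW series, with attribute
#'   `n_missing` (count of constant windows).
#' @export
dynamic_acw_panel <- function(panel, window = window_spec(), kind = "acw0") {
  stopifnot(inherits(panel, "subject_region_panel"))
  d <- dim(panel$data)
  ws <- window_samples(window, panel$fs)
  n_win <- (d[3] - ws$L) %/% ws$step + 1L
  out <- array(NA_real_, c(d[1], d[2], n_win))
  n_missing <- 0L
  for (s in seq_len(d[1])) for (r in seq_len(d[2])) {
    dyn <- dynamic_acw(panel_series(panel, s, r), window, kind)
    n_missing <- n_missing + sum(is.na(dyn$values))
    out[s, r, ] <- dyn$values
  }
  p <- subject_region_panel(out, panel$subject_ids, panel$region_labels,
                            fs = panel$fs / ws$step,
                            t0 = panel$t0)
  attr(p, "n_missing") <- n_missing
  p
}

#' Reorder a region correlation matrix by network grouping
#'
#' Orders the rows/columns of a region-by-region matrix so that regions of
#' the same functional network are adjacent (networks in first-appearance
#' order), the layout used for grouped triangular displays.
#'
#' @param mat Square matrix with region dimnames.
#' @param networks Data frame with columns `region` and `network` (e.g.
#'   read from a TSV); regions absent from it keep their position at the
#'   end.
#' @return The reordered matrix, with a `networks` attribute giving the
#'   network per row.
#' @export
reorder_by_network <- function(mat, networks) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)),
            all(c("region", "network") %in% names(networks)))
  net <- networks$network[match(rownames(mat), networks$region)]
  ord <- order(match(net, unique(stats::na.omit(net))), na.last = TRUE)
  out <- mat[ord, ord]
  attr(out, "networks") <- net[ord]
  out
}

#' Levene variance-homogeneity test
#'
#' Classic Levene W on absolute deviations from the group mean, referred to
#' an `F(k - 1, N - k)` distribution. Used to contrast the variability of
#' dynamic timescales between conditions (e.g. movie vs rest).
#'
#' @param ... Two or more numeric groups, or a single list of groups.
#' @param center `"mean"` (classic Levene, default) or `"median"`
#'   (Brown-Forsythe).
#' @return A `levene_result`: `W`, `df` (between, within), `p`.
#' @examples
#' levene_test(c(1, 2, 3), c(2, 4, 6))  # W = 0.8, df (1, 4)
#' @export
levene_test <- function(..., center = c("mean", "median")) {
  center <- match.arg(center)
  groups <- list(...)
  if (length(groups) == 1 && is.list(groups[[1]])) groups <- groups[[1]]
  if (length(groups) < 2) stop("need at least two groups")
  k <- length(groups)
  ns <- lengths(groups)
  if (any(ns < 2)) stop("each group needs at least 2 values")
  centerfun <- if (center == "mean") mean else median
  zs <- lapply(groups, function(g) abs(g - centerfun(g)))
  flat <- which(vapply(zs, function(z) var(z) == 0, logical(1)))
  if (length(flat) > 0)
    stop("degenerate absolute deviations (zero spread) in group ",
         paste(flat, collapse = ", "))
  zbar_g <- vapply(zs, mean, numeric(1))
  N <- sum(ns)
  zbar <- sum(unlist(zs)) / N
  ssb <- sum(ns * (zbar_g - zbar)^2)
  ssw <- sum(vapply(seq_len(k), function(g) sum((zs[[g]] - zbar_g[g])^2),
                    numeric(1)))
  W <- ((N - k) / (k - 1)) * ssb / ssw
  df <- c(k - 1, N - k)
  structure(list(W = W, df = df, p = pf(W, df[1], df[2], lower.tail = FALSE),
                 center = center),
            class = "levene_result")
}

#' @export
print.levene_result <- function(x, ...) {
  cat(sprintf("<levene_result> W = %.4f, df = (%d, %d), p = %.4g [center = %s]\n",
              x$W, x$df[1], x$df[2], x$p, x$center))
  invisible(x)
}
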