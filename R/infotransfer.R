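#' Transfer-entropy parameters
#'
#' @param lag Source-to-target lag `u` in samples (>= 1); may be a vector to
#'   evaluate several lags.
#' @param target_history Target embedding length `k` in samples (>= 1).
#' @param source_history Source embedding length `l` in samples (>= 1).
#' @param k_neighbors Neighbour count `K` of the KSG estimator.
#' @param standardize Z-score both series before embedding.
#' @param jitter_scale Amplitude of the deterministic tie-breaking jitter in
#'   units of `1e-10` per-dimension standard deviations; 0 disables it.
#' @param jitter_seed RNG seed of the tie-breaking jitter.
#' @param theiler Theiler window in samples: temporal neighbours closer than
#'   this are excluded from the KSG neighbour search (dynamic correlation
#'   exclusion). 0 disables it; series with slow autocorrelation (e.g.
#'   sliding-window statistics) need it for calibrated surrogate inference.
#' @return An object of class `te_params`.
#' @export
te_params <- function(lag = 1L, target_history = 1L, source_history = 1L,
                      k_neighbors = 4L, standardize = TRUE,
                      jitter_scale = 1, jitter_seed = 1L, theiler = 0L) {
  if (any(lag < 1) || target_history < 1 || source_history < 1 ||
      k_neighbors < 1)
    stop("lag, histories and k_neighbors must all be >= 1")
  if (jitter_scale < 0) stop("jitter_scale must be >= 0")
  structure(list(lag = as.integer(lag),
                 target_history = as.integer(target_history),
                 source_history = as.integer(source_history),
                 k_neighbors = as.integer(k_neighbors),
                 standardize = isTRUE(standardize),
                 jitter_scale = jitter_scale,
                 jitter_seed = as.integer(jitter_seed),
                 theiler = as.integer(theiler)),
            class = "te_params")
}

# deterministic tie-breaking jitter: KSG needs distinct distances.
add_jitter <- function(m, scale, seed) {
  if (scale <= 0) return(m)
  sds <- apply(m, 2, sd)
  sds[sds == 0] <- 1
  with_seed(seed, m + matrix(rnorm(length(m)), nrow(m), ncol(m)) *
              rep(sds, each = nrow(m)) * scale * 1e-10)
}

#' KSG conditional mutual information
#'
#' Kraskov-Stoegbauer-Grassberger k-nearest-neighbour estimate of
#' `I(X; Y | Z)` in nats, using max-norm distances and the Frenzel-Pompe
#' digamma correction `psi(K) - <psi(n_xz+1) + psi(n_yz+1) - psi(n_z+1)>`.
#' With `z = NULL` this is the standard two-variable KSG algorithm-1 MI
#' estimator. Estimates may be slightly negative (estimator bias); they are
#' never clipped.
#'
#' @param x,y,z Numeric vectors or matrices (rows are samples); `z` may be
#'   `NULL` for unconditional MI.
#' @param K Neighbour count (`n > K` required).
#' @param jitter_scale,jitter_seed Deterministic jitter breaking distance
#'   ties; see [te_params()].
#' @param theiler Temporal exclusion window in samples; see [te_params()].
#' @return Estimate in nats.
#' @export
ksg_cmi <- function(x, y, z = NULL, K = 4, jitter_scale = 1, jitter_seed = 1L,
                    theiler = 0L) {
  x <- as.matrix(x); y <- as.matrix(y)
  z <- if (is.null(z)) matrix(numeric(0), nrow(x), 0) else as.matrix(z)
  n <- nrow(x)
  if (nrow(y) != n || (ncol(z) > 0 && nrow(z) != n))
    stop("x, y, z must have equal sample counts")
  if (n <= K) stop("need more samples (", n, ") than neighbours K = ", K)
  if (anyNA(x) || anyNA(y) || anyNA(z)) stop("inputs must be finite")
  x <- add_jitter(x, jitter_scale, jitter_seed)
  y <- add_jitter(y, jitter_scale, jitter_seed + 1L)
  if (ncol(z) > 0) z <- add_jitter(z, jitter_scale, jitter_seed + 2L)
  ksg_cmi_cpp(x, y, z, as.integer(K), as.integer(theiler))
}

# time-delay embedding matrices for TE; returns x (target present),
# y (source past block), z (target past block).
te_embed <- function(src, tgt, u, k, l, K = 0) {
  n <- length(tgt)
  t0 <- max(k + 1, u + l)
  if (n - t0 + 1 <= K + 1)
    stop("series too short for the TE embedding: need length > ",
         t0 + K, " samples (lag ", u, ", histories k = ", k, ", l = ", l,
         ", K = ", K, ")")
  t_idx <- t0:n
  x <- matrix(tgt[t_idx], ncol = 1)
  z <- sapply(1:k, function(j) tgt[t_idx - j])
  y <- sapply(1:l, function(j) src[t_idx - u - j + 1])
  list(x = x, y = as.matrix(y), z = as.matrix(z))
}

#' Lagged transfer entropy (source to target)
#'
#' `TE(source -> target, lag u) = I(target_t ; source_{t-u, ..., t-u-l+1} |
#' target_{t-1, ..., t-k})`, estimated with [ksg_cmi()]. Series are z-scored
#' first when `standardize` is set.
#'
#' @param source,target [uniform_series()] or numeric vectors of equal
#'   length (aligned on the same time base).
#' @param params A [te_params()]; `params$lag` must be a single lag here.
#' @return A `te_estimate`: list with `value` (nats), `lag` (samples),
#'   `n_points` and `params`.
#' @export
transfer_entropy <- function(source, target, params = te_params()) {
  src <- as_series_values(source)
  tgt <- as_series_values(target)
  if (length(src) != length(tgt))
    stop("source and target must have equal lengths after alignment (",
         length(src), " vs ", length(tgt), ")")
  if (length(params$lag) != 1)
    stop("transfer_entropy takes one lag; use te_over_lags() for several")
  if (params$standardize) {
    # a constant series is centred but not scaled (its TE is estimator
    # noise around zero, which is the honest answer)
    zsafe <- function(v) {
      s <- sd(v)
      if (s == 0) v - mean(v) else (v - mean(v)) / s
    }
    src <- zsafe(src)
    tgt <- zsafe(tgt)
  }
  e <- te_embed(src, tgt, params$lag, params$target_history,
                params$source_history, K = params$k_neighbors)
  val <- ksg_cmi(e$x, e$y, e$z, K = params$k_neighbors,
                 jitter_scale = params$jitter_scale,
                 jitter_seed = params$jitter_seed,
                 theiler = params$theiler)
  structure(list(value = val, lag = params$lag, n_points = nrow(e$x),
                 params = params),
            class = "te_estimate")
}

#' @export
print.te_estimate <- function(x, ...) {
  cat(sprintf("<te_estimate> %.4f nats at lag %d (n = %d, K = %d)\n",
              x$value, x$lag, x$n_points, x$params$k_neighbors))
  invisible(x)
}

#' Transfer entropy over a set of lags
#'
#' @param source,target As in [transfer_entropy()].
#' @param params A [te_params()] whose `lag` may be a vector.
#' @return Numeric vector of TE values in nats, named by lag.
#' @export
te_over_lags <- function(source, target, params = te_params(lag = 1:5)) {
  vapply(params$lag, function(u) {
    p <- params; p$lag <- u
    transfer_entropy(source, target, p)$value
  }, numeric(1)) |> stats::setNames(params$lag)
}

#' Markov block shuffle
#'
#' Partitions a series into consecutive blocks of `block_len` samples (the
#' final partial block is kept) and permutes the block order uniformly at
#' random, leaving within-block order untouched. With block lengths matched
#' to the series' mean ACW this preserves local temporal structure while
#' destroying long-range coupling.
#'
#' @param series A [uniform_series()] or numeric vector.
#' @param block_len Block length in samples (>= 1).
#' @param seed RNG seed for the block permutation.
#' @return Same type as the input, with shuffled blocks.
#' @export
markov_block_shuffle <- function(series, block_len, seed = 1L) {
  x <- as_series_values(series)
  block_len <- max(1L, as.integer(round(block_len)))
  n <- length(x)
  n_blocks <- ceiling(n / block_len)
  if (n_blocks <= 1) {
    y <- x
  } else {
    idx <- split(seq_len(n), rep(seq_len(n_blocks), each = block_len)[1:n])
    perm <- with_seed(seed, sample.int(n_blocks))
    y <- unlist(idx[perm], use.names = FALSE)
    y <- x[y]
  }
  if (inherits(series, "uniform_series"))
    uniform_series(y, fs = series$fs, t0 = series$t0)
  else y
}

#' Block-bootstrap surrogate test for transfer entropy
#'
#' Compares the observed TE against TE values recomputed on block-shuffled
#' inputs. The shuffled side is re-fed through the same computation as the
#' observed statistic (via `recompute`), so for timescale-level TE a shuffled
#' raw signal is re-passed through the sliding-window ACW stage. The p-value
#' per lag is the proportion of surrogate TE values strictly greater than the
#' observed TE (no +1 correction unless `bias_corrected`).
#'
#' @param source,target The inputs of `recompute`. With the default
#'   `recompute` these are equal-length series fed directly to
#'   [te_over_lags()]; `target` may instead be a list of per-subject series
#'   when `recompute` aggregates an ensemble.
#' @param params A [te_params()]; `lag` may be a vector.
#' @param n_surrogates Number of shuffled datasets (>= 1).
#' @param block_len Block length(s) in samples: a scalar, or a vector with
#'   one entry per ensemble member when the shuffled side is a list.
#' @param shuffle_side Which input is block-shuffled: `"target"` (default,
#'   the brain side) or `"source"`.
#' @param recompute Function `(source, target, params) -> numeric vector of
#'   TE per lag` reproducing the observed pipeline; defaults to direct TE.
#' @param seed Base RNG seed; surrogate `i` uses `seed + i`.
#' @param bias_corrected Use `(count + 1) / (n + 1)` instead of `count / n`.
#' @param coherent When the shuffled side is a subject ensemble, apply the
#'   same block permutation to every subject. This preserves the structure
#'   of across-subject aggregates (their shared slow fluctuations survive as
#'   reordered segments) while still destroying alignment with the other
#'   side; per-subject independent permutations flatten the group mean.
#' @return A `te_surrogate_result`: observed TE per lag, surrogate matrix
#'   (`n_surrogates` x lags), p-value per lag.
#' @export
surrogate_test <- function(source, target, params = te_params(),
                           n_surrogates = 1000, block_len,
                           shuffle_side = c("target", "source"),
                           recompute = NULL, seed = 1L,
                           bias_corrected = FALSE, coherent = FALSE) {
  shuffle_side <- match.arg(shuffle_side)
  if (n_surrogates < 1) stop("n_surrogates must be >= 1")
  if (is.null(recompute))
    recompute <- function(src, tgt, p) te_over_lags(src, tgt, p)
  observed <- recompute(source, target, params)
  n_lags <- length(observed)
  shuffle_one <- function(obj, i) {
    if (is.list(obj) && !inherits(obj, "uniform_series")) {
      bl <- rep_len(block_len, length(obj))
      lapply(seq_along(obj), function(j)
        markov_block_shuffle(obj[[j]], bl[j],
                             seed = seed + i * 131L +
                               (if (coherent) 0L else j)))
    } else {
      markov_block_shuffle(obj, block_len[1], seed = seed + i * 131L)
    }
  }
  surr <- matrix(NA_real_, n_surrogates, n_lags)
  for (i in seq_len(n_surrogates)) {
    if (shuffle_side == "target") {
      surr[i, ] <- recompute(source, shuffle_one(target, i), params)
    } else {
      surr[i, ] <- recompute(shuffle_one(source, i), target, params)
    }
  }
  counts <- colSums(surr > matrix(observed, n_surrogates, n_lags, byrow = TRUE))
  p <- if (bias_corrected) (counts + 1) / (n_surrogates + 1)
       else counts / n_surrogates
  structure(list(observed = observed, surrogates = surr,
                 n_surrogates = n_surrogates, p_value = unname(p),
                 lags = params$lag, params = params,
                 shuffle_side = shuffle_side, seed = seed),
            class = "te_surrogate_result")
}

#' @export
print.te_surrogate_result <- function(x, ...) {
  cat(sprintf("<te_surrogate_result> %d surrogates, %s shuffled\n",
              x$n_surrogates, x$shuffle_side))
  df <- data.frame(lag = x$lags, te_nats = round(unname(x$observed), 4),
                   p_value = x$p_value)
  print(df, row.names = FALSE)
  invisible(x)
}
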