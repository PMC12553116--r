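#' Simulate a stationary AR(1) series
#'
#' `x_t = phi * x_{t-1} + e_t`, `e_t ~ N(0, sigma^2)`, with the first sample
#' drawn from the stationary distribution. Its analytic ACF is `phi^m`, so
#' the ACW of the generated signal is known in closed form, which makes the
#' generator a parameter-recovery oracle for the timescale stage.
#'
#' @param phi AR coefficient, `|phi| < 1`.
#' @param sigma Innovation standard deviation (> 0).
#' @param n Number of samples.
#' @param seed RNG seed (bit-reproducible output).
#' @param fs Sampling rate in Hz.
#' @return A [uniform_series()].
#' @export
gen_ar1 <- function(phi, sigma = 1, n = 1000, seed = 1L, fs = 1) {
  if (abs(phi) >= 1) stop("|phi| must be < 1 for stationarity")
  if (sigma <= 0) stop("sigma must be positive")
  x <- with_seed(seed, {
    e <- rnorm(n, sd = sigma)
    out <- numeric(n)
    out[1] <- rnorm(1, sd = sigma / sqrt(1 - phi^2))
    for (t in 2:n) out[t] <- phi * out[t - 1] + e[t]
    out
  })
  uniform_series(x, fs = fs)
}

# moving-average smoothed white noise, standardized and squashed into
# (0, 1) through a logistic map; the common driver of local timescales.
make_driver01 <- function(n, smooth_w, seed) {
  z <- with_seed(seed, rnorm(n + smooth_w))
  sm <- as.numeric(stats::filter(z, rep(1 / smooth_w, smooth_w), sides = 1))
  sm <- sm[(smooth_w + 1):(smooth_w + n)]
  sm <- (sm - mean(sm)) / sd(sm)
  plogis(2 * sm)
}

# AR(1) with a time-varying coefficient phi_t
gen_tvar1 <- function(phi_t, sigma, seed) {
  n <- length(phi_t)
  with_seed(seed, {
    e <- rnorm(n, sd = sigma)
    out <- numeric(n)
    out[1] <- e[1] / sqrt(1 - phi_t[1]^2)
    for (t in 2:n) out[t] <- phi_t[t] * out[t - 1] + e[t]
    out
  })
}

#' Simulate a timescale-coupled source/target ensemble
#'
#' Positive (and negative) control for the timescale-transfer analysis. A
#' smooth bounded driver in `(0, 1)` modulates local timescales on both
#' sides: it sets the local AR(1) coefficient (within `phi_range`) of every
#' target subject at a delay of `coupling_lag_s`, and the instantaneous
#' period (within `source_period_range`) of a quasi-periodic
#' frequency-modulated source at lag 0. The source emulates a fixed
#' stimulus-derived series: its local timescale is an almost deterministic
#' readout of the driver, the way a semantic series is a fixed function of
#' the stimulus, whereas each target is a noisy stochastic realization. All
#' innovations and noises are independent across series, so the raw signals
#' are uncorrelated while their local timescales share the driver:
#' information flows from the source's timescale to the targets'
#' timescales, never between the raw signals and never backwards. With
#' `independent_drivers = TRUE` the targets follow their own driver and the
#' ensemble is a proper null.
#'
#' @param n Samples per series (at 1 Hz; about a 15-min naturalistic run by
#'   default).
#' @param n_subjects Number of target subjects.
#' @param phi_range Range `(lo, hi)` of the targets' local AR coefficient,
#'   inside `(0, 1)`; the default spans sluggish-to-fast local timescales
#'   (windowed ACW roughly 1-15 s).
#' @param source_period_range Range of the source's instantaneous period in
#'   seconds; its windowed ACW-0 is about a quarter period, matching the
#'   targets' timescale range.
#' @param driver_smoothness_s Moving-average width of the driver in seconds;
#'   sets how slowly the local timescale drifts.
#' @param coupling_lag_s Delay, in seconds, between the driver's effect on
#'   the source and on the targets (targets lag the source).
#' @param observation_noise_sd SD of white measurement noise added to each
#'   target (the target innovations have unit SD).
#' @param source_noise_sd SD of white noise added to the unit-amplitude
#'   source.
#' @param source_kind `"fm"` (frequency-modulated quasi-periodic source,
#'   default) or `"ar1"` (a time-varying AR(1) source like the targets; its
#'   timescale readout is then as noisy as a single subject's, which blurs
#'   the direction of transfer).
#' @param independent_drivers Use a separate driver for the targets (null
#'   ensemble).
#' @param seed RNG seed.
#' @return List with `source` ([uniform_series()]), `targets`
#'   ([subject_region_panel()] with one region), `driver` (the
#'   [uniform_series()] in `(0, 1)` driving the source at lag 0),
#'   `driver_phi` (the targets' local AR coefficient) and `coupling_lag_s`.
#' @export
gen_timescale_coupled_ensemble <- function(n = 900, n_subjects = 20,
                                           phi_range = c(0.3, 0.95),
                                           source_period_range = c(6, 40),
                                           driver_smoothness_s = 60,
                                           coupling_lag_s = 3,
                                           observation_noise_sd = 0.1,
                                           source_noise_sd = 0.05,
                                           source_kind = c("fm", "ar1"),
                                           independent_drivers = FALSE,
                                           seed = 1L) {
  stopifnot(phi_range[1] > 0, phi_range[2] < 1, phi_range[1] < phi_range[2],
            coupling_lag_s >= 0)
  source_kind <- match.arg(source_kind)
  lag <- as.integer(round(coupling_lag_s))
  smooth_w <- max(2L, as.integer(round(driver_smoothness_s)))
  # driver long enough to delay by `lag` for the targets
  d_src <- make_driver01(n + lag, smooth_w, seed = seed * 1000L + 1L)
  drv_source <- d_src[(lag + 1):(lag + n)]
  drv_target <- if (independent_drivers) {
    make_driver01(n + lag, smooth_w, seed = seed * 1000L + 2L)[1:n]
  } else {
    d_src[1:n]  # the same driver, delayed by `lag` relative to the source
  }
  if (source_kind == "fm") {
    period <- source_period_range[1] + diff(source_period_range) * drv_source
    phase <- cumsum(1 / period)
    sv <- sin(2 * pi * phase)
  } else {
    sv <- gen_tvar1(phi_range[1] + diff(phi_range) * drv_source, sigma = 1,
                    seed = seed * 1000L + 10L)
  }
  if (source_noise_sd > 0)
    sv <- sv + with_seed(seed * 1000L + 3L, rnorm(n, sd = source_noise_sd))
  source <- uniform_series(sv, fs = 1)
  tgt_phi <- phi_range[1] + diff(phi_range) * drv_target
  dat <- array(NA_real_, c(n_subjects, 1, n))
  for (j in seq_len(n_subjects)) {
    x <- gen_tvar1(tgt_phi, sigma = 1, seed = seed * 1000L + 100L + j)
    if (observation_noise_sd > 0)
      x <- x + with_seed(seed * 1000L + 500L + j,
                         rnorm(n, sd = observation_noise_sd))
    dat[j, 1, ] <- x
  }
  list(source = source,
       targets = subject_region_panel(dat, region_labels = "R1", fs = 1),
       driver = uniform_series(drv_source, fs = 1),
       driver_phi = uniform_series(tgt_phi, fs = 1),
       coupling_lag_s = coupling_lag_s)
}

#' Default synthetic vocabulary
#'
#' Forty tokens spanning hypernym depths 1-10, loosely mimicking a
#' concrete-to-abstract gradient.
#'
#' @return Data frame with `token` and `depth`.
#' @export
default_vocab <- function() {
  data.frame(
    token = c("entity", "object", "thing", "matter",
              "organism", "artifact", "substance", "structure",
              "animal", "plant", "device", "building",
              "mammal", "bird", "tool", "vehicle",
              "dog", "cat", "hammer", "car",
              "food", "fruit", "drink", "meal",
              "apple", "pineapple", "coffee", "bread",
              "idea", "feeling", "thought", "plan",
              "freedom", "justice", "beauty", "truth",
              "person", "friend", "teacher", "child"),
    depth = c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 3, 4, 4, 4, 4,
              7, 7, 6, 6, 5, 6, 5, 5, 8, 9, 8, 7, 3, 3, 4, 4,
              5, 5, 5, 5, 4, 6, 7, 6),
    stringsAsFactors = FALSE
  )
}

#' Simulate a timed transcript with a matching depth lexicon
#'
#' Word onsets follow a Poisson process at `word_rate_hz`, thinned to zero
#' inside rest gaps (silent intervals, as between clips of a naturalistic
#' movie run). Tokens are drawn uniformly from the vocabulary; each word ends
#' before the next begins.
#'
#' @param duration_s Total duration in seconds.
#' @param word_rate_hz Mean word rate in words per second.
#' @param vocab Data frame with `token` and `depth` columns.
#' @param rest_gaps List of `c(start_s, end_s)` silent intervals.
#' @param seed RNG seed.
#' @return List with `transcript` ([transcript()]) and `lexicon`
#'   ([depth_lexicon()] covering the vocabulary exactly).
#' @export
gen_transcript <- function(duration_s = 900, word_rate_hz = 2,
                           vocab = default_vocab(), rest_gaps = list(),
                           seed = 1L) {
  stopifnot(duration_s > 0, word_rate_hz > 0, all(vocab$depth >= 0))
  out <- with_seed(seed, {
    t <- 0
    starts <- numeric(0)
    repeat {
      t <- t + rexp(1, rate = word_rate_hz)
      if (t >= duration_s) break
      starts <- c(starts, t)
    }
    in_gap <- rep(FALSE, length(starts))
    for (g in rest_gaps)
      in_gap <- in_gap | (starts >= g[1] & starts < g[2])
    starts <- starts[!in_gap]
    tokens <- sample(vocab$token, length(starts), replace = TRUE)
    list(starts = starts, tokens = tokens)
  })
  starts <- out$starts
  gap_to_next <- c(diff(starts), duration_s - starts[length(starts)])
  ends <- starts + pmin(0.3, 0.8 * gap_to_next)
  tr <- transcript(out$tokens, starts, ends, duration_s = duration_s)
  list(transcript = tr, lexicon = depth_lexicon(vocab$token, vocab$depth))
}

# zero-speech sentinel: empty or whitespace-only text
is_empty_text <- function(text) !grepl("[^[:space:]]", text)

#' Deterministic hashed bag-of-words embedder
#'
#' Test stand-in for a pretrained sentence-embedding model: each token hashes
#' (FNV-1a, mixed with `hash_seed`) to one of `dim` dimensions with a +/-1
#' sign; a text embeds as its unit-normalized signed token-count vector.
#' Deterministic across sessions. Empty text returns `NULL` (the zero-speech
#' sentinel handled by [sentence_similarity_series()]).
#'
#' @param dim Embedding dimension (>= 8).
#' @param hash_seed Integer seed mixed into the hash.
#' @param signed Use +/-1 hash signs; with `signed = FALSE` embeddings are
#'   non-negative and cosine similarities stay in `[0, 1]`.
#' @return An embedding provider: list with `embed(text)` and `dim`.
#' @export
toy_embedder <- function(dim = 64, hash_seed = 1L, signed = TRUE) {
  if (dim < 8) stop("dim must be >= 8")
  dim <- as.integer(dim)
  hash_seed <- as.integer(hash_seed)
  embed <- function(text) {
    if (length(text) != 1) stop("embed() takes a single text")
    if (is_empty_text(text)) return(NULL)
    tokens <- normalize_token(strsplit(trimws(text), "[[:space:]]+")[[1]])
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) == 0) return(NULL)
    h <- hash_tokens_cpp(tokens, hash_seed)
    idx <- (h %% dim) + 1L
    sign <- if (signed) ifelse(((h %/% dim) %% 2L) == 0L, 1, -1)
            else rep(1, length(idx))
    v <- numeric(dim)
    for (i in seq_along(idx)) v[idx[i]] <- v[idx[i]] + sign[i]
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(NULL)  # signs cancelled exactly
    v / nv
  }
  list(embed = embed, dim = dim, name = "hashed-bag-of-words")
}
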