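#' Default analysis configuration
#'
#' The canonical parameters of the analysis: 60-s window with 1-s step,
#' 0.05-0.5 Hz third-order zero-phase Butterworth band-pass, 20-s
#' leading/trailing trim, ACW-0 timescales, TE at lags 1-5 samples with
#' k = l = 1 and K = 4 neighbours, 1000 surrogates, the four movie-clip
#' segments, and the window-size sweep 60-540 s.
#'
#' @return A nested list; override entries via [read_config()] or by
#'   assignment.
#' @export
default_config <- function() {
  list(
    window = list(length_s = 60, step_s = 1),
    bandpass = list(low_hz = 0.05, high_hz = 0.5, order = 3,
                    zero_phase = TRUE),
    trim_s = 20,
    acw_kind = "acw0",
    acw_interpolate = FALSE,
    filter_semantic = FALSE,
    te = list(lags = 1:5, target_history = 1, source_history = 1,
              k_neighbors = 4, standardize = TRUE,
              embed_step_s = 10, theiler_s = 60),
    surrogate = list(coherent = TRUE, block_windows = 2.5),
    n_surrogates = 1000,
    seed = 1,
    segments = list(c(20, 246), c(267, 525), c(545, 794), c(815, 897)),
    window_sweep_s = seq(60, 540, by = 60),
    psd = list(segment_s = 120, overlap_fraction = 0.5, trim_samples = 20),
    embedder = list(dim = 64, hash_seed = 1, signed = TRUE)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a YAML configuration, merged onto the defaults
#'
#' @param path YAML file; keys mirror [default_config()].
#' @return The merged configuration list.
#' @export
read_config <- function(path) {
  merge_config(default_config(), yaml::read_yaml(path))
}

config_window <- function(config) window_spec(config$window$length_s,
                                              config$window$step_s)
config_bandpass <- function(config) bandpass_spec(config$bandpass$low_hz,
                                                  config$bandpass$high_hz,
                                                  config$bandpass$order,
                                                  config$bandpass$zero_phase)
config_te_params <- function(config, lag = NULL) {
  te <- config$te
  te_params(lag = if (is.null(lag)) te$lags else lag,
            target_history = te$target_history,
            source_history = te$source_history,
            k_neighbors = te$k_neighbors,
            standardize = te$standardize)
}

# drop `trim_s` seconds at both ends
trim_series <- function(series, trim_s) {
  if (trim_s <= 0) return(series)
  k <- as.integer(round(trim_s * series$fs))
  n <- length(series$values)
  if (n - 2 * k < 2) stop("series too short to trim ", trim_s, " s at both ends")
  uniform_series(series$values[(k + 1):(n - k)], fs = series$fs,
                 t0 = series$t0 + k / series$fs)
}

# trim -> linear detrend -> zero-phase band-pass
preprocess_brain_series <- function(series, config) {
  s <- trim_series(series, config$trim_s)
  s <- linear_detrend(s)
  bandpass(s, config_bandpass(config))
}

#' Truncate two uniform series to their common time range
#'
#' Both series must share the sampling rate and have sample times on the
#' same grid.
#'
#' @param a,b [uniform_series()] objects.
#' @return List with the aligned `a` and `b`.
#' @export
align_series <- function(a, b) {
  stopifnot(inherits(a, "uniform_series"), inherits(b, "uniform_series"))
  if (abs(a$fs - b$fs) > 1e-9) stop("sampling rates differ")
  fs <- a$fs
  off <- (b$t0 - a$t0) * fs
  if (abs(off - round(off)) > 1e-6) stop("sample grids are not aligned")
  t0 <- max(a$t0, b$t0)
  t1 <- min(a$t0 + (length(a$values) - 1) / fs,
            b$t0 + (length(b$values) - 1) / fs)
  if (t1 - t0 < 1 / fs) stop("series do not overlap in time")
  slice <- function(s) {
    i0 <- as.integer(round((t0 - s$t0) * fs)) + 1L
    i1 <- as.integer(round((t1 - s$t0) * fs)) + 1L
    uniform_series(s$values[i0:i1], fs = fs, t0 = t0)
  }
  list(a = slice(a), b = slice(b))
}

#' Across-subject mean of aligned dynamic series
#'
#' Averages the window values of several [dynamic_series()] with identical
#' window grids, ignoring missing windows subject-wise.
#'
#' @param dyn_list List of [dynamic_series()] with equal window starts.
#' @return A [dynamic_series()] of per-window means.
#' @export
group_mean_dynamic <- function(dyn_list) {
  starts <- dyn_list[[1]]$window_starts_s
  vals <- sapply(dyn_list, function(d) {
    stopifnot(isTRUE(all.equal(d$window_starts_s, starts)))
    d$values
  })
  dynamic_series(rowMeans(as.matrix(vals), na.rm = TRUE), starts,
                 dyn_list[[1]]$window_length_s,
                 statistic_name = dyn_list[[1]]$statistic_name)
}

#' Brain pipeline: preprocessing and group-mean dynamic ACW
#'
#' Per subject and region: trim the leading/trailing rest seconds, linearly
#' detrend, band-pass the complete series, then compute the sliding-window
#' ACW. Finally the across-subject mean dynamic ACW per region.
#'
#' @param panel A [subject_region_panel()] of raw signals.
#' @param config Configuration list (see [default_config()]).
#' @return List with `group_mean` (named list of [dynamic_series()] per
#'   region), `per_subject` (list of lists of [dynamic_series()]),
#'   `preprocessed` (list of lists of [uniform_series()]), `mean_acw_s`
#'   (subject x region matrix of each subject's mean dynamic ACW in seconds,
#'   the block length basis for surrogate shuffles) and `n_censored`.
#' @export
run_brain_pipeline <- function(panel, config = default_config()) {
  stopifnot(inherits(panel, "subject_region_panel"))
  window <- config_window(config)
  S <- length(panel$subject_ids); R <- length(panel$region_labels)
  per_subject <- preprocessed <- vector("list", S)
  mean_acw <- matrix(NA_real_, S, R,
                     dimnames = list(panel$subject_ids, panel$region_labels))
  n_censored <- 0L
  for (s in seq_len(S)) {
    per_subject[[s]] <- preprocessed[[s]] <- vector("list", R)
    for (r in seq_len(R)) {
      pre <- preprocess_brain_series(panel_series(panel, s, r), config)
      dyn <- dynamic_acw(pre, window, config$acw_kind,
                         interpolate = isTRUE(config$acw_interpolate))
      preprocessed[[s]][[r]] <- pre
      per_subject[[s]][[r]] <- dyn
      mean_acw[s, r] <- mean(dyn$values, na.rm = TRUE)
      n_censored <- n_censored + sum(dyn$censored)
    }
    names(per_subject[[s]]) <- names(preprocessed[[s]]) <- panel$region_labels
  }
  group_mean <- lapply(seq_len(R), function(r)
    group_mean_dynamic(lapply(per_subject, `[[`, r)))
  names(group_mean) <- panel$region_labels
  list(group_mean = group_mean, per_subject = per_subject,
       preprocessed = preprocessed, mean_acw_s = mean_acw,
       n_censored = n_censored, window = window, config = config)
}

#' Semantic pipeline: the two 1-Hz series and their dynamic ACWs
#'
#' Builds the per-second word-depth series and the windowed
#' sentence-similarity series from a timed transcript, then applies the same
#' sliding-window ACW as the brain pipeline. Semantic series are not
#' band-passed unless `config$filter_semantic` is set.
#'
#' @param transcript A [transcript()].
#' @param lexicon A [depth_lexicon()].
#' @param provider Embedding provider; defaults to the configured
#'   [toy_embedder()].
#' @param config Configuration list.
#' @param coverage_floor Warn when lexicon coverage falls below this
#'   fraction.
#' @return List with `word_depth`, `sentence_similarity` (each a list with
#'   `series` and `dynamic_acw`) and `coverage`.
#' @export
run_semantic_pipeline <- function(transcript, lexicon, provider = NULL,
                                  config = default_config(),
                                  coverage_floor = 0.5) {
  window <- config_window(config)
  if (is.null(provider))
    provider <- toy_embedder(config$embedder$dim, config$embedder$hash_seed,
                             config$embedder$signed)
  wd <- word_depth_series(transcript, lexicon)
  coverage <- attr(wd, "coverage")
  if (!is.na(coverage) && coverage < coverage_floor)
    warning(sprintf("lexicon coverage %.1f%% below the %.0f%% floor",
                    100 * coverage, 100 * coverage_floor))
  windows <- window_text(transcript, window)
  ss <- sentence_similarity_series(windows, provider)
  if (isTRUE(config$filter_semantic)) {
    wd <- bandpass(wd, config_bandpass(config))
    ss <- bandpass(ss, config_bandpass(config))
  }
  interp <- isTRUE(config$acw_interpolate)
  list(word_depth = list(
         series = wd,
         dynamic_acw = dynamic_acw(wd, window, config$acw_kind,
                                   interpolate = interp)),
       sentence_similarity = list(
         series = ss,
         dynamic_acw = dynamic_acw(ss, window, config$acw_kind,
                                   interpolate = interp)),
       coverage = coverage, window = window)
}

# dynamic series -> uniform series with missing windows linearly interpolated
# (constant-window gaps are rare and isolated; interpolation keeps the TE
# embedding rectangular)
dyn_to_uniform <- function(dyn) {
  v <- dyn$values
  if (anyNA(v)) {
    idx <- seq_along(v)
    v <- stats::approx(idx[!is.na(v)], v[!is.na(v)], xout = idx,
                       rule = 2)$y
    dyn <- dynamic_series(v, dyn$window_starts_s, dyn$window_length_s,
                          dyn$statistic_name)
  }
  as_uniform_series(dyn)
}

# shared machinery: build a recompute hook that maps (source uniform series,
# list of per-subject raw uniform series) -> TE per lag at the requested
# level, and run the block-bootstrap surrogate test around it.
te_test_level <- function(source_series, subject_series, config,
                          level = c("acw", "raw"),
                          direction = c("forward", "reverse"),
                          n_surrogates = NULL, seed = NULL) {
  level <- match.arg(level)
  direction <- match.arg(direction)
  if (is.null(n_surrogates)) n_surrogates <- config$n_surrogates
  if (is.null(seed)) seed <- config$seed
  window <- config_window(config)
  params <- config_te_params(config)
  kind <- config$acw_kind
  interp <- isTRUE(config$acw_interpolate)

  reduce <- if (level == "acw") {
    function(subj_list) {
      dyn_to_uniform(group_mean_dynamic(
        lapply(subj_list, dynamic_acw, window = window, kind = kind,
               interpolate = interp)))
    }
  } else {
    function(subj_list) {
      vals <- rowMeans(sapply(subj_list, function(s) s$values))
      uniform_series(vals, fs = subj_list[[1]]$fs, t0 = subj_list[[1]]$t0)
    }
  }
  src_series <- if (level == "acw")
    dyn_to_uniform(dynamic_acw(source_series, window, kind,
                               interpolate = interp))
  else source_series

  # the sliding-window statistic is heavily oversampled relative to its
  # innovation timescale: the TE embedding lives on a coarser grid of
  # embed_step_s block means, and the KSG neighbour search excludes a
  # Theiler band of theiler_s seconds (in embedded samples)
  d <- if (level == "acw")
    max(1L, as.integer(round(config$te$embed_step_s / window$step_s)))
  else 1L
  sec_per_sample <- if (level == "acw") d * window$step_s
                    else 1 / subject_series[[1]]$fs
  params$theiler <- as.integer(ceiling(config$te$theiler_s / sec_per_sample))
  recompute <- function(src, tgt, p) {
    brain <- reduce(tgt)
    al <- if (direction == "forward") align_series(src, brain)
          else align_series(brain, src)
    te_over_lags(bin_series(al$a, d), bin_series(al$b, d), p)
  }
  if (level == "acw") {
    # blocks must span several windows so the recomputed sliding-window
    # statistic keeps its local structure; the shuffle is coherent across
    # subjects so the group mean keeps its shared fluctuations
    block_len <- max(1, round(config$surrogate$block_windows *
                                window$length_s * subject_series[[1]]$fs))
    coherent <- isTRUE(config$surrogate$coherent)
  } else {
    # raw level: block length per subject follows its mean dynamic ACW
    block_len <- vapply(subject_series, function(s) {
      dyn <- dynamic_acw(s, window, kind)
      max(1, round(mean(dyn$values, na.rm = TRUE) * s$fs))
    }, numeric(1))
    coherent <- FALSE
  }
  # the brain side is always the shuffled side, whichever direction is tested
  res <- surrogate_test(src_series, subject_series, params,
                        n_surrogates = n_surrogates, block_len = block_len,
                        shuffle_side = "target", recompute = recompute,
                        seed = seed, coherent = coherent)
  res$level <- level
  res$direction <- direction
  res
}

#' Transfer-entropy test between a semantic input and a brain region
#'
#' Observed TE between the semantic series and the across-subject mean brain
#' series, at the timescale (`"acw"`) or raw level, with Markov
#' block-bootstrap significance: each subject's preprocessed signal is
#' shuffled in blocks matched to that subject's mean dynamic ACW, the full
#' downstream pipeline (dynamic ACW, group mean, alignment, TE) is recomputed
#' per surrogate, and the p-value per lag is the proportion of surrogate TE
#' values exceeding the observed one. `direction = "reverse"` tests
#' brain-to-input transfer (the brain side is still the shuffled side).
#'
#' @param source_series Semantic [uniform_series()] (raw; the ACW level
#'   derives its timescale series internally).
#' @param subject_series List of per-subject preprocessed [uniform_series()]
#'   for one region (e.g. `run_brain_pipeline()$preprocessed` sliced).
#' @param config Configuration list.
#' @param level `"acw"` (timescale-level, default) or `"raw"`.
#' @param direction `"forward"` (input to brain) or `"reverse"`.
#' @param n_surrogates,seed Override the configured values.
#' @return A `te_surrogate_result` with `level` and `direction` fields.
#' @export
semantic_brain_te <- function(source_series, subject_series,
                              config = default_config(),
                              level = "acw", direction = "forward",
                              n_surrogates = NULL, seed = NULL) {
  te_test_level(source_series, subject_series, config, level, direction,
                n_surrogates, seed)
}

#' Full TE analysis table
#'
#' Runs [semantic_brain_te()] for every requested combination of semantic
#' source, region, level and direction, and returns one row per lag in the
#' standard results layout.
#'
#' @param semantic Output of [run_semantic_pipeline()].
#' @param brain Output of [run_brain_pipeline()].
#' @param config Configuration list.
#' @param sources Semantic sources to test.
#' @param levels,directions Analysis levels and directions to include.
#' @param n_surrogates,seed Override the configured values.
#' @return Data frame with columns `source`, `target_region`, `level`,
#'   `direction`, `lag_s`, `te_nats`, `p_value`, `n_surrogates`, `seed`.
#' @export
run_te_analysis <- function(semantic, brain, config = default_config(),
                            sources = c("word_depth", "sentence_similarity"),
                            levels = c("acw", "raw"),
                            directions = "forward",
                            n_surrogates = NULL, seed = NULL) {
  if (is.null(n_surrogates)) n_surrogates <- config$n_surrogates
  if (is.null(seed)) seed <- config$seed
  regions <- names(brain$group_mean)
  rows <- list()
  for (src in sources) for (rg in regions) for (lv in levels)
    for (dir in directions) {
      subj <- lapply(brain$preprocessed, `[[`, rg)
      res <- semantic_brain_te(semantic[[src]]$series, subj, config,
                               level = lv, direction = dir,
                               n_surrogates = n_surrogates, seed = seed)
      lag_s <- if (lv == "acw") res$lags * config$te$embed_step_s
               else res$lags / subj[[1]]$fs
      rows[[length(rows) + 1]] <- data.frame(
        source = src, target_region = rg, level = lv, direction = dir,
        lag_s = lag_s,
        te_nats = unname(res$observed), p_value = res$p_value,
        n_surrogates = n_surrogates, seed = seed)
    }
  do.call(rbind, rows)
}

#' Write a TE results table to TSV
#'
#' @param te_table Data frame from [run_te_analysis()].
#' @param path Output file path.
#' @export
write_te_table <- function(te_table, path) {
  write.table(te_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-segment transfer entropy
#'
#' Restricts both series to each `[start_s, end_s]` segment and runs the
#' timescale-level TE test per segment. Segments too short for the window
#' plus the TE embedding are reported with a skip reason, never as silent
#' missing values.
#'
#' @param source_series Semantic [uniform_series()].
#' @param subject_series List of per-subject preprocessed [uniform_series()].
#' @param config Configuration list; `config$segments` holds the segment
#'   list.
#' @param n_surrogates,seed Override the configured values.
#' @return Data frame with one row per segment and lag (or one skip row).
#' @export
run_te_segments <- function(source_series, subject_series,
                            config = default_config(),
                            n_surrogates = NULL, seed = NULL) {
  if (is.null(n_surrogates)) n_surrogates <- config$n_surrogates
  if (is.null(seed)) seed <- config$seed
  window <- config_window(config)
  params <- config_te_params(config)
  # the TE embedding lives on the binned (embed_step_s) grid
  min_len <- window$length_s +
    (max(params$lag) + max(params$target_history, params$source_history) +
       params$k_neighbors + 2) * config$te$embed_step_s
  rows <- list()
  slice_to <- function(s, a, b) {
    al <- max(a, s$t0)
    bl <- min(b, s$t0 + (length(s$values) - 1) / s$fs)
    i0 <- as.integer(round((al - s$t0) * s$fs)) + 1L
    i1 <- as.integer(round((bl - s$t0) * s$fs)) + 1L
    uniform_series(s$values[i0:i1], fs = s$fs, t0 = al)
  }
  for (seg in config$segments) {
    seg_len <- seg[2] - seg[1]
    if (seg_len < min_len) {
      rows[[length(rows) + 1]] <- data.frame(
        segment_start_s = seg[1], segment_end_s = seg[2],
        lag_s = NA_real_, te_nats = NA_real_, p_value = NA_real_,
        skipped = TRUE,
        reason = sprintf("segment %g s shorter than window + TE embedding (%g s)",
                         seg_len, min_len))
      next
    }
    src <- slice_to(source_series, seg[1], seg[2])
    subj <- lapply(subject_series, slice_to, a = seg[1], b = seg[2])
    res <- te_test_level(src, subj, config, level = "acw",
                         direction = "forward",
                         n_surrogates = n_surrogates, seed = seed)
    rows[[length(rows) + 1]] <- data.frame(
      segment_start_s = seg[1], segment_end_s = seg[2],
      lag_s = res$lags * config$window$step_s,
      te_nats = unname(res$observed), p_value = res$p_value,
      skipped = FALSE, reason = "")
  }
  do.call(rbind, rows)
}

#' Window-size sweep of timescale-level transfer entropy
#'
#' Recomputes the observed timescale-level TE (first configured lag) for a
#' series of window lengths; with longer windows the timescale series is
#' smoother and shorter and TE is expected to fall.
#'
#' @param source_series Semantic [uniform_series()].
#' @param subject_series List of per-subject preprocessed [uniform_series()].
#' @param config Configuration list; `config$window_sweep_s` holds the
#'   window lengths in seconds.
#' @return Data frame with `window_s` and `te_nats`.
#' @export
window_size_sweep <- function(source_series, subject_series,
                              config = default_config()) {
  params <- config_te_params(config, lag = config$te$lags[1])
  kind <- config$acw_kind
  interp <- isTRUE(config$acw_interpolate)
  d <- max(1L, as.integer(round(config$te$embed_step_s /
                                  config$window$step_s)))
  params$theiler <- as.integer(ceiling(config$te$theiler_s /
                                         config$te$embed_step_s))
  out <- lapply(config$window_sweep_s, function(L) {
    window <- window_spec(L, config$window$step_s)
    src <- dyn_to_uniform(dynamic_acw(source_series, window, kind,
                                      interpolate = interp))
    brain <- dyn_to_uniform(group_mean_dynamic(
      lapply(subject_series, dynamic_acw, window = window, kind = kind,
             interpolate = interp)))
    al <- align_series(src, brain)
    data.frame(window_s = L,
               te_nats = transfer_entropy(bin_series(al$a, d),
                                          bin_series(al$b, d), params)$value)
  })
  do.call(rbind, out)
}

#' Welch PSD with the pipeline's edge handling
#'
#' Removes `trim_samples` at each end to mitigate edge effects, linearly
#' detrends, optionally band-passes (the brain pipeline's front end), then
#' estimates the Welch PSD.
#'
#' @param series A [uniform_series()].
#' @param config Configuration list (`config$psd` holds segment length,
#'   overlap and trim).
#' @param apply_bandpass Band-pass before the PSD (use for brain signals,
#'   not for semantic series).
#' @return List with `freq_hz` and `psd`.
#' @export
psd_pipeline <- function(series, config = default_config(),
                         apply_bandpass = FALSE) {
  k <- config$psd$trim_samples
  n <- length(series$values)
  s <- uniform_series(series$values[(k + 1):(n - k)], fs = series$fs,
                      t0 = series$t0 + k / series$fs)
  s <- linear_detrend(s)
  if (apply_bandpass) s <- bandpass(s, config_bandpass(config))
  welch_psd(s, config$psd$segment_s, config$psd$overlap_fraction)
}

#' Movie-vs-rest variance contrast of the dynamic timescale
#'
#' Pools the window values of the subject-mean dynamic ACW series per region
#' under two conditions and applies the Levene variance test; varying input
#' timescales should widen the timescale distribution during the movie.
#'
#' @param dyn_movie,dyn_rest [dynamic_series()] objects (e.g. the
#'   `group_mean` entries of two [run_brain_pipeline()] runs).
#' @return A `levene_result`.
#' @export
movie_rest_variance_contrast <- function(dyn_movie, dyn_rest) {
  a <- dyn_movie$values[!is.na(dyn_movie$values)]
  b <- dyn_rest$values[!is.na(dyn_rest$values)]
  levene_test(a, b)
}
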