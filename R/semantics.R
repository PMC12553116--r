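#' Timed transcript
#'
#' Ordered words with start and end times, the source of both semantic
#' series: per-second mean word depth and windowed sentence similarity.
#'
#' @param token Character vector of words.
#' @param start_s,end_s Word start/end times in seconds (`end_s >= start_s`).
#' @param duration_s Total duration in seconds; defaults to the ceiling of
#'   the last word's end time.
#' @return An object of class `transcript`: a data frame of words plus a
#'   `duration_s` attribute.
#' @export
transcript <- function(token, start_s, end_s = start_s, duration_s = NULL) {
  stopifnot(length(start_s) == length(token), length(end_s) == length(token))
  if (length(token) > 0 && (any(start_s < 0) || any(end_s < start_s)))
    stop("word times must satisfy 0 <= start_s <= end_s")
  ord <- order(start_s)
  df <- data.frame(token = as.character(token)[ord],
                   start_s = as.numeric(start_s)[ord],
                   end_s = as.numeric(end_s)[ord],
                   stringsAsFactors = FALSE)
  if (is.null(duration_s))
    duration_s <- if (nrow(df) > 0) ceiling(max(df$end_s)) else 0
  if (nrow(df) > 0 && any(df$start_s >= duration_s))
    stop("all word start times must fall before duration_s")
  structure(df, duration_s = as.numeric(duration_s),
            class = c("transcript", "data.frame"))
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript> %d words over %g s\n", nrow(x),
              attr(x, "duration_s")))
  invisible(x)
}

#' Read a timed transcript
#'
#' TSV with header `token`, `start_s`, `end_s`, or a JSON array of objects
#' with the same keys.
#'
#' @param path File path; format inferred from the extension (`.json` vs
#'   anything else as TSV).
#' @param duration_s Optional total duration override in seconds.
#' @return A [transcript()].
#' @export
read_transcript <- function(path, duration_s = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON transcripts requires the jsonlite package")
    df <- jsonlite::fromJSON(path)
  } else {
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  }
  transcript(df$token, df$start_s, df$end_s, duration_s = duration_s)
}

# lowercase + strip surrounding punctuation; no lemmatization.
normalize_token <- function(token) {
  gsub("^[[:punct:]]+|[[:punct:]]+$", "", tolower(token))
}

#' Word-depth lexicon
#'
#' Maps a token to its depth in a hypernym ("is-a") hierarchy. Lookup is
#' case-insensitive after token normalization (lowercasing and stripping of
#' surrounding punctuation).
#'
#' @param token Character vector of tokens.
#' @param depth Non-negative integer depths, one per token.
#' @return An object of class `depth_lexicon`.
#' @export
depth_lexicon <- function(token, depth) {
  stopifnot(length(token) == length(depth))
  if (any(depth < 0)) stop("depths must be non-negative")
  key <- normalize_token(token)
  depths <- as.numeric(depth)
  names(depths) <- key
  structure(list(depths = depths), class = "depth_lexicon")
}

#' @export
print.depth_lexicon <- function(x, ...) {
  cat(sprintf("<depth_lexicon> %d tokens, depths %g..%g\n",
              length(x$depths), min(x$depths), max(x$depths)))
  invisible(x)
}

#' Read a word-depth lexicon from TSV (`token<TAB>depth`)
#'
#' @param path File path.
#' @return A [depth_lexicon()].
#' @export
read_lexicon_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  depth_lexicon(df$token, df$depth)
}

#' Look up token depths
#'
#' @param lexicon A [depth_lexicon()].
#' @param token Character vector of tokens (normalized internally).
#' @return Numeric depths, `NA` where absent.
#' @export
lexicon_lookup <- function(lexicon, token) {
  stopifnot(inherits(lexicon, "depth_lexicon"))
  unname(lexicon$depths[normalize_token(token)])
}

#' Per-second word-depth series
#'
#' Bins words into one-second intervals `[b, b+1)` by their start time; each
#' bin receives the mean depth of its lexicon-covered words, and bins with no
#' covered words receive zero. Words absent from the lexicon are skipped and
#' counted in the `coverage` attribute.
#'
#' @param transcript A [transcript()].
#' @param lexicon A [depth_lexicon()].
#' @return A 1-Hz [uniform_series()] of length `duration_s`, with attributes
#'   `coverage` (fraction of words found in the lexicon) and `n_skipped`.
#' @export
word_depth_series <- function(transcript, lexicon) {
  stopifnot(inherits(transcript, "transcript"))
  duration <- attr(transcript, "duration_s")
  n_bins <- as.integer(ceiling(duration))
  vals <- numeric(n_bins)
  n_words <- nrow(transcript)
  coverage <- if (n_words == 0) 1 else NA_real_
  n_skipped <- 0L
  if (n_words > 0) {
    depths <- lexicon_lookup(lexicon, transcript$token)
    covered <- !is.na(depths)
    coverage <- mean(covered)
    n_skipped <- sum(!covered)
    if (any(covered)) {
      bin <- floor(transcript$start_s[covered]) + 1L  # 1-based
      means <- tapply(depths[covered], bin, mean)
      vals[as.integer(names(means))] <- as.numeric(means)
    }
  }
  out <- uniform_series(vals, fs = 1, t0 = 0)
  attr(out, "coverage") <- coverage
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Sliding text windows
#'
#' Concatenates, in temporal order, the tokens whose start time falls within
#' each window `[w, w + L)` (half-open: a word starting exactly at `w` is
#' included, one starting exactly at `w + L` is not).
#'
#' @param transcript A [transcript()].
#' @param window A [window_spec()].
#' @return Data frame with `start_s`, `end_s`, `text` (empty string for
#'   windows with no words).
#' @export
window_text <- function(transcript, window = window_spec()) {
  stopifnot(inherits(transcript, "transcript"))
  duration <- attr(transcript, "duration_s")
  L <- window$length_s
  step <- window$step_s
  if (duration < L) stop("transcript shorter than one window")
  n_win <- floor((duration - L) / step) + 1
  starts <- (seq_len(n_win) - 1) * step
  texts <- vapply(starts, function(w) {
    sel <- transcript$start_s >= w & transcript$start_s < w + L
    paste(transcript$token[sel], collapse = " ")
  }, character(1))
  data.frame(start_s = starts, end_s = starts + L, text = texts,
             stringsAsFactors = FALSE)
}

#' Cosine similarity between two vectors
#'
#' @param u,v Non-zero numeric vectors of equal length.
#' @return `dot(u, v) / (|u| |v|)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal dimension")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("degenerate (zero) embedding: cosine similarity undefined")
  min(1, max(-1, sum(u * v) / (nu * nv)))  # clamp rounding spill
}

#' Sentence-similarity series from windowed text
#'
#' Value `k` is the cosine similarity between the embeddings of windows `k`
#' and `k + 1`, indexed by the earlier window's start time. Windows with no
#' speech embed to a zero-speech sentinel; any similarity involving a
#' sentinel is set to 0, which keeps the series defined across rest gaps.
#'
#' @param windows Output of [window_text()].
#' @param provider An embedding provider, e.g. [toy_embedder()]: a list with
#'   `embed(text)` returning a fixed-dimension numeric vector or `NULL` for
#'   empty text, and a `dim` field.
#' @return A [uniform_series()] at `1/step` Hz (one value per window pair).
#' @export
sentence_similarity_series <- function(windows, provider) {
  if (nrow(windows) < 3)
    stop("need at least 3 windows to form a similarity series")
  emb <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    emb[[i]] <- tryCatch(provider$embed(windows$text[i]),
                         error = function(e)
                           stop("embedding failed at window ", i, " (start ",
                                windows$start_s[i], " s): ",
                                conditionMessage(e)))
  }
  vals <- numeric(nrow(windows) - 1)
  for (k in seq_along(vals)) {
    a <- emb[[k]]; b <- emb[[k + 1]]
    vals[k] <- if (is.null(a) || is.null(b)) 0 else cosine_similarity(a, b)
  }
  step <- if (nrow(windows) > 1) windows$start_s[2] - windows$start_s[1] else 1
  uniform_series(vals, fs = 1 / step, t0 = windows$start_s[1])
}
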