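test_that("word_depth_series bins by start time with zero for empty bins", {
  # empty transcript: all zeros
  empty <- transcript(character(0), numeric(0), numeric(0), duration_s = 10)
  lex <- make_test_lexicon()
  s <- word_depth_series(empty, lex)
  expect_equal(s$values, rep(0, 10))

  # one covered word of depth 7 starting at 3.2 s
  tr1 <- transcript("dog", 3.2, 3.5, duration_s = 10)
  s1 <- word_depth_series(tr1, lex)
  expect_equal(s1$values, c(0, 0, 0, 7, 0, 0, 0, 0, 0, 0))

  # two words in one second average their depths
  tr2 <- transcript(c("freedom", "dog"), c(3.1, 3.8), c(3.4, 4.0),
                    duration_s = 6)
  expect_equal(word_depth_series(tr2, lex)$values[4], 6)  # (5 + 7) / 2

  # unknown words are skipped and reported in the coverage
  tr3 <- make_test_transcript()
  s3 <- word_depth_series(tr3, lex)
  expect_equal(attr(s3, "coverage"), 0.8)
  expect_equal(attr(s3, "n_skipped"), 1L)
})

test_that("word depth mass is conserved and bounded", {
  gen <- gen_transcript(duration_s = 300, word_rate_hz = 2, seed = 7)
  s <- word_depth_series(gen$transcript, gen$lexicon)
  depths <- lexicon_lookup(gen$lexicon, gen$transcript$token)
  bins <- floor(gen$transcript$start_s)
  counts <- table(bins)
  mass <- sum(s$values[as.integer(names(counts)) + 1] * as.integer(counts))
  expect_equal(mass, sum(depths))
  expect_true(all(s$values >= 0))
  expect_lte(max(s$values), max(depths))
})

test_that("integer time shifts translate both semantic series exactly", {
  gen <- gen_transcript(duration_s = 200, word_rate_hz = 1.5, seed = 3)
  tr <- gen$transcript
  k <- 5
  shifted <- transcript(tr$token, tr$start_s + k, tr$end_s + k,
                        duration_s = attr(tr, "duration_s") + k)
  a <- word_depth_series(tr, gen$lexicon)$values
  b <- word_depth_series(shifted, gen$lexicon)$values
  expect_equal(b[(k + 1):length(b)], a[1:(length(b) - k)])

  w <- window_spec(30, 1)
  prov <- toy_embedder(32, 1)
  sa <- sentence_similarity_series(window_text(tr, w), prov)$values
  sb <- sentence_similarity_series(window_text(shifted, w), prov)$values
  expect_equal(sb[(k + 1):length(sb)], sa[1:(length(sb) - k)])
})

test_that("window_text applies the half-open start-time rule", {
  tr <- transcript(c("a", "b", "c"), c(0, 10, 70), c(1, 11, 71),
                   duration_s = 130)
  w <- window_text(tr, window_spec(60, 10))
  expect_equal(nrow(w), 8L)  # floor((130 - 60) / 10) + 1
  expect_equal(w$text[1], "a b")          # starts 0 and 10 fall in [0, 60)
  expect_equal(w$text[2], "b")            # 70 = 10 + 60 exactly: excluded
  expect_false(grepl("c", w$text[1]))     # 70 is exactly at 0 + 60: excluded
  # a word starting exactly at the window start is included
  expect_equal(w$text[8], "c")            # window [70, 130) starts on c
})

test_that("897-s transcript yields 838 60-s windows", {
  gen <- gen_transcript(duration_s = 897, word_rate_hz = 1, seed = 1)
  w <- window_text(gen$transcript, window_spec(60, 1))
  expect_equal(nrow(w), 838L)
})

test_that("cosine_similarity obeys its closed-form cases", {
  u <- c(1, 2, 3)
  expect_equal(cosine_similarity(u, u), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(u, -u), -1)
  expect_error(cosine_similarity(u, c(0, 0, 0)), "degenerate")
  expect_error(cosine_similarity(u, c(1, 2)), "equal dimension")
})

test_that("sentence similarity: identical, disjoint and empty windows", {
  prov <- toy_embedder(64, 1)
  w <- data.frame(start_s = 0:2, end_s = 3:5,
                  text = c("the red fox", "the red fox", "green idea sleeps"))
  s <- sentence_similarity_series(w, prov)
  expect_equal(s$values[1], 1)
  expect_lt(abs(s$values[2]), 0.999)  # different vocab -> similarity drops

  # fully disjoint vocabularies give ~0 (no collisions for these tokens)
  w2 <- data.frame(start_s = 0:2, end_s = 3:5,
                   text = c("alpha beta gamma", "delta epsilon zeta",
                            "alpha beta gamma"))
  expect_lt(max(abs(sentence_similarity_series(w2, prov)$values)), 1e-12)

  # empty windows are the zero-speech sentinel: similarity forced to 0
  w3 <- data.frame(start_s = 0:2, end_s = 3:5,
                   text = c("words here", "", "more words"))
  expect_equal(sentence_similarity_series(w3, prov)$values, c(0, 0))
})

test_that("similarity values stay in [-1,1], and in [0,1] unsigned", {
  gen <- gen_transcript(duration_s = 300, word_rate_hz = 2, seed = 11)
  w <- window_text(gen$transcript, window_spec(60, 1))
  s_signed <- sentence_similarity_series(w, toy_embedder(64, 1))
  expect_true(all(s_signed$values >= -1 & s_signed$values <= 1))
  expect_equal(length(s_signed$values), nrow(w) - 1L)
  s_unsigned <- sentence_similarity_series(w, toy_embedder(64, 1,
                                                           signed = FALSE))
  expect_true(all(s_unsigned$values >= 0 & s_unsigned$values <= 1))
})

test_that("overlapping 60-s windows over running speech stay similar", {
  gen <- gen_transcript(duration_s = 400, word_rate_hz = 2, seed = 21)
  w <- window_text(gen$transcript, window_spec(60, 1))
  s <- sentence_similarity_series(w, toy_embedder(64, 1))
  expect_gt(mean(s$values > 0.9), 0.9)
})

test_that("transcript and lexicon I/O round-trip", {
  tr <- make_test_transcript()
  p <- withr::local_tempfile(fileext = ".tsv")
  write.table(as.data.frame(tr), p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read_transcript(p, duration_s = 10)
  expect_equal(back$token, tr$token)
  expect_equal(attr(back, "duration_s"), 10)

  lp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("token\tdepth", "Dog\t7", "cat\t7"), lp)
  lex <- read_lexicon_tsv(lp)
  expect_equal(lexicon_lookup(lex, c("dog", "DOG,", "cat", "mouse")),
               c(7, 7, 7, NA))
})
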