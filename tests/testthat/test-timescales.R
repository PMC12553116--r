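test_that("acf_biased matches hand-evaluated examples", {
  expect_equal(acf_biased(uniform_series(c(1, 2, 3, 4)), 1)$acf,
               c(1, 0.25))
  expect_equal(acf_biased(uniform_series(c(1, -1, 1, -1)), 1)$acf,
               c(1, -0.75))
  s <- gen_ar1(0.5, n = 50, seed = 2)
  expect_equal(acf_biased(s, 10)$acf[1], 1)
})

test_that("acf_biased equals the brute-force ratio to 1e-12 on random input", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(20:200, 1)
    x <- rnorm(n)
    ml <- sample(1:(n - 1), 1)
    expect_equal(acf_biased(uniform_series(x), ml)$acf, brute_acf(x, ml),
                 tolerance = 1e-12)
  }
})

test_that("biased estimator keeps |acf| <= 1 and acf[0] = 1", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- cumsum(rnorm(80))  # strongly autocorrelated
    a <- acf_biased(uniform_series(x), 79)$acf
    expect_equal(a[1], 1)
    expect_true(all(abs(a) <= 1 + 1e-12))
  }
})

test_that("acf errors on degenerate input and bad lags", {
  expect_error(acf_biased(uniform_series(rep(2, 10)), 3), "constant")
  expect_error(acf_biased(uniform_series(1:10), 10), "max_lag")
  expect_error(acf_biased(uniform_series(1:10), 0), "max_lag")
})

test_that("acw variants find the stated first crossings", {
  r <- structure(list(acf = c(1, 0.6, 0.2, -0.1), fs = 1),
                 class = "acf_result")
  expect_equal(as.numeric(acw(r, "acw0")), 3)
  expect_equal(as.numeric(acw(r, "acw50")), 2)
  expect_equal(as.numeric(acw(r, "acwe")), 2)
  expect_false(attr(acw(r, "acw0"), "censored"))
  # no crossing: censored at max lag
  r2 <- structure(list(acf = c(1, 0.9, 0.8), fs = 2), class = "acf_result")
  a <- acw(r2, "acw0")
  expect_equal(as.numeric(a), 1)  # 2 lags at 2 Hz
  expect_true(attr(a, "censored"))
})

test_that("acw thresholds are monotone: acw50 <= acwe <= acw0", {
  for (seed in 1:10) {
    s <- gen_ar1(runif(1, 0.2, 0.95), n = 400, seed = seed)
    r <- acf_biased(s, 399)
    expect_lte(as.numeric(acw(r, "acw50")), as.numeric(acw(r, "acwe")))
    expect_lte(as.numeric(acw(r, "acwe")), as.numeric(acw(r, "acw0")))
  }
})

test_that("AR(1) acw50 approaches the analytic crossing", {
  # at phi = 0.7 the true ACF sits at 0.49 on lag 2, a hair under the 0.5
  # threshold; a long series keeps the sample crossing on the right side
  s <- gen_ar1(0.7, n = 2e5, seed = 42)
  a <- as.numeric(acw(acf_biased(s, 100), "acw50"))
  expect_lt(abs(a - analytic_acw50(0.7)) / analytic_acw50(0.7), 0.2)
  # the continuous (interpolated) crossing recovers the analytic value
  ai <- as.numeric(acw(acf_biased(s, 100), "acw50", interpolate = TRUE))
  expect_lt(abs(ai - analytic_acw50(0.7)) / analytic_acw50(0.7), 0.05)
})

test_that("linear_detrend removes ramps and keeps orthogonal components", {
  t <- 1:100
  ramp <- uniform_series(3 * t + 2)
  expect_lt(max(abs(linear_detrend(ramp)$values)), 1e-9)
  # a sinusoid even-symmetric about the data midpoint is orthogonal to the
  # linear trend over whole periods (an arbitrary-phase sinusoid is not
  # exactly so in discrete time)
  cosine <- cos(2 * pi * 0.1 * ((0:99) - 49.5))
  out <- linear_detrend(uniform_series(cosine))
  expect_lt(max(abs(out$values - cosine)), 1e-6)
  comp <- uniform_series((0:99) + cosine)
  out2 <- linear_detrend(comp)
  expect_lt(max(abs(out2$values - cosine)), 1e-6)
  expect_lt(abs(mean(out2$values)), 1e-10)
})

test_that("bandpass preserves passband tones and kills DC and slow drift", {
  t <- 0:999
  tone <- uniform_series(sin(2 * pi * 0.2 * t), fs = 1)
  y <- bandpass(tone, bandpass_spec(0.05, 0.5, 3))$values
  mid <- 200:800
  amp <- (max(y[mid]) - min(y[mid])) / 2
  expect_lt(abs(amp - 1), 0.05)

  const <- uniform_series(rep(5, 1000), fs = 1)
  expect_lt(max(abs(bandpass(const)$values)), 1e-3)

  slow <- uniform_series(sin(2 * pi * 0.01 * t), fs = 1)
  ys <- bandpass(slow)$values
  expect_lt(sqrt(mean(ys[mid]^2)), 0.2 * sqrt(mean(slow$values[mid]^2)))

  expect_error(bandpass(tone, bandpass_spec(0.05, 0.6)), "Nyquist")
})

test_that("bandpass is nearly idempotent in the passband", {
  t <- 0:999
  tone <- uniform_series(sin(2 * pi * 0.2 * t), fs = 1)
  once <- bandpass(tone)
  twice <- bandpass(once)
  mid <- 200:800
  amp1 <- (max(once$values[mid]) - min(once$values[mid])) / 2
  amp2 <- (max(twice$values[mid]) - min(twice$values[mid])) / 2
  expect_lt(abs(amp2 - amp1) / amp1, 0.1)
})

test_that("dynamic_acw window count and grid ordering", {
  s <- gen_ar1(0.5, n = 897, seed = 3)
  d <- dynamic_acw(s, window_spec(60, 1), "acw0")
  expect_equal(length(d$values), 838L)
  expect_equal(d$window_starts_s[1], 0)
  expect_equal(d$window_length_s, 60)

  means <- sapply(c(0.3, 0.6, 0.9), function(phi)
    mean(dynamic_acw(gen_ar1(phi, n = 900, seed = 11), window_spec(60, 1),
                     "acw50")$values, na.rm = TRUE))
  expect_true(all(diff(means) > 0))
})

test_that("dynamic_acw mean tracks the analytic AR(1) timescale", {
  d <- dynamic_acw(gen_ar1(0.8, n = 2000, seed = 7), window_spec(60, 1),
                   "acw50")
  expect_lt(abs(mean(d$values) - analytic_acw50(0.8)) / analytic_acw50(0.8),
            0.25)
})

test_that("a timescale change shows up in the windowed ACW halves", {
  a <- gen_ar1(0.95, n = 450, seed = 1)$values
  b <- gen_ar1(0.2, n = 450, seed = 2)$values
  d <- dynamic_acw(uniform_series(c(a, b)), window_spec(60, 1), "acw0")
  n <- length(d$values)
  first <- d$values[1:(n %/% 2)]
  last <- d$values[(n %/% 2 + 1):n]
  expect_gt(mean(first, na.rm = TRUE), mean(last, na.rm = TRUE))
})

test_that("constant windows yield missing values, not an abort", {
  x <- c(rep(1, 80), rnorm(120))
  d <- dynamic_acw(uniform_series(x), window_spec(60, 1), "acw0")
  expect_true(any(is.na(d$values)))
  expect_true(any(!is.na(d$values)))
})

test_that("welch_psd peaks at the tone and integrates to the variance", {
  t <- 0:2047
  tone <- uniform_series(sin(2 * pi * 0.2 * t) + 0.05 * rnorm(2048), fs = 1)
  p <- welch_psd(tone, segment_s = 256)
  expect_lt(abs(p$freq_hz[which.max(p$psd)] - 0.2), 1 / 256 + 1e-9)

  set.seed(5)
  wn <- uniform_series(rnorm(10000), fs = 1)
  pw <- welch_psd(wn, segment_s = 125)
  df <- pw$freq_hz[2] - pw$freq_hz[1]
  expect_lt(abs(sum(pw$psd) * df - var(wn$values)) / var(wn$values), 0.1)
  # flat spectrum after mild smoothing
  sm <- stats::filter(pw$psd, rep(1 / 8, 8))
  sm <- sm[!is.na(sm)]
  expect_lt(max(sm) / min(sm), 3)

  expect_error(welch_psd(uniform_series(rnorm(50)), segment_s = 100),
               "longer than the series")
})
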