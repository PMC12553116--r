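# Independent brute-force oracles, kept deliberately naive so they share no
# code path with the implementation.

# direct evaluation of the biased autocorrelation ratio
brute_acf <- function(x, max_lag) {
  n <- length(x)
  xbar <- mean(x)
  v <- sum((x - xbar)^2) / n
  sapply(0:max_lag, function(m) {
    s <- 0
    for (t in 1:(n - m)) s <- s + (x[t] - xbar) * (x[t + m] - xbar)
    (s / n) / v
  })
}

# Levene W from the textbook formula, loop form
brute_levene_W <- function(groups) {
  k <- length(groups)
  z <- lapply(groups, function(g) abs(g - mean(g)))
  N <- sum(lengths(groups))
  zdd <- mean(unlist(z))
  num <- 0; den <- 0
  for (g in 1:k) {
    zi <- mean(z[[g]])
    num <- num + length(z[[g]]) * (zi - zdd)^2
    for (val in z[[g]]) den <- den + (val - zi)^2
  }
  ((N - k) / (k - 1)) * num / den
}

# AR(1) analytic ACW-50 in lag units
analytic_acw50 <- function(phi) log(0.5) / log(phi)

make_test_transcript <- function() {
  transcript(token = c("dog", "cat", "freedom", "apple", "unknownword"),
             start_s = c(0.5, 3.2, 3.9, 7.0, 8.5),
             end_s = c(0.9, 3.6, 4.4, 7.3, 8.9),
             duration_s = 10)
}

make_test_lexicon <- function() {
  depth_lexicon(c("dog", "cat", "freedom", "apple"), c(7, 7, 5, 8))
}
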