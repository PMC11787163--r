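# Independent oracles used across the suite. These are deliberately naive
# (loop-based, closed-form) and share no code with the package internals.

# Brute-force n-back scorer: literal scan.
oracle_score_nback <- function(letters, lag) {
  count <- 0L
  for (i in seq_along(letters)) {
    if (i > lag && letters[i] == letters[i - lag]) count <- count + 1L
  }
  count
}

# Naive first-order DFA, window by window with lm().
oracle_dfa_alpha <- function(x, window_sizes) {
  N <- length(x)
  prof <- cumsum(x - mean(x))
  Fn <- numeric(length(window_sizes))
  for (j in seq_along(window_sizes)) {
    n <- window_sizes[j]
    k <- N %/% n
    ss <- 0; m <- 0L
    for (w in seq_len(k)) {
      seg <- prof[((w - 1) * n + 1):(w * n)]
      t <- seq_len(n)
      r <- stats::residuals(stats::lm(seg ~ t))
      ss <- ss + sum(r^2); m <- m + n
    }
    Fn[j] <- sqrt(ss / m)
  }
  unname(stats::coef(stats::lm(log10(Fn) ~ log10(window_sizes)))[2])
}

# Squared magnitude response of a zero-phase digital Butterworth filter
# (bilinear transform with prewarped cutoff), amplitude ratio.
oracle_butter_zerophase_gain <- function(f, cutoff, fs, order, type = "low") {
  r <- tan(pi * f / fs) / tan(pi * cutoff / fs)
  one_pass_sq <- if (type == "low") 1 / (1 + r^(2 * order)) else
    r^(2 * order) / (1 + r^(2 * order))
  one_pass_sq  # forward-backward pass has amplitude |H|^2
}

# Small helper: mean DFA estimate of package-generated fractal series.
mean_recovered_alpha <- function(alpha, n, seeds) {
  mean(vapply(seeds, function(s) dfa(generate_fractal_series(n, alpha, s))$alpha,
              numeric(1)))
}

make_trial <- function(x, y, fs = 100, ...) {
  cop_trial(time = (seq_along(x) - 1) / fs, x = x, y = y, sampling_rate = fs, ...)
}
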