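# Independent brute-force oracles used to cross-check the implementation.
# They deliberately share no code with the package internals.

# Ordinal pattern id by explicit comparison counting over the permutation
# of stable ranks (Lehmer code, most-significant digit first).
naive_pattern_id <- function(w) {
  m <- length(w)
  # stable ranks: position of each element in the sorted order,
  # earlier occurrence wins ties
  perm <- order(w)        # order() is stable
  # Lehmer code of the inverse view: digit i = later elements smaller
  id <- 0
  for (i in 1:(m - 1)) {
    cnt <- 0
    for (j in (i + 1):m) if (w[j] < w[i]) cnt <- cnt + 1
    id <- id + cnt * factorial(m - i)
  }
  id
}

# Permutation entropy by naive per-window pattern counting.
naive_permutation_entropy <- function(x, m, normalize = TRUE) {
  n <- length(x) - m + 1
  ids <- vapply(seq_len(n), function(s) naive_pattern_id(x[s:(s + m - 1)]),
                numeric(1))
  p <- table(ids) / n
  h <- -sum(p * log(p))
  if (normalize) h / log(factorial(m)) else h
}

# Exact two-sided rank-sum p-value by enumeration of all group assignments.
enum_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(a)])
  mu <- length(a) * (n + 1) / 2
  sets <- utils::combn(n, length(a))
  w_all <- apply(sets, 2, function(ix) sum(r[ix]))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# Log-log spectral slope via Welch PSD from an independent route
# (spec.pgram-based averaging is avoided; plain segment periodograms).
fit_loglog_slope <- function(x, fs, fmin = 5, fmax = 300, seg_s = 8) {
  nseg <- seg_s * fs
  ns <- floor(length(x) / nseg)
  acc <- NULL
  for (k in seq_len(ns)) {
    seg <- x[((k - 1) * nseg + 1):(k * nseg)]
    seg <- seg - mean(seg)
    P <- Mod(fft(seg))^2
    acc <- if (is.null(acc)) P else acc + P
  }
  P <- acc / ns
  f <- (0:(nseg - 1)) * fs / nseg
  sel <- f >= fmin & f <= fmax
  unname(coef(lm(log10(P[sel]) ~ log10(f[sel])))[2])
}

# Dominant frequency of a signal by zero-padded periodogram argmax.
periodogram_peak_hz <- function(x, fs) {
  n <- length(x)
  P <- Mod(fft(x - mean(x)))^2
  f <- (0:(n - 1)) * fs / n
  half <- f > 0 & f < fs / 2
  f[half][which.max(P[half])]
}

# Analytic-signal phase via an independent minimal construction.
naive_band_phase <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- fft(x)
  f <- (0:(n - 1)) * fs / n
  keep <- (f >= lo & f <= hi)
  X[!keep] <- 0
  z <- fft(X, inverse = TRUE) / n  # analytic: negative freqs are zeroed
  Arg(z)
}

expect_wrapped_close <- function(a, b, tol) {
  d <- atan2(sin(a - b), cos(a - b))
  expect_lt(abs(d), tol)
}

unwrap_phase <- function(p) cumsum(c(p[1], atan2(sin(diff(p)), cos(diff(p)))))

resultant_length_oracle <- function(theta) Mod(mean(exp(1i * theta)))
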