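# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

#' @noRd
hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# Welch power spectral density with Hann-tapered, demeaned, overlapping
# modified periodograms. One-sided density in input-units^2/Hz; the DC bin is
# dropped (windows are demeaned).
welch_psd <- function(x, fs, nwin, overlap = 0.5) {
  n <- length(x)
  stop_if(n < nwin, "signal shorter than one window (", nwin, " samples)")
  step <- max(1L, as.integer(round(nwin * (1 - overlap))))
  starts <- seq.int(1L, n - nwin + 1L, by = step)
  w <- hann_window(nwin)
  u <- sum(w^2)
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + nwin - 1L)]
    (seg - mean(seg)) * w
  }, numeric(nwin))
  X <- stats::mvfft(segs)
  nf <- nwin %/% 2L
  psd <- rowMeans(Mod(X[2:(nf + 1L), , drop = FALSE])^2) * 2 / (fs * u)
  # the Nyquist bin should not carry the one-sided doubling
  if (nwin %% 2L == 0L) psd[nf] <- psd[nf] / 2
  list(freq = (1:nf) * fs / nwin, psd = psd, n_windows = length(starts))
}

# Per-window modified periodograms (no averaging); returns windows in columns.
welch_periodograms <- function(x, fs, nwin, overlap = 0.5) {
  n <- length(x)
  stop_if(n < nwin, "signal shorter than one window (", nwin, " samples)")
  step <- max(1L, as.integer(round(nwin * (1 - overlap))))
  starts <- seq.int(1L, n - nwin + 1L, by = step)
  w <- hann_window(nwin)
  u <- sum(w^2)
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + nwin - 1L)]
    (seg - mean(seg)) * w
  }, numeric(nwin))
  X <- stats::mvfft(segs)
  nf <- nwin %/% 2L
  P <- Mod(X[2:(nf + 1L), , drop = FALSE])^2 * 2 / (fs * u)
  if (nwin %% 2L == 0L) P[nf, ] <- P[nf, ] / 2
  list(freq = (1:nf) * fs / nwin, power = P,
       time = (starts - 1L) / fs + nwin / fs / 2)
}

# Aggregate a PSD on a fine regular grid onto a coarser grid by averaging the
# native bins nearest each output center (bin j <- natives in
# [j*df_out - df_out/2, j*df_out + df_out/2)).
aggregate_psd <- function(freq, p, df_out = 0.5, fmax = 300) {
  grp <- floor(freq / df_out + 0.5)
  keep <- grp >= 1 & grp * df_out <= fmax
  grp <- grp[keep]
  if (is.matrix(p)) {
    p <- p[keep, , drop = FALSE]
    out <- rowsum(p, grp) / as.vector(table(grp))
    list(freq = as.numeric(rownames(out)) * df_out, p = unname(out))
  } else {
    p <- p[keep]
    out <- rowsum(cbind(p), grp) / as.vector(table(grp))
    list(freq = as.numeric(rownames(out)) * df_out, p = as.numeric(out))
  }
}

# Fourier resampling of a real series to m samples (ideal low-pass for
# downsampling under the periodic extension).
fft_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x)
  kf <- floor((min(n, m) - 1) / 2)
  Y <- complex(real = numeric(m))
  Y[1] <- X[1]
  if (kf >= 1) {
    Y[2:(kf + 1)] <- X[2:(kf + 1)]
    Y[m:(m - kf + 1)] <- X[n:(n - kf + 1)]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

# Analytic signal via half-spectrum doubling; Arg() of the result is the
# instantaneous phase.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n %/% 2L + 1L)] <- 1
    h[2:(n %/% 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) %/% 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Wrap angles to (-pi, pi].
wrap_pi <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

circular_mean <- function(theta) Arg(mean(exp(1i * theta)))

resultant_length <- function(theta) Mod(mean(exp(1i * theta)))

check_finite_scalar <- function(x, name) {
  stop_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
          sprintf("`%s` must be a single finite number", name))
  invisible(x)
}
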