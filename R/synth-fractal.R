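#' Generate a 1/f^alpha arrhythmic background signal
#'
#' Synthesizes a stationary Gaussian time series whose power spectrum follows
#' \eqn{f^{-\alpha}} by spectral shaping of white Gaussian noise: random
#' phases are imposed on a frequency-domain amplitude envelope
#' \eqn{|H(f)| \propto f^{-\alpha/2}} and transformed back. This emulates the
#' arrhythmic (fractal) component of LFP recordings against which rhythmic
#' activity is normalized.
#'
#' @param duration_s Duration in seconds (> 0).
#' @param fs Sampling rate in Hz (> 0).
#' @param exponent Spectral exponent alpha (>= 0); 0 gives white noise.
#' @param scale Target signal variance (micro-V^2). The output is rescaled so
#'   its empirical variance equals `scale` exactly.
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return Numeric vector of `duration_s * fs` samples (micro-V).
#' @examples
#' x <- generate_fractal_signal(10, 500, exponent = 2, seed = 1)
#' var(x)
#' @export
generate_fractal_signal <- function(duration_s, fs, exponent, scale = 1,
                                    seed = NULL) {
  check_finite_scalar(duration_s, "duration_s")
  check_finite_scalar(fs, "fs")
  check_finite_scalar(exponent, "exponent")
  check_finite_scalar(scale, "scale")
  stop_if(duration_s <= 0, "`duration_s` must be > 0")
  stop_if(fs <= 0, "`fs` must be > 0")
  stop_if(exponent < 0, "`exponent` must be >= 0")
  stop_if(scale < 0, "`scale` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration_s * fs))
  stop_if(n < 4L, "signal too short")
  nf <- (n - 1L) %/% 2L
  f <- (1:nf) * fs / n
  amp <- f^(-exponent / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  full <- complex(real = numeric(n))
  full[2:(nf + 1L)] <- complex(modulus = amp, argument = ph)
  full[n:(n - nf + 1L)] <- Conj(full[2:(nf + 1L)])
  if (n %% 2L == 0L) {
    fnyq <- (n / 2) * fs / n
    full[n %/% 2L + 1L] <- fnyq^(-exponent / 2) * sample(c(-1, 1), 1L)
  }
  x <- Re(stats::fft(full, inverse = TRUE))
  if (scale == 0) return(numeric(n))
  x / stats::sd(x) * sqrt(scale)
}
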