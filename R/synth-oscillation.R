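#' Draw samples from a von Mises (circular normal) distribution
#'
#' Best–Fisher rejection sampler. Used by the synthetic-data generator to
#' impose a controlled concentration on cross-channel phase offsets;
#' `kappa = Inf` returns the mean direction exactly.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0, may be `Inf`).
#' @return Numeric vector of angles wrapped to (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stop_if(kappa < 0, "`kappa` must be >= 0")
  if (n == 0L) return(numeric(0))
  if (!is.finite(kappa)) return(rep(wrap_pi(mu), n))
  if (kappa < 1e-8) return(wrap_pi(stats::runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- max(16L, as.integer(ceiling((n - got) * 1.5)))
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    fz <- (1 + r * z) / (r + z)
    cc <- kappa * (r - fz)
    u2 <- stats::runif(m)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    acc <- fz[ok]
    if (length(acc)) {
      take <- min(length(acc), n - got)
      u3 <- stats::runif(take)
      out[(got + 1L):(got + take)] <- sign(u3 - 0.5) * acos(acc[seq_len(take)])
      got <- got + take
    }
  }
  wrap_pi(out + mu)
}

# Complex analytic narrowband carrier: Gaussian spectral envelope centered at
# center_f with full width at half maximum (of power) = bandwidth; unit
# variance of the real part.
make_burst_carrier <- function(n, fs, center_f, bandwidth) {
  sigma_g <- bandwidth / (2 * sqrt(log(2) / 2))
  f <- (0:(n - 1)) * fs / n
  g <- exp(-((f - center_f) / sigma_g)^2)
  g[f <= 0 | f >= fs / 2] <- 0
  ph <- stats::runif(n, 0, 2 * pi)
  z <- stats::fft(g * exp(1i * ph), inverse = TRUE) / n
  s <- stats::sd(Re(z))
  if (s > 0) z <- z / (s * sqrt(2))  # Re(z) unit variance after rotation
  z
}

# Slow phase drift: low-pass-filtered white noise rescaled to `sd_rad`.
make_phase_drift <- function(n, fs, sd_rad, cutoff_hz = 1) {
  if (sd_rad <= 0 || n < 8L) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  W[f > cutoff_hz] <- 0
  d <- Re(stats::fft(W, inverse = TRUE)) / n
  s <- stats::sd(d)
  if (s == 0) return(numeric(n))
  d / s * sd_rad
}

validate_schedule <- function(episode_schedule, duration_s) {
  stop_if(!is.data.frame(episode_schedule) ||
            !all(c("start_s", "end_s") %in% names(episode_schedule)),
          "`episode_schedule` must be a data.frame with start_s and end_s")
  es <- episode_schedule[order(episode_schedule$start_s), , drop = FALSE]
  stop_if(any(es$end_s <= es$start_s), "episodes must have end_s > start_s")
  stop_if(any(es$start_s < 0) || any(es$end_s > duration_s + 1e-9),
          "episode schedule extends outside the signal duration")
  if (nrow(es) > 1L)
    stop_if(any(es$start_s[-1L] < es$end_s[-nrow(es)]),
            "episodes must not overlap")
  es
}

#' Generate a multichannel narrowband oscillatory component
#'
#' Synthesizes band-limited oscillation episodes shared across channels. A
#' common complex carrier (Gaussian spectral envelope, FWHM = `bandwidth`)
#' drives every channel; channel `k` is rotated by `channel_phase_lags[k]`
#' plus a per-episode von Mises offset drawn with concentration `kappa` for
#' its offset group. The first offset group acts as phase reference (zero
#' offset), so phase differences against it have exactly the configured
#' concentration. Outside episodes the component is zero.
#'
#' Amplitude semantics: `amplitude_db` is the target rhythmic peak height in
#' dB above the fractal background at `center_f`
#' (\eqn{10 \log_{10}(\mathrm{total}/\mathrm{fractal})}). When `background`
#' is supplied the component is calibrated empirically against its measured
#' spectrum (per channel, or on consecutive-pair differences when
#' `calibrate = "bipolar"`, matching how the analysis pipeline measures
#' power). `amplitude_db = 0` gives an all-zero component. Without a
#' background the episodes have unit RMS.
#'
#' @param fs Sampling rate (Hz).
#' @param duration_s Total duration (s).
#' @param center_f Center frequency (Hz); `center_f + bandwidth/2` must be
#'   below Nyquist.
#' @param bandwidth Full width at half maximum of the burst power spectrum
#'   (Hz), 0 < bandwidth < center_f.
#' @param amplitude_db Peak height in dB above the fractal background (>= 0).
#' @param episode_schedule data.frame with `start_s`, `end_s` (non-
#'   overlapping, within duration). Optional column `center_f` overrides the
#'   per-episode center frequency.
#' @param channel_phase_lags Numeric vector, one phase lag (radians) per
#'   channel.
#' @param kappa Von Mises concentration of per-episode phase offsets
#'   (`Inf` = fixed lags).
#' @param seed Optional integer seed.
#' @param background Optional background signal: matrix (channels x time) or
#'   vector, used for amplitude calibration.
#' @param calibrate `"channel"` (default), `"bipolar"` (calibrate on
#'   consecutive channel differences) or `"none"`.
#' @param freq_jitter Half-range (Hz) of uniform per-episode center-frequency
#'   jitter.
#' @param offset_group Integer vector mapping channels to offset groups
#'   (default: each channel its own group; group of the first channel is the
#'   reference).
#' @param drift_sd Within-episode phase drift SD (radians) applied to
#'   non-reference groups when `kappa` is finite.
#' @param ramp_s Raised-cosine on/off ramp inside each episode (s).
#' @return Matrix channels x time. Attribute `"episodes"` holds the realized
#'   schedule with per-episode center frequencies and offsets per group.
#' @export
generate_oscillatory_component <- function(fs, duration_s, center_f,
                                           bandwidth, amplitude_db,
                                           episode_schedule,
                                           channel_phase_lags,
                                           kappa = Inf,
                                           seed = NULL,
                                           background = NULL,
                                           calibrate = c("channel", "bipolar",
                                                         "none"),
                                           freq_jitter = 0,
                                           offset_group = NULL,
                                           drift_sd = 0.05,
                                           ramp_s = 0.1) {
  calibrate <- match.arg(calibrate)
  stop_if(center_f + bandwidth / 2 >= fs / 2,
          "band extends beyond the Nyquist frequency")
  stop_if(bandwidth <= 0 || bandwidth >= center_f,
          "need 0 < bandwidth < center_f")
  stop_if(amplitude_db < 0, "`amplitude_db` must be >= 0")
  stop_if(kappa < 0, "`kappa` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration_s * fs))
  nch <- length(channel_phase_lags)
  stop_if(nch < 1L, "need at least one channel")
  if (is.null(offset_group)) offset_group <- seq_len(nch)
  stop_if(length(offset_group) != nch,
          "`offset_group` must have one entry per channel")
  out <- matrix(0, nrow = nch, ncol = n)
  es <- validate_schedule(episode_schedule, duration_s)
  groups <- sort(unique(offset_group))
  ref_group <- groups[1L]
  ep_fc <- numeric(nrow(es))
  ep_off <- matrix(0, nrow = nrow(es), ncol = length(groups),
                   dimnames = list(NULL, paste0("g", groups)))
  if (amplitude_db == 0 || nrow(es) == 0L) {
    attr(out, "episodes") <- cbind(es[0, c("start_s", "end_s"), drop = FALSE])
    return(out)
  }
  for (e in seq_len(nrow(es))) {
    i0 <- floor(es$start_s[e] * fs) + 1L
    i1 <- min(floor(es$end_s[e] * fs), n)
    m <- i1 - i0 + 1L
    if (m < 8L) next
    fc <- if (!is.null(es$center_f)) es$center_f[e] else
      center_f + stats::runif(1, -freq_jitter, freq_jitter)
    ep_fc[e] <- fc
    z <- make_burst_carrier(m, fs, fc, bandwidth)
    env <- rep(1, m)
    nr <- min(as.integer(round(ramp_s * fs)), m %/% 4L)
    if (nr > 1L) {
      r <- 0.5 - 0.5 * cos(pi * (0:(nr - 1)) / (nr - 1))
      env[1:nr] <- r
      env[m:(m - nr + 1L)] <- r
    }
    offs <- setNames(numeric(length(groups)), paste0("g", groups))
    for (g in groups) {
      if (g == ref_group) next
      offs[paste0("g", g)] <- rvonmises(1L, 0, kappa)
    }
    ep_off[e, ] <- offs
    for (g in groups) {
      drift <- if (is.finite(kappa) && g != ref_group)
        make_phase_drift(m, fs, drift_sd) else numeric(m)
      rot <- exp(1i * (offs[paste0("g", g)] + drift))
      zg <- z * rot
      for (k in which(offset_group == g)) {
        out[k, i0:i1] <- Re(zg * exp(1i * channel_phase_lags[k])) * env * sqrt(2)
      }
    }
  }
  # amplitude calibration against the background spectrum at center_f
  if (!is.null(background) && calibrate != "none") {
    bg <- if (is.matrix(background)) background else
      matrix(background, nrow = nch, ncol = n, byrow = TRUE)
    stop_if(ncol(bg) != n, "`background` length must match the component")
    if (calibrate == "bipolar" && nch >= 2L) {
      bsig <- bg[1L, ] - bg[2L, ]
      osig <- out[1L, ] - out[2L, ]
    } else {
      bsig <- bg[1L, ]
      osig <- out[1L, ]
    }
    g2 <- calibration_gain2(bsig, osig, es, fs, center_f, amplitude_db)
    out <- out * sqrt(g2)
  }
  es$center_f <- ep_fc
  attr(out, "episodes") <- cbind(es, ep_off)
  out
}

# Squared gain aligning the measured oscillation PSD at center_f with
# (10^(A/10) - 1) times the background PSD. Welch windows are fitted inside
# episodes so the measurement sees full oscillation amplitude.
calibration_gain2 <- function(bsig, osig, es, fs, center_f, amplitude_db) {
  ep_len <- floor((es$end_s - es$start_s) * fs)
  nwin <- min(8 * fs, max(ep_len))
  nwin <- as.integer(2 * (nwin %/% 2))
  if (nwin < 64L) return(1)
  pb <- welch_psd(bsig, fs, nwin)
  ib <- which.min(abs(pb$freq - center_f))
  pow_o <- 0; nw <- 0L
  for (e in seq_len(nrow(es))) {
    i0 <- floor(es$start_s[e] * fs) + 1L
    i1 <- min(floor(es$end_s[e] * fs), length(osig))
    if (i1 - i0 + 1L < nwin) next
    po <- welch_psd(osig[i0:i1], fs, nwin)
    pow_o <- pow_o + po$psd[ib] * po$n_windows
    nw <- nw + po$n_windows
  }
  if (nw == 0L || pow_o == 0) return(1)
  target <- (10^(amplitude_db / 10) - 1) * pb$psd[ib]
  target / (pow_o / nw)
}
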