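#' Spectrogram with Hanning-tapered overlapping windows
#'
#' Time-frequency power spectral density from 50 percent overlapping 8-s
#' Hanning windows. Each window is a demeaned modified periodogram; the
#' native 0.125 Hz bins are aggregated onto the declared 0.5 Hz output grid
#' by averaging four native bins per output bin, retaining the declared
#' window length while matching the declared resolution. The grid starts at
#' 0.5 Hz (windows are demeaned, so the DC bin is degenerate).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param window_s Window length (s), default 8.
#' @param overlap Fractional overlap, default 0.5.
#' @param fmax Upper frequency bound (Hz), default 300.
#' @param df_out Output bin width (Hz), default 0.5.
#' @param source Optional identifier stored with the result.
#' @return Object of class `"lfp_spectrogram"`: `power` (time bins x
#'   frequency bins, micro-V^2/Hz), `freq`, `time` (window centers, s), `fs`.
#' @export
compute_spectrogram <- function(x, fs, window_s = 8, overlap = 0.5,
                                fmax = 300, df_out = 0.5, source = NULL) {
  nwin <- as.integer(round(window_s * fs))
  stop_if(length(x) < nwin,
          sprintf("signal must be at least %g s (%d samples) long",
                  window_s, nwin))
  pg <- welch_periodograms(x, fs, nwin, overlap)
  ag <- aggregate_psd(pg$freq, pg$power, df_out = df_out, fmax = fmax)
  structure(list(power = t(ag$p), freq = ag$freq, time = pg$time,
                 fs = fs, source = source),
            class = "lfp_spectrogram")
}

#' @export
print.lfp_spectrogram <- function(x, ...) {
  cat(sprintf("<lfp_spectrogram> %d time bins x %d freq bins (%.1f-%.1f Hz)\n",
              nrow(x$power), ncol(x$power), min(x$freq), max(x$freq)))
  invisible(x)
}

#' Average spectra across electrode pairs of one structure
#'
#' Arithmetic mean across inputs (electrode pairs), then across time bins in
#' the requested window. Inputs may be `lfp_spectrogram` objects, numeric
#' vectors on a common grid, or `fractal_decomposition` objects (their
#' `oscillatory_db` is averaged).
#'
#' @param spectra List of inputs sharing one frequency grid.
#' @param time_window Optional `c(start_s, end_s)` restricting spectrogram
#'   time bins.
#' @return List with `freq` and `spectrum` (the averaged values).
#' @export
structure_average_spectrum <- function(spectra, time_window = NULL) {
  stop_if(length(spectra) < 1L, "need at least one spectrum")
  if (!is.list(spectra) || inherits(spectra, c("lfp_spectrogram",
                                               "fractal_decomposition")))
    spectra <- list(spectra)
  as_vec <- function(s) {
    if (inherits(s, "fractal_decomposition"))
      return(list(freq = s$freq, v = s$oscillatory_db))
    if (inherits(s, "lfp_spectrogram")) {
      keep <- rep(TRUE, length(s$time))
      if (!is.null(time_window))
        keep <- s$time >= time_window[1L] & s$time < time_window[2L]
      stop_if(!any(keep), "time window selects no spectrogram bins")
      return(list(freq = s$freq,
                  v = colMeans(s$power[keep, , drop = FALSE])))
    }
    stop_if(is.null(attr(s, "freq")) && is.null(names(s)) && !is.numeric(s),
            "unsupported spectrum input")
    list(freq = attr(s, "freq"), v = as.numeric(s))
  }
  parts <- lapply(spectra, as_vec)
  f0 <- parts[[1L]]$freq
  for (p in parts) {
    stop_if(!is.null(p$freq) && !is.null(f0) &&
              (length(p$freq) != length(f0) || any(p$freq != f0)),
            "frequency grids do not match")
    stop_if(length(p$v) != length(parts[[1L]]$v),
            "spectrum lengths do not match")
  }
  v <- rowMeans(vapply(parts, `[[`, numeric(length(parts[[1L]]$v)), "v"))
  list(freq = f0, spectrum = v)
}
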