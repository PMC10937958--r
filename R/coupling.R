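#' Instantaneous phase of a band-limited signal
#'
#' Zero-phase 4th-order Butterworth band-pass (applied forward and backward)
#' followed by the analytic-signal phase. The band is typically the 20 Hz
#' analysis band centered on the session peak frequency.
#'
#' @param x Bipolar LFP trace.
#' @param fs Sampling rate (Hz).
#' @param center_f Band center (Hz).
#' @param half_width Half band width (Hz), default 10.
#' @return Object of class `"phase_series"`: `phase` (radians, wrapped to
#'   (-pi, pi]), `fs`, `center_f`, and an all-true validity `mask` (set via
#'   [mask_from_detections()] for HFO-gated analyses).
#' @export
extract_band_phase <- function(x, fs, center_f, half_width = 10) {
  lo <- center_f - half_width
  hi <- center_f + half_width
  stop_if(lo <= 0 || hi >= fs / 2, "band must lie inside (0, Nyquist)")
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  ph <- Arg(analytic_signal(xf))
  structure(list(phase = ph, fs = fs, center_f = center_f,
                 mask = rep(TRUE, length(ph))),
            class = "phase_series")
}

#' Validity mask from block detections
#'
#' Marks samples as usable only inside blocks where the HFO detector fired,
#' restricting phase statistics to episodes of detected oscillations.
#'
#' @param n_samples Length of the phase series.
#' @param fs Sampling rate (Hz).
#' @param fits data.frame of block fits (needs `detected` and
#'   `block_start_s`).
#' @param block_s Block length (s).
#' @return Logical vector of length `n_samples`.
#' @export
mask_from_detections <- function(n_samples, fs, fits, block_s = 60) {
  mask <- rep(FALSE, n_samples)
  for (r in which(fits$detected)) {
    i0 <- floor(fits$block_start_s[r] * fs) + 1L
    i1 <- min(i0 + as.integer(round(block_s * fs)) - 1L, n_samples)
    if (i0 <= n_samples) mask[i0:i1] <- TRUE
  }
  mask
}

#' Phase differences between two phase series
#'
#' Wrapped differences `a - b` restricted to jointly valid samples and
#' decimated to one sample per oscillation cycle (`round(fs / center_f)`
#' samples) to reduce serial dependence before concentration estimation.
#'
#' @param series_a,series_b `phase_series` objects on a common sampling rate.
#' @param per_cycle Decimate to one sample per cycle (default TRUE).
#' @return Numeric vector of wrapped phase differences (possibly empty; an
#'   empty overlap yields an empty sample with attribute `reason`).
#' @export
phase_differences <- function(series_a, series_b, per_cycle = TRUE) {
  stop_if(series_a$fs != series_b$fs, "sampling rates differ")
  stop_if(length(series_a$phase) != length(series_b$phase),
          "series lengths differ")
  ok <- series_a$mask & series_b$mask
  if (!any(ok)) {
    out <- numeric(0)
    attr(out, "reason") <- "no jointly valid samples"
    return(out)
  }
  d <- wrap_pi(series_a$phase[ok] - series_b$phase[ok])
  if (per_cycle) {
    step <- max(1L, as.integer(round(series_a$fs / series_a$center_f)))
    d <- d[seq.int(1L, length(d), by = step)]
  }
  d
}

#' Fit a von Mises (circular normal) distribution
#'
#' Mean direction from the circular mean; concentration kappa from the
#' resultant length by Fisher's piecewise approximation to the
#' maximum-likelihood inverse, capped at 500. The reporting convention
#' sigma^2 = 1/kappa links kappa to a circular variance.
#'
#' @param theta Circular sample (radians).
#' @param min_n Minimum sample size (default 10); smaller samples give an
#'   undefined fit with a reason.
#' @return Object of class `"phase_distribution"`: `n`, `mu`, `rbar`,
#'   `kappa`, `sigma2`, `reason`.
#' @export
estimate_von_mises <- function(theta, min_n = 10L) {
  theta <- theta[is.finite(theta)]
  n <- length(theta)
  if (n < min_n) {
    return(structure(list(n = n, mu = NA_real_, rbar = NA_real_,
                          kappa = NA_real_, sigma2 = NA_real_,
                          reason = sprintf("n = %d below minimum %d", n,
                                           min_n)),
                     class = "phase_distribution"))
  }
  z <- mean(exp(1i * theta))
  rbar <- Mod(z)
  mu <- Arg(z)
  kappa <- kappa_from_rbar(rbar)
  structure(list(n = n, mu = mu, rbar = rbar,
                 kappa = kappa, sigma2 = 1 / kappa, reason = NA_character_),
            class = "phase_distribution")
}

# Fisher's piecewise ML inverse of the resultant length
kappa_from_rbar <- function(rbar, cap = 500) {
  k <- if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
  min(max(k, 0), cap)
}

#' @export
print.phase_distribution <- function(x, ...) {
  if (is.na(x$kappa)) {
    cat("<phase_distribution> undefined:", x$reason, "\n")
  } else {
    cat(sprintf("<phase_distribution> n=%d mu=%.3f rad Rbar=%.3f kappa=%.2f\n",
                x$n, x$mu, x$rbar, x$kappa))
  }
  invisible(x)
}

#' Change in phase coupling between conditions
#'
#' Elementwise `kappa_condition - kappa_reference` over a common set of
#' structure pairs; cells undefined in either condition propagate as `NA`.
#'
#' @param condition_kappa,reference_kappa Named numeric vectors (names =
#'   structure-pair labels) or data.frames with `pair` and `kappa`.
#' @return data.frame with `pair`, `kappa_condition`, `kappa_reference`,
#'   `delta_kappa`.
#' @export
coupling_change_matrix <- function(condition_kappa, reference_kappa) {
  as_named <- function(k) {
    if (is.data.frame(k)) stats::setNames(k$kappa, k$pair) else k
  }
  ck <- as_named(condition_kappa)
  rk <- as_named(reference_kappa)
  stop_if(!setequal(names(ck), names(rk)),
          "condition and reference must cover the same structure pairs")
  rk <- rk[names(ck)]
  data.frame(pair = names(ck),
             kappa_condition = unname(ck),
             kappa_reference = unname(rk),
             delta_kappa = unname(ck - rk),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Joint histogram of co-occurring peak frequencies
#'
#' For every block with simultaneous detections in two or more structures,
#' counts all (B_structure_i, B_structure_j) combinations on a binned grid.
#' A diagonal-dominated histogram shows that simultaneous HFOs share one
#' frequency.
#'
#' @param fits data.frame of block fits across structures (needs
#'   `structure`, `condition`, `block`, `session`, `B`, `detected`).
#' @param bin_hz Histogram bin width (Hz), default 1.
#' @return List: `pairs` (data.frame with B_a, B_b per co-detection),
#'   `diagonal_fraction` (share of mass with |B_a - B_b| <= 2 Hz); empty
#'   inputs give zero rows without error.
#' @export
joint_frequency_histogram <- function(fits, bin_hz = 1) {
  det <- fits[fits$detected, , drop = FALSE]
  out <- list()
  if (nrow(det)) {
    key <- paste(det$session, det$condition, det$block, sep = "|")
    for (k in unique(key)) {
      d <- det[key == k, , drop = FALSE]
      if (nrow(d) < 2L) next
      cmb <- utils::combn(nrow(d), 2L)
      out[[k]] <- data.frame(B_a = d$B[cmb[1L, ]], B_b = d$B[cmb[2L, ]],
                             structure_a = d$structure[cmb[1L, ]],
                             structure_b = d$structure[cmb[2L, ]])
    }
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(B_a = numeric(0), B_b = numeric(0),
               structure_a = character(0), structure_b = character(0))
  rownames(pairs) <- NULL
  pairs$B_a <- round(pairs$B_a / bin_hz) * bin_hz
  pairs$B_b <- round(pairs$B_b / bin_hz) * bin_hz
  list(pairs = pairs,
       diagonal_fraction = if (nrow(pairs))
         mean(abs(pairs$B_a - pairs$B_b) <= 2) else NA_real_)
}

#' Kappa per structure pair from a bipolar set
#'
#' High-level wrapper: for every pair of structures, extracts band phases of
#' the first electrode pair in each structure, gates samples to blocks where
#' the detector fired in both structures (matching "HFOs detected in
#' parallel"), pools phase differences within the condition, and fits the
#' circular normal.
#'
#' @param bset A [bipolar_derive()] result.
#' @param fits Block fits from [fit_blocks()].
#' @param condition Condition label to analyze.
#' @param center_f Analysis band center (Hz); default: median detected B in
#'   the condition.
#' @param block_s Block length used for the fits (s).
#' @param half_width Band half width (Hz).
#' @return data.frame with pair, structure_a, structure_b, n, mu, rbar,
#'   kappa.
#' @export
structure_pair_coupling <- function(bset, fits, condition, center_f = NULL,
                                    block_s = 60, half_width = 10) {
  fc <- fits[fits$condition == condition, , drop = FALSE]
  if (is.null(center_f)) {
    bdet <- fc$B[fc$detected]
    stop_if(length(bdet) == 0L,
            "no detections in this condition; give `center_f` explicitly")
    center_f <- stats::median(bdet)
  }
  structs <- unique(bset$pairs$structure)
  stop_if(length(structs) < 2L, "need at least two structures")
  n <- ncol(bset$signals)
  series <- list()
  for (s in structs) {
    row <- which(bset$pairs$structure == s)[1L]
    ps <- extract_band_phase(bset$signals[row, ], bset$fs, center_f,
                             half_width)
    ps$mask <- mask_from_detections(n, bset$fs,
                                    fc[fc$structure == s, , drop = FALSE],
                                    block_s)
    series[[s]] <- ps
  }
  cmb <- utils::combn(length(structs), 2L)
  out <- lapply(seq_len(ncol(cmb)), function(j) {
    a <- structs[cmb[1L, j]]
    b <- structs[cmb[2L, j]]
    d <- phase_differences(series[[a]], series[[b]])
    vm <- estimate_von_mises(d)
    data.frame(pair = paste(a, b, sep = "-"), structure_a = a,
               structure_b = b, n = vm$n, mu = vm$mu, rbar = vm$rbar,
               kappa = vm$kappa, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
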