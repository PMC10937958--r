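#' Block-wise rhythmic-residue spectra per structure
#'
#' Partitions each condition epoch into non-overlapping blocks (default
#' 60 s), runs the fractal/rhythmic separation per electrode pair and block,
#' and averages the dB_fractal residue across pairs of the same
#' (structure, hemisphere). Blocks are the temporal unit on which the peak
#' detector operates.
#'
#' @param bset A [bipolar_derive()] result.
#' @param block_s Block length (s); epochs shorter than one block are
#'   dropped.
#' @param h_set,window_s,fmax,df_out Passed to [irasa_decompose()].
#' @param method IRASA method (see [irasa_decompose()]).
#' @return Object of class `"block_spectra"`: `freq`, `spectra` (blocks x
#'   frequency matrix of dB_fractal values), `meta` (data.frame with
#'   structure, hemisphere, condition, block, block_start_s, animal,
#'   session).
#' @export
block_spectra <- function(bset, block_s = 60,
                          h_set = seq(1.10, 1.90, by = 0.05),
                          window_s = 8, fmax = 300, df_out = 0.5,
                          method = "rescale") {
  stop_if(!inherits(bset, "bipolar_set"), "`bset` must be a bipolar_set")
  fs <- bset$fs
  nblk <- as.integer(round(block_s * fs))
  ep <- bset$epochs
  stop_if(nrow(ep) == 0L, "recording has no condition epochs")
  groups <- split(seq_len(nrow(bset$pairs)),
                  paste(bset$pairs$structure, bset$pairs$hemisphere,
                        sep = "|"))
  meta <- list()
  rows <- list()
  freq <- NULL
  for (e in seq_len(nrow(ep))) {
    i0 <- floor(ep$start_s[e] * fs) + 1L
    i1 <- floor(ep$end_s[e] * fs)
    nb <- (i1 - i0 + 1L) %/% nblk
    if (nb < 1L) next
    for (b in seq_len(nb)) {
      j0 <- i0 + (b - 1L) * nblk
      j1 <- j0 + nblk - 1L
      for (g in names(groups)) {
        dbs <- lapply(groups[[g]], function(p)
          irasa_decompose(bset$signals[p, j0:j1], fs, h_set = h_set,
                          window_s = window_s, fmax = fmax,
                          df_out = df_out, method = method))
        avg <- structure_average_spectrum(dbs)
        freq <- avg$freq
        key <- strsplit(g, "|", fixed = TRUE)[[1L]]
        rows[[length(rows) + 1L]] <- avg$spectrum
        meta[[length(meta) + 1L]] <- data.frame(
          structure = key[1L], hemisphere = key[2L],
          condition = ep$label[e], block = b,
          block_start_s = (j0 - 1L) / fs,
          animal = bset$animal, session = bset$session,
          stringsAsFactors = FALSE)
      }
    }
  }
  stop_if(length(rows) == 0L, "no epoch long enough for one block")
  structure(list(freq = freq, spectra = do.call(rbind, rows),
                 meta = do.call(rbind, meta)),
            class = "block_spectra")
}

#' Fit the peak model to every block spectrum
#'
#' @param blocks A [block_spectra()] result.
#' @param band A [band_definition()].
#' @return data.frame: block metadata plus A, B, C, D, E, R2, detected.
#' @export
fit_blocks <- function(blocks, band) {
  stop_if(!inherits(blocks, "block_spectra"), "`blocks` from block_spectra()")
  fits <- lapply(seq_len(nrow(blocks$spectra)), function(i)
    fit_peak_model(blocks$spectra[i, ], band, freq = blocks$freq))
  cbind(blocks$meta,
        do.call(rbind, lapply(fits, function(f)
          data.frame(A = f$A, B = f$B, C = f$C, D = f$D, E = f$E,
                     R2 = f$R2, detected = f$detected))))
}

#' Session peak frequency
#'
#' Median of the fitted `B` parameter across detected blocks of one
#' recording session and structure; `NA` when nothing was detected (a
#' "peak absent" structure).
#'
#' @param fits data.frame of fits (needs `B`, `detected`).
#' @return Peak frequency (Hz) or `NA`.
#' @export
session_peak_frequency <- function(fits) {
  b <- fits$B[which(fits$detected)]
  if (length(b) == 0L) return(NA_real_)
  stats::median(b)
}

#' Band power around a peak frequency
#'
#' Arithmetic mean of the dB_fractal residue over a 20 Hz band centered on
#' the session peak frequency (inclusive endpoints: 41 bins on a 0.5 Hz
#' grid). Bands reaching outside the grid are truncated with a warning.
#'
#' @param spectrum_db Residue spectrum (dB) or `fractal_decomposition`.
#' @param peak_frequency Center (Hz), typically [session_peak_frequency()].
#' @param freq Frequency grid (for plain vectors).
#' @param half_width Half band width (Hz), default 10.
#' @return Band power (dB_fractal).
#' @export
band_power <- function(spectrum_db, peak_frequency, freq = NULL,
                       half_width = 10) {
  if (inherits(spectrum_db, "fractal_decomposition")) {
    freq <- spectrum_db$freq
    spectrum_db <- spectrum_db$oscillatory_db
  }
  stop_if(is.na(peak_frequency), "peak frequency undefined")
  lo <- peak_frequency - half_width
  hi <- peak_frequency + half_width
  if (lo < min(freq) || hi > max(freq)) {
    warning("band truncated at the grid edge", call. = FALSE)
    lo <- max(lo, min(freq))
    hi <- min(hi, max(freq))
  }
  sel <- freq >= lo - 1e-9 & freq <= hi + 1e-9
  mean(spectrum_db[sel])
}

#' Summarize detections per structure and condition
#'
#' Detection rate (percent of blocks), band power (dB_fractal, centered on
#' the per-session-and-structure median B across all conditions) and peak
#' frequency (median detected B within the condition).
#'
#' @param fits data.frame from [fit_blocks()].
#' @param blocks The matching [block_spectra()] (for band-power spectra).
#' @return data.frame with structure, hemisphere, condition, n_blocks,
#'   detection_rate, band_power, peak_frequency.
#' @export
summarize_band <- function(fits, blocks = NULL) {
  stop_if(nrow(fits) == 0L, "no blocks to summarize")
  groups <- split(seq_len(nrow(fits)),
                  paste(fits$structure, fits$hemisphere, fits$condition,
                        sep = "|"))
  session_groups <- split(seq_len(nrow(fits)),
                          paste(fits$structure, fits$hemisphere,
                                fits$session, sep = "|"))
  session_peak <- vapply(session_groups, function(i)
    session_peak_frequency(fits[i, ]), numeric(1))
  out <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    key <- strsplit(g, "|", fixed = TRUE)[[1L]]
    det <- fits$detected[i]
    bp <- NA_real_
    if (!is.null(blocks)) {
      bp_blocks <- vapply(i, function(r) {
        pk <- session_peak[[paste(key[1L], key[2L], fits$session[r],
                                  sep = "|")]]
        if (is.na(pk)) return(NA_real_)
        band_power(blocks$spectra[r, ], pk, freq = blocks$freq)
      }, numeric(1))
      if (any(!is.na(bp_blocks))) bp <- mean(bp_blocks, na.rm = TRUE)
    }
    data.frame(structure = key[1L], hemisphere = key[2L],
               condition = key[3L], n_blocks = length(i),
               detection_rate = 100 * mean(det),
               band_power = bp,
               peak_frequency = if (any(det))
                 stats::median(fits$B[i][det]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
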