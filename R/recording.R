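#' Multichannel LFP recording container
#'
#' Holds a channels x time voltage matrix (micro-V) with sampling rate,
#' channel identifiers, condition epoch annotations and session metadata.
#' Epochs use seconds from recording start and half-open `[start, end)`
#' intervals.
#'
#' @param samples Numeric matrix, channels in rows.
#' @param fs Sampling rate (Hz), > 0.
#' @param channel_ids Unique channel identifier per row.
#' @param epochs data.frame with `label`, `start_s`, `end_s` (may be empty).
#' @param animal,session Identifier strings.
#' @return Object of class `"lfp_recording"`.
#' @export
lfp_recording <- function(samples, fs, channel_ids,
                          epochs = NULL, animal = NA_character_,
                          session = NA_character_) {
  stop_if(!is.matrix(samples), "`samples` must be a channels x time matrix")
  stop_if(fs <= 0, "`fs` must be > 0")
  stop_if(length(channel_ids) != nrow(samples),
          "one channel_id per sample row required")
  stop_if(anyDuplicated(channel_ids) > 0, "channel_ids must be unique")
  dur <- ncol(samples) / fs
  if (is.null(epochs)) {
    epochs <- data.frame(label = character(0), start_s = numeric(0),
                         end_s = numeric(0))
  }
  stop_if(!all(c("label", "start_s", "end_s") %in% names(epochs)),
          "`epochs` needs columns label, start_s, end_s")
  stop_if(any(epochs$start_s < 0) || any(epochs$end_s > dur + 1e-9),
          "epochs must lie within [0, duration]")
  rownames(samples) <- channel_ids
  structure(list(samples = samples, fs = fs,
                 channel_ids = as.character(channel_ids),
                 epochs = epochs[, c("label", "start_s", "end_s")],
                 animal = animal, session = session),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channels x %.1f s @ %g Hz\n",
              nrow(x$samples), ncol(x$samples) / x$fs, x$fs))
  cat(sprintf("  animal %s, session %s; %d epoch(s): %s\n",
              x$animal, x$session, nrow(x$epochs),
              paste(x$epochs$label, collapse = ", ")))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording An `lfp_recording`.
#' @export
recording_duration <- function(recording) {
  ncol(recording$samples) / recording$fs
}

#' Extract one condition epoch as a recording slice
#'
#' Sample-accurate slicing with half-open `[start, end)` boundaries: sample
#' indices `floor(start_s * fs) + 1` through `floor(end_s * fs)`.
#'
#' @param recording An `lfp_recording`.
#' @param label Epoch label to extract.
#' @return An `lfp_recording` covering the epoch (its epoch table holds the
#'   selected epoch re-referenced to slice start).
#' @export
extract_epoch <- function(recording, label) {
  ep <- recording$epochs
  hit <- which(ep$label == label)
  stop_if(length(hit) == 0L,
          sprintf("epoch '%s' not found; available: %s", label,
                  paste(unique(ep$label), collapse = ", ")))
  e <- ep[hit[1L], ]
  fs <- recording$fs
  i0 <- floor(e$start_s * fs) + 1L
  i1 <- floor(e$end_s * fs)
  stop_if(i1 > ncol(recording$samples), "epoch extends beyond the recording")
  lfp_recording(recording$samples[, i0:i1, drop = FALSE], fs,
                recording$channel_ids,
                epochs = data.frame(label = label, start_s = 0,
                                    end_s = (i1 - i0 + 1L) / fs),
                animal = recording$animal, session = recording$session)
}

#' Downsample a signal with anti-alias filtering
#'
#' Rational-factor Fourier resampling: the spectrum is truncated at the
#' output Nyquist frequency (an ideal brick-wall anti-alias filter), so
#' passband amplitudes below `0.4 * fs_out` are preserved within 1 percent
#' and content above the output Nyquist is rejected.
#'
#' @param x Numeric vector or channels x time matrix.
#' @param fs_in Input rate (Hz).
#' @param fs_out Output rate (Hz), `fs_out <= fs_in`; the ratio must be
#'   rational (within 1e-9).
#' @return Downsampled signal (same shape family as input).
#' @export
downsample <- function(x, fs_in, fs_out = 2000) {
  stop_if(fs_out > fs_in, "`fs_out` must be <= `fs_in`")
  if (fs_in == fs_out) return(x)
  fr <- ratio_as_fraction(fs_out / fs_in)
  stop_if(is.null(fr), "fs_in / fs_out must form a rational ratio")
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, downsample_vec, p = fr[1L], q = fr[2L],
                   fs_in = fs_in, fs_out = fs_out))
    return(out)
  }
  downsample_vec(x, fr[1L], fr[2L], fs_in, fs_out)
}

downsample_vec <- function(x, p, q, fs_in, fs_out) {
  # Fourier resampling: ideal brick-wall anti-alias filter, exact passband
  m <- as.integer(round(length(x) * p / q))
  fft_resample(x, m)
}

ratio_as_fraction <- function(r, max_den = 10000L, tol = 1e-9) {
  for (q in seq_len(max_den)) {
    p <- r * q
    if (abs(p - round(p)) < tol * q) {
      g <- gcd_int(as.integer(round(p)), q)
      return(c(as.integer(round(p)) %/% g, q %/% g))
    }
  }
  NULL
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Write / read the recording container
#'
#' Plain-text directory container: `samples.csv` (time in rows, one column
#' per channel, full double precision) plus `meta.json` (fs, channel ids,
#' epochs, animal, session). Round-trips are lossless for samples and
#' metadata.
#'
#' @param recording An `lfp_recording`.
#' @param path Directory to create/use.
#' @return `write_recording` the path, invisibly; `read_recording` an
#'   `lfp_recording`.
#' @export
write_recording <- function(recording, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  # full 17-digit decimal representation: doubles survive the round trip
  chr <- apply(t(recording$samples), 2L, sprintf, fmt = "%.17g")
  if (!is.matrix(chr)) chr <- matrix(chr, nrow = 1L)
  dt <- data.table::as.data.table(chr)
  data.table::setnames(dt, recording$channel_ids)
  data.table::fwrite(dt, file.path(path, "samples.csv"), quote = FALSE)
  meta <- list(fs = recording$fs, channel_ids = recording$channel_ids,
               epochs = recording$epochs, animal = recording$animal,
               session = recording$session)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  dt <- data.table::fread(file.path(path, "samples.csv"))
  samples <- t(as.matrix(dt))
  epochs <- as.data.frame(meta$epochs)
  if (!nrow(epochs))
    epochs <- data.frame(label = character(0), start_s = numeric(0),
                         end_s = numeric(0))
  lfp_recording(samples, meta$fs, meta$channel_ids, epochs = epochs,
                animal = meta$animal %||% NA_character_,
                session = meta$session %||% NA_character_)
}

#' Read / write a channel map
#'
#' CSV dialect: `channel_id,structure,hemisphere,animal,session`. Structure
#' labels are checked against a declared vocabulary.
#'
#' @param path CSV file path.
#' @param vocabulary Allowed structure labels; `NULL` disables the check.
#' @export
read_channel_map <- function(path, vocabulary = structure_vocabulary()) {
  cm <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_channel_map(cm, vocabulary)
  cm
}

#' @rdname read_channel_map
#' @param channel_map data.frame to write.
#' @export
write_channel_map <- function(channel_map, path) {
  utils::write.csv(channel_map, path, row.names = FALSE)
  invisible(path)
}

validate_channel_map <- function(channel_map, vocabulary = NULL) {
  need <- c("channel_id", "structure", "hemisphere")
  stop_if(!all(need %in% names(channel_map)),
          "channel map needs columns channel_id, structure, hemisphere")
  stop_if(anyDuplicated(channel_map$channel_id) > 0,
          "duplicate channel_id in channel map")
  if (!is.null(vocabulary)) {
    bad <- setdiff(unique(channel_map$structure), vocabulary)
    if (length(bad))
      warning("structures outside the declared vocabulary: ",
              paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(channel_map)
}

#' Read a condition-epoch table from CSV
#'
#' Dialect: `label,start_s,end_s`.
#'
#' @param path CSV file path.
#' @return data.frame with label, start_s, end_s.
#' @export
read_epochs <- function(path) {
  ep <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if(!all(c("label", "start_s", "end_s") %in% names(ep)),
          "epoch table needs columns label, start_s, end_s")
  ep[, c("label", "start_s", "end_s")]
}
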