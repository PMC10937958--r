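#' Bipolar derivation from electrode pairs within a structure
#'
#' Differencing two nearby electrodes of the same structure rejects
#' volume-conducted signals common to both, isolating local sources. Under
#' the default `"consecutive"` policy channels within each
#' (structure, hemisphere) group are sorted by id and paired 1-2, 3-4, ...;
#' each channel enters at most one pair. The `"all_pairs"` policy forms every
#' within-group combination (for electrode-level coupling analyses).
#'
#' @param recording An [lfp_recording()].
#' @param channel_map data.frame mapping `channel_id` to `structure` and
#'   `hemisphere`.
#' @param policy `"consecutive"` (default) or `"all_pairs"`.
#' @return Object of class `"bipolar_set"`: `signals` (pairs x time matrix),
#'   `pairs` (data.frame with pair_id, structure, hemisphere, channel_a,
#'   channel_b), `fs`, and the recording's epochs/metadata. Structures with a
#'   single channel are skipped with a warning.
#' @export
bipolar_derive <- function(recording, channel_map,
                           policy = c("consecutive", "all_pairs")) {
  policy <- match.arg(policy)
  validate_channel_map(channel_map, vocabulary = NULL)
  stop_if(!all(recording$channel_ids %in% channel_map$channel_id),
          "every recorded channel must be mapped")
  cm <- channel_map[match(recording$channel_ids, channel_map$channel_id), ]
  gkey <- paste(cm$structure, cm$hemisphere, sep = "|")
  groups <- split(seq_along(recording$channel_ids), gkey)
  groups <- groups[unique(gkey)]  # keep channel-map order, not locale order
  pairs <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    idx <- idx[order(recording$channel_ids[idx])]
    if (length(idx) < 2L) {
      warning("structure ", g, " has a single channel; skipped",
              call. = FALSE)
      next
    }
    ab <- if (policy == "consecutive") {
      npair <- length(idx) %/% 2L
      cbind(idx[2 * seq_len(npair) - 1L], idx[2 * seq_len(npair)])
    } else {
      t(utils::combn(idx, 2L))
    }
    key <- strsplit(g, "|", fixed = TRUE)[[1L]]
    pairs[[g]] <- data.frame(
      structure = key[1L], hemisphere = key[2L],
      a = ab[, 1L], b = ab[, 2L], stringsAsFactors = FALSE)
  }
  stop_if(length(pairs) == 0L, "no structure with >= 2 channels")
  pr <- do.call(rbind, pairs)
  rownames(pr) <- NULL
  sig <- recording$samples[pr$a, , drop = FALSE] -
    recording$samples[pr$b, , drop = FALSE]
  pairs_df <- data.frame(
    pair_id = paste0(pr$structure, "_",
                     substr(pr$hemisphere, 1L, 1L), "_p",
                     stats::ave(seq_len(nrow(pr)),
                                paste(pr$structure, pr$hemisphere),
                                FUN = seq_along)),
    structure = pr$structure, hemisphere = pr$hemisphere,
    channel_a = recording$channel_ids[pr$a],
    channel_b = recording$channel_ids[pr$b],
    stringsAsFactors = FALSE)
  rownames(sig) <- pairs_df$pair_id
  structure(list(signals = sig, pairs = pairs_df, fs = recording$fs,
                 epochs = recording$epochs, animal = recording$animal,
                 session = recording$session),
            class = "bipolar_set")
}

#' @export
print.bipolar_set <- function(x, ...) {
  cat(sprintf("<bipolar_set> %d pairs x %.1f s @ %g Hz (%d structures)\n",
              nrow(x$signals), ncol(x$signals) / x$fs, x$fs,
              length(unique(x$pairs$structure))))
  invisible(x)
}
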