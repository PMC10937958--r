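#' Configuration for a synthetic multichannel LFP session
#'
#' Bundles and validates the generative parameters for one recording session:
#' a 1/f^alpha arrhythmic background per channel plus narrowband oscillation
#' episodes (gamma and/or HFO band) injected per condition epoch with
#' controlled amplitude (dB above the fractal background), cross-structure
#' phase lags and von Mises concentration.
#'
#' @param duration_s Session duration (s).
#' @param condition_epochs data.frame with `label`, `start_s`, `end_s`;
#'   non-overlapping, within the session.
#' @param structures data.frame with `structure` and `hemisphere`
#'   (`"lesioned"` or `"intact"`); defaults to mPFC/OFC/vStr, lesioned.
#' @param fs Sampling rate (Hz), default 2000.
#' @param channels_per_structure Electrodes per structure (>= 2 so bipolar
#'   pairs exist).
#' @param fractal_exponent Background spectral exponent alpha.
#' @param fractal_scale Background variance (micro-V^2).
#' @param oscillations List of oscillation specs; each a list with fields
#'   `condition`, `band`, `center_f`, `bandwidth`, `amplitude_db`,
#'   `phase_lag_map` (named radians per structure; first name is the phase
#'   reference), `kappa`, and either `episode_schedule` (data.frame, absolute
#'   seconds) or `episode_rate_per_min` + `episode_duration_s`; optional
#'   `freq_jitter`.
#' @param spatial_phase_step Phase increment (radians) between successive
#'   electrodes within a structure; a nonzero value keeps the oscillation
#'   visible after bipolar differencing.
#' @param animal,session Identifier strings.
#' @param seed Optional integer seed for [generate_session()].
#' @return A validated list of class `"synthetic_session_config"`.
#' @seealso [generate_session()]
#' @export
synthetic_session_config <- function(duration_s,
                                     condition_epochs,
                                     structures = default_structures(),
                                     fs = 2000,
                                     channels_per_structure = 2,
                                     fractal_exponent = 2,
                                     fractal_scale = 2500,
                                     oscillations = list(),
                                     spatial_phase_step = pi / 2,
                                     animal = "A1",
                                     session = "S1",
                                     seed = NULL) {
  stop_if(fs <= 0 || duration_s <= 0, "fs and duration_s must be > 0")
  stop_if(!is.data.frame(structures) ||
            !all(c("structure", "hemisphere") %in% names(structures)),
          "`structures` needs columns structure, hemisphere")
  stop_if(!all(structures$hemisphere %in% c("lesioned", "intact")),
          "hemisphere must be 'lesioned' or 'intact'")
  ce <- condition_epochs
  stop_if(!is.data.frame(ce) ||
            !all(c("label", "start_s", "end_s") %in% names(ce)),
          "`condition_epochs` needs columns label, start_s, end_s")
  ce <- ce[order(ce$start_s), , drop = FALSE]
  stop_if(any(ce$start_s < 0) || any(ce$end_s > duration_s + 1e-9),
          "condition epochs must lie within [0, duration_s]")
  stop_if(any(ce$end_s <= ce$start_s), "epochs need end_s > start_s")
  if (nrow(ce) > 1L)
    stop_if(any(ce$start_s[-1L] < ce$end_s[-nrow(ce)]),
            "condition epochs must not overlap")
  skey <- paste(structures$structure, structures$hemisphere)
  for (o in oscillations) {
    stop_if(is.null(o$condition) || !o$condition %in% ce$label,
            "oscillation spec refers to unknown condition epoch")
    stop_if((o$amplitude_db %||% 0) < 0, "amplitude_db must be >= 0")
    stop_if(o$bandwidth <= 0 || o$bandwidth >= o$center_f,
            "need 0 < bandwidth < center_f")
    stop_if((o$kappa %||% Inf) < 0, "kappa must be >= 0")
    stop_if(is.null(names(o$phase_lag_map)) ||
              !all(names(o$phase_lag_map) %in% structures$structure),
            "phase_lag_map names must be declared structures")
  }
  structure(list(
    fs = fs, duration_s = duration_s, structures = structures,
    channels_per_structure = as.integer(channels_per_structure),
    fractal_exponent = fractal_exponent, fractal_scale = fractal_scale,
    oscillations = oscillations, condition_epochs = ce,
    spatial_phase_step = spatial_phase_step,
    animal = animal, session = session, seed = seed,
    structure_key = skey
  ), class = "synthetic_session_config")
}

#' @rdname synthetic_session_config
#' @export
default_structures <- function() {
  data.frame(structure = c("mPFC", "OFC", "vStr"),
             hemisphere = "lesioned", stringsAsFactors = FALSE)
}

#' The 11-structure recording vocabulary
#' @return Character vector of structure abbreviations.
#' @export
structure_vocabulary <- function() {
  c("amyg", "dStr", "OC", "OFC", "PC", "mPFC", "M1", "S1",
    "thal", "vHipp", "vStr")
}

# Poisson episode schedule within one epoch; overlapping draws are dropped.
draw_episode_schedule <- function(rate_per_min, duration_ep_s, ep_start,
                                  ep_end, gap_s = 1) {
  span <- ep_end - ep_start - duration_ep_s
  if (span <= 0) {
    return(data.frame(start_s = ep_start,
                      end_s = min(ep_end, ep_start + duration_ep_s)))
  }
  k <- stats::rpois(1L, rate_per_min * (ep_end - ep_start) / 60)
  if (k == 0L) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  starts <- sort(stats::runif(k, ep_start, ep_end - duration_ep_s))
  keep <- logical(k)
  last_end <- -Inf
  for (i in seq_len(k)) {
    if (starts[i] >= last_end + gap_s) {
      keep[i] <- TRUE
      last_end <- starts[i] + duration_ep_s
    }
  }
  data.frame(start_s = starts[keep], end_s = starts[keep] + duration_ep_s)
}

#' Generate a synthetic LFP session with ground truth
#'
#' Realizes a [synthetic_session_config()]: independent fractal backgrounds
#' per channel plus the configured oscillation episodes, returned as an
#' [lfp_recording()] with its channel map and a ground-truth ledger (injected
#' episodes with realized center frequencies and phase offsets, true
#' structure-pair lags and concentrations, and a per-condition oscillation
#' regime tag) for downstream validation.
#'
#' @param config A `synthetic_session_config`.
#' @return List of class `"lfp_session"` with elements `recording`,
#'   `channel_map`, `ground_truth`.
#' @export
generate_session <- function(config) {
  stop_if(!inherits(config, "synthetic_session_config") && !is.list(config),
          "`config` must come from synthetic_session_config()")
  cfg <- config
  stop_if(cfg$channels_per_structure < 2L,
          "channels_per_structure must be >= 2 (bipolar derivation needs pairs)")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fs <- cfg$fs
  n <- as.integer(round(cfg$duration_s * fs))
  nstr <- nrow(cfg$structures)
  cps <- cfg$channels_per_structure
  nch <- nstr * cps
  hemi_tag <- ifelse(cfg$structures$hemisphere == "lesioned", "L", "I")
  channel_ids <- as.vector(t(outer(
    paste0(cfg$structures$structure, "_", hemi_tag),
    paste0("_c", seq_len(cps)), paste0)))
  channel_map <- data.frame(
    channel_id = channel_ids,
    structure = rep(cfg$structures$structure, each = cps),
    hemisphere = rep(cfg$structures$hemisphere, each = cps),
    animal = cfg$animal, session = cfg$session,
    stringsAsFactors = FALSE)

  samples <- matrix(0, nrow = nch, ncol = n)
  for (k in seq_len(nch)) {
    samples[k, ] <- generate_fractal_signal(
      cfg$duration_s, fs, cfg$fractal_exponent, cfg$fractal_scale)
  }
  fractal_only <- samples  # pristine copy: amplitude calibration reference

  episodes <- list()
  pair_truth <- list()
  for (o in cfg$oscillations) {
    target <- names(o$phase_lag_map)
    rows <- which(cfg$structures$structure %in% target)
    ch_idx <- as.vector(vapply(rows, function(r)
      (r - 1L) * cps + seq_len(cps), integer(cps)))
    # order channels by phase_lag_map order so group 1 is the reference
    ord <- order(match(channel_map$structure[ch_idx], target))
    ch_idx <- ch_idx[ord]
    lags <- o$phase_lag_map[channel_map$structure[ch_idx]] +
      ((seq_along(ch_idx) - 1L) %% cps) * cfg$spatial_phase_step
    grp <- match(channel_map$structure[ch_idx], target)
    ep <- o$condition
    epoch <- cfg$condition_epochs[cfg$condition_epochs$label == ep, ]
    sched <- if (!is.null(o$episode_schedule)) {
      validate_schedule(o$episode_schedule, cfg$duration_s)
    } else {
      draw_episode_schedule(o$episode_rate_per_min %||% 2,
                            o$episode_duration_s %||% 30,
                            epoch$start_s, epoch$end_s)
    }
    if (nrow(sched) == 0L) next
    comp <- generate_oscillatory_component(
      fs = fs, duration_s = cfg$duration_s,
      center_f = o$center_f, bandwidth = o$bandwidth,
      amplitude_db = o$amplitude_db %||% 0,
      episode_schedule = sched,
      channel_phase_lags = unname(lags),
      kappa = o$kappa %||% Inf,
      background = fractal_only[ch_idx, , drop = FALSE],
      calibrate = "bipolar",
      freq_jitter = o$freq_jitter %||% 0,
      offset_group = grp)
    samples[ch_idx, ] <- samples[ch_idx, ] + comp
    ei <- attr(comp, "episodes")
    if (!is.null(ei) && nrow(ei)) {
      ei$condition <- ep
      ei$band <- o$band %||% "HFO"
      ei$amplitude_db <- o$amplitude_db %||% 0
      ei$structures <- paste(target, collapse = ",")
      names(ei)[grep("^g[0-9]+$", names(ei))] <-
        paste0("offset_", target[as.integer(
          sub("g", "", grep("^g[0-9]+$", names(ei), value = TRUE)))])
      episodes[[length(episodes) + 1L]] <- ei
    }
    if (length(target) > 1L) {
      cmb <- utils::combn(seq_along(target), 2L)
      pair_truth[[length(pair_truth) + 1L]] <- data.frame(
        condition = ep, band = o$band %||% "HFO",
        structure_a = target[cmb[1L, ]], structure_b = target[cmb[2L, ]],
        lag = unname(o$phase_lag_map[cmb[1L, ]] - o$phase_lag_map[cmb[2L, ]]),
        kappa = o$kappa %||% Inf,
        exact_kappa = cmb[1L, ] == 1L,  # reference pairs carry exactly kappa
        stringsAsFactors = FALSE)
    }
  }
  regimes <- vapply(cfg$condition_epochs$label, function(lb) {
    amps <- vapply(cfg$oscillations, function(o)
      if (identical(o$condition, lb)) o$amplitude_db %||% 0 else 0, numeric(1))
    if (length(amps) && max(amps) > 0) "oscillatory" else "arrhythmic"
  }, character(1))

  rec <- lfp_recording(samples, fs, channel_ids,
                       epochs = cfg$condition_epochs,
                       animal = cfg$animal, session = cfg$session)
  gt <- list(
    episodes = if (length(episodes))
      do.call(rbind_fill, episodes) else NULL,
    pair_truth = if (length(pair_truth)) do.call(rbind, pair_truth) else NULL,
    condition_regime = data.frame(condition = cfg$condition_epochs$label,
                                  regime = unname(regimes),
                                  stringsAsFactors = FALSE),
    config_seed = cfg$seed)
  structure(list(recording = rec, channel_map = channel_map,
                 ground_truth = gt), class = "lfp_session")
}

# rbind data.frames with unequal columns (missing filled with NA)
rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cn in setdiff(cols, names(d))) d[[cn]] <- NA
    d[, cols, drop = FALSE]
  }))
}

#' Write a ground-truth ledger as JSON
#' @param ground_truth The `ground_truth` element of an `lfp_session`.
#' @param path Output file path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
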