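#' Pipeline configuration
#'
#' Validated configuration for the end-to-end synthetic experiment: session
#' generation, spectral decomposition, peak detection, coupling, entropy,
#' brain-state similarity, behavior, and statistics. Defaults reproduce a
#' desk-scale psychotomimetic-challenge contrast: a baseline epoch without
#' oscillations, a "vehicle" epoch with strong, tightly phase-locked HFOs
#' and a "treatment" epoch with weaker, less coherent HFOs.
#'
#' @param n_animals Number of synthetic animals (default 3).
#' @param n_sessions Sessions per animal (default 2).
#' @param structures Structure data.frame (see
#'   [synthetic_session_config()]).
#' @param epoch_s Length of each condition epoch (s), default 120.
#' @param band A [band_definition()], default HFO.
#' @param hfo_center Center frequency (Hz), default 145.
#' @param hfo_bandwidth Bandwidth (Hz), default 10.
#' @param amplitude_vehicle,amplitude_treatment HFO amplitudes (dB above
#'   fractal), defaults 6 and 2.
#' @param kappa_vehicle,kappa_treatment Phase concentrations, defaults 8
#'   and 2.
#' @param phase_lags Named lag map (radians per structure); default 0 for
#'   the reference and pi/8 steps for the rest.
#' @param block_s Detection block length (s), default 60.
#' @param entropy_window,entropy_hop Permutation-entropy window/hop
#'   (samples).
#' @param bout_rate_baseline,bout_rate_vehicle Locomotion bouts per minute
#'   for the behavior contrast (defaults 2 and 6).
#' @param n_perm Permutations for the statistics stage.
#' @param seed Master seed; per-stage seeds derive from it by fixed
#'   offsets.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_animals = 3L, n_sessions = 2L,
                            structures = default_structures(),
                            epoch_s = 120, band = band_definition("HFO"),
                            hfo_center = 145, hfo_bandwidth = 10,
                            amplitude_vehicle = 6, amplitude_treatment = 2,
                            kappa_vehicle = 8, kappa_treatment = 2,
                            phase_lags = NULL, block_s = 60,
                            entropy_window = 30000L, entropy_hop = 10000L,
                            bout_rate_baseline = 2, bout_rate_vehicle = 6,
                            n_perm = 500L, seed = 1L) {
  stop_if(n_animals < 1L || n_sessions < 1L, "need >= 1 animal and session")
  stop_if(epoch_s < block_s, "`epoch_s` must hold at least one block")
  stop_if(!inherits(band, "band_definition"), "`band` from band_definition()")
  if (is.null(phase_lags)) {
    phase_lags <- setNames((seq_len(nrow(structures)) - 1L) * pi / 8,
                           structures$structure)
  }
  stop_if(!all(names(phase_lags) %in% structures$structure),
          "phase_lags must name declared structures")
  structure(list(
    n_animals = as.integer(n_animals), n_sessions = as.integer(n_sessions),
    structures = structures, epoch_s = epoch_s, band = band,
    hfo_center = hfo_center, hfo_bandwidth = hfo_bandwidth,
    amplitude_vehicle = amplitude_vehicle,
    amplitude_treatment = amplitude_treatment,
    kappa_vehicle = kappa_vehicle, kappa_treatment = kappa_treatment,
    phase_lags = phase_lags, block_s = block_s,
    entropy_window = as.integer(entropy_window),
    entropy_hop = as.integer(entropy_hop),
    bout_rate_baseline = bout_rate_baseline,
    bout_rate_vehicle = bout_rate_vehicle,
    n_perm = as.integer(n_perm), seed = as.integer(seed)),
    class = "pipeline_config")
}

session_config_for <- function(cfg, animal, session, seed) {
  ep <- data.frame(label = c("baseline", "vehicle", "treatment"),
                   start_s = c(0, 1, 2) * cfg$epoch_s,
                   end_s = c(1, 2, 3) * cfg$epoch_s)
  osc <- list(
    list(condition = "vehicle", band = cfg$band$name,
         center_f = cfg$hfo_center, bandwidth = cfg$hfo_bandwidth,
         amplitude_db = cfg$amplitude_vehicle,
         episode_schedule = data.frame(start_s = cfg$epoch_s,
                                       end_s = 2 * cfg$epoch_s),
         phase_lag_map = cfg$phase_lags, kappa = cfg$kappa_vehicle),
    list(condition = "treatment", band = cfg$band$name,
         center_f = cfg$hfo_center, bandwidth = cfg$hfo_bandwidth,
         amplitude_db = cfg$amplitude_treatment,
         episode_schedule = data.frame(start_s = 2 * cfg$epoch_s,
                                       end_s = 3 * cfg$epoch_s),
         phase_lag_map = cfg$phase_lags, kappa = cfg$kappa_treatment))
  synthetic_session_config(
    duration_s = 3 * cfg$epoch_s, condition_epochs = ep,
    structures = cfg$structures, oscillations = osc,
    animal = sprintf("A%d", animal), session = sprintf("S%d", session),
    seed = seed)
}

#' Run the full analysis pipeline on synthetic sessions
#'
#' Generates `n_animals x n_sessions` synthetic sessions (three condition
#' epochs each), then runs every stage: bipolar derivation, block-wise
#' fractal/rhythmic separation, parametric peak detection with per-condition
#' summaries, structure-pair phase coupling with a change matrix against
#' vehicle, permutation entropy per channel and condition, brain-state
#' vectors with similarity analysis, locomotion-bout quantification on
#' matched pose tracks, and a hierarchical permutation comparison of
#' detection rates (vehicle vs treatment). Deterministic given the master
#' seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every stage's table is
#'   written as CSV together with a JSON run manifest.
#' @return List of class `"pipeline_result"` with elements `summaries`,
#'   `fits`, `coupling`, `coupling_change`, `entropy`, `similarity`,
#'   `behavior`, `stats`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stop_if(!inherits(config, "pipeline_config"),
          "`config` must come from pipeline_config()")
  cfg <- config
  t0 <- Sys.time()
  fits_all <- list()
  spectra_all <- list()
  coupling_all <- list()
  entropy_all <- list()
  state_vectors <- list()   # [[condition]][[animal]] average across sessions
  behavior_all <- list()
  k <- 0L
  for (a in seq_len(cfg$n_animals)) {
    for (s in seq_len(cfg$n_sessions)) {
      k <- k + 1L
      sess_seed <- cfg$seed + 1000L * k
      sess <- generate_session(session_config_for(cfg, a, s, sess_seed))
      bset <- bipolar_derive(sess$recording, sess$channel_map)
      blocks <- block_spectra(bset, block_s = cfg$block_s)
      fits <- fit_blocks(blocks, cfg$band)
      fits_all[[k]] <- fits
      spectra_all[[k]] <- blocks
      # coupling per condition (needs detections in >= 2 structures)
      for (cond in c("vehicle", "treatment")) {
        fc <- fits[fits$condition == cond, ]
        if (sum(tapply(fc$detected, fc$structure, any),
                na.rm = TRUE) >= 2L) {
          cp <- structure_pair_coupling(bset, fits, cond,
                                        center_f = cfg$hfo_center,
                                        block_s = cfg$block_s)
          cp$condition <- cond
          cp$animal <- sess$recording$animal
          cp$session <- sess$recording$session
          coupling_all[[length(coupling_all) + 1L]] <- cp
        }
      }
      # permutation entropy per channel
      for (ch in seq_along(sess$recording$channel_ids)) {
        er <- permutation_entropy_series(
          sess$recording$samples[ch, ], sess$recording$fs,
          sess$recording$epochs, window_len = cfg$entropy_window,
          hop = cfg$entropy_hop)
        es <- er$summary
        es$channel <- sess$recording$channel_ids[ch]
        es$structure <- sess$channel_map$structure[ch]
        es$animal <- sess$recording$animal
        es$session <- sess$recording$session
        entropy_all[[length(entropy_all) + 1L]] <- es
      }
      # state vectors per condition
      for (cond in sess$recording$epochs$label) {
        fc <- blocks$meta$condition == cond
        decs <- lapply(split(which(fc), blocks$meta$structure[fc]),
                       function(i) colMeans(
                         blocks$spectra[i, , drop = FALSE]))
        sv <- build_state_vector(decs, freq = blocks$freq)
        an <- sess$recording$animal
        state_vectors[[cond]][[an]] <-
          c(state_vectors[[cond]][[an]] %||% list(), list(sv))
      }
      # behavior: baseline sparse, vehicle dense bout schedule
      for (cond in c("baseline", "vehicle", "treatment")) {
        rate <- if (cond == "baseline") cfg$bout_rate_baseline else
          cfg$bout_rate_vehicle
        sched <- draw_episode_schedule(rate, 2, 0, cfg$epoch_s, gap_s = 2)
        names(sched) <- c("start_s", "end_s")
        tr <- generate_pose_track(sched, duration_s = cfg$epoch_s,
                                  noise_cm = 0.05)
        cen <- average_position(tr)
        spd <- compute_speed(cen)
        bouts <- detect_bouts(spd, fps = 25)
        bst <- bout_statistics(bouts, cfg$epoch_s)
        bst$condition <- cond
        bst$true_n_bouts <- nrow(sched)
        bst$animal <- sess$recording$animal
        bst$session <- sess$recording$session
        behavior_all[[length(behavior_all) + 1L]] <- bst
      }
    }
  }
  fits <- do.call(rbind, fits_all)
  summaries <- summarize_band_multi(fits_all, spectra_all)
  coupling <- if (length(coupling_all)) do.call(rbind, coupling_all) else NULL
  coupling_change <- NULL
  if (!is.null(coupling)) {
    agg <- stats::aggregate(kappa ~ pair + condition, coupling, mean)
    veh <- agg[agg$condition == "vehicle", ]
    trt <- agg[agg$condition == "treatment", ]
    shared <- intersect(veh$pair, trt$pair)
    if (length(shared)) {
      coupling_change <- coupling_change_matrix(
        stats::setNames(trt$kappa[match(shared, trt$pair)], shared),
        stats::setNames(veh$kappa[match(shared, veh$pair)], shared))
    }
  }
  entropy <- do.call(rbind, entropy_all)
  behavior <- do.call(rbind, behavior_all)
  # state similarity: average vectors across sessions per animal
  avg_states <- lapply(state_vectors, function(by_an)
    lapply(by_an, function(vs) {
      m <- Reduce(`+`, lapply(vs, as.numeric)) / length(vs)
      attributes(m) <- attributes(vs[[1L]])
      m
    }))
  similarity <- state_similarity_analysis(
    treatment_vectors = list(treatment = avg_states[["treatment"]],
                             vehicle = avg_states[["vehicle"]]),
    baseline_vectors = avg_states[["baseline"]],
    vehicle_vectors = avg_states[["vehicle"]])
  # statistics: detection rate vehicle vs treatment per block
  det_tab <- data.frame(value = as.numeric(fits$detected),
                        condition = fits$condition, animal = fits$animal,
                        session = fits$session)
  det_tab <- det_tab[det_tab$condition %in% c("vehicle", "treatment"), ]
  stat <- hierarchical_permutation_test(det_tab,
                                        conditions = c("vehicle",
                                                       "treatment"),
                                        n_perm = cfg$n_perm,
                                        seed = cfg$seed + 77L)
  manifest <- list(
    seed = cfg$seed, n_animals = cfg$n_animals,
    n_sessions = cfg$n_sessions, epoch_s = cfg$epoch_s,
    band = cfg$band$name, block_s = cfg$block_s,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    r_version = as.character(getRversion()))
  res <- structure(list(summaries = summaries, fits = fits,
                        coupling = coupling,
                        coupling_change = coupling_change,
                        entropy = entropy, similarity = similarity,
                        behavior = behavior, stats = stat,
                        manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

summarize_band_multi <- function(fits_list, blocks_list) {
  per <- lapply(seq_along(fits_list), function(i)
    summarize_band(fits_list[[i]], blocks_list[[i]]))
  all <- do.call(rbind, per)
  agg <- stats::aggregate(
    cbind(detection_rate, band_power, peak_frequency) ~
      structure + hemisphere + condition, all, mean, na.action = NULL,
    na.rm = TRUE)
  agg[order(agg$structure, agg$condition), ]
}

#' Write a pipeline result bundle as CSV tables plus a manifest
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f) if (!is.null(d) && is.data.frame(d))
    utils::write.csv(d, file.path(out_dir, f), row.names = FALSE)
  wr(result$summaries, "oscillation_summary.csv")
  wr(result$fits, "block_fits.csv")
  wr(result$coupling, "coupling_kappa.csv")
  wr(result$coupling_change, "coupling_change.csv")
  wr(result$entropy, "entropy.csv")
  wr(result$similarity$coefficients, "state_similarity.csv")
  wr(result$behavior, "behavior_summary.csv")
  jsonlite::write_json(
    c(result$manifest,
      list(stats = list(estimate = result$stats$estimate,
                        p = result$stats$p))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d block fits; detection vehicle vs treatment p = %.3g\n",
              nrow(x$fits), x$stats$p))
  print(x$summaries)
  invisible(x)
}
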