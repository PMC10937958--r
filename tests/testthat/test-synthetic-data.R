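test_that("fractal generator hits the requested spectral exponent", {
  fs <- 2000
  x0 <- generate_fractal_signal(120, fs, exponent = 0, seed = 5)
  expect_lt(abs(fit_loglog_slope(x0, fs, fmin = 5, fmax = 300)), 0.1)
  x2 <- generate_fractal_signal(120, fs, exponent = 2, seed = 5)
  expect_lt(abs(fit_loglog_slope(x2, fs, fmin = 5, fmax = 300) + 2), 0.1)
  expect_equal(var(x2), 1, tolerance = 1e-12)
})

test_that("fractal generator is deterministic and validates input", {
  a <- generate_fractal_signal(5, 1000, 1.5, seed = 7)
  b <- generate_fractal_signal(5, 1000, 1.5, seed = 7)
  expect_identical(a, b)
  expect_error(generate_fractal_signal(NaN, 1000, 1), "finite")
  expect_error(generate_fractal_signal(10, 1000, -1), ">= 0")
  expect_error(generate_fractal_signal(10, 1000, Inf), "finite")
})

test_that("oscillatory component: zero amplitude, spectral peak, fixed lag", {
  fs <- 2000
  sched <- data.frame(start_s = 0, end_s = 60)
  z <- generate_oscillatory_component(fs, 60, 145, 10, 0, sched,
                                      channel_phase_lags = c(0, 0),
                                      seed = 1)
  expect_true(all(z == 0))

  comp <- generate_oscillatory_component(fs, 60, 145, 10, 6, sched,
                                         channel_phase_lags = c(0, pi / 8),
                                         kappa = Inf, seed = 2)
  expect_lt(abs(periodogram_peak_hz(comp[1, ], fs) - 145), 1)

  # analytic-signal phase difference equals the configured lag
  ph1 <- naive_band_phase(comp[1, ], fs, 135, 155)
  ph2 <- naive_band_phase(comp[2, ], fs, 135, 155)
  mid <- 20000:100000  # avoid ramps/edges
  d <- atan2(sin(ph1[mid] - ph2[mid]), cos(ph1[mid] - ph2[mid]))
  expect_lt(abs(mean(d) + pi / 8), 0.01)  # channel 2 leads by +pi/8
})

test_that("oscillatory component rejects invalid schedules and bands", {
  sched_bad <- data.frame(start_s = 50, end_s = 70)
  expect_error(generate_oscillatory_component(2000, 60, 145, 10, 3,
                                              sched_bad, 0),
               "outside")
  expect_error(generate_oscillatory_component(2000, 60, 995, 20, 3,
                                              data.frame(start_s = 0,
                                                         end_s = 10), 0),
               "Nyquist")
  overlapping <- data.frame(start_s = c(0, 5), end_s = c(10, 15))
  expect_error(generate_oscillatory_component(2000, 60, 145, 10, 3,
                                              overlapping, 0),
               "overlap")
})

test_that("injected amplitude is recovered in dB_fractal units", {
  fs <- 2000
  for (seed in c(3, 4)) {
    set.seed(seed)
    bg <- rbind(generate_fractal_signal(240, fs, 2, 2500),
                generate_fractal_signal(240, fs, 2, 2500))
    sched <- data.frame(start_s = 0, end_s = 240)
    comp <- generate_oscillatory_component(fs, 240, 145, 10, 6, sched,
                                           channel_phase_lags = c(0, pi / 2),
                                           kappa = Inf, background = bg,
                                           calibrate = "bipolar")
    bip <- (bg[1, ] + comp[1, ]) - (bg[2, ] + comp[2, ])
    dec <- irasa_decompose(bip, fs)
    peak <- dec$oscillatory_db[which.min(abs(dec$freq - 145))]
    expect_lt(abs(peak - 6), 1)
  }
})

test_that("per-episode phase offsets carry the configured concentration", {
  set.seed(11)
  for (kappa in c(2, 8)) {
    draws <- rvonmises(5000, 0, kappa)
    est <- estimate_von_mises(draws)
    expect_lt(abs(est$kappa - kappa) / kappa, 0.10)
  }
})

test_that("session generator assembles epochs, ledger, and rejects bad configs", {
  ep <- data.frame(label = c("baseline", "drug"),
                   start_s = c(0, 300), end_s = c(300, 900))
  cfg <- synthetic_session_config(
    duration_s = 900, condition_epochs = ep, fs = 200,
    oscillations = list(list(
      condition = "drug", band = "HFO", center_f = 45, bandwidth = 8,
      amplitude_db = 4, episode_rate_per_min = 1, episode_duration_s = 20,
      phase_lag_map = c(mPFC = 0, OFC = pi / 8), kappa = 4)),
    seed = 21)
  sess <- generate_session(cfg)
  expect_equal(sess$recording$epochs$label, c("baseline", "drug"))
  expect_equal(sess$recording$epochs$start_s, c(0, 300))
  expect_equal(sess$recording$epochs$end_s, c(300, 900))
  expect_equal(nrow(sess$recording$samples), 6)

  # episode bookkeeping: every ledger episode within the drug epoch
  eps <- sess$ground_truth$episodes
  expect_true(all(eps$start_s >= 300 & eps$end_s <= 900))
  # Poisson count tolerance: rate 1/min over 10 min
  expect_gt(nrow(eps), 10 - 3 * sqrt(10))
  expect_lt(nrow(eps), 10 + 3 * sqrt(10))
  expect_true(all(c("structure_a", "structure_b", "lag", "kappa") %in%
                    names(sess$ground_truth$pair_truth)))

  cfg_bad <- cfg
  cfg_bad$channels_per_structure <- 1L
  expect_error(generate_session(cfg_bad), "bipolar")
  expect_error(synthetic_session_config(
    duration_s = 100,
    condition_epochs = data.frame(label = c("a", "b"), start_s = c(0, 40),
                                  end_s = c(60, 80))), "overlap")
})

test_that("session generator is reproducible under a fixed seed", {
  ep <- data.frame(label = "base", start_s = 0, end_s = 30)
  cfg <- synthetic_session_config(duration_s = 30, condition_epochs = ep,
                                  fs = 500, seed = 33)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$recording$samples, s2$recording$samples)
})

test_that("no-oscillation sessions yield almost no downstream detections", {
  ep <- data.frame(label = "base", start_s = 0, end_s = 480)
  cfg <- synthetic_session_config(duration_s = 480, condition_epochs = ep,
                                  structures = data.frame(
                                    structure = "mPFC",
                                    hemisphere = "lesioned"),
                                  seed = 44)
  sess <- generate_session(cfg)
  bset <- bipolar_derive(sess$recording, sess$channel_map)
  fits <- fit_blocks(block_spectra(bset, block_s = 60),
                     band_definition("HFO"))
  expect_lte(mean(fits$detected), 0.05)
})

test_that("pose track generator honors schedules, speeds and turning", {
  # empty schedule, zero noise: static centroid
  tr0 <- generate_pose_track(data.frame(start_s = numeric(0),
                                        end_s = numeric(0)),
                             duration_s = 10, seed = 1)
  v0 <- compute_speed(average_position(tr0))
  expect_equal(max(v0), 0)

  # three scheduled bouts recovered exactly
  bs <- data.frame(start_s = c(2, 6, 10), end_s = c(4, 8, 12), speed = 5)
  tr <- generate_pose_track(bs, duration_s = 15, seed = 2)
  bouts <- detect_bouts(compute_speed(average_position(tr)), fps = 25)
  expect_equal(nrow(bouts), 3)

  # constant 10 deg/s turn for 60 s integrates to 600 degrees
  trc <- generate_pose_track(data.frame(start_s = 0, end_s = 60, speed = 3),
                             duration_s = 60, arena_diameter_cm = 100,
                             turn_rate_deg_s = 10, seed = 3)
  ang <- cumulative_turning(average_position(trc))
  expect_lt(abs(ang - 600), 5)

  expect_error(generate_pose_track(
    data.frame(start_s = c(0, 1), end_s = c(2, 3)), duration_s = 10),
    "overlap")
})
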