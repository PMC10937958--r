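test_that("peak model evaluates in closed form", {
  f <- seq(100, 185, by = 0.5)
  expect_equal(evaluate_peak_model(0, 145, 5, 0.1, 2, f), 0.1 * f + 2)
  expect_equal(evaluate_peak_model(7, 145, 5, 0.2, 1, 145), 7 + 0.2 * 145 + 1)
  expect_equal(evaluate_peak_model(10, 145, 5, 0, 0, 150), 10 * exp(-1))
  expect_error(evaluate_peak_model(1, 145, 0, 0, 0, f), "nonzero")
})

test_that("noiseless model spectra are recovered to high precision", {
  f <- seq(0.5, 300, by = 0.5)
  y <- evaluate_peak_model(10, 145, 5, 0, 0, f)
  pf <- fit_peak_model(y, band_definition("HFO"), freq = f)
  expect_lt(abs(pf$A - 10), 1e-3)
  expect_lt(abs(pf$B - 145), 1e-3)
  expect_lt(abs(pf$C - 5), 1e-3)
  expect_gt(pf$R2, 0.999)
  expect_true(pf$detected)
})

test_that("flat spectra are not detections", {
  f <- seq(0.5, 300, by = 0.5)
  pf <- fit_peak_model(rep(0, length(f)), band_definition("HFO"), freq = f)
  expect_false(pf$detected)
})

test_that("fit absorbs constant offsets into E", {
  f <- seq(0.5, 300, by = 0.5)
  y <- evaluate_peak_model(10, 145, 5, 0, 0, f)
  p0 <- fit_peak_model(y, band_definition("HFO"), freq = f)
  p5 <- fit_peak_model(y + 5, band_definition("HFO"), freq = f)
  expect_lt(abs(p5$A - p0$A), 1e-6)
  expect_lt(abs(p5$B - p0$B), 1e-6)
  expect_lt(abs(p5$C - p0$C), 1e-6)
  expect_lt(abs(p5$E - p0$E - 5), 1e-6)
})

test_that("detection thresholds are strict and band-aware", {
  hfo <- band_definition("HFO")
  gamma <- band_definition("gamma")
  base <- list(A = 3, B = 145, C = 5, D = 0, E = 0, R2 = 0.5)
  expect_true(classify_detection(base, hfo))
  expect_false(classify_detection(modifyList(base, list(A = 1.9)), hfo))
  expect_false(classify_detection(modifyList(base, list(A = 2)), hfo))
  expect_false(classify_detection(modifyList(base, list(B = 100)), hfo))
  expect_false(classify_detection(modifyList(base, list(B = 100)), gamma))
  expect_false(classify_detection(modifyList(base, list(R2 = 0.2)), hfo))
  expect_false(classify_detection(modifyList(base, list(C = 25)), hfo))
  expect_false(classify_detection(modifyList(base, list(D = 1.5)), hfo))
  expect_false(classify_detection(modifyList(base, list(E = -12)), hfo))
  expect_true(classify_detection(modifyList(base, list(B = 50)), gamma))
})

test_that("session peak frequency is the median of detected B", {
  fits <- data.frame(B = c(140, 145, 150), detected = TRUE)
  expect_equal(session_peak_frequency(fits), 145)
  expect_equal(session_peak_frequency(
    data.frame(B = 152.5, detected = TRUE)), 152.5)
  expect_true(is.na(session_peak_frequency(
    data.frame(B = c(140, 150), detected = FALSE))))
})

test_that("band power averages a 20 Hz band, matching direct integration", {
  f <- seq(0.5, 300, by = 0.5)
  expect_equal(band_power(rep(3, length(f)), 145, freq = f), 3)
  y <- evaluate_peak_model(10, 145, 5, 0, 0, f)
  # oracle: direct mean over the inclusive 41-bin band
  oracle <- mean(10 * exp(-((seq(135, 155, by = 0.5) - 145) / 5)^2))
  expect_equal(band_power(y, 145, freq = f), oracle, tolerance = 1e-12)
  expect_equal(sum(f >= 135 & f <= 155), 41)
  expect_warning(band_power(y, 295, freq = f), "truncated")
})

test_that("Monte-Carlo B recovery under 0.5 dB noise", {
  f <- seq(100, 185, by = 0.5)
  y0 <- evaluate_peak_model(10, 145, 5, 0, 0, f)
  errs <- vapply(1:25, function(s) {
    set.seed(s)
    pf <- fit_peak_model(y0 + rnorm(length(f), 0, 0.5),
                         band_definition("HFO"), freq = f)
    abs(pf$B - 145)
  }, numeric(1))
  expect_true(all(errs < 0.5))
})

test_that("summaries report rates, powers and peak frequencies", {
  fits <- data.frame(
    structure = "mPFC", hemisphere = "lesioned",
    condition = rep(c("veh"), 20), block = 1:20,
    session = "S1", animal = "A1",
    A = 5, B = seq(140, 150, length.out = 20), C = 5, D = 0, E = 0,
    R2 = 0.9, detected = rep(c(TRUE, FALSE), c(6, 14)))
  sm <- summarize_band(fits)
  expect_equal(sm$detection_rate, 30)
  expect_equal(sm$peak_frequency,
               median(fits$B[fits$detected]))
  expect_error(summarize_band(fits[0, ]), "no blocks")
})

test_that("detection rate grows with injected amplitude", {
  fs <- 2000
  rates <- vapply(c(0, 6), function(amp) {
    fits <- lapply(1:4, function(s) {
      set.seed(amp * 10 + s)
      bg <- rbind(generate_fractal_signal(60, fs, 2, 2500),
                  generate_fractal_signal(60, fs, 2, 2500))
      x <- bg
      if (amp > 0) {
        comp <- generate_oscillatory_component(
          fs, 60, 145, 10, amp, data.frame(start_s = 0, end_s = 60),
          channel_phase_lags = c(0, pi / 2), kappa = Inf,
          background = bg, calibrate = "bipolar")
        x <- bg + comp
      }
      d <- irasa_decompose(x[1, ] - x[2, ], fs)
      fit_peak_model(d, band_definition("HFO"))$detected
    })
    mean(unlist(fits))
  }, numeric(1))
  expect_lte(rates[1], 0.05)
  expect_gte(rates[2], 0.9)
})
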