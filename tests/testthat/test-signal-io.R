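make_recording <- function(nch = 4, dur = 2, fs = 100, seed = 1) {
  set.seed(seed)
  lfp_recording(matrix(rnorm(nch * dur * fs), nrow = nch), fs,
                paste0("ch", seq_len(nch)),
                epochs = data.frame(label = "all", start_s = 0,
                                    end_s = dur),
                animal = "A1", session = "S1")
}

two_structure_map <- function(rec) {
  data.frame(channel_id = rec$channel_ids,
             structure = rep(c("mPFC", "OFC"), each = 2),
             hemisphere = "lesioned", animal = "A1", session = "S1",
             stringsAsFactors = FALSE)
}

test_that("bipolar derivation differences pairs and rejects common mode", {
  rec <- make_recording()
  cm <- two_structure_map(rec)
  bset <- bipolar_derive(rec, cm)
  expect_equal(nrow(bset$signals), 2)
  expect_equal(bset$signals[1, ],
               unname(rec$samples[1, ] - rec$samples[2, ]))

  # identical channels give a zero trace
  rec2 <- rec
  rec2$samples[2, ] <- rec2$samples[1, ]
  expect_true(all(bipolar_derive(rec2, cm)$signals[1, ] == 0))

  # swapping a and b negates the trace
  rec3 <- rec
  rec3$samples[1, ] <- rec$samples[2, ]
  rec3$samples[2, ] <- rec$samples[1, ]
  expect_equal(bipolar_derive(rec3, cm)$signals[1, ],
               -bset$signals[1, ])

  # a shared (volume-conducted) sinusoid is fully rejected
  tgrid <- seq_len(ncol(rec$samples)) / rec$fs
  shared <- 10 * sin(2 * pi * 7 * tgrid)
  rec4 <- rec
  rec4$samples[1, ] <- rec4$samples[1, ] + shared
  rec4$samples[2, ] <- rec4$samples[2, ] + shared
  expect_equal(bipolar_derive(rec4, cm)$signals[1, ], bset$signals[1, ],
               tolerance = 1e-12)
})

test_that("bipolar pairing policies and degenerate structures", {
  rec <- make_recording(nch = 5)
  cm <- data.frame(channel_id = rec$channel_ids,
                   structure = c("mPFC", "mPFC", "mPFC", "mPFC", "OFC"),
                   hemisphere = "lesioned", stringsAsFactors = FALSE)
  expect_warning(bset <- bipolar_derive(rec, cm), "single channel")
  expect_equal(nrow(bset$signals), 2)  # consecutive: 1-2, 3-4
  expect_warning(ball <- bipolar_derive(rec, cm, policy = "all_pairs"),
                 "single channel")
  expect_equal(nrow(ball$signals), choose(4, 2))
})

test_that("epoch extraction is sample-accurate and validates labels", {
  fs <- 2000
  rec <- lfp_recording(matrix(0, 1, 1500 * fs), fs, "ch1",
                       epochs = data.frame(
                         label = c("baseline", "tail"),
                         start_s = c(300, 1400), end_s = c(1500, 1500)))
  sl <- extract_epoch(rec, "baseline")
  expect_equal(ncol(sl$samples), 2400000)
  # epoch ending exactly at the recording end is allowed
  expect_equal(ncol(extract_epoch(rec, "tail")$samples), 100 * fs)
  expect_error(extract_epoch(rec, "nope"), "available")
  expect_error(lfp_recording(matrix(0, 1, 100), 100, "c1",
                             epochs = data.frame(label = "x", start_s = 0,
                                                 end_s = 2)),
               "within")
})

test_that("downsampling preserves the passband and rejects aliases", {
  fs_in <- 30000
  t <- seq(0, 2 - 1 / fs_in, by = 1 / fs_in)
  x <- sin(2 * pi * 100 * t)
  y <- downsample(x, fs_in, 2000)
  expect_equal(length(y), 4000)
  # amplitude preserved within 1 percent (interior samples)
  mid <- y[500:3500]
  expect_lt(abs(diff(range(mid)) / 2 - 1), 0.01)

  # identity when rates match
  expect_identical(downsample(x, 2000, 2000), x)

  # 1500 Hz content must be attenuated by >= 40 dB after 30k -> 2k
  x2 <- sin(2 * pi * 1500 * t)
  y2 <- downsample(x2, fs_in, 2000)
  p_in <- mean(x2^2)
  p_out <- mean(y2[500:3500]^2)
  expect_gt(10 * log10(p_in / p_out), 40)
})

test_that("recording container round-trips losslessly", {
  rec <- make_recording()
  dir <- withr::local_tempdir()
  write_recording(rec, dir)
  back <- read_recording(dir)
  expect_identical(back$samples, rec$samples)
  expect_equal(back$fs, rec$fs)
  expect_identical(back$channel_ids, rec$channel_ids)
  expect_equal(back$epochs, rec$epochs)

  cmp <- file.path(dir, "map.csv")
  cm <- two_structure_map(rec)
  write_channel_map(cm, cmp)
  expect_identical(read_channel_map(cmp), cm)
  cm_bad <- cm
  cm_bad$structure[1] <- "unknown_area"
  write_channel_map(cm_bad, cmp)
  expect_warning(read_channel_map(cmp), "vocabulary")
})
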