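mk_dec <- function(db, freq) {
  fractal_decomposition(10^(db / 10), rep(1, length(freq)), freq)
}

test_that("state vectors concatenate structures in declared order", {
  freq <- seq(0.5, 300, by = 0.5)
  decs <- list(mPFC = mk_dec(rep(1, length(freq)), freq),
               OFC = mk_dec(rep(2, length(freq)), freq))
  v <- build_state_vector(decs, c("mPFC", "OFC"))
  # 1-300 Hz inclusive at 0.5 Hz: 599 bins per structure
  expect_length(v, 2 * 599)
  expect_equal(attr(v, "structures"), c("mPFC", "OFC"))

  # six structures reproduce the canonical 3594-bin vector
  six <- setNames(rep(list(mk_dec(rnorm(length(freq)), freq)), 6),
                  c("amyg", "dStr", "OFC", "mPFC", "vHipp", "vStr"))
  expect_length(build_state_vector(six), 3594)

  # a single structure is just its own spectrum
  v1 <- build_state_vector(decs["mPFC"], "mPFC")
  expect_equal(as.numeric(v1),
               decs$mPFC$oscillatory_db[freq >= 1 & freq <= 300])

  expect_error(build_state_vector(decs, c("mPFC", "vStr")), "vStr")
})

test_that("state correlation honors its invariances and degeneracies", {
  freq <- seq(0.5, 300, by = 0.5)
  set.seed(4)
  v <- build_state_vector(list(s = mk_dec(rnorm(length(freq)), freq)), "s")
  w <- build_state_vector(list(s = mk_dec(rnorm(length(freq)), freq)), "s")
  expect_equal(correlate_states(v, v), 1)
  neg <- v
  attributes(neg) <- attributes(v)
  neg[] <- -as.numeric(v)
  expect_equal(correlate_states(v, neg), -1)
  # shift/scale invariance
  shifted <- v
  shifted[] <- 2 * as.numeric(v) + 3
  expect_equal(correlate_states(v, shifted), 1)
  expect_equal(correlate_states(v, w), cor(as.numeric(v), as.numeric(w)))
  flat <- v
  flat[] <- 1
  expect_error(correlate_states(v, flat), "zero-variance")
  # order contract
  w2 <- w
  attr(w2, "structures") <- "other"
  expect_error(correlate_states(v, w2), "order")
})

test_that("similarity analysis ranks constructed treatments correctly", {
  freq <- seq(0.5, 300, by = 0.5)
  nb <- length(freq)
  set.seed(9)
  base_shape <- rnorm(nb)
  veh_shape <- rnorm(nb)
  mk <- function(shape, noise = 0.2)
    build_state_vector(list(s = mk_dec(shape + rnorm(nb, 0, noise), freq)),
                       "s")
  animals <- paste0("A", 1:4)
  baseline <- setNames(lapply(animals, function(a) mk(base_shape)), animals)
  vehicle <- setNames(lapply(animals, function(a) mk(veh_shape)), animals)
  like_veh <- setNames(lapply(animals, function(a) mk(veh_shape)), animals)
  like_base <- setNames(lapply(animals, function(a) mk(base_shape)), animals)

  res <- state_similarity_analysis(
    list(tveh = like_veh, tbase = like_base), baseline, vehicle)
  m <- res$medians
  expect_gt(m$r_vehicle_med[m$treatment == "tveh"],
            m$r_baseline_med[m$treatment == "tveh"])
  expect_gt(m$r_baseline_med[m$treatment == "tbase"],
            m$r_vehicle_med[m$treatment == "tbase"])
  expect_gt(nrow(res$tests), 0)

  # identical vectors in every group: tests degenerate and suppressed
  same <- setNames(rep(list(mk(base_shape, 0)), 4), animals)
  res0 <- state_similarity_analysis(list(t1 = same, t2 = same), same, same)
  expect_true(all(res0$coefficients$r_vs_baseline == 1))
  expect_equal(nrow(res0$tests), 0)
})

test_that("pairwise treatment similarity with omnibus test", {
  freq <- seq(0.5, 300, by = 0.5)
  nb <- length(freq)
  set.seed(10)
  ref_shape <- rnorm(nb)
  other_shape <- rnorm(nb)
  animals <- paste0("A", 1:6)
  mk <- function(shape)
    build_state_vector(list(s = mk_dec(shape + rnorm(nb, 0, 0.3), freq)),
                       "s")
  ref <- setNames(lapply(animals, function(a) mk(ref_shape)), animals)
  close_t <- setNames(lapply(animals, function(a) mk(ref_shape)), animals)
  far_t <- setNames(lapply(animals, function(a) mk(other_shape)), animals)

  res <- pairwise_treatment_similarity(ref, list(close = close_t,
                                                 far = far_t))
  med <- tapply(res$coefficients$r, res$coefficients$comparison, median)
  expect_gt(med[["close"]], med[["far"]])
  expect_equal(nrow(res$test), 1)
  expect_lt(res$test$p, 0.05)

  # single comparison group: omnibus suppressed
  res1 <- pairwise_treatment_similarity(ref, list(close = close_t))
  expect_equal(nrow(res1$test), 0)
})

test_that("within-parameter sessions correlate higher than between", {
  fs <- 2000
  mk_session_vec <- function(amp, center, seed) {
    ep <- data.frame(label = "c", start_s = 0, end_s = 60)
    cfg <- synthetic_session_config(
      duration_s = 60, condition_epochs = ep,
      structures = data.frame(structure = c("mPFC", "OFC"),
                              hemisphere = "lesioned"),
      oscillations = list(list(
        condition = "c", band = "HFO", center_f = center, bandwidth = 10,
        amplitude_db = amp,
        episode_schedule = data.frame(start_s = 0, end_s = 60),
        phase_lag_map = c(mPFC = 0, OFC = pi / 8), kappa = Inf)),
      seed = seed)
    sess <- generate_session(cfg)
    bset <- bipolar_derive(sess$recording, sess$channel_map)
    decs <- lapply(seq_len(nrow(bset$pairs)), function(i)
      irasa_decompose(bset$signals[i, ], fs))
    names(decs) <- bset$pairs$structure
    build_state_vector(decs)
  }
  wins <- vapply(1:6, function(s) {
    a1 <- mk_session_vec(6, 145, 1000 + s)
    a2 <- mk_session_vec(6, 145, 2000 + s)
    b1 <- mk_session_vec(2, 135, 3000 + s)
    within <- correlate_states(a1, a2)
    between <- max(correlate_states(a1, b1), correlate_states(a2, b1))
    within > between
  }, logical(1))
  expect_gte(sum(wins), 5)
})
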