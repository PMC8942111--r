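test_that("energy envelope matches closed forms", {
  expect_true(all(energy_envelope(numeric(4000), 1000)$rms == 0))
  x <- sin(2 * pi * 50 * seq(0, 2, by = 1 / 4000))
  env <- energy_envelope(x, 4000, frame = 0.5, hop = 0.1)
  expect_true(all(abs(env$rms - 1 / sqrt(2)) < 0.01))
  expect_error(energy_envelope(numeric(0), 1000),
               class = "breathsnr_invalid_configuration")
})

test_that("envelope steps within one frame of a silence/noise junction", {
  withr::with_seed(1, x <- c(numeric(4000), rnorm(4000)))
  env <- energy_envelope(x, 1000, frame = 0.1, hop = 0.025)
  # direct RMS oracle: frames fully before 4000 are zero, fully after ~1
  first_hot <- env$center_sample[min(which(env$rms > 0.5))]
  expect_lt(abs(first_hot - 4000), 100)  # one frame length
  expect_true(all(env$rms[env$center_sample < 3900] < 1e-12))
})

test_that("all-quiet and flat-zero input give one quiet interval", {
  env <- energy_envelope(numeric(8000), 1000)
  segs <- detect_activity(env)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$phase, "quiet")
  expect_equal(c(segs$start_sample, segs$end_sample), c(0, 8000))
})

test_that("an envelope permanently above threshold gives one active interval", {
  withr::with_seed(2, x <- rnorm(8000))
  env <- energy_envelope(x, 1000)
  segs <- detect_activity(env, floor = 0.1)  # calibrated floor well below RMS
  expect_equal(nrow(segs), 1)
  expect_equal(segs$phase, "active")
  expect_equal(c(segs$start_sample, segs$end_sample), c(0, 8000))
})

test_that("square-envelope bursts are recovered within one frame", {
  rate <- 2000
  on <- list(c(2, 4), c(7, 10), c(13, 15))  # seconds
  withr::with_seed(3, {
    x <- rnorm(16 * rate) * 0.01
    for (iv in on) {
      idx <- (iv[1] * rate + 1):(iv[2] * rate)
      x[idx] <- rnorm(length(idx))
    }
  })
  segs <- detect_activity(energy_envelope(x, rate))
  act <- segs[segs$phase == "active", ]
  expect_equal(nrow(act), 3)
  for (k in seq_along(on)) {
    expect_lt(abs(act$start_sample[k] - on[[k]][1] * rate), 0.1 * rate + 1)
    expect_lt(abs(act$end_sample[k] - on[[k]][2] * rate), 0.1 * rate + 1)
  }
})

test_that("active bursts shorter than the minimum duration are dropped", {
  rate <- 2000
  withr::with_seed(4, {
    x <- rnorm(10 * rate) * 0.01
    x[(5 * rate):(5.1 * rate)] <- rnorm(0.1 * rate + 1)  # 100 ms blip
  })
  segs <- detect_activity(energy_envelope(x, rate), min_duration = 0.25)
  expect_equal(nrow(segs[segs$phase == "active", ]), 0)
})

test_that("depth classification follows the exact two-means split", {
  rate <- 1000
  segs <- tibble::tibble(
    start_sample = seq(0, 9000, 1000), end_sample = seq(1000, 10000, 1000),
    phase = "active", depth = NA_character_, motion_rejected = FALSE
  )
  withr::with_seed(5, {
    w <- rep(rep(c(1, 10), 5), each = rate) * rnorm(10 * rate)
  })
  out <- classify_depth(w, rate, segs)
  expect_equal(out$depth, rep(c("normal", "deep"), 5))

  # equal powers -> no separation -> all normal
  withr::with_seed(6, w_eq <- rnorm(10 * rate))
  expect_true(all(classify_depth(w_eq, rate, segs)$depth == "normal"))

  # a single interval is undefined
  one <- segs[1, ]
  expect_true(is.na(classify_depth(w, rate, one)$depth))
})

test_that("motion gating flags exactly the overlapped intervals, idempotently", {
  segs <- tibble::tibble(
    start_sample = c(0L, 4000L, 8000L), end_sample = c(4000L, 8000L, 12000L),
    phase = c("active", "quiet", "active"), depth = NA_character_,
    motion_rejected = FALSE
  )
  withr::with_seed(7, {
    motion <- tibble::tibble(time_s = seq(0, 11.98, by = 0.02),
                             value = rnorm(600) * 0.02)
  })
  # burst inside the second active interval only (samples 8000-12000 @1kHz)
  motion$value[motion$time_s >= 9 & motion$time_s < 9.3] <- 0.5
  gated <- motion_gate(segs, motion, rate = 1000, threshold = 5)
  expect_equal(gated$motion_rejected, c(FALSE, FALSE, TRUE))
  # idempotent
  expect_identical(motion_gate(gated, motion, rate = 1000, threshold = 5),
                   gated)
  # zero trace rejects nothing; missing trace warns and is a no-op
  zero <- motion; zero$value <- 0
  expect_true(all(!motion_gate(segs, zero, 1000)$motion_rejected))
  expect_warning(ungated <- motion_gate(segs, NULL, 1000), "motion")
  expect_identical(ungated, segs)
  # threshold 0 rejects everything and starves the power estimator
  all_gone <- motion_gate(segs, motion, 1000, threshold = 0)
  expect_true(all(all_gone$motion_rejected))
  expect_error(
    estimate_powers(rnorm(12000), 1000, all_gone, band = c(50, 400)),
    class = "breathsnr_insufficient_data"
  )
})

test_that("segmentation tiles the recording before and after gating", {
  for (seed in 1:5) {
    sim <- mono_session(seed, program = short_program(15, breath_rate = 15),
                        rate = 2500)
    segs <- segment_session(sim$recording$audio[, 1], 2500,
                            motion = sim$recording$motion)
    n <- nrow(sim$recording$audio)
    expect_equal(segs$start_sample[1], 0)
    expect_equal(segs$end_sample[nrow(segs)], n)
    expect_equal(segs$start_sample[-1], segs$end_sample[-nrow(segs)])
  }
})

test_that("truth breath intervals are recovered at default thresholds", {
  rates <- vapply(1:5, function(seed) {
    sim <- mono_session(seed, program = short_program(30, breath_rate = 12),
                        rate = 2500)
    segs <- segment_session(sim$recording$audio[, 1], 2500)
    segment_recovery(sim$truth_segments, segs, min_jaccard = 0.8)
  }, numeric(1))
  expect_gte(mean(rates), 0.9)
})
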