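test_that("snr_db matches closed forms and caps its range", {
  expect_equal(snr_db(1, 1), 0)
  expect_equal(snr_db(10, 1), 10)
  expect_equal(snr_db(2, 1), 3.0103, tolerance = 1e-4)
  expect_equal(snr_db(0, 1), -60)
  expect_equal(snr_db(1e12, 1), 60)
  expect_equal(snr_db(1, 1e12), -60)
  expect_error(snr_db(1, 0), class = "breathsnr_invalid_configuration")
  expect_error(snr_db(-1, 1), class = "breathsnr_invalid_configuration")
})

test_that("ratio and dB-difference forms of the SNR agree", {
  withr::with_seed(1, {
    p_s <- 10^runif(1000, -6, 3)
    p_n <- 10^runif(1000, -6, 3)
  })
  ratio_form <- 10 * log10(p_s / p_n)
  diff_form <- 10 * log10(p_s) - 10 * log10(p_n)
  expect_lt(max(abs(ratio_form - diff_form)), 1e-9)
})

test_that("pure stationary noise labelled active/quiet hits the cap floor", {
  withr::with_seed(2, x <- rnorm(60000) * 0.1)
  segs <- tibble::tibble(
    start_sample = c(0L, 30000L), end_sample = c(30000L, 60000L),
    phase = c("active", "quiet"), depth = NA_character_,
    motion_rejected = FALSE
  )
  pw <- estimate_powers(x, 4000, segs, band = c(100, 1000))
  expect_lt(pw$p_signal / pw$p_noise, 0.2)  # subtraction removes the "signal"
  # with the two halves statistically identical, P_raw - P_N is tiny; the
  # epsilon floor keeps it positive
  expect_gt(pw$p_signal, 0)
})

test_that("estimated SNR tracks the generator truth without turbulence", {
  errs <- vapply(1:4, function(seed) {
    sim <- mono_session(seed, program = short_program(120, breath_rate = 12))
    pw <- estimate_powers(sim$recording$audio[, 1], 4000, sim$truth_segments,
                          band = c(100, 1000))
    est <- snr_db(pw$p_signal, pw$p_noise)
    est - sim$truth$snr_db[sim$truth$channel == "left"]
  }, numeric(1))
  expect_lte(median(abs(errs)), 1)
})

test_that("doubling the clean amplitude raises the SNR by ~6.02 dB", {
  est_for <- function(clean_power) {
    sim <- mono_session(seed = 31, program = short_program(60),
                        clean_power = clean_power)
    pw <- estimate_powers(sim$recording$audio[, 1], 4000, sim$truth_segments,
                          band = c(100, 1000))
    snr_db(pw$p_signal, pw$p_noise)
  }
  gain <- est_for(0.4) - est_for(0.1)  # 4x power = 2x amplitude
  expect_lt(abs(gain - 6.02), 0.5)
})

test_that("snr_db is invariant to an overall waveform scale", {
  sim <- mono_session(seed = 32, program = short_program(30))
  x <- sim$recording$audio[, 1]
  est <- function(w) {
    pw <- estimate_powers(w, 4000, sim$truth_segments, band = c(100, 1000))
    snr_db(pw$p_signal, pw$p_noise)
  }
  expect_lt(abs(est(x) - est(37.2 * x)), 1e-6)
})

test_that("missing phases raise insufficient-data errors naming the phase", {
  x <- rnorm(10000)
  all_active <- tibble::tibble(start_sample = 0L, end_sample = 10000L,
                               phase = "active", depth = NA_character_,
                               motion_rejected = FALSE)
  expect_error(estimate_powers(x, 1000, all_active, c(50, 400)),
               regexp = "quiet", class = "breathsnr_insufficient_data")
  all_quiet <- all_active
  all_quiet$phase <- "quiet"
  expect_error(estimate_powers(x, 1000, all_quiet, c(50, 400)),
               regexp = "active", class = "breathsnr_insufficient_data")
})

test_that("duplicated mono channels give identical per-channel results", {
  sim <- mono_session(seed = 33, program = short_program(30))
  x <- sim$recording$audio[, 1]
  rec <- recording(cbind(x, x), 4000, channels = c("left", "right"))
  res <- session_snr(rec)
  expect_equal(res$snr_db[1], res$snr_db[2])
  expect_equal(res$p_signal[1], res$p_signal[2])
})

test_that("a severity-mapped turbulence twin scores a lower session SNR", {
  # twins identical except obstruction severity: turbulence power rises ~16x
  # from health scale 9 to 3 while (per the severity map) clean breath power
  # falls with it, so both the truth and the estimated SNR must drop
  session_est <- function(scale) {
    subj <- sim_subject("twin", scale, "healthy", seed = 34)
    sim <- simulate_subject(subj, short_program(60), heart_amplitude = 0,
                            n_motion_bursts = 0)
    list(est = session_snr(recording(sim$recording$audio[, 1], 4000))$snr_db,
         truth = sim$truth$snr_db[1])
  }
  healthy <- session_est(9)
  severe <- session_est(3)
  expect_gt(healthy$est, severe$est)
  expect_gt(healthy$truth, severe$truth)
})

test_that("session results satisfy the dB identity and carry the band", {
  sim <- mono_session(seed = 35, program = short_program(30))
  res <- session_snr(recording(sim$recording$audio[, 1], 4000))
  expect_equal(res$snr_db, res$p_signal_db - res$p_noise_db, tolerance = 1e-9)
  expect_equal(c(res$band_lo_hz, res$band_hi_hz), c(100, 1000))
  segs <- attr(res, "segments")[["left"]]
  expect_s3_class(segs, "tbl_df")
})
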