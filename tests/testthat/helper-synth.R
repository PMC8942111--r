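# Shared fixtures: short breathing programs and quick simulated sessions so
# individual tests stay fast. Durations are multiples of the breath cycle so
# truth intervals are never truncated at block boundaries.

short_program <- function(duration = 10, depth = "normal", breath_rate = 15,
                          ...) {
  breath_program(
    depth_sequence = data.frame(depth = depth, duration = duration),
    breath_rate = breath_rate, ...
  )
}

two_phase_program <- function(each = 20, ...) {
  breath_program(
    depth_sequence = data.frame(depth = c("normal", "deep"),
                                duration = c(each, each)),
    ...
  )
}

# A subject with fixed (non-severity-mapped) generator physics, for tests
# that vary one knob at a time.
fixed_subject <- function(seed = 1, clean_power = 0.5, turbulence = 0,
                          scale = 8, group = "healthy") {
  sim_subject(
    paste0("T", seed), scale, group, seed = seed,
    scale_map = function(h) turbulence,
    clean_power_map = function(h) clean_power
  )
}

# Mono 1-channel session for estimator tests: source -> channel, no heart,
# no motion, truth powers from the generator's own components.
mono_session <- function(seed, program = short_program(60, breath_rate = 12),
                         rate = 4000, band = c(100, 1000),
                         clean_power = 0.5, ambient = 2e-3, turbulence = 0,
                         fabric_db = 0) {
  subj <- fixed_subject(seed, clean_power, turbulence)
  models <- subject_channel_models(subj, fabric_attenuation_db = fabric_db,
                                   ambient_noise_power = ambient)
  sim <- simulate_subject(
    subj, program, models, rate = rate, band = band,
    heart_amplitude = 0, n_motion_bursts = 0, keep_components = TRUE
  )
  sim
}

# Coherent band-noise signal plus per-channel noises, with known labels:
# the workhorse fixture for the array tests.
two_channel_fixture <- function(seed, dur = 20, rate = 4000, lag = 0,
                                noise_sd = 0.2, correlated_noise = FALSE,
                                signal_sd = 1) {
  withr::with_seed(seed, {
    n <- dur * rate
    s <- bandpass(rnorm(n), rate, c(100, 1000))
    s <- signal_sd * s / sd(s)
    # breathing-style gating: 2 s on / 2 s off
    gate <- rep(rep(c(1, 0), each = 2 * rate), length.out = n)
    s <- s * gate
    n1 <- rnorm(n, sd = noise_sd)
    n2 <- if (correlated_noise) n1 else rnorm(n, sd = noise_sd)
    left <- s + n1
    right <- breathsnr:::shift_samples(s, lag) + n2
    segs <- tibble::tibble(
      start_sample = seq(0, n - 2 * rate, by = 2 * rate),
      end_sample = seq(2 * rate, n, by = 2 * rate),
      phase = rep(c("active", "quiet"), length.out = dur / 2),
      depth = NA_character_, motion_rejected = FALSE
    )
    list(left = left, right = right, segs = segs, rate = rate)
  })
}

active_mask_of <- function(sim) {
  n <- nrow(sim$recording$audio)
  breathsnr:::intervals_mask(
    sim$truth_segments[sim$truth_segments$phase == "active", ], n
  )
}
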