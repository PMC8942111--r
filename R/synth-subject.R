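#' Health-scale severity maps
#'
#' Obstruction severity is parameterized by the self-reported health scale
#' (1--10, 10 = excellent health). Two monotone maps translate the scale into
#' generator physics:
#'
#' * `default_scale_map()`: turbulence-noise power falls 2 dB per health-scale
#'   step, i.e. obstruction-induced turbulence is strongest at scale 1.
#' * `default_clean_power_map()`: clean breath-sound power in the analysis
#'   band falls 2 dB per step of *severity* (rises with health), because an
#'   obstructed airway carries less laminar airflow -- turbulent energy
#'   replaces, rather than adds to, clean breath-sound energy.
#'
#' Together these make both the true and the estimated SNR decrease with
#' obstruction severity, spanning roughly 18 dB of turbulence power and
#' 26 dB of true SNR across the ten scale values.
#'
#' @param health_scale Integer vector in 1..10.
#' @param p0 Turbulence power (watts) at health scale 1 (worst obstruction).
#' @param p_healthy Clean breath-sound band power (watts) at health scale 10.
#' @param db_per_step Slope of the map in dB per health-scale step.
#' @return Power in watts.
#' @export
default_scale_map <- function(health_scale, p0 = 0.006, db_per_step = 2) {
  p0 * 10^(-(health_scale - 1) * db_per_step / 10)
}

#' @rdname default_scale_map
#' @export
default_clean_power_map <- function(health_scale, p_healthy = 0.5,
                                    db_per_step = 2) {
  p_healthy * 10^(-(10 - health_scale) * db_per_step / 10)
}

#' Define a simulated subject
#'
#' @param subject_id Opaque identifier string.
#' @param health_scale Integer 1--10 (10 = excellent health).
#' @param group `"healthy"` or `"copd"`.
#' @param seed Integer seed; all of the subject's randomness derives from it.
#' @param scale_map Function health scale -> turbulence noise power (watts);
#'   must be monotone decreasing.
#' @param clean_power_map Function health scale -> clean breath-sound band
#'   power (watts); monotone increasing.
#' @return A list of class `sim_subject`.
#' @export
sim_subject <- function(subject_id, health_scale, group = c("healthy", "copd"),
                        seed = 1L,
                        scale_map = default_scale_map,
                        clean_power_map = default_clean_power_map) {
  group <- match.arg(group)
  if (!health_scale %in% 1:10) {
    abort_config("health_scale must be an integer in 1..10.")
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      health_scale = as.integer(health_scale),
      group = group,
      turbulence_noise_power = scale_map(health_scale),
      clean_signal_power = clean_power_map(health_scale),
      seed = as.integer(seed)
    ),
    class = "sim_subject"
  )
}

default_taps <- function(side) {
  if (side == "left") {
    data.frame(attenuation = c(1, 0.4), delay = c(0, 0.004))
  } else {
    data.frame(attenuation = c(1, 0.4), delay = c(0.00075, 0.005))
  }
}

#' Default bilateral channel models for a simulated subject
#'
#' Two-tap multipath per side (direct path plus one weaker reflection), the
#' right channel's direct path arriving a fraction of a millisecond later
#' than the left's, with the subject's severity-mapped turbulence power on
#' both channels.
#'
#' @param subject A [sim_subject()].
#' @param fabric_attenuation_db Broadband fabric loss in dB.
#' @param ambient_noise_power Ambient white-noise variance (watts).
#' @return List with elements `left` and `right`, each a [channel_model()].
#' @export
subject_channel_models <- function(subject, fabric_attenuation_db = 0,
                                   ambient_noise_power = 2e-3) {
  make <- function(side) {
    channel_model(
      taps_left = default_taps(side), taps_right = default_taps(side),
      fabric_attenuation_db = fabric_attenuation_db,
      ambient_noise_power = ambient_noise_power,
      turbulence_noise_power = subject$turbulence_noise_power
    )
  }
  list(left = make("left"), right = make("right"))
}

# Active-interval mean square of a component (the generator's power unit).
active_power <- function(x, mask) mean(x[mask]^2)

#' Simulate one subject's bilateral session
#'
#' Composes the source, channel, heart-sound and motion-artifact generators
#' into a fully annotated two-channel session: left/right thorax audio, a
#' motion trace with injected artifact bursts, ground-truth breath-phase
#' segments, and ground-truth per-channel SNR computed from the generator's
#' known clean-signal and noise powers inside breath-active intervals.
#'
#' The source amplitude is rescaled so the realized clean breath-sound band
#' power matches the subject's severity-mapped `clean_signal_power`. Heart
#' sounds are added to the left channel only; by default their in-band power
#' counts toward signal (`heart_counts_as_signal = TRUE`), which reproduces
#' the empirically higher left-thorax SNR.
#'
#' @param subject A [sim_subject()].
#' @param program A [breath_program()] (default: 4-minute
#'   normal/deep/normal/deep sequence).
#' @param models List with `left` and `right` [channel_model()]s; default
#'   [subject_channel_models()].
#' @param rate Sampling rate in Hz.
#' @param band Breath-sound band in Hz.
#' @param shared_source If `TRUE` both channels receive the same source
#'   waveform through their respective channels (coherent lungs); if `FALSE`
#'   each lung gets an independent carrier with the same breath envelope.
#' @param heart_amplitude Peak S1 amplitude on the left channel; 0 disables.
#' @param heart_rate Beats per minute.
#' @param heart_counts_as_signal Whether heart-sound in-band power is credited
#'   to the truth signal power (else it is counted as noise).
#' @param motion_rate Motion-trace sampling rate in Hz.
#' @param n_motion_bursts Number of injected motion-artifact bursts; `NULL`
#'   draws 0--3 uniformly.
#' @param keep_components Keep the per-channel clean/noise component
#'   waveforms (for bookkeeping tests); off by default to save memory.
#'
#' @return A list of class `sim_output`: `recording` ([recording()] with
#'   motion trace), `truth_segments` (tibble), `truth` (tibble with one row
#'   per channel: `channel`, `p_signal`, `p_noise`, `snr_db`), `burst_times_s`,
#'   `subject`, and optionally `components`.
#' @export
simulate_subject <- function(subject,
                             program = breath_program(),
                             models = subject_channel_models(subject),
                             rate = 4000,
                             band = c(100, 1000),
                             shared_source = TRUE,
                             heart_amplitude = 0.3,
                             heart_rate = 72,
                             heart_counts_as_signal = TRUE,
                             motion_rate = 50,
                             n_motion_bursts = NULL,
                             keep_components = FALSE) {
  seeds <- derive_seeds(subject$seed, 7)
  src_l <- simulate_breath_source(program, band, rate, amplitude = 1,
                                  seed = seeds[1])
  src_r <- if (shared_source) src_l else {
    simulate_breath_source(program, band, rate, amplitude = 1,
                           seed = seeds[2])
  }
  segs <- src_l$segments
  n <- length(src_l$waveform)
  mask <- intervals_mask(segs[segs$phase == "active", ], n)
  band_fraction <- (band[2] - band[1]) / (rate / 2)

  one_side <- function(src, side, model, seed) {
    # rescale the source so the post-tap clean band power (before fabric and
    # noise) hits the severity-mapped target exactly on both sides
    taps <- if (side == "left") model$taps_left else model$taps_right
    dry <- tap_sum(src$waveform, taps, rate)
    scale <- sqrt(subject$clean_signal_power / active_power(dry, mask))
    apply_channel(scale * src$waveform, model, side = side, rate = rate,
                  breath_active = segs, seed = seed)
  }
  left <- one_side(src_l, "left", models$left, seeds[3])
  right <- one_side(src_r, "right", models$right, seeds[4])

  heart <- NULL
  if (heart_amplitude > 0) {
    hs <- add_heart_sounds(left$waveform, rate, heart_rate,
                           amplitude = heart_amplitude, seed = seeds[5])
    left$waveform <- hs$waveform
    heart <- hs$heart
  }

  truth_row <- function(ch, side) {
    p_sig <- active_power(ch$clean, mask)
    p_noise <- models[[side]]$ambient_noise_power * band_fraction +
      models[[side]]$turbulence_noise_power
    if (side == "left" && !is.null(heart)) {
      p_heart <- active_power(bandpass(heart, rate, band), mask)
      if (heart_counts_as_signal) p_sig <- p_sig + p_heart
      else p_noise <- p_noise + p_heart
    }
    snr <- if (p_noise <= 0) 60 else max(min(power_to_db(p_sig / p_noise), 60), -60)
    tibble::tibble(channel = side, p_signal = p_sig, p_noise = p_noise,
                   snr_db = snr)
  }
  truth <- dplyr::bind_rows(truth_row(left, "left"), truth_row(right, "right"))

  # motion trace: small baseline sway plus 0-3 artifact bursts, each burst a
  # simultaneous audio thump and a motion-trace spike >= 5x baseline RMS
  n_m <- round(n / rate * motion_rate)
  motion_out <- withr::with_seed(seeds[6], {
    baseline_sd <- 0.02
    trace <- rnorm(n_m, sd = baseline_sd)
    k <- n_motion_bursts %||% sample(0:3, 1)
    dur_s <- n / rate
    times <- if (k > 0) sort(runif(k, 0, max(dur_s - 0.3, 0))) else numeric(0)
    thump <- numeric(n)
    for (t0 in times) {
      # motion-trace spike
      ms <- round(t0 * motion_rate); mlen <- min(round(0.3 * motion_rate), n_m - ms)
      if (mlen > 0) {
        trace[(ms + 1):(ms + mlen)] <- trace[(ms + 1):(ms + mlen)] +
          8 * baseline_sd * tukey_window(mlen, 1)
      }
      # broadband audio thump overlapping the breath band
      as_ <- round(t0 * rate); alen <- min(round(0.3 * rate), n - as_)
      if (alen > 0) {
        tt <- seq_len(alen) / rate
        thump[(as_ + 1):(as_ + alen)] <- thump[(as_ + 1):(as_ + alen)] +
          3 * sin(2 * pi * 180 * tt) * exp(-tt / 0.08)
      }
    }
    list(trace = trace, times = times, thump = thump)
  })
  left$waveform <- left$waveform + motion_out$thump
  right$waveform <- right$waveform + 0.8 * motion_out$thump

  rec <- recording(
    cbind(left$waveform, right$waveform), rate,
    channels = c("left", "right"),
    motion = tibble::tibble(
      time_s = (seq_len(n_m) - 1) / motion_rate,
      value = motion_out$trace
    )
  )
  out <- list(
    recording = rec,
    truth_segments = segs,
    truth = truth,
    burst_times_s = motion_out$times,
    subject = subject,
    band = band
  )
  if (keep_components) {
    out$components <- list(left = left, right = right, heart = heart)
  }
  structure(out, class = "sim_output")
}
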