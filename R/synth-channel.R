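#' Pass a lung-sound source through a thorax channel
#'
#' Realizes the sparse multipath convolution of the channel model on a source
#' waveform: a sum of attenuated, integer-sample-delayed copies (delays are
#' rounded to the nearest sample), followed by broadband fabric attenuation,
#' plus white ambient noise everywhere and band-limited turbulence noise
#' inside breath-active intervals only (turbulence requires airflow).
#'
#' @param source A [simulate_breath_source()] result or a numeric waveform.
#' @param model A [channel_model()].
#' @param side `"left"` or `"right"`: which side's filter taps to use.
#' @param rate Sampling rate in Hz (taken from `source` when it is a
#'   `breath_source`).
#' @param breath_active Tibble of truth intervals (`start_sample`,
#'   `end_sample`, `phase`) gating the turbulence noise; taken from `source`
#'   when it is a `breath_source`.
#' @param seed Optional integer seed for the noise draws.
#'
#' @return A list of class `received_channel`: `waveform` (the received
#'   signal), plus the stored `clean`, `ambient` and `turbulence` components
#'   and `rate`, for ground-truth bookkeeping.
#' @export
apply_channel <- function(source, model, side = c("left", "right"),
                          rate = NULL, breath_active = NULL, seed = NULL) {
  side <- match.arg(side)
  if (inherits(source, "breath_source")) {
    rate <- rate %||% source$rate
    breath_active <- breath_active %||% source$segments
    x <- source$waveform
  } else {
    x <- as.numeric(source)
    if (is.null(rate)) abort_config("rate is required for a bare waveform.")
  }
  n <- length(x)
  if (n == 0) abort_config("empty source waveform.")
  taps <- if (side == "left") model$taps_left else model$taps_right
  clean <- tap_sum(x, taps, rate) *
    db_to_amplitude(-model$fabric_attenuation_db)

  out <- with_seed_if(seed, {
    ambient <- if (model$ambient_noise_power > 0) {
      rnorm(n, sd = sqrt(model$ambient_noise_power))
    } else {
      numeric(n)
    }
    turbulence <- numeric(n)
    if (model$turbulence_noise_power > 0) {
      if (is.null(breath_active)) {
        abort_config("breath_active intervals required when turbulence power > 0.")
      }
      mask <- intervals_mask(
        breath_active[breath_active$phase == "active", , drop = FALSE], n
      )
      if (any(mask)) {
        raw <- bandpass(rnorm(n), rate, model$turbulence_band)
        # scale so realized variance over the gated samples equals the
        # requested power exactly
        raw <- raw * sqrt(model$turbulence_noise_power / var(raw[mask]))
        turbulence[mask] <- raw[mask]
      }
    }
    list(ambient = ambient, turbulence = turbulence)
  })

  structure(
    list(
      waveform = clean + out$ambient + out$turbulence,
      clean = clean,
      ambient = out$ambient,
      turbulence = out$turbulence,
      rate = rate
    ),
    class = "received_channel"
  )
}

# Sparse multipath convolution: sum of attenuated, integer-sample-delayed
# copies of the source.
tap_sum <- function(x, taps, rate) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(nrow(taps))) {
    d <- round(taps$delay[i] * rate)
    if (d >= n) {
      abort_config(sprintf(
        "tap delay %.4f s exceeds the signal duration.", taps$delay[i]
      ))
    }
    out <- out + taps$attenuation[i] * shift_samples(x, d)
  }
  out
}

#' Superimpose heart sounds on a waveform
#'
#' Adds a periodic S1/S2-like heart-sound train: two short damped low-frequency
#' tone bursts per cardiac cycle (S1 at cycle onset, the quieter S2 300 ms
#' later). The cohort simulator applies this to the left-thorax channel only,
#' mirroring the stronger heart-sound coupling at the anterior left chest.
#'
#' @param waveform Numeric waveform.
#' @param rate Sampling rate in Hz.
#' @param heart_rate Beats per minute (> 0).
#' @param amplitude Peak S1 amplitude; `0` leaves the input untouched.
#' @param seed Optional seed for the small per-beat amplitude variability.
#'
#' @return A list with `waveform` (input plus heart sounds) and `heart` (the
#'   heart-sound component alone).
#' @export
add_heart_sounds <- function(waveform, rate, heart_rate = 72,
                             amplitude = 0.3, seed = NULL) {
  if (heart_rate <= 0) abort_config("heart_rate must be positive.")
  if (rate <= 0) abort_config("rate must be positive.")
  n <- length(waveform)
  heart <- numeric(n)
  if (amplitude > 0) {
    period <- 60 / heart_rate
    onsets <- seq(0, (n - 1) / rate, by = period)
    jitter <- with_seed_if(seed, runif(length(onsets), 0.9, 1.1))
    burst <- function(t0, freq, dur, amp) {
      s <- round(t0 * rate)
      len <- min(round(dur * rate), n - s)
      if (len <= 0) return(invisible(NULL))
      tt <- seq_len(len) / rate
      heart[(s + 1):(s + len)] <<- heart[(s + 1):(s + len)] +
        amp * sin(2 * pi * freq * tt) * exp(-tt / 0.03)
      invisible(NULL)
    }
    for (k in seq_along(onsets)) {
      burst(onsets[k], 45, 0.12, amplitude * jitter[k])          # S1
      burst(onsets[k] + 0.3, 70, 0.09, 0.6 * amplitude * jitter[k]) # S2
    }
  }
  list(waveform = waveform + heart, heart = heart)
}
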