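#' Signal-to-noise ratio in dB
#'
#' The breathing-intensity metric: `10 * log10(P_S / P_N)`, identically equal
#' to the difference of the dB powers. Values are capped to `[-cap, +cap]`
#' (default 60 dB) so noise-free and signal-free limits stay finite; a zero
#' signal power returns the cap floor.
#'
#' @param p_signal Signal power in watts (>= 0).
#' @param p_noise Noise power in watts (> 0).
#' @param cap_db Symmetric cap in dB.
#' @return SNR in dB (vectorized).
#' @export
#' @examples
#' snr_db(10, 1)   # 10
#' snr_db(2, 1)    # 3.0103
snr_db <- function(p_signal, p_noise, cap_db = 60) {
  if (any(p_noise <= 0)) abort_config("noise power must be > 0.")
  if (any(p_signal < 0)) abort_config("signal power must be >= 0.")
  out <- ifelse(p_signal == 0, -cap_db,
                10 * log10(p_signal / p_noise))
  pmax(pmin(out, cap_db), -cap_db)
}

#' Estimate signal and noise powers from a segmented waveform
#'
#' Noise power is the analysis-band power over the concatenated non-rejected
#' quiet intervals (the observable ambient proxy). Raw active power is the
#' band power over the concatenated non-rejected breath-active intervals, and
#' the signal power is the ambient-subtracted `P_raw - P_N`, floored at
#' `epsilon * P_N` so it can never go negative. Turbulence noise co-occurring
#' with airflow is therefore attributed to the signal term to the extent it
#' exceeds the quiet-interval estimate -- a documented property of the
#' quiet-interval estimator.
#'
#' @param waveform Numeric waveform (unfiltered; band restriction happens in
#'   the spectral estimate).
#' @param rate Sampling rate in Hz.
#' @param segments Segment tibble (see [segment_session()]); motion-rejected
#'   intervals are excluded.
#' @param band Analysis band in Hz.
#' @param config An [analysis_config()] providing the Welch parameters and
#'   deep-breath inclusion policy.
#' @param epsilon Signal-power floor as a fraction of the noise power.
#' @return Named list: `p_signal`, `p_noise`, `p_raw`, `n_active`, `n_quiet`,
#'   `n_rejected`.
#' @export
estimate_powers <- function(waveform, rate, segments, band = c(100, 1000),
                            config = analysis_config(band = band),
                            epsilon = 1e-6) {
  if (!"motion_rejected" %in% names(segments)) segments$motion_rejected <- FALSE
  if (!"depth" %in% names(segments)) segments$depth <- NA_character_
  usable <- segments[!segments$motion_rejected, , drop = FALSE]
  act <- usable[usable$phase == "active", , drop = FALSE]
  if (!config$include_deep) {
    act <- act[is.na(act$depth) | act$depth != "deep", , drop = FALSE]
  }
  qui <- usable[usable$phase == "quiet", , drop = FALSE]
  if (nrow(act) == 0) {
    abort_insufficient(
      "no usable breath-active interval (all missing or motion-rejected)."
    )
  }
  if (nrow(qui) == 0) {
    abort_insufficient(
      "no usable quiet interval (all missing or motion-rejected)."
    )
  }
  concat <- function(iv) {
    unlist(lapply(seq_len(nrow(iv)), function(i) {
      waveform[(iv$start_sample[i] + 1):iv$end_sample[i]]
    }), use.names = FALSE)
  }
  bp <- function(x) {
    band_power(
      welch_psd(x, rate, config$welch_segment, config$welch_overlap), band
    )
  }
  p_raw <- bp(concat(act))
  p_noise <- bp(concat(qui))
  p_noise <- max(p_noise, .Machine$double.xmin)
  list(
    p_signal = max(p_raw - p_noise, epsilon * p_noise),
    p_noise = p_noise,
    p_raw = p_raw,
    n_active = nrow(act),
    n_quiet = nrow(qui),
    n_rejected = sum(segments$motion_rejected)
  )
}

#' Per-channel session SNR
#'
#' Runs the full single-channel pipeline on every channel of a recording:
#' band-pass, energy envelope, hysteresis activity detection, depth
#' classification, motion gating, quiet-interval power estimation, and the
#' dB SNR. A result is flagged `low_confidence` when fewer than 3 usable
#' active or quiet intervals supported it.
#'
#' @param rec A [recording()].
#' @param config An [analysis_config()].
#' @return A tibble of class `breathsnr_snr` with one row per channel:
#'   `channel`, `p_signal`, `p_noise`, `p_signal_db`, `p_noise_db`, `snr_db`,
#'   `band_lo_hz`, `band_hi_hz`, `n_active`, `n_quiet`, `n_rejected`,
#'   `low_confidence`. The per-channel segment tibbles are attached as
#'   attribute `"segments"`.
#' @export
session_snr <- function(rec, config = analysis_config()) {
  seg_list <- list()
  rows <- purrr::map_dfr(seq_along(rec$channels), function(ci) {
    ch <- rec$channels[ci]
    x <- rec$audio[, ci]
    if (sd(x) == 0) {
      abort_config(sprintf("channel '%s' has zero variance.", ch))
    }
    segs <- segment_session(x, rec$rate, config, motion = rec$motion)
    seg_list[[ch]] <<- segs
    pw <- tryCatch(
      estimate_powers(x, rec$rate, segs, config$band, config),
      error = function(e) {
        abort(sprintf("channel '%s': %s", ch, conditionMessage(e)),
              class = class(e)[1], parent = e)
      }
    )
    tibble::tibble(
      channel = ch,
      p_signal = pw$p_signal,
      p_noise = pw$p_noise,
      p_signal_db = power_to_db(pw$p_signal),
      p_noise_db = power_to_db(pw$p_noise),
      snr_db = snr_db(pw$p_signal, pw$p_noise, config$snr_cap_db),
      band_lo_hz = config$band[1],
      band_hi_hz = config$band[2],
      n_active = pw$n_active,
      n_quiet = pw$n_quiet,
      n_rejected = pw$n_rejected,
      low_confidence = pw$n_active < 3 || pw$n_quiet < 3
    )
  })
  attr(rows, "segments") <- seg_list
  class(rows) <- c("breathsnr_snr", class(rows))
  rows
}
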