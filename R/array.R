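#' Estimate the bilateral alignment between the two thorax channels
#'
#' Normalized cross-correlation between the left and right channels within
#' `+/- max_lag`, restricted (when segments are supplied) to breath-active,
#' non-rejected samples -- the coherent component across the chest is the
#' breath signal, not the ambient noise. Positive lag means the right channel
#' lags the left. Exact ties are broken toward the smallest `|lag|`, then the
#' negative lag. Combination weights are proportional to the per-channel
#' linear SNR estimates (equal when none are supplied), normalized to sum
#' to 1.
#'
#' @param x_left,x_right Numeric channel waveforms of equal length.
#' @param rate Sampling rate in Hz.
#' @param max_lag Maximum |lag| searched, in seconds.
#' @param segments Optional segment tibble used to mask to breath-active,
#'   non-rejected samples.
#' @param snr_linear Optional length-2 numeric: linear (not dB) per-channel
#'   SNR estimates `c(left, right)` for the combination weights.
#' @return A list of class `breathsnr_alignment`: `lag` (samples, signed),
#'   `peak_correlation`, `weights` (named, sums to 1), `rate`, `max_lag`.
#' @export
estimate_delay <- function(x_left, x_right, rate, max_lag = 0.05,
                           segments = NULL, snr_linear = NULL) {
  n <- length(x_left)
  if (length(x_right) != n) abort_config("channels must have equal length.")
  max_lag_samp <- round(max_lag * rate)
  if (n < 2 * max_lag_samp) {
    abort_config("channels shorter than twice the maximum lag.")
  }
  if (sd(x_left) == 0) abort_config("left channel has zero variance.")
  if (sd(x_right) == 0) abort_config("right channel has zero variance.")

  xl <- x_left; xr <- x_right
  if (!is.null(segments)) {
    mask <- intervals_mask(
      segments[segments$phase == "active" & !segments$motion_rejected, ], n
    )
    if (any(mask)) {
      xl <- ifelse(mask, xl, 0)
      xr <- ifelse(mask, xr, 0)
    }
  }
  cc <- ccf(xl, xr, lag.max = max_lag_samp, plot = FALSE,
            demean = TRUE)
  # ccf lag k correlates left[t+k] with right[t]; right lagging left by d
  # peaks at k = -d, so our signed lag is the negated ccf lag
  lags <- -as.vector(cc$lag)
  vals <- as.vector(cc$acf)
  peak <- max(vals)
  cand <- which(vals >= peak - 1e-12)
  cand <- cand[order(abs(lags[cand]), lags[cand])]
  best <- cand[1]

  if (is.null(snr_linear)) snr_linear <- c(1, 1)
  if (any(snr_linear < 0)) abort_config("snr_linear must be >= 0.")
  w <- snr_linear / sum(snr_linear)

  structure(
    list(
      lag = lags[best],
      peak_correlation = vals[best],
      weights = c(left = w[1], right = w[2]),
      rate = rate,
      max_lag = max_lag
    ),
    class = "breathsnr_alignment"
  )
}

#' @export
print.breathsnr_alignment <- function(x, ...) {
  cat(sprintf(
    "<alignment> lag %d samples (%.2f ms), peak correlation %.3f, weights L %.2f / R %.2f\n",
    x$lag, 1000 * x$lag / x$rate, x$peak_correlation,
    x$weights[1], x$weights[2]
  ))
  invisible(x)
}

#' @describeIn estimate_delay Tidy the alignment into a one-row tibble.
#' @param x A `breathsnr_alignment`.
#' @param ... Unused.
#' @export
tidy.breathsnr_alignment <- function(x, ...) {
  tibble::tibble(
    lag_samples = x$lag,
    lag_ms = 1000 * x$lag / x$rate,
    peak_correlation = x$peak_correlation,
    weight_left = unname(x$weights[1]),
    weight_right = unname(x$weights[2])
  )
}

#' Delay-and-sum bilateral combination
#'
#' Shifts the right channel to undo the estimated lag and forms the weighted
#' sum of the two channels (weights sum to one, so a coherent signal passes
#' at unit gain while independent noise is averaged down). If the peak
#' cross-correlation is below `coherence_threshold` the channels are too
#' incoherent for useful summing and the combination degrades to selecting
#' the higher-weighted (higher-SNR) channel, with a notice.
#'
#' @param x_left,x_right Numeric channel waveforms of equal length.
#' @param alignment A [estimate_delay()] result.
#' @param coherence_threshold Peak-correlation fallback threshold.
#' @return Combined numeric waveform of the same length.
#' @export
combine_bilateral <- function(x_left, x_right, alignment,
                              coherence_threshold = 0.2) {
  if (length(x_left) != length(x_right)) {
    abort_config("channels must have equal length.")
  }
  w <- alignment$weights
  if (alignment$peak_correlation < coherence_threshold) {
    inform(sprintf(
      "peak correlation %.2f below %.2f; selecting the higher-SNR channel.",
      alignment$peak_correlation, coherence_threshold
    ))
    return(if (w[1] >= w[2]) x_left else x_right)
  }
  aligned_right <- shift_samples(x_right, -alignment$lag)
  w[1] * x_left + w[2] * aligned_right
}

#' Bilateral array gain in dB
#'
#' SNR improvement of the combined array signal over the best single
#' channel: `combined_snr - max(single_snrs)`. May be negative (reported,
#' never clamped). All inputs must share the same analysis band.
#'
#' @param combined One-row slice of a [session_snr()] tibble for the
#'   combined channel.
#' @param singles [session_snr()] rows for the individual channels.
#' @return Array gain in dB.
#' @export
array_gain_db <- function(combined, singles) {
  bands <- unique(rbind(
    combined[, c("band_lo_hz", "band_hi_hz")],
    singles[, c("band_lo_hz", "band_hi_hz")]
  ))
  if (nrow(bands) != 1) {
    abort_config("combined and single-channel results use different bands.")
  }
  combined$snr_db - max(singles$snr_db)
}

#' Bilateral session analysis
#'
#' Runs [session_snr()] on both channels, estimates the bilateral alignment
#' over the left channel's breath-active intervals with SNR-proportional
#' weights, forms the delay-and-sum combination, analyzes the combined
#' waveform with the same pipeline, and reports the array gain.
#'
#' @param rec A two-channel [recording()].
#' @param config An [analysis_config()].
#' @return A tibble of class `breathsnr_snr` with rows `left`, `right` and
#'   `combined`, plus columns `array_gain_db`, `lag_samples` and
#'   `peak_correlation` (populated on the combined row). The alignment
#'   object is attached as attribute `"alignment"`.
#' @export
bilateral_snr <- function(rec, config = analysis_config()) {
  if (ncol(rec$audio) != 2) {
    abort_config("bilateral analysis needs a two-channel recording.")
  }
  singles <- session_snr(rec, config)
  segs_left <- attr(singles, "segments")[["left"]]
  align <- estimate_delay(
    rec$audio[, 1], rec$audio[, 2], rec$rate, config$max_lag,
    segments = segs_left,
    snr_linear = db_to_power(singles$snr_db)
  )
  combined_wave <- combine_bilateral(rec$audio[, 1], rec$audio[, 2], align,
                                     config$coherence_threshold)
  rec_comb <- recording(combined_wave, rec$rate, channels = "combined",
                        motion = rec$motion)
  combined <- session_snr(rec_comb, config)
  gain <- array_gain_db(combined, singles)

  out <- dplyr::bind_rows(singles, combined)
  out$array_gain_db <- c(NA_real_, NA_real_, gain)
  out$lag_samples <- c(NA_real_, NA_real_, align$lag)
  out$peak_correlation <- c(NA_real_, NA_real_, align$peak_correlation)
  attr(out, "segments") <- c(attr(singles, "segments"),
                             attr(combined, "segments"))
  attr(out, "alignment") <- align
  class(out) <- c("breathsnr_snr", class(tibble::tibble()))
  out
}
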