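#' Welch power spectral density
#'
#' Averaged-periodogram PSD with a Hann window. The one-sided density is
#' normalized so that integrating it over frequency returns the total signal
#' power (Parseval contract): for a stationary input the trapezoid integral
#' of `density` over `[0, rate/2]` matches the time-domain variance.
#'
#' @param waveform Numeric waveform (demeaned internally).
#' @param rate Sampling rate in Hz.
#' @param segment_length Welch segment length in seconds.
#' @param overlap_fraction Segment overlap in `[0, 1)`.
#' @return Tibble of class `breathsnr_spectrum` with columns `frequency`
#'   (Hz, `0` to `rate/2`) and `density` (power per Hz); attributes `rate`,
#'   `window`, `segment_length`, `overlap_fraction`, `n_segments`.
#' @export
#' @examples
#' x <- sin(2 * pi * 50 * seq(0, 2, by = 1 / 1000))
#' ps <- welch_psd(x, 1000, segment_length = 0.5)
#' band_power(ps, c(40, 60))  # ~ 0.5 = A^2/2
welch_psd <- function(waveform, rate, segment_length = 1,
                      overlap_fraction = 0.5) {
  n <- length(waveform)
  nseg <- round(segment_length * rate)
  if (nseg < 8) abort_config("segment_length must cover at least 8 samples.")
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    abort_config("overlap_fraction must be in [0, 1).")
  }
  x <- waveform - mean(waveform)
  if (n < nseg) {
    warn("signal shorter than one Welch segment; using a single periodogram.")
    nseg <- n
  }
  hop <- max(round(nseg * (1 - overlap_fraction)), 1)
  starts <- seq(1, n - nseg + 1, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nseg - 1) / nseg))  # Hann
  wss <- sum(w^2)

  segs <- vapply(starts, function(s) x[s:(s + nseg - 1)] * w,
                 numeric(nseg))
  spec <- Mod(stats::mvfft(segs))^2 / (rate * wss)
  n_keep <- nseg %/% 2 + 1
  pxx <- rowMeans(spec[seq_len(n_keep), , drop = FALSE])
  # one-sided: double everything except DC (and Nyquist when nseg is even)
  scale2 <- rep(2, n_keep)
  scale2[1] <- 1
  if (nseg %% 2 == 0) scale2[n_keep] <- 1
  pxx <- pxx * scale2

  out <- tibble::tibble(
    frequency = seq(0, n_keep - 1) * rate / nseg,
    density = pxx
  )
  attr(out, "rate") <- rate
  attr(out, "window") <- "hann"
  attr(out, "segment_length") <- nseg / rate
  attr(out, "overlap_fraction") <- overlap_fraction
  attr(out, "n_segments") <- length(starts)
  class(out) <- c("breathsnr_spectrum", class(out))
  out
}

#' Integrate a power spectrum over a band
#'
#' Trapezoid-rule integral of the spectral density over `[band[1], band[2]]`
#' on the spectrum's native frequency grid, with linearly interpolated
#' values at the exact band edges so that disjoint bands add exactly.
#'
#' @param spectrum A [welch_psd()] result (or any tibble with `frequency`
#'   and `density`).
#' @param band Length-2 numeric band in Hz within `[0, rate/2]`.
#' @return Band power in watts (same power units as the input signal
#'   variance).
#' @export
band_power <- function(spectrum, band) {
  f <- spectrum$frequency
  d <- spectrum$density
  if (length(band) != 2 || band[2] <= band[1]) {
    abort_config("`band` must be c(lo, hi) with lo < hi.")
  }
  if (band[1] < 0 || band[2] > max(f) + 1e-9) {
    abort_config("band must lie within [0, rate/2].")
  }
  lo <- max(band[1], min(f)); hi <- min(band[2], max(f))
  inside <- f > lo & f < hi
  fk <- c(lo, f[inside], hi)
  dk <- c(approx(f, d, lo)$y, d[inside], approx(f, d, hi)$y)
  sum(diff(fk) * (head(dk, -1) + tail(dk, -1)) / 2)
}

#' Export a spectrum to CSV
#'
#' Two columns, `frequency` (Hz) and `density` (power per Hz), for plotting
#' parity with external tools.
#'
#' @param spectrum A [welch_psd()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
spectrum_write <- function(spectrum, path) {
  readr::write_csv(tibble::as_tibble(spectrum)[, c("frequency", "density")],
                   path)
  invisible(path)
}

#' @describeIn welch_psd Plot the power spectrum on a dB scale.
#' @param object A `breathsnr_spectrum`.
#' @param ... Unused.
#' @export
autoplot.breathsnr_spectrum <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$density > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency, 10 * log10(.data$density))) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Frequency (Hz)", y = "PSD (dB/Hz)",
                  title = "Breathing power spectrum") +
    ggplot2::theme_minimal()
}
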