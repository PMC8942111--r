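# dB <-> linear power helpers used throughout
db_to_power <- function(db) 10^(db / 10)
power_to_db <- function(p) 10 * log10(p)
db_to_amplitude <- function(db) 10^(db / 20)

abort_config <- function(msg) {
  abort(msg, class = "breathsnr_invalid_configuration")
}

abort_insufficient <- function(msg) {
  abort(msg, class = "breathsnr_insufficient_data")
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain band-pass: the signal is transformed with the FFT
#' (zero-padded to a fast length), components outside `[band[1], band[2]]`
#' are zeroed, and the result transformed back. The filter is exactly
#' zero-phase with ideal band edges, so band-power bookkeeping on filtered
#' components is exact.
#'
#' @param x Numeric waveform.
#' @param rate Sampling rate in Hz.
#' @param band Length-2 numeric, band edges in Hz; upper edge must be below
#'   the Nyquist frequency `rate / 2`.
#' @return Filtered numeric vector, same length as `x`.
#' @export
bandpass <- function(x, rate, band) {
  check_band(band, rate)
  n <- length(x)
  m <- stats::nextn(n)
  xf <- fft(c(x, numeric(m - n)))
  f <- (seq_len(m) - 1) / m * rate
  f <- pmin(f, rate - f)              # fold to physical frequency
  xf[f < band[1] | f > band[2]] <- 0
  Re(fft(xf, inverse = TRUE))[seq_len(n)] / m
}

check_band <- function(band, rate) {
  if (length(band) != 2 || !is.numeric(band) || band[1] < 0 ||
      band[2] <= band[1]) {
    abort_config("`band` must be numeric c(lo, hi) with 0 <= lo < hi.")
  }
  if (band[2] >= rate / 2) {
    abort_config(sprintf(
      "band upper edge (%.1f Hz) must be below the Nyquist frequency (%.1f Hz).",
      band[2], rate / 2
    ))
  }
  invisible(band)
}

# Delay a signal by an integer number of samples, zero-padding at the head and
# truncating the tail so length is preserved.
shift_samples <- function(x, d) {
  n <- length(x)
  if (d == 0) return(x)
  if (d > 0) c(rep(0, d), x[seq_len(n - d)]) else c(x[-seq_len(-d)], rep(0, -d))
}

# Logical mask of length n marking half-open [start, end) sample intervals
# (0-based indices, as stored in segment tables).
intervals_mask <- function(intervals, n) {
  mask <- logical(n)
  if (nrow(intervals) == 0) return(mask)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start_sample[i]
    e <- intervals$end_sample[i]
    if (e > s) mask[(s + 1):min(e, n)] <- TRUE
  }
  mask
}

# Draw per-subject child seeds reproducibly from a parent seed, keeping them
# inside the 32-bit integer range.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
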