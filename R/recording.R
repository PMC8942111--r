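#' Audio recording container
#'
#' Holds one session of chest-wall audio: a samples-by-channels matrix, the
#' sampling rate, a channel-to-side mapping, and an optional synchronized
#' motion trace (one scalar per motion frame).
#'
#' @param audio Numeric vector (mono) or samples-by-channels matrix (1--2
#'   columns).
#' @param rate Sampling rate in Hz.
#' @param channels Character vector naming each column; by convention
#'   `c("left", "right")` for bilateral recordings (channel 0 = left thorax).
#' @param motion Optional tibble with columns `time_s` and `value`, the
#'   motion trace aligned to the audio timeline.
#'
#' @return An object of class `recording`.
#' @export
recording <- function(audio, rate,
                      channels = if (NCOL(audio) == 2) c("left", "right") else "left",
                      motion = NULL) {
  audio <- as.matrix(audio)
  if (ncol(audio) < 1 || ncol(audio) > 2) {
    abort_config("recordings must have 1 or 2 channels.")
  }
  if (length(channels) != ncol(audio)) {
    abort_config("`channels` must name each audio column.")
  }
  if (rate <= 0) abort_config("rate must be positive.")
  if (!is.null(motion)) {
    motion <- tibble::as_tibble(motion)
    if (!all(c("time_s", "value") %in% names(motion))) {
      abort_config("motion trace needs columns `time_s` and `value`.")
    }
  }
  structure(
    list(audio = audio, rate = rate, channels = channels, motion = motion),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d channel(s) [%s], %.1f s @ %d Hz%s\n",
    ncol(x$audio), paste(x$channels, collapse = ", "),
    nrow(x$audio) / x$rate, round(x$rate),
    if (is.null(x$motion)) "" else ", with motion trace"
  ))
  invisible(x)
}

#' Read and write WAV audio
#'
#' Minimal RIFF/WAVE support for the two encodings the pipeline uses:
#' 16-bit integer PCM and 32-bit IEEE float, mono or stereo, with the
#' sampling rate carried in the file header. For bilateral recordings
#' channel 0 is the left thorax and channel 1 the right.
#'
#' @param path File path.
#' @param x A [recording()], numeric vector, or samples-by-channels matrix.
#' @param rate Sampling rate in Hz (ignored when `x` is a `recording`).
#' @param format `"float32"` or `"pcm16"`.
#' @return `wav_read()` returns a [recording()]; `wav_write()` returns `path`
#'   invisibly.
#' @export
wav_write <- function(x, path, rate = NULL, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  if (inherits(x, "recording")) {
    audio <- x$audio
    rate <- x$rate
  } else {
    audio <- as.matrix(x)
    if (is.null(rate)) abort_config("rate is required.")
  }
  n_ch <- ncol(audio)
  bits <- if (format == "float32") 32L else 16L
  fmt_code <- if (format == "float32") 3L else 1L
  block <- n_ch * bits / 8L
  interleaved <- as.numeric(t(audio))
  data_bytes <- length(interleaved) * bits / 8L

  con <- file(path, "wb")
  on.exit(close(con))
  wr_str <- function(s) writeBin(charToRaw(s), con)
  wr_u32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wr_u16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")

  wr_str("RIFF"); wr_u32(36 + data_bytes); wr_str("WAVE")
  wr_str("fmt "); wr_u32(16)
  wr_u16(fmt_code); wr_u16(n_ch); wr_u32(round(rate))
  wr_u32(round(rate) * block); wr_u16(block); wr_u16(bits)
  wr_str("data"); wr_u32(data_bytes)
  if (format == "float32") {
    writeBin(interleaved, con, size = 4, endian = "little")
  } else {
    samples <- as.integer(pmax(pmin(round(interleaved * 32767), 32767L), -32768L))
    writeBin(samples, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' @rdname wav_write
#' @export
wav_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(k) rawToChar(readBin(con, "raw", k))
  rd_u32 <- function() readBin(con, "integer", 1, size = 4, endian = "little")
  rd_u16 <- function() readBin(con, "integer", 1, size = 2, endian = "little",
                               signed = FALSE)
  if (rd_str(4) != "RIFF") abort_config("not a RIFF file.")
  rd_u32()
  if (rd_str(4) != "WAVE") abort_config("not a WAVE file.")

  fmt_code <- NULL; n_ch <- NULL; rate <- NULL; bits <- NULL; audio <- NULL
  repeat {
    id <- readBin(con, "raw", 4)
    if (length(id) < 4) break
    size <- rd_u32()
    chunk <- rawToChar(id)
    if (chunk == "fmt ") {
      fmt_code <- rd_u16(); n_ch <- rd_u16(); rate <- rd_u32()
      rd_u32(); rd_u16(); bits <- rd_u16()
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (chunk == "data") {
      if (is.null(fmt_code)) abort_config("data chunk before fmt chunk.")
      if (fmt_code == 3 && bits == 32) {
        raw_samp <- readBin(con, "numeric", size / 4, size = 4,
                            endian = "little")
      } else if (fmt_code == 1 && bits == 16) {
        raw_samp <- readBin(con, "integer", size / 2, size = 2,
                            endian = "little") / 32767
      } else {
        abort_config("only PCM16 and float32 WAV files are supported.")
      }
      audio <- matrix(raw_samp, ncol = n_ch, byrow = TRUE)
    } else {
      readBin(con, "raw", size + size %% 2)
    }
    if (!is.null(audio)) break
  }
  if (is.null(audio)) abort_config("no data chunk found.")
  recording(audio, rate)
}

#' Read and write motion-trace CSV files
#'
#' A motion trace is one scalar per motion frame, stored as a two-column CSV
#' (`time_s`, `value`) aligned to the audio timeline.
#'
#' @param motion Tibble with columns `time_s` and `value`.
#' @param path File path.
#' @return `motion_read()` returns a tibble; `motion_write()` returns `path`
#'   invisibly.
#' @export
motion_write <- function(motion, path) {
  readr::write_csv(motion[, c("time_s", "value")], path)
  invisible(path)
}

#' @rdname motion_write
#' @export
motion_read <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
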