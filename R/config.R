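#' Analysis configuration
#'
#' Bundles every tunable parameter of the session pipeline. Defaults follow
#' standard auscultation practice: breath-sound energy concentrates in roughly
#' 100--1000 Hz, breath bursts at rest last at least half a second, and the
#' quiet-interval noise floor is estimated robustly so sessions that are mostly
#' breath-active do not inflate it.
#'
#' @param band Analysis band in Hz for all power terms (signal, noise, depth
#'   classification). Default `c(100, 1000)`, the breath-sound band; excludes
#'   DC drift and most heart-sound energy (heart sounds live below ~150 Hz).
#' @param frame,hop Envelope frame length and hop in seconds (100 ms / 25 ms).
#' @param hi_threshold,lo_threshold Hysteresis activity thresholds, as
#'   multiples of the robust noise floor; enter breath-active above
#'   `hi_threshold * floor`, leave below `lo_threshold * floor`.
#' @param min_duration Minimum interval duration in seconds; shorter active
#'   bursts are dropped and shorter quiet gaps merged (250 ms default).
#' @param depth_min_separation_db Minimum two-cluster separation in dB before
#'   intervals are split into normal vs deep breaths; below it all intervals
#'   are labelled normal.
#' @param motion_threshold Motion-gate threshold as a multiple of the motion
#'   trace baseline RMS.
#' @param welch_segment Welch segment length in seconds (Hann window).
#' @param welch_overlap Welch segment overlap fraction in `[0, 1)`.
#' @param max_lag Maximum bilateral alignment lag in seconds; inter-sensor
#'   acoustic path differences across the chest are far below 50 ms.
#' @param coherence_threshold Peak cross-correlation below which bilateral
#'   combination falls back to selecting the better single channel.
#' @param snr_cap_db Cap (+/-) on reported SNR in dB so noise-free and
#'   signal-free limits stay finite.
#' @param include_deep Include deep-breathing intervals in the signal-power
#'   estimate (default `TRUE`; set `FALSE` to restrict to normal breaths).
#'
#' @return A list of class `breathsnr_config`.
#' @export
#' @examples
#' cfg <- analysis_config(band = c(150, 800))
#' cfg$band
analysis_config <- function(band = c(100, 1000),
                            frame = 0.1,
                            hop = 0.025,
                            hi_threshold = 3.0,
                            lo_threshold = 1.5,
                            min_duration = 0.25,
                            depth_min_separation_db = 3,
                            motion_threshold = 5,
                            welch_segment = 1,
                            welch_overlap = 0.5,
                            max_lag = 0.05,
                            coherence_threshold = 0.2,
                            snr_cap_db = 60,
                            include_deep = TRUE) {
  if (hi_threshold <= lo_threshold || lo_threshold <= 1) {
    abort_config("need hi_threshold > lo_threshold > 1.")
  }
  if (frame <= 0 || hop <= 0 || hop > frame) {
    abort_config("need 0 < hop <= frame.")
  }
  if (welch_overlap < 0 || welch_overlap >= 1) {
    abort_config("welch_overlap must be in [0, 1).")
  }
  structure(
    list(
      band = band, frame = frame, hop = hop,
      hi_threshold = hi_threshold, lo_threshold = lo_threshold,
      min_duration = min_duration,
      depth_min_separation_db = depth_min_separation_db,
      motion_threshold = motion_threshold,
      welch_segment = welch_segment, welch_overlap = welch_overlap,
      max_lag = max_lag, coherence_threshold = coherence_threshold,
      snr_cap_db = snr_cap_db, include_deep = include_deep
    ),
    class = "breathsnr_config"
  )
}
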