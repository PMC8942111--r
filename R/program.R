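#' Breathing exercise program
#'
#' Describes the breathing sequence a (simulated) subject performs: breath
#' rate, how much of each breath cycle carries airflow, and an ordered series
#' of normal/deep phase blocks. The default emulates a ~4 minute session of
#' normal-to-deep breathing transitions.
#'
#' @param breath_rate Breaths per minute.
#' @param inspiration_fraction Fraction of the breath-active window occupied
#'   by inspiration, strictly in (0, 1); the remainder is expiration.
#' @param depth_sequence Data frame with columns `depth` (`"normal"` or
#'   `"deep"`) and `duration` (seconds), in order.
#' @param depth_gain_db Amplitude boost of deep over normal breaths, in dB.
#' @param active_fraction Fraction of each breath cycle with audible airflow
#'   (one contiguous inspiration+expiration burst per cycle).
#'
#' @return A list of class `breath_program`.
#' @export
#' @examples
#' p <- breath_program(depth_sequence = data.frame(depth = "normal", duration = 10))
#' program_duration(p)
breath_program <- function(breath_rate = 12,
                           inspiration_fraction = 0.45,
                           depth_sequence = data.frame(
                             depth = c("normal", "deep", "normal", "deep"),
                             duration = c(60, 60, 60, 60)
                           ),
                           depth_gain_db = 6,
                           active_fraction = 0.4) {
  depth_sequence <- tibble::as_tibble(depth_sequence)
  if (!all(c("depth", "duration") %in% names(depth_sequence))) {
    abort_config("depth_sequence needs columns `depth` and `duration`.")
  }
  if (nrow(depth_sequence) == 0 || any(depth_sequence$duration <= 0)) {
    abort_config("every depth block must have a positive duration.")
  }
  if (!all(depth_sequence$depth %in% c("normal", "deep"))) {
    abort_config("depth must be 'normal' or 'deep'.")
  }
  if (inspiration_fraction <= 0 || inspiration_fraction >= 1) {
    abort_config("inspiration_fraction must be strictly between 0 and 1.")
  }
  if (breath_rate <= 0) abort_config("breath_rate must be positive.")
  if (active_fraction <= 0 || active_fraction >= 1) {
    abort_config("active_fraction must be strictly between 0 and 1.")
  }
  structure(
    list(
      breath_rate = breath_rate,
      inspiration_fraction = inspiration_fraction,
      depth_sequence = depth_sequence,
      depth_gain_db = depth_gain_db,
      active_fraction = active_fraction
    ),
    class = "breath_program"
  )
}

#' @rdname breath_program
#' @param program A `breath_program`.
#' @export
program_duration <- function(program) {
  sum(program$depth_sequence$duration)
}
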