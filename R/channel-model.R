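#' Bilateral acoustic channel model
#'
#' The received signal at each thorax sensor is modelled as the source lung
#' sound convolved with a sparse multipath impulse response (a sum of
#' attenuated, delayed copies), attenuated broadband by any fabric between
#' sensor and skin, plus ambient background noise everywhere and
#' obstruction-turbulence noise while air is flowing:
#'
#' \deqn{s(t) = \sum_j A_j \, x(t - \tau_j) \cdot 10^{-F/20} + n_{amb}(t) + n_{turb}(t)}
#'
#' Turbulence noise is band-limited to the breath band because it is generated
#' by airflow through obstructed airways, so it is spectrally confounded with
#' the breath signal itself.
#'
#' @param taps_left,taps_right Data frames with columns `attenuation`
#'   (unitless, > 0) and `delay` (seconds, >= 0); one row per filter tap.
#' @param fabric_attenuation_db Broadband loss in dB applied to the convolved
#'   signal (models garment material between sensor and skin).
#' @param ambient_noise_power Variance (watts) of the white ambient noise,
#'   always present.
#' @param turbulence_noise_power Variance (watts) of the band-limited
#'   turbulence noise, present only during breath-active intervals.
#' @param turbulence_band Band (Hz) occupied by turbulence noise.
#'
#' @return A list of class `channel_model`.
#' @export
#' @examples
#' m <- channel_model(taps_left = data.frame(attenuation = 1, delay = 0))
channel_model <- function(taps_left = data.frame(attenuation = 1, delay = 0),
                          taps_right = taps_left,
                          fabric_attenuation_db = 0,
                          ambient_noise_power = 2e-3,
                          turbulence_noise_power = 0,
                          turbulence_band = c(100, 1000)) {
  check_taps <- function(taps, side) {
    taps <- tibble::as_tibble(taps)
    if (nrow(taps) < 1) {
      abort_config(sprintf("%s filter needs at least one tap.", side))
    }
    if (!all(c("attenuation", "delay") %in% names(taps))) {
      abort_config("taps need columns `attenuation` and `delay`.")
    }
    if (any(taps$attenuation <= 0) || any(taps$delay < 0)) {
      abort_config("attenuation factors must be > 0 and delays >= 0.")
    }
    taps
  }
  if (ambient_noise_power < 0 || turbulence_noise_power < 0) {
    abort_config("noise powers must be >= 0.")
  }
  structure(
    list(
      taps_left = check_taps(taps_left, "left"),
      taps_right = check_taps(taps_right, "right"),
      fabric_attenuation_db = fabric_attenuation_db,
      ambient_noise_power = ambient_noise_power,
      turbulence_noise_power = turbulence_noise_power,
      turbulence_band = turbulence_band
    ),
    class = "channel_model"
  )
}
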