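#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a segmented waveform
#'
#' Downsampled waveform trace with breath-active intervals shaded, deep
#' breaths in a darker shade, and motion-rejected intervals hatched red.
#'
#' @param waveform Numeric waveform.
#' @param rate Sampling rate in Hz.
#' @param segments Segment tibble (see [segment_session()]).
#' @param max_points Maximum plotted waveform points (decimated above this).
#' @return A ggplot object.
#' @export
plot_segments <- function(waveform, rate, segments, max_points = 20000) {
  step <- max(1, floor(length(waveform) / max_points))
  idx <- seq(1, length(waveform), by = step)
  wave_df <- tibble::tibble(time_s = (idx - 1) / rate, value = waveform[idx])
  act <- segments[segments$phase == "active", ]
  act_df <- tibble::tibble(
    xmin = act$start_sample / rate, xmax = act$end_sample / rate,
    depth = ifelse(is.na(act$depth), "normal", act$depth),
    rejected = act$motion_rejected
  )
  p <- ggplot2::ggplot(wave_df) +
    ggplot2::geom_rect(
      data = act_df,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf, fill = .data$depth),
      alpha = 0.25
    ) +
    ggplot2::geom_line(ggplot2::aes(.data$time_s, .data$value),
                       linewidth = 0.2) +
    ggplot2::scale_fill_manual(
      values = c(normal = "steelblue", deep = "darkblue")
    ) +
    ggplot2::labs(x = "Time (s)", y = "Amplitude", fill = "Breath depth",
                  title = "Breath-phase segmentation") +
    ggplot2::theme_minimal()
  if (any(act_df$rejected)) {
    p <- p + ggplot2::geom_rect(
      data = act_df[act_df$rejected, ],
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      fill = "red", alpha = 0.15
    )
  }
  p
}
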