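#' Short-time RMS energy envelope
#'
#' @param waveform Numeric waveform.
#' @param rate Sampling rate in Hz.
#' @param frame Frame length in seconds.
#' @param hop Hop between frames in seconds (`0 < hop <= frame`).
#' @return Tibble with one row per frame: `frame` (1-based index),
#'   `center_sample` (0-based sample of the frame center) and `rms`; sampling
#'   parameters are carried as attributes `rate`, `frame`, `hop`.
#' @export
energy_envelope <- function(waveform, rate, frame = 0.1, hop = 0.025) {
  n <- length(waveform)
  if (n == 0) abort_config("empty waveform.")
  if (hop <= 0 || hop > frame) abort_config("need 0 < hop <= frame.")
  if (frame * rate > n) abort_config("frame longer than the waveform.")
  fl <- max(round(frame * rate), 1)
  hl <- max(round(hop * rate), 1)
  starts <- seq(0, n - fl, by = hl)             # 0-based frame starts
  cs <- c(0, cumsum(waveform^2))
  rms <- sqrt((cs[starts + fl + 1] - cs[starts + 1]) / fl)
  out <- tibble::tibble(
    frame = seq_along(starts),
    center_sample = starts + fl %/% 2,
    rms = rms
  )
  attr(out, "rate") <- rate
  attr(out, "frame") <- frame
  attr(out, "hop") <- hop
  attr(out, "n_samples") <- n
  out
}

# Robust noise floor: median of the lowest quartile of envelope frames, so
# sessions that are mostly breath-active do not inflate the floor.
noise_floor <- function(rms) {
  q <- quantile(rms, 0.25, names = FALSE)
  floor_val <- median(rms[rms <= q])
  max(floor_val, .Machine$double.eps)
}

#' Detect breath-active intervals by hysteresis thresholding
#'
#' Enters the breath-active state when the envelope exceeds
#' `hi_threshold * floor` and leaves it when the envelope drops below
#' `lo_threshold * floor`, where the floor is the robust quiet baseline
#' ([noise floor][energy_envelope]: median of the lowest envelope quartile).
#' Active runs shorter than `min_duration` are dropped and quiet gaps shorter
#' than `min_duration` are merged, then frame indices are converted back to
#' half-open 0-based sample intervals tiling the whole recording.
#'
#' @param envelope Output of [energy_envelope()].
#' @param hi_threshold,lo_threshold Entry/exit thresholds as multiples of the
#'   noise floor; require `hi_threshold > lo_threshold > 1`.
#' @param min_duration Minimum interval duration in seconds.
#' @param floor Noise floor override (envelope RMS units); `NULL` estimates
#'   it robustly from the envelope itself.
#' @return Segment tibble: `start_sample`, `end_sample`, `phase`
#'   (`"active"`/`"quiet"`), `depth` (`NA` until classified),
#'   `motion_rejected` (`FALSE` until gated). A flat-zero envelope yields a
#'   single quiet interval.
#' @export
detect_activity <- function(envelope, hi_threshold = 3.0, lo_threshold = 1.5,
                            min_duration = 0.25, floor = NULL) {
  if (hi_threshold <= lo_threshold || lo_threshold <= 1) {
    abort_config("need hi_threshold > lo_threshold > 1.")
  }
  rms <- envelope$rms
  n_samples <- attr(envelope, "n_samples")
  rate <- attr(envelope, "rate")
  hop_len <- max(round(attr(envelope, "hop") * rate), 1)
  nf <- length(rms)

  if (all(rms == 0)) {
    return(new_segments(0L, n_samples, "quiet", n_samples))
  }
  floor_val <- floor %||% noise_floor(rms)
  active <- logical(nf)
  state <- FALSE
  for (i in seq_len(nf)) {
    state <- if (state) rms[i] >= lo_threshold * floor_val
             else rms[i] > hi_threshold * floor_val
    active[i] <- state
  }

  min_frames <- max(ceiling(min_duration * rate / hop_len), 1)
  active <- prune_runs(active, TRUE, min_frames)   # drop short active bursts
  active <- prune_runs(active, FALSE, min_frames)  # merge short quiet gaps

  r <- rle(active)
  ends_f <- cumsum(r$lengths)
  starts_f <- ends_f - r$lengths + 1
  # frame i covers samples [(i-1)*hop, i*hop); first/last runs absorb edges
  start_samp <- (starts_f - 1) * hop_len
  end_samp <- ends_f * hop_len
  start_samp[1] <- 0L
  end_samp[length(end_samp)] <- n_samples
  end_samp <- pmin(end_samp, n_samples)
  new_segments(start_samp, end_samp,
               ifelse(r$values, "active", "quiet"), n_samples)
}

# Flip runs of `value` shorter than min_len (interior runs only for the
# FALSE/gap case would be ideal, but edge runs are harmless to keep).
prune_runs <- function(x, value, min_len) {
  r <- rle(x)
  short <- r$values == value & r$lengths < min_len
  if (value == FALSE) {
    # only merge gaps that sit between active runs
    interior <- seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
    short <- short & interior
  }
  r$values[short] <- !value
  inverse.rle(r)
}

new_segments <- function(start, end, phase, n_samples) {
  segs <- tibble::tibble(
    start_sample = as.integer(start),
    end_sample = as.integer(end),
    phase = phase,
    depth = NA_character_,
    motion_rejected = FALSE
  )
  segs <- segs[segs$end_sample > segs$start_sample, ]
  attr(segs, "n_samples") <- n_samples
  class(segs) <- c("breathsnr_segments", class(segs))
  segs
}

#' Classify breath depth (normal vs deep)
#'
#' Computes the analysis-band power of every breath-active interval and
#' splits the intervals into two groups by exact 1-D two-means on the dB
#' powers (exhaustive split search on the sorted values, no random
#' initialization; ties broken toward the split minimizing within-cluster
#' variance). The higher-power cluster is labelled `"deep"` -- depth is
#' within-session relative, since absolute calibration across sensors and
#' fabrics is unavailable. If the two cluster means are separated by less
#' than `min_separation_db`, all intervals are labelled `"normal"`. A single
#' active interval is labelled `NA` (undefined).
#'
#' @param waveform Numeric waveform (band-filter beforehand, or pass `band`).
#' @param rate Sampling rate in Hz.
#' @param segments Segment tibble from [detect_activity()].
#' @param band Optional band (Hz); when given the waveform is band-passed
#'   before computing interval powers.
#' @param min_separation_db Minimum cluster separation to accept a
#'   normal/deep split.
#' @return `segments` with the `depth` column filled for active intervals.
#' @export
classify_depth <- function(waveform, rate, segments, band = NULL,
                           min_separation_db = 3) {
  act <- which(segments$phase == "active")
  if (length(act) == 0) return(segments)
  if (!is.null(band)) waveform <- bandpass(waveform, rate, band)
  p_db <- vapply(act, function(i) {
    s <- segments$start_sample[i]; e <- segments$end_sample[i]
    power_to_db(mean(waveform[(s + 1):e]^2))
  }, numeric(1))

  if (length(act) == 1) {
    segments$depth[act] <- NA_character_
    return(segments)
  }
  split <- two_means_1d(p_db)
  labels <- if (split$separation < min_separation_db) {
    rep("normal", length(act))
  } else {
    ifelse(p_db > split$boundary, "deep", "normal")
  }
  segments$depth[act] <- labels
  segments
}

# Exact 1-D two-means: try every split of the sorted values, keep the one
# with minimal within-cluster sum of squares.
two_means_1d <- function(x) {
  s <- sort(x)
  n <- length(s)
  best <- list(sse = Inf)
  for (k in seq_len(n - 1)) {
    lo <- s[1:k]; hi <- s[(k + 1):n]
    sse <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (sse < best$sse) {
      best <- list(
        sse = sse,
        boundary = (s[k] + s[k + 1]) / 2,
        separation = mean(hi) - mean(lo)
      )
    }
  }
  best
}

#' Flag motion-contaminated intervals
#'
#' Any interval overlapping a motion-trace sample whose absolute value
#' exceeds `threshold` times the trace baseline RMS is flagged
#' `motion_rejected`. Flagging never deletes samples: the segment partition
#' is unchanged, and flagged intervals are simply excluded from downstream
#' power estimates. Applying the gate twice equals applying it once.
#'
#' @param segments Segment tibble.
#' @param motion Motion-trace tibble (`time_s`, `value`) or `NULL`; `NULL`
#'   is a no-op with a warning.
#' @param rate Audio sampling rate in Hz (to map samples to time).
#' @param threshold Multiple of the baseline RMS above which a motion sample
#'   marks its interval as contaminated.
#' @return `segments` with `motion_rejected` updated.
#' @export
motion_gate <- function(segments, motion, rate, threshold = 5) {
  if (is.null(motion)) {
    warn("no motion trace supplied; motion gating skipped.")
    return(segments)
  }
  baseline <- sqrt(mean(motion$value^2))
  hot_times <- motion$time_s[abs(motion$value) > threshold * baseline]
  segments$motion_rejected <- purrr::map_lgl(seq_len(nrow(segments)), function(i) {
    lo <- segments$start_sample[i] / rate
    hi <- segments$end_sample[i] / rate
    any(hot_times >= lo & hot_times < hi)
  })
  segments
}

#' Fraction of truth active intervals recovered by an estimate
#'
#' Matches each ground-truth breath-active interval to the estimated active
#' interval with the largest Jaccard overlap (intersection over union of the
#' sample sets) and reports the fraction of truth intervals whose best match
#' reaches `min_jaccard`.
#'
#' @param truth,estimate Segment tibbles.
#' @param min_jaccard Minimum Jaccard overlap to count as recovered.
#' @return A scalar recovery fraction in `[0, 1]`.
#' @export
segment_recovery <- function(truth, estimate, min_jaccard = 0.8) {
  ta <- truth[truth$phase == "active", ]
  ea <- estimate[estimate$phase == "active", ]
  if (nrow(ta) == 0) return(NA_real_)
  if (nrow(ea) == 0) return(0)
  hit <- vapply(seq_len(nrow(ta)), function(i) {
    s <- ta$start_sample[i]; e <- ta$end_sample[i]
    inter <- pmax(pmin(e, ea$end_sample) - pmax(s, ea$start_sample), 0)
    uni <- (e - s) + (ea$end_sample - ea$start_sample) - inter
    any(inter / uni >= min_jaccard)
  }, logical(1))
  mean(hit)
}

#' Full segmentation for one channel
#'
#' Band-passes the waveform to the analysis band, computes the energy
#' envelope, detects breath activity by hysteresis, classifies breath depth,
#' and applies the motion gate. The returned partition always tiles
#' `[0, n_samples)` exactly.
#'
#' @param waveform Numeric waveform.
#' @param rate Sampling rate in Hz.
#' @param config An [analysis_config()].
#' @param motion Optional motion-trace tibble.
#' @return Segment tibble, see [detect_activity()].
#' @export
segment_session <- function(waveform, rate, config = analysis_config(),
                            motion = NULL) {
  filtered <- bandpass(waveform, rate, config$band)
  env <- energy_envelope(filtered, rate, config$frame, config$hop)
  segs <- detect_activity(env, config$hi_threshold, config$lo_threshold,
                          config$min_duration)
  segs <- classify_depth(filtered, rate, segs,
                         min_separation_db = config$depth_min_separation_db)
  if (!is.null(motion)) {
    segs <- motion_gate(segs, motion, rate, config$motion_threshold)
  }
  segs
}
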