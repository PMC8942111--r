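# Tukey (tapered-cosine) window on a 0..1 grid; r = total taper fraction.
tukey_window <- function(n, r = 0.5) {
  if (n == 1) return(1)
  u <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- u < r / 2
  hi <- u > 1 - r / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * u[lo] / r - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (u[hi] - 1 + r / 2) / r)))
  w
}

# Build the amplitude envelope and ground-truth intervals for a breath
# program: one contiguous inspiration+expiration burst per breath cycle,
# Tukey-shaped lobes, expiration slightly quieter than inspiration.
breath_envelope <- function(program, rate, expiration_level = 0.8) {
  total <- program_duration(program)
  n <- round(total * rate)
  env <- numeric(n)
  cycle <- 60 / program$breath_rate
  active_dur <- program$active_fraction * cycle
  gain <- db_to_amplitude(program$depth_gain_db)

  starts <- integer(0); ends <- integer(0); depths <- character(0)
  block_start <- 0
  for (b in seq_len(nrow(program$depth_sequence))) {
    depth <- program$depth_sequence$depth[b]
    block_end <- block_start + program$depth_sequence$duration[b]
    amp <- if (depth == "deep") gain else 1
    cs <- block_start
    while (cs < block_end - 1e-9) {
      ce <- min(cs + active_dur, block_end)
      if (ce - cs > 0.1 * cycle) {   # skip degenerate slivers at block edges
        s <- round(cs * rate); e <- min(round(ce * rate), n)
        if (e > s) {
          w <- e - s
          ni <- max(round(w * program$inspiration_fraction), 1)
          # drop the exact-zero window endpoints so the envelope is strictly
          # positive throughout the burst (inspiration flows into expiration)
          tw <- function(k) tukey_window(k + 2, 0.5)[2:(k + 1)]
          lobe <- c(tw(ni), expiration_level * tw(w - ni))
          env[(s + 1):e] <- amp * lobe
          starts <- c(starts, s); ends <- c(ends, e)
          depths <- c(depths, depth)
        }
      }
      cs <- cs + cycle
    }
    block_start <- block_end
  }

  # tile [0, n) with the quiet gaps between active bursts
  intervals <- tibble::tibble(
    start_sample = starts, end_sample = ends,
    phase = "active", depth = depths
  )
  bounds <- c(0L, as.vector(rbind(starts, ends)), n)
  quiet <- tibble::tibble(
    start_sample = bounds[seq(1, length(bounds) - 1, by = 2)],
    end_sample = bounds[seq(2, length(bounds), by = 2)],
    phase = "quiet", depth = NA_character_
  )
  quiet <- quiet[quiet$end_sample > quiet$start_sample, ]
  segs <- dplyr::arrange(dplyr::bind_rows(intervals, quiet), .data$start_sample)
  list(envelope = env, segments = segs)
}

#' Simulate a single-lung breath-sound source
#'
#' Produces the raw thorax acoustic source waveform for one lung: band-limited
#' Gaussian noise amplitude-modulated by a smooth breath envelope. The
#' waveform is audible (nonzero) during each inspiration/expiration burst and
#' silent between breaths; deep-breathing blocks are boosted by the program's
#' `depth_gain_db`. Ground-truth phase intervals (half-open, 0-based sample
#' indices) tile the whole recording.
#'
#' @param program A [breath_program()].
#' @param band Breath-sound band in Hz; upper edge must be below `rate / 2`.
#' @param rate Sampling rate in Hz.
#' @param amplitude Peak envelope amplitude of a normal inspiration.
#' @param seed Optional integer seed for a reproducible waveform.
#'
#' @return A list of class `breath_source` with elements `waveform` (numeric),
#'   `envelope` (numeric amplitude envelope), `segments` (tibble of truth
#'   intervals with `start_sample`, `end_sample`, `phase`, `depth`), `rate`.
#' @export
#' @examples
#' p <- breath_program(depth_sequence = data.frame(depth = "normal", duration = 10),
#'                     breath_rate = 15)
#' src <- simulate_breath_source(p, rate = 2500, seed = 1)
#' sum(src$segments$phase == "active")
simulate_breath_source <- function(program, band = c(100, 1000), rate = 4000,
                                   amplitude = 1, seed = NULL) {
  if (rate <= 0) abort_config("rate must be positive.")
  check_band(band, rate)
  be <- breath_envelope(program, rate)
  n <- length(be$envelope)
  carrier <- with_seed_if(seed, rnorm(n))
  carrier <- bandpass(carrier, rate, band)
  carrier <- carrier / sd(carrier)
  structure(
    list(
      waveform = amplitude * be$envelope * carrier,
      envelope = amplitude * be$envelope,
      segments = be$segments,
      rate = rate,
      band = band
    ),
    class = "breath_source"
  )
}
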