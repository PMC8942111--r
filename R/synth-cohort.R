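#' Simulate a study cohort
#'
#' Builds the metadata and per-subject generator parameters for a cohort of
#' healthy and COPD subjects. Healthy subjects' health scales are skewed high
#' (they were recruited at running events); COPD subjects' scales center near
#' 5.5/10. Audio is *not* materialized here -- each subject's session is
#' generated on demand by [cohort_subject()] so arbitrarily large cohorts fit
#' in memory -- but everything is fully reproducible from `seed`.
#'
#' @param n_healthy,n_copd Subject counts (total >= 2).
#' @param seed Integer master seed; per-subject seeds derive from it.
#' @param scale_map,clean_power_map Severity maps, see [default_scale_map()].
#' @param program Breathing [breath_program()] every subject performs.
#' @param rate,band Sampling rate and breath band (Hz).
#' @param ... Further arguments stored and passed to [simulate_subject()]
#'   (e.g. `shared_source`, `heart_amplitude`, `n_motion_bursts`).
#'
#' @return A list of class `breathsnr_cohort` with a `metadata` tibble
#'   (`subject_id`, `age`, `gender`, `group`, `health_scale`, `seed`) and the
#'   stored generator settings.
#' @export
#' @examples
#' coh <- simulate_cohort(n_healthy = 4, n_copd = 1, seed = 7,
#'   program = breath_program(depth_sequence = data.frame(depth = "normal", duration = 10)))
#' coh$metadata
simulate_cohort <- function(n_healthy = 35, n_copd = 3, seed = 1,
                            scale_map = default_scale_map,
                            clean_power_map = default_clean_power_map,
                            program = breath_program(),
                            rate = 4000, band = c(100, 1000), ...) {
  n <- n_healthy + n_copd
  if (n < 2) abort_config("need at least 2 subjects.")
  meta <- withr::with_seed(seed, {
    healthy_scales <- sample(1:10, n_healthy, replace = TRUE,
                             prob = c(0, 0, 0.01, 0.03, 0.06, 0.10,
                                      0.18, 0.24, 0.24, 0.14))
    copd_scales <- sample(4:7, n_copd, replace = TRUE,
                          prob = c(0.2, 0.3, 0.3, 0.2))
    tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      age = c(sample(18:70, n_healthy, replace = TRUE),
              sample(55:80, n_copd, replace = TRUE)),
      gender = sample(c("male", "female"), n, replace = TRUE,
                      prob = c(0.7, 0.3)),
      group = rep(c("healthy", "copd"), c(n_healthy, n_copd)),
      health_scale = c(healthy_scales, copd_scales),
      seed = derive_seeds(seed + 1L, n)
    )
  })
  structure(
    list(
      metadata = meta,
      scale_map = scale_map,
      clean_power_map = clean_power_map,
      program = program,
      rate = rate,
      band = band,
      sim_args = list(...)
    ),
    class = "breathsnr_cohort"
  )
}

#' Materialize one cohort subject's session
#'
#' @param cohort A [simulate_cohort()] result.
#' @param i Row index or `subject_id` in `cohort$metadata`.
#' @param ... Overrides forwarded to [simulate_subject()].
#' @return A `sim_output`, see [simulate_subject()].
#' @export
cohort_subject <- function(cohort, i, ...) {
  meta <- cohort$metadata
  if (is.character(i)) i <- match(i, meta$subject_id)
  row <- meta[i, ]
  subj <- sim_subject(row$subject_id, row$health_scale, row$group,
                      seed = row$seed, scale_map = cohort$scale_map,
                      clean_power_map = cohort$clean_power_map)
  args <- utils::modifyList(
    c(list(subject = subj, program = cohort$program, rate = cohort$rate,
           band = cohort$band), cohort$sim_args),
    list(...)
  )
  do.call(simulate_subject, args)
}

#' Write a cohort to disk
#'
#' Emits `<subject_id>.wav` (2-channel float32, channel 0 = left thorax),
#' `<subject_id>.motion.csv`, `<subject_id>.segments.csv` (truth labels:
#' `subject_id`, `channel`, `start_sample`, `end_sample`, `phase`, `depth`)
#' per subject, plus one `metadata.csv`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
cohort_write <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_len(nrow(cohort$metadata))) {
    sim <- cohort_subject(cohort, i)
    id <- sim$subject$subject_id
    wav_write(sim$recording, file.path(dir, paste0(id, ".wav")))
    motion_write(sim$recording$motion, file.path(dir, paste0(id, ".motion.csv")))
    labels <- tidyr::crossing(channel = c("left", "right"),
                              sim$truth_segments) |>
      dplyr::mutate(subject_id = id, .before = 1) |>
      dplyr::arrange(.data$channel, .data$start_sample)
    readr::write_csv(labels, file.path(dir, paste0(id, ".segments.csv")))
  }
  readr::write_csv(cohort$metadata, file.path(dir, "metadata.csv"))
  invisible(dir)
}

#' Run the session pipeline over a whole cohort
#'
#' Materializes each subject in turn, runs [session_snr()] on the session,
#' and discards the audio, returning the stacked per-channel results joined
#' to the cohort metadata. Set `truth = TRUE` to also carry the generator's
#' ground-truth SNR for estimator-validation work.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param config An [analysis_config()].
#' @param truth Attach ground-truth columns (`truth_snr_db`).
#' @param ... Overrides forwarded to [cohort_subject()].
#' @return Tibble with one row per subject x channel: metadata columns plus
#'   the [session_snr()] outputs (and truth when requested).
#' @export
analyze_cohort <- function(cohort, config = analysis_config(),
                           truth = FALSE, ...) {
  purrr::map_dfr(seq_len(nrow(cohort$metadata)), function(i) {
    sim <- cohort_subject(cohort, i, ...)
    res <- session_snr(sim$recording, config)
    res <- dplyr::mutate(res,
      subject_id = sim$subject$subject_id,
      group = sim$subject$group,
      health_scale = sim$subject$health_scale,
      .before = 1
    )
    if (truth) {
      res <- dplyr::left_join(
        res,
        dplyr::select(sim$truth, channel, truth_snr_db = "snr_db"),
        by = "channel"
      )
    }
    res
  })
}
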