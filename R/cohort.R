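#' Aggregate per-channel SNR results to one value per subject
#'
#' Arithmetic mean in dB across a subject's channels and sessions (dB
#' averaging is the convention for normalized-SNR comparisons). Results
#' flagged `low_confidence` are excluded when `filter_low_confidence` is on,
#' unless every result for a subject is flagged (then all are used).
#'
#' @param results Tibble with columns `subject_id`, `snr_db` and optionally
#'   `low_confidence` (e.g. stacked [session_snr()] rows).
#' @param filter_low_confidence Drop low-confidence rows before averaging.
#' @return Tibble with one row per subject: `subject_id`, `mean_snr_db`,
#'   `n_results`; any metadata columns constant within subject
#'   (`group`, `health_scale`) are carried through.
#' @export
aggregate_subjects <- function(results, filter_low_confidence = TRUE) {
  if (nrow(results) == 0) abort_insufficient("no SNR results to aggregate.")
  if (!"low_confidence" %in% names(results)) results$low_confidence <- FALSE
  carry <- intersect(c("group", "health_scale"), names(results))
  results |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(df, key) {
      keep <- if (filter_low_confidence && any(!df$low_confidence)) {
        df[!df$low_confidence, ]
      } else {
        df
      }
      out <- tibble::tibble(
        mean_snr_db = mean(keep$snr_db),
        n_results = nrow(keep)
      )
      for (cc in carry) out[[cc]] <- df[[cc]][1]
      out
    }) |>
    dplyr::ungroup()
}

#' Normalize group-mean SNR across health scales
#'
#' Averages `mean_snr_db` within each occupied health-scale value and
#' min-max normalizes the group means to `[0, 1]` (the maximum-mean scale
#' maps to 1, the minimum to 0). Unoccupied scales are omitted, never
#' interpolated. Normalization removes offset and scale, so it is invariant
#' to any affine transform of the dB values.
#'
#' @param table Tibble with columns `health_scale` and `mean_snr_db` (one
#'   row per subject, e.g. from [aggregate_subjects()]).
#' @param degenerate Policy when all group means are equal: `"error"`
#'   (default) or `"midpoint"` (all 0.5).
#' @return Tibble with one row per occupied scale: `health_scale`, `n`,
#'   `group_mean_snr_db`, `normalized_snr`.
#' @export
group_normalize <- function(table, degenerate = c("error", "midpoint")) {
  degenerate <- match.arg(degenerate)
  if (length(unique(table$health_scale)) < 2) {
    abort_insufficient("need at least 2 distinct health scales to normalize.")
  }
  g <- table |>
    dplyr::group_by(.data$health_scale) |>
    dplyr::summarise(
      n = dplyr::n(),
      group_mean_snr_db = mean(.data$mean_snr_db),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$health_scale)
  rng <- range(g$group_mean_snr_db)
  if (diff(rng) == 0) {
    if (degenerate == "error") {
      abort_insufficient("all group means are equal; normalization undefined.")
    }
    g$normalized_snr <- 0.5
  } else {
    g$normalized_snr <- (g$group_mean_snr_db - rng[1]) / diff(rng)
  }
  g
}

#' Spearman correlation of SNR with health scale, permutation-tested
#'
#' Spearman rank correlation between per-subject health scale and mean SNR
#' (average ranks for ties), with a one-sided permutation p-value for
#' positive association: health scales are shuffled `n_permutations` times
#' under a fixed seed and `p = (1 + #{rho_perm >= rho_obs}) / (n_permutations
#' + 1)`, so p always lies in `[1/(n+1), 1]` and is reproducible.
#'
#' @param table Tibble with columns `health_scale` and `mean_snr_db`.
#' @param n_permutations Number of shuffles.
#' @param seed Integer seed for the shuffles.
#' @return A list: `rho`, `p_value`, `n`, `n_permutations`,
#'   `method = "spearman"`.
#' @export
correlation_test <- function(table, n_permutations = 999, seed = 1) {
  n <- nrow(table)
  if (n < 5) abort_insufficient("need at least 5 subjects.")
  if (length(unique(table$health_scale)) < 2) {
    abort_insufficient("need at least 2 distinct health scales.")
  }
  if (sd(table$mean_snr_db) == 0) {
    abort(
      "SNR values are constant; the rank correlation is undefined.",
      class = "breathsnr_undefined_correlation"
    )
  }
  r_scale <- rank(table$health_scale)
  r_snr <- rank(table$mean_snr_db)
  rho <- cor(r_scale, r_snr)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations),
           function(i) cor(sample(r_scale), r_snr), numeric(1))
  })
  list(
    rho = rho,
    p_value = (1 + sum(perm >= rho)) / (n_permutations + 1),
    n = n,
    n_permutations = n_permutations,
    method = "spearman"
  )
}

#' Cohort-level SNR vs health-scale analysis
#'
#' The full cohort stage: aggregate per-channel results to one mean SNR per
#' subject, average and min-max normalize within health-scale groups, and
#' test the positive SNR--health-scale association with a permutation
#' Spearman test. COPD subjects enter the pooled correlation; the `group`
#' column keeps the distinction for reporting.
#'
#' @param results Stacked per-channel results (see [analyze_cohort()] or
#'   [session_snr()]) with `subject_id`, `snr_db` and, if not supplied via
#'   `metadata`, `health_scale` and `group`.
#' @param metadata Optional metadata tibble (`subject_id`, `health_scale`,
#'   `group`, ...) joined onto the results.
#' @param n_permutations,seed Permutation-test settings.
#' @param filter_low_confidence See [aggregate_subjects()].
#' @return An object of class `breathsnr_cohort_fit`: list with `table`
#'   (per-subject), `by_scale` (normalized group means), `rho`, `p_value`,
#'   `n`, `n_permutations`.
#' @export
cohort_analysis <- function(results, metadata = NULL, n_permutations = 999,
                            seed = 1, filter_low_confidence = TRUE) {
  if (!is.null(metadata)) {
    results <- dplyr::left_join(
      dplyr::select(results, -dplyr::any_of(c("health_scale", "group"))),
      dplyr::select(metadata, dplyr::any_of(
        c("subject_id", "health_scale", "group")
      )),
      by = "subject_id"
    )
  }
  table <- aggregate_subjects(results, filter_low_confidence)
  ct <- correlation_test(table, n_permutations, seed)
  structure(
    list(
      table = table,
      by_scale = group_normalize(table),
      rho = ct$rho,
      p_value = ct$p_value,
      n = ct$n,
      n_permutations = ct$n_permutations
    ),
    class = "breathsnr_cohort_fit"
  )
}

#' @export
print.breathsnr_cohort_fit <- function(x, ...) {
  cat(sprintf(
    "<cohort fit> n = %d subjects, Spearman rho = %.3f, one-sided p = %.4g (%d permutations)\n",
    x$n, x$rho, x$p_value, x$n_permutations
  ))
  print(x$by_scale)
  invisible(x)
}

#' @describeIn cohort_analysis Per-scale normalized group means as a tibble.
#' @param x A `breathsnr_cohort_fit`.
#' @param ... Unused.
#' @export
tidy.breathsnr_cohort_fit <- function(x, ...) x$by_scale

#' @describeIn cohort_analysis One-row model summary (`rho`, `p_value`, `n`).
#' @export
glance.breathsnr_cohort_fit <- function(x, ...) {
  tibble::tibble(
    rho = x$rho, p_value = x$p_value, n = x$n,
    n_permutations = x$n_permutations
  )
}

#' @describeIn cohort_analysis Plot normalized group-mean SNR vs health scale.
#' @param object A `breathsnr_cohort_fit`.
#' @export
autoplot.breathsnr_cohort_fit <- function(object, ...) {
  ggplot2::ggplot(object$by_scale,
                  ggplot2::aes(.data$health_scale, .data$normalized_snr)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), colour = "steelblue") +
    ggplot2::scale_x_continuous(breaks = 1:10, limits = c(1, 10)) +
    ggplot2::labs(
      x = "Health-scale score (10 = excellent)",
      y = "Normalized group-mean SNR",
      size = "Subjects",
      title = sprintf("Spearman rho = %.2f, p = %.3g", object$rho,
                      object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Write the cohort summary to CSV + JSON
#'
#' @param fit A [cohort_analysis()] result.
#' @param csv_path Per-subject cohort table destination.
#' @param json_path JSON summary destination (`rho`, `p`, `n`, per-scale
#'   normalized means).
#' @return Invisibly, the two paths.
#' @export
cohort_summary_write <- function(fit, csv_path, json_path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("jsonlite is required to write the JSON summary.")
  }
  readr::write_csv(fit$table, csv_path)
  jsonlite::write_json(
    list(
      rho = fit$rho, p = fit$p_value, n = fit$n,
      normalized_means = fit$by_scale[, c("health_scale", "normalized_snr")]
    ),
    json_path, auto_unbox = TRUE, digits = NA
  )
  invisible(c(csv_path, json_path))
}
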