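subject_rows <- function(id, snrs, low_conf = FALSE, scale = 5,
                         group = "healthy") {
  tibble::tibble(
    subject_id = id, snr_db = snrs,
    low_confidence = rep_len(low_conf, length(snrs)),
    health_scale = scale, group = group
  )
}

test_that("per-subject aggregation averages in dB with confidence filtering", {
  expect_equal(aggregate_subjects(subject_rows("a", 12))$mean_snr_db, 12)
  expect_equal(aggregate_subjects(subject_rows("a", c(10, 14)))$mean_snr_db, 12)
  # a flagged outlier channel is excluded when filtering is on
  mixed <- subject_rows("a", c(10, 10, 40),
                        low_conf = c(FALSE, FALSE, TRUE))
  expect_equal(aggregate_subjects(mixed)$mean_snr_db, 10)
  expect_equal(aggregate_subjects(mixed, filter_low_confidence = FALSE)$mean_snr_db,
               20)
  # when everything is flagged, fall back to using all rows
  all_flagged <- subject_rows("a", c(10, 20), low_conf = TRUE)
  expect_equal(aggregate_subjects(all_flagged)$mean_snr_db, 15)
  expect_error(aggregate_subjects(subject_rows("a", numeric(0))),
               class = "breathsnr_insufficient_data")
})

test_that("group normalization is the min-max affine map", {
  tab <- tibble::tibble(health_scale = c(3, 5, 7), mean_snr_db = c(5, 10, 15))
  norm <- group_normalize(tab)
  expect_equal(norm$normalized_snr, c(0, 0.5, 1))
  # degenerate: all means equal
  flat <- tibble::tibble(health_scale = c(3, 5), mean_snr_db = c(7, 7))
  expect_error(group_normalize(flat), class = "breathsnr_insufficient_data")
  expect_equal(group_normalize(flat, degenerate = "midpoint")$normalized_snr,
               c(0.5, 0.5))
  expect_error(group_normalize(tibble::tibble(health_scale = 5,
                                              mean_snr_db = 1)),
               class = "breathsnr_insufficient_data")
})

test_that("group normalization is invariant to affine transforms of dB", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      tab <- tibble::tibble(
        health_scale = sample(1:10, 30, replace = TRUE),
        mean_snr_db = rnorm(30, 10, 5)
      )
      a <- runif(1, 0.1, 4); b <- runif(1, -20, 20)
    })
    if (length(unique(tab$health_scale)) < 2) next
    base <- group_normalize(tab)
    scaled <- tab
    scaled$mean_snr_db <- a * scaled$mean_snr_db + b
    expect_equal(group_normalize(scaled)$normalized_snr, base$normalized_snr,
                 tolerance = 1e-10)
  }
})

test_that("a perfectly monotone cohort reaches rho 1 at the minimal p", {
  tab <- tibble::tibble(health_scale = 1:10, mean_snr_db = seq(2, 20, 2))
  ct <- correlation_test(tab, n_permutations = 199, seed = 1)
  expect_equal(ct$rho, 1)
  expect_equal(ct$p_value, 1 / 200)
})

test_that("permutation p-values are bounded, reproducible and tie-safe", {
  withr::with_seed(2, {
    tab <- tibble::tibble(
      health_scale = sample(1:10, 24, replace = TRUE),  # heavy ties
      mean_snr_db = rnorm(24)
    )
  })
  a <- correlation_test(tab, n_permutations = 99, seed = 7)
  b <- correlation_test(tab, n_permutations = 99, seed = 7)
  expect_identical(a, b)
  expect_gte(a$p_value, 1 / 100)
  expect_lte(a$p_value, 1)
  # Spearman with average ranks: agrees with stats::cor
  expect_equal(a$rho, cor(tab$health_scale, tab$mean_snr_db,
                          method = "spearman"))
})

test_that("constant SNR raises an explicit undefined-correlation signal", {
  tab <- tibble::tibble(health_scale = 1:6, mean_snr_db = rep(5, 6))
  expect_error(correlation_test(tab),
               class = "breathsnr_undefined_correlation")
  expect_error(correlation_test(tab[1:4, ]),
               class = "breathsnr_insufficient_data")
})

test_that("null cohorts reject near the nominal 5% level", {
  # quick null calibration; the full 500-cohort check lives in acceptance
  rejections <- vapply(1:80, function(seed) {
    withr::with_seed(seed, {
      tab <- tibble::tibble(
        health_scale = sample(1:10, 38, replace = TRUE),
        mean_snr_db = rnorm(38)
      )
    })
    correlation_test(tab, n_permutations = 199, seed = seed)$p_value <= 0.05
  }, logical(1))
  expect_lt(mean(rejections), 0.15)
})

test_that("cohort_analysis assembles table, normalization and test", {
  withr::with_seed(3, {
    results <- purrr::map_dfr(1:12, function(i) {
      scale <- sample(2:9, 1)
      subject_rows(sprintf("S%02d", i), 2 * scale + rnorm(2), scale = scale,
                   group = ifelse(i <= 10, "healthy", "copd"))
    })
  })
  fit <- cohort_analysis(results, n_permutations = 199, seed = 1)
  expect_s3_class(fit, "breathsnr_cohort_fit")
  expect_equal(fit$n, 12)
  expect_gt(fit$rho, 0.8)
  expect_lt(fit$p_value, 0.05)
  expect_equal(nrow(fit$table), 12)
  expect_equal(max(fit$by_scale$normalized_snr), 1)
  expect_equal(min(fit$by_scale$normalized_snr), 0)
  # broom-style accessors
  expect_identical(tidy(fit), fit$by_scale)
  g <- glance(fit)
  expect_equal(g$rho, fit$rho)
  # metadata join path gives the same fit
  meta <- dplyr::distinct(results[, c("subject_id", "health_scale", "group")])
  fit2 <- cohort_analysis(dplyr::select(results, -health_scale, -group),
                          metadata = meta, n_permutations = 199, seed = 1)
  expect_equal(fit2$rho, fit$rho)
  # summary export
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  cohort_summary_write(fit, csv, js)
  summ <- jsonlite::read_json(js)
  expect_equal(summ$n, 12)
})

test_that("autoplot methods return ggplot objects", {
  ps <- welch_psd(rnorm(4000), 1000)
  expect_s3_class(ggplot2::autoplot(ps), "ggplot")
  tab <- tibble::tibble(health_scale = rep(1:5, each = 4),
                        mean_snr_db = rep(1:5, each = 4) + rnorm(20, 0, 0.1),
                        subject_id = sprintf("S%d", 1:20), snr_db = 0)
  fit <- cohort_analysis(
    dplyr::mutate(tab, snr_db = mean_snr_db, group = "healthy"),
    n_permutations = 99
  )
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
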