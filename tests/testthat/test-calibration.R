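make_records <- function(n = 6, analyte = "CRP", channel = "green",
                         conc = rep(c(0, 5, 10), each = 2),
                         auc = c(10, 12, 100, 104, 200, 196)) {
  data.frame(image_id = sprintf("img%02d", seq_len(n)), lane_id = "lane_1",
             channel = channel, band_index = 1L, kind = "test",
             raw_auc = auc + 50, background_level = 50, corrected_auc = auc,
             saturated = FALSE, analyte = analyte, concentration = conc,
             unit = "nM",
             replicate_group = paste0("g", ceiling(seq_len(n) / 2)),
             role = ifelse(conc == 0, "blank", "calibrant"),
             stringsAsFactors = FALSE)
}

test_that("intensity tables import with schema and row-level validation", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("lane_id,corrected_auc", "lane_1,10.5", "lane_2,20",
               "lane_3,30"), p)
  d <- import_intensity_table(p)
  expect_equal(nrow(d), 3L)
  expect_equal(d$corrected_auc, c(10.5, 20, 30))
  expect_equal(d$image_id, rep("unknown_image", 3))  # default filled

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("lane_id,foo", "lane_1,1"), bad)
  expect_error(import_intensity_table(bad), class = "lfa_schema_error")

  rowbad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("lane_id,auc", "lane_1,1", "lane_2,2", "lane_3,abc"), rowbad)
  expect_error(import_intensity_table(rowbad), regexp = "line 4",
               class = "lfa_parse_error")
})

test_that("design merge joins on image/lane/channel and reconciles leftovers", {
  rec <- make_records()
  design <- rec[c("image_id", "lane_id", "channel", "analyte",
                  "concentration", "unit", "replicate_group", "role")]
  meas <- rec[c("image_id", "lane_id", "channel", "band_index", "kind",
                "raw_auc", "background_level", "corrected_auc", "saturated")]

  merged <- merge_with_design(meas, design)
  expect_equal(nrow(merged), 6L)
  rc <- attr(merged, "reconciliation")
  expect_equal(nrow(rc$unmatched_measurements), 0L)
  expect_equal(nrow(rc$unmatched_design), 0L)

  merged5 <- merge_with_design(meas, design[1:5, ])
  expect_equal(nrow(merged5), 5L)
  expect_equal(nrow(attr(merged5, "reconciliation")$unmatched_measurements), 1L)

  dup <- rbind(design, design[1, ])
  expect_error(merge_with_design(meas, dup), class = "lfa_integrity_error")
})

test_that("replicate averaging uses the n-1 sd and flags singletons", {
  rec <- make_records(n = 3, conc = rep(5, 3), auc = c(10, 12, 14))
  rec$replicate_group <- "g1"
  avg <- average_replicates(rec)
  expect_equal(avg$mean_auc, 12)
  expect_equal(avg$sd_auc, 2)
  expect_equal(avg$n, 3L)

  single <- make_records(n = 1, conc = 5, auc = 7)
  expect_warning(avg1 <- average_replicates(single),
                 class = "lfa_singleton_sd")
  expect_equal(avg1$mean_auc, 7)
  expect_equal(avg1$sd_auc, 0)
  expect_true(avg1$singleton)

  same <- make_records(n = 4, conc = rep(5, 4), auc = rep(5, 4))
  same$replicate_group <- "g1"
  avg4 <- average_replicates(same)
  expect_equal(avg4$sd_auc, 0)
  expect_equal(avg4$n, 4L)
})

avg_table <- function(conc, auc, analyte = "A", channel = "green") {
  data.frame(analyte = analyte, channel = channel,
             replicate_group = paste0("g", seq_along(conc)),
             concentration = conc, unit = "nM",
             role = ifelse(conc == 0, "blank", "calibrant"),
             mean_auc = auc, sd_auc = 0, n = 3L, singleton = FALSE,
             stringsAsFactors = FALSE)
}

test_that("calibration fitting reproduces hand-computed OLS", {
  exact <- fit_calibration(avg_table(c(0, 1, 2), c(1, 3, 5)), "A", "green")
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r_squared, 1)
  expect_equal(exact$residual_sd, 0)

  # OLS by hand on (0,0), (1,1), (2,0): slope 0, intercept 1/3
  bump <- fit_calibration(avg_table(c(0, 1, 2), c(0, 1, 0)), "A", "green")
  expect_equal(bump$slope, 0, tolerance = 1e-12)
  expect_equal(bump$intercept, 1 / 3)

  expect_error(fit_calibration(avg_table(c(0, 0, 1), c(1, 1, 2)), "A", "green"),
               class = "lfa_insufficient_data")
  expect_error(fit_calibration(avg_table(c(1, 2), c(1, 2)), "A", "green"),
               class = "lfa_insufficient_data")
})

test_that("r_squared equals the squared Pearson correlation", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    conc <- sort(runif(n, 0, 50))
    auc <- 3 + 2 * conc + rnorm(n, sd = 5)
    fit <- fit_calibration(avg_table(conc, auc), "A", "green")
    expect_equal(fit$r_squared, cor(conc, auc)^2, tolerance = 1e-10)
  }
})

test_that("inverse prediction inverts the calibration line", {
  fit <- calibration_fit("A", "green", slope = 2, intercept = 1,
                         r_squared = 1, residual_sd = 0, n_points = 3)
  expect_equal(inverse_predict(fit, 5), 2)
  expect_equal(inverse_predict(fit, 1), 0)
  fit2 <- calibration_fit("A", "green", slope = 2, intercept = 4,
                          r_squared = 1, residual_sd = 0, n_points = 3)
  expect_equal(inverse_predict(fit2, 2), -1)

  set.seed(3)
  for (i in 1:20) {
    f <- calibration_fit("A", "green", slope = runif(1, -5, 5) + 0.1,
                         intercept = runif(1, -10, 10), r_squared = 0.9,
                         residual_sd = 1, n_points = 5)
    conc <- runif(1, 0, 100)
    expect_equal(inverse_predict(f, f$intercept + f$slope * conc), conc,
                 tolerance = 1e-12)
  }

  flat <- calibration_fit("A", "green", slope = 0, intercept = 1,
                          r_squared = 0, residual_sd = 0, n_points = 3)
  expect_error(inverse_predict(flat, 2), class = "lfa_degenerate_fit")
})

test_that("key measures follow the blank-based formulas", {
  fit <- calibration_fit("A", "green", slope = 2, intercept = 1,
                         r_squared = 1, residual_sd = 0, n_points = 3)
  km0 <- key_measures(fit, c(1, 1, 1))
  expect_equal(km0$lob, 0)
  expect_equal(km0$lod, 0)
  expect_equal(km0$loq, 0)

  unit <- calibration_fit("A", "green", slope = 1, intercept = 0,
                          r_squared = 1, residual_sd = 0, n_points = 3)
  # blanks with mean 0, sd 1; sd_low 1
  blanks <- c(-1, 0, 1)
  km <- key_measures(unit, blanks, low_conc_records = c(-1, 0, 1))
  expect_equal(km$lob, 1.645)
  expect_equal(km$lod, 3.29)
  expect_equal(km$loq, 10)

  expect_error(key_measures(unit, c(1)), class = "lfa_insufficient_data")
  expect_error(key_measures(flat <- calibration_fit("A", "green", 0, 1, 0, 0, 3),
                            c(1, 2)), class = "lfa_degenerate_fit")
})

test_that("a blank signal mapping below zero concentration reports 'Negative'", {
  # intercept above the blank LOB signal, positive slope
  fit <- calibration_fit("A", "green", slope = 2, intercept = 10,
                         r_squared = 1, residual_sd = 0, n_points = 3)
  km <- key_measures(fit, c(1, 1.2, 0.8))
  expect_identical(km$lob, "Negative")
  expect_identical(km$lod, "Negative")
})

test_that("key measures preserve lob <= lod <= loq in signal units", {
  set.seed(9)
  fit <- calibration_fit("A", "green", slope = 3, intercept = 2,
                         r_squared = 1, residual_sd = 0, n_points = 3)
  for (i in 1:50) {
    blanks <- rnorm(5, mean = runif(1, 0, 20), sd = runif(1, 0.1, 4))
    low <- rnorm(5, mean = 30, sd = runif(1, 0.1, 4))
    km <- key_measures(fit, blanks, low)
    expect_lte(km$lob_signal, km$lod_signal)
    expect_lte(km$lob_signal, km$loq_signal)
  }
})

test_that("key measures from summary stats match the record-based path", {
  fit <- calibration_fit("A", "green", slope = 5, intercept = 2,
                         r_squared = 1, residual_sd = 0, n_points = 3)
  blanks <- c(3, 4, 5, 6)
  low <- c(10, 12, 14)
  a <- key_measures(fit, blanks, low)
  b <- key_measures_from_stats(fit, mean(blanks), sd(blanks), sd(low))
  expect_equal(a$lob, b$lob)
  expect_equal(a$lod, b$lod)
  expect_equal(a$loq, b$loq)
})
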