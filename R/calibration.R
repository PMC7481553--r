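# Merging measurements with experiment metadata, replicate averaging,
# linear calibration and the key measures LOB / LOD / LOQ.

design_columns <- c("image_id", "lane_id", "channel", "analyte",
                    "concentration", "unit", "replicate_group", "role")

#' Read an experiment design table
#'
#' The design CSV maps every measured lane to its sample: columns
#' `image_id`, `lane_id`, `channel`, `analyte`, `concentration`, `unit`,
#' `replicate_group`, `role` (`calibrant`, `blank` or `unknown`). Blanks
#' must have concentration 0; every calibrant needs a finite concentration.
#'
#' @param path CSV path.
#' @return A data.frame with the design schema.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) lfa_io_error(sprintf("design file not found: '%s'", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(design_columns, names(d))
  if (length(missing) > 0L) {
    lfa_schema_error(sprintf("design CSV lacks mandatory column(s): %s",
                             paste(missing, collapse = ", ")))
  }
  validate_design(d)
  d
}

validate_design <- function(d) {
  keys <- paste(d$image_id, d$lane_id, d$channel, sep = "\r")
  if (anyDuplicated(keys)) {
    dup <- d[duplicated(keys), c("image_id", "lane_id", "channel")][1L, ]
    lfa_integrity_error(sprintf(
      "duplicate design key (image_id='%s', lane_id='%s', channel='%s')",
      dup$image_id, dup$lane_id, dup$channel))
  }
  if (!all(d$role %in% c("calibrant", "blank", "unknown"))) {
    lfa_schema_error("design role must be calibrant, blank or unknown")
  }
  cal <- d$role == "calibrant"
  if (any(cal & !is.finite(d$concentration))) {
    lfa_schema_error("every calibrant needs a finite concentration")
  }
  blank <- d$role == "blank"
  if (any(blank & d$concentration != 0)) {
    lfa_schema_error("blanks must have concentration 0")
  }
  invisible(d)
}

#' Import an externally produced intensity table
#'
#' Reads AUC lists exported from other densitometry software. The CSV must
#' contain `lane_id` and a numeric AUC column (`corrected_auc`, `auc` or
#' `AUC`); missing optional columns (`image_id`, `band_index`, `kind`,
#' `channel`, `raw_auc`, `background_level`, `saturated`) are filled with
#' defaults and logged.
#'
#' @param path CSV path.
#' @return A data.frame in the band-measurement schema.
#' @export
import_intensity_table <- function(path) {
  if (!file.exists(path)) lfa_io_error(sprintf("intensity file not found: '%s'", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  if (!"lane_id" %in% names(d)) {
    lfa_schema_error("intensity CSV lacks mandatory column: lane_id")
  }
  auc_col <- intersect(c("corrected_auc", "auc", "AUC"), names(d))[1]
  if (is.na(auc_col)) {
    lfa_schema_error(
      "intensity CSV lacks an AUC column (corrected_auc, auc or AUC)")
  }
  auc <- suppressWarnings(as.numeric(d[[auc_col]]))
  bad <- which(is.na(auc) & !is.na(d[[auc_col]]) & nzchar(d[[auc_col]]))
  if (length(bad) > 0L) {
    # +1 for the header row so the message cites the file line
    lfa_parse_error(sprintf(
      "non-numeric AUC value '%s' on line %d of '%s'",
      d[[auc_col]][bad[1L]], bad[1L] + 1L, path))
  }
  defaults <- list(image_id = "unknown_image", band_index = 1L, kind = "test",
                   channel = "gray", raw_auc = NA_real_,
                   background_level = NA_real_, saturated = FALSE)
  for (col in names(defaults)) {
    if (!col %in% names(d)) {
      lfa_log("info", "intensity table: filling missing column '", col,
              "' with default")
      d[[col]] <- defaults[[col]]
    }
  }
  d$corrected_auc <- auc
  d$band_index <- as.integer(d$band_index)
  d$raw_auc <- suppressWarnings(as.numeric(d$raw_auc))
  d$background_level <- suppressWarnings(as.numeric(d$background_level))
  d$saturated <- as.logical(d$saturated)
  d[c("image_id", "lane_id", "band_index", "kind", "channel",
      "raw_auc", "background_level", "corrected_auc", "saturated")]
}

#' Merge band measurements with the experiment design
#'
#' Inner join on (`image_id`, `lane_id`, `channel`). Rows without a partner
#' on either side are reported in a reconciliation summary attached as
#' attribute `"reconciliation"` and logged; they are not an error, since a
#' design often describes more strips than one batch image contains.
#'
#' @param measurements Band-measurement data.frame ([quantify_image()] or
#'   [import_intensity_table()]).
#' @param design Design data.frame ([read_design()]).
#' @return Merged `MeasurementRecord` data.frame; attribute
#'   `"reconciliation"` lists `unmatched_measurements` and
#'   `unmatched_design`.
#' @export
merge_with_design <- function(measurements, design) {
  validate_design(design)
  mkey <- paste(measurements$image_id, measurements$lane_id,
                measurements$channel, sep = "\r")
  dkey <- paste(design$image_id, design$lane_id, design$channel, sep = "\r")
  merged <- merge(measurements, design,
                  by = c("image_id", "lane_id", "channel"))
  un_m <- unique(measurements[!(mkey %in% dkey),
                              c("image_id", "lane_id", "channel")])
  un_d <- design[!(dkey %in% mkey), c("image_id", "lane_id", "channel")]
  if (nrow(un_m) > 0L || nrow(un_d) > 0L) {
    lfa_log("warning", sprintf(
      "reconciliation: %d measurement key(s) without design row, %d design row(s) without measurement",
      nrow(un_m), nrow(un_d)))
  }
  merged <- merged[order(merged$image_id, merged$lane_id, merged$band_index), ]
  rownames(merged) <- NULL
  attr(merged, "reconciliation") <- list(unmatched_measurements = un_m,
                                         unmatched_design = un_d)
  merged
}

#' Average technical replicates
#'
#' Groups records by (`analyte`, `channel`, `replicate_group`) and returns
#' the arithmetic mean and sample standard deviation (n-1 denominator) of
#' the corrected AUC. Singleton groups get sd 0 and are flagged.
#'
#' @param records Merged measurement records ([merge_with_design()]).
#'   Only test-line rows are averaged by default.
#' @param kinds Band kinds to include (default `"test"`).
#' @return Data.frame with `analyte`, `channel`, `replicate_group`,
#'   `concentration`, `unit`, `role`, `mean_auc`, `sd_auc`, `n`,
#'   `singleton`.
#' @export
average_replicates <- function(records, kinds = "test") {
  records <- records[records$kind %in% kinds, , drop = FALSE]
  if (nrow(records) == 0L) {
    lfa_insufficient_data("no records of the requested band kind(s) to average")
  }
  key <- interaction(records$analyte, records$channel,
                     records$replicate_group, drop = TRUE, lex.order = TRUE)
  groups <- split(records, key)
  out <- lapply(groups, function(g) {
    if (length(unique(g$concentration)) > 1L) {
      lfa_warn(sprintf(
        "replicate group '%s' mixes concentrations; using the first",
        g$replicate_group[1L]), "lfa_mixed_group")
    }
    n <- nrow(g)
    data.frame(analyte = g$analyte[1L], channel = g$channel[1L],
               replicate_group = g$replicate_group[1L],
               concentration = g$concentration[1L], unit = g$unit[1L],
               role = g$role[1L],
               mean_auc = mean(g$corrected_auc),
               sd_auc = if (n > 1L) stats::sd(g$corrected_auc) else 0,
               n = n, singleton = n == 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (any(out$singleton)) {
    lfa_warn(sprintf("%d replicate group(s) have a single member; sd set to 0",
                     sum(out$singleton)), "lfa_singleton_sd")
  }
  out[order(out$analyte, out$channel, out$concentration), ]
}

#' Construct a calibration fit object
#'
#' Usually produced by [fit_calibration()]; the constructor is exported so
#' fits from other software can be fed into [key_measures()] and
#' [inverse_predict()].
#'
#' @param analyte,channel Identify the calibrated response.
#' @param slope,intercept Linear model `signal = intercept + slope * conc`.
#' @param r_squared Coefficient of determination.
#' @param residual_sd Residual standard deviation, `sqrt(SS_res / (n - 2))`.
#' @param n_points Number of calibration points (>= 3).
#' @param concentration_unit Unit string (e.g. `"nM"`, `"pM"`).
#' @param data Optional data.frame of the fitted points
#'   (`concentration`, `mean_auc`, `sd_auc`, `n`), kept for reporting.
#' @return A `calibration_fit` object.
#' @export
calibration_fit <- function(analyte, channel, slope, intercept, r_squared,
                            residual_sd, n_points,
                            concentration_unit = "conc", data = NULL) {
  if (n_points < 3L) lfa_insufficient_data("a calibration fit needs >= 3 points")
  if (!is.na(r_squared) && (r_squared < -1e-12 || r_squared > 1 + 1e-12)) {
    lfa_usage_error("r_squared must lie in [0, 1]")
  }
  structure(list(analyte = analyte, channel = channel, slope = slope,
                 intercept = intercept,
                 r_squared = min(max(r_squared, 0), 1),
                 residual_sd = residual_sd, n_points = as.integer(n_points),
                 concentration_unit = concentration_unit, data = data),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit %s/%s: signal = %.6g + %.6g * conc [%s], R^2 = %.4f, residual sd = %.4g, n = %d>\n",
    x$analyte, x$channel, x$intercept, x$slope, x$concentration_unit,
    x$r_squared, x$residual_sd, x$n_points))
  invisible(x)
}

#' Fit a linear calibration curve
#'
#' Ordinary least squares of the replicate-mean signal on concentration
#' (classic calibration direction: `signal = intercept + slope * conc`),
#' fitted on the averaged table. Saturated measurements should be excluded
#' before averaging. Optional weights allow e.g. 1/concentration weighting.
#'
#' @param averaged Averaged table from [average_replicates()].
#' @param analyte,channel Which response to fit.
#' @param weights Optional numeric weights, one per averaged point.
#' @return A [calibration_fit].
#' @export
fit_calibration <- function(averaged, analyte, channel, weights = NULL) {
  sub <- averaged[averaged$analyte == analyte & averaged$channel == channel, ,
                  drop = FALSE]
  if (nrow(sub) == 0L) {
    lfa_insufficient_data(sprintf("no averaged data for %s/%s", analyte, channel))
  }
  if (length(unique(sub$concentration)) < 3L) {
    lfa_insufficient_data(sprintf(
      "calibration for %s/%s needs >= 3 distinct concentration levels, got %d",
      analyte, channel, length(unique(sub$concentration))))
  }
  if (stats::var(sub$concentration) == 0) {
    lfa_degenerate_fit("zero concentration variance; cannot calibrate")
  }
  fit <- stats::lm(mean_auc ~ concentration, data = sub, weights = weights)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((sub$mean_auc - mean(sub$mean_auc))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  n <- nrow(sub)
  calibration_fit(analyte = analyte, channel = channel,
                  slope = unname(stats::coef(fit)[2L]),
                  intercept = unname(stats::coef(fit)[1L]),
                  r_squared = r2,
                  residual_sd = sqrt(ss_res / (n - 2)),
                  n_points = n,
                  concentration_unit = sub$unit[1L],
                  data = sub[c("concentration", "mean_auc", "sd_auc", "n")])
}

#' Inverse prediction: signal to concentration
#'
#' Inverts the calibration line: `(signal - intercept) / slope`. The result
#' may be negative; deciding whether to report a negative estimate as the
#' label `"Negative"` is done downstream (see [key_measures()]).
#'
#' @param fit A [calibration_fit].
#' @param signal Numeric signal value(s).
#' @return Estimated concentration(s), possibly negative.
#' @export
inverse_predict <- function(fit, signal) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope == 0) lfa_degenerate_fit("slope is 0; calibration not invertible")
  (signal - fit$intercept) / fit$slope
}

#' Key measures: limit of blank, detection and quantification
#'
#' Blank-statistics-based sensitivity measures, computed in signal units and
#' converted to concentration by inverse prediction:
#' \deqn{LOB_s = \bar{x}_{blank} + 1.645\, s_{blank}}
#' \deqn{LOD_s = LOB_s + 1.645\, s_{low}}
#' \deqn{LOQ_s = \bar{x}_{blank} + 10\, s_{blank}}
#' where \eqn{s_{low}} is the signal standard deviation of the lowest
#' non-blank calibrant (falling back to \eqn{s_{blank}} when absent, with a
#' logged note). A limit that maps below zero concentration is reported as
#' the label `"Negative"` instead of a negative number.
#'
#' @param fit A [calibration_fit].
#' @param blank_records Blank signals: either a numeric vector of corrected
#'   AUCs or a data.frame with a `corrected_auc` column. At least 2 values.
#' @param low_conc_records Signals of the lowest non-blank calibrant, same
#'   forms as `blank_records`; optional.
#' @param definitions_id Identifier of the formula set recorded with the
#'   result (default `"blank_1.645sd"`).
#' @return A `key_measures` object: `lob`, `lod`, `loq` (numeric
#'   concentration or the character label `"Negative"`), `unit`,
#'   `definitions_id`, plus the underlying signal-unit limits
#'   (`lob_signal`, `lod_signal`, `loq_signal`) and blank statistics.
#' @export
key_measures <- function(fit, blank_records, low_conc_records = NULL,
                         definitions_id = "blank_1.645sd") {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope == 0) lfa_degenerate_fit("slope is 0; key measures undefined")
  blanks <- extract_signals(blank_records)
  if (length(blanks) < 2L) {
    lfa_insufficient_data("key measures need >= 2 blank replicates")
  }
  mean_b <- mean(blanks)
  sd_b <- stats::sd(blanks)
  if (is.null(low_conc_records)) {
    lfa_log("info", "no low-concentration records; using blank sd for LOD")
    sd_low <- sd_b
  } else {
    low <- extract_signals(low_conc_records)
    sd_low <- if (length(low) > 1L) stats::sd(low) else {
      lfa_log("info", "single low-concentration record; using blank sd for LOD")
      sd_b
    }
  }
  key_measures_from_stats(fit, blank_mean = mean_b, blank_sd = sd_b,
                          sd_low = sd_low, definitions_id = definitions_id)
}

#' Key measures from blank summary statistics
#'
#' Same formulas as [key_measures()], but starting from pre-computed blank
#' mean and standard deviations (e.g. when only a replicate-averaged table
#' is available).
#'
#' @inheritParams key_measures
#' @param blank_mean,blank_sd Mean and sample sd of the blank signals.
#' @param sd_low Signal sd of the lowest non-blank calibrant; defaults to
#'   `blank_sd`.
#' @return A `key_measures` object.
#' @export
key_measures_from_stats <- function(fit, blank_mean, blank_sd,
                                    sd_low = blank_sd,
                                    definitions_id = "blank_1.645sd") {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope == 0) lfa_degenerate_fit("slope is 0; key measures undefined")
  if (blank_sd < 0 || sd_low < 0) lfa_usage_error("sds must be >= 0")
  lob_s <- blank_mean + 1.645 * blank_sd
  lod_s <- lob_s + 1.645 * sd_low
  loq_s <- blank_mean + 10 * blank_sd

  to_conc <- function(s) {
    conc <- inverse_predict(fit, s)
    if (conc < 0) "Negative" else conc
  }
  structure(list(lob = to_conc(lob_s), lod = to_conc(lod_s),
                 loq = to_conc(loq_s), unit = fit$concentration_unit,
                 definitions_id = definitions_id,
                 lob_signal = lob_s, lod_signal = lod_s, loq_signal = loq_s,
                 blank_mean = blank_mean, blank_sd = blank_sd, sd_low = sd_low,
                 analyte = fit$analyte, channel = fit$channel),
            class = "key_measures")
}

extract_signals <- function(x) {
  if (is.data.frame(x)) {
    if (!"corrected_auc" %in% names(x)) {
      lfa_schema_error("records need a corrected_auc column")
    }
    x$corrected_auc
  } else {
    as.numeric(x)
  }
}

format_measure <- function(m, digits = 4) {
  if (is.character(m)) m else formatC(m, digits = digits, format = "g")
}

#' @export
print.key_measures <- function(x, ...) {
  cat(sprintf("<key_measures %s/%s [%s], definitions '%s'>\n",
              x$analyte, x$channel, x$unit, x$definitions_id))
  cat(sprintf("  LOB: %s\n  LOD: %s\n  LOQ: %s\n",
              format_measure(x$lob), format_measure(x$lod),
              format_measure(x$loq)))
  invisible(x)
}
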