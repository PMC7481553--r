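# Pipeline orchestration: simulate -> quantify -> calibrate -> report.
#
# A run is driven by a declarative YAML config (see read_run_config) and is
# deterministic for a fixed seed; the exec/lfaquant script wraps these
# functions for shell use.

#' Read and validate a run configuration
#'
#' The YAML file has up to four sections: `output_dir` (string), `simulate`,
#' `quantify` and `calibrate`. See the packaged example
#' `system.file("extdata", "example_config.yaml", package = "lfaquant")`
#' for the full schema.
#'
#' @param path YAML config path.
#' @return A named list with class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) lfa_io_error(sprintf("config file not found: '%s'", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$output_dir)) {
    lfa_usage_error("config must set output_dir")
  }
  structure(cfg, class = "run_config")
}

default_config <- function(output_dir, seed = 1L) {
  structure(list(
    output_dir = output_dir,
    simulate = list(preset = "sandwich", seed = seed),
    quantify = list(n_lanes = 1L, expected_bands = 2L),
    calibrate = list(stage = "raw", include_saturated = FALSE)),
    class = "run_config")
}

design_from_config <- function(sim) {
  seed <- if (is.null(sim$seed)) 1L else as.integer(sim$seed)
  if (identical(sim$preset, "clinical_range")) {
    return(clinical_range_design(seed = seed,
                                 replicates = sim$replicates %||% 3L))
  }
  args <- sim[names(sim) %in% c(
    "analyte_a", "analyte_b", "concentrations_a", "concentrations_b",
    "unit_a", "unit_b", "response_a", "response_b", "control_amplitude",
    "replicates", "crosstalk")]
  # YAML sequences of mixed int/real arrive as lists; flatten numeric fields
  for (f in c("concentrations_a", "concentrations_b")) {
    if (!is.null(args[[f]])) args[[f]] <- as.numeric(unlist(args[[f]]))
  }
  for (f in c("response_a", "response_b")) {
    if (!is.null(args[[f]])) {
      args[[f]] <- lapply(args[[f]], function(x)
        if (is.character(x)) x else as.numeric(x))
    }
  }
  if (!is.null(sim$strip)) {
    strip <- sim$strip
    if (!is.null(strip$band_centers)) {
      strip$band_centers <- as.numeric(unlist(strip$band_centers))
    }
    args$spec <- do.call(strip_spec, strip)
  }
  args$seed <- seed
  do.call(duplex_design, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a duplex experiment to disk
#'
#' Builds the duplex design from the config's `simulate` section (either
#' `preset: clinical_range` or explicit [duplex_design()] fields plus an
#' optional `strip:` block of [strip_spec()] fields), writes images, design
#' and ground-truth CSVs under `<output_dir>/images`, and a manifest
#' listing every artifact.
#'
#' @param config A `run_config` (or plain list with the same fields).
#' @return Invisible list with `image_dir`, `design`, `manifest`,
#'   `band_rows`.
#' @export
run_simulate <- function(config) {
  if (is.null(config$simulate)) lfa_usage_error("config has no simulate section")
  design <- design_from_config(config$simulate)
  if (!isTRUE(config$simulate$replicates >= 1) &&
      !is.null(config$simulate$replicates) && config$simulate$replicates < 1) {
    lfa_usage_error("replicates must be >= 1")
  }
  image_dir <- file.path(config$output_dir, "images")
  res <- generate_duplex_experiment(design, out_dir = image_dir)
  lfa_log("info", sprintf("simulated %d images into %s", length(res$images),
                          image_dir))
  invisible(list(image_dir = image_dir,
                 design = file.path(image_dir, "design.csv"),
                 manifest = file.path(image_dir, "manifest.txt"),
                 band_rows = res$band_rows))
}

channel_from_filename <- function(path) {
  base <- basename(path)
  if (grepl("green", base, fixed = TRUE)) "green"
  else if (grepl("red", base, fixed = TRUE)) "red"
  else "gray"
}

#' Quantify a batch of strip images
#'
#' Runs crop, lane splitting, band localisation and Otsu-background-
#' corrected band measurement over every image and writes
#' `<output_dir>/measurements.csv`. Image channels are taken from the
#' config's `channels` map (filename -> channel) or inferred from
#' "green"/"red" in the filename.
#'
#' @param config A `run_config`; its `quantify` section supplies `images`
#'   (paths) or `image_dir`, `n_lanes`, `expected_bands`, optional `crop`
#'   (top/left/height/width), `band_rows`, `channel_rule` and peak/Otsu
#'   parameters (`min_prominence`, `smoothing_window`, `boundary_fraction`,
#'   `margin_factor`, `search_halfwidth`).
#' @return Invisible path of the measurement CSV.
#' @export
run_quantify <- function(config) {
  q <- config$quantify %||% list()
  paths <- q$images
  if (is.null(paths)) {
    dir <- q$image_dir %||% file.path(config$output_dir, "images")
    paths <- list.files(dir, pattern = "\\.(png|tif|tiff)$", full.names = TRUE)
  }
  if (length(paths) == 0L) lfa_io_error("no input images to quantify")
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    lfa_io_error(sprintf("missing image file(s): %s",
                         paste(missing, collapse = ", ")))
  }
  region <- if (!is.null(q$crop)) do.call(crop_region, q$crop) else NULL
  extra <- q[names(q) %in% c("min_prominence", "smoothing_window",
                             "boundary_fraction", "margin_factor",
                             "search_halfwidth")]
  if (!is.null(q$band_rows)) extra$reference_rows <- as.numeric(q$band_rows)

  out <- lapply(paths, function(p) {
    img <- load_image(p, channel_rule = q$channel_rule %||% "native_gray",
                      channel_label = channel_from_filename(p))
    do.call(quantify_image,
            c(list(image = img, n_lanes = q$n_lanes %||% 1L,
                   expected_n = q$expected_bands %||% 2L, region = region,
                   image_id = tools::file_path_sans_ext(basename(p))),
              extra))
  })
  measurements <- do.call(rbind, out)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(config$output_dir, "measurements.csv")
  write_measurements(measurements, csv)
  lfa_log("info", sprintf("wrote %d band measurements to %s",
                          nrow(measurements), csv))
  invisible(csv)
}

#' Calibrate from measurements and design
#'
#' Merges measurements with the design, drops saturated bands (unless
#' `include_saturated`), averages technical replicates, fits one linear
#' calibration per (analyte, channel), computes LOB/LOD/LOQ and renders the
#' HTML + Markdown report. With `stage: averaged` the input CSV is taken to
#' be an already-averaged table (columns `analyte`, `channel`,
#' `concentration`, `unit`, `role`, `mean_auc`, `sd_auc`, `n`) and the
#' merge/average steps are skipped.
#'
#' @param config A `run_config`; its `calibrate` section supplies
#'   `measurements` (CSV path, default `<output_dir>/measurements.csv`),
#'   `design` (CSV path, default `<output_dir>/images/design.csv`),
#'   `stage` (`"raw"` or `"averaged"`), `include_saturated`,
#'   `definitions_id` and `report` (logical, default TRUE).
#' @return Invisible list with `results`, `averaged`, `report` paths and
#'   the fitted objects (`fits`, `measures`).
#' @export
run_calibrate <- function(config) {
  cal <- config$calibrate %||% list()
  stage <- cal$stage %||% "raw"
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (identical(stage, "averaged")) {
    averaged <- utils::read.csv(cal$measurements %||%
                                  file.path(out_dir, "averaged.csv"),
                                stringsAsFactors = FALSE)
    need <- c("analyte", "channel", "concentration", "mean_auc")
    missing <- setdiff(need, names(averaged))
    if (length(missing) > 0L) {
      lfa_schema_error(sprintf("averaged table lacks column(s): %s",
                               paste(missing, collapse = ", ")))
    }
    if (is.null(averaged$unit)) averaged$unit <- "conc"
    if (is.null(averaged$role)) {
      averaged$role <- ifelse(averaged$concentration == 0, "blank", "calibrant")
    }
    if (is.null(averaged$sd_auc)) averaged$sd_auc <- NA_real_
    if (is.null(averaged$n)) averaged$n <- NA_integer_
    records <- NULL
  } else {
    mpath <- cal$measurements %||% file.path(out_dir, "measurements.csv")
    dpath <- cal$design %||% file.path(out_dir, "images", "design.csv")
    measurements <- import_intensity_table(mpath)
    design <- read_design(dpath)
    records <- merge_with_design(measurements, design)
    if (!isTRUE(cal$include_saturated) && any(records$saturated)) {
      lfa_warn(sprintf(
        "excluding %d saturated band measurement(s) from calibration",
        sum(records$saturated)), "lfa_saturation_excluded")
      fit_records <- records[!records$saturated, , drop = FALSE]
    } else {
      fit_records <- records
    }
    averaged <- average_replicates(fit_records)
    utils::write.csv(averaged, file.path(out_dir, "averaged.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  combos <- unique(averaged[c("analyte", "channel")])
  fits <- list(); measures <- list()
  for (i in seq_len(nrow(combos))) {
    an <- combos$analyte[i]; ch <- combos$channel[i]
    fit <- fit_calibration(averaged, an, ch)
    km <- tryCatch({
      if (identical(stage, "averaged")) {
        sub <- averaged[averaged$analyte == an & averaged$channel == ch, ]
        blank <- sub[sub$role == "blank", ]
        lowc <- sub[sub$role != "blank" & sub$concentration > 0, ]
        lowc <- lowc[which.min(lowc$concentration), ]
        if (nrow(blank) == 0L) NULL else {
          key_measures_from_stats(fit, blank_mean = blank$mean_auc[1L],
                                  blank_sd = blank$sd_auc[1L],
                                  sd_low = if (nrow(lowc)) lowc$sd_auc[1L]
                                           else blank$sd_auc[1L],
                                  definitions_id = cal$definitions_id %||%
                                    "blank_1.645sd")
        }
      } else {
        sub <- fit_records[fit_records$analyte == an &
                             fit_records$channel == ch &
                             fit_records$kind == "test", ]
        blanks <- sub[sub$role == "blank", ]
        nonblank <- sub[sub$concentration > 0, ]
        lowc <- if (nrow(nonblank)) {
          nonblank[nonblank$concentration == min(nonblank$concentration), ]
        } else NULL
        if (nrow(blanks) < 2L) NULL else {
          key_measures(fit, blanks, lowc,
                       definitions_id = cal$definitions_id %||% "blank_1.645sd")
        }
      }
    }, lfa_error = function(e) {
      lfa_log("warning", sprintf("key measures unavailable for %s/%s: %s",
                                 an, ch, conditionMessage(e)))
      NULL
    })
    fits[[i]] <- fit
    measures[[i]] <- km
  }

  results <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]; km <- measures[[i]]
    data.frame(analyte = f$analyte, channel = f$channel, slope = f$slope,
               intercept = f$intercept, r_squared = f$r_squared,
               residual_sd = f$residual_sd, n_points = f$n_points,
               unit = f$concentration_unit,
               lob = if (is.null(km)) NA else format_measure(km$lob),
               lod = if (is.null(km)) NA else format_measure(km$lod),
               loq = if (is.null(km)) NA else format_measure(km$loq),
               definitions_id = if (is.null(km)) NA else km$definitions_id,
               stringsAsFactors = FALSE)
  }))
  results_path <- file.path(out_dir, "results.csv")
  utils::write.csv(results, results_path, row.names = FALSE, quote = FALSE)

  report_paths <- NULL
  if (!identical(cal$report, FALSE)) {
    report_paths <- render_report(
      fits, measures, out_path = file.path(out_dir, "report.html"),
      records = records,
      config = list(stage = stage,
                    include_saturated = isTRUE(cal$include_saturated),
                    definitions_id = cal$definitions_id %||% "blank_1.645sd"))
  }
  lfa_log("info", sprintf("calibrated %d analyte/channel combination(s)",
                          length(fits)))
  invisible(list(results = results_path,
                 averaged = file.path(out_dir, "averaged.csv"),
                 report = report_paths, fits = fits, measures = measures))
}

#' Run the full pipeline
#'
#' `simulate -> quantify -> calibrate -> report` in one call. With a fixed
#' seed the measurement CSV, results CSV and report body are byte-identical
#' across runs.
#'
#' @param config A `run_config` with all three sections.
#' @return Invisible list of the stage results.
#' @export
run_all <- function(config) {
  sim <- run_simulate(config)
  if (is.null(config$quantify)) config$quantify <- list()
  if (is.null(config$quantify$image_dir)) {
    config$quantify$image_dir <- sim$image_dir
  }
  if (is.null(config$quantify$band_rows)) {
    config$quantify$band_rows <- sim$band_rows
  }
  mcsv <- run_quantify(config)
  if (is.null(config$calibrate)) config$calibrate <- list()
  if (is.null(config$calibrate$measurements)) config$calibrate$measurements <- mcsv
  if (is.null(config$calibrate$design)) config$calibrate$design <- sim$design
  cal <- run_calibrate(config)
  invisible(list(simulate = sim, measurements = mcsv, calibrate = cal))
}
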