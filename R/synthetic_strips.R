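# Ground-truthed synthetic strip images: single strips and full duplex
# calibration experiments, so every pipeline stage is testable without
# real assay photographs.

#' Specify a synthetic strip image
#'
#' The noise-free signal at row r, column c is
#' `background_level + background_gradient * (r - 1) +
#'  sum_i amplitude_i * exp(-(r - center_i)^2 / (2 * band_sigma_px^2))`,
#' uniform across the strip width; reagent lines are horizontal Gaussian
#' stripes along the flow axis. Optional Gaussian blur, additive Gaussian
#' read noise and saturation clipping emulate the imager.
#'
#' @param height_px,width_px Strip dimensions in pixels.
#' @param bit_depth 8 or 16 (default 16, matching fluorescence captures).
#' @param band_centers Strictly increasing band centre rows (at most 6).
#' @param band_sigma_px Gaussian band width (sd, rows).
#' @param background_level Membrane background intensity (counts).
#' @param background_gradient Additive per-row background slope.
#' @param noise_sd Additive Gaussian noise sd (counts).
#' @param blur_sigma_px Gaussian blur sd in pixels (0 = none).
#' @param clip_saturation If TRUE clip to the representable range; if FALSE
#'   an out-of-range noise-free signal raises a range error.
#' @return A `strip_spec` object.
#' @export
strip_spec <- function(height_px = 120L, width_px = 30L, bit_depth = 16L,
                       band_centers = c(40L, 90L), band_sigma_px = 3,
                       background_level = 500, background_gradient = 0,
                       noise_sd = 0, blur_sigma_px = 0,
                       clip_saturation = TRUE) {
  if (length(band_centers) > 6L) {
    lfa_usage_error("at most 6 bands per strip are supported")
  }
  if (is.unsorted(band_centers, strictly = TRUE)) {
    lfa_usage_error("band_centers must be strictly increasing")
  }
  if (any(band_centers < 1 | band_centers > height_px)) {
    lfa_geometry_error("band_centers must lie inside [1, height_px]")
  }
  if (band_sigma_px <= 0) lfa_usage_error("band_sigma_px must be > 0")
  if (noise_sd < 0 || blur_sigma_px < 0 || background_level < 0) {
    lfa_usage_error("noise_sd, blur_sigma_px and background_level must be >= 0")
  }
  structure(list(height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 bit_depth = as.integer(bit_depth),
                 band_centers = as.numeric(band_centers),
                 band_sigma_px = band_sigma_px,
                 background_level = background_level,
                 background_gradient = background_gradient,
                 noise_sd = noise_sd, blur_sigma_px = blur_sigma_px,
                 clip_saturation = isTRUE(clip_saturation)),
            class = "strip_spec")
}

gaussian_kernel <- function(sigma) {
  radius <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-radius:radius)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur with edge replication
blur_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel(sigma)
  radius <- (length(k) - 1L) %/% 2L
  conv1 <- function(v) {
    padded <- c(rep(v[1L], radius), v, rep(v[length(v)], radius))
    as.numeric(stats::filter(padded, k, sides = 2L))[
      (radius + 1L):(radius + length(v))]
  }
  m <- apply(m, 2L, conv1)        # along rows (flow axis)
  t(apply(m, 1L, conv1))          # along columns
}

#' Generate one synthetic strip image
#'
#' Renders the noise-free signal of `spec`, applies optional blur, adds
#' seeded Gaussian noise, rounds to integers and clips (or errors) at the
#' representable range. Identical `spec` + `amplitudes` + `seed` give a
#' bit-identical image.
#'
#' @param spec A [strip_spec].
#' @param band_amplitudes Peak amplitudes (counts above background), one per
#'   band centre; 0 renders an absent band.
#' @param seed Integer seed for the noise.
#' @param channel_label Channel label of the output image.
#' @param source_id Identifier stored with the image.
#' @return List with `image` (a [raster_image]) and `truth`: a data.frame
#'   of band windows (`band_index`, `center`, `start`, `end` = centre
#'   +/- 3 sigma clipped to the strip, `amplitude`) plus attributes
#'   `background_level` and `background_gradient`.
#' @export
generate_strip <- function(spec, band_amplitudes, seed = 1L,
                           channel_label = "gray",
                           source_id = sprintf("synthetic_seed%d", seed)) {
  stopifnot(inherits(spec, "strip_spec"))
  if (length(band_amplitudes) != length(spec$band_centers)) {
    lfa_usage_error("need one amplitude per band centre")
  }
  if (any(band_amplitudes < 0)) lfa_usage_error("amplitudes must be >= 0")
  r <- seq_len(spec$height_px)
  profile <- spec$background_level + spec$background_gradient * (r - 1)
  for (i in seq_along(spec$band_centers)) {
    profile <- profile + band_amplitudes[i] *
      exp(-(r - spec$band_centers[i])^2 / (2 * spec$band_sigma_px^2))
  }
  signal <- matrix(profile, nrow = spec$height_px, ncol = spec$width_px)
  signal <- blur_matrix(signal, spec$blur_sigma_px)

  maxval <- 2^spec$bit_depth - 1
  if (!spec$clip_saturation && (max(signal) > maxval || min(signal) < 0)) {
    lfa_range_error(sprintf(
      "noise-free signal range [%.1f, %.1f] exceeds [0, %d] and clip_saturation is FALSE",
      min(signal), max(signal), maxval))
  }
  if (spec$noise_sd > 0) {
    noise <- withr::with_seed(as.integer(seed), {
      stats::rnorm(length(signal), sd = spec$noise_sd)
    })
    signal <- signal + noise
  }
  px <- round(signal)
  px[px < 0] <- 0
  px[px > maxval] <- maxval

  truth <- data.frame(
    band_index = seq_along(spec$band_centers),
    center = spec$band_centers,
    start = pmax(1, round(spec$band_centers - 3 * spec$band_sigma_px)),
    end = pmin(spec$height_px, round(spec$band_centers + 3 * spec$band_sigma_px)),
    amplitude = band_amplitudes)
  attr(truth, "background_level") <- spec$background_level
  attr(truth, "background_gradient") <- spec$background_gradient
  list(image = raster_image(px, bit_depth = spec$bit_depth,
                            channel_label = channel_label,
                            source_id = source_id),
       truth = truth)
}

#' Apply a saturation ceiling
#'
#' Clips every pixel at `ceiling`, producing the flat-topped band profiles
#' of an oversaturated capture.
#'
#' @param image A [raster_image].
#' @param ceiling Integer in `(0, 2^bit_depth - 1]`. When the ceiling equals
#'   the representable maximum the clipped rows read as saturated pixels.
#' @return The clipped [raster_image].
#' @export
saturate_image <- function(image, ceiling) {
  stopifnot(inherits(image, "raster_image"))
  maxval <- image_max_value(image)
  if (ceiling <= 0 || ceiling > maxval) {
    lfa_usage_error(sprintf("ceiling must be in (0, %d], got %s", maxval,
                            ceiling))
  }
  raster_image(pmin(image$pixels, as.integer(ceiling)),
               bit_depth = image$bit_depth,
               channel_label = image$channel_label,
               source_id = image$source_id)
}

response_function <- function(response) {
  if (identical(response$type, "linear")) {
    function(conc) response$slope * conc
  } else if (identical(response$type, "langmuir")) {
    function(conc) response$amax * conc / (response$k_half + conc)
  } else {
    lfa_usage_error("response type must be 'linear' or 'langmuir'")
  }
}

#' Specify a duplex calibration experiment
#'
#' Two analytes read out on one strip through two emission channels:
#' analyte A in the green channel, analyte B in the red channel. Each
#' concentration level pairs `concentrations_a[k]` with
#' `concentrations_b[k]`; every level is replicated, and each strip is
#' imaged once per channel. `crosstalk` is the fraction of the other
#' channel's test-band amplitude leaking into an image (0 = spectrally
#' clean labels).
#'
#' @param analyte_a,analyte_b Analyte names.
#' @param concentrations_a,concentrations_b Non-negative concentration
#'   vectors of equal length (level k of A and B run on the same strip).
#' @param unit_a,unit_b Concentration units.
#' @param response_a,response_b Response of test-band amplitude to
#'   concentration: `list(type = "linear", slope = )` or
#'   `list(type = "langmuir", amax = , k_half = )`.
#' @param control_amplitude Control-band amplitude (counts), same in both
#'   channels.
#' @param replicates Technical replicates per level (>= 1).
#' @param spec [strip_spec] of the individual strips; must define exactly
#'   two bands (test line above the control line).
#' @param crosstalk Fraction in `[0, 1]` of the other label's amplitude
#'   leaking into a channel (default 0).
#' @param seed Master seed; per-image seeds are derived from it.
#' @return A `duplex_design` object.
#' @export
duplex_design <- function(analyte_a = "CRP", analyte_b = "IL6",
                          concentrations_a = c(0, 2.5, 5, 10, 20),
                          concentrations_b = c(0, 2.5, 5, 10, 20),
                          unit_a = "nM", unit_b = "nM",
                          response_a = list(type = "linear", slope = 150),
                          response_b = list(type = "linear", slope = 150),
                          control_amplitude = 4000, replicates = 3L,
                          spec = strip_spec(noise_sd = 60),
                          crosstalk = 0, seed = 1L) {
  if (length(concentrations_a) != length(concentrations_b)) {
    lfa_usage_error("concentration vectors must pair up level by level")
  }
  if (length(concentrations_a) == 0L) {
    lfa_usage_error("concentration lists must be non-empty")
  }
  if (any(concentrations_a < 0) || any(concentrations_b < 0)) {
    lfa_usage_error("concentrations must be >= 0")
  }
  if (replicates < 1L) lfa_usage_error("replicates must be >= 1")
  if (crosstalk < 0 || crosstalk > 1) {
    lfa_usage_error("crosstalk must be in [0, 1]")
  }
  if (length(spec$band_centers) != 2L) {
    lfa_usage_error("duplex strips need exactly two bands (test + control)")
  }
  if (control_amplitude <= 0) lfa_usage_error("control_amplitude must be > 0")
  structure(list(analyte_a = analyte_a, analyte_b = analyte_b,
                 concentrations_a = concentrations_a,
                 concentrations_b = concentrations_b,
                 unit_a = unit_a, unit_b = unit_b,
                 response_a = response_a, response_b = response_b,
                 control_amplitude = control_amplitude,
                 replicates = as.integer(replicates), spec = spec,
                 crosstalk = crosstalk, seed = as.integer(seed)),
            class = "duplex_design")
}

#' Clinical-range duplex preset
#'
#' Concentration levels spanning the clinically relevant ranges of the two
#' sepsis biomarkers: CRP 0-1000 nM (green channel) and IL-6 0-60 pM (red
#' channel).
#'
#' @param ... Overrides passed on to [duplex_design()].
#' @return A `duplex_design`.
#' @export
clinical_range_design <- function(...) {
  args <- list(analyte_a = "CRP", analyte_b = "IL6",
               concentrations_a = c(0, 50, 125, 250, 500, 1000),
               concentrations_b = c(0, 3, 7.5, 15, 30, 60),
               unit_a = "nM", unit_b = "pM",
               response_a = list(type = "linear", slope = 3),
               response_b = list(type = "linear", slope = 50))
  override <- list(...)
  args[names(override)] <- override
  do.call(duplex_design, args)
}

#' Generate a duplex calibration experiment
#'
#' For each concentration level x replicate, renders one strip and images
#' it in both channels (green carries analyte A's test band, red analyte
#' B's; the control band appears in both). Per-image seeds are derived
#' from the master seed (`seed + 2 * (strip - 1)` for green, `+ 1` more
#' for red) so replicates are independent but the whole experiment is
#' reproducible. Optionally writes the images (16-bit TIFF) plus design
#' and ground-truth CSVs.
#'
#' @param design A [duplex_design].
#' @param out_dir Output directory; `NULL` (default) keeps everything in
#'   memory.
#' @param format `"tiff"` (default) or `"png"` (8-bit specs only).
#' @return List with `images` (named list of [raster_image]), `design_table`
#'   (experiment design data.frame in the calibration schema), `truth`
#'   (data.frame of true amplitudes and band windows per image) and, when
#'   written, `manifest` (paths of all artifacts).
#' @export
generate_duplex_experiment <- function(design, out_dir = NULL,
                                       format = c("tiff", "png")) {
  stopifnot(inherits(design, "duplex_design"))
  format <- match.arg(format)
  resp_a <- response_function(design$response_a)
  resp_b <- response_function(design$response_b)
  n_levels <- length(design$concentrations_a)

  images <- list()
  design_rows <- list()
  truth_rows <- list()
  strip <- 0L
  for (lev in seq_len(n_levels)) {
    ca <- design$concentrations_a[lev]
    cb <- design$concentrations_b[lev]
    amp_a <- resp_a(ca)
    amp_b <- resp_b(cb)
    for (rep_i in seq_len(design$replicates)) {
      strip <- strip + 1L
      base_seed <- design$seed + 2L * (strip - 1L)
      for (ch in c("green", "red")) {
        test_amp <- if (ch == "green") {
          amp_a + design$crosstalk * amp_b
        } else {
          amp_b + design$crosstalk * amp_a
        }
        img_seed <- base_seed + (ch == "red")
        image_id <- sprintf("strip%03d_%s", strip, ch)
        gs <- generate_strip(design$spec,
                             band_amplitudes = c(test_amp,
                                                 design$control_amplitude),
                             seed = img_seed, channel_label = ch,
                             source_id = image_id)
        images[[image_id]] <- gs$image
        analyte <- if (ch == "green") design$analyte_a else design$analyte_b
        conc <- if (ch == "green") ca else cb
        unit <- if (ch == "green") design$unit_a else design$unit_b
        design_rows[[image_id]] <- data.frame(
          image_id = image_id, lane_id = "lane_1", channel = ch,
          analyte = analyte, concentration = conc, unit = unit,
          replicate_group = sprintf("%s_level%02d", analyte, lev),
          role = if (conc == 0) "blank" else "calibrant",
          stringsAsFactors = FALSE)
        truth_rows[[image_id]] <- cbind(
          data.frame(image_id = image_id, channel = ch,
                     stringsAsFactors = FALSE),
          gs$truth)
      }
    }
  }
  design_table <- do.call(rbind, design_rows)
  truth <- do.call(rbind, truth_rows)
  rownames(design_table) <- rownames(truth) <- NULL

  result <- list(images = images, design_table = design_table, truth = truth,
                 band_rows = design$spec$band_centers)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ext <- if (format == "tiff") "tif" else "png"
    image_paths <- vapply(names(images), function(id) {
      p <- file.path(out_dir, paste0(id, ".", ext))
      write_image(images[[id]], p)
      p
    }, character(1))
    design_path <- file.path(out_dir, "design.csv")
    truth_path <- file.path(out_dir, "truth.csv")
    utils::write.csv(design_table, design_path, row.names = FALSE, quote = FALSE)
    utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
    manifest <- c(unname(image_paths), design_path, truth_path)
    manifest_path <- file.path(out_dir, "manifest.txt")
    writeLines(basename(manifest), manifest_path)
    result$manifest <- c(manifest, manifest_path)
  }
  result
}
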