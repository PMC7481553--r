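# Lane geometry, intensity profiles, Otsu background correction, band AUC.
#
# Geometry convention: 1-based inclusive indices; the flow axis runs along
# image rows (bands are horizontal stripes, strips run top -> bottom).

#' Define a crop rectangle
#'
#' @param top,left 1-based row/column of the upper-left corner.
#' @param height,width Extent in pixels (>= 1).
#' @return A `crop_region` object.
#' @export
crop_region <- function(top, left, height, width) {
  if (height < 1L || width < 1L) {
    lfa_geometry_error("crop height and width must be >= 1")
  }
  if (top < 1L || left < 1L) lfa_geometry_error("crop top/left must be >= 1")
  structure(list(top = as.integer(top), left = as.integer(left),
                 height = as.integer(height), width = as.integer(width)),
            class = "crop_region")
}

#' Crop an image
#'
#' Cropping is the one manual step of the readout: the user selects the
#' membrane area containing the aligned strips; everything downstream is
#' automatic.
#'
#' @param image A [raster_image].
#' @param region A [crop_region] lying fully inside the image.
#' @return The cropped [raster_image]; bit depth and channel label preserved.
#' @export
crop_image <- function(image, region) {
  stopifnot(inherits(image, "raster_image"), inherits(region, "crop_region"))
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  bottom <- region$top + region$height - 1L
  right <- region$left + region$width - 1L
  if (bottom > nr || right > nc) {
    lfa_geometry_error(sprintf(
      "crop region rows %d..%d x cols %d..%d exceeds image %dx%d",
      region$top, bottom, region$left, right, nr, nc))
  }
  raster_image(image$pixels[region$top:bottom, region$left:right, drop = FALSE],
               bit_depth = image$bit_depth,
               channel_label = image$channel_label,
               source_id = image$source_id)
}

#' Split a batch image into equal-width lanes
#'
#' Batch photographs contain several well-aligned strips side by side; they
#' are partitioned left to right into `n_lanes` vertical lanes of equal
#' width. When the width is not divisible, the leftmost `width %% n_lanes`
#' lanes get one extra column, so the lanes tile the input exactly.
#'
#' @param image A [raster_image].
#' @param n_lanes Number of strips in the image (>= 1, <= image width).
#' @return A list of [raster_image] lanes, left to right; each carries a
#'   `lane_id` of the form `"lane_<k>"` in its `source_id`.
#' @export
split_lanes <- function(image, n_lanes) {
  stopifnot(inherits(image, "raster_image"))
  n_lanes <- as.integer(n_lanes)
  w <- ncol(image$pixels)
  if (n_lanes < 1L) lfa_usage_error("n_lanes must be >= 1")
  if (n_lanes > w) {
    lfa_usage_error(sprintf("n_lanes (%d) exceeds image width (%d)", n_lanes, w))
  }
  base <- w %/% n_lanes
  widths <- rep(base, n_lanes)
  extra <- w %% n_lanes
  if (extra > 0L) widths[seq_len(extra)] <- widths[seq_len(extra)] + 1L
  stops <- cumsum(widths)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  lapply(seq_len(n_lanes), function(k) {
    raster_image(image$pixels[, starts[k]:stops[k], drop = FALSE],
                 bit_depth = image$bit_depth,
                 channel_label = image$channel_label,
                 source_id = sprintf("%s#lane_%d", image$source_id, k))
  })
}

#' Extract a lane's flow-axis intensity profile
#'
#' The profile value at row `r` is the arithmetic mean of that row's pixels;
#' band AUCs are areas under this profile.
#'
#' @param lane A [raster_image] of a single strip.
#' @param lane_id Identifier stored with the profile.
#' @return An `intensity_profile`: list with `values` (one per row, top to
#'   bottom), `lane_id` and `channel_label`.
#' @export
lane_profile <- function(lane, lane_id = lane$source_id) {
  stopifnot(inherits(lane, "raster_image"))
  structure(list(values = rowMeans(lane$pixels), lane_id = lane_id,
                 channel_label = lane$channel_label),
            class = "intensity_profile")
}

#' Otsu's threshold for integer pixel values
#'
#' Returns the threshold maximising the between-class variance of the value
#' histogram, the basis of the background subtraction: pixels `>= threshold`
#' are foreground (band), pixels below are membrane background. Candidate
#' thresholds are the distinct observed values; ties are broken towards the
#' smallest threshold.
#'
#' @param values Integer vector (>= 2 distinct values).
#' @return The integer threshold.
#' @export
otsu_threshold <- function(values) {
  values <- as.integer(values)
  if (anyNA(values)) lfa_usage_error("values must not contain NA")
  lev <- sort(unique(values))
  if (length(lev) < 2L) {
    lfa_degenerate_input("all values identical; no threshold separates classes")
  }
  counts <- tabulate(match(values, lev), nbins = length(lev))
  n <- length(values)
  # For threshold t = lev[k], background = values < t, foreground = values >= t.
  # Cumulate over the sorted histogram: class statistics in one pass.
  csum_n <- cumsum(counts)
  csum_v <- cumsum(counts * as.numeric(lev))
  total <- csum_v[length(lev)]
  k <- seq_len(length(lev) - 1L)           # background = levels 1..k
  n0 <- csum_n[k]; n1 <- n - n0
  mu0 <- csum_v[k] / n0
  mu1 <- (total - csum_v[k]) / n1
  between <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
  best <- which.max(between)               # first max -> smallest threshold
  lev[best + 1L]
}

moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  half <- (window - 1L) %/% 2L
  # replicate edges so the smoothed profile keeps full length
  padded <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(padded, rep(1 / window, window), sides = 2L))[
    (half + 1L):(half + length(x))]
}

#' Locate bands in an intensity profile
#'
#' Smooths the profile with a centred moving average, finds the
#' `expected_n` most prominent local maxima and grows a window around each
#' peak out to the first row where the smoothed profile drops below
#' `background + boundary_fraction * (peak - background)`. At most six
#' bands per lane are supported. By default the last (bottom-most) band is
#' taken to be the control line, all others test lines.
#'
#' @param profile An `intensity_profile` from [lane_profile()].
#' @param expected_n Number of bands to find (1..6).
#' @param min_prominence Minimum peak height above the profile background to
#'   count as a band (default 0: take the `expected_n` highest).
#' @param smoothing_window Odd moving-average width in rows (default 5).
#' @param boundary_fraction Window boundary level as a fraction of
#'   peak-above-background (default 0.1).
#' @param band_kinds Optional character vector of length `expected_n` with
#'   entries from `"test"`, `"control"`, `"unknown"`; default: last band is
#'   `"control"`, the rest `"test"`.
#' @param reference_rows Optional numeric vector of length `expected_n` with
#'   the approximate band centre rows (strictly increasing). Reagent lines
#'   are printed at fixed positions on the membrane, so when the strip
#'   layout is known each band's peak is searched only within
#'   `search_halfwidth` rows of its reference position. A band with no
#'   distinct peak there (e.g. the test line of a blank) still gets a
#'   window centred on the reference row, so its noise-level AUC is
#'   measured rather than a spurious peak elsewhere.
#' @param search_halfwidth Half-width in rows of the per-band search
#'   neighbourhood used with `reference_rows` (default 10).
#' @return A data.frame of band windows: `band_index`, `start`, `end`
#'   (1-based inclusive rows), `peak_row`, `kind`, sorted top to bottom.
#' @export
locate_bands <- function(profile, expected_n, min_prominence = 0,
                         smoothing_window = 5L, boundary_fraction = 0.1,
                         band_kinds = NULL, reference_rows = NULL,
                         search_halfwidth = 10L) {
  stopifnot(inherits(profile, "intensity_profile"))
  expected_n <- as.integer(expected_n)
  if (expected_n < 1L || expected_n > 6L) {
    lfa_usage_error(sprintf(
      "expected_n must be between 1 and 6 bands per lane, got %d", expected_n))
  }
  x <- profile$values
  if (length(x) <= smoothing_window) {
    lfa_usage_error("profile shorter than the smoothing window")
  }
  if (smoothing_window %% 2L == 0L) {
    lfa_usage_error("smoothing_window must be odd")
  }
  s <- moving_average(x, as.integer(smoothing_window))
  n <- length(s)
  bg <- min(s)

  if (!is.null(reference_rows)) {
    if (length(reference_rows) != expected_n || is.unsorted(reference_rows,
                                                            strictly = TRUE)) {
      lfa_usage_error(
        "reference_rows must give one strictly increasing row per expected band")
    }
    sel <- vapply(reference_rows, function(ref) {
      lo <- max(1L, as.integer(round(ref)) - as.integer(search_halfwidth))
      hi <- min(n, as.integer(round(ref)) + as.integer(search_halfwidth))
      lo + which.max(s[lo:hi]) - 1L
    }, integer(1))
  } else {
    # local maxima; a flat plateau contributes its first index
    left_ok <- c(TRUE, diff(s) > 0)           # rising into i
    right_ok <- c(s[-n] >= s[-1], TRUE)       # not rising after i
    peaks <- which(left_ok & right_ok)
    prominence <- s[peaks] - bg
    keep <- prominence >= min_prominence
    peaks <- peaks[keep]; prominence <- prominence[keep]
    if (length(peaks) < expected_n) {
      lfa_detection_error(sprintf(
        "expected %d bands but found %d peaks above prominence %g (rows: %s)",
        expected_n, length(peaks), min_prominence,
        paste(peaks, collapse = ", ")))
    }
    # most prominent first; equal prominence -> topmost retained first
    ord <- order(-prominence, peaks)
    sel <- sort(peaks[ord][seq_len(expected_n)])
  }

  win <- lapply(seq_along(sel), function(i) {
    p <- sel[i]
    # with a known line position the window may not leave that line's
    # membrane region; otherwise it may grow until the boundary level
    lo_lim <- if (is.null(reference_rows)) 1L else
      max(1L, as.integer(round(reference_rows[i])) - as.integer(search_halfwidth))
    hi_lim <- if (is.null(reference_rows)) n else
      min(n, as.integer(round(reference_rows[i])) + as.integer(search_halfwidth))
    level <- bg + boundary_fraction * (s[p] - bg)
    start <- p
    while (start > lo_lim && s[start - 1L] >= level && s[start - 1L] <= s[start]) {
      start <- start - 1L
    }
    end <- p
    while (end < hi_lim && s[end + 1L] >= level && s[end + 1L] <= s[end]) {
      end <- end + 1L
    }
    c(start, end)
  })
  starts <- vapply(win, `[`, integer(1), 1L)
  ends <- vapply(win, `[`, integer(1), 2L)
  # enforce disjoint windows: split overlapping neighbours between the peaks
  if (expected_n > 1L) {
    for (i in seq_len(expected_n - 1L)) {
      if (ends[i] >= starts[i + 1L]) {
        mid <- (sel[i] + sel[i + 1L]) %/% 2L
        ends[i] <- mid
        starts[i + 1L] <- mid + 1L
      }
    }
  }
  if (is.null(band_kinds)) {
    band_kinds <- c(rep("test", expected_n - 1L), "control")
    if (expected_n == 1L) band_kinds <- "test"
  }
  if (length(band_kinds) != expected_n ||
      !all(band_kinds %in% c("test", "control", "unknown"))) {
    lfa_usage_error("band_kinds must give one of test/control/unknown per band")
  }
  data.frame(band_index = seq_len(expected_n), start = starts, end = ends,
             peak_row = sel, kind = band_kinds, stringsAsFactors = FALSE)
}

#' Measure one band: Otsu-background-corrected AUC
#'
#' Otsu's threshold is computed over the pixels of the band window plus a
#' flanking margin (default twice the window length on each side, clipped to
#' the lane), so a bright control line cannot corrupt a faint test line's
#' background estimate. The background level is the mean of the sub-threshold
#' pixels of the flanking margin - the bare membrane next to the band; pixels
#' inside the window are excluded because the band's own tails would inflate
#' the estimate. The corrected AUC sums the positive part of
#' (profile - background) over the window. Negative residuals are floored
#' at zero so noise around background cannot cancel genuine signal.
#'
#' @param lane A [raster_image] of a single strip.
#' @param window One row of a [locate_bands()] result (or any list with
#'   `start`, `end`, `band_index`, `kind`).
#' @param margin_factor Flanking margin as a multiple of the window length
#'   (default 2).
#' @param lane_id Identifier for the output record.
#' @param exclude_rows Rows to drop from the background context, typically
#'   the other bands' windows: a neighbouring line's shoulder would
#'   otherwise contaminate the membrane background estimate.
#'   [quantify_image()] passes the sibling windows automatically.
#' @return A one-row data.frame: `lane_id`, `band_index`, `kind`, `channel`,
#'   `raw_auc`, `background_level`, `corrected_auc`, `saturated`.
#' @export
measure_band <- function(lane, window, margin_factor = 2,
                         lane_id = lane$source_id, exclude_rows = NULL) {
  stopifnot(inherits(lane, "raster_image"))
  nr <- nrow(lane$pixels)
  start <- as.integer(window$start); end <- as.integer(window$end)
  if (start < 1L || end > nr || start > end) {
    lfa_geometry_error(sprintf("band window %d..%d outside lane rows 1..%d",
                               start, end, nr))
  }
  len <- end - start + 1L
  margin <- as.integer(ceiling(margin_factor * len))
  ctx_start <- max(1L, start - margin)
  ctx_end <- min(nr, end + margin)
  ctx_rows <- setdiff(ctx_start:ctx_end, setdiff(exclude_rows, start:end))
  ctx_pixels <- lane$pixels[ctx_rows, , drop = FALSE]
  flank_pixels <- lane$pixels[setdiff(ctx_rows, start:end), , drop = FALSE]

  background <- tryCatch({
    thr <- otsu_threshold(ctx_pixels)
    sub <- flank_pixels[flank_pixels < thr]
    if (length(sub) == 0L) sub <- ctx_pixels[ctx_pixels < thr]
    if (length(sub) == 0L) mean(ctx_pixels) else mean(sub)
  }, lfa_degenerate_input = function(e) {
    lfa_warn(sprintf(
      "uniform pixel context for band %s in lane '%s'; whole window treated as background",
      window$band_index, lane_id), "lfa_degenerate_background")
    mean(ctx_pixels)
  })

  prof <- rowMeans(lane$pixels[start:end, , drop = FALSE])
  raw_auc <- sum(prof)
  corrected <- sum(pmax(prof - background, 0))
  saturated <- any(lane$pixels[start:end, ] == image_max_value(lane))

  data.frame(lane_id = lane_id,
             band_index = as.integer(window$band_index),
             kind = as.character(window$kind),
             channel = lane$channel_label,
             raw_auc = raw_auc,
             background_level = background,
             corrected_auc = corrected,
             saturated = saturated,
             stringsAsFactors = FALSE)
}

#' Quantify all bands of all lanes in one image
#'
#' Runs crop (optional), lane splitting, profile extraction, band
#' localisation and band measurement over one channel image.
#'
#' @param image A [raster_image].
#' @param n_lanes Number of strips in the image.
#' @param expected_n Bands per lane (1..6).
#' @param region Optional [crop_region] applied first.
#' @param image_id Identifier written to the output (default: source basename).
#' @param ... Passed to [locate_bands()] and [measure_band()]
#'   (`min_prominence`, `smoothing_window`, `boundary_fraction`,
#'   `band_kinds`, `margin_factor`).
#' @return A data.frame with one row per (lane, band): columns `image_id`,
#'   `lane_id`, `band_index`, `kind`, `channel`, `raw_auc`,
#'   `background_level`, `corrected_auc`, `saturated`.
#' @export
quantify_image <- function(image, n_lanes, expected_n, region = NULL,
                           image_id = basename(image$source_id), ...) {
  stopifnot(inherits(image, "raster_image"))
  dots <- list(...)
  locate_args <- dots[names(dots) %in%
    c("min_prominence", "smoothing_window", "boundary_fraction", "band_kinds",
      "reference_rows", "search_halfwidth")]
  measure_args <- dots[names(dots) %in% "margin_factor"]
  if (!is.null(region)) image <- crop_image(image, region)
  lanes <- split_lanes(image, n_lanes)
  out <- lapply(seq_along(lanes), function(k) {
    lane <- lanes[[k]]
    lane_id <- sprintf("lane_%d", k)
    prof <- lane_profile(lane, lane_id = lane_id)
    bands <- do.call(locate_bands,
                     c(list(profile = prof, expected_n = expected_n),
                       locate_args))
    rows <- lapply(seq_len(nrow(bands)), function(i) {
      siblings <- unlist(lapply(setdiff(seq_len(nrow(bands)), i), function(j) {
        bands$start[j]:bands$end[j]
      }))
      do.call(measure_band,
              c(list(lane = lane, window = bands[i, ], lane_id = lane_id,
                     exclude_rows = siblings),
                measure_args))
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  res <- cbind(image_id = image_id, res, stringsAsFactors = FALSE)
  if (any(res$saturated)) {
    lfa_warn(sprintf(
      "%d band(s) in image '%s' contain saturated pixels; their AUCs are biased (flat-topped peaks)",
      sum(res$saturated), image_id), "lfa_saturation_warning")
  }
  res
}

#' Write band measurements to CSV
#'
#' @param measurements Data.frame from [quantify_image()] (rows from several
#'   images may be concatenated).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
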