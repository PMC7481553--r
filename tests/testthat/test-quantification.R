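test_that("cropping extracts the requested block and validates bounds", {
  img <- raster_image(matrix(1:16, 4, 4), 8L)
  whole <- crop_image(img, crop_region(1, 1, 4, 4))
  expect_identical(whole$pixels, img$pixels)

  centre <- crop_image(img, crop_region(2, 2, 2, 2))
  expect_identical(centre$pixels, img$pixels[2:3, 2:3])

  expect_error(crop_image(img, crop_region(1, 4, 2, 2)),
               class = "lfa_geometry_error")
})

test_that("lane splitting tiles the image with remainder columns to the left", {
  img10 <- raster_image(matrix(0L, 4, 10), 8L)
  lanes <- split_lanes(img10, 2)
  expect_equal(vapply(lanes, function(l) ncol(l$pixels), integer(1)), c(5L, 5L))

  img9 <- raster_image(matrix(seq_len(36), 4, 9), 8L)
  lanes9 <- split_lanes(img9, 2)
  expect_equal(vapply(lanes9, function(l) ncol(l$pixels), integer(1)), c(5L, 4L))
  expect_identical(cbind(lanes9[[1]]$pixels, lanes9[[2]]$pixels), img9$pixels)

  expect_identical(split_lanes(img9, 1)[[1]]$pixels, img9$pixels)
  expect_error(split_lanes(img9, 10), class = "lfa_usage_error")
})

test_that("lane splitting reconstructs arbitrary images exactly", {
  set.seed(7)
  for (i in 1:10) {
    w <- sample(5:40, 1)
    n <- sample(1:min(6, w), 1)
    img <- raster_image(matrix(sample(0:255, 8 * w, TRUE), 8, w), 8L)
    lanes <- split_lanes(img, n)
    widths <- vapply(lanes, function(l) ncol(l$pixels), integer(1))
    expect_lte(diff(range(widths)), 1L)
    expect_identical(do.call(cbind, lapply(lanes, `[[`, "pixels")), img$pixels)
  }
})

test_that("lane profiles are per-row pixel means", {
  expect_equal(lane_profile(raster_image(matrix(5L, 3, 4), 8L))$values,
               rep(5, 3))
  lane <- raster_image(matrix(c(0L, 4L, 2L, 6L), 2, 2), 8L)
  expect_equal(lane_profile(lane)$values, c(1, 5))
  col <- raster_image(matrix(c(3L, 9L, 27L), 3, 1), 8L)
  expect_equal(lane_profile(col)$values, c(3, 9, 27))
})

test_that("otsu_threshold matches the stated examples and rejects uniform input", {
  expect_identical(otsu_threshold(c(0, 0, 0, 0, 10, 10, 10, 10)), 10L)
  expect_identical(otsu_threshold(c(1, 1, 1, 9)), 9L)
  expect_error(otsu_threshold(c(5, 5, 5, 5)), class = "lfa_degenerate_input")
})

test_that("otsu_threshold agrees with the exhaustive maximiser on random arrays", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(2:64, 1)
    v <- sample(0:255, n, replace = TRUE)
    if (length(unique(v)) < 2L) v <- c(v, 256L - v[1L])
    expect_identical(otsu_threshold(v), as.integer(brute_force_otsu(v)),
                     info = paste("case", i))
  }
})

test_that("band localisation finds peaks and enforces the six-band limit", {
  tri <- structure(list(values = c(0, 0, 2, 6, 2, 0, 0, 0), lane_id = "l",
                        channel_label = "gray"), class = "intensity_profile")
  b <- locate_bands(tri, 1, smoothing_window = 3)
  expect_equal(nrow(b), 1L)
  expect_true(b$start <= 4 && b$end >= 4)  # contains the peak row

  two <- structure(list(values = c(rep(0, 5), 0, 5, 10, 5, 0, rep(0, 8),
                                   0, 5, 10, 5, 0, rep(0, 5)),
                        lane_id = "l", channel_label = "gray"),
                   class = "intensity_profile")
  b2 <- locate_bands(two, 2, smoothing_window = 3)
  expect_equal(nrow(b2), 2L)
  expect_true(b2$end[1] < b2$start[2])           # disjoint
  expect_true(b2$peak_row[1] < b2$peak_row[2])   # position order
  expect_equal(b2$kind, c("test", "control"))

  expect_error(locate_bands(tri, 7), class = "lfa_usage_error")
  expect_error(locate_bands(tri, 0), class = "lfa_usage_error")
})

test_that("band localisation reports a detection error when peaks are missing", {
  flat_one <- structure(list(values = c(0, 0, 2, 6, 2, 0, 0, 0, 0, 0),
                             lane_id = "l", channel_label = "gray"),
                        class = "intensity_profile")
  expect_error(locate_bands(flat_one, 3, smoothing_window = 3,
                            min_prominence = 1),
               class = "lfa_detection_error")
})

test_that("reference-row guidance pins windows near printed line positions", {
  spec <- strip_spec(height_px = 100, width_px = 20, band_centers = c(30, 70),
                     noise_sd = 40)
  gs <- generate_strip(spec, c(0, 3000), seed = 5)  # blank: no test band
  b <- locate_bands(lane_profile(gs$image), 2, reference_rows = c(30, 70))
  expect_equal(nrow(b), 2L)
  # the control window must sit on the control line, not on a noise bump
  expect_lte(abs(b$peak_row[2] - 70), 3)
  expect_lte(abs(b$peak_row[1] - 30), 10)
  expect_equal(b$kind, c("test", "control"))
})

test_that("measure_band applies Otsu background correction over window + margin", {
  lane <- lane_from_profile(c(0, 0, 4, 8, 4, 0, 0))
  m <- measure_band(lane, list(start = 3, end = 5, band_index = 1,
                               kind = "test"))
  expect_equal(m$background_level, 0)
  expect_equal(m$raw_auc, 16)
  expect_equal(m$corrected_auc, 16)
  expect_false(m$saturated)

  # uniform lane: degenerate Otsu input, whole window is background
  flat <- lane_from_profile(rep(7, 9))
  expect_warning(
    mf <- measure_band(flat, list(start = 4, end = 6, band_index = 1,
                                  kind = "test")),
    class = "lfa_degenerate_background")
  expect_equal(mf$corrected_auc, 0)

  sat <- lane_from_profile(c(0, 0, 100, 255, 100, 0, 0))
  ms <- measure_band(sat, list(start = 3, end = 5, band_index = 1,
                               kind = "test"))
  expect_true(ms$saturated)
})

test_that("corrected AUC is invariant under a constant offset without clipping", {
  spec <- strip_spec(height_px = 80, width_px = 10, band_centers = 40,
                     background_level = 100, noise_sd = 0)
  gs <- generate_strip(spec, 500, seed = 1)
  b <- locate_bands(lane_profile(gs$image), 1)
  m0 <- measure_band(gs$image, b[1, ])

  shifted <- raster_image(gs$image$pixels + 1000L, bit_depth = 16L)
  b1 <- locate_bands(lane_profile(shifted), 1)
  m1 <- measure_band(shifted, b1[1, ])
  expect_equal(m1$corrected_auc, m0$corrected_auc)
})

test_that("corrected AUC grows monotonically with band amplitude", {
  spec <- strip_spec(height_px = 100, width_px = 15, band_centers = 50,
                     background_level = 200, noise_sd = 0)
  aucs <- vapply(c(20, 50, 100, 400, 1500, 5000), function(a) {
    gs <- generate_strip(spec, a, seed = 1)
    b <- locate_bands(lane_profile(gs$image), 1)
    measure_band(gs$image, b[1, ])$corrected_auc
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("quantify_image emits one row per lane and band", {
  spec <- strip_spec(height_px = 90, width_px = 24, band_centers = c(30, 65),
                     noise_sd = 0)
  lane_px <- generate_strip(spec, c(800, 3000), seed = 1)$image$pixels
  batch <- raster_image(cbind(lane_px, lane_px, lane_px), 16L,
                        source_id = "batch.tif")
  res <- quantify_image(batch, n_lanes = 3, expected_n = 2,
                        reference_rows = c(30, 65))
  expect_equal(nrow(res), 6L)
  expect_equal(unique(res$lane_id), c("lane_1", "lane_2", "lane_3"))
  expect_setequal(unique(res$kind), c("test", "control"))
  # identical lanes must give identical measurements
  expect_equal(res$corrected_auc[res$lane_id == "lane_1"],
               res$corrected_auc[res$lane_id == "lane_3"])
})
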