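# Shared fixtures and independent oracles.

# Exhaustive between-class-variance maximiser: tries every distinct value as
# threshold t (foreground = values >= t), computes the between-class variance
# directly from the class definitions, and returns the smallest maximiser.
# Deliberately naive; the package's histogram-cumulant version is checked
# against it.
brute_force_otsu <- function(values) {
  values <- as.numeric(values)
  cand <- sort(unique(values))
  stopifnot(length(cand) >= 2L)
  best_var <- -Inf
  best_t <- NA_real_
  n <- length(values)
  for (t in cand) {
    bg <- values[values < t]
    fg <- values[values >= t]
    if (length(bg) == 0L || length(fg) == 0L) next
    w0 <- length(bg) / n
    w1 <- length(fg) / n
    v <- w0 * w1 * (mean(bg) - mean(fg))^2
    if (v > best_var + 1e-12) {
      best_var <- v
      best_t <- t
    }
  }
  best_t
}

# lane whose rows are constant at the given profile values
lane_from_profile <- function(profile, width = 4L, bit_depth = 8L,
                              channel = "gray") {
  raster_image(matrix(as.integer(round(profile)), nrow = length(profile),
                      ncol = width),
               bit_depth = bit_depth, channel_label = channel,
               source_id = "fixture_lane")
}

# small noisy duplex design used by several tests
small_duplex <- function(seed = 1L, noise_sd = 60, crosstalk = 0,
                         replicates = 3L,
                         concentrations = c(0, 2.5, 5, 10, 20)) {
  duplex_design(concentrations_a = concentrations,
                concentrations_b = concentrations,
                replicates = replicates, crosstalk = crosstalk,
                spec = strip_spec(noise_sd = noise_sd), seed = seed)
}

# quantify every image of a generated experiment in memory
quantify_experiment <- function(ex, channels = c("green", "red")) {
  ids <- names(ex$images)
  ids <- ids[vapply(ids, function(id) ex$images[[id]]$channel_label,
                    character(1)) %in% channels]
  do.call(rbind, lapply(ids, function(id) {
    quantify_image(ex$images[[id]], n_lanes = 1L, expected_n = 2L,
                   image_id = id, reference_rows = ex$band_rows)
  }))
}
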