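# Shared fixtures: small simulated geometries used across test files.

# Default epifluorescence geometry (160 nm pixels, 480 nm FWHM PSF).
test_spec <- function(n_spots = 25L, image_shape_px = c(192L, 192L),
                      seed = 11L, ...) {
  simulation_spec(n_spots = n_spots, image_shape_px = image_shape_px,
                  seed = seed, ...)
}

# Super-resolution calibration geometry: 20 nm pixels, ~31 nm FWHM antibody
# spots, small fitting ROI matched to the spot scale.
sr_calib_config <- function(...) {
  pipeline_config(smoothing_sigma_nm = 13, roi_side_nm = 300,
                  maxima_min_separation_nm = 200, ...)
}

sr_calib_spec <- function(...) {
  simulation_spec(image_shape_px = c(420L, 420L), pixel_size_nm = 20,
                  psf_sigma_nm = 13, background_level = 100,
                  channel_amplitude_means = c(calibration = 300),
                  amplitude_cv = 0.15, min_separation_nm = 400,
                  margin_nm = 200, ...)
}

# Exhaustive, loop-based scan for qualifying local maxima; the independent
# oracle for the vectorised detector.
exhaustive_maxima_scan <- function(raster, r, threshold, border) {
  n1 <- nrow(raster); n2 <- ncol(raster)
  out <- list()
  for (y in seq_len(n1)) {
    for (x in seq_len(n2)) {
      if (y <= border || y > n1 - border || x <= border || x > n2 - border) next
      v <- raster[y, x]
      if (v < threshold) next
      ok <- TRUE
      for (dy in -r:r) {
        for (dx in -r:r) {
          if (dy == 0 && dx == 0) next
          yy <- y + dy; xx <- x + dx
          if (yy < 1 || yy > n1 || xx < 1 || xx > n2) next
          w <- raster[yy, xx]
          later <- dy > 0 || (dy == 0 && dx > 0)
          if (later) {
            if (v < w) { ok <- FALSE; break }
          } else {
            if (v <= w) { ok <- FALSE; break }
          }
        }
        if (!ok) break
      }
      if (ok) out[[length(out) + 1L]] <- c(x = x, y = y, value = v)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(x = integer(), y = integer(), value = numeric()))
  }
  as.data.frame(do.call(rbind, out))
}

# Match detected candidates to planted truth positions within a radius;
# returns indices of matched truth spots (NA when unmatched).
match_to_truth <- function(candidates, truth_xy, radius_px = 2) {
  vapply(seq_len(nrow(candidates)), function(i) {
    d2 <- (truth_xy$x_px - candidates$x_px[i])^2 +
      (truth_xy$y_px - candidates$y_px[i])^2
    j <- which.min(d2)
    if (length(j) == 1L && d2[j] <= radius_px^2) j else NA_integer_
  }, integer(1))
}
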