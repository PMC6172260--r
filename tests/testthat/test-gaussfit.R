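test_that("the 2D Gaussian model evaluates its quadratic form correctly", {
  expect_equal(gaussian2d(3, 5, 3, 5, 2, 1, 0.7, 40, 10), 50) # peak
  # isotropic case is rotation invariant
  for (th in c(0, 0.3, 1.1, 2.9)) {
    expect_equal(gaussian2d(4.2, 6.1, 3, 5, 1.5, 1.5, th, 40, 10),
                 gaussian2d(4.2, 6.1, 3, 5, 1.5, 1.5, 0, 40, 10))
  }
  # one major-axis sigma from the centre: offset + A * exp(-1/2); the
  # quadratic form orients the major axis at angle -theta in (x, y)
  for (th in c(0, 0.4, 1.3)) {
    v <- gaussian2d(3 + 2 * cos(th), 5 - 2 * sin(th), 3, 5, 2, 1, th, 40, 10)
    expect_equal(v, 10 + 40 * exp(-0.5))
  }
  expect_error(gaussian2d(0, 0, 0, 0, -1, 1, 0, 1, 0), "positive")
})

test_that("r_squared follows its sums-of-squares definition", {
  d <- c(1, 2, 3, 4)
  expect_equal(r_squared(d, d), 1)
  expect_equal(r_squared(d, rep(mean(d), 4)), 0)
  expect_equal(r_squared(d, c(1, 2, 3, 5)), 1 - 1 / 5)
  expect_true(is.na(r_squared(rep(2, 4), c(1, 2, 3, 4))))
  expect_error(r_squared(1:4, 1:5), "shapes")
})

test_that("a noiseless spot is recovered to high precision", {
  px <- 160
  cfg <- pipeline_config()
  xs <- matrix(1:31, 31, 31, byrow = TRUE); ys <- matrix(1:31, 31, 31)
  img <- gaussian2d(xs, ys, 16.3, 15.6, 2, 1.4, 0.4, 100, 10)
  field <- image_field(list(img), "poi", px, sample_kind = "calibration")
  cand <- data.frame(x_px = 16L, y_px = 16L, candidate_id = 1L)
  fit <- fit_roi(field, cand, "poi", cfg)
  expect_true(fit$converged)
  expect_equal(fit$x0_px, 16.3, tolerance = 1e-3)
  expect_equal(fit$y0_px, 15.6, tolerance = 1e-3)
  expect_equal(fit$sigma_major_px, 2, tolerance = 1e-3)
  expect_equal(fit$sigma_minor_px, 1.4, tolerance = 1e-3)
  expect_equal(fit$theta_rad, 0.4, tolerance = 1e-3)
  expect_equal(fit$amplitude, 100, tolerance = 1e-3)
  expect_equal(fit$offset, 10, tolerance = 1e-3)
  expect_gte(fit$r2, 0.999999)
  expect_equal(fit$integrated_intensity, 2 * pi * 100 * 2 * 1.4,
               tolerance = 1e-3)
})

test_that("integrated intensity equals the brute-force model volume", {
  # sum the offset-subtracted model over a wide grid (half-width >= 6 sigma)
  for (p in list(c(2, 1.4, 0.4, 100), c(3, 3, 0, 50), c(2.5, 1, 1.2, 250))) {
    n <- ceiling(6 * p[1]) * 2 + 1
    c0 <- (n + 1) / 2
    xs <- matrix(1:n, n, n, byrow = TRUE); ys <- matrix(1:n, n, n)
    vol <- sum(gaussian2d(xs, ys, c0, c0, p[1], p[2], p[3], p[4], 0))
    expect_equal(vol, 2 * pi * p[4] * p[1] * p[2], tolerance = 5e-3)
  }
})

test_that("fits are canonical and robust to shot noise", {
  px <- 160
  cfg <- pipeline_config()
  xs <- matrix(1:31, 31, 31, byrow = TRUE); ys <- matrix(1:31, 31, 31)
  errs <- c(); cent <- c()
  for (seed in 1:5) {
    set.seed(seed)
    clean <- gaussian2d(xs, ys, 16.2, 15.7, 2, 2, 0, 100, 10)
    noisy <- matrix(rpois(length(clean), clean), 31, 31) # peak SNR ~ 10
    field <- image_field(list(noisy), "poi", px, sample_kind = "calibration")
    fit <- fit_roi(field, data.frame(x_px = 16L, y_px = 16L, candidate_id = 1L),
                   "poi", cfg)
    expect_true(fit$converged)
    expect_gte(fit$sigma_major_px, fit$sigma_minor_px)
    expect_true(fit$theta_rad >= 0 && fit$theta_rad < pi)
    cent <- c(cent, sqrt((fit$x0_px - 16.2)^2 + (fit$y0_px - 15.7)^2))
    errs <- c(errs, abs(fit$integrated_intensity - 2 * pi * 100 * 4) /
                (2 * pi * 100 * 4))
  }
  expect_true(all(cent < 0.2))
  expect_true(all(errs < 0.05))
})

test_that("a pure-noise ROI never yields an acceptable fit", {
  set.seed(33)
  img <- matrix(rpois(31 * 31, 100), 31, 31)
  field <- image_field(list(img), "poi", 160, sample_kind = "calibration")
  cfg <- pipeline_config()
  fit <- fit_roi(field, data.frame(x_px = 16L, y_px = 16L, candidate_id = 1L),
                 "poi", cfg)
  expect_true(!fit$converged || fit$r2 < 0.6) # fails the POI threshold
})

test_that("fit_all_channels fits every candidate in every channel", {
  sim <- simulate_field(test_spec(n_spots = 4L, seed = 13L))
  cfg <- pipeline_config()
  det <- find_candidates(sim$field, cfg)
  rec <- fit_all_channels(sim$field, det, cfg)
  expect_identical(nrow(rec), nrow(det$candidates) * 3L)
  expect_setequal(unique(rec$channel_role), c("marker", "active_zone", "poi"))
  # detection from another field is refused
  other <- simulate_field(test_spec(n_spots = 3L, seed = 14L))
  other$field$field_id <- "other"
  expect_error(fit_all_channels(other$field, det, cfg), "different field")
  # out-of-bounds ROI is a precondition violation
  expect_error(
    fit_roi(sim$field, data.frame(x_px = 2L, y_px = 2L, candidate_id = 1L),
            "marker", cfg),
    "out of image bounds")
})

test_that("a marker-only punctum is rejected through its flat POI channel", {
  shape <- c(96L, 96L)
  sigma_px <- 3 / 2.354820045
  set.seed(91)
  marker <- cosiquant:::render_spots(shape, data.frame(x = 48, y = 48), 600,
                                     sigma_px, 100)
  marker <- matrix(rpois(length(marker), marker), shape[1], shape[2])
  flat <- matrix(rpois(prod(shape), 100), shape[1], shape[2])
  az <- cosiquant:::render_spots(shape, data.frame(x = 48, y = 48), 500,
                                 sigma_px, 100)
  az <- matrix(rpois(length(az), az), shape[1], shape[2])
  field <- image_field(list(marker, az, flat),
                       c("marker", "active_zone", "poi"), 160)
  cfg <- pipeline_config()
  det <- find_candidates(field, cfg)
  expect_identical(nrow(det$candidates), 1L)
  rec <- filter_records(fit_all_channels(field, det, cfg), cfg)
  expect_false(any(rec$accepted))
  expect_match(rec$reject_reason[1], "poi")
})
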