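test_that("gaussian smoothing matches the closed-form kernel and conserves mass", {
  delta <- matrix(0, 33, 33); delta[17, 17] <- 1
  sm <- gaussian_smooth(delta, 3)
  # discrete normalised kernel's centre weight approximates 1/(2*pi*sigma^2)
  expect_equal(sm[17, 17], 1 / (2 * pi * 9), tolerance = 5e-3)
  expect_equal(sm, t(sm), tolerance = 1e-12)          # symmetric response
  expect_equal(sm[17, 20], sm[17, 14], tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-6)          # interior spot conserved

  const <- matrix(7.5, 20, 20)
  expect_equal(gaussian_smooth(const, 2.5), const, tolerance = 1e-9)
  expect_error(gaussian_smooth(const, 0), "positive")
})

test_that("robust threshold is median + k * 1.4826 * MAD", {
  expect_equal(robust_threshold(matrix(4, 10, 10), 5), 4)
  lone <- matrix(0, 20, 20); lone[10, 10] <- 100
  expect_equal(robust_threshold(lone, 5), 0) # MAD of near-constant background
  set.seed(402)
  x <- matrix(rnorm(1e6, 10, 2), 1000, 1000)
  expect_equal(robust_threshold(x, 3), 10 + 3 * 2, tolerance = 0.02)
})

test_that("planted bright spots are found, dim and border spots excluded", {
  shape <- c(128L, 128L)
  sigma_px <- 480 / (2 * sqrt(2 * log(2))) / 160
  pos <- data.frame(x = c(30, 70, 100, 50), y = c(40, 90, 30, 60))
  amps <- c(500, 600, 550, 20) # last spot far below the robust threshold
  img <- cosiquant:::render_spots(shape, pos, amps, sigma_px, background = 100)
  set.seed(77)
  img <- matrix(rpois(length(img), img), shape[1], shape[2])
  field <- image_field(list(img), "marker", 160, sample_kind = "synaptosome")
  cfg <- pipeline_config()
  det <- find_candidates(field, cfg)
  expect_identical(nrow(det$candidates), 3L)
  m <- match_to_truth(det$candidates,
                      data.frame(x_px = pos$x[1:3], y_px = pos$y[1:3]),
                      radius_px = 1)
  expect_true(all(!is.na(m)) && !anyDuplicated(m))
  expect_true(all(det$candidates$smoothed_peak >= det$threshold_used))

  # vectorised detector agrees with the exhaustive pixel-scan oracle
  sm <- gaussian_smooth(img, det$sigma_px)
  oracle <- exhaustive_maxima_scan(sm, r = 3, det$threshold_used, border = 7)
  expect_identical(nrow(oracle), 3L)
  expect_setequal(paste(oracle$x, oracle$y),
                  paste(det$candidates$x_px, det$candidates$y_px))

  # a spot whose ROI would not fit inside the image is excluded
  img2 <- cosiquant:::render_spots(shape, data.frame(x = 3, y = 64), 500,
                                   sigma_px, background = 100)
  set.seed(78)
  img2 <- matrix(rpois(length(img2), img2), shape[1], shape[2])
  det2 <- find_candidates(image_field(list(img2), "marker", 160), cfg)
  expect_identical(nrow(det2$candidates), 0L)
})

test_that("all-background and too-small fields yield no candidates", {
  cfg <- pipeline_config()
  zero <- image_field(list(matrix(0, 128, 128)), "marker", 160)
  expect_identical(nrow(find_candidates(zero, cfg)$candidates), 0L)
  tiny <- image_field(list(matrix(1, 8, 8)), "marker", 160)
  expect_warning(det <- find_candidates(tiny, cfg), "smaller than the ROI")
  expect_identical(nrow(det$candidates), 0L)
})

test_that("raising the threshold never increases the candidate count", {
  sim <- simulate_field(test_spec(seed = 21L))
  field <- sim$field
  last <- Inf
  for (thr in c(100, 120, 150, 200, 400, 1000)) {
    cfg <- pipeline_config(detect_threshold_mode = "absolute",
                           detect_threshold_value = thr)
    n <- nrow(find_candidates(field, cfg)$candidates)
    expect_lte(n, last)
    last <- n
  }
})

test_that("candidates are equivariant under whole-pixel translation", {
  shape <- c(128L, 128L)
  sigma_px <- 3 / 2.354820045
  pos <- data.frame(x = c(40, 80), y = c(50, 70))
  img <- cosiquant:::render_spots(shape, pos, c(500, 650), sigma_px, 100)
  shift <- function(m, d) {
    out <- matrix(100, nrow(m), ncol(m))
    out[(1 + d):nrow(m), (1 + d):ncol(m)] <-
      m[1:(nrow(m) - d), 1:(ncol(m) - d)]
    out
  }
  cfg <- pipeline_config(detect_threshold_mode = "absolute",
                         detect_threshold_value = 120)
  d0 <- find_candidates(image_field(list(img), "marker", 160), cfg)$candidates
  d5 <- find_candidates(image_field(list(shift(img, 5)), "marker", 160),
                        cfg)$candidates
  expect_identical(nrow(d0), nrow(d5))
  expect_setequal(paste(d0$x_px + 5, d0$y_px + 5), paste(d5$x_px, d5$y_px))
})

test_that("detection recall is >= 0.95 with no false positives at high SNR", {
  # well-separated spots, SNR >= 5, robust threshold at k = 5
  recalls <- c()
  for (seed in c(5L, 6L, 7L)) {
    spec <- test_spec(n_spots = 20L, seed = seed, amplitude_cv = 0.2,
                      image_shape_px = c(256L, 256L))
    sim <- simulate_field(spec)
    det <- find_candidates(sim$field, pipeline_config())
    truth <- sim$truth[sim$truth$role == "marker", ]
    m <- match_to_truth(det$candidates, truth, radius_px = 2)
    expect_identical(sum(is.na(m)), 0L) # no false positives
    recalls <- c(recalls, length(unique(m[!is.na(m)])) / nrow(truth))
  }
  expect_true(all(recalls >= 0.95))
})
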