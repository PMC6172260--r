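# Build a records table with prescribed per-channel R2 values.
records_with_r2 <- function(r2_triples) {
  roles <- c("marker", "active_zone", "poi")
  rows <- lapply(seq_len(nrow(r2_triples)), function(i) {
    data.frame(field_id = "f", candidate_id = i, channel_role = roles,
               x0_px = 10, y0_px = 10, x0_nm = 1520, y0_nm = 1520,
               sigma_major_px = 2, sigma_minor_px = 1.5, theta_rad = 0.1,
               amplitude = 100, offset = 5,
               integrated_intensity = 2 * pi * 100 * 3,
               r2 = as.numeric(r2_triples[i, ]), converged = TRUE,
               accepted = NA, reject_reason = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

accepted_flags <- function(rec) {
  rec$accepted[rec$channel_role == "marker"]
}

test_that("R2 filtering applies the inclusive 0.85/0.70/0.60 thresholds", {
  cfg <- pipeline_config()
  rec <- records_with_r2(rbind(c(0.90, 0.75, 0.65),
                               c(0.84, 0.99, 0.99),
                               c(0.85, 0.70, 0.60),
                               c(0.99, 0.69, 0.99),
                               c(0.99, 0.99, 0.59)))
  out <- filter_records(rec, cfg)
  expect_identical(accepted_flags(out), c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(out$reject_reason[out$candidate_id == 2][1], "marker")
  expect_identical(out$reject_reason[out$candidate_id == 4][1], "active_zone")
  expect_identical(out$reject_reason[out$candidate_id == 5][1], "poi")
  # a non-converged fit always rejects, naming its channel
  rec2 <- records_with_r2(rbind(c(0.99, 0.99, 0.99)))
  rec2$converged[rec2$channel_role == "poi"] <- FALSE
  out2 <- filter_records(rec2, cfg)
  expect_false(any(out2$accepted))
  expect_identical(out2$reject_reason[1], "poi")
})

test_that("random R2 triples match a direct predicate oracle", {
  cfg <- pipeline_config()
  set.seed(71)
  triples <- matrix(runif(3 * 400, 0.4, 1), ncol = 3)
  out <- filter_records(records_with_r2(triples), cfg)
  oracle <- triples[, 1] >= 0.85 & triples[, 2] >= 0.70 & triples[, 3] >= 0.60
  expect_identical(accepted_flags(out), unname(oracle))
})

test_that("tightening any threshold never increases the accepted count", {
  set.seed(72)
  triples <- matrix(runif(3 * 200, 0.4, 1), ncol = 3)
  rec <- records_with_r2(triples)
  base <- sum(accepted_flags(filter_records(rec, pipeline_config())))
  for (role in c("marker", "active_zone", "poi")) {
    thr <- c(marker = 0.85, active_zone = 0.70, poi = 0.60)
    thr[role] <- thr[role] + 0.1
    n <- sum(accepted_flags(filter_records(rec, pipeline_config(r2_thresholds = thr))))
    expect_lte(n, base)
  }
})

test_that("mean_sem computes the sample-sd SEM", {
  expect_equal(unname(mean_sem(c(5, 5, 5, 5))[1:2]), c(5, 0))
  ms <- mean_sem(c(1, 2, 3))
  expect_equal(ms[["mean"]], 2)
  expect_equal(ms[["sem"]], 1 / sqrt(3), tolerance = 1e-12) # sd = 1
  expect_true(is.na(mean_sem(4)[["sem"]]))
  expect_error(mean_sem(numeric()), "non-empty")
})

test_that("the 30 vesicle reconstruction counts summarise to 250 +/- 26", {
  ms <- mean_sem(em_vesicle_counts)
  expect_identical(round(ms[["mean"]]), 250)
  expect_identical(round(ms[["sem"]]), 26)
  expect_identical(ms[["n"]], 30)
})

test_that("copy-number interpolation is the intensity ratio times the reference", {
  syn <- c(80, 100, 120)
  est <- estimate_copy_numbers(rep(mean(syn), 4), syn, 1000)
  expect_equal(est$mean_copies, 1000)
  expect_equal(est$per_synapse_copies, rep(1000, 4))

  # a single synapse at half the synaptosome mean, Synapsin1/2 reference
  est2 <- estimate_copy_numbers(50, c(100, 100), 23422.77)
  expect_equal(est2$per_synapse_copies, 11711.385)

  expect_error(estimate_copy_numbers(numeric(), 1:3, 10), "non-empty")
  expect_error(estimate_copy_numbers(1:3, c(-2, 2, 0), 10), "positive")
  expect_error(estimate_copy_numbers(1:3, 1:3, -5), "positive")
})

test_that("copy-number estimates are invariant to a common intensity scale", {
  set.seed(5)
  syn <- rlnorm(50, 5, 0.4); cult <- rlnorm(40, 4.8, 0.4)
  a <- estimate_copy_numbers(cult, syn, 23422.77)
  b <- estimate_copy_numbers(cult * 37.5, syn * 37.5, 23422.77)
  expect_equal(b$mean_copies, a$mean_copies)
  expect_equal(b$sem_copies, a$sem_copies)
  expect_equal(b$per_synapse_copies, a$per_synapse_copies)
})

test_that("intensities divide into antibody counts", {
  expect_equal(antibodies_per_structure(250, 250), 1)
  expect_equal(antibodies_per_structure(750, 250), 3)
  expect_equal(antibodies_per_structure(c(0, 0), 250), c(0, 0))
  expect_error(antibodies_per_structure(1, 0), "positive")
})

test_that("measured-vs-estimated regression recovers slope and R2", {
  x <- 1:5
  same <- compare_measured_vs_estimated(x, x)
  expect_equal(same$slope, 1); expect_equal(same$r2, 1)
  twice <- compare_measured_vs_estimated(2 * x, x)
  expect_equal(twice$slope, 2); expect_equal(twice$r2, 1)
  set.seed(8)
  xx <- runif(100, 1, 10)
  yy <- 1.3 * xx + rnorm(100, 0, 0.1)
  fit <- compare_measured_vs_estimated(yy, xx)
  expect_equal(fit$slope, 1.3, tolerance = 0.02)
  expect_gt(fit$r2, 0.99)
  expect_error(compare_measured_vs_estimated(1:3, 1:4), "length mismatch")
})

test_that("intensity summaries report SEM over accepted candidates", {
  rec <- records_with_r2(rbind(c(0.9, 0.8, 0.7), c(0.95, 0.9, 0.8),
                               c(0.5, 0.9, 0.9)))
  rec$integrated_intensity <- rep(c(100, 200, 999), each = 1, times = 1)[
    rep(1:3, each = 3)]
  out <- summarize_intensities(filter_records(rec, pipeline_config()), "synaptosome")
  poi <- out[out$role == "poi", ]
  expect_identical(poi$n, 2L) # third candidate rejected on the marker
  expect_equal(poi$mean_intensity, 150)
  expect_equal(poi$sem_intensity, sd(c(100, 200)) / sqrt(2))
})
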