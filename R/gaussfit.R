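#' Rotated elliptical 2D Gaussian with offset
#'
#' The punctum model fitted to every candidate in every channel:
#' `offset + amplitude * exp(-(a*(x-x0)^2 + 2*b*(x-x0)*(y-y0) + c*(y-y0)^2))`
#' with
#' `a = cos^2(theta)/(2*s1^2) + sin^2(theta)/(2*s2^2)`,
#' `b = -sin(2*theta)/(4*s1^2) + sin(2*theta)/(4*s2^2)`,
#' `c = sin^2(theta)/(2*s1^2) + cos^2(theta)/(2*s2^2)`.
#' The volume under the peak above the offset is
#' `2 * pi * amplitude * sigma1 * sigma2`, the "integrated intensity" used as
#' the punctum's signal measure. With these coefficients the `sigma1` (major)
#' axis lies along the direction `(cos(-theta), sin(-theta))` in `(x, y)`.
#'
#' @param x,y coordinates (vectorised).
#' @param x0,y0 centre.
#' @param sigma1,sigma2 spreads along the rotated axes (> 0).
#' @param theta orientation in radians.
#' @param amplitude peak height above the offset.
#' @param offset constant background term.
#' @return model values at `(x, y)`.
#' @export
gaussian2d <- function(x, y, x0, y0, sigma1, sigma2, theta, amplitude, offset) {
  if (any(sigma1 <= 0) || any(sigma2 <= 0)) {
    stop("gaussian2d(): sigmas must be positive", call. = FALSE)
  }
  ct2 <- cos(theta)^2; st2 <- sin(theta)^2; s2t <- sin(2 * theta)
  a <- ct2 / (2 * sigma1^2) + st2 / (2 * sigma2^2)
  b <- -s2t / (4 * sigma1^2) + s2t / (4 * sigma2^2)
  cc <- st2 / (2 * sigma1^2) + ct2 / (2 * sigma2^2)
  dx <- x - x0; dy <- y - y0
  offset + amplitude * exp(-(a * dx^2 + 2 * b * dx * dy + cc * dy^2))
}

#' Coefficient of determination between data and model
#'
#' `1 - SS_res / SS_tot` over the region-of-interest pixels. Used as the
#' goodness-of-fit measure that decides whether a candidate is kept. Data
#' with zero variance make the statistic undefined; `NA` is returned and the
#' fit is treated as failed downstream.
#'
#' @param data,model numeric arrays of equal shape.
#' @return a scalar `<= 1`, or `NA` if the data have no variance.
#' @export
r_squared <- function(data, model) {
  if (!identical(dim(data), dim(model)) || length(data) != length(model)) {
    stop("r_squared(): shapes differ", call. = FALSE)
  }
  ss_tot <- sum((data - mean(data))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((data - model)^2) / ss_tot
}

# Initial spread/orientation guesses from the intensity-weighted covariance
# of the median-subtracted ROI. The model's quadratic form orients the major
# axis at angle -theta in (x, y), hence the negated eigenvector angle.
roi_moments <- function(roi, grid_x, grid_y, lo, hi) {
  w <- pmax(roi - median(roi), 0)
  tot <- sum(w)
  if (tot <= 0) return(NULL)
  mx <- sum(w * grid_x) / tot; my <- sum(w * grid_y) / tot
  cxx <- sum(w * (grid_x - mx)^2) / tot
  cyy <- sum(w * (grid_y - my)^2) / tot
  cxy <- sum(w * (grid_x - mx) * (grid_y - my)) / tot
  ev <- tryCatch(eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE),
                 error = function(e) NULL)
  if (is.null(ev) || any(ev$values <= 0)) return(NULL)
  theta <- -atan2(ev$vectors[2, 1], ev$vectors[1, 1])
  # equivalent angle mod pi, centred on zero: starts near +/-pi converge
  # poorly even though they parameterise the same model
  theta <- ((theta + pi / 2) %% pi) - pi / 2
  list(s1 = min(max(sqrt(ev$values[1]), lo), hi),
       s2 = min(max(sqrt(ev$values[2]), lo), hi),
       theta = theta, cx = mx, cy = my)
}

# Canonical form: sigma_major >= sigma_minor, theta in [0, pi).
canonicalize_fit <- function(s1, s2, theta) {
  if (s2 > s1) {
    tmp <- s1; s1 <- s2; s2 <- tmp
    theta <- theta + pi / 2
  }
  theta <- theta %% pi
  list(sigma_major = s1, sigma_minor = s2, theta = theta)
}

# (sigma1, sigma2, theta) -> exponent quadratic-form coefficients (a, b, c).
shape_to_abc <- function(s1, s2, theta) {
  ct2 <- cos(theta)^2; st2 <- sin(theta)^2; s2t <- sin(2 * theta)
  c(ct2 / (2 * s1^2) + st2 / (2 * s2^2),
    -s2t / (4 * s1^2) + s2t / (4 * s2^2),
    st2 / (2 * s1^2) + ct2 / (2 * s2^2))
}

# Inverse map: eigen-decompose [[a, b], [b, c]] (positive definite for a real
# ellipse) into canonical sigma_major >= sigma_minor and theta in [0, pi).
abc_to_shape <- function(a, b, cc) {
  m <- matrix(c(a, b, b, cc), 2)
  ev <- tryCatch(eigen(m, symmetric = TRUE), error = function(e) NULL)
  if (is.null(ev) || any(ev$values <= 0)) return(NULL)
  # largest eigenvalue = narrowest axis; its perpendicular is the major axis
  s_minor <- 1 / sqrt(2 * ev$values[1])
  s_major <- 1 / sqrt(2 * ev$values[2])
  v <- ev$vectors[, 2] # major-axis direction, at angle -theta in (x, y)
  can <- canonicalize_fit(s_major, s_minor, -atan2(v[2], v[1]))
  can
}

failed_fit_row <- function(field, candidate, role) {
  data.frame(field_id = field$field_id, candidate_id = candidate$candidate_id,
             channel_role = role, x0_px = NA_real_, y0_px = NA_real_,
             x0_nm = NA_real_, y0_nm = NA_real_, sigma_major_px = NA_real_,
             sigma_minor_px = NA_real_, theta_rad = NA_real_,
             amplitude = NA_real_, offset = NA_real_,
             integrated_intensity = NA_real_, r2 = -Inf, converged = FALSE,
             accepted = NA, reject_reason = "", stringsAsFactors = FALSE)
}

#' Fit one candidate in one channel
#'
#' Extracts the square region of interest (side `roi_side_nm`, default
#' 2.2 um) around the candidate from the raw (unsmoothed) channel and fits
#' the [gaussian2d()] model by bounded Levenberg-Marquardt least squares.
#' Initialisation: centre at the candidate position, offset at the ROI
#' minimum, amplitude at ROI max minus offset, isotropic sigma at the
#' detection smoothing sigma, theta 0. Bounds keep the centre inside the ROI,
#' the sigmas in `[0.5 px, ROI side / 2]` and the amplitude non-negative, so
#' noise cannot be "fitted" with a degenerate, enormous Gaussian.
#'
#' @param field an [image_field()].
#' @param candidate one-row data frame (or list) with `x_px`, `y_px`,
#'   `candidate_id`.
#' @param role channel role to fit.
#' @param config a [pipeline_config()].
#' @return one-row records data frame (see [write_records()]); a fit that did
#'   not converge carries `converged = FALSE` and `r2 = -Inf` so it can never
#'   pass the acceptance filter.
#' @export
fit_roi <- function(field, candidate, role, config) {
  stopifnot(inherits(field, "image_field"), inherits(config, "pipeline_config"))
  px <- field$pixel_size_nm
  half <- roi_half_px(config, px)
  ch <- get_channel(field, role)
  cx <- as.integer(candidate$x_px); cy <- as.integer(candidate$y_px)
  if (cx - half < 1L || cx + half > ncol(ch) ||
      cy - half < 1L || cy + half > nrow(ch)) {
    stop("fit_roi(): ROI out of image bounds; detection should have excluded this candidate",
         call. = FALSE)
  }
  xs <- (cx - half):(cx + half)
  ys <- (cy - half):(cy + half)
  roi <- ch[ys, xs, drop = FALSE]
  grid_x <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  grid_y <- matrix(ys, nrow = length(ys), ncol = length(xs))
  dat <- as.vector(roi)
  if (max(dat) == min(dat)) return(failed_fit_row(field, candidate, role))

  side_px <- 2 * half + 1
  sig_lo <- 0.5; sig_hi <- side_px / 2
  sigma0 <- min(max(0.6, nm_to_px(config$smoothing_sigma_nm, px)), sig_hi - 0.1)
  # The ellipse is fitted through the quadratic-form coefficients (a, b, c) of
  # the exponent rather than (sigma1, sigma2, theta): the angle parameter is
  # degenerate for near-isotropic spots and its periodicity strands the
  # optimiser in local minima. Spread/orientation starts come from the
  # intensity-weighted covariance moments of the median-subtracted ROI.
  mom <- roi_moments(roi, grid_x, grid_y, lo = 0.6, hi = sig_hi - 0.1)
  abc0 <- if (is.null(mom)) {
    c(1 / (2 * sigma0^2), 0, 1 / (2 * sigma0^2))
  } else {
    shape_to_abc(mom$s1, mom$s2, mom$theta)
  }
  # box bounds on a and c are the sigma bounds of the axis-aligned widths
  q_lo <- 1 / (2 * sig_hi^2); q_hi <- 1 / (2 * sig_lo^2)
  lower <- c(min(xs), min(ys), q_lo, -q_hi, q_lo, 0, -Inf)
  upper <- c(max(xs), max(ys), q_hi, q_hi, q_hi, Inf, Inf)
  resid_fn <- function(p) {
    dx <- grid_x - p[1]; dy <- grid_y - p[2]
    as.vector(p[7] + p[6] * exp(-(p[3] * dx^2 + 2 * p[4] * dx * dy +
                                    p[5] * dy^2))) - dat
  }
  iso0 <- 1 / (2 * sigma0^2)
  starts <- list(
    c(x0 = cx, y0 = cy, a = abc0[1], b = abc0[2], cc = abc0[3],
      A = max(dat) - min(dat), off = min(dat)),
    # fallback: intensity centroid with an isotropic shape
    c(x0 = if (is.null(mom)) cx else min(max(mom$cx, min(xs)), max(xs)),
      y0 = if (is.null(mom)) cy else min(max(mom$cy, min(ys)), max(ys)),
      a = iso0, b = 0, cc = iso0, A = max(dat) - min(dat), off = min(dat)))
  p <- NULL; can <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || !(fit$info %in% 1:4)) next
    pp <- coef(fit)
    shape <- abc_to_shape(pp[["a"]], pp[["b"]], pp[["cc"]])
    if (is.null(shape) || pp[["A"]] <= 0 ||
        shape$sigma_minor < sig_lo * 0.9 || shape$sigma_major > sig_hi * 1.5) {
      next # degenerate ellipse or vanished amplitude
    }
    p <- pp; can <- shape
    break
  }
  if (is.null(p)) return(failed_fit_row(field, candidate, role))
  model <- gaussian2d(grid_x, grid_y, p[["x0"]], p[["y0"]],
                      can$sigma_major, can$sigma_minor, can$theta,
                      p[["A"]], p[["off"]])
  r2 <- r_squared(roi, model)
  if (is.na(r2)) return(failed_fit_row(field, candidate, role))
  data.frame(field_id = field$field_id, candidate_id = candidate$candidate_id,
             channel_role = role,
             x0_px = p[["x0"]], y0_px = p[["y0"]],
             x0_nm = (p[["x0"]] - 0.5) * px, y0_nm = (p[["y0"]] - 0.5) * px,
             sigma_major_px = can$sigma_major, sigma_minor_px = can$sigma_minor,
             theta_rad = can$theta, amplitude = p[["A"]], offset = p[["off"]],
             integrated_intensity = 2 * pi * p[["A"]] * can$sigma_major * can$sigma_minor,
             r2 = r2, converged = TRUE, accepted = NA, reject_reason = "",
             stringsAsFactors = FALSE)
}

#' Fit all candidates in all channels of a field
#'
#' Stage 2 of the pipeline: goes back to the raw (unfiltered) channels and
#' fits position, size, orientation, amplitude and offset for every candidate
#' in every channel, using the detected position as the initial centre guess.
#' Each channel is fitted independently with the single-spot model; crowded
#' or compound puncta are expected to fail the later R-squared filter rather
#' than being split here.
#'
#' @param field an [image_field()].
#' @param detection a `detection_result` from [find_candidates()] on the same
#'   field.
#' @param config a [pipeline_config()].
#' @param roles channel roles to fit; defaults to all channels of the field.
#' @return records data frame, one row per (candidate, channel), with the
#'   `accepted` flag unset (filtering is a separate stage).
#' @export
fit_all_channels <- function(field, detection, config,
                             roles = field$channel_roles) {
  stopifnot(inherits(detection, "detection_result"))
  cand <- detection$candidates
  if (nrow(cand) > 0L && !all(cand$field_id == field$field_id)) {
    stop("fit_all_channels(): detection was produced on a different field",
         call. = FALSE)
  }
  if (nrow(cand) == 0L) return(empty_records())
  rows <- vector("list", nrow(cand) * length(roles))
  k <- 0L
  for (i in seq_len(nrow(cand))) {
    for (role in roles) {
      k <- k + 1L
      rows[[k]] <- fit_roi(field, cand[i, ], role, config)
    }
  }
  do.call(rbind, rows)
}
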