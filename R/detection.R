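#' Gaussian smoothing with reflective boundary
#'
#' Convolves a raster with a normalised isotropic Gaussian kernel. The image
#' is reflect-padded by the kernel radius before convolution, so constants are
#' preserved exactly and interior intensity is conserved; this avoids the edge
#' dimming that would bias threshold decisions near borders.
#'
#' @param raster numeric matrix.
#' @param sigma_px kernel standard deviation in pixels (> 0).
#' @return smoothed matrix of the same dimension.
#' @export
gaussian_smooth <- function(raster, sigma_px) {
  if (!is.numeric(sigma_px) || length(sigma_px) != 1L || sigma_px <= 0) {
    stop("gaussian_smooth(): sigma_px must be a positive scalar", call. = FALSE)
  }
  stopifnot(is.matrix(raster))
  r <- max(1L, as.integer(ceiling(4 * sigma_px)))
  g <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  g <- g / sum(g)
  # separable spatial convolution: deterministic pixel values (no FFT ripple),
  # so exact plateaus stay exact and tie-breaking is well defined
  padded <- reflect_pad(raster, r)
  tmp <- stats::filter(padded, g, sides = 2) # along columns
  tmp <- tmp[(r + 1):(r + nrow(raster)), , drop = FALSE]
  out <- t(stats::filter(t(tmp), g, sides = 2)) # along rows
  out <- out[, (r + 1):(r + ncol(raster)), drop = FALSE]
  matrix(as.numeric(out), nrow(raster), ncol(raster))
}

# Symmetric (edge-repeating) reflection padding by r pixels on all sides.
reflect_pad <- function(m, r) {
  n1 <- nrow(m); n2 <- ncol(m)
  ri <- c(pmin(r:1, n1), 1:n1, pmax(n1 - seq_len(r) + 1L, 1L))
  ci <- c(pmin(r:1, n2), 1:n2, pmax(n2 - seq_len(r) + 1L, 1L))
  m[ri, ci, drop = FALSE]
}

#' Robust automatic intensity threshold
#'
#' `median(x) + k * 1.4826 * MAD(x)`: an outlier-resistant estimate of the
#' background level plus `k` background standard deviations. On images
#' dominated by background with a minority of bright puncta, the median and
#' MAD are unaffected by the puncta, so the threshold tracks the noise floor.
#' It is deliberately permissive (default `k = 5` with sparse signal):
#' detection is allowed false positives because badly fitted candidates are
#' removed later by the R-squared filter.
#'
#' @param raster numeric matrix (typically the smoothed marker channel).
#' @param k number of robust standard deviations above the median.
#' @return the threshold value.
#' @export
robust_threshold <- function(raster, k) {
  if (length(raster) == 0L) {
    stop("robust_threshold(): empty raster", call. = FALSE)
  }
  median(raster) + k * mad(raster, constant = 1) * 1.4826
}

# Strict local maxima of `raster` in a (2r+1)^2 neighbourhood, above
# `threshold`, with centres at least `border` pixels from every edge.
# Plateau ties are broken by earliest row-major position (smaller y, then x).
# Returns a data.frame(x, y, value) plus the count of maxima rejected by the
# threshold, and an independent list of all maxima.
local_maxima <- function(raster, r, threshold, border) {
  n1 <- nrow(raster); n2 <- ncol(raster)
  is_max <- matrix(TRUE, n1, n2)
  for (dy in -r:r) {
    for (dx in -r:r) {
      if (dy == 0L && dx == 0L) next
      shifted <- shift_matrix(raster, dy, dx)
      later <- dy > 0L || (dy == 0L && dx > 0L)
      # strict maximum, except that a tie with a *later* (row-major)
      # neighbour is won by this pixel and the duplicate suppressed
      ok <- if (later) raster >= shifted else raster > shifted
      ok[is.na(shifted)] <- TRUE # neighbours outside the image never veto
      is_max <- is_max & ok
    }
  }
  idx <- which(is_max)
  y <- ((idx - 1L) %% n1) + 1L
  x <- ((idx - 1L) %/% n1) + 1L
  v <- raster[idx]
  inside <- y > border & y <= n1 - border & x > border & x <= n2 - border
  above <- v >= threshold
  n_below <- sum(!above & inside)
  keep <- inside & above
  ord <- order(-v[keep], y[keep], x[keep])
  list(x = x[keep][ord], y = y[keep][ord], value = v[keep][ord],
       n_rejected_by_threshold = n_below)
}

# Shift matrix by (dy, dx), padding the vacated band with NA.
shift_matrix <- function(m, dy, dx) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(NA_real_, n1, n2)
  ys <- seq_len(n1) + dy; xs <- seq_len(n2) + dx
  oky <- ys >= 1L & ys <= n1; okx <- xs >= 1L & xs <= n2
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

#' Detect synapse candidates on the smoothed marker channel
#'
#' Stage 1 of the pipeline. The synapse-marker channel is smoothed with a
#' Gaussian kernel (default sigma 480 nm), and candidate positions are taken
#' as strict local intensity maxima of the smoothed raster at or above the
#' configured threshold. Maxima whose square fitting region would not fit
#' inside the image are excluded, and maxima closer than the minimum
#' separation to a brighter maximum are suppressed (greedily, brightest
#' first, Euclidean distance).
#'
#' @param field an [image_field()] with a `marker` channel (or a single
#'   `calibration` channel, in which case detection runs on it).
#' @param config a [pipeline_config()].
#' @param raster optional pre-filtered raster to search instead of the
#'   smoothed marker channel (used by the calibration stage, which detects on
#'   a bandpass-filtered image); must match the field dimensions.
#' @return an object of class `detection_result`: a list with `candidates`
#'   (data frame `field_id, candidate_id, x_px, y_px, smoothed_peak`),
#'   `threshold_used`, `sigma_px`, and `n_rejected_by_threshold`.
#' @export
find_candidates <- function(field, config, raster = NULL) {
  stopifnot(inherits(field, "image_field"), inherits(config, "pipeline_config"))
  px <- field$pixel_size_nm
  sigma_px <- nm_to_px(config$smoothing_sigma_nm, px)
  if (is.null(raster)) {
    ch <- if ("marker" %in% field$channel_roles) {
      get_channel(field, "marker")
    } else if (identical(field$channel_roles, "calibration")) {
      get_channel(field, "calibration")
    } else {
      stop("find_candidates(): field has no marker channel", call. = FALSE)
    }
    raster <- gaussian_smooth(ch, sigma_px)
  } else {
    stopifnot(identical(dim(raster), dim(field$channels[[1]])))
  }
  half <- roi_half_px(config, px)
  empty <- data.frame(field_id = character(), candidate_id = integer(),
                      x_px = integer(), y_px = integer(),
                      smoothed_peak = numeric(), stringsAsFactors = FALSE)
  if (nrow(raster) < 2 * half + 1 || ncol(raster) < 2 * half + 1) {
    warning(sprintf("find_candidates(): field '%s' is smaller than the ROI",
                    field$field_id))
    return(structure(list(candidates = empty, threshold_used = NA_real_,
                          sigma_px = sigma_px, n_rejected_by_threshold = 0L),
                     class = "detection_result"))
  }
  thr <- switch(config$detect_threshold_mode,
                absolute = config$detect_threshold_value,
                robust = robust_threshold(raster, config$detect_threshold_value))
  r_nb <- max(1L, as.integer(round(
    nm_to_px(config$maxima_min_separation_nm, px))))
  mx <- local_maxima(raster, r_nb, thr, border = half)
  # Euclidean minimum-separation suppression, brightest first
  keep <- rep(TRUE, length(mx$x))
  if (length(mx$x) > 1L) {
    for (i in seq_along(mx$x)[-1]) {
      prev <- which(keep[seq_len(i - 1L)])
      if (length(prev) > 0L) {
        d2 <- (mx$x[prev] - mx$x[i])^2 + (mx$y[prev] - mx$y[i])^2
        if (any(d2 < r_nb^2)) keep[i] <- FALSE
      }
    }
  }
  xs <- mx$x[keep]; ys <- mx$y[keep]; vs <- mx$value[keep]
  ord <- order(ys, xs) # stable row-major ids
  cand <- data.frame(field_id = rep(field$field_id, length(xs)),
                     candidate_id = seq_along(xs),
                     x_px = as.integer(xs[ord]), y_px = as.integer(ys[ord]),
                     smoothed_peak = vs[ord], stringsAsFactors = FALSE)
  structure(list(candidates = cand, threshold_used = thr, sigma_px = sigma_px,
                 n_rejected_by_threshold = mx$n_rejected_by_threshold),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(
    "<detection_result> %d candidate(s), threshold %.4g, sigma %.3g px, %d below threshold\n",
    nrow(x$candidates), x$threshold_used, x$sigma_px, x$n_rejected_by_threshold))
  invisible(x)
}
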