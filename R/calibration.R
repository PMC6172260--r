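#' Difference-of-Gaussians bandpass filter
#'
#' `gaussian_smooth(raster, sigma_small) - gaussian_smooth(raster,
#' sigma_large)`: suppresses both pixel noise (below the small scale) and
#' slowly varying background (above the large scale), leaving spots of the
#' intermediate scale. Used to detect single-antibody spots before fitting
#' them on the raw image.
#'
#' @param raster numeric matrix.
#' @param sigma_small_px,sigma_large_px scales in pixels with
#'   `0 < sigma_small_px < sigma_large_px`.
#' @return filtered matrix (zero mean on constant images).
#' @export
bandpass <- function(raster, sigma_small_px, sigma_large_px) {
  if (!(sigma_small_px > 0 && sigma_large_px > sigma_small_px)) {
    stop("bandpass(): need 0 < sigma_small_px < sigma_large_px", call. = FALSE)
  }
  gaussian_smooth(raster, sigma_small_px) - gaussian_smooth(raster, sigma_large_px)
}

#' Full width at half maximum of a fitted spot, in nanometres
#'
#' `2 * sqrt(2 * ln 2) * sigma_mean * pixel_size_nm` with `sigma_mean` the
#' geometric mean of the fitted major and minor spreads, so elliptical fits
#' with equal area report the same width.
#'
#' @param fit one or more record rows (anything with `sigma_major_px` and
#'   `sigma_minor_px` fields).
#' @param pixel_size_nm physical pixel size.
#' @return FWHM in nanometres (vectorised over rows).
#' @export
fwhm_of_fit <- function(fit, pixel_size_nm) {
  s <- sqrt(fit$sigma_major_px * fit$sigma_minor_px)
  2 * sqrt(2 * log(2)) * s * pixel_size_nm
}

#' Calibrate the mean single-antibody intensity
#'
#' Implements the single-antibody calibration: antibody spots are detected on
#' a bandpass-filtered image (difference of Gaussians at the spot scale and
#' three times the spot scale), each spot is Gaussian-fitted on the raw image
#' to obtain its integrated intensity, oversized spots are discarded as
#' non-antibody debris, and the retained intensity population is fitted with
#' a single 1D Gaussian whose peak position is the average single-antibody
#' intensity.
#'
#' The 50 nm FWHM debris cutoff is only meaningful when the optics resolve
#' below it; it is applied when `pixel_size_nm <= 25` (super-resolution data).
#' At coarser pixel sizes an upper sanity bound of twice the fitted
#' population's median FWHM is used instead.
#'
#' The population Gaussian is a least-squares fit to the Freedman-Diaconis
#' histogram of retained intensities; the median intensity is reported
#' alongside as a robust cross-check. A population fit with R-squared below
#' 0.5 triggers a warning (multimodal population, e.g. extensive antibody
#' clusters).
#'
#' @param fields list of calibration [image_field()]s (single `calibration`
#'   channel), or a single field.
#' @param config a [pipeline_config()] whose `smoothing_sigma_nm` is the
#'   expected spot scale (the imaging point-spread sigma) and whose
#'   `roi_side_nm` sizes the fitting region.
#' @param fwhm_cutoff_nm debris cutoff (default 50 nm).
#' @param min_spots minimum number of retained spots (default 10).
#' @return an object of class `calibration_result`: list with
#'   `spot_intensities`, `n_spots`, `n_rejected_fwhm`, `population_mu`,
#'   `population_sigma`, `population_fit_r2`, `median_intensity`,
#'   `fwhm_cutoff_nm`, `cutoff_active`.
#' @export
calibrate <- function(fields, config, fwhm_cutoff_nm = 50, min_spots = 10L) {
  if (inherits(fields, "image_field")) fields <- list(fields)
  if (length(fields) == 0L) {
    stop("calibrate(): at least one calibration field is required", call. = FALSE)
  }
  stopifnot(inherits(config, "pipeline_config"))
  fits <- list()
  for (field in fields) {
    ch <- if ("calibration" %in% field$channel_roles) {
      get_channel(field, "calibration")
    } else {
      field$channels[[1]]
    }
    s_small <- nm_to_px(config$smoothing_sigma_nm, field$pixel_size_nm)
    dog <- bandpass(ch, s_small, 3 * s_small)
    det <- find_candidates(field, config, raster = dog)
    if (nrow(det$candidates) == 0L) next
    rec <- fit_all_channels(field, det, config,
                            roles = field$channel_roles[1])
    rec <- rec[rec$converged & rec$amplitude > 0, , drop = FALSE]
    if (nrow(rec) > 0L) {
      rec$fwhm_nm <- fwhm_of_fit(rec, field$pixel_size_nm)
      fits[[length(fits) + 1L]] <- rec
    }
  }
  if (length(fits) == 0L) {
    stop("calibrate(): no antibody spots could be fitted", call. = FALSE)
  }
  rec <- do.call(rbind, fits)
  px <- fields[[1]]$pixel_size_nm
  cutoff_active <- px <= 25
  if (cutoff_active) {
    keep <- rec$fwhm_nm <= fwhm_cutoff_nm
  } else {
    keep <- rec$fwhm_nm <= 2 * median(rec$fwhm_nm)
  }
  n_rejected <- sum(!keep)
  intens <- rec$integrated_intensity[keep]
  intens <- intens[is.finite(intens) & intens > 0]
  if (length(intens) < min_spots) {
    stop(sprintf(
      "calibrate(): only %d spot(s) retained; at least %d are required",
      length(intens), min_spots), call. = FALSE)
  }
  pop <- fit_population_gaussian(intens)
  if (is.finite(pop$r2) && pop$r2 < 0.5) {
    warning("calibrate(): intensity population is poorly described by a single Gaussian (possible antibody clusters)")
  }
  structure(
    list(spot_intensities = intens, n_spots = length(intens),
         n_rejected_fwhm = n_rejected, population_mu = pop$mu,
         population_sigma = pop$sigma, population_fit_r2 = pop$r2,
         median_intensity = median(intens), fwhm_cutoff_nm = fwhm_cutoff_nm,
         cutoff_active = cutoff_active),
    class = "calibration_result"
  )
}

# Least-squares Gaussian fit to the Freedman-Diaconis histogram of a sample;
# the fitted peak position estimates the population mode/mean.
fit_population_gaussian <- function(x) {
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  mids <- h$mids; counts <- h$counts
  p0 <- c(mu = median(x), s = max(mad(x), diff(range(x)) / 20, 1e-12),
          A = max(counts))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = p0,
      lower = c(min(x), 1e-12, 0), upper = c(max(x), diff(range(x)) + 1e-12, Inf),
      fn = function(p) p[3] * exp(-(mids - p[1])^2 / (2 * p[2]^2)) - counts,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) {
    return(list(mu = mean(x), sigma = sd(x), r2 = NA_real_))
  }
  p <- coef(fit)
  model <- p[["A"]] * exp(-(mids - p[["mu"]])^2 / (2 * p[["s"]]^2))
  list(mu = p[["mu"]], sigma = p[["s"]],
       r2 = r_squared(as.numeric(counts), as.numeric(model)))
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> mu = %.4g (sigma %.3g, fit R2 %.3f) from %d spot(s); %d rejected by size; median %.4g\n",
    x$population_mu, x$population_sigma, x$population_fit_r2, x$n_spots,
    x$n_rejected_fwhm, x$median_intensity))
  invisible(x)
}
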