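#' Physical unit conversions between nanometres and pixels
#'
#' Detection and fitting parameters are specified in nanometres and converted
#' to pixel units with the field's pixel size, so one configuration applies to
#' images acquired at different magnifications (e.g. 800 nm corresponds to
#' 5 pixels at a 160 nm pixel size).
#'
#' @param value_nm,value_px value to convert.
#' @param pixel_size_nm physical pixel size in nanometres; must be positive.
#' @return the converted value.
#' @examples
#' nm_to_px(800, 160) # 5
#' px_to_nm(nm_to_px(480, 160), 160) # 480
#' @export
nm_to_px <- function(value_nm, pixel_size_nm) {
  if (any(value_nm <= 0) || any(pixel_size_nm <= 0)) {
    stop("nm_to_px(): both arguments must be positive", call. = FALSE)
  }
  value_nm / pixel_size_nm
}

#' @rdname nm_to_px
#' @export
px_to_nm <- function(value_px, pixel_size_nm) {
  if (any(value_px <= 0) || any(pixel_size_nm <= 0)) {
    stop("px_to_nm(): both arguments must be positive", call. = FALSE)
  }
  value_px * pixel_size_nm
}

valid_roles <- c("marker", "active_zone", "poi", "calibration")

#' Construct a registered multi-channel image field
#'
#' The unit of acquisition: an ordered set of registered 2D intensity rasters
#' with a physical pixel size. Synaptosome and culture fields carry exactly
#' one synapse-marker channel (detection runs on it); calibration fields hold
#' single-antibody images. Pixel indices are 1-based with pixel centres at
#' integer coordinates; `x` indexes columns and `y` indexes rows.
#'
#' @param channels list of numeric matrices, all the same dimension, with
#'   non-negative finite intensities in arbitrary fluorescence units.
#' @param channel_roles character vector, one of `"marker"`, `"active_zone"`,
#'   `"poi"`, `"calibration"` per channel.
#' @param pixel_size_nm physical pixel size in nanometres.
#' @param field_id identifier carried into all downstream tables.
#' @param sample_kind `"synaptosome"`, `"culture"`, or `"calibration"`.
#' @return an object of class `image_field`.
#' @export
image_field <- function(channels, channel_roles, pixel_size_nm,
                        field_id = "field", sample_kind = "synaptosome") {
  if (!is.list(channels) || length(channels) == 0L) {
    stop("image_field(): 'channels' must be a non-empty list of matrices",
         call. = FALSE)
  }
  channels <- lapply(channels, function(ch) {
    if (!is.matrix(ch) || !is.numeric(ch)) {
      stop("image_field(): every channel must be a numeric matrix", call. = FALSE)
    }
    storage.mode(ch) <- "double"
    ch
  })
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("image_field(): all channels must share the same height x width",
         call. = FALSE)
  }
  if (length(channel_roles) != length(channels)) {
    stop("image_field(): one role per channel is required", call. = FALSE)
  }
  if (!all(channel_roles %in% valid_roles)) {
    stop("image_field(): roles must be among ",
         paste(valid_roles, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0) {
    stop("image_field(): pixel_size_nm must be a positive scalar", call. = FALSE)
  }
  sample_kind <- match.arg(sample_kind, c("synaptosome", "culture", "calibration"))
  if (sample_kind %in% c("synaptosome", "culture") &&
      sum(channel_roles == "marker") != 1L) {
    stop("image_field(): synaptosome/culture fields need exactly one 'marker' channel",
         call. = FALSE)
  }
  names(channels) <- channel_roles
  structure(
    list(channels = channels, channel_roles = channel_roles,
         pixel_size_nm = pixel_size_nm, field_id = as.character(field_id),
         sample_kind = sample_kind),
    class = "image_field"
  )
}

#' @export
print.image_field <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_field '%s'> %s, %d x %d px @ %g nm/px, channels: %s\n",
              x$field_id, x$sample_kind, d[1], d[2], x$pixel_size_nm,
              paste(x$channel_roles, collapse = ", ")))
  invisible(x)
}

#' Extract a channel raster by role
#'
#' @param field an [image_field()].
#' @param role channel role to extract.
#' @return the channel matrix.
#' @export
get_channel <- function(field, role) {
  stopifnot(inherits(field, "image_field"))
  i <- which(field$channel_roles == role)
  if (length(i) != 1L) {
    stop(sprintf("get_channel(): field '%s' has %d channels with role '%s'",
                 field$field_id, length(i), role), call. = FALSE)
  }
  field$channels[[i]]
}

#' Pipeline configuration
#'
#' One flat, versioned set of tunables governs every stage, so that the two
#' samples of a comparison are processed identically. Physical parameters are
#' in nanometres and converted per field. Defaults follow the published
#' protocol: a 480 nm smoothing kernel for detection, a 2.2 um square fitting
#' region, and per-channel R-squared acceptance thresholds of 0.85 (synapse
#' marker), 0.70 (active-zone marker) and 0.60 (protein of interest).
#'
#' @param smoothing_sigma_nm standard deviation of the Gaussian kernel used to
#'   smooth the marker channel before maxima search.
#' @param roi_side_nm side of the square fitting region of interest.
#' @param r2_thresholds named numeric vector of per-role R-squared acceptance
#'   thresholds in `[0, 1]`; comparisons are inclusive (a fit exactly at the
#'   threshold passes).
#' @param detect_threshold_mode `"robust"` (default) uses
#'   `median + k * 1.4826 * MAD` of the smoothed raster with
#'   `k = detect_threshold_value`; `"absolute"` uses `detect_threshold_value`
#'   as the intensity threshold itself.
#' @param detect_threshold_value `k` for robust mode (default 5) or the
#'   absolute intensity threshold.
#' @param maxima_min_separation_nm minimum separation between detected maxima;
#'   also sets the strict local-maximum neighbourhood radius.
#' @param seed integer seed recorded with the run for provenance.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(smoothing_sigma_nm = 480,
                            roi_side_nm = 2200,
                            r2_thresholds = c(marker = 0.85, active_zone = 0.70,
                                              poi = 0.60),
                            detect_threshold_mode = c("robust", "absolute"),
                            detect_threshold_value = 5,
                            maxima_min_separation_nm = 480,
                            seed = 1L) {
  detect_threshold_mode <- match.arg(detect_threshold_mode)
  for (v in c(smoothing_sigma_nm, roi_side_nm, maxima_min_separation_nm)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("pipeline_config(): physical scalars must be positive", call. = FALSE)
    }
  }
  if (is.null(names(r2_thresholds)) || any(!nzchar(names(r2_thresholds)))) {
    stop("pipeline_config(): r2_thresholds must be named by channel role",
         call. = FALSE)
  }
  if (any(r2_thresholds < 0 | r2_thresholds > 1)) {
    stop("pipeline_config(): r2_thresholds must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(config_version = "1",
         smoothing_sigma_nm = smoothing_sigma_nm,
         roi_side_nm = roi_side_nm,
         r2_thresholds = r2_thresholds,
         detect_threshold_mode = detect_threshold_mode,
         detect_threshold_value = detect_threshold_value,
         maxima_min_separation_nm = maxima_min_separation_nm,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "<pipeline_config v%s> smooth %g nm, ROI %g nm, threshold %s (%g), min sep %g nm\n",
    x$config_version, x$smoothing_sigma_nm, x$roi_side_nm,
    x$detect_threshold_mode, x$detect_threshold_value,
    x$maxima_min_separation_nm))
  cat("  R2 thresholds:",
      paste(sprintf("%s >= %g", names(x$r2_thresholds), x$r2_thresholds),
            collapse = ", "), "\n")
  invisible(x)
}

# Square ROI half-width in pixels for a field; the ROI is (2h+1) x (2h+1).
roi_half_px <- function(config, pixel_size_nm) {
  side <- round(nm_to_px(config$roi_side_nm, pixel_size_nm))
  max(1L, as.integer(floor(side / 2)))
}
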