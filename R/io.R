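#' Read a multi-page grayscale TIFF into an image field
#'
#' Pages are promoted to double precision and kept in their raw intensity
#' scale (no rescaling), one page per channel role.
#'
#' @param path path to a single- or multi-page grayscale TIFF.
#' @param pixel_size_nm physical pixel size of the acquisition.
#' @param channel_roles roles of the pages, in page order.
#' @param field_id identifier; defaults to the file name without extension.
#' @param sample_kind sample type of the field.
#' @return an [image_field()].
#' @export
read_field <- function(path, pixel_size_nm, channel_roles,
                       field_id = NULL, sample_kind = "synaptosome") {
  if (!file.exists(path)) {
    stop(sprintf("read_field(): cannot read '%s'", path), call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(channel_roles)) {
    stop(sprintf(
      "read_field(): '%s' has %d page(s) but %d channel role(s) were given",
      path, length(pages), length(channel_roles)), call. = FALSE)
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] != 1L) {
        stop("read_field(): only grayscale TIFF pages are supported", call. = FALSE)
      }
      p <- p[, , 1]
    }
    # undo the exact power-of-two scaling applied by write_field()
    p * 65536
  })
  if (is.null(field_id)) field_id <- tools::file_path_sans_ext(basename(path))
  image_field(pages, channel_roles, pixel_size_nm,
              field_id = field_id, sample_kind = sample_kind)
}

#' Write an image field to a multi-page 32-bit float TIFF
#'
#' The TIFF writer stores floats on a `[0, 1]` scale, so intensities are
#' divided by 2^16 on write and multiplied back on read - an exact operation
#' in binary floating point. Reading the file back with [read_field()]
#' therefore reproduces the channel arrays within 32-bit float precision.
#' Intensities must lie in `[0, 65536]` (any real camera's range).
#'
#' @param field an [image_field()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "image_field"))
  if (any(vapply(field$channels, max, numeric(1)) > 65536) ||
      any(vapply(field$channels, min, numeric(1)) < 0)) {
    stop("write_field(): intensities must lie in [0, 65536]", call. = FALSE)
  }
  tiff::writeTIFF(lapply(field$channels, function(ch) ch / 65536),
                  path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

# Fixed column order of the per-(candidate, channel) records table.
record_columns <- function() {
  c("field_id", "candidate_id", "channel_role",
    "x0_px", "y0_px", "x0_nm", "y0_nm",
    "sigma_major_px", "sigma_minor_px", "theta_rad",
    "amplitude", "offset", "integrated_intensity", "r2", "converged",
    "accepted", "reject_reason")
}

#' Write and read synapse-fit records
#'
#' Records are a long-format data frame with one row per (candidate, channel)
#' carrying the full fit parameterisation, the integrated intensity, the
#' R-squared, and the accept flag set by [filter_records()]. The CSV header is
#' fixed (see `cosiquant:::record_columns()`); numeric fields round-trip to at
#' least 12 significant digits. Continuous coordinates use 1-based pixel
#' centres; `*_nm` columns give the distance of the centre from the image
#' border, `(px - 0.5) * pixel_size_nm`.
#'
#' @param records records data frame as produced by [fit_all_channels()].
#' @param path CSV path.
#' @return `write_records()` returns `path` invisibly; `read_records()`
#'   returns the records data frame.
#' @export
write_records <- function(records, path) {
  cols <- record_columns()
  if (nrow(records) == 0L) {
    records <- empty_records()
  }
  missing <- setdiff(cols, names(records))
  if (length(missing) > 0L) {
    stop("write_records(): records lack columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- records[, cols, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "candidate_id"
  out[num] <- lapply(out[num], function(x) sprintf("%.15g", x))
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_records(): cannot read '%s'", path), call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  num <- setdiff(record_columns(),
                 c("field_id", "channel_role", "converged", "accepted",
                   "reject_reason", "candidate_id"))
  for (cl in num) df[[cl]] <- as.numeric(df[[cl]])
  df$candidate_id <- as.integer(df$candidate_id)
  df$converged <- as.logical(df$converged)
  df$accepted <- as.logical(df$accepted)
  df$reject_reason <- as.character(df$reject_reason)
  df$reject_reason[is.na(df$reject_reason)] <- ""
  df
}

empty_records <- function() {
  data.frame(field_id = character(), candidate_id = integer(),
             channel_role = character(), x0_px = numeric(), y0_px = numeric(),
             x0_nm = numeric(), y0_nm = numeric(), sigma_major_px = numeric(),
             sigma_minor_px = numeric(), theta_rad = numeric(),
             amplitude = numeric(), offset = numeric(),
             integrated_intensity = numeric(), r2 = numeric(),
             converged = logical(), accepted = logical(),
             reject_reason = character(), stringsAsFactors = FALSE)
}

#' Write and read a pipeline configuration as flat JSON
#'
#' The on-disk format is one flat key-value JSON document carrying a
#' `config_version` field, so runs are reproducible from the config file.
#'
#' @param config a [pipeline_config()].
#' @param path JSON path.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns
#'   the [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$r2_thresholds <- as.list(x$r2_thresholds) # keep role names in the JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    smoothing_sigma_nm = x$smoothing_sigma_nm,
    roi_side_nm = x$roi_side_nm,
    r2_thresholds = unlist(x$r2_thresholds),
    detect_threshold_mode = x$detect_threshold_mode,
    detect_threshold_value = x$detect_threshold_value,
    maxima_min_separation_nm = x$maxima_min_separation_nm,
    seed = x$seed
  )
}
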