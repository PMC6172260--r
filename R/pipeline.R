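#' Run the comparative pipeline end to end
#'
#' Chains detection, per-channel Gaussian fitting and R-squared filtering over
#' both samples with one shared configuration (the method's validity rests on
#' identical processing of the compared samples; the only override allowed is
#' the detection threshold, because lawn and culture backgrounds differ),
#' then converts the culture's protein-of-interest intensities into copy
#' numbers via the synaptosome reference ratio, and - when a single-antibody
#' calibration is supplied - into antibodies per structure.
#'
#' @param synaptosome_fields list of synaptosome [image_field()]s.
#' @param culture_fields list of culture [image_field()]s.
#' @param config a [pipeline_config()] applied to both samples.
#' @param target reference target name, or a one-row `reference_table` entry;
#'   `NULL` skips the copy-number conversion.
#' @param reference a `reference_table` (defaults to the packaged one when a
#'   target name must be resolved).
#' @param calibration optional `calibration_result` or single-antibody mean
#'   intensity; adds antibodies-per-structure summaries.
#' @param culture_detect_threshold optional per-sample override of the
#'   detection threshold value for the culture sample only.
#' @param ... passed to [lookup_reference()] (e.g. `catalog_number`).
#' @return an object of class `run_report`: config snapshot, per-field stage
#'   counts, per-role intensity summaries for both samples, the
#'   `copy_number_estimate`, antibody counts if calibrated, and the records.
#' @export
run_pipeline <- function(synaptosome_fields, culture_fields, config,
                         target = NULL, reference = NULL, calibration = NULL,
                         culture_detect_threshold = NULL, ...) {
  if (length(synaptosome_fields) == 0L || length(culture_fields) == 0L) {
    stop("run_pipeline(): both samples must contain at least one field",
         call. = FALSE)
  }
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(synaptosome_fields, "image_field")) {
    synaptosome_fields <- list(synaptosome_fields)
  }
  if (inherits(culture_fields, "image_field")) {
    culture_fields <- list(culture_fields)
  }
  culture_config <- config
  if (!is.null(culture_detect_threshold)) {
    culture_config$detect_threshold_value <- culture_detect_threshold
  }
  syn <- process_sample(synaptosome_fields, config, "synaptosome")
  cult <- process_sample(culture_fields, culture_config, "culture")
  for (s in list(syn, cult)) {
    if (s$n_accepted == 0L) {
      stop(sprintf(
        "run_pipeline(): zero accepted synapses in the %s sample (stage: %s)",
        s$sample_kind, s$empty_stage), call. = FALSE)
    }
  }
  estimate <- NULL
  entry <- NULL
  if (!is.null(target)) {
    if (inherits(target, "reference_table") || is.data.frame(target)) {
      if (nrow(target) != 1L) {
        stop("run_pipeline(): a reference entry must be a single row", call. = FALSE)
      }
      entry <- target
    } else {
      if (is.null(reference)) reference <- load_reference()
      entry <- lookup_reference(target, reference = reference, ...)
    }
    if (is.na(entry$copies_mean)) {
      stop(sprintf(
        "run_pipeline(): reference entry '%s' has no measured copy number (provenance: %s)",
        entry$target, entry$copies_provenance), call. = FALSE)
    }
    estimate <- estimate_copy_numbers(
      cult$poi_intensities, syn$poi_intensities, entry$copies_mean,
      target = entry$target, reference_copies_sem = entry$copies_sem)
  }
  antibodies <- NULL
  if (!is.null(calibration)) {
    mu <- if (inherits(calibration, "calibration_result")) {
      calibration$population_mu
    } else {
      calibration
    }
    antibodies <- list(
      single_ab_mean_intensity = mu,
      synaptosome = mean_sem(antibodies_per_structure(syn$poi_intensities, mu)),
      culture = mean_sem(antibodies_per_structure(cult$poi_intensities, mu)))
  }
  structure(
    list(config = config,
         culture_detect_threshold = culture_detect_threshold,
         counts = rbind(syn$counts, cult$counts),
         intensity_summaries = rbind(syn$summary, cult$summary),
         copy_number_estimate = estimate, reference_entry = entry,
         antibodies = antibodies,
         records = list(synaptosome = syn$records, culture = cult$records),
         seed = config$seed,
         version = as.character(utils::packageVersion("cosiquant"))),
    class = "run_report"
  )
}

process_sample <- function(fields, config, sample_kind) {
  recs <- list()
  counts <- list()
  for (field in fields) {
    det <- find_candidates(field, config)
    rec <- fit_all_channels(field, det, config)
    rec <- filter_records(rec, config)
    n_cand <- nrow(det$candidates)
    n_fit <- if (nrow(rec) > 0L) {
      length(unique(rec$candidate_id[rec$converged]))
    } else 0L
    n_acc <- if (nrow(rec) > 0L) {
      length(unique(rec$candidate_id[!is.na(rec$accepted) & rec$accepted]))
    } else 0L
    counts[[length(counts) + 1L]] <- data.frame(
      sample_kind = sample_kind, field_id = field$field_id,
      n_candidates = n_cand, n_fitted = n_fit, n_accepted = n_acc,
      threshold_used = det$threshold_used, stringsAsFactors = FALSE)
    recs[[length(recs) + 1L]] <- rec
  }
  records <- do.call(rbind, recs)
  counts <- do.call(rbind, counts)
  acc <- records[!is.na(records$accepted) & records$accepted &
                   records$channel_role == "poi", , drop = FALSE]
  n_accepted <- sum(counts$n_accepted)
  empty_stage <- if (sum(counts$n_candidates) == 0L) {
    "detection"
  } else if (sum(counts$n_fitted) == 0L) {
    "fitting"
  } else {
    "filtering"
  }
  list(sample_kind = sample_kind, records = records, counts = counts,
       summary = summarize_intensities(records, sample_kind),
       poi_intensities = acc$integrated_intensity,
       n_accepted = n_accepted, empty_stage = empty_stage)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> cosiquant", x$version, "(seed", paste0(x$seed, ")"), "\n")
  agg <- stats::aggregate(
    cbind(n_candidates, n_fitted, n_accepted) ~ sample_kind, data = x$counts,
    FUN = sum)
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-12s candidates %4d -> fitted %4d -> accepted %4d\n",
                agg$sample_kind[i], agg$n_candidates[i], agg$n_fitted[i],
                agg$n_accepted[i]))
  }
  if (!is.null(x$copy_number_estimate)) print(x$copy_number_estimate)
  if (!is.null(x$antibodies)) {
    cat(sprintf(
      "  antibodies/structure: synaptosome %.3g +/- %.2g, culture %.3g +/- %.2g (mu = %.4g)\n",
      x$antibodies$synaptosome[["mean"]], x$antibodies$synaptosome[["sem"]],
      x$antibodies$culture[["mean"]], x$antibodies$culture[["sem"]],
      x$antibodies$single_ab_mean_intensity))
  }
  invisible(x)
}

#' Serialise a run report to JSON
#'
#' Writes the report (without the full per-record tables) as JSON for
#' downstream consumption; reports are reproducible from config plus inputs,
#' so no timestamp is included.
#'
#' @param report a `run_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  out <- list(
    version = report$version, seed = report$seed,
    config = unclass(report$config),
    culture_detect_threshold = report$culture_detect_threshold,
    counts = report$counts,
    intensity_summaries = report$intensity_summaries)
  if (!is.null(report$copy_number_estimate)) {
    e <- report$copy_number_estimate
    out$copy_number_estimate <- list(
      target = e$target, mean_copies = e$mean_copies, sem_copies = e$sem_copies,
      n = e$n, reference_copies = e$reference_copies,
      reference_copies_sem = e$reference_copies_sem,
      reference_mean_intensity = e$reference_mean_intensity,
      mean_intensity_ratio = e$mean_intensity_ratio)
  }
  if (!is.null(report$antibodies)) out$antibodies <- report$antibodies
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
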