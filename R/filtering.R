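#' Filter fitted records by per-channel R-squared thresholds
#'
#' Stage 3 of the pipeline. A candidate is accepted iff, for every channel
#' role named in `config$r2_thresholds` and present in the records, its fit
#' converged and reached the role's threshold (defaults: synapse marker 0.85,
#' active-zone marker 0.70, protein of interest 0.60). Comparisons are
#' inclusive - a fit exactly at the threshold passes, since it is candidates
#' *below* the threshold that are discarded. Rejected candidates carry the
#' failing role name(s) in `reject_reason`.
#'
#' @param records records data frame from [fit_all_channels()].
#' @param config a [pipeline_config()].
#' @return the same records with `accepted` and `reject_reason` filled on
#'   every row of each candidate.
#' @export
filter_records <- function(records, config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (nrow(records) == 0L) return(records)
  thr <- config$r2_thresholds
  roles_checked <- intersect(names(thr), unique(records$channel_role))
  key <- paste(records$field_id, records$candidate_id, sep = "\r")
  for (k in unique(key)) {
    sel <- key == k
    failing <- character()
    for (role in roles_checked) {
      rr <- records[sel & records$channel_role == role, , drop = FALSE]
      ok <- nrow(rr) > 0L && all(rr$converged) && all(!is.na(rr$r2)) &&
        all(rr$r2 >= thr[[role]])
      if (!ok) failing <- c(failing, role)
    }
    records$accepted[sel] <- length(failing) == 0L
    records$reject_reason[sel] <-
      if (length(failing) > 0L) paste(failing, collapse = ",") else ""
  }
  records
}

#' Mean and standard error of the mean
#'
#' The summary used for all reported intensities and copy numbers: the
#' arithmetic mean and `sd(x) / sqrt(n)` with the sample (n - 1) standard
#' deviation.
#'
#' @param values numeric vector, non-empty.
#' @return named numeric vector `c(mean = ..., sem = ..., n = ...)`; `sem` is
#'   `NA` for a single value.
#' @examples
#' mean_sem(c(1, 2, 3)) # mean 2, sem 1/sqrt(3)
#' @export
mean_sem <- function(values) {
  if (length(values) == 0L || !is.numeric(values)) {
    stop("mean_sem(): non-empty numeric vector required", call. = FALSE)
  }
  n <- length(values)
  c(mean = mean(values), sem = if (n >= 2L) sd(values) / sqrt(n) else NA_real_,
    n = n)
}

#' Summarise accepted integrated intensities per channel role
#'
#' @param records filtered records data frame ([filter_records()]).
#' @param sample_kind label copied into the summary.
#' @param accepted_only summarise accepted candidates only (default).
#' @return data frame `sample_kind, role, n, mean_intensity, sem_intensity`.
#' @export
summarize_intensities <- function(records, sample_kind = "sample",
                                  accepted_only = TRUE) {
  if (accepted_only) {
    records <- records[!is.na(records$accepted) & records$accepted, , drop = FALSE]
  }
  roles <- unique(records$channel_role)
  out <- lapply(roles, function(role) {
    v <- records$integrated_intensity[records$channel_role == role]
    v <- v[is.finite(v)]
    ms <- if (length(v) > 0L) mean_sem(v) else c(mean = NA_real_, sem = NA_real_, n = 0)
    data.frame(sample_kind = sample_kind, role = role, n = as.integer(ms[["n"]]),
               mean_intensity = ms[["mean"]], sem_intensity = ms[["sem"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Interpolate per-synapse protein copy numbers from a synaptosome reference
#'
#' The core comparative step: each synapse's intensity is divided by the mean
#' synaptosome intensity from the parallel staining and multiplied by the
#' published average copies per synaptosome. Copy numbers are computed per
#' synapse and then summarised (mean and SEM over synapses); the reference
#' table's own SEM is reported separately, not propagated.
#'
#' @param synapse_intensities integrated intensities of accepted synapses in
#'   the sample of interest.
#' @param synaptosome_intensities integrated intensities of accepted
#'   synaptosomes from the parallel staining.
#' @param reference_copies published mean protein copies per synaptosome.
#' @param target optional target-protein label carried into the result.
#' @param reference_copies_sem optional SEM of the reference copies, reported
#'   alongside.
#' @return an object of class `copy_number_estimate`: a list with
#'   `per_synapse_copies`, `mean_copies`, `sem_copies`, `n`,
#'   `reference_copies`, `reference_mean_intensity`, `mean_intensity_ratio`.
#' @export
estimate_copy_numbers <- function(synapse_intensities, synaptosome_intensities,
                                  reference_copies, target = NA_character_,
                                  reference_copies_sem = NA_real_) {
  if (length(synapse_intensities) == 0L || length(synaptosome_intensities) == 0L) {
    stop("estimate_copy_numbers(): both intensity lists must be non-empty",
         call. = FALSE)
  }
  ref_mean <- mean(synaptosome_intensities)
  if (!is.finite(ref_mean) || ref_mean <= 0) {
    stop("estimate_copy_numbers(): mean synaptosome intensity must be positive",
         call. = FALSE)
  }
  if (!is.finite(reference_copies) || reference_copies <= 0) {
    stop("estimate_copy_numbers(): reference_copies must be positive",
         call. = FALSE)
  }
  per <- synapse_intensities / ref_mean * reference_copies
  ms <- mean_sem(per)
  structure(
    list(target = target, per_synapse_copies = per,
         mean_copies = ms[["mean"]], sem_copies = ms[["sem"]],
         n = as.integer(ms[["n"]]), reference_copies = reference_copies,
         reference_copies_sem = reference_copies_sem,
         reference_mean_intensity = ref_mean,
         mean_intensity_ratio = mean(synapse_intensities) / ref_mean),
    class = "copy_number_estimate"
  )
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf(
    "<copy_number_estimate%s> %.4g +/- %.3g copies per synapse (n = %d; intensity ratio %.3g; reference %.4g copies/synaptosome)\n",
    if (is.na(x$target)) "" else paste0(" ", x$target),
    x$mean_copies, x$sem_copies, x$n, x$mean_intensity_ratio,
    x$reference_copies))
  invisible(x)
}

#' Express structure intensities as numbers of antibodies
#'
#' Divides intensities by the mean intensity of a single immunolabelled
#' primary antibody (from [calibrate()]), converting arbitrary fluorescence
#' units into an antibody count - the transferable currency that lets
#' different laboratories compare stainings without sharing samples. Assumes
#' antibody intensities sum linearly.
#'
#' @param structure_intensities integrated intensities of the structures.
#' @param single_ab_mean_intensity mean single-antibody intensity (> 0).
#' @return numeric vector of antibody counts.
#' @export
antibodies_per_structure <- function(structure_intensities,
                                     single_ab_mean_intensity) {
  if (!is.finite(single_ab_mean_intensity) || single_ab_mean_intensity <= 0) {
    stop("antibodies_per_structure(): calibration mean must be positive",
         call. = FALSE)
  }
  structure_intensities / single_ab_mean_intensity
}

#' Ordinary least-squares comparison of measured vs estimated values
#'
#' Utility for cross-dataset validation: regresses `measured` on `estimated`
#' (`y = a * x + b`) and reports the slope and coefficient of determination.
#'
#' @param measured,estimated numeric vectors of equal length (>= 2).
#' @return list with `slope`, `intercept`, `r2`.
#' @export
compare_measured_vs_estimated <- function(measured, estimated) {
  if (length(measured) != length(estimated)) {
    stop("compare_measured_vs_estimated(): length mismatch", call. = FALSE)
  }
  if (length(measured) < 2L) {
    stop("compare_measured_vs_estimated(): need at least 2 points", call. = FALSE)
  }
  fit <- lm(measured ~ estimated)
  ss_tot <- sum((measured - mean(measured))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = r2)
}
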