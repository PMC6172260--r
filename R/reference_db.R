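#' Synaptic vesicle counts from 30 electron-microscopy 3D reconstructions
#'
#' Individual synaptic vesicle counts of 30 cultured hippocampal synapses,
#' reconstructed in 3D electron microscopy. Their mean and SEM (250 +/- 26
#' after rounding, via [mean_sem()]) anchor the expectation that cultured
#' synapses hold fewer vesicles than synaptosomes (which average ~380).
#'
#' @format integer vector of length 30.
#' @export
em_vesicle_counts <- c(36L, 86L, 89L, 95L, 119L, 124L, 128L, 136L, 137L, 173L,
                       185L, 191L, 197L, 197L, 212L, 224L, 233L, 248L, 249L,
                       252L, 257L, 302L, 315L, 377L, 403L, 450L, 509L, 516L,
                       526L, 544L)

#' Load the packaged synaptosome reference table
#'
#' The reference database behind the comparative method: for 120 stainings of
#' over 100 target proteins, the mean number of primary antibodies per
#' synaptosome with its dispersion (SEM over synapses, or range of values over
#' experiments), the biochemically determined mean protein copies per
#' synaptosome with SEM where available, and the staining conditions (vendor,
#' catalogue number, clonality, dilution, fixation, blocking,
#' permeabilisation). Copy numbers flagged as author estimates are stored as
#' ranges/qualifiers (`copies_low`, `copies_high`, `copies_qualifier`), not
#' coerced to a single float; targets never characterised biochemically carry
#' `copies_provenance = "not_determined"`.
#'
#' @param path path to the TSV resource; defaults to the packaged copy.
#' @return a data frame of class `reference_table`, one row per staining.
#' @export
load_reference <- function(path = system.file("extdata",
                                              "synaptosome_reference.tsv",
                                              package = "cosiquant")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("load_reference(): packaged reference table not found", call. = FALSE)
  }
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                   colClasses = "character")
  expected <- c("target", "antibodies_mean", "dispersion_value",
                "dispersion_kind", "copies_mean", "copies_sem", "copies_low",
                "copies_high", "copies_qualifier", "copies_provenance",
                "copies_note", "company", "catalog_number",
                "species_clonality", "dilution", "fixation", "blocking",
                "permeabilization")
  if (!identical(names(df), expected)) {
    stop("load_reference(): reference table is corrupted (unexpected columns)",
         call. = FALSE)
  }
  for (cl in c("antibodies_mean", "dispersion_value", "copies_mean",
               "copies_sem", "copies_low", "copies_high")) {
    df[[cl]] <- as.numeric(df[[cl]])
  }
  df$copies_note[is.na(df$copies_note)] <- ""
  df$copies_qualifier[is.na(df$copies_qualifier)] <- ""
  df$catalog_number[is.na(df$catalog_number)] <- ""
  ok <- nrow(df) >= 100 &&
    all(df$antibodies_mean > 0) &&
    all(df$dispersion_value >= 0) &&
    all(df$dispersion_kind %in% c("SEM", "ROV")) &&
    all(df$copies_provenance %in%
          c("measured", "estimated_by_authors", "not_determined")) &&
    all(!is.na(df$copies_mean[df$copies_provenance == "measured"])) &&
    all(is.na(df$copies_mean[df$copies_provenance == "not_determined"]))
  if (!ok) {
    stop("load_reference(): reference table failed integrity checks",
         call. = FALSE)
  }
  class(df) <- c("reference_table", "data.frame")
  df
}

#' Look up one staining in the reference table
#'
#' Case-insensitive exact match on the target name. Several targets appear
#' more than once (two vendors for the active-zone marker, two dilutions for
#' some antibodies, duplicate rows differing only in dispersion convention);
#' `catalog_number`, `dilution` and `dispersion_kind` disambiguate. An
#' ambiguous query fails with an error enumerating the candidate rows; an
#' unmatched target fails with suggestions of the nearest names.
#'
#' @param target target protein name (case-insensitive).
#' @param catalog_number optional vendor catalogue number.
#' @param dilution optional dilution string such as `"1:500"`.
#' @param dispersion_kind optional `"SEM"` or `"ROV"`.
#' @param reference a `reference_table`; defaults to the packaged one.
#' @return the matching one-row `reference_table`.
#' @export
lookup_reference <- function(target, catalog_number = NULL, dilution = NULL,
                             dispersion_kind = NULL,
                             reference = load_reference()) {
  stopifnot(inherits(reference, "reference_table"))
  hit <- tolower(reference$target) == tolower(target)
  if (!any(hit)) {
    near <- unique(reference$target[agrepl(target, reference$target,
                                           ignore.case = TRUE,
                                           max.distance = 0.3)])
    stop(structure(class = c("cosiquant_not_found", "error", "condition"),
                   list(message = sprintf(
                     "lookup_reference(): no entry for '%s'%s", target,
                     if (length(near) > 0L) {
                       paste0("; nearest names: ", paste(near, collapse = ", "))
                     } else ""),
                     call = NULL)))
  }
  if (!is.null(catalog_number)) {
    hit <- hit & reference$catalog_number == catalog_number
  }
  if (!is.null(dilution)) hit <- hit & reference$dilution == dilution
  if (!is.null(dispersion_kind)) {
    hit <- hit & reference$dispersion_kind == dispersion_kind
  }
  n <- sum(hit)
  if (n == 0L) {
    stop(structure(class = c("cosiquant_not_found", "error", "condition"),
                   list(message = sprintf(
                     "lookup_reference(): no entry for '%s' with the given qualifiers",
                     target), call = NULL)))
  }
  if (n > 1L) {
    rows <- reference[hit, , drop = FALSE]
    desc <- sprintf("%s [%s %s, %s, %s]", rows$target, rows$company,
                    rows$catalog_number, rows$dilution, rows$dispersion_kind)
    stop(structure(class = c("cosiquant_ambiguous", "error", "condition"),
                   list(message = paste0(
                     sprintf("lookup_reference(): '%s' matches %d rows; disambiguate by catalog_number/dilution/dispersion_kind:\n  ",
                             target, n),
                     paste(desc, collapse = "\n  ")), call = NULL)))
  }
  reference[hit, , drop = FALSE]
}

#' Export the reference table to CSV
#'
#' Round-trip safe: re-importing the CSV reproduces every field.
#'
#' @param path output CSV path.
#' @param reference a `reference_table`; defaults to the packaged one.
#' @return `path`, invisibly.
#' @export
export_reference <- function(path, reference = load_reference()) {
  write.csv(reference, path, row.names = FALSE, na = "")
  invisible(path)
}
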