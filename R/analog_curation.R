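# Four-stage curation of raw analog matches into a curated analog library:
# source filter, mass-offset filter, library-match filter, detection-
# frequency filter; plus duplicate-spectrum collapsing and the analog-parent
# co-occurrence statistic.
#
# A match table has one row per (drug entry, candidate analog spectrum)
# pair: query_id (drug library entry_id), target_id (analog spectrum_id),
# score, matched_peaks, mass_offset (analog precursor - drug precursor).

#' Source filter: drop analogs of endogenous- or food-sourced drugs
#'
#' Exposure to a drug that is also endogenous or dietary cannot be
#' established from its analogs, so all their matches are removed.
#'
#' @param matches Analog match tibble (`query_id` = drug entry id).
#' @param library Drug library tibble with `exposure_sources`.
#' @return The retained matches.
#' @export
source_filter <- function(matches, library) {
  matches <- tibble::as_tibble(matches)
  if (!nrow(matches)) return(matches)
  idx <- match(matches$query_id, library$entry_id)
  if (anyNA(idx)) {
    stop("unresolvable drug entries for match(es): ",
         paste(matches$query_id[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  src <- .split_sources(library$exposure_sources[idx])
  drop <- purrr::map_lgl(src, function(s) {
    any(c("endogenous", "food") %in% s)
  })
  matches[!drop, ]
}

#' Mass-offset filter: keep analogs with explainable precursor shifts
#'
#' A match is retained only when its mass offset lies within `tol` of some
#' entry of the curated offset table (common drug-metabolism deltas,
#' adducts, isotopes). Offsets are signed: a gain and a loss are distinct.
#'
#' @param matches Analog match tibble.
#' @param offsets Mass-offset table, e.g. [default_mass_offsets()].
#' @param tol Absolute matching tolerance, Da (> 0).
#' @return The retained matches.
#' @export
mass_offset_filter <- function(matches, offsets = default_mass_offsets(),
                               tol = 0.01) {
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0) {
    stop("`tol` must be a single positive number", call. = FALSE)
  }
  offsets <- tibble::as_tibble(offsets)
  if (!nrow(offsets)) stop("`offsets` must be non-empty", call. = FALSE)
  matches <- tibble::as_tibble(matches)
  if (!nrow(matches)) return(matches)
  keep <- vapply(matches$mass_offset, function(d) {
    any(abs(d - offsets$delta_mass) <= tol)
  }, logical(1))
  matches[keep, ]
}

#' Library-match filter: drop analogs explained by known compounds
#'
#' Analog spectra that match any entry of the full reference library at the
#' given thresholds (direct match: precursor difference within
#' `precursor_tol`) are removed — they are known compounds (often drugs of
#' the same pharmacologic family), not novel analogs.
#'
#' @param matches Analog match tibble.
#' @param analog_spectra Spectra tibble holding the analog spectra
#'   referenced by `matches$target_id`.
#' @param full_library Drug library tibble to screen against (non-empty).
#' @param score_thr,peaks_thr Match thresholds for exclusion.
#' @param precursor_tol,frag_tol m/z tolerances, Da.
#' @return The retained matches.
#' @export
library_match_filter <- function(matches, analog_spectra, full_library,
                                 score_thr = 0.7, peaks_thr = 6L,
                                 precursor_tol = 0.02, frag_tol = 0.02) {
  full_library <- validate_drug_library(full_library)
  if (!nrow(full_library)) {
    stop("`full_library` must be non-empty", call. = FALSE)
  }
  matches <- tibble::as_tibble(matches)
  if (!nrow(matches)) return(matches)
  analog_spectra <- validate_spectra(analog_spectra)
  ids <- unique(matches$target_id)
  i <- match(ids, analog_spectra$spectrum_id)
  if (anyNA(i)) {
    stop("analog spectra missing for: ",
         paste(ids[is.na(i)], collapse = ", "), call. = FALSE)
  }
  hit <- vapply(i, function(k) {
    q <- list(spectrum_id = analog_spectra$spectrum_id[k],
              precursor_mz = analog_spectra$precursor_mz[k],
              peaks = analog_spectra$peaks[[k]])
    cand <- which(abs(full_library$precursor_mz - q$precursor_mz) <=
                    precursor_tol)
    for (j in cand) {
      r <- modified_cosine(q, list(spectrum_id = full_library$entry_id[j],
                                   precursor_mz = full_library$precursor_mz[j],
                                   peaks = full_library$peaks[[j]]),
                           frag_tol = frag_tol)
      if (r$score >= score_thr && r$matched_peaks >= peaks_thr) return(TRUE)
    }
    FALSE
  }, logical(1))
  matches[!(matches$target_id %in% ids[hit]), ]
}

#' Frequency filter: drop implausibly ubiquitous analogs
#'
#' An analog detected above `max_frequency` in any test dataset cannot be
#' confidently linked to drug exposure (the drug would have to be used by
#' most of a general-population cohort) and is removed.
#'
#' @param matches Analog match tibble.
#' @param test_detections Tibble with `target_id`, `dataset_id`, `fraction`
#'   (detection fraction of the analog in that dataset, in \[0, 1\]).
#' @param max_frequency Maximum allowed detection fraction.
#' @return The retained matches; removed rows carry the offending dataset
#'   in the `"frequency_removals"` attribute.
#' @export
frequency_filter <- function(matches, test_detections,
                             max_frequency = 0.5) {
  test_detections <- tibble::as_tibble(test_detections)
  if (nrow(test_detections) &&
      (any(test_detections$fraction < 0) ||
       any(test_detections$fraction > 1))) {
    stop("detection fractions must lie in [0, 1]", call. = FALSE)
  }
  matches <- tibble::as_tibble(matches)
  if (!nrow(matches)) return(matches)
  offending <- test_detections[test_detections$fraction > max_frequency, ]
  keep <- !(matches$target_id %in% offending$target_id)
  out <- matches[keep, ]
  attr(out, "frequency_removals") <-
    offending[offending$target_id %in% matches$target_id,
              c("target_id", "dataset_id", "fraction")]
  out
}

#' Collapse near-duplicate analog spectra
#'
#' Greedy single-linkage grouping of analog spectra whose precursors lie
#' within `precursor_tol` and whose zero-offset modified cosine is at least
#' `min_score`; the highest-total-intensity spectrum represents each group.
#'
#' @param matches Analog match tibble.
#' @param analog_spectra Spectra tibble for `matches$target_id`.
#' @param precursor_tol Precursor grouping tolerance, Da.
#' @param min_score Similarity threshold for grouping.
#' @param frag_tol Fragment tolerance for the similarity, Da.
#' @return Matches restricted to representative spectra, with a
#'   `"dedup_map"` attribute (tibble `target_id` -> `representative`).
#' @export
dedup_analogs <- function(matches, analog_spectra, precursor_tol = 0.02,
                          min_score = 0.95, frag_tol = 0.02) {
  matches <- tibble::as_tibble(matches)
  if (!nrow(matches)) {
    attr(matches, "dedup_map") <- tibble::tibble(target_id = character(),
                                                 representative = character())
    return(matches)
  }
  analog_spectra <- validate_spectra(analog_spectra)
  ids <- unique(matches$target_id)
  sp <- analog_spectra[match(ids, analog_spectra$spectrum_id), ]
  n <- nrow(sp)
  comp <- seq_len(n)
  find <- function(k) { while (comp[k] != k) k <- comp[k]; k }
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b <= a) next
      if (abs(sp$precursor_mz[a] - sp$precursor_mz[b]) > precursor_tol) next
      # similarity at offset zero: compare as if equal precursors
      r <- modified_cosine(
        list(spectrum_id = sp$spectrum_id[a],
             precursor_mz = sp$precursor_mz[a], peaks = sp$peaks[[a]]),
        list(spectrum_id = sp$spectrum_id[b],
             precursor_mz = sp$precursor_mz[a], peaks = sp$peaks[[b]]),
        frag_tol = frag_tol)
      if (r$score >= min_score) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) comp[rb] <- ra
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  total_int <- purrr::map_dbl(sp$peaks, ~ sum(.x$intensity))
  rep_of_group <- tapply(seq_len(n), root, function(members) {
    members[order(-total_int[members], sp$spectrum_id[members])][1]
  })
  rep_idx <- rep_of_group[as.character(root)]
  map <- tibble::tibble(target_id = ids,
                        representative = ids[rep_idx])
  out <- matches[matches$target_id %in% unique(map$representative), ]
  attr(out, "dedup_map") <- map
  out
}

#' Run the full analog curation pipeline
#'
#' Applies the four filters (source, mass offset, library match, detection
#' frequency) and the duplicate collapse in sequence, and reports per-stage
#' removal counts. The four filters are pure per-match predicates, so their
#' order does not affect the retained set; the order used mirrors the
#' curation narrative.
#'
#' @param matches Raw analog match tibble.
#' @param library Drug library (for the source filter).
#' @param analog_spectra Spectra tibble for the analog spectra.
#' @param full_library Reference library for the library-match filter;
#'   defaults to `library`.
#' @param offsets Mass-offset table.
#' @param test_detections Detection-frequency table (see
#'   [frequency_filter()]); `NULL` skips the frequency stage.
#' @param offset_tol,max_frequency,dedup_min_score,precursor_tol,frag_tol
#'   Stage parameters.
#' @param lib_score_thr,lib_peaks_thr Library-match exclusion thresholds.
#' @return List with `matches` (curated tibble) and `report`
#'   (a `curation_report`).
#' @export
curate_analogs <- function(matches, library, analog_spectra,
                           full_library = library,
                           offsets = default_mass_offsets(),
                           test_detections = NULL, offset_tol = 0.01,
                           lib_score_thr = 0.7, lib_peaks_thr = 6L,
                           max_frequency = 0.5, dedup_min_score = 0.95,
                           precursor_tol = 0.02, frag_tol = 0.02) {
  matches <- tibble::as_tibble(matches)
  n0 <- nrow(matches)
  s1 <- source_filter(matches, library)
  s2 <- mass_offset_filter(s1, offsets, tol = offset_tol)
  s3 <- library_match_filter(s2, analog_spectra, full_library,
                             score_thr = lib_score_thr,
                             peaks_thr = lib_peaks_thr,
                             precursor_tol = precursor_tol,
                             frag_tol = frag_tol)
  if (is.null(test_detections)) {
    s4 <- s3
  } else {
    s4 <- frequency_filter(s3, test_detections,
                           max_frequency = max_frequency)
  }
  s5 <- dedup_analogs(s4, analog_spectra, precursor_tol = precursor_tol,
                      min_score = dedup_min_score, frag_tol = frag_tol)
  report <- structure(list(
    input_count = n0,
    removed_by_source = n0 - nrow(s1),
    removed_by_offset = nrow(s1) - nrow(s2),
    removed_by_library_match = nrow(s2) - nrow(s3),
    removed_by_frequency = nrow(s3) - nrow(s4),
    removed_as_duplicates = nrow(s4) - nrow(s5),
    retained_count = nrow(s5)
  ), class = "curation_report")
  list(matches = s5, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("<curation_report>\n")
  for (k in names(x)) cat(sprintf("  %-26s %d\n", k, x[[k]]))
  invisible(x)
}

#' Tidy a curation report
#' @param x A `curation_report`.
#' @param ... Unused.
#' @return Tibble with `stage` and `count`.
#' @method tidy curation_report
#' @export
tidy.curation_report <- function(x, ...) {
  tibble::tibble(stage = names(unclass(x)),
                 count = unlist(unclass(x), use.names = FALSE))
}

#' Analog-parent co-occurrence fraction
#'
#' The fraction of data files containing the analog that also contain its
#' parent drug — the statistic used to argue that propagated analogs track
#' real drug exposure.
#'
#' @param detections Presence table: tibble with `file_id`, `compound_id`
#'   (analog spectrum ids and parent drug names alike), and logical
#'   `detected` (optional; rows present are taken as detections).
#' @param analog_id Analog identifier.
#' @param parent_drug Parent drug identifier.
#' @return Fraction in \[0, 1\], or `NA` (with a warning) when the analog
#'   was never detected.
#' @export
cooccurrence_fraction <- function(detections, analog_id, parent_drug) {
  detections <- tibble::as_tibble(detections)
  if ("detected" %in% names(detections)) {
    detections <- detections[detections$detected, ]
  }
  files_analog <- unique(detections$file_id[
    detections$compound_id == analog_id])
  if (!length(files_analog)) {
    warning("analog never detected: ", analog_id)
    return(NA_real_)
  }
  files_parent <- unique(detections$file_id[
    detections$compound_id == parent_drug])
  length(intersect(files_analog, files_parent)) / length(files_analog)
}
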