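# Classification of curated analogs as isotopes, adducts, in-source
# fragments, or candidate derivatives: named mass offsets first, then
# XIC peak-shape correlation in co-occurring files, then MS/MS fragment
# evidence, with derivative as the default.

# Named ion-form spacings (Da): carbon isotopes and common cation adducts.
.named_offsets <- function() {
  tibble::tibble(
    name = c("isotope", "isotope", "adduct_Na", "adduct_Ca", "adduct_K"),
    delta = c(1.003355, 2.006710,
              adduct_offset("[M+Na]+", "[M+H]+"),
              adduct_offset("[M+Ca-H]+", "[M+H]+"),
              adduct_offset("[M+K]+", "[M+H]+"))
  )
}

#' Classify a mass offset against named isotope/adduct spacings
#'
#' @param delta Signed mass offset, Da (analog minus drug precursor).
#' @param tol Matching tolerance, Da (> 0).
#' @return One of `"isotope"`, `"adduct_Na"`, `"adduct_Ca"`, `"adduct_K"`,
#'   or `"none"` (nearest named spacing within `tol` wins).
#' @export
#' @examples
#' classify_by_mass_offset(1.0034)   # isotope
#' classify_by_mass_offset(21.982)   # adduct_Na
classify_by_mass_offset <- function(delta, tol = 0.01) {
  if (!is.numeric(tol) || tol <= 0) stop("`tol` must be > 0", call. = FALSE)
  tab <- .named_offsets()
  vapply(delta, function(d) {
    dist <- abs(d - tab$delta)
    i <- which.min(dist)
    if (dist[i] <= tol) tab$name[i] else "none"
  }, character(1))
}

#' Squared Pearson correlation of two XIC peak shapes
#'
#' Measures co-elution: ion forms of the same molecule share the
#' chromatographic profile of the parent, so their XIC intensity vectors
#' over the same scans correlate near-perfectly.
#'
#' @param trace_drug,trace_analog XIC traces: tibbles with `scan_index`
#'   and `intensity` (equal length, >= 3 points), or bare numeric vectors.
#' @return R-squared in \[0, 1\], or `NA` with a warning when either trace
#'   is constant (correlation undefined).
#' @export
peak_shape_correlation <- function(trace_drug, trace_analog) {
  v1 <- if (is.numeric(trace_drug)) trace_drug else trace_drug$intensity
  v2 <- if (is.numeric(trace_analog)) trace_analog else trace_analog$intensity
  if (length(v1) != length(v2)) {
    stop("traces must have equal length", call. = FALSE)
  }
  if (length(v1) < 3L) {
    stop("traces must have at least 3 scans", call. = FALSE)
  }
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    warning("constant XIC trace: correlation undefined")
    return(NA_real_)
  }
  stats::cor(v1, v2)^2
}

#' MS/MS fragment evidence for adducts and in-source fragments
#'
#' An analog with a higher precursor than the drug whose MS/MS contains a
#' fragment at the drug's precursor m/z is an adduct; an analog with a
#' lower precursor equal to one of the drug's fragment m/z values is an
#' in-source fragment. No intensity filtering is applied.
#'
#' @param drug,analog Spectra (one-row spectra tibbles or lists with
#'   `precursor_mz` and `peaks`).
#' @param tol Fragment m/z tolerance, Da.
#' @return `"adduct"`, `"in_source_fragment"`, or `"none"`.
#' @export
fragment_evidence <- function(drug, analog, tol = 0.02) {
  drug <- .as_spec(drug); analog <- .as_spec(analog)
  if (analog$precursor_mz > drug$precursor_mz) {
    if (nrow(analog$peaks) &&
        any(abs(analog$peaks$mz - drug$precursor_mz) <= tol)) {
      return("adduct")
    }
  } else if (analog$precursor_mz < drug$precursor_mz) {
    if (nrow(drug$peaks) &&
        any(abs(drug$peaks$mz - analog$precursor_mz) <= tol)) {
      return("in_source_fragment")
    }
  }
  "none"
}

#' Classify the ion form of a drug-analog pair
#'
#' The decision procedure, in order: (1) named mass-offset spacings
#' (isotopes, Na/Ca/K adducts); (2) when the pair co-occurs in data files,
#' the maximum XIC peak-shape R-squared across files — above
#' `r2_threshold` the analog is an analytical artifact (adduct for a
#' positive offset, in-source fragment for a negative one), otherwise a
#' derivative; (3) with no co-occurrence, MS/MS fragment evidence;
#' (4) default: derivative. The boundary R-squared equal to the threshold
#' classifies as derivative.
#'
#' @param pair One-row tibble or list with `mass_offset` and optionally
#'   `query_id`/`target_id`.
#' @param cooccurring_traces List of `list(drug = trace, analog = trace)`
#'   XIC trace pairs, one per co-occurring file (may be empty).
#' @param drug_spectrum,analog_spectrum Spectra for the fragment-evidence
#'   stage (may be `NULL` when traces exist).
#' @param r2_threshold Artifact threshold on the maximum R-squared.
#' @param offset_tol Tolerance for the named-offset stage, Da.
#' @return One-row tibble: `label` (isotope/adduct/in_source_fragment/
#'   derivative), `evidence` (mass_offset/peak_shape/fragment_match/
#'   default), `detail` (adduct name or max R-squared).
#' @export
classify_ion_form <- function(pair, cooccurring_traces = list(),
                              drug_spectrum = NULL, analog_spectrum = NULL,
                              r2_threshold = 0.9, offset_tol = 0.01) {
  offset <- pair$mass_offset
  res <- function(label, evidence, detail = NA_character_) {
    tibble::tibble(label = label, evidence = evidence, detail = detail)
  }
  named <- classify_by_mass_offset(offset, tol = offset_tol)
  if (named == "isotope") {
    return(res("isotope", "mass_offset", "isotope spacing"))
  }
  if (startsWith(named, "adduct_")) {
    return(res("adduct", "mass_offset", sub("adduct_", "", named)))
  }
  if (length(cooccurring_traces)) {
    r2 <- purrr::map_dbl(cooccurring_traces, function(tr) {
      suppressWarnings(peak_shape_correlation(tr$drug, tr$analog))
    })
    max_r2 <- suppressWarnings(max(r2, na.rm = TRUE))
    if (is.finite(max_r2)) {
      detail <- sprintf("max R2 = %.4f", max_r2)
      if (max_r2 > r2_threshold) {
        lab <- if (offset > 0) "adduct" else "in_source_fragment"
        return(res(lab, "peak_shape", detail))
      }
      return(res("derivative", "peak_shape", detail))
    }
  }
  if (!is.null(drug_spectrum) && !is.null(analog_spectrum)) {
    fe <- fragment_evidence(drug_spectrum, analog_spectrum)
    if (fe != "none") return(res(fe, "fragment_match"))
  }
  res("derivative", "default")
}

#' Classify many analog pairs at once
#'
#' Vectorized driver over a curated match table: looks up XIC trace pairs
#' and spectra per match and calls [classify_ion_form()].
#'
#' @param matches Curated analog match tibble (`query_id`, `target_id`,
#'   `mass_offset`).
#' @param traces_by_match Named list (by `target_id`) of trace-pair lists,
#'   as accepted by [classify_ion_form()].
#' @param drug_spectra,analog_spectra Spectra tibbles for the
#'   fragment-evidence stage (drug spectra keyed by `query_id`).
#' @param r2_threshold,offset_tol Passed through.
#' @return `matches` with `label`, `evidence`, `detail` columns appended.
#' @export
classify_ion_forms <- function(matches, traces_by_match = list(),
                               drug_spectra = NULL, analog_spectra = NULL,
                               r2_threshold = 0.9, offset_tol = 0.01) {
  matches <- tibble::as_tibble(matches)
  lab <- purrr::map_dfr(seq_len(nrow(matches)), function(i) {
    tid <- matches$target_id[i]
    ds <- if (!is.null(drug_spectra)) {
      j <- match(matches$query_id[i], drug_spectra$spectrum_id)
      if (!is.na(j)) drug_spectra[j, ] else NULL
    }
    as_ <- if (!is.null(analog_spectra)) {
      j <- match(tid, analog_spectra$spectrum_id)
      if (!is.na(j)) analog_spectra[j, ] else NULL
    }
    classify_ion_form(matches[i, ],
                      cooccurring_traces = traces_by_match[[tid]] %||% list(),
                      drug_spectrum = ds, analog_spectrum = as_,
                      r2_threshold = r2_threshold, offset_tol = offset_tol)
  })
  dplyr::bind_cols(matches, lab)
}
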