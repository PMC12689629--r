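# Drug library data model: reference entries with controlled-vocabulary
# pharmacologic metadata, identifier/name matching, and parent-metadata
# inheritance for metabolites and propagated analogs.
#
# A drug library is a tibble with one row per reference entry. Spectrum
# columns (precursor_mz, rt, peaks) follow the spectra-tibble convention;
# metadata columns hold the controlled vocabularies.

.metadata_cols <- c("exposure_sources", "therapeutic_area",
                    "pharmacologic_class", "therapeutic_indication",
                    "mechanism_of_action", "clinical_phase")

#' Exposure-source controlled vocabulary
#'
#' The five exposure-source categories attached to every curated drug;
#' multiple sources are stored as a single `";"`-separated string.
#'
#' @return Character vector of allowed values.
#' @export
exposure_source_vocabulary <- function() {
  c("medical", "endogenous", "food", "personal care", "industrial")
}

.split_sources <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE), trimws)
}

#' Validate a drug library tibble
#'
#' Enforces the entry invariants: unique `entry_id`; `annotation_type` in
#' drug/metabolite/analog; drugs are their own parent; analogs carry a
#' `mass_offset`; InChIKeys, when present, match the 14-10-1 block pattern;
#' exposure sources drawn from [exposure_source_vocabulary()].
#'
#' @param lib A drug library tibble.
#' @return `lib` as a tibble.
#' @export
validate_drug_library <- function(lib) {
  lib <- tibble::as_tibble(lib)
  need <- c("entry_id", "compound_name", "parent_drug", "annotation_type",
            "precursor_mz", "peaks")
  miss <- setdiff(need, names(lib))
  if (length(miss)) {
    stop("drug library missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(lib$entry_id)) {
    stop("duplicate entry_id values in drug library", call. = FALSE)
  }
  bad_type <- setdiff(unique(lib$annotation_type),
                      c("drug", "metabolite", "analog"))
  if (length(bad_type)) {
    stop("unknown annotation_type: ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  is_drug <- lib$annotation_type == "drug"
  if (any(lib$parent_drug[is_drug] != lib$compound_name[is_drug])) {
    stop("entries with annotation_type 'drug' must have parent_drug equal ",
         "to compound_name", call. = FALSE)
  }
  if ("mass_offset" %in% names(lib)) {
    if (any(lib$annotation_type == "analog" & !is.finite(lib$mass_offset))) {
      stop("analog entries must carry a finite mass_offset", call. = FALSE)
    }
  } else if (any(lib$annotation_type == "analog")) {
    stop("analog entries require a mass_offset column", call. = FALSE)
  }
  if ("inchikey" %in% names(lib)) {
    ik <- lib$inchikey[!is.na(lib$inchikey) & nzchar(lib$inchikey)]
    ok <- grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", ik)
    if (!all(ok)) {
      stop("malformed InChIKey(s): ", paste(ik[!ok], collapse = ", "),
           call. = FALSE)
    }
  }
  if ("exposure_sources" %in% names(lib)) {
    vals <- unlist(.split_sources(lib$exposure_sources))
    bad <- setdiff(setdiff(unique(vals), ""), exposure_source_vocabulary())
    if (length(bad)) {
      stop("exposure source(s) outside the controlled vocabulary: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  lib
}

#' Match a query identifier against a compound registry
#'
#' Ranks hits in three tiers: exact full-InChIKey matches first, then
#' first-block (stereochemistry-stripped) InChIKey matches, then
#' case-insensitive synonym matches. Within a tier, registry order is
#' preserved, so results are deterministic.
#'
#' @param query A full InChIKey, an InChIKey first block (14 characters),
#'   or a compound synonym.
#' @param registry Tibble with columns `inchikey` and `synonyms`
#'   (`";"`-separated string or list-column).
#' @return Registry rows matched, with a `match_type` column
#'   (`exact_inchikey`, `inchikey_block1`, `synonym`) and `exact` flag.
#' @export
match_identifier <- function(query, registry) {
  if (!is.character(query) || length(query) != 1L || !nzchar(trimws(query))) {
    stop("`query` must be a non-empty string", call. = FALSE)
  }
  registry <- tibble::as_tibble(registry)
  query <- trimws(query)
  syn <- registry$synonyms
  if (!is.list(syn)) syn <- .split_sources(syn)
  syn_hit <- purrr::map_lgl(syn, function(s) tolower(query) %in% tolower(s))
  ik <- ifelse(is.na(registry$inchikey), "", registry$inchikey)
  exact_hit <- ik == query
  q_block <- sub("-.*$", "", query)
  block_hit <- grepl("^[A-Z]{14}$", q_block) &
    sub("-.*$", "", ik) == q_block & !exact_hit
  tier <- function(rows, type) {
    out <- registry[rows, , drop = FALSE]
    out$match_type <- type
    out$exact <- type == "exact_inchikey"
    out
  }
  dplyr::bind_rows(
    tier(which(exact_hit), "exact_inchikey"),
    tier(which(block_hit), "inchikey_block1"),
    tier(which(syn_hit & !exact_hit & !block_hit), "synonym")
  )
}

#' Partial-name matching for drug metabolites
#'
#' Returns the candidate names that contain the drug name as a
#' case-insensitive substring, excluding the exact name itself — the rule
#' used to sweep up named metabolites (e.g. "N-desmethylvenlafaxine" for
#' "venlafaxine").
#'
#' @param drug_name Non-empty drug name.
#' @param candidate_names Character vector of candidate compound names.
#' @return The matching subset of `candidate_names`.
#' @export
partial_name_match <- function(drug_name, candidate_names) {
  if (!is.character(drug_name) || length(drug_name) != 1L ||
      !nzchar(.norm_name(drug_name))) {
    stop("`drug_name` must be a non-empty string", call. = FALSE)
  }
  if (!length(candidate_names)) return(character())
  q <- .norm_name(drug_name)
  cand <- .norm_name(candidate_names)
  candidate_names[grepl(q, cand, fixed = TRUE) & cand != q]
}

# lower-case, trim, collapse internal whitespace
.norm_name <- function(x) {
  gsub("[[:space:]]+", " ", trimws(tolower(x)))
}

#' Inherit parent-drug metadata onto metabolites and analogs
#'
#' Copies the parent drug's pharmacologic metadata (exposure sources,
#' therapeutic area, pharmacologic class, therapeutic indication, mechanism
#' of action, clinical phase) verbatim onto every metabolite and analog
#' entry. Drug entries and annotation types are unchanged; the operation is
#' idempotent.
#'
#' @param lib A drug library tibble containing both the child entries and
#'   their parent drug entries.
#' @return `lib` with metadata columns filled for metabolites/analogs.
#' @export
inherit_metadata <- function(lib) {
  lib <- validate_drug_library(lib)
  parents <- lib[lib$annotation_type == "drug", ]
  child <- lib$annotation_type %in% c("metabolite", "analog")
  idx <- match(lib$parent_drug[child], parents$compound_name)
  if (anyNA(idx)) {
    orphan <- lib$entry_id[child][is.na(idx)]
    stop("unresolved parent drug for entries: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  for (col in intersect(.metadata_cols, names(lib))) {
    lib[[col]][child] <- parents[[col]][idx]
  }
  lib
}

#' Report library entries without pharmacologic metadata
#'
#' Withdrawn or never-marketed drugs may legitimately lack metadata; this
#' report makes them explicit rather than silently incomplete.
#'
#' @param lib A drug library tibble.
#' @return Tibble of entries whose `exposure_sources` is empty or missing.
#' @export
no_metadata_report <- function(lib) {
  lib <- tibble::as_tibble(lib)
  src <- if ("exposure_sources" %in% names(lib)) lib$exposure_sources
         else rep(NA_character_, nrow(lib))
  lib[is.na(src) | !nzchar(src),
      intersect(c("entry_id", "compound_name", "annotation_type"),
                names(lib))]
}

#' Write a drug library to disk (MGF + metadata CSV)
#'
#' Mirrors the deposited library layout: an MGF file holding the reference
#' spectra (TITLE = entry_id) and a CSV with one metadata row per entry.
#'
#' @param lib A drug library tibble.
#' @param mgf_path,csv_path Output paths.
#' @return `csv_path`, invisibly.
#' @export
write_drug_library <- function(lib, mgf_path, csv_path) {
  lib <- validate_drug_library(lib)
  sp <- spectra_tbl(lib$entry_id, lib$precursor_mz, lib$peaks,
                    rt = if ("rt" %in% names(lib)) lib$rt else NA_real_)
  write_mgf(sp, mgf_path)
  meta <- lib[, setdiff(names(lib), c("peaks", "precursor_mz", "rt"))]
  readr::write_csv(meta, csv_path)
  invisible(csv_path)
}

#' Read a drug library from disk (MGF + metadata CSV)
#'
#' @param mgf_path,csv_path Paths written by [write_drug_library()].
#' @return A validated drug library tibble.
#' @export
read_drug_library <- function(mgf_path, csv_path) {
  sp <- read_mgf(mgf_path)
  meta <- readr::read_csv(csv_path, show_col_types = FALSE)
  if (!"entry_id" %in% names(meta)) {
    stop("library metadata must have an entry_id column", call. = FALSE)
  }
  i <- match(meta$entry_id, sp$spectrum_id)
  if (anyNA(i)) {
    stop("metadata entries without spectra: ",
         paste(meta$entry_id[is.na(i)], collapse = ", "), call. = FALSE)
  }
  meta$precursor_mz <- sp$precursor_mz[i]
  meta$rt <- sp$rt[i]
  meta$peaks <- sp$peaks[i]
  validate_drug_library(meta)
}

#' Spectra tibble view of a drug library
#'
#' @param lib A drug library tibble.
#' @return Spectra tibble with `spectrum_id = entry_id`.
#' @export
library_spectra <- function(lib) {
  spectra_tbl(lib$entry_id, lib$precursor_mz, lib$peaks,
              rt = if ("rt" %in% names(lib)) lib$rt else NA_real_)
}
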