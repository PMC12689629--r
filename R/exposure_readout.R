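# From annotated feature tables to per-sample drug exposure records:
# blank filtering, noise flooring, parent-drug grouping, removal of
# endogenous/food-sourced drugs, ontology-level summaries, and
# demographic normalization.

#' Blank filter for feature tables
#'
#' Drops features whose mean peak area across non-blank samples is below
#' `fold` times the mean area in blanks; in retained features, a cell
#' counts as detected only when its area exceeds `fold` times the blank
#' mean.
#'
#' @param ft A [feature_table()] with at least one blank sample.
#' @param fold Fold-change threshold over the blank mean.
#' @return The filtered `feature_table` (blank columns retained, detection
#'   flags updated).
#' @export
blank_filter <- function(ft, fold = 3) {
  stopifnot(inherits(ft, "feature_table"))
  blanks <- ft$samples$sample_id[ft$samples$is_blank]
  if (!length(blanks)) {
    stop("blank_filter requires at least one blank sample; disable the ",
         "filter (--no-blank-filter) if none exist", call. = FALSE)
  }
  samples <- setdiff(ft$samples$sample_id, blanks)
  a <- as.matrix(ft$areas[, c(samples, blanks), drop = FALSE])
  blank_mean <- rowMeans(a[, blanks, drop = FALSE])
  sample_mean <- rowMeans(a[, samples, drop = FALSE])
  keep <- sample_mean >= fold * blank_mean
  features <- ft$features[keep, ]
  areas <- ft$areas[keep, ]
  detected <- areas
  thr <- fold * blank_mean[keep]
  for (s in samples) detected[[s]] <- areas[[s]] > thr
  for (s in blanks) detected[[s]] <- FALSE
  feature_table(features, areas, ft$samples, detected = detected)
}

#' Noise floor for feature tables
#'
#' Replaces peak areas below `floor` with zero to suppress detections at
#' instrument-noise level; detection flags are re-derived where the area
#' was zeroed.
#'
#' @param ft A [feature_table()].
#' @param floor Noise floor in area units (>= 0).
#' @return The floored `feature_table`.
#' @export
noise_floor <- function(ft, floor = 1e4) {
  stopifnot(inherits(ft, "feature_table"))
  if (!is.numeric(floor) || floor < 0) {
    stop("`floor` must be >= 0", call. = FALSE)
  }
  areas <- ft$areas
  detected <- ft$detected
  for (s in ft$samples$sample_id) {
    zeroed <- areas[[s]] < floor
    areas[[s]][zeroed] <- 0
    detected[[s]][zeroed] <- FALSE
  }
  feature_table(ft$features, areas, ft$samples, detected = detected)
}

#' Group annotations by parent drug into an exposure table
#'
#' Collapses drug, metabolite, and analog annotations onto the parent
#' drug: per sample and parent, areas are summed over all annotated member
#' features and the drug counts as detected when any member is detected —
#' so an analog-only detection still flags exposure to the parent.
#'
#' @param ft A [feature_table()] (post-filtering).
#' @param annotations Tibble linking features to library entries: columns
#'   `feature_id` and `entry_id` (typically accepted [library_search()]
#'   hits joined to feature ids).
#' @param library Drug library tibble resolving `entry_id` to
#'   `parent_drug`.
#' @return An `exposure_table`: long tibble with `sample_id`,
#'   `parent_drug`, `summed_area`, `detected` (class `exposure_table`),
#'   non-blank samples only.
#' @export
group_by_parent <- function(ft, annotations, library) {
  stopifnot(inherits(ft, "feature_table"))
  annotations <- tibble::as_tibble(annotations)
  empty <- tibble::tibble(sample_id = character(),
                          parent_drug = character(),
                          summed_area = numeric(), detected = logical())
  if (!nrow(annotations)) {
    return(structure(empty, class = c("exposure_table", class(empty))))
  }
  idx <- match(annotations$entry_id, library$entry_id)
  if (anyNA(idx)) {
    stop("unresolvable library entries: ",
         paste(unique(annotations$entry_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  annotations$parent_drug <- library$parent_drug[idx]
  long <- tidy.feature_table(ft)
  long <- long[long$sample_id %in%
                 ft$samples$sample_id[!ft$samples$is_blank], ]
  joined <- dplyr::inner_join(long,
                              annotations[, c("feature_id", "parent_drug")],
                              by = "feature_id",
                              relationship = "many-to-many")
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$sample_id, .data$parent_drug),
    summed_area = sum(.data$area),
    detected = any(.data$detected & .data$area > 0),
    .groups = "drop"
  )
  structure(out, class = c("exposure_table", class(out)))
}

#' Drop drugs with endogenous or food sources from an exposure table
#'
#' Exposure to drugs that are also endogenous or dietary cannot be
#' interpreted as medication, so their columns are removed; the removals
#' are returned as an attribute for reporting.
#'
#' @param et An `exposure_table`.
#' @param library Drug library with `exposure_sources` (parent drug rows).
#' @return The filtered `exposure_table` with a `"removed_drugs"`
#'   attribute.
#' @export
exclude_nonmedical <- function(et, library) {
  drugs <- unique(et$parent_drug)
  parents <- library[library$annotation_type == "drug", ]
  src <- .split_sources(parents$exposure_sources[
    match(drugs, parents$compound_name)])
  is_nonmed <- purrr::map_lgl(src, function(s) {
    any(c("endogenous", "food") %in% s)
  })
  removed <- drugs[is_nonmed]
  out <- et[!(et$parent_drug %in% removed), ]
  attr(out, "removed_drugs") <- removed
  structure(out, class = unique(c("exposure_table", class(out))))
}

.ontology_levels <- c("drug", "pharmacologic_class", "therapeutic_area",
                      "indication", "mechanism")

#' Summarize an exposure table at an ontology level
#'
#' Per sample, collects the distinct values of the requested metadata
#' level among detected drugs — each pharmacologic class (area, indication,
#' mechanism) counts once per individual no matter how many of its drugs
#' were detected. Drugs without metadata at the level go to an
#' `"unclassified"` bucket with a warning.
#'
#' @param et An `exposure_table`.
#' @param library Drug library carrying the metadata (parent drug rows).
#' @param level One of `"drug"`, `"pharmacologic_class"`,
#'   `"therapeutic_area"`, `"indication"`, `"mechanism"`.
#' @return Tibble with `sample_id`, `level_value`, `n_drugs` (distinct
#'   detected drugs behind the value).
#' @export
summarize_ontology <- function(et, library, level = "pharmacologic_class") {
  level <- match.arg(level, .ontology_levels)
  det <- et[et$detected, ]
  if (level == "drug") {
    out <- dplyr::distinct(tibble::tibble(sample_id = det$sample_id,
                                          level_value = det$parent_drug))
    out$n_drugs <- 1L
    return(out)
  }
  col <- switch(level,
                pharmacologic_class = "pharmacologic_class",
                therapeutic_area = "therapeutic_area",
                indication = "therapeutic_indication",
                mechanism = "mechanism_of_action")
  parents <- library[library$annotation_type == "drug", ]
  vals <- parents[[col]][match(det$parent_drug, parents$compound_name)]
  missing <- is.na(vals) | !nzchar(vals)
  if (any(missing)) {
    warning(sum(missing), " detection(s) without ", level,
            " metadata routed to 'unclassified'")
    vals[missing] <- "unclassified"
  }
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(sample_id = det$sample_id,
                                   level_value = vals,
                                   drug = det$parent_drug),
                    .data$sample_id, .data$level_value),
    n_drugs = dplyr::n_distinct(.data$drug), .groups = "drop")
}

#' Demographic normalization of detection counts
#'
#' Divides, within every (age bin, sex) group, the number of individuals
#' with a detection of each ontology value by the group size, yielding
#' comparable detection rates across demographic strata. Age bins are
#' 10-year intervals from 0 to 90; samples outside the range or with
#' missing demographics are excluded and reported.
#'
#' @param summary Output of [summarize_ontology()].
#' @param samples Sample metadata tibble with `sample_id`, `age`, `sex`.
#' @return Tibble with `age_bin`, `sex`, `level_value`, `n_detected`,
#'   `group_size`, `rate`; excluded samples in the `"excluded_samples"`
#'   attribute.
#' @export
demographic_normalize <- function(summary, samples) {
  samples <- tibble::as_tibble(samples)
  ok <- !is.na(samples$age) & !is.na(samples$sex) &
    samples$age >= 0 & samples$age <= 90
  excluded <- samples$sample_id[!ok]
  samples <- samples[ok, ]
  breaks <- seq(0, 90, by = 10)
  samples$age_bin <- cut(samples$age, breaks = breaks, right = FALSE,
                         include.lowest = TRUE,
                         labels = paste(head(breaks, -1), breaks[-1] - 1,
                                        sep = "-"))
  sizes <- dplyr::count(samples, .data$age_bin, .data$sex,
                        name = "group_size")
  det <- dplyr::inner_join(summary,
                           samples[, c("sample_id", "age_bin", "sex")],
                           by = "sample_id")
  counts <- dplyr::summarise(
    dplyr::group_by(det, .data$age_bin, .data$sex, .data$level_value),
    n_detected = dplyr::n_distinct(.data$sample_id), .groups = "drop")
  out <- dplyr::left_join(counts, sizes, by = c("age_bin", "sex"))
  out$rate <- out$n_detected / out$group_size
  attr(out, "excluded_samples") <- excluded
  out
}
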