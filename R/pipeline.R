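# End-to-end pipeline driver: runs an ordered subset of stages over a
# working directory of CSV/MGF artifacts and emits a machine-readable run
# report (config echo, per-stage input/output counts, wall clock,
# warnings) sufficient to reproduce the run.

.pipeline_stages <- c("simulate", "search", "curate", "ionform", "readout",
                      "stratify")

.stage_paths <- function(workdir) {
  p <- function(...) file.path(workdir, ...)
  list(
    library_mgf = p("library.mgf"), library_csv = p("library.csv"),
    spectra_mgf = p("cohort_spectra.mgf"),
    features_csv = p("features.csv"), samples_csv = p("samples.csv"),
    ms1_csv = p("ms1_scans.csv"), truth_json = p("ground_truth.json"),
    annotations_csv = p("annotations.csv"),
    analog_matches_csv = p("analog_matches.csv"),
    curated_csv = p("curated_matches.csv"),
    curation_json = p("curation_report.json"),
    labels_csv = p("ion_form_labels.csv"),
    exposure_csv = p("exposure.csv"),
    summary_csv = p("ontology_summary.csv"),
    clusters_csv = p("clusters.csv"),
    report_json = p("run_report.json")
  )
}

.require_inputs <- function(paths, stage) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("stage '", stage, "' is missing input file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Run an ordered subset of pipeline stages
#'
#' Stages (in their canonical order `simulate`, `search`, `curate`,
#' `ionform`, `readout`, `stratify`) read and write plain-text artifacts
#' under `config$workdir`; each stage's inputs must exist on disk or be
#' produced by an earlier stage of the same run.
#'
#' * `simulate` — generate the synthetic library, cohort, and MS1 runs.
#' * `search` — two-tier library search of the cohort spectra plus analog
#'   search of the drug spectra against the cohort.
#' * `curate` — the four-filter analog curation with report.
#' * `ionform` — ion-form classification of curated analogs.
#' * `readout` — blank filter, noise floor, parent grouping, removal of
#'   endogenous/food drugs, ontology summary.
#' * `stratify` — hierarchical clustering of exposure profiles.
#'
#' @param stages Character vector, subset of the stage names.
#' @param config Configuration from [resolve_config()].
#' @return A `pipeline_report` (also written to `run_report.json`).
#' @export
pipeline_run <- function(stages, config = resolve_config()) {
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  wd <- config$workdir
  if (!dir.exists(wd)) dir.create(wd, recursive = TRUE)
  paths <- .stage_paths(wd)
  report <- list(
    package_version = as.character(utils::packageVersion("drugtrace")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config, stages = list())
  run_stage <- function(name, fn) {
    t0 <- Sys.time()
    warns <- character()
    counts <- withCallingHandlers(fn(), warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    report$stages[[name]] <<- list(
      counts = counts, warnings = warns,
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  for (stage in stages) {
    switch(stage,
      simulate = run_stage("simulate", function() {
        gl <- generate_library(seed = config$seed)
        co <- generate_cohort(gl, seed = config$seed + 1)
        ms1 <- generate_ms1_runs(co, seed = config$seed + 2)
        write_drug_library(gl$library, paths$library_mgf, paths$library_csv)
        write_mgf(co$spectra, paths$spectra_mgf)
        write_feature_table(co$feature_table, paths$features_csv,
                            paths$samples_csv)
        readr::write_csv(ms1, paths$ms1_csv)
        truth <- co$ground_truth
        jsonlite::write_json(
          list(seed = config$seed, params = truth$params,
               exposures = truth$exposures, ion_forms = truth$ion_forms),
          paths$truth_json, auto_unbox = TRUE, digits = NA)
        list(library_entries = nrow(gl$library),
             cohort_spectra = nrow(co$spectra),
             features = nrow(co$feature_table$features))
      }),
      search = run_stage("search", function() {
        .require_inputs(c(paths$library_mgf, paths$library_csv,
                          paths$spectra_mgf), "search")
        lib <- read_drug_library(paths$library_mgf, paths$library_csv)
        sp <- read_mgf(paths$spectra_mgf)
        ann <- library_search(
          sp, lib, precursor_tol = config$precursor_tol,
          frag_tol = config$frag_tol,
          search_min_score = config$search_min_score,
          search_min_peaks = config$search_min_peaks,
          accept_min_score = config$accept_min_score,
          accept_min_peaks = config$accept_min_peaks)
        readr::write_csv(ann, paths$annotations_csv)
        drug_entries <- lib[lib$annotation_type == "drug", ]
        analog <- purrr::map_dfr(seq_len(nrow(drug_entries)), function(i) {
          analog_search(
            list(spectrum_id = drug_entries$entry_id[i],
                 precursor_mz = drug_entries$precursor_mz[i],
                 peaks = drug_entries$peaks[[i]]),
            sp, precursor_window = config$analog_window,
            min_score = config$analog_min_score,
            min_peaks = config$analog_min_peaks,
            frag_tol = config$frag_tol)
        })
        analog <- analog[abs(analog$mass_offset) > config$precursor_tol, ]
        readr::write_csv(analog, paths$analog_matches_csv)
        list(annotations = nrow(ann), accepted = sum(ann$accepted),
             analog_matches = nrow(analog))
      }),
      curate = run_stage("curate", function() {
        .require_inputs(c(paths$analog_matches_csv, paths$library_mgf,
                          paths$library_csv, paths$spectra_mgf), "curate")
        lib <- read_drug_library(paths$library_mgf, paths$library_csv)
        sp <- read_mgf(paths$spectra_mgf)
        matches <- readr::read_csv(paths$analog_matches_csv,
                                   show_col_types = FALSE)
        cur <- curate_analogs(
          matches, lib, sp, offset_tol = config$offset_tol,
          max_frequency = config$max_frequency,
          dedup_min_score = config$dedup_min_score,
          precursor_tol = config$precursor_tol,
          frag_tol = config$frag_tol)
        readr::write_csv(cur$matches, paths$curated_csv)
        jsonlite::write_json(unclass(cur$report), paths$curation_json,
                             auto_unbox = TRUE)
        as.list(unclass(cur$report))
      }),
      ionform = run_stage("ionform", function() {
        .require_inputs(c(paths$curated_csv, paths$ms1_csv,
                          paths$features_csv, paths$samples_csv,
                          paths$library_mgf, paths$library_csv,
                          paths$spectra_mgf), "ionform")
        lib <- read_drug_library(paths$library_mgf, paths$library_csv)
        sp <- read_mgf(paths$spectra_mgf)
        matches <- readr::read_csv(paths$curated_csv,
                                   show_col_types = FALSE)
        ft <- read_feature_table(paths$features_csv, paths$samples_csv)
        ms1 <- readr::read_csv(paths$ms1_csv, show_col_types = FALSE)
        pairs <- .cooccurrence_pairs(matches, ft, lib,
                                     config$precursor_tol)
        traces <- xic_pair_traces(ms1, pairs, tol = config$xic_tol)
        labels <- classify_ion_forms(
          matches, traces_by_match = traces,
          drug_spectra = library_spectra(lib), analog_spectra = sp,
          r2_threshold = config$r2_threshold,
          offset_tol = config$offset_tol)
        readr::write_csv(labels, paths$labels_csv)
        as.list(table(labels$label))
      }),
      readout = run_stage("readout", function() {
        .require_inputs(c(paths$annotations_csv, paths$features_csv,
                          paths$samples_csv, paths$library_mgf,
                          paths$library_csv), "readout")
        lib <- read_drug_library(paths$library_mgf, paths$library_csv)
        ft <- read_feature_table(paths$features_csv, paths$samples_csv)
        ann <- readr::read_csv(paths$annotations_csv,
                               show_col_types = FALSE)
        ann <- ann[ann$accepted & ann$is_best, ]
        ann <- dplyr::left_join(
          ann, ft$features[, c("feature_id", "ms2_spectrum_id")],
          by = c(spectrum_id = "ms2_spectrum_id"))
        ann <- ann[!is.na(ann$feature_id), ]
        ft <- noise_floor(blank_filter(ft, fold = config$blank_fold),
                          floor = config$noise_floor)
        et <- group_by_parent(ft, ann, lib)
        et <- exclude_nonmedical(et, lib)
        readr::write_csv(tibble::as_tibble(et), paths$exposure_csv)
        summ <- summarize_ontology(et, lib, level = config$ontology_level)
        readr::write_csv(summ, paths$summary_csv)
        list(exposure_rows = nrow(et),
             drugs = dplyr::n_distinct(et$parent_drug),
             removed_nonmedical = length(attr(et, "removed_drugs")))
      }),
      stratify = run_stage("stratify", function() {
        .require_inputs(paths$exposure_csv, "stratify")
        et <- readr::read_csv(paths$exposure_csv, show_col_types = FALSE)
        class(et) <- c("exposure_table", class(et))
        cl <- cluster_samples(et, k = config$cluster_k)
        readr::write_csv(tibble::as_tibble(cl), paths$clusters_csv)
        as.list(table(paste0("cluster_", cl$cluster)))
      })
    )
  }
  inputs <- list.files(wd, pattern = "\\.(csv|mgf)$", full.names = TRUE)
  report$input_hashes <- as.list(tools::md5sum(inputs))
  report <- structure(report, class = "pipeline_report")
  jsonlite::write_json(unclass(report), paths$report_json,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  report
}

# parent/analog feature lookup for co-occurrence tracing: the analog
# feature is found through its MS2 link, the parent feature by precursor
# proximity to the drug entry (largest total area on ties).
.cooccurrence_pairs <- function(matches, ft, lib, precursor_tol) {
  long <- tidy.feature_table(ft)
  present <- long[long$area > 0, ]
  total <- dplyr::summarise(dplyr::group_by(long, .data$feature_id),
                            total = sum(.data$area), .groups = "drop")
  out <- list()
  for (i in seq_len(nrow(matches))) {
    tid <- matches$target_id[i]
    af <- ft$features$feature_id[
      !is.na(ft$features$ms2_spectrum_id) &
        ft$features$ms2_spectrum_id == tid]
    if (!length(af)) next
    qprec <- lib$precursor_mz[match(matches$query_id[i], lib$entry_id)]
    cand <- ft$features$feature_id[
      abs(ft$features$mz - qprec) <= precursor_tol]
    if (!length(cand)) next
    pf <- cand[order(-total$total[match(cand, total$feature_id)])][1]
    both <- intersect(present$sample_id[present$feature_id == af[1]],
                      present$sample_id[present$feature_id == pf])
    if (!length(both)) next
    out[[length(out) + 1L]] <- tibble::tibble(
      target_id = tid, sample_id = both,
      parent_mz = ft$features$mz[ft$features$feature_id == pf],
      analog_mz = ft$features$mz[ft$features$feature_id == af[1]])
  }
  if (!length(out)) {
    return(tibble::tibble(target_id = character(), sample_id = character(),
                          parent_mz = numeric(), analog_mz = numeric()))
  }
  dplyr::bind_rows(out)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> drugtrace", x$package_version, "\n")
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  %-9s %5.1fs  %s\n", s, st$seconds,
                paste(names(st$counts), unlist(st$counts),
                      sep = "=", collapse = ", ")))
  }
  invisible(x)
}
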