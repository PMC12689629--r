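# Deterministic generators for drug libraries, cohorts, and MS1 runs with
# serialized ground truth, so every pipeline stage can be tested without
# external data. All stochastic choices come from one seeded stream per
# artifact; regeneration from (seed, params) is identical.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# small synthetic vocabulary pools for generated pharmacologic metadata
.vocab_pool <- function() {
  tibble::tribble(
    ~therapeutic_area, ~pharmacologic_class, ~therapeutic_indication, ~mechanism_of_action,
    "cardiology", "statin", "hypercholesterolemia", "HMG-CoA reductase inhibitor",
    "cardiology", "ACE inhibitor", "hypertension", "angiotensin converting enzyme inhibitor",
    "cardiology", "beta blocker", "hypertension", "beta-adrenergic receptor antagonist",
    "infectious disease", "antiretroviral", "HIV infection", "reverse transcriptase inhibitor",
    "infectious disease", "antibiotic", "bacterial infection", "cell wall synthesis inhibitor",
    "infectious disease", "antifungal", "fungal infection", "ergosterol synthesis inhibitor",
    "neurology/psychiatry", "SSRI", "depression", "serotonin reuptake inhibitor",
    "neurology/psychiatry", "benzodiazepine", "anxiety", "GABA-A receptor modulator",
    "gastroenterology", "PPI", "gastroesophageal reflux", "proton pump inhibitor",
    "analgesics", "NSAID", "pain", "cyclooxygenase inhibitor",
    "allergy", "antihistamine", "allergic rhinitis", "histamine H1 receptor antagonist",
    "endocrinology", "biguanide", "type 2 diabetes", "AMPK activator"
  )
}

.random_inchikey <- function(n) {
  blk <- function(k) {
    vapply(seq_len(n), function(i)
      paste(sample(LETTERS, k, replace = TRUE), collapse = ""), character(1))
  }
  paste(blk(14), blk(10), blk(1), sep = "-")
}

# random drug-like formula and its fragment ladder (neutral-loss partitions
# of the precursor, so in-source fragment fixtures are self-consistent)
.random_compound <- function(n_frag_range) {
  nC <- sample(12:30, 1)
  nH <- sample(seq(nC, 2 * nC + 2), 1)
  nN <- sample(0:4, 1)
  nO <- sample(1:6, 1)
  nS <- sample(0:1, 1)
  f <- paste0("C", nC, "H", nH,
              if (nN) paste0("N", nN) else "",
              "O", nO, if (nS) "S" else "")
  prec <- ion_mz(f, "[M+H]+")
  k <- sample(seq(n_frag_range[1], n_frag_range[2]), 1)
  repeat {
    losses <- sort(stats::runif(k, 18, prec - 60))
    mz <- prec - losses
    if (all(diff(sort(mz)) > 0.6)) break
  }
  peaks <- tibble::tibble(mz = sort(mz),
                          intensity = stats::rlnorm(k, log(1e3), 1))
  list(formula = f, precursor_mz = prec, peaks = peaks)
}

#' Generate a synthetic drug library with ground truth
#'
#' Builds `n_drugs` reference drug entries with random but valid molecular
#' formulas, theoretical `[M+H]+` precursors, 8-20 fragment peaks drawn as
#' neutral-loss partitions of the precursor, and vocabulary-valid
#' pharmacologic metadata (a configurable fraction carrying endogenous or
#' food sources). Metabolite entries are planted by applying curated
#' metabolism mass offsets: the precursor and a random subset of fragments
#' shift by the offset.
#'
#' @param n_drugs Number of parent drugs (>= 1).
#' @param seed Generator seed (all randomness flows from it).
#' @param endogenous_fraction Fraction of drugs additionally labeled with
#'   an endogenous or food source.
#' @param metabolite_rate Probability that a drug has planted metabolites.
#' @param max_metabolites Maximum metabolites per drug.
#' @param n_fragments Range of fragment counts per spectrum.
#' @param offsets Mass-offset table supplying metabolism deltas.
#' @return List with `library` (drug library tibble) and `ground_truth`
#'   (params plus per-entry truth).
#' @export
generate_library <- function(n_drugs = 50, seed = 1,
                             endogenous_fraction = 0.2,
                             metabolite_rate = 0.6, max_metabolites = 3,
                             n_fragments = c(8, 20),
                             offsets = default_mass_offsets()) {
  stopifnot(n_drugs >= 1)
  .with_seed(seed, {
    vocab <- .vocab_pool()
    met_offsets <- offsets[offsets$category == "metabolism", ]
    # drop metabolism deltas within 0.02 Da of a named isotope/adduct
    # spacing (e.g. hydrogenation vs the +2 isotope): a metabolite planted
    # there would carry an ambiguous ground-truth ion-form label
    named <- .named_offsets()$delta
    ambiguous <- vapply(met_offsets$delta_mass, function(d) {
      any(abs(d - named) <= 0.02)
    }, logical(1))
    met_offsets <- met_offsets[!ambiguous, ]
    rows <- list()
    truth <- list()
    eid <- 0L
    next_id <- function() {
      eid <<- eid + 1L
      sprintf("LIB%06d", eid)
    }
    n_endo <- round(endogenous_fraction * n_drugs)
    endo_drugs <- sample(n_drugs, n_endo)
    for (i in seq_len(n_drugs)) {
      cmp <- .random_compound(n_fragments)
      drug_rt <- stats::runif(1, 0.5, 9.5)
      name <- sprintf("drug_%03d", i)
      v <- vocab[sample(nrow(vocab), 1), ]
      src <- if (i %in% endo_drugs) {
        paste("medical", sample(c("endogenous", "food"), 1), sep = ";")
      } else "medical"
      id <- next_id()
      rows[[length(rows) + 1L]] <- tibble::tibble(
        entry_id = id, compound_name = name, parent_drug = name,
        annotation_type = "drug", inchikey = .random_inchikey(1),
        smiles = NA_character_, mass_offset = NA_real_,
        formula = cmp$formula, precursor_mz = cmp$precursor_mz,
        rt = drug_rt, peaks = list(cmp$peaks),
        exposure_sources = src, therapeutic_area = v$therapeutic_area,
        pharmacologic_class = v$pharmacologic_class,
        therapeutic_indication = v$therapeutic_indication,
        mechanism_of_action = v$mechanism_of_action,
        clinical_phase = "approved"
      )
      truth[[length(truth) + 1L]] <- tibble::tibble(
        entry_id = id, parent_drug = name, annotation_type = "drug",
        mass_offset = 0)
      if (stats::runif(1) < metabolite_rate) {
        n_met <- sample(max_metabolites, 1)
        cand <- met_offsets[cmp$precursor_mz + met_offsets$delta_mass > 100, ]
        picks <- cand[sample(nrow(cand), min(n_met, nrow(cand))), ]
        for (m in seq_len(nrow(picks))) {
          delta <- picks$delta_mass[m]
          new_prec <- cmp$precursor_mz + delta
          pk <- cmp$peaks
          shiftable <- which(pk$mz + delta > 50 & pk$mz + delta < new_prec - 18)
          n_shift <- max(1L, round(stats::runif(1, 0.3, 0.7) *
                                     length(shiftable)))
          sh <- sample(shiftable, min(n_shift, length(shiftable)))
          pk$mz[sh] <- pk$mz[sh] + delta
          pk <- pk[order(pk$mz), ]
          # metabolites elute resolved from the parent (>= 0.3 min apart);
          # an unresolved metabolite would be indistinguishable from a
          # co-eluting artifact and its ground-truth label ill-defined
          repeat {
            met_rt <- stats::runif(1, 0.5, 9.5)
            if (abs(met_rt - drug_rt) >= 0.3) break
          }
          mid <- next_id()
          rows[[length(rows) + 1L]] <- tibble::tibble(
            entry_id = mid,
            compound_name = paste(name, picks$label[m]),
            parent_drug = name, annotation_type = "metabolite",
            inchikey = NA_character_, smiles = NA_character_,
            mass_offset = delta, formula = NA_character_,
            precursor_mz = new_prec, rt = met_rt,
            peaks = list(pk), exposure_sources = src,
            therapeutic_area = NA_character_,
            pharmacologic_class = NA_character_,
            therapeutic_indication = NA_character_,
            mechanism_of_action = NA_character_,
            clinical_phase = NA_character_
          )
          truth[[length(truth) + 1L]] <- tibble::tibble(
            entry_id = mid, parent_drug = name,
            annotation_type = "metabolite", mass_offset = delta)
        }
      }
    }
    lib <- inherit_metadata(dplyr::bind_rows(rows))
    list(library = lib,
         ground_truth = list(
           seed = seed,
           params = list(n_drugs = n_drugs,
                         endogenous_fraction = endogenous_fraction,
                         metabolite_rate = metabolite_rate,
                         max_metabolites = max_metabolites),
           entries = dplyr::bind_rows(truth)))
  })
}

#' Generate a synthetic cohort with ground truth
#'
#' Simulates an aligned feature table over `n_samples` study samples and
#' `n_blanks` blanks. Samples are partitioned into exposure groups, each
#' exposed to a fixed drug set; exposed samples carry the parent drug
#' feature (lognormal areas around a per-drug mean), its library
#' metabolites, co-eluting analytical artifacts (carbon isotope, sodium and
#' ammonium adducts, an in-source fragment sharing the parent's elution
#' profile), decoy features with spectra unrelated to the library, and
#' background features present in blanks and samples alike. Each feature
#' links to one representative MS/MS spectrum perturbed with fragment m/z
#' jitter and lognormal intensity noise.
#'
#' @param library_gen Output of [generate_library()].
#' @param n_samples,n_blanks Cohort sizes.
#' @param exposure_design Tibble with `group`, `drug` mapping groups to
#'   exposed drugs; default: `n_groups` disjoint random sets of
#'   `drugs_per_group` drugs.
#' @param n_groups,drugs_per_group Used when `exposure_design` is NULL.
#' @param noise_sd Lognormal sigma of per-sample area and intensity noise.
#' @param metabolite_prob Probability an exposed sample shows each planted
#'   metabolite.
#' @param artifact_types Ion-form artifacts planted per exposed drug.
#' @param mz_jitter Half-width of uniform fragment m/z jitter, Da.
#' @param n_decoys,n_background Counts of decoy and background features.
#' @param seed Generator seed.
#' @return List with `feature_table`, `spectra` (representative MS/MS per
#'   feature), and `ground_truth` (exposures, ion-form labels, samples,
#'   params).
#' @export
generate_cohort <- function(library_gen, n_samples = 60, n_blanks = 6,
                            exposure_design = NULL, n_groups = 3,
                            drugs_per_group = 5, noise_sd = 0.2,
                            metabolite_prob = 0.7,
                            artifact_types = c("isotope", "adduct_na",
                                               "adduct_nh4",
                                               "in_source_fragment"),
                            mz_jitter = 0.005, n_decoys = 20,
                            n_background = 10, seed = 2) {
  lib <- library_gen$library
  drugs <- lib[lib$annotation_type == "drug", ]
  .with_seed(seed, {
    if (is.null(exposure_design)) {
      pool <- sample(drugs$compound_name,
                     min(n_groups * drugs_per_group, nrow(drugs)))
      exposure_design <- tibble::tibble(
        group = rep(paste0("G", seq_len(n_groups)),
                    each = length(pool) %/% n_groups),
        drug = pool)
    }
    bad <- setdiff(exposure_design$drug, drugs$compound_name)
    if (length(bad)) {
      stop("exposure design references unknown drug(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    groups <- unique(exposure_design$group)
    samples <- tibble::tibble(
      sample_id = sprintf("S%03d", seq_len(n_samples)),
      group = sort(rep(groups, length.out = n_samples)),
      age = sample(20:80, n_samples, replace = TRUE),
      sex = sample(c("female", "male"), n_samples, replace = TRUE),
      is_blank = FALSE)
    blanks <- tibble::tibble(
      sample_id = sprintf("B%02d", seq_len(n_blanks)),
      group = NA_character_, age = NA_integer_, sex = NA_character_,
      is_blank = TRUE)
    meta <- dplyr::bind_rows(samples, blanks)
    all_ids <- meta$sample_id
    feats <- list(); spectra <- list(); area_rows <- list()
    truth_forms <- list(); exposures <- list()
    fid <- 0L
    add_feature <- function(mz, rt, spec_peaks, spec_precursor, areas) {
      fid <<- fid + 1L
      id <- sprintf("F%04d", fid)
      sid <- paste0("MS2_", id)
      feats[[fid]] <<- tibble::tibble(feature_id = id, mz = mz, rt = rt,
                                      ms2_spectrum_id = sid)
      spectra[[fid]] <<- list(id = sid, precursor = spec_precursor,
                              rt = rt, peaks = spec_peaks)
      row <- as.list(stats::setNames(rep(0, length(all_ids)), all_ids))
      row[names(areas)] <- areas
      area_rows[[fid]] <<- tibble::as_tibble(
        c(list(feature_id = id), row))
      id
    }
    jitter_peaks <- function(pk) {
      pk$mz <- pk$mz + stats::runif(nrow(pk), -mz_jitter, mz_jitter)
      pk$intensity <- pk$intensity * exp(stats::rnorm(nrow(pk), 0, noise_sd))
      pk[order(pk$mz), ]
    }
    exposed_samples <- function(drug) {
      g <- exposure_design$group[exposure_design$drug == drug]
      samples$sample_id[samples$group %in% g]
    }
    for (d in unique(exposure_design$drug)) {
      drow <- drugs[drugs$compound_name == d, ]
      ex <- exposed_samples(d)
      base <- stats::rlnorm(1, log(1e6), 0.5)
      areas <- stats::setNames(
        base * exp(stats::rnorm(length(ex), 0, noise_sd)), ex)
      parent_fid <- add_feature(drow$precursor_mz, drow$rt,
                                jitter_peaks(drow$peaks[[1]]),
                                drow$precursor_mz, areas)
      exposures[[length(exposures) + 1L]] <- tibble::tibble(
        sample_id = ex, drug = d, area = unname(areas))
      # library metabolites of this drug: independent elution, partial presence
      mets <- lib[lib$annotation_type == "metabolite" & lib$parent_drug == d, ]
      for (m in seq_len(nrow(mets))) {
        present <- ex[stats::runif(length(ex)) < metabolite_prob]
        if (!length(present)) next
        m_areas <- stats::setNames(
          0.5 * base * exp(stats::rnorm(length(present), 0, noise_sd)),
          present)
        mf <- add_feature(mets$precursor_mz[m], mets$rt[m],
                          jitter_peaks(mets$peaks[[m]]),
                          mets$precursor_mz[m], m_areas)
        truth_forms[[length(truth_forms) + 1L]] <- tibble::tibble(
          feature_id = mf, spectrum_id = paste0("MS2_", mf),
          parent_drug = d, parent_feature_id = parent_fid,
          parent_entry_id = drow$entry_id,
          label = "derivative", mass_offset = mets$mass_offset[m],
          coeluting = FALSE)
      }
      # co-eluting analytical artifacts sharing the parent elution profile
      pk <- drow$peaks[[1]]
      for (art in artifact_types) {
        if (art == "isotope") {
          off <- 1.003355
          a_pk <- jitter_peaks(pk)
          ratio <- 0.25
        } else if (art == "adduct_na") {
          off <- adduct_offset("[M+Na]+", "[M+H]+")
          a_pk <- jitter_peaks(dplyr::bind_rows(
            pk, tibble::tibble(mz = drow$precursor_mz,
                               intensity = max(pk$intensity))))
          ratio <- 0.3
        } else if (art == "adduct_nh4") {
          off <- monoisotopic_mass("NH3")
          a_pk <- jitter_peaks(dplyr::bind_rows(
            pk, tibble::tibble(mz = drow$precursor_mz,
                               intensity = max(pk$intensity))))
          ratio <- 0.35
        } else if (art == "in_source_fragment") {
          frag <- pk$mz[which.max(pk$intensity)]
          off <- frag - drow$precursor_mz
          a_pk <- jitter_peaks(pk[pk$mz < frag - 1, , drop = FALSE])
          if (!nrow(a_pk)) next
          ratio <- 0.4
        }
        a_prec <- drow$precursor_mz + off
        a_areas <- ratio * areas
        af <- add_feature(a_prec, drow$rt, a_pk, a_prec, a_areas)
        lab <- switch(art, isotope = "isotope",
                      adduct_na = "adduct", adduct_nh4 = "adduct",
                      in_source_fragment = "in_source_fragment")
        truth_forms[[length(truth_forms) + 1L]] <- tibble::tibble(
          feature_id = af, spectrum_id = paste0("MS2_", af),
          parent_drug = d, parent_feature_id = parent_fid,
          parent_entry_id = drow$entry_id,
          label = lab, mass_offset = off, coeluting = TRUE)
      }
    }
    # decoy features: random spectra unrelated to the library
    for (i in seq_len(n_decoys)) {
      cmp <- .random_compound(c(6, 12))
      present <- sample(samples$sample_id,
                        min(n_samples, sample(3:10, 1)))
      d_areas <- stats::setNames(
        stats::rlnorm(length(present), log(3e5), 0.5), present)
      add_feature(cmp$precursor_mz, stats::runif(1, 0.5, 9.5), cmp$peaks,
                  cmp$precursor_mz, d_areas)
    }
    # background features at comparable level in samples and blanks
    for (i in seq_len(n_background)) {
      cmp <- .random_compound(c(4, 8))
      lv <- stats::rlnorm(1, log(5e3), 0.3)
      b_areas <- stats::setNames(
        lv * exp(stats::rnorm(length(all_ids), 0, 0.2)), all_ids)
      add_feature(cmp$precursor_mz, stats::runif(1, 0.5, 9.5), cmp$peaks,
                  cmp$precursor_mz, b_areas)
    }
    features <- dplyr::bind_rows(feats)
    areas <- dplyr::bind_rows(area_rows)
    ft <- feature_table(features, areas, meta)
    sp <- spectra_tbl(
      spectrum_id = purrr::map_chr(spectra, "id"),
      precursor_mz = purrr::map_dbl(spectra, "precursor"),
      peaks = purrr::map(spectra, "peaks"),
      rt = purrr::map_dbl(spectra, "rt"))
    list(feature_table = ft, spectra = sp,
         ground_truth = list(
           seed = seed,
           params = list(n_samples = n_samples, n_blanks = n_blanks,
                         noise_sd = noise_sd,
                         metabolite_prob = metabolite_prob,
                         mz_jitter = mz_jitter),
           exposure_design = exposure_design,
           exposures = dplyr::bind_rows(exposures),
           ion_forms = dplyr::bind_rows(truth_forms),
           samples = meta))
  })
}

#' Generate MS1 runs for a synthetic cohort
#'
#' Produces per-sample MS1 scan tables ("mzML-like" scan sets) with
#' Gaussian elution profiles for every feature present in a sample.
#' Co-eluting artifacts share the parent's apex and peak width (scaled in
#' intensity); metabolites elute at their own apexes.
#'
#' @param cohort Output of [generate_cohort()].
#' @param scan_interval Scan spacing in minutes.
#' @param peak_width Gaussian elution sigma in minutes.
#' @param rt_range Run duration, minutes.
#' @param seed Generator seed (small intensity ripple).
#' @return Tibble of MS1 signals: `sample_id`, `scan_index`, `rt`, `mz`,
#'   `intensity`.
#' @export
generate_ms1_runs <- function(cohort, scan_interval = 0.1,
                              peak_width = 0.15, rt_range = c(0, 10),
                              seed = 3) {
  ft <- cohort$feature_table
  .with_seed(seed, {
    grid <- tibble::tibble(
      scan_index = seq_len(floor(diff(rt_range) / scan_interval)) )
    grid$rt <- rt_range[1] + (grid$scan_index - 1L) * scan_interval
    long <- tidy.feature_table(ft)
    long <- long[long$area > 0, ]
    long <- dplyr::left_join(long, ft$features, by = "feature_id")
    purrr::map_dfr(seq_len(nrow(long)), function(i) {
      rt_f <- long$rt[i]
      sel <- abs(grid$rt - rt_f) <= 4 * peak_width
      g <- grid[sel, ]
      inten <- long$area[i] * exp(-((g$rt - rt_f)^2) / (2 * peak_width^2))
      tibble::tibble(sample_id = long$sample_id[i],
                     scan_index = g$scan_index, rt = g$rt,
                     mz = long$mz[i], intensity = inten)
    })
  })
}

#' Apex-centered XIC trace pairs for drug-analog classification
#'
#' For each analog match, finds the samples where both the parent drug and
#' the analog features are present, locates the parent's apex scan, and
#' extracts `scans_per_peak` consecutive MS1 scans centered on it
#' (truncated with a warning at run boundaries) for both target m/z values.
#'
#' @param ms1 MS1 scan table from [generate_ms1_runs()] (or equivalent
#'   with `sample_id`, `scan_index`, `rt`, `mz`, `intensity`).
#' @param pairs Tibble with `target_id` (analog id), `parent_mz`,
#'   `analog_mz`, and `sample_id` rows for co-occurring files.
#' @param tol XIC m/z tolerance, Da.
#' @param scans_per_peak Number of consecutive scans per trace.
#' @return Named list (by `target_id`) of lists of
#'   `list(drug = trace, analog = trace)` per co-occurring sample.
#' @export
xic_pair_traces <- function(ms1, pairs, tol = 0.01, scans_per_peak = 10L) {
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    sid <- pairs$sample_id[i]
    scans <- ms1[ms1$sample_id == sid, ]
    tr <- xic_traces(scans, c(pairs$parent_mz[i], pairs$analog_mz[i]), tol)
    drug_tr <- tr[tr$target_mz == pairs$parent_mz[i], ]
    apex <- drug_tr$scan_index[which.max(drug_tr$intensity)]
    lo <- apex - floor((scans_per_peak - 1) / 2)
    hi <- lo + scans_per_peak - 1L
    rng <- range(drug_tr$scan_index)
    if (lo < rng[1] || hi > rng[2]) {
      warning("apex window truncated at run boundary for ",
              pairs$target_id[i], " in ", sid)
      lo <- max(lo, rng[1]); hi <- min(hi, rng[2])
    }
    sel <- function(t) t[t$scan_index >= lo & t$scan_index <= hi, ]
    key <- pairs$target_id[i]
    out[[key]] <- c(out[[key]] %||% list(),
                    list(list(drug = sel(drug_tr),
                              analog = sel(tr[tr$target_mz ==
                                                pairs$analog_mz[i], ]))))
  }
  out
}
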