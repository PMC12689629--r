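gaussian_trace <- function(apex, scale = 1, n = 10) {
  tibble::tibble(scan_index = 1:n,
                 intensity = scale * exp(-((1:n) - apex)^2 / 2))
}

test_that("named mass-offset spacings classify isotopes and cation adducts", {
  expect_identical(classify_by_mass_offset(1.0034), "isotope")
  expect_identical(classify_by_mass_offset(2.0067), "isotope")
  expect_identical(classify_by_mass_offset(21.982), "adduct_Na")
  expect_identical(classify_by_mass_offset(37.947), "adduct_Ca")
  expect_identical(classify_by_mass_offset(37.9559), "adduct_K")
  expect_identical(classify_by_mass_offset(5.5), "none")
  expect_identical(classify_by_mass_offset(-1.0034), "none")
  expect_error(classify_by_mass_offset(1, tol = -1), "> 0")
})

test_that("peak-shape correlation matches the direct Pearson formula", {
  t1 <- gaussian_trace(5)
  expect_equal(peak_shape_correlation(t1, t1), 1.0)

  # asymmetric peak vs its mirror image: frozen hand computation
  x <- c(0, 1, 4, 9, 10, 8, 5, 3, 2, 1)
  y <- rev(x)
  expect_equal(peak_shape_correlation(x, y), hand_r_squared(x, y),
               tolerance = 1e-12)

  expect_warning(r <- peak_shape_correlation(x, rep(0, 10)), "constant")
  expect_true(is.na(r))
  expect_error(peak_shape_correlation(x, x[1:5]), "equal length")
  expect_error(peak_shape_correlation(x[1:2], y[1:2]), "at least 3")
})

test_that("R-squared is invariant to affine rescaling of either trace", {
  set.seed(3)
  x <- rlnorm(10); y <- rlnorm(10)
  base <- peak_shape_correlation(x, y)
  expect_equal(peak_shape_correlation(3.7 * x + 11, y), base)
  expect_equal(peak_shape_correlation(x, 0.02 * y + 5), base)
})

test_that("fragment evidence follows the precursor/fragment matching rules", {
  drug <- list(precursor_mz = 346.122,
               peaks = tibble::tibble(mz = c(136.08, 198.07, 268.1),
                                      intensity = c(5, 10, 2)))
  adduct <- list(precursor_mz = 368.104,
                 peaks = tibble::tibble(mz = c(136.08, 346.122),
                                        intensity = c(1, 3)))
  expect_identical(fragment_evidence(drug, adduct), "adduct")
  isf <- list(precursor_mz = 198.07,
              peaks = tibble::tibble(mz = c(91.05, 120.08),
                                     intensity = c(2, 4)))
  expect_identical(fragment_evidence(drug, isf), "in_source_fragment")
  neither <- list(precursor_mz = 500.5,
                  peaks = tibble::tibble(mz = 400.4, intensity = 1))
  expect_identical(fragment_evidence(drug, neither), "none")
  same <- list(precursor_mz = 346.122, peaks = drug$peaks)
  expect_identical(fragment_evidence(drug, same), "none")
})

test_that("the staged decision procedure is ordered and deterministic", {
  # stage 1: isotope spacing wins regardless of traces
  tr <- list(list(drug = gaussian_trace(5), analog = gaussian_trace(9)))
  r <- classify_ion_form(list(mass_offset = 1.0034), cooccurring_traces = tr)
  expect_identical(r$label, "isotope")
  expect_identical(r$evidence, "mass_offset")

  # stage 2: co-eluting shapes -> artifact, sign decides the flavor
  co <- list(list(drug = gaussian_trace(5), analog = gaussian_trace(5, 0.3)))
  r2 <- classify_ion_form(list(mass_offset = 17.0265), cooccurring_traces = co)
  expect_identical(r2$label, "adduct")
  expect_identical(r2$evidence, "peak_shape")
  r3 <- classify_ion_form(list(mass_offset = -57.02), cooccurring_traces = co)
  expect_identical(r3$label, "in_source_fragment")

  # shifted apex -> derivative
  off <- list(list(drug = gaussian_trace(3), analog = gaussian_trace(8)))
  r4 <- classify_ion_form(list(mass_offset = 14.0157),
                          cooccurring_traces = off)
  expect_identical(r4$label, "derivative")

  # boundary R^2 == threshold classifies as derivative
  r5 <- classify_ion_form(list(mass_offset = 14.0157),
                          cooccurring_traces = co, r2_threshold = 1.0)
  expect_identical(r5$label, "derivative")

  # stage 3: no co-occurrence falls back to fragment evidence
  drug <- spectra_tbl("d", 346.122,
                      list(tibble::tibble(mz = c(136.08, 198.07),
                                          intensity = c(5, 10))))
  isf <- spectra_tbl("a", 198.07,
                     list(tibble::tibble(mz = 91.05, intensity = 2)))
  r6 <- classify_ion_form(list(mass_offset = 198.07 - 346.122),
                          drug_spectrum = drug, analog_spectrum = isf)
  expect_identical(r6$label, "in_source_fragment")
  expect_identical(r6$evidence, "fragment_match")

  # stage 4: default derivative
  r7 <- classify_ion_form(list(mass_offset = 14.0157))
  expect_identical(r7$label, "derivative")
  expect_identical(r7$evidence, "default")

  # determinism
  expect_identical(classify_ion_form(list(mass_offset = 17.0265),
                                     cooccurring_traces = co),
                   r2)
})

test_that("max-over-files aggregation uses the best co-occurring file", {
  bad <- list(drug = gaussian_trace(3), analog = gaussian_trace(8))
  good <- list(drug = gaussian_trace(5), analog = gaussian_trace(5, 2))
  r <- classify_ion_form(list(mass_offset = 17.0265),
                         cooccurring_traces = list(bad, good))
  expect_identical(r$label, "adduct")
})

test_that("classification recovers every planted ion form on a synthetic cohort", {
  gl <- generate_library(n_drugs = 8, seed = 401)
  co <- generate_cohort(gl, n_samples = 12, n_blanks = 2, n_groups = 2,
                        drugs_per_group = 3, seed = 402)
  ms1 <- generate_ms1_runs(co, seed = 403)
  truth <- co$ground_truth$ion_forms
  ft <- co$feature_table
  long <- tidy(ft)
  present <- long[long$area > 0, ]
  pairs <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    both <- intersect(
      present$sample_id[present$feature_id == truth$feature_id[i]],
      present$sample_id[present$feature_id == truth$parent_feature_id[i]])
    if (!length(both)) return(NULL)
    tibble::tibble(target_id = truth$spectrum_id[i],
                   sample_id = utils::head(both, 3),
                   parent_mz = ft$features$mz[
                     ft$features$feature_id == truth$parent_feature_id[i]],
                   analog_mz = ft$features$mz[
                     ft$features$feature_id == truth$feature_id[i]])
  })
  traces <- xic_pair_traces(ms1, pairs, tol = 0.01)
  matches <- tibble::tibble(query_id = truth$parent_entry_id,
                            target_id = truth$spectrum_id,
                            mass_offset = truth$mass_offset)
  labelled <- classify_ion_forms(
    matches, traces_by_match = traces,
    drug_spectra = library_spectra(gl$library),
    analog_spectra = co$spectra)
  expect_identical(labelled$label, truth$label)
})
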