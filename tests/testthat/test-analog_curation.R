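# shared fixture: three analog spectra matched to the tiny library drugs
curation_fixture <- function() {
  lib <- tiny_library()
  analog_spectra <- dplyr::bind_rows(
    # methylated darunavir analog, novel spectrum
    spectra_tbl("an1", 548.24 + 14.01565,
                list(tibble::tibble(mz = c(110.2, 205.3, 324.4),
                                    intensity = c(10, 10, 10)))),
    # testosterone analog (endogenous parent)
    spectra_tbl("an2", 289.22 + 15.994915,
                list(tibble::tibble(mz = c(97.1, 125.1),
                                    intensity = c(10, 5)))),
    # unexplained offset
    spectra_tbl("an3", 548.24 + 100.123,
                list(tibble::tibble(mz = c(110.2, 205.3),
                                    intensity = c(10, 10)))),
    # spectrum identical to the omeprazole library entry (known compound)
    spectra_tbl("an4", 346.122, lib$peaks[lib$entry_id == "D3"]))
  matches <- tibble::tibble(
    query_id = c("D1", "D2", "D1", "D1"),
    target_id = c("an1", "an2", "an3", "an4"),
    score = c(0.95, 0.92, 0.9, 1.0),
    matched_peaks = c(7L, 6L, 6L, 4L),
    mass_offset = c(14.01565, 15.994915, 100.123,
                    346.122 - 548.24))
  list(lib = lib, spectra = analog_spectra, matches = matches)
}

test_that("source filter removes analogs of endogenous/food drugs only", {
  fx <- curation_fixture()
  kept <- source_filter(fx$matches, fx$lib)
  expect_false("an2" %in% kept$target_id)  # testosterone is endogenous
  expect_true("an1" %in% kept$target_id)   # darunavir is medical-only
  expect_equal(nrow(source_filter(fx$matches[0, ], fx$lib)), 0L)
  bad <- fx$matches; bad$query_id[1] <- "D999"
  expect_error(source_filter(bad, fx$lib), "unresolvable")
})

test_that("mass-offset filter keeps explainable offsets under the tolerance", {
  fx <- curation_fixture()
  kept <- mass_offset_filter(fx$matches, tol = 0.01)
  expect_true("an1" %in% kept$target_id)    # methylation +14.0157
  expect_false("an3" %in% kept$target_id)   # +100.123 unexplained
  # the tolerance governs: a coarse 2 dp table entry misses at 1e-5
  coarse <- tibble::tibble(delta_mass = 14.02, label = "methylation",
                           category = "metabolism", composition = NA)
  expect_false("an1" %in%
                 mass_offset_filter(fx$matches, coarse, tol = 1e-5)$target_id)
  expect_true("an1" %in%
                mass_offset_filter(fx$matches, coarse, tol = 0.01)$target_id)
  expect_error(mass_offset_filter(fx$matches, tol = 0), "positive")
})

test_that("library-match filter removes analogs explained by known spectra", {
  fx <- curation_fixture()
  kept <- library_match_filter(fx$matches, fx$spectra, fx$lib,
                               score_thr = 0.7, peaks_thr = 3L)
  expect_false("an4" %in% kept$target_id)  # identical to the omeprazole entry
  expect_true("an1" %in% kept$target_id)
  expect_error(library_match_filter(fx$matches, fx$spectra, fx$lib[0, ]),
               "non-empty")
})

test_that("frequency filter drops analogs above the detection-fraction cap", {
  fx <- curation_fixture()
  det <- tibble::tibble(target_id = c("an1", "an2"),
                        dataset_id = c("fecal1", "fecal1"),
                        fraction = c(0.6, 0.1))
  kept <- frequency_filter(fx$matches, det, max_frequency = 0.5)
  expect_false("an1" %in% kept$target_id)
  expect_true("an2" %in% kept$target_id)
  expect_identical(attr(kept, "frequency_removals")$dataset_id, "fecal1")
  # threshold 1.0 removes nothing
  expect_equal(nrow(frequency_filter(fx$matches, det, max_frequency = 1)),
               nrow(fx$matches))
  expect_error(frequency_filter(fx$matches,
                                dplyr::mutate(det, fraction = c(1.2, 0.1))),
               "\\[0, 1\\]")
})

test_that("the four filters are order-independent and subset-preserving", {
  fx <- curation_fixture()
  det <- tibble::tibble(target_id = "an1", dataset_id = "d",
                        fraction = 0.8)
  filters <- list(
    src = function(m) source_filter(m, fx$lib),
    off = function(m) mass_offset_filter(m, tol = 0.01),
    lib = function(m) library_match_filter(m, fx$spectra, fx$lib,
                                           peaks_thr = 3L),
    frq = function(m) frequency_filter(m, det)
  )
  ref <- NULL
  set.seed(31)
  for (i in 1:20) {
    ord <- sample(names(filters))
    m <- fx$matches
    for (f in ord) {
      m2 <- filters[[f]](m)
      expect_true(all(m2$target_id %in% m$target_id))  # subset property
      m <- m2
    }
    ids <- sort(m$target_id)
    if (is.null(ref)) ref <- ids else expect_identical(ids, ref)
  }
})

test_that("curation report counts are conserved", {
  fx <- curation_fixture()
  det <- tibble::tibble(target_id = "an1", dataset_id = "d", fraction = 0.8)
  cur <- curate_analogs(fx$matches, fx$lib, fx$spectra,
                        test_detections = det, lib_peaks_thr = 3L)
  r <- cur$report
  expect_equal(r$input_count,
               r$retained_count + r$removed_by_source + r$removed_by_offset +
                 r$removed_by_library_match + r$removed_by_frequency +
                 r$removed_as_duplicates)
  expect_equal(nrow(cur$matches), r$retained_count)
  td <- tidy(r)
  expect_identical(td$stage[1], "input_count")
})

test_that("loosening any curation threshold never shrinks the retained set", {
  fx <- curation_fixture()
  tight <- mass_offset_filter(fx$matches, tol = 0.001)
  loose <- mass_offset_filter(fx$matches, tol = 0.05)
  expect_true(all(tight$target_id %in% loose$target_id))
  det <- tibble::tibble(target_id = c("an1", "an2"), dataset_id = "d",
                        fraction = c(0.6, 0.4))
  expect_true(all(frequency_filter(fx$matches, det, 0.5)$target_id %in%
                    frequency_filter(fx$matches, det, 0.7)$target_id))
})

test_that("duplicate analog spectra collapse to one representative", {
  base <- tibble::tibble(mz = c(100, 150, 200, 250, 300),
                         intensity = c(5, 10, 20, 10, 5))
  sp <- dplyr::bind_rows(
    spectra_tbl("a", 400.1, list(base)),
    spectra_tbl("b", 400.1, list(dplyr::mutate(base, intensity = intensity * 2))),
    spectra_tbl("c", 410.1, list(base)))
  matches <- tibble::tibble(query_id = "D1", target_id = c("a", "b", "c"),
                            score = 0.9, matched_peaks = 5L, mass_offset = 10)
  out <- dedup_analogs(matches, sp, precursor_tol = 0.02, min_score = 0.95)
  expect_setequal(out$target_id, c("b", "c"))  # b has the higher total intensity
  map <- attr(out, "dedup_map")
  expect_identical(map$representative[map$target_id == "a"], "b")

  # 10 Da apart in precursor: never grouped
  out2 <- dedup_analogs(matches[c(1, 3), ], sp, precursor_tol = 0.02)
  expect_equal(nrow(out2), 2L)
})

test_that("dedup recovers the planted number of duplicate groups", {
  set.seed(8)
  k <- 4
  specs <- list(); matches <- list()
  for (g in seq_len(k)) {
    pk <- random_peaks(6)
    prec <- 300 + g * 30
    for (copy in 1:3) {
      id <- sprintf("g%d_%d", g, copy)
      jit <- pk
      jit$intensity <- jit$intensity * runif(1, 0.8, 1.2)
      specs[[id]] <- spectra_tbl(id, prec, list(jit))
      matches[[id]] <- tibble::tibble(query_id = "D1", target_id = id,
                                      score = 0.9, matched_peaks = 6L,
                                      mass_offset = 12)
    }
  }
  out <- dedup_analogs(dplyr::bind_rows(matches), dplyr::bind_rows(specs))
  expect_equal(nrow(out), k)
})

test_that("co-occurrence fraction is the definitional file ratio", {
  det <- tibble::tibble(
    file_id = c("A", "B", "C", "A", "B", "A", "B", "C"),
    compound_id = c("an1", "an1", "an1", "drug1", "drug1",
                    "drug2", "drug2", "drug2"))
  expect_equal(cooccurrence_fraction(det, "an1", "drug1"), 2 / 3)
  expect_equal(cooccurrence_fraction(det, "an1", "drug2"), 1.0)
  expect_warning(res <- cooccurrence_fraction(det, "ghost", "drug1"),
                 "never detected")
  expect_true(is.na(res))
})
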