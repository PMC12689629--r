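readout_fixture <- function() {
  features <- tibble::tibble(
    feature_id = c("F1", "F2", "F3", "F4"),
    mz = c(548.24, 562.26, 346.122, 289.22),
    rt = c(5, 5.2, 4, 6),
    ms2_spectrum_id = c("s1", "s2", "s3", "s4"))
  areas <- tibble::tibble(
    feature_id = features$feature_id,
    sampleA = c(1e5, 5e4, 2e4, 8e4),
    sampleB = c(0, 3e4, 0, 6e4),
    blank1 = c(0, 0, 1e4, 0))
  samples <- tibble::tibble(sample_id = c("sampleA", "sampleB", "blank1"),
                            is_blank = c(FALSE, FALSE, TRUE),
                            group = c("g1", "g2", NA),
                            age = c(34, 61, NA), sex = c("female", "male", NA))
  feature_table(features, areas, samples)
}

test_that("blank filter drops low-fold features and gates cell detection", {
  features <- tibble::tibble(feature_id = c("hi", "lo", "edge"),
                             mz = 1:3 * 100, rt = 1:3)
  areas <- tibble::tibble(feature_id = c("hi", "lo", "edge"),
                          s1 = c(1e5, 2e4, 9e4),
                          s2 = c(1e5, 2e4, 2.5e4),
                          b1 = c(1e4, 1e4, 1e4))
  samples <- tibble::tibble(sample_id = c("s1", "s2", "b1"),
                            is_blank = c(FALSE, FALSE, TRUE))
  ft <- feature_table(features, areas, samples)
  out <- blank_filter(ft, fold = 3)
  expect_setequal(out$features$feature_id, c("hi", "edge"))
  # retained feature, one cell at 2.5x the blank mean: not detected
  det <- out$detected[out$areas$feature_id == "edge", ]
  expect_true(det$s1); expect_false(det$s2)

  no_blanks <- feature_table(features, areas[, 1:3],
                             samples[1:2, ])
  expect_error(blank_filter(no_blanks), "blank")
})

test_that("noise floor zeroes sub-threshold areas and is identity at 0", {
  ft <- readout_fixture()
  out <- noise_floor(ft, floor = 1e4 + 1)
  expect_equal(out$areas$blank1, c(0, 0, 0, 0))
  expect_equal(out$areas$sampleA, c(1e5, 5e4, 2e4, 8e4))
  same <- noise_floor(ft, floor = 0)
  expect_equal(same$areas, ft$areas)
  expect_error(noise_floor(ft, floor = -1), ">= 0")
})

test_that("blank filter and noise floor commute on detection flags when nested", {
  ft <- readout_fixture()
  # floor below 3x the blank mean of every feature
  a <- noise_floor(blank_filter(ft, 3), floor = 100)
  b <- blank_filter(noise_floor(ft, floor = 100), 3)
  expect_equal(a$detected, b$detected)
})

test_that("parent grouping sums member areas and ORs detection", {
  ft <- readout_fixture()
  lib <- tiny_library()
  child <- tibble::tibble(
    entry_id = c("M1", "A1"),
    compound_name = c("darunavir M1", "darunavir analog"),
    parent_drug = "darunavir", annotation_type = c("metabolite", "analog"),
    mass_offset = c(14.0157, 14.0157), precursor_mz = c(562.26, 562.26),
    rt = 5.2, peaks = list(tibble::tibble(mz = 1, intensity = 1)),
    exposure_sources = "medical", therapeutic_area = "infectious disease",
    pharmacologic_class = "antiretroviral",
    therapeutic_indication = "HIV infection",
    mechanism_of_action = "protease inhibitor", clinical_phase = "approved")
  lib2 <- dplyr::bind_rows(lib, child)
  ann <- tibble::tibble(feature_id = c("F1", "F2", "F3", "F4"),
                        entry_id = c("D1", "M1", "D3", "D2"))
  et <- group_by_parent(ft, ann, lib2)
  a_dar <- et[et$sample_id == "sampleA" & et$parent_drug == "darunavir", ]
  expect_equal(a_dar$summed_area, 1e5 + 5e4)
  expect_true(a_dar$detected)
  # analog-only detection in sampleB still flags the parent drug
  b_dar <- et[et$sample_id == "sampleB" & et$parent_drug == "darunavir", ]
  expect_equal(b_dar$summed_area, 3e4)
  expect_true(b_dar$detected)
  # blanks never appear as exposure rows
  expect_false(any(et$sample_id == "blank1"))
  # no annotations -> empty table
  expect_equal(nrow(group_by_parent(ft, ann[0, ], lib2)), 0L)
  expect_error(group_by_parent(ft, dplyr::mutate(ann, entry_id = "zz"), lib2),
               "unresolvable")
})

test_that("endogenous and food-sourced drugs are excluded with a report", {
  ft <- readout_fixture()
  lib <- tiny_library()
  ann <- tibble::tibble(feature_id = c("F1", "F4"), entry_id = c("D1", "D2"))
  et <- group_by_parent(ft, ann, lib)
  out <- exclude_nonmedical(et, lib)
  expect_false("testosterone" %in% out$parent_drug)
  expect_true("darunavir" %in% out$parent_drug)
  expect_identical(attr(out, "removed_drugs"), "testosterone")
  all_gone <- exclude_nonmedical(et[et$parent_drug == "testosterone", ], lib)
  expect_equal(nrow(all_gone), 0L)
  expect_identical(attr(all_gone, "removed_drugs"), "testosterone")
})

test_that("ontology summaries count each class once per individual", {
  lib <- tiny_library()
  lib$pharmacologic_class[lib$entry_id == "D3"] <- "antiretroviral"
  et <- structure(tibble::tibble(
    sample_id = c("s1", "s1", "s2"),
    parent_drug = c("darunavir", "omeprazole", "darunavir"),
    summed_area = c(1e5, 2e5, 3e5),
    detected = TRUE), class = c("exposure_table", "tbl_df", "tbl", "data.frame"))
  s <- summarize_ontology(et, lib, level = "pharmacologic_class")
  s1 <- s[s$sample_id == "s1", ]
  expect_equal(nrow(s1), 1L)           # both drugs share one class
  expect_identical(s1$level_value, "antiretroviral")
  expect_equal(s1$n_drugs, 2L)

  # level = drug is the identity on the detection matrix
  sd <- summarize_ontology(et, lib, level = "drug")
  expect_setequal(paste(sd$sample_id, sd$level_value),
                  paste(et$sample_id, et$parent_drug))

  lib$pharmacologic_class[lib$entry_id == "D1"] <- NA
  expect_warning(su <- summarize_ontology(et, lib), "unclassified")
  expect_true("unclassified" %in% su$level_value)
})

test_that("demographic normalization divides by the group size", {
  samples <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:25),
    age = c(rep(34, 20), rep(35, 4), NA),
    sex = c(rep("female", 20), rep("male", 4), "female"))
  summary <- tibble::tibble(
    sample_id = c(sprintf("s%02d", 1:5), sprintf("s%02d", 21:24)),
    level_value = "statin", n_drugs = 1L)
  out <- demographic_normalize(summary, samples)
  f30 <- out[out$sex == "female", ]
  expect_equal(f30$rate, 5 / 20)
  m30 <- out[out$sex == "male", ]
  expect_equal(m30$rate, 4 / 4)     # all-detected bin
  expect_identical(attr(out, "excluded_samples"), "s25")
  # empty bins simply do not appear (no 0/0 rows)
  expect_false(any(!is.finite(out$rate)))
})
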