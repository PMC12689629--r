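make_spec <- function(id, prec, mz, inten = rep(10, length(mz))) {
  spectra_tbl(id, prec, list(tibble::tibble(mz = mz, intensity = inten)))
}

test_that("preprocessing removes the precursor zone and rank-filters windows", {
  s <- make_spec("s", 346.122, c(120, 340, 345.5), c(5, 50, 80))
  out <- preprocess_spectra(s)
  expect_equal(out$peaks[[1]]$mz, 120)

  # 8 peaks inside one 50 Da span: the 6 most intense survive
  s2 <- make_spec("s2", 900, seq(100, 135, by = 5), inten = 1:8)
  out2 <- preprocess_spectra(s2)
  expect_equal(out2$peaks[[1]]$intensity, 3:8)

  s3 <- make_spec("s3", 300, numeric(0), numeric(0))
  expect_equal(nrow(preprocess_spectra(s3)$peaks[[1]]), 0L)
})

test_that("identical spectra score exactly 1 with no shifted pairs", {
  a <- make_spec("a", 346.122, c(100, 150, 200, 250, 300), c(5, 10, 20, 10, 5))
  r <- modified_cosine(a, a)
  expect_equal(r$score, 1.0)
  expect_equal(r$matched_peaks, 5L)
  expect_equal(r$shifted_pairs, 0L)
  expect_equal(r$mass_offset, 0)
})

test_that("a precursor shift moved onto fragments is recovered via shifted pairs", {
  delta <- 14.01565
  mz <- c(100, 150, 200, 250, 300)
  mz_b <- mz; mz_b[c(2, 4)] <- mz_b[c(2, 4)] + delta
  a <- make_spec("a", 346.122, mz, c(5, 10, 20, 10, 5))
  b <- make_spec("b", 346.122 + delta, sort(mz_b),
                 c(5, 10, 20, 10, 5)[order(mz_b)])
  r <- modified_cosine(a, b)
  expect_equal(r$score, 1.0)
  expect_equal(r$matched_peaks, 5L)
  expect_equal(r$shifted_pairs, 2L)
  expect_equal(r$mass_offset, delta)
})

test_that("modified cosine is symmetric and degenerate-safe", {
  set.seed(42)
  for (i in 1:20) {
    a <- make_spec("a", runif(1, 200, 500), random_peaks(6)$mz,
                   rlnorm(6, 3, 1))
    b <- make_spec("b", runif(1, 200, 500), random_peaks(7)$mz,
                   rlnorm(7, 3, 1))
    expect_equal(modified_cosine(a, b)$score, modified_cosine(b, a)$score,
                 tolerance = 1e-9)
  }
  empty <- make_spec("e", 300, numeric(0), numeric(0))
  a <- make_spec("a", 300, c(100, 200), c(1, 1))
  r <- modified_cosine(a, empty)
  expect_equal(r$score, 0)
  expect_equal(r$matched_peaks, 0L)
})

test_that("self-similarity is exactly 1 for random non-empty spectra", {
  set.seed(7)
  for (i in 1:20) {
    pk <- random_peaks(sample(3:10, 1))
    s <- spectra_tbl("s", runif(1, 150, 600), list(pk))
    expect_equal(modified_cosine(s, s)$score, 1.0, tolerance = 1e-12)
  }
})

test_that("greedy assignment equals the exhaustive optimum on small spectra", {
  set.seed(99)
  for (i in 1:300) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    pa <- random_peaks(na, c(60, 400))
    pb <- random_peaks(nb, c(60, 400))
    # plant shared and shifted structure so eligibility is non-trivial
    prec_a <- runif(1, 380, 450)
    shift <- sample(c(0, 14.0157, -18.0106, 21.9819), 1)
    share <- sample(na, min(na, nb, sample(1:4, 1)))
    pb$mz[seq_along(share)] <- pa$mz[share] +
      sample(c(0, shift), length(share), replace = TRUE) +
      runif(length(share), -0.01, 0.01)
    pb <- pb[order(pb$mz), ]
    a <- spectra_tbl("a", prec_a, list(pa))
    b <- spectra_tbl("b", prec_a + shift, list(pb))
    got <- modified_cosine(a, b)
    want <- oracle_modified_cosine(pa, prec_a, pb, prec_a + shift)
    expect_equal(got$score, want$score, tolerance = 1e-9,
                 info = paste("case", i))
  }
})

test_that("analog search windows, thresholds, and ordering behave as specified", {
  mz <- c(100, 150, 200, 250, 300, 330)
  q <- make_spec("q", 400, mz)
  corpus <- dplyr::bind_rows(
    make_spec("self", 400, mz),
    make_spec("far", 650, mz),                     # outside the 200 Da window
    make_spec("met", 414.0157, c(mz[1:4], mz[5:6] + 14.0157)))
  hits <- analog_search(q, corpus, precursor_window = 200,
                        min_score = 0.8, min_peaks = 6)
  expect_equal(hits$target_id, c("self", "met"))
  expect_equal(hits$score, c(1, 1), tolerance = 1e-9)
  expect_false("far" %in% hits$target_id)
  expect_error(analog_search(q, corpus[0, ]), "non-empty")
})

test_that("raising analog-search thresholds never enlarges the hit set", {
  set.seed(5)
  corpus <- dplyr::bind_rows(lapply(1:12, function(i) {
    make_spec(paste0("c", i), runif(1, 200, 600),
              random_peaks(8)$mz, rlnorm(8, 3, 1))
  }))
  q <- corpus[3, ]
  loose <- analog_search(q, corpus, min_score = 0.1, min_peaks = 1)
  for (ms in c(0.3, 0.6, 0.9)) {
    tight <- analog_search(q, corpus, min_score = ms, min_peaks = 1)
    expect_true(all(tight$target_id %in% loose$target_id))
    expect_lte(nrow(tight), nrow(loose))
  }
  tighter_peaks <- analog_search(q, corpus, min_score = 0.1, min_peaks = 4)
  expect_true(all(tighter_peaks$target_id %in% loose$target_id))
})

test_that("library search reports two tiers and keeps the best accepted hit", {
  lib <- tiny_library()
  # identical to the omeprazole entry
  d1 <- spectra_tbl("q1", 346.122, lib$peaks[lib$entry_id == "D3"])
  # shares 5 of 6 peaks with a 6-peak variant entry: candidate tier only
  lib2 <- lib
  lib2$peaks[[3]] <- tibble::tibble(mz = c(136.08, 150.0, 198.07, 268.1, 290.0, 312.1),
                                    intensity = rep(10, 6))
  d2 <- spectra_tbl("q2", 346.122,
                    list(tibble::tibble(
                      mz = c(136.08, 150.0, 198.07, 268.1, 290.0, 777 - 400),
                      intensity = rep(10, 6))))
  ann1 <- library_search(d1, lib)
  expect_true(ann1$accepted[ann1$entry_id == "D3"])
  expect_equal(ann1$score[ann1$entry_id == "D3"], 1.0)
  expect_true(ann1$is_best[ann1$entry_id == "D3"])

  ann2 <- library_search(d2, lib2)
  row <- ann2[ann2$entry_id == "D3", ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$matched_peaks, 5L)
  expect_lt(row$score, 0.9)
  expect_gte(row$score, 0.7)
  expect_false(row$accepted)

  expect_error(library_search(d1, lib[0, ]), "non-empty")
})
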