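# Independent oracles and fixture builders used across the suite.

# Exhaustive maximum-weight one-to-one assignment for the modified cosine:
# recomputes pair eligibility from scratch (sqrt scaling, normalization,
# direct and precursor-shifted channels) and maximizes the summed products
# by exhaustive branch-and-bound over the eligible pairs. Independent of
# the package's greedy pairing code.
oracle_modified_cosine <- function(a_peaks, a_prec, b_peaks, b_prec,
                                   frag_tol = 0.02) {
  wa <- sqrt(a_peaks$intensity)
  wb <- sqrt(b_peaks$intensity)
  na_ <- sqrt(sum(wa^2)); nb_ <- sqrt(sum(wb^2))
  if (na_ == 0 || nb_ == 0) return(list(score = 0, matched = 0L))
  shift <- b_prec - a_prec
  pairs <- list()
  for (i in seq_along(wa)) {
    for (j in seq_along(wb)) {
      direct <- abs(a_peaks$mz[i] - b_peaks$mz[j]) <= frag_tol
      shifted <- abs(shift) > frag_tol &&
        abs(b_peaks$mz[j] - a_peaks$mz[i] - shift) <= frag_tol
      if (direct || shifted) {
        pairs[[length(pairs) + 1L]] <-
          c(i, j, (wa[i] / na_) * (wb[j] / nb_))
      }
    }
  }
  if (!length(pairs)) return(list(score = 0, matched = 0L))
  P <- do.call(rbind, pairs)
  best <- new.env()
  best$score <- 0; best$matched <- 0L
  recurse <- function(r, used_i, used_j, acc, cnt) {
    if (acc > best$score + 1e-15 ||
        (abs(acc - best$score) <= 1e-15 && cnt > best$matched)) {
      best$score <- acc; best$matched <- cnt
    }
    if (r > nrow(P)) return()
    # upper bound: even taking every remaining pair cannot beat best
    if (acc + sum(P[r:nrow(P), 3]) < best$score - 1e-15) return()
    i <- P[r, 1]; j <- P[r, 2]
    if (!(i %in% used_i) && !(j %in% used_j)) {
      recurse(r + 1L, c(used_i, i), c(used_j, j), acc + P[r, 3], cnt + 1L)
    }
    recurse(r + 1L, used_i, used_j, acc, cnt)
  }
  recurse(1L, integer(), integer(), 0, 0L)
  list(score = min(1, best$score), matched = best$matched)
}

# hand-written Pearson r^2 (direct formula, no stats::cor)
hand_r_squared <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  (num / den)^2
}

# random peak list with distinct m/z values
random_peaks <- function(n, mz_range = c(60, 500)) {
  mz <- sort(runif(n, mz_range[1], mz_range[2]))
  while (any(diff(mz) < 0.1)) {
    mz <- sort(runif(n, mz_range[1], mz_range[2]))
  }
  tibble::tibble(mz = mz, intensity = rlnorm(n, log(100), 1))
}

# small drug library fixture used by curation and readout tests
tiny_library <- function() {
  pk <- function(...) list(tibble::tibble(mz = c(...),
                                          intensity = rep(10, length(c(...)))))
  lib <- dplyr::bind_rows(
    tibble::tibble(entry_id = "D1", compound_name = "darunavir",
                   parent_drug = "darunavir", annotation_type = "drug",
                   mass_offset = NA_real_, precursor_mz = 548.24, rt = 5,
                   peaks = pk(110.2, 205.3, 310.4, 401.1, 480.5),
                   exposure_sources = "medical",
                   therapeutic_area = "infectious disease",
                   pharmacologic_class = "antiretroviral",
                   therapeutic_indication = "HIV infection",
                   mechanism_of_action = "protease inhibitor",
                   clinical_phase = "approved"),
    tibble::tibble(entry_id = "D2", compound_name = "testosterone",
                   parent_drug = "testosterone", annotation_type = "drug",
                   mass_offset = NA_real_, precursor_mz = 289.22, rt = 6,
                   peaks = pk(97.1, 109.1, 253.2),
                   exposure_sources = "medical;endogenous",
                   therapeutic_area = "endocrinology",
                   pharmacologic_class = "androgen",
                   therapeutic_indication = "hypogonadism",
                   mechanism_of_action = "androgen receptor agonist",
                   clinical_phase = "approved"),
    tibble::tibble(entry_id = "D3", compound_name = "omeprazole",
                   parent_drug = "omeprazole", annotation_type = "drug",
                   mass_offset = NA_real_, precursor_mz = 346.122, rt = 4,
                   peaks = pk(136.08, 198.07, 268.1, 303.2, 312.1),
                   exposure_sources = "medical",
                   therapeutic_area = "gastroenterology",
                   pharmacologic_class = "PPI",
                   therapeutic_indication = "gastroesophageal reflux",
                   mechanism_of_action = "proton pump inhibitor",
                   clinical_phase = "approved")
  )
  validate_drug_library(lib)
}

# minimal mzML writer (uncompressed 64-bit arrays) for exercising the
# mzR-backed reader on a synthetic file
write_tiny_mzml <- function(path, scans) {
  b64 <- function(x) jsonlite::base64_enc(writeBin(x, raw(), size = 8,
                                                   endian = "little"))
  spec_xml <- function(i, rt_min, mz, inten) {
    sprintf(paste0(
      '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">\n',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>\n',
      '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum"/>\n',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>\n',
      '<scanList count="1"><cvParam cvRef="MS" accession="MS:1000795" name="no combination"/>',
      '<scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%f" ',
      'unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"/></scan></scanList>\n',
      '<binaryDataArrayList count="2">\n',
      '<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
      '<binary>%s</binary></binaryDataArray>\n',
      '<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
      '<binary>%s</binary></binaryDataArray>\n',
      '</binaryDataArrayList></spectrum>'),
      i, i + 1L, length(mz), rt_min,
      nchar(b64(mz)), b64(mz), nchar(b64(inten)), b64(inten))
  }
  body <- paste(vapply(seq_along(scans), function(k) {
    s <- scans[[k]]
    spec_xml(k - 1L, s$rt, s$mz, s$intensity)
  }, character(1)), collapse = "\n")
  doc <- sprintf(paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<indexedmzML xmlns="http://psi.hupo.org/ms/mzml">',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2"><cv id="MS" fullName="PSI-MS" URI="https://x"/>',
    '<cv id="UO" fullName="UO" URI="https://y"/></cvList>\n',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum"/>',
    '</fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="sw" version="1">',
    '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="synthetic"/>',
    '</software></softwareList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1">',
    '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model"/>',
    '</instrumentConfiguration></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="dp">',
    '<processingMethod order="1" softwareRef="sw">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>',
    '</processingMethod></dataProcessing></dataProcessingList>\n',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    '<spectrumList count="%d" defaultDataProcessingRef="dp">\n%s\n',
    '</spectrumList></run></mzML></indexedmzML>'),
    length(scans), body)
  writeLines(doc, path)
  invisible(path)
}
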