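Package: drugtrace
Title: Drug Exposure Readout from Untargeted Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building drug spectral libraries with
    controlled-vocabulary pharmacologic metadata and reading out drug
    exposure from untargeted LC-MS/MS metabolomics data. Implements
    precursor-shift-aware (modified cosine) spectral analog search, a
    four-stage curation pipeline for candidate drug analogs, ion-form
    classification of analogs (isotope, adduct, in-source fragment,
    derivative) from extracted-ion-chromatogram peak-shape correlation
    and fragment evidence, per-sample exposure summarization at multiple
    ontology levels, and cohort stratification by exposure profile.
    Includes a deterministic synthetic-data generator so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
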