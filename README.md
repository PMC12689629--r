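# drugtrace

Empirical drug-exposure readout from untargeted LC-MS/MS metabolomics.

Medication records are incomplete — they miss over-the-counter drugs,
adherence, and timing, and are unavailable for wastewater, food, or
environmental samples. `drugtrace` reads drug exposure directly from
untargeted metabolomics data instead: it matches MS/MS spectra against a
drug reference library carrying controlled-vocabulary pharmacologic
metadata (exposure source, pharmacologic class, therapeutic area,
indication, mechanism of action), extends coverage to unannotated drug
metabolites via precursor-shift-aware spectral analog search, curates those
analogs, classifies them as isotopes / adducts / in-source fragments /
derivatives, and turns the annotations into per-sample exposure tables that
support ontology-level summaries and cohort stratification.

## The core machinery

**Modified cosine.** For spectra with precursor difference
Δ = m₂ − m₁, fragment pairs are eligible directly
(|mᵢ − mⱼ| ≤ τ) or shifted (|mⱼ − mᵢ − Δ| ≤ τ). With square-root-scaled,
norm-scaled intensities and a greedy one-to-one assignment, the score is
the summed product of matched intensities; identical spectra score 1.
Analog hits require score ≥ 0.8 and ≥ 6 matched ions within a ±200 Da
precursor window; library annotation searches at 0.7/2 and accepts at
0.9/5.

**Analog curation.** Four order-independent filters: drop analogs of
endogenous/food-sourced drugs; require the mass offset to match a curated
table of biotransformation, adduct, and isotope deltas (methylation +14.02,
glucuronidation +176.03, oxidation +15.99, dehydration −18.01, sodium
+21.98 Da, ...); drop analog spectra that match known library entries; drop
analogs detected in >50% of a test dataset.

**Ion-form classification.** Named spacings first (isotopes +1.00/+2.01;
Na/Ca/K adducts), then the maximum squared Pearson correlation of
apex-centered ten-scan XIC profiles across co-occurring files (R² > 0.9 ⇒
co-eluting artifact; adduct if the offset is positive, in-source fragment
if negative), then MS/MS fragment evidence, defaulting to derivative.

**Readout and stratification.** 3-fold blank filtering, a 10⁴ noise floor,
parent-drug grouping (an analog-only detection still flags the drug),
exclusion of endogenous/food drugs, once-per-individual class counting,
demographic normalization, Ward/Euclidean hierarchical clustering of
log(1 + area) exposure profiles, and Kruskal–Wallis + pairwise Wilcoxon +
Benjamini–Hochberg testing of downstream metabolites.

A deterministic synthetic-data generator (`generate_library()`,
`generate_cohort()`, `generate_ms1_runs()`) produces libraries, cohorts,
and MS1 runs with serialized ground truth, so the full pipeline is testable
without any external data.

## Worked example

```r
library(drugtrace)
library(dplyr)

ion_mz("C17H19N3O3S", "[M+H]+")   # omeprazole [M+H]+
#> [1] 346.122

gl <- generate_library(n_drugs = 10, seed = 42)
co <- generate_cohort(gl, n_samples = 12, n_blanks = 2, n_groups = 2,
                      drugs_per_group = 3, seed = 43)

ann <- library_search(co$spectra, gl$library) |>
  filter(accepted, is_best) |>
  left_join(co$feature_table$features[, c("feature_id", "ms2_spectrum_id")],
            by = c(spectrum_id = "ms2_spectrum_id")) |>
  filter(!is.na(feature_id))

ft <- co$feature_table |> blank_filter(fold = 3) |> noise_floor(floor = 1e4)
et <- group_by_parent(ft, ann, gl$library)
head(as_tibble(et), 4)
#> # A tibble: 4 × 4
#>   sample_id parent_drug summed_area detected
#>   <chr>     <chr>             <dbl> <lgl>
#> 1 S001      drug_002             0  FALSE
#> 2 S001      drug_004       2247803. TRUE
#> 3 S001      drug_005        883712. TRUE
#> 4 S001      drug_007             0  FALSE

cl <- cluster_samples(et, k = 2)
glance(cl)
#> # A tibble: 1 × 4
#>       k n_samples method  metric
#>   <int>     <int> <chr>   <chr>
#> 1     2        12 ward.D2 euclidean
```

The exposure table gives, per sample and parent drug, the summed peak area
over the drug, its metabolites, and its analogs, plus a detection flag;
here the two planted exposure groups are recovered exactly by the
clustering (all 12 samples in their design group). Plot helpers
(`plot_spectrum_mirror()`, `autoplot()` on exposure tables and cluster
assignments, `plot_mass_offset_frequency()`) visualize matches, exposure
heatmaps, and offset frequencies.

A command-line wrapper for the staged pipeline
(simulate → search → curate → ionform → readout → stratify over a working
directory of CSV/MGF artifacts) ships as `inst/cli/drugtrace.R`:

```sh
Rscript inst/cli/drugtrace.R simulate --workdir work --seed 5
Rscript inst/cli/drugtrace.R search   --workdir work
Rscript inst/cli/drugtrace.R readout  --workdir work --level pharmacologic_class
```

See `vignettes/drugtrace-methods.Rmd` for the model, its assumptions, all
tunable parameters, and known limitations.

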