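---
title: "Methods: drug exposure readout from untargeted metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug exposure readout from untargeted metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugtrace)
```

## The problem

Clinical records of medication use are incomplete: they miss over-the-counter
drugs, adherence, and timing, and they are unavailable outside clinical
settings. Untargeted LC-MS/MS metabolomics can establish drug exposure
empirically — a drug, its metabolites, or its ionization artifacts leave
MS/MS signatures in biofluid data. `drugtrace` implements the machinery for
this readout: a drug spectral library with controlled-vocabulary
pharmacologic metadata, precursor-shift-aware analog search to extend the
library with candidate drug metabolites, curation filters that keep only
analogs interpretable as drug exposure, ion-form classification of those
analogs, per-sample exposure summaries at several ontology levels, and
exposure-based cohort stratification. Every stage runs on synthetic
fixtures with known ground truth, so the whole pipeline is testable offline.

## Spectral similarity and analog search

Two MS/MS spectra of related molecules share fragment peaks either at
identical m/z (unmodified substructures) or displaced by the precursor mass
difference $\Delta = m_b - m_a$ (fragments carrying the modification). The
modified cosine treats a peak pair $(i, j)$ as eligible when
$|m_{a,i} - m_{b,j}| \le \tau$ or $|m_{b,j} - m_{a,i} - \Delta| \le \tau$,
with fragment tolerance $\tau$ (default 0.02 Da). Intensities are
square-root scaled — the convention in spectral networking, damping
dominance of base peaks — and normalized, and a one-to-one assignment of
eligible pairs is chosen greedily by descending intensity product, ties
broken by smaller m/z residual. The score is the summed product of matched,
norm-scaled intensities, so identical spectra score exactly 1.

Greedy assignment can in principle fall short of the maximum-weight
matching when one peak is eligible against several others. In practice
fragment tolerances are far smaller than peak spacings and conflicts are
rare; the test suite compares the greedy score against an exhaustive
branch-and-bound assignment oracle on randomized spectra with up to 8 peaks
per side and requires exact agreement.

Analog search (`analog_search()`) scores a drug spectrum against a corpus
within a ±200 Da precursor window and keeps hits with score ≥ 0.8 and ≥ 6
matched ions. Library annotation (`library_search()`) is two-tier: a
permissive search tier (score ≥ 0.7, ≥ 2 matched peaks, direct precursor
match within 0.02 Da) and an acceptance tier (score ≥ 0.9, ≥ 5 peaks)
applied downstream; each query keeps its best accepted entry. Spectrum
preprocessing for search removes fragments within ±17 Da of the precursor
and keeps the six most intense fragments per ±50 Da window.

## Curating candidate drug analogs

Raw analog matches are filtered in four independent, per-match stages:

1. **Source filter** — analogs of drugs that are also endogenous or dietary
   are removed: their detection cannot be attributed to medication.
2. **Mass-offset filter** — the precursor shift must match (±0.01 Da,
   configurable, signed) an entry of a curated table of common drug
   biotransformations, adduct spacings, and isotope spacings. The packaged
   table (`default_mass_offsets()`) covers ~40 entries, including
   methylation +14.02, glucuronidation +176.03, oxidation +15.99,
   dehydration −18.01, (de)ethylation ±28.03, ammonium +17.03, sodium
   +21.98, calcium +37.95, potassium +37.96, and carbon-isotope +1.00 /
   +2.01 Da; it is user-replaceable via CSV.
3. **Library-match filter** — analog spectra that match any known library
   entry (same precursor within tolerance, score ≥ 0.7, ≥ 6 peaks) are
   known compounds, typically same-family drugs, not novel analogs.
4. **Frequency filter** — analogs detected in more than 50% of any test
   dataset cannot plausibly reflect drug exposure in a general cohort.

Because each filter is a pure predicate of a single match, the retained set
is invariant to filter order; the report (`curate_analogs()`) counts
removals per stage and the counts always sum to the input count. Duplicate
analog spectra are collapsed by greedy single-linkage grouping (precursor
within tolerance, zero-offset modified cosine ≥ 0.95), keeping the
highest-total-intensity spectrum. This documented dedup stands in for
repository-scale spectrum clustering; the 0.95 score maps only
approximately onto clustering tools' distance parameters and is not claimed
equivalent. The analog-parent co-occurrence fraction
(`cooccurrence_fraction()`) — the share of files containing an analog that
also contain its parent — is the summary used to argue analogs track
exposure.

## Ion-form classification

A curated analog can still be an analytical artifact of the parent drug
rather than a metabolite. Classification proceeds in fixed stages:

1. **Named mass offsets.** +1.0034 / +2.0067 Da are carbon isotopes;
   +21.9819, +37.9469, +37.9559 Da are sodium, calcium ([M+Ca−H]⁺, the
   singly-charged form consistent with the +37.95 spacing), and potassium
   adducts. Nearest spacing within 0.01 Da wins.
2. **Peak-shape correlation.** Where the analog and drug co-occur in a
   file, their extracted ion chromatograms over the same ten consecutive
   MS1 scans centered on the drug's apex are compared by squared Pearson
   correlation; the maximum R² across files above 0.9 marks a co-eluting
   artifact (adduct if the offset is positive, in-source fragment if
   negative), otherwise a derivative. R² exactly at the threshold is
   classified derivative (the rule's boundary is unspecified; the
   conservative side keeps candidate metabolites). XIC intensities are
   summed within the m/z tolerance rather than base-peak; for clean
   centroided data the two coincide.
3. **Fragment evidence.** Without co-occurrence, an analog with a higher
   precursor whose MS/MS contains the drug's precursor m/z is an adduct; an
   analog whose precursor equals one of the drug's fragment m/z values is
   an in-source fragment. No intensity filtering is applied.
4. **Default**: derivative.

The mass-offset stage runs first even when traces exist, mirroring the
order in which the rules are stated; for true isotopes and cation adducts
the two stages agree whenever both apply, so the order only matters for
pathological inputs. Truncation of the ten-scan window at run boundaries
warns rather than fails.

## Exposure readout

Feature tables (features × samples peak areas) are filtered by the blank
rule — a feature is dropped when its mean area across study samples is
below 3× its mean blank area, and a retained cell counts as detected only
above that same 3-fold line — and by a noise floor that zeroes areas below
10⁴ (Orbitrap-scale instrument noise). The two rules are exposed as
independent switches because they come from different acquisition settings;
applied together the fixed order is blank filter, then floor (on detection
flags they commute whenever the floor is below the 3-fold blank line).
Annotations are grouped by parent drug: per sample, areas of the drug, its
metabolites, and its analogs are summed, and the drug counts as detected
when any member is — so an analog-only detection still flags exposure,
which matters when the parent is fully metabolized. Drugs with endogenous
or food sources are excluded from exposure calls (with a report), and
summaries at drug / pharmacologic class / therapeutic area / indication /
mechanism level count each value once per individual. Demographic
normalization divides detection counts by the (10-year age bin × sex) group
size; samples with missing demographics or age outside 0–90 are excluded
and reported.

## Stratification

Samples are clustered on the samples × drugs matrix of log(1 + summed
area) — the offset accommodates the zeros that dominate exposure data — by
Ward's-criterion agglomerative clustering on Euclidean distances
(`hclust(method = "ward.D2")`), cut at a user-chosen k (there is no
automatic k selection). Labels are renumbered by decreasing cluster size
for reproducible reports. Downstream metabolite differences across clusters
use the Kruskal–Wallis omnibus test followed by all pairwise two-sided
Wilcoxon rank-sum tests (normal approximation with tie correction by
default; exact optional for small groups) with Benjamini–Hochberg
adjustment over the pairwise family. All-tied input returns an omnibus
statistic of 0. Group-count comparisons across cohorts use the Pearson
chi-square test without continuity correction.

## The synthetic-data generator

`generate_library()` builds drug entries with random drug-like formulas
(C₁₂–C₃₀ with H, N, O, S), theoretical [M+H]⁺ precursors from hard-coded
monoisotopic masses (proton 1.007276 Da, electron-corrected adducts), and
8–20 fragments drawn as neutral-loss partitions of the precursor so that
in-source-fragment fixtures are chemically self-consistent. A configurable
fraction of drugs (default 20%) carries an endogenous or food source;
metabolites are planted by applying curated metabolism offsets to precursor
and a random subset of fragments. Two generator constraints keep ground
truth well-defined: planted metabolites elute at least 0.3 min from the
parent (an unresolved metabolite would be indistinguishable from a
co-eluting artifact under the R² rule), and metabolism offsets within
0.02 Da of a named isotope/adduct spacing (e.g. hydrogenation +2.0157 vs
the +2.0067 isotope) are not used for planting.

`generate_cohort()` partitions samples into exposure groups with fixed drug
sets (default: 60 samples, 6 blanks, 3 groups × 5 drugs); exposed samples
carry the parent feature with lognormal areas (noise σ = 0.2 on the log
scale — typical within-cohort variation for untargeted peak areas), its
metabolites (each present with probability 0.7), four co-eluting artifacts
per drug (carbon isotope, sodium and ammonium adducts — the latter
exercising the peak-shape route since it has no named spacing in the
classifier — and an in-source fragment at the most intense fragment m/z),
decoy features with library-unrelated spectra, and background features at
comparable levels in samples and blanks (removed by the blank rule). MS/MS
spectra carry fragment m/z jitter (±0.005 Da, half the fragment tolerance)
and lognormal intensity noise. `generate_ms1_runs()` emits per-sample MS1
scan tables (0.1 min scan spacing, Gaussian elution σ = 0.15 min);
artifacts share the parent's elution profile exactly (R² = 1 by
construction), metabolites have their own apexes. All randomness flows from
a single seeded stream per artifact; regeneration from (seed, parameters)
is identical.

What the generator does **not** emulate: chromatographic tailing and drift,
correlated noise, isotope envelope shapes, co-eluting isomers, matrix
effects, and missing-at-random MS2 acquisition. Passing tests therefore
demonstrate the correctness of the rules and plumbing on data that obeys
the stated model, not annotation performance on real instrument data.

## Numerical and design choices

- Atomic monoisotopic masses are hard-coded at 6 dp; proton mass
  1.007276 Da; adduct deltas are electron-corrected. Display convention: 2
  dp for offsets, 3 dp for m/z.
- The isotope spacing is stored exactly (+1.003355, +2.006710 Da) under
  unit-mass labels; matching tolerances absorb the difference from the
  printed +1.00/+2.00.
- Offsets are signed throughout; a gain and a loss are distinct entries.
- Greedy pair assignment breaks product ties by smaller m/z residual, then
  peak index, making scores independent of input ordering.
- Annotation ties across library entries: higher score, then more matched
  peaks, then lexicographic entry id.
- Configuration files are YAML; precedence is explicit overrides (CLI
  flags) > config file > package defaults, with unknown keys rejected.
- Cluster label order, filter report fields, and CSV column sets are fixed
  so repeated runs with the same seed produce byte-identical artifacts.

Problem sizes in the test suite and acceptance script (12–50 drugs, 18–60
samples, 1000 randomized assignment fixtures, 1000 null replicates for the
Kruskal–Wallis calibration) were chosen as the smallest scales at which
every rule fires on multiple instances; the statistical checks use the
standard ±2 standard-error band of a 1000-replicate binomial.

## Known limitations

- Analog search is in-memory and pairwise; repository-scale indexed search
  is out of scope.
- Structure handling is limited to carrying SMILES/InChIKey strings;
  standardization (salt stripping, canonicalization) is expected upstream.
- "Manual review" steps of library curation are replaced by emitted
  reports (no-metadata entries, review flags), not automated judgment.
- The R²-based artifact call needs MS1 runs where drug and analog co-occur;
  without them classification falls back to fragment evidence, which cannot
  see isotopes.
- Relative peak areas only; no dosage estimation.
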