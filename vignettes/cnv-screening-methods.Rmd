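---
title: "Methods: two-stage array-CGH screening and trio-based de novo CNV calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage array-CGH screening and trio-based de novo CNV calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvtrio)
library(dplyr)
```

## The problem

Germline structural mutagenesis studies in mice ask whether an exposure —
here, chronic low dose-rate gamma irradiation of sires — increases the rate
at which offspring acquire *de novo* copy number variants (CNVs). The
measurement chain is long: two-colour array CGH with dye-swap replication,
a two-tier probe design (a genome-wide ~2 kb-spaced screening array and a
~0.1 kb-spaced confirmation array), family analysis against both parents to
separate new mutations from inherited polymorphisms, duplex qPCR as the
final arbiter, and cohort statistics on the resulting per-mouse tallies,
CNV sizes, and lifespans. `cnvtrio` implements that chain as composable,
tidy functions, together with a synthetic-cohort generator so that every
stage can be tested against known ground truth without any array data.

## Signal model and screening rules

A probe inside a CNV shifts its expected log2 fluorescence ratio to
`log2(copy/2)`: −1 for a hemizygous deletion, `log2(3/2) ≈ +0.585` for a
single-copy duplication. Each of the two dye-swap hybridisations adds
independent Gaussian noise; both columns are stored sample-over-reference
(the generator sign-normalises the swapped experiment, with a
`raw_orientation` flag for scanner-native signs).

First-screen positivity (`first_screen()`) uses two rules with strict
inequalities, reflecting wording in which a threshold must be *exceeded*:

* **single-probe rule** — both |log2 ratios| > 0.8;
* **adjacent-pair rule** — two consecutive probes on the same chromosome
  with all four |log2 ratios| > 0.5. Runs chain: every probe of a maximal
  run in which each consecutive pair passes is positive. Probes at
  chromosome ends are never adjacent across chromosomes.

Both rules additionally require the two hybridisations to agree in sign,
and the pair rule requires a shared direction. The rationale is physical: a
genuine copy-number change moves both dye-swap experiments the same way, so
a probe that is large in magnitude but discordant in sign is an artifact.
This halves the single-probe null false-positive rate relative to a pure
magnitude rule, to `2·Φ̄(0.8/σ)²` per probe under noise sd σ; at the default
σ = 0.15 that is ~5 × 10⁻¹⁵, vanishingly small relative to any realistic
array size, which is how the default was chosen.

Second-screen confirmation (`select_second_tier_probes()` +
`second_screen()`) re-tests each positive probe on the dense tier: at least
10 neighbouring dense probes are selected per positive (split evenly per
side, filled one-sided at chromosome edges, deterministic lower-coordinate
ordering), and the probe is confirmed only if (1) it again shows both
|log2 ratios| > 0.5 and (2) at least one newly selected neighbour within 3
probe ranks does too, in the same direction.

## Family analysis, candidates, intervals

`family_filter()` keeps an offspring positive probe only when neither
parent shows a same-direction positive within a 10 kb window (five
first-tier spacings; parent and offspring share the probe map, but noise
jitters run boundaries, so exact-coordinate matching would under-filter).
Probe-level matching was chosen over interval-level matching because it is
the more conservative direction for de novo claims.

`call_candidates()` aggregates surviving positives into maximal
same-direction runs of consecutive first-tier probes, with a configurable
gap tolerance that defaults to 0 (no merge rule is defensible a priori;
zero is the conservative choice and the flag documents the uncertainty).
Candidates with a single positive probe are Type S, all others Type L —
the class split matters because single-probe events are where array CGH at
common spacing is blind and where false positives concentrate. Small
candidates that a human would traditionally review by eye go through the
same programmatic path here; the second screen and the qPCR verdict provide
the filtering that the review performed, which keeps the pipeline
reproducible.

Intervals (`estimate_interval()`) span the outermost supporting positive
probes, pooling first-tier run members with every second-tier probe that
passed confirmation thresholds for the run. Coordinates are 1-based closed
internally with **size = end − start**; that convention is forced by the
published worked example (7,323,541 − 7,323,388 = 153 bp) and is converted
to BED's 0-based half-open form only at the file boundary. Gene overlap
(`annotate_genes()`) counts closed-interval overlaps of at least 1 bp, so
an annotation starting at `end + 1` does not count.

## qPCR confirmation

`simulate_qpcr_plate()` emulates a duplex TaqMan copy-number assay over a
genomic-DNA dilution series (default 1.25/2.5/5 ng, triplicate) with
`Ct = intercept + slope·log10(mass × copy/2)` and the reference gene fixed
at two copies. The default slope `−1/log10(2) = −3.3219` is 100% efficient
chemistry; `fit_standard_curve()` recovers slope, intercept and efficiency
`10^(−1/slope) − 1`. `confirm_copy_number()` implements the relative
standard curve method: both assays' curves are fitted on a calibrator plate
(reference DNA against itself), sample wells are interpolated to
quantities, and the target/reference ratio is normalised by the
calibrator's. Expected relative quantities are 0.5 / 1.0 / 1.5 for one /
two / three copies; the confirmation thresholds (0.75, 1.25) are the
midpoints, a choice the package makes explicitly because no numeric
cut-off is standard. The estimate is invariant to rescaling the dilution
series.

## Cohort statistics

* **Contingency** (`fisher_p()`, `cnv_contingency()`, `tally_mice()`): the
  unit is the *mouse*, not the CNV, so animals with many events cannot
  dominate; mice with ≥ 4 confirmed calls are excluded from numerator and
  denominator alike, on the view that they reflect a different mutational
  process. Fisher's exact test defaults to the two-sided probability-mass
  convention of `stats::fisher.test`.
* **Sizes** (`geometric_stats()`, `log_size_test()`): CNV sizes span four
  orders of magnitude, so location and spread are summarised as geometric
  mean and geometric SD (n−1 log-SD), and group comparison is an F-test on
  log-variances followed by the pooled t-test on logs (Welch form when the
  F-test rejects at 0.05).
* **Lifespan** (`exclude_short_lived()`, `cox_lifespan_fit()`): very
  short-lived animals are excluded only when *both* an iterative one-sided
  Grubbs test of the sample minimum (α = 0.05 per iteration) rejects them
  *and* they lived ≤ 300 days. The survival model is Cox proportional
  hazards with three binary covariates — female sex, irradiation, de novo
  CNV carriage — with male/non-irradiated/CNV-free as reference and Efron
  tie handling by default (Breslow available). All animals live out their
  natural lifespan in this design, so every record is an observed event;
  a censoring column is honoured if supplied.

Reported tables round percentages to 1 decimal place, p-values to 3, and
geometric means to the nearest integer, matching the conventions of the
published tables they mirror.

### Reproducing published tables: two forensic notes

Recomputing the published contingency table from its own counts shows that
the pooled rows reproduce under the two-sided Fisher test (0.001, 0.004,
0.075 at 3 dp) while the sex-stratified rows reproduce only under the
one-sided test (0.018, 0.009, 0.085, 0.024); the package therefore records,
next to each published p-value in `example_cnv_tallies()`, the sidedness
under which it reproduces, and `fisher_p()` exposes `alternative`
explicitly.

The published size table is also internally inconsistent: the control
deletions' log-SD reproduces the *irradiated* column's printed geometric SD
and vice versa (the cells are evidently swapped), and only 30 of 31
irradiated deletion coordinates are published. The missing size is
recoverable from the printed irradiated geometric mean (n = 31): solving
`exp(31·ln 12674 − Σ ln sizes)` gives ≈ 192,082 bp, and with that one value
the geometric mean, the geometric SD *and* the published t-test p-value
(0.6758) all reproduce simultaneously. `example_cnv_calls()` ships that row
flagged `reconstructed = TRUE`.

## The synthetic cohort generator

`sim_config()` fixes the study conditions: F1 groups of 156 and 142 mice;
probe tiers at 2 kb and 0.1 kb spacing; de novo CNV counts per F1 drawn
Poisson with rates 0.074 (control) and 0.23 (irradiated), calibrated so
that roughly 7% and 20% of F1 mice carry at least one de novo deletion;
CNV sizes log-uniform over 150 bp–2 Mb; founder CNVs (default 1 per
founder) transmitted to each offspring with probability 1/2; dye-swap noise
sd 0.15. The genome is a synthetic 5 × 20 Mb model — coordinates, not
biology, are what the downstream code consumes. Lifespans are Weibull
(shape 7, giving the observed ~15–20% coefficient of variation) with a
reference-stratum mean of 914 days and multiplicative hazards
(female 1.972, irradiated 1.175, CNV carrier 1.435). The published hazard
table prints ratios below 1 for the coded-1 levels while its own text and
the stratum means point the other way; the package resolves the
contradiction by using the inverted magnitudes, so that simulated males
outlive females and CNV carriers die earlier, matching the stratum means.

What the generator deliberately does **not** emulate: GC/wave artifacts,
probe-specific response, repeat-mediated probe failure, segmental
duplications, reference-DNA polymorphism, or any dose-response structure.
Passing tests therefore demonstrate the correctness of the *rules and
statistics*, not robustness to real-array artifacts — inputs are assumed to
be pre-normalised log2 ratios, as produced by standard feature-extraction
software.

Determinism is part of the contract: a `sim_config()` seed fixes the
cohort, the signals and the plates exactly, and `run_cnv_pipeline()` tags
every artifact it writes with a hash of the configuration.

## Numerical and design choices worth knowing

* Thresholds use strict `>` everywhere ("exceeded").
* Planted CNVs within one family are kept at least `min_cnv_separation`
  (default 20 kb) apart, inherited copies of a founder CNV excepted. Real
  germline CNVs essentially never coincide within a family except by
  descent; without this constraint the compressed synthetic genome would
  routinely collide events, and a de novo CNV falling inside the family
  window of a parental CNV is removed by family analysis — exactly as the
  real design would remove it, but not a property worth simulating by
  accident.
* CNVs smaller than the first-tier spacing usually cover no screening probe
  and are lost in the first screen — a stated limitation of the emulated
  two-tier design; the dense tier only refines loci the coarse tier found.
* Problem sizes in the tests (2 × 5 Mb genomes, 50 trios for the zero-noise
  recovery study, 5,000 mice for Cox recovery, 1,000 plates per copy state)
  were chosen as the smallest scales at which each property is sharply
  testable.

## Known limitations

The pipeline has no breakpoint refinement beyond probe resolution, no
normalisation or wave correction, no X/Y handling (autosomal probes only),
and applies no multiple-testing correction across strata — the statistics
layer mirrors a design that reported unadjusted per-stratum tests. The
qPCR model is a clean log-linear chemistry; competition effects in duplex
reactions are not modelled.
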