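---
title: "Mining multimorbidity patterns in stratified EHR cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining multimorbidity patterns in stratified EHR cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmpatterns)
```

## The problem and the model

Multimorbidity is defined here as the presence of two or more chronic
conditions in one individual, operationalised as an itemset of size ≥ 2
of 3-character ICD-10-CM parental categories. The package asks a
stratified question: within each race/ethnicity × age-band ×
obesity-class subgroup, which disease combinations occur in at least a
fraction ξ of patients, and how does the set of combinations compare
across race groups of the same age/obesity cell?

The mining model is standard frequent-itemset detection. Let
*I* = {P₁, …, Pₘ} be the observed disease categories and each patient's
aggregated diagnosis list *L ⊆ I* a transaction. The support of a
pattern *A* is the number of transactions containing every item of *A*;
*A* is frequent when its support count is at least ⌈ξ·n⌉, where *n* is
the stratum denominator. Two modelling commitments matter:

* **The threshold is inclusive** (support ≥ ξ·n). In the five-patient
  example shipped with the package, lipidemia sits at exactly 60% under
  a 60% threshold and is reported frequent; an exclusive reading would
  drop it and contradict the expected output, so ≥ is used throughout
  and the minimum count is `ceiling(xi * n)` (computed with a small
  subtractive guard, since products like `0.05 * 2000` exceed 100 by one
  ulp in floating point and must not round up to 101).
* **Support is prevalence.** The denominator is all included patients in
  the stratum, including patients whose in-window records contain no
  *eligible* category: the inclusion criteria require a diagnosis
  record, not an eligible chronic one, so dropping empty transactions
  would silently inflate every prevalence. A `drop_empty` flag exists
  for the alternative reading.

## Cohort construction

Patients are included iff: age ≥ 45; at least one valid BMI measurement
(18.5–206, both bounds inclusive — recorded BMI values above ~206 are
treated as data errors and dropped, not clamped); a mappable
race/ethnicity; at least one in-window ICD-10-CM record; and no
in-window ICD-9-CM record (a mixed-era coding history makes category
aggregation unreliable). Every failed criterion is recorded — exclusion
reasons are not short-circuited — so planted violations can be counted
exactly in tests.

Age bands are 45–64 (`middle_aged`) and 65+ (`elderly`). The obesity
class uses the unweighted arithmetic mean of a patient's valid BMI
measurements with an inclusive boundary: mean ≥ 30 is `with_obesity`.
Age is taken as supplied in the demographics table; the package does not
attempt to reconstruct age at a particular encounter. Race labels pass
through a configurable mapping that merges Asian, Pacific Islander and
Asian/Pacific Islander (the source labels cannot be separated), sends
missing/"Other"/"Mid-Eastern Indian" to `excluded`, and rejects — with a
warning, never silently — anything unrecognised.

The eligible-category filter defaults to the chapters D50–D89, E00–E89,
F01–F99, G00–G99, I00–I99, J00–J99, K00–K95, M00–M99 and N00–N99, minus
E66. Two deliberate choices sit here. The blood-disorder block D50–D89
is included because anemia categories are legitimate chronic conditions
of this kind of analysis even though D is not always listed with the
classic chronic chapters; the filter is fully config-overridable, so an
analysis that wants the narrower list passes its own ranges. E66
(obesity) is excluded by default because BMI already stratifies the
analysis; keeping the obesity diagnosis as an outcome would make every
`with_obesity` stratum trivially enriched for it.

## Mining and classification

FP-growth is implemented from scratch: items are ordered by descending
support with lexicographic tie-breaks (any consistent order is correct;
this one makes output deterministic and input-order invariant),
transactions are inserted into a prefix tree, and the tree is mined
recursively through conditional pattern bases. A brute-force enumerator
with the identical output contract — every non-empty subset of the
observed universe, support counted by containment, guarded to ≤ 20
items — serves as the independent oracle; the test suite requires exact
equality on randomized inputs, plus downward closure and
threshold-monotonicity as properties. Itemset size is uncapped by
default (`max_size` exists as a safety valve).

Classification is per (age band, obesity class) cell and never across
cells. A pattern's class is determined by the set of configured races in
which it is frequent; a race with no patients in the cell simply cannot
make a pattern `shared_all`, which the tests exercise directly. For
every configured race the full support count, prevalence and
Clopper–Pearson interval are retained even below threshold, because the
downstream g-test needs the complete table and because "not frequent" is
a display state, not missing data. `report_filter()` applies a
presentation-only prevalence floor (e.g. 0.08 or 0.065 when a cell holds
too many patterns to plot) and is guaranteed not to affect
classification.

## Statistics

* **Clopper–Pearson** intervals invert the exact binomial tails; the
  implementation uses the equivalent Beta-quantile closed form
  (`qbeta(α/2, x, n−x+1)` / `qbeta(1−α/2, x+1, n−x)`) with the x = 0 and
  x = n boundaries fixed at 0 and 1. Tests verify agreement with direct
  bisection of the binomial tails to 10⁻⁸ and conservative coverage by
  simulation.
* **g-test**: G = 2 Σ O·ln(O/E) with 0·ln 0 = 0, referred to χ² on
  (r−1)(c−1) df. By default the table includes *all* configured races
  (present/absent per race), using the full information; a Williams
  correction flag exists but is off by default, and no multiple-testing
  correction is applied by default (a Benjamini–Hochberg option is
  available via `pattern_g_tests(..., p_adjust = "BH")`). The g-test is
  the canonical comparison here; Pearson's χ² is asymptotically
  equivalent and the suite checks the two agree within 5% when expected
  counts are large.
* **Kruskal–Wallis** with mid-ranks and the tie correction
  C = 1 − Σ(t³−t)/(N³−N) compares per-patient mean BMI across races
  within each cell, guarding against a race's BMI distribution driving
  its prevalence differences within a weight class. This is the standard
  rank statistic — an approximation to a "median ANOVA", chosen because
  it is exact, assumption-light and has a verifiable closed form. All
  values identical is an error (C = 0, statistic undefined), not a
  silent zero.

## The synthetic-data generator

`generate_ehr()` emulates the qualitative shape of a large US EHR
warehouse cohort, not any real dataset: six race groups with strongly
unequal sizes (default per-stratum sizes 4000 Caucasian down to 800
Biracial, echoing a Caucasian-dominant population), two age bands, two
obesity classes, BMI drawn from truncated normals centred near the
class-typical medians (location 25.5, scale 2.5 without obesity;
34, 3 with), about seven encounters per patient (shifted Poisson) with
uniform in-window dates, and a configurable block of deliberately
invalid patients, each violating exactly one inclusion criterion so the
exclusion cascade can be checked count-for-count.

Disease incidence uses a conditional-independence-given-cluster model:
each background item is an independent Bernoulli(pᵢ) per patient, and
each planted cluster adds all of its items with activation probability
q, giving the closed-form joint prevalence q′ = q + (1−q)·Πpᵢ. That
closed form is the point — it makes exact oracles possible (recovery
within 3 binomial standard errors, unbiasedness across seeds). Default
plantings use item-disjoint clusters ({E78,I10} everywhere, q = 0.30;
{E11,N18} in two races, q = 0.25; {F17,J44} in one, q = 0.20) with the
cluster items' background prevalence held at 0.02 elsewhere, so each
cluster's intended sharing class is unambiguous by design margin.
Independent clusters can still produce emergent frequent pairs (e.g.
{E11,I10} at ≈ q₁·q₂ in a stratum carrying both clusters); these are
legitimate mined patterns and the ground-truth ledger verifies planted
clusters only.

What the generator does *not* emulate: real comorbidity dependence
structures (everything off-cluster is independent), disease progression
over time, encounter-type or care-setting structure, within-patient BMI
drift (repeated measurements are identical by construction, so the
obesity-class constraint on the mean holds exactly), and coding noise
beyond random sub-code suffixes. Passing tests therefore demonstrate
correctness of the pipeline's logic and statistics, not fidelity of any
particular prevalence estimate to real populations.

## Problem sizes and reproducibility

The default end-to-end validation uses ~44,000 synthetic patients
(24 strata of 800–4000), which the full pipeline processes in seconds;
simulation-based checks use 5000 replicates for interval coverage and
2000 for test sizes — enough for ±0.02 Monte-Carlo resolution at the
0.05 level. All generation and analysis is deterministic given a seed
and a config; output CSVs are stamped with an FNV-1a hash of the
analytic config, and equal hash plus equal inputs implies bit-identical
tables.

## Known limitations

* Eligibility is a chapter-range approximation; no validation against a
  curated chronic-condition sub-code list is attempted, and no
  ICD-9→ICD-10 mapping is provided (ICD-9 carriers are excluded
  instead).
* Hispanic participates as a race category alongside racial groups,
  mirroring common warehouse labelling; it is an ethnicity, and the
  configurable `race_list` is the escape hatch.
* Mining is single-machine. The per-stratum loop is embarrassingly
  parallel and strata are modest after stratification, so distributed
  execution is out of scope.
* No association-rule confidence/lift, no closed/maximal itemset
  reduction, and no gender stratification.
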