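---
title: "Quantitative H/CL scoring for bone-tracer cardiac scintigraphy: methods and design"
author: "hclquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative H/CL scoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hclquant)
```

## The problem

Transthyretin cardiac amyloidosis (TTR-CA) avidly binds bone-seeking
technetium tracers (DPD, PYP), while light-chain amyloidosis (LC-CA) shows
little or no uptake. Planar scintigraphy therefore separates the two
non-invasively, but two reading methods coexist:

* the **Perugini visual score** - grades 0-3 comparing cardiac with bone
  uptake (0 none, 1 less than bone, 2 equal, 3 greater); and
* the **quantitative H/CL ratio** - total counts in a circular heart ROI
  divided by the counts in the same ROI mirrored across the sternal
  midline onto the contralateral hemithorax.

Grade-1 studies and ratios between 1.0 and 1.5 are equivocal under the
consensus (ASNC) reading. This package implements the quantitative
pipeline that addresses exactly that gap: per-grade H/CL intervals that
reclassify grade-1 studies, and an optimized single cut-off (1.3 instead
of the conventional 1.5) evaluated by sensitivity/specificity and ROC
analysis. Because patient images from the derivation cohort are not
publicly available, the package ships a Poisson-noise phantom and a
cohort simulator that reproduce the statistical structure every stage
assumes, plus the derivation cohort's published grade-by-diagnosis
composition as a built-in fixture.

## Quantification: ROI mirroring and the pixel-center rule

A `PlanarImage` stores a matrix of detected events per pixel (1-based
`[row, col]`, pixel centers at integer coordinates) with pixel spacing,
acquisition time and projection. A `CircularROI` is a continuous center
plus radius; a pixel belongs to the ROI when its center lies within the
radius, boundary inclusive (with a 1e-9 slack on the squared distance to
keep exactly-on-boundary pixels stable under floating-point mirroring).
Mirroring reflects the center column: `col' = 2 * midline - col`.

`computeHcl()` requires the midline to sit on an integer or half-integer
column. Under that restriction the mirror maps integer pixel columns to
integer pixel columns bijectively, so the heart ROI and its contralateral
twin always contain the *same number of pixels* - the property that makes
H/CL a pure uptake contrast rather than partly an area ratio. Arbitrary
fractional midlines would break the pixel-count equality silently, so
they are rejected rather than accepted approximately.

Further conventions, chosen where the clinical procedure is manual and
under-specified:

* **ROI placement is an explicit input.** Readers place ROIs by hand;
  `centerOnCentroid()` optionally centers the ROI on the count-weighted
  centroid of a user-supplied search box.
* **Midline default** is the vertical image center, overridable in the
  run configuration; no anatomical midline detection is attempted.
* **Projection/time**: H/CL is defined on the anterior projection at
  about 3 h post-injection. Other projections or times are accepted with
  a warning, never silently.
* **No background or blood-pool correction** is applied; the ratio is
  raw-count H over raw-count CL. A contralateral total of zero is a
  domain error (flagged), not an infinite ratio.

## Classification rules

`classifyAsnc()` implements the consensus three-category reading:
suggestive when grade >= 2 *or* H/CL >= 1.5; inconclusive when grade = 1
*or* H/CL in [1.0, 1.5); otherwise not suggestive. Each category is a
disjunction, so conflicting visual/quantitative signals need a
precedence: any suggestive clause wins, then any inconclusive clause.
The printed band "1 to 1.49" is read as the half-open interval
[1.0, 1.5) at full precision - reading it as closed at 1.49 would leave
ratios like 1.495 unclassifiable.

`classifyThreshold()` applies pure H/CL rules: two-category (suggestive
iff ratio >= cutoff) or three-category with an inconclusive band
[lower, cutoff). The 1.3 rule that motivates the package is usually run
two-category; the band variant (default lower bound 1.0, the blood-pool
floor) exists because inconclusive proportions are reported against both
1.5 and 1.3 cut-offs.

### Grade-1 reclassification

`fitGradeIntervals()` estimates the per-grade H/CL arithmetic mean and
sample SD (n - 1 denominator; a single-record grade reports an NA SD,
never zero). The derivation cohort's intervals are
0.98 ± 0.11, 1.32 ± 0.40, 1.54 ± 0.35 and 2.40 ± 0.76 for grades 0-3.

The reported clinical procedure "regroups" grade-1 studies using these
ranges without stating the assignment function, and the ranges overlap
(grade 1's ±1 SD band spans 0.92-1.72, covering the grade-2 mean).
`reclassifyGrade1()` therefore implements two explicit interpretations:

* **nearest mean** (default): assign the grade minimizing
  `|hcl - mean_g|`. Parameter-free, reproduces the reported
  directionality (low ratios move to grade 0, high to grade 3, the
  grade-2 slot is reachable between the tie points), and is monotone in
  H/CL whenever the means increase with grade.
* **standardized distance** (`method = "standardized"`): minimize
  `|hcl - mean_g| / sd_g`, which lets the wide grade-1 interval retain
  more of its patients.

Ties break toward the lower grade - the conservative direction, since
higher grades imply TTR-CA. Both variants are interpretations: the exact
published reassignment of individual patients cannot be reverse-engineered
without patient-level ratios, which were never printed. For the same
reason the number of grade-1 patients that *move* under reclassification
is not a reproduction target: with the published grade-1 SD of 0.40,
nearest-mean moves most simulated grade-1 records, whereas the derivation
cohort reported 6 of 19.

## Performance evaluation

Disease-positive means a final diagnosis of TTR-CA; LC-CA counts as
disease-negative, which is why a suggestive LC-CA study is a false
positive. `confusion()` counts inconclusive studies as test-negative by
default - the only convention under which the published percentages are
arithmetically consistent (76 of 81 TTR-CA positive at 1.3 gives 93.8%)
- with an option to exclude them instead.

Percentages are kept at full precision and rounded only at reporting
time (`performanceRow()`), half away from zero so 98.876 prints as 99,
matching clinical-table conventions; `round()`'s half-to-even would
print 90.5 as 90.

`rocCurve()` sweeps "positive iff H/CL >= t" over the sorted distinct
observed ratios plus ∓Inf sentinels. `optimalCutoff()` supports the
criterion that actually produced the 1.3 proposal - maximize sensitivity
subject to specificity not dropping below the reference (1.5-rule)
specificity, returning the smallest such threshold - plus the Youden
index (ties to the larger threshold). When no threshold meets the
reference specificity the result is an explicit NA, not a silent
fallback. Because thresholds are observed values, the selected numeric
cutoff can land on the first observed ratio marginally above the
reference rule's cutoff while being classification-equivalent to it;
tests therefore assert dominance of the operating point rather than a
knife-edge inequality on the numeric threshold.

Group comparison across grades uses the tie-corrected Kruskal-Wallis
test (delegated to `stats::kruskal.test()`) with per-group mean pooled
midranks. When every observation is tied the H statistic is 0 by
definition (all midranks equal); `kruskalWallisByGrade()` returns that
rather than the 0/0 the tie-correction formula produces. No specific post-hoc
procedure is canonical after a Kruskal-Wallis omnibus; Dunn's z-test on
the pooled midranks with Holm adjustment is the standard choice and is
implemented directly (no CRAN implementation is assumed), configurable
to Bonferroni or unadjusted.

## The synthetic-data generators

### Phantom

`generatePhantom()` draws each pixel independently from a Poisson law
whose mean is a uniform soft-tissue background, plus an additive rate on
vertical bone stripes (a spine band on the midline and one
mirror-symmetric rib band per side), plus the grade's cardiac rate on a
circular disc left of the midline. Defaults: 128 x 128 pixels,
background 100 counts/pixel, bone +60, heart disc radius 20 at
(64, 36), midline 64.5. Grade-specific cardiac rates are the background
multiplied by the canonical per-grade H/CL levels (1.00, 1.32, 1.54,
2.40): grade 0 equals background (no uptake) and the expected disc-total
ratio of a grade-g phantom is the H/CL its grade should produce
(`expectedPhantomRatio()` gives the closed form from the rate image).
The bone default puts stripe pixels at 160 counts/pixel so grade-1
hearts (132) sit visually below bone, grade 2 (154) near it, grade 3
(240) above it - the Perugini ordering. With these rates the
contralateral disc collects ~1.3e5 expected counts, so the Poisson
relative error of the ratio is ~0.4%, far inside the 5% recovery
tolerance the tests use.

The phantom deliberately emulates *only* what H/CL consumes - regional
count totals under counting noise. It has no attenuation, scatter,
collimator blur, organ anatomy, or patient variability; passing phantom
tests validates the quantification arithmetic, not clinical image
realism.

### Cohort

`generateCohort()` draws per-grade H/CL values from a normal law
truncated below at `hclFloor` (default 0.5) - published per-grade summary
statistics do not pin down a distribution family, and a floor-truncated
normal keeps ratios physical while the published SDs clip essentially no mass except in the
wide grade-1 interval. Sampling is by inverse CDF, so it is exact and
rejection-free. Defaults reproduce the derivation cohort: 170 patients
split (77, 19, 7, 67) across grades with the per-grade moments above,
and the empirical grade-wise diagnosis mix (grade 0: 3 LC-CA, 74 none;
grade 1: 8 TTR-CA, 5 LC-CA, 6 none; grade 2: all TTR-CA; grade 3:
66 TTR-CA, 1 LC-CA).

Diagnosis labels are assigned by largest-remainder allocation of
`n_grade x mix`, shuffled within the grade: the realized composition is
the closest integer composition to the expected one, so the default
parameterization yields exactly 81 TTR-CA / 9 LC-CA / 80 none on every
seed (a multinomial draw would only hit those totals with ~2% probability
per grade margin), while non-integer expectations still land within one
record of them. Grade counts match `nPerGrade` exactly by construction.

Randomness follows a one-root-seed contract: the root seed is mixed into
independent per-grade (and, in the pipeline, per-image) child streams by
a Lehmer-style step `(root * 48271 + index) mod (2^31 - 1)`, so
generators are pure functions of `(params, seed)`, never touch the
caller's RNG state, and sub-sampling one grade does not shift another's
draw.

Whether grade-1 TTR-CA and grade-1 LC-CA patients differ in their H/CL
distribution is unknowable from published data; the generator
deliberately draws H/CL independently of diagnosis within a grade, and
the mix matrix is the single knob a user can turn to explore that
coupling.

### Reference fixtures

`referenceCohort()` is the deterministic 170-record grade-by-diagnosis
contingency skeleton of the derivation cohort (H/CL unset; supports
grade-level analyses such as the visual rule). `referenceCohortHcl()`
additionally assigns each record a *band-representative* H/CL value
(1.60 / 1.40 / 1.10 / 0.90) reconstructed from the published
classification margins - 75 suggestive at 1.5 (2 LC-CA), 4 patients
moving to suggestive at 1.3 (3 TTR-CA), 41 inconclusive at 1.3, 50 below
1.0 (3 LC-CA). These are synthetic placeholder values: any analysis that
depends only on band membership (threshold rules, confusion counts,
inconclusive proportions) is exact on this fixture, while
distribution-sensitive analyses (Kruskal-Wallis, interval fitting, exact
reclassification) are not meaningful on it and use simulated cohorts
instead.

## Problem sizes used by the checks

The test suite and acceptance script size their computations as follows:
the reference fixtures are the full 170 records; oracle-equivalence
properties run on ~250 randomized instances of at most 20 records each
against brute-force reimplementations; distributional recovery uses
1e4 records per grade (against the truncated-normal expectation, within
3 standard errors); the Kruskal-Wallis ordering property uses 10 cohorts
of 170 at the default parameters; cut-off parameter recovery uses 10
cohorts of 17,000 (100x the study composition); phantom recovery uses
single 128 x 128 images (>= 1e5 contralateral counts).

## Known limitations

* The reconstructed H/CL values in `referenceCohortHcl()` are band
  placeholders, not measurements; the exact published Kruskal-Wallis
  chi-squared (129.57) and mean ranks depend on unpublished patient-level
  ratios and are reproduced only as stochastic properties (p < 0.001,
  ranks strictly increasing with grade) on simulated cohorts.
* The reclassification function is an interpretation (two variants
  provided); the published per-patient reassignment is not recoverable.
* The phantom validates count arithmetic, not acquisition physics.
* DICOM ingestion is not provided; images enter through the plain-text
  grid + JSON sidecar format (8-bit PNG export is preview-only).
* The derivation cohort is a single-center population; its thresholds
  and intervals are inputs here, not re-validated clinical claims.
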