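# hclquant

Quantitative heart/contralateral (H/CL) count-ratio scoring of planar
bone-tracer scintigraphy for the diagnosis of transthyretin cardiac
amyloidosis (TTR-CA), for nuclear-medicine and cardiology researchers who
want the quantitative reading pipeline as tested, scriptable code rather
than a manual workstation procedure.

TTR amyloid binds bone-seeking ⁹⁹ᵐTc tracers (DPD, PYP); light-chain
amyloid largely does not. Two readings of the anterior planar image
coexist: the Perugini visual grade (0–3, cardiac vs bone uptake) and the
quantitative ratio

    H/CL = (total counts in a circular cardiac ROI)
         / (total counts in the same ROI mirrored across the sternal midline)

The consensus (ASNC) reading is *suggestive* of TTR-CA when grade ≥ 2 or
H/CL ≥ 1.5, *inconclusive* when grade = 1 or H/CL ∈ [1.0, 1.5), and *not
suggestive* otherwise — leaving grade-1 studies equivocal. This package
implements the quantitative extensions aimed at that gap:

* **H/CL quantification** from count images via pixel-center circular ROI
  membership and midline mirroring (`computeHcl`), with guaranteed equal
  pixel counts in the two ROIs;
* **classification rules**: the ASNC three-category rule, single-threshold
  rules (conventional 1.5, optimized 1.3), and **grade-1 reclassification**
  through per-grade H/CL intervals (mean ± SD per Perugini grade,
  nearest-mean or standardized-distance assignment);
* **performance evaluation**: confusion tables against the final diagnosis
  (TTR-CA = disease-positive), sensitivity/specificity with reporting-time
  rounding, ROC sweeps, cut-off optimization holding a reference
  specificity, Kruskal–Wallis across grades with Dunn–Holm post-hoc;
* **synthetic data**: a Poisson-noise thorax phantom with grade-dependent
  cardiac uptake, a seeded cohort simulator calibrated to the published
  per-grade H/CL moments (0.98 ± 0.11, 1.32 ± 0.40, 1.54 ± 0.35,
  2.40 ± 0.76; 77/19/7/67 patients per grade), and the 170-patient
  reference cohort composition as a built-in fixture.

## Worked example

```r
library(hclquant)

## 1. Quantify a grade-3 phantom image
p <- PhantomParams()
img <- generatePhantom(3, p, seed = 7)
computeHcl(img, heartRoi(p))
#> HClResult: H = 302042, CL = 126060 (1257 px each), H/CL = 2.3960
```

The measured ratio 2.396 recovers the phantom's closed-form expected disc
ratio of 2.40 (`expectedPhantomRatio(3, p)`) to within Poisson noise.

```r
## 2. Threshold rules on the built-in 170-patient reference cohort
coh <- referenceCohortHcl()
cat15 <- classifyThreshold(coh$hcl, ThresholdRule(1.5, 1.0, "three_category"))
performanceRow(sensSpec(confusion(coh, cat15)), 0, "H/CL >= 1.5")
#>          rule sensitivity specificity
#> 1 H/CL >= 1.5          90          98
cat13 <- classifyThreshold(coh$hcl, ThresholdRule(1.3, mode = "two_category"))
performanceRow(sensSpec(confusion(coh, cat13)), 0, "H/CL >= 1.3")
#>          rule sensitivity specificity
#> 1 H/CL >= 1.3          94          97
```

Lowering the cut-off from 1.5 to 1.3 raises sensitivity (90% → 94%;
76 of 81 TTR-CA patients positive, 93.8% at one decimal) while the
inconclusive share drops from 45/170 (26.5%) to 41/170 (24.1%).

```r
## 3. Interval fitting, group separation and grade-1 reclassification
sim <- generateCohort(CohortParams(), seed = 42)
fitGradeIntervals(sim)
#> GradeIntervals (H/CL by Perugini grade):
#>   grade 0: mean 0.992, sd 0.114, n 77
#>   grade 1: mean 1.358, sd 0.342, n 19
#>   grade 2: mean 1.451, sd 0.404, n 7
#>   grade 3: mean 2.499, sd 0.809, n 67
kruskalWallisByGrade(sim)
#> Kruskal-Wallis: chi-squared 120.24, p <0.001
#>   mean ranks: 0=43.34, 1=86.00, 2=88.57, 3=133.49
head(reclassificationFlow(sim), 3)
#>   patient_id diagnosis      hcl new_grade
#> 1       P078    TTR-CA 1.331684         1
#> 2       P079    TTR-CA 1.047392         0
#> 3       P080    TTR-CA 1.840905         2
```

The simulated cohort recovers the calibrated per-grade intervals, the
H/CL distributions separate sharply across grades (p < 0.001 with mean
ranks increasing in grade), and equivocal grade-1 records are reassigned
to the grade whose interval their ratio falls in.

A command-line front end over the same functions ships at
`inst/cli/hclquant.R` (subcommands `simulate`, `quantify`, `classify`,
`evaluate`, `report`; JSON run configuration; exit code 2 on validation
errors).

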