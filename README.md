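# drquad

Quadrant analysis of diabetic retinopathy (DR) lesions on a modified
ETDRS grid.

## What it is for

Microaneurysms (MA) and retinal hemorrhages (HEM) are the elementary
lesions of diabetic retinopathy, and their *spatial* distribution across
the retina carries clinical signal: lesions concentrate in the temporal
and inferior retina, increasingly so with severity. `drquad` is for
researchers quantifying that asymmetry from macula-centered 45-degree
fundus photographs. It provides:

* **Grid geometry** — a modified ETDRS grid centered on the fovea: a
  1500 µm central ring reported separately, and four quadrants
  (superior / temporal / nasal / inferior, boundaries on the ±45°
  diagonals) extended to the periphery of the photographed field.
  Temporal and nasal are anatomical: eye laterality is inferred from the
  optic-disc side (`infer_laterality`), and every point gets exactly one
  region label (`assign_region`, `count_by_region`).
* **Grading** — the MESSIDOR count-based severity rules
  (`grade_from_counts`): level 0 (µA = 0 ∧ H = 0); level 1
  (0 < µA ≤ 5 ∧ H = 0); level 2 ((5 < µA < 15 ∨ 0 < H < 5) ∧ NV = 0);
  level 3 (µA ≥ 15 ∨ H ≥ 5 ∨ NV = 1), evaluated severe-first.
* **Statistics** — per lesion × grade × quadrant summaries (n, mean, SD,
  SEM), one-way ANOVA across quadrants and across grades, and pairwise
  two-sample t against a reference quadrant, computable from raw values
  (`t_independent`) or straight from printed summary statistics
  (`t_from_summary`): t = (m₁ − m₂) / √(s₁²/n₁ + s₂²/n₂).
* **Synthetic cohorts** — `simulate_cohort` draws per-quadrant lesion
  counts from negative-binomial distributions moment-matched to published
  MESSIDOR-like and MIRADATASET-like per-grade tables, places lesions
  geometrically, and optionally renders fundus-like images
  (`render_fundus`) for the classical blob detector (`detect_lesions`) —
  a fully specified stand-in for a trained segmenter, so the whole
  pipeline runs with no downloads or model weights.

## Worked example

Simulate the severe-DR stratum of the MESSIDOR-like preset (261 images),
count lesions on the grid, and build the cohort report:

```r
library(drquad)

co  <- simulate_cohort(cohort_spec("messidor", grades = "Severe", seed = 7))
cc  <- cohort_counts(co)
rep <- build_report(cc, data.frame(image_id = co$strata$image_id,
                                   grade = co$strata$grade),
                    database = "messidor")

rep$summary[rep$summary$lesion == "MA", c("quadrant", "n", "mean", "sd", "sem")]
#>  quadrant   n mean   sd   sem
#>  superior 261 2.28 2.85 0.177
#>  temporal 261 5.33 6.59 0.408
#>     nasal 261 1.92 2.46 0.152
#>  inferior 261 3.34 3.44 0.213

rep$pairwise_t[rep$pairwise_t$lesion == "MA", c("comparison", "t", "df", "p")]
#>            comparison    t  df        p
#>  temporal vs superior 6.87 354 2.94e-11
#>     temporal vs nasal 7.83 331 6.72e-14
#>  temporal vs inferior 4.32 392 1.97e-05
```

The temporal quadrant carries the largest MA burden (mean 5.33 per image
against 1.92 nasally), the pairwise t values are large and the one-way
ANOVA across the four quadrant groups rejects equality decisively
(F(3, 1040) = 35.3, p ≈ 1e-21) — the temporal/inferior concentration the
grid analysis is designed to expose. Recomputing t from published summary
cells works the same way:

```r
t_from_summary(as_summary_stats(5.50, 6.52, 261),
               as_summary_stats(1.86, 2.22, 261))
#> two-sample t (welch): t = 8.538, df = 319.5, p = 5.63e-16
```

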