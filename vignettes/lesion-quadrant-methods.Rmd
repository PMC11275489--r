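---
title: "Methods: lesion quadrant mapping, grading and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion quadrant mapping, grading and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drquad)
```

## The problem

Diabetic retinopathy (DR) is graded from counts of its elementary lesions —
microaneurysms (MA, small saccular capillary outpouchings, typically below
125 um) and retinal hemorrhages (HEM, larger and darker) — on 45-degree
macula-centered fundus photographs. Beyond the totals, the *spatial
distribution* of these lesions is clinically informative: lesions
concentrate in the temporal and inferior retina, and that asymmetry grows
with severity. `drquad` implements the geometric, grading and statistical
machinery needed to quantify this: a modified ETDRS grid whose four
quadrants extend to the periphery of the photographed field, the MESSIDOR
count-based severity rules, and per-grade per-quadrant cohort statistics.

Because clinical image cohorts and trained lesion segmenters are not
redistributable, the package also ships a calibrated synthetic cohort
generator and a simple classical blob detector, so that every stage of the
pipeline — detection, quadrant counting, grading, statistics — is
exercisable and testable end-to-end from a bare install.

## Grid geometry

The grid is centered on the fovea. Three nested decisions define it:

* **Central ring.** Points within 750 um of the fovea (a 1500 um diameter
  ring, the foveal avascular zone) form the `central_ring` region, reported
  separately and never merged into a quadrant. Healthy anatomy predicts no
  vascular lesions here, and the generator guarantees it by construction,
  so a nonzero central-ring count in a report flags a geometry error.
* **Quadrants.** The classic ETDRS diagonal division: boundary rays at 45,
  135, 225 and 315 degrees from the horizontal through the fovea, extended
  outward to the field periphery. With theta the counter-clockwise angle
  from the rightward horizontal (superior up), the superior wedge is
  (45, 135] and the inferior wedge (225, 315]; the half-open intervals
  make assignment total and deterministic — a point exactly on a boundary
  ray belongs to the wedge clockwise of it. The two horizontal wedges are
  named by anatomy, not by image side: *temporal* is the side opposite the
  optic disc, *nasal* the disc side.
* **Field.** The analysis field is the inscribed circle of the image
  (radius `min(width, height)/2` px around the image center); anything
  beyond it is `outside_field` and excluded from quadrant totals. This is
  a deliberate simplification of the camera aperture: on a 3:2 image the
  optic disc (about 4500 um from the fovea) falls just outside this
  circle, which matches the macula-focused intent of the grid.

Laterality is inferred from the optic-disc side (`infer_laterality`): the
package convention is a non-mirrored macula-centered photograph, in which
the disc is nasal, so a disc on the image-right of the fovea means a right
eye. Two symmetry properties follow and are tested: flipping the
laterality at fixed image positions swaps temporal and nasal labels, while
mirroring the frame *and* the marks together preserves every anatomical
label (a mirrored right-eye photograph is indistinguishable from a left
eye).

Physical scale is set by `um_per_px = fov_deg x 288 / width_px`, using the
standard emmetropic conversion of roughly 288 um of retina per degree of
visual angle; at the default 1440-px-wide 45-degree field this is
9 um/px. The 288 um/deg constant is configurable; none of the geometric
logic depends on its exact value, only the absolute ring size does.

## Grading

`grade_from_counts` applies the MESSIDOR rule set to whole-image totals:
level 0 when both counts are zero; level 1 (mild) when 0 < MA <= 5 and
HEM = 0; level 2 (moderate) when (5 < MA < 15 or 0 < HEM < 5) and no
neovascularization; level 3 (severe) when MA >= 15, HEM >= 5 or
neovascularization is present. The clauses overlap at their boundaries
(MA = 3 with HEM = 7 satisfies fragments of both moderate and severe), so
the implementation evaluates severe first, then moderate, then mild; this
makes the function total and monotone in each count, which the tests
verify exhaustively over a grid of inputs against a literal re-evaluation
of the boolean formulas. Counts used for grading are whole-image totals
(inside the field); per-quadrant grading is deliberately not defined.
Macular edema is out of scope.

## Cohort statistics

`summary_stats` reports n, mean, SD (n − 1 denominator) and SEM.
`t_from_summary` computes the independent two-sample t from two
(mean, sd, n) triples — the form in which cohort tables are published —
with Welch (default) or pooled variance; with equal group sizes the two t
values are identical and only the degrees of freedom differ.
`t_independent` is defined as the composition of the two, and the test
suite holds the routes together to 1e-9 and cross-checks both against
`stats::t.test`. `anova_oneway` is the classic fixed-effects one-way F,
delegated to `stats::oneway.test(var.equal = TRUE)` with an explicit
F = 0, p = 1 convention for the fully degenerate all-identical case.

`build_report` assembles the full cohort report: the summary grid per
lesion type x grade x quadrant, ANOVA across the four quadrants within
each grade and across grades within each quadrant, and pairwise t tests of
a reference quadrant (temporal by default) against the other three.
Design choices worth stating:

* **Quadrants as independent groups.** The four quadrant samples of one
  cohort come from the same eyes and could be treated as paired;
  published severe-DR pairwise t values are reproducible only under the
  independent two-sample formula at the stratum n, so that is the
  default procedure here. (A paired analysis would be *more* powerful;
  the independent analysis is the conservative and reproducible choice.)
* **No multiplicity correction** is applied; p-values are raw, matching
  the source procedure. Users comparing many cells should correct
  downstream (`p.adjust`).
* **Degenerate cells.** Grade x quadrant cells with fewer than two images
  appear with `n` and `NA` statistics — explicit absence, never a silent
  zero. A pairwise comparison of two identical constant groups reports
  t = 0, p = 1.

A documented discrepancy: recomputing the severe-DR hemorrhage
temporal-versus-nasal t from the published summary cells gives about
6.90, not the printed 7.72; the other five severe-DR t values reproduce
to within 0.05. The acceptance tests assert the recomputed value and
treat the printed one as an erratum. Printed p-values attached to some
published t statistics (p = 0.02 at t about 6.9 with over 500 degrees of
freedom) are internally inconsistent and are not reproduced; t values are
the audited surface.

## Synthetic cohorts

The generator's presets encode the study conditions: a MESSIDOR-like
cohort (182 mild, 162 moderate, 261 severe images) and a MIRADATASET-like
cohort (300 images per grade), each with per-quadrant MA/HEM count
distributions whose means and SDs equal the published per-cell values.
Presets are plain YAML under `inst/extdata/presets/`.

* **Count law.** Only means and SDs are published. Every severe-DR cell
  is overdispersed (SD > mean), so counts are drawn from a negative
  binomial with moment-matched size `r = mean^2/(sd^2 - mean)`; cells with
  `sd^2 <= mean` fall back to Poisson (matching the mean exactly, the
  variance approximately), and a zero mean is a point mass at zero.
  Moment recovery is tested at 1e5 draws.
* **Placement.** Within its target quadrant a lesion is uniform — no
  sub-quadrant spatial law is published — implemented by rejection
  sampling against `assign_region` itself, so geometric closure (every
  mark maps back to its target quadrant; the central ring stays empty) is
  a construction property, not a hope. An optional minimum-separation
  constraint produces non-overlapping scenes for detector tests.
* **Laterality mix** is unreported; the default is 50/50 right/left,
  reflected in the simulated disc positions and hence in which image side
  is temporal.
* **Consistency modes.** The default `table_calibrated` mode reproduces
  the published cell moments even where they contradict the grading rules
  (published mild-DR strata have nonzero hemorrhage means although the
  mild rule requires HEM = 0 — the source tables and rules genuinely
  disagree). The `rule_consistent` mode instead minimally adjusts each
  image's counts (dropping or adding single lesions) until its recomputed
  grade matches its stratum, at the cost of biasing the calibrated
  moments. Tests cover both; table calibration is the default because the
  statistical tables are the reproduction target.

What the generator does *not* emulate: vessel trees, exudates, image
noise and contrast variation of real cameras, lesion clustering along
vessels, inter-eye correlation, or grader disagreement. Passing tests
demonstrate that the pipeline's geometry, grading and statistics are
correct and that the published table arithmetic is reproducible under the
stated distributional assumptions — not that the detector would perform
on real photographs.

## Rendering and detection

`render_fundus` paints a deliberately simplified fundus: uniform reddish
background inside a circular aperture (radius `width/2`; corners black),
a bright optic disc, a mildly darker macula, MAs as small dark-red discs
and HEMs as larger, darker, mildly elliptical blotches with
equivalent-circle area preserved, plus a little Gaussian pixel noise.

`detect_lesions` is the matching classical detector: the green channel
(standard for red-lesion contrast) is inverted, the median background
over the usable area subtracted, the response smoothed (Gaussian,
sigma 1 px), thresholded (default 0.15) and decomposed into connected
components; each component yields a centroid, an equivalent-circle
diameter and a mean contrast. Components are gated to
[20 um, 1500 um] and typed by the conventional clinical size cutoff:
diameter <= 125 um is an MA, larger is an HEM. The search area excludes
the optic-disc neighbourhood and everything outside the field circle.
The detector is deterministic, and raising the threshold can only shrink
the detected set on non-overlapping scenes.

This detector is a **stand-in**: the system it emulates used a trained
deep segmenter whose architecture and weights are not available. It
exists so the image-driven path of the pipeline is fully specified and
testable; round-trip tests (simulate, render, detect, count) recover
per-type counts exactly on non-overlapping scenes and are required to
reach F1 >= 0.95 over about 200 lesions. The default render diameter
ranges (MA 30-110 um, HEM 150-800 um) sit clear of the 125 um cutoff so
that pixelation at 9 um/px cannot flip a type.

## Numerical and size choices

* Stochastic tests fix seed 101 (replicate loops use 101..200); the
  acceptance script takes its seed from the command line.
* Parameter-recovery checks run at the preset stratum sizes (261 and 300
  images) and accept within 3 SEM of the generating mean; significance
  replication uses 100 simulated cohorts. These sizes keep the full suite
  to a few minutes while leaving the Monte-Carlo bands meaningful.
* Detector round-trip scenes use 14 rendered images of 16 lesions each
  with a 650 um minimum separation and HEM diameters capped at 500 um, so
  that no two lesions can merge into one component.
* `t_from_summary` errors on zero variance in both groups with equal
  means (t undefined) and returns an infinite t with p = 0 when the means
  differ; `build_report` maps the degenerate equal case to t = 0, p = 1.

## Limitations

The package reproduces a published analysis pipeline on calibrated
synthetic data; it makes no claim about real-image detector performance,
does not model macular edema or proliferative disease, does not implement
the original 9-subfield ETDRS rings beyond the central ring, and treats
quadrant samples as independent groups by design. The MESSIDOR severity
scale used here does not coincide with the International Clinical DR
scale.
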