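---
title: "Hippocampal substructure dosimetry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hippocampal substructure dosimetry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippodvh)
```

## The problem

In radiotherapy of nasopharyngeal carcinoma, the hippocampus sits close
enough to the target that it can receive a substantial incidental dose even
though it is rarely constrained during planning. Because the hippocampal
head lies anterior-inferior — nearest the nasopharynx — while the tail
points posterior-superior, the three anatomical subregions (head, body,
tail) are expected to receive systematically different doses, and they play
different roles in memory function. `hippodvh` quantifies that gradient: it
splits a delineated hippocampus into head, body and tail along the
anterior–posterior slice axis, computes the standard dose–volume metrics
for each part against a 3-D dose grid, and summarizes a patient cohort with
the usual tests.

## The layer-ratio split

The segmentation rule is deliberately simple enough for routine clinical
use. Count the coronal layers on which the structure appears; assign the
anterior 35% of layers to the head, the next 45% to the body and the
posterior 20% to the tail. In this package:

* **Layer count** is the *span*: the number of slices between the first and
  last occupied slice, inclusive (`count_layers()`). A gap inside the span
  (a slice where the delineation happens to be empty) still counts. A
  physician counting visible layers would bridge a single missing slice;
  the span convention makes the boundaries robust to such gaps.
* **Boundaries** are cumulative with round-half-up:
  `c1 = round_half_up(0.35 N)`, `c2 = round_half_up(0.80 N)`. Rounding the
  cumulative sums (rather than each fraction separately) guarantees the
  three counts add to N with no leftover layer. Round-half-up is
  implemented as `floor(x + 0.5 + 1e-9)`; the `1e-9` guard absorbs the
  binary representation shortfall of products such as `0.35 * 10`, which is
  stored as 3.4999999...ULP-below-3.5 territory in some expressions.
* **Whole layers only.** Every parent voxel on a layer goes with that
  layer; no layer is divided between two subregions. Together with
  cumulative boundaries this makes the split an exact partition: union
  equals parent, pairwise intersections empty, voxel counts additive —
  properties the test suite asserts on every random mask it generates.

For a structure with per-slice-constant volume and N divisible by 20 the
volume fractions are exactly 35/45/20%; for real (curved, tapering)
structures they drift a few percent, which is inherent to a layer-based
rather than volume-based rule.

An open choice was whether the ratios apply to the occupied-layer count or
to the physical anterior–posterior length. These coincide for uniform slice
thickness; we use layer count, matching how the rule is stated and applied
clinically (layers are what a physician scrolls through).

## Dose metrics

All doses are stored in cGy. The metrics follow the rank-statistic
convention rather than curve interpolation:

* `D_x%` (`dose_at_volume()`): the minimum dose received by the hottest x%
  of the structure — the dose at rank `ceiling(x M / 100)` of the M voxel
  doses sorted descending. `D_1%` approximates the maximum, `D_99%` the
  minimum, `D_50%` the volume median. Computing from order statistics
  removes any bin-width sensitivity; the binned cumulative histogram
  (`compute_dvh()`, default 10 cGy bins) exists only for curve export and
  plotting. Planning systems interpolate in slightly different,
  undocumented ways; the rank convention is declared and exactly testable.
* `V_d` (`volume_at_dose()`): the percentage of structure volume receiving
  at least d, with `>=` at the threshold (a boundary voxel counts as
  irradiated). Thresholds are named in Gy, as is conventional (`V5` = 5 Gy
  = 500 cGy), and converted internally.
* Masks are resampled to the dose grid (nearest neighbour,
  `resample_mask()`) before any metric is computed, so there is one
  canonical grid per patient and no intra-voxel dose interpolation. This
  matches treatment-planning practice; the cost is a volume discretization
  error of at most one dose-grid voxel per boundary voxel.

Rasterization of planar contours (`rasterize_contours()`) uses the
centre-inside / even-odd rule with no partial volumes: a voxel belongs to
the structure iff its centre lies inside an odd number of nested polygons
of its nearest contour plane (ties between planes resolve to the lower
slice index). The rule is deterministic and exactly reproducible by a
brute-force point-in-polygon scan, which is how the tests verify it.

## The synthetic cohort

No clinical images ship with the package; `make_cohort()` generates
phantoms carrying the geometric relationships the analysis depends on:

* **Anatomy.** Each hippocampus is a curved tube (default length 35 mm,
  radius 5 mm, volume ≈ 3.4 cc) running anterior-inferior to
  posterior-superior at ≈ 30° elevation, mirrored about the mid-sagittal
  plane, on an 80 × 80 × 60 grid at 2 mm isotropic spacing. Mild
  per-patient lognormal jitter (SD 6%) on length, radius and lateral offset
  gives the cohort realistic volume spread; both sides of a patient share
  the draw, preserving left–right symmetry.
* **Dose.** `dose(v) = d0 · j · exp(−‖v − s‖/λ)` with the source point `s`
  at a nasopharynx-like position anterior-inferior-medial to both
  structures, peak `d0 = 7040` cGy (a typical nasopharyngeal prescription,
  7040 cGy in 32 fractions), falloff length `λ = 25` mm, and a per-patient
  lognormal scale `j` (sdlog 0.2) emulating inter-patient anatomy and plan
  variation. λ was chosen so hippocampal mean doses land in the
  500–3000 cGy range reported for such plans; with the default geometry the
  simulated whole-structure mean dose is ≈ 1000 cGy and the head/body/tail
  means ≈ 1500/850/550 cGy.
* **Scores.** Optional paired digit-span scores:
  `pre ~ round(N(8.6, 1.34²))`, `post = round(pre − 0.6 + N(0, 1))`, both
  clipped to the instrument's 0–17 range.

Because the source is anterior-inferior and the field strictly decreasing
with distance, every phantom satisfies
`Dmean(head) > Dmean(body) > Dmean(tail)` on both sides — the qualitative
ordering the pipeline is designed to detect. That is also the generator's
main limitation: a real IMRT dose distribution is shaped by beams and
optimizer constraints, is not radially monotone, and can locally invert the
gradient (a posterior-extending tumour can dose the tail above the body).
Passing tests on phantoms therefore demonstrate correctness of the
*computation*, not universality of the head>body>tail finding in patients.
The phantoms likewise make no claim to atlas-level anatomical realism.

## Cohort statistics

Per side and metric, subregions are compared with classical one-way ANOVA
(`F = MSB/MSW`, via `lm`/`anova`) and pairwise Fisher-LSD t tests using the
pooled within-group mean square and its degrees of freedom
(`pairwise_tests()`), unadjusted by default. Clinical substructure tables
typically report unadjusted per-pair P values without naming a post-hoc
procedure; LSD reproduces that, and a Bonferroni option is provided for the
stricter reader. The pre/post score comparison is a paired two-tailed t
test. Significance is declared strictly below 0.050. Sample SD uses the
n − 1 denominator and is reported as undefined (an em dash in the CSVs) for
n = 1.

Degenerate cells are resolved explicitly rather than left to the fitting
machinery: all-identical values give F = 0, p = 1; zero within-group
variance with unequal means raises an error (no finite F exists); and in
the cohort tables a subregion whose cohort mean is 0 takes part in no test
— with one zero-mean group the overall ANOVA is computed over the remaining
groups, with two it is skipped — matching how such cells are conventionally
dashed out of published tables.

## Reporting pipeline

`run_study()` ties the stages together: simulate or load a cohort,
resample each structure to its dose grid, split 35/45/20, compute metrics,
then summarize across patients. It writes four CSVs (per-patient long
table; whole-structure D metrics per side; D metrics by subregion with test
columns; V metrics by subregion with test columns), an optional paired-score
table and a run log with one line per patient/side so skipped structures
are auditable. Structures spanning fewer than 3 layers (no valid 3-way
split) are skipped with a logged warning. Given the same seed the whole
run, files included, is byte-identical.

Internal exchange formats are plain JSON (contours, masks, dose grids) and
CSV (manifests, reports), so every test and example runs without binary
fixtures; a cohort written with `write_cohort()` reloads with
`load_cohort()`, and contour-format structures are rasterized onto the
patient's dose grid at load time.

## Problem sizes and numerical choices

The default phantom grid (384k voxels) keeps a 10-patient end-to-end study
under a few seconds, which is the scale the bundled examples and checks
use; the per-module verification runs brute-force oracles on random fields
of up to ~10⁵ voxels and a 1000-replicate null simulation for the ANOVA
type-I error. Determinism is enforced by deriving all per-patient seeds
from one master seed and by saving/restoring the RNG state inside the
generators, so library code never perturbs a caller's random stream.

## Known limitations

* Layer-based splitting is a surrogate for anatomical (landmark-based)
  head/body/tail boundaries such as the uncal apex; the two need not agree
  for atypical anatomy.
* Nearest-neighbour resampling and centre-inside rasterization ignore
  partial volumes; metrics for very small structures on coarse dose grids
  carry corresponding discretization error.
* DICOM-RT ingestion is out of scope; inputs arrive via the documented JSON
  formats, to which planning-system exports are straightforward to convert.
* The statistics treat left and right structures separately and patients as
  independent; no repeated-measures or mixed-effects modelling is offered.
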