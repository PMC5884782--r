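# hippodvh

Dose–volume analysis of the hippocampus and its head/body/tail
substructures in radiotherapy plans.

In intensity-modulated radiotherapy of nasopharyngeal carcinoma the
hippocampus receives a substantial incidental dose, and the dose is not
uniform along the structure: the hippocampal head lies anterior-inferior,
closest to the nasopharynx, while the tail points posterior-superior away
from it. Because head, body and tail contribute differently to memory
function, the dose to each part matters, not just the whole-structure mean.
`hippodvh` is a pipeline for physicists and clinical researchers who want
to quantify that gradient:

* **Substructure split** — a delineated hippocampus is divided along the
  anterior–posterior slice axis by fractional layer counts. With N coronal
  layers, the anterior `round(0.35 N)` layers form the head, the next
  layers up to `round(0.80 N)` the body, the rest the tail (ratios
  configurable; the split is an exact partition of the voxel mask).
* **DVH metrics** — cumulative dose–volume histograms and the clinical
  point metrics. `D_x%` is the dose at rank `ceil(x·M/100)` of the M voxel
  doses sorted descending (the minimum dose to the hottest x% of volume;
  D_1% ≈ max, D_99% ≈ min); `D_mean` is the voxel mean; `V_d` is the
  percent volume receiving ≥ d Gy. Doses are handled in cGy throughout.
* **Geometry** — rasterization of planar contours to voxel masks
  (centre-inside, even-odd rule with hole support) and nearest-neighbour
  resampling of masks onto the dose grid.
* **Cohort statistics** — mean ± SD tables per side and subregion, one-way
  ANOVA across head/body/tail, Fisher-LSD (or Bonferroni) pairwise
  comparisons, and a paired t test for pre/post cognitive scores.
* **Synthetic phantoms** — bilateral hippocampus-like curved tubes plus a
  nasopharynx-centred exponentially decaying dose field
  (`d0·j·exp(−r/λ)`, peak 7040 cGy), so the whole pipeline runs end to end
  with no clinical data.

## Worked example

```r
library(hippodvh)

# a 10-patient simulated cohort
cohort <- make_cohort(10, phantom_config(), seed = 1)
p <- cohort[[1]]

# split the left hippocampus 35/45/20 along anterior -> posterior
sp <- split_structure(p$left)
sp
#> subregion_split over 20 layers (boundaries after layers 7 and 16 )
#>   head     1.088 cc (34.9%)
#>   body     1.552 cc (49.7%)
#>   tail     0.480 cc (15.4%)

metrics_bundle(p$dose, sp$head)
#> dose_metrics 'HC-L_head' (1.088 cc)
#>   D1%       2230.7 cGy
#>   D50%      1679.9 cGy
#>   D99%      1174.0 cGy
#>   Dmean     1692.5 cGy
#>   V5       100.00 %
#>   V10      100.00 %
#>   V15       71.32 %
#>   V20       16.91 %
#>   V30        0.00 %
#>   V40        0.00 %
#>   V50        0.00 %
```

The head sits closest to the dose source, so its metrics are the highest;
the layer fractions deviate a little from 35/45/20 because the tube
tapers while whole layers are assigned to one part.

The full study — per-patient metrics, then cohort tables with tests:

```r
res <- run_study(study_config(n_patients = 10, seed = 1))
subset(res$table2_d_metrics, side == "HC-L" & metric == "Dmean")
#>    side metric region   mean    sd  n overall_p p_head_body p_head_tail p_body_tail
#> 10 HC-L  Dmean   head 1533.4 357.0 10 1.981e-08   3.837e-06   5.548e-09     0.01504
#> 11 HC-L  Dmean   body  864.6 222.4 10 1.981e-08   3.837e-06   5.548e-09     0.01504
#> 12 HC-L  Dmean   tail  563.9 155.7 10 1.981e-08   3.837e-06   5.548e-09     0.01504
```

Mean dose falls monotonically head → body → tail (1533 > 865 > 564 cGy),
the ANOVA rejects equality of the three subregions, and every pairwise
comparison is significant — the expected picture when the dose source sits
anterior-inferior to the structure. With `out_dir` set, `run_study()`
writes the tables as CSV (whole-structure D metrics; D metrics by
subregion; V metrics by subregion; per-patient long table; paired-score
test; run log), with undefined/skipped cells marked `—`.

A thin command-line front end with `simulate`, `segment`, `dvh`, `stats`
and `run` subcommands is installed at `inst/cli/hippodvh.R`.

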