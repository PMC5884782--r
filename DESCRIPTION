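Package: hippodvh
Title: Hippocampal Substructure Dosimetry for Radiotherapy Dose Grids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dose-volume analysis of the hippocampus and its head, body and
    tail substructures against three-dimensional radiotherapy dose grids.
    Rasterizes planar structure contours to voxel masks, splits a structure
    along the anterior-posterior slice axis by fractional layer counts
    (default 35/45/20 for head/body/tail), computes cumulative dose-volume
    histograms and the standard clinical metrics (D1%, D50%, D99%, Dmean,
    V5-V50), and produces cohort summary tables with one-way ANOVA,
    Fisher-LSD pairwise comparisons and paired pre/post tests. Includes a
    synthetic phantom generator emulating bilateral hippocampi irradiated
    by a nasopharynx-centred dose field, so the full pipeline can be
    exercised end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
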