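# lcpipe

Fully automated localization, segmentation and contrast-ratio analysis of
the locus coeruleus (LC) in neuromelanin-sensitive MRI.

The LC is a small bilateral noradrenergic nucleus in the brainstem —
roughly 2 mm in diameter and 12–17 mm long — that appears hyperintense on
neuromelanin-sensitive T1-weighted MRI and is among the earliest
structures affected in Alzheimer's and Parkinson's disease. The standard
imaging biomarker is the contrast ratio (CR) of LC intensity against a
pontine reference region, conventionally derived from painstaking manual
delineation. `lcpipe` automates the whole chain for researchers working
with such acquisitions:

1. **Localization** — a 3D U-Net with a differentiable
   spatial-to-numerical transform (DSNT) head regresses the left/right LC
   centres of mass. The heatmap `h` is softmax-normalised and reduced to
   a coordinate by its spatial expectation, `x̂ = Σ_v h(v) · x_v`, trained
   with the mean per-side Euclidean distance as loss. One scale-agnostic
   network is trained on patches at several resolutions and applied
   iteratively coarse-to-fine (default schedule 3 → 1.5 → 0.75 →
   0.375 mm), each patch centred on the previous prediction; a
   whole-volume single-pass variant serves as baseline.
2. **Segmentation** — patch-based 3D U-Nets trained with the fuzzy Dice
   loss `1 − (2Σpt + ε)/(Σp + Σt + ε)` against manual masks from one or
   several raters: single-rater training, the raters' intersection, or
   random switching between raters per optimisation step. Largest
   connected component per side is kept (26-connectivity).
3. **Quantification** — a substructure U-Net provides the pons mask,
   which is split between the two LC centres in Voronoi fashion
   (every pons voxel joins its nearest centre); a 20³-voxel cuboid at
   each half's centre of mass becomes the reference region, and per-side
   CRs are reported as `(stat(LC) − stat(ref))/stat(ref)` for
   `stat ∈ {median, max}`.
4. **Evaluation** — Dice, false discovery rate, the multi-rater Dice
   `MRDSC = 2Σᵢ|P∩Rᵢ| / (n|P| + Σᵢ|Rᵢ|)`, per-axis localization errors,
   ICC(2,1) agreement of CRs, Welch t tests, and a stratified nested
   3×5 cross-validation planner.

Because clinical neuromelanin cohorts with multi-rater annotations are
private, the package includes a synthetic brainstem phantom generator
(`generate_phantom()`, `make_cohort()`) with known LC geometry, known
contrast, substructure labels and simulated raters calibrated to the
inter-expert agreement regime (Dice ≈ 0.68). Every stage is trained and
validated against this ground truth; see `vignettes/lc-analysis.Rmd` for
what the phantom does and does not emulate.

## Worked example

The self-contained demo generates a 10-phantom cohort, trains tiny
localization, LC-segmentation and substructure networks (6 train / 2
validation subjects), runs the full pipeline on the 2 held-out subjects,
and compares automatic against ground-truth contrast ratios across the
cohort:

```r
library(lcpipe)
res <- lc_demo(seed = 1)
#> LC pipeline demo (seed 1 )
#>           metric     value
#>   test_dsc_truth 0.8701952
#>       test_mrdsc 0.7571935
#>  test_loc_err_mm 0.5849461
#>    test_pons_dsc 0.9601220
#>     icc_cr_med_L 0.9624041
#>     icc_cr_med_R 0.9595655
#>     icc_cr_max_L 0.9321207
#>     icc_cr_max_R 0.9883972
```

`test_dsc_truth` is the Dice overlap of the predicted LC mask with the
phantom's true mask on held-out subjects; `test_mrdsc` the joint agreement
with both simulated raters; `test_loc_err_mm` the mean Euclidean
localization error (the demo grid has 0.75 mm voxels, so this is sub-voxel);
`test_pons_dsc` the pons overlap feeding the reference regions; and the
four ICCs compare the automatically extracted CRs (median/max × left/right)
with CRs computed from the ground-truth masks over the whole cohort.

A file-level interface for cohort generation and CR extraction is in
`inst/cli/lcpipe.R` (`phantom`, `quantify`, `demo` verbs).

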