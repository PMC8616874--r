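---
title: "Automated locus coeruleus analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated locus coeruleus analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`lcpipe` implements a fully automated analysis chain for the locus
coeruleus (LC) in neuromelanin-sensitive T1-weighted MRI: iterative
multi-scale localization of the two LC centres, patch-based volumetric
segmentation trained against one or several manual raters, brainstem
substructure segmentation, and contrast-ratio (CR) extraction against
pontine reference regions. This vignette explains the underlying models,
the parameters that matter, the synthetic phantom used for validation, and
the design decisions taken where several reasonable options existed.

## The processing model

**Preprocessing.** Acquisitions are assumed to be isotropic (0.75 mm is
the typical acquisition resolution; a 0.375 mm working grid is obtained by
windowed-sinc upsampling, `resample_volume()` with Lanczos-3), bias-field
corrected upstream, and z-score normalised per volume (`znormalize()`).
All geometry is kept in world millimetres: voxel indices are 0-based,
world coordinates refer to voxel centres, and landmarks survive any change
of resolution unchanged. CRs, however, are computed on the *raw* intensity
scale: the CR is invariant under positive rescaling of the scanner
intensities but not under the additive shift that z-normalisation applies,
so the pipeline keeps both copies of each volume.

**Localization.** A single 3D U-Net with two output channels (left and
right LC) produces per-voxel scores which are softmax-normalised over the
patch into heatmaps; the differentiable spatial-to-numerical transform
(DSNT) reduces each heatmap to its spatial expectation, i.e. a continuous
world-mm coordinate. Training minimises the mean of the two per-side
Euclidean distances (mm) with Adam. The network is scale-agnostic: during
training each patch is drawn at a resolution sampled uniformly from the
schedule, and at inference the same weights are applied iteratively from
coarse to fine, each patch centred at the midpoint of the previous
prediction (the first at the volume centre — the coarsest patch is large
enough that this is always a valid start). A single-pass variant applies
one forward pass to the whole volume at native resolution; it is the
baseline the iterative scheme is compared against. Because whole-volume
training has a far larger memory footprint, its batch size is limited
(default 2) while the patch-based variant trains with large batches
(default 32) — the same asymmetry the full-scale setting exhibits.

**Segmentation.** LC segmentation uses the same U-Net backbone with one
sigmoid output channel, trained patch-wise with the fuzzy Dice loss
`1 - (2*sum(p*t) + eps) / (sum(p) + sum(t) + eps)` (`eps = 1e-5` on both
numerator and denominator). The only augmentation is a random integer-voxel
translation of the patch window, so neither the image nor the target masks
are ever interpolated. Four multi-rater target strategies are provided:
train on rater 1, on rater 2, on the voxelwise intersection, or on a rater
drawn uniformly at random *per optimisation step*. The per-step granularity
(rather than per epoch or per subject) was chosen to maximise target
variance, which is the hypothesised source of the random-switch strategy's
robustness. Validation for the random-switch strategy scores against the
voxelwise rater average, the target that strategy converges to in
expectation. Inference runs inside a cubic ROI centred at the localized
midpoint (128 voxels at the 0.375 mm working resolution; scaled settings
use proportionally smaller ROIs) and binarizes at threshold 0.5.
Post-processing keeps the largest 26-connected component *per side*, the
sides being split at the mid-plane through the landmark midpoint: a
global largest-component rule would delete one entire LC of a healthy
bilateral segmentation, so the per-side form is the only sensible reading.
Ties between equal-sized components go to the component whose centroid is
nearest that side's landmark.

**Sliding-window inference.** Patch-trained networks see zero-padding at
every patch border; applying them to a much larger grid in one pass changes
the border context and measurably degrades accuracy. Trained segmenters are
therefore applied tile-wise (tiles of the training patch size, stride of
half a tile) and blended with a triangular centre weighting. This is the
standard sliding-window scheme used throughout volumetric segmentation
practice.

**Substructure segmentation.** A five-class variant (background, midbrain,
pons, medulla oblongata, superior cerebellar peduncle) of the same
backbone with channel softmax. The loss is the fuzzy Dice averaged over
the foreground classes *plus* a voxelwise cross-entropy term: Dice alone
has vanishing gradients for classes absent from a training patch and
exerts no pressure on the background channel, which at small patch sizes
lets background drift into rare classes (we measured the pons Dice
collapsing to 0.35 without the CE term, against 0.98 with it). Dice + CE
is also the standard pairing in volumetric segmentation practice. The
input carries a second channel holding each voxel's normalized
rostrocaudal coordinate: the compartments are ordered along that axis, and
a local patch cannot tell midbrain from medulla without positional
context. Only the pons class is consumed downstream; samples without
substructure labels are excluded with a message.

**Quantification.** Every pons voxel is assigned to the nearer LC centre
(Euclidean distance in mm; exact ties to the left), which partitions the
pons into two halves. At each half's centre of mass (rounded to the
nearest voxel) a fixed-size cuboid (20^3 voxels at the working resolution)
is clipped to the pons half and used as the reference region; the clipped
fraction is recorded and a warning is raised above 0.5. Clipping was
preferred over shifting the cuboid inward because it is deterministic and
needs no search. For each side,
`CR = (stat(LC) - stat(ref)) / stat(ref)` with `stat` either the median or
the maximum applied identically to both regions; the pure ratio
`stat(LC)/stat(ref)` is available as a config option, as are
contralateral or pooled reference variants. The ipsilateral relative
difference is the default because per-side references guard against
lateral intensity bias. Reports carry per-field `NA`s with reasons rather
than failing outright — an empty predicted side (which does occur on
low-signal subjects) leaves the other side's CRs intact.

**Evaluation.** Agreement is measured by the Dice coefficient, the false
discovery rate (`|pred \\ ref| / |pred|`), the multi-rater Dice
`MRDSC = 2*sum_i |P ∩ R_i| / (n|P| + sum_i |R_i|)`, and per-side
localization errors split into the axial (rostrocaudal, third axis) and
in-plane components. Conventions for degenerate cases: the DSC of two
empty masks is 1, the FDR of an empty prediction is 0; both are logged
choices, not mathematical necessities. CR agreement across methods uses
ICC(2,1) — two-way random effects, absolute agreement, single measurement —
computed from the ANOVA mean squares; the ICC variant is stated
prominently because ICC values are not comparable across variants. Group
differences use the Welch t test. The fold planner produces a nested
3 x 5 cross-validation with stratification preserved within one subject in
every subset (largest-remainder allocation per stratum), deterministic
given its seed.

## The synthetic phantom

Real neuromelanin-sensitive cohorts with multi-rater annotations are not
publicly available, so the package ships a generator
(`generate_phantom()`, `make_cohort()`) that provides ground truth for
every stage:

* a brainstem modelled as an elliptic cylinder with midbrain / pons /
  medulla / SCP compartments at slightly different intensity levels
  (pons = 1 by construction);
* two slightly curved cylindrical LCs, 2 mm in diameter and 12-17 mm
  long, at the dorsal edge of the pons. The LC *core* is exactly
  `(1 + c)` times the pons level — so the median CR of a noiseless
  phantom recovers the configured contrast `c` to machine precision — and
  is surrounded by a narrow (0.4 mm) smooth intensity edge that mimics
  partial-volume averaging and makes sub-voxel localization meaningful;
* additive Gaussian noise (default sd 0.05 of the pons level) and an
  optional smooth multiplicative bias field (default off, since inputs
  are assumed bias-corrected);
* two simulated raters, produced by warping the true mask with a smooth
  random displacement field plus an optional systematic dilation/erosion,
  then keeping the largest component per side. The default boundary
  jitter (0.42 voxels sd) was calibrated once, by simulation over 30
  seeds, so that the two raters' mutual Dice is approximately 0.69 —
  the agreement regime reported between human experts — and was not
  revisited afterwards;
* cohort-level variation of length, contrast, curvature and position,
  plus younger/older group labels in a configurable 25:57 ratio ("older"
  phantoms draw their contrast from the lower half of the range), so
  stratified fold planning can be exercised.

What the phantom does **not** emulate: MR acquisition physics (no k-space,
no motion artifacts), anatomically realistic brainstem shape, partial
volume beyond the smooth LC edge, spatially correlated noise, or the
pathology-driven signal loss of clinical cohorts. Passing the recovery
tests therefore demonstrates that the algorithms are implemented correctly
and can learn and quantify structures of this size and contrast — it does
not certify performance on clinical data.

## Scaled problem sizes

The package's validation suite trains real networks, scaled so the whole
cycle stays comfortable on a single CPU. The choices, stated once here:

* phantom grids of 40^3 voxels at 0.75 mm (a 30 mm field of view around
  the brainstem), cohorts of 34 (20 train / 4 validation / 10 test) for
  the recovery runs and 10 for the quick-start demo;
* a two-level localization schedule (1.5 mm, 0.75 mm) with 16^3 patches
  — the coarsest patch (24 mm) still covers the brainstem, preserving
  the coarse-to-fine structure of the full four-level schedule;
* U-Nets of width 4 (localizer, ~11 k parameters) and width 8 (segmenter,
  ~42 k parameters), Adam at 1-3 x 10^-3, batches of 2-8, a few hundred
  optimisation steps with early stopping on validation loss;
* segmentation ROI of 32^3 and reference cuboids of 10^3 voxels at
  0.75 mm — the same 7.5 mm physical cuboid as the default 20^3 at the
  0.375 mm working resolution.

At these sizes the scaled runs recover held-out localization errors around
1.2 voxels (the full-scale analogue reports errors of the same order in
mm), segmentation Dice against phantom truth above 0.8, and the
characteristic multi-rater pattern: intersection training trades Dice for
a clearly lower false discovery rate, while random switching attains the
best joint agreement (MRDSC).

## Numerical and API choices

* Heatmap normalisation is softmax over all patch voxels; the DSNT then
  needs no separate normalisation and training is end-to-end
  differentiable. An all-zero heatmap is a hard error, never silently
  renormalised.
* Out-of-bounds regions of extracted patches are filled with 0 — the
  background mean after z-normalisation, making the fill statistically
  neutral.
* Patch extraction snaps near-integer voxel coordinates (within 1e-9) so
  aligned crops are bit-exact; training crops for segmentation are
  lattice-aligned by construction and never interpolated.
* Early stopping keeps the best-validation weights; `patience = 0` is the
  degenerate case that returns the initial weights untrained.
* Training is deterministic given the config seed: every stochastic
  choice (weight init, subject sampling, augmentation, rater switching)
  derives its own stream from it. Reruns on the same machine are
  bit-identical.
* All randomness in cohort generation and fold planning flows from a
  single root seed through a documented derivation
  (`seed * 48271 + offset mod 2^31 - 19`), so no two stages share a
  stream.
* Volumes are written to NIfTI as float64, so write/read round trips are
  bit-exact; label volumes are only ever resampled with nearest-neighbour
  interpolation.

## Known limitations

* The conv-net engine is intentionally minimal (one pooling level, fixed
  3^3 kernels); it is sized for the package's scaled validation runs, not
  for full-resolution head volumes on GPU clusters.
* The single-pass localizer trains on whole volumes and is therefore the
  slowest component; the iterative multi-scale variant is both more
  accurate and cheaper, which is the point of having it.
* Automatic reference-region placement depends on the pons mask and LC
  centres; on atypical anatomy the cuboid may clip heavily (the report
  flags this) or graze the LC itself.
* ICC estimates on very small cohorts (the 10-subject demo) are noisy;
  they stabilise at the 30+ subject scale used by the acceptance script.
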