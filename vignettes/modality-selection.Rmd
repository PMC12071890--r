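---
title: "Synthetic-CT based photon/proton modality selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic-CT based photon/proton modality selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sctselect)
```

## The problem

Choosing between photon and proton radiotherapy ideally relies on comparing
dose distributions computed on a planning CT (pCT) — but the pCT is acquired
weeks after the initial consultation, and proton insurance approval adds
further delay. A diagnostic CT (dCT) is available immediately, yet differs
from a pCT in patient positioning (curved diagnostic bed vs. flat treatment
couch), scanning protocol (HU calibration, exposure, contrast agent), and
sometimes field-of-view truncation. `sctselect` implements an expedited
workflow: predict a planning-like *synthetic CT* (sCT) from the dCT with a
deformation-field-predicting 3D encoder–decoder, compute photon and proton
dose/toxicity comparisons on the sCT, and check whether the modality
decision made on the sCT agrees with the one that would be made on the pCT.

The decision statistic is the sign of the proton-minus-photon difference in
normal tissue complication probability (NTCP) per endpoint: a negative
difference favors protons. Agreement between sCT-based and pCT-based
decisions is summarized by the sign-concordance rate and by Lin's
concordance correlation coefficient (CCC).

## The synthetic-CT network

The network is a fully convolutional 3D encoder–decoder with skip
connections. It takes one channel (the dCT, HU mapped from
[-1000, 1000] to [0, 1]) and outputs three channels — a dense displacement
vector field (DVF) in millimetres on the same grid. The sCT is the dCT
backward-warped by the DVF: `sct(x) = dct(x + u(x))`, with trilinear
interpolation and border clamping. Keeping the output a *deformation* (rather
than synthesizing intensities directly) guarantees the sCT contains only HU
values present in the dCT, and the same field can propagate contours onto
the sCT.

Architecture parameters (`network_spec()`): `levels` resolution levels
(2× average-pooling each; default 3), `base_channels` at the first level
(doubling per level; default 32), `convs_per_block` convolution blocks per
level (default 1; each block is a 3³ convolution, batch normalization, and a
leaky-ReLU with fixed slope 0.1, used here as the "PReLU-like" nonlinearity).
With the defaults the network has the commonly quoted "three extraction
levels / seven encoder–decoder blocks plus a bottom block" structure; both
counts are constructible because the level count is a parameter. Two
numerical choices are deliberate:

* the output head is **zero-initialized**, so an untrained model predicts the
  identity transform — standard practice for registration networks, and the
  property the test suite pins down;
* normalization statistics are computed **per volume** rather than across a
  minibatch. Minibatches here contain one or two volumes, so per-volume
  statistics are nearly identical to minibatch statistics while making
  training and inference behave identically and keeping runs bit-reproducible.

### Loss and training

The loss is `(1 - SSIM(warp(dct, u), pct)) + λ·R(u)`, where SSIM is the mean
structural similarity over sliding 7³ windows (stabilizing constants
C1 = 0.01², C2 = 0.03² on the [0, 1] scale) and `R` is a diffusion
regularizer — the mean squared forward-difference gradient of each
displacement component (mm²). λ defaults to 0.01; larger values produce
smoother, smaller fields at the cost of image match. Optimization is Adam
(default learning rate 1e-5, batch size 2, 1500 epochs — the full-scale
settings; desk-scale runs in the tests use 32×32×16 volumes, a 2-level /
8-channel network, learning rates around 2e-3–5e-3 and 8–300 epochs, sizes
chosen so the whole suite runs on one CPU in minutes). Gradients flow
through the SSIM, the warp (derivative of the trilinear interpolant with
respect to the sampling position, zeroed where the sample clamps at the
border), and the network; all of it is implemented in compiled code with
hand-written backpropagation, and training is deterministic given the data,
the initialization seed and the batch order.

Because the DVF is stored in millimetres, a field predicted on a coarse grid
can be upsampled trilinearly and applied to the native-resolution dCT
(`predict_sct(..., predict_shape = )`); this is the package's
resolution-bridging choice for inputs larger than the training grid.

## Preprocessing

* **Couch removal** (`remove_couch()`): voxels above `air_threshold`
  (default -250 HU) are closed with an approximately spherical structuring
  element (`closing_radius_mm`, default 5 mm; realized with two Euclidean
  distance transforms and kept *extensive* — the original foreground is never
  eroded), the largest 3D connected component is kept, internal cavities
  (lungs) are filled, and everything outside is set to -1000 HU. A QA flag
  is raised — as a warning, not an error — when the body mask touches two or
  more of the four lateral volume faces. Symmetric lateral truncation clips
  both lateral faces, so the threshold is two (configurable); the pipeline
  treats the flag as an exclusion criterion and halts.
* **HU normalization** (`build_hu_lut()`, `apply_lut()`): classical
  histogram matching restricted to body voxels, as a monotone look-up table.
  The LUT bins span the *occupied* source range (256 bins by default) with
  identity tails outside it, so the domain still covers [-1024, 3071] and
  air maps to air. Each bin maps at its mid-mass quantile through the
  inverse-ECDF (type 1) quantile of the reference, which returns actual
  reference HU values: with the spiky histograms of synthetic (and to a
  lesser degree real) CT, interpolating quantiles across empty histogram
  gaps drags values hundreds of HU off at tissue boundaries, and binning
  the full HU axis instead of the occupied range has the same effect.
  Matching direction is dCT → pCT (configurable by the caller by swapping
  arguments).
* **Rigid alignment** (`rigid_align()`): translation-only, initialized at
  the body-centroid difference, refined by an exhaustive ±10 mm / 2 mm NCC
  search and a ±2 mm / 0.5 mm local search. Rotation is neglected (supine
  thorax); a warning is issued if the optimum lies on the search boundary.
* **Resampling** (`resample_volume()`): trilinear onto the target shape
  (default 128×128×64), spacing rescaled so the physical extent is
  preserved; masks are co-resampled nearest-neighbor.
* **Augmentation** (`augment()`): in-plane clockwise 45° rotation (viewer
  convention on axial slices; direction configurable) and horizontal flip,
  applied jointly to a pair and its masks.

## Image and agreement metrics

`mae()` is the mean |ΔHU| over all voxels by default (a body-masked variant
is available). `uqi()` is the Wang–Bovik index
`4·cov(a,b)·ā·b̄ / ((var a + var b)(ā² + b̄²))`, computed globally by default
with a windowed variant (8³ windows, degenerate windows skipped) available —
which one a given published table used is generally unstated, so both are
provided. `ccc()` is Lin's coefficient with population moments;
`ccc_band()` maps values to the conventional qualitative bands
(≥0.99 near-perfect, ≥0.95 substantial, ≥0.90 moderate, else poor;
boundaries closed on the lower edge).

## Dosimetry and the LKB model

`compute_dvh()` bins the voxel dose multiset in 0.1 Gy bins into a
cumulative DVH (fraction of structure volume receiving at least each bin
edge). `VxGy` uses the closed threshold (≥ x Gy) and is reported as percent
of structure volume — relative rather than absolute volume, because the
comparisons span structures of very different sizes. The OAR panel follows
the thoracic convention: esophagus (mean, V35Gy, V60Gy), total lung (mean,
V10Gy, V20Gy), heart (mean, max, V30Gy). The maximum dose is the highest
occupied bin (no D0.03cc smoothing). Doses are used as given, with no
fractionation (EQD2) conversion.

NTCP uses the Lyman–Kutcher–Burman model:
`Deff = (Σ v_i d_i^{1/n})^n` over the differential DVH (a power mean:
n = 1 gives the mean dose, n → 0 the maximum), and
`NTCP = Φ((Deff - TD50)/(m·TD50))`. The packaged parameter file
(`inst/extdata/lkb_defaults.json`) carries classical literature defaults —
heart pericarditis (TD50 48 Gy, m 0.10, n 0.35), lung pneumonitis
(24.5 Gy, 0.18, 0.87), esophageal perforation (68 Gy, 0.11, 0.06) — and is
meant to be overridden with institution-specific values
(`default_lkb_params(path)`); the trend logic does not depend on the exact
triplets.

Endpoint-cases enter the comparison only if an NTCP value exceeds 0.05%
(below that the endpoint cannot influence the decision). The filter includes
a case when *any* of its four values (2 modalities × 2 CTs) passes: a
one-sided rule would break the paired comparison; requiring all four is
available as `rule = "all"`. Zero differences count as concordant with
either sign.

## The phantom generator

`make_thorax_phantom()` builds an elliptical body (fat ring, muscle layer,
soft-tissue interior), two lungs, heart, esophagus, spine and a spherical
CTV in the upper lung, with standard-range HU assignments (air -1000, lung
-700, fat -90, muscle 40, soft tissue 20, bone 400, couch 200 — all
configurable) and optional Gaussian HU noise (σ = 5 default in fixtures).
`make_case()` assembles a full paired case: the pCT is the anatomy deformed
by a known smooth field (sum of Gaussian displacement blobs, amplitude kept
below the blob width so the field stays invertible) on a flat couch; the dCT
is the undeformed anatomy with a protocol HU shift, a curved bed that sags
the posterior body shell, and optional contrast or truncation failure modes.
`truncate_fov()` crops the lateral field of view — the way truncated
reconstructions actually present — rather than blanking columns in place, so
the truncation QA check fires on the cropped body.

Dose fields (`make_dose()`) are geometric: the target receives the
prescription exactly; outside it the dose falls off with Gaussian widths
along the beam axis and laterally, plus an entrance plateau on the proximal
side; the proton kind adds a sharp distal falloff with a hard cutoff. This
is explicitly *not* beam physics — it exists to give the pipeline dose pairs
whose NTCP ordering is controllable (`dose_spec_pair(favor = )`), providing
ground-truth signs for end-to-end tests. Default falloffs were chosen so
that, at a 60 Gy prescription, pneumonitis NTCP is well above the 0.05%
relevance threshold while pericarditis/perforation sit near it — a cohort in
which the filter visibly includes some endpoint-cases and excludes others.

What passing tests on this generator shows — and what it does not: the
phantom exercises the full pipeline (couch geometry, protocol shifts,
smooth deformations, controllable dose orderings, failure modes) with exact
ground truth, so recovery and concordance properties are checkable. It does
not contain real anatomical texture, breathing motion, scanner artifacts,
or realistic plan optimization trade-offs; per-case random anatomic
deformation is deliberately unlearnable from a single dCT, so held-out
improvement measures only what a deployed model could honestly learn (the
systematic positional difference). Quantitative results on patient data
cannot be inferred from phantom numbers.

## Known limitations

* Translation-only rigid alignment; rotations must be negligible or handled
  upstream.
* The dose model is geometric; absolute NTCP values on phantom doses are
  only as meaningful as the parameter file and dose model allow — the
  package's claims are about *agreement between sCT and pCT decisions*, not
  absolute toxicity prediction.
* Whether contours should be mapped with the forward or inverse field is a
  genuine modelling choice; the package warps masks with the same forward
  field as the image, which is consistent for the small, smooth fields it
  predicts.
* Training at full clinical resolution (128×128×64, 1500 epochs) is
  supported but slow on one CPU; the desk-scale defaults in
  `pipeline_config()` are sized for minutes, not hours.
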