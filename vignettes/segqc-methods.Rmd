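---
title: "Quality control scoring for automated prostate segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control scoring for automated prostate segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Automated (deep-learning) segmentation of the prostate gland on T2-weighted
MRI occasionally fails in unpredictable ways, and every mask still has to be
checked by a radiologist before it can drive downstream analysis such as
MRI–ultrasound fusion biopsy planning. `segqc` implements a fully automated
quality-control pipeline with two halves:

* a **reference quality score (rQS)**: a 0–100 composite of twelve
  region-wise segmentation metrics, computable only when a manual reference
  mask exists;
* an **estimated quality score (eQS)**: a LASSO linear regression that
  predicts the rQS from 321 radiomics features of the automated mask and the
  underlying image alone, so new cases can be scored with no reference.

## The reference score

For an automated mask $A$ and a reference mask $R$ on the same voxel grid,
four metrics are computed on each of three regions — the whole gland, the
apex and the base:

* Dice similarity coefficient, $\mathrm{DSC} = 2|A\cap R|/(|A|+|R|)$;
* absolute relative volume difference,
  $\mathrm{aRVD} = |V_A/V_R - 1|\times 100$ (percent);
* 95th-percentile Hausdorff distance (mm): the maximum of the two directed
  95th-percentile surface distances;
* average symmetric surface distance (mm): the mean of all directed surface
  distances pooled from both directions (not the mean of the two directed
  means — the two differ whenever the surfaces have unequal sizes).

The apex and base are defined operationally, not anatomically: with $n$
mask-containing slices and $k = \lfloor n/3 \rfloor$, the apex is the first
(most inferior) $k$ slices and the base the last $k$; remainder slices go to
the middle so that apex and base stay symmetric. For the metric panel the
partition is derived from the *reference* mask and applied to both masks, so
both are compared in the same anatomical frame; for feature extraction it is
derived from the *automated* mask, because no reference exists at inference
time.

Surfaces are voxel-centre point sets under 6-connectivity (a foreground
voxel is surface if any 6-neighbour is background; the grid boundary counts
as background), and distances are Euclidean distances between voxel centres
in millimetres. Percentiles use linear interpolation between order
statistics. These conventions are simple, reproducible and oracle-checkable;
the test suite verifies both distance metrics against brute-force all-pairs
enumeration on hundreds of random mask pairs.

### Calibration against a second observer

The twelve raw metrics live on incompatible scales. Each cell (metric ×
region) is mapped to a 0–100 score by the line through two anchor points:
the metric's ideal value (DSC 1; aRVD, HD95, ASD 0) maps to 100, and the
mean of that cell over a second-observer cohort — a human re-segmentation of
a sample of cases — maps to 85. Choosing the ideal-value anchor is the only
second point consistent with a 0–100 scale; linearity and the 85 anchor are
the method's defining convention. Cell scores are clipped to $[0, 100]$
*before* averaging (order matters and is documented here: clipping first
keeps every cell on the stated scale), and the rQS is the arithmetic mean of
the twelve cell scores.

Two consequences are worth stating because the tests rely on them:

* a perfect segmentation scores exactly 100;
* as long as no cell clips, the calibration cohort scored with its own
  calibration averages to exactly 85 — per cell, the mean of
  $s(m) = a m + b$ over the cohort is $s(\bar m) = 85$.

Degenerate cases are flagged, not fatal: if the automated mask is empty in a
region, DSC (0) and aRVD (100) are still computed but the distance cells are
invalid and receive the floor score 0 — the safe worst-case behaviour for a
QC system. A cohort whose mean equals the ideal value in some cell leaves
that line underdetermined and is rejected with an explicit error.

## The feature vector

Each case yields exactly 321 features: 107 per region (whole, apex, base)
— 18 first-order, 14 shape and 75 texture features (24 GLCM, 16 GLRLM, 16
GLSZM, 14 GLDM, 5 NGTDM). The layout is frozen — region-major, class order
as above, alphabetical within class — because the model stores coefficients
by position.

Intensity discretization uses a fixed bin width of 64 (appropriate for a
large volume of interest) anchored at the in-mask minimum:
$\mathrm{bin}(x) = \lfloor (x - \min)/w \rfloor + 1$. Anchoring at the
minimum makes all discretized-texture features invariant to constant
intensity shifts, a property the tests assert. Each region is discretized
independently (regions are independent ROIs); this is a documented choice —
reusing whole-gland bounds would be the main alternative.

Texture matrices follow the conventions of the mainstream radiomics
extractors: GLCM and GLRLM are built per direction along the 13 unique
directions of the 26-neighbourhood at distance 1, features are computed per
direction and then averaged (directions with no voxel pairs are excluded
from the average — merging matrices before computing features is *not*
equivalent, and a test asserts the difference); GLSZM zones are 26-connected
iso-intensity components and inherently direction-free; GLDM uses distance
1 and similarity tolerance 0, with the dependence of a voxel defined as 1
plus its number of equal-level neighbours; NGTDM averages the in-mask
26-neighbours. Gray levels are the sorted distinct bin labels present in
the ROI. Kurtosis is the uncorrected $m_4/m_2^2$ form (3 for a Gaussian),
variance is the population variance, and zero-variance skewness/kurtosis are
0. Every matrix builder is verified against brute-force enumeration on
hundreds of random small ROIs.

Shape features need a surface mesh. `segqc` triangulates the 0.5-isosurface
of the binary mask by marching tetrahedra over the Freudenthal (six-
tetrahedra) decomposition of each grid cell, with crossing vertices at edge
midpoints. The Freudenthal split is face-compatible across neighbouring
cells, so the mesh is watertight; surface area is the sum of triangle areas
and volume follows from the divergence theorem with outward-oriented
triangles. Marching tetrahedra was chosen over classic marching cubes for
its 16-case logic with no ambiguous configurations; for binary masks at
midpoint crossings the two differ only in corner chamfering, well below the
scale of any downstream use. Maximum 3D/2D diameters are maximal pairwise
distances between surface-voxel centres (checked against a brute-force
oracle); axis lengths are $4\sqrt{\lambda}$ of the population covariance
eigenvalues of the physical voxel coordinates. Masks with fewer than two
voxels get 0 for the eigenvalue-derived features.

Degenerate regions (empty, or single-voxel) emit the documented zero
conventions and a validity flag, but a case always emits 321 finite entries.

## The model

The eQS model is a linear regression of rQS on the 321 features with an L1
penalty, fitted by cyclic coordinate descent (with active-set iteration and
warm starts along the penalty path) on predictors standardized to zero mean
and unit SD on the training data; the response is left unstandardized and
the objective is $\tfrac{1}{2n}\|y - X\beta\|^2 + \lambda\|\beta\|_1$.
Zero-variance features are dropped and reported with coefficient 0. The
implementation is cross-checked against an independent lasso solver
(glmnet) in the test suite. Raw predictions are clamped to $[0, 100]$:
above 100 becomes 100, below 0 becomes 0.

The penalty is selected by 5-fold cross-validation with folds assigned at
the *patient* level, so all segmentations of one patient share a fold and
the CV error is honest to new patients. The original method requires the
selected model to show "a non-biased distribution" on Bland–Altman plots — a
human judgement that `segqc` automates as a screen: eligible lambdas must
have an out-of-fold mean difference (eQS − rQS) within ±1 score point
(configurable); among those, the CV-MSE minimiser wins, with ties broken
toward the larger (sparser) lambda, and a warning-accompanied fallback to
the unconstrained minimiser if nothing passes. The default grid is
log-spaced with 100 points from $\lambda_{\max}$ (the smallest
all-zero-coefficient penalty, computed from the data) down four decades.

Evaluation reports MAE, SD and IQR of the absolute errors, Spearman's rho
(average ranks, approximate p-value), the OLS fit of eQS on rQS — the
regression direction is a documented choice — with its pointwise 95%
prediction interval, the Bland–Altman mean difference, and the cases outside
the interval as flagged outliers. Subgroup reports repeat this per
dataset × method combination, skipping groups with fewer than three cases.

## The synthetic phantom

No clinical dataset ships with or is needed by this package. The phantom
module generates ellipsoidal "glands" (default semi-axes 20 × 25 × 22 mm on
a 64³ grid at 1 mm spacing, matching typical prostate dimensions) embedded
in a textured background: a two-compartment intensity model with a brighter
peripheral-zone shell (the outer 25% of the normalized ellipsoid radius),
spatially correlated multiplicative noise (Gaussian-smoothed, correlation
length 2 voxels, relative SD 0.12) plus white noise. Every generator is a
pure function of its seed.

Graded perturbations stand in for segmentation failure modes:
erosion/dilation (under/over-segmentation), translation (misregistration),
dropped apex/base slices (missing coverage), an adjacent leaked blob
(leakage into rectum/bladder), and boundary jitter (observer-style
variability, implemented as thresholding the smoothed mask with a
spatially-correlated noisy threshold whose gain is fixed so that magnitude
approximates boundary displacement in voxels). Magnitude 0 is always the
identity; a perturbation that empties the mask warns and flags rather than
erroring, because downstream code must survive empty automated masks. The
second-observer cohort uses boundary jitter of magnitude 1, which keeps
cohort Dice in (0.8, 1) — the "good but not perfect" regime a human second
observer occupies.

What the phantom does *not* emulate: MR physics (no bias fields beyond the
pluggable correction hook, no coil profiles), anatomical zonal structure,
inter-patient shape variability beyond the ellipsoid, and the specific error
distributions of real CNNs. Passing tests therefore demonstrate the
correctness and internal consistency of the scoring machinery, not clinical
performance on real cohorts; applying the system to new data requires its
own validation.

## Numerical choices and problem sizes

* Percentile and quantile computations use linear interpolation (type 7),
  matching the mainstream numeric stacks.
* Coordinate descent converges at tolerance 1e-9 on coefficient changes for
  final fits, and at a response-scaled 1e-5 during cross-validation, where
  only the MSE ranking of lambdas matters.
* The calibration anchor test and the acceptance script use a 50-case
  cohort at 64³; property suites use ≥200 random instances at ≤16³
  (distances) and ≤6³ (texture matrices); the LASSO recovery test uses
  n = 500 cases × 321 features with a 5-feature sparse truth and noise SD 2;
  the end-to-end pipeline test uses 6 patients × 4 methods at 32³. These
  sizes were chosen so each suite exercises the full code path at desk
  scale.
* File formats: NIfTI via RNifti; MetaImage via a minimal uncompressed
  reader/writer (text header + little-endian raw). Spacing always comes
  from the header — a header without spacing is an error, never an assumed
  1 mm.

## Known limitations

* The rQS calibration quality depends entirely on the observer cohort; a
  cohort of near-perfect masks makes the error-metric slopes extreme and
  the score volatile (the degenerate zero-error cohort is rejected
  outright).
* Bias-field correction is a hook, not an implementation; N4-style
  correction must be supplied externally if needed. AutoRef-style
  reference-tissue normalization is out of scope; z-score and percentile
  rescaling are provided instead.
* DICOM input, resampling and registration are out of scope; masks must be
  voxel-aligned to their images.
* The feature panel excludes wavelet/filtered-image variants by design.
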