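---
title: "Dynamic FET-PET radiomics: parametric maps, feature extraction and TERTp-mutation modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic FET-PET radiomics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynFET)
```

## The problem

O-(2-[18F]-fluoroethyl)-L-tyrosine (FET) PET is an amino-acid tracer study
used to characterise gliomas. Beyond the standard late summation image
(20--40 min post injection), the *dynamic* acquisition carries kinetic
information: aggressive tumour tissue tends to show an early uptake peak
(5--15 min) followed by washout, while less aggressive tissue accumulates
tracer slowly with its maximum late in the scan. `dynFET` turns a 4D dynamic
study into three parametric maps — early TBR (5--15 min), late TBR
(20--40 min), and a categorical time-to-peak (TTP) map — extracts a
107-feature radiomics vector from each, and fits class-balanced logistic
models of TERT-promoter (TERTp) mutation status, the binary label of
interest in IDH-wildtype high-grade glioma.

Because no patient data ship with the package, a seeded phantom generator
produces synthetic dynamic cohorts with known kinetic ground truth; every
stage of the pipeline is validated against that ground truth, against
closed-form arithmetic, and against an independent reference implementation
of the feature definitions.

## Acquisition model and summation windows

The default frame schedule is the fixed 16-frame, 40-minute protocol:
7 x 10 s, 3 x 30 s, 1 x 2 min, 3 x 5 min and 2 x 10 min (2380 s total).

```{r}
defaultFrameSchedule()
```

Summation images are duration-weighted means over frames whose **mid-time**
lies in the window `[t0, t1)` minutes. The schedule's frame boundaries do
not line up with the nominal 5/15/20/40-minute cuts (frames end at 4.67,
14.67, 19.67 and 39.67 min); selecting by frame mid-time reproduces the
intended two-frame windows — frames 12--13 for 5--15 min and the two 10-min
frames for 20--40 min — without partial-frame bookkeeping.

TBR images divide a summation image by the mean activity of a
crescent-shaped background VOI in the contralateral hemisphere; by
construction the background mean of a TBR image is exactly 1. The tumour
VOI is the set of voxels with late TBR at or above 1.6 (inclusive, matching
the exclusion of tumours *below* 1.6), restricted to the largest
26-connected component. Connectivity handling is a package choice: a single
contiguous VOI mirrors clinical delineation practice, and the threshold
comparison and component rule are both exercised by tests.

## TTP classification

Each tumour voxel's time-activity curve (TAC) is classified into six TTP
categories by peak time: <5, 5--10, 10--15, 15--20, 20--30 and 30--40 min.
Two documented rules shape the implementation:

* **Late-slope override.** An ordinary least-squares slope of frame value
  against frame mid-time is fitted over the frames with mid-times in
  [15, 40) min (the last three frames of the default schedule). A strictly
  positive slope assigns category 6 regardless of the arg-max location;
  strict `> 0` is the package's documented choice of positivity, so a
  perfectly flat late segment is not treated as increasing.
* **2.7-minute exclusion.** To avoid the early blood-flush signal, frames
  ending within the first 2.7 min are ineligible for the arg-max; the rule
  is implemented as "end-time <= 162 s", which excludes exactly the ten
  short early frames of the default schedule. Ties break toward the
  earliest frame.

The TTP *image* stores each category's midpoint in minutes (2.5, 7.5, 12.5,
17.5, 25, 35), with NA outside the tumour VOI. The voxel encoding is a
design decision: with the fixed 5-min bin width used downstream, midpoints
discretise to six distinct grey levels (1, 2, 3, 4, 5, 7), so category
identity survives discretisation exactly.

## Radiomics engine

`extractRadiomics()` implements the fixed-settings IBSI-style pipeline: no
image filters, isotropic resampling, fixed-bin-width discretisation, and
seven feature classes totalling 107 features — 18 first-order, 14 shape,
24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM and 5 NGTDM. The class split is the
default of the standard radiomics toolkits; the grey-level
non-uniformity-normalised measure lives in the GLRLM/GLSZM families, since
the 14-feature GLDM class omits its copy as mathematically equal to
first-order Uniformity.

Numerical conventions, all of which differ across tools and are therefore
fixed and tested here:

* **Resampling** is trilinear for intensities and nearest-neighbour for the
  mask, onto an origin-aligned isotropic grid of `floor(n * spacing /
  target)` voxels per axis (default target 2.03 mm). NA voxels (outside the
  TTP mask) are excluded by renormalising the trilinear weights over finite
  corners, so boundary intensities are never contaminated by the
  outside-mask fill value.
* **Discretisation** maps value `v` to level `floor((v - min) / w) + 1`,
  anchored at the masked minimum. The TBR bin widths follow the mean
  interquartile range over patients divided by 4 (quartiles by linear
  interpolation between order statistics), derived on the training cohort;
  they may also be set verbatim (0.18 early, 0.13 late) for strict
  replication. TTP images use a fixed 5-min width, the smallest frame
  duration spanned by a category.
* **Texture matrices** use the 13 unique 3D directions at distance 1 (GLCM
  symmetric, GLRLM runs), features computed per direction and averaged;
  zones and connected components use 26-connectivity; GLDM uses the
  26-neighbourhood with dependence tolerance 0; NGTDM averages in-mask
  neighbours. Degenerate single-level regions follow the reference
  conventions (Correlation and MCC report 1; Busyness and Contrast 0;
  Coarseness capped at 1e6).
* **Shape** features are mesh-based: a table-driven marching-cubes surface
  (iso-level 0.5 on the zero-padded binary mask, vertices on voxel-edge
  midpoints) yields surface area, mesh volume and sphericity; maximum
  diameters are vertex pair distances in 3D and within slice/column/row
  planes; axis lengths are `4 * sqrt(lambda)` from the population
  covariance of physical voxel centres.

### What the oracle tests show

The entire 107-feature vector is checked, on more than twenty seeded random
fixtures (up to 20^3 voxels, irregular masks, both continuous and
TTP-like categorical intensities), against an independent numpy/scipy
implementation of the same documented definitions
(`inst/oracle/radiomics_oracle.py`, surface meshes from scikit-image's
marching cubes). Agreement is required within 1e-4 relative and observed at
~1e-13. This establishes that the two implementations compute the same
mathematics; it cannot, by itself, certify agreement with any specific
third-party toolkit version on conventions that toolkit leaves
undocumented.

## Synthetic cohorts

The phantom generator defines the study conditions for all end-to-end
validation:

* **Kinetics.** Each voxel follows a piecewise-linear "tent" curve: linear
  rise from baseline to an amplitude at the peak time, then a linear
  washout (floored at baseline) or a late increase. The pipeline consumes
  only peak timing and late slope, and the tent makes per-frame averages
  closed-form testable; per-frame values are duration-weighted integrals of
  the continuous curve, mirroring scanner frame integration, and are
  verified against dense numeric integration.
* **Geometry.** An axis-aligned ellipsoidal tumour (semi-axes 4--6.5
  voxels) in one hemisphere of a 40 x 40 x 24 grid at the scanner spacing
  2.03 x 2.03 x 2.43 mm — a desk-scale stand-in for the clinical
  128 x 128 x 63 matrix that keeps a full 160-patient cohort tractable on
  one CPU — plus a fixed crescent-shaped background VOI (the difference of
  two overlapping spheres) in the contralateral half with flat unit
  kinetics.
* **Contrast.** Tumour baselines are 2.0 against background 1.0, so every
  tumour voxel's late TBR is at least 2 under zero noise and the
  TBR >= 1.6 segmentation recovers the planted volume.
* **Label effect.** Each patient has a dominant TTP category; voxels defect
  to a uniformly random category with mixing probability 0.12 for wildtype
  and `min(0.12 + 0.38 * effect, 0.95)` for mutant patients. At
  `effect = 0` the classes are exchangeable by construction (null
  cohorts); at the default `effect = 1` mutant tumours have markedly more
  heterogeneous TTP maps — lower grey-level uniformity — which is the
  recoverable signal the modelling stage must find. Washout categories
  plant their peak at the corresponding frame mid-time, so the noise-free
  TTP map equals the planted category map exactly.
* **Noise.** Additive per-frame Gaussian noise (default sd 0.05 against a
  unit background), clipped at zero, applied to the tumour and background
  VOIs. Real FET-PET noise is neither Gaussian nor spatially white, and no
  quantitative noise description was available; the model is a stand-in
  that exercises robustness, not a calibrated simulation. Consequently,
  passing end-to-end tests demonstrates pipeline correctness and
  signal-recovery capability — not clinical performance on real data.

One master seed drives labels, geometry, kinetics and noise through
independent derived streams (FNV-1a hashed), so stages rerun in isolation
reproduce bit-identical artifacts.

## Modelling

* **Split.** Stratified 70/30 with per-class rounding:
  `round(class_size * 0.7)` per class into training (112/47 with 90 + 22
  and 38 + 9 on a 128/31 cohort).
* **Standardisation.** Training mean and *population* (divisor n) standard
  deviation, applied unchanged to the test cohort; divisor conventions
  differ across tools, and the population divisor matches the common
  machine-learning scaler default. Zero-variance features drop with a
  warning.
* **Correlation de-duplication.** Features are visited in alphabetical
  order and the later member of any pair with |PCC| > 0.99 is dropped,
  making the survivor set deterministic.
* **RFE.** The base learner is a class-balanced, L2-penalised logistic
  regression (penalty 1/(2C) with C = 1, intercept unpenalised, Newton
  iterations); one feature — the smallest absolute standardised
  coefficient — is removed per iteration, ties broken by dropping the
  alphabetically later name.
* **Feature-count selection.** Stratified 10-fold cross-validation; the RFE
  path is recomputed inside each fold and the held-out fold scored at every
  candidate count; the count maximising mean out-of-fold AUC wins, with the
  smallest count on ties. Selection criteria vary in practice (best mean
  score, one-standard-error rules, parsimony cut-offs); maximising mean CV
  AUC with a smallest-n tie-break is the package's documented choice.
* **Class weights.** `n_total / (n_classes * n_k)`, recomputed on whatever
  cohort is being fitted, so each class carries equal total weight.
* **Evaluation.** AUC by the Mann-Whitney rank statistic with 0.5 credit
  for ties; accuracy, sensitivity, specificity, PPV and NPV at the strict
  P > 0.5 threshold with TERTp-mutation as the positive class; 95%
  percentile confidence intervals over 1000 stratified bootstrap resamples
  (stratification keeps both classes in every replicate, which plain
  resampling cannot guarantee on small imbalanced cohorts).

## Validation problem sizes

The test suite validates the full pipeline at desk scale: synthetic cohorts
of n = 160 (20% wildtype) across ten effect seeds and six null seeds for
planted-signal recovery; 22 oracle fixtures up to 20^3 voxels; a TTP
classification grid over peak times 3--38 min and both washout signs; and a
five-stage pipeline smoke run of 20 patients with three-fold CV. These
sizes are the package's validation conditions, chosen to exercise every
code path with stable statistics.

## Known limitations

* The phantom's voxel kinetics are spatially independent within the
  mixture; real tumours have spatially correlated kinetic domains, so
  texture feature distributions on real data will differ.
* No scanner physics: attenuation, scatter, reconstruction filters, partial
  volume and motion are all out of scope.
* The marching-cubes mesh follows one fixed triangulation convention;
  toolkits using different ambiguity resolutions will report slightly
  different surface areas for the same mask.
* Bin widths derived by the IQR/4 rule depend on the training cohort;
  replicating a previously derived width exactly requires setting it
  verbatim in the configuration.
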