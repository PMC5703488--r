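---
title: "Registration-based prediction of trabecular bone fabric"
author: "fabricmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registration-based prediction of trabecular bone fabric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabricmap)
```

## The problem

The mechanical competence of trabecular bone depends on how much bone there
is (the bone volume fraction, BV/TV) and on how the trabecular
micro-architecture is oriented. The orientation is summarized by the
*fabric tensor*: a symmetric positive-definite second-order tensor **M**,
normalized here to `tr(M) = 3`, whose eigenvectors give the preferred
structural directions and whose eigenvalue ratio `DA = m3/m1` measures the
degree of anisotropy. Fabric can be measured by mean-intercept-length (MIL)
stereology on high-resolution peripheral QCT (HRpQCT), but clinical QCT of
the proximal femur (voxels around 0.33 mm) does not resolve individual
trabeculae, so fabric cannot be measured where it is clinically needed.

`fabricmap` implements a registration-based work-around. A *femur atlas* --
a real femur with a paired HRpQCT image, hence with measurable fabric -- is
deformably registered to the patient QCT image. The transform establishes
point correspondences, and the atlas fabric tensors are transported into
the patient image using decompositions of the local deformation gradient of
that transform.

## Registration model

Registration minimizes

$$C(T) = -C_{\mathrm{similarity}}(T) + \gamma\, C_{\mathrm{smooth}}(T)$$

over a two-stage transform $T(x) = T_B(T_A(x))$: a 12-parameter affine
stage $T_A$ followed by a cubic B-spline free-form deformation $T_B$ on a
regular coefficient grid. The similarity is the normalized correlation
coefficient (NCC), appropriate for the mono-modal QCT-to-QCT setting; the
regularizer is the curvature penalty $\|\Delta u\|^2$, the squared 7-point
discrete Laplacian of the displacement summed over the B-spline coefficient
lattice (replicate boundaries). Affine displacement fields have zero
interior curvature, so the penalty does not resist global alignment.

Both stages are optimized with analytic gradients (BFGS for the affine
stage, L-BFGS-B for the B-spline coefficients) in a 3-level
multi-resolution pyramid (factor 2, Gaussian pre-smoothing). Intensities
are first clamped at the 0.5th/99.5th percentiles and rescaled to `[0, 1]`:
NCC is invariant to affine intensity maps, but clamping keeps outlier
voxels from dominating the gradient. Masks are resampled by
nearest-neighbour, intensities by trilinear interpolation. The whole
procedure is deterministic: rerunning with the same inputs and parameters
reproduces the transform bit-for-bit.

Tunable parameters, with defaults:

* `gamma = 0.1` -- regularization weight (dimensionless). Chosen by the
  Dice-overlap tuning protocol on phantom pairs; it is a configuration
  value, not a constant baked into the code.
* `gridSpacing` -- B-spline control spacing in mm; defaults to one fifth of
  the smallest fixed-image extent, and to 5.3 mm (the MIL VOI side) for the
  evaluation control grid.
* `levels = 3`, `maxIter = c(60, 40, 30)` -- pyramid schedule,
  coarse to fine.

Registration quality is monitored with the Dice coefficient between the
fixed mask and the moving mask transported through the recovered chain
(nearest-neighbour resampling), and by checking `det F > 0` at probe points
(a fold means the transform is locally non-physical; it is reported as a
warning on the result object).

## Deformation distance and atlas selection

The amount of *non-rigid* deformation a registration needs is measured by
the log-stretch distance
$$DM = \sum_{j=1}^{J} \lVert \log V_j \rVert_F ,$$
where at each control point $j$ the deformation gradient $F = \nabla T$
is factored by the left polar decomposition $F = VR$ ($V$ SPD stretch,
$R$ rotation, computed through the SVD of $F$). Rigid motions give
$DM = 0$; a global isotropic scaling by $s$ gives the closed form
$J\sqrt{3}\,|\ln s|$, used as a unit test. The per-stage product form
$\log(V_B V_A)$ is also available (`mode = "product"`); the product of two
SPD matrices need not be SPD, so the default evaluates the stretch of the
fully composed gradient, which is always well defined, and the product
mode symmetrizes before the logarithm. On the smooth warps we generate the
two modes agree to well within 20%.

Six atlas-selection strategies operate on the pairwise DM matrix of a
database (rows = fixed/patient, columns = moving/candidate; DM is
asymmetric, and the implementation fixes the patient as the fixed image):
closest (CTP/CSP), farthest (FTP/FSP, a deliberate worst case), and the
population-mean femur (MTP/MSP) -- the *real* image minimizing the
accumulated DM over the candidate set, rather than a synthetic average
image, which would blur exactly the texture the method depends on. The
`*SP` variants restrict candidates to the target's sex. The target and its
contralateral femur (same subject) are always excluded; ties break to the
lexicographically smallest id so selection is permutation invariant.

## MIL fabric extraction

Fabric is measured on the high-resolution image in four steps: a
Laplace-Hamming sharpening filter (frequency response
$(1 + \alpha\,|k|^2_{\mathrm{norm}})$ windowed by a separable Hamming
window cut off at 0.9 Nyquist; $\alpha = 1$), min-max normalization,
threshold segmentation (default 0.5), and MIL analysis of a cubic volume
of interest (VOI) of side 5.3 mm centred at each control point. The filter
and threshold defaults are package choices documented here; the upstream
segmentation literature does not pin them down.

For each of 321 (default; 129 in the fast tests) hemisphere directions --
vertices of a subdivided icosahedron, antipodes removed since fabric is
axial -- a parallel grid of test lines (spacing twice the voxel size) is
marched through the VOI. The binary phase is probed by trilinear
interpolation against the 0.5 iso-level; a nearest-neighbour marcher
systematically inflates intercept counts along oblique directions
(staircase bias), which measurably distorts weak-anisotropy tensors.
With $L(\omega)$ the in-bone length and $I(\omega)$ the count of
marrow-to-bone transitions, $\mathrm{MIL}(\omega) = 2L(\omega)/I(\omega)$
(Underwood's convention). The directional distribution is fitted by the
MIL ellipsoid $1/\mathrm{MIL}^2(\omega) = \omega^\top H \omega$ by least
squares over the six unique components of $H$; fabric eigenvalues are
$m_i = 1/\sqrt{h_i}$ with the eigenvectors of $H$, normalized to trace 3.

Two numerical guards: directions with zero intercepts are dropped (fewer
than six usable directions is an error), and the eigenvalues of $H$ are
floored at 1% of the largest. The floor matters for idealized structures:
parallel rods have intercept-free runs along their axis, the polar
$1/\mathrm{MIL}^2$ tends to zero, and sampling noise can push the
unconstrained least-squares eigenvalue slightly negative. Flooring caps
the measurable DA at 10 -- far above anything trabecular -- and raises a
warning when engaged.

## Fabric tensor mapping

Given the registration chain and its gradient $F = V R$ (with affine-stage
factors $V_A, R_A$ and B-spline factors $V_B, R_B$), five schemes
transport an atlas tensor to the patient image:

| scheme | transform | character |
|--------|--------------------------------|------------------|
| NR | $M' = M$ | translation only |
| AR | $M' = R_A M R_A^\top$ | global rotation |
| AD | $M' = F_A M F_A^{-1}$ | global rotation + stretch |
| CR | $M' = R M R^\top$, $R = R_B R_A$ | local rotation |
| CD | $M' = F M F^{-1}$ | local full gradient |

AR and CR are congruences by rotations: they change eigenvectors only, so
the degree of anisotropy is preserved exactly -- the package asserts this
at $10^{-12}$. AD and CD are similarity transforms: the *raw* result has
the same eigenvalues as $M$ but is generally not symmetric, so it is not a
valid fabric tensor. The package returns the symmetrized,
trace-renormalized tensor (symmetrization does change eigenvalues) and
keeps the raw matrix reachable via `attr(x, "raw")` for inspection;
whether symmetrization should be applied is genuinely open, so both
results are exposed. Mapping runs atlas → patient: tensors are
established at the corresponding atlas points $T(x_j)$ and attached to the
patient control points $x_j$.

The fabric atlas averages, per control point, the CR-mapped tensors of all
population members registered to the atlas image (arithmetic mean, then
trace renormalization -- a Euclidean mean, deliberately not log-Euclidean,
keeping the construction linear and transparent). The averaging step does
not state in its source whether trace renormalization follows; we
renormalize so every atlas tensor satisfies the trace-3 invariant.

## Femur morphology

The implicit femoral coordinate system is built from a binary mask alone:

* *head*: the distance-transform maximum locates the largest inscribed
  sphere; the center is refined as the mass center of the spherical
  region and the radius from its maximal cross-section area. An elongated
  distance ridge (a shaft without a head) is rejected.
* *neck*: the head sphere enlarged by 25% seeds the initial neck center;
  the axis is refined by centroid iteration on the locally cylindrical
  neck segment, and the neck center by 1-D derivative-free minimization of
  the cross-section area along the axis. (A free 3-parameter simplex
  search is unstable here: planes pushed past the femoral surface have
  zero area and attract the minimizer.)
* *shaft*: mass centers of slices distal to the neck-axis-end-point,
  fitted by RANSAC (inlier threshold 1.5 mm, 500 seeded iterations) and
  refit on the consensus set; robust to a simulated lesser-trochanter
  bulge.
* the *mid point* sits at the closest approach of the two axes, and the
  CCD angle is measured there between the neck direction toward the head
  and the shaft direction toward the knee.

Shaft-length standardization crops distal slices until
`d(head, mid) / d(mid, shaft-distal) = 0.7` (within one slice) and
recenters the volume at the mid point, so that registration is not driven
by arbitrary differences in scan length.

## Synthetic phantoms: what they emulate and what they do not

All tests run on generated data with known ground truth:

* `makeTrabecularVolume()` builds binary microstructure: seeded white
  noise filtered by an anisotropic Gaussian whose correlation lengths are
  proportional to the target fabric eigenvalues along its eigenvectors,
  thresholded at the exact BV/TV quantile (optionally spatially modulated
  for realistic intensity contrast); analytic rod/plate lattices as
  anisotropic extremes; Boolean spheres as the isotropic control.
* `simulateQCT()` blurs the HR volume at the target resolution scale,
  resamples, and adds seeded Gaussian noise, so simulated intensity tracks
  local BV/TV as in a calibrated scan.
* `makeFemurPhantom()` assembles a sphere head, cylindrical neck at the
  design CCD angle and cylindrical shaft, and returns the landmarks the
  construction implies.
* `warpPopulation()` resamples a base image through seeded random
  affine + B-spline chains (folding-checked) and stores each chain, so the
  member's ground-truth fabric at any point is the finite-strain
  reorientation $R\,M_{\mathrm{base}}(T(x))\,R^\top$ of the base fabric --
  computable analytically, which is what makes the scheme comparisons
  exact.

Default scales keep the full pipeline tractable on one CPU while
preserving the ~4x HR/QCT resolution ratio of dual femur acquisitions:
19.2 mm cubes at 0.15 mm (HR) and 0.6 mm (QCT); the population and
registration-recovery experiments use 14.4 mm cubes (32^3 QCT voxels),
warp magnitudes up to 5 QCT voxels, and 3.6 mm control grids. The femur
phantom uses a 9 mm head radius, 26 mm neck at CCD 128 deg and a 55 mm
shaft at 0.75 mm voxels.

What passing phantom tests does and does not show: the phantoms validate
the *mechanics* of the method -- transform recovery, tensor transport,
selection logic, stereology -- under controlled truth. They do not
reproduce cortical shells, marrow inhomogeneity, scanner calibration or
beam hardening, inter-subject anatomical variability, or the true
covariance of fabric with anatomy; quantitative error levels on real
femora cannot be inferred from them.

## Evaluation scheme

Prediction quality is scored per control point by the tensor norm error
$\lVert \hat M - M\rVert_F / \lVert M \rVert_F$, the DA error
$|\hat{DA} - DA|/DA$ (truth in the denominator), and the principal tensor
direction error $\arccos\,|\hat m_3 \cdot m_3|$ in degrees. The absolute
value makes PTD an axial comparison clamped to `[0, 90]` -- without it an
antiparallel axis would score 180 degrees for a perfect prediction; the
clamped form is the package default and configurable in spirit by calling
the metric on raw vectors. Degenerate directions (relative eigenvalue gap
below $10^{-6}$) are excluded from PTD aggregates and logged; they stay in
TN/DA. Aggregation is mean over control points per femur, then mean and sd
over femora. BV/TV-binned summaries use half-open 0.05-wide bins over
`[0, 0.5]` by default.

The leave-one-out plan makes every image the target once and excludes the
target and its contralateral side from the candidate pool: 36 pairs yield
70 candidates per target and 5,040 registrations. `runExperiment()` runs
the full factorial (target x atlas mode x mapping scheme), caching each
registration so all five schemes reuse the single (target, atlas)
transform.

On the synthetic population the qualitative findings that motivated the
method reproduce: the closest atlas beats the mean atlas beats the
farthest (TN and PTD), local rotation (CR) beats global rotation (AR)
beats no rotation (NR) in PTD, and the DA error is bit-identical across
NR/AR/CR because rotations cannot change eigenvalues.

## Numerical choices and limitations

* Polar decompositions run through the SVD; `R` stays orthogonal to
  machine precision even for ill-conditioned gradients.
* Symmetry drift from mapping arithmetic is absorbed by symmetrizing
  inputs within a $10^{-8}$ relative tolerance; worse asymmetry is an
  error, not silently repaired.
* Eigenvalues are reported ascending (`m1 <= m2 <= m3`); principal
  directions fix their sign by making the largest-magnitude component
  positive (axial quantity).
* The B-spline Jacobian is analytic; finite differences (step 0.25x voxel)
  are used only as a test oracle.
* Registration quality depends on image texture: featureless regions give
  NCC no gradient, and the curvature penalty then freezes the B-spline
  locally. Masks should cover textured anatomy.
* The DM matrix is asymmetric and computed in one direction
  (patient = fixed); averaging both directions is a possible extension,
  not implemented.
* MIL assumes an approximately stationary structure inside the 5.3 mm VOI;
  strong gradients within a VOI bias the tensor toward the denser half.

## A small worked example

```{r example, eval = FALSE}
spec <- phantomSpec(texture = "anisotropic-noise", bvtv = 0.25,
                    bvtvRange = c(0.08, 0.4), side = 14.4, seed = 21)
hr <- makeTrabecularVolume(spec)
qct <- simulateQCT(hr$image, qctSpacing = 0.6, seed = 22)
base <- list(qct = qct, mask = NULL,
             fabricFun = syntheticFabricFun(zRange = c(0, 14.4)))
members <- warpPopulation(base, 3, magnitudes = c(0, 0.7, 1.6), seed = 200)
db <- syntheticDatabase(members, base = base)
db <- pairwiseDM(db, gridSpacing = 3.6)
selectAtlas(db, "BASE", "CTP")$id   # the identical copy wins
ex <- runExperiment(db, modes = c("CTP", "FTP"), schemes = c("NR", "CR"),
                    gridSpacing = 3.6)
ex$records[, c("target", "mode", "scheme", "tn_mean", "ptd_mean")]
```
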