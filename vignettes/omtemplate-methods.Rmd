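---
title: "Methods: unbiased multimodal templating and age-dependent atlases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unbiased multimodal templating and age-dependent atlases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters with their
defaults and units, what the synthetic phantom does and does not emulate,
the numerical choices made where the design was genuinely open, and the
known limitations. Nothing stated here as an empirical result goes beyond
what the test suite itself computes.

## 1. The problem

A population template should not be more similar to any one subject than to
any other — neither in shape nor in appearance. Shape bias is removed by
requiring the average nonlinear deformation from template to subjects to be
(numerically) zero; appearance bias by making each template voxel the
average of the subjects' resampled intensities. The package implements this
as the classical iterate: register, average the warps, compose each warp
with the inverted average ("unbiasing"), resample every native channel in
one step, and average. Both contracts are asserted by tests: the in-brain
mean nonlinear displacement after every iteration stays below 0.1 voxel,
and template voxel values equal the mean of the resampled subject values.

## 2. Geometry and warp algebra

* **Convention.** All geometry derives from the NIfTI voxel-to-world
  affine; voxel indices are 0-based. A `DisplacementField` stores mm
  world-space displacements $d$ on the template grid and represents the
  *pullback* map $\varphi(x) = x + d(x)$ from template space to subject
  space: resampling evaluates the source image at $\varphi(x)$.
* **Composition order.** Transform chains written
  $A \circ \Phi \circ \bar\Phi^{-1}$ are applied left-innermost-last:
  $\tilde\Phi(x) = A(\Phi(\bar\Phi^{-1}(x)))$. Only this attachment makes
  the post-unbiasing mean nonlinear displacement vanish, which is the
  stated purpose of the unbiasing step; the test suite verifies the
  residual is two orders of magnitude below the 0.1-voxel budget.
* **Inversion** is fixed-point iteration
  $d^{-1}(x) \leftarrow -d(x + d^{-1}(x))$, started at $-d$ (default
  tolerance 0.01 mm, 50 iterations). It converges for fields whose
  displacement varies slowly relative to the grid spacing — all fields this
  package produces; non-convergence is an error, never silent.
* **Jacobians** use central differences (one-sided at the boundary) in
  world units. Small-deformation (Euclidean) algebra is used throughout for
  means and the GP — diffeomorphism is *checked* empirically (minimum
  Jacobian), not enforced.
* **Interpolation.** Trilinear for masks and displacement look-ups, cubic
  (Catmull–Rom, an interpolating spline) for intensities. Out-of-field
  values are 0 for intensities and invalid for tensors; warp-of-warp
  evaluation clamps to the boundary and reports an out-of-bounds count.

## 3. Tensors

Tensors are symmetric 3x3 matrices stored as 6 components
`(Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)` with a per-voxel validity flag (invalid
when zero or with non-positive largest eigenvalue).

* **Averaging** is log-Euclidean over valid voxels only: the matrix
  exponential of the mean matrix log. Before the log, eigenvalues are
  clamped below at $10^{-9}$ of the voxel's largest eigenvalue — a
  numerical guard for rank-deficient tensors.
* **Interpolation during resampling** is trilinear in the log-tensor
  domain. This keeps interpolants positive definite and avoids eigenvalue
  swelling along interpolation paths; the source data's own interpolation
  domain is not documented anywhere authoritative, so this is a package
  choice.
* **Reorientation** follows preservation of principal directions: for
  pullback map $\varphi$, the principal frame is carried by
  $M = J(\varphi)^{-1}$ (normalised inside the algorithm), i.e.
  $n_1 = Me_1/\lVert Me_1\rVert$, $n_2$ the orthogonalised image of $e_2$,
  and $D' = RDR^\top$ with $R = [n_1 n_2 n_3][e_1 e_2 e_3]^\top$. A rigid
  rotation therefore rotates eigenvectors exactly and leaves eigenvalues
  untouched (tested to 1e-5).
* **Anti-swelling, precisely.** Log-Euclidean averaging provably does not
  inflate determinants: $\det$ of the log-Euclidean mean is the geometric
  mean of the input determinants, which never exceeds the determinant of
  the Euclidean mean (log-concavity of $\det$ on the positive-definite
  cone). The often-quoted *FA* inequality — FA of the log-Euclidean mean
  at least that of the Euclidean mean — is **not** a theorem:
  $\mathrm{diag}(4,1,1)$ and $\mathrm{diag}(1,1,4)$ give log-Euclidean mean
  $\mathrm{diag}(2,1,2)$ with FA $1/3$, below the Euclidean mean's
  $0.408$, and random rotated anisotropic pairs violate it tens of percent
  of the time. The package tests the determinant property (green) and the
  pipeline-level claim that the *template's* in-tract FA stays within 80%
  of the individuals' (green at the default resolution); the pointwise FA
  inequality is kept as a deliberately failing acceptance test so the
  discrepancy is visible, not hidden.

## 4. The affine stage

Subjects' T1 channels are registered pairwise to an arbitrary seed subject
(12 DOF, multiresolution smoothed pyramid, Nelder–Mead on a mean-squared
cost; deterministic). Seed bias is removed by mapping into the cohort
midspace: with $L_n = \log A_n$ (matrix logarithm via inverse scaling and
squaring, robust to the defective matrices that pure translations
produce), the midspace transforms are
$M_n = \exp(L_n - \bar L)$. Their log-mean is exactly zero — the testable
statement of "unbiased midspace" — and relative geometry
$M_j M_i^{-1} = A_j A_i^{-1}$ is preserved up to the non-commutativity of
small affines. Templates built from different seed subjects agree after
affine alignment (tested at 2% normalised RMS).

Scalar channels combine by voxel-wise *median* at this stage (sharper than
the mean before any nonlinear alignment exists); tensors by the
log-Euclidean valid-voxel mean; binary masks are resampled trilinearly and
averaged into soft masks.

Mask recipes follow the published arithmetic exactly:

* **Intracranial weighting**: threshold the soft T1 mask at 0.1, binarise,
  multiply by 7, add 1, rescale to whole-volume mean 1 — intra to
  extracranial weight ratio 8:1.
* **Reduced DTI masks**: 3x3x3 box-mean smoothing (zero-padded), threshold
  0.9, one-voxel 6-connectivity erosion. The box filter is normalised by
  27 by default so the 0.9 threshold acts on a [0, 1] scale; the literal
  unnormalised-sum reading is available behind a flag (it is
  dilation-like and was judged inconsistent with the stated purpose of
  *reducing* the mask).
* **Scalp clamping**: outside-brain intensities above the 99th percentile
  of the outside-brain distribution are compressed with the exponential
  saturation $v \mapsto t + S(1 - e^{-(v-t)/S})$, $S = 0.2\,(v_{max}-t)$ —
  continuous, unit slope at the threshold, strictly monotone, bounded by
  $t + S$. The original clamp function is not published; softness and
  percentile are configurable.

## 5. Multimodal nonlinear registration

This is a compatible re-implementation of the *cost structure*, not of any
particular optimiser: displacement parameterised on a regular knot grid
with trilinear basis functions, analytic gradients, gradient descent with a
backtracking line search, coarse-to-fine over knot spacing and image
smoothing. Choices worth recording:

* **Schedule.** The full-scale schedule is six levels, knot spacing 32 mm
  and FWHM 8 mm halved per level; the desk default keeps the four coarsest
  levels, matching a 48^3 x 3 mm grid (finer levels would place knots
  below the voxel size).
* **Channel rescaling.** Channel costs are rescaled to equal effective
  contributions at the start of every level, with one guard: a channel
  whose cost falls below `cost_floor_rel` (default 1e-3) times its squared
  intensity scale is floored there. Without the floor, a channel that is
  already numerically matched (cost near machine zero) would be inflated
  into vetoing every warp — a pathology that real, noisy data never
  triggers but degenerate phantom configurations do. Rescaling per level
  rather than per step keeps the within-level cost trace monotone (which
  is asserted) and makes the optimisation exactly invariant to global
  intensity rescaling (also asserted).
* **Tensor term.** Components are smoothed per level like the scalars
  (Euclidean, adequate for a data term); the sampled tensors are compared
  after finite-strain reorientation of the current total map, refreshed
  once per level by rotating the template-side tensors (congruence by the
  transposed rotation — algebraically identical, much cheaper).
* **Regularisation** is a bending-energy analogue on the knot
  coefficients (squared second differences). The published pipeline
  modulates *relative regularisation* through the 8:1 mask; here the same
  ratio enters as data-term weighting, equivalent up to a global
  regularisation factor.
* **Scale matters for thin structures.** The phantom tract tube is about
  2.4 voxels wide at the default 48^3 x 3 mm; at 32^3 it is under-resolved
  and partial-volume mixing, not misregistration, dominates tensor
  metrics. Tests of tract-level claims therefore run at the default
  resolution and say so.

## 6. The templating loop

Each iteration: register all subjects (initialised by their affine),
average the warps, invert the average (tolerance 5% of a voxel), compose
per subject, resample all native channels in one step, average, normalise
scalars to a nonbackground mean of 1000. The normalisation background
threshold defaults to 0 (strictly positive voxels) for the bare operation;
the templating loop passes 10 intensity units because the phantom
deliberately maintains an intensity gap under 20 between background (true
zeros) and the dimmest tissue, and interpolation ripple at the gap edge
must not flip voxels in and out of the nonbackground set (which would make
the normalisation factor unstable at the percent level).

Convergence is reported per iteration as RMS, RMS-percentage (denominator
$\max(|prev|, \varepsilon)$, $\varepsilon = 10^{-6}\max|prev|$ — the
denominator convention is not published), Pearson correlation over the
union of nonbackground voxels, and mean Frobenius norm for tensors.

Direct (one-pass) templates and subgroup templates reuse the same
machinery: one registration pass, unbias, either average the resampled
subjects or warp the fixed template by the inverted mean subgroup warp.

## 7. Gaussian-process age model

* **Stratification.** Half-yearly bins over the training range, two
  random sub-bins per bin, Euclidean mean field and count $p_l$ per
  nonempty sub-bin (empty sub-bins — possible at desk scale — are dropped
  rather than imputed). Only nonlinear warp components are modelled:
  overall brain size is deliberately outside the model.
* **Model.** Independent GP per voxel-component, shared hyperparameters,
  zero prior mean, squared-exponential kernel, noise $\sigma_n^2 W$ with
  $W = \mathrm{diag}(1/p_l)$: sub-bins pooled from more subjects carry
  proportionally less noise. This is the only tractable reading of fitting
  a GP "to the deformation fields directly", and it makes prediction one
  cached Cholesky solve reused across all components.
* **Fitting.** Nelder–Mead on the negated log marginal likelihood over
  $(\log\sigma_f, \log\sigma_n, \log\ell)$; initialisation (unpublished)
  is $\sigma_f$ = the training components' standard deviation,
  $\sigma_n = \sigma_f/2$, $\ell = 10$ years; a jitter of
  $10^{-8}\sigma_f^2$ stabilises the factorisation; the voxel subsample
  (default 10,000 in-brain) is drawn once from the given seed, so fits are
  bit-reproducible. Likelihood sums pool all three displacement components
  of each sampled voxel.
* **Prediction and extrapolation.** The predictive mean reverts to the
  zero prior (hence to the fixed template) as the query age leaves the
  training range; prediction outside the range is permitted but warns.
  Age-dependent templates compose the inverted predicted field with each
  construction subject's full transform and re-average — intensities come
  only from the construction cohort, so age changes shape, never
  appearance. Every predicted warp's minimum Jacobian is reported; on the
  phantom model all predictions across the training range remain
  diffeomorphic (an empirical check, mirrored in the acceptance suite).

## 8. The phantom: what it is and is not

The generator produces a deterministic canonical head — bright scalp
shell, dark skull gap, GM shell, WM interior, two mirrored ellipsoidal
ventricles with distinct T1/FLAIR contrast — and a tensor channel whose
cigar-shaped tensors (FA about 0.7) follow the tangent of a C-shaped arc
inside the WM, isotropic elsewhere. Subjects differ from the canonical
anatomy by an analytic composite map (affine jitter, then a smooth random
field, then the age map), retained exactly as ground truth.

Defaults, with rationale (chosen once; they are the stated world of the
tests, not dials):

| parameter | default | why |
|---|---|---|
| grid | 48^3 x 3 mm | full pipeline in minutes; tract tube resolved |
| warp amplitude | 4 mm (95th pct) | matches the registration recovery budget |
| warp smoothness | 12 mm | inter-subject cortical-scale variation |
| affine jitter | 3 deg / 3% / 3 mm | scanner positioning variability |
| ventricle slope | 1.2%/year radius | a few percent volume change per year |
| reference age | 52.5 y | centre of the construction-cohort age band |
| channel noise | 10 (scalars), 1e-5 (tensor) | mild, SNR ~50 |

The age effect is a *uniform contraction* about each ventricle centre out
to a margin beyond the ventricle boundary, smoothly tapered to zero by 3.2
ellipsoidal radii, with the two supports disjoint — so ventricle volume
follows $(1 + s\,\Delta\mathrm{age})^3$ *exactly* and finite-difference
Jacobian integration can recover it within 3%. Amplitude is calibrated as
the 95th percentile of the field magnitude; fields are built by Gaussian
filtering of white noise in the spatial domain (no wrap-around);
non-diffeomorphic draws are regenerated at reduced amplitude with a
warning.

Not emulated: MR physics (bias fields, noise correlations, Gibbs ringing),
cortical folding, white-matter hyperintensities, tensor estimation from
diffusion-weighted images. A green test on the phantom therefore
establishes the *algorithmic* contracts (unbiasing, recovery, calibration)
— it does not establish robustness to artefacts real pipelines face
upstream.

## 9. Evaluation machinery

ROI volumetrics integrate the Jacobian determinant over a binary ROI;
pairwise Dice analysis computes all unordered subject pairs per ROI per
registration target, aggregates means and reports relative differences as
(mean with target A - mean with target B) / (mean with target B). Warped
ROI masks are binarised at 0.5 (the published convention for subcortical
masks, reused for all ROI warping). Reference cerebral-volume constants
for common adult templates are bundled for scale comparisons (ratio 1.33,
difference above 465 ml). A significance test across ROIs is deliberately
not bundled: the original analysis does not state one, and picking one
silently would misrepresent it.

## 10. Known limitations

* Small-deformation algebra throughout: means and GP outputs are valid
  only while warps stay well clear of folding; the package checks, and
  reports, minimum Jacobians rather than guaranteeing them.
* The registration backend is a compatible re-implementation: cost
  structure, weighting, schedule and rescaling semantics match the
  published description, but numerical trajectories of the original
  optimiser are not reproduced.
* The GP models age only; conditioning on additional covariates (e.g.
  sex) would need a cohort with those strata represented.
* Desk scale is the design point: 48^3 grids, cohorts of tens. The code
  paths are the same at scale, but memory layout (dense L x 3V training
  matrices) is sized for phantoms, not for tens of thousands of 2 mm
  fields.
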