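# omtemplate

Groupwise, fully unbiased construction of **multimodal brain templates** from
coregistered scalar (T1-like, FLAIR-like) and diffusion-tensor channels, and
**age-dependent template** generation by Gaussian-process regression on
deformation fields — exercised end to end on synthetic multimodal head
phantoms with known ground truth.

## Who this is for

Researchers building or studying population-average neuroimaging templates:
the package re-implements, at desk scale, the full algorithmic chain used by
modern unbiased multimodal atlas pipelines — so that every step (warp
algebra, tensor averaging, unbiasing, spatiotemporal modelling) can be run,
inspected and validated on a laptop against analytic ground truth.

## The model

**Unbiased templating.** Given subjects $R_n$ with modalities
$m \in \{\mathrm{T1}, \mathrm{FLAIR}, \mathrm{DTI}\}$, the template $T$
minimises simultaneously the population shape bias and intensity bias

$$\arg\min_T \sum_n \lVert \Phi_{T \to R_n}\rVert^2, \qquad
  \arg\min_T \sum_n \big(T - \Phi_{T \to R_n}(T)\big)^2 ,$$

iterated as: (1) register every subject to the current template with a
multimodal cost
$C = \lambda_{T1} C_{T1} + \lambda_{FL} C_{FL} + \lambda_{DTI} C_{DTI} +
\lambda_{REG} C_{REG}$ (mean squared difference for scalars, mean squared
Frobenius norm for tensors, bending-energy regularisation, 8:1
intra/extracranial weighting); (2) *unbias* by composing each warp with the
inverse of the average deformation
$\tilde\Phi_n = A_n \circ \Phi_n \circ \bar\Phi^{-1}$ (applied
right-to-left); (3) resample all native channels in one step (spline for
intensities, preservation-of-principal-directions reorientation for
tensors) and average (voxel-wise mean; log-Euclidean valid-voxel mean for
tensors; nonbackground mean normalised to 1000). Six hierarchical levels,
knot spacing 32 mm and smoothing 8 mm FWHM halved per level, three
iterations each, reproduce the published full-scale schedule; the desk
default truncates to the four coarsest levels.

**Age-dependent templates.** Warps of a large cohort to the fixed template
are stratified into half-yearly age bins (two random sub-bins each, mean
field $\bar y_l$, count $p_l$) and modelled per voxel-component as a shared
GP over age with squared-exponential kernel
$k(x,x') = \sigma_f^2 \exp(-(x-x')^2/2\ell^2)$ and heteroscedastic noise
$\sigma_n^2 W$, $W = \mathrm{diag}(1/p_l)$. Hyperparameters maximise the
marginal likelihood (Nelder–Mead over $\log\sigma_f, \log\sigma_n,
\log\ell$, 10,000 sampled in-brain voxels); the predictive mean field
$\bar\Psi_{x^*} = k(x^*,\bar x)(K + \sigma_n^2 W)^{-1}\bar Y$ is inverted
and composed with the construction cohort's transforms to synthesise a
template for any age in the training range.

## Worked example

```r
library(omtemplate)

params <- phantom_params(grid_shape = 32, voxel_size = 3, seed = 42)
cohort <- make_cohort(params, n = 6, age_low = 50, age_high = 55, seed = 42)

aff <- build_affine_template(cohort, seed_subject = 1)
res <- nonlinear_iteration(cohort, aff$template, aff$affines,
                           reg_params(schedule = default_reg_schedule(2, 10)))
```

Printed output of the full example (including the ground-truth ventricle
check at the default 48^3 resolution):

```
ages: 54.6 54.7 51.4 54.2 53.2 52.6
midspace log-mean norm: 1.06e-15
max in-brain mean nonlinear displacement after unbiasing: 0.0195 mm
template in-tract mean FA: 0.54
ventricle volume at age 70: 2380 mm^3 (1.76 x canonical; theory 1.77)
```

Reading: the matrix-log mean of the midspace transforms is numerically zero
(the affine stage is unbiased); after one nonlinear iteration the cohort's
mean nonlinear displacement is 0.02 mm — less than 1% of a voxel, the
spatial-unbiasing contract; the tensor template preserves an anisotropic
tract; and integrating the Jacobian determinant of a subject's ground-truth
warp over the canonical ventricle mask recovers the generative cubic age
law (1.76 measured vs 1.77 theoretical at age 70).

## Command line

```sh
inst/cli/omtemplate run --out out/ --n 10 --age-range 45,82 --seed 1
```

Subcommands `phantom`, `build-affine`, `build-template`, `fit-gp`,
`predict-adt`, `evaluate`, `run`; every stage caches its artefacts
(NIfTI volumes, plain-text 4x4 affines, CSV manifests, JSON provenance)
and re-runs only when the configuration hash changes.

## File formats

* Scalar volumes: NIfTI-1 (`.nii` / `.nii.gz`), sform affine authoritative.
* Displacement fields: 5-D NIfTI `(nx, ny, nz, 1, 3)`, mm, vector intent.
* Tensors: 4-D NIfTI with 6 components `(Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)`
  (lower-triangle row order).
* Affines: whitespace-separated 4x4 world-to-world (mm) text files.
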