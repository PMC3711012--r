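---
title: "Viscous fluid registration and VBM: model, solvers and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Viscous fluid registration and VBM: model, solvers and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluidvbm)
```

# The model

`fluidvbm` registers 3D gray matter probability maps by treating the moving
subject as a viscous fluid. At every instant the internal viscous stresses
balance an external image-matching force:

$$\mu \nabla^2 v(x,t) + (\mu + \lambda)\,\nabla(\nabla \cdot v(x,t)) + F(x, u(x,t)) = 0,$$

where $v$ is the velocity field, $u$ the displacement field, and $\mu$,
$\lambda$ the two viscosity constants. Warps use the Eulerian convention: the
deformed position of grid point $x$ is $x - u(x)$, and the warped subject is
$S(x - u(x))$, interpolated trilinearly with background value 0 (gray matter
probability vanishes outside the head). Discretized with finite differences
this is a sparse linear system $Lv = -F$ per iteration.

The driving force is the demons-style sum-of-squared-differences (SSD)
gradient, the warped subject compared against the target and weighted by its
own spatial gradient:

$$F(x) = \left[S(x - u(x)) - T(x)\right]\,\nabla S\big|_{x-u(x)}.$$

A word on signs, because the conventions interlock: with the solvers
returning $Lv = -F$ (the literal force balance above) and the warp reading
the subject at $x - u(x)$, the sign written here is the one that makes the
induced velocity a *descent* direction of the SSD cost — we verified this
numerically (a perturbation of $u$ along $F$ reduces the cost; the opposite
sign increases it, and a registration loop built on it stalls immediately).
Presentations that place the force on the other side of the equation, or
define the warp as $x + u(x)$, flip this sign; the loop here is internally
consistent and its cost trace is non-increasing by construction.

## Time integration

Each iteration converts the velocity into a displacement update through the
material derivative. Because the reference grid does not move with the
fluid, the velocity must be corrected by a transport term:

$$R(x) = v(x) - \sum_{i=1}^{3} v_i(x)\,\frac{\partial u}{\partial x_i}(x),$$

which reduces to $v$ when $u = 0$. The update is an explicit Euler step
$u^{(k+1)} = u^{(k)} + R^{(k)} \Delta T^{(k)}$ with the adaptive step

$$\Delta T^{(k)} = \frac{m}{\lVert R^{(k)} \rVert_{\max}},$$

so the largest voxel displacement per iteration is exactly `m` voxels
(default 0.3; small enough to keep the explicit integration stable, and the
property is asserted to $10^{-12}$ relative precision in the tests).

## Topology preservation by regridding

The Jacobian determinant of $x \mapsto x - u(x)$, computed voxelwise from
central-difference displacement gradients, must stay positive or the warp
folds. Whenever the minimum determinant of the working field drops below the
regrid threshold (default 0.5, the conventional choice in the fluid
registration literature), the field is pushed onto a stack, the working
subject is resampled through it, and integration restarts from the identity.
Each saved piece is then mildly deformed, and the total warp — the saved
pieces composed with the final field via
$u_{tot}(x) = u_{outer}(x) + u_{inner}(x - u_{outer}(x))$ — retains a
positive determinant even when the cumulative compression is far below the
threshold. The registration result exposes the composed field, its Jacobian
map and the regrid events.

# The solver family

Four interchangeable solvers produce the velocity from the force:

* **SOR** — lexicographic Gauss–Seidel sweeps with over-relaxation (default
  factor 1.5) on the coupled three-component system, velocity clamped to 0
  on the boundary ring. It stops when the interior relative residual
  $\lVert Lv + F\rVert / \lVert F \rVert$ falls below the tolerance
  (default $10^{-3}$) and is the reference implementation: `applyOperator()`
  implements $L$ itself, so every solver can be checked against the forward
  operator.
* **SORA** — SOR with adaptive updates: sweeps touch only an active set
  (voxels whose force or last update magnitude exceeds a threshold, plus
  their 6-neighbours), re-expanding to the full interior when the residual
  stalls. The update schedule is a reconstruction validated purely by
  equivalence with SOR — the final residual check is always global.
* **Gaussian kernel** — each force component convolved with an isotropic
  Gaussian; fast, no residual guarantee, kept for completeness as the
  crudest member of the family.
* **Viscous (eigenfunction) kernel** — the default. The discretized operator
  is diagonal in the Fourier basis: for frequency $\omega$ the $3 \times 3$
  block is $A(\omega) = \mu \Lambda(\omega) I + (\mu+\lambda) d(\omega)
  d(\omega)^H$ with $\Lambda(\omega) = \sum_j 2(1 - \cos \omega_j)$ (7-point
  Laplacian symbol) and $d(\omega)_j = i \sin \omega_j$ (central-difference
  symbol). The rank-one structure gives a closed-form Sherman–Morrison
  inverse applied to all frequencies at once; the singular zero-frequency
  mode is set to 0 (the returned solution has zero mean per component).

One discretization detail matters for cross-solver agreement: the
$\nabla(\nabla \cdot v)$ term is a central-difference divergence followed by
a central-difference gradient, so its diagonal part couples voxels **two**
steps apart (symbol $-\sin^2 \omega_j$), not the tight 3-point second
difference. The SOR stencil, `applyOperator()` and the Fourier symbol all
use this same discretization; with it, the Fourier solution satisfies the
periodic system to machine precision.

## Boundary conditions and how equivalence is tested

The iterative solvers clamp the boundary velocity to zero; the Fourier
kernel is periodic. Both are natural for their algorithm and the choice
matters only near the boundary — but on a small grid the *near-DC* part of
the velocity response decays like $1/r$ and feels the boundary model
everywhere. Cross-solver equivalence is therefore assessed on a compact
mid-frequency wave packet (carrier $3\pi/4$), where the response is
well-localized and the two boundary models agree in the interior to about
$2 \times 10^{-3}$ relative $L_2$; a broadband low-frequency force would
instead measure the (deliberate) difference between the boundary models,
not solver correctness. Similarly, the forward-residual oracle for the
kernel uses zero-mean forces, since the DC mode lies outside the operator's
range and is defined to zero.

# Registration defaults

* $\mu = 1$, $\lambda = 0$: the standard compressible-flow choice, right for
  recovering local volume change (atrophy). For recovering *bulk* motion of
  objects with flat interiors (e.g. the translation-recovery experiment), a
  large second viscosity ($\lambda = 10$) is the appropriate configuration:
  penalizing divergence propagates the rim-driven force into the
  gradient-free interior, where a compressible flow would leave the interior
  behind (the aperture problem). This is a per-experiment modelling choice,
  not a fixed constant of the method.
* Iteration cap 15 — ample for maps that are already coarsely normalized,
  which is the intended regime: the fluid step refines an existing
  registration rather than performing it from scratch. Validation
  experiments that must recover large deformations (3-voxel translations,
  80%-radius shrinkage) raise the cap to 60.
* Early stopping when $\lVert R \rVert_{\max} < 10^{-4}$ voxels, and (by
  default) when the SSD cost would increase — the offending update is rolled
  back, so the recorded cost trace is non-increasing and the final cost
  never exceeds the initial one.
* No multi-resolution pyramid: inputs are expected at 2 mm isotropic
  resolution, already coarsely aligned; `resampleIsotropic()` handles the
  reslicing.

# The morphometry stage

Warped probability maps are modulated by the Jacobian determinant of the
warp so that tissue *amount* rather than concentration is compared; on
smooth phantoms warp + modulation conserves total probability mass to
within 2% (interpolation error). TIV is the probability-mass sum of the
native-space GM/WM/CSF segments times the voxel volume; regional volumes
are head-size-corrected by proportional scaling to the mean control TIV,
and group differences are reported as percent change of the patient mean
relative to the control mean at one-decimal rounding. (Recomputing the
published normalized hippocampal means reproduces the reported percentages
for the AD and MCI comparisons; the two remaining cells of the second AD
cohort were evidently derived from unrounded means not available in print —
recomputation from the rounded means differs in the last digit — so they
are not used as exact checks.)

The statistics stage is deliberately minimal: Gaussian smoothing by FWHM
(default 8 mm; 6 and 10 mm give very similar maps), a relative threshold
mask (voxel kept only if every image exceeds 0.2 of that image's mean over
positive voxels), and a voxelwise OLS fit of
`value ~ group + TIV + intercept` with the one-sided contrast
control − patient (positive $t$ = atrophy). Zero-residual-variance voxels
report $t = 0$ and are flagged rather than NaN so thresholding is total; a
constant TIV column is dropped with a warning. Family-wise error control is
max-statistic permutation of the group labels (TIV stays attached to its
subject): the threshold is the $1-\alpha$ quantile of the max-$t$ null
distribution, enumerated exactly when the number of distinct labelings is
small enough and otherwise sampled deterministically given a seed. This is
an explicit substitution for random-field theory, which is out of scope.

# What the synthetic cohorts emulate

The phantom generator emulates the geometry, not the biology, of a VBM
study: a large tissue ellipsoid (~76–82% of the half field of view per
axis, peak probability 0.35 after mild 2 mm smoothing) with an embedded
high-probability spherical structure (39% of the half-FOV, combined peak
0.8) standing in for a subcortical target. Subjects are independent smooth
random warps of this template (white noise smoothed at 5 mm, scaled to
2.5 mm RMS — residual inter-subject variability after coarse
normalization), plus voxelwise Gaussian noise (sd 0.05) and clipping to
[0, 1]; TIVs are drawn from $N(1.5\,\mathrm{L}, 0.12\,\mathrm{L})$
independent of group. Patients additionally carry a *calibrated* atrophy: a
radially contracting, Gaussian-tapered analytic field about the structure's
centroid whose strength is root-found so the regional probability mass
drops by exactly the requested fraction; the ground-truth field is returned
with the cohort.

Two definitions deserve a note:

* **Truth region.** At 2 mm voxels with 8 mm smoothing, the honest target
  for a localization comparison is the *effect support at the analysis
  resolution*: the voxels where the smoothed ground-truth mass difference
  between the clean and atrophied templates exceeds 10% of its peak.
  Comparing a $p < 0.001$ map against the raw structure mask would mostly
  measure the smoothing kernel's halo. The Dice score of the detection
  experiment is stable (0.6–0.8) across a wide band of support thresholds.
* **Fiducials.** Twenty landmarks are placed quasi-uniformly (Fibonacci
  sphere) on the main structure boundary. Because image features land at
  the *inverse*-map position under the $x - u(x)$ convention,
  `invertWarpPoints()` (a fixed-point solve of $x - u(x) = p$) carries
  landmarks between spaces; `warpPoints()` is the literal pullback
  $p - u(p)$. Cluster dispersion across subjects is summarized by
  $\lambda_1 = \sqrt{e_1}$ (a standard-deviation-like spread along the
  dominant error direction, mm) and $R_1 = e_1 / (e_1+e_2+e_3) \in
  [1/3, 1]$ (anisotropy), from the eigenvalues $e_1 \ge e_2 \ge e_3$ of the
  cluster covariance; an all-identical cluster reports $\lambda_1 = 0$,
  $R_1 = 1/3$ by convention.

What passing these tests does *not* show: the phantoms contain no cortical
folding, no segmentation error, no bias fields, no partial-volume structure
and no scanner differences, so they validate the algorithmic contracts
(descent, topology, mass conservation, calibration, localization) rather
than clinical performance on real scans.

# Problem sizes and determinism

Validation runs at deliberately small scales chosen as the package's own
test design: $16^3$ grids for solver cross-checks, $32^3$ (2 mm, 6.4 cm
FOV) for registration and detection experiments with cohorts of 10 + 10,
and $24^3$ with 8 + 8 and 200 replicates for the null-calibration study
(type-I rate at $p < 0.001$ within its simulation confidence interval of
0.001; permutation FWE within the binomial confidence interval of 0.05 at
$\alpha = 0.05$, 199 permutations per replicate). Every stochastic
component — phantoms, jitter fields, noise, TIVs, permutations — is a pure
function of an integer seed, and generators restore the caller's RNG state.

# Known limitations

* Inverse consistency is neither sought nor tested: the method deliberately
  relaxes diffeomorphism; only determinant positivity (via regridding) is
  guaranteed.
* The Euler integration is first-order; large `m` can overshoot (mitigated
  by the cost-increase rollback).
* The Gaussian-kernel solver is an approximation without residual control;
  it is not used by default.
* Permutation FWE requires group exchangeability under the null, which the
  synthetic cohorts satisfy by construction; real confounded designs would
  need care.
* The TIV estimator is a plain probability-mass sum; skull-cleanup
  refinements of dedicated TIV pipelines are out of scope.
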