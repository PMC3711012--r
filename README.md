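# fluidvbm

Viscous fluid registration of gray matter probability maps, with the
morphometry steps needed to turn the warps into a voxel-based morphometry
(VBM) study: Jacobian modulation, intracranial-volume normalization,
smoothing, masking, a two-group GLM with a head-size covariate, and
permutation-based family-wise error control. The package targets
neuroimaging researchers who want a lightly regularized, high
degrees-of-freedom refinement step on top of an existing coarse spatial
normalization — the regime of atrophic (dementia) cohorts, where strongly
regularized diffeomorphic methods can smear focal atrophy into amorphous
blobs.

## The model

The subject volume is treated as a viscous fluid whose velocity field
`v` balances an image-matching body force `F` through the linearized
Navier–Stokes equation

    mu * lap(v) + (mu + lambda) * grad(div v) + F(x, u) = 0,

with `F = [S(x − u(x)) − T(x)] * grad S|_{x−u(x)}` the SSD-descent
(demons-style) force, `u` the Eulerian displacement (warped subject
`S(x − u(x))`). Each iteration solves `Lv = −F` with one of four
interchangeable solvers — successive over-relaxation (SOR), SOR with
adaptive updates (SORA), a Gaussian convolution kernel, or exact
Fourier-domain inversion of the discretized operator (the "viscous
kernel", default) — then integrates `u` by an explicit Euler step whose
adaptive time step `dT = m / max|R|` caps the per-iteration displacement
at `m` voxels. Topology is preserved by regridding: whenever the Jacobian
determinant of the working warp drops below a threshold (0.5), the field
is saved and integration restarts from the identity; the composed total
warp keeps a strictly positive determinant. Warped probability maps are
modulated by the Jacobian determinant so that tissue amount, not
concentration, enters the group statistics.

A phantom module generates deterministic synthetic cohorts with
ground-truth regional atrophy (calibrated to a requested probability-mass
reduction) and fiducial dispersion metrics (λ₁, R₁) for registration
assessment, so every claim is testable without patient data.

## Worked example

Build a synthetic cohort (10 controls, 10 patients with 30% regional
atrophy), register every subject to the template with the viscous-kernel
solver, modulate, smooth, and test group differences:

```r
library(fluidvbm)

co  <- makeCohort(nControls = 10, nPatients = 10, atrophyFraction = 0.3,
                  shape = c(32L, 32L, 32L), seed = 11)
cfg <- registrationConfig(solver = solverSpec("viscous_kernel"),
                          maxIterations = 15, maxStep = 0.3)

registerFluid(co$maps[[11]], co$phantom, cfg)   # first patient
#> RegistrationResult: 15 iterations, cost 173.7 -> 17.54 (10.1%), 2 regrid(s),
#>   min |J| = 0.234, stop: max_iter

mods <- lapply(co$maps, function(m) {
  reg <- registerFluid(m, co$phantom, cfg)
  smoothFWHM(modulate(warpedVolume(reg), jacobianVolume(reg)), 8)
})
mask <- relativeThresholdMask(mods, 0.2)
stat <- glmTwoGroupT(mods, co$design, mask)
stat
#> StatMap: dof = 17, 16115 in-mask voxels, max t = 19.846, uncorrected

sig   <- thresholdMap(stat, "unc001")
truth <- volData(co$truthRegion) > 0
2 * sum(volData(sig) > 0 & truth) / (sum(volData(sig) > 0) + sum(truth))
#> [1] 0.81
```

The registration line reads: the SSD cost fell to 10% of its initial
value in 15 iterations, two regrid events kept the determinant of the
working field above threshold, and the composed warp's minimum Jacobian
determinant is 0.234 (positive: topology preserved; well below 1: the
atrophic structure is compressed). The final Dice of 0.81 says the
`p < 0.001` suprathreshold map essentially coincides with the ground-truth
effect support. Group volume arithmetic works on printed tables too:

```r
groupPercentChange(1667, 1399)
#> [1] -16.1
```

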