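## Central S4 data model. Grids are plain 3D arrays indexed 1-based in R;
## the world position of voxel (i,j,k) is origin + (c(i,j,k) - 1) * voxelSize.
## Displacement and vector fields are stored in voxel units as a 4D array with
## the fourth dimension holding the three components.

#' ScalarVolume: a 3D scalar grid with voxel geometry
#'
#' Container for probability maps, t-maps and Jacobian maps: a 3D numeric
#' array plus the voxel size (mm) and the world-space origin (mm) of voxel
#' (1,1,1).
#'
#' @slot data 3D numeric array.
#' @slot voxelSize numeric(3), strictly positive voxel edge lengths in mm.
#' @slot origin numeric(3), world offset in mm of the first voxel.
#' @exportClass ScalarVolume
setClass("ScalarVolume",
  representation(data = "array", voxelSize = "numeric", origin = "numeric"),
  prototype(voxelSize = c(1, 1, 1), origin = c(0, 0, 0))
)

setValidity("ScalarVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return(sprintf("data must be a 3D array, got %d dimensions", length(d)))
  if (any(d < 2L))
    return("grid dimensions must be >= 2 along every axis")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    return("voxelSize must be 3 strictly positive finite values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite values")
  TRUE
})

#' Construct a ScalarVolume
#'
#' @param data 3D numeric array.
#' @param voxelSize numeric(3) voxel edge lengths in mm (scalar recycled).
#' @param origin numeric(3) world position (mm) of voxel (1,1,1).
#' @return A [ScalarVolume-class] object.
#' @examples
#' v <- scalarVolume(array(0, c(4, 4, 4)), voxelSize = 2)
#' @export
scalarVolume <- function(data, voxelSize = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(data) <- "double"
  new("ScalarVolume", data = data, voxelSize = rep_len(as.numeric(voxelSize), 3L),
      origin = rep_len(as.numeric(origin), 3L))
}

#' VectorField: a 3-component vector field on a grid
#'
#' Used for velocity fields, force fields and perturbation fields. The
#' components live in the fourth array dimension and are expressed in voxel
#' units.
#'
#' @slot u 4D numeric array, dimensions (nx, ny, nz, 3).
#' @slot voxelSize numeric(3), mm.
#' @exportClass VectorField
setClass("VectorField",
  representation(u = "array", voxelSize = "numeric"),
  prototype(voxelSize = c(1, 1, 1))
)

setValidity("VectorField", function(object) {
  d <- dim(object@u)
  if (length(d) != 4L || d[4] != 3L)
    return("field array must be 4D with 3 components in the last dimension")
  if (any(!is.finite(object@u)))
    return("field must be finite everywhere (no NaN/Inf)")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 strictly positive values")
  TRUE
})

#' DisplacementField: an Eulerian displacement field
#'
#' Same layout as [VectorField-class], interpreted as the displacement u(x)
#' of the warp x -> x - u(x) (voxel units).
#'
#' @exportClass DisplacementField
setClass("DisplacementField", contains = "VectorField")

#' Construct a VectorField or DisplacementField
#'
#' @param u 4D numeric array (nx, ny, nz, 3), or a 3D array shape from which
#'   a zero field is built when `dim` is given instead.
#' @param voxelSize numeric(3) voxel size in mm.
#' @return A [VectorField-class] object.
#' @export
vectorField <- function(u, voxelSize = c(1, 1, 1)) {
  storage.mode(u) <- "double"
  new("VectorField", u = u, voxelSize = rep_len(as.numeric(voxelSize), 3L))
}

#' @rdname vectorField
#' @export
displacementField <- function(u, voxelSize = c(1, 1, 1)) {
  storage.mode(u) <- "double"
  new("DisplacementField", u = u, voxelSize = rep_len(as.numeric(voxelSize), 3L))
}

#' Zero displacement field matching a volume
#'
#' @param vol A [ScalarVolume-class].
#' @return A [DisplacementField-class] of zeros with the volume's shape.
#' @export
zeroField <- function(vol) {
  displacementField(array(0, c(dim(vol@data), 3L)), voxelSize = vol@voxelSize)
}

#' ViscosityParams: viscosity constants of the fluid model
#'
#' @slot mu first viscosity constant, > 0.
#' @slot lambda second viscosity constant, with mu + lambda > 0.
#' @exportClass ViscosityParams
setClass("ViscosityParams",
  representation(mu = "numeric", lambda = "numeric"),
  prototype(mu = 1, lambda = 0)
)

setValidity("ViscosityParams", function(object) {
  if (length(object@mu) != 1L || !is.finite(object@mu) || object@mu <= 0)
    return("mu must be a single positive number")
  if (length(object@lambda) != 1L || !is.finite(object@lambda) ||
      object@mu + object@lambda <= 0)
    return("lambda must satisfy mu + lambda > 0")
  TRUE
})

#' @param mu first viscosity constant (> 0).
#' @param lambda second viscosity constant (mu + lambda > 0).
#' @rdname ViscosityParams-class
#' @export
viscosityParams <- function(mu = 1, lambda = 0) {
  new("ViscosityParams", mu = mu, lambda = lambda)
}

#' SolverSpec: which solver to use for the force balance and how
#'
#' @slot kind one of "sor", "sora", "gaussian", "viscous_kernel".
#' @slot tolerance relative residual target for iterative solvers.
#' @slot maxSweeps sweep cap for SOR/SORA.
#' @slot relaxation over-relaxation factor in (0, 2).
#' @slot gaussianSigma kernel width in voxels (gaussian kind).
#' @slot activeThreshold activity threshold for SORA's adaptive updates.
#' @exportClass SolverSpec
setClass("SolverSpec",
  representation(kind = "character", tolerance = "numeric",
                 maxSweeps = "integer", relaxation = "numeric",
                 gaussianSigma = "numeric", activeThreshold = "numeric"),
  prototype(kind = "viscous_kernel", tolerance = 1e-3, maxSweeps = 200L,
            relaxation = 1.5, gaussianSigma = 2, activeThreshold = 0)
)

setValidity("SolverSpec", function(object) {
  kinds <- c("sor", "sora", "gaussian", "viscous_kernel")
  if (length(object@kind) != 1L || !(object@kind %in% kinds))
    return(sprintf("kind must be one of %s", paste(kinds, collapse = ", ")))
  if (object@tolerance <= 0) return("tolerance must be > 0")
  if (object@maxSweeps < 1L) return("maxSweeps must be >= 1")
  if (object@relaxation <= 0 || object@relaxation >= 2)
    return("relaxation must lie in the open interval (0, 2)")
  if (object@gaussianSigma <= 0) return("gaussianSigma must be > 0")
  if (object@activeThreshold < 0) return("activeThreshold must be >= 0")
  TRUE
})

#' @param kind solver kind.
#' @param tolerance relative residual target.
#' @param maxSweeps sweep cap.
#' @param relaxation over-relaxation factor in (0, 2).
#' @param gaussianSigma Gaussian kernel sigma in voxels.
#' @param activeThreshold SORA activity threshold.
#' @rdname SolverSpec-class
#' @export
solverSpec <- function(kind = c("viscous_kernel", "sor", "sora", "gaussian"),
                       tolerance = 1e-3, maxSweeps = 200L, relaxation = 1.5,
                       gaussianSigma = 2, activeThreshold = 0) {
  new("SolverSpec", kind = match.arg(kind), tolerance = tolerance,
      maxSweeps = as.integer(maxSweeps), relaxation = relaxation,
      gaussianSigma = gaussianSigma, activeThreshold = activeThreshold)
}

#' RegistrationConfig: tunables of the outer registration loop
#'
#' @slot solver a [SolverSpec-class].
#' @slot visc a [ViscosityParams-class].
#' @slot maxIterations iteration cap (default 15).
#' @slot maxStep per-iteration maximum voxel displacement m.
#' @slot regridThreshold Jacobian determinant value below which the field is
#'   regridded, in (0, 1).
#' @slot stopOnCostIncrease roll back and stop when the SSD cost rises.
#' @slot stepTolerance stop early when the max perturbation norm falls below
#'   this value (voxels).
#' @slot seed integer seed reserved for stochastic tie-breaking (unused by
#'   the default deterministic pipeline).
#' @exportClass RegistrationConfig
setClass("RegistrationConfig",
  representation(solver = "SolverSpec", visc = "ViscosityParams",
                 maxIterations = "integer", maxStep = "numeric",
                 regridThreshold = "numeric", stopOnCostIncrease = "logical",
                 stepTolerance = "numeric", seed = "integer"),
  prototype(maxIterations = 15L, maxStep = 0.3, regridThreshold = 0.5,
            stopOnCostIncrease = TRUE, stepTolerance = 1e-4, seed = 0L)
)

setValidity("RegistrationConfig", function(object) {
  if (object@maxIterations < 1L) return("maxIterations must be >= 1")
  if (object@maxStep <= 0) return("maxStep must be > 0")
  if (object@regridThreshold <= 0 || object@regridThreshold >= 1)
    return("regridThreshold must lie in (0, 1)")
  if (object@stepTolerance < 0) return("stepTolerance must be >= 0")
  TRUE
})

#' @param solver a [SolverSpec-class].
#' @param visc a [ViscosityParams-class].
#' @param maxIterations iteration cap.
#' @param maxStep maximum voxel displacement per iteration.
#' @param regridThreshold Jacobian regrid threshold in (0, 1).
#' @param stopOnCostIncrease roll back and stop on a cost increase.
#' @param stepTolerance early-stop threshold on the perturbation max norm.
#' @param seed integer seed (reserved).
#' @rdname RegistrationConfig-class
#' @export
registrationConfig <- function(solver = solverSpec(), visc = viscosityParams(),
                               maxIterations = 15L, maxStep = 0.3,
                               regridThreshold = 0.5,
                               stopOnCostIncrease = TRUE,
                               stepTolerance = 1e-4, seed = 0L) {
  new("RegistrationConfig", solver = solver, visc = visc,
      maxIterations = as.integer(maxIterations), maxStep = maxStep,
      regridThreshold = regridThreshold,
      stopOnCostIncrease = isTRUE(stopOnCostIncrease),
      stepTolerance = stepTolerance, seed = as.integer(seed))
}

#' RegridStack: displacement fields saved at regrid events
#'
#' @slot fields list of [DisplacementField-class] in the order they were
#'   saved (earliest first).
#' @slot events integer iteration indices at which each regrid fired.
#' @exportClass RegridStack
setClass("RegridStack",
  representation(fields = "list", events = "integer"),
  prototype(fields = list(), events = integer(0))
)

setValidity("RegridStack", function(object) {
  if (length(object@fields) != length(object@events))
    return("fields and events must have equal length")
  if (length(object@fields) > 1L) {
    d <- dim(object@fields[[1L]]@u)
    same <- vapply(object@fields, function(f) identical(dim(f@u), d), logical(1))
    if (!all(same)) return("all saved fields must share one shape")
  }
  TRUE
})

#' @rdname RegridStack-class
#' @export
regridStack <- function() new("RegridStack")

#' RegistrationResult: output of the fluid registration loop
#'
#' @slot totalField composed [DisplacementField-class] mapping the target
#'   grid into the original subject.
#' @slot warpedSubject subject resampled into target space.
#' @slot jacobian Jacobian determinant map of the total field.
#' @slot costTrace SSD cost per iteration (first entry = initial cost).
#' @slot regrids the [RegridStack-class] accumulated during the run.
#' @slot convergedReason one of "max_iter", "cost_increase", "step_tolerance".
#' @exportClass RegistrationResult
setClass("RegistrationResult",
  representation(totalField = "DisplacementField", warpedSubject = "ScalarVolume",
                 jacobian = "ScalarVolume", costTrace = "numeric",
                 regrids = "RegridStack", convergedReason = "character")
)

setValidity("RegistrationResult", function(object) {
  if (length(object@costTrace) < 1L) return("costTrace must be non-empty")
  if (any(object@jacobian@data <= 0))
    return("jacobian determinant must be strictly positive at every voxel")
  if (!(object@convergedReason %in% c("max_iter", "cost_increase", "step_tolerance")))
    return("unknown convergedReason")
  TRUE
})

#' GroupDesign: two-group design with a TIV nuisance covariate
#'
#' @slot subjectIds character subject identifiers.
#' @slot group factor with levels control, patient.
#' @slot tiv numeric total intracranial volumes, mm^3.
#' @exportClass GroupDesign
setClass("GroupDesign",
  representation(subjectIds = "character", group = "factor", tiv = "numeric")
)

setValidity("GroupDesign", function(object) {
  n <- length(object@subjectIds)
  if (length(object@group) != n || length(object@tiv) != n)
    return("subjectIds, group and tiv must have equal length")
  if (!identical(levels(object@group), c("control", "patient")))
    return("group must be a factor with levels control, patient")
  if (any(table(object@group) < 2L))
    return("need at least 2 subjects per group")
  if (any(!is.finite(object@tiv)) || any(object@tiv <= 0))
    return("tiv must be positive and finite for all subjects")
  TRUE
})

#' @param subjectIds character ids.
#' @param group character or factor of "control"/"patient".
#' @param tiv positive TIVs in mm^3.
#' @rdname GroupDesign-class
#' @export
groupDesign <- function(subjectIds, group, tiv) {
  new("GroupDesign", subjectIds = as.character(subjectIds),
      group = factor(as.character(group), levels = c("control", "patient")),
      tiv = as.numeric(tiv))
}

#' StatMap: voxelwise t statistics with their mask and threshold metadata
#'
#' @slot tValues [ScalarVolume-class] of t statistics (0 outside the mask).
#' @slot dof residual degrees of freedom.
#' @slot mask binary [ScalarVolume-class] analysis mask.
#' @slot flagged binary [ScalarVolume-class]: in-mask voxels with zero
#'   residual variance whose t was set to 0.
#' @slot thresholdUsed threshold applied by [thresholdMap()] (NA before).
#' @slot correction "uncorrected" or "permutation_fwe".
#' @exportClass StatMap
setClass("StatMap",
  representation(tValues = "ScalarVolume", dof = "integer",
                 mask = "ScalarVolume", flagged = "ScalarVolume",
                 thresholdUsed = "numeric", correction = "character"),
  prototype(thresholdUsed = NA_real_, correction = "uncorrected")
)

setValidity("StatMap", function(object) {
  if (object@dof < 1L) return("dof must be a positive integer")
  inMask <- object@mask@data > 0
  if (any(!is.finite(object@tValues@data[inMask])))
    return("t values must be finite inside the mask")
  TRUE
})

#' PhantomSpec: recipe for a synthetic gray matter probability phantom
#'
#' @slot shape integer(3) grid dimensions.
#' @slot voxelMm isotropic voxel size in mm.
#' @slot structures list of lists with elements `center` (mm), `radii` (mm)
#'   and `peak` (probability in (0, 1]); ellipsoidal bumps summed.
#' @slot smoothnessMm FWHM-free Gaussian smoothing sigma applied to the
#'   summed bumps, mm (0 = none).
#' @slot noiseSd standard deviation of additive Gaussian noise (0 = none).
#' @slot seed integer seed making the phantom deterministic.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(shape = "integer", voxelMm = "numeric", structures = "list",
                 smoothnessMm = "numeric", noiseSd = "numeric", seed = "integer"),
  prototype(shape = c(32L, 32L, 32L), voxelMm = 2, structures = list(),
            smoothnessMm = 0, noiseSd = 0, seed = 0L)
)

setValidity("PhantomSpec", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 2L))
    return("shape must be 3 integers >= 2")
  if (object@voxelMm <= 0) return("voxelMm must be > 0")
  for (s in object@structures) {
    if (!all(c("center", "radii", "peak") %in% names(s)))
      return("each structure needs center, radii and peak")
    if (s$peak <= 0 || s$peak > 1) return("structure peak must lie in (0, 1]")
    if (any(s$radii <= 0)) return("structure radii must be > 0")
  }
  if (object@smoothnessMm < 0) return("smoothnessMm must be >= 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' @param shape integer(3) grid dimensions.
#' @param voxelMm isotropic voxel size, mm.
#' @param structures list of structures (center/radii in mm, peak in (0,1]).
#' @param smoothnessMm Gaussian sigma in mm applied to the bumps.
#' @param noiseSd additive Gaussian noise sd.
#' @param seed integer seed.
#' @rdname PhantomSpec-class
#' @export
phantomSpec <- function(shape = c(32L, 32L, 32L), voxelMm = 2,
                        structures = list(), smoothnessMm = 0, noiseSd = 0,
                        seed = 0L) {
  new("PhantomSpec", shape = as.integer(shape), voxelMm = voxelMm,
      structures = structures, smoothnessMm = smoothnessMm, noiseSd = noiseSd,
      seed = as.integer(seed))
}

#' FiducialCluster: one landmark's positions across subjects
#'
#' @slot locationId identifier of the anatomical location.
#' @slot points numeric matrix (n x 3) of world-space mm coordinates, one
#'   row per subject; at least 3 rows so a covariance is estimable.
#' @exportClass FiducialCluster
setClass("FiducialCluster",
  representation(locationId = "character", points = "matrix")
)

setValidity("FiducialCluster", function(object) {
  if (!is.numeric(object@points) || ncol(object@points) != 3L)
    return("points must be a numeric n x 3 matrix")
  if (nrow(object@points) < 3L)
    return("need at least 3 points per cluster")
  if (any(!is.finite(object@points))) return("points must be finite")
  TRUE
})

#' @param locationId identifier.
#' @param points numeric n x 3 matrix of mm coordinates.
#' @rdname FiducialCluster-class
#' @export
fiducialCluster <- function(locationId, points) {
  new("FiducialCluster", locationId = as.character(locationId),
      points = as.matrix(points))
}
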