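## Synthetic data: gray matter probability phantoms, cohorts with
## ground-truth atrophy, smooth random warps, and the fiducial dispersion
## metrics used to assess registration quality. World coordinates are mm
## with voxel (1,1,1) at 0 mm (isotropic voxelMm grids).

#' Build a probability phantom from ellipsoidal structures
#'
#' Sums hard ellipsoidal bumps (per-structure `center`/`radii` in mm and
#' `peak` probability), optionally Gaussian-smooths them by
#' `smoothnessMm`, adds Gaussian noise of sd `noiseSd`, and clips to the
#' unit interval.
#' Deterministic given `spec@seed`; overlapping structures that exceed
#' probability 1 are clipped with a warning.
#'
#' @param spec a [PhantomSpec-class].
#' @return A probability [ScalarVolume-class].
#' @export
makePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  d <- spec@shape
  vm <- spec@voxelMm
  g <- .gridCoords(d)
  xm <- (g$x - 1) * vm
  ym <- (g$y - 1) * vm
  zm <- (g$z - 1) * vm
  a <- numeric(prod(d))
  for (s in spec@structures) {
    q <- ((xm - s$center[1]) / s$radii[1])^2 +
         ((ym - s$center[2]) / s$radii[2])^2 +
         ((zm - s$center[3]) / s$radii[3])^2
    a <- a + s$peak * (q <= 1)
  }
  dim(a) <- d
  if (any(a > 1))
    warning("overlapping structures exceed probability 1; clipping", call. = FALSE)
  if (spec@smoothnessMm > 0)
    a <- .gaussSmooth(a, rep(spec@smoothnessMm / vm, 3))
  if (spec@noiseSd > 0)
    a <- a + .withSeed(spec@seed, array(rnorm(prod(d), sd = spec@noiseSd), d))
  a <- pmin(pmax(a, 0), 1)
  dim(a) <- d
  scalarVolume(a, voxelSize = rep(vm, 3))
}

#' Smooth random displacement field
#'
#' White Gaussian noise per component, smoothed by a Gaussian of `sigmaMm`,
#' and rescaled so the root-mean-square displacement magnitude equals
#' `rmsMm`. Used to emulate residual inter-subject anatomical variability
#' after coarse normalization.
#'
#' @param shape integer(3) grid dimensions.
#' @param voxelMm isotropic voxel size in mm.
#' @param rmsMm target RMS displacement magnitude, mm.
#' @param sigmaMm smoothness of the field, mm.
#' @param seed integer seed.
#' @return A [DisplacementField-class] in voxel units.
#' @export
randomSmoothField <- function(shape, voxelMm, rmsMm, sigmaMm = 5, seed = 0L) {
  d <- as.integer(shape)
  u <- array(0, c(d, 3L))
  if (rmsMm > 0) {
    raw <- .withSeed(seed, array(rnorm(prod(d) * 3L), c(d, 3L)))
    for (c in 1:3)
      u[, , , c] <- .gaussSmooth(raw[, , , c], rep(sigmaMm / voxelMm, 3))
    rms <- sqrt(mean(.vecNorm(u)^2))
    if (rms > 0) u <- u * (rmsMm / voxelMm) / rms
  }
  displacementField(u, voxelSize = rep(voxelMm, 3))
}

#' Apply a calibrated synthetic atrophy to a phantom
#'
#' Contracts the phantom radially about the region's centroid with a
#' Gaussian-tapered analytic field `u(x) = -alpha (x - c) exp(-r^2/(2 tau^2))`
#' (reading the phantom farther out shrinks the structure), with `alpha`
#' calibrated by root finding so the probability mass inside `region` drops
#' by exactly `fraction`. The ground-truth field is returned alongside the
#' atrophied volume.
#'
#' @param phantom a probability [ScalarVolume-class].
#' @param region binary [ScalarVolume-class] marking the target structure.
#' @param fraction regional mass reduction in (0, 1).
#' @return A list with `volume` (atrophied [ScalarVolume-class]), `field`
#'   (ground-truth [DisplacementField-class]) and `alpha` (the calibrated
#'   contraction strength).
#' @export
applySyntheticAtrophy <- function(phantom, region, fraction) {
  stopifnot(is(phantom, "ScalarVolume"), is(region, "ScalarVolume"))
  .stopShape(phantom@data, region@data, "phantom and region")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop("fraction must lie in (0, 1)", call. = FALSE)
  d <- dim(phantom@data)
  g <- .gridCoords(d)
  inReg <- region@data > 0
  if (!any(inReg)) stop("region is empty", call. = FALSE)
  w <- as.vector(inReg * 1)
  cc <- c(sum(g$x * w), sum(g$y * w), sum(g$z * w)) / sum(w)
  dx <- g$x - cc[1]; dy <- g$y - cc[2]; dz <- g$z - cc[3]
  r2 <- dx^2 + dy^2 + dz^2
  tau <- sqrt(max(r2[as.vector(inReg)]))   # region radius in voxels
  wgt <- exp(-r2 / (2 * tau^2))
  fieldFor <- function(alpha) {
    u <- array(0, c(d, 3L))
    u[, , , 1] <- array(-alpha * dx * wgt, d)
    u[, , , 2] <- array(-alpha * dy * wgt, d)
    u[, , , 3] <- array(-alpha * dz * wgt, d)
    displacementField(u, voxelSize = phantom@voxelSize)
  }
  mass0 <- sum(phantom@data[inReg])
  massAt <- function(alpha)
    sum(sampleWarped(phantom, fieldFor(alpha))@data[inReg])
  target <- (1 - fraction) * mass0
  upper <- 2
  if (massAt(upper) > target)
    stop("requested atrophy fraction is not attainable for this region",
         call. = FALSE)
  alpha <- uniroot(function(a) massAt(a) - target, c(0, upper),
                   tol = 1e-4)$root
  field <- fieldFor(alpha)
  list(volume = sampleWarped(phantom, field), field = field, alpha = alpha)
}

## Default brain-like phantom used by the cohort generator: a large tissue
## ellipsoid plus a small high-probability subcortical structure that the
## synthetic atrophy targets.
.defaultCohortSpec <- function(shape = c(32L, 32L, 32L), voxelMm = 2,
                               seed = 0L) {
  ctr <- (shape - 1) / 2 * voxelMm
  half <- mean((shape - 1) * voxelMm / 2)   # structures scale with the FOV
  phantomSpec(
    shape = shape, voxelMm = voxelMm,
    structures = list(
      list(center = ctr, radii = half * c(0.76, 0.82, 0.70), peak = 0.35),
      list(center = ctr + half * c(-0.26, -0.19, 0),
           radii = rep(half * 0.39, 3), peak = 0.45)
    ),
    smoothnessMm = 2, noiseSd = 0, seed = seed
  )
}

.defaultAtrophyRegion <- function(spec) {
  d <- spec@shape
  vm <- spec@voxelMm
  s <- spec@structures[[2L]]
  g <- .gridCoords(d)
  q <- (((g$x - 1) * vm - s$center[1]) / s$radii[1])^2 +
       (((g$y - 1) * vm - s$center[2]) / s$radii[2])^2 +
       (((g$z - 1) * vm - s$center[3]) / s$radii[3])^2
  scalarVolume(array((q <= 1) * 1, d), voxelSize = rep(vm, 3))
}

#' Generate a synthetic two-group cohort with ground-truth atrophy
#'
#' Controls are copies of a brain-like probability phantom deformed by
#' independent smooth random warps (residual inter-subject variability) with
#' additive Gaussian noise; patients additionally carry a calibrated
#' regional atrophy of `atrophyFraction` applied before the jitter. TIVs are
#' drawn from a normal distribution (mean 1.5 L, sd 0.12 L) independent of
#' group. Deterministic given `seed`.
#'
#' The returned `truthRegion` is the ground-truth effect support at the
#' analysis resolution: the voxels where the smoothed (`truthFwhmMm` FWHM)
#' mass difference between the clean and the atrophied base volume exceeds
#' 10 percent of its peak. This is the region against which a detection map
#' from the same smoothing kernel is meaningfully compared.
#'
#' @param nControls,nPatients group sizes (>= 3 each).
#' @param atrophyFraction regional mass reduction in patients; 0 produces an
#'   exchangeable null cohort.
#' @param jitterMm RMS magnitude of the inter-subject jitter warps, mm.
#' @param noiseSd additive Gaussian noise sd on the probability maps.
#' @param shape integer(3) grid dimensions.
#' @param voxelMm isotropic voxel size, mm.
#' @param truthFwhmMm smoothing at which the truth region is defined, mm.
#' @param seed integer seed.
#' @return A list with `maps` (list of [ScalarVolume-class], controls
#'   first), `design` (a [GroupDesign-class]), `truthRegion` (binary
#'   [ScalarVolume-class], all zero for a null cohort), `phantom` (the clean
#'   base volume, the natural registration target) and `atrophyField`
#'   (ground truth, NULL for a null cohort).
#' @export
makeCohort <- function(nControls = 10L, nPatients = 10L, atrophyFraction = 0.3,
                       jitterMm = 2.5, noiseSd = 0.05,
                       shape = c(32L, 32L, 32L), voxelMm = 2,
                       truthFwhmMm = 8, seed = 0L) {
  if (nControls < 3L || nPatients < 3L)
    stop("need at least 3 subjects per group", call. = FALSE)
  spec <- .defaultCohortSpec(shape, voxelMm, seed)
  base <- makePhantom(spec)
  d <- dim(base@data)
  atroField <- NULL
  truth <- scalarVolume(array(0, d), voxelSize = rep(voxelMm, 3))
  patientBase <- base
  if (atrophyFraction > 0) {
    region <- .defaultAtrophyRegion(spec)
    at <- applySyntheticAtrophy(base, region, atrophyFraction)
    patientBase <- at$volume
    atroField <- at$field
    diffMap <- smoothFWHM(
      scalarVolume(base@data - patientBase@data, voxelSize = rep(voxelMm, 3)),
      truthFwhmMm)
    truth <- scalarVolume((diffMap@data > 0.1 * max(diffMap@data)) * 1,
                          voxelSize = rep(voxelMm, 3))
  }
  n <- nControls + nPatients
  subSeed <- function(k) (as.numeric(seed) * 1009 + k) %% 2147483647
  maps <- vector("list", n)
  for (i in seq_len(n)) {
    src <- if (i <= nControls) base else patientBase
    jit <- randomSmoothField(d, voxelMm, rmsMm = jitterMm, sigmaMm = 5,
                             seed = subSeed(i))
    vol <- sampleWarped(src, jit)@data
    if (noiseSd > 0)
      vol <- vol + .withSeed(subSeed(500L + i),
                             array(rnorm(prod(d), sd = noiseSd), d))
    maps[[i]] <- scalarVolume(array(pmin(pmax(vol, 0), 1), d),
                              voxelSize = rep(voxelMm, 3))
  }
  tiv <- .withSeed(subSeed(777L), rnorm(n, mean = 1.5e6, sd = 1.2e5))
  design <- groupDesign(
    subjectIds = sprintf("S%02d", seq_len(n)),
    group = rep(c("control", "patient"), c(nControls, nPatients)),
    tiv = tiv
  )
  list(maps = maps, design = design, truthRegion = truth, phantom = base,
       atrophyField = atroField)
}

#' Landmarks on the boundary of a phantom structure
#'
#' Places `n` points quasi-uniformly (Fibonacci sphere) on the surface of
#' the first structure of a phantom spec, in world mm, to serve as fiducial
#' locations.
#'
#' @param spec a [PhantomSpec-class] with at least one structure.
#' @param n number of landmarks (default 20).
#' @return An `n x 3` matrix of mm coordinates.
#' @export
structureFiducials <- function(spec, n = 20L) {
  stopifnot(is(spec, "PhantomSpec"), length(spec@structures) >= 1L)
  s <- spec@structures[[1L]]
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  dir <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  sweep(dir %*% diag(s$radii), 2, s$center, `+`)
}

#' Map points through an Eulerian warp
#'
#' Applies the same x - u(x) convention as image warping: each mm point p is
#' converted to voxel coordinates, the field is trilinearly interpolated
#' there, and the displaced position p - u(p) (back in mm) is returned.
#' Points outside the field's domain are dropped with a warning; the dropped
#' row indices are attached as `attr(, "excluded")`.
#'
#' @param points `n x 3` matrix of mm coordinates.
#' @param u a [DisplacementField-class] (voxel units).
#' @param voxelMm isotropic voxel size of the field's grid, mm.
#' @return An `m x 3` matrix of warped mm coordinates (m <= n).
#' @export
warpPoints <- function(points, u, voxelMm) {
  stopifnot(is(u, "VectorField"))
  points <- as.matrix(points)
  d <- dim(u@u)[1:3]
  vox <- points / voxelMm + 1
  inside <- vox[, 1] >= 1 & vox[, 1] <= d[1] &
            vox[, 2] >= 1 & vox[, 2] <= d[2] &
            vox[, 3] >= 1 & vox[, 3] <= d[3]
  if (any(!inside))
    warning(sprintf("%d point(s) outside the field domain were excluded",
                    sum(!inside)), call. = FALSE)
  vin <- vox[inside, , drop = FALSE]
  disp <- vapply(1:3, function(c)
    .trilinear(u@u[, , , c], vin[, 1], vin[, 2], vin[, 3]),
    numeric(nrow(vin)))
  out <- points[inside, , drop = FALSE] - disp * voxelMm
  attr(out, "excluded") <- which(!inside)
  out
}

#' Pull points back through an Eulerian warp (inverse point mapping)
#'
#' Solves x - u(x) = p for each mm point p by fixed-point iteration
#' `x <- p + u(x)`, giving the template-space location whose warped position
#' is p. Used to carry subject-space fiducials into template space for
#' dispersion analysis.
#'
#' @inheritParams warpPoints
#' @param iters fixed-point iterations (the fields in use are small and
#'   smooth; 25 is ample).
#' @return An `n x 3` matrix of mm coordinates.
#' @export
invertWarpPoints <- function(points, u, voxelMm, iters = 25L) {
  stopifnot(is(u, "VectorField"))
  points <- as.matrix(points)
  x <- points
  for (k in seq_len(iters)) {
    vox <- x / voxelMm + 1
    disp <- vapply(1:3, function(c)
      .trilinear(u@u[, , , c], vox[, 1], vox[, 2], vox[, 3]),
      numeric(nrow(x)))
    x <- points + disp * voxelMm
  }
  x
}

#' Fiducial dispersion metrics lambda1 and R1
#'
#' From the 3x3 covariance of a cluster of warped fiducial positions (one
#' per subject) with eigenvalues e1 >= e2 >= e3: `lambda1 = sqrt(e1)` is a
#' standard-deviation-like spread (mm) along the direction of greatest
#' positional uncertainty, and `R1 = e1 / (e1 + e2 + e3)` measures how
#' anisotropic that dispersion is (1/3 isotropic, 1 collinear). A degenerate
#' cluster of identical points reports lambda1 = 0 and R1 = 1/3.
#'
#' @param cluster a [FiducialCluster-class], or an `n x 3` matrix of mm
#'   coordinates (n >= 3).
#' @return Named numeric vector `c(lambda1 = , r1 = )`.
#' @export
fiducialDispersion <- function(cluster) {
  pts <- if (is(cluster, "FiducialCluster")) cluster@points else as.matrix(cluster)
  if (nrow(pts) < 3L)
    stop("need at least 3 points to estimate a covariance", call. = FALSE)
  C <- cov(pts)
  ee <- sort(pmax(eigen(C, symmetric = TRUE, only.values = TRUE)$values, 0),
             decreasing = TRUE)
  tot <- sum(ee)
  if (tot <= .Machine$double.eps)
    return(c(lambda1 = 0, r1 = 1 / 3))
  c(lambda1 = sqrt(ee[1]), r1 = ee[1] / tot)
}
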