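#' Read a 3D volume from a NIfTI-1 file
#'
#' Voxel dimensions are taken from the header (`pixdim`), the origin from the
#' stored affine's translation. Data are cast to double.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [ScalarVolume-class].
#' @export
loadVolume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read volume: file '%s' does not exist", path),
         call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3D volume, got a %dD image of shape %s",
                 length(d), paste(d, collapse = "x")), call. = FALSE)
  vs <- abs(RNifti::pixdim(img))[1:3]
  aff <- try(RNifti::xform(img), silent = TRUE)
  orig <- if (inherits(aff, "try-error")) c(0, 0, 0) else as.numeric(aff[1:3, 4])
  scalarVolume(array(as.numeric(img), d), voxelSize = vs, origin = orig)
}

#' Write a ScalarVolume as a NIfTI-1 file
#'
#' The voxel size and origin are stored in the qform/sform affine (a diagonal
#' scaling plus translation); data are written as 64-bit floats so that
#' `loadVolume(saveVolume(v))` round-trips values exactly.
#'
#' @param vol a [ScalarVolume-class].
#' @param path destination path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
saveVolume <- function(vol, path) {
  stopifnot(is(vol, "ScalarVolume"))
  img <- RNifti::asNifti(vol@data)
  RNifti::pixdim(img) <- vol@voxelSize
  aff <- diag(4)
  diag(aff)[1:3] <- vol@voxelSize
  aff[1:3, 4] <- vol@origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  ok <- try(RNifti::writeNifti(img, path, datatype = "double"), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop(sprintf("cannot write volume to '%s'", path), call. = FALSE)
  invisible(path)
}

#' Resample a volume to an isotropic voxel size
#'
#' Trilinear interpolation onto a grid with voxel size `targetMm` along all
#' axes; the world-space field of view is preserved to within one voxel, and
#' resampling at the native resolution is the identity.
#'
#' @param vol a [ScalarVolume-class].
#' @param targetMm positive target voxel size in mm.
#' @return A [ScalarVolume-class] at `(targetMm, targetMm, targetMm)`.
#' @export
resampleIsotropic <- function(vol, targetMm) {
  stopifnot(is(vol, "ScalarVolume"))
  if (!is.numeric(targetMm) || length(targetMm) != 1L || targetMm <= 0)
    stop("targetMm must be a single positive number", call. = FALSE)
  d <- dim(vol@data)
  vs <- vol@voxelSize
  if (all(abs(vs - targetMm) < 1e-12)) return(vol)
  nd <- pmax(2L, as.integer(round(d * vs / targetMm)))
  g <- .gridCoords(nd)
  # new sample k sits at world offset (k-1)*targetMm -> old index coordinate
  cx <- (g$x - 1) * targetMm / vs[1] + 1
  cy <- (g$y - 1) * targetMm / vs[2] + 1
  cz <- (g$z - 1) * targetMm / vs[3] + 1
  out <- array(.trilinear(vol@data, cx, cy, cz), nd)
  scalarVolume(out, voxelSize = rep(targetMm, 3), origin = vol@origin)
}

#' Warp a volume through an Eulerian displacement field
#'
#' The output at grid point x is the input interpolated at x - u(x)
#' (trilinear); coordinates falling outside the grid read the background
#' value 0, matching probability maps that vanish outside the head.
#'
#' @param vol a [ScalarVolume-class].
#' @param u a [DisplacementField-class] (voxel units) of the same shape.
#' @return The warped [ScalarVolume-class].
#' @export
sampleWarped <- function(vol, u) {
  stopifnot(is(vol, "ScalarVolume"), is(u, "VectorField"))
  .stopShape(vol@data, u@u, "volume and field")
  d <- dim(vol@data)
  g <- .gridCoords(d)
  out <- .trilinear(vol@data,
                    g$x - as.vector(u@u[, , , 1]),
                    g$y - as.vector(u@u[, , , 2]),
                    g$z - as.vector(u@u[, , , 3]))
  scalarVolume(array(out, d), voxelSize = vol@voxelSize, origin = vol@origin)
}

#' Spatial gradient of a scalar volume
#'
#' Central differences in the interior, one-sided at the boundary slabs;
#' units are intensity per voxel.
#'
#' @param vol a [ScalarVolume-class].
#' @return A [VectorField-class] holding the three partial derivatives.
#' @export
spatialGradient <- function(vol) {
  stopifnot(is(vol, "ScalarVolume"))
  d <- dim(vol@data)
  g <- array(0, c(d, 3L))
  for (ax in 1:3) g[, , , ax] <- .centralDiff(vol@data, ax)
  vectorField(g, voxelSize = vol@voxelSize)
}
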