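#' Accessors for the grid data model
#'
#' `volData()` returns the raw 3D array of a [ScalarVolume-class];
#' `voxelSize()` the voxel edge lengths in mm; `origin()` the world position
#' of the first voxel; `fieldArray()` the (nx, ny, nz, 3) array of a
#' [VectorField-class].
#'
#' @param x the object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname accessors
#' @export
setGeneric("fieldArray", function(x) standardGeneric("fieldArray"))

#' @rdname accessors
#' @export
setMethod("volData", "ScalarVolume", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("voxelSize", "ScalarVolume", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("voxelSize", "VectorField", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("origin", "ScalarVolume", function(x) x@origin)

#' @rdname accessors
#' @export
setMethod("fieldArray", "VectorField", function(x) x@u)

#' Accessors for registration results
#'
#' @param x a [RegistrationResult-class].
#' @return `totalField()` the composed displacement field; `warpedVolume()`
#'   the subject warped into target space; `jacobianVolume()` the Jacobian
#'   determinant map; `costTrace()` the per-iteration SSD cost;
#'   `regridEvents()` the iteration indices at which regridding fired.
#' @name registration-accessors
NULL

#' @rdname registration-accessors
#' @export
setGeneric("totalField", function(x) standardGeneric("totalField"))
#' @rdname registration-accessors
#' @export
setGeneric("warpedVolume", function(x) standardGeneric("warpedVolume"))
#' @rdname registration-accessors
#' @export
setGeneric("jacobianVolume", function(x) standardGeneric("jacobianVolume"))
#' @rdname registration-accessors
#' @export
setGeneric("costTrace", function(x) standardGeneric("costTrace"))
#' @rdname registration-accessors
#' @export
setGeneric("regridEvents", function(x) standardGeneric("regridEvents"))

#' @rdname registration-accessors
#' @export
setMethod("totalField", "RegistrationResult", function(x) x@totalField)
#' @rdname registration-accessors
#' @export
setMethod("warpedVolume", "RegistrationResult", function(x) x@warpedSubject)
#' @rdname registration-accessors
#' @export
setMethod("jacobianVolume", "RegistrationResult", function(x) x@jacobian)
#' @rdname registration-accessors
#' @export
setMethod("costTrace", "RegistrationResult", function(x) x@costTrace)
#' @rdname registration-accessors
#' @export
setMethod("regridEvents", "RegistrationResult", function(x) x@regrids@events)

#' Accessors for StatMap
#'
#' @param x a [StatMap-class].
#' @return `tMap()` the t-statistic volume; `statDof()` the residual degrees
#'   of freedom; `statMask()` the binary analysis mask.
#' @name statmap-accessors
NULL

#' @rdname statmap-accessors
#' @export
setGeneric("tMap", function(x) standardGeneric("tMap"))
#' @rdname statmap-accessors
#' @export
setGeneric("statDof", function(x) standardGeneric("statDof"))
#' @rdname statmap-accessors
#' @export
setGeneric("statMask", function(x) standardGeneric("statMask"))

#' @rdname statmap-accessors
#' @export
setMethod("tMap", "StatMap", function(x) x@tValues)
#' @rdname statmap-accessors
#' @export
setMethod("statDof", "StatMap", function(x) x@dof)
#' @rdname statmap-accessors
#' @export
setMethod("statMask", "StatMap", function(x) x@mask)

setMethod("show", "ScalarVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ScalarVolume %dx%dx%d, voxel %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3],
              paste(format(object@voxelSize, digits = 3), collapse = "x"),
              min(object@data), max(object@data)))
})

setMethod("show", "VectorField", function(object) {
  d <- dim(object@u)
  mag <- sqrt(object@u[, , , 1]^2 + object@u[, , , 2]^2 + object@u[, , , 3]^2)
  cat(sprintf("%s %dx%dx%d, voxel %s mm, max |u| = %.4g voxels\n",
              class(object), d[1], d[2], d[3],
              paste(format(object@voxelSize, digits = 3), collapse = "x"),
              max(mag)))
})

setMethod("show", "RegistrationResult", function(object) {
  ct <- object@costTrace
  cat(sprintf(paste0("RegistrationResult: %d iterations, cost %.4g -> %.4g ",
                     "(%.1f%%), %d regrid(s), min |J| = %.3f, stop: %s\n"),
              length(ct) - 1L, ct[1], ct[length(ct)],
              100 * ct[length(ct)] / max(ct[1], .Machine$double.xmin),
              length(object@regrids@fields), min(object@jacobian@data),
              object@convergedReason))
})

setMethod("show", "GroupDesign", function(object) {
  tab <- table(object@group)
  cat(sprintf("GroupDesign: %d controls, %d patients, TIV %.0f +/- %.0f mm^3\n",
              tab[["control"]], tab[["patient"]],
              mean(object@tiv), sd(object@tiv)))
})

setMethod("show", "StatMap", function(object) {
  inMask <- object@mask@data > 0
  cat(sprintf("StatMap: dof = %d, %d in-mask voxels, max t = %.3f, %s\n",
              object@dof, sum(inMask), max(object@tValues@data[inMask]),
              object@correction))
})
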