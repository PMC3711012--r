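#' Jacobian modulation of a warped probability map
#'
#' Multiplies the warped map voxelwise by the Jacobian determinant of the
#' warp, so that total tissue amount (probability mass times voxel volume),
#' not just tissue concentration, is carried into the analysis: warping plus
#' modulation approximately conserves the total probability mass of the
#' input map.
#'
#' @param warped warped probability [ScalarVolume-class].
#' @param jac Jacobian determinant [ScalarVolume-class], strictly positive.
#' @return The modulated [ScalarVolume-class].
#' @export
modulate <- function(warped, jac) {
  stopifnot(is(warped, "ScalarVolume"), is(jac, "ScalarVolume"))
  .stopShape(warped@data, jac@data, "map and jacobian")
  if (any(jac@data <= 0))
    stop("topology violation: Jacobian determinant must be strictly positive everywhere",
         call. = FALSE)
  scalarVolume(warped@data * jac@data, voxelSize = warped@voxelSize,
               origin = warped@origin)
}

#' Total intracranial volume from native-space tissue segments
#'
#' TIV is the summed probability mass of the gray matter, white matter and
#' CSF segments times the voxel volume, in mm^3.
#'
#' @param gm,wm,csf tissue probability [ScalarVolume-class]s sharing shape
#'   and voxel size.
#' @return TIV in mm^3.
#' @export
estimateTIV <- function(gm, wm, csf) {
  stopifnot(is(gm, "ScalarVolume"), is(wm, "ScalarVolume"), is(csf, "ScalarVolume"))
  .stopShape(gm@data, wm@data, "gm and wm")
  .stopShape(gm@data, csf@data, "gm and csf")
  voxVol <- prod(gm@voxelSize)
  (sum(gm@data) + sum(wm@data) + sum(csf@data)) * voxVol
}

#' Normalize a regional volume to the mean control TIV
#'
#' Head-size correction by simple proportional scaling:
#' `raw * meanControlTiv / subjectTiv`.
#'
#' @param rawVolume regional volume in mm^3.
#' @param subjectTiv the subject's TIV in mm^3 (> 0).
#' @param meanControlTiv mean TIV of the control cohort in mm^3 (> 0).
#' @return The TIV-normalized volume in mm^3.
#' @export
normalizeToMeanTIV <- function(rawVolume, subjectTiv, meanControlTiv) {
  if (any(subjectTiv <= 0) || any(meanControlTiv <= 0))
    stop("TIV values must be positive", call. = FALSE)
  rawVolume * meanControlTiv / subjectTiv
}

#' Percentage volume change of a patient group relative to controls
#'
#' `100 * (patientMean - controlMean) / controlMean`, rounded to one decimal
#' as conventionally reported alongside group means.
#'
#' @param controlMean control-group mean volume (> 0).
#' @param patientMean patient-group mean volume.
#' @param digits decimals in the returned value (default 1).
#' @return The percent change (negative = atrophy).
#' @export
groupPercentChange <- function(controlMean, patientMean, digits = 1L) {
  if (any(controlMean <= 0)) stop("controlMean must be positive", call. = FALSE)
  round(100 * (patientMean - controlMean) / controlMean, digits)
}
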