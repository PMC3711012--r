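## Minimal VBM statistics stage: smoothing, relative-threshold masking, a
## voxelwise two-group GLM with a TIV nuisance covariate, and thresholds
## (uncorrected p < 0.001, or family-wise error control by max-statistic
## permutation of the group labels).

#' Gaussian smoothing by FWHM in mm
#'
#' Separable Gaussian smoothing with per-axis sigma
#' `fwhmMm / (voxelSize * sqrt(8 ln 2))` voxels and zero-padded boundaries,
#' the standard VBM preprocessing step (8 mm FWHM typical, 6-10 mm common).
#'
#' @param vol a [ScalarVolume-class].
#' @param fwhmMm positive full width at half maximum, mm.
#' @return The smoothed [ScalarVolume-class].
#' @export
smoothFWHM <- function(vol, fwhmMm) {
  stopifnot(is(vol, "ScalarVolume"))
  if (!is.numeric(fwhmMm) || length(fwhmMm) != 1L || fwhmMm <= 0)
    stop("fwhmMm must be a single positive number", call. = FALSE)
  sigmaVox <- fwhmMm / (vol@voxelSize * sqrt(8 * log(2)))
  scalarVolume(.gaussSmooth(vol@data, sigmaVox), voxelSize = vol@voxelSize,
               origin = vol@origin)
}

#' Relative-threshold analysis mask
#'
#' A voxel enters the mask only if, in every image, its value exceeds
#' `fraction` times that image's global mean computed over strictly positive
#' voxels (an SPM-like global proxy). The conventional VBM fraction is 0.2.
#'
#' @param images non-empty list of [ScalarVolume-class]s sharing one shape.
#' @param fraction relative threshold in (0, 1).
#' @return A binary [ScalarVolume-class] (1 in-mask).
#' @export
relativeThresholdMask <- function(images, fraction = 0.2) {
  if (!is.list(images) || length(images) == 0L)
    stop("images must be a non-empty list of volumes", call. = FALSE)
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie in (0, 1)", call. = FALSE)
  ref <- images[[1L]]
  keep <- array(TRUE, dim(ref@data))
  for (img in images) {
    .stopShape(ref@data, img@data, "mask input images")
    pos <- img@data[img@data > 0]
    gmean <- if (length(pos)) mean(pos) else 0
    keep <- keep & (img@data > fraction * gmean)
  }
  scalarVolume(keep * 1, voxelSize = ref@voxelSize, origin = ref@origin)
}

.designMatrix <- function(design) {
  patient <- as.numeric(design@group == "patient")
  tiv <- design@tiv - mean(design@tiv)
  if (sd(tiv) == 0) {
    warning("TIV covariate is constant; dropping it from the design",
            call. = FALSE)
    return(cbind(intercept = 1, patient = patient))
  }
  # standardized for conditioning; rescaling a column leaves t unchanged
  cbind(intercept = 1, patient = patient, tiv = tiv / sd(tiv))
}

## Voxelwise OLS t statistics for the control - patient contrast given a
## design matrix X (first columns intercept, patient, [tiv]) and data matrix
## Y (subjects x voxels). Returns list(t, dof, flagged).
.fitTwoGroup <- function(X, Y) {
  n <- nrow(X)
  p <- ncol(X)
  XtXinv <- solve(crossprod(X))
  B <- XtXinv %*% crossprod(X, Y)           # p x V coefficients
  res <- Y - X %*% B
  dof <- n - p
  sigma2 <- colSums(res^2) / dof
  cvec <- numeric(p)
  cvec[2L] <- -1                             # control - patient
  se2 <- drop(t(cvec) %*% XtXinv %*% cvec) * sigma2
  est <- drop(crossprod(cvec, B))
  # zero residual variance up to rounding: flag and report t = 0
  flagged <- !is.finite(se2) |
    sigma2 <= 1e-12 * (colSums(Y^2) / n + .Machine$double.xmin)
  t <- ifelse(flagged, 0, est / sqrt(pmax(se2, .Machine$double.xmin)))
  list(t = t, dof = as.integer(dof), flagged = flagged)
}

#' Voxelwise two-group t-test with a TIV nuisance covariate
#'
#' Ordinary least squares fit of `value ~ group + TIV + intercept` at every
#' in-mask voxel; the returned t statistic tests the one-sided contrast
#' control - patient, so positive t marks atrophy in patients. Voxels with
#' zero residual variance get t = 0 and are flagged rather than NaN so that
#' downstream thresholding is total. A constant TIV column is dropped with a
#' warning and the degrees of freedom adjust accordingly.
#'
#' @param maps list of [ScalarVolume-class]s, one per subject, in the order
#'   of the design rows.
#' @param design a [GroupDesign-class].
#' @param mask binary [ScalarVolume-class] analysis mask.
#' @return A [StatMap-class].
#' @export
glmTwoGroupT <- function(maps, design, mask) {
  stopifnot(is(design, "GroupDesign"), is(mask, "ScalarVolume"))
  if (length(maps) != length(design@subjectIds))
    stop("need exactly one map per design row", call. = FALSE)
  ref <- maps[[1L]]
  for (m in maps) .stopShape(ref@data, m@data, "subject maps")
  .stopShape(ref@data, mask@data, "maps and mask")
  inMask <- which(mask@data > 0)
  Y <- vapply(maps, function(m) m@data[inMask], numeric(length(inMask)))
  Y <- t(Y)                                  # subjects x voxels
  X <- .designMatrix(design)
  fit <- .fitTwoGroup(X, Y)
  tArr <- array(0, dim(ref@data))
  tArr[inMask] <- fit$t
  flagArr <- array(0, dim(ref@data))
  flagArr[inMask] <- fit$flagged * 1
  new("StatMap",
      tValues = scalarVolume(tArr, voxelSize = ref@voxelSize, origin = ref@origin),
      dof = fit$dof, mask = mask,
      flagged = scalarVolume(flagArr, voxelSize = ref@voxelSize, origin = ref@origin),
      thresholdUsed = NA_real_, correction = "uncorrected")
}

#' Family-wise error threshold by max-statistic permutation
#'
#' Permutes the group labels (the TIV column stays attached to its subject),
#' refits the voxelwise GLM for each permutation and records the maximum t
#' over the mask; the returned threshold is the `1 - alpha` empirical
#' quantile of that max-t null distribution. The observed labelling is
#' always included as the first permutation. When the number of distinct
#' label assignments does not exceed `nPerm` the null distribution is
#' enumerated exactly instead of sampled. Deterministic given `seed`.
#'
#' @inheritParams glmTwoGroupT
#' @param nPerm number of permutations (>= 100).
#' @param alpha family-wise error rate to control.
#' @param seed integer seed for the sampled permutations.
#' @return The scalar t threshold.
#' @export
permutationFWEThreshold <- function(maps, design, mask, nPerm = 1000L,
                                    alpha = 0.05, seed = 0L) {
  stopifnot(is(design, "GroupDesign"), is(mask, "ScalarVolume"))
  if (nPerm < 100L) stop("nPerm must be >= 100", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]", call. = FALSE)
  inMask <- which(mask@data > 0)
  Y <- t(vapply(maps, function(m) m@data[inMask], numeric(length(inMask))))
  n <- length(design@subjectIds)
  nPat <- sum(design@group == "patient")
  patIdx0 <- which(design@group == "patient")
  tiv <- design@tiv - mean(design@tiv)
  useTiv <- sd(tiv) > 0
  if (useTiv) tiv <- tiv / sd(tiv)
  nDistinct <- choose(n, nPat)
  if (nDistinct <= nPerm) {
    perms <- combn(n, nPat, simplify = FALSE)
  } else {
    perms <- .withSeed(seed, {
      c(list(patIdx0),
        replicate(nPerm - 1L, sort(sample.int(n, nPat)), simplify = FALSE))
    })
  }
  maxt <- vapply(perms, function(idx) {
    pat <- numeric(n)
    pat[idx] <- 1
    X <- if (useTiv) cbind(1, pat, tiv) else cbind(1, pat)
    max(.fitTwoGroup(X, Y)$t)   # one-sided family: control - patient
  }, numeric(1))
  as.numeric(quantile(maxt, probs = 1 - alpha, type = 1, names = FALSE))
}

#' Threshold a statistic map
#'
#' Produces the binary suprathreshold map for either the uncorrected
#' p < 0.001 voxel threshold (one-sided, via the t quantile at the map's
#' degrees of freedom) or a supplied permutation-based family-wise error
#' threshold. Connected clusters (6-connectivity) smaller than `extentK`
#' voxels are removed; `extentK = 0` keeps every suprathreshold voxel.
#'
#' @param stat a [StatMap-class].
#' @param mode `"unc001"` or `"fwe05"`.
#' @param extentK nonnegative cluster extent threshold in voxels.
#' @param fweThreshold the t threshold from [permutationFWEThreshold()]
#'   (required for mode `"fwe05"`).
#' @return A binary [ScalarVolume-class]; the applied t threshold is
#'   available as `attr(, "threshold")`.
#' @export
thresholdMap <- function(stat, mode = c("unc001", "fwe05"), extentK = 0L,
                         fweThreshold = NULL) {
  stopifnot(is(stat, "StatMap"))
  mode <- match.arg(mode)
  if (extentK < 0) stop("extentK must be >= 0", call. = FALSE)
  thr <- if (mode == "unc001") {
    qt(0.999, df = stat@dof)
  } else {
    if (is.null(fweThreshold) || !is.finite(fweThreshold))
      stop("mode 'fwe05' needs the permutation threshold in fweThreshold",
           call. = FALSE)
    fweThreshold
  }
  sig <- (stat@tValues@data > thr) & (stat@mask@data > 0)
  if (extentK > 0L && any(sig)) {
    d <- dim(sig)
    lab <- cpp_label6(as.logical(sig), d[1], d[2], d[3])
    sizes <- tabulate(lab)
    keep <- which(sizes >= extentK)
    sig <- array(lab %in% keep & lab > 0, d)
  }
  out <- scalarVolume(sig * 1, voxelSize = stat@tValues@voxelSize,
                      origin = stat@tValues@origin)
  attr(out, "threshold") <- thr
  out
}
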