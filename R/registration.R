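## Outer fluid-registration loop. Each iteration: force -> velocity (solver)
## -> perturbation field (material-derivative correction) -> adaptive time
## step capping the displacement increment -> explicit Euler update ->
## Jacobian-threshold regrid check.

#' Perturbation field from a velocity field
#'
#' The Eulerian update direction for the displacement field,
#' \deqn{R(x) = v(x) - \sum_{i=1}^{3} v_i(x) \, \partial u / \partial x_i,}
#' i.e. the velocity corrected by the material-derivative transport term,
#' which vanishes when the deforming body and the reference grid coincide
#' (u = 0 gives R = v). Derivatives are central differences applied
#' componentwise.
#'
#' @param v velocity [VectorField-class].
#' @param u current [DisplacementField-class] of the same shape.
#' @return The perturbation [VectorField-class] R.
#' @export
perturbationField <- function(v, u) {
  stopifnot(is(v, "VectorField"), is(u, "VectorField"))
  .stopShape(v@u, u@u, "velocity and displacement")
  out <- v@u
  for (comp in 1:3) {
    uc <- u@u[, , , comp]
    adv <- 0
    for (i in 1:3) adv <- adv + v@u[, , , i] * .centralDiff(uc, i)
    out[, , , comp] <- v@u[, , , comp] - adv
  }
  vectorField(out, voxelSize = v@voxelSize)
}

#' Adaptive time step enforcing a maximum displacement per iteration
#'
#' Returns `m / max_x ||R(x)||`, so that the Euler increment `R * dt` has
#' maximum voxelwise Euclidean norm exactly `m` whenever R is nonzero. A
#' zero perturbation field returns 0, signalling convergence.
#'
#' @param R perturbation [VectorField-class].
#' @param m positive maximum displacement in voxels.
#' @return A nonnegative scalar time step.
#' @export
timeStep <- function(R, m) {
  stopifnot(is(R, "VectorField"))
  if (!is.numeric(m) || length(m) != 1L || m <= 0)
    stop("m must be a single positive number", call. = FALSE)
  rmax <- max(.vecNorm(R@u))
  if (rmax == 0) 0 else m / rmax
}

#' Explicit Euler update of the displacement field
#'
#' @param u current [DisplacementField-class].
#' @param R perturbation [VectorField-class].
#' @param dt nonnegative time step.
#' @return The updated [DisplacementField-class] `u + R * dt`.
#' @export
eulerUpdate <- function(u, R, dt) {
  stopifnot(is(u, "VectorField"), is(R, "VectorField"), dt >= 0)
  .stopShape(u@u, R@u, "displacement and perturbation")
  displacementField(u@u + R@u * dt, voxelSize = u@voxelSize)
}

#' Jacobian determinant of an Eulerian warp
#'
#' The warp maps x to x - u(x), so its Jacobian is `I - du/dx`; the
#' determinant is evaluated voxelwise from central-difference displacement
#' gradients (one-sided at boundaries). Values below 1 indicate local
#' compression, above 1 expansion; topology preservation requires the map to
#' keep the determinant strictly positive everywhere.
#'
#' @param u a [DisplacementField-class].
#' @return A [ScalarVolume-class] of unitless determinants.
#' @export
jacobianDeterminant <- function(u) {
  stopifnot(is(u, "VectorField"))
  J <- vector("list", 9L)
  for (comp in 1:3)
    for (ax in 1:3)
      J[[(comp - 1) * 3 + ax]] <- .centralDiff(u@u[, , , comp], ax)
  # M = I - J, det expanded elementwise
  m11 <- 1 - J[[1]]; m12 <- -J[[2]]; m13 <- -J[[3]]
  m21 <- -J[[4]]; m22 <- 1 - J[[5]]; m23 <- -J[[6]]
  m31 <- -J[[7]]; m32 <- -J[[8]]; m33 <- 1 - J[[9]]
  det <- m11 * (m22 * m33 - m23 * m32) -
         m12 * (m21 * m33 - m23 * m31) +
         m13 * (m21 * m32 - m22 * m31)
  scalarVolume(det, voxelSize = u@voxelSize)
}

#' Regrid the deformation when the Jacobian crosses a threshold
#'
#' If the minimum Jacobian determinant of `u` falls below `threshold`, the
#' current field is pushed onto the stack, the working subject is resampled
#' through it, and the field restarts from zero; otherwise everything is
#' returned unchanged. Restarting from the identity keeps every saved piece
#' mildly deformed, so the composed total warp retains a positive
#' determinant (topology preservation).
#'
#' @param u current [DisplacementField-class].
#' @param subjectCurrent working subject [ScalarVolume-class].
#' @param threshold regrid threshold in (0, 1).
#' @param stack the [RegridStack-class] accumulated so far.
#' @param iteration iteration index recorded when the regrid fires.
#' @return A list with elements `u`, `subject`, `stack`, `regridded`.
#' @export
maybeRegrid <- function(u, subjectCurrent, threshold, stack = regridStack(),
                        iteration = NA_integer_) {
  stopifnot(is(u, "VectorField"), is(subjectCurrent, "ScalarVolume"),
            is(stack, "RegridStack"))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  minDet <- min(jacobianDeterminant(u)@data)
  if (minDet >= threshold)
    return(list(u = u, subject = subjectCurrent, stack = stack,
                regridded = FALSE))
  stack@fields <- c(stack@fields, list(as(u, "DisplacementField")))
  stack@events <- c(stack@events, as.integer(iteration))
  list(u = zeroField(subjectCurrent),
       subject = sampleWarped(subjectCurrent, u),
       stack = stack, regridded = TRUE)
}

#' Compose two Eulerian displacement fields
#'
#' Returns the single field equivalent to warping first through `outer` and
#' then reading the `inner` warp at the displaced position:
#' `u_total(x) = u_outer(x) + u_inner(x - u_outer(x))` (inner interpolated
#' trilinearly, background 0). Warping once through the composition agrees
#' with sequential warping to within interpolation error.
#'
#' @param outer,inner [DisplacementField-class]s of one shape.
#' @return The composed [DisplacementField-class].
#' @export
composeDisplacements <- function(outer, inner) {
  stopifnot(is(outer, "VectorField"), is(inner, "VectorField"))
  .stopShape(outer@u, inner@u, "outer and inner fields")
  d <- dim(outer@u)[1:3]
  g <- .gridCoords(d)
  cx <- g$x - as.vector(outer@u[, , , 1])
  cy <- g$y - as.vector(outer@u[, , , 2])
  cz <- g$z - as.vector(outer@u[, , , 3])
  out <- outer@u
  for (c in 1:3)
    out[, , , c] <- outer@u[, , , c] +
      array(.trilinear(inner@u[, , , c], cx, cy, cz), d)
  displacementField(out, voxelSize = outer@voxelSize)
}

## Fold the regrid stack plus the final field into one total warp. The
## earliest saved field is the first warp applied to the original subject;
## each later field reads the accumulated warp at its displaced position.
.composeStack <- function(fields) {
  Reduce(function(acc, f) composeDisplacements(f, acc),
         fields[-1L], fields[[1L]])
}

#' Viscous fluid registration of two probability maps
#'
#' Iterates force computation, velocity solution, perturbation field,
#' adaptive time stepping (per-iteration displacement capped at
#' `cfg@maxStep` voxels), explicit Euler update and Jacobian-threshold
#' regridding, for at most `cfg@maxIterations` iterations. The SSD cost
#' against the target is recorded every iteration; with
#' `cfg@stopOnCostIncrease` a worsening update is rolled back and the loop
#' ends, so the recorded trace is non-increasing. The returned total field
#' composes all regrid pieces with the final field, and its Jacobian map is
#' strictly positive everywhere.
#'
#' @param subject moving [ScalarVolume-class] (probability-like or general
#'   scalar volume).
#' @param target fixed [ScalarVolume-class] of the same shape.
#' @param cfg a [RegistrationConfig-class].
#' @return A [RegistrationResult-class].
#' @export
registerFluid <- function(subject, target, cfg = registrationConfig()) {
  stopifnot(is(subject, "ScalarVolume"), is(target, "ScalarVolume"),
            is(cfg, "RegistrationConfig"))
  .stopShape(subject@data, target@data, "subject and target")
  if (any(!is.finite(subject@data)) || any(!is.finite(target@data)))
    stop("subject and target must be finite everywhere", call. = FALSE)
  Sw <- subject                 # working subject (re-sampled at regrids)
  u <- zeroField(subject)
  stack <- regridStack()
  warped <- sampleWarped(Sw, u)
  cost <- .ssd(warped@data, target@data)
  trace <- cost
  reason <- "max_iter"
  for (it in seq_len(cfg@maxIterations)) {
    F <- computeForce(Sw, target, u)
    v <- suppressWarnings(solveVelocity(F, cfg@visc, cfg@solver))
    R <- perturbationField(v, u)
    rmax <- max(.vecNorm(R@u))
    if (rmax < cfg@stepTolerance) { reason <- "step_tolerance"; break }
    dt <- cfg@maxStep / rmax
    uTrial <- eulerUpdate(u, R, dt)
    warpedTrial <- sampleWarped(Sw, uTrial)
    costTrial <- .ssd(warpedTrial@data, target@data)
    if (cfg@stopOnCostIncrease && costTrial > trace[length(trace)]) {
      reason <- "cost_increase"
      break
    }
    u <- uTrial
    trace <- c(trace, costTrial)
    rg <- maybeRegrid(u, Sw, cfg@regridThreshold, stack, iteration = it)
    if (rg$regridded) {
      u <- rg$u
      Sw <- rg$subject
      stack <- rg$stack
    }
  }
  total <- .composeStack(c(stack@fields, list(u)))
  warpedFinal <- sampleWarped(subject, total)
  jac <- jacobianDeterminant(total)
  new("RegistrationResult", totalField = total, warpedSubject = warpedFinal,
      jacobian = jac, costTrace = trace, regrids = stack,
      convergedReason = reason)
}
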