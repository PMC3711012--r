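## Force field and solvers for the linearized Navier-Stokes force balance
##   mu * Lap(v) + (mu + lam) * grad(div v) + F = 0,
## written L v = -F below. applyOperator() implements L itself and serves as
## the forward oracle against which every solver is validated.

#' Intensity-difference driving force
#'
#' The demons-style force for sum-of-squared-differences matching: the warped
#' subject S(x - u(x)) is compared against the target and weighted by its own
#' spatial gradient,
#' \deqn{F(x) = [S(x-u(x)) - T(x)] \nabla S|_{x-u(x)}.}
#' Because the solvers return the velocity with `L v = -F` and the warp reads
#' the subject at x - u(x), this sign makes F (half) the negative SSD
#' gradient with respect to u: the induced velocity drives the warped subject
#' toward the target, and the update descends the SSD cost.
#'
#' @param subject,target [ScalarVolume-class]s of one shape.
#' @param u current [DisplacementField-class].
#' @return A [VectorField-class] force, intensity^2 per voxel.
#' @export
computeForce <- function(subject, target, u) {
  .stopShape(subject@data, target@data, "subject and target")
  .stopShape(subject@data, u@u, "subject and field")
  warped <- sampleWarped(subject, u)
  g <- spatialGradient(warped)
  diff <- warped@data - target@data
  Farr <- g@u
  for (c in 1:3) Farr[, , , c] <- diff * Farr[, , , c]
  vectorField(Farr, voxelSize = subject@voxelSize)
}

#' Apply the discrete viscous operator L
#'
#' Computes \eqn{L v = \mu \nabla^2 v + (\mu+\lambda) \nabla(\nabla \cdot v)}
#' with the 7-point Laplacian and central-difference divergence/gradient;
#' values outside the grid are taken as 0, matching the clamped boundary
#' condition of the iterative solvers. This is the forward oracle used to
#' measure solver residuals.
#'
#' @param v a [VectorField-class].
#' @param visc a [ViscosityParams-class].
#' @return The [VectorField-class] L v.
#' @export
applyOperator <- function(v, visc = viscosityParams()) {
  stopifnot(is(v, "VectorField"), is(visc, "ViscosityParams"))
  mu <- visc@mu
  ml <- visc@mu + visc@lambda
  out <- array(0, dim(v@u))
  comp <- list(v@u[, , , 1], v@u[, , , 2], v@u[, , , 3])
  for (j in 1:3) {
    a <- comp[[j]]
    lap <- -6 * a
    for (ax in 1:3) lap <- lap + .shiftZero(a, ax, 1L) + .shiftZero(a, ax, -1L)
    # central-difference divergence followed by central-difference gradient:
    # the diagonal term couples voxels two steps apart along axis j
    djj <- (.shiftZero(a, j, 2L) + .shiftZero(a, j, -2L) - 2 * a) / 4
    cross <- 0
    for (i in 1:3) {
      if (i == j) next
      b <- comp[[i]]
      cross <- cross +
        (.shiftZero(.shiftZero(b, i, 1L), j, 1L) -
         .shiftZero(.shiftZero(b, i, 1L), j, -1L) -
         .shiftZero(.shiftZero(b, i, -1L), j, 1L) +
         .shiftZero(.shiftZero(b, i, -1L), j, -1L)) / 4
    }
    out[, , , j] <- mu * lap + ml * (djj + cross)
  }
  vectorField(out, voxelSize = v@voxelSize)
}

## Relative residual ||L v + F|| / ||F|| over the interior (the boundary ring
## carries the clamped v = 0 constraint, not an equation of the system).
.sorResidual <- function(v, F, visc) {
  r <- applyOperator(v, visc)@u + F@u
  d <- dim(F@u)[1:3]
  int <- list(2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1))
  ri <- r[int[[1]], int[[2]], int[[3]], , drop = FALSE]
  Fi <- F@u[int[[1]], int[[2]], int[[3]], , drop = FALSE]
  fn <- sqrt(sum(Fi^2))
  if (fn == 0) return(0)
  sqrt(sum(ri^2)) / fn
}

.dilate6 <- function(mask) {
  m <- mask * 1
  out <- m
  for (ax in 1:3) out <- out + .shiftZero(m, ax, 1L) + .shiftZero(m, ax, -1L)
  out > 0
}

#' Solve the force balance by successive over-relaxation
#'
#' Lexicographic Gauss-Seidel sweeps with over-relaxation on the coupled
#' three-component system, velocity clamped to 0 on the boundary ring. Stops
#' when the interior relative residual `||Lv + F||/||F||` drops below
#' `spec@tolerance`, or at `spec@maxSweeps` with a warning; the result then
#' carries `attr(, "converged") = FALSE`.
#'
#' @param F a [VectorField-class] force.
#' @param visc a [ViscosityParams-class].
#' @param spec a [SolverSpec-class] with kind `"sor"`.
#' @return The velocity [VectorField-class].
#' @export
solveSOR <- function(F, visc = viscosityParams(), spec = solverSpec("sor")) {
  stopifnot(is(F, "VectorField"))
  if (spec@kind != "sor") stop("spec.kind must be 'sor'", call. = FALSE)
  .sorLike(F, visc, spec, active = NULL, activeThreshold = 0)
}

#' Solve the force balance by SOR with adaptive updates (SORA)
#'
#' Same solution contract as [solveSOR()], but sweeps update only an active
#' set of voxels: those whose local force magnitude or last update magnitude
#' exceeds `activeThreshold`, plus their 6-neighbours. The set is re-expanded
#' to the full interior whenever the residual stalls, and the final residual
#' check is always global, so the answer matches plain SOR; only the sweep
#' schedule differs.
#'
#' @inheritParams solveSOR
#' @param spec a [SolverSpec-class] with kind `"sora"`.
#' @param activeThreshold nonnegative activity threshold; 0 makes every voxel
#'   active, reproducing plain SOR.
#' @return The velocity [VectorField-class].
#' @export
solveSORA <- function(F, visc = viscosityParams(), spec = solverSpec("sora"),
                      activeThreshold = spec@activeThreshold) {
  stopifnot(is(F, "VectorField"))
  if (spec@kind != "sora") stop("spec.kind must be 'sora'", call. = FALSE)
  if (activeThreshold < 0) stop("activeThreshold must be >= 0", call. = FALSE)
  if (activeThreshold == 0) {
    .sorLike(F, visc, spec, active = NULL, activeThreshold = 0)
  } else {
    fm <- array(.vecNorm(F@u), dim(F@u)[1:3])
    active <- .dilate6(fm > activeThreshold)
    .sorLike(F, visc, spec, active = active, activeThreshold = activeThreshold)
  }
}

.sorLike <- function(F, visc, spec, active, activeThreshold) {
  d <- dim(F@u)[1:3]
  n <- prod(d)
  if (all(F@u == 0)) {
    out <- vectorField(array(0, dim(F@u)), voxelSize = F@voxelSize)
    attr(out, "converged") <- TRUE
    attr(out, "sweeps") <- 0L
    return(out)
  }
  fm <- array(.vecNorm(F@u), d)
  v <- numeric(3 * n)
  dim(v) <- c(d, 3L)
  chunk <- 8L
  done <- 0L
  converged <- FALSE
  lastRes <- Inf
  vField <- NULL
  while (done < spec@maxSweeps) {
    ns <- min(chunk, spec@maxSweeps - done)
    updmag <- numeric(n)
    act <- if (is.null(active)) logical(0) else as.logical(active)
    cpp_sor_sweeps(v, F@u, d[1], d[2], d[3], visc@mu, visc@lambda,
                   spec@relaxation, as.integer(ns), act, updmag)
    done <- done + ns
    vField <- vectorField(v, voxelSize = F@voxelSize)
    res <- .sorResidual(vField, F, visc)
    if (res <= spec@tolerance) { converged <- TRUE; break }
    if (!is.null(active)) {
      um <- array(updmag, d)
      grown <- .dilate6(um > activeThreshold | fm > activeThreshold)
      # residual stalled: fall back to full-interior sweeps
      if (res > 0.98 * lastRes) grown[] <- TRUE
      active <- grown
    }
    lastRes <- res
  }
  if (is.null(vField)) vField <- vectorField(v, voxelSize = F@voxelSize)
  if (!converged)
    warning(sprintf("solver stopped at maxSweeps = %d with residual above tolerance",
                    spec@maxSweeps), call. = FALSE)
  attr(vField, "converged") <- converged
  attr(vField, "sweeps") <- done
  vField
}

#' Gaussian-kernel approximation of the velocity field
#'
#' Approximates the inverse operator by an isotropic Gaussian convolution of
#' each force component (separable, zero-padded boundaries). This is the
#' fastest and crudest of the solver family: it satisfies no operator
#' residual guarantee and is provided for completeness.
#'
#' @param F a [VectorField-class] force.
#' @param spec a [SolverSpec-class] with kind `"gaussian"`; `gaussianSigma`
#'   is the kernel width in voxels.
#' @return The velocity [VectorField-class].
#' @export
solveGaussian <- function(F, spec = solverSpec("gaussian")) {
  stopifnot(is(F, "VectorField"))
  if (spec@kind != "gaussian") stop("spec.kind must be 'gaussian'", call. = FALSE)
  out <- F@u
  for (c in 1:3)
    out[, , , c] <- .gaussSmooth(F@u[, , , c], rep(spec@gaussianSigma, 3))
  vectorField(out, voxelSize = F@voxelSize)
}

#' Eigenfunction ("viscous kernel") solution in the Fourier domain
#'
#' Solves `L v = -F` exactly for the discretized operator under a periodic
#' boundary assumption. For each discrete frequency w the 3x3 system
#' \deqn{A(w) = \mu \Lambda(w) I + (\mu+\lambda) d(w) d(w)^H}
#' is inverted, where \eqn{\Lambda(w) = \sum_j 2(1 - \cos w_j)} is the
#' discrete-Laplacian symbol and \eqn{d(w)_j = i \sin w_j} the
#' central-difference symbol; the singular zero-frequency mode is set to 0,
#' so the returned solution has zero mean. The rank-one structure of A makes
#' the inversion a closed-form Sherman-Morrison update, applied to every
#' frequency at once.
#'
#' @param F a [VectorField-class] force; grid dimensions must be >= 4.
#' @param visc a [ViscosityParams-class] with mu + lambda > 0.
#' @return The velocity [VectorField-class].
#' @export
solveViscousKernel <- function(F, visc = viscosityParams()) {
  stopifnot(is(F, "VectorField"))
  d <- dim(F@u)[1:3]
  if (any(d < 4L))
    stop("viscous kernel solver needs grid dimensions >= 4", call. = FALSE)
  mu <- visc@mu
  ml <- visc@mu + visc@lambda
  if (ml <= 0) stop("mu + lambda must be > 0", call. = FALSE)
  w <- lapply(d, function(n) 2 * pi * (seq_len(n) - 1) / n)
  s1 <- array(sin(w[[1]]), d)
  s2 <- array(rep(sin(w[[2]]), each = d[1]), d)
  s3 <- array(rep(sin(w[[3]]), each = d[1] * d[2]), d)
  Lam <- array(2 * (1 - cos(w[[1]])), d) +
    array(rep(2 * (1 - cos(w[[2]])), each = d[1]), d) +
    array(rep(2 * (1 - cos(w[[3]])), each = d[1] * d[2]), d)
  Fh <- list(fft(F@u[, , , 1]), fft(F@u[, , , 2]), fft(F@u[, , , 3]))
  # A = mu*Lam*I + (mu+lam) s s^T (real symmetric after d d^H simplifies);
  # Sherman-Morrison gives A^-1 F = (F - c (s.F) s) / (mu*Lam)
  S2 <- s1^2 + s2^2 + s3^2
  sdotF <- s1 * Fh[[1]] + s2 * Fh[[2]] + s3 * Fh[[3]]
  coef <- ml / (mu * Lam + ml * S2)
  zero <- Lam == 0
  denom <- mu * Lam
  denom[zero] <- 1  # avoid 0/0; these modes are zeroed below
  out <- array(0, dim(F@u))
  ss <- list(s1, s2, s3)
  nvox <- prod(d)
  for (c in 1:3) {
    vh <- (Fh[[c]] - coef * sdotF * ss[[c]]) / denom
    vh[zero] <- 0
    out[, , , c] <- Re(fft(vh, inverse = TRUE)) / nvox
  }
  vectorField(out, voxelSize = F@voxelSize)
}

#' Dispatch to the solver selected in a SolverSpec
#'
#' @param F a [VectorField-class] force.
#' @param visc a [ViscosityParams-class].
#' @param spec a [SolverSpec-class]; its `kind` picks the solver.
#' @return The velocity [VectorField-class].
#' @export
solveVelocity <- function(F, visc = viscosityParams(), spec = solverSpec()) {
  switch(spec@kind,
         sor = solveSOR(F, visc, spec),
         sora = solveSORA(F, visc, spec),
         gaussian = solveGaussian(F, spec),
         viscous_kernel = solveViscousKernel(F, visc),
         stop("unknown solver kind"))
}
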