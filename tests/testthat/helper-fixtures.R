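# Fixtures built in code: small phantoms, analytic fields and force patterns.

mkSphere <- function(shape = c(32L, 32L, 32L), radiusMm = 16, voxelMm = 2,
                     smoothMm = 3, peak = 1, seed = 1L) {
  ctr <- (shape - 1) / 2 * voxelMm
  makePhantom(phantomSpec(
    shape = shape, voxelMm = voxelMm,
    structures = list(list(center = ctr, radii = rep(radiusMm, 3), peak = peak)),
    smoothnessMm = smoothMm, noiseSd = 0, seed = seed))
}

constantField <- function(shape, t, voxelMm = 2) {
  u <- array(rep(t, each = prod(shape)), c(shape, 3L))
  displacementField(u, voxelSize = rep(voxelMm, 3))
}

# linear displacement along one axis: u_axis = slope * (index - 1)
linearField <- function(shape, axis, slope, voxelMm = 2) {
  u <- array(0, c(shape, 3L))
  idx <- switch(axis,
    `1` = rep(seq_len(shape[1]) - 1, times = shape[2] * shape[3]),
    `2` = rep(rep(seq_len(shape[2]) - 1, each = shape[1]), times = shape[3]),
    `3` = rep(seq_len(shape[3]) - 1, each = shape[1] * shape[2]))
  u[, , , axis] <- array(slope * idx, shape)
  displacementField(u, voxelSize = rep(voxelMm, 3))
}

gaussBump3 <- function(shape, center, sigma) {
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  array(exp(-((g$x - center[1])^2 + (g$y - center[2])^2 +
              (g$z - center[3])^2) / (2 * sigma^2)), shape)
}

# compact zero-mean dipole force (component 1 and 2 populated)
dipoleForce <- function(shape = c(16L, 16L, 16L), sigma = 1.2) {
  c0 <- (shape + 1) / 2
  Fa <- array(0, c(shape, 3L))
  Fa[, , , 1] <- gaussBump3(shape, c0 + c(-1.5, 0, 0), sigma) -
                 gaussBump3(shape, c0 + c(1.5, 0, 0), sigma)
  Fa[, , , 2] <- 0.5 * (gaussBump3(shape, c0 + c(0, -1.5, 0), sigma) -
                        gaussBump3(shape, c0 + c(0, 1.5, 0), sigma))
  vectorField(Fa)
}

# compact mid-frequency wave packet; carrier away from the near-DC band where
# the clamped and periodic boundary treatments legitimately differ
wavePacketForce <- function(shape = c(16L, 16L, 16L), carrier = 3 * pi / 4,
                            sigma = 2.5) {
  c0 <- (shape + 1) / 2
  env <- gaussBump3(shape, c0, sigma)
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  Fa <- array(0, c(shape, 3L))
  Fa[, , , 1] <- env * array(cos(carrier * (g$x - c0[1])), shape)
  Fa[, , , 2] <- 0.6 * env * array(sin(carrier * (g$y - c0[2])), shape)
  Fa[, , , 3] <- 0.3 * env * array(cos(carrier * (g$z - c0[3])), shape)
  for (c in 1:3) Fa[, , , c] <- Fa[, , , c] - mean(Fa[, , , c])
  vectorField(Fa)
}

randomSmoothForce <- function(shape = c(16L, 16L, 16L), seed = 1L,
                              zeroMean = TRUE) {
  f <- fieldArray(randomSmoothField(shape, 1, rmsMm = 1, sigmaMm = 1.5,
                                    seed = seed))
  if (zeroMean) for (c in 1:3) f[, , , c] <- f[, , , c] - mean(f[, , , c])
  vectorField(f)
}

relL2 <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))

interiorIdx <- function(shape, margin = 2L) {
  lapply(shape, function(n) (1 + margin):(n - margin))
}

sorResidualInterior <- function(v, F, visc) {
  r <- fieldArray(applyOperator(v, visc)) + fieldArray(F)
  d <- dim(fieldArray(F))[1:3]
  int <- interiorIdx(d, 1L)
  ri <- r[int[[1]], int[[2]], int[[3]], , drop = FALSE]
  Fi <- fieldArray(F)[int[[1]], int[[2]], int[[3]], , drop = FALSE]
  sqrt(sum(ri^2)) / sqrt(sum(Fi^2))
}

diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
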