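test_that("force vanishes for a registered pair and for gradient-free subjects", {
  s <- mkSphere(c(16L, 16L, 16L), radiusMm = 8, smoothMm = 2)
  F0 <- computeForce(s, s, zeroField(s))
  expect_true(all(fieldArray(F0) == 0))

  konst <- scalarVolume(array(0.5, c(16, 16, 16)), voxelSize = rep(2, 3))
  tgt <- mkSphere(c(16L, 16L, 16L), radiusMm = 6, smoothMm = 2)
  Fc <- computeForce(konst, tgt, zeroField(konst))
  expect_true(all(fieldArray(Fc) == 0))
})

test_that("the force is the SSD descent direction (numeric gradient oracle)", {
  set.seed(42)
  d <- c(12L, 12L, 12L)
  s <- scalarVolume(fluidvbm:::.gaussSmooth(array(rnorm(prod(d)), d), rep(1.5, 3)))
  tg <- scalarVolume(fluidvbm:::.gaussSmooth(array(rnorm(prod(d)), d), rep(1.5, 3)))
  u <- zeroField(s)
  Fv <- fieldArray(computeForce(s, tg, u))
  h <- 1e-4
  cost <- function(uu) sum((volData(sampleWarped(s, uu)) - volData(tg))^2)
  # probe interior voxels with a meaningful force and compare signs
  cand <- which(abs(Fv[, , , 1]) > quantile(abs(Fv[, , , 1]), 0.99))
  cand <- head(cand, 5)
  for (idx in cand) {
    up <- fieldArray(u); um <- fieldArray(u)
    up[idx] <- h; um[idx] <- -h
    dc <- (cost(displacementField(up)) - cost(displacementField(um))) / (2 * h)
    # descent: numeric dCost/du must oppose the force
    expect_lt(dc * Fv[idx], 0)
  }
})

test_that("the discrete operator annihilates constants and conserves the impulse stencil", {
  visc <- viscosityParams(1, 0.5)
  z <- vectorField(array(0, c(8, 8, 8, 3)))
  expect_true(all(fieldArray(applyOperator(z, visc)) == 0))

  konst <- vectorField(array(rep(c(1, -2, 3), each = 8^3), c(8, 8, 8, 3)))
  Lk <- fieldArray(applyOperator(konst, visc))
  int <- interiorIdx(c(8, 8, 8), 2L)
  expect_true(all(abs(Lk[int[[1]], int[[2]], int[[3]], ]) < 1e-12))

  # unit impulse at the centre of 5^3: stencil weights sum to zero
  imp <- array(0, c(5, 5, 5, 3))
  imp[3, 3, 3, 1] <- 1
  Li <- fieldArray(applyOperator(vectorField(imp), viscosityParams(1, 0)))
  expect_equal(sum(Li), 0, tolerance = 1e-12)
})

test_that("SOR solves the system to tolerance and degenerates to Gauss-Seidel", {
  visc <- viscosityParams(1, 0)
  z <- vectorField(array(0, c(8, 8, 8, 3)))
  v0 <- solveSOR(z, visc, solverSpec("sor"))
  expect_true(all(fieldArray(v0) == 0))
  expect_identical(attr(v0, "sweeps"), 0L)

  F <- randomSmoothForce(c(16L, 16L, 16L), seed = 7L)
  spec <- solverSpec("sor", tolerance = 1e-6, maxSweeps = 3000)
  v <- solveSOR(F, visc, spec)
  expect_true(attr(v, "converged"))
  expect_lt(sorResidualInterior(v, F, visc), 1e-5)

  gs <- solverSpec("sor", tolerance = 1e-6, maxSweeps = 6000, relaxation = 1)
  vgs <- solveSOR(F, visc, gs)
  expect_true(attr(vgs, "converged"))
  expect_lt(relL2(fieldArray(vgs), fieldArray(v)), 1e-4)
  expect_gte(attr(vgs, "sweeps"), attr(v, "sweeps"))
})

test_that("SORA matches SOR and degenerates to it at zero threshold", {
  visc <- viscosityParams(1, 0)
  F <- dipoleForce(c(16L, 16L, 16L))
  sorSpec <- solverSpec("sor", tolerance = 1e-6, maxSweeps = 3000)
  v <- solveSOR(F, visc, sorSpec)
  soraSpec <- solverSpec("sora", tolerance = 1e-6, maxSweeps = 3000)
  va <- solveSORA(F, visc, soraSpec, activeThreshold = 1e-3)
  expect_lt(relL2(fieldArray(va), fieldArray(v)), 1e-4)

  va0 <- solveSORA(F, visc, soraSpec, activeThreshold = 0)
  expect_equal(fieldArray(va0), fieldArray(v), tolerance = 1e-12)

  z <- vectorField(array(0, c(8, 8, 8, 3)))
  expect_true(all(fieldArray(solveSORA(z, visc, soraSpec)) == 0))
})

test_that("the Gaussian solver is a plain separable convolution", {
  spec <- solverSpec("gaussian", gaussianSigma = 1.5)
  z <- vectorField(array(0, c(8, 8, 8, 3)))
  expect_true(all(fieldArray(solveGaussian(z, spec)) == 0))

  d <- c(11L, 11L, 11L)
  imp <- array(0, c(d, 3L))
  imp[6, 6, 6, 1] <- 1
  v <- fieldArray(solveGaussian(vectorField(imp), spec))[, , , 1]
  # oracle: truncated normalized separable kernel
  r <- ceiling(4 * 1.5)
  k <- exp(-((-r):r)^2 / (2 * 1.5^2)); k <- k / sum(k)
  expect_equal(v[6, 6, 6], k[r + 1]^3, tolerance = 1e-12)
  expect_equal(v[7, 6, 6], k[r + 2] * k[r + 1]^2, tolerance = 1e-12)
  expect_equal(which.max(v), (6 - 1) * d[1] * d[2] + (6 - 1) * d[1] + 6)

  # constant force: every voxel equals the constant scaled by the kernel's
  # partial sum inside the grid (zero padding)
  konst <- array(0.8, c(d, 3L))
  vc <- fieldArray(solveGaussian(vectorField(konst), spec))[, , , 1]
  ps <- function(i) sum(k[(max(1, i - r):min(d[1], i + r)) - i + r + 1])
  expect_equal(vc[6, 6, 6], 0.8 * ps(6)^3, tolerance = 1e-9)
  expect_equal(vc[1, 6, 6], 0.8 * ps(1) * ps(6)^2, tolerance = 1e-9)
})

test_that("the Fourier viscous kernel inverts the discretized operator", {
  visc <- viscosityParams(1, 0)
  z <- vectorField(array(0, c(8, 8, 8, 3)))
  expect_true(all(fieldArray(solveViscousKernel(z, visc)) == 0))
  expect_error(solveViscousKernel(vectorField(array(0, c(3, 8, 8, 3))), visc),
               ">= 4")
  expect_error(viscosityParams(1, -2), "mu \\+ lambda")

  F <- randomSmoothForce(c(16L, 16L, 16L), seed = 3L, zeroMean = TRUE)
  v <- solveViscousKernel(F, visc)
  r <- fieldArray(applyOperator(v, visc)) + fieldArray(F)
  int <- interiorIdx(c(16, 16, 16), 2L)
  rel <- sqrt(sum(r[int[[1]], int[[2]], int[[3]], ]^2)) /
         sqrt(sum(fieldArray(F)[int[[1]], int[[2]], int[[3]], ]^2))
  expect_lt(rel, 1e-3)
})

test_that("solvers are linear and agree across kinds in the interior", {
  visc <- viscosityParams(1, 0)
  F1 <- randomSmoothForce(c(16L, 16L, 16L), seed = 11L)
  F2 <- randomSmoothForce(c(16L, 16L, 16L), seed = 12L)
  Fmix <- vectorField(2 * fieldArray(F1) - 0.5 * fieldArray(F2))
  spec <- solverSpec("sor", tolerance = 1e-7, maxSweeps = 5000)
  vmix <- solveSOR(Fmix, visc, spec)
  vlin <- 2 * fieldArray(solveSOR(F1, visc, spec)) -
          0.5 * fieldArray(solveSOR(F2, visc, spec))
  expect_lt(relL2(fieldArray(vmix), vlin), 1e-4)

  kmix <- solveViscousKernel(Fmix, visc)
  klin <- 2 * fieldArray(solveViscousKernel(F1, visc)) -
          0.5 * fieldArray(solveViscousKernel(F2, visc))
  expect_lt(relL2(fieldArray(kmix), klin), 1e-10)

  # dispatcher routes by kind
  expect_equal(fieldArray(solveVelocity(F1, visc, solverSpec("viscous_kernel"))),
               fieldArray(solveViscousKernel(F1, visc)))
})
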