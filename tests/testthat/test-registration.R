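test_that("perturbation field reduces to v at zero displacement and follows the transport term", {
  d <- c(10L, 10L, 10L)
  v <- vectorField(array(rnorm(prod(d) * 3), c(d, 3L)))
  u0 <- displacementField(array(0, c(d, 3L)))
  expect_equal(fieldArray(perturbationField(v, u0)), fieldArray(v))

  z <- vectorField(array(0, c(d, 3L)))
  expect_true(all(fieldArray(perturbationField(z, u0)) == 0))

  # u1 = 0.1 * x1, v = (1,0,0): R1 = 1 - 0.1 at interior voxels
  u <- linearField(d, 1L, 0.1)
  vc <- constantField(d, c(1, 0, 0))
  R <- fieldArray(perturbationField(vectorField(fieldArray(vc)), u))
  expect_true(all(abs(R[2:9, 2:9, 2:9, 1] - 0.9) < 1e-12))
})

test_that("the adaptive time step enforces the displacement cap exactly", {
  d <- c(6L, 6L, 6L)
  R <- array(0, c(d, 3L))
  R[3, 3, 3, ] <- c(3, 4, 0)
  expect_equal(timeStep(vectorField(R), 1), 0.2)
  expect_equal(timeStep(vectorField(array(0, c(d, 3L))), 1), 0)
  expect_error(timeStep(vectorField(R), -1), "positive")

  set.seed(5)
  for (k in 1:5) {
    Rr <- vectorField(array(rnorm(prod(d) * 3), c(d, 3L)))
    dt <- timeStep(Rr, 0.5)
    stepped <- fieldArray(Rr) * dt
    expect_equal(max(sqrt(stepped[, , , 1]^2 + stepped[, , , 2]^2 +
                          stepped[, , , 3]^2)), 0.5, tolerance = 1e-12)
  }
})

test_that("Euler updates are elementwise and additive", {
  d <- c(6L, 6L, 6L)
  u0 <- displacementField(array(0, c(d, 3L)))
  R <- vectorField(array(1, c(d, 3L)))
  expect_equal(fieldArray(eulerUpdate(u0, R, 0)), fieldArray(u0))
  u1 <- eulerUpdate(u0, R, 0.5)
  expect_true(all(fieldArray(u1) == 0.5))
  u2 <- eulerUpdate(eulerUpdate(u0, R, 0.2), R, 0.3)
  expect_equal(fieldArray(u2), fieldArray(u1), tolerance = 1e-15)
})

test_that("Jacobian determinants match analytic affine maps", {
  d <- c(10L, 10L, 10L)
  expect_true(all(volData(jacobianDeterminant(
    displacementField(array(0, c(d, 3L))))) == 1))
  expect_true(all(abs(volData(jacobianDeterminant(
    constantField(d, c(2, -1, 0.5)))) - 1) < 1e-12))

  comp <- jacobianDeterminant(linearField(d, 1L, 0.5))
  expect_true(all(abs(volData(comp)[2:9, , ] - 0.5) < 1e-12))
})

test_that("regridding fires on the determinant threshold and resets the field", {
  d <- c(10L, 10L, 10L)
  s <- mkSphere(c(10L, 10L, 10L), radiusMm = 6, smoothMm = 2)
  st <- regridStack()

  r0 <- maybeRegrid(displacementField(array(0, c(d, 3L))), s, 0.5, st)
  expect_false(r0$regridded)
  expect_length(r0$stack@fields, 0)

  # u1 = 0.6 x1 -> det 0.4 interior: fires at threshold 0.5
  uC <- linearField(d, 1L, 0.6)
  r1 <- maybeRegrid(uC, s, 0.5, st, iteration = 3L)
  expect_true(r1$regridded)
  expect_length(r1$stack@fields, 1)
  expect_identical(r1$stack@events, 3L)
  expect_true(all(fieldArray(r1$u) == 0))
  expect_equal(volData(r1$subject), volData(sampleWarped(s, uC)))

  # milder compression, det 0.6: no regrid
  r2 <- maybeRegrid(linearField(d, 1L, 0.4), s, 0.5, st)
  expect_false(r2$regridded)
  expect_error(maybeRegrid(uC, s, 1.5, st), "\\(0, 1\\)")
})

test_that("displacement composition has identity elements and the translation group", {
  d <- c(12L, 12L, 12L)
  z <- displacementField(array(0, c(d, 3L)))
  u <- randomSmoothField(d, 1, rmsMm = 1, sigmaMm = 2, seed = 4L)
  expect_equal(fieldArray(composeDisplacements(z, u)), fieldArray(u))
  expect_equal(fieldArray(composeDisplacements(u, z)), fieldArray(u))

  # away from the boundary (where the inner field reads background 0) two
  # constant translations compose to their sum
  t1 <- constantField(d, c(1, 0.5, 0)); t2 <- constantField(d, c(-0.5, 1, 2))
  comp <- fieldArray(composeDisplacements(t1, t2))[4:9, 4:9, 4:9, ]
  expected <- fieldArray(constantField(d, c(0.5, 1.5, 2)))[4:9, 4:9, 4:9, ]
  expect_equal(comp, expected, tolerance = 1e-12)
})

test_that("one composed warp matches sequential warping within interpolation error", {
  d <- c(16L, 16L, 16L)
  vol <- mkSphere(c(16L, 16L, 16L), radiusMm = 9, smoothMm = 3)
  u1 <- randomSmoothField(d, 2, rmsMm = 2, sigmaMm = 6, seed = 21L)
  u2 <- randomSmoothField(d, 2, rmsMm = 2, sigmaMm = 6, seed = 22L)
  seq2 <- sampleWarped(sampleWarped(vol, u1), u2)
  onc <- sampleWarped(vol, composeDisplacements(u2, u1))
  expect_lt(max(abs(volData(seq2) - volData(onc))), 0.05)
})

test_that("registering a volume to itself is stable", {
  s <- mkSphere(c(16L, 16L, 16L), radiusMm = 9, smoothMm = 3)
  cfg <- registrationConfig(solver = solverSpec("viscous_kernel"),
                            maxIterations = 10)
  r <- registerFluid(s, s, cfg)
  expect_true(all(abs(costTrace(r) - costTrace(r)[1]) <= 1e-9 * max(1, costTrace(r)[1])))
  expect_lt(max(abs(fieldArray(totalField(r)))), 1e-3)
  expect_identical(r@convergedReason, "step_tolerance")
})

test_that("the registration loop descends the cost and preserves topology", {
  S <- mkSphere(c(24L, 24L, 24L), radiusMm = 12, smoothMm = 3)
  Tg <- mkSphere(c(24L, 24L, 24L), radiusMm = 9, smoothMm = 3)
  cfg <- registrationConfig(solver = solverSpec("viscous_kernel"),
                            maxIterations = 15, maxStep = 0.3)
  r <- registerFluid(S, Tg, cfg)
  ct <- costTrace(r)
  expect_true(all(diff(ct) <= 0))
  expect_lt(ct[length(ct)], ct[1])
  jd <- volData(jacobianVolume(r))
  expect_gt(min(jd), 0)
  expect_lt(min(jd), 1)  # compression inside the shrinkage zone

  expect_error(registerFluid(S, mkSphere(c(16L, 16L, 16L))), "dimension mismatch")
  bad <- scalarVolume(array(c(NaN, rep(0, 24^3 - 1)), c(24, 24, 24)))
  expect_error(registerFluid(bad, bad, cfg), "finite")
})
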