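test_that("FWHM smoothing preserves constants and halves at the nominal radius", {
  d <- c(16L, 16L, 16L)
  konst <- scalarVolume(array(0.6, d), voxelSize = rep(2, 3))
  sm <- volData(smoothFWHM(konst, 8))
  # deep interior (farther from the edge than the kernel radius) is exact
  expect_true(all(abs(sm[8:9, 8:9, 8:9] - 0.6) < 1e-6))
  # boundary attenuates under zero padding
  expect_lt(sm[1, 8, 8], 0.6)

  imp <- array(0, d); imp[8, 8, 8] <- 1
  for (fwhm in c(6, 8, 10)) {
    s <- volData(smoothFWHM(scalarVolume(imp, voxelSize = rep(2, 3)), fwhm))
    hw <- fwhm / 2 / 2  # half-width in voxels at 2 mm
    # exact on-axis ratio at integer radii; interpolate around hw otherwise
    r1 <- floor(hw); r2 <- ceiling(hw)
    v1 <- s[8 + r1, 8, 8] / s[8, 8, 8]
    v2 <- s[8 + r2, 8, 8] / s[8, 8, 8]
    expect_true(v2 <= 0.5 + 1e-9 && v1 >= 0.5 - 1e-9)
    if (r1 == r2) expect_equal(v1, 0.5, tolerance = 1e-9)
  }
})

test_that("the relative threshold mask intersects per-image thresholds", {
  d <- c(10L, 10L, 10L)
  konst <- scalarVolume(array(0.5, d), voxelSize = rep(2, 3))
  m <- relativeThresholdMask(list(konst, konst), 0.2)
  expect_true(all(volData(m) == 1))

  holed <- volData(konst); holed[5, 5, 5] <- 0
  m2 <- relativeThresholdMask(list(konst, scalarVolume(holed, voxelSize = rep(2, 3))), 0.2)
  expect_equal(volData(m2)[5, 5, 5], 0)
  expect_equal(sum(volData(m2) == 0), 1)

  expect_error(relativeThresholdMask(list(), 0.2), "non-empty")

  # phantom cohort: mask recovers the tissue support
  co <- makeCohort(nControls = 3, nPatients = 3, atrophyFraction = 0,
                   shape = c(24L, 24L, 24L), jitterMm = 0, noiseSd = 0.01,
                   seed = 2L)
  msk <- volData(relativeThresholdMask(co$maps, 0.2)) > 0
  support <- volData(co$phantom) > 0.05
  expect_gt(diceCoef(msk, support), 0.95)
})

test_that("the two-group GLM matches the noncentral-t model and absorbs constants", {
  d <- c(2L, 2L, 2L)
  n1 <- 8L; n2 <- 8L; n <- n1 + n2
  des <- groupDesign(sprintf("s%d", 1:n), rep(c("control", "patient"), c(n1, n2)),
                     tiv = rnorm(n, 1.5e6, 1e5))
  mask <- scalarVolume(array(1, d), voxelSize = rep(2, 3))

  # identical values at a voxel: flagged t = 0
  flat <- lapply(1:n, function(i) scalarVolume(array(0.4, d), voxelSize = rep(2, 3)))
  sflat <- glmTwoGroupT(flat, des, mask)
  expect_true(all(volData(tMap(sflat)) == 0))
  expect_true(all(volData(sflat@flagged) == 1))
  expect_identical(statDof(sflat), n - 3L)

  # Monte-Carlo: mean t over simulations matches the noncentral-t mean
  delta <- 1; sigma <- 1
  nsim <- 800
  set.seed(31)
  # TIV orthogonal to group (same values in both groups) so the closed-form
  # noncentrality delta / (sigma sqrt(1/n1 + 1/n2)) is exact for this design
  tivs <- rep(rnorm(n1, 1.5e6, 1e5), 2)
  desMC <- groupDesign(sprintf("s%d", 1:n), rep(c("control", "patient"), c(n1, n2)), tivs)
  ts <- replicate(nsim, {
    y <- rnorm(n, sd = sigma) - delta * (desMC@group == "patient")
    maps <- lapply(y, function(v) scalarVolume(array(v, d), voxelSize = rep(2, 3)))
    volData(tMap(glmTwoGroupT(maps, desMC, mask)))[1, 1, 1]
  })
  ncp <- delta / (sigma * sqrt(1 / n1 + 1 / n2))
  df <- n - 3
  expectedMean <- ncp * sqrt(df / 2) * gamma((df - 1) / 2) / gamma(df / 2)
  expect_lt(abs(mean(ts) - expectedMean) / expectedMean, 0.05)

  # adding a constant to every subject's map leaves t unchanged
  co <- makeCohort(3, 3, atrophyFraction = 0, shape = c(12L, 12L, 12L), seed = 8L)
  msk <- relativeThresholdMask(co$maps, 0.2)
  t1 <- volData(tMap(glmTwoGroupT(co$maps, co$design, msk)))
  shifted <- lapply(co$maps, function(m)
    scalarVolume(volData(m) + 0.37, voxelSize = voxelSize(m)))
  t2 <- volData(tMap(glmTwoGroupT(shifted, co$design, msk)))
  expect_equal(t2, t1, tolerance = 1e-8)

  # constant TIV column is dropped with a warning, dof adjusts
  desConst <- groupDesign(sprintf("s%d", 1:n), rep(c("control", "patient"), c(n1, n2)),
                          tiv = rep(1.5e6, n))
  expect_warning(sConst <- glmTwoGroupT(flat, desConst, mask), "constant")
  expect_identical(statDof(sConst), n - 2L)
})

test_that("the permutation FWE threshold matches exact enumeration and is deterministic", {
  d <- c(3L, 3L, 3L)
  n <- 6L
  set.seed(77)
  maps <- lapply(1:n, function(i)
    scalarVolume(array(rnorm(prod(d), mean = 0.5, sd = 0.1), d), voxelSize = rep(2, 3)))
  tivs <- rnorm(n, 1.5e6, 1e5)
  des <- groupDesign(sprintf("s%d", 1:n), rep(c("control", "patient"), each = 3), tivs)
  mask <- scalarVolume(array(1, d), voxelSize = rep(2, 3))

  thr <- permutationFWEThreshold(maps, des, mask, nPerm = 100, alpha = 0.05, seed = 1)
  expect_equal(thr,
               permutationFWEThreshold(maps, des, mask, nPerm = 100, alpha = 0.05, seed = 1))

  # independent oracle: enumerate all choose(6,3) labelings with lm()
  Y <- sapply(maps, function(m) as.vector(volData(m)))
  tivC <- tivs - mean(tivs)
  maxts <- apply(combn(n, 3), 2, function(idx) {
    g <- as.numeric(seq_len(n) %in% idx)
    tv <- apply(Y, 1, function(y) {
      fit <- summary(lm(y ~ g + tivC))
      -coef(fit)["g", "t value"]
    })
    max(tv)
  })
  expect_equal(thr, as.numeric(quantile(maxts, 0.95, type = 1)), tolerance = 1e-8)

  # degenerate alpha = 1 passes everything
  thrAll <- permutationFWEThreshold(maps, des, mask, nPerm = 100, alpha = 1, seed = 1)
  expect_equal(thrAll, min(maxts), tolerance = 1e-8)
})

test_that("thresholding honours the extent parameter", {
  d <- c(12L, 12L, 12L)
  mask <- scalarVolume(array(1, d), voxelSize = rep(2, 3))
  zero <- scalarVolume(array(0, d), voxelSize = rep(2, 3))
  sm <- new("StatMap", tValues = zero, dof = 13L, mask = mask, flagged = zero,
            thresholdUsed = NA_real_, correction = "uncorrected")
  expect_true(all(volData(thresholdMap(sm, "unc001")) == 0))

  tv <- array(0, d)
  tv[6, 6, 6] <- 10                  # single suprathreshold voxel
  tv[2:3, 2:5, 2][] <- 10            # a cluster of 8 voxels (2 x 4 x 1)
  sm2 <- new("StatMap", tValues = scalarVolume(tv, voxelSize = rep(2, 3)),
             dof = 13L, mask = mask, flagged = zero,
             thresholdUsed = NA_real_, correction = "uncorrected")
  sig0 <- volData(thresholdMap(sm2, "unc001", extentK = 0))
  expect_equal(sig0[6, 6, 6], 1)
  expect_equal(sum(sig0), 9)
  sig20 <- volData(thresholdMap(sm2, "unc001", extentK = 20))
  expect_true(all(sig20 == 0))
  sig5 <- volData(thresholdMap(sm2, "unc001", extentK = 5))
  expect_equal(sum(sig5), 8)  # the 8-voxel cluster survives, the singleton not

  expect_error(thresholdMap(sm2, "fwe05"), "fweThreshold")
  sigF <- thresholdMap(sm2, "fwe05", fweThreshold = 11)
  expect_true(all(volData(sigF) == 0))
})
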