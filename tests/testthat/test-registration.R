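randomLandmarks <- function(sd = 20) {
  repeat {
    P <- matrix(stats::rnorm(18, sd = sd), 6, 3)
    ok <- tryCatch({ LandmarkSet(P); TRUE }, error = function(e) FALSE)
    if (ok) return(P)
  }
}

test_that("landmark alignment recovers exact transforms to 1e-9", {
  set.seed(31)
  for (i in 1:25) {
    P <- randomLandmarks()
    truth <- randomRigidTransform(180, 40)
    Q <- applyTransform(truth, P)
    fit <- landmarkAlign(LandmarkSet(P), LandmarkSet(Q))
    expect_lt(rotationDistanceDeg(fit$transform, truth), 1e-9)
    expect_lt(translationDistanceMm(fit$transform, truth), 1e-9)
    expect_lt(fit$rmsdMm, 1e-9)
  }
  lm <- LandmarkSet(randomLandmarks())
  self <- landmarkAlign(lm, lm)
  expect_equal(rotation(self$transform), diag(3), tolerance = 1e-12)
  expect_equal(self$rmsdMm, 0, tolerance = 1e-12)
})

test_that("noisy landmark alignment matches an iterative least-squares oracle", {
  set.seed(32)
  ssd <- function(R, t, P, Q) sum((sweep(P %*% t(R), 2, t, "+") - Q)^2)
  for (i in 1:5) {
    P <- randomLandmarks()
    truth <- randomRigidTransform(60, 20)
    Q <- applyTransform(truth, P) + matrix(rnorm(18, sd = 0.5), 6, 3)
    fit <- landmarkAlign(LandmarkSet(P), LandmarkSet(Q))
    ours <- ssd(rotation(fit$transform), translation(fit$transform), P, Q)
    # independent oracle: general optimiser over axis-angle + translation,
    # multi-start
    obj <- function(par) {
      th <- sqrt(sum(par[1:3]^2))
      R <- if (th < 1e-12) diag(3) else rotationAboutAxis(par[1:3], th * 180 / pi)
      ssd(R, par[4:6], P, Q)
    }
    best <- Inf
    for (s in 1:8) {
      start <- c(rnorm(3, sd = 0.5), rnorm(3, sd = 5))
      o <- stats::optim(start, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
      best <- min(best, o$value)
    }
    expect_lt(ours, best + 1e-6)
  }
})

test_that("landmark alignment SSD is not beaten by random rigid candidates", {
  set.seed(33)
  for (i in 1:20) {
    P <- randomLandmarks()
    Q <- applyTransform(randomRigidTransform(90, 30), P) +
      matrix(rnorm(18, sd = 0.5), 6, 3)
    fit <- landmarkAlign(LandmarkSet(P), LandmarkSet(Q))
    ours <- sum((applyTransform(fit$transform, P) - Q)^2)
    for (k in 1:200) {
      cand <- if (k <= 100) randomRigidTransform(180, 50)
              else perturbTransform(fit$transform, 5, 1)
      expect_gte(sum((applyTransform(cand, P) - Q)^2), ours - 1e-12)
    }
  }
})

test_that("collinear landmarks are rejected", {
  P <- cbind(1:6, 2 * (1:6), -1 * (1:6))
  expect_error(LandmarkSet(P), "collinear")
})

test_that("surface clouds sample the mask surface deterministically", {
  v <- cubeVolume(15, 0.2)
  cloud <- surfaceCloud(v, 2000, seed = 5)
  expect_identical(dim(cloud), c(2000L, 3L))
  expect_identical(cloud, surfaceCloud(v, 2000, seed = 5))
  expect_false(identical(cloud, surfaceCloud(v, 2000, seed = 6)))
  # all sampled points lie within half a voxel of the cube's surface
  half <- 15 * 0.2 / 2
  ctr <- colMeans(apply(cloud, 2, range))
  rel <- abs(sweep(cloud, 2, ctr))
  distToSurface <- abs(apply(rel, 1, max) - half)
  expect_lt(max(distToSurface), 0.1 + 1e-9)
  # more points than the mesh has faces still works (with replacement)
  tiny <- cubeVolume(2, 0.4)
  expect_identical(nrow(surfaceCloud(tiny, 5000, seed = 1)), 5000L)
})

test_that("ICP is a no-op on already-aligned identical clouds", {
  set.seed(41)
  cloud <- matrix(rnorm(900, sd = 10), ncol = 3)
  out <- icpRefine(cloud, cloud, identityTransform(), icpConfig(maxIter = 50))
  expect_lt(out$diagnostics$finalMeanDistanceMm, 1e-9)
  expect_lt(rotationAngleDeg(rotation(out$transform)), 1e-9)
  expect_identical(out$diagnostics$terminationReason, "tolerance")
})

test_that("ICP rejects non-finite input", {
  cloud <- matrix(rnorm(30), ncol = 3)
  bad <- cloud; bad[1] <- NaN
  expect_error(icpRefine(bad, cloud), "non-finite")
})

test_that("ICP recovers a perturbed pose on phantom surfaces", {
  set.seed(43)
  transform <- randomRigidTransform(25, 15)
  case <- generateCase(smallPhantomParams(trueTransform = transform, seed = 7L))
  src <- surfaceCloud(case@mriVolume, 4000, seed = 1)
  dst <- surfaceCloud(case@ctVolume, 24000, seed = 2)
  init <- perturbTransform(case@truth, 10, 5)
  out <- icpRefine(src, dst, init)
  expect_lt(rotationDistanceDeg(out$transform, case@truth), 2)
  expect_lt(translationDistanceMm(out$transform, case@truth), 1)
  md <- out$diagnostics$iterations
  for (ph in unique(md$phase))
    expect_true(all(diff(md$rmsDistanceMm[md$phase == ph]) <= 1e-12))
})

test_that("ICP flags convergence to a wrong basin instead of silently succeeding", {
  set.seed(44)
  # near-symmetric cuboid cloud; initialisation 90 degrees off lands in a
  # local optimum whose residual betrays the mismatch
  u <- matrix(runif(6000), ncol = 3)
  cloud <- sweep(u, 2, c(20, 10, 4), "*")
  init <- RigidTransform(rotationAboutAxis("z", 90), c(0, 0, 0))
  out <- icpRefine(cloud, cloud, init, icpConfig(maxIter = 200))
  expect_gt(rotationAngleDeg(rotation(out$transform)), 45)  # stuck far away
  # identical clouds align with zero residual, so a clearly nonzero residual
  # flags the wrong basin
  expect_gt(out$diagnostics$finalMeanDistanceMm, 0.2)
})
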