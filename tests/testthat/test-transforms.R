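test_that("rigid transform algebra satisfies the group laws", {
  expect_equal(rotation(identityTransform()), diag(3))
  # analytic rotation: 90 deg about z maps (1,0,0) to (0,1,0)
  T90 <- RigidTransform(rotationAboutAxis("z", 90))
  expect_equal(as.numeric(applyTransform(T90, matrix(c(1, 0, 0), 1))),
               c(0, 1, 0), tolerance = 1e-12)
  set.seed(42)
  for (i in 1:20) {
    a <- randomRigidTransform(180, 50)
    b <- randomRigidTransform(180, 50)
    ab <- composeTransform(a, b)          # closure: passes validity
    expect_s4_class(ab, "RigidTransform")
    ident <- composeTransform(a, invertTransform(a))
    expect_lt(max(abs(rotation(ident) - diag(3))), 1e-9)
    expect_lt(max(abs(translation(ident))), 1e-9)
    # compose is "a after b"
    p <- matrix(rnorm(9), 3)
    expect_equal(applyTransform(ab, p),
                 applyTransform(a, applyTransform(b, p)), tolerance = 1e-9)
  }
})

test_that("transforms preserve pairwise distances", {
  set.seed(7)
  cloud <- matrix(rnorm(150, sd = 20), ncol = 3)
  transform <- randomRigidTransform(180, 100)
  d0 <- dist(cloud)
  d1 <- dist(applyTransform(transform, cloud))
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("rotation angles are recovered from matrices", {
  expect_equal(rotationAngleDeg(rotationAboutAxis(c(1, 2, 3), 17)), 17,
               tolerance = 1e-9)
  a <- RigidTransform(rotationAboutAxis("y", 30), c(1, 2, 3))
  b <- RigidTransform(rotationAboutAxis("y", 55), c(1, 2, 7))
  expect_equal(rotationDistanceDeg(a, b), 25, tolerance = 1e-9)
  expect_equal(translationDistanceMm(a, b), 4, tolerance = 1e-12)
})

test_that("invalid rotations are rejected by validity", {
  expect_error(RigidTransform(diag(c(1, 1, -1))), "determinant")
  expect_error(RigidTransform(matrix(1, 3, 3)), "orthonormal")
})

test_that("transform methods act on meshes and landmark sets alike", {
  m <- boxMesh(4, 2, 1)
  transform <- RigidTransform(rotationAboutAxis("x", 45), c(1, -2, 3))
  m2 <- applyTransform(transform, m)
  expect_equal(vertices(m2),
               applyTransform(transform, vertices(m)))
  expect_identical(faces(m2), faces(m))
  lm <- LandmarkSet(matrix(rnorm(18), 6, 3))
  lm2 <- applyTransform(transform, lm, frameId = "CT")
  expect_identical(frameId(lm2), "CT")
  expect_equal(coords(lm2), applyTransform(transform, coords(lm)))
})
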