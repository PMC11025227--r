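test_that("voxel volume bookkeeping is definitional", {
  v <- cubeVolume(10, 0.2)
  expect_equal(cartilageVolume(v), sum(voxels(v) == 1L) * 0.2^3)
  expect_equal(cartilageVolume(v), 8)  # 1000 voxels x 0.008 mm^3
})

test_that("resampling through the identity onto the same grid is lossless", {
  v <- cubeVolume(8, 0.4)
  out <- resampleVolume(v, identityTransform(), v)
  expect_identical(voxels(out), voxels(v))
})

test_that("cross-resolution resampling conserves volume within a boundary shell", {
  v <- cubeVolume(10, 0.4)  # 4 mm cube
  d <- as.integer(dim(voxels(v)) * 2)
  target <- LabelVolume(array(0L, d), 0.2,
                        originMm = originMm(v) - 0.1, frameId = frameId(v))
  out <- resampleVolume(v, identityTransform(), target)
  bound <- meshArea(maskToMesh(v)) * 0.2
  expect_lt(abs(cartilageVolume(out) - cartilageVolume(v)), bound)
  expect_true(all(unique(as.vector(voxels(out))) %in% unique(as.vector(voxels(v)))))
})

test_that("translation by exactly one voxel pitch shifts indices by one", {
  v <- cubeVolume(6, 0.4)
  shift <- RigidTransform(translation = c(0.4, 0, 0))
  out <- resampleVolume(v, shift, v)
  expect_identical(voxels(out)[2:dim(voxels(v))[1], , ],
                   voxels(v)[1:(dim(voxels(v))[1] - 1), , ])
})

test_that("resampling with no overlap warns and returns background", {
  v <- cubeVolume(6, 0.4)
  far <- RigidTransform(translation = c(1000, 0, 0))
  expect_warning(out <- resampleVolume(v, far, v), "no overlap")
  expect_true(all(voxels(out) == 0L))
})

test_that("mask meshes are watertight and enclose the voxel volume", {
  v <- cubeVolume(20, 0.2)  # 4 mm cube, 64 mm^3
  m <- maskToMesh(v)
  expect_equal(eulerCharacteristic(m), 2)
  expect_lt(abs(meshVolume(m) / 64 - 1), 0.05)
  s <- sphereVolume(5, 0.2)
  ms <- maskToMesh(s)
  expect_equal(eulerCharacteristic(ms), 2)
  expect_lt(abs(meshVolume(ms) / (4 / 3 * pi * 125) - 1), 0.02)
  expect_identical(frameId(ms), frameId(s))
})

test_that("meshing an absent label is an explicit error", {
  v <- cubeVolume(5)
  expect_error(maskToMesh(v, label = 3L), "empty mask")
})

test_that("analytic sphere mesh matches closed-form volume and area", {
  m <- meshSphere(5)
  expect_equal(eulerCharacteristic(m), 2)
  expect_lt(abs(meshVolume(m) / (4 / 3 * pi * 125) - 1), 0.01)
  expect_lt(abs(meshArea(m) / (4 * pi * 25) - 1), 0.01)
})

test_that("cartilage volume is invariant under rigid resampling within a shell", {
  s <- sphereVolume(4, 0.2)
  set.seed(11)
  transform <- randomRigidTransform(30, 1)
  d <- dim(voxels(s))
  target <- LabelVolume(array(0L, d + 10L), 0.2,
                        originMm = originMm(s) - 1, frameId = "CT")
  out <- resampleVolume(s, transform, target)
  bound <- meshArea(maskToMesh(s)) * 0.2
  expect_lt(abs(cartilageVolume(out) - cartilageVolume(s)), bound)
})
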