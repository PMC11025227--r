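sil <- function(m) BinarySilhouette(m, 0.1)

test_that("2D Dice follows the definitional count quotient", {
  a <- matrix(FALSE, 4, 4); b <- a
  a[1, 1:4] <- TRUE          # |A| = 4
  b[1, 1:2] <- TRUE          # |B| = 2, overlap 2
  r <- dsc2d(sil(a), sil(b))
  expect_equal(dsc(r), 2 * 2 / (4 + 2), tolerance = 1e-15)
  expect_equal(r@intersectionCount, 2)
  expect_equal(dsc(dsc2d(sil(a), sil(a))), 1)
  disjoint <- matrix(FALSE, 4, 4); disjoint[4, 4] <- TRUE
  expect_equal(dsc(dsc2d(sil(a), sil(disjoint))), 0)
  expect_equal(dsc(dsc2d(sil(a), sil(b))), dsc(dsc2d(sil(b), sil(a))))
})

test_that("degenerate or mismatched silhouettes are rejected", {
  e <- matrix(FALSE, 3, 3)
  expect_error(dsc2d(sil(e), sil(e)), "0/0")
  a <- matrix(TRUE, 3, 3)
  expect_error(dsc2d(sil(a), BinarySilhouette(matrix(TRUE, 4, 4), 0.1)), "shape")
  expect_error(dsc2d(sil(a), BinarySilhouette(a, 0.2)), "scale")
})

test_that("3D Dice is exact on identical volumes and degrades under shift", {
  v <- cubeVolume(12, 0.2)
  expect_equal(dsc(dsc3d(v, v, identityTransform())), 1)
  # 5 mm-thick slab phantom shifted by 1 mm against itself
  slab <- array(0L, c(60, 60, 35)); slab[6:55, 6:55, 6:30] <- 1L
  sv <- LabelVolume(slab, 0.2)
  shifted <- dsc3d(sv, sv, RigidTransform(translation = c(1, 0, 0)))
  expect_lt(dsc(shifted), 1)
  more <- dsc3d(sv, sv, RigidTransform(translation = c(2, 0, 0)))
  expect_lt(dsc(more), dsc(shifted))
  empty <- LabelVolume(array(0L, c(4, 4, 4)), 0.2)
  expect_error(dsc3d(empty, v, identityTransform()), "empty foreground")
})

test_that("Dice decreases monotonically as a mask is eroded shell by shell", {
  full <- cubeVolume(16, 0.2, pad = 1)
  dscs <- vapply(0:3, function(k) {
    n <- 16 - 2 * k
    d <- dim(voxels(full))
    v <- array(0L, d)
    lo <- 2 + k; hi <- lo + n - 1
    v[lo:hi, lo:hi, lo:hi] <- 1L
    dsc(dsc3d(LabelVolume(v, 0.2), full, identityTransform()))
  }, numeric(1))
  expect_equal(dscs[1], 1)
  expect_true(all(diff(dscs) < 0))
})

test_that("cartilage volume arithmetic and absent-label warning", {
  v <- sphereVolume(3, 0.2)
  expect_equal(cartilageVolume(v), sum(voxels(v)) * 0.008)
  expect_warning(z <- cartilageVolume(v, label = 9L), "absent")
  expect_equal(z, 0)
})

test_that("Pearson correlation matches its definitional formula", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  r <- pearsonR(x, y)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r$r, manual, tolerance = 1e-12)
  tval <- manual * sqrt(3 / (1 - manual^2))
  expect_equal(r$pValue, 2 * stats::pt(-abs(tval), df = 3), tolerance = 1e-12)
  expect_equal(pearsonR(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonR(x, -x)$r, -1)
})

test_that("Pearson correlation is invariant under positive affine rescaling", {
  set.seed(51)
  x <- rnorm(20); y <- rnorm(20) + 0.5 * x
  expect_equal(pearsonR(3.7 * x + 11, y)$r, pearsonR(x, y)$r, tolerance = 1e-12)
  expect_equal(pearsonR(x, 0.2 * y - 4)$r, pearsonR(x, y)$r, tolerance = 1e-12)
})

test_that("undefined correlations are errors, not numbers", {
  expect_error(pearsonR(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearsonR(1:3, 1:4), "lengths")
  expect_error(pearsonR(1:2, 2:3), "at least 3")
})
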