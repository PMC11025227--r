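test_that("case generation is bit-reproducible under a seed", {
  p <- smallPhantomParams(seed = 123L, boundaryNoiseSdMm = 0.15)
  a <- generateCase(p)
  b <- generateCase(p)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("the MRI model under-represents volume exactly by the thickness bias", {
  for (beta in c(0.5, 0.7, 0.9, 1.0)) {
    case <- generateCase(smallPhantomParams(thicknessBias = beta,
                                            boundaryNoiseSdMm = 0, seed = 3L))
    ratio <- cartilageVolume(case@mriVolume) / cartilageVolume(case@ctVolume)
    expect_lt(abs(ratio - beta), 0.08)
    if (beta <= 0.9)
      expect_gt(cartilageVolume(case@ctVolume), cartilageVolume(case@mriVolume))
  }
})

test_that("landmarks correspond exactly across frames before measurement noise", {
  set.seed(9)
  transform <- randomRigidTransform(25, 15)
  case <- generateCase(smallPhantomParams(trueTransform = transform,
                                          landmarkNoiseSdMm = 0, seed = 4L))
  mapped <- applyTransform(case@truth, coords(case@landmarksMRI))
  expect_lt(max(abs(mapped - coords(case@landmarksCT))), 1e-9)
  noisy <- generateCase(smallPhantomParams(trueTransform = transform,
                                           landmarkNoiseSdMm = 0.5, seed = 4L))
  mapped2 <- applyTransform(noisy@truth, coords(noisy@landmarksMRI))
  expect_gt(max(abs(mapped2 - coords(noisy@landmarksCT))), 0.05)
})

test_that("cartilage volume strictly decreases with growing defect burden", {
  vols <- vapply(c(0, 2, 4), function(r) {
    defects <- if (r > 0) matrix(c(-9, 0, r), 1) else matrix(numeric(0), 0, 3)
    cartilageVolume(generateCase(smallPhantomParams(defects = defects,
                                                    seed = 5L))@ctVolume)
  }, numeric(1))
  expect_true(all(diff(vols) < 0))
})

test_that("defects swallowing the whole cartilage are a degenerate-case error", {
  expect_error(generateCase(smallPhantomParams(
    defects = matrix(c(0, 0, 60), 1), seed = 1L)), "degenerate")
})

test_that("the photograph footprint matches the CT-volume footprint", {
  case <- generateCase(smallPhantomParams(boundaryNoiseSdMm = 0, seed = 6L))
  footprint <- sum(apply(voxels(case@ctVolume), c(1, 2), max)) *
    spacingMm(case@ctVolume)^2
  photoArea <- sum(pixels(case@photo)) * mmPerPx(case@photo)^2
  expect_lt(abs(photoArea / footprint - 1), 0.02)
})

test_that("interior defects survive into the photograph as holes", {
  case <- generateCase(smallPhantomParams(defects = matrix(c(-9, 0, 2.5), 1),
                                          seed = 6L))
  px <- pixels(case@photo)
  # the defect disk centre must be background while the patch around it is not
  m <- function(x, y) {
    col <- round(x / mmPerPx(case@photo) + 0.5)
    row <- round(y / mmPerPx(case@photo) + 0.5)
    px[row, col]
  }
  x0 <- -9 - (-24)  # defect centre relative to the field origin (margin 6 mm)
  y0 <- 0 - (-19)
  expect_false(m(x0, y0))
  expect_true(m(x0 + 4, y0))
})

test_that("cohorts are reproducible, sized-checked, and draw distinct transforms", {
  expect_error(generateCohort(1), "n must be >= 2")
  co <- generateCohort(3, paramRanges = list(), seed = 77L)
  co2 <- generateCohort(3, paramRanges = list(), seed = 77L)
  expect_identical(serialize(co, NULL), serialize(co2, NULL))
  angs <- vapply(co, function(cs) rotationAngleDeg(rotation(cs@truth)), numeric(1))
  expect_equal(length(unique(round(angs, 6))), 3)
  betas <- vapply(co, function(cs) cs@params@thicknessBias, numeric(1))
  expect_true(all(betas >= 0.5 & betas <= 0.9))
})
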