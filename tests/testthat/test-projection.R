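test_that("PCA rectification of an axis-aligned box is a signed permutation", {
  m <- boxMesh(8, 4, 2)
  out <- pcaRectify(m)
  R <- rotation(out$transform)
  expect_equal(sort(apply(abs(R), 1, max)), c(1, 1, 1), tolerance = 1e-9)
  expect_equal(abs(R), diag(3), tolerance = 1e-9)  # already axis-aligned
})

test_that("PCA rectification undoes a known rotation up to axis signs", {
  m <- boxMesh(8, 4, 2)
  Rknown <- rotationAboutAxis(c(1, 2, 1), 37)
  rotated <- applyTransform(RigidTransform(Rknown, c(5, -3, 2)), m)
  out <- pcaRectify(rotated)
  W <- vertices(out$mesh)
  C <- cov(W)
  expect_lt(max(abs(C - diag(diag(C)))), 1e-6 * sum(diag(C)))
  expect_lt(max(abs(colMeans(W))), 1e-9)
  # variance ordering x >= y >= z
  expect_true(all(diff(diag(C)) <= 1e-9))
  # net rotation is a signed permutation of the known rotation
  P <- rotation(out$transform) %*% Rknown
  expect_equal(abs(P), diag(3), tolerance = 1e-6)
})

test_that("PCA rectification is idempotent and rejects coplanar input", {
  case <- generateCase(smallPhantomParams(seed = 2L))
  mesh <- maskToMesh(case@mriVolume)
  r1 <- pcaRectify(mesh)
  r2 <- pcaRectify(r1$mesh)
  expect_lt(rotationAngleDeg(rotation(r2$transform)), 1e-4)
  expect_lt(max(abs(translation(r2$transform))), 1e-6)
  flat <- SurfaceMesh(cbind(matrix(rnorm(20), 10), 0), matrix(c(1, 2, 3), 1))
  expect_error(pcaRectify(flat), "coplanar")
})

test_that("rendered sphere silhouette area matches the analytic disc", {
  m <- meshSphere(5)
  sil <- renderSilhouette(m, cameraSpec(mmPerPx = 0.05))
  area <- sum(pixels(sil)) * 0.05^2
  expect_lt(abs(area / (pi * 25) - 1), 0.01)
  expect_identical(provenance(sil), "rendered")
})

test_that("silhouette area is invariant under in-plane rotation", {
  case <- generateCase(smallPhantomParams(seed = 2L))
  mesh <- pcaRectify(maskToMesh(case@mriVolume))$mesh
  a0 <- sum(pixels(renderSilhouette(mesh, cameraSpec())))
  rot <- applyTransform(RigidTransform(rotationAboutAxis("z", 30)), mesh)
  a1 <- sum(pixels(renderSilhouette(rot, cameraSpec())))
  expect_gt(a0, 1000)
  expect_lt(abs(a1 / a0 - 1), 0.01)
})

test_that("empty meshes render to all-background and small canvases error", {
  empty <- SurfaceMesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  sil <- renderSilhouette(empty, cameraSpec())
  expect_false(any(pixels(sil)))
  m <- meshSphere(5)
  expect_error(renderSilhouette(m, cameraSpec(), canvasMm = c(4, 4)),
               "requires at least")
})

test_that("orthographic and pinhole projections agree for low objects at 140 mm", {
  # cartilage-like object a few mm high on the grid plane
  case <- generateCase(smallPhantomParams(seed = 2L))
  mesh <- pcaRectify(maskToMesh(case@ctVolume))$mesh
  expect_lt(diff(range(vertices(mesh)[, 3])), 5.5)
  canvas <- c(60, 50)
  so <- renderSilhouette(mesh, cameraSpec(mode = "orthographic"), canvas)
  sp <- renderSilhouette(mesh, cameraSpec(mode = "pinhole"), canvas)
  xorPx <- sum(xor(pixels(so), pixels(sp)))
  expect_lt(xorPx / sum(pixels(so)), 0.03)
})

test_that("binarisation thresholds exactly and preserves interior holes", {
  img <- matrix(0, 60, 60)
  img[10:50, 10:50] <- 255
  img[25:30, 25:30] <- 0          # defect hole
  img[2:4, 2:4] <- 255            # small spurious component
  s <- binarizePhoto(img, threshold = 128, mmPerPx = 0.1)
  expect_true(s@pixels[12, 12])
  expect_false(s@pixels[27, 27])      # hole survives
  expect_false(s@pixels[3, 3])        # spurious component removed
  expect_equal(sum(pixels(s)), 41 * 41 - 36)
  expect_error(binarizePhoto(matrix(0, 5, 5), 128, 0.1), "empty-foreground")
})

test_that("Otsu threshold maximises inter-class variance", {
  set.seed(21)
  img <- matrix(c(rnorm(3000, 0.25, 0.05), rnorm(3000, 0.75, 0.05)), 60, 100)
  img <- pmin(pmax(img, 0), 1)
  s <- binarizePhoto(img, "otsu", 0.1)
  thr <- attr(s, "threshold")
  # exhaustive inter-class variance maximisation over the same 256 levels;
  # any threshold in the inter-mode gap maximises it, so compare variances,
  # not threshold values
  between <- function(t) {
    w0 <- mean(img <= t)
    if (w0 %in% c(0, 1)) return(0)
    (w0 * (1 - w0)) * (mean(img[img > t]) - mean(img[img <= t]))^2
  }
  best <- max(vapply((0:255) / 255, between, numeric(1)))
  expect_gte(between(thr), 0.999 * best)
  expect_gt(thr, 0.3); expect_lt(thr, 0.7)
})

test_that("silhouette alignment recovers translations, flips and scale changes", {
  a <- blobSilhouette(0.1)
  b <- blobSilhouette(0.1, shiftMm = c(3, -1.3))
  al <- alignSilhouettes(a, b)
  expect_gt(al$dsc, 0.99)
  b180 <- blobSilhouette(0.1, angleRad = pi)
  al2 <- alignSilhouettes(a, b180)
  expect_gt(al2$dsc, 0.99)
  expect_equal(al2$candidate, 2)
  bFine <- blobSilhouette(0.05, angleRad = 0.4, shiftMm = c(1, 2), nPx = 640)
  al3 <- alignSilhouettes(a, bFine)
  expect_gt(al3$dsc, 0.98)
  expect_equal(mmPerPx(al3$a), 0.05)
  expect_identical(dim(pixels(al3$a)), dim(pixels(al3$b)))
})

test_that("circularly symmetric silhouettes fall back to centroid alignment", {
  n <- 200
  xs <- (seq_len(n) - 0.5) - n / 2
  D <- outer(xs^2, xs^2, "+")
  disk <- BinarySilhouette(D <= 60^2, 0.1)
  expect_warning(al <- alignSilhouettes(disk, disk), "centroid-only")
  expect_true(al$degenerate)
  expect_equal(al$dsc, 1)
})

test_that("the grid calibration identity holds", {
  cam <- cameraSpec()
  expect_equal(gridPitchPx(cam), 10)
  expect_equal(gridPitchPx(cameraSpec(mmPerPx = 0.05, gridPitchMm = 1)), 20)
})
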