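# Shared fixtures, built in code at test time.

# scaled-down phantom for fast unit tests (acceptance tests use the
# full-size defaults)
smallPhantomParams <- function(...) {
  phantomParams(plateauExtentMm = c(36, 26),
                patchCentersMm = rbind(c(-9, 0), c(9, 0)),
                patchRadiiMm = c(8.5, 7.5), ...)
}

# solid cube mask: n^3 foreground voxels inside a padded grid
cubeVolume <- function(n = 20, spacing = 0.2, pad = 2) {
  d <- n + 2 * pad
  v <- array(0L, c(d, d, d))
  v[(pad + 1):(pad + n), (pad + 1):(pad + n), (pad + 1):(pad + n)] <- 1L
  LabelVolume(v, spacing, frameId = "synthetic-world")
}

# rasterised solid sphere mask (voxel centre inside radius)
sphereVolume <- function(radius = 5, spacing = 0.2) {
  n <- as.integer(ceiling(2 * radius / spacing)) + 5L
  ctr <- (n + 1) / 2 * spacing
  g <- seq_len(n) * spacing
  d2 <- outer(outer((g - ctr)^2, (g - ctr)^2, "+"), (g - ctr)^2, "+")
  LabelVolume(array(as.integer(d2 < radius^2), c(n, n, n)), spacing,
              frameId = "synthetic-world")
}

# watertight axis-aligned box mesh with outward normals, centred at origin
boxMesh <- function(a, b, c) {
  h <- c(a, b, c) / 2
  V <- as.matrix(expand.grid(x = c(-h[1], h[1]), y = c(-h[2], h[2]),
                             z = c(-h[3], h[3])))
  quad <- function(p1, p2, p3, p4) rbind(c(p1, p2, p3), c(p1, p3, p4))
  F <- rbind(quad(1, 3, 4, 2),   # z = -h
             quad(5, 6, 8, 7),   # z = +h
             quad(1, 2, 6, 5),   # y = -h
             quad(3, 7, 8, 4),   # y = +h
             quad(1, 5, 7, 3),   # x = -h
             quad(2, 4, 8, 6))   # x = +h
  SurfaceMesh(V, F)
}

# asymmetric blob silhouette (ellipse with a notch), for alignment tests
blobSilhouette <- function(mmPerPx = 0.1, angleRad = 0, shiftMm = c(0, 0),
                           nPx = 320) {
  xs <- ((seq_len(nPx) - 0.5) * mmPerPx) - nPx * mmPerPx / 2
  X <- matrix(xs, nPx, nPx, byrow = TRUE)
  Y <- matrix(xs, nPx, nPx)
  ct <- cos(-angleRad); st <- sin(-angleRad)
  U <- ct * (X - shiftMm[1]) - st * (Y - shiftMm[2])
  W <- st * (X - shiftMm[1]) + ct * (Y - shiftMm[2])
  fg <- (U / 10)^2 + (W / 6)^2 <= 1
  fg[(U - 6)^2 + W^2 <= 9] <- FALSE          # notch breaks symmetry
  BinarySilhouette(fg, mmPerPx, provenance = "rendered")
}

# brute-force Dice by explicit element-wise counting (independent oracle)
bruteDice <- function(a, b) {
  ia <- 0; ib <- 0; ii <- 0
  for (k in seq_along(a)) {
    if (a[k]) ia <- ia + 1
    if (b[k]) ib <- ib + 1
    if (a[k] && b[k]) ii <- ii + 1
  }
  2 * ii / (ia + ib)
}
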