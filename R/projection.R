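# Track A: pose rectification by principal axes, calibrated silhouette
# rendering emulating the photographic setup, photograph binarisation, and
# mutual 2D alignment of silhouettes.

#' Rectify a mesh pose by principal component analysis
#'
#' Rotates the mesh so the principal axes of its vertex covariance align with
#' x (largest variance), y, z (smallest variance) and moves the centroid to
#' the origin. Sign conventions make the result deterministic: the z axis is
#' oriented so the majority of the surface area has outward normals with a
#' positive z component (the articular surface faces up), and the x axis so
#' the third central moment of the x coordinates is non-negative; y completes
#' a right-handed frame.
#'
#' @param mesh A \linkS4class{SurfaceMesh} with at least 4 non-coplanar
#'   vertices.
#' @return List with elements \code{mesh} (the rectified
#'   \linkS4class{SurfaceMesh}) and \code{transform} (the
#'   \linkS4class{RigidTransform} mapping input to output).
#' @export
pcaRectify <- function(mesh) {
  V <- mesh@vertices
  if (nrow(V) < 4) stop("pcaRectify: need at least 4 vertices")
  ctr <- colMeans(V)
  C <- stats::cov(V)
  eg <- eigen(C, symmetric = TRUE)
  if (eg$values[3] <= 1e-12 * max(eg$values[1], .Machine$double.eps))
    stop("pcaRectify: degenerate vertex covariance (points are coplanar)")
  R <- t(eg$vectors) # rows = principal axes, decreasing variance
  if (det(R) < 0) R[3, ] <- -R[3, ]

  W <- sweep(V, 2, ctr) %*% t(R)
  F <- mesh@faces
  # area balance of faces whose outward normal points up vs down
  u <- W[F[, 2], , drop = FALSE] - W[F[, 1], , drop = FALSE]
  w <- W[F[, 3], , drop = FALSE] - W[F[, 1], , drop = FALSE]
  nz <- u[, 1] * w[, 2] - u[, 2] * w[, 1] # z of cross product, 2x signed area
  if (sum(nz) < 0) { R[3, ] <- -R[3, ]; R[1, ] <- -R[1, ]; W[, c(1, 3)] <- -W[, c(1, 3)] }
  skew <- sum((W[, 1])^3)
  if (skew < 0) { R[1, ] <- -R[1, ]; R[2, ] <- -R[2, ]; W[, c(1, 2)] <- -W[, c(1, 2)] }
  list(mesh = SurfaceMesh(W, F, frameId = mesh@frameId),
       transform = RigidTransform(R, as.numeric(-R %*% ctr)))
}

#' Render the calibrated silhouette of a rectified mesh
#'
#' Emulates photographing the model from directly above. In orthographic mode
#' a pixel is foreground iff the vertical ray through its centre intersects
#' the mesh; pinhole mode projects through a camera at
#' \code{(0, 0, distanceMm)} looking down, scaled so the z = 0 (grid-paper)
#' plane maps at \code{mmPerPx}. Under grid calibration the nominal zoom
#' cancels, so orthographic is the default; the parallax disagreement for an
#' object of height h is of order h / distance.
#'
#' @param mesh a pose-rectified \linkS4class{SurfaceMesh} (z up).
#' @param cam A \linkS4class{CameraSpec}.
#' @param canvasMm optional c(width, height) of the canvas in mm, centred on
#'   the projected centroid; an error reports the required size if the mesh
#'   does not fit. Default: auto-fit with a 1 mm margin.
#' @return A \linkS4class{BinarySilhouette} with provenance "rendered".
#' @export
renderSilhouette <- function(mesh, cam = cameraSpec(), canvasMm = NULL) {
  s <- cam@mmPerPx
  V <- mesh@vertices
  if (nrow(mesh@faces) == 0L)
    return(BinarySilhouette(matrix(FALSE, 8, 8), s, provenance = "rendered"))
  if (cam@mode == "pinhole") {
    if (max(V[, 3]) >= cam@distanceMm)
      stop("renderSilhouette: mesh reaches the pinhole camera plane (height >= distanceMm)")
    sc <- cam@distanceMm / (cam@distanceMm - V[, 3])
    P <- cbind(V[, 1] * sc, V[, 2] * sc)
  } else {
    P <- V[, 1:2, drop = FALSE]
  }
  marginMm <- 1
  cx <- mean(range(P[, 1])); cy <- mean(range(P[, 2]))
  needW <- diff(range(P[, 1])) + 2 * marginMm
  needH <- diff(range(P[, 2])) + 2 * marginMm
  if (is.null(canvasMm)) {
    wMm <- needW; hMm <- needH
  } else {
    wMm <- canvasMm[1]; hMm <- canvasMm[2]
    if (wMm < needW || hMm < needH)
      stop(sprintf("renderSilhouette: mesh extends beyond canvas; requires at least %.2f x %.2f mm",
                   needW, needH))
  }
  nx <- as.integer(ceiling(wMm / s)); ny <- as.integer(ceiling(hMm / s))
  x0 <- cx - nx * s / 2; y0 <- cy - ny * s / 2
  Ppx <- cbind((P[, 1] - x0) / s, (P[, 2] - y0) / s)
  img <- .cpp_rasterize_triangles(Ppx, mesh@faces, ny, nx)
  BinarySilhouette(img, s, provenance = "rendered")
}

#' Binarise a grayscale photograph into a silhouette
#'
#' Thresholds the image (fixed value or Otsu's method), keeps the largest
#' connected foreground component, and deliberately does NOT fill interior
#' holes: cartilage defects are the morphology of interest and must survive
#' binarisation.
#'
#' @param image numeric matrix; values in [0, 1] or [0, 255].
#' @param threshold numeric cut, or "otsu" for automatic threshold selection
#'   by inter-class variance maximisation.
#' @param mmPerPx physical pixel size of the photograph, mm (from the grid
#'   calibration paper).
#' @param polarity "bright" (foreground above threshold) or "dark".
#' @return A \linkS4class{BinarySilhouette} with provenance "photo".
#' @export
binarizePhoto <- function(image, threshold = "otsu", mmPerPx,
                          polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  image <- as.matrix(image)
  if (!length(image)) stop("binarizePhoto: empty image")
  if (max(image) > 1) {
    image <- image / 255
    if (is.numeric(threshold)) threshold <- threshold / 255
  }
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(image), range = c(0, 1), levels = 256)
  } else as.numeric(threshold)
  fg <- if (polarity == "bright") image > thr else image < thr
  if (!any(fg))
    stop("binarizePhoto: threshold leaves no foreground (empty-foreground)")
  lab <- EBImage::bwlabel(fg)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  out <- lab == keep
  dim(out) <- dim(image)
  structure(BinarySilhouette(out, mmPerPx, provenance = "photo"),
            threshold = thr)
}

# foreground centroid (mm) and principal-axis angle of a silhouette;
# moments use pixel centres at ((col-0.5), (row-0.5)) * mmPerPx
.silhouetteMoments <- function(s) {
  idx <- which(s@pixels, arr.ind = TRUE)
  x <- (idx[, 2] - 0.5) * s@mmPerPx
  y <- (idx[, 1] - 0.5) * s@mmPerPx
  cx <- mean(x); cy <- mean(y)
  mu20 <- mean((x - cx)^2); mu02 <- mean((y - cy)^2); mu11 <- mean((x - cx) * (y - cy))
  M <- matrix(c(mu20, mu11, mu11, mu02), 2)
  ev <- eigen(M, symmetric = TRUE)$values
  list(centroid = c(cx, cy), angle = 0.5 * atan2(2 * mu11, mu20 - mu02),
       anisotropy = 1 - ev[2] / ev[1])
}

# nearest-neighbour resample of silhouette src onto a canvas grid; the canvas
# pixel centre p (mm, common frame) reads source pixel at
# rot(-theta) (p - pivotDst) + pivotSrc
.resampleOntoCanvas <- function(src, canvas, theta, pivotDst, pivotSrc) {
  xs <- canvas$x0 + (seq_len(canvas$nx) - 0.5) * canvas$s
  ys <- canvas$y0 + (seq_len(canvas$ny) - 0.5) * canvas$s
  X <- matrix(xs, canvas$ny, canvas$nx, byrow = TRUE)
  Y <- matrix(ys, canvas$ny, canvas$nx)
  dx <- X - pivotDst[1]; dy <- Y - pivotDst[2]
  ct <- cos(-theta); st <- sin(-theta)
  sx <- ct * dx - st * dy + pivotSrc[1]
  sy <- st * dx + ct * dy + pivotSrc[2]
  col <- round(sx / src@mmPerPx + 0.5)
  row <- round(sy / src@mmPerPx + 0.5)
  d <- dim(src@pixels)
  ok <- col >= 1 & col <= d[2] & row >= 1 & row <= d[1]
  out <- matrix(FALSE, canvas$ny, canvas$nx)
  out[ok] <- src@pixels[cbind(row[ok], col[ok])]
  out
}

#' Mutually align two silhouettes for 2D comparison
#'
#' Resamples both silhouettes to the finer pixel scale, superposes foreground
#' centroids, and rotates \code{b} so its 2D principal axis aligns with that
#' of \code{a}. Excluding mirrors (a photograph and a top-view render share
#' handedness), the axis-sign ambiguity leaves two proper-rotation candidates
#' (theta and theta + 180 deg); the one maximising 2D Dice is returned, ties
#' broken by candidate order. Circularly symmetric foregrounds (no stable
#' principal axis) fall back to centroid-only alignment with a warning.
#'
#' @param a,b \linkS4class{BinarySilhouette}s with non-empty foreground.
#' @return List with the aligned silhouettes \code{a} and \code{b} (equal
#'   grid and scale), plus \code{rotationDeg}, \code{candidate} (1 or 2),
#'   \code{dsc}, and \code{degenerate} (TRUE if centroid-only fallback).
#' @export
alignSilhouettes <- function(a, b) {
  stopifnot(is(a, "BinarySilhouette"), is(b, "BinarySilhouette"))
  if (!any(a@pixels) || !any(b@pixels))
    stop("alignSilhouettes: both silhouettes must have non-empty foreground")
  s <- min(a@mmPerPx, b@mmPerPx)
  ma <- .silhouetteMoments(a); mb <- .silhouetteMoments(b)
  degenerate <- ma$anisotropy < 0.05 || mb$anisotropy < 0.05
  if (degenerate) {
    warning("alignSilhouettes: near-circular foreground; principal axis unstable, falling back to centroid-only alignment")
    cands <- 0
  } else {
    base <- ma$angle - mb$angle
    cands <- c(base, base + pi)
  }
  # canvas in a's frame, centred on a's centroid, covering both footprints
  half <- function(sil, m) {
    idx <- which(sil@pixels, arr.ind = TRUE)
    x <- (idx[, 2] - 0.5) * sil@mmPerPx - m$centroid[1]
    y <- (idx[, 1] - 0.5) * sil@mmPerPx - m$centroid[2]
    max(sqrt(x^2 + y^2))
  }
  hr <- max(half(a, ma), half(b, mb)) + 2 * s
  n <- as.integer(2 * ceiling(hr / s))
  canvas <- list(x0 = ma$centroid[1] - n * s / 2, y0 = ma$centroid[2] - n * s / 2,
                 nx = n, ny = n, s = s)
  pa <- .resampleOntoCanvas(a, canvas, 0, ma$centroid, ma$centroid)
  best <- NULL
  for (ci in seq_along(cands)) {
    pb <- .resampleOntoCanvas(b, canvas, cands[ci], ma$centroid, mb$centroid)
    inter <- sum(pa & pb)
    d <- 2 * inter / (sum(pa) + sum(pb))
    if (is.null(best) || d > best$dsc)
      best <- list(pb = pb, dsc = d, candidate = ci, theta = cands[ci])
  }
  list(a = BinarySilhouette(pa, s, provenance = a@provenance),
       b = BinarySilhouette(best$pb, s, provenance = b@provenance),
       rotationDeg = best$theta * 180 / pi, candidate = best$candidate,
       dsc = best$dsc, degenerate = degenerate)
}
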