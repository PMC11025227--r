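# Synthetic tibial-plateau phantom generator. Every downstream stage of the
# validation pipeline is exercised on these cases, so the generator is
# first-class, seeded, and bit-reproducible.
#
# Geometry: an elliptical plateau bears two condylar cartilage patches
# (medial / lateral). The thickness profile per patch is a raised-cosine
# falloff on a floor (cartilage is centrally fairly uniform and thins towards
# the margin, where it ends in an abrupt edge rather than tapering to zero).
# The height map is smoothed with a fixed-width Gaussian and thresholded at a
# quarter millimetre so the margin is crisp at the voxel-resolvable level;
# full-thickness defect disks are punched out after smoothing (sharp-edged
# lesions). The MRI-side model is the same field with thickness multiplied by
# beta (the underestimation knob) plus a smooth additive boundary-noise field,
# rasterised at 0.4 mm in the MRI frame; the CT gold standard is rasterised at
# 0.2 mm in the CT frame (= the world frame of the field).

.CT_SPACING <- 0.2
.MRI_SPACING <- 0.4
.FIELD_PITCH <- 0.1   # mm, height-map grid
.SMOOTH_SD <- 1.5     # mm, Gaussian smoothing of the height map
.T_FLOOR <- 0.25      # mm, thickness threshold defining the cartilage margin
.PROFILE_FLOOR <- 0.65  # thickness at the patch margin as fraction of peak
.EMINENCE_H <- 2.0    # mm, intercondylar eminence height above the plateau
.EMINENCE_SX <- 6     # mm, eminence Gaussian half-width, medio-lateral
.EMINENCE_SY <- 16    # mm, eminence Gaussian half-width, antero-posterior
.WEDGE <- 0.12        # antero-posterior thickness asymmetry (fractional)

#' Construct phantom parameters
#'
#' Defaults describe a realistic severe-osteoarthritis tibial plateau:
#' 75 x 50 mm plateau, condylar patches of radius 18 / 16 mm, peak thickness
#' 2.2 mm. \code{thicknessBias} (beta) multiplies the MRI-side thickness and
#' is the single knob reproducing the high-2D / low-3D Dice signature of
#' thickness underestimation.
#'
#' @param plateauExtentMm ellipse axis lengths (x, y), mm.
#' @param patchCentersMm 2 x 2 matrix of medial / lateral patch centres, mm.
#' @param patchRadiiMm the two patch radii, mm.
#' @param baseThicknessMm peak cartilage thickness, mm.
#' @param thicknessBias beta in (0, 1].
#' @param defects K x 3 matrix (cx, cy, radius) of full-thickness defect
#'   disks, mm.
#' @param boundaryNoiseSdMm sd of the smooth MRI-side thickness noise, mm.
#' @param landmarkNoiseSdMm sd of MRI-side landmark measurement noise, mm.
#' @param trueTransform ground-truth \linkS4class{RigidTransform} MRI -> CT.
#' @param mmPerPxPhoto photograph pixel size, mm.
#' @param seed integer seed; same params + seed give a bit-identical case.
#' @return A \linkS4class{PhantomParams}.
#' @export
phantomParams <- function(plateauExtentMm = c(75, 50),
                          patchCentersMm = rbind(c(-19, 0), c(19, 0)),
                          patchRadiiMm = c(18, 16),
                          baseThicknessMm = 2.2,
                          thicknessBias = 1,
                          defects = matrix(numeric(0), 0, 3),
                          boundaryNoiseSdMm = 0.15,
                          landmarkNoiseSdMm = 0.5,
                          trueTransform = identityTransform(),
                          mmPerPxPhoto = 0.1,
                          seed = 1L) {
  new("PhantomParams", plateauExtentMm = as.numeric(plateauExtentMm),
      patchCentersMm = as.matrix(patchCentersMm),
      patchRadiiMm = as.numeric(patchRadiiMm),
      baseThicknessMm = as.numeric(baseThicknessMm),
      thicknessBias = as.numeric(thicknessBias),
      defects = matrix(as.numeric(defects), ncol = 3),
      boundaryNoiseSdMm = as.numeric(boundaryNoiseSdMm),
      landmarkNoiseSdMm = as.numeric(landmarkNoiseSdMm),
      trueTransform = trueTransform, mmPerPxPhoto = as.numeric(mmPerPxPhoto),
      seed = as.integer(seed))
}

# separable Gaussian blur with zero padding, sd in grid units
.gaussBlur <- function(m, sd) {
  r <- ceiling(3 * sd)
  k <- stats::dnorm(-r:r, sd = sd)
  k <- k / sum(k)
  pad <- function(x, n) rbind(matrix(0, n, ncol(x)), x, matrix(0, n, ncol(x)))
  conv1 <- function(x) { # along rows (dim 1)
    xp <- pad(x, r)
    out <- matrix(0, nrow(x), ncol(x))
    for (i in seq_along(k)) out <- out + k[i] * xp[i:(i + nrow(x) - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(m))))
}

# height-map container: matrix indexed [ix, iy], world x = x0 + h*(ix-1)
.evalField <- function(fld, x, y) {
  gx <- (x - fld$x0) / fld$h + 1
  gy <- (y - fld$y0) / fld$h + 1
  nx <- nrow(fld$mat); ny <- ncol(fld$mat)
  i0 <- pmin(pmax(floor(gx), 1), nx - 1); fx <- pmin(pmax(gx - i0, 0), 1)
  j0 <- pmin(pmax(floor(gy), 1), ny - 1); fy <- pmin(pmax(gy - j0, 0), 1)
  inside <- gx >= 1 & gx <= nx & gy >= 1 & gy <= ny
  m <- fld$mat
  v <- (1 - fx) * (1 - fy) * m[cbind(i0, j0)] +
       fx * (1 - fy) * m[cbind(i0 + 1L, j0)] +
       (1 - fx) * fy * m[cbind(i0, j0 + 1L)] +
       fx * fy * m[cbind(i0 + 1L, j0 + 1L)]
  v[!inside] <- 0
  v
}

# build the true (CT-side) thickness field of a phantom; deterministic
.thicknessField <- function(p) {
  ex <- p@plateauExtentMm / 2
  marginMm <- 6
  h <- .FIELD_PITCH
  xs <- seq(-ex[1] - marginMm, ex[1] + marginMm, by = h)
  ys <- seq(-ex[2] - marginMm, ex[2] + marginMm, by = h)
  X <- matrix(xs, length(xs), length(ys))
  Y <- matrix(ys, length(xs), length(ys), byrow = TRUE)
  f <- matrix(0, length(xs), length(ys))
  for (i in 1:2) {
    d <- sqrt((X - p@patchCentersMm[i, 1])^2 + (Y - p@patchCentersMm[i, 2])^2)
    r <- p@patchRadiiMm[i]
    fi <- ifelse(d < r, .PROFILE_FLOOR + (1 - .PROFILE_FLOOR) * cos(pi / 2 * d / r)^2, 0)
    f <- pmax(f, fi)
  }
  inEllipse <- (X / ex[1])^2 + (Y / ex[2])^2 <= 1
  # antero-posterior wedge (plateau cartilage is thicker posteriorly) and the
  # intercondylar eminence ridge between the condylar patches; both give the
  # articular surface the relief that makes its pose observable
  wedge <- 1 + .WEDGE * Y / ex[2]
  em <- .EMINENCE_H * exp(-(X / .EMINENCE_SX)^2 - (Y / .EMINENCE_SY)^2)
  t0 <- (p@baseThicknessMm * f * wedge + em) * inEllipse
  t0 <- .gaussBlur(t0, .SMOOTH_SD / h)
  t0[t0 < .T_FLOOR] <- 0
  if (nrow(p@defects))
    for (i in seq_len(nrow(p@defects))) {
      d <- sqrt((X - p@defects[i, 1])^2 + (Y - p@defects[i, 2])^2)
      t0[d < p@defects[i, 3]] <- 0
    }
  list(x0 = xs[1], y0 = ys[1], h = h, mat = t0)
}

# smooth unit-sd noise field on the same grid (consumes RNG)
.noiseField <- function(fld, sdMm) {
  if (sdMm <= 0) return(NULL)
  coarse <- 2 # mm
  nx <- ceiling((nrow(fld$mat) - 1) * fld$h / coarse) + 2L
  ny <- ceiling((ncol(fld$mat) - 1) * fld$h / coarse) + 2L
  cm <- matrix(stats::rnorm(nx * ny), nx, ny)
  cf <- list(x0 = fld$x0, y0 = fld$y0, h = coarse, mat = cm)
  xs <- fld$x0 + fld$h * (seq_len(nrow(fld$mat)) - 1)
  ys <- fld$y0 + fld$h * (seq_len(ncol(fld$mat)) - 1)
  X <- matrix(xs, length(xs), length(ys))
  Y <- matrix(ys, length(xs), length(ys), byrow = TRUE)
  up <- matrix(.evalField(cf, as.numeric(X), as.numeric(Y)), nrow(fld$mat))
  up / stats::sd(up) * sdMm
}

# rasterise a thickness field into a LabelVolume in its own (world) frame
.rasterizeField <- function(fld, spacing, frameId) {
  nx <- floor((nrow(fld$mat) - 1) * fld$h / spacing) + 1L
  ny <- floor((ncol(fld$mat) - 1) * fld$h / spacing) + 1L
  zmax <- max(fld$mat)
  nz <- ceiling(zmax / spacing) + 4L
  origin <- c(fld$x0, fld$y0, spacing / 2 - 2 * spacing)
  xs <- origin[1] + spacing * (seq_len(nx) - 1)
  ys <- origin[2] + spacing * (seq_len(ny) - 1)
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  tc <- matrix(.evalField(fld, as.numeric(X), as.numeric(Y)), nx, ny)
  zc <- origin[3] + spacing * (0:(nz - 1))
  vox <- array(0L, c(nx, ny, nz))
  for (k in seq_len(nz))
    if (zc[k] > 0) vox[, , k] <- (zc[k] < tc) * 1L
  LabelVolume(vox, spacing, origin, frameId = frameId)
}

#' Generate one synthetic case
#'
#' Builds the true thickness field, rasterises the CT gold standard at 0.2 mm
#' in the CT frame, rasterises the beta-degraded noisy MRI model at 0.4 mm in
#' the MRI frame (the CT frame mapped through the inverse of the true
#' transform), renders the top-down specimen photograph, and places the six
#' ordered landmarks in both frames (MRI side with measurement noise).
#'
#' @param params A \linkS4class{PhantomParams}.
#' @return A \linkS4class{SyntheticCase}.
#' @export
generateCase <- function(params) {
  stopifnot(is(params, "PhantomParams"))
  withr::with_seed(params@seed, .generateCaseImpl(params))
}

.generateCaseImpl <- function(p) {
  fld <- .thicknessField(p)
  if (max(fld$mat) <= 0)
    stop("generateCase: defects cover the entire cartilage (degenerate all-background case)")
  ct <- .rasterizeField(fld, .CT_SPACING, "CT")

  # MRI-side field: thickness x beta + smooth boundary noise, support of t
  noise <- .noiseField(fld, p@boundaryNoiseSdMm)
  mriMat <- p@thicknessBias * fld$mat
  if (!is.null(noise)) mriMat <- mriMat + noise * (fld$mat > 0)
  mriMat[mriMat < 0 | fld$mat <= 0] <- 0
  mriFld <- list(x0 = fld$x0, y0 = fld$y0, h = fld$h, mat = mriMat)

  truth <- p@trueTransform
  toMri <- invertTransform(truth)
  # MRI grid: AABB (in the MRI frame) of the world-frame field box
  wx <- c(fld$x0, fld$x0 + fld$h * (nrow(fld$mat) - 1))
  wy <- c(fld$y0, fld$y0 + fld$h * (ncol(fld$mat) - 1))
  wz <- c(-2 * .MRI_SPACING, max(mriMat) + 2 * .MRI_SPACING)
  corners <- as.matrix(expand.grid(wx, wy, wz))
  mc <- applyTransform(toMri, corners)
  # cell-centred grid: voxel centres at lo + (k + 1/2) * spacing relative to
  # the raw bounds, so axis-aligned surfaces are sampled without half-voxel
  # bias when the transform is axis-aligned
  lo <- apply(mc, 2, min) - .MRI_SPACING + .MRI_SPACING / 2
  hi <- apply(mc, 2, max) + .MRI_SPACING
  dims <- as.integer(ceiling((hi - lo) / .MRI_SPACING)) + 1L
  ctr <- .gridCentres(dims, .MRI_SPACING, lo)
  q <- applyTransform(truth, ctr)
  tm <- .evalField(mriFld, q[, 1], q[, 2])
  fg <- as.integer(q[, 3] > 0 & q[, 3] < tm)
  dim(fg) <- dims
  mri <- LabelVolume(fg, .MRI_SPACING, lo, frameId = "MRI")

  # top-down photograph of the physical specimen (the true field)
  ppx <- p@mmPerPxPhoto
  pnx <- floor((nrow(fld$mat) - 1) * fld$h / ppx) + 1L
  pny <- floor((ncol(fld$mat) - 1) * fld$h / ppx) + 1L
  pxs <- fld$x0 + ppx * (seq_len(pnx) - 1)
  pys <- fld$y0 + ppx * (seq_len(pny) - 1)
  PX <- matrix(pxs, pnx, pny)
  PY <- matrix(pys, pnx, pny, byrow = TRUE)
  tp <- matrix(.evalField(fld, as.numeric(PX), as.numeric(PY)), pnx, pny)
  # pixels[row = y, col = x] to match the silhouette convention
  photo <- BinarySilhouette(t(tp > 0), ppx, provenance = "photo")

  lmCT <- .placeLandmarks(p, fld)
  lmMRIpts <- applyTransform(toMri, lmCT@points)
  if (p@landmarkNoiseSdMm > 0)
    lmMRIpts <- lmMRIpts + matrix(stats::rnorm(18, sd = p@landmarkNoiseSdMm), 6, 3)
  lmMRI <- LandmarkSet(lmMRIpts, lmCT@labels, frameId = "MRI")

  new("SyntheticCase", ctVolume = ct, mriVolume = mri, photo = photo,
      landmarksCT = lmCT, landmarksMRI = lmMRI, truth = truth, params = p)
}

.placeLandmarks <- function(p, fld) {
  ex <- p@plateauExtentMm / 2
  xy <- rbind(c(0, -0.92 * ex[2]),
              p@patchCentersMm[1, ] + c(0, -p@patchRadiiMm[1] / 2),
              p@patchCentersMm[1, ] + c(0, p@patchRadiiMm[1] / 2),
              c(0, 0.92 * ex[2]),
              p@patchCentersMm[2, ] + c(0, -p@patchRadiiMm[2] / 2),
              p@patchCentersMm[2, ] + c(0, p@patchRadiiMm[2] / 2))
  z <- .evalField(fld, xy[, 1], xy[, 2])
  LandmarkSet(cbind(xy, z), frameId = "CT")
}

#' Generate a reproducible cohort of synthetic cases
#'
#' Per case, beta, the true transform, and defect burden are drawn
#' independently from the stated ranges; each case receives its own derived
#' seed so the cohort is bit-reproducible under \code{seed}.
#'
#' @param n number of cases (>= 2; Pearson correlation is undefined below 2).
#' @param paramRanges list overriding any of: \code{betaRange} (default
#'   c(0.5, 0.9)), \code{maxRotationDeg} (25), \code{maxTranslationMm} (15),
#'   \code{defectCountRange} (c(0, 2)), \code{defectRadiusRangeMm} (c(2, 6)),
#'   \code{sizeScaleRange} (c(0.85, 1.15); per-case linear scaling of the
#'   plateau and patch geometry — knees differ in size),
#'   \code{thicknessRangeMm} (c(2.0, 2.4); per-case peak thickness),
#'   \code{boundaryNoiseSdMm} (0.15), \code{landmarkNoiseSdMm} (0.5).
#' @param seed master seed.
#' @return List of \linkS4class{SyntheticCase}s.
#' @export
generateCohort <- function(n, paramRanges = list(), seed = 1L) {
  if (n < 2) stop("generateCohort: n must be >= 2 (Pearson correlation undefined for fewer cases)")
  rg <- utils::modifyList(list(betaRange = c(0.5, 0.9), maxRotationDeg = 25,
                               maxTranslationMm = 15, defectCountRange = c(0L, 2L),
                               defectRadiusRangeMm = c(2, 6),
                               sizeScaleRange = c(0.85, 1.15),
                               thicknessRangeMm = c(2.0, 2.4),
                               boundaryNoiseSdMm = 0.15, landmarkNoiseSdMm = 0.5),
                          paramRanges)
  base <- phantomParams()
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      caseSeed <- sample.int(.Machine$integer.max, 1L)
      beta <- stats::runif(1, rg$betaRange[1], rg$betaRange[2])
      truth <- randomRigidTransform(rg$maxRotationDeg, rg$maxTranslationMm)
      sc <- stats::runif(1, rg$sizeScaleRange[1], rg$sizeScaleRange[2])
      thick <- stats::runif(1, rg$thicknessRangeMm[1], rg$thicknessRangeMm[2])
      nd <- sample(seq(rg$defectCountRange[1], rg$defectCountRange[2]), 1L)
      defects <- matrix(numeric(0), 0, 3)
      if (nd > 0) {
        defects <- t(vapply(seq_len(nd), function(j) {
          patch <- sample(1:2, 1L)
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- stats::runif(1, 0, 0.6 * sc * base@patchRadiiMm[patch])
          c(sc * base@patchCentersMm[patch, ] + rad * c(cos(ang), sin(ang)),
            stats::runif(1, rg$defectRadiusRangeMm[1], rg$defectRadiusRangeMm[2]))
        }, numeric(3)))
      }
      generateCase(phantomParams(plateauExtentMm = sc * base@plateauExtentMm,
                                 patchCentersMm = sc * base@patchCentersMm,
                                 patchRadiiMm = sc * base@patchRadiiMm,
                                 baseThicknessMm = thick,
                                 thicknessBias = beta, defects = defects,
                                 boundaryNoiseSdMm = rg$boundaryNoiseSdMm,
                                 landmarkNoiseSdMm = rg$landmarkNoiseSdMm,
                                 trueTransform = truth, seed = caseSeed))
    })
  })
}

#' Write / read a synthetic case as a directory of standard files
#'
#' Layout: \code{ct.nii.gz}, \code{mri.nii.gz}, \code{photo.png} (+ JSON
#' sidecar), \code{landmarks_ct.csv}, \code{landmarks_mri.csv},
#' \code{truth.json}.
#'
#' @param case A \linkS4class{SyntheticCase}.
#' @param dir output directory (created if needed).
#' @return \code{writeCase}: \code{dir}, invisibly. \code{readCase}: a named
#'   list (mriVolume, ctVolume, photo, landmarksMRI, landmarksCT, truth,
#'   caseId) usable as a case bundle for \code{\link{runCase}}.
#' @export
writeCase <- function(case, dir) {
  stopifnot(is(case, "SyntheticCase"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLabelVolume(case@ctVolume, file.path(dir, "ct.nii.gz"))
  writeLabelVolume(case@mriVolume, file.path(dir, "mri.nii.gz"))
  writeSilhouette(case@photo, file.path(dir, "photo.png"))
  writeLandmarks(case@landmarksCT, file.path(dir, "landmarks_ct.csv"))
  writeLandmarks(case@landmarksMRI, file.path(dir, "landmarks_mri.csv"))
  writeTransform(case@truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' @rdname writeCase
#' @export
readCase <- function(dir) {
  pick <- function(f) file.path(dir, f)
  out <- list(caseId = basename(dir))
  if (file.exists(pick("mri.nii.gz")))
    out$mriVolume <- readLabelVolume(pick("mri.nii.gz"), frameId = "MRI")
  if (file.exists(pick("ct.nii.gz")))
    out$ctVolume <- readLabelVolume(pick("ct.nii.gz"), frameId = "CT")
  if (file.exists(pick("photo.png")))
    out$photo <- readSilhouette(pick("photo.png"))
  if (file.exists(pick("landmarks_ct.csv")))
    out$landmarksCT <- readLandmarks(pick("landmarks_ct.csv"), frameId = "CT")
  if (file.exists(pick("landmarks_mri.csv")))
    out$landmarksMRI <- readLandmarks(pick("landmarks_mri.csv"), frameId = "MRI")
  if (file.exists(pick("truth.json")))
    out$truth <- readTransform(pick("truth.json"))
  out
}
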