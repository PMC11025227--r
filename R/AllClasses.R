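#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib CartilageDice, .registration = TRUE
NULL

.TOL_ORTHO <- 1e-9

#' Rigid transform (rotation + translation) between mm coordinate frames
#'
#' A proper rigid-body motion: a point \eqn{p} maps to \eqn{R p + t}. Used to
#' relate the MRI-model frame to the CT gold-standard frame; no scaling or
#' shear is permitted because the cartilage is the same physical object in
#' both modalities.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation length-3 numeric vector, millimetres.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0)))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!is.numeric(R) || !identical(dim(R), c(3L, 3L)))
    return("rotation must be a numeric 3x3 matrix")
  if (any(!is.finite(R))) return("rotation contains non-finite values")
  if (max(abs(crossprod(R) - diag(3))) > .TOL_ORTHO)
    return("rotation is not orthonormal (R'R != I within 1e-9)")
  if (abs(det(R) - 1) > .TOL_ORTHO)
    return("rotation determinant is not +1 within 1e-9 (improper rotation)")
  if (length(object@translation) != 3L || any(!is.finite(object@translation)))
    return("translation must be a finite length-3 vector")
  TRUE
})

#' Construct a RigidTransform
#'
#' @param rotation 3x3 orthonormal matrix, determinant +1.
#' @param translation length-3 numeric vector in mm.
#' @return A \linkS4class{RigidTransform}.
#' @examples
#' RigidTransform()                    # identity
#' RigidTransform(rotationAboutAxis("z", 90), c(1, 0, 0))
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation, translation = as.numeric(translation))
}

#' 3D label volume on an isotropic voxel grid
#'
#' Carrier of all cartilage masks. Voxel index (i,j,k) (1-based) has world
#' centre \code{originMm + spacingMm * (i-1, j-1, k-1)}; voxel centres, not
#' corners. The volume of label L is definitionally
#' \code{sum(voxels == L) * spacingMm^3}. Only isotropic grids are supported.
#'
#' @slot voxels 3D integer array; 0 = background, 1 = cartilage, further
#'   labels permitted.
#' @slot spacingMm positive scalar, isotropic voxel edge length in mm
#'   (0.4 for MRI-derived, 0.2 for CT-derived volumes in the study setting).
#' @slot originMm length-3 vector, world position of the centre of voxel
#'   (1,1,1) in mm.
#' @slot frameId coordinate-frame tag, e.g. "MRI", "CT", "synthetic-world".
#' @export
setClass("LabelVolume",
  representation(voxels = "array", spacingMm = "numeric",
                 originMm = "numeric", frameId = "character"))

setValidity("LabelVolume", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L) return("voxels must be a 3D array")
  if (!is.numeric(v) && !is.integer(v)) return("voxels must be numeric/integer")
  if (length(object@spacingMm) != 1L || !is.finite(object@spacingMm) ||
      object@spacingMm <= 0)
    return("spacingMm must be a single positive number")
  if (length(object@originMm) != 3L || any(!is.finite(object@originMm)))
    return("originMm must be a finite length-3 vector")
  if (length(v) && (min(v) < 0 || any(v != round(v))))
    return("voxel values must be non-negative integers")
  if (length(object@frameId) != 1L || !nzchar(object@frameId))
    return("frameId must be a single non-empty string")
  TRUE
})

#' Construct a LabelVolume
#'
#' @param voxels 3D integer array of labels (0 = background).
#' @param spacingMm isotropic voxel spacing in mm.
#' @param originMm world position of the centre of voxel (1,1,1), mm.
#' @param frameId coordinate-frame tag.
#' @return A \linkS4class{LabelVolume}.
#' @export
LabelVolume <- function(voxels, spacingMm, originMm = c(0, 0, 0),
                        frameId = "synthetic-world") {
  storage.mode(voxels) <- "integer"
  new("LabelVolume", voxels = voxels, spacingMm = as.numeric(spacingMm),
      originMm = as.numeric(originMm), frameId = frameId)
}

#' Triangulated surface mesh in mm coordinates
#'
#' @slot vertices N x 3 numeric matrix of mm coordinates.
#' @slot faces M x 3 integer matrix of 1-based vertex indices, oriented so
#'   face normals point out of the enclosed solid.
#' @slot frameId coordinate-frame tag.
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix", frameId = "character"))

setValidity("SurfaceMesh", function(object) {
  V <- object@vertices; F <- object@faces
  if (ncol(V) != 3L) return("vertices must be an N x 3 matrix")
  if (ncol(F) != 3L) return("faces must be an M x 3 matrix")
  if (any(!is.finite(V))) return("vertices contain non-finite values")
  if (nrow(F) && (min(F) < 1 || max(F) > nrow(V)))
    return("face indices out of range (must be in 1..N)")
  TRUE
})

#' Construct a SurfaceMesh
#' @param vertices N x 3 numeric matrix (mm).
#' @param faces M x 3 matrix of 1-based vertex indices.
#' @param frameId coordinate-frame tag.
#' @return A \linkS4class{SurfaceMesh}.
#' @export
SurfaceMesh <- function(vertices, faces, frameId = "synthetic-world") {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  new("SurfaceMesh", vertices = vertices, faces = faces, frameId = frameId)
}

#' 2D binary silhouette with physical pixel scale
#'
#' The common currency of the silhouette-photography comparison: a boolean
#' foreground mask whose pixel (i,j) covers a square of side \code{mmPerPx}.
#' Foreground area in mm^2 is \code{sum(pixels) * mmPerPx^2}.
#'
#' @slot pixels logical matrix (rows = y, columns = x).
#' @slot mmPerPx positive scalar, mm per pixel.
#' @slot provenance "rendered" (projected from a 3D model) or "photo".
#' @export
setClass("BinarySilhouette",
  representation(pixels = "matrix", mmPerPx = "numeric", provenance = "character"))

setValidity("BinarySilhouette", function(object) {
  if (!is.logical(object@pixels)) return("pixels must be a logical matrix")
  if (length(object@mmPerPx) != 1L || !is.finite(object@mmPerPx) ||
      object@mmPerPx <= 0)
    return("mmPerPx must be a single positive number")
  if (!object@provenance %in% c("rendered", "photo"))
    return('provenance must be "rendered" or "photo"')
  TRUE
})

#' Construct a BinarySilhouette
#' @param pixels logical matrix.
#' @param mmPerPx mm per pixel (> 0).
#' @param provenance "rendered" or "photo".
#' @return A \linkS4class{BinarySilhouette}.
#' @export
BinarySilhouette <- function(pixels, mmPerPx, provenance = "rendered") {
  pixels <- as.matrix(pixels)
  if (!is.logical(pixels)) { p <- pixels > 0; dim(p) <- dim(pixels); pixels <- p }
  new("BinarySilhouette", pixels = pixels, mmPerPx = as.numeric(mmPerPx),
      provenance = provenance)
}

.LANDMARK_LABELS <- c("anterior-tibia", "medial-plateau-1", "medial-plateau-2",
                      "posterior-tibia", "lateral-plateau-1", "lateral-plateau-2")

#' Ordered set of six anatomical landmarks
#'
#' The six points marked in sequence on the tibial plateau (anterior rim, two
#' medial-plateau points, posterior rim, two lateral-plateau points) used to
#' initialise rigid registration. Correspondence between two sets is by index.
#'
#' @slot points 6 x 3 numeric matrix, mm.
#' @slot labels ordered landmark names.
#' @slot frameId coordinate-frame tag.
#' @export
setClass("LandmarkSet",
  representation(points = "matrix", labels = "character", frameId = "character"))

setValidity("LandmarkSet", function(object) {
  P <- object@points
  if (!identical(dim(P), c(6L, 3L))) return("points must be a 6 x 3 matrix")
  if (any(!is.finite(P))) return("points contain non-finite values")
  if (length(object@labels) != 6L) return("labels must have length 6")
  ctr <- scale(P, scale = FALSE)
  sv <- svd(ctr)$d
  if (sv[2] <= 1e-9 * max(sv[1], 1))
    return("landmarks are collinear (rank of centred points < 2)")
  TRUE
})

#' Construct a LandmarkSet
#' @param points 6 x 3 numeric matrix of mm coordinates.
#' @param labels landmark names in order; defaults to the canonical six.
#' @param frameId coordinate-frame tag.
#' @return A \linkS4class{LandmarkSet}.
#' @export
LandmarkSet <- function(points, labels = .LANDMARK_LABELS,
                        frameId = "synthetic-world") {
  points <- as.matrix(points); storage.mode(points) <- "double"
  dimnames(points) <- NULL
  new("LandmarkSet", points = points, labels = labels, frameId = frameId)
}

#' Camera geometry for silhouette rendering
#'
#' Mirrors the photographic setup: camera fixed vertically 140 mm above the
#' specimen plane, 1.3x zoom, on 1 x 1 mm grid calibration paper. Under grid
#' calibration both images are expressed in mm via \code{mmPerPx}, so absolute
#' magnification cancels; the rendered pitch of one grid square is exactly
#' \code{gridPitchMm / mmPerPx} pixels (the calibration identity).
#'
#' @slot distanceMm camera-to-plane distance, mm (default 140).
#' @slot magnification nominal zoom factor (default 1.3; informational under
#'   grid calibration).
#' @slot mmPerPx calibrated pixel size of the output image (default 0.1).
#' @slot gridPitchMm pitch of the calibration grid (default 1).
#' @slot mode "orthographic" or "pinhole" projection.
#' @export
setClass("CameraSpec",
  representation(distanceMm = "numeric", magnification = "numeric",
                 mmPerPx = "numeric", gridPitchMm = "numeric", mode = "character"),
  prototype(distanceMm = 140, magnification = 1.3, mmPerPx = 0.1,
            gridPitchMm = 1, mode = "orthographic"))

setValidity("CameraSpec", function(object) {
  for (s in c("distanceMm", "magnification", "mmPerPx", "gridPitchMm")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      return(sprintf("%s must be a single positive number", s))
  }
  if (!object@mode %in% c("orthographic", "pinhole"))
    return('mode must be "orthographic" or "pinhole"')
  TRUE
})

#' Construct a CameraSpec
#' @param distanceMm camera-to-plane distance in mm.
#' @param magnification nominal zoom factor.
#' @param mmPerPx calibrated pixel size, mm.
#' @param gridPitchMm calibration-grid pitch, mm.
#' @param mode "orthographic" or "pinhole".
#' @return A \linkS4class{CameraSpec}.
#' @export
cameraSpec <- function(distanceMm = 140, magnification = 1.3, mmPerPx = 0.1,
                       gridPitchMm = 1, mode = c("orthographic", "pinhole")) {
  new("CameraSpec", distanceMm = distanceMm, magnification = magnification,
      mmPerPx = mmPerPx, gridPitchMm = gridPitchMm, mode = match.arg(mode))
}

#' Pitch of one calibration-grid square in rendered pixels
#' @param cam A \linkS4class{CameraSpec}.
#' @return Pixels per grid square (\code{gridPitchMm / mmPerPx}).
#' @export
gridPitchPx <- function(cam) cam@gridPitchMm / cam@mmPerPx

#' Overlap (Dice) result with auditable counts
#'
#' @slot dsc Dice similarity coefficient, 2|A intersect B| / (|A| + |B|),
#'   in [0, 1].
#' @slot intersectionCount,aCount,bCount foreground counts backing the DSC so
#'   the quotient can be recomputed by a reviewer.
#' @slot units "px" or "voxel".
#' @export
setClass("OverlapResult",
  representation(dsc = "numeric", intersectionCount = "numeric",
                 aCount = "numeric", bCount = "numeric", units = "character"))

setValidity("OverlapResult", function(object) {
  if (object@dsc < 0 || object@dsc > 1) return("dsc must lie in [0, 1]")
  if (min(object@intersectionCount, object@aCount, object@bCount) < 0)
    return("counts must be non-negative")
  if (!object@units %in% c("px", "voxel")) return('units must be "px" or "voxel"')
  den <- object@aCount + object@bCount
  if (den > 0 && abs(object@dsc - 2 * object@intersectionCount / den) > 1e-12)
    return("dsc inconsistent with counts")
  TRUE
})

#' Synthetic tibial-plateau phantom parameters
#'
#' Defines one synthetic case: an elliptical plateau bearing two smoothed
#' condylar cartilage patches (medial/lateral), optional full-thickness defect
#' disks, a multiplicative MRI-side thickness bias (the single knob that
#' reproduces the high-2D / low-3D Dice signature of thickness
#' underestimation), boundary noise, and a ground-truth MRI-to-CT rigid
#' transform.
#'
#' @slot plateauExtentMm ellipse axis lengths (x = medio-lateral,
#'   y = antero-posterior), mm.
#' @slot patchCentersMm 2 x 2 matrix; rows = medial/lateral patch centres (mm).
#' @slot patchRadiiMm radii of the two condylar patches, mm.
#' @slot baseThicknessMm peak cartilage thickness, mm.
#' @slot thicknessBias beta in (0, 1]: MRI thickness = beta * true thickness.
#' @slot defects K x 3 matrix (cx, cy, radius) of zero-thickness disks, mm.
#' @slot boundaryNoiseSdMm sd of the smooth additive thickness noise on the
#'   MRI side, mm.
#' @slot landmarkNoiseSdMm sd of isotropic landmark measurement noise applied
#'   to the MRI-frame landmarks after correspondence, mm.
#' @slot trueTransform ground-truth \linkS4class{RigidTransform}, MRI -> CT.
#' @slot mmPerPxPhoto pixel size of the synthetic specimen photograph, mm.
#' @slot seed integer RNG seed; identical params + seed give a bit-identical
#'   case.
#' @export
setClass("PhantomParams",
  representation(plateauExtentMm = "numeric", patchCentersMm = "matrix",
                 patchRadiiMm = "numeric", baseThicknessMm = "numeric",
                 thicknessBias = "numeric", defects = "matrix",
                 boundaryNoiseSdMm = "numeric", landmarkNoiseSdMm = "numeric",
                 trueTransform = "RigidTransform", mmPerPxPhoto = "numeric",
                 seed = "integer"))

setValidity("PhantomParams", function(object) {
  if (length(object@plateauExtentMm) != 2L || any(object@plateauExtentMm <= 0))
    return("plateauExtentMm must be two positive lengths")
  if (!identical(dim(object@patchCentersMm), c(2L, 2L)))
    return("patchCentersMm must be a 2 x 2 matrix")
  if (length(object@patchRadiiMm) != 2L || any(object@patchRadiiMm <= 0))
    return("patchRadiiMm must be two positive radii")
  if (object@baseThicknessMm <= 0) return("baseThicknessMm must be positive")
  b <- object@thicknessBias
  if (length(b) != 1L || b <= 0 || b > 1)
    return("thicknessBias must lie in (0, 1]")
  if (ncol(object@defects) != 3L)
    return("defects must be a K x 3 matrix (cx, cy, radius)")
  if (nrow(object@defects) && any(object@defects[, 3] <= 0))
    return("defect radii must be positive")
  if (object@boundaryNoiseSdMm < 0 || object@landmarkNoiseSdMm < 0)
    return("noise standard deviations must be >= 0")
  if (object@mmPerPxPhoto <= 0) return("mmPerPxPhoto must be positive")
  TRUE
})

#' One generated synthetic case
#'
#' @slot ctVolume CT-frame gold-standard \linkS4class{LabelVolume} (0.2 mm).
#' @slot mriVolume MRI-frame AI-model \linkS4class{LabelVolume} (0.4 mm) with
#'   thickness bias and boundary noise applied.
#' @slot photo top-down specimen \linkS4class{BinarySilhouette}.
#' @slot landmarksCT,landmarksMRI ordered \linkS4class{LandmarkSet}s;
#'   corresponding by index, MRI side carries measurement noise.
#' @slot truth ground-truth \linkS4class{RigidTransform} (MRI -> CT).
#' @slot params the generating \linkS4class{PhantomParams}.
#' @export
setClass("SyntheticCase",
  representation(ctVolume = "LabelVolume", mriVolume = "LabelVolume",
                 photo = "BinarySilhouette", landmarksCT = "LandmarkSet",
                 landmarksMRI = "LandmarkSet", truth = "RigidTransform",
                 params = "PhantomParams"))

#' Per-case validation report
#'
#' Mirrors the per-case reporting of the study: two 2D Dice values (model
#' render vs specimen photo; model render vs CT-model render), the 3D Dice
#' after registration, the two cartilage volumes, the final registration
#' residual, and a record of every alignment choice and tie-break taken.
#' Fields not computable from the supplied inputs are NA.
#'
#' @slot caseId case identifier.
#' @slot dsc2dModelVsPhoto,dsc2dModelVsCtModel,dsc3d Dice values in [0,1] or NA.
#' @slot volumeMriMm3,volumeCtMm3 cartilage volumes, mm^3, or NA.
#' @slot registrationResidualMm final trimmed mean ICP correspondence
#'   distance, mm, or NA.
#' @slot alignmentChoices list recording modes, candidates chosen, seeds,
#'   ICP termination.
#' @export
setClass("CaseReport",
  representation(caseId = "character", dsc2dModelVsPhoto = "numeric",
                 dsc2dModelVsCtModel = "numeric", dsc3d = "numeric",
                 volumeMriMm3 = "numeric", volumeCtMm3 = "numeric",
                 registrationResidualMm = "numeric", alignmentChoices = "list"))

setValidity("CaseReport", function(object) {
  for (s in c("dsc2dModelVsPhoto", "dsc2dModelVsCtModel", "dsc3d")) {
    v <- slot(object, s)
    if (!is.na(v) && (v < 0 || v > 1)) return(sprintf("%s must be in [0,1]", s))
  }
  for (s in c("volumeMriMm3", "volumeCtMm3")) {
    v <- slot(object, s)
    if (!is.na(v) && v < 0) return(sprintf("%s must be >= 0", s))
  }
  TRUE
})

#' Cohort-level validation report
#'
#' @slot perCase list of \linkS4class{CaseReport}s.
#' @slot meanDsc2dPhoto,meanDsc2dCt,meanDsc3d arithmetic means of the
#'   per-case Dice fields.
#' @slot pearsonRVolumes,pearsonP Pearson correlation (and two-sided p-value)
#'   between MRI-model and CT-model cartilage volumes across cases.
#' @slot configHash md5 of the serialized pipeline configuration.
#' @slot seed master seed of the run.
#' @export
setClass("CohortReport",
  representation(perCase = "list", meanDsc2dPhoto = "numeric",
                 meanDsc2dCt = "numeric", meanDsc3d = "numeric",
                 pearsonRVolumes = "numeric", pearsonP = "numeric",
                 configHash = "character", seed = "integer"))
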