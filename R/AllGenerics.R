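# Accessor generics; slot access stays internal to the package.

#' @rdname LabelVolume-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname LabelVolume-class
#' @export
setGeneric("spacingMm", function(x) standardGeneric("spacingMm"))
#' @rdname LabelVolume-class
#' @export
setGeneric("originMm", function(x) standardGeneric("originMm"))
#' @rdname LabelVolume-class
#' @export
setGeneric("frameId", function(x) standardGeneric("frameId"))
#' @rdname SurfaceMesh-class
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname SurfaceMesh-class
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))
#' @rdname BinarySilhouette-class
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname BinarySilhouette-class
#' @export
setGeneric("mmPerPx", function(x) standardGeneric("mmPerPx"))
#' @rdname BinarySilhouette-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname RigidTransform-class
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))
#' @rdname RigidTransform-class
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))
#' @rdname LandmarkSet-class
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname LandmarkSet-class
#' @export
setGeneric("landmarkLabels", function(x) standardGeneric("landmarkLabels"))
#' @rdname OverlapResult-class
#' @export
setGeneric("dsc", function(x) standardGeneric("dsc"))

#' Apply a rigid transform to points, a mesh or a landmark set
#'
#' Every point p is replaced by \code{rotation \%*\% p + translation}; pairwise
#' distances are preserved. The frame tag of transformed container objects is
#' left for the caller to reinterpret.
#'
#' @param transform A \linkS4class{RigidTransform}.
#' @param x An N x 3 point matrix, \linkS4class{SurfaceMesh} or
#'   \linkS4class{LandmarkSet}.
#' @param frameId optional new frame tag for container results.
#' @return Object of the same type as \code{x}.
#' @export
setGeneric("applyTransform",
           function(transform, x, frameId = NULL) standardGeneric("applyTransform"))

#' @export
setMethod("voxels", "LabelVolume", function(x) x@voxels)
#' @export
setMethod("spacingMm", "LabelVolume", function(x) x@spacingMm)
#' @export
setMethod("originMm", "LabelVolume", function(x) x@originMm)
#' @export
setMethod("frameId", "LabelVolume", function(x) x@frameId)
#' @export
setMethod("frameId", "SurfaceMesh", function(x) x@frameId)
#' @export
setMethod("frameId", "LandmarkSet", function(x) x@frameId)
#' @export
setMethod("vertices", "SurfaceMesh", function(x) x@vertices)
#' @export
setMethod("faces", "SurfaceMesh", function(x) x@faces)
#' @export
setMethod("pixels", "BinarySilhouette", function(x) x@pixels)
#' @export
setMethod("mmPerPx", "BinarySilhouette", function(x) x@mmPerPx)
#' @export
setMethod("provenance", "BinarySilhouette", function(x) x@provenance)
#' @export
setMethod("rotation", "RigidTransform", function(x) x@rotation)
#' @export
setMethod("translation", "RigidTransform", function(x) x@translation)
#' @export
setMethod("coords", "LandmarkSet", function(x) x@points)
#' @export
setMethod("landmarkLabels", "LandmarkSet", function(x) x@labels)
#' @export
setMethod("dsc", "OverlapResult", function(x) x@dsc)

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@voxels)
  fg <- sum(object@voxels != 0L)
  cat(sprintf("LabelVolume [%s]: %d x %d x %d @ %.4g mm, %d foreground voxels (%.2f mm^3)\n",
              object@frameId, d[1], d[2], d[3], object@spacingMm, fg,
              fg * object@spacingMm^3))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh [%s]: %d vertices, %d faces\n",
              object@frameId, nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "BinarySilhouette", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BinarySilhouette [%s]: %d x %d px @ %.4g mm/px, area %.2f mm^2\n",
              object@provenance, d[1], d[2], object@mmPerPx,
              sum(object@pixels) * object@mmPerPx^2))
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: rotation %.3f deg, translation [%.3f, %.3f, %.3f] mm\n",
              rotationAngleDeg(object@rotation), object@translation[1],
              object@translation[2], object@translation[3]))
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet [%s]: 6 ordered landmarks\n", object@frameId))
  df <- data.frame(label = object@labels, object@points)
  colnames(df) <- c("label", "x_mm", "y_mm", "z_mm")
  print(df, digits = 4)
})

setMethod("show", "OverlapResult", function(object) {
  cat(sprintf("OverlapResult: DSC = %.4f (2*%d / (%d + %d) %s)\n",
              object@dsc, object@intersectionCount, object@aCount,
              object@bCount, object@units))
})

setMethod("show", "SyntheticCase", function(object) {
  cat("SyntheticCase\n")
  cat("  beta (thickness bias):", object@params@thicknessBias, "\n")
  cat("  "); show(object@ctVolume)
  cat("  "); show(object@mriVolume)
  cat("  "); show(object@photo)
  cat("  truth "); show(object@truth)
})

setMethod("show", "CaseReport", function(object) {
  cat(sprintf("CaseReport %s\n", object@caseId))
  cat(sprintf("  2D DSC model vs photo    : %.4f\n", object@dsc2dModelVsPhoto))
  cat(sprintf("  2D DSC model vs CT model : %.4f\n", object@dsc2dModelVsCtModel))
  cat(sprintf("  3D DSC after registration: %.4f\n", object@dsc3d))
  cat(sprintf("  volumes (MRI / CT)       : %.1f / %.1f mm^3\n",
              object@volumeMriMm3, object@volumeCtMm3))
  cat(sprintf("  registration residual    : %.3f mm\n",
              object@registrationResidualMm))
})

setMethod("show", "CohortReport", function(object) {
  cat(sprintf("CohortReport: %d cases\n", length(object@perCase)))
  cat(sprintf("  mean 2D DSC vs photo   : %.4f\n", object@meanDsc2dPhoto))
  cat(sprintf("  mean 2D DSC vs CT model: %.4f\n", object@meanDsc2dCt))
  cat(sprintf("  mean 3D DSC            : %.4f\n", object@meanDsc3d))
  cat(sprintf("  volume Pearson r (p)   : %.4f (%.3g)\n",
              object@pearsonRVolumes, object@pearsonP))
})
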