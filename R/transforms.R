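#' Identity rigid transform
#' @return The identity \linkS4class{RigidTransform}.
#' @export
identityTransform <- function() RigidTransform()

#' Elementary rotation matrix about a coordinate axis
#' @param axis "x", "y" or "z", or a length-3 axis vector.
#' @param angleDeg rotation angle in degrees (right-hand rule).
#' @return 3x3 rotation matrix.
#' @export
rotationAboutAxis <- function(axis, angleDeg) {
  if (is.character(axis))
    axis <- switch(match.arg(axis, c("x", "y", "z")),
                   x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  u <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Compose two rigid transforms
#'
#' \code{composeTransform(a, b)} is "a after b": the result maps p to
#' \code{a(b(p))}.
#' @param a,b \linkS4class{RigidTransform}s.
#' @return The composed \linkS4class{RigidTransform}.
#' @export
composeTransform <- function(a, b) {
  RigidTransform(a@rotation %*% b@rotation,
                 as.numeric(a@rotation %*% b@translation) + a@translation)
}

#' Invert a rigid transform
#' @param transform A \linkS4class{RigidTransform}.
#' @return The inverse \linkS4class{RigidTransform}.
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  RigidTransform(Rt, as.numeric(-Rt %*% transform@translation))
}

#' Rotation angle of a rotation matrix or transform, degrees
#'
#' The geodesic distance of R from the identity on SO(3), computed as
#' \code{atan2(|sin|, cos)} with the sine taken from the skew-symmetric part
#' and the cosine from the trace. This form stays accurate for tiny angles,
#' where the plain arccos-of-trace formula loses half the working precision.
#' @param x 3x3 rotation matrix or \linkS4class{RigidTransform}.
#' @return Angle in degrees in [0, 180].
#' @export
rotationAngleDeg <- function(x) {
  R <- if (is(x, "RigidTransform")) x@rotation else x
  s <- sqrt(sum((R - t(R))^2)) / (2 * sqrt(2))   # |sin(theta)|
  co <- (sum(diag(R)) - 1) / 2                   # cos(theta)
  atan2(min(s, 1), max(-1, min(1, co))) * 180 / pi
}

#' Geodesic rotation distance between two transforms, degrees
#' @param a,b \linkS4class{RigidTransform}s.
#' @return Rotation angle of \code{a^-1 b} in degrees.
#' @export
rotationDistanceDeg <- function(a, b) rotationAngleDeg(crossprod(a@rotation, b@rotation))

#' Translation distance between two transforms, mm
#' @param a,b \linkS4class{RigidTransform}s.
#' @return Euclidean distance between the translation vectors, mm.
#' @export
translationDistanceMm <- function(a, b) sqrt(sum((a@translation - b@translation)^2))

#' Draw a random rigid transform
#'
#' Uniform random rotation axis, rotation angle uniform in
#' \code{[0, maxAngleDeg]}, translation uniform in the ball of radius
#' \code{maxTranslationMm}. Uses the current RNG stream.
#' @param maxAngleDeg maximum rotation angle, degrees.
#' @param maxTranslationMm maximum translation norm, mm.
#' @return A \linkS4class{RigidTransform}.
#' @export
randomRigidTransform <- function(maxAngleDeg = 25, maxTranslationMm = 15) {
  ax <- stats::rnorm(3)
  R <- rotationAboutAxis(ax, stats::runif(1, 0, maxAngleDeg))
  d <- stats::rnorm(3)
  d <- d / sqrt(sum(d^2)) * maxTranslationMm * stats::runif(1)^(1 / 3)
  RigidTransform(R, d)
}

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature(x = "matrix"),
  function(transform, x, frameId = NULL) {
    stopifnot(ncol(x) == 3L)
    sweep(x %*% t(transform@rotation), 2, transform@translation, "+")
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature(x = "SurfaceMesh"),
  function(transform, x, frameId = NULL) {
    SurfaceMesh(applyTransform(transform, x@vertices), x@faces,
                frameId = if (is.null(frameId)) x@frameId else frameId)
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature(x = "LandmarkSet"),
  function(transform, x, frameId = NULL) {
    LandmarkSet(applyTransform(transform, x@points), x@labels,
                frameId = if (is.null(frameId)) x@frameId else frameId)
  })
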