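# Track B: closed-form rigid alignment from the six ordered landmarks,
# refined by trimmed point-to-point ICP on surface point clouds.

# Closed-form least-squares rigid fit (cross-covariance SVD with
# proper-rotation correction). Returns the transform mapping src to dst.
.kabsch <- function(src, dst, warn = TRUE) {
  cs <- colMeans(src); cd <- colMeans(dst)
  H <- crossprod(sweep(src, 2, cs), sweep(dst, 2, cd))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d < 0 && warn)
    warning("rigid fit: configuration favours a reflection; proper rotation enforced")
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  RigidTransform(R, as.numeric(cd - R %*% cs))
}

#' Least-squares rigid alignment of two ordered landmark sets
#'
#' Computes the rigid transform minimising the sum of squared distances
#' between the transformed source landmarks and the destination landmarks
#' (correspondence is by index), via the closed-form cross-covariance SVD
#' with proper-rotation correction. This is the preliminary registration
#' before ICP refinement.
#'
#' @param src,dst \linkS4class{LandmarkSet}s (6 points each, ordered).
#' @return List with \code{transform} (the \linkS4class{RigidTransform}
#'   src -> dst) and \code{rmsdMm} (residual root-mean-square distance).
#' @export
landmarkAlign <- function(src, dst) {
  stopifnot(is(src, "LandmarkSet"), is(dst, "LandmarkSet"))
  P <- src@points; Q <- dst@points
  sv <- svd(scale(P, scale = FALSE))$d
  if (sv[2] <= 1e-9 * max(sv[1], 1))
    stop("landmarkAlign: source landmarks are collinear")
  tr <- .kabsch(P, Q)
  res <- applyTransform(tr, P) - Q
  list(transform = tr, rmsdMm = sqrt(mean(rowSums(res^2))))
}

#' ICP configuration
#'
#' @param maxIter maximum iterations (default 1000; the tangential
#'   components of the pose converge slowly under point-to-point
#'   correspondence on quasi-planar surfaces, so the cap is generous).
#' @param tolMm convergence tolerance on the change in trimmed RMS
#'   correspondence distance, mm (default 1e-6).
#' @param samplePoints surface points sampled from the source (evaluated)
#'   surface (default 10000; sparser clouds leave a tangential sampling-noise
#'   floor above the accuracy the registration is asked for); the
#'   destination (reference) surface is sampled
#'   \code{dstOversample} times denser so nearest-neighbour distances
#'   approximate true point-to-surface distances.
#' @param dstOversample density factor for the destination cloud (default 6).
#' @param outlierTrimFraction fraction of worst correspondences discarded per
#'   iteration, in [0, 0.5) (default 0.1; absorbs imperfect correspondence
#'   between modalities).
#' @return List of class "ICPConfig".
#' @export
icpConfig <- function(maxIter = 1000L, tolMm = 1e-6, samplePoints = 10000L,
                      outlierTrimFraction = 0.1, dstOversample = 6L) {
  stopifnot(maxIter >= 1, tolMm > 0, dstOversample >= 1,
            outlierTrimFraction >= 0, outlierTrimFraction < 0.5)
  structure(list(maxIter = as.integer(maxIter), tolMm = tolMm,
                 samplePoints = as.integer(samplePoints),
                 outlierTrimFraction = outlierTrimFraction,
                 dstOversample = as.integer(dstOversample)),
            class = "ICPConfig")
}

#' Sample a surface point cloud from a label volume
#'
#' Extracts the iso-surface mesh of the mask and samples \code{n} points
#' uniformly by area (faces drawn with probability proportional to area,
#' sampling with replacement, uniform barycentric placement within each
#' face). Deterministic under \code{seed}.
#'
#' @param v A \linkS4class{LabelVolume} with non-empty foreground.
#' @param n number of points.
#' @param seed RNG seed.
#' @param label label to extract (default 1).
#' @return n x 3 matrix of mm coordinates in the volume's frame.
#' @export
surfaceCloud <- function(v, n = 5000L, seed = 1L, label = 1L) {
  mesh <- maskToMesh(v, label)
  V <- mesh@vertices; F <- mesh@faces
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  w <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  area <- sqrt(rowSums(cr^2)) / 2
  withr::with_seed(as.integer(seed), {
    fi <- sample.int(nrow(F), n, replace = TRUE, prob = area)
    r1 <- stats::runif(n); r2 <- stats::runif(n)
    flip <- r1 + r2 > 1
    r1[flip] <- 1 - r1[flip]; r2[flip] <- 1 - r2[flip]
    V[F[fi, 1], , drop = FALSE] + r1 * u[fi, , drop = FALSE] + r2 * w[fi, , drop = FALSE]
  })
}

#' Trimmed point-to-point ICP refinement
#'
#' Iterates: exact nearest-neighbour correspondence from the transformed
#' source cloud to the destination cloud; discard the worst
#' \code{outlierTrimFraction} by distance; closed-form rigid update on the
#' kept pairs. Terminates when the trimmed mean correspondence distance
#' changes by less than \code{tolMm}, or at \code{maxIter}.
#'
#' When \code{outlierTrimFraction > 0} the iteration runs in two phases:
#' first untrimmed to convergence, then trimmed. Trimming a fixed fraction
#' from the start can silently discard exactly the high-curvature rim and
#' ridge correspondences that constrain tangential motion while the clouds
#' are still far apart, stalling the registration in a flat valley; once the
#' untrimmed phase has locked the pose, the trimmed phase provides the
#' robustness to imperfect correspondences that the trimming is for. The
#' recorded per-iteration RMS distance is non-increasing within each phase
#' and across the phase boundary (the trimmed RMS never exceeds the
#' untrimmed RMS at the same pose).
#'
#' @param srcCloud,dstCloud point clouds (N x 3 mm matrices); src is the
#'   model under evaluation (MRI), dst the gold standard (CT).
#' @param init initial \linkS4class{RigidTransform} (e.g. from
#'   \code{\link{landmarkAlign}}).
#' @param cfg An \code{\link{icpConfig}}.
#' @return List with \code{transform} (refined \linkS4class{RigidTransform}),
#'   and \code{diagnostics}: a list holding the per-iteration data frame
#'   (\code{iterations}), \code{terminationReason} ("tolerance" or
#'   "max_iter"), and \code{finalMeanDistanceMm}.
#' @export
icpRefine <- function(srcCloud, dstCloud, init = identityTransform(),
                      cfg = icpConfig()) {
  srcCloud <- as.matrix(srcCloud); dstCloud <- as.matrix(dstCloud)
  if (!nrow(srcCloud) || !nrow(dstCloud))
    stop("icpRefine: point clouds must be non-empty")
  if (any(!is.finite(srcCloud)) || any(!is.finite(dstCloud)))
    stop("icpRefine: non-finite coordinates in point cloud")
  n <- nrow(srcCloud)
  phases <- if (cfg$outlierTrimFraction > 0) {
    c(n, max(3L, ceiling((1 - cfg$outlierTrimFraction) * n)))
  } else n
  transform <- init
  hist <- list()
  reason <- "max_iter"
  it <- 0L
  for (ph in seq_along(phases)) {
    nKeep <- phases[ph]
    prev <- Inf
    reason <- "max_iter"
    while (it < cfg$maxIter) {
      it <- it + 1L
      moved <- applyTransform(transform, srcCloud)
      nn <- .cpp_nearest_neighbour(moved, dstCloud)
      keep <- order(nn$distance)[seq_len(nKeep)]
      rmsDist <- sqrt(mean(nn$distance[keep]^2))
      hist[[it]] <- data.frame(iteration = it, phase = ph,
                               meanDistanceMm = mean(nn$distance[keep]),
                               rmsDistanceMm = rmsDist, nKept = nKeep)
      if (abs(prev - rmsDist) < cfg$tolMm) { reason <- "tolerance"; break }
      prev <- rmsDist
      transform <- .kabsch(srcCloud[keep, , drop = FALSE],
                           dstCloud[nn$index[keep], , drop = FALSE],
                           warn = FALSE)
    }
    if (it >= cfg$maxIter && reason == "max_iter" && ph < length(phases)) next
  }
  iterations <- do.call(rbind, hist)
  list(transform = transform,
       diagnostics = list(iterations = iterations,
                          terminationReason = reason,
                          finalMeanDistanceMm = iterations$meanDistanceMm[nrow(iterations)]))
}

#' Randomly perturb a rigid transform
#'
#' Composes \code{transform} with a random rotation of at most
#' \code{maxAngleDeg} and a random translation of at most
#' \code{maxTranslationMm}; used to build controlled initialisations for
#' convergence experiments. Uses the current RNG stream.
#'
#' @param transform A \linkS4class{RigidTransform}.
#' @param maxAngleDeg,maxTranslationMm perturbation bounds.
#' @return A perturbed \linkS4class{RigidTransform}.
#' @export
perturbTransform <- function(transform, maxAngleDeg, maxTranslationMm) {
  composeTransform(randomRigidTransform(maxAngleDeg, maxTranslationMm), transform)
}
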