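# Overlap and association statistics: 2D and 3D Dice, cartilage volume,
# Pearson correlation.

.overlapResult <- function(inter, na, nb, units) {
  new("OverlapResult", dsc = 2 * inter / (na + nb),
      intersectionCount = as.numeric(inter), aCount = as.numeric(na),
      bCount = as.numeric(nb), units = units)
}

#' 2D Dice similarity coefficient of two silhouettes
#'
#' DSC = 2|A intersect B| / (|A| + |B|) over foreground pixels; symmetric in
#' its arguments. The silhouettes must already share grid shape and pixel
#' scale — use \code{\link{alignSilhouettes}} first. Two empty masks are an
#' error (0/0 is undefined, and silently returning a value would hide
#' pipeline failures).
#'
#' @param a,b \linkS4class{BinarySilhouette}s on the same grid.
#' @return An \linkS4class{OverlapResult} with units "px".
#' @export
dsc2d <- function(a, b) {
  stopifnot(is(a, "BinarySilhouette"), is(b, "BinarySilhouette"))
  if (!identical(dim(a@pixels), dim(b@pixels)))
    stop("dsc2d: silhouettes have different grid shapes; align them first (alignSilhouettes)")
  if (abs(a@mmPerPx - b@mmPerPx) > 1e-12)
    stop("dsc2d: silhouettes have different mm-per-pixel scales; align them first (alignSilhouettes)")
  na <- sum(a@pixels); nb <- sum(b@pixels)
  if (na + nb == 0L)
    stop("dsc2d: both silhouettes are empty (0/0 DSC undefined)")
  .overlapResult(sum(a@pixels & b@pixels), na, nb, "px")
}

#' 3D Dice similarity coefficient after rigid registration
#'
#' Resamples the source volume (MRI frame) through \code{transform} onto the
#' grid of the destination volume (CT frame) — the finer of the two grids, so
#' resampling loss is minimised — and computes the Dice coefficient over
#' foreground voxels on that grid. Counts are reported so the quotient can be
#' recomputed.
#'
#' @param a source \linkS4class{LabelVolume} (MRI frame).
#' @param b destination \linkS4class{LabelVolume} (CT frame).
#' @param transform \linkS4class{RigidTransform} mapping a's frame to b's.
#' @param label foreground label (default 1).
#' @return An \linkS4class{OverlapResult} with units "voxel".
#' @export
dsc3d <- function(a, b, transform, label = 1L) {
  stopifnot(is(a, "LabelVolume"), is(b, "LabelVolume"))
  if (!any(a@voxels == label) || !any(b@voxels == label))
    stop("dsc3d: empty foreground in input volume")
  ra <- resampleVolume(a, transform, b)
  fa <- ra@voxels == label
  fb <- b@voxels == label
  .overlapResult(sum(fa & fb), sum(fa), sum(fb), "voxel")
}

#' Cartilage volume of a label, mm^3
#'
#' Definitionally \code{count(voxels == label) * spacingMm^3}.
#'
#' @param v A \linkS4class{LabelVolume}.
#' @param label the label to measure (default 1).
#' @return Volume in mm^3; 0 with a warning if the label is absent.
#' @export
cartilageVolume <- function(v, label = 1L) {
  stopifnot(is(v, "LabelVolume"))
  n <- sum(v@voxels == label)
  if (n == 0L)
    warning(sprintf("cartilageVolume: label %d absent from volume; returning 0", label))
  n * v@spacingMm^3
}

#' Pearson correlation with two-sided p-value
#'
#' Covariance over the product of standard deviations; p-value from the
#' t distribution with n - 2 degrees of freedom (via \code{stats::cor.test}).
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant.
#' @return List with \code{r}, \code{pValue}, \code{n}.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y))
    stop("pearsonR: x and y have different lengths")
  if (length(x) < 3)
    stop("pearsonR: need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearsonR: correlation undefined for constant input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), pValue = ct$p.value, n = length(x))
}
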