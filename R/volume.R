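# Voxel-grid and mesh operations shared by both validation tracks.

# world coordinates of all voxel centres of a grid, as an N x 3 matrix,
# in the grid's own frame; column-major voxel order
.gridCentres <- function(dims, spacing, origin) {
  n <- prod(dims)
  idx <- seq_len(n) - 1L
  i <- idx %% dims[1]
  j <- (idx %/% dims[1]) %% dims[2]
  k <- idx %/% (dims[1] * dims[2])
  cbind(origin[1] + spacing * i, origin[2] + spacing * j, origin[3] + spacing * k)
}

#' Resample a label volume through a rigid transform onto a target grid
#'
#' Nearest-neighbour label resampling: each target voxel centre is mapped back
#' through \code{transform} (which takes the source frame to the target frame)
#' into the source grid and takes the label of the nearest source voxel.
#' Nearest-neighbour interpolation is used because averaging labels would
#' create values that are not labels. Output labels are therefore a subset of
#' the input labels.
#'
#' @param v source \linkS4class{LabelVolume}.
#' @param transform \linkS4class{RigidTransform} mapping v's frame to the
#'   target frame.
#' @param target \linkS4class{LabelVolume} supplying the output geometry
#'   (dims, spacing, origin, frame); its voxel values are ignored.
#' @return A \linkS4class{LabelVolume} on the target grid.
#' @details If the transformed source does not overlap the target grid at all,
#'   an all-background volume is returned with a warning.
#' @export
resampleVolume <- function(v, transform, target) {
  stopifnot(is(v, "LabelVolume"), is(transform, "RigidTransform"),
            is(target, "LabelVolume"))
  dims <- dim(target@voxels)
  src <- v@voxels
  sdim <- dim(src)
  ctr <- .gridCentres(dims, target@spacingMm, target@originMm)
  inv <- invertTransform(transform)
  p <- applyTransform(inv, ctr)
  ii <- as.integer(round((p[, 1] - v@originMm[1]) / v@spacingMm)) + 1L
  jj <- as.integer(round((p[, 2] - v@originMm[2]) / v@spacingMm)) + 1L
  kk <- as.integer(round((p[, 3] - v@originMm[3]) / v@spacingMm)) + 1L
  ok <- ii >= 1L & ii <= sdim[1] & jj >= 1L & jj <= sdim[2] &
        kk >= 1L & kk <= sdim[3]
  out <- integer(prod(dims))
  if (any(ok))
    out[ok] <- src[cbind(ii[ok], jj[ok], kk[ok])]
  if (!any(out != 0L) && any(src != 0L))
    warning("resampleVolume: transformed source has no overlap with the target grid; returning all-background volume")
  dim(out) <- dims
  LabelVolume(out, target@spacingMm, target@originMm, frameId = target@frameId)
}

#' Extract the iso-surface mesh of a label from a volume
#'
#' Marching-tetrahedra surface at the 0.5 iso-level of the binary indicator
#' of \code{label}, with vertices in world mm coordinates of the volume's
#' frame. The volume is padded with one background voxel on every side so the
#' surface is closed (watertight) for any solid mask.
#'
#' @param v A \linkS4class{LabelVolume}.
#' @param label the label to extract (default 1).
#' @return A \linkS4class{SurfaceMesh} with outward-oriented faces.
#' @export
maskToMesh <- function(v, label = 1L) {
  ind <- v@voxels == label
  if (!any(ind))
    stop(sprintf("maskToMesh: label %d is absent from the volume (empty mask)", label))
  d <- dim(ind)
  pad <- array(0, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- as.numeric(ind)
  res <- .cpp_marching_tets(as.numeric(pad), dim(pad), 0.5)
  # padded 0-based index c maps to original 0-based voxel index (c - 1),
  # whose world centre is origin + spacing * (c - 1)
  V <- res$vertices
  W <- cbind(v@originMm[1] + v@spacingMm * (V[, 1] - 1),
             v@originMm[2] + v@spacingMm * (V[, 2] - 1),
             v@originMm[3] + v@spacingMm * (V[, 3] - 1))
  SurfaceMesh(W, res$faces, frameId = v@frameId)
}

#' Enclosed volume of a closed mesh, mm^3
#'
#' Divergence-theorem signed volume; positive for outward-oriented closed
#' surfaces.
#' @param mesh A \linkS4class{SurfaceMesh}.
#' @return Volume in mm^3.
#' @export
meshVolume <- function(mesh) {
  V <- mesh@vertices; F <- mesh@faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c[, 3] - b[, 3] * c[, 2],
              b[, 3] * c[, 1] - b[, 1] * c[, 3],
              b[, 1] * c[, 2] - b[, 2] * c[, 1])
  sum(rowSums(a * cr)) / 6
}

#' Total surface area of a mesh, mm^2
#' @param mesh A \linkS4class{SurfaceMesh}.
#' @return Area in mm^2.
#' @export
meshArea <- function(mesh) {
  V <- mesh@vertices; F <- mesh@faces
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  w <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Euler characteristic V - E + F of a mesh
#'
#' Equals 2 for a watertight genus-0 surface; used as the closedness check on
#' extracted masks.
#' @param mesh A \linkS4class{SurfaceMesh}.
#' @return Integer Euler characteristic.
#' @export
eulerCharacteristic <- function(mesh) {
  F <- mesh@faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  nE <- nrow(unique(e))
  nrow(mesh@vertices) - nE + nrow(F)
}

#' Analytic UV-sphere mesh
#'
#' Latitude/longitude triangulated sphere, used as an analytic ground-truth
#' shape for silhouette and volume calibration.
#' @param radiusMm sphere radius, mm.
#' @param centreMm centre, mm.
#' @param nSegments longitudinal segments (default 96); latitudinal rings are
#'   half that.
#' @param frameId frame tag.
#' @return A watertight \linkS4class{SurfaceMesh} with outward normals.
#' @export
meshSphere <- function(radiusMm, centreMm = c(0, 0, 0), nSegments = 96,
                       frameId = "synthetic-world") {
  nlon <- as.integer(nSegments)
  nlat <- as.integer(nSegments / 2)
  # interior ring vertices + 2 poles
  theta <- pi * seq_len(nlat - 1) / nlat          # colatitude of rings
  phi <- 2 * pi * (seq_len(nlon) - 1) / nlon
  ring <- function(th) cbind(radiusMm * sin(th) * cos(phi),
                             radiusMm * sin(th) * sin(phi),
                             rep(radiusMm * cos(th), nlon))
  V <- do.call(rbind, lapply(theta, ring))
  npole <- nrow(V) + 1L
  spole <- nrow(V) + 2L
  V <- rbind(V, c(0, 0, radiusMm), c(0, 0, -radiusMm))
  V <- sweep(V, 2, centreMm, "+")
  idx <- function(r, l) (r - 1L) * nlon + ((l - 1L) %% nlon) + 1L
  F <- list()
  for (l in seq_len(nlon)) {
    F[[length(F) + 1L]] <- c(npole, idx(1, l), idx(1, l + 1))
    F[[length(F) + 1L]] <- c(spole, idx(nlat - 1, l + 1), idx(nlat - 1, l))
  }
  if (nlat > 2) for (r in seq_len(nlat - 2)) for (l in seq_len(nlon)) {
    a <- idx(r, l); b <- idx(r, l + 1); cc <- idx(r + 1, l); d <- idx(r + 1, l + 1)
    F[[length(F) + 1L]] <- c(a, cc, b)
    F[[length(F) + 1L]] <- c(b, cc, d)
  }
  SurfaceMesh(V, do.call(rbind, F), frameId = frameId)
}
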