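# File I/O for every domain type. Formats: NIfTI (.nii/.nii.gz) and
# MetaImage (.mha) for label volumes; ASCII STL/PLY for meshes; PNG with a
# JSON sidecar (pixel scale + provenance) for silhouettes; CSV for landmark
# sets; JSON (4x4 homogeneous matrix) for rigid transforms.

.isoTol <- 1e-6

#' Read a label volume from NIfTI or MetaImage
#'
#' Only axis-aligned grids with isotropic spacing are accepted; anisotropic or
#' oblique inputs are rejected with an error (the resampling and volume
#' bookkeeping in this package assume isotropic voxels).
#'
#' @param path file path ending in .nii, .nii.gz or .mha.
#' @param frameId frame tag to attach to the result.
#' @return A \linkS4class{LabelVolume}.
#' @export
readLabelVolume <- function(path, frameId = "unknown") {
  if (!file.exists(path)) stop("readLabelVolume: file not found: ", path)
  if (grepl("\\.mha$", path, ignore.case = TRUE))
    return(.readMha(path, frameId))
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3) stop("readLabelVolume: malformed NIfTI: pixdim has fewer than 3 entries")
  if (max(pd[1:3]) - min(pd[1:3]) > .isoTol * max(pd[1:3]))
    stop(sprintf("readLabelVolume: anisotropic spacing [%s] is not supported; resample to an isotropic grid first",
                 paste(signif(pd[1:3], 6), collapse = ", ")))
  xf <- RNifti::xform(img)
  Rpart <- xf[1:3, 1:3]
  if (max(abs(Rpart - diag(diag(Rpart)))) > 1e-6 * max(abs(Rpart)))
    stop("readLabelVolume: oblique NIfTI orientation is not supported")
  v <- as.array(img)
  v <- array(as.vector(v), dim = dim(v))   # drop the niftiImage class
  if (length(dim(v)) != 3L) stop("readLabelVolume: expected a 3D volume, got dim ",
                                 paste(dim(v), collapse = "x"))
  if (any(v != round(v)) || min(v) < 0)
    stop("readLabelVolume: malformed label volume: voxel values must be non-negative integers")
  LabelVolume(v, pd[1], xf[1:3, 4], frameId = frameId)
}

#' Write a label volume to NIfTI or MetaImage
#' @param v A \linkS4class{LabelVolume}.
#' @param path output path (.nii, .nii.gz or .mha).
#' @return \code{path}, invisibly.
#' @export
writeLabelVolume <- function(v, path) {
  stopifnot(is(v, "LabelVolume"))
  if (grepl("\\.mha$", path, ignore.case = TRUE)) return(.writeMha(v, path))
  img <- RNifti::asNifti(v@voxels)
  RNifti::pixdim(img) <- rep(v@spacingMm, 3)
  aff <- diag(c(rep(v@spacingMm, 3), 1))
  aff[1:3, 4] <- v@originMm
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Minimal MetaImage (.mha) support: uncompressed, local data, MET_INT.
.writeMha <- function(v, path) {
  d <- dim(v@voxels)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           sprintf("TransformMatrix = 1 0 0 0 1 0 0 0 1"),
           sprintf("Offset = %.9g %.9g %.9g", v@originMm[1], v@originMm[2], v@originMm[3]),
           sprintf("ElementSpacing = %.9g %.9g %.9g", v@spacingMm, v@spacingMm, v@spacingMm),
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           "ElementType = MET_INT", "ElementDataFile = LOCAL")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.integer(v@voxels), con, size = 4L, endian = "little")
  invisible(path)
}

.readMha <- function(path, frameId) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("readLabelVolume: malformed MetaImage header: missing ElementDataFile")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("readLabelVolume: malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  need <- function(k) {
    if (is.null(hdr[[k]])) stop("readLabelVolume: MetaImage header missing field: ", k)
    hdr[[k]]
  }
  if (need("ElementDataFile") != "LOCAL")
    stop("readLabelVolume: only ElementDataFile = LOCAL MetaImage files are supported")
  if (need("ElementType") != "MET_INT")
    stop("readLabelVolume: unsupported ElementType (field ElementType): ", hdr$ElementType)
  d <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
  sp <- as.numeric(strsplit(need("ElementSpacing"), "\\s+")[[1]])
  if (max(sp) - min(sp) > .isoTol * max(sp))
    stop("readLabelVolume: anisotropic spacing (field ElementSpacing) is not supported")
  off <- as.numeric(strsplit(need("Offset"), "\\s+")[[1]])
  vox <- readBin(con, "integer", n = prod(d), size = 4L, endian = "little")
  if (length(vox) != prod(d))
    stop("readLabelVolume: truncated MetaImage data block (field DimSize inconsistent)")
  dim(vox) <- d
  LabelVolume(vox, sp[1], off, frameId = frameId)
}

#' Read / write a surface mesh (ASCII STL or PLY)
#'
#' Coordinates survive a round trip within 1e-6 mm. STL files duplicate
#' vertices per facet; on read, identical coordinates are merged back into a
#' shared vertex table.
#'
#' @param path file path ending in .stl or .ply.
#' @param frameId frame tag.
#' @return \code{readSurfaceMesh}: a \linkS4class{SurfaceMesh}.
#' @export
readSurfaceMesh <- function(path, frameId = "unknown") {
  if (!file.exists(path)) stop("readSurfaceMesh: file not found: ", path)
  if (grepl("\\.ply$", path, ignore.case = TRUE)) return(.readPly(path, frameId))
  lines <- readLines(path)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) stop("readSurfaceMesh: malformed STL: no vertex records found")
  if (length(vl) %% 3 != 0) stop("readSurfaceMesh: malformed STL: vertex count not a multiple of 3")
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4])))
  if (any(!is.finite(nums))) stop("readSurfaceMesh: malformed STL: non-numeric vertex coordinates")
  key <- apply(nums, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  V <- nums[uk, , drop = FALSE]
  F <- matrix(vid, ncol = 3, byrow = TRUE)
  SurfaceMesh(V, F, frameId = frameId)
}

#' @rdname readSurfaceMesh
#' @param mesh A \linkS4class{SurfaceMesh}.
#' @return \code{writeSurfaceMesh}: \code{path}, invisibly.
#' @export
writeSurfaceMesh <- function(mesh, path) {
  stopifnot(is(mesh, "SurfaceMesh"))
  if (grepl("\\.ply$", path, ignore.case = TRUE)) return(.writePly(mesh, path))
  V <- mesh@vertices; F <- mesh@faces
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  w <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  for (t in seq_len(nrow(F))) {
    writeLines(sprintf("facet normal %.9g %.9g %.9g", n[t, 1], n[t, 2], n[t, 3]), con)
    writeLines("  outer loop", con)
    for (c in 1:3)
      writeLines(sprintf("    vertex %.9g %.9g %.9g",
                         V[F[t, c], 1], V[F[t, c], 2], V[F[t, c], 3]), con)
    writeLines("  endloop", con)
    writeLines("endfacet", con)
  }
  writeLines("endsolid mesh", con)
  invisible(path)
}

.writePly <- function(mesh, path) {
  V <- mesh@vertices; F <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(F)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
  invisible(path)
}

.readPly <- function(path, frameId) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "ply") stop("readSurfaceMesh: malformed PLY: missing magic line")
  endH <- match("end_header", lines)
  if (is.na(endH)) stop("readSurfaceMesh: malformed PLY: missing end_header")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", lines, value = TRUE)))
  if (!length(nv) || !length(nf)) stop("readSurfaceMesh: malformed PLY: missing element counts")
  vlines <- lines[(endH + 1):(endH + nv)]
  flines <- lines[(endH + nv + 1):(endH + nv + nf)]
  V <- do.call(rbind, lapply(strsplit(vlines, "\\s+"), function(x) as.numeric(x[1:3])))
  F <- do.call(rbind, lapply(strsplit(flines, "\\s+"), function(x) as.integer(x[2:4]) + 1L))
  if (any(!is.finite(V))) stop("readSurfaceMesh: malformed PLY: non-numeric vertex data")
  SurfaceMesh(V, F, frameId = frameId)
}

#' Read / write a binary silhouette (PNG + JSON sidecar)
#'
#' The PNG stores the boolean mask; the sidecar \code{<path>.json} stores
#' \code{mm_per_px} and \code{provenance}, without which the image has no
#' physical scale.
#'
#' @param path PNG file path.
#' @return \code{readSilhouette}: a \linkS4class{BinarySilhouette}.
#' @export
readSilhouette <- function(path) {
  if (!file.exists(path)) stop("readSilhouette: file not found: ", path)
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("readSilhouette: missing sidecar (field mm_per_px unavailable): ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$mm_per_px))
    stop("readSilhouette: sidecar is missing field mm_per_px")
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  BinarySilhouette(img > 0.5, meta$mm_per_px,
                   provenance = if (is.null(meta$provenance)) "photo" else meta$provenance)
}

#' @rdname readSilhouette
#' @param s A \linkS4class{BinarySilhouette}.
#' @return \code{writeSilhouette}: \code{path}, invisibly.
#' @export
writeSilhouette <- function(s, path) {
  stopifnot(is(s, "BinarySilhouette"))
  png::writePNG(s@pixels * 1, path)
  jsonlite::write_json(list(mm_per_px = s@mmPerPx, provenance = s@provenance),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a landmark set (CSV with columns label,x,y,z)
#'
#' @param path CSV path.
#' @param frameId frame tag.
#' @return \code{readLandmarks}: a \linkS4class{LandmarkSet}.
#' @export
readLandmarks <- function(path, frameId = "unknown") {
  if (!file.exists(path)) stop("readLandmarks: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(colnames(df), c("label", "x", "y", "z")))
    stop("readLandmarks: malformed landmark CSV: expected columns label,x,y,z, got: ",
         paste(colnames(df), collapse = ","))
  if (nrow(df) != 6L)
    stop("readLandmarks: malformed landmark CSV: expected exactly 6 rows, got ", nrow(df))
  if (any(!is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop("readLandmarks: malformed landmark CSV: non-numeric coordinate in columns x,y,z")
  LandmarkSet(as.matrix(df[, c("x", "y", "z")]), df$label, frameId = frameId)
}

#' @rdname readLandmarks
#' @param lm A \linkS4class{LandmarkSet}.
#' @return \code{writeLandmarks}: \code{path}, invisibly.
#' @export
writeLandmarks <- function(lm, path) {
  stopifnot(is(lm, "LandmarkSet"))
  df <- data.frame(label = lm@labels, x = lm@points[, 1], y = lm@points[, 2],
                   z = lm@points[, 3])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a rigid transform (JSON, 4x4 homogeneous matrix)
#' @param path JSON path.
#' @return \code{readTransform}: a \linkS4class{RigidTransform}.
#' @export
readTransform <- function(path) {
  if (!file.exists(path)) stop("readTransform: file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$matrix)) stop("readTransform: malformed transform JSON: missing field matrix")
  M <- as.matrix(obj$matrix)
  if (!identical(dim(M), c(4L, 4L)))
    stop("readTransform: malformed transform JSON: field matrix is not 4x4")
  RigidTransform(M[1:3, 1:3], M[1:3, 4])
}

#' @rdname readTransform
#' @param transform A \linkS4class{RigidTransform}.
#' @return \code{writeTransform}: \code{path}, invisibly.
#' @export
writeTransform <- function(transform, path) {
  stopifnot(is(transform, "RigidTransform"))
  M <- rbind(cbind(transform@rotation, transform@translation), c(0, 0, 0, 1))
  jsonlite::write_json(list(matrix = M), path, digits = NA, matrix = "rowmajor")
  invisible(path)
}
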