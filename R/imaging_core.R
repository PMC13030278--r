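#' Construct a VoxelGrid
#'
#' @param shape integer(3), voxels per axis.
#' @param spacing numeric(3), mm per axis. Ignored when \code{transform} is
#'   given (spacing is then taken from the transform's column norms).
#' @param transform optional 4x4 voxel-to-world affine (0-based indices ->
#'   mm). Defaults to a diagonal scaling by \code{spacing}.
#' @param orientation axis-direction code, default "RAS".
#' @return a [VoxelGrid-class]
#' @export
VoxelGrid <- function(shape, spacing = c(1, 1, 1), transform = NULL,
                      orientation = "RAS") {
  shape <- as.integer(shape)
  if (is.null(transform)) {
    transform <- diag(c(spacing, 1))
  } else {
    spacing <- sqrt(colSums(transform[1:3, 1:3]^2))
  }
  new("VoxelGrid", shape = shape, spacing = as.numeric(spacing),
      transform = transform, orientation = orientation)
}

#' Construct a ScalarVolume from an array
#'
#' @param values numeric 3D array.
#' @param grid a [VoxelGrid-class]; defaults to unit 1 mm spacing.
#' @return a [ScalarVolume-class]
#' @export
ScalarVolume <- function(values, grid = VoxelGrid(dim(values))) {
  storage.mode(values) <- "double"
  new("ScalarVolume", grid = grid, values = values)
}

#' Construct a BinaryMask from an array
#'
#' Non-logical input is binarized as \code{values > 0.5}.
#'
#' @param values 3D array (logical, 0/1, or probabilistic).
#' @param grid a [VoxelGrid-class]; defaults to unit 1 mm spacing.
#' @return a [BinaryMask-class]
#' @export
BinaryMask <- function(values, grid = VoxelGrid(dim(values))) {
  v <- if (is.logical(values)) values else values > 0.5
  a <- array(as.integer(v), dim = dim(values))
  new("BinaryMask", grid = grid, values = a)
}

#' Accessors for image objects
#'
#' \code{imgGrid} returns the [VoxelGrid-class]; \code{imgValues} the value
#' array; \code{voxelCount} the number of positive voxels of a mask.
#'
#' @param x a [ScalarVolume-class] or [BinaryMask-class] (or, for
#'   \code{voxelVolume}, also a [VoxelGrid-class]).
#' @return see individual descriptions.
#' @export
imgGrid <- function(x) x@grid

#' @rdname imgGrid
#' @export
imgValues <- function(x) x@values

#' @rdname imgGrid
#' @export
voxelCount <- function(x) {
  stopifnot(is(x, "BinaryMask"))
  sum(x@values)
}

#' Voxel volume in cubic millimetres
#'
#' The product of the three spacing entries: the physical volume of one
#' voxel, used to convert voxel counts to volumes.
#'
#' @param x a [VoxelGrid-class], [ScalarVolume-class] or [BinaryMask-class].
#' @return numeric(1), mm^3 per voxel.
#' @export
voxelVolume <- function(x) {
  g <- if (is(x, "VoxelGrid")) x else x@grid
  prod(g@spacing)
}

.dim3 <- function(img) c(dim(img), 1L, 1L)[1:3]

.gridFromNifti <- function(img) {
  tf <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  tf <- matrix(as.numeric(tf), 4, 4)
  VoxelGrid(.dim3(img), transform = tf,
            orientation = RNifti::orientation(img))
}

.readCanonical <- function(path, takeFirstOf4D) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (nd > 4L) stop("unsupported dimensionality: ", nd, "D image in ", path)
  if (nd == 4L) {
    if (!takeFirstOf4D)
      stop("4D input ", path, ": pass takeFirstOf4D = TRUE to extract ",
           "the first volume")
    img <- RNifti::asNifti(img[, , , 1L, drop = FALSE], reference = img)
    img <- RNifti::asNifti(array(as.array(img), dim = dim(img)[1:3]),
                           reference = img)
  }
  # canonical closest-to-RAS orientation so axis indices are comparable
  # across inputs; a no-op when no orientation is encoded in the header
  if (!identical(RNifti::orientation(img), "RAS")) {
    ok <- tryCatch({ RNifti::orientation(img) <- "RAS"; TRUE },
                   warning = function(w) FALSE)
  }
  img
}

#' Load a NIfTI scalar volume
#'
#' Reads a 3D (or, with \code{takeFirstOf4D}, 4D) NIfTI-1/2 file, reorients
#' it to the canonical closest-to-RAS axis order, and returns it with its
#' grid populated from the header. For 4D multi-timepoint acquisitions the
#' first volume along the fourth axis is extracted.
#'
#' @param path path to a .nii or .nii.gz file.
#' @param takeFirstOf4D logical; extract timepoint 1 of a 4D file. A 4D
#'   file with this unset is an error.
#' @return a [ScalarVolume-class]
#' @export
loadVolume <- function(path, takeFirstOf4D = FALSE) {
  img <- .readCanonical(path, takeFirstOf4D)
  vals <- array(as.numeric(as.array(img)), dim = .dim3(img))
  if (any(!is.finite(vals))) {
    vals[!is.finite(vals)] <- 0
    warning("non-finite voxels in ", path, " replaced by 0")
  }
  ScalarVolume(vals, .gridFromNifti(img))
}

#' Load a NIfTI mask, binarizing at a threshold
#'
#' As [loadVolume()], then binarized as \code{value > threshold} so that
#' probabilistic segmentation outputs become crisp masks.
#'
#' @inheritParams loadVolume
#' @param threshold binarization threshold, default 0.5.
#' @return a [BinaryMask-class]
#' @export
loadMask <- function(path, threshold = 0.5, takeFirstOf4D = FALSE) {
  img <- .readCanonical(path, takeFirstOf4D)
  vals <- array(as.array(img) > threshold, dim = .dim3(img))
  BinaryMask(vals, .gridFromNifti(img))
}

.toNifti <- function(obj) {
  img <- RNifti::asNifti(obj@values)
  img <- RNifti::`pixdim<-`(img, obj@grid@spacing)
  RNifti::`qform<-`(img, structure(obj@grid@transform, code = 2L))
}

#' Write a ScalarVolume or BinaryMask to NIfTI
#'
#' Volumes are stored as float64 so that a write/read round trip is
#' bit-exact; masks as uint8.
#'
#' @param x a [ScalarVolume-class] or [BinaryMask-class].
#' @param path output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(x, path) {
  stopifnot(is(x, "ScalarVolume"))
  RNifti::writeNifti(.toNifti(x), path, datatype = "double")
  invisible(path)
}

#' @rdname writeVolume
#' @export
writeMask <- function(x, path) {
  stopifnot(is(x, "BinaryMask"))
  RNifti::writeNifti(.toNifti(x), path, datatype = "uint8")
  invisible(path)
}

#' Map 0-based voxel indices to world coordinates
#'
#' @param grid a [VoxelGrid-class].
#' @param idx n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxelToWorld <- function(grid, idx) {
  idx <- matrix(idx, ncol = 3)
  h <- cbind(idx, 1) %*% t(grid@transform)
  h[, 1:3, drop = FALSE]
}

#' Check two images (or grids) for grid agreement
#'
#' Shapes must match exactly and world transforms agree within \code{tol}
#' mm; raises a grid-mismatch error naming the differing field otherwise.
#' \code{sameGrid} is the non-throwing predicate.
#'
#' @param a,b [VoxelGrid-class]es or objects carrying one.
#' @param tol transform agreement tolerance in mm, default 1e-4.
#' @return \code{assertSameGrid} returns \code{invisible(TRUE)} on success.
#' @export
assertSameGrid <- function(a, b, tol = 1e-4) {
  ga <- if (is(a, "VoxelGrid")) a else a@grid
  gb <- if (is(b, "VoxelGrid")) b else b@grid
  if (!identical(ga@shape, gb@shape))
    stop("grid mismatch: shape (", paste(ga@shape, collapse = ","), ") vs (",
         paste(gb@shape, collapse = ","), ")")
  if (max(abs(ga@transform - gb@transform)) > tol)
    stop("grid mismatch: world transforms differ by more than ", tol, " mm")
  invisible(TRUE)
}

#' @rdname assertSameGrid
#' @export
sameGrid <- function(a, b, tol = 1e-4) {
  !inherits(tryCatch(assertSameGrid(a, b, tol), error = identity), "error")
}

#' Resample a binary mask onto a target grid by nearest neighbour
#'
#' Each target voxel takes the value of the source voxel whose world-mapped
#' center is nearest (the target voxel center is mapped through the target
#' affine and the inverse source affine, then rounded). Values stay in
#' {0, 1}; target voxels falling outside the source field of view are 0.
#'
#' @param mask a [BinaryMask-class].
#' @param target a [VoxelGrid-class] (or object carrying one).
#' @return a [BinaryMask-class] on \code{target}.
#' @export
resampleNearest <- function(mask, target) {
  stopifnot(is(mask, "BinaryMask"))
  tg <- if (is(target, "VoxelGrid")) target else target@grid
  if (sameGrid(mask@grid, tg)) return(mask)
  src <- mask@grid
  M <- tryCatch(solve(src@transform) %*% tg@transform,
                error = function(e) stop("geometry error: singular transform"))
  sh <- tg@shape
  ix <- rep(seq_len(sh[1]) - 1L, times = sh[2] * sh[3])
  iy <- rep(rep(seq_len(sh[2]) - 1L, each = sh[1]), times = sh[3])
  iz <- rep(seq_len(sh[3]) - 1L, each = sh[1] * sh[2])
  sx <- round(M[1, 1] * ix + M[1, 2] * iy + M[1, 3] * iz + M[1, 4])
  sy <- round(M[2, 1] * ix + M[2, 2] * iy + M[2, 3] * iz + M[2, 4])
  sz <- round(M[3, 1] * ix + M[3, 2] * iy + M[3, 3] * iz + M[3, 4])
  ok <- sx >= 0 & sx < src@shape[1] & sy >= 0 & sy < src@shape[2] &
        sz >= 0 & sz < src@shape[3]
  out <- integer(prod(sh))
  lin <- 1L + sx[ok] + src@shape[1] * (sy[ok] + src@shape[2] * sz[ok])
  out[ok] <- mask@values[lin]
  new("BinaryMask", grid = tg, values = array(out, dim = sh))
}
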