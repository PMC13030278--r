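#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib strokemark, .registration = TRUE
NULL

#' VoxelGrid: the 3D sampling geometry shared by volumes and masks
#'
#' A \code{VoxelGrid} records the array shape, voxel spacing in mm, and the
#' 4x4 affine mapping 0-based voxel indices to world coordinates in mm
#' (NIfTI convention). All images and masks in the package carry one, and
#' operations that combine images check grid agreement explicitly.
#'
#' @slot shape integer(3), number of voxels per axis, all >= 1.
#' @slot spacing numeric(3), voxel edge lengths in mm, all > 0.
#' @slot transform 4x4 numeric matrix, voxel-index -> world-mm affine.
#' @slot orientation character(1), axis-direction code (e.g. "RAS") after
#'   canonical reorientation at load time.
#'
#' @seealso [VoxelGrid()], [voxelVolume()], [assertSameGrid()]
#' @export
setClass("VoxelGrid",
  representation(shape = "integer", spacing = "numeric",
                 transform = "matrix", orientation = "character"))

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be three integers >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive reals (mm)")
  if (!all(dim(object@transform) == c(4L, 4L)))
    msg <- c(msg, "transform must be a 4x4 matrix")
  else {
    d <- det(object@transform)
    if (!is.finite(d) || abs(d) < 1e-12)
      msg <- c(msg, "transform must be invertible")
    else {
      cn <- sqrt(colSums(object@transform[1:3, 1:3]^2))
      rel <- abs(cn - object@spacing) / object@spacing
      if (any(rel > 1e-6))
        msg <- c(msg, "transform column norms must equal spacing (1e-6 rel. tol.)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ScalarVolume: a 3D scalar image on a VoxelGrid
#'
#' Holds one finite scalar value per voxel (e.g. an ADC map) together with
#' its sampling geometry.
#'
#' @slot grid a [VoxelGrid-class].
#' @slot values numeric 3D array with dimensions equal to the grid shape;
#'   all values finite.
#' @seealso [loadVolume()], [ScalarVolume()]
#' @export
setClass("ScalarVolume", representation(grid = "VoxelGrid", values = "array"))

setValidity("ScalarVolume", function(object) {
  msg <- character()
  if (!identical(as.integer(dim(object@values)), object@grid@shape))
    msg <- c(msg, "values dimensions must equal grid shape")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite (no NaN/Inf)")
  if (length(msg)) msg else TRUE
})

#' BinaryMask: a 3D 0/1 mask on a VoxelGrid
#'
#' @slot grid a [VoxelGrid-class].
#' @slot values integer 3D array of exactly 0s and 1s with dimensions equal
#'   to the grid shape.
#' @seealso [loadMask()], [BinaryMask()], [voxelCount()]
#' @export
setClass("BinaryMask", representation(grid = "VoxelGrid", values = "array"))

setValidity("BinaryMask", function(object) {
  msg <- character()
  if (!identical(as.integer(dim(object@values)), object@grid@shape))
    msg <- c(msg, "values dimensions must equal grid shape")
  v <- object@values
  if (!(is.integer(v) || is.logical(v)) || anyNA(v)) {
    msg <- c(msg, "mask values must be integer 0 or 1")
  } else {
    r <- range(v)
    if (r[1] < 0L || r[2] > 1L)
      msg <- c(msg, "mask values must be exactly 0 or 1")
  }
  if (length(msg)) msg else TRUE
})

#' GLCMatrix: a normalized symmetric grey-level co-occurrence matrix
#'
#' The joint probability p(i, j) of grey-level pairs at a fixed pixel
#' offset, made symmetric and normalized to sum to 1, together with its
#' marginal means/SDs and the number of valid (both-in-mask) ordered pixel
#' pairs that produced it. When no valid pair exists, p is all zero and
#' \code{validPairCount} is 0; callers skip such matrices.
#'
#' @slot p levels x levels numeric matrix of probabilities.
#' @slot muI,muJ,sigmaI,sigmaJ marginal means and standard deviations.
#' @slot validPairCount integer, ordered in-mask pixel pairs counted.
#' @seealso [glcmSlice()], [haralickFeatures()]
#' @export
setClass("GLCMatrix",
  representation(p = "matrix", muI = "numeric", muJ = "numeric",
                 sigmaI = "numeric", sigmaJ = "numeric",
                 validPairCount = "integer"))

setValidity("GLCMatrix", function(object) {
  msg <- character()
  if (nrow(object@p) != ncol(object@p))
    msg <- c(msg, "p must be square")
  if (any(object@p < 0))
    msg <- c(msg, "p entries must be non-negative")
  if (object@validPairCount > 0L && abs(sum(object@p) - 1) > 1e-9)
    msg <- c(msg, "p must sum to 1 when validPairCount > 0")
  if (max(abs(object@p - t(object@p))) > 1e-12)
    msg <- c(msg, "p must be symmetric")
  if (length(msg)) msg else TRUE
})

#' CohortTable: per-subject feature records with optional outcome labels
#'
#' Rows are subjects; columns are the vectorized expansion of the 19 named
#' imaging features (see [featureRegistry()]) plus bookkeeping columns.
#' Carries the hash of the extraction configuration that produced it;
#' tables from different configurations refuse to combine.
#'
#' @slot features data.frame, one row per subject; column \code{subject_id}
#'   plus the registry columns, and after [attachLabels()] the columns
#'   \code{mrs}, \code{outcome} (1 = unfavourable, mRS > 2) and
#'   \code{labeled}.
#' @slot configHash character(1), hash of the extraction configuration.
#' @slot version character(1), package version that produced the table.
#' @export
setClass("CohortTable",
  representation(features = "data.frame", configHash = "character",
                 version = "character"))

setValidity("CohortTable", function(object) {
  msg <- character()
  if (!"subject_id" %in% names(object@features))
    msg <- c(msg, "features must contain a subject_id column")
  else if (anyDuplicated(object@features$subject_id))
    msg <- c(msg, "subject_id values must be unique")
  if (length(object@configHash) != 1L)
    msg <- c(msg, "configHash must be a single string")
  if (length(msg)) msg else TRUE
})

setMethod("show", "VoxelGrid", function(object) {
  cat("VoxelGrid:", paste(object@shape, collapse = " x "),
      "voxels @", paste(format(object@spacing), collapse = " x "),
      "mm |", object@orientation, "\n")
})

setMethod("show", "ScalarVolume", function(object) {
  cat("ScalarVolume:", paste(object@grid@shape, collapse = " x "),
      sprintf("| range [%.4g, %.4g]\n", min(object@values), max(object@values)))
})

setMethod("show", "BinaryMask", function(object) {
  cat("BinaryMask:", paste(object@grid@shape, collapse = " x "),
      "|", voxelCount(object), "positive voxels\n")
})

setMethod("show", "GLCMatrix", function(object) {
  cat("GLCMatrix:", nrow(object@p), "levels |", object@validPairCount,
      "valid pairs\n")
})

setMethod("show", "CohortTable", function(object) {
  f <- object@features
  cat("CohortTable:", nrow(f), "subjects,", ncol(f), "columns")
  if ("labeled" %in% names(f)) cat(",", sum(f$labeled), "labeled")
  cat(" | config", substr(object@configHash, 1, 8), "\n")
})
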