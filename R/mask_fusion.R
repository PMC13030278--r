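#' Fuse candidate lesion masks by voxel-wise majority voting
#'
#' Combines the binary outputs of several segmentation models into one
#' consensus mask. A voxel is labelled lesion only when a strict majority
#' of the inputs agree (for three models: at least two); voxels without
#' majority agreement are assigned non-lesion. This conservative rule
#' limits the propagation of model-specific false positives. With an even
#' number of inputs, ties resolve to non-lesion; a single mask passes
#' through unchanged (the single-model configuration).
#'
#' @param masks list of [BinaryMask-class] objects, all on one grid.
#' @return a [BinaryMask-class] on the shared grid.
#' @examples
#' m <- BinaryMask(array(c(1, 0), dim = c(2, 1, 1)))
#' identical(imgValues(majorityVote(list(m, m, m))), imgValues(m))
#' @export
majorityVote <- function(masks) {
  if (!is.list(masks) || length(masks) == 0L)
    stop("masks must be a non-empty list of BinaryMask objects")
  for (m in masks) stopifnot(is(m, "BinaryMask"))
  n <- length(masks)
  if (n > 1L)
    for (i in 2:n) assertSameGrid(masks[[1L]], masks[[i]])
  if (n == 1L) return(masks[[1L]])
  votes <- Reduce(`+`, lapply(masks, imgValues))
  need <- n %/% 2L + 1L
  new("BinaryMask", grid = masks[[1L]]@grid,
      values = array(as.integer(votes >= need), dim = dim(votes)))
}
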