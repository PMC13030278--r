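#' Lesion-corticospinal tract overlap metrics
#'
#' Quantifies the spatial relationship between a lesion and the left and
#' right corticospinal tract (CST) masks. Tract masks on a different grid
#' are first resampled onto the lesion grid by nearest neighbour (never
#' the reverse, so the lesion mask is untouched). Per side the tract
#' volume, the overlap volume of the intersection with the lesion, and the
#' overlap percentage
#' \deqn{Overlap\% = 100 \cdot V_{overlap} / V_{CST}}
#' are reported, with volumes in mL using the lesion grid's voxel volume.
#' The denominator is the tract volume, not the lesion volume. A tract
#' that is empty after resampling yields NA for that side with a warning.
#'
#' @param lesion a [BinaryMask-class].
#' @param cstLeft,cstRight [BinaryMask-class] tract masks.
#' @return named list: \code{left_cst_volume_ml}, \code{right_cst_volume_ml},
#'   \code{left_overlap_volume_ml}, \code{right_overlap_volume_ml},
#'   \code{left_overlap_pct}, \code{right_overlap_pct} (percentages in
#'   [0, 100]).
#' @export
overlapMetrics <- function(lesion, cstLeft, cstRight) {
  stopifnot(is(lesion, "BinaryMask"), is(cstLeft, "BinaryMask"),
            is(cstRight, "BinaryMask"))
  vv <- voxelVolume(lesion)
  side <- function(tract, label) {
    tract <- resampleNearest(tract, lesion@grid)
    nt <- voxelCount(tract)
    if (nt == 0L) {
      warning("empty ", label, " tract mask after resampling")
      return(c(vol = NA_real_, ovl = NA_real_, pct = NA_real_))
    }
    no <- sum(lesion@values == 1L & tract@values == 1L)
    c(vol = nt * vv / 1000, ovl = no * vv / 1000, pct = 100 * no / nt)
  }
  l <- side(cstLeft, "left")
  r <- side(cstRight, "right")
  list(left_cst_volume_ml = unname(l["vol"]),
       right_cst_volume_ml = unname(r["vol"]),
       left_overlap_volume_ml = unname(l["ovl"]),
       right_overlap_volume_ml = unname(r["ovl"]),
       left_overlap_pct = unname(l["pct"]),
       right_overlap_pct = unname(r["pct"]))
}
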