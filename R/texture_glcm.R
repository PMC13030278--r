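#' GLCM texture protocol configuration
#'
#' Defaults follow the slice-wise protocol used throughout the package:
#' 256 grey levels, pixel distances 1--3, the four in-plane directions
#' 0/45/90/135 degrees, symmetric probability-normalized matrices, and
#' axial slicing (third array axis).
#'
#' @param levels number of discrete grey levels, >= 2.
#' @param distances integer vector of pixel distances, all >= 1.
#' @param anglesDeg directions in degrees (subset of 0, 45, 90, 135).
#' @param symmetric make each co-occurrence matrix symmetric.
#' @param normalized normalize counts to probabilities.
#' @param sliceAxis 1-based array axis along which slices are taken.
#' @param perSliceNormalization rescale intensities to 0..(levels-1) per
#'   slice instead of once per subject over the whole 3D lesion.
#' @param perDistance also return per-distance feature values (averaged
#'   over angles only) as an attribute of the [lesionTexture()] result.
#' @return a list with class "glcmConfig".
#' @export
glcmConfig <- function(levels = 256L, distances = 1:3,
                       anglesDeg = c(0, 45, 90, 135), symmetric = TRUE,
                       normalized = TRUE, sliceAxis = 3L,
                       perSliceNormalization = FALSE, perDistance = FALSE) {
  levels <- as.integer(levels)
  distances <- as.integer(distances)
  if (levels < 2L) stop("levels must be >= 2")
  if (any(distances < 1L)) stop("distances must all be >= 1")
  structure(list(levels = levels, distances = distances,
                 anglesDeg = anglesDeg, symmetric = symmetric,
                 normalized = normalized, sliceAxis = as.integer(sliceAxis),
                 perSliceNormalization = perSliceNormalization,
                 perDistance = perDistance),
            class = "glcmConfig")
}

.angleOffset <- function(angleDeg, d) {
  switch(as.character(angleDeg),
         "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L),
         "135" = c(-d, -d),
         stop("unsupported angle: ", angleDeg))
}

#' Quantize in-lesion intensities to discrete grey levels
#'
#' Min-max scales the in-mask intensities to the integer range
#' 0..(levels-1) (default 8-bit, 0--255) by
#' \code{floor((levels - 1) * (v - min) / (max - min))}; a constant lesion
#' maps to level 0 everywhere. Voxels outside the mask are NA.
#'
#' @param volume a [ScalarVolume-class].
#' @param mask a non-empty [BinaryMask-class] on the same grid.
#' @param levels number of grey levels, default 256.
#' @return integer array of the volume's shape: level inside the mask,
#'   NA outside.
#' @export
normalizeTo8bit <- function(volume, mask, levels = 256L) {
  stopifnot(is(volume, "ScalarVolume"), is(mask, "BinaryMask"))
  assertSameGrid(volume, mask)
  if (voxelCount(mask) == 0L) stop("empty lesion: nothing to normalize")
  out <- array(NA_integer_, dim = dim(volume@values))
  sel <- mask@values == 1L
  v <- volume@values[sel]
  rng <- range(v)
  lev <- if (rng[2] > rng[1]) {
    pmin(as.integer(floor((levels - 1) * (v - rng[1]) / (rng[2] - rng[1]))),
         levels - 1L)
  } else rep(0L, length(v))
  out[sel] <- lev
  out
}

# shared Haralick evaluation on the sparse nonzero cells of a symmetric
# normalized GLCM; i0/j0 are 0-based grey levels
.haralickFromSparse <- function(i0, j0, p) {
  pi_ <- rowsum(p, i0)
  iv <- as.numeric(rownames(pi_))
  muI <- sum(iv * pi_)
  sigI <- sqrt(sum((iv - muI)^2 * pi_))
  pj_ <- rowsum(p, j0)
  jv <- as.numeric(rownames(pj_))
  muJ <- sum(jv * pj_)
  sigJ <- sqrt(sum((jv - muJ)^2 * pj_))
  d <- i0 - j0
  contrast <- sum(d^2 * p)
  dissimilarity <- sum(abs(d) * p)
  homogeneity <- sum(p / (1 + abs(d)))
  asm <- sum(p^2)
  energy <- sqrt(asm)
  correlation <- if (sigI * sigJ < 1e-12) 1 else
    sum((i0 - muI) * (j0 - muJ) * p) / (sigI * sigJ)
  c(contrast = contrast, dissimilarity = dissimilarity,
    homogeneity = homogeneity, asm = asm, energy = energy,
    correlation = correlation, muI = muI, muJ = muJ,
    sigmaI = sigI, sigmaJ = sigJ)
}

# raw ordered-pair triplets for one offset; slice given as an integer
# matrix with level in [0, levels) inside the mask and NA (or < 0) outside
.sliceTriplets <- function(levelSlice, distance, angleDeg, levels) {
  m <- levelSlice
  m[is.na(m)] <- -1L
  storage.mode(m) <- "integer"
  off <- .angleOffset(angleDeg, as.integer(distance))
  cpp_glcm_pairs(m, off[1], off[2], levels)
}

.symmetrizeTriplets <- function(trip, levels, symmetric) {
  if (nrow(trip) == 0L)
    return(list(i = integer(), j = integer(), n = numeric(), total = 0))
  i <- trip[, 1]; j <- trip[, 2]; n <- as.numeric(trip[, 3])
  if (symmetric) {
    key <- c(i + levels * j, j + levels * i)
    n <- c(n, n)
  } else {
    key <- i + levels * j
  }
  agg <- rowsum(n, key)
  k <- as.numeric(rownames(agg))
  list(i = k %% levels, j = k %/% levels, n = as.numeric(agg),
       total = sum(agg))
}

#' Grey-level co-occurrence matrix of one masked slice
#'
#' Counts ordered pixel pairs at the given offset (distance along the
#' direction) where both pixels lie inside the mask, adds the transpose
#' (symmetric) and divides by the total (normalized). Pairs with either
#' pixel outside the mask are never counted. With zero valid pairs the
#' matrix is all zero and \code{validPairCount} is 0.
#'
#' @param levelSlice integer matrix of grey levels (0-based), NA outside
#'   the mask.
#' @param distance pixel distance, >= 1.
#' @param angleDeg direction: 0, 45, 90 or 135.
#' @param levels number of grey levels (matrix size), default 256.
#' @param symmetric,normalized protocol flags, default both TRUE.
#' @return a [GLCMatrix-class].
#' @export
glcmSlice <- function(levelSlice, distance, angleDeg, levels = 256L,
                      symmetric = TRUE, normalized = TRUE) {
  trip <- .sliceTriplets(levelSlice, distance, angleDeg, levels)
  sym <- .symmetrizeTriplets(trip, levels, symmetric)
  p <- matrix(0, levels, levels)
  npairs <- sum(trip[, 3])
  if (sym$total > 0) {
    p[cbind(sym$i + 1L, sym$j + 1L)] <-
      if (normalized) sym$n / sym$total else sym$n
  }
  if (sym$total > 0 && normalized) {
    h <- .haralickFromSparse(sym$i, sym$j, sym$n / sym$total)
    new("GLCMatrix", p = p, muI = unname(h["muI"]), muJ = unname(h["muJ"]),
        sigmaI = unname(h["sigmaI"]), sigmaJ = unname(h["sigmaJ"]),
        validPairCount = as.integer(npairs))
  } else {
    new("GLCMatrix", p = p, muI = NA_real_, muJ = NA_real_,
        sigmaI = NA_real_, sigmaJ = NA_real_,
        validPairCount = as.integer(npairs))
  }
}

#' Haralick features of a co-occurrence matrix
#'
#' The six second-order texture statistics: contrast
#' \eqn{\sum (i-j)^2 p(i,j)}, dissimilarity \eqn{\sum |i-j| p(i,j)},
#' homogeneity \eqn{\sum p(i,j) / (1 + |i-j|)}, angular second moment
#' \eqn{\sum p(i,j)^2}, energy \eqn{\sqrt{ASM}}, and correlation
#' \eqn{\sum (i - \mu_i)(j - \mu_j) p(i,j) / (\sigma_i \sigma_j)}.
#' When both marginal variances vanish (a constant region) correlation is
#' 1 by the usual limit convention.
#'
#' @param g a [GLCMatrix-class] with \code{validPairCount > 0}.
#' @return named numeric(6): contrast, dissimilarity, homogeneity, asm,
#'   energy, correlation.
#' @export
haralickFeatures <- function(g) {
  stopifnot(is(g, "GLCMatrix"))
  if (g@validPairCount == 0L)
    stop("undefined features: co-occurrence matrix has no valid pairs")
  nz <- which(g@p > 0)
  i0 <- (nz - 1L) %% nrow(g@p)
  j0 <- (nz - 1L) %/% nrow(g@p)
  h <- .haralickFromSparse(i0, j0, g@p[nz])
  h[c("contrast", "dissimilarity", "homogeneity", "asm", "energy",
      "correlation")]
}

#' Shannon entropy of a masked slice's grey-level histogram
#'
#' Base-2 entropy of the slice-wise intensity histogram over the discrete
#' grey levels (computed from the histogram directly, not from a GLCM),
#' with 0 log 0 := 0.
#'
#' @param levelSlice integer matrix of grey levels, NA outside the mask.
#' @return numeric(1), bits.
#' @export
sliceEntropy <- function(levelSlice) {
  v <- levelSlice[!is.na(levelSlice) & levelSlice >= 0]
  if (length(v) == 0L) stop("empty slice mask: entropy undefined")
  pr <- tabulate(v + 1L)
  pr <- pr[pr > 0] / length(v)
  -sum(pr * log2(pr))
}

.sliceOf <- function(arr, axis, k) {
  d <- dim(arr)
  if (axis == 1L) array(arr[k, , , drop = FALSE], d[2:3])
  else if (axis == 2L) array(arr[, k, , drop = FALSE], d[c(1, 3)])
  else array(arr[, , k, drop = FALSE], d[1:2])
}

#' Per-subject GLCM texture features of a lesion
#'
#' Implements the slice-wise texture protocol: in-lesion ADC intensities
#' are quantized to \code{config$levels} grey levels (min-max over the
#' whole 3D lesion by default), then for every slice containing lesion
#' voxels a co-occurrence matrix is computed for each distance/direction
#' combination, each Haralick feature is averaged over directions and
#' distances (uniform weights), slice entropy is taken from the slice
#' histogram, and the per-slice 7-vectors are averaged across contributing
#' slices with the arithmetic mean. Offsets (and slices) with zero valid
#' pixel pairs are excluded from the corresponding averages rather than
#' contributing zeros.
#'
#' @param volume a [ScalarVolume-class] (the ADC map).
#' @param mask a non-empty [BinaryMask-class] on the same grid.
#' @param config a [glcmConfig()].
#' @return named numeric(7): contrast, dissimilarity, homogeneity, asm,
#'   energy, correlation, entropy. With \code{config$perDistance}, the
#'   per-distance matrix is attached as attribute "perDistance".
#' @export
lesionTexture <- function(volume, mask, config = glcmConfig()) {
  stopifnot(is(volume, "ScalarVolume"), is(mask, "BinaryMask"))
  assertSameGrid(volume, mask)
  if (voxelCount(mask) == 0L) stop("empty lesion: texture undefined")
  L <- config$levels
  axis <- config$sliceAxis
  lev3 <- if (config$perSliceNormalization) NULL
          else normalizeTo8bit(volume, mask, L)
  ks <- which(apply(mask@values, axis, sum) > 0)
  featNames <- c("contrast", "dissimilarity", "homogeneity", "asm",
                 "energy", "correlation")
  sliceFeats <- matrix(NA_real_, length(ks), 7,
                       dimnames = list(NULL, c(featNames, "entropy")))
  perDist <- if (config$perDistance)
    array(NA_real_, c(length(ks), length(config$distances), 6)) else NULL
  for (si in seq_along(ks)) {
    k <- ks[si]
    if (config$perSliceNormalization) {
      mvals <- .sliceOf(mask@values, axis, k)
      vvals <- .sliceOf(volume@values, axis, k)
      sel <- mvals == 1L
      sl <- matrix(NA_integer_, nrow(mvals), ncol(mvals))
      v <- vvals[sel]
      rng <- range(v)
      sl[sel] <- if (rng[2] > rng[1])
        pmin(as.integer(floor((L - 1) * (v - rng[1]) / (rng[2] - rng[1]))),
             L - 1L) else 0L
    } else {
      sl <- .sliceOf(lev3, axis, k)
    }
    # crop to the in-mask bounding box: pairs require both pixels in the
    # mask, so cropping cannot change any count
    rr <- range(which(rowSums(!is.na(sl)) > 0))
    cc <- range(which(colSums(!is.na(sl)) > 0))
    sl <- sl[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    if (config$symmetric && config$normalized) {
      m <- sl
      m[is.na(m)] <- -1L
      storage.mode(m) <- "integer"
      offs <- do.call(rbind, lapply(config$distances, function(d)
        do.call(rbind, lapply(config$anglesDeg, .angleOffset, d = d))))
      acc <- cpp_haralick_slice(m, offs, L)[, 1:6, drop = FALSE]
    } else {
      acc <- matrix(NA_real_, length(config$distances) * length(config$anglesDeg), 6)
      r <- 0L
      for (d in config$distances) {
        for (ang in config$anglesDeg) {
          r <- r + 1L
          g <- glcmSlice(sl, d, ang, L, config$symmetric, config$normalized)
          if (g@validPairCount > 0L) acc[r, ] <- haralickFeatures(g)
        }
      }
    }
    if (config$perDistance) {
      nA <- length(config$anglesDeg)
      for (di in seq_along(config$distances)) {
        rows <- (di - 1L) * nA + seq_len(nA)
        perDist[si, di, ] <- colMeans(acc[rows, , drop = FALSE], na.rm = TRUE)
      }
    }
    if (any(!is.na(acc[, 1])))
      sliceFeats[si, 1:6] <- colMeans(acc, na.rm = TRUE)
    sliceFeats[si, 7] <- sliceEntropy(sl)
  }
  if (all(is.na(sliceFeats[, 1])))
    stop("undefined texture: no slice yields any valid pixel pair")
  out <- colMeans(sliceFeats, na.rm = TRUE)
  if (config$perDistance) attr(out, "perDistance") <- perDist
  out
}
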