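#' Synthetic phantom specification
#'
#' Defines the geometry and stochastic models of the built-in phantom
#' generator: a scaled-down head-sized grid carrying two bilateral
#' tract-shaped tubes (corticospinal-tract stand-ins, curved, symmetric
#' about the left/right midplane), one ellipsoidal lesion with random
#' size, orientation and placement (optionally biased toward a tract), an
#' ADC volume with reduced intensity and spatially correlated texture
#' inside the lesion, a per-model segmentation-noise model producing
#' candidate masks for fusion, and a logistic outcome model on true lesion
#' volume and mean tract overlap.
#'
#' The outcome model is
#' \deqn{logit P(unfavourable) = \beta_0 + \beta_1 V_{ml} + \beta_2
#'   \overline{Overlap\%}}
#' with the mean of the left/right overlap percentages as the linear
#' term. \code{signal = "strong"} is the overlap-dominated configuration;
#' \code{signal = "null"} makes labels independent of the images
#' (all betas 0, prevalence 0.5).
#'
#' @param shape,spacingMm grid shape (voxels) and isotropic spacing (mm).
#' @param tract list: \code{radiusMm} tube radius, \code{lateralOffsetMm}
#'   distance of each tube from the midplane, \code{bowMm} centerline
#'   curvature amplitude, \code{zMarginVox} end margin in slices.
#' @param lesion list: \code{semiAxesMmRange} uniform range of ellipsoid
#'   semi-axes, \code{nearTractProb} probability of tract-biased
#'   placement, \code{jitterSdMm} placement jitter SD around the tract
#'   centerline.
#' @param adc list: \code{backgroundMean}, \code{noiseSd},
#'   \code{lesionDelta} (added inside the lesion, negative for the
#'   ADC-dark infarct core), \code{noiseLengthScaleMm} correlation length
#'   of the smoothed noise field (units: 1e-6 mm^2/s, typical brain ADC
#'   scale).
#' @param segNoise list: \code{boundaryRadiusVox} per-model
#'   erosion(-)/dilation(+) radius in voxels (length = number of candidate
#'   models), \code{flipRate} probability of flipping voxels in a 2-voxel
#'   boundary shell, in [0, 0.5).
#' @param outcome list: \code{beta0}, \code{betaVolume},
#'   \code{betaOverlap}.
#' @param signal preset: "strong" (default) or "null"; an explicit
#'   \code{outcome} list overrides the preset.
#' @return a list with class "phantomSpec".
#' @export
phantomSpec <- function(shape = c(40L, 46L, 30L), spacingMm = 2,
                        tract = list(radiusMm = 3.5, lateralOffsetMm = 16,
                                     bowMm = 5, zMarginVox = 4L),
                        lesion = list(semiAxesMmRange = c(6, 16),
                                      nearTractProb = 0.75, jitterSdMm = 5),
                        adc = list(backgroundMean = 1100, noiseSd = 70,
                                   lesionDelta = -450,
                                   noiseLengthScaleMm = 3),
                        segNoise = list(boundaryRadiusVox = c(-1L, 0L, 1L),
                                        flipRate = 0.02),
                        outcome = NULL,
                        signal = c("strong", "null")) {
  signal <- match.arg(signal)
  if (is.null(outcome)) {
    outcome <- if (signal == "strong")
      list(beta0 = -4.5, betaVolume = 0, betaOverlap = 0.45)
    else
      list(beta0 = 0, betaVolume = 0, betaOverlap = 0)
  }
  if (segNoise$flipRate < 0 || segNoise$flipRate >= 0.5)
    stop("flipRate must be in [0, 0.5)")
  if (tract$radiusMm <= 0) stop("tract radius must be positive")
  if (2 * tract$lateralOffsetMm <= 2 * tract$radiusMm)
    stop("tract tubes must be disjoint across the midplane")
  structure(list(shape = as.integer(shape), spacingMm = spacingMm,
                 tract = tract, lesion = lesion, adc = adc,
                 segNoise = segNoise, outcome = outcome, signal = signal),
            class = "phantomSpec")
}

.phantomGrid <- function(spec) {
  VoxelGrid(spec$shape, spacing = rep(spec$spacingMm, 3))
}

.tractCenterline <- function(spec, side) {
  sh <- spec$shape; sp <- spec$spacingMm
  cx <- (sh[1] - 1) / 2 * sp; cy <- (sh[2] - 1) / 2 * sp
  ks <- seq(spec$tract$zMarginVox, sh[3] - 1 - spec$tract$zMarginVox)
  t <- (ks - min(ks)) / (max(ks) - min(ks))
  sgn <- if (side == "left") -1 else 1
  data.frame(
    x = cx + sgn * (spec$tract$lateralOffsetMm + spec$tract$bowMm * sin(pi * t)),
    y = cy + spec$tract$bowMm * 0.5 * sin(2 * pi * t),
    z = ks * sp, k = ks)
}

#' Bilateral tract-shaped phantom masks
#'
#' Deterministic given the spec: two curved tubes of the configured radius
#' placed symmetrically about the left/right midplane, running along the
#' slice axis. Left is the low-x side (canonical RAS axes).
#'
#' @param spec a [phantomSpec()].
#' @return list of two [BinaryMask-class]: \code{left}, \code{right}.
#' @export
makeTracts <- function(spec) {
  grid <- .phantomGrid(spec)
  sh <- spec$shape; sp <- spec$spacingMm
  xs <- (seq_len(sh[1]) - 1) * sp
  ys <- (seq_len(sh[2]) - 1) * sp
  one <- function(side) {
    cl <- .tractCenterline(spec, side)
    v <- array(0L, sh)
    r2 <- spec$tract$radiusMm^2
    for (i in seq_len(nrow(cl))) {
      d2 <- outer((xs - cl$x[i])^2, (ys - cl$y[i])^2, `+`)
      v[, , cl$k[i] + 1L] <- v[, , cl$k[i] + 1L] | (d2 <= r2)
    }
    new("BinaryMask", grid = grid, values = array(as.integer(v), sh))
  }
  list(left = one("left"), right = one("right"))
}

# random rotation matrix via QR of a Gaussian matrix
.randomRotation <- function() {
  qr <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

.makeLesion <- function(spec) {
  sh <- spec$shape; sp <- spec$spacingMm
  fov <- (sh - 1) * sp
  rng <- spec$lesion$semiAxesMmRange
  for (attempt in 1:25) {
    semi <- stats::runif(3, rng[1], rng[2])
    rot <- .randomRotation()
    if (stats::runif(1) < spec$lesion$nearTractProb) {
      side <- if (stats::runif(1) < 0.5) "left" else "right"
      cl <- .tractCenterline(spec, side)
      i <- sample.int(nrow(cl), 1)
      ctr <- c(cl$x[i], cl$y[i], cl$z[i]) +
        stats::rnorm(3, 0, spec$lesion$jitterSdMm)
    } else {
      ctr <- stats::runif(3, 0.2 * fov, 0.8 * fov)
    }
    ctr <- pmin(pmax(ctr, 0.1 * fov), 0.9 * fov)
    # evaluate the rotated ellipsoid over its bounding box only
    rmax <- max(semi)
    lo <- pmax(floor((ctr - rmax) / sp), 0)
    hi <- pmin(ceiling((ctr + rmax) / sp), sh - 1)
    ix <- (lo[1]:hi[1]); iy <- (lo[2]:hi[2]); iz <- (lo[3]:hi[3])
    g <- expand.grid(x = ix * sp, y = iy * sp, z = iz * sp)
    d <- t(rot) %*% rbind(g$x - ctr[1], g$y - ctr[2], g$z - ctr[3])
    inside <- colSums((d / semi)^2) <= 1
    if (!any(inside)) next
    v <- array(0L, sh)
    sub <- array(as.integer(inside), c(length(ix), length(iy), length(iz)))
    v[ix + 1L, iy + 1L, iz + 1L] <- sub
    return(v)
  }
  stop("phantom spec error: lesion cannot be placed on this grid")
}

.dilate1 <- function(a) cpp_morph3d(a, dim(a), 1L)

.erode1 <- function(a) cpp_morph3d(a, dim(a), -1L)

.morphN <- function(a, n) {
  if (n == 0L) return(a)
  cpp_morph3d(a, dim(a), as.integer(n))
}

.candidateMasks <- function(lesion, spec, grid) {
  # morphology and flips act within the lesion bounding box (plus margin),
  # so operate on the cropped subarray and paste back
  sh <- dim(lesion)
  idx <- which(lesion == 1L, arr.ind = TRUE)
  marg <- 3L + max(abs(spec$segNoise$boundaryRadiusVox))
  lo <- pmax(apply(idx, 2, min) - marg, 1L)
  hi <- pmin(apply(idx, 2, max) + marg, sh)
  sub <- lesion[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  shell <- .dilate1(.dilate1(sub)) & !(.erode1(.erode1(sub)))
  shellIdx <- which(shell)
  lapply(spec$segNoise$boundaryRadiusVox, function(r) {
    v <- .morphN(sub, as.integer(r))
    if (spec$segNoise$flipRate > 0 && length(shellIdx)) {
      flip <- shellIdx[stats::runif(length(shellIdx)) < spec$segNoise$flipRate]
      v[flip] <- 1L - v[flip]
    }
    full <- array(0L, sh)
    full[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- v
    new("BinaryMask", grid = grid, values = full)
  })
}

#' Generate one synthetic subject
#'
#' Fully deterministic given (spec, seed). Returns the ADC volume, the
#' ground-truth lesion mask, noisy candidate masks (one per configured
#' segmentation model), the bilateral tract masks, and a truth record with
#' the analytically counted lesion volume, per-side overlap percentages,
#' the outcome probability from the spec's logistic model, the sampled
#' binary label, and an mRS value consistent with it (0--2 favourable,
#' 3--6 unfavourable).
#'
#' @param spec a [phantomSpec()].
#' @param seed integer seed.
#' @param tracts optional precomputed [makeTracts()] result (they are
#'   deterministic per spec, so callers generating many subjects reuse
#'   them).
#' @return list: \code{adc}, \code{lesionTruth}, \code{candidates},
#'   \code{cstLeft}, \code{cstRight}, \code{truth}.
#' @export
makeSubject <- function(spec, seed, tracts = NULL) {
  stopifnot(inherits(spec, "phantomSpec"))
  if (is.null(tracts)) tracts <- makeTracts(spec)
  grid <- .phantomGrid(spec)
  .withSeed(as.integer(seed), {
    lesionArr <- .makeLesion(spec)
    lesion <- new("BinaryMask", grid = grid, values = lesionArr)

    # spatially correlated noise, generated around the lesion (all
    # intensity and texture features read in-lesion voxels only; the far
    # background stays at its constant mean)
    sigmaVox <- spec$adc$noiseLengthScaleMm / spec$spacingMm
    idx <- which(lesionArr == 1L, arr.ind = TRUE)
    marg <- as.integer(ceiling(3 * sigmaVox)) + 2L
    lo <- pmax(apply(idx, 2, min) - marg, 1L)
    hi <- pmin(apply(idx, 2, max) + marg, spec$shape)
    bd <- hi - lo + 1L
    noise <- cpp_gauss_smooth3d(array(stats::rnorm(prod(bd)), bd), bd, sigmaVox)
    noise <- noise / stats::sd(noise) * spec$adc$noiseSd
    vals <- array(spec$adc$backgroundMean, spec$shape)
    vals[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      vals[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + noise
    vals <- vals + spec$adc$lesionDelta * lesionArr
    vals <- pmax(vals, 1)
    adc <- ScalarVolume(array(vals, spec$shape), grid)

    candidates <- .candidateMasks(lesionArr, spec, grid)

    ov <- overlapMetrics(lesion, tracts$left, tracts$right)
    volMl <- lesionVolume(lesion)
    meanOv <- mean(c(ov$left_overlap_pct, ov$right_overlap_pct))
    b <- spec$outcome
    p <- stats::plogis(b$beta0 + b$betaVolume * volMl + b$betaOverlap * meanOv)
    label <- stats::rbinom(1, 1, p)
    mrs <- if (label == 1L) sample(3:6, 1) else sample(0:2, 1)
    list(adc = adc, lesionTruth = lesion, candidates = candidates,
         cstLeft = tracts$left, cstRight = tracts$right,
         truth = list(volume_ml = volMl,
                      left_overlap_pct = ov$left_overlap_pct,
                      right_overlap_pct = ov$right_overlap_pct,
                      mean_overlap_pct = meanOv, p_unfavourable = p,
                      label = label, mrs = mrs))
  })
}

#' Generate and extract a whole phantom cohort in memory
#'
#' Generates \code{n} subjects (per-subject seeds derived as
#' \code{seed + i}), runs the full feature extraction on each, attaches
#' the generated mRS labels, and returns the labeled
#' [CohortTable-class] together with the generator's truth table.
#' Subjects are discarded after extraction, so memory stays flat.
#'
#' @param spec a [phantomSpec()].
#' @param n number of subjects, >= 1.
#' @param seed integer base seed.
#' @param config an [extractionConfig()].
#' @return list: \code{table} (labeled cohort), \code{truth} (data.frame,
#'   one row per subject).
#' @export
phantomCohort <- function(spec, n, seed, config = extractionConfig()) {
  stopifnot(n >= 1)
  tracts <- makeTracts(spec)
  recs <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf("phantom-%04d", i)
    s <- makeSubject(spec, seed + i, tracts = tracts)
    recs[[i]] <- suppressWarnings(
      extractSubject(sid, s$adc, s$candidates, s$cstLeft, s$cstRight, config))
    truth[[i]] <- cbind(data.frame(subject_id = sid), as.data.frame(s$truth))
  }
  tab <- makeCohortTable(recs, config)
  truthDf <- do.call(rbind, truth)
  tab <- suppressMessages(
    attachLabels(tab, data.frame(subject_id = truthDf$subject_id,
                                 mrs = truthDf$mrs)))
  list(table = tab, truth = truthDf)
}

#' Write a phantom cohort to disk in the pipeline's file layout
#'
#' Generates \code{n} subjects and writes, per subject, the ADC volume,
#' the candidate lesion masks and the tract masks as NIfTI files, plus a
#' manifest CSV consumable by [cohortFromManifest()], a labels CSV
#' (subject_id, mrs) and the generator truth CSV.
#'
#' @inheritParams phantomCohort
#' @param dir output directory (created if needed).
#' @return invisible list with the \code{manifest}, \code{labels} and
#'   \code{truth} file paths.
#' @export
makeCohort <- function(spec, n, seed, dir) {
  stopifnot(n >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tracts <- makeTracts(spec)
  lp <- file.path(dir, "cst_left.nii.gz")
  rp <- file.path(dir, "cst_right.nii.gz")
  writeMask(tracts$left, lp)
  writeMask(tracts$right, rp)
  rows <- vector("list", n)
  labs <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf("phantom-%04d", i)
    s <- makeSubject(spec, seed + i, tracts = tracts)
    adcPath <- file.path(dir, paste0(sid, "_adc.nii.gz"))
    writeVolume(s$adc, adcPath)
    candPaths <- vapply(seq_along(s$candidates), function(m) {
      p <- file.path(dir, sprintf("%s_lesion_model%d.nii.gz", sid, m))
      writeMask(s$candidates[[m]], p)
      p
    }, "")
    rows[[i]] <- data.frame(subject_id = sid, adc = adcPath,
                            lesions = paste(candPaths, collapse = ";"),
                            cst_left = lp, cst_right = rp)
    labs[[i]] <- data.frame(subject_id = sid, mrs = s$truth$mrs)
    truth[[i]] <- cbind(data.frame(subject_id = sid), as.data.frame(s$truth))
  }
  manifest <- file.path(dir, "manifest.csv")
  labels <- file.path(dir, "labels.csv")
  truthPath <- file.path(dir, "truth.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  utils::write.csv(do.call(rbind, labs), labels, row.names = FALSE)
  utils::write.csv(do.call(rbind, truth), truthPath, row.names = FALSE)
  invisible(list(manifest = manifest, labels = labels, truth = truthPath))
}
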