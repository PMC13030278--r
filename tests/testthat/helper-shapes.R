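# fixture builders and independent brute-force oracles used across tests

digitalSphere <- function(r, pad = 3L, spacing = c(1, 1, 1)) {
  n <- 2L * r + 2L * pad + 1L
  c0 <- (n - 1) / 2
  ax <- (seq_len(n) - 1) - c0
  d2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  BinaryMask(array(d2 <= r^2, dim = c(n, n, n)),
             VoxelGrid(c(n, n, n), spacing = spacing))
}

filledBox <- function(dims, pad = 2L, spacing = c(1, 1, 1)) {
  sh <- dims + 2L * pad
  v <- array(0L, sh)
  v[pad + seq_len(dims[1]), pad + seq_len(dims[2]), pad + seq_len(dims[3])] <- 1L
  BinaryMask(v, VoxelGrid(sh, spacing = spacing))
}

randomMask <- function(shape, p = 0.3) {
  BinaryMask(array(stats::runif(prod(shape)) < p, dim = shape),
             VoxelGrid(shape))
}

# direct triple-loop intensity-weighted centroid (0-based indices)
bruteCentroid <- function(vals, mask) {
  sh <- dim(vals)
  num <- c(0, 0, 0); den <- 0
  for (i in seq_len(sh[1])) for (j in seq_len(sh[2])) for (k in seq_len(sh[3]))
    if (mask[i, j, k] == 1L) {
      w <- vals[i, j, k]
      num <- num + w * c(i - 1, j - 1, k - 1)
      den <- den + w
    }
  num / den
}

# population covariance of positive voxel centers by explicit enumeration
bruteCovEigen <- function(mask, spacing = c(1, 1, 1)) {
  idx <- which(mask == 1L, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, spacing, `*`)
  ctr <- colMeans(pts)
  cc <- sweep(pts, 2, ctr)
  cv <- crossprod(cc) / nrow(pts)
  sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

# brute-force masked GLCM by explicit pixel-pair enumeration, plus the
# texture features evaluated as direct sums over the full matrix
bruteGLCM <- function(levels, dr, dc, nlevels = 256L, symmetric = TRUE) {
  nr <- nrow(levels); nc <- ncol(levels)
  counts <- matrix(0, nlevels, nlevels)
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    r2 <- r + dr; c2 <- cl + dc
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    a <- levels[r, cl]; b <- levels[r2, c2]
    if (is.na(a) || is.na(b) || a < 0 || b < 0) next
    counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
  }
  if (symmetric) counts <- counts + t(counts)
  counts
}

bruteHaralick <- function(p) {
  # p: normalized symmetric co-occurrence matrix (full, dense)
  L <- nrow(p)
  iv <- matrix(0:(L - 1), L, L)
  jv <- t(iv)
  pi_ <- rowSums(p); pj_ <- colSums(p)
  mi <- sum((0:(L - 1)) * pi_); mj <- sum((0:(L - 1)) * pj_)
  si <- sqrt(sum(((0:(L - 1)) - mi)^2 * pi_))
  sj <- sqrt(sum(((0:(L - 1)) - mj)^2 * pj_))
  asm <- sum(p^2)
  c(contrast = sum((iv - jv)^2 * p),
    dissimilarity = sum(abs(iv - jv) * p),
    homogeneity = sum(p / (1 + abs(iv - jv))),
    asm = asm, energy = sqrt(asm),
    correlation = if (si * sj < 1e-12) 1 else
      sum((iv - mi) * (jv - mj) * p) / (si * sj))
}

# random masked level slice for oracle comparisons
randomLevelSlice <- function(nr, nc, maskP = 0.7, nlevels = 256L) {
  m <- matrix(stats::runif(nr * nc) < maskP, nr, nc)
  lv <- matrix(sample.int(nlevels, nr * nc, replace = TRUE) - 1L, nr, nc)
  lv[!m] <- NA_integer_
  lv
}

smallPhantomSpec <- function(...) phantomSpec(...)
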