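test_that("8-bit quantization: endpoints, floor rule, constant lesions", {
  v <- array(0, c(3, 1, 1)); v[] <- c(100, 200, 300)
  m <- BinaryMask(array(1L, c(3, 1, 1)))
  lev <- normalizeTo8bit(ScalarVolume(v), m)
  expect_equal(as.integer(lev), c(0L, 127L, 255L))
  v2 <- array(0, c(2, 1, 1)); v2[] <- c(100, 300)
  m2 <- BinaryMask(array(1L, c(2, 1, 1)))
  expect_equal(as.integer(normalizeTo8bit(ScalarVolume(v2), m2)), c(0L, 255L))
  cons <- normalizeTo8bit(ScalarVolume(array(5, c(2, 2, 2))),
                          BinaryMask(array(1L, c(2, 2, 2))))
  expect_true(all(cons == 0L))
  # outside the mask is NA
  mm <- array(0L, c(2, 1, 1)); mm[1, 1, 1] <- 1L
  lev3 <- normalizeTo8bit(ScalarVolume(v2), BinaryMask(mm))
  expect_true(is.na(lev3[2, 1, 1]))
})

test_that("slice GLCM: constant region, single pixel, symmetry and normalization", {
  cons <- matrix(0L, 2, 2)
  g <- glcmSlice(cons, 1, 0)
  expect_equal(g@p[1, 1], 1)
  expect_equal(sum(g@p), 1)
  expect_gt(g@validPairCount, 0)
  one <- matrix(NA_integer_, 3, 3); one[2, 2] <- 5L
  g1 <- glcmSlice(one, 1, 0)
  expect_equal(g1@validPairCount, 0L)
  expect_true(all(g1@p == 0))
})

test_that("checkerboard texture has its closed-form feature values", {
  n <- 8
  lv <- matrix(0L, n, n)
  lv[(row(lv) + col(lv)) %% 2 == 0] <- 255L
  g <- glcmSlice(lv, 1, 0)
  h <- haralickFeatures(g)
  expect_equal(unname(h["contrast"]), 65025)
  expect_equal(unname(h["dissimilarity"]), 255)
  expect_equal(unname(h["homogeneity"]), 1 / 256)
  expect_equal(unname(h["asm"]), 0.5)
  expect_equal(unname(h["energy"]), sqrt(0.5))
  expect_equal(unname(h["correlation"]), -1)
})

test_that("constant region features follow the zero-variance conventions", {
  g <- glcmSlice(matrix(0L, 4, 4), 1, 0)
  h <- haralickFeatures(g)
  expect_equal(unname(h), c(0, 0, 1, 1, 1, 1))
  expect_error(haralickFeatures(glcmSlice(matrix(NA_integer_, 2, 2), 1, 0)),
               "no valid pairs")
})

test_that("GLCM and features match the brute-force pair-enumeration oracle", {
  set.seed(41)
  for (rep in 1:25) {
    nr <- sample(6:16, 1); nc <- sample(6:16, 1)
    lv <- randomLevelSlice(nr, nc, maskP = runif(1, 0.4, 0.95))
    if (all(is.na(lv))) next
    for (d in 1:3) for (ang in c(0, 45, 90, 135)) {
      off <- strokemark:::.angleOffset(ang, d)
      counts <- bruteGLCM(lv, off[1], off[2])
      g <- glcmSlice(lv, d, ang)
      expect_equal(g@validPairCount, as.integer(sum(counts) / 2))
      if (sum(counts) == 0) next
      p <- counts / sum(counts)
      expect_lt(max(abs(g@p - p)), 1e-12)
      expect_equal(haralickFeatures(g), bruteHaralick(p), tolerance = 1e-10)
    }
  }
})

test_that("energy squares to ASM for every co-occurrence matrix", {
  set.seed(42)
  for (rep in 1:10) {
    lv <- randomLevelSlice(10, 10)
    g <- glcmSlice(lv, sample(1:3, 1), sample(c(0, 45, 90, 135), 1))
    if (g@validPairCount == 0) next
    h <- haralickFeatures(g)
    expect_equal(unname(h["energy"]^2), unname(h["asm"]), tolerance = 1e-12)
  }
})

test_that("slice entropy from the level histogram", {
  expect_equal(sliceEntropy(matrix(7L, 3, 3)), 0)
  lv <- matrix(rep(0:255, length.out = 256), 16, 16)
  expect_equal(sliceEntropy(lv), 8)
  two <- matrix(c(rep(0L, 9), rep(1L, 3)), 3, 4)
  expect_equal(sliceEntropy(two), 0.8113, tolerance = 1e-4)
  expect_error(sliceEntropy(matrix(NA_integer_, 2, 2)), "empty")
})

test_that("per-subject texture: averaging protocol and degenerate cases", {
  set.seed(43)
  sh <- c(12, 12, 8)
  vol <- ScalarVolume(array(rnorm(prod(sh), 100, 25), sh))
  # one-slice lesion: subject features equal that slice's features
  m1 <- array(0L, sh); m1[3:9, 3:9, 4] <- 1L
  mk1 <- BinaryMask(m1)
  tx <- lesionTexture(vol, mk1)
  expect_length(tx, 7)
  lev <- normalizeTo8bit(vol, mk1)
  acc <- NULL
  for (d in 1:3) for (ang in c(0, 45, 90, 135)) {
    g <- glcmSlice(lev[, , 4], d, ang)
    if (g@validPairCount > 0) acc <- rbind(acc, haralickFeatures(g))
  }
  manual <- c(colMeans(acc), entropy = sliceEntropy(lev[, , 4]))
  expect_equal(unname(tx), unname(manual), tolerance = 1e-12)

  # constant in-lesion intensities
  cvol <- ScalarVolume(array(7, sh))
  m2 <- array(0L, sh); m2[4:8, 4:8, 3:5] <- 1L
  txc <- lesionTexture(cvol, BinaryMask(m2))
  expect_equal(unname(txc),
               c(0, 0, 1, 1, 1, 1, 0))

  # single-voxel lesion: no pairs anywhere
  m3 <- array(0L, sh); m3[6, 6, 4] <- 1L
  expect_error(lesionTexture(vol, BinaryMask(m3)), "no slice yields")
})

test_that("texture is invariant under affine rescaling of the raw volume", {
  set.seed(44)
  sh <- c(14, 14, 6)
  vals <- array(rnorm(prod(sh), 500, 80), sh)
  m <- array(0L, sh); m[3:12, 3:12, 2:5] <- 1L
  mk <- BinaryMask(m)
  t1 <- lesionTexture(ScalarVolume(vals), mk)
  t2 <- lesionTexture(ScalarVolume(vals * 3.7 + 42), mk)
  expect_equal(t1, t2, tolerance = 1e-9)
})

test_that("texture is invariant under in-slice translation of the lesion", {
  set.seed(45)
  sh <- c(20, 20, 5)
  patch <- array(rnorm(6 * 6 * 2, 300, 40), c(6, 6, 2))
  v1 <- array(0, sh); v1[3:8, 3:8, 2:3] <- patch
  v2 <- array(0, sh); v2[12:17, 10:15, 2:3] <- patch
  m1 <- array(0L, sh); m1[3:8, 3:8, 2:3] <- 1L
  m2 <- array(0L, sh); m2[12:17, 10:15, 2:3] <- 1L
  expect_equal(lesionTexture(ScalarVolume(v1), BinaryMask(m1)),
               lesionTexture(ScalarVolume(v2), BinaryMask(m2)),
               tolerance = 1e-12)
})
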