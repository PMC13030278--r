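test_that("lesion volume is voxel count times voxel volume, in mL", {
  m <- filledBox(c(10, 10, 10))
  expect_equal(lesionVolume(m), 1.0)
  m8 <- filledBox(c(2, 2, 2), spacing = c(2, 2, 2))
  expect_equal(lesionVolume(m8), 0.064)
  expect_equal(lesionVolume(BinaryMask(array(0L, c(3, 3, 3)))), 0)
})

test_that("surface area: digital sphere near analytic, exact spacing scaling", {
  s <- digitalSphere(20L)
  a <- surfaceArea(s)
  expect_lt(abs(a / (4 * pi * 20^2) - 1), 0.03)
  s2 <- digitalSphere(20L, spacing = c(2, 2, 2))
  expect_equal(surfaceArea(s2), 4 * a, tolerance = 1e-6)
  # minimal input still yields a positive finite area
  v <- array(0L, c(5, 5, 5)); v[3, 3, 3] <- 1L
  a1 <- surfaceArea(BinaryMask(v))
  expect_true(is.finite(a1) && a1 > 0)
  expect_error(surfaceArea(BinaryMask(array(0L, c(3, 3, 3)))), "empty")
})

test_that("sphericity and compactness: closed forms and algebraic identity", {
  # sphere identity: A = (36 pi V^2)^(1/3)
  v <- 2.7
  a <- (36 * pi * (1000 * v)^2)^(1 / 3)
  expect_equal(sphericity(v, a), 1.0)
  expect_equal(compactness(v, a), 1.0)
  # analytic cube, any L: sphericity (pi/6)^(1/3), compactness 6/pi
  L <- 13
  expect_equal(sphericity(L^3 / 1000, 6 * L^2), (pi / 6)^(1 / 3))
  expect_equal(compactness(L^3 / 1000, 6 * L^2), 6 / pi)
  # compactness * sphericity^3 = 1 for arbitrary valid (V, A)
  set.seed(31)
  for (i in 1:20) {
    vv <- runif(1, 0.1, 50); aa <- runif(1, 50, 5000)
    expect_equal(compactness(vv, aa) * sphericity(vv, aa)^3, 1.0)
  }
  expect_error(sphericity(0, 10), "positive")
  expect_error(compactness(1, -1), "positive")
})

test_that("measured sphere sphericity approaches 1", {
  s <- digitalSphere(20L)
  v <- lesionVolume(s); a <- surfaceArea(s)
  expect_lt(abs(sphericity(v, a) - 1), 0.05)
})

test_that("solidity: convex solids near 1, L-shape matches the hull oracle", {
  box <- filledBox(c(8, 10, 6))
  expect_lt(abs(solidity(box) - 1.0), 0.05)
  # L-shaped union of two boxes; hull volume frozen from an independent
  # qhull computation on the same corner cloud (437.5 mm^3)
  v <- array(0L, c(14, 14, 9))
  v[2:11, 2:6, 2:6] <- 1L
  v[2:6, 7:11, 2:6] <- 1L
  L <- BinaryMask(v)
  expect_equal(voxelCount(L), 375L)
  expect_equal(convexHullVolume(L) * 1000, 437.5, tolerance = 1e-6)
  expect_equal(solidity(L), 375 / 437.5, tolerance = 1e-9)
  # solid spheres: bounded by 1, and the half-voxel hull inflation
  # shrinks with radius (0.9 is reached by r = 20)
  s15 <- solidity(digitalSphere(15L)); s20 <- solidity(digitalSphere(20L))
  expect_lte(s15, 1); expect_lte(s20, 1)
  expect_gte(s15, 0.85)
  expect_gte(s20, 0.9)
  expect_gt(s20, s15)
  v1 <- array(0L, c(3, 3, 3)); v1[2, 2, 2] <- 1L
  expect_equal(solidity(BinaryMask(v1)), 1.0)
})

test_that("elongation matches the brute-force covariance oracle", {
  # 1 x 1 x 41 rod
  v <- array(0L, c(5, 5, 45)); v[3, 3, 3:43] <- 1L
  rod <- BinaryMask(v)
  ev <- bruteCovEigen(imgValues(rod))
  expect_equal(elongation(rod), sqrt(ev[3] / ev[1]))
  # digital ball is isotropic
  expect_lt(abs(elongation(digitalSphere(10L)) - 1), 0.05)
  # invariant under axis permutation of the volume
  set.seed(33)
  m <- randomMask(c(7, 8, 9), 0.3)
  e1 <- elongation(m)
  perm <- BinaryMask(aperm(imgValues(m), c(3, 1, 2)),
                     VoxelGrid(dim(imgValues(m))[c(3, 1, 2)]))
  expect_equal(elongation(perm), e1, tolerance = 1e-10)
  # spacing enters in world mm: a stretched grid changes the answer
  iso <- BinaryMask(imgValues(m), VoxelGrid(dim(imgValues(m)), c(1, 1, 4)))
  expect_false(isTRUE(all.equal(elongation(iso), e1)))
  v1 <- array(0L, c(3, 3, 3)); v1[2, 2, 2] <- 1L
  expect_equal(elongation(BinaryMask(v1)), 1.0)
})

test_that("principal axes are sorted and non-negative", {
  set.seed(34)
  m <- randomMask(c(6, 9, 7), 0.4)
  pa <- principalAxes(m)
  expect_true(all(diff(pa$eigenvalues) <= 0))
  expect_true(all(pa$eigenvalues >= 0))
  expect_equal(pa$eigenvalues, bruteCovEigen(imgValues(m)))
})

test_that("quadrant fractions follow the index midplane rule", {
  # all voxels below both midlines of a (10,10,10) volume
  v <- array(0L, c(10, 10, 10)); v[1:4, , 1:4] <- 1L
  q <- quadrantFractions(BinaryMask(v))
  expect_equal(unname(q$fractions["LA"]), 1.0)
  expect_equal(sum(q$fractions), 1.0)
  expect_equal(q$dominant, "LA")
  # mirror-symmetric lesion: a quarter in each quadrant
  v2 <- array(0L, c(10, 10, 10))
  v2[c(3, 8), 5, c(3, 8)] <- 1L
  q2 <- quadrantFractions(BinaryMask(v2))
  expect_equal(unname(q2$fractions), rep(0.25, 4))
  # the midplane sits at shape/2 of the configured axes
  v3 <- array(0L, c(512, 4, 4)); v3[256, 2, 2] <- 1L  # 0-based index 255 < 256
  q3 <- quadrantFractions(BinaryMask(v3))
  expect_equal(unname(q3$fractions[["LA"]] + q3$fractions[["LP"]]), 1)
  v3[256, , ] <- 0L; v3[257, 2, 2] <- 1L  # 0-based 256, not < 256
  q4 <- quadrantFractions(BinaryMask(v3))
  expect_equal(unname(q4$fractions[["RA"]] + q4$fractions[["RP"]]), 1)
  expect_error(quadrantConfig(1, 1), "distinct")
})

test_that("intensity centroid matches brute-force weighted summation", {
  # two voxels at indices 0 and 10 with weights 1 and 3 -> 7.5
  vals <- array(1, c(11, 1, 1)); vals[11, 1, 1] <- 3
  m <- array(0L, c(11, 1, 1)); m[c(1, 11), 1, 1] <- 1L
  ctr <- intensityCentroid(ScalarVolume(vals), BinaryMask(m))
  expect_equal(ctr$voxel[1], 7.5)
  # uniform weights reduce to the geometric centroid
  set.seed(35)
  mk <- randomMask(c(6, 7, 8), 0.3)
  u <- ScalarVolume(array(4.2, c(6, 7, 8)))
  idx <- which(imgValues(mk) == 1L, arr.ind = TRUE)
  expect_equal(intensityCentroid(u, mk)$voxel, unname(colMeans(idx - 1)))
  # random weights against the triple-loop oracle
  vol <- ScalarVolume(array(runif(6 * 7 * 8, 1, 10), c(6, 7, 8)))
  expect_equal(intensityCentroid(vol, mk)$voxel,
               bruteCentroid(imgValues(vol), imgValues(mk)))
  # world centroid maps through the affine
  expect_equal(intensityCentroid(vol, mk)$world,
               as.numeric(voxelToWorld(imgGrid(mk),
                                       intensityCentroid(vol, mk)$voxel)))
})

test_that("max and average in-lesion intensity", {
  v <- array(0, c(3, 1, 1)); v[] <- c(1, 2, 3)
  m <- BinaryMask(array(1L, c(3, 1, 1)))
  mi <- maxAvgIntensity(ScalarVolume(v), m)
  expect_equal(unname(mi["max"]), 3)
  expect_equal(unname(mi["avg"]), 2)
  cst <- maxAvgIntensity(ScalarVolume(array(7, c(3, 1, 1))), m)
  expect_equal(unname(cst), c(7, 7))
  set.seed(36)
  mk <- randomMask(c(5, 5, 5), 0.5)
  vol <- ScalarVolume(array(rnorm(125), c(5, 5, 5)))
  r <- maxAvgIntensity(vol, mk)
  expect_lte(r["avg"], r["max"])
})

test_that("shape features are translation-invariant", {
  base <- array(0L, c(30, 30, 30))
  base[5:12, 6:11, 7:12] <- 1L
  base[8:15, 9:14, 9:14] <- 1L
  m1 <- BinaryMask(base)
  shifted <- array(0L, c(30, 30, 30))
  shifted[(5:12) + 9, (6:11) + 10, (7:12) + 8] <- 1L
  shifted[(8:15) + 9, (9:14) + 10, (9:14) + 8] <- 1L
  m2 <- BinaryMask(shifted)
  f1 <- morphologyFeatures(m1); f2 <- morphologyFeatures(m2)
  for (nm in names(f1)) expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-9)
})
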