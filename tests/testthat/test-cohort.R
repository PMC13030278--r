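test_that("the registry names exactly 19 features expanding to 26 columns", {
  reg <- featureRegistry()
  expect_equal(nrow(reg), 19L)
  expect_equal(sum(reg$width), 26L)
  expect_equal(length(featureColumns()), 26L)
  expect_equal(anyDuplicated(featureColumns()), 0L)
  expect_equal(as.vector(table(reg$group)[c("morphological", "intensity",
                                            "texture", "tract")]),
               c(6L, 4L, 7L, 2L))
})

test_that("extractSubject composes the stage results into one record", {
  spec <- smallPhantomSpec()
  s <- makeSubject(spec, 7)
  rec <- extractSubject("s7", s$adc, s$candidates, s$cstLeft, s$cstRight)
  expect_equal(nrow(rec), 1L)
  expect_setequal(names(rec), c("subject_id", featureColumns()))

  fused <- majorityVote(s$candidates)
  expect_equal(rec$volume_ml, lesionVolume(fused))
  m <- morphologyFeatures(fused)
  expect_equal(rec$sphericity, m$sphericity)
  expect_equal(rec$solidity, m$solidity)
  expect_equal(rec$elongation, m$elongation)
  si <- spatialIntensityFeatures(s$adc, fused)
  expect_equal(rec$max_intensity, si$max_intensity)
  expect_equal(rec$centroid_x_mm, si$centroid_world_mm[1])
  expect_equal(rec$quadrant_la, unname(si$quadrants["LA"]))
  tx <- lesionTexture(s$adc, fused)
  expect_equal(rec$contrast, unname(tx["contrast"]))
  expect_equal(rec$entropy, unname(tx["entropy"]))
  ov <- overlapMetrics(fused, s$cstLeft, s$cstRight)
  expect_equal(rec$cst_left_overlap_pct, ov$left_overlap_pct)
  expect_equal(rec$cst_right_volume_ml, ov$right_cst_volume_ml)
})

test_that("an empty fused lesion yields the documented degenerate record", {
  spec <- smallPhantomSpec()
  s <- makeSubject(spec, 8)
  empty <- BinaryMask(array(0L, dim(imgValues(s$adc))), imgGrid(s$adc))
  expect_warning(
    rec <- extractSubject("sEmpty", s$adc, list(empty), s$cstLeft, s$cstRight),
    "empty fused lesion")
  expect_equal(rec$volume_ml, 0)
  expect_true(is.na(rec$sphericity))
  expect_true(is.na(rec$contrast))
  expect_true(is.na(rec$max_intensity))
  expect_equal(rec$cst_left_overlap_pct, 0)
  expect_equal(rec$cst_right_overlap_pct, 0)
})

test_that("label attachment: exclusion bookkeeping and mRS dichotomisation", {
  cols <- featureColumns()
  n <- 149L
  df <- data.frame(subject_id = sprintf("s%03d", 1:n))
  for (cl in cols) df[[cl]] <- rnorm(n)
  tab <- makeCohortTable(df)
  labels <- data.frame(subject_id = sprintf("s%03d", 1:97),
                       mrs = rep(c(0:6), length.out = 97))
  expect_message(lab <- attachLabels(tab, labels), "52 of 149")
  f <- lab@features
  expect_equal(sum(f$labeled), 97L)
  expect_equal(sum(!f$labeled), 52L)
  expect_equal(f$outcome[f$mrs == 2 & !is.na(f$mrs)][1], 0L)
  expect_equal(f$outcome[f$mrs == 3 & !is.na(f$mrs)][1], 1L)
  expect_true(all(is.na(f$outcome[!f$labeled])))

  # all labeled -> zero exclusions, no message about exclusion
  all97 <- makeCohortTable(df[1:97, ])
  expect_no_message(attachLabels(all97, labels))
  # unknown subject ids in the label table are ignored with a warning
  labX <- rbind(labels, data.frame(subject_id = "nope", mrs = 1))
  expect_warning(attachLabels(all97, labX), "unknown subject ids")
})

test_that("cohort CSV round trip is lossless including NA cells", {
  spec <- smallPhantomSpec()
  ph <- phantomCohort(spec, 4, 99)
  tab <- ph$table
  tab@features$sphericity[2] <- NA_real_
  f <- tempfile(fileext = ".csv")
  writeCohort(tab, f)
  back <- readCohort(f)
  expect_equal(back@features, tab@features, tolerance = 1e-12)
  expect_equal(back@configHash, tab@configHash)
  # documented fixed column layout
  hdr <- strsplit(readLines(f, n = 2)[2], ",")[[1]]
  expect_equal(gsub('"', "", hdr)[1:27], c("subject_id", featureColumns()))
  expect_error(suppressWarnings(readCohort(tempfile())),
               "cannot open|parse error")
  bad <- tempfile(fileext = ".csv")
  writeLines("just,some,csv", bad)
  expect_error(readCohort(bad), "line 1")
})

test_that("cohort tables refuse to combine across configurations", {
  spec <- smallPhantomSpec()
  a <- phantomCohort(spec, 2, 1)$table
  b <- phantomCohort(spec, 2, 50)$table
  b@features$subject_id <- paste0("b-", b@features$subject_id)
  ab <- combineCohorts(a, b)
  expect_equal(nrow(ab@features), 4L)
  other <- extractionConfig(glcm = glcmConfig(distances = 1:2))
  c2 <- phantomCohort(spec, 2, 80, config = other)$table
  c2@features$subject_id <- paste0("c-", c2@features$subject_id)
  expect_error(combineCohorts(a, c2), "different configuration")
})

test_that("extraction is deterministic for identical inputs and config", {
  spec <- smallPhantomSpec()
  s <- makeSubject(spec, 12)
  r1 <- extractSubject("x", s$adc, s$candidates, s$cstLeft, s$cstRight)
  r2 <- extractSubject("x", s$adc, s$candidates, s$cstLeft, s$cstRight)
  expect_identical(r1, r2)
})

test_that("manifest-driven extraction reproduces in-memory records", {
  spec <- smallPhantomSpec()
  dir <- file.path(tempdir(), "phantom-cohort-io")
  unlink(dir, recursive = TRUE)
  paths <- makeCohort(spec, 2, 5, dir)
  tab <- suppressMessages(
    cohortFromManifest(paths$manifest, labels = paths$labels))
  expect_equal(nrow(tab@features), 2L)
  expect_true(all(c("mrs", "outcome", "labeled") %in% names(tab@features)))
  mem <- phantomCohort(spec, 2, 5)
  expect_equal(tab@features[, featureColumns()],
               mem$table@features[, featureColumns()], tolerance = 1e-9)
  truth <- read.csv(paths$truth)
  expect_equal(tab@features$mrs, truth$mrs)
})
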