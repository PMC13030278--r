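test_that("ANOVA F equals the squared pooled two-sample t statistic", {
  set.seed(61)
  y <- rep(c(0, 1), each = 30)
  X <- cbind(a = rnorm(60) + 0.8 * y, b = rnorm(60))
  f <- anovaFScores(X, y)
  for (cl in colnames(X)) {
    tt <- t.test(X[y == 0, cl], X[y == 1, cl], var.equal = TRUE)
    expect_equal(unname(f[cl]), unname(tt$statistic^2), tolerance = 1e-10)
    lmF <- anova(lm(X[, cl] ~ factor(y)))$`F value`[1]
    expect_equal(unname(f[cl]), lmF, tolerance = 1e-10)
  }
  # a feature identical across classes scores zero
  X2 <- cbind(flat = rep(3.5, 60))
  expect_equal(unname(anovaFScores(X2, y)["flat"]), 0)
  expect_error(anovaFScores(X, rep(1, 60)), "one class")
})

test_that("null features are rejected at the nominal 5% rate", {
  set.seed(62)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 10000), n, 10000)
  f <- anovaFScores(X, y)
  p <- pf(f, 1, n - 2, lower.tail = FALSE)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
})

test_that("top-k selection is deterministic with index tie-breaks", {
  expect_equal(selectTopK(c(3, 1, 2), 2), c(1L, 3L))
  s <- c(5, 5, 1, 5)
  expect_equal(selectTopK(s, 2), c(1L, 2L))
  expect_equal(selectTopK(s, 4), c(1L, 2L, 4L, 3L))
  expect_error(selectTopK(c(1, NA, 2), 3), "exceeds")
  # identity selection at k = length
  sc <- c(0.2, 9, 4)
  expect_setequal(selectTopK(sc, 3), 1:3)
})

test_that("stratified split reproduces the 97 -> 77/20 bookkeeping", {
  y <- rep(c(0, 1), c(55, 42))
  sp <- stratifiedSplit(y, 0.2, seed = 5)
  expect_length(sp$test, 20L)
  expect_length(sp$train, 77L)
  expect_equal(sort(c(sp$train, sp$test)), 1:97)
  # class proportions within one subject of the cohort proportions
  propTest <- mean(y[sp$test])
  expect_lt(abs(propTest * 20 - 20 * mean(y)), 1 + 1e-9)
  # reproducible under the seed, different otherwise
  sp2 <- stratifiedSplit(y, 0.2, seed = 5)
  expect_identical(sp, sp2)
  sp3 <- stratifiedSplit(y, 0.2, seed = 6)
  expect_false(identical(sp$test, sp3$test))
  expect_error(stratifiedSplit(c(0, 0, 0, 1), 0.2), "stratification")
})

test_that("grid-search CV picks the only grid point and fits separable data", {
  set.seed(63)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  X <- data.frame(sig = y * 4 + rnorm(n, 0, 0.1), noise = rnorm(n))
  rownames(X) <- paste0("r", 1:n)
  cfg <- modelConfig(grid = data.frame(mtry = 2, nodesize = 1),
                     seed = 1, bootstrapReps = 0L, permReps = 0L)
  fit <- trainWithCV(X, y, cfg)
  expect_equal(nrow(fit$cvResults), 1L)
  expect_equal(fit$best$mtry, 2)
  pr <- strokemark:::.predictProb(fit$fit, X)
  expect_equal(as.integer(pr >= 0.5), y)  # training accuracy 1
  expect_error(trainWithCV(X, y, modelConfig(grid = data.frame()[0, ])),
               "empty")
})

test_that("evaluation metrics match closed forms from the confusion counts", {
  obs <- rep(c(1, 0), each = 10)
  scores <- c(rep(0.9, 9), 0.1, rep(0.1, 9), 0.9)  # TP=9 FN=1 TN=9 FP=1
  m <- strokemark:::.metricsFrom(obs, scores)
  expect_equal(unname(m["accuracy"]), 0.9)
  expect_equal(unname(m["precision"]), 0.9)
  expect_equal(unname(m["recall"]), 0.9)
  expect_equal(unname(m["f1"]), 0.9)
  perfect <- strokemark:::.metricsFrom(obs, as.numeric(obs))
  expect_equal(unname(perfect[c("accuracy", "precision", "recall", "f1",
                                "roc_auc", "mcc")]),
               rep(1, 6))
  # single-class truth: AUC is NA, others still defined
  one <- strokemark:::.metricsFrom(rep(1, 5), c(0.9, 0.8, 0.9, 0.2, 0.7))
  expect_true(is.na(one["roc_auc"]))
  expect_equal(unname(one["accuracy"]), 0.8)
})

test_that("label-permuted scores give chance-level AUC", {
  set.seed(64)
  obs <- rbinom(4000, 1, 0.5)
  scores <- runif(4000)
  expect_equal(strokemark:::.aucOf(obs, scores), 0.5, tolerance = 0.05)
})

test_that("bootstrap CIs: degenerate width, seeding, and n-scaling", {
  accFun <- strokemark:::.metricFuns()$accuracy
  obs <- rep(c(0, 1), each = 10)
  ci <- bootstrapCI(accFun, obs, as.numeric(obs), reps = 200, seed = 2)
  expect_equal(as.numeric(ci), c(1, 1))  # all predictions correct everywhere
  set.seed(65)
  obs2 <- rbinom(2000, 1, 0.5)
  sc2 <- ifelse(runif(2000) < 0.8, obs2, 1 - obs2)
  ciBig <- bootstrapCI(accFun, obs2, sc2, reps = 300, seed = 3)
  ciSmall <- bootstrapCI(accFun, obs2[1:20], sc2[1:20], reps = 300, seed = 3)
  expect_gt(diff(ciSmall) / diff(ciBig), 3)
  ciRep <- bootstrapCI(accFun, obs2, sc2, reps = 300, seed = 3)
  expect_identical(as.numeric(ciRep), as.numeric(ciBig))
  expect_error(bootstrapCI(accFun, obs, as.numeric(obs), reps = 10), ">= 100")
})

test_that("feature importance separates signal from noise", {
  set.seed(66)
  n <- 240
  y <- rep(c(0, 1), each = n / 2)
  X <- data.frame(signal = y + rnorm(n, 0, 0.25),
                  noise1 = rnorm(n), noise2 = rnorm(n))
  rownames(X) <- paste0("r", 1:n)
  idx <- sample(n)
  Xtr <- X[idx[1:160], ]; ytr <- y[idx[1:160]]
  Xte <- X[idx[161:n], ]; yte <- y[idx[161:n]]
  cfg <- modelConfig(grid = data.frame(mtry = 2, nodesize = 1), seed = 4)
  fit <- trainWithCV(Xtr, ytr, cfg)
  imp <- featureImportance(fit, Xte, yte, reps = 30, seed = 4)
  expect_equal(imp$ranking[1], "signal")
  expect_equal(names(which.max(imp$impurity)), "signal")
  # pure-noise features sit near zero permutation importance
  expect_lt(max(abs(imp$permutation[c("noise1", "noise2")])), 0.05)
})

test_that("the full protocol keeps model development blind to test rows", {
  spec <- smallPhantomSpec()
  ph <- phantomCohort(spec, 60, 3)
  seen <- list()
  hook <- function(stage, ids) seen[[length(seen) + 1]] <<- list(stage = stage, ids = ids)
  cfg <- modelConfig(seed = 9, bootstrapReps = 0L, permReps = 0L,
                     auditHook = hook)
  res <- runOutcomeModel(ph$table, cfg)
  stages <- vapply(seen, `[[`, "", "stage")
  expect_setequal(unique(stages), c("selection", "cv", "evaluate"))
  testIds <- res$split$test
  for (rec in seen)
    if (rec$stage %in% c("selection", "cv"))
      expect_length(intersect(rec$ids, testIds), 0L)
  evalIds <- unlist(lapply(seen[stages == "evaluate"], `[[`, "ids"))
  expect_setequal(evalIds, testIds)
})

test_that("the end-to-end protocol returns a complete report", {
  spec <- smallPhantomSpec()
  ph <- phantomCohort(spec, 80, 17)
  cfg <- modelConfig(seed = 2, bootstrapReps = 200L, permReps = 5L)
  res <- runOutcomeModel(ph$table, cfg)
  expect_length(res$selectedFeatures, 17L)
  expect_equal(length(res$fScores), 19L)
  m <- res$report$metrics
  expect_true(all(m[c("accuracy", "precision", "recall", "f1")] >= 0 &
                  m[c("accuracy", "precision", "recall", "f1")] <= 1))
  expect_true(m["mcc"] >= -1 && m["mcc"] <= 1)
  ci <- res$report$ci
  expect_equal(nrow(ci), 6L)
  ok <- !is.na(ci$low)
  expect_true(all(ci$low[ok] <= ci$high[ok]))
  expect_equal(sum(res$report$confusion), res$report$nTest)
  expect_length(res$importance$permutation,
                length(unlist(strsplit(featureRegistry()$columns[
                  featureRegistry()$feature %in% res$selectedFeatures], ","))))
  # same seed, same table -> identical metrics
  res2 <- runOutcomeModel(ph$table, cfg)
  expect_identical(res$report$metrics, res2$report$metrics)
})
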