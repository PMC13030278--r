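.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Outcome-modelling configuration
#'
#' @param kSelect number of named features retained by ANOVA selection.
#' @param testFraction held-out test fraction of the stratified split.
#' @param cvFolds folds for the grid-search cross-validation.
#' @param family classifier family: "random-forest" (randomForest) or
#'   "gradient-boosting" (xgboost, if installed).
#' @param grid data.frame of hyperparameter combinations; NULL uses a
#'   small default grid per family (random forest: mtry x nodesize;
#'   gradient boosting: max_depth x eta x nrounds).
#' @param ntree trees per random forest.
#' @param bootstrapReps bootstrap resamples for metric CIs (0 skips CIs).
#' @param ciLevel confidence level of the percentile intervals.
#' @param permReps permutation repetitions for importance (0 skips).
#' @param seed RNG seed for split/CV/bootstrap reproducibility.
#' @param auditHook optional function(stage, rowIds) called with the
#'   subject ids of every data subset touched by selection, CV training
#'   and evaluation; used to audit that model development never reads
#'   test rows.
#' @return a list with class "modelConfig".
#' @export
modelConfig <- function(kSelect = 17L, testFraction = 0.2, cvFolds = 5L,
                        family = c("random-forest", "gradient-boosting"),
                        grid = NULL, ntree = 300L, bootstrapReps = 1000L,
                        ciLevel = 0.95, permReps = 20L, seed = NULL,
                        auditHook = NULL) {
  family <- match.arg(family)
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must be in (0, 1)")
  if (kSelect < 1L) stop("kSelect must be >= 1")
  if (is.null(grid)) {
    grid <- if (family == "random-forest")
      expand.grid(mtry = c(3L, 5L), nodesize = c(1L, 5L))
    else
      expand.grid(max_depth = c(2L, 3L), eta = c(0.1, 0.3), nrounds = 60L)
  }
  structure(list(kSelect = as.integer(kSelect), testFraction = testFraction,
                 cvFolds = as.integer(cvFolds), family = family, grid = grid,
                 ntree = as.integer(ntree),
                 bootstrapReps = as.integer(bootstrapReps),
                 ciLevel = ciLevel, permReps = as.integer(permReps),
                 seed = seed, auditHook = auditHook),
            class = "modelConfig")
}

#' One-way ANOVA F statistic per feature column
#'
#' For a binary outcome the per-column F statistic between the two label
#' groups (equal to the squared pooled two-sample t statistic). Columns
#' with zero within-group variance but distinct group means score Inf;
#' columns constant overall score 0.
#'
#' @param X numeric matrix or data.frame, samples x features (no NAs).
#' @param y binary labels (0/1), at least 2 samples per class.
#' @return named numeric of F statistics, one per column.
#' @export
anovaFScores <- function(X, y) {
  X <- as.matrix(X)
  y <- as.integer(y)
  cls <- sort(unique(y))
  if (length(cls) < 2L) stop("degenerate labels: only one class present")
  if (min(table(y)) < 2L) stop("need at least 2 samples per class")
  n <- nrow(X)
  g1 <- y == cls[2]
  n0 <- sum(!g1); n1 <- sum(g1)
  m0 <- colMeans(X[!g1, , drop = FALSE])
  m1 <- colMeans(X[g1, , drop = FALSE])
  m <- colMeans(X)
  ssb <- n0 * (m0 - m)^2 + n1 * (m1 - m)^2
  ssw <- colSums((X[!g1, , drop = FALSE] - rep(m0, each = n0))^2) +
         colSums((X[g1, , drop = FALSE] - rep(m1, each = n1))^2)
  f <- ifelse(ssw > 0, ssb / (ssw / (n - 2)),
              ifelse(ssb > 0, Inf, 0))
  stats::setNames(f, colnames(X))
}

#' Indices of the k largest selection scores
#'
#' Ties break toward the lower column index for determinism; non-finite
#' scores are never selected and \code{k} must not exceed the number of
#' finite scores.
#'
#' @param scores numeric vector of per-feature scores.
#' @param k number of features to retain.
#' @return integer vector of the selected indices, in decreasing score
#'   order.
#' @export
selectTopK <- function(scores, k) {
  fin <- !is.na(scores)
  if (k > sum(fin)) stop("k exceeds the number of scored features")
  ord <- order(-scores, seq_along(scores))
  ord <- ord[fin[ord]]
  ord[seq_len(k)]
}

#' Stratified train/test split
#'
#' Allocates \code{ceiling(n * testFraction)} samples to the test set,
#' distributed across classes proportionally (largest-remainder rounding)
#' so test class proportions match the cohort within one subject.
#' Reproducible under \code{seed}.
#'
#' @param y binary labels of all samples.
#' @param testFraction test fraction in (0, 1).
#' @param seed optional RNG seed.
#' @return list with integer index vectors \code{train} and \code{test}.
#' @export
stratifiedSplit <- function(y, testFraction = 0.2, seed = NULL) {
  y <- as.integer(y)
  tab <- table(y)
  if (length(tab) < 2L || min(tab) < 2L)
    stop("stratification error: each class needs at least 2 members")
  n <- length(y)
  nTest <- as.integer(ceiling(n * testFraction))
  exact <- as.numeric(tab) * nTest / n
  base <- floor(exact)
  rem <- nTest - sum(base)
  if (rem > 0) {
    extra <- order(-(exact - base))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base <- pmin(pmax(base, 1L), as.numeric(tab) - 1L)
  .withSeed(seed, {
    test <- unlist(lapply(seq_along(tab), function(ci) {
      idx <- which(y == as.integer(names(tab))[ci])
      sample(idx, base[ci])
    }))
    test <- sort(test)
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

.stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.f1Score <- function(obs, pred) {
  tp <- sum(obs == 1 & pred == 1)
  fp <- sum(obs == 0 & pred == 1)
  fn <- sum(obs == 1 & pred == 0)
  if (tp == 0) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

.fitOne <- function(X, y, config, params) {
  if (config$family == "random-forest") {
    randomForest::randomForest(
      x = X, y = factor(y, levels = c(0, 1)), ntree = config$ntree,
      mtry = min(params$mtry, ncol(X)), nodesize = params$nodesize)
  } else {
    if (!requireNamespace("xgboost", quietly = TRUE))
      stop("the gradient-boosting family requires the xgboost package")
    xgboost::xgboost(
      data = as.matrix(X), label = y, verbose = 0,
      nrounds = params$nrounds, max_depth = params$max_depth,
      eta = params$eta, objective = "binary:logistic", nthread = 1)
  }
}

.predictProb <- function(fit, X) {
  if (inherits(fit, "randomForest"))
    unname(stats::predict(fit, newdata = X, type = "prob")[, "1"])
  else
    stats::predict(fit, as.matrix(X))
}

#' Grid-search cross-validated training
#'
#' Evaluates every hyperparameter combination of the configuration grid by
#' stratified k-fold cross-validation on the training data only, scores
#' each by mean CV F1 at the 0.5 probability threshold, picks the best
#' (first row on ties) and refits it on the full training set.
#'
#' @param X training feature matrix (data.frame, samples x features).
#' @param y training binary labels.
#' @param config a [modelConfig()].
#' @return list: \code{fit} (the refitted classifier), \code{best} (chosen
#'   grid row), \code{cvResults} (grid with mean CV F1), \code{family},
#'   \code{featureNames}.
#' @export
trainWithCV <- function(X, y, config = modelConfig()) {
  grid <- config$grid
  if (is.null(grid) || nrow(grid) == 0L) stop("empty hyperparameter grid")
  if (!is.null(config$auditHook)) config$auditHook("cv", rownames(X))
  y <- as.integer(y)
  fold <- .stratifiedFolds(y, config$cvFolds)
  cvF1 <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    f1s <- numeric(config$cvFolds)
    for (k in seq_len(config$cvFolds)) {
      tr <- fold != k
      if (length(unique(y[tr])) < 2L) { f1s[k] <- NA; next }
      fit <- .fitOne(X[tr, , drop = FALSE], y[tr], config, grid[gi, , drop = FALSE])
      pr <- .predictProb(fit, X[!tr, , drop = FALSE])
      f1s[k] <- .f1Score(y[!tr], as.integer(pr >= 0.5))
    }
    cvF1[gi] <- mean(f1s, na.rm = TRUE)
  }
  bi <- which.max(cvF1)
  fit <- .fitOne(X, y, config, grid[bi, , drop = FALSE])
  list(fit = fit, best = grid[bi, , drop = FALSE],
       cvResults = cbind(grid, cvF1 = cvF1), family = config$family,
       featureNames = colnames(X))
}

.confusion <- function(obs, pred) {
  c(TP = sum(obs == 1 & pred == 1), FP = sum(obs == 0 & pred == 1),
    TN = sum(obs == 0 & pred == 0), FN = sum(obs == 1 & pred == 0))
}

.aucOf <- function(obs, scores) {
  if (length(unique(obs)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(obs, scores, levels = c(0, 1),
                                 direction = "<", quiet = TRUE)))
}

.metricsFrom <- function(obs, scores, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  cf <- .confusion(obs, pred)
  tp <- cf["TP"]; fp <- cf["FP"]; tn <- cf["TN"]; fn <- cf["FN"]
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- .f1Score(obs, pred)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) NA_real_ else
    (tp * tn - fp * fn) / denom
  c(accuracy = unname((tp + tn) / length(obs)),
    precision = unname(precision), recall = unname(recall),
    f1 = unname(f1), roc_auc = .aucOf(obs, scores), mcc = unname(mcc))
}

#' Evaluate a fitted classifier on held-out data
#'
#' Computes accuracy, precision, recall, F1, ROC-AUC and Matthews
#' correlation from the held-out predictions at the 0.5 probability
#' threshold (positive class = unfavourable outcome). With a single-class
#' test set ROC-AUC is NA and the other metrics are still computed.
#'
#' @param model the list returned by [trainWithCV()].
#' @param X held-out feature matrix (columns as trained).
#' @param y held-out binary labels.
#' @param config a [modelConfig()] (audit hook only).
#' @return list: \code{metrics} (named numeric(6)), \code{confusion}
#'   (TP/FP/TN/FN), \code{nTest}, \code{scores}, \code{obs}.
#' @export
evaluateModel <- function(model, X, y, config = modelConfig()) {
  if (!is.null(config$auditHook)) config$auditHook("evaluate", rownames(X))
  X <- X[, model$featureNames, drop = FALSE]
  scores <- .predictProb(model$fit, X)
  obs <- as.integer(y)
  list(metrics = .metricsFrom(obs, scores),
       confusion = .confusion(obs, as.integer(scores >= 0.5)),
       nTest = length(obs), scores = scores, obs = obs)
}

#' Bootstrap percentile confidence interval of a test metric
#'
#' Recomputes the metric on \code{reps} resamples (with replacement, of
#' the test-set size) of the held-out predictions and returns the
#' percentile interval. Resamples on which the metric is undefined
#' (e.g. single-class for ROC-AUC) are skipped and counted.
#'
#' @param metricFun function(obs, scores) -> numeric(1).
#' @param obs held-out labels.
#' @param scores held-out predicted scores.
#' @param reps resamples, >= 100.
#' @param level confidence level, default 0.95.
#' @param seed optional RNG seed.
#' @return numeric c(low, high) with attributes "skipped" (count of
#'   undefined resamples) and "point" (the full-test-set value); NA/NA
#'   when every resample was undefined.
#' @export
bootstrapCI <- function(metricFun, obs, scores, reps = 1000L, level = 0.95,
                        seed = NULL) {
  if (reps < 100L) stop("reps must be >= 100")
  n <- length(obs)
  vals <- .withSeed(seed, vapply(seq_len(reps), function(r) {
    i <- sample.int(n, n, replace = TRUE)
    metricFun(obs[i], scores[i])
  }, 0.0))
  ok <- !is.na(vals)
  if (!any(ok)) {
    ci <- c(low = NA_real_, high = NA_real_)
  } else {
    a <- (1 - level) / 2
    q <- stats::quantile(vals[ok], c(a, 1 - a), names = FALSE, type = 7)
    ci <- c(low = q[1], high = q[2])
  }
  attr(ci, "skipped") <- sum(!ok)
  attr(ci, "point") <- metricFun(obs, scores)
  ci
}

.metricFuns <- function() {
  list(
    accuracy = function(o, s) mean(o == as.integer(s >= 0.5)),
    precision = function(o, s) {
      p <- as.integer(s >= 0.5)
      if (sum(p) == 0) 0 else sum(o == 1 & p == 1) / sum(p)
    },
    recall = function(o, s) {
      if (sum(o) == 0) return(NA_real_)
      sum(o == 1 & s >= 0.5) / sum(o)
    },
    f1 = function(o, s) .f1Score(o, as.integer(s >= 0.5)),
    roc_auc = function(o, s) .aucOf(o, s),
    mcc = function(o, s) unname(.metricsFrom(o, s)["mcc"]))
}

#' Impurity and permutation feature importance
#'
#' Impurity importance comes from the fitted trees; permutation importance
#' is the mean drop in held-out ROC-AUC (accuracy when AUC is undefined)
#' when one column of the held-out data is shuffled, averaged over
#' \code{reps} shuffles. Permutation uses only held-out data.
#'
#' @param model the list returned by [trainWithCV()].
#' @param X held-out feature matrix.
#' @param y held-out labels.
#' @param reps shuffles per feature.
#' @param seed optional RNG seed.
#' @return list: \code{impurity}, \code{permutation} (named numerics) and
#'   \code{ranking} (feature names by decreasing permutation importance).
#' @export
featureImportance <- function(model, X, y, reps = 20L, seed = NULL) {
  X <- X[, model$featureNames, drop = FALSE]
  obs <- as.integer(y)
  imp <- if (inherits(model$fit, "randomForest")) {
    v <- model$fit$importance[, 1]
    stats::setNames(as.numeric(v), rownames(model$fit$importance))
  } else {
    it <- xgboost::xgb.importance(model = model$fit)
    v <- stats::setNames(rep(0, ncol(X)), colnames(X))
    v[it$Feature] <- it$Gain
    v
  }
  base <- .aucOf(obs, .predictProb(model$fit, X))
  scoreFun <- if (is.na(base)) {
    function(o, s) mean(o == as.integer(s >= 0.5))
  } else .aucOf
  base <- scoreFun(obs, .predictProb(model$fit, X))
  perm <- .withSeed(seed, {
    vapply(colnames(X), function(cl) {
      drops <- vapply(seq_len(reps), function(r) {
        Xp <- X
        Xp[[cl]] <- sample(Xp[[cl]])
        base - scoreFun(obs, .predictProb(model$fit, Xp))
      }, 0.0)
      mean(drops)
    }, 0.0)
  })
  list(impurity = imp, permutation = perm,
       ranking = names(sort(perm, decreasing = TRUE)))
}

#' Run the full outcome-modelling protocol on a labeled cohort
#'
#' Implements the exploratory protocol end to end with a strict
#' train/test separation: stratified split of the labeled subjects;
#' training-median imputation of degenerate (NA) feature cells; per-column
#' ANOVA F statistics on the training rows aggregated to the 19 named
#' features (a multi-component feature scores by its best column); top-k
#' feature selection; grid-search cross-validated training; one-shot
#' held-out evaluation with bootstrap percentile CIs; and impurity plus
#' permutation feature importance. Feature selection, imputation
#' statistics, and CV read training rows only.
#'
#' @param table a labeled [CohortTable-class] (see [attachLabels()]).
#' @param config a [modelConfig()].
#' @return list: \code{report} (metrics, CIs, confusion, nTest),
#'   \code{model}, \code{selectedFeatures}, \code{fScores} (per named
#'   feature), \code{split} (subject ids), \code{importance},
#'   \code{config}.
#' @export
runOutcomeModel <- function(table, config = modelConfig()) {
  stopifnot(is(table, "CohortTable"))
  f <- table@features
  if (!"outcome" %in% names(f))
    stop("cohort table has no outcome labels; call attachLabels() first")
  f <- f[!is.na(f$outcome), , drop = FALSE]
  cols <- featureColumns()
  X <- as.data.frame(f[, cols, drop = FALSE])
  rownames(X) <- f$subject_id
  y <- f$outcome

  .withSeed(config$seed, {
    sp <- stratifiedSplit(y, config$testFraction)
    Xtr <- X[sp$train, , drop = FALSE]
    Xte <- X[sp$test, , drop = FALSE]
    ytr <- y[sp$train]; yte <- y[sp$test]

    # impute degenerate cells from the training distribution only
    med <- vapply(Xtr, function(v) stats::median(v, na.rm = TRUE), 0.0)
    med[is.na(med)] <- 0
    for (cl in cols) {
      Xtr[[cl]][is.na(Xtr[[cl]])] <- med[[cl]]
      Xte[[cl]][is.na(Xte[[cl]])] <- med[[cl]]
    }

    if (!is.null(config$auditHook)) config$auditHook("selection", rownames(Xtr))
    fCol <- anovaFScores(Xtr, ytr)
    reg <- featureRegistry()
    fFeat <- vapply(seq_len(nrow(reg)), function(i) {
      cc <- strsplit(reg$columns[i], ",")[[1]]
      max(fCol[cc])
    }, 0.0)
    names(fFeat) <- reg$feature
    keep <- selectTopK(fFeat, min(config$kSelect, nrow(reg)))
    selFeat <- reg$feature[sort(keep)]
    selCols <- unlist(strsplit(reg$columns[sort(keep)], ","), use.names = FALSE)

    model <- trainWithCV(Xtr[, selCols, drop = FALSE], ytr, config)
    ev <- evaluateModel(model, Xte[, selCols, drop = FALSE], yte, config)

    cis <- NULL
    if (config$bootstrapReps > 0L) {
      mf <- .metricFuns()
      cis <- do.call(rbind, lapply(names(mf), function(nm) {
        ci <- bootstrapCI(mf[[nm]], ev$obs, ev$scores,
                          reps = config$bootstrapReps, level = config$ciLevel)
        data.frame(metric = nm, point = attr(ci, "point"),
                   low = ci[["low"]], high = ci[["high"]],
                   skipped = attr(ci, "skipped"))
      }))
    }
    importance <- if (config$permReps > 0L)
      featureImportance(model, Xte[, selCols, drop = FALSE], yte,
                        reps = config$permReps) else NULL

    list(report = list(metrics = ev$metrics, ci = cis,
                       confusion = ev$confusion, nTest = ev$nTest),
         model = model, selectedFeatures = selFeat,
         fScores = fFeat,
         split = list(train = rownames(Xtr), test = rownames(Xte)),
         importance = importance, config = config)
  })
}
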