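#' Prediction configuration
#'
#' Hyperparameters follow the study's settings: MARS with 5 degrees of
#' interaction and 35 model terms; random forest with 100 trees and 8
#' candidate variables per split; SVM with an RBF kernel
#' (`k(x, y) = exp(-gamma * ||x - y||^2)`, `gamma = 0.125`) and `C = 6`;
#' a 75/25 train/test split; SMOTE with `k = 20` neighbors and ratio 2;
#' fourfold cross-validation repeated over 10 iteration cycles.
#'
#' @param trainFraction fraction of dishes used for training.
#' @param marsDegree,marsMaxTerms MARS settings.
#' @param rfTrees,rfMtry random-forest settings.
#' @param svmGamma,svmCost SVM settings.
#' @param smoteK,smoteRatio SMOTE settings.
#' @param cvFolds,cvIterations repeated cross-validation settings.
#' @return list of class `predictConfig`.
#' @export
predictConfig <- function(trainFraction = 0.75,
                          marsDegree = 5L, marsMaxTerms = 35L,
                          rfTrees = 100L, rfMtry = 8L,
                          svmGamma = 0.125, svmCost = 6,
                          smoteK = 20L, smoteRatio = 2L,
                          cvFolds = 4L, cvIterations = 10L) {
  stopifnot(trainFraction > 0, trainFraction < 1, marsDegree >= 1,
            marsMaxTerms >= 1, rfTrees >= 1, rfMtry >= 1, svmGamma > 0,
            svmCost > 0, smoteK >= 1, smoteRatio >= 0, cvFolds >= 2,
            cvIterations >= 1)
  structure(list(trainFraction = trainFraction, marsDegree = marsDegree,
                 marsMaxTerms = marsMaxTerms, rfTrees = rfTrees,
                 rfMtry = rfMtry, svmGamma = svmGamma, svmCost = svmCost,
                 smoteK = smoteK, smoteRatio = smoteRatio, cvFolds = cvFolds,
                 cvIterations = cvIterations),
            class = "predictConfig")
}

#' The four balanced feature groups
#'
#' Two features per group, used for the leave-one-in / leave-one-out
#' importance analysis: spikes (`ch_spikes`, `mfr`), bursts (`ch_bursts`,
#' `mbr`), synchrony (`sttc`, `sttc_dbscan`), connectivity
#' (`clustering_coeff`, `efficiency`).
#'
#' @return named list of character vectors.
#' @export
featureGroups <- function() {
  list(spikes = c("ch_spikes", "mfr"),
       bursts = c("ch_bursts", "mbr"),
       synchrony = c("sttc", "sttc_dbscan"),
       connectivity = c("clustering_coeff", "efficiency"))
}

#' Assemble the prediction dataset from dish trajectories
#'
#' Predictors are the 18 first-interval (DIV 6-8) feature means; the target
#' is the third-interval (DIV 13-18) mean of the chosen feature. Dishes
#' lacking either interval are excluded. Remaining missing predictor cells
#' are mean-imputed columnwise (the number of filled cells is reported in a
#' message); no scaling is applied here -- [fitPredict()] z-scores with
#' statistics fit on the training rows only.
#'
#' @param trajectories output of [aggregateTrajectories()].
#' @param target one of `"sttc"`, `"ch_bursts"`, `"mfr"`.
#' @param scheme the [intervalScheme()] that produced the trajectories.
#' @return list with `x` (matrix, 18 columns), `y` (numeric), `dishes`.
#' @export
assembleDataset <- function(trajectories, target = c("sttc", "ch_bursts",
                                                     "mfr"),
                            scheme = intervalScheme()) {
  target <- match.arg(target)
  featCols <- intersect(featureNames(), names(trajectories))
  early <- scheme$labels[1]
  late <- scheme$labels[length(scheme$labels)]
  dishes <- unique(trajectories$dish)
  xRows <- list(); yVals <- numeric(0); keptDishes <- character(0)
  for (d in dishes) {
    eRow <- trajectories[trajectories$dish == d &
                           trajectories$interval == early, ]
    lRow <- trajectories[trajectories$dish == d &
                           trajectories$interval == late, ]
    if (nrow(eRow) != 1 || nrow(lRow) != 1 ||
        eRow$nRecordings == 0 || lRow$nRecordings == 0 ||
        is.na(lRow[[target]])) {
      next
    }
    xRows[[d]] <- unlist(eRow[featCols])
    yVals <- c(yVals, lRow[[target]])
    keptDishes <- c(keptDishes, d)
  }
  if (length(keptDishes) < 8) stop("insufficient data: fewer than 8 dishes")
  x <- do.call(rbind, xRows)
  rownames(x) <- keptDishes
  nMissing <- sum(is.na(x))
  x <- meanImpute(x)
  if (nMissing) {
    message(sprintf("assembleDataset: mean-imputed %d missing cells",
                    nMissing))
  }
  list(x = x, y = yVals, dishes = keptDishes)
}

# z-score columns of train and test with statistics fit on train only
scaleTrainTest <- function(xTrain, xTest) {
  mu <- colMeans(xTrain)
  sdv <- apply(xTrain, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(xTrain, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(xTest, 2, mu), 2, sdv, "/"))
}

#' Fit one regression learner and evaluate on held-out rows
#'
#' Predictors are z-scored with training-set statistics. `r2` is
#' `1 - SS_res / SS_tot` on the test rows (can be negative; `NA` with a
#' warning when the test target is constant); `rmse` is in target units.
#'
#' @param model `"mars"`, `"svm"` or `"rf"`.
#' @param xTrain,yTrain training rows.
#' @param xTest,yTest held-out rows.
#' @param cfg a [predictConfig()].
#' @param seed RNG seed (random forest and MARS tie-breaks).
#' @return list with `predictions`, `r2`, `rmse`.
#' @export
fitPredict <- function(model = c("mars", "svm", "rf"), xTrain, yTrain,
                       xTest, yTest, cfg = predictConfig(), seed = 1L) {
  model <- match.arg(model)
  xTrain <- as.matrix(xTrain); xTest <- as.matrix(xTest)
  sc <- scaleTrainTest(xTrain, xTest)
  set.seed(seed)
  pred <- switch(model,
    mars = {
      fit <- marsFit(sc$train, yTrain, degree = cfg$marsDegree,
                     maxTerms = cfg$marsMaxTerms)
      predict(fit, sc$test)
    },
    svm = {
      # standardize the target as the reference implementations do, so the
      # epsilon tube (0.1) is in target-s.d. units regardless of feature
      muY <- mean(yTrain)
      sdY <- stats::sd(yTrain)
      if (!is.finite(sdY) || sdY == 0) sdY <- 1
      fit <- e1071::svm(sc$train, (yTrain - muY) / sdY,
                        type = "eps-regression", kernel = "radial",
                        gamma = cfg$svmGamma, cost = cfg$svmCost,
                        scale = FALSE)
      muY + sdY * as.numeric(stats::predict(fit, sc$test))
    },
    rf = {
      fit <- randomForest::randomForest(
        sc$train, yTrain, ntree = cfg$rfTrees,
        mtry = min(cfg$rfMtry, ncol(sc$train)))
      as.numeric(stats::predict(fit, sc$test))
    })
  ssRes <- sum((yTest - pred)^2)
  ssTot <- sum((yTest - mean(yTest))^2)
  r2 <- if (ssTot == 0) {
    warning("constant test target: R^2 undefined")
    NA_real_
  } else 1 - ssRes / ssTot
  list(predictions = pred, r2 = r2, rmse = sqrt(mean((yTest - pred)^2)))
}

#' Regression error characteristic (REC) curve
#'
#' Fraction of test points whose standardized absolute error (|error| divided
#' by the s.d. of the observed test targets) falls within a tolerance, over a
#' tolerance grid from 0 to the maximum error. Non-decreasing, reaching 1.
#'
#' @param errors absolute prediction errors (target units).
#' @param targetSd s.d. used to standardize (e.g. `sd(yTest)`).
#' @param nGrid grid size.
#' @return data.frame `tolerance`, `accuracy`.
#' @export
recCurve <- function(errors, targetSd, nGrid = 101L) {
  stopifnot(targetSd > 0, all(errors >= 0))
  z <- errors / targetSd
  grid <- seq(0, max(z), length.out = nGrid)
  data.frame(tolerance = grid,
             accuracy = vapply(grid, function(e) mean(z <= e), numeric(1)))
}

#' Train/test evaluation of the three learners
#'
#' Splits dishes 75/25 (dish-level, seeded), fits MARS, SVM and random
#' forest, and reports per-model test R^2, RMSE and REC curve.
#'
#' @param dataset output of [assembleDataset()].
#' @param cfg a [predictConfig()].
#' @param seed RNG seed for the split and the learners.
#' @param models learners to run.
#' @return list of class `predictionReport`: per-model list with `r2`,
#'   `rmse`, `rec`, plus `split` (train/test dish ids).
#' @export
evaluateModels <- function(dataset, cfg = predictConfig(), seed = 1L,
                           models = c("mars", "svm", "rf")) {
  n <- length(dataset$y)
  set.seed(seed)
  nTrain <- max(2L, round(cfg$trainFraction * n))
  idx <- sample.int(n, nTrain)
  out <- list()
  for (m in models) {
    fit <- fitPredict(m, dataset$x[idx, , drop = FALSE], dataset$y[idx],
                      dataset$x[-idx, , drop = FALSE], dataset$y[-idx],
                      cfg, seed = deriveSeed(seed, match(m, models)))
    sdTest <- stats::sd(dataset$y[-idx])
    out[[m]] <- list(
      r2 = fit$r2, rmse = fit$rmse,
      rec = recCurve(abs(dataset$y[-idx] - fit$predictions), sdTest))
  }
  out$split <- list(train = dataset$dishes[idx],
                    test = dataset$dishes[-idx])
  class(out) <- "predictionReport"
  out
}

# One repeated-CV run of the SVM on a column subset; SMOTE is applied to the
# training folds only, never to the evaluation fold. The returned vector
# carries an `evalSizes` attribute with the number of (original) rows each
# out-of-fold R^2 was computed on.
cvSvm <- function(x, y, cols, cfg, seed) {
  n <- length(y)
  r2s <- numeric(0)
  evalSizes <- integer(0)
  for (iter in seq_len(cfg$cvIterations)) {
    set.seed(deriveSeed(seed, iter))
    folds <- sample(rep(seq_len(cfg$cvFolds), length.out = n))
    for (f in seq_len(cfg$cvFolds)) {
      tr <- folds != f
      rowsTr <- cbind(x[tr, cols, drop = FALSE], .y = y[tr])
      aug <- smoteAugment(rowsTr, kNeighbors = cfg$smoteK,
                          ratio = cfg$smoteRatio,
                          seed = deriveSeed(seed, iter, f))
      fit <- fitPredict("svm",
                        aug[, seq_along(cols), drop = FALSE],
                        aug[, ".y"],
                        x[!tr, cols, drop = FALSE], y[!tr],
                        cfg, seed = deriveSeed(seed, iter, f, 1L))
      r2s <- c(r2s, fit$r2)
      evalSizes <- c(evalSizes, sum(!tr))
    }
  }
  attr(r2s, "evalSizes") <- evalSizes
  r2s
}

#' Feature-group importance by leave-one-in / leave-one-out
#'
#' Evaluates the SVM under SMOTE-augmented fourfold cross-validation repeated
#' 10 times (40 out-of-fold evaluations per strategy): a baseline with all 18
#' features, a baseline with the 8 balanced group features, leave-one-in
#' (only one group's 2 features) and leave-one-out (the 8 group features
#' minus one group) for each of the four groups. SMOTE augments training
#' folds only.
#'
#' @param dataset output of [assembleDataset()].
#' @param cfg a [predictConfig()].
#' @param seed RNG seed.
#' @param groups the [featureGroups()].
#' @return data.frame `strategy`, `group`, `meanR2`, `sem`, `nEvaluations`.
#' @export
groupImportance <- function(dataset, cfg = predictConfig(), seed = 1L,
                            groups = featureGroups()) {
  x <- dataset$x
  y <- dataset$y
  all8 <- unlist(groups, use.names = FALSE)
  strategies <- list(list(strategy = "baseline", group = "all18",
                          cols = colnames(x)),
                     list(strategy = "baseline", group = "group8",
                          cols = all8))
  for (g in names(groups)) {
    strategies[[length(strategies) + 1L]] <-
      list(strategy = "leave-one-in", group = g, cols = groups[[g]])
    strategies[[length(strategies) + 1L]] <-
      list(strategy = "leave-one-out", group = g,
           cols = setdiff(all8, groups[[g]]))
  }
  # same seed for every strategy: identical fold assignments, so strategies
  # differ only in the columns they see
  rows <- lapply(strategies, function(s) {
    r2s <- cvSvm(x, y, s$cols, cfg, seed = seed)
    r2s <- r2s[!is.na(r2s)]
    data.frame(strategy = s$strategy, group = s$group,
               meanR2 = mean(r2s),
               sem = stats::sd(r2s) / sqrt(length(r2s)),
               nEvaluations = length(r2s), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
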