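test_that("all three learners recover a noiseless linear signal", {
  set.seed(127)
  n <- 200
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- 3 * x[, 2] + 1
  idx <- sample(n, 150)
  for (model in c("mars", "rf")) {
    fit <- fitPredict(model, x[idx, ], y[idx], x[-idx, ], y[-idx], seed = 3)
    expect_gte(fit$r2, 0.99)
  }
  # the epsilon-insensitive tube of the fixed-hyperparameter RBF SVM caps
  # its accuracy on exactly-linear targets slightly below the tree/spline
  # learners
  fit <- fitPredict("svm", x[idx, ], y[idx], x[-idx, ], y[-idx], seed = 3)
  expect_gte(fit$r2, 0.97)
})

test_that("R^2 and RMSE follow their definitions", {
  yTest <- c(1, 2, 3, 4)
  # predicting the training mean cannot beat the test mean
  predMean <- rep(10, 4)
  ssRes <- sum((yTest - predMean)^2)
  ssTot <- sum((yTest - mean(yTest))^2)
  expect_lte(1 - ssRes / ssTot, 0)

  set.seed(131)
  x <- matrix(rnorm(120), 60, 2)
  y <- x[, 1]
  fit <- fitPredict("mars", x[1:40, ], y[1:40], x[41:60, ], y[41:60])
  expect_equal(fit$rmse, sqrt(mean((y[41:60] - fit$predictions)^2)))
  # a perfect linear fit has RMSE ~ 0
  expect_lt(fit$rmse, 1e-6)

  expect_warning(
    fitPredict("rf", x[1:40, ], y[1:40], x[41:60, ], rep(1, 20)),
    "constant")
})

test_that("MARS prunes to a parsimonious exact model on hinge data", {
  set.seed(137)
  x <- matrix(runif(300, -2, 2), 150, 2)
  y <- 2 * pmax(0, x[, 1] - 0.5) - 1 * pmax(0, 0.3 - x[, 2])
  fit <- marsFit(x, y, degree = 2, maxTerms = 20)
  expect_lt(mean((predict(fit, x) - y)^2), 1e-3)
  expect_lte(length(fit$terms), 10)
})

test_that("the REC curve is a non-decreasing step function reaching one", {
  expect_equal(recCurve(rep(0, 5), targetSd = 1)$accuracy, rep(1, 101))
  cv <- recCurve(c(0.5, 1.5), targetSd = 1)
  expect_equal(cv$accuracy[1], 0)
  expect_equal(tail(cv$accuracy, 1), 1)
  expect_true(all(diff(cv$accuracy) >= 0))
  # tolerance 1 captures exactly the 0.5 error
  expect_equal(cv$accuracy[which.min(abs(cv$tolerance - 1))], 0.5)
})

test_that("SMOTE output size, betweenness and determinism hold", {
  set.seed(139)
  rows <- matrix(rnorm(30 * 4), 30, 4)
  aug <- smoteAugment(rows, kNeighbors = 20, ratio = 2, seed = 5)
  expect_equal(nrow(aug), 90)
  parents <- attr(aug, "parents")
  for (k in seq_len(60)) {
    a <- rows[parents[k, 1], ]
    b <- rows[parents[k, 2], ]
    s <- aug[30 + k, ]
    expect_true(all(s >= pmin(a, b) - 1e-12 & s <= pmax(a, b) + 1e-12))
  }
  aug2 <- smoteAugment(rows, kNeighbors = 20, ratio = 2, seed = 5)
  expect_identical(aug, aug2)

  expect_warning(smoteAugment(rows[1:10, ], kNeighbors = 20, ratio = 1),
                 "reduced")
})

test_that("dataset assembly excludes incomplete dishes and imputes cells", {
  traj <- expand.grid(dish = sprintf("d%02d", 1:10),
                      interval = c("div6_8", "div9_12", "div13_18"),
                      stringsAsFactors = FALSE)
  traj$nRecordings <- 1L
  set.seed(149)
  for (f in featureNames()) traj[[f]] <- runif(nrow(traj))
  # dish d01 lacks the late interval; d02 has one missing predictor cell
  traj$nRecordings[traj$dish == "d01" & traj$interval == "div13_18"] <- 0L
  traj$mbr[traj$dish == "d02" & traj$interval == "div6_8"] <- NA

  suppressMessages(ds <- assembleDataset(traj, target = "sttc"))
  expect_equal(nrow(ds$x), 9)
  expect_false("d01" %in% ds$dishes)
  expect_false(anyNA(ds$x))
  # complete columns untouched
  keep <- setdiff(featureNames(), "mbr")
  orig <- traj[traj$interval == "div6_8" & traj$dish %in% ds$dishes, keep]
  expect_equal(unname(as.matrix(orig)), unname(ds$x[, keep]),
               ignore_attr = TRUE)

  expect_error(assembleDataset(traj[traj$dish %in% sprintf("d%02d", 1:5), ],
                               target = "sttc"),
               "insufficient")
})

test_that("out-of-fold evaluations use original rows only", {
  set.seed(151)
  n <- 40
  x <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(NULL, unlist(featureGroups())))
  y <- x[, 1] + rnorm(n, sd = 0.1)
  cfg <- predictConfig(cvFolds = 4, cvIterations = 2)
  r2s <- meadev:::cvSvm(x, y, colnames(x), cfg, seed = 3)
  sizes <- attr(r2s, "evalSizes")
  expect_length(r2s, 8)
  # every fold evaluates exactly its share of the 40 original rows
  expect_equal(sum(sizes[1:4]), n)
  expect_true(all(sizes == 10))
})

test_that("group importance finds a signal planted in one group", {
  set.seed(157)
  n <- 150
  x <- matrix(rnorm(n * 18), n, 18, dimnames = list(NULL, featureNames()))
  y <- 2 * x[, "sttc"] + 1.5 * x[, "sttc_dbscan"] + rnorm(n, sd = 0.2)
  ds <- list(x = x, y = y, dishes = sprintf("d%d", 1:n))
  cfg <- predictConfig(cvIterations = 3)  # 12 evaluations per strategy
  imp <- groupImportance(ds, cfg, seed = 11)
  li <- imp[imp$strategy == "leave-one-in", ]
  expect_equal(li$group[which.max(li$meanR2)], "synchrony")
  # removing the signal group is catastrophic ...
  looSync <- imp[imp$strategy == "leave-one-out" &
                   imp$group == "synchrony", "meanR2"]
  base8 <- imp[imp$strategy == "baseline" & imp$group == "group8", "meanR2"]
  expect_lt(looSync, 0.2)
  # ... while the irrelevant groups are interchangeable: dropping any of
  # them gives near-identical accuracy, never much below the baseline
  looIrr <- imp$meanR2[imp$strategy == "leave-one-out" &
                         imp$group != "synchrony"]
  expect_lt(max(looIrr) - min(looIrr), 0.05)
  expect_gt(min(looIrr), base8 - 0.05)
})

test_that("train/test evaluation reports consistent structures", {
  set.seed(163)
  n <- 40
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- x[, 1] - 0.5 * x[, 3] + rnorm(n, sd = 0.1)
  ds <- list(x = x, y = y, dishes = sprintf("d%d", 1:n))
  rep1 <- evaluateModels(ds, seed = 4, models = c("svm", "rf"))
  expect_named(rep1, c("svm", "rf", "split"))
  expect_length(rep1$split$test, 10)
  expect_gt(rep1$svm$r2, 0.5)
  expect_true(all(diff(rep1$svm$rec$accuracy) >= 0))
})
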