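test_that("the 7:3 split yields 280/120 on 400 seeds, reproducibly", {
  sim <- simulateSpectra(simConfig(nPerGroup = 80L, rngSeed = 1L))
  sp <- splitDataset(sim$dataset, ratio = 0.7, seed = 5L)
  expect_equal(ncol(sp$calibration), 280L)
  expect_equal(ncol(sp$prediction), 120L)
  expect_equal(sort(c(sp$calIdx, sp$preIdx)), 1:400)
  sp2 <- splitDataset(sim$dataset, ratio = 0.7, seed = 5L)
  expect_identical(sp$calIdx, sp2$calIdx)
})

test_that("stratified splitting keeps class proportions within one seed", {
  set.seed(2)
  n <- 100L
  viable <- rep(c(TRUE, FALSE), times = c(60L, 40L))
  ds <- spectralSet(matrix(rnorm(n * 6), n, 6), seq(400, 900, 100),
                    seedId = sprintf("s%03d", 1:n),
                    group = rep("A0", n), viable = viable)
  sp <- splitDataset(ds, ratio = 0.7, seed = 3L, stratifyBy = "viable")
  calV <- sum(viability(sp$calibration))
  expect_lte(abs(calV - 0.7 * 60), 1)
  expect_lte(abs((ncol(sp$calibration) - calV) - 0.7 * 40), 1)
  expect_equal(ncol(sp$calibration), 70L)
})

test_that("all four classifiers separate a linearly separable toy set", {
  set.seed(3)
  n <- 60L
  y <- factor(rep(c("lo", "hi"), each = n / 2))
  X <- cbind(rnorm(n, ifelse(y == "hi", 3, -3), 0.3),
             rnorm(n, ifelse(y == "hi", -2, 2), 0.3))
  for (alg in c("xgboost", "lightgbm", "svmRBF", "randomForest")) {
    fit <- trainClassifier(X, y, algorithm = alg, seed = 1L)
    rep <- evaluateClassifier(fit, X, y, set = "calibration")
    expect_equal(rep@calibration$accuracy, 100,
                 label = paste(alg, "calibration accuracy"))
  }
  expect_error(trainClassifier(X, factor(rep("lo", n))), "single class")
})

test_that("shuffled labels give only majority-rate accuracy", {
  sim <- simulateSpectra(coarseConfig(nPerGroup = 40L, rngSeed = 4L))
  ds <- sim$dataset
  set.seed(5)
  shuffled <- sample(viability(ds))
  SummarizedExperiment::colData(ds)$viable <- shuffled
  sp <- splitDataset(ds, seed = 1L)
  fit <- trainClassifier(spectraMatrix(sp$calibration),
                         factor(viability(sp$calibration)),
                         algorithm = "xgboost", seed = 1L)
  rep <- evaluateClassifier(fit, spectraMatrix(sp$prediction),
                            factor(viability(sp$prediction)))
  m <- max(mean(shuffled), 1 - mean(shuffled))
  n <- rep@prediction$n
  expect_lte(rep@prediction$accuracy / 100,
             m + 4 * sqrt(m * (1 - m) / n))
})

test_that("classification accuracy reports exact counts at 2 decimals", {
  expect_equal(classificationAccuracy(255, 280), 91.07)
  expect_equal(classificationAccuracy(280, 280), 100)
  expect_equal(classificationAccuracy(0, 280), 0)
  set.seed(6)
  y <- factor(rep(c("a", "b"), each = 10))
  X <- cbind(c(rnorm(10, -2), rnorm(10, 2)), rnorm(20))
  fit <- trainClassifier(X, y, algorithm = "randomForest", seed = 1L)
  rep <- evaluateClassifier(fit, X, y, set = "calibration")
  cm <- rep@calibration$confusion
  expect_equal(sum(cm), 20)
  expect_equal(rep@calibration$accuracy,
               classificationAccuracy(sum(diag(cm)), sum(cm)))
})

test_that("PLSR reproduces simple and multiple least squares", {
  set.seed(7)
  # univariate, one component = simple regression
  x <- matrix(rnorm(30), 30, 1)
  y <- 2 + 3 * x[, 1] + rnorm(30, 0, 0.2)
  p1 <- plsrFit(x, y, 1L)
  ls <- stats::lm.fit(cbind(1, x), y)
  expect_equal(predict(p1, x), drop(cbind(1, x) %*% ls$coefficients),
               tolerance = 1e-10)
  # full rank = OLS
  X <- matrix(rnorm(40 * 5), 40, 5)
  y2 <- drop(X %*% c(1, -2, 0.5, 0, 3)) + rnorm(40, 0, 0.1)
  pf <- plsrFit(X, y2, 5L)
  ols <- stats::lm.fit(cbind(1, X), y2)
  expect_equal(predict(pf, X), drop(cbind(1, X) %*% ols$coefficients),
               tolerance = 1e-8)
  # constant response collapses to the mean
  pc <- plsrFit(X, rep(4.2, 40), 3L)
  expect_equal(predict(pc, X), rep(4.2, 40), tolerance = 1e-10)
  expect_error(plsrFit(X, y2, 0L), "ncomp")
  expect_error(plsrFit(matrix(1, 10, 3), rnorm(10), 2L), "variance")
})

test_that("PLSR training residuals shrink as components are added", {
  set.seed(8)
  X <- matrix(rnorm(50 * 8), 50, 8)
  y <- drop(X %*% rnorm(8)) + rnorm(50, 0, 0.3)
  rss <- vapply(1:6, function(a)
    sum((y - predict(plsrFit(X, y, a), X))^2), numeric(1))
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("PLSR agrees with an independent latent-variable implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(9)
  X <- matrix(rnorm(40 * 10), 40, 10,
              dimnames = list(NULL, paste0("b", 1:10)))
  y <- drop(X %*% rnorm(10)) + rnorm(40, 0, 0.2)
  mine <- plsrFit(X, y, 3L)
  theirs <- mixOmics::pls(X, y, ncomp = 3, mode = "regression",
                          scale = FALSE)
  pred <- predict(theirs, X)$predict[, 1, 3]
  expect_equal(unname(predict(mine, X)), unname(pred), tolerance = 1e-6)
})

test_that("regression metrics match hand-computed values", {
  y <- c(1, 2, 3, 4, 5)
  yh <- c(1.1, 1.9, 3.2, 3.9, 5.3)
  ssres <- sum((y - yh)^2)                 # 0.01+0.01+0.04+0.01+0.09 = 0.16
  sstot <- sum((y - 3)^2)                  # 10
  expect_equal(regressionR2(y, yh), 1 - ssres / sstot)
  expect_equal(regressionR2(y, yh), 0.984)
  expect_equal(rmse(y, yh), sqrt(0.16 / 5))
  expect_equal(regressionR2(y, y), 1)
  expect_equal(rmse(y, y), 0)
  expect_equal(regressionR2(y, rep(mean(y), 5)), 0)
})

test_that("the results grid covers the full design and is deterministic", {
  sim <- simulateSpectra(coarseConfig(nPerGroup = 12L, rngSeed = 10L))
  ds <- sim$dataset
  g1 <- runClassificationGrid(ds, preprocess = c("raw", "MSC"),
                              selectors = c("full", "catboost"),
                              models = c("xgboost", "svmRBF"),
                              k = 10L, seed = 2L)
  expect_equal(nrow(g1$table), 2L * 2L * 2L)
  expect_equal(length(g1$reports), 8L)
  g2 <- runClassificationGrid(ds, preprocess = c("raw", "MSC"),
                              selectors = c("full", "catboost"),
                              models = c("xgboost", "svmRBF"),
                              k = 10L, seed = 2L)
  expect_identical(g1$table, g2$table)
  # the flagged best cell attains the maximum prediction accuracy
  expect_equal(g1$best$pre_accuracy, max(g1$table$pre_accuracy))
  # calibration and prediction sets never overlap
  expect_length(intersect(g1$split$calIdx, g1$split$preIdx), 0L)
})

test_that("the regression grid reports R2 and RMSE per cell", {
  sim <- simulateSpectra(coarseConfig(nPerGroup = 12L, rngSeed = 11L))
  gr <- runRegressionGrid(sim$dataset, preprocess = "MSC",
                          selectors = c("full", "gbdt"),
                          models = c("plsr", "xgboost"), k = 10L, seed = 2L)
  expect_equal(nrow(gr$table), 4L)
  expect_true(all(gr$table$cal_RMSE >= 0))
  expect_true(all(gr$table$cal_R2 <= 1))
  expect_equal(gr$best$pre_R2, max(gr$table$pre_R2))
})
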