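#' Split a dataset into calibration and prediction sets
#'
#' Deterministic 7:3 (by default) split. With stratification, calibration
#' quotas per stratum are allocated by largest remainder so the overall
#' calibration size is exactly `round(ratio * n)` and every stratum is
#' within one seed of its proportional share.
#'
#' @param x a [SpectralSet] or anything with length/rows to index.
#' @param ratio calibration fraction, 0 < ratio < 1 (default 0.7).
#' @param seed RNG seed making the split reproducible.
#' @param stratifyBy for a SpectralSet: `"viable"`, `"group"` or NULL
#'   (unstratified).
#' @return list with elements `calibration` and `prediction`
#'   ([SpectralSet]s), plus integer index vectors `calIdx`, `preIdx`.
#' @examples
#' sim <- simulateSpectra(simConfig(nPerGroup = 10, rngSeed = 1))
#' sp <- splitDataset(sim$dataset, seed = 1)
#' ncol(sp$calibration)  # 35 of 50
#' @export
splitDataset <- function(x, ratio = 0.7, seed = 1L, stratifyBy = "viable") {
  stopifnot(ratio > 0, ratio < 1)
  n <- ncol(x)
  ncal <- round(ratio * n)
  strata <- if (is.null(stratifyBy)) factor(rep(1L, n))
            else factor(colData(x)[[stratifyBy]])
  set.seed(seed)
  quota <- ratio * table(strata)
  take <- floor(quota)
  rem <- ncal - sum(take)
  if (rem > 0) {
    extra <- order(quota - take, decreasing = TRUE)[seq_len(rem)]
    take[extra] <- take[extra] + 1L
  }
  calIdx <- integer(0)
  for (s in levels(strata)) {
    idx <- which(strata == s)
    calIdx <- c(calIdx, sample(idx, take[[s]]))
  }
  calIdx <- sort(calIdx)
  preIdx <- setdiff(seq_len(n), calIdx)
  list(calibration = x[, calIdx], prediction = x[, preIdx],
       calIdx = calIdx, preIdx = preIdx)
}

#' Train a seed-viability classifier
#'
#' Four algorithm families: `"xgboost"` (depthwise gradient boosting),
#' `"lightgbm"` (histogram, leaf-wise gradient boosting), `"svmRBF"`
#' (support vector machine with radial basis kernel) and
#' `"randomForest"`. All fits are deterministic given `seed` (tree
#' methods are single-threaded).
#'
#' @param x calibration spectra, samples x bands matrix.
#' @param y factor of class labels (>= 2 classes).
#' @param algorithm one of the four families above.
#' @param seed RNG seed.
#' @param params named list overriding algorithm defaults: boosting
#'   `nrounds`/`maxDepth`/`eta`; SVM `cost`/`gamma` (default gamma
#'   1/(bands * overall variance)); forest `ntree`.
#' @return a [VigorClassifier].
#' @export
trainClassifier <- function(x, y,
                            algorithm = c("xgboost", "lightgbm", "svmRBF",
                                          "randomForest"),
                            seed = 1L, params = list()) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(x)
  y <- droplevels(factor(y))
  if (nlevels(y) < 2L) stop("calibration set has a single class")
  set.seed(seed)
  fit <- switch(algorithm,
    xgboost = ,
    lightgbm = {
      p <- modifyList(list(nrounds = 200L, maxDepth = 6L, eta = 0.1), params)
      nl <- nlevels(y)
      xp <- list(objective = if (nl == 2L) "binary:logistic"
                             else "multi:softprob",
                 eta = p$eta, nthread = 1L, seed = as.integer(seed))
      if (nl > 2L) xp$num_class <- nl
      if (algorithm == "xgboost") {
        xp$max_depth <- p$maxDepth
      } else {
        xp$tree_method <- "hist"
        xp$grow_policy <- "lossguide"
        xp$max_depth <- 0L
        xp$max_leaves <- 31L
      }
      xm <- x; colnames(xm) <- paste0("f", seq_len(ncol(xm)))
      xgboost::xgb.train(params = xp,
                         data = xgboost::xgb.DMatrix(xm,
                                                     label = as.integer(y) - 1L),
                         nrounds = p$nrounds, verbose = 0)
    },
    svmRBF = {
      p <- modifyList(list(cost = 1,
                           gamma = 1 / (ncol(x) * stats::var(as.vector(x)))),
                      params)
      e1071::svm(x, y, kernel = "radial", cost = p$cost, gamma = p$gamma,
                 scale = FALSE)
    },
    randomForest = {
      p <- modifyList(list(ntree = 500L), params)
      randomForest::randomForest(x, y, ntree = p$ntree)
    })
  new("VigorClassifier", algorithm = algorithm, fit = fit,
      levels = levels(y), nBands = ncol(x))
}

#' Predict class labels from a fitted classifier
#'
#' @param model a [VigorClassifier].
#' @param x samples x bands matrix with the training band layout.
#' @return factor of predicted labels.
#' @export
predictClassifier <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model@nBands)
    stop("band count mismatch: model expects ", model@nBands)
  if (model@algorithm %in% c("xgboost", "lightgbm")) {
    xm <- x; colnames(xm) <- paste0("f", seq_len(ncol(xm)))
    pr <- predict(model@fit, xgboost::xgb.DMatrix(xm))
    nl <- length(model@levels)
    lab <- if (nl == 2L) ifelse(pr > 0.5, 2L, 1L)
           else max.col(matrix(pr, ncol = nl, byrow = TRUE))
    factor(model@levels[lab], levels = model@levels)
  } else {
    factor(as.character(predict(model@fit, x)), levels = model@levels)
  }
}

#' Evaluate a classifier on a labelled set
#'
#' @param model a [VigorClassifier].
#' @param x samples x bands matrix.
#' @param y true labels.
#' @param set which side of the split this is, for the report.
#' @return a [ModelReport] with `accuracy` (percent, 0-100), the
#'   `confusion` matrix (rows = true, cols = predicted) and the exact
#'   `correct` count in the corresponding slot.
#' @export
evaluateClassifier <- function(model, x, y,
                               set = c("prediction", "calibration")) {
  set <- match.arg(set)
  y <- factor(y, levels = model@levels)
  pred <- predictClassifier(model, x)
  cm <- table(true = y, predicted = pred)
  metrics <- list(accuracy = classificationAccuracy(sum(diag(cm)), length(y)),
                  correct = sum(diag(cm)), n = length(y),
                  confusion = unclass(cm))
  rep <- new("ModelReport", preprocess = "", selector = "",
             model = model@algorithm, task = "classification",
             calibration = list(), prediction = list())
  slot(rep, set) <- metrics
  rep
}

#' Classification accuracy on the 0-100 scale
#'
#' @param correct correctly classified count.
#' @param total set size.
#' @param digits decimals in the reported value (default 2, the
#'   conventional reporting precision).
#' @return accuracy percentage rounded to `digits`.
#' @examples
#' classificationAccuracy(255, 280)  # 91.07
#' @export
classificationAccuracy <- function(correct, total, digits = 2) {
  round(100 * correct / total, digits)
}

#' Fit partial least squares regression (NIPALS, single response)
#'
#' Mean-centres X and y and extracts `ncomp` latent components by the
#' NIPALS algorithm; the regression coefficient vector is
#' W (P'W)^-1 q. With `ncomp` equal to the rank of centred X the fit
#' reproduces ordinary least squares.
#'
#' @param X samples x bands predictor matrix (non-constant).
#' @param y numeric response.
#' @param ncomp number of latent components,
#'   1 <= ncomp <= min(n - 1, bands).
#' @return a [PLSRModel].
#' @export
plsrFit <- function(X, y, ncomp) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > min(n - 1L, p))
    stop("ncomp must be in [1, min(n - 1, bands)]")
  if (all(apply(X, 2, stats::sd) == 0)) stop("X has zero variance")
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tt <- matrix(0, n, ncomp); q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) { # residual X carries no covariance with y; stop early
      ncomp <- a - 1L
      W <- W[, seq_len(ncomp), drop = FALSE]
      P <- P[, seq_len(ncomp), drop = FALSE]
      Tt <- Tt[, seq_len(ncomp), drop = FALSE]
      q <- q[seq_len(ncomp)]
      break
    }
    w <- w / nw
    tt <- drop(Xc %*% w)
    tt2 <- sum(tt^2)
    pp <- drop(crossprod(Xc, tt)) / tt2
    qq <- sum(yc * tt) / tt2
    Xc <- Xc - tcrossprod(tt, pp)
    yc <- yc - qq * tt
    W[, a] <- w; P[, a] <- pp; Tt[, a] <- tt; q[a] <- qq
  }
  if (ncomp == 0L) {
    coef <- numeric(p)
  } else {
    coef <- drop(W %*% solve(crossprod(P, W), q))
  }
  new("PLSRModel", ncomp = ncomp, weights = W, loadings = P, scores = Tt,
      yloadings = q, coef = coef, xMeans = xm, yMean = ym)
}

#' @describeIn plsrFit predict responses for new spectra.
#' @param object a [PLSRModel].
#' @param newdata samples x bands matrix.
#' @param ... ignored.
#' @export
setMethod("predict", "PLSRModel", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(sweep(newdata, 2, object@xMeans) %*% object@coef) + object@yMean
})

setMethod("show", "PLSRModel", function(object) {
  cat("PLSRModel:", object@ncomp, "latent components over",
      length(object@coef), "bands\n")
})

#' Choose the PLSR component count by cross-validation
#'
#' 5-fold cross-validated RMSE on the calibration set, component counts
#' 1..`maxComp` (default capped at 15, the selected-band count).
#'
#' @param X,y calibration predictors and response.
#' @param maxComp largest component count tried.
#' @param folds number of CV folds.
#' @param seed RNG seed for the fold assignment.
#' @return the component count minimising CV RMSE.
#' @export
selectPlsrNcomp <- function(X, y, maxComp = 15L, folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  maxComp <- min(maxComp, ncol(X), n - ceiling(n / folds) - 1L)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  rmse <- numeric(maxComp)
  for (a in seq_len(maxComp)) {
    sse <- 0
    for (f in seq_len(folds)) {
      hold <- fold == f
      fit <- plsrFit(X[!hold, , drop = FALSE], y[!hold], a)
      sse <- sse + sum((y[hold] - predict(fit, X[hold, , drop = FALSE]))^2)
    }
    rmse[a] <- sqrt(sse / n)
  }
  which.min(rmse)
}

#' Train an SOD regression model
#'
#' @param x calibration spectra, samples x bands.
#' @param y numeric response (SOD activity).
#' @param algorithm `"plsr"` (NIPALS, CV-chosen components) or
#'   `"xgboost"`.
#' @param seed RNG seed.
#' @param params overrides: PLSR `ncomp` (NULL = choose by CV),
#'   `maxComp`; xgboost `nrounds`/`maxDepth`/`eta`.
#' @return a fitted model ([PLSRModel] or xgboost booster wrapped with
#'   prediction metadata).
#' @export
trainRegressor <- function(x, y, algorithm = c("plsr", "xgboost"),
                           seed = 1L, params = list()) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(x)
  if (algorithm == "plsr") {
    p <- modifyList(list(ncomp = NULL, maxComp = 15L), params)
    ncomp <- if (is.null(p$ncomp))
      selectPlsrNcomp(x, y, maxComp = p$maxComp, seed = seed) else p$ncomp
    plsrFit(x, y, ncomp)
  } else {
    p <- modifyList(list(nrounds = 200L, maxDepth = 6L, eta = 0.1), params)
    xm <- x; colnames(xm) <- paste0("f", seq_len(ncol(xm)))
    set.seed(seed)
    fit <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror", eta = p$eta,
                    max_depth = p$maxDepth, nthread = 1L,
                    seed = as.integer(seed)),
      data = xgboost::xgb.DMatrix(xm, label = as.numeric(y)),
      nrounds = p$nrounds, verbose = 0)
    structure(list(fit = fit, nBands = ncol(x)), class = "xgbRegressor")
  }
}

#' @exportS3Method stats::predict
predict.xgbRegressor <- function(object, newdata, ...) {
  xm <- as.matrix(newdata)
  colnames(xm) <- paste0("f", seq_len(ncol(xm)))
  predict(object$fit, xgboost::xgb.DMatrix(xm))
}

#' Evaluate a regression model on a labelled set
#'
#' R2 = 1 - SSres/SStot and RMSE = sqrt(mean squared error).
#'
#' @param model a fitted regressor with a `predict` method.
#' @param x samples x bands matrix.
#' @param y true responses.
#' @param set which side of the split, for the report.
#' @return a [ModelReport] carrying `R2`, `RMSE` and `n`.
#' @export
evaluateRegression <- function(model, x, y,
                               set = c("prediction", "calibration")) {
  set <- match.arg(set)
  pred <- predict(model, as.matrix(x))
  metrics <- list(R2 = regressionR2(y, pred), RMSE = rmse(y, pred),
                  n = length(y))
  rep <- new("ModelReport", preprocess = "", selector = "",
             model = class(model)[1], task = "regression",
             calibration = list(), prediction = list())
  slot(rep, set) <- metrics
  rep
}

#' @rdname evaluateRegression
#' @param observed,predicted numeric vectors.
#' @export
regressionR2 <- function(observed, predicted) {
  1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
}

#' @rdname evaluateRegression
#' @export
rmse <- function(observed, predicted) {
  sqrt(mean((observed - predicted)^2))
}

setMethod("show", "ModelReport", function(object) {
  cell <- paste(Filter(nzchar, c(object@preprocess, object@selector,
                                 object@model)), collapse = "-")
  cat("ModelReport [", object@task, "] ", cell, "\n", sep = "")
  for (side in c("calibration", "prediction")) {
    m <- slot(object, side)
    if (!length(m)) next
    if (object@task == "classification")
      cat(sprintf("  %s: accuracy %.2f%% (%d/%d)\n", side, m$accuracy,
                  m$correct, m$n))
    else
      cat(sprintf("  %s: R2 %.4f, RMSE %.4f (n=%d)\n", side, m$R2, m$RMSE,
                  m$n))
  }
})

# Preprocess calibration and prediction matrices consistently: the MSC
# reference and every fitted quantity come from calibration only.
.prep_pair <- function(calX, preX, method, ...) {
  if (method == "MSC") {
    calP <- mscCorrect(calX)
    ref <- attr(calP, "reference")
    preP <- mscCorrect(preX, reference = ref)
    list(cal = calP, pre = preP)
  } else {
    list(cal = preprocessSpectra(calX, method, ...),
         pre = preprocessSpectra(preX, method, ...))
  }
}

.grid_core <- function(dataset, target, preprocess, selectors, models,
                       k, ratio, seed, trainFun, evalFun, metricName,
                       maximise) {
  sp <- splitDataset(dataset, ratio = ratio, seed = seed,
                     stratifyBy = if (target == "viability") "viable" else
                       "group")
  calX0 <- spectraMatrix(sp$calibration)
  preX0 <- spectraMatrix(sp$prediction)
  wl <- wavelengths(dataset)
  ycal <- if (target == "viability")
    factor(ifelse(viability(sp$calibration), "viable", "nonviable"))
  else sodValues(sp$calibration)
  ypre <- if (target == "viability")
    factor(ifelse(viability(sp$prediction), "viable", "nonviable"))
  else sodValues(sp$prediction)
  rows <- list(); reports <- list()
  for (pp in preprocess) {
    pair <- .prep_pair(calX0, preX0, pp)
    for (sel in selectors) {
      if (sel == "full") {
        calX <- pair$cal; preX <- pair$pre
      } else {
        rk <- rankBands(pair$cal, y = ycal, wl = wl, method = sel, k = k,
                       seed = seed)
        idx <- match(rk@wavelengths, wl)
        calX <- pair$cal[, idx, drop = FALSE]
        preX <- pair$pre[, idx, drop = FALSE]
      }
      for (mod in models) {
        fit <- trainFun(calX, ycal, mod, seed)
        repCal <- evalFun(fit, calX, ycal, "calibration")
        repPre <- evalFun(fit, preX, ypre, "prediction")
        rep <- new("ModelReport", preprocess = pp, selector = sel,
                   model = mod, task = repCal@task,
                   calibration = repCal@calibration,
                   prediction = repPre@prediction)
        reports[[length(reports) + 1L]] <- rep
        row <- data.frame(preprocess = pp, selector = sel, model = mod,
                          stringsAsFactors = FALSE)
        for (nm in metricName) {
          row[[paste0("cal_", nm)]] <- rep@calibration[[nm]]
          row[[paste0("pre_", nm)]] <- rep@prediction[[nm]]
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  tab <- do.call(rbind, rows)
  crit <- tab[[paste0("pre_", metricName[1])]]
  best <- if (maximise) which.max(crit) else which.min(crit)
  list(table = tab, reports = reports, best = tab[best, ], split = sp)
}

#' Run the full classification results grid
#'
#' Crosses preprocessing methods, band selectors (`"full"` plus the two
#' boosted-tree rankers) and classifier families, reporting calibration
#' and prediction accuracy for every cell. All fitting — the MSC
#' reference, the band ranking, the classifier — uses the calibration
#' set only.
#'
#' @param dataset a [SpectralSet] with viability labels.
#' @param preprocess subset of c("raw", "SG", "MSC", "MF").
#' @param selectors subset of c("full", "catboost", "gbdt").
#' @param models subset of c("xgboost", "lightgbm", "svmRBF",
#'   "randomForest").
#' @param k bands kept by each selector.
#' @param ratio calibration fraction.
#' @param seed RNG seed for split, ranking and model fits.
#' @return list: `table` (one row per cell with cal/pre accuracy),
#'   `reports` (list of [ModelReport]), `best` (row with the highest
#'   prediction accuracy), `split`.
#' @export
runClassificationGrid <- function(dataset,
                                  preprocess = c("raw", "SG", "MSC", "MF"),
                                  selectors = c("full", "catboost", "gbdt"),
                                  models = c("xgboost", "lightgbm", "svmRBF",
                                             "randomForest"),
                                  k = 15L, ratio = 0.7, seed = 1L) {
  .grid_core(dataset, "viability", preprocess, selectors, models, k, ratio,
             seed,
             trainFun = function(x, y, mod, s)
               trainClassifier(x, y, algorithm = mod, seed = s),
             evalFun = evaluateClassifier,
             metricName = c("accuracy"), maximise = TRUE)
}

#' Run the full SOD regression results grid
#'
#' As [runClassificationGrid] but with a numeric SOD target, regressor
#' families `"plsr"` and `"xgboost"`, and R2/RMSE metrics; the best cell
#' is the one with the highest prediction R2.
#'
#' @inheritParams runClassificationGrid
#' @param models subset of c("plsr", "xgboost").
#' @return list as in [runClassificationGrid] with cal/pre R2 and RMSE
#'   columns.
#' @export
runRegressionGrid <- function(dataset,
                              preprocess = c("raw", "SG", "MSC", "MF"),
                              selectors = c("full", "catboost", "gbdt"),
                              models = c("plsr", "xgboost"),
                              k = 15L, ratio = 0.7, seed = 1L) {
  .grid_core(dataset, "sod", preprocess, selectors, models, k, ratio, seed,
             trainFun = function(x, y, mod, s)
               trainRegressor(x, y, algorithm = mod, seed = s),
             evalFun = evaluateRegression,
             metricName = c("R2", "RMSE"), maximise = TRUE)
}
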