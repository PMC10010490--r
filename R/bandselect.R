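# Fit one gradient-boosted ensemble and return per-feature gain importance.
# flavour "catboost": depthwise trees (symmetric-leaning, CatBoost-like);
# flavour "gbdt": histogram, leaf-wise growth (classic GBDT/LightGBM-like).
.boost_importance <- function(x, y, flavour, nrounds, maxDepth, eta, seed) {
  is_class <- is.factor(y)
  if (is_class) {
    nl <- nlevels(y)
    label <- as.integer(y) - 1L
    obj <- if (nl == 2L) "binary:logistic" else "multi:softprob"
  } else {
    label <- as.numeric(y)
    obj <- "reg:squarederror"
  }
  params <- list(objective = obj, eta = eta, nthread = 1L, seed = seed)
  if (flavour == "catboost") {
    params$max_depth <- maxDepth
    params$grow_policy <- "depthwise"
  } else {
    params$tree_method <- "hist"
    params$grow_policy <- "lossguide"
    params$max_depth <- 0L
    params$max_leaves <- 2L^maxDepth %/% 2L
  }
  if (is_class && nlevels(y) > 2L) params$num_class <- nlevels(y)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  set.seed(seed)
  fit <- xgboost::xgb.train(params = params,
                            data = xgboost::xgb.DMatrix(x, label = label),
                            nrounds = nrounds, verbose = 0)
  imp <- xgboost::xgb.importance(model = fit)
  w <- numeric(ncol(x))
  w[match(imp$Feature, colnames(x))] <- imp$Gain
  w
}

#' Rank wavelengths by boosted-tree feature importance
#'
#' Fits a gradient-boosted tree ensemble on the full-wavelength spectra
#' and ranks bands by gain importance (total loss reduction), keeping the
#' top `k`. Two ensemble flavours are provided: `"catboost"` grows
#' depth-limited depthwise trees, `"gbdt"` grows leaf-wise histogram
#' trees, so the two rankers genuinely differ. Ties are broken by
#' ascending wavelength; results are deterministic given `seed`.
#'
#' @param x a [SpectralSet], or a seeds x bands matrix.
#' @param target for a SpectralSet: `"viability"` (classification) or
#'   `"sod"` (regression).
#' @param y for the matrix method: a factor (classification) or numeric
#'   (regression) response.
#' @param wl for the matrix method: the wavelength grid.
#' @param method ranker flavour, `"catboost"` or `"gbdt"`.
#' @param k number of bands to keep (default 15).
#' @param seed RNG seed for the ensemble fit.
#' @param nrounds,maxDepth,eta boosting hyperparameters (defaults 500
#'   trees, depth 6, learning rate 0.1).
#' @return a [BandRanking]; weights are sum-normalised gains.
#' @rdname rankBands
#' @export
setMethod("rankBands", "SpectralSet",
  function(x, target = c("viability", "sod"), method = c("catboost", "gbdt"),
           k = 15L, seed = 1L, nrounds = 500L, maxDepth = 6L, eta = 0.1) {
    target <- match.arg(target)
    y <- if (target == "viability") {
      factor(ifelse(viability(x), "viable", "nonviable"))
    } else sodValues(x)
    rankBands(spectraMatrix(x), y = y, wl = wavelengths(x),
              method = match.arg(method), k = k, seed = seed,
              nrounds = nrounds, maxDepth = maxDepth, eta = eta)
  })

#' @rdname rankBands
#' @export
setMethod("rankBands", "matrix",
  function(x, y, wl, method = c("catboost", "gbdt"), k = 15L, seed = 1L,
           nrounds = 500L, maxDepth = 6L, eta = 0.1) {
    method <- match.arg(method)
    k <- as.integer(k)
    if (k > ncol(x)) stop("k (", k, ") exceeds band count (", ncol(x), ")")
    if (is.factor(y)) {
      if (nlevels(droplevels(y)) < 2L) stop("degenerate target: one class")
    } else if (stats::sd(y) == 0) stop("degenerate target: constant response")
    stopifnot(length(wl) == ncol(x))
    w <- .boost_importance(x, y, method, nrounds, maxDepth, eta,
                           as.integer(seed))
    total <- sum(w)
    if (total > 0) w <- w / total
    ord <- order(-w, wl)
    top <- ord[seq_len(k)]
    new("BandRanking", wavelengths = wl[top], weights = w[top],
        method = method, k = k)
  })

#' Restrict a SpectralSet to a band ranking
#'
#' @param x a [SpectralSet].
#' @param ranking a [BandRanking] whose wavelengths all occur in `x`.
#' @return a [SpectralSet] with only the ranked bands, in ranking order.
#' @export
subsetToRanking <- function(x, ranking) {
  stopifnot(is(x, "SpectralSet"), is(ranking, "BandRanking"))
  idx <- match(ranking@wavelengths, wavelengths(x))
  if (anyNA(idx)) stop("ranking contains wavelengths absent from the dataset")
  x[idx, ]
}

setMethod("show", "BandRanking", function(object) {
  cat("BandRanking (", object@method, "): top ", object@k, " bands\n",
      sep = "")
  print(data.frame(rank = seq_len(object@k),
                   wavelength_nm = round(object@wavelengths, 2),
                   weight = signif(object@weights, 4)),
        row.names = FALSE)
})

#' Write a BandRanking as CSV (wavelength_nm, weight, rank)
#' @param ranking a [BandRanking].
#' @param path file path.
#' @export
writeRankingCSV <- function(ranking, path) {
  utils::write.csv(data.frame(wavelength_nm = ranking@wavelengths,
                              weight = ranking@weights,
                              rank = seq_len(ranking@k)),
                   path, row.names = FALSE)
  invisible(path)
}
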