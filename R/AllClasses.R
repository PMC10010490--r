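#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

AGING_GROUPS <- c("A0", "A1", "A2", "A3", "A4")

#' SimConfig: parameters of the synthetic aging-experiment generator
#'
#' Holds every knob of the synthetic hyperspectral / phenotype generator:
#' the wavelength grid, the group-wise reflectance baselines and absorption
#' dip depths, per-sample scatter and noise magnitudes, and the group-wise
#' germination probabilities and SOD (superoxide dismutase) activity levels.
#' Defaults emulate an accelerated-aging experiment with five groups
#' (A0 unaged through A4 aged 96 h): overall reflectance rises with aging
#' while the absorption features near 450, 550, 920 and 970 nm grow
#' shallower, germination probability falls from 0.9625 to 0.225, and mean
#' SOD activity falls from above 3 to well below 3 U/g FW.
#'
#' @slot nPerGroup seeds simulated per aging group.
#' @slot wavelengths strictly increasing band grid in nm.
#' @slot baselineByGroup broadband reflectance level per group, increasing
#'   with aging.
#' @slot spectralSlope relative rise of the broadband profile from the
#'   first to the last band (reflectance of seeds climbs towards the NIR).
#' @slot featureCenters centres (nm) of the Gaussian absorption dips.
#' @slot featureWidths Gaussian sigma (nm) of each dip.
#' @slot featureDepthsByGroup 5 x length(featureCenters) matrix of dip
#'   depths (reflectance units); each column non-increasing with aging.
#' @slot scatterSd sd of the per-seed multiplicative gain (gain ~ N(1, sd)).
#' @slot offsetSd sd of the per-seed additive baseline offset.
#' @slot noiseSd sd of per-band white noise.
#' @slot vigorSd sd of the per-seed latent vigor deviation within a group.
#' @slot vigorDepthCoef dip-depth change per unit latent vigor, in units
#'   of the unaged (A0) depth; the additive (linear-in-state) coupling
#'   lets a linear calibration recover the phenotype from the spectrum.
#' @slot vigorFeatureIdx which features (indices into `featureCenters`)
#'   respond to latent vigor; default the 920/970 nm protein and O-H
#'   overtone dips.
#' @slot germProbByGroup P(germinate within 8 d) per group.
#' @slot sodMeanByGroup mean SOD activity (U/g FW) per group, decreasing.
#' @slot sodVigorCoef SOD units per unit of within-group latent vigor.
#' @slot sodSd residual sd of SOD about its latent-vigor prediction.
#' @slot meanGermDayByGroup mean germination day per group (later when aged).
#' @slot germDaySd sd of the germination-day distribution (days).
#' @slot seedlingMassByGroup group-level seedling (root) mass scale S.
#' @slot seedlingMassSdlog lognormal sdlog of the realised S.
#' @slot rngSeed integer seed; identical configs give identical output.
#' @export
setClass("SimConfig", representation(
  nPerGroup = "integer",
  wavelengths = "numeric",
  baselineByGroup = "numeric",
  spectralSlope = "numeric",
  featureCenters = "numeric",
  featureWidths = "numeric",
  featureDepthsByGroup = "matrix",
  scatterSd = "numeric",
  offsetSd = "numeric",
  noiseSd = "numeric",
  vigorSd = "numeric",
  vigorDepthCoef = "numeric",
  vigorFeatureIdx = "integer",
  germProbByGroup = "numeric",
  sodMeanByGroup = "numeric",
  sodVigorCoef = "numeric",
  sodSd = "numeric",
  meanGermDayByGroup = "numeric",
  germDaySd = "numeric",
  seedlingMassByGroup = "numeric",
  seedlingMassSdlog = "numeric",
  rngSeed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  num_slots <- c("wavelengths", "baselineByGroup", "spectralSlope",
                 "featureCenters",
                 "featureWidths", "scatterSd", "offsetSd", "noiseSd",
                 "vigorSd", "vigorDepthCoef", "germProbByGroup",
                 "sodMeanByGroup", "sodVigorCoef", "sodSd",
                 "meanGermDayByGroup", "germDaySd", "seedlingMassByGroup",
                 "seedlingMassSdlog")
  for (s in num_slots)
    if (!all(is.finite(slot(object, s))))
      msg <- c(msg, sprintf("non-finite values in '%s'", s))
  if (object@nPerGroup < 1L)
    msg <- c(msg, "nPerGroup must be >= 1")
  if (is.unsorted(object@wavelengths, strictly = TRUE))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (any(object@germProbByGroup < 0 | object@germProbByGroup > 1))
    msg <- c(msg, "germProbByGroup must lie in [0, 1]")
  if (any(object@baselineByGroup < 0))
    msg <- c(msg, "baselineByGroup must be non-negative")
  if (any(object@featureDepthsByGroup < 0))
    msg <- c(msg, "featureDepthsByGroup must be non-negative")
  if (length(object@baselineByGroup) != 5L ||
      length(object@germProbByGroup) != 5L ||
      length(object@sodMeanByGroup) != 5L)
    msg <- c(msg, "group-wise parameters must have length 5 (A0-A4)")
  if (nrow(object@featureDepthsByGroup) != 5L ||
      ncol(object@featureDepthsByGroup) != length(object@featureCenters))
    msg <- c(msg, "featureDepthsByGroup must be 5 x length(featureCenters)")
  if (any(object@vigorFeatureIdx < 1L |
          object@vigorFeatureIdx > length(object@featureCenters)))
    msg <- c(msg, "vigorFeatureIdx out of range")
  if (length(msg)) msg else TRUE
})

#' SpectralSet: per-seed mean spectra with phenotype annotation
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying one
#' `"reflectance"` assay with bands as rows and seeds as columns.
#' `rowData` holds the wavelength grid (`wavelength_nm`); `colData` holds
#' `seed_id`, aging `group` (A0-A4), logical `viable`, and `sod` activity
#' (possibly NA when not assayed).
#'
#' @export
setClass("SpectralSet", contains = "SummarizedExperiment")

setValidity("SpectralSet", function(object) {
  msg <- character()
  if (!"reflectance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'reflectance' is required")
  wl <- rowData(object)$wavelength_nm
  if (is.null(wl)) {
    msg <- c(msg, "rowData must contain 'wavelength_nm'")
  } else {
    if (!all(is.finite(wl)) || anyDuplicated(wl))
      msg <- c(msg, "wavelengths must be finite and unique")
  }
  needed <- c("seed_id", "group", "viable")
  miss <- setdiff(needed, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste("colData missing:", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' HyperCube: a rows x cols x bands reflectance (or raw-count) cube
#'
#' @slot data numeric array, rows x cols x bands.
#' @slot wavelengths nm grid, length = bands, strictly increasing.
#' @slot kind "raw" (camera counts) or "corrected" (reflectance).
#' @export
setClass("HyperCube", representation(
  data = "array", wavelengths = "numeric", kind = "character"
))

setValidity("HyperCube", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a 3-D array")
  else {
    if (d[3] < 2L) msg <- c(msg, "at least 2 bands required")
    if (d[3] != length(object@wavelengths))
      msg <- c(msg, "length(wavelengths) must equal dim(data)[3]")
  }
  if (!all(is.finite(object@data))) msg <- c(msg, "data must be finite")
  if (is.unsorted(object@wavelengths, strictly = TRUE))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (!object@kind %in% c("raw", "corrected"))
    msg <- c(msg, "kind must be 'raw' or 'corrected'")
  if (length(msg)) msg else TRUE
})

#' BandRanking: wavelengths ordered by tree-ensemble importance
#'
#' @slot wavelengths nm, sorted by descending importance weight.
#' @slot weights non-negative, sum-normalised, non-increasing.
#' @slot method ranker flavour, "catboost" or "gbdt".
#' @slot k number of retained bands.
#' @export
setClass("BandRanking", representation(
  wavelengths = "numeric", weights = "numeric",
  method = "character", k = "integer"
))

setValidity("BandRanking", function(object) {
  msg <- character()
  if (length(object@wavelengths) != object@k)
    msg <- c(msg, "length(wavelengths) must equal k")
  if (length(object@weights) != object@k)
    msg <- c(msg, "length(weights) must equal k")
  if (anyDuplicated(object@wavelengths))
    msg <- c(msg, "wavelengths must be unique")
  if (any(object@weights < 0)) msg <- c(msg, "weights must be non-negative")
  if (is.unsorted(rev(object@weights)))
    msg <- c(msg, "weights must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' GerminationRecord: daily germination counts for one seed lot
#'
#' Either full daily counts `Gt` (days 1..8) or only the summary counts
#' `m1` (germinated within 3 d) and `m2` (within 8 d) may be supplied;
#' indices needing the daily profile are NA in the summary-only case.
#'
#' @slot M total seeds tested.
#' @slot Gt germinated-seed count per day, length 8 (all NA if unknown).
#' @slot m1 seeds germinated within 3 days.
#' @slot m2 seeds germinated within 8 days.
#' @slot S seedling (root) mass scale after 8 days; NA when unmeasured.
#' @export
setClass("GerminationRecord", representation(
  M = "integer", Gt = "numeric", m1 = "integer", m2 = "integer", S = "numeric"
))

setValidity("GerminationRecord", function(object) {
  msg <- character()
  if (object@M < 0L) msg <- c(msg, "M must be >= 0")
  if (length(object@Gt) != 8L) msg <- c(msg, "Gt must have length 8")
  if (!all(is.na(object@Gt))) {
    if (any(object@Gt < 0, na.rm = TRUE)) msg <- c(msg, "Gt must be >= 0")
    if (!is.na(object@m2) && sum(object@Gt) != object@m2)
      msg <- c(msg, "m2 must equal sum(Gt)")
  }
  if (!is.na(object@m1) && !is.na(object@m2) && object@m1 > object@m2)
    msg <- c(msg, "m1 must be <= m2")
  if (!is.na(object@m2) && object@m2 > object@M)
    msg <- c(msg, "m2 must be <= M")
  if (length(msg)) msg else TRUE
})

#' VigorIndices: the six germination vigor indices
#'
#' GP and GE are percentages; GI is a per-day weighted count; MGT is in
#' days (NA, with `mgtDefined = FALSE`, when nothing germinated); VI and
#' SVI carry the seedling-mass scale S.
#'
#' @slot GP germination potential, percent (within 3 d).
#' @slot GE germination rate, percent (within 8 d).
#' @slot GI germination index, sum(Gt / Dt).
#' @slot MGT mean germination time, days.
#' @slot VI vitality index, GI * S.
#' @slot SVI simple vitality index, (GP fraction) * S.
#' @slot mgtDefined FALSE when no seed germinated.
#' @export
setClass("VigorIndices", representation(
  GP = "numeric", GE = "numeric", GI = "numeric",
  MGT = "numeric", VI = "numeric", SVI = "numeric", mgtDefined = "logical"
))

#' PLSRModel: a NIPALS partial-least-squares regression fit
#'
#' @slot ncomp number of latent components.
#' @slot weights p x A X-weight matrix W.
#' @slot loadings p x A X-loading matrix P.
#' @slot scores n x A training score matrix T.
#' @slot yloadings length-A y-loading vector q.
#' @slot coef length-p regression coefficient vector (centred scale).
#' @slot xMeans,yMean centring vectors of the training data.
#' @export
setClass("PLSRModel", representation(
  ncomp = "integer", weights = "matrix", loadings = "matrix",
  scores = "matrix", yloadings = "numeric", coef = "numeric",
  xMeans = "numeric", yMean = "numeric"
))

#' VigorClassifier: a fitted seed-viability classifier
#'
#' @slot algorithm one of "xgboost", "lightgbm", "svmRBF", "randomForest".
#' @slot fit the underlying fitted model object.
#' @slot levels class labels in training order.
#' @slot nBands predictor count the model was trained on.
#' @export
setClass("VigorClassifier", representation(
  algorithm = "character", fit = "ANY", levels = "character",
  nBands = "integer"
))

#' ModelReport: metrics for one (preprocess, selector, model) grid cell
#'
#' @slot preprocess,selector,model cell identifiers ("" when standalone).
#' @slot task "classification" or "regression".
#' @slot calibration named list of metrics on the calibration set
#'   (accuracy/confusion, or R2/RMSE); empty when not evaluated.
#' @slot prediction same, for the held-out prediction set.
#' @export
setClass("ModelReport", representation(
  preprocess = "character", selector = "character", model = "character",
  task = "character", calibration = "list", prediction = "list"
))

setValidity("ModelReport", function(object) {
  msg <- character()
  if (!object@task %in% c("classification", "regression"))
    msg <- c(msg, "task must be 'classification' or 'regression'")
  for (side in c("calibration", "prediction")) {
    m <- slot(object, side)
    if (length(m) && object@task == "classification" &&
        !is.null(m$confusion)) {
      # accuracy is stored at 2-decimal reporting precision
      if (abs(m$accuracy - 100 * sum(diag(m$confusion)) / sum(m$confusion))
          > 0.005 + 1e-8)
        msg <- c(msg, sprintf("%s accuracy inconsistent with confusion", side))
    }
    if (length(m) && object@task == "regression") {
      if (!is.null(m$RMSE) && m$RMSE < 0) msg <- c(msg, "RMSE must be >= 0")
      if (!is.null(m$R2) && m$R2 > 1 + 1e-12) msg <- c(msg, "R2 must be <= 1")
    }
  }
  if (length(msg)) msg else TRUE
})
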