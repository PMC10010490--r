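#' Savitzky-Golay smoothing of spectra
#'
#' Replaces each band by the value of a local least-squares polynomial of
#' order `polyorder` fitted over a `window`-band neighbourhood. Interior
#' bands use centred windows; the first and last half-windows are handled
#' by fitting the polynomial to the edge window and evaluating it at the
#' off-centre positions, so the filter is exact on polynomials up to
#' `polyorder` everywhere.
#'
#' @param x spectra matrix (rows = spectra, columns = bands) or a vector.
#' @param window odd window width in bands (default 11).
#' @param polyorder polynomial order, < window (default 3).
#' @return object of the same shape, smoothed along the band axis.
#' @examples
#' savitzkyGolay(matrix(sin(1:50 / 5) + rnorm(50, 0, 0.05), 1))
#' @export
savitzkyGolay <- function(x, window = 11L, polyorder = 3L) {
  if (window %% 2 == 0 || window < 3) stop("window must be odd and >= 3")
  if (polyorder >= window) stop("polyorder must be < window")
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  if (window > ncol(m)) stop("window exceeds band count")
  out <- t(apply(m, 1, signal::sgolayfilt, p = polyorder, n = window))
  dimnames(out) <- dimnames(m)
  if (vec) drop(out) else out
}

#' Multiplicative scatter correction (MSC)
#'
#' Regresses every spectrum on a reference spectrum, x = a + b * ref, and
#' returns (x - a) / b, removing per-sample multiplicative scatter gain
#' and additive baseline offset. The reference defaults to the mean
#' spectrum of `x`; for a calibration/prediction workflow compute the
#' reference on the calibration set once and pass it when transforming
#' the prediction set (see `attr(, "reference")` on the result).
#'
#' @param x spectra matrix (rows = spectra, columns = bands).
#' @param reference reference spectrum, length = bands; must not be
#'   constant.
#' @return corrected matrix with the used reference attached as
#'   `attr(, "reference")`.
#' @examples
#' X <- matrix(runif(60), 3, 20)
#' Xc <- mscCorrect(X)
#' Xp <- mscCorrect(X, reference = attr(Xc, "reference"))
#' @export
mscCorrect <- function(x, reference = NULL) {
  m <- as.matrix(x)
  if (is.null(reference)) reference <- colMeans(m)
  if (length(reference) != ncol(m))
    stop("reference length must equal the band count")
  if (stats::sd(reference) == 0) stop("reference spectrum is constant")
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  out <- m
  for (i in seq_len(nrow(m))) {
    b <- sum(rc * (m[i, ] - mean(m[i, ]))) / denom
    if (b == 0) stop("fitted scatter slope b = 0 for spectrum ", i)
    a <- mean(m[i, ]) - b * mean(reference)
    out[i, ] <- (m[i, ] - a) / b
  }
  attr(out, "reference") <- reference
  out
}

#' Median filtering along the spectral axis
#'
#' Each band is replaced by the median of a centred odd window; edges use
#' reflected padding so the output length is unchanged.
#'
#' @param x spectra matrix (rows = spectra, columns = bands) or a vector.
#' @param window odd window width >= 3 (default 5).
#' @return object of the same shape.
#' @export
medianFilterSpectra <- function(x, window = 5L) {
  if (window %% 2 == 0 || window < 3) stop("window must be odd and >= 3")
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  k <- (window - 1L) / 2L
  nb <- ncol(m)
  if (window > nb) stop("window exceeds band count")
  pad_idx <- c((k + 1L):2L, seq_len(nb), (nb - 1L):(nb - k))
  out <- t(apply(m, 1, function(v) {
    pv <- v[pad_idx]
    vapply(seq_len(nb), function(i) stats::median(pv[i:(i + window - 1L)]),
           numeric(1))
  }))
  dimnames(out) <- dimnames(m)
  if (vec) drop(out) else out
}

#' Apply a named preprocessing method
#'
#' Dispatcher over the preprocessing variants compared in the pipeline:
#' `"raw"` (identity), `"SG"` (Savitzky-Golay), `"MSC"` (multiplicative
#' scatter correction) and `"MF"` (spectral median filter).
#'
#' @param x spectra matrix (rows = spectra, columns = bands).
#' @param method one of "raw", "SG", "MSC", "MF".
#' @param sgWindow,sgPolyorder Savitzky-Golay parameters.
#' @param mfWindow median-filter window.
#' @param reference MSC reference (NULL = mean of `x`).
#' @return preprocessed matrix; for MSC the reference used is attached
#'   as `attr(, "reference")`.
#' @export
preprocessSpectra <- function(x, method = c("raw", "SG", "MSC", "MF"),
                              sgWindow = 11L, sgPolyorder = 3L,
                              mfWindow = 5L, reference = NULL) {
  method <- match.arg(method)
  switch(method,
         raw = as.matrix(x),
         SG = savitzkyGolay(x, sgWindow, sgPolyorder),
         MSC = mscCorrect(x, reference),
         MF = medianFilterSpectra(x, mfWindow))
}
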