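#' Group-level summary linking spectra, vigor indices and SOD
#'
#' Builds the five-row (A0-A4) table used for correlation analysis: mean
#' reflectance at each selected wavelength, the six vigor indices, and
#' mean SOD activity per group.
#'
#' @param dataset a [SpectralSet] covering all five groups.
#' @param indexTable data.frame of vigor indices per group (rownames
#'   A0-A4, columns GP, GE, GI, MGT, VI, SVI), e.g. from
#'   [vigorIndexTable].
#' @param sodByGroup optional named numeric of group mean SOD; defaults
#'   to group means of `sodValues(dataset)`.
#' @param topBands wavelengths (nm) whose group-mean reflectance enters
#'   the table; must occur in the dataset grid.
#' @return data.frame, 5 rows, columns GP..SVI, SOD, then one `R<nm>`
#'   column per band.
#' @export
buildGroupSummary <- function(dataset, indexTable, sodByGroup = NULL,
                              topBands) {
  grp <- agingGroup(dataset)
  missing_g <- setdiff(AGING_GROUPS, as.character(unique(grp)))
  if (length(missing_g))
    stop("dataset is missing group(s): ", paste(missing_g, collapse = ", "))
  if (!all(AGING_GROUPS %in% rownames(indexTable)))
    stop("indexTable must have rows A0-A4")
  wl <- wavelengths(dataset)
  idx <- match(topBands, wl)
  if (anyNA(idx)) {
    # tolerate nearest-band lookup for wavelengths quoted at print precision
    idx <- vapply(topBands, function(b) which.min(abs(wl - b)), integer(1))
  }
  mat <- spectraMatrix(dataset)
  refl <- do.call(rbind, lapply(AGING_GROUPS, function(g)
    colMeans(mat[grp == g, idx, drop = FALSE])))
  colnames(refl) <- paste0("R", format(wl[idx], trim = TRUE, digits = 6))
  if (is.null(sodByGroup))
    sodByGroup <- vapply(AGING_GROUPS, function(g)
      mean(sodValues(dataset)[grp == g], na.rm = TRUE), numeric(1))
  out <- cbind(indexTable[AGING_GROUPS, c("GP", "GE", "GI", "MGT", "VI",
                                          "SVI")],
               SOD = as.numeric(sodByGroup[AGING_GROUPS]),
               as.data.frame(refl))
  rownames(out) <- AGING_GROUPS
  out
}

#' Pearson correlation matrix of a group summary
#'
#' Pairwise Pearson correlations over the (typically five) group rows.
#' With so few rows the coefficients are descriptive only; a warning
#' notes the sample size, and constant columns are flagged and returned
#' as NA.
#'
#' @param summary data.frame of numeric columns (e.g. from
#'   [buildGroupSummary]).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearsonMatrix <- function(summary) {
  m <- as.matrix(summary)
  storage.mode(m) <- "double"
  if (nrow(m) < 3) stop("need at least 3 rows for a correlation")
  const <- apply(m, 2, stats::sd) == 0
  if (any(const))
    warning("constant column(s), correlations undefined: ",
            paste(colnames(m)[const], collapse = ", "))
  if (nrow(m) <= 5)
    warning("correlations computed over only ", nrow(m),
            " group means; descriptive, not inferential")
  cc <- suppressWarnings(stats::cor(m))
  diag(cc) <- 1
  cc
}

#' Render the correlation heat map
#'
#' Vigor indices first, then SOD, then wavelengths ascending, matching
#' the conventional layout of such figures. Requires the pheatmap
#' package.
#'
#' @param corMat matrix from [pearsonMatrix].
#' @param ... passed to [pheatmap::pheatmap].
#' @return the pheatmap object, invisibly.
#' @export
plotCorrelationHeatmap <- function(corMat, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plotCorrelationHeatmap requires the pheatmap package")
  fixed <- c("GP", "GE", "GI", "MGT", "VI", "SVI", "SOD")
  bands <- setdiff(colnames(corMat), fixed)
  bands <- bands[order(as.numeric(sub("^R", "", bands)))]
  ord <- c(intersect(fixed, colnames(corMat)), bands)
  invisible(pheatmap::pheatmap(corMat[ord, ord], cluster_rows = FALSE,
                               cluster_cols = FALSE,
                               breaks = seq(-1, 1, length.out = 101), ...))
}
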