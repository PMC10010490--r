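#' Construct a SpectralSet
#'
#' @param spectra seeds x bands reflectance matrix.
#' @param wavelengths nm grid, length = bands.
#' @param seedId character seed identifiers.
#' @param group aging group labels (A0-A4 or any factor-able vector).
#' @param viable logical viability flag per seed.
#' @param sod SOD activity per seed (NA when not assayed).
#' @return a [SpectralSet].
#' @examples
#' ss <- spectralSet(matrix(runif(20), 4, 5), wavelengths = 1:5 * 100,
#'                   seedId = paste0("s", 1:4), group = rep("A0", 4),
#'                   viable = rep(TRUE, 4))
#' @export
spectralSet <- function(spectra, wavelengths, seedId, group, viable,
                        sod = NA_real_) {
  spectra <- as.matrix(spectra)
  stopifnot(ncol(spectra) == length(wavelengths),
            nrow(spectra) == length(seedId))
  lv <- if (all(group %in% AGING_GROUPS)) AGING_GROUPS else sort(unique(group))
  assay <- t(spectra)
  dimnames(assay) <- list(NULL, seedId)
  se <- SummarizedExperiment(
    assays = list(reflectance = assay),
    rowData = DataFrame(wavelength_nm = as.numeric(wavelengths)),
    colData = DataFrame(seed_id = as.character(seedId),
                        group = factor(group, levels = lv),
                        viable = as.logical(viable),
                        sod = rep_len(as.numeric(sod), length(seedId)))
  )
  new("SpectralSet", se)
}

#' Wavelength grid accessor
#' @param x a [SpectralSet] or [HyperCube].
#' @return numeric vector of band centres in nm.
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectralSet",
          function(x) rowData(x)$wavelength_nm)

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "HyperCube", function(x) x@wavelengths)

#' Seeds-by-bands reflectance matrix
#' @param x a [SpectralSet].
#' @return numeric matrix, rows = seeds (named by seed id), columns =
#'   bands (named by wavelength).
#' @rdname spectraMatrix
#' @export
setMethod("spectraMatrix", "SpectralSet", function(x) {
  m <- t(assay(x, "reflectance"))
  dimnames(m) <- list(colData(x)$seed_id,
                      format(wavelengths(x), trim = TRUE, digits = 10))
  m
})

#' Aging-group factor accessor
#' @param x a [SpectralSet].
#' @rdname agingGroup
#' @export
setMethod("agingGroup", "SpectralSet", function(x) colData(x)$group)

#' Viability flag accessor
#' @param x a [SpectralSet].
#' @rdname viability
#' @export
setMethod("viability", "SpectralSet", function(x) colData(x)$viable)

#' SOD activity accessor
#' @param x a [SpectralSet].
#' @rdname sodValues
#' @export
setMethod("sodValues", "SpectralSet", function(x) colData(x)$sod)

#' @describeIn trimBands drop bands outside `[loNm, hiNm]`, preserving
#'   band order (idempotent).
#' @export
setMethod("trimBands", "SpectralSet", function(x, loNm = 400, hiNm = 1000) {
  wl <- wavelengths(x)
  keep <- wl >= loNm & wl <= hiNm
  if (!any(keep)) stop("no bands fall inside [", loNm, ", ", hiNm, "] nm")
  x[keep, ]
})

setMethod("show", "SpectralSet", function(object) {
  cat("SpectralSet:", ncol(object), "seeds x", nrow(object), "bands (",
      format(min(wavelengths(object)), digits = 6), "-",
      format(max(wavelengths(object)), digits = 6), "nm )\n")
  cat("  groups:", paste(levels(agingGroup(object)), table(agingGroup(object)),
                         sep = ":", collapse = " "), "\n")
  nv <- sum(viability(object))
  cat("  viable:", nv, "/", ncol(object),
      if (all(is.na(sodValues(object)))) "| SOD: not assayed"
      else sprintf("| SOD: mean %.2f", mean(sodValues(object), na.rm = TRUE)),
      "\n")
})
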