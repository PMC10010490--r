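#' @rdname wavelengths
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname spectraMatrix
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' @rdname agingGroup
#' @export
setGeneric("agingGroup", function(x) standardGeneric("agingGroup"))

#' @rdname viability
#' @export
setGeneric("viability", function(x) standardGeneric("viability"))

#' @rdname sodValues
#' @export
setGeneric("sodValues", function(x) standardGeneric("sodValues"))

#' @rdname trimBands
#' @export
setGeneric("trimBands", function(x, loNm = 400, hiNm = 1000)
  standardGeneric("trimBands"))

#' @rdname rankBands
#' @export
setGeneric("rankBands", function(x, ...) standardGeneric("rankBands"))
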