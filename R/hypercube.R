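#' Construct a HyperCube
#'
#' @param data rows x cols x bands numeric array.
#' @param wavelengths nm grid, length = bands, strictly increasing.
#' @param kind "raw" camera counts or "corrected" reflectance.
#' @return a [HyperCube].
#' @export
hyperCube <- function(data, wavelengths, kind = c("raw", "corrected")) {
  new("HyperCube", data = data, wavelengths = as.numeric(wavelengths),
      kind = match.arg(kind))
}

#' Cube dimensions and show
#' @param object a [HyperCube].
#' @rdname HyperCube-class
setMethod("show", "HyperCube", function(object) {
  d <- dim(object@data)
  cat("HyperCube (", object@kind, "): ", d[1], " x ", d[2], " px, ",
      d[3], " bands (", format(min(object@wavelengths), digits = 6), "-",
      format(max(object@wavelengths), digits = 6), " nm)\n", sep = "")
})

#' @rdname HyperCube-class
#' @export
setMethod("dim", "HyperCube", function(x) dim(x@data))

# Broadcast a reference frame recorded as a single scan line
# (1 x cols x bands) to the full cube height.
.broadcast_ref <- function(ref, target_dim) {
  d <- dim(ref@data)
  if (identical(d, target_dim)) return(ref@data)
  if (d[1] == 1L && d[2] == target_dim[2] && d[3] == target_dim[3]) {
    out <- array(0, target_dim)
    for (b in seq_len(d[3]))
      out[, , b] <- matrix(ref@data[1, , b], target_dim[1], target_dim[2],
                           byrow = TRUE)
    return(out)
  }
  stop("reference cube shape ", paste(d, collapse = "x"),
       " does not match sample shape ", paste(target_dim, collapse = "x"))
}

#' Black/white reflectance correction
#'
#' Converts raw camera counts to reflectance with the standard two-point
#' calibration R = (Sample - dark) / (White - dark), elementwise. Dark
#' and white references may be full cubes or single-line frames, which
#' are broadcast along the scan direction.
#'
#' @param sample,dark,white [HyperCube]s on the same wavelength grid.
#' @return a corrected [HyperCube] (kind "corrected").
#' @examples
#' wl <- c(500, 600)
#' s <- hyperCube(array(0.5, c(2, 2, 2)), wl)
#' d <- hyperCube(array(0, c(2, 2, 2)), wl)
#' w <- hyperCube(array(1, c(2, 2, 2)), wl)
#' range(blackWhiteCorrect(s, d, w)@data)  # 0.5
#' @export
blackWhiteCorrect <- function(sample, dark, white) {
  stopifnot(is(sample, "HyperCube"), is(dark, "HyperCube"),
            is(white, "HyperCube"))
  if (!isTRUE(all.equal(sample@wavelengths, dark@wavelengths)) ||
      !isTRUE(all.equal(sample@wavelengths, white@wavelengths)))
    stop("wavelength grids of sample, dark and white must match")
  d <- dim(sample@data)
  darkA <- .broadcast_ref(dark, d)
  whiteA <- .broadcast_ref(white, d)
  denom <- whiteA - darkA
  if (any(denom == 0))
    stop("white - dark is zero at ", sum(denom == 0), " element(s)")
  new("HyperCube", data = (sample@data - darkA) / denom,
      wavelengths = sample@wavelengths, kind = "corrected")
}

#' Segment seeds in a corrected cube
#'
#' Thresholds the image at the band nearest `bandNm` (default 800 nm,
#' where seeds are bright against dark cardboard), labels connected
#' components, discards those below `minArea`, and orders the surviving
#' masks row-major by centroid: components are grouped into tray rows
#' wherever the gap between sorted centroid rows exceeds half the median
#' component height, then sorted by column within a row.
#'
#' @param cube a corrected [HyperCube].
#' @param bandNm wavelength (nm) of the thresholding band.
#' @param threshold reflectance cut separating seed from background.
#' @param minArea minimum component area in pixels.
#' @param expected optional expected seed count; a mismatch is reported
#'   with a message (e.g. two seeds merged under a low threshold).
#' @return list of masks, each a 2-column (row, col) pixel-index matrix.
#' @export
segmentSeeds <- function(cube, bandNm = 800, threshold = 0.2, minArea = 20,
                         expected = NULL) {
  stopifnot(is(cube, "HyperCube"))
  if (cube@kind != "corrected")
    warning("segmenting an uncorrected cube; threshold is in raw counts")
  b <- which.min(abs(cube@wavelengths - bandNm))
  img <- cube@data[, , b]
  lab <- EBImage::bwlabel(img > threshold)
  ncomp <- max(lab)
  masks <- list()
  for (i in seq_len(ncomp)) {
    px <- which(lab == i, arr.ind = TRUE)
    if (nrow(px) >= minArea) masks[[length(masks) + 1L]] <- unname(px)
  }
  if (!length(masks)) stop("no component found above threshold ", threshold)
  cen <- t(vapply(masks, colMeans, numeric(2)))
  hts <- vapply(masks, function(px) diff(range(px[, 1])) + 1, numeric(1))
  ord <- order(cen[, 1])
  rowgrp <- cumsum(c(1, diff(cen[ord, 1]) > stats::median(hts) / 2))
  masks <- masks[ord][order(rowgrp, cen[ord, 2])]
  if (!is.null(expected) && length(masks) != expected)
    message("segmentSeeds: found ", length(masks), " components, expected ",
            expected, " (seeds may have merged or split)")
  masks
}

#' Mean spectrum over a seed mask
#'
#' @param cube a [HyperCube].
#' @param mask 2-column (row, col) pixel-index matrix inside the cube.
#' @return numeric vector of per-band means over the mask pixels.
#' @export
meanSpectrum <- function(cube, mask) {
  stopifnot(is(cube, "HyperCube"), is.matrix(mask), ncol(mask) == 2)
  d <- dim(cube@data)
  if (any(mask[, 1] < 1 | mask[, 1] > d[1] | mask[, 2] < 1 | mask[, 2] > d[2]))
    stop("mask pixels outside cube bounds")
  vapply(seq_len(d[3]),
         function(b) mean(cube@data[cbind(mask, b)]), numeric(1))
}

#' Extract per-seed mean spectra into a SpectralSet
#'
#' @param cube a corrected [HyperCube].
#' @param masks list of seed masks (row-major tray order).
#' @param group,viable,sod optional per-seed annotation.
#' @return a [SpectralSet] with one column per mask.
#' @export
cubeToSpectralSet <- function(cube, masks, group = NA, viable = NA,
                              sod = NA_real_) {
  spectra <- t(vapply(masks, function(m) meanSpectrum(cube, m),
                      numeric(dim(cube@data)[3])))
  n <- length(masks)
  spectralSet(spectra, cube@wavelengths,
              seedId = sprintf("S%02d", seq_len(n)),
              group = rep_len(group, n), viable = rep_len(viable, n),
              sod = rep_len(sod, n))
}

#' @describeIn trimBands drop noisy edge bands of a cube outside
#'   `[loNm, hiNm]` (default 400-1000 nm).
#' @export
setMethod("trimBands", "HyperCube", function(x, loNm = 400, hiNm = 1000) {
  keep <- x@wavelengths >= loNm & x@wavelengths <= hiNm
  if (!any(keep)) stop("no bands fall inside [", loNm, ", ", hiNm, "] nm")
  new("HyperCube", data = x@data[, , keep, drop = FALSE],
      wavelengths = x@wavelengths[keep], kind = x@kind)
})

#' Write / read a HyperCube in ENVI format
#'
#' Band-sequential (BSQ) 32-bit float raw file plus a key-value text
#' header carrying the wavelength list. `readENVI` also accepts BIL
#' interleave and 64-bit (data type 5) files.
#'
#' @param cube a [HyperCube].
#' @param path path of the raw data file; the header is `<path>.hdr`.
#' @return `writeENVI` returns `path` invisibly; `readENVI` a [HyperCube].
#' @export
writeENVI <- function(cube, path) {
  stopifnot(is(cube, "HyperCube"))
  d <- dim(cube@data)
  hdr <- c(
    "ENVI",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    paste0("wavelength = { ",
           paste(format(cube@wavelengths, trim = TRUE, digits = 10),
                 collapse = ", "), " }")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  # BSQ: per band, line-major (row by row)
  for (b in seq_len(d[3]))
    writeBin(as.numeric(t(cube@data[, , b])), con, size = 4, endian = "little")
  invisible(path)
}

.parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  getval <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?mi)^", key,
                                        "\\s*=\\s*([^\n{]+)$"), txt, perl = TRUE))[[1]]
    if (length(m) < 2) NA_character_ else trimws(m[2])
  }
  braced <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?si)", key, "\\s*=\\s*\\{(.*?)\\}"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) return(NULL)
    as.numeric(strsplit(m[2], "[,\n]")[[1]])
  }
  list(samples = as.integer(getval("samples")),
       lines = as.integer(getval("lines")),
       bands = as.integer(getval("bands")),
       dtype = as.integer(getval("data type")),
       interleave = tolower(getval("interleave")),
       byteorder = as.integer(getval("byte order")),
       wavelength = braced("wavelength"))
}

#' @rdname writeENVI
#' @param kind passed to the returned [HyperCube].
#' @export
readENVI <- function(path, kind = "corrected") {
  h <- .parse_envi_header(paste0(path, ".hdr"))
  if (!h$dtype %in% c(4L, 5L))
    stop("unsupported ENVI data type ", h$dtype, " (need 4 or 5)")
  size <- if (h$dtype == 4L) 4L else 8L
  endian <- if (identical(h$byteorder, 1L)) "big" else "little"
  n <- h$samples * h$lines * h$bands
  vals <- readBin(path, numeric(), n = n, size = size, endian = endian)
  cube <- array(0, c(h$lines, h$samples, h$bands))
  if (identical(h$interleave, "bsq")) {
    for (b in seq_len(h$bands)) {
      off <- (b - 1L) * h$lines * h$samples
      cube[, , b] <- matrix(vals[off + seq_len(h$lines * h$samples)],
                            h$lines, h$samples, byrow = TRUE)
    }
  } else if (identical(h$interleave, "bil")) {
    idx <- 0L
    for (l in seq_len(h$lines)) for (b in seq_len(h$bands)) {
      cube[l, , b] <- vals[idx + seq_len(h$samples)]
      idx <- idx + h$samples
    }
  } else stop("unsupported interleave '", h$interleave, "'")
  wl <- if (is.null(h$wavelength)) seq_len(h$bands) else h$wavelength
  new("HyperCube", data = cube, wavelengths = wl, kind = kind)
}
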