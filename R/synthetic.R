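#' Build a synthetic-experiment configuration
#'
#' Returns a [SimConfig] describing a five-group accelerated-aging
#' experiment (A0 unaged, A1-A4 aged 24-96 h). The defaults encode the
#' structure the downstream analysis assumes:
#'
#' * 256 evenly spaced bands over 384-1034 nm (matching a ~2.5 nm grid);
#' * a broadband reflectance profile rising towards the NIR whose level
#'   increases with aging (organic-matter loss);
#' * Gaussian absorption dips at 450, 550, 920 and 970 nm (pigment,
#'   soluble sugar, protein, and O-H overtone features) whose depth
#'   shrinks as seeds age — the visible and NIR features at different
#'   rates, so the spectral shape change is not a pure rescaling and
#'   survives scatter correction;
#' * per-seed multiplicative scatter, additive baseline offset, and
#'   per-band white noise;
#' * a per-seed latent vigor deviation that modulates the depth of the
#'   920/970 nm protein and O-H features, drives the viability outcome,
#'   and carries SOD activity, so spectra, germination and enzyme assay
#'   are mechanistically linked;
#' * group germination probabilities 0.9625, 0.85, 0.65, 0.3875, 0.225
#'   and mean SOD activity falling from 3.32 (unaged, above 3) to 1.80.
#'
#' @param nPerGroup seeds per group (default 80, i.e. 400 seeds total).
#' @param rngSeed integer seed; identical configs produce identical data.
#' @param ... override any other [SimConfig] slot by name.
#' @return a validated [SimConfig].
#' @examples
#' cfg <- simConfig(nPerGroup = 10, rngSeed = 1)
#' @export
simConfig <- function(nPerGroup = 80L, rngSeed = 7L, ...) {
  depth_base <- c(0.060, 0.050, 0.050, 0.070)
  # visible (pigment/sugar) features fade slower with aging than the
  # NIR protein and O-H features, so aging changes the dip *ratios*
  scale_vis <- c(1.00, 0.90, 0.80, 0.70, 0.60)
  scale_nir <- c(1.00, 0.82, 0.66, 0.52, 0.40)
  defaults <- list(
    nPerGroup = as.integer(nPerGroup),
    wavelengths = seq(384, 1034, length.out = 256),
    baselineByGroup = c(0.36, 0.41, 0.46, 0.51, 0.56),
    spectralSlope = 0.45,
    featureCenters = c(450, 550, 920, 970),
    featureWidths = c(25, 30, 18, 16),
    featureDepthsByGroup = cbind(outer(scale_vis, depth_base[1:2]),
                                 outer(scale_nir, depth_base[3:4])),
    scatterSd = 0.08,
    offsetSd = 0.02,
    noiseSd = 0.004,
    vigorSd = 1.0,
    vigorDepthCoef = 0.20,
    vigorFeatureIdx = c(3L, 4L),
    germProbByGroup = c(0.9625, 0.85, 0.65, 0.3875, 0.225),
    sodMeanByGroup = c(3.32, 2.84, 2.47, 2.12, 1.80),
    sodVigorCoef = 0.30,
    sodSd = 0.08,
    meanGermDayByGroup = c(2.78, 3.24, 4.30, 5.74, 7.21),
    germDaySd = 1.2,
    seedlingMassByGroup = c(1.69, 1.77, 1.58, 1.57, 1.52),
    seedlingMassSdlog = 0.05,
    rngSeed = as.integer(rngSeed)
  )
  override <- list(...)
  bad <- setdiff(names(override), names(defaults))
  if (length(bad))
    stop("unknown SimConfig fields: ", paste(bad, collapse = ", "))
  defaults[names(override)] <- override
  defaults$nPerGroup <- as.integer(defaults$nPerGroup)
  defaults$rngSeed <- as.integer(defaults$rngSeed)
  do.call(new, c(list("SimConfig"), defaults))
}

#' Noise-free mean reflectance curve of one aging group
#'
#' The deterministic part of the generative model: group baseline minus
#' the sum of Gaussian absorption dips, at the group's mean latent vigor.
#'
#' @param config a [SimConfig].
#' @param group group index 1..5 or label "A0".."A4".
#' @return numeric vector over `config@wavelengths`.
#' @export
groupMeanCurve <- function(config, group) {
  g <- if (is.character(group)) match(group, AGING_GROUPS) else as.integer(group)
  stopifnot(!is.na(g), g >= 1L, g <= 5L)
  drop(.clean_spectra(config, g, dev = 0))
}

# Broadband profile: relative reflectance rising linearly towards the NIR.
.broad_shape <- function(config) {
  wl <- config@wavelengths
  1 + config@spectralSlope * (wl - wl[1]) / (wl[length(wl)] - wl[1])
}

# Noise-free spectra for groups `g` (vector) at latent-vigor deviations
# `dev` (vector, recycled); returns length(g) x bands matrix.
.clean_spectra <- function(config, g, dev) {
  wl <- config@wavelengths
  nb <- length(wl)
  dipShapes <- vapply(seq_along(config@featureCenters), function(j) {
    exp(-0.5 * ((wl - config@featureCenters[j]) / config@featureWidths[j])^2)
  }, numeric(nb))
  shape <- .broad_shape(config)
  n <- length(g)
  dev <- rep_len(dev, n)
  vmask <- seq_along(config@featureCenters) %in% config@vigorFeatureIdx
  out <- matrix(0, n, nb)
  for (i in seq_len(n)) {
    # additive vigor response in units of the unaged (A0) depth: dip
    # depth is linear in the seed's physiological state, so a linear
    # calibration (PLSR) can recover it
    depth <- pmax(0, config@featureDepthsByGroup[g[i], ] +
                    config@vigorDepthCoef * dev[i] *
                      config@featureDepthsByGroup[1L, ] * vmask)
    out[i, ] <- config@baselineByGroup[g[i]] * shape - drop(dipShapes %*% depth)
  }
  out
}

# Latent-vigor group means: chosen so P(vigor > 0) reproduces the
# group germination probabilities exactly (vigorSd = 1 scale).
.vigor_means <- function(config) stats::qnorm(config@germProbByGroup)

# Shared per-seed machinery: latent vigor, viability, SOD, spectrum.
# Called inside an established RNG stream.
.draw_seeds <- function(config, groups_idx) {
  n <- length(groups_idx)
  mu <- .vigor_means(config)
  vigor <- mu[groups_idx] + stats::rnorm(n, 0, config@vigorSd)
  dev <- vigor - mu[groups_idx]
  viable <- vigor > 0
  sod <- config@sodMeanByGroup[groups_idx] + config@sodVigorCoef * dev +
    stats::rnorm(n, 0, config@sodSd)
  gain <- pmax(0.2, stats::rnorm(n, 1, config@scatterSd))
  offset <- stats::rnorm(n, 0, config@offsetSd)
  nb <- length(config@wavelengths)
  clean <- .clean_spectra(config, groups_idx, dev)
  spectra <- gain * clean + offset +
    matrix(stats::rnorm(n * nb, 0, config@noiseSd), n, nb)
  list(spectra = spectra, vigor = vigor, viable = viable, sod = sod,
       gain = gain, offset = offset)
}

#' Simulate per-seed mean spectra with phenotype truth
#'
#' Draws `nPerGroup` seeds per aging group. Each seed gets a latent vigor
#' value (group mean + deviation); the deviation scales the absorption-dip
#' depths, decides viability (vigor > 0), and shifts SOD activity, so the
#' spectrum genuinely encodes the phenotype rather than just the group
#' label. Scatter gain, baseline offset and white noise are then applied.
#'
#' @param config a [SimConfig]; `config@rngSeed` fixes the output.
#' @return list with `dataset` (a [SpectralSet]) and `truth` (a
#'   `DataFrame` with seed_id, group, viable, sod, vigor, gain, offset).
#' @examples
#' sim <- simulateSpectra(simConfig(nPerGroup = 5, rngSeed = 1))
#' dim(spectraMatrix(sim$dataset))
#' @export
simulateSpectra <- function(config) {
  validObject(config)
  set.seed(config@rngSeed)
  groups_idx <- rep(seq_len(5L), each = config@nPerGroup)
  d <- .draw_seeds(config, groups_idx)
  seed_id <- sprintf("%s_%03d", AGING_GROUPS[groups_idx],
                     sequence(rep(config@nPerGroup, 5L)))
  dataset <- spectralSet(
    spectra = d$spectra, wavelengths = config@wavelengths,
    seedId = seed_id, group = AGING_GROUPS[groups_idx],
    viable = d$viable, sod = d$sod
  )
  truth <- DataFrame(
    seed_id = seed_id, group = factor(AGING_GROUPS[groups_idx],
                                      levels = AGING_GROUPS),
    viable = d$viable, sod = d$sod, vigor = d$vigor,
    gain = d$gain, offset = d$offset
  )
  list(dataset = dataset, truth = truth)
}

#' Simulate a hyperspectral tray cube with per-seed masks
#'
#' Lays `nSeeds` elliptical seed regions on a dark tray background in a
#' `rows x cols` grid (row-major order), injecting each seed's simulated
#' spectrum into its pixels plus per-pixel noise.
#'
#' @param config a [SimConfig].
#' @param rows,cols tray layout (default 4 x 5 as on the sample stage).
#' @param nSeeds seeds placed (default full tray); must fit the layout.
#' @param cellPx pixel size of one tray cell.
#' @param radii ellipse semi-axes (row, col) in pixels; must fit a cell.
#' @param background reflectance of the dark cardboard.
#' @return list with `cube` ([HyperCube]), `masks` (list of 2-column
#'   pixel-index matrices, row-major tray order), and `truth` (`DataFrame`
#'   incl. the injected spectra as a matrix column `spectrum`).
#' @export
simulateCube <- function(config, rows = 4L, cols = 5L, nSeeds = rows * cols,
                         cellPx = 16L, radii = c(5, 6), background = 0.02) {
  validObject(config)
  if (nSeeds > rows * cols)
    stop("layout capacity (", rows * cols, ") < seeds requested (", nSeeds, ")")
  if (2 * radii[1] + 1 > cellPx || 2 * radii[2] + 1 > cellPx)
    stop("seed ellipse does not fit the tray cell: seeds would overlap")
  set.seed(config@rngSeed)
  groups_idx <- sort(rep_len(seq_len(5L), nSeeds))
  d <- .draw_seeds(config, groups_idx)
  nb <- length(config@wavelengths)
  nr <- rows * cellPx; nc <- cols * cellPx
  cube <- array(background, dim = c(nr, nc, nb))
  if (config@noiseSd > 0)
    cube <- cube + array(stats::rnorm(nr * nc * nb, 0, config@noiseSd),
                         dim = c(nr, nc, nb))
  masks <- vector("list", nSeeds)
  for (i in seq_len(nSeeds)) {
    tr <- (i - 1L) %/% cols; tc <- (i - 1L) %% cols
    cy <- tr * cellPx + (cellPx + 1) / 2
    cx <- tc * cellPx + (cellPx + 1) / 2
    rws <- seq_len(nr); cls <- seq_len(nc)
    inside <- outer(((rws - cy) / radii[1])^2, ((cls - cx) / radii[2])^2, "+") <= 1
    px <- which(inside, arr.ind = TRUE)
    masks[[i]] <- unname(px)
    for (b in seq_len(nb)) {
      val <- d$spectra[i, b]
      cube[cbind(px, b)] <- val +
        if (config@noiseSd > 0) stats::rnorm(nrow(px), 0, config@noiseSd) else 0
    }
  }
  truth <- DataFrame(
    seed_id = sprintf("S%02d", seq_len(nSeeds)),
    group = factor(AGING_GROUPS[groups_idx], levels = AGING_GROUPS),
    viable = d$viable, sod = d$sod, vigor = d$vigor
  )
  truth$spectrum <- d$spectra
  list(cube = new("HyperCube", data = cube,
                  wavelengths = config@wavelengths, kind = "corrected"),
       masks = masks, truth = truth)
}

#' Simulate roll-paper germination records per aging group
#'
#' Each of `nPerGroup` seeds in a group germinates with that group's
#' probability; germinating seeds are assigned a day in 1..8 from a
#' discretised normal whose mean increases with aging. The group seedling
#' mass S is drawn lognormal about the group scale.
#'
#' @param config a [SimConfig].
#' @return named list (A0..A4) of [GerminationRecord] objects.
#' @export
simulateGermination <- function(config) {
  validObject(config)
  set.seed(config@rngSeed + 1L)
  days <- 1:8
  out <- vector("list", 5L)
  names(out) <- AGING_GROUPS
  for (g in seq_len(5L)) {
    n <- config@nPerGroup
    germinated <- stats::rbinom(n, 1L, config@germProbByGroup[g])
    m2 <- sum(germinated)
    pday <- stats::dnorm(days, config@meanGermDayByGroup[g], config@germDaySd)
    pday <- pday / sum(pday)
    Gt <- numeric(8)
    if (m2 > 0) {
      day <- sample(days, m2, replace = TRUE, prob = pday)
      Gt <- as.numeric(tabulate(day, nbins = 8L))
    }
    S <- stats::rlnorm(1, log(config@seedlingMassByGroup[g]),
                       config@seedlingMassSdlog)
    out[[g]] <- germinationRecord(M = n, Gt = Gt, S = S)
  }
  out
}

#' Write / read a SpectralSet as CSV
#'
#' Column layout: seed_id, group, viable, sod, then one column per band
#' named by its wavelength in nm.
#'
#' @param x a [SpectralSet].
#' @param path file path.
#' @return `writeSpectraCSV` returns `path` invisibly; `readSpectraCSV`
#'   returns a [SpectralSet].
#' @export
writeSpectraCSV <- function(x, path) {
  mat <- spectraMatrix(x)
  df <- data.frame(
    seed_id = colData(x)$seed_id,
    group = as.character(agingGroup(x)),
    viable = viability(x),
    sod = sodValues(x),
    mat, check.names = FALSE
  )
  colnames(df)[-(1:4)] <- format(wavelengths(x), trim = TRUE, digits = 10)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectraCSV
#' @export
readSpectraCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wl <- as.numeric(colnames(df)[-(1:4)])
  spectralSet(
    spectra = as.matrix(df[, -(1:4), drop = FALSE]),
    wavelengths = wl, seedId = df$seed_id, group = df$group,
    viable = as.logical(df$viable), sod = df$sod
  )
}
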