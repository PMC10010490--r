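# Shared fixtures: all synthetic, generated at test time.

# Small default-structure config for fast tests.
smallConfig <- function(nPerGroup = 10L, rngSeed = 1L, ...) {
  simConfig(nPerGroup = nPerGroup, rngSeed = rngSeed, ...)
}

# Every stochastic term switched off: spectra equal the group mean curves.
noiseFreeConfig <- function(nPerGroup = 1L, rngSeed = 1L, ...) {
  simConfig(nPerGroup = nPerGroup, rngSeed = rngSeed,
            scatterSd = 0, offsetSd = 0, noiseSd = 0, vigorSd = 0, ...)
}

# A coarse-grid config keeping model-fitting tests quick.
coarseConfig <- function(nPerGroup = 10L, rngSeed = 1L, nBands = 60L, ...) {
  simConfig(nPerGroup = nPerGroup, rngSeed = rngSeed,
            wavelengths = seq(400, 1000, length.out = nBands), ...)
}

# Brute-force Savitzky-Golay oracle: explicit least-squares polynomial fit
# in each (edge-shifted) window, evaluated at the target band.
sgOracle <- function(v, window, polyorder) {
  nb <- length(v)
  k <- (window - 1L) / 2L
  out <- numeric(nb)
  for (i in seq_len(nb)) {
    lo <- max(1L, min(i - k, nb - window + 1L))
    idx <- lo:(lo + window - 1L)
    cf <- stats::coef(stats::lm.fit(outer(idx - i, 0:polyorder, "^"), v[idx]))
    out[i] <- cf[1]
  }
  out
}

# Brute-force windowed-sort median oracle with reflected padding.
mfOracle <- function(v, window) {
  k <- (window - 1L) / 2L
  nb <- length(v)
  pv <- c(v[(k + 1L):2L], v, v[(nb - 1L):(nb - k)])
  vapply(seq_len(nb), function(i) {
    w <- sort(pv[i:(i + window - 1L)])
    w[k + 1L]
  }, numeric(1))
}

# Printed germination-test summary of the five aging groups
# (counts of 80, GP/GE in percent, GI, MGT days, VI, SVI).
referenceVigorTable <- function() {
  data.frame(
    row.names = c("A0", "A1", "A2", "A3", "A4"),
    m1 = c(77, 61, 43, 23, 9),   # m1 = GP/100 * 80
    m2 = c(77, 68, 52, 31, 18),
    GP = c(96.25, 76.25, 53.75, 28.75, 11.25),
    GE = c(96.25, 85, 65, 38.75, 22.5),
    GI = c(25.66, 21.20, 15.62, 8.95, 3.17),
    MGT = c(2.78, 3.24, 4.30, 5.74, 7.21),
    VI = c(43.37, 37.52, 24.68, 14.05, 4.82),
    SVI = c(1.63, 1.50, 1.03, 0.61, 0.32)
  )
}
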