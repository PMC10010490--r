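test_that("noise-free generation degenerates to the group mean curves", {
  cfg <- noiseFreeConfig(nPerGroup = 1L)
  sim <- simulateSpectra(cfg)
  m <- spectraMatrix(sim$dataset)
  expect_equal(nrow(m), 5L)
  for (g in 1:5)
    expect_equal(unname(m[g, ]), groupMeanCurve(cfg, g), tolerance = 1e-12)
})

test_that("identical configs give byte-identical datasets", {
  cfg <- smallConfig(rngSeed = 7L)
  a <- simulateSpectra(cfg)
  b <- simulateSpectra(cfg)
  expect_identical(spectraMatrix(a$dataset), spectraMatrix(b$dataset))
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  expect_identical(simulateGermination(cfg), simulateGermination(cfg))
  ca <- simulateCube(cfg)
  cb <- simulateCube(cfg)
  expect_identical(ca$cube@data, cb$cube@data)
  expect_identical(ca$masks, cb$masks)
})

test_that("group mean reflectance increases with aging", {
  # default-noise run, checked at 700 nm over the generator's own output
  sim <- simulateSpectra(simConfig(nPerGroup = 200L, rngSeed = 3L))
  m <- spectraMatrix(sim$dataset)
  b <- which.min(abs(wavelengths(sim$dataset) - 700))
  means <- tapply(m[, b], agingGroup(sim$dataset), mean)
  expect_true(all(diff(means) > 0))

  # with noise off, the ordering holds at every band
  nf <- simulateSpectra(noiseFreeConfig(nPerGroup = 1L))
  mm <- spectraMatrix(nf$dataset)
  expect_true(all(apply(mm, 2, function(col) all(diff(col) > 0))))
})

test_that("generated truth is internally consistent", {
  sim <- simulateSpectra(smallConfig(nPerGroup = 50L, rngSeed = 2L))
  tr <- sim$truth
  expect_equal(nrow(tr), ncol(sim$dataset))
  expect_true(all(tr$gain > 0))
  expect_identical(tr$viable, tr$vigor > 0)
  # SOD decreases with aging on average and A0 sits above 3
  sodm <- tapply(tr$sod, tr$group, mean)
  expect_true(all(diff(sodm) < 0))
  expect_gt(sodm[["A0"]], 3)
  expect_true(all(sodm[c("A1", "A2", "A3", "A4")] < 3))
})

test_that("non-finite config values are rejected", {
  expect_error(simConfig(noiseSd = NaN), "non-finite")
  expect_error(simConfig(germProbByGroup = c(0.9, 0.8, 0.7, 0.6, 1.2)),
               "germProbByGroup")
  expect_error(simConfig(nPerGroup = 0L), "nPerGroup")
  expect_error(simConfig(bogusField = 1), "unknown")
})

test_that("tray cube has disjoint row-major masks recovering the spectra", {
  cfg <- smallConfig(nPerGroup = 4L, rngSeed = 5L)
  cb <- simulateCube(cfg, rows = 4L, cols = 5L)
  expect_length(cb$masks, 20L)
  keys <- lapply(cb$masks, function(px) paste(px[, 1], px[, 2]))
  expect_equal(anyDuplicated(unlist(keys)), 0L)
  # row-major: mask centroids ordered by tray row then column
  cen <- t(vapply(cb$masks, colMeans, numeric(2)))
  trayRow <- rep(1:4, each = 5)
  expect_true(all(diff(cen[, 1]) >= -1e-9))
  expect_true(all(tapply(cen[, 2], trayRow, function(v) all(diff(v) > 0))))

  # mean spectrum over each mask recovers the injected spectrum
  for (i in seq_len(20L)) {
    got <- meanSpectrum(cb$cube, cb$masks[[i]])
    se <- cfg@noiseSd / sqrt(nrow(cb$masks[[i]]))
    expect_lt(max(abs(got - cb$truth$spectrum[i, ])), 6 * se)
  }
})

test_that("noise-free background stays below every seed region", {
  cfg <- noiseFreeConfig(nPerGroup = 4L)
  cb <- simulateCube(cfg, rows = 4L, cols = 5L, background = 0.02)
  seedPx <- do.call(rbind, cb$masks)
  for (b in c(1L, 100L, 256L)) {
    sl <- cb$cube@data[, , b]
    seedMin <- min(sl[seedPx])
    bg <- sl[-(seedPx[, 1] + (seedPx[, 2] - 1) * nrow(sl))]
    expect_true(all(bg <= seedMin))
  }
})

test_that("overfull or overlapping layouts are rejected", {
  cfg <- smallConfig(nPerGroup = 10L)
  expect_error(simulateCube(cfg, rows = 2L, cols = 2L, nSeeds = 5L),
               "capacity")
  expect_error(simulateCube(cfg, cellPx = 8L, radii = c(5, 6)), "overlap")
})

test_that("germination records track the group probabilities", {
  cfg <- simConfig(nPerGroup = 80L, rngSeed = 9L)
  recs <- simulateGermination(cfg)
  expect_named(recs, c("A0", "A1", "A2", "A3", "A4"))
  for (g in 1:5) {
    r <- recs[[g]]
    p <- cfg@germProbByGroup[g]
    ge <- vigorIndices(r)@GE / 100
    # realized GE within the binomial 95% band of the target
    expect_lt(abs(ge - p), 1.96 * sqrt(p * (1 - p) / 80) + 1e-12)
    expect_lte(r@m2, r@M)
    expect_equal(sum(r@Gt), r@m2)
  }
  # later mean germination day for older groups
  mgt <- vapply(recs, function(r) vigorIndices(r)@MGT, numeric(1))
  expect_gt(mgt[["A4"]], mgt[["A0"]])
})

test_that("degenerate germination probabilities give the forced indices", {
  allNow <- simConfig(nPerGroup = 20L, rngSeed = 1L,
                      germProbByGroup = rep(1, 5),
                      meanGermDayByGroup = rep(0.1, 5), germDaySd = 0.2)
  vi <- vigorIndices(simulateGermination(allNow)$A0)
  expect_equal(vi@GP, 100)
  expect_equal(vi@GE, 100)
  expect_equal(vi@GI, 20)
  expect_equal(vi@MGT, 1)

  never <- simConfig(nPerGroup = 20L, rngSeed = 1L,
                     germProbByGroup = rep(0, 5))
  vi0 <- vigorIndices(simulateGermination(never)$A2)
  expect_equal(vi0@GP, 0)
  expect_equal(vi0@GE, 0)
  expect_equal(vi0@GI, 0)
  expect_false(vi0@mgtDefined)
  expect_true(is.na(vi0@MGT))
})

test_that("spectra CSV round-trips", {
  sim <- simulateSpectra(smallConfig(nPerGroup = 3L))
  path <- withr::local_tempfile(fileext = ".csv")
  writeSpectraCSV(sim$dataset, path)
  back <- readSpectraCSV(path)
  expect_equal(spectraMatrix(back), spectraMatrix(sim$dataset),
               tolerance = 1e-12)
  expect_equal(as.character(agingGroup(back)),
               as.character(agingGroup(sim$dataset)))
  expect_equal(sodValues(back), sodValues(sim$dataset), tolerance = 1e-12)
})
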