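wl2 <- c(500, 600)

cubeOf <- function(val, d = c(3, 4, 2), wl = wl2, kind = "raw") {
  hyperCube(array(val, dim = d), wl, kind = kind)
}

test_that("black/white correction satisfies the calibration identities", {
  dark <- cubeOf(0.1)
  white <- cubeOf(0.9)
  expect_equal(blackWhiteCorrect(white, dark, white)@data,
               array(1, c(3, 4, 2)))
  expect_equal(blackWhiteCorrect(dark, dark, white)@data,
               array(0, c(3, 4, 2)))
  mid <- cubeOf(0.5)
  corr <- blackWhiteCorrect(mid, dark, white)
  expect_equal(corr@data, array(0.5, c(3, 4, 2)))
  expect_identical(corr@kind, "corrected")
})

test_that("correction is invariant under affine re-scaling of the counts", {
  set.seed(1)
  s <- hyperCube(array(runif(24, 0.2, 0.8), c(3, 4, 2)), wl2)
  d <- hyperCube(array(runif(24, 0, 0.1), c(3, 4, 2)), wl2)
  w <- hyperCube(array(runif(24, 0.9, 1.1), c(3, 4, 2)), wl2)
  base <- blackWhiteCorrect(s, d, w)
  for (a in c(0.5, 3)) for (b in c(-0.2, 1)) {
    scale <- function(x) hyperCube(a * x@data + b, wl2)
    expect_equal(blackWhiteCorrect(scale(s), scale(d), scale(w))@data,
                 base@data, tolerance = 1e-12)
  }
})

test_that("correction rejects mismatched or degenerate references", {
  s <- cubeOf(0.5)
  expect_error(blackWhiteCorrect(s, cubeOf(0, d = c(2, 4, 2)), cubeOf(1)),
               "shape")
  wrongGrid <- hyperCube(array(0, c(3, 4, 2)), c(500, 700))
  expect_error(blackWhiteCorrect(s, wrongGrid, cubeOf(1)), "grids")
  expect_error(blackWhiteCorrect(s, cubeOf(0.3), cubeOf(0.3)), "zero")
})

test_that("single-line dark/white frames broadcast down the scan axis", {
  s <- cubeOf(0.5)
  dark1 <- hyperCube(array(0.1, c(1, 4, 2)), wl2)
  white1 <- hyperCube(array(0.9, c(1, 4, 2)), wl2)
  expect_equal(blackWhiteCorrect(s, dark1, white1)@data,
               array(0.5, c(3, 4, 2)))
})

test_that("segmentation recovers the generator's masks on a clean tray", {
  cfg <- noiseFreeConfig(nPerGroup = 4L)
  cb <- simulateCube(cfg, rows = 4L, cols = 5L)
  masks <- segmentSeeds(cb$cube, bandNm = 800, threshold = 0.15)
  expect_length(masks, 20L)
  key <- function(px) paste(sort(paste(px[, 1], px[, 2])), collapse = ";")
  expect_identical(vapply(masks, key, character(1)),
                   vapply(cb$masks, key, character(1)))
})

test_that("segmentation reports failure modes", {
  flat <- hyperCube(array(0.02, c(10, 10, 2)), wl2, kind = "corrected")
  expect_error(segmentSeeds(flat, bandNm = 500, threshold = 0.2),
               "no component")
  # a threshold below the background merges everything into one component
  cfg <- noiseFreeConfig(nPerGroup = 4L)
  cb <- simulateCube(cfg, rows = 4L, cols = 5L)
  expect_message(
    merged <- segmentSeeds(cb$cube, bandNm = 800, threshold = 0.001,
                           expected = 20L),
    "expected 20")
  expect_lt(length(merged), 20L)
})

test_that("mean spectrum is the exact per-band mask average", {
  cube <- cubeOf(0.7, kind = "corrected")
  mask <- cbind(c(1, 2), c(1, 1))
  expect_equal(meanSpectrum(cube, mask), c(0.7, 0.7))
  cube@data[1, 1, 1] <- 0.2
  cube@data[2, 1, 1] <- 0.4
  expect_equal(meanSpectrum(cube, mask)[1], 0.3)
  expect_error(meanSpectrum(cube, cbind(99, 1)), "bounds")
})

test_that("mean spectrum is linear in the cube values", {
  set.seed(4)
  a1 <- array(runif(24), c(3, 4, 2)); a2 <- array(runif(24), c(3, 4, 2))
  mask <- cbind(c(1, 2, 3), c(2, 3, 4))
  m1 <- meanSpectrum(hyperCube(a1, wl2), mask)
  m2 <- meanSpectrum(hyperCube(a2, wl2), mask)
  both <- meanSpectrum(hyperCube(2 * a1 + 3 * a2, wl2), mask)
  expect_equal(both, 2 * m1 + 3 * m2, tolerance = 1e-12)
})

test_that("band trimming keeps exactly the in-range bands and is idempotent", {
  sim <- simulateSpectra(smallConfig(nPerGroup = 2L))
  ds <- sim$dataset
  tr <- trimBands(ds)
  wl <- wavelengths(ds)
  expect_equal(length(wavelengths(tr)), sum(wl >= 400 & wl <= 1000))
  expect_true(all(wavelengths(tr) >= 400 & wavelengths(tr) <= 1000))
  expect_equal(wavelengths(trimBands(tr)), wavelengths(tr))
  expect_equal(spectraMatrix(trimBands(tr)), spectraMatrix(tr))
  # a grid already inside the window is untouched
  inside <- spectralSet(matrix(runif(10), 2, 5), seq(500, 900, 100),
                        seedId = c("a", "b"), group = c("A0", "A0"),
                        viable = c(TRUE, TRUE))
  expect_equal(spectraMatrix(trimBands(inside)), spectraMatrix(inside))
  # HyperCube method agrees
  cube <- simulateCube(noiseFreeConfig(nPerGroup = 1L), rows = 1L, cols = 5L,
                       nSeeds = 5L)$cube
  tc <- trimBands(cube)
  expect_equal(wavelengths(tc),
               wavelengths(cube)[wavelengths(cube) >= 400 &
                                 wavelengths(cube) <= 1000])
})

test_that("ENVI cubes round-trip through the BSQ writer", {
  cfg <- smallConfig(nPerGroup = 1L,
                     wavelengths = seq(400, 1000, length.out = 12))
  cube <- simulateCube(cfg, rows = 1L, cols = 5L, nSeeds = 5L)$cube
  path <- withr::local_tempfile()
  writeENVI(cube, path)
  back <- readENVI(path)
  expect_equal(back@wavelengths, cube@wavelengths, tolerance = 1e-6)
  expect_equal(back@data, cube@data, tolerance = 1e-6)  # float32 storage
  expect_true(file.exists(paste0(path, ".hdr")))
})

test_that("the ENVI reader handles BIL interleave", {
  arr <- array(seq_len(2 * 3 * 2) / 10, c(2, 3, 2))
  path <- withr::local_tempfile()
  con <- file(path, "wb")
  for (l in 1:2) for (b in 1:2)
    writeBin(as.numeric(arr[l, , b]), con, size = 4, endian = "little")
  close(con)
  writeLines(c("ENVI", "samples = 3", "lines = 2", "bands = 2",
               "data type = 4", "interleave = bil", "byte order = 0",
               "wavelength = { 500, 600 }"), paste0(path, ".hdr"))
  back <- readENVI(path)
  expect_equal(back@data, arr, tolerance = 1e-6)
})
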