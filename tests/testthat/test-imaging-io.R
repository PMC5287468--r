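test_that("MRC mode-2 write/read round trip preserves pixels and pixel size", {
  m <- renderPorePatch(largeModel(), patchRadius = 26, noiseSigma = 0.05,
                       seed = 3)
  path <- file.path(tempdir(), "rt.mrc")
  writeMicrograph(m, path)
  back <- readMicrograph(path)
  # float32 storage: identical to single precision
  expect_equal(pixels(back), pixels(m), tolerance = 1e-6)
  expect_equal(pixelSize(back), 0.69, tolerance = 1e-6)
  unlink(c(path, paste0(path, ".json")))
})

test_that("16-bit TIFF round trip restores the intensity scale and is idempotent", {
  m <- renderPorePatch(largeModel(), patchRadius = 26, noiseSigma = 0.05,
                       seed = 4)
  path <- file.path(tempdir(), "rt.tif")
  writeMicrograph(m, path)
  once <- readMicrograph(path)
  # quantization error bounded by one 16-bit step of the intensity range
  step <- diff(range(pixels(m))) / 65535
  expect_lt(max(abs(pixels(once) - pixels(m))), step)
  expect_equal(pixelSize(once), 0.69)
  # a second write/read cycle is stable to within one quantization step
  path2 <- file.path(tempdir(), "rt2.tif")
  writeMicrograph(once, path2)
  twice <- readMicrograph(path2)
  expect_lt(max(abs(pixels(twice) - pixels(once))), 1.01 * step)
  unlink(c(path, path2, paste0(c(path, path2), ".json")))
})

test_that("missing pixel size and unknown formats raise distinct errors", {
  m <- Micrograph(matrix(rnorm(400), 20), 0.69)
  path <- file.path(tempdir(), "nosidecar.tif")
  tiff::writeTIFF(matrix(0.5, 20, 20), path, bits.per.sample = 16L)
  expect_error(readMicrograph(path), "pixel size unavailable")
  expect_equal(pixelSize(readMicrograph(path, pixelSizeOverride = 1.2)), 1.2)
  expect_error(writeMicrograph(m, file.path(tempdir(), "x.png")),
               "unknown output format")
  expect_error(readMicrograph(path = file.path(tempdir(), "missing.mrc")),
               "not found")
  unlink(path)
})

test_that("extractPatch obeys the side formula and border contract", {
  m <- Micrograph(matrix(rnorm(300 * 300), 300), 0.69)
  p <- extractPatch(m, centerNm = c(100, 100), radiusNm = 25)
  expect_identical(dim(pixels(p)), rep(as.integer(2 * ceiling(25 / 0.69) + 1), 2L))
  expect_identical(nrow(pixels(p)) %% 2L, 1L)
  expect_error(extractPatch(m, centerNm = c(3, 100), radiusNm = 25),
               "crosses the image border")
})

test_that("extractPatch is translation-consistent for integer-pixel shifts", {
  m <- Micrograph(matrix(rnorm(200 * 200), 200), 0.69)
  a <- extractPatch(m, centerNm = c(60, 60), radiusNm = 15)
  b <- extractPatch(m, centerNm = c(60 + 5 * 0.69, 60 - 3 * 0.69), radiusNm = 15)
  side <- nrow(pixels(a))
  expect_identical(pixels(a)[1:(side - 3), 6:side],
                   pixels(b)[4:side, 1:(side - 5)])
})

test_that("a patch of a rendered pore carries the true centre at its centre pixel", {
  sc <- smallScene(density = 30, seed = 14, widthNm = 500, noiseSigma = 0)
  out <- renderSheet(sc)
  tr <- poreTruth(out$truth)
  p <- extractPatch(out$micrograph, c(tr$x_nm[1], tr$y_nm[1]), 25)
  px <- pixels(p)
  ctr <- (nrow(px) + 1L) %/% 2L
  win <- px[(ctr - 2):(ctr + 2), (ctr - 2):(ctr + 2)]
  at <- arrayInd(which.min(win), dim(win))   # plug is the darkest point
  expect_lte(max(abs(at - 3L)), 1L)
})

test_that("bandpass filter has the stated feature-size transfer behaviour", {
  n <- 200L
  mkSine <- function(wavelength) {
    Micrograph(0.5 + 0.2 * sin(outer(rep(0, n), 2 * pi * (1:n) / wavelength, "+")),
               1)
  }
  amp <- function(m) (max(pixels(m)) - min(pixels(m))) / 2
  s10 <- mkSine(10)
  f10 <- bandpassFilter(s10, 40, 3)
  expect_gt(amp(f10) / amp(s10), 0.8)        # 10 px structure passes
  s100 <- mkSine(100)
  f100 <- bandpassFilter(s100, 40, 3)
  expect_lt(amp(f100) / amp(s100), 0.2)      # 100 px structure suppressed
  # DC preservation
  const <- Micrograph(matrix(0.7, 64, 64), 1)
  fc <- bandpassFilter(const)
  expect_equal(pixels(fc), pixels(const), tolerance = 1e-10)
  expect_equal(mean(pixels(f10)), mean(pixels(s10)), tolerance = 1e-10)
  expect_error(bandpassFilter(s10, 3, 40), "cutoffs")
})

test_that("median denoise removes isolated impulses", {
  px <- matrix(0.5, 40, 40)
  px[20, 20] <- 5
  m <- medianDenoise(Micrograph(px, 0.69), radiusPx = 1L)
  expect_lt(abs(pixels(m)[20, 20] - 0.5), 1e-6)
})

test_that("ground-truth and detection tables round trip through CSV", {
  sc <- smallScene(density = 40, seed = 19, widthNm = 500)
  out <- renderSheet(sc)
  truth <- placeGold(out$truth, sc, 0.8, 20, 25, seed = 2)
  pp <- file.path(tempdir(), "pores.csv")
  gp <- file.path(tempdir(), "gold.csv")
  writeGroundTruth(truth, pp, gp)
  back <- readGroundTruth(pp, gp)
  expect_equal(poreTruth(back), poreTruth(truth), tolerance = 1e-12)
  expect_equal(goldTruth(back), goldTruth(truth), tolerance = 1e-12)
  unlink(c(pp, gp))
})
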