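test_that("tilt estimation matches the foreshortening geometry", {
  # untilted: axis ratio 1 within 0.01
  p0 <- renderPorePatch(largeModel(), patchRadius = 26, noiseSigma = 0)
  t0 <- estimateTilt(p0, ridgeRadiusNm = 16.75)
  expect_gt(t0@axisRatio, 0.99)
  # 10-degree tilt: ratio ~ cos(10 deg) within 0.01
  p10 <- renderPorePatch(largeModel(tiltDeg = 10, tiltAxisDeg = 40),
                         patchRadius = 26, noiseSigma = 0)
  t10 <- estimateTilt(p10, 16.75)
  expect_lt(abs(t10@axisRatio - cos(10 * pi / 180)), 0.01)
  # 8-degree tilt (within the observed regime): recovered within 2 degrees
  p8 <- renderPorePatch(largeModel(tiltDeg = 8, tiltAxisDeg = 120),
                        patchRadius = 26, noiseSigma = 0)
  t8 <- estimateTilt(p8, 16.75)
  expect_lt(abs(t8@tiltDeg - 8), 2)
  expect_false(t8@highTilt)
})

test_that("tilt estimation requires ridge contrast", {
  expect_error(estimateTilt(Micrograph(matrix(0.5, 41, 41), 0.69), 10),
               "no ridge pixels")
})

test_that("de-ellipsing restores circularity and is the identity when circular", {
  p0 <- renderPorePatch(largeModel(), patchRadius = 26, noiseSigma = 0)
  t1 <- new("TiltEstimate", axisRatio = 1, tiltDeg = 0, orientationDeg = 0,
            highTilt = FALSE)
  expect_identical(pixels(deellipse(p0, t1)), pixels(p0))
  p10 <- renderPorePatch(largeModel(tiltDeg = 10, tiltAxisDeg = 40),
                         patchRadius = 26, noiseSigma = 0)
  est <- estimateTilt(p10, 16.75)
  corrected <- deellipse(p10, est)
  expect_gte(estimateTilt(corrected, 16.75)@axisRatio, 0.99)
  bad <- new("TiltEstimate", axisRatio = 0.4, tiltDeg = 66, orientationDeg = 0,
             highTilt = TRUE)
  expect_error(deellipse(p10, bad), "extreme ellipticity")
})

test_that("symmetry of a tilted pore is recovered after tilt correction", {
  p8 <- renderPorePatch(largeModel(tiltDeg = 8, tiltAxisDeg = 70),
                        patchRadius = 26,
                        noiseSigma = noiseFor(largeModel(), 5), seed = 17)
  est <- estimateTilt(p8, 16.75)
  corrected <- deellipse(p8, est)
  scT <- assessSymmetry(corrected, seed = 3)
  p0 <- renderPorePatch(largeModel(), patchRadius = 26,
                        noiseSigma = noiseFor(largeModel(), 5), seed = 17)
  sc0 <- assessSymmetry(p0, seed = 3)
  expect_identical(selectedOrder(scT), selectedOrder(sc0))
  expect_identical(selectedOrder(scT), 8L)
})

test_that("Markham superposition is the identity for n = 1 and for circular input", {
  p <- renderPorePatch(largeModel(), patchRadius = 26, noiseSigma = 0.05,
                       seed = 2)
  expect_identical(pixels(markhamSuperposition(p, 1L)), pixels(p))
  ctr <- poreSym:::patchCenterNm(p)
  expect_error(markhamSuperposition(p, 4L), "centerNm is required")
  # circularly symmetric input: superposition equals input within interpolation
  circ <- renderPorePatch(PoreModel(subunitAmplitude = 0), patchRadius = 26,
                          noiseSigma = 0)
  c0 <- poreSym:::patchCenterNm(circ)
  for (n in c(2L, 5L, 8L)) {
    sup <- markhamSuperposition(circ, n, c0)
    expect_lt(max(abs(pixels(sup) - pixels(circ))), 0.02)
  }
})

test_that("stored rotation increments are 360/n and display as 45.0 and 51.4", {
  p <- renderPorePatch(largeModel(), patchRadius = 26,
                       noiseSigma = noiseFor(largeModel(), 3), seed = 1)
  sc <- assessSymmetry(p, seed = 1)
  expect_identical(sc@incrementsDeg, 360 / sc@orders)
  shown <- sprintf("%.1f", sc@incrementsDeg[sc@orders %in% c(8L, 7L)])
  expect_identical(shown, c("51.4", "45.0"))
})

test_that("reinforcement is maximal at the true order with tied divisors", {
  p <- renderPorePatch(largeModel(nFold = 8L), patchRadius = 26, noiseSigma = 0)
  ctr <- refineCenter(p)$centerNm
  band <- c(0.25 * 9.5, 0.55 * 33.5)
  ss <- vapply(2:12, function(n)
    reinforcementScore(p, n, ctr, band)$score, numeric(1))
  names(ss) <- 2:12
  expect_identical(names(which.max(ss)) %in% c("2", "4", "8"), TRUE)
  # divisor orders tie near the maximum; non-divisors fall far below
  expect_lt(max(ss) - min(ss[c("2", "4", "8")]), 0.05)
  expect_lt(max(ss[c("3", "5", "7")]), max(ss) - 0.5)
})

test_that("pure-noise reinforcement stays within two control s.d.", {
  set.seed(11)
  p <- Micrograph(matrix(rnorm(73 * 73), 73), 0.69)
  ctr <- c(36 * 0.69, 36 * 0.69)
  rs <- reinforcementScore(p, 8L, ctr, c(2, 22), mControls = 99L, seed = 5)
  expect_lt(abs(rs$score - rs$control$mean), 2 * rs$control$sd)
})

test_that("8-fold beats 7-fold at SNR 3 on the default pore", {
  p <- renderPorePatch(largeModel(), patchRadius = 26,
                       noiseSigma = noiseFor(largeModel(), 3), seed = 42)
  ctr <- refineCenter(p)$centerNm
  band <- c(0.25 * 9.5, 0.55 * 33.5)
  s8 <- reinforcementScore(p, 8L, ctr, band)$score
  s7 <- reinforcementScore(p, 7L, ctr, band)$score
  expect_gt(s8, s7)
})

test_that("angular power spectrum finds the modulation harmonic", {
  p <- renderPorePatch(largeModel(nFold = 8L), patchRadius = 26, noiseSigma = 0)
  ctr <- poreSym:::patchCenterNm(p)
  sp <- angularPowerSpectrum(p, ctr, c(0.85, 1.15) * 16.75)
  expect_identical(sp$dominant, 8L)
  p6 <- renderPorePatch(largeModel(nFold = 6L), patchRadius = 26,
                        noiseSigma = 0.02, seed = 3)
  sp6 <- angularPowerSpectrum(p6, poreSym:::patchCenterNm(p6),
                              c(0.85, 1.15) * 16.75)
  expect_identical(sp6$dominant, 6L)
  # unmodulated ring: the angular profile carries no meaningful variance,
  # so no harmonic can dominate (pixelization residues are < 1 percent)
  pc <- renderPorePatch(PoreModel(subunitAmplitude = 0), patchRadius = 26,
                        noiseSigma = 0)
  spc <- angularPowerSpectrum(pc, poreSym:::patchCenterNm(pc),
                              c(0.85, 1.15) * 16.75)
  expect_lt(spc$angularVarFraction, 0.01)
  sp8 <- angularPowerSpectrum(p, ctr, c(0.85, 1.15) * 16.75)
  expect_gt(sp8$angularVarFraction, 0.05)
  expect_error(angularPowerSpectrum(p, ctr, c(0.85, 1.15) * 16.75, nBins = 20),
               "nBins")
})

test_that("symmetry scan selects the generator order and matches the spectrum", {
  p5 <- renderPorePatch(largeModel(nFold = 5L), patchRadius = 26,
                        noiseSigma = noiseFor(largeModel(), 5), seed = 23)
  sc5 <- assessSymmetry(p5, seed = 4)
  expect_identical(selectedOrder(sc5), 5L)
  expect_identical(sc5@spectrumHarmonic, 5L)
  # circular pore: no order is selected
  pc <- renderPorePatch(PoreModel(subunitAmplitude = 0), patchRadius = 26,
                        noiseSigma = 0)
  expect_true(is.na(selectedOrder(assessSymmetry(pc, seed = 5))))
})

test_that("symmetry analysis warns on bandpass-filtered input", {
  p <- renderPorePatch(largeModel(), patchRadius = 26,
                       noiseSigma = noiseFor(largeModel(), 3), seed = 8)
  filtered <- bandpassFilter(p)
  expect_warning(assessSymmetry(filtered, seed = 2), "raw data")
})
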