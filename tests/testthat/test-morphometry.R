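test_that("centre refinement recovers known sub-pixel offsets", {
  # already centred
  p0 <- renderPorePatch(largeModel(), patchRadius = 26, noiseSigma = 0)
  rc0 <- refineCenter(p0)
  expect_lt(max(abs(rc0$offsetPx)), 0.5)
  # shifted by (+3, -2) pixels
  p1 <- renderPorePatch(largeModel(), patchRadius = 26, noiseSigma = 0,
                        centerOffsetNm = c(3 * 0.69, -2 * 0.69))
  rc1 <- refineCenter(p1)
  expect_lt(abs(rc1$offsetPx[["x"]] - 3), 0.5)
  expect_lt(abs(rc1$offsetPx[["y"]] + 2), 0.5)
})

test_that("centre refinement agrees with an exhaustive 180-degree search", {
  p <- renderPorePatch(largeModel(), patchRadius = 26, noiseSigma = 0.08,
                       seed = 5, centerOffsetNm = c(2 * 0.69, 1 * 0.69))
  px <- pixels(p) - mean(pixels(p))
  n <- nrow(px)
  # brute-force oracle: integer displacement maximizing sum(P(x+d) * P(2g-x))
  best <- c(NA, NA); bestV <- -Inf
  Q <- px[n:1, n:1]
  for (dr in -6:6) for (dc in -6:6) {
    rows <- max(1, 1 + dr):min(n, n + dr)
    cols <- max(1, 1 + dc):min(n, n + dc)
    v <- sum(px[rows, cols] * Q[rows - dr, cols - dc])
    if (v > bestV) { bestV <- v; best <- c(dr, dc) }
  }
  rc <- refineCenter(p)
  expect_lt(abs(rc$offsetPx[["y"]] - best[1] / 2), 1)
  expect_lt(abs(rc$offsetPx[["x"]] - best[2] / 2), 1)
})

test_that("flat patches cannot be centre-refined", {
  expect_error(refineCenter(Micrograph(matrix(1, 31, 31), 0.69)), "flat patch")
})

test_that("radial profile is constant on uniform input and peaks on a delta ring", {
  u <- radialProfile(Micrograph(matrix(2.5, 41, 41), 1))
  expect_lt(diff(range(u@intensity)), 1e-12)
  # synthetic ring at radius 10 px
  n <- 41L
  d <- sqrt(outer((1:n - 21)^2, (1:n - 21)^2, "+"))
  ring <- Micrograph(exp(-(d - 10)^2 / 2), 1)
  prof <- radialProfile(ring)
  expect_equal(which.max(prof@intensity), 11L)   # bin centred at 10.5 px
  expect_error(radialProfile(ring, centerNm = c(100, 100)), "outside")
  expect_error(radialProfile(ring, binWidth = 0.2), "binWidth")
})

test_that("noiseless default pore measures all three diameters within a bin", {
  p <- renderPorePatch(largeModel(), patchRadius = 26, noiseSigma = 0)
  m <- measurePore(p)$measurement
  expect_length(m@flags, 0L)
  expect_lt(abs(m@dOuter - 33.5), 0.69)
  expect_lt(abs(m@dInner - 17.5), 0.69)
  expect_lt(abs(m@dPlug - 9.5), 0.69)
  expect_true(m@dPlug < m@dInner && m@dInner < m@dOuter)
})

test_that("a pore rendered without an outer ring is flagged, not guessed", {
  mdl <- largeModel(contrastOuter = 0)
  p <- renderPorePatch(mdl, patchRadius = 26, noiseSigma = 0)
  m <- measureRings(radialProfile(p))
  expect_true(is.na(m@dOuter))
  expect_true("outer_missing" %in% m@flags)
  expect_false(is.na(m@dPlug))
})

test_that("measurements are invariant to patch rotation within a bin width", {
  p <- renderPorePatch(largeModel(), patchRadius = 26, noiseSigma = 0)
  m0 <- measurePore(p, deEllipse = FALSE)$measurement
  px <- pixels(p)
  ctr <- c((nrow(px) + 1) / 2, (ncol(px) + 1) / 2)
  for (ang in c(33, 118)) {
    rot <- poreSym:::rotateAbout(px, ang, ctr, fill = median(px))
    m1 <- measurePore(Micrograph(rot, 0.69), deEllipse = FALSE)$measurement
    expect_lt(abs(m1@dOuter - m0@dOuter), 0.69)
    expect_lt(abs(m1@dInner - m0@dInner), 0.69)
    expect_lt(abs(m1@dPlug - m0@dPlug), 0.69)
  }
})

test_that("diameter bias vanishes as the noise vanishes", {
  mdl <- largeModel()
  biasAt <- function(snr, nrep) {
    noise <- if (is.finite(snr)) noiseFor(mdl, snr) else 0
    est <- vapply(seq_len(nrep), function(i) {
      p <- renderPorePatch(mdl, patchRadius = 26, noiseSigma = noise,
                           seed = 1000 + i)
      measurePore(p, deEllipse = FALSE)$measurement@dOuter
    }, numeric(1))
    abs(mean(est, na.rm = TRUE) - 33.5)
  }
  b <- c(inf = biasAt(Inf, 1), s10 = biasAt(10, 15), s5 = biasAt(5, 15),
         s2 = biasAt(2, 15))
  # noiseless bias is smallest; noisy biases do not undercut it meaningfully
  expect_lte(b[["inf"]], b[["s10"]] + 0.05)
  expect_lte(b[["inf"]], b[["s2"]] + 0.05)
  expect_lt(b[["inf"]], 0.35)
  # heavy noise does not explode the estimate either
  expect_lt(b[["s2"]], 2)
})

test_that("ring measurement reports ordered diameters or an explicit flag", {
  set.seed(5)
  for (i in 1:10) {
    p <- renderPorePatch(largeModel(), patchRadius = 26,
                         noiseSigma = noiseFor(largeModel(), 5),
                         seed = sample.int(1e6, 1))
    m <- measurePore(p)$measurement
    d <- c(m@dPlug, m@dInner, m@dOuter)
    if (all(is.finite(d)) && !"order_violation" %in% m@flags)
      expect_true(d[1] < d[2] && d[2] < d[3])
  }
})
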