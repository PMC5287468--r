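test_that("membrane mask recovers the sheet area on an elliptical scene", {
  sc <- SheetScene(widthNm = 800, heightNm = 600, maskType = "ellipse",
                   density = 40, minSeparation = 40, seed = 6,
                   noiseSigma = 0.08)
  out <- renderSheet(sc)
  mask <- makeMembraneMask(out$micrograph)
  truthArea <- maskArea(sceneMask(sc))
  expect_lt(abs(maskArea(mask) - truthArea) / truthArea, 0.05)
})

test_that("membrane mask rejects uniform images", {
  expect_error(makeMembraneMask(Micrograph(matrix(0.5, 64, 64), 0.69)),
               "uniform image")
})

test_that("scene mask of a 2 x 2 um full-frame sheet has 4 square microns", {
  sc <- SheetScene(widthNm = 2000, heightNm = 2000, density = 10,
                   minSeparation = 40, seed = 1)
  expect_equal(maskArea(sceneMask(sc)), 4, tolerance = 0.01)
})

test_that("a single noiseless pore is detected at its centre and ridge radius", {
  p <- renderPorePatch(largeModel(), patchRadius = 50, noiseSigma = 0)
  dt <- detectPores(p)
  det <- detections(dt)
  expect_identical(nrow(det), 1L)
  truth <- poreSym:::patchCenterNm(p)
  expect_lt(abs(det$x_nm - truth[1]), 0.69)
  expect_lt(abs(det$y_nm - truth[2]), 0.69)
  expect_lte(abs(det$ridge_radius_nm - 33.5 / 2), 2)   # one grid step
})

test_that("pure noise yields no detections at the default threshold", {
  set.seed(42)
  m <- Micrograph(matrix(rnorm(400 * 400, mean = 0.5, sd = 0.08), 400), 0.69)
  dt <- detectPores(m)
  expect_identical(nrow(detections(dt)), 0L)
})

test_that("detection is invariant to affine intensity rescaling", {
  sc <- smallScene(density = 60, seed = 9, widthNm = 600)
  out <- renderSheet(sc)
  dt1 <- detectPores(out$micrograph)
  rescaled <- Micrograph(3.7 * pixels(out$micrograph) + 11, 0.69)
  dt2 <- detectPores(rescaled)
  expect_equal(detections(dt1)[, c("x_nm", "y_nm", "ridge_radius_nm")],
               detections(dt2)[, c("x_nm", "y_nm", "ridge_radius_nm")],
               tolerance = 1e-6)
})

test_that("detection recovers a dense SNR-5 sheet with high recall and precision", {
  sc <- smallScene(density = 200, seed = 13, widthNm = 800, minSeparation = 35)
  out <- renderSheet(sc)
  mask <- makeMembraneMask(out$micrograph)
  dt <- detectPores(out$micrograph, mask)
  tr <- poreTruth(out$truth)
  de <- detections(dt)
  matched <- matchDetections(tr, de, matchNm = 20)
  expect_gte(matched / nrow(tr), 0.9)
  expect_gte(matched / nrow(de), 0.9)
})

test_that("non-maximum suppression respects the minimum separation", {
  set.seed(7)
  for (i in 1:4) {
    sc <- SheetScene(widthNm = 600, heightNm = 600,
                     density = runif(1, 50, 150), minSeparation = 40,
                     seed = sample.int(1e6, 1))
    dt <- detectPores(renderSheet(sc)$micrograph,
                      minSeparation = 30)
    de <- detections(dt)
    if (nrow(de) > 1L) {
      D <- as.matrix(dist(de[, c("x_nm", "y_nm")]))
      diag(D) <- Inf
      expect_gte(min(D), 30)
    }
  }
})

test_that("detection guards its preconditions", {
  m <- Micrograph(matrix(rnorm(10000, 0.5, 0.05), 100), 0.69)
  expect_error(detectPores(m, radiusGrid = numeric()), "radius grid")
  expect_error(detectPores(m, minSeparation = 0), "minSeparation")
})

test_that("density estimate is count over area with a Poisson interval", {
  det <- data.frame(detection_id = 1:10,
                    x_nm = seq(0, 900, by = 100), y_nm = seq(0, 900, by = 100),
                    ridge_radius_nm = 16, score = rep(0.8, 10),
                    edge_flag = FALSE)
  dt <- new("DetectionTable", detections = det,
            params = list(minSeparation = 50), maskAreaUm2 = 0.1)
  d <- estimateDensity(dt)
  expect_equal(d$density, 100)
  expect_equal(d$lower, (10 - 1.96 * sqrt(10)) / 0.1)
  expect_equal(d$upper, (10 + 1.96 * sqrt(10)) / 0.1)
  # zero detections
  dt0 <- new("DetectionTable", detections = det[0, ], params = list(),
             maskAreaUm2 = 0.5)
  expect_equal(estimateDensity(dt0)$density, 0)
})

test_that("density is estimated without bias on clean scenes", {
  ests <- vapply(1:6, function(s) {
    sc <- SheetScene(widthNm = 700, heightNm = 700, density = 87,
                     minSeparation = 40, seed = 100 + s, noiseSigma = 0)
    out <- renderSheet(sc)
    estimateDensity(detectPores(out$micrograph))$density
  }, numeric(1))
  expect_lt(abs(mean(ests) - 87) / 87, 0.05)
})
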