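#' @include AllClasses.R
NULL

# band pixel selection: linear indices of pixels whose radius from centerNm
# lies in [band[1], band[2]] (nm), plus the per-pixel radii and angles.
bandPixels <- function(patch, centerNm, bandNm) {
  ps <- patch@pixelSize
  P <- patch@pixels
  nr <- nrow(P); nc <- ncol(P)
  dx <- rep((seq_len(nc) - 1) * ps - centerNm[1], each = nr)
  dy <- rep((seq_len(nr) - 1) * ps - centerNm[2], times = nc)
  r <- sqrt(dx^2 + dy^2)
  idx <- which(r >= bandNm[1] & r <= bandNm[2])
  if (!length(idx)) stop("degenerate band: no pixels in the radial band")
  list(idx = idx, r = r, theta = atan2(dy, dx))
}

# azimuthal residual: patch minus its radial (rotational) average, computed in
# one-pixel radial bins about centerNm; zero outside the patch's inscribed
# support. Rotations of this residual isolate the angular structure that the
# reinforcement statistic measures.
azimuthalResidual <- function(patch, centerNm) {
  ps <- patch@pixelSize
  P <- patch@pixels
  nr <- nrow(P); nc <- ncol(P)
  dx <- rep((seq_len(nc) - 1) * ps - centerNm[1], each = nr)
  dy <- rep((seq_len(nr) - 1) * ps - centerNm[2], times = nc)
  r <- sqrt(dx^2 + dy^2)
  bin <- floor(r / ps) + 1L
  nb <- max(bin)
  counts <- tabulate(bin, nbins = nb)
  sums <- rep(0, nb)
  agg <- rowsum(as.vector(P), bin)
  sums[as.integer(rownames(agg))] <- agg
  means <- ifelse(counts > 0L, sums / pmax(counts, 1L), 0)
  matrix(as.vector(P) - means[bin], nr, nc)
}

# Shared preparation for the reinforcement statistic. The azimuthal residual
# is lightly smoothed (sigma = smoothSigmaPx) so that grid-locked
# pixelization artifacts are suppressed, and the reference copy is rotated by
# a fixed dither angle so that reference and candidate rotations go through
# exactly one bilinear resampling each: without the dither, 90/180-degree
# rotations are exact on the pixel grid while all other angles lose
# correlation to interpolation, which would bias divisor-order comparisons.
# azFraction is the share of the band variance carried by azimuthal
# (non-radial) structure; when it falls below a small floor the patch is
# treated as circularly symmetric and every score is 0. neff approximates the
# number of independent samples in the smoothed band (pixels per
# smoothing-correlation area) and feeds a parametric null floor for
# correlation significance.
prepareAzimuthal <- function(patch, centerNm, bandNm, smoothSigmaPx = 1,
                             azFractionMin = 0.01, ditherDeg = 14.142) {
  res <- azimuthalResidual(patch, centerNm)
  if (smoothSigmaPx > 0) res <- gaussianBlur(res, smoothSigmaPx)
  bp <- bandPixels(patch, centerNm, bandNm)
  ctrPx <- nmToPx(centerNm, patch@pixelSize)
  ref <- rotateAbout(res, ditherDeg, ctrPx, fill = 0)
  v0 <- ref[bp$idx]
  bandVals <- patch@pixels[bp$idx]
  totVar <- stats::var(bandVals)
  azFraction <- if (totVar > 0) stats::var(res[bp$idx]) / totVar else 0
  degenerate <- totVar < 1e-24 || azFraction < azFractionMin
  neff <- max(length(bp$idx) / (1 + 4 * pi * smoothSigmaPx^2), 8)
  list(res = res, idx = bp$idx, v0 = v0, degenerate = degenerate,
       azFraction = azFraction, neff = neff,
       seNull = 1 / sqrt(neff - 3), ditherDeg = ditherDeg,
       ctrPx = ctrPx)
}

# random control angles, uniform in (0, 360) but excluding neighbourhoods of
# angles commensurate with any candidate order (multiples of 360/n, n <= nMax)
controlAngles <- function(m, nMax = 12L, excludeDeg = 1.5, seed = NULL) {
  commensurate <- unique(unlist(lapply(seq_len(nMax), function(n)
    (360 / n) * seq_len(n - 1L))))
  withSeed(seed, {
    out <- numeric(0)
    while (length(out) < m) {
      a <- stats::runif(2L * m, 0, 360)
      dist <- vapply(a, function(x) min(abs(c(x, x - 360, commensurate - x))),
                     numeric(1))
      out <- c(out, a[dist > excludeDeg])
    }
    out[seq_len(m)]
  })
}

#' Estimate tilt foreshortening from ring ellipticity
#'
#' Fits an ellipse to the outer-ring ridge by the second moments of the
#' ridge-band pixels, weighted by contrast polarity (darker-than-band-median
#' pixels carry weight for an electron-dense ring). The minor/major axis
#' ratio gives the implied membrane tilt, \code{acos(ratio)}. The patch is
#' lightly smoothed before the moment fit: near-circular rings make the tilt
#' angle ill-conditioned, and unsmoothed noise otherwise inflates the
#' apparent ellipticity. The \code{highTilt} flag marks estimates above 10
#' degrees, outside the regime the foreshortening model is intended for.
#'
#' @param patch a \linkS4class{Micrograph}.
#' @param ridgeRadiusNm outer-ring ridge radius (nm).
#' @param centerNm ring centre (x, y) in nm; default: geometric patch centre.
#' @param polarity -1 for a dark ridge, +1 for a bright ridge.
#' @param band radial band searched, as multiples of \code{ridgeRadiusNm}.
#' @param smoothSigmaPx Gaussian smoothing applied before the moment fit
#'   (pixels; 0 disables).
#' @return A \linkS4class{TiltEstimate}.
#' @export
estimateTilt <- function(patch, ridgeRadiusNm, centerNm = NULL, polarity = -1,
                         band = c(0.7, 1.3), smoothSigmaPx = 1) {
  stopifnot(is(patch, "Micrograph"))
  if (is.null(centerNm)) centerNm <- patchCenterNm(patch)
  bp <- bandPixels(patch, centerNm, band * ridgeRadiusNm)
  smoothed <- if (smoothSigmaPx > 0) gaussianBlur(patch@pixels, smoothSigmaPx)
              else patch@pixels
  vals <- smoothed[bp$idx]
  w <- pmax(0, polarity * (vals - stats::median(vals)))
  if (sum(w) <= 0) stop("no ridge pixels: the band carries no contrast of the stated polarity")
  ps <- patch@pixelSize
  dxv <- (ceiling(bp$idx / nrow(patch@pixels)) - 1) * ps - centerNm[1]
  dyv <- ((bp$idx - 1) %% nrow(patch@pixels)) * ps - centerNm[2]
  mx <- sum(w * dxv) / sum(w); my <- sum(w * dyv) / sum(w)
  cxx <- sum(w * (dxv - mx)^2) / sum(w)
  cyy <- sum(w * (dyv - my)^2) / sum(w)
  cxy <- sum(w * (dxv - mx) * (dyv - my)) / sum(w)
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2L, 2L), symmetric = TRUE)
  ratio <- sqrt(max(ev$values[2], 0) / ev$values[1])
  ratio <- min(ratio, 1)
  v1 <- ev$vectors[, 1]
  orient <- (atan2(v1[2], v1[1]) * 180 / pi) %% 180
  tilt <- acos(ratio) * 180 / pi
  new("TiltEstimate", axisRatio = ratio, tiltDeg = tilt,
      orientationDeg = orient, highTilt = tilt > 10)
}

#' Correct tilt foreshortening by an inverse affine stretch
#'
#' Resamples the patch so the minor axis is stretched by the inverse axis
#' ratio, undoing the in-plane compression produced by a tilted membrane.
#' Axis ratios of 0.5 or below are rejected as outside the small-tilt model.
#'
#' @param patch a \linkS4class{Micrograph}.
#' @param tilt a \linkS4class{TiltEstimate}.
#' @param centerNm stretch centre; default: geometric patch centre.
#' @return The corrected \linkS4class{Micrograph}; re-estimating the tilt on
#'   the result yields an axis ratio of at least 0.99 for well-formed rings.
#' @export
deellipse <- function(patch, tilt, centerNm = NULL) {
  stopifnot(is(patch, "Micrograph"), is(tilt, "TiltEstimate"))
  if (tilt@axisRatio <= 0.5)
    stop("extreme ellipticity (axis ratio <= 0.5): outside the foreshortening model")
  if (tilt@axisRatio >= 1) return(patch)
  if (is.null(centerNm)) centerNm <- patchCenterNm(patch)
  ps <- patch@pixelSize
  a <- tilt@orientationDeg * pi / 180
  # major/minor unit vectors in (row, col) = (y, x) space
  maj <- c(sin(a), cos(a))
  mnr <- c(cos(a), -sin(a))
  A <- maj %o% maj + tilt@axisRatio * (mnr %o% mnr)
  ctrPx <- nmToPx(centerNm, ps)
  out <- resampleAffine(patch@pixels, A, ctrPx, fill = stats::median(patch@pixels))
  Micrograph(out, ps,
             provenance = c(patch@provenance,
                            sprintf("deellipse(ratio=%.4f, axis=%.1f)",
                                    tilt@axisRatio, tilt@orientationDeg)),
             meta = patch@meta)
}

#' Markham rotational superposition
#'
#' Pixelwise mean of the patch rotated by k * (360/n) degrees, k = 0..n-1,
#' about the refined centre (bilinear interpolation). For n = 1 the input is
#' returned unchanged. Pixels outside the inscribed circular support are set
#' to the patch median. True n-fold features reinforce in the superposition
#' while uncorrelated structure averages out. Must be applied to raw patches:
#' bandpass-filtered input triggers a warning.
#'
#' @param patch a \linkS4class{Micrograph}.
#' @param n assumed rotational order (>= 1).
#' @param centerNm refined rotation centre (x, y) in nm; required for n > 1.
#' @return The superimposed \linkS4class{Micrograph}.
#' @export
markhamSuperposition <- function(patch, n, centerNm = NULL) {
  stopifnot(is(patch, "Micrograph"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (n == 1L) return(patch)
  if (is.null(centerNm))
    stop("centerNm is required: refine the pore centre before superposition")
  warnIfFiltered(patch)
  ps <- patch@pixelSize
  P <- patch@pixels
  ctrPx <- nmToPx(centerNm, ps)
  med <- stats::median(P)
  acc <- P
  for (k in seq_len(n - 1L))
    acc <- acc + rotateAbout(P, k * 360 / n, ctrPx, fill = med)
  acc <- acc / n
  nr <- nrow(P); nc <- ncol(P)
  support <- min(ctrPx[1] - 1, ctrPx[2] - 1, nr - ctrPx[1], nc - ctrPx[2])
  dr <- rep(seq_len(nr) - ctrPx[1], times = nc)
  dc <- rep(seq_len(nc) - ctrPx[2], each = nr)
  acc[sqrt(dr^2 + dc^2) > support] <- med
  Micrograph(acc, ps,
             provenance = c(patch@provenance,
                            sprintf("markhamSuperposition(n=%d, increment=%.10g deg)",
                                    n, 360 / n)),
             meta = patch@meta)
}

warnIfFiltered <- function(patch) {
  if (any(grepl("bandpassFilter", patch@provenance)))
    warning("symmetry analysis on bandpass-filtered input: reinforcement must be computed on raw data only")
  invisible(NULL)
}

#' Rotational reinforcement score
#'
#' The reinforcement of an assumed n-fold symmetry is quantified as the mean
#' Pearson correlation, over k = 1..n-1, between the patch and its rotation
#' by k * (360/n) degrees, computed on the azimuthal component (the patch
#' minus its rotational average) within a radial band. The random-rotation
#' control evaluates the same single-rotation correlation at \code{mControls}
#' uniformly random non-commensurate angles; its mean is the no-symmetry
#' baseline and the standard error of that mean quantifies its uncertainty.
#'
#' @param patch a \linkS4class{Micrograph} (raw, not bandpass-filtered).
#' @param n assumed order (>= 2).
#' @param centerNm refined centre (x, y), nm.
#' @param bandNm length-2 radial band in nm, typically half the plug radius
#'   to 1.1 x the outer-ring radius.
#' @param mControls number of random control angles (0 disables the control).
#' @param seed RNG seed for the control angles.
#' @return A list with \code{score}, \code{perAngle} (correlation at each
#'   commensurate rotation) and \code{control} (list with \code{mean},
#'   \code{sd}, \code{se}, \code{m}) or NULL.
#' @export
reinforcementScore <- function(patch, n, centerNm, bandNm, mControls = 0L,
                               seed = 1L) {
  stopifnot(is(patch, "Micrograph"), n >= 2L)
  warnIfFiltered(patch)
  az <- prepareAzimuthal(patch, centerNm, bandNm)
  corAt <- function(angle) {
    if (az$degenerate) return(0)
    rot <- rotateAbout(az$res, az$ditherDeg + angle, az$ctrPx, fill = 0)
    stats::cor(az$v0, rot[az$idx])
  }
  perAngle <- vapply(seq_len(n - 1L), function(k) corAt(k * 360 / n), numeric(1))
  ctrl <- NULL
  if (mControls > 0L) {
    angles <- controlAngles(mControls, seed = seed)
    cc <- vapply(angles, corAt, numeric(1))
    ctrl <- list(mean = mean(cc), sd = stats::sd(cc),
                 se = stats::sd(cc) / sqrt(mControls), m = mControls,
                 values = cc)
  }
  list(score = mean(perAngle), perAngle = perAngle, control = ctrl)
}

#' Angular intensity profile and its harmonic power spectrum
#'
#' Mean intensity versus azimuth within a radial band, resampled on uniform
#' angle bins, with the discrete Fourier power at integer harmonics. The
#' dominant non-DC harmonic is an estimate of the rotational order that is
#' independent of the Markham superposition.
#'
#' @param patch a \linkS4class{Micrograph}.
#' @param centerNm centre (x, y) in nm.
#' @param bandNm length-2 radial band in nm (typically around the outer ridge).
#' @param nBins number of angle bins (>= 4 x \code{nMax}).
#' @param nMax largest harmonic reported.
#' @return A list with \code{angleDeg}, \code{profile}, \code{harmonics},
#'   \code{power} and \code{dominant}.
#' @export
angularPowerSpectrum <- function(patch, centerNm, bandNm, nBins = 360L,
                                 nMax = 12L) {
  stopifnot(is(patch, "Micrograph"))
  if (nBins < 4L * nMax) stop("nBins must be at least 4 x nMax")
  bp <- bandPixels(patch, centerNm, bandNm)
  th <- (bp$theta[bp$idx] %% (2 * pi))
  bin <- pmin(floor(th / (2 * pi / nBins)) + 1L, nBins)
  # profile of the azimuthal residual: subtracting the rotational average
  # removes the radial ring structure, whose pixel-grid aliasing would
  # otherwise leak into the angular profile
  res <- gaussianBlur(azimuthalResidual(patch, centerNm), 1)
  rawVals <- patch@pixels[bp$idx]
  vals <- res[bp$idx]
  sums <- rep(NA_real_, nBins); cnts <- tabulate(bin, nbins = nBins)
  agg <- rowsum(vals, bin)
  sums[as.integer(rownames(agg))] <- agg
  prof <- sums / ifelse(cnts > 0L, cnts, NA)
  # circular linear interpolation across empty bins
  if (anyNA(prof)) {
    filled <- which(!is.na(prof))
    if (length(filled) < 2L) stop("degenerate band: too few angle bins populated")
    idx <- seq_len(nBins)
    prof <- stats::approx(x = c(filled - nBins, filled, filled + nBins),
                          y = rep(prof[filled], 3L), xout = idx)$y
  }
  ft <- stats::fft(prof - mean(prof))
  power <- Mod(ft[2:(nMax + 1L)])^2
  bandVar <- stats::var(rawVals)
  list(angleDeg = (seq_len(nBins) - 0.5) * 360 / nBins, profile = prof,
       harmonics = seq_len(nMax), power = power,
       dominant = which.max(power),
       angularVarFraction = if (bandVar > 0) stats::var(prof) / bandVar else 0)
}

#' Scan candidate rotational orders and select the reinforced symmetry
#'
#' Evaluates the Markham reinforcement score for every order n = 2..nMax
#' (rotation increments exactly 360/n degrees) together with a shared
#' random-rotation control, and reports the angular-power-spectrum dominant
#' harmonic as an independent cross-check. The selected order is the LARGEST
#' candidate whose score (i) is within \code{epsilon} of the maximum score,
#' (ii) exceeds the control mean by at least three standard errors, and
#' (iii) exceeds it by at least \code{minMargin} in absolute correlation.
#' The largest-n tie-break resolves the divisor degeneracy of rotational
#' superposition (a perfect 8-fold image also reinforces at n = 2 and 4).
#' Returns order NA ("none") when no candidate beats the control, as for a
#' circularly symmetric or pure-noise patch.
#'
#' @param patch a raw \linkS4class{Micrograph} patch; patches with bandpass
#'   filtering in their provenance trigger a warning. Tilted pores should be
#'   corrected with \code{\link{deellipse}} first when the fitted axis ratio
#'   is below 0.97.
#' @param centerNm refined centre; default: \code{\link{refineCenter}}.
#' @param nMax largest candidate order (default 12).
#' @param bandNm radial band (nm) for the correlations; default: half the
#'   measured plug radius to 1.1 x the measured outer-ring radius.
#' @param mControls number of random control angles.
#' @param seed RNG seed for the control.
#' @param epsilon score tie tolerance for the largest-n tie-break,
#'   calibrated from the noiseless divisor-tie spread of the implementation.
#' @param minMargin minimum score excess over the control mean.
#' @return A \linkS4class{SymmetryScan}.
#' @examples
#' p <- renderPorePatch(PoreModel(), noiseSigma = 0.4 / 3, seed = 42)
#' sc <- assessSymmetry(p, seed = 1)
#' selectedOrder(sc)
#' @export
assessSymmetry <- function(patch, centerNm = NULL, nMax = 12L, bandNm = NULL,
                           mControls = 99L, seed = 1L, epsilon = 0.12,
                           minMargin = 0.05) {
  stopifnot(is(patch, "Micrograph"))
  warnIfFiltered(patch)
  ps <- patch@pixelSize
  if (is.null(centerNm)) centerNm <- refineCenter(patch)$centerNm
  inscribed <- min(centerNm[1], centerNm[2],
                   (ncol(patch@pixels) - 1) * ps - centerNm[1],
                   (nrow(patch@pixels) - 1) * ps - centerNm[2])
  rOuterHat <- NA_real_
  if (is.null(bandNm)) {
    meas <- tryCatch(measureRings(radialProfile(patch, centerNm = centerNm)),
                     error = function(e) NULL)
    if (!is.null(meas) && is.finite(meas@dOuter) && is.finite(meas@dPlug)) {
      rOuterHat <- meas@dOuter / 2
      bandNm <- c(0.5 * meas@dPlug / 2, min(1.1 * rOuterHat, inscribed - ps))
    } else {
      bandNm <- c(2 * ps, inscribed - ps)
    }
  }
  orders <- 2:as.integer(nMax)
  az <- prepareAzimuthal(patch, centerNm, bandNm)
  corAt <- function(angle) {
    if (az$degenerate) return(0)
    rot <- rotateAbout(az$res, az$ditherDeg + angle, az$ctrPx, fill = 0)
    stats::cor(az$v0, rot[az$idx])
  }
  scoreVec <- vapply(orders, function(n)
    mean(vapply(seq_len(n - 1L), function(k) corAt(k * 360 / n), numeric(1))),
    numeric(1))
  angles <- controlAngles(as.integer(mControls), nMax = as.integer(nMax),
                          seed = seed)
  ctrlVals <- vapply(angles, corAt, numeric(1))
  ctrlMean <- mean(ctrlVals)
  ctrlSd <- stats::sd(ctrlVals)
  ctrlSe <- ctrlSd / sqrt(length(ctrlVals))
  # per-order significance floor: the larger of the control-mean uncertainty
  # and the parametric null s.e. of a mean of (n-1) band correlations
  seNullN <- az$seNull / sqrt(orders - 1)
  beats <- scoreVec > ctrlMean + 3 * pmax(ctrlSe, seNullN) &
    scoreVec - ctrlMean >= minMargin
  tied <- scoreVec >= max(scoreVec) - epsilon
  selected <- if (any(beats & tied)) max(orders[beats & tied]) else NA_integer_
  specBand <- if (is.finite(rOuterHat))
    c(0.85, 1.15) * rOuterHat else bandNm
  spec <- angularPowerSpectrum(patch, centerNm, specBand, nMax = as.integer(nMax))
  new("SymmetryScan", orders = orders, incrementsDeg = 360 / orders,
      scores = scoreVec, ctrlMean = ctrlMean, ctrlSd = ctrlSd,
      ctrlSe = ctrlSe, mControls = as.integer(mControls),
      selectedN = as.integer(selected),
      spectrumHarmonic = as.integer(spec$dominant),
      epsilon = epsilon, minMargin = minMargin, seed = as.integer(seed),
      bandNm = as.numeric(bandNm))
}

#' Export a symmetry scan as JSON
#'
#' @param scan a \linkS4class{SymmetryScan}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeSymmetryScan <- function(scan, path) {
  perN <- lapply(seq_along(scan@orders), function(i)
    list(n = scan@orders[i],
         increment_deg = round(scan@incrementsDeg[i], 1),
         score = scan@scores[i]))
  writeJSONFile(list(
    per_order = perN,
    control = list(mean = scan@ctrlMean, sd = scan@ctrlSd, se = scan@ctrlSe,
                   m = scan@mControls, seed = scan@seed),
    selected_n = if (is.na(scan@selectedN)) "none" else scan@selectedN,
    spectrum_harmonic = scan@spectrumHarmonic,
    band_nm = scan@bandNm), path)
  invisible(path)
}

#' Plot a Markham rotation panel
#'
#' Draws the input patch followed by its rotational superpositions for the
#' given orders on the current graphics device.
#'
#' @param patch a \linkS4class{Micrograph}.
#' @param centerNm refined centre; default: \code{\link{refineCenter}}.
#' @param orders orders to display.
#' @return Invisibly, the list of superimposed patches.
#' @export
plotMarkhamPanel <- function(patch, centerNm = NULL, orders = 2:9) {
  if (is.null(centerNm)) centerNm <- refineCenter(patch)$centerNm
  sups <- lapply(orders, function(n) markhamSuperposition(patch, n, centerNm))
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(orders) + 1L),
                       mar = c(0.5, 0.5, 1.5, 0.5))
  on.exit(graphics::par(old))
  drawOne <- function(px, label) {
    graphics::image(t(px[nrow(px):1, ]), col = grDevices::gray.colors(256),
                    axes = FALSE, main = label, useRaster = TRUE)
  }
  drawOne(patch@pixels, "input")
  for (i in seq_along(orders))
    drawOne(sups[[i]]@pixels, sprintf("n = %d (%.1f deg)", orders[i],
                                      360 / orders[i]))
  invisible(sups)
}
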