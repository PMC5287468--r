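#' @include AllClasses.R
NULL

# Analytic pore intensity (background excluded) at offsets (dxNm, dyNm) from
# the pore centre. Tilt is rendered as in-plane foreshortening: image
# coordinates along the tilt axis are the membrane coordinates compressed by
# cos(tilt), so the membrane-frame radius is recovered by dividing the
# along-axis component by cos(tilt).
poreIntensity <- function(model, dxNm, dyNm) {
  if (model@tiltDeg > 0) {
    phi <- model@tiltAxisDeg * pi / 180
    ct <- cos(model@tiltDeg * pi / 180)
    p <- (dxNm * cos(phi) + dyNm * sin(phi)) / ct
    q <- -dxNm * sin(phi) + dyNm * cos(phi)
    r <- sqrt(p^2 + q^2)
    th <- atan2(q, p) + phi
  } else {
    r <- sqrt(dxNm^2 + dyNm^2)
    th <- atan2(dyNm, dxNm)
  }
  rPlug <- model@dPlug / 2
  rInner <- model@dInner / 2
  rOuter <- model@dOuter / 2
  v <- model@contrastPlug * 0.5 * erfc((r - rPlug) / (sqrt(2) * model@ringWidthPlug))
  if (model@contrastInner != 0)
    v <- v + model@contrastInner * exp(-(r - rInner)^2 / (2 * model@ringWidthInner^2))
  if (model@contrastOuter != 0) {
    mod <- 1 + model@subunitAmplitude *
      cos(model@nFold * (th - model@phaseDeg * pi / 180))
    v <- v + model@contrastOuter * mod * exp(-(r - rOuter)^2 / (2 * model@ringWidthOuter^2))
  }
  v
}

#' Render a single synthetic pore patch
#'
#' Renders one pore complex on a uniform membrane background: a plug disk
#' (half-contrast radius \code{dPlug/2}), Gaussian-profile annuli with ridge
#' radii \code{dInner/2} and \code{dOuter/2}, n-fold azimuthal modulation of
#' the outer ring, affine tilt foreshortening, Gaussian PSF blur, and i.i.d.
#' Gaussian noise. Ground-truth parameters are echoed in the patch metadata.
#'
#' @param model a \linkS4class{PoreModel}.
#' @param pixelSize nm per pixel (default 0.69).
#' @param patchRadius half-width of the square patch in nm; must be at least
#'   0.75 x the outer diameter.
#' @param noiseSigma additive Gaussian noise s.d. (0 = noiseless). The
#'   signal-to-noise ratio convention is \code{abs(contrastOuter)/noiseSigma}.
#' @param seed RNG seed for the noise (ignored when noiseSigma = 0).
#' @param background membrane background intensity.
#' @param psfSigma Gaussian point-spread sigma in nm (0 disables blurring).
#' @param centerOffsetNm length-2 (x, y) offset of the pore centre from the
#'   central pixel, in nm; used to test centre refinement.
#' @return A \linkS4class{Micrograph} patch with odd side length. The metadata
#'   list carries \code{model}, \code{centerNm} (true centre in patch
#'   coordinates) and the render settings.
#' @examples
#' p <- renderPorePatch(PoreModel(), patchRadius = 26, noiseSigma = 0)
#' p
#' @export
renderPorePatch <- function(model, pixelSize = 0.69, patchRadius = 26,
                            noiseSigma = 0, seed = NULL, background = 0.5,
                            psfSigma = 1.0, centerOffsetNm = c(0, 0)) {
  stopifnot(is(model, "PoreModel"))
  validObject(model)
  if (pixelSize <= 0) stop("pixelSize must be > 0")
  if (patchRadius < 0.75 * model@dOuter)
    stop(sprintf(paste0("patch too small: patchRadius %g nm < 0.75 x outer ",
                        "diameter (%g nm); enlarge the patch"),
                 patchRadius, 0.75 * model@dOuter))
  half <- ceiling(patchRadius / pixelSize)
  side <- 2L * half + 1L
  centerPx <- half + 1L                      # central pixel (row = col)
  cxNm <- (centerPx - 1L) * pixelSize + centerOffsetNm[1]
  cyNm <- (centerPx - 1L) * pixelSize + centerOffsetNm[2]
  xNm <- (seq_len(side) - 1) * pixelSize
  dx <- matrix(rep(xNm - cxNm, each = side), side, side)   # columns vary x
  dy <- matrix(rep(xNm - cyNm, times = side), side, side)  # rows vary y
  img <- background + poreIntensity(model, dx, dy)
  if (psfSigma > 0) img <- gaussianBlur(img, psfSigma / pixelSize)
  if (noiseSigma > 0)
    img <- img + withSeed(seed, matrix(stats::rnorm(side * side, sd = noiseSigma),
                                       side, side))
  Micrograph(img, pixelSize,
             provenance = sprintf("renderPorePatch(dOuter=%g, nFold=%d, noise=%g)",
                                  model@dOuter, model@nFold, noiseSigma),
             meta = list(model = model, centerNm = c(x = cxNm, y = cyNm),
                         background = background, psfSigma = psfSigma,
                         noiseSigma = noiseSigma, seed = seed))
}

# Analytic membership test for the scene's membrane region, coordinates in nm.
# margin shrinks the region so that tested points keep that distance from the
# boundary (used to keep rendered rings complete).
sceneInMask <- function(scene, x, y, margin = 0) {
  w <- scene@widthNm; h <- scene@heightNm
  if (scene@maskType == "full") {
    x >= margin & x <= w - margin & y >= margin & y <= h - margin
  } else {
    a <- w / 2 - margin; b <- h / 2 - margin
    if (a <= 0 || b <= 0) return(rep(FALSE, length(x)))
    ((x - w / 2) / a)^2 + ((y - h / 2) / b)^2 <= 1
  }
}

sceneMaskArea <- function(scene) {
  # analytic area in um^2
  if (scene@maskType == "full") scene@widthNm * scene@heightNm * 1e-6
  else pi * (scene@widthNm / 2) * (scene@heightNm / 2) * 1e-6
}

#' Ground-truth membrane mask of a scene
#'
#' Rasterizes the scene's analytic membrane region at the scene's pixel size.
#'
#' @param scene a \linkS4class{SheetScene}.
#' @return A \linkS4class{MembraneMask}.
#' @export
sceneMask <- function(scene) {
  nc <- round(scene@widthNm / scene@pixelSize)
  nr <- round(scene@heightNm / scene@pixelSize)
  x <- (seq_len(nc) - 1) * scene@pixelSize
  y <- (seq_len(nr) - 1) * scene@pixelSize
  m <- outer(y, x, function(yy, xx) sceneInMask(scene, xx, yy))
  MembraneMask(m, scene@pixelSize)
}

# Sequential hard-core rejection sampler. Returns a 2-column matrix (x, y) or
# stops when the target count cannot be placed.
hardCoreSample <- function(scene, target) {
  if (target == 0L) return(matrix(numeric(), 0L, 2L))
  maxAttempts <- 100L * target
  xs <- numeric(target); ys <- numeric(target)
  placed <- 0L; attempts <- 0L
  minSep2 <- scene@minSeparation^2
  margin <- scene@edgeMarginNm
  while (placed < target && attempts < maxAttempts) {
    attempts <- attempts + 1L
    px <- stats::runif(1, 0, scene@widthNm)
    py <- stats::runif(1, 0, scene@heightNm)
    if (!sceneInMask(scene, px, py, margin = margin)) next
    if (placed > 0L) {
      d2 <- (xs[seq_len(placed)] - px)^2 + (ys[seq_len(placed)] - py)^2
      if (min(d2) < minSep2) next
    }
    placed <- placed + 1L
    xs[placed] <- px; ys[placed] <- py
  }
  if (placed < target)
    stop(sprintf(paste0("hard-core placement infeasible: placed %d of %d pores ",
                        "after %d attempts (density %.4g /um^2, min separation ",
                        "%.3g nm)"), placed, target, maxAttempts,
                 scene@density, scene@minSeparation))
  cbind(xs, ys)
}

#' Render a synthetic membrane sheet with ground truth
#'
#' Draws pore centres by sequential hard-core rejection sampling (uniform
#' proposals inside the membrane region, proposals closer than the minimum
#' separation to an accepted centre rejected) until \code{round(density x
#' mask area)} pores are placed, renders each pore from its mixture class
#' with a random azimuthal phase, applies the PSF blur and adds noise. The
#' membrane region and the exterior have distinct mean intensities.
#'
#' @param scene a \linkS4class{SheetScene}.
#' @return A list with elements \code{micrograph} (\linkS4class{Micrograph})
#'   and \code{truth} (\linkS4class{GroundTruth}).
#' @examples
#' sc <- SheetScene(widthNm = 600, heightNm = 600, density = 30, seed = 3)
#' out <- renderSheet(sc)
#' nrow(poreTruth(out$truth))
#' @export
renderSheet <- function(scene) {
  stopifnot(is(scene, "SheetScene"))
  validObject(scene)
  ps <- scene@pixelSize
  nc <- round(scene@widthNm / ps)
  nr <- round(scene@heightNm / ps)
  target <- round(scene@density * sceneMaskArea(scene))
  mix <- scene@poreMix
  out <- withSeed(scene@seed, {
    centers <- hardCoreSample(scene, target)
    classes <- if (target > 0L)
      sample.int(length(mix@models), target, replace = TRUE,
                 prob = mix@proportions) else integer()
    phases <- stats::runif(max(target, 0L), 0, 360)
    maskM <- sceneMask(scene)@mask
    img <- matrix(scene@backgroundExterior, nr, nc)
    img[maskM] <- scene@backgroundMembrane
    if (target > 0L) {
      for (i in seq_len(target)) {
        mdl <- mix@models[[classes[i]]]
        mdl@phaseDeg <- phases[i]
        wr <- mdl@dOuter / 2 + 4 * mdl@ringWidthOuter + 2
        xc <- centers[i, 1]; yc <- centers[i, 2]
        colIdx <- max(1L, floor((xc - wr) / ps) + 1L):min(nc, ceiling((xc + wr) / ps) + 1L)
        rowIdx <- max(1L, floor((yc - wr) / ps) + 1L):min(nr, ceiling((yc + wr) / ps) + 1L)
        dx <- matrix(rep((colIdx - 1) * ps - xc, each = length(rowIdx)),
                     length(rowIdx), length(colIdx))
        dy <- matrix(rep((rowIdx - 1) * ps - yc, times = length(colIdx)),
                     length(rowIdx), length(colIdx))
        img[rowIdx, colIdx] <- img[rowIdx, colIdx] + poreIntensity(mdl, dx, dy)
      }
    }
    if (scene@psfSigma > 0) img <- gaussianBlur(img, scene@psfSigma / ps)
    if (scene@noiseSigma > 0)
      img <- img + matrix(stats::rnorm(nr * nc, sd = scene@noiseSigma), nr, nc)
    list(img = img, centers = centers, classes = classes, phases = phases)
  })
  pores <- data.frame(
    pore_id = seq_len(target),
    x_nm = if (target) out$centers[, 1] else numeric(),
    y_nm = if (target) out$centers[, 2] else numeric(),
    class = if (target) out$classes else integer(),
    n_fold = if (target)
      vapply(out$classes, function(k) mix@models[[k]]@nFold, integer(1)) else integer(),
    tilt_deg = if (target)
      vapply(out$classes, function(k) mix@models[[k]]@tiltDeg, numeric(1)) else numeric()
  )
  truth <- new("GroundTruth", pores = pores, gold = emptyGoldTable())
  mic <- Micrograph(out$img, ps,
                    provenance = sprintf("renderSheet(density=%g, seed=%d)",
                                         scene@density, scene@seed),
                    meta = list(scene = scene, nPores = target))
  list(micrograph = mic, truth = truth)
}

# Minimum edge (or centre) distance from points to a pore table; returns the
# distance and the index of the nearest pore.
goldDistances <- function(x, y, pores, mode = "edge") {
  n <- length(x)
  if (nrow(pores) == 0L)
    return(list(distance = rep(Inf, n), nearest = rep(NA_integer_, n)))
  dist <- numeric(n); nearest <- integer(n)
  for (i in seq_len(n)) {
    d <- sqrt((pores$x_nm - x[i])^2 + (pores$y_nm - y[i])^2)
    if (mode == "edge") d <- pmax(0, d - pores$outer_radius_nm)
    j <- which.min(d)
    dist[i] <- d[j]; nearest[i] <- j
  }
  list(distance = dist, nearest = nearest)
}

poreTableFromTruth <- function(truth, scene) {
  pt <- truth@pores
  radii <- vapply(pt$class, function(k) scene@poreMix@models[[k]]@dOuter / 2,
                  numeric(1))
  data.frame(x_nm = pt$x_nm, y_nm = pt$y_nm, outer_radius_nm = radii)
}

#' Place immunogold particles with a controlled associated fraction
#'
#' Places \code{round(fracAssociated * nParticles)} particles uniformly within
#' the threshold distance of the outer-ring edge of a randomly chosen pore,
#' and the remainder uniformly in the membrane region at more than the
#' threshold distance from every pore. Intended association flags and exact
#' nearest-pore distances are recorded in the gold table.
#'
#' @param truth a \linkS4class{GroundTruth} with pores placed.
#' @param scene the \linkS4class{SheetScene} the truth was generated from
#'   (provides the mask geometry and per-class outer radii).
#' @param fracAssociated proportion in [0, 1] of particles to associate.
#' @param thresholdNm association distance threshold in nm (default 20,
#'   inclusive: a particle exactly at the threshold is associated).
#' @param nParticles total number of particles.
#' @param seed RNG seed.
#' @return The \linkS4class{GroundTruth} with the gold table filled.
#' @export
placeGold <- function(truth, scene, fracAssociated, thresholdNm = 20,
                      nParticles, seed = 1L) {
  stopifnot(is(truth, "GroundTruth"), is(scene, "SheetScene"))
  if (fracAssociated < 0 || fracAssociated > 1)
    stop("fracAssociated must lie in [0, 1]")
  if (thresholdNm <= 0) stop("thresholdNm must be > 0")
  pores <- poreTableFromTruth(truth, scene)
  nA <- round(fracAssociated * nParticles)
  nN <- nParticles - nA
  if (nA > 0L && nrow(pores) == 0L)
    stop("cannot place associated particles: ground truth contains no pores")
  pts <- withSeed(seed, {
    xs <- numeric(nParticles); ys <- numeric(nParticles)
    # associated: uniform in the disk of radius (outer radius + threshold)
    # around a random pore, clipped to the membrane region
    for (i in seq_len(nA)) {
      ok <- FALSE
      for (att in seq_len(10000L)) {
        j <- sample.int(nrow(pores), 1L)
        R <- pores$outer_radius_nm[j] + thresholdNm
        rr <- R * sqrt(stats::runif(1))
        aa <- stats::runif(1, 0, 2 * pi)
        px <- pores$x_nm[j] + rr * cos(aa)
        py <- pores$y_nm[j] + rr * sin(aa)
        if (sceneInMask(scene, px, py)) { ok <- TRUE; break }
      }
      if (!ok) stop("failed to place an associated gold particle inside the mask")
      xs[i] <- px; ys[i] <- py
    }
    # non-associated: uniform in mask, strictly beyond the threshold from all pores
    for (i in seq_len(nN)) {
      ok <- FALSE
      for (att in seq_len(10000L)) {
        px <- stats::runif(1, 0, scene@widthNm)
        py <- stats::runif(1, 0, scene@heightNm)
        if (!sceneInMask(scene, px, py)) next
        d <- goldDistances(px, py, pores, mode = "edge")$distance
        if (d > thresholdNm) { ok <- TRUE; break }
      }
      if (!ok)
        stop("mask too crowded to place non-associated particles beyond the threshold")
      xs[nA + i] <- px; ys[nA + i] <- py
    }
    list(x = xs, y = ys)
  })
  dd <- goldDistances(pts$x, pts$y, pores, mode = "edge")
  truth@gold <- data.frame(
    gold_id = seq_len(nParticles), x_nm = pts$x, y_nm = pts$y,
    intended_associated = seq_len(nParticles) <= nA,
    nearest_pore_id = dd$nearest, distance_nm = dd$distance
  )
  truth
}
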