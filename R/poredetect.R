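#' @include AllClasses.R
NULL

#' Segment the membrane sheet
#'
#' Otsu threshold on the intensity histogram, morphological closing and
#' selection of the largest connected component. Assumes the sheet's mean
#' intensity differs from the exterior; a (near-)uniform image is an error.
#'
#' @param m a \linkS4class{Micrograph}.
#' @param polarity \code{"bright"} when the membrane is brighter than the
#'   exterior (the synthetic generator's convention), \code{"dark"} otherwise.
#' @param closingRadiusPx radius of the closing brush in pixels.
#' @param smoothSigmaPx Gaussian pre-smoothing before thresholding (pixels);
#'   suppresses pixel noise that would otherwise percolate through the
#'   morphological closing.
#' @return A \linkS4class{MembraneMask} with its area in square microns.
#' @export
makeMembraneMask <- function(m, polarity = c("bright", "dark"),
                             closingRadiusPx = 5L, smoothSigmaPx = 3) {
  stopifnot(is(m, "Micrograph"))
  polarity <- match.arg(polarity)
  px <- if (smoothSigmaPx > 0) gaussianBlur(m@pixels, smoothSigmaPx) else m@pixels
  rng <- range(px)
  if (diff(rng) < 1e-12 * max(1, abs(rng[2])))
    stop("uniform image: no separable membrane component")
  scaled <- (px - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(scaled))
  mask <- if (polarity == "bright") scaled > th else scaled < th
  if (!any(mask)) stop("empty membrane mask after thresholding")
  brush <- EBImage::makeBrush(2L * as.integer(closingRadiusPx) + 1L, shape = "disc")
  closed <- EBImage::closing(EBImage::Image(mask * 1), brush) > 0.5
  # pores are enclosed dark (or bright) spots within the sheet: fill them
  closed <- EBImage::fillHull(EBImage::Image(closed * 1)) > 0.5
  lab <- EBImage::bwlabel(EBImage::Image(closed * 1))
  labv <- as.integer(EBImage::imageData(lab))
  if (!any(labv > 0L)) stop("empty membrane mask after morphology")
  counts <- tabulate(labv)
  keep <- which.max(counts)
  MembraneMask(matrix(labv == keep, nrow(px), ncol(px)), m@pixelSize)
}

# Zero-mean Gaussian annulus template on a square support; polarity -1 makes
# electron-dense (dark) rings score positively.
annulusTemplate <- function(radiusPx, widthPx, sidePx, polarity = -1) {
  ctr <- (sidePx + 1) / 2
  d <- seq_len(sidePx) - ctr
  r <- sqrt(outer(d^2, d^2, "+"))
  t <- polarity * exp(-(r - radiusPx)^2 / (2 * widthPx^2))
  t - mean(t)
}

#' Detect ring-shaped pores by annulus matched filtering
#'
#' Normalized cross-correlation of the locally standardized image against
#' zero-mean Gaussian-profile annulus templates over a grid of ridge radii,
#' followed by thresholding, 3x3 local-maximum selection within the membrane
#' mask, and greedy non-maximum suppression with a minimum centre separation
#' (ties broken by score, then by lower row and column index). Detections
#' whose centre lies closer to the mask boundary than their ridge radius are
#' flagged \code{"edge"} but kept; the density estimate uses all detections.
#' The standardized correlation makes detection invariant to affine intensity
#' changes of the image.
#'
#' @param m a \linkS4class{Micrograph}.
#' @param mask optional \linkS4class{MembraneMask}; default: the whole frame.
#' @param radiusGrid candidate ridge radii in nm; must be non-empty and span
#'   the expected outer-ring radius.
#' @param scoreThreshold minimum normalized correlation in [-1, 1].
#' @param minSeparation minimum centre-to-centre distance (nm) kept by NMS.
#' @param ringWidthNm radial sigma of the annulus template (nm); default
#'   matches the generator's outer-ring width.
#' @param polarity -1 for electron-dense (dark) rings, +1 for bright rings.
#' @return A \linkS4class{DetectionTable}.
#' @export
detectPores <- function(m, mask = NULL, radiusGrid = seq(12, 22, by = 2),
                        scoreThreshold = 0.3, minSeparation = 25,
                        ringWidthNm = 2.2, polarity = -1) {
  stopifnot(is(m, "Micrograph"))
  if (length(radiusGrid) == 0L) stop("radius grid must not be empty")
  if (minSeparation <= 0) stop("minSeparation must be > 0")
  ps <- m@pixelSize
  img <- m@pixels
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(mask)) mask <- MembraneMask(matrix(TRUE, nr, nc), ps)
  side <- 2L * ceiling((max(radiusGrid) + 3 * ringWidthNm) / ps) + 1L
  if (side >= min(nr, nc))
    stop("image too small for the largest template radius")
  half <- (side - 1L) %/% 2L
  nT <- side * side
  ones <- matrix(1, side, side)
  S1 <- fftCrossCorrelate(img, ones)
  S2 <- fftCrossCorrelate(img * img, ones)
  localVar <- pmax(S2 - S1^2 / nT, 0)
  denomBase <- sqrt(localVar)
  bestScore <- matrix(-Inf, nrow(S1), ncol(S1))
  bestRadius <- matrix(NA_real_, nrow(S1), ncol(S1))
  for (r0 in radiusGrid) {
    tpl <- annulusTemplate(r0 / ps, ringWidthNm / ps, side, polarity)
    num <- fftCrossCorrelate(img, tpl)
    den <- sqrt(sum(tpl^2)) * denomBase
    ncc <- ifelse(den > 1e-12, num / den, 0)
    upd <- ncc > bestScore
    bestScore[upd] <- ncc[upd]
    bestRadius[upd] <- r0
  }
  bestScore <- pmin(pmax(bestScore, -1), 1)
  # 3x3 local maxima above threshold, centres inside the mask
  vr <- nrow(bestScore); vc <- ncol(bestScore)
  pad <- matrix(-Inf, vr + 2L, vc + 2L)
  pad[2:(vr + 1L), 2:(vc + 1L)] <- bestScore
  isMax <- bestScore >= scoreThreshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    isMax <- isMax & bestScore >= pad[(2L + dr):(vr + 1L + dr),
                                      (2L + dc):(vc + 1L + dc)]
  }
  ctrRow <- row(bestScore) + half    # centre pixel in image coordinates
  ctrCol <- col(bestScore) + half
  inMask <- mask@mask[cbind(as.vector(ctrRow), as.vector(ctrCol))]
  cand <- which(as.vector(isMax) & inMask)
  det <- data.frame(detection_id = integer(), x_nm = numeric(), y_nm = numeric(),
                    ridge_radius_nm = numeric(), score = numeric(),
                    edge_flag = logical())
  if (length(cand)) {
    cr <- as.vector(ctrRow)[cand]; ccol <- as.vector(ctrCol)[cand]
    sc <- as.vector(bestScore)[cand]; rad <- as.vector(bestRadius)[cand]
    ord <- order(-sc, cr, ccol)
    cr <- cr[ord]; ccol <- ccol[ord]; sc <- sc[ord]; rad <- rad[ord]
    xs <- (ccol - 1) * ps; ys <- (cr - 1) * ps
    keep <- logical(length(cand))
    accX <- numeric(0); accY <- numeric(0)
    for (i in seq_along(cand)) {
      if (length(accX) == 0L ||
          min((accX - xs[i])^2 + (accY - ys[i])^2) >= minSeparation^2) {
        keep[i] <- TRUE
        accX <- c(accX, xs[i]); accY <- c(accY, ys[i])
      }
    }
    xs <- xs[keep]; ys <- ys[keep]; sc <- sc[keep]; rad <- rad[keep]
    cr <- cr[keep]; ccol <- ccol[keep]
    # edge flag: centre closer to the mask boundary than the ridge radius
    dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask@mask * 1))) * ps
    edge <- dm[cbind(cr, ccol)] < rad
    det <- data.frame(detection_id = seq_along(xs), x_nm = xs, y_nm = ys,
                      ridge_radius_nm = rad, score = sc, edge_flag = edge)
  }
  new("DetectionTable", detections = det,
      params = list(radiusGrid = radiusGrid, scoreThreshold = scoreThreshold,
                    minSeparation = minSeparation, ringWidthNm = ringWidthNm,
                    polarity = polarity, templateSidePx = side),
      maskAreaUm2 = mask@areaUm2)
}

#' Estimate areal pore density
#'
#' Count divided by membrane area, with a Poisson 95 percent interval
#' \code{(count +/- 1.96 sqrt(count)) / area}.
#'
#' @param dt a \linkS4class{DetectionTable}.
#' @return A list with \code{density}, \code{lower}, \code{upper} (pores per
#'   square micron), \code{count} and \code{areaUm2}.
#' @examples
#' # 10 detections on 0.1 um^2 -> 100 pores/um^2
#' @export
estimateDensity <- function(dt) {
  stopifnot(is(dt, "DetectionTable"))
  n <- nrow(dt@detections)
  a <- dt@maskAreaUm2
  list(density = n / a,
       lower = max(0, (n - 1.96 * sqrt(n))) / a,
       upper = (n + 1.96 * sqrt(n)) / a,
       count = n, areaUm2 = a)
}
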