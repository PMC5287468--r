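#' @include AllClasses.R
NULL

patchCenterNm <- function(patch) {
  ps <- patch@pixelSize
  c(x = (ncol(patch@pixels) - 1) / 2 * ps, y = (nrow(patch@pixels) - 1) / 2 * ps)
}

nmToPx <- function(centerNm, ps) c(centerNm[2] / ps + 1, centerNm[1] / ps + 1)

#' Refine a pore centre by 180-degree self-correlation
#'
#' The symmetry centre of the patch is located as the sub-pixel shift
#' maximizing the correlation between the patch and its 180-degree rotated
#' copy (computed by FFT cross-correlation with 3-point parabolic sub-pixel
#' refinement; the displacement of the correlation peak equals twice the
#' centre offset). The search is limited to offsets within a quarter of the
#' patch radius.
#'
#' @param patch a \linkS4class{Micrograph} containing one pore.
#' @param maxShiftNm optional search limit for the centre offset (default:
#'   patch radius / 4).
#' @return A list with \code{centerNm} (x, y of the symmetry centre in patch
#'   coordinates), \code{offsetNm} (x, y offset from the geometric centre)
#'   and \code{offsetPx}.
#' @export
refineCenter <- function(patch, maxShiftNm = NULL) {
  stopifnot(is(patch, "Micrograph"))
  P <- patch@pixels
  ps <- patch@pixelSize
  if (stats::sd(P) < 1e-12) stop("flat patch: no symmetry centre can be refined")
  nr <- nrow(P); nc <- ncol(P)
  radiusNm <- (min(nr, nc) - 1) / 2 * ps
  if (is.null(maxShiftNm)) maxShiftNm <- radiusNm / 4
  maxD <- ceiling(2 * maxShiftNm / ps)      # peak displacement = 2 x offset
  Pc <- P - mean(P)
  Q <- Pc[nr:1, nc:1]
  C <- Re(stats::fft(stats::fft(Pc) * Conj(stats::fft(Q)), inverse = TRUE)) / (nr * nc)
  # displacement of entry (i, j) is (i-1, j-1) with circular wrap-around
  dr <- ((seq_len(nr) - 1 + floor(nr / 2)) %% nr) - floor(nr / 2)
  dc <- ((seq_len(nc) - 1 + floor(nc / 2)) %% nc) - floor(nc / 2)
  allowed <- outer(abs(dr) <= maxD, abs(dc) <= maxD, "&")
  Cm <- C; Cm[!allowed] <- -Inf
  peak <- arrayInd(which.max(Cm), dim(Cm))
  pr <- peak[1]; pc <- peak[2]
  wrap <- function(i, n) ((i - 1) %% n) + 1
  offR <- parabolicOffset(C[wrap(pr - 1, nr), pc], C[pr, pc], C[wrap(pr + 1, nr), pc])
  offC <- parabolicOffset(C[pr, wrap(pc - 1, nc)], C[pr, pc], C[pr, wrap(pc + 1, nc)])
  dRow <- dr[pr] + offR
  dCol <- dc[pc] + offC
  geo <- patchCenterNm(patch)
  offsetNm <- c(x = dCol / 2 * ps, y = dRow / 2 * ps)
  list(centerNm = geo + offsetNm, offsetNm = offsetNm,
       offsetPx = offsetNm / ps)
}

#' Radial intensity profile about a centre
#'
#' Mean intensity in concentric annular bins about the given centre, out to
#' the largest radius fully contained in the patch.
#'
#' @param patch a \linkS4class{Micrograph}.
#' @param centerNm length-2 (x, y) centre in patch coordinates (nm); default:
#'   the geometric centre.
#' @param binWidth bin width in nm; must be at least half the pixel size.
#'   Default: one pixel.
#' @return A \linkS4class{RadialProfile}.
#' @export
radialProfile <- function(patch, centerNm = NULL, binWidth = NULL) {
  stopifnot(is(patch, "Micrograph"))
  ps <- patch@pixelSize
  if (is.null(centerNm)) centerNm <- patchCenterNm(patch)
  if (is.null(binWidth)) binWidth <- ps
  if (binWidth < ps / 2) stop("binWidth must be at least half the pixel size")
  P <- patch@pixels
  nr <- nrow(P); nc <- ncol(P)
  xmax <- (nc - 1) * ps; ymax <- (nr - 1) * ps
  if (centerNm[1] < 0 || centerNm[1] > xmax || centerNm[2] < 0 || centerNm[2] > ymax)
    stop("centre lies outside the patch")
  dx <- rep((seq_len(nc) - 1) * ps - centerNm[1], each = nr)
  dy <- rep((seq_len(nr) - 1) * ps - centerNm[2], times = nc)
  r <- sqrt(dx^2 + dy^2)
  rmax <- min(centerNm[1], centerNm[2], xmax - centerNm[1], ymax - centerNm[2]) + ps / 2
  nb <- max(1L, floor(rmax / binWidth))
  bin <- floor(r / binWidth) + 1L
  keep <- bin <= nb
  counts <- tabulate(bin[keep], nbins = nb)
  if (any(counts == 0L))
    stop("empty radial bins: increase binWidth (bins must each contain pixels)")
  sums <- as.vector(rowsum(as.vector(P)[keep], bin[keep]))
  new("RadialProfile", binCenters = (seq_len(nb) - 0.5) * binWidth,
      intensity = sums / counts, counts = as.integer(counts),
      binWidth = binWidth)
}

# standard error of a 3-point parabola vertex (in bins) for i.i.d. bin noise
parabolaVertexSE <- function(u, v, w, sigma) {
  D <- u - 2 * v + w
  if (abs(D) < 1e-12) return(Inf)
  du <- (D - (u - w)) / (2 * D^2)
  dv <- (u - w) / D^2
  dw <- (-D - (u - w)) / (2 * D^2)
  sigma * sqrt(du^2 + dv^2 + dw^2)
}

#' Measure plug, inner-ring and outer-ring diameters from a radial profile
#'
#' The plug diameter is the full width at half contrast of the central disk
#' (twice the radius where the profile decays halfway from its central value
#' to the baseline). Ring diameters are twice the radii of the corresponding
#' annulus ridge extrema, localized to sub-bin precision by a 3-point
#' parabola. The baseline is the median of the outermost 15 percent of bins.
#' Features whose amplitude does not exceed the noise-derived prominence
#' threshold are flagged missing rather than guessed; uncertainties combine
#' half a bin width with the peak-fit standard error in quadrature.
#'
#' @param profile a \linkS4class{RadialProfile}.
#' @param polarity named numeric vector with elements \code{plug},
#'   \code{inner}, \code{outer} in \{-1, +1\}; the default (-1, +1, -1) is the
#'   negative-stain convention (dark plug, bright inner ring, dark outer ring).
#' @return A \linkS4class{RingMeasurement}.
#' @export
measureRings <- function(profile,
                         polarity = c(plug = -1, inner = 1, outer = -1)) {
  stopifnot(is(profile, "RadialProfile"))
  p <- profile@intensity
  r <- profile@binCenters
  bw <- profile@binWidth
  nb <- length(p)
  if (nb < 5L) stop("profile too short to measure rings")
  baseIdx <- r >= 0.85 * max(r)
  if (sum(baseIdx) < 2L) baseIdx <- seq.int(max(1L, nb - 2L), nb)
  baseline <- stats::median(p[baseIdx])
  sigma <- stats::mad(diff(p)) / sqrt(2)
  prom <- max(3 * sigma, 0.02 * diff(range(p)))
  flags <- character()
  dPlug <- dInner <- dOuter <- NA_real_
  sePlug <- seInner <- seOuter <- NA_real_

  # --- plug: half-contrast radius of the central extremum
  v0 <- p[1]
  sp <- polarity[["plug"]]
  rPlug <- NA_real_
  if (sp * (v0 - baseline) > prom) {
    half <- (v0 + baseline) / 2
    below <- which(sp * (p - baseline) <= sp * (half - baseline))
    below <- below[below > 1L]
    if (length(below)) {
      i <- below[1]
      tfrac <- (half - p[i - 1]) / (p[i] - p[i - 1])
      tfrac <- max(0, min(1, tfrac))
      rPlug <- r[i - 1] + tfrac * bw
      dPlug <- 2 * rPlug
      slope <- (p[i] - p[i - 1]) / bw
      sePlug <- 2 * sqrt((bw / 2)^2 + (sigma / max(abs(slope), 1e-12))^2)
    }
  }
  if (is.na(dPlug)) flags <- c(flags, "plug_missing")

  # --- ring ridges: strongest local extremum of the stated polarity
  findRidge <- function(sgn, rMin) {
    idx <- 2:(nb - 1L)
    isExt <- sgn * (p[idx] - p[idx - 1L]) >= 0 & sgn * (p[idx] - p[idx + 1L]) >= 0 &
      (sgn * (p[idx] - p[idx - 1L]) > 0 | sgn * (p[idx] - p[idx + 1L]) > 0)
    cand <- idx[isExt & r[idx] > rMin & sgn * (p[idx] - baseline) > prom]
    if (!length(cand)) return(NULL)
    i <- cand[which.max(sgn * (p[cand] - baseline))]
    off <- parabolicOffset(p[i - 1L], p[i], p[i + 1L])
    se <- sqrt((bw / 2)^2 + (parabolaVertexSE(p[i - 1L], p[i], p[i + 1L], sigma) * bw)^2)
    list(radius = r[i] + off * bw, se = se)
  }
  rMinInner <- if (is.finite(rPlug)) rPlug else bw
  inner <- findRidge(polarity[["inner"]], rMinInner)
  if (!is.null(inner)) {
    dInner <- 2 * inner$radius; seInner <- 2 * inner$se
  } else flags <- c(flags, "inner_missing")
  rMinOuter <- if (!is.null(inner)) inner$radius else rMinInner
  outerRidge <- findRidge(polarity[["outer"]], rMinOuter)
  if (!is.null(outerRidge)) {
    dOuter <- 2 * outerRidge$radius; seOuter <- 2 * outerRidge$se
  } else flags <- c(flags, "outer_missing")

  d <- c(dPlug, dInner, dOuter)
  if (all(is.finite(d)) && !(d[1] < d[2] && d[2] < d[3]))
    flags <- c(flags, "order_violation")
  new("RingMeasurement", dPlug = dPlug, dInner = dInner, dOuter = dOuter,
      sePlug = sePlug, seInner = seInner, seOuter = seOuter, flags = flags)
}

#' Measure one pore end to end
#'
#' Convenience wrapper: refine the centre, optionally estimate and correct
#' tilt ellipticity (when the fitted axis ratio falls below
#' \code{deEllipseBelow}), compute the radial profile and measure ring
#' diameters.
#'
#' @param patch a \linkS4class{Micrograph} containing one pore.
#' @param binWidth radial bin width in nm (default: one pixel).
#' @param deEllipse logical; apply tilt correction when needed.
#' @param deEllipseBelow axis-ratio threshold triggering the correction.
#' @return A list with \code{center} (refined centre, nm), \code{profile},
#'   \code{measurement} and \code{tilt} (NULL unless estimated).
#' @export
measurePore <- function(patch, binWidth = NULL, deEllipse = TRUE,
                        deEllipseBelow = 0.97) {
  ctr <- refineCenter(patch)
  prof <- radialProfile(patch, centerNm = ctr$centerNm, binWidth = binWidth)
  meas <- measureRings(prof)
  tilt <- NULL
  if (deEllipse && is.finite(meas@dOuter)) {
    tilt <- tryCatch(
      estimateTilt(patch, ridgeRadiusNm = meas@dOuter / 2,
                   centerNm = ctr$centerNm),
      error = function(e) NULL)
    if (!is.null(tilt) && tilt@axisRatio < deEllipseBelow) {
      corrected <- deellipse(patch, tilt)
      ctr <- refineCenter(corrected)
      prof <- radialProfile(corrected, centerNm = ctr$centerNm,
                            binWidth = binWidth)
      meas <- measureRings(prof)
    }
  }
  list(center = ctr$centerNm, profile = prof, measurement = meas, tilt = tilt)
}
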