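#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' \code{pixels} and \code{pixelSize} extract the intensity matrix and the
#' physical pixel size of a \linkS4class{Micrograph} (or classes that carry
#' one); \code{detections}, \code{poreTruth}, \code{goldTruth},
#' \code{selectedOrder} and \code{scores} extract the corresponding tables
#' and results.
#'
#' @param x an object of the documented class.
#' @return The slot contents (matrix, numeric, data.frame, ...).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("detections", function(x) standardGeneric("detections"))

#' @rdname accessors
#' @export
setGeneric("poreTruth", function(x) standardGeneric("poreTruth"))

#' @rdname accessors
#' @export
setGeneric("goldTruth", function(x) standardGeneric("goldTruth"))

#' @rdname accessors
#' @export
setGeneric("selectedOrder", function(x) standardGeneric("selectedOrder"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("maskArea", function(x) standardGeneric("maskArea"))

#' @rdname accessors
#' @export
setMethod("pixels", "Micrograph", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("pixelSize", "Micrograph", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setMethod("provenance", "Micrograph", function(x) x@provenance)

#' @rdname accessors
#' @export
setMethod("pixelSize", "MembraneMask", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setMethod("maskArea", "MembraneMask", function(x) x@areaUm2)

#' @rdname accessors
#' @export
setMethod("maskArea", "DetectionTable", function(x) x@maskAreaUm2)

#' @rdname accessors
#' @export
setMethod("detections", "DetectionTable", function(x) x@detections)

#' @rdname accessors
#' @export
setMethod("poreTruth", "GroundTruth", function(x) x@pores)

#' @rdname accessors
#' @export
setMethod("goldTruth", "GroundTruth", function(x) x@gold)

#' @rdname accessors
#' @export
setMethod("selectedOrder", "SymmetryScan", function(x) x@selectedN)

#' @rdname accessors
#' @export
setMethod("scores", "SymmetryScan", function(x) {
  stats::setNames(x@scores, x@orders)
})

setMethod("show", "Micrograph", function(object) {
  cat(sprintf("Micrograph: %d x %d px, %.3g nm/px (%.3g x %.3g nm)\n",
              nrow(object@pixels), ncol(object@pixels), object@pixelSize,
              ncol(object@pixels) * object@pixelSize,
              nrow(object@pixels) * object@pixelSize))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@pixels), max(object@pixels)))
  if (length(object@provenance))
    cat("  provenance:", paste(object@provenance, collapse = " | "), "\n")
})

setMethod("show", "PoreModel", function(object) {
  cat(sprintf("PoreModel: plug/inner/outer = %.3g/%.3g/%.3g nm, %d-fold (amplitude %.2g)\n",
              object@dPlug, object@dInner, object@dOuter, object@nFold,
              object@subunitAmplitude))
  if (object@tiltDeg > 0)
    cat(sprintf("  tilt %.3g deg about axis %.3g deg\n",
                object@tiltDeg, object@tiltAxisDeg))
})

setMethod("show", "PoreClassMix", function(object) {
  cat(sprintf("PoreClassMix of %d class(es): proportions %s\n",
              length(object@models),
              paste(signif(object@proportions, 3), collapse = ", ")))
})

setMethod("show", "SheetScene", function(object) {
  cat(sprintf("SheetScene: %.4g x %.4g nm (%s mask), %.4g pores/um^2, hard core %.3g nm\n",
              object@widthNm, object@heightNm, object@maskType,
              object@density, object@minSeparation))
  cat(sprintf("  pixel %.3g nm, PSF sigma %.3g nm, noise sigma %.3g, seed %d\n",
              object@pixelSize, object@psfSigma, object@noiseSigma, object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d pores, %d gold particles\n",
              nrow(object@pores), nrow(object@gold)))
})

setMethod("show", "MembraneMask", function(object) {
  cat(sprintf("MembraneMask: %d x %d px, area %.4g um^2\n",
              nrow(object@mask), ncol(object@mask), object@areaUm2))
})

setMethod("show", "DetectionTable", function(object) {
  cat(sprintf("DetectionTable: %d detections on %.4g um^2 (%.4g per um^2)\n",
              nrow(object@detections), object@maskAreaUm2,
              nrow(object@detections) / object@maskAreaUm2))
})

setMethod("show", "RadialProfile", function(object) {
  cat(sprintf("RadialProfile: %d bins of %.3g nm, radius span [0, %.4g] nm\n",
              length(object@binCenters), object@binWidth,
              max(object@binCenters) + object@binWidth / 2))
})

setMethod("show", "RingMeasurement", function(object) {
  fmt <- function(d, se) if (is.na(d)) "missing" else sprintf("%.2f +/- %.2f nm", d, se)
  cat("RingMeasurement:\n")
  cat("  plug  :", fmt(object@dPlug, object@sePlug), "\n")
  cat("  inner :", fmt(object@dInner, object@seInner), "\n")
  cat("  outer :", fmt(object@dOuter, object@seOuter), "\n")
  if (length(object@flags)) cat("  flags :", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "TiltEstimate", function(object) {
  cat(sprintf("TiltEstimate: axis ratio %.4f -> tilt %.2f deg (major axis %.1f deg)%s\n",
              object@axisRatio, object@tiltDeg, object@orientationDeg,
              if (object@highTilt) " [tilt > 10 deg]" else ""))
})

setMethod("show", "SymmetryScan", function(object) {
  cat("SymmetryScan:\n")
  for (i in seq_along(object@orders))
    cat(sprintf("  n = %2d (%5.1f deg): score %+0.4f\n", object@orders[i],
                object@incrementsDeg[i], object@scores[i]))
  cat(sprintf("  control: %0.4f +/- %0.4f (se %0.4f, m = %d)\n",
              object@ctrlMean, object@ctrlSd, object@ctrlSe, object@mControls))
  cat(sprintf("  selected order: %s | spectrum harmonic: %d\n",
              if (is.na(object@selectedN)) "none" else object@selectedN,
              object@spectrumHarmonic))
})

setMethod("show", "GoldParticleSet", function(object) {
  ref <- if (nrow(object@pores)) sprintf("%d pores", nrow(object@pores))
         else "membrane trace"
  cat(sprintf("GoldParticleSet: %d particles vs %s, threshold %.3g nm (%s distance)\n",
              nrow(object@particles), ref, object@thresholdNm, object@mode))
})

setMethod("show", "AssociationResult", function(object) {
  cat(sprintf("AssociationResult: %d associated / %d not (fraction %.3f) at %.3g nm\n",
              object@nAssociated, object@nNot, object@fraction,
              object@thresholdNm))
  if (!is.na(object@pValue))
    cat(sprintf("  permutation p-value: %.4g\n", object@pValue))
})
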