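#' @import methods
NULL

# ---------------------------------------------------------------------------
# Image carrier
# ---------------------------------------------------------------------------

#' Micrograph: a 2D intensity image with a physical pixel size
#'
#' The universal image carrier of the package. Pixel \code{(i, j)} (1-based
#' row, column) has physical coordinates \code{x = (j - 1) * pixelSize},
#' \code{y = (i - 1) * pixelSize} in nanometres, i.e. 0-based pixel centres
#' lie on integer multiples of the pixel size.
#'
#' @slot pixels numeric matrix of intensities (rows = y, columns = x).
#' @slot pixelSize physical pixel size in nm/pixel.
#' @slot provenance free-text processing history, one entry per step.
#' @slot meta list of generator/acquisition metadata (ground-truth parameters
#'   are echoed here for synthetic renders).
#' @export
setClass("Micrograph", representation(
  pixels = "matrix",
  pixelSize = "numeric",
  provenance = "character",
  meta = "list"
))

setValidity("Micrograph", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 16L || ncol(p) < 16L) return("image must be at least 16 x 16 pixels")
  if (!all(is.finite(p))) return("all pixel values must be finite")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0) return("pixelSize must be a single positive number")
  TRUE
})

#' Construct a Micrograph
#'
#' @param pixels numeric matrix of intensities.
#' @param pixelSize pixel size in nm/pixel.
#' @param provenance character vector of processing notes.
#' @return A \linkS4class{Micrograph}.
#' @examples
#' m <- Micrograph(matrix(rnorm(32 * 32), 32), pixelSize = 0.69)
#' pixelSize(m)
#' @export
Micrograph <- function(pixels, pixelSize, provenance = character(),
                       meta = list()) {
  new("Micrograph", pixels = pixels, pixelSize = as.numeric(pixelSize),
      provenance = provenance, meta = meta)
}

# ---------------------------------------------------------------------------
# Parametric pore model and scene description
# ---------------------------------------------------------------------------

#' Parametric model of a ring/plug pore complex
#'
#' Describes one pore class as seen en face: a central electron-dense plug,
#' a thin inner ring and a thicker outer ring whose intensity is optionally
#' modulated n-fold around the azimuth (discrete subunits). Diameters refer
#' to the annulus ridge (intensity peak) line; the plug diameter is the full
#' width at half contrast of the central disk. Contrasts are signed relative
#' to the membrane background; negative means electron-dense (darker).
#'
#' @slot dPlug,dInner,dOuter plug / inner-ring / outer-ring diameters (nm).
#' @slot nFold integer subunit count of the outer ring.
#' @slot subunitAmplitude angular modulation depth of the outer ring, in [0, 1].
#' @slot ringWidthPlug plug edge width (Gaussian sigma of the edge, nm).
#' @slot ringWidthInner,ringWidthOuter Gaussian radial sigma of each annulus (nm).
#' @slot contrastPlug,contrastInner,contrastOuter signed contrasts.
#' @slot basketDepth basket depth (nm); stored as metadata only, never rendered
#'   (the analysis is strictly 2D en face).
#' @slot tiltDeg membrane tilt (degrees); rendered as in-plane foreshortening
#'   by cos(tilt) along the tilt axis.
#' @slot tiltAxisDeg tilt axis orientation (degrees from the x axis).
#' @slot phaseDeg azimuthal phase of the subunit modulation (degrees).
#' @export
setClass("PoreModel", representation(
  dPlug = "numeric", dInner = "numeric", dOuter = "numeric",
  nFold = "integer", subunitAmplitude = "numeric",
  ringWidthPlug = "numeric", ringWidthInner = "numeric",
  ringWidthOuter = "numeric",
  contrastPlug = "numeric", contrastInner = "numeric",
  contrastOuter = "numeric",
  basketDepth = "numeric", tiltDeg = "numeric", tiltAxisDeg = "numeric",
  phaseDeg = "numeric"
))

setValidity("PoreModel", function(object) {
  if (!(object@dPlug > 0 && object@dPlug < object@dInner &&
        object@dInner < object@dOuter))
    return("diameters must satisfy 0 < dPlug < dInner < dOuter")
  if (object@nFold < 1L) return("nFold must be >= 1")
  if (object@subunitAmplitude < 0 || object@subunitAmplitude > 1)
    return("subunitAmplitude must lie in [0, 1]")
  if (any(c(object@ringWidthPlug, object@ringWidthInner,
            object@ringWidthOuter) <= 0))
    return("all ring widths must be > 0")
  if (object@tiltDeg < 0 || object@tiltDeg >= 45)
    return("tiltDeg must lie in [0, 45)")
  if (object@tiltAxisDeg < 0 || object@tiltAxisDeg >= 180)
    return("tiltAxisDeg must lie in [0, 180)")
  TRUE
})

#' Construct a PoreModel
#'
#' Defaults describe the large pore class of the Gemmata obscuriglobus
#' internal membranes: 33.5 nm outer ring, 17.5 nm inner ring, 9.5 nm plug,
#' 8-fold subunit structure. Negative-stain polarity: plug dark, inner ring
#' bright, outer ring dark.
#'
#' @param dPlug,dInner,dOuter ridge diameters in nm.
#' @param nFold subunit count (rotational order) of the outer ring.
#' @param subunitAmplitude modulation depth in [0, 1]; 0 renders a circularly
#'   symmetric pore.
#' @param ringWidthPlug plug edge sigma (nm).
#' @param ringWidthInner,ringWidthOuter annulus radial sigma (nm).
#' @param contrastPlug,contrastInner,contrastOuter signed contrasts relative
#'   to the background intensity.
#' @param basketDepth metadata-only basket depth (nm).
#' @param tiltDeg,tiltAxisDeg membrane tilt magnitude and axis (degrees).
#' @param phaseDeg azimuthal subunit phase (degrees).
#' @return A \linkS4class{PoreModel}.
#' @examples
#' PoreModel()                    # large pore class
#' PoreModel(tiltDeg = 8)         # same, foreshortened by cos(8 deg)
#' @export
PoreModel <- function(dPlug = 9.5, dInner = 17.5, dOuter = 33.5, nFold = 8L,
                      subunitAmplitude = 0.3, ringWidthPlug = 1.2,
                      ringWidthInner = 1.4, ringWidthOuter = 2.2,
                      contrastPlug = -0.5, contrastInner = 0.3,
                      contrastOuter = -0.4, basketDepth = 25,
                      tiltDeg = 0, tiltAxisDeg = 0, phaseDeg = 0) {
  new("PoreModel", dPlug = dPlug, dInner = dInner, dOuter = dOuter,
      nFold = as.integer(nFold), subunitAmplitude = subunitAmplitude,
      ringWidthPlug = ringWidthPlug, ringWidthInner = ringWidthInner,
      ringWidthOuter = ringWidthOuter, contrastPlug = contrastPlug,
      contrastInner = contrastInner, contrastOuter = contrastOuter,
      basketDepth = basketDepth, tiltDeg = tiltDeg,
      tiltAxisDeg = tiltAxisDeg, phaseDeg = phaseDeg)
}

#' Preset pore models
#'
#' Three pore classes are modelled. \code{"large"}: 33.5 nm outer ring,
#' 17.5 nm inner ring, 9.5 nm plug, 8-fold subunits (the class comparable to
#' the eukaryote nuclear pore complex). \code{"medium"}: a single 14.5 nm ring
#' with a 5 nm dense centre and no inner ring (inner contrast 0).
#' \code{"small"}: 6 nm rings with a dense centre.
#'
#' @param class one of \code{"large"}, \code{"medium"}, \code{"small"}.
#' @return A \linkS4class{PoreModel}.
#' @examples
#' poreModelPreset("medium")
#' @export
poreModelPreset <- function(class = c("large", "medium", "small")) {
  class <- match.arg(class)
  switch(class,
    large = PoreModel(),
    medium = PoreModel(dPlug = 5, dInner = 9.75, dOuter = 14.5, nFold = 8L,
                       subunitAmplitude = 0, ringWidthPlug = 1.0,
                       ringWidthInner = 1.0, ringWidthOuter = 1.4,
                       contrastPlug = -0.5, contrastInner = 0,
                       contrastOuter = -0.4, basketDepth = 0),
    small = PoreModel(dPlug = 2.5, dInner = 4.25, dOuter = 6, nFold = 8L,
                      subunitAmplitude = 0, ringWidthPlug = 0.7,
                      ringWidthInner = 0.7, ringWidthOuter = 0.9,
                      contrastPlug = -0.5, contrastInner = 0,
                      contrastOuter = -0.4, basketDepth = 0)
  )
}

#' Mixture of pore classes
#'
#' @slot models list of \linkS4class{PoreModel}.
#' @slot proportions mixing proportions (non-negative, sum to 1).
#' @export
setClass("PoreClassMix", representation(
  models = "list", proportions = "numeric"
))

setValidity("PoreClassMix", function(object) {
  if (length(object@models) != length(object@proportions))
    return("models and proportions must have equal length")
  if (!all(vapply(object@models, is, logical(1), "PoreModel")))
    return("all mixture components must be PoreModel objects")
  if (any(object@proportions < 0)) return("proportions must be >= 0")
  if (abs(sum(object@proportions) - 1) > 1e-8)
    return("proportions must sum to 1")
  TRUE
})

#' Construct a PoreClassMix
#' @param models list of \linkS4class{PoreModel} (a single model is accepted).
#' @param proportions mixing proportions summing to 1.
#' @return A \linkS4class{PoreClassMix}.
#' @export
PoreClassMix <- function(models, proportions = NULL) {
  if (is(models, "PoreModel")) models <- list(models)
  if (is.null(proportions)) proportions <- rep(1 / length(models), length(models))
  new("PoreClassMix", models = models, proportions = as.numeric(proportions))
}

#' Scene description for a synthetic membrane sheet
#'
#' Describes a rectangular field of view containing a membrane sheet region
#' (the full frame or an inscribed ellipse, the "canoe") carrying pores at a
#' stated areal density with a hard-core minimum separation.
#'
#' @slot widthNm,heightNm field of view in nm.
#' @slot maskType \code{"full"} (whole frame is membrane) or \code{"ellipse"}
#'   (inscribed ellipse).
#' @slot density pores per square micron.
#' @slot minSeparation hard-core centre-to-centre distance (nm).
#' @slot poreMix \linkS4class{PoreClassMix} of pore classes.
#' @slot noiseSigma additive Gaussian noise s.d. (intensity units).
#' @slot psfSigma Gaussian point-spread sigma (nm).
#' @slot pixelSize nm per pixel.
#' @slot seed RNG seed making the scene fully reproducible.
#' @slot backgroundMembrane,backgroundExterior mean intensities inside and
#'   outside the sheet.
#' @slot edgeMarginNm pore centres are kept at least this far inside the mask
#'   boundary so rendered rings are complete (0 disables).
#' @export
setClass("SheetScene", representation(
  widthNm = "numeric", heightNm = "numeric", maskType = "character",
  density = "numeric", minSeparation = "numeric", poreMix = "PoreClassMix",
  noiseSigma = "numeric", psfSigma = "numeric", pixelSize = "numeric",
  seed = "integer", backgroundMembrane = "numeric",
  backgroundExterior = "numeric", edgeMarginNm = "numeric"
))

setValidity("SheetScene", function(object) {
  if (object@density < 0) return("density must be >= 0")
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  if (!object@maskType %in% c("full", "ellipse"))
    return("maskType must be 'full' or 'ellipse'")
  dmax <- max(vapply(object@poreMix@models, function(m) m@dOuter, numeric(1)))
  if (object@minSeparation < dmax)
    return(sprintf("minSeparation (%g nm) must be >= largest outer diameter (%g nm)",
                   object@minSeparation, dmax))
  # packing feasibility: density [um^-2] x pi (minSep/2)^2 [nm^2] x 1e-6
  pack <- object@density * pi * (object@minSeparation / 2)^2 * 1e-6
  if (pack >= 0.55)
    return(sprintf("infeasible packing fraction %.2f (must be < 0.55)", pack))
  TRUE
})

#' Construct a SheetScene
#'
#' Defaults describe a 2 x 2 um membrane sheet at the density observed on
#' sonication-lysed membranes (87 pores per square micron), imaged at
#' 0.69 nm/pixel with SNR 5 relative to the outer-ring contrast.
#'
#' @param widthNm,heightNm field of view (nm).
#' @param maskType \code{"full"} or \code{"ellipse"}.
#' @param density pores per square micron.
#' @param minSeparation hard-core distance (nm).
#' @param poreMix \linkS4class{PoreClassMix}; default = large pore class only.
#' @param noiseSigma additive Gaussian noise s.d.
#' @param psfSigma Gaussian PSF sigma (nm).
#' @param pixelSize nm/pixel.
#' @param seed integer RNG seed.
#' @param backgroundMembrane,backgroundExterior background intensities.
#' @param edgeMarginNm margin keeping pore centres inside the mask
#'   (default: largest outer radius).
#' @return A \linkS4class{SheetScene}.
#' @examples
#' sc <- SheetScene(widthNm = 1000, heightNm = 1000, density = 87, seed = 7)
#' @export
SheetScene <- function(widthNm = 2000, heightNm = 2000, maskType = "full",
                       density = 87, minSeparation = 40,
                       poreMix = PoreClassMix(PoreModel()),
                       noiseSigma = 0.08, psfSigma = 1.0, pixelSize = 0.69,
                       seed = 1L, backgroundMembrane = 0.5,
                       backgroundExterior = 0.35, edgeMarginNm = NULL) {
  if (is(poreMix, "PoreModel")) poreMix <- PoreClassMix(poreMix)
  if (is.null(edgeMarginNm))
    edgeMarginNm <- max(vapply(poreMix@models, function(m) m@dOuter, numeric(1))) / 2
  new("SheetScene", widthNm = widthNm, heightNm = heightNm,
      maskType = maskType, density = density, minSeparation = minSeparation,
      poreMix = poreMix, noiseSigma = noiseSigma, psfSigma = psfSigma,
      pixelSize = pixelSize, seed = as.integer(seed),
      backgroundMembrane = backgroundMembrane,
      backgroundExterior = backgroundExterior, edgeMarginNm = edgeMarginNm)
}

#' Ground truth for a synthetic scene
#'
#' @slot pores data.frame with columns \code{pore_id, x_nm, y_nm, class,
#'   n_fold, tilt_deg}.
#' @slot gold data.frame with columns \code{gold_id, x_nm, y_nm,
#'   intended_associated, nearest_pore_id, distance_nm} (0 rows until
#'   \code{\link{placeGold}} is run).
#' @export
setClass("GroundTruth", representation(pores = "data.frame", gold = "data.frame"))

groundTruthPoreCols <- c("pore_id", "x_nm", "y_nm", "class", "n_fold", "tilt_deg")
groundTruthGoldCols <- c("gold_id", "x_nm", "y_nm", "intended_associated",
                         "nearest_pore_id", "distance_nm")

setValidity("GroundTruth", function(object) {
  if (!identical(names(object@pores), groundTruthPoreCols))
    return("pore table must have columns pore_id, x_nm, y_nm, class, n_fold, tilt_deg")
  if (!identical(names(object@gold), groundTruthGoldCols))
    return("gold table must have columns gold_id, x_nm, y_nm, intended_associated, nearest_pore_id, distance_nm")
  TRUE
})

emptyGoldTable <- function() {
  data.frame(gold_id = integer(), x_nm = numeric(), y_nm = numeric(),
             intended_associated = logical(), nearest_pore_id = integer(),
             distance_nm = numeric())
}

# ---------------------------------------------------------------------------
# Detection / morphometry / symmetry / gold result carriers
# ---------------------------------------------------------------------------

#' Membrane sheet mask
#'
#' @slot mask logical matrix (TRUE = membrane).
#' @slot pixelSize nm/pixel.
#' @slot areaUm2 mask area in square microns.
#' @export
setClass("MembraneMask", representation(
  mask = "matrix", pixelSize = "numeric", areaUm2 = "numeric"
))

setValidity("MembraneMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  if (object@areaUm2 <= 0) return("mask area must be > 0")
  expected <- sum(object@mask) * object@pixelSize^2 * 1e-6
  if (abs(expected - object@areaUm2) > 1e-9 * max(1, expected))
    return("areaUm2 inconsistent with pixel count and pixel size")
  TRUE
})

MembraneMask <- function(mask, pixelSize) {
  new("MembraneMask", mask = mask, pixelSize = pixelSize,
      areaUm2 = sum(mask) * pixelSize^2 * 1e-6)
}

#' Table of detected pores
#'
#' @slot detections data.frame with columns \code{detection_id, x_nm, y_nm,
#'   ridge_radius_nm, score, edge_flag}.
#' @slot params list echoing the search parameters (radius grid, threshold,
#'   minimum separation, template width).
#' @slot maskAreaUm2 area of the searched membrane mask in square microns.
#' @export
setClass("DetectionTable", representation(
  detections = "data.frame", params = "list", maskAreaUm2 = "numeric"
))

setValidity("DetectionTable", function(object) {
  d <- object@detections
  need <- c("detection_id", "x_nm", "y_nm", "ridge_radius_nm", "score", "edge_flag")
  if (!identical(names(d), need))
    return("detections must have columns detection_id, x_nm, y_nm, ridge_radius_nm, score, edge_flag")
  if (nrow(d) && (any(d$score < -1 - 1e-9) || any(d$score > 1 + 1e-9)))
    return("scores must lie in [-1, 1]")
  if (object@maskAreaUm2 <= 0) return("maskAreaUm2 must be > 0")
  ms <- object@params$minSeparation
  if (!is.null(ms) && nrow(d) > 1L) {
    dd <- as.matrix(stats::dist(d[, c("x_nm", "y_nm")]))
    diag(dd) <- Inf
    if (min(dd) < ms - 1e-9)
      return("detections violate the minimum separation constraint")
  }
  TRUE
})

#' Radial intensity profile of a pore patch
#'
#' @slot binCenters annulus bin centres (nm).
#' @slot intensity mean intensity per bin.
#' @slot counts pixels per bin.
#' @slot binWidth bin width (nm).
#' @export
setClass("RadialProfile", representation(
  binCenters = "numeric", intensity = "numeric", counts = "integer",
  binWidth = "numeric"
))

setValidity("RadialProfile", function(object) {
  n <- length(object@binCenters)
  if (length(object@intensity) != n || length(object@counts) != n)
    return("binCenters, intensity and counts must have equal length")
  if (any(object@counts <= 0L)) return("every bin must contain pixels")
  if (object@binWidth <= 0) return("binWidth must be > 0")
  TRUE
})

#' Ring diameter measurements for one pore
#'
#' Estimated diameters in nm with per-estimate uncertainties (half bin width
#' combined in quadrature with the parabolic peak-fit standard error).
#' Missing features are flagged, never guessed.
#'
#' @slot dPlug,dInner,dOuter estimated diameters (nm; NA when flagged missing).
#' @slot sePlug,seInner,seOuter uncertainties (nm).
#' @slot flags character vector, subset of \code{"plug_missing"},
#'   \code{"inner_missing"}, \code{"outer_missing"}, \code{"order_violation"}.
#' @export
setClass("RingMeasurement", representation(
  dPlug = "numeric", dInner = "numeric", dOuter = "numeric",
  sePlug = "numeric", seInner = "numeric", seOuter = "numeric",
  flags = "character"
))

setValidity("RingMeasurement", function(object) {
  d <- c(object@dPlug, object@dInner, object@dOuter)
  if (all(is.finite(d)) && !(d[1] < d[2] && d[2] < d[3]) &&
      !("order_violation" %in% object@flags))
    return("diameters out of order must carry the order_violation flag")
  TRUE
})

#' Tilt (ellipticity) estimate of a pore patch
#'
#' @slot axisRatio minor/major axis ratio in (0, 1].
#' @slot tiltDeg implied membrane tilt, \code{acos(axisRatio)} in degrees.
#' @slot orientationDeg major-axis orientation (degrees from the x axis,
#'   in [0, 180)).
#' @slot highTilt TRUE when tiltDeg exceeds 10 degrees (larger tilts were not
#'   part of the analysed regime and the affine foreshortening model degrades).
#' @export
setClass("TiltEstimate", representation(
  axisRatio = "numeric", tiltDeg = "numeric", orientationDeg = "numeric",
  highTilt = "logical"
))

setValidity("TiltEstimate", function(object) {
  if (object@axisRatio <= 0 || object@axisRatio > 1 + 1e-9)
    return("axisRatio must lie in (0, 1]")
  if (object@tiltDeg < 0) return("tiltDeg must be >= 0")
  TRUE
})

#' Result of a rotational-symmetry scan
#'
#' Markham reinforcement scores for candidate orders plus a random-rotation
#' control and the independent angular-power-spectrum cross-check.
#'
#' @slot orders candidate rotational orders.
#' @slot incrementsDeg rotation increments, exactly 360/n degrees.
#' @slot scores reinforcement score per order (mean rotational
#'   self-correlation of the azimuthal component, in [-1, 1]).
#' @slot ctrlMean,ctrlSd mean and s.d. of the single-angle random-rotation
#'   control correlations.
#' @slot ctrlSe standard error of the control mean (ctrlSd / sqrt(m)).
#' @slot mControls number of control angles.
#' @slot selectedN selected order (NA integer when no order beats the control).
#' @slot spectrumHarmonic dominant angular harmonic (independent check).
#' @slot epsilon score tie tolerance used by the largest-n tie-break.
#' @slot minMargin minimum score excess over the control mean.
#' @slot seed control RNG seed.
#' @slot bandNm radial band (nm) on which correlations were computed.
#' @export
setClass("SymmetryScan", representation(
  orders = "integer", incrementsDeg = "numeric", scores = "numeric",
  ctrlMean = "numeric", ctrlSd = "numeric", ctrlSe = "numeric",
  mControls = "integer", selectedN = "integer", spectrumHarmonic = "integer",
  epsilon = "numeric", minMargin = "numeric", seed = "integer",
  bandNm = "numeric"
))

setValidity("SymmetryScan", function(object) {
  if (length(object@incrementsDeg) != length(object@orders) ||
      length(object@scores) != length(object@orders))
    return("orders, incrementsDeg and scores must align")
  if (any(abs(object@incrementsDeg - 360 / object@orders) > 1e-9))
    return("increments must equal 360/n")
  ok <- is.finite(object@scores)
  if (any(object@scores[ok] < -1 - 1e-9 | object@scores[ok] > 1 + 1e-9))
    return("scores must lie in [-1, 1]")
  if (!is.na(object@selectedN) && !(object@selectedN %in% object@orders))
    return("selectedN must be one of the candidate orders or NA")
  TRUE
})

#' Immunogold particle set with reference structures
#'
#' @slot particles data.frame with columns \code{gold_id, x_nm, y_nm}.
#' @slot pores data.frame with columns \code{x_nm, y_nm, outer_radius_nm}
#'   (0 rows when the reference is a membrane trace).
#' @slot membrane a \linkS4class{MembraneMask}, polyline matrix (columns
#'   x_nm, y_nm) or NULL, stored in a 1-element list.
#' @slot thresholdNm association distance threshold (nm, inclusive).
#' @slot mode \code{"edge"} (distance to the pore outer-ring edge) or
#'   \code{"center"} (distance to the pore centre).
#' @export
setClass("GoldParticleSet", representation(
  particles = "data.frame", pores = "data.frame", membrane = "list",
  thresholdNm = "numeric", mode = "character"
))

setValidity("GoldParticleSet", function(object) {
  if (!all(c("gold_id", "x_nm", "y_nm") %in% names(object@particles)))
    return("particles must have columns gold_id, x_nm, y_nm")
  if (object@thresholdNm <= 0) return("thresholdNm must be > 0")
  if (!object@mode %in% c("edge", "center"))
    return("mode must be 'edge' or 'center'")
  hasPores <- nrow(object@pores) > 0L
  hasMembrane <- length(object@membrane) == 1L && !is.null(object@membrane[[1L]])
  if (!hasPores && !hasMembrane)
    return("at least one reference structure (pores or membrane) is required")
  if (hasPores && !all(c("x_nm", "y_nm", "outer_radius_nm") %in% names(object@pores)))
    return("pores must have columns x_nm, y_nm, outer_radius_nm")
  TRUE
})

#' Construct a GoldParticleSet
#'
#' @param particles data.frame with columns gold_id, x_nm, y_nm (gold_id is
#'   added when absent).
#' @param pores data.frame of reference pores (x_nm, y_nm, outer_radius_nm),
#'   or a \linkS4class{DetectionTable}.
#' @param membrane optional \linkS4class{MembraneMask} or polyline matrix with
#'   columns x_nm, y_nm; used when \code{pores} is NULL.
#' @param thresholdNm association threshold in nm (default 20, inclusive).
#' @param mode \code{"edge"} or \code{"center"} distance convention.
#' @return A \linkS4class{GoldParticleSet}.
#' @export
GoldParticleSet <- function(particles, pores = NULL, membrane = NULL,
                            thresholdNm = 20, mode = c("edge", "center")) {
  mode <- match.arg(mode)
  particles <- as.data.frame(particles)
  if (!"gold_id" %in% names(particles))
    particles$gold_id <- seq_len(nrow(particles))
  particles <- particles[, c("gold_id", "x_nm", "y_nm")]
  if (is(pores, "DetectionTable"))
    pores <- data.frame(x_nm = pores@detections$x_nm,
                        y_nm = pores@detections$y_nm,
                        outer_radius_nm = pores@detections$ridge_radius_nm)
  if (is.null(pores))
    pores <- data.frame(x_nm = numeric(), y_nm = numeric(),
                        outer_radius_nm = numeric())
  new("GoldParticleSet", particles = particles, pores = as.data.frame(pores),
      membrane = list(membrane), thresholdNm = thresholdNm, mode = mode)
}

#' Association counts for immunogold particles
#'
#' @slot particles per-particle table: \code{gold_id, x_nm, y_nm, distance_nm,
#'   associated}.
#' @slot nAssociated,nNot counts.
#' @slot fraction associated fraction.
#' @slot pValue permutation p-value (NA until computed).
#' @slot thresholdNm threshold used.
#' @export
setClass("AssociationResult", representation(
  particles = "data.frame", nAssociated = "integer", nNot = "integer",
  fraction = "numeric", pValue = "numeric", thresholdNm = "numeric"
))

setValidity("AssociationResult", function(object) {
  if (object@nAssociated + object@nNot != nrow(object@particles))
    return("nAssociated + nNot must equal the particle count")
  if (nrow(object@particles) > 0L &&
      (object@fraction < 0 || object@fraction > 1))
    return("fraction must lie in [0, 1]")
  TRUE
})
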