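#' @include AllClasses.R
NULL

# ---------------------------------------------------------------------------
# Minimal MRC mode-2 (float32) reader/writer. The 1024-byte header follows the
# MRC2014 layout: nx/ny/nz, mode, starts, sampling grid, cell dimensions in
# Angstrom (cella = n * pixel_size_nm * 10), axis order x fastest.
# ---------------------------------------------------------------------------

readMRC <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  if (mode != 2L)
    stop(sprintf("unsupported MRC mode %d (only mode 2, float32, is supported)", mode))
  if (nz != 1L) stop("only single-section (nz = 1) MRC files are supported")
  cella <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  seek(con, where = 1024, origin = "start")
  v <- readBin(con, "numeric", n = nx * ny, size = 4L, endian = "little")
  pixelSize <- if (hdr[8] > 0 && cella[1] > 0) cella[1] / hdr[8] / 10 else NA_real_
  list(pixels = t(matrix(v, nrow = nx, ncol = ny)), pixelSizeNm = pixelSize)
}

writeMRC <- function(m, path) {
  px <- m@pixels
  nx <- ncol(px); ny <- nrow(px)
  con <- file(path, "wb")
  on.exit(close(con))
  ints <- integer(256)
  ints[1:3] <- c(nx, ny, 1L)          # nx ny nz
  ints[4] <- 2L                       # mode 2 = float32
  ints[8:10] <- c(nx, ny, 1L)         # mx my mz
  ints[17:19] <- c(1L, 2L, 3L)        # mapc mapr maps
  writeBin(ints[1:10], con, size = 4L, endian = "little")
  writeBin(as.numeric(c(nx, ny, 1) * m@pixelSize * 10), con, size = 4L,
           endian = "little")         # cella (Angstrom)
  writeBin(as.numeric(c(90, 90, 90)), con, size = 4L, endian = "little")
  writeBin(ints[17:19], con, size = 4L, endian = "little")
  writeBin(as.numeric(c(min(px), max(px), mean(px))), con, size = 4L,
           endian = "little")         # dmin dmax dmean
  # remaining header words up to byte 208, then "MAP " + machine stamp + rms
  writeBin(integer(30), con, size = 4L, endian = "little")
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)
  writeBin(as.numeric(stats::sd(px)), con, size = 4L, endian = "little")
  writeBin(integer(201), con, size = 4L, endian = "little")  # nlabl + labels
  writeBin(as.numeric(t(px)), con, size = 4L, endian = "little")
  invisible(path)
}

sidecarPath <- function(path) paste0(path, ".json")

# ---------------------------------------------------------------------------
# Micrograph read/write
# ---------------------------------------------------------------------------

#' Read a micrograph from TIFF or MRC
#'
#' TIFF files are read as raw sample values (integer inputs are promoted to
#' doubles without rescaling) unless a JSON sidecar written by
#' \code{\link{writeMicrograph}} records the original intensity scale, in
#' which case the original intensities are restored. The pixel size is taken
#' from the MRC header, the JSON sidecar (\code{<file>.json}, field
#' \code{pixel_size_nm}), or the override -- in that order of preference;
#' a missing pixel size is an error, never a silent default.
#'
#' @param path path to a \code{.tif}/\code{.tiff} or \code{.mrc} file.
#' @param pixelSizeOverride optional pixel size in nm/pixel.
#' @return A \linkS4class{Micrograph}.
#' @export
readMicrograph <- function(path, pixelSizeOverride = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  sidecar <- if (file.exists(sidecarPath(path)))
    jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE) else NULL
  if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
    px <- matrix(as.numeric(raw), nrow(raw), ncol(raw))
    if (!is.null(sidecar$intensity_min) && !is.null(sidecar$intensity_max)) {
      scale <- (sidecar$intensity_max - sidecar$intensity_min) / 65535
      px <- sidecar$intensity_min + px * scale
    }
    pixelSize <- pixelSizeOverride %||% sidecar$pixel_size_nm
    if (is.null(pixelSize))
      stop("pixel size unavailable: TIFF has no JSON sidecar and no override was given")
    Micrograph(px, pixelSize, provenance = sprintf("readMicrograph('%s')", path))
  } else if (ext == "mrc") {
    mrc <- readMRC(path)
    pixelSize <- pixelSizeOverride %||%
      (if (is.finite(mrc$pixelSizeNm)) mrc$pixelSizeNm else sidecar$pixel_size_nm)
    if (is.null(pixelSize) || !is.finite(pixelSize))
      stop("pixel size unavailable: MRC header has no cell dimensions and no override was given")
    Micrograph(mrc$pixels, pixelSize,
               provenance = sprintf("readMicrograph('%s')", path))
  } else {
    stop(sprintf("unknown micrograph format '.%s' (supported: TIFF, MRC mode 2)", ext))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a micrograph to TIFF (16-bit) or MRC mode 2
#'
#' The format is chosen from the file extension. TIFF output quantizes
#' intensities linearly to 16 bits and records the scale and the pixel size
#' in a JSON sidecar (\code{<file>.json}) so the read path can restore them;
#' MRC stores float32 samples and carries the pixel size in its header.
#'
#' @param m a \linkS4class{Micrograph}.
#' @param path output path ending in \code{.tif}, \code{.tiff} or \code{.mrc}.
#' @return The path, invisibly.
#' @export
writeMicrograph <- function(m, path) {
  stopifnot(is(m, "Micrograph"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    lo <- min(m@pixels); hi <- max(m@pixels)
    scaled <- if (hi > lo) (m@pixels - lo) / (hi - lo) else m@pixels * 0
    # writeTIFF stores round(x * 65535) for 16-bit output
    tiff::writeTIFF(scaled, path, bits.per.sample = 16L, compression = "none")
    writeJSONFile(list(pixel_size_nm = m@pixelSize, intensity_min = lo,
                       intensity_max = hi, bits = 16L), sidecarPath(path))
  } else if (ext == "mrc") {
    writeMRC(m, path)
    writeJSONFile(list(pixel_size_nm = m@pixelSize), sidecarPath(path))
  } else {
    stop(sprintf("unknown output format '.%s' (supported: TIFF, MRC)", ext))
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Patch extraction
# ---------------------------------------------------------------------------

#' Extract a square odd-sided patch centred on a physical coordinate
#'
#' The patch side is \code{2 * ceiling(radius / pixelSize) + 1} pixels and is
#' centred on the pixel nearest the requested centre. Windows crossing the
#' image border are an error; no padding is invented.
#'
#' @param m a \linkS4class{Micrograph}.
#' @param centerNm length-2 (x, y) centre in nm.
#' @param radiusNm patch half-width in nm.
#' @return A \linkS4class{Micrograph} patch; its metadata records the origin
#'   offset \code{originNm} (x, y of the patch's [1,1] pixel in the source
#'   image) and the originating centre.
#' @export
extractPatch <- function(m, centerNm, radiusNm) {
  stopifnot(is(m, "Micrograph"), length(centerNm) == 2L)
  ps <- m@pixelSize
  half <- ceiling(radiusNm / ps)
  ctrCol <- round(centerNm[1] / ps) + 1L
  ctrRow <- round(centerNm[2] / ps) + 1L
  rows <- (ctrRow - half):(ctrRow + half)
  cols <- (ctrCol - half):(ctrCol + half)
  if (min(rows) < 1L || min(cols) < 1L || max(rows) > nrow(m@pixels) ||
      max(cols) > ncol(m@pixels))
    stop(sprintf(paste0("patch window crosses the image border (centre %.4g, %.4g nm, ",
                        "radius %.4g nm)"), centerNm[1], centerNm[2], radiusNm))
  Micrograph(m@pixels[rows, cols], ps,
             provenance = c(m@provenance,
                            sprintf("extractPatch(%.4g, %.4g, r=%.4g)",
                                    centerNm[1], centerNm[2], radiusNm)),
             meta = c(m@meta,
                      list(originNm = c(x = (min(cols) - 1) * ps,
                                        y = (min(rows) - 1) * ps),
                           requestedCenterNm = centerNm)))
}

#' Stack of equally sized pore patches
#'
#' @slot patches list of \linkS4class{Micrograph}, all square with the same
#'   odd side length.
#' @slot centersNm matrix of originating centres (columns x, y) in nm.
#' @slot pixelSize nm/pixel.
#' @export
setClass("PatchStack", representation(
  patches = "list", centersNm = "matrix", pixelSize = "numeric"
))

setValidity("PatchStack", function(object) {
  if (length(object@patches) != nrow(object@centersNm))
    return("one centre per patch is required")
  sides <- vapply(object@patches, function(p) nrow(p@pixels), integer(1))
  if (length(sides) && (any(sides != sides[1]) ||
                        any(vapply(object@patches, function(p) ncol(p@pixels),
                                   integer(1)) != sides[1])))
    return("all patches must be square with identical side length")
  if (length(sides) && sides[1] %% 2L == 0L)
    return("patch side must be odd so a centre pixel exists")
  TRUE
})

#' Extract a stack of patches at listed centres
#'
#' @param m a \linkS4class{Micrograph}.
#' @param centersNm data.frame or matrix with x/y centre coordinates in nm
#'   (columns \code{x_nm}, \code{y_nm} or the first two columns).
#' @param radiusNm patch half-width in nm.
#' @return A \linkS4class{PatchStack}.
#' @export
extractPatches <- function(m, centersNm, radiusNm) {
  cc <- as.data.frame(centersNm)
  if (all(c("x_nm", "y_nm") %in% names(cc))) cc <- cc[, c("x_nm", "y_nm")]
  cc <- as.matrix(cc[, 1:2])
  patches <- lapply(seq_len(nrow(cc)), function(i)
    extractPatch(m, cc[i, ], radiusNm))
  new("PatchStack", patches = patches, centersNm = cc, pixelSize = m@pixelSize)
}

# ---------------------------------------------------------------------------
# Display filters
# ---------------------------------------------------------------------------

#' Fourier-domain Gaussian bandpass filter (display only)
#'
#' Difference-of-Gaussians bandpass with feature-size semantics: structures
#' larger than \code{lowCutPx} pixels and smaller than \code{highCutPx} pixels
#' are suppressed, with the Gaussian transfer functions crossing half
#' amplitude exactly at the two cutoff feature sizes. The mean intensity is
#' restored after filtering. Defaults (40, 3) match conservative display
#' filtering of cryo-EM pore images. The output is flagged in its provenance:
#' symmetry analysis refuses to run silently on bandpass-filtered input,
#' because rotational reinforcement must be computed on raw data only.
#'
#' @param m a \linkS4class{Micrograph}.
#' @param lowCutPx low-frequency cutoff as a feature size in pixels.
#' @param highCutPx high-frequency cutoff as a feature size in pixels.
#' @return The filtered \linkS4class{Micrograph}.
#' @export
bandpassFilter <- function(m, lowCutPx = 40, highCutPx = 3) {
  stopifnot(is(m, "Micrograph"))
  if (!(lowCutPx > highCutPx && highCutPx > 0))
    stop("cutoffs must satisfy lowCutPx > highCutPx > 0")
  px <- m@pixels
  nr <- nrow(px); nc <- ncol(px)
  fr <- ((seq_len(nr) - 1 + floor(nr / 2)) %% nr - floor(nr / 2)) / nr
  fc <- ((seq_len(nc) - 1 + floor(nc / 2)) %% nc - floor(nc / 2)) / nc
  f2 <- outer(fr^2, fc^2, "+")
  # half-amplitude at feature sizes lowCutPx and highCutPx
  s2L <- (1 / lowCutPx)^2 / (2 * log(2))
  s2H <- (1 / highCutPx)^2 / (2 * log(2))
  H <- (1 - exp(-f2 / (2 * s2L))) * exp(-f2 / (2 * s2H))
  out <- Re(stats::fft(stats::fft(px) * H, inverse = TRUE)) / (nr * nc)
  out <- out + (mean(px) - mean(out))
  Micrograph(out, m@pixelSize,
             provenance = c(m@provenance,
                            sprintf("bandpassFilter(%g, %g)", lowCutPx, highCutPx)),
             meta = m@meta)
}

#' Median filter for detector-noise cleanup
#'
#' Optional pre-processing step (radius 1 pixel by default); off by default in
#' every pipeline stage.
#'
#' @param m a \linkS4class{Micrograph}.
#' @param radiusPx median filter radius in pixels.
#' @return The filtered \linkS4class{Micrograph}.
#' @export
medianDenoise <- function(m, radiusPx = 1L) {
  px <- m@pixels
  lo <- min(px); hi <- max(px)
  scaled <- if (hi > lo) (px - lo) / (hi - lo) else px * 0
  f <- EBImage::medianFilter(EBImage::Image(scaled), size = as.integer(radiusPx))
  Micrograph(EBImage::imageData(f) * (hi - lo) + lo, m@pixelSize,
             provenance = c(m@provenance, sprintf("medianDenoise(%d)", radiusPx)),
             meta = m@meta)
}

# ---------------------------------------------------------------------------
# Coordinate table I/O (fixed CSV headers)
# ---------------------------------------------------------------------------

#' Read/write ground-truth and detection coordinate tables
#'
#' CSVs use fixed headers: pore table \code{pore_id,x_nm,y_nm,class,n_fold,
#' tilt_deg}; gold table \code{gold_id,x_nm,y_nm,intended_associated,
#' nearest_pore_id,distance_nm}; detection table \code{detection_id,x_nm,y_nm,
#' ridge_radius_nm,score,edge_flag}.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param poresPath,goldPath output CSV paths (\code{goldPath} optional).
#' @param dt a \linkS4class{DetectionTable}.
#' @param path CSV path.
#' @name table-io
NULL

#' @rdname table-io
#' @export
writeGroundTruth <- function(truth, poresPath, goldPath = NULL) {
  utils::write.csv(truth@pores, poresPath, row.names = FALSE)
  if (!is.null(goldPath)) utils::write.csv(truth@gold, goldPath, row.names = FALSE)
  invisible(poresPath)
}

#' @rdname table-io
#' @export
readGroundTruth <- function(poresPath, goldPath = NULL) {
  pores <- utils::read.csv(poresPath)
  gold <- if (!is.null(goldPath)) utils::read.csv(goldPath) else emptyGoldTable()
  new("GroundTruth", pores = pores, gold = gold)
}

#' @rdname table-io
#' @export
writeDetections <- function(dt, path) {
  utils::write.csv(dt@detections, path, row.names = FALSE)
  writeJSONFile(dt@params, sidecarPath(path))
  invisible(path)
}
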