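#' @include AllClasses.R
NULL

# distance from points (nm) to the nearest point of a polyline given as a
# matrix with columns x_nm, y_nm
distToPolyline <- function(x, y, poly) {
  segs <- nrow(poly) - 1L
  best <- rep(Inf, length(x))
  for (s in seq_len(segs)) {
    ax <- poly[s, 1]; ay <- poly[s, 2]
    bx <- poly[s + 1L, 1]; by <- poly[s + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    t <- if (len2 > 0) pmin(pmax(((x - ax) * vx + (y - ay) * vy) / len2, 0), 1) else 0
    d <- sqrt((x - (ax + t * vx))^2 + (y - (ay + t * vy))^2)
    best <- pmin(best, d)
  }
  best
}

# distance from points to the reference structures of a GoldParticleSet
referenceDistances <- function(g, x, y) {
  if (nrow(g@pores) > 0L) {
    dd <- goldDistances(x, y, g@pores, mode = g@mode)
    return(list(distance = dd$distance, nearest = dd$nearest))
  }
  mem <- g@membrane[[1L]]
  if (is(mem, "MembraneMask")) {
    dm <- EBImage::imageData(EBImage::distmap(EBImage::Image((!mem@mask) * 1))) *
      mem@pixelSize
    rows <- y / mem@pixelSize + 1
    cols <- x / mem@pixelSize + 1
    d <- bilinearAt(dm, rows, cols, fill = Inf)
    list(distance = d, nearest = rep(NA_integer_, length(x)))
  } else if (is.matrix(mem) || is.data.frame(mem)) {
    list(distance = distToPolyline(x, y, as.matrix(mem)),
         nearest = rep(NA_integer_, length(x)))
  } else {
    stop("unsupported membrane reference (use a MembraneMask or a polyline matrix)")
  }
}

#' Classify immunogold particles by the distance-association rule
#'
#' A particle is associated when its distance to the nearest reference
#' structure does not exceed the threshold (inclusive: a particle exactly at
#' the threshold counts as associated). For pore references the distance is
#' measured to the outer-ring edge, \code{max(0, |particle - centre| - outer
#' radius)}, keeping the 20 nm rule independent of pore size; distance to the
#' centre is available via the particle set's \code{mode}. For membrane
#' references the distance is to the nearest point of the trace.
#'
#' @param g a \linkS4class{GoldParticleSet}.
#' @return An \linkS4class{AssociationResult}. An empty particle set yields a
#'   zero-count result, not an error.
#' @examples
#' pores <- data.frame(x_nm = 50, y_nm = 50, outer_radius_nm = 16.75)
#' pts <- data.frame(x_nm = c(50, 90), y_nm = c(68, 95))
#' classifyAssociation(GoldParticleSet(pts, pores))
#' @export
classifyAssociation <- function(g) {
  stopifnot(is(g, "GoldParticleSet"))
  validObject(g)
  n <- nrow(g@particles)
  if (n == 0L) {
    return(new("AssociationResult",
               particles = data.frame(gold_id = integer(), x_nm = numeric(),
                                      y_nm = numeric(), distance_nm = numeric(),
                                      associated = logical()),
               nAssociated = 0L, nNot = 0L, fraction = NA_real_,
               pValue = NA_real_, thresholdNm = g@thresholdNm))
  }
  dd <- referenceDistances(g, g@particles$x_nm, g@particles$y_nm)
  assoc <- dd$distance <= g@thresholdNm
  tab <- data.frame(gold_id = g@particles$gold_id, x_nm = g@particles$x_nm,
                    y_nm = g@particles$y_nm, distance_nm = dd$distance,
                    associated = assoc)
  new("AssociationResult", particles = tab,
      nAssociated = sum(assoc), nNot = sum(!assoc),
      fraction = mean(assoc), pValue = NA_real_, thresholdNm = g@thresholdNm)
}

#' Permutation test of association enrichment
#'
#' Compares the observed associated fraction with the distribution obtained
#' by placing the same number of particles uniformly at random in the
#' membrane region, B times. The p-value is
#' \code{(1 + #\{replicate fraction >= observed\}) / (B + 1)}; its smallest
#' attainable value is \code{1/(B + 1)}.
#'
#' @param g a \linkS4class{GoldParticleSet}.
#' @param mask a \linkS4class{MembraneMask} defining the uniform null region.
#' @param B number of permutation replicates (>= 1).
#' @param seed RNG seed.
#' @return A list with \code{p.value}, \code{observed} (fraction),
#'   \code{nullMean}, \code{nullSd}, \code{nullFractions} and \code{B}.
#' @export
permutationEnrichment <- function(g, mask, B = 999L, seed = 1L) {
  stopifnot(is(g, "GoldParticleSet"), is(mask, "MembraneMask"))
  if (B < 1L) stop("B must be >= 1")
  obs <- classifyAssociation(g)
  n <- nrow(g@particles)
  if (n == 0L) stop("no particles to test")
  ps <- mask@pixelSize
  idx <- which(mask@mask)
  nr <- nrow(mask@mask)
  fracs <- withSeed(seed, vapply(seq_len(B), function(b) {
    pick <- idx[sample.int(length(idx), n, replace = TRUE)]
    px <- (ceiling(pick / nr) - 1 + stats::runif(n, -0.5, 0.5)) * ps
    py <- ((pick - 1) %% nr + stats::runif(n, -0.5, 0.5)) * ps
    dd <- referenceDistances(g, px, py)
    mean(dd$distance <= g@thresholdNm)
  }, numeric(1)))
  p <- (1 + sum(fracs >= obs@fraction)) / (B + 1)
  list(p.value = p, observed = obs@fraction, nullMean = mean(fracs),
       nullSd = stats::sd(fracs), nullFractions = fracs, B = as.integer(B))
}

#' Export an association result
#'
#' Writes the per-particle CSV and a JSON summary.
#'
#' @param res an \linkS4class{AssociationResult}.
#' @param csvPath per-particle CSV path.
#' @param jsonPath summary JSON path.
#' @return \code{csvPath}, invisibly.
#' @export
writeAssociationResult <- function(res, csvPath, jsonPath) {
  utils::write.csv(res@particles, csvPath, row.names = FALSE)
  writeJSONFile(list(n_associated = res@nAssociated, n_not = res@nNot,
                     fraction = res@fraction, threshold_nm = res@thresholdNm,
                     p_value = if (is.na(res@pValue)) NULL else res@pValue),
                jsonPath)
  invisible(csvPath)
}
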