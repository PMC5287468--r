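# Shared fixtures built in code at test time.

largeModel <- function(...) PoreModel(...)

# SNR convention: noiseSigma = |contrastOuter| / snr
noiseFor <- function(model, snr) abs(model@contrastOuter) / snr

smallScene <- function(density = 60, seed = 1L, widthNm = 700,
                       minSeparation = 40, ...) {
  SheetScene(widthNm = widthNm, heightNm = widthNm, density = density,
             minSeparation = minSeparation, seed = seed, ...)
}

# brute-force nearest-pore edge distance (independent oracle for goldassoc)
bruteForceEdgeDist <- function(x, y, pores) {
  vapply(seq_along(x), function(i) {
    min(pmax(0, sqrt((pores$x_nm - x[i])^2 + (pores$y_nm - y[i])^2) -
               pores$outer_radius_nm))
  }, numeric(1))
}

# greedy bipartite matching of detections to ground truth within matchNm
matchDetections <- function(truth, det, matchNm = 20) {
  if (!nrow(det) || !nrow(truth)) return(0L)
  D <- outer(truth$x_nm, det$x_nm, "-")^2 + outer(truth$y_nm, det$y_nm, "-")^2
  used <- rep(FALSE, nrow(det))
  matched <- 0L
  for (i in order(apply(D, 1, min))) {
    j <- which.min(ifelse(used, Inf, D[i, ]))
    if (is.finite(D[i, j]) && D[i, j] <= matchNm^2) {
      matched <- matched + 1L
      used[j] <- TRUE
    }
  }
  matched
}
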