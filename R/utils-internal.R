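# Internal numerical helpers shared across modules.

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

erfc <- function(x) 2 * stats::pnorm(-sqrt(2) * x)

# Smallest size >= n whose prime factors are all 2, 3 or 5 (efficient FFT).
goodFFTSize <- function(n) {
  n <- as.integer(n)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# Bilinear interpolation of matrix `m` at fractional (row, col) positions.
# Positions outside [1, nrow] x [1, ncol] return `fill`.
bilinearAt <- function(m, r, c, fill = NA_real_) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(fill, length(r))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- floor(r); c0 <- floor(c)
  r0 <- pmin(r0, nr - 1L); c0 <- pmin(c0, nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * nr + r0
  v <- (1 - fr) * (1 - fc) * m[i00] +
    fr * (1 - fc) * m[i00 + 1] +
    (1 - fr) * fc * m[i00 + nr] +
    fr * fc * m[i00 + nr + 1]
  out[ok] <- v
  out
}

# Resample `m` through the affine map out(x) = in(center + A %*% (x - center)),
# with A acting on (row, col) offsets. Used for rotation and de-ellipsing.
resampleAffine <- function(m, A, center, fill = NA_real_) {
  nr <- nrow(m); nc <- ncol(m)
  dr <- rep(seq_len(nr) - center[1], times = nc)
  dc <- rep(seq_len(nc) - center[2], each = nr)
  sr <- center[1] + A[1, 1] * dr + A[1, 2] * dc
  sc <- center[2] + A[2, 1] * dr + A[2, 2] * dc
  matrix(bilinearAt(m, sr, sc, fill = fill), nr, nc)
}

# Rotate about `center` (row, col, 1-based, possibly fractional) by `angleDeg`.
rotateAbout <- function(m, angleDeg, center, fill = NA_real_) {
  th <- angleDeg * pi / 180
  A <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  resampleAffine(m, A, center, fill = fill)
}

# Separable Gaussian blur with replicate edge handling; sigma in pixels.
gaussianBlur <- function(m, sigmaPx) {
  if (sigmaPx <= 0) return(m)
  rad <- max(1L, ceiling(4 * sigmaPx))
  k <- stats::dnorm(seq(-rad, rad), sd = sigmaPx)
  k <- k / sum(k)
  blur1 <- function(x) {
    # x convolved along rows (first dim) by shift-and-add with edge replication
    nr <- nrow(x)
    acc <- matrix(0, nr, ncol(x))
    for (s in seq(-rad, rad)) {
      idx <- pmin(pmax(seq_len(nr) + s, 1L), nr)
      acc <- acc + k[s + rad + 1L] * x[idx, , drop = FALSE]
    }
    acc
  }
  t(blur1(t(blur1(m))))
}

# Linear (zero-padded) FFT cross-correlation of image with kernel.
# Returns matrix C where C[i, j] = sum_{u,v} img[i+u-1, j+v-1] * ker[u, v]
# for i in 1..(nr-kr+1), j in 1..(nc-kc+1) ("valid" alignment, top-left).
fftCrossCorrelate <- function(img, ker) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(ker); kc <- ncol(ker)
  pr <- goodFFTSize(nr + kr - 1L)
  pc <- goodFFTSize(nc + kc - 1L)
  I <- matrix(0, pr, pc); I[seq_len(nr), seq_len(nc)] <- img
  K <- matrix(0, pr, pc); K[seq_len(kr), seq_len(kc)] <- ker
  C <- Re(stats::fft(stats::fft(I) * Conj(stats::fft(K)), inverse = TRUE)) / (pr * pc)
  C[seq_len(nr - kr + 1L), seq_len(nc - kc + 1L), drop = FALSE]
}

# Quadratic (3-point parabola) sub-sample peak offset in [-0.5, 0.5].
parabolicOffset <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  if (!is.finite(den) || abs(den) < .Machine$double.eps) return(0)
  off <- 0.5 * (ym1 - yp1) / den
  max(min(off, 0.5), -0.5)
}

fmtNum <- function(x, digits = 3) formatC(x, digits = digits, format = "fg")

writeJSONFile <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
}
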