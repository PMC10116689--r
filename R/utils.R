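# Internal numerical helpers shared across modules.

# C1 smoothstep: 0 below 0, 1 above 1, 3x^2 - 2x^3 between.
smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

rotY <- function(angleRad) {
  ca <- cos(angleRad); sa <- sin(angleRad)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

deg2rad <- function(x) x * pi / 180

# Signed volume (mm^3) of a closed triangulated surface given vertex
# matrices va, vb, vc (n x 3). Positive for outward-oriented triangles.
triVolume <- function(va, vb, vc) {
  sum(va[, 1] * (vb[, 2] * vc[, 3] - vb[, 3] * vc[, 2]) +
      va[, 2] * (vb[, 3] * vc[, 1] - vb[, 1] * vc[, 3]) +
      va[, 3] * (vb[, 1] * vc[, 2] - vb[, 2] * vc[, 1])) / 6
}

# Enclosed volume of a structured surface grid (3 x Nu x Nv, u periodic,
# v from apex row to base row), closed with a fan over the base ring.
# Returns mm^3 (absolute value; orientation-agnostic).
gridEnclosedVolume <- function(pts) {
  nu <- dim(pts)[2]; nv <- dim(pts)[3]
  P <- t(matrix(pts, 3))                     # (nu*nv) x 3, u fastest
  idx <- function(u, v) (v - 1L) * nu + u
  u1 <- rep(seq_len(nu), nv - 1L)
  u2 <- rep(c(seq_len(nu)[-1], 1L), nv - 1L)
  vv <- rep(seq_len(nv - 1L), each = nu)
  a <- idx(u1, vv); b <- idx(u2, vv); cc <- idx(u2, vv + 1L); d <- idx(u1, vv + 1L)
  vol <- triVolume(P[a, , drop = FALSE], P[b, , drop = FALSE], P[cc, , drop = FALSE]) +
         triVolume(P[a, , drop = FALSE], P[cc, , drop = FALSE], P[d, , drop = FALSE])
  ring <- P[idx(seq_len(nu), nv), , drop = FALSE]
  ctr <- matrix(colMeans(ring), nu, 3, byrow = TRUE)
  ringNext <- ring[c(seq_len(nu)[-1], 1L), , drop = FALSE]
  vol <- vol + triVolume(ring, ringNext, ctr)
  abs(vol)
}

# Vectorized even-odd point-in-polygon test. px/py: point coords; poly:
# closed or open polygon matrix (n x 2; closure implied).
pointInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Centered 2D FFT helpers (DC at floor(n/2)+1 after shift).
fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((floor(n1 / 2) + 1):n1, 1:floor(n1 / 2)),
    c((floor(n2 / 2) + 1):n2, 1:floor(n2 / 2))]
}

ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((n1 - floor(n1 / 2) + 1):n1, 1:(n1 - floor(n1 / 2))),
    c((n2 - floor(n2 / 2) + 1):n2, 1:(n2 - floor(n2 / 2)))]
}

ft2 <- function(img) stats::fft(img) / length(img)
ift2 <- function(k) stats::fft(k, inverse = TRUE)

# Bilinear interpolation of a matrix at fractional 1-based indices.
# Out-of-range queries are clamped to the border.
bilinear <- function(m, xi, yi) {
  nx <- nrow(m); ny <- ncol(m)
  xi <- pmin(pmax(xi, 1), nx); yi <- pmin(pmax(yi, 1), ny)
  x0 <- pmin(floor(xi), nx - 1L); y0 <- pmin(floor(yi), ny - 1L)
  fx <- xi - x0; fy <- yi - y0
  m[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    m[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    m[cbind(x0, y0 + 1)] * (1 - fx) * fy +
    m[cbind(x0 + 1, y0 + 1)] * fx * fy
}

# Nearest-neighbour sampling of a matrix at fractional 1-based indices.
nearestSample <- function(m, xi, yi) {
  nx <- nrow(m); ny <- ncol(m)
  xi <- pmin(pmax(round(xi), 1), nx)
  yi <- pmin(pmax(round(yi), 1), ny)
  m[cbind(xi, yi)]
}

normalizeRows <- function(m) m / sqrt(rowSums(m^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
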