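# Contour extraction and epicardial-contour-matched 2D warping.

shoelaceArea <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Extract the outer contour of a class in a label slice
#'
#' Sub-pixel (marching-squares) iso-contour of the class mask at level
#' 0.5, in world millimetres. With multiple connected components the
#' largest is kept with a warning.
#'
#' @param slice 2D integer label matrix.
#' @param classId integer class label (must be present).
#' @param spacing,origin 2D grid geometry (mm).
#' @return closed polyline (n x 2 matrix, mm; last point != first).
#' @export
extractContour <- function(slice, classId, spacing = c(1, 1),
                           origin = c(0, 0)) {
  mask <- (slice == classId) * 1
  if (!any(mask == 1)) stop("class ", classId, " absent from slice")
  xs <- origin[1] + (seq_len(nrow(slice)) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(ncol(slice)) - 1) * spacing[2]
  # light separable smoothing before iso-contouring: moves the 0.5 level
  # set off the pixel staircase to sub-pixel accuracy
  blur1 <- function(m, d) {
    n <- dim(m)[d]
    if (d == 1) (m[c(1, 1:(n - 1)), ] + 2 * m + m[c(2:n, n), ]) / 4
    else (m[, c(1, 1:(n - 1))] + 2 * m + m[, c(2:n, n)]) / 4
  }
  sm <- blur1(blur1(blur1(blur1(mask, 1), 2), 1), 2)
  cl <- grDevices::contourLines(xs, ys, sm, levels = 0.5)
  if (!length(cl)) stop("degenerate contour: class region too small")
  areas <- vapply(cl, function(cc) abs(shoelaceArea(cbind(cc$x, cc$y))), 0)
  if (length(cl) > 1)
    warning("multiple contour components; keeping the largest")
  best <- cl[[which.max(areas)]]
  poly <- cbind(best$x, best$y)
  if (max(areas) < 2 * prod(spacing))
    stop("degenerate contour: area below two pixels")
  if (isTRUE(all.equal(poly[1, ], poly[nrow(poly), ])))
    poly <- poly[-nrow(poly), , drop = FALSE]
  poly
}

# Resample a closed polyline to n points by arc length, starting at the
# point whose azimuth (about the centroid) is closest to anchorAngle, in
# counter-clockwise orientation.
resampleContour <- function(poly, n = 64, anchorAngle = pi) {
  if (shoelaceArea(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  ctr <- colMeans(poly)
  ang <- atan2(poly[, 2] - ctr[2], poly[, 1] - ctr[1])
  start <- which.min(abs(wrapAngle(ang - anchorAngle)))
  poly <- poly[c(start:nrow(poly), seq_len(start - 1L)), , drop = FALSE]
  closed <- rbind(poly, poly[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  stot <- s[length(s)]
  tgt <- (seq_len(n) - 1) / n * stot
  out <- matrix(0, n, 2)
  j <- 1L
  for (i in seq_len(n)) {
    while (s[j + 1] < tgt[i]) j <- j + 1L
    f <- if (seg[j] == 0) 0 else (tgt[i] - s[j]) / seg[j]
    out[i, ] <- (1 - f) * closed[j, ] + f * closed[j + 1, ]
  }
  out
}

#' Build a smooth contour-matched 2D warp field
#'
#' Correspondences between the background and foreground contours are
#' established by matched arc-length parameterization anchored at a common
#' azimuth (the RV-septal junction); the control-point displacements are
#' interpolated over the slice by normalized Gaussian-kernel (Shepard)
#' regression with a smooth distance-based decay envelope, giving a
#' smooth, overshoot-free field that reproduces the control displacements
#' at the contour and decays away from it. The warp is stored in backward
#' convention: sampling the background at x + u(x) moves its contour onto
#' the foreground contour. If the warped grid folds (non-positive
#' Jacobian) the kernel is widened and the fit retried.
#'
#' @param bgContour,fgContour closed polylines (n x 2, mm).
#' @param grid a \code{\link{gridSpec}} (in-plane part used).
#' @param kernelWidth Gaussian kernel width (mm; default half the mean
#'   contour radius).
#' @param nControl number of arc-length control points.
#' @param anchorAngle common anchor azimuth (rad).
#' @return a \linkS4class{WarpField} with one slice.
#' @export
buildWarp <- function(bgContour, fgContour, grid, kernelWidth = NULL,
                      nControl = 96L, anchorAngle = pi) {
  fgR <- resampleContour(fgContour, nControl, anchorAngle)
  bgR <- resampleContour(bgContour, nControl, anchorAngle)
  disp <- bgR - fgR                       # backward displacement at fg pts
  perim <- sum(sqrt(rowSums((fgR - fgR[c(2:nControl, 1), ])^2)))
  if (is.null(kernelWidth))
    kernelWidth <- 1.5 * perim / nControl # ~1.5 control spacings
  xs <- gridAxis(grid, 1); ys <- gridAxis(grid, 2)
  px <- rep(xs, times = length(ys)); py <- rep(ys, each = length(xs))
  G2 <- outer(px, fgR[, 1], "-")^2 + outer(py, fgR[, 2], "-")^2
  dmin <- sqrt(apply(G2, 1, min))
  for (attempt in 1:4) {
    s2 <- 2 * kernelWidth^2
    K <- exp(-G2 / s2)
    wsum <- rowSums(K) + 1e-300
    decayLen <- max(6 * kernelWidth, 15)
    env <- 1 - smoothstep(dmin / decayLen)
    ux <- matrix(K %*% disp[, 1] / wsum * env, length(xs))
    uy <- matrix(K %*% disp[, 2] / wsum * env, length(xs))
    jac <- warpJacobian(ux, uy, grid$spacing[1:2])
    if (all(jac > 0)) {
      return(new("WarpField",
                 dx = array(ux, c(dim(ux), 1L)),
                 dy = array(uy, c(dim(uy), 1L)),
                 controls = list(list(points = fgR, disp = disp)),
                 spacing = grid$spacing, origin = grid$origin))
    }
    kernelWidth <- kernelWidth * 1.5
  }
  stop("warp folds (non-positive Jacobian) even after kernel widening")
}

#' Jacobian determinant of (identity + displacement)
#'
#' @param ux,uy displacement component matrices (mm).
#' @param spacing in-plane voxel spacing (mm).
#' @return matrix of Jacobian determinants.
#' @export
warpJacobian <- function(ux, uy, spacing) {
  gr <- function(m, d) {
    n <- dim(m)[d]
    if (d == 1) (m[c(2:n, n), ] - m[c(1, 1:(n - 1)), ]) /
      (spacing[1] * c(1, rep(2, n - 2), 1))
    else (m[, c(2:n, n)] - m[, c(1, 1:(n - 1))]) /
      (spacing[2] * c(1, rep(2, n - 2), 1))[col(m)]
  }
  (1 + gr(ux, 1)) * (1 + gr(uy, 2)) - gr(ux, 2) * gr(uy, 1)
}

#' Apply a warp field to a label volume or tissue maps
#'
#' Backward warping per slice: output(x) = input(x + u(x)), with
#' nearest-neighbour sampling for integer labels and bilinear interpolation
#' for continuous maps.
#'
#' @param x a \linkS4class{LabelVolume} or \linkS4class{TissueMaps}.
#' @param warp a \linkS4class{WarpField} on the same grid (single-slice
#'   fields are recycled across slices).
#' @return object of the same class as \code{x}.
#' @export
applyWarp <- function(x, warp) {
  interpSlice <- function(m, ux, uy, nearest) {
    nx <- nrow(m); ny <- ncol(m)
    xi <- row(m) + ux / warp@spacing[1]
    yi <- col(m) + uy / warp@spacing[2]
    out <- if (nearest) nearestSample(m, as.vector(xi), as.vector(yi))
      else bilinear(m, as.vector(xi), as.vector(yi))
    matrix(out, nx, ny)
  }
  wslice <- function(k) min(k, dim(warp@dx)[3])
  if (is(x, "LabelVolume")) {
    if (!identical(dim(x@data)[1:2], dim(warp@dx)[1:2]))
      stop("warp grid does not match volume grid")
    out <- x@data
    for (k in seq_len(dim(out)[3]))
      out[, , k] <- interpSlice(x@data[, , k], warp@dx[, , wslice(k)],
                                warp@dy[, , wslice(k)], nearest = TRUE)
    return(new("LabelVolume", data = out, spacing = x@spacing,
               origin = x@origin, classes = x@classes, frame = x@frame))
  }
  if (is(x, "TissueMaps")) {
    warpA <- function(a) {
      for (k in seq_len(dim(a)[3]))
        a[, , k] <- interpSlice(a[, , k], warp@dx[, , wslice(k)],
                                warp@dy[, , wslice(k)], nearest = FALSE)
      a
    }
    return(new("TissueMaps", PD = warpA(x@PD), T1 = warpA(x@T1),
               T2 = warpA(x@T2), spacing = x@spacing, origin = x@origin,
               frame = x@frame))
  }
  stop("unsupported input for applyWarp")
}

#' Symmetric Hausdorff distance between two contours (mm)
#' @param a,b polylines (n x 2).
#' @return scalar distance.
#' @export
hausdorffDistance <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}
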