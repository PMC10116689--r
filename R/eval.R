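# Ground-truth packaging and evaluation metrics (Dice, displacement
# error, strain summaries, resampling/cropping preprocessing).

#' Dice overlap between two masks
#'
#' 2|A n B| / (|A| + |B|); the overlap of two empty masks is defined as 1.
#'
#' @param a,b logical/0-1 arrays on the same grid.
#' @return scalar in [0, 1].
#' @export
diceScore <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask grids do not match")
  a <- a != 0; b <- b != 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Displacement error statistics (mm)
#'
#' Per-voxel Euclidean norm of (predicted - ground truth) displacement,
#' optionally with the through-plane (third) component zeroed first
#' (projection onto the short-axis plane), summarized over a region of
#' interest.
#'
#' @param pred,gt displacement arrays (... x 3, last dimension the vector
#'   components) on the same grid.
#' @param roi logical array selecting the voxels to evaluate.
#' @param projectSax zero the through-plane component before the norm.
#' @return list with mean, sd and the per-voxel errors.
#' @export
displacementError <- function(pred, gt, roi, projectSax = TRUE) {
  if (!identical(dim(pred), dim(gt))) stop("displacement grids do not match")
  nd <- length(dim(pred))
  nComp <- dim(pred)[nd]
  if (sum(roi) == 0) stop("empty region of interest")
  d <- pred - gt
  dm <- matrix(d, ncol = nComp)
  sel <- as.vector(roi)
  comps <- if (projectSax) seq_len(min(2, nComp)) else seq_len(nComp)
  err <- sqrt(rowSums(dm[sel, comps, drop = FALSE]^2))
  list(mean = mean(err), sd = stats::sd(err), errors = err)
}

#' Region-wise strain summary curves
#'
#' Mean and standard deviation per frame of each strain component for each
#' region, plus peak values (signed extremum) and peak times.
#'
#' @param strain a \linkS4class{StrainField}.
#' @param regions optional factor of regions per element (default the
#'   field's scar/remote labels; use a single level for whole-myocardium
#'   curves).
#' @return data.frame with columns region, component, time, mean, sd.
#'   Peak summaries are attached as attribute \code{"peaks"}.
#' @export
strainSummary <- function(strain, regions = NULL) {
  if (is.null(regions)) regions <- droplevels(strain@region)
  regions <- as.factor(regions)
  if (any(table(regions) == 0)) stop("empty strain region")
  comps <- list(er = strain@er, ec = strain@ec, el = strain@el)
  out <- NULL; peaks <- NULL
  for (cn in names(comps)) {
    M <- comps[[cn]]
    for (rg in levels(regions)) {
      sel <- regions == rg
      mu <- colMeans(M[sel, , drop = FALSE])
      sdv <- apply(M[sel, , drop = FALSE], 2, stats::sd)
      out <- rbind(out, data.frame(region = rg, component = cn,
                                   time = strain@time, mean = mu, sd = sdv))
      ipk <- which.max(abs(mu))
      peaks <- rbind(peaks, data.frame(region = rg, component = cn,
                                       peak = mu[ipk],
                                       peakTime = strain@time[ipk]))
    }
  }
  rownames(out) <- NULL
  attr(out, "peaks") <- peaks
  out
}

# 1D linear interpolation of a vector at fractional 1-based indices.
interp1 <- function(v, xi) {
  n <- length(v)
  xi <- pmin(pmax(xi, 1), n)
  x0 <- pmin(floor(xi), n - 1L)
  f <- xi - x0
  v[x0] * (1 - f) + v[x0 + 1L] * f
}

# Trilinear resampling of a 3D array at fractional index coordinates.
resample3 <- function(a, xi, yi, zi) {
  n <- dim(a)
  xi <- pmin(pmax(xi, 1), n[1]); yi <- pmin(pmax(yi, 1), n[2])
  zi <- pmin(pmax(zi, 1), n[3])
  x0 <- pmin(floor(xi), max(n[1] - 1L, 1L)); fx <- xi - x0
  y0 <- pmin(floor(yi), max(n[2] - 1L, 1L)); fy <- yi - y0
  z0 <- pmin(floor(zi), max(n[3] - 1L, 1L)); fz <- zi - z0
  x1 <- pmin(x0 + 1L, n[1]); y1 <- pmin(y0 + 1L, n[2]); z1 <- pmin(z0 + 1L, n[3])
  g <- function(ix, iy, iz) a[cbind(ix, iy, iz)]
  g(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
  g(x1, y0, z0) * fx * (1 - fy) * (1 - fz) +
  g(x0, y1, z0) * (1 - fx) * fy * (1 - fz) +
  g(x1, y1, z0) * fx * fy * (1 - fz) +
  g(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
  g(x1, y0, z1) * fx * (1 - fy) * fz +
  g(x0, y1, z1) * (1 - fx) * fy * fz +
  g(x1, y1, z1) * fx * fy * fz
}

#' Resample and crop an image for strain-network evaluation
#'
#' Standard preprocessing of segmentation/motion networks: trilinear
#' resampling to 1.25 mm isotropic in-plane and 16 slices, cropping to
#' 128 x 128 x 16 voxels centered on the LV mask centroid, and robust
#' intensity normalization to [0, 1] by the 1st/99th percentiles.
#'
#' @param image 3D array (x, y, slice).
#' @param mask logical 3D array marking the LV (nonempty).
#' @param spacing voxel spacing of \code{image} (mm).
#' @param targetRes target in-plane resolution (mm, default 1.25).
#' @param targetDims target dimensions (default 128 x 128 x 16).
#' @param normalize robust-normalize intensities.
#' @return resampled/cropped/normalized array of size \code{targetDims}.
#' @export
resampleForEval <- function(image, mask, spacing, targetRes = 1.25,
                            targetDims = c(128L, 128L, 16L),
                            normalize = TRUE) {
  if (sum(mask) == 0) stop("LV mask is empty")
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  n <- dim(image)
  # index step per target voxel
  stepX <- targetRes / spacing[1]; stepY <- targetRes / spacing[2]
  stepZ <- if (n[3] > 1) (n[3] - 1) / (targetDims[3] - 1) else 0
  gx <- ctr[1] + (seq_len(targetDims[1]) - (targetDims[1] + 1) / 2) * stepX
  gy <- ctr[2] + (seq_len(targetDims[2]) - (targetDims[2] + 1) / 2) * stepY
  gz <- if (n[3] > 1) 1 + (seq_len(targetDims[3]) - 1) * stepZ
        else rep(1, targetDims[3])
  xi <- rep(gx, times = targetDims[2] * targetDims[3])
  yi <- rep(rep(gy, each = targetDims[1]), times = targetDims[3])
  zi <- rep(gz, each = targetDims[1] * targetDims[2])
  out <- array(resample3(image, xi, yi, zi), targetDims)
  if (normalize) {
    qs <- stats::quantile(out, c(0.01, 0.99), names = FALSE)
    if (qs[2] > qs[1]) out <- (out - qs[1]) / (qs[2] - qs[1])
    out <- pmin(pmax(out, 0), 1)
  }
  out
}

#' Assemble the per-frame ground-truth bundle
#'
#' Packages, for each output frame of a simulation: LV masks voxelized on
#' the image grid, dense displacement fields from the end-diastolic
#' reference (zero at the reference frame), the strain field with
#' scar/remote split, and the global indices (EDV, ESV, EF, mass).
#'
#' @param result a \linkS4class{SimulationResult}.
#' @param grid image-grid \code{\link{gridSpec}}.
#' @param frames frame indices to include (default all).
#' @return a \linkS4class{GroundTruthBundle}.
#' @export
buildGroundTruth <- function(result, grid, frames = NULL) {
  if (is.null(frames)) frames <- seq_along(result@time)
  mesh <- result@mesh
  strain <- computeStrain(result, frames)
  ss <- strainSummary(strain)
  masks <- list(); disp <- list(); scarMasks <- list()
  xs <- gridAxis(grid, 1); ys <- gridAxis(grid, 2); zs <- gridAxis(grid, 3)
  refPos <- result@positionsED
  scarNodes <- NULL
  if (any(result@scarWeight > 0.5)) {
    scarElems <- which(result@scarWeight > 0.5)
    scarNodes <- unique(as.vector(mesh@elems[scarElems, ]))
  }
  for (j in seq_along(frames)) {
    f <- frames[j]
    pos <- result@positions[, , f]
    lab <- voxelizeLV(mesh, grid, positions = pos, frame = f)
    masks[[j]] <- lab
    # displacement from ED, nearest-node interpolation on myocardium voxels
    U <- pos - refPos
    myo <- which(lab@data == lab@classes[["lvMyo"]], arr.ind = TRUE)
    D <- array(0, c(grid$dims, 3))
    S <- array(FALSE, grid$dims)
    if (nrow(myo)) {
      wpos <- cbind(xs[myo[, 1]], ys[myo[, 2]], zs[myo[, 3]])
      nn <- nearestNodeIndex(pos, wpos)
      for (d in 1:3) {
        tmp <- array(0, grid$dims)
        tmp[myo] <- U[nn, d]
        D[, , , d] <- tmp
      }
      if (!is.null(scarNodes)) S[myo] <- nn %in% scarNodes
    }
    disp[[j]] <- D
    scarMasks[[j]] <- if (is.null(scarNodes)) NULL else S
  }
  new("GroundTruthBundle", masks = masks, displacement = disp,
      strain = strain, strainSummary = ss, EDV = result@EDV,
      ESV = result@ESV, EF = result@EF, mass = result@mass,
      scarMasks = scarMasks)
}

# Index of the nearest mesh node for each query point (chunked).
nearestNodeIndex <- function(nodes, pts, chunk = 4000L) {
  out <- integer(nrow(pts))
  for (s in seq(1, nrow(pts), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(pts))
    block <- pts[s:e, , drop = FALSE]
    d2 <- outer(block[, 1], nodes[, 1], "-")^2 +
          outer(block[, 2], nodes[, 2], "-")^2 +
          outer(block[, 3], nodes[, 3], "-")^2
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' @describeIn ejectionFraction EF stored in a ground-truth bundle.
#' @export
setMethod("ejectionFraction", "GroundTruthBundle",
          function(object) object@EF)

setMethod("show", "GroundTruthBundle", function(object) {
  cat(sprintf(
    "GroundTruthBundle: %d frames, EDV %.1f ml, ESV %.1f ml, EF %.1f%%, mass %.1f g\n",
    length(object@masks), object@EDV, object@ESV, object@EF, object@mass))
})
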