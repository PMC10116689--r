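# Low-rank generative shape model: principal components on flattened
# surface-grid coordinates with a whitened (standard-normal) latent space.

shapeToVector <- function(grid) c(as.vector(grid@endo), as.vector(grid@epi))

vectorToGrid <- function(x, gridDim) {
  nU <- gridDim[1]; nV <- gridDim[2]
  p <- 3L * nU * nV
  endo <- array(x[seq_len(p)], c(3, nU, nV))
  epi <- array(x[p + seq_len(p)], c(3, nU, nV))
  apex <- rowMeans(matrix(endo[, , 1], 3))
  basePoint <- rowMeans(matrix(endo[, , nV], 3))
  axis <- basePoint - apex
  axis <- axis / sqrt(sum(axis^2))
  new("LVSurfaceGrid", endo = endo, epi = epi,
      basePlane = list(point = basePoint, normal = axis), apex = apex)
}

# Rotation taking unit vector a onto unit vector b (Rodrigues).
rotationBetween <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) {
    # pick any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ax - sum(ax * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + cth)
}

#' Normalize the rigid-body pose of a surface grid
#'
#' Translates the apex to the origin, aligns the long axis (apex to base
#' centroid) with +z, and rotates about z so the first circumferential node
#' of the base row lies at azimuth zero. Removes the rigid-body variance
#' that the shape model does not represent.
#'
#' @param grid an \linkS4class{LVSurfaceGrid}.
#' @return a pose-normalized \linkS4class{LVSurfaceGrid}.
#' @export
normalizePose <- function(grid) {
  nV <- gridDim(grid)[2]
  apex <- rowMeans(matrix(grid@endo[, , 1], 3))
  basePoint <- rowMeans(matrix(grid@endo[, , nV], 3))
  axis <- basePoint - apex
  axis <- axis / sqrt(sum(axis^2))
  R1 <- rotationBetween(axis, c(0, 0, 1))
  ref <- R1 %*% (grid@endo[, 1, nV] - apex)
  alpha <- atan2(ref[2], ref[1])
  ca <- cos(-alpha); sa <- sin(-alpha)
  R2 <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  R <- R2 %*% R1
  tx <- function(pts) {
    P <- R %*% (matrix(pts, 3) - apex)
    array(P, dim(pts))
  }
  endo <- tx(grid@endo); epi <- tx(grid@epi)
  new("LVSurfaceGrid", endo = endo, epi = epi,
      basePlane = list(point = as.vector(R %*% (grid@basePlane$point - apex)),
                       normal = as.vector(R %*% grid@basePlane$normal)),
      apex = c(0, 0, 0))
}

#' Fit the low-rank generative shape model
#'
#' Principal-component analysis of flattened, pose-normalized endo/epi
#' coordinate grids. Latent coordinates are whitened so the training set
#' has per-coordinate mean ~0 and variance ~1; decoding the zero vector
#' returns the population mean shape.
#'
#' @param shapes list of \linkS4class{LVSurfaceGrid} (at least 50 for a
#'   meaningful model) with identical grid dimensions.
#' @param d latent dimension (default 16); must be below the population
#'   size. Truncated with a warning if the population is rank deficient.
#' @param seed seed recorded in the model metadata.
#' @return a \linkS4class{ShapeModel}.
#' @export
fitShapeModel <- function(shapes, d = 16L, seed = 1) {
  stopifnot(length(shapes) >= 2, d < length(shapes))
  gd <- gridDim(shapes[[1]])
  X <- vapply(shapes, function(s) shapeToVector(normalizePose(s)),
              numeric(6L * prod(gd)))
  X <- t(X)                              # n x p
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = min(d, nrow(X) - 1L), nv = min(d, nrow(X) - 1L))
  sdev <- sv$d / sqrt(nrow(X) - 1L)
  keep <- which(sdev > 1e-8 * max(sdev, 1e-12))
  keep <- keep[keep <= min(d, length(sv$d))]
  if (length(keep) < d)
    warning(sprintf(
      "population is rank deficient: latent dimension truncated to %d",
      length(keep)))
  d <- length(keep)
  new("ShapeModel", mean = mu,
      rotation = sv$v[, keep, drop = FALSE],
      sdev = sdev[keep], d = as.integer(d), gridDim = as.integer(gd),
      meta = list(n = nrow(X), seed = seed))
}

#' Decode a latent vector into a surface grid
#'
#' Latent coordinates are on the standard-normal scale of the training
#' population; values beyond +-3 lie outside the region the model was
#' meant to sample and trigger a warning. A decoded shape violating the
#' wall-thickness invariant is rejected with a diagnostic.
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param z numeric latent vector of length \code{model@d} (shorter vectors
#'   are zero-padded).
#' @param repair principal-component extrapolation can occasionally thin
#'   the wall below the 0.5 mm floor; with \code{repair = TRUE} (default)
#'   the epicardium is pushed minimally outward to a 0.6 mm floor at the
#'   offending grid nodes, keeping every decoded shape a valid surface
#'   grid. With \code{repair = FALSE} such shapes are rejected with a
#'   diagnostic instead.
#' @return an \linkS4class{LVSurfaceGrid}.
#' @export
sampleShape <- function(model, z, repair = TRUE) {
  z <- c(z, numeric(model@d))[seq_len(model@d)]
  if (any(abs(z) > 3))
    warning("latent coordinates beyond +-3 sigma; shape may be unrealistic")
  x <- model@mean + as.vector(model@rotation %*% (z * model@sdev))
  # repair before object construction (validity would reject otherwise)
  p <- 3L * prod(model@gridDim)
  endo <- array(x[seq_len(p)], c(3, model@gridDim))
  epi <- array(x[p + seq_len(p)], c(3, model@gridDim))
  thick <- sqrt(colSums((epi - endo)^2, dims = 1))
  if (any(thick <= 0.5)) {
    if (!repair)
      stop(sprintf(
        "decoded shape violates the wall-thickness invariant (min %.3f mm)",
        min(thick)))
    fac <- pmax(0.6 / pmax(thick, 1e-6), 1)
    for (d in 1:3)
      epi[d, , ] <- endo[d, , ] + (epi[d, , ] - endo[d, , ]) * fac
    x[p + seq_len(p)] <- as.vector(epi)
  }
  grid <- vectorToGrid(x, model@gridDim)
  v <- validObject(grid, test = TRUE)
  if (!isTRUE(v))
    stop("decoded shape violates surface-grid invariants: ", v)
  grid
}

#' Encode a surface grid into latent coordinates
#'
#' Projection onto the principal subspace after pose normalization; exact
#' inverse of \code{\link{sampleShape}} for shapes lying in the subspace.
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param shape an \linkS4class{LVSurfaceGrid} with matching grid layout.
#' @return numeric latent vector of length \code{model@d}.
#' @export
encodeShape <- function(model, shape) {
  stopifnot(identical(as.integer(gridDim(shape)), model@gridDim))
  x <- shapeToVector(normalizePose(shape)) - model@mean
  as.vector(crossprod(model@rotation, x)) / model@sdev
}

#' Mean point-to-point reconstruction error (mm)
#'
#' Average Euclidean distance between corresponding endocardial and
#' epicardial points of a shape and its encode-decode reconstruction.
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param shape an \linkS4class{LVSurfaceGrid}.
#' @return nonnegative scalar (mm).
#' @export
reconstructionError <- function(model, shape) {
  ref <- normalizePose(shape)
  rec <- sampleShape(model, encodeShape(model, shape))
  dEndo <- sqrt(colSums((ref@endo - rec@endo)^2, dims = 1))
  dEpi <- sqrt(colSums((ref@epi - rec@epi)^2, dims = 1))
  mean(c(dEndo, dEpi))
}

#' k-means clustering of latent vectors into anatomical presets
#'
#' Standard k-means (deterministic given \code{seed}) on latent-space
#' vectors. With \code{k = 3} and a fitted model the centers are labelled
#' NOR/DCM/HCM by decoded anatomy: the largest cavity is DCM, the thickest
#' wall among the rest is HCM, the remainder NOR.
#'
#' @param latents n x d matrix (or list of latent vectors).
#' @param k number of clusters (default 3).
#' @param seed RNG seed for center initialization.
#' @param model optional \linkS4class{ShapeModel} used to label centers.
#' @return a \linkS4class{PresetClusters}; the k-means assignment is
#'   attached as attribute \code{"cluster"}.
#' @export
clusterLatent <- function(latents, k = 3L, seed = 1, model = NULL) {
  if (is.list(latents)) latents <- do.call(rbind, latents)
  if (k > nrow(latents)) stop("k must not exceed the number of latents")
  set.seed(seed)
  km <- stats::kmeans(latents, centers = k, nstart = 10, iter.max = 100)
  labels <- paste0("C", seq_len(k))
  if (!is.null(model) && k == 3L) {
    vols <- numeric(3); thick <- numeric(3)
    for (i in 1:3) {
      s <- sampleShape(model, km$centers[i, ])
      vols[i] <- cavityVolume(s); thick[i] <- wallThickness(s)
    }
    labels <- rep(NA_character_, 3)
    labels[which.max(vols)] <- "DCM"
    rest <- which(is.na(labels))
    labels[rest[which.max(thick[rest])]] <- "HCM"
    labels[is.na(labels)] <- "NOR"
  }
  out <- new("PresetClusters", centers = unname(km$centers), labels = labels)
  attr(out, "cluster") <- km$cluster
  out
}

setMethod("show", "ShapeModel", function(object) {
  cat(sprintf(
    "ShapeModel: d = %d, grid %d x %d, trained on %d shapes\n",
    object@d, object@gridDim[1], object@gridDim[2],
    object@meta$n %||% NA_integer_))
})
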