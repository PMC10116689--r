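# Layered hexahedral meshing of the LV wall and volume/mass measures.

# Local trilinear node signs (8 nodes x 3 reference dims).
hexSigns <- local({
  s1 <- c(-1, 1, 1, -1, -1, 1, 1, -1)
  s2 <- c(-1, -1, 1, 1, -1, -1, 1, 1)
  s3 <- c(-1, -1, -1, -1, 1, 1, 1, 1)
  cbind(s1, s2, s3)
})

# Shape-function derivatives dN/dxi (8 x 3) at reference point xi (length 3).
hexDeriv <- function(xi) {
  S <- hexSigns
  D <- matrix(0, 8, 3)
  for (d in 1:3) {
    others <- setdiff(1:3, d)
    D[, d] <- S[, d] / 8 *
      (1 + S[, others[1]] * xi[others[1]]) *
      (1 + S[, others[2]] * xi[others[2]])
  }
  D
}

# Vectorized 3x3 determinant for J stored as list of E x 3 column blocks.
det3 <- function(J) {
  J[[1]][, 1] * (J[[2]][, 2] * J[[3]][, 3] - J[[2]][, 3] * J[[3]][, 2]) -
  J[[1]][, 2] * (J[[2]][, 1] * J[[3]][, 3] - J[[2]][, 3] * J[[3]][, 1]) +
  J[[1]][, 3] * (J[[2]][, 1] * J[[3]][, 2] - J[[2]][, 2] * J[[3]][, 1])
}

# Jacobian of the trilinear map per element: list J[[d1]] = E x 3 matrix of
# rows (dx_d1/dxi_1..3). X: E x 8 x 3 element node coordinates.
hexJacobian <- function(X, D) {
  lapply(1:3, function(d1) X[, , d1] %*% D)
}

# Exact (2x2x2 Gauss) volumes of trilinear hexahedra. X: E x 8 x 3.
hexVolumes <- function(X) {
  g <- 1 / sqrt(3)
  vol <- numeric(dim(X)[1])
  for (s1 in c(-g, g)) for (s2 in c(-g, g)) for (s3 in c(-g, g)) {
    D <- hexDeriv(c(s1, s2, s3))
    vol <- vol + det3(hexJacobian(X, D))
  }
  vol
}

#' Build a layered hexahedral mesh of the LV wall
#'
#' Interpolates the wall between the endo- and epicardial surface grids
#' into \code{nTrans} transmural element layers on an \code{nCirc} x
#' \code{nLong} circumferential-longitudinal grid. Every node carries its
#' transmural coordinate t (0 = endo, 1 = epi), normalized longitudinal
#' coordinate (0 apex, 1 base), azimuth, and an orthonormal local frame
#' (outward radial, circumferential, apex-to-base longitudinal). Trilinear
#' shape-function gradients and exact element volumes are precomputed. The
#' innermost longitudinal station sits half a cell above the (degenerate)
#' apex point, so all elements are proper hexahedra.
#'
#' @param grid an \linkS4class{LVSurfaceGrid}.
#' @param nTrans number of transmural element layers (>= 3).
#' @param nCirc,nLong circumferential / longitudinal element counts.
#' @return a \linkS4class{VolumetricMesh}.
#' @export
buildVolumeMesh <- function(grid, nTrans = 3L, nCirc = 24L, nLong = 12L) {
  stopifnot(nTrans >= 3L)
  nU <- gridDim(grid)[1]; nV <- gridDim(grid)[2]
  v0 <- 0.35 / nLong
  us <- (seq_len(nCirc) - 1L) / nCirc           # fraction of full circle
  vs <- v0 + (1 - v0) * (0:nLong) / nLong
  nLongP <- nLong + 1L

  # periodic bilinear interpolation of a surface grid at (us, vs)
  interpSurf <- function(surf) {
    ui <- us * nU + 1                           # 1-based fractional index
    vi <- vs * (nV - 1) + 1
    out <- array(0, c(3, nCirc, nLongP))
    u0 <- floor(ui); fu <- ui - u0
    u0w <- ((u0 - 1L) %% nU) + 1L; u1w <- (u0 %% nU) + 1L
    v0i <- pmin(floor(vi), nV - 1L); fv <- vi - v0i
    for (d in 1:3) {
      M <- surf[d, , ]
      for (j in seq_len(nLongP)) {
        a <- M[u0w, v0i[j]] * (1 - fu) + M[u1w, v0i[j]] * fu
        b <- M[u0w, v0i[j] + 1L] * (1 - fu) + M[u1w, v0i[j] + 1L] * fu
        out[d, , j] <- a * (1 - fv[j]) + b * fv[j]
      }
    }
    out
  }
  en <- interpSurf(grid@endo)
  ep <- interpSurf(grid@epi)

  nStations <- nCirc * nLongP
  enM <- t(matrix(en, 3)); epM <- t(matrix(ep, 3))   # stations x 3
  rhat <- normalizeRows(epM - enM)
  mid <- (enM + epM) / 2
  midA <- array(t(mid), c(3, nCirc, nLongP))
  dU <- midA[, c(2:nCirc, 1), ] - midA[, c(nCirc, 1:(nCirc - 1)), ]
  dUM <- t(matrix(dU, 3))
  chat <- dUM - rowSums(dUM * rhat) * rhat
  chat <- normalizeRows(chat)
  lhat <- cbind(rhat[, 2] * chat[, 3] - rhat[, 3] * chat[, 2],
                rhat[, 3] * chat[, 1] - rhat[, 1] * chat[, 3],
                rhat[, 1] * chat[, 2] - rhat[, 2] * chat[, 1])

  nLayers <- nTrans + 1L
  ts <- (0:nTrans) / nTrans
  N <- nStations * nLayers
  nodes <- matrix(0, N, 3)
  for (k in seq_len(nLayers)) {
    rows <- (k - 1L) * nStations + seq_len(nStations)
    nodes[rows, ] <- enM + ts[k] * (epM - enM)
  }
  nodeT <- rep(ts, each = nStations)
  nodeV <- rep(rep(vs, each = nCirc), times = nLayers)
  nodePhi <- rep(rep(2 * pi * us, times = nLongP), times = nLayers)
  frameR <- do.call(rbind, rep(list(rhat), nLayers))
  frameC <- do.call(rbind, rep(list(chat), nLayers))
  frameL <- do.call(rbind, rep(list(lhat), nLayers))

  sid <- function(i, j) (j - 1L) * nCirc + i    # station index
  nid <- function(i, j, k) (k - 1L) * nStations + sid(i, j)
  ii <- rep(seq_len(nCirc), times = nLong * nTrans)
  jj <- rep(rep(seq_len(nLong), each = nCirc), times = nTrans)
  kk <- rep(seq_len(nTrans), each = nCirc * nLong)
  i2 <- ii %% nCirc + 1L
  elems <- cbind(nid(ii, jj, kk),     nid(i2, jj, kk),
                 nid(i2, jj + 1L, kk), nid(ii, jj + 1L, kk),
                 nid(ii, jj, kk + 1L), nid(i2, jj, kk + 1L),
                 nid(i2, jj + 1L, kk + 1L), nid(ii, jj + 1L, kk + 1L))

  E <- nrow(elems)
  X <- array(0, c(E, 8, 3))
  for (a in 1:8) X[, a, ] <- nodes[elems[, a], ]
  D0 <- hexDeriv(c(0, 0, 0))
  J <- hexJacobian(X, D0)
  detJ <- det3(J)
  if (any(detJ <= 0)) {
    bad <- which(detJ <= 0)
    stop(sprintf(
      "meshing failed: %d inverted elements (first at circ %d, long %d, layer %d) — self-intersecting surfaces?",
      length(bad), ii[bad[1]], jj[bad[1]], kk[bad[1]]))
  }
  # inverse Jacobians via adjugate
  inv <- array(0, c(E, 3, 3))
  Jarr <- array(0, c(E, 3, 3))
  for (d1 in 1:3) Jarr[, d1, ] <- J[[d1]]
  cof <- function(r1, r2, c1, c2)
    Jarr[, r1, c1] * Jarr[, r2, c2] - Jarr[, r1, c2] * Jarr[, r2, c1]
  inv[, 1, 1] <- cof(2, 3, 2, 3); inv[, 1, 2] <- -cof(1, 3, 2, 3)
  inv[, 1, 3] <- cof(1, 2, 2, 3); inv[, 2, 1] <- -cof(2, 3, 1, 3)
  inv[, 2, 2] <- cof(1, 3, 1, 3); inv[, 2, 3] <- -cof(1, 2, 1, 3)
  inv[, 3, 1] <- cof(2, 3, 1, 2); inv[, 3, 2] <- -cof(1, 3, 1, 2)
  inv[, 3, 3] <- cof(1, 2, 1, 2)
  inv <- inv / array(detJ, c(E, 3, 3))
  gradN <- array(0, c(E, 8, 3))
  for (a in 1:8) for (d in 1:3)
    gradN[, a, d] <- D0[a, 1] * inv[, 1, d] + D0[a, 2] * inv[, 2, d] +
                     D0[a, 3] * inv[, 3, d]

  elemVol <- hexVolumes(X)
  elemT <- rowMeans(matrix(nodeT[elems], E))
  elemV <- rowMeans(matrix(nodeV[elems], E))
  phiN <- matrix(nodePhi[elems], E)
  # circular mean of node azimuths
  elemPhi <- atan2(rowMeans(sin(phiN)), rowMeans(cos(phiN))) %% (2 * pi)

  new("VolumetricMesh", nodes = nodes, elems = elems, nodeT = nodeT,
      nodeV = nodeV, nodePhi = nodePhi, frameR = frameR, frameC = frameC,
      frameL = frameL, dims = as.integer(c(nLayers, nCirc, nLongP)),
      gradN = gradN,
      elemVol = elemVol, elemT = elemT, elemV = elemV, elemPhi = elemPhi)
}

# Indices of the endo (t = 0) or epi (t = 1) surface layer, as an
# nCirc x nLongP matrix of node indices.
layerIndex <- function(mesh, layer = c("endo", "epi")) {
  layer <- match.arg(layer)
  nStations <- mesh@dims[2] * mesh@dims[3]
  off <- if (layer == "endo") 0L else (mesh@dims[1] - 1L) * nStations
  matrix(off + seq_len(nStations), mesh@dims[2], mesh@dims[3])
}

# Cavity volume (mm^3) of a deformed mesh state: endo layer closed by an
# apex cap (fan over the innermost ring) and a base cap.
meshCavityVolumeMM3 <- function(mesh, positions = mesh@nodes) {
  idx <- layerIndex(mesh, "endo")
  nCirc <- nrow(idx); nLongP <- ncol(idx)
  pts <- array(0, c(3, nCirc, nLongP + 1L))
  surf <- t(positions[as.vector(idx), , drop = FALSE])
  dim(surf) <- c(3, nCirc, nLongP)
  apexCap <- rowMeans(matrix(surf[, , 1], 3))
  pts[, , 1] <- apexCap
  pts[, , 2:(nLongP + 1L)] <- surf
  gridEnclosedVolume(pts)
}

#' @describeIn cavityVolume cavity volume of a (possibly deformed) mesh
#'   state; pass \code{positions} to evaluate a deformed configuration.
#' @param positions optional N x 3 matrix of deformed node positions.
#' @export
setMethod("cavityVolume", "VolumetricMesh",
  function(x, positions = x@nodes, ...) {
    meshCavityVolumeMM3(x, positions) / 1000
  })

#' @describeIn wallVolume total element volume of the wall mesh (ml);
#'   pass \code{positions} for a deformed configuration.
#' @param positions optional N x 3 matrix of deformed node positions.
#' @export
setMethod("wallVolume", "VolumetricMesh",
  function(x, positions = x@nodes, ...) {
    if (missing(positions)) return(sum(x@elemVol) / 1000)
    E <- nrow(x@elems)
    X <- array(0, c(E, 8, 3))
    for (a in 1:8) X[, a, ] <- positions[x@elems[, a], ]
    sum(hexVolumes(X)) / 1000
  })

#' @describeIn lvMass wall volume times density for a mesh.
#' @export
setMethod("lvMass", "VolumetricMesh", function(x, rho = 1.05, ...) {
  wallVolume(x) * rho
})

setMethod("show", "VolumetricMesh", function(object) {
  cat(sprintf(
    "VolumetricMesh: %d nodes, %d hex elements (%d x %d x %d), wall %.1f ml, cavity %.1f ml\n",
    nrow(object@nodes), nrow(object@elems), object@dims[1] - 1L,
    object@dims[2], object@dims[3] - 1L, wallVolume(object),
    cavityVolume(object)))
})
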