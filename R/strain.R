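# Directional myocardial strains relative to end-diastole.

#' Element deformation gradients from nodal positions
#'
#' Trilinear one-point-quadrature deformation gradient per element of a
#' deformed mesh state, relative to the reference configuration.
#'
#' @param mesh a \linkS4class{VolumetricMesh}.
#' @param positions N x 3 deformed node positions.
#' @return E x 9 matrix (column-major 3 x 3 per row).
#' @export
elementDeformation <- function(mesh, positions) {
  E <- nrow(mesh@elems)
  Fv <- matrix(0, E, 9)
  for (k in 1:3) for (d in 1:3) {
    col <- (k - 1L) * 3L + d
    acc <- numeric(E)
    for (a in 1:8)
      acc <- acc + positions[mesh@elems[, a], d] * mesh@gradN[, a, k]
    Fv[, col] <- acc
  }
  Fv
}

# |F d| per element for direction matrix dirs (E x 3); Fv is E x 9.
stretchAlong <- function(Fv, dirs) {
  out <- 0
  for (d in 1:3) {
    comp <- Fv[, d] * dirs[, 1] + Fv[, 3 + d] * dirs[, 2] +
            Fv[, 6 + d] * dirs[, 3]
    out <- out + comp^2
  }
  sqrt(out)
}

# Element-centroid local frames (averaged nodal frames, normalized).
elementFrames <- function(mesh) {
  avg <- function(M) {
    out <- matrix(0, nrow(mesh@elems), 3)
    for (a in 1:8) out <- out + M[mesh@elems[, a], ]
    normalizeRows(out / 8)
  }
  list(r = avg(mesh@frameR), c = avg(mesh@frameC), l = avg(mesh@frameL))
}

# Orthonormal local frames recomputed from a deformed configuration:
# radial from the endo-to-epi direction per station, circumferential from
# the mid-surface tangent, longitudinal their cross product. Returned per
# element (averaged over its nodes, re-orthonormalized).
framesFromPositions <- function(mesh, positions) {
  endoI <- layerIndex(mesh, "endo"); epiI <- layerIndex(mesh, "epi")
  nCirc <- mesh@dims[2]; nLongP <- mesh@dims[3]
  en <- positions[as.vector(endoI), , drop = FALSE]
  ep <- positions[as.vector(epiI), , drop = FALSE]
  rhat <- normalizeRows(ep - en)
  mid <- (en + ep) / 2
  midA <- array(t(mid), c(3, nCirc, nLongP))
  dU <- midA[, c(2:nCirc, 1), ] - midA[, c(nCirc, 1:(nCirc - 1)), ]
  dUM <- t(matrix(dU, 3))
  chat <- normalizeRows(dUM - rowSums(dUM * rhat) * rhat)
  lhat <- cbind(rhat[, 2] * chat[, 3] - rhat[, 3] * chat[, 2],
                rhat[, 3] * chat[, 1] - rhat[, 1] * chat[, 3],
                rhat[, 1] * chat[, 2] - rhat[, 2] * chat[, 1])
  nLayers <- mesh@dims[1]
  expand <- function(M) do.call(rbind, rep(list(M), nLayers))
  fr <- list(r = expand(rhat), c = expand(chat), l = expand(lhat))
  avg <- function(M) {
    out <- matrix(0, nrow(mesh@elems), 3)
    for (a in 1:8) out <- out + M[mesh@elems[, a], ]
    normalizeRows(out / 8)
  }
  r <- avg(fr$r); c2 <- avg(fr$c)
  c2 <- normalizeRows(c2 - rowSums(c2 * r) * r)
  l <- cbind(r[, 2] * c2[, 3] - r[, 3] * c2[, 2],
             r[, 3] * c2[, 1] - r[, 1] * c2[, 3],
             r[, 1] * c2[, 2] - r[, 2] * c2[, 1])
  list(r = r, c = c2, l = l)
}

# Batch 3x3 inverse and product for E x 9 column-major stores.
batInv3 <- function(Fv) {
  Fc <- function(d, k) Fv[, (k - 1L) * 3L + d]
  J <- Fc(1,1) * (Fc(2,2) * Fc(3,3) - Fc(2,3) * Fc(3,2)) -
       Fc(1,2) * (Fc(2,1) * Fc(3,3) - Fc(2,3) * Fc(3,1)) +
       Fc(1,3) * (Fc(2,1) * Fc(3,2) - Fc(2,2) * Fc(3,1))
  inv <- matrix(0, nrow(Fv), 9)
  co <- function(a1, a2, b1, b2)
    Fc(a1, b1) * Fc(a2, b2) - Fc(a1, b2) * Fc(a2, b1)
  inv[, 1] <- co(2, 3, 2, 3); inv[, 4] <- -co(1, 3, 2, 3)
  inv[, 7] <- co(1, 2, 2, 3)
  inv[, 2] <- -co(2, 3, 1, 3); inv[, 5] <- co(1, 3, 1, 3)
  inv[, 8] <- -co(1, 2, 1, 3)
  inv[, 3] <- co(2, 3, 1, 2); inv[, 6] <- -co(1, 3, 1, 2)
  inv[, 9] <- co(1, 2, 1, 2)
  inv / J
}

batMul3 <- function(A, B) {
  out <- matrix(0, nrow(A), 9)
  for (d in 1:3) for (k in 1:3) {
    col <- (k - 1L) * 3L + d
    out[, col] <- A[, d] * B[, (k - 1L) * 3L + 1L] +
                  A[, 3L + d] * B[, (k - 1L) * 3L + 2L] +
                  A[, 6L + d] * B[, (k - 1L) * 3L + 3L]
  }
  out
}

#' Directional myocardial strains over the cycle
#'
#' For each element and output frame, the Green-Lagrange normal strain of
#' the end-diastolic local radial/circumferential/longitudinal directions
#' (orthonormal frames recomputed from the end-diastolic geometry) under
#' the incremental deformation from end-diastole:
#' e_d = (lambda_d^2 - 1)/2 with lambda_d the stretch of direction d under
#' F(t) F(ED)^-1. Strains are zero at the reference frame by construction.
#' Elements are labelled "scar" (blend weight above 0.5) or "remote".
#' Set \code{type = "engineering"} for stretch-minus-one strains instead.
#'
#' @param result a \linkS4class{SimulationResult}.
#' @param frames frame indices to evaluate (default all).
#' @return a \linkS4class{StrainField}.
#' @export
computeStrain <- function(result, frames = NULL,
                          type = c("green", "engineering")) {
  type <- match.arg(type)
  if (is.null(frames)) frames <- seq_along(result@time)
  mesh <- result@mesh
  # directions: orthonormal local frames of the end-diastolic geometry
  fr <- framesFromPositions(mesh, result@positionsED)
  FEDinv <- batInv3(t(result@FelED))
  nF <- length(frames)
  E <- nrow(mesh@elems)
  er <- matrix(0, E, nF); ec <- er; el <- er
  toStrain <- if (type == "green") function(lam) (lam^2 - 1) / 2
    else function(lam) lam - 1
  for (j in seq_len(nF)) {
    Frel <- batMul3(t(result@Fel[, , frames[j]]), FEDinv)
    er[, j] <- toStrain(stretchAlong(Frel, fr$r))
    ec[, j] <- toStrain(stretchAlong(Frel, fr$c))
    el[, j] <- toStrain(stretchAlong(Frel, fr$l))
  }
  region <- factor(ifelse(result@scarWeight > 0.5, "scar", "remote"),
                   levels = c("remote", "scar"))
  new("StrainField", er = er, ec = ec, el = el, region = region,
      time = result@time[frames])
}

#' Directional strain between two deformation states
#'
#' Low-level form of \code{\link{computeStrain}}: strain of a
#' reference-frame direction under the deformation from a reference state
#' to a deformed state, both given as element deformation gradients
#' relative to the same stress-free mesh.
#'
#' @param Fref,Fdef E x 9 deformation gradients (reference and deformed).
#' @param dirs E x 3 unit directions in the stress-free configuration.
#' @param type "green" (default) for Green-Lagrange normal strain,
#'   "engineering" for stretch minus one.
#' @return numeric vector of strains.
#' @export
directionalStrain <- function(Fref, Fdef, dirs,
                              type = c("green", "engineering")) {
  type <- match.arg(type)
  lam <- stretchAlong(Fdef, dirs) / stretchAlong(Fref, dirs)
  if (type == "green") (lam^2 - 1) / 2 else lam - 1
}
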