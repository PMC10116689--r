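#' Construct an elliptical free-wall scar
#'
#' @param centerPhi azimuth of the scar center (rad; pi is the free wall
#'   opposite the septal azimuth 0).
#' @param centerV longitudinal center (0 apex .. 1 base).
#' @param semiCirc,semiLong elliptical semi-axes (mm).
#' @param transitionWidth core-to-remote transition width (mm).
#' @param thicknessFactor wall-thinning multiplier at the core (< 1).
#' @param stiffnessFactor passive-stiffness multiplier at the core (> 1).
#' @param taFactor active-stress multiplier at the core (~0).
#' @param conductionFactor conduction-velocity multiplier at the core (< 1).
#' @return a \linkS4class{ScarDefect}.
#' @export
scarDefect <- function(centerPhi = pi, centerV = 0.55, semiCirc = 25,
                       semiLong = 25, transitionWidth = 16,
                       thicknessFactor = 0.7, stiffnessFactor = 5,
                       taFactor = 0.02, conductionFactor = 0.5) {
  new("ScarDefect", centerPhi = centerPhi, centerV = centerV,
      semiCirc = semiCirc, semiLong = semiLong,
      transitionWidth = transitionWidth, thicknessFactor = thicknessFactor,
      stiffnessFactor = stiffnessFactor, taFactor = taFactor,
      conductionFactor = conductionFactor)
}

wrapAngle <- function(x) ((x + pi) %% (2 * pi)) - pi

# Smooth scar blend weight in [0, 1]: 1 inside the elliptical core,
# C1-decaying to exactly 0 beyond the transition width.
scarBlendAt <- function(phi, v, R, L, scar) {
  dC <- R * wrapAngle(phi - scar@centerPhi)
  dL <- (v - scar@centerV) * L
  rho <- sqrt((dC / scar@semiCirc)^2 + (dL / scar@semiLong)^2)
  distOut <- pmax(rho - 1, 0) * (scar@semiCirc + scar@semiLong) / 2
  1 - smoothstep(distOut / scar@transitionWidth)
}

# Blend weights on mesh nodes or element centroids.
scarBlend <- function(mesh, scar, what = c("node", "elem")) {
  what <- match.arg(what)
  L <- diff(range(mesh@nodes[, 3]))
  if (what == "node") {
    R <- sqrt(mesh@nodes[, 1]^2 + mesh@nodes[, 2]^2)
    scarBlendAt(mesh@nodePhi, mesh@nodeV, R, L, scar)
  } else {
    ctr <- (mesh@nodes[mesh@elems[, 1], ] + mesh@nodes[mesh@elems[, 7], ]) / 2
    R <- sqrt(ctr[, 1]^2 + ctr[, 2]^2)
    scarBlendAt(mesh@elemPhi, mesh@elemV, R, L, scar)
  }
}

#' Personalize anatomy and model inputs to a pathology preset
#'
#' NOR leaves all inputs unchanged. DCM and HCM stiffen the passive tissue
#' by setting the pathology multiplier on the stress-like HO coefficients
#' (5 to 10 fold). INFARCT thins the wall inside an elliptical free-wall
#' scar (epicardium pulled toward the endocardium by the thickness factor,
#' blended smoothly into healthy tissue) and attaches the scar so that the
#' solver scales passive stiffness, active stress and conduction locally.
#'
#' @param grid an \linkS4class{LVSurfaceGrid} reference anatomy.
#' @param material a \linkS4class{MaterialParams}.
#' @param activation an \linkS4class{ActivationModel}.
#' @param preset one of "NOR", "DCM", "HCM", "INFARCT".
#' @param scar \linkS4class{ScarDefect} used for INFARCT (default scar if
#'   missing).
#' @param pathologyScale stiffening factor for DCM/HCM in [5, 10].
#' @return list with personalized \code{grid}, \code{material},
#'   \code{activation} and \code{scar} (NULL unless INFARCT).
#' @export
applyPathology <- function(grid, material, activation, preset,
                           scar = NULL, pathologyScale = 5) {
  if (!preset %in% c("NOR", "DCM", "HCM", "INFARCT"))
    stop("unknown preset: ", preset)
  out <- list(grid = grid, material = material, activation = activation,
              scar = NULL)
  if (preset %in% c("DCM", "HCM")) {
    stopifnot(pathologyScale >= 5, pathologyScale <= 10)
    material@pathologyScale <- pathologyScale
    out$material <- material
  } else if (preset == "INFARCT") {
    if (is.null(scar)) scar <- scarDefect()
    nU <- gridDim(grid)[1]; nV <- gridDim(grid)[2]
    phi <- 2 * pi * (seq_len(nU) - 1L) / nU
    vv <- (seq_len(nV) - 1L) / (nV - 1L)
    mid <- (grid@endo + grid@epi) / 2
    R <- sqrt(mid[1, , ]^2 + mid[2, , ]^2)
    L <- diff(range(grid@endo[3, , ]))
    b <- scarBlendAt(matrix(phi, nU, nV), matrix(vv, nU, nV, byrow = TRUE),
                     R, L, scar)
    shrink <- 1 - (1 - scar@thicknessFactor) * b
    epi <- grid@epi
    for (d in 1:3)
      epi[d, , ] <- grid@endo[d, , ] +
        (grid@epi[d, , ] - grid@endo[d, , ]) * shrink
    out$grid <- new("LVSurfaceGrid", endo = grid@endo, epi = epi,
                    basePlane = grid@basePlane, apex = grid@apex)
    out$scar <- scar
  }
  out
}
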