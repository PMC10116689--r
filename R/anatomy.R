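#' Construct anatomical parameters
#'
#' Convenience constructor for \linkS4class{AnatomyParams} with documented
#' physiologic defaults (healthy adult LV): cavity length 90 mm, base
#' radius 23.5 mm, wall thickness 9 mm (base) to 7 mm (apex), sphericity
#' 0.5, no basal tilt.
#'
#' @param cavityLength apex-to-base cavity length (mm).
#' @param baseRadius endocardial radius at the base plane (mm).
#' @param wallThicknessBase,wallThicknessApex wall thickness (mm).
#' @param sphericity cavity shape factor in [0, 1]; 0 gives an elongated
#'   half-ellipsoid truncated at its equator, 1 a near-spherical cavity
#'   truncated well above the equator.
#' @param baseTilt basal-plane tilt (deg).
#' @param globalScale isotropic scale factor.
#' @param rngSeed integer seed recorded for provenance.
#' @return an \linkS4class{AnatomyParams} object.
#' @export
anatomyParams <- function(cavityLength = 90, baseRadius = 23.5,
                          wallThicknessBase = 9, wallThicknessApex = 7,
                          sphericity = 0.5, baseTilt = 0, globalScale = 1,
                          rngSeed = 0) {
  new("AnatomyParams", cavityLength = cavityLength, baseRadius = baseRadius,
      wallThicknessBase = wallThicknessBase,
      wallThicknessApex = wallThicknessApex, sphericity = sphericity,
      baseTilt = baseTilt, globalScale = globalScale, rngSeed = rngSeed)
}

# Ellipsoid geometry implied by (cavityLength, sphericity): long semi-axis
# c and truncation polar angle thetaB, with apex at the origin.
anatomyEllipsoid <- function(params) {
  L <- params@cavityLength
  cAx <- L * (1 - 0.4 * params@sphericity)
  cosB <- 1 - L / cAx
  thetaB <- acos(pmin(pmax(cosB, -1), 1))
  aAx <- params@baseRadius / sin(thetaB)
  list(a = aAx, c = cAx, thetaB = thetaB)
}

#' Analytic cavity volume of the untilted truncated-spheroid anatomy
#'
#' Closed-form volume (ml) of the endocardial cavity described by an
#' \linkS4class{AnatomyParams} object, before any basal tilt: a spheroid
#' with semi-axes (a, a, c) truncated at height \code{cavityLength} above
#' the apex pole.
#'
#' @param params an \linkS4class{AnatomyParams} object.
#' @return cavity volume in ml.
#' @export
analyticCavityVolume <- function(params) {
  g <- anatomyEllipsoid(params)
  L <- params@cavityLength
  vol <- pi * g$a^2 * (L - ((L - g$c)^3 + g$c^3) / (3 * g$c^2))
  vol * params@globalScale^3 / 1000
}

#' Generate a synthetic LV surface-grid anatomy
#'
#' Builds a truncated thick-walled prolate-ellipsoid left ventricle as a
#' pair of structured surface grids. The endocardium is a spheroid (semi-
#' axes set by cavity length, base radius and sphericity) truncated at the
#' base; the epicardium is offset along the outward surface normal by a
#' wall thickness varying linearly from apex to base. An optional smooth
#' basal tilt rotates the upper part of the ventricle about the y axis.
#' Deterministic given the parameters.
#'
#' @param params an \linkS4class{AnatomyParams} object.
#' @param nU,nV grid resolution (circumferential x apex-to-base), default
#'   128 x 128.
#' @return an \linkS4class{LVSurfaceGrid}.
#' @export
generateAnatomy <- function(params, nU = 128L, nV = 128L) {
  stopifnot(is(params, "AnatomyParams"))
  validObject(params)
  g <- anatomyEllipsoid(params)
  L <- params@cavityLength
  phi <- 2 * pi * (seq_len(nU) - 1L) / nU
  vv <- (seq_len(nV) - 1L) / (nV - 1L)
  theta <- vv * g$thetaB

  st <- sin(theta); ct <- cos(theta)
  cp <- cos(phi); sp <- sin(phi)
  # outer products: nU x nV
  X <- g$a * outer(cp, st); Y <- g$a * outer(sp, st)
  Z <- matrix(g$c * (1 - ct), nU, nV, byrow = TRUE)

  # outward ellipsoid normal
  nx <- outer(cp, st / g$a); ny <- outer(sp, st / g$a)
  nz <- matrix(-ct / g$c, nU, nV, byrow = TRUE)
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  nx <- nx / nn; ny <- ny / nn; nz <- nz / nn

  h <- params@wallThicknessApex +
    (params@wallThicknessBase - params@wallThicknessApex) *
    matrix(vv, nU, nV, byrow = TRUE)
  if (any(h <= 0.5))
    stop("non-physical anatomy: wall thickness <= 0.5 mm after modulation")

  endo <- array(0, c(3, nU, nV)); epi <- endo
  endo[1, , ] <- X; endo[2, , ] <- Y; endo[3, , ] <- Z
  epi[1, , ] <- X + h * nx; epi[2, , ] <- Y + h * ny
  # the wall is truncated at the base plane: the epicardial surface must
  # not extend beyond it
  epi[3, , ] <- pmin(Z + h * nz, L)

  baseNormal <- c(0, 0, 1)
  if (params@baseTilt != 0) {
    ang <- deg2rad(params@baseTilt)
    pivot <- c(0, 0, 0.55 * L)
    tiltPts <- function(pts) {
      P <- matrix(pts, 3)
      w <- smoothstep((P[3, ] / L - 0.4) / 0.6)
      out <- P
      for (i in which(w > 0)) {
        R <- rotY(ang * w[i])
        out[, i] <- R %*% (P[, i] - pivot) + pivot
      }
      array(out, dim(pts))
    }
    endo <- tiltPts(endo); epi <- tiltPts(epi)
    baseNormal <- as.vector(rotY(ang) %*% baseNormal)
  }
  endo <- endo * params@globalScale
  epi <- epi * params@globalScale

  basePoint <- rowMeans(matrix(endo[, , nV], 3))
  new("LVSurfaceGrid", endo = endo, epi = epi,
      basePlane = list(point = basePoint, normal = baseNormal),
      apex = endo[, 1, 1])
}

#' @describeIn cavityVolume divergence-theorem volume of the endocardial
#'   grid surface closed over the base ring.
#' @export
setMethod("cavityVolume", "LVSurfaceGrid", function(x, ...) {
  gridEnclosedVolume(x@endo) / 1000
})

#' Mean wall thickness of a surface grid (mm)
#'
#' Average endo-to-epi point distance over the grid; \code{row} selects a
#' single apex-to-base row (e.g. the base row \code{gridDim(x)[2]}).
#'
#' @param x an \linkS4class{LVSurfaceGrid}.
#' @param row optional v-row index.
#' @return thickness in mm.
#' @export
wallThickness <- function(x, row = NULL) {
  d <- sqrt(colSums((x@epi - x@endo)^2, dims = 1))
  if (!is.null(row)) mean(d[, row]) else mean(d)
}

#' @describeIn LVSurfaceGrid-class grid dimensions (Nu, Nv).
#' @export
setMethod("gridDim", "LVSurfaceGrid", function(object) dim(object@endo)[2:3])

setMethod("show", "LVSurfaceGrid", function(object) {
  d <- gridDim(object)
  cat(sprintf(
    "LVSurfaceGrid: %d x %d grid, cavity %.1f ml, mean wall %.1f mm\n",
    d[1], d[2], cavityVolume(object), wallThickness(object)))
})

#' Sample anatomical parameters for a synthetic population
#'
#' Draws \code{n} parameter sets from preset-specific distributions that
#' emulate the anatomical variability of a training population: healthy
#' (NOR) hearts with normal cavity and wall, dilated (DCM) hearts with
#' enlarged thin-walled cavities, hypertrophic (HCM) hearts with thickened
#' walls and near-normal cavities. Variation covers global scale, length,
#' wall thickness, sphericity and basal tilt.
#'
#' @param n number of parameter sets.
#' @param preset one of "NOR", "DCM", "HCM" or "MIX" (equal thirds).
#' @param seed RNG seed.
#' @return list of \linkS4class{AnatomyParams}.
#' @export
sampleAnatomyParams <- function(n, preset = "MIX", seed = 1) {
  stopifnot(preset %in% c("NOR", "DCM", "HCM", "MIX"))
  set.seed(seed)
  draw1 <- function(p) {
    base <- switch(p,
      NOR = list(len = 90, rad = 23.5, wb = 9, wa = 7, sph = 0.5),
      DCM = list(len = 100, rad = 30.5, wb = 6.5, wa = 5.5, sph = 0.75),
      HCM = list(len = 88, rad = 24.5, wb = 15, wa = 10, sph = 0.55))
    anatomyParams(
      cavityLength = base$len * stats::rnorm(1, 1, 0.05),
      baseRadius = base$rad * stats::rnorm(1, 1, 0.06),
      wallThicknessBase = max(2, base$wb * stats::rnorm(1, 1, 0.08)),
      wallThicknessApex = max(1.5, base$wa * stats::rnorm(1, 1, 0.08)),
      sphericity = pmin(pmax(base$sph + stats::rnorm(1, 0, 0.06), 0), 1),
      baseTilt = stats::rnorm(1, 0, 4),
      globalScale = stats::rnorm(1, 1, 0.05),
      rngSeed = seed)
  }
  kinds <- if (preset == "MIX")
    rep(c("NOR", "DCM", "HCM"), length.out = n) else rep(preset, n)
  lapply(kinds, draw1)
}
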