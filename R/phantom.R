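# Label-map phantom assembly: LV voxelization, procedural torso
# background, and composition.

#' The 12-class label dictionary
#'
#' Integer labels of the multi-class segmentation masks: background/air,
#' body soft tissue, left and right lung, LV myocardium, LV blood pool,
#' RV myocardium, RV blood pool, left and right atrium, aorta, and a
#' liver/subcutaneous-fat bundle.
#'
#' @return named integer vector of length 12.
#' @export
phantomClasses <- function() {
  c(background = 0L, body = 1L, lungL = 2L, lungR = 3L,
    lvMyo = 4L, lvBlood = 5L, rvMyo = 6L, rvBlood = 7L,
    la = 8L, ra = 9L, aorta = 10L, liverFat = 11L)
}

#' Define a regular voxel grid
#'
#' @param spacing voxel spacing (mm), length 3 (x, y, slice).
#' @param origin world coordinate of voxel (1,1,1) (mm).
#' @param dims integer(3) voxel counts.
#' @return list grid specification.
#' @export
gridSpec <- function(spacing, origin, dims) {
  stopifnot(all(spacing > 0), length(dims) == 3)
  list(spacing = spacing, origin = origin, dims = as.integer(dims))
}

gridAxis <- function(gs, d) gs$origin[d] + (seq_len(gs$dims[d]) - 1L) * gs$spacing[d]

# Intersect each circumferential column of a structured surface (3 x nu x
# nv, apex-to-base in v) with the plane z = z0; returns nu x 2 polygon or
# NULL if the plane misses the surface.
slicePolygon <- function(surf, z0) {
  nu <- dim(surf)[2]; nv <- dim(surf)[3]
  poly <- matrix(NA_real_, nu, 2)
  for (i in seq_len(nu)) {
    zs <- surf[3, i, ]
    cross <- which((zs[-nv] - z0) * (zs[-1] - z0) <= 0)
    if (!length(cross)) return(NULL)
    j <- cross[1]
    f <- if (zs[j + 1] == zs[j]) 0 else (z0 - zs[j]) / (zs[j + 1] - zs[j])
    poly[i, ] <- (1 - f) * surf[1:2, i, j] + f * surf[1:2, i, j + 1]
  }
  poly
}

# Rasterize: inside-epi & not inside-endo -> myo; inside-endo -> blood.
rasterizeWall <- function(slice, endoPoly, epiPoly, xs, ys, classes) {
  if (is.null(epiPoly)) return(slice)
  nx <- length(xs); ny <- length(ys)
  xb <- range(epiPoly[, 1]); yb <- range(epiPoly[, 2])
  ix <- which(xs >= xb[1] - 1 & xs <= xb[2] + 1)
  iy <- which(ys >= yb[1] - 1 & ys <= yb[2] + 1)
  if (!length(ix) || !length(iy)) return(slice)
  px <- rep(xs[ix], times = length(iy))
  py <- rep(ys[iy], each = length(ix))
  inEpi <- pointInPolygon(px, py, epiPoly)
  inEndo <- if (is.null(endoPoly)) rep(FALSE, length(px)) else
    pointInPolygon(px, py, endoPoly)
  sub <- slice[ix, iy]
  sub[matrix(inEpi & !inEndo, length(ix))] <- classes[["lvMyo"]]
  sub[matrix(inEndo, length(ix))] <- classes[["lvBlood"]]
  slice[ix, iy] <- sub
  slice
}

#' Voxelize an LV wall into a label volume
#'
#' Slices the deformed endo/epi surfaces at each grid slice position and
#' rasterizes: voxels inside the endocardium become LV blood pool, voxels
#' between endo- and epicardium LV myocardium, everything else background.
#'
#' @param mesh a \linkS4class{VolumetricMesh}.
#' @param grid a \code{\link{gridSpec}} covering the ventricle in x/y.
#' @param positions optional deformed node positions (default reference).
#' @param frame frame index stored in the result.
#' @return a \linkS4class{LabelVolume} with classes background, lvMyo,
#'   lvBlood.
#' @export
voxelizeLV <- function(mesh, grid, positions = mesh@nodes, frame = 1) {
  endoI <- layerIndex(mesh, "endo"); epiI <- layerIndex(mesh, "epi")
  toSurf <- function(idx) {
    s <- t(positions[as.vector(idx), , drop = FALSE])
    dim(s) <- c(3, nrow(idx), ncol(idx))
    # prepend the apex cap centroid so apical slices close
    out <- array(0, c(3, nrow(idx), ncol(idx) + 1L))
    out[, , 1] <- rowMeans(matrix(s[, , 1], 3))
    out[, , -1] <- s
    out
  }
  voxelizeSurfaces(toSurf(endoI), toSurf(epiI), grid, frame = frame)
}

#' Voxelize a pair of structured surfaces (low-level)
#'
#' @param endo,epi 3 x nu x nv coordinate arrays (apex/south pole first).
#' @param grid a \code{\link{gridSpec}}.
#' @param frame frame index stored in the result.
#' @return a \linkS4class{LabelVolume}.
#' @export
voxelizeSurfaces <- function(endo, epi, grid, frame = 1) {
  cls <- phantomClasses()
  xs <- gridAxis(grid, 1); ys <- gridAxis(grid, 2); zs <- gridAxis(grid, 3)
  xr <- range(epi[1, , ]); yr <- range(epi[2, , ])
  if (xr[1] < min(xs) - 1 || xr[2] > max(xs) + 1 ||
      yr[1] < min(ys) - 1 || yr[2] > max(ys) + 1)
    stop("voxel grid does not cover the mesh in-plane")
  vol <- array(cls[["background"]], grid$dims)
  for (k in seq_along(zs)) {
    vol[, , k] <- rasterizeWall(vol[, , k], slicePolygon(endo, zs[k]),
                                slicePolygon(epi, zs[k]), xs, ys, cls)
  }
  new("LabelVolume", data = vol, spacing = grid$spacing,
      origin = grid$origin, classes = cls, frame = frame)
}

#' Construct a procedural torso background model
#'
#' Parametric stand-in for an anthropomorphic torso phantom: body ellipse
#' with a subcutaneous fat rim, two lungs, a placeholder LV (whose
#' epicardial contour is later warped to match the simulated foreground),
#' an RV crescent with periodic contraction, atria (basal slices), a
#' descending aorta and a liver block (apical slices). Geometry is jittered
#' once from the seed; the class dictionary never changes.
#'
#' @param seed integer seed.
#' @return a \linkS4class{TorsoModel}.
#' @export
torsoModel <- function(seed = 1) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  jit <- function(x, s) x * stats::rnorm(length(x), 1, s)
  p <- list(
    bodyCenter = c(45, -5) + stats::rnorm(2, 0, 3),
    bodyAxes = jit(c(190, 130), 0.03),
    fatRim = 9,
    lungLCenter = c(100, 10) + stats::rnorm(2, 0, 3),
    lungLAxes = jit(c(52, 70), 0.06),
    lungRCenter = c(-22, 25) + stats::rnorm(2, 0, 3),
    lungRAxes = jit(c(42, 58), 0.06),
    lvCenter = c(0, 0),
    lvEpiR = 33, lvWall = 8,
    rvCenter = c(-28, -10), rvAxes = c(27, 32), rvWall = 4.5,
    rvSqueeze = 0.16,
    laCenter = c(16, 40), laR = 15,
    raCenter = c(-18, 38), raR = 13,
    aortaCenter = c(52, 42) + stats::rnorm(2, 0, 2), aortaR = 10.5,
    liverCenter = c(85, -32), liverAxes = c(72, 52))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  new("TorsoModel", params = p, seed = seed)
}

inEllipse <- function(px, py, center, axes) {
  ((px - center[1]) / (axes[1] / 2))^2 + ((py - center[2]) / (axes[2] / 2))^2 <= 1
}

#' Generate the torso background label volume
#'
#' Paints the torso primitives slice by slice. The RV blood pool contracts
#' periodically with the cardiac phase. Atria are painted in basal slices
#' (upper third of the stack), the liver in apical slices (lower third);
#' with fewer than three slices they share slices so that all 12 classes
#' appear in the volume.
#'
#' @param torso a \linkS4class{TorsoModel}.
#' @param grid a \code{\link{gridSpec}}; slices are ordered apex to base.
#' @param phase cardiac phase in [0, 1).
#' @return a \linkS4class{LabelVolume} containing all 12 classes.
#' @export
generateBackground <- function(torso, grid, phase = 0) {
  stopifnot(phase >= 0, phase < 1)
  p <- torso@params
  cls <- phantomClasses()
  xs <- gridAxis(grid, 1); ys <- gridAxis(grid, 2); zs <- gridAxis(grid, 3)
  nz <- length(zs)
  squeeze <- 1 - p$rvSqueeze * (0.5 - 0.5 * cos(2 * pi * phase))
  vol <- array(cls[["background"]], grid$dims)
  px <- rep(xs, times = length(ys)); py <- rep(ys, each = length(xs))
  dims2 <- c(length(xs), length(ys))
  zrank <- rank(zs, ties.method = "first")
  for (k in seq_len(nz)) {
    sl <- matrix(cls[["background"]], dims2[1], dims2[2])
    paint <- function(mask, class) {
      sl[matrix(mask, dims2[1])] <<- cls[[class]]
    }
    paint(inEllipse(px, py, p$bodyCenter, p$bodyAxes), "liverFat")  # fat rim
    paint(inEllipse(px, py, p$bodyCenter, p$bodyAxes - 2 * p$fatRim), "body")
    paint(inEllipse(px, py, p$lungLCenter, p$lungLAxes), "lungL")
    paint(inEllipse(px, py, p$lungRCenter, p$lungRAxes), "lungR")
    isBasal <- zrank[k] > 2 * nz / 3 || nz < 3
    isApical <- zrank[k] <= nz / 3 || nz < 3
    if (isApical)
      paint(inEllipse(px, py, p$liverCenter, p$liverAxes), "liverFat")
    # RV crescent: outside the LV epi placeholder
    rvAx <- p$rvAxes * squeeze
    lvEpi <- (px - p$lvCenter[1])^2 + (py - p$lvCenter[2])^2 <= p$lvEpiR^2
    rvOuter <- inEllipse(px, py, p$rvCenter, rvAx + 2 * p$rvWall) & !lvEpi
    rvInner <- inEllipse(px, py, p$rvCenter, rvAx) & !lvEpi
    paint(rvOuter, "rvMyo"); paint(rvInner, "rvBlood")
    if (isBasal) {
      paint((px - p$laCenter[1])^2 + (py - p$laCenter[2])^2 <= p$laR^2, "la")
      paint((px - p$raCenter[1])^2 + (py - p$raCenter[2])^2 <= p$raR^2, "ra")
    }
    paint((px - p$aortaCenter[1])^2 + (py - p$aortaCenter[2])^2 <= p$aortaR^2,
          "aorta")
    # LV placeholder on top
    rIn <- p$lvEpiR - p$lvWall * (2 - squeeze)
    paint(lvEpi, "lvMyo")
    paint((px - p$lvCenter[1])^2 + (py - p$lvCenter[2])^2 <=
            (rIn * squeeze)^2, "lvBlood")
    vol[, , k] <- sl
  }
  new("LabelVolume", data = vol, spacing = grid$spacing,
      origin = grid$origin, classes = cls, frame = phase)
}

#' Compose foreground and (warped) background label maps
#'
#' Foreground LV classes (myocardium and blood pool) overwrite the
#' background so the LV ground truth is preserved exactly; elsewhere the
#' background is kept.
#'
#' @param fg,bg \linkS4class{LabelVolume}s on the same grid.
#' @return a \linkS4class{LabelVolume}.
#' @export
composePhantom <- function(fg, bg) {
  if (!identical(dim(fg@data), dim(bg@data)) ||
      !isTRUE(all.equal(fg@spacing, bg@spacing)))
    stop("foreground and background grids do not match")
  cls <- phantomClasses()
  out <- bg@data
  # the background's placeholder LV must not survive composition: the LV
  # classes of the output are exactly the foreground's
  residual <- (out == cls[["lvMyo"]] | out == cls[["lvBlood"]])
  out[residual] <- cls[["body"]]
  lv <- fg@data == cls[["lvMyo"]] | fg@data == cls[["lvBlood"]]
  out[lv] <- fg@data[lv]
  new("LabelVolume", data = out, spacing = bg@spacing, origin = bg@origin,
      classes = cls, frame = fg@frame)
}

#' Count voxels of one class (ml)
#' @param vol a \linkS4class{LabelVolume}.
#' @param class class name or integer label.
#' @return volume in ml.
#' @export
classVolume <- function(vol, class) {
  id <- if (is.character(class)) vol@classes[[class]] else class
  sum(vol@data == id) * prod(vol@spacing) / 1000
}

setMethod("show", "LabelVolume", function(object) {
  present <- names(object@classes)[object@classes %in%
                                     unique(as.vector(object@data))]
  cat(sprintf(
    "LabelVolume: %s voxels at %s mm, classes: %s\n",
    paste(dim(object@data), collapse = " x "),
    paste(signif(object@spacing, 3), collapse = " x "),
    paste(present, collapse = ", ")))
})
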