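# End-to-end orchestration: shape -> mechanics -> phantom -> tissue ->
# imaging -> ground truth, with NIfTI/CSV/JSON outputs.

#' Run the biomechanical stage of a preset
#'
#' Builds the preset anatomy, applies the pathology personalization,
#' meshes, assigns fibers and simulates one cardiac cycle. Cached per
#' session by preset name and solver settings, since mechanics dominates
#' the pipeline cost.
#'
#' @param config a \linkS4class{PresetConfig}.
#' @param cache reuse a per-session cache (default TRUE).
#' @return list with grid, mesh, fibers, scar and the
#'   \linkS4class{SimulationResult}.
#' @export
runBiomech <- function(config, cache = TRUE) {
  sv <- config@solver
  key <- paste0("biomech_", config@name, "_",
                paste(unlist(sv), collapse = "_"), "_",
                config@activation@TaMax, "_",
                config@material@pathologyScale)
  if (cache && !is.null(.presetCache[[key]])) return(.presetCache[[key]])
  grid0 <- generateAnatomy(config@anatomy, nU = sv$gridNU, nV = sv$gridNV)
  pp <- applyPathology(grid0, config@material, config@activation,
                       config@name, scar = config@scar[[1]])
  mesh <- buildVolumeMesh(pp$grid, nTrans = sv$nTrans, nCirc = sv$nCirc,
                          nLong = sv$nLong)
  fibers <- assignFibers(mesh)
  res <- solveCycle(mesh, fibers, pp$material, pp$activation,
                    config@circulation, scar = pp$scar,
                    basisSize = sv$basisSize, nFrames = sv$nFrames,
                    dt = sv$dt, kPeri = sv$kPeri)
  out <- list(grid = pp$grid, mesh = mesh, fibers = fibers,
              scar = pp$scar, result = res)
  if (cache) .presetCache[[key]] <- out
  out
}

# Mid-ventricular slice positions (mm) for a simulation result.
midSlices <- function(result, nSlices = 1L, gap = 8) {
  zr <- range(result@mesh@nodes[, 3])
  zc <- zr[1] + 0.45 * diff(zr)
  zc + (seq_len(nSlices) - (nSlices + 1) / 2) * gap
}

#' Run a full preset through the imaging pipeline
#'
#' Executes shape generation, pathology personalization, the cardiac-cycle
#' simulation, label-map phantom assembly with background warping, tissue
#' property assignment with texture, bSSFP image formation, and
#' ground-truth packaging; writes cine NIfTI images, ground-truth masks
#' and displacement fields, strain curves (CSV) and a JSON manifest.
#' Deterministic given the configuration seeds.
#'
#' @param config a \linkS4class{PresetConfig} (or preset name).
#' @param outdir output directory (created if missing); NULL skips all
#'   file output.
#' @param imagingFrames cine frames to image (default the sequence's
#'   frame count, evenly subsampled from the simulated frames).
#' @return invisible list with the simulation result, phantom labels,
#'   cine image, ground-truth bundle and the manifest list.
#' @export
runPreset <- function(config, outdir = NULL, imagingFrames = NULL) {
  if (is.character(config)) config <- presetConfig(config)
  t0 <- Sys.time()
  sv <- config@solver
  sq <- config@sequence

  bm <- runBiomech(config)
  res <- bm$result

  nIm <- imagingFrames %||% sq@nFrames
  frameIdx <- unique(round(seq(1, length(res@time), length.out = nIm)))
  sq@nFrames <- length(frameIdx)
  sq@seed <- config@seeds$noise

  # image grids: target (image/ground truth) and high-res (phantom)
  zs <- midSlices(res, sv$nSlices)
  nt <- sq@matrixSize
  fov <- nt * sq@resolution
  ctr <- c(55, -15)                      # torso center (heart offset left)
  tgtGrid <- gridSpec(c(sq@resolution, sq@resolution,
                        if (length(zs) > 1) diff(zs)[1] else sq@sliceThickness),
                      c(ctr - fov / 2, zs[1]),
                      c(nt, length(zs)))
  hiF <- sv$hiResFactor
  hiGrid <- gridSpec(c(sq@resolution / hiF, sq@resolution / hiF,
                       tgtGrid$spacing[3]),
                     tgtGrid$origin, c(nt * hiF, length(zs)))

  torso <- torsoModel(config@seeds$shape)
  coils <- makeCoils(sq@nCoils, hiGrid, torsoCenter = ctr)
  tex <- textureModel(seed = config@seeds$texture)

  # static background texture field (advected per frame by the warp)
  bg0 <- generateBackground(torso, hiGrid, 0)
  cycleLen <- res@time[length(res@time)]

  mapsList <- list(); labsList <- list(); warps <- list()
  phantoms <- list()
  for (j in seq_along(frameIdx)) {
    f <- frameIdx[j]
    phase <- (res@time[f] %% cycleLen) / cycleLen
    fg <- voxelizeLV(bm$mesh, hiGrid, positions = res@positions[, , f],
                     frame = f)
    bg <- generateBackground(torso, hiGrid, phase)
    warped <- bg
    wf <- NULL
    for (k in seq_len(length(zs))) {
      fgC <- tryCatch(extractContour(fg@data[, , k],
                                     fg@classes[["lvMyo"]],
                                     hiGrid$spacing[1:2],
                                     hiGrid$origin[1:2]),
                      error = function(e) NULL)
      if (is.null(fgC)) next
      bgC <- extractContour(bg@data[, , k], bg@classes[["lvMyo"]],
                            hiGrid$spacing[1:2], hiGrid$origin[1:2])
      wk <- buildWarp(bgC, fgC, hiGrid)
      if (is.null(wf)) {
        wf <- wk
        wf@dx <- array(0, c(dim(wk@dx)[1:2], length(zs)))
        wf@dy <- wf@dx
      }
      wf@dx[, , k] <- wk@dx[, , 1]; wf@dy[, , k] <- wk@dy[, , 1]
    }
    if (!is.null(wf)) warped <- applyWarp(bg, wf)
    phl <- composePhantom(fg, warped)
    phantoms[[j]] <- phl
    maps <- assignProperties(phl)
    texMaps <- applyTexture(maps, phl, tex)
    if (!is.null(wf)) {
      # advect background texture with the background deformation
      ref <- applyTexture(assignProperties(bg0), bg0, tex)
      refW <- warpProperties(ref, wf)
      keep <- phl@data == phl@classes[["lvMyo"]] |
              phl@data == phl@classes[["lvBlood"]]
      texMaps@PD[!keep] <- refW@PD[!keep]
      texMaps@T1[!keep] <- refW@T1[!keep]
      texMaps@T2[!keep] <- pmin(refW@T2[!keep], refW@T1[!keep])
    }
    mapsList[[j]] <- texMaps
    labsList[[j]] <- phl
    warps[[j]] <- wf
  }

  cine <- simulateCine(mapsList, labsList, coils, sq, slice = 1L)

  gtGrid <- tgtGrid
  gt <- buildGroundTruth(res, gtGrid, frames = frameIdx)

  manifest <- list(
    preset = config@name,
    parameters = configToList(config),
    frames = frameIdx,
    sliceZ = zs,
    EDV = res@EDV, ESV = res@ESV, EF = res@EF, mass = res@mass,
    runtimeSec = as.numeric(Sys.time() - t0, units = "secs"),
    version = as.character(utils::packageVersion(
      methods::getPackageName(environment(runPreset)))))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeCineNifti(cine, file.path(outdir, "cine.nii"))
    writeMasksNifti(gt, file.path(outdir, "masks.nii"))
    ss <- gt@strainSummary
    utils::write.csv(ss, file.path(outdir, "strain_curves.csv"),
                     row.names = FALSE)
    traces <- data.frame(time = res@time, volume = res@volume,
                         plv = res@plv, pao = res@pao)
    utils::write.csv(traces, file.path(outdir, "hemodynamics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(result = res, phantoms = phantoms, cine = cine,
                 groundTruth = gt, warps = warps, manifest = manifest,
                 mapsList = mapsList))
}

writeCineNifti <- function(cine, path) {
  img <- RNifti::asNifti(cine@frames,
                         pixdim = c(cine@spacing[1:2], 1, 1))
  RNifti::writeNifti(img, path)
}

writeMasksNifti <- function(gt, path) {
  arr <- vapply(gt@masks, function(m) m@data,
                array(0L, dim(gt@masks[[1]]@data)))
  img <- RNifti::asNifti(arr,
                         pixdim = c(gt@masks[[1]]@spacing, 1))
  RNifti::writeNifti(img, path)
}
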