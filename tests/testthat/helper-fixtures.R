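# Shared fixtures, memoised per test session. Mechanics runs are the
# expensive part, so every preset cycle is simulated once and reused.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

smallAnatomy <- function() memo("smallAnatomy", {
  generateAnatomy(anatomyParams(), nU = 48L, nV = 48L)
})

smallMesh <- function() memo("smallMesh", {
  buildVolumeMesh(smallAnatomy(), nTrans = 3L, nCirc = 16L, nLong = 8L)
})

tinyMesh <- function() memo("tinyMesh", {
  g <- generateAnatomy(anatomyParams(), nU = 24L, nV = 24L)
  buildVolumeMesh(g, nTrans = 3L, nCirc = 8L, nLong = 5L)
})

shapePopulation <- function() memo("shapePopulation", {
  lapply(sampleAnatomyParams(60, "MIX", seed = 2),
         generateAnatomy, nU = 32L, nV = 32L)
})

fittedShapeModel <- function() memo("fittedShapeModel", {
  fitShapeModel(shapePopulation(), d = 10L, seed = 1)
})

presetRun <- function(name) memo(paste0("preset_", name), {
  t0 <- Sys.time()
  out <- runBiomech(presetConfig(name))
  out$elapsedSec <- as.numeric(Sys.time() - t0, units = "secs")
  out
})

# one imaged mid-ventricular NOR slice-frame at the default sequence
norImagingFixture <- function() memo("norImaging", {
  bm <- presetRun("NOR")
  res <- bm$result
  sq <- sequenceParams()
  zc <- CardioPhantom:::midSlices(res, 1L)
  hiGrid <- gridSpec(c(0.5, 0.5, 8), c(55 - 128, -15 - 128, zc),
                     c(512L, 512L, 1L))
  fg <- voxelizeLV(bm$mesh, hiGrid, positions = res@positions[, , 1])
  bg <- generateBackground(torsoModel(1), hiGrid, 0)
  ph <- composePhantom(fg, bg)
  maps <- applyTexture(assignProperties(ph), ph, textureModel(seed = 11))
  coils <- makeCoils(8L, hiGrid, torsoCenter = c(55, -15))
  sig <- bssfpSignal(maps@PD[, , 1], maps@T1[, , 1], maps@T2[, , 1], sq)
  k <- encodeKspace(sig, coils, sq)
  noiseless <- reconstructImage(k)
  blood <- ph@data[, , 1] == ph@classes[["lvBlood"]]
  bloodLow <- blood[seq(1, 512, 4), seq(1, 512, 4)]
  myo <- ph@data[, , 1] == ph@classes[["lvMyo"]]
  myoLow <- myo[seq(1, 512, 4), seq(1, 512, 4)]
  list(k = k, noiseless = noiseless, bloodLow = bloodLow, myoLow = myoLow,
       ph = ph, maps = maps, coils = coils, sq = sq, hiGrid = hiGrid)
})

presetStrain <- function(name) memo(paste0("strain_", name), {
  computeStrain(presetRun(name)$result)
})

# concentric-sphere surface grids (south pole first), for voxelization
sphereSurfaces <- function(rIn = 20, rOut = 30, nu = 48L, nv = 48L) {
  th <- seq(0, pi, length.out = nv)
  ph <- 2 * pi * (seq_len(nu) - 1L) / nu
  mk <- function(r) {
    s <- array(0, c(3, nu, nv))
    s[1, , ] <- r * outer(cos(ph), sin(th))
    s[2, , ] <- r * outer(sin(ph), sin(th))
    # common center at z = rOut so the spheres are concentric
    s[3, , ] <- matrix(rOut - r * cos(th), nu, nv, byrow = TRUE)
    s
  }
  list(endo = mk(rIn), epi = mk(rOut))
}
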