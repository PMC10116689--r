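test_that("mesh wall volume agrees with divergence-theorem surface volumes", {
  m <- buildVolumeMesh(smallAnatomy(), nTrans = 4L, nCirc = 32L, nLong = 16L)
  # divergence-theorem oracle on a surface layer of the mesh itself; the
  # two diagonal triangulations of each bilinear quad are averaged, which
  # reproduces the bilinear-patch flux of the hexahedral faces
  layerVol <- function(layer) {
    idx <- CardioPhantom:::layerIndex(m, layer)
    P <- m@nodes
    nCirc <- nrow(idx); nLongP <- ncol(idx)
    vol2 <- 0
    tv <- function(a, b, cc) {
      va <- P[a, , drop = FALSE]; vb <- P[b, , drop = FALSE]
      vc <- P[cc, , drop = FALSE]
      sum(va[, 1] * (vb[, 2] * vc[, 3] - vb[, 3] * vc[, 2]) +
          va[, 2] * (vb[, 3] * vc[, 1] - vb[, 1] * vc[, 3]) +
          va[, 3] * (vb[, 1] * vc[, 2] - vb[, 2] * vc[, 1])) / 6
    }
    for (j in seq_len(nLongP - 1L)) {
      i1 <- seq_len(nCirc); i2 <- i1 %% nCirc + 1L
      a <- idx[i1, j]; b <- idx[i2, j]; cc <- idx[i2, j + 1]; d <- idx[i1, j + 1]
      vol2 <- vol2 + (tv(a, b, cc) + tv(a, cc, d) +
                      tv(a, b, d) + tv(b, cc, d)) / 2
    }
    # apex fan and base cap
    i1 <- seq_len(nCirc); i2 <- i1 %% nCirc + 1L
    apexC <- colMeans(P[idx[, 1], , drop = FALSE])
    baseC <- colMeans(P[idx[, nLongP], , drop = FALSE])
    Paug <- rbind(P, apexC, baseC)
    tvA <- function(a, b, cc) {
      va <- Paug[a, , drop = FALSE]; vb <- Paug[b, , drop = FALSE]
      vc <- Paug[cc, , drop = FALSE]
      sum(va[, 1] * (vb[, 2] * vc[, 3] - vb[, 3] * vc[, 2]) +
          va[, 2] * (vb[, 3] * vc[, 1] - vb[, 1] * vc[, 3]) +
          va[, 3] * (vb[, 1] * vc[, 2] - vb[, 2] * vc[, 1])) / 6
    }
    nP <- nrow(P)
    vol2 <- vol2 + tvA(rep(nP + 1L, nCirc), idx[i2, 1], idx[i1, 1])
    vol2 <- vol2 + tvA(rep(nP + 2L, nCirc), idx[i1, nLongP], idx[i2, nLongP])
    abs(vol2) / 1000
  }
  expect_lt(abs(wallVolume(m) - (layerVol("epi") - layerVol("endo"))) /
              wallVolume(m), 0.01)
})

test_that("local frames are orthonormal and transmural coordinates correct", {
  m <- smallMesh()
  expect_lt(max(abs(rowSums(m@frameR * m@frameC))), 1e-8)
  expect_lt(max(abs(rowSums(m@frameR * m@frameL))), 1e-8)
  expect_lt(max(abs(sqrt(rowSums(m@frameR^2)) - 1)), 1e-8)
  cross <- cbind(
    m@frameR[, 2] * m@frameC[, 3] - m@frameR[, 3] * m@frameC[, 2],
    m@frameR[, 3] * m@frameC[, 1] - m@frameR[, 1] * m@frameC[, 3],
    m@frameR[, 1] * m@frameC[, 2] - m@frameR[, 2] * m@frameC[, 1])
  expect_lt(max(abs(cross - m@frameL)), 1e-8)
  # endo layer nodes carry t = 0 and sit on the endo surface
  endoIdx <- as.vector(CardioPhantom:::layerIndex(m, "endo"))
  expect_true(all(m@nodeT[endoIdx] == 0))
  expect_true(all(m@elemVol > 0))
})

test_that("cavity volume matches the analytic truncated spheroid", {
  p <- anatomyParams()
  g <- generateAnatomy(p, nU = 96L, nV = 96L)
  m <- buildVolumeMesh(g, nTrans = 3L, nCirc = 48L, nLong = 32L)
  expect_lt(abs(cavityVolume(m) - analyticCavityVolume(p)) /
              analyticCavityVolume(p), 0.005)
})

test_that("cavity volume scales cubically and is rotation invariant", {
  m <- tinyMesh()
  v0 <- cavityVolume(m)
  expect_equal(cavityVolume(m, positions = m@nodes * 1.7), v0 * 1.7^3,
               tolerance = 1e-12)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  expect_equal(cavityVolume(m, positions = m@nodes %*% R), v0,
               tolerance = 1e-9)
})

test_that("LV mass is density times wall volume and rigid-motion invariant", {
  m <- smallMesh()
  expect_equal(lvMass(m, rho = 1.05), wallVolume(m) * 1.05,
               tolerance = 1e-12)
  # arithmetic anchor: an 85.7 ml wall at 1.05 g/ml weighs 90 g
  expect_equal(85.7 * 1.05, 90.0, tolerance = 0.01)
  th <- -0.4
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3)
  expect_equal(wallVolume(m, positions = m@nodes %*% R + 5), wallVolume(m),
               tolerance = 1e-9)
})

test_that("degenerate meshing inputs are rejected", {
  g <- smallAnatomy()
  expect_error(buildVolumeMesh(g, nTrans = 2L), "nTrans")
  # self-intersecting surfaces: swap endo and epi so elements invert
  bad <- new("LVSurfaceGrid", endo = g@epi, epi = g@endo,
             basePlane = g@basePlane, apex = g@apex)
  expect_error(buildVolumeMesh(bad), "invert|intersect")
})
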