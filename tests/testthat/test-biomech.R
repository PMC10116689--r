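deg2rad_ <- function(x) x * pi / 180

# Material law, fibers, activation, circulation, strain kinematics and
# pathology personalization.

test_that("HO energy and stress vanish at the identity and match a numeric gradient", {
  mp <- materialParams()
  f <- c(1, 0, 0); s <- c(0, 0, 1)
  at0 <- passiveStress(diag(3), mp, f, s)
  expect_equal(at0$energy, 0, tolerance = 1e-14)
  expect_equal(max(abs(at0$stress)), 0, tolerance = 1e-12)

  set.seed(7)
  for (rep in 1:3) {
    F <- diag(3) + 0.05 * matrix(runif(9, -1, 1), 3)
    res <- passiveStress(F, mp, f, s)
    num <- matrix(0, 3, 3)
    h <- 1e-6
    for (i in 1:3) for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      num[i, j] <- (passiveStress(Fp, mp, f, s)$energy -
                    passiveStress(Fm, mp, f, s)$energy) / (2 * h)
    }
    expect_lt(max(abs(res$stress - num)) / max(abs(num)), 1e-4)
  }
})

test_that("fiber stress increases strictly under uniaxial fiber stretch", {
  mp <- materialParams()
  f <- c(1, 0, 0); s <- c(0, 0, 1)
  lams <- seq(1, 1.2, by = 0.02)
  sig <- vapply(lams, function(l) {
    F <- diag(c(l, 1 / sqrt(l), 1 / sqrt(l)))
    passiveStress(F, mp, f, s)$stress[1, 1]
  }, 0)
  expect_true(all(diff(sig) > 0))
  expect_error(passiveStress(diag(c(-1, 1, 1)), mp, f, s), "inversion")
})

test_that("fiber field follows the linear transmural helix law", {
  m <- tinyMesh()
  fib <- assignFibers(m, 60, -60)
  expect_equal(helixAngle(fib, 0), 60)
  expect_equal(helixAngle(fib, 0.5), 0)
  expect_equal(helixAngle(fib, 1), -60)
  expect_lt(max(abs(sqrt(rowSums(fib@fibers^2)) - 1)), 1e-8)
  expect_lt(max(abs(rowSums(fib@fibers * m@frameR))), 1e-8)
  # node at one-third depth has the interpolated helix angle
  mid <- which(abs(m@nodeT - 1 / 3) < 1e-9)[1]
  expect_equal(sum(fib@fibers[mid, ] * m@frameC[mid, ]),
               cos(deg2rad_(20)), tolerance = 1e-8)
})

test_that("active twitch respects its invariants", {
  act <- activationModel(TaMax = 80)
  t <- seq(0, act@cycleLength, by = 1)
  Ta <- activeStress(t, tAct = 40, act)
  expect_true(all(Ta[t <= 40] == 0))
  expect_true(all(Ta >= 0 & Ta <= 80 + 1e-9))
  expect_equal(max(activeStress(seq(0, 1000, by = 0.25), 0, act)), 80,
               tolerance = 1e-6)
  expect_lt(activeStress(act@cycleLength, 0, act), 0.01 * 80)
})

test_that("activation map matches a brute-force shortest-path oracle", {
  m <- tinyMesh()
  v <- 0.8
  stim <- 5L
  tAct <- computeActivationMap(m, v, stimulus = stim)
  expect_equal(tAct[stim], 0)
  # Bellman-Ford oracle on the same edge set
  edges <- CardioPhantom:::meshEdges(m)
  len <- sqrt(rowSums((m@nodes[edges[, 1], ] - m@nodes[edges[, 2], ])^2))
  w <- len / v
  d <- rep(Inf, nrow(m@nodes)); d[stim] <- 0
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]
      if (d[a] + w[e] < d[b] - 1e-12) { d[b] <- d[a] + w[e]; changed <- TRUE }
      if (d[b] + w[e] < d[a] - 1e-12) { d[a] <- d[b] + w[e]; changed <- TRUE }
    }
    if (!changed) break
  }
  expect_equal(tAct, d, tolerance = 1e-9)
  # immediate neighbour activates after edge length / velocity
  nb <- edges[edges[, 1] == stim, 2][1]
  eLen <- sqrt(sum((m@nodes[stim, ] - m@nodes[nb, ])^2))
  expect_lte(tAct[nb], eLen / v + 1e-9)
})

test_that("scar slows conduction monotonically", {
  m <- smallMesh()
  scar <- scarDefect(conductionFactor = 0.5)
  t0 <- computeActivationMap(m, 1.2, scar = NULL)
  t1 <- computeActivationMap(m, 1.2, scar = scar)
  expect_true(all(t1 >= t0 - 1e-9))
  core <- scarBlendElems <- CardioPhantom:::scarBlend(m, scar, "node") > 0.9
  expect_gt(mean(t1[core] - t0[core]), 0)
})

test_that("windkessel decay, steady state and conservation are exact", {
  circ <- circulationModel(pAo = 80)
  # both valves closed: exponential decay with time constant Rp * C
  p <- circ@pAo
  dt <- 0.5
  c2 <- circ
  for (i in 1:2000) {
    st <- circulationStep(c2, pLv = 0, dt = dt, eps = 0)
    expect_equal(st$qAo, 0)
    c2 <- st$circ
  }
  tEnd <- 2000 * dt
  # semi-implicit update: (1 + dt/RpC)^-n vs exp(-t/RpC), close at small dt
  expect_equal(c2@pAo, p * exp(-tEnd / (circ@Rp * circ@C)),
               tolerance = 1e-3 * p)
  # mitral closed when LV pressure exceeds venous pressure
  expect_equal(circulationStep(circ, pLv = 50, dt = 1, eps = 0)$qMit, 0)

  # constant inflow -> steady aortic pressure Q * Rp
  Q <- 0.08
  c3 <- circulationModel(pAo = 0)
  for (i in 1:200000) {
    c3@pAo <- (c3@pAo + 1 * Q / c3@C) / (1 + 1 / (c3@Rp * c3@C))
  }
  expect_equal(c3@pAo, Q * c3@Rp, tolerance = 1e-3 * Q * c3@Rp)

  expect_error(circulationModel(C = -1), "positive")
})

test_that("strain kinematics: identity, analytic fields and FD oracle", {
  m <- tinyMesh()
  Fid <- elementDeformation(m, m@nodes)
  fr <- CardioPhantom:::elementFrames(m)
  expect_lt(max(abs(directionalStrain(Fid, Fid, fr$r))), 1e-12)

  # isotropic stretch 1.5: every directional engineering strain is 0.5
  F2 <- elementDeformation(m, m@nodes * 1.5)
  expect_equal(directionalStrain(Fid, F2, fr$r, type = "engineering"),
               rep(0.5, nrow(m@elems)), tolerance = 1e-9)
  expect_equal(directionalStrain(Fid, F2, fr$c, type = "engineering"),
               rep(0.5, nrow(m@elems)), tolerance = 1e-9)
  # Green-Lagrange counterpart: (1.5^2 - 1)/2
  expect_equal(directionalStrain(Fid, F2, fr$l),
               rep((1.5^2 - 1) / 2, nrow(m@elems)), tolerance = 1e-9)

  # affine displacement field: element F matches the analytic gradient
  A <- matrix(c(0.02, 0.01, 0, -0.01, 0.03, 0.005, 0, 0.02, -0.01), 3)
  pos <- m@nodes + m@nodes %*% t(A)
  Fv <- elementDeformation(m, pos)
  Fexp <- diag(3) + A
  for (k in 1:3) for (d in 1:3)
    expect_equal(Fv[, (k - 1) * 3 + d], rep(Fexp[d, k], nrow(Fv)),
                 tolerance = 1e-9)
})

test_that("pathology personalization follows the preset rules", {
  g <- smallAnatomy()
  mp <- materialParams(); act <- activationModel()
  nor <- applyPathology(g, mp, act, "NOR")
  expect_identical(nor$material@pathologyScale, 1)
  expect_identical(nor$grid@epi, g@epi)

  dcm <- applyPathology(g, mp, act, "DCM", pathologyScale = 5)
  expect_equal(dcm$material@pathologyScale, 5)
  # effective stress-like coefficients are exactly 5x healthy
  F <- diag(3) + 0.04
  f <- c(1, 0, 0); s <- c(0, 0, 1)
  mp5 <- dcm$material; mp5@kappa <- 1e-12
  mp1 <- mp; mp1@kappa <- 1e-12
  expect_equal(passiveStress(F, mp5, f, s)$energy,
               5 * passiveStress(F, mp1, f, s)$energy, tolerance = 1e-9)
  expect_error(applyPathology(g, mp, act, "XXX"), "unknown")
  expect_error(applyPathology(g, mp, act, "DCM", pathologyScale = 2),
               ">=")
})

test_that("infarct active stress is abolished at the core with a smooth transition", {
  m <- smallMesh()
  scar <- scarDefect()
  b <- CardioPhantom:::scarBlend(m, scar, "elem")
  taScale <- 1 - (1 - scar@taFactor) * b
  expect_lt(min(taScale), 0.05)       # core < 5% of remote
  expect_equal(max(taScale), 1)       # remote exactly healthy
  # profile scan along the circumference at the scar's longitudinal level:
  # no jump above 10% of the healthy value per mm of arc
  lv <- sort(unique(m@elemV))
  lev <- lv[which.min(abs(lv - scar@centerV))]
  sel <- which(abs(m@elemV - lev) < 1e-9 & m@elemT < 0.4)
  ord <- sel[order(m@elemPhi[sel])]
  ctr <- (m@nodes[m@elems[ord, 1], ] + m@nodes[m@elems[ord, 7], ]) / 2
  arc <- sqrt(rowSums((ctr - ctr[c(2:nrow(ctr), 1), ])^2))
  jump <- abs(diff(c(taScale[ord], taScale[ord[1]])))
  expect_true(all(jump / arc < 0.10))
})

test_that("infarct thinning reduces wall thickness smoothly at the scar", {
  g <- smallAnatomy()
  pp <- applyPathology(g, materialParams(), activationModel(), "INFARCT")
  th0 <- sqrt(colSums((g@epi - g@endo)^2, dims = 1))
  th1 <- sqrt(colSums((pp$grid@epi - pp$grid@endo)^2, dims = 1))
  expect_lt(min(th1 / th0), pp$scar@thicknessFactor + 0.05)
  expect_equal(max(th1 / th0), 1, tolerance = 1e-9)
})
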