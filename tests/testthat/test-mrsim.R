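test_that("bSSFP closed form matches an independent evaluation and is linear in PD", {
  sq <- sequenceParams()
  expect_equal(bssfpSignal(0, 900, 50, sq), 0)
  expect_equal(bssfpSignal(0.8, 900, 50, sq),
               2 * bssfpSignal(0.4, 900, 50, sq), tolerance = 1e-15)
  # independently coded evaluation of the same steady-state expression
  oracle <- function(PD, T1, T2, TR, TE, flipDeg) {
    alpha <- flipDeg / 180 * pi
    E1 <- exp(-TR / T1); E2 <- exp(-TR / T2)
    num <- PD * sin(alpha) * (1 - E1)
    den <- 1 - (E1 - E2) * cos(alpha) - E1 * E2
    num / den * exp(-TE / T2)
  }
  expect_equal(bssfpSignal(1, 900, 50, sq), oracle(1, 900, 50, 3, 1.5, 60),
               tolerance = 1e-12)
  # blood is brighter than myocardium at the default table
  tb <- defaultTissueTable()
  sBlood <- bssfpSignal(0.95, 1200, 250, sq)
  sMyo <- bssfpSignal(0.80, 870, 50, sq)
  expect_gt(sBlood, sMyo)
})

test_that("coil maps obey the n-fold rotation symmetry about their circle", {
  gs <- gridSpec(c(2, 2, 8), c(-128, -128, 0), c(128L, 128L, 1L))
  coils <- makeCoils(8L, gs, torsoRadius = 100, torsoCenter = c(0, 0))
  set.seed(3)
  pts <- cbind(runif(50, -90, 90), runif(50, -90, 90))
  rot <- 2 * pi / 8
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
  for (i in 1:7) {
    # coil i evaluated at back-rotated points equals coil i+1
    si <- CardioPhantom:::coilSensitivityAt(coils, i, pts %*% R)
    s1 <- CardioPhantom:::coilSensitivityAt(coils, i + 1, pts)
    expect_lt(max(Mod(si - s1)), 1e-6)
  }
  # all maps finite, each nonzero somewhere; single-coil peak at its center
  expect_true(all(vapply(coils@maps, function(m) all(is.finite(Mod(m))), NA)))
  expect_true(all(vapply(coils@maps, function(m) max(Mod(m)) > 0, NA)))
  one <- makeCoils(1L, gs, torsoRadius = 0.1, torsoCenter = c(0, 0))
  sos <- Mod(one@maps[[1]])
  peak <- which(sos == max(sos), arr.ind = TRUE)[1, ]
  ctrIdx <- c(which.min(abs(CardioPhantom:::gridAxis(gs, 1))),
              which.min(abs(CardioPhantom:::gridAxis(gs, 2))))
  expect_lt(max(abs(peak - ctrIdx)), 2)
})

test_that("encoding is a centered low-pass with exact band-limited round trip", {
  gs <- gridSpec(c(1, 1, 8), c(0, 0, 0), c(64L, 64L, 1L))
  sq <- sequenceParams(matrixSize = c(32L, 32L), nCoils = 1L, SNR = Inf)
  uniformCoil <- makeCoils(1L, gs, torsoRadius = 1e5, torsoCenter = c(32, 32),
                           sigma = 1e9, phaseCoef = 0)
  # uniform image -> single central k-space peak
  k <- encodeKspace(matrix(1, 64, 64), uniformCoil, sq)
  mags <- Mod(k@data[, , 1])
  dc <- c(17, 17)   # floor(32/2)+1
  expect_lt(max(mags[-((dc[2] - 1) * 32 + dc[1])] / mags[dc[1], dc[2]]),
            1e-10)
  # band-limited image: exact round trip through encode + reconstruct
  xs <- 0:63
  img <- outer(1 + 0.5 * cos(2 * pi * 3 * xs / 64),
               1 + 0.4 * sin(2 * pi * 5 * xs / 64))
  rec <- reconstructImage(encodeKspace(img, uniformCoil, sq))
  expect_lt(sqrt(mean((rec - img[seq(1, 64, 2), seq(1, 64, 2)])^2)), 1e-8)
  # low-pass bound: cropped reconstruction cannot gain energy
  set.seed(2)
  noisy <- matrix(runif(64 * 64), 64)
  recN <- reconstructImage(encodeKspace(noisy, uniformCoil, sq))
  expect_lte(mean(recN^2), mean(noisy^2) + 1e-12)
  expect_error(encodeKspace(matrix(1, 63, 63), uniformCoil, sq), "integer")
})

test_that("root-sum-of-squares dominates each coil and dimensions are right", {
  gs <- gridSpec(c(2, 2, 8), c(-64, -64, 0), c(64L, 64L, 1L))
  sq <- sequenceParams(matrixSize = c(32L, 32L), nCoils = 4L, SNR = Inf)
  coils <- makeCoils(4L, gs, torsoRadius = 80, torsoCenter = c(0, 0))
  img <- matrix(1, 64, 64)
  k <- encodeKspace(img, coils, sq)
  rss <- reconstructImage(k)
  expect_identical(dim(rss), c(32L, 32L))
  for (cIdx in 1:4) {
    single <- new("KSpaceData", data = k@data[, , cIdx, drop = FALSE],
                  mask = k@mask)
    expect_true(all(rss >= reconstructImage(single) - 1e-12))
  }
})

test_that("noise calibration hits the target SNR across seeds", {
  gs <- gridSpec(c(1, 1, 8), c(-32, -32, 0), c(64L, 64L, 1L))
  sq <- sequenceParams(matrixSize = c(32L, 32L), nCoils = 8L, SNR = 30)
  coils <- makeCoils(8L, gs, torsoRadius = 60, torsoCenter = c(0, 0))
  xs <- CardioPhantom:::gridAxis(gs, 1)
  blood <- outer(xs^2, xs^2, "+") < 15^2
  img <- matrix(0.2, 64, 64); img[blood] <- 1
  k <- encodeKspace(img, coils, sq)
  noiseless <- reconstructImage(k)
  bloodLow <- blood[seq(1, 64, 2), seq(1, 64, 2)]
  ref <- mean(noiseless[bloodLow])
  snrs <- vapply(1:20, function(sd) {
    sqi <- sq; sqi@seed <- sd
    noisy <- reconstructImage(addNoise(k, sqi, refSignal = ref))
    sigma <- stats::sd(noisy - noiseless)
    ref / sigma
  }, 0)
  expect_lt(abs(mean(snrs) - 30) / 30, 0.10)
  # SNR = Inf passes k-space through untouched
  sqInf <- sq; sqInf@SNR <- Inf
  expect_identical(addNoise(k, sqInf, ref)@data, k@data)
})

test_that("single-coil air background magnitudes are Rayleigh distributed", {
  sq <- sequenceParams(matrixSize = c(64L, 64L), nCoils = 1L, SNR = 20,
                       seed = 5)
  k <- new("KSpaceData", data = array(0i, c(64, 64, 1)),
           mask = matrix(1, 64, 64))
  noisy <- reconstructImage(addNoise(k, sq, refSignal = 1))
  x <- as.vector(noisy)
  sigma <- sqrt(mean(x^2) / 2)
  ks <- stats::ks.test(x, function(q) 1 - exp(-q^2 / (2 * sigma^2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("cine simulation is deterministic and static phantoms give static frames", {
  gs <- gridSpec(c(1, 1, 8), c(-32, -32, 0), c(64L, 64L, 1L))
  lab <- new("LabelVolume",
             data = array(rep(c(5L, 4L), each = 2048), c(64, 64, 1)),
             spacing = gs$spacing, origin = gs$origin,
             classes = phantomClasses(), frame = 0)
  maps <- assignProperties(lab)
  coils <- makeCoils(4L, gs, torsoRadius = 60, torsoCenter = c(0, 0))
  sq <- sequenceParams(matrixSize = c(32L, 32L), nCoils = 4L, nFrames = 3L,
                       SNR = Inf)
  cine <- simulateCine(rep(list(maps), 3), rep(list(lab), 3), coils, sq)
  expect_identical(cine@frames[, , 1], cine@frames[, , 2])
  expect_identical(cine@frames[, , 1], cine@frames[, , 3])
  sq2 <- sq; sq2@SNR <- 25
  c1 <- simulateCine(rep(list(maps), 3), rep(list(lab), 3), coils, sq2)
  c2 <- simulateCine(rep(list(maps), 3), rep(list(lab), 3), coils, sq2)
  expect_identical(c1@frames, c2@frames)
  expect_error(simulateCine(rep(list(maps), 2), rep(list(lab), 2), coils,
                            sq), "frames")
})
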