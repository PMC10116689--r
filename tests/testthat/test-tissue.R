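labFixture <- function() {
  gs <- gridSpec(c(2, 2, 8), c(-64, -64, 30), c(64L, 64L, 2L))
  torso <- torsoModel(seed = 2)
  generateBackground(torso, gs, 0)
}

test_that("property assignment is an exact per-class lookup", {
  lab <- labFixture()
  tp <- assignProperties(lab)
  tb <- defaultTissueTable()
  # one distinct T1 value per present class
  present <- unique(as.vector(lab@data))
  expect_equal(length(unique(as.vector(tp@T1))),
               length(unique(tb$T1[tb$class %in% present])))
  # single-class volume gives constant maps
  one <- new("LabelVolume", data = array(4L, c(8, 8, 1)),
             spacing = c(1, 1, 1), origin = c(0, 0, 0),
             classes = phantomClasses(), frame = 0)
  tpo <- assignProperties(one)
  expect_true(all(tpo@T1 == tb$T1[tb$class == 4]))
  expect_true(all(tpo@PD == tb$PD[tb$class == 4]))
  # unknown class id raises with the id in the message
  bad <- one; bad@data[1] <- 10L; bad@classes <- c(bad@classes, extra = 10L)
  tbNo <- tb[tb$class != 10, ]
  expect_error(assignProperties(bad, tbNo), "10")
})

test_that("relabelling classes consistently leaves maps unchanged", {
  lab <- labFixture()
  tb <- defaultTissueTable()
  tp1 <- assignProperties(lab, tb)
  # swap ids of lungL (2) and aorta (10) in both labels and table
  lab2 <- lab
  lab2@data[lab@data == 2L] <- 99L
  lab2@data[lab@data == 10L] <- 2L
  lab2@data[lab2@data == 99L] <- 10L
  lab2@classes[["lungL"]] <- 10L; lab2@classes[["aorta"]] <- 2L
  tb2 <- tb
  tb2$class[tb$class == 2] <- 10; tb2$class[tb$class == 10] <- 2
  tp2 <- assignProperties(lab2, tb2)
  expect_identical(tp1@T1, tp2@T1)
  expect_identical(tp1@PD, tp2@PD)
})

test_that("texture preserves means, spares the LV and matches its target SD", {
  lab <- labFixture()
  tp <- assignProperties(lab)
  tex <- textureModel(sd = 0.10, corrLength = 5, seed = 8)
  tt <- applyTexture(tp, lab, tex)
  cls <- phantomClasses()
  # LV myocardium untouched; background untouched
  myo <- lab@data == cls[["lvMyo"]]
  expect_identical(tt@PD[myo], tp@PD[myo])
  # per-class means preserved (renormalized exactly)
  present <- setdiff(unique(as.vector(lab@data)),
                     cls[c("lvMyo", "background")])
  sizes <- vapply(present, function(id) sum(lab@data == id), 0)
  for (id in present[order(-sizes)][1:2]) {
    sel <- lab@data == id
    expect_equal(mean(tt@T1[sel]), mean(tp@T1[sel]), tolerance = 1e-9)
    relSD <- stats::sd(tt@PD[sel]) / mean(tt@PD[sel])
    expect_lt(abs(relSD - 0.10) / 0.10, 0.3)
  }
  # larger, more homogeneous fixture hits the configured SD within 15%
  big <- new("LabelVolume", data = array(1L, c(64, 64, 4)),
             spacing = c(1, 1, 1), origin = c(0, 0, 0),
             classes = cls, frame = 0)
  tb <- assignProperties(big)
  tbt <- applyTexture(tb, big, textureModel(sd = 0.10, corrLength = 3,
                                            seed = 4))
  relSD <- stats::sd(tbt@PD) / mean(tbt@PD)
  expect_lt(abs(relSD - 0.10) / 0.10, 0.15)
  # determinism and the T2 <= T1 invariant
  expect_identical(applyTexture(tp, lab, tex)@T2, tt@T2)
  expect_true(all(tt@T2 <= tt@T1 + 1e-9))
  expect_identical(applyTexture(tp, lab, textureModel(sd = 0))@PD, tp@PD)
})

test_that("bSSFP property fitting recovers noiseless parameters within 1%", {
  # acquisitions must differ substantially in TR: at a single short TR
  # the bSSFP signal depends on T2/T1 only (flip angles cannot separate
  # the two), so the fixture spans short to long repetition times
  seqs <- mapply(function(a, tr) sequenceParams(flip = a, TR = tr,
                                                TE = 1.5, SNR = Inf),
                 c(60, 40, 30), c(3, 200, 800), SIMPLIFY = FALSE)
  truth <- c(PD = 0.8, T1 = 900, T2 = 50)
  y <- vapply(seqs, function(sq) bssfpSignal(0.8, 900, 50, sq), 0)
  fit <- fitTissueProperties(matrix(y, 1), seqs)
  expect_lt(abs(fit$PD - 0.8) / 0.8, 0.01)
  expect_lt(abs(fit$T1 - 900) / 900, 0.01)
  expect_lt(abs(fit$T2 - 50) / 50, 0.01)
  expect_lt(fit$residual, 1e-6)
  # zero signal flagged degenerate at the lower bounds
  f0 <- fitTissueProperties(matrix(0, 1, 3), seqs)
  expect_true(f0$degenerate)
  expect_equal(f0$PD, 1e-3)
  # fewer observations than parameters is an explicit error
  expect_error(fitTissueProperties(matrix(1, 1, 2), seqs[1:2]),
               "underdetermined|3 acquisitions")
})

test_that("Monte-Carlo recovery at SNR 50 stays below 10% RMSE per parameter", {
  seqs <- mapply(function(a, tr) sequenceParams(flip = a, TR = tr,
                                                TE = 1.5, SNR = Inf),
                 c(60, 50, 40, 30, 20), c(3, 100, 300, 800, 2000),
                 SIMPLIFY = FALSE)
  set.seed(12)
  n <- 60
  truth <- cbind(PD = runif(n, 0.4, 1), T1 = runif(n, 300, 1500),
                 T2 = runif(n, 30, 200))
  truth[, "T2"] <- pmin(truth[, "T2"], truth[, "T1"])
  Y <- t(apply(truth, 1, function(p)
    vapply(seqs, function(sq) bssfpSignal(p[1], p[2], p[3], sq), 0)))
  # per-pixel SNR 50: noise sd is the pixel mean signal over 50
  Y <- pmax(Y + matrix(rnorm(length(Y), sd = rep(rowMeans(Y) / 50,
                                                 ncol(Y))), nrow(Y)), 0)
  fit <- fitTissueProperties(Y, seqs)
  for (p in c("PD", "T1", "T2")) {
    rmse <- sqrt(mean(((fit[[p]] - truth[, p]) / truth[, p])^2))
    expect_lt(rmse, 0.10)
  }
})
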