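pointInPolygonWrap <- function(px, py, poly)
  CardioPhantom:::pointInPolygon(px, py, poly)

discSlice <- function(r, n = 128L, spacing = 1) {
  xs <- (seq_len(n) - (n + 1) / 2) * spacing
  m <- matrix(0L, n, n)
  m[outer(xs^2, xs^2, "+") <= r^2] <- 4L
  list(slice = m, origin = c(xs[1], xs[1]), spacing = c(spacing, spacing))
}

test_that("contour extraction has sub-pixel accuracy on a disc", {
  d <- discSlice(20)
  ct <- extractContour(d$slice, 4L, d$spacing, d$origin)
  len <- sum(sqrt(rowSums((ct - ct[c(2:nrow(ct), 1), ])^2)))
  expect_lt(abs(len - 2 * pi * 20) / (2 * pi * 20), 0.02)
  # shoelace area vs pixel count
  area <- abs(CardioPhantom:::shoelaceArea(ct))
  expect_lt(abs(area - sum(d$slice == 4L) * prod(d$spacing)) / area, 0.02)
  expect_error(extractContour(d$slice, 9L), "absent")
  single <- matrix(0L, 32, 32); single[16, 16] <- 4L
  expect_error(extractContour(single, 4L), "degenerate")
})

test_that("identical contours give a null warp", {
  d <- discSlice(20, n = 96L)
  gs <- gridSpec(c(1, 1, 1), c(d$origin, 0), c(96L, 96L, 1L))
  ct <- extractContour(d$slice, 4L, d$spacing, d$origin)
  wf <- buildWarp(ct, ct, gs)
  expect_lt(max(abs(wf@dx)), 1e-6)
  expect_lt(max(abs(wf@dy)), 1e-6)
})

test_that("concentric-circle warp is radial at the contour and decays outward", {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  bg <- cbind(30 * cos(th), 30 * sin(th))
  fg <- cbind(33 * cos(th), 33 * sin(th))
  gs <- gridSpec(c(1, 1, 1), c(-80, -80, 0), c(160L, 160L, 1L))
  wf <- buildWarp(bg, fg, gs)
  xs <- CardioPhantom:::gridAxis(gs, 1)
  # displacement magnitude at the fg contour ~ 3 mm, pointing inward
  i33 <- which.min(abs(xs - 33)); i0 <- which.min(abs(xs - 0))
  mag <- sqrt(wf@dx[i33, i0, 1]^2 + wf@dy[i33, i0, 1]^2)
  expect_equal(mag, 3, tolerance = 0.15)
  # decays with distance from the contour
  iFar <- which.min(abs(xs - 75))
  magFar <- sqrt(wf@dx[iFar, i0, 1]^2 + wf@dy[iFar, i0, 1]^2)
  expect_lt(magFar, 0.3 * mag)
  # no folding anywhere
  jac <- warpJacobian(wf@dx[, , 1], wf@dy[, , 1], gs$spacing[1:2])
  expect_true(all(jac > 0))
})

test_that("warped label maps land on the target contour within one voxel", {
  gs <- gridSpec(c(1, 1, 1), c(-64, -64, 0), c(128L, 128L, 1L))
  set.seed(42)
  for (rep in 1:12) {
    # preset-like contour pairs: the torso placeholder is a circle, the
    # simulated epicardium a smooth oval with a small offset
    th <- seq(0, 2 * pi, length.out = 145)[-145]
    rBg <- rep(runif(1, 27, 33), length(th))
    rFg <- runif(1, 28, 33) + 1.5 * sin(2 * th + runif(1, 0, 2 * pi))
    off <- runif(2, -3, 3)
    bgC <- cbind(rBg * cos(th), rBg * sin(th))
    fgC <- cbind(off[1] + rFg * cos(th), off[2] + rFg * sin(th))
    wf <- buildWarp(bgC, fgC, gs, nControl = 128L)
    jac <- warpJacobian(wf@dx[, , 1], wf@dy[, , 1], gs$spacing[1:2])
    expect_true(all(jac > 0))
    # rasterize bg disc, warp it, re-extract its contour
    xs <- CardioPhantom:::gridAxis(gs, 1)
    px <- rep(xs, times = 128); py <- rep(xs, each = 128)
    bgLab <- new("LabelVolume",
                 data = array(pointInPolygonWrap(px, py, bgC) * 4L,
                              c(128L, 128L, 1L)),
                 spacing = gs$spacing, origin = gs$origin,
                 classes = phantomClasses(), frame = 0)
    warped <- applyWarp(bgLab, wf)
    wc <- extractContour(warped@data[, , 1], 4L, gs$spacing[1:2],
                         gs$origin[1:2])
    # reference carrying the same rasterization/extraction bias: the
    # directly rasterized foreground disc
    fgLab <- new("LabelVolume",
                 data = array(pointInPolygonWrap(px, py, fgC) * 4L,
                              c(128L, 128L, 1L)),
                 spacing = gs$spacing, origin = gs$origin,
                 classes = phantomClasses(), frame = 0)
    fgCx <- extractContour(fgLab@data[, , 1], 4L, gs$spacing[1:2],
                           gs$origin[1:2])
    expect_lte(hausdorffDistance(wc, fgCx), 1.0)
  }
})

test_that("tissue-map warping: identity, integer shift and round trip", {
  gs <- gridSpec(c(1, 1, 1), c(0, 0, 0), c(48L, 48L, 1L))
  xs <- seq_len(48)
  base <- array(900 + 100 * outer(sin(2 * pi * xs / 24),
                                  cos(2 * pi * xs / 16)), c(48, 48, 1))
  maps <- new("TissueMaps", PD = base / 2000, T1 = base,
              T2 = base / 4, spacing = gs$spacing, origin = gs$origin,
              frame = 1)
  zerow <- new("WarpField", dx = array(0, c(48, 48, 1)),
               dy = array(0, c(48, 48, 1)), controls = list(),
               spacing = gs$spacing, origin = gs$origin)
  expect_lt(max(abs(warpProperties(maps, zerow)@T1 - maps@T1)), 1e-6)

  shiftw <- zerow; shiftw@dx[] <- 3    # +3 voxels in x (backward sampling)
  sh <- warpProperties(maps, shiftw)
  expect_equal(sh@T1[1:45, , 1], maps@T1[4:48, , 1], tolerance = 1e-12)

  # smooth forward/backward round trip within 2% RMS (interior)
  xs <- seq_len(48)
  ux <- 1.5 * sin(2 * pi * outer(xs, xs, function(a, b) a) / 48)
  fw <- zerow; fw@dx[, , 1] <- ux
  bw <- zerow; bw@dx[, , 1] <- -ux
  rt <- warpProperties(warpProperties(maps, fw), bw)
  core <- 5:44
  rms <- sqrt(mean((rt@T1[core, core, 1] - maps@T1[core, core, 1])^2))
  expect_lt(rms / mean(maps@T1), 0.02)
})
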