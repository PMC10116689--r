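test_that("concentric-sphere voxelization recovers the analytic shell volume", {
  sp <- sphereSurfaces(20, 30)
  gs <- gridSpec(c(0.5, 0.5, 0.5), c(-32, -32, -2), c(128L, 128L, 128L))
  lab <- voxelizeSurfaces(sp$endo, sp$epi, gs)
  analytic <- 4 / 3 * pi * (30^3 - 20^3) / 1000
  expect_lt(abs(classVolume(lab, "lvMyo") - analytic) / analytic, 0.01)
  bloodAnalytic <- 4 / 3 * pi * 20^3 / 1000
  expect_lt(abs(classVolume(lab, "lvBlood") - bloodAnalytic) /
              bloodAnalytic, 0.01)
  # region far from the surfaces stays background
  expect_true(all(lab@data[1:5, , ] == lab@classes[["background"]]))
})

test_that("voxelization is invariant to the circumferential start column", {
  sp <- sphereSurfaces(20, 30, nu = 32L, nv = 32L)
  gs <- gridSpec(c(1, 1, 8), c(-32, -32, 20), c(64L, 64L, 3L))
  rot <- function(s) s[, c(9:32, 1:8), ]
  a <- voxelizeSurfaces(sp$endo, sp$epi, gs)
  b <- voxelizeSurfaces(rot(sp$endo), rot(sp$epi), gs)
  expect_identical(a@data, b@data)
})

test_that("mesh voxelization volumes agree with mesh volumes", {
  m <- smallMesh()
  bb <- apply(m@nodes, 2, range)
  gs <- gridSpec(c(1, 1, 1),
                 c(bb[1, 1] - 2, bb[1, 2] - 2, bb[1, 3] - 2),
                 c(ceiling(diff(bb[, 1])) + 4, ceiling(diff(bb[, 2])) + 4,
                   ceiling(diff(bb[, 3])) + 4))
  lab <- voxelizeLV(m, gs)
  expect_lt(abs(classVolume(lab, "lvMyo") - wallVolume(m)) / wallVolume(m),
            0.04)
  expect_lt(abs(classVolume(lab, "lvBlood") - cavityVolume(m)) /
              cavityVolume(m), 0.04)
  expect_error(voxelizeLV(m, gridSpec(c(1, 1, 1), c(0, 0, 0), c(4L, 4L, 4L))),
               "cover")
})

test_that("background generation is deterministic, complete and phase dependent", {
  gs <- gridSpec(c(2, 2, 8), c(-180, -160, 30), c(160L, 160L, 3L))
  torso <- torsoModel(seed = 3)
  bg0 <- generateBackground(torso, gs, 0)
  bg5 <- generateBackground(torso, gs, 0.5)
  # all 12 classes present somewhere in the stack
  expect_setequal(sort(unique(as.vector(bg0@data))),
                  sort(unname(phantomClasses())))
  # RV blood pool contracts between phase 0 and 0.5
  expect_lt(classVolume(bg5, "rvBlood"), classVolume(bg0, "rvBlood"))
  # determinism and seed dependence
  expect_identical(generateBackground(torsoModel(seed = 3), gs, 0)@data,
                   bg0@data)
  torso2 <- torsoModel(seed = 4)
  expect_false(identical(torso2@params$lungLAxes, torso@params$lungLAxes))
  expect_identical(phantomClasses(), phantomClasses())

  # body region forms a single connected component per slice (flood fill)
  sl <- bg0@data[, , 2] != phantomClasses()[["background"]]
  lab <- matrix(0L, nrow(sl), ncol(sl))
  comp <- 0L
  for (seed in which(sl)) {
    if (lab[seed] != 0L) next
    comp <- comp + 1L
    queue <- seed
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      if (lab[cur] != 0L || !sl[cur]) next
      lab[cur] <- comp
      i <- (cur - 1L) %% nrow(sl) + 1L; j <- (cur - 1L) %/% nrow(sl) + 1L
      nb <- c(if (i > 1) cur - 1L, if (i < nrow(sl)) cur + 1L,
              if (j > 1) cur - nrow(sl), if (j < ncol(sl)) cur + nrow(sl))
      queue <- c(queue, nb[sl[nb] & lab[nb] == 0L])
    }
  }
  expect_equal(comp, 1L)
})

test_that("phantom composition preserves the foreground exactly", {
  gs <- gridSpec(c(2, 2, 8), c(-64, -64, 30), c(64L, 64L, 3L))
  m <- smallMesh()
  fg <- voxelizeLV(m, gs)
  torso <- torsoModel(seed = 1)
  bgGs <- gridSpec(gs$spacing, gs$origin, gs$dims)
  bg <- generateBackground(torso, bgGs, 0)
  ph <- composePhantom(fg, bg)
  cls <- phantomClasses()
  expect_identical(ph@data == cls[["lvMyo"]], fg@data == cls[["lvMyo"]])
  expect_identical(ph@data == cls[["lvBlood"]], fg@data == cls[["lvBlood"]])
  # empty foreground: background survives except its placeholder LV,
  # which is erased so LV classes always equal the foreground's
  fg0 <- fg; fg0@data[] <- cls[["background"]]
  c0 <- composePhantom(fg0, bg)@data
  bgLV <- bg@data == cls[["lvMyo"]] | bg@data == cls[["lvBlood"]]
  expect_identical(c0[!bgLV], bg@data[!bgLV])
  expect_true(all(c0[bgLV] == cls[["body"]]))
  expect_setequal(names(composePhantom(fg, bg)@classes), names(cls))
  bgBad <- generateBackground(torso, gridSpec(gs$spacing, gs$origin,
                                              c(32L, 32L, 3L)), 0)
  expect_error(composePhantom(fg, bgBad), "match")
})
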