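test_that("held-out reconstruction error is small and matches a brute-force oracle", {
  model <- fittedShapeModel()
  held <- lapply(sampleAnatomyParams(10, "MIX", seed = 99),
                 generateAnatomy, nU = 32L, nV = 32L)
  errs <- vapply(held, function(s) reconstructionError(model, s), 0)
  expect_lt(mean(errs), 2)

  # oracle: explicit loop over corresponding points
  s <- held[[1]]
  ref <- normalizePose(s)
  rec <- sampleShape(model, encodeShape(model, s))
  tot <- 0; n <- 0
  for (surf in c("endo", "epi")) {
    A <- slot(ref, surf); B <- slot(rec, surf)
    for (i in seq_len(dim(A)[2])) for (j in seq_len(dim(A)[3])) {
      tot <- tot + sqrt(sum((A[, i, j] - B[, i, j])^2)); n <- n + 1
    }
  }
  expect_equal(reconstructionError(model, s), tot / n, tolerance = 1e-12)
})

test_that("the latent space is standardized and decode(0) is the mean", {
  model <- fittedShapeModel()
  lat <- t(vapply(shapePopulation(), function(s) encodeShape(model, s),
                  numeric(model@d)))
  expect_lt(max(abs(colMeans(lat))), 1e-8)
  expect_equal(unname(apply(lat, 2, var)), rep(1, model@d),
               tolerance = 1e-8)
  m0 <- sampleShape(model, rep(0, model@d))
  expect_equal(as.vector(CardioPhantom:::shapeToVector(m0)), as.vector(model@mean),
               tolerance = 1e-8)
  expect_lt(max(abs(encodeShape(model, m0))), 1e-6)
})

test_that("a degenerate population triggers rank truncation and exact recovery", {
  one <- generateAnatomy(anatomyParams(), nU = 24L, nV = 24L)
  pop <- rep(list(one), 10)
  expect_warning(model <- fitShapeModel(pop, d = 4L), "rank deficient")
  rec <- sampleShape(model, numeric(model@d))
  expect_lt(reconstructionError(model, one), 1e-8)
  expect_equal(rec@endo, normalizePose(one)@endo, tolerance = 1e-8)
})

test_that("rigid translation cannot inflate the error beyond its size", {
  model <- fittedShapeModel()
  s <- shapePopulation()[[3]]
  moved <- s
  moved@endo <- s@endo + 10
  moved@epi <- s@epi + 10
  moved@apex <- s@apex + 10
  moved@basePlane$point <- s@basePlane$point + 10
  expect_lte(reconstructionError(model, moved), 10 + 1e-6)
})

test_that("scale-dominant latent coordinate changes cavity volume monotonically", {
  model <- fittedShapeModel()
  vols <- vapply(seq_len(model@d), function(i) {
    z <- numeric(model@d)
    vp <- cavityVolume(sampleShape(model, replace(z, i, 3)))
    vm <- cavityVolume(sampleShape(model, replace(z, i, -3)))
    abs(vp - vm)
  }, 0)
  iScale <- which.max(vols)
  v <- vapply(c(-3, -1, 0, 1, 3), function(a) {
    cavityVolume(sampleShape(model, replace(numeric(model@d), iScale, a)))
  }, 0)
  expect_true(all(diff(v) > 0) || all(diff(v) < 0))
})

test_that("sampled shapes satisfy the surface-grid invariants (property sweep)", {
  model <- fittedShapeModel()
  set.seed(31)
  ok <- vapply(seq_len(200), function(i) {
    z <- pmax(pmin(rnorm(model@d), 3), -3)
    g <- tryCatch(sampleShape(model, z), error = function(e) NULL)
    !is.null(g) && isTRUE(validObject(g, test = TRUE))
  }, logical(1))
  expect_true(all(ok))
  expect_warning(sampleShape(model, replace(numeric(model@d), 1, 4)),
                 "beyond")
})

test_that("k-means recovers well-separated blobs exactly", {
  set.seed(5)
  centers <- rbind(c(10, 0, 0), c(-10, 8, 0), c(0, -9, 9))
  lab <- rep(1:3, each = 30)
  X <- centers[lab, ] + matrix(rnorm(270, sd = 0.5), ncol = 3)
  cl <- clusterLatent(X, k = 3L, seed = 2)
  assign <- attr(cl, "cluster")
  # brute-force confusion-matrix accuracy over all label permutations
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  acc <- max(vapply(perms, function(p) mean(p[assign] == lab), 0))
  expect_equal(acc, 1.0)
})

test_that("k = 1 returns the latent mean and k > n errors", {
  X <- matrix(rnorm(40), ncol = 4)
  cl <- clusterLatent(X, k = 1L, seed = 1)
  expect_equal(as.vector(cl@centers), colMeans(X), tolerance = 1e-10)
  expect_error(clusterLatent(X, k = 20L), "exceed")
})

test_that("shipped preset clusters decode to the expected morphologies", {
  pc <- presetShapeClusters(n = 60, d = 8, seed = 7)
  expect_setequal(pc$clusters@labels, c("NOR", "DCM", "HCM"))
  shapes <- lapply(seq_len(3), function(i)
    sampleShape(pc$model, pc$clusters@centers[i, ]))
  vols <- vapply(shapes, cavityVolume, 0)
  thick <- vapply(shapes, wallThickness, 0)
  expect_equal(pc$clusters@labels[which.max(vols)], "DCM")
  rest <- setdiff(1:3, which.max(vols))
  expect_equal(pc$clusters@labels[rest[which.max(thick[rest])]], "HCM")
})
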