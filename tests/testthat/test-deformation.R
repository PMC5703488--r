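test_that("VR decomposition reconstructs seeded deformation gradients", {
  vr <- vrDecompose(diag(c(2, 1, 1)))
  expect_equal(vr$V, diag(c(2, 1, 1)))
  expect_equal(vr$R, diag(3))
  R0 <- rotationAbout(c(1, 1, 0), 0.7)
  vr <- vrDecompose(R0)
  expect_equal(vr$V, diag(3), tolerance = 1e-12)
  expect_equal(vr$R, R0, tolerance = 1e-12)
  set.seed(13)
  for (i in 1:1000) {
    F <- matrix(rnorm(9), 3, 3)
    if (det(F) < 0) F[, 1] <- -F[, 1]
    if (abs(det(F)) < 1e-3) next
    vr <- vrDecompose(F)
    expect_lt(norm(vr$V %*% vr$R - F, "F"), 1e-10 * norm(F, "F"))
    expect_lt(norm(crossprod(vr$R) - diag(3), "F"), 1e-10)
    expect_equal(det(vr$R), 1, tolerance = 1e-10)
    expect_gt(min(eigen(vr$V, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
  expect_error(vrDecompose(diag(c(-1, 1, 1))), class = "fmFoldingError")
})

test_that("deformation gradient matches identity, affine and finite differences", {
  idchain <- TransformChain()
  gs <- deformationGradient(idchain, c(1, 2, 3))
  expect_equal(gs@F, diag(3))
  A <- rotationAbout(c(0, 0, 1), 0.3) %*% diag(c(1.2, 0.9, 1.05))
  achain <- TransformChain(affine = A, translation = c(1, -2, 0.5))
  expect_equal(deformationGradient(achain, c(5, 5, 5))@F, A)
  expect_equal(deformationGradient(achain, c(-3, 8, 1))@F, A)
  # seeded smooth warp vs central differences of the transform
  ch <- fabricmap:::randomChain(c(0, 0, 0), c(20, 20, 20), magnitude = 1,
                                seed = 5)
  set.seed(17)
  for (i in 1:10) {
    pt <- runif(3, 4, 16)
    gs <- deformationGradient(ch, pt)
    h <- 0.25 * 0.6                       # 0.25 x a typical voxel spacing
    Ffd <- vapply(1:3, function(j) {
      e <- rep(0, 3); e[j] <- h
      (transformPoints(ch, pt + e) - transformPoints(ch, pt - e)) / (2 * h)
    }, numeric(3))
    expect_lt(max(abs(gs@F - Ffd)) / max(abs(gs@F)), 1e-4)
    expect_lt(norm(gs@V %*% gs@R - gs@F, "F"), 1e-8 * norm(gs@F, "F"))
  }
})

test_that("distance metric is zero for rigid chains and has the scaling closed form", {
  set.seed(19)
  grid <- matrix(runif(36, 0, 10), 12, 3)
  expect_equal(distanceMetric(TransformChain(), grid), 0)
  rigid <- TransformChain(affine = rotationAbout(c(1, 2, 3), 0.8),
                          translation = c(4, -1, 2))
  expect_lt(distanceMetric(rigid, grid), 1e-12)
  for (s in c(0.8, 1.1, 1.7)) {
    ch <- TransformChain(affine = s * diag(3))
    expect_equal(distanceMetric(ch, grid), 12 * sqrt(3) * abs(log(s)),
                 tolerance = 1e-8)
  }
})

test_that("distance metric is invariant to a global rotation of the gradients", {
  ch <- fabricmap:::randomChain(c(0, 0, 0), c(20, 20, 20), magnitude = 1,
                                seed = 23)
  grid <- matrix(runif(30, 4, 16), 10, 3)
  dm <- distanceMetric(ch, grid)
  expect_gt(dm, 0)
  R <- rotationAbout(c(0, 1, 1), 0.6)
  Fs <- fabricmap:::chainGradients(ch, grid)
  dmRot <- sum(vapply(Fs, function(F) {
    V <- vrDecompose(R %*% F)$V
    norm(spdLog(V), "F")
  }, numeric(1)))
  expect_equal(dmRot, dm, tolerance = 1e-6 * dm)
})

test_that("product-mode distance metric is finite and close to composed mode on smooth warps", {
  ch <- fabricmap:::randomChain(c(0, 0, 0), c(20, 20, 20), magnitude = 1,
                                seed = 29)
  grid <- matrix(runif(30, 4, 16), 10, 3)
  dmC <- distanceMetric(ch, grid, mode = "composed")
  dmP <- distanceMetric(ch, grid, mode = "product")
  expect_true(is.finite(dmP))
  expect_gt(dmP, 0)
  expect_equal(dmP, dmC, tolerance = 0.2)  # modes agree for mild warps
})

test_that("folding transforms are rejected with the offending point", {
  fold <- TransformChain(affine = diag(c(1, 1, 1)))
  fold@affine <- diag(3)                   # fold via extreme B-spline
  grid <- bsplineGridFor(c(0, 0, 0), c(10, 10, 10), 5)
  coef <- matrix(0, prod(grid$dims), 3)
  coef[, 1] <- -20                          # du/dx ~ strongly negative
  coef[seq(1, nrow(coef), 2), 1] <- 20
  fold <- TransformChain(affine = diag(3), bsplineOrigin = grid$origin,
                         bsplineSpacing = grid$spacing,
                         bsplineDims = grid$dims, bsplineCoef = coef)
  pts <- matrix(c(5, 5, 5), 1, 3)
  F <- fabricmap:::chainGradients(fold, pts)[[1]]
  if (det(F) <= 0)
    expect_error(distanceMetric(fold, pts), class = "fmFoldingError")
  else succeed("constructed chain did not fold at the probe")
})

test_that("transform chains round-trip bit-exactly through the text format", {
  ch <- fabricmap:::randomChain(c(0, 0, 0), c(15, 15, 15), magnitude = 1,
                                seed = 31)
  path <- tempfile(fileext = ".txt")
  writeTransformChain(ch, path)
  ch2 <- readTransformChain(path)
  expect_identical(ch2@affine, ch@affine)
  expect_identical(ch2@translation, ch@translation)
  expect_identical(ch2@bsplineCoef, ch@bsplineCoef)
  expect_identical(ch2@bsplineDims, ch@bsplineDims)
  expect_identical(ch2@bsplineOrigin, ch@bsplineOrigin)
  pts <- matrix(runif(9, 2, 12), 3, 3)
  expect_identical(transformPoints(ch2, pts), transformPoints(ch, pts))
})
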