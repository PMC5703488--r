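test_that("NR mapping is the identity on tensors", {
  set.seed(51)
  for (i in 1:5) {
    M <- normalizeTrace(randomSPD())
    out <- mapNR(M)
    expect_equal(tensorMatrix(out), tensorMatrix(M))
    expect_equal(fabricEigenvalues(out), fabricEigenvalues(M))
    expect_equal(as.numeric(principalDirection(out)),
                 as.numeric(principalDirection(M)))
  }
})

test_that("AR rotates the axes and preserves eigenvalues", {
  M <- normalizeTrace(diag(c(0.5, 1, 1.5)))
  expect_equal(tensorMatrix(mapAR(M, diag(3))), tensorMatrix(M))
  Rx <- rotationAbout(c(1, 0, 0), pi / 2)
  out <- mapAR(M, Rx)
  # 90 degrees about x maps the e3 principal axis onto e2
  expect_lt(angleBetweenAxes(principalDirection(out), c(0, 1, 0)), 1e-8)
  set.seed(53)
  for (i in 1:1000) {
    M <- normalizeTrace(randomSPD())
    R <- randomRotation()
    expect_equal(fabricEigenvalues(mapAR(M, R)), fabricEigenvalues(M),
                 tolerance = 1e-12)
  }
  expect_error(mapAR(M, diag(c(1, 1, 2))), class = "fmRotationError")
})

test_that("AD is a similarity transform: raw eigenvalues preserved, output symmetrized", {
  M <- normalizeTrace(diag(c(0.5, 1, 1.5)))
  expect_equal(tensorMatrix(mapAD(M, diag(3))), tensorMatrix(M))
  set.seed(57)
  for (i in 1:200) {
    M <- normalizeTrace(randomSPD())
    # moderate gradients, the regime registration actually produces;
    # strongly misaligned stretches may still trip the definiteness floor
    F <- randomRotation() %*% diag(runif(3, 0.7, 1.4)) %*% randomRotation()
    out <- suppressWarnings(mapAD(M, F))
    raw <- attr(out, "raw")
    expect_equal(sort(Re(eigen(raw)$values)), fabricEigenvalues(M),
                 tolerance = 1e-10)
    expect_equal(sum(diag(tensorMatrix(out))), 3, tolerance = 1e-12)
  }
  R <- randomRotation()
  expect_equal(tensorMatrix(mapAD(M, R)), tensorMatrix(mapAR(M, R)),
               tolerance = 1e-12)
  expect_error(mapAD(M, matrix(0, 3, 3)), class = "fmInvertibilityError")
})

test_that("CR composes the stage rotations", {
  M <- normalizeTrace(diag(c(0.5, 1, 1.5)))
  R1 <- rotationAbout(c(0, 0, 1), 0.3)
  R2 <- rotationAbout(c(0, 0, 1), 0.5)
  out <- mapCR(M, R1, R2)
  direct <- rotationAbout(c(0, 0, 1), 0.8) %*% tensorMatrix(M) %*%
    t(rotationAbout(c(0, 0, 1), 0.8))
  expect_equal(tensorMatrix(out), direct, tolerance = 1e-12)
  expect_equal(tensorMatrix(mapCR(M, R1, diag(3))),
               tensorMatrix(mapAR(M, R1)))
  set.seed(59)
  for (i in 1:1000) {
    M <- normalizeTrace(randomSPD())
    expect_equal(fabricEigenvalues(mapCR(M, randomRotation(),
                                         randomRotation())),
                 fabricEigenvalues(M), tolerance = 1e-12)
  }
})

test_that("CD reduces to CR for pure rotations and commutes with diagonal stretches", {
  M <- normalizeTrace(diag(c(0.5, 1, 1.5)))
  expect_equal(tensorMatrix(mapCD(M, diag(3))), tensorMatrix(M))
  set.seed(61)
  for (i in 1:50) {
    R <- randomRotation()
    expect_equal(tensorMatrix(mapCD(M, R)),
                 tensorMatrix(mapCR(M, R, diag(3))), tolerance = 1e-12)
  }
  # diagonal F commutes with diagonal M: raw result unchanged
  out <- mapCD(M, diag(c(2, 1, 1)))
  expect_equal(attr(out, "raw"), tensorMatrix(M), tolerance = 1e-12)
  expect_equal(tensorMatrix(out), tensorMatrix(M), tolerance = 1e-12)
})

test_that("mapTensor dispatches on the gradient sample factors", {
  ch <- TransformChain(affine = rotationAbout(c(0, 1, 0), 0.4))
  gs <- deformationGradient(ch, c(1, 1, 1))
  M <- normalizeTrace(diag(c(0.6, 1, 1.4)))
  expect_equal(tensorMatrix(mapTensor(M, gs, "NR")), tensorMatrix(M))
  expect_equal(tensorMatrix(mapTensor(M, gs, "AR")),
               tensorMatrix(mapAR(M, gs@RA)))
  expect_equal(tensorMatrix(mapTensor(M, gs, "CR")),
               tensorMatrix(mapCD(M, gs@F)), tolerance = 1e-12)
})

test_that("field mapping: identity chain preserves, global rotations rotate pointwise", {
  set.seed(67)
  pts <- matrix(runif(30, 2, 12), 10, 3)
  tensors <- lapply(1:10, function(i) normalizeTrace(randomSPD()))
  field <- FabricField(pts, tensors)
  for (scheme in c("NR", "AR", "CR", "AD", "CD")) {
    out <- mapField(field, TransformChain(), scheme)
    for (i in 1:10)
      expect_equal(tensorMatrix(fieldTensors(out)[[i]]),
                   tensorMatrix(tensors[[i]]), tolerance = 1e-12)
  }
  R <- rotationAbout(c(1, 1, 1), 30 * pi / 180)
  rotChain <- TransformChain(affine = R)
  outCR <- mapField(field, rotChain, "CR")
  outNR <- mapField(field, rotChain, "NR")
  ptd <- numeric(10)
  for (i in 1:10) {
    expect_equal(tensorMatrix(fieldTensors(outCR)[[i]]),
                 R %*% tensorMatrix(tensors[[i]]) %*% t(R),
                 tolerance = 1e-10)
    # rotation-only schemes keep DA; NR and CR differ in direction
    expect_equal(degreeOfAnisotropy(fieldTensors(outCR)[[i]]),
                 degreeOfAnisotropy(tensors[[i]]), tolerance = 1e-12)
    ptd[i] <- ptdError(fieldTensors(outCR)[[i]], fieldTensors(outNR)[[i]])
  }
  expect_gt(mean(ptd), 5)
})
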