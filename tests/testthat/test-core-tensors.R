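test_that("trace normalization scales SPD matrices to trace 3 and is idempotent", {
  expect_equal(tensorMatrix(normalizeTrace(diag(3))), diag(3))
  expect_equal(tensorMatrix(normalizeTrace(diag(c(2, 2, 2)))), diag(3))
  expect_equal(tensorMatrix(normalizeTrace(diag(c(1, 2, 3)))),
               diag(c(0.5, 1, 1.5)))
  set.seed(11)
  for (i in 1:20) {
    M <- randomSPD()
    n1 <- tensorMatrix(normalizeTrace(M))
    expect_equal(sum(diag(n1)), 3, tolerance = 1e-12)
    expect_equal(tensorMatrix(normalizeTrace(n1)), n1, tolerance = 1e-14)
  }
})

test_that("invalid fabric tensor inputs raise classed errors", {
  M <- diag(3); M[1, 2] <- 0.5            # asymmetric
  expect_error(normalizeTrace(M), class = "fmSymmetryError")
  expect_error(normalizeTrace(diag(c(1, 1, -1))),
               class = "fmDefinitenessError")
  expect_error(meanTensor(list()), class = "fmEmptyInputError")
})

test_that("degree of anisotropy matches an independent SVD oracle and is rotation invariant", {
  expect_equal(degreeOfAnisotropy(diag(3)), 1)
  expect_equal(degreeOfAnisotropy(diag(c(0.5, 1, 1.5))), 3)
  set.seed(42)
  for (i in 1:1000) {
    M <- randomSPD()
    sv <- svd(M)$d                        # SPD: singular values = eigenvalues
    expect_equal(degreeOfAnisotropy(M), max(sv) / min(sv),
                 tolerance = 1e-10)
    R <- randomRotation()
    expect_equal(degreeOfAnisotropy(R %*% M %*% t(R)),
                 degreeOfAnisotropy(M), tolerance = 1e-10)
  }
})

test_that("principal direction recovers constructed axes with sign convention", {
  v <- principalDirection(FabricTensor(diag(c(1, 2, 3))))
  expect_equal(as.numeric(v), c(0, 0, 1))
  expect_false(attr(v, "degenerate"))
  set.seed(7)
  for (i in 1:100) {
    R <- randomRotation()
    M <- R %*% diag(c(1, 2, 3)) %*% t(R)
    v <- principalDirection(FabricTensor(M))
    u <- R[, 3]
    if (sum(v * u) < 0) u <- -u           # axial identification
    # small-angle metric via the cross product (acos loses precision at 1)
    cr <- c(v[2] * u[3] - v[3] * u[2], v[3] * u[1] - v[1] * u[3],
            v[1] * u[2] - v[2] * u[1])
    expect_lt(sqrt(sum(cr^2)), 1e-8)
    expect_gt(v[which.max(abs(v))], 0)    # sign convention
  }
  vI <- principalDirection(FabricTensor(diag(3)))
  expect_true(attr(vI, "degenerate"))
})

test_that("SPD log/exp are mutual inverses and act elementwise on diagonals", {
  expect_equal(spdLog(diag(3)), matrix(0, 3, 3))
  expect_equal(spdLog(diag(c(exp(1), 1, 1))), diag(c(1, 0, 0)))
  expect_equal(spdLog(diag(c(2, 3, 4))), diag(log(c(2, 3, 4))))
  set.seed(5)
  for (i in 1:500) {
    V <- randomSPD()
    expect_equal(spdExp(spdLog(V)), V, tolerance = 1e-9)
  }
  expect_error(spdLog(diag(c(1, 0, 1))), class = "fmDefinitenessError")
})

test_that("mean tensor is the renormalized elementwise average", {
  t1 <- normalizeTrace(diag(c(0.5, 1, 1.5)))
  expect_equal(tensorMatrix(meanTensor(list(t1, t1, t1))),
               tensorMatrix(t1))
  # 90-degree rotation about x maps diag(0.5,1,1.5) -> diag(0.5,1.5,1)
  t2 <- normalizeTrace(diag(c(0.5, 1.5, 1)))
  expect_equal(tensorMatrix(meanTensor(list(t1, t2))),
               diag(c(0.5, 1.25, 1.25)))
  set.seed(9)
  for (i in 1:25) {
    ts <- lapply(1:4, function(j) normalizeTrace(randomSPD()))
    direct <- Reduce(`+`, lapply(ts, tensorMatrix)) / 4   # brute-force sum
    direct <- 3 * direct / sum(diag(direct))
    expect_equal(tensorMatrix(meanTensor(ts)), direct, tolerance = 1e-12)
    expect_equal(sum(diag(tensorMatrix(meanTensor(ts)))), 3,
                 tolerance = 1e-12)
  }
})

test_that("tensor-field tables round-trip through CSV", {
  set.seed(3)
  pts <- matrix(runif(15, 0, 10), 5, 3)
  tensors <- lapply(1:5, function(i) normalizeTrace(randomSPD()))
  f <- FabricField(pts, tensors, bvtv = runif(5))
  path <- tempfile(fileext = ".csv")
  writeFabricField(f, path)
  g <- readFabricField(path)
  expect_equal(controlPoints(g), controlPoints(f), ignore_attr = TRUE)
  expect_equal(fieldBVTV(g), fieldBVTV(f), tolerance = 1e-12)
  for (i in 1:5)
    expect_equal(tensorMatrix(fieldTensors(g)[[i]]),
                 tensorMatrix(fieldTensors(f)[[i]]), tolerance = 1e-12)
})

test_that("nearest-point field lookup returns the closest unflagged tensor", {
  pts <- rbind(c(0, 0, 0), c(10, 0, 0))
  tensors <- list(normalizeTrace(diag(c(1, 1, 1))),
                  normalizeTrace(diag(c(0.5, 1, 1.5))))
  f <- FabricField(pts, tensors)
  at <- fabricFieldAt(f, rbind(c(1, 0, 0), c(9, 0, 0)))
  expect_equal(tensorMatrix(at$tensors[[1]]), diag(3))
  expect_equal(tensorMatrix(at$tensors[[2]]), diag(c(0.5, 1, 1.5)))
})
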