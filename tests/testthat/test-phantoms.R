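test_that("generators are deterministic under a fixed seed", {
  s <- phantomSpec(texture = "anisotropic-noise", bvtv = 0.3, side = 4.8,
                   hrSpacing = 0.15, seed = 5)
  v1 <- makeTrabecularVolume(s)
  v2 <- makeTrabecularVolume(s)
  expect_identical(voxels(v1$image), voxels(v2$image))
  q1 <- simulateQCT(v1$image, 0.6, noiseSd = 0.05, seed = 9)
  q2 <- simulateQCT(v2$image, 0.6, noiseSd = 0.05, seed = 9)
  expect_identical(voxels(q1), voxels(q2))
})

test_that("noise phantoms hit the target BV/TV and the rod axis is correct", {
  s <- phantomSpec(texture = "anisotropic-noise", bvtv = 0.3, side = 4.8,
                   hrSpacing = 0.15, seed = 5)
  v <- makeTrabecularVolume(s)
  expect_lt(abs(mean(voxels(v$image)) - 0.3), 0.005)
  expect_error(makeTrabecularVolume(
    phantomSpec(texture = "unknown-texture")), class = "fmParameterError")
  expect_error(phantomSpec(bvtv = 1.2), class = "fmParameterError")
})

test_that("simulated QCT tracks local bone volume fraction", {
  # half-bone, half-marrow: intensity strictly higher in the bone half
  arr <- array(0, c(64, 64, 64)); arr[, , 33:64] <- 1
  hr <- BoneImage(arr, spacing = rep(0.15, 3))
  q <- simulateQCT(hr, qctSpacing = 0.6, noiseSd = 0, seed = 1)
  expect_gt(mean(voxels(q)[, , 14:16]), mean(voxels(q)[, , 1:3]) + 0.5)
  # constant input, zero noise -> constant output
  qc <- simulateQCT(BoneImage(array(1, c(32, 32, 32)),
                              spacing = rep(0.15, 3)),
                    qctSpacing = 0.6, noiseSd = 0, seed = 1)
  expect_lt(diff(range(voxels(qc))), 1e-9)
  expect_error(simulateQCT(hr, qctSpacing = 0.1),
               class = "fmParameterError")
  # correlation between local BV/TV (window average of the binary
  # phantom) and local mean intensity on a modulated phantom
  s <- phantomSpec(texture = "anisotropic-noise", bvtv = 0.25,
                   bvtvRange = c(0.05, 0.45), side = 9.6,
                   hrSpacing = 0.15, seed = 31)
  v <- makeTrabecularVolume(s)
  q2 <- simulateQCT(v$image, qctSpacing = 0.6, noiseSd = 0.02, seed = 1)
  localBvtv <- sampleImage(gaussianSmooth(v$image, 1.2), voxelCenters(q2))
  localMean <- as.numeric(voxels(gaussianSmooth(q2, 1.2)))
  expect_gt(cor(localBvtv, localMean), 0.9)
})

test_that("warped members store their exact generating chain", {
  base <- qctBase()
  members <- population()$members
  m0 <- warpPopulation(base, 1, magnitudes = 0, seed = 999)[[1]]
  expect_equal(voxels(m0$qct), voxels(base$qct), tolerance = 1e-12)
  # stored chain reproduces the member bit-exactly by construction
  m1 <- members[[2]]
  redone <- applyTransform(base$qct, base$qct, m1$chain, interp = "linear")
  expect_identical(voxels(redone), voxels(m1$qct))
})

test_that("warp magnitude drives a monotone deformation distance", {
  base <- qctBase()
  grid <- controlGrid(base$qct, spacing = 3.6, margin = 1.2)
  mags <- c(0.3, 0.8, 1.4, 2)
  dms <- vapply(seq_along(mags), function(i) {
    ch <- warpPopulation(base, 1, magnitudes = mags[i],
                         seed = 500 + i)[[1]]$chain
    distanceMetric(ch, grid)
  }, numeric(1))
  expect_true(all(diff(dms) > 0))
})

test_that("member ground-truth fabric is the rotated base fabric", {
  pop <- population()
  base <- qctBase()
  m <- pop$members[[3]]
  pts <- matrix(c(4, 5, 6, 7, 8, 6), 2, 3, byrow = TRUE)
  got <- m$fabricFun(pts)
  for (i in 1:2) {
    F <- fabricmap:::chainGradients(m$chain, pts)[[i]]
    R <- vrDecompose(F)$R
    Mb <- base$fabricFun(transformPoints(m$chain, pts))$tensors[[i]]
    expect_equal(tensorMatrix(got$tensors[[i]]),
                 R %*% tensorMatrix(Mb) %*% t(R), tolerance = 1e-10)
    expect_equal(degreeOfAnisotropy(got$tensors[[i]]),
                 degreeOfAnisotropy(Mb), tolerance = 1e-10)
  }
})

test_that("femur phantom mask is a single connected component", {
  fx <- femurFixture()
  m <- voxels(fx$phantom$mask) > 0
  # 6-connected flood fill from one in-mask voxel
  idx <- which(m, arr.ind = TRUE)[1, ]
  visited <- array(FALSE, dim(m))
  queue <- matrix(idx, 1, 3)
  visited[queue] <- TRUE
  d <- dim(m)
  while (nrow(queue) > 0) {
    nxt <- do.call(rbind, lapply(1:3, function(ax) {
      up <- queue; up[, ax] <- up[, ax] + 1
      dn <- queue; dn[, ax] <- dn[, ax] - 1
      rbind(up, dn)
    }))
    ok <- nxt[, 1] >= 1 & nxt[, 1] <= d[1] & nxt[, 2] >= 1 &
      nxt[, 2] <= d[2] & nxt[, 3] >= 1 & nxt[, 3] <= d[3]
    nxt <- nxt[ok, , drop = FALSE]
    keep <- m[nxt] & !visited[nxt]
    nxt <- nxt[keep, , drop = FALSE]
    nxt <- nxt[!duplicated(nxt), , drop = FALSE]
    visited[nxt] <- TRUE
    queue <- nxt
  }
  expect_equal(sum(visited), sum(m))
})
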