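test_that("head detection recovers the design sphere and rejects cylinders", {
  fx <- femurFixture()
  tr <- fx$phantom$landmarks
  head <- headCenter(fx$phantom$mask)
  expect_lt(sqrt(sum((head$center - tr@headCenter)^2)),
            fx$spec$femurSpacing)
  expect_lt(abs(head$radius - tr@headRadius) / tr@headRadius, 0.02)
  # pure cylinder: elongated distance ridge, no head-like sphere
  cyl <- BoneImage(array(0, c(20, 20, 60)), spacing = rep(1, 3))
  co <- voxelCenters(cyl)
  inside <- (co[, 1] - 10)^2 + (co[, 2] - 10)^2 <= 36
  cylMask <- BoneImage(array(as.numeric(inside), dim(cyl)),
                       spacing = rep(1, 3))
  expect_error(headCenter(cylMask), class = "fmDetectionError")
})

test_that("head detection is translation equivariant", {
  fx <- femurFixture()
  m <- fx$phantom$mask
  shifted <- BoneImage(voxels(m), spacing = voxelSpacing(m),
                       origin = imageOrigin(m) + c(5, -3, 2))
  h0 <- headCenter(m)
  h1 <- headCenter(shifted)
  expect_equal(h1$center, h0$center + c(5, -3, 2), tolerance = 1e-9)
  expect_equal(h1$radius, h0$radius)
})

test_that("neck and shaft axes match the phantom construction", {
  fx <- femurFixture()
  lm <- fx$landmarks
  tr <- fx$phantom$landmarks
  expect_equal(sqrt(sum(lm@neckAxis^2)), 1, tolerance = 1e-12)
  expect_lt(angleBetweenAxes(lm@neckAxis, tr@neckAxis), 2)
  expect_lt(angleBetweenAxes(lm@shaftAxis, tr@shaftAxis), 1)
  expect_equal(lm@ccd, tr@ccd, tolerance = 2)
  expect_lt(sqrt(sum((lm@midPoint - tr@midPoint)^2)), 2)
})

test_that("landmark extraction is equivariant under rigid rotation", {
  fx <- femurFixture()
  m <- fx$phantom$mask
  R <- rotationAbout(c(0, 1, 0), 15 * pi / 180)
  ctr <- imageOrigin(m) + imageExtent(m) / 2
  # rotated mask: sample the original at R^-1-rotated coordinates
  pad <- 14
  big <- BoneImage(array(0, dim(m) + 2 * round(pad / voxelSpacing(m))),
                   spacing = voxelSpacing(m),
                   origin = imageOrigin(m) - pad)
  rot <- TransformChain(affine = t(R), translation = ctr - t(R) %*% ctr)
  mR <- applyTransform(m, big, rot, interp = "nearest")
  lmR <- femurLandmarks(mR, seed = 3)
  lm0 <- fx$landmarks
  expect_lt(angleBetweenAxes(lmR@neckAxis, R %*% lm0@neckAxis), 2)
  expect_lt(angleBetweenAxes(lmR@shaftAxis, R %*% lm0@shaftAxis), 2)
  expect_equal(lmR@ccd, lm0@ccd, tolerance = 2)
})

test_that("shaft RANSAC resists outlier slices and is seeded-deterministic", {
  fx <- femurFixture()
  m <- fx$phantom$mask
  # simulate a lesser-trochanter bulge: a lateral sphere on the shaft
  co <- voxelCenters(m)
  bulge <- rowSums((co - matrix(c(8, 0, 20), nrow(co), 3,
                                byrow = TRUE))^2) <= 36
  mB <- BoneImage(array(pmax(voxels(m), as.numeric(bulge)), dim(m)),
                  spacing = voxelSpacing(m), origin = imageOrigin(m))
  tr <- fx$phantom$landmarks
  s1 <- shaftAxis(mB, tr@neckAxisEndPoint, seed = 9)
  expect_lt(angleBetweenAxes(s1$direction, tr@shaftAxis), 2)
  s2 <- shaftAxis(mB, tr@neckAxisEndPoint, seed = 9)
  expect_identical(s1$direction, s2$direction)
})

test_that("CCD angle basics", {
  lm <- list(neckAxis = c(1, 0, 0), shaftAxis = c(0, 0, -1))
  expect_equal(ccdAngle(lm), 90)
  lmR <- list(neckAxis = rotationAbout(c(0, 1, 0), 0.3) %*% c(1, 0, 0),
              shaftAxis = rotationAbout(c(0, 1, 0), 0.3) %*% c(0, 0, -1))
  expect_equal(ccdAngle(lmR), 90, tolerance = 1e-10)
})

test_that("shaft standardization achieves the 0.7 ratio and keeps proximal voxels", {
  fx <- femurFixture()
  lm <- fx$landmarks
  st <- standardizeShaft(fx$phantom$hr, fx$phantom$mask, lm, ratio = 0.7)
  d1 <- sqrt(sum((lm@headCenter - lm@midPoint)^2))
  # one slice of cropping changes the ratio by about 0.7 * h / (d1/0.7)
  sliceTol <- 0.7 * fx$spec$femurSpacing / (d1 / 0.7)
  expect_lt(abs(st$achievedRatio - 0.7), sliceTol + 1e-9)
  # proximal voxel counts unchanged (crop is distal only); the output frame
  # is recentered at the mid point
  mid <- lm@midPoint
  proximal0 <- sum(voxels(fx$phantom$mask)[voxelCenters(
    fx$phantom$mask)[, 3] > mid[3]])
  proximal1 <- sum(voxels(st$mask)[voxelCenters(st$mask)[, 3] > 0])
  expect_equal(proximal1, proximal0)
  # a second pass on an already-standardized geometry changes nothing
  expect_error(standardizeShaft(fx$phantom$hr, fx$phantom$mask, lm,
                                ratio = 0.2), class = "fmLengthError")
})

test_that("landmarks round-trip through JSON", {
  fx <- femurFixture()
  path <- tempfile(fileext = ".json")
  writeLandmarks(fx$landmarks, path)
  lm2 <- readLandmarks(path)
  expect_equal(lm2@headCenter, fx$landmarks@headCenter)
  expect_equal(lm2@ccd, fx$landmarks@ccd)
  expect_equal(lm2@shaftAxis, fx$landmarks@shaftAxis)
})
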