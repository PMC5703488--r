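# Shared fixtures, built once per test session (all generated in code).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# seeded random SPD matrix
randomSPD <- function(scale = 1) {
  A <- matrix(rnorm(9), 3, 3)
  crossprod(A) * scale + diag(3) * 0.1
}

# seeded random rotation
randomRotation <- function() {
  ax <- rnorm(3)
  rotationAbout(ax / sqrt(sum(ax^2)), runif(1, 0, pi))
}

angleBetweenAxes <- function(a, b)
  acos(min(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)))) * 180 / pi

# light registration parameters used throughout the phantom tests
testRegParams <- function()
  registrationParams(gamma = 0.05, levels = 3, maxIter = c(30, 20, 12))

# cube QCT base: modulated trabecular HR volume blurred to QCT resolution,
# analytic fabric ground truth, ball mask
qctBase <- function() fixture("qctBase", function() {
  side <- 14.4
  spec <- phantomSpec(texture = "anisotropic-noise", bvtv = 0.25,
                      bvtvRange = c(0.08, 0.4), side = side,
                      hrSpacing = 0.15, qctSpacing = 0.6, seed = 21)
  tv <- makeTrabecularVolume(spec)
  qct <- simulateQCT(tv$image, qctSpacing = 0.6, noiseSd = 0.01, seed = 22)
  ctr <- imageOrigin(qct) + imageExtent(qct) / 2
  co <- voxelCenters(qct)
  ball <- as.numeric(sqrt(rowSums((co - matrix(ctr, nrow(co), 3,
                                               byrow = TRUE))^2)) <=
                       side / 2 - 1.2)
  mask <- BoneImage(array(ball, dim(qct)), spacing = voxelSpacing(qct),
                    origin = imageOrigin(qct))
  list(qct = qct, mask = mask, hr = tv$image, side = side,
       fabricFun = syntheticFabricFun(rotationRate = 2,
                                      zRange = c(0, side)))
})

# 4-record population: identical copy, mild warp, strong warp + the base,
# with pairwise DM and a shared registration cache
population <- function() fixture("population", function() {
  base <- qctBase()
  members <- warpPopulation(base, 3, magnitudes = c(0, 0.7, 1.6),
                            rotDeg = 7, transMm = 1.2, maxDisp = 1.5,
                            seed = 200)
  db <- syntheticDatabase(members, base = base)
  cache <- new.env()
  db <- pairwiseDM(db, params = testRegParams(), gridSpacing = 3.6,
                   cache = cache)
  list(db = db, members = members, cache = cache, gridSpacing = 3.6)
})

# full factorial experiment on the population (atlas modes x schemes)
populationExperiment <- function() fixture("populationExperiment",
  function() {
    pop <- population()
    runExperiment(pop$db, modes = c("CTP", "MTP", "FTP"),
                  schemes = c("NR", "AR", "CR"), params = testRegParams(),
                  gridSpacing = pop$gridSpacing, cache = pop$cache)
})

# known-warp registration recovery (peak B-spline displacement 5 voxels);
# run at full registration effort, unlike the population screens
warpRecovery <- function() fixture("warpRecovery", function() {
  base <- qctBase()
  mem <- warpPopulation(base, 1, magnitudes = 1, rotDeg = 6,
                        transMm = 1.5, maxDisp = 3.0, seed = 400)[[1]]
  reg <- registerPair(mem$qct, base$qct,
                      registrationParams(gamma = 0.01, levels = 3,
                                         maxIter = c(60, 40, 30)))
  probe <- controlGrid(mem$qct, spacing = 2.4, margin = 2)
  err <- sqrt(rowSums((transformPoints(transformChain(reg), probe) -
                         transformPoints(mem$chain, probe))^2))
  dice <- diceQC(mem$mask, base$mask, transformChain(reg))
  list(member = mem, reg = reg, errMM = err,
       voxel = voxelSpacing(base$qct)[1], dice = dice)
})

# femur phantom and recovered landmarks
femurFixture <- function() fixture("femur", function() {
  spec <- phantomSpec(geometry = "femur", texture = "none", seed = 1)
  ph <- makeFemurPhantom(spec)
  lm <- femurLandmarks(ph$mask, seed = 3)
  list(phantom = ph, landmarks = lm, spec = spec)
})

# small trabecular VOIs for MIL tests
milFixtures <- function() fixture("mil", function() {
  # 0.10 mm voxels give ~1000 spheres per VOI: enough structures for the
  # MIL estimator variance to sit well inside the isotropy band
  iso <- makeTrabecularVolume(phantomSpec(texture = "boolean-spheres",
                                          bvtv = 0.3, side = 7.2,
                                          hrSpacing = 0.10, seed = 3))
  rod <- makeTrabecularVolume(phantomSpec(texture = "rods",
                                          fabric = diag(c(0.8, 0.8, 1.4)),
                                          bvtv = 0.3, side = 7.2,
                                          hrSpacing = 0.15, seed = 2))
  aniso <- makeTrabecularVolume(phantomSpec(texture = "anisotropic-noise",
                                            fabric = diag(c(0.55, 1, 1.45)),
                                            bvtv = 0.3, side = 12,
                                            hrSpacing = 0.15, seed = 4))
  ctr <- c(3.6, 3.6, 3.6)
  list(isoVOI = extractVOI(iso$image, ctr, side = 5.3),
       rodVOI = extractVOI(rod$image, ctr, side = 5.3),
       rodImage = rod$image, isoImage = iso$image,
       anisoImage = aniso$image)
})
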