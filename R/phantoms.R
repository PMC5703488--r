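#' Phantom specification
#'
#' Collects the parameters of the synthetic generators. Defaults emulate
#' the HR/QCT resolution ratio of a dual HRpQCT/QCT femur acquisition
#' (about 4x) at a desk-scale volume: 19.2 mm cubes, 0.15 mm HR voxels,
#' 0.6 mm QCT voxels.
#'
#' @param geometry `"cube"` or `"femur"`.
#' @param texture `"anisotropic-noise"`, `"rods"`, `"plates"`,
#'   `"boolean-spheres"` or `"none"`.
#' @param fabric target fabric tensor (SPD 3x3 or [FabricTensor-class]);
#'   its principal axis orients the generated structure.
#' @param bvtv target bone volume fraction in (0, 1).
#' @param bvtvRange optional `c(lo, hi)`: spatially modulate BV/TV with a
#'   smooth seeded field instead of a uniform fraction.
#' @param side cube side length (mm).
#' @param hrSpacing,qctSpacing voxel spacings (mm).
#' @param corrLength structure correlation length (mm) of the noise texture.
#' @param noiseSd QCT additive noise standard deviation (intensity units).
#' @param headRadius,neckRadius,shaftRadius,neckLength,shaftLength,ccd
#'   femur-geometry parameters (mm, degrees).
#' @param femurSpacing voxel spacing of femur phantoms (mm).
#' @param seed integer; fixes all randomness of the generator.
#' @return named list of class `phantomSpec`.
#' @export
phantomSpec <- function(geometry = c("cube", "femur"),
                        texture = "anisotropic-noise",
                        fabric = diag(3), bvtv = 0.3, bvtvRange = NULL,
                        side = 19.2, hrSpacing = 0.15, qctSpacing = 0.6,
                        corrLength = 0.45, noiseSd = 0.02,
                        headRadius = 9, neckRadius = 4, shaftRadius = 6,
                        neckLength = 26, shaftLength = 55, ccd = 128,
                        femurSpacing = 0.75, seed = 1L) {
  geometry <- match.arg(geometry)
  if (bvtv <= 0 || bvtv >= 1)
    fmStop("fmParameterError", "bvtv must be in (0, 1)")
  if (hrSpacing <= 0 || qctSpacing <= 0 || side <= 0)
    fmStop("fmParameterError", "spacings and side must be positive")
  structure(list(geometry = geometry, texture = texture,
                 fabric = fabric, bvtv = bvtv, bvtvRange = bvtvRange,
                 side = side, hrSpacing = hrSpacing,
                 qctSpacing = qctSpacing, corrLength = corrLength,
                 noiseSd = noiseSd, headRadius = headRadius,
                 neckRadius = neckRadius, shaftRadius = shaftRadius,
                 neckLength = neckLength, shaftLength = shaftLength,
                 ccd = ccd, femurSpacing = femurSpacing,
                 seed = as.integer(seed)), class = "phantomSpec")
}

fftFreq <- function(n, h) {
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]
  k / (n * h)            # cycles/mm
}

#' Synthetic trabecular microstructure with prescribed fabric
#'
#' Generates a binary volume whose MIL fabric approximates a target tensor.
#' The primary `"anisotropic-noise"` mode filters seeded white noise with an
#' anisotropic Gaussian whose correlation lengths are proportional to the
#' target eigenvalues along the target eigenvectors, then thresholds at the
#' quantile matching the target BV/TV (optionally spatially modulated).
#' `"rods"` and `"plates"` place periodic structures analytically along the
#' target principal axis; `"boolean-spheres"` unions seeded random spheres
#' (isotropic).
#'
#' @param spec a [phantomSpec()].
#' @return list with `image` (binary HR [BoneImage-class]), `fabric`
#'   (trace-3 target [FabricTensor-class]), and `bvtvField` (smooth local
#'   BV/TV [BoneImage-class], or `NULL` for uniform phantoms).
#' @export
makeTrabecularVolume <- function(spec) {
  target <- normalizeTrace(spec$fabric)
  h <- spec$hrSpacing
  n <- max(8L, round(spec$side / h))
  dims <- rep(n, 3)
  u <- principalDirection(target)
  bvtvField <- NULL
  vol <- withSeed(spec$seed, {
    if (spec$texture == "anisotropic-noise") {
      noise <- array(rnorm(prod(dims)), dims)
      sig <- spec$corrLength * fabricEigenvalues(target)
      V <- fabricEigenvectors(target)
      f1 <- fftFreq(n, h); f2 <- f1; f3 <- f1
      K1 <- array(rep(f1, times = n * n), dims)
      K2 <- array(rep(rep(f2, each = n), times = n), dims)
      K3 <- array(rep(f3, each = n * n), dims)
      Kt1 <- V[1, 1] * K1 + V[2, 1] * K2 + V[3, 1] * K3
      Kt2 <- V[1, 2] * K1 + V[2, 2] * K2 + V[3, 2] * K3
      Kt3 <- V[1, 3] * K1 + V[2, 3] * K2 + V[3, 3] * K3
      G <- exp(-2 * pi^2 * ((sig[1] * Kt1)^2 + (sig[2] * Kt2)^2 +
                              (sig[3] * Kt3)^2))
      sm <- Re(fft(fft(noise) * G, inverse = TRUE)) / prod(dims)
      z <- (sm - mean(sm)) / sd(sm)
      if (is.null(spec$bvtvRange)) {
        as.numeric(z > quantile(z, 1 - spec$bvtv))
      } else {
        mod <- array(rnorm(prod(dims)), dims)
        # modulation field varies on a third-of-volume scale
        Gm <- exp(-2 * pi^2 * (spec$side / 3)^2 * (K1^2 + K2^2 + K3^2))
        mz <- Re(fft(fft(mod) * Gm, inverse = TRUE)) / prod(dims)
        mz <- (mz - mean(mz)) / sd(mz)
        p <- spec$bvtvRange[1] + (spec$bvtvRange[2] - spec$bvtvRange[1]) *
          stats::pnorm(mz)
        bvtvField <- p
        as.numeric(z > qnorm(1 - p))
      }
    } else if (spec$texture %in% c("rods", "plates")) {
      co <- voxelCenters(BoneImage(array(0, dims), spacing = rep(h, 3)))
      e1 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- e1 - sum(e1 * u) * u; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
              u[1] * e1[2] - u[2] * e1[1])
      if (spec$texture == "rods") {
        s <- 8 * h
        rodR <- s * sqrt(spec$bvtv / pi)
        p1 <- (co %*% e1) %% s - s / 2
        p2 <- (co %*% e2) %% s - s / 2
        as.numeric(p1^2 + p2^2 < rodR^2)
      } else {
        period <- 8 * h
        t <- (co %*% u) %% period
        as.numeric(t < spec$bvtv * period)
      }
    } else if (spec$texture == "boolean-spheres") {
      rs <- 3 * h
      rvox <- ceiling(rs / h)
      off <- as.matrix(expand.grid(-rvox:rvox, -rvox:rvox, -rvox:rvox))
      off <- off[rowSums((off * h)^2) <= (rs + h / 2)^2, , drop = FALSE]
      vball <- nrow(off) * h^3        # rasterized ball volume
      Vtot <- prod(dims) * h^3
      nball <- max(1L, round(-log(1 - spec$bvtv) * Vtot / vball))
      a <- array(0, dims)
      ctr <- matrix(runif(3 * nball, 0, n * h), ncol = 3)
      for (b in seq_len(nball)) {
        cidx <- round(ctr[b, ] / h - 0.5) + 1
        idx <- off + matrix(cidx, nrow(off), 3, byrow = TRUE)
        ok <- idx[, 1] >= 1 & idx[, 1] <= n & idx[, 2] >= 1 &
          idx[, 2] <= n & idx[, 3] >= 1 & idx[, 3] <= n
        a[idx[ok, , drop = FALSE]] <- 1
      }
      as.numeric(a)
    } else {
      fmStop("fmParameterError", "unknown texture %s", spec$texture)
    }
  })
  img <- BoneImage(array(vol, dims), spacing = rep(h, 3))
  b <- mean(vol)
  if (b <= 0 || b >= 1)
    fmStop("fmGenerationError",
           "texture %s could not realize BV/TV %.3g (got %.3g)",
           spec$texture, spec$bvtv, b)
  field <- if (!is.null(bvtvField))
    BoneImage(array(bvtvField, dims), spacing = rep(h, 3)) else NULL
  list(image = img, fabric = target, bvtvField = field)
}

#' Femur-like geometry phantom
#'
#' Builds a proximal-femur-like binary mask from analytic primitives: a
#' spherical head, a cylindrical neck meeting the shaft at the design CCD
#' angle, and a cylindrical shaft, together with the ground-truth landmarks
#' implied by the construction. The shaft axis runs along z (distal at
#' z = 0); the neck lies in the x-z plane.
#'
#' @param spec a [phantomSpec()] with `geometry = "femur"`.
#' @return list with `mask` (binary [BoneImage-class]), `hr` (grayscale
#'   copy of the mask, optionally textured), and `landmarks`
#'   ([FemurLandmarks-class] ground truth).
#' @export
makeFemurPhantom <- function(spec) {
  a <- (180 - spec$ccd) * pi / 180
  u <- c(sin(a), 0, cos(a))                  # toward the head
  L <- spec$shaftLength
  P0 <- c(0, 0, L)                            # neck-shaft junction
  hc <- P0 + spec$neckLength * u
  if (spec$neckLength <= spec$headRadius)
    fmStop("fmParameterError", "neck shorter than the head radius")
  h <- spec$femurSpacing
  margin <- 3
  lo <- pmin(c(-spec$shaftRadius, -spec$shaftRadius, 0),
             hc - spec$headRadius) - margin
  hi <- pmax(c(spec$shaftRadius, spec$shaftRadius, L),
             hc + spec$headRadius) + margin
  dims <- as.integer(ceiling((hi - lo) / h))
  img <- BoneImage(array(0, dims), spacing = rep(h, 3), origin = lo)
  co <- voxelCenters(img)
  # head sphere
  inHead <- rowSums((co - matrix(hc, nrow(co), 3, byrow = TRUE))^2) <=
    spec$headRadius^2
  # shaft cylinder along z
  inShaft <- co[, 1]^2 + co[, 2]^2 <= spec$shaftRadius^2 &
    co[, 3] >= 0 & co[, 3] <= L
  # neck cylinder from P0 to head center
  rel <- co - matrix(P0, nrow(co), 3, byrow = TRUE)
  t <- rel %*% u
  d2 <- rowSums(rel^2) - t^2
  inNeck <- d2 <= spec$neckRadius^2 & t >= 0 & t <= spec$neckLength
  mask <- BoneImage(array(as.numeric(inHead | inShaft | inNeck), dims),
                    spacing = rep(h, 3), origin = lo)
  lm <- new("FemurLandmarks", headCenter = hc, headRadius = spec$headRadius,
            neckCenter = hc - 1.25 * spec$headRadius * u,
            neckAxis = -u, neckAxisEndPoint = P0,
            shaftPoint = c(0, 0, L / 2), shaftAxis = c(0, 0, -1),
            shaftDistalPoint = c(0, 0, 0), midPoint = P0, ccd = spec$ccd)
  hr <- mask
  if (!identical(spec$texture, "none")) {
    tex <- withSeed(spec$seed, array(runif(prod(dims), 0.6, 1), dims))
    hr <- BoneImage(array(mask@.Data * tex, dims), spacing = rep(h, 3),
                    origin = lo)
  }
  list(mask = mask, hr = hr, landmarks = lm)
}

#' Simulate a clinical-resolution QCT from a high-resolution volume
#'
#' Gaussian blur at the target resolution scale, resampling to the QCT
#' lattice, and seeded additive Gaussian noise. The simulated intensity is
#' proportional to the local bone volume fraction, as in a calibrated QCT.
#'
#' @param hr high-resolution [BoneImage-class] (binary or grayscale).
#' @param qctSpacing target isotropic spacing (mm), coarser than the input.
#' @param noiseSd additive noise standard deviation.
#' @param seed integer seed.
#' @return simulated QCT [BoneImage-class].
#' @export
simulateQCT <- function(hr, qctSpacing = 0.6, noiseSd = 0.02, seed = 1L) {
  if (qctSpacing <= max(hr@spacing))
    fmStop("fmParameterError",
           "qctSpacing must be coarser than the input spacing")
  sm <- gaussianSmooth(hr, sigma = qctSpacing / 2)
  out <- resampleImage(sm, spacing = qctSpacing)
  if (noiseSd > 0) {
    noise <- withSeed(seed, rnorm(prod(dim(out)), 0, noiseSd))
    out <- BoneImage(array(out@.Data + noise, dim(out)),
                     spacing = out@spacing, origin = out@origin)
  }
  out
}

#' Analytic fabric field with spatially rotating principal direction
#'
#' Returns a function mapping points (N x 3, mm) to fabric tensors whose
#' principal direction rotates about `axis` at `rotationRate` degrees per mm
#' of z, with fixed eigenvalues. The companion BV/TV ramps linearly along z
#' over `bvtvRange`. Used as ground truth for synthetic populations.
#'
#' @param eigenvalues length-3, ascending, summing to 3.
#' @param rotationRate degrees of rotation per mm.
#' @param axis rotation axis (unit 3-vector).
#' @param center point of zero rotation (mm).
#' @param zRange z extent used to normalize the BV/TV ramp (mm).
#' @param bvtvRange `c(lo, hi)` BV/TV ramp.
#' @return function `f(points) -> list(tensors =, bvtv =)`.
#' @export
syntheticFabricFun <- function(eigenvalues = c(0.7, 1.0, 1.3),
                               rotationRate = 2, axis = c(0, 1, 0),
                               center = c(0, 0, 0), zRange = c(0, 20),
                               bvtvRange = c(0.1, 0.35)) {
  axis <- axis / sqrt(sum(axis^2))
  base <- diag(eigenvalues)
  function(points) {
    points <- matrix(as.numeric(points), ncol = 3)
    tensors <- lapply(seq_len(nrow(points)), function(i) {
      ang <- rotationRate * (points[i, 3] - center[3]) * pi / 180
      R <- rotationAbout(axis, ang)
      normalizeTrace(R %*% base %*% t(R))
    })
    zf <- pmin(1, pmax(0, (points[, 3] - zRange[1]) /
                         (zRange[2] - zRange[1])))
    list(tensors = tensors, bvtv = bvtvRange[1] +
           (bvtvRange[2] - bvtvRange[1]) * zf)
  }
}

#' Rotation matrix about an axis
#'
#' Rodrigues rotation by `angle` radians about a unit `axis`.
#'
#' @param axis 3-vector (normalized internally).
#' @param angle radians.
#' @return 3x3 rotation matrix.
#' @export
rotationAbout <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# seeded random smooth chain (affine + B-spline) over a domain
randomChain <- function(domainLo, domainHi, magnitude = 1, rotDeg = 8,
                        scaleJitter = 0.03, transMm = 1.5,
                        gridSpacing = NULL, seed = 1L) {
  ctr <- (domainLo + domainHi) / 2
  withSeed(seed, {
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    ang <- runif(1, 0.5, 1) * rotDeg * magnitude * pi / 180
    sc <- 1 + runif(3, -1, 1) * scaleJitter * magnitude
    A <- rotationAbout(axis, ang) %*% diag(sc)
    delta <- runif(3, -1, 1) * transMm * magnitude
    trans <- ctr - A %*% ctr + delta
    if (is.null(gridSpacing))
      gridSpacing <- max((domainHi - domainLo)) / 3
    corners <- as.matrix(expand.grid(c(domainLo[1], domainHi[1]),
                                     c(domainLo[2], domainHi[2]),
                                     c(domainLo[3], domainHi[3])))
    yc <- corners %*% t(A) + matrix(trans, 8, 3, byrow = TRUE)
    grid <- bsplineGridFor(apply(yc, 2, min), apply(yc, 2, max),
                           gridSpacing)
    ncoef <- prod(grid$dims)
    coef <- matrix(rnorm(ncoef * 3), ncoef, 3)
    arr <- array(coef, c(grid$dims, 3))
    for (d in 1:3) arr[, , , d] <- array(
      cpp_blur_sep(as.numeric(arr[, , , d]), grid$dims, rep(1, 3)),
      grid$dims)
    coef <- matrix(arr, ncoef, 3)
    probe <- as.matrix(expand.grid(
      seq(domainLo[1], domainHi[1], length.out = 7),
      seq(domainLo[2], domainHi[2], length.out = 7),
      seq(domainLo[3], domainHi[3], length.out = 7)))
    if (magnitude > 0) {
      disp <- cpp_bspline_disp(probe %*% t(A) +
                                 matrix(trans, nrow(probe), 3, byrow = TRUE),
                               grid$origin, grid$spacing, grid$dims, coef)
      maxd <- max(sqrt(rowSums(disp^2)))
      scale <- if (maxd > 0) magnitude * 1.0 / maxd else 0
      coef <- coef * scale
    } else coef <- coef * 0
    chain <- TransformChain(affine = A, translation = as.numeric(trans),
                            bsplineOrigin = grid$origin,
                            bsplineSpacing = grid$spacing,
                            bsplineDims = grid$dims, bsplineCoef = coef)
    # guard against folding: shrink the warp until det F is safely positive
    repeat {
      dets <- vapply(chainGradients(chain, probe), det, numeric(1))
      if (min(dets) > 0.2) break
      message("randomChain: shrinking warp to avoid folding")
      chain@bsplineCoef <- chain@bsplineCoef * 0.7
    }
    chain
  })
}

#' Warped synthetic population with stored ground truth
#'
#' Generates population members by resampling a base image through seeded
#' random affine + smooth B-spline chains. Each member stores its exact
#' chain, so the member's ground-truth fabric at any point `x` is the
#' finite-strain reorientation `R(x) M_base(T(x)) R(x)'` of the base
#' fabric, computable analytically.
#'
#' @param base list with `qct` ([BoneImage-class]), optional `mask`, and
#'   `fabricFun` (see [syntheticFabricFun()]).
#' @param n number of members.
#' @param magnitudes per-member warp magnitude multipliers (recycled).
#' @param rotDeg,transMm,maxDisp global rotation (degrees), translation
#'   (mm) and peak B-spline displacement (mm) at magnitude 1.
#' @param seed integer; member k uses `seed + k`.
#' @return list of members, each
#'   `list(id, qct, mask, chain, fabricFun)`; the member image is the base
#'   resampled through its chain.
#' @export
warpPopulation <- function(base, n, magnitudes = rep(1, n), rotDeg = 8,
                           transMm = 1.5, maxDisp = 1.5, seed = 1L) {
  magnitudes <- rep_len(magnitudes, n)
  domLo <- base$qct@origin
  domHi <- base$qct@origin + (dim(base$qct) - 1) * base$qct@spacing
  lapply(seq_len(n), function(k) {
    mag <- magnitudes[k]
    chain <- randomChain(domLo, domHi, magnitude = mag, rotDeg = rotDeg,
                         transMm = transMm, seed = seed + k)
    # scale B-spline part to the requested peak displacement
    if (mag > 0 && any(chain@bsplineDims > 0)) {
      probe <- voxelCenters(base$qct)
      probe <- probe[seq(1, nrow(probe), length.out = 300), , drop = FALSE]
      y <- probe %*% t(chain@affine) +
        matrix(chain@translation, nrow(probe), 3, byrow = TRUE)
      u <- cpp_bspline_disp(y, chain@bsplineOrigin, chain@bsplineSpacing,
                            chain@bsplineDims, chain@bsplineCoef)
      maxd <- max(sqrt(rowSums(u^2)))
      if (maxd > 0)
        chain@bsplineCoef <- chain@bsplineCoef * (maxDisp * mag / maxd)
    }
    qct <- applyTransform(base$qct, base$qct, chain, interp = "linear")
    mask <- if (!is.null(base$mask))
      applyTransform(base$mask, base$mask, chain, interp = "nearest")
      else NULL
    fabricFun <- local({
      ch <- chain; bf <- base$fabricFun
      function(points) {
        points <- matrix(as.numeric(points), ncol = 3)
        moved <- transformPoints(ch, points)
        baseFab <- bf(moved)
        Fs <- chainGradients(ch, points)
        tensors <- lapply(seq_len(nrow(points)), function(i) {
          R <- vrDecompose(Fs[[i]])$R
          normalizeTrace(R %*% tensorMatrix(baseFab$tensors[[i]]) %*% t(R))
        })
        list(tensors = tensors, bvtv = baseFab$bvtv)
      }
    })
    list(id = sprintf("P%02d", k), qct = qct, mask = mask, chain = chain,
         fabricFun = fabricFun)
  })
}

#' Assemble a synthetic atlas database
#'
#' Builds an in-memory [AtlasDatabase-class] from a warped population plus
#' (optionally) the unwarped base as an extra record. Members are unpaired
#' subjects with alternating sexes.
#'
#' @param members output of [warpPopulation()].
#' @param base optional base list (`qct`, `mask`, `fabricFun`) appended as
#'   record `"BASE"`.
#' @return an [AtlasDatabase-class].
#' @export
syntheticDatabase <- function(members, base = NULL) {
  ids <- vapply(members, `[[`, character(1), "id")
  images <- lapply(members, function(m)
    list(qct = m$qct, mask = m$mask, fabricFun = m$fabricFun,
         chain = m$chain))
  names(images) <- ids
  sex <- rep(c("M", "F"), length.out = length(ids))
  rec <- data.frame(id = ids, subject = ids,
                    side = rep("left", length(ids)), sex = sex)
  if (!is.null(base)) {
    rec <- rbind(rec, data.frame(id = "BASE", subject = "BASE",
                                 side = "left", sex = "M"))
    images$BASE <- list(qct = base$qct, mask = base$mask,
                        fabricFun = base$fabricFun)
  }
  AtlasDatabase(rec, images = images)
}
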