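# Bring one axis of a k-D array to the front, apply f on the unrolled
# matrix (rows = that axis), restore shape.
alongAxis <- function(A, ax, f) {
  d <- dim(A)
  perm <- c(ax, setdiff(seq_along(d), ax))
  B <- aperm(A, perm)
  db <- dim(B)
  dim(B) <- c(db[1], prod(db[-1]))
  B <- f(B)
  dim(B) <- db
  aperm(B, order(perm))
}

# Second difference along one axis, replicate (Neumann) boundary.
secondDiff <- function(A, ax, h) alongAxis(A, ax, function(B) {
  n <- nrow(B)
  (B[c(2:n, n), , drop = FALSE] + B[c(1, 1:(n - 1)), , drop = FALSE] -
     2 * B) / h^2
})

# Exact adjoint of secondDiff (for analytic penalty gradients).
secondDiffAdj <- function(R, ax, h) alongAxis(R, ax, function(B) {
  n <- nrow(B)
  out <- -2 * B
  out[2:n, ] <- out[2:n, ] + B[1:(n - 1), , drop = FALSE]
  out[n, ] <- out[n, ] + B[n, ]
  out[1:(n - 1), ] <- out[1:(n - 1), ] + B[2:n, , drop = FALSE]
  out[1, ] <- out[1, ] + B[1, ]
  out / h^2
})

discreteLaplacian <- function(A, h) {
  secondDiff(A, 1, h[1]) + secondDiff(A, 2, h[2]) + secondDiff(A, 3, h[3])
}

laplacianAdjoint <- function(R, h) {
  secondDiffAdj(R, 1, h[1]) + secondDiffAdj(R, 2, h[2]) +
    secondDiffAdj(R, 3, h[3])
}

#' Curvature regularization of a displacement field
#'
#' Sum over grid nodes and vector components of the squared discrete
#' Laplacian of the displacement, \eqn{\|\Delta u\|^2}, discretized with the
#' standard 7-point stencil and replicate (Neumann) boundary handling.
#' Affine displacement fields have zero curvature at interior nodes, so the
#' penalty does not oppose global alignment.
#'
#' @param disp 4-D array `nx x ny x nz x 3` of displacement vectors on a
#'   regular grid.
#' @param spacing grid spacing (length 1 or 3).
#' @return non-negative scalar.
#' @export
curvaturePenalty <- function(disp, spacing = c(1, 1, 1)) {
  d <- dim(disp)
  if (length(d) != 4 || d[4] != 3)
    fmStop("fmDimensionError", "disp must be an nx x ny x nz x 3 array")
  if (any(d[1:3] < 3))
    fmStop("fmSizeError", "grid smaller than the 7-point stencil")
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  L <- discreteLaplacian(disp, spacing)
  sum(L^2)
}

# penalty and its gradient with respect to the displacement values
curvaturePenaltyGrad <- function(disp, spacing) {
  L <- discreteLaplacian(disp, spacing)
  list(value = sum(L^2), grad = 2 * laplacianAdjoint(L, spacing))
}

#' Normalized correlation coefficient between images
#'
#' Similarity measure for mono-modal registration: the Pearson correlation
#' of the two intensity samples over the (masked) voxel lattice.
#'
#' @param fixed,moving two [BoneImage-class] on the same voxel lattice
#'   (the moving image already resampled).
#' @param mask optional binary [BoneImage-class] on the same lattice.
#' @return scalar in `[-1, 1]`.
#' @export
nccSimilarity <- function(fixed, moving, mask = NULL) {
  if (!identical(dim(fixed), dim(moving)) ||
      max(abs(fixed@spacing - moving@spacing)) > 1e-9 ||
      max(abs(fixed@origin - moving@origin)) > 1e-6)
    fmStop("fmLatticeError", "images must share one voxel lattice")
  f <- as.numeric(fixed@.Data)
  m <- as.numeric(moving@.Data)
  if (!is.null(mask)) {
    keep <- as.numeric(mask@.Data) > 0
    f <- f[keep]; m <- m[keep]
  }
  fc <- f - mean(f); mc <- m - mean(m)
  sff <- sum(fc^2); smm <- sum(mc^2)
  if (sff <= 0 || smm <= 0)
    fmStop("fmUndefinedCorrelationError",
           "zero intensity variance over the evaluation region")
  sum(fc * mc) / sqrt(sff * smm)
}

#' Registration parameter set
#'
#' @param gamma weight of the curvature regularization against the
#'   (negated) correlation similarity; dimensionless.
#' @param gridSpacing B-spline control grid spacing in mm; `NULL` picks
#'   one fifth of the smallest fixed-image extent.
#' @param levels number of multi-resolution levels (factor 2).
#' @param maxIter optimizer iterations per level, coarse to fine (recycled).
#' @param maxPoints cap on the number of sampled fixed voxels per level.
#' @param seed integer; registration is deterministic, the seed is recorded
#'   in provenance and used by any stochastic caller.
#' @return named list of class `registrationParams`.
#' @export
registrationParams <- function(gamma = 0.1, gridSpacing = NULL, levels = 3,
                               maxIter = c(60, 40, 30), maxPoints = 40000,
                               seed = 0L) {
  if (gamma < 0) fmStop("fmParameterError", "gamma must be >= 0")
  if (levels < 1) fmStop("fmParameterError", "levels must be >= 1")
  if (!is.null(gridSpacing) && gridSpacing <= 0)
    fmStop("fmParameterError", "gridSpacing must be positive")
  structure(list(gamma = gamma, gridSpacing = gridSpacing,
                 levels = as.integer(levels),
                 maxIter = rep_len(maxIter, levels),
                 maxPoints = as.integer(maxPoints), seed = as.integer(seed)),
            class = "registrationParams")
}

# central-difference gradient volumes of an image (replicate boundary)
imageGradient <- function(img) {
  h <- img@spacing
  g <- lapply(1:3, function(ax) alongAxis(img@.Data, ax, function(B) {
    n <- nrow(B)
    (B[c(2:n, n), , drop = FALSE] - B[c(1, 1:(n - 1)), , drop = FALSE]) /
      (2 * h[ax])
  }))
  lapply(g, function(v) BoneImage(array(v, dim(img)), spacing = img@spacing,
                                  origin = img@origin))
}

# -NCC and d(-NCC)/dm for a sample pair (fc precentered fixed values)
nccCostGrad <- function(fc, sff, m) {
  mc <- m - mean(m)
  smm <- sum(mc^2)
  if (smm <= 0 || sff <= 0)
    return(list(cost = 0, q = rep(0, length(m)), ncc = 0))
  sfm <- sum(fc * mc)
  ncc <- sfm / sqrt(sff * smm)
  dm <- (fc - (sfm / smm) * mc) / sqrt(sff * smm)
  list(cost = -ncc, q = -dm, ncc = ncc)
}

samplePointsOf <- function(img, mask, maxPoints) {
  pts <- voxelCenters(img)
  if (!is.null(mask)) {
    keep <- sampleImage(mask, pts, interp = "nearest", fill = 0) > 0
    if (any(keep)) pts <- pts[keep, , drop = FALSE]
  }
  n <- nrow(pts)
  if (n > maxPoints) pts <- pts[seq(1, n, length.out = maxPoints), ,
                                drop = FALSE]
  pts
}

#' Two-stage intensity-based registration
#'
#' Registers `moving` to `fixed` by minimizing
#' \eqn{C = -C_{similarity} + \gamma\, C_{smooth}} (normalized correlation
#' plus curvature regularization of the B-spline coefficients) over a
#' composed transform `T(x) = T_B(T_A(x))`: first a 12-parameter affine
#' stage, then a cubic B-spline free-form deformation, both optimized with
#' analytic gradients (BFGS / L-BFGS-B) in a multi-resolution pyramid.
#' Deterministic for fixed inputs and parameters.
#'
#' @param fixed,moving [BoneImage-class] volumes with overlapping physical
#'   domains.
#' @param params a [registrationParams()] list.
#' @param fixedMask optional binary [BoneImage-class]; the similarity is
#'   evaluated only at fixed voxels inside the mask.
#' @return a [RegistrationResult-class]; use [transformChain()] to extract
#'   the recovered chain.
#' @export
registerPair <- function(fixed, moving, params = registrationParams(),
                         fixedMask = NULL) {
  stopifnot(is(fixed, "BoneImage"), is(moving, "BoneImage"))
  fixedN <- normalizeIntensity(fixed)
  movingN <- normalizeIntensity(moving)

  # image pyramid, coarse (level `levels`) to fine (level 1)
  pyrF <- list(fixedN); pyrM <- list(movingN)
  for (l in seq_len(params$levels - 1)) {
    pyrF[[l + 1]] <- downsampleImage(pyrF[[l]])
    pyrM[[l + 1]] <- downsampleImage(pyrM[[l]])
  }
  costTrace <- list()

  # ---- affine stage -------------------------------------------------------
  p <- c(as.vector(diag(3)), c(0, 0, 0))
  for (l in params$levels:1) {
    fl <- pyrF[[l]]; ml <- pyrM[[l]]
    grads <- imageGradient(ml)
    pts <- samplePointsOf(fl, fixedMask, params$maxPoints)
    f <- sampleImage(fl, pts)
    fc <- f - mean(f); sff <- sum(fc^2)
    trace <- numeric(0)
    fn <- function(p) {
      A <- matrix(p[1:9], 3, 3)
      y <- pts %*% t(A) + matrix(p[10:12], nrow(pts), 3, byrow = TRUE)
      m <- sampleImage(ml, y)
      out <- nccCostGrad(fc, sff, m)
      trace <<- c(trace, out$cost)
      out$cost
    }
    gr <- function(p) {
      A <- matrix(p[1:9], 3, 3)
      y <- pts %*% t(A) + matrix(p[10:12], nrow(pts), 3, byrow = TRUE)
      m <- sampleImage(ml, y)
      g <- cbind(sampleImage(grads[[1]], y), sampleImage(grads[[2]], y),
                 sampleImage(grads[[3]], y))
      out <- nccCostGrad(fc, sff, m)
      qg <- g * out$q
      gA <- t(qg) %*% pts            # [j, k] = sum q g_j x_k
      c(as.vector(gA), colSums(qg))
    }
    iterMax <- params$maxIter[params$levels - l + 1]
    if (l == params$levels) {
      # exhaustive translation pre-search on the coarsest level: NCC of
      # fine-grained texture has a narrow capture range, so gradient
      # descent alone can miss large offsets
      stepT <- fl@spacing / 2
      r <- 0.3 * imageExtent(fl)
      offs <- lapply(1:3, function(a)
        (-floor(r[a] / stepT[a]):floor(r[a] / stepT[a])) * stepT[a])
      best <- p; bestCost <- fn(p)
      for (tz in offs[[3]]) for (ty in offs[[2]]) for (tx in offs[[1]]) {
        cand <- p; cand[10:12] <- p[10:12] + c(tx, ty, tz)
        cc <- fn(cand)
        if (cc < bestCost) { bestCost <- cc; best <- cand }
      }
      p <- best
    }
    c0 <- fn(p)
    opt <- optim(p, fn, gr, method = "BFGS",
                 control = list(maxit = iterMax, reltol = 1e-9,
                                parscale = c(rep(0.05, 9), rep(1, 3))))
    if (opt$value > c0 + 1e-12)
      fmStop("fmConvergenceError",
             "affine cost increased over level %d (%.6g -> %.6g)",
             l, c0, opt$value)
    p <- opt$par
    costTrace[[paste0("affine_level", l)]] <- trace
  }
  A <- matrix(p[1:9], 3, 3)
  trans <- p[10:12]
  if (det(A) <= 0)
    fmStop("fmFoldingError", "affine stage produced det <= 0")

  # ---- B-spline stage -----------------------------------------------------
  gs <- params$gridSpacing
  if (is.null(gs)) gs <- min(imageExtent(fixed)) / 5
  corners <- as.matrix(expand.grid(
    fixed@origin[1] + c(0, (dim(fixed)[1] - 1) * fixed@spacing[1]),
    fixed@origin[2] + c(0, (dim(fixed)[2] - 1) * fixed@spacing[2]),
    fixed@origin[3] + c(0, (dim(fixed)[3] - 1) * fixed@spacing[3])))
  yc <- corners %*% t(A) + matrix(trans, 8, 3, byrow = TRUE)
  grid <- bsplineGridFor(apply(yc, 2, min), apply(yc, 2, max), gs)
  ncoef <- prod(grid$dims)
  coef <- rep(0, ncoef * 3)

  for (l in params$levels:1) {
    fl <- pyrF[[l]]; ml <- pyrM[[l]]
    grads <- imageGradient(ml)
    pts <- samplePointsOf(fl, fixedMask, params$maxPoints)
    y <- pts %*% t(A) + matrix(trans, nrow(pts), 3, byrow = TRUE)
    f <- sampleImage(fl, pts)
    fc <- f - mean(f); sff <- sum(fc^2)
    trace <- numeric(0)
    evalCost <- function(cf, withGrad) {
      cfm <- matrix(cf, ncoef, 3)
      u <- cpp_bspline_disp(y, grid$origin, grid$spacing, grid$dims, cfm)
      z <- y + u
      m <- sampleImage(ml, z)
      out <- nccCostGrad(fc, sff, m)
      arr <- array(cf, c(grid$dims, 3))
      pen <- curvaturePenaltyGrad(arr, grid$spacing)
      cost <- out$cost + params$gamma * pen$value
      if (!withGrad) return(cost)
      g <- cbind(sampleImage(grads[[1]], z), sampleImage(grads[[2]], z),
                 sampleImage(grads[[3]], z))
      gc <- cpp_bspline_scatter(y, g * out$q, grid$origin, grid$spacing,
                                grid$dims)
      list(cost = cost, grad = as.vector(gc) +
             params$gamma * as.vector(pen$grad))
    }
    fn <- function(cf) {
      v <- evalCost(cf, FALSE); trace <<- c(trace, v); v
    }
    gr <- function(cf) evalCost(cf, TRUE)$grad
    iterMax <- params$maxIter[params$levels - l + 1]
    c0 <- fn(coef)
    opt <- optim(coef, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = iterMax, factr = 1e5))
    if (opt$value > c0 + 1e-12)
      fmStop("fmConvergenceError",
             "B-spline cost increased over level %d (%.6g -> %.6g)",
             l, c0, opt$value)
    coef <- opt$par
    costTrace[[paste0("bspline_level", l)]] <- trace
  }

  chain <- TransformChain(affine = A, translation = trans,
                          bsplineOrigin = grid$origin,
                          bsplineSpacing = grid$spacing,
                          bsplineDims = grid$dims,
                          bsplineCoef = matrix(coef, ncoef, 3))

  # QC: folding probe + final similarity on the finest level
  probe <- controlGrid(fixed, spacing = gs)
  dets <- vapply(chainGradients(chain, probe), det, numeric(1))
  folding <- any(dets <= 0)
  if (folding)
    fmWarn("fmFoldingWarning",
           "det F <= 0 at %d of %d probe points", sum(dets <= 0),
           length(dets))
  warped <- applyTransform(movingN, fixedN, chain)
  finalNCC <- nccSimilarity(fixedN, warped, mask = fixedMask)

  new("RegistrationResult", chain = chain, costTrace = costTrace,
      finalNCC = finalNCC, foldingWarning = folding,
      params = unclass(params))
}

#' Dice overlap quality control
#'
#' Transforms the moving mask with the recovered chain, resamples it to the
#' fixed lattice by nearest-neighbour interpolation, and reports
#' `Dice = 2|A n B| / (|A| + |B|)`.
#'
#' @param fixedMask,movingMask binary [BoneImage-class] masks.
#' @param chain a [TransformChain-class] (fixed -> moving).
#' @return scalar in `[0, 1]`.
#' @export
diceQC <- function(fixedMask, movingMask, chain) {
  warped <- applyTransform(movingMask, fixedMask, chain,
                           interp = "nearest", fill = 0)
  a <- fixedMask@.Data > 0
  b <- warped@.Data > 0
  if (!any(a) && !any(b))
    fmStop("fmUndefinedDiceError", "both masks are empty")
  2 * sum(a & b) / (sum(a) + sum(b))
}
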