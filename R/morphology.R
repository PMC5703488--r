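maskCoords <- function(mask) {
  idx <- which(mask@.Data > 0)
  d <- dim(mask)
  i <- (idx - 1) %% d[1]
  j <- ((idx - 1) %/% d[1]) %% d[2]
  k <- (idx - 1) %/% (d[1] * d[2])
  cbind(mask@origin[1] + i * mask@spacing[1],
        mask@origin[2] + j * mask@spacing[2],
        mask@origin[3] + k * mask@spacing[3])
}

#' Femoral head center and radius
#'
#' Finds the femoral head as the quasi-spherical region of the mask: the
#' maximum of the Euclidean distance transform locates the largest inscribed
#' sphere (the head, in a proximal femur mask), the center is refined as the
#' mass center of the spherical region, and the radius is taken from the
#' maximal cross-section area of that region. A mask whose near-maximal
#' distance ridge is elongated (a shaft-only cylinder) is rejected.
#'
#' @param mask binary [BoneImage-class] femur mask.
#' @return list with `center` (mm) and `radius` (mm).
#' @export
headCenter <- function(mask) {
  edt <- distanceTransform(mask)
  r0 <- max(edt@.Data, na.rm = TRUE)
  if (!is.finite(r0) || r0 <= 2 * max(mask@spacing))
    fmStop("fmDetectionError", "no spherical region detected")
  ridge <- maskCoords(BoneImage(array(
    as.numeric(edt@.Data >= 0.9 * r0 & !is.na(edt@.Data)), dim(mask)),
    spacing = mask@spacing, origin = mask@origin))
  ctr <- colMeans(ridge)
  spreadR <- sqrt(max(rowSums((ridge - matrix(ctr, nrow(ridge), 3,
                                              byrow = TRUE))^2)))
  if (spreadR > 1.5 * r0)
    fmStop("fmDetectionError",
           "distance ridge is elongated (%.3g mm vs radius %.3g mm): no head-like sphere",
           spreadR, r0)
  # refine on the spherical region
  co <- maskCoords(mask)
  dc <- sqrt(rowSums((co - matrix(ctr, nrow(co), 3, byrow = TRUE))^2))
  region <- co[dc <= 1.15 * r0, , drop = FALSE]
  center <- colMeans(co[dc <= 1.02 * r0, , drop = FALSE])
  # maximal cross-section area over z-slices of the spherical region
  zs <- round((region[, 3] - mask@origin[3]) / mask@spacing[3])
  areas <- table(zs) * mask@spacing[1] * mask@spacing[2]
  radius <- sqrt(max(areas) / pi)
  list(center = center, radius = radius)
}

# cross-section area (mm^2) of the mask in the plane through p with normal d,
# restricted to a disc of radius rmax; triangle-kernel slab weighting makes
# the objective smooth enough for a derivative-free optimizer
neckSectionArea <- function(co, p, d, rmax, slab) {
  rel <- co - matrix(p, nrow(co), 3, byrow = TRUE)
  t <- rel %*% d
  w <- pmax(0, 1 - abs(t) / slab)
  inPlane2 <- rowSums(rel^2) - t^2
  sum(w[inPlane2 <= rmax^2])
}

#' Femoral neck center and axis
#'
#' Enlarges the head sphere by 25% and takes the mask centroid in that
#' shell as the initial neck center. The axis direction is refined by
#' centroid iteration on the locally cylindrical neck segment, and the neck
#' center is then located by derivative-free minimization of the neck
#' cross-section area along the axis. The neck axis is the line from the
#' head center through the refined neck center.
#'
#' @param mask binary femur mask.
#' @param head output of [headCenter()].
#' @return list with `center` (mm) and unit `axis` (head -> neck).
#' @export
neckAxis <- function(mask, head) {
  co <- maskCoords(mask)
  c0 <- head$center; r <- head$radius
  dc <- sqrt(rowSums((co - matrix(c0, nrow(co), 3, byrow = TRUE))^2))
  shell <- co[dc >= 1.2 * r & dc <= 1.3 * r, , drop = FALSE]
  if (nrow(shell) < 10)
    fmStop("fmConvergenceError", "no mask voxels in the enlarged head shell")
  d0 <- colMeans(shell) - c0
  d0 <- d0 / sqrt(sum(d0^2))
  near <- co[dc <= 3 * r, , drop = FALSE]
  rel <- near - matrix(c0, nrow(near), 3, byrow = TRUE)
  # refine the axis direction: the neck is locally cylindrical, so the
  # centroid of the neck segment lies on its axis; iterate to convergence
  d <- d0
  for (it in 1:8) {
    t <- as.numeric(rel %*% d)
    rad2 <- rowSums(rel^2) - t^2
    sel <- t > 1.1 * r & t < 2.1 * r & rad2 < r^2
    if (sum(sel) < 10)
      fmStop("fmConvergenceError", "neck segment empty during refinement")
    cN <- colMeans(near[sel, , drop = FALSE])
    dNew <- cN - c0
    dNew <- dNew / sqrt(sum(dNew^2))
    if (sum(dNew * d) > 1 - 1e-8) { d <- dNew; break }
    d <- dNew
  }
  # derivative-free 1-D minimization of the section area along the axis
  slab <- max(mask@spacing)
  opt <- stats::optimize(function(t)
    neckSectionArea(near, c0 + t * d, d, rmax = r, slab = slab),
    interval = c(1.05 * r, 2.2 * r), tol = 1e-3 * r)
  if (!is.finite(opt$objective) || opt$objective <= 0)
    fmStop("fmConvergenceError", "neck refinement did not converge")
  center <- c0 + opt$minimum * d
  list(center = center, axis = d)
}

# last in-mask point marching from the head center along the neck axis
neckAxisEndPoint <- function(mask, head, neck) {
  step <- min(mask@spacing) / 2
  tmax <- 12 * head$radius
  ts <- seq(0, tmax, by = step)
  pts <- matrix(head$center, length(ts), 3, byrow = TRUE) +
    outer(ts, neck$axis)
  inside <- sampleImage(mask, pts, "nearest", fill = 0) > 0
  last <- max(which(inside))
  pts[last, ]
}

#' Femoral shaft axis by robust line fitting
#'
#' Computes mass centers of mask slices distal to the neck-axis-end-point
#' and fits a line by random-sample consensus (RANSAC): pairs of slice
#' centers propose lines, inliers are counted within a distance threshold,
#' and the best consensus set is refit by least squares (principal
#' component). Deterministic under a fixed seed.
#'
#' @param mask binary femur mask.
#' @param endPoint the neck-axis-end-point (mm), see [femurLandmarks()].
#' @param threshold RANSAC inlier distance (mm).
#' @param iterations RANSAC iterations.
#' @param seed integer seed.
#' @return list with `point`, unit `direction` (proximal -> distal) and
#'   `distalPoint` (mm).
#' @export
shaftAxis <- function(mask, endPoint, threshold = 1.5, iterations = 500,
                      seed = 1L) {
  co <- maskCoords(mask)
  ctr <- colMeans(co)
  pc1 <- eigen(cov(co), symmetric = TRUE)$vectors[, 1]
  if (sum(pc1 * (ctr - endPoint)) < 0) pc1 <- -pc1   # orient distal
  ax <- which.max(abs(pc1))
  sgn <- sign(pc1[ax])
  coord <- co[, ax]
  cut <- endPoint[ax]
  distal <- if (sgn > 0) coord > cut else coord < cut
  if (!any(distal)) fmStop("fmDataError", "no slices distal to the neck end")
  cod <- co[distal, , drop = FALSE]
  sliceIdx <- round((cod[, ax] - mask@origin[ax]) / mask@spacing[ax])
  centers <- do.call(rbind, lapply(split(seq_len(nrow(cod)), sliceIdx),
                                   function(ii) colMeans(cod[ii, ,
                                                             drop = FALSE])))
  if (nrow(centers) < 3)
    fmStop("fmDataError", "fewer than 3 distal slices for the shaft fit")
  withSeed(seed, {
    best <- NULL; bestN <- -1
    for (it in seq_len(iterations)) {
      s <- sample(nrow(centers), 2)
      d <- centers[s[2], ] - centers[s[1], ]
      len <- sqrt(sum(d^2))
      if (len < 1e-9) next
      d <- d / len
      rel <- centers - matrix(centers[s[1], ], nrow(centers), 3,
                              byrow = TRUE)
      t <- rel %*% d
      dist <- sqrt(pmax(rowSums(rel^2) - t^2, 0))
      inl <- dist < threshold
      if (sum(inl) > bestN) { bestN <- sum(inl); best <- inl }
    }
    inlC <- centers[best, , drop = FALSE]
    point <- colMeans(inlC)
    dir <- eigen(cov(inlC), symmetric = TRUE)$vectors[, 1]
    if (sum(dir * pc1) < 0) dir <- -dir
    t <- (inlC - matrix(point, nrow(inlC), 3, byrow = TRUE)) %*% dir
    distalPoint <- point + max(t) * dir
    list(point = point, direction = dir, distalPoint = distalPoint)
  })
}

# closest-approach midpoint of two lines (p1 + s d1, p2 + t d2)
lineMidPoint <- function(p1, d1, p2, d2) {
  w <- p1 - p2
  a <- sum(d1 * d1); b <- sum(d1 * d2); c3 <- sum(d2 * d2)
  d <- sum(d1 * w); e <- sum(d2 * w)
  den <- a * c3 - b * b
  if (abs(den) < 1e-12) { s <- 0; t <- e / c3 }
  else { s <- (b * e - c3 * d) / den; t <- (a * e - b * d) / den }
  (p1 + s * d1 + p2 + t * d2) / 2
}

#' Caput-collum-diaphyseal (CCD) angle
#'
#' Angle in degrees at the mid point between the neck axis (pointing toward
#' the femoral head) and the shaft axis (pointing distally).
#'
#' @param landmarks a [FemurLandmarks-class] or a list with `neckAxis`
#'   (head -> neck) and `shaftAxis` (proximal -> distal) unit vectors.
#' @return angle in degrees.
#' @export
ccdAngle <- function(landmarks) {
  nd <- if (is(landmarks, "FemurLandmarks")) landmarks@neckAxis
        else landmarks$neckAxis
  sd <- if (is(landmarks, "FemurLandmarks")) landmarks@shaftAxis
        else landmarks$shaftAxis
  towardHead <- -nd / sqrt(sum(nd^2))
  distal <- sd / sqrt(sum(sd^2))
  acos(max(-1, min(1, sum(towardHead * distal)))) * 180 / pi
}

#' Extract all femur landmarks
#'
#' Orchestrates [headCenter()], [neckAxis()], the neck-axis-end-point,
#' [shaftAxis()] and the implicit coordinate system (mid point, CCD angle).
#'
#' @param mask binary femur mask.
#' @param seed seed for the RANSAC shaft fit.
#' @return a [FemurLandmarks-class].
#' @export
femurLandmarks <- function(mask, seed = 1L) {
  head <- headCenter(mask)
  neck <- neckAxis(mask, head)
  endPoint <- neckAxisEndPoint(mask, head, neck)
  shaft <- shaftAxis(mask, endPoint, seed = seed)
  mid <- lineMidPoint(head$center, neck$axis, shaft$point, shaft$direction)
  lm <- new("FemurLandmarks", headCenter = head$center,
            headRadius = head$radius, neckCenter = neck$center,
            neckAxis = neck$axis, neckAxisEndPoint = endPoint,
            shaftPoint = shaft$point, shaftAxis = shaft$direction,
            shaftDistalPoint = shaft$distalPoint, midPoint = mid,
            ccd = 0)
  lm@ccd <- ccdAngle(lm)
  lm
}

#' Standardize the femoral shaft length
#'
#' Crops the distal shaft so that the ratio between the head-center to
#' mid-point distance and the mid-point to shaft-axis-distal-point distance
#' equals `ratio` (default 0.7), then recenters the image at the mid point
#' (origin translated so that the mid point is at 0). Cropping never removes
#' voxels proximal to the mid point.
#'
#' @param image grayscale [BoneImage-class].
#' @param mask matching binary mask.
#' @param landmarks a [FemurLandmarks-class].
#' @param ratio target distance ratio.
#' @return list with `image`, `mask`, `achievedRatio`.
#' @export
standardizeShaft <- function(image, mask, landmarks, ratio = 0.7) {
  d1 <- sqrt(sum((landmarks@headCenter - landmarks@midPoint)^2))
  dir <- landmarks@shaftAxis
  tDistal <- sum((landmarks@shaftDistalPoint - landmarks@midPoint) * dir)
  tNeed <- d1 / ratio
  if (tDistal < tNeed - 1e-9)
    fmStop("fmLengthError",
           "shaft too short: has %.3g mm distal of the mid point, needs %.3g",
           tDistal, tNeed)
  ax <- which.max(abs(dir))
  sgn <- sign(dir[ax])
  cutPoint <- landmarks@midPoint + tNeed * dir
  d <- dim(image)
  idxCoord <- image@origin[ax] + (seq_len(d[ax]) - 1) * image@spacing[ax]
  keep <- if (sgn > 0) idxCoord <= cutPoint[ax] + image@spacing[ax] / 2
          else idxCoord >= cutPoint[ax] - image@spacing[ax] / 2
  sel <- which(keep)
  crop <- function(img) {
    a <- img@.Data
    a <- switch(ax, a[sel, , , drop = FALSE], a[, sel, , drop = FALSE],
                a[, , sel, drop = FALSE])
    o <- img@origin
    o[ax] <- o[ax] + (min(sel) - 1) * img@spacing[ax]
    BoneImage(a, spacing = img@spacing, origin = o - landmarks@midPoint)
  }
  outImg <- crop(image)
  outMask <- crop(mask)
  lastCoord <- idxCoord[if (sgn > 0) max(sel) else min(sel)]
  tAchieved <- (lastCoord - landmarks@midPoint[ax]) / dir[ax]
  list(image = outImg, mask = outMask, achievedRatio = d1 / tAchieved)
}

#' Write / read femur landmarks as JSON
#'
#' @param landmarks a [FemurLandmarks-class].
#' @param path JSON path (mm coordinates).
#' @export
writeLandmarks <- function(landmarks, path) {
  l <- list(headCenter = landmarks@headCenter,
            headRadius = landmarks@headRadius,
            neckCenter = landmarks@neckCenter,
            neckAxis = landmarks@neckAxis,
            neckAxisEndPoint = landmarks@neckAxisEndPoint,
            shaftPoint = landmarks@shaftPoint,
            shaftAxis = landmarks@shaftAxis,
            shaftDistalPoint = landmarks@shaftDistalPoint,
            midPoint = landmarks@midPoint, ccd = landmarks@ccd)
  jsonlite::write_json(l, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeLandmarks
#' @export
readLandmarks <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("FemurLandmarks", headCenter = l$headCenter,
      headRadius = l$headRadius, neckCenter = l$neckCenter,
      neckAxis = l$neckAxis, neckAxisEndPoint = l$neckAxisEndPoint,
      shaftPoint = l$shaftPoint, shaftAxis = l$shaftAxis,
      shaftDistalPoint = l$shaftDistalPoint, midPoint = l$midPoint,
      ccd = l$ccd)
}
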