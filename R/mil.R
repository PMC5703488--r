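#' Hemisphere test directions from a subdivided icosahedron
#'
#' MIL test directions are the vertices of a recursively subdivided
#' icosahedron projected onto the unit sphere, restricted to one hemisphere
#' (fabric is axial, so antipodal directions are redundant). Subdivision
#' levels 0..3 give 6, 21, 81 and 321 hemisphere directions.
#'
#' @param n requested minimum number of directions; the smallest subdivision
#'   level reaching `n` is used (all its directions are returned).
#' @return K x 3 matrix of unit vectors, `K >= n`.
#' @export
milDirections <- function(n = 321) {
  for (level in 0:6) {
    dirs <- icoHemisphere(level)
    if (nrow(dirs) >= n) return(dirs)
  }
  dirs
}

icoHemisphere <- function(level) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7),
             c(8, 2, 9), c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9),
             c(4, 9, 10), c(5, 10, 6), c(3, 5, 12), c(7, 3, 11),
             c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(level)) {
    nv <- nrow(v)
    edgeKey <- new.env()
    mid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- edgeKey[[key]]
      if (!is.null(idx)) return(idx)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      edgeKey[[key]] <- nrow(v)
      nrow(v)
    }
    fnew <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c3 <- f[t, 3]
      ab <- mid(a, b); bc <- mid(b, c3); ca <- mid(c3, a)
      fnew <- rbind(fnew, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc),
                    c(ab, bc, ca))
    }
    f <- fnew
  }
  tol <- 1e-9
  keep <- v[, 3] > tol |
    (abs(v[, 3]) <= tol & (v[, 2] > tol |
                             (abs(v[, 2]) <= tol & v[, 1] > tol)))
  unname(v[keep, , drop = FALSE])
}

#' Laplace-Hamming sharpening filter
#'
#' Frequency-domain sharpening used before segmenting trabecular structure:
#' the spectrum is multiplied by a Laplacian-of-identity response
#' `1 + alpha * |k|^2` (with `|k|^2` normalized to `[0, 1]` at the Nyquist
#' corner) windowed by a separable Hamming window cut off at
#' `cutoff x` Nyquist per axis; the filtered volume is then min-max
#' normalized to `[0, 1]`.
#'
#' @param img a [BoneImage-class] (all three dimensions > 1).
#' @param alpha sharpening strength (default 1).
#' @param cutoff Hamming cutoff as a fraction of Nyquist (default 0.9).
#' @return filtered, `[0, 1]`-normalized [BoneImage-class].
#' @export
laplaceHamming <- function(img, alpha = 1, cutoff = 0.9) {
  d <- dim(img)
  if (any(d < 2))
    fmStop("fmDimensionError",
           "Laplace-Hamming needs a true 3-D volume, got %s",
           paste(d, collapse = "x"))
  freqAxis <- function(n) {
    k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]
    abs(k) / n                       # cycles/sample in [0, 0.5]
  }
  fx <- freqAxis(d[1]); fy <- freqAxis(d[2]); fz <- freqAxis(d[3])
  hamming <- function(f) ifelse(f <= cutoff * 0.5,
                                0.54 + 0.46 * cos(pi * f / (cutoff * 0.5)),
                                0)
  r2 <- (outer(outer(fx^2, fy^2, `+`), fz^2, `+`)) / (3 * 0.25)
  H <- (1 + alpha * r2) *
    outer(outer(hamming(fx), hamming(fy)), hamming(fz))
  out <- Re(fft(fft(img@.Data) * H, inverse = TRUE)) / prod(d)
  rng <- range(out)
  # structureless volumes map to zero (guard against FFT rounding noise)
  out <- if (rng[2] - rng[1] > 1e-9 * max(1, max(abs(out))))
    (out - rng[1]) / (rng[2] - rng[1]) else out * 0
  BoneImage(out, spacing = img@spacing, origin = img@origin,
            direction = img@direction)
}

#' Threshold segmentation into bone and marrow
#'
#' @param img a `[0, 1]`-normalized [BoneImage-class].
#' @param threshold scalar in `[0, 1]`; voxels `>= threshold` become bone.
#' @return binary [BoneImage-class] (1 = bone, 0 = marrow).
#' @export
segmentBone <- function(img, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1)
    fmStop("fmParameterError", "threshold must be a scalar in [0, 1]")
  BoneImage(array(as.numeric(img@.Data >= threshold), dim(img)),
            spacing = img@spacing, origin = img@origin,
            direction = img@direction)
}

#' Cubic volume of interest
#'
#' A cubic crop of a binary image used for MIL analysis, with its bone
#' volume fraction.
#'
#' @slot voxels binary 3-D array (cubic).
#' @slot spacing isotropic voxel spacing (mm).
#' @slot side physical side length (mm).
#' @slot bvtv bone volume fraction of the crop.
#' @export
setClass("BinaryVOI",
  representation(voxels = "array", spacing = "numeric", side = "numeric",
                 bvtv = "numeric"))

setValidity("BinaryVOI", function(object) {
  d <- dim(object@voxels)
  if (length(unique(d)) != 1) return("VOI must be cubic")
  if (abs(object@bvtv - mean(object@voxels != 0)) > 1e-12)
    return("bvtv must equal mean(voxels)")
  TRUE
})

setMethod("show", "BinaryVOI", function(object) {
  cat(sprintf("BinaryVOI %d^3 voxels, side %.3g mm, BV/TV %.3f\n",
              dim(object@voxels)[1], object@side, object@bvtv))
})

#' Extract a cubic VOI around a control point
#'
#' Crops a cube of side `side` mm (default 5.3) centered at a physical
#' point from a segmented image. The crop must lie fully inside the image
#' (and inside `mask`, when given); otherwise the point must be skipped by
#' the caller.
#'
#' @param img binary [BoneImage-class] with isotropic spacing.
#' @param center physical center (mm), length 3.
#' @param side cube side length in mm.
#' @param mask optional binary [BoneImage-class]; the VOI center must fall
#'   inside it.
#' @return a [BinaryVOI-class].
#' @export
extractVOI <- function(img, center, side = 5.3, mask = NULL) {
  sp <- img@spacing
  if (max(abs(sp - sp[1])) > 1e-9)
    fmStop("fmParameterError", "extractVOI requires isotropic spacing")
  sp <- sp[1]
  nvox <- max(1L, round(side / sp))
  ctrIdx <- round((as.numeric(center) - img@origin) / sp) + 1
  half <- floor(nvox / 2)
  lo <- ctrIdx - half
  hi <- lo + nvox - 1
  if (any(lo < 1) || any(hi > dim(img)))
    fmStop("fmOutOfBoundsError",
           "VOI of %d voxels at (%s) exceeds image bounds", nvox,
           paste(signif(center, 4), collapse = ", "))
  if (!is.null(mask) &&
      sampleImage(mask, matrix(center, 1, 3), "nearest", fill = 0) == 0)
    fmStop("fmOutOfBoundsError", "VOI center outside the trabecular mask")
  crop <- img@.Data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  crop <- array(as.numeric(crop != 0), rep(nvox, 3))
  new("BinaryVOI", voxels = crop, spacing = sp, side = nvox * sp,
      bvtv = mean(crop))
}

#' MIL fabric tensor of a binary VOI
#'
#' Classical mean-intercept-length stereology: for each test direction a
#' parallel grid of lines is cast through the VOI; marrow-to-bone interface
#' crossings `I(w)` are counted and the in-bone line length `L(w)`
#' accumulated, giving `MIL(w) = 2 L(w) / I(w)`. The directional
#' distribution is fitted by the MIL ellipsoid
#' `1/MIL^2(w) = w' H w` by least squares over the six unique components
#' of `H`; fabric eigenvalues are `m_i = 1/sqrt(h_i)` with the eigenvectors
#' of `H`, and the tensor is normalized to trace 3.
#'
#' @param voi a [BinaryVOI-class] containing both phases.
#' @param nDirections minimum number of hemisphere test directions
#'   (see [milDirections()]).
#' @param lineSpacing in-plane distance between parallel test lines (mm);
#'   default twice the voxel spacing.
#' @param step sampling step along each line (mm); default half the voxel
#'   spacing.
#' @param directions optional explicit K x 3 matrix of unit test directions
#'   (overrides `nDirections`); directions are axial, the sign is
#'   irrelevant.
#' @param details if `TRUE` return a list with the per-direction samples.
#' @return a trace-3 [FabricTensor-class], or (with `details`) a list with
#'   elements `tensor` and `samples` (data.frame of direction, mil,
#'   intercepts, length).
#' @export
milTensor <- function(voi, nDirections = 321, lineSpacing = NULL,
                      step = NULL, directions = NULL, details = FALSE) {
  b <- mean(voi@voxels != 0)
  if (b <= 0 || b >= 1)
    fmStop("fmParameterError",
           "VOI must contain both bone and marrow (BV/TV = %.3g)", b)
  if (is.null(lineSpacing)) lineSpacing <- 2 * voi@spacing
  if (is.null(step)) step <- voi@spacing / 2
  dirs <- if (is.null(directions)) milDirections(nDirections)
          else matrix(as.numeric(directions), ncol = 3)
  res <- cpp_mil(as.integer(voi@voxels != 0), dim(voi@voxels),
                 rep(voi@spacing, 3), dirs, lineSpacing, step)
  usable <- res[, 2] > 0
  if (any(!usable))
    fmWarn("fmZeroInterceptWarning",
           "%d of %d directions had no intercepts and were dropped",
           sum(!usable), nrow(dirs))
  if (sum(usable) < 6)
    fmStop("fmRankError", "fewer than 6 usable MIL directions")
  dirs <- dirs[usable, , drop = FALSE]
  mil <- 2 * res[usable, 1] / res[usable, 2]
  # least squares for H: 1/MIL^2 = w' H w
  X <- cbind(dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
             2 * dirs[, 1] * dirs[, 2], 2 * dirs[, 1] * dirs[, 3],
             2 * dirs[, 2] * dirs[, 3])
  h <- qr.solve(X, 1 / mil^2)
  H <- matrix(c(h[1], h[4], h[5],
                h[4], h[2], h[6],
                h[5], h[6], h[3]), 3, 3)
  e <- eigen(H, symmetric = TRUE)
  if (max(e$values) <= 0)
    fmStop("fmFitError", "MIL ellipsoid fit is not positive-definite")
  # Structures with unbounded intercept-free runs (ideal parallel rods) push
  # the polar 1/MIL^2 eigenvalue to zero and sampling noise can take the
  # unconstrained least-squares estimate slightly negative. Eigenvalues are
  # floored at 1% of the largest, capping the measurable degree of
  # anisotropy at 10 -- far above trabecular bone.
  if (min(e$values) <= 0.01 * max(e$values))
    fmWarn("fmFitClippedWarning",
           "MIL ellipsoid eigenvalues floored at 1%% of the maximum")
  vals <- pmax(e$values, 0.01 * max(e$values))
  m <- 1 / sqrt(vals)
  M <- e$vectors %*% (m * t(e$vectors))
  tensor <- normalizeTrace(M)
  if (!details) return(tensor)
  list(tensor = tensor,
       samples = data.frame(wx = dirs[, 1], wy = dirs[, 2], wz = dirs[, 3],
                            mil = mil, intercepts = res[usable, 2],
                            boneLength = res[usable, 1]))
}

#' Extract a fabric field from a high-resolution image
#'
#' Full extraction pipeline at a set of control points: Laplace-Hamming
#' sharpening, threshold segmentation, VOI extraction and MIL tensor fit.
#' Control points whose VOI leaves the image or mask are flagged and
#' skipped.
#'
#' @param img high-resolution grayscale [BoneImage-class], or an already
#'   binary image if `segmented = TRUE`.
#' @param points N x 3 matrix of control points (mm).
#' @param mask optional trabecular mask.
#' @param side VOI side length (mm).
#' @param threshold segmentation threshold on the normalized filtered image.
#' @param nDirections MIL directions, see [milTensor()].
#' @param segmented set `TRUE` when `img` is already binary.
#' @return a [FabricField-class].
#' @export
extractFabric <- function(img, points, mask = NULL, side = 5.3,
                          threshold = 0.5, nDirections = 129,
                          segmented = FALSE) {
  seg <- if (segmented) img else segmentBone(laplaceHamming(img), threshold)
  points <- matrix(as.numeric(points), ncol = 3)
  n <- nrow(points)
  tensors <- vector("list", n)
  bvtv <- rep(NA_real_, n)
  flagged <- rep(FALSE, n)
  for (i in seq_len(n)) {
    ok <- tryCatch({
      voi <- extractVOI(seg, points[i, ], side = side, mask = mask)
      tensors[[i]] <- milTensor(voi, nDirections = nDirections)
      bvtv[i] <- voi@bvtv
      TRUE
    }, fabricmapError = function(e) FALSE)
    if (!ok) flagged[i] <- TRUE
  }
  FabricField(points = points, tensors = tensors, bvtv = bvtv,
              flagged = flagged)
}
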