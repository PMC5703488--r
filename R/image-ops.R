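#' Physical coordinates of all voxel centers
#'
#' @param img a [BoneImage-class].
#' @return `prod(dim(img)) x 3` matrix, first index fastest (matches the
#'   linear order of the voxel array).
#' @export
voxelCenters <- function(img) {
  d <- dim(img)
  sp <- img@spacing; o <- img@origin
  cbind(rep(o[1] + (seq_len(d[1]) - 1) * sp[1], times = d[2] * d[3]),
        rep(rep(o[2] + (seq_len(d[2]) - 1) * sp[2], each = d[1]),
            times = d[3]),
        rep(o[3] + (seq_len(d[3]) - 1) * sp[3], each = d[1] * d[2]))
}

#' Sample an image at physical points
#'
#' @param img a [BoneImage-class] (identity direction assumed).
#' @param pts N x 3 matrix of physical coordinates (mm).
#' @param interp `"linear"` (trilinear) or `"nearest"`.
#' @param fill value for points outside the volume.
#' @return numeric vector of sampled values.
#' @export
sampleImage <- function(img, pts, interp = c("linear", "nearest"),
                        fill = 0) {
  interp <- match.arg(interp)
  pts <- matrix(as.numeric(pts), ncol = 3)
  if (interp == "linear")
    cpp_sample_linear(as.numeric(img@.Data), dim(img), img@origin,
                      img@spacing, pts, fill)
  else
    cpp_sample_nn(as.numeric(img@.Data), dim(img), img@origin,
                  img@spacing, pts, fill)
}

#' Resample an image onto a new voxel lattice
#'
#' @param img a [BoneImage-class].
#' @param spacing target spacing (mm, length 1 or 3). Ignored when `dims`
#'   and `origin` are both given.
#' @param dims,origin explicit target lattice (defaults cover the source
#'   domain at `spacing`).
#' @param interp interpolation, see [sampleImage()].
#' @param fill outside value.
#' @return resampled [BoneImage-class].
#' @export
resampleImage <- function(img, spacing = NULL, dims = NULL, origin = NULL,
                          interp = "linear", fill = 0) {
  if (is.null(spacing) && is.null(dims))
    fmStop("fmParameterError", "spacing or dims must be given")
  if (!is.null(spacing) && length(spacing) == 1) spacing <- rep(spacing, 3)
  if (is.null(dims)) dims <- pmax(1L, as.integer(ceiling(
    dim(img) * img@spacing / spacing)))
  if (is.null(spacing)) spacing <- dim(img) * img@spacing / dims
  if (is.null(origin)) origin <- img@origin + (spacing - img@spacing) / 2
  target <- BoneImage(array(0, dims), spacing = spacing, origin = origin)
  vals <- sampleImage(img, voxelCenters(target), interp = interp, fill = fill)
  BoneImage(array(vals, dims), spacing = spacing, origin = origin)
}

#' Gaussian smoothing in physical units
#'
#' Separable Gaussian blur with reflecting boundaries.
#'
#' @param img a [BoneImage-class].
#' @param sigma standard deviation in mm (length 1 or 3).
#' @return smoothed [BoneImage-class].
#' @export
gaussianSmooth <- function(img, sigma) {
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  out <- cpp_blur_sep(as.numeric(img@.Data), dim(img), sigma / img@spacing)
  BoneImage(array(out, dim(img)), spacing = img@spacing,
            origin = img@origin, direction = img@direction)
}

# One pyramid step: blur at the new scale, then subsample by 2.
downsampleImage <- function(img, factor = 2) {
  sm <- gaussianSmooth(img, sigma = 0.5 * factor * img@spacing)
  resampleImage(sm, spacing = img@spacing * factor)
}

#' Percentile intensity normalization
#'
#' Clamps intensities at the given percentiles and rescales to `[0, 1]`.
#' NCC is invariant to affine intensity changes, but clamping stabilizes
#' optimizer gradients in the presence of outlier voxels.
#'
#' @param img a [BoneImage-class].
#' @param probs lower/upper clamping percentiles.
#' @export
normalizeIntensity <- function(img, probs = c(0.005, 0.995)) {
  q <- quantile(img@.Data, probs, names = FALSE)
  if (q[2] <= q[1]) q <- range(img@.Data)
  v <- pmin(pmax(img@.Data, q[1]), q[2])
  if (q[2] > q[1]) v <- (v - q[1]) / (q[2] - q[1])
  BoneImage(array(v, dim(img)), spacing = img@spacing, origin = img@origin,
            direction = img@direction)
}

#' Euclidean distance transform
#'
#' Distance (mm) from each foreground voxel to the nearest background voxel;
#' exact separable transform, anisotropic spacing supported.
#'
#' @param mask binary [BoneImage-class].
#' @return [BoneImage-class] of distances (`NA` where no background exists).
#' @export
distanceTransform <- function(mask) {
  d <- cpp_edt(as.integer(mask@.Data != 0), dim(mask), mask@spacing)
  BoneImage(array(d, dim(mask)), spacing = mask@spacing,
            origin = mask@origin, direction = mask@direction)
}

#' Regular lattice of control points inside a mask
#'
#' Builds the cubic lattice of evaluation points used both for the
#' deformation distance metric and for fabric extraction/mapping: points are
#' spaced `spacing` mm apart over the image domain and restricted to the
#' (optionally eroded) trabecular mask.
#'
#' @param img a [BoneImage-class] defining the domain.
#' @param spacing lattice spacing in mm (default 5.3, the MIL VOI side).
#' @param mask optional binary [BoneImage-class]; points whose
#'   nearest-neighbour mask value is zero are dropped.
#' @param margin domain margin in mm kept free at the image border.
#' @return N x 3 matrix of points (mm).
#' @export
controlGrid <- function(img, spacing = 5.3, mask = NULL, margin = 0) {
  lo <- img@origin + margin
  hi <- img@origin + (dim(img) - 1) * img@spacing - margin
  ax <- lapply(1:3, function(a) {
    n <- max(1L, floor((hi[a] - lo[a]) / spacing) + 1L)
    lo[a] + (hi[a] - lo[a] - (n - 1) * spacing) / 2 + (seq_len(n) - 1) * spacing
  })
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  colnames(pts) <- NULL
  if (!is.null(mask)) {
    keep <- sampleImage(mask, pts, interp = "nearest", fill = 0) > 0
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) < 1)
    fmStop("fmEmptyGridError", "control grid contains no points")
  pts
}
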