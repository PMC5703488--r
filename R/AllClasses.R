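#' 3-D scalar image with physical geometry
#'
#' A `BoneImage` is a 3-D numeric array with voxel spacing, origin and
#' direction metadata (millimetres). Physical coordinates follow the usual
#' convention `x = origin + index0 * spacing` with zero-based voxel indices;
#' the direction cosine matrix must be orthonormal and is identity for all
#' images produced by this package.
#'
#' @slot spacing numeric(3), voxel spacing in mm, strictly positive.
#' @slot origin numeric(3), physical position of voxel (1,1,1) in mm.
#' @slot direction 3x3 orthonormal direction cosine matrix.
#' @export
setClass("BoneImage",
  contains = "array",
  representation(spacing = "numeric", origin = "numeric",
                 direction = "matrix"),
  prototype(array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0), direction = diag(3))
)

setValidity("BoneImage", function(object) {
  d <- dim(object@.Data)
  if (length(d) != 3L) return("voxel array must be 3-D")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive values")
  if (length(object@origin) != 3L) return("origin must be length 3")
  dd <- object@direction
  if (!all(dim(dd) == c(3L, 3L))) return("direction must be 3x3")
  if (max(abs(crossprod(dd) - diag(3))) > 1e-6)
    return("direction matrix must be orthonormal (1e-6)")
  TRUE
})

#' @param voxels 3-D numeric array.
#' @param spacing,origin,direction image geometry, see slots.
#' @rdname BoneImage-class
#' @export
BoneImage <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      direction = diag(3)) {
  new("BoneImage", voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), direction = direction)
}

#' Trace-normalized fabric tensor
#'
#' Symmetric positive-definite 3x3 tensor describing trabecular anisotropy,
#' with its eigen-structure cached. Eigenvalues are sorted ascending
#' (`m1 <= m2 <= m3`); eigenvectors are the matching unit vectors (columns).
#' Most code paths keep the tensor normalized to trace 3.
#'
#' @slot matrix symmetric positive-definite 3x3 matrix.
#' @slot eigenvalues numeric(3), ascending.
#' @slot eigenvectors 3x3 matrix, column i is the eigenvector of
#'   `eigenvalues[i]`.
#' @export
setClass("FabricTensor",
  representation(matrix = "matrix", eigenvalues = "numeric",
                 eigenvectors = "matrix"))

setValidity("FabricTensor", function(object) {
  M <- object@matrix
  if (!all(dim(M) == c(3L, 3L))) return("matrix must be 3x3")
  rel <- max(abs(M - t(M))) / max(max(abs(M)), .Machine$double.eps)
  if (rel > 1e-8) return("matrix must be symmetric (1e-8 relative)")
  if (any(object@eigenvalues <= 0))
    return("eigenvalues must be strictly positive")
  if (is.unsorted(object@eigenvalues))
    return("eigenvalues must be sorted ascending")
  V <- object@eigenvectors
  if (max(abs(crossprod(V) - diag(3))) > 1e-8)
    return("eigenvectors must be orthonormal (1e-8)")
  TRUE
})

#' @param M 3x3 symmetric positive-definite matrix. Inputs within 1e-8
#'   relative symmetry tolerance are symmetrized as `(M + t(M))/2` before
#'   eigendecomposition; larger asymmetry is an error.
#' @rdname FabricTensor-class
#' @export
FabricTensor <- function(M) {
  M <- as.matrix(M)
  if (!all(dim(M) == c(3L, 3L)))
    fmStop("fmDimensionError", "fabric tensor must be 3x3")
  rel <- max(abs(M - t(M))) / max(max(abs(M)), .Machine$double.eps)
  if (rel > 1e-8)
    fmStop("fmSymmetryError",
           "matrix is not symmetric (relative asymmetry %.3g > 1e-8)", rel)
  Ms <- (M + t(M)) / 2
  e <- eigen(Ms, symmetric = TRUE)
  if (any(e$values <= 0))
    fmStop("fmDefinitenessError",
           "matrix is not positive-definite (min eigenvalue %.3g)",
           min(e$values))
  ord <- order(e$values)            # ascending m1 <= m2 <= m3
  new("FabricTensor", matrix = Ms, eigenvalues = e$values[ord],
      eigenvectors = e$vectors[, ord, drop = FALSE])
}

#' Affine + cubic B-spline transform chain
#'
#' Represents the two-stage registration transform
#' `T(x) = T_B(T_A(x))` with `T_A(x) = A x + t` and
#' `T_B(y) = y + u(y)`, where `u` is a cubic B-spline free-form deformation
#' on a regular control-coefficient grid. A chain with `bsplineDims = 0`
#' is purely affine.
#'
#' @slot affine 3x3 linear part of the affine stage (positive determinant).
#' @slot translation numeric(3), affine translation (mm).
#' @slot bsplineOrigin,bsplineSpacing numeric(3), geometry of the coefficient
#'   grid (mm); the grid lives in the space *after* the affine stage.
#' @slot bsplineDims integer(3), number of coefficient nodes per axis.
#' @slot bsplineCoef numeric matrix `prod(bsplineDims) x 3` of coefficient
#'   vectors (mm), node `(i,j,k)` at row `i + nx*(j + ny*k)` (zero-based).
#' @export
setClass("TransformChain",
  representation(affine = "matrix", translation = "numeric",
                 bsplineOrigin = "numeric", bsplineSpacing = "numeric",
                 bsplineDims = "integer", bsplineCoef = "matrix"))

setValidity("TransformChain", function(object) {
  if (!all(dim(object@affine) == c(3L, 3L))) return("affine must be 3x3")
  if (det(object@affine) <= 0)
    return("affine linear part must have positive determinant")
  if (length(object@translation) != 3L) return("translation must be length 3")
  nd <- object@bsplineDims
  if (length(nd) != 3L) return("bsplineDims must be length 3")
  if (any(nd > 0L)) {
    if (any(nd < 4L)) return("a non-empty B-spline grid needs >= 4 nodes/axis")
    if (nrow(object@bsplineCoef) != prod(nd) || ncol(object@bsplineCoef) != 3L)
      return("bsplineCoef must be prod(dims) x 3")
    if (any(object@bsplineSpacing <= 0))
      return("bsplineSpacing must be positive")
  }
  TRUE
})

#' @param affine,translation affine stage.
#' @param bsplineOrigin,bsplineSpacing,bsplineDims,bsplineCoef B-spline
#'   stage; omit for an affine-only chain.
#' @rdname TransformChain-class
#' @export
TransformChain <- function(affine = diag(3), translation = c(0, 0, 0),
                           bsplineOrigin = numeric(3),
                           bsplineSpacing = c(1, 1, 1),
                           bsplineDims = integer(3),
                           bsplineCoef = matrix(0, 0, 3)) {
  new("TransformChain", affine = affine,
      translation = as.numeric(translation),
      bsplineOrigin = as.numeric(bsplineOrigin),
      bsplineSpacing = as.numeric(bsplineSpacing),
      bsplineDims = as.integer(bsplineDims),
      bsplineCoef = bsplineCoef)
}

#' Deformation gradient sample
#'
#' The local deformation gradient `F` of a [TransformChain-class] at one
#' point, with its left polar factors `F = V R` and the per-stage factors of
#' the affine (`VA`, `RA`) and B-spline (`VB`, `RB`) stages.
#'
#' @slot point numeric(3), evaluation point (mm, fixed-image space).
#' @slot F,V,R composed gradient and its stretch/rotation factors.
#' @slot VA,RA,VB,RB per-stage factors.
#' @export
setClass("GradientSample",
  representation(point = "numeric", F = "matrix", V = "matrix", R = "matrix",
                 VA = "matrix", RA = "matrix", VB = "matrix", RB = "matrix"))

#' Fabric tensor field on control points
#'
#' A set of control points in a reference image, each carrying a fabric
#' tensor and a local bone volume fraction. Points skipped by an operation
#' (out of bounds, degenerate) are kept with `flagged = TRUE`.
#'
#' @slot points N x 3 matrix of physical coordinates (mm).
#' @slot tensors list of [FabricTensor-class] (or `NULL` for flagged rows).
#' @slot bvtv numeric(N) local BV/TV, `NA` when unknown.
#' @slot ids character(N) point identifiers.
#' @slot flagged logical(N).
#' @export
setClass("FabricField",
  representation(points = "matrix", tensors = "list", bvtv = "numeric",
                 ids = "character", flagged = "logical"))

setValidity("FabricField", function(object) {
  n <- nrow(object@points)
  if (ncol(object@points) != 3L) return("points must be N x 3")
  if (length(object@tensors) != n) return("one tensor per point required")
  if (length(object@bvtv) != n) return("one bvtv per point required")
  if (length(object@ids) != n) return("one id per point required")
  if (length(object@flagged) != n) return("one flag per point required")
  TRUE
})

#' @param points,tensors,bvtv,ids,flagged see slots.
#' @rdname FabricField-class
#' @export
FabricField <- function(points, tensors, bvtv = rep(NA_real_, nrow(points)),
                        ids = as.character(seq_len(nrow(points))),
                        flagged = rep(FALSE, nrow(points))) {
  new("FabricField", points = points, tensors = tensors,
      bvtv = as.numeric(bvtv), ids = as.character(ids),
      flagged = as.logical(flagged))
}

#' Atlas database
#'
#' A collection of image records (id, subject, side, sex, image paths) with
#' optional in-memory images/fabric and a pairwise deformation-distance
#' matrix. Contralateral femora of one subject share the `subject` field.
#'
#' @slot records data.frame with columns `id`, `subject`, `side`, `sex`,
#'   `qct_path`, `hr_path`, `mask_path`, `fabric_path`.
#' @slot images named list (by id) of lists with optional elements `qct`,
#'   `hr`, `mask` ([BoneImage-class]), `fabric` ([FabricField-class]) and
#'   `fabricFun` (function mapping an N x 3 point matrix to a list of
#'   [FabricTensor-class]).
#' @slot dm pairwise distance-metric matrix (row = fixed, col = moving;
#'   `NA` diagonal), or a 0x0 matrix when not yet computed.
#' @export
setClass("AtlasDatabase",
  representation(records = "data.frame", images = "list", dm = "matrix"))

setValidity("AtlasDatabase", function(object) {
  need <- c("id", "subject", "side", "sex")
  if (!all(need %in% names(object@records)))
    return(paste("records must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(object@records$id)) return("record ids must be unique")
  if (nrow(object@dm) > 0 && !identical(rownames(object@dm),
                                        object@records$id))
    return("dm matrix dimnames must match record ids")
  TRUE
})

#' @param records,images,dm see slots.
#' @rdname AtlasDatabase-class
#' @export
AtlasDatabase <- function(records, images = list(),
                          dm = matrix(numeric(0), 0, 0)) {
  for (col in c("qct_path", "hr_path", "mask_path", "fabric_path"))
    if (is.null(records[[col]])) records[[col]] <- NA_character_
  records$id <- as.character(records$id)
  records$subject <- as.character(records$subject)
  new("AtlasDatabase", records = records, images = images, dm = dm)
}

#' Femur landmark set
#'
#' Landmarks of the implicit femoral coordinate system: head center and
#' radius, neck center/axis, shaft axis, the mid point on the common
#' perpendicular of the two axes, and the CCD angle between them.
#'
#' @slot headCenter,headRadius femoral head sphere (mm).
#' @slot neckCenter,neckAxis neck center and unit axis (head -> neck).
#' @slot neckAxisEndPoint intersection of the neck axis with the lateral
#'   femoral surface (mm).
#' @slot shaftPoint,shaftAxis a point on the shaft axis and its unit
#'   direction (proximal -> distal).
#' @slot shaftDistalPoint most distal shaft-axis point (mm).
#' @slot midPoint point at the shortest distance between neck and shaft axes.
#' @slot ccd caput-collum-diaphyseal angle (degrees).
#' @export
setClass("FemurLandmarks",
  representation(headCenter = "numeric", headRadius = "numeric",
                 neckCenter = "numeric", neckAxis = "numeric",
                 neckAxisEndPoint = "numeric", shaftPoint = "numeric",
                 shaftAxis = "numeric", shaftDistalPoint = "numeric",
                 midPoint = "numeric", ccd = "numeric"))

#' Registration result
#'
#' Output of [registerPair()]: the recovered [TransformChain-class] plus
#' per-level cost traces, the final similarity, and QC flags.
#'
#' @slot chain recovered transform chain.
#' @slot costTrace list of per-stage, per-level numeric cost traces.
#' @slot finalNCC normalized correlation after registration.
#' @slot foldingWarning `TRUE` if `det F <= 0` was observed at any probe
#'   point of the final transform.
#' @slot params the [registrationParams()] list used.
#' @export
setClass("RegistrationResult",
  representation(chain = "TransformChain", costTrace = "list",
                 finalNCC = "numeric", foldingWarning = "logical",
                 params = "list"))
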