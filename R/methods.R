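#' @describeIn BoneImage-class voxel spacing in mm.
#' @param object a `BoneImage`.
#' @export
setMethod("voxelSpacing", "BoneImage", function(object) object@spacing)

#' @describeIn BoneImage-class physical origin in mm.
#' @export
setMethod("imageOrigin", "BoneImage", function(object) object@origin)

#' Voxel array of an image
#' @param img a [BoneImage-class].
#' @return plain 3-D array.
#' @export
voxels <- function(img) {
  stopifnot(is(img, "BoneImage"))
  img@.Data
}

#' Physical extent of an image (mm per axis)
#' @param img a [BoneImage-class].
#' @export
imageExtent <- function(img) dim(img) * img@spacing

setMethod("show", "BoneImage", function(object) {
  d <- dim(object)
  cat(sprintf("BoneImage %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = " x ")))
  cat(sprintf("  origin (%s) mm, range [%.4g, %.4g]\n",
              paste(signif(object@origin, 4), collapse = ", "),
              min(object@.Data), max(object@.Data)))
})

#' @describeIn FabricTensor-class the symmetric 3x3 matrix.
#' @param object a `FabricTensor`.
#' @export
setMethod("tensorMatrix", "FabricTensor", function(object) object@matrix)

#' @describeIn FabricTensor-class eigenvalues, ascending (`m1 <= m2 <= m3`).
#' @export
setMethod("fabricEigenvalues", "FabricTensor",
          function(object) object@eigenvalues)

#' @describeIn FabricTensor-class matching unit eigenvectors (columns).
#' @export
setMethod("fabricEigenvectors", "FabricTensor",
          function(object) object@eigenvectors)

setMethod("show", "FabricTensor", function(object) {
  ev <- object@eigenvalues
  cat(sprintf(
    "FabricTensor  trace %.6g  eigenvalues (%.4g, %.4g, %.4g)  DA %.4g\n",
    sum(diag(object@matrix)), ev[1], ev[2], ev[3], ev[3] / ev[1]))
})

setMethod("show", "TransformChain", function(object) {
  cat("TransformChain\n  affine linear part:\n")
  print(signif(object@affine, 5))
  cat(sprintf("  translation: (%s) mm\n",
              paste(signif(object@translation, 5), collapse = ", ")))
  if (any(object@bsplineDims > 0)) {
    cat(sprintf("  B-spline grid %s nodes, spacing (%s) mm, max |coef| %.3g mm\n",
                paste(object@bsplineDims, collapse = " x "),
                paste(signif(object@bsplineSpacing, 4), collapse = ", "),
                max(abs(object@bsplineCoef))))
  } else cat("  (affine only)\n")
})

setMethod("show", "GradientSample", function(object) {
  cat(sprintf("GradientSample at (%s) mm, det F = %.5g\n",
              paste(signif(object@point, 4), collapse = ", "),
              det(object@F)))
})

#' @describeIn FabricField-class control point coordinates (N x 3, mm).
#' @param object a `FabricField`.
#' @export
setMethod("controlPoints", "FabricField", function(object) object@points)

#' @describeIn FabricField-class list of per-point fabric tensors.
#' @export
setMethod("fieldTensors", "FabricField", function(object) object@tensors)

#' @describeIn FabricField-class per-point bone volume fraction.
#' @export
setMethod("fieldBVTV", "FabricField", function(object) object@bvtv)

setMethod("show", "FabricField", function(object) {
  cat(sprintf("FabricField with %d control points (%d flagged)\n",
              nrow(object@points), sum(object@flagged)))
})

setMethod("show", "AtlasDatabase", function(object) {
  cat(sprintf("AtlasDatabase with %d records (%d subjects)\n",
              nrow(object@records), length(unique(object@records$subject))))
  if (nrow(object@dm) > 0) cat("  pairwise DM matrix present\n")
})

setMethod("show", "FemurLandmarks", function(object) {
  cat(sprintf("FemurLandmarks: head r = %.3g mm, CCD = %.4g deg\n",
              object@headRadius, object@ccd))
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult: final NCC %.4f%s\n", object@finalNCC,
              if (object@foldingWarning) " (folding warning)" else ""))
})

#' @describeIn RegistrationResult-class the recovered transform chain.
#' @param object a `RegistrationResult`.
#' @export
setMethod("transformChain", "RegistrationResult", function(object)
  object@chain)
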