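checkRotation <- function(R, name = "rotation") {
  R <- as.matrix(R)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    fmStop("fmRotationError", "%s is not a proper rotation matrix", name)
  R
}

asTensorMatrix <- function(M) if (is(M, "FabricTensor")) M@matrix else
  FabricTensor(M)@matrix

# similarity-transform the tensor, keep the raw result, then symmetrize and
# renormalize so the output is a valid fabric tensor
similarityMap <- function(M, F) {
  F <- as.matrix(F)
  if (abs(det(F)) < 1e-12)
    fmStop("fmInvertibilityError", "deformation gradient is singular")
  if (det(F) <= 0)
    fmStop("fmFoldingError", "deformation gradient has det <= 0")
  raw <- F %*% M %*% solve(F)
  sym <- (raw + t(raw)) / 2
  # the raw similarity transform preserves eigenvalues but not symmetry;
  # its symmetric part can lose definiteness for strongly non-normal
  # gradients, so eigenvalues are floored to keep the output a valid
  # fabric tensor
  e <- eigen(sym, symmetric = TRUE)
  if (min(e$values) <= 0) {
    fmWarn("fmDefinitenessWarning",
           "symmetrized mapped tensor not positive-definite; eigenvalues floored")
    vals <- pmax(e$values, 1e-6 * max(abs(e$values)))
    sym <- e$vectors %*% (vals * t(e$vectors))
  }
  out <- normalizeTrace(sym)
  attr(out, "raw") <- raw
  out
}

#' Fabric tensor mapping schemes
#'
#' Transport a fabric tensor from atlas to patient space using one of five
#' decompositions of the registration's deformation gradient:
#' \describe{
#'   \item{NR}{no rotation -- the tensor is copied unchanged (translation
#'     only).}
#'   \item{AR}{affine rotation -- `M' = R_A M R_A'` with the global rotation
#'     factor of the affine stage.}
#'   \item{AD}{affine deformation -- `M' = F_A M F_A^{-1}` with the global
#'     affine gradient `F_A = V_A R_A`.}
#'   \item{CR}{complete rotation -- `M' = R M R'` with the local rotation
#'     `R = R_B R_A` at the control point.}
#'   \item{CD}{complete deformation -- `M' = F M F^{-1}` with the full local
#'     gradient.}
#' }
#' Rotation schemes preserve eigenvalues exactly. The deformation schemes
#' (AD, CD) are similarity transforms whose raw result is generally not
#' symmetric; the returned tensor is symmetrized and trace-renormalized
#' (the raw matrix is available as `attr(result, "raw")`).
#'
#' `mapTensor` dispatches on `scheme`; `mapNR`, `mapAR`, `mapAD`, `mapCR`
#' and `mapCD` are the individual schemes.
#'
#' @param M a [FabricTensor-class] (or SPD matrix).
#' @param gradient a [GradientSample-class] providing the required factors.
#' @param scheme one of `"NR"`, `"AR"`, `"AD"`, `"CR"`, `"CD"`.
#' @return mapped [FabricTensor-class].
#' @export
mapTensor <- function(M, gradient, scheme = c("NR", "AR", "AD", "CR", "CD")) {
  scheme <- match.arg(scheme)
  switch(scheme,
    NR = mapNR(M),
    AR = mapAR(M, gradient@RA),
    AD = mapAD(M, gradient@VA %*% gradient@RA),
    CR = mapCR(M, gradient@RA, gradient@RB),
    CD = mapCD(M, gradient@F))
}

#' @rdname mapTensor
#' @export
mapNR <- function(M) FabricTensor(asTensorMatrix(M))

#' @rdname mapTensor
#' @param RA global rotation factor of the affine stage.
#' @export
mapAR <- function(M, RA) {
  RA <- checkRotation(RA, "affine rotation")
  M <- asTensorMatrix(M)
  FabricTensor(RA %*% M %*% t(RA))
}

#' @rdname mapTensor
#' @param FA affine deformation gradient `V_A R_A` (det > 0).
#' @export
mapAD <- function(M, FA) similarityMap(asTensorMatrix(M), FA)

#' @rdname mapTensor
#' @param RB local rotation factor of the B-spline stage.
#' @export
mapCR <- function(M, RA, RB) {
  RA <- checkRotation(RA, "affine rotation")
  RB <- checkRotation(RB, "B-spline rotation")
  R <- RB %*% RA
  M <- asTensorMatrix(M)
  FabricTensor(R %*% M %*% t(R))
}

#' @rdname mapTensor
#' @param F full local deformation gradient (det > 0).
#' @export
mapCD <- function(M, F) similarityMap(asTensorMatrix(M), F)

#' Map a fabric field through a transform chain
#'
#' Applies one mapping scheme at every control point of a field whose
#' points live in the fixed (patient) image and whose tensors were
#' established at the corresponding atlas points `T(x_j)`. Local schemes
#' (CR, CD) evaluate the deformation gradient at each point; global schemes
#' (AR, AD) use the affine stage factors once. Points that fail (folding,
#' singular gradient) are flagged rather than dropped.
#'
#' @param field a [FabricField-class] on the fixed-image control points.
#' @param chain the registration [TransformChain-class] (fixed -> atlas).
#' @param scheme mapping scheme, see [mapTensor()].
#' @return a [FabricField-class] with mapped tensors.
#' @export
mapField <- function(field, chain, scheme = c("NR", "AR", "AD", "CR", "CD")) {
  scheme <- match.arg(scheme)
  n <- nrow(field@points)
  tensors <- vector("list", n)
  flagged <- field@flagged
  vrA <- vrDecompose(chain@affine)
  Fs <- if (scheme %in% c("CR", "CD")) chainGradients(chain, field@points)
        else NULL
  FAinv <- solve(chain@affine)
  for (i in seq_len(n)) {
    if (flagged[i] || is.null(field@tensors[[i]])) {
      flagged[i] <- TRUE
      next
    }
    M <- field@tensors[[i]]
    tensors[[i]] <- tryCatch(switch(scheme,
      NR = mapNR(M),
      AR = mapAR(M, vrA$R),
      AD = mapAD(M, chain@affine),
      CR = {
        FB <- Fs[[i]] %*% FAinv
        mapCR(M, vrA$R, vrDecompose(FB)$R)
      },
      CD = mapCD(M, Fs[[i]])),
      fabricmapError = function(e) NULL)
    if (is.null(tensors[[i]])) flagged[i] <- TRUE
  }
  FabricField(points = field@points, tensors = tensors, bvtv = field@bvtv,
              ids = field@ids, flagged = flagged)
}
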