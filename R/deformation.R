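#' Left polar (VR) decomposition of a deformation gradient
#'
#' Factors `F = V R` with `V = (F F^T)^{1/2}` symmetric positive-definite
#' (the left stretch) and `R = V^{-1} F` a proper rotation, evaluated
#' through the SVD of `F` (whose left singular vectors are the eigenvectors
#' of `F F^T`), which keeps `R` orthogonal to machine precision even for
#' ill-conditioned gradients. A non-positive determinant means the
#' transform folds space locally and is rejected.
#'
#' @param F 3x3 matrix with `det(F) > 0`.
#' @return list with elements `V` (SPD) and `R` (rotation).
#' @examples
#' vrDecompose(diag(c(2, 1, 1)))
#' @export
vrDecompose <- function(F) {
  F <- as.matrix(F)
  if (det(F) <= 0)
    fmStop("fmFoldingError",
           "deformation gradient has det %.3g <= 0 (local fold)", det(F))
  s <- svd(F)
  # F = U S V' gives the left polar factors exactly: V = U S U', R = U V';
  # with det(F) > 0 and positive singular values, det(R) = +1
  R <- s$u %*% t(s$v)
  V <- s$u %*% (s$d * t(s$u))
  list(V = (V + t(V)) / 2, R = R)
}

#' Deformation gradient of a transform chain at a point
#'
#' Evaluates `F = grad T` at a fixed-image point by the chain rule:
#' `F = F_B(T_A(x)) F_A` where `F_A` is the affine linear part and
#' `F_B = I + grad u` is the analytic spatial Jacobian of the cubic
#' B-spline displacement. The composed gradient and both stage gradients
#' are VR-decomposed.
#'
#' @param chain a [TransformChain-class].
#' @param point physical point (mm), length 3.
#' @return a [GradientSample-class].
#' @export
deformationGradient <- function(chain, point) {
  point <- as.numeric(point)
  FA <- chain@affine
  y <- as.numeric(FA %*% point + chain@translation)
  FB <- diag(3)
  if (any(chain@bsplineDims > 0)) {
    J <- cpp_bspline_jac(matrix(y, 1, 3), chain@bsplineOrigin,
                         chain@bsplineSpacing, chain@bsplineDims,
                         chain@bsplineCoef)
    FB <- diag(3) + matrix(J[1, ], 3, 3)
  }
  F <- FB %*% FA
  vr <- vrDecompose(F)
  vrA <- vrDecompose(FA)
  vrB <- vrDecompose(FB)
  new("GradientSample", point = point, F = F, V = vr$V, R = vr$R,
      VA = vrA$V, RA = vrA$R, VB = vrB$V, RB = vrB$R)
}

# Vectorized deformation gradients: list of 3x3 F matrices at N points.
chainGradients <- function(chain, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  FA <- chain@affine
  y <- pts %*% t(FA) + matrix(chain@translation, nrow(pts), 3, byrow = TRUE)
  if (any(chain@bsplineDims > 0)) {
    J <- cpp_bspline_jac(y, chain@bsplineOrigin, chain@bsplineSpacing,
                         chain@bsplineDims, chain@bsplineCoef)
    lapply(seq_len(nrow(pts)), function(i)
      (diag(3) + matrix(J[i, ], 3, 3)) %*% FA)
  } else {
    rep(list(FA), nrow(pts))
  }
}

#' Log-stretch deformation distance metric
#'
#' Quantifies how much non-rigid deformation a registration needs:
#' \deqn{DM = \sum_{j=1}^{J} \| \log V_j \|_F}
#' summed over a grid of control points, where `V_j` is the local stretch
#' tensor and the norm is Frobenius. Rigid transforms (`V = I` everywhere)
#' score zero.
#'
#' Two evaluation modes are provided. `"composed"` (default) takes the left
#' stretch of the fully composed gradient `F` at each point, which is always
#' well defined. `"product"` evaluates the literal per-stage product
#' `V_B V_A`, which need not be symmetric; it is symmetrized before the
#' logarithm and rejected if not positive-definite.
#'
#' @param chain a [TransformChain-class].
#' @param grid J x 3 matrix of control points (see [controlGrid()]).
#' @param mode `"composed"` or `"product"`.
#' @return non-negative scalar.
#' @export
distanceMetric <- function(chain, grid, mode = c("composed", "product")) {
  mode <- match.arg(mode)
  grid <- matrix(as.numeric(grid), ncol = 3)
  Fs <- chainGradients(chain, grid)
  FA <- chain@affine
  vrA <- vrDecompose(FA)
  total <- 0
  for (j in seq_along(Fs)) {
    F <- Fs[[j]]
    if (det(F) <= 0)
      fmStop("fmFoldingError",
             "folding (det F = %.3g) at control point %d", det(F), j)
    if (mode == "composed") {
      V <- vrDecompose(F)$V
    } else {
      FB <- F %*% solve(FA)
      VB <- vrDecompose(FB)$V
      P <- VB %*% vrA$V
      V <- (P + t(P)) / 2
      if (min(eigen(V, symmetric = TRUE, only.values = TRUE)$values) <= 0)
        fmStop("fmDefinitenessError",
               "symmetrized stretch product not SPD at point %d", j)
    }
    L <- spdLog(V)
    total <- total + sqrt(sum(L^2))
  }
  total
}
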