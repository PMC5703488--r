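#' Trace normalization of a fabric tensor
#'
#' Scales a symmetric positive-definite matrix so that its trace equals 3,
#' the conventional normalization for second-order fabric tensors
#' (`M' = 3 M / tr(M)`). Idempotent.
#'
#' @param M a 3x3 SPD matrix or a [FabricTensor-class].
#' @return a [FabricTensor-class] with trace 3.
#' @examples
#' normalizeTrace(diag(c(1, 2, 3)))
#' @export
normalizeTrace <- function(M) {
  if (is(M, "FabricTensor")) M <- M@matrix
  ft <- FabricTensor(M)   # validates symmetry and definiteness
  tr <- sum(diag(ft@matrix))
  FabricTensor(3 * ft@matrix / tr)
}

#' @describeIn degreeOfAnisotropy ratio `m3 / m1` of the extreme
#'   eigenvalues; 1 for isotropy.
#' @export
setMethod("degreeOfAnisotropy", "FabricTensor", function(object) {
  ev <- object@eigenvalues
  ev[3] / ev[1]
})

#' @describeIn degreeOfAnisotropy accepts a plain SPD matrix.
#' @export
setMethod("degreeOfAnisotropy", "matrix", function(object)
  degreeOfAnisotropy(FabricTensor(object)))

#' @describeIn principalDirection eigenvector of the largest eigenvalue.
#'   Fabric is an axial quantity (`v` and `-v` are the same axis), so the
#'   sign is fixed by making the largest-magnitude component positive. When
#'   the relative eigenvalue gap `(m3 - m2)/m3` falls below `degeneracyTol`
#'   the direction is meaningless and the result carries
#'   `attr(, "degenerate") = TRUE`.
#' @export
setMethod("principalDirection", "FabricTensor",
          function(object, degeneracyTol = 1e-6) {
  ev <- object@eigenvalues
  v <- object@eigenvectors[, 3]
  k <- which.max(abs(v))
  if (v[k] < 0) v <- -v
  attr(v, "degenerate") <- (ev[3] - ev[2]) / ev[3] < degeneracyTol
  v
})

#' @describeIn principalDirection accepts a plain SPD matrix.
#' @export
setMethod("principalDirection", "matrix",
          function(object, degeneracyTol = 1e-6)
            principalDirection(FabricTensor(object), degeneracyTol))

#' Matrix logarithm and exponential of SPD matrices
#'
#' Computed through the eigendecomposition `U diag(f(lambda)) U^T`. The
#' logarithm of the local stretch tensor is the quantity accumulated by the
#' deformation [distanceMetric()].
#'
#' @param V symmetric positive-definite matrix (for `spdLog`).
#' @param S symmetric matrix (for `spdExp`).
#' @return symmetric matrix; `spdExp(spdLog(V))` recovers `V`.
#' @examples
#' spdLog(diag(c(exp(1), 1, 1)))
#' @export
spdLog <- function(V) {
  V <- as.matrix(V)
  rel <- max(abs(V - t(V))) / max(max(abs(V)), .Machine$double.eps)
  if (rel > 1e-8)
    fmStop("fmSymmetryError", "spdLog input is not symmetric")
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (any(e$values <= 0))
    fmStop("fmDefinitenessError",
           "spdLog input is not positive-definite (min eigenvalue %.3g)",
           min(e$values))
  e$vectors %*% (log(e$values) * t(e$vectors))
}

#' @rdname spdLog
#' @export
spdExp <- function(S) {
  S <- as.matrix(S)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (exp(e$values) * t(e$vectors))
}

#' Arithmetic mean of fabric tensors
#'
#' Element-wise average of trace-3 tensors, then re-normalized to trace 3.
#' This is the population averaging used to build a fabric atlas; it is a
#' Euclidean (not log-Euclidean) mean.
#'
#' @param tensors non-empty list of [FabricTensor-class] (or SPD matrices).
#' @return a trace-3 [FabricTensor-class].
#' @export
meanTensor <- function(tensors) {
  if (length(tensors) == 0)
    fmStop("fmEmptyInputError", "meanTensor needs at least one tensor")
  mats <- lapply(tensors, function(t)
    if (is(t, "FabricTensor")) t@matrix else as.matrix(t))
  M <- Reduce(`+`, mats) / length(mats)
  normalizeTrace(M)
}

#' Read/write a tensor-field table
#'
#' The interchange format is a CSV with one row per control point and
#' columns `id, x, y, z` (mm, reference-image physical coordinates),
#' the six unique tensor components `m11, m22, m33, m12, m13, m23`,
#' and `bvtv`.
#'
#' @param field a [FabricField-class].
#' @param path CSV path.
#' @return `readFabricField` returns a [FabricField-class];
#'   `writeFabricField` returns `path` invisibly.
#' @export
writeFabricField <- function(field, path) {
  n <- nrow(field@points)
  comp <- t(vapply(seq_len(n), function(i) {
    t <- field@tensors[[i]]
    if (is.null(t)) return(rep(NA_real_, 6))
    M <- t@matrix
    c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])
  }, numeric(6)))
  df <- data.frame(id = field@ids,
                   x = field@points[, 1], y = field@points[, 2],
                   z = field@points[, 3],
                   m11 = comp[, 1], m22 = comp[, 2], m33 = comp[, 3],
                   m12 = comp[, 4], m13 = comp[, 5], m23 = comp[, 6],
                   bvtv = field@bvtv)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFabricField
#' @export
readFabricField <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "z", "m11", "m22", "m33", "m12", "m13", "m23",
            "bvtv")
  if (!all(need %in% names(df)))
    fmStop("fmIOError", "tensor-field table must have columns %s",
           paste(need, collapse = ", "))
  tensors <- lapply(seq_len(nrow(df)), function(i) {
    if (is.na(df$m11[i])) return(NULL)
    FabricTensor(matrix(c(df$m11[i], df$m12[i], df$m13[i],
                          df$m12[i], df$m22[i], df$m23[i],
                          df$m13[i], df$m23[i], df$m33[i]), 3, 3))
  })
  FabricField(points = as.matrix(df[, c("x", "y", "z")]),
              tensors = tensors, bvtv = df$bvtv, ids = as.character(df$id),
              flagged = vapply(tensors, is.null, logical(1)))
}

#' Interpolate a fabric field at query points
#'
#' Nearest-control-point lookup: each query point receives the tensor and
#' BV/TV of the closest unflagged field point.
#'
#' @param field a [FabricField-class].
#' @param pts N x 3 matrix of query points (mm).
#' @return list with elements `tensors` (list) and `bvtv` (numeric).
#' @export
fabricFieldAt <- function(field, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  ok <- which(!field@flagged)
  if (length(ok) == 0)
    fmStop("fmEmptyInputError", "fabric field has no usable points")
  P <- field@points[ok, , drop = FALSE]
  idx <- vapply(seq_len(nrow(pts)), function(i) {
    d2 <- (P[, 1] - pts[i, 1])^2 + (P[, 2] - pts[i, 2])^2 +
      (P[, 3] - pts[i, 3])^2
    ok[which.min(d2)]
  }, integer(1))
  list(tensors = field@tensors[idx], bvtv = field@bvtv[idx])
}
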