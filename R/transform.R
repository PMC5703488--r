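#' Apply a transform chain to points
#'
#' Evaluates `T(x) = T_B(T_A(x))`: the affine stage first, then the cubic
#' B-spline displacement added in the affinely transformed space.
#'
#' @param chain a [TransformChain-class].
#' @param pts N x 3 matrix of physical points (mm).
#' @return N x 3 matrix of transformed points.
#' @export
transformPoints <- function(chain, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  y <- pts %*% t(chain@affine) +
    matrix(chain@translation, nrow(pts), 3, byrow = TRUE)
  if (any(chain@bsplineDims > 0)) {
    u <- cpp_bspline_disp(y, chain@bsplineOrigin, chain@bsplineSpacing,
                          chain@bsplineDims, chain@bsplineCoef)
    y <- y + u
  }
  y
}

#' Resample an image through a transform chain
#'
#' Produces the warped moving image on the fixed lattice:
#' `out(x) = moving(T(x))` for every voxel center `x` of `fixed`.
#'
#' @param moving a [BoneImage-class] to be warped.
#' @param fixed a [BoneImage-class] whose lattice defines the output.
#' @param chain a [TransformChain-class] mapping fixed to moving space.
#' @param interp `"linear"` for intensities, `"nearest"` for masks.
#' @param fill outside value.
#' @return [BoneImage-class] on the fixed lattice.
#' @export
applyTransform <- function(moving, fixed, chain, interp = "linear",
                           fill = 0) {
  pts <- transformPoints(chain, voxelCenters(fixed))
  vals <- sampleImage(moving, pts, interp = interp, fill = fill)
  BoneImage(array(vals, dim(fixed)), spacing = fixed@spacing,
            origin = fixed@origin, direction = fixed@direction)
}

#' Serialize a transform chain to a text parameter file
#'
#' Plain-text format (stage type, matrix, translation, grid geometry,
#' coefficient vectors) written with 17 significant digits so that a
#' write/read round trip is bit-exact.
#'
#' @param chain a [TransformChain-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTransformChain <- function(chain, path) {
  fmt <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  lines <- c(
    "fabricmap-transform-chain 1",
    paste("affine", fmt(t(chain@affine))),        # row-major
    paste("translation", fmt(chain@translation)),
    paste("bspline_dims", paste(chain@bsplineDims, collapse = " ")),
    paste("bspline_origin", fmt(chain@bsplineOrigin)),
    paste("bspline_spacing", fmt(chain@bsplineSpacing)))
  if (any(chain@bsplineDims > 0)) {
    lines <- c(lines, "coefficients",
               vapply(seq_len(nrow(chain@bsplineCoef)),
                      function(i) fmt(chain@bsplineCoef[i, ]),
                      character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeTransformChain
#' @export
readTransformChain <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "fabricmap-transform-chain"))
    fmStop("fmIOError", "not a fabricmap transform chain file: %s", path)
  grab <- function(key) {
    ln <- lines[startsWith(lines, paste0(key, " "))]
    if (length(ln) != 1) fmStop("fmIOError", "missing field %s", key)
    as.numeric(strsplit(sub(paste0("^", key, " "), "", ln), " ")[[1]])
  }
  affine <- matrix(grab("affine"), 3, 3, byrow = TRUE)
  dims <- as.integer(grab("bspline_dims"))
  coef <- matrix(0, 0, 3)
  if (any(dims > 0)) {
    i0 <- which(lines == "coefficients")
    coef <- do.call(rbind, lapply(lines[(i0 + 1):(i0 + prod(dims))],
      function(l) as.numeric(strsplit(l, " ")[[1]])))
  }
  TransformChain(affine = affine, translation = grab("translation"),
                 bsplineOrigin = grab("bspline_origin"),
                 bsplineSpacing = grab("bspline_spacing"),
                 bsplineDims = dims, bsplineCoef = coef)
}

# Build a B-spline coefficient grid covering a physical bounding box with the
# one-node padding required by the cubic support.
bsplineGridFor <- function(lo, hi, spacing) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  n <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)))
  # nodes at origin + (0:(dims-1))*spacing; need floor(t)-1 .. floor(t)+2
  origin <- lo - spacing
  dims <- n + 4L
  list(origin = origin, spacing = spacing, dims = dims)
}
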