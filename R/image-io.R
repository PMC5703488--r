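#' Read a 3-D image (MetaImage or NIfTI)
#'
#' Supports MetaImage (`.mha`, `.mhd` + `.raw`) and NIfTI
#' (`.nii`, `.nii.gz`; via \pkg{RNifti}). Only identity direction matrices
#' are produced; non-axis-aligned files are rejected.
#'
#' @param path file path.
#' @return a [BoneImage-class].
#' @export
readImage3D <- function(path) {
  if (!file.exists(path))
    fmStop("fmIOError", "image file not found: %s", path)
  low <- tolower(path)
  if (grepl("\\.(mha|mhd)$", low)) return(readMetaImage(path))
  if (grepl("\\.nii(\\.gz)?$", low)) {
    nii <- RNifti::readNifti(path)
    arr <- array(as.numeric(nii), dim(nii))
    sp <- RNifti::pixdim(nii)[1:3]
    xf <- RNifti::xform(nii)
    return(BoneImage(arr, spacing = sp, origin = xf[1:3, 4]))
  }
  fmStop("fmIOError", "unsupported image format: %s", path)
}

#' Write a 3-D image (MetaImage or NIfTI)
#'
#' @param img a [BoneImage-class].
#' @param path output path; format chosen by extension (`.mha`, `.nii`,
#'   `.nii.gz`).
#' @param elementType for MetaImage: `MET_DOUBLE`, `MET_FLOAT` or
#'   `MET_UCHAR` (use `MET_UCHAR` for binary masks).
#' @return `path`, invisibly.
#' @export
writeImage3D <- function(img, path, elementType = "MET_DOUBLE") {
  stopifnot(is(img, "BoneImage"))
  low <- tolower(path)
  if (grepl("\\.mha$", low)) {
    writeMetaImage(img, path, elementType)
  } else if (grepl("\\.nii(\\.gz)?$", low)) {
    nii <- RNifti::asNifti(img@.Data)
    nii <- RNifti::`pixdim<-`(nii, img@spacing)
    xf <- diag(4)
    diag(xf)[1:3] <- img@spacing
    xf[1:3, 4] <- img@origin
    nii <- RNifti::`qform<-`(nii, structure(xf, code = 2L))
    RNifti::writeNifti(nii, path)
  } else {
    fmStop("fmIOError", "unsupported image format: %s", path)
  }
  invisible(path)
}

metaTypeInfo <- function(type) {
  switch(type,
    MET_UCHAR  = list(what = "integer", size = 1, signed = FALSE),
    MET_CHAR   = list(what = "integer", size = 1, signed = TRUE),
    MET_USHORT = list(what = "integer", size = 2, signed = FALSE),
    MET_SHORT  = list(what = "integer", size = 2, signed = TRUE),
    MET_INT    = list(what = "integer", size = 4, signed = TRUE),
    MET_FLOAT  = list(what = "numeric", size = 4, signed = TRUE),
    MET_DOUBLE = list(what = "numeric", size = 8, signed = TRUE),
    fmStop("fmIOError", "unsupported MetaImage ElementType: %s", type))
}

readMetaImage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) fmStop("fmIOError", "truncated MetaImage header")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["NDims"]], "3"))
    fmStop("fmIOError", "only 3-D MetaImages are supported")
  if (identical(hdr[["CompressedData"]], "True"))
    fmStop("fmIOError", "compressed MetaImage not supported")
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr[["ElementSpacing"]] %||% "1 1 1",
                            "\\s+")[[1]])
  off <- as.numeric(strsplit(hdr[["Offset"]] %||% "0 0 0", "\\s+")[[1]])
  ti <- metaTypeInfo(hdr[["ElementType"]] %||% "MET_DOUBLE")
  n <- prod(dims)
  if (identical(hdr[["ElementDataFile"]], "LOCAL")) {
    raw <- readBin(con, ti$what, n = n, size = ti$size, signed = ti$signed,
                   endian = "little")
  } else {
    rawPath <- file.path(dirname(path), hdr[["ElementDataFile"]])
    rcon <- file(rawPath, "rb")
    on.exit(close(rcon), add = TRUE)
    raw <- readBin(rcon, ti$what, n = n, size = ti$size, signed = ti$signed,
                   endian = "little")
  }
  if (length(raw) != n) fmStop("fmIOError", "truncated MetaImage data")
  BoneImage(array(as.numeric(raw), dims), spacing = sp, origin = off)
}

writeMetaImage <- function(img, path, elementType = "MET_DOUBLE") {
  ti <- metaTypeInfo(elementType)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %s", paste(format(img@origin, digits = 17),
                                 collapse = " ")),
    sprintf("ElementSpacing = %s", paste(format(img@spacing, digits = 17),
                                         collapse = " ")),
    sprintf("DimSize = %s", paste(dim(img), collapse = " ")),
    sprintf("ElementType = %s", elementType),
    "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  v <- as.numeric(img@.Data)
  if (ti$what == "integer")
    writeBin(as.integer(round(v)), con, size = ti$size, endian = "little")
  else
    writeBin(v, con, size = ti$size, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
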