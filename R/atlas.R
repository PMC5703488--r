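#' Read / write an atlas database manifest
#'
#' The manifest is a CSV with columns `id, subject, side, sex, qct_path,
#' hr_path, mask_path, fabric_path`; relative paths are resolved against
#' the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return `readAtlasManifest` returns an [AtlasDatabase-class].
#' @export
readAtlasManifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "subject", "side", "sex")
  if (!all(need %in% names(df)))
    fmStop("fmIOError", "manifest must have columns %s",
           paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  for (col in c("qct_path", "hr_path", "mask_path", "fabric_path")) {
    if (is.null(df[[col]])) { df[[col]] <- NA_character_; next }
    rel <- !is.na(df[[col]]) & nzchar(df[[col]]) &
      !grepl("^(/|[A-Za-z]:)", df[[col]])
    df[[col]][rel] <- file.path(base, df[[col]][rel])
    df[[col]][!nzchar(df[[col]] %||% "")] <- NA_character_
  }
  AtlasDatabase(df)
}

#' @param db an [AtlasDatabase-class].
#' @rdname readAtlasManifest
#' @export
writeAtlasManifest <- function(db, path) {
  write.csv(db@records, path, row.names = FALSE)
  invisible(path)
}

dbRecord <- function(db, id) {
  i <- match(id, db@records$id)
  if (is.na(i)) fmStop("fmSelectionError", "unknown record id %s", id)
  db@records[i, , drop = FALSE]
}

# image of a record: in-memory first, then file path
dbImage <- function(db, id, what = c("qct", "hr", "mask")) {
  what <- match.arg(what)
  mem <- db@images[[id]][[what]]
  if (!is.null(mem)) return(mem)
  rec <- dbRecord(db, id)
  path <- rec[[paste0(what, "_path")]]
  if (is.na(path))
    fmStop("fmIOError", "record %s has no %s image", id, what)
  readImage3D(path)
}

dbHasImage <- function(db, id, what) {
  !is.null(db@images[[id]][[what]]) ||
    !is.na(dbRecord(db, id)[[paste0(what, "_path")]])
}

# control grid of a record's QCT image restricted to its mask
targetControlGrid <- function(db, id, spacing = 5.3) {
  img <- dbImage(db, id, "qct")
  mask <- if (dbHasImage(db, id, "mask")) dbImage(db, id, "mask") else NULL
  controlGrid(img, spacing = spacing, mask = mask)
}

# fabric of a record at arbitrary points of its own image space:
# analytic function > precomputed field > MIL extraction from the HR image
recordFabric <- function(db, id, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  fun <- db@images[[id]][["fabricFun"]]
  if (!is.null(fun)) {
    res <- fun(points)
    tensors <- if (is.list(res) && !is.null(res$tensors)) res$tensors else res
    bvtv <- if (is.list(res) && !is.null(res$bvtv)) res$bvtv
            else rep(NA_real_, nrow(points))
    return(FabricField(points = points, tensors = tensors, bvtv = bvtv))
  }
  field <- db@images[[id]][["fabric"]]
  if (is.null(field)) {
    rec <- dbRecord(db, id)
    if (!is.na(rec$fabric_path)) field <- readFabricField(rec$fabric_path)
  }
  if (!is.null(field)) {
    at <- fabricFieldAt(field, points)
    return(FabricField(points = points, tensors = at$tensors,
                       bvtv = at$bvtv))
  }
  if (dbHasImage(db, id, "hr")) {
    mask <- if (dbHasImage(db, id, "mask")) dbImage(db, id, "mask") else NULL
    return(extractFabric(dbImage(db, id, "hr"), points, mask = mask))
  }
  fmStop("fmIOError", "record %s has no fabric source", id)
}

# atlas fabric established at the corresponding points T(x_j), placed at
# the fixed-image control points x_j
correspondingFabric <- function(db, atlasId, chain, fixedPoints) {
  moved <- transformPoints(chain, fixedPoints)
  fab <- recordFabric(db, atlasId, moved)
  FabricField(points = matrix(as.numeric(fixedPoints), ncol = 3),
              tensors = fab@tensors, bvtv = fab@bvtv,
              flagged = fab@flagged)
}

regCacheKey <- function(fixedId, movingId, params) {
  paste(fixedId, movingId,
        paste(deparse(unclass(params)), collapse = ""), sep = "|")
}

# registration between two database records, memoized in `cache`
cachedRegistration <- function(db, fixedId, movingId, params, cache) {
  key <- regCacheKey(fixedId, movingId, params)
  if (!is.null(cache[[key]])) return(cache[[key]])
  fixed <- dbImage(db, fixedId, "qct")
  moving <- dbImage(db, movingId, "qct")
  mask <- if (dbHasImage(db, fixedId, "mask"))
    dbImage(db, fixedId, "mask") else NULL
  res <- registerPair(fixed, moving, params = params, fixedMask = mask)
  cache[[key]] <- res
  res
}

#' Pairwise deformation-distance matrix
#'
#' Registers every ordered pair of database records (row = fixed image p,
#' column = moving image q) and evaluates the log-stretch
#' [distanceMetric()] on the fixed image's control grid. The diagonal is
#' `NA`; failed registrations are flagged `NA` with a warning and excluded
#' from accumulated sums.
#'
#' @param db an [AtlasDatabase-class] with at least two records.
#' @param params a [registrationParams()] list.
#' @param gridSpacing control-grid spacing (mm).
#' @param cache environment memoizing registrations.
#' @return the database with its `dm` slot filled.
#' @export
pairwiseDM <- function(db, params = registrationParams(),
                       gridSpacing = 5.3, cache = new.env()) {
  ids <- db@records$id
  if (length(ids) < 2)
    fmStop("fmSelectionError", "pairwise DM needs >= 2 records")
  dm <- matrix(NA_real_, length(ids), length(ids),
               dimnames = list(ids, ids))
  for (p in ids) {
    grid <- targetControlGrid(db, p, gridSpacing)
    for (q in ids) {
      if (p == q) next
      dm[p, q] <- tryCatch({
        reg <- cachedRegistration(db, p, q, params, cache)
        distanceMetric(transformChain(reg), grid)
      }, fabricmapError = function(e) {
        fmWarn("fmRegistrationFailedWarning",
               "registration %s -> %s failed: %s", p, q,
               conditionMessage(e))
        NA_real_
      })
    }
  }
  db@dm <- dm
  db
}

#' Atlas selection strategies
#'
#' Selects a femur atlas for a target image from the pairwise DM matrix:
#' \describe{
#'   \item{CTP / CSP}{closest femur: argmin over candidates q of
#'     `DM(target, q)`, in the total / sex-specific population.}
#'   \item{FTP / FSP}{farthest femur: argmax of `DM(target, q)` (worst-case
#'     control).}
#'   \item{MTP / MSP}{population-mean femur: the real image minimizing the
#'     accumulated distance `sum_q DM(p, q)` over the candidate set.}
#' }
#' The target itself and its contralateral counterpart (same subject) are
#' always excluded. Ties break to the lexicographically smallest id.
#'
#' @param db an [AtlasDatabase-class] with a computed `dm` matrix
#'   (see [pairwiseDM()]).
#' @param targetId id of the target (patient) record.
#' @param mode one of `"CTP"`, `"CSP"`, `"FTP"`, `"FSP"`, `"MTP"`, `"MSP"`.
#' @return the selected record as a one-row data.frame.
#' @export
selectAtlas <- function(db, targetId,
                        mode = c("CTP", "CSP", "FTP", "FSP", "MTP", "MSP")) {
  mode <- match.arg(mode)
  if (nrow(db@dm) == 0)
    fmStop("fmSelectionError", "database has no DM matrix; run pairwiseDM")
  rec <- db@records
  target <- dbRecord(db, targetId)
  cand <- rec[rec$id != targetId & rec$subject != target$subject, ,
              drop = FALSE]
  if (endsWith(mode, "SP")) {
    if (is.na(target$sex) || target$sex == "unknown")
      fmStop("fmSelectionError",
             "sex-specific selection needs a known target sex")
    cand <- cand[cand$sex == target$sex, , drop = FALSE]
  }
  if (nrow(cand) == 0)
    fmStop("fmSelectionError", "empty candidate set for %s / %s",
           targetId, mode)
  cand <- cand[order(cand$id), , drop = FALSE]   # deterministic ties
  score <- switch(substr(mode, 1, 1),
    C = db@dm[targetId, cand$id],
    F = -db@dm[targetId, cand$id],
    M = vapply(cand$id, function(p) {
      v <- db@dm[p, setdiff(cand$id, p)]
      if (length(v) == 0) 0            # single candidate: trivially mean
      else if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
    }, numeric(1)))
  if (all(is.na(score)))
    fmStop("fmSelectionError", "no usable DM entries for %s / %s",
           targetId, mode)
  cand[which.min(score), , drop = FALSE]
}

#' Build a population fabric atlas
#'
#' Constructs a femur atlas carrying a population-mean fabric field: every
#' member's high-resolution image is registered to the atlas image
#' (fixed = atlas), the member's fabric is computed at the corresponding
#' points `T(x_j)`, mapped into atlas space with the complete-rotation (CR)
#' scheme, and averaged per control point with [meanTensor()].
#'
#' @param db an [AtlasDatabase-class].
#' @param atlasId id of the atlas record (must have an HR image).
#' @param params a [registrationParams()] list.
#' @param gridSpacing control-grid spacing (mm).
#' @param cache registration cache environment.
#' @return a [FabricField-class] on the atlas control grid; the attribute
#'   `"support"` counts contributing members per point (points with fewer
#'   than 2 contributors are flagged low-support).
#' @export
buildFabricAtlas <- function(db, atlasId, params = registrationParams(),
                             gridSpacing = 5.3, cache = new.env()) {
  what <- if (dbHasImage(db, atlasId, "hr")) "hr" else "qct"
  atlasImg <- dbImage(db, atlasId, what)
  mask <- if (dbHasImage(db, atlasId, "mask"))
    dbImage(db, atlasId, "mask") else NULL
  grid <- controlGrid(atlasImg, spacing = gridSpacing, mask = mask)
  n <- nrow(grid)
  sums <- vector("list", n)
  support <- integer(n)
  bvtvSum <- numeric(n); bvtvN <- integer(n)
  for (memberId in db@records$id) {
    mapped <- tryCatch({
      if (memberId == atlasId) {
        chain <- TransformChain()          # identity self-contribution
      } else {
        memberImg <- dbImage(db, memberId,
                             if (dbHasImage(db, memberId, "hr")) "hr"
                             else "qct")
        chain <- transformChain(registerPair(atlasImg, memberImg,
                                             params = params,
                                             fixedMask = mask))
      }
      fab <- correspondingFabric(db, memberId, chain, grid)
      mapField(fab, chain, "CR")
    }, fabricmapError = function(e) {
      fmWarn("fmRegistrationFailedWarning",
             "member %s excluded from fabric atlas: %s", memberId,
             conditionMessage(e))
      NULL
    })
    if (is.null(mapped)) next
    for (i in seq_len(n)) {
      if (mapped@flagged[i]) next
      M <- mapped@tensors[[i]]@matrix
      sums[[i]] <- if (is.null(sums[[i]])) M else sums[[i]] + M
      support[i] <- support[i] + 1L
      if (!is.na(mapped@bvtv[i])) {
        bvtvSum[i] <- bvtvSum[i] + mapped@bvtv[i]
        bvtvN[i] <- bvtvN[i] + 1L
      }
    }
  }
  tensors <- vector("list", n)
  for (i in seq_len(n))
    if (support[i] > 0) tensors[[i]] <- meanTensor(list(sums[[i]] /
                                                          support[i]))
  field <- FabricField(points = grid, tensors = tensors,
                       bvtv = ifelse(bvtvN > 0, bvtvSum / pmax(bvtvN, 1),
                                     NA_real_),
                       flagged = support < 2)
  attr(field, "support") <- support
  field
}
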