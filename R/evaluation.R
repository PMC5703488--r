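#' Fabric prediction error metrics
#'
#' Three complementary errors between a predicted and a ground-truth fabric
#' tensor:
#' \describe{
#'   \item{tnError}{relative tensor norm error
#'     \eqn{\|\hat M - M\|_F / \|M\|_F} (truth in the denominator).}
#'   \item{daError}{relative degree-of-anisotropy error
#'     \eqn{|\hat{DA} - DA| / DA} with `DA = m3/m1`.}
#'   \item{ptdError}{angular deviation of the principal tensor directions in
#'     degrees, `acos(|v_hat . v|)`; fabric axes are axial quantities so the
#'     absolute dot product clamps the error to `[0, 90]`.}
#' }
#'
#' @param predicted,truth [FabricTensor-class] objects (or SPD matrices).
#' @return scalar error (fraction for TN/DA, degrees for PTD).
#' @export
tnError <- function(predicted, truth) {
  P <- asTensorMatrix(predicted)
  M <- asTensorMatrix(truth)
  sqrt(sum((P - M)^2)) / sqrt(sum(M^2))
}

#' @rdname tnError
#' @export
daError <- function(predicted, truth) {
  da <- degreeOfAnisotropy(if (is(truth, "FabricTensor")) truth
                           else FabricTensor(truth))
  dah <- degreeOfAnisotropy(if (is(predicted, "FabricTensor")) predicted
                            else FabricTensor(predicted))
  abs(dah - da) / da
}

#' @rdname tnError
#' @export
ptdError <- function(predicted, truth) {
  if (!is(predicted, "FabricTensor")) predicted <- FabricTensor(predicted)
  if (!is(truth, "FabricTensor")) truth <- FabricTensor(truth)
  vp <- principalDirection(predicted)
  vt <- principalDirection(truth)
  if (isTRUE(attr(vp, "degenerate")) || isTRUE(attr(vt, "degenerate")))
    fmStop("fmDegeneracyError",
           "principal direction is degenerate; PTD undefined")
  acos(min(1, abs(sum(vp * vt)))) * 180 / pi
}

#' Leave-one-out evaluation plan
#'
#' Enumerates the LOO design: every image serves once as the target; its
#' candidate atlas pool is the whole database minus the target itself and
#' minus its contralateral counterpart (same `subject`, other side).
#'
#' @param db an [AtlasDatabase-class] (only `records` is used).
#' @return list with one element per target: `list(target =, candidates =)`;
#'   the attribute `"registrations"` carries the total count
#'   `sum(length(candidates))`.
#' @export
looPlan <- function(db) {
  rec <- db@records
  plan <- lapply(seq_len(nrow(rec)), function(i) {
    drop <- rec$id == rec$id[i] |
      (rec$subject == rec$subject[i] & rec$id != rec$id[i])
    # counterpart = same subject, different id; target = same id
    list(target = rec$id[i], candidates = rec$id[!drop])
  })
  attr(plan, "registrations") <- sum(vapply(plan, function(p)
    length(p$candidates), integer(1)))
  plan
}

#' BV/TV-binned error aggregation
#'
#' Assigns control points to half-open BV/TV bins `[lo, hi)` and aggregates
#' each error metric per bin (mean, sd, count). Empty bins are reported
#' with `NA` aggregates.
#'
#' @param perPoint data.frame with columns `bvtv` and one or more of
#'   `tn_error`, `da_error`, `ptd_error`.
#' @param edges increasing bin edges (default 0.05-wide bins over
#'   `[0, 0.5]`).
#' @return data.frame with one row per bin.
#' @export
bvtvBinnedErrors <- function(perPoint, edges = seq(0, 0.5, by = 0.05)) {
  if (is.unsorted(edges, strictly = TRUE))
    fmStop("fmParameterError", "bin edges must be strictly increasing")
  metrics <- intersect(c("tn_error", "da_error", "ptd_error"),
                       names(perPoint))
  nb <- length(edges) - 1
  bin <- findInterval(perPoint$bvtv, edges, rightmost.closed = FALSE,
                      left.open = FALSE)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1])
  out$n <- vapply(seq_len(nb), function(b) sum(bin == b, na.rm = TRUE),
                  numeric(1))
  for (m in metrics) {
    out[[paste0(m, "_mean")]] <- vapply(seq_len(nb), function(b) {
      v <- perPoint[[m]][bin == b & !is.na(bin)]
      if (length(v) == 0) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    out[[paste0(m, "_sd")]] <- vapply(seq_len(nb), function(b) {
      v <- perPoint[[m]][bin == b & !is.na(bin)]
      if (length(v) < 2) NA_real_ else sd(v, na.rm = TRUE)
    }, numeric(1))
  }
  out
}

# per-point errors between a predicted and a truth field on shared points
fieldErrors <- function(predicted, truth) {
  n <- nrow(predicted@points)
  tn <- da <- ptd <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (predicted@flagged[i] || truth@flagged[i]) next
    p <- predicted@tensors[[i]]; t <- truth@tensors[[i]]
    tn[i] <- tnError(p, t)
    da[i] <- daError(p, t)
    ptd[i] <- tryCatch(ptdError(p, t),
                       fmDegeneracyError = function(e) NA_real_)
  }
  data.frame(point = seq_len(n), tn_error = tn, da_error = da,
             ptd_error = ptd, bvtv = truth@bvtv)
}

#' Full factorial fabric-prediction experiment
#'
#' Runs the complete evaluation over every LOO target, atlas-selection mode
#' and mapping scheme: pairwise DM computation (once), atlas selection,
#' registration of the target to the selected atlas (cached and reused
#' across schemes), fabric mapping, and per-point error metrics against the
#' target's ground-truth fabric.
#'
#' @param db an [AtlasDatabase-class] whose records resolve to QCT images,
#'   masks and fabric (field, function or HR image).
#' @param modes atlas-selection modes, subset of
#'   `c("CTP","CSP","FTP","FSP","MTP","MSP")`.
#' @param schemes mapping schemes, subset of `c("NR","AR","AD","CR","CD")`.
#' @param params a [registrationParams()] list.
#' @param gridSpacing control-grid spacing (mm) for DM and fabric points.
#' @param cache environment reused across calls to avoid recomputing
#'   registrations.
#' @return list with `records` (data.frame of aggregates, one row per
#'   target x mode x scheme) and `perPoint` (named list of per-point error
#'   data.frames).
#' @export
runExperiment <- function(db, modes = "CTP", schemes = "CR",
                          params = registrationParams(),
                          gridSpacing = 5.3, cache = new.env()) {
  if (nrow(db@dm) == 0)
    db <- pairwiseDM(db, params = params, gridSpacing = gridSpacing,
                     cache = cache)
  plan <- looPlan(db)
  records <- list()
  perPoint <- list()
  for (p in plan) {
    target <- p$target
    for (mode in modes) {
      atlasId <- tryCatch(
        selectAtlas(db, target, mode)$id,
        fabricmapError = function(e) NA_character_)
      if (is.na(atlasId)) next
      reg <- cachedRegistration(db, fixedId = target, movingId = atlasId,
                                params = params, cache = cache)
      chain <- transformChain(reg)
      grid <- targetControlGrid(db, target, gridSpacing)
      truth <- recordFabric(db, target, grid)
      atlasFab <- correspondingFabric(db, atlasId, chain, grid)
      for (scheme in schemes) {
        mapped <- mapField(atlasFab, chain, scheme)
        errs <- fieldErrors(mapped, truth)
        key <- paste(target, mode, scheme, sep = "|")
        perPoint[[key]] <- errs
        records[[key]] <- data.frame(
          target = target, atlas = atlasId, mode = mode, scheme = scheme,
          dm = db@dm[target, atlasId],
          tn_mean = mean(errs$tn_error, na.rm = TRUE),
          tn_sd = sd(errs$tn_error, na.rm = TRUE),
          da_mean = mean(errs$da_error, na.rm = TRUE),
          da_sd = sd(errs$da_error, na.rm = TRUE),
          ptd_mean = mean(errs$ptd_error, na.rm = TRUE),
          ptd_sd = sd(errs$ptd_error, na.rm = TRUE),
          n_points = sum(!is.na(errs$tn_error)))
      }
    }
  }
  list(records = do.call(rbind, c(records, list(make.row.names = FALSE))),
       perPoint = perPoint)
}
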