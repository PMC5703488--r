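#' Pipeline configuration
#'
#' Collects all knobs of the end-to-end fabric prediction pipeline. Can be
#' read from a YAML file; explicit arguments override file values.
#'
#' @param mode atlas-selection mode (`"CTP"`, `"CSP"`, `"FTP"`, `"FSP"`,
#'   `"MTP"`, `"MSP"`).
#' @param scheme tensor mapping scheme (`"NR"`, `"AR"`, `"AD"`, `"CR"`,
#'   `"CD"`).
#' @param gridSpacing control-grid spacing (mm).
#' @param params a [registrationParams()] list.
#' @param seed integer seed recorded in provenance.
#' @param file optional YAML file with any of the above fields.
#' @return named list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(mode = "CTP", scheme = "CR", gridSpacing = 5.3,
                           params = registrationParams(), seed = 1L,
                           file = NULL) {
  y <- if (!is.null(file)) yaml::read_yaml(file) else list()
  pick <- function(name, arg, miss)
    if (miss && !is.null(y[[name]])) y[[name]] else arg
  cfg <- list(
    mode = pick("mode", mode, missing(mode)),
    scheme = pick("scheme", scheme, missing(scheme)),
    gridSpacing = pick("gridSpacing", gridSpacing, missing(gridSpacing)),
    params = if (missing(params) && !is.null(y$params))
      do.call(registrationParams, y$params) else params,
    seed = as.integer(pick("seed", seed, missing(seed))))
  if (!cfg$mode %in% c("CTP", "CSP", "FTP", "FSP", "MTP", "MSP"))
    fmStop("fmConfigError", "invalid atlas mode %s", cfg$mode)
  if (!cfg$scheme %in% c("NR", "AR", "AD", "CR", "CD"))
    fmStop("fmConfigError", "invalid mapping scheme %s", cfg$scheme)
  structure(cfg, class = "pipelineConfig")
}

#' End-to-end fabric prediction for a target image
#'
#' Orchestrates the full pipeline: atlas selection by deformation distance,
#' registration of the target (fixed) to the atlas (moving), establishment
#' of the atlas fabric at corresponding points, tensor mapping into the
#' target image, and a provenance report.
#'
#' @param db an [AtlasDatabase-class]; its records must include the target.
#'   If the database has no DM matrix, [pairwiseDM()] is run first.
#' @param targetId record id of the target (patient) image.
#' @param config a [pipelineConfig()].
#' @param cache registration cache environment.
#' @param outDir optional directory; when given, the predicted field is
#'   written to `predicted_fabric.csv` and the provenance to
#'   `provenance.json`.
#' @return list with `field` (predicted [FabricField-class]), `atlasId`,
#'   and `provenance` (list).
#' @export
predictFabric <- function(db, targetId, config = pipelineConfig(),
                          cache = new.env(), outDir = NULL) {
  stopifnot(inherits(config, "pipelineConfig"))
  if (nrow(db@dm) == 0)
    db <- pairwiseDM(db, params = config$params,
                     gridSpacing = config$gridSpacing, cache = cache)
  atlas <- selectAtlas(db, targetId, config$mode)
  reg <- cachedRegistration(db, fixedId = targetId, movingId = atlas$id,
                            params = config$params, cache = cache)
  chain <- transformChain(reg)
  grid <- targetControlGrid(db, targetId, config$gridSpacing)
  atlasFab <- correspondingFabric(db, atlas$id, chain, grid)
  mapped <- mapField(atlasFab, chain, config$scheme)
  dice <- tryCatch({
    if (dbHasImage(db, targetId, "mask") && dbHasImage(db, atlas$id, "mask"))
      diceQC(dbImage(db, targetId, "mask"), dbImage(db, atlas$id, "mask"),
             chain)
    else NA_real_
  }, fabricmapError = function(e) NA_real_)
  prov <- list(
    target = targetId, atlas = atlas$id, mode = config$mode,
    scheme = config$scheme, dm = unname(db@dm[targetId, atlas$id]),
    dice = dice, finalNCC = reg@finalNCC,
    foldingWarning = reg@foldingWarning,
    gridSpacing = config$gridSpacing, seed = config$seed,
    params = unclass(config$params),
    nPoints = nrow(grid), nFlagged = sum(mapped@flagged),
    package = as.character(utils::packageVersion("fabricmap")))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeFabricField(mapped, file.path(outDir, "predicted_fabric.csv"))
    jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(field = mapped, atlasId = atlas$id, provenance = prov)
}
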