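## End-to-end pipeline: containers in, JSON report + CSV tables + PNG maps
## out.

.defaultPipelineConfig <- function() {
  list(
    knownC = NULL, knownQ = NULL,
    geometryParameter = 4,
    shapeE = defaultShapeParameter(),
    windowLength = 256L, overlap = 0.5,
    thresholdDb = -15, volumeThresholdDb = -20, volumeBoundary = "peak",
    dynamicRange = 50, attenuationBand = c(20, 55),
    roiLateralMm = 0.6, roiElevationalMm = 5.0,
    ## calcium estimation: baseline impedance Q_0 plus scatterer/ECM
    ## acoustics; requires knownC for the scatterer count
    calcium = NULL,   # list(q0=, cScatterer=, rhoEcm=, cEcm=)
    maps = c("diameter", "cq2"),
    cFluid = 1480)
}

.mergeConfig <- function(config) {
  out <- .defaultPipelineConfig()
  for (nm in names(config)) out[[nm]] <- config[[nm]]
  out
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline on a container pair
#'
#' Reads the sample and reference RF containers, runs bulk analysis
#' (surfaces, thickness, speed of sound, attenuation, volume from serial
#' B-mode contours), spectral analysis (calibrated spectra, slope/MBF,
#' radius and acoustic concentration, optional C/Q completion and calcium
#' estimation), builds parametric maps, and writes a versioned JSON
#' report, CSV tables and PNG overlays to \code{outDir}.  Output is
#' deterministic for identical inputs and configuration.
#'
#' @param sampleDir,referenceDir RF container directories.
#' @param outDir output directory (created if needed).
#' @param config named list overriding pipeline defaults (see the methods
#'   vignette); notable entries: \code{knownC} or \code{knownQ},
#'   \code{calcium} (list with q0, cScatterer, rhoEcm, cEcm),
#'   \code{maps}, \code{windowLength}, \code{thresholdDb}.
#' @return The report, invisibly (also written as report.json).
#' @export
runPipeline <- function(sampleDir, referenceDir, outDir, config = list()) {
  cfg <- .mergeConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  volume <- .stage("read", readRFContainer(sampleDir))
  reference <- .stage("read", readRFContainer(referenceDir))
  medium <- mediumSpec(cFluid = cfg$cFluid)
  message("[pipeline] read: sample ", sampleDir, ", reference ", referenceDir)

  ana <- .stage("spectral", susiAnalysis(
    volume, reference, medium, knownC = cfg$knownC, knownQ = cfg$knownQ,
    n = cfg$geometryParameter, shapeE = cfg$shapeE,
    windowLength = cfg$windowLength, overlap = cfg$overlap,
    thresholdDb = cfg$thresholdDb, attenuationBand = cfg$attenuationBand))
  bulk <- ana$bulk
  message(sprintf("[pipeline] bulk: L=%.3f mm c_t=%.1f m/s alpha=%.3f",
                  thickness(bulk), soundSpeed(bulk), attenuation(bulk)))

  g <- volume@grid
  bmodes <- .stage("volume", lapply(seq_len(g@nSlices), function(k)
    bmodeImage(volume, k, cfg$dynamicRange)))
  ## exclude the gel-pad echo from the contour search
  gelIdx <- floor(ana$times@tGel / g@axialDt + 1) - 80L
  vol <- .stage("volume", constructVolume(
    bmodes, cfg$volumeThresholdDb, g@sliceSpacing,
    soundSpeed = soundSpeed(bulk), axialLimit = c(1L, gelIdx),
    boundary = cfg$volumeBoundary))
  message(sprintf("[pipeline] volume: %.3f mm^3", vol$volumeMm3))

  est <- ana$estimate
  est$equivalentScatterers <- equivalentScattererNumber(est$cq2,
                                                        vol$volumeMm3)
  wt <- ana$windowTable
  if (!is.null(cfg$calcium)) {
    ca <- cfg$calcium
    if (is.null(cfg$knownC))
      stop("[stage calcium] calcium estimation requires knownC")
    nScat <- cfg$knownC * vol$volumeMm3
    qi <- est$impedance
    cm <- .stage("calcium", calciumMass(
      ca$q0, qi, nScat, est$radiusUm,
      rhoEcm = ca$rhoEcm %||% 1000, cEcm = ca$cEcm %||% 1540,
      cScatterer = ca$cScatterer %||% 1540,
      constructVolumeMm3 = vol$volumeMm3))
    est$calciumMassUg <- cm$massUg
    est$calciumConcUgMl <- cm$concentrationUgMl
    ## per-window calcium concentration for mapping
    qiW <- sqrt(pmax(wt$cq2, 0) / cfg$knownC)
    wt$calciumConcUgMl <- vapply(seq_len(nrow(wt)), function(w) {
      if (!is.finite(qiW[w]) || !is.finite(wt$radiusUm[w])) return(NA_real_)
      m <- suppressWarnings(calciumMass(ca$q0, qiW[w], nScat, wt$radiusUm[w],
                                        rhoEcm = ca$rhoEcm %||% 1000,
                                        cEcm = ca$cEcm %||% 1540,
                                        cScatterer = ca$cScatterer %||% 1540,
                                        constructVolumeMm3 = vol$volumeMm3))
      m$concentrationUgMl
    }, numeric(1))
    message(sprintf("[pipeline] calcium: %.3g ug (%.3g ug/ml)",
                    cm$massUg, cm$concentrationUgMl))
  }
  roi <- .stage("roi", tryCatch(
    roiStatistics(wt, g, roiSpec(cfg$roiLateralMm, cfg$roiElevationalMm)),
    error = function(e) NULL))

  mapFiles <- list()
  for (pm in cfg$maps) {
    col <- .MAP_COLUMNS[[pm]]
    if (is.null(col) || !col %in% names(wt)) next
    mp <- .stage("map", buildParametricMap(bmodes[[1]], wt, pm,
                                           windowLength = cfg$windowLength))
    f <- file.path(outDir, paste0("map_", pm, ".png"))
    .stage("map", renderOverlay(bmodes[[1]], mp, f))
    mapFiles[[pm]] <- basename(f)
  }

  report <- list(
    schema_version = 1L,
    inputs = list(
      sample = basename(sampleDir), reference = basename(referenceDir),
      sample_md5 = unname(tools::md5sum(file.path(sampleDir, "metadata.json"))),
      reference_md5 = unname(tools::md5sum(file.path(referenceDir, "metadata.json")))),
    parameters = cfg[c("geometryParameter", "shapeE", "windowLength",
                       "overlap", "thresholdDb", "volumeThresholdDb",
                       "attenuationBand", "cFluid")],
    bulk = list(thickness_mm = thickness(bulk),
                sound_speed_mps = soundSpeed(bulk),
                attenuation_db_cm_mhz = attenuation(bulk),
                attenuation_fit_r2 = bulk@fitR2),
    volume = list(volume_mm3 = vol$volumeMm3,
                  per_slice_area_mm2 = vol$perSliceAreaMm2),
    spectral = est,
    roi = if (!is.null(roi)) list(per_roi = roi$perRoi,
                                  construct = as.list(roi$construct)),
    maps = mapFiles)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  utils::write.csv(wt, file.path(outDir, "windows.csv"), row.names = FALSE)
  for (s in seq_along(vol$contours))
    utils::write.csv(vol$contours[[s]],
                     file.path(outDir, sprintf("contour_%03d.csv", s)),
                     row.names = FALSE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
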