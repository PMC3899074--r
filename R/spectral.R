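## Calibrated power spectra, slope/MBF regression and attenuation
## correction.

#' Calibrated per-window power spectra
#'
#' Sliding Hamming-tapered windows along each valid A-line interior
#' (between the detected top and bottom surfaces, excluding a margin around
#' each surface echo) are Fourier transformed and divided by the
#' calibration spectrum, the ensemble-averaged power spectrum of the
#' gel-pad echo of the reference scan:
#' \code{S(f) = 10 log10(|FFT(sample window)|^2 / |FFT(reference)|^2)}.
#' The analysis band is the -9 dB span of the calibration spectrum
#' intersected with the transducer band.
#'
#' @slot freq frequency grid, MHz.
#' @slot spectraDb windows x frequency matrix of calibrated dB values.
#' @slot windows per-window table (slice, line, center sample, depth z mm).
#' @slot band analysis band c(lo, hi), MHz.
#' @slot fCenter band center frequency, MHz.
#' @slot refDb calibration spectrum, dB (arbitrary reference).
#' @name CalibratedSpectra-class
#' @rdname CalibratedSpectra
#' @exportClass CalibratedSpectra
setClass("CalibratedSpectra",
  representation(freq = "numeric", spectraDb = "matrix",
                 windows = "data.frame", band = "numeric",
                 fCenter = "numeric", refDb = "numeric"))

setMethod("show", "CalibratedSpectra", function(object) {
  cat(sprintf("CalibratedSpectra: %d windows, band %.1f-%.1f MHz (center %.1f)\n",
              nrow(object@spectraDb), object@band[1], object@band[2],
              object@fCenter))
})

#' @rdname CalibratedSpectra
#' @param volume sample \linkS4class{RFVolume}.
#' @param reference matching reference \linkS4class{RFVolume}.
#' @param times \linkS4class{EchoTimes} from \code{\link{detectSurfaces}}.
#' @param soundSpeed in-sample sound speed for depth conversion, m/s.
#' @param windowLength window length, samples.
#' @param overlap fractional window overlap in [0, 1).
#' @param margin samples excluded next to each surface echo.
#' @return A \linkS4class{CalibratedSpectra}.
#' @export
calibratedSpectrum <- function(volume, reference, times,
                               soundSpeed = 1540, windowLength = 256L,
                               overlap = 0.5, margin = 40L) {
  stopifnot(is(volume, "RFVolume"), is(reference, "RFVolume"))
  if (!identical(dim(volume@samples), dim(reference@samples)))
    stop("sample and reference scans must share the acquisition grid")
  g <- volume@grid
  fs <- 1 / g@axialDt
  half <- windowLength %/% 2
  freq <- (0:half) * fs / windowLength / 1e6
  perLine <- times@perLine
  ## calibration spectrum: mean power of the reference gel-pad echo
  refPow <- numeric(half + 1L); nRef <- 0L
  for (r in which(perLine$valid)) {
    A0 <- .echoSpectrum(reference@samples[, perLine$line[r], perLine$slice[r]],
                        perLine$tRef[r] / g@axialDt + 1, windowLength)
    if (is.null(A0)) next
    refPow <- refPow + A0^2; nRef <- nRef + 1L
  }
  if (nRef == 0L) stop("no usable reference gel-pad echo windows")
  refPow <- refPow / nRef
  ## analysis band: -9 dB span of the calibration spectrum within the
  ## transducer band
  refDb <- 10 * log10(refPow + .Machine$double.xmin)
  tband <- analysisBand(volume@transducer)
  inT <- freq >= tband[1] & freq <= tband[2] & freq > 0
  sel <- inT & (refDb >= max(refDb[inT]) - 9)
  if (sum(sel) < 5L) stop("analysis band narrower than 5 points")
  band <- range(freq[sel])
  step <- max(1L, round(windowLength * (1 - overlap)))
  taper <- 0.54 - 0.46 * cos(2 * pi * seq(0, windowLength - 1) /
                               (windowLength - 1))
  specs <- list(); meta <- list(); w <- 0L
  for (r in which(perLine$valid)) {
    k <- perLine$slice[r]; i <- perLine$line[r]
    topIdx <- perLine$tTop[r] / g@axialDt + 1
    botIdx <- perLine$tBot[r] / g@axialDt + 1
    lo <- ceiling(topIdx + margin + half)
    hi <- floor(botIdx - margin - half)
    if (hi < lo) next
    centers <- seq(lo, hi, by = step)
    trace <- volume@samples[, i, k]
    for (ctr in centers) {
      seg <- trace[(ctr - half):(ctr + half - 1L)]
      P <- abs(stats::fft(seg * taper))[seq_len(half + 1L)]^2
      w <- w + 1L
      specs[[w]] <- 10 * log10(P / refPow + .Machine$double.xmin)
      zMm <- (ctr - topIdx) * g@axialDt * soundSpeed / 2 * 1000
      meta[[w]] <- data.frame(slice = k, line = i, center = ctr, zMm = zMm)
    }
  }
  if (w == 0L) stop("no analysis windows fit inside the sample interior")
  new("CalibratedSpectra", freq = freq,
      spectraDb = do.call(rbind, specs),
      windows = do.call(rbind, meta),
      band = band, fCenter = mean(band), refDb = refDb)
}

#' Spectral slope and mid-band fit by linear regression
#'
#' Ordinary least squares of the calibrated spectrum (dB) against
#' frequency (MHz) over the analysis band; the slope is m' (dB/MHz) and the
#' mid-band fit MBF' is the fitted value at the band center frequency.
#'
#' @param freqMhz frequency grid, MHz.
#' @param spectrumDb calibrated spectrum, dB.
#' @param band analysis band c(lo, hi), MHz.
#' @param fCenter evaluation frequency for the MBF (band midpoint by
#'   default).
#' @return List with \code{slope} (dB/MHz), \code{mbf} (dB), \code{band},
#'   \code{fCenter} and \code{bandFreqs} (the grid points regressed on).
#' @export
fitSlopeMBF <- function(freqMhz, spectrumDb, band = range(freqMhz),
                        fCenter = mean(band)) {
  sel <- freqMhz >= band[1] & freqMhz <= band[2]
  if (sum(sel) < 5L) stop("band narrower than 5 regression points")
  f <- freqMhz[sel]; y <- spectrumDb[sel]
  slope <- .olsSlope(f, y)
  list(slope = slope, mbf = mean(y) + slope * (fCenter - mean(f)),
       band = band, fCenter = fCenter, bandFreqs = f)
}

#' Attenuation correction of spectral parameters
#'
#' \code{m = m' + 2 alpha z} and \code{MBF = MBF' + 2 alpha z f_c}, with
#' alpha in dB/(cm MHz) and the window-center one-way depth z in cm.
#'
#' @param slope raw slope m', dB/MHz.
#' @param mbf raw mid-band fit MBF', dB.
#' @param alpha attenuation coefficient, dB/(cm MHz).
#' @param zCm one-way propagation depth in the sample, cm.
#' @param fCenter band center frequency, MHz.
#' @return List with corrected \code{slope} and \code{mbf}.
#' @export
correctAttenuation <- function(slope, mbf, alpha, zCm, fCenter) {
  if (any(zCm < 0)) stop("depth z must be non-negative")
  list(slope = slope + 2 * alpha * zCm,
       mbf = mbf + 2 * alpha * zCm * fCenter)
}

#' Ensemble calibrated spectrum
#'
#' Averages per-window calibrated power linearly (not in dB) after
#' depth-resolved attenuation compensation of each window
#' (+2 alpha z f dB), yielding the attenuation-corrected ensemble spectrum
#' used for stable slope/MBF regression.
#'
#' @param cs a \linkS4class{CalibratedSpectra}.
#' @param alpha attenuation coefficient, dB/(cm MHz).
#' @return List with \code{freq} and \code{db}.
#' @export
ensembleSpectrum <- function(cs, alpha = 0) {
  zCm <- cs@windows$zMm / 10
  gain <- outer(2 * alpha * zCm, cs@freq)      # dB, windows x freq
  pow <- 10^((cs@spectraDb + gain) / 10)
  list(freq = cs@freq, db = 10 * log10(colMeans(pow)))
}

#' Per-window spectral fits with attenuation correction
#'
#' @param cs a \linkS4class{CalibratedSpectra}.
#' @param alpha attenuation coefficient, dB/(cm MHz).
#' @return data.frame with one row per window: slice, line, center, zMm,
#'   slopeRaw, mbfRaw, slope, mbf.
#' @export
spectralFits <- function(cs, alpha = 0) {
  n <- nrow(cs@spectraDb)
  out <- cs@windows
  out$slopeRaw <- out$mbfRaw <- out$slope <- out$mbf <- NA_real_
  for (w in seq_len(n)) {
    fit <- fitSlopeMBF(cs@freq, cs@spectraDb[w, ], cs@band, cs@fCenter)
    corr <- correctAttenuation(fit$slope, fit$mbf, alpha,
                               out$zMm[w] / 10, cs@fCenter)
    out$slopeRaw[w] <- fit$slope; out$mbfRaw[w] <- fit$mbf
    out$slope[w] <- corr$slope; out$mbf[w] <- corr$mbf
  }
  out
}

#' Full spectral scatterer analysis of a scan pair
#'
#' Runs the complete estimation chain: surface detection, time-of-flight
#' thickness and speed of sound, attenuation coefficient, calibrated
#' spectra, slope/MBF regression with attenuation correction, and
#' inversion to effective scatterer radius and acoustic concentration.
#' The headline estimates come from the attenuation-compensated ensemble
#' spectrum; per-window estimates (for parametric maps and ROI statistics)
#' are also returned, with non-physical inversions left NA.
#'
#' @param volume sample \linkS4class{RFVolume}.
#' @param reference reference \linkS4class{RFVolume}.
#' @param medium a \linkS4class{MediumSpec}.
#' @param knownC known number concentration, /mm^3 (optional).
#' @param knownQ known relative impedance (optional).
#' @param n geometry exponent.
#' @param shapeE shape/system constant E, dB.
#' @param windowLength,overlap spectral window settings.
#' @param thresholdDb surface-detection threshold, dB.
#' @param attenuationBand attenuation fit band, MHz.
#' @return List with \code{bulk} (\linkS4class{BulkProperties}),
#'   \code{times}, \code{spectra}, \code{windowTable} (per-window fits and
#'   inversions), and \code{estimate}: ensemble slope/MBF, diameter (um),
#'   cq2 (/mm^3) and, when one of C/Q is supplied, the completed pair.
#' @export
susiAnalysis <- function(volume, reference, medium = mediumSpec(),
                         knownC = NULL, knownQ = NULL, n = 4,
                         shapeE = defaultShapeParameter(),
                         windowLength = 256L, overlap = 0.5,
                         thresholdDb = -15, attenuationBand = c(20, 55)) {
  times <- detectSurfaces(volume, reference, thresholdDb = thresholdDb)
  ts <- thicknessAndSpeed(times, medium)
  att <- attenuationCoefficient(volume, reference, times, ts$thickness,
                                fitBand = attenuationBand,
                                windowLength = windowLength)
  bulk <- new("BulkProperties", thickness = ts$thickness,
              soundSpeed = ts$soundSpeed, attenuation = att$coefficient,
              attenuationBand = attenuationBand, fitR2 = att$r2)
  cs <- calibratedSpectrum(volume, reference, times,
                           soundSpeed = ts$soundSpeed,
                           windowLength = windowLength, overlap = overlap)
  alpha <- max(att$coefficient, 0)
  wt <- spectralFits(cs, alpha)
  wt$radiusUm <- radiusFromSlope(wt$slope, .bandFreqs(cs), n, ts$soundSpeed)
  wt$diameterUm <- 2 * wt$radiusUm
  wt$cq2 <- acousticConcentration(wt$mbf, wt$radiusUm, .bandFreqs(cs),
                                  cs@fCenter, shapeE, n, ts$soundSpeed)
  ens <- ensembleSpectrum(cs, alpha)
  fit <- fitSlopeMBF(ens$freq, ens$db, cs@band, cs@fCenter)
  radius <- radiusFromSlope(fit$slope, fit$bandFreqs, n, ts$soundSpeed)
  cq2 <- acousticConcentration(fit$mbf, radius, fit$bandFreqs, cs@fCenter,
                               shapeE, n, ts$soundSpeed)
  estimate <- list(slope = fit$slope, mbf = fit$mbf,
                   radiusUm = radius, diameterUm = 2 * radius, cq2 = cq2)
  if (!is.null(knownC) || !is.null(knownQ)) {
    comp <- concentrationAndImpedance(cq2, knownC, knownQ)
    estimate$concentration <- comp$concentration
    estimate$impedance <- comp$impedance
  }
  list(bulk = bulk, times = times, spectra = cs, windowTable = wt,
       estimate = estimate)
}

.bandFreqs <- function(cs)
  cs@freq[cs@freq >= cs@band[1] & cs@freq <= cs@band[2]]

#' Region-of-interest specification
#'
#' Analysis element dimensions for ROI statistics; defaults are a
#' 0.6 mm x 5.0 mm element spanning the full construct thickness.
#'
#' @param lateralMm lateral extent, mm.
#' @param elevationalMm elevational extent, mm.
#' @param axialMm axial extent, mm (Inf = full thickness).
#' @return A list with class "RoiSpec".
#' @export
roiSpec <- function(lateralMm = 0.6, elevationalMm = 5.0, axialMm = Inf) {
  stopifnot(lateralMm > 0, elevationalMm > 0, axialMm > 0)
  structure(list(lateralMm = lateralMm, elevationalMm = elevationalMm,
                 axialMm = axialMm), class = "RoiSpec")
}

#' Per-ROI statistics of window-level estimates
#'
#' Assigns windows to ROI elements by their center coordinates and returns
#' the mean and standard deviation of the requested parameters per ROI,
#' plus construct-level means weighted by ROI window counts.  ROIs with
#' fewer than \code{minWindows} windows (or with only non-physical,
#' excluded inversions) are dropped with a message.
#'
#' @param windowTable per-window table from \code{\link{susiAnalysis}} (or
#'   \code{\link{spectralFits}}).
#' @param grid the scan's \linkS4class{AcquisitionGrid} (for spacings).
#' @param roi an \code{\link{roiSpec}}.
#' @param params columns of \code{windowTable} to summarize.
#' @param minWindows minimum windows per ROI.
#' @return List with \code{perRoi} (data.frame) and \code{construct}
#'   (named means).
#' @export
roiStatistics <- function(windowTable, grid, roi = roiSpec(),
                          params = c("diameterUm", "cq2"),
                          minWindows = 5L) {
  ## line i sits at lateral position i * spacing, so a 0.6 mm element at
  ## 31 um spacing spans floor(600/31) = 19 A-lines
  latMm <- windowTable$line * grid@lateralSpacing / 1000
  elevMm <- windowTable$slice * grid@sliceSpacing / 1000
  roiId <- paste(floor(latMm / roi$lateralMm),
                 floor(elevMm / roi$elevationalMm), sep = ":")
  rows <- list()
  for (id in unique(roiId)) {
    sel <- roiId == id
    if (sum(sel) < minWindows) {
      message("ROI ", id, " excluded: fewer than ", minWindows, " windows")
      next
    }
    stats <- lapply(params, function(p) {
      v <- windowTable[[p]][sel]
      v <- v[is.finite(v)]
      c(mean = mean(v), sd = stats::sd(v), n = length(v))
    })
    row <- data.frame(roi = id, nWindows = sum(sel))
    for (j in seq_along(params)) {
      row[[paste0(params[j], "Mean")]] <- stats[[j]]["mean"]
      row[[paste0(params[j], "Sd")]] <- stats[[j]]["sd"]
    }
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) stop("no ROI met the minimum window count")
  perRoi <- do.call(rbind, rows)
  rownames(perRoi) <- NULL
  construct <- vapply(params, function(p) {
    m <- perRoi[[paste0(p, "Mean")]]
    stats::weighted.mean(m, perRoi$nWindows, na.rm = TRUE)
  }, numeric(1))
  list(perRoi = perRoi, construct = construct)
}

#' Calibrate the shape/system constant E against the simulator
#'
#' Simulates noise-free, attenuation-free scans of a reference
#' configuration with known ground truth, runs the standard analysis
#' chain, and solves the MBF model for E using the true radius and
#' acoustic concentration.  The mean over seeds is the calibration; the
#' frozen package default (\code{\link{defaultShapeParameter}}) was
#' produced by this procedure at the default settings.
#'
#' @param seeds integer seeds to average over.
#' @param config calibration configuration (defaults: 14 um scatterers,
#'   C = 1000 /mm^3, Q = 0.6, no attenuation, noise-free).
#' @param transducer,medium acquisition settings.
#' @param nLines A-lines per scan.
#' @param windowLength,overlap analysis window settings.
#' @return E in dB (scalar); per-seed values as attribute "perSeed".
#' @export
calibrateShapeParameter <- function(seeds = 1:8,
                                    config = phantomConfig(attenuation = 0,
                                                           snrDb = Inf),
                                    transducer = transducerSpec(),
                                    medium = mediumSpec(),
                                    nLines = 30L,
                                    windowLength = 256L, overlap = 0.5) {
  perSeed <- vapply(seeds, function(sd) {
    scan <- simulateScan(config, transducer, medium, nLines = nLines,
                         seed = sd)
    times <- detectSurfaces(scan$sample, scan$reference)
    ts <- thicknessAndSpeed(times, medium)
    cs <- calibratedSpectrum(scan$sample, scan$reference, times,
                             soundSpeed = ts$soundSpeed,
                             windowLength = windowLength, overlap = overlap)
    ens <- ensembleSpectrum(cs, 0)
    fit <- fitSlopeMBF(ens$freq, ens$db, cs@band, cs@fCenter)
    truthMbf <- mbfForScatterers(config@scattererDiameter / 2,
                                 config@concentration * config@impedance^2,
                                 fit$bandFreqs, cs@fCenter, shapeE = 0,
                                 n = config@geometryParameter,
                                 soundSpeed = config@soundSpeed)
    fit$mbf - truthMbf
  }, numeric(1))
  structure(mean(perSeed), perSeed = perSeed)
}
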