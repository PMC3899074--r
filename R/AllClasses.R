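#' @import methods
NULL

## ---------------------------------------------------------------------------
## Acquisition-side classes
## ---------------------------------------------------------------------------

#' Transducer specification
#'
#' Describes the single-element high-frequency transducer used for
#' acquisition: nominal center frequency, the -6 dB analysis band, focal
#' geometry and the RF sampling rate.  The analysis band is stored by its
#' endpoints because for real probes it need not be centered on the nominal
#' center frequency (the default probe is nominally 55 MHz with a
#' 20--75 MHz band).
#'
#' @slot centerFrequency nominal center frequency, MHz.
#' @slot bandLow,bandHigh -6 dB band endpoints, MHz.
#' @slot focalDistance focal distance, mm.
#' @slot depthOfFocus -6 dB depth of focus, mm.
#' @slot samplingRate RF sampling rate, samples/s.
#' @name TransducerSpec-class
#' @rdname TransducerSpec
#' @exportClass TransducerSpec
setClass("TransducerSpec",
  representation(
    centerFrequency = "numeric",
    bandLow         = "numeric",
    bandHigh        = "numeric",
    focalDistance   = "numeric",
    depthOfFocus    = "numeric",
    samplingRate    = "numeric"
  )
)

setValidity("TransducerSpec", function(object) {
  msgs <- character()
  if (object@centerFrequency <= 0) msgs <- c(msgs, "centerFrequency must be > 0")
  if (object@bandLow <= 0 || object@bandHigh <= object@bandLow)
    msgs <- c(msgs, "band endpoints must satisfy 0 < bandLow < bandHigh")
  nyq <- object@samplingRate / 2 / 1e6
  if (object@bandHigh >= nyq)
    msgs <- c(msgs, sprintf("band must lie below Nyquist (%.1f MHz)", nyq))
  if (object@samplingRate <= 0) msgs <- c(msgs, "samplingRate must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TransducerSpec
#'
#' Defaults match the RMV-708-class probe emulated throughout the package:
#' 55 MHz nominal center frequency, 20--75 MHz (-6 dB) band, 4.5 mm focal
#' distance, 1.5 mm depth of focus, 420 MS/s sampling.
#'
#' @param centerFrequency MHz.
#' @param bandLow,bandHigh -6 dB band endpoints, MHz.
#' @param focalDistance mm.
#' @param depthOfFocus mm.
#' @param samplingRate samples/s.
#' @return A \linkS4class{TransducerSpec}.
#' @export
#' @examples
#' transducerSpec()
transducerSpec <- function(centerFrequency = 55, bandLow = 20, bandHigh = 75,
                           focalDistance = 4.5, depthOfFocus = 1.5,
                           samplingRate = 420e6) {
  new("TransducerSpec", centerFrequency = centerFrequency,
      bandLow = bandLow, bandHigh = bandHigh,
      focalDistance = focalDistance, depthOfFocus = depthOfFocus,
      samplingRate = samplingRate)
}

#' Acquisition grid geometry
#'
#' Sample/line/slice counts and spacings for a 3D RF scan.  Defaults follow
#' the acquisition emulated by the simulator: 31 um between adjacent
#' A-lines and 200 um between adjacent B-scan slices.
#'
#' @slot axialDt axial sample period, s (1/samplingRate).
#' @slot lateralSpacing A-line spacing, um.
#' @slot sliceSpacing B-scan slice spacing, um.
#' @slot nSamples,nLines,nSlices array dimensions.
#' @name AcquisitionGrid-class
#' @rdname AcquisitionGrid
#' @exportClass AcquisitionGrid
setClass("AcquisitionGrid",
  representation(
    axialDt        = "numeric",
    lateralSpacing = "numeric",
    sliceSpacing   = "numeric",
    nSamples       = "integer",
    nLines         = "integer",
    nSlices        = "integer"
  )
)

setValidity("AcquisitionGrid", function(object) {
  msgs <- character()
  if (object@axialDt <= 0) msgs <- c(msgs, "axialDt must be > 0")
  if (object@lateralSpacing <= 0) msgs <- c(msgs, "lateralSpacing must be > 0")
  if (object@sliceSpacing <= 0) msgs <- c(msgs, "sliceSpacing must be > 0")
  if (any(c(object@nSamples, object@nLines, object@nSlices) < 1L))
    msgs <- c(msgs, "all dimension counts must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct an AcquisitionGrid
#'
#' @param nSamples,nLines,nSlices array dimensions.
#' @param axialDt axial sample period in s; default 1/420e6.
#' @param lateralSpacing A-line spacing, um.
#' @param sliceSpacing slice spacing, um.
#' @return An \linkS4class{AcquisitionGrid}.
#' @export
acquisitionGrid <- function(nSamples, nLines, nSlices = 1L,
                            axialDt = 1 / 420e6,
                            lateralSpacing = 31, sliceSpacing = 200) {
  new("AcquisitionGrid", axialDt = axialDt,
      lateralSpacing = lateralSpacing, sliceSpacing = sliceSpacing,
      nSamples = as.integer(nSamples), nLines = as.integer(nLines),
      nSlices = as.integer(nSlices))
}

#' RF volume
#'
#' A 3D stack of raw backscattered RF A-lines (axial x lateral x slice,
#' arbitrary linear amplitude units) together with its acquisition grid,
#' transducer specification and a kind flag distinguishing a sample scan
#' from the matching no-sample reference scan.
#'
#' @slot samples 3D numeric array, axial x lateral x slice.
#' @slot grid an \linkS4class{AcquisitionGrid}.
#' @slot transducer a \linkS4class{TransducerSpec}.
#' @slot kind "sample" or "reference".
#' @name RFVolume-class
#' @rdname RFVolume
#' @exportClass RFVolume
setClass("RFVolume",
  representation(
    samples    = "array",
    grid       = "AcquisitionGrid",
    transducer = "TransducerSpec",
    kind       = "character"
  )
)

setValidity("RFVolume", function(object) {
  msgs <- character()
  d <- dim(object@samples)
  if (length(d) != 3L)
    return("samples must be a 3D array (axial x lateral x slice)")
  g <- object@grid
  if (!identical(d, c(g@nSamples, g@nLines, g@nSlices)))
    msgs <- c(msgs, "array dimensions do not match grid counts")
  if (!all(is.finite(object@samples)))
    msgs <- c(msgs, "samples must be finite (no NA/NaN/Inf)")
  if (!object@kind %in% c("sample", "reference"))
    msgs <- c(msgs, "kind must be 'sample' or 'reference'")
  if (length(msgs)) msgs else TRUE
})

#' Construct an RFVolume
#'
#' @param samples 3D numeric array (axial x lateral x slice).
#' @param grid \linkS4class{AcquisitionGrid}; defaults to one matching the
#'   array dimensions.
#' @param transducer \linkS4class{TransducerSpec}.
#' @param kind "sample" or "reference".
#' @return An \linkS4class{RFVolume}.
#' @export
rfVolume <- function(samples, grid = NULL, transducer = transducerSpec(),
                     kind = "sample") {
  d <- dim(samples)
  if (is.null(grid))
    grid <- acquisitionGrid(d[1], d[2], d[3],
                            axialDt = 1 / transducer@samplingRate)
  new("RFVolume", samples = samples, grid = grid,
      transducer = transducer, kind = kind)
}

#' Medium specification
#'
#' Sound speed of the coupling fluid plus mass density and sound speed of
#' the extracellular matrix (background medium of the scatterers); used by
#' time-of-flight geometry (fluid) and the impedance/calcium model (ECM).
#'
#' @slot cFluid coupling fluid sound speed, m/s (default 1480).
#' @slot rhoEcm ECM mass density, kg/m^3.
#' @slot cEcm ECM sound speed, m/s.
#' @name MediumSpec-class
#' @rdname MediumSpec
#' @exportClass MediumSpec
setClass("MediumSpec",
  representation(cFluid = "numeric", rhoEcm = "numeric", cEcm = "numeric"))

setValidity("MediumSpec", function(object) {
  if (object@cFluid <= 0 || object@rhoEcm <= 0 || object@cEcm <= 0)
    "all MediumSpec fields must be positive" else TRUE
})

#' Construct a MediumSpec
#'
#' @param cFluid coupling fluid sound speed, m/s.
#' @param rhoEcm ECM density, kg/m^3.
#' @param cEcm ECM sound speed, m/s.
#' @return A \linkS4class{MediumSpec}.
#' @export
mediumSpec <- function(cFluid = 1480, rhoEcm = 1000, cEcm = 1540) {
  new("MediumSpec", cFluid = cFluid, rhoEcm = rhoEcm, cEcm = cEcm)
}

#' B-mode image
#'
#' Log-compressed envelope of one RF slice, in dB relative to the slice
#' maximum, clipped to [-dynamicRange, 0].
#'
#' @slot values axial x lateral matrix of dB values.
#' @slot dynamicRange display dynamic range, dB.
#' @slot axialDt axial sample period, s.
#' @slot lateralSpacing A-line spacing, um.
#' @slot sliceIndex source slice index.
#' @name BModeImage-class
#' @rdname BModeImage
#' @exportClass BModeImage
setClass("BModeImage",
  representation(
    values         = "matrix",
    dynamicRange   = "numeric",
    axialDt        = "numeric",
    lateralSpacing = "numeric",
    sliceIndex     = "integer"
  )
)

setValidity("BModeImage", function(object) {
  msgs <- character()
  if (object@dynamicRange <= 0) msgs <- c(msgs, "dynamicRange must be > 0")
  v <- object@values
  if (any(v > 1e-9 | v < -object@dynamicRange - 1e-9))
    msgs <- c(msgs, "values must lie within [-dynamicRange, 0]")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Simulator configuration classes
## ---------------------------------------------------------------------------

#' Simulated transmit pulse
#'
#' Gaussian-envelope sinusoid sampled at the transducer sampling rate.
#'
#' @slot centerFrequency MHz.
#' @slot fractionalBandwidth -6 dB spectral full width / center frequency.
#' @slot duration s.
#' @slot waveform sampled real waveform.
#' @slot dt sample period, s.
#' @name PulseModel-class
#' @rdname PulseModel
#' @exportClass PulseModel
setClass("PulseModel",
  representation(
    centerFrequency     = "numeric",
    fractionalBandwidth = "numeric",
    duration            = "numeric",
    waveform            = "numeric",
    dt                  = "numeric"
  )
)

#' Phantom / construct configuration for the simulator
#'
#' Ground-truth description of one simulated sample: monodisperse spherical
#' scatterers Poisson-placed in a homogeneous slab, with interface echoes
#' at the top surface, bottom surface and an agarose gel pad below.
#'
#' @slot scattererDiameter 2a, um.
#' @slot concentration number concentration C, /mm^3.
#' @slot impedance relative acoustic impedance Q (dimensionless).
#' @slot soundSpeed sample interior sound speed c_t, m/s.
#' @slot attenuation attenuation coefficient alpha, dB/(cm*MHz).
#' @slot thickness sample thickness L, mm.
#' @slot standoff fluid path from transducer to sample top, mm.
#' @slot gelpadGap fluid gap between sample bottom and gel pad, mm.
#' @slot geometryParameter scatterer geometry exponent n (4 = Rayleigh
#'   spheres).
#' @slot beamRadius effective scattering-tube radius, mm.
#' @slot constructRadius lateral radius of the sample disc, mm (Inf =
#'   laterally unbounded slab).
#' @slot snrDb additive white noise level, dB (Inf = noise-free).
#' @slot reflectivity amplitude reflectivities of the top / bottom / gel-pad
#'   interfaces.
#' @name PhantomConfig-class
#' @rdname PhantomConfig
#' @exportClass PhantomConfig
setClass("PhantomConfig",
  representation(
    scattererDiameter = "numeric",
    concentration     = "numeric",
    impedance         = "numeric",
    soundSpeed        = "numeric",
    attenuation       = "numeric",
    thickness         = "numeric",
    standoff          = "numeric",
    gelpadGap         = "numeric",
    geometryParameter = "numeric",
    beamRadius        = "numeric",
    constructRadius   = "numeric",
    snrDb             = "numeric",
    reflectivity      = "numeric"
  )
)

setValidity("PhantomConfig", function(object) {
  msgs <- character()
  if (object@scattererDiameter <= 0) msgs <- c(msgs, "scattererDiameter must be > 0")
  if (object@concentration < 0) msgs <- c(msgs, "concentration must be >= 0")
  if (object@impedance < 0) msgs <- c(msgs, "impedance must be >= 0")
  if (object@thickness <= 0) msgs <- c(msgs, "thickness must be > 0")
  if (object@scattererDiameter / 1000 >= object@thickness)
    msgs <- c(msgs, "scatterer diameter must be smaller than sample thickness")
  if (object@attenuation < 0) msgs <- c(msgs, "attenuation must be >= 0")
  if (length(object@reflectivity) != 3L)
    msgs <- c(msgs, "reflectivity must have 3 elements (top, bottom, gel)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PhantomConfig
#'
#' @param scattererDiameter um.
#' @param concentration /mm^3 (1e6 scatterers/ml = 1000 /mm^3).
#' @param impedance relative impedance Q.
#' @param soundSpeed m/s.
#' @param attenuation dB/(cm*MHz).
#' @param thickness mm.
#' @param standoff mm.
#' @param gelpadGap mm.
#' @param geometryParameter n.
#' @param beamRadius mm.
#' @param constructRadius mm.
#' @param snrDb dB; Inf disables noise.
#' @param reflectivity length-3 amplitudes (top, bottom, gel pad).
#' @return A \linkS4class{PhantomConfig}.
#' @export
phantomConfig <- function(scattererDiameter = 14, concentration = 1000,
                          impedance = 0.6, soundSpeed = 1540,
                          attenuation = 0.5, thickness = 2,
                          standoff = 2, gelpadGap = 0.5,
                          geometryParameter = 4, beamRadius = 0.1,
                          constructRadius = Inf, snrDb = 30,
                          reflectivity = c(0.1, 0.1, 0.1)) {
  new("PhantomConfig", scattererDiameter = scattererDiameter,
      concentration = concentration, impedance = impedance,
      soundSpeed = soundSpeed, attenuation = attenuation,
      thickness = thickness, standoff = standoff, gelpadGap = gelpadGap,
      geometryParameter = geometryParameter, beamRadius = beamRadius,
      constructRadius = constructRadius, snrDb = snrDb,
      reflectivity = reflectivity)
}

## ---------------------------------------------------------------------------
## Result classes
## ---------------------------------------------------------------------------

#' Round-trip echo times
#'
#' Median-aggregated round-trip times to the construct top surface, bottom
#' surface and gel pad (sample scan present) and to the gel pad of the
#' reference scan, plus the per-A-line table they were aggregated from.
#'
#' @slot tTop,tBot,tGel,tRef aggregated round-trip times, s.
#' @slot perLine per-A-line data.frame (slice, line, tTop, tBot, tGel,
#'   tRef, valid).
#' @name EchoTimes-class
#' @rdname EchoTimes
#' @exportClass EchoTimes
setClass("EchoTimes",
  representation(tTop = "numeric", tBot = "numeric", tGel = "numeric",
                 tRef = "numeric", perLine = "data.frame"))

setValidity("EchoTimes", function(object) {
  msgs <- character()
  tm <- c(object@tTop, object@tBot, object@tGel, object@tRef)
  if (any(tm <= 0)) msgs <- c(msgs, "all echo times must be positive")
  if (!(object@tTop < object@tBot && object@tBot < object@tGel))
    msgs <- c(msgs, "echo times must satisfy tTop < tBot < tGel")
  if (length(msgs)) msgs else TRUE
})

#' Construct EchoTimes from scalar times
#'
#' @param tTop,tBot,tGel,tRef round-trip times, s.
#' @param perLine optional per-A-line table.
#' @return An \linkS4class{EchoTimes}.
#' @export
echoTimes <- function(tTop, tBot, tGel, tRef, perLine = data.frame()) {
  new("EchoTimes", tTop = tTop, tBot = tBot, tGel = tGel, tRef = tRef,
      perLine = perLine)
}

#' Bulk acoustic properties of a construct
#'
#' @slot thickness L, mm.
#' @slot soundSpeed c_t, m/s.
#' @slot attenuation alpha, dB/(cm*MHz).
#' @slot attenuationBand linear-fit band, MHz.
#' @slot fitR2 r-squared of the attenuation fit.
#' @name BulkProperties-class
#' @rdname BulkProperties
#' @exportClass BulkProperties
setClass("BulkProperties",
  representation(thickness = "numeric", soundSpeed = "numeric",
                 attenuation = "numeric", attenuationBand = "numeric",
                 fitR2 = "numeric"))

setValidity("BulkProperties", function(object) {
  if (object@thickness <= 0) "thickness must be > 0" else TRUE
})

#' Parametric map aligned to a B-mode slice
#'
#' @slot parameter one of "diameter", "calcium", "mbf", "slope", "cq2".
#' @slot values per-pixel value matrix (same geometry as the B-mode).
#' @slot mask logical matrix; values are defined only where TRUE.
#' @slot range display range, c(lo, hi).
#' @slot colormap colormap name (passed to grDevices::hcl.colors).
#' @name ParametricMap-class
#' @rdname ParametricMap
#' @exportClass ParametricMap
setClass("ParametricMap",
  representation(parameter = "character", values = "matrix",
                 mask = "matrix", range = "numeric", colormap = "character"))

setValidity("ParametricMap", function(object) {
  msgs <- character()
  if (!identical(dim(object@values), dim(object@mask)))
    msgs <- c(msgs, "values and mask must have identical dimensions")
  if (any(!is.finite(object@values[object@mask])))
    msgs <- c(msgs, "values must be finite wherever mask is TRUE")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "TransducerSpec", function(object) {
  cat(sprintf("TransducerSpec: %.1f MHz nominal, band %.1f-%.1f MHz, %.0f MS/s\n",
              object@centerFrequency, object@bandLow, object@bandHigh,
              object@samplingRate / 1e6))
  cat(sprintf("  focal distance %.1f mm, depth of focus %.1f mm\n",
              object@focalDistance, object@depthOfFocus))
})

setMethod("show", "AcquisitionGrid", function(object) {
  cat(sprintf("AcquisitionGrid: %d samples x %d lines x %d slices\n",
              object@nSamples, object@nLines, object@nSlices))
  cat(sprintf("  dt %.3g s, lateral %.0f um, slice %.0f um\n",
              object@axialDt, object@lateralSpacing, object@sliceSpacing))
})

setMethod("show", "RFVolume", function(object) {
  d <- dim(object@samples)
  cat(sprintf("RFVolume (%s): %d x %d x %d, amplitude range [%.3g, %.3g]\n",
              object@kind, d[1], d[2], d[3],
              min(object@samples), max(object@samples)))
  show(object@grid)
})

setMethod("show", "BModeImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("BModeImage: %d x %d px, dynamic range %.0f dB (slice %d)\n",
              d[1], d[2], object@dynamicRange, object@sliceIndex))
})

setMethod("show", "EchoTimes", function(object) {
  cat(sprintf("EchoTimes (s): top %.4g, bottom %.4g, gel %.4g, ref %.4g\n",
              object@tTop, object@tBot, object@tGel, object@tRef))
  if (nrow(object@perLine))
    cat(sprintf("  aggregated over %d valid A-lines\n",
                sum(object@perLine$valid)))
})

setMethod("show", "BulkProperties", function(object) {
  cat(sprintf("BulkProperties: L = %.3f mm, c_t = %.1f m/s, alpha = %.3f dB/(cm*MHz)\n",
              object@thickness, object@soundSpeed, object@attenuation))
  cat(sprintf("  attenuation fit %.0f-%.0f MHz, R2 = %.3f\n",
              object@attenuationBand[1], object@attenuationBand[2], object@fitR2))
})

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf("PhantomConfig: 2a = %.1f um, C = %.3g /mm^3, Q = %.2f\n",
              object@scattererDiameter, object@concentration, object@impedance))
  cat(sprintf("  c_t = %.0f m/s, alpha = %.2f dB/(cm*MHz), L = %.2f mm, SNR %.0f dB\n",
              object@soundSpeed, object@attenuation, object@thickness,
              object@snrDb))
})

setMethod("show", "ParametricMap", function(object) {
  cat(sprintf("ParametricMap '%s': %d x %d px, %d valid, range [%.3g, %.3g]\n",
              object@parameter, nrow(object@values), ncol(object@values),
              sum(object@mask), object@range[1], object@range[2]))
})
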