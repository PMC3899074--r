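## Synthetic RF backscatter simulator.
##
## Forward model: incoherent point scatterers Poisson-placed in an
## effective beam tube per A-line, each echoing a Gaussian-envelope pulse
## at its round-trip delay (standoff in fluid, interior at the sample sound
## speed) with amplitude Q * Vs, Rayleigh frequency weighting f^(n/2), a
## Gaussian form-factor amplitude filter for the configured radius, and
## cumulative frequency-linear attenuation over the in-sample round-trip
## path.  Specular echoes are inserted at the top surface, bottom surface
## and gel pad.  Synthesis is done in the frequency domain (exact
## sub-sample delays), with Hermitian symmetry enforced before the inverse
## FFT.

## -6 dB amplitude full width b of a Gaussian |P(f)| = exp(-(f-fc)^2/(2 s^2))
## satisfies b = 2 s sqrt(2 ln 2)
.sigmaF <- function(bandwidthMhz) bandwidthMhz / (2 * sqrt(2 * log(2)))

#' Simulated transmit pulse for a transducer
#'
#' Gaussian-envelope sinusoid at the transducer's nominal center frequency,
#' sampled at its sampling rate, with -6 dB spectral full width equal to
#' the transducer band span.
#'
#' @param transducer a \linkS4class{TransducerSpec}.
#' @param fractionalBandwidth optional override of the -6 dB fractional
#'   bandwidth (band span / center frequency by default).
#' @return A \linkS4class{PulseModel}.
#' @export
makePulse <- function(transducer = transducerSpec(),
                      fractionalBandwidth = NULL) {
  fc <- transducer@centerFrequency
  b <- if (is.null(fractionalBandwidth))
    transducer@bandHigh - transducer@bandLow else fractionalBandwidth * fc
  if (fc + b / 2 >= transducer@samplingRate / 2 / 1e6)
    stop("pulse band exceeds Nyquist")
  sigF <- .sigmaF(b)                       # MHz
  sigT <- 1 / (2 * pi * sigF * 1e6)        # s
  dt <- 1 / transducer@samplingRate
  half <- ceiling(4 * sigT / dt)
  t <- (-half:half) * dt
  w <- exp(-t^2 / (2 * sigT^2)) * cos(2 * pi * fc * 1e6 * t)
  new("PulseModel", centerFrequency = fc, fractionalBandwidth = b / fc,
      duration = length(t) * dt, waveform = w, dt = dt)
}

setMethod("show", "PulseModel", function(object) {
  cat(sprintf("PulseModel: %.1f MHz, fractional bandwidth %.2f, %.1f ns (%d samples)\n",
              object@centerFrequency, object@fractionalBandwidth,
              object@duration * 1e9, length(object@waveform)))
})

## Deterministic per-A-line substream seed so that lateral order never
## changes results.  Kept within 32-bit integer range.
.substreamSeed <- function(seed, slice, line) {
  as.integer((as.numeric(seed) * 48271 + slice * 1000003 + line * 7919) %%
               2147483647)
}

## Positive-frequency amplitude spectrum of the transmit pulse (zero phase
## at the echo center).
.pulseHalfSpec <- function(freqMhz, fc, bandwidthMhz) {
  exp(-(freqMhz - fc)^2 / (2 * .sigmaF(bandwidthMhz)^2))
}

## Synthesize one A-line from echo delays/filters.  halfAccum is a complex
## vector over the positive-frequency grid; returns the real trace.
.hermitianSynth <- function(halfAccum, nfft) {
  S <- complex(length.out = nfft)
  nh <- length(halfAccum)                 # nfft/2 + 1 bins (DC..Nyquist)
  S[seq_len(nh)] <- halfAccum
  S[seq(nfft, nh + 1L)] <- Conj(halfAccum[2:(nh - 1L)])
  Re(stats::fft(S, inverse = TRUE)) / nfft
}

## Core A-line synthesis.  `inside` says whether this lateral position
## intersects the construct.  Returns the noise-free trace.
.synthAline <- function(config, transducer, medium, nSamples, inside = TRUE,
                        reference = FALSE) {
  fs <- transducer@samplingRate
  nfft <- nSamples
  freq <- (0:(nfft %/% 2)) * fs / nfft / 1e6     # MHz grid
  fc <- transducer@centerFrequency
  bw <- transducer@bandHigh - transducer@bandLow
  P <- .pulseHalfSpec(freq, fc, bw)
  cf <- medium@cFluid; ct <- config@soundSpeed
  s <- config@standoff; L <- config@thickness; g <- config@gelpadGap
  omega <- 2 * pi * freq * 1e6                   # rad/s
  acc <- complex(length.out = length(freq))
  r <- config@reflectivity
  ## one-way in-sample attenuation amplitude factor at depth z (mm):
  ## dB = alpha * f * (2 z / 10)  =>  exponent alpha*f*z/100
  attAmp <- function(z) 10^(-(config@attenuation / 100) * freq * z)
  if (reference || !inside) {
    tGel <- 2 * ((s + L + g) / 1000) / cf        # s (distances mm -> m)
    acc <- acc + r[3] * exp(-1i * omega * tGel)
  } else {
    tTop <- 2 * (s / 1000) / cf
    tBot <- tTop + 2 * (L / 1000) / ct
    tGel <- tBot + 2 * (g / 1000) / cf
    acc <- acc + r[1] * exp(-1i * omega * tTop)
    acc <- acc + r[2] * attAmp(L) * exp(-1i * omega * tBot)
    acc <- acc + r[3] * attAmp(L) * exp(-1i * omega * tGel)
    if (config@concentration > 0) {
      tubeVol <- pi * config@beamRadius^2 * L    # mm^3
      nScat <- stats::rpois(1, config@concentration * tubeVol)
      if (nScat > 0) {
        z <- stats::runif(nScat, 0, L)           # depth below top, mm
        a <- config@scattererDiameter / 2        # um
        vs <- 4 / 3 * pi * (a / 1000)^3          # mm^3
        ## common per-frequency amplitude: Q * Vs * f^(n/2) * sqrt(FF)
        common <- config@impedance * vs * freq^(config@geometryParameter / 2) *
          sqrt(gaussianFormFactor(freq, a, ct))
        tau <- tTop + 2 * (z / 1000) / ct
        ## delays + per-scatterer attenuation, summed over scatterers
        ph <- exp(-1i * outer(omega, tau)) *
          10^(-(config@attenuation / 100) * outer(freq, z))
        acc <- acc + common * as.vector(ph %*% rep(1, nScat))
      }
    }
  }
  .hermitianSynth(P * acc, nfft)
}

## Amplitude scale the configured SNR refers to: the expected (ensemble)
## RMS of the diffuse backscatter over the sample interior, computed in
## closed form from the forward model so the receiver noise level is
## uniform across A-lines and independent of the per-line Poisson draw.
## With no diffuse scattering it falls back to the RMS of the noise-free
## echo train over its support.
.signalRms <- function(config, transducer, medium, nSamples) {
  nfft <- nSamples
  fs <- transducer@samplingRate
  freq <- (0:(nfft %/% 2)) * fs / nfft / 1e6
  P <- .pulseHalfSpec(freq, transducer@centerFrequency,
                      transducer@bandHigh - transducer@bandLow)
  L <- config@thickness; ct <- config@soundSpeed
  if (config@concentration > 0) {
    a <- config@scattererDiameter / 2
    vs <- 4 / 3 * pi * (a / 1000)^3
    common <- config@impedance * vs * freq^(config@geometryParameter / 2) *
      sqrt(gaussianFormFactor(freq, a, ct))
    ## mean squared attenuation over uniform depth in (0, L)
    att2 <- vapply(freq, function(f) {
      k <- 2 * (config@attenuation / 100) * f * log(10) / 10   # nats/mm
      if (k < 1e-12) 1 else (1 - exp(-k * L)) / (k * L)
    }, numeric(1))
    lambda <- config@concentration * pi * config@beamRadius^2 * L
    energy <- 2 * sum((P * common)^2 * att2) / nfft
    nInterior <- (2 * (L / 1000) / ct) * fs
    sqrt(lambda * energy / nInterior)
  } else {
    tr <- .synthAline(config, transducer, medium, nSamples)
    env <- abs(tr)
    support <- env > max(env) * 0.01
    if (any(support)) sqrt(mean(tr[support]^2)) else 0
  }
}

.addNoise <- function(trace, noiseSd) {
  if (noiseSd <= 0) return(trace)
  trace + stats::rnorm(length(trace), sd = noiseSd)
}

#' Simulate a single RF A-line
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @param transducer a \linkS4class{TransducerSpec}.
#' @param medium a \linkS4class{MediumSpec}.
#' @param nSamples trace length (default from
#'   \code{\link{tracelengthFor}}).
#' @param seed RNG seed for the scatterer realization and noise.
#' @param reference simulate the no-sample reference trace instead.
#' @return Numeric RF trace of length \code{nSamples}.
#' @export
simulateAline <- function(config, transducer = transducerSpec(),
                          medium = mediumSpec(), nSamples = NULL,
                          seed = 1L, reference = FALSE) {
  validObject(config)
  if (is.null(nSamples)) nSamples <- tracelengthFor(config, transducer, medium)
  noiseSd <- if (is.finite(config@snrDb))
    .signalRms(config, transducer, medium, nSamples) *
      10^(-config@snrDb / 20) else 0
  set.seed(seed)
  tr <- .synthAline(config, transducer, medium, nSamples,
                    reference = reference)
  .addNoise(tr, noiseSd)
}

#' Trace length covering the full echo train of a configuration
#'
#' @inheritParams simulateAline
#' @return Number of samples (even, for FFT symmetry).
#' @export
tracelengthFor <- function(config, transducer = transducerSpec(),
                           medium = mediumSpec()) {
  tMax <- 2 * ((config@standoff + config@thickness + config@gelpadGap) / 1000) /
    min(medium@cFluid, config@soundSpeed)
  n <- ceiling((tMax + 1.0e-6) * transducer@samplingRate)
  n + n %% 2L
}

#' Simulate a 3D scan pair (sample + reference)
#'
#' Generates a sample volume and a reference volume identical except that
#' the sample is absent (gel-pad echo through fluid only).  Scatterer
#' realizations are independent per A-line, drawn from deterministic
#' per-line substreams of \code{seed}, so results do not depend on
#' traversal order.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @param transducer a \linkS4class{TransducerSpec}.
#' @param medium a \linkS4class{MediumSpec}.
#' @param nLines,nSlices grid size (used when \code{grid} is NULL).
#' @param grid optional \linkS4class{AcquisitionGrid}; its sample count
#'   must cover the echo train.
#' @param seed integer seed; the same seed reproduces the volumes exactly.
#' @return List with elements \code{sample} and \code{reference}
#'   (\linkS4class{RFVolume}s) and \code{truth} (ground-truth record).
#' @export
simulateScan <- function(config, transducer = transducerSpec(),
                         medium = mediumSpec(), nLines = 30L, nSlices = 1L,
                         grid = NULL, seed = 1L) {
  validObject(config)
  if (is.null(grid)) {
    grid <- acquisitionGrid(tracelengthFor(config, transducer, medium),
                            nLines, nSlices,
                            axialDt = 1 / transducer@samplingRate)
  }
  nS <- grid@nSamples; nL <- grid@nLines; nK <- grid@nSlices
  xs <- (seq_len(nL) - (nL + 1) / 2) * grid@lateralSpacing / 1000   # mm
  ys <- (seq_len(nK) - (nK + 1) / 2) * grid@sliceSpacing / 1000     # mm
  samp <- array(0, c(nS, nL, nK)); ref <- array(0, c(nS, nL, nK))
  noiseSd <- if (is.finite(config@snrDb))
    .signalRms(config, transducer, medium, nS) * 10^(-config@snrDb / 20)
  else 0
  for (k in seq_len(nK)) {
    for (i in seq_len(nL)) {
      inside <- (xs[i]^2 + ys[k]^2) <= config@constructRadius^2
      set.seed(.substreamSeed(seed, k, i))
      samp[, i, k] <- .addNoise(
        .synthAline(config, transducer, medium, nS, inside = inside),
        noiseSd)
      set.seed(.substreamSeed(seed, k, i + 100000L))
      ref[, i, k] <- .addNoise(
        .synthAline(config, transducer, medium, nS, reference = TRUE),
        noiseSd)
    }
  }
  cf <- medium@cFluid; ct <- config@soundSpeed
  tTop <- 2 * (config@standoff / 1000) / cf
  truth <- list(
    radiusUm = config@scattererDiameter / 2,
    diameterUm = config@scattererDiameter,
    concentration = config@concentration,
    impedance = config@impedance,
    cq2 = config@concentration * config@impedance^2,
    attenuation = config@attenuation,
    soundSpeed = ct,
    thickness = config@thickness,
    tTop = tTop,
    tBot = tTop + 2 * (config@thickness / 1000) / ct,
    tGel = tTop + 2 * (config@thickness / 1000) / ct +
      2 * (config@gelpadGap / 1000) / cf,
    tRef = 2 * ((config@standoff + config@thickness + config@gelpadGap) /
                  1000) / cf)
  list(sample = rfVolume(samp, grid, transducer, "sample"),
       reference = rfVolume(ref, grid, transducer, "reference"),
       truth = truth)
}
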