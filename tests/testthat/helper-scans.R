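## Shared simulated fixtures, built once per test run and memoised.
.scanCache <- new.env(parent = emptyenv())

cachedScan <- function(key, config, nLines = 30L, seed = 1L, nSlices = 1L) {
  if (is.null(.scanCache[[key]]))
    .scanCache[[key]] <- simulateScan(config, nLines = nLines,
                                      nSlices = nSlices, seed = seed)
  .scanCache[[key]]
}

## clean phantom: no attenuation, no noise (model-oracle checks)
cleanScan <- function(diameter = 14, seed = 1L, nLines = 30L)
  cachedScan(paste0("clean", diameter, "s", seed),
             phantomConfig(scattererDiameter = diameter, attenuation = 0,
                           snrDb = Inf),
             nLines = nLines, seed = seed)

## study-condition phantom: alpha = 0.5 dB/(cm MHz), SNR 30 dB
studyScan <- function(diameter = 14, concentration = 1000, seed = 1L)
  cachedScan(paste0("study", diameter, "c", concentration, "s", seed),
             phantomConfig(scattererDiameter = diameter,
                           concentration = concentration),
             nLines = 34L, seed = seed)

## analytic echo times for a forward time-of-flight scenario
forwardTimes <- function(L = 1.2, ct = 1540, cf = 1480, standoff = 3,
                         gap = 0.5) {
  tTop <- 2 * (standoff / 1000) / cf
  tBot <- tTop + 2 * (L / 1000) / ct
  tGel <- tBot + 2 * (gap / 1000) / cf
  tRef <- 2 * ((standoff + L + gap) / 1000) / cf
  echoTimes(tTop, tBot, tGel, tRef)
}

## synthetic B-mode with a filled bright disc (for volume oracles)
discBMode <- function(radiusMm, nSamples = 1200, nLines = 141,
                      dynamicRange = 50, axialDt = 1 / 420e6,
                      lateralSpacing = 31, soundSpeed = 1540,
                      centerRow = NULL, rowScale = NULL) {
  axMm <- axialDt * soundSpeed / 2 * 1000
  latMm <- lateralSpacing / 1000
  if (is.null(centerRow)) centerRow <- nSamples / 2
  centerCol <- (nLines + 1) / 2
  rows <- ((seq_len(nSamples)) - centerRow) * axMm
  cols <- ((seq_len(nLines)) - centerCol) * latMm
  inside <- outer(rows^2, cols^2, "+") <= radiusMm^2
  v <- matrix(-dynamicRange, nSamples, nLines)
  v[inside] <- 0
  new("BModeImage", values = v, dynamicRange = dynamicRange,
      axialDt = axialDt, lateralSpacing = lateralSpacing, sliceIndex = 1L)
}
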