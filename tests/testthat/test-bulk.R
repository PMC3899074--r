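test_that("time-of-flight inversion is exact on analytic echo times", {
  ## forward-constructed times recover L and c_t to machine precision
  et <- forwardTimes(L = 1.2, ct = 1540)
  ts <- thicknessAndSpeed(et)
  expect_equal(ts$thickness, 1.2, tolerance = 1e-12)
  expect_equal(ts$soundSpeed, 1540, tolerance = 1e-12)

  ## no-contrast case: t_gel = t_ref arrangement gives c_t = c_fluid exactly
  et0 <- forwardTimes(L = 1.0, ct = 1480)
  expect_equal(et0@tGel, et0@tRef, tolerance = 1e-15)
  expect_equal(thicknessAndSpeed(et0)$soundSpeed, 1480, tolerance = 1e-12)

  ## substitution identities hold for the implemented arrangement
  expect_equal(2 * (1.2 / 1000) / 1540, et@tBot - et@tTop, tolerance = 1e-15)
  expect_equal(2 * (1.2 / 1000) / 1480,
               (et@tRef - et@tGel) + (et@tBot - et@tTop), tolerance = 1e-15)

  ## non-physical times rejected (validity: tTop < tBot < tGel)
  expect_error(thicknessAndSpeed(echoTimes(1e-6, 2e-6, 1.5e-6, 3e-6)))
  expect_warning(thicknessAndSpeed(forwardTimes(L = 1, ct = 1290)), "sanity")
})

test_that("surface detection recovers simulated geometry", {
  ## c_t = c_fluid: t_bot - t_top = 2L/c_fluid within one sample period
  cfg <- phantomConfig(soundSpeed = 1480, thickness = 1, standoff = 3,
                       snrDb = Inf, attenuation = 0)
  scan <- cachedScan("surf1480", cfg, nLines = 10L, seed = 11)
  times <- detectSurfaces(scan$sample, scan$reference)
  dt <- acqGrid(scan$sample)@axialDt
  expect_lt(abs((times@tBot - times@tTop) - 2 * 1e-3 / 1480), dt)
  expect_lt(abs(times@tRef - scan$truth$tRef), dt)

  ## end-to-end recovery: L within one sample-distance, c_t within 1%
  cfg2 <- phantomConfig(soundSpeed = 1520, thickness = 1)
  scan2 <- cachedScan("surf1520", cfg2, nLines = 10L, seed = 11)
  ts <- thicknessAndSpeed(detectSurfaces(scan2$sample, scan2$reference))
  expect_lt(abs(ts$thickness - 1), 1520 / 2 / 420e6 * 1000 * 2)
  expect_lt(abs(ts$soundSpeed - 1520) / 1520, 0.01)

  ## threshold above all echoes: everything flagged missing
  expect_error(detectSurfaces(scan2$sample, scan2$reference,
                              thresholdDb = 10), "no A-line")
})

test_that("attenuation coefficient recovery is unbiased", {
  runAlpha <- function(alpha, seed = 21) {
    cfg <- phantomConfig(attenuation = alpha, thickness = 1)
    scan <- cachedScan(paste0("att", alpha), cfg, nLines = 100L, seed = seed)
    times <- detectSurfaces(scan$sample, scan$reference)
    ts <- thicknessAndSpeed(times)
    attenuationCoefficient(scan$sample, scan$reference, times,
                           ts$thickness)$coefficient
  }
  ## zero attenuation within +/- 0.05 dB/(cm MHz)
  expect_lt(abs(runAlpha(0)), 0.05)
  ## recovery bias < 10% across the tested range at SNR 30 dB
  for (a in c(0.1, 0.5, 1.0))
    expect_lt(abs(runAlpha(a) - a) / a, 0.10)
})

test_that("insertion loss scales with path length before normalization", {
  gelLoss <- function(L) {
    cfg <- phantomConfig(concentration = 0, attenuation = 0.5, thickness = L,
                         snrDb = Inf)
    scan <- simulateScan(cfg, nLines = 2L, seed = 2)
    times <- detectSurfaces(scan$sample, scan$reference)
    att <- attenuationCoefficient(scan$sample, scan$reference, times, L)
    ## un-normalize: alpha(f) * 2L gives the raw insertion loss in dB
    att$alphaOfF$alphaDbCm * 2 * (L / 10)
  }
  l1 <- gelLoss(1); l2 <- gelLoss(2)
  sel <- l1 > 1     # avoid ratios of near-zero losses at low f
  expect_lt(max(abs(l2[sel] / l1[sel] - 2)), 0.2)
})

test_that("construct volume matches analytic solids", {
  ## cylinder: disc cross-section constant along the slice axis, so
  ## 5 slices x 0.2 mm reproduce pi r^2 h
  bm <- discBMode(2, nSamples = 2400)
  est <- constructVolume(rep(list(bm), 5), thresholdDb = -20,
                         sliceSpacingUm = 200)
  expect_lt(abs(est$volumeMm3 - pi * 2^2 * 1) / (pi * 4), 0.10)

  ## noise-only stack: zero volume with a warning
  empty <- new("BModeImage", values = matrix(-50, 100, 20),
               dynamicRange = 50, axialDt = 1 / 420e6, lateralSpacing = 31,
               sliceIndex = 1L)
  expect_warning(v0 <- constructVolume(list(empty)), "no above-threshold")
  expect_equal(v0$volumeMm3, 0)

  ## sphere: volume error decreases monotonically as slice spacing shrinks
  r <- 1
  sphereVol <- function(spacingMm) {
    ys <- seq(-r + spacingMm / 2, r - spacingMm / 2, by = spacingMm)
    bms <- lapply(ys, function(y) {
      rad <- sqrt(max(r^2 - y^2, 0))
      if (rad > 0.01) discBMode(rad, nSamples = 1400, nLines = 101)
      else new("BModeImage", values = matrix(-50, 1400, 101),
               dynamicRange = 50, axialDt = 1 / 420e6,
               lateralSpacing = 31, sliceIndex = 1L)
    })
    suppressWarnings(constructVolume(bms, sliceSpacingUm = spacingMm * 1000))
  }
  truth <- 4 / 3 * pi * r^3
  errs <- vapply(c(0.4, 0.2, 0.1),
                 function(s) abs(sphereVol(s)$volumeMm3 - truth), numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("bulkProperties wrapper assembles a valid result", {
  scan <- studyScan(14, seed = 11)
  bp <- bulkProperties(scan$sample, scan$reference)
  expect_s4_class(bp, "BulkProperties")
  expect_equal(thickness(bp), 2, tolerance = 0.01)
  expect_equal(soundSpeed(bp), 1540, tolerance = 0.01)
  expect_equal(attenuation(bp), 0.5, tolerance = 0.1)
  expect_equal(bp@attenuationBand, c(20, 55))
})
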