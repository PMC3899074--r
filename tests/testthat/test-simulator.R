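test_that("simulated pulse has the nominal spectral properties", {
  tr <- transducerSpec()
  p <- makePulse(tr)
  n <- 4096
  w <- c(p@waveform, numeric(n - length(p@waveform)))
  spec <- abs(stats::fft(w))[1:(n / 2)]
  freq <- (0:(n / 2 - 1)) * tr@samplingRate / n / 1e6

  ## spectral peak at the nominal center frequency (within 5%)
  expect_lt(abs(freq[which.max(spec)] - 55), 55 * 0.05)

  ## -6 dB full width within 10% of the nominal band span
  half <- max(spec) / 2
  width <- diff(range(freq[spec >= half]))
  expect_lt(abs(width - 55) / 55, 0.10)

  ## narrowband limit: -6 dB width shrinks toward zero
  pn <- makePulse(tr, fractionalBandwidth = 0.05)
  wn <- c(pn@waveform, numeric(8192 - length(pn@waveform)))
  sn <- abs(stats::fft(wn))[1:4096]
  fn <- (0:4095) * tr@samplingRate / 8192 / 1e6
  widthN <- diff(range(fn[sn >= max(sn) / 2]))
  expect_lt(widthN, 4)

  ## Parseval: time-domain energy equals spectral energy
  X <- stats::fft(p@waveform)
  expect_equal(sum(p@waveform^2), sum(Mod(X)^2) / length(X))
})

test_that("zero concentration yields exactly the three interface echoes", {
  cfg <- phantomConfig(concentration = 0, snrDb = Inf)
  tr <- simulateAline(cfg, seed = 3)
  env <- rfEnvelope(tr)
  thr <- max(env) * 10^(-30 / 20)
  above <- which(env >= thr)
  clusters <- sum(diff(above) > 100) + 1L
  expect_equal(clusters, 3L)
})

test_that("ensemble backscatter power follows the C*Q^2 law", {
  cfg <- phantomConfig(attenuation = 0, snrDb = Inf, reflectivity = c(0, 0, 0))
  power <- function(config, seeds) {
    mean(vapply(seeds, function(s) {
      tr <- simulateAline(config, seed = s)
      mean(tr^2)
    }, numeric(1)))
  }
  seeds <- 1:250
  p0 <- power(cfg, seeds)

  cfgQ <- cfg; cfgQ@impedance <- cfg@impedance * 2
  expect_lt(abs(power(cfgQ, seeds) / p0 - 4), 0.4)     # Q doubling -> x4

  cfgC <- cfg; cfgC@concentration <- cfg@concentration * 2
  expect_lt(abs(power(cfgC, seeds) / p0 - 2), 0.2)     # C doubling -> x2
})

test_that("attenuation leaves the configured spectral signature on the gel echo", {
  ## gel-pad echo spectral ratio between alpha = 0 and alpha = 0.5 has
  ## slope 2*alpha*L dB/(cm MHz) * L in cm
  mkGel <- function(alpha) {
    cfg <- phantomConfig(concentration = 0, attenuation = alpha,
                         thickness = 1, snrDb = Inf)
    tr <- simulateAline(cfg, seed = 1)
    env <- rfEnvelope(tr)
    ## gel echo is the last of the three interface echoes
    pk <- which(env > max(env) * 0.5)
    gelIdx <- max(pk)
    seg <- tr[(gelIdx - 128):(gelIdx + 127)]
    abs(stats::fft(seg))[1:129]
  }
  A0 <- mkGel(0); A1 <- mkGel(0.5)
  freq <- (0:128) * 420 / 256
  sel <- freq >= 25 & freq <= 70
  loss <- 20 * log10(A0[sel] / A1[sel])
  slope <- coef(lm(loss ~ freq[sel]))[2]
  ## expected 2 * alpha * L = 2 * 0.5 * 0.1 cm = 0.1 dB/MHz
  expect_lt(abs(slope - 0.1) / 0.1, 0.10)
})

test_that("simulateScan is reproducible and geometrically faithful", {
  cfg <- phantomConfig()
  s1 <- simulateScan(cfg, nLines = 4L, seed = 42)
  s2 <- simulateScan(cfg, nLines = 4L, seed = 42)
  expect_identical(rfSamples(s1$sample), rfSamples(s2$sample))
  expect_identical(rfSamples(s1$reference), rfSamples(s2$reference))

  ## grid defaults recorded
  expect_equal(acqGrid(s1$sample)@lateralSpacing, 31)
  expect_equal(acqGrid(s1$sample)@sliceSpacing, 200)

  ## reference gel-pad echo at 2*(standoff+L+gap)/c_fluid within one sample
  env <- rfEnvelope(rfSamples(s1$reference)[, 1, 1])
  tPk <- (which.max(env) - 1) * acqGrid(s1$reference)@axialDt
  expect_lt(abs(tPk - s1$truth$tRef), 1 / 420e6 + 1e-12)
})

test_that("simulated diffuse spectra match the closed-form Gaussian model", {
  ## ensemble calibrated spectrum of a 14 um phantom within 1 dB of the
  ## model curve over the -9 dB band (>= 200 windows)
  scan <- cleanScan(14, seed = 2, nLines = 40L)
  times <- detectSurfaces(scan$sample, scan$reference)
  cs <- calibratedSpectrum(scan$sample, scan$reference, times, 1540)
  expect_gte(nrow(cs@spectraDb), 200)
  ens <- ensembleSpectrum(cs, 0)
  sel <- ens$freq >= cs@band[1] & ens$freq <= cs@band[2]
  f <- ens$freq[sel]
  model <- modelSpectrum(f, 7, 360, soundSpeed = 1540)
  resid <- (ens$db[sel] - mean(ens$db[sel])) - (model - mean(model))
  expect_lt(max(abs(resid)), 1)
})

test_that("point scatterers without frequency weighting give a flat spectrum", {
  ## impedance scaled up so the sub-wavelength scatterers are acoustically
  ## comparable to the interfaces (pure numerical oracle)
  cfg <- phantomConfig(scattererDiameter = 1, geometryParameter = 0,
                       concentration = 5000, impedance = 1e6,
                       attenuation = 0, snrDb = Inf)
  scan <- simulateScan(cfg, nLines = 40L, seed = 4)
  times <- detectSurfaces(scan$sample, scan$reference)
  cs <- calibratedSpectrum(scan$sample, scan$reference, times, 1540)
  ens <- ensembleSpectrum(cs, 0)
  fit <- fitSlopeMBF(ens$freq, ens$db, cs@band)
  sel <- ens$freq >= cs@band[1] & ens$freq <= cs@band[2]
  expect_lt(max(abs(ens$db[sel] - mean(ens$db[sel]))), 1.5)
  expect_lt(abs(fit$slope), 0.02)
})

test_that("timecourse simulation encodes compaction and mineralization", {
  tc <- exampleTimecourseConfig()
  days <- simulateTimecourse(tc, nLines = 4L, seed = 1)
  vols <- vapply(days, function(d) d$truth$volumeMm3, numeric(1))
  expect_true(all(diff(vols) <= 0))                   # compaction then plateau
  expect_equal(vols[2] / vols[1], 0.65^3, tolerance = 1e-10)
  expect_gte(vols[2] / vols[1], 0.25)
  expect_lte(vols[2] / vols[1], 0.30)

  ## no calcium -> impedance constant across days
  tc0 <- exampleTimecourseConfig(calciumConcUgMl = 0)
  days0 <- simulateTimecourse(tc0, nLines = 2L, seed = 1)
  qs <- vapply(days0, function(d) d$truth$impedance, numeric(1))
  expect_equal(qs, rep(qs[1], length(qs)))

  ## forward impedance model round-trips through the calcium inversion
  d21 <- days[[4]]$truth
  back <- calciumMass(d21$baselineImpedance, d21$impedance,
                      d21$nScatterers, d21$radiusUm)
  expect_equal(back$massUg, d21$calciumMassUg, tolerance = 1e-10)

  expect_error(timecourseConfig(c(7, 1), list(phantomConfig(), phantomConfig())),
               "increasing")
})
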