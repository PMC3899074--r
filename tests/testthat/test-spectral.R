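test_that("calibrated spectra carry sane windows and band", {
  scan <- studyScan(14, seed = 1)
  times <- detectSurfaces(scan$sample, scan$reference)
  cs <- calibratedSpectrum(scan$sample, scan$reference, times, 1540)
  tband <- analysisBand(transducer(scan$sample))
  expect_gte(cs@band[1], tband[1])
  expect_lte(cs@band[2], tband[2])
  expect_true(all(cs@windows$zMm > 0 & cs@windows$zMm < 2))
  expect_gte(nrow(cs@spectraDb), 200)
  ## window overlapping a surface would be excluded: all centers interior
  g <- acqGrid(scan$sample)
  topIdx <- times@tTop / g@axialDt + 1
  botIdx <- times@tBot / g@axialDt + 1
  expect_true(all(cs@windows$center > topIdx + 128))
  expect_true(all(cs@windows$center < botIdx - 128))
})

test_that("corrected MBF shows no systematic depth trend", {
  scan <- studyScan(14, seed = 1)
  ana <- susiAnalysis(scan$sample, scan$reference)
  wt <- ana$windowTable
  ## raw MBF decays with depth at about -2*alpha*f_c dB/cm
  rawFit <- lm(mbfRaw ~ zMm, data = wt)
  expectedRaw <- -2 * 0.5 * ana$spectra@fCenter / 10    # dB/mm
  expect_lt(abs(coef(rawFit)[2] - expectedRaw) / abs(expectedRaw), 0.5)
  ## corrected MBF: slope consistent with zero (and far below the raw one)
  corFit <- summary(lm(mbf ~ zMm, data = wt))
  expect_lt(abs(coef(corFit)[2, 1]),
            max(2 * coef(corFit)[2, 2], 0.1 * abs(expectedRaw)))
})

test_that("amplitude scaling shifts MBF by 20 log10(k) and leaves size alone", {
  scan <- cleanScan(14, seed = 3)
  base <- susiAnalysis(scan$sample, scan$reference)
  k <- 3.7
  scaled <- rfVolume(rfSamples(scan$sample) * k, acqGrid(scan$sample),
                     transducer(scan$sample))
  both <- susiAnalysis(scaled, scan$reference)
  expect_equal(both$estimate$mbf - base$estimate$mbf, 20 * log10(k),
               tolerance = 1e-6)
  expect_equal(both$estimate$slope, base$estimate$slope, tolerance = 1e-9)
  expect_equal(both$estimate$diameterUm, base$estimate$diameterUm,
               tolerance = 1e-6)
  ## scaling sample and reference together cancels entirely
  refScaled <- rfVolume(rfSamples(scan$reference) * k,
                        acqGrid(scan$reference), transducer(scan$reference),
                        kind = "reference")
  cal <- susiAnalysis(scaled, refScaled)
  expect_equal(cal$estimate$mbf, base$estimate$mbf, tolerance = 1e-6)
})

test_that("scatterer size and concentration are recovered from simulation", {
  ## single-seed diameter recovery, alpha = 0.5, SNR 30 dB
  for (d in c(6, 16)) {
    scan <- studyScan(d, seed = 7)
    ana <- susiAnalysis(scan$sample, scan$reference, knownC = 1000)
    expect_lt(abs(ana$estimate$diameterUm - d) / d, 0.15)
  }
  ## multi-seed medians: diameter within 15%, CQ^2 within 20%
  for (d in c(6, 25)) {
    errD <- errC <- numeric(5)
    for (s in 1:5) {
      scan <- studyScan(d, seed = s)
      ana <- susiAnalysis(scan$sample, scan$reference)
      errD[s] <- abs(ana$estimate$diameterUm - d) / d
      errC[s] <- abs(ana$estimate$cq2 - 360) / 360
    }
    expect_lt(stats::median(errD), 0.15)
    expect_lt(stats::median(errC), 0.20)
  }
  ## doubling C doubles CQ^2 (within 15%)
  s1 <- studyScan(14, concentration = 1000, seed = 5)
  s2 <- studyScan(14, concentration = 2000, seed = 5)
  a1 <- susiAnalysis(s1$sample, s1$reference)
  a2 <- susiAnalysis(s2$sample, s2$reference)
  expect_lt(abs(a2$estimate$cq2 / a1$estimate$cq2 - 2) / 2, 0.15)
})

test_that("per-window inversions flag non-physical slopes instead of clipping", {
  scan <- studyScan(6, seed = 2)
  ana <- susiAnalysis(scan$sample, scan$reference)
  wt <- ana$windowTable
  ## small scatterers put some windows past the zero-radius slope limit;
  ## those must be NA, not clipped to zero
  expect_true(all(is.na(wt$radiusUm) | wt$radiusUm > 0))
  expect_true(all(is.na(wt$cq2[is.na(wt$radiusUm)])))
})

test_that("ROI statistics aggregate windows by element geometry", {
  g <- acquisitionGrid(1000, 60, 1)
  ## a 0.6 mm element at 31 um spacing spans floor(600/31) = 19 A-lines
  wt <- data.frame(slice = 1L, line = rep(1:60, each = 2),
                   center = rep(c(300, 500), 60))
  wt$diameterUm <- 14; wt$cq2 <- 360
  rs <- roiStatistics(wt, g, minWindows = 2L)
  expect_equal(rs$perRoi$nWindows[rs$perRoi$roi == "0:0"], 19 * 2)
  ## identical values: mean v, sd 0
  expect_true(all(rs$perRoi$diameterUmMean == 14))
  expect_true(all(rs$perRoi$diameterUmSd == 0))
  expect_equal(unname(rs$construct["diameterUm"]), 14)

  ## two ROIs with different values: construct mean is count-weighted
  wt2 <- data.frame(slice = 1L, line = c(rep(1:19, 2), rep(20:38, 3)),
                    center = 300)
  wt2$diameterUm <- c(rep(10, 38), rep(20, 57))
  wt2$cq2 <- 1
  rs2 <- roiStatistics(wt2, g, minWindows = 2L)
  expect_equal(unname(rs2$construct["diameterUm"]),
               (38 * 10 + 57 * 20) / 95)

  ## sparse ROI excluded
  wt3 <- rbind(wt2, data.frame(slice = 1L, line = 59, center = 300,
                               diameterUm = 99, cq2 = 1))
  expect_message(rs3 <- roiStatistics(wt3, g, minWindows = 2L), "excluded")
  expect_false(any(rs3$perRoi$diameterUmMean == 99))
})
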