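test_that("nearest-window maps are exact at window centers and uniform for uniform input", {
  scan <- cleanScan(14, seed = 3)
  bm <- bmodeImage(scan$sample, 1L)
  times <- detectSurfaces(scan$sample, scan$reference)
  cs <- calibratedSpectrum(scan$sample, scan$reference, times, 1540)
  wt <- cs@windows
  wt$diameterUm <- 14

  mp <- buildParametricMap(bm, wt, "diameter")
  ## uniform input: uniform map inside the mask
  expect_true(all(mapValues(mp)[mapMask(mp)] == 14))
  expect_true(any(mapMask(mp)))

  ## exact values at window centers under nearest mode
  wt$diameterUm <- seq_len(nrow(wt))
  mp2 <- buildParametricMap(bm, wt, "diameter")
  for (w in sample(nrow(wt), 10))
    expect_equal(mapValues(mp2)[round(wt$center[w]), wt$line[w]],
                 wt$diameterUm[w])

  expect_error(buildParametricMap(bm, wt, "nonsense"))
  ## calcium map on zero-calcium table: all-zero overlay
  wt$calciumConcUgMl <- 0
  mc <- buildParametricMap(bm, wt, "calcium")
  expect_true(all(mapValues(mc)[mapMask(mc)] == 0))
})

test_that("two-region constructs map to their regional diameters", {
  ## splice window tables from two homogeneous simulations: 6 um in the
  ## upper half, 25 um in the lower half
  s6 <- studyScan(6, seed = 8)
  s25 <- studyScan(25, seed = 8)
  a6 <- susiAnalysis(s6$sample, s6$reference)
  a25 <- susiAnalysis(s25$sample, s25$reference)
  wt6 <- a6$windowTable; wt25 <- a25$windowTable
  zSplit <- stats::median(wt6$zMm)
  spliced <- rbind(wt6[wt6$zMm < zSplit, ], wt25[wt25$zMm >= zSplit, ])
  bm <- bmodeImage(s6$sample, 1L)
  mp <- buildParametricMap(bm, spliced, "diameter")
  split <- stats::median(spliced$center)
  top <- mapValues(mp)[seq_len(floor(split)), ][mapMask(mp)[seq_len(floor(split)), ]]
  bot <- mapValues(mp)[-seq_len(floor(split)), ][mapMask(mp)[-seq_len(floor(split)), ]]
  expect_lt(abs(stats::median(top, na.rm = TRUE) - 6) / 6, 0.15)
  expect_lt(abs(stats::median(bot, na.rm = TRUE) - 25) / 25, 0.15)
})

test_that("overlay rendering is aligned, deterministic and mask-aware", {
  dir <- withr::local_tempdir()
  scan <- cleanScan(14, seed = 3)
  bm <- bmodeImage(scan$sample, 1L)
  times <- detectSurfaces(scan$sample, scan$reference)
  cs <- calibratedSpectrum(scan$sample, scan$reference, times, 1540)
  wt <- cs@windows
  wt$diameterUm <- stats::runif(nrow(wt), 10, 20)
  mp <- buildParametricMap(bm, wt, "diameter")

  f1 <- file.path(dir, "o1.png")
  renderOverlay(bm, mp, f1)
  expect_true(file.exists(f1))
  img <- png::readPNG(f1)
  expect_equal(dim(img)[1], nrow(bmodeValues(bm)))

  ## byte-identical re-render
  f2 <- file.path(dir, "o2.png")
  renderOverlay(bm, mp, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  ## empty mask renders the pure B-mode (same underlay pixels)
  empty <- new("ParametricMap", parameter = "diameter",
               values = matrix(NA_real_, nrow(bmodeValues(bm)),
                               ncol(bmodeValues(bm))),
               mask = matrix(FALSE, nrow(bmodeValues(bm)),
                             ncol(bmodeValues(bm))),
               range = c(0, 0), colormap = "viridis")
  f3 <- file.path(dir, "o3.png")
  renderOverlay(bm, empty, f3)
  plain <- png::readPNG(f3)
  full <- png::readPNG(f1)
  nc <- ncol(bmodeValues(bm))
  gray <- (bmodeValues(bm) + bm@dynamicRange) / bm@dynamicRange
  expect_lt(max(abs(plain[, seq_len(nc), 1] - gray)), 1 / 250)

  ## misaligned geometry rejected
  small <- new("ParametricMap", parameter = "diameter",
               values = matrix(0, 2, 2), mask = matrix(TRUE, 2, 2),
               range = c(0, 1), colormap = "viridis")
  expect_error(renderOverlay(bm, small, file.path(dir, "bad.png")),
               "misaligned")
})

test_that("bilinear interpolation stays within the window value range", {
  scan <- cleanScan(14, seed = 3)
  bm <- bmodeImage(scan$sample, 1L)
  times <- detectSurfaces(scan$sample, scan$reference)
  cs <- calibratedSpectrum(scan$sample, scan$reference, times, 1540)
  wt <- cs@windows
  wt$diameterUm <- stats::runif(nrow(wt), 5, 30)
  mp <- buildParametricMap(bm, wt, "diameter", interpolation = "bilinear")
  v <- mapValues(mp)[mapMask(mp)]
  expect_true(all(v >= 5 - 1e-9 & v <= 30 + 1e-9))
})
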