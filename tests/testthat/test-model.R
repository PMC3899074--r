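bandGrid <- seq(21, 75, by = 420 / 256)   # typical analysis-band FFT grid

test_that("radius inversion is the exact algebraic inverse of the slope model", {
  for (a in c(3, 5, 7, 8, 12.5)) {
    m <- slopeForRadius(a, bandGrid)
    expect_equal(radiusFromSlope(m, bandGrid), a, tolerance = 1e-12)
  }
  ## slope above the zero-radius limit is non-physical
  m0 <- slopeForRadius(1e-9, bandGrid)
  expect_true(is.na(radiusFromSlope(m0 + 0.1, bandGrid)))
})

test_that("concentration inversion is the exact inverse of the MBF model", {
  for (cq2 in c(360, 7.2e5)) {
    mbf <- mbfForScatterers(7, cq2, bandGrid)
    expect_equal(acousticConcentration(mbf, 7, bandGrid), cq2,
                 tolerance = 1e-10)
  }
  ## geometry exponent and sound speed propagate consistently
  mbf <- mbfForScatterers(5, 1000, bandGrid, n = 3.5, soundSpeed = 1500)
  expect_equal(acousticConcentration(mbf, 5, bandGrid, n = 3.5,
                                     soundSpeed = 1500), 1000,
               tolerance = 1e-10)
})

test_that("C / Q completion follows Q = sqrt(CQ2/C) and C = CQ2/Q^2", {
  got <- concentrationAndImpedance(360, knownC = 1000)
  expect_equal(got$impedance, 0.6)
  expect_equal(concentrationAndImpedance(123.4, knownQ = 1)$concentration,
               123.4)
  expect_error(concentrationAndImpedance(1, knownC = 1, knownQ = 1),
               "exactly one")
  expect_error(concentrationAndImpedance(1), "exactly one")
})

test_that("equivalent scatterer number is concentration times volume", {
  expect_equal(equivalentScattererNumber(360, 100), 3.6e4)
  expect_equal(equivalentScattererNumber(360, 0), 0)
  ## shrinking volume at fixed C, Q tracks proportionally
  v <- c(100, 50, 25)
  expect_equal(equivalentScattererNumber(360, v) / v, rep(360, 3))
})

test_that("calcium mass is the exact inverse of the impedance forward model", {
  ## configured mass forward to Q_i, then inverted: machine precision
  q0 <- 0.6; N <- 1e4; a <- 7
  qi <- impedanceForCalcium(4, q0, N, a)
  got <- calciumMass(q0, qi, N, a)
  expect_equal(got$massUg, 4, tolerance = 1e-10)

  ## no deposition
  expect_equal(calciumMass(0.6, 0.6, N, a)$massUg, 0)

  ## impedance below baseline clamps at zero with a warning
  expect_warning(neg <- calciumMass(0.6, 0.5, N, a), "zero mass")
  expect_equal(neg$massUg, 0)

  ## concentration divides by construct volume in ml
  cc <- calciumMass(q0, qi, N, a, constructVolumeMm3 = 500)
  expect_equal(cc$concentrationUgMl, 4 / 0.5, tolerance = 1e-10)
})

test_that("attenuation correction applies the printed formulas exactly", {
  got <- correctAttenuation(0.5, -10, alpha = 0.5, zCm = 0.1, fCenter = 47.5)
  expect_equal(got$slope - 0.5, 0.1)
  expect_equal(got$mbf - (-10), 4.75)
  ## alpha = 0: identity
  same <- correctAttenuation(0.3, -5, 0, 0.2, 47.5)
  expect_equal(same$slope, 0.3)
  expect_equal(same$mbf, -5)
  expect_error(correctAttenuation(0, 0, 0.5, -1, 47.5), "non-negative")
})

test_that("relative impedance follows the fractional contrast definition", {
  expect_equal(relativeImpedance(1000, 1540, 1000, 1540), 0)
  expect_equal(relativeImpedance(1600, 1540, 1000, 1540), 0.6)
  ## forward mineralization raises impedance monotonically with mass
  q <- vapply(c(0, 1, 2, 4), function(m)
    impedanceForCalcium(m, 0.6, 1e4, 7), numeric(1))
  expect_true(all(diff(q) > 0))
  expect_equal(q[1], 0.6)
})

test_that("slope and MBF regression are exact on synthetic spectra", {
  f <- seq(20, 75, by = 0.5)
  ## exact line: recovered to machine precision
  y <- 0.5 * f - 10
  fit <- fitSlopeMBF(f, y, band = c(20, 75))
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$mbf, 0.5 * 47.5 - 10, tolerance = 1e-12)

  ## flat zero spectrum
  fit0 <- fitSlopeMBF(f, numeric(length(f)), band = c(20, 75))
  expect_equal(fit0$slope, 0)
  expect_equal(fit0$mbf, 0)

  ## noisy line: estimate within 3 standard errors
  set.seed(3)
  yn <- 0.5 * f - 10 + rnorm(length(f), sd = 1)
  fitn <- fitSlopeMBF(f, yn, band = c(20, 75))
  se <- summary(lm(yn ~ f))$coefficients[2, 2]
  expect_lt(abs(fitn$slope - 0.5), 3 * se)

  expect_error(fitSlopeMBF(f, y, band = c(47, 48.4)), "5 regression points")
})
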