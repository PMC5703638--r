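th <- thresholdSet(0.3, 3.0, 5.3, 7.5, 16)

test_that("background solves the internal-standard ratio equation", {
  expect_equal(signif(estimateBackground(5.3, 16, 2.29), 3), 24.3)
  expect_equal(signif(estimateBackground(7.5, 16, 1.57), 3), 30.9)
  # exact solution of (ref - x)/(water - x) = ratio
  x <- estimateBackground(5.3, 16, 2.29)
  expect_equal((5.3 - x) / (16 - x), 2.29, tolerance = 1e-12)
  expect_gt(x, 16)
})

test_that("background approaches water from above as the ratio grows", {
  x <- estimateBackground(15, 16, 1e6)
  expect_gt(x, 16)
  expect_lt(x - 16, 1e-5)
  expect_error(estimateBackground(5.3, 16, 0.9), "exceed 1")
  expect_error(estimateBackground(17, 16, 2.29), "polarity")
})

test_that("TCP intensity extrapolates linearly below zero", {
  expect_equal(extrapolateTcpIntensity(24.3, 16, 6.06), -26.0,
               tolerance = 0.05)
  expect_equal(extrapolateTcpIntensity(30.9, 16, 6.06), -59.4,
               tolerance = 0.05)
  expect_equal(extrapolateTcpIntensity(24.3, 16, 1), 16)
  expect_error(extrapolateTcpIntensity(10, 16, 6.06), "polarity")
})

test_that("density fractions reproduce the evaluation grid", {
  calib <- intensityCalibration(th, quoteX = TRUE)
  est <- densityFraction(0.3, calib)
  expect_equal(round(est$ratioToWater, 2), 2.89)
  expect_equal(round(est$fractionOfTcp, 2), 0.48)
  expect_equal(round(densityFraction(3.0, calib)$ratioToWater, 2), 2.57)
  # background maps to zero, TCP level to one, exactly
  expect_equal(densityFraction(backgroundX(calib), calib)$fractionOfTcp, 0)
  expect_equal(densityFraction(tcpIntensity(calib), calib)$fractionOfTcp, 1)
  # water maps to 1/tcpWaterRatio exactly
  expect_equal(densityFraction(16, calib)$fractionOfTcp, 1 / 6.06,
               tolerance = 1e-12)
})

test_that("intensities above background are flagged, not clipped", {
  calib <- intensityCalibration(th)
  expect_warning(est <- densityFraction(30, calib), "above background")
  expect_true(est$aboveBackground)
  expect_lt(est$fractionOfTcp, 0)
})

test_that("density fraction is strictly decreasing and affine-invariant", {
  calib <- intensityCalibration(th)
  ii <- seq(-20, 24, length.out = 40)
  fr <- densityFraction(ii, calib)$fractionOfTcp
  expect_true(all(diff(fr) < 0))
  set.seed(7)
  for (k in 1:5) {
    a <- runif(1, 0.2, 5); b <- runif(1, -10, 10)
    th2 <- thresholdSet(a * 0.3 + b, a * 3.0 + b, a * 5.3 + b,
                        a * 7.5 + b, a * 16 + b)
    c2 <- intensityCalibration(th2)
    expect_equal(densityFraction(a * ii + b, c2)$fractionOfTcp,
                 fr, tolerance = 1e-9)
  }
})

test_that("calibrating on the reference level returns the predicted ratio", {
  calib <- intensityCalibration(th, reference = "rna_peak")
  est <- densityFraction(5.3, calib)
  expect_equal(est$ratioToWater, 2.29, tolerance = 1e-12)
  expect_equal(est$fractionOfTcp, 2.29 / 6.06, tolerance = 1e-12)
})

test_that("full evaluation report matches cell-for-cell", {
  rep <- granuleDensityReport(th)
  expect_equal(signif(backgroundX(rep$primary), 3), 24.3)
  expect_equal(signif(backgroundX(rep$parenthetical), 3), 30.9)
  expect_equal(round(tcpIntensity(rep$primary), 1), -26.0)
  expect_equal(round(tcpIntensity(rep$parenthetical), 1), -59.4)
  g <- rep$grid
  expect_equal(g$ratioToWater, c(2.89, 2.57, 2.29, 2.02, 1.00))
  expect_equal(g$ratioToTcp[1:4], c(0.48, 0.42, 0.38, 0.33))
  expect_lt(abs(g$ratioToTcp[5] - 0.165), 0.006)
  expect_equal(g$ratioToWaterAlt, c(2.05, 1.87, 1.72, 1.57, 1.00))
  expect_equal(g$ratioToTcpAlt[1:4], c(0.34, 0.31, 0.28, 0.26))
})

test_that("degenerate thresholds violate the ordering invariant", {
  expect_error(thresholdSet(5, 5, 5, 5, 5), "ordering")
  expect_error(thresholdSet(3, 0.3, 5.3, 7.5, 16), "ordering")
  expect_error(thresholdSet(0.3, 3, 7.5, 5.3, 16), "ordering")
})

test_that("equivalent concentrations follow the dissolution arithmetic", {
  conc <- equivalentConcentration(0.31, volumeFraction = 0.20)
  expect_equal(round(conc[["calcium_M"]], 1), 1.9)
  expect_equal(round(conc[["phosphate_M"]], 1), 1.3)
  expect_equal(unname(equivalentConcentration(0.31, 0)), c(0, 0, 0))
  # intra-granule molarity at volume fraction 1
  expect_equal(equivalentConcentration(0.31, 1)[["formula_M"]], 3.138,
               tolerance = 1e-3)
  expect_error(equivalentConcentration(0.31, 1.5), "volumeFraction")
})

test_that("fractions of TCP map to the quoted mass-density ranges", {
  expect_equal(round(c(0.34, 0.48) * 3.14, 1), c(1.1, 1.5))
  expect_equal(round(c(0.31, 0.42) * 3.14, 1), c(1.0, 1.3))
  calib <- intensityCalibration(th, quoteX = TRUE)
  expect_equal(round(densityFraction(0.3, calib)$massDensity, 1), 1.5)
})
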