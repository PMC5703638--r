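# Small phantoms keep these tests fast; the full-scale recovery lives in
# the acceptance suite.
smallSpec <- function(...) {
  args <- utils::modifyList(
    list(shape = c(96L, 96L, 96L), voxelSize = 4,
         semiAxes = c(140, 150, 160), nGranules = 40L,
         targetFill = 0.10, nRibosomes = 12L,
         psfSigma = 0, noiseSd = 0, seed = 42L),
    list(...))
  do.call(phantomSpec, args)
}

test_that("phantom generation is deterministic and seed-driven", {
  ph1 <- generatePhantom(smallSpec())
  ph2 <- generatePhantom(smallSpec())
  expect_identical(volumeData(ph1$volume), volumeData(ph2$volume))
  expect_identical(ph1$groundTruth$granules, ph2$groundTruth$granules)
  ph3 <- generatePhantom(smallSpec(seed = 43L))
  expect_false(identical(volumeData(ph1$volume), volumeData(ph3$volume)))
})

test_that("phantom generation leaves the global RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generatePhantom(smallSpec()))
  expect_identical(.Random.seed, before)
})

test_that("empty spec yields a constant volume at the cytosol level", {
  sp <- phantomSpec(shape = c(32L, 32L, 32L), nGranules = 0L,
                    targetFill = 0, nRibosomes = 0L, psfSigma = 0,
                    noiseSd = 0)
  sp@matrixSignal <- sp@cytosolSignal
  ph <- generatePhantom(sp)
  expect_equal(max(volumeData(ph$volume)) - min(volumeData(ph$volume)), 0)
  expect_equal(volumeData(ph$volume)[1], 16, tolerance = 1e-9)
})

test_that("noise-free granule intensity inverts to its TCP fraction", {
  sig <- c(water = signalValue(signalPerVolume(referenceProfile("water"))),
           rib = signalValue(signalPerVolume(referenceProfile("ribosome"))),
           tcp = signalValue(signalPerVolume(referenceProfile("TCP"))))
  sp <- phantomSpec(shape = c(64L, 64L, 64L), voxelSize = 4,
                    semiAxes = c(90, 90, 90), nGranules = 1L,
                    targetFill = 0, fractionOfTcp = 0.4772,
                    diameterMedian = 60, diameterSdlog = 1e-6,
                    nRibosomes = 0L, psfSigma = 0, noiseSd = 0, seed = 1L)
  ph <- generatePhantom(sp)
  g <- ph$groundTruth$granules
  expect_equal(nrow(g), 1L)
  cidx <- round(c(g$cz_nm, g$cy_nm, g$cx_nm) / 4 + 0.5)
  interior <- volumeData(ph$volume)[cidx[1], cidx[2], cidx[3]]
  calib <- calibrationFromReference(
    referenceIntensity = 24.3 - sp@contrastGain * sig[["rib"]],
    waterIntensity = 16,
    referenceRatio = sig[["rib"]] / sig[["water"]],
    tcpWaterRatio = sig[["tcp"]] / sig[["water"]])
  expect_equal(backgroundX(calib), 24.3, tolerance = 1e-9)
  expect_equal(densityFraction(interior, calib)$fractionOfTcp, 0.4772,
               tolerance = 1e-9)
})

test_that("water region sits at the implied water level within noise", {
  sp <- smallSpec(noiseSd = 0.5, psfSigma = 4)
  ph <- generatePhantom(sp)
  lv <- measureReferenceLevels(ph)
  n <- 1000  # conservative lower bound on cytosol voxels used
  expect_lt(abs(lv$waterLevel - 16), 3 * 0.5 / sqrt(n) + 0.02)
  # threshold ordering invariant holds for measured levels
  expect_true(lv$thresholds[["granule_peak"]] <
                lv$thresholds[["granule_inclusive"]])
  expect_true(lv$thresholds[["ribosome_peak"]] < lv$waterLevel)
})

test_that("realized fill honours the target within 10% relative", {
  ph <- generatePhantom(smallSpec(targetFill = 0.15))
  fill <- ph$groundTruth$realizedFill
  expect_lt(abs(fill - 0.15), 0.1 * 0.15 + 0.01)
  # granules do not overlap: mask voxels equal the sum of sphere voxels
  g <- ph$groundTruth$granules
  expect_gt(nrow(g), 3)
  expect_true(all(g$diameter_nm >= 20 & g$diameter_nm <= 100))
})

test_that("infeasible packing raises an explicit error", {
  sp <- phantomSpec(shape = c(48L, 48L, 48L), voxelSize = 4,
                    semiAxes = c(60, 60, 60), nGranules = 400L,
                    targetFill = 0.55, diameterMedian = 40,
                    nRibosomes = 0L, seed = 7L)
  expect_error(generatePhantom(sp, maxAttempts = 50L),
               "infeasible packing")
})

test_that("granule statistics recover the generated size distribution", {
  sp <- phantomSpec(shape = c(160L, 160L, 160L), voxelSize = 4,
                    semiAxes = c(260, 280, 300), nGranules = 50L,
                    targetFill = 0, nRibosomes = 0L,
                    psfSigma = 4, noiseSd = 0.3, seed = 9L)
  ph <- generatePhantom(sp)
  truth <- ph$groundTruth$granules
  expect_equal(nrow(truth), 50L)
  lv <- measureReferenceLevels(ph)
  seg <- segmentByThreshold(ph$volume,
                            lv$granuleInclusive)
  st <- granuleStatistics(seg, minDiameter = 15)
  expect_equal(nrow(st), 50L)
  expect_lt(abs(mean(st$diameter_nm) - mean(truth$diameter_nm)) /
              mean(truth$diameter_nm), 0.10)
})
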