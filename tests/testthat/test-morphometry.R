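test_that("band-pass removes DC and preserves in-band sinusoids", {
  const <- volumeGrid(array(7, dim = c(2, 32, 32)))
  out <- bandpassFilter(const, 1, 100)
  expect_lt(max(abs(volumeData(out))), 1e-10)

  # wavelength 10 px along y on a 500-px grid: exact FFT bin, in band
  n <- 500
  s <- sin(2 * pi * (0:(n - 1)) / 10)
  arr <- array(rep(s, times = 4), dim = c(1, n, 4))
  filt <- bandpassFilter(volumeGrid(arr), 1, 100)
  expect_lt(max(abs(volumeData(filt) - arr)), 0.01)
})

test_that("band-pass suppresses wavelengths beyond the upper cutoff", {
  n <- 1200  # wavelength 400 px sits on an exact FFT bin (3 cycles)
  s <- sin(2 * pi * (0:(n - 1)) / 400)
  arr <- array(rep(s, times = 4), dim = c(1, n, 4))
  filt <- bandpassFilter(volumeGrid(arr), 1, 100)
  expect_lt(stats::sd(volumeData(filt)), 0.1 * stats::sd(arr))
})

test_that("3D band-pass matches the slice filter on slice-constant input", {
  set.seed(11)
  sl <- matrix(rnorm(32 * 32), 32, 32)
  arr <- array(rep(sl, each = 8), dim = c(8, 32, 32))
  a2 <- volumeData(bandpassFilter(volumeGrid(arr), 2, 16, dims = 2))
  a3 <- bandpassFilter(volumeGrid(arr), 2, 16, dims = 3)
  expect_equal(dim(volumeData(a3)), dim(arr))
  expect_error(bandpassFilter(volumeGrid(arr), 16, 2), "lowCut")
  expect_equal(a2[3, , ], a2[5, , ])  # slice filter acts identically per z
})

test_that("threshold segmentation counts components correctly", {
  flat <- volumeGrid(array(10, dim = c(8, 8, 8)))
  expect_equal(nComponents(segmentByThreshold(flat, 5)), 0L)

  # two separated spheres
  arr <- array(10, dim = c(24, 24, 24))
  v <- volumeGrid(arr)
  v@data[3:7, 3:7, 3:7] <- 0
  v@data[15:20, 15:20, 15:20] <- 0
  expect_equal(nComponents(segmentByThreshold(v, 5)), 2L)

  # corner-touching cubes: one component at 26-connectivity, two at 6
  w <- volumeGrid(array(10, dim = c(10, 10, 10)))
  w@data[2:4, 2:4, 2:4] <- 0
  w@data[5:7, 5:7, 5:7] <- 0
  expect_equal(nComponents(segmentByThreshold(w, 5, 26)), 1L)
  expect_equal(nComponents(segmentByThreshold(w, 5, 6)), 2L)
})

test_that("segmented sphere volume matches the analytic value", {
  v <- sphereVolume(n = 32, radius = 10)
  seg <- segmentByThreshold(v, 5)
  expect_equal(nComponents(seg), 1L)
  vox <- sum(labelData(seg) > 0)
  expect_lt(abs(vox - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
})

test_that("granule statistics recover diameters and satisfy bookkeeping", {
  v <- sphereVolume(n = 56, radius = 25, voxelSize = 1)
  seg <- segmentByThreshold(v, 5)
  st <- granuleStatistics(seg, minDiameter = 0)
  expect_equal(nrow(st), 1L)
  expect_lt(abs(st$diameter_nm - 50), 2)
  expect_equal(st$cz_nm, 56 / 2, tolerance = 0.05)
  expect_equal(sum(st$volume_nm3),
               attr(st, "totalForegroundVoxels") * 1^3)

  emptySeg <- segmentByThreshold(volumeGrid(array(10, dim = c(6, 6, 6))), 5)
  st0 <- granuleStatistics(emptySeg)
  expect_equal(nrow(st0), 0L)
})

test_that("minimum-diameter filter excludes specks but counts them", {
  v <- sphereVolume(n = 40, radius = 10)
  v@data[2, 2, 2] <- 0  # single-voxel speck
  seg <- segmentByThreshold(v, 5)
  expect_equal(nComponents(seg), 2L)
  st <- granuleStatistics(seg, minDiameter = 10)
  expect_equal(nrow(st), 1L)
  expect_equal(attr(st, "nExcluded"), 1L)
})

test_that("volume fraction inside an ROI behaves at the extremes", {
  v <- sphereVolume(n = 32, radius = 12)
  seg <- segmentByThreshold(v, 5)
  inside <- rbind(c(14, 14, 14), c(18, 18, 18))
  expect_equal(volumeFraction(seg, inside), 1)
  corner <- rbind(c(0, 0, 0), c(3, 3, 3))
  expect_equal(volumeFraction(seg, corner), 0)
  expect_error(volumeFraction(seg, rbind(c(0, 0, 0), c(40, 8, 8))),
               "bounds")
  expect_error(volumeFraction(seg, rbind(c(4, 4, 4), c(4, 8, 8))),
               "bounds")
})

test_that("segmentation is monotone in the BF threshold level", {
  set.seed(3)
  arr <- array(rnorm(20^3, mean = 5, sd = 3), dim = c(20, 20, 20))
  v <- volumeGrid(arr)
  lv1 <- labelData(segmentByThreshold(v, 2)) > 0
  lv2 <- labelData(segmentByThreshold(v, 4)) > 0
  expect_true(all(lv2[lv1]))  # raising the level never removes a voxel
})

test_that("component count is invariant under 90-degree rotation", {
  set.seed(5)
  arr <- array(10, dim = c(16, 16, 16))
  v <- volumeGrid(arr)
  for (k in 1:4) {
    c0 <- 2 + 3 * k %% 3
    v@data[c0:(c0 + 2), (2 * k):(2 * k + 2), (15 - 2 * k):(16 - k)] <- 0
  }
  n1 <- nComponents(segmentByThreshold(v, 5))
  rot <- volumeGrid(aperm(v@data, c(2, 3, 1)))
  expect_equal(nComponents(segmentByThreshold(rot, 5)), n1)
})

test_that("volume fraction is invariant under affine intensity rescaling", {
  v <- sphereVolume(n = 24, radius = 8)
  f1 <- volumeFraction(segmentByThreshold(v, 5),
                       rbind(c(0, 0, 0), c(24, 24, 24)))
  v2 <- volumeGrid(3 * v@data - 7, voxelSize = 1)
  f2 <- volumeFraction(segmentByThreshold(v2, 3 * 5 - 7),
                       rbind(c(0, 0, 0), c(24, 24, 24)))
  expect_equal(f1, f2)
})
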