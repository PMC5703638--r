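# Fixtures built in code: printed reference tables and small geometric
# volumes shared across tests.

# Quoted per-element densities (atoms/nm^3) of the reference tabulation.
printedDensities <- list(
  rRNA = c(C = 31.2, H = 35.5, N = 12.7, O = 22.9, P = 3.3, Mg = 0.24),
  ribosome = c(C = 19.3, H = 53.2, N = 6.86, O = 23.0, S = 0.072,
               P = 1.03, Mg = 0.034),
  TCP = c(Ca = 18.4, P = 12.2, O = 49.1))

# Packaged atom counts.
refCountsFixture <- list(
  rRNA = c(C = 68671, H = 78158, N = 27884, O = 50462, P = 7216, Mg = 239),
  ribosome = c(C = 135061, H = 372416, N = 48041, O = 161037, S = 501,
               P = 7216, Mg = 239))

# A volume containing one centered sphere of given radius (voxels),
# foreground intensity inside, background outside (BF polarity).
sphereVolume <- function(n, radius, inside = 0, outside = 10,
                         voxelSize = 1, center = NULL) {
  if (is.null(center)) center <- rep((n + 1) / 2, 3)
  ax <- seq_len(n)
  r2 <- outer(outer((ax - center[1])^2, (ax - center[2])^2, "+"),
              (ax - center[3])^2, "+")
  arr <- array(outside, dim = c(n, n, n))
  arr[r2 <= radius^2] <- inside
  volumeGrid(arr, voxelSize, "bf")
}

# independent mass-density oracle: atoms/nm^3 -> g/cm^3 by hand arithmetic
massDensityOracle <- function(densities) {
  sum(densities * atomicWeights(names(densities))) / 6.02214076e23 * 1e21
}
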