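## Synthetic-data module: phantom BF tomograms with known ground truth.
## The intensity model matches the calibration model: voxel intensity =
## backgroundX - contrastGain * (local scattering signal), Gaussian-blurred
## (detector/reconstruction PSF) with additive Gaussian noise. Linear in
## the signal (thin-sample, low-contrast regime); exponential attenuation
## is deliberately omitted.

#' Phantom specification
#'
#' Full generative description of a synthetic BF tomogram: an ellipsoidal
#' mitochondrion containing spherical calcium-phosphate granules, plus
#' ribosome-like reference puncta in the cytosol.
#'
#' Defaults encode the imaged conditions: granule diameters lognormal
#' (median 50 nm, sdlog 0.35) truncated to the observed 20-100 nm range,
#' granules filling 20\% of the mitochondrial volume at 40\% of crystalline
#' TCP density, 25 nm ribosomes at the predicted ribosome signal, cytosol
#' at the vitreous-water signal, and intensities scaled so that water sits
#' at 16 with background x = 24.3 (the representative tomogram's scale).
#'
#' @param shape grid (z, y, x) in voxels.
#' @param voxelSize nm per voxel.
#' @param center,semiAxes ellipsoid center and semi-axes in nm
#'   (default: grid center; semi-axes (300, 350, 450) nm).
#' @param nGranules maximum number of granules to place.
#' @param diameterMedian,diameterSdlog lognormal diameter parameters (nm).
#' @param diameterRange truncation range (nm).
#' @param targetFill granule volume fraction of the ellipsoid to reach
#'   (placement stops when reached; 0 disables the fill target).
#' @param fractionOfTcp granule density as fraction of crystalline TCP;
#'   scalar or range c(lo, hi) sampled per granule.
#' @param nRibosomes,ribosomeDiameter cytosolic reference puncta.
#' @param ribosomeSignal,matrixSignal,cytosolSignal,tcpSignal scattering
#'   signals, nm^-1; defaults from the packaged composition/cross-section
#'   tables (unrounded).
#' @param backgroundX,contrastGain intensity model; default gain puts
#'   water (cytosol) at intensity 16.
#' @param psfSigma Gaussian PSF sigma, nm.
#' @param noiseSd additive Gaussian noise sd, intensity units.
#' @param minSeparation minimum surface-to-surface gap between granules, nm.
#' @param seed RNG seed; all phantom randomness flows from it.
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(shape = c(256L, 256L, 256L), voxelSize = 4,
                        center = NULL, semiAxes = c(300, 350, 450),
                        nGranules = 1000L,
                        diameterMedian = 50, diameterSdlog = 0.35,
                        diameterRange = c(20, 100),
                        targetFill = 0.20, fractionOfTcp = 0.40,
                        nRibosomes = 100L, ribosomeDiameter = 25,
                        ribosomeSignal = NULL, matrixSignal = 0.18,
                        cytosolSignal = NULL, tcpSignal = NULL,
                        backgroundX = 24.3, contrastGain = NULL,
                        psfSigma = 4, noiseSd = 0.5,
                        minSeparation = 8, seed = 1L) {
  if (is.null(cytosolSignal))
    cytosolSignal <- signalPerVolume(referenceProfile("water"))@signal
  if (is.null(ribosomeSignal))
    ribosomeSignal <- signalPerVolume(referenceProfile("ribosome"))@signal
  if (is.null(tcpSignal))
    tcpSignal <- signalPerVolume(referenceProfile("TCP"))@signal
  if (is.null(contrastGain))
    contrastGain <- (backgroundX - 16) / cytosolSignal
  if (is.null(center)) center <- shape / 2 * voxelSize
  new("PhantomSpec", shape = as.integer(shape), voxelSize = voxelSize,
      center = center, semiAxes = semiAxes,
      nGranules = as.integer(nGranules),
      diameterMedian = diameterMedian, diameterSdlog = diameterSdlog,
      diameterRange = diameterRange, targetFill = targetFill,
      fractionOfTcp = fractionOfTcp, nRibosomes = as.integer(nRibosomes),
      ribosomeDiameter = ribosomeDiameter,
      ribosomeSignal = ribosomeSignal, matrixSignal = matrixSignal,
      cytosolSignal = cytosolSignal, tcpSignal = tcpSignal,
      backgroundX = backgroundX, contrastGain = contrastGain,
      psfSigma = psfSigma, noiseSd = noiseSd,
      minSeparation = minSeparation, seed = as.integer(seed))
}

## run expr with a private RNG stream seeded by `seed`
.withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## paint value into arr inside a sphere (center nm, radius nm); returns arr
.paintSphere <- function(arr, voxelSize, center, radius, value) {
  d <- dim(arr)
  cv <- center / voxelSize + 0.5           # voxel-center coordinates
  rv <- radius / voxelSize
  lo <- pmax(ceiling(cv - rv - 1), 1)
  hi <- pmin(floor(cv + rv + 1), d)
  if (any(hi < lo)) return(arr)
  zz <- (lo[1]:hi[1] - cv[1])^2
  yy <- (lo[2]:hi[2] - cv[2])^2
  xx <- (lo[3]:hi[3] - cv[3])^2
  m <- outer(outer(zz, yy, "+"), xx, "+") <= rv^2
  blk <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  blk[m] <- value
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- blk
  arr
}

## separable Gaussian blur via FFT; sigma in voxels
.gaussianBlurFFT <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  d <- dim(arr)
  tf1 <- function(n) exp(-2 * pi^2 * sigma^2 * .fftFreq(n)^2)
  tf <- outer(outer(tf1(d[1]), tf1(d[2])), tf1(d[3]))
  out <- Re(stats::fft(stats::fft(arr) * tf, inverse = TRUE)) / length(arr)
  dim(out) <- d
  out
}

## truncated lognormal diameter draw
.drawDiameter <- function(n, median, sdlog, range) {
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n && tries < 50L) {
    x <- stats::rlnorm(2L * n, meanlog = log(median), sdlog = sdlog)
    out <- c(out, x[x >= range[1] & x <= range[2]])
    tries <- tries + 1L
  }
  if (length(out) < n)
    stop("could not draw diameters inside the truncation range")
  out[seq_len(n)]
}

#' Generate a phantom BF tomogram
#'
#' Builds the scattering-signal volume (cytosol everywhere, matrix signal
#' inside the ellipsoid, granules placed by rejection sampling without
#' overlap, ribosome puncta in the cytosol), converts it to intensities
#' with the linear BF model, applies the Gaussian PSF and adds noise.
#' Deterministic for a fixed spec seed; no global RNG state is disturbed.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param maxAttempts rejection-sampling attempts per granule before the
#'   packing is declared infeasible.
#' @return list:
#'   \describe{
#'     \item{volume}{the noisy blurred \linkS4class{VolumeGrid};}
#'     \item{groundTruth}{list with \code{granules} (data.frame: center,
#'       diameter, fractionOfTcp), \code{ribosomes} (data.frame of centers),
#'       \code{realizedFill} (voxelized granule fraction of the ellipsoid),
#'       \code{granuleMask}, \code{mitoMask} (logical arrays),
#'       \code{signals} (named numeric of model signals), and the spec.}
#'   }
#' @export
generatePhantom <- function(spec, maxAttempts = 2000L) {
  stopifnot(is(spec, "PhantomSpec"))
  .withLocalSeed(spec@seed, {
    d <- spec@shape
    vox <- spec@voxelSize
    sig <- array(spec@cytosolSignal, dim = d)

    ## ellipsoid mask and matrix signal
    zz <- ((seq_len(d[1]) - 0.5) * vox - spec@center[1]) / spec@semiAxes[1]
    yy <- ((seq_len(d[2]) - 0.5) * vox - spec@center[2]) / spec@semiAxes[2]
    xx <- ((seq_len(d[3]) - 0.5) * vox - spec@center[3]) / spec@semiAxes[3]
    mito <- outer(outer(zz^2, yy^2, "+"), xx^2, "+") <= 1
    sig[mito] <- spec@matrixSignal

    ## granule placement: largest-first rejection sampling, no overlap,
    ## entirely inside the ellipsoid
    ellVol <- 4 / 3 * pi * prod(spec@semiAxes)
    centers <- matrix(numeric(0), 0, 3)
    radii <- numeric(0)
    fracs <- numeric(0)
    placedVol <- 0
    if (spec@nGranules > 0L && spec@targetFill >= 0) {
      dia <- sort(.drawDiameter(spec@nGranules, spec@diameterMedian,
                                spec@diameterSdlog, spec@diameterRange),
                  decreasing = TRUE)
      for (dd in dia) {
        if (spec@targetFill > 0 && placedVol / ellVol >= spec@targetFill)
          break
        r <- dd / 2
        ## skip granules that would overshoot the fill target by > 10%
        if (spec@targetFill > 0 &&
            (placedVol + 4 / 3 * pi * r^3) / ellVol >
              1.1 * spec@targetFill) next
        a <- spec@semiAxes - r
        if (any(a <= 0)) next
        ok <- FALSE
        for (att in seq_len(maxAttempts)) {
          u <- stats::runif(3, -1, 1)
          if (sum(u^2) > 1) next
          cand <- spec@center + u * a
          if (nrow(centers)) {
            gap <- sqrt(colSums((t(centers) - cand)^2)) - radii - r
            if (any(gap < spec@minSeparation)) next
          }
          ok <- TRUE
          break
        }
        if (!ok) next  # placement failed; smaller granules may still fit
        centers <- rbind(centers, cand)
        radii <- c(radii, r)
        fr <- if (length(spec@fractionOfTcp) == 2L)
          stats::runif(1, spec@fractionOfTcp[1], spec@fractionOfTcp[2])
        else spec@fractionOfTcp
        fracs <- c(fracs, fr)
        placedVol <- placedVol + 4 / 3 * pi * r^3
      }
      if (spec@targetFill > 0 &&
          placedVol / ellVol < 0.9 * spec@targetFill)
        stop("infeasible packing: realized fill misses the target by >10%")
    }
    granMask <- array(FALSE, dim = d)
    for (i in seq_along(radii)) {
      sig <- .paintSphere(sig, vox, centers[i, ], radii[i],
                          fracs[i] * spec@tcpSignal)
      granMask <- .paintSphere(granMask, vox, centers[i, ], radii[i], TRUE)
    }

    ## ribosome puncta in cytosol, kept clear of the ellipsoid and borders
    ribC <- matrix(numeric(0), 0, 3)
    rr <- spec@ribosomeDiameter / 2
    margin <- rr + 3 * spec@psfSigma + vox
    lim <- d * vox
    att <- 0L
    while (nrow(ribC) < spec@nRibosomes && att < 200L * spec@nRibosomes) {
      att <- att + 1L
      cand <- stats::runif(3, margin, lim - margin)
      ell <- sum(((cand - spec@center) / (spec@semiAxes + margin))^2)
      if (ell <= 1) next
      if (nrow(ribC) &&
          min(sqrt(colSums((t(ribC) - cand)^2))) < 2 * rr + margin) next
      ribC <- rbind(ribC, cand)
    }
    for (i in seq_len(nrow(ribC)))
      sig <- .paintSphere(sig, vox, ribC[i, ], rr, spec@ribosomeSignal)

    ## linear BF intensity model, PSF, noise
    img <- spec@backgroundX - spec@contrastGain * sig
    img <- .gaussianBlurFFT(img, spec@psfSigma / vox)
    if (spec@noiseSd > 0)
      img <- img + stats::rnorm(length(img), sd = spec@noiseSd)
    dim(img) <- d

    realizedFill <- if (any(mito)) sum(granMask & mito) / sum(mito) else 0
    granules <- data.frame(
      cz_nm = centers[, 1], cy_nm = centers[, 2], cx_nm = centers[, 3],
      diameter_nm = 2 * radii, fractionOfTcp = fracs)
    ribosomes <- if (nrow(ribC))
      data.frame(cz_nm = ribC[, 1], cy_nm = ribC[, 2], cx_nm = ribC[, 3])
    else data.frame(cz_nm = numeric(), cy_nm = numeric(),
                    cx_nm = numeric())
    list(volume = volumeGrid(img, vox, "bf"),
         groundTruth = list(
           granules = granules, ribosomes = ribosomes,
           realizedFill = realizedFill,
           granuleMask = granMask, mitoMask = mito,
           signals = c(water = spec@cytosolSignal,
                       matrix = spec@matrixSignal,
                       ribosome = spec@ribosomeSignal,
                       tcp = spec@tcpSignal),
           spec = spec))
  })
}

#' Measure calibration reference levels from phantom ground truth
#'
#' Reads the intensity levels a calibration needs directly off the
#' ground-truth geometry: water = mean over cytosol voxels clear of all
#' objects; ribosome peak = mean over the ribosome center voxels; granule
#' peak = mean over granule interiors eroded clear of the PSF margin;
#' granule inclusive = half-contrast level between matrix and granule
#' interior (the level that just captures a blurred sphere at its true
#' boundary).
#'
#' @param phantom output of \code{\link{generatePhantom}}.
#' @param erodeMargin interior erosion margin in nm (default 2 x PSF + one
#'   voxel).
#' @return list: \code{thresholds} (a \code{\link{thresholdSet}}),
#'   \code{granuleInterior}, \code{matrixLevel}, \code{waterLevel},
#'   \code{ribosomeLevel} (numeric means).
#' @export
measureReferenceLevels <- function(phantom, erodeMargin = NULL) {
  gt <- phantom$groundTruth
  spec <- gt$spec
  vox <- spec@voxelSize
  img <- phantom$volume@data
  if (is.null(erodeMargin)) erodeMargin <- 2 * spec@psfSigma + vox

  ## cytosol far from everything: outside a dilated ellipsoid, away from
  ## ribosomes
  d <- dim(img)
  grow <- 4 * spec@psfSigma + 2 * vox
  zz <- ((seq_len(d[1]) - 0.5) * vox - spec@center[1]) /
    (spec@semiAxes[1] + grow)
  yy <- ((seq_len(d[2]) - 0.5) * vox - spec@center[2]) /
    (spec@semiAxes[2] + grow)
  xx <- ((seq_len(d[3]) - 0.5) * vox - spec@center[3]) /
    (spec@semiAxes[3] + grow)
  cyt <- outer(outer(zz^2, yy^2, "+"), xx^2, "+") > 1
  ribClear <- spec@ribosomeDiameter / 2 + grow
  for (i in seq_len(nrow(gt$ribosomes)))
    cyt <- .paintSphere(cyt, vox, as.numeric(gt$ribosomes[i, ]),
                        ribClear, FALSE)
  ## keep away from the grid border (blur wrap-around)
  b <- ceiling(grow / vox)
  border <- array(FALSE, dim = d)
  border[(b + 1):(d[1] - b), (b + 1):(d[2] - b), (b + 1):(d[3] - b)] <- TRUE
  waterLevel <- mean(img[cyt & border])

  ## ribosome centers (peak level)
  ribosomeLevel <- if (nrow(gt$ribosomes)) {
    idx <- as.matrix(round(gt$ribosomes / vox + 0.5))
    idx <- pmin(pmax(idx, 1), matrix(d, nrow(idx), 3, byrow = TRUE))
    mean(img[idx])
  } else NA_real_
  ## eroded granule interiors
  core <- array(FALSE, dim = d)
  g <- gt$granules
  for (i in seq_len(nrow(g))) {
    r <- g$diameter_nm[i] / 2 - erodeMargin
    if (r < vox) next
    core <- .paintSphere(core, vox,
                         c(g$cz_nm[i], g$cy_nm[i], g$cx_nm[i]), r, TRUE)
  }
  granuleInterior <- if (any(core)) mean(img[core]) else NA_real_
  matrixLevel <- mean(img[gt$mitoMask & !gt$granuleMask])
  inclusive <- (granuleInterior + matrixLevel) / 2

  th <- if (is.finite(ribosomeLevel) && is.finite(granuleInterior))
    thresholdSet(granulePeak = granuleInterior,
                 granuleInclusive = inclusive,
                 ribosomePeak = ribosomeLevel,
                 ribosomeInclusive = (ribosomeLevel + waterLevel) / 2,
                 water = waterLevel)
  else NULL  # phantom lacks one of the reference populations
  list(thresholds = th, granuleInclusive = inclusive,
       granuleInterior = granuleInterior,
       matrixLevel = matrixLevel, waterLevel = waterLevel,
       ribosomeLevel = ribosomeLevel)
}
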