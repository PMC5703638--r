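## Morphometry module: Fourier band-pass preprocessing, threshold
## segmentation with 3D connected components, granule size statistics and
## volume fractions.

#' VolumeGrid constructor
#'
#' @param data 3D numeric array in (z, y, x) order.
#' @param voxelSize isotropic voxel edge, nm.
#' @param polarity \code{"bf"} (darker = denser, default) or \code{"df"}.
#' @return a \linkS4class{VolumeGrid}.
#' @export
volumeGrid <- function(data, voxelSize = 1, polarity = "bf") {
  new("VolumeGrid", data = data, voxelSize = voxelSize, polarity = polarity)
}

## FFT frequency magnitudes (cycles/pixel) along one axis
.fftFreq <- function(n) {
  k <- 0:(n - 1)
  pmin(k, n - k) / n
}

#' Fourier band-pass filter
#'
#' Annular band-pass retaining spatial wavelengths between \code{lowCut}
#' and \code{highCut} pixels (i.e. radial frequencies in
#' [1/highCut, 1/lowCut] cycles/pixel). Used to remove the slow shading
#' artifacts of iterative reconstructions before quantitative analysis;
#' the reference setting is \code{lowCut = 1}, \code{highCut = 100}.
#'
#' Applied per (y, x) slice by default (reconstruction shading is a
#' per-slice artifact); \code{dims = 3} applies a single 3D annulus. The
#' DC component (infinite wavelength) is removed whenever \code{highCut}
#' is finite, so the output of any DC-excluding band has zero mean.
#'
#' @param volume a \linkS4class{VolumeGrid}.
#' @param lowCut,highCut wavelength band in pixels, 0 < lowCut < highCut.
#' @param dims 2 (per-slice, default) or 3.
#' @return a filtered \linkS4class{VolumeGrid}.
#' @export
bandpassFilter <- function(volume, lowCut = 1, highCut = 100, dims = 2) {
  stopifnot(is(volume, "VolumeGrid"))
  if (!(lowCut > 0 && lowCut < highCut))
    stop("need 0 < lowCut < highCut (pixels)")
  arr <- volume@data
  d <- dim(arr)
  fLo <- 1 / highCut
  fHi <- 1 / lowCut
  if (dims == 2) {
    fy <- .fftFreq(d[2]); fx <- .fftFreq(d[3])
    fr <- sqrt(outer(fy^2, fx^2, "+"))
    mask <- fr >= fLo & fr <= fHi
    out <- arr
    for (iz in seq_len(d[1])) {
      sl <- matrix(arr[iz, , ], d[2], d[3])
      out[iz, , ] <- Re(stats::fft(stats::fft(sl) * mask, inverse = TRUE)) /
        length(sl)
    }
  } else if (dims == 3) {
    fz <- .fftFreq(d[1]); fy <- .fftFreq(d[2]); fx <- .fftFreq(d[3])
    fr <- sqrt(outer(outer(fz^2, fy^2, "+"), fx^2, "+"))
    mask <- fr >= fLo & fr <= fHi
    out <- Re(stats::fft(stats::fft(arr) * mask, inverse = TRUE)) /
      length(arr)
    dim(out) <- d
  } else stop("dims must be 2 or 3")
  volumeGrid(out, volume@voxelSize, volume@polarity)
}

#' Threshold segmentation with 3D connected components
#'
#' For BF polarity, voxels at or below \code{level} (more scattering than
#' the threshold) are foreground; for DF polarity, voxels at or above it.
#' Connected components are labeled under 6-, 18- or 26-connectivity.
#'
#' @param volume a \linkS4class{VolumeGrid}.
#' @param level intensity threshold.
#' @param connectivity 6, 18 or 26 (default 26: granules are compact blobs).
#' @return a \linkS4class{LabelVolume}; empty segmentations are allowed.
#' @export
segmentByThreshold <- function(volume, level, connectivity = 26) {
  stopifnot(is(volume, "VolumeGrid"))
  if (!is.finite(level)) stop("level must be finite")
  mask <- if (volume@polarity == "bf") volume@data <= level
          else volume@data >= level
  labels <- .label3d(as.logical(mask), dim(volume@data),
                     as.integer(connectivity))
  new("LabelVolume", labels = labels,
      nComponents = as.integer(attr(labels, "n")),
      connectivity = as.integer(connectivity),
      voxelSize = volume@voxelSize)
}

#' Per-granule morphometry
#'
#' Per-component voxel counts, volumes, equivalent spherical diameters
#' d = (6V/pi)^(1/3) and centroids. Components below \code{minDiameter}
#' (noise specks) are excluded from the table and counted separately.
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param voxelSize voxel edge in nm (default: from \code{labels}).
#' @param minDiameter minimum equivalent diameter in nm (default 10 nm,
#'   below the smallest granules of interest but above the noise scale).
#' @return data.frame with one row per retained component: label, voxels,
#'   volume_nm3, diameter_nm, cz_nm, cy_nm, cx_nm. Attributes:
#'   \code{nExcluded} (components below the size cut),
#'   \code{totalForegroundVoxels}.
#' @export
granuleStatistics <- function(labels, voxelSize = NULL, minDiameter = 10) {
  stopifnot(is(labels, "LabelVolume"))
  if (is.null(voxelSize)) voxelSize <- labels@voxelSize
  if (voxelSize <= 0) stop("voxelSize must be positive")
  if (minDiameter < 0) stop("minDiameter must be non-negative")
  lab <- labels@labels
  n <- labels@nComponents
  empty <- data.frame(label = integer(), voxels = integer(),
                      volume_nm3 = numeric(), diameter_nm = numeric(),
                      cz_nm = numeric(), cy_nm = numeric(),
                      cx_nm = numeric())
  if (n == 0L) {
    attr(empty, "nExcluded") <- 0L
    attr(empty, "totalForegroundVoxels") <- 0L
    return(empty)
  }
  fg <- which(lab > 0L)
  lv <- lab[fg]
  counts <- tabulate(lv, nbins = n)
  d <- dim(lab)
  ## 1-based array index -> (z, y, x) voxel-center coordinates in nm
  iz <- (fg - 1L) %% d[1]
  iy <- ((fg - 1L) %/% d[1]) %% d[2]
  ix <- (fg - 1L) %/% (d[1] * d[2])
  cz <- rowsum(iz + 0.5, lv)[, 1] / counts * voxelSize
  cy <- rowsum(iy + 0.5, lv)[, 1] / counts * voxelSize
  cx <- rowsum(ix + 0.5, lv)[, 1] / counts * voxelSize
  vol <- counts * voxelSize^3
  dia <- (6 * vol / pi)^(1 / 3)
  keep <- dia >= minDiameter
  out <- data.frame(label = seq_len(n), voxels = counts,
                    volume_nm3 = vol, diameter_nm = dia,
                    cz_nm = cz, cy_nm = cy, cx_nm = cx)[keep, ]
  rownames(out) <- NULL
  attr(out, "nExcluded") <- sum(!keep)
  attr(out, "totalForegroundVoxels") <- length(fg)
  out
}

#' Granule volume fraction within a rectangular ROI
#'
#' The ratio of foreground (labeled) voxels inside an axis-aligned box to
#' the total voxels of the box — the estimator behind "granules occupy a
#' fraction f of the mitochondrial volume".
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param roi 2 x 3 matrix \code{rbind(lo, hi)} of 0-based half-open voxel
#'   bounds [lo, hi) in (z, y, x) order.
#' @return the volume fraction (dimensionless).
#' @export
volumeFraction <- function(labels, roi) {
  stopifnot(is(labels, "LabelVolume"))
  roi <- as.matrix(roi)
  if (!all(dim(roi) == c(2, 3))) stop("roi must be a 2 x 3 matrix (lo; hi)")
  d <- dim(labels@labels)
  lo <- roi[1, ]; hi <- roi[2, ]
  if (any(lo < 0) || any(hi > d) || any(hi <= lo))
    stop("roi must be non-empty and inside the volume bounds")
  sub <- labels@labels[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2],
                       (lo[3] + 1):hi[3]]
  sum(sub > 0L) / length(sub)
}
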