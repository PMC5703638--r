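## Accessor generics and show methods.

#' @rdname accessors
#' @param object an object of one of the package's S4 classes.
#' @export
setGeneric("densities", function(object) standardGeneric("densities"))

#' @rdname accessors
#' @export
setGeneric("massDensity", function(object) standardGeneric("massDensity"))

#' @rdname accessors
#' @export
setGeneric("materialLabel", function(object) standardGeneric("materialLabel"))

#' @rdname accessors
#' @export
setGeneric("crossSections", function(object) standardGeneric("crossSections"))

#' @rdname accessors
#' @export
setGeneric("signalValue", function(object) standardGeneric("signalValue"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("volumeData", function(object) standardGeneric("volumeData"))

#' @rdname accessors
#' @export
setGeneric("labelData", function(object) standardGeneric("labelData"))

#' @rdname accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))

#' @rdname accessors
#' @export
setGeneric("backgroundX", function(object) standardGeneric("backgroundX"))

#' @rdname accessors
#' @export
setGeneric("tcpIntensity", function(object) standardGeneric("tcpIntensity"))

#' @rdname accessors
#' @export
setGeneric("tiltAngles", function(object) standardGeneric("tiltAngles"))

#' @rdname accessors
#' @export
setGeneric("projections", function(object) standardGeneric("projections"))

#' Accessors for cstetQuant classes
#'
#' Slot accessors: prefer these over direct \code{@} access.
#' @name accessors
#' @aliases densities,NumberDensityProfile-method
NULL

#' @rdname accessors
setMethod("densities", "NumberDensityProfile", function(object) object@densities)
#' @rdname accessors
setMethod("massDensity", "NumberDensityProfile", function(object) object@massDensity)
#' @rdname accessors
setMethod("materialLabel", "NumberDensityProfile", function(object) object@label)
#' @rdname accessors
setMethod("materialLabel", "ScatteringSignal", function(object) object@label)
#' @rdname accessors
setMethod("crossSections", "CrossSectionTable", function(object) object@sigma)
#' @rdname accessors
setMethod("signalValue", "ScatteringSignal", function(object) object@signal)
#' @rdname accessors
setMethod("voxelSize", "VolumeGrid", function(object) object@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "LabelVolume", function(object) object@voxelSize)
#' @rdname accessors
setMethod("volumeData", "VolumeGrid", function(object) object@data)
#' @rdname accessors
setMethod("labelData", "LabelVolume", function(object) object@labels)
#' @rdname accessors
setMethod("nComponents", "LabelVolume", function(object) object@nComponents)
#' @rdname accessors
setMethod("backgroundX", "IntensityCalibration", function(object) object@backgroundX)
#' @rdname accessors
setMethod("tcpIntensity", "IntensityCalibration", function(object) object@tcpIntensity)
#' @rdname accessors
setMethod("tiltAngles", "TiltSeries", function(object) object@angles)
#' @rdname accessors
setMethod("projections", "TiltSeries", function(object) object@projections)

setMethod("show", "NumberDensityProfile", function(object) {
  cat(sprintf("NumberDensityProfile '%s' (%s)\n", object@label, object@source))
  cat(sprintf("  mass density: %.3f g/cm^3\n", object@massDensity))
  d <- object@densities
  cat("  atoms/nm^3: ",
      paste(sprintf("%s %.4g", names(d), d), collapse = ", "), "\n")
})

setMethod("show", "CrossSectionTable", function(object) {
  cat(sprintf(
    "CrossSectionTable (%s): %g keV, BF cutoff %g mrad\n",
    object@provenance, object@beam@energy, object@beam@cutoff))
  s <- object@sigma
  cat("  sigma (nm^2): ",
      paste(sprintf("%s %.4g", names(s), s), collapse = ", "), "\n")
})

setMethod("show", "ScatteringSignal", function(object) {
  cat(sprintf("ScatteringSignal '%s': %.4f nm^-1\n",
              object@label, object@signal))
})

setMethod("show", "IntensityCalibration", function(object) {
  cat("IntensityCalibration (reference:", object@referenceUsed, ")\n")
  cat(sprintf("  background x     : %.4g\n", object@backgroundX))
  cat(sprintf("  water intensity  : %.4g\n", object@waterIntensity))
  cat(sprintf("  TCP intensity    : %.4g (ratio TCP/water %.3g)\n",
              object@tcpIntensity, object@tcpWaterRatio))
})

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeGrid %d x %d x %d (z,y,x), voxel %g nm, %s polarity\n",
              d[1], d[2], d[3], object@voxelSize, object@polarity))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  cat(sprintf(
    "LabelVolume %d x %d x %d: %d component(s), %d-connectivity\n",
    d[1], d[2], d[3], object@nComponents, object@connectivity))
})

setMethod("show", "TiltSeries", function(object) {
  d <- dim(object@projections)
  cat(sprintf("TiltSeries: %d projections (%d x %d), angles %g..%g deg\n",
              d[3], d[1], d[2], min(object@angles), max(object@angles)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec %s voxels at %g nm, seed %d\n",
              paste(object@shape, collapse = "x"), object@voxelSize,
              object@seed))
  cat(sprintf("  %d granules (target fill %.2f, fraction of TCP %s)\n",
              object@nGranules, object@targetFill,
              paste(signif(object@fractionOfTcp, 3), collapse = "-")))
  cat(sprintf("  %d ribosomes; background x %.3g, gain %.3g, psf %.3g nm, noise %.3g\n",
              object@nRibosomes, object@backgroundX, object@contrastGain,
              object@psfSigma, object@noiseSd))
})
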