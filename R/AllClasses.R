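## Central S4 containers. Constructors with validation live next to the
## module code; these definitions carry the invariants.

#' @import methods
NULL

#' BeamConfig: STEM beam and bright-field detector geometry
#'
#' @slot energy beam energy in keV.
#' @slot cutoff outer acceptance semi-angle of the BF detector, mrad.
#'   Electrons scattered beyond this angle are lost from the BF signal.
#' @export
setClass("BeamConfig",
  representation(energy = "numeric", cutoff = "numeric"))

setValidity("BeamConfig", function(object) {
  if (length(object@energy) != 1L || !is.finite(object@energy) ||
      object@energy <= 0)
    return("energy must be a single positive keV value")
  if (length(object@cutoff) != 1L || !is.finite(object@cutoff) ||
      object@cutoff <= 0 || object@cutoff >= pi * 1000)
    return("cutoff must be in (0, pi*1000) mrad")
  TRUE
})

#' NumberDensityProfile: per-element atom number densities of a material
#'
#' @slot label material name.
#' @slot densities named numeric, atoms per nm^3 per element.
#' @slot massDensity bulk mass density in g/cm^3.
#' @slot source how the profile was derived: one of
#'   \code{"counts_and_volume"}, \code{"formula_and_density"}, \code{"psv"},
#'   \code{"mixture"}, \code{"table"}.
#' @export
setClass("NumberDensityProfile",
  representation(label = "character", densities = "numeric",
                 massDensity = "numeric", source = "character"))

setValidity("NumberDensityProfile", function(object) {
  d <- object@densities
  if (!length(d) || is.null(names(d)))
    return("densities must be a named numeric vector")
  if (any(!is.finite(d)) || any(d < 0))
    return("densities must be finite and non-negative")
  if (length(object@massDensity) != 1L || !is.finite(object@massDensity) ||
      object@massDensity <= 0)
    return("massDensity must be a single positive g/cm^3 value")
  ok <- object@source %in% c("counts_and_volume", "formula_and_density",
                             "psv", "mixture", "table")
  if (!ok) return("unknown source tag")
  ## stored mass density must agree with the one implied by the densities,
  ## except for 'table' profiles which hold externally quoted values
  if (object@source != "table") {
    implied <- .profileMassDensity(d)
    if (abs(implied - object@massDensity) > 0.005 * object@massDensity)
      return(sprintf(
        "massDensity %.4f inconsistent with densities (imply %.4f)",
        object@massDensity, implied))
  }
  TRUE
})

#' CrossSectionTable: per-element partial elastic cross-sections
#'
#' Cross-sections (nm^2 per atom) for scattering beyond the BF cutoff angle
#' at the stated beam energy. Hydrogen is taken as zero: above a few mrad
#' it scatters negligibly at these energies.
#'
#' @slot beam a \linkS4class{BeamConfig}.
#' @slot sigma named numeric, nm^2 per atom.
#' @slot provenance \code{"packaged"}, \code{"lenz_model"} or \code{"user"}.
#' @export
setClass("CrossSectionTable",
  representation(beam = "BeamConfig", sigma = "numeric",
                 provenance = "character"))

setValidity("CrossSectionTable", function(object) {
  s <- object@sigma
  if (!length(s) || is.null(names(s)))
    return("sigma must be a named numeric vector")
  if (any(!is.finite(s)) || any(s < 0))
    return("sigma values must be finite and non-negative")
  if (!object@provenance %in% c("packaged", "lenz_model", "user"))
    return("unknown provenance tag")
  if (object@provenance == "packaged" && "H" %in% names(s) &&
      s[["H"]] != 0)
    return("packaged table must carry sigma(H) = 0")
  TRUE
})

#' ScatteringSignal: predicted BF scattering signal per unit volume
#'
#' @slot label material name.
#' @slot signal expected scattering signal per nm^3 of material, nm^-1
#'   (sum over elements of number density x partial cross-section).
#' @export
setClass("ScatteringSignal",
  representation(label = "character", signal = "numeric"))

setValidity("ScatteringSignal", function(object) {
  if (length(object@signal) != 1L || !is.finite(object@signal) ||
      object@signal < 0)
    return("signal must be a single non-negative value")
  TRUE
})

#' IntensityCalibration: map from BF tomogram intensity to density
#'
#' Bright-field polarity throughout: lower intensity = more scattering =
#' denser material, so the additive unscattered background x lies above the
#' water level and the (extrapolated) TCP level lies below it.
#'
#' @slot backgroundX additive unscattered-background intensity x.
#' @slot waterIntensity measured water (cytosol) intensity.
#' @slot tcpIntensity extrapolated intensity of pure crystalline TCP.
#' @slot referenceUsed \code{"rna_peak"} or \code{"ribosome_inclusive"},
#'   the internal-standard pairing that produced x.
#' @slot tcpWaterRatio predicted TCP/water scattering ratio used for the
#'   extrapolation.
#' @slot tcpMassDensity mass density of crystalline TCP, g/cm^3.
#' @slot tcpFormulaWeight formula weight of Ca3(PO4)2, g/mol.
#' @export
setClass("IntensityCalibration",
  representation(backgroundX = "numeric", waterIntensity = "numeric",
                 tcpIntensity = "numeric", referenceUsed = "character",
                 tcpWaterRatio = "numeric", tcpMassDensity = "numeric",
                 tcpFormulaWeight = "numeric"))

setValidity("IntensityCalibration", function(object) {
  if (!(object@backgroundX > object@waterIntensity))
    return("BF polarity violated: backgroundX must exceed waterIntensity")
  if (!(object@tcpIntensity < object@waterIntensity))
    return("BF polarity violated: tcpIntensity must lie below waterIntensity")
  if (!object@referenceUsed %in% c("rna_peak", "ribosome_inclusive", "user"))
    return("unknown referenceUsed tag")
  if (object@tcpWaterRatio <= 1)
    return("tcpWaterRatio must exceed 1")
  if (object@tcpMassDensity <= 0 || object@tcpFormulaWeight <= 0)
    return("TCP density and formula weight must be positive")
  TRUE
})

#' VolumeGrid: a 3D scalar volume with physical voxel size
#'
#' Array axis order is (z, y, x); voxel indices are 1-based in R.
#'
#' @slot data 3D numeric array.
#' @slot voxelSize isotropic voxel edge, nm.
#' @slot polarity \code{"bf"} (darker = denser) or \code{"df"}.
#' @export
setClass("VolumeGrid",
  representation(data = "array", voxelSize = "numeric",
                 polarity = "character"))

setValidity("VolumeGrid", function(object) {
  if (length(dim(object@data)) != 3L)
    return("data must be a 3D array (z, y, x)")
  if (any(!is.finite(object@data)))
    return("volume values must all be finite")
  if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
      object@voxelSize <= 0)
    return("voxelSize must be a single positive nm value")
  if (!object@polarity %in% c("bf", "df"))
    return("polarity must be 'bf' or 'df'")
  TRUE
})

#' LabelVolume: integer-labeled segmentation of a VolumeGrid
#'
#' @slot labels 3D integer array; 0 = background, components 1..N.
#' @slot nComponents number of connected components N.
#' @slot connectivity 6, 18 or 26.
#' @slot voxelSize nm, inherited from the segmented volume.
#' @export
setClass("LabelVolume",
  representation(labels = "array", nComponents = "integer",
                 connectivity = "integer", voxelSize = "numeric"))

setValidity("LabelVolume", function(object) {
  if (length(dim(object@labels)) != 3L)
    return("labels must be a 3D array")
  if (!object@connectivity %in% c(6L, 18L, 26L))
    return("connectivity must be 6, 18 or 26")
  n <- object@nComponents
  if (length(n) != 1L || n < 0L)
    return("nComponents must be a single non-negative integer")
  u <- unique(as.integer(object@labels))
  if (length(setdiff(u, 0:n)))
    return("labels must be contiguous 0..nComponents")
  if (n > 0L && !all(seq_len(n) %in% u))
    return("labels must be contiguous 1..nComponents with no gaps")
  TRUE
})

#' TiltSeries: stack of parallel-beam projections
#'
#' Projections are stored as an array (detector u, y, angle); the tilt axis
#' is the y axis of the source volume and u runs along the rotated x axis.
#'
#' @slot projections 3D numeric array (u, y, angle).
#' @slot angles tilt angles in degrees, strictly increasing.
#' @export
setClass("TiltSeries",
  representation(projections = "array", angles = "numeric"))

setValidity("TiltSeries", function(object) {
  if (length(dim(object@projections)) != 3L)
    return("projections must be a 3D array (u, y, angle)")
  if (dim(object@projections)[3] != length(object@angles))
    return("one projection per angle required")
  if (length(object@angles) > 1 && any(diff(object@angles) <= 0))
    return("angles must be strictly increasing")
  TRUE
})

#' PhantomSpec: generative description of a synthetic BF tomogram
#'
#' See \code{\link{phantomSpec}} for field semantics and defaults.
#' @slot shape grid dimensions (z, y, x) in voxels.
#' @slot voxelSize nm.
#' @slot center,semiAxes mitochondrion ellipsoid geometry, nm.
#' @slot nGranules,diameterMedian,diameterSdlog,diameterRange,targetFill,fractionOfTcp
#'   granule population parameters.
#' @slot nRibosomes,ribosomeDiameter,ribosomeSignal ribosome puncta.
#' @slot matrixSignal,cytosolSignal,tcpSignal scattering signals, nm^-1.
#' @slot backgroundX,contrastGain intensity model.
#' @slot psfSigma,noiseSd blur (nm) and additive Gaussian noise (intensity).
#' @slot minSeparation minimum surface gap between granules, nm.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", voxelSize = "numeric",
                 center = "numeric", semiAxes = "numeric",
                 nGranules = "integer", diameterMedian = "numeric",
                 diameterSdlog = "numeric", diameterRange = "numeric",
                 targetFill = "numeric", fractionOfTcp = "numeric",
                 nRibosomes = "integer", ribosomeDiameter = "numeric",
                 ribosomeSignal = "numeric",
                 matrixSignal = "numeric", cytosolSignal = "numeric",
                 tcpSignal = "numeric",
                 backgroundX = "numeric", contrastGain = "numeric",
                 psfSigma = "numeric", noiseSd = "numeric",
                 minSeparation = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 4L))
    return("shape must be three voxel counts >= 4")
  if (object@voxelSize <= 0) return("voxelSize must be positive")
  if (length(object@center) != 3L || length(object@semiAxes) != 3L)
    return("center and semiAxes must be length-3 (z, y, x) in nm")
  if (any(object@semiAxes <= 0)) return("semiAxes must be positive")
  if (object@nGranules < 0L || object@nRibosomes < 0L)
    return("object counts must be non-negative")
  if (object@targetFill < 0 || object@targetFill > 1)
    return("targetFill must lie in [0, 1]")
  if (any(object@fractionOfTcp < 0) || any(object@fractionOfTcp > 1))
    return("fractionOfTcp must lie in [0, 1]")
  if (length(object@diameterRange) != 2L ||
      object@diameterRange[1] <= 0 ||
      object@diameterRange[2] < object@diameterRange[1])
    return("diameterRange must be increasing positive (min, max) nm")
  if (object@psfSigma < 0 || object@noiseSd < 0 || object@minSeparation < 0)
    return("psfSigma, noiseSd, minSeparation must be non-negative")
  if (object@contrastGain <= 0) return("contrastGain must be positive")
  TRUE
})
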