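## Composition module: atom number densities (atoms/nm^3) for reference
## materials, derived from atom counts + envelope volume, partial specific
## volume, or chemical formula + bulk mass density.

.newProfile <- function(label, densities, massDensity, source) {
  new("NumberDensityProfile", label = label,
      densities = densities[order(names(densities))],
      massDensity = massDensity, source = source)
}

#' Atom number densities from atom counts and an envelope volume
#'
#' Divides per-element atom counts by the enclosing volume. Used for the
#' ribosome reference, whose solvated envelope is taken as 7000 nm^3.
#'
#' @param counts named numeric vector, element symbol -> atom count.
#' @param volume enclosing volume in nm^3.
#' @param label material name.
#' @return a \linkS4class{NumberDensityProfile}.
#' @examples
#' densitiesFromCounts(c(O = 602.2), volume = 10)
#' @export
densitiesFromCounts <- function(counts, volume, label = "material") {
  .checkCounts(counts)
  if (!is.numeric(volume) || length(volume) != 1L || !is.finite(volume) ||
      volume <= 0)
    stop("volume must be a single positive nm^3 value")
  dens <- counts / volume
  md <- .countsMassGrams(counts) / volume * .NM3_PER_CM3
  .newProfile(label, dens, md, "counts_and_volume")
}

#' Atom number densities from atom counts and a partial specific volume
#'
#' The occupied volume is molecular mass x partial specific volume (PSV);
#' densities are counts over that volume. Used for ribosomal RNA with
#' PSV 0.569 cm^3/g.
#'
#' @param counts named numeric vector, element symbol -> atom count.
#' @param psv partial specific volume in cm^3/g.
#' @inheritParams densitiesFromCounts
#' @return a \linkS4class{NumberDensityProfile}.
#' @export
densitiesFromPSV <- function(counts, psv, label = "material") {
  .checkCounts(counts)
  if (!is.numeric(psv) || length(psv) != 1L || !is.finite(psv) || psv <= 0)
    stop("psv must be a single positive cm^3/g value")
  mass <- .countsMassGrams(counts)           # g
  volume <- mass * psv * .NM3_PER_CM3        # nm^3
  .newProfile(label, counts / volume, 1 / psv, "psv")
}

#' Atom number densities from a chemical formula and bulk mass density
#'
#' Formula units per nm^3 = mass density x N_A / formula weight; per-element
#' densities follow the stoichiometry. Used for crystalline tricalcium
#' phosphate, Ca3(PO4)2 at 3.14 g/cm^3, and for vitreous ice.
#'
#' @param formula chemical formula string, e.g. \code{"Ca3(PO4)2"}.
#' @param massDensity bulk density in g/cm^3.
#' @inheritParams densitiesFromCounts
#' @return a \linkS4class{NumberDensityProfile}.
#' @examples
#' densitiesFromFormula("Ca3(PO4)2", 3.14, label = "TCP")
#' @export
densitiesFromFormula <- function(formula, massDensity, label = formula) {
  counts <- parseFormula(formula)
  if (!is.numeric(massDensity) || length(massDensity) != 1L ||
      !is.finite(massDensity) || massDensity <= 0)
    stop("massDensity must be a single positive g/cm^3 value")
  unitsPerNm3 <- massDensity * avogadro() / formulaWeight(counts) /
    .NM3_PER_CM3
  .newProfile(label, counts * unitsPerNm3, massDensity,
              "formula_and_density")
}

#' Vitreous ice reference profile
#'
#' Bulk low-density amorphous ice at 0.93 g/cm^3 (configurable), the
#' "water" internal standard of the intensity calibration.
#'
#' @param massDensity ice density in g/cm^3.
#' @return a \linkS4class{NumberDensityProfile}.
#' @export
waterProfile <- function(massDensity = 0.93) {
  densitiesFromFormula("H2O", massDensity, label = "water")
}

#' Add bulk solvent to a macromolecule profile
#'
#' For a macromolecule profile expressed over its full (solvated) envelope
#' volume, adds \code{solventFraction} of the solvent profile element-wise.
#' Used to treat the 42\% solvent inside the ribosome isosurface as bulk
#' vitreous ice.
#'
#' @param macromolecule \linkS4class{NumberDensityProfile} of the dry
#'   component over the full envelope volume.
#' @param solvent solvent \linkS4class{NumberDensityProfile} (bulk).
#' @param solventFraction volume fraction of solvent in the envelope, [0,1].
#' @return a \linkS4class{NumberDensityProfile} with source "mixture".
#' @export
solvatedComposition <- function(macromolecule, solvent, solventFraction) {
  stopifnot(is(macromolecule, "NumberDensityProfile"),
            is(solvent, "NumberDensityProfile"))
  if (!is.numeric(solventFraction) || length(solventFraction) != 1L ||
      !is.finite(solventFraction) || solventFraction < 0 ||
      solventFraction > 1)
    stop("solventFraction must lie in [0, 1]")
  els <- union(names(macromolecule@densities), names(solvent@densities))
  d <- stats::setNames(numeric(length(els)), els)
  d[names(macromolecule@densities)] <- macromolecule@densities
  d[names(solvent@densities)] <- d[names(solvent@densities)] +
    solventFraction * solvent@densities
  md <- .profileMassDensity(d)
  .newProfile(paste0(macromolecule@label, "+solvent"), d, md, "mixture")
}

## ---- packaged reference tables ------------------------------------------

.extdata <- function(name) {
  path <- system.file("extdata", name, package = "cstetQuant")
  if (!nzchar(path)) stop("packaged data file not found: ", name)
  path
}

#' Packaged reference compositions
#'
#' The atom counts and derivation parameters for the reference materials:
#' ribosomal RNA (counts + PSV 0.569 cm^3/g), the solvated 70S/80S ribosome
#' (counts over a 7000 nm^3 envelope, 42\% bulk solvent included in the
#' counts), and crystalline TCP (formula + 3.14 g/cm^3). A user file in the
#' same layout (columns material, element, count) may be supplied.
#'
#' @param file optional path to a counts CSV replacing the packaged one.
#' @return data.frame with columns material, element, count.
#' @export
referenceCounts <- function(file = NULL) {
  path <- if (is.null(file)) .extdata("reference_counts.csv") else file
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  need <- c("material", "element", "count")
  if (!all(need %in% names(df)))
    stop("counts file must have columns: ", paste(need, collapse = ", "))
  df
}

#' Reference number-density profiles
#'
#' Builds the \linkS4class{NumberDensityProfile} for one of the packaged
#' reference materials. Two pathways are available: \code{"computed"}
#' derives the densities from the packaged atom counts and parameters;
#' \code{"printed"} returns the quoted per-element densities exactly as
#' tabulated (source \code{"table"}), which are the canonical inputs of the
#' calibration chain.
#'
#' @param material one of \code{"ribosome"}, \code{"rRNA"}, \code{"TCP"},
#'   \code{"water"}.
#' @param pathway \code{"printed"} or \code{"computed"}.
#' @param iceDensity vitreous-ice mass density, g/cm^3 (water reference).
#' @param tcpDensity crystalline TCP mass density, g/cm^3.
#' @return a \linkS4class{NumberDensityProfile}.
#' @examples
#' referenceProfile("TCP")
#' referenceProfile("rRNA", pathway = "computed")
#' @export
referenceProfile <- function(material = c("ribosome", "rRNA", "TCP", "water"),
                             pathway = c("printed", "computed"),
                             iceDensity = 0.93, tcpDensity = 3.14) {
  material <- match.arg(material)
  pathway <- match.arg(pathway)
  if (material == "water")
    return(waterProfile(iceDensity))
  if (pathway == "computed") {
    cnt <- referenceCounts()
    get <- function(m) {
      sub <- cnt[cnt$material == m, ]
      stats::setNames(sub$count, sub$element)
    }
    return(switch(material,
      ribosome = densitiesFromCounts(get("ribosome"), volume = 7000,
                                     label = "ribosome"),
      rRNA = densitiesFromPSV(get("rRNA"), psv = 0.569, label = "rRNA"),
      TCP = densitiesFromFormula("Ca3(PO4)2", tcpDensity, label = "TCP")))
  }
  df <- utils::read.csv(.extdata("reference_densities.csv"),
                        comment.char = "#", stringsAsFactors = FALSE)
  sub <- df[df$material == material, ]
  d <- stats::setNames(sub$atoms_per_nm3, sub$element)
  .newProfile(material, d, .profileMassDensity(d), "table")
}
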