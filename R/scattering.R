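## Scattering module: predicted BF scattering signal per unit volume and
## material/water intensity ratios, from per-element partial elastic
## cross-sections beyond the BF detector cutoff.

#' Beam configuration constructor
#'
#' @param energy beam energy in keV (default 200, the tomographic setting).
#' @param cutoff BF detector outer acceptance semi-angle in mrad (default 5).
#' @return a \linkS4class{BeamConfig}.
#' @export
beamConfig <- function(energy = 200, cutoff = 5) {
  new("BeamConfig", energy = energy, cutoff = cutoff)
}

#' Packaged partial cross-section table
#'
#' Per-atom partial elastic cross-sections (nm^2) for scattering beyond the
#' 5 mrad BF cutoff at 200 keV, for H, C, N, O, P, Mg, S, Ca. Hydrogen
#' carries zero: it does not scatter appreciably beyond the cutoff angle.
#'
#' @return a \linkS4class{CrossSectionTable} with provenance "packaged".
#' @examples
#' defaultCrossSections()
#' @export
defaultCrossSections <- function() {
  readCrossSectionTable(.extdata("cross_sections_200kV_5mrad.csv"),
                        provenance = "packaged")
}

#' Read / write cross-section tables
#'
#' Tabular format: CSV with columns \code{element}, \code{sigma_nm2} and
#' header comment lines \code{# energy_keV:} and \code{# cutoff_mrad:}
#' recording the beam conditions.
#'
#' @param path file path.
#' @param provenance provenance tag for the table read.
#' @return \code{readCrossSectionTable} returns a
#'   \linkS4class{CrossSectionTable}; \code{writeCrossSectionTable} returns
#'   the path invisibly.
#' @export
readCrossSectionTable <- function(path, provenance = "user") {
  hdr <- readLines(path, n = 10L)
  getNum <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(ln)) stop("cross-section file missing '# ", key, ":' header")
    as.numeric(sub(paste0("^#\\s*", key, ":\\s*"), "", ln[1]))
  }
  energy <- getNum("energy_keV")
  cutoff <- getNum("cutoff_mrad")
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("element", "sigma_nm2") %in% names(df)))
    stop("cross-section file must have columns element, sigma_nm2")
  new("CrossSectionTable", beam = beamConfig(energy, cutoff),
      sigma = stats::setNames(df$sigma_nm2, df$element),
      provenance = provenance)
}

#' @rdname readCrossSectionTable
#' @param xsec a \linkS4class{CrossSectionTable} to write.
#' @export
writeCrossSectionTable <- function(xsec, path) {
  stopifnot(is(xsec, "CrossSectionTable"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# energy_keV: %g", xsec@beam@energy),
               sprintf("# cutoff_mrad: %g", xsec@beam@cutoff)), con)
  utils::write.csv(data.frame(element = names(xsec@sigma),
                              sigma_nm2 = unname(xsec@sigma)),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Scattering signal per unit volume of a material
#'
#' The expected BF scattering signal of 1 nm^3 of material: the sum over
#' elements of atom number density times partial cross-section,
#' giving nm^-1. Hydrogen may be absent from the table (treated as zero);
#' any other element with nonzero density must be present.
#'
#' @param profile a \linkS4class{NumberDensityProfile}.
#' @param xsec a \linkS4class{CrossSectionTable}
#'   (default: \code{\link{defaultCrossSections}()}).
#' @return a \linkS4class{ScatteringSignal}.
#' @examples
#' signalPerVolume(referenceProfile("TCP"))
#' @export
signalPerVolume <- function(profile, xsec = defaultCrossSections()) {
  stopifnot(is(profile, "NumberDensityProfile"),
            is(xsec, "CrossSectionTable"))
  d <- profile@densities
  s <- xsec@sigma
  missing <- setdiff(names(d)[d > 0], c(names(s), "H"))
  if (length(missing))
    stop("no cross-section for element(s): ",
         paste(missing, collapse = ", "))
  common <- intersect(names(d), names(s))
  new("ScatteringSignal", label = profile@label,
      signal = sum(d[common] * s[common]))
}

#' Predicted intensity ratio of two materials
#'
#' Plain quotient of two per-volume scattering signals; in the linear BF
#' contrast model this equals the ratio of background-subtracted image
#' intensities of the two materials.
#'
#' @param numerator,denominator \linkS4class{ScatteringSignal} objects (or
#'   bare numerics).
#' @return the unrounded ratio (numeric).
#' @export
predictedRatio <- function(numerator, denominator) {
  num <- if (is(numerator, "ScatteringSignal")) numerator@signal else numerator
  den <- if (is(denominator, "ScatteringSignal")) denominator@signal else denominator
  if (!is.finite(den) || den <= 0) stop("denominator signal must be positive")
  num / den
}

#' Predicted BF signal table for the reference materials
#'
#' Computes the per-nm^3 scattering signals of vitreous water, the solvated
#' ribosome, ribosomal RNA and crystalline TCP, and the material/water
#' ratios. Signals are quoted at 3 decimals and the ratios are formed from
#' the quoted signals, then quoted at 2 decimals — the reporting convention
#' of the reference tabulation, which the downstream calibration chain
#' propagates. Unrounded signals are returned alongside.
#'
#' @param xsec a \linkS4class{CrossSectionTable}.
#' @param pathway profile pathway, see \code{\link{referenceProfile}}.
#' @param iceDensity,tcpDensity reference mass densities, g/cm^3.
#' @return list with \code{signals} (data.frame: material, signal_nm1,
#'   quoted), and \code{ratios} (data.frame: pair, ratio, quoted).
#' @examples
#' bfSignalTable()$ratios
#' @export
bfSignalTable <- function(xsec = defaultCrossSections(),
                          pathway = "printed",
                          iceDensity = 0.93, tcpDensity = 3.14) {
  mats <- c("water", "ribosome", "rRNA", "TCP")
  sig <- vapply(mats, function(m)
    signalPerVolume(referenceProfile(m, pathway = pathway,
                                     iceDensity = iceDensity,
                                     tcpDensity = tcpDensity),
                    xsec)@signal, numeric(1))
  quoted <- round(sig, 3)
  pairs <- c(ribosome = "ribosome/water", rRNA = "rRNA/water",
             TCP = "TCP/water")
  ratio <- quoted[names(pairs)] / quoted[["water"]]
  list(
    signals = data.frame(material = mats, signal_nm1 = unname(sig),
                         quoted = unname(quoted)),
    ratios = data.frame(pair = unname(pairs),
                        ratio = unname(ratio),
                        quoted = unname(round(ratio, 2)))
  )
}

## ---- screened-atom elastic model ----------------------------------------

## relativistic electron wavelength, nm
.electronWavelength <- function(energyKeV) {
  h <- 6.62607015e-34; me <- 9.1093837015e-31
  c0 <- 2.99792458e8; e <- 1.602176634e-19
  V <- energyKeV * 1e3
  h / sqrt(2 * me * e * V * (1 + e * V / (2 * me * c0^2))) * 1e9
}

## Lenz screening angle theta0 (rad) for atomic number Z
.lenzTheta0 <- function(Z, energyKeV) {
  a0 <- 0.0529177  # Bohr radius, nm
  R <- a0 * Z^(-1 / 3)
  .electronWavelength(energyKeV) / (2 * pi * R)
}

#' Screened-Rutherford (Lenz) differential elastic cross-section
#'
#' \eqn{d\sigma/d\Omega = (2 Z e^2 / (4\pi\epsilon_0 p v))^2 /
#' (\theta^2+\theta_0^2)^2} with the Lenz screening angle
#' \eqn{\theta_0 = \lambda / (2\pi a_0 Z^{-1/3})} and relativistic
#' \eqn{pv}. Small-angle form; nm^2/sr.
#'
#' @param theta scattering angle(s), rad.
#' @param Z atomic number.
#' @param beam a \linkS4class{BeamConfig}.
#' @return differential cross-section values, nm^2/sr.
#' @export
lenzDifferentialCrossSection <- function(theta, Z, beam = beamConfig()) {
  stopifnot(Z >= 1)
  eVnm <- 1.43996454               # e^2/(4 pi eps0), eV nm
  E0 <- 510.99895                  # electron rest energy, keV
  gamma <- 1 + beam@energy / E0
  beta2 <- 1 - 1 / gamma^2
  pv_eV <- gamma * E0 * 1e3 * beta2     # p*v in eV
  pref <- (2 * Z * eVnm / pv_eV)^2      # nm^2
  th0 <- .lenzTheta0(Z, beam@energy)
  pref / (theta^2 + th0^2)^2
}

#' Partial elastic cross-section beyond a cutoff angle (Lenz model)
#'
#' Closed-form integral of the screened-Rutherford differential
#' cross-section over solid angle from \code{thetaMin} to pi rad (small-angle
#' measure \eqn{2\pi\theta\,d\theta}). Provided for sensitivity analysis;
#' the packaged table remains the default pathway for calibration and the
#' model is not expected to reproduce it (the tabulated values' underlying
#' model is unidentified).
#'
#' @param Z atomic number (>= 1).
#' @param beam a \linkS4class{BeamConfig}.
#' @param thetaMin lower cutoff in mrad (default: the beam's BF cutoff).
#' @return partial cross-section, nm^2.
#' @examples
#' lenzPartialCrossSection(8)             # oxygen beyond 5 mrad at 200 keV
#' @export
lenzPartialCrossSection <- function(Z, beam = beamConfig(),
                                    thetaMin = beam@cutoff) {
  if (!is.numeric(Z) || Z < 1) stop("Z must be >= 1")
  thMin <- thetaMin / 1000
  if (thMin < 0 || thMin >= pi) stop("thetaMin must lie in [0, pi) rad")
  th0 <- .lenzTheta0(Z, beam@energy)
  pref <- lenzDifferentialCrossSection(0, Z, beam) * th0^4  # recover prefactor
  ## integral of 2 pi theta / (theta^2 + th0^2)^2 dtheta from thMin to pi
  pref * pi * (1 / (thMin^2 + th0^2) - 1 / (pi^2 + th0^2))
}

#' Cross-section table from the Lenz model
#'
#' @param elements character vector of element symbols.
#' @param beam a \linkS4class{BeamConfig}.
#' @return a \linkS4class{CrossSectionTable} with provenance "lenz_model";
#'   hydrogen is forced to zero to match the BF-cutoff convention.
#' @export
lenzCrossSectionTable <- function(elements = c("H", "C", "N", "O", "P",
                                               "Mg", "S", "Ca"),
                                  beam = beamConfig()) {
  Zmap <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
            F = 9, Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15,
            S = 16, Cl = 17, K = 19, Ca = 20, Mn = 25, Fe = 26, Zn = 30)
  bad <- setdiff(elements, names(Zmap))
  if (length(bad)) stop("no atomic number for: ", paste(bad, collapse = ", "))
  sig <- vapply(elements, function(el)
    if (el == "H") 0 else lenzPartialCrossSection(Zmap[[el]], beam),
    numeric(1))
  new("CrossSectionTable", beam = beam, sigma = sig,
      provenance = "lenz_model")
}
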