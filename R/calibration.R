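## Calibration module: from measured BF intensity levels to absolute
## densities. The measured tomogram intensity of a material is modeled as
##   I = x - g * S
## where x is the additive background from unscattered illumination, g an
## unknown gain and S the material's scattering signal per volume. Ratios of
## background-subtracted intensities therefore equal predicted signal
## ratios, which pins down x from two internal standards; the TCP level is
## then extrapolated and intensities map linearly onto a [background, TCP]
## density scale.

#' Measured intensity threshold set
#'
#' The five intensity levels measured from a representative BF tomogram.
#' BF polarity: lower intensity = more scattering, so peaks lie below
#' inclusive levels which lie below water.
#'
#' @param granulePeak,granuleInclusive granule peak / inclusive levels.
#' @param ribosomePeak,ribosomeInclusive ribosome peak / inclusive levels.
#' @param water cytosolic water level.
#' @return named numeric vector of class validation-checked thresholds.
#' @examples
#' thresholdSet(0.3, 3.0, 5.3, 7.5, 16)
#' @export
thresholdSet <- function(granulePeak, granuleInclusive, ribosomePeak,
                         ribosomeInclusive, water) {
  th <- c(granule_peak = granulePeak, granule_inclusive = granuleInclusive,
          ribosome_peak = ribosomePeak,
          ribosome_inclusive = ribosomeInclusive, water = water)
  if (any(!is.finite(th))) stop("thresholds must be finite")
  if (!(granulePeak < granuleInclusive && granuleInclusive < water))
    stop("ordering violated: granule peak < granule inclusive < water")
  if (!(ribosomePeak < ribosomeInclusive && ribosomeInclusive < water))
    stop("ordering violated: ribosome peak < ribosome inclusive < water")
  th
}

#' Estimate the additive unscattered background
#'
#' Solves (reference - x) / (water - x) = ratio for x, where ratio is the
#' predicted scattering ratio of the reference material to water. With
#' BF polarity (reference below water, ratio > 1) the solution
#' x = (ratio * water - reference) / (ratio - 1) always lies above water.
#'
#' @param reference measured intensity of the reference material.
#' @param water measured water intensity.
#' @param ratio predicted reference/water scattering ratio (> 1).
#' @return the background intensity x.
#' @examples
#' estimateBackground(5.3, 16, 2.29)  # 24.3
#' @export
estimateBackground <- function(reference, water, ratio) {
  if (!is.finite(ratio) || ratio <= 1)
    stop("predicted ratio must exceed 1 for a BF-polarity solution")
  if (!(reference < water))
    stop("reference intensity must lie below the water intensity (BF polarity)")
  (ratio * water - reference) / (ratio - 1)
}

#' Extrapolate the intensity of pure crystalline TCP
#'
#' On the linear intensity scale, TCP scatters \code{tcpWaterRatio} times
#' as much as water, so its intensity extrapolates (usually below zero) to
#' \code{x - tcpWaterRatio * (x - water)}.
#'
#' @param x background intensity (above water).
#' @param water measured water intensity.
#' @param tcpWaterRatio predicted TCP/water scattering ratio (> 1).
#' @return the extrapolated TCP intensity.
#' @examples
#' extrapolateTcpIntensity(24.3, 16, 6.06)  # -26.0
#' @export
extrapolateTcpIntensity <- function(x, water, tcpWaterRatio) {
  if (!(x > water)) stop("polarity violation: x must exceed water intensity")
  if (!is.finite(tcpWaterRatio) || tcpWaterRatio < 1)
    stop("tcpWaterRatio must be >= 1")
  x - tcpWaterRatio * (x - water)
}

#' Build an intensity calibration from measured thresholds
#'
#' Estimates the background x from the chosen internal-standard pairing —
#' ribosome-peak intensity against the rRNA/water ratio (primary), or
#' ribosome-inclusive intensity against the ribosome/water ratio — then
#' extrapolates the TCP intensity.
#'
#' @param thresholds a \code{\link{thresholdSet}}.
#' @param reference \code{"rna_peak"} (default) or
#'   \code{"ribosome_inclusive"}.
#' @param ratios named numeric with elements \code{rna_water},
#'   \code{ribosome_water}, \code{tcp_water}; defaults to the quoted
#'   reference-table ratios.
#' @param tcpDensity crystalline TCP mass density, g/cm^3.
#' @param quoteX quote x at 3 significant figures before extrapolating TCP
#'   (the reporting convention of the reference tabulation). Default FALSE:
#'   keep the exact solution.
#' @return an \linkS4class{IntensityCalibration}.
#' @examples
#' th <- thresholdSet(0.3, 3.0, 5.3, 7.5, 16)
#' intensityCalibration(th)
#' @export
intensityCalibration <- function(thresholds,
                                 reference = c("rna_peak",
                                               "ribosome_inclusive"),
                                 ratios = quotedReferenceRatios(),
                                 tcpDensity = 3.14,
                                 quoteX = FALSE) {
  reference <- match.arg(reference)
  need <- c("rna_water", "ribosome_water", "tcp_water")
  if (!all(need %in% names(ratios)))
    stop("ratios must carry: ", paste(need, collapse = ", "))
  refI <- if (reference == "rna_peak") thresholds[["ribosome_peak"]]
          else thresholds[["ribosome_inclusive"]]
  refRatio <- if (reference == "rna_peak") ratios[["rna_water"]]
              else ratios[["ribosome_water"]]
  water <- thresholds[["water"]]
  x <- estimateBackground(refI, water, refRatio)
  if (quoteX) x <- signif(x, 3)
  tcp <- extrapolateTcpIntensity(x, water, ratios[["tcp_water"]])
  new("IntensityCalibration", backgroundX = x, waterIntensity = water,
      tcpIntensity = tcp, referenceUsed = reference,
      tcpWaterRatio = ratios[["tcp_water"]], tcpMassDensity = tcpDensity,
      tcpFormulaWeight = formulaWeight("Ca3(PO4)2"))
}

#' Build a calibration from one reference level and one water level
#'
#' Lower-level constructor used when the reference material and its
#' predicted ratio to water are supplied directly (e.g. phantom recovery,
#' where the reference puncta have a known composition).
#'
#' @param referenceIntensity measured reference-material intensity.
#' @param waterIntensity measured water intensity.
#' @param referenceRatio predicted reference/water scattering ratio (> 1).
#' @param tcpWaterRatio predicted TCP/water scattering ratio.
#' @param tcpDensity crystalline TCP mass density, g/cm^3.
#' @param quoteX quote x at 3 significant figures before extrapolation.
#' @return an \linkS4class{IntensityCalibration} (referenceUsed = "user").
#' @export
calibrationFromReference <- function(referenceIntensity, waterIntensity,
                                     referenceRatio, tcpWaterRatio,
                                     tcpDensity = 3.14, quoteX = FALSE) {
  x <- estimateBackground(referenceIntensity, waterIntensity, referenceRatio)
  if (quoteX) x <- signif(x, 3)
  new("IntensityCalibration", backgroundX = x,
      waterIntensity = waterIntensity,
      tcpIntensity = extrapolateTcpIntensity(x, waterIntensity,
                                             tcpWaterRatio),
      referenceUsed = "user", tcpWaterRatio = tcpWaterRatio,
      tcpMassDensity = tcpDensity,
      tcpFormulaWeight = formulaWeight("Ca3(PO4)2"))
}

#' Quoted reference scattering ratios
#'
#' The material/water ratios of the packaged signal table at its 2-decimal
#' quoting convention (see \code{\link{bfSignalTable}}).
#'
#' @param ... passed to \code{\link{bfSignalTable}}.
#' @return named numeric: rna_water, ribosome_water, tcp_water.
#' @export
quotedReferenceRatios <- function(...) {
  r <- bfSignalTable(...)$ratios
  stats::setNames(r$quoted, c("ribosome_water", "rna_water", "tcp_water"))
}

#' Map BF intensities to density estimates
#'
#' Places intensities on the linear scale from background (density 0) to
#' the extrapolated TCP level (density 1):
#' fraction of TCP = (x - I) / (x - I_TCP), ratio to water =
#' (x - I) / (x - I_water). Mass density is fraction times the TCP density;
#' the molar density divides by the Ca3(PO4)2 formula weight.
#'
#' Intensities above the background (which would imply negative density)
#' are flagged in the \code{aboveBackground} column with a warning, never
#' silently clipped.
#'
#' @param intensity numeric vector of tomogram intensities.
#' @param calib an \linkS4class{IntensityCalibration}.
#' @return data.frame: intensity, ratioToWater, fractionOfTcp,
#'   massDensity (g/cm^3), molarDensity (mol/cm^3), aboveBackground.
#' @examples
#' th <- thresholdSet(0.3, 3.0, 5.3, 7.5, 16)
#' densityFraction(0.3, intensityCalibration(th, quoteX = TRUE))
#' @export
densityFraction <- function(intensity, calib) {
  stopifnot(is(calib, "IntensityCalibration"))
  x <- calib@backgroundX
  frac <- (x - intensity) / (x - calib@tcpIntensity)
  rw <- (x - intensity) / (x - calib@waterIntensity)
  above <- intensity > x
  if (any(above))
    warning("intensity above background: negative density flagged")
  md <- frac * calib@tcpMassDensity
  data.frame(intensity = intensity, ratioToWater = rw,
             fractionOfTcp = frac, massDensity = md,
             molarDensity = md / calib@tcpFormulaWeight,
             aboveBackground = above)
}

#' Equivalent molar ion concentrations
#'
#' Converts a granule density estimate into the liquid-equivalent molar
#' concentrations obtained if the granule material were dissolved over a
#' region of which the granules occupy \code{volumeFraction}: formula-unit
#' molarity = molar density x volume fraction x 1000 cm^3/L; each formula
#' unit carries 3 calcium and 2 phosphate ions.
#'
#' @param estimate a row of \code{\link{densityFraction}} output, or a
#'   bare fraction-of-TCP value.
#' @param volumeFraction fraction of the region occupied by granules, [0,1].
#' @param tcpDensity,tcpFormulaWeight used only when \code{estimate} is a
#'   bare fraction.
#' @return named numeric: formula_M, calcium_M, phosphate_M (mol/L).
#' @examples
#' equivalentConcentration(0.31, volumeFraction = 0.20)
#' @export
equivalentConcentration <- function(estimate, volumeFraction,
                                    tcpDensity = 3.14,
                                    tcpFormulaWeight =
                                      formulaWeight("Ca3(PO4)2")) {
  if (!is.finite(volumeFraction) || volumeFraction < 0 || volumeFraction > 1)
    stop("volumeFraction must lie in [0, 1]")
  molar <- if (is.data.frame(estimate)) estimate$molarDensity
           else estimate * tcpDensity / tcpFormulaWeight
  formulaM <- molar * volumeFraction * 1000
  c(formula_M = formulaM, calcium_M = 3 * formulaM,
    phosphate_M = 2 * formulaM)
}

#' Full granule density evaluation report
#'
#' Runs the whole evaluation for a measured threshold set: both
#' internal-standard calibrations (primary: rRNA/water ratio on the
#' ribosome-peak level; parenthetical: ribosome/water ratio on the
#' ribosome-inclusive level), both TCP extrapolations, and the grid of
#' ratio-to-water / ratio-to-TCP for all five levels. Background values are
#' quoted at 3 significant figures and ratios at 2 decimals, the reporting
#' convention of the reference evaluation.
#'
#' @param thresholds a \code{\link{thresholdSet}}.
#' @param ratios see \code{\link{intensityCalibration}}.
#' @param tcpDensity crystalline TCP mass density, g/cm^3.
#' @return list with elements \code{grid} (data.frame), \code{primary} and
#'   \code{parenthetical} (\linkS4class{IntensityCalibration}), printed via
#'   its own method.
#' @examples
#' granuleDensityReport(thresholdSet(0.3, 3.0, 5.3, 7.5, 16))$grid
#' @export
granuleDensityReport <- function(thresholds,
                                 ratios = quotedReferenceRatios(),
                                 tcpDensity = 3.14) {
  primary <- intensityCalibration(thresholds, "rna_peak", ratios,
                                  tcpDensity, quoteX = TRUE)
  secondary <- intensityCalibration(thresholds, "ribosome_inclusive",
                                    ratios, tcpDensity, quoteX = TRUE)
  comp <- names(thresholds)
  dfP <- densityFraction(unname(thresholds), primary)
  dfS <- densityFraction(unname(thresholds), secondary)
  grid <- data.frame(
    component = comp,
    intensity = unname(thresholds),
    ratioToWater = round(dfP$ratioToWater, 2),
    ratioToTcp = round(dfP$fractionOfTcp, 2),
    ratioToWaterAlt = round(dfS$ratioToWater, 2),
    ratioToTcpAlt = round(dfS$fractionOfTcp, 2))
  structure(list(grid = grid, primary = primary,
                 parenthetical = secondary, thresholds = thresholds),
            class = "granuleDensityReport")
}

#' @export
print.granuleDensityReport <- function(x, ...) {
  cat("Granule density evaluation\n")
  cat(sprintf("  background x: %.3g (%.3g)\n",
              x$primary@backgroundX, x$parenthetical@backgroundX))
  cat(sprintf("  TCP intensity: %.1f (%.1f)\n",
              x$primary@tcpIntensity, x$parenthetical@tcpIntensity))
  g <- x$grid
  cat(sprintf("  %-20s %9s %14s %12s\n", "component", "intensity",
              "ratio/water", "ratio/TCP"))
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-20s %9.3g %7.2f (%.2f) %5.2f (%.2f)\n",
                g$component[i], g$intensity[i], g$ratioToWater[i],
                g$ratioToWaterAlt[i], g$ratioToTcp[i], g$ratioToTcpAlt[i]))
  invisible(x)
}

#' Read a threshold CSV
#'
#' CSV with columns component, intensity; components named as in
#' \code{\link{thresholdSet}}.
#' @param path file path.
#' @return a validated threshold set.
#' @export
readThresholds <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("component", "intensity") %in% names(df)))
    stop("threshold file must have columns component, intensity")
  need <- c("granule_peak", "granule_inclusive", "ribosome_peak",
            "ribosome_inclusive", "water")
  missing <- setdiff(need, df$component)
  if (length(missing))
    stop("threshold file missing component(s): ",
         paste(missing, collapse = ", "))
  v <- stats::setNames(df$intensity, df$component)[need]
  thresholdSet(v[[1]], v[[2]], v[[3]], v[[4]], v[[5]])
}
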