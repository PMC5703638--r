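## Physical constants and unit conversions. All lengths are nm internally,
## number densities atoms/nm^3, mass densities g/cm^3. Every unit conversion
## in the package goes through the helpers below.

#' Avogadro constant
#'
#' @return Avogadro's number (mol^-1), 2019 SI exact value.
#' @export
avogadro <- function() 6.02214076e23

## nm^3 per cm^3
.NM3_PER_CM3 <- 1e21

#' Standard atomic weights
#'
#' IUPAC 2021 conventional atomic weights for the elements handled by the
#' composition module. Returned as a named numeric vector in g/mol.
#'
#' @param elements optional character vector of element symbols to subset;
#'   unknown symbols raise an error.
#' @return named numeric vector of atomic weights (g/mol).
#' @examples
#' atomicWeights(c("Ca", "P", "O"))
#' @export
atomicWeights <- function(elements = NULL) {
  w <- c(
    H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81,
    C = 12.011, N = 14.007, O = 15.999, F = 18.998, Ne = 20.180,
    Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.973762,
    S = 32.06, Cl = 35.45, K = 39.098, Ar = 39.95, Ca = 40.078,
    Mn = 54.938, Fe = 55.845, Zn = 65.38
  )
  if (is.null(elements)) return(w)
  bad <- setdiff(elements, names(w))
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  w[elements]
}

## mass (g) of a set of atom counts
.countsMassGrams <- function(counts) {
  sum(counts * atomicWeights(names(counts))) / avogadro()
}

## mass density (g/cm^3) of a number-density profile (atoms/nm^3)
.profileMassDensity <- function(densities) {
  sum(densities * atomicWeights(names(densities))) / avogadro() * .NM3_PER_CM3
}

## validate a named counts vector (ElementCounts contract)
.checkCounts <- function(counts) {
  if (!is.numeric(counts) || is.null(names(counts)) || !length(counts))
    stop("counts must be a non-empty named numeric vector (element -> count)")
  if (any(!nzchar(names(counts))) || anyDuplicated(names(counts)))
    stop("counts names must be unique non-empty element symbols")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  atomicWeights(names(counts))  # errors on unknown symbols
  invisible(counts)
}

#' Parse a chemical formula
#'
#' Parses formulas such as \code{"Ca3(PO4)2"} into per-element atom counts.
#' Supports case-sensitive element symbols, integer subscripts, and
#' parenthesized groups with integer multipliers. No nesting of parentheses,
#' no hydrates/charges.
#'
#' @param formula a single formula string.
#' @return named numeric vector of stoichiometric counts.
#' @examples
#' parseFormula("Ca3(PO4)2")
#' @export
parseFormula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || !nzchar(formula))
    stop("formula must be a single non-empty string")
  counts <- c()
  add <- function(tab, sym, n) {
    tab[sym] <- if (sym %in% names(tab)) tab[[sym]] + n else n
    tab
  }
  parseFlat <- function(s) {
    tab <- c()
    pos <- 1L
    while (pos <= nchar(s)) {
      m <- regmatches(substr(s, pos, nchar(s)),
                      regexpr("^[A-Z][a-z]?[0-9]*", substr(s, pos, nchar(s))))
      if (!length(m) || !nzchar(m))
        stop("cannot parse formula at: '", substr(s, pos, nchar(s)), "'")
      sym <- sub("[0-9]*$", "", m)
      num <- sub("^[A-Za-z]+", "", m)
      tab <- add(tab, sym, if (nzchar(num)) as.numeric(num) else 1)
      pos <- pos + nchar(m)
    }
    tab
  }
  rest <- formula
  while (nzchar(rest)) {
    grp <- regmatches(rest, regexpr("^\\(([A-Za-z0-9]+)\\)([0-9]*)", rest))
    if (length(grp) && nzchar(grp)) {
      inner <- sub("^\\(([A-Za-z0-9]+)\\)[0-9]*$", "\\1", grp)
      mult <- sub("^\\([A-Za-z0-9]+\\)", "", grp)
      mult <- if (nzchar(mult)) as.numeric(mult) else 1
      tab <- parseFlat(inner)
      for (sym in names(tab)) counts <- add(counts, sym, tab[[sym]] * mult)
      rest <- substr(rest, nchar(grp) + 1L, nchar(rest))
    } else {
      m <- regmatches(rest, regexpr("^[A-Z][a-z]?[0-9]*", rest))
      if (!length(m) || !nzchar(m))
        stop("cannot parse formula at: '", rest, "'")
      sym <- sub("[0-9]*$", "", m)
      num <- sub("^[A-Za-z]+", "", m)
      counts <- add(counts, sym, if (nzchar(num)) as.numeric(num) else 1)
      rest <- substr(rest, nchar(m) + 1L, nchar(rest))
    }
  }
  .checkCounts(counts)
  counts
}

#' Formula weight
#'
#' @param formula formula string or named counts vector.
#' @return molecular/formula weight in g/mol.
#' @examples
#' formulaWeight("Ca3(PO4)2")  # ~310.17
#' @export
formulaWeight <- function(formula) {
  counts <- if (is.character(formula)) parseFormula(formula) else formula
  .checkCounts(counts)
  sum(counts * atomicWeights(names(counts)))
}
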