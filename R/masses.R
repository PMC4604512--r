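## Monoisotopic mass constants (Da). Proton/water values fixed by package
## convention; all arithmetic in the package is monoisotopic.
PROTON_MASS <- 1.007276
WATER_MASS <- 18.010565
CO_MASS <- 27.994915
NH3_MASS <- 17.026549
ISOTOPE_SPACING <- 1.00335

## Monoisotopic residue masses of the canonical amino acids. Ile is mass-identical
## to Leu and is folded into 'L' everywhere (input canonicalization).
.BASE_RESIDUE_MASSES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, N = 114.04293, D = 115.02694,
  Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Residue mass table with fixed and variable modifications
#'
#' Builds the lookup table of residue symbol to monoisotopic residue mass.
#' Fixed modifications replace the base mass of their residue; each variable
#' modification adds one extra lowercase entry (e.g. oxidized Met is `"m"`).
#' Ile is represented as Leu throughout, so the base table holds 19 symbols.
#'
#' The defaults match the common benchmark settings for tryptic CID data:
#' carbamidomethylation of Cys as fixed and oxidation of Met as variable.
#'
#' @param fixedMods named numeric vector of mass deltas (Da) applied to the
#'   base residue mass, e.g. `c(C = 57.02146)`.
#' @param variableMods named numeric vector of mass deltas (Da); each adds a
#'   lowercase variant symbol, e.g. `c(M = 15.99491)` adds `"m"`.
#' @return named numeric vector of residue masses (Da).
#' @examples
#' tab <- residueMassTable()
#' tab["G"]   # 57.02146
#' tab["C"]   # carbamidomethylated: 160.03065
#' tab["m"]   # oxidized Met
#' @export
residueMassTable <- function(fixedMods = c(C = 57.02146),
                             variableMods = c(M = 15.99491)) {
  tab <- .BASE_RESIDUE_MASSES
  if (length(fixedMods)) {
    bad <- setdiff(names(fixedMods), names(tab))
    if (length(bad)) {
      stop("unknown residue symbol in fixed modifications: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    tab[names(fixedMods)] <- tab[names(fixedMods)] + fixedMods
  }
  if (length(variableMods)) {
    bad <- setdiff(names(variableMods), names(.BASE_RESIDUE_MASSES))
    if (length(bad)) {
      stop("unknown residue symbol in variable modifications: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    extra <- .BASE_RESIDUE_MASSES[names(variableMods)] + variableMods
    names(extra) <- tolower(names(variableMods))
    tab <- c(tab, extra)
  }
  tab
}

#' Canonicalize a residue symbol
#'
#' Folds Ile into Leu and validates the symbol against a mass table.
#'
#' @param code character vector of single-residue symbols.
#' @param massTable residue mass table from [residueMassTable()].
#' @return canonicalized symbols.
#' @export
canonicalResidue <- function(code, massTable = residueMassTable()) {
  code[code == "I"] <- "L"
  bad <- setdiff(unique(code), names(massTable))
  if (length(bad)) {
    stop("unknown residue symbol: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  code
}

## The nine CID fragment ion types. Column order is the canonical layout order
## used by the feature extractors. "series" tells which terminus carries the
## fragment; doubly charged variants exist only for b and y.
.ION_TYPES <- data.frame(
  name = c("y", "b", "a", "y2", "b2", "b-18", "b-17", "y-18", "y-17"),
  series = c("y", "b", "b", "y", "b", "b", "b", "y", "y"),
  charge = c(1L, 1L, 1L, 2L, 2L, 1L, 1L, 1L, 1L),
  loss = c(0, 0, CO_MASS, 0, 0, WATER_MASS, NH3_MASS, WATER_MASS, NH3_MASS),
  stringsAsFactors = FALSE
)

#' The nine fragment ion types
#'
#' Returns the table of ion types scored at every fragmentation site:
#' y, b, a, y(2+), b(2+), b-18, b-17, y-18 and y-17, with series
#' (b-like or y-like), charge and neutral loss.
#'
#' @return data.frame with columns `name`, `series`, `charge`, `loss`.
#' @export
ionTypes <- function() .ION_TYPES

#' Theoretical fragment m/z from a prefix mass
#'
#' Computes the m/z of any of the nine ion types at a fragmentation site,
#' given the prefix residue mass and the total residue mass of the peptide.
#' The suffix mass is `totalResidueMass - prefixMass`; b-like ions are built
#' from the prefix, y-like ions from the suffix plus water.
#'
#' @param prefixMass prefix residue mass (Da), vectorized.
#' @param totalResidueMass total residue mass of the peptide (Da, water
#'   excluded).
#' @param ionName one of the nine ion type names from [ionTypes()].
#' @return theoretical m/z (Da).
#' @examples
#' ionMz(71.03711, 128.05857, "b")    # b1 of AG: 72.04439
#' ionMz(71.03711, 128.05857, "y")    # y1 of AG: 76.03930
#' @export
ionMz <- function(prefixMass, totalResidueMass, ionName) {
  i <- match(ionName, .ION_TYPES$name)
  if (is.na(i)) stop("unknown ion type: ", ionName, call. = FALSE)
  z <- .ION_TYPES$charge[i]
  if (.ION_TYPES$series[i] == "b") {
    neutral <- prefixMass - .ION_TYPES$loss[i]
  } else {
    neutral <- (totalResidueMass - prefixMass) + WATER_MASS - .ION_TYPES$loss[i]
  }
  (neutral + z * PROTON_MASS) / z
}

#' Fragment m/z for a peptide fragmentation site
#'
#' @param peptide a [Peptide-class] object.
#' @param site fragmentation site index, between 1 and `length - 1`.
#' @param ionName ion type name (see [ionTypes()]).
#' @return theoretical m/z (Da).
#' @examples
#' tab <- residueMassTable()
#' p <- Peptide(c("A", "G"), tab)
#' fragmentMz(p, 1, "b")     # 72.04439
#' fragmentMz(p, 1, "b-18")  # 54.03383
#' @export
fragmentMz <- function(peptide, site, ionName) {
  n <- peptideLength(peptide)
  if (any(site < 1L | site > n - 1L)) {
    stop("fragmentation site out of range [1, n-1]", call. = FALSE)
  }
  pref <- prefixMasses(peptide)[site]
  ionMz(pref, totalResidueMass(peptide), ionName)
}
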