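#' @import methods
NULL

#' Centroided MS/MS spectrum
#'
#' A centroided peak list with its precursor descriptor. Peaks are stored
#' sorted by m/z; the neutral peptide mass is derived once from the precursor
#' as `precursorMz * z - z * proton`.
#'
#' @slot mz numeric, peak m/z values (Da), ascending.
#' @slot intensity numeric, peak intensities (arbitrary units, >= 0).
#' @slot precursorMz numeric(1), precursor m/z (Da).
#' @slot precursorCharge integer(1), precursor charge (>= 1).
#' @slot id character(1), opaque spectrum identifier.
#' @aliases Spectrum-class
#' @exportClass Spectrum
setClass("Spectrum",
  representation(
    mz = "numeric",
    intensity = "numeric",
    precursorMz = "numeric",
    precursorCharge = "integer",
    id = "character"
  )
)

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity must have equal length")
  if (is.unsorted(object@mz))
    msg <- c(msg, "peaks must be sorted by m/z ascending")
  if (length(object@intensity) && any(object@intensity < 0))
    msg <- c(msg, "intensities must be >= 0")
  if (length(object@precursorMz) != 1L || object@precursorMz <= 0)
    msg <- c(msg, "precursorMz must be a positive scalar")
  if (length(object@precursorCharge) != 1L || object@precursorCharge < 1L)
    msg <- c(msg, "precursorCharge must be an integer >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' Peaks are sorted by m/z on construction.
#'
#' @param mz,intensity peak list.
#' @param precursorMz precursor m/z (Da).
#' @param precursorCharge precursor charge state.
#' @param id spectrum identifier.
#' @return a [Spectrum-class] object.
#' @export
Spectrum <- function(mz, intensity, precursorMz, precursorCharge = 2L,
                     id = "") {
  o <- order(mz)
  new("Spectrum",
      mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
      precursorMz = as.numeric(precursorMz),
      precursorCharge = as.integer(precursorCharge),
      id = as.character(id))
}

#' @describeIn Spectrum-class peak m/z values
#' @param x,object a `Spectrum`.
#' @export
peakMz <- function(x) x@mz

#' @describeIn Spectrum-class peak intensities
#' @export
peakIntensity <- function(x) x@intensity

#' @describeIn Spectrum-class number of peaks
#' @export
peakCount <- function(x) length(x@mz)

#' @describeIn Spectrum-class precursor m/z (Da)
#' @export
precursorMz <- function(x) x@precursorMz

#' @describeIn Spectrum-class precursor charge state
#' @export
precursorCharge <- function(x) x@precursorCharge

#' @describeIn Spectrum-class spectrum identifier
#' @export
spectrumId <- function(x) x@id

#' @describeIn Spectrum-class derived neutral peptide mass,
#'   `precursorMz * z - z * proton` (Da)
#' @export
neutralMass <- function(x) x@precursorMz * x@precursorCharge -
  x@precursorCharge * PROTON_MASS

#' @describeIn Spectrum-class total residue mass (neutral mass minus water)
#' @export
spectrumResidueMass <- function(x) neutralMass(x) - WATER_MASS

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum '%s': %d peaks, precursor %.4f m/z (%d+), M = %.4f Da\n",
              object@id, length(object@mz), object@precursorMz,
              object@precursorCharge, neutralMass(object)))
})

#' Peptide sequence with resolved residue masses
#'
#' An ordered residue sequence with masses resolved against a residue mass
#' table at construction time. Modified residues carry their own symbol
#' (e.g. `"m"` for oxidized Met); Ile is canonicalized to Leu.
#'
#' @slot residues character, residue symbols.
#' @slot masses numeric, monoisotopic residue masses (Da).
#' @slot nTermMod numeric(1), optional N-terminal mass delta (Da).
#' @aliases Peptide-class
#' @exportClass Peptide
setClass("Peptide",
  representation(
    residues = "character",
    masses = "numeric",
    nTermMod = "numeric"
  )
)

setValidity("Peptide", function(object) {
  msg <- character()
  if (length(object@residues) < 1L)
    msg <- c(msg, "peptide must have at least one residue")
  if (length(object@residues) != length(object@masses))
    msg <- c(msg, "residues and masses must have equal length")
  if (length(object@masses) && any(object@masses <= 0))
    msg <- c(msg, "residue masses must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a Peptide
#'
#' @param residues character vector of residue symbols (Ile is folded to Leu).
#' @param massTable residue mass table from [residueMassTable()].
#' @param nTermMod optional N-terminal mass delta (Da).
#' @return a [Peptide-class] object.
#' @export
Peptide <- function(residues, massTable = residueMassTable(), nTermMod = 0) {
  residues <- canonicalResidue(residues, massTable)
  new("Peptide", residues = residues,
      masses = unname(massTable[residues]), nTermMod = as.numeric(nTermMod))
}

#' @describeIn Peptide-class residue symbols
#' @param x,object a `Peptide`.
#' @export
residues <- function(x) x@residues

#' @describeIn Peptide-class residue masses (Da)
#' @export
residueMasses <- function(x) x@masses

#' @describeIn Peptide-class number of residues
#' @export
peptideLength <- function(x) length(x@residues)

#' @describeIn Peptide-class total residue mass including any N-terminal
#'   modification (water excluded)
#' @export
totalResidueMass <- function(x) sum(x@masses) + x@nTermMod

#' @describeIn Peptide-class neutral peptide mass (residues + water)
#' @export
peptideMass <- function(x) totalResidueMass(x) + WATER_MASS

#' @describeIn Peptide-class cumulative prefix masses after residues 1..n;
#'   interior fragmentation sites are entries 1..n-1
#' @export
prefixMasses <- function(x) cumsum(x@masses) + x@nTermMod

#' @describeIn Peptide-class sequence as a single string
#' @export
peptideString <- function(x) paste(x@residues, collapse = "")

setMethod("show", "Peptide", function(object) {
  cat(sprintf("Peptide %s (n = %d, M = %.5f Da)\n",
              peptideString(object), length(object@residues),
              peptideMass(object)))
})

#' Parse a peptide string
#'
#' Accepts sequences of single-letter residue codes with optional
#' parenthesized modification tags. Supported tags: `"(O)"` after `M`
#' (oxidation, mapped to the `"m"` table entry). Ile is folded to Leu.
#' Unsupported tags raise an error of class `treeDenovo_unsupported_mod`,
#' which the MSP reader turns into a skip.
#'
#' @param x peptide string, e.g. `"AGM(O)K"`.
#' @param massTable residue mass table.
#' @return a [Peptide-class] object.
#' @export
parsePeptide <- function(x, massTable = residueMassTable()) {
  toks <- regmatches(x, gregexpr("[A-Za-z](\\([^)]*\\))?", x))[[1]]
  if (!length(toks) || sum(nchar(gsub("\\(.*", "", toks))) == 0L)
    stop("cannot parse peptide string: ", x, call. = FALSE)
  codes <- vapply(toks, function(t) {
    base <- substr(t, 1L, 1L)
    tag <- if (nchar(t) > 1L) substr(t, 3L, nchar(t) - 1L) else ""
    if (tag == "") return(base)
    if (base == "M" && tag %in% c("O", "Oxidation", "ox")) return("m")
    stop(structure(
      class = c("treeDenovo_unsupported_mod", "error", "condition"),
      list(message = sprintf("unsupported modification '%s' on %s", tag, base),
           call = NULL)))
  }, character(1), USE.NAMES = FALSE)
  Peptide(codes, massTable)
}

#' De novo sequencing result
#'
#' The best candidate peptide for a spectrum together with its per-residue
#' correctness probabilities, integer confidence scores (0-100), the
#' mass-weighted aggregate residue score and the dynamic-programming stage
#' score `sum(p_i - 0.1)` over interior fragmentation sites.
#'
#' @slot peptide the candidate [Peptide-class]; length-0 residues when empty.
#' @slot residueProbs numeric, per-residue correctness probabilities.
#' @slot residueScores integer, `round(100 * p)` per residue.
#' @slot aggregateScore numeric(1), `sum(p_i m_i) / sum(m_i)`.
#' @slot fragStageScore numeric(1), DP-stage fragmentation score.
#' @slot empty logical(1), TRUE when the spectrum could not be sequenced.
#' @slot info list of search counters (DP runs, refinement iterations,
#'   maximum segment fillings).
#' @aliases DeNovoResult-class
#' @exportClass DeNovoResult
setClass("DeNovoResult",
  representation(
    peptide = "Peptide",
    residueProbs = "numeric",
    residueScores = "integer",
    aggregateScore = "numeric",
    fragStageScore = "numeric",
    empty = "logical",
    info = "list"
  )
)

setValidity("DeNovoResult", function(object) {
  msg <- character()
  if (!object@empty) {
    n <- length(object@peptide@residues)
    if (length(object@residueProbs) != n)
      msg <- c(msg, "one probability per residue required")
    if (length(object@residueProbs) &&
        any(object@residueProbs <= 0 | object@residueProbs >= 1))
      msg <- c(msg, "residue probabilities must lie strictly in (0, 1)")
  }
  if (length(msg)) msg else TRUE
})

.emptyPeptide <- function() new("Peptide", residues = "X", masses = 1,
                                nTermMod = 0)

#' Construct a DeNovoResult
#' @param peptide candidate peptide (or NULL for an empty result).
#' @param residueProbs per-residue correctness probabilities.
#' @param fragStageScore DP-stage score.
#' @param info list of counters.
#' @return a [DeNovoResult-class].
#' @export
DeNovoResult <- function(peptide = NULL, residueProbs = numeric(),
                         fragStageScore = NA_real_, info = list()) {
  if (is.null(peptide)) {
    return(new("DeNovoResult", peptide = .emptyPeptide(),
               residueProbs = numeric(), residueScores = integer(),
               aggregateScore = NA_real_, fragStageScore = NA_real_,
               empty = TRUE, info = info))
  }
  m <- residueMasses(peptide)
  new("DeNovoResult",
      peptide = peptide,
      residueProbs = residueProbs,
      residueScores = as.integer(round(100 * residueProbs)),
      aggregateScore = sum(residueProbs * m) / sum(m),
      fragStageScore = fragStageScore,
      empty = FALSE, info = info)
}

#' @describeIn DeNovoResult-class the candidate peptide
#' @param x,object a `DeNovoResult`.
#' @export
resultPeptide <- function(x) x@peptide

#' @describeIn DeNovoResult-class per-residue probabilities
#' @export
residueProbs <- function(x) x@residueProbs

#' @describeIn DeNovoResult-class per-residue integer scores 0-100
#' @export
residueScores <- function(x) x@residueScores

#' @describeIn DeNovoResult-class mass-weighted aggregate residue score
#' @export
aggregateScore <- function(x) x@aggregateScore

#' @describeIn DeNovoResult-class DP-stage fragmentation score
#' @export
fragStageScore <- function(x) x@fragStageScore

#' @describeIn DeNovoResult-class TRUE when no sequence could be produced
#' @export
isEmptyResult <- function(x) x@empty

#' @describeIn DeNovoResult-class search counters
#' @export
resultInfo <- function(x) x@info

setMethod("show", "DeNovoResult", function(object) {
  if (object@empty) {
    cat("DeNovoResult: <no sequence>\n")
  } else {
    cat(sprintf("DeNovoResult: %s  score %.3f\n  residue scores: %s\n",
                peptideString(object@peptide), object@aggregateScore,
                paste(object@residueScores, collapse = ",")))
  }
})
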