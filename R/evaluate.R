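#' Residue-level matching between a true and a de novo peptide
#'
#' A residue `x` of the true peptide is correctly sequenced when the de novo
#' sequence contains a residue `y` with (1) `|mass(x) - mass(y)| <= 0.1 Da`
#' and (2) total residue mass before `x` and before `y` differing by at most
#' 0.5 Da. Low-resolution fragment mass accuracy cannot separate pairs such
#' as Lys/Gln or oxidized Met/Phe, which is why masses rather than symbols
#' are compared. Each de novo residue is consumed at most once; pairing is
#' greedy left to right. Both peptides are assumed I->L canonicalized
#' (construction does this).
#'
#' @param truePeptide,denovoPeptide [Peptide-class] objects.
#' @param massTol residue mass tolerance (Da).
#' @param prefixTol prefix mass tolerance (Da).
#' @return logical vector over true residues, with attribute `pairs`
#'   giving the index of the consumed de novo residue (NA if unmatched).
#' @export
matchResidues <- function(truePeptide, denovoPeptide, massTol = 0.1,
                          prefixTol = 0.5) {
  mT <- residueMasses(truePeptide)
  mD <- residueMasses(denovoPeptide)
  preT <- c(0, cumsum(mT))[seq_along(mT)] + truePeptide@nTermMod
  preD <- c(0, cumsum(mD))[seq_along(mD)] + denovoPeptide@nTermMod
  used <- rep(FALSE, length(mD))
  matched <- logical(length(mT))
  pairs <- rep(NA_integer_, length(mT))
  for (i in seq_along(mT)) {
    ok <- which(!used & abs(mT[i] - mD) <= massTol &
                  abs(preT[i] - preD) <= prefixTol)
    if (length(ok)) {
      j <- ok[1L]
      used[j] <- TRUE
      matched[i] <- TRUE
      pairs[i] <- j
    }
  }
  attr(matched, "pairs") <- pairs
  matched
}

#' Build a per-spectrum residue match report
#'
#' @param truePeptide the annotated [Peptide-class].
#' @param result the [DeNovoResult-class] for the same spectrum.
#' @return a `MatchReport`: list with the number of true residues `N`, all
#'   de novo residue scores, and the scores of de novo residues matched to
#'   a true residue.
#' @export
matchReport <- function(truePeptide, result) {
  N <- peptideLength(truePeptide)
  if (isEmptyResult(result)) {
    return(structure(list(N = N, denovoScores = integer(),
                          matchedScores = integer(),
                          matched = rep(FALSE, N)),
                     class = "MatchReport"))
  }
  flags <- matchResidues(truePeptide, resultPeptide(result))
  pairs <- attr(flags, "pairs")
  sc <- residueScores(result)
  structure(list(N = N, denovoScores = sc,
                 matchedScores = sc[pairs[!is.na(pairs)]],
                 matched = as.logical(flags)),
            class = "MatchReport")
}

#' Precision-recall curve over residue confidence thresholds
#'
#' For each threshold `t`, `recall(t) = correct(t) / N` and
#' `precision(t) = correct(t) / denovo(t)`, where `N` is the total number
#' of residues in the true peptides, `denovo(t)` the number of de novo
#' residues with score at least `t`, and `correct(t)` the number of
#' correctly sequenced residues with score at least `t`. Precision is NA
#' where `denovo(t) = 0`. Threshold 0 gives the maximum recall (no
#' filtration).
#'
#' @param reports list of [matchReport()] objects.
#' @param thresholds integer score thresholds (default 0:100).
#' @return data.frame with columns `t`, `precision`, `recall`, `denovo`,
#'   `correct`, `N`.
#' @export
prCurve <- function(reports, thresholds = 0:100) {
  N <- sum(vapply(reports, `[[`, numeric(1), "N"))
  if (N == 0) stop("no true residues: N = 0", call. = FALSE)
  denovoAll <- unlist(lapply(reports, `[[`, "denovoScores"))
  matchedAll <- unlist(lapply(reports, `[[`, "matchedScores"))
  den <- vapply(thresholds, function(t) sum(denovoAll >= t), numeric(1))
  cor <- vapply(thresholds, function(t) sum(matchedAll >= t), numeric(1))
  data.frame(t = thresholds,
             precision = ifelse(den > 0, cor / den, NA_real_),
             recall = cor / N, denovo = den, correct = cor, N = N)
}

## Site verifiability flags for one annotated spectrum: positions 0..n
## (termini always verifiable). A site is verifiable when at least one of
## the b, y, b(2+), y(2+) ions matches a peak with relative intensity >=
## minRelInt.
.verifiableSites <- function(spectrum, peptide, fragTol = 0.5,
                             minRelInt = 0.05) {
  n <- peptideLength(peptide)
  sites <- rep(TRUE, n + 1L)
  if (n < 2L || peakCount(spectrum) == 0L) return(sites)
  pref <- prefixMasses(peptide)[seq_len(n - 1L)]
  Mres <- totalResidueMass(peptide)
  base <- max(peakIntensity(spectrum))
  hit <- rep(FALSE, n - 1L)
  for (ion in c("y", "b", "y2", "b2")) {
    idx <- matchPeak(spectrum, ionMz(pref, Mres, ion), fragTol)
    ok <- !is.na(idx)
    hit[ok] <- hit[ok] |
      (peakIntensity(spectrum)[idx[ok]] / base >= minRelInt)
  }
  sites[2:n] <- hit
  sites
}

#' Fraction of verifiable residues
#'
#' A fragmentation site is verifiable when at least one of the b, y, b(2+)
#' and y(2+) ions has relative intensity of at least 5% (boundary
#' inclusive); the N- and C-termini are always verifiable. A residue is
#' verifiable when both of its flanking sites are. The fraction of
#' verifiable residues measures fragmentation completeness and bounds the
#' recall of any de novo sequencer that relies only on abundant peaks of
#' those four ion types.
#'
#' @param records list of `list(spectrum =, peptide =)` pairs.
#' @param fragTol fragment tolerance (Da).
#' @param minRelInt relative intensity floor (default 0.05).
#' @return fraction of verifiable residues across all records.
#' @export
verifiableFraction <- function(records, fragTol = 0.5, minRelInt = 0.05) {
  tot <- 0L
  ver <- 0L
  for (r in records) {
    s <- .verifiableSites(r$spectrum, r$peptide, fragTol, minRelInt)
    n <- peptideLength(r$peptide)
    tot <- tot + n
    ver <- ver + sum(s[seq_len(n)] & s[2:(n + 1L)])
  }
  ver / tot
}

## Does any of the nine ion types match a peak at this prefix mass?
.anyIonShows <- function(spectrum, prefix, Mres, fragTol) {
  for (ion in ionTypes()$name) {
    if (!is.na(matchPeak(spectrum, ionMz(prefix, Mres, ion), fragTol)))
      return(TRUE)
  }
  FALSE
}

#' Dipeptide mass-gap census
#'
#' Counts, over qualifying dipeptide mass gaps, how often the de novo
#' output gives the correct order versus the reversed order. A dipeptide
#' `X1 X2` of the true peptide qualifies when (1) each flanking site shows
#' at least one of the b, y, b(2+), y(2+) ions (the termini count as
#' showing), (2) the middle site shows none of the nine ion types, and
#' (3) condition 2 also holds for the site implied by the swapped order
#' `X2 X1`. For qualifying gaps the de novo output is classified by the
#' residue-matching rule applied to the original and to the swapped true
#' peptide; a symmetric dipeptide (e.g. GG) counts as correct.
#'
#' @param records list of `list(spectrum =, peptide =)` pairs.
#' @param results list of [DeNovoResult-class], parallel to `records`.
#' @param fragTol fragment tolerance (Da).
#' @param minRelInt relative intensity floor for the flanking condition.
#' @param massTable residue mass table.
#' @return data.frame with columns `dipeptide`, `correct`, `reversed`,
#'   sorted by total count.
#' @export
dipeptideGapCensus <- function(records, results, fragTol = 0.5,
                               minRelInt = 0.05,
                               massTable = residueMassTable()) {
  tallies <- new.env(parent = emptyenv())
  bump <- function(dp, slot) {
    cur <- if (exists(dp, tallies)) get(dp, tallies) else c(correct = 0L,
                                                            reversed = 0L)
    cur[slot] <- cur[slot] + 1L
    assign(dp, cur, tallies)
  }
  for (k in seq_along(records)) {
    sp <- records[[k]]$spectrum
    pep <- records[[k]]$peptide
    res <- results[[k]]
    if (isEmptyResult(res)) next
    n <- peptideLength(pep)
    if (n < 2L) next
    Mres <- totalResidueMass(pep)
    flank <- .verifiableSites(sp, pep, fragTol, minRelInt)
    pref <- prefixMasses(pep)
    rs <- residues(pep)
    rmass <- residueMasses(pep)
    for (i in seq_len(n - 1L)) {
      ## dipeptide rs[i] rs[i+1]; middle site = i, flanks = sites i-1, i+1
      if (!(flank[i] && flank[i + 2L])) next
      mid <- pref[i]
      if (.anyIonShows(sp, mid, Mres, fragTol)) next
      midSwap <- mid - rmass[i] + rmass[i + 1L]
      if (abs(midSwap - mid) > 1e-9 &&
          .anyIonShows(sp, midSwap, Mres, fragTol)) next
      dp <- paste0(rs[i], rs[i + 1L])
      fwd <- matchResidues(pep, resultPeptide(res))
      if (fwd[i] && fwd[i + 1L]) {
        bump(dp, "correct")
        next
      }
      swapped <- rs
      swapped[c(i, i + 1L)] <- swapped[c(i + 1L, i)]
      rev <- matchResidues(Peptide(swapped, massTable), resultPeptide(res))
      if (rev[i] && rev[i + 1L]) bump(dp, "reversed")
    }
  }
  dps <- ls(tallies)
  if (!length(dps)) {
    return(data.frame(dipeptide = character(), correct = integer(),
                      reversed = integer()))
  }
  out <- data.frame(
    dipeptide = dps,
    correct = vapply(dps, function(d) get(d, tallies)[["correct"]],
                     integer(1)),
    reversed = vapply(dps, function(d) get(d, tallies)[["reversed"]],
                      integer(1)),
    row.names = NULL)
  out[order(-(out$correct + out$reversed)), ]
}

#' Keep the best PSM per (peptide, charge)
#'
#' Redundancy removal for ground-truth tables: when a peptide was
#' identified by several spectra at the same charge state, only the
#' highest-scoring one is kept.
#'
#' @param psms data.frame with columns `peptide`, `charge`, `score`.
#' @return the de-duplicated data.frame.
#' @export
removeRedundant <- function(psms) {
  stopifnot(all(c("peptide", "charge", "score") %in% names(psms)))
  o <- order(psms$peptide, psms$charge, -psms$score)
  s <- psms[o, ]
  s[!duplicated(s[, c("peptide", "charge")]), ]
}
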