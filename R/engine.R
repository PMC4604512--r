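#' De novo search configuration
#'
#' @param fragTolDa fragment ion tolerance (Da).
#' @param precTolPpm precursor mass tolerance (ppm).
#' @param binWidth prefix-mass discretization (Da). 0.01 Da keeps the
#'   rounding error far below the fragment tolerance.
#' @param topK partial sequences kept per prefix-mass bin in the DP.
#' @param sitePenalty per-site penalty in the DP objective
#'   `sum(p_i - penalty)`; discourages filling mass with many small
#'   residues.
#' @param maxDpRuns maximum DP invocations per spectrum (first run plus
#'   relabeling reruns).
#' @param maxRefineIter maximum refinement iterations.
#' @param maxSegmentFillings a refinement segment must admit at most this
#'   many residue-sequence fillings before it is re-sequenced.
#' @return list of class `denovoConfig`.
#' @export
denovoConfig <- function(fragTolDa = 0.5, precTolPpm = 15, binWidth = 0.01,
                         topK = 8L, sitePenalty = 0.1, maxDpRuns = 3L,
                         maxRefineIter = 3L, maxSegmentFillings = 100L) {
  structure(list(fragTolDa = fragTolDa, precTolPpm = precTolPpm,
                 binWidth = binWidth, topK = as.integer(topK),
                 sitePenalty = sitePenalty, maxDpRuns = as.integer(maxDpRuns),
                 maxRefineIter = as.integer(maxRefineIter),
                 maxSegmentFillings = as.integer(maxSegmentFillings)),
            class = "denovoConfig")
}

.precTolDa <- function(spectrum, config) {
  config$precTolPpm * 1e-6 * neutralMass(spectrum)
}

## Candidate prefix masses implied by each observed peak under each of the
## nine ion-type interpretations (inverted mass formulas).
.invertPeaks <- function(mz, Mres) {
  it <- ionTypes()
  out <- lapply(seq_len(nrow(it)), function(t) {
    z <- it$charge[t]
    neutral <- mz * z - z * PROTON_MASS
    if (it$series[t] == "b") neutral + it$loss[t]
    else Mres - (neutral - WATER_MASS + it$loss[t])
  })
  v <- unlist(out)
  v[v > 0 & v < Mres]
}

#' Precompute fragmentation-site scores over prefix-mass bins
#'
#' Evaluates the fragmentation-score tree once for every prefix-mass bin in
#' `(0, Mres)`, where `Mres` is the spectrum's total residue mass. The
#' returned array has `ceiling(Mres / binWidth)` entries; bin `b` holds the
#' correctness probability of a fragmentation site at prefix mass
#' `b * binWidth`. Bins where no observed peak can be interpreted as any of
#' the nine ion types carry the tree's no-evidence probability.
#'
#' @param spectrum a [Spectrum-class].
#' @param model model list with a trained `fragTree`.
#' @param config a [denovoConfig()].
#' @param pidx optional precomputed [buildPeakIndex()].
#' @param excludeB,excludeY peak indices barred from matching b-like /
#'   y-like ion types (relabeling reruns).
#' @return numeric vector of site probabilities, one per bin.
#' @export
precomputeSiteScores <- function(spectrum, model, config = denovoConfig(),
                                 pidx = NULL, excludeB = integer(),
                                 excludeY = integer()) {
  Mres <- spectrumResidueMass(spectrum)
  if (Mres <= min(.BASE_RESIDUE_MASSES)) {
    stop("precursor too small: neutral mass at or below the smallest residue",
         call. = FALSE)
  }
  bw <- config$binWidth
  B <- as.integer(ceiling(Mres / bw - 1e-9))
  pm <- seq_len(B) * bw
  ## no-evidence baseline: piecewise-constant in the prefix mass
  prof <- .noEvidenceProfile(model$fragTree, neutralMass(spectrum),
                             precursorCharge(spectrum), Mres)
  out <- prof$prob[pmin(pmax(findInterval(pm, prof$lo), 1L),
                        length(prof$prob))]
  ## bins where an observed peak can be read as one of the nine ion types
  ## get the full feature extraction
  if (peakCount(spectrum) > 0L) {
    if (is.null(pidx)) pidx <- buildPeakIndex(spectrum)
    centers <- .invertPeaks(peakMz(spectrum), Mres)
    if (length(centers)) {
      lo <- pmax(1L, as.integer(floor((centers - config$fragTolDa) / bw)))
      hi <- pmin(B, as.integer(ceiling((centers + config$fragTolDa) / bw)))
      active <- logical(B)
      for (i in seq_along(lo)) active[lo[i]:hi[i]] <- TRUE
      act <- which(active)
      if (length(act)) {
        Xa <- .fragSiteMatrix(spectrum, pidx, act * bw, config$fragTolDa,
                              excludeB, excludeY)
        out[act] <- predictTree(model$fragTree, Xa)
      }
    }
  }
  out
}

#' Dynamic-programming search over prefix masses
#'
#' Finds the residue sequences whose cumulative score
#' `sum(p_i - sitePenalty)` over interior fragmentation sites is maximal
#' among sequences whose total residue mass lands within the precursor
#' tolerance of the target. Residue masses are integerized at the bin
#' resolution for the DP transitions; candidates are then filtered by an
#' exact-mass check. Up to `topK` candidates per bin survive; ties are
#' broken lexicographically by sequence for full determinism.
#'
#' @param siteScores per-bin site probabilities from
#'   [precomputeSiteScores()].
#' @param massTable residue mass table (the DP alphabet).
#' @param targetMass total residue mass to reach (Da).
#' @param precTolDa precursor tolerance (Da) for the exact-mass check.
#' @param config a [denovoConfig()].
#' @return list of candidates, each `list(seq =, score =, mass =)`, best
#'   first; empty with attribute `noPath = TRUE` when no sequence reaches
#'   the target.
#' @export
dpSearch <- function(siteScores, massTable, targetMass, precTolDa,
                     config = denovoConfig()) {
  bw <- config$binWidth
  syms <- sort(names(massTable))            # lexicographic tie-break order
  masses <- unname(massTable[syms])
  resBins <- as.integer(round(masses / bw))
  targetBin <- as.integer(round(targetMass / bw))
  maxLen <- ceiling(targetMass / min(masses))
  slack <- as.integer(ceiling(precTolDa / bw) + ceiling(maxLen * 0.5) + 1L)
  raw <- .dpSearchCpp(siteScores - config$sitePenalty, resBins,
                      max(1L, targetBin - slack), targetBin + slack,
                      config$topK)
  if (!length(raw$score)) {
    return(structure(list(), noPath = TRUE))
  }
  seqs <- lapply(raw$seq, function(iv) syms[iv])
  exact <- vapply(seqs, function(s) sum(massTable[s]), numeric(1))
  keep <- abs(exact - targetMass) <= precTolDa
  if (!any(keep)) {
    return(structure(list(), noPath = TRUE))
  }
  seqs <- seqs[keep]
  sc <- raw$score[keep]
  exact <- exact[keep]
  key <- vapply(seqs, paste, character(1), collapse = "")
  o <- order(-sc, key)
  seqs <- seqs[o]; sc <- sc[o]; exact <- exact[o]; key <- key[o]
  first <- !duplicated(key)
  idx <- which(first)[seq_len(min(config$topK, sum(first)))]
  lapply(idx, function(i) list(seq = seqs[[i]], score = sc[i],
                               mass = exact[i]))
}

#' Dynamic-programming stage with artificial b/y relabeling reruns
#'
#' Runs the DP once, detects peaks that support both the y-ion ladder and
#' the b-ion ladder of the best candidate (the typical misinterpretation
#' artifact of prefix-mass scoring), and reruns the DP at most twice with
#' those peaks artificially labeled: once forced to the b series (masked
#' from y-type matching) and once forced to the y series. All candidates
#' are pooled and deduplicated. Total DP invocations never exceed
#' `maxDpRuns`.
#'
#' @param spectrum a [Spectrum-class].
#' @param model model list with a trained `fragTree`.
#' @param config a [denovoConfig()].
#' @param massTable residue mass table.
#' @return list with `candidates` (deduplicated, best first), `dpRuns` and
#'   the peak index `pidx`.
#' @export
relabelAndRerun <- function(spectrum, model, config = denovoConfig(),
                            massTable = residueMassTable()) {
  pidx <- buildPeakIndex(spectrum)
  Mres <- spectrumResidueMass(spectrum)
  tolPrec <- .precTolDa(spectrum, config)
  ss <- precomputeSiteScores(spectrum, model, config, pidx)
  cands <- dpSearch(ss, massTable, Mres, tolPrec, config)
  dpRuns <- 1L
  if (length(cands)) {
    best <- Peptide(cands[[1L]]$seq, massTable)
    n <- peptideLength(best)
    if (n >= 2L) {
      pref <- prefixMasses(best)[seq_len(n - 1L)]
      yIdx <- matchPeak(spectrum, ionMz(pref, Mres, "y"), config$fragTolDa)
      bIdx <- matchPeak(spectrum, ionMz(pref, Mres, "b"), config$fragTolDa)
      overlap <- intersect(yIdx[!is.na(yIdx)], bIdx[!is.na(bIdx)])
      if (length(overlap) && config$maxDpRuns >= 2L) {
        ssB <- precomputeSiteScores(spectrum, model, config, pidx,
                                    excludeY = overlap)
        cands <- c(cands, dpSearch(ssB, massTable, Mres, tolPrec, config))
        dpRuns <- dpRuns + 1L
        if (config$maxDpRuns >= 3L) {
          ssY <- precomputeSiteScores(spectrum, model, config, pidx,
                                      excludeB = overlap)
          cands <- c(cands, dpSearch(ssY, massTable, Mres, tolPrec, config))
          dpRuns <- dpRuns + 1L
        }
      }
    }
  }
  if (length(cands)) {
    key <- vapply(cands, function(c) paste(c$seq, collapse = ""), character(1))
    o <- order(-vapply(cands, `[[`, numeric(1), "score"), key)
    cands <- cands[o][!duplicated(key[o])]
  }
  list(candidates = cands, dpRuns = dpRuns, pidx = pidx)
}

## Residue-score a candidate sequence: per-residue probabilities and the
## mass-weighted aggregate.
.scoreResidues <- function(spectrum, pidx, pep, model, config, massTable) {
  X <- .residueMatrix(spectrum, pidx, pep, config$fragTolDa,
                      massTable = massTable)
  p <- predictTree(model$residueTree, X)
  m <- residueMasses(pep)
  list(probs = p, aggregate = sum(p * m) / sum(m))
}

## Enumerate residue sequences whose total mass lies within tol of mass.
## Stops early once more than cap sequences are found or the search budget
## is exhausted (overflow = TRUE in either case).
.enumerateFillings <- function(mass, tol, massTable, cap = 100L,
                               budget = 20000L) {
  syms <- sort(names(massTable))
  masses <- unname(massTable[syms])
  out <- vector("list", cap + 1L)
  cnt <- 0L
  visits <- 0L
  overflow <- FALSE
  rec <- function(rem, seq) {
    if (overflow) return()
    visits <<- visits + 1L
    if (visits > budget) { overflow <<- TRUE; return() }
    if (rem <= tol) {
      if (rem >= -tol) {
        cnt <<- cnt + 1L
        if (cnt > cap) overflow <<- TRUE else out[[cnt]] <<- seq
      }
      return()  # residue masses exceed 2*tol, no deeper sequence can return
    }
    for (i in seq_along(syms)) {
      if (rem - masses[i] >= -tol) rec(rem - masses[i], c(seq, syms[i]))
    }
  }
  rec(mass, character())
  list(fillings = out[seq_len(min(cnt, cap))], count = cnt,
       overflow = overflow)
}

#' Refine dynamic-programming candidates with the residue score
#'
#' Scores every candidate with the residue-score tree and takes the best.
#' Its highest-probability residues are then fixed greedily (descending
#' probability) until every maximal unfixed segment admits at most
#' `maxSegmentFillings` residue-sequence fillings within the fragment
#' tolerance of the segment mass. Each segment is substituted with every
#' filling, full sequences failing the precursor mass check are discarded,
#' the rest are rescored, and the best sequence is kept. The whole
#' procedure is iterated at most `maxRefineIter` times or until no
#' improvement. The refined score is never below the input candidate's.
#'
#' @param spectrum a [Spectrum-class].
#' @param candidates DP-stage candidates from [relabelAndRerun()].
#' @param model model list with `fragTree` and `residueTree`.
#' @param config a [denovoConfig()].
#' @param pidx optional precomputed peak index.
#' @param massTable residue mass table.
#' @param dpRuns DP invocation count to record in the result.
#' @return a [DeNovoResult-class].
#' @export
refineCandidates <- function(spectrum, candidates, model,
                             config = denovoConfig(), pidx = NULL,
                             massTable = residueMassTable(), dpRuns = NA_integer_) {
  stopifnot(length(candidates) >= 1L)
  if (is.null(pidx)) pidx <- buildPeakIndex(spectrum)
  Mres <- spectrumResidueMass(spectrum)
  tolPrec <- .precTolDa(spectrum, config)
  scored <- lapply(candidates, function(cd) {
    pep <- Peptide(cd$seq, massTable)
    c(list(pep = pep), .scoreResidues(spectrum, pidx, pep, model, config,
                                      massTable))
  })
  aggs <- vapply(scored, `[[`, numeric(1), "aggregate")
  best <- scored[[which.max(aggs)]]
  iter <- 0L
  maxFillSeen <- 0L
  repeat {
    if (iter >= config$maxRefineIter) break
    iter <- iter + 1L
    seqv <- residues(best$pep)
    rmass <- residueMasses(best$pep)
    n <- length(seqv)
    ord <- order(-best$probs, seq_len(n))
    fixed <- rep(FALSE, n)
    segInfo <- function() {
      r <- rle(!fixed)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values
      data.frame(start = starts[keep], end = ends[keep])
    }
    worstFill <- function(segs) {
      if (!nrow(segs)) return(0L)
      max(vapply(seq_len(nrow(segs)), function(i) {
        m <- sum(rmass[segs$start[i]:segs$end[i]])
        e <- .enumerateFillings(m, config$fragTolDa, massTable,
                                config$maxSegmentFillings)
        if (e$overflow) config$maxSegmentFillings + 1L else e$count
      }, integer(1)))
    }
    fi <- 0L
    segs <- segInfo()
    while (worstFill(segs) > config$maxSegmentFillings && fi < n) {
      fi <- fi + 1L
      fixed[ord[fi]] <- TRUE
      segs <- segInfo()
    }
    maxFillSeen <- max(maxFillSeen, worstFill(segs))
    improved <- FALSE
    if (nrow(segs)) {
      variants <- list()
      for (i in seq_len(nrow(segs))) {
        a <- segs$start[i]; b <- segs$end[i]
        m <- sum(rmass[a:b])
        e <- .enumerateFillings(m, config$fragTolDa, massTable,
                                config$maxSegmentFillings)
        cur <- paste(seqv[a:b], collapse = "")
        for (f in e$fillings) {
          if (paste(f, collapse = "") == cur) next
          cand <- c(if (a > 1L) seqv[seq_len(a - 1L)], f,
                    if (b < n) seqv[(b + 1L):n])
          if (abs(sum(massTable[cand]) - Mres) > tolPrec) next
          variants[[length(variants) + 1L]] <- cand
        }
      }
      if (length(variants)) {
        for (v in variants) {
          pep <- Peptide(v, massTable)
          s <- .scoreResidues(spectrum, pidx, pep, model, config, massTable)
          if (s$aggregate > best$aggregate + 1e-12) {
            best <- c(list(pep = pep), s)
            improved <- TRUE
          }
        }
      }
    }
    if (!improved) break
  }
  ## DP-stage score of the final sequence
  n <- peptideLength(best$pep)
  fragScore <- NA_real_
  if (n >= 2L) {
    pref <- prefixMasses(best$pep)[seq_len(n - 1L)]
    Xs <- .fragSiteMatrix(spectrum, pidx, pref, config$fragTolDa)
    fragScore <- sum(predictTree(model$fragTree, Xs) - config$sitePenalty)
  }
  DeNovoResult(best$pep, best$probs, fragScore,
               info = list(dpRuns = dpRuns, refineIterations = iter,
                           maxSegmentFillings = maxFillSeen,
                           nCandidates = length(candidates)))
}

#' De novo sequence one spectrum
#'
#' The full two-stage pipeline: site-score precomputation, dynamic
#' programming with at most `maxDpRuns` relabeling reruns, and residue-score
#' refinement. Unsequenceable spectra (no peaks, precursor too small, or no
#' sequence reaching the precursor mass) give an empty-flagged result, never
#' an error.
#'
#' @param spectrum a [Spectrum-class].
#' @param model trained model list (`fragTree`, `residueTree`).
#' @param config a [denovoConfig()].
#' @param massTable residue mass table.
#' @return a [DeNovoResult-class].
#' @export
denovo <- function(spectrum, model, config = denovoConfig(),
                   massTable = residueMassTable()) {
  if (peakCount(spectrum) == 0L ||
      spectrumResidueMass(spectrum) <= min(massTable)) {
    return(DeNovoResult(info = list(reason = "unsequenceable", dpRuns = 0L)))
  }
  stage <- tryCatch(relabelAndRerun(spectrum, model, config, massTable),
                    error = function(e) NULL)
  if (is.null(stage) || !length(stage$candidates)) {
    return(DeNovoResult(info = list(reason = "no path",
                                    dpRuns = if (is.null(stage)) 0L else
                                      stage$dpRuns)))
  }
  refineCandidates(spectrum, stage$candidates, model, config, stage$pidx,
                   massTable, dpRuns = stage$dpRuns)
}

#' De novo sequence a batch of spectra
#'
#' @param spectra list of [Spectrum-class] objects.
#' @param model trained model list.
#' @param config a [denovoConfig()].
#' @param massTable residue mass table.
#' @return list of [DeNovoResult-class] objects.
#' @export
denovoBatch <- function(spectra, model, config = denovoConfig(),
                        massTable = residueMassTable()) {
  lapply(spectra, denovo, model = model, config = config,
         massTable = massTable)
}
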