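## ---- peak index -----------------------------------------------------------

#' Per-peak significance statistics
#'
#' Precomputes, for every peak of a spectrum, the eight statistics used by
#' the fragment-ion features: relative intensity (fraction of the base
#' peak), rank (number of peaks at least as abundant), half rank (number of
#' peaks at least half as abundant), their local variants restricted to the
#' closed +/- 50 Da m/z window, the local base peak relative intensity, and
#' the charge state / isotope flag when determinable (NA otherwise).
#'
#' A peak is flagged as an isotope when a peak exists `1.00335 / z` below it
#' (z in 1, 2, within 0.02 Da) with intensity between 0.1x and 10x its own;
#' charge 2 is inferred from a matching isotope spacing of 0.50168 above,
#' charge 1 from a spacing of 1.00335.
#'
#' @param spectrum a [Spectrum-class] with at least one peak.
#' @param localWindow half-width of the local window (Da).
#' @return a `PeakIndex`: list of per-peak numeric vectors.
#' @export
buildPeakIndex <- function(spectrum, localWindow = 50) {
  mz <- peakMz(spectrum)
  h <- peakIntensity(spectrum)
  n <- length(mz)
  if (n < 1L) stop("cannot index an empty spectrum", call. = FALSE)
  base <- max(h)
  si <- sort(h)
  cntLess <- function(x) findInterval(x, si, left.open = TRUE)
  rank <- n - cntLess(h)           # peaks with intensity >= h
  halfRank <- n - cntLess(h / 2)   # peaks with intensity >= h/2
  lo <- findInterval(mz - localWindow, mz, left.open = TRUE) + 1L
  hi <- findInterval(mz + localWindow, mz)
  localRank <- integer(n)
  localHalfRank <- integer(n)
  localBaseInt <- numeric(n)
  for (i in seq_len(n)) {
    w <- h[lo[i]:hi[i]]
    localRank[i] <- sum(w >= h[i])
    localHalfRank[i] <- sum(w >= h[i] / 2)
    localBaseInt[i] <- max(w) / base
  }
  chargeState <- rep(NA_real_, n)
  isotope <- rep(NA_real_, n)
  spacingTol <- 0.02
  hasNeighbor <- function(delta, i) {
    a <- findInterval(mz[i] + delta - spacingTol, mz, left.open = TRUE) + 1L
    b <- findInterval(mz[i] + delta + spacingTol, mz)
    if (a > b) return(FALSE)
    any(h[a:b] >= 0.1 * h[i] & h[a:b] <= 10 * h[i])
  }
  for (i in seq_len(n)) {
    below1 <- hasNeighbor(-ISOTOPE_SPACING, i)
    below2 <- hasNeighbor(-ISOTOPE_SPACING / 2, i)
    if (below1 || below2) isotope[i] <- 1
    above2 <- hasNeighbor(ISOTOPE_SPACING / 2, i)
    above1 <- hasNeighbor(ISOTOPE_SPACING, i)
    if (above2 || below2) chargeState[i] <- 2
    else if (above1 || below1) chargeState[i] <- 1
    if (!below1 && !below2 && (above1 || above2)) isotope[i] <- 0
  }
  structure(list(mz = mz, intensity = h, relInt = h / base,
                 rank = as.numeric(rank), halfRank = as.numeric(halfRank),
                 localRank = as.numeric(localRank),
                 localHalfRank = as.numeric(localHalfRank),
                 localBaseInt = localBaseInt,
                 chargeState = chargeState, isotope = isotope,
                 basePeak = base),
            class = "PeakIndex")
}

#' Match a theoretical m/z against a spectrum
#'
#' Returns the index of the matched peak within `+/- tol`, or `NA` when no
#' peak falls in the window. When several peaks fall inside the window the
#' most intense one is chosen (ties: lower m/z).
#'
#' @param spectrum a [Spectrum-class].
#' @param theoreticalMz query m/z values (vectorized).
#' @param tol tolerance (Da), > 0.
#' @return integer vector of peak indices (NA = no match).
#' @export
matchPeak <- function(spectrum, theoreticalMz, tol = 0.5) {
  stopifnot(tol > 0)
  .matchPeaksCpp(peakMz(spectrum), peakIntensity(spectrum),
                 as.numeric(theoreticalMz), tol)
}

## ---- feature layouts ------------------------------------------------------

.PEAK_FEATURE_NAMES <- c("rel_int", "rank", "half_rank", "local_rank",
                         "local_half_rank", "local_base_int", "charge",
                         "isotope")
.SPECTRUM_FEATURE_NAMES <- c("peptide_mass", "precursor_charge",
                             "prefix_mass", "suffix_mass")

#' Feature layout of the fragmentation-site vector
#'
#' 76 features: 4 spectrum features (peptide mass, precursor charge, prefix
#' mass, suffix mass) followed by 8 peak statistics for each of the nine ion
#' types (72 fragment-ion features). Missing peaks are encoded as NA in all
#' eight channels of their ion type.
#'
#' @return list with `names`, `categorical` (integer indices, none here) and
#'   `kind`.
#' @export
fragFeatureLayout <- function() {
  ions <- ionTypes()$name
  nm <- c(.SPECTRUM_FEATURE_NAMES,
          as.vector(t(outer(ions, .PEAK_FEATURE_NAMES, paste, sep = "."))))
  list(names = nm, categorical = integer(), levels = list(), kind = "frag")
}

#' Feature layout of the residue vector
#'
#' 169 features: 4 spectrum features, 72 fragment-ion features for the site
#' left of the residue, 72 for the site at its right, the categorical
#' identities of the left neighbour, the residue, and the right neighbour
#' (terminal positions use the boundary symbol `"."`), 9 residue mass-error
#' features and 9 adjacent-ion log2 intensity-ratio features.
#'
#' @param massTable residue mass table defining the residue alphabet.
#' @return list with `names`, `categorical` indices, `levels` (alphabet) and
#'   `kind`.
#' @export
residueFeatureLayout <- function(massTable = residueMassTable()) {
  ions <- ionTypes()$name
  ionBlock <- as.vector(t(outer(ions, .PEAK_FEATURE_NAMES, paste, sep = ".")))
  nm <- c(.SPECTRUM_FEATURE_NAMES,
          paste0("left.", ionBlock), paste0("right.", ionBlock),
          "residue_left", "residue", "residue_right",
          paste0("mass_err.", ions), paste0("ratio.", ions))
  catIdx <- 4L + 144L + 1:3
  alphabet <- c(".", sort(names(massTable)))
  list(names = nm, categorical = catIdx,
       levels = stats::setNames(rep(list(alphabet), 3), nm[catIdx]),
       kind = "residue")
}

## Sentinel for one-sided adjacent-ion ratios (stands in for +/- infinity;
## beyond any realistic log2 intensity ratio, so threshold splits behave
## identically).
RATIO_SENTINEL <- 32

## ---- fragmentation-site features ------------------------------------------

## Core extractor: one row of 76 features per prefix mass. Also returns the
## matched peak m/z and intensity per ion type (needed by the residue
## features) as attributes. excludeB/excludeY: peak indices barred from
## matching b-like / y-like ion types (used by the relabeling reruns).
.fragSiteMatrix <- function(spectrum, pidx, prefixMass, fragTol = 0.5,
                            excludeB = integer(), excludeY = integer()) {
  it <- ionTypes()
  nP <- length(prefixMass)
  Mres <- spectrumResidueMass(spectrum)
  M <- neutralMass(spectrum)
  z <- precursorCharge(spectrum)
  X <- matrix(NA_real_, nP, 76L)
  X[, 1L] <- M
  X[, 2L] <- z
  X[, 3L] <- prefixMass
  X[, 4L] <- Mres - prefixMass
  matchedMz <- matrix(NA_real_, nP, 9L)
  matchedInt <- matrix(NA_real_, nP, 9L)
  mzAll <- pidx$mz
  intAll <- pidx$intensity
  subsetFor <- function(excl) {
    if (!length(excl)) return(NULL)
    keep <- setdiff(seq_along(mzAll), excl)
    list(keep = keep)
  }
  subB <- subsetFor(excludeB)
  subY <- subsetFor(excludeY)
  for (t in 1:9) {
    theo <- ionMz(prefixMass, Mres, it$name[t])
    sub <- if (it$series[t] == "b") subB else subY
    if (is.null(sub)) {
      idx <- .matchPeaksCpp(mzAll, intAll, theo, fragTol)
    } else {
      idx <- .matchPeaksCpp(mzAll[sub$keep], intAll[sub$keep], theo, fragTol)
      idx <- sub$keep[idx]
    }
    ok <- !is.na(idx)
    cols <- 4L + (t - 1L) * 8L + 1:8
    if (any(ok)) {
      j <- idx[ok]
      X[ok, cols[1L]] <- pidx$relInt[j]
      X[ok, cols[2L]] <- pidx$rank[j]
      X[ok, cols[3L]] <- pidx$halfRank[j]
      X[ok, cols[4L]] <- pidx$localRank[j]
      X[ok, cols[5L]] <- pidx$localHalfRank[j]
      X[ok, cols[6L]] <- pidx$localBaseInt[j]
      X[ok, cols[7L]] <- pidx$chargeState[j]
      X[ok, cols[8L]] <- pidx$isotope[j]
      matchedMz[ok, t] <- mzAll[j]
      matchedInt[ok, t] <- intAll[j]
    }
  }
  attr(X, "matchedMz") <- matchedMz
  attr(X, "matchedInt") <- matchedInt
  X
}

#' Fragmentation-site feature vector (76 features)
#'
#' For each of the nine ion types the theoretical m/z at the given prefix
#' mass is matched against the spectrum; a matched peak contributes its
#' eight precomputed statistics, an unmatched ion type contributes NA in
#' all eight channels. The four spectrum features (peptide mass, precursor
#' charge, prefix mass, suffix mass) are prepended. The suffix mass excludes
#' water, so prefix + suffix equals the total residue mass.
#'
#' @param spectrum a [Spectrum-class].
#' @param pidx [buildPeakIndex()] of the spectrum.
#' @param prefixMass prefix mass (Da), strictly between 0 and the total
#'   residue mass.
#' @param fragTol fragment tolerance (Da).
#' @return numeric vector of length 76 (see [fragFeatureLayout()]).
#' @export
fragSiteFeatures <- function(spectrum, pidx, prefixMass, fragTol = 0.5) {
  Mres <- spectrumResidueMass(spectrum)
  if (any(prefixMass <= 0 | prefixMass >= Mres)) {
    stop("prefix mass must lie strictly between 0 and the total residue mass",
         call. = FALSE)
  }
  X <- .fragSiteMatrix(spectrum, pidx, prefixMass, fragTol)
  if (length(prefixMass) == 1L) {
    stats::setNames(drop(X[1L, , drop = TRUE]), fragFeatureLayout()$names)
  } else {
    colnames(X) <- fragFeatureLayout()$names
    X
  }
}

## ---- residue features -----------------------------------------------------

## Residue feature rows for a whole candidate peptide: n x 169 matrix.
.residueMatrix <- function(spectrum, pidx, peptide, fragTol = 0.5,
                           layout = NULL, massTable = residueMassTable()) {
  if (is.null(layout)) layout <- residueFeatureLayout(massTable)
  n <- peptideLength(peptide)
  res <- residues(peptide)
  rmass <- residueMasses(peptide)
  pref <- prefixMasses(peptide)
  Mres <- spectrumResidueMass(spectrum)
  M <- neutralMass(spectrum)
  z <- precursorCharge(spectrum)
  ## site features for interior sites 1..n-1 (site i = after residue i)
  interior <- if (n >= 2L) pref[seq_len(n - 1L)] else numeric()
  siteX <- if (length(interior))
    .fragSiteMatrix(spectrum, pidx, interior, fragTol) else
    matrix(NA_real_, 0L, 76L)
  mMz <- attr(siteX, "matchedMz")
  mInt <- attr(siteX, "matchedInt")
  naSite <- rep(NA_real_, 72L)
  alphabet <- layout$levels[[1L]]
  code <- function(sym) match(sym, alphabet)
  out <- matrix(NA_real_, n, 169L)
  for (i in seq_len(n)) {
    leftSite <- i - 1L   # 0 = N-terminus
    rightSite <- i       # n = C-terminus
    leftF <- if (leftSite >= 1L) siteX[leftSite, 5:76] else naSite
    rightF <- if (rightSite <= n - 1L) siteX[rightSite, 5:76] else naSite
    xl <- if (i > 1L) res[i - 1L] else "."
    xr <- if (i < n) res[i + 1L] else "."
    ml <- if (leftSite >= 1L) mMz[leftSite, ] else rep(NA_real_, 9L)
    mr <- if (rightSite <= n - 1L) mMz[rightSite, ] else rep(NA_real_, 9L)
    hl <- if (leftSite >= 1L) mInt[leftSite, ] else rep(NA_real_, 9L)
    hr <- if (rightSite <= n - 1L) mInt[rightSite, ] else rep(NA_real_, 9L)
    massErr <- ifelse(is.na(ml) | is.na(mr), 1,
                      abs(abs(mr - ml) - rmass[i]) / fragTol)
    ratio <- ifelse(!is.na(hl) & !is.na(hr), log2(hr / hl),
                    ifelse(!is.na(hr), RATIO_SENTINEL,
                           ifelse(!is.na(hl), -RATIO_SENTINEL, NA_real_)))
    out[i, ] <- c(M, z, if (leftSite >= 1L) pref[leftSite] else 0,
                  Mres - (if (leftSite >= 1L) pref[leftSite] else 0),
                  leftF, rightF, code(xl), code(res[i]), code(xr),
                  massErr, ratio)
  }
  colnames(out) <- layout$names
  out
}

#' Residue feature vector (169 features)
#'
#' Features describing one residue `X` of a candidate sequence in its
#' `Xl X Xr` context: the 4 spectrum features, the 72 fragment-ion features
#' of the fragmentation sites at the left and at the right of `X` (144),
#' the three residue identities (terminal neighbours use the boundary symbol
#' `"."`), the 9 per-ion-type residue mass errors
#' `||mr - ml| - mass(X)| / tol` (1 when either flanking peak is missing),
#' and the 9 adjacent-ion ratios `log2(hr / hl)` (+/-32 when exactly one
#' peak is present, NA when both are missing).
#'
#' @param spectrum a [Spectrum-class].
#' @param pidx [buildPeakIndex()] of the spectrum.
#' @param peptide candidate [Peptide-class].
#' @param which residue index (1..n), or `NULL` for the full n x 169 matrix.
#' @param fragTol fragment tolerance (Da).
#' @param massTable residue mass table (defines the categorical alphabet).
#' @return numeric vector of length 169, or an n x 169 matrix.
#' @export
residueFeatures <- function(spectrum, pidx, peptide, which = NULL,
                            fragTol = 0.5, massTable = residueMassTable()) {
  X <- .residueMatrix(spectrum, pidx, peptide, fragTol,
                      massTable = massTable)
  if (is.null(which)) X else
    stats::setNames(drop(X[which, , drop = TRUE]),
                    residueFeatureLayout(massTable)$names)
}

#' Dump feature vectors to a TSV file (debug aid)
#'
#' @param X feature matrix with column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFeatureTsv <- function(X, path) {
  utils::write.table(as.data.frame(X), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
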