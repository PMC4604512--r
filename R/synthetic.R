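## Simulator of annotated CID-like spectra. Not a physical fragmentation
## model: it reproduces only the statistical regularities the scoring
## functions exploit (y > b intensity hierarchy, residue-dependent site
## intensities, charge-dependent 2+ ions, neutral losses, isotopes, missing
## ions, noise).

## Rough proteome-like residue frequencies (Ile folded into Leu).
.RESIDUE_FREQS <- c(
  L = 0.140, A = 0.080, G = 0.070, S = 0.070, V = 0.070, E = 0.062,
  K = 0.058, T = 0.053, D = 0.053, R = 0.050, P = 0.050, N = 0.043,
  Q = 0.040, F = 0.039, Y = 0.029, H = 0.023, C = 0.020, M = 0.022,
  W = 0.011
)

#' Simulator configuration
#'
#' Defaults emulate tryptic CID spectra: dominant y ladders, weaker b
#' ladders, sparse a/2+/neutral-loss ions, proline enhancing fragmentation
#' at its left and suppressing it at its right (glycine and serine milder),
#' lognormal intensity scatter, m/z jitter, isotope satellites, stochastic
#' missing ions and uniform noise peaks.
#'
#' The lognormal intensity multiplier (`sigma`) is truncated at two
#' standard deviations, so in the noiseless configuration
#' (`missingIonProb = 0`) every y-ion is guaranteed a relative intensity
#' above the 5% verifiability floor.
#'
#' @param lengthRange peptide length range (uniform).
#' @param trypticProb probability that the C-terminal residue is K or R.
#' @param charges,chargeProbs precursor charge states and probabilities.
#' @param ionProb named base emission probabilities per ion type; 2+ ions
#'   require precursor charge >= 2.
#' @param ionScale named intensity scales per ion type (y > b > others).
#' @param leftEnhance named per-residue multiplier applied to the site at
#'   the residue's left (e.g. `P = 2`).
#' @param rightSuppress named per-residue multiplier applied to the site at
#'   the residue's right (e.g. `P = 0.6`).
#' @param missingIonProb probability that an otherwise-emitted ion is
#'   dropped.
#' @param noiseMean mean number of noise peaks (Poisson); intensities are
#'   drawn uniformly below the lower quartile of the signal intensities.
#' @param mzJitterSd m/z jitter standard deviation (Da).
#' @param isotopeProb probability of emitting a +1 isotope satellite
#'   (intensity 0.3x).
#' @param oxidationProb probability that a Met is oxidized.
#' @param sigma lognormal intensity sigma (truncated at +/- 2 sigma).
#' @param residueFreqs residue sampling frequencies.
#' @param seed integer seed; all randomness in [simulateLibrary()] derives
#'   from it.
#' @return list of class `simConfig`.
#' @export
simConfig <- function(lengthRange = c(7L, 12L), trypticProb = 0.95,
                      charges = c(2L, 3L), chargeProbs = c(0.8, 0.2),
                      ionProb = c(y = 1, b = 1, a = 0.25, y2 = 0.45,
                                  b2 = 0.35, `b-18` = 0.2, `b-17` = 0.2,
                                  `y-18` = 0.25, `y-17` = 0.2),
                      ionScale = c(y = 1, b = 0.5, a = 0.15, y2 = 0.3,
                                   b2 = 0.2, `b-18` = 0.12, `b-17` = 0.12,
                                   `y-18` = 0.15, `y-17` = 0.12),
                      leftEnhance = c(P = 2, G = 1.3, S = 1.2),
                      rightSuppress = c(P = 0.6, G = 0.8, S = 0.85),
                      missingIonProb = 0.15, noiseMean = 20,
                      mzJitterSd = 0.008, isotopeProb = 0.5,
                      oxidationProb = 0.15, sigma = 0.4,
                      residueFreqs = .RESIDUE_FREQS, seed = 1L) {
  stopifnot(missingIonProb >= 0, missingIonProb <= 1,
            all(ionProb >= 0), all(ionProb <= 1), all(ionScale > 0),
            abs(sum(chargeProbs) - 1) < 1e-9)
  structure(list(lengthRange = as.integer(lengthRange),
                 trypticProb = trypticProb, charges = as.integer(charges),
                 chargeProbs = chargeProbs, ionProb = ionProb,
                 ionScale = ionScale, leftEnhance = leftEnhance,
                 rightSuppress = rightSuppress,
                 missingIonProb = missingIonProb, noiseMean = noiseMean,
                 mzJitterSd = mzJitterSd, isotopeProb = isotopeProb,
                 oxidationProb = oxidationProb, sigma = sigma,
                 residueFreqs = residueFreqs, seed = as.integer(seed)),
            class = "simConfig")
}

## Lognormal multiplier truncated at +/- 2 sigma.
.lnNoise <- function(n, sigma) {
  exp(pmin(pmax(stats::rnorm(n, 0, sigma), -2 * sigma), 2 * sigma))
}

.samplePeptide <- function(cfg, massTable) {
  n <- sample(cfg$lengthRange[1L]:cfg$lengthRange[2L], 1L)
  syms <- names(cfg$residueFreqs)
  res <- sample(syms, n, replace = TRUE, prob = cfg$residueFreqs)
  if (stats::runif(1) < cfg$trypticProb) {
    res[n] <- sample(c("K", "R"), 1L)
  }
  ox <- res == "M" & stats::runif(length(res)) < cfg$oxidationProb
  res[ox] <- "m"
  Peptide(res, massTable)
}

#' Simulate an annotated spectral library
#'
#' Draws peptides from the residue alphabet, emits fragment ion peaks per
#' site and ion type with the configured probabilities and intensity laws,
#' adds isotope satellites and noise peaks, and records per-site emission
#' bookkeeping. Deterministic given `config$seed`.
#'
#' @param config a [simConfig()].
#' @param nSpectra number of spectra to generate.
#' @param massTable residue mass table.
#' @return list of records `list(peptide =, spectrum =, ions =)` where
#'   `ions` is the per-site emission bookkeeping data.frame.
#' @export
simulateLibrary <- function(config, nSpectra,
                            massTable = residueMassTable()) {
  set.seed(config$seed)
  it <- ionTypes()
  out <- vector("list", nSpectra)
  for (k in seq_len(nSpectra)) {
    pep <- .samplePeptide(config, massTable)
    n <- peptideLength(pep)
    z <- sample(config$charges, 1L, prob = config$chargeProbs)
    Mres <- totalResidueMass(pep)
    pref <- prefixMasses(pep)[seq_len(n - 1L)]
    res <- residues(pep)
    siteMod <- rep(1, n - 1L)
    for (i in seq_len(n - 1L)) {
      le <- config$leftEnhance[res[i + 1L]]
      rs <- config$rightSuppress[res[i]]
      if (!is.na(le)) siteMod[i] <- siteMod[i] * le
      if (!is.na(rs)) siteMod[i] <- siteMod[i] * rs
    }
    nIon <- nrow(it)
    book <- data.frame(
      site = rep(seq_len(n - 1L), each = nIon),
      ion = rep(it$name, n - 1L),
      emitted = FALSE, mz = NA_real_, intensity = NA_real_,
      stringsAsFactors = FALSE)
    mzs <- numeric(0)
    ints <- numeric(0)
    row <- 0L
    for (i in seq_len(n - 1L)) {
      for (t in seq_len(nIon)) {
        row <- row + 1L
        if (it$charge[t] > 1L && z < 2L) next
        p <- config$ionProb[[it$name[t]]] * (1 - config$missingIonProb)
        if (stats::runif(1) >= p) next
        theo <- ionMz(pref[i], Mres, it$name[t])
        h <- config$ionScale[[it$name[t]]] * siteMod[i] *
          .lnNoise(1L, config$sigma)
        m <- theo + stats::rnorm(1L, 0, config$mzJitterSd)
        book$emitted[row] <- TRUE
        book$mz[row] <- m
        book$intensity[row] <- h
        mzs <- c(mzs, m)
        ints <- c(ints, h)
        if (stats::runif(1) < config$isotopeProb) {
          mzs <- c(mzs, m + ISOTOPE_SPACING / it$charge[t])
          ints <- c(ints, 0.3 * h)
        }
      }
    }
    nNoise <- if (config$noiseMean > 0) stats::rpois(1L, config$noiseMean)
      else 0L
    if (nNoise > 0L && length(ints)) {
      noiseCap <- stats::quantile(ints, 0.25, names = FALSE)
      mzs <- c(mzs, stats::runif(nNoise, 50, Mres + WATER_MASS))
      ints <- c(ints, stats::runif(nNoise, 0, noiseCap))
    }
    sp <- Spectrum(mzs, ints,
                   (Mres + WATER_MASS + z * PROTON_MASS) / z, z,
                   sprintf("sim_%05d", k))
    out[[k]] <- list(peptide = pep, spectrum = sp, ions = book)
  }
  out
}

#' Simulate a training library spanning spectrum-quality regimes
#'
#' Annotated spectral libraries mix consensus spectra of very different
#' quality: some entries are averaged over many replicates and nearly
#' noise-free, others keep missing ions, m/z scatter and chemical noise.
#' A scoring model trained on a single noise condition mis-calibrates on
#' spectra outside it, so the default training library drawn here spans
#' three regimes in equal parts: the default noisy configuration, an
#' intermediate one (5% missing ions, ~8 noise peaks, 0.004 Da jitter),
#' and a clean noiseless one. Records are shuffled; everything derives
#' deterministically from `baseSeed`.
#'
#' @param nSpectra total number of spectra.
#' @param baseSeed integer seed (a few consecutive seeds are consumed).
#' @param massTable residue mass table.
#' @return shuffled list of simulated records (see [simulateLibrary()]).
#' @export
simulateMixedLibrary <- function(nSpectra, baseSeed = 1L,
                                 massTable = residueMassTable()) {
  cfgs <- list(
    simConfig(seed = baseSeed),
    simConfig(missingIonProb = 0.05, noiseMean = 8, mzJitterSd = 0.004,
              seed = baseSeed + 1L),
    simConfig(missingIonProb = 0, noiseMean = 0, mzJitterSd = 0,
              isotopeProb = 0, seed = baseSeed + 2L))
  ns <- diff(round(seq(0, nSpectra, length.out = 4L)))
  recs <- list()
  for (i in 1:3) recs <- c(recs, simulateLibrary(cfgs[[i]], ns[i], massTable))
  set.seed(baseSeed + 3L)
  recs[sample.int(length(recs))]
}

#' Shuffle and split records into train / development / reserved parts
#'
#' @param records list of records.
#' @param fractions three fractions summing to 1 (default 80/10/10).
#' @param seed integer seed for the shuffle.
#' @return list with elements `train`, `dev`, `reserved`; disjoint and
#'   exhaustive.
#' @export
makeSplits <- function(records, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be three non-negative numbers summing to 1",
         call. = FALSE)
  }
  n <- length(records)
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- diff(c(0L, round(cumsum(fractions) * n)))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  part <- function(i) if (sizes[i] > 0L)
    records[perm[starts[i]:ends[i]]] else list()
  list(train = part(1L), dev = part(2L), reserved = part(3L))
}

#' Write a simulated library to disk
#'
#' Writes the spectra as MGF, the annotated pairs as NIST MSP (so the
#' training path exercises the MSP reader), and the ground truth as a TSV
#' with columns `spectrum_id`, `peptide`, `charge`.
#'
#' @param records simulated records from [simulateLibrary()].
#' @param dir output directory (created if needed).
#' @param name basename for the three files.
#' @return named character vector of the written paths, invisibly.
#' @export
writeLibrary <- function(records, dir, name = "library") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mgf <- file.path(dir, paste0(name, ".mgf"))
  msp <- file.path(dir, paste0(name, ".msp"))
  tsv <- file.path(dir, paste0(name, "_truth.tsv"))
  writeMgf(lapply(records, `[[`, "spectrum"), mgf)
  writeMsp(records, msp)
  df <- data.frame(
    spectrum_id = vapply(records, function(r) spectrumId(r$spectrum),
                         character(1)),
    peptide = vapply(records, function(r)
      paste(sub("^m$", "M(O)", residues(r$peptide)), collapse = ""),
      character(1)),
    charge = vapply(records, function(r)
      precursorCharge(r$spectrum), integer(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(mgf = mgf, msp = msp, truth = tsv))
}
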