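## Shared fixtures: deterministic spectra built from peptides, and lazily
## trained models cached for the whole test run.

.fixtureCache <- new.env(parent = emptyenv())

PROTON <- 1.007276
WATER <- 18.010565

cachedFixture <- function(name, build) {
  if (!exists(name, .fixtureCache)) assign(name, build(), .fixtureCache)
  get(name, .fixtureCache)
}

## Exact-mass spectrum of a peptide: the requested ion types at every
## interior site, fixed intensities, no noise.
spectrumFromPeptide <- function(pep, ions = c("y", "b"),
                                intensity = c(y = 100, b = 50),
                                charge = 2L, extraMz = numeric(),
                                extraInt = numeric(), id = "fix") {
  n <- peptideLength(pep)
  Mres <- totalResidueMass(pep)
  mzs <- extraMz
  ints <- extraInt
  if (n >= 2L) {
    for (ion in ions) {
      for (s in seq_len(n - 1L)) {
        mzs <- c(mzs, fragmentMz(pep, s, ion))
        ints <- c(ints, unname(intensity[ion]))
      }
    }
  }
  Spectrum(mzs, ints, (Mres + WATER + charge * PROTON) / charge,
           charge, id)
}

cleanSimConfig <- function(...) {
  simConfig(missingIonProb = 0, noiseMean = 0, mzJitterSd = 0,
            isotopeProb = 0, ...)
}

## Small model for engine unit tests: quick to train, good enough to rank
## true sites above decoys.
tinyModel <- function() {
  cachedFixture("tinyModel", function() {
    recs <- simulateLibrary(simConfig(seed = 401L), 250)
    fe <- makeFragExamples(recs, seed = 402L)
    ft <- trainTree(fe$X, fe$y, fragFeatureLayout(), treeConfig())
    model <- list(fragTree = ft)
    re <- makeResidueExamples(recs[1:60], model)
    model$residueTree <- trainTree(re$X, re$y, residueFeatureLayout(),
                                   treeConfig())
    model
  })
}

## Reference model at the study scale: fragmentation tree trained on 5000
## simulated spectra spanning quality regimes, residue tree on DP
## candidates from 1000 of them.
refModel <- function() {
  cachedFixture("refModel", function() {
    trainModel(simulateMixedLibrary(5000, baseSeed = 501L), seed = 502L)
  })
}
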