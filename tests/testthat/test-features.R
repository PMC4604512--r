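## Brute-force oracle for the per-peak statistics, straight from their
## definitions on the raw peak list.
bruteIndex <- function(mz, h, w = 50) {
  n <- length(mz)
  base <- max(h)
  list(
    relInt = h / base,
    rank = vapply(seq_len(n), function(i) sum(h >= h[i]), numeric(1)),
    halfRank = vapply(seq_len(n), function(i) sum(h >= h[i] / 2), numeric(1)),
    localRank = vapply(seq_len(n), function(i) {
      win <- abs(mz - mz[i]) <= w
      sum(h[win] >= h[i])
    }, numeric(1)),
    localHalfRank = vapply(seq_len(n), function(i) {
      win <- abs(mz - mz[i]) <= w
      sum(h[win] >= h[i] / 2)
    }, numeric(1)),
    localBaseInt = vapply(seq_len(n), function(i)
      max(h[abs(mz - mz[i]) <= w]) / base, numeric(1)))
}

test_that("peak rank statistics equal brute-force counts on random spectra", {
  set.seed(71)
  for (i in 1:1000) {
    n <- sample(2:40, 1)
    mz <- sort(runif(n, 100, 1500))
    h <- round(runif(n, 1, 1000))   # ties likely
    sp <- Spectrum(mz, h, 600, 2L, "r")
    idx <- buildPeakIndex(sp)
    oracle <- bruteIndex(mz, h)
    expect_equal(idx$relInt, oracle$relInt)
    expect_equal(idx$rank, oracle$rank)
    expect_equal(idx$halfRank, oracle$halfRank)
    expect_equal(idx$localRank, oracle$localRank)
    expect_equal(idx$localHalfRank, oracle$localHalfRank)
    expect_equal(idx$localBaseInt, oracle$localBaseInt)
  }
})

test_that("rank statistics on the documented four-peak example", {
  sp <- Spectrum(c(100, 200, 300, 400), c(100, 50, 50, 10), 500, 2L, "ex")
  idx <- buildPeakIndex(sp)
  expect_equal(idx$rank[1], 1)          # base peak
  expect_equal(idx$relInt[1], 1.0)
  expect_equal(idx$rank[2], 3)          # three peaks >= 50
  expect_equal(idx$halfRank[1], 3)      # peaks >= 50: 100, 50, 50
  expect_error(buildPeakIndex(Spectrum(numeric(), numeric(), 500, 2L)),
               "empty spectrum")
})

test_that("peak matching respects the window and the intensity tie-break", {
  sp <- Spectrum(c(99.8, 100.3, 201.0), c(5, 50, 10), 500, 2L, "m")
  expect_identical(matchPeak(sp, 100.0, 0.5), 2L)    # more intense wins
  expect_identical(matchPeak(sp, 100.30, 0.5), 2L)
  expect_true(is.na(matchPeak(sp, 200.0, 0.5)))      # nearest peak 1.0 away
  expect_identical(matchPeak(sp, c(100, 201.2), 0.5), c(2L, 3L))
  expect_error(matchPeak(sp, 100, 0), "tol > 0")
})

test_that("fragmentation-site features have the documented layout", {
  lay <- fragFeatureLayout()
  expect_length(lay$names, 76L)
  tab <- residueMassTable()
  pep <- Peptide(c("A", "G", "K"), tab)
  sp <- spectrumFromPeptide(pep, intensity = c(y = 100, b = 40))
  pidx <- buildPeakIndex(sp)
  f <- fragSiteFeatures(sp, pidx, prefixMasses(pep)[1])
  expect_length(f, 76L)
  expect_equal(unname(f["prefix_mass"] + f["suffix_mass"]),
               totalResidueMass(pep), tolerance = 1e-9)
  expect_equal(unname(f["peptide_mass"]), peptideMass(pep), tolerance = 1e-4)
  expect_equal(unname(f["y.rel_int"]), 1.0)       # y is the base peak here
  expect_equal(unname(f["b.rel_int"]), 0.4)
  expect_true(is.na(f["a.rel_int"]))              # no a-ion in the fixture
  ## pure function: identical inputs give identical vectors
  expect_identical(f, fragSiteFeatures(sp, pidx, prefixMasses(pep)[1]))
  expect_error(fragSiteFeatures(sp, pidx, 0), "strictly between")
  expect_error(fragSiteFeatures(sp, pidx, totalResidueMass(pep)),
               "strictly between")
})

test_that("a site with no matching peaks is missing-encoded in all channels", {
  sp <- Spectrum(c(1500, 1600), c(10, 20), 900, 2L, "far")
  pidx <- buildPeakIndex(sp)
  f <- fragSiteFeatures(sp, pidx, 300)
  expect_true(all(is.na(f[5:76])))
  expect_false(anyNA(f[1:4]))
})

test_that("residue features encode mass errors, ratios and identities", {
  lay <- residueFeatureLayout()
  expect_length(lay$names, 169L)
  tab <- residueMassTable()
  pep <- Peptide(c("A", "G", "K"), tab)
  ## y-only fixture: left y of G at intensity 50, right y at 100
  n <- peptideLength(pep)
  yMz <- vapply(1:2, function(s) fragmentMz(pep, s, "y"), numeric(1))
  ## left site of residue 2 is site 1 -> its y is yMz[1]; right site is 2
  sp <- Spectrum(yMz, c(100, 50), precursorMz(spectrumFromPeptide(pep)), 2L)
  ## (site 1 y has intensity 100? order: sorted by mz; y1 < y2 in mz)
  ## set intensities explicitly by mz: y at site1 = y2-ion mass of suffix GK
  spl <- Spectrum(sort(yMz), c(50, 100)[order(yMz)],
                  precursorMz(spectrumFromPeptide(pep)), 2L)
  pidx <- buildPeakIndex(spl)
  f <- residueFeatures(spl, pidx, pep, which = 2L)
  expect_length(f, 169L)
  ## |mr - ml| = y(site1) - y(site2) difference = mass(G) exactly -> error 0
  expect_equal(unname(f["mass_err.y"]), 0, tolerance = 1e-9)
  ## hl (left site y) = 50, hr = 100 -> log2(100/50) = 1... left site of
  ## residue 2 is site 1. y at site 1 has the larger m/z (suffix GK).
  hl <- peakIntensity(spl)[matchPeak(spl, fragmentMz(pep, 1, "y"), 0.5)]
  hr <- peakIntensity(spl)[matchPeak(spl, fragmentMz(pep, 2, "y"), 0.5)]
  expect_equal(unname(f["ratio.y"]), log2(hr / hl))
  ## no b peaks at all: b ratio missing, b mass error = 1
  expect_true(is.na(f["ratio.b"]))
  expect_equal(unname(f["mass_err.b"]), 1)
  ## identities: Xl = A, X = G, Xr = K
  alpha <- lay$levels[[1]]
  expect_identical(alpha[f["residue_left"]], "A")
  expect_identical(alpha[f["residue"]], "G")
  expect_identical(alpha[f["residue_right"]], "K")
  ## terminal residue: boundary symbol and one-sided sentinel
  f1 <- residueFeatures(spl, pidx, pep, which = 1L)
  expect_identical(alpha[f1["residue_left"]], ".")
  expect_equal(unname(f1["ratio.y"]), 32)   # left peak absent -> +sentinel
  f3 <- residueFeatures(spl, pidx, pep, which = 3L)
  expect_identical(alpha[f3["residue_right"]], ".")
  expect_equal(unname(f3["ratio.y"]), -32)  # right peak absent -> -sentinel
})

test_that("intensity ratio uses log2(hr/hl) when both flanking peaks exist", {
  tab <- residueMassTable()
  pep <- Peptide(c("L", "P", "K"), tab)
  yMz <- vapply(1:2, function(s) fragmentMz(pep, s, "y"), numeric(1))
  sp <- Spectrum(sort(yMz), c(10, 10)[order(yMz)] * c(5, 10)[order(yMz)],
                 precursorMz(spectrumFromPeptide(pep)), 2L)
  pidx <- buildPeakIndex(sp)
  f <- residueFeatures(sp, pidx, pep, which = 2L)
  hl <- peakIntensity(sp)[matchPeak(sp, yMz[1], 0.5)]
  hr <- peakIntensity(sp)[matchPeak(sp, yMz[2], 0.5)]
  expect_equal(unname(f["ratio.y"]), log2(hr / hl))
})
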