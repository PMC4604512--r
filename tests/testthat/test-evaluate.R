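test_that("residue matching uses mass and prefix-position conditions", {
  tab <- residueMassTable()
  agk <- Peptide(c("A", "G", "K"), tab)
  expect_true(all(matchResidues(agk, agk)))            # identity
  ## K vs Q: |128.09496 - 128.05858| = 0.036 <= 0.1 -> matched
  k <- Peptide("K", tab)
  q <- Peptide("Q", tab)
  expect_true(all(matchResidues(k, q)))
  ## oxidized Met vs Phe are mass-equivalent at 0.1 Da
  expect_true(all(matchResidues(Peptide("m", tab), Peptide("F", tab))))
  ## AG vs GA: residue masses swap positions by 14.016 Da > 0.5 -> no match
  expect_false(any(matchResidues(Peptide(c("A", "G"), tab),
                                 Peptide(c("G", "A"), tab))))
  ## each de novo residue consumed at most once
  gg <- Peptide(c("G", "G"), tab)
  g <- Peptide("G", tab)
  flags <- matchResidues(gg, g)
  expect_identical(sum(flags), 1L)
  ## a candidate with two swapped interior residues loses exactly those two
  truth <- Peptide(c("L", "A", "G", "K"), tab)
  swap <- Peptide(c("L", "G", "A", "K"), tab)
  expect_identical(as.logical(matchResidues(truth, swap)),
                   c(TRUE, FALSE, FALSE, TRUE))
})

test_that("precision-recall curves follow their definitions", {
  tab <- residueMassTable()
  pep <- Peptide(c("A", "G", "K"), tab)
  perfect <- matchReport(pep, DeNovoResult(pep, c(0.999, 0.999, 0.999), 1))
  pr <- prCurve(list(perfect))
  expect_true(all(pr$recall == 1))
  expect_true(all(pr$precision == 1))
  ## threshold 0 applies no filtration: maximum recall
  mixed <- matchReport(pep, DeNovoResult(Peptide(c("A", "G", "R"), tab),
                                         c(0.9, 0.6, 0.4), 1))
  pr2 <- prCurve(list(mixed))
  expect_equal(pr2$recall[pr2$t == 0], 2 / 3)
  expect_equal(pr2$precision[pr2$t == 0], 2 / 3)
  expect_equal(pr2$recall[pr2$t == 70], 1 / 3)   # only the 0.9 survives
  expect_equal(pr2$precision[pr2$t == 70], 1)
  ## monotone non-increasing in t, bounded in [0, 1]
  expect_true(all(diff(pr2$recall) <= 0))
  expect_true(all(pr2$recall >= 0 & pr2$recall <= 1))
  ok <- !is.na(pr2$precision)
  expect_true(all(pr2$precision[ok] >= 0 & pr2$precision[ok] <= 1))
  ## precision undefined when nothing passes the threshold
  expect_true(all(is.na(pr2$precision[pr2$t > 90])))
  ## doubling N with all-unmatched padding halves recall, precision intact
  pad <- structure(list(N = 3, denovoScores = integer(),
                        matchedScores = integer(), matched = rep(FALSE, 3)),
                   class = "MatchReport")
  pr3 <- prCurve(list(mixed, pad))
  expect_equal(pr3$recall, pr2$recall / 2)
  expect_equal(pr3$precision, pr2$precision)
  expect_error(prCurve(list(structure(list(N = 0, denovoScores = integer(),
                                           matchedScores = integer()),
                                      class = "MatchReport"))), "N = 0")
})

test_that("verifiable residues require abundant flanking ions, termini free", {
  tab <- residueMassTable()
  ## single-residue peptide: both flanks are termini -> always verifiable
  one <- list(spectrum = Spectrum(500, 1, (128.09496 + WATER +
                                             2 * PROTON) / 2, 2L),
              peptide = Peptide("K", tab))
  expect_equal(verifiableFraction(list(one)), 1)
  ## 2-mer: single interior site; y-ion at exactly 5% of base counts
  pep <- Peptide(c("A", "K"), tab)
  y1 <- fragmentMz(pep, 1, "y")
  mkrec <- function(h) list(
    spectrum = Spectrum(c(300, y1), c(100, h),
                        (totalResidueMass(pep) + WATER + 2 * PROTON) / 2, 2L),
    peptide = pep)
  expect_equal(verifiableFraction(list(mkrec(5))), 1)      # boundary >= 5%
  expect_equal(verifiableFraction(list(mkrec(4.99))), 0)
  ## spectrum stripped of b/y/2+ ions: no interior site verifiable
  far <- list(spectrum = Spectrum(c(1900, 1950), c(10, 100),
                                  (totalResidueMass(pep) + WATER +
                                     2 * PROTON) / 2, 2L),
              peptide = pep)
  expect_equal(verifiableFraction(list(far, one)), 1 / 3)
})

test_that("dipeptide gap census counts correct and reversed orders", {
  tab <- residueMassTable()
  pep <- Peptide(c("A", "L", "D", "K"), tab)   # gap dipeptide L-D
  n <- peptideLength(pep)
  pref <- prefixMasses(pep)
  Mres <- totalResidueMass(pep)
  pmz <- (Mres + WATER + 2 * PROTON) / 2
  ## ions only at sites 1 and 3; site 2 dark under both orderings
  mzs <- c(ionMz(pref[c(1, 3)], Mres, "y"), ionMz(pref[c(1, 3)], Mres, "b"))
  sp <- Spectrum(mzs, rep(100, 4), pmz, 2L, "gap")
  rec <- list(spectrum = sp, peptide = pep)
  mkres <- function(p) DeNovoResult(p, rep(0.9, peptideLength(p)), 1)
  ## de novo reproduces the true order
  cen <- dipeptideGapCensus(list(rec), list(mkres(pep)))
  expect_identical(cen$dipeptide, "LD")
  expect_identical(cen$correct, 1L)
  expect_identical(cen$reversed, 0L)
  ## de novo reverses the dipeptide
  revp <- Peptide(c("A", "D", "L", "K"), tab)
  cen2 <- dipeptideGapCensus(list(rec), list(mkres(revp)))
  expect_identical(cen2$reversed, 1L)
  expect_identical(cen2$correct, 0L)
  ## neither order: no counter moves
  oth <- Peptide(c("A", "W", "S", "K"), tab)   # W+S ~ L+D mass region
  cen3 <- dipeptideGapCensus(list(rec), list(mkres(oth)))
  expect_true(nrow(cen3) == 0L ||
                (sum(cen3$correct) + sum(cen3$reversed)) == 0L)
  ## a middle-site ion disqualifies the gap
  sp2 <- Spectrum(c(mzs, ionMz(pref[2], Mres, "y")), rep(100, 5), pmz, 2L)
  cen4 <- dipeptideGapCensus(list(list(spectrum = sp2, peptide = pep)),
                             list(mkres(pep)))
  expect_identical(nrow(cen4), 0L)
  ## symmetric dipeptide counts as correct
  gg <- Peptide(c("A", "G", "G", "K"), tab)
  prefg <- prefixMasses(gg)
  Mg <- totalResidueMass(gg)
  ## y-only flank evidence (the b3 ion would collide with the y-18 of the
  ## middle site within 0.5 Da and disqualify the gap)
  spg <- Spectrum(ionMz(prefg[c(1, 3)], Mg, "y"), rep(100, 2),
                  (Mg + WATER + 2 * PROTON) / 2, 2L)
  ceng <- dipeptideGapCensus(list(list(spectrum = spg, peptide = gg)),
                             list(mkres(gg)))
  expect_identical(ceng$dipeptide, "GG")
  expect_identical(ceng$correct, 1L)
})

test_that("redundancy removal keeps the best PSM per peptide and charge", {
  df <- data.frame(peptide = c("AGK", "AGK", "AGK", "LLK"),
                   charge = c(2L, 2L, 3L, 2L),
                   score = c(10, 30, 20, 5),
                   spectrum_id = c("a", "b", "c", "d"))
  out <- removeRedundant(df)
  expect_identical(nrow(out), 3L)
  expect_identical(out$spectrum_id[out$peptide == "AGK" & out$charge == 2L],
                   "b")
})
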