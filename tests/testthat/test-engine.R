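test_that("site-score array has one entry per bin and a constant no-evidence value", {
  model <- tinyModel()
  cfg <- denovoConfig()
  tab <- residueMassTable()
  pep <- Peptide(c("A", "G", "K"), tab)
  Mres <- totalResidueMass(pep)
  empty <- Spectrum(numeric(), numeric(),
                    (Mres + WATER + 2 * PROTON) / 2, 2L, "empty")
  ss <- precomputeSiteScores(empty, model, cfg)
  expect_length(ss, ceiling(Mres / cfg$binWidth))
  expect_true(all(ss > 0 & ss < 1))
  ## zero peaks: every bin carries the tree's no-evidence probability,
  ## i.e. exactly what the tree predicts for an all-missing ion vector
  probe <- sample(length(ss), 25)
  Xp <- cbind(neutralMass(empty), 2, probe * cfg$binWidth,
              Mres - probe * cfg$binWidth,
              matrix(NA_real_, length(probe), 72))
  expect_identical(ss[probe], predictTree(model$fragTree, Xp))
  ## and that probability is low: missing evidence must not look like a site
  expect_true(all(ss < 0.5))
  ## a clean AGK spectrum scores the true sites at local maxima
  sp <- spectrumFromPeptide(pep)
  ss2 <- precomputeSiteScores(sp, model, cfg)
  bins <- round(prefixMasses(pep)[1:2] / cfg$binWidth)
  for (b in bins) {
    away <- c(b - 300, b + 300)
    away <- away[away >= 1 & away <= length(ss2)]
    expect_gt(ss2[b], max(ss2[away]))
  }
  tiny <- Spectrum(100, 10, (30 + 2 * PROTON) / 2, 2L, "tiny")
  expect_error(precomputeSiteScores(tiny, model, cfg), "precursor too small")
})

test_that("toy dynamic programs pick the evidence-supported ordering", {
  cfg <- denovoConfig()
  tab <- residueMassTable()[c("G", "A")]
  target <- sum(tab)                       # mass of GA / AG
  B <- ceiling(target / cfg$binWidth)
  ss <- rep(0.05, B)
  ss[round(tab["G"] / cfg$binWidth)] <- 0.9   # site after leading G
  ss[round(tab["A"] / cfg$binWidth)] <- 0.2   # site after leading A
  cands <- dpSearch(ss, tab, target, 0.02, cfg)
  expect_identical(paste(cands[[1]]$seq, collapse = ""), "GA")
  expect_equal(cands[[1]]$score, 0.9 - 0.1, tolerance = 1e-9)
  ## single-residue alphabet: forced path and its score
  tabG <- residueMassTable()["G"]
  target3 <- 3 * tabG
  B3 <- ceiling(target3 / cfg$binWidth)
  ss3 <- rep(0.3, B3)
  c3 <- dpSearch(ss3, tabG, target3, 0.02, cfg)
  expect_identical(paste(c3[[1]]$seq, collapse = ""), "GGG")
  expect_equal(c3[[1]]$score, 2 * (0.3 - 0.1), tolerance = 1e-9)
  ## unreachable target is flagged, not an error
  none <- dpSearch(ss3, tabG, target3 + 20, 0.02, cfg)
  expect_length(none, 0L)
  expect_true(attr(none, "noPath"))
})

test_that("DP equals exhaustive enumeration on random score arrays", {
  cfg <- denovoConfig()
  set.seed(101)
  tab <- residueMassTable()[c("G", "A", "S")]
  resBins <- as.integer(round(tab / cfg$binWidth))
  for (i in 1:10) {
    target <- runif(1, 250, 500)
    B <- ceiling(target / cfg$binWidth)
    ss <- rep(0.02, B)
    ss[sample(B, 60)] <- runif(60, 0, 1)
    cands <- dpSearch(ss, tab, target, 0.5, cfg)
    oracle <- bruteBest(ss, tab, cfg$binWidth, cfg$sitePenalty, target, 0.5)
    if (!length(cands)) {
      expect_identical(oracle, -Inf)
    } else {
      expect_equal(cands[[1]]$score, oracle, tolerance = 1e-9)
    }
  }
})

test_that("relabeling reruns are bounded and deduplicated", {
  model <- tinyModel()
  cfg <- denovoConfig()
  recs <- simulateLibrary(simConfig(seed = 103L), 6)
  for (r in recs) {
    st <- relabelAndRerun(r$spectrum, model, cfg)
    expect_lte(st$dpRuns, 3L)
    expect_lte(length(st$candidates), 3L * cfg$topK)
    key <- vapply(st$candidates, function(c) paste(c$seq, collapse = ""),
                  character(1))
    expect_identical(anyDuplicated(key), 0L)
  }
  ## forced overlap: add a peak matching both a y and a b of the candidate
  rec <- recs[[1]]
  st1 <- relabelAndRerun(rec$spectrum, model, cfg)
  best <- Peptide(st1$candidates[[1]]$seq)
  Mres <- totalResidueMass(best)
  pref <- prefixMasses(best)[seq_len(peptideLength(best) - 1L)]
  yv <- ionMz(pref, Mres, "y")
  bv <- ionMz(pref, Mres, "b")
  pairs <- which(abs(outer(yv, bv, "-")) < 0.9, arr.ind = TRUE)
  if (!nrow(pairs)) {
    ## no y/b pair close enough on this candidate: plant one explicitly by
    ## putting a strong peak midway between the nearest y and b ions
    pairs <- which(abs(outer(yv, bv, "-")) ==
                     min(abs(outer(yv, bv, "-"))), arr.ind = TRUE)
  }
  pair <- pairs[1, ]
  mid <- (yv[pair[1]] + bv[pair[2]]) / 2
  sp2 <- Spectrum(c(peakMz(rec$spectrum), mid),
                  c(peakIntensity(rec$spectrum),
                    max(peakIntensity(rec$spectrum))),
                  precursorMz(rec$spectrum), precursorCharge(rec$spectrum))
  st2 <- relabelAndRerun(sp2, model, cfg)
  expect_lte(st2$dpRuns, 3L)
})

test_that("segment fillings enumerate mass-compatible sequences under the cap", {
  tab <- residueMassTable()
  e <- treeDenovo:::.enumerateFillings(128.059, 0.5, tab, cap = 100L)
  seqs <- vapply(e$fillings, paste, character(1), collapse = "")
  expect_true(all(c("Q", "K", "AG", "GA") %in% seqs))
  expect_false(e$overflow)
  expect_lte(e$count, 100L)
  ## every filling lands within tolerance
  masses <- vapply(e$fillings, function(f) sum(tab[f]), numeric(1))
  expect_true(all(abs(masses - 128.059) <= 0.5))
  ## a large gap overflows the cap
  big <- treeDenovo:::.enumerateFillings(800, 0.5, tab, cap = 100L)
  expect_true(big$overflow)
})

test_that("refinement is monotone and the pipeline respects its bounds", {
  model <- tinyModel()
  cfg <- denovoConfig()
  recs <- simulateLibrary(simConfig(seed = 104L), 8)
  for (r in recs) {
    st <- relabelAndRerun(r$spectrum, model, cfg)
    if (!length(st$candidates)) next
    inAgg <- max(vapply(st$candidates, function(cd) {
      pep <- Peptide(cd$seq)
      treeDenovo:::.scoreResidues(r$spectrum, st$pidx, pep, model, cfg,
                                  residueMassTable())$aggregate
    }, numeric(1)))
    res <- refineCandidates(r$spectrum, st$candidates, model, cfg, st$pidx,
                            dpRuns = st$dpRuns)
    expect_gte(aggregateScore(res), inAgg - 1e-12)
    info <- resultInfo(res)
    expect_lte(info$dpRuns, 3L)
    expect_lte(info$refineIterations, 3L)
    expect_lte(info$maxSegmentFillings, 100L)
    ## output peptide mass within precursor tolerance, always
    expect_lte(abs(peptideMass(resultPeptide(res)) -
                     neutralMass(r$spectrum)),
               cfg$precTolPpm * 1e-6 * neutralMass(r$spectrum) + 1e-9)
    expect_true(all(residueProbs(res) > 0 & residueProbs(res) < 1))
    expect_identical(residueScores(res),
                     as.integer(round(100 * residueProbs(res))))
  }
})

test_that("denovo is deterministic and degrades gracefully", {
  model <- tinyModel()
  cfg <- denovoConfig()
  recs <- simulateLibrary(simConfig(seed = 105L), 5)
  res1 <- denovoBatch(lapply(recs, `[[`, "spectrum"), model, cfg)
  res2 <- denovoBatch(lapply(recs, `[[`, "spectrum"), model, cfg)
  for (i in seq_along(res1)) {
    expect_identical(isEmptyResult(res1[[i]]), isEmptyResult(res2[[i]]))
    if (!isEmptyResult(res1[[i]])) {
      expect_identical(peptideString(resultPeptide(res1[[i]])),
                       peptideString(resultPeptide(res2[[i]])))
      expect_identical(residueScores(res1[[i]]), residueScores(res2[[i]]))
    }
  }
  ## all peaks deleted -> empty-flagged result, never a crash
  sp <- recs[[1]]$spectrum
  bare <- Spectrum(numeric(), numeric(), precursorMz(sp),
                   precursorCharge(sp), "bare")
  out <- denovo(bare, model, cfg)
  expect_true(isEmptyResult(out))
  ## refinement of a refined result leaves the sequence unchanged
  full <- denovo(sp, model, cfg)
  if (!isEmptyResult(full)) {
    again <- refineCandidates(
      sp, list(list(seq = residues(resultPeptide(full)), score = 0)),
      model, cfg)
    expect_gte(aggregateScore(again), aggregateScore(full) - 1e-12)
  }
})
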