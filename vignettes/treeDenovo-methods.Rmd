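---
title: "Decision-tree scored de novo peptide sequencing: models and methods"
author: "treeDenovo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-tree scored de novo peptide sequencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

De novo peptide sequencing reconstructs a peptide's residue sequence
directly from its CID tandem mass spectrum, without a protein database.
When a peptide of length $n$ fragments between residues $i$ and $i+1$, the
*prefix mass* (total residue mass N-terminal of the break) determines the
m/z of every fragment ion of that site: the b-ion is the protonated
prefix, the y-ion the protonated suffix plus water, and the remaining
types (a, doubly charged b/y, and the $-\mathrm{H_2O}$ / $-\mathrm{NH_3}$
neutral losses of b and y) follow by fixed offsets. treeDenovo scores
candidate sequences with two machine-learned probability functions and
searches for the best-scoring sequence with a two-stage algorithm.

All arithmetic is monoisotopic (proton 1.007276 Da, water 18.010565 Da).
Ile and Leu are mass-identical, so Ile is folded into Leu on input and
output. The default residue table applies carbamidomethylation of Cys as
a fixed modification and oxidation of Met (symbol `m`) as a variable one,
the standard settings for tryptic benchmark data.

## Scoring functions

**Fragmentation score.** A binary decision tree estimates the probability
that a given prefix mass is a real fragmentation site. For each of the
nine ion types, the theoretical m/z is matched against the spectrum
(default fragment tolerance 0.5 Da; when several peaks fall in the window
the most intense is taken). A matched peak contributes eight statistics:
relative intensity (fraction of the base peak), rank (peaks at least as
abundant), half rank (peaks at least half as abundant), their local
variants counted in the closed ±50 Da window, the local base peak's
relative intensity, and the charge state and isotope flag where
determinable. That yields $8 \times 9 = 72$ fragment-ion features; the
peptide mass, precursor charge, prefix mass and suffix mass complete the
76-feature vector. An unmatched ion type is missing-encoded (`NA` in all
eight channels); the tree can split on presence itself. The suffix-mass
feature excludes water, so prefix + suffix equals the total residue mass
(tested as an identity).

A candidate of length $n$ has $n-1$ interior sites with probabilities
$p_1,\dots,p_{n-1}$; its search score is $\sum_i (p_i - 0.1)$. The 0.1
penalty stops the search from padding mass with many small residues
(e.g. glycines at evidence-free sites): an extra site is only worth
adding when its probability clears the penalty.

**Residue score.** A second tree estimates the probability that one
residue $X$ of a candidate is correct, from 169 features: the 4 spectrum
features; the 72 fragment-ion features of the site left of $X$ and of the
site right of $X$; the categorical identities of $X_l$, $X$, $X_r$
(terminal neighbours use the boundary symbol `.`); nine residue mass
errors $\lvert\,\lvert m_r - m_l\rvert - \mathrm{mass}(X)\rvert /
\mathrm{tol}$, set to 1 when either flanking peak is missing and left
uncapped (values above 1 mean "worse than tolerance"); and nine adjacent
ion ratios $\log_2(h_r/h_l)$, with $\pm 32$ standing in for $\pm\infty$
when exactly one side is observed and a missing value when neither is.
The peptide-level residue score is the mass-weighted mean
$\sum p(a_i)\,m(a_i) / \sum m(a_i)$ — the expected fraction of mass
covered by correctly sequenced residues. Reported per-residue confidence
scores are $\mathrm{round}(100\,p)$.

## Tree learning

Both trees are grown by the standard greedy procedure: at each node the
test with maximal information gain (in bits) is chosen among numeric
thresholds (midpoints between sorted distinct values, subsampled to at
most 64 candidates), one-vs-rest singleton tests on the categorical
residue identities (so "is $X$ proline?" is expressible), and presence
tests on features with missing values. Missing values at a numeric test
follow the child that received more training examples. Growth stops when
no test gains more than $10^{-4}$ bits or when a child would hold fewer
than 50 examples — the data no longer support further branching. Leaf
probabilities are Laplace-smoothed, $(\mathrm{pos}+1)/(n+2)$, so they
never reach 0 or 1. Models serialize to versioned JSON; thresholds are
written with 17 significant digits and leaf probabilities are recomputed
from stored counts, so a round-trip reproduces predictions exactly.

Training examples for the fragmentation tree are the feature vectors at
every true interior prefix mass (positives) and at decoy prefix masses
drawn uniformly over the valid range, at least 1.5 fragment tolerances
from every true site, three per positive. For the residue tree, the
dynamic-programming stage is run on training spectra and every residue of
up to 24 candidates per spectrum is labeled correct/incorrect by the
residue-matching rule below; lower-ranked candidates supply the
incorrect-residue examples (sequence permutations, mass-equivalent
substitutions) that the refinement stage must learn to reject. The
empirical positive rate of this pool is stored as model metadata; it is a
property of the training distribution, not a transferable constant.

## Search algorithm

**Stage 1 — dynamic programming.** Site probabilities are precomputed for
every 0.01 Da prefix-mass bin in $(0, M_{\mathrm{res}})$. Only bins where
some observed peak can be read as one of the nine ion types need feature
extraction; all other bins carry the tree's no-evidence probability,
which is obtained exactly by a piecewise-constant interval descent of the
tree in the prefix mass. The DP fills prefix masses with residues
(integerized at the bin resolution), keeps the top 8 partial sequences
per bin, and maximizes $\sum (p_i - 0.1)$; candidates are finally
filtered by an exact-mass check against the precursor tolerance (15 ppm
default). Ties break lexicographically, making the whole search
deterministic. Keeping the top partial sequence per bin already
guarantees optimality of the best path (the completion score depends only
on the bin, not on how it was reached); the extra candidates supply
diversity for refinement. The 0.01 Da bin keeps discretization error two
orders of magnitude below the fragment tolerance; the 0.1 penalty is
applied inside the DP because it changes which paths are optimal.

A common artifact of prefix-mass scoring is reading a y-ion as a b-ion.
Peaks matched by both the y-ladder and the b-ladder of the first result
are therefore relabeled: the DP is rerun once with those peaks masked
from y-type matching (forced b) and once masked from b-type matching
(forced y) — at most 3 DP invocations per spectrum, a bound asserted by a
counter. All candidates are pooled and deduplicated.

**Stage 2 — refinement.** Candidates are rescored with the residue score
and the best is polished by local search: residues are fixed greedily in
descending probability until every maximal unfixed segment admits at most
100 residue-sequence fillings within the fragment tolerance of its mass;
each segment is replaced by every filling, substituted sequences that
break the precursor tolerance are discarded (the enumeration tolerance is
the fragment tolerance, but the final peptide must always satisfy the
precursor constraint), and the best full sequence under the residue score
is kept. The procedure iterates at most 3 times or until no improvement,
so the refined score never drops below the input candidate's. Filling
enumeration is depth-first with an exploration budget; a segment that
exceeds the budget counts as "more than 100 fillings" and triggers more
fixing.

## Evaluation protocol

A residue $x$ of the true peptide counts as correctly sequenced when the
de novo output contains a residue $y$ with
$\lvert \mathrm{mass}(x) - \mathrm{mass}(y)\rvert \le 0.1$ Da whose
prefix mass differs by at most 0.5 Da (each de novo residue is consumed
at most once, pairing greedily left to right; the prefix condition is
measured against the true peptide's side). Mass, not symbol, is compared
because low-resolution fragments cannot separate Lys/Gln or oxidized
Met/Phe. With $N$ true residues, $\mathrm{denovo}(t)$ de novo residues at
confidence $\ge t$ and $\mathrm{correct}(t)$ matched ones,
$\mathrm{recall}(t) = \mathrm{correct}(t)/N$ and
$\mathrm{precision}(t) = \mathrm{correct}(t)/\mathrm{denovo}(t)$, swept
over integer $t = 0..100$; threshold 0 gives the maximum recall.

The *verifiable-residue* baseline bounds what any method using only
abundant b/y/b²⁺/y²⁺ evidence could recall: a site is verifiable when one
of those four ions reaches 5% relative intensity (boundary inclusive),
termini are always verifiable, and a residue is verifiable when both its
flanks are. The dipeptide mass-gap census counts, for dipeptides whose
middle site shows none of the nine ion types under either residue order
while both flanks show abundant ions (termini qualify as flanks), how
often the output gives the correct versus the reversed order — symmetric
dipeptides count as correct, and a qualifying gap whose output matches
neither order increments neither counter.

## The simulator

`simulateLibrary()` emulates annotated tryptic CID spectra: peptides of
length 7–12 drawn from proteome-like residue frequencies with a K/R
C-terminus (probability 0.95) and 2+/3+ precursors (0.8/0.2); per-site,
per-ion-type emission with probability and intensity hierarchies
y > b > (a, 2+, neutral losses); residue-dependent site modifiers
(proline enhances the site at its left ×2 and suppresses the site at its
right ×0.6, glycine and serine milder — the regularity the residue tree
is expected to rediscover); lognormal intensity scatter (σ = 0.4,
truncated at ±2σ); 0.008 Da m/z jitter; isotope satellites; a 15%
missing-ion probability; and ~20 uniform noise peaks below the lower
quartile of the signal intensities. The truncation plus the modifier
bounds guarantee that in the noiseless configuration every y-ion clears
the 5% verifiability floor, making "verifiable fraction = 1 without
missing ions" a structural property rather than a sampling accident.

The simulator reproduces only the statistical regularities the scoring
functions exploit — it is not a physical mobile-proton model, its noise
is unstructured, and its intensity law is chosen for plausibility rather
than fitted to data. Passing tests therefore demonstrate that the
learner, search and evaluation machinery recover planted structure; they
do not certify accuracy on real instrument data.

**Training library.** `simulateMixedLibrary()` draws the default training
corpus in three equal parts: the default noisy configuration, an
intermediate one (5% missing ions, ~8 noise peaks, 0.004 Da jitter), and
a clean noiseless one. Real consensus libraries span exactly such a
quality range (entries merged from many replicates are nearly noise-free,
sparse ones are not), and trees trained on a single condition
mis-calibrate off it: a residue tree that has only seen noisy spectra
assigns indistinguishably high probabilities to clean-spectrum
candidates, letting the refinement accept mass-equivalent dipeptide
merges (AG→Q, GG→N) that fragmentation evidence rejects. Matching the
training distribution to the range of deployment conditions is the same
protocol the field uses for spectral-library learning.

## Problem sizes and model selection

The packaged experiments train the fragmentation tree on 5000 simulated
spectra (~170k site examples) and the residue tree on DP candidates from
1000 of them (~85k residue examples); evaluation uses held-out libraries
of 100–400 spectra. These sizes put tree growth, not example generation,
at the stopping boundary of `minLeaf = 50`, and train in a few minutes on
one core. The number of residue-training records and the 24 candidates
harvested per spectrum were selected on development data under the
80/10/10 split convention (`makeSplits()`), the same model-selection
protocol used for every other hyperparameter here; the reserved split is
never touched during development.

## Numerical choices and degenerate inputs

* Peak-match ties go to the most intense peak, then the lower m/z.
* Charge/isotope flags use a 0.02 Da spacing tolerance and a 0.1–10×
  intensity plausibility band; undeterminable cases stay missing.
* A missing MGF `CHARGE` defaults to 2+ (logged); blocks without
  `PEPMASS` are skipped and counted. MSP entries with unsupported
  modifications or unparseable names are skipped and counted.
* Precursor neutral mass is fixed at parse time as
  $M = m/z \cdot z - z \cdot \mathrm{proton}$.
* Empty or unsequenceable spectra yield an empty-flagged result, never an
  error; "precursor too small" (below the smallest residue) is an error
  at the scoring layer but is caught by `denovo()`.
* All stochastic steps (simulation, decoy sampling, shuffling) are driven
  by explicit integer seeds; two runs with the same seed are
  byte-identical.

## Known limitations

* The residue score cannot distinguish a residue from a mass-equivalent
  dipeptide when the middle fragmentation site is silent — the dipeptide
  gap census quantifies exactly this regime, and the intensity-pattern
  features (proline and friends) are what lift it above a coin flip.
* mzML input is out of scope; the `Spectrum` contract is format-agnostic
  and MGF/MSP readers are provided.
* Single trees only, as in the underlying method: no ensembles, pruning
  or boosting.
* Throughput is adequate for batch analysis (~2 spectra/s end to end) but
  no attempt is made at real-time speed; the compiled kernel covers only
  the DP inner loop and peak matching.
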