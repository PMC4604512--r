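## Independent reference implementations used as oracles across test files.
## They are written from the definitions, not from the package internals.

entropy2 <- function(pos, n) {
  if (n == 0) return(0)
  p <- pos / n
  if (p <= 0 || p >= 1) return(0)
  -(p * log2(p) + (1 - p) * log2(1 - p))
}

## Exhaustive information gain over every midpoint threshold of every
## feature (no candidate subsampling), NAs routed to the larger child.
exhaustiveRootGain <- function(X, y, minLeaf = 1L) {
  n <- length(y)
  H <- entropy2(sum(y), n)
  best <- -Inf
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    d <- sort(unique(x[!is.na(x)]))
    if (length(d) < 2) next
    for (th in (d[-1] + d[-length(d)]) / 2) {
      l <- !is.na(x) & x <= th
      r <- !is.na(x) & x > th
      if (sum(l) >= sum(r)) l <- l | is.na(x) else r <- r | is.na(x)
      if (sum(l) < minLeaf || sum(r) < minLeaf) next
      g <- H - (sum(l) * entropy2(sum(y[l]), sum(l)) +
                  sum(r) * entropy2(sum(y[r]), sum(r))) / n
      best <- max(best, g)
    }
  }
  best
}

## Brute-force DP oracle: enumerate every residue sequence, score it under
## the same bin arithmetic as the DP (site contribution at each interior
## prefix bin), accept sequences whose exact mass is within tolerance of
## the target, keep the best score.
bruteBest <- function(siteScores, masses, binWidth, penalty, target, tol) {
  resBins <- as.integer(round(masses / binWidth))
  best <- -Inf
  rec <- function(bin, mass, score) {
    if (mass > 0 && abs(mass - target) <= tol) best <<- max(best, score)
    for (r in seq_along(masses)) {
      nm <- mass + masses[r]
      if (nm > target + tol) next
      add <- if (bin > 0L && bin <= length(siteScores))
        siteScores[bin] - penalty else 0
      rec(bin + resBins[r], nm, score + if (bin > 0L) add else 0)
    }
  }
  rec(0L, 0, 0)
  best
}
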