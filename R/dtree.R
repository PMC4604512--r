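## Binary decision trees with leaf correctness probabilities, grown by greedy
## information-gain splitting. Trees are stored flat (parallel vectors, like
## rpart's frame) for fast vectorized descent.
##
## Node test types:
##   0 numeric threshold  (x <= value goes left; NA follows defaultLeft)
##   1 categorical singleton (x == value goes left; one-vs-rest)
##   2 presence bit       (x present, i.e. not NA, goes left)
##   3 leaf

#' Tree training configuration
#'
#' @param minLeaf minimum number of training examples per child; a split
#'   that would create a smaller child is not considered ("not enough data
#'   to confidently support further branching").
#' @param minGain minimum information gain (bits) for a split to be kept.
#' @param maxThresholds numeric features are split at midpoints between
#'   sorted distinct values, subsampled to at most this many candidates.
#' @param minNode minimum number of examples required to attempt a split.
#' @return list of class `treeConfig`.
#' @export
treeConfig <- function(minLeaf = 50L, minGain = 1e-4, maxThresholds = 64L,
                       minNode = 2L * minLeaf) {
  structure(list(minLeaf = as.integer(minLeaf), minGain = minGain,
                 maxThresholds = as.integer(maxThresholds),
                 minNode = as.integer(minNode)),
            class = "treeConfig")
}

.entropyBits <- function(pos, n) {
  p <- pos / n
  h <- numeric(length(p))
  ok <- n > 0 & p > 0 & p < 1
  h[ok] <- -(p[ok] * log2(p[ok]) + (1 - p[ok]) * log2(1 - p[ok]))
  h
}

## Best split for one numeric feature. Returns c(gain, threshold, defaultLeft)
## or NULL. NAs are routed to the larger child (stored as defaultLeft).
.bestNumericSplit <- function(x, y, minLeaf, maxThresholds) {
  miss <- is.na(x)
  xs <- x[!miss]
  ys <- y[!miss]
  if (length(xs) < 2L) return(NULL)
  d <- sort(unique(xs))
  if (length(d) < 2L) return(NULL)
  mids <- (d[-1L] + d[-length(d)]) / 2
  if (length(mids) > maxThresholds) {
    mids <- mids[unique(round(seq(1L, length(mids),
                                  length.out = maxThresholds)))]
  }
  bin <- findInterval(xs, mids)  # 0..m, bin < t  <=>  x <= mids[t]
  m <- length(mids)
  allC <- cumsum(tabulate(bin + 1L, m + 1L))[seq_len(m)]
  posC <- cumsum(tabulate(bin[ys == 1L] + 1L, m + 1L))[seq_len(m)]
  nMissPos <- sum(y[miss])
  nMiss <- sum(miss)
  n <- length(y)
  pos <- sum(y)
  nL0 <- allC; pL0 <- posC
  nR0 <- (n - nMiss) - allC; pR0 <- (pos - nMissPos) - posC
  defLeft <- nL0 >= nR0
  nL <- nL0 + ifelse(defLeft, nMiss, 0L)
  pL <- pL0 + ifelse(defLeft, nMissPos, 0L)
  nR <- nR0 + ifelse(defLeft, 0L, nMiss)
  pR <- pR0 + ifelse(defLeft, 0L, nMissPos)
  valid <- nL >= minLeaf & nR >= minLeaf
  if (!any(valid)) return(NULL)
  gain <- .entropyBits(pos, n) -
    (nL * .entropyBits(pL, nL) + nR * .entropyBits(pR, nR)) / n
  gain[!valid] <- -Inf
  i <- which.max(gain)
  c(gain = gain[i], value = mids[i], defaultLeft = as.numeric(defLeft[i]))
}

## Best one-vs-rest singleton split for a categorical (integer-coded) feature.
.bestCategoricalSplit <- function(x, y, minLeaf) {
  n <- length(y)
  pos <- sum(y)
  maxCode <- max(x)
  allC <- tabulate(x, maxCode)
  posC <- tabulate(x[y == 1L], maxCode)
  nL <- allC; pL <- posC
  nR <- n - nL; pR <- pos - pL
  valid <- nL >= minLeaf & nR >= minLeaf
  if (!any(valid)) return(NULL)
  gain <- .entropyBits(pos, n) -
    (nL * .entropyBits(pL, nL) + nR * .entropyBits(pR, nR)) / n
  gain[!valid] <- -Inf
  i <- which.max(gain)
  c(gain = gain[i], value = i, defaultLeft = 1)
}

.bestPresenceSplit <- function(x, y, minLeaf) {
  miss <- is.na(x)
  nL <- sum(!miss)
  nR <- sum(miss)
  if (nL < minLeaf || nR < minLeaf) return(NULL)
  n <- length(y)
  pos <- sum(y)
  pL <- sum(y[!miss])
  gain <- .entropyBits(pos, n) -
    (nL * .entropyBits(pL, nL) + nR * .entropyBits(pos - pL, nR)) / n
  c(gain = gain, value = NA_real_, defaultLeft = 1)
}

.bestSplit <- function(X, y, rows, categorical, cfg) {
  best <- NULL
  for (j in seq_len(ncol(X))) {
    x <- X[rows, j]
    cand <- list()
    if (j %in% categorical) {
      s <- .bestCategoricalSplit(x, y[rows], cfg$minLeaf)
      if (!is.null(s)) cand <- c(cand, list(c(type = 1, feature = j, s)))
    } else {
      s <- .bestNumericSplit(x, y[rows], cfg$minLeaf, cfg$maxThresholds)
      if (!is.null(s)) cand <- c(cand, list(c(type = 0, feature = j, s)))
      if (anyNA(x)) {
        s <- .bestPresenceSplit(x, y[rows], cfg$minLeaf)
        if (!is.null(s)) cand <- c(cand, list(c(type = 2, feature = j, s)))
      }
    }
    for (s in cand) {
      if (is.null(best) || s[["gain"]] > best[["gain"]]) best <- s
    }
  }
  best
}

#' Train a binary decision tree by greedy information-gain splitting
#'
#' At each node, the candidate test (numeric midpoint threshold, categorical
#' one-vs-rest singleton, or presence bit for features with missing values)
#' with the largest information gain is chosen. Splitting stops when no
#' candidate gains more than `minGain` bits or when every candidate would
#' leave a child with fewer than `minLeaf` examples. Leaf probabilities are
#' Laplace-smoothed positive fractions `(pos + 1) / (n + 2)`, so they lie
#' strictly in (0, 1).
#'
#' @param X numeric feature matrix (categorical features integer-coded;
#'   missing values as NA).
#' @param y binary labels (0/1).
#' @param layout feature layout (from [fragFeatureLayout()] or
#'   [residueFeatureLayout()]); `NULL` for an all-numeric ad hoc layout.
#' @param config a [treeConfig()].
#' @return an object of class `denovoTree`.
#' @export
trainTree <- function(X, y, layout = NULL, config = treeConfig()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) == 0L) stop("empty training set", call. = FALSE)
  stopifnot(length(y) == nrow(X), all(y %in% c(0L, 1L)))
  categorical <- if (is.null(layout)) integer() else layout$categorical
  ## growable flat arrays
  cap <- 256L
  type <- integer(cap); feature <- integer(cap); value <- numeric(cap)
  defaultLeft <- logical(cap); left <- integer(cap); right <- integer(cap)
  pos <- integer(cap); nn <- integer(cap); depth <- integer(cap)
  nNodes <- 0L
  grow <- function() {
    cap2 <- 2L * cap
    length(type) <<- cap2; length(feature) <<- cap2; length(value) <<- cap2
    length(defaultLeft) <<- cap2; length(left) <<- cap2; length(right) <<- cap2
    length(pos) <<- cap2; length(nn) <<- cap2; length(depth) <<- cap2
    cap <<- cap2
  }
  newNode <- function(d) {
    nNodes <<- nNodes + 1L
    if (nNodes > cap) grow()
    depth[nNodes] <<- d
    nNodes
  }
  root <- newNode(0L)
  queue <- list(list(node = root, rows = seq_len(nrow(X))))
  while (length(queue)) {
    job <- queue[[1L]]
    queue <- queue[-1L]
    rows <- job$rows
    id <- job$node
    nn[id] <- length(rows)
    pos[id] <- sum(y[rows])
    makeLeaf <- TRUE
    if (length(rows) >= config$minNode && pos[id] > 0L &&
        pos[id] < length(rows)) {
      s <- .bestSplit(X, y, rows, categorical, config)
      if (!is.null(s) && s[["gain"]] > config$minGain) {
        makeLeaf <- FALSE
        type[id] <- s[["type"]]
        feature[id] <- s[["feature"]]
        value[id] <- s[["value"]]
        defaultLeft[id] <- s[["defaultLeft"]] > 0
        x <- X[rows, s[["feature"]]]
        goLeft <- switch(as.character(s[["type"]]),
          "0" = ifelse(is.na(x), s[["defaultLeft"]] > 0, x <= s[["value"]]),
          "1" = !is.na(x) & x == s[["value"]],
          "2" = !is.na(x))
        l <- newNode(depth[id] + 1L)
        r <- newNode(depth[id] + 1L)
        left[id] <- l
        right[id] <- r
        queue <- c(queue, list(list(node = l, rows = rows[goLeft]),
                               list(node = r, rows = rows[!goLeft])))
      }
    }
    if (makeLeaf) type[id] <- 3L
  }
  keep <- seq_len(nNodes)
  structure(list(
    type = as.integer(type[keep]), feature = as.integer(feature[keep]),
    value = as.numeric(value[keep]),
    defaultLeft = as.logical(defaultLeft[keep]),
    left = as.integer(left[keep]), right = as.integer(right[keep]),
    pos = as.integer(pos[keep]), n = as.integer(nn[keep]),
    depth = as.integer(depth[keep]),
    prob = (pos[keep] + 1) / (nn[keep] + 2),
    nFeatures = ncol(X),
    layoutKind = if (is.null(layout)) "numeric" else layout$kind),
    class = "denovoTree")
}

#' Predict leaf correctness probabilities
#'
#' Deterministic descent from the root: numeric tests send `x <= value`
#' left (missing values follow the stored default branch), categorical
#' singleton tests send `x == value` left, presence tests send non-missing
#' left. Returns the Laplace-smoothed leaf probability.
#'
#' @param tree a `denovoTree` from [trainTree()].
#' @param X feature matrix (or a single feature vector) with the same
#'   layout the tree was trained on.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predictTree <- function(tree, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != tree$nFeatures) {
    stop("feature layout mismatch: tree expects ", tree$nFeatures,
         " features, got ", ncol(X), call. = FALSE)
  }
  cur <- rep.int(1L, nrow(X))
  repeat {
    active <- which(tree$type[cur] != 3L)
    if (!length(active)) break
    nd <- cur[active]
    x <- X[cbind(active, tree$feature[nd])]
    tp <- tree$type[nd]
    goLeft <- logical(length(active))
    isNum <- tp == 0L
    if (any(isNum)) {
      xi <- x[isNum]
      gl <- xi <= tree$value[nd[isNum]]
      gl[is.na(gl)] <- tree$defaultLeft[nd[isNum]][is.na(gl)]
      goLeft[isNum] <- gl
    }
    isCat <- tp == 1L
    if (any(isCat)) {
      goLeft[isCat] <- !is.na(x[isCat]) & x[isCat] == tree$value[nd[isCat]]
    }
    isPres <- tp == 2L
    if (any(isPres)) goLeft[isPres] <- !is.na(x[isPres])
    cur[active] <- ifelse(goLeft, tree$left[nd], tree$right[nd])
  }
  tree$prob[cur]
}

## Leaf probability as a piecewise-constant function of the prefix mass for
## rows whose fragment-ion features are all missing (no-evidence bins).
## Descends the tree once, splitting the prefix interval at thresholds on
## the prefix-mass and suffix-mass features; all other numeric tests follow
## the stored default branch (value missing) or compare against the scalar
## spectrum features. Returns breakpoints and per-interval probabilities.
.noEvidenceProfile <- function(tree, M, z, Mres) {
  segLo <- numeric(); segHi <- numeric(); segP <- numeric()
  stack <- list(list(node = 1L, lo = 0, hi = Mres))
  while (length(stack)) {
    s <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- s$node; lo <- s$lo; hi <- s$hi
    repeat {
      tp <- tree$type[node]
      if (tp == 3L) {
        segLo <- c(segLo, lo); segHi <- c(segHi, hi)
        segP <- c(segP, tree$prob[node])
        break
      }
      f <- tree$feature[node]
      if (tp == 2L) {                      # presence test: spectrum features
        node <- if (f <= 4L) tree$left[node] else tree$right[node]
      } else if (tp == 1L) {               # categorical: never present here
        node <- tree$right[node]
      } else if (f == 1L) {
        node <- if (M <= tree$value[node]) tree$left[node] else
          tree$right[node]
      } else if (f == 2L) {
        node <- if (z <= tree$value[node]) tree$left[node] else
          tree$right[node]
      } else if (f == 3L) {                # prefix mass <= v
        v <- tree$value[node]
        if (v >= hi) node <- tree$left[node]
        else if (v <= lo) node <- tree$right[node]
        else {
          stack[[length(stack) + 1L]] <- list(node = tree$right[node],
                                              lo = v, hi = hi)
          hi <- v
          node <- tree$left[node]
        }
      } else if (f == 4L) {                # suffix <= v  <=>  prefix >= M-v
        bp <- Mres - tree$value[node]
        if (bp <= lo) node <- tree$left[node]
        else if (bp >= hi) node <- tree$right[node]
        else {
          stack[[length(stack) + 1L]] <- list(node = tree$right[node],
                                              lo = lo, hi = bp)
          lo <- bp
          node <- tree$left[node]
        }
      } else {                             # missing ion feature
        node <- if (tree$defaultLeft[node]) tree$left[node] else
          tree$right[node]
      }
    }
  }
  o <- order(segLo)
  list(lo = segLo[o], hi = segHi[o], prob = segP[o])
}

#' Tree size and depth statistics
#'
#' @param tree a `denovoTree`.
#' @return list with the number of branching nodes, number of leaves, and
#'   the mean root-to-leaf path length weighted by training examples.
#' @export
treeStats <- function(tree) {
  leaves <- tree$type == 3L
  list(nBranching = sum(!leaves),
       nLeaves = sum(leaves),
       meanPathLength = sum(tree$depth[leaves] * tree$n[leaves]) /
         sum(tree$n[leaves]))
}

#' @export
print.denovoTree <- function(x, ...) {
  s <- treeStats(x)
  cat(sprintf(
    "Decision tree (%s layout, %d features): %d branching nodes, %d leaves, mean path length %.1f\n",
    x$layoutKind, x$nFeatures, s$nBranching, s$nLeaves, s$meanPathLength))
  invisible(x)
}

## ---- model container ------------------------------------------------------

#' Save a trained model to versioned JSON
#'
#' The model file stores both trees (flat node tables with leaf counts, so
#' probabilities are recomputed exactly on load), the feature layout
#' descriptors and training metadata.
#'
#' @param model a model list from [trainModel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
saveModel <- function(model, path) {
  enc <- function(tree) {
    tree$value <- sprintf("%.17g", tree$value)  # exact double round-trip
    unclass(tree)
  }
  obj <- list(format = "treeDenovo-model", version = 1L,
              fragTree = enc(model$fragTree),
              residueTree = enc(model$residueTree),
              meta = model$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE, na = "null")
  invisible(path)
}

#' Load a model saved by [saveModel()]
#'
#' @param path path to the JSON model file.
#' @return model list; `predictTree` output is identical to the model
#'   before serialization.
#' @export
loadModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "treeDenovo-model")) {
    stop("not a treeDenovo model file: ", path, call. = FALSE)
  }
  dec <- function(tr) {
    tr$type <- as.integer(tr$type)
    tr$feature <- as.integer(tr$feature)
    tr$value <- suppressWarnings(as.numeric(tr$value))  # "NA" for presence tests
    tr$defaultLeft <- as.logical(tr$defaultLeft)
    tr$left <- as.integer(tr$left)
    tr$right <- as.integer(tr$right)
    tr$pos <- as.integer(tr$pos)
    tr$n <- as.integer(tr$n)
    tr$depth <- as.integer(tr$depth)
    tr$prob <- (tr$pos + 1) / (tr$n + 2)
    tr$nFeatures <- as.integer(tr$nFeatures)
    structure(tr, class = "denovoTree")
  }
  list(fragTree = dec(obj$fragTree), residueTree = dec(obj$residueTree),
       meta = obj$meta)
}

## ---- training example construction ----------------------------------------

#' Build labeled fragmentation-site examples from an annotated library
#'
#' Positives are the 76-feature vectors at every true interior prefix mass
#' of the annotated peptide; negatives are vectors at decoy prefix masses
#' sampled uniformly over the valid range, at least `1.5 * fragTol` away
#' from every true site, `decoyRatio` per positive.
#'
#' @param records list of `list(spectrum =, peptide =)` pairs.
#' @param fragTol fragment tolerance (Da).
#' @param decoyRatio negatives per positive.
#' @param seed integer seed for decoy sampling.
#' @return list with feature matrix `X`, labels `y`.
#' @export
makeFragExamples <- function(records, fragTol = 0.5, decoyRatio = 3L,
                             seed = 1L) {
  set.seed(seed)
  Xs <- vector("list", length(records))
  ys <- vector("list", length(records))
  for (k in seq_along(records)) {
    sp <- records[[k]]$spectrum
    pep <- records[[k]]$peptide
    n <- peptideLength(pep)
    if (n < 2L || peakCount(sp) < 1L) next
    pidx <- buildPeakIndex(sp)
    true <- prefixMasses(pep)[seq_len(n - 1L)]
    Mres <- spectrumResidueMass(sp)
    lo <- min(.BASE_RESIDUE_MASSES)
    want <- decoyRatio * (n - 1L)
    decoys <- numeric(0)
    tries <- 0L
    while (length(decoys) < want && tries < 20L) {
      cand <- stats::runif(2L * want, lo, Mres - lo)
      ok <- vapply(cand, function(m) all(abs(m - true) >= 1.5 * fragTol),
                   logical(1))
      decoys <- c(decoys, cand[ok])
      tries <- tries + 1L
    }
    decoys <- decoys[seq_len(min(want, length(decoys)))]
    pm <- c(true, decoys)
    Xs[[k]] <- .fragSiteMatrix(sp, pidx, pm, fragTol)
    ys[[k]] <- c(rep(1L, length(true)), rep(0L, length(decoys)))
  }
  keep <- !vapply(Xs, is.null, logical(1))
  X <- do.call(rbind, Xs[keep])
  colnames(X) <- fragFeatureLayout()$names
  list(X = X, y = unlist(ys[keep]))
}

#' Build labeled residue examples from DP-stage candidates
#'
#' Runs the dynamic-programming stage (no refinement) on each annotated
#' spectrum, labels every residue of each candidate sequence correct or
#' incorrect with the residue-matching rule against the annotation, and
#' extracts the 169-feature vectors in candidate context.
#'
#' @param records list of `list(spectrum =, peptide =)` pairs.
#' @param model list holding a trained `fragTree`.
#' @param config a [denovoConfig()].
#' @param nCandidates candidates per spectrum to harvest.
#' @param massTable residue mass table.
#' @return list with `X`, `y`, the empirical positive rate `posRate`, and
#'   the number of spectra skipped due to search errors.
#' @export
makeResidueExamples <- function(records, model, config = denovoConfig(),
                                nCandidates = 24L,
                                massTable = residueMassTable()) {
  Xs <- list()
  ys <- list()
  skipped <- 0L
  for (k in seq_along(records)) {
    sp <- records[[k]]$spectrum
    truth <- records[[k]]$peptide
    got <- tryCatch({
      stage <- relabelAndRerun(sp, model, config, massTable)
      cands <- stage$candidates[seq_len(min(nCandidates,
                                            length(stage$candidates)))]
      pidx <- stage$pidx
      lapply(cands, function(cd) {
        pep <- Peptide(cd$seq, massTable)
        flags <- matchResidues(truth, pep)
        pairs <- attr(flags, "pairs")
        lab <- integer(peptideLength(pep))
        lab[pairs[!is.na(pairs)]] <- 1L
        list(X = .residueMatrix(sp, pidx, pep, config$fragTolDa,
                                massTable = massTable), y = lab)
      })
    }, error = function(e) NULL)
    if (is.null(got) || !length(got)) {
      skipped <- skipped + 1L
      next
    }
    Xs <- c(Xs, lapply(got, `[[`, "X"))
    ys <- c(ys, lapply(got, `[[`, "y"))
  }
  if (!length(Xs)) stop("no residue examples could be generated",
                        call. = FALSE)
  X <- do.call(rbind, Xs)
  y <- unlist(ys)
  list(X = X, y = y, posRate = mean(y), skipped = skipped)
}

#' Train the full scoring model
#'
#' Trains the fragmentation-score tree (76 features) on site examples and
#' then, using the dynamic-programming stage driven by that tree, the
#' residue-score tree (169 features) on candidate residues. The residue
#' tree can be trained on a subset of the records (DP is the expensive
#' step).
#'
#' @param records annotated `list(spectrum =, peptide =)` pairs.
#' @param config tree training configuration.
#' @param engineConfig search configuration used for residue examples.
#' @param residueRecords how many records to run the DP stage on for the
#'   residue tree (the DP is the expensive step; 1000 records yield on the
#'   order of 1e5 labeled residues).
#' @param nCandidates DP candidates harvested per spectrum for the residue
#'   tree; lower-ranked candidates supply the incorrect-residue examples.
#' @param decoyRatio decoys per true site for the fragmentation tree.
#' @param seed integer seed.
#' @param massTable residue mass table.
#' @return model list with `fragTree`, `residueTree` and `meta`.
#' @export
trainModel <- function(records, config = treeConfig(),
                       engineConfig = denovoConfig(),
                       residueRecords = 1000L, nCandidates = 24L,
                       decoyRatio = 3L, seed = 1L,
                       massTable = residueMassTable()) {
  fe <- makeFragExamples(records, engineConfig$fragTolDa, decoyRatio, seed)
  fragTree <- trainTree(fe$X, fe$y, fragFeatureLayout(), config)
  partial <- list(fragTree = fragTree)
  sub <- records[seq_len(min(residueRecords, length(records)))]
  re <- makeResidueExamples(sub, partial, engineConfig, nCandidates,
                            massTable = massTable)
  residueTree <- trainTree(re$X, re$y, residueFeatureLayout(massTable),
                           config)
  list(fragTree = fragTree, residueTree = residueTree,
       meta = list(nFragExamples = length(fe$y),
                   nResidueExamples = length(re$y),
                   residuePosRate = re$posRate,
                   fragStats = treeStats(fragTree),
                   residueStats = treeStats(residueTree),
                   alphabet = residueFeatureLayout(massTable)$levels[[1L]]))
}
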