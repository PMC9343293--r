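## Independent oracles used by the property-style tests. Each is a separate
## implementation of the quantity it checks (dynamic programming, exhaustive
## enumeration, textbook recurrences, graph search) and never calls the
## package function it is compared against.

suppressPackageStartupMessages({
  library(ape)
})

## ---- global affine-gap alignment --------------------------------------

## Gotoh three-state dynamic program, end gaps penalized, gap of length L
## costing gapOpen + L * gapExt; N scores as a mismatch against everything.
oracleAlignScore <- function(a, b, match = 5, mismatch = -4, gapOpen = -10,
                             gapExt = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes A)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes B)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- gapOpen + gapExt * i
  for (j in seq_len(m)) Y[1, j + 1] <- gapOpen + gapExt * j
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (A[i] == B[j] && A[i] != "N") match else mismatch
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] + gapOpen + gapExt,
                           X[i, j + 1] + gapExt,
                           Y[i, j + 1] + gapOpen + gapExt)
    Y[i + 1, j + 1] <- max(M[i + 1, j] + gapOpen + gapExt,
                           Y[i + 1, j] + gapExt,
                           X[i + 1, j] + gapOpen + gapExt)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

## Exhaustive enumeration of every alignment (for tiny sequences): generate
## all monotone column sequences, score each whole alignment by runs.
enumAlignments <- function(a, b) {
  if (!nzchar(a) && !nzchar(b)) return(list(c("", "")))
  res <- list()
  add <- function(al) res[[length(res) + 1]] <<- al
  if (nzchar(a) && nzchar(b))
    for (al in enumAlignments(substring(a, 2), substring(b, 2)))
      add(c(paste0(substring(a, 1, 1), al[1]),
            paste0(substring(b, 1, 1), al[2])))
  if (nzchar(a))
    for (al in enumAlignments(substring(a, 2), b))
      add(c(paste0(substring(a, 1, 1), al[1]), paste0("-", al[2])))
  if (nzchar(b))
    for (al in enumAlignments(a, substring(b, 2)))
      add(c(paste0("-", al[1]), paste0(substring(b, 1, 1), al[2])))
  res
}

scoreGapped <- function(qa, ra, match = 5, mismatch = -4, gapOpen = -10,
                        gapExt = -1) {
  qc <- strsplit(qa, "")[[1]]; rc <- strsplit(ra, "")[[1]]
  sub <- 0
  for (k in seq_along(qc)) {
    if (qc[k] == "-" || rc[k] == "-") next
    sub <- sub + if (qc[k] == rc[k] && qc[k] != "N") match else mismatch
  }
  runCost <- function(x) {
    r <- rle(x == "-")
    sum(vapply(which(r$values), function(i) gapOpen + gapExt * r$lengths[i],
               numeric(1)))
  }
  sub + runCost(qc) + runCost(rc)
}

bruteAlignScore <- function(a, b, ...) {
  max(vapply(enumAlignments(a, b), function(al)
    scoreGapped(al[1], al[2], ...), numeric(1)))
}

randomSeq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

## ---- UPGMA (textbook recurrence) --------------------------------------

## Returns the cophenetic (merge-height) distance matrix implied by UPGMA
## on distance matrix D.
oracleUpgmaCophenetic <- function(D) {
  labs <- rownames(D)
  members <- as.list(labs)
  sizes <- rep(1, length(labs))
  d <- D
  coph <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  while (length(members) > 1) {
    n <- length(members)
    best <- c(Inf, NA, NA)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (d[i, j] < best[1]) best <- c(d[i, j], i, j)
    i <- best[2]; j <- best[3]; h <- best[1]
    for (x in members[[i]]) for (y in members[[j]]) {
      coph[x, y] <- h; coph[y, x] <- h
    }
    newRow <- vapply(seq_len(n), function(k)
      (sizes[i] * d[i, k] + sizes[j] * d[j, k]) / (sizes[i] + sizes[j]),
      numeric(1))
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newRow[keep]),
               c(newRow[keep], 0))
    members <- c(members[keep], list(c(members[[i]], members[[j]])))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
  }
  coph
}

## ---- Fitch parsimony (exhaustive internal-state minimization) ----------

## Minimum substitution count over all assignments of {A,C,G,T} to internal
## nodes; leaves with N/-/? may take any state.
oracleFitchScore <- function(alnMatrix, tree) {
  states <- c("A", "C", "G", "T")
  ntip <- length(tree$tip.label)
  internals <- sort(unique(tree$edge[, 1]))
  edges <- tree$edge
  leafAllowed <- function(ch) if (ch %in% states) ch else states
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(states), length(internals)),
                                stringsAsFactors = FALSE))
  for (col in seq_len(ncol(alnMatrix))) {
    obs <- alnMatrix[tree$tip.label, col]
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      assign <- grid[g, ]
      names(assign) <- internals
      cost <- 0
      for (e in seq_len(nrow(edges))) {
        par <- as.character(edges[e, 1]); chd <- edges[e, 2]
        ps <- assign[[par]]
        if (chd <= ntip) {
          allowed <- leafAllowed(obs[chd])
          if (!(ps %in% allowed)) cost <- cost + 1
        } else if (ps != assign[[as.character(chd)]]) cost <- cost + 1
      }
      if (cost < best) best <- cost
      if (best == 0) break
    }
    total <- total + best
  }
  total
}

## ---- band matching (graph transitive closure) --------------------------

## Connected components of the pairwise-within-tolerance relation by BFS,
## then recursive largest-gap splitting of components containing two bands
## from one lane. Returns a set of clusters, each a sorted character key.
oracleBandClusters <- function(bands, tol) {
  n <- nrow(bands)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    lo <- min(bands$mw_kda[i], bands$mw_kda[j])
    hi <- max(bands$mw_kda[i], bands$mw_kda[j])
    adj[i, j] <- (hi - lo) / lo <= tol
  }
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; comp <- integer()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      comp <- c(comp, v)
      queue <- c(queue, which(adj[v, ] & !seen))
    }
    comps[[length(comps) + 1]] <- comp
  }
  splitDupes <- function(idx) {
    idx <- idx[order(bands$mw_kda[idx])]
    if (!anyDuplicated(bands$lane_id[idx])) return(list(idx))
    mws <- bands$mw_kda[idx]
    gaps <- (mws[-1] - mws[-length(mws)]) / mws[-length(mws)]
    cut <- which.max(gaps)
    c(splitDupes(idx[seq_len(cut)]), splitDupes(idx[-seq_len(cut)]))
  }
  pieces <- unlist(lapply(comps, splitDupes), recursive = FALSE)
  sort(vapply(pieces, function(idx)
    paste(sort(sprintf("%s@%.6f", bands$lane_id[idx], bands$mw_kda[idx])),
          collapse = ";"), character(1)))
}

## cluster keys of a BandMatrix, in the same canonical form
bandMatrixClusters <- function(bm) {
  sort(vapply(bm@members, function(p)
    paste(sort(sprintf("%s@%.6f", p$lane_id, p$mw_kda)), collapse = ";"),
    character(1)))
}

## ---- bipartition tallying (edge traversal) -----------------------------

## Nontrivial splits of a tree, canonicalized as the sorted side not
## containing the alphabetically first label, by explicit recursion over
## the edge table (independent of ape::prop.part).
oracleTreeSplits <- function(tree) {
  labels <- sort(tree$tip.label)
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  desc <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    unlist(lapply(kids[[as.character(v)]], desc))
  }
  out <- character()
  for (e in seq_len(nrow(tree$edge))) {
    v <- tree$edge[e, 2]
    if (v <= ntip) next
    side <- desc(v)
    if (labels[1] %in% side) side <- setdiff(labels, side)
    if (length(side) >= 2 && length(side) <= length(labels) - 2)
      out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

## ---- misc ---------------------------------------------------------------

randomAdditiveTree <- function(ntaxa, minLen = 0.05, maxLen = 1) {
  tr <- ape::rtree(ntaxa, rooted = FALSE)
  tr$edge.length <- runif(nrow(tr$edge), minLen, maxLen)
  tr
}

## 4-taxon alignment built from two conflicting column classes: class 1
## supports AB|CD, class 2 supports AC|BD.
conflictAlignment <- function(n1, n2) {
  col1 <- c(A = "A", B = "A", C = "T", D = "T")
  col2 <- c(A = "A", B = "T", C = "A", D = "T")
  m <- cbind(matrix(rep(col1, n1), nrow = 4),
             matrix(rep(col2, n2), nrow = 4))
  rownames(m) <- names(col1)
  m
}

## support attached to the bipartition separating `side` in a
## habidBootstrap result (NA when the point tree lacks that split)
splitSupport <- function(bs, side) {
  tree <- bs$tree
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  desc <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    unlist(lapply(kids[[as.character(v)]], desc))
  }
  all <- tree$tip.label
  for (v in sort(unique(tree$edge[, 1]))) {
    d <- desc(v)
    if (setequal(d, side) || setequal(d, setdiff(all, side)))
      return(bs$supports[v - ntip])
  }
  NA_real_
}
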