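## Distance computation, tree building, parsimony scoring, bootstrap and
## majority-rule consensus for aligned sequence sets.
## Trees are ape "phylo" objects throughout.

#' Validate an already-aligned sequence set
#'
#' Multiple sequence alignment is an input to this package, not a stage:
#' this validator checks that all records have equal length, that there are
#' enough of them, and that labels are unique, then returns the alignment
#' as an uppercase character matrix (taxa in rows). Accepts a
#' [Biostrings::DNAStringSet], a character vector of equal-length strings
#' or a character matrix.
#'
#' @param x the alignment.
#' @param minTaxa minimum number of records (3 for tree building; default
#'   2).
#' @return character matrix with rownames.
#' @export
validateAlignment <- function(x, minTaxa = 2) {
  if (is(x, "DNAStringSet") || is(x, "BStringSet")) {
    ids <- names(x)
    x <- as.character(x)
    names(x) <- ids
  }
  if (is.character(x) && !is.matrix(x)) {
    if (length(unique(nchar(x))) > 1)
      stopValidation("aligned sequences must all have equal length")
    ids <- names(x)
    if (is.null(ids)) ids <- sprintf("seq%d", seq_along(x))
    x <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(x) <- ids
  } else if (is.matrix(x)) {
    x <- toupper(x)
    if (is.null(rownames(x)))
      rownames(x) <- sprintf("seq%d", seq_len(nrow(x)))
  } else stopValidation("unsupported alignment representation")
  if (nrow(x) < minTaxa)
    stopValidation("alignment needs at least %d records", minTaxa)
  if (anyDuplicated(rownames(x)))
    stopValidation("alignment record ids must be unique")
  if (ncol(x) == 0) stopValidation("alignment has zero columns")
  x
}

#' Jukes-Cantor distance from a mismatch proportion
#'
#' Closed form `d = -(3/4) * log(1 - 4p/3)`, the expected number of
#' substitutions per site under the one-parameter JC69 model given an
#' observed proportion `p` of differing sites. The model saturates at
#' `p >= 3/4`, where the distance is undefined.
#'
#' @param p numeric vector of mismatch proportions in `[0, 0.75)`.
#' @return numeric vector of distances.
#' @export
jc69Distance <- function(p) {
  if (any(p < 0 | p > 1)) stopValidation("p must lie in [0, 1]")
  if (any(p >= 0.75))
    stopCompute("JC69 distance undefined at p >= 0.75 (saturation)")
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise distances from an alignment
#'
#' Mismatch proportions are computed with pairwise deletion: for each pair,
#' alignment columns where either sequence carries a gap or an ambiguous
#' base are dropped and `p = mismatches / compared sites`. `model = "p"`
#' returns `p` itself; `model = "jc69"` applies the [jc69Distance()]
#' transform (erroring at saturation).
#'
#' @param aln an alignment accepted by [validateAlignment()].
#' @param model `"jc69"` (default) or `"p"`.
#' @return a [stats::dist] with a `model` attribute.
#' @export
pairwiseDistance <- function(aln, model = c("jc69", "p")) {
  model <- match.arg(model)
  m <- validateAlignment(aln, minTaxa = 2)
  bin <- ape::as.DNAbin(tolower(m))
  p <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE)
  if (any(!is.finite(p)))
    stopCompute("some sequence pair has zero comparable sites")
  d <- if (model == "jc69") {
    out <- p
    out[] <- jc69Distance(as.vector(p))
    out
  } else p
  attr(d, "model") <- model
  d
}

asDistMatrix <- function(dm) {
  m <- as.matrix(dm)
  if (is.null(rownames(m))) stopValidation("distance matrix needs labels")
  if (any(!is.finite(m))) stopCompute("non-finite distances")
  m
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining (Studier-Keppler Q-matrix), consistent on
#' additive distances: when the input is the patristic distance matrix of
#' a tree, that tree's unrooted topology and branch lengths are recovered
#' exactly. Negative branch-length estimates (possible on noisy,
#' non-additive input) are clamped to 0 with a warning.
#'
#' @param dm a [stats::dist] or symmetric matrix with labels, at least 3
#'   taxa.
#' @return an unrooted [ape::phylo].
#' @export
neighborJoining <- function(dm) {
  m <- asDistMatrix(dm)
  if (nrow(m) < 3) stopValidation("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(as.dist(m))
  if (any(tr$edge.length < 0)) {
    warning(sprintf("%d negative NJ branch length(s) clamped to 0",
                    sum(tr$edge.length < 0)))
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' UPGMA tree from sequence distances
#'
#' Average-linkage agglomeration on substitutions-per-site distances,
#' producing a rooted ultrametric tree; merge heights are halved into
#' branch lengths so cophenetic distances reproduce an ultrametric input
#' exactly. Labels are sorted lexicographically first so ties break
#' deterministically.
#'
#' @param dm a [stats::dist] or symmetric matrix with labels, at least 2
#'   taxa.
#' @return a rooted [ape::phylo].
#' @export
upgmaTree <- function(dm) {
  m <- asDistMatrix(dm)
  if (nrow(m) < 2) stopValidation("UPGMA needs at least 2 taxa")
  ord <- order(rownames(m))
  ape::as.phylo(hclust(as.dist(m[ord, ord]), method = "average"))
}

#' Fitch parsimony score of a tree
#'
#' Minimum number of substitutions required to explain the alignment on
#' the given topology, summed over columns (Fitch's bottom-up
#' union/intersection pass). Gaps, `N` and other ambiguity codes are
#' treated as missing data (the full state set). The score does not depend
#' on rooting.
#'
#' @param aln an alignment accepted by [validateAlignment()].
#' @param tree an [ape::phylo] whose tip labels equal the alignment record
#'   ids.
#' @return integer parsimony score.
#' @export
fitchScore <- function(aln, tree) {
  m <- validateAlignment(aln, minTaxa = 2)
  if (!inherits(tree, "phylo")) stopValidation("tree must be a phylo object")
  if (!setequal(tree$tip.label, rownames(m)))
    stopValidation("tree tip labels do not match alignment record ids")
  pd <- phangorn::phyDat(tolower(m), type = "DNA")
  as.integer(phangorn::fitch(tree, pd))
}

buildTree <- function(aln, builder, model) {
  d <- pairwiseDistance(aln, model = model)
  switch(builder, nj = neighborJoining(d), upgma = upgmaTree(d))
}

#' Bootstrap support for a distance tree
#'
#' Builds the point-estimate tree from the full alignment, then resamples
#' alignment columns with replacement `replicates` times, rebuilds the tree
#' from each resample, and labels each internal bipartition of the point
#' tree with the percentage of successful replicates containing it.
#' Replicates whose resampled alignment defeats the distance model (zero
#' comparable sites or JC69 saturation) are skipped, counted and warned
#' about; supports are percentages of the replicates actually kept.
#' Fixing the seed fixes every support value.
#'
#' @param aln an alignment accepted by [validateAlignment()] (at least 3
#'   records).
#' @param builder `"nj"` (default) or `"upgma"`.
#' @param replicates bootstrap replicates (default 500).
#' @param seed integer RNG seed (required).
#' @param model distance model, `"jc69"` (default) or `"p"`.
#' @return list of class `habidBootstrap`: `tree` (the point-estimate
#'   [ape::phylo] with `node.label` set to supports in `[0, 100]`),
#'   `supports`, `replicates`, `kept`, `skipped`, `seed`, `builder`,
#'   `model`.
#' @export
bootstrapSupport <- function(aln, builder = c("nj", "upgma"),
                             replicates = 500, seed, model = c("jc69", "p")) {
  builder <- match.arg(builder)
  model <- match.arg(model)
  if (replicates < 1) stopValidation("replicates must be >= 1")
  if (missing(seed)) stopValidation("a seed is required")
  m <- validateAlignment(aln, minTaxa = 3)
  point <- buildTree(m, builder, model)
  reps <- withr::with_seed(seed, {
    lapply(seq_len(replicates), function(i) {
      idx <- sample.int(ncol(m), ncol(m), replace = TRUE)
      tryCatch(buildTree(m[, idx, drop = FALSE], builder, model),
               habid_compute_error = function(e) NULL)
    })
  })
  skipped <- sum(vapply(reps, is.null, logical(1)))
  if (skipped > 0)
    warning(sprintf("%d of %d bootstrap replicate(s) skipped (degenerate resample)",
                    skipped, replicates))
  reps <- Filter(Negate(is.null), reps)
  kept <- length(reps)
  if (kept == 0) stopCompute("all bootstrap replicates failed")
  counts <- ape::prop.clades(point, reps, rooted = (builder == "upgma"))
  counts[is.na(counts)] <- 0
  supports <- counts / kept * 100
  point$node.label <- sprintf("%g", supports)
  structure(list(tree = point, supports = supports, replicates = replicates,
                 kept = kept, skipped = skipped, seed = seed,
                 builder = builder, model = model),
            class = "habidBootstrap")
}

#' @export
print.habidBootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap %s tree (%s distances): %d replicates (%d kept, %d skipped), seed %s\n",
              x$builder, x$model, x$replicates, x$kept, x$skipped,
              format(x$seed)))
  cat("supports:", paste(round(x$supports, 1), collapse = ", "), "\n")
  invisible(x)
}

## nontrivial splits of an unrooted tree, each canonicalized as the side
## not containing the first label of `labels`, encoded "a|b|c"
treeSplits <- function(tree, labels) {
  tree <- ape::unroot(tree)
  pp <- ape::prop.part(tree)
  out <- character()
  for (cl in pp) {
    side <- tree$tip.label[cl]
    if (labels[1] %in% side) side <- setdiff(labels, side)
    if (length(side) >= 2 && length(side) <= length(labels) - 2)
      out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Strict majority-rule consensus tree
#'
#' Tallies the nontrivial bipartitions of the input trees and keeps those
#' occurring in strictly more than `threshold` of them; bipartitions tied
#' exactly at the threshold are excluded. For `threshold >= 0.5` the kept
#' splits are mutually compatible and assemble into a unique
#' multifurcating tree, whose internal nodes are labelled with the
#' occurrence percentage of their split. Branch lengths are not assigned.
#'
#' @param trees list (or `multiPhylo`) of [ape::phylo] sharing one leaf
#'   set.
#' @param threshold fraction in `[0.5, 1)` (default 0.5, the classical
#'   majority rule).
#' @return a rooted-display multifurcating [ape::phylo] with `node.label`
#'   supports.
#' @export
majorityConsensus <- function(trees, threshold = 0.5) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) == 0) stopValidation("no trees supplied")
  if (threshold < 0.5 || threshold >= 1)
    stopValidation("threshold must lie in [0.5, 1)")
  labels <- sort(trees[[1]]$tip.label)
  for (tr in trees)
    if (!setequal(tr$tip.label, labels))
      stopValidation("all trees must share one leaf set")
  n <- length(trees)
  tallies <- table(unlist(lapply(trees, treeSplits, labels = labels)))
  keep <- tallies[tallies / n > threshold]
  clades <- lapply(names(keep), function(s) strsplit(s, "\\|")[[1]])
  pct <- as.numeric(keep) / n * 100
  ## assemble the laminar clade family into a Newick string; clades are
  ## nested-or-disjoint because each is supported by > half of the trees
  ord <- order(-lengths(clades))
  clades <- clades[ord]
  pct <- pct[ord]
  buildNode <- function(members, available) {
    ## available: indices of clades strictly inside `members` not yet used
    childIdx <- available[vapply(available, function(i)
      all(clades[[i]] %in% members) && length(clades[[i]]) < length(members),
      logical(1))]
    ## maximal clades among the candidates
    maximal <- childIdx[vapply(childIdx, function(i)
      !any(vapply(childIdx, function(j)
        j != i && all(clades[[i]] %in% clades[[j]]), logical(1))),
      logical(1))]
    taken <- unique(unlist(clades[maximal]))
    parts <- c(
      vapply(maximal, function(i)
        sprintf("%s%g", buildNode(clades[[i]], setdiff(childIdx, i)),
                pct[i]), character(1)),
      sort(setdiff(members, taken)))
    sprintf("(%s)", paste(parts, collapse = ","))
  }
  txt <- sprintf("%s;", buildNode(labels, seq_along(clades)))
  ape::read.tree(text = txt)
}

#' Read / write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] and [ape::write.tree()] with
#' strict error behaviour: malformed Newick raises a parse error rather
#' than returning `NULL`, and labels containing Newick metacharacters
#' (`():;,` or whitespace) are rejected on write. Bootstrap supports ride
#' along as internal node labels; branch lengths survive a round trip to
#' at least 6 significant digits.
#'
#' @param text Newick string (or `NULL` when reading from `path`).
#' @param path file path (optional for writing: when `NULL` the string is
#'   returned).
#' @param tree an [ape::phylo].
#' @return `readNewickTree()` returns an [ape::phylo];
#'   `writeNewickTree()` the Newick string (invisibly when written to
#'   file).
#' @export
readNewickTree <- function(text = NULL, path = NULL) {
  src <- if (!is.null(text)) text else {
    if (is.null(path)) stopValidation("supply text or path")
    if (!file.exists(path)) stopParse("Newick file not found: %s", path)
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  tr <- tryCatch(
    withCallingHandlers(ape::read.tree(text = src),
                        warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  if (is.null(tr)) stopParse("malformed Newick: %s",
                             substr(src, 1, 60))
  tr
}

#' @rdname readNewickTree
#' @export
writeNewickTree <- function(tree, path = NULL) {
  if (!inherits(tree, "phylo")) stopValidation("tree must be a phylo object")
  lab <- c(tree$tip.label, tree$node.label)
  bad <- grepl("[():;,'\"[:space:]]", lab) | grepl("\\[|\\]", lab)
  if (any(bad))
    stopValidation("labels contain Newick metacharacters: %s",
                   paste(lab[bad], collapse = ", "))
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
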