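## Lane-to-lane similarity and UPGMA dendrograms.

#' Binary similarity between gel lanes
#'
#' For lanes i and j let `a` be the number of bands present in both, `b`
#' and `c` the bands exclusive to i and to j, and `d` the joint absences.
#' Coefficients:
#' * `dice` = 2a / (2a + b + c) — the usual choice for dominant/binary
#'   fingerprint data (shared bands weighted double);
#' * `jaccard` = a / (a + b + c);
#' * `simple_matching` = (a + d) / (a + b + c + d) — the only one crediting
#'   joint absences.
#'
#' A pair of lanes with no presences at all has an undefined Dice/Jaccard
#' ratio and is defined here as similarity 0; the diagonal is always 1.
#'
#' @param x a [BandMatrix-class].
#' @param coefficient `"dice"` (default), `"jaccard"` or
#'   `"simple_matching"`.
#' @return a [SimilarityMatrix-class].
#' @examples
#' gel <- bandTable(lane_id = rep(c("i", "j"), each = 3),
#'                  mw_kda = c(50, 30, 20, 30, 20, 10), intensity_pct = 1)
#' similarityValues(similarityMatrix(matchBands(gel)))          # dice 2/3
#' similarityValues(similarityMatrix(matchBands(gel), "jaccard"))  # 1/2
#' @export
similarityMatrix <- function(x, coefficient = c("dice", "jaccard",
                                                "simple_matching")) {
  stopifnot(is(x, "BandMatrix"))
  coefficient <- match.arg(coefficient)
  p <- x@presence
  nlane <- ncol(p)
  a <- crossprod(p)                       # shared presences
  tot <- diag(a)                          # presences per lane
  v <- matrix(0, nlane, nlane, dimnames = dimnames(a))
  for (i in seq_len(nlane)) for (j in seq_len(nlane)) {
    aa <- a[i, j]; bb <- tot[i] - aa; cc <- tot[j] - aa
    dd <- nrow(p) - aa - bb - cc
    v[i, j] <- switch(coefficient,
      dice = if (2 * aa + bb + cc == 0) 0 else 2 * aa / (2 * aa + bb + cc),
      jaccard = if (aa + bb + cc == 0) 0 else aa / (aa + bb + cc),
      simple_matching = (aa + dd) / nrow(p))
  }
  diag(v) <- 1
  new("SimilarityMatrix", values = v, coefficient = coefficient)
}

#' UPGMA dendrogram from a similarity matrix
#'
#' Agglomerative average-linkage clustering on the distance
#' `1 - similarity`: the two most similar lanes merge first, at height
#' equal to their distance, and heights are non-decreasing up the tree.
#' Labels are sorted lexicographically before clustering so that ties break
#' deterministically across platforms.
#'
#' @param sim a [SimilarityMatrix-class].
#' @return an [stats::hclust] object whose merge heights are
#'   `1 - similarity`; [stats::cophenetic()] applies, and
#'   [copheneticSimilarity()] returns the implied pairwise similarities.
#' @seealso [dendrogramNewick()] for Newick export, [upgmaTree()] for the
#'   substitutions-per-site variant used on sequence distances.
#' @export
upgmaDendrogram <- function(sim) {
  stopifnot(is(sim, "SimilarityMatrix"))
  v <- sim@values
  ord <- order(rownames(v))
  d <- as.dist(1 - v[ord, ord])
  hclust(d, method = "average")
}

#' @rdname upgmaDendrogram
#' @param dend an [stats::hclust] from `upgmaDendrogram()`.
#' @export
copheneticSimilarity <- function(dend) {
  1 - as.matrix(cophenetic(dend))
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are taken from the merge heights (leaf depth equals the
#' height at which the leaf's cluster merges), so the tree stays
#' ultrametric with root depth `1 - min(similarity at root merge)`.
#'
#' @param dend an [stats::hclust] from [upgmaDendrogram()].
#' @param path optional file; when `NULL` the Newick string is returned.
#' @return Newick string (invisibly when written to file).
#' @export
dendrogramNewick <- function(dend, path = NULL) {
  phy <- ape::as.phylo(dend)
  ## as.phylo.hclust halves merge heights into branch lengths; restore the
  ## 1 - similarity height scale
  phy$edge.length <- phy$edge.length * 2
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Write a similarity matrix as square CSV
#'
#' @param sim a [SimilarityMatrix-class].
#' @param path file path.
#' @param header optional comment lines (prefixed `# `; the coefficient tag
#'   is always recorded).
#' @return `path`, invisibly.
#' @export
writeSimilarityMatrix <- function(sim, path, header = NULL) {
  stopifnot(is(sim, "SimilarityMatrix"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste("#", c(sprintf("coefficient: %s", sim@coefficient),
                          header)), con)
  write.csv(data.frame(lane = rownames(sim@values), sim@values,
                       check.names = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
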