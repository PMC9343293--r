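test_that("JC69 transform is exact, monotone, and errors at saturation", {
  expect_equal(jc69Distance(0.3), -0.75 * log(0.6), tolerance = 1e-15)
  expect_equal(jc69Distance(0), 0)
  expect_error(jc69Distance(0.75), class = "habid_compute_error")
  p <- seq(0.01, 0.74, by = 0.01)
  d <- jc69Distance(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("pairwise distances use pairwise deletion of gapped/ambiguous sites", {
  aln <- c(s1 = "ACGTACGT", s2 = "ACGAACGA", s3 = "ACGT-CGN")
  d <- pairwiseDistance(aln, model = "p")
  m <- as.matrix(d)
  expect_equal(m["s1", "s2"], 2 / 8)
  expect_equal(m["s1", "s3"], 0 / 6)    # gap and N columns dropped
  expect_equal(m["s2", "s3"], 1 / 6)
  expect_equal(attr(d, "model"), "p")

  dj <- pairwiseDistance(aln, model = "jc69")
  expect_equal(as.matrix(dj)["s1", "s2"], jc69Distance(0.25))
  expect_equal(as.matrix(dj)["s1", "s1"], 0)

  ## identical rows have distance 0 under both models
  same <- c(a = "ACGT", b = "ACGT")
  expect_equal(as.vector(pairwiseDistance(same, "p")), 0)
  expect_equal(as.vector(pairwiseDistance(same, "jc69")), 0)

  ## saturation and zero-overlap errors
  expect_error(pairwiseDistance(c(a = "ACGT", b = "TGCA"), model = "jc69"),
               class = "habid_compute_error")
  expect_error(pairwiseDistance(c(a = "NNNN", b = "ACGT"), model = "p"),
               class = "habid_compute_error")
  expect_error(validateAlignment(c(a = "ACGT", b = "ACG")),
               class = "habid_validation_error")
})

test_that("NJ recovers additive matrices exactly (consistency)", {
  withr::with_seed(41, {
    for (rep in 1:100) {
      tr <- randomAdditiveTree(sample(4:8, 1))
      dm <- cophenetic(tr)
      nj <- neighborJoining(dm)
      expect_equal(ape::dist.topo(tr, nj), 0, ignore_attr = TRUE)
      got <- cophenetic(nj)[rownames(dm), colnames(dm)]
      expect_lt(max(abs(got - dm)), 1e-9)
    }
  })
})

test_that("three-taxon NJ solves the closed-form star lengths", {
  m <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighborJoining(m)
  len <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                       tr$edge[, 2])], tr$tip.label)
  expect_equal(len[["a"]], (3 + 4 - 5) / 2)
  expect_equal(len[["b"]], (3 + 5 - 4) / 2)
  expect_equal(len[["c"]], (4 + 5 - 3) / 2)
  expect_error(neighborJoining(m[1:2, 1:2]),
               class = "habid_validation_error")
})

test_that("UPGMA tree halves heights, matches the oracle, and agrees with NJ on ultrametric input", {
  ## 2-taxon cherry at height d/2
  m2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- upgmaTree(m2)
  expect_equal(sort(t2$edge.length), c(0.15, 0.15))

  withr::with_seed(43, {
    for (rep in 1:15) {
      n <- 6
      labs <- sprintf("t%d", 1:n)
      d <- matrix(0, n, n, dimnames = list(labs, labs))
      d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.05, 0.6)
      d <- d + t(d)
      tu <- upgmaTree(d)
      expect_equal(as.matrix(cophenetic(tu))[labs, labs],
                   oracleUpgmaCophenetic(d), tolerance = 1e-12)
    }
  })

  ## ultrametric input: cophenetic reproduction and NJ/UPGMA agreement
  u <- matrix(c(0, 0.1, 0.5, 0.5,
                0.1, 0, 0.5, 0.5,
                0.5, 0.5, 0, 0.2,
                0.5, 0.5, 0.2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tu <- upgmaTree(u)
  expect_equal(as.matrix(cophenetic(tu))[letters[1:4], letters[1:4]], u,
               tolerance = 1e-12)
  nj <- neighborJoining(u)
  expect_equal(ape::dist.topo(ape::unroot(tu), nj), 0, ignore_attr = TRUE)
})

test_that("Fitch score matches forced cases and the exhaustive oracle", {
  tr <- readNewickTree(text = "((t1,t2),(t3,t4));")
  same <- matrix("A", 4, 5, dimnames = list(sprintf("t%d", 1:4), NULL))
  expect_equal(fitchScore(same, tr), 0L)

  one <- matrix(c("A", "A", "C", "C"), 4, 1,
                dimnames = list(sprintf("t%d", 1:4), NULL))
  expect_equal(fitchScore(one, tr), 1L)

  withr::with_seed(47, {
    for (rep in 1:100) {
      tree <- ape::rtree(5)
      aln <- matrix(sample(c("A", "C", "G", "T", "N", "-"), 50,
                           replace = TRUE,
                           prob = c(rep(0.225, 4), 0.05, 0.05)),
                    nrow = 5, dimnames = list(tree$tip.label, NULL))
      expect_equal(fitchScore(aln, tree), oracleFitchScore(aln, tree),
                   info = paste("rep", rep))
    }
  })

  bad <- matrix("A", 4, 2, dimnames = list(sprintf("x%d", 1:4), NULL))
  expect_error(fitchScore(bad, tr), class = "habid_validation_error")
})

test_that("bootstrap supports are seeded, bounded, and degenerate cases behave", {
  ## every column supports the same split: support 100
  aln <- conflictAlignment(40, 0)
  bs <- bootstrapSupport(aln, replicates = 25, seed = 2, model = "p")
  expect_true(all(bs$supports >= 0 & bs$supports <= 100))
  expect_equal(unname(splitSupport(bs, c("A", "B"))), 100)

  ## one replicate: supports all 0 or 100
  one <- bootstrapSupport(conflictAlignment(30, 10), replicates = 1,
                          seed = 9, model = "p")
  expect_true(all(one$supports %in% c(0, 100)))

  ## fixed seed fixes every support; different seed may differ
  mixed <- conflictAlignment(30, 20)
  b1 <- bootstrapSupport(mixed, replicates = 40, seed = 7, model = "p")
  b2 <- bootstrapSupport(mixed, replicates = 40, seed = 7, model = "p")
  expect_identical(b1$supports, b2$supports)
  expect_identical(writeNewickTree(b1$tree), writeNewickTree(b2$tree))
})

test_that("majority consensus keeps exactly the splits the tally oracle finds", {
  tAB <- readNewickTree(text = "((A,B),(C,D));")
  tAC <- readNewickTree(text = "((A,C),(B,D));")
  ## identical trees: the tree itself, support 100
  cons <- majorityConsensus(list(tAB, tAB, tAB))
  expect_setequal(oracleTreeSplits(cons), oracleTreeSplits(tAB))
  expect_true(all(as.numeric(cons$node.label[nzchar(cons$node.label)]) == 100))

  ## 2 of 3 agree on the only split of four: kept at 66.7
  cons2 <- majorityConsensus(list(tAB, tAB, tAC))
  expect_setequal(oracleTreeSplits(cons2), oracleTreeSplits(tAB))

  ## an exact 50/50 tie is excluded: star
  cons3 <- majorityConsensus(list(tAB, tAC))
  expect_length(oracleTreeSplits(cons3), 0)

  ## random 7-leaf tree sets against brute-force bipartition counting
  withr::with_seed(53, {
    for (rep in 1:20) {
      trees <- lapply(1:5, function(i) ape::rtree(7,
        tip.label = sprintf("s%d", 1:7)))
      cons <- majorityConsensus(trees)
      tally <- table(unlist(lapply(trees, oracleTreeSplits)))
      expected <- names(tally[tally / 5 > 0.5])
      expect_setequal(oracleTreeSplits(cons), expected)
    }
  })

  bad <- readNewickTree(text = "((A,B),(C,E));")
  expect_error(majorityConsensus(list(tAB, bad)),
               class = "habid_validation_error")
  expect_error(majorityConsensus(list(tAB), threshold = 0.4),
               class = "habid_validation_error")
})

test_that("Newick IO round-trips trees and rejects malformed input", {
  cherry <- readNewickTree(text = "(A:0.1,B:0.1);")
  expect_equal(sort(cherry$tip.label), c("A", "B"))
  expect_equal(sort(cherry$edge.length), c(0.1, 0.1))

  withr::with_seed(59, {
    for (rep in 1:100) {
      tr <- ape::rtree(sample(3:10, 1))
      back <- readNewickTree(text = writeNewickTree(tr))
      expect_true(ape::all.equal.phylo(tr, back, use.edge.length = FALSE))
      d1 <- cophenetic(tr); d2 <- cophenetic(back)[rownames(d1), colnames(d1)]
      expect_lt(max(abs(d1 - d2)), 1e-6 * max(d1))
    }
  })

  ## supports serialized as node labels survive the round trip
  aln <- conflictAlignment(30, 10)
  bs <- bootstrapSupport(aln, replicates = 20, seed = 3, model = "p")
  back <- readNewickTree(text = writeNewickTree(bs$tree))
  expect_equal(sort(back$node.label), sort(bs$tree$node.label))

  expect_error(readNewickTree(text = "((A,B,(C);"),
               class = "habid_parse_error")
  colon <- readNewickTree(text = "(A,B);")
  colon$tip.label[1] <- "bad:label"
  expect_error(writeNewickTree(colon), class = "habid_validation_error")
})
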