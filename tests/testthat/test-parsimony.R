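mat4 <- function(cols) {
  M <- do.call(cbind, cols)
  rownames(M) <- paste0("t", seq_len(nrow(M)))
  M
}

test_that("fitch_score matches hand-executable cases", {
  # single column A,A,T,T over the two 4-taxon topologies
  M <- mat4(list(c("A", "A", "T", "T")))
  good <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  bad <- ape::read.tree(text = "((t1,t3),(t2,t4));")
  expect_equal(fitch_score(good, M), 1L)
  expect_equal(fitch_score(bad, M), 2L)
  # invariant matrix scores zero
  Mi <- mat4(list(c("C", "C", "C", "C"), c("G", "G", "G", "G")))
  expect_equal(fitch_score(good, Mi), 0L)
  # gaps are wildcards, never forcing a change
  Mg <- mat4(list(c("A", "-", "T", "T")))
  expect_equal(fitch_score(good, Mg), 1L)
  expect_equal(fitch_score(ape::read.tree(text = "((t1,t4),(t2,t3));"),
                           Mg), 1L)
  expect_error(fitch_score(good, mat4(list(c("A", "A", "T")))),
               "taxa differ")
})

test_that("fitch_score is invariant to rooting and leaf order", {
  set.seed(6)
  M <- matrix(sample(c(BASES, "-"), 5 * 40, replace = TRUE,
                     prob = c(rep(0.23, 4), 0.08)), nrow = 5)
  rownames(M) <- paste0("t", 1:5)
  tr <- ape::read.tree(text = "((t1,t2),(t3,(t4,t5)));")
  s0 <- fitch_score(tr, M)
  for (og in paste0("t", 2:5)) {
    rerooted <- ape::root(ape::unroot(tr), outgroup = og,
                          resolve.root = TRUE)
    expect_equal(fitch_score(rerooted, M), s0)
  }
  expect_equal(fitch_score(tr, M[sample(5), , drop = FALSE]), s0)
})

test_that("fitch_score equals the exhaustive labeling oracle", {
  set.seed(61)
  for (n in c(4, 5, 6)) {
    M <- matrix(sample(c(BASES, "-"), n * 25, replace = TRUE,
                       prob = c(rep(0.22, 4), 0.12)), nrow = n)
    rownames(M) <- paste0("t", seq_len(n))
    trees <- enumerate_topologies(rownames(M))
    for (tr in trees[unique(round(seq(1, length(trees),
                                      length.out = 4)))]) {
      expect_equal(fitch_score(tr, M), oracle_parsimony(tr, M))
    }
  }
})

test_that("fitch_score agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(62)
  M <- matrix(sample(BASES, 6 * 80, replace = TRUE), nrow = 6)
  rownames(M) <- paste0("t", 1:6)
  pd <- phangorn::phyDat(M, type = "DNA")
  for (i in 1:4) {
    tr <- ape::rtree(6, tip.label = sample(rownames(M)))
    expect_equal(fitch_score(tr, M),
                 as.integer(phangorn::fitch(ape::unroot(tr), pd)))
  }
})

test_that("topology enumeration counts (2n-5)!! distinct trees", {
  expect_equal(length(enumerate_topologies(paste0("t", 1:4))), 3L)
  expect_equal(length(enumerate_topologies(paste0("t", 1:5))), 15L)
  t7 <- enumerate_topologies(paste0("t", 1:7))
  expect_equal(length(t7), 945L)
  # all 15 five-taxon topologies are pairwise distinct
  t5 <- enumerate_topologies(paste0("t", 1:5))
  for (i in 1:14) for (j in (i + 1):15) {
    expect_gt(ape::dist.topo(t5[[i]], t5[[j]]), 0)
  }
  expect_error(enumerate_topologies(paste0("t", 1:10)), "limited to 9")
})

test_that("exhaustive search finds the optimum and all ties", {
  set.seed(63)
  M <- matrix(sample(BASES, 6 * 30, replace = TRUE), nrow = 6)
  rownames(M) <- paste0("t", 1:6)
  mp <- exhaustive_mp(M)
  expect_equal(mp$n_topologies, 105L)
  expect_equal(mp$score, min(mp$scores))
  expect_equal(length(mp$trees), sum(mp$scores == mp$score))
  # best score is a lower bound for any supplied tree
  for (i in 1:5) {
    expect_lte(mp$score, fitch_score(ape::rtree(6,
      tip.label = rownames(M)), M))
  }
})

test_that("neighbor joining recovers additive distances exactly", {
  # distances generated on a known tree with positive branch lengths
  tree <- ape::read.tree(
    text = "((t1:0.1,t2:0.2):0.15,(t3:0.12,t4:0.08):0.1,t5:0.3);")
  D <- ape::cophenetic.phylo(tree)
  nj <- cphotspot:::nj_from_dist(D[paste0("t", 1:5), paste0("t", 1:5)],
                                 paste0("t", 1:5))
  expect_equal(ape::dist.topo(ape::unroot(nj), ape::unroot(tree)), 0,
               ignore_attr = TRUE)
  # and the tree module agrees with the reference NJ implementation
  set.seed(64)
  M <- matrix(sample(BASES, 6 * 200, replace = TRUE), nrow = 6)
  rownames(M) <- paste0("t", 1:6)
  mine <- nj_tree(M)
  ref <- ape::nj(ape::dist.dna(ape::as.DNAbin(M), model = "raw",
                               pairwise.deletion = TRUE))
  expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
  # degenerate identical sequences resolve with zero branch lengths
  Mi <- matrix("A", nrow = 4, ncol = 20)
  rownames(Mi) <- paste0("t", 1:4)
  njd <- nj_tree(Mi)
  expect_equal(sum(njd$edge.length), 0)
  expect_error(nj_tree(Mi[1:3, ]), "at least 4")
})

test_that("p-distances use pairwise deletion", {
  M <- rbind(t1 = c("A", "A", "A", "A"),
             t2 = c("A", "-", "T", "T"),
             t3 = c("A", "C", "N", "T"),
             t4 = c("A", "A", "A", "A"))
  D <- p_distance(M)
  expect_equal(D["t1", "t2"], 2 / 3)
  expect_equal(D["t2", "t3"], 0)       # shared unambiguous sites: 1, 4
  Mz <- rbind(t1 = c("A", "-"), t2 = c("-", "A"))
  expect_error(p_distance(Mz), "no comparable")
})

test_that("bootstrap consensus is deterministic with sensible supports", {
  # every column supports the same split -> support 100, one edge
  M <- mat4(list(c("A", "A", "T", "T"), c("C", "C", "G", "G"),
                 c("A", "A", "C", "C"), c("T", "T", "A", "A")))
  for (method in c("mp", "nj")) {
    cons <- bootstrap_consensus(M, method, replicates = 50, seed = 2)
    expect_equal(resolution(cons)$resolved_edges, 1L)
    sp <- attr(cons, "splits")
    expect_equal(sp$support[1], 100)
  }
  # zero variation -> star consensus
  Mi <- matrix("G", nrow = 5, ncol = 30)
  rownames(Mi) <- paste0("t", 1:5)
  star <- bootstrap_consensus(Mi, "nj", replicates = 30, seed = 3)
  expect_equal(resolution(star)$resolved_edges, 0L)
  expect_false(resolution(star)$fully_resolved)
  # fixed seed -> byte-identical Newick
  set.seed(65)
  Mr <- matrix(sample(BASES, 6 * 60, replace = TRUE), nrow = 6)
  rownames(Mr) <- paste0("t", 1:6)
  a <- bootstrap_consensus(Mr, "mp", replicates = 40, seed = 11)
  b <- bootstrap_consensus(Mr, "mp", replicates = 40, seed = 11)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  expect_error(bootstrap_consensus(Mr, "mp", replicates = 0, seed = 1),
               "positive integer")
})

test_that("resolution counts internal edges against the n-3 maximum", {
  full <- ape::read.tree(text = "((t1,t2),((t3,t4),(t5,t6)),t7);")
  r <- resolution(full)
  expect_equal(r$resolved_edges, 4L)
  expect_equal(r$max_edges, 4L)
  expect_true(r$fully_resolved)
  star <- ape::read.tree(text = "(t1,t2,t3,t4,t5,t6,t7);")
  rs <- resolution(star)
  expect_equal(rs$resolved_edges, 0L)
  expect_false(rs$fully_resolved)
})

test_that("two individually weak loci can resolve a tree jointly", {
  # each locus carries clean signal for a different part of the tree
  tree <- ape::read.tree(text = "(((t1,t2),t3),((t4,t5),t6),t7);")
  half1 <- sim_matrix_on_tree(tree, 120, 0.0, seed = 71)  # constant
  # locus A: informative only about (t1,t2) and (t1,t2,t3)
  lA <- half1
  lA[c("t1", "t2"), 1:12] <- "T"
  lA[c("t1", "t2", "t3"), 13:24] <- matrix("G", 3, 12)
  # locus B: informative only about (t4,t5) and (t4,t5,t6)
  lB <- half1
  lB[c("t4", "t5"), 25:36] <- "C"
  lB[c("t4", "t5", "t6"), 37:48] <- matrix("A", 3, 12)
  rA <- resolution(bootstrap_consensus(lA, "mp", 60, seed = 4))
  rB <- resolution(bootstrap_consensus(lB, "mp", 60, seed = 4))
  rAB <- resolution(bootstrap_consensus(cbind(lA, lB), "mp", 60, seed = 4))
  expect_false(rA$fully_resolved)
  expect_false(rB$fully_resolved)
  expect_true(rAB$fully_resolved)
  expect_gt(rAB$resolved_edges, max(rA$resolved_edges, rB$resolved_edges))
})
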