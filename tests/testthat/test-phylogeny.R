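# Alignments, p-distance, neighbour joining, bootstrap, topology recovery.

test_that("complete deletion removes exactly the gapped columns", {
  aln <- as_alignment(c(a = "AC-T", b = "ACGT"))
  out <- complete_deletion(aln)
  expect_equal(ncol(out), 3)
  expect_equal(paste(out["a", ], collapse = ""), "ACT")
  # gapless alignment unchanged; idempotent
  g <- as_alignment(c(a = "ACDE", b = "ACDF"))
  expect_identical(complete_deletion(g), g)
  expect_identical(complete_deletion(complete_deletion(aln)), out)
  # every column gapped somewhere
  allgap <- as_alignment(c(a = "-C", b = "A-"))
  expect_error(complete_deletion(allgap), "every column")
})

test_that("p-distance counts mismatched sites", {
  aln <- as_alignment(c(x = "ACDEF", y = "ACDFF"))
  d <- p_distance(aln)
  expect_equal(d["x", "y"], 0.2)
  expect_equal(attr(d, "sites_used"), 5)
  expect_equal(unname(diag(d)), c(0, 0))
  expect_error(p_distance(as_alignment(c(a = "A-", b = "AA"))), "gaps")

  # independent naive recount on random pairs
  set.seed(12)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    a <- strsplit(rand_seq(n), "")[[1]]
    b <- strsplit(rand_seq(n), "")[[1]]
    naive <- sum(a != b) / n
    d2 <- p_distance(rbind(a = a, b = b))
    expect_equal(unname(d2["a", "b"]), naive)
  }
})

test_that("NJ reproduces additive 4-taxon trees exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)); distances by path sums
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(D)
  expect_equal(max(abs(ape::cophenetic.phylo(tr)[rownames(D), rownames(D)] - D)),
               0, tolerance = 1e-9)
  true <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  expect_equal(topology_recovery(tr, true), 1)
})

test_that("NJ on 3 taxa uses the three-point closed form", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(len[["a"]], (2 + 3 - 4) / 2)
  expect_equal(len[["b"]], (2 + 4 - 3) / 2)
  expect_equal(len[["c"]], (3 + 4 - 2) / 2)
})

test_that("NJ recovers random additive trees and agrees with ape's NJ", {
  set.seed(9)
  for (i in 1:50) {
    ra <- random_additive(6)
    tr <- nj_tree(ra$d)
    expect_equal(topology_recovery(tr, ra$tree), 1)
    expect_lt(max(abs(ape::cophenetic.phylo(tr)[rownames(ra$d), rownames(ra$d)]
                      - ra$d)), 1e-9)
    # independent implementation cross-check
    expect_equal(phangorn::RF.dist(tr, ape::nj(ra$d)), 0)
  }
})

test_that("degenerate distance input is rejected", {
  D <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(nj_tree(D), "at least 3")
  D3 <- matrix(c(0, 1, 2, 1, 0, -1, 2, -1, 0), 3, 3)
  expect_error(nj_tree(D3), "negative")
  D4 <- matrix(runif(9), 3, 3); diag(D4) <- 0
  expect_error(nj_tree(D4), "symmetric")
})

test_that("bootstrap is deterministic, bounded and edge-case safe", {
  aln <- perfect_alignment()
  b1 <- nj_bootstrap(aln, replicates = 30, seed = 11)
  b2 <- nj_bootstrap(aln, replicates = 30, seed = 11)
  expect_identical(attr(b1, "support"), attr(b2, "support"))
  expect_true(all(attr(b1, "support") >= 0 & attr(b1, "support") <= 100))
  # single replicate: supports are 0 or 100
  b3 <- nj_bootstrap(aln, replicates = 1, seed = 2)
  expect_true(all(attr(b3, "support") %in% c(0, 100)))
  expect_error(nj_bootstrap(aln, replicates = 0), ">= 1")
})

test_that("perfect phylogenetic signal yields 100% support everywhere", {
  b <- nj_bootstrap(perfect_alignment(), replicates = 50, seed = 7)
  expect_true(all(attr(b, "support") == 100))
})

test_that("bootstrap supports are invariant to taxa input order", {
  aln <- perfect_alignment()
  b1 <- nj_bootstrap(aln, replicates = 40, seed = 13)
  set.seed(99)
  for (i in 1:10) {
    perm <- sample(nrow(aln))
    b2 <- nj_bootstrap(aln[perm, , drop = FALSE], replicates = 40, seed = 13)
    expect_equal(phangorn::RF.dist(b1, b2), 0)
    expect_equal(sort(attr(b2, "support")), sort(attr(b1, "support")))
  }
})

test_that("topology recovery approaches 1 as the mutation rate vanishes", {
  tr <- ape::read.tree(text = paste0(
    "(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1);"))
  fam_lo <- make_family(tr, rate = 0.02, seed = 21)
  expect_equal(topology_recovery(infer_nj_test(fam_lo$alignment), tr), 1)
  # saturation destroys most of the signal
  fam_hi <- make_family(tr, rate = 50, seed = 21)
  rec_hi <- topology_recovery(infer_nj_test(fam_hi$alignment), tr)
  expect_lt(rec_hi, 1)
})

test_that("three well-separated simulated clades come out monophyletic", {
  tr <- ape::read.tree(text = paste0(
    "((A1:0.2,A2:0.2):3,(B1:0.2,B2:0.2):3,(C1:0.2,C2:0.2):3);"))
  fam <- make_family(tr, rate = 0.3, seed = 31)
  inf <- infer_nj_test(fam$alignment)
  for (cl in list(c("A1", "A2"), c("B1", "B2"), c("C1", "C2")))
    expect_true(ape::is.monophyletic(inf, cl))
})

test_that("newick and distance-matrix output round-trip", {
  ra <- random_additive(5)
  tr <- nj_tree(ra$d)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_equal(phangorn::RF.dist(back, tr), 0)
  ftsv <- withr::local_tempfile(fileext = ".tsv")
  write_distance_tsv(ra$d, ftsv)
  expect_equal(readLines(ftsv)[1], "5")
})
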