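# Progressive alignment, neighbor joining, bootstrap supports and
# anchor-based subgroup assignment.

test_that("identical sequences align gaplessly", {
  aln <- progressive_align(c(a = "ACGTACGT", b = "ACGTACGT"), mode = "nt")
  expect_equal(aln$rows, c("ACGTACGT", "ACGTACGT"))
})

test_that("a single-gap pair matches the Needleman-Wunsch optimum", {
  aln <- progressive_align(c(a = "ACGT", b = "ACGGT"), mode = "nt")
  expect_equal(sum(strsplit(aln$rows[1], "")[[1]] == "-"), 1)
  # recompute the score of the produced alignment and compare to the oracle
  r1 <- strsplit(aln$rows[1], "")[[1]]; r2 <- strsplit(aln$rows[2], "")[[1]]
  sc <- 0; in_gap <- FALSE
  for (i in seq_along(r1)) {
    if (r1[i] == "-" || r2[i] == "-") {
      sc <- sc - ifelse(in_gap, 2, 7); in_gap <- TRUE
    } else {
      sc <- sc + ifelse(r1[i] == r2[i], 2, -3); in_gap <- FALSE
    }
  }
  expect_equal(sc, oracle_nw_score("ACGT", "ACGGT"))
})

test_that("codon-mode alignment never splits a triplet", {
  withr::local_seed(41)
  for (rep in 1:5) {
    seqs <- stats::setNames(
      vapply(1:5, function(i) random_codons(sample(30:40, 1)), character(1)),
      paste0("s", 1:5))
    aln <- progressive_align(seqs, mode = "codon")
    expect_true(aln$is_codon_aligned)
    for (r in aln$rows) {
      expect_equal(nchar(r) %% 3, 0)
      cods <- substring(r, seq(1, nchar(r) - 2, 3), seq(3, nchar(r), 3))
      # every codon is either an intact triplet or a full gap triplet
      expect_true(all(!grepl("-", cods) | cods == "---"))
      expect_equal(gsub("-", "", r), seqs[[aln$names[match(r, aln$rows)]]])
    }
  }
})

test_that("p-distances agree with ape::dist.dna on ungapped data", {
  withr::local_seed(55)
  seqs <- vapply(1:6, function(i) mutate_seq(random_codons(50), 0.1),
                 character(1))
  names(seqs) <- paste0("t", 1:6)
  aln <- fam_alignment(names(seqs), unname(seqs))
  D <- aln_dist(aln, "p")
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
  Dape <- as.matrix(ape::dist.dna(bin, model = "raw"))
  expect_equal(unname(D), unname(Dape[rownames(D), colnames(D)]),
               tolerance = 1e-12)
  DJC <- aln_dist(aln, "JC")
  DapeJC <- as.matrix(ape::dist.dna(bin, model = "JC69"))
  expect_equal(unname(DJC), unname(DapeJC[rownames(D), colnames(D)]),
               tolerance = 1e-12)
})

test_that("three-taxon NJ reproduces the closed-form branch lengths", {
  D <- matrix(c(0, 0.2, 0.4, 0.2, 0, 0.4, 0.4, 0.4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["A"]), 0.1, tolerance = 1e-12)
  expect_equal(unname(bl["B"]), 0.1, tolerance = 1e-12)
  expect_equal(unname(bl["C"]), 0.3, tolerance = 1e-12)
})

test_that("NJ recovers random additive topologies exactly", {
  skip_if_not_installed("phangorn")
  withr::local_seed(61)
  for (n in c(6, 9, 12)) {
    for (rep in 1:5) {
      tr <- ape::rtree(n)
      D <- ape::cophenetic.phylo(tr)
      rec <- nj_tree(D)
      expect_equal(phangorn::RF.dist(ape::unroot(tr), rec), 0)
    }
  }
})

test_that("degenerate equal distances give zero internal branches", {
  D <- matrix(0.4, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  tr <- suppressMessages(nj_tree(D))
  internal <- tr$edge[, 2] > length(tr$tip.label)
  expect_true(all(tr$edge.length[internal] < 1e-9))
})

test_that("invalid distance matrices are rejected", {
  D <- matrix(c(0, NA, NA, 0), 2, 2)
  expect_error(nj_tree(D), "NA")
  D2 <- matrix(c(0, -0.1, -0.1, 0), 2, 2)
  expect_error(nj_tree(D2), "negative")
})

test_that("bootstrap separates clearly distinct clades with high support", {
  withr::local_seed(71)
  anc1 <- random_codons(100)
  anc2 <- mutate_seq(anc1, 0.3)
  seqs <- c(
    stats::setNames(vapply(1:4, function(i) mutate_seq(anc1, 0.02),
                           character(1)), paste0("a", 1:4)),
    stats::setNames(vapply(1:4, function(i) mutate_seq(anc2, 0.02),
                           character(1)), paste0("b", 1:4)))
  aln <- fam_alignment(names(seqs), unname(seqs))
  tr <- bootstrap_support(aln, n_replicates = 100, seed = 5)
  sup <- attr(tr, "supports")
  # the a/b split is an internal edge; its support must be near 1
  expect_gte(max(sup, na.rm = TRUE), 0.95)
  expect_error(bootstrap_support(aln, n_replicates = 0), "n_replicates")
})

test_that("bootstrap supports are invariant to leaf order", {
  withr::local_seed(72)
  seqs <- vapply(1:6, function(i) mutate_seq(random_codons(60), 0.08),
                 character(1))
  names(seqs) <- paste0("t", 1:6)
  a1 <- fam_alignment(names(seqs), unname(seqs))
  perm <- c(4, 2, 6, 1, 3, 5)
  a2 <- fam_alignment(names(seqs)[perm], unname(seqs)[perm])
  t1 <- bootstrap_support(a1, n_replicates = 50, seed = 9)
  t2 <- bootstrap_support(a2, n_replicates = 50, seed = 9)
  expect_equal(sort(attr(t1, "supports")), sort(attr(t2, "supports")))
})

test_that("subgroup labels follow the nearest anchor and survive re-rooting", {
  withr::local_seed(81)
  ancs <- list(CEACAM = random_codons(100))
  ancs$PSGI <- mutate_seq(ancs$CEACAM, 0.3)
  ancs$PSGII <- mutate_seq(ancs$CEACAM, 0.3)
  seqs <- character(0); truth <- character(0)
  for (grp in names(ancs)) {
    for (i in 1:5) {
      nm <- sprintf("%s_%d", grp, i)
      seqs[nm] <- mutate_seq(ancs[[grp]], 0.05)
      truth[nm] <- grp
    }
  }
  aln <- progressive_align(seqs, mode = "nt")
  tr <- nj_tree(aln_dist(aln, "p"))
  anchors <- c(CEACAM = "CEACAM_1", PSGI = "PSGI_1", PSGII = "PSGII_1")
  sg <- assign_subgroups(tr, anchors)
  expect_gte(mean(sg$labels[names(truth)] == truth), 0.95)
  expect_true(all(sg$monophyletic))
  # anchor leaves label themselves
  expect_equal(unname(sg$labels["PSGI_1"]), "PSGI")
  # re-rooting does not change labels
  tr2 <- ape::root(tr, outgroup = "PSGII_3", resolve.root = TRUE)
  sg2 <- assign_subgroups(tr2, anchors)
  expect_equal(sg2$labels[names(sg$labels)], sg$labels)
  expect_error(assign_subgroups(tr, c(X = "missing_leaf")), "anchor leaf")
})
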