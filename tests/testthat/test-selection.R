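# Nei-Gojobori counting core, pairwise dN/dS, SLAC-style tree counting and
# cumulative substitution profiles.

test_that("site counts match hand enumeration for canonical codons", {
  expect_equal(ng86_site_counts("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(ng86_site_counts("GGG"), c(s = 1, n = 2))
  expect_equal(ng86_site_counts("ATG"), c(s = 0, n = 3))
  expect_error(ng86_site_counts("TAA"), "sense codon")
})

test_that("pair counts average over stop-avoiding pathways", {
  expect_equal(ng86_pair_counts("GGG", "GGA"), c(Sd = 1, Nd = 0))
  expect_equal(ng86_pair_counts("TTT", "TTA"), c(Sd = 0, Nd = 1))
  expect_equal(ng86_pair_counts("TTT", "GTA"), c(Sd = 0.5, Nd = 1.5))
  expect_equal(ng86_pair_counts("AAA", "AAA"), c(Sd = 0, Nd = 0))
  expect_error(ng86_pair_counts("TAA", "GGG"), "stop")
})

test_that("pairwise dN/dS reproduces the closed-form example", {
  res <- pairwise_dnds(c(a = "GGGGGG", b = "GGAGGG"))
  expect_equal(res$Sd, 1)
  expect_equal(res$Nd, 0)
  expect_equal(res$S, 2)
  expect_equal(res$pS, 0.5)
  expect_equal(res$dS, -0.75 * log(1 - 2 / 3), tolerance = 1e-12)
  expect_equal(res$dN, 0)
  expect_equal(res$dnds, 0)
})

test_that("identical rows give zero distances and an undefined ratio", {
  res <- pairwise_dnds(c(a = "ATGGCC", b = "ATGGCC"))
  expect_equal(res$dS, 0)
  expect_equal(res$dN, 0)
  expect_true(is.na(res$dnds))
})

test_that("pairwise output is symmetric under row swap", {
  withr::local_seed(91)
  x <- random_codons(60); y <- mutate_seq(x, 0.1)
  r1 <- pairwise_dnds(c(a = x, b = y))
  r2 <- pairwise_dnds(c(b = y, a = x))
  expect_equal(r1[, c("S", "N", "Sd", "Nd", "dS", "dN", "dnds")],
               r2[, c("S", "N", "Sd", "Nd", "dS", "dN", "dnds")])
})

test_that("expected sites sum to three per codon site for every row", {
  withr::local_seed(92)
  rows <- vapply(1:4, function(i) random_codons(40), character(1))
  tabsum <- vapply(rows, function(r) {
    cods <- substring(r, seq(1, nchar(r) - 2, 3), seq(3, nchar(r), 3))
    sum(vapply(cods, function(cd) sum(ng86_site_counts(cd)), numeric(1)))
  }, numeric(1))
  expect_equal(unname(tabsum), rep(120, 4))
})

test_that("SLAC counts a single synonymous change on the right branch", {
  aln <- c(A = "GGG", B = "GGG", C = "GGG", D = "GGA")
  tree <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);")
  res <- slac_analyze(aln, tree)
  expect_equal(res$per_site$Sd, 1)
  expect_equal(res$per_site$Nd, 0)
  d_branch <- res$per_branch[res$per_branch$child ==
                               which(tree$tip.label == "D"), ]
  expect_equal(d_branch$Sd, 1)
  expect_equal(sum(res$per_branch$Sd), 1)
})

test_that("an invariant alignment yields no substitutions and NA mean", {
  aln <- c(a = "ATGGCCAAA", b = "ATGGCCAAA", c = "ATGGCCAAA")
  tree <- ape::read.tree(text = "(a:0.1,b:0.1,c:0.1);")
  res <- slac_analyze(aln, tree)
  expect_equal(sum(res$per_site$Sd) + sum(res$per_site$Nd), 0)
  expect_true(is.na(res$mean_dnds))
  expect_true(all(is.na(res$per_site$p)))
})

test_that("SLAC on two leaves equals the pairwise counter", {
  withr::local_seed(93)
  x <- random_codons(80); y <- mutate_seq(x, 0.08)
  y <- paste(vapply(seq(1, nchar(y), 3), function(p) {
    cd <- substr(y, p, p + 2)
    if (cd %in% c("TAA", "TAG", "TGA")) substr(x, p, p + 2) else cd
  }, character(1)), collapse = "")
  pw <- pairwise_dnds(c(a = x, b = y))
  tree <- ape::read.tree(text = "(a:0.05,b:0.05);")
  sl <- slac_analyze(c(a = x, b = y), tree)
  expect_equal(sum(sl$per_site$Sd), pw$Sd)
  expect_equal(sum(sl$per_site$Nd), pw$Nd)
  expect_equal(sl$totals$ES, pw$S)
  expect_equal(sl$totals$EN, pw$N)
  expect_equal(sl$mean_dnds_jc, pw$dnds)
})

test_that("rows with internal stops are excluded and logged", {
  aln <- c(a = "ATGGCCAAA", b = "ATGTAAAAA", c = "ATGGCGAAA", d = "ATGGCCAAG")
  expect_message(res <- slac_analyze(aln), "internal stop")
  expect_equal(res$excluded_rows, "b")
})

test_that("codon evolution at omega=1 versus omega=3 is ranked correctly", {
  tree <- ape::read.tree(text = paste0(
    "(((t1:0.05,t2:0.05):0.04,(t3:0.05,t4:0.05):0.04):0.03,",
    "((t5:0.05,t6:0.05):0.04,(t7:0.05,t8:0.05):0.04):0.03);"))
  a1 <- simulate_codon_evolution(tree, 200, omega = 1, seed = 7)
  a3 <- simulate_codon_evolution(tree, 200, omega = 3, seed = 7)
  r1 <- slac_analyze(a1, tree)
  r3 <- slac_analyze(a3, tree)
  expect_gt(r3$mean_dnds, r1$mean_dnds)
})

test_that("the cumulative profile localizes planted nonsynonymous changes", {
  withr::local_seed(94)
  base <- random_codons(40)
  rows <- c(a = base, b = base)
  # plant nonsynonymous differences in codons 10..20 of row b only
  bb <- rows[["b"]]
  code <- Biostrings::GENETIC_CODE
  for (cd in 10:20) {
    p <- (cd - 1) * 3 + 1
    orig <- substr(bb, p, p + 2)
    repl <- names(code)[code != code[[orig]] & code != "*"][1]
    substr(bb, p, p + 2) <- repl
  }
  rows[["b"]] <- bb
  prof <- cumulative_profile(rows)
  expect_true(all(diff(prof$cum_nonsyn) >= 0))
  expect_equal(prof$cum_nonsyn[9], 0)
  expect_gt(prof$cum_nonsyn[20], 0)
  expect_equal(prof$cum_nonsyn[40], prof$cum_nonsyn[20])
  # flat-zero for identical rows
  flat <- cumulative_profile(c(x = base, y = base))
  expect_true(all(flat$cum_syn == 0) && all(flat$cum_nonsyn == 0))
})

test_that("profile endpoints equal the pairwise mean counts", {
  withr::local_seed(95)
  seqs <- stats::setNames(vapply(1:4, function(i) {
    s <- mutate_seq(random_codons(30), 0)
    s
  }, character(1)), paste0("s", 1:4))
  base <- random_codons(30)
  seqs <- stats::setNames(vapply(1:4, function(i) {
    x <- mutate_seq(base, 0.06)
    # remove stop codons to keep rows comparable
    paste(vapply(seq(1, nchar(x), 3), function(p) {
      cd <- substr(x, p, p + 2)
      if (cd %in% c("TAA", "TAG", "TGA")) substr(base, p, p + 2) else cd
    }, character(1)), collapse = "")
  }, character(1)), paste0("s", 1:4))
  prof <- cumulative_profile(seqs)
  pw <- pairwise_dnds(seqs)
  expect_equal(prof$cum_syn[nrow(prof)], mean(pw$Sd) * nrow(pw) / nrow(pw))
  expect_equal(prof$cum_syn[nrow(prof)], sum(pw$Sd) / nrow(pw))
  expect_equal(prof$cum_nonsyn[nrow(prof)], sum(pw$Nd) / nrow(pw))
})
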