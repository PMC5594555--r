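# Seeded search must agree with a brute-force Smith-Waterman oracle for
# gate-passing hits, apply the E-value and query-cover gates, and refine
# exon boundaries to the planted splice sites.

test_that("an exact substring is found with identity and cover 1", {
  withr::local_seed(1)
  q <- random_codons(60)
  px <- plant_exon(q)
  hits <- seeded_local_search(c(ctg = px$contig), c(q1 = q))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, px$start)
  expect_equal(hits$end, px$end)
  expect_equal(hits$identity, 1)
  expect_equal(hits$query_cover, 1)
  expect_equal(hits$strand, "+")
})

test_that("empty contig sets and bad inputs behave as specified", {
  expect_equal(nrow(seeded_local_search(character(0), c(q = "ACGTACGTACGT"))), 0)
  expect_error(seeded_local_search(c(c1 = "ACGT"), character(0)), "non-empty")
  expect_error(mining_params(word_size = 3), "word_size")
})

test_that("hits at moderate divergence match the Smith-Waterman oracle", {
  withr::local_seed(42)
  q <- random_codons(80)  # 240 nt
  mut <- mutate_seq(q, 0.15)
  px <- plant_exon(mut, left = 500, right = 500)
  hits <- seeded_local_search(c(ctg = px$contig), c(q1 = q))
  expect_equal(nrow(hits), 1)
  osw <- oracle_sw(q, px$contig)
  expect_equal(hits$score, osw$score)
  # interval overlap with truth >= 90%
  ov <- min(hits$end, px$end) - max(hits$start, px$start)
  expect_gte(ov / (px$end - px$start), 0.9)
})

test_that("gene-free contigs yield zero calls at the default gates", {
  withr::local_seed(7)
  contigs <- c(r1 = random_dna(40000), r2 = random_dna(40000))
  hits <- seeded_local_search(contigs, seed_queries())
  expect_equal(nrow(hits), 0)
})

test_that("low query cover is gated out even when the E-value passes", {
  withr::local_seed(3)
  core <- random_codons(20)            # 60 nt matches perfectly
  q <- paste0(core, random_codons(30)) # 150 nt query, 40% coverable
  px <- plant_exon(core, left = 400, right = 400)
  hits <- seeded_local_search(c(ctg = px$contig), c(q = q))
  expect_equal(nrow(hits), 0)
  # the same core passes when it constitutes the whole query
  hits2 <- seeded_local_search(c(ctg = px$contig), c(q = core))
  expect_equal(nrow(hits2), 1)
})

test_that("boundary refinement recovers planted coordinates exactly", {
  sim <- simulate_genome(tiny_spec(paralog_divergence = 0, seed = 2))
  calls <- mine_sim(sim)
  truth <- sim$exons
  for (i in seq_len(nrow(truth))) {
    hit <- calls[calls$contig_id == truth$contig_id[i] &
                   calls$start == truth$start[i] &
                   calls$end == truth$end[i], ]
    expect_equal(nrow(hit), 1, label = paste("exon", i))
  }
})

test_that("a mutated splice donor leaves donor_ok FALSE with exact boundaries", {
  withr::local_seed(9)
  exon <- random_codons(30)  # 90 nt
  px <- plant_exon(exon, donor = "AT")
  hit <- seeded_local_search(c(ctg = px$contig), c(q = exon))
  call <- refine_exon_boundaries(hit, px$contig, expected_length = 90,
                                 domain_type = "Cyt1", query = exon)
  expect_false(call$donor_ok)
  expect_true(call$acceptor_ok)
  expect_equal(call$start, px$start)
  expect_equal(call$end, px$end)
})

test_that("an exon truncated by the contig edge becomes a partial call", {
  withr::local_seed(10)
  exon <- random_codons(80)
  full <- plant_exon(exon, left = 400, right = 400)
  truncated <- substr(full$contig, 1, full$start + 150)  # cuts the exon
  hit <- seeded_local_search(c(ctg = truncated), c(q = exon),
                             mining_params(min_cover = 0.3))
  expect_equal(nrow(hit), 1)
  call <- refine_exon_boundaries(hit, truncated, expected_length = 240,
                                 domain_type = "N", query = exon)
  expect_true(call$partial)
  expect_false(call$length_ok)
})

test_that("iterative mining finds a distant paralog only via an intermediate", {
  withr::local_seed(5)
  s <- random_codons(107)                 # 321 nt seed
  # at 40% divergence the expected local-alignment score drift is zero, so
  # B has no significant segment against the seed; A sits halfway
  pos <- sample(321, 128)
  b <- mutate_k(s, pos)                   # 40% from the seed
  a <- mutate_k(s, sample(pos, 64))       # 20% from both seed and B
  ca <- plant_exon(a, left = 400, right = 400)
  cb <- plant_exon(b, left = 400, right = 400)
  contig <- paste0(ca$contig, cb$contig)
  # direct search: seed finds A but not B
  direct <- seeded_local_search(c(ctg = contig), c(seed = s))
  expect_equal(nrow(direct), 1)
  expect_equal(direct$start, ca$start)
  # iterative search pulls B in via A in round 2
  calls <- iterative_mine(c(ctg = contig), c(seed = s), c(seed = "N"),
                          max_rounds = 3)
  expect_equal(nrow(calls), 2)
  expect_setequal(calls$round, c(1, 2))
  b_call <- calls[calls$round == 2, ]
  expect_equal(b_call$start, nchar(ca$contig) + cb$start)
})

test_that("reverse-complementing the genome mirrors all calls", {
  sim <- simulate_genome(tiny_spec(seed = 4, n_genes = 4, contig_count = 1))
  calls <- mine_sim(sim)
  rc <- vapply(sim$contigs, revcomp, character(1))
  calls_rc <- mine_sim(list(contigs = rc))
  expect_equal(nrow(calls), nrow(calls_rc))
  L <- nchar(sim$contigs[[1]])
  mirrored <- data.frame(start = L - calls_rc$end, end = L - calls_rc$start,
                         strand = ifelse(calls_rc$strand == "+", "-", "+"))
  mirrored <- mirrored[order(mirrored$start), ]
  orig <- calls[order(calls$start), c("start", "end", "strand")]
  rownames(orig) <- rownames(mirrored) <- NULL
  expect_equal(orig$start, mirrored$start)
  expect_equal(orig$end, mirrored$end)
  expect_equal(orig$strand, mirrored$strand)
})

test_that("contigs with characters outside A/C/G/T/N are rejected", {
  expect_error(seeded_local_search(c(c1 = "ACGTRYACGT"), c(q = "ACGTACGT")),
               "A/C/G/T/N")
})
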