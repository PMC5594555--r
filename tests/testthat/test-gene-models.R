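# Gene-model assembly, ORF/pseudogene status, architecture classification,
# N-glycosylation counting and the census.

test_that("ORF status flags in-frame stops before the final codon", {
  r <- call_orf_status("ATGGGGCCC")
  expect_true(r$orf_intact)
  expect_length(r$stop_positions, 0)
  r <- call_orf_status("ATGTAACCC")
  expect_false(r$orf_intact)
  expect_equal(r$stop_positions, 1L)
  # a terminal stop codon does not break the ORF
  r <- call_orf_status("ATGGGGTAA")
  expect_true(r$orf_intact)
  expect_equal(r$stop_positions, 2L)
  expect_error(call_orf_status("ATGRRR"), "non-ACGTN")
  expect_error(call_orf_status("AT"), "shorter")
})

test_that("planted pseudogene stops are recovered at the planted codon", {
  sim <- simulate_genome(tiny_spec(pseudogene_fraction = 1, seed = 6))
  for (g in seq_len(nrow(sim$genes))) {
    ex <- sim$exons[sim$exons$gene_id == sim$genes$gene_id[g] &
                      sim$exons$domain == "N", ]
    s <- substr(sim$contigs[[ex$contig_id]], ex$start + 1, ex$end)
    if (ex$strand == "-") s <- revcomp(s)
    r <- call_orf_status(s)
    expect_false(r$orf_intact)
    expect_equal(r$stop_positions[1], sim$genes$n_stop_codon[g])
  }
})

test_that("exon calls chain into the planted gene models", {
  sim <- simulate_genome(tiny_spec(seed = 12))
  calls <- mine_sim(sim)
  models <- assemble_gene_models(calls)
  expect_equal(length(models), nrow(sim$genes))
  # single N exon per model; exons ordered in transcript orientation
  for (m in models) {
    expect_lte(sum(m$exons$domain_type == "N"), 1)
    if (m$strand == "+") expect_true(all(diff(m$exons$start) > 0))
  }
})

test_that("two N exons without intervening domains give two models", {
  withr::local_seed(15)
  n1 <- random_codons(107); n2 <- mutate_seq(n1, 0.05)
  p1 <- plant_exon(n1, left = 300, right = 10)
  contig <- paste0(p1$contig, plant_exon(n2, left = 290, right = 300)$contig)
  calls <- iterative_mine(c(ctg = contig), c(N = n1), c(N = "N"))
  expect_equal(nrow(calls), 2)
  models <- assemble_gene_models(calls)
  expect_length(models, 2)
})

test_that("exons split across contigs form separate partial models", {
  sim <- simulate_genome(tiny_spec(seed = 2, psg_fraction = 0))
  calls <- mine_sim(sim)
  g1 <- calls[calls$contig_id == "contig_01", ][1:4, ]
  g2 <- calls[calls$contig_id == "contig_01", ][5:8, ]
  g2$contig_id <- "contig_XX"
  models <- assemble_gene_models(rbind(g1, g2))
  expect_length(models, 2)
  expect_setequal(vapply(models, `[[`, character(1), "contig_id"),
                  c("contig_01", "contig_XX"))
})

test_that("a distant exon beyond the gap limit opens a new model", {
  withr::local_seed(19)
  calls <- data.frame(
    query_id = "q", contig_id = "c", start = c(100L, 30000L),
    end = c(421L, 30279L), strand = "+",
    domain_type = c("N", "A2"), acceptor_ok = TRUE, donor_ok = TRUE,
    length_ok = TRUE, partial = FALSE, has_n = FALSE, score = 100,
    evalue = 1e-30, sequence = c(random_codons(107), random_codons(93)),
    stringsAsFactors = FALSE)
  expect_length(assemble_gene_models(calls, max_gap = 25000), 2)
  expect_length(assemble_gene_models(calls, max_gap = 50000), 1)
})

test_that("PSG architectures split on terminal versus internal IgC stops", {
  refs <- reference_exons()
  igc_refs <- c(A1 = refs$A1, B = refs$B, A2 = refs$A2)
  make_model <- function(stop_codon) {
    withr::local_seed(30)
    a2 <- refs$A2
    substr(a2, (stop_codon - 1) * 3 + 1, stop_codon * 3) <- "TAA"
    calls <- data.frame(
      query_id = "q", contig_id = "c",
      start = c(0L, 500L, 1200L), end = c(102L, 821L, 1479L), strand = "+",
      domain_type = c("leader", "N", "A2"), acceptor_ok = TRUE,
      donor_ok = TRUE, length_ok = TRUE, partial = FALSE, has_n = FALSE,
      score = 100, evalue = 1e-30,
      sequence = c(refs$leader, refs$N, a2), stringsAsFactors = FALSE)
    assemble_gene_models(calls)[[1]]
  }
  m_term <- classify_architecture(make_model(93), igc_refs)  # final codon
  expect_equal(m_term$architecture, "PSG-2dom")
  m_late <- classify_architecture(make_model(89), igc_refs)  # within final 6
  expect_equal(m_late$architecture, "PSG-2dom")
  m_int <- classify_architecture(make_model(30), igc_refs)   # internal
  expect_equal(m_int$architecture, "PSG-1dom")
  expect_equal(m_int$igc_stop_codon, 29L)
  expect_equal(m_int$igc_subtypes, "A2")
})

test_that("full receptor models classify as CEACAM-TM with typed IgC exons", {
  sim <- simulate_genome(tiny_spec(psg_fraction = 0, pseudogene_fraction = 0,
                                   donor_mutated_fraction = 0, seed = 23))
  models <- annotate_sim(sim, mine_sim(sim))
  expect_true(all(vapply(models, `[[`, character(1), "architecture") ==
                    "CEACAM-TM"))
  for (m in models) {
    expect_equal(m$igc_subtypes, c("A1", "B", "A2"))
    expect_false(m$is_pseudogene)
  }
})

test_that("N-glycosylation sequons are counted non-overlapping, X != P", {
  expect_equal(count_nglyc("AAAAA"), 0)
  expect_equal(count_nglyc("ANASA"), 1)
  expect_equal(count_nglyc("NPSNAT"), 1)
  expect_equal(count_nglyc("NASNAT"), 2)
  expect_equal(count_nglyc("NAS*NAT"), 1)  # truncated at the stop
  expect_equal(count_nglyc(""), 0)
})

test_that("the census matches the planted composition", {
  expect_equal(census(list())$n_exons_total, 0)
  sim <- simulate_genome(tiny_spec(n_genes = 12, seed = 31))
  models <- annotate_sim(sim, mine_sim(sim))
  cen <- census(models, species = "Sim")
  expect_equal(cen$n_exons_total, 12)
  expect_equal(cen$n_exons_orf, sum(!sim$genes$is_pseudogene))
  expect_equal(cen$n_psg1dom, sum(sim$genes$architecture == "PSG-1dom"))
  expect_equal(cen$n_psg2dom, sum(sim$genes$architecture == "PSG-2dom"))
  expect_equal(cen$n_tm_itim,
               sum(sim$genes$signaling %in% c("inhibitory", "inhibitory-ITSM")))
  expect_equal(cen$n_tm_itam, sum(sim$genes$signaling == "activating"))
  expect_lte(cen$n_exons_orf, cen$n_exons_total)
})

test_that("reassembling a model from its own exon calls is idempotent", {
  sim <- simulate_genome(tiny_spec(seed = 12))
  models <- assemble_gene_models(mine_sim(sim))
  for (m in models[1:3]) {
    again <- assemble_gene_models(m$exons)
    expect_length(again, 1)
    expect_equal(again[[1]]$exons$start, m$exons$start)
    expect_equal(again[[1]]$exons$end, m$exons$end)
    expect_equal(again[[1]]$exons$domain_type, m$exons$domain_type)
  }
})
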