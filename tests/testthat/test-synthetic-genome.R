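# The generator must be deterministic, respect the requested family
# composition, and emit sequences whose re-extracted features agree with the
# truth tables exactly.

test_that("invalid specifications are rejected", {
  expect_error(family_spec(psg_fraction = 1.2), "proportions")
  expect_error(family_spec(paralog_divergence = 0.7), "paralog_divergence")
  expect_error(family_spec(contig_count = 0), "contig_count")
  expect_error(family_spec(exon_lengths = c(default_exon_lengths()[-2],
                                            N = 320L)), "multiples of 3")
})

test_that("an empty family yields an empty genome and truth set", {
  sim <- simulate_genome(family_spec(n_genes = 0, seed = 5))
  expect_length(sim$contigs, 0)
  expect_equal(nrow(sim$genes), 0)
  expect_equal(nrow(sim$exons), 0)
})

test_that("identical spec and seed give byte-identical emitted files", {
  spec <- tiny_spec()
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  p1 <- write_genome(simulate_genome(spec), d1)
  p2 <- write_genome(simulate_genome(spec), d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("pseudogene counts fall in the binomial 99% interval and rerun is identical", {
  spec <- family_spec(n_genes = 200, pseudogene_fraction = 0.5, seed = 99,
                      contig_count = 8)
  sim <- simulate_genome(spec)
  expect_equal(nrow(sim$genes), 200)
  k <- sum(sim$genes$is_pseudogene)
  expect_gte(k, qbinom(0.005, 200, 0.5))
  expect_lte(k, qbinom(0.995, 200, 0.5))
  sim2 <- simulate_genome(spec)
  expect_identical(sim$genes, sim2$genes)
  expect_identical(sim$contigs, sim2$contigs)
})

test_that("architecture frequencies track the spec fractions", {
  sim <- simulate_genome(family_spec(n_genes = 300, psg_fraction = 0.8,
                                     contig_count = 10, seed = 17))
  p_psg <- mean(startsWith(sim$genes$architecture, "PSG"))
  expect_gt(p_psg, 0.72)
  expect_lt(p_psg, 0.88)
  expect_true(all(table(sim$genes$subgroup) > 0))
})

test_that("every planted exon re-extracts with the planted features", {
  sim <- simulate_genome(tiny_spec())
  for (g in seq_len(nrow(sim$genes))) {
    row <- sim$genes[g, ]
    ex <- sim$exons[sim$exons$gene_id == row$gene_id, ]
    cs <- sim$contigs[[row$contig_id]]
    get_seq <- function(i) {
      s <- substr(cs, ex$start[i] + 1, ex$end[i])
      if (ex$strand[i] == "-") revcomp(s) else s
    }
    # exactly one N exon per gene, coordinates within bounds
    expect_equal(sum(ex$domain == "N"), 1)
    expect_true(all(ex$start >= 0 & ex$end <= nchar(cs)))
    # splice dinucleotides at every junction except the planted donor mutation
    for (i in seq_len(nrow(ex) - 1)) {
      if (ex$strand[i] == "+") {
        don <- substr(cs, ex$end[i] + 1, ex$end[i] + 2)
      } else {
        don <- revcomp(substr(cs, ex$start[i] - 1, ex$start[i]))
      }
      expected <- if (!is.na(row$donor_mutated_junction) &&
                      i == row$donor_mutated_junction) "AT" else "GT"
      expect_identical(don, expected)
    }
    # pseudogene status is carried by the N exon reading frame
    n_orf <- call_orf_status(get_seq(which(ex$domain == "N")))
    expect_identical(!n_orf$orf_intact, row$is_pseudogene)
    if (row$is_pseudogene) {
      expect_equal(n_orf$stop_positions[1], row$n_stop_codon)
    }
    if (startsWith(row$architecture, "PSG")) {
      # planted IgC stop at the recorded codon; AATAAA within 200 nt downstream
      a2 <- get_seq(which(ex$domain == "A2"))
      cds <- substring(a2, seq(1, nchar(a2) - 2, 3), seq(3, nchar(a2), 3))
      stops <- which(cds %in% c("TAA", "TAG", "TGA")) - 1L
      expect_equal(stops[1], row$igc_stop_codon)
      i <- which(ex$domain == "A2")
      stop_end0 <- ex$start[i] + (row$igc_stop_codon + 1) * 3
      region <- substr(cs, stop_end0 + 1, stop_end0 + 200)
      expect_true(grepl("AATAAA", region, fixed = TRUE))
    } else {
      # cytoplasmic motifs equal the planted signaling class
      cyt <- paste(vapply(which(ex$domain %in% c("Cyt1", "Cyt2")), get_seq,
                          character(1)), collapse = "")
      kinds <- detect_tyrosine_motifs(translate_nt(cyt))$kind
      base <- sub("CEACAM-", "", row$architecture)
      if (row$architecture == "CEACAM-ITAM") {
        expect_identical(kinds, "ITAM")
      } else if (row$architecture == "CEACAM-ITSM") {
        expect_setequal(kinds, c("ITIM", "ITSM"))
      } else if (row$architecture == "CEACAM-ITIM") {
        expect_identical(unique(kinds), "ITIM")
      }
    }
  }
})

test_that("coding frames of non-pseudogene receptor genes are stop-free", {
  sim <- simulate_genome(tiny_spec(psg_fraction = 0, pseudogene_fraction = 0,
                                   donor_mutated_fraction = 0, seed = 3))
  for (g in seq_len(nrow(sim$genes))) {
    ex <- sim$exons[sim$exons$gene_id == sim$genes$gene_id[g], ]
    cs <- sim$contigs[[sim$genes$contig_id[g]]]
    cds <- paste(vapply(seq_len(nrow(ex)), function(i) {
      s <- substr(cs, ex$start[i] + 1, ex$end[i])
      if (ex$strand[i] == "-") revcomp(s) else s
    }, character(1)), collapse = "")
    aa <- translate_nt(cds)
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
  }
})

test_that("donor mutation is planted only at the requested junction", {
  sim <- simulate_genome(tiny_spec(psg_fraction = 0,
                                   donor_mutated_fraction = 1, seed = 8))
  expect_true(all(sim$genes$architecture == "CEACAM-nonfunctional"))
  expect_true(all(sim$genes$donor_mutated_junction == 7L))
})

test_that("strand randomization reverse-complements cassettes coherently", {
  sim <- simulate_genome(tiny_spec(randomize_strand = TRUE, seed = 13))
  expect_true(all(c("+", "-") %in% sim$exons$strand))
  minus <- sim$exons[sim$exons$strand == "-" & sim$exons$domain == "N", ]
  for (i in seq_len(nrow(minus))) {
    s <- revcomp(substr(sim$contigs[[minus$contig_id[i]]],
                        minus$start[i] + 1, minus$end[i]))
    expect_equal(nchar(s), default_exon_lengths()[["N"]])
  }
})
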