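# Shared fixture builders: everything is generated in code at test time.

tiny_spec <- function(...) {
  args <- list(n_genes = 8L, contig_count = 2L, seed = 11L,
               psg_fraction = 0.5, paralog_divergence = 0.05,
               intron_length_range = c(250L, 500L),
               intergenic_range = c(400L, 700L))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(family_spec, args)
}

seed_queries <- function(refs = reference_exons()) {
  vapply(names(attr(refs, "domains")), function(n) refs[[n]], character(1))
}

seed_domains <- function(refs = reference_exons()) {
  attr(refs, "domains")
}

mine_sim <- function(sim, ...) {
  iterative_mine(sim$contigs, seed_queries(), seed_domains(), ...)
}

annotate_sim <- function(sim, calls) {
  refs <- reference_exons()
  models <- assemble_gene_models(calls)
  models <- lapply(models, function(m) {
    classify_architecture(m, c(A1 = refs$A1, B = refs$B, A2 = refs$A2),
                          contig_seq = sim$contigs[[m$contig_id]])
  })
  lapply(models, function(m) {
    classify_receptor_signaling(
      m, c(`CEACAM1-like` = refs$TM_CEACAM1, `CEACAM3-like` = refs$TM_CEACAM3),
      contig_seq = sim$contigs[[m$contig_id]])
  })
}

# plant an exon with AG/GT flanks inside random sequence, returning the
# contig and the exon interval (0-based half-open)
plant_exon <- function(exon, left = 300L, right = 300L, donor = "GT") {
  contig <- paste0(random_dna(left - 2L), "AG", exon, donor,
                   random_dna(right - 2L))
  list(contig = contig, start = left, end = left + nchar(exon))
}

# mutate exactly k positions of a sequence (deterministic given RNG state)
mutate_k <- function(seq, pos) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}
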