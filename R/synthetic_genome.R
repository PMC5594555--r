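# Synthetic multi-contig genomes carrying planted CEA-family gene cassettes
# with a machine-readable truth set. The generator emulates the genomic
# structures the pipeline is designed to recover: duplicated gene cassettes
# (leader/N/IgC/TM/Cyt exons separated by GT..AG introns), configurable
# paralog divergence, pseudogenization by in-frame stops, secreted PSG
# architectures with exon-internal or exon-terminal stop codons plus a
# downstream polyadenylation signal, two transmembrane exon types, cytoplasmic
# exons carrying ITIM/ITSM or ITAM motifs, and mutated splice-donor sites.

#' Default exon lengths for the synthetic cassette (nt)
#'
#' All lengths are multiples of three with phase-0 junctions so that frame
#' bookkeeping stays simple and testable.
#' @return Named integer vector over domain types.
#' @export
default_exon_lengths <- function() {
  c(leader = 102L, N = 321L, A1 = 279L, B = 279L, A2 = 279L,
    TM = 108L, Cyt1 = 90L, Cyt2 = 150L)
}

#' Specification of a synthetic CEA gene family
#'
#' Defaults emulate the scale reported for *Myotis lucifugus*: on the order of
#' one hundred N-domain exons, about half of them pseudogenized, roughly one
#' in ten genes membrane-anchored, with a balanced split of inhibitory and
#' activating receptor types, a minority of inhibitory tails carrying an ITSM,
#' and a sizeable fraction of receptor genes with a mutated splice-donor site.
#'
#' @param n_genes Number of genes to plant.
#' @param psg_fraction Proportion of genes with secreted PSG architecture.
#' @param pseudogene_fraction Proportion of genes whose N-domain exon carries
#'   an in-frame stop codon.
#' @param tm_activating_fraction Among receptor (non-PSG) genes, proportion
#'   built on the activating (CEACAM3-like TM + ITAM) cassette.
#' @param itsm_fraction Among inhibitory receptor genes, proportion whose
#'   distal cytoplasmic exon carries an ITSM instead of a second ITIM.
#' @param donor_mutated_fraction Proportion of receptor genes whose splice
#'   donor between the cytoplasmic exons is mutated (GT -> AT), rendering the
#'   signaling motifs non-functional.
#' @param paralog_divergence Expected substitutions/site between each planted
#'   gene and its ancestral cassette, in \[0, 0.5\].
#' @param psg_subgroup_divergence Divergence of each of the two PSG N-domain
#'   subgroup ancestors (PSG I / PSG II) from the CEACAM N ancestor.
#' @param intron_length_range Length range (nt) for introns.
#' @param intergenic_range Length range (nt) for intergenic spacers.
#' @param contig_count Number of contigs the genes are distributed over.
#' @param exon_lengths Named nt lengths per domain type; must be multiples
#'   of 3 (phase-0 junctions).
#' @param randomize_strand Place each gene on a random strand.
#' @param seed Integer seed; identical spec + seed gives byte-identical output.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(n_genes = 100L,
                        psg_fraction = 0.9,
                        pseudogene_fraction = 0.5,
                        tm_activating_fraction = 0.5,
                        itsm_fraction = 0.25,
                        donor_mutated_fraction = 0.3,
                        paralog_divergence = 0.10,
                        psg_subgroup_divergence = 0.2,
                        intron_length_range = c(250L, 1200L),
                        intergenic_range = c(500L, 1500L),
                        contig_count = 8L,
                        exon_lengths = default_exon_lengths(),
                        randomize_strand = FALSE,
                        seed = 1L) {
  props <- c(psg_fraction = psg_fraction,
             pseudogene_fraction = pseudogene_fraction,
             tm_activating_fraction = tm_activating_fraction,
             itsm_fraction = itsm_fraction,
             donor_mutated_fraction = donor_mutated_fraction)
  if (any(props < 0 | props > 1)) {
    stop("famscan configuration error: all proportions must lie in [0, 1]")
  }
  if (paralog_divergence < 0 || paralog_divergence > 0.5) {
    stop("famscan configuration error: paralog_divergence must lie in [0, 0.5]")
  }
  if (n_genes < 0) stop("famscan configuration error: n_genes must be >= 0")
  if (contig_count < 1) {
    stop("famscan configuration error: contig_count must be >= 1")
  }
  need <- names(default_exon_lengths())
  if (!all(need %in% names(exon_lengths))) {
    stop("famscan configuration error: exon_lengths must name all of: ",
         paste(need, collapse = ", "))
  }
  exon_lengths <- as.integer(exon_lengths[need])
  names(exon_lengths) <- need
  if (any(exon_lengths <= 0L) || any(exon_lengths %% 3L != 0L)) {
    stop("famscan configuration error: exon lengths must be positive multiples of 3")
  }
  if (length(intron_length_range) != 2L || intron_length_range[1] < 20L ||
      diff(intron_length_range) < 0) {
    stop("famscan configuration error: invalid intron_length_range")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    psg_fraction = psg_fraction,
    pseudogene_fraction = pseudogene_fraction,
    tm_activating_fraction = tm_activating_fraction,
    itsm_fraction = itsm_fraction,
    donor_mutated_fraction = donor_mutated_fraction,
    paralog_divergence = paralog_divergence,
    psg_subgroup_divergence = psg_subgroup_divergence,
    intron_length_range = as.integer(intron_length_range),
    intergenic_range = as.integer(intergenic_range),
    contig_count = as.integer(contig_count),
    exon_lengths = exon_lengths,
    randomize_strand = isTRUE(randomize_strand),
    seed = as.integer(seed)
  ), class = "family_spec")
}

# motif layouts planted into the cytoplasmic reference exons, as 1-based
# codon positions and the codons written there
.cyt_motif_layout <- function() {
  list(
    Cyt1_inh  = list(kinds = "ITIM",
                     at = list(ITIM = 8L),
                     codons = list(ITIM = c("GTG", "ACC", "TAC", "TCC", "ACA", "CTG"))),  # VTYSTL
    Cyt2_inh  = list(kinds = "ITIM",
                     at = list(ITIM = 15L),
                     codons = list(ITIM = c("GTG", "ATC", "TAC", "TCC", "GAG", "GTG"))),  # VIYSEV
    Cyt2_itsm = list(kinds = "ITSM",
                     at = list(ITSM = 15L),
                     codons = list(ITSM = c("ACC", "GAG", "TAC", "AGC", "AGC", "GTG"))),  # TEYSSV
    Cyt1_act  = list(kinds = character(0), at = list(), codons = list()),
    Cyt2_act  = list(kinds = "ITAM",
                     at = list(ITAM = 10L),
                     codons = list(ITAM = c("TAC", "CAG", "CCC", "CTG",           # YQPL
                                            "GCC", "GGG", "GAC", "GAG", "TCC", "AGC", "CCA",  # 7-aa spacer
                                            "TAC", "GAG", "AAC", "CTG")))         # YENL
  )
}

.plant_codons <- function(seq, at_codon, codons) {
  for (i in seq_along(codons)) {
    p <- (at_codon + i - 2L) * 3L
    substr(seq, p + 1L, p + 3L) <- codons[i]
  }
  seq
}

.motif_codon_span <- function(at_codon, codons) {
  seq(at_codon, at_codon + length(codons) - 1L)
}

# nt positions (1-based) covered by the codon indices (1-based)
.codon_nt <- function(codon_idx) {
  as.integer(outer(1:3, (codon_idx - 1L) * 3L, `+`))
}

#' Ancestral reference exon set
#'
#' Deterministically generated reference exons of the ancestral CEA cassette.
#' These double as the default seed queries for exon mining and as the
#' IgC (A1/B/A2) and TM typing references. The two TM types and the A1/B/A2
#' IgC subtypes are mutually diverged so that nearest-reference typing is
#' well defined; cytoplasmic exons carry the planted signaling motifs and are
#' otherwise guaranteed motif-free.
#'
#' @param exon_lengths Named nt lengths per domain type.
#' @return Named list of nucleotide strings with attribute `motifs` (the
#'   planted motif layout) and attribute `domains` mapping each reference to
#'   its domain type.
#' @export
reference_exons <- function(exon_lengths = default_exon_lengths()) {
  key <- paste(names(exon_lengths), exon_lengths, collapse = ";")
  if (!is.null(.fam_cache$refs) && identical(.fam_cache$refs_key, key)) {
    return(.fam_cache$refs)
  }
  L <- exon_lengths
  out <- with_seed(20170911L, {
    layout <- .cyt_motif_layout()
    refs <- list()
    refs$leader <- paste0("ATG", random_codons(L[["leader"]] / 3L - 1L))
    # N exon with one N-glycosylation sequon (N-A-S) at codons 30..32
    nseq <- random_codons(L[["N"]] / 3L)
    nseq <- .plant_codons(nseq, 30L, c("AAC", "GCC", "AGC"))
    refs$N <- nseq
    # IgC subtypes: B and A2 derived from A1 at ~30% divergence
    refs$A1 <- random_codons(L[["A1"]] / 3L)
    refs$B <- .destop(mutate_seq(refs$A1, 0.30))
    refs$A2 <- .destop(mutate_seq(refs$A1, 0.30))
    # TM types
    refs$TM_CEACAM1 <- random_codons(L[["TM"]] / 3L)
    refs$TM_CEACAM3 <- .destop(mutate_seq(refs$TM_CEACAM1, 0.35))
    # cytoplasmic exons: rejection-sample backgrounds until each concatenation
    # used by an architecture shows exactly the planted motifs
    repeat {
      cyt <- list()
      for (nm in names(layout)) {
        len <- if (startsWith(nm, "Cyt1")) L[["Cyt1"]] else L[["Cyt2"]]
        s <- random_codons(len / 3L)
        lay <- layout[[nm]]
        for (k in lay$kinds) s <- .plant_codons(s, lay$at[[k]], lay$codons[[k]])
        cyt[[nm]] <- s
      }
      ok <- .cyt_pair_clean(cyt$Cyt1_inh, cyt$Cyt2_inh, c("ITIM", "ITIM")) &&
        .cyt_pair_clean(cyt$Cyt1_inh, cyt$Cyt2_itsm, c("ITIM", "ITSM")) &&
        .cyt_pair_clean(cyt$Cyt1_act, cyt$Cyt2_act, "ITAM")
      if (ok) break
    }
    refs <- c(refs, cyt)
    attr(refs, "motifs") <- layout
    attr(refs, "domains") <- c(
      leader = "leader", N = "N", A1 = "A1", B = "B", A2 = "A2",
      TM_CEACAM1 = "TM", TM_CEACAM3 = "TM",
      Cyt1_inh = "Cyt1", Cyt2_inh = "Cyt2", Cyt2_itsm = "Cyt2",
      Cyt1_act = "Cyt1", Cyt2_act = "Cyt2")
    refs
  })
  .fam_cache$refs <- out
  .fam_cache$refs_key <- key
  out
}

# replace in-frame stop codons by random sense codons (keeps the planted
# codon indices in `keep`, 1-based)
.destop <- function(seq, keep = integer(0)) {
  cds <- codons_of(seq)
  bad <- which(cds %in% stop_codon_set())
  bad <- setdiff(bad, keep)
  for (i in bad) {
    substr(seq, (i - 1L) * 3L + 1L, i * 3L) <- sample(sense_codons(), 1L)
  }
  seq
}

# does the concatenated cytoplasmic translation show exactly these motif kinds?
.cyt_pair_clean <- function(cyt1, cyt2, expected_kinds) {
  hits <- detect_tyrosine_motifs(translate_nt(paste0(cyt1, cyt2)))
  identical(sort(hits$kind), sort(expected_kinds))
}

# revert codons of a mutated coding exon back to the ancestor wherever a
# non-planted in-frame stop appeared
.revert_stops <- function(mut, anc, keep = integer(0)) {
  cds <- codons_of(mut)
  bad <- setdiff(which(cds %in% stop_codon_set()), keep)
  for (i in bad) {
    p <- (i - 1L) * 3L
    substr(mut, p + 1L, p + 3L) <- substr(anc, p + 1L, p + 3L)
  }
  mut
}

# clean a mutated cytoplasmic exon pair so the detected motif set equals the
# planted expectation exactly; falls back to the ancestral exons
.clean_cyt_pair <- function(m1, m2, a1, a2, expected) {
  n1 <- nchar(m1) %/% 3L
  for (it in 1:8) {
    hits <- detect_tyrosine_motifs(translate_nt(paste0(m1, m2)))
    got <- paste(hits$kind, hits$tyrosine_position)
    want <- paste(expected$kind, expected$tyrosine_position)
    if (identical(sort(got), sort(want))) return(list(m1, m2))
    extra <- hits[!(got %in% want), , drop = FALSE]
    spans <- unique(c(
      unlist(lapply(seq_len(nrow(extra)), function(i) {
        seq(extra$start[i] + 1L, extra$end[i])   # 1-based aa = codon indices
      })),
      unlist(lapply(seq_len(nrow(expected)), function(i) {
        seq(expected$start[i] + 1L, expected$end[i])
      }))
    ))
    for (cd in spans) {
      if (cd <= n1) {
        p <- (cd - 1L) * 3L
        substr(m1, p + 1L, p + 3L) <- substr(a1, p + 1L, p + 3L)
      } else {
        p <- (cd - n1 - 1L) * 3L
        substr(m2, p + 1L, p + 3L) <- substr(a2, p + 1L, p + 3L)
      }
    }
  }
  list(a1, a2)
}

#' Simulate a genome with a planted CEA gene family
#'
#' Generates the truth set (planted genes with exon layouts and architecture
#' labels) and the contig sequences in one deterministic pass: the same spec
#' and seed always yield byte-identical output.
#'
#' @param spec A [family_spec()].
#' @return An object of class `cea_genome`: a list with elements
#'   `contigs` (named character vector of contig sequences), `genes`
#'   (truth table, one row per planted gene), `exons` (truth exon
#'   coordinates, 0-based half-open), `ancestors` (the N-domain ancestor
#'   sequences per subgroup), `refs` (the reference exon set) and `spec`.
#' @export
#' @examples
#' sim <- simulate_genome(family_spec(n_genes = 4, contig_count = 1, seed = 7))
#' sim$genes$architecture
simulate_genome <- function(spec) {
  if (!inherits(spec, "family_spec")) spec <- do.call(family_spec, spec)
  refs <- reference_exons(spec$exon_lengths)
  with_seed(spec$seed, {
    ancestors <- list(
      CEACAM   = refs$N,
      `PSG-I`  = .destop(mutate_seq(refs$N, spec$psg_subgroup_divergence)),
      `PSG-II` = .destop(mutate_seq(refs$N, spec$psg_subgroup_divergence))
    )
    genes <- vector("list", spec$n_genes)
    for (g in seq_len(spec$n_genes)) {
      genes[[g]] <- .build_gene(g, spec, refs, ancestors)
    }
    if (spec$n_genes == 0L) {
      return(structure(list(
        contigs = stats::setNames(character(0), character(0)),
        genes = .empty_gene_truth(), exons = .empty_exon_truth(),
        ancestors = ancestors, refs = refs, spec = spec
      ), class = "cea_genome"))
    }
    # distribute genes over contigs round-robin and assemble sequences
    contig_of <- ((seq_len(spec$n_genes) - 1L) %% spec$contig_count) + 1L
    contig_ids <- sprintf("contig_%02d", seq_len(spec$contig_count))
    contigs <- character(spec$contig_count)
    gene_rows <- list(); exon_rows <- list()
    for (ci in seq_len(spec$contig_count)) {
      idx <- which(contig_of == ci)
      pos <- 0L
      parts <- character(0)
      for (g in idx) {
        sp <- random_dna(sample(spec$intergenic_range[1]:spec$intergenic_range[2], 1L))
        parts <- c(parts, sp)
        pos <- pos + nchar(sp)
        gb <- genes[[g]]
        parts <- c(parts, gb$block)
        ex <- gb$exons
        ex$start <- ex$start + pos
        ex$end <- ex$end + pos
        ex$contig_id <- contig_ids[ci]
        row <- gb$gene
        row$contig_id <- contig_ids[ci]
        row$start <- min(ex$start)
        row$end <- max(ex$end)
        gene_rows[[g]] <- row
        exon_rows[[g]] <- ex
        pos <- pos + nchar(gb$block)
      }
      tail_sp <- random_dna(sample(spec$intergenic_range[1]:spec$intergenic_range[2], 1L))
      contigs[ci] <- paste(c(parts, tail_sp), collapse = "")
    }
    names(contigs) <- contig_ids
    genes_df <- do.call(rbind, lapply(gene_rows, as.data.frame))
    exons_df <- do.call(rbind, exon_rows)
    rownames(genes_df) <- rownames(exons_df) <- NULL
    structure(list(contigs = contigs, genes = genes_df, exons = exons_df,
                   ancestors = ancestors, refs = refs, spec = spec),
              class = "cea_genome")
  })
}

.empty_gene_truth <- function() {
  data.frame(gene_id = character(0), contig_id = character(0),
             strand = character(0), start = integer(0), end = integer(0),
             architecture = character(0), signaling = character(0),
             subgroup = character(0), is_pseudogene = logical(0),
             tm_type = character(0), igc_stop_codon = integer(0),
             n_stop_codon = integer(0), donor_mutated_junction = integer(0),
             stringsAsFactors = FALSE)
}

.empty_exon_truth <- function() {
  data.frame(gene_id = character(0), contig_id = character(0),
             domain = character(0), start = integer(0), end = integer(0),
             strand = character(0), tx_index = integer(0),
             stringsAsFactors = FALSE)
}

# build one planted gene: draws its architecture, mutates the ancestral
# cassette, plants stops/motifs/splice sites, and assembles the gene block
.build_gene <- function(g, spec, refs, ancestors) {
  L <- spec$exon_lengths
  layout <- attr(refs, "motifs")
  is_psg <- stats::runif(1) < spec$psg_fraction
  pseudo <- stats::runif(1) < spec$pseudogene_fraction
  div <- spec$paralog_divergence

  if (is_psg) {
    two_dom <- stats::runif(1) < 0.5
    subgroup <- if (stats::runif(1) < 0.5) "PSG-I" else "PSG-II"
    arch <- if (two_dom) "PSG-2dom" else "PSG-1dom"
    signaling <- "secreted"
    tm_type <- NA_character_
    donor_junction <- NA_integer_
    domains <- c("leader", "N", "A2")
    anc <- list(leader = refs$leader, N = ancestors[[subgroup]], A2 = refs$A2)
    n_igc_cod <- L[["A2"]] / 3L
    igc_stop <- if (two_dom) sample((n_igc_cod - 5L):n_igc_cod, 1L)
                else sample(10L:(n_igc_cod - 7L), 1L)
  } else {
    activating <- stats::runif(1) < spec$tm_activating_fraction
    itsm <- !activating && stats::runif(1) < spec$itsm_fraction
    donor_mut <- stats::runif(1) < spec$donor_mutated_fraction
    subgroup <- "CEACAM"
    base_arch <- if (activating) "CEACAM-ITAM" else if (itsm) "CEACAM-ITSM" else "CEACAM-ITIM"
    arch <- if (donor_mut) "CEACAM-nonfunctional" else base_arch
    signaling <- if (donor_mut) "nonfunctional"
                 else if (activating) "activating"
                 else if (itsm) "inhibitory-ITSM" else "inhibitory"
    tm_type <- if (activating) "CEACAM3-like" else "CEACAM1-like"
    donor_junction <- if (donor_mut) 7L else NA_integer_  # junction after Cyt1
    domains <- c("leader", "N", "A1", "B", "A2", "TM", "Cyt1", "Cyt2")
    cyt1_ref <- if (activating) "Cyt1_act" else "Cyt1_inh"
    cyt2_ref <- if (activating) "Cyt2_act" else if (itsm) "Cyt2_itsm" else "Cyt2_inh"
    anc <- list(leader = refs$leader, N = ancestors$CEACAM,
                A1 = refs$A1, B = refs$B, A2 = refs$A2,
                TM = if (activating) refs$TM_CEACAM3 else refs$TM_CEACAM1,
                Cyt1 = refs[[cyt1_ref]], Cyt2 = refs[[cyt2_ref]])
    igc_stop <- NA_integer_
    cyt1_lay <- layout[[cyt1_ref]]; cyt2_lay <- layout[[cyt2_ref]]
  }

  n_stop <- if (pseudo) sample(setdiff(6L:100L, 30L:32L), 1L) else NA_integer_

  exon_seq <- list()
  for (d in domains) {
    s <- anc[[d]]
    protect <- integer(0)
    keep_stop <- integer(0)
    if (d == "leader") protect <- 1:3
    if (d == "N" && !is.na(n_stop)) {
      s <- .plant_codons(s, n_stop, sample(stop_codon_set(), 1L))
      protect <- .codon_nt(n_stop)
      keep_stop <- n_stop
    }
    if (d == "A2" && !is.na(igc_stop)) {
      s <- .plant_codons(s, igc_stop, sample(stop_codon_set(), 1L))
      protect <- .codon_nt(igc_stop)
      keep_stop <- igc_stop
    }
    if (!is_psg && d == "Cyt1" && length(cyt1_lay$kinds)) {
      protect <- c(protect, .codon_nt(unlist(lapply(cyt1_lay$kinds, function(k)
        .motif_codon_span(cyt1_lay$at[[k]], cyt1_lay$codons[[k]])))))
    }
    if (!is_psg && d == "Cyt2" && length(cyt2_lay$kinds)) {
      protect <- c(protect, .codon_nt(unlist(lapply(cyt2_lay$kinds, function(k)
        .motif_codon_span(cyt2_lay$at[[k]], cyt2_lay$codons[[k]])))))
    }
    m <- mutate_seq(s, div, protect = protect)
    m <- .revert_stops(m, s, keep = keep_stop)
    exon_seq[[d]] <- m
  }

  # keep the emitted motif set equal to the planted one despite divergence
  if (!is_psg) {
    expected <- .expected_motif_hits(cyt1_lay, cyt2_lay, nchar(exon_seq$Cyt1) %/% 3L)
    cl <- .clean_cyt_pair(exon_seq$Cyt1, exon_seq$Cyt2,
                          anc$Cyt1, anc$Cyt2, expected)
    exon_seq$Cyt1 <- cl[[1]]; exon_seq$Cyt2 <- cl[[2]]
  }

  # assemble block: 5' flank ending in AG, exons separated by GT..AG introns,
  # 3' flank starting with GT
  parts <- character(0)
  rel <- data.frame(domain = domains, start = NA_integer_, end = NA_integer_,
                    stringsAsFactors = FALSE)
  pos <- 0L
  flank5 <- paste0(random_dna(48L), "AG")
  parts <- c(parts, flank5); pos <- pos + nchar(flank5)
  for (k in seq_along(domains)) {
    d <- domains[k]
    rel$start[k] <- pos
    rel$end[k] <- pos + nchar(exon_seq[[d]])
    parts <- c(parts, exon_seq[[d]])
    pos <- rel$end[k]
    if (k < length(domains)) {
      donor_ok <- !(!is.na(donor_junction) && k == donor_junction)
      ilen <- sample(spec$intron_length_range[1]:spec$intron_length_range[2], 1L)
      intron <- paste0(if (donor_ok) "GT" else "AT",
                       random_dna(ilen - 4L), "AG")
      parts <- c(parts, intron); pos <- pos + nchar(intron)
    }
  }
  flank3 <- paste0("GT", random_dna(160L))
  parts <- c(parts, flank3); pos <- pos + nchar(flank3)
  block <- paste(parts, collapse = "")

  # polyadenylation signal 40 nt downstream of the PSG stop codon
  if (is_psg) {
    a2_start <- rel$start[rel$domain == "A2"]
    p <- a2_start + igc_stop * 3L + 40L   # 0-based offset into block
    substr(block, p + 1L, p + 6L) <- "AATAAA"
  }

  strand <- "+"
  if (spec$randomize_strand && stats::runif(1) < 0.5) {
    strand <- "-"
    lb <- nchar(block)
    block <- revcomp(block)
    new_start <- lb - rel$end
    new_end <- lb - rel$start
    rel$start <- new_start; rel$end <- new_end
  }

  gene_id <- sprintf("simgene_%03d", g)
  exons <- data.frame(gene_id = gene_id, contig_id = NA_character_,
                      domain = rel$domain, start = rel$start, end = rel$end,
                      strand = strand, tx_index = seq_along(domains),
                      stringsAsFactors = FALSE)
  gene <- list(gene_id = gene_id, contig_id = NA_character_, strand = strand,
               start = NA_integer_, end = NA_integer_,
               architecture = arch, signaling = signaling,
               subgroup = subgroup, is_pseudogene = pseudo,
               tm_type = tm_type, igc_stop_codon = if (is.na(igc_stop)) NA_integer_ else igc_stop - 1L,
               n_stop_codon = if (is.na(n_stop)) NA_integer_ else n_stop - 1L,
               donor_mutated_junction = donor_junction)
  list(block = block, exons = exons, gene = gene)
}

# expected motif hits on the concatenated cytoplasmic translation
.expected_motif_hits <- function(cyt1_lay, cyt2_lay, n1_codons) {
  rows <- list()
  add <- function(kind, at, codons, offset) {
    start0 <- offset + at - 1L
    y_off <- if (kind == "ITAM") 0L else 2L
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, tyrosine_position = start0 + y_off,
      start = start0, end = start0 + length(codons), stringsAsFactors = FALSE)
  }
  for (k in cyt1_lay$kinds) add(k, cyt1_lay$at[[k]], cyt1_lay$codons[[k]], 0L)
  for (k in cyt2_lay$kinds) add(k, cyt2_lay$at[[k]], cyt2_lay$codons[[k]], n1_codons)
  if (!length(rows)) return(data.frame(kind = character(0),
                                       tyrosine_position = integer(0),
                                       start = integer(0), end = integer(0)))
  do.call(rbind, rows)
}

#' Write a simulated genome to disk
#'
#' Emits the contigs as wrapped FASTA, the truth exons as GFF3 (gene/exon
#' hierarchy with `ID`/`Parent` attributes) and the truth tables as TSV.
#'
#' @param sim A `cea_genome` from [simulate_genome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_genome <- function(sim, dir) {
  stopifnot(inherits(sim, "cea_genome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fasta = file.path(dir, "contigs.fa"),
    gff3 = file.path(dir, "truth.gff3"),
    genes = file.path(dir, "truth_genes.tsv"),
    exons = file.path(dir, "truth_exons.tsv")
  )
  write_fasta(sim$contigs, paths["fasta"])
  write_truth_gff3(sim, paths["gff3"])
  write_tsv(sim$genes, paths["genes"])
  write_tsv(sim$exons, paths["exons"])
  invisible(paths)
}

# truth GFF3 (gene + exon records); coordinates converted to 1-based inclusive
write_truth_gff3 <- function(sim, path) {
  if (!nrow(sim$exons)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  g <- sim$genes; e <- sim$exons
  gr_gene <- GenomicRanges::GRanges(
    seqnames = g$contig_id,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand, type = "gene", ID = g$gene_id,
    architecture = g$architecture)
  gr_exon <- GenomicRanges::GRanges(
    seqnames = e$contig_id,
    ranges = IRanges::IRanges(start = e$start + 1L, end = e$end),
    strand = e$strand, type = "exon",
    ID = paste0(e$gene_id, ":", e$domain),
    architecture = NA_character_)
  S4Vectors::mcols(gr_exon)$Parent <- e$gene_id
  S4Vectors::mcols(gr_gene)$Parent <- NA_character_
  gr <- c(gr_gene, gr_exon)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
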