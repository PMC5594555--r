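# Assembly of exon calls into gene models, ORF/pseudogene status, IgC
# subtype typing, PSG vs receptor architecture classification,
# N-glycosylation counting and the per-species census.

.DOMAIN_RANK <- c(leader = 1, N = 2, A1 = 3, B = 4, A2 = 5,
                  TM = 6, Cyt1 = 7, Cyt2 = 8)

#' ORF status of an exon sequence
#'
#' Reading frame is given by the exon phase (phase 0 by default; phase-0
#' junctions are assumed throughout). The ORF is intact iff no in-frame stop
#' codon occurs before the exon's final codon.
#'
#' @param seq Exon nucleotide sequence (length >= 3).
#' @param phase Exon phase (0, 1 or 2); bases skipped before the first codon.
#' @return List with `orf_intact` and `stop_positions` (0-based codon
#'   indices of every in-frame stop, including a terminal one).
#' @export
#' @examples
#' call_orf_status("ATGTAACCC")   # stop at codon 1
call_orf_status <- function(seq, phase = 0L) {
  if (grepl("[^ACGTN]", seq)) {
    stop("famscan input error: sequence contains non-ACGTN characters")
  }
  if (nchar(seq) < 3L) stop("famscan input error: exon sequence shorter than one codon")
  body <- substr(seq, phase + 1L, nchar(seq))
  cds <- codons_of(body)
  stops <- which(cds %in% stop_codon_set()) - 1L
  list(orf_intact = !any(stops < length(cds) - 1L), stop_positions = stops)
}

#' Assemble exon calls into gene models
#'
#' Exon calls are grouped per contig and strand, ordered in transcript
#' orientation and chained into genes. A new gene is opened whenever the
#' intra-gene gap would exceed `max_gap`, whenever a second N-domain exon
#' would otherwise enter the model (each CEA family gene contains a single N
#' exon), and more generally whenever the expected domain order
#' (leader < N < A1 < B < A2 < TM < Cyt1 < Cyt2) fails to advance, since a
#' repeated or regressing domain marks the start of the next cassette.
#' Exons that cannot be chained become single-exon (orphan) models.
#'
#' @param calls Exon-call data frame from [iterative_mine()].
#' @param max_gap Maximum intra-gene distance between consecutive exons (nt).
#' @return List of `gene_model` objects: each a list with `gene_id`,
#'   `contig_id`, `strand`, `exons` (calls in transcript order), per-exon
#'   `orf` results and the gene span.
#' @export
assemble_gene_models <- function(calls, max_gap = 25000L) {
  if (!nrow(calls)) return(list())
  models <- list()
  for (key in unique(paste(calls$contig_id, calls$strand))) {
    sub <- calls[paste(calls$contig_id, calls$strand) == key, , drop = FALSE]
    sub <- if (sub$strand[1] == "+") sub[order(sub$start), , drop = FALSE]
           else sub[order(-sub$start), , drop = FALSE]
    grp <- integer(nrow(sub))
    gid <- 1L
    for (i in seq_len(nrow(sub))) {
      if (i > 1L) {
        gap <- if (sub$strand[1] == "+") sub$start[i] - sub$end[i - 1L]
               else sub$start[i - 1L] - sub$end[i]
        rank_prev <- .DOMAIN_RANK[[sub$domain_type[i - 1L]]]
        rank_cur <- .DOMAIN_RANK[[sub$domain_type[i]]]
        if (gap > max_gap || is.null(rank_cur) || is.null(rank_prev) ||
            rank_cur <= rank_prev) {
          gid <- gid + 1L
        }
      }
      grp[i] <- gid
    }
    for (gidx in unique(grp)) {
      ex <- sub[grp == gidx, , drop = FALSE]
      orf <- lapply(ex$sequence, call_orf_status)
      models[[length(models) + 1L]] <- structure(list(
        gene_id = NA_character_,
        contig_id = ex$contig_id[1], strand = ex$strand[1],
        start = min(ex$start), end = max(ex$end),
        exons = ex, orf = orf
      ), class = "gene_model")
    }
  }
  # deterministic ordering and ids
  ord <- order(vapply(models, `[[`, character(1), "contig_id"),
               vapply(models, `[[`, integer(1), "start"))
  models <- models[ord]
  for (i in seq_along(models)) models[[i]]$gene_id <- sprintf("gene_%03d", i)
  models
}

#' Classify the architecture of a gene model
#'
#' A model with a TM exon is a membrane-anchored receptor (`CEACAM-TM`).
#' A model without a TM exon whose (terminal) IgC-like exon carries an
#' in-frame stop codon is a secreted PSG: a first stop within the final
#' `terminal_codons` codons of the exon yields a two-domain PSG
#' (`PSG-2dom`), an earlier stop a one-domain PSG (`PSG-1dom`). Models
#' lacking both IgC and TM exons are `orphan`. IgC exons are (re)typed as
#' A1/B/A2 by highest alignment score against the reference IgC exons; the
#' N-domain exon drives the pseudogene call and the N-glycosylation count.
#'
#' @param model A `gene_model`.
#' @param igc_references Named nucleotide references for IgC typing
#'   (defaults to the package reference A1/B/A2 exons).
#' @param contig_seq Optional contig sequence; when given, the
#'   polyadenylation signal (AATAAA) is sought within `polya_window` nt
#'   downstream of a PSG stop codon.
#' @param terminal_codons Size of the exon-terminal stop region (codons).
#' @param polya_window Downstream window for the polyadenylation signal (nt).
#' @return The model with added fields: `architecture`, `igc_subtypes`,
#'   `is_pseudogene`, `n_stop_codons`, `igc_stop_codon`, `n_glyc_sites`,
#'   `orf_intact`, `has_polya`.
#' @export
classify_architecture <- function(model, igc_references = NULL,
                                  contig_seq = NULL,
                                  terminal_codons = 6L,
                                  polya_window = 200L) {
  stopifnot(inherits(model, "gene_model"))
  if (is.null(igc_references)) {
    refs <- reference_exons()
    igc_references <- c(A1 = refs$A1, B = refs$B, A2 = refs$A2)
  }
  ex <- model$exons
  igc_idx <- which(ex$domain_type %in% c("A1", "B", "A2"))
  model$igc_subtypes <- if (length(igc_idx)) {
    vapply(igc_idx, function(i) {
      .nearest_reference(ex$sequence[i], igc_references)$label
    }, character(1))
  } else character(0)
  if (length(igc_idx)) {
    ex$domain_type[igc_idx] <- model$igc_subtypes
    model$exons <- ex
  }
  has_tm <- any(ex$domain_type == "TM")
  n_idx <- which(ex$domain_type == "N")

  model$is_pseudogene <- FALSE
  model$n_stop_codons <- integer(0)
  model$n_glyc_sites <- NA_integer_
  if (length(n_idx)) {
    orf_n <- model$orf[[n_idx[1]]]
    model$is_pseudogene <- !orf_n$orf_intact
    model$n_stop_codons <- orf_n$stop_positions
    model$n_glyc_sites <- count_nglyc(translate_nt(ex$sequence[n_idx[1]]))
  }

  model$igc_stop_codon <- NA_integer_
  model$has_polya <- NA
  if (has_tm) {
    model$architecture <- "CEACAM-TM"
  } else if (length(igc_idx)) {
    term <- igc_idx[length(igc_idx)]  # terminal IgC exon in transcript order
    cds <- codons_of(ex$sequence[term])
    stops <- which(cds %in% stop_codon_set()) - 1L
    if (length(stops)) {
      first <- stops[1]
      model$igc_stop_codon <- first
      model$architecture <- if (first >= length(cds) - terminal_codons) {
        "PSG-2dom"
      } else "PSG-1dom"
      if (!is.null(contig_seq)) {
        model$has_polya <- .polya_downstream(ex[term, ], first, contig_seq,
                                             polya_window)
      }
    } else {
      model$architecture <- "orphan"
    }
  } else {
    model$architecture <- "orphan"
  }
  model$orf_intact <- all(vapply(seq_along(model$orf), function(i) {
    st <- model$orf[[i]]$stop_positions
    plant <- if (!is.na(model$igc_stop_codon) &&
                 length(igc_idx) && i == igc_idx[length(igc_idx)]) {
      TRUE  # PSG stop is part of the architecture, not a defect
    } else FALSE
    plant || model$orf[[i]]$orf_intact
  }, logical(1)))
  model
}

.nearest_reference <- function(seq, refs, params = mining_params()) {
  sm <- .sub_matrix(params$match, params$mismatch)
  scores <- vapply(refs, function(r) {
    Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seq), Biostrings::DNAString(r),
      type = "local", substitutionMatrix = sm,
      gapOpening = params$gap_open, gapExtension = params$gap_extend))
  }, numeric(1))
  best <- max(scores)
  winners <- names(refs)[scores == best]
  list(label = sort(winners)[1], score = best, tie = length(winners) > 1L)
}

# AATAAA within `window` nt downstream of the stop codon (strand-aware)
.polya_downstream <- function(exon_row, stop_codon0, contig_seq, window) {
  if (exon_row$strand == "+") {
    p0 <- exon_row$start + (stop_codon0 + 1L) * 3L
    region <- seq_slice(contig_seq, p0, min(nchar(contig_seq), p0 + window))
  } else {
    p1 <- exon_row$end - (stop_codon0 + 1L) * 3L
    region <- revcomp(seq_slice(contig_seq, max(0L, p1 - window), p1))
  }
  grepl("AATAAA", region, fixed = TRUE)
}

#' Count N-glycosylation sequons
#'
#' Counts N-X-\[S/T\] sequons with X != P, non-overlapping from the left;
#' the scanned region is truncated at the first stop character.
#'
#' @param aa_seq Amino-acid string (translated IgV domain).
#' @return Integer count.
#' @export
#' @examples
#' count_nglyc("NPSNAT")  # NPS rejected (X = P), NAT counted
count_nglyc <- function(aa_seq) {
  s <- sub("\\*.*$", "", aa_seq)
  if (!nzchar(s)) return(0L)
  m <- gregexpr("N[^P][ST]", s)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' Per-species census of the annotated family
#'
#' Tallies N-domain exons (total and ORF-intact) and the architecture and
#' signaling classes, mirroring the per-species totals used to describe a
#' family expansion.
#'
#' @param models List of classified `gene_model`s (after
#'   [classify_architecture()] and, for receptor tallies,
#'   [classify_receptor_signaling()]).
#' @param species Species label for the row.
#' @return One-row data frame: `species`, `n_exons_total`, `n_exons_orf`,
#'   `n_psg1dom`, `n_psg2dom`, `n_tm_itim`, `n_tm_itam`.
#' @export
census <- function(models, species = "sample") {
  has_n <- vapply(models, function(m) any(m$exons$domain_type == "N"), logical(1))
  n_orf <- vapply(models, function(m) {
    i <- which(m$exons$domain_type == "N")
    length(i) > 0L && m$orf[[i[1]]]$orf_intact
  }, logical(1))
  arch <- vapply(models, function(m) m$architecture %||% "orphan", character(1))
  sig <- vapply(models, function(m) {
    if (!is.null(m$receptor)) m$receptor$signaling else NA_character_
  }, character(1))
  data.frame(
    species = species,
    n_exons_total = sum(has_n),
    n_exons_orf = sum(n_orf),
    n_psg1dom = sum(arch == "PSG-1dom"),
    n_psg2dom = sum(arch == "PSG-2dom"),
    n_tm_itim = sum(sig %in% c("inhibitory", "inhibitory-ITSM"), na.rm = TRUE),
    n_tm_itam = sum(sig == "activating", na.rm = TRUE),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign family-style gene names
#'
#' Receptor genes are named `CEACAM1-like_k` (inhibitory) or
#' `CEACAM3-like_k` (activating), secreted genes `PSGk`, remaining models
#' `CEACAM-like_k`, each prefixed with the species label.
#'
#' @param models List of classified models.
#' @param species_prefix Species prefix, e.g. `"Mlu"`.
#' @return The models with `gene_id` replaced by family-style names.
#' @export
name_models <- function(models, species_prefix = "Sim") {
  counters <- c(psg = 0L, cc1 = 0L, cc3 = 0L, other = 0L)
  for (i in seq_along(models)) {
    m <- models[[i]]
    sig <- if (!is.null(m$receptor)) m$receptor$signaling else NA_character_
    nm <- if (!is.null(m$architecture) && startsWith(m$architecture, "PSG")) {
      counters["psg"] <- counters["psg"] + 1L
      sprintf("%s_PSG%d", species_prefix, counters["psg"])
    } else if (identical(sig, "inhibitory") || identical(sig, "inhibitory-ITSM")) {
      counters["cc1"] <- counters["cc1"] + 1L
      sprintf("%s_CEACAM1-like_%d", species_prefix, counters["cc1"])
    } else if (identical(sig, "activating")) {
      counters["cc3"] <- counters["cc3"] + 1L
      sprintf("%s_CEACAM3-like_%d", species_prefix, counters["cc3"])
    } else {
      counters["other"] <- counters["other"] + 1L
      sprintf("%s_CEACAM-like_%d", species_prefix, counters["other"])
    }
    models[[i]]$gene_id <- nm
  }
  models
}

#' Flatten gene models to a data frame
#' @param models List of `gene_model`s.
#' @return Data frame with one row per model.
#' @export
models_to_df <- function(models) {
  if (!length(models)) {
    return(data.frame(gene_id = character(0), contig_id = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), n_exons = integer(0),
                      architecture = character(0), is_pseudogene = logical(0),
                      n_glyc_sites = integer(0), tm_type = character(0),
                      signaling = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(models, function(m) {
    data.frame(gene_id = m$gene_id, contig_id = m$contig_id,
               strand = m$strand, start = m$start, end = m$end,
               n_exons = nrow(m$exons),
               architecture = m$architecture %||% NA_character_,
               is_pseudogene = m$is_pseudogene %||% NA,
               n_glyc_sites = m$n_glyc_sites %||% NA_integer_,
               tm_type = if (!is.null(m$receptor)) m$receptor$tm_type else NA_character_,
               signaling = if (!is.null(m$receptor)) m$receptor$signaling else NA_character_,
               stringsAsFactors = FALSE)
  }))
}
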