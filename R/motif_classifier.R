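# Tyrosine-based signaling motif detection in translated cytoplasmic exons,
# splice-donor verification and receptor classification.
#
# Consensus patterns (standard immunology definitions; configurable):
#   ITIM  [ILVS] x Y x x [ILV]
#   ITSM  T x Y x x [VI]
#   ITAM  Y x x [LI] x{6,12} Y x x [LI]
# An ITIM and an ITSM sharing the same tyrosine are reported as ITSM only;
# tyrosines that are part of an ITAM are not additionally reported as
# ITIM/ITSM (an ITAM half-site can match the looser ITIM consensus).

.AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                  "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "*", "-")

.empty_motifs <- function() {
  data.frame(kind = character(0), tyrosine_position = integer(0),
             start = integer(0), end = integer(0),
             matched_text = character(0), stringsAsFactors = FALSE)
}

#' Detect ITIM, ITSM and ITAM motifs in an amino-acid sequence
#'
#' All match positions are scanned (overlapping matches at different
#' tyrosines are all reported); an ITIM and an ITSM centred on the same
#' tyrosine collapse to the ITSM. For an ITAM the shortest admissible spacer
#' (6-12 residues) is taken per starting tyrosine.
#'
#' @param aa_seq Amino-acid string (may be empty).
#' @param itam_spacer Allowed ITAM spacer lengths (residues).
#' @return Data frame of hits sorted by position: `kind`,
#'   `tyrosine_position` (0-based index of the (first) motif tyrosine),
#'   `start`, `end` (0-based half-open span) and `matched_text`.
#' @export
#' @examples
#' detect_tyrosine_motifs("AASVYTTLAA")    # one ITIM
#' detect_tyrosine_motifs("ATEYSSVA")      # one ITSM
detect_tyrosine_motifs <- function(aa_seq, itam_spacer = 6:12) {
  if (!nzchar(aa_seq)) return(.empty_motifs())
  ch <- strsplit(aa_seq, "", fixed = TRUE)[[1]]
  if (any(!ch %in% .AA_ALPHABET)) {
    stop("famscan input error: non-amino-acid characters in sequence")
  }
  n <- length(ch)
  rows <- list()
  itam_y <- integer(0)
  add <- function(kind, start1, end1, y1) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, tyrosine_position = y1 - 1L,
      start = start1 - 1L, end = end1,
      matched_text = paste(ch[start1:end1], collapse = ""),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(max(0L, n - 5L))) {
    if (ch[i + 2L] == "Y" && ch[i + 5L] %in% c("I", "L", "V")) {
      if (ch[i] %in% c("I", "L", "V", "S")) add("ITIM", i, i + 5L, i + 2L)
    }
    if (ch[i] == "T" && ch[i + 2L] == "Y" && ch[i + 5L] %in% c("V", "I")) {
      add("ITSM", i, i + 5L, i + 2L)
    }
  }
  for (i in seq_len(max(0L, n - 3L))) {
    if (ch[i] != "Y" || !ch[i + 3L] %in% c("L", "I")) next
    for (sp in sort(itam_spacer)) {
      j <- i + 4L + sp
      if (j + 3L > n) break
      if (ch[j] == "Y" && ch[j + 3L] %in% c("L", "I")) {
        add("ITAM", i, j + 3L, i)
        itam_y <- c(itam_y, i - 1L, j - 1L)
        break
      }
    }
  }
  if (!length(rows)) return(.empty_motifs())
  hits <- do.call(rbind, rows)
  itsm_y <- hits$tyrosine_position[hits$kind == "ITSM"]
  drop <- (hits$kind == "ITIM" & hits$tyrosine_position %in% itsm_y) |
    (hits$kind %in% c("ITIM", "ITSM") & hits$tyrosine_position %in% itam_y)
  hits <- hits[!drop, , drop = FALSE]
  hits <- hits[order(hits$tyrosine_position, hits$kind), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Check splice-donor functionality at every inter-exon junction
#'
#' Each junction between consecutive exons (transcript order) is labeled
#' `canonical` when the two intron bases immediately downstream of the
#' upstream exon read GT, `mutated` otherwise, and `unknown` when the contig
#' is unavailable or the junction lies outside it.
#'
#' @param model A `gene_model` with >= 2 exons.
#' @param contig_seq The contig sequence (or NULL).
#' @return Data frame: `junction` (1-based index after the k-th exon),
#'   `upstream_domain`, `dinucleotide`, `status`.
#' @export
check_splice_donor <- function(model, contig_seq = NULL) {
  stopifnot(inherits(model, "gene_model"))
  ex <- model$exons
  k <- nrow(ex) - 1L
  if (k < 1L) {
    return(data.frame(junction = integer(0), upstream_domain = character(0),
                      dinucleotide = character(0), status = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- lapply(seq_len(k), function(i) {
    dinuc <- NA_character_
    status <- "unknown"
    if (!is.null(contig_seq)) {
      if (ex$strand[i] == "+") {
        p <- ex$end[i]
        if (p + 2L <= nchar(contig_seq)) dinuc <- seq_slice(contig_seq, p, p + 2L)
      } else {
        p <- ex$start[i]
        if (p - 2L >= 0L) dinuc <- revcomp(seq_slice(contig_seq, p - 2L, p))
      }
      if (!is.na(dinuc)) status <- if (dinuc == "GT") "canonical" else "mutated"
    }
    data.frame(junction = i, upstream_domain = ex$domain_type[i],
               dinucleotide = dinuc, status = status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Classify receptor signaling of a gene model
#'
#' The transmembrane type is assigned by the higher alignment score of the
#' TM exon against the CEACAM1-like and CEACAM3-like TM references (ties
#' broken by score then lexical reference order and recorded). Signaling is
#' derived from the motifs of the concatenated translated cytoplasmic exons
#' (ITAM => activating; ITIM+ITSM => inhibitory-ITSM; any ITIM or ITSM =>
#' inhibitory), overridden to `nonfunctional` when any splice donor at or
#' downstream of the TM exon is mutated; a model without a TM exon is
#' `secreted`.
#'
#' @param model A classified `gene_model`.
#' @param tm_references Named nucleotide references, default the package
#'   CEACAM1/CEACAM3 TM exons.
#' @param contig_seq Contig sequence for the splice-donor check (optional;
#'   without it donor status is `unknown` and no override applies).
#' @return The model with a `receptor` field: list with `tm_type`,
#'   `motifs` (hit data frame), `signaling`, `tie` and `donor_status`.
#' @export
classify_receptor_signaling <- function(model, tm_references = NULL,
                                        contig_seq = NULL) {
  stopifnot(inherits(model, "gene_model"))
  if (is.null(tm_references)) {
    refs <- reference_exons()
    tm_references <- c(`CEACAM1-like` = refs$TM_CEACAM1,
                       `CEACAM3-like` = refs$TM_CEACAM3)
  }
  ex <- model$exons
  tm_idx <- which(ex$domain_type == "TM")
  if (!length(tm_idx)) {
    model$receptor <- list(tm_type = "none", motifs = .empty_motifs(),
                           signaling = "secreted", tie = FALSE,
                           donor_status = check_splice_donor(model, contig_seq))
    return(model)
  }
  nr <- .nearest_reference(ex$sequence[tm_idx[1]], tm_references)
  cyt_idx <- which(ex$domain_type %in% c("Cyt1", "Cyt2"))
  cyt_aa <- if (length(cyt_idx)) {
    translate_nt(paste(ex$sequence[cyt_idx], collapse = ""))
  } else ""
  motifs <- detect_tyrosine_motifs(cyt_aa)
  donors <- check_splice_donor(model, contig_seq)
  donor_mut <- any(donors$status == "mutated" & donors$junction >= tm_idx[1])
  signaling <- if (donor_mut) {
    "nonfunctional"
  } else if (any(motifs$kind == "ITAM")) {
    "activating"
  } else if (any(motifs$kind == "ITIM") && any(motifs$kind == "ITSM")) {
    "inhibitory-ITSM"
  } else if (any(motifs$kind %in% c("ITIM", "ITSM"))) {
    if (any(motifs$kind == "ITSM")) "inhibitory-ITSM" else "inhibitory"
  } else {
    "nonfunctional"
  }
  model$receptor <- list(tm_type = nr$label, motifs = motifs,
                         signaling = signaling, tie = nr$tie,
                         donor_status = donors)
  model
}
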