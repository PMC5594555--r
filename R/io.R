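# Standard-format readers and writers. Internal coordinates are 0-based
# half-open everywhere; GFF3 is emitted/read as 1-based inclusive and BED as
# 0-based half-open, converting only at these boundaries.

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @param type `"dna"` or `"aa"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("famscan parse error: no such file: ", path)
  set <- tryCatch({
    if (type == "dna") Biostrings::readDNAStringSet(path)
    else Biostrings::readAAStringSet(path)
  }, error = function(e) {
    stop("famscan parse error in ", path, ": ", conditionMessage(e))
  })
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to FASTA (wrapped at 60 columns)
#' @param x Named character vector of sequences.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path) {
  set <- if (!length(x)) {
    Biostrings::BStringSet()
  } else if (all(!grepl("[^ACGTN-]", x))) {
    Biostrings::DNAStringSet(x)
  } else {
    Biostrings::AAStringSet(x)
  }
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Write a data frame as TSV
#' @param df Data frame.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path File path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("famscan parse error: no such file: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Convert exon calls to a GRanges (1-based, for serialization)
#' @param calls Exon-call data frame.
#' @return A `GRanges` with call metadata.
#' @export
calls_to_granges <- function(calls) {
  if (!nrow(calls)) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = calls$contig_id,
    ranges = IRanges::IRanges(start = calls$start + 1L, end = calls$end),
    strand = calls$strand,
    type = "exon",
    ID = sprintf("exoncall_%03d", seq_len(nrow(calls))),
    domain = calls$domain_type,
    score = calls$score)
}

#' Write exon calls as GFF3
#' @param calls Exon-call data frame.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_calls_gff3 <- function(calls, path) {
  gr <- calls_to_granges(calls)
  if (!length(gr)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write exon calls as BED (0-based half-open)
#' @param calls Exon-call data frame.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_calls_bed <- function(calls, path) {
  if (!nrow(calls)) {
    file.create(path)
    return(invisible(path))
  }
  gr <- calls_to_granges(calls)
  names(gr) <- paste0(S4Vectors::mcols(gr)$ID, "_", S4Vectors::mcols(gr)$domain)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a GFF3 file into a 0-based data frame
#' @param path GFF3 file.
#' @return Data frame: `contig_id`, `start` (0-based), `end`, `strand`,
#'   `type`, `ID`, `Parent`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("famscan parse error: no such file: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) {
                   stop("famscan parse error in ", path, ": ",
                        conditionMessage(e))
                 })
  if (!length(gr)) {
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      type = character(0), ID = character(0),
                      Parent = character(0), stringsAsFactors = FALSE))
  }
  mc <- S4Vectors::mcols(gr)
  parent <- if ("Parent" %in% names(mc)) {
    vapply(as.list(mc$Parent), function(p) {
      if (length(p)) as.character(p[1]) else NA_character_
    }, character(1))
  } else NA_character_
  data.frame(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = if ("type" %in% names(mc)) as.character(mc$type) else NA_character_,
    ID = if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_,
    Parent = parent, stringsAsFactors = FALSE)
}

#' Write gene models as GFF3 (gene/mRNA/exon hierarchy)
#' @param models List of `gene_model`s.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_models_gff3 <- function(models, path) {
  if (!length(models)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  rows <- list()
  for (m in models) {
    mrna_id <- paste0(m$gene_id, ".t1")
    rows[[length(rows) + 1L]] <- data.frame(
      contig = m$contig_id, start = m$start + 1L, end = m$end,
      strand = m$strand, type = c("gene", "mRNA"),
      ID = c(m$gene_id, mrna_id),
      Parent = c(NA_character_, m$gene_id), stringsAsFactors = FALSE)
    ex <- m$exons
    rows[[length(rows) + 1L]] <- data.frame(
      contig = ex$contig_id, start = ex$start + 1L, end = ex$end,
      strand = ex$strand, type = "exon",
      ID = sprintf("%s.exon%d", m$gene_id, seq_len(nrow(ex))),
      Parent = mrna_id, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand, type = df$type, ID = df$ID)
  S4Vectors::mcols(gr)$Parent <- df$Parent
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a tree in Newick format (supports as internal node labels)
#' @param tree `ape::phylo`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Newick file.
#' @return `ape::phylo`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("famscan parse error: no such file: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("famscan parse error in ", path, ": not a Newick tree")
  tr
}
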