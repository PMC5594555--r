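# Low-level nucleotide / codon utilities shared by all modules.
# Internal coordinate convention everywhere: 0-based half-open intervals;
# conversion to 1-based happens only at serialization boundaries (GFF3) and
# at substring access.

DNA_BASES <- c("A", "C", "G", "T")

.fam_cache <- new.env(parent = emptyenv())

#' Standard nuclear genetic code as a named character vector
#'
#' @return Named character vector mapping the 64 codons to one-letter amino
#'   acids, with `"*"` for the three stop codons.
#' @keywords internal
genetic_code <- function() {
  if (is.null(.fam_cache$code)) {
    code <- Biostrings::GENETIC_CODE
    .fam_cache$code <- stats::setNames(as.character(code), names(code))
  }
  .fam_cache$code
}

#' The 61 sense codons in lexical order
#' @keywords internal
sense_codons <- function() {
  code <- genetic_code()
  sort(names(code)[code != "*"])
}

stop_codon_set <- function() c("TAA", "TAG", "TGA")

#' Split a nucleotide string into its in-frame codons
#'
#' Trailing bases that do not complete a codon are dropped.
#' @param seq A nucleotide string.
#' @return Character vector of codons (possibly empty).
#' @keywords internal
codons_of <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate a nucleotide string with the standard code
#'
#' Unknown codons (containing N or other ambiguity characters) translate to
#' `"X"`; stops to `"*"`. A trailing partial codon is ignored.
#' @param seq A nucleotide string.
#' @return An amino-acid string.
#' @export
#' @examples
#' translate_nt("ATGGGGTAA")
translate_nt <- function(seq) {
  cds <- codons_of(seq)
  if (!length(cds)) return("")
  aa <- genetic_code()[cds]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Reverse complement of nucleotide strings
#' @param x Character vector of nucleotide strings (IUPAC letters allowed).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Random DNA with a given GC content
#' @param n Length in nucleotides.
#' @param gc GC proportion in \[0,1\].
#' @return A nucleotide string.
#' @export
random_dna <- function(n, gc = 0.4) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Random in-frame coding sequence
#' @param n_codons Number of codons.
#' @param avoid_stop Draw only sense codons (default TRUE).
#' @return A nucleotide string of `3 * n_codons` bases.
#' @export
random_codons <- function(n_codons, avoid_stop = TRUE) {
  pool <- if (avoid_stop) sense_codons() else names(genetic_code())
  paste(sample(pool, n_codons, replace = TRUE), collapse = "")
}

#' Mutate a sequence by i.i.d. per-site substitution
#'
#' Each position is substituted with probability `rate`, drawing uniformly
#' among the three alternative bases. Positions listed in `protect`
#' (1-based) are never touched. No indels are introduced.
#' @param seq Nucleotide string.
#' @param rate Per-site substitution probability.
#' @param protect Integer vector of protected 1-based positions.
#' @return Mutated string.
#' @export
mutate_seq <- function(seq, rate, protect = integer(0)) {
  n <- nchar(seq)
  if (rate <= 0 || n == 0L) return(seq)
  hit <- which(stats::runif(n) < rate)
  if (length(protect)) hit <- setdiff(hit, protect)
  if (!length(hit)) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[hit] <- vapply(chars[hit], function(b) {
    sample(setdiff(DNA_BASES, b), 1L)
  }, character(1), USE.NAMES = FALSE)
  paste(chars, collapse = "")
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so library code does not
#' disturb user-level reproducibility.
#' @keywords internal
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(expr)
}

# substring access for 0-based half-open intervals
seq_slice <- function(seq, start0, end0) {
  if (end0 <= start0) return("")
  substr(seq, start0 + 1L, end0)
}
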