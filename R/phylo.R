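# Alignment and distance-based phylogenetics of family member sequences:
# a progressive profile aligner (guide tree from k-mer distances, affine-gap
# profile-profile Needleman-Wunsch, codon-aware back-threading),
# neighbor-joining trees, bootstrap supports and anchor-based subgroup
# assignment.

#' Construct an alignment object
#' @param names Sequence identifiers.
#' @param rows Gapped sequence strings of equal length.
#' @param is_codon_aligned Gaps guaranteed to be frame-preserving triplets.
#' @return Object of class `fam_alignment`.
#' @export
fam_alignment <- function(names, rows, is_codon_aligned = FALSE) {
  stopifnot(length(names) == length(rows))
  if (length(rows) && length(unique(nchar(rows))) != 1L) {
    stop("famscan input error: alignment rows must have equal length")
  }
  if (is_codon_aligned && length(rows) && nchar(rows[1]) %% 3L != 0L) {
    stop("famscan input error: codon alignment length must be divisible by 3")
  }
  structure(list(names = as.character(names), rows = as.character(rows),
                 is_codon_aligned = isTRUE(is_codon_aligned)),
            class = "fam_alignment")
}

.aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
}

.NT_SCORE <- function(match = 2, mismatch = -3) {
  b <- DNA_BASES
  m <- matrix(mismatch, 4, 4, dimnames = list(b, b))
  diag(m) <- match
  m
}

.aa_score <- function() {
  if (is.null(.fam_cache$blosum)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .fam_cache$blosum <- e$BLOSUM62
  }
  .fam_cache$blosum
}

# k-mer distance between two sequences (1 - shared-word fraction)
.kmer_dist <- function(seqs, k) {
  words <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  n <- length(seqs)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      denom <- min(length(words[[i]]), length(words[[j]]))
      d <- if (denom == 0L) 1 else 1 - length(intersect(words[[i]], words[[j]])) / denom
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

# profile = frequency matrix (alphabet x columns) over non-gap residues
.profile_of <- function(rows, alphabet) {
  L <- nchar(rows[1])
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  prof <- matrix(0, length(alphabet), L, dimnames = list(alphabet, NULL))
  for (a in alphabet) prof[a, ] <- colSums(mat == a)
  prof / length(rows)
}

.merge_profiles <- function(rows1, rows2, score_mat, gap_open, gap_extend) {
  alphabet <- rownames(score_mat)
  p1 <- .profile_of(rows1, alphabet)
  p2 <- .profile_of(rows2, alphabet)
  S <- t(p1) %*% score_mat %*% p2
  path <- cpp_profile_align(S, gap_open, gap_extend)
  expand <- function(rows, idx) {
    vapply(rows, function(r) {
      ch <- strsplit(r, "", fixed = TRUE)[[1]]
      paste(ifelse(idx == 0L, "-", ch[pmax(idx, 1L)]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  c(expand(rows1, path$a), expand(rows2, path$b))
}

#' Progressive multiple alignment
#'
#' Builds a guide tree from k-mer distances (UPGMA) and merges profiles by
#' affine-gap global profile-profile alignment. In codon mode the
#' translations are aligned and the nucleotides are threaded back in intact
#' triplets, so codons are never split; rows with internal stop codons are
#' aligned but flagged in the `stopped_rows` attribute.
#'
#' @param seqs Named character vector of sequences (>= 1).
#' @param mode `"nt"`, `"aa"` or `"codon"`.
#' @param gap_open,gap_extend Affine gap costs (defaults: 5/2 for
#'   nucleotides, 10/1 for amino acids).
#' @return A [fam_alignment()].
#' @export
progressive_align <- function(seqs, mode = c("nt", "aa", "codon"),
                              gap_open = NULL, gap_extend = NULL) {
  mode <- match.arg(mode)
  if (!length(seqs)) stop("famscan input error: no sequences to align")
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))

  if (mode == "codon") {
    trimmed <- vapply(seqs, function(s) {
      substr(s, 1L, 3L * (nchar(s) %/% 3L))
    }, character(1))
    aa <- vapply(trimmed, translate_nt, character(1))
    stopped <- vapply(aa, function(a) {
      grepl("*", substr(a, 1, nchar(a) - 1L), fixed = TRUE)
    }, logical(1))
    aa_aln <- progressive_align(stats::setNames(aa, names(seqs)), mode = "aa",
                                gap_open = gap_open, gap_extend = gap_extend)
    rows <- vapply(seq_along(aa_aln$rows), function(i) {
      cods <- codons_of(trimmed[[aa_aln$names[i]]])
      ch <- strsplit(aa_aln$rows[i], "", fixed = TRUE)[[1]]
      k <- 0L
      paste(vapply(ch, function(a) {
        if (a == "-") return("---")
        k <<- k + 1L
        cods[k]
      }, character(1)), collapse = "")
    }, character(1))
    out <- fam_alignment(aa_aln$names, rows, is_codon_aligned = TRUE)
    attr(out, "stopped_rows") <- names(seqs)[stopped]
    return(out)
  }

  score_mat <- if (mode == "nt") .NT_SCORE() else .aa_score()
  if (is.null(gap_open)) gap_open <- if (mode == "nt") 5 else 10
  if (is.null(gap_extend)) gap_extend <- if (mode == "nt") 2 else 1
  if (length(seqs) == 1L) return(fam_alignment(names(seqs), unname(seqs)))

  k <- if (mode == "nt") 4L else 2L
  D <- .kmer_dist(seqs, k)
  profiles <- as.list(seq_along(seqs))
  rows_of <- lapply(seqs, function(s) s)
  names_of <- lapply(names(seqs), function(n) n)
  if (length(seqs) == 2L) {
    merged <- .merge_profiles(seqs[[1]], seqs[[2]], score_mat, gap_open, gap_extend)
    return(fam_alignment(names(seqs), merged))
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  acc <- vector("list", nrow(hc$merge))
  get_node <- function(x) {
    if (x < 0) list(rows = unname(seqs[-x]), names = names(seqs)[-x])
    else acc[[x]]
  }
  for (i in seq_len(nrow(hc$merge))) {
    a <- get_node(hc$merge[i, 1]); b <- get_node(hc$merge[i, 2])
    merged <- .merge_profiles(a$rows, b$rows, score_mat, gap_open, gap_extend)
    acc[[i]] <- list(rows = merged, names = c(a$names, b$names))
  }
  res <- acc[[nrow(hc$merge)]]
  fam_alignment(res$names, res$rows)
}

#' Pairwise distances from an alignment
#'
#' p-distance (proportion of differing sites among columns where both rows
#' are ungapped) or its Jukes-Cantor correction (nucleotides only).
#'
#' @param aln A [fam_alignment()].
#' @param model `"p"` or `"JC"`.
#' @return Symmetric distance matrix with sequence names as dimnames.
#' @export
aln_dist <- function(aln, model = c("p", "JC")) {
  model <- match.arg(model)
  mat <- .aln_matrix(aln)
  D <- .dist_from_matrix(mat, model)
  dimnames(D) <- list(aln$names, aln$names)
  D
}

.dist_from_matrix <- function(mat, model = "p") {
  letters_seen <- setdiff(unique(as.vector(mat)), c("-", "N", "X", "?"))
  n <- nrow(mat); L <- ncol(mat)
  nongap <- (mat != "-") * 1
  valid <- tcrossprod(nongap)
  matches <- matrix(0, n, n)
  for (a in letters_seen) {
    ind <- (mat == a) * 1
    matches <- matches + tcrossprod(ind)
  }
  p <- 1 - matches / pmax(valid, 1)
  p[valid == 0] <- NA
  diag(p) <- 0
  if (model == "JC") {
    arg <- 1 - 4 / 3 * p
    jc <- matrix(NA_real_, nrow(p), ncol(p))
    ok <- !is.na(arg) & arg > 0
    jc[ok] <- -3 / 4 * log(arg[ok])
    p <- jc
    diag(p) <- 0
  }
  p
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining; negative branch-length estimates are clamped
#' to zero (with a message). For n = 2 the unique two-leaf tree with the
#' distance split evenly is returned.
#'
#' @param D Symmetric distance matrix with zero diagonal (dimnames = taxa).
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (any(is.na(D)) || any(is.nan(D))) {
    stop("famscan input error: distance matrix contains NA/NaN")
  }
  if (any(D < 0)) stop("famscan input error: negative distances")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)) ||
      any(abs(diag(D)) > 1e-12)) {
    stop("famscan input error: distance matrix must be symmetric with zero diagonal")
  }
  n <- nrow(D)
  if (n < 2L) stop("famscan input error: need at least 2 taxa")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- sprintf("t%d", seq_len(n))
  if (n == 2L) {
    return(ape::read.tree(text = sprintf("(%s:%f,%s:%f);",
                                         rownames(D)[1], D[1, 2] / 2,
                                         rownames(D)[2], D[1, 2] / 2)))
  }
  tree <- ape::nj(stats::as.dist(D))
  if (any(tree$edge.length < 0)) {
    message("famscan: clamping ", sum(tree$edge.length < 0),
            " negative NJ branch length(s) to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement (codon triplets for codon
#' alignments), rebuilds the NJ tree per replicate and reports for every
#' internal branch the fraction of replicates containing the bipartition.
#'
#' @param aln A [fam_alignment()] with >= 4 taxa.
#' @param n_replicates Number of bootstrap replicates (default 500).
#' @param seed Optional RNG seed for the resampling (deterministic runs).
#' @param model Distance model passed to [aln_dist()].
#' @return The NJ tree with supports in `node.label` and the numeric vector
#'   in the `supports` attribute.
#' @export
bootstrap_support <- function(aln, n_replicates = 500L, seed = NULL,
                              model = "p") {
  if (n_replicates < 1L) {
    stop("famscan configuration error: n_replicates must be >= 1")
  }
  if (length(aln$names) < 4L) {
    stop("famscan input error: bootstrap needs >= 4 taxa")
  }
  mat <- .aln_matrix(aln)
  D0 <- .dist_from_matrix(mat, model)
  dimnames(D0) <- list(aln$names, aln$names)
  base <- nj_tree(D0)
  run <- function() {
    reps <- vector("list", n_replicates)
    L <- ncol(mat)
    for (b in seq_len(n_replicates)) {
      if (aln$is_codon_aligned) {
        blocks <- sample.int(L %/% 3L, replace = TRUE)
        cols <- as.vector(rbind(3L * blocks - 2L, 3L * blocks - 1L, 3L * blocks))
      } else {
        cols <- sample.int(L, replace = TRUE)
      }
      Db <- .dist_from_matrix(mat[, cols, drop = FALSE], model)
      if (any(is.na(Db))) Db[is.na(Db)] <- max(Db, na.rm = TRUE)
      dimnames(Db) <- list(aln$names, aln$names)
      reps[[b]] <- nj_tree(Db)
    }
    reps
  }
  reps <- if (is.null(seed)) run() else with_seed(seed, run())
  counts <- ape::prop.clades(base, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- counts / n_replicates
  base$node.label <- formatC(supports, digits = 3, format = "f")
  attr(base, "supports") <- supports
  base
}

#' Assign tree leaves to subgroups via anchor sequences
#'
#' Every leaf is labeled with the subgroup of its nearest anchor leaf by
#' patristic (tree-path) distance; distances are invariant to re-rooting.
#' A monophyly report states for each label whether its leaf set forms a
#' clade.
#'
#' @param tree An `ape::phylo` tree.
#' @param anchors Named character vector: subgroup label -> anchor leaf name.
#' @return List with `labels` (named character vector over leaves) and
#'   `monophyletic` (named logical over subgroup labels).
#' @export
assign_subgroups <- function(tree, anchors) {
  if (is.null(names(anchors)) || any(!nzchar(names(anchors)))) {
    stop("famscan configuration error: anchors must be named (label -> leaf)")
  }
  missing <- setdiff(anchors, tree$tip.label)
  if (length(missing)) {
    stop("famscan configuration error: anchor leaf not in tree: ",
         paste(missing, collapse = ", "))
  }
  cd <- ape::cophenetic.phylo(tree)
  labels <- vapply(tree$tip.label, function(tip) {
    d <- cd[tip, anchors]
    names(anchors)[which.min(d)]   # ties: first anchor in the given order
  }, character(1))
  mono <- vapply(names(anchors), function(lab) {
    tips <- names(labels)[labels == lab]
    if (length(tips) <= 1L) return(TRUE)
    ape::is.monophyletic(tree, tips)
  }, logical(1))
  list(labels = labels, monophyletic = mono)
}
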