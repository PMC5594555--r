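# Independent brute-force oracles. These deliberately re-derive results with
# different algorithms (naive dynamic programs, recursive enumeration, regex
# matching) so the package implementations are checked against a second,
# unrelated code path.

# Full Smith-Waterman local alignment by a naive O(nm) dynamic program with
# affine gaps (gap of length L costs gap_open + gap_extend * L). Returns the
# best score and the best-scoring subject interval (0-based half-open).
oracle_sw <- function(query, subject, match = 2, mismatch = -3,
                      gap_open = 5, gap_extend = 2) {
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(q); m <- length(s)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  beg <- matrix(0L, n + 1, m + 1)  # subject start (0-based) of local path
  begX <- matrix(0L, n + 1, m + 1); begY <- matrix(0L, n + 1, m + 1)
  best <- 0; best_end <- 0L; best_beg <- 0L
  for (i in 1:n) {
    for (j in 1:m) {
      sub <- if (q[i] == s[j] && q[i] != "N") match else mismatch
      prev <- c(M[i, j], X[i, j], Y[i, j])
      pb <- c(beg[i, j], begX[i, j], begY[i, j])
      k <- which.max(prev)
      cand <- prev[k] + sub
      if (cand <= 0) {
        M[i + 1, j + 1] <- 0
        beg[i + 1, j + 1] <- j - 1L
      } else {
        M[i + 1, j + 1] <- cand
        beg[i + 1, j + 1] <- if (prev[k] == 0) j - 1L else pb[k]
      }
      ox <- M[i, j + 1] - gap_open - gap_extend
      ex <- X[i, j + 1] - gap_extend
      if (ox >= ex) { X[i + 1, j + 1] <- ox; begX[i + 1, j + 1] <- beg[i, j + 1] }
      else { X[i + 1, j + 1] <- ex; begX[i + 1, j + 1] <- begX[i, j + 1] }
      oy <- M[i + 1, j] - gap_open - gap_extend
      ey <- Y[i + 1, j] - gap_extend
      if (oy >= ey) { Y[i + 1, j + 1] <- oy; begY[i + 1, j + 1] <- beg[i + 1, j] }
      else { Y[i + 1, j + 1] <- ey; begY[i + 1, j + 1] <- begY[i + 1, j] }
      if (M[i + 1, j + 1] > best) {
        best <- M[i + 1, j + 1]
        best_end <- j
        best_beg <- beg[i + 1, j + 1]
      }
    }
  }
  list(score = best, start = best_beg, end = best_end)
}

# Global Needleman-Wunsch score by naive DP (end gaps penalized), same
# affine-gap convention as above.
oracle_nw_score <- function(a, b, match = 2, mismatch = -3,
                            gap_open = 5, gap_extend = 2) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  M <- matrix(-Inf, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 1:n) X[i + 1, 1] <- -gap_open - gap_extend * i
  for (j in 1:m) Y[1, j + 1] <- -gap_open - gap_extend * j
  for (i in 1:n) {
    for (j in 1:m) {
      sub <- if (x[i] == y[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sub
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend,
                             Y[i, j + 1] - gap_open - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend,
                             X[i + 1, j] - gap_open - gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

.oracle_code <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})
.oracle_stops <- c("TAA", "TAG", "TGA")

# Recursive enumeration of all mutational pathways between two codons,
# excluding pathways through stop codons (all pathways if every one is
# blocked). Returns mean c(Sd, Nd).
oracle_pair_counts <- function(a, b) {
  rec <- function(cur, allow_stops) {
    if (cur == b) return(list(c(0, 0)))
    ca <- strsplit(cur, "")[[1]]; cb <- strsplit(b, "")[[1]]
    out <- list()
    for (p in which(ca != cb)) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (!allow_stops && nxt %in% .oracle_stops) next
      step <- if (.oracle_code[[cur]] == .oracle_code[[nxt]]) c(1, 0) else c(0, 1)
      out <- c(out, lapply(rec(nxt, allow_stops), function(v) v + step))
    }
    out
  }
  paths <- rec(a, FALSE)
  if (!length(paths)) paths <- rec(a, TRUE)
  colMeans(do.call(rbind, paths))
}

# Expected-site enumeration: per position, synonymous single-base changes
# over non-stop single-base changes.
oracle_site_counts <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) {
    neigh <- vapply(setdiff(c("A", "C", "G", "T"), ch[p]), function(bs) {
      x <- ch; x[p] <- bs; paste(x, collapse = "")
    }, character(1))
    keep <- neigh[!neigh %in% .oracle_stops]
    if (length(keep)) {
      s <- s + mean(.oracle_code[keep] == .oracle_code[[codon]])
    }
  }
  c(s = s, n = 3 - s)
}

# Sliding-window regex matcher for the motif consensi, applying the same
# reporting rules (ITSM shadows ITIM at a shared tyrosine; ITAM tyrosines
# are not re-reported as ITIM/ITSM; shortest ITAM spacer per start).
oracle_motifs <- function(aa) {
  n <- nchar(aa)
  hits <- list()
  itam_y <- integer(0)
  for (i in seq_len(max(0, n - 5))) {
    w <- substring(aa, i, i + 5)
    if (grepl("^[ILVS].Y..[ILV]$", w)) {
      hits[[length(hits) + 1]] <- list(kind = "ITIM", y = i + 1L)
    }
    if (grepl("^T.Y..[VI]$", w)) {
      hits[[length(hits) + 1]] <- list(kind = "ITSM", y = i + 1L)
    }
  }
  for (i in seq_len(n)) {
    for (sp in 6:12) {
      w <- substring(aa, i, i + 4 + sp + 3)
      if (nchar(w) < 8 + sp) next
      if (grepl(paste0("^Y..[LI].{", sp, "}Y..[LI]$"), w)) {
        hits[[length(hits) + 1]] <- list(kind = "ITAM", y = i - 1L)
        itam_y <- c(itam_y, i - 1L, i + 4L + sp - 1L)
        break
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(kind = character(0), tyrosine_position = integer(0)))
  }
  df <- do.call(rbind, lapply(hits, function(h) {
    data.frame(kind = h$kind, tyrosine_position = h$y, stringsAsFactors = FALSE)
  }))
  itsm_y <- df$tyrosine_position[df$kind == "ITSM"]
  df <- df[!(df$kind == "ITIM" & df$tyrosine_position %in% itsm_y) &
             !(df$kind %in% c("ITIM", "ITSM") &
                 df$tyrosine_position %in% itam_y), , drop = FALSE]
  df <- df[order(df$tyrosine_position, df$kind), , drop = FALSE]
  rownames(df) <- NULL
  df
}
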