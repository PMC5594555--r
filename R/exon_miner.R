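# Homology-seeded exon mining. Candidate loci are found with an exact-word
# two-hit seed filter (BLAST-like), then scored by Smith-Waterman local
# alignment; hits are gated on an E-value surrogate and on query cover, and
# exon boundaries are refined against splice-site dinucleotides and the
# expected domain length. Iterative rounds re-seed the search with newly
# called exon sequences to pull in distant paralogs.

#' Mining parameters
#'
#' The significance gates default to an E-value below `1e-10` and a query
#' cover above 50%. The E-value is a Karlin-Altschul-style surrogate
#' `E = K * m * n * exp(-lambda * S)` with pinned constants so the decision
#' rule is deterministic and testable; scoring is match +2, mismatch -3 and
#' affine gaps costing `gap_open + gap_extend * L`.
#'
#' @param word_size Exact-word seed length (>= 4).
#' @param min_cover Minimum query cover (strict inequality), proportion.
#' @param max_evalue Maximum E-value (strict inequality).
#' @param match,mismatch Substitution scores; N never matches anything.
#' @param gap_open,gap_extend Affine gap costs (positive numbers).
#' @param K,lambda E-value constants.
#' @param cluster_gap Seed hits closer than this are grouped into one
#'   candidate locus.
#' @param seed_min_hits Minimum seed words per candidate locus (two-hit rule;
#'   reduced to 1 for very short queries).
#' @return A named list of parameters.
#' @export
mining_params <- function(word_size = 9L, min_cover = 0.5, max_evalue = 1e-10,
                          match = 2, mismatch = -3,
                          gap_open = 5, gap_extend = 2,
                          K = 0.1, lambda = 0.33,
                          cluster_gap = 150L, seed_min_hits = 2L) {
  if (word_size < 4L) stop("famscan configuration error: word_size must be >= 4")
  list(word_size = as.integer(word_size), min_cover = min_cover,
       max_evalue = max_evalue, match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend, K = K, lambda = lambda,
       cluster_gap = as.integer(cluster_gap),
       seed_min_hits = as.integer(seed_min_hits))
}

.sub_matrix <- function(match, mismatch) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- mismatch
  m[, "N"] <- mismatch
  m
}

#' E-value surrogate for a local alignment score
#' @param score Alignment score.
#' @param m Query length.
#' @param n Search-space length.
#' @param K,lambda Constants (see [mining_params()]).
#' @export
evalue_of <- function(score, m, n, K = 0.1, lambda = 0.33) {
  K * m * n * exp(-lambda * score)
}

.empty_hits <- function() {
  data.frame(query_id = character(0), contig_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             score = numeric(0), evalue = numeric(0),
             query_cover = numeric(0), identity = numeric(0),
             stringsAsFactors = FALSE)
}

# one shared word dictionary over all queries: a single PDict is built per
# search (PDict construction dominates runtime otherwise) and each pattern
# is mapped back to the queries containing it
.seed_index <- function(queries, word_size) {
  word_sets <- lapply(queries, function(q) {
    n <- nchar(q)
    if (n < word_size) {
      return(data.frame(word = character(0), off = integer(0)))
    }
    w <- substring(q, 1:(n - word_size + 1L), word_size:n)
    keep <- !grepl("[^ACGT]", w) & !duplicated(w)
    data.frame(word = w[keep], off = which(keep), stringsAsFactors = FALSE)
  })
  all_words <- unique(unlist(lapply(word_sets, `[[`, "word"),
                             use.names = FALSE))
  if (!length(all_words)) {
    return(list(pdict = NULL,
                word_idx = lapply(queries, function(q) integer(0)),
                word_off = lapply(queries, function(q) integer(0))))
  }
  list(pdict = Biostrings::PDict(all_words),
       word_idx = lapply(word_sets, function(w) match(w$word, all_words)),
       word_off = lapply(word_sets, `[[`, "off"))
}

# per-query seed positions with alignment diagonals (pos - query offset)
.seed_positions_from_index <- function(match_starts, word_idx, word_off) {
  if (!length(word_idx)) {
    return(data.frame(pos = integer(0), diag = integer(0)))
  }
  counts <- lengths(match_starts[word_idx])
  pos <- unlist(match_starts[word_idx], use.names = FALSE)
  if (!length(pos)) return(data.frame(pos = integer(0), diag = integer(0)))
  dg <- pos - rep(word_off, counts)
  o <- order(pos)
  data.frame(pos = pos[o], diag = dg[o])
}

# merge 0-based half-open intervals into disjoint sorted intervals
.merge_intervals <- function(s, e) {
  o <- order(s)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) me <- max(me, e[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

# TRUE for 1-based positions lying inside the 0-based half-open intervals
.pos_in_intervals <- function(p, iv) {
  if (is.null(iv) || !nrow(iv)) return(rep(FALSE, length(p)))
  i <- findInterval(p, iv[, 1] + 1L)
  ok <- i > 0L
  ok[ok] <- p[ok] <= iv[i[ok], 2]
  ok
}

# group seed hits into candidate windows; the two-hit rule requires two
# distinct-position hits on nearby alignment diagonals (BLAST-style), which
# suppresses chance word-match clusters
.seed_windows <- function(seeds, word_size, qlen, slen, cluster_gap, min_hits,
                          diag_band = 32L) {
  pos <- seeds$pos
  if (!length(pos)) return(NULL)
  brk <- c(0L, which(diff(pos) > cluster_gap + qlen %/% 2L), length(pos))
  out <- list()
  for (i in seq_len(length(brk) - 1L)) {
    sel <- (brk[i] + 1L):brk[i + 1L]
    p <- pos[sel]
    if (length(unique(p)) < min_hits) next
    if (min_hits > 1L) {
      d <- sort(seeds$diag[sel])
      if (!any(diff(d) <= diag_band)) next
    }
    out[[length(out) + 1L]] <- c(max(1L, min(p) - qlen),
                                 min(slen, max(p) + word_size - 1L + qlen))
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# search one query against one contig strand given precomputed seed
# positions; returns hit rows in forward contig coordinates (0-based
# half-open)
.search_strand <- function(query, contig_id, subj, subj_dna, strand, pos,
                           params, search_space, exclude = NULL,
                           excl_iv = NULL) {
  qlen <- nchar(query)
  min_hits <- if (qlen >= 2L * params$word_size + 4L) params$seed_min_hits else 1L
  if (!is.null(excl_iv)) pos <- pos[!.pos_in_intervals(pos$pos, excl_iv), ,
                                    drop = FALSE]
  win <- .seed_windows(pos, params$word_size, qlen, nchar(subj),
                       params$cluster_gap, min_hits)
  if (is.null(win)) return(.empty_hits())

  # map a strand-space interval [s0, e0) to forward coordinates
  to_forward <- function(s0, e0) {
    if (strand == "+") c(s0, e0) else c(nchar(subj) - e0, nchar(subj) - s0)
  }
  if (!is.null(exclude) && nrow(exclude)) {
    keep <- vapply(seq_len(nrow(win)), function(i) {
      fwd <- to_forward(win[i, 1] - 1L, win[i, 2])
      !any(exclude$contig_id == contig_id &
             pmin(exclude$end, fwd[2]) - pmax(exclude$start, fwd[1]) >
               0.5 * pmin(exclude$end - exclude$start, fwd[2] - fwd[1]))
    }, logical(1))
    win <- win[keep, , drop = FALSE]
    if (!nrow(win)) return(.empty_hits())
  }

  windows <- Biostrings::DNAStringSet(vapply(seq_len(nrow(win)), function(i) {
    as.character(Biostrings::subseq(subj_dna, win[i, 1], win[i, 2]))
  }, character(1)))
  sm <- .sub_matrix(params$match, params$mismatch)
  aln <- Biostrings::pairwiseAlignment(
    pattern = windows, subject = Biostrings::DNAString(query),
    type = "local", substitutionMatrix = sm,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  scores <- Biostrings::score(aln)
  ev <- evalue_of(scores, qlen, search_space, params$K, params$lambda)
  qr <- Biostrings::subject(aln)   # query side (vectorized ranges)
  cover <- (Biostrings::end(qr) - Biostrings::start(qr) + 1L) / qlen
  pass <- ev < params$max_evalue & cover > params$min_cover
  if (!any(pass)) return(.empty_hits())
  pr <- Biostrings::pattern(aln)   # window side
  s0 <- win[, 1] - 1L + Biostrings::start(pr) - 1L
  e0 <- win[, 1] - 1L + Biostrings::end(pr)
  identity <- Biostrings::pid(aln, type = "PID1") / 100
  rows <- lapply(which(pass), function(i) {
    fwd <- to_forward(s0[i], e0[i])
    data.frame(query_id = NA_character_, contig_id = contig_id,
               start = fwd[1], end = fwd[2], strand = strand,
               score = scores[i], evalue = ev[i], query_cover = cover[i],
               identity = identity[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# fraction of reciprocal overlap used to decide that two hits are one locus
.same_locus <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2)
  ov > 0.5 * pmin(e1 - s1, e2 - s2)
}

# collapse overlapping hits to the best-scoring call per locus
.collapse_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits <- hits[order(-hits$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(hits)) > i &
                 hits$contig_id == hits$contig_id[i] &
                 .same_locus(hits$start, hits$end,
                             hits$start[i], hits$end[i]))
    keep[j] <- FALSE
  }
  hits <- hits[keep, , drop = FALSE]
  hits[order(hits$contig_id, hits$start), , drop = FALSE]
}

#' Seeded local search of queries against contigs
#'
#' Finds the non-overlapping best local alignments of each query on both
#' strands of each contig that pass the significance gates (E-value below
#' `max_evalue` and query cover above `min_cover`). Overlapping hits from
#' different queries (reciprocal overlap > 50%) are collapsed to the
#' best-scoring hit per locus.
#'
#' @param contigs Named character vector of contig sequences (A/C/G/T/N).
#' @param queries Named character vector of query sequences (must be
#'   non-empty).
#' @param params [mining_params()].
#' @param exclude Optional data frame with `contig_id`, `start`, `end` of
#'   loci to skip (used by iterative mining to avoid re-scoring known loci).
#' @return Data frame of hits: `query_id`, `contig_id`, `start`, `end`
#'   (0-based half-open, forward coordinates), `strand`, `score`, `evalue`,
#'   `query_cover`, `identity`.
#' @export
seeded_local_search <- function(contigs, queries, params = mining_params(),
                                exclude = NULL) {
  if (!length(queries)) stop("famscan input error: queries must be non-empty")
  if (is.null(names(queries)) || any(!nzchar(names(queries)))) {
    stop("famscan input error: queries must be named")
  }
  if (!length(contigs)) return(.empty_hits())
  if (any(grepl("[^ACGTN]", contigs))) {
    stop("famscan input error: contigs restricted to A/C/G/T/N")
  }
  search_space <- sum(nchar(contigs))
  idx <- .seed_index(queries, params$word_size)
  if (is.null(idx$pdict)) return(.empty_hits())
  out <- list()
  for (ci in seq_along(contigs)) {
    cid <- names(contigs)[ci]
    # excluded loci as merged strand-space intervals (seed hits inside them
    # are dropped before clustering, which keeps iterative rounds cheap)
    excl_c <- if (!is.null(exclude)) {
      exclude[exclude$contig_id == cid, , drop = FALSE]
    } else NULL
    L <- nchar(contigs[[ci]])
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") contigs[[ci]] else revcomp(contigs[[ci]])
      subj_dna <- Biostrings::DNAString(subj)
      excl_iv <- if (!is.null(excl_c) && nrow(excl_c)) {
        if (strand == "+") .merge_intervals(excl_c$start, excl_c$end)
        else .merge_intervals(L - excl_c$end, L - excl_c$start)
      } else NULL
      starts <- Biostrings::startIndex(
        Biostrings::matchPDict(idx$pdict, subj_dna))
      for (qi in seq_along(queries)) {
        pos <- .seed_positions_from_index(starts, idx$word_idx[[qi]],
                                          idx$word_off[[qi]])
        if (!nrow(pos)) next
        h <- .search_strand(queries[[qi]], cid, subj, subj_dna, strand, pos,
                            params, search_space, exclude = exclude,
                            excl_iv = excl_iv)
        if (nrow(h)) {
          h$query_id <- names(queries)[qi]
          out[[length(out) + 1L]] <- h
        }
      }
    }
  }
  if (!length(out)) return(.empty_hits())
  .collapse_hits(do.call(rbind, out))
}

.empty_calls <- function() {
  data.frame(query_id = character(0), contig_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             domain_type = character(0), acceptor_ok = logical(0),
             donor_ok = logical(0), length_ok = logical(0),
             partial = logical(0), has_n = logical(0),
             score = numeric(0), evalue = numeric(0),
             sequence = character(0), stringsAsFactors = FALSE)
}

#' Refine exon boundaries of a hit against splice sites
#'
#' Scans a +/- `window` nt region around each raw alignment end for the
#' intron-side dinucleotides (AG immediately upstream of the acceptor
#' boundary, GT immediately downstream of the donor boundary) consistent with
#' the expected domain length, preferring the candidate pair whose length is
#' closest to `expected_length` and then the smallest shift from the raw
#' alignment. Missing signals leave the corresponding flag FALSE; a window
#' truncated by the contig edge marks the call partial.
#'
#' @param hit One-row data frame as returned by [seeded_local_search()].
#' @param contig_seq The contig sequence the hit lies on.
#' @param expected_length Expected exon length (nt).
#' @param domain_type Domain label to attach to the call.
#' @param window Scan window around each raw end (nt).
#' @param length_tol Tolerance on the exon length for `length_ok` (nt).
#' @return One-row data frame: an exon call with refined coordinates
#'   (0-based half-open, forward), splice flags and the extracted
#'   (strand-corrected) sequence.
#' @export
refine_exon_boundaries <- function(hit, contig_seq, expected_length,
                                   domain_type = NA_character_,
                                   window = 30L, length_tol = 6L,
                                   query = NULL) {
  slen <- nchar(contig_seq)
  minus <- identical(hit$strand, "-")
  seq_s <- if (minus) revcomp(contig_seq) else contig_seq
  # strand-space raw interval
  s0 <- if (minus) slen - hit$end else hit$start
  e0 <- if (minus) slen - hit$start else hit$end

  partial <- FALSE
  lo_s <- s0 - window; hi_s <- s0 + window
  lo_e <- e0 - window; hi_e <- e0 + window
  if (lo_s < 2L) { lo_s <- 2L; partial <- TRUE }
  if (hi_e > slen - 2L) { hi_e <- slen - 2L; partial <- TRUE }
  hi_s <- min(hi_s, e0 - 1L); lo_e <- max(lo_e, s0 + 1L)

  acc <- if (hi_s >= lo_s) {
    cand <- lo_s:hi_s
    cand[substring(seq_s, cand - 1L, cand) == "AG"]
  } else integer(0)
  don <- if (hi_e >= lo_e) {
    cand <- lo_e:hi_e
    cand[substring(seq_s, cand + 1L, cand + 2L) == "GT"]
  } else integer(0)

  # Candidate placements combine three kinds of evidence into one penalty:
  # sequence mismatches against the query (when supplied), a fixed charge
  # per missing splice signal, and deviation from the expected length. This
  # keeps a nearby spurious AG..GT pair (length-exact but sequence-shifted)
  # from masking a genuinely mutated donor site, while still preferring a
  # canonical pair over single-signal placements on intact exons.
  cands <- list()
  add_cand <- function(s, e, acc_f, don_f, shift) {
    cands[[length(cands) + 1L]] <<- data.frame(
      s = s, e = e, acc = acc_f, don = don_f, shift = shift)
  }
  if (length(acc) && length(don)) {
    grid <- expand.grid(s = acc, e = don)
    grid <- grid[grid$e > grid$s &
                   abs((grid$e - grid$s) - expected_length) <= length_tol, ,
                 drop = FALSE]
    if (nrow(grid)) {
      add_cand(grid$s, grid$e, TRUE, TRUE,
               abs(grid$s - s0) + abs(grid$e - e0))
    }
  }
  # single-signal candidates place the other boundary at the expected
  # length; if the implied position carries the canonical dinucleotide the
  # candidate becomes a full pair (rescues exons whose raw alignment end
  # was trimmed beyond the scan window)
  if (length(acc)) {
    e_imp <- pmin(acc + expected_length, slen)
    don_imp <- substring(seq_s, e_imp + 1L, e_imp + 2L) == "GT" &
      e_imp == acc + expected_length
    add_cand(acc, e_imp, TRUE, don_imp, abs(acc - s0))
  }
  if (length(don)) {
    s_imp <- pmax(don - expected_length, 0L)
    acc_imp <- s_imp >= 2L & s_imp == don - expected_length &
      substring(seq_s, s_imp - 1L, s_imp) == "AG"
    add_cand(s_imp, don, acc_imp, TRUE, abs(don - e0))
  }
  acceptor_ok <- donor_ok <- FALSE
  if (length(cands)) {
    cd <- do.call(rbind, cands)
    cd <- cd[!duplicated(paste(cd$s, cd$e, cd$acc, cd$don)), , drop = FALSE]
    dev <- abs((cd$e - cd$s) - expected_length)
    miss <- (!cd$acc) + (!cd$don)
    mm <- numeric(nrow(cd))
    if (!is.null(query)) {
      qc <- strsplit(query, "", fixed = TRUE)[[1]]
      for (i in seq_len(nrow(cd))) {
        len <- cd$e[i] - cd$s[i]
        cmp <- min(len, length(qc))
        sc <- strsplit(seq_slice(seq_s, cd$s[i], cd$s[i] + cmp), "",
                       fixed = TRUE)[[1]]
        mm[i] <- sum(sc != qc[seq_len(cmp)]) + 0.75 * abs(len - length(qc))
      }
    }
    cd$penalty <- mm + 3 * miss + dev
    # for calls truncated by the contig edge the expected-length prior is
    # unreliable, so boundary evidence nearest the raw alignment wins
    best <- if (partial) cd[order(cd$shift, cd$penalty), ][1, ]
            else cd[order(cd$penalty, cd$shift), ][1, ]
    s0 <- best$s; e0 <- best$e
    acceptor_ok <- best$acc; donor_ok <- best$don
  }
  length_ok <- abs((e0 - s0) - expected_length) <= length_tol
  sq <- seq_slice(seq_s, s0, e0)
  fwd <- if (minus) c(slen - e0, slen - s0) else c(s0, e0)
  data.frame(query_id = hit$query_id, contig_id = hit$contig_id,
             start = fwd[1], end = fwd[2], strand = hit$strand,
             domain_type = domain_type,
             acceptor_ok = acceptor_ok, donor_ok = donor_ok,
             length_ok = length_ok, partial = partial,
             has_n = grepl("N", sq, fixed = TRUE),
             score = hit$score, evalue = hit$evalue,
             sequence = sq, stringsAsFactors = FALSE)
}

#' Iterative homology mining of CEA-family exons
#'
#' Round 1 searches the contigs with the seed queries; each later round
#' re-seeds the search with the exon sequences called in the previous round,
#' terminating at a fixed point (no new loci) or after `max_rounds`. Short
#' cytoplasmic exons are additionally sought in 2-kb windows downstream of
#' each transmembrane exon call, where the smaller search space relaxes the
#' E-value gate.
#'
#' @param contigs Named character vector of contig sequences.
#' @param seed_queries Named character vector of seed exon sequences.
#' @param query_domains Named character vector mapping query names to domain
#'   types (`leader`, `N`, `A1`, `B`, `A2`, `TM`, `Cyt1`, `Cyt2`).
#' @param params [mining_params()].
#' @param max_rounds Maximum number of search rounds (>= 1).
#' @param window,length_tol Passed to [refine_exon_boundaries()].
#' @param downstream_window Window searched downstream of TM calls (nt).
#' @return Data frame of exon calls (see [refine_exon_boundaries()]) with an
#'   additional `round` column.
#' @export
iterative_mine <- function(contigs, seed_queries,
                           query_domains = NULL,
                           params = mining_params(), max_rounds = 3L,
                           window = 30L, length_tol = 6L,
                           downstream_window = 2000L) {
  if (max_rounds < 1L) stop("famscan configuration error: max_rounds must be >= 1")
  if (is.null(query_domains)) {
    query_domains <- stats::setNames(names(seed_queries), names(seed_queries))
  }
  calls <- .empty_calls()
  calls$round <- integer(0)
  queries <- seed_queries
  expected_len <- stats::setNames(nchar(seed_queries), names(seed_queries))
  for (round in seq_len(max_rounds)) {
    if (!length(queries)) break
    if (round > 1L) {
      # re-seeded queries are close to their targets; a longer word keeps
      # later rounds sensitive while suppressing chance seed clusters
      params$word_size <- max(params$word_size, 12L)
    }
    # loci already called cleanly are skipped; imperfect calls stay open for
    # rescue by closer paralogs found in later rounds
    good <- calls$length_ok & !calls$partial & calls$acceptor_ok & calls$donor_ok
    hits <- seeded_local_search(contigs, queries, params,
                                exclude = calls[good, c("contig_id", "start", "end"), drop = FALSE])
    new_calls <- .refine_hits(hits, contigs, query_domains, expected_len,
                              window, length_tol, queries = queries)
    # targeted short-exon search downstream of newly found TM exons
    tm_new <- new_calls[new_calls$domain_type == "TM", , drop = FALSE]
    cyt_queries <- queries[query_domains[names(queries)] %in% c("Cyt1", "Cyt2")]
    if (!length(cyt_queries)) {
      cyt_queries <- seed_queries[query_domains[names(seed_queries)] %in% c("Cyt1", "Cyt2")]
    }
    if (nrow(tm_new) && length(cyt_queries)) {
      ds <- .downstream_search(tm_new, contigs, cyt_queries, params,
                               downstream_window,
                               exclude = rbind(calls[, c("contig_id", "start", "end")],
                                               new_calls[, c("contig_id", "start", "end")]))
      ds_calls <- .refine_hits(ds, contigs, query_domains, expected_len,
                               window, length_tol, queries = cyt_queries)
      new_calls <- .merge_new(new_calls, ds_calls)
    }
    # keep new loci; a better-supported re-call (higher splice/length
    # quality, then score) replaces an imperfect old call
    if (nrow(calls) && nrow(new_calls)) {
      fresh <- logical(nrow(new_calls))
      for (i in seq_len(nrow(new_calls))) {
        ov <- which(calls$contig_id == new_calls$contig_id[i] &
                      calls$strand == new_calls$strand[i] &
                      .same_locus(calls$start, calls$end,
                                  new_calls$start[i], new_calls$end[i]))
        if (!length(ov)) {
          fresh[i] <- TRUE
          next
        }
        q_old <- max(.call_quality(calls[ov, , drop = FALSE]))
        q_new <- .call_quality(new_calls[i, , drop = FALSE])
        same_bounds <- any(calls$start[ov] == new_calls$start[i] &
                             calls$end[ov] == new_calls$end[i])
        if (!same_bounds &&
            (q_new > q_old ||
               (q_new == q_old && q_old < 4L &&
                  new_calls$score[i] > max(calls$score[ov])))) {
          calls <- calls[-ov, , drop = FALSE]
          fresh[i] <- TRUE
        }
      }
      new_calls <- new_calls[fresh, , drop = FALSE]
    }
    if (!nrow(new_calls)) break
    new_calls$round <- round
    calls <- rbind(calls, new_calls)
    # re-seed with complete, unambiguous new calls
    ok <- new_calls$length_ok & !new_calls$partial & !new_calls$has_n
    nq <- new_calls$sequence[ok]
    if (!length(nq)) break
    names(nq) <- sprintf("r%d_call_%03d", round, seq_along(nq))
    query_domains[names(nq)] <- new_calls$domain_type[ok]
    expected_len[names(nq)] <- nchar(nq)
    queries <- nq
  }
  rownames(calls) <- NULL
  calls[order(calls$contig_id, calls$start), , drop = FALSE]
}

.refine_hits <- function(hits, contigs, query_domains, expected_len,
                         window, length_tol, queries = NULL) {
  if (!nrow(hits)) return(.empty_calls())
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, , drop = FALSE]
    refine_exon_boundaries(h, contigs[[h$contig_id]],
                           expected_length = expected_len[[h$query_id]],
                           domain_type = query_domains[[h$query_id]],
                           window = window, length_tol = length_tol,
                           query = if (!is.null(queries)) queries[[h$query_id]])
  })
  .collapse_calls(do.call(rbind, rows))
}

.call_quality <- function(calls) {
  calls$acceptor_ok + calls$donor_ok + calls$length_ok + !calls$partial
}

# after refinement two hits may have converged on the same locus; keep the
# best-supported call (splice/length flags first, then score) per locus
.collapse_calls <- function(calls) {
  if (!nrow(calls)) return(calls)
  calls <- calls[order(-.call_quality(calls), -calls$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(calls)) > i &
                 calls$contig_id == calls$contig_id[i] &
                 .same_locus(calls$start, calls$end,
                             calls$start[i], calls$end[i]))
    keep[j] <- FALSE
  }
  calls <- calls[keep, , drop = FALSE]
  calls[order(calls$contig_id, calls$start), , drop = FALSE]
}

.merge_new <- function(a, b) .collapse_calls(rbind(a, b))

# search 2-kb windows downstream of TM calls with cytoplasmic queries
.downstream_search <- function(tm_calls, contigs, cyt_queries, params,
                               downstream_window, exclude) {
  out <- list()
  for (i in seq_len(nrow(tm_calls))) {
    tc <- tm_calls[i, ]
    cseq <- contigs[[tc$contig_id]]
    if (tc$strand == "+") {
      w0 <- tc$end; w1 <- min(nchar(cseq), tc$end + downstream_window)
    } else {
      w0 <- max(0L, tc$start - downstream_window); w1 <- tc$start
    }
    if (w1 - w0 < 30L) next
    wseq <- stats::setNames(seq_slice(cseq, w0, w1), tc$contig_id)
    h <- seeded_local_search(wseq, cyt_queries, params)
    if (!nrow(h)) next
    h$start <- h$start + w0
    h$end <- h$end + w0
    out[[length(out) + 1L]] <- h
  }
  if (!length(out)) return(.empty_hits())
  h <- do.call(rbind, out)
  if (!is.null(exclude) && nrow(exclude) && nrow(h)) {
    keep <- vapply(seq_len(nrow(h)), function(i) {
      !any(exclude$contig_id == h$contig_id[i] &
             .same_locus(exclude$start, exclude$end, h$start[i], h$end[i]))
    }, logical(1))
    h <- h[keep, , drop = FALSE]
  }
  .collapse_hits(h)
}
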