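# Counting-based molecular-evolution analysis of in-frame codon alignments:
# Nei-Gojobori (1986) expected site counts and pathway-averaged substitution
# counts, pairwise dN/dS with Jukes-Cantor correction, a SLAC-style
# tree-aware analysis with Fitch-parsimony ancestral codons and per-site
# binomial classification, and cumulative substitution profiles along the
# coding region.
#
# Stop-codon policy (standard NG86 practice): single-base changes through
# stop codons are excluded; per-position synonymous fractions are computed
# over the non-stop changes only, so expected sites always satisfy
# ES + EN = 3 per codon. Mutational pathways passing through a stop codon
# are excluded from pathway averaging.

.codon_tables <- function() {
  if (!is.null(.fam_cache$codon_tables)) return(.fam_cache$codon_tables)
  sc <- sense_codons()
  code <- genetic_code()
  stops <- stop_codon_set()
  nsc <- length(sc)
  s_site <- numeric(nsc)
  neighbors <- vector("list", nsc)
  for (ci in seq_len(nsc)) {
    cod <- sc[ci]
    ch <- strsplit(cod, "", fixed = TRUE)[[1]]
    to <- character(0); syn <- logical(0)
    s <- 0
    for (pos in 1:3) {
      alts <- setdiff(DNA_BASES, ch[pos])
      neigh <- vapply(alts, function(b) {
        x <- ch; x[pos] <- b; paste(x, collapse = "")
      }, character(1))
      nonstop <- neigh[!neigh %in% stops]
      if (length(nonstop)) {
        s <- s + sum(code[nonstop] == code[cod]) / length(nonstop)
      }
      to <- c(to, nonstop)
      syn <- c(syn, code[nonstop] == code[cod])
    }
    s_site[ci] <- s
    neighbors[[ci]] <- list(to = match(to, sc), syn = unname(syn))
  }
  # pathway-averaged pair counts for all sense-codon pairs
  Sd <- Nd <- matrix(0, nsc, nsc, dimnames = list(sc, sc))
  for (i in seq_len(nsc - 1L)) {
    for (j in (i + 1L):nsc) {
      pc <- .pair_paths(sc[i], sc[j], code, stops)
      Sd[i, j] <- Sd[j, i] <- pc[1]
      Nd[i, j] <- Nd[j, i] <- pc[2]
    }
  }
  .fam_cache$codon_tables <- list(sc = sc, s_site = s_site,
                                  n_site = 3 - s_site,
                                  Sd = Sd, Nd = Nd, neighbors = neighbors)
  .fam_cache$codon_tables
}

.PERMS <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# average (Sd, Nd) over all orderings of the differing positions whose
# intermediates avoid stop codons; falls back to all orderings if every
# pathway is blocked
.pair_paths <- function(a, b, code, stops) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  diffs <- which(ca != cb)
  k <- length(diffs)
  if (k == 0L) return(c(0, 0))
  paths <- .PERMS[[k]]
  tally <- function(require_sense) {
    acc <- matrix(NA_real_, length(paths), 2)
    for (pi in seq_along(paths)) {
      cur <- ca; sd <- 0; nd <- 0; ok <- TRUE
      for (pos in diffs[paths[[pi]]]) {
        nxt <- cur; nxt[pos] <- cb[pos]
        nxt_c <- paste(nxt, collapse = "")
        if (require_sense && nxt_c %in% stops) { ok <- FALSE; break }
        cur_c <- paste(cur, collapse = "")
        if (identical(code[[cur_c]], code[[nxt_c]])) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) acc[pi, ] <- c(sd, nd)
    }
    acc[stats::complete.cases(acc), , drop = FALSE]
  }
  acc <- tally(TRUE)
  if (!nrow(acc)) acc <- tally(FALSE)
  colMeans(acc)
}

#' Nei-Gojobori expected synonymous/nonsynonymous site counts of a codon
#'
#' Per codon position the synonymous fraction is the number of synonymous
#' single-base changes over the non-stop single-base changes; `s` sums the
#' three positions and `n = 3 - s`.
#'
#' @param codon One of the 61 sense codons.
#' @return Named numeric vector `c(s = , n = )`.
#' @export
#' @examples
#' ng86_site_counts("TTT")  # s = 1/3
ng86_site_counts <- function(codon) {
  tab <- .codon_tables()
  i <- match(codon, tab$sc)
  if (is.na(i)) stop("famscan input error: not a sense codon: ", codon)
  c(s = tab$s_site[i], n = tab$n_site[i])
}

#' Pathway-averaged substitution counts between two codons
#'
#' Averages observed synonymous (`Sd`) and nonsynonymous (`Nd`) steps over
#' all minimal mutational pathways between the codons that avoid stop-codon
#' intermediates.
#'
#' @param codon_a,codon_b Sense codons (0-3 differing positions).
#' @return Named numeric vector `c(Sd = , Nd = )`.
#' @export
#' @examples
#' ng86_pair_counts("TTT", "GTA")  # c(0.5, 1.5)
ng86_pair_counts <- function(codon_a, codon_b) {
  tab <- .codon_tables()
  i <- match(codon_a, tab$sc); j <- match(codon_b, tab$sc)
  if (is.na(i) || is.na(j)) {
    stop("famscan input error: stop or invalid codon in pair: ",
         codon_a, " / ", codon_b)
  }
  c(Sd = tab$Sd[i, j], Nd = tab$Nd[i, j])
}

# Jukes-Cantor correction of a substitution proportion
.jc <- function(p) {
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 / 3 * p))
}

.as_codon_alignment <- function(aln) {
  if (inherits(aln, "fam_alignment")) {
    if (length(aln$rows) && nchar(aln$rows[1]) %% 3L != 0L) {
      stop("famscan input error: alignment length not divisible by 3")
    }
    return(aln)
  }
  if (is.character(aln)) {
    if (is.null(names(aln))) names(aln) <- sprintf("seq%d", seq_along(aln))
    return(fam_alignment(names(aln), unname(aln), is_codon_aligned = TRUE))
  }
  stop("famscan input error: cannot interpret codon alignment input")
}

# codon-index matrix (nseq x nsites); NA for gap/ambiguous/stop codons
.codon_index_matrix <- function(aln) {
  tab <- .codon_tables()
  ncod <- nchar(aln$rows[1]) %/% 3L
  cm <- t(vapply(aln$rows, function(r) {
    match(codons_of(r), tab$sc)
  }, integer(ncod), USE.NAMES = FALSE))
  if (ncod == 1L) cm <- matrix(cm, nrow = length(aln$rows))
  rownames(cm) <- aln$names
  cm
}

.internal_stop_rows <- function(aln) {
  vapply(aln$rows, function(r) {
    cds <- codons_of(gsub("-", "", r, fixed = TRUE))
    any(cds[-length(cds)] %in% stop_codon_set())
  }, logical(1), USE.NAMES = FALSE)
}

#' Pairwise dN/dS by Nei-Gojobori counting
#'
#' For each sequence pair, expected sites are averaged over the two rows,
#' observed substitutions are pathway-averaged per codon site, the
#' proportions `pS = Sd/S` and `pN = Nd/N` are Jukes-Cantor corrected into
#' `dS` and `dN`, and the ratio is reported (`NA` when `dS = 0` or a
#' proportion exceeds the correctable range).
#'
#' @param aln Codon alignment ([fam_alignment()] or named character vector
#'   of equal-length in-frame sequences).
#' @param pairwise_deletion Use per-pair complete codon columns instead of
#'   alignment-wide complete columns.
#' @return Data frame with one row per pair: `seq_a`, `seq_b`, `S`, `N`,
#'   `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`, `dnds`.
#' @export
pairwise_dnds <- function(aln, pairwise_deletion = FALSE) {
  aln <- .as_codon_alignment(aln)
  if (length(aln$rows) < 2L) {
    stop("famscan input error: need >= 2 sequences")
  }
  tab <- .codon_tables()
  cm <- .codon_index_matrix(aln)
  complete <- colSums(is.na(cm)) == 0L
  n <- nrow(cm)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(cm[i, ]) & !is.na(cm[j, ])
      if (!pairwise_deletion) ok <- ok & complete
      ai <- cm[i, ok]; bj <- cm[j, ok]
      S <- (sum(tab$s_site[ai]) + sum(tab$s_site[bj])) / 2
      N <- (sum(tab$n_site[ai]) + sum(tab$n_site[bj])) / 2
      Sd <- sum(tab$Sd[cbind(ai, bj)])
      Nd <- sum(tab$Nd[cbind(ai, bj)])
      pS <- if (S > 0) Sd / S else NA_real_
      pN <- if (N > 0) Nd / N else NA_real_
      dS <- .jc(pS); dN <- .jc(pN)
      dnds <- if (is.na(dS) || is.na(dN) || dS == 0) NA_real_ else dN / dS
      out[[length(out) + 1L]] <- data.frame(
        seq_a = aln$names[i], seq_b = aln$names[j],
        S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
        dS = dS, dN = dN, dnds = dnds, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' SLAC-style tree-aware selection analysis
#'
#' Ancestral codons are reconstructed per codon site by Fitch parsimony
#' (ties resolved deterministically to the lexically smallest codon;
#' a declared substitute for likelihood ancestors), substitutions are
#' pathway-counted on every branch, per-site expected proportions come from
#' `EN/(ES+EN)` over the observed rows, and each site with at least one
#' inferred substitution is classified positive/negative by a two-tailed
#' binomial test at significance `alpha` (raw p; Benjamini-Hochberg q-values
#' are reported alongside). The alignment-wide mean dN/dS is the ratio of
#' the tree-wide rates `(sum(Nd)/sum(EN)) / (sum(Sd)/sum(ES))`; a
#' Jukes-Cantor-corrected version is reported in `mean_dnds_jc`, which on a
#' two-leaf tree equals the pairwise estimator. On a two-leaf tree the
#' branch counts sum exactly to the pairwise pathway counts.
#'
#' Rows containing internal stop codons are excluded (and logged); codon
#' columns containing gaps or ambiguous codons are skipped.
#'
#' @param aln Codon alignment.
#' @param tree `ape::phylo` with leaves equal to the (retained) alignment
#'   names; built internally by NJ on p-distances when NULL.
#' @param alpha Per-site significance level for classification.
#' @return Object of class `slac_result`: list with `mean_dnds`,
#'   `mean_dnds_jc`, `totals`, `per_site` data frame, `per_branch`
#'   data frame, `n_sites_used`, `excluded_rows` and `tree`.
#' @export
slac_analyze <- function(aln, tree = NULL, alpha = 0.1) {
  aln <- .as_codon_alignment(aln)
  bad <- .internal_stop_rows(aln)
  excluded <- aln$names[bad]
  if (any(bad)) {
    message("famscan: excluding ", sum(bad),
            " row(s) with internal stop codons from selection analysis")
    aln <- fam_alignment(aln$names[!bad], aln$rows[!bad],
                         is_codon_aligned = aln$is_codon_aligned)
  }
  n <- length(aln$rows)
  if (n < 2L) stop("famscan input error: need >= 2 stop-free sequences")
  if (is.null(tree)) {
    D <- aln_dist(aln, "p")
    tree <- nj_tree(D)
  }
  if (!setequal(tree$tip.label, aln$names)) {
    stop("famscan input error: tree leaves must equal alignment names")
  }
  tab <- .codon_tables()
  cm <- .codon_index_matrix(aln)
  cm <- cm[tree$tip.label, , drop = FALSE]  # leaf order of the tree
  usable <- which(colSums(is.na(cm)) == 0L)
  nsite <- length(usable)

  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  root <- ntip + 1L
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  children <- split(edge[, 2], edge[, 1])
  po_parents <- unique(edge[, 1])           # children-first order
  pre_edges <- edge[rev(seq_len(nrow(edge))), , drop = FALSE]  # parents-first

  states <- matrix(NA_integer_, ntot, nsite)
  for (si in seq_len(nsite)) {
    col <- cm[, usable[si]]
    down <- vector("list", ntot)
    for (i in seq_len(ntip)) down[[i]] <- col[i]
    for (p in po_parents) {
      sets <- lapply(children[[as.character(p)]], function(c) down[[c]])
      inter <- Reduce(intersect, sets)
      down[[p]] <- if (length(inter)) inter else sort(unique(unlist(sets)))
    }
    st <- integer(ntot)
    st[root] <- min(down[[root]])
    for (k in seq_len(nrow(pre_edges))) {
      p <- pre_edges[k, 1]; c <- pre_edges[k, 2]
      st[c] <- if (st[p] %in% down[[c]]) st[p] else min(down[[c]])
    }
    states[, si] <- st
  }

  es_site <- colMeans(matrix(tab$s_site[cm[, usable, drop = FALSE]], nrow = n))
  en_site <- 3 - es_site
  sd_site <- numeric(nsite); nd_site <- numeric(nsite)
  per_branch <- data.frame(parent = edge[, 1], child = edge[, 2],
                           Sd = 0, Nd = 0)
  for (k in seq_len(nrow(edge))) {
    a <- states[edge[k, 1], ]; b <- states[edge[k, 2], ]
    w <- which(a != b)
    if (!length(w)) next
    sd_b <- tab$Sd[cbind(a[w], b[w])]
    nd_b <- tab$Nd[cbind(a[w], b[w])]
    sd_site[w] <- sd_site[w] + sd_b
    nd_site[w] <- nd_site[w] + nd_b
    per_branch$Sd[k] <- sum(sd_b)
    per_branch$Nd[k] <- sum(nd_b)
  }

  ES <- sum(es_site); EN <- sum(en_site)
  pS <- if (ES > 0) sum(sd_site) / ES else NA_real_
  pN <- if (EN > 0) sum(nd_site) / EN else NA_real_
  dS <- .jc(pS); dN <- .jc(pN)
  no_subs <- sum(sd_site) + sum(nd_site) == 0
  # the mean is the ratio of the tree-wide substitution rates; the branch-wise
  # counting already spreads changes over the tree, so no multiple-hit
  # correction is applied to the totals (the corrected ratio is reported
  # separately and is NA when a proportion leaves the correctable range)
  mean_dnds <- if (no_subs || is.na(pS) || pS == 0) NA_real_ else pN / pS
  mean_jc <- if (no_subs || is.na(dS) || is.na(dN) || dS == 0) NA_real_ else dN / dS

  total <- sd_site + nd_site
  rate_diff <- ifelse(en_site > 0, nd_site / en_site, 0) -
    ifelse(es_site > 0, sd_site / es_site, 0)
  pval <- rep(NA_real_, nsite)
  class <- rep(NA_character_, nsite)
  for (si in which(total >= 1 - 1e-9)) {
    k <- round(nd_site[si]); m <- max(1L, round(total[si]))
    k <- min(k, m)
    pexp <- en_site[si] / 3
    pval[si] <- stats::binom.test(k, m, pexp)$p.value
    class[si] <- if (pval[si] < alpha) {
      if (nd_site[si] / total[si] > pexp) "positive" else "negative"
    } else "neutral"
  }
  qval <- rep(NA_real_, nsite)
  tested <- !is.na(pval)
  qval[tested] <- stats::p.adjust(pval[tested], method = "BH")

  per_site <- data.frame(site = usable, ES = es_site, EN = en_site,
                         Sd = sd_site, Nd = nd_site,
                         dN_minus_dS = rate_diff,
                         p = pval, q = qval, class = class,
                         stringsAsFactors = FALSE)
  structure(list(mean_dnds = mean_dnds,
                 mean_dnds_jc = mean_jc,
                 totals = list(ES = ES, EN = EN,
                               Sd = sum(sd_site), Nd = sum(nd_site),
                               dS = dS, dN = dN),
                 per_site = per_site, per_branch = per_branch,
                 n_sites_used = nsite, excluded_rows = excluded,
                 alpha = alpha, tree = tree),
            class = "slac_result")
}

#' @export
print.slac_result <- function(x, ...) {
  cat("SLAC-style selection analysis\n")
  cat(sprintf("  sites used: %d, mean dN/dS: %s\n", x$n_sites_used,
              format(x$mean_dnds, digits = 4)))
  cls <- table(x$per_site$class[!is.na(x$per_site$class)])
  if (length(cls)) {
    cat("  classified sites:",
        paste(sprintf("%s=%d", names(cls), as.integer(cls)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Cumulative average substitution profile along the coding region
#'
#' For every codon position `j`, the cumulative mean over all sequence pairs
#' of pathway-averaged synonymous and nonsynonymous substitutions summed
#' over sites `<= j` (both curves monotone non-decreasing), plus a
#' cumulative gap-opening (indel) curve averaged over rows.
#'
#' @param aln Codon alignment (>= 2 rows).
#' @return Data frame: `site`, `cum_syn`, `cum_nonsyn`, `cum_indel`.
#' @export
cumulative_profile <- function(aln) {
  aln <- .as_codon_alignment(aln)
  if (length(aln$rows) < 2L) stop("famscan input error: need >= 2 sequences")
  tab <- .codon_tables()
  cm <- .codon_index_matrix(aln)
  n <- nrow(cm); ncod <- ncol(cm)
  sd_tot <- nd_tot <- numeric(ncod)
  npair <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      npair <- npair + 1L
      ok <- !is.na(cm[i, ]) & !is.na(cm[j, ])
      if (any(ok)) {
        sd_tot[ok] <- sd_tot[ok] + tab$Sd[cbind(cm[i, ok], cm[j, ok])]
        nd_tot[ok] <- nd_tot[ok] + tab$Nd[cbind(cm[i, ok], cm[j, ok])]
      }
    }
  }
  gap <- t(vapply(aln$rows, function(r) {
    cds <- codons_of(r)
    grepl("-", cds, fixed = TRUE)
  }, logical(ncod), USE.NAMES = FALSE))
  if (ncod == 1L) gap <- matrix(gap, nrow = n)
  openings <- gap & !cbind(FALSE, gap[, -ncod, drop = FALSE])
  data.frame(site = seq_len(ncod),
             cum_syn = cumsum(sd_tot) / npair,
             cum_nonsyn = cumsum(nd_tot) / npair,
             cum_indel = cumsum(colSums(openings)) / n)
}

#' Simulate codon evolution along a tree
#'
#' Continuous-time simulation per codon site: single-nucleotide changes to
#' non-stop codons occur at relative rate 1 (synonymous) or `omega`
#' (nonsynonymous), scaled so one unit of branch length corresponds to
#' roughly one substitution per nucleotide site under neutrality. Used to
#' benchmark the counting estimators against a known omega.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param n_codons Number of codon sites.
#' @param omega Nonsynonymous/synonymous rate ratio.
#' @param seed Optional RNG seed.
#' @return A codon [fam_alignment()] of the leaf sequences.
#' @export
simulate_codon_evolution <- function(tree, n_codons, omega = 1, seed = NULL) {
  tab <- .codon_tables()
  run <- function() {
    ntip <- length(tree$tip.label)
    ntot <- ntip + tree$Nnode
    root <- ntip + 1L
    edge <- ape::reorder.phylo(tree, "cladewise")$edge
    elen <- ape::reorder.phylo(tree, "cladewise")$edge.length
    seqs <- vector("list", ntot)
    seqs[[root]] <- sample.int(length(tab$sc), n_codons, replace = TRUE)
    for (k in seq_len(nrow(edge))) {
      parent <- edge[k, 1]; child <- edge[k, 2]
      s <- seqs[[parent]]
      t_branch <- elen[k]
      for (ci in seq_len(n_codons)) {
        t_rem <- t_branch
        repeat {
          nb <- tab$neighbors[[s[ci]]]
          w <- ifelse(nb$syn, 1, omega)
          rate <- sum(w) / 3
          if (rate <= 0) break
          dt <- stats::rexp(1, rate)
          if (dt > t_rem) break
          t_rem <- t_rem - dt
          s[ci] <- nb$to[sample.int(length(nb$to), 1L, prob = w)]
        }
      }
      seqs[[child]] <- s
    }
    rows <- vapply(seq_len(ntip), function(i) {
      paste(tab$sc[seqs[[i]]], collapse = "")
    }, character(1))
    fam_alignment(tree$tip.label, rows, is_codon_aligned = TRUE)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
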