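# End-to-end pipeline driver and configuration handling, plus the
# truth-scoring helper used to benchmark runs on synthetic genomes.

#' Pipeline configuration
#'
#' Bundles paths and thresholds for [run_pipeline()]; can be round-tripped
#' through YAML with [read_config()]/[write_config()].
#'
#' @param genome Path to the genome FASTA (ignored when a simulated genome
#'   object is passed to [run_pipeline()] directly).
#' @param seeds Optional path to a seed-exon FASTA; default uses the
#'   package reference exons.
#' @param species Species label used in outputs.
#' @param max_evalue,min_cover,length_tol Mining gates (see
#'   [mining_params()] and [refine_exon_boundaries()]).
#' @param max_rounds Mining rounds.
#' @param max_gap Maximum intra-gene exon gap (nt).
#' @param n_bootstrap Bootstrap replicates for the N-domain tree.
#' @param alpha Per-site significance level for selection classification.
#' @param anchors Optional named list/vector: subgroup label -> gene id.
#' @param seed Integer seed for all stochastic stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genome = NULL, seeds = NULL, species = "sample",
                            max_evalue = 1e-10, min_cover = 0.5,
                            length_tol = 6L, max_rounds = 3L,
                            max_gap = 25000L, n_bootstrap = 500L,
                            alpha = 0.1, anchors = NULL, seed = 1L) {
  structure(list(genome = genome, seeds = seeds, species = species,
                 max_evalue = max_evalue, min_cover = min_cover,
                 length_tol = as.integer(length_tol),
                 max_rounds = as.integer(max_rounds),
                 max_gap = as.integer(max_gap),
                 n_bootstrap = as.integer(n_bootstrap),
                 alpha = alpha,
                 anchors = if (is.null(anchors)) NULL else as.list(anchors),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("famscan parse error: no such file: ", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Write a pipeline configuration to YAML
#' @param config A `pipeline_config`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[!vapply(unclass(config), is.null, logical(1))],
                   path)
  invisible(path)
}

.param_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

.stage_log <- function(quiet, stage, seed, hash) {
  if (!quiet) {
    message(sprintf("famscan [stage=%s seed=%d params=%s]", stage, seed, hash))
  }
}

#' Run the full annotation and analysis pipeline
#'
#' Stages run in order: mine -> annotate -> receptors -> census -> tree ->
#' subgroups -> selection. Every output file is written under `out_dir`
#' together with a manifest of parameters, the seed and per-file checksums;
#' rerunning with an identical configuration reproduces the
#' manifest-tracked outputs byte for byte. An empty genome produces valid,
#' empty outputs at every stage.
#'
#' @param genome A named character vector of contigs, a `cea_genome` from
#'   [simulate_genome()], or a FASTA path.
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage log lines.
#' @return Invisibly, a list with `calls`, `models`, `census`, `tree`,
#'   `subgroups`, `selection`, `profile` and `files`.
#' @export
run_pipeline <- function(genome, out_dir, config = pipeline_config(),
                         quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .param_hash(unclass(config))
  sim <- NULL
  contigs <- if (inherits(genome, "cea_genome")) {
    sim <- genome
    genome$contigs
  } else if (is.character(genome) && length(genome) == 1L &&
             file.exists(genome)) {
    read_fasta(genome)
  } else {
    genome
  }
  refs <- reference_exons()
  if (!is.null(config$seeds)) {
    seeds <- read_fasta(config$seeds)
    seed_domains <- stats::setNames(.infer_domains(names(seeds)), names(seeds))
  } else {
    seeds <- vapply(names(attr(refs, "domains")), function(n) refs[[n]],
                    character(1))
    seed_domains <- attr(refs, "domains")
  }
  params <- mining_params(max_evalue = config$max_evalue,
                          min_cover = config$min_cover)
  files <- c()

  # --- mine -----------------------------------------------------------
  .stage_log(quiet, "mine", config$seed, hash)
  calls <- iterative_mine(contigs, seeds, seed_domains, params,
                          max_rounds = config$max_rounds,
                          length_tol = config$length_tol)
  files["calls_tsv"] <- file.path(out_dir, "exon_calls.tsv")
  write_tsv(calls, files["calls_tsv"])
  files["calls_bed"] <- file.path(out_dir, "exon_calls.bed")
  write_calls_bed(calls, files["calls_bed"])
  files["calls_gff3"] <- file.path(out_dir, "exon_calls.gff3")
  write_calls_gff3(calls, files["calls_gff3"])

  # --- annotate -------------------------------------------------------
  .stage_log(quiet, "annotate", config$seed, hash)
  models <- assemble_gene_models(calls, max_gap = config$max_gap)
  igc_refs <- c(A1 = refs$A1, B = refs$B, A2 = refs$A2)
  tm_refs <- c(`CEACAM1-like` = refs$TM_CEACAM1,
               `CEACAM3-like` = refs$TM_CEACAM3)
  models <- lapply(models, function(m) {
    classify_architecture(m, igc_refs, contig_seq = contigs[[m$contig_id]])
  })
  .stage_log(quiet, "receptors", config$seed, hash)
  models <- lapply(models, function(m) {
    classify_receptor_signaling(m, tm_refs, contig_seq = contigs[[m$contig_id]])
  })
  models <- name_models(models, species_prefix = config$species)
  gene_df <- models_to_df(models)
  files["genes_tsv"] <- file.path(out_dir, "gene_models.tsv")
  write_tsv(gene_df, files["genes_tsv"])
  files["genes_gff3"] <- file.path(out_dir, "gene_models.gff3")
  write_models_gff3(models, files["genes_gff3"])

  cen <- census(models, species = config$species)
  files["census"] <- file.path(out_dir, "census.tsv")
  write_tsv(cen, files["census"])

  # N-domain sequences for downstream stages
  n_seqs <- .n_domain_seqs(models, orf_only = TRUE)
  files["n_nt"] <- file.path(out_dir, "n_domains_nt.fa")
  write_fasta(n_seqs, files["n_nt"])
  files["n_aa"] <- file.path(out_dir, "n_domains_aa.fa")
  write_fasta(vapply(n_seqs, translate_nt, character(1)), files["n_aa"])

  # --- tree -----------------------------------------------------------
  .stage_log(quiet, "tree", config$seed, hash)
  tree <- NULL
  if (length(n_seqs) >= 4L) {
    aa_aln <- progressive_align(
      stats::setNames(vapply(n_seqs, translate_nt, character(1)), names(n_seqs)),
      mode = "aa")
    tree <- bootstrap_support(aa_aln, n_replicates = config$n_bootstrap,
                              seed = config$seed)
  }
  files["tree"] <- file.path(out_dir, "n_domain_tree.nwk")
  if (!is.null(tree)) write_newick(tree, files["tree"]) else file.create(files["tree"])

  # --- subgroups ------------------------------------------------------
  .stage_log(quiet, "subgroups", config$seed, hash)
  subgroups <- NULL
  if (!is.null(tree) && !is.null(config$anchors)) {
    anchors <- unlist(config$anchors)
    if (all(anchors %in% tree$tip.label)) {
      subgroups <- assign_subgroups(tree, anchors)
    }
  }
  files["subgroups"] <- file.path(out_dir, "subgroups.tsv")
  if (!is.null(subgroups)) {
    write_tsv(data.frame(gene_id = names(subgroups$labels),
                         subgroup = unname(subgroups$labels),
                         stringsAsFactors = FALSE), files["subgroups"])
  } else {
    write_tsv(data.frame(gene_id = character(0), subgroup = character(0)),
              files["subgroups"])
  }

  # --- selection (PSG N domains) --------------------------------------
  .stage_log(quiet, "selection", config$seed, hash)
  psg_ids <- gene_df$gene_id[startsWith(gene_df$architecture, "PSG") &
                               !gene_df$is_pseudogene]
  psg_seqs <- n_seqs[names(n_seqs) %in% psg_ids]
  selection <- NULL; profile <- NULL
  if (length(psg_seqs) >= 3L) {
    codon_aln <- progressive_align(psg_seqs, mode = "codon")
    selection <- slac_analyze(codon_aln, alpha = config$alpha)
    profile <- cumulative_profile(codon_aln)
  }
  files["selection_site"] <- file.path(out_dir, "selection_per_site.tsv")
  files["selection_summary"] <- file.path(out_dir, "selection_summary.tsv")
  files["profile"] <- file.path(out_dir, "cumulative_profile.tsv")
  if (!is.null(selection)) {
    write_tsv(selection$per_site, files["selection_site"])
    write_tsv(data.frame(mean_dnds = selection$mean_dnds,
                         mean_dnds_jc = selection$mean_dnds_jc,
                         n_sites = selection$n_sites_used,
                         n_sequences = length(psg_seqs)),
              files["selection_summary"])
    write_tsv(profile, files["profile"])
  } else {
    write_tsv(data.frame(site = integer(0)), files["selection_site"])
    write_tsv(data.frame(mean_dnds = numeric(0)), files["selection_summary"])
    write_tsv(data.frame(site = integer(0)), files["profile"])
  }

  # --- manifest -------------------------------------------------------
  manifest <- list(seed = config$seed, parameter_hash = hash,
                   parameters = unclass(config)[
                     !vapply(unclass(config), is.null, logical(1))],
                   files = as.list(vapply(files, function(f) {
                     unname(tools::md5sum(f))
                   }, character(1))))
  files["manifest"] <- file.path(out_dir, "manifest.yml")
  yaml::write_yaml(manifest, files["manifest"])

  invisible(list(calls = calls, models = models, census = cen, tree = tree,
                 subgroups = subgroups, selection = selection,
                 profile = profile, files = files))
}

.infer_domains <- function(nms) {
  known <- c("leader", "N", "A1", "B", "A2", "TM", "Cyt1", "Cyt2")
  vapply(nms, function(n) {
    hit <- known[vapply(known, function(k) grepl(k, n, fixed = TRUE), logical(1))]
    if (length(hit)) hit[which.max(nchar(hit))] else "N"
  }, character(1))
}

.n_domain_seqs <- function(models, orf_only = TRUE) {
  out <- character(0)
  for (m in models) {
    i <- which(m$exons$domain_type == "N")
    if (!length(i)) next
    if (orf_only && !m$orf[[i[1]]]$orf_intact) next
    if (!m$exons$length_ok[i[1]]) next
    # codon-stage analyses need frame-consistent exons; a boundary off by a
    # non-multiple of 3 would inject a frameshifted translation
    if (nchar(m$exons$sequence[i[1]]) %% 3L != 0L) next
    out[m$gene_id] <- m$exons$sequence[i[1]]
  }
  out
}

#' Score a pipeline run against the planted truth of a synthetic genome
#'
#' @param sim A `cea_genome`.
#' @param calls Exon calls from the run.
#' @param models Classified gene models from the run.
#' @return List of recovery metrics: `n_exon_recovery` (fraction of planted
#'   N exons called with exactly correct boundaries), `pseudogene_accuracy`
#'   (over recovered N exons), `architecture_accuracy` and
#'   `signaling_accuracy` (over all planted genes), `false_positive_calls`
#'   (calls not overlapping any planted exon), and the counts behind them.
#' @export
score_against_truth <- function(sim, calls, models) {
  truth_n <- sim$exons[sim$exons$domain == "N", , drop = FALSE]
  gene_truth <- sim$genes

  # N exon recovery with exact boundaries
  matched <- logical(nrow(truth_n))
  call_pseudo_ok <- logical(0)
  for (i in seq_len(nrow(truth_n))) {
    hit <- which(calls$contig_id == truth_n$contig_id[i] &
                   calls$start == truth_n$start[i] &
                   calls$end == truth_n$end[i])
    matched[i] <- length(hit) > 0L
    if (matched[i]) {
      orf <- call_orf_status(calls$sequence[hit[1]])
      is_pseudo_call <- !orf$orf_intact
      truth_pseudo <- gene_truth$is_pseudogene[
        gene_truth$gene_id == truth_n$gene_id[i]]
      call_pseudo_ok <- c(call_pseudo_ok, is_pseudo_call == truth_pseudo)
    }
  }

  # map each planted gene to the model containing its N exon
  arch_ok <- logical(nrow(gene_truth))
  sig_ok <- logical(nrow(gene_truth))
  exp_arch <- ifelse(startsWith(gene_truth$architecture, "PSG"),
                     gene_truth$architecture, "CEACAM-TM")
  for (i in seq_len(nrow(gene_truth))) {
    tn <- truth_n[truth_n$gene_id == gene_truth$gene_id[i], , drop = FALSE]
    model <- NULL
    for (m in models) {
      k <- which(m$exons$domain_type == "N" &
                   m$exons$contig_id == tn$contig_id[1] &
                   pmin(m$exons$end, tn$end[1]) -
                     pmax(m$exons$start, tn$start[1]) > 0)
      if (length(k)) { model <- m; break }
    }
    if (is.null(model)) next
    arch_ok[i] <- identical(model$architecture, exp_arch[i])
    sig <- if (!is.null(model$receptor)) model$receptor$signaling else NA_character_
    sig_ok[i] <- identical(sig, gene_truth$signaling[i])
  }

  # false positives: calls not overlapping any planted exon
  fp <- 0L
  for (i in seq_len(nrow(calls))) {
    ov <- any(sim$exons$contig_id == calls$contig_id[i] &
                pmin(sim$exons$end, calls$end[i]) -
                  pmax(sim$exons$start, calls$start[i]) > 0)
    if (!ov) fp <- fp + 1L
  }

  list(
    n_exon_recovery = if (nrow(truth_n)) mean(matched) else NA_real_,
    pseudogene_accuracy = if (length(call_pseudo_ok)) mean(call_pseudo_ok) else NA_real_,
    architecture_accuracy = if (nrow(gene_truth)) mean(arch_ok) else NA_real_,
    signaling_accuracy = if (nrow(gene_truth)) mean(sig_ok) else NA_real_,
    false_positive_calls = fp,
    n_planted_n_exons = nrow(truth_n),
    n_recovered_n_exons = sum(matched),
    n_genes = nrow(gene_truth)
  )
}
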