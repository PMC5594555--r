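---
title: "Annotating and analyzing expanded CEA/PSG gene families with famscan"
author: "famscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating and analyzing expanded CEA/PSG gene families with famscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famscan)
```

## The problem famscan addresses

The carcinoembryonic antigen (CEA) family is one of the fastest-evolving
gene families in mammals. In several bat species of the Yangochiroptera
suborder it has expanded to on the order of one hundred members, the
majority of which are secreted, pregnancy-specific-glycoprotein-like (PSG)
genes rather than membrane-anchored CEACAM receptors. Annotating such an
expansion from whole-genome shotgun contigs is laborious: exons must be
found by homology from a handful of reference exons, validated by length
and splice-site context, chained into gene models contig by contig,
classified into receptor versus secreted architectures, and finally
analyzed phylogenetically and for signatures of diversifying selection on
the ligand-binding (IgV-like, "N") domain.

famscan packages that workflow as composable, tested R functions:

* `simulate_genome()` — a synthetic-genome generator that plants CEA-family
  gene cassettes with a machine-readable truth set;
* `iterative_mine()` — homology-seeded exon discovery with significance
  gates and splice-site-aware boundary refinement;
* `assemble_gene_models()`, `classify_architecture()`,
  `classify_receptor_signaling()`, `census()` — gene-model assembly and
  classification;
* `progressive_align()`, `nj_tree()`, `bootstrap_support()`,
  `assign_subgroups()` — N-domain phylogenetics;
* `ng86_site_counts()`, `ng86_pair_counts()`, `pairwise_dnds()`,
  `slac_analyze()`, `cumulative_profile()` — counting-based selection
  analysis;
* `run_pipeline()` and the `famscan` command-line script — the end-to-end
  driver.

Because the genuine genomes behind such studies are large external
downloads, every stage is exercised against synthetic genomes with planted
ground truth; this vignette explains the model behind each stage, the
parameters that matter, and what the synthetic benchmarks do and do not
demonstrate.

## The synthetic genome generator

`family_spec()` describes a gene family: the number of genes, the fraction
with secreted PSG architecture, the pseudogene fraction, the split of
activating versus inhibitory receptor cassettes, the expected per-site
divergence of each paralog from the ancestral cassette, intron and
intergenic length ranges, and a seed. The same spec and seed always produce
byte-identical FASTA/GFF3/TSV output.

Each planted gene is a cassette of phase-0 exons separated by GT..AG
introns:

* secreted PSG genes: leader, N (IgV-like) and one A2-type IgC exon whose
  reading frame carries a stop codon — within the final six codons for a
  two-domain PSG, earlier for a one-domain PSG — followed by a
  polyadenylation signal (AATAAA) 40 nt downstream of the stop;
* receptor genes: leader, N, A1, B, A2, a transmembrane exon of either the
  CEACAM1-like or the CEACAM3-like reference type, and two cytoplasmic
  exons carrying either two ITIMs, an ITIM plus an ITSM, or an ITAM. A
  configurable fraction of receptor genes has the splice donor between the
  cytoplasmic exons mutated (GT to AT), which renders the signaling motifs
  non-functional;
* any gene may additionally be pseudogenized by an in-frame stop planted in
  the N exon.

Default exon lengths are leader 102 nt, N 321 nt, IgC 279 nt, TM 108 nt and
cytoplasmic 90/150 nt. Real CEACAM exon lengths are not standardized in the
literature we model, so these are round, frame-preserving choices exposed
via `exon_lengths`; phase-0 junctions keep frame bookkeeping independent of
exon order.

Divergence is realized by i.i.d. per-site substitution (uniform over the
three alternative bases; no indels by default). After mutation the
generator restores the planted invariants: non-planted in-frame stops are
reverted to the ancestral codon, splice dinucleotides, start codons,
planted stops and the polyadenylation hexamer are never mutated, and the
cytoplasmic motif set is re-verified against the planted motifs (a drifted
exon pair is repaired toward the ancestral codons). The truth tables
therefore describe the emitted sequence exactly, which is what makes
end-to-end recovery measurable.

The N-domain ancestors come in three flavours — one for receptor genes and
two diverged PSG subgroup ancestors (default 0.2 substitutions/site from
the base) — so that the PSG I / PSG II subgroup structure reported for
vespertilionid bats has a synthetic counterpart and anchor-based subgroup
assignment can be scored against generator ancestry.

Default fractions emulate the *Myotis lucifugus*-scale family: 100 genes,
90% secreted, half pseudogenized, a balanced activating/inhibitory split,
one quarter of inhibitory tails carrying an ITSM, and 30% of receptor genes
with a mutated donor.

What the generator does **not** emulate: realistic base composition,
repeats, segmental-duplication mosaics, assembly gaps or sequencing error.
Passing the recovery benchmarks therefore demonstrates the correctness of
the pipeline's logic under its stated assumptions, not its sensitivity on
raw wgs data.

## Exon mining

`seeded_local_search()` finds candidate loci with an exact-word seed filter
(default word size 9, two hits on nearby alignment diagonals required per
locus, BLAST-style) and scores each candidate window by Smith-Waterman
local alignment (match +2, mismatch −3, gap open 5, gap extend 2; N never
matches). Hits are gated on a Karlin–Altschul-style E-value surrogate
`E = K·m·n·exp(−λS)` with pinned constants K = 0.1, λ = 0.33 (`E < 1e-10`)
and on query cover (> 50%). The constants are fixed so the decision rule is
deterministic and testable; any monotone surrogate with calibrated gates
reproduces the same accept/reject behaviour. Overlapping hits from
different queries (reciprocal overlap > 50%) collapse to the best call per
locus, since loci — not hits — are the unit of annotation.

`refine_exon_boundaries()` scans ±30 nt around each raw alignment end for
the intron-side dinucleotides (AG upstream, GT downstream). Candidate
placements are ranked by a combined penalty: ungapped mismatches against
the query, a charge of 3 per missing splice signal, and the deviation from
the expected domain length (`length_ok` tolerance ±6 nt). Two properties
of this ranking matter in practice. First, a single-signal placement at
the exact expected length beats a nearby AG..GT pair whose implied length
is off — otherwise a chance intronic GT would mask a genuinely mutated
donor site. Second, when a raw alignment end was trimmed past the scan
window (distant paralogs), the boundary implied by the expected length is
checked for the canonical dinucleotide and promoted to a full pair when it
carries one. For calls truncated by a contig edge the expected-length
prior is unreliable, so evidence nearest the raw alignment wins and the
call is flagged `partial`.

`iterative_mine()` re-seeds the search each round with the exon sequences
called in the previous round (longer seed words in later rounds, since
re-seeded queries are close to their targets), terminating at a fixed
point or `max_rounds`. Loci already called with full splice/length support
are excluded from re-scoring; imperfect calls remain open and are replaced
when a closer paralog yields a better-supported call. Short cytoplasmic
exons are additionally sought in 2-kb windows downstream of each TM call,
where the smaller search space relaxes the E-value gate — this is how
exons too short to pass a genome-wide significance threshold are
recovered.

## Gene models and architectures

Exons on one contig and strand are chained into genes in transcript order.
A new gene opens when the gap exceeds `max_gap` (default 25 kb, chosen to
exceed any plausible intron in the synthetic cassettes and configurable for
real data), when a second N exon would enter the model — each CEA-family
gene carries exactly one N-domain exon — and, more generally, whenever the
canonical domain order (leader < N < A1 < B < A2 < TM < Cyt1 < Cyt2) fails
to advance. The last rule is needed because consecutive cassettes on one
contig are often closer than `max_gap`, and without it the leader of a
downstream gene would be absorbed into the upstream model.

Architecture classification: a TM exon makes a membrane-anchored receptor;
without one, the terminal IgC exon's first in-frame stop decides between a
two-domain PSG (stop within the final six codons) and a one-domain PSG
(earlier stop). The six-codon cutoff operationalizes the distinction
between a stop "at the end of" versus "within" the IgC exon; the boundary
is a parameter (`terminal_codons`). IgC exons are (re)typed A1/B/A2 by
best alignment score against reference IgC exons; an N exon with an
internal stop marks the gene as a pseudogene; N-glycosylation sequons
(N-X-[S/T], X ≠ P, non-overlapping from the left) are counted on the
translated N domain; and for PSGs the polyadenylation signal is sought
within 200 nt downstream of the stop ("near proximity" is not quantified
in the source literature; 200 nt is the configurable default).

Receptor signaling: TM type by nearest reference (CEACAM1-like versus
CEACAM3-like; ties broken by score then lexical order and recorded), then
motifs of the concatenated translated cytoplasmic exons. ITIM
`[ILVS]xYxx[ILV]`, ITSM `TxYxx[VI]` and ITAM `Yxx[LI]x{6,12}Yxx[LI]` are
the standard immunology consensi; they are configuration, not constants.
An ITIM and an ITSM centred on the same tyrosine report as ITSM only, and
tyrosines inside an ITAM are not re-reported as ITIM/ITSM (an ITAM
half-site can match the looser ITIM consensus). Any mutated splice donor
at or downstream of the TM exon overrides the class to `nonfunctional`,
mirroring the rule that such genes cannot produce functional
tyrosine-based signaling motifs.

## Phylogenetics

`progressive_align()` is a progressive profile aligner: a UPGMA guide tree
from k-mer distances, then affine-gap global profile–profile alignment
(compiled Gotoh DP; BLOSUM62 for amino acids, +2/−3 with gap 5/2 for
nucleotides). Codon mode aligns the translations and threads the
nucleotides back in intact triplets, so codons are never split; rows with
internal stops are aligned but flagged. For the equal-length, indel-free
sequences the generator produces, alignment is near-trivial; the aligner
exists so the same interface works on real, length-variable families.

Trees are built by neighbor joining on p- or Jukes–Cantor distances
(`nj_tree()`, negative branch estimates clamped to zero with a message).
Distance-based NJ with bootstrap (default 500 column-resampling replicates,
codon-aware for codon alignments) stands in for the maximum-likelihood
search used in the original analyses: the downstream decisions —
clustering into CEACAM/PSG subgroups — depend on tree distances rather
than likelihoods, and NJ on these strongly structured families recovers
the same groups; a likelihood hook would be a natural extension point.
`assign_subgroups()` labels every leaf by its nearest anchor leaf in
patristic distance (invariant to re-rooting) and reports per-label
monophyly.

## Selection analysis

The counting core follows Nei–Gojobori (1986). Expected sites: per codon
position, the synonymous fraction is computed over the non-stop single-base
changes, so `s + n = 3` holds exactly for every sense codon. Observed
substitutions between two codons average the synonymous/nonsynonymous
steps over all orderings of the differing positions whose intermediates
avoid stop codons (all orderings if every pathway is blocked). Pairwise
`dN/dS` applies the Jukes–Cantor correction to `pS` and `pN` and reports
`NA` when `dS = 0` or a proportion exceeds the correctable range (3/4).

`slac_analyze()` is the tree-aware version: ancestral codons per site by
Fitch parsimony with ties resolved to the lexically smallest codon — a
deterministic, documented substitute for the likelihood ancestors of the
original SLAC — substitutions pathway-counted on every branch, and the
alignment-wide mean reported as the ratio of tree-wide rates
`(ΣNd/ΣEN)/(ΣSd/ΣES)`. No multiple-hit correction is applied to the
tree-wide totals (branch-wise counting already spreads changes over the
tree; correcting the totals saturates on deep trees), but a
Jukes–Cantor-corrected companion value `mean_dnds_jc` is reported, and on
a two-leaf tree it equals the pairwise estimator exactly. Per-site
classification uses a two-tailed binomial test of the nonsynonymous count
against the site's expected nonsynonymous proportion `EN/(ES+EN)`,
classifying only sites with at least one inferred substitution, at raw
`alpha = 0.1` (the reporting convention of the analyses this mirrors);
Benjamini–Hochberg q-values are reported alongside. Codon columns
containing gaps are skipped (pairwise deletion is available for the
pairwise counter); rows with internal stops are excluded and logged. This
per-site binomial test is a counting-based substitute for random-effects
likelihood models (BUSTED/MEME), and no recombination screening is
performed — both are labeled as such in the outputs' documentation rather
than silently approximated.

`cumulative_profile()` reports, per codon position, the cumulative mean of
synonymous and nonsynonymous substitutions over all sequence pairs plus a
gap-opening curve — the classic way to visualize where along the N exon
nonsynonymous changes accumulate (e.g. in the CC'C″FG β-strand region when
region annotations are overlaid).

`simulate_codon_evolution()` provides the calibration oracle: codon sites
evolve by single-nucleotide jumps at relative rate 1 (synonymous) versus
ω (nonsynonymous), scaled so a unit branch length is roughly one
substitution per nucleotide site under neutrality. The benchmark tree is an
8-taxon balanced tree with branch lengths 0.03–0.05 so that parsimony
reconstruction stays reliable; with ≥300 codon sites the estimator returns
a mean near 1 under ω = 1 and well above 1.5 under ω = 3.

## Numerical and degenerate-input policy

* Coordinates are 0-based half-open internally; GFF3 (1-based inclusive)
  and BED (0-based half-open) conversions happen only at serialization.
* All RNG-dependent stages accept a seed; the pipeline derives per-stage
  behaviour from one seed and writes a manifest with parameter hash and
  per-file checksums, so identical configurations reproduce identical
  tracked outputs.
* Empty genomes, gene-free contigs, single-sequence families and
  all-invariant alignments produce valid, empty-or-flat outputs rather
  than errors; zero-substitution alignments report `NA` means.
* Equal pairwise distances produce an arbitrary resolved NJ topology with
  zero-length internal branches; anchor ties resolve to the first anchor
  in the given order.

## Benchmark scales used by the test-suite

The packaged tests run the full pipeline on genomes of 8–12 genes and the
acceptance benchmarks on a 200-gene, 8-contig genome (~0.8 Mb) at 0.10
substitutions/site — the family size and pseudogene load reported for the
most expanded bat genomes — plus counting-core equivalence over all 3,721
sense-codon pairs, ω-calibration on 320 codons, and topology-recovery over
random trees of up to 12 taxa. These sizes keep the whole suite within a
few minutes on one core while leaving every algorithmic path exercised.

## Known limitations

* The miner assumes exon lengths near the seed-exon lengths; exons whose
  true length differs by more than the ±6 nt tolerance lose their
  `length_ok` flag and may be refined against the wrong signal. Genuinely
  length-variable families need a per-domain tolerance.
* Fitch-parsimony ancestors undercount substitutions on deep branches;
  mean dN/dS from heavily saturated alignments is conservative.
* The E-value surrogate is calibrated for the packaged scoring scheme; if
  you change match/mismatch scores, recalibrate K and λ.
* Splice-site validation recognizes only canonical GT..AG introns;
  minor-spliceosome introns would be flagged as mutated.
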