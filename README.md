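# glrevo

Evolutionary analysis of a plant gene family — the glutamate-like receptors
(GLRs), plant homologs of animal ionotropic glutamate receptors — as a
tested, reusable R pipeline. The package is aimed at comparative genomicists
who study how a gene family expands across genomes: which copies arose by
tandem duplication, which by whole-genome/segmental (WGD) events, which are
dispersed; how expansion proceeded as a chain of nearest duplicates; how
strongly purifying selection acts on each subfamily; and how expression
patterns cluster across tissues.

Every stage runs on synthetic genomes with planted ground truth, so the
entire chain — from FASTA/BED input to duplication calls, dN/dS estimates,
trees and expression clusters — is verifiable end to end without downloading
a single genome.

## What it computes

* **Family identification** — ORF-integrity pseudogene filtering
  (frameshift, premature stop, short fragment), PSSM-based domain
  architecture calls for the seven GLR domains (ATD, GlnH1, M1, M2-Pore,
  M3, GlnH2, M4), and domain-loss rate tables.
* **Duplication classification** — all-vs-all local alignment (BLOSUM62,
  top-5 hits, null-calibrated score threshold), MCScanX-style collinear
  chain detection by dynamic programming (≥ 5 anchors, rank gap ≤ 25), and
  fixed-priority mode calls: a gene in a syntenic block is WGD/segmental; a
  gene whose homolog lies within 10 neighbouring genes on the same
  chromosome is tandem; remaining homologous genes are dispersed. Tandem
  arrays are maximal runs of tandem-called genes; the tandem-related
  fraction is reported as a percentage.
* **Expansion history** — nearest-duplicate selection (highest identity,
  then most shared flanking block anchors, then lowest Ks), linear
  expansion-series assembly, and cross-species orthology series with
  ancestral-anchor flags.
* **Conservation and gene structure** — per-column conservation index
  (number of the 10 Livingstone–Barton physico-chemical property classes on
  which all rows agree, 0–10), sliding-window profiles (20-residue window,
  10-residue slide), group identity, intron projection onto protein
  alignments (column + phase) and conserved-intron detection.
* **Selection** — dN/dS (ω) per pair by Nei–Gojobori (1986) counting with
  pathway averaging and Jukes–Cantor correction, and by GY94/M0 maximum
  likelihood over (ω, κ, t) with three restarts and F3x4 codon frequencies;
  per-group ω medians with Wilcoxon rank-sum tests.
* **Phylogenetics** — NJ trees with bootstrap supports, marker-anchored
  subfamily classification (GLR0/GLR1&2/GLR3/GLR4), sister-clade tests.
* **Expression** — Cq → relative expression (E^(−ΔCq), E = 2 default),
  log2 + z-score standardization, k-means++ clustering, tissue-preference
  calls.
* **Synthetic data** — generators for genomes with planted tandem arrays,
  collinear blocks, dispersed copies and singletons; codon pairs evolved
  under GY94/M0 with known ω; alignments with planted conserved columns;
  gene models with planted intron slots; expression matrices with planted
  clusters. All pure functions of (spec, seed).

The methods vignette (`vignettes/glr-family-evolution.Rmd`) documents the
models, parameter defaults and numerical choices in detail.

## Worked example

Simulate a genome, detect homolog pairs and blocks, classify duplication
modes (this is `analysis/03_duplication_classification.R` condensed):

```r
library(glrevo)

spec <- family_spec(n_tandem_arrays = 2, array_sizes = c(3, 2),
                    n_segmental_blocks = 1, block_gene_count = 5,
                    n_dispersed = 2, n_singletons = 1)
sim  <- simulate_genome(n_chrom = 4, genes_per_chrom = 120, spec, seed = 42)

thr    <- calibrate_homolog_threshold(sim$proteins, seed = 42)
pairs  <- find_homolog_pairs(sim$proteins, top_k = 5, score_threshold = thr)
blocks <- detect_collinear_chains(
  rbind(pairs[, c("a", "b")], sim$truth$background_pairs), sim$genes)
calls  <- classify_duplications(sim$genes, pairs, blocks,
                                gene_ids = sim$proteins$id)
table(calls$mode)
#>     dispersed     singleton        tandem wgd_segmental
#>             2             1             5            10

arrays <- group_tandem_arrays(calls, pairs, sim$genes)
arrays$summary
#> $n_arrays   [1] 2
#> $mean_size  [1] 2.5
tandem_related_fraction(calls)
#> [1] 27.78
```

All 18 planted modes are recovered (the truth table is in
`sim$truth$modes`): the two planted arrays of 3 and 2 genes come back as 2
arrays of mean size 2.5, the 5 × 2 block anchors as WGD/segmental calls, and
the unrelated singleton stays below the null-calibrated score threshold.
With the published counts as input, `tandem_related_fraction(581, 881)`
prints `65.95` — the tandem-related percentage of all analysed plant GLRs.

Selection estimates recover their generating parameters (from
`analysis/06_selection_analysis.R`, 500-codon pairs, κ = 2, t = 0.5):

```
true 0.10 -> NG86 0.083, M0 0.097 (kappa 1.92, t 0.486)
true 0.30 -> NG86 0.249, M0 0.303 (kappa 2.34, t 0.517)
true 1.00 -> NG86 0.833, M0 1.003 (kappa 1.83, t 0.513)
```

M0 is close to unbiased; NG86 shows its well-known downward bias under
transition-biased evolution.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end, writing tables
under `results/`:

```sh
Rscript analysis/01_simulate_genome.R         # genome + sequences + truth
Rscript analysis/02_family_identification.R   # pseudogenes, domains, losses
Rscript analysis/03_duplication_classification.R
Rscript analysis/04_expansion_series.R
Rscript analysis/05_conservation_profile.R
Rscript analysis/06_selection_analysis.R
Rscript analysis/07_phylogeny_classification.R
Rscript analysis/08_expression_clusters.R
```

`run_pipeline()` runs the same stages from one YAML config (see
`inst/extdata/demo_config.yaml`) with byte-identical reruns for a fixed
seed.

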