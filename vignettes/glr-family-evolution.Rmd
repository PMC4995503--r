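---
title: "Methods: gene-family expansion, selection and expression analysis for plant GLRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family expansion, selection and expression analysis for plant GLRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`glrevo` re-implements, as a tested pipeline, the comparative-genomics
workflow used to study the expansion of the plant glutamate-like receptor
(GLR) family: pseudogene filtering, domain-architecture calls, duplication
mode classification, expansion and orthology series, conservation profiling,
dN/dS estimation, marker-anchored subfamily classification, and expression
clustering. Every stage runs against synthetic genomes with planted ground
truth, so the whole chain is verifiable without downloading any genome.

This document describes the models, the tunable parameters and their
defaults, the design of the synthetic-data generators, and the numerical
choices — the information a maintainer needs to trust or change the code.

## Pseudogene filtering

A CDS is called a pseudogene when it is structurally incapable of encoding a
full-length family protein. Verdicts are checked in a fixed order, first hit
wins:

1. `frameshift` — length not a multiple of 3;
2. `premature_stop` — an in-frame stop before the final codon;
3. `short_fragment` — translated length below a fraction (default 0.5) of a
   family reference length (default: the median translated length of the
   input set).

The precedence puts structural defects ahead of length defects; any order is
defensible, this one is fixed and documented. The short-fragment fraction is
a calibration choice: no published cut-off exists for this filter, only the
categories themselves.

## Domain detection by PSSM scan

Domain presence is a binary gate in this workflow, so profile HMM searches
are replaced by ungapped position-specific scoring matrix (PSSM) scans. A
PSSM is built from a seed alignment with additive pseudocounts,

p(j, a) = (count(j, a) + c * q(a)) / (n + c),

scored as log-odds against the background q (uniform 1/20 by default,
pseudocount mass c = 1). A scan reports the best-scoring ungapped window;
presence means the score reaches a threshold calibrated as the 99th
percentile of scores on residue-shuffled sequences. Shuffling destroys motif
structure while preserving composition, which is exactly the null the scan
must reject. Domain-loss rates are then simple fractions: the loss rate of a
domain is the share of genes lacking it; a subfamily's share of loss events
is its fraction of all losses.

## Homolog pairs and the score threshold

Candidate homolog pairs come from all-vs-all Smith–Waterman local alignment
(BLOSUM62, affine gaps open 10 / extend 1), keeping for each query its five
best hits — ties at the fifth score are kept, as search tools report them —
above a score threshold, then taking the symmetric closure. The threshold
stands in for an E-value cut-off: local-alignment score maxima follow an
extreme-value (Gumbel) law, so the null distribution is estimated from
shuffled-sequence alignments, a Gumbel is fitted by the method of moments,
and the 99.999th-percentile quantile is extrapolated from it. A plain
empirical quantile of a small null sample would sit far too low and admit
chance similarities between unrelated proteins.

## Collinear chains and duplication modes

Synteny blocks are detected MCScanX-style: anchors (homolog pairs) grouped by
chromosome pair are chained by dynamic programming, where an anchor extends a
previous one when both rank increments lie in (0, 25]; for inverted chains
the second side must strictly decrease. Chains with at least 5 anchors are
reported greedily by score (anchor count), each anchor used at most once,
score ties broken by the first anchor id. Same-chromosome anchors closer
than the tandem gap are excluded from chaining: tandem copies are not
collinearity evidence, and without this exclusion a large tandem array chains
with itself into a spurious "block".

Duplication modes follow fixed-priority rules:

* no homolog pair → `singleton`;
* anchor of any block → `wgd_segmental`;
* same-chromosome partner with fewer than 10 intervening genes → `tandem`;
* otherwise → `dispersed`.

"Fewer than 10 intervening genes" is the strict reading of the
neighbouring-genes rule (the MCScanX convention); the off-by-one alternative
(rank difference below 10) is exposed as `tandem_rule = "rank_diff"`. No
separate "proximal" category exists; such cases fold into `dispersed`.
Tandem arrays are the connected components of the tandem-adjacency relation
restricted to tandem-called genes, ordered by rank; their member counts sum
to the number of tandem calls by construction.

## Expansion and orthology series

Each family gene selects a nearest duplicate lexicographically: highest
percent identity, then most shared flanking block-anchor genes (non-family
genes anchoring a block that contains both genes), then lowest Ks (NG86 dS;
undefined Ks counts as +Inf and is flagged), final ties by partner id. The
order of the criteria follows their order of importance in the workflow and
is fixed; a config override exists. The edge graph is then linearized: nodes
of degree above 2 keep their two best incident edges under the same
criteria, cycles break at their worst edge, and the remaining simple paths
are the expansion series. Isolated genes are length-1 series. Degree capping
is an artifact decision forced by the requirement that series be linear; it
reuses the selection criteria for consistency.

Orthology series are connected components of cross-species block-anchor
pairs restricted to family genes; components spanning at least two species
are reported in species order, and a component touching every species marks
its members as ancestral anchors.

## Conservation profiling

Each alignment column gets an integer 0–10: the number of Livingstone–Barton
physico-chemical property classes (hydrophobic, polar, small, tiny,
aliphatic, aromatic, positive, negative, charged, proline) on which all rows
agree, counting both all-members and all-non-members agreement. Gaps and X
belong to no class, so a gap breaks agreement on every property the other
residues share while preserving agreement on the properties they all lack.
The index is capped at 10 — no identity bonus level — so it reads literally
as "number of conserved properties". Profiles are summarized by sliding
windows of 20 columns advancing by 10; a final window shorter than 20 is
reported but flagged truncated and excluded from region means by default.
Group identity (for example between intron sequences of two subfamilies) is
available as mean pairwise identity or consensus-vs-consensus identity, and
the denominator — columns where both rows are ungapped (default) or all
covered columns — is an explicit option because published identity values
rarely state their convention.

## Intron projection

An intron after CDS nucleotide n maps to protein residue floor(n/3) + 1 with
phase n mod 3, then through the gapped row to an alignment column. A
column/phase combination is conserved when at least a fraction (default 1.0)
of genes carry a mark there.

## dN/dS estimation

Two estimators are implemented:

**NG86 counting.** Synonymous site counts use the equal-weight
mutation-fraction rule per codon (changes to stop codons count as
nonsynonymous so S + N = 3 exactly), averaged over the two sequences.
Differences are averaged over all minimal substitution pathways between each
codon pair, excluding pathways that pass through a stop codon; if every
pathway does (a rare 3-difference case), all pathways are used and the
estimate is flagged. Proportions are Jukes–Cantor corrected,
d = −(3/4) ln(1 − 4p/3); p ≥ 3/4 is reported `saturated`, dS = 0 as
`undefined_dS`.

**GY94/M0 maximum likelihood.** The one-ratio codon model over the 61 sense
codons (universal code): instantaneous rates are zero for multi-nucleotide
changes and proportional to the target codon frequency, times kappa for
transitions and omega for nonsynonymous changes; the matrix is normalized to
one expected substitution per codon per unit time. The pairwise likelihood
is maximized over (omega, kappa, t) by bounded quasi-Newton (L-BFGS-B on log
parameters) from three fixed starting points — (0.2, 2, 0.3), (1, 1, 1),
(3, 5, 0.1) — to guard against local optima. Transition probabilities come
from the symmetric eigendecomposition available for reversible models, which
makes each likelihood evaluation a single 61×61 spectral reconstruction;
the decomposition is cached per (kappa, omega) so line searches in t are
cheap. Codon frequencies default to F3x4 estimated from the data; uniform
frequencies exist for oracle tests. dN and dS are decomposed from t via the
model's synonymous and nonsynonymous rate flows with site proportions taken
at omega = 1, which makes dN/dS equal the fitted omega.

Group comparisons use medians over `ok`-status estimates and two-sided
Wilcoxon rank-sum tests; groups with fewer than two usable estimates are
reported untestable.

Only pairwise M0 is implemented: every statistic the pipeline reports
(per-pair omega, group medians) is pairwise, and the optimizer stays
3-dimensional. Ks values feeding the expansion series come from NG86 dS
(closed form, fast); M0 is reserved for the selection report.

## Trees and marker classification

Protein distances are p-distances over columns where both rows are ungapped,
optionally Kimura-corrected (−ln(1 − p − p²/5); undefined values are
flagged). Trees are built by neighbor joining; negative branch lengths are
clamped to zero with the deficit moved to the sibling edge so downstream
consumers see a valid tree. Bootstrap supports resample columns with
replacement and report the percentage of replicates containing each original
internal bipartition. Maximum-likelihood tree inference is deliberately not
reproduced: the classification claims are tested against planted truth, not
against published tree figures, and NJ with bootstrap is sufficient for
that purpose. This is the package's largest methodological substitution.

Marker-anchored classification roots the tree at the marker labelled GLR0
when present — the family's original group — and, for each query, finds the
smallest clade containing the query and at least one marker. A single marker
label assigns the query with that clade's bootstrap support; mixed labels
fall back to the nearest marker by patristic distance over the whole marker
set (ties by id), recorded as `method = "nearest"` so downstream users can
see which rule fired. The clade-then-nearest rule is an artifact decision:
published marker classifications rarely state one.

The sister-clade test calls two groups `sister` when each group and their
union are monophyletic, `nested` when only the union is, and `neither`
otherwise.

## Expression analysis

Cq values convert to relative expression per sample and replicate as
E^(−ΔCq) with ΔCq = Cq(gene) − mean Cq(reference genes) and efficiency E =
2.0 by default (a per-gene efficiency vector is accepted); replicates
average after the transformation, since averaging cycle values before
exponentiation would bias the result. Genes undetected in a sample get
relative 0 and a flag; genes undetected everywhere are dropped and listed.
Matrices are log2-transformed with a pseudocount (default 1e-4 of the
smallest positive entry, only when zeros exist) and row-standardized with
the population standard deviation; constant rows become all-zero and are
flagged. K-means uses k-means++ seeding with 10 restarts and Lloyd
refinement, best run by inertia, deterministic given the seed. The number of
clusters k is always explicit — published cluster counts for this kind of
data are inconsistent enough that no default deserves to be privileged — and
is recorded in the run report. Tissue preference is the argmax of
per-tissue mean standardized expression, with ties listing every argmax
tissue (so per-group preference fractions can exceed 1 in sum when ties
exist).

## The synthetic-data generators

The generators define the study conditions; they are first-class, tested
code.

`simulate_genome()` builds multi-chromosome genomes of background genes
(coordinates only — duplication logic needs coordinates, not sequence) and
plants one gene family: tandem arrays as runs with fewer than 10 intervening
background genes (gaps drawn from 0–3), collinear blocks as two chromosome
intervals holding anchor pairs in conserved order with paired background
genes between anchors, dispersed copies, and unrelated singletons. All
family members except singletons descend from one ancestral protein (150
residues by default); tandem arrays are chains of successive copies with
decaying identity (about 2% divergence per step), so nearest-duplicate
series can recover the planted order. Planted features are separated by 30
background genes — beyond both the tandem rule (10) and the default
collinearity rank gap (25) — so distinct features never abut into a single
chain or tandem run; errors at feature boundaries are exactly the failure
mode this layout excludes, and genomes violating it would need the
boundary-case logging the classifier provides. CDS are uniform-synonymous
reverse translations with a terminal stop.

`evolve_codon_sequences()` draws an ancestral codon sequence from the
stationary distribution and evolves a partner under the same GY94/M0
transition probabilities the estimator fits — substitutions only, no indels.
`simulate_msa()` plants fully conserved column intervals in otherwise
independent background columns whose entropy is set by the residue pool
size. `simulate_gene_structures()` plants shared intron slots (same column
and phase in every row) plus row-private noise introns.
`simulate_expression()` draws replicate-level Gaussian noise around
per-cluster tissue profiles on the log2 scale.

Every generator is a pure function of (spec, seed); one global seed fans out
to per-generator substreams by a stable hash of the generator name, so
adding a generator never perturbs another's stream.

What the generators do **not** emulate — and therefore what passing tests do
not show about real data: insertions and deletions in coding sequence,
alignment error (alignments are inputs or exact by construction), rate
variation among sites and lineages, gene conversion between tandem copies,
fractionation after whole-genome duplication, and realistic intergenic
content. Recovery rates on this synthetic substrate are upper bounds on
real-data performance.

## Problem sizes and determinism

The bundled analyses run at deliberately small scale — genomes of a few
hundred genes with family sizes around 20, codon pairs of 500 codons, 20
seeds per property — chosen so the full suite and the demonstration pipeline
each complete in minutes on one core while still giving the estimators
enough signal for their stated tolerances (for example, the M0 omega
recovery band of ±20% at 500 codons). The omega-recovery grid runs at
kappa = 1 so both estimators face data matching the counting estimator's
equal-rate assumption; the transition-biased regime (kappa = 2) is asserted
separately against a wider pilot band. The end-to-end pipeline writes all
outputs with fixed formatting and derives every random stream from the
config seed, so identical configs produce byte-identical output files; the
run report carries an MD5 hash of the canonical config serialization.

## Known limitations

* Domain calls are ungapped PSSM scans, not profile HMMs; heavily diverged
  or indel-riddled domains would be missed where HMMs might not.
* The chain detector scores chains by anchor count, not by summed anchor
  quality, and resolves ties lexicographically; dense homology graphs (every
  family member matching every other) can in principle produce boundary-case
  blocks, which is why the generators keep planted features separated.
* Pairwise M0 cannot express branch- or site-specific selection; omega is a
  single genome-pair average.
* NJ trees are distance-based; very short internal edges may be unresolved
  where ML inference would resolve them, which the bootstrap supports make
  visible.
* The Cq model assumes one shared efficiency unless per-gene efficiencies
  are supplied, and reference genes are taken as given rather than validated.
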