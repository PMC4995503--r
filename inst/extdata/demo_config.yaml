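# Demo pipeline configuration: a small synthetic genome exercising every
# stage. Parameters mirror the package defaults except for scaled-down
# bootstrap replicates.
seed: 42
n_chrom: 4
genes_per_chrom: 120
n_tandem_arrays: 2
array_sizes: [3, 2]
n_segmental_blocks: 1
block_gene_count: 5
n_dispersed: 2
n_singletons: 1
tandem_gap: 10
min_block_pairs: 5
max_rank_gap: 25
top_k: 5
window: 20
slide: 10
bootstrap_reps: 20
k_clusters: 3
n_expr_genes: 18
tissues: [leaf, stem, root]
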