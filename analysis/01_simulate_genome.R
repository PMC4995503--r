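#!/usr/bin/env Rscript
# Simulate the study genome: four chromosomes carrying one GLR-like gene
# family expanded by planted tandem arrays, one collinear (WGD/segmental)
# block, dispersed copies and an unrelated singleton. Writes the coordinate
# and sequence substrate used by every later step.

suppressPackageStartupMessages(library(glrevo))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

spec <- family_spec(n_tandem_arrays = 2, array_sizes = c(3, 2),
                    n_segmental_blocks = 1, block_gene_count = 5,
                    n_dispersed = 2, n_singletons = 1)
sim <- simulate_genome(n_chrom = 4, genes_per_chrom = 120, spec, seed = 42)

write_gene_positions(sim$genes, "results/data/genes.bed")
write_fasta(sim$proteins, "results/data/family_proteins.fasta")
write_fasta(sim$cds, "results/data/family_cds.fasta")
write.table(sim$truth$modes, "results/data/truth_modes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$truth$background_pairs, "results/data/background_pairs.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Simulated %d genes on %d chromosomes; %d family members:\n",
            nrow(sim$genes), length(unique(sim$genes$chromosome)),
            nrow(sim$proteins)))
print(table(sim$truth$modes$mode))
cat("Data written under results/data/\n")
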