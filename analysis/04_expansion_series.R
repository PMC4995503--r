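#!/usr/bin/env Rscript
# Nearest-duplicate edges (identity, shared flanking block anchors, Ks) and
# linear expansion-series assembly; cross-species orthology series on a
# second simulated genome.

suppressPackageStartupMessages(library(glrevo))
dir.create("results", showWarnings = FALSE)

genes <- read_gene_positions("results/data/genes.bed", "bed")
prot <- read_fasta("results/data/family_proteins.fasta")
cds <- read_fasta("results/data/family_cds.fasta", kind = "cds")
pairs <- read.delim("results/homolog_pairs.tsv")
bg_pairs <- read.delim("results/data/background_pairs.tsv")
blocks <- detect_collinear_chains(rbind(pairs[, c("a", "b")], bg_pairs),
                                  genes)

seqs <- setNames(cds$residues, cds$id)
strip <- function(s) if (substr(s, nchar(s) - 2, nchar(s)) %in%
                         c("TAA", "TAG", "TGA"))
  substr(s, 1, nchar(s) - 3) else s

edges <- do.call(rbind, lapply(prot$id, function(g) {
  prs <- pairs[pairs$a == g | pairs$b == g, , drop = FALSE]
  if (nrow(prs) == 0) return(NULL)
  partner <- ifelse(prs$a == g, prs$b, prs$a)
  cand <- data.frame(
    partner = partner, identity = prs$identity,
    flanking = vapply(partner, function(p)
      shared_flanking_count(g, p, blocks, prot$id), integer(1)),
    ks = vapply(partner, function(p) {
      e <- ng86(strip(seqs[[g]]), strip(seqs[[p]]))
      if (is.na(e$dS)) NA_real_ else e$dS
    }, numeric(1)))
  nd <- nearest_duplicate(g, cand)
  data.frame(gene = g, partner = nd$partner, identity = nd$identity,
             flanking = nd$flanking, ks = nd$ks)
}))
series <- assemble_expansion_series(edges, genes = prot$id)
out <- data.frame(series_id = sprintf("series_%d", seq_along(series)),
                  length = vapply(series, length, integer(1)),
                  genes = vapply(series, paste, character(1),
                                 collapse = ","))
write.table(out, "results/expansion_series.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("%d expansion series (longest %d genes):\n", nrow(out),
            max(out$length)))
print(out)

# orthology series: anchor components across two simulated "species"
spec <- family_spec(0, integer(0), 1, 5, 0, 0)
simA <- simulate_genome(2, 120, spec, seed = 1)
fam <- data.frame(
  gene_id = simA$truth$modes$gene_id,
  species = ifelse(grepl("_a", simA$truth$modes$gene_id), "speciesA",
                   "speciesB"))
anchor_pairs <- data.frame(a = sprintf("fam_b1_a%d", 1:5),
                           b = sprintf("fam_b1_b%d", 1:5))
blk <- detect_collinear_chains(rbind(anchor_pairs,
                                     simA$truth$background_pairs),
                               simA$genes)
ortho <- build_orthology_series(fam, blk, c("speciesA", "speciesB"))
write.table(ortho, "results/orthology_series.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d orthology series, %d spanning all species (ancestral)\n",
            nrow(ortho), sum(ortho$ancestral)))
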