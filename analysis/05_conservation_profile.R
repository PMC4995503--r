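#!/usr/bin/env Rscript
# Physico-chemical conservation profiling with a 20-column window sliding by
# 10; region means over a planted conserved interval; intron projection and
# conserved-intron detection.

suppressPackageStartupMessages(library(glrevo))
dir.create("results", showWarnings = FALSE)

# protein MSA with one planted conserved region (a pore-like core)
msa <- simulate_msa(10, 120, conserved_intervals = list(c(51, 70)),
                    background_entropy = 12, seed = 5)
prof <- conservation_profile(msa$rows)
w <- sliding_window_profile(prof, window = 20, slide = 10)
write.table(w, "results/window_means.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("Mean index in conserved region [51,70]: %.2f\n",
            region_mean(prof, c(51, 70))))
cat(sprintf("Mean index outside it: %.2f\n",
            mean(prof[c(1:50, 71:120)])))
cat("Window means (start, mean):\n")
print(w[, c("start", "end", "mean")])

# group identity between two halves of the alignment
ga <- names(msa$rows)[1:5]; gb <- names(msa$rows)[6:10]
cat(sprintf("Cross-group identity (mean pairwise): %.2f%%\n",
            group_identity(msa$rows, ga, gb)))
cat(sprintf("Cross-group identity (consensus): %.2f%%\n",
            group_identity(msa$rows, ga, gb, mode = "consensus")))

# intron structure: one conserved slot, a few private ones
gs <- simulate_gene_structures(msa$rows,
                               conserved_intron_slots =
                                 list(list(column = 80, phase = 0)),
                               noise_slots = 4, seed = 6)
marks <- project_introns(gs$models, msa$rows)
write.table(marks, "results/intron_marks.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cons <- conserved_intron_positions(marks, n_genes = length(msa$rows))
write.table(cons, "results/conserved_introns.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d intron marks; conserved position(s): column %s phase %s\n",
            nrow(marks), paste(cons$column, collapse = ","),
            paste(cons$phase, collapse = ",")))
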