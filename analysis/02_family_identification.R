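#!/usr/bin/env Rscript
# Candidate screening on the simulated family: ORF-integrity (pseudogene)
# filtering, PSSM domain-architecture calls on proteins with planted domain
# losses, and the domain-loss rate table.

suppressPackageStartupMessages(library(glrevo))
dir.create("results", showWarnings = FALSE)
set.seed(7)

cds <- read_fasta("results/data/family_cds.fasta", kind = "cds")

# plant defects into three extra candidates so the filter has work to do
codons <- function(s) substring(s, seq(1, nchar(s) - 2, 3),
                                seq(3, nchar(s), 3))
good <- cds$residues[1]
cd <- codons(good)
defective <- data.frame(
  id = c("cand_stop", "cand_frameshift", "cand_fragment"), kind = "cds",
  residues = c(paste(c(cd[1:20], "TAA", cd[22:length(cd)]), collapse = ""),
               substr(good, 1, nchar(good) - 1),
               paste(cd[1:40], collapse = "")))
candidates <- rbind(cds, defective)

calls <- call_pseudogenes(candidates)
write.table(calls, "results/pseudogene_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
acc <- pseudogene_accounting(nrow(calls), calls)
cat(sprintf("%d candidates, %d pseudogene calls, %d complete genes kept\n",
            acc$candidates, acc$pseudogenes, acc$retained))

# domain architecture: PSSMs seeded from noisy copies of 7 domain motifs,
# threshold calibrated on a shuffled null (99th percentile)
motifs <- setNames(lapply(GLR_DOMAINS, function(d)
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), 10, TRUE), collapse = "")),
  GLR_DOMAINS)
pssms <- lapply(motifs, function(m)
  build_pssm(setNames(rep(m, 4), paste0("s", 1:4)), pseudocount = 0.5))

# proteins: full architecture for most, ATD dropped for two (planted loss)
mk_protein <- function(drop = character(0))
  paste(unlist(motifs[setdiff(GLR_DOMAINS, drop)]), collapse = "GSGS")
prots <- c(setNames(replicate(8, mk_protein()), sprintf("g%d", 1:8)),
           setNames(replicate(2, mk_protein("ATD")), sprintf("g%d", 9:10)))

# thresholds from the shuffled-protein null (99th percentile): shuffling the
# analysed proteins destroys the planted motifs but keeps composition
for (d in names(pssms))
  pssms[[d]]$threshold <- calibrate_pssm_threshold(pssms[[d]], prots,
                                                   n_shuffles = 10, seed = 3)
arch <- lapply(prots, call_domain_architecture, pssms = pssms)
subf <- setNames(c(rep("GLR3", 5), rep("GLR1&2", 5)), names(prots))
loss <- domain_loss_rates(arch, subf)
write.table(loss$per_domain, "results/domain_loss_rates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Domain loss rates:\n")
print(loss$per_domain)
cat("Loss-event shares by subfamily:\n")
print(loss$per_subfamily)
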