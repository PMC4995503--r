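# Synthetic-genome and data generators with planted ground truth. Every
# generator is a pure function of (spec, seed); a global seed fans out to
# per-generator substreams via a stable hash of the generator name.

.stable_hash <- function(name) {
  v <- utf8ToInt(name)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 1000003
  as.integer(h)
}

.substream_seed <- function(seed, name) {
  as.integer((as.numeric(seed) * 7919 + .stable_hash(name)) %% .Machine$integer.max)
}

AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.random_protein <- function(len) paste(sample(AMINO_ACIDS, len, TRUE),
                                       collapse = "")

# Substitute a fraction of residues with random different residues.
.mutate_protein <- function(seq, rate) {
  v <- strsplit(seq, "")[[1]]
  k <- max(0L, round(rate * length(v)))
  if (k > 0) {
    pos <- sample(length(v), k)
    for (p in pos) v[p] <- sample(setdiff(AMINO_ACIDS, v[p]), 1)
  }
  paste(v, collapse = "")
}

# Reverse-translate: uniform choice among synonymous sense codons.
.reverse_translate <- function(protein) {
  gc <- genetic_code()
  by_aa <- split(names(gc), gc)
  v <- strsplit(protein, "")[[1]]
  paste(vapply(v, function(a) sample(by_aa[[a]], 1), character(1)),
        collapse = "")
}

#' Family specification for genome simulation
#'
#' Describes how many planted tandem arrays, collinear (WGD/segmental)
#' blocks, dispersed copies and unrelated singletons the simulated genome
#' carries.
#'
#' @param n_tandem_arrays Number of tandem arrays.
#' @param array_sizes Integer vector of array sizes (each >= 2), recycled to
#'   `n_tandem_arrays`.
#' @param n_segmental_blocks Number of collinear blocks.
#' @param block_gene_count Family anchor pairs per block (>= 5).
#' @param n_dispersed Number of dispersed family copies.
#' @param n_singletons Number of unrelated singleton genes.
#' @param max_intergenic_gap Maximum background genes between consecutive
#'   tandem-array members (must stay below the tandem rule's 10).
#' @return A `family_spec` list.
#' @export
family_spec <- function(n_tandem_arrays = 2, array_sizes = c(3, 2),
                        n_segmental_blocks = 1, block_gene_count = 5,
                        n_dispersed = 2, n_singletons = 1,
                        max_intergenic_gap = 3) {
  stopifnot(n_tandem_arrays >= 0, n_segmental_blocks >= 0, n_dispersed >= 0,
            n_singletons >= 0, max_intergenic_gap >= 0,
            max_intergenic_gap < 10)
  if (n_tandem_arrays > 0) {
    array_sizes <- rep_len(array_sizes, n_tandem_arrays)
    stopifnot(all(array_sizes >= 2))
  } else array_sizes <- integer(0)
  if (n_segmental_blocks > 0) stopifnot(block_gene_count >= 5)
  structure(list(n_tandem_arrays = n_tandem_arrays,
                 array_sizes = array_sizes,
                 n_segmental_blocks = n_segmental_blocks,
                 block_gene_count = block_gene_count,
                 n_dispersed = n_dispersed, n_singletons = n_singletons,
                 max_intergenic_gap = max_intergenic_gap),
            class = "family_spec")
}

#' Simulate a multi-chromosome genome with a planted gene family
#'
#' Background genes carry coordinates only; family genes also carry protein
#' and CDS sequences derived from a common ancestor (tandem arrays as chains
#' of successive copies with decaying identity). Collinear blocks are two
#' chromosome intervals holding family anchor pairs in conserved order, with
#' paired background genes between anchors. Dispersed copies and singletons
#' are placed at least 10 genes away from any other family member.
#'
#' @param n_chrom Number of chromosomes.
#' @param genes_per_chrom Background genes per chromosome.
#' @param spec A [family_spec()].
#' @param seed Integer seed.
#' @param protein_length Ancestral protein length (residues).
#' @return List with `genes` (a `gene_set`), `proteins` and `cds` (sequence
#'   record data.frames), and `truth` (list: `modes` data.frame with
#'   gene_id/mode/array_id/block_id, `background_pairs` data.frame).
#' @export
simulate_genome <- function(n_chrom, genes_per_chrom, spec, seed,
                            protein_length = 150) {
  stopifnot(inherits(spec, "family_spec"), n_chrom >= 1)
  set.seed(.substream_seed(seed, "simulate_genome"))
  # background genes between planted features: beyond the tandem rule (10)
  # and beyond the default collinearity rank gap (25), so separate features
  # never abut into one chain or tandem run
  sep <- 30L

  # features to place: list of (ids, internal gap vector, kind)
  feats <- list()
  fam <- data.frame(gene_id = character(0), mode = character(0),
                    array_id = character(0), block_id = character(0),
                    stringsAsFactors = FALSE)
  ancestor <- .random_protein(protein_length)
  prot <- character(0)

  for (k in seq_len(spec$n_tandem_arrays)) {
    s <- spec$array_sizes[k]
    ids <- sprintf("fam_t%d_%d", k, seq_len(s))
    gaps <- sample(0:spec$max_intergenic_gap, s - 1, TRUE)
    feats[[length(feats) + 1]] <- list(ids = ids, gaps = gaps,
                                       kind = "tandem")
    fam <- rbind(fam, data.frame(gene_id = ids, mode = "tandem",
                                 array_id = sprintf("array_%d", k),
                                 block_id = "."))
    p <- .mutate_protein(ancestor, 0.03)
    for (i in seq_len(s)) {
      prot[ids[i]] <- p
      p <- .mutate_protein(p, 0.02)
    }
  }

  bg_pairs <- data.frame(a = character(0), b = character(0))
  for (b in seq_len(spec$n_segmental_blocks)) {
    m <- spec$block_gene_count
    ids_a <- sprintf("fam_b%d_a%d", b, seq_len(m))
    ids_b <- sprintf("fam_b%d_b%d", b, seq_len(m))
    bga <- sprintf("bgb_%d_a%d", b, seq_len(m - 1))
    bgb <- sprintf("bgb_%d_b%d", b, seq_len(m - 1))
    # interleave anchors with one paired background gene between them
    ia <- character(0); ib <- character(0)
    for (i in seq_len(m)) {
      ia <- c(ia, ids_a[i]); ib <- c(ib, ids_b[i])
      if (i < m) { ia <- c(ia, bga[i]); ib <- c(ib, bgb[i]) }
    }
    feats[[length(feats) + 1]] <- list(ids = ia, gaps = rep(0L, length(ia) - 1),
                                       kind = "block_half")
    feats[[length(feats) + 1]] <- list(ids = ib, gaps = rep(0L, length(ib) - 1),
                                       kind = "block_half")
    fam <- rbind(fam,
                 data.frame(gene_id = c(ids_a, ids_b), mode = "wgd_segmental",
                            array_id = ".",
                            block_id = sprintf("block_%d", b)))
    bg_pairs <- rbind(bg_pairs, data.frame(a = bga, b = bgb))
    for (i in seq_len(m)) {
      founder <- .mutate_protein(ancestor, 0.04)
      prot[ids_a[i]] <- .mutate_protein(founder, 0.02)
      prot[ids_b[i]] <- .mutate_protein(founder, 0.02)
    }
  }

  for (d in seq_len(spec$n_dispersed)) {
    id <- sprintf("fam_d%d", d)
    feats[[length(feats) + 1]] <- list(ids = id, gaps = integer(0),
                                       kind = "dispersed")
    fam <- rbind(fam, data.frame(gene_id = id, mode = "dispersed",
                                 array_id = ".", block_id = "."))
    prot[id] <- .mutate_protein(ancestor, 0.06)
  }
  for (s in seq_len(spec$n_singletons)) {
    id <- sprintf("fam_s%d", s)
    feats[[length(feats) + 1]] <- list(ids = id, gaps = integer(0),
                                       kind = "singleton")
    fam <- rbind(fam, data.frame(gene_id = id, mode = "singleton",
                                 array_id = ".", block_id = "."))
    prot[id] <- .random_protein(protein_length)
  }

  # round-robin assignment, block halves forced onto distinct chromosomes
  chrom_feats <- vector("list", n_chrom)
  cc <- 0L
  for (f in feats) {
    cc <- cc + 1L
    target <- ((cc - 1L) %% n_chrom) + 1L
    chrom_feats[[target]] <- c(chrom_feats[[target]], list(f))
  }

  # capacity check and layout
  rows <- list()
  bg_i <- 0L
  for (c in seq_len(n_chrom)) {
    chrom <- sprintf("chr%d", c)
    need <- sum(vapply(chrom_feats[[c]], function(f)
      sum(f$gaps), integer(1))) + sep * (length(chrom_feats[[c]]) + 1L)
    if (need > genes_per_chrom)
      stop("infeasible family_spec: chromosome ", chrom, " needs ", need,
           " background genes but has ", genes_per_chrom)
    order_ids <- character(0)
    take_bg <- function(n) {
      ids <- sprintf("bg_%d", bg_i + seq_len(n))
      bg_i <<- bg_i + n
      ids
    }
    remaining <- genes_per_chrom - need
    for (f in chrom_feats[[c]]) {
      order_ids <- c(order_ids, take_bg(sep))
      for (i in seq_along(f$ids)) {
        order_ids <- c(order_ids, f$ids[i])
        if (i <= length(f$gaps) && f$gaps[i] > 0)
          order_ids <- c(order_ids, take_bg(f$gaps[i]))
      }
    }
    order_ids <- c(order_ids, take_bg(sep + remaining))
    start <- seq_along(order_ids) * 2000L + 1L
    rows[[c]] <- data.frame(id = order_ids, chromosome = chrom,
                            start = start, end = start + 999L,
                            strand = sample(c("+", "-"), length(order_ids),
                                            TRUE),
                            stringsAsFactors = FALSE)
  }
  genes <- gene_set(do.call(rbind, rows), species = "synthetica")

  proteins <- data.frame(id = names(prot), kind = "protein",
                         residues = unname(prot), stringsAsFactors = FALSE)
  cds <- data.frame(id = names(prot), kind = "cds",
                    residues = vapply(prot, function(p)
                      paste0(.reverse_translate(p), "TAA"), character(1)),
                    stringsAsFactors = FALSE)
  list(genes = genes, proteins = proteins, cds = cds,
       truth = list(modes = fam, background_pairs = bg_pairs))
}

#' Evolve a pair of codon sequences under GY94/M0
#'
#' The first row is drawn from the stationary distribution; the second from
#' the transition probabilities at divergence `t` (expected substitutions
#' per codon), obtained by matrix exponential of the normalized rate matrix.
#' Substitutions only; no indels.
#'
#' @param length_codons Number of codons.
#' @param omega dN/dS ratio (> 0, or 0 to forbid nonsynonymous change).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param t Divergence in expected substitutions per codon (>= 0).
#' @param codon_freq `"uniform"` or a numeric vector of 61 frequencies.
#' @param seed Integer seed.
#' @return List with `rows` (named character vector of two codon sequences)
#'   and `truth` (omega, kappa, t).
#' @export
evolve_codon_sequences <- function(length_codons, omega, kappa, t,
                                   codon_freq = "uniform", seed = 1) {
  stopifnot(length_codons >= 1, omega >= 0, kappa > 0, t >= 0)
  set.seed(.substream_seed(seed, "evolve_codon_sequences"))
  pi <- if (identical(codon_freq, "uniform")) rep(1 / 61, 61)
        else .check_pi(codon_freq)
  cod <- sense_codons()
  anc <- sample.int(61, length_codons, TRUE, prob = pi)
  if (t == 0) {
    der <- anc
  } else {
    eg <- .gy94_eigen(kappa, max(omega, 1e-12), pi)
    # omega = 0 exactly: zero out nonsynonymous rates without normalization
    if (omega == 0) {
      rel <- .codon_relations()
      Q <- .gy94_Q(kappa, 1, pi)$Q
      Q[rel$one_diff & !rel$is_syn] <- 0
      diag(Q) <- 0; diag(Q) <- -rowSums(Q)
      sp <- sqrt(pi)
      B <- (Q * outer(sp, 1 / sp) + t(Q * outer(sp, 1 / sp))) / 2
      e <- eigen(B, symmetric = TRUE)
      eg <- list(U = e$vectors, lambda = e$values, sp = sp)
    }
    P <- .gy94_P(eg, t)
    der <- vapply(anc, function(i) sample.int(61, 1, prob = P[i, ]),
                  integer(1))
  }
  rows <- c(seq_a = paste(cod[anc], collapse = ""),
            seq_b = paste(cod[der], collapse = ""))
  list(rows = rows, truth = list(omega = omega, kappa = kappa, t = t))
}

#' Simulate a protein alignment with planted conserved intervals
#'
#' Columns inside `conserved_intervals` hold a single residue repeated in
#' every row; background columns are drawn independently per row from a
#' residue pool whose size sets the background entropy.
#'
#' @param n_rows Number of sequences.
#' @param length Alignment length (columns).
#' @param conserved_intervals List of `c(start, end)` column intervals.
#' @param background_entropy Number of residues in the background pool
#'   (2..20; larger = noisier background).
#' @param seed Integer seed.
#' @return List with `rows` (named character vector) and `truth`
#'   (`conserved_columns` integer vector).
#' @export
simulate_msa <- function(n_rows, length, conserved_intervals = list(),
                         background_entropy = 20, seed = 1) {
  stopifnot(n_rows >= 2, length >= 1,
            background_entropy >= 2, background_entropy <= 20)
  set.seed(.substream_seed(seed, "simulate_msa"))
  cons <- rep(FALSE, length)
  for (iv in conserved_intervals) {
    stopifnot(iv[1] >= 1, iv[2] <= length, iv[1] <= iv[2])
    cons[iv[1]:iv[2]] <- TRUE
  }
  pool <- sample(AMINO_ACIDS, background_entropy)
  m <- matrix("", n_rows, length)
  for (j in seq_len(length)) {
    if (cons[j]) m[, j] <- sample(AMINO_ACIDS, 1)
    else m[, j] <- sample(pool, n_rows, TRUE)
  }
  rows <- apply(m, 1, paste, collapse = "")
  names(rows) <- sprintf("seq_%d", seq_len(n_rows))
  list(rows = rows, truth = list(conserved_columns = which(cons)))
}

#' Simulate gene models with planted intron positions
#'
#' Conserved intron slots appear at the same alignment column and phase in
#' every gene; noise slots are private to one random gene each.
#'
#' @param alignment Named character vector: gapped protein rows.
#' @param conserved_intron_slots List of `list(column =, phase =)`.
#' @param noise_slots Number of row-private random introns.
#' @param seed Integer seed.
#' @return List with `models` (data.frame gene_id, cds_offset: nucleotide
#'   position after which the intron falls) and `truth` (the conserved
#'   slots).
#' @export
simulate_gene_structures <- function(alignment, conserved_intron_slots = list(),
                                     noise_slots = 0, seed = 1) {
  set.seed(.substream_seed(seed, "simulate_gene_structures"))
  ids <- names(alignment)
  models <- data.frame(gene_id = character(0), cds_offset = integer(0))
  col_to_residue <- function(row, column) {
    # residue index of an alignment column in the ungapped row (NA on gap)
    chars <- strsplit(row, "")[[1]]
    if (chars[column] == "-") return(NA_integer_)
    sum(chars[seq_len(column)] != "-")
  }
  for (slot in conserved_intron_slots) {
    for (id in ids) {
      res <- col_to_residue(alignment[[id]], slot$column)
      if (is.na(res)) next
      off <- 3L * (res - 1L) + slot$phase
      models <- rbind(models, data.frame(gene_id = id, cds_offset = off))
    }
  }
  if (noise_slots > 0) {
    for (k in seq_len(noise_slots)) {
      id <- sample(ids, 1)
      len <- sum(strsplit(alignment[[id]], "")[[1]] != "-")
      off <- sample.int(3L * len - 1L, 1)
      models <- rbind(models, data.frame(gene_id = id, cds_offset = off))
    }
  }
  models <- unique(models)
  models <- models[order(models$gene_id, models$cds_offset), , drop = FALSE]
  rownames(models) <- NULL
  list(models = models, truth = list(conserved_slots = conserved_intron_slots))
}

#' Simulate an expression matrix with planted clusters
#'
#' Cluster means are tissue profiles on the log2 scale; replicate-level noise
#' is independent Gaussian.
#'
#' @param n_genes Number of genes, split evenly over clusters (remainder to
#'   the first clusters).
#' @param tissues Character vector of tissue names.
#' @param cluster_spec List of per-cluster `list(mean = <numeric per tissue>,
#'   sd = <noise sd>)`.
#' @param n_reps Replicates per tissue.
#' @param seed Integer seed.
#' @return List with `matrix` (genes x samples, log2 scale), `samples`
#'   (data.frame sample/tissue/replicate) and `truth` (per-gene cluster and
#'   preferred tissue).
#' @export
simulate_expression <- function(n_genes, tissues, cluster_spec, n_reps = 3,
                                seed = 1) {
  stopifnot(n_genes >= length(cluster_spec), length(tissues) >= 2)
  set.seed(.substream_seed(seed, "simulate_expression"))
  k <- length(cluster_spec)
  sizes <- rep(n_genes %/% k, k)
  if (n_genes %% k) sizes[seq_len(n_genes %% k)] <- sizes[seq_len(n_genes %% k)] + 1L
  gene_cluster <- rep(seq_len(k), sizes)
  samples <- expand.grid(replicate = seq_len(n_reps), tissue = tissues,
                         stringsAsFactors = FALSE)[, 2:1]
  samples$sample <- sprintf("%s_r%d", samples$tissue, samples$replicate)
  m <- matrix(0, n_genes, nrow(samples),
              dimnames = list(sprintf("gene_%d", seq_len(n_genes)),
                              samples$sample))
  for (g in seq_len(n_genes)) {
    cs <- cluster_spec[[gene_cluster[g]]]
    stopifnot(length(cs$mean) == length(tissues))
    mu <- cs$mean[match(samples$tissue, tissues)]
    m[g, ] <- mu + stats::rnorm(nrow(samples), 0, cs$sd)
  }
  pref <- vapply(seq_len(n_genes), function(g)
    tissues[which.max(cluster_spec[[gene_cluster[g]]]$mean)], character(1))
  list(matrix = m, samples = samples,
       truth = data.frame(gene_id = rownames(m), cluster = gene_cluster,
                          preferred_tissue = pref))
}
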