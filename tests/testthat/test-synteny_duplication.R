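# Homolog pairs, collinear chains, duplication classification and arrays.

make_geneset <- function(chrom_sizes, ids = NULL) {
  rows <- do.call(rbind, lapply(seq_along(chrom_sizes), function(c) {
    n <- chrom_sizes[c]
    data.frame(id = sprintf("c%dg%d", c, seq_len(n)),
               chromosome = sprintf("chr%d", c),
               start = seq_len(n) * 1000, end = seq_len(n) * 1000 + 500,
               strand = "+")
  }))
  if (!is.null(ids)) rows$id <- ids
  gene_set(rows)
}

test_that("identical proteins all pair; top_k caps then closure restores", {
  prot <- data.frame(id = c("a", "b", "c"), kind = "protein",
                     residues = rep(strrep("MKVLWQERT", 6), 3))
  pairs <- find_homolog_pairs(prot, score_threshold = 10)
  expect_equal(nrow(pairs), 3)

  # 7 identical proteins, top_k = 5: closure keeps all 21 pairs
  prot7 <- data.frame(id = letters[1:7], kind = "protein",
                      residues = rep(strrep("MKVLWQERT", 6), 7))
  pairs7 <- find_homolog_pairs(prot7, top_k = 5, score_threshold = 10)
  expect_equal(nrow(pairs7), 21)
  deg <- table(c(pairs7$a, pairs7$b))
  expect_true(all(deg >= 5))
})

test_that("unrelated background stays below a null-calibrated threshold", {
  set.seed(13)
  fam <- strrep("MKVLWQERTHHCCAD", 10)
  prot <- data.frame(
    id = c("f1", "f2", sprintf("bg%d", 1:4)), kind = "protein",
    residues = c(fam, fam, replicate(4, random_protein(150))))
  thr <- calibrate_homolog_threshold(prot, n_pairs = 40, seed = 7)
  pairs <- find_homolog_pairs(prot, score_threshold = thr)
  expect_equal(nrow(pairs), 1)
  expect_setequal(c(pairs$a, pairs$b), c("f1", "f2"))
})

test_that("chain detection finds planted, gapped and inverted blocks", {
  gs <- make_geneset(c(60, 60))
  # planted collinear block: ranks 10,12,14,16,18 on both chromosomes
  anchors <- data.frame(a = sprintf("c1g%d", c(11, 13, 15, 17, 19)),
                        b = sprintf("c2g%d", c(11, 13, 15, 17, 19)))
  blocks <- detect_collinear_chains(anchors, gs)
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$score, 5)
  expect_equal(blocks[[1]]$orientation, "same")

  # gaps of 30 background genes break the chain (max_rank_gap 25)
  wide <- data.frame(a = sprintf("c1g%d", c(1, 31) ),
                     b = sprintf("c2g%d", c(1, 31)))
  wide <- rbind(wide, data.frame(a = "c1g60", b = "c2g60"))
  expect_length(detect_collinear_chains(wide, gs, min_block_pairs = 2), 0)

  # inverted block: second side strictly decreasing
  inv <- data.frame(a = sprintf("c1g%d", c(11, 13, 15, 17, 19)),
                    b = sprintf("c2g%d", c(50, 48, 46, 44, 42)))
  binv <- detect_collinear_chains(inv, gs)
  expect_length(binv, 1)
  expect_equal(binv[[1]]$orientation, "inverted")
})

test_that("chain DP equals brute-force enumeration on small instances", {
  set.seed(23)
  for (rep in 1:12) {
    n <- sample(4:12, 1)
    r1 <- sort(sample(1:40, n))
    r2 <- sample(1:40, n)
    gs <- make_geneset(c(45, 45))
    anchors <- data.frame(a = sprintf("c1g%d", r1 + 1),
                          b = sprintf("c2g%d", r2 + 1))
    blocks <- detect_collinear_chains(anchors, gs, min_block_pairs = 2,
                                      max_rank_gap = 25)
    dp_best <- if (length(blocks) == 0) 1 else
      max(vapply(blocks, `[[`, numeric(1), "score"))
    oracle <- brute_force_best_chain(r1, r2, 25)
    if (oracle < 2) oracle_best <- 1 else oracle_best <- oracle
    expect_equal(dp_best, max(oracle_best, 1),
                 info = sprintf("rep %d", rep))
  }
})

test_that("duplication classification applies the rules in priority order", {
  gs <- make_geneset(c(30, 30))
  # two homologs on chr1 with 5 intervening genes -> both tandem
  pairs <- data.frame(a = "c1g10", b = "c1g16")
  calls <- classify_duplications(gs, pairs, list())
  expect_equal(calls$mode, c("tandem", "tandem"))

  # gene with no homolog -> singleton
  calls2 <- classify_duplications(gs, pairs, list(),
                                  gene_ids = c("c1g10", "c1g16", "c2g5"))
  expect_equal(calls2$mode[calls2$gene_id == "c2g5"], "singleton")

  # block anchor beats tandem (priority)
  blocks <- list(list(block_id = "block_1", chrom_a = "chr1",
                      chrom_b = "chr2", orientation = "same", score = 5,
                      anchors = data.frame(a = "c1g10", b = "c2g10")))
  calls3 <- classify_duplications(gs, pairs, blocks)
  expect_equal(calls3$mode[calls3$gene_id == "c1g10"], "wgd_segmental")
  expect_equal(calls3$mode[calls3$gene_id == "c1g16"], "tandem")

  # homologs on different chromosomes, no block -> dispersed
  calls4 <- classify_duplications(gs, data.frame(a = "c1g5", b = "c2g20"),
                                  list())
  expect_equal(calls4$mode, c("dispersed", "dispersed"))

  # exactly 10 intervening genes: not tandem under the strict reading,
  # tandem under the rank-difference reading minus one
  pr <- data.frame(a = "c1g1", b = "c1g12")  # ranks 0 and 11: 10 intervening
  expect_equal(classify_duplications(gs, pr, list())$mode[1], "dispersed")
  pr9 <- data.frame(a = "c1g1", b = "c1g11")  # 9 intervening
  expect_equal(classify_duplications(gs, pr9, list())$mode[1], "tandem")

  expect_error(classify_duplications(gs, data.frame(a = "nope", b = "c1g1"),
                                     list()), "unknown")
})

test_that("classification is invariant to chromosome relabeling and shifts", {
  gs <- make_geneset(c(30, 30))
  pairs <- data.frame(a = c("c1g10", "c1g5"), b = c("c1g16", "c2g20"))
  base <- classify_duplications(gs, pairs, list())

  shifted <- as.data.frame(gs)
  shifted$start <- shifted$start + 10000; shifted$end <- shifted$end + 10000
  shifted$chromosome <- sub("chr", "scaf", shifted$chromosome)
  gs2 <- gene_set(shifted[, c("id", "chromosome", "start", "end", "strand")])
  expect_equal(classify_duplications(gs2, pairs, list())$mode, base$mode)
})

test_that("tandem arrays are maximal runs with correct summaries", {
  gs <- make_geneset(c(40, 40))
  pairs <- data.frame(a = c("c1g5", "c1g7", "c2g10"),
                      b = c("c1g7", "c1g9", "c2g12"))
  calls <- classify_duplications(gs, pairs, list())
  arr <- group_tandem_arrays(calls, pairs, gs)
  expect_equal(arr$summary$n_arrays, 2)
  expect_equal(arr$summary$mean_size, 2.5)
  sizes <- vapply(arr$arrays, nrow, integer(1))
  expect_equal(sum(sizes), sum(calls$mode == "tandem"))
  # members ordered by rank
  expect_true(all(vapply(arr$arrays, function(a) !is.unsorted(a$rank),
                         logical(1))))
})

test_that("tandem-related fraction reports the printed arithmetic", {
  expect_equal(tandem_related_fraction(581, 881), 65.95)
  expect_equal(tandem_related_fraction(0, 50), 0)
  expect_equal(tandem_related_fraction(50, 50), 100)
  calls <- data.frame(mode = c("tandem", "tandem", "dispersed"))
  expect_equal(tandem_related_fraction(calls), 66.67)
})

test_that("planted duplication modes are recovered across seeded genomes", {
  confusion <- table(character(0), character(0))
  for (sd in 1:6) {
    spec <- family_spec(n_tandem_arrays = 2, array_sizes = c(3, 2),
                        n_segmental_blocks = 1, block_gene_count = 5,
                        n_dispersed = 2, n_singletons = 1)
    sim <- simulate_genome(4, 120, spec, seed = sd)
    thr <- calibrate_homolog_threshold(sim$proteins, n_pairs = 40, seed = sd)
    pairs <- find_homolog_pairs(sim$proteins, score_threshold = thr)
    blocks <- detect_collinear_chains(
      rbind(pairs[, c("a", "b")], sim$truth$background_pairs), sim$genes)
    calls <- classify_duplications(sim$genes, pairs, blocks,
                                   gene_ids = sim$proteins$id)
    tab <- merge(calls, sim$truth$modes, by = "gene_id")
    expect_gte(mean(tab$mode.x == tab$mode.y), 0.95)
  }
})
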