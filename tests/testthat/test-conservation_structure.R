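# Conservation index, sliding windows, group identity, intron projection.

test_that("column index counts agreeing property classes", {
  expect_equal(column_conservation_index("VVVV"), 10)

  # D vs E: computed straight off the property table
  tab <- property_table()
  expected_DE <- sum(tab[, "D"] == tab[, "E"])
  expect_equal(column_conservation_index("DE"), expected_DE)

  # V vs gap: agreement only on properties V lacks
  expected_Vgap <- sum(!tab[, "V"])
  expect_equal(column_conservation_index("V-"), expected_Vgap)
  expect_equal(column_conservation_index("V-"), 10 - sum(tab[, "V"]))

  # X behaves like a gap (member of no class)
  expect_equal(column_conservation_index("VX"),
               column_conservation_index("V-"))

  # random columns: brute-force oracle over the table
  set.seed(51)
  for (i in 1:20) {
    col <- sample(colnames(tab), sample(2:6, 1), replace = TRUE)
    oracle <- sum(apply(tab[, col, drop = FALSE], 1,
                        function(x) all(x) || all(!x)))
    expect_equal(column_conservation_index(col), oracle)
  }
})

test_that("index is 10 iff residues share identical property vectors", {
  tab <- property_table()
  expect_equal(column_conservation_index(c("I", "I", "I")), 10)
  # I and V differ only outside? check via table
  same_vec <- apply(tab, 2, paste, collapse = "")
  pairs <- which(outer(same_vec, same_vec, "==") & upper.tri(diag(20)),
                 arr.ind = TRUE)
  if (nrow(pairs) > 0) {
    r1 <- colnames(tab)[pairs[1, 1]]; r2 <- colnames(tab)[pairs[1, 2]]
    expect_equal(column_conservation_index(c(r1, r2)), 10)
  }
  expect_lt(column_conservation_index(c("D", "W")), 10)
})

test_that("profiles are invariant to row order", {
  sim <- simulate_msa(5, 25, list(c(5, 10)), seed = 2)
  p1 <- conservation_profile(sim$rows)
  p2 <- conservation_profile(rev(sim$rows))
  expect_equal(p1, p2)
})

test_that("window segmentation matches direct enumeration", {
  prof30 <- rep(4, 30)
  w <- sliding_window_profile(prof30)
  expect_equal(w$start, c(1, 11))
  expect_equal(w$end, c(20, 30))
  expect_equal(w$mean, c(4, 4))
  expect_false(any(w$truncated))

  w20 <- sliding_window_profile(rep(1, 20))
  expect_equal(nrow(w20), 1)

  for (L in c(20, 30, 55, 200)) {
    prof <- seq_len(L)
    w <- sliding_window_profile(prof)
    n_full <- if (L >= 20) floor((L - 20) / 10) + 1 else 0
    expect_equal(sum(!w$truncated), n_full)
    # enumerate expected means directly
    for (r in seq_len(nrow(w)))
      expect_equal(w$mean[r], mean(prof[w$start[r]:w$end[r]]))
    # truncated window present iff full windows do not reach the end
    covered <- if (n_full > 0) (n_full - 1) * 10 + 20 else 0
    expect_equal(any(w$truncated), covered < L)
  }
})

test_that("region means reflect planted conservation", {
  prof <- c(rep(2, 10), rep(9, 5), rep(2, 10))
  expect_equal(region_mean(prof, c(11, 15)), 9)
  expect_equal(region_mean(prof, c(3, 3)), 2)

  for (sd in 1:5) {
    sim <- simulate_msa(8, 60, list(c(21, 40)), seed = sd)
    prof <- conservation_profile(sim$rows)
    expect_gt(region_mean(prof, c(21, 40)), region_mean(prof, c(1, 20)))
  }
})

test_that("group identity covers both modes and denominators", {
  rows <- c(a1 = "AAAA", a2 = "AAAA", b1 = "AAAA", b2 = "AAAA")
  expect_equal(group_identity(rows, c("a1", "a2"), c("b1", "b2")), 100)

  rows2 <- c(a1 = "AAAA", b1 = "CCCC")
  expect_equal(group_identity(rows2, "a1", "b1"), 0)

  # hand-averaged cross-pair identities
  rows3 <- c(a1 = "AAAA", a2 = "AACC", b1 = "AAAC")
  # a1-b1: 3/4; a2-b1: 3/4 -> mean 75
  expect_equal(group_identity(rows3, c("a1", "a2"), "b1"), 75)

  # consensus mode
  rows4 <- c(a1 = "AATT", a2 = "AATT", a3 = "CCTT", b1 = "AAGT")
  expect_equal(group_identity(rows4, c("a1", "a2", "a3"), "b1",
                              mode = "consensus"), 75)

  # gap-inclusive denominator differs
  rows5 <- c(a1 = "AA--", b1 = "AAAA")
  expect_equal(group_identity(rows5, "a1", "b1"), 100)
  expect_equal(group_identity(rows5, "a1", "b1",
                              denominator = "all_columns"), 50)
})

test_that("intron projection follows the offset arithmetic", {
  aln <- c(g1 = "MK-VD", g2 = "MKAVD")
  # intron after nucleotide 6 -> residue 3, phase 0
  m1 <- project_introns(data.frame(gene_id = "g1", cds_offset = 6), aln)
  expect_equal(m1$phase, 0)
  expect_equal(m1$column, 4)  # residue 3 of g1 sits in column 4 (gap at 3)
  # after nucleotide 7 -> residue 3, phase 1
  m2 <- project_introns(data.frame(gene_id = "g2", cds_offset = 7), aln)
  expect_equal(m2$phase, 1)
  expect_equal(m2$column, 3)

  expect_error(project_introns(data.frame(gene_id = "g1", cds_offset = 40),
                               aln), "beyond")
})

test_that("conserved intron calls respect the membership fraction", {
  marks <- data.frame(gene_id = c("a", "b", "c"), column = 7, phase = 2)
  all3 <- conserved_intron_positions(marks, n_genes = 3)
  expect_equal(nrow(all3), 1)

  # one gene missing the mark at min_fraction 1.0
  part <- conserved_intron_positions(marks, n_genes = 4)
  expect_equal(nrow(part), 0)
  # but present at 0.5
  half <- conserved_intron_positions(marks, n_genes = 4, min_fraction = 0.5)
  expect_equal(nrow(half), 1)

  # fraction edge: exactly at the boundary counts
  m2 <- data.frame(gene_id = c("a", "b"), column = 3, phase = 0)
  expect_equal(nrow(conserved_intron_positions(m2, 4, min_fraction = 0.5)),
               1)
  # same column, different phase is a different slot when phases required
  m3 <- data.frame(gene_id = c("a", "b"), column = c(3, 3), phase = c(0, 1))
  expect_equal(nrow(conserved_intron_positions(m3, 2, min_fraction = 1)), 0)
  expect_equal(nrow(conserved_intron_positions(m3, 2, min_fraction = 1,
                                               require_same_phase = FALSE)),
               1)
})
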