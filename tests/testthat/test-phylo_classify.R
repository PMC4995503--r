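# Distances, NJ trees, bootstrap, marker classification, sister tests.

test_that("protein distances follow the closed forms", {
  rows <- c(a = "AAAA", b = "AAAA")
  expect_equal(protein_distance(rows)["a", "b"], 0)

  rows2 <- c(a = "AAAA", b = "CCCC")
  expect_equal(protein_distance(rows2, "p")["a", "b"], 1)
  expect_warning(dk <- protein_distance(rows2, "kimura"),
                 "undefined")
  expect_true(is.na(dk["a", "b"]))

  # p = 0.1 over 10 columns -> kimura = -ln(1 - 0.1 - 0.01/5)
  rows3 <- c(a = "AAAAAAAAAA", b = "CAAAAAAAAA")
  expect_equal(protein_distance(rows3, "kimura")["a", "b"],
               -log(1 - 0.1 - 0.01 / 5))

  # gapped columns are excluded from the comparison
  rows4 <- c(a = "A-AA", b = "ACAA")
  expect_equal(protein_distance(rows4, "p")["a", "b"], 0)
})

test_that("NJ matches closed forms for 2 and 3 taxa", {
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- neighbor_joining(D2)
  expect_equal(sort(t2$tip.label), c("a", "b"))
  expect_equal(unname(t2$edge.length), c(0.2, 0.2))

  # 3-taxon star: x_a = (d_ab + d_ac - d_bc)/2 etc.
  D3 <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  D3["a", "b"] <- D3["b", "a"] <- 0.6
  D3["a", "c"] <- D3["c", "a"] <- 0.8
  D3["b", "c"] <- D3["c", "b"] <- 0.4
  t3 <- neighbor_joining(D3)
  got <- setNames(t3$edge.length[match(seq_along(t3$tip.label),
                                       t3$edge[, 2])], t3$tip.label)
  expect_equal(unname(got["a"]), (0.6 + 0.8 - 0.4) / 2)
  expect_equal(unname(got["b"]), (0.6 + 0.4 - 0.8) / 2)
  expect_equal(unname(got["c"]), (0.8 + 0.4 - 0.6) / 2)
})

test_that("NJ recovers the topology of additive matrices", {
  set.seed(91)
  for (i in 1:20) {
    n <- sample(6:10, 1)
    case <- random_additive_case(n)
    tr <- neighbor_joining(case$D)
    expect_true(same_unrooted_topology(tr, case$tree),
                info = sprintf("case %d (n=%d)", i, n))
  }
})

test_that("negative NJ branches are clamped to zero", {
  # near-degenerate matrix that drives NJ lengths negative
  D <- matrix(c(0, 0.1, 0.5, 0.45,
                0.1, 0, 0.5, 0.45,
                0.5, 0.5, 0, 0.02,
                0.45, 0.45, 0.02, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports behave at the degenerate extremes", {
  # two clearly separated clades: the split gets 100%
  rows <- c(a1 = strrep("A", 30), a2 = strrep("A", 30),
            b1 = strrep("W", 30), b2 = strrep("W", 30))
  rows <- vapply(seq_along(rows), function(i)
    paste0(substr(rows[i], 1, 25),
           c("AAAAA", "AAAAC", "WWWWW", "WWWWG")[i]), character(1))
  names(rows) <- c("a1", "a2", "b1", "b2")
  tr <- bootstrap_support(rows, n_reps = 50, seed = 4)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))

  tr0 <- bootstrap_support(rows, n_reps = 0)
  expect_null(tr0$node.label)

  # deterministic given the seed
  t1 <- bootstrap_support(rows, n_reps = 20, seed = 9)
  t2 <- bootstrap_support(rows, n_reps = 20, seed = 9)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("marker anchoring classifies planted subfamilies perfectly", {
  set.seed(101)
  # four divergent clusters, one marker in each, plus a GLR0 outgroup
  founders <- replicate(4, random_protein(60))
  mutate <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    pos <- sample(length(v), k)
    for (p in pos) v[p] <- sample(setdiff(AA20, v[p]), 1)
    paste(v, collapse = "")
  }
  rows <- c()
  truth <- c()
  labels <- c("GLR1&2", "GLR3", "GLR4", "GLR0")
  for (f in 1:4) {
    rows[sprintf("mk%d", f)] <- founders[f]
    for (q in 1:3) {
      id <- sprintf("q%d_%d", f, q)
      rows[id] <- mutate(founders[f], 3)
      truth[id] <- labels[f]
    }
  }
  markers <- setNames(labels, sprintf("mk%d", 1:4))
  tr <- bootstrap_support(rows, n_reps = 30, seed = 5)
  cls <- classify_by_markers(tr, markers)
  expect_equal(setNames(cls$label, cls$query)[names(truth)], truth)
  expect_true(all(cls$method %in% c("clade", "nearest")))
})

test_that("mixed smallest clades fall back to the nearest marker", {
  tr <- ape::read.tree(text = "((q:0.1,(m1:0.3,m2:0.3):0.05):0.1,o:1);")
  cls <- classify_by_markers(tr, c(m1 = "GLR3", m2 = "GLR4", o = "GLR0"))
  # q's smallest marker-containing clade holds both labels -> nearest; tie
  # on distance broken by id order
  expect_equal(cls$method[cls$query == "q"], "nearest")
  expect_equal(cls$label[cls$query == "q"], "GLR3")
})

test_that("sister-clade verdicts distinguish sister, nested and neither", {
  tr <- ape::read.tree(text = "(((a1,a2),(b1,b2)),(c1,c2));")
  expect_equal(sister_clade_test(tr, c("a1", "a2"),
                                 c("b1", "b2"))$verdict, "sister")

  tr2 <- ape::read.tree(text = "(((a1,(b1,b2)),a2),(c1,c2));")
  expect_equal(sister_clade_test(tr2, c("a1", "a2"),
                                 c("b1", "b2"))$verdict, "nested")

  tr3 <- ape::read.tree(text = "(((a1,c1),(b1,b2)),(a2,c2));")
  expect_equal(sister_clade_test(tr3, c("a1", "a2"),
                                 c("b1", "b2"))$verdict, "neither")
})
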