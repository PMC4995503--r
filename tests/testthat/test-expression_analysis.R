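# Cq conversion, standardization, K-means and tissue preference.

make_cq <- function(rows) {
  do.call(rbind, lapply(rows, function(r)
    data.frame(gene = r[[1]], sample = r[[2]], replicate = as.integer(r[[3]]),
               cq = as.numeric(r[[4]]))))
}

test_that("Cq conversion follows the efficiency model", {
  cq <- make_cq(list(
    list("ref", "s1", 1, 20), list("g1", "s1", 1, 20),
    list("g2", "s1", 1, 19),
    list("ref", "s2", 1, 22), list("g1", "s2", 1, 23),
    list("g2", "s2", 1, 21)))
  out <- cq_to_relative(cq, "ref")
  expect_equal(out$matrix["g1", "s1"], 1.0)   # dCq = 0
  expect_equal(out$matrix["g2", "s1"], 2.0)   # one cycle earlier doubles
  expect_equal(out$matrix["g1", "s2"], 0.5)
  # efficiency 1.9 changes the base
  out2 <- cq_to_relative(cq, "ref", efficiency = 1.9)
  expect_equal(out2$matrix["g2", "s1"], 1.9)
})

test_that("undetected genes are zeroed, dropped and listed", {
  cq <- make_cq(list(
    list("ref", "s1", 1, 20), list("ref", "s2", 1, 20),
    list("g1", "s1", 1, 20), list("g1", "s2", 1, NA),
    list("gone", "s1", 1, NA), list("gone", "s2", 1, NA)))
  out <- cq_to_relative(cq, "ref")
  expect_equal(out$dropped, "gone")
  expect_false("gone" %in% rownames(out$matrix))
  expect_equal(out$matrix["g1", "s2"], 0)
  expect_equal(out$flagged$gene, "g1")

  # missing reference errors
  cq_bad <- make_cq(list(list("ref", "s1", 1, 20), list("g1", "s1", 1, 20),
                         list("g1", "s2", 1, 21)))
  expect_error(cq_to_relative(cq_bad, "ref"), "reference")
})

test_that("replicates average after transformation, not before", {
  cq <- make_cq(list(
    list("ref", "s1", 1, 20), list("ref", "s1", 2, 20),
    list("g1", "s1", 1, 19), list("g1", "s1", 2, 21)))
  out <- cq_to_relative(cq, "ref")
  expect_equal(out$matrix["g1", "s1"], (2 + 0.5) / 2)  # not 2^0 = 1
})

test_that("log2 standardization matches hand arithmetic", {
  m <- matrix(c(1, 2, 4), 1, 3, dimnames = list("g", c("a", "b", "c")))
  z <- log2_standardize(m, pseudocount = 0)
  expect_equal(unname(z[1, ]), c(-1, 0, 1) / sqrt(2 / 3),
               tolerance = 1e-12)

  # constant rows become zero and are flagged
  mc <- matrix(5, 2, 3, dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  zc <- log2_standardize(mc)
  expect_true(all(zc == 0))
  expect_setequal(attr(zc, "constant_rows"), c("g1", "g2"))

  # standardized rows have mean 0, population sd 1
  set.seed(111)
  mr <- matrix(stats::runif(50, 1, 100), 5, 10,
               dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:10)))
  zr <- log2_standardize(mr, pseudocount = 0)
  expect_equal(unname(rowMeans(zr)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(sqrt(rowMeans(zr^2))), rep(1, 5), tolerance = 1e-12)

  # scale invariance at pseudocount 0
  expect_equal(log2_standardize(mr * 7, pseudocount = 0), zr,
               ignore_attr = TRUE)
})

test_that("K-means recovers planted clusters and degenerate cases", {
  spec <- list(list(mean = c(10, 0, 0), sd = 0.5),
               list(mean = c(0, 10, 0), sd = 0.5),
               list(mean = c(0, 0, 10), sd = 0.5))
  sim <- simulate_expression(30, c("leaf", "stem", "root"), spec, seed = 2)
  cl <- kmeans_cluster(sim$matrix, k = 3, seed = 2)
  ari <- mclust::adjustedRandIndex(cl$cluster, sim$truth$cluster)
  expect_equal(ari, 1.0)

  # k = 1: centroid is the column means
  cl1 <- kmeans_cluster(sim$matrix, k = 1, seed = 1)
  expect_equal(unname(cl1$centroids[1, ]), unname(colMeans(sim$matrix)))

  # k = n: zero inertia
  m <- sim$matrix[1:5, ]
  cln <- kmeans_cluster(m, k = 5, seed = 1)
  expect_equal(cln$inertia, 0)

  # determinism
  c1 <- kmeans_cluster(sim$matrix, k = 3, seed = 7)
  c2 <- kmeans_cluster(sim$matrix, k = 3, seed = 7)
  expect_identical(c1$cluster, c2$cluster)
})

test_that("tissue preference takes the argmax and lists ties", {
  m <- matrix(c(5, 5, 1, 1, 0, 0,
                2, 2, 2, 2, 2, 2), 2, 6, byrow = TRUE,
              dimnames = list(c("g1", "g2"),
                              c("camb1", "camb2", "xyl1", "xyl2",
                                "phl1", "phl2")))
  st <- setNames(rep(c("cambium", "xylem", "phloem"), each = 2),
                 colnames(m))
  out <- tissue_preference(m, st)
  expect_equal(out$preference$preferred[out$preference$gene == "g1"],
               "cambium")
  expect_equal(out$preference$preferred[out$preference$gene == "g2"],
               "cambium,xylem,phloem")

  groups <- setNames(c("GLR1&2", "GLR3"), c("g1", "g2"))
  out2 <- tissue_preference(m, st, groups)
  fr <- out2$fractions
  expect_equal(fr$fraction[fr$group == "GLR1&2" & fr$tissue == "cambium"], 1)
  expect_equal(fr$fraction[fr$group == "GLR1&2" & fr$tissue == "xylem"], 0)
})

test_that("planted preference fractions are recovered exactly", {
  spec <- list(list(mean = c(9, 1, 1), sd = 0.2),
               list(mean = c(1, 9, 1), sd = 0.2))
  sim <- simulate_expression(12, c("cambium", "xylem", "phloem"), spec,
                             seed = 6)
  st <- setNames(sim$samples$tissue, sim$samples$sample)
  groups <- setNames(paste0("cl", sim$truth$cluster), sim$truth$gene_id)
  out <- tissue_preference(sim$matrix, st, groups)
  fr <- out$fractions
  expect_equal(fr$fraction[fr$group == "cl1" & fr$tissue == "cambium"], 1)
  expect_equal(fr$fraction[fr$group == "cl2" & fr$tissue == "xylem"], 1)
})
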