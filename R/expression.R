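# Expression analysis: Cq -> relative expression, log2 standardization,
# K-means clustering (k-means++ seeding) and tissue-preference calls.

#' Convert qPCR Cq values to relative expression
#'
#' Per sample and replicate, `dCq = Cq(gene) - mean Cq(reference genes)`
#' and relative expression is `E^(-dCq)`; replicates are averaged after the
#' transformation. Genes with missing Cq in a sample get relative 0 there
#' (flagged); genes undetected in every sample are dropped and listed.
#'
#' @param cq_table Long data.frame with columns `gene`, `sample`,
#'   `replicate`, `cq` (NA = undetected).
#' @param reference_genes Character vector of reference gene ids (>= 1),
#'   required in every sample/replicate.
#' @param efficiency Amplification efficiency E (default 2.0), or a named
#'   per-gene vector.
#' @return List: `matrix` (gene x sample relative expression), `dropped`
#'   (gene ids undetected everywhere), `flagged` (data.frame gene/sample of
#'   partial non-detections).
#' @export
cq_to_relative <- function(cq_table, reference_genes, efficiency = 2.0) {
  stopifnot(all(c("gene", "sample", "replicate", "cq") %in% names(cq_table)),
            length(reference_genes) >= 1)
  if (any(cq_table$cq[!is.na(cq_table$cq)] <= 0)) stop("Cq must be > 0")
  eff_of <- function(g) {
    if (length(efficiency) == 1 && is.null(names(efficiency)))
      return(efficiency)
    if (!g %in% names(efficiency)) stop("no efficiency for gene ", g)
    efficiency[[g]]
  }
  genes <- setdiff(unique(cq_table$gene), reference_genes)
  samples <- unique(cq_table$sample)
  rel <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
  flagged <- data.frame(gene = character(0), sample = character(0))
  for (s in samples) {
    sub <- cq_table[cq_table$sample == s, , drop = FALSE]
    for (r in unique(sub$replicate)) {
      refs <- sub$cq[sub$replicate == r & sub$gene %in% reference_genes]
      if (length(refs) < length(reference_genes) || anyNA(refs))
        stop("missing reference gene Cq in sample ", s, " replicate ", r)
    }
    for (g in genes) {
      reps <- sort(unique(sub$replicate))
      vals <- vapply(reps, function(r) {
        cq <- sub$cq[sub$replicate == r & sub$gene == g]
        if (length(cq) == 0 || is.na(cq)) return(NA_real_)
        ref <- mean(sub$cq[sub$replicate == r &
                             sub$gene %in% reference_genes])
        eff_of(g)^(-(cq - ref))
      }, numeric(1))
      if (all(is.na(vals))) {
        rel[g, s] <- 0
        flagged <- rbind(flagged, data.frame(gene = g, sample = s))
      } else rel[g, s] <- mean(vals, na.rm = TRUE)
    }
  }
  dropped <- rownames(rel)[rowSums(rel) == 0]
  list(matrix = rel[!rownames(rel) %in% dropped, , drop = FALSE],
       dropped = dropped,
       flagged = flagged[!flagged$gene %in% dropped, , drop = FALSE])
}

#' Log2-transform and row-standardize an expression matrix
#'
#' `v -> log2(v + pseudocount)`, then each row is centred on its mean and
#' divided by its population standard deviation; constant rows become
#' all-zero and are flagged in the `"constant_rows"` attribute.
#'
#' @param m Numeric gene x sample matrix (non-negative).
#' @param pseudocount Added before the log; default `1e-4` of the smallest
#'   positive entry (0 when all entries are positive and no zeros exist).
#' @return Standardized matrix, with attribute `constant_rows`.
#' @export
log2_standardize <- function(m, pseudocount = NULL) {
  stopifnot(is.matrix(m), all(m >= 0))
  if (is.null(pseudocount)) {
    pos <- m[m > 0]
    pseudocount <- if (any(m == 0) && length(pos) > 0) 1e-4 * min(pos) else 0
  }
  lg <- log2(m + pseudocount)
  mu <- rowMeans(lg)
  sdv <- sqrt(rowMeans((lg - mu)^2))
  const <- sdv == 0
  z <- (lg - mu) / ifelse(const, 1, sdv)
  z[const, ] <- 0
  attr(z, "constant_rows") <- rownames(m)[const]
  z
}

.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- numeric(0)
  centers[1] <- sample.int(n, 1)
  for (j in seq_len(k - 1)) {
    d2 <- apply(x, 1, function(r)
      min(colSums((t(x[centers, , drop = FALSE]) - r)^2)))
    if (sum(d2) == 0) centers[j + 1] <- sample.int(n, 1)
    else centers[j + 1] <- sample.int(n, 1, prob = d2)
  }
  x[centers, , drop = FALSE]
}

#' K-means clustering of an expression matrix
#'
#' Best of `n_init` runs (k-means++ seeding, Lloyd refinement) by total
#' within-cluster sum of squares. Deterministic given `seed`.
#'
#' @param m Numeric gene x sample matrix (typically standardized).
#' @param k Number of clusters (explicit; no default is privileged).
#' @param n_init Number of seeded runs (default 10).
#' @param seed Integer seed.
#' @return List: `cluster` (named integer vector), `centroids` (k x sample
#'   matrix), `inertia`, `k`, `seed`.
#' @export
kmeans_cluster <- function(m, k, n_init = 10, seed = 1) {
  stopifnot(k >= 1, k <= nrow(m))
  set.seed(.substream_seed(seed, "kmeans_cluster"))
  best <- NULL
  for (i in seq_len(n_init)) {
    cen <- .kmeanspp_centers(m, k)
    fit <- suppressWarnings(
      stats::kmeans(m, centers = cen, algorithm = "Lloyd",
                    iter.max = 100))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  list(cluster = stats::setNames(best$cluster, rownames(m)),
       centroids = best$centers, inertia = best$tot.withinss, k = k,
       seed = seed)
}

#' Per-gene tissue preference and per-group preference fractions
#'
#' A gene's preferred tissue is the argmax of its per-tissue mean value
#' (all argmax tissues listed on ties). A group's fraction for tissue T is
#' the share of members preferring T (tied genes count for each of their
#' preferred tissues).
#'
#' @param m Gene x sample matrix (standardized values).
#' @param sample_tissue Named character vector: sample -> tissue.
#' @param groups Optional named character vector: gene -> group label.
#' @return List: `preference` (data.frame gene/preferred, comma-joined on
#'   ties), `fractions` (data.frame group/tissue/fraction; NULL without
#'   groups).
#' @export
tissue_preference <- function(m, sample_tissue, groups = NULL) {
  stopifnot(all(colnames(m) %in% names(sample_tissue)))
  tissues <- unique(unname(sample_tissue[colnames(m)]))
  tmeans <- sapply(tissues, function(tt)
    rowMeans(m[, sample_tissue[colnames(m)] == tt, drop = FALSE]))
  if (is.null(dim(tmeans))) tmeans <- matrix(tmeans, nrow = 1,
                                             dimnames = list(rownames(m),
                                                             tissues))
  pref_list <- apply(tmeans, 1, function(v)
    tissues[v == max(v)], simplify = FALSE)
  preference <- data.frame(
    gene = rownames(m),
    preferred = vapply(pref_list, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  fractions <- NULL
  if (!is.null(groups)) {
    stopifnot(all(rownames(m) %in% names(groups)))
    gl <- sort(unique(unname(groups[rownames(m)])))
    fractions <- do.call(rbind, lapply(gl, function(g) {
      members <- rownames(m)[groups[rownames(m)] == g]
      data.frame(group = g, tissue = tissues,
                 fraction = vapply(tissues, function(tt)
                   mean(vapply(pref_list[members], function(p) tt %in% p,
                               logical(1))), numeric(1)))
    }))
    rownames(fractions) <- NULL
  }
  list(preference = preference, fractions = fractions)
}
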