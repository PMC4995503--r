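# Homolog-pair detection, collinear-chain (synteny) detection, duplication
# mode classification and tandem-array statistics.

#' Find homologous protein pairs
#'
#' All-vs-all local alignment; for each query the `top_k` best non-self hits
#' at or above `score_threshold` are kept, then the symmetric closure is
#' taken (a pair survives if either direction retained it). Pairs are stored
#' once in canonical id order.
#'
#' @param proteins Sequence-record data.frame (`id`, `residues`).
#' @param top_k Hits kept per query (default 5; hits tied with the k-th
#'   best score are also kept).
#' @param score_threshold Minimum local alignment score; see
#'   [calibrate_homolog_threshold()].
#' @return data.frame `a`, `b`, `score`, `identity`, `rank_in_a` (rank of
#'   the hit among the canonical-first gene's hits).
#' @export
find_homolog_pairs <- function(proteins, top_k = 5, score_threshold = 0) {
  n <- nrow(proteins)
  stopifnot(n >= 2)
  ids <- proteins$id
  score <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  ident <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  # one vectorized set-vs-subject alignment call per subject; identity is
  # PID2 (identical / both-ungapped columns), matching pairwise_align()
  aa <- Biostrings::AAStringSet(stats::setNames(proteins$residues, ids))
  for (j in 2:n) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = aa[seq_len(j - 1)], subject = aa[[j]], type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1)
    sc <- Biostrings::score(pa)
    pid <- Biostrings::pid(pa, type = "PID2")
    score[seq_len(j - 1), j] <- score[j, seq_len(j - 1)] <- sc
    ident[seq_len(j - 1), j] <- ident[j, seq_len(j - 1)] <- pid
  }
  kept <- matrix(FALSE, n, n)
  rank_of <- matrix(NA_integer_, n, n)
  for (i in seq_len(n)) {
    s <- score[i, ]
    ok <- which(!is.na(s) & s >= score_threshold)
    if (length(ok) == 0) next
    ord <- ok[order(-s[ok], ids[ok])]
    # keep top_k hits plus any hit tied with the k-th best score
    cutoff <- s[ord[min(top_k, length(ord))]]
    keep <- ord[seq_along(ord) <= top_k | s[ord] >= cutoff]
    kept[i, keep] <- TRUE
    rank_of[i, keep] <- seq_along(keep)
  }
  out <- which(kept | t(kept), arr.ind = TRUE)
  out <- out[out[, 1] < out[, 2], , drop = FALSE]
  if (nrow(out) == 0)
    return(data.frame(a = character(0), b = character(0), score = numeric(0),
                      identity = numeric(0), rank_in_a = integer(0)))
  df <- data.frame(a = ids[out[, 1]], b = ids[out[, 2]],
                   score = score[out], identity = ident[out],
                   rank_in_a = rank_of[out], stringsAsFactors = FALSE)
  df <- df[order(df$a, df$b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Calibrate a homolog score threshold from a shuffled-sequence null
#'
#' Local-alignment surrogate for an E-value cut-off: residue-shuffled
#' sequence pairs are aligned and an extreme-value (Gumbel) distribution is
#' fitted to the null scores by the method of moments — local alignment
#' score maxima are Gumbel-distributed (Karlin-Altschul) — so the extreme
#' `quantile` can be extrapolated beyond the sample size.
#'
#' @param proteins Sequence-record data.frame.
#' @param n_pairs Null score samples (minimum; rounded up to whole
#'   set-vs-subject batches).
#' @param quantile Null quantile (default 0.99999).
#' @param seed Integer seed.
#' @return Numeric threshold.
#' @export
calibrate_homolog_threshold <- function(proteins, n_pairs = 50,
                                        quantile = 0.99999, seed = 1) {
  set.seed(.substream_seed(seed, "calibrate_homolog_threshold"))
  shuffle <- function(s) paste(sample(strsplit(s, "")[[1]]), collapse = "")
  shuffled <- vapply(proteins$residues, shuffle, character(1),
                     USE.NAMES = FALSE)
  n_subjects <- max(1L, ceiling(n_pairs / length(shuffled)))
  scores <- unlist(lapply(seq_len(n_subjects), function(k) {
    subj <- shuffle(proteins$residues[((k - 1) %% nrow(proteins)) + 1])
    Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAStringSet(shuffled), subject = subj,
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 1, scoreOnly = TRUE)
  }))
  beta <- stats::sd(scores) * sqrt(6) / pi
  mu <- mean(scores) - 0.5772156649 * beta
  mu - beta * log(-log(quantile))
}

.gene_index <- function(genesets) {
  if (inherits(genesets, "gene_set")) genesets <- list(genesets)
  idx <- do.call(rbind, lapply(genesets, function(gs)
    data.frame(id = gs$id, chromosome = gs$chromosome, rank = gs$rank,
               stringsAsFactors = FALSE)))
  if (anyDuplicated(idx$id)) stop("duplicate gene ids across gene sets")
  idx
}

# Longest valid chain by DP over anchors sorted by rank on side 1.
# dir = +1 (side-2 ranks strictly increasing) or -1 (strictly decreasing).
.chain_dp <- function(r1, r2, max_gap, dir) {
  n <- length(r1)
  len <- rep(1L, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      d1 <- r1[i] - r1[j]
      d2 <- dir * (r2[i] - r2[j])
      if (d1 > 0 && d1 <= max_gap && d2 > 0 && d2 <= max_gap &&
          len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  list(len = len, prev = prev)
}

.chain_backtrack <- function(dp, i) {
  path <- integer(0)
  while (!is.na(i)) { path <- c(i, path); i <- dp$prev[i] }
  path
}

#' Detect collinear chains (synteny blocks)
#'
#' Anchors (homolog pairs) are grouped by chromosome pair and chained by
#' dynamic programming: an anchor extends a previous one when both rank
#' increments are in `(0, max_rank_gap]` (the second side strictly
#' decreasing for inverted chains). Maximal chains with at least
#' `min_block_pairs` anchors are reported greedily by chain score; each
#' anchor belongs to at most one block. Same-chromosome anchor pairs closer
#' than `exclude_proximal_gap` ranks are not used as collinearity evidence
#' (tandem copies are not synteny).
#'
#' @param pairs Homolog pairs (`a`, `b`).
#' @param genesets A `gene_set` or list of them.
#' @param min_block_pairs Minimum anchors per block (default 5).
#' @param max_rank_gap Maximum rank increment between consecutive anchors
#'   (default 25).
#' @param exclude_proximal_gap Same-chromosome pairs with rank distance at
#'   or below this are dropped from the anchor set (default 10).
#' @return List of blocks: each `list(block_id, chrom_a, chrom_b,
#'   orientation, score, anchors)` where `anchors` is a data.frame `a`, `b`
#'   ordered along side 1.
#' @export
detect_collinear_chains <- function(pairs, genesets, min_block_pairs = 5,
                                    max_rank_gap = 25,
                                    exclude_proximal_gap = 10) {
  idx <- .gene_index(genesets)
  if (nrow(pairs) == 0) return(list())
  miss <- setdiff(unique(c(pairs$a, pairs$b)), idx$id)
  if (length(miss) > 0)
    stop("pairs reference unknown genes: ", paste(miss, collapse = ", "))
  loc <- function(g, what) idx[[what]][match(g, idx$id)]
  ca <- loc(pairs$a, "chromosome"); cb <- loc(pairs$b, "chromosome")
  ra <- loc(pairs$a, "rank"); rb <- loc(pairs$b, "rank")
  # orient: side 1 = lexicographically smaller chromosome (lower rank if same)
  flip <- ca > cb | (ca == cb & ra > rb)
  g1 <- ifelse(flip, pairs$b, pairs$a); g2 <- ifelse(flip, pairs$a, pairs$b)
  c1 <- ifelse(flip, cb, ca); c2 <- ifelse(flip, ca, cb)
  r1 <- ifelse(flip, rb, ra); r2 <- ifelse(flip, ra, rb)
  proximal <- c1 == c2 & abs(r1 - r2) <= exclude_proximal_gap
  anchors <- data.frame(g1, g2, c1, c2, r1, r2,
                        stringsAsFactors = FALSE)[!proximal, , drop = FALSE]
  blocks <- list()
  bi <- 0L
  for (grp in split(anchors, paste(anchors$c1, anchors$c2))) {
    grp <- grp[order(grp$r1, grp$r2, grp$g1), , drop = FALSE]
    used <- rep(FALSE, nrow(grp))
    repeat {
      live <- which(!used)
      if (length(live) < min_block_pairs) break
      sub <- grp[live, , drop = FALSE]
      best <- NULL
      for (dir in c(1L, -1L)) {
        dp <- .chain_dp(sub$r1, sub$r2, max_rank_gap, dir)
        top <- max(dp$len)
        cand <- which(dp$len == top)
        # ties by first anchor id of the backtracked chain
        paths <- lapply(cand, function(i) .chain_backtrack(dp, i))
        first_ids <- vapply(paths, function(p) sub$g1[p[1]], character(1))
        pick <- paths[[order(first_ids)[1]]]
        if (is.null(best) || top > best$score ||
            (top == best$score && dir == 1L))
          best <- list(score = top, path = pick, dir = dir)
      }
      if (best$score < min_block_pairs) break
      bi <- bi + 1L
      sel <- best$path
      blocks[[bi]] <- list(
        block_id = sprintf("block_%d", bi),
        chrom_a = sub$c1[1], chrom_b = sub$c2[1],
        orientation = if (best$dir == 1L) "same" else "inverted",
        score = best$score,
        anchors = data.frame(a = sub$g1[sel], b = sub$g2[sel],
                             stringsAsFactors = FALSE))
      used[live[sel]] <- TRUE
    }
  }
  blocks
}

.block_anchor_genes <- function(blocks) {
  unique(unlist(lapply(blocks, function(b) c(b$anchors$a, b$anchors$b))))
}

#' Classify duplication modes
#'
#' Fixed-priority rules: a gene with no homolog pair is a `singleton`; a
#' block anchor is `wgd_segmental`; a gene with a same-chromosome partner
#' separated by fewer than `tandem_gap` intervening genes is `tandem`; the
#' remainder are `dispersed`.
#'
#' @param geneset A `gene_set` (or list).
#' @param pairs Homolog pairs.
#' @param blocks Output of [detect_collinear_chains()].
#' @param gene_ids Genes to classify (default: all genes referenced by
#'   `pairs`).
#' @param tandem_gap Tandem threshold (default 10).
#' @param tandem_rule `"intervening"` (strictly fewer than `tandem_gap`
#'   genes between the two homologs; default) or `"rank_diff"` (rank
#'   difference below `tandem_gap`).
#' @return data.frame `gene_id`, `mode`, `support` (partner or block id,
#'   `"."` for singletons/dispersed without support).
#' @export
classify_duplications <- function(geneset, pairs, blocks,
                                  gene_ids = NULL, tandem_gap = 10,
                                  tandem_rule = c("intervening", "rank_diff")) {
  tandem_rule <- match.arg(tandem_rule)
  idx <- .gene_index(geneset)
  if (is.null(gene_ids)) gene_ids <- sort(unique(c(pairs$a, pairs$b)))
  miss <- setdiff(unique(c(pairs$a, pairs$b)), idx$id)
  if (length(miss) > 0)
    stop("pairs reference unknown genes: ", paste(miss, collapse = ", "))
  anchor_genes <- .block_anchor_genes(blocks)
  in_block <- function(g) g %in% anchor_genes
  block_of <- function(g) {
    for (b in blocks) if (g %in% c(b$anchors$a, b$anchors$b))
      return(b$block_id)
    "."
  }
  partners <- function(g) {
    c(pairs$b[pairs$a == g], pairs$a[pairs$b == g])
  }
  res <- lapply(gene_ids, function(g) {
    ps <- partners(g)
    if (length(ps) == 0)
      return(data.frame(gene_id = g, mode = "singleton", support = "."))
    if (in_block(g))
      return(data.frame(gene_id = g, mode = "wgd_segmental",
                        support = block_of(g)))
    chr_g <- idx$chromosome[match(g, idx$id)]
    rank_g <- idx$rank[match(g, idx$id)]
    same <- ps[idx$chromosome[match(ps, idx$id)] == chr_g]
    if (length(same) > 0) {
      dd <- abs(idx$rank[match(same, idx$id)] - rank_g)
      near <- if (tandem_rule == "intervening") dd - 1 < tandem_gap
              else dd < tandem_gap
      if (any(near))
        return(data.frame(gene_id = g, mode = "tandem",
                          support = same[which(near)[1]]))
    }
    data.frame(gene_id = g, mode = "dispersed", support = ".")
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Group tandem-called genes into maximal tandem arrays
#'
#' Arrays are the connected components of the tandem-adjacency relation
#' (homolog pair, same chromosome, fewer than `tandem_gap` intervening
#' genes) restricted to tandem-called genes; each component is ordered by
#' rank.
#'
#' @param calls [classify_duplications()] output.
#' @param pairs Homolog pairs.
#' @param geneset A `gene_set` (or list).
#' @param tandem_gap Tandem threshold (default 10).
#' @return List with `arrays` (list of data.frames `gene_id`, `chromosome`,
#'   `rank`) and `summary` (`n_arrays`, `mean_size`, `n_tandem_genes`).
#' @export
group_tandem_arrays <- function(calls, pairs, geneset, tandem_gap = 10) {
  idx <- .gene_index(geneset)
  tg <- calls$gene_id[calls$mode == "tandem"]
  if (length(tg) == 0)
    return(list(arrays = list(),
                summary = list(n_arrays = 0L, mean_size = NA_real_,
                               n_tandem_genes = 0L)))
  sub <- pairs[pairs$a %in% tg & pairs$b %in% tg, , drop = FALSE]
  chr <- function(g) idx$chromosome[match(g, idx$id)]
  rnk <- function(g) idx$rank[match(g, idx$id)]
  adj <- sub[chr(sub$a) == chr(sub$b) &
             abs(rnk(sub$a) - rnk(sub$b)) - 1 < tandem_gap, , drop = FALSE]
  g <- igraph::graph_from_data_frame(adj[, c("a", "b")], directed = FALSE,
                                     vertices = data.frame(name = tg))
  comp <- igraph::components(g)$membership
  arrays <- lapply(split(names(comp), comp), function(members) {
    df <- data.frame(gene_id = members, chromosome = chr(members),
                     rank = rnk(members), stringsAsFactors = FALSE)
    df <- df[order(df$rank), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  names(arrays) <- sprintf("array_%d", seq_along(arrays))
  sizes <- vapply(arrays, nrow, integer(1))
  stopifnot(sum(sizes) == length(tg))
  list(arrays = arrays,
       summary = list(n_arrays = length(arrays), mean_size = mean(sizes),
                      n_tandem_genes = length(tg)))
}

#' Tandem-related fraction
#'
#' Percentage of tandem-related genes among all analysed genes, rounded to
#' two decimals for reporting.
#'
#' @param tandem Either a [classify_duplications()] data.frame (tandem-mode
#'   rows counted) or a tandem-related gene count.
#' @param total Total gene count (required when `tandem` is a count).
#' @return Percentage (0-100), rounded to 2 decimals.
#' @export
tandem_related_fraction <- function(tandem, total = NULL) {
  if (is.data.frame(tandem)) {
    n_t <- sum(tandem$mode == "tandem")
    n <- nrow(tandem)
  } else {
    stopifnot(!is.null(total))
    n_t <- tandem; n <- total
  }
  stopifnot(n > 0, n_t >= 0, n_t <= n)
  round(100 * n_t / n, 2)
}
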