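# Distance-based trees with bootstrap, marker-anchored subfamily
# classification and sister-clade testing.

#' Pairwise protein distances from an alignment
#'
#' `p` is the mismatch proportion over columns where both rows are non-gap;
#' `kimura` applies the Kimura (1983) correction `-ln(1 - p - p^2/5)`.
#' Pairs with no comparable columns, or with p too large for the
#' correction, get `NA` with a warning.
#'
#' @param rows Named character vector of equal-length gapped rows.
#' @param correction `"p"` or `"kimura"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
protein_distance <- function(rows, correction = c("p", "kimura")) {
  correction <- match.arg(correction)
  n <- length(rows)
  stopifnot(n >= 2, length(unique(nchar(rows))) == 1)
  m <- do.call(rbind, strsplit(rows, ""))
  D <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(both)) {
      warning("no comparable columns for ", names(rows)[i], " / ",
              names(rows)[j])
      D[i, j] <- D[j, i] <- NA_real_
      next
    }
    p <- sum(m[i, both] != m[j, both]) / sum(both)
    d <- if (correction == "p") p else {
      arg <- 1 - p - p^2 / 5
      if (arg <= 0) {
        warning("Kimura correction undefined at p = ", round(p, 3))
        NA_real_
      } else -log(arg)
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree with negative-branch handling
#'
#' Standard NJ agglomeration (via \pkg{ape}); negative branch lengths are
#' clamped to zero with the deficit moved to the sibling edge.
#'
#' @param D Symmetric distance matrix with row/column names.
#' @return An \pkg{ape} `phylo` tree (unrooted for 3+ taxa).
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) >= 2, !anyNA(D))
  if (nrow(D) == 2) {
    d <- D[1, 2]
    return(ape::read.tree(text = sprintf("(%s:%g,%s:%g);",
                                         rownames(D)[1], d / 2,
                                         rownames(D)[2], d / 2)))
  }
  tr <- ape::nj(stats::as.dist(D))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sibs) > 0)
      tr$edge.length[sibs[1]] <- max(0, tr$edge.length[sibs[1]] + deficit)
  }
  tr
}

#' Bootstrap supports for an NJ tree
#'
#' Columns are resampled with replacement `n_reps` times; the support of
#' each internal bipartition of the original tree is the percentage of
#' replicate trees containing it. Deterministic given `seed`.
#'
#' @param rows Named character vector of aligned rows.
#' @param n_reps Bootstrap replicates (0 = no supports).
#' @param correction Distance correction passed to [protein_distance()].
#' @param seed Integer seed.
#' @return The NJ tree with integer percent supports in `node.label`
#'   (absent when `n_reps = 0`).
#' @export
bootstrap_support <- function(rows, n_reps = 100,
                              correction = "p", seed = 1) {
  tr <- neighbor_joining(protein_distance(rows, correction))
  if (n_reps == 0) return(tr)
  m <- do.call(rbind, strsplit(rows, ""))
  rownames(m) <- names(rows)
  build <- function(x) {
    rws <- apply(x, 1, paste, collapse = "")
    neighbor_joining(protein_distance(rws, correction))
  }
  set.seed(.substream_seed(seed, "bootstrap_support"))
  counts <- ape::boot.phylo(tr, m, build, B = n_reps, quiet = TRUE,
                            rooted = FALSE)
  supports <- round(100 * counts / n_reps)
  supports[1] <- NA  # root "bipartition" is not informative
  tr$node.label <- ifelse(is.na(supports), "", as.character(supports))
  tr
}

.clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, .clade_tips, tree = tree))
}

.parent_of <- function(tree, node) {
  e <- which(tree$edge[, 2] == node)
  if (length(e) == 0) NA_integer_ else tree$edge[e, 1]
}

#' Classify query sequences by marker anchoring
#'
#' The tree is rooted at the marker labelled `GLR0` when present (the
#' family's original group), else left as provided. For each query tip the
#' smallest clade containing it and at least one marker decides: a single
#' marker label assigns it (with the clade's bootstrap support); mixed
#' labels fall back to the nearest marker by patristic distance (ties by
#' id); a tree without markers leaves queries unassigned.
#'
#' @param tree A `phylo` tree whose tips include the markers.
#' @param markers Named character vector: marker tip id -> subfamily label.
#' @return data.frame `query`, `label`, `support` (percent or NA),
#'   `method` (`clade`/`nearest`/`none`).
#' @export
classify_by_markers <- function(tree, markers) {
  marker_ids <- names(markers)
  stopifnot(all(marker_ids %in% tree$tip.label))
  glr0 <- marker_ids[markers == "GLR0"]
  if (length(glr0) >= 1 && !ape::is.rooted(tree))
    tree <- ape::root(tree, outgroup = glr0[1], resolve.root = TRUE)
  ntip <- length(tree$tip.label)
  coph <- stats::cophenetic(tree)
  queries <- setdiff(tree$tip.label, marker_ids)
  res <- lapply(queries, function(q) {
    tip <- match(q, tree$tip.label)
    node <- .parent_of(tree, tip)
    while (!is.na(node)) {
      tips <- .clade_tips(tree, node)
      mk <- intersect(tips, marker_ids)
      if (length(mk) > 0) {
        labs <- unique(markers[mk])
        if (length(labs) == 1) {
          sup <- if (!is.null(tree$node.label)) {
            s <- tree$node.label[node - ntip]
            if (is.na(s) || s == "") NA_real_ else as.numeric(s)
          } else NA_real_
          return(data.frame(query = q, label = unname(labs),
                            support = sup, method = "clade"))
        }
        d <- coph[q, marker_ids]
        near <- marker_ids[order(d, marker_ids)][1]
        return(data.frame(query = q, label = unname(markers[near]),
                          support = NA_real_, method = "nearest"))
      }
      node <- .parent_of(tree, node)
    }
    data.frame(query = q, label = "unassigned", support = NA_real_,
               method = "none")
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Sister-clade test for two groups of tips
#'
#' `sister` when A, B and their union are each monophyletic; `nested` when
#' the union is monophyletic but one of the groups is not; `neither`
#' otherwise. Evaluated on the tree as rooted (root the tree on an
#' outgroup first for a meaningful test).
#'
#' @param tree A `phylo` tree.
#' @param group_a,group_b Character vectors of tip labels.
#' @return List: `verdict`, `union_monophyletic`, `a_monophyletic`,
#'   `b_monophyletic`.
#' @export
sister_clade_test <- function(tree, group_a, group_b) {
  stopifnot(all(c(group_a, group_b) %in% tree$tip.label),
            length(intersect(group_a, group_b)) == 0)
  mono <- function(tips) {
    if (length(tips) == 1) return(TRUE)
    ape::is.monophyletic(tree, tips)
  }
  a <- mono(group_a); b <- mono(group_b); u <- mono(c(group_a, group_b))
  verdict <- if (u && a && b) "sister"
             else if (u) "nested" else "neither"
  list(verdict = verdict, union_monophyletic = u,
       a_monophyletic = a, b_monophyletic = b)
}
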