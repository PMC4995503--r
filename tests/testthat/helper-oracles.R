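# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive and kept separate from the package implementations.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

# Affine-gap Needleman-Wunsch (Gotoh) score, gap cost = open + ext * L.
gotoh_global_score <- function(a, b, S, open = 10, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(open + ext * (i - 1))
  for (j in 2:(m + 1)) Iy[1, j] <- -(open + ext * (j - 1))
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- S[av[i - 1], bv[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
    Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
    Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Exhaustive longest-chain search over anchors (both orientations).
brute_force_best_chain <- function(r1, r2, max_gap) {
  n <- length(r1)
  best <- 1L
  extend <- function(chain, dir) {
    last <- chain[length(chain)]
    grew <- FALSE
    for (k in seq_len(n)) {
      d1 <- r1[k] - r1[last]
      d2 <- dir * (r2[k] - r2[last])
      if (d1 > 0 && d1 <= max_gap && d2 > 0 && d2 <= max_gap) {
        grew <- TRUE
        extend(c(chain, k), dir)
      }
    }
    if (!grew && length(chain) > best) best <<- length(chain)
  }
  for (s in seq_len(n)) for (dir in c(1L, -1L)) extend(s, dir)
  best
}

# Naive NG86 per-codon oracle: synonymous site fraction and pathway-averaged
# differences, written independently of the package internals.
naive_codon_sites <- function(codon, code) {
  b <- strsplit(codon, "")[[1]]
  syn <- 0
  for (p in 1:3) for (alt in setdiff(c("T", "C", "A", "G"), b[p])) {
    nb <- b; nb[p] <- alt
    alt_aa <- code[[paste(nb, collapse = "")]]
    if (alt_aa != "*" && alt_aa == code[[codon]]) syn <- syn + 1
  }
  syn / 3
}

naive_pathway_diffs <- function(c1, c2, code) {
  b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
  dpos <- which(b1 != b2)
  if (length(dpos) == 0) return(c(0, 0))
  perms <- combinat_perms(dpos)
  res <- lapply(perms, function(ord) {
    cur <- b1; syn <- 0; nonsyn <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur; nxt[p] <- b2[p]
      a1 <- code[[paste(cur, collapse = "")]]
      a2 <- code[[paste(nxt, collapse = "")]]
      if (a2 == "*") ok <- FALSE
      if (a1 == a2) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn, nonsyn, ok)
  })
  res <- do.call(rbind, res)
  valid <- res[, 3] == 1
  if (!any(valid)) valid <- rep(TRUE, nrow(res))
  c(mean(res[valid, 1]), mean(res[valid, 2]))
}

combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in combinat_perms(x[-i]))
      out[[length(out) + 1]] <- c(x[i], rest)
  out
}

# Sample a random additive distance matrix from a random topology with
# positive branch lengths; returns the matrix and the generating tree.
random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.05, 1))
  tr$tip.label <- sprintf("t%d", seq_len(n_taxa))
  D <- stats::cophenetic(tr)
  D <- D[sort(rownames(D)), sort(colnames(D))]
  list(tree = tr, D = D)
}

same_unrooted_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}
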