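# Expansion-series assembly: nearest-duplicate selection, linear series
# within a species, and cross-species orthology series from block anchors.

.edge_better <- function(id1, fl1, ks1, p1, id2, fl2, ks2, p2) {
  # lexicographic: max identity, max flanking, min Ks, then partner id
  if (id1 != id2) return(id1 > id2)
  if (fl1 != fl2) return(fl1 > fl2)
  k1 <- ifelse(is.na(ks1), Inf, ks1); k2 <- ifelse(is.na(ks2), Inf, ks2)
  if (k1 != k2) return(k1 < k2)
  p1 < p2
}

#' Choose a gene's nearest duplicate
#'
#' Lexicographic choice among candidate partners: highest percent identity,
#' then most shared flanking block-anchor genes, then lowest Ks (undefined
#' Ks treated as +Inf and flagged), final ties by partner id.
#'
#' @param gene Gene id.
#' @param candidates data.frame with columns `partner`, `identity`,
#'   `flanking`, `ks`.
#' @return List: `gene`, `partner`, `identity`, `flanking`, `ks`,
#'   `ks_undefined` flag.
#' @export
nearest_duplicate <- function(gene, candidates) {
  stopifnot(nrow(candidates) >= 1,
            all(c("partner", "identity", "flanking", "ks") %in%
                names(candidates)))
  best <- 1L
  for (i in seq_len(nrow(candidates))[-1]) {
    if (.edge_better(candidates$identity[i], candidates$flanking[i],
                     candidates$ks[i], candidates$partner[i],
                     candidates$identity[best], candidates$flanking[best],
                     candidates$ks[best], candidates$partner[best]))
      best <- i
  }
  list(gene = gene, partner = candidates$partner[best],
       identity = candidates$identity[best],
       flanking = candidates$flanking[best],
       ks = candidates$ks[best],
       ks_undefined = is.na(candidates$ks[best]))
}

#' Count shared flanking block-anchor genes for a gene pair
#'
#' The number of non-family genes that are anchors in a block containing
#' both genes of the pair.
#'
#' @param a,b Gene ids.
#' @param blocks Output of [detect_collinear_chains()].
#' @param family_genes Character vector of family gene ids.
#' @return Integer count.
#' @export
shared_flanking_count <- function(a, b, blocks, family_genes) {
  n <- 0L
  for (bl in blocks) {
    members <- c(bl$anchors$a, bl$anchors$b)
    if (a %in% members && b %in% members)
      n <- n + length(setdiff(members, family_genes))
  }
  n
}

#' Assemble linear expansion series from nearest-duplicate edges
#'
#' Builds the undirected graph of nearest-duplicate edges; nodes of degree
#' above 2 keep their two best incident edges (same lexicographic criteria)
#' and drop the rest; cycles are broken at their worst edge; each remaining
#' component is a simple path reported as one series. Isolated genes become
#' length-1 series.
#'
#' @param edges data.frame `gene`, `partner`, `identity`, `flanking`, `ks`.
#' @param genes Optional character vector of all family genes (isolated
#'   ones become singleton series).
#' @return List of character vectors (ordered gene-id paths).
#' @export
assemble_expansion_series <- function(edges, genes = NULL) {
  if (nrow(edges) > 0) {
    key <- ifelse(edges$gene < edges$partner,
                  paste(edges$gene, edges$partner),
                  paste(edges$partner, edges$gene))
    ed <- edges[!duplicated(key), , drop = FALSE]
  } else ed <- edges
  nodes <- unique(c(ed$gene, ed$partner, genes))
  if (length(nodes) == 0) return(list())
  # edge quality for capping/cycle-breaking
  live <- rep(TRUE, nrow(ed))
  incident <- function(v) which(live & (ed$gene == v | ed$partner == v))
  edge_order <- function(ii) {
    # best first
    ord <- ii
    if (length(ii) > 1) {
      cmp <- sapply(ii, function(i) c(-ed$identity[i], -ed$flanking[i],
                                      ifelse(is.na(ed$ks[i]), Inf, ed$ks[i])))
      other <- ifelse(ed$gene[ii] == ed$gene[ii[1]], ed$partner[ii],
                      ed$gene[ii])
      ord <- ii[order(cmp[1, ], cmp[2, ], cmp[3, ],
                      pmin(ed$gene[ii], ed$partner[ii]),
                      pmax(ed$gene[ii], ed$partner[ii]))]
    }
    ord
  }
  # cap degree at 2
  repeat {
    deg <- table(factor(c(ed$gene[live], ed$partner[live]), levels = nodes))
    over <- names(deg)[deg > 2]
    if (length(over) == 0) break
    v <- over[1]
    ii <- edge_order(incident(v))
    live[ii[-(1:2)]] <- FALSE
  }
  g <- igraph::graph_from_data_frame(
    ed[live, c("gene", "partner"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = nodes))
  # break cycles at the worst live edge of each cyclic component
  repeat {
    comp <- igraph::components(g)
    cyc <- NULL
    for (ci in seq_len(comp$no)) {
      vs <- names(comp$membership)[comp$membership == ci]
      sub <- igraph::induced_subgraph(g, vs)
      if (igraph::ecount(sub) >= igraph::vcount(sub)) { cyc <- vs; break }
    }
    if (is.null(cyc)) break
    ii <- which(live & (ed$gene %in% cyc | ed$partner %in% cyc))
    worst <- rev(edge_order(ii))[1]
    live[worst] <- FALSE
    g <- igraph::delete_edges(g, paste(ed$gene[worst], ed$partner[worst],
                                       sep = "|"))
  }
  comp <- igraph::components(g)
  series <- lapply(seq_len(comp$no), function(ci) {
    vs <- names(comp$membership)[comp$membership == ci]
    if (length(vs) == 1) return(vs)
    sub <- igraph::induced_subgraph(g, vs)
    ends <- names(which(igraph::degree(sub) == 1))
    start <- sort(ends)[1]
    path <- names(unlist(
      igraph::shortest_paths(sub, from = start,
                             to = sort(ends)[2])$vpath[[1]]))
    if (is.null(path) || length(path) == 0)
      path <- igraph::V(sub)$name
    path
  })
  series[order(vapply(series, `[`, character(1), 1))]
}

#' Build cross-species orthology series from inter-genome block anchors
#'
#' Anchor pairs restricted to family genes form a graph; connected
#' components spanning at least two species become series (ordered along
#' `species_order`); components spanning every species flag their members
#' as ancestral anchors.
#'
#' @param family_genes data.frame `gene_id`, `species`.
#' @param blocks Inter-genome blocks ([detect_collinear_chains()] output).
#' @param species_order Character vector of species, the reporting order.
#' @return data.frame: one row per series, one column per species (gene ids
#'   joined by `,`, gap = `"."`), plus `ancestral` flag.
#' @export
build_orthology_series <- function(family_genes, blocks, species_order) {
  fam <- family_genes$gene_id
  sp <- stats::setNames(family_genes$species, family_genes$gene_id)
  ed <- do.call(rbind, lapply(blocks, function(b)
    b$anchors[b$anchors$a %in% fam & b$anchors$b %in% fam, , drop = FALSE]))
  if (is.null(ed) || nrow(ed) == 0)
    return(cbind(stats::setNames(
      data.frame(matrix(character(0), 0, length(species_order))),
      species_order), data.frame(ancestral = logical(0))))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  comp <- igraph::components(g)$membership
  rows <- lapply(split(names(comp), comp), function(members) {
    spans <- unique(sp[members])
    if (length(spans) < 2) return(NULL)
    entries <- vapply(species_order, function(s) {
      m <- sort(members[sp[members] == s])
      if (length(m) == 0) "." else paste(m, collapse = ",")
    }, character(1))
    c(entries, ancestral = all(species_order %in% spans))
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0)
    return(cbind(stats::setNames(
      data.frame(matrix(character(0), 0, length(species_order))),
      species_order), data.frame(ancestral = logical(0))))
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  out$ancestral <- as.logical(out$ancestral)
  rownames(out) <- NULL
  out
}
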