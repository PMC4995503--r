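# Family identification: ORF-integrity (pseudogene) filtering, PSSM domain
# scans, domain-architecture calls and domain-loss statistics.

#' Canonical GLR domain names
#'
#' The seven domains of the family's modular architecture: amino-terminal
#' domain, first ligand-binding lobe, trans-membrane segments M1-M4 with
#' the M2 pore loop, and second ligand-binding lobe.
#'
#' @format Character vector of length 7.
#' @export
GLR_DOMAINS <- c("ATD", "GlnH1", "M1", "M2_Pore", "M3", "GlnH2", "M4")

#' Check ORF integrity of a CDS (pseudogene filter)
#'
#' Verdicts are checked in fixed order, first hit wins: `frameshift` when the
#' length is not a multiple of 3; `premature_stop` when an in-frame stop
#' occurs before the final codon; `short_fragment` when the translated
#' length falls below `min_fraction` of the family reference length;
#' otherwise `complete`.
#'
#' @param cds CDS string (A,C,G,T,N) or a single-row record data.frame.
#' @param family_length_reference Reference protein length (residues).
#' @param min_fraction Short-fragment threshold (default 0.5).
#' @return List: `verdict`, `evidence` (named list; empty when complete).
#' @export
check_orf_integrity <- function(cds, family_length_reference,
                                min_fraction = 0.5) {
  if (is.data.frame(cds)) cds <- cds$residues[1]
  if (is.null(cds) || !nzchar(cds)) stop("empty CDS")
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3 != 0)
    return(list(verdict = "frameshift",
                evidence = list(length_mod_3 = n %% 3)))
  aa <- translate_cds(cds)
  stops <- gregexpr("\\*", aa)[[1]]
  n_codons <- nchar(aa)
  internal <- stops[stops > 0 & stops < n_codons]
  if (length(internal) > 0)
    return(list(verdict = "premature_stop",
                evidence = list(stop_codon = internal[1])))
  translated <- n_codons - as.integer(substr(aa, n_codons, n_codons) == "*")
  ratio <- translated / family_length_reference
  if (ratio < min_fraction)
    return(list(verdict = "short_fragment",
                evidence = list(length_ratio = ratio)))
  list(verdict = "complete", evidence = list())
}

#' Pseudogene calls for a set of CDS records
#'
#' @param cds_records data.frame of CDS records (`id`, `residues`).
#' @param family_length_reference Reference protein length; default is the
#'   median translated length of the inputs.
#' @param min_fraction Short-fragment threshold.
#' @return data.frame gene_id / verdict / evidence.
#' @export
call_pseudogenes <- function(cds_records, family_length_reference = NULL,
                             min_fraction = 0.5) {
  if (is.null(family_length_reference)) {
    lens <- floor(nchar(cds_records$residues) / 3)
    family_length_reference <- stats::median(lens)
  }
  calls <- lapply(cds_records$residues, check_orf_integrity,
                  family_length_reference = family_length_reference,
                  min_fraction = min_fraction)
  data.frame(gene_id = cds_records$id,
             verdict = vapply(calls, `[[`, character(1), "verdict"),
             evidence = vapply(calls, function(x)
               if (length(x$evidence) == 0) "." else
                 paste(names(x$evidence), unlist(x$evidence), sep = "=",
                       collapse = ";"), character(1)),
             stringsAsFactors = FALSE)
}

#' Filter accounting: candidates minus pseudogenes
#'
#' @param n_candidates Number of screened candidates.
#' @param pseudogenes Either the number of pseudogene calls or a data.frame
#'   from [call_pseudogenes()] (non-`complete` rows counted).
#' @return List: `candidates`, `pseudogenes`, `retained`.
#' @export
pseudogene_accounting <- function(n_candidates, pseudogenes) {
  n_pseudo <- if (is.data.frame(pseudogenes))
    sum(pseudogenes$verdict != "complete") else as.integer(pseudogenes)
  stopifnot(n_pseudo <= n_candidates)
  list(candidates = as.integer(n_candidates), pseudogenes = n_pseudo,
       retained = as.integer(n_candidates) - n_pseudo)
}

#' Build a position-specific scoring matrix from a seed alignment
#'
#' Position probabilities are `(count + pseudocount * background) /
#' (n + pseudocount)`; scores are log-odds against the background.
#'
#' @param seed_rows Named character vector of equal-length (ungapped or
#'   gapped; gap columns are kept and treated as missing observations)
#'   protein rows.
#' @param pseudocount Total pseudocount mass (default 1).
#' @param background Residue background frequencies (default uniform 1/20).
#' @param threshold Optional score threshold; see
#'   [calibrate_pssm_threshold()].
#' @return A `pssm`: list with `logodds` (L x 20 matrix), `background`,
#'   `threshold`.
#' @export
build_pssm <- function(seed_rows, pseudocount = 1, background = NULL,
                       threshold = -Inf) {
  stopifnot(length(seed_rows) >= 1)
  lens <- nchar(seed_rows)
  stopifnot(length(unique(lens)) == 1)
  if (is.null(background))
    background <- stats::setNames(rep(1 / 20, 20), AMINO_ACIDS)
  m <- do.call(rbind, strsplit(seed_rows, ""))
  L <- ncol(m)
  probs <- matrix(0, L, 20, dimnames = list(NULL, AMINO_ACIDS))
  for (j in seq_len(L)) {
    col <- m[, j]
    col <- col[col %in% AMINO_ACIDS]
    n <- length(col)
    cnt <- table(factor(col, levels = AMINO_ACIDS))
    probs[j, ] <- (as.numeric(cnt) + pseudocount * background) /
      (n + pseudocount)
  }
  stopifnot(abs(rowSums(probs) - 1) < 1e-9)
  structure(list(logodds = log(probs / rep(background, each = L)),
                 background = background, threshold = threshold,
                 length = L),
            class = "pssm")
}

#' Scan a protein with a PSSM
#'
#' Best-scoring ungapped window over the protein. Residues outside the
#' 20-letter alphabet (X) contribute 0.
#'
#' @param protein Protein string.
#' @param pssm A [build_pssm()] object.
#' @return List: `score`, `start`, `end`, `present` (score >= threshold).
#'   Proteins shorter than the motif give score `-Inf`, absent.
#' @export
scan_pssm <- function(protein, pssm) {
  stopifnot(inherits(pssm, "pssm"))
  v <- strsplit(protein, "")[[1]]
  L <- pssm$length
  n <- length(v)
  if (n < L)
    return(list(score = -Inf, start = NA_integer_, end = NA_integer_,
                present = FALSE))
  idx <- match(v, AMINO_ACIDS)
  best <- -Inf; best_s <- NA_integer_
  for (s in seq_len(n - L + 1L)) {
    ii <- idx[s:(s + L - 1L)]
    ok <- !is.na(ii)
    sc <- sum(pssm$logodds[cbind(which(ok), ii[ok])])
    if (sc > best) { best <- sc; best_s <- s }
  }
  list(score = best, start = best_s, end = best_s + L - 1L,
       present = best >= pssm$threshold)
}

#' Calibrate a PSSM presence threshold from a shuffled-sequence null
#'
#' Scores the PSSM against residue-shuffled versions of the input proteins
#' and returns the given quantile of the null score distribution.
#'
#' @param pssm A PSSM.
#' @param proteins Character vector of protein sequences.
#' @param n_shuffles Shuffles per protein.
#' @param quantile Null quantile (default 0.99).
#' @param seed Integer seed.
#' @return Numeric threshold.
#' @export
calibrate_pssm_threshold <- function(pssm, proteins, n_shuffles = 20,
                                     quantile = 0.99, seed = 1) {
  set.seed(.substream_seed(seed, "calibrate_pssm_threshold"))
  null_scores <- unlist(lapply(proteins, function(p) {
    v <- strsplit(p, "")[[1]]
    vapply(seq_len(n_shuffles), function(i)
      scan_pssm(paste(sample(v), collapse = ""), pssm)$score, numeric(1))
  }))
  stats::quantile(null_scores, quantile, names = FALSE)
}

#' Call domain architecture for a protein
#'
#' One presence flag per domain PSSM; hit order along the protein is
#' reported but not enforced.
#'
#' @param protein Protein string.
#' @param pssms Named list of PSSMs (names = domain names).
#' @return data.frame domain / present / score / start / end, in input
#'   domain order.
#' @export
call_domain_architecture <- function(protein, pssms) {
  hits <- lapply(pssms, function(p) scan_pssm(protein, p))
  data.frame(domain = names(pssms),
             present = vapply(hits, `[[`, logical(1), "present"),
             score = vapply(hits, `[[`, numeric(1), "score"),
             start = vapply(hits, `[[`, integer(1), "start"),
             end = vapply(hits, `[[`, integer(1), "end"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Domain-loss statistics
#'
#' Loss rate of a domain is the fraction of genes lacking it; a subfamily's
#' share is its fraction of all loss events.
#'
#' @param architectures Named list (gene id ->
#'   [call_domain_architecture()] data.frame) or a long data.frame with
#'   columns gene_id / domain / present.
#' @param subfamilies Named character vector: gene id -> subfamily label.
#' @return List of data.frames: `per_domain` (domain, loss_rate),
#'   `per_subfamily` (subfamily, loss_events, share; share is `"."` when no
#'   losses), `per_domain_subfamily` (domain, subfamily, rate).
#' @export
domain_loss_rates <- function(architectures, subfamilies) {
  if (is.data.frame(architectures)) long <- architectures
  else {
    long <- do.call(rbind, lapply(names(architectures), function(g)
      cbind(gene_id = g, architectures[[g]][, c("domain", "present")])))
  }
  long$subfamily <- unname(subfamilies[long$gene_id])
  stopifnot(!any(is.na(long$subfamily)))
  genes <- unique(long$gene_id)
  doms <- unique(long$domain)
  per_domain <- data.frame(
    domain = doms,
    loss_rate = vapply(doms, function(d)
      sum(!long$present[long$domain == d]) / length(genes), numeric(1)),
    row.names = NULL)
  losses <- long[!long$present, , drop = FALSE]
  subs <- sort(unique(long$subfamily))
  cnt <- vapply(subs, function(s) sum(losses$subfamily == s), numeric(1))
  per_subfamily <- data.frame(
    subfamily = subs, loss_events = cnt,
    share = if (sum(cnt) == 0) rep(".", length(subs))
            else format(cnt / sum(cnt), digits = 6),
    row.names = NULL, stringsAsFactors = FALSE)
  grid <- expand.grid(domain = doms, subfamily = subs,
                      stringsAsFactors = FALSE)
  grid$rate <- mapply(function(d, s) {
    in_s <- unique(long$gene_id[long$subfamily == s])
    if (length(in_s) == 0) return(NA_real_)
    sum(!long$present[long$domain == d & long$subfamily == s]) / length(in_s)
  }, grid$domain, grid$subfamily)
  list(per_domain = per_domain, per_subfamily = per_subfamily,
       per_domain_subfamily = grid)
}
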