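# Physico-chemical conservation profiling, group identity, and intron
# projection onto protein alignments.

#' Conservation index of one alignment column
#'
#' Counts the physico-chemical property classes on which every row agrees
#' (all members, or all non-members). Gaps and X belong to no class, so a
#' gap breaks agreement for every property the other residues share while
#' preserving agreement on properties they all lack. The index is capped at
#' 10 (no identity bonus).
#'
#' @param column Character vector of residues (one per row) or a single
#'   string.
#' @param table Property table (default [property_table()]).
#' @return Integer 0..10.
#' @export
column_conservation_index <- function(column, table = property_table()) {
  if (length(column) == 1 && nchar(column) > 1)
    column <- strsplit(column, "")[[1]]
  stopifnot(length(column) >= 1)
  member <- matrix(FALSE, nrow(table), length(column),
                   dimnames = list(rownames(table), NULL))
  known <- column %in% colnames(table)
  member[, known] <- table[, column[known], drop = FALSE]
  agree <- apply(member, 1, function(x) all(x) || all(!x))
  sum(agree)
}

#' Per-column conservation profile of an alignment
#'
#' @param rows Named character vector of equal-length gapped protein rows.
#' @param table Property table.
#' @return Integer vector, one index per column.
#' @export
conservation_profile <- function(rows, table = property_table()) {
  stopifnot(length(rows) >= 1, length(unique(nchar(rows))) == 1)
  m <- do.call(rbind, strsplit(rows, ""))
  apply(m, 2, column_conservation_index, table = table)
}

#' Sliding-window means of a conservation profile
#'
#' Windows start at columns 1, 1+slide, 1+2*slide, ...; a final window
#' shorter than `window` is truncated and flagged.
#'
#' @param profile Numeric vector of per-column indices.
#' @param window Window size in columns (default 20).
#' @param slide Step in columns (default 10).
#' @return data.frame `start`, `end`, `mean`, `truncated`.
#' @export
sliding_window_profile <- function(profile, window = 20, slide = 10) {
  L <- length(profile)
  stopifnot(L >= 1, window >= 1, slide >= 1)
  starts <- seq(1L, max(1L, L - window + 1L), by = slide)
  starts <- starts[starts + window - 1L <= L]
  if (length(starts) == 0L) starts <- integer(0)
  last_end <- if (length(starts)) starts[length(starts)] + window - 1L else 0L
  trunc_start <- if (last_end < L)
    (if (length(starts)) starts[length(starts)] + slide else 1L)
  else integer(0)
  all_starts <- c(starts, trunc_start[trunc_start <= L])
  out <- do.call(rbind, lapply(all_starts, function(s) {
    e <- min(s + window - 1L, L)
    data.frame(start = s, end = e, mean = mean(profile[s:e]),
               truncated = (e - s + 1L) < window)
  }))
  rownames(out) <- NULL
  out
}

#' Mean conservation index over a column interval
#'
#' @param profile Per-column indices.
#' @param interval `c(start, end)` (1-based, inclusive).
#' @return Mean index.
#' @export
region_mean <- function(profile, interval) {
  stopifnot(interval[1] >= 1, interval[2] <= length(profile),
            interval[1] <= interval[2])
  mean(profile[interval[1]:interval[2]])
}

.row_pid <- function(a, b, denominator = c("both_ungapped", "all_columns")) {
  denominator <- match.arg(denominator)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  both <- av != "-" & bv != "-"
  denom <- if (denominator == "both_ungapped") sum(both)
           else sum(av != "-" | bv != "-")
  if (denom == 0) return(NA_real_)
  100 * sum(av[both] == bv[both]) / denom
}

.consensus_row <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  apply(m, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) return("-")
    tb <- sort(table(col), decreasing = TRUE)
    names(tb)[1]
  })
}

#' Percent identity between two groups of aligned sequences
#'
#' `mean_pairwise` averages pairwise percent identity over all cross-group
#' pairs; `consensus` compares the two group majority-consensus strings.
#' The identity denominator is configurable because the statistic's
#' definition is convention-dependent: by default columns where either row
#' is gapped are excluded.
#'
#' @param rows Named character vector of aligned rows.
#' @param group_a,group_b Character vectors of row ids.
#' @param mode `"mean_pairwise"` (default) or `"consensus"`.
#' @param denominator `"both_ungapped"` (default) or `"all_columns"`.
#' @return Percent identity (0-100).
#' @export
group_identity <- function(rows, group_a, group_b,
                           mode = c("mean_pairwise", "consensus"),
                           denominator = c("both_ungapped", "all_columns")) {
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  stopifnot(all(c(group_a, group_b) %in% names(rows)))
  if (mode == "mean_pairwise") {
    vals <- outer(group_a, group_b, Vectorize(function(a, b)
      .row_pid(rows[[a]], rows[[b]], denominator)))
    return(mean(vals, na.rm = TRUE))
  }
  ca <- paste(.consensus_row(rows[group_a]), collapse = "")
  cb <- paste(.consensus_row(rows[group_b]), collapse = "")
  .row_pid(ca, cb, denominator)
}

#' Project CDS-relative intron positions onto a protein alignment
#'
#' An intron after CDS nucleotide `n` maps to protein residue
#' `floor(n/3) + 1` with phase `n mod 3`, then to that residue's alignment
#' column through the gapped row.
#'
#' @param models data.frame `gene_id`, `cds_offset` (nucleotides before the
#'   intron).
#' @param alignment Named character vector of gapped protein rows.
#' @return data.frame `gene_id`, `column` (1-based alignment column),
#'   `phase` (0/1/2).
#' @export
project_introns <- function(models, alignment) {
  out <- lapply(seq_len(nrow(models)), function(i) {
    id <- models$gene_id[i]
    n <- models$cds_offset[i]
    if (!id %in% names(alignment)) stop("gene not in alignment: ", id)
    chars <- strsplit(alignment[[id]], "")[[1]]
    res_cols <- which(chars != "-")
    residue <- n %/% 3L + 1L
    phase <- n %% 3L
    if (residue > length(res_cols))
      stop("intron offset ", n, " beyond CDS of ", id)
    data.frame(gene_id = id, column = res_cols[residue], phase = phase)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Conserved intron positions across genes
#'
#' A column/phase combination is conserved when at least `min_fraction` of
#' the genes carry an intron mark there.
#'
#' @param marks [project_introns()] output.
#' @param n_genes Total number of genes considered.
#' @param min_fraction Fraction of genes required (default 1.0).
#' @param require_same_phase Group marks by column and phase (default) or
#'   by column only.
#' @return data.frame `column`, `phase` (NA when phases not required and
#'   mixed), `n_genes`, `members` (comma-joined gene ids).
#' @export
conserved_intron_positions <- function(marks, n_genes, min_fraction = 1.0,
                                       require_same_phase = TRUE) {
  if (nrow(marks) == 0)
    return(data.frame(column = integer(0), phase = integer(0),
                      n_genes = integer(0), members = character(0)))
  key <- if (require_same_phase) paste(marks$column, marks$phase)
         else as.character(marks$column)
  out <- lapply(split(marks, key), function(grp) {
    genes <- unique(grp$gene_id)
    if (length(genes) < min_fraction * n_genes) return(NULL)
    data.frame(column = grp$column[1],
               phase = if (require_same_phase) grp$phase[1]
                       else if (length(unique(grp$phase)) == 1) grp$phase[1]
                       else NA_integer_,
               n_genes = length(genes),
               members = paste(sort(genes), collapse = ","))
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(out))
    return(data.frame(column = integer(0), phase = integer(0),
                      n_genes = integer(0), members = character(0)))
  out <- out[order(out$column, out$phase), , drop = FALSE]
  rownames(out) <- NULL
  out
}
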