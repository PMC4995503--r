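# Readers/writers for the standard formats (FASTA, BED/GFF3, Newick) and
# pairwise alignment. Sequence sets are plain data.frames with columns
# id / kind / residues; gene sets are data.frames with ranked coordinates.

#' Read a FASTA file into a sequence-record table
#'
#' @param path Path to a FASTA file.
#' @param kind One of `"protein"`, `"cds"`, `"intron"`; stored per record.
#' @return data.frame with columns `id`, `kind`, `residues`.
#' @export
read_fasta <- function(path, kind = "protein") {
  stopifnot(file.exists(path))
  kind <- match.arg(kind, c("protein", "cds", "intron"))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path,
                                           ": ", conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(id = ids, kind = kind, residues = as.character(set),
             stringsAsFactors = FALSE)
}

#' Write sequence records as FASTA
#'
#' @param records data.frame with `id` and `residues` columns.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  stopifnot(nrow(records) > 0L)
  if (anyDuplicated(records$id))
    stop("duplicate ids in records")
  set <- Biostrings::BStringSet(stats::setNames(records$residues, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

.assign_ranks <- function(df) {
  # per-chromosome 0-based ranks ordered by start; ties by end then id
  ord <- order(df$chromosome, df$start, df$end, df$id, method = "radix")
  df <- df[ord, , drop = FALSE]
  df$rank <- stats::ave(seq_len(nrow(df)), df$chromosome,
                        FUN = function(i) seq_along(i) - 1L)
  rownames(df) <- NULL
  df
}

#' Build a gene set from coordinates
#'
#' Internal coordinates are 1-based inclusive. Ranks are 0-based positions
#' among genes on the same chromosome ordered by start (ties broken by
#' ascending end, then id).
#'
#' @param genes data.frame with columns `id`, `chromosome`, `start`, `end`,
#'   `strand`.
#' @param species Species label.
#' @return A `gene_set`: data.frame with an added `rank` column and a
#'   `species` attribute.
#' @export
gene_set <- function(genes, species = "unknown") {
  stopifnot(all(c("id", "chromosome", "start", "end", "strand") %in%
                names(genes)))
  if (anyDuplicated(genes$id))
    stop("duplicate gene ids: ",
         paste(unique(genes$id[duplicated(genes$id)]), collapse = ", "))
  if (any(genes$end < genes$start))
    stop("end < start for gene(s): ",
         paste(genes$id[genes$end < genes$start], collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  gs <- .assign_ranks(genes[, c("id", "chromosome", "start", "end", "strand")])
  attr(gs, "species") <- species
  class(gs) <- c("gene_set", "data.frame")
  gs
}

#' Read gene positions from BED or GFF3
#'
#' BED is 0-based half-open and converted on read; GFF3 is taken as 1-based
#' inclusive. For GFF3 only `gene` features are used (all features if none is
#' typed `gene`), identified by their `ID` (or `Name`) attribute.
#'
#' @param path Input file.
#' @param format `"bed"` or `"gff3"`.
#' @param species Species label for the resulting gene set.
#' @return A `gene_set`.
#' @export
read_gene_positions <- function(path, format = c("bed", "gff3"),
                                species = "unknown") {
  stopifnot(file.exists(path))
  format <- match.arg(format)
  gr <- if (format == "bed") rtracklayer::import(path, format = "BED")
        else rtracklayer::import(path, format = "GFF3")
  if (format == "gff3") {
    type <- as.character(gr$type)
    if (any(type == "gene")) gr <- gr[type == "gene"]
    ids <- if (!is.null(gr$ID) && !all(is.na(gr$ID))) as.character(gr$ID)
           else as.character(gr$Name)
  } else {
    ids <- as.character(gr$name)
  }
  if (any(is.na(ids)) || any(!nzchar(ids)))
    stop("missing gene identifiers in ", path)
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  genes <- data.frame(id = ids,
                      chromosome = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      strand = strand, stringsAsFactors = FALSE)
  gene_set(genes, species = species)
}

#' Write a gene set as BED (0-based half-open)
#'
#' @param gs A `gene_set`.
#' @param path Output path.
#' @export
write_gene_positions <- function(gs, path) {
  bed <- data.frame(chrom = gs$chromosome, start = gs$start - 1L,
                    end = gs$end, name = gs$id, score = ".",
                    strand = gs$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers over \pkg{ape} keeping branch lengths and integer node
#' supports.
#'
#' @param path File path.
#' @return `read_newick`: an \pkg{ape} `phylo` object.
#' @export
read_newick <- function(path) {
  stopifnot(file.exists(path))
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  tr
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Pairwise sequence alignment (Needleman-Wunsch / Smith-Waterman)
#'
#' Affine-gap pairwise alignment via \pkg{Biostrings}. Percent identity is
#' the number of identical aligned residue pairs over columns where both rows
#' are non-gap (x100).
#'
#' @param a,b Sequence strings (or single-row record data.frames).
#' @param mode `"global"` or `"local"`.
#' @param substitution Substitution matrix name or matrix (default BLOSUM62
#'   for proteins).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param type Alphabet, `"protein"` or `"nucleotide"`.
#' @return List with `a_aln`, `b_aln` (gapped rows), `score`,
#'   `percent_identity`.
#' @export
pairwise_align <- function(a, b, mode = c("global", "local"),
                           substitution = NULL,
                           gap_open = 10, gap_extend = 1,
                           type = c("protein", "nucleotide")) {
  if (is.data.frame(a)) a <- a$residues[1]
  if (is.data.frame(b)) b <- b$residues[1]
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  mode <- match.arg(mode)
  type <- match.arg(type)
  if (is.null(substitution)) {
    substitution <- if (type == "protein") "BLOSUM62" else
      Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                               baseOnly = TRUE)
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b,
    type = if (mode == "global") "global" else "local",
    substitutionMatrix = substitution,
    gapOpening = gap_open, gapExtension = gap_extend)
  arow <- as.character(Biostrings::alignedPattern(pa))
  brow <- as.character(Biostrings::alignedSubject(pa))
  av <- strsplit(arow, "")[[1]]
  bv <- strsplit(brow, "")[[1]]
  both <- av != "-" & bv != "-"
  pid <- if (any(both)) 100 * sum(av[both] == bv[both]) / sum(both) else 0
  list(a_aln = arow, b_aln = brow, score = Biostrings::score(pa),
       percent_identity = pid)
}
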