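# Static lookup tables: universal genetic code over the 61 sense codons and
# the Livingstone-Barton physico-chemical residue classes.

BASES <- c("T", "C", "A", "G")

#' Universal genetic code
#'
#' Named character vector mapping all 64 codons to one-letter amino acids,
#' with `*` for the three stop codons.
#'
#' @return Named character vector of length 64.
#' @export
genetic_code <- function() {
  aa <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"
  codons <- character(64)
  k <- 0L
  for (b1 in BASES) for (b2 in BASES) for (b3 in BASES) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(strsplit(aa, "")[[1]], codons)
}

#' The 61 sense codons (universal code), in fixed order
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

#' Translate a CDS string
#'
#' @param cds Nucleotide string over A,C,G,T,N; length need not be a multiple
#'   of 3 (trailing partial codon is dropped).
#' @return One-letter amino-acid string; `*` marks stops, `X` marks codons
#'   containing N.
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L, nzchar(cds))
  cds <- toupper(cds)
  n <- nchar(cds) %/% 3L
  if (n == 0L) return("")
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  gc <- genetic_code()
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Livingstone & Barton (AMAS) residue property classes, as used by the
# Jalview conservation shading. Gap and X belong to no class.
.PROPERTY_CLASSES <- list(
  hydrophobic = c("A", "C", "F", "G", "H", "I", "K", "L", "M", "T", "V", "W", "Y"),
  polar       = c("C", "D", "E", "H", "K", "N", "Q", "R", "S", "T", "W", "Y"),
  small       = c("A", "C", "D", "G", "N", "P", "S", "T", "V"),
  tiny        = c("A", "G", "S"),
  aliphatic   = c("I", "L", "V"),
  aromatic    = c("F", "H", "W", "Y"),
  positive    = c("H", "K", "R"),
  negative    = c("D", "E"),
  charged     = c("D", "E", "H", "K", "R"),
  proline     = c("P")
)

#' Physico-chemical property table
#'
#' Membership of the 20 amino acids in the 10 Livingstone-Barton property
#' classes used for conservation scoring.
#'
#' @return Logical matrix, 10 properties x 20 residues.
#' @export
property_table <- function() {
  residues <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  m <- sapply(residues, function(r)
    vapply(.PROPERTY_CLASSES, function(cls) r %in% cls, logical(1)))
  rownames(m) <- names(.PROPERTY_CLASSES)
  m
}
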