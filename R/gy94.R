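# GY94 (M0) codon substitution machinery: rate matrix over the 61 sense
# codons, transition probabilities via symmetric eigendecomposition (the
# model is time-reversible), and codon frequency estimation (F3x4).

.gy94_cache <- new.env(parent = emptyenv())

# Pairwise codon relations: for each ordered sense-codon pair, whether they
# differ at exactly one position, whether that change is a transition, and
# whether it is synonymous. Computed once.
.codon_relations <- function() {
  if (!is.null(.gy94_cache$rel)) return(.gy94_cache$rel)
  cod <- sense_codons()
  gc <- genetic_code()
  n <- length(cod)
  mat <- matrix(strsplit(paste(cod, collapse = ""), "")[[1]], nrow = n,
                ncol = 3, byrow = TRUE)
  one_diff <- matrix(FALSE, n, n)
  is_ts <- matrix(FALSE, n, n)
  is_syn <- matrix(FALSE, n, n)
  ts_pair <- function(x, y) (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "T") | (x == "T" & y == "C")
  for (p in 1:3) {
    same_other <- Reduce(`&`, lapply(setdiff(1:3, p), function(q)
      outer(mat[, q], mat[, q], `==`)))
    diff_p <- outer(mat[, p], mat[, p], `!=`)
    hit <- same_other & diff_p
    one_diff <- one_diff | hit
    is_ts[hit] <- outer(mat[, p], mat[, p], ts_pair)[hit]
  }
  aa <- gc[cod]
  is_syn <- outer(aa, aa, `==`)
  diag(one_diff) <- FALSE
  rel <- list(codons = cod, one_diff = one_diff, is_ts = is_ts,
              is_syn = is_syn)
  .gy94_cache$rel <- rel
  rel
}

# Normalized GY94 rate matrix (expected substitutions per codon per unit t).
.gy94_Q <- function(kappa, omega, pi) {
  rel <- .codon_relations()
  f <- matrix(0, 61, 61)
  f[rel$one_diff] <- 1
  f[rel$one_diff & rel$is_ts] <- kappa
  f[rel$one_diff & !rel$is_syn] <- f[rel$one_diff & !rel$is_syn] * omega
  Q <- f * rep(pi, each = 61)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  list(Q = Q / mu, mu = mu, f = f)
}

# Spectral form of Q for fast P(t) at many t.
.gy94_eigen <- function(kappa, omega, pi) {
  qq <- .gy94_Q(kappa, omega, pi)
  sp <- sqrt(pi)
  B <- qq$Q * outer(sp, 1 / sp)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = e$vectors, lambda = e$values, sp = sp, Q = qq$Q, f = qq$f)
}

.gy94_P <- function(eg, t) {
  M <- eg$U %*% (t(eg$U) * exp(eg$lambda * t))
  P <- M * outer(1 / eg$sp, eg$sp)
  P[P < 0] <- 0
  P / rowSums(P)
}

.check_pi <- function(pi) {
  stopifnot(length(pi) == 61, all(pi >= 0))
  pi <- pmax(pi, 1e-8)
  pi / sum(pi)
}

#' F3x4 codon frequencies from codon data
#'
#' Position-specific base frequencies are estimated from all codons in the
#' input rows; sense-codon frequencies are the product over the three
#' positions, renormalized after removing stops.
#'
#' @param rows Character vector of codon sequences (no gaps).
#' @return Numeric vector of 61 frequencies (order of [sense_codons()]).
#' @export
f3x4_frequencies <- function(rows) {
  chars <- strsplit(paste(toupper(rows), collapse = ""), "")[[1]]
  stopifnot(length(chars) %% 3 == 0)
  pos <- rep_len(1:3, length(chars))
  freq <- sapply(1:3, function(p) {
    tb <- table(factor(chars[pos == p], levels = c("T", "C", "A", "G")))
    (tb + 0.5) / sum(tb + 0.5)  # small prior keeps frequencies positive
  })
  cod <- sense_codons()
  pi <- vapply(cod, function(cd) {
    b <- strsplit(cd, "")[[1]]
    freq[b[1], 1] * freq[b[2], 2] * freq[b[3], 3]
  }, numeric(1))
  unname(pi / sum(pi))
}

# Split codon string into codon vector; error on partial codons or gaps.
.codon_split <- function(x) {
  x <- toupper(x)
  if (nchar(x) %% 3 != 0) stop("sequence length not a multiple of 3")
  substring(x, 3 * seq_len(nchar(x) %/% 3) - 2, 3 * seq_len(nchar(x) %/% 3))
}
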