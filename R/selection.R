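# dN/dS estimation: codon-alignment construction, Nei-Gojobori (1986)
# counting with pathway averaging, and GY94/M0 pairwise maximum likelihood.

.strip_terminal_stop <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n >= 3 && substr(cds, n - 2, n) %in% c("TAA", "TAG", "TGA"))
    cds <- substr(cds, 1, n - 3)
  cds
}

#' Build a gap-free codon alignment from a protein alignment and CDS
#'
#' Each protein column expands to one codon column guided by the aligned
#' protein rows; columns containing any gap are then deleted. Each CDS must
#' translate (universal code, terminal stop stripped) to its ungapped
#' protein row.
#'
#' @param protein_rows Named character vector of gapped protein rows.
#' @param cds_records Sequence-record data.frame with matching ids.
#' @return Named character vector of equal-length gap-free codon sequences.
#' @export
build_codon_alignment <- function(protein_rows, cds_records) {
  ids <- names(protein_rows)
  stopifnot(all(ids %in% cds_records$id))
  cds <- stats::setNames(cds_records$residues, cds_records$id)[ids]
  cds <- vapply(cds, .strip_terminal_stop, character(1))
  L <- unique(nchar(protein_rows))
  stopifnot(length(L) == 1)
  codon_rows <- matrix("", length(ids), L, dimnames = list(ids, NULL))
  for (id in ids) {
    prot <- gsub("-", "", protein_rows[[id]])
    aa <- translate_cds(cds[[id]])
    if (grepl("\\*", aa))
      stop("internal stop codon in CDS of ", id, " at codon ",
           regexpr("\\*", aa))
    if (aa != prot) {
      pos <- which(strsplit(aa, "")[[1]] != strsplit(prot, "")[[1]])[1]
      stop("CDS of ", id, " does not translate to its protein row ",
           "(first mismatch at residue ", pos, ")")
    }
    chars <- strsplit(protein_rows[[id]], "")[[1]]
    k <- 0L
    for (j in seq_len(L)) {
      if (chars[j] == "-") codon_rows[id, j] <- "---"
      else {
        k <- k + 1L
        codon_rows[id, j] <- substr(cds[[id]], 3L * k - 2L, 3L * k)
      }
    }
  }
  keep <- apply(codon_rows, 2, function(col) !any(col == "---"))
  apply(codon_rows[, keep, drop = FALSE], 1, paste, collapse = "")
}

# --- NG86 -------------------------------------------------------------------

.ng86_cache <- new.env(parent = emptyenv())

# Synonymous site count of each sense codon (stop changes count as
# nonsynonymous so S + N = 3 exactly).
.ng86_sites <- function() {
  if (!is.null(.ng86_cache$sites)) return(.ng86_cache$sites)
  gc <- genetic_code()
  cod <- sense_codons()
  s <- vapply(cod, function(cd) {
    b <- strsplit(cd, "")[[1]]
    syn <- 0
    for (p in 1:3) for (alt in setdiff(BASES, b[p])) {
      nb <- b; nb[p] <- alt
      ncd <- paste(nb, collapse = "")
      if (gc[[ncd]] != "*" && gc[[ncd]] == gc[[cd]]) syn <- syn + 1 / 3
    }
    syn
  }, numeric(1))
  .ng86_cache$sites <- s
  s
}

# Average synonymous/nonsynonymous differences between two codons over all
# minimal substitution pathways, excluding pathways through stop codons
# (all pathways used, flagged, if none avoids a stop).
.ng86_codon_diff <- function(c1, c2) {
  gc <- genetic_code()
  b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
  dpos <- which(b1 != b2)
  d <- length(dpos)
  if (d == 0) return(c(syn = 0, nonsyn = 0, stop_flag = 0))
  perms <- if (d == 1) list(dpos) else
    if (d == 2) list(dpos, rev(dpos)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2),
                  c(3,2,1)), function(o) dpos[o])
  count_path <- function(order) {
    cur <- b1; syn <- 0; nonsyn <- 0; ok <- TRUE
    for (p in order) {
      nxt <- cur; nxt[p] <- b2[p]
      a1 <- gc[[paste(cur, collapse = "")]]
      a2 <- gc[[paste(nxt, collapse = "")]]
      if (a2 == "*" || a1 == "*") ok <- FALSE
      if (a1 == a2) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn, nonsyn, ok)
  }
  res <- vapply(perms, count_path, numeric(3))
  valid <- res[3, ] == 1
  flag <- 0
  if (!any(valid)) { valid <- rep(TRUE, ncol(res)); flag <- 1 }
  c(syn = mean(res[1, valid]), nonsyn = mean(res[2, valid]),
    stop_flag = flag)
}

.jc_correct <- function(p) {
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (1986) dN/dS for a codon sequence pair
#'
#' Site counts use the equal-weight mutation-fraction rule averaged over the
#' two sequences; differences are averaged over all minimal substitution
#' pathways (stop-passing pathways excluded); proportions are
#' Jukes-Cantor-corrected.
#'
#' @param row_a,row_b Gap-free codon sequences of equal length.
#' @return List: `method`, `dN`, `dS`, `omega`, `S`, `N`, `pS`, `pN`,
#'   `status` (`ok`, `saturated`, `undefined_dS`).
#' @export
ng86 <- function(row_a, row_b) {
  ca <- .codon_split(row_a); cb <- .codon_split(row_b)
  if (length(ca) != length(cb)) stop("codon sequence length mismatch")
  sites <- .ng86_sites()
  if (any(!c(ca, cb) %in% names(sites)))
    stop("stop codon or invalid codon in input")
  S <- (sum(sites[ca]) + sum(sites[cb])) / 2
  N <- 3 * length(ca) - S
  diffs <- vapply(seq_along(ca), function(i)
    .ng86_codon_diff(ca[i], cb[i]), numeric(3))
  Sd <- sum(diffs[1, ]); Nd <- sum(diffs[2, ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  dS <- .jc_correct(pS); dN <- .jc_correct(pN)
  status <- if (is.na(dS) || is.na(dN)) "saturated"
            else if (dS == 0) "undefined_dS" else "ok"
  list(method = "NG86", dN = dN, dS = dS,
       omega = if (status == "ok") dN / dS else NA_real_,
       S = S, N = N, pS = pS, pN = pN, status = status)
}

# --- M0 maximum likelihood --------------------------------------------------

.m0_counts <- function(row_a, row_b) {
  ca <- .codon_split(row_a); cb <- .codon_split(row_b)
  stopifnot(length(ca) == length(cb))
  cod <- sense_codons()
  ia <- match(ca, cod); ib <- match(cb, cod)
  if (anyNA(ia) || anyNA(ib)) stop("stop codon or invalid codon in input")
  cnt <- matrix(0, 61, 61)
  for (k in seq_along(ia)) cnt[ia[k], ib[k]] <- cnt[ia[k], ib[k]] + 1
  cnt
}

#' Fit the GY94/M0 model to a codon sequence pair by maximum likelihood
#'
#' Maximizes the pairwise M0 likelihood over (omega, kappa, t) by bounded
#' quasi-Newton optimization from `n_restarts` fixed starting points
#' (a deterministic spread; `seed` is accepted for interface stability but
#' the restarts themselves are not random). Transition probabilities come
#' from the spectral decomposition of the normalized reversible rate
#' matrix. dN and dS are decomposed from t via the model's synonymous and
#' nonsynonymous rate flows, with site proportions taken at omega = 1.
#'
#' @param rows Named character vector of two gap-free codon sequences, or a
#'   list with two elements.
#' @param codon_freq `"f3x4"` (estimated from the data; default),
#'   `"uniform"`, or a numeric vector of 61 frequencies.
#' @param n_restarts Number of starting points used (up to 3 distinct ones).
#' @param seed Unused source of randomness kept for interface stability.
#' @return List: `method`, `dN`, `dS`, `omega`, `kappa`, `t`, `lnL`,
#'   `status` (`ok` or `not_converged`).
#' @export
m0_fit <- function(rows, codon_freq = "f3x4", n_restarts = 3, seed = 1) {
  rows <- unlist(rows)
  stopifnot(length(rows) == 2)
  cnt <- .m0_counts(rows[[1]], rows[[2]])
  pi <- if (identical(codon_freq, "f3x4")) f3x4_frequencies(rows)
        else if (identical(codon_freq, "uniform")) rep(1 / 61, 61)
        else .check_pi(codon_freq)
  pi <- .check_pi(pi)
  cache <- new.env(parent = emptyenv())
  eig_for <- function(kappa, omega) {
    key <- sprintf("%.12g_%.12g", kappa, omega)
    if (is.null(cache[[key]])) cache[[key]] <- .gy94_eigen(kappa, omega, pi)
    cache[[key]]
  }
  nll <- function(par) {
    omega <- exp(par[1]); kappa <- exp(par[2]); tt <- exp(par[3])
    P <- .gy94_P(eig_for(kappa, omega), tt)
    ll <- sum(cnt * log(pmax(rep(pi, 61) * P, 1e-300)))
    -ll
  }
  starts <- list(c(0.2, 2, 0.3), c(1.0, 1, 1.0), c(3.0, 5, 0.1))
  starts <- starts[seq_len(min(n_restarts, length(starts)))]
  best <- NULL
  any_ok <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(log(s), nll, method = "L-BFGS-B",
                   lower = log(c(1e-4, 1e-2, 1e-4)),
                   upper = log(c(50, 100, 20)),
                   control = list(maxit = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) any_ok <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("M0 optimization failed from every start")
  omega <- exp(best$par[1]); kappa <- exp(best$par[2]); tt <- exp(best$par[3])
  # dN/dS decomposition via rate flows
  rel <- .codon_relations()
  qq <- .gy94_Q(kappa, omega, pi)
  flow <- pi * qq$Q
  syn_mask <- rel$one_diff & rel$is_syn
  nonsyn_mask <- rel$one_diff & !rel$is_syn
  Fs <- sum(flow[syn_mask]); Fn <- sum(flow[nonsyn_mask])
  q1 <- .gy94_Q(kappa, 1, pi)
  flow1 <- pi * q1$Q
  pS1 <- sum(flow1[syn_mask]); pN1 <- sum(flow1[nonsyn_mask])
  dS <- tt * Fs / (3 * pS1 / (pS1 + pN1))
  dN <- tt * Fn / (3 * pN1 / (pS1 + pN1))
  list(method = "M0", dN = dN, dS = dS, omega = omega, kappa = kappa,
       t = tt, lnL = -best$value,
       status = if (any_ok) "ok" else "not_converged")
}

#' Per-group median omega and pairwise rank-sum tests
#'
#' Medians are taken over `ok`-status estimates only; groups with fewer
#' than two usable estimates get `"."` entries in the test table.
#'
#' @param estimates data.frame with columns `omega` and `status`.
#' @param groups Character vector of group labels, one per estimate.
#' @return List: `medians` (group, n_ok, median_omega), `tests` (group_a,
#'   group_b, p_value as character, `"."` when untestable).
#' @export
omega_by_group <- function(estimates, groups) {
  stopifnot(nrow(estimates) == length(groups))
  ok <- estimates$status == "ok" & !is.na(estimates$omega)
  gl <- sort(unique(groups))
  medians <- data.frame(
    group = gl,
    n_ok = vapply(gl, function(g) sum(ok & groups == g), integer(1)),
    median_omega = vapply(gl, function(g) {
      v <- estimates$omega[ok & groups == g]
      if (length(v) == 0) NA_real_ else stats::median(v)
    }, numeric(1)), row.names = NULL)
  combs <- if (length(gl) >= 2) utils::combn(gl, 2) else
    matrix(character(0), 2, 0)
  tests <- data.frame(
    group_a = combs[1, ], group_b = combs[2, ],
    p_value = apply(combs, 2, function(pr) {
      va <- estimates$omega[ok & groups == pr[1]]
      vb <- estimates$omega[ok & groups == pr[2]]
      if (length(va) < 2 || length(vb) < 2) return(".")
      format(stats::wilcox.test(va, vb, exact = FALSE)$p.value, digits = 6)
    }), stringsAsFactors = FALSE)
  list(medians = medians, tests = tests)
}
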