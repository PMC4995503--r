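# Pseudogene filtering, PSSM scans, domain architecture and loss rates.

test_that("ORF verdicts follow the documented precedence", {
  # stop at codon 2 of 10
  cds <- paste0("ATG", "TAA", paste(rep("GGG", 7), collapse = ""), "TGA")
  expect_equal(check_orf_integrity(cds, 300)$verdict, "premature_stop")

  expect_equal(check_orf_integrity(paste(rep("A", 100), collapse = ""),
                                   300)$verdict, "frameshift")

  clean <- paste(rep("GCT", 300), collapse = "")
  expect_equal(check_orf_integrity(clean, 300)$verdict, "complete")

  short <- paste(rep("GCT", 100), collapse = "")
  expect_equal(check_orf_integrity(short, 300)$verdict, "short_fragment")

  # frameshift masks premature stop (precedence)
  both <- paste0("ATGTAAGG")
  expect_equal(check_orf_integrity(both, 300)$verdict, "frameshift")

  expect_error(check_orf_integrity("", 300), "empty")
})

test_that("pseudogene filter recovers planted defect types exactly", {
  set.seed(11)
  good <- vapply(1:6, function(i)
    paste(c(sample(setdiff(sense_codons(),
                           c("TAA", "TAG", "TGA")), 200, TRUE), "TAA"),
          collapse = ""), character(1))
  codons <- strsplit(good[1], "(?<=.{3})", perl = TRUE)[[1]]
  premature <- paste(c(codons[1:50], "TAA", codons[52:201]), collapse = "")
  frameshift <- substr(good[2], 1, 601)
  shortfrag <- substr(good[3], 1, 150)
  recs <- data.frame(
    id = c(sprintf("ok%d", 1:3), "ps", "fs", "sf"),
    residues = c(good[4:6], premature, frameshift, shortfrag))
  calls <- call_pseudogenes(recs, family_length_reference = 200)
  expect_equal(calls$verdict,
               c("complete", "complete", "complete",
                 "premature_stop", "frameshift", "short_fragment"))
})

test_that("filter accounting subtracts pseudogene calls from candidates", {
  acc <- pseudogene_accounting(10, 3)
  expect_equal(acc$retained, 7)
  calls <- data.frame(verdict = c("complete", "frameshift", "complete"))
  expect_equal(pseudogene_accounting(3, calls)$retained, 2)
})

test_that("PSSM probabilities and log-odds match the closed form", {
  # all-identical column: that residue has the maximum log-odds
  p1 <- build_pssm(c(a = "AA", b = "AA", c = "AA"), pseudocount = 1)
  expect_equal(colnames(p1$logodds)[apply(p1$logodds, 1, which.max)],
               c("A", "A"))

  # uniform column over 20 rows with uniform background: log-odds near 0
  rows <- setNames(paste0(AA20, AA20), sprintf("s%d", 1:20))
  p2 <- build_pssm(rows, pseudocount = 1)
  # each residue observed exactly once out of 20: prob = (1 + 1/20)/21 = 1/20
  expect_equal(unname(p2$logodds[1, "A"]), 0, tolerance = 1e-12)
  expect_true(all(abs(p2$logodds) < 1e-9))

  # hand-computed 2-column, 2-sequence case
  p3 <- build_pssm(c(x = "AC", y = "AD"), pseudocount = 1)
  expect_equal(unname(exp(p3$logodds[1, "A"]) * (1 / 20)),
               (2 + 1 / 20) / 3)
  expect_equal(unname(exp(p3$logodds[2, "C"]) * (1 / 20)),
               (1 + 1 / 20) / 3)
  expect_equal(unname(exp(p3$logodds[2, "W"]) * (1 / 20)), (1 / 20) / 3)
})

test_that("PSSM scanning finds planted motifs and respects thresholds", {
  set.seed(21)
  motif <- "WWCHHKY"
  seed_rows <- setNames(rep(motif, 4), sprintf("s%d", 1:4))
  pssm <- build_pssm(seed_rows, pseudocount = 0.5)
  prot <- paste0(random_protein(13), motif, random_protein(9))
  hit <- scan_pssm(prot, pssm)
  expect_equal(hit$start, 14)
  expect_true(hit$present)

  short <- scan_pssm("MK", pssm)
  expect_equal(short$score, -Inf)
  expect_false(short$present)

  # null-calibrated threshold rejects random proteins
  thr <- calibrate_pssm_threshold(pssm, replicate(10, random_protein(60)),
                                  n_shuffles = 10, seed = 2)
  pssm$threshold <- thr
  hits <- vapply(1:20, function(i)
    scan_pssm(random_protein(60), pssm)$present, logical(1))
  expect_lt(mean(hits), 0.25)
  expect_true(scan_pssm(prot, pssm)$present)
})

test_that("scan score never decreases when the protein is extended", {
  set.seed(31)
  pssm <- build_pssm(setNames(rep("ACDEF", 3), c("a", "b", "c")))
  for (i in 1:10) {
    p <- random_protein(20)
    s1 <- scan_pssm(p, pssm)$score
    s2 <- scan_pssm(paste0(p, random_protein(5)), pssm)$score
    expect_gte(s2, s1)
  }
})

test_that("domain architecture flags present and missing domains", {
  set.seed(41)
  motifs <- setNames(replicate(7, random_protein(8)), GLR_DOMAINS)
  pssms <- lapply(motifs, function(m)
    build_pssm(setNames(rep(m, 3), c("a", "b", "c")), threshold = 5))
  full <- paste(motifs, collapse = "GG")
  arch <- call_domain_architecture(full, pssms)
  expect_true(all(arch$present))

  no_atd <- paste(motifs[-1], collapse = "GG")
  arch2 <- call_domain_architecture(no_atd, pssms)
  expect_false(arch2$present[arch2$domain == "ATD"])
  expect_true(all(arch2$present[arch2$domain != "ATD"]))

  arch3 <- call_domain_architecture("M", pssms)
  expect_false(any(arch3$present))
})

test_that("domain loss rates and subfamily shares add up", {
  mk_arch <- function(missing = character(0)) {
    data.frame(domain = GLR_DOMAINS, present = !GLR_DOMAINS %in% missing,
               score = 1, start = 1L, end = 8L)
  }
  arch <- list(g1 = mk_arch(), g2 = mk_arch("ATD"), g3 = mk_arch(),
               g4 = mk_arch(c("ATD", "M4")), g5 = mk_arch(),
               g6 = mk_arch(), g7 = mk_arch(), g8 = mk_arch(),
               g9 = mk_arch(), g10 = mk_arch())
  subf <- setNames(c(rep("GLR1&2", 4), rep("GLR3", 6)),
                   sprintf("g%d", 1:10))
  res <- domain_loss_rates(arch, subf)
  expect_equal(res$per_domain$loss_rate[res$per_domain$domain == "ATD"], 0.2)
  expect_equal(res$per_domain$loss_rate[res$per_domain$domain == "M1"], 0)
  shares <- as.numeric(res$per_subfamily$share)
  expect_equal(sum(shares), 1)
  expect_equal(sum(res$per_subfamily$loss_events), 3)

  # no losses: shares undefined
  res0 <- domain_loss_rates(list(g1 = mk_arch(), g2 = mk_arch()),
                            setNames(c("A", "B"), c("g1", "g2")))
  expect_true(all(res0$per_subfamily$share == "."))
  expect_true(all(res0$per_domain$loss_rate == 0))

  # single planted loss of ATD in 10 genes: rate 0.10
  arch1 <- c(list(gx = mk_arch("ATD")),
             setNames(lapply(1:9, function(i) mk_arch()),
                      sprintf("gy%d", 1:9)))
  subf1 <- setNames(rep("GLR3", 10), names(arch1))
  r1 <- domain_loss_rates(arch1, subf1)
  expect_equal(r1$per_domain$loss_rate[r1$per_domain$domain == "ATD"], 0.10)
})
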