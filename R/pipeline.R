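# Pipeline orchestration: flat key-value config (YAML), stage sequencing,
# deterministic TSV outputs and a run report.

.config_defaults <- function() list(
  seed = 1L,
  n_chrom = 4L, genes_per_chrom = 120L,
  n_tandem_arrays = 2L, array_sizes = c(3L, 2L),
  n_segmental_blocks = 1L, block_gene_count = 5L,
  n_dispersed = 2L, n_singletons = 1L,
  tandem_gap = 10L, min_block_pairs = 5L, max_rank_gap = 25L, top_k = 5L,
  window = 20L, slide = 10L,
  bootstrap_reps = 50L,
  k_clusters = 3L, n_expr_genes = 24L,
  tissues = c("leaf", "stem", "root"),
  stages = c("simulate", "identify", "duplication", "expansion",
             "conservation", "selection", "phylo", "expression")
)

.config_ranges <- list(
  tandem_gap = c(1, Inf), min_block_pairs = c(2, Inf),
  max_rank_gap = c(1, Inf), top_k = c(1, Inf), window = c(1, Inf),
  slide = c(1, Inf), bootstrap_reps = c(0, Inf), k_clusters = c(1, Inf),
  n_chrom = c(1, Inf), genes_per_chrom = c(10, Inf),
  n_expr_genes = c(3, Inf)
)

#' Validate a pipeline configuration
#'
#' Reads a flat YAML key-value file (or takes a list), rejects unknown
#' keys, fills defaults and range-checks parameters.
#'
#' @param config Path to a YAML file or a named list.
#' @return A `pipeline_config` list with every key populated.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    stopifnot(file.exists(config))
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  defaults <- .config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  for (key in names(.config_ranges)) {
    rng <- .config_ranges[[key]]
    if (any(cfg[[key]] < rng[1]) || any(cfg[[key]] > rng[2]))
      stop("config key ", key, " out of range [", rng[1], ", ", rng[2], "]")
  }
  bad <- setdiff(cfg$stages, .config_defaults()$stages)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

#' Stable hash of a configuration
#'
#' @param cfg A `pipeline_config`.
#' @return MD5 hex string of the canonical YAML serialization.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg[order(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}

.write_tsv <- function(df, path) {
  df[] <- lapply(df, function(col) {
    if (is.numeric(col)) formatC(col, format = "g", digits = 10) else col
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Run the full analysis pipeline on a simulated genome
#'
#' Stages run in dependency order (simulate, identify, duplication,
#' expansion, conservation, selection, phylo, expression); any stage
#' failure aborts naming the stage. Outputs are TSV/Newick files under
#' `out_dir`; identical configs produce byte-identical outputs.
#'
#' @param config A config path, list, or `pipeline_config`.
#' @param out_dir Output directory (created if missing).
#' @return Run report: per-stage row counts, config echo and hash.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = unclass(cfg), hash = config_hash(cfg),
                 stages = list())
  stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    report$stages[[name]] <<- res
    invisible(res)
  }
  env <- new.env()

  stage("simulate", function() {
    spec <- family_spec(cfg$n_tandem_arrays, cfg$array_sizes,
                        cfg$n_segmental_blocks, cfg$block_gene_count,
                        cfg$n_dispersed, cfg$n_singletons)
    env$sim <- simulate_genome(cfg$n_chrom, cfg$genes_per_chrom, spec,
                               seed = cfg$seed)
    write_gene_positions(env$sim$genes, file.path(out_dir, "genes.bed"))
    write_fasta(env$sim$proteins, file.path(out_dir, "proteins.fasta"))
    write_fasta(env$sim$cds, file.path(out_dir, "cds.fasta"))
    .write_tsv(env$sim$truth$modes, file.path(out_dir, "truth_modes.tsv"))
    list(n_genes = nrow(env$sim$genes),
         n_family = nrow(env$sim$proteins))
  })

  stage("identify", function() {
    calls <- call_pseudogenes(env$sim$cds)
    .write_tsv(calls, file.path(out_dir, "pseudogene_calls.tsv"))
    env$complete_ids <- calls$gene_id[calls$verdict == "complete"]
    list(n_candidates = nrow(calls),
         n_complete = length(env$complete_ids))
  })

  stage("duplication", function() {
    prot <- env$sim$proteins
    thr <- calibrate_homolog_threshold(prot, n_pairs = 30,
                                       seed = cfg$seed)
    pairs <- find_homolog_pairs(prot, top_k = cfg$top_k,
                                score_threshold = thr)
    # background block genes pair by planted homology (coordinates only)
    bg <- env$sim$truth$background_pairs
    all_pairs <- rbind(pairs[, c("a", "b")], bg)
    blocks <- detect_collinear_chains(all_pairs, env$sim$genes,
                                      min_block_pairs = cfg$min_block_pairs,
                                      max_rank_gap = cfg$max_rank_gap,
                                      exclude_proximal_gap = cfg$tandem_gap)
    calls <- classify_duplications(env$sim$genes, pairs, blocks,
                                   gene_ids = env$sim$proteins$id,
                                   tandem_gap = cfg$tandem_gap)
    arrays <- group_tandem_arrays(calls, pairs, env$sim$genes,
                                  tandem_gap = cfg$tandem_gap)
    env$pairs <- pairs; env$blocks <- blocks; env$calls <- calls
    .write_tsv(pairs, file.path(out_dir, "homolog_pairs.tsv"))
    .write_tsv(calls, file.path(out_dir, "duplication_calls.tsv"))
    block_df <- do.call(rbind, lapply(blocks, function(b)
      data.frame(block_id = b$block_id, chrom_a = b$chrom_a,
                 chrom_b = b$chrom_b, orientation = b$orientation,
                 score = b$score,
                 anchors = paste(paste(b$anchors$a, b$anchors$b, sep = ":"),
                                 collapse = ","))))
    if (is.null(block_df))
      block_df <- data.frame(block_id = character(0))
    .write_tsv(block_df, file.path(out_dir, "synteny_blocks.tsv"))
    list(n_pairs = nrow(pairs), n_blocks = length(blocks),
         n_tandem = sum(calls$mode == "tandem"),
         tandem_fraction = tandem_related_fraction(calls),
         n_arrays = arrays$summary$n_arrays)
  })

  stage("expansion", function() {
    fam <- env$sim$proteins$id
    seqs <- stats::setNames(env$sim$cds$residues, env$sim$cds$id)
    edges <- do.call(rbind, lapply(fam, function(g) {
      prs <- env$pairs[env$pairs$a == g | env$pairs$b == g, , drop = FALSE]
      if (nrow(prs) == 0) return(NULL)
      cand <- data.frame(
        partner = ifelse(prs$a == g, prs$b, prs$a),
        identity = prs$identity,
        flanking = vapply(ifelse(prs$a == g, prs$b, prs$a), function(p)
          shared_flanking_count(g, p, env$blocks, fam), integer(1)),
        ks = vapply(ifelse(prs$a == g, prs$b, prs$a), function(p) {
          est <- ng86(.strip_terminal_stop(seqs[[g]]),
                      .strip_terminal_stop(seqs[[p]]))
          if (is.na(est$dS)) NA_real_ else est$dS
        }, numeric(1)))
      nd <- nearest_duplicate(g, cand)
      data.frame(gene = g, partner = nd$partner, identity = nd$identity,
                 flanking = nd$flanking, ks = nd$ks)
    }))
    if (is.null(edges))
      edges <- data.frame(gene = character(0), partner = character(0),
                          identity = numeric(0), flanking = numeric(0),
                          ks = numeric(0))
    series <- assemble_expansion_series(edges, genes = fam)
    env$edges <- edges
    .write_tsv(data.frame(
      series_id = sprintf("series_%d", seq_along(series)),
      genes = vapply(series, paste, character(1), collapse = ",")),
      file.path(out_dir, "expansion_series.tsv"))
    list(n_edges = nrow(edges), n_series = length(series))
  })

  stage("conservation", function() {
    rows <- stats::setNames(env$sim$proteins$residues,
                            env$sim$proteins$id)
    prof <- conservation_profile(rows)
    wins <- sliding_window_profile(prof, cfg$window, cfg$slide)
    .write_tsv(data.frame(column = seq_along(prof), index = prof),
               file.path(out_dir, "conservation_profile.tsv"))
    .write_tsv(wins, file.path(out_dir, "window_means.tsv"))
    list(n_columns = length(prof), n_windows = nrow(wins),
         mean_index = mean(prof))
  })

  stage("selection", function() {
    seqs <- stats::setNames(env$sim$cds$residues, env$sim$cds$id)
    ed <- env$edges
    if (nrow(ed) > 0) {
      key <- ifelse(ed$gene < ed$partner, paste(ed$gene, ed$partner),
                    paste(ed$partner, ed$gene))
      ed <- ed[!duplicated(key), , drop = FALSE]
    }
    est <- do.call(rbind, lapply(seq_len(nrow(ed)), function(i) {
      e <- ng86(.strip_terminal_stop(seqs[[ed$gene[i]]]),
                .strip_terminal_stop(seqs[[ed$partner[i]]]))
      data.frame(a = ed$gene[i], b = ed$partner[i], method = e$method,
                 dN = e$dN, dS = e$dS, omega = e$omega, status = e$status)
    }))
    if (is.null(est))
      est <- data.frame(a = character(0), b = character(0),
                        method = character(0), dN = numeric(0),
                        dS = numeric(0), omega = numeric(0),
                        status = character(0))
    .write_tsv(est, file.path(out_dir, "omega_pairs.tsv"))
    list(n_estimates = nrow(est),
         median_omega = if (any(est$status == "ok"))
           stats::median(est$omega[est$status == "ok"]) else NA_real_)
  })

  stage("phylo", function() {
    rows <- stats::setNames(env$sim$proteins$residues,
                            env$sim$proteins$id)
    tr <- bootstrap_support(rows, n_reps = cfg$bootstrap_reps,
                            seed = cfg$seed)
    write_newick(tr, file.path(out_dir, "family_tree.nwk"))
    list(n_tips = length(tr$tip.label))
  })

  stage("expression", function() {
    k <- cfg$k_clusters
    profiles <- lapply(seq_len(k), function(i) {
      mu <- rep(2, length(cfg$tissues))
      mu[(i - 1) %% length(cfg$tissues) + 1] <- 8
      list(mean = mu, sd = 0.3)
    })
    sim <- simulate_expression(cfg$n_expr_genes, cfg$tissues, profiles,
                               seed = cfg$seed)
    rel <- 2^sim$matrix
    z <- log2_standardize(rel, pseudocount = 0)
    cl <- kmeans_cluster(z, k = k, seed = cfg$seed)
    st <- stats::setNames(sim$samples$tissue, sim$samples$sample)
    pref <- tissue_preference(z, st)
    .write_tsv(data.frame(gene = names(cl$cluster),
                          cluster = unname(cl$cluster)),
               file.path(out_dir, "clusters.tsv"))
    .write_tsv(pref$preference, file.path(out_dir, "tissue_preference.tsv"))
    list(n_genes = nrow(z), k = k, inertia = cl$inertia)
  })

  report
}
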