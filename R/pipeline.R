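## End-to-end orchestration: preprocess -> paired EWAS + DGE -> DMR calling
## -> cis integration -> networks -> overlap enrichment, from a single
## configuration with one seed, writing fixed-name TSV/BED/JSON outputs.
## All stochastic stages draw sub-seeds from the run seed, so identical
## configurations produce byte-identical output files.

#' Run the full twin analysis pipeline
#'
#' Stages: preprocessing (probe/gene QC filters, within-pair log2 ratios),
#' the paired association scans for methylation and expression, DMR
#' calling with genomic-feature enrichment, cis methylation-expression
#' integration with the permutation threshold, group network construction
#' with module detection and differential connectivity, and Fisher overlap
#' of the differentially methylated and expressed gene sets.
#'
#' @param config Path to a YAML run configuration, or a configuration list
#'   as returned by [load_run_config()].  Ignored fields fall back to
#'   defaults.  When `simulate` is given, input paths are not required.
#' @param out_dir Output directory (created if needed).
#' @param simulate Optional [sim_config()] (or argument list for it): the
#'   inputs are generated rather than read.
#' @param seed Overrides the config seed.
#' @param verbose Log per-stage progress.
#' @return The run report (invisibly written as `report.json`): per-stage
#'   counts, thresholds and seeds.
#' @export
run_twin_pipeline <- function(config = NULL, out_dir, simulate = NULL,
                              seed = NULL, verbose = TRUE) {
  cfg <- if (is.null(config)) {
    run_config_defaults()
  } else if (is.character(config)) {
    load_run_config(config,
                    require_inputs = if (is.null(simulate)) {
                      c("beta", "tpm", "manifest", "genes", "samples")
                    } else character(0),
                    verbose = verbose)
  } else {
    config
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(simulate)) {
    if (!inherits(simulate, "sim_config")) {
      simulate <- do.call(sim_config, c(simulate, list(seed = cfg$seed)))
    }
    log_msg("simulate: %d pairs, %d probes, %d genes, seed %d",
            simulate$n_pairs, simulate$n_probes, simulate$n_genes,
            simulate$seed, verbose = verbose)
    study <- sim_twin_study(simulate)
    beta <- study$beta; tpm <- study$tpm
    manifest <- study$manifest; genes <- study$genes; sheet <- study$cohort
  } else {
    log_msg("reading inputs", verbose = verbose)
    beta <- read_matrix(cfg$inputs$beta, "beta")
    tpm <- read_matrix(cfg$inputs$tpm, "tpm")
    manifest <- read_manifest(cfg$inputs$manifest)
    genes <- read_tsv(cfg$inputs$genes)
    sheet <- read_sample_sheet(cfg$inputs$samples)
  }
  report <- list(config = cfg[setdiff(names(cfg), "inputs")],
                 seed = as.integer(cfg$seed))

  ## preprocess -------------------------------------------------------------
  pp <- cfg$preprocess
  pf <- filter_probes(manifest, beta, pp$detect_fail_max, pp$intensity_z_max)
  beta <- beta[pf$retained, , drop = FALSE]
  kept_genes <- filter_genes(tpm, pp$gene_floor, pp$gene_max_low_fraction)
  tpm <- tpm[kept_genes, , drop = FALSE]
  log_msg("preprocess: %d probes and %d genes retained", nrow(beta),
          nrow(tpm), verbose = verbose)
  write_tsv(pf$exclusions, file.path(out_dir, "probe_exclusions.tsv"))
  report$preprocess <- list(n_probes_retained = nrow(beta),
                            n_genes_retained = nrow(tpm),
                            probe_exclusions = pf$exclusions$n_excluded)

  covariate_names <- c("age", "sex", "bmi", "smoking", "alcohol", "income",
                       "education")
  meth_ratios <- within_pair_logratio(beta, sheet, offset = 1e-6)
  expr_ratios <- within_pair_logratio(tpm, sheet, offset = 1)

  ## paired scans -----------------------------------------------------------
  log_msg("EWAS scan: %d probes", nrow(beta), verbose = verbose)
  ewas <- run_feature_scan(meth_ratios, covariates = covariate_names,
                           verbose = verbose)
  log_msg("DGE scan: %d genes", nrow(tpm), verbose = verbose)
  dge <- run_feature_scan(expr_ratios, covariates = covariate_names,
                          verbose = verbose)
  write_tsv(ewas, file.path(out_dir, "ewas.tsv"))
  write_tsv(dge, file.path(out_dir, "degs.tsv"))
  report$ewas <- list(n_tested = nrow(ewas),
                      n_q05 = sum(ewas$q < 0.05, na.rm = TRUE))
  report$dge <- list(n_tested = nrow(dge),
                     n_q05 = sum(dge$q < 0.05, na.rm = TRUE))

  ## DMR calling ------------------------------------------------------------
  dmrcfg <- cfg$dmr
  cands <- form_candidate_regions(manifest[manifest$probe_id %in%
                                             rownames(beta), ],
                                  ewas, dmrcfg$max_gap_bp)
  scored <- score_regions(cands, ewas, beta, sheet, manifest,
                          corr_method = dmrcfg$corr_method)
  dmrs <- call_dmrs(scored, dmrcfg$min_probes, dmrcfg$peak_p,
                    dmrcfg$min_corr, dmrcfg$q_max)
  log_msg("regions: %d candidates, %d DMRs (%d significant)", nrow(scored),
          nrow(dmrs), sum(dmrs$significant), verbose = verbose)
  dmr_out <- dmrs[setdiff(names(dmrs), "probe_ids")]
  write_tsv(dmr_out, file.path(out_dir, "dmrs.tsv"))
  if (nrow(dmrs)) write_dmr_bed(dmrs, file.path(out_dir, "dmrs.bed"))
  enr <- feature_enrichment(unlist(dmrs$probe_ids[dmrs$significant]),
                            manifest, rownames(beta))
  write_tsv(enr, file.path(out_dir, "dmr_feature_enrichment.tsv"))
  report$dmr <- list(n_candidates = nrow(scored), n_dmrs = nrow(dmrs),
                     n_significant = sum(dmrs$significant))

  ## integration ------------------------------------------------------------
  icfg <- cfg$integration
  cis <- map_cis_pairs(manifest[manifest$probe_id %in% rownames(beta), ],
                       genes[genes$gene_id %in% rownames(tpm), ],
                       icfg$cis_window)
  report$integration <- list(n_cis_pairs = nrow(cis))
  if (nrow(cis)) {
    covs <- sample_covariate_matrix(sheet, covariate_names)
    covs <- covs[colnames(beta), , drop = FALSE]
    cis <- cis_correlations(beta, tpm, covs, cis)
    thr <- permutation_threshold(beta, tpm, covs, cis,
                                 B = icfg$permutations, alpha = icfg$alpha,
                                 tail = icfg$tail,
                                 seed = stage_seed(cfg$seed, "permutation"))
    cls <- classify_cis_pairs(cis, thr, window = icfg$cis_window,
                              bin_bp = icfg$bin_bp)
    mdd <- as.integer(sheet$role[match(colnames(beta),
                                       sheet$sample_id)] == "depressed")
    rob <- robustness_with_mdd(beta, tpm, covs, cls, mdd, thr)
    log_msg("integration: %d cis pairs, %d significant (thresholds %.3f/%.3f)",
            nrow(cis), cls$summary$n_significant, thr$lower, thr$upper,
            verbose = verbose)
    write_tsv(cls$pairs, file.path(out_dir, "cis_pairs.tsv"))
    write_tsv(cls$profile, file.path(out_dir, "cis_offset_profile.tsv"))
    report$integration <- c(report$integration,
                            cls$summary[c("n_significant",
                                          "negative_fraction", "lower",
                                          "upper")],
                            list(B = thr$B,
                                 fraction_robust_to_mdd = rob$fraction_robust))
  }

  ## networks ---------------------------------------------------------------
  ncfg <- cfg$network
  report$network <- list(n_nodes = 0L, n_modules = 0L)
  nominal <- scored[!is.na(scored$region_p) & scored$region_p < ncfg$p_max, ,
                    drop = FALSE]
  dep_cols <- sheet$sample_id[sheet$role == "depressed"][
    order(sheet$pair_id[sheet$role == "depressed"])]
  ctl_cols <- sheet$sample_id[sheet$role == "nondepressed"][
    order(sheet$pair_id[sheet$role == "nondepressed"])]
  if (nrow(nominal) >= 10 && length(dep_cols) >= 10) {
    node_vals <- region_node_values(nominal, beta)
    mat_a <- node_vals[dep_cols, , drop = FALSE]
    mat_b <- node_vals[ctl_cols, , drop = FALSE]
    net_a <- build_group_network(mat_a, edge_cutoff = ncfg$edge_cutoff)
    net_b <- build_group_network(mat_b, power = net_a$power,
                                 edge_cutoff = ncfg$edge_cutoff)
    mods <- detect_modules(net_a, min_size = ncfg$min_module_size,
                           cut_height = ncfg$cut_height)
    write_tsv(mods$assignment, file.path(out_dir, "modules.tsv"))
    conn_rows <- lapply(seq_len(nrow(mods$modules)), function(i) {
      nodes <- mods$assignment$node[mods$assignment$module ==
                                      mods$modules$module[i]]
      dc <- differential_connectivity(nodes, mat_a, mat_b,
                                      power = net_a$power,
                                      edge_cutoff = ncfg$edge_cutoff,
                                      B_perm = ncfg$permutations,
                                      seed = stage_seed(cfg$seed, "network") + i)
      data.frame(module = mods$modules$module[i], n_nodes = length(nodes),
                 mean_degree_depressed = dc$mean_degree_a,
                 mean_degree_nondepressed = dc$mean_degree_b, p = dc$p)
    })
    conn <- do.call(rbind, conn_rows) %||%
      data.frame(module = integer(0), n_nodes = integer(0),
                 mean_degree_depressed = numeric(0),
                 mean_degree_nondepressed = numeric(0), p = numeric(0))
    write_tsv(conn, file.path(out_dir, "module_connectivity.tsv"))
    log_msg("networks: %d nodes, %d modules (power %d)", ncol(node_vals),
            nrow(mods$modules), net_a$power, verbose = verbose)
    report$network <- list(n_nodes = ncol(node_vals),
                           n_modules = nrow(mods$modules),
                           power = net_a$power)
  } else {
    log_msg("networks skipped: %d nominal regions (< 10 nodes)",
            nrow(nominal), verbose = verbose)
  }

  ## overlap enrichment -----------------------------------------------------
  dm_genes <- unique(dmrs$gene[dmrs$significant])
  de_genes <- unique(dge$feature_id[!is.na(dge$q) & dge$q < 0.05])
  probe_genes <- unique(manifest$gene_symbol[manifest$probe_id %in%
                                               rownames(beta)])
  background <- intersect(probe_genes, rownames(tpm))
  dm_genes <- intersect(dm_genes, background)
  de_genes <- intersect(de_genes, background)
  if (length(background)) {
    ov <- fisher_overlap(dm_genes, de_genes, background)
    report$overlap <- list(n_dm_genes = length(dm_genes),
                           n_de_genes = length(de_genes),
                           both = unname(ov$counts[["both"]]),
                           fold_enrichment = ov$fold_enrichment,
                           odds_ratio = ov$odds_ratio, p = ov$p)
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  log_msg("done: outputs in %s", out_dir, verbose = verbose)
  invisible(report)
}
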