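## Synthetic twin-cohort generator.
##
## Emulates the data structure of a discordant monozygotic co-twin study:
## paired samples sharing pair-level covariates and array batch, probe-level
## methylation beta values with spatially adjacent correlated CpG blocks and
## planted within-pair fold changes, gene-level TPM expression with planted
## differential expression, and signed cis methylation-expression couplings
## whose TSS offset is configurable.  Every planted signal is returned as a
## ground-truth label so downstream stages can be validated against it.

#' Build a validated simulation configuration
#'
#' @param n_pairs Number of discordant twin pairs (>= 2).
#' @param n_probes Number of CpG probes on the synthetic array.
#' @param n_genes Number of genes in the synthetic expression matrix.
#' @param n_batches Number of array batches (chips). Twins of a pair always
#'   share a batch; pairs are assigned to batches in contiguous blocks.
#' @param batch_sd SD of the per-probe batch random intercept, on the
#'   within-pair log2-ratio scale.
#' @param noise_sd Within-pair log2-ratio residual SD for methylation.
#' @param pair_sd Between-pair biological SD on the logit-beta scale
#'   (shared by both twins of a pair; does not enter the ratio).
#' @param expr_noise_sd Per-sample residual SD of log2(TPM+1).
#' @param expr_pair_sd Between-pair SD of log2(TPM+1).
#' @param planted_dmrs Data frame with columns `n_probes`, `r` (target
#'   within-block correlation of beta values across samples), `fc` (planted
#'   within-pair fold change, 2^alpha, > 0), `gap_bp` (genomic spacing of
#'   adjacent block probes). A block of one probe plants a single-CpG effect.
#' @param planted_degs Data frame with columns `gene` (index) and `fc`
#'   (planted expression fold change, depressed vs nondepressed twin).
#' @param cis_couplings Data frame with columns `probe` (index), `gene`
#'   (index), `r` (target signed partial correlation, in (-1, 1)) and
#'   `offset_bp` (signed probe position relative to the gene TSS; negative =
#'   probe upstream).
#' @param covariate_effects Named numeric vector of per-covariate effects on
#'   the log2-ratio scale; names must be twin-varying covariates
#'   (`bmi`, `smoking`, `alcohol`, `income`, `education`, `ace`, `ptsd`,
#'   `antidep`).
#' @param feature_class_props,cgi_props Named proportions used to sample the
#'   manifest annotation categories.
#' @param seed Integer seed; one seed drives every stage deterministically.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 79, n_probes = 2000, n_genes = 500,
                       n_batches = 20, batch_sd = 0.1, noise_sd = 0.2,
                       pair_sd = 0.5, expr_noise_sd = 0.4, expr_pair_sd = 0.4,
                       planted_dmrs = NULL, planted_degs = NULL,
                       cis_couplings = NULL, covariate_effects = NULL,
                       feature_class_props = NULL, cgi_props = NULL,
                       seed = 1L) {
  if (!is_count(n_pairs) || n_pairs < 2) {
    stopf("invalid config: n_pairs must be an integer >= 2 (got %s)",
          format(n_pairs))
  }
  if (!is_count(n_probes) || n_probes < 1) stopf("invalid config: n_probes")
  if (!is_count(n_genes) || n_genes < 1) stopf("invalid config: n_genes")
  if (!is_count(n_batches) || n_batches < 1) stopf("invalid config: n_batches")
  stopifnot(batch_sd >= 0, noise_sd > 0, pair_sd >= 0,
            expr_noise_sd > 0, expr_pair_sd >= 0)

  planted_dmrs <- normalize_planted_dmrs(planted_dmrs)
  if (nrow(planted_dmrs)) {
    if (any(planted_dmrs$fc <= 0)) stopf("invalid config: planted FC must be > 0")
    if (any(planted_dmrs$r < 0 | planted_dmrs$r >= 1)) {
      stopf("invalid config: within-block correlation targets must be in [0, 1)")
    }
    if (sum(planted_dmrs$n_probes) > n_probes) {
      stopf("invalid config: planted blocks need %d probes but n_probes = %d",
            sum(planted_dmrs$n_probes), n_probes)
    }
  }
  planted_degs <- normalize_planted_degs(planted_degs)
  if (nrow(planted_degs)) {
    if (any(planted_degs$fc <= 0)) stopf("invalid config: planted FC must be > 0")
    if (any(planted_degs$gene < 1 | planted_degs$gene > n_genes)) {
      stopf("invalid config: planted DEG references a gene outside 1..%d", n_genes)
    }
  }
  cis_couplings <- normalize_cis_couplings(cis_couplings)
  if (nrow(cis_couplings)) {
    if (any(abs(cis_couplings$r) >= 1)) {
      stopf("invalid config: coupling target correlations must be in (-1, 1)")
    }
    if (any(cis_couplings$probe < 1 | cis_couplings$probe > n_probes)) {
      stopf("invalid config: coupling references a probe outside 1..%d", n_probes)
    }
    if (any(cis_couplings$gene < 1 | cis_couplings$gene > n_genes)) {
      stopf("invalid config: coupling references a gene outside 1..%d", n_genes)
    }
    if (anyDuplicated(cis_couplings$gene)) {
      stopf("invalid config: each gene may carry at most one cis coupling")
    }
  }
  covariate_effects <- covariate_effects %||% numeric(0)
  bad <- setdiff(names(covariate_effects), twin_varying_covariates())
  if (length(bad)) {
    stopf("invalid config: covariate_effects for unknown twin-varying covariates: %s",
          paste(bad, collapse = ", "))
  }

  default_fc <- c(TSS1500 = 0.14, TSS200 = 0.08, "5'UTR" = 0.09,
                  "1stExon" = 0.04, Body = 0.36, "3'UTR" = 0.03,
                  Intergenic = 0.26)
  default_cgi <- c(Island = 0.20, Shore = 0.18, Shelf = 0.10, OpenSea = 0.52)
  feature_class_props <- feature_class_props %||% default_fc
  cgi_props <- cgi_props %||% default_cgi
  if (!setequal(names(feature_class_props), names(default_fc))) {
    stopf("invalid config: feature_class_props must name exactly: %s",
          paste(names(default_fc), collapse = ", "))
  }
  if (!setequal(names(cgi_props), names(default_cgi))) {
    stopf("invalid config: cgi_props must name exactly: %s",
          paste(names(default_cgi), collapse = ", "))
  }

  structure(list(
    n_pairs = as.integer(n_pairs), n_probes = as.integer(n_probes),
    n_genes = as.integer(n_genes), n_batches = as.integer(n_batches),
    batch_sd = batch_sd, noise_sd = noise_sd, pair_sd = pair_sd,
    expr_noise_sd = expr_noise_sd, expr_pair_sd = expr_pair_sd,
    planted_dmrs = planted_dmrs, planted_degs = planted_degs,
    cis_couplings = cis_couplings, covariate_effects = covariate_effects,
    feature_class_props = feature_class_props / sum(feature_class_props),
    cgi_props = cgi_props / sum(cgi_props),
    seed = as.integer(seed)
  ), class = "sim_config")
}

normalize_planted_dmrs <- function(x) {
  if (is.null(x)) {
    return(data.frame(n_probes = integer(0), r = numeric(0),
                      fc = numeric(0), gap_bp = numeric(0)))
  }
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind.data.frame, x)
  x <- as.data.frame(x)
  stopifnot(all(c("n_probes", "r", "fc", "gap_bp") %in% names(x)))
  x[c("n_probes", "r", "fc", "gap_bp")]
}

normalize_planted_degs <- function(x) {
  if (is.null(x)) return(data.frame(gene = integer(0), fc = numeric(0)))
  x <- as.data.frame(x)
  stopifnot(all(c("gene", "fc") %in% names(x)))
  x[c("gene", "fc")]
}

normalize_cis_couplings <- function(x) {
  if (is.null(x)) {
    return(data.frame(probe = integer(0), gene = integer(0),
                      r = numeric(0), offset_bp = numeric(0)))
  }
  x <- as.data.frame(x)
  stopifnot(all(c("probe", "gene", "r", "offset_bp") %in% names(x)))
  x[c("probe", "gene", "r", "offset_bp")]
}

twin_varying_covariates <- function() {
  c("bmi", "smoking", "alcohol", "income", "education",
    "ace", "ptsd", "antidep")
}

pair_shared_covariates <- function() c("age", "sex")

#' Generate a twin-pair sample sheet
#'
#' Pair-level covariates (age, sex) are identical within a pair; the
#' twin-varying covariates are drawn independently per twin.  Both twins of
#' a pair are always assigned to the same batch, mirroring co-hybridization
#' of pairs on one chip.
#'
#' @param config A [sim_config()] object.
#' @return Sample sheet data frame, two rows per pair, with columns
#'   `sample_id`, `pair_id`, `role` (depressed/nondepressed), `batch_id`
#'   and the covariates.
#' @export
sim_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$seed, "cohort"), {
    np <- config$n_pairs
    pair_id <- sprintf("P%04d", seq_len(np))
    batch <- sprintf("B%03d", rep(seq_len(config$n_batches),
                                  each = ceiling(np / config$n_batches))[seq_len(np)])
    age <- round(runif(np, 18, 70), 1)
    sex <- ifelse(rbinom(np, 1, 0.684) == 1, "F", "M")
    draw_twin <- function() data.frame(
      bmi = round(rnorm(np, 27, 5), 1),
      smoking = round(pmax(rnorm(np, 2.3, 5), 0), 1),
      alcohol = pmin(pmax(round(rnorm(np, 3.5, 2.6)), 0), 12),
      income = sample(1:5, np, replace = TRUE),
      education = sample(1:5, np, replace = TRUE),
      ace = rbinom(np, 1, 0.11),
      ptsd = rbinom(np, 1, 0.05),
      antidep = rbinom(np, 1, 0.3)
    )
    dep <- draw_twin()
    ctl <- draw_twin()
    dep$ptsd <- rbinom(np, 1, 0.08)   # higher comorbidity in affected twins
    dep$antidep <- rbinom(np, 1, 0.5)
    sheet <- rbind(
      data.frame(sample_id = paste0(pair_id, "_D"), pair_id = pair_id,
                 role = "depressed", batch_id = batch, age = age, sex = sex,
                 dep, stringsAsFactors = FALSE),
      data.frame(sample_id = paste0(pair_id, "_N"), pair_id = pair_id,
                 role = "nondepressed", batch_id = batch, age = age, sex = sex,
                 ctl, stringsAsFactors = FALSE)
    )
    sheet <- sheet[order(sheet$pair_id, sheet$role), ]
    rownames(sheet) <- NULL
    sheet
  })
}

# Chromosome / position layout.  Planted blocks are inserted as runs of
# adjacent manifest rows separated by their configured gap; background
# probes are spaced >= 1500 bp apart so they never co-cluster at the
# default 1000 bp region gap.
probe_layout <- function(config) {
  n <- config$n_probes
  blocks <- config$planted_dmrs
  nb <- nrow(blocks)
  block_id <- rep(NA_integer_, n)
  if (nb > 0) {
    # spread block start slots evenly through the probe order
    starts <- floor(seq(1, n - sum(blocks$n_probes) + 1,
                        length.out = nb + 2))[2:(nb + 1)]
    slot <- starts[1]
    for (b in seq_len(nb)) {
      slot <- max(slot, starts[b])
      block_id[slot:(slot + blocks$n_probes[b] - 1)] <- b
      slot <- slot + blocks$n_probes[b]
    }
  }
  chrom_idx <- rep(seq_len(22), each = ceiling(n / 22))[seq_len(n)]
  # keep each block on one chromosome
  if (nb > 0) {
    for (b in seq_len(nb)) {
      idx <- which(block_id == b)
      chrom_idx[idx] <- chrom_idx[idx[1]]
    }
  }
  pos <- numeric(n)
  gap <- round(runif(n, 1500, 30000))
  if (nb > 0) {
    in_block_follow <- !is.na(block_id) & c(NA, block_id[-n]) == block_id
    in_block_follow[is.na(in_block_follow)] <- FALSE
    gap[in_block_follow] <- blocks$gap_bp[block_id[in_block_follow]]
  }
  for (ci in unique(chrom_idx)) {
    idx <- which(chrom_idx == ci)
    pos[idx] <- 1e6 + cumsum(gap[idx])
  }
  list(chrom = paste0("chr", chrom_idx), pos = pos, block_id = block_id)
}

#' Generate the synthetic methylation beta matrix
#'
#' Beta values are produced on the logit scale: a per-probe baseline
#' (mixture of low/mid/high-methylation components), a pair-shared
#' biological effect, individual noise, a shared block factor inducing the
#' target within-block correlation, and a within-pair treatment contrast of
#' +alpha/2 (depressed twin) vs -alpha/2 (co-twin) where alpha combines the
#' planted log2 fold change, the per-probe batch random intercept and the
#' configured covariate effects.  Log2-ratio quantities are mapped to the
#' logit scale by local linearization at the probe baseline, and the
#' realized mean within-pair ratio of every planted probe is recorded in
#' the truth labels.
#'
#' @param config A [sim_config()] object.
#' @param cohort Sample sheet from [sim_cohort()] built from the same config.
#' @return List with `beta` (probes x samples matrix in \[0,1\]), `manifest`
#'   (annotation data frame, sorted by chrom/pos) and `truth`
#'   (per-probe planted alpha, block membership, realized log2 FC).
#' @export
sim_methylation <- function(config, cohort) {
  stopifnot(inherits(config, "sim_config"))
  np <- config$n_probes
  npair <- config$n_pairs
  stopifnot(nrow(cohort) == 2 * npair)
  with_seed(stage_seed(config$seed, "methylation"), {
    layout <- probe_layout(config)
    blocks <- config$planted_dmrs
    probe_id <- sprintf("cg%07d", seq_len(np))

    # baseline logit-beta: bimodal-plus-intermediate mixture; planted probes
    # are kept in the mid-methylation range where the log2-ratio scale is
    # close to linear in the logit
    comp <- sample(1:3, np, replace = TRUE, prob = c(0.3, 0.3, 0.4))
    m <- c(rnorm(np, -2.5, 0.8), rnorm(np, 2.5, 0.8),
           rnorm(np, 0, 1))[seq_len(np) + (comp - 1) * np]
    planted <- !is.na(layout$block_id)
    m[planted] <- rnorm(sum(planted), -0.85, 0.3)
    beta0 <- plogis(m)
    # d(logit)/d(log2 beta) at the baseline; the slope is floored so that
    # highly methylated probes (baseline > 0.8, where log2 ratios of beta
    # values are intrinsically compressed) get bounded logit perturbations
    # instead of exploding ones
    kappa <- log(2) / pmax(1 - beta0, 0.2)

    ord <- order(factor(layout$chrom, levels = paste0("chr", 1:22)), layout$pos)

    pair_of <- match(cohort$pair_id, unique(cohort$pair_id))
    depressed <- cohort$role == "depressed"
    batch_of_pair <- cohort$batch_id[match(unique(cohort$pair_id), cohort$pair_id)]
    batch_idx <- match(batch_of_pair, unique(batch_of_pair))
    nbat <- max(batch_idx)

    alpha <- rep(0, np)
    if (nrow(blocks)) alpha[planted] <- log2(blocks$fc[layout$block_id[planted]])

    # per-probe batch random intercepts on the log2-ratio scale
    u_batch <- matrix(rnorm(np * nbat, 0, config$batch_sd), np, nbat)

    # covariate contribution to the within-pair log2 ratio
    cov_term <- rep(0, npair)
    if (length(config$covariate_effects)) {
      dsheet <- cohort[depressed, ][order(cohort$pair_id[depressed]), ]
      nsheet <- cohort[!depressed, ][order(cohort$pair_id[!depressed]), ]
      for (cv in names(config$covariate_effects)) {
        cov_term <- cov_term +
          config$covariate_effects[[cv]] * (dsheet[[cv]] - nsheet[[cv]])
      }
    }

    # treatment contrast per (probe, pair), log2-ratio scale
    tmat <- alpha + u_batch[, batch_idx, drop = FALSE] +
      matrix(cov_term, np, npair, byrow = TRUE)

    sigma_ind <- config$noise_sd * kappa / sqrt(2)

    block_noise <- function(nc) {
      z <- matrix(rnorm(np * nc), np, nc)
      if (nrow(blocks)) {
        for (b in seq_len(nrow(blocks))) {
          idx <- which(layout$block_id == b)
          r <- blocks$r[b]
          if (r > 0 && length(idx) > 1) {
            shared <- matrix(rnorm(nc), 1, nc)
            z[idx, ] <- sqrt(r) * shared[rep(1, length(idx)), ] +
              sqrt(1 - r) * z[idx, , drop = FALSE]
          }
        }
      }
      z
    }

    pairZ <- config$pair_sd * block_noise(npair)
    indZ <- block_noise(2 * npair) * sigma_ind

    sign_s <- ifelse(depressed, 0.5, -0.5)
    L <- matrix(m, np, 2 * npair) +
      pairZ[, pair_of, drop = FALSE] +
      indZ +
      (tmat[, pair_of, drop = FALSE] * kappa) *
        matrix(sign_s, np, 2 * npair, byrow = TRUE)

    beta <- plogis(L)
    beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
    dimnames(beta) <- list(probe_id, cohort$sample_id)

    manifest <- data.frame(
      probe_id = probe_id,
      chrom = layout$chrom,
      pos = layout$pos,
      gene_symbol = sprintf("G%05d", 1 + (seq_len(np) - 1) %% config$n_genes),
      feature_class = sample(names(config$feature_class_props), np,
                             replace = TRUE, prob = config$feature_class_props),
      cgi_context = sample(names(config$cgi_props), np, replace = TRUE,
                           prob = config$cgi_props),
      sex_chrom = FALSE,
      multi_mapped = FALSE,
      snp_overlap = FALSE,
      detection_fail_fraction = round(runif(np, 0, 0.10), 4),
      intensity_z = round(runif(np, -2.5, 2.5), 3),
      stringsAsFactors = FALSE
    )
    if (nrow(config$cis_couplings)) {
      cc <- config$cis_couplings
      manifest$gene_symbol[cc$probe] <- sprintf("G%05d", cc$gene)
    }
    manifest <- manifest[ord, ]
    rownames(manifest) <- NULL
    beta <- beta[ord, , drop = FALSE]

    eps <- 1e-6
    dep_cols <- cohort$sample_id[depressed][order(cohort$pair_id[depressed])]
    ctl_cols <- cohort$sample_id[!depressed][order(cohort$pair_id[!depressed])]
    realized <- rowMeans(log2((beta[, dep_cols, drop = FALSE] + eps) /
                              (beta[, ctl_cols, drop = FALSE] + eps)))

    truth <- data.frame(
      probe_id = manifest$probe_id,
      alpha = alpha[ord],
      fc = 2^alpha[ord],
      block = layout$block_id[ord],
      realized_log2fc = realized,
      stringsAsFactors = FALSE
    )
    list(beta = beta, manifest = manifest, truth = truth)
  })
}

#' Generate the synthetic expression matrix
#'
#' Expression is generated on the log2(TPM+1) scale with a per-gene
#' baseline, pair-shared and individual noise, planted within-pair fold
#' changes for configured DEGs, and, for each configured cis coupling, a
#' term proportional to the coupled probe's (standardized) beta values
#' scaled so the correlation approaches the target.  Coupled genes are
#' annotated with a TSS at the configured signed offset from the probe.
#'
#' @param config A [sim_config()] object.
#' @param cohort Sample sheet from [sim_cohort()].
#' @param meth Output of [sim_methylation()]; required when cis couplings
#'   are configured.
#' @return List with `tpm` (genes x samples), `genes` (annotation with
#'   `gene_id`, `chrom`, `tss`, `strand`) and `truth` (per-gene planted
#'   log2 FC plus the coupling table with its planted signs).
#' @export
sim_expression <- function(config, cohort, meth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ng <- config$n_genes
  npair <- config$n_pairs
  cc <- config$cis_couplings
  if (nrow(cc) && is.null(meth)) {
    stopf("cis couplings are configured: generate methylation first")
  }
  with_seed(stage_seed(config$seed, "expression"), {
    gene_id <- sprintf("G%05d", seq_len(ng))
    base <- rnorm(ng, 4, 1.5)
    log2fc <- rep(0, ng)
    if (nrow(config$planted_degs)) {
      log2fc[config$planted_degs$gene] <- log2(config$planted_degs$fc)
    }

    pair_of <- match(cohort$pair_id, unique(cohort$pair_id))
    depressed <- cohort$role == "depressed"
    nsamp <- nrow(cohort)

    pairZ <- matrix(rnorm(ng * npair, 0, config$expr_pair_sd), ng, npair)
    indZ <- matrix(rnorm(ng * nsamp, 0, config$expr_noise_sd), ng, nsamp)
    sign_s <- ifelse(depressed, 0.5, -0.5)

    L <- matrix(base, ng, nsamp) + pairZ[, pair_of, drop = FALSE] + indZ +
      outer(log2fc, sign_s)

    # gene annotation: uncoupled genes land near a random probe so that
    # null cis pairs arise naturally; coupled genes get the configured offset
    probe_pick <- sample(config$n_probes, ng, replace = TRUE)
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    off <- round(runif(ng, -20000, 20000))
    if (!is.null(meth)) {
      probe_order <- match(sprintf("cg%07d", probe_pick), meth$manifest$probe_id)
      chrom <- meth$manifest$chrom[probe_order]
      pos <- meth$manifest$pos[probe_order]
    } else {
      chrom <- paste0("chr", sample(22, ng, replace = TRUE))
      pos <- round(runif(ng, 1e6, 5e7))
    }
    tss <- ifelse(strand == "+", pos - off, pos + off)

    if (nrow(cc)) {
      probe_ids <- sprintf("cg%07d", cc$probe)
      midx <- match(probe_ids, rownames(meth$beta))
      for (k in seq_len(nrow(cc))) {
        g <- cc$gene[k]
        z <- as.numeric(scale(meth$beta[midx[k], cohort$sample_id]))
        sig <- sqrt(config$expr_pair_sd^2 + config$expr_noise_sd^2)
        cstr <- sign(cc$r[k]) * abs(cc$r[k]) / sqrt(1 - cc$r[k]^2) * sig
        L[g, ] <- L[g, ] + cstr * z
        prow <- match(probe_ids[k], meth$manifest$probe_id)
        chrom[g] <- meth$manifest$chrom[prow]
        if (strand[g] == "+") {
          tss[g] <- meth$manifest$pos[prow] - cc$offset_bp[k]
        } else {
          tss[g] <- meth$manifest$pos[prow] + cc$offset_bp[k]
        }
      }
    }

    tpm <- pmax(2^L - 1, 0)
    dimnames(tpm) <- list(gene_id, cohort$sample_id)
    genes <- data.frame(gene_id = gene_id, chrom = chrom,
                        tss = pmax(round(tss), 1), strand = strand,
                        stringsAsFactors = FALSE)
    truth <- list(
      genes = data.frame(gene_id = gene_id, log2fc = log2fc, fc = 2^log2fc,
                         stringsAsFactors = FALSE),
      couplings = if (nrow(cc)) {
        data.frame(probe_id = sprintf("cg%07d", cc$probe),
                   gene_id = sprintf("G%05d", cc$gene),
                   r = cc$r, sign = ifelse(cc$r < 0, "negative", "positive"),
                   offset_bp = cc$offset_bp, stringsAsFactors = FALSE)
      } else {
        data.frame(probe_id = character(0), gene_id = character(0),
                   r = numeric(0), sign = character(0), offset_bp = numeric(0))
      }
    )
    list(tpm = tpm, genes = genes, truth = truth)
  })
}

#' Generate a complete synthetic twin study
#'
#' Convenience wrapper running [sim_cohort()], [sim_methylation()] and
#' [sim_expression()] from one configuration.
#'
#' @param config A [sim_config()] object.
#' @return List with `config`, `cohort`, `beta`, `manifest`, `tpm`, `genes`
#'   and `truth` (methylation and expression truth labels).
#' @export
sim_twin_study <- function(config) {
  cohort <- sim_cohort(config)
  meth <- sim_methylation(config, cohort)
  expr <- sim_expression(config, cohort, meth)
  list(config = config, cohort = cohort, beta = meth$beta,
       manifest = meth$manifest, tpm = expr$tpm, genes = expr$genes,
       truth = list(methylation = meth$truth, expression = expr$truth))
}

#' Write a synthetic study to disk as plain-text fixtures
#'
#' @param study Output of [sim_twin_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    beta = file.path(dir, "beta.tsv"),
    tpm = file.path(dir, "tpm.tsv"),
    manifest = file.path(dir, "manifest.tsv"),
    genes = file.path(dir, "genes.tsv"),
    samples = file.path(dir, "samples.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_matrix(study$beta, paths["beta"], feature_col = "probe_id")
  write_matrix(study$tpm, paths["tpm"], feature_col = "gene_id")
  write_tsv(study$manifest, paths["manifest"])
  write_tsv(study$genes, paths["genes"])
  write_tsv(study$cohort, paths["samples"])
  jsonlite::write_json(study$truth, paths["truth"], digits = NA,
                       na = "null", dataframe = "columns")
  invisible(paths)
}
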