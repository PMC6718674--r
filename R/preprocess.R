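## Probe/gene QC filters and the within-pair log2-ratio transform that the
## paired association model consumes.

#' Filter CpG probes on QC flags
#'
#' Exclusion rules, applied in order: detection failure in more than
#' `detect_fail_max` of samples; raw intensity more than `intensity_z_max`
#' SD from the mean (strict inequality, so a probe at exactly 3 SD is
#' retained); sex-chromosome probes; multi-mapped probes; SNP-overlapping
#' probes.  A probe failing any rule is excluded.
#'
#' @param manifest Manifest data frame with QC flag columns.
#' @param beta Beta matrix; every row must be present in the manifest.
#' @param detect_fail_max Maximum tolerated detection-failure fraction.
#' @param intensity_z_max Intensity z-score bound.
#' @return List with `retained` (probe ids), `exclusions` (per-rule report
#'   data frame: rule, n_excluded, example ids).
#' @export
filter_probes <- function(manifest, beta, detect_fail_max = 0.20,
                          intensity_z_max = 3) {
  absent <- setdiff(rownames(beta), manifest$probe_id)
  if (length(absent)) {
    stopf("consistency error: %d probe(s) in matrix absent from manifest (e.g. %s)",
          length(absent), absent[1])
  }
  mf <- manifest[manifest$probe_id %in% rownames(beta), ]
  rules <- list(
    detection_fail = mf$detection_fail_fraction > detect_fail_max,
    intensity_outlier = abs(mf$intensity_z) > intensity_z_max,
    sex_chrom = mf$sex_chrom | mf$chrom %in% c("chrX", "chrY"),
    multi_mapped = mf$multi_mapped,
    snp_overlap = mf$snp_overlap
  )
  excluded <- rep(FALSE, nrow(mf))
  report <- data.frame(rule = names(rules), n_excluded = 0L,
                       examples = "", stringsAsFactors = FALSE)
  for (i in seq_along(rules)) {
    hit <- rules[[i]] & !excluded       # count each probe under its first rule
    report$n_excluded[i] <- sum(hit)
    report$examples[i] <- paste(head(mf$probe_id[hit], 3), collapse = ",")
    excluded <- excluded | rules[[i]]
  }
  list(retained = mf$probe_id[!excluded], exclusions = report)
}

#' Filter genes on minimum expression
#'
#' A gene is retained iff the fraction of samples with
#' log2(TPM + 1) < `floor` is at most `max_low_fraction`.
#'
#' @param tpm TPM matrix (genes x samples).
#' @param floor Threshold on the log2(TPM+1) scale.
#' @param max_low_fraction Maximum tolerated fraction of low samples.
#' @return Character vector of retained gene ids.
#' @export
filter_genes <- function(tpm, floor = 1.0, max_low_fraction = 0.05) {
  low <- rowMeans(log2(tpm + 1) < floor)
  rownames(tpm)[low <= max_low_fraction]
}

#' Confirm monozygosity from SNP probes
#'
#' For each pair, the Pearson correlation of SNP-probe beta values between
#' the two twins; a pair is called monozygotic iff r >= `min_concordance`.
#' Genotype-tracking probes are tri-modal in beta, so unrelated individuals
#' correlate near zero.
#'
#' @param beta Beta matrix including the SNP probes.
#' @param sample_sheet Validated sample sheet.
#' @param snp_probe_ids Ids of genotype (SNP) probes; at least 10 required
#'   for a verdict.
#' @param min_concordance Correlation threshold for an MZ call.
#' @return Data frame: pair_id, r, verdict in {MZ, not_MZ, insufficient}.
#' @export
zygosity_check <- function(beta, sample_sheet, snp_probe_ids,
                           min_concordance = 0.9) {
  present <- intersect(snp_probe_ids, rownames(beta))
  pairs <- unique(sample_sheet$pair_id)
  if (length(present) < 10) {
    warnf("only %d SNP probes available (need >= 10); zygosity not assessable",
          length(present))
    return(data.frame(pair_id = pairs, r = NA_real_,
                      verdict = "insufficient", stringsAsFactors = FALSE))
  }
  res <- lapply(pairs, function(p) {
    ids <- sample_sheet$sample_id[sample_sheet$pair_id == p]
    r <- cor(beta[present, ids[1]], beta[present, ids[2]])
    data.frame(pair_id = p, r = r,
               verdict = if (is.na(r)) "insufficient"
                         else if (r >= min_concordance) "MZ" else "not_MZ",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Within-pair log2-ratio matrix
#'
#' For each feature and pair computes
#' log2((value in depressed twin + offset) / (value in nondepressed twin +
#' offset)).  For methylation betas use `offset = 1e-6` (a floor, since
#' beta = 0 is representable); for TPM use `offset = 1`, matching the
#' log2(TPM+1) filtering scale.  The companion covariate frame carries,
#' per pair, the within-pair difference (depressed minus nondepressed) for
#' twin-varying covariates and the shared value for pair-level covariates.
#'
#' @param values Feature x sample matrix.
#' @param sample_sheet Validated sample sheet covering all columns.
#' @param offset Non-negative offset added to both members before the ratio;
#'   0 is rejected for beta-like data that can contain zeros.
#' @return List of class `pair_ratios` with `ratios` (features x pairs),
#'   `covariates` (one row per pair), `batch` (factor, one level per chip)
#'   and `pair_id`.
#' @export
within_pair_logratio <- function(values, sample_sheet, offset) {
  stopifnot(offset >= 0)
  if (offset == 0 && any(values == 0)) {
    stopf("offset 0 not allowed: value matrix contains zeros")
  }
  sheet <- validate_sample_sheet(sample_sheet)
  missing <- setdiff(sheet$sample_id, colnames(values))
  if (length(missing)) {
    bad_pairs <- unique(sheet$pair_id[sheet$sample_id %in% missing])
    stopf("incomplete pair(s): %s", paste(head(bad_pairs, 5), collapse = ", "))
  }
  pairs <- unique(sheet$pair_id)
  dep <- sheet[sheet$role == "depressed", ]
  ctl <- sheet[sheet$role == "nondepressed", ]
  dep <- dep[match(pairs, dep$pair_id), ]
  ctl <- ctl[match(pairs, ctl$pair_id), ]
  ratios <- log2((values[, dep$sample_id, drop = FALSE] + offset) /
                 (values[, ctl$sample_id, drop = FALSE] + offset))
  colnames(ratios) <- pairs

  covs <- data.frame(row.names = pairs)
  for (cv in intersect(pair_shared_covariates(), names(sheet))) {
    covs[[cv]] <- if (is.numeric(dep[[cv]])) dep[[cv]]
                  else as.numeric(factor(dep[[cv]]))
  }
  for (cv in intersect(twin_varying_covariates(), names(sheet))) {
    covs[[cv]] <- dep[[cv]] - ctl[[cv]]
  }
  structure(list(ratios = ratios, covariates = covs,
                 batch = factor(dep$batch_id), pair_id = pairs),
            class = "pair_ratios")
}
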