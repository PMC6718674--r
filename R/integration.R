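## Cis methylation-expression integration: covariate-adjusted partial
## correlations for probe-gene pairs within a window of the TSS, an
## empirical permutation-derived significance threshold, sign
## classification with a TSS-offset profile, and a phenotype-adjusted
## robustness check.  Expression enters on the log2(TPM+1) scale.

#' Map cis probe-gene pairs
#'
#' A probe is paired with a gene when its position lies within `window` bp
#' of the gene's TSS.  The reported offset is strand-aware and signed:
#' negative = probe upstream of the TSS.
#'
#' @param manifest Probe manifest.
#' @param genes Gene annotation with `gene_id`, `chrom`, `tss`, `strand`.
#' @param window Cis window in bp (default +-5 kb).
#' @return Data frame: `probe_id`, `gene_id`, `offset_bp`; unique pairs.
#' @export
map_cis_pairs <- function(manifest, genes, window = 5000) {
  no_tss <- is.na(genes$tss)
  if (any(no_tss)) {
    warnf("skipping %d gene(s) without a TSS", sum(no_tss))
    genes <- genes[!no_tss, ]
  }
  out <- lapply(seq_len(nrow(genes)), function(g) {
    hit <- manifest$chrom == genes$chrom[g] &
      abs(manifest$pos - genes$tss[g]) <= window
    if (!any(hit)) return(NULL)
    pos <- manifest$pos[hit]
    offset <- if (genes$strand[g] == "-") genes$tss[g] - pos
              else pos - genes$tss[g]
    data.frame(probe_id = manifest$probe_id[hit], gene_id = genes$gene_id[g],
               offset_bp = offset, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(probe_id = character(0), gene_id = character(0),
                      offset_bp = numeric(0)))
  }
  unique(out)
}

#' Partial correlation given covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' projection on an intercept plus the covariates; with no covariates this
#' is the plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric matrix / data frame (samples x k);
#'   requires at least k + 3 samples.
#' @return Partial correlation in \[-1, 1\], or `NA` when a residual
#'   variance is zero.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  C <- covariate_design(covariates, n)
  if (n < ncol(C) - 1 + 3) stopf("need >= k + 3 samples")
  qC <- qr(C)
  rx <- qr.resid(qC, x)
  ry <- qr.resid(qC, y)
  # zero residual variance (up to numerical noise relative to the input
  # scale) leaves the partial correlation undefined
  degenerate <- function(r, orig) {
    sd(r) <= 1e-10 * max(sd(orig), .Machine$double.eps)
  }
  if (degenerate(rx, x) || degenerate(ry, y)) return(NA_real_)
  cor(rx, ry)
}

covariate_design <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1))
  M <- as.matrix(as.data.frame(covariates))
  stopifnot(nrow(M) == n)
  storage.mode(M) <- "double"
  cbind(1, M)
}

#' Numeric sample-level covariate matrix from a sample sheet
#'
#' @param sample_sheet Sample sheet.
#' @param covariates Covariate column names; character columns are coded as
#'   factor levels.
#' @return Numeric matrix (samples x covariates) with sample_id rownames.
#' @export
sample_covariate_matrix <- function(sample_sheet,
                                    covariates = c("age", "sex", "bmi",
                                                   "smoking", "alcohol",
                                                   "income", "education")) {
  covariates <- intersect(covariates, names(sample_sheet))
  M <- sapply(covariates, function(cv) {
    v <- sample_sheet[[cv]]
    if (is.numeric(v)) v else as.numeric(factor(v))
  })
  rownames(M) <- sample_sheet$sample_id
  M
}

# Residualize the columns of M against [1, C]; columns are returned
# standardized to unit sum of squares so pairwise correlations reduce to
# cross products.
resid_std <- function(M, qC) {
  R <- qr.resid(qC, M)
  ss <- sqrt(colSums(R^2))
  ss[ss == 0] <- NA_real_
  sweep(R, 2, ss, "/")
}

#' Covariate-adjusted partial correlations for cis pairs
#'
#' @param beta Beta matrix (probes x samples).
#' @param tpm TPM matrix (genes x samples, same sample order); correlated
#'   on the log2(TPM+1) scale.
#' @param covariates Sample-level covariate matrix (samples x k) or `NULL`.
#' @param pairs Cis pair table from [map_cis_pairs()].
#' @return `pairs` with a `partial_r` column.
#' @export
cis_correlations <- function(beta, tpm, covariates, pairs) {
  stopifnot(identical(colnames(beta), colnames(tpm)))
  n <- ncol(beta)
  qC <- qr(covariate_design(covariates, n))
  probes <- unique(pairs$probe_id)
  genes <- unique(pairs$gene_id)
  X <- resid_std(t(beta[probes, , drop = FALSE]), qC)
  Y <- resid_std(t(log2(tpm[genes, , drop = FALSE] + 1)), qC)
  pi_ <- match(pairs$probe_id, probes)
  gi <- match(pairs$gene_id, genes)
  pairs$partial_r <- colSums(X[, pi_, drop = FALSE] * Y[, gi, drop = FALSE])
  pairs
}

#' Permutation-derived significance threshold for cis correlations
#'
#' Expression sample labels are permuted `B` times, breaking the
#' probe-gene linkage while preserving the covariate linkage to the
#' methylation samples; all cis-pair partial correlations are recomputed
#' per permutation and pooled into one empirical null.  The threshold pair
#' is the (alpha/2, 1 - alpha/2) percentiles of the signed pooled null
#' (`tail = "two"`, the default), or its (alpha, 1 - alpha) percentiles
#' under the literal one-tail fifth-percentile reading (`tail = "one"`).
#'
#' @param beta,tpm,covariates,pairs As in [cis_correlations()].
#' @param B Number of permutations (>= 20).
#' @param alpha Significance level of the empirical rule.
#' @param tail `"two"` or `"one"`.
#' @param seed Seed for the permutation stream.
#' @return List: `lower`, `upper`, `B`, `alpha`, `tail`, `n_null`.
#' @export
permutation_threshold <- function(beta, tpm, covariates, pairs, B = 100,
                                  alpha = 0.05, tail = c("two", "one"),
                                  seed = 1) {
  tail <- match.arg(tail)
  if (B < 20) stopf("B must be >= 20 for a stable percentile")
  n <- ncol(beta)
  qC <- qr(covariate_design(covariates, n))
  probes <- unique(pairs$probe_id)
  genes <- unique(pairs$gene_id)
  X <- resid_std(t(beta[probes, , drop = FALSE]), qC)
  E <- t(log2(tpm[genes, , drop = FALSE] + 1))
  pi_ <- match(pairs$probe_id, probes)
  gi <- match(pairs$gene_id, genes)
  null_r <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      Y <- resid_std(E[sample(n), , drop = FALSE], qC)
      colSums(X[, pi_, drop = FALSE] * Y[, gi, drop = FALSE])
    }, numeric(nrow(pairs)))
  })
  null_r <- as.numeric(null_r)
  probs <- if (tail == "two") c(alpha / 2, 1 - alpha / 2)
           else c(alpha, 1 - alpha)
  qs <- quantile(null_r, probs, na.rm = TRUE, names = FALSE)
  list(lower = qs[1], upper = qs[2], B = B, alpha = alpha, tail = tail,
       n_null = length(null_r))
}

#' Classify cis pairs against the permutation thresholds
#'
#' @param pairs Cis pairs with `partial_r` (from [cis_correlations()]).
#' @param thresholds Output of [permutation_threshold()].
#' @param window Cis window (for the offset profile range).
#' @param bin_bp Offset bin width for the TSS profile.
#' @return List: `pairs` (with `significant` and `sign`), `summary`
#'   (counts, negative fraction among significant pairs, unique
#'   probes/genes) and `profile` (mean partial r per signed offset bin).
#' @export
classify_cis_pairs <- function(pairs, thresholds, window = 5000,
                               bin_bp = 500) {
  pairs$significant <- !is.na(pairs$partial_r) &
    (pairs$partial_r < thresholds$lower | pairs$partial_r > thresholds$upper)
  pairs$sign <- ifelse(pairs$partial_r < 0, "negative", "positive")
  sig <- pairs[pairs$significant, ]
  breaks <- seq(-window, window, by = bin_bp)
  bin <- cut(pairs$offset_bp, breaks = breaks, include.lowest = TRUE)
  prof <- data.frame(
    bin_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
    mean_r = as.numeric(tapply(pairs$partial_r, bin, mean)),
    n = as.integer(table(bin))
  )
  list(
    pairs = pairs,
    summary = list(
      n_pairs = nrow(pairs),
      n_significant = nrow(sig),
      negative_fraction = if (nrow(sig)) mean(sig$sign == "negative")
                          else NA_real_,
      n_unique_probes = length(unique(sig$probe_id)),
      n_unique_genes = length(unique(sig$gene_id)),
      lower = thresholds$lower, upper = thresholds$upper
    ),
    profile = prof
  )
}

#' Robustness of cis correlations to phenotype adjustment
#'
#' Recomputes the partial correlations with the depression indicator
#' appended to the covariates and reports the fraction of previously
#' significant pairs that remain beyond the thresholds.
#'
#' @param beta,tpm,covariates As in [cis_correlations()].
#' @param classified Output of [classify_cis_pairs()].
#' @param mdd 0/1 vector per sample (1 = depressed).
#' @param thresholds Output of [permutation_threshold()].
#' @return List: `fraction_robust` (`NA` when no pair was significant) and
#'   the re-evaluated pair table.
#' @export
robustness_with_mdd <- function(beta, tpm, covariates, classified, mdd,
                                thresholds) {
  covs2 <- cbind(covariate_design(covariates, ncol(beta))[, -1, drop = FALSE],
                 mdd = mdd)
  pairs2 <- cis_correlations(beta, tpm, covs2, classified$pairs)
  was_sig <- classified$pairs$significant
  still <- !is.na(pairs2$partial_r) &
    (pairs2$partial_r < thresholds$lower |
       pairs2$partial_r > thresholds$upper)
  list(
    fraction_robust = if (any(was_sig)) mean(still[was_sig]) else NA_real_,
    pairs = transform(pairs2, robust_to_mdd = still)
  )
}
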