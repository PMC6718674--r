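## Region-level aggregation of probe EWAS results and DMR calling.
##
## Candidate regions are maximal runs of same-chromosome probes whose
## inter-probe gap does not exceed `max_gap_bp`.  A candidate's region-level
## p-value combines the signed probe z-scores by an equal-weight Stouffer
## sum; a DMR requires >= `min_probes` probes, a peak probe p below
## `peak_p_max` (strict) and a mean pairwise probe correlation of at least
## `min_corr`, and is significant when its Benjamini-Hochberg q over all
## scored candidates falls below `q_max`.

#' Form candidate regions from adjacent probes
#'
#' @param manifest Manifest sorted by (chrom, pos); an unsorted manifest is
#'   an error.
#' @param results EWAS results from [run_feature_scan()]; only probes with
#'   a result participate in clustering.
#' @param max_gap_bp Maximum genomic gap between adjacent probes of a
#'   region.
#' @return Data frame with one row per candidate (>= 2 probes): `chrom`,
#'   `start`, `end`, `n_probes` and a `probe_ids` list-column ordered by
#'   position.  Singleton probes are dropped.
#' @export
form_candidate_regions <- function(manifest, results, max_gap_bp = 1000) {
  ord <- order(chrom_rank(manifest$chrom), manifest$pos)
  if (!identical(ord, seq_len(nrow(manifest)))) {
    stopf("manifest must be sorted by (chrom, pos)")
  }
  mf <- manifest[manifest$probe_id %in% results$feature_id, ]
  if (nrow(mf) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_probes = integer(0),
                      probe_ids = I(list())))
  }
  new_run <- c(TRUE, mf$chrom[-1] != mf$chrom[-nrow(mf)] |
                 diff(mf$pos) > max_gap_bp)
  run_id <- cumsum(new_run)
  keep <- as.integer(names(which(table(run_id) >= 2)))
  cands <- lapply(keep, function(r) {
    idx <- which(run_id == r)
    data.frame(chrom = mf$chrom[idx[1]], start = mf$pos[idx[1]],
               end = mf$pos[idx[length(idx)]], n_probes = length(idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, cands)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_probes = integer(0))
  }
  out$probe_ids <- I(lapply(keep, function(r) mf$probe_id[run_id == r]))
  rownames(out) <- NULL
  out
}

#' Mean pairwise probe correlation within a region
#'
#' Mean of the pairwise Pearson correlations of beta values across all
#' samples, over all probe pairs; a zero-variance probe contributes 0 to
#' its pairs (with a warning).  `method = "min"` returns the minimum
#' pairwise correlation instead.
#'
#' @param probe_ids Probes of the region (>= 2).
#' @param beta Beta matrix.
#' @param method `"mean"` (default) or `"min"`.
#' @return Scalar correlation summary.
#' @export
probe_correlation <- function(probe_ids, beta, method = c("mean", "min")) {
  method <- match.arg(method)
  stopifnot(length(probe_ids) >= 2)
  b <- beta[probe_ids, , drop = FALSE]
  sds <- apply(b, 1, sd)
  if (any(sds == 0)) {
    warnf("zero-variance probe(s) in region: %s",
          paste(probe_ids[sds == 0], collapse = ","))
  }
  cm <- suppressWarnings(cor(t(b)))
  cm[!is.finite(cm)] <- 0
  vals <- cm[upper.tri(cm)]
  if (method == "mean") mean(vals) else min(vals)
}

stouffer_p <- function(p, sign) {
  z <- sign(sign) * qnorm(pmax(pmin(p, 1 - 1e-16), 1e-300) / 2,
                          lower.tail = FALSE)
  Z <- sum(z) / sqrt(length(z))
  2 * pnorm(-abs(Z))
}

region_gene <- function(probe_ids, manifest) {
  g <- manifest$gene_symbol[match(probe_ids, manifest$probe_id)]
  names(sort(table(g), decreasing = TRUE))[1]
}

#' Score candidate regions
#'
#' Computes, per candidate: the peak probe (minimum p; ties broken by
#' larger |alpha|, then by position), the Stouffer-combined region p, the
#' mean fold change 2^(mean alpha), the mean and peak within-pair percent
#' methylation differences, the mean pairwise probe correlation, and the
#' direction (hyper when mean FC > 1; an exact tie is broken to "hyper"
#' and flagged).
#'
#' @param candidates Output of [form_candidate_regions()].
#' @param results Probe-level EWAS results.
#' @param beta Beta matrix.
#' @param sample_sheet Validated sample sheet (for the depressed-minus-
#'   nondepressed beta differences).
#' @param manifest Manifest (for peak-tie position order and gene labels).
#' @param corr_method Passed to [probe_correlation()].
#' @return Candidate table extended with the region statistics; candidates
#'   whose probes lack results are skipped with a logged reason.
#' @export
score_regions <- function(candidates, results, beta, sample_sheet, manifest,
                          corr_method = "mean") {
  sheet <- validate_sample_sheet(sample_sheet)
  pairs <- unique(sheet$pair_id)
  dep <- sheet$sample_id[sheet$role == "depressed"][
    order(sheet$pair_id[sheet$role == "depressed"])]
  ctl <- sheet$sample_id[sheet$role == "nondepressed"][
    order(sheet$pair_id[sheet$role == "nondepressed"])]
  ridx <- setNames(seq_len(nrow(results)), results$feature_id)

  rows <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    pids <- candidates$probe_ids[[i]]
    if (!all(pids %in% names(ridx)) ||
        any(is.na(results$p[ridx[pids]]))) {
      log_msg("region %s:%d-%d skipped: missing probe result",
              candidates$chrom[i], candidates$start[i], candidates$end[i])
      next
    }
    rr <- results[ridx[pids], ]
    pos <- manifest$pos[match(pids, manifest$probe_id)]
    peak_ord <- order(rr$p, -abs(rr$alpha), pos)
    peak <- peak_ord[1]
    mean_alpha <- mean(rr$alpha)
    diffs <- rowMeans(beta[pids, dep, drop = FALSE] -
                      beta[pids, ctl, drop = FALSE])
    tie <- mean_alpha == 0
    rows[[i]] <- data.frame(
      chrom = candidates$chrom[i], start = candidates$start[i],
      end = candidates$end[i], size = candidates$end[i] - candidates$start[i],
      gene = region_gene(pids, manifest),
      n_probes = candidates$n_probes[i],
      peak_probe_id = pids[peak],
      peak_p = rr$p[peak],
      region_p = stouffer_p(rr$p, rr$alpha),
      mean_probe_corr = probe_correlation(pids, beta, corr_method),
      mean_fc = 2^mean_alpha,
      mean_diff_pct = 100 * mean(diffs),
      peak_diff_pct = 100 * diffs[peak],
      direction = if (mean_alpha >= 0) "hyper" else "hypo",
      direction_tie = tie,
      stringsAsFactors = FALSE
    )
  }
  keep <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[keep])
  if (is.null(out)) return(empty_region_table())
  out$probe_ids <- I(candidates$probe_ids[keep])
  rownames(out) <- NULL
  out
}

empty_region_table <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             size = numeric(0), gene = character(0), n_probes = integer(0),
             peak_probe_id = character(0), peak_p = numeric(0),
             region_p = numeric(0), mean_probe_corr = numeric(0),
             mean_fc = numeric(0), mean_diff_pct = numeric(0),
             peak_diff_pct = numeric(0), direction = character(0),
             direction_tie = logical(0), region_q = numeric(0),
             significant = logical(0), probe_ids = I(list()),
             stringsAsFactors = FALSE)
}

#' Call DMRs from scored candidates
#'
#' A DMR must have at least `min_probes` probes, a peak probe p strictly
#' below `peak_p_max` and a mean probe correlation of at least `min_corr`.
#' Region q-values are Benjamini-Hochberg over the region p of *all*
#' scored candidates (the candidate count is the correction family), and a
#' DMR is significant when q < `q_max`.  Output is sorted by region p.
#'
#' @param scored Output of [score_regions()].
#' @param min_probes,peak_p_max,min_corr,q_max Calling thresholds.
#' @return Data frame of DMRs (candidates meeting the probe-count, peak-p
#'   and correlation criteria) with `region_q` and `significant`; the total
#'   candidate count used as the correction family is attached as
#'   attribute `m`.
#' @export
call_dmrs <- function(scored, min_probes = 5, peak_p_max = 0.01,
                      min_corr = 0.30, q_max = 0.05) {
  if (nrow(scored) == 0) return(empty_region_table())
  scored$region_q <- bh_fdr(scored$region_p)
  pass <- scored$n_probes >= min_probes &
    scored$peak_p < peak_p_max &
    scored$mean_probe_corr >= min_corr
  out <- scored[pass, , drop = FALSE]
  out$significant <- out$region_q < q_max
  out <- out[order(out$region_p), ]
  rownames(out) <- NULL
  attr(out, "m") <- nrow(scored)
  out
}

#' Genomic-feature enrichment of DMR probes
#'
#' For every genomic feature class and CGI context, a 2x2 Fisher exact
#' test of DMR probes against the retained probe background, with the
#' odds ratio, fold enrichment (observed fraction / background fraction)
#' and Benjamini-Hochberg q over categories.
#'
#' @param dmr_probe_ids Probes belonging to called DMRs.
#' @param manifest Manifest covering the background.
#' @param background_ids Background probe ids (default: whole manifest).
#' @return Data frame: category type, level, counts, odds ratio, fold
#'   enrichment, p, q.
#' @export
feature_enrichment <- function(dmr_probe_ids, manifest,
                               background_ids = manifest$probe_id) {
  if (length(dmr_probe_ids) == 0) {
    return(data.frame(type = character(0), level = character(0),
                      n_dmr = integer(0), n_background = integer(0),
                      odds_ratio = numeric(0), fold = numeric(0),
                      p = numeric(0), q = numeric(0)))
  }
  mf <- manifest[match(background_ids, manifest$probe_id), ]
  in_dmr <- mf$probe_id %in% dmr_probe_ids
  one_type <- function(col, type) {
    lv <- sort(unique(mf[[col]]))
    do.call(rbind, lapply(lv, function(l) {
      in_cat <- mf[[col]] == l
      tab <- matrix(c(sum(in_dmr & in_cat), sum(in_dmr & !in_cat),
                      sum(!in_dmr & in_cat), sum(!in_dmr & !in_cat)), 2, 2,
                    byrow = TRUE)
      ft <- fisher.test(tab)
      data.frame(type = type, level = l,
                 n_dmr = tab[1, 1], n_background = sum(in_cat),
                 odds_ratio = unname(ft$estimate),
                 fold = (tab[1, 1] / sum(in_dmr)) / (sum(in_cat) / nrow(mf)),
                 p = ft$p.value, stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(one_type("feature_class", "feature_class"),
               one_type("cgi_context", "cgi_context"))
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}
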