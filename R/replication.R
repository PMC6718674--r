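## Case-control replication scan in an unpaired dataset: per-feature
## logistic regression of case status on the feature value with
## covariates, FDR over the tested region/gene family, and a
## direction-concordance call against the discovery effect signs.

#' Case-control logistic replication scan
#'
#' For each feature, fits `case ~ value + covariates` by maximum-likelihood
#' logistic regression and reports the Wald p for the value coefficient.
#' When a `regions` map is supplied (probe -> region), q-values are
#' computed by Benjamini-Hochberg on each region's minimum probe p with
#' the number of regions as the family size; a region replicates iff any
#' of its probes reaches q < `q_max` with a direction concordant with
#' discovery.  Without regions, the family is the tested features
#' themselves.
#'
#' @param values Feature x sample matrix (methylation beta or expression).
#' @param case 0/1 vector per sample (1 = case); >= 10 cases and >= 10
#'   controls required.
#' @param covariates Sample-level covariate matrix / data frame or `NULL`.
#' @param features Feature ids to test (must exist in `values`).
#' @param regions Optional data frame `feature_id` / `region_id` mapping
#'   probes to discovery regions.
#' @param discovery_alpha Optional named vector of discovery effect signs
#'   (log2 FC) for the concordance flag.
#' @param q_max Replication significance threshold.
#' @return List: `features` (per-feature coefficient, p, q, concordance,
#'   status), `regions` (per-region min p, q, replicated flag; `NULL`
#'   without a region map).
#' @export
casecontrol_scan <- function(values, case, covariates = NULL, features,
                             regions = NULL, discovery_alpha = NULL,
                             q_max = 0.05) {
  case <- as.integer(case)
  if (sum(case == 1) < 10 || sum(case == 0) < 10) {
    stopf("need >= 10 cases and >= 10 controls (got %d / %d)",
          sum(case == 1), sum(case == 0))
  }
  missing <- setdiff(features, rownames(values))
  if (length(missing)) {
    stopf("feature(s) absent from matrix: %s",
          paste(head(missing, 5), collapse = ", "))
  }
  C <- if (is.null(covariates)) NULL else as.matrix(as.data.frame(covariates))
  rows <- lapply(features, function(f) {
    v <- values[f, ]
    if (sd(v) == 0) {
      return(data.frame(feature_id = f, coef = NA_real_, se = NA_real_,
                        p = NA_real_, status = "non-converged",
                        stringsAsFactors = FALSE))
    }
    dat <- if (is.null(C)) data.frame(v = v) else data.frame(v = v, C)
    fit <- tryCatch(
      suppressWarnings(glm(case ~ ., data = dat, family = binomial())),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged ||
        any(abs(coef(fit)) > 1e3, na.rm = TRUE)) {
      warnf("feature %s: logistic fit did not converge (separation?)", f)
      return(data.frame(feature_id = f, coef = NA_real_, se = NA_real_,
                        p = NA_real_, status = "non-converged",
                        stringsAsFactors = FALSE))
    }
    sm <- summary(fit)$coefficients
    data.frame(feature_id = f, coef = sm["v", 1], se = sm["v", 2],
               p = 2 * pnorm(-abs(sm["v", 1] / sm["v", 2])),
               status = "ok", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (!is.null(discovery_alpha)) {
    res$direction_concordant <- !is.na(res$coef) &
      sign(res$coef) == sign(discovery_alpha[res$feature_id])
  }
  region_tab <- NULL
  if (!is.null(regions)) {
    res$region_id <- regions$region_id[match(res$feature_id,
                                             regions$feature_id)]
    ok <- res$status == "ok" & !is.na(res$region_id)
    min_p <- tapply(res$p[ok], res$region_id[ok], min)
    region_tab <- data.frame(region_id = names(min_p),
                             min_p = as.numeric(min_p),
                             stringsAsFactors = FALSE)
    region_tab$q <- bh_fdr(region_tab$min_p, m = nrow(region_tab))
    best <- vapply(region_tab$region_id, function(r) {
      sub <- res[ok & res$region_id == r, ]
      sub$feature_id[which.min(sub$p)]
    }, character(1))
    region_tab$best_probe <- best
    conc <- if (!is.null(discovery_alpha)) {
      res$direction_concordant[match(best, res$feature_id)]
    } else {
      TRUE
    }
    region_tab$replicated <- region_tab$q < q_max & conc
    # per-feature q inherited from the region family
    res$q <- region_tab$q[match(res$region_id, region_tab$region_id)]
  } else {
    res$q <- NA_real_
    ok <- res$status == "ok"
    res$q[ok] <- bh_fdr(res$p[ok], m = sum(ok))
  }
  list(features = res, regions = region_tab)
}
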