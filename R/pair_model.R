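## Per-feature within-pair association model for discordant twin pairs.
##
## The response for each feature is the within-pair log2 ratio
## (depressed / nondepressed).  The model is
##
##   ratio_j = alpha + sum_i beta_i x_ij + u_{batch(j)} + e_j
##
## with a batch random intercept fitted by REML.  alpha is the mean
## log2 fold change between depressed and nondepressed twins (FC = 2^alpha;
## alpha > 0 = hypermethylation / upregulation in the depressed twin) and
## is tested against 0 with a Wald t-statistic on
## n_pairs - n_fixed_effects degrees of freedom.  When the batch variance
## estimate is zero or there are fewer than 3 batches, the fit falls back
## to ordinary least squares.

build_fixed_design <- function(covariates, n) {
  if (is.null(covariates) || (!is.null(dim(covariates)) && ncol(covariates) == 0)) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == n)
  M <- as.matrix(covariates)
  # Pair-shared covariates (age, sex) are mean-centered so the intercept is
  # the mean log2 FC at the cohort average rather than an extrapolation
  # (e.g. to age 0) with an inflated SE.  Difference-coded twin-varying
  # covariates stay raw: a systematic within-pair difference is exactly the
  # confounding the covariate should absorb from the intercept.
  shared <- colnames(M) %in% pair_shared_covariates()
  if (any(shared)) {
    M[, shared] <- scale(M[, shared, drop = FALSE], center = TRUE,
                         scale = FALSE)
  }
  X <- cbind("(Intercept)" = 1, M)
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(v) {
    length(unique(v)) > 1
  }))
  if (any(!keep)) {
    warnf("dropping constant covariate(s): %s",
          paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    warnf("dropping rank-deficient covariate(s): %s",
          paste(drop, collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  X
}

ols_fit <- function(y, X) {
  fit <- lm.fit(X, y)
  n <- length(y); p <- ncol(X)
  df <- n - p
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * sigma2)
  list(coef = fit$coefficients, se = se, df = df, batch_var = 0,
       method = "ols")
}

mixed_template <- function(y, X, batch) {
  dat <- data.frame(.y = y, X[, -1, drop = FALSE], .batch = batch,
                    check.names = FALSE)
  fixed <- if (ncol(X) > 1) {
    paste0(".y ~ 1 + ", paste(sprintf("`%s`", colnames(X)[-1]), collapse = " + "))
  } else {
    ".y ~ 1"
  }
  fml <- stats::as.formula(paste0(fixed, " + (1 | .batch)"))
  suppressMessages(lme4::lmer(
    fml, data = dat, REML = TRUE,
    control = lme4::lmerControl(calc.derivs = FALSE,
                                check.conv.singular = "ignore")))
}

extract_mixed <- function(m, n, p) {
  vc <- as.data.frame(lme4::VarCorr(m))
  batch_var <- vc$vcov[vc$grp == ".batch"]
  list(coef = lme4::fixef(m),
       se = sqrt(diag(as.matrix(vcov(m)))),
       df = n - p, batch_var = batch_var, method = "mixed")
}

result_row <- function(feature_id, fit, X, n) {
  tt <- fit$coef / fit$se
  pv <- 2 * pt(-abs(tt), fit$df)
  out <- data.frame(feature_id = feature_id,
                    alpha = unname(fit$coef[1]),
                    fc = 2^unname(fit$coef[1]),
                    se = unname(fit$se[1]),
                    p = unname(pv[1]),
                    batch_var = fit$batch_var,
                    n_pairs_used = n,
                    method = fit$method,
                    status = "ok",
                    stringsAsFactors = FALSE)
  if (ncol(X) > 1) {
    for (j in 2:ncol(X)) {
      nm <- colnames(X)[j]
      out[[paste0("beta_", nm)]] <- unname(fit$coef[j])
      out[[paste0("p_", nm)]] <- unname(pv[j])
    }
  }
  out
}

na_row <- function(feature_id, reason, X, n) {
  out <- data.frame(feature_id = feature_id, alpha = NA_real_, fc = NA_real_,
                    se = NA_real_, p = NA_real_, batch_var = NA_real_,
                    n_pairs_used = n, method = "failed", status = reason,
                    stringsAsFactors = FALSE)
  if (ncol(X) > 1) {
    for (j in 2:ncol(X)) {
      out[[paste0("beta_", colnames(X)[j])]] <- NA_real_
      out[[paste0("p_", colnames(X)[j])]] <- NA_real_
    }
  }
  out
}

#' Fit the within-pair model for a single feature
#'
#' @param y Numeric vector of within-pair log2 ratios, one per pair.
#' @param covariates Optional per-pair covariate data frame (within-pair
#'   differences for twin-varying covariates, shared values for pair-level
#'   ones).  Constant and rank-deficient columns are dropped with a warning.
#' @param batch Optional factor of pair-level batch assignments, fitted as
#'   a random intercept; with fewer than 3 batches, or a zero variance
#'   estimate, ordinary least squares is used instead.
#' @return One-row data frame: `alpha` (mean within-pair log2 FC),
#'   `fc = 2^alpha`, `se`, `p` (Wald t, df = n_pairs - n_fixed),
#'   per-covariate `beta_*`/`p_*`, `batch_var`, `method`.
#' @export
fit_pair_model <- function(y, covariates = NULL, batch = NULL) {
  ok <- is.finite(y)
  if (sum(ok) < 3) stopf("need >= 3 pairs with finite response (got %d)", sum(ok))
  n <- length(y)
  X <- build_fixed_design(covariates, n)
  use_mixed <- !is.null(batch) && nlevels(factor(batch)) >= 3
  fit <- if (use_mixed) {
    m <- mixed_template(y, X, factor(batch))
    f <- extract_mixed(m, n, ncol(X))
    if (f$batch_var <= 0) ols_fit(y, X) else f
  } else {
    ols_fit(y, X)
  }
  result_row("feature", fit, X, n)
}

#' Genome-wide within-pair association scan
#'
#' Fits the within-pair model for every feature (row) of a log2-ratio
#' matrix and appends Benjamini-Hochberg q-values.  Per-feature fit
#' failures are recorded with a reason and do not stop the scan.
#'
#' Batch inference pools information across features: each feature's batch
#' variance ratio is estimated by REML (and reported), but test statistics
#' use generalized least squares with the *consensus* ratio (the median
#' over features), in the spirit of limma's duplicateCorrelation.
#' Per-feature REML ratios hit the boundary at zero for a sizeable
#' fraction of features even when a batch effect is real, and Wald tests
#' at a boundary estimate are anti-conservative; the consensus ratio is
#' estimated from thousands of features, so per-feature GLS with it gives
#' an essentially exact t-test on n_pairs - n_fixed degrees of freedom.
#' A consensus ratio of zero reduces to ordinary least squares.
#'
#' @param ratios A `pair_ratios` object from [within_pair_logratio()], or a
#'   features x pairs numeric matrix.
#' @param covariates Covariates to adjust for: a per-pair data frame, or
#'   (for `pair_ratios` input) a character vector naming columns of its
#'   covariate frame.  `NULL` adjusts for nothing.
#' @param batch Pair-level batch factor; defaults to the one carried by the
#'   `pair_ratios` object.
#' @param verbose Log progress every 1000 features.
#' @return Data frame with one row per feature (alpha, fc, se, p, q,
#'   covariate effects, batch_var, method, status).
#' @export
run_feature_scan <- function(ratios, covariates = NULL, batch = NULL,
                             verbose = FALSE) {
  if (inherits(ratios, "pair_ratios")) {
    if (is.character(covariates)) {
      missing <- setdiff(covariates, names(ratios$covariates))
      if (length(missing)) {
        stopf("unknown covariate(s): %s", paste(missing, collapse = ", "))
      }
      covariates <- ratios$covariates[, covariates, drop = FALSE]
    }
    batch <- batch %||% ratios$batch
    mat <- ratios$ratios
  } else {
    mat <- ratios
  }
  if (nrow(mat) == 0) {
    return(data.frame(feature_id = character(0), alpha = numeric(0),
                      fc = numeric(0), se = numeric(0), p = numeric(0),
                      batch_var = numeric(0), n_pairs_used = integer(0),
                      method = character(0), status = character(0),
                      q = numeric(0), stringsAsFactors = FALSE))
  }
  n <- ncol(mat)
  if (n < 3) stopf("need >= 3 pairs (got %d)", n)
  X <- withCallingHandlers(
    build_fixed_design(covariates, n),
    warning = function(w) {
      log_msg("%s", conditionMessage(w), verbose = verbose)
      invokeRestart("muffleWarning")
    })
  use_mixed <- !is.null(batch) && nlevels(factor(batch)) >= 3
  template <- NULL
  if (use_mixed) {
    template <- tryCatch(mixed_template(mat[1, ], X, factor(batch)),
                         error = function(e) NULL)
    if (is.null(template)) {
      use_mixed <- FALSE
      log_msg("mixed template failed; using OLS for all features",
              verbose = verbose)
    }
  }

  ## pass 1: per-feature REML batch variance ratios
  nfeat <- nrow(mat)
  ok_y <- apply(mat, 1, function(y) all(is.finite(y)))
  lambda_i <- rep(NA_real_, nfeat)    # theta^2 = batch_var / residual_var
  batch_var_i <- rep(NA_real_, nfeat)
  if (use_mixed) {
    for (i in which(ok_y)) {
      m <- tryCatch(
        suppressMessages(suppressWarnings(lme4::refit(template, mat[i, ]))),
        error = function(e) NULL)
      if (!is.null(m)) {
        th <- lme4::getME(m, "theta")
        lambda_i[i] <- th^2
        batch_var_i[i] <- th^2 * lme4::getME(m, "sigma")^2
      }
      if (i %% 1000 == 0) log_msg("scan (variance pass): %d/%d features", i,
                                  nfeat, verbose = verbose)
    }
  }
  lambda <- if (use_mixed) median(lambda_i, na.rm = TRUE) else 0
  if (!is.finite(lambda) || lambda <= 1e-8) lambda <- 0
  log_msg("consensus batch variance ratio: %.4g", lambda, verbose = verbose)

  ## pass 2: GLS at the consensus ratio (OLS when it is zero)
  if (lambda > 0) {
    Z <- stats::model.matrix(~ 0 + factor(batch))
    W <- solve(chol(diag(n) + lambda * tcrossprod(Z)))
    Xt <- crossprod(W, X)
    dimnames(Xt) <- dimnames(X)
  } else {
    W <- NULL
    Xt <- X
  }
  XtXinv <- chol2inv(chol(crossprod(Xt)))
  p_fixed <- ncol(X)
  rows <- vector("list", nfeat)
  for (i in seq_len(nfeat)) {
    fid <- rownames(mat)[i] %||% as.character(i)
    rows[[i]] <- tryCatch({
      if (!ok_y[i]) stop("non-finite response")
      yt <- if (is.null(W)) mat[i, ] else as.numeric(crossprod(W, mat[i, ]))
      f <- lm.fit(Xt, yt)
      s2 <- sum(f$residuals^2) / (n - p_fixed)
      fit <- list(coef = f$coefficients,
                  se = sqrt(diag(XtXinv) * s2),
                  df = n - p_fixed,
                  batch_var = if (use_mixed) batch_var_i[i] else 0,
                  method = if (lambda > 0) "gls" else "ols")
      result_row(fid, fit, X, n)
    }, error = function(e) na_row(fid, conditionMessage(e), X, n))
    if (i %% 1000 == 0) log_msg("scan: %d/%d features", i, nfeat,
                                verbose = verbose)
  }
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  ok <- !is.na(res$p)
  res$q[ok] <- bh_fdr(res$p[ok])
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param m Total number of tests to correct for; defaults to `length(p)`
#'   and may be larger (e.g. when a subset of a known family is supplied).
#' @return Vector of q-values with enforced step-up monotonicity.
#' @export
bh_fdr <- function(p, m = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  m <- m %||% length(p)
  if (m < length(p)) stopf("m must be >= number of p-values")
  p.adjust(p, method = "BH", n = m)
}

#' Sensitivity re-run with extra covariates
#'
#' Re-runs the feature scan with an augmented fixed-effect set (e.g. adding
#' adverse childhood experience, PTSD, or antidepressant-use indicators) and
#' reports, per feature, p before and after plus significance flips at
#' q < `q_max`.  Extra covariates that are constant or collinear with the
#' base set are dropped (with a log message), leaving results unchanged.
#'
#' @param ratios A `pair_ratios` object.
#' @param base_covariates Character vector of covariate names for the base
#'   model.
#' @param extra_covariates Character vector of covariate names to add.
#' @param q_max Significance threshold for the flip report.
#' @param verbose Log progress.
#' @return Data frame: feature_id, p_before, p_after, q_before, q_after,
#'   significant_before/after, flipped.
#' @export
sensitivity_rerun <- function(ratios, base_covariates, extra_covariates,
                              q_max = 0.05, verbose = FALSE) {
  stopifnot(inherits(ratios, "pair_ratios"))
  before <- run_feature_scan(ratios, covariates = base_covariates,
                             verbose = verbose)
  after <- run_feature_scan(ratios,
                            covariates = union(base_covariates,
                                               extra_covariates),
                            verbose = verbose)
  out <- data.frame(feature_id = before$feature_id,
                    p_before = before$p, p_after = after$p,
                    q_before = before$q, q_after = after$q,
                    stringsAsFactors = FALSE)
  out$significant_before <- !is.na(out$q_before) & out$q_before < q_max
  out$significant_after <- !is.na(out$q_after) & out$q_after < q_max
  out$flipped <- out$significant_before != out$significant_after
  out
}
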