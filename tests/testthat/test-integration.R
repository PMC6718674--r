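test_that("cis pair mapping is window-bounded and strand-aware", {
  mf <- toy_manifest(c("cgA", "cgB", "cgC"), "chr1", c(10000, 19001, 30000))
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      chrom = "chr1", tss = c(14000, 14000, 28000),
                      strand = c("+", "-", "-"), stringsAsFactors = FALSE)
  pairs <- map_cis_pairs(mf, genes, window = 5000)
  # probe 4000 bp upstream of a + strand TSS
  expect_equal(pairs$offset_bp[pairs$probe_id == "cgA" &
                                 pairs$gene_id == "g1"], -4000)
  # same geometry on the - strand flips the sign
  expect_equal(pairs$offset_bp[pairs$probe_id == "cgA" &
                                 pairs$gene_id == "g2"], 4000)
  # |offset| = 5001 is not paired
  expect_false(any(pairs$probe_id == "cgB" & pairs$gene_id == "g1"))
  # - strand gene with probe 3' of the TSS in genome coordinates
  expect_equal(pairs$offset_bp[pairs$probe_id == "cgC" &
                                 pairs$gene_id == "g3"], -2000)

  genes$tss[1] <- NA
  expect_warning(p2 <- map_cis_pairs(mf, genes), "TSS")
  expect_false("g1" %in% p2$gene_id)
})

test_that("partial correlation identities and interval recovery", {
  set.seed(2)
  x <- rnorm(50); y <- 0.5 * x + rnorm(50)
  expect_equal(partial_corr(x, y), cor(x, y))
  z <- rnorm(50)
  expect_equal(partial_corr(x, x + z, cbind(z)), 1)
  expect_true(is.na(partial_corr(x, 2 * x, cbind(x))))

  # known partial correlation 0.5 at n = 200: Fisher-z style interval
  set.seed(3)
  n <- 200
  C <- matrix(rnorm(n * 3), n, 3)
  u <- rnorm(n); v <- rnorm(n)
  xs <- C %*% c(1, -1, 0.5) + u
  ys <- C %*% c(-0.5, 1, 1) + 0.5 * u + sqrt(0.75) * v
  r <- partial_corr(as.numeric(xs), as.numeric(ys), C)
  expect_gt(r, 0.38)
  expect_lt(r, 0.60)
})

test_that("permutation threshold matches the analytic critical value", {
  # small-n closed form: n = 8, no covariates
  set.seed(11)
  n <- 8
  beta <- matrix(runif(5 * n), 5, n,
                 dimnames = list(paste0("p", 1:5), paste0("S", 1:n)))
  tpm <- matrix(rexp(5 * n, 0.1), 5, n,
                dimnames = list(paste0("g", 1:5), paste0("S", 1:n)))
  pairs <- expand.grid(probe_id = paste0("p", 1:5),
                       gene_id = paste0("g", 1:5),
                       stringsAsFactors = FALSE)
  pairs$offset_bp <- 0
  thr <- permutation_threshold(beta, tpm, NULL, pairs, B = 400, seed = 1)
  df <- n - 2
  tcrit <- stats::qt(0.975, df)
  rstar <- tcrit / sqrt(tcrit^2 + df)
  expect_equal(thr$upper, rstar, tolerance = 0.08)
  expect_equal(thr$lower, -rstar, tolerance = 0.08)

  # degenerate alpha = 1 is defined: both cutoffs at the null median
  thr1 <- permutation_threshold(beta, tpm, NULL, pairs, B = 50, alpha = 1,
                                seed = 2)
  expect_equal(thr1$lower, thr1$upper)
  expect_lt(abs(thr1$upper), 0.3)

  expect_error(permutation_threshold(beta, tpm, NULL, pairs, B = 10),
               "B must be")
})

test_that("classification summary, antisymmetry and null calibration", {
  set.seed(21)
  pairs <- data.frame(probe_id = paste0("p", 1:400),
                      gene_id = paste0("g", 1:400),
                      offset_bp = round(runif(400, -5000, 5000)),
                      partial_r = runif(400, -1, 1))
  thr <- list(lower = -0.6, upper = 0.6)
  cls <- classify_cis_pairs(pairs, thr)
  expect_equal(cls$summary$n_significant,
               sum(pairs$partial_r < -0.6 | pairs$partial_r > 0.6))
  # antisymmetry: negating the correlations swaps the sign counts exactly
  neg <- pairs; neg$partial_r <- -neg$partial_r
  cls_neg <- classify_cis_pairs(neg, thr)
  expect_equal(cls_neg$summary$n_significant, cls$summary$n_significant)
  sig <- cls$pairs[cls$pairs$significant, ]
  sig_neg <- cls_neg$pairs[cls_neg$pairs$significant, ]
  expect_equal(sum(sig_neg$sign == "negative"), sum(sig$sign == "positive"))

  # under an exact null with thresholds at the alpha quantiles, the
  # significant fraction approaches alpha
  set.seed(4)
  n <- 158; k <- 7
  C <- matrix(rnorm(n * k), n, k)
  beta <- matrix(runif(30 * n), 30, n,
                 dimnames = list(paste0("p", 1:30), paste0("S", 1:n)))
  tpm <- matrix(rexp(30 * n, 0.05), 30, n,
                dimnames = list(paste0("g", 1:30), paste0("S", 1:n)))
  cpairs <- expand.grid(probe_id = paste0("p", 1:30),
                        gene_id = paste0("g", 1:30),
                        stringsAsFactors = FALSE)
  cpairs$offset_bp <- 0
  cpairs <- cis_correlations(beta, tpm, C, cpairs)
  thr2 <- permutation_threshold(beta, tpm, C, cpairs, B = 100, seed = 5)
  cls2 <- classify_cis_pairs(cpairs, thr2)
  frac <- cls2$summary$n_significant / cls2$summary$n_pairs
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
})

test_that("cis correlations recover planted sign structure and TSS profile", {
  st <- ts_planted()
  covs <- sample_covariate_matrix(st$cohort)
  cis <- map_cis_pairs(st$manifest, st$genes, window = 5000)
  cis <- cis_correlations(st$beta, st$tpm, covs, cis)
  truth <- st$truth$expression$couplings
  merged <- merge(cis, truth, by = c("probe_id", "gene_id"))
  expect_equal(nrow(merged), 3)
  expect_true(all(sign(merged$partial_r) == sign(merged$r)))
  expect_true(all(abs(merged$partial_r) > 0.5))
})

test_that("robustness to phenotype adjustment separates MDD-driven couplings", {
  set.seed(31)
  n <- 120
  mdd <- rep(c(1, 0), n / 2)
  # coupling independent of the phenotype
  shared <- rnorm(n)
  beta <- matrix(plogis(shared + rnorm(n, 0, 0.3)), 1, n,
                 dimnames = list("pA", paste0("S", 1:n)))
  tpm <- matrix(pmax(2^(4 - 2 * shared + rnorm(n, 0, 0.3)) - 1, 0), 1, n,
                dimnames = list("gA", paste0("S", 1:n)))
  pairs <- data.frame(probe_id = "pA", gene_id = "gA", offset_bp = 0)
  pairs <- cis_correlations(beta, tpm, NULL, pairs)
  thr <- list(lower = -0.5, upper = 0.5)
  cls <- classify_cis_pairs(pairs, thr)
  expect_true(cls$pairs$significant)
  rob <- robustness_with_mdd(beta, tpm, NULL, cls, mdd, thr)
  expect_equal(rob$fraction_robust, 1)

  # coupling driven entirely by the phenotype mean shift
  beta2 <- matrix(plogis(2 * mdd - 1 + rnorm(n, 0, 0.2)), 1, n,
                  dimnames = list("pB", paste0("S", 1:n)))
  tpm2 <- matrix(pmax(2^(3 + 3 * mdd + rnorm(n, 0, 0.2)) - 1, 0), 1, n,
                 dimnames = list("gB", paste0("S", 1:n)))
  pairs2 <- data.frame(probe_id = "pB", gene_id = "gB", offset_bp = 0)
  pairs2 <- cis_correlations(beta2, tpm2, NULL, pairs2)
  cls2 <- classify_cis_pairs(pairs2, thr)
  expect_true(cls2$pairs$significant)
  rob2 <- robustness_with_mdd(beta2, tpm2, NULL, cls2, mdd, thr)
  expect_equal(rob2$fraction_robust, 0)

  # no significant pairs: fraction undefined
  cls3 <- classify_cis_pairs(transform(pairs, partial_r = 0.1), thr)
  rob3 <- robustness_with_mdd(beta, tpm, NULL, cls3, mdd, thr)
  expect_true(is.na(rob3$fraction_robust))
})
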