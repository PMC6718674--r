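test_that("cohort structure: paired samples share batch and pair-level covariates", {
  cfg <- sim_config(n_pairs = 79, n_probes = 10, n_genes = 5,
                    n_batches = 10, seed = 1)
  co <- sim_cohort(cfg)
  expect_equal(nrow(co), 158)
  expect_equal(length(unique(co$pair_id)), 79)
  expect_true(all(table(co$pair_id, co$role) == 1))
  by_pair <- split(co, co$pair_id)
  expect_true(all(vapply(by_pair, function(p) {
    length(unique(p$batch_id)) == 1 &&
      length(unique(p$age)) == 1 && length(unique(p$sex)) == 1
  }, logical(1))))
  # twin-varying covariates actually vary within pairs somewhere
  expect_true(any(vapply(by_pair, function(p) {
    p$bmi[1] != p$bmi[2]
  }, logical(1))))

  tiny <- sim_cohort(sim_config(n_pairs = 2, n_probes = 5, n_genes = 2))
  expect_equal(nrow(tiny), 4)
  expect_error(sim_config(n_pairs = 0), "n_pairs")
  expect_error(sim_config(n_pairs = 1), "n_pairs")
})

test_that("identical config and seed give bit-identical output; seeds differ", {
  cfg <- sim_config(n_pairs = 5, n_probes = 40, n_genes = 15, seed = 7)
  s1 <- sim_twin_study(cfg)
  s2 <- sim_twin_study(cfg)
  expect_identical(s1$beta, s2$beta)
  expect_identical(s1$tpm, s2$tpm)
  expect_identical(s1$cohort, s2$cohort)
  cfg3 <- sim_config(n_pairs = 5, n_probes = 40, n_genes = 15, seed = 8)
  s3 <- sim_twin_study(cfg3)
  expect_false(identical(s1$cohort$bmi, s3$cohort$bmi))
  expect_false(identical(s1$beta, s3$beta))
})

test_that("beta values are bounded and TPM non-negative", {
  st <- ts_planted()
  expect_true(all(st$beta >= 0 & st$beta <= 1))
  expect_true(all(st$tpm >= 0))
})

test_that("planted blocks are adjacent in the manifest and hit the target correlation", {
  cfg <- sim_config(n_pairs = 79, n_probes = 300, n_genes = 10,
                    planted_dmrs = data.frame(n_probes = 6, r = 0.6,
                                              fc = 1.15, gap_bp = 200),
                    seed = 3)
  st <- sim_twin_study(cfg)
  tr <- st$truth$methylation
  idx <- which(!is.na(tr$block))
  expect_length(idx, 6)
  expect_true(all(diff(idx) == 1))           # adjacent manifest rows
  mf <- st$manifest[idx, ]
  expect_equal(length(unique(mf$chrom)), 1)
  expect_true(all(diff(mf$pos) == 200))
  # empirical mean pairwise correlation across the 158 samples near target
  cm <- cor(t(st$beta[tr$probe_id[idx], ]))
  expect_gt(mean(cm[upper.tri(cm)]), 0.5)
  expect_lt(mean(cm[upper.tri(cm)]), 0.7)
})

test_that("planted fold changes are recovered by the within-pair ratio mean", {
  # strong-n Monte-Carlo check of the planted-value contract
  cfg <- sim_config(n_pairs = 500, n_probes = 50, n_genes = 5,
                    noise_sd = 0.2,
                    planted_dmrs = data.frame(n_probes = 1, r = 0,
                                              fc = 1.15, gap_bp = 200),
                    seed = 5)
  st <- sim_twin_study(cfg)
  tr <- st$truth$methylation
  fc <- 2^tr$realized_log2fc[!is.na(tr$block)]
  expect_gt(fc, 1.12)
  expect_lt(fc, 1.18)

  # null case: no planted effect anywhere
  null_cfg <- sim_config(n_pairs = 79, n_probes = 400, n_genes = 5,
                         noise_sd = 0.2, seed = 6)
  null_st <- sim_twin_study(null_cfg)
  m <- mean(null_st$truth$methylation$realized_log2fc)
  expect_lt(abs(m), 3 * 0.2 / sqrt(79 * 400))
})

test_that("planted block exceeding n_probes is an invalid config", {
  expect_error(sim_config(n_probes = 10,
                          planted_dmrs = data.frame(n_probes = 20, r = 0.5,
                                                    fc = 1.2, gap_bp = 100)),
               "planted blocks")
  expect_error(sim_config(planted_dmrs = data.frame(n_probes = 3, r = 0.5,
                                                    fc = -1, gap_bp = 100)),
               "FC")
})

test_that("cis couplings reach the target partial correlation", {
  cfg <- sim_config(n_pairs = 200, n_probes = 60, n_genes = 30,
                    cis_couplings = data.frame(probe = 5, gene = 10,
                                               r = -0.9, offset_bp = -500),
                    seed = 9)
  st <- sim_twin_study(cfg)
  covs <- sample_covariate_matrix(st$cohort)
  r <- partial_corr(st$beta["cg0000005", st$cohort$sample_id],
                    log2(st$tpm["G00010", st$cohort$sample_id] + 1),
                    covs)
  expect_gt(r, -0.95)
  expect_lt(r, -0.80)
  # coupled gene TSS placed at the configured offset from the probe
  g <- st$genes[st$genes$gene_id == "G00010", ]
  p <- st$manifest[st$manifest$probe_id == "cg0000005", ]
  off <- if (g$strand == "-") g$tss - p$pos else p$pos - g$tss
  expect_equal(off, -500)
  expect_error(
    sim_config(n_probes = 10, n_genes = 5,
               cis_couplings = data.frame(probe = 50, gene = 1, r = 0.5,
                                          offset_bp = 0)),
    "outside")
})

test_that("planted coupling signs are labelled exactly in the truth", {
  n_neg <- 37; n_pos <- 13   # 74% negative
  cc <- data.frame(probe = 1:50, gene = 1:50,
                   r = c(rep(-0.9, n_neg), rep(0.9, n_pos)),
                   offset_bp = 0)
  cfg <- sim_config(n_pairs = 5, n_probes = 60, n_genes = 60,
                    cis_couplings = cc, seed = 2)
  st <- sim_twin_study(cfg)
  expect_equal(mean(st$truth$expression$couplings$sign == "negative"), 0.74)
})

test_that("batch intercept variance on the ratio scale approaches batch_sd^2", {
  cfg <- sim_config(n_pairs = 300, n_probes = 60, n_genes = 5,
                    n_batches = 50, batch_sd = 0.3, noise_sd = 0.05,
                    seed = 12)
  st <- sim_twin_study(cfg)
  pr <- within_pair_logratio(st$beta, st$cohort, offset = 1e-6)
  # per probe, variance of batch means of the ratio (residual term is
  # noise_sd^2 / 6 per batch, negligible at noise_sd = 0.05); restricted to
  # moderate-baseline probes, where ratio-scale effects are uncompressed
  moderate <- rowMeans(st$beta) > 0.1 & rowMeans(st$beta) < 0.7
  bvar <- apply(pr$ratios[moderate, , drop = FALSE], 1,
                function(y) var(tapply(y, pr$batch, mean)))
  expect_gt(mean(bvar), 0.3^2 * 0.6)
  expect_lt(mean(bvar), 0.3^2 * 1.4)
})
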