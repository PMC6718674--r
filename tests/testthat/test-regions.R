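fake_results <- function(probe_ids, p = 0.5, alpha = 0.1) {
  data.frame(feature_id = probe_ids, alpha = alpha, fc = 2^alpha,
             se = 0.05, p = p, q = p, batch_var = 0, n_pairs_used = 10,
             method = "ols", status = "ok", stringsAsFactors = FALSE)
}

test_that("candidate formation clusters by gap and drops singletons", {
  mf <- toy_manifest(paste0("cg", 1:4), "chr1", c(100, 600, 1500, 9000))
  res <- fake_results(mf$probe_id)
  cands <- form_candidate_regions(mf, res, max_gap_bp = 1000)
  expect_equal(nrow(cands), 1)
  expect_equal(cands$start, 100)
  expect_equal(cands$end, 1500)
  expect_equal(cands$probe_ids[[1]], paste0("cg", 1:3))

  # probes on different chromosomes never merge
  mf2 <- toy_manifest(paste0("cg", 1:4), rep(c("chr1", "chr2"), each = 2),
                      c(100, 200, 100, 200))
  cands2 <- form_candidate_regions(mf2, fake_results(mf2$probe_id))
  expect_equal(nrow(cands2), 2)
  expect_equal(cands2$chrom, c("chr1", "chr2"))

  # all gaps above the limit: nothing
  mf3 <- toy_manifest(paste0("cg", 1:3), "chr1", c(100, 2000, 4000))
  expect_equal(nrow(form_candidate_regions(mf3, fake_results(mf3$probe_id))),
               0)

  unsorted <- mf[c(2, 1, 3, 4), ]
  expect_error(form_candidate_regions(unsorted, res), "sorted")
})

test_that("doubling the gap never decreases probes assigned to candidates", {
  st <- ts_planted()
  res <- fake_results(st$manifest$probe_id)
  for (gap in c(500, 1000, 2000, 4000)) {
    n1 <- sum(form_candidate_regions(st$manifest, res, gap)$n_probes)
    n2 <- sum(form_candidate_regions(st$manifest, res, 2 * gap)$n_probes)
    expect_gte(n2, n1)
  }
})

test_that("probe correlation summaries", {
  b <- rbind(a = 1:10 / 10, b = 1:10 / 10, c = rep(0.5, 10))
  colnames(b) <- paste0("S", 1:10)
  expect_equal(probe_correlation(c("a", "b"), b), 1.0)
  expect_warning(r <- probe_correlation(c("a", "b", "c"), b),
                 "zero-variance")
  expect_equal(r, mean(c(1, 0, 0)))

  # independent probes: mean pairwise r near zero
  set.seed(8)
  ind <- matrix(rnorm(5 * 158), 5, 158,
                dimnames = list(paste0("p", 1:5), NULL))
  expect_lt(abs(probe_correlation(paste0("p", 1:5), ind)), 0.15)

  # generator block at target r
  st <- ts_planted()
  tr <- st$truth$methylation
  blk <- tr$probe_id[!is.na(tr$block) & tr$block == 1]
  r_blk <- probe_correlation(blk, st$beta)
  expect_gt(r_blk, 0.4)
  expect_lt(r_blk, 0.8)
})

test_that("region scoring: Stouffer closed form and hand-computed differences", {
  # 5 probes, all p = 0.01, same direction
  mf <- toy_manifest(paste0("cg", 1:5), "chr1", seq(100, 500, 100))
  res <- fake_results(mf$probe_id, p = 0.01, alpha = 0.1)
  sheet <- toy_sheet(2)
  beta <- matrix(0.5, 5, 4, dimnames = list(mf$probe_id, sheet$sample_id))
  beta[, c("P01_D", "P02_D")] <- 0.54        # dep - ctl = 0.04 everywhere
  cands <- form_candidate_regions(mf, res, 1000)
  suppressWarnings(sc <- score_regions(cands, res, beta, sheet, mf))
  z <- qnorm(0.005, lower.tail = FALSE)
  expect_equal(sc$region_p, 2 * pnorm(-sqrt(5) * z), tolerance = 1e-12)
  expect_lt(sc$region_p, 0.01)
  expect_equal(sc$peak_p, 0.01)
  expect_equal(sc$mean_fc, 2^0.1, tolerance = 1e-12)
  expect_equal(sc$mean_diff_pct, 4.0, tolerance = 1e-12)
  expect_equal(sc$peak_diff_pct, 4.0, tolerance = 1e-12)
  expect_equal(sc$direction, "hyper")

  # mixed signs summing to zero: FC 1, tie broken to hyper and flagged
  res2 <- res
  res2$alpha <- c(0.1, -0.1, 0.1, -0.1, 0)
  suppressWarnings(sc2 <- score_regions(cands, res2, beta, sheet, mf))
  expect_equal(sc2$mean_fc, 1)
  expect_equal(sc2$direction, "hyper")
  expect_true(sc2$direction_tie)
})

test_that("region p never exceeds peak p for a region of identical probes", {
  mf <- toy_manifest(paste0("cg", 1:4), "chr1", seq(100, 400, 100))
  sheet <- toy_sheet(3)
  b <- matrix(rep(runif(6, 0.3, 0.7), each = 4), 4, 6,
              dimnames = list(mf$probe_id, sheet$sample_id))
  for (p in c(0.5, 0.05, 0.001)) {
    res <- fake_results(mf$probe_id, p = p, alpha = 0.2)
    cands <- form_candidate_regions(mf, res, 1000)
    sc <- score_regions(cands, res, b, sheet, mf)
    expect_lte(sc$region_p, sc$peak_p)
  }
})

test_that("DMR calling enforces all three criteria with strict peak-p boundary", {
  st <- ts_planted()
  pr <- within_pair_logratio(st$beta, st$cohort, offset = 1e-6)
  res <- run_feature_scan(pr)
  cands <- form_candidate_regions(st$manifest, res, 1000)
  sc <- score_regions(cands, res, st$beta, st$cohort, st$manifest)
  dmrs <- call_dmrs(sc)
  # every reported DMR satisfies the stated criteria
  expect_true(all(dmrs$n_probes >= 5))
  expect_true(all(dmrs$peak_p < 0.01))
  expect_true(all(dmrs$mean_probe_corr >= 0.30))
  # the planted 6-probe block is called significant; the 4-probe block
  # (identical effect) is never called, failing the probe-count criterion
  tr <- st$truth$methylation
  six <- tr$probe_id[!is.na(tr$block) & tr$block == 1]
  four <- tr$probe_id[!is.na(tr$block) & tr$block == 2]
  hit6 <- vapply(dmrs$probe_ids, function(p) all(six %in% p), logical(1))
  expect_true(any(dmrs$significant[hit6]))
  expect_false(any(vapply(dmrs$probe_ids, function(p) any(four %in% p),
                          logical(1))))
  # q-values over candidates match the step-up oracle
  expect_equal(bh_fdr(sc$region_p), bh_oracle(sc$region_p))

  # boundary: peak probe p exactly at the threshold is excluded
  mf <- toy_manifest(paste0("cg", 1:5), "chr1", seq(100, 500, 100))
  resb <- fake_results(mf$probe_id, p = 0.01)
  sheet <- toy_sheet(3)
  b <- matrix(rep(runif(6, 0.3, 0.7), each = 5), 5, 6,
              dimnames = list(mf$probe_id, sheet$sample_id))
  scb <- score_regions(form_candidate_regions(mf, resb, 1000), resb, b,
                       sheet, mf)
  expect_equal(nrow(call_dmrs(scb)), 0)

  expect_equal(nrow(call_dmrs(twinewas:::empty_region_table()[0, ])), 0)
})

test_that("genomic-feature enrichment: construction and exact null table", {
  mf <- toy_manifest(sprintf("cg%03d", 1:700), "chr1",
                     seq(1000, by = 2000, length.out = 700))
  mf$feature_class <- rep(c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body",
                            "3'UTR", "Intergenic"), each = 100)
  dmr_probes <- mf$probe_id[mf$feature_class == "1stExon"][1:30]
  enr <- feature_enrichment(dmr_probes, mf)
  fe <- enr[enr$type == "feature_class", ]
  expect_equal(fe$fold[fe$level == "1stExon"], 7, tolerance = 1e-12)
  expect_true(all(fe$fold[fe$level != "1stExon"] == 0))
  expect_lt(fe$q[fe$level == "1stExon"], 0.05)

  # independence 2x2 table (10, 90, 100, 900): OR = 1, Fisher p = 1
  ft <- fisher.test(matrix(c(10, 90, 100, 900), 2, byrow = TRUE))
  expect_equal(ft$p.value, 1)
  mf2 <- toy_manifest(sprintf("cg%04d", 1:1100), "chr1",
                      seq(1000, by = 2000, length.out = 1100))
  mf2$feature_class <- c(rep("Body", 990), rep("1stExon", 110))
  dmr2 <- c(mf2$probe_id[1:90], mf2$probe_id[991:1000])
  enr2 <- feature_enrichment(dmr2, mf2)
  row <- enr2[enr2$type == "feature_class" & enr2$level == "1stExon", ]
  expect_equal(row$p, 1, tolerance = 1e-12)
  expect_equal(row$fold, 1, tolerance = 1e-12)

  expect_equal(nrow(feature_enrichment(character(0), mf)), 0)
})
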