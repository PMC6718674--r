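# Shared fixtures, generated in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small null study for structural tests
ts_small <- function() cached("small", {
  sim_twin_study(sim_config(n_pairs = 20, n_probes = 200, n_genes = 60,
                            n_batches = 5, seed = 101))
})

# study with planted blocks, DEGs and cis couplings
ts_planted <- function() cached("planted", {
  sim_twin_study(sim_config(
    n_pairs = 40, n_probes = 400, n_genes = 120, n_batches = 8,
    planted_dmrs = data.frame(n_probes = c(6, 4), r = c(0.6, 0.6),
                              fc = c(1.3, 1.3), gap_bp = c(200, 200)),
    planted_degs = data.frame(gene = 1:5, fc = c(2, 2, 0.5, 0.5, 1.8)),
    cis_couplings = data.frame(probe = c(10, 30, 50), gene = c(80, 90, 100),
                               r = c(-0.9, -0.85, 0.85),
                               offset_bp = c(-1000, -800, 1500)),
    seed = 202))
})

# minimal hand-built sample sheet: n pairs, one batch unless given
toy_sheet <- function(n = 2, batch = "B1") {
  pid <- sprintf("P%02d", seq_len(n))
  data.frame(
    sample_id = c(paste0(pid, "_D"), paste0(pid, "_N")),
    pair_id = rep(pid, 2),
    role = rep(c("depressed", "nondepressed"), each = n),
    batch_id = batch,
    age = rep(30 + seq_len(n), 2),
    sex = rep("F", 2 * n),
    stringsAsFactors = FALSE
  )
}

# minimal manifest with benign QC flags
toy_manifest <- function(probe_id, chrom, pos, gene = "GENE",
                         feature_class = "Body", cgi = "OpenSea") {
  data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
             gene_symbol = gene, feature_class = feature_class,
             cgi_context = cgi, sex_chrom = FALSE, multi_mapped = FALSE,
             snp_overlap = FALSE, detection_fail_fraction = 0,
             intensity_z = 0, stringsAsFactors = FALSE)
}

# brute-force two-sided Fisher p by enumerating the hypergeometric support
fisher_oracle <- function(both, a_only, b_only, neither) {
  na <- both + a_only; nb <- both + b_only
  n <- both + a_only + b_only + neither
  support <- max(0, na + nb - n):min(na, nb)
  probs <- stats::dhyper(support, nb, n - nb, na)
  sum(probs[probs <= stats::dhyper(both, nb, n - nb, na) * (1 + 1e-7)])
}

# independent iteratively-reweighted least-squares logistic oracle
irls_logistic <- function(X, y, iter = 50) {
  b <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    eta <- X %*% b
    mu <- 1 / (1 + exp(-eta))
    W <- as.numeric(mu * (1 - mu))
    z <- eta + (y - mu) / W
    b <- solve(crossprod(X, X * W), crossprod(X, W * z))
  }
  as.numeric(b)
}

# independent brute-force Benjamini-Hochberg step-up oracle
bh_oracle <- function(p, m = length(p)) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in rev(seq_len(n))) {
    prev <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- prev
  }
  pmin(q, 1)
}
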