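## Weighted co-methylation / co-expression networks built separately per
## twin group, with topological-overlap module detection and a
## differential-connectivity permutation test that respects the paired
## design (the null flips, within each twin pair, which member carries the
## "depressed" label).

#' Select nominally associated features as network nodes
#'
#' @param results Scan results from [run_feature_scan()] (or a scored
#'   region table with a `region_p` column).
#' @param p_max Strict raw-p threshold (default 0.001).
#' @return Character vector of selected feature ids.
#' @export
select_nominal_features <- function(results, p_max = 0.001) {
  p <- results$p %||% results$region_p
  id <- results$feature_id %||% region_ids(results)
  sel <- !is.na(p) & p < p_max
  if (!any(sel)) warnf("no features pass raw p < %g", p_max)
  id[sel]
}

region_ids <- function(regions) {
  sprintf("%s:%d-%d", regions$chrom, as.integer(regions$start),
          as.integer(regions$end))
}

#' Per-sample node values for region-level networks
#'
#' A region's node value in a sample is the mean beta of its probes.
#'
#' @param regions Scored region table (with `probe_ids` list-column).
#' @param beta Beta matrix.
#' @return Samples x regions matrix (region ids as columns).
#' @export
region_node_values <- function(regions, beta) {
  vals <- vapply(regions$probe_ids,
                 function(p) colMeans(beta[p, , drop = FALSE]),
                 numeric(ncol(beta)))
  colnames(vals) <- region_ids(regions)
  vals
}

# Scale-free topology criterion: smallest soft power in 1..12 whose
# log-log degree-distribution fit reaches R^2 >= 0.8 with negative slope;
# falls back to 6 (the customary unsigned-network default).
pick_soft_power <- function(cormat, powers = 1:12, target_r2 = 0.8) {
  for (b in powers) {
    a <- abs(cormat)^b
    diag(a) <- 0
    k <- rowSums(a)
    if (all(k == 0)) next
    br <- unique(quantile(k, seq(0, 1, length.out = 11)))
    if (length(br) < 4) next
    cut_k <- cut(k, breaks = br, include.lowest = TRUE)
    dk <- tapply(k, cut_k, mean)
    pk <- as.numeric(table(cut_k)) / length(k)
    okbin <- pk > 0 & dk > 0 & !is.na(dk)
    if (sum(okbin) < 3) next
    fit <- stats::lm(log10(pk[okbin]) ~ log10(dk[okbin]))
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= target_r2 && coef(fit)[2] < 0) return(b)
  }
  6L
}

tom_similarity <- function(adj) {
  L <- adj %*% adj
  k <- rowSums(adj)
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (L + adj) / denom
  diag(tom) <- 1
  tom
}

#' Build a weighted correlation network for one twin group
#'
#' Unsigned adjacency `|cor|^power` with zero diagonal, topological-overlap
#' similarity, and binary node degrees (neighbors with adjacency >=
#' `edge_cutoff`).
#'
#' @param mat Samples x nodes value matrix for one group (>= 10 nodes and
#'   >= 10 samples).
#' @param power Soft-thresholding power; `NULL` selects it by the
#'   scale-free criterion (fallback 6).
#' @param edge_cutoff Adjacency cutoff defining a binary edge.
#' @return List of class `group_network`: `nodes`, `power`, `adjacency`,
#'   `tom`, `degree`, `edge_cutoff`.
#' @export
build_group_network <- function(mat, power = NULL, edge_cutoff = 0.1) {
  stopifnot(ncol(mat) >= 10, nrow(mat) >= 10)
  const <- apply(mat, 2, sd) == 0
  cm <- suppressWarnings(cor(mat))
  if (any(const)) {
    warnf("constant node(s): %s", paste(colnames(mat)[const], collapse = ","))
    cm[const, ] <- 0
    cm[, const] <- 0
  }
  cm[!is.finite(cm)] <- 0
  power <- power %||% pick_soft_power(cm)
  adj <- abs(cm)^power
  diag(adj) <- 0
  structure(list(
    nodes = colnames(mat),
    power = power,
    adjacency = adj,
    tom = tom_similarity(adj),
    degree = as.integer(rowSums(adj >= edge_cutoff)),
    edge_cutoff = edge_cutoff
  ), class = "group_network")
}

#' Detect network modules
#'
#' Average-linkage hierarchical clustering of the topological-overlap
#' dissimilarity (1 - TOM) with a static tree cut; clusters smaller than
#' `min_size` are dissolved to unassigned (module 0).  Each module's hub
#' is the member with the highest module membership (mean adjacency to the
#' other members); ties break by node order.
#'
#' @param network A `group_network`.
#' @param min_size Minimum module size.
#' @param cut_height Static cut height on 1 - TOM.
#' @return List: `assignment` (data frame node/module), `modules` (module
#'   id, size, hub).
#' @export
detect_modules <- function(network, min_size = 50, cut_height = 0.95) {
  diss <- 1 - network$tom
  hc <- hclust(as.dist(diss), method = "average")
  cl <- cutree(hc, h = cut_height)
  sizes <- table(cl)
  big <- as.integer(names(sizes)[sizes >= min_size])
  module <- integer(length(cl))
  for (i in seq_along(big)) module[cl == big[i]] <- i
  if (!any(module > 0)) warnf("no module reaches min_size = %d", min_size)
  assignment <- data.frame(node = network$nodes, module = module,
                           stringsAsFactors = FALSE)
  mods <- lapply(seq_along(big), function(i) {
    idx <- which(module == i)
    mm <- rowSums(network$adjacency[idx, idx, drop = FALSE]) /
      pmax(length(idx) - 1, 1)
    data.frame(module = i, size = length(idx),
               hub = network$nodes[idx[which.max(mm)]],
               stringsAsFactors = FALSE)
  })
  list(assignment = assignment,
       modules = do.call(rbind, mods) %||%
         data.frame(module = integer(0), size = integer(0),
                    hub = character(0)))
}

group_degrees <- function(mat, power, edge_cutoff) {
  cm <- suppressWarnings(cor(mat))
  cm[!is.finite(cm)] <- 0
  adj <- abs(cm)^power
  diag(adj) <- 0
  rowSums(adj >= edge_cutoff)
}

#' Differential connectivity between twin groups
#'
#' Statistic: mean binary node degree of `node_set` in group A minus group
#' B.  The null distribution flips, independently within each twin pair,
#' which member is labeled depressed, rebuilding both group networks per
#' permutation; the two-sided p is (1 + #{|null| >= |observed|}) /
#' (B_perm + 1).
#'
#' @param node_set Node ids to test (non-empty, present in both matrices).
#' @param mat_a,mat_b Samples x nodes matrices for the two groups, with row
#'   i of both matrices holding the two members of pair i.
#' @param power Soft power; `NULL` selects once from the pooled samples and
#'   reuses it for every rebuild.
#' @param edge_cutoff Binary-edge adjacency cutoff.
#' @param B_perm Number of permutations.
#' @param seed Permutation seed.
#' @return List: `mean_degree_a`, `mean_degree_b`, `statistic`, `p`,
#'   `power`, `B_perm`.
#' @export
differential_connectivity <- function(node_set, mat_a, mat_b, power = NULL,
                                      edge_cutoff = 0.1, B_perm = 200,
                                      seed = 1) {
  if (length(node_set) == 0) stopf("node_set must be non-empty")
  stopifnot(identical(colnames(mat_a), colnames(mat_b)),
            nrow(mat_a) == nrow(mat_b))
  missing <- setdiff(node_set, colnames(mat_a))
  if (length(missing)) {
    stopf("node_set members absent from matrices: %s",
          paste(head(missing, 5), collapse = ", "))
  }
  power <- power %||% pick_soft_power(
    suppressWarnings(cor(rbind(mat_a, mat_b))))
  idx <- match(node_set, colnames(mat_a))
  stat_fn <- function(A, B) {
    mean(group_degrees(A, power, edge_cutoff)[idx]) -
      mean(group_degrees(B, power, edge_cutoff)[idx])
  }
  observed <- stat_fn(mat_a, mat_b)
  npair <- nrow(mat_a)
  null_stats <- with_seed(seed, {
    vapply(seq_len(B_perm), function(b) {
      flip <- runif(npair) < 0.5
      A <- mat_a; B <- mat_b
      A[flip, ] <- mat_b[flip, ]
      B[flip, ] <- mat_a[flip, ]
      stat_fn(A, B)
    }, numeric(1))
  })
  p <- (1 + sum(abs(null_stats) >= abs(observed))) / (B_perm + 1)
  dega <- group_degrees(mat_a, power, edge_cutoff)[idx]
  degb <- group_degrees(mat_b, power, edge_cutoff)[idx]
  list(mean_degree_a = mean(dega), mean_degree_b = mean(degb),
       statistic = observed, p = p, power = power, B_perm = B_perm)
}
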