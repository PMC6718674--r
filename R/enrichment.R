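## Fisher-exact overlap of two gene sets on a common background universe,
## reporting both the odds ratio and the observed/expected fold enrichment
## (the two readings of "x times more likely").

#' Fisher exact overlap of two gene sets
#'
#' Builds the 2x2 table of membership in `set_a` and `set_b` over the
#' `background` universe and tests it with the two-sided Fisher exact
#' (hypergeometric) test.  Fold enrichment is the observed overlap divided
#' by the overlap expected under independence,
#' (both / |A|) / (|B| / |background|); it is symmetric in A and B.
#'
#' @param set_a,set_b Character vectors; must be subsets of `background`.
#' @param background Character vector, the common universe (non-empty).
#' @return List of class `overlap_result`: `counts` (both, a_only, b_only,
#'   neither), `odds_ratio`, `fold_enrichment`, `p`, `background_size`.
#' @export
fisher_overlap <- function(set_a, set_b, background) {
  if (length(background) == 0) stopf("background must be non-empty")
  background <- unique(background)
  set_a <- unique(set_a); set_b <- unique(set_b)
  bad_a <- setdiff(set_a, background)
  bad_b <- setdiff(set_b, background)
  if (length(bad_a) || length(bad_b)) {
    stopf("sets are not subsets of the background (e.g. %s)",
          paste(head(c(bad_a, bad_b), 5), collapse = ", "))
  }
  in_a <- background %in% set_a
  in_b <- background %in% set_b
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)), 2, 2, byrow = TRUE)
  ft <- fisher.test(tab)
  both <- tab[1, 1]
  fold <- if (length(set_a) == 0 || length(set_b) == 0) 0 else {
    (both / length(set_a)) / (length(set_b) / length(background))
  }
  structure(list(
    counts = c(both = both, a_only = tab[1, 2], b_only = tab[2, 1],
               neither = tab[2, 2]),
    odds_ratio = unname(ft$estimate),
    fold_enrichment = fold,
    p = ft$p.value,
    background_size = length(background)
  ), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "Overlap: %d of %d background genes in both sets\n  fold enrichment %.3g, odds ratio %.3g, Fisher p = %.3g\n",
    x$counts[["both"]], x$background_size, x$fold_enrichment, x$odds_ratio,
    x$p))
  invisible(x)
}
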