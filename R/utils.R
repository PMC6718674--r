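#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor lm.fit median na.omit p.adjust pnorm pt qnorm
#'   quantile rbinom rnorm runif sd setNames var plogis qlogis fisher.test
#'   glm binomial vcov as.dist cutree hclust rexp
#' @importFrom utils head write.table read.delim
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.  All stochastic stages go through this so
# that a single top-level seed gives bit-identical runs.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Deterministic per-stage sub-seed from one global seed.  Kept < 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(cohort = 11L, methylation = 23L, expression = 37L,
               permutation = 53L, network = 71L, replication = 89L)
  stopifnot(stage %in% names(offsets))
  (as.numeric(seed) * 101 + offsets[[stage]]) %% 2147483629
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Timestamped stage logging used across the pipeline.
log_msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) {
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(...))
  }
  invisible(NULL)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}
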