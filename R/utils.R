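# Internal helpers shared across modules.

# Normal 97.5th percentile used for all Wald-type confidence intervals.
Z_CI <- 1.959964

#' Run code with a locally scoped RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded estimators do not perturb the global stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Two-sided p-value from a z statistic; floored so it stays in (0, 1].
pval_from_z <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmax(p, 1e-300)
}

# Derive a reproducible child seed below 2^31 from a base seed and an index.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + index * 9176) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
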