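# Internal helpers: seeded RNG scoping, stratified folds, logging.

#' @importFrom stats predict quantile rbinom rnorm runif glm binomial coef setNames aggregate
#' @importFrom utils read.delim write.table head modifyList
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code does not disturb user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed) %% .Machine$integer.max)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

# Derive a child seed from a root seed and a string tag; keeps every stage's
# randomness a pure function of one root seed while remaining < 2^31.
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h %% 104729) %% 2147483587)
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each observation to one of `k` folds such that both classes are
#' spread as evenly as possible across folds (fold sizes differ by at most
#' one within each class). Deterministic for a fixed seed.
#'
#' @param labels binary labels (any two-level vector).
#' @param k number of folds.
#' @param seed integer seed controlling the shuffle.
#' @return integer vector of fold ids in `1:k`, one per observation.
#' @export
stratified_folds <- function(labels, k = 10, seed = 1) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (n < k) stop("fewer observations (", n, ") than folds (", k, ")")
  fold <- integer(n)
  with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

log_msg <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
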