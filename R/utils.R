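#' Derive a child seed from a root seed and a stream name
#'
#' All stages of the pipeline draw their randomness from named streams
#' derived deterministically from one root seed, so each stage is
#' independently reproducible. The result is always a valid 32-bit integer
#' seed.
#'
#' @param seed Integer root seed.
#' @param stream Character stream name (e.g. `"cohort"`, `"evolve"`).
#' @return An integer seed.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  code <- utf8ToInt(stream)
  h <- sum(code * seq_along(code)) %% 1048573
  as.integer((abs(as.numeric(seed)) * 48271 + h * 8191 + 1) %% 2147483629)
}

## Evaluate expr with the RNG seeded, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

## Check that a named probability vector is a simplex.
check_simplex <- function(p, what) {
  if (!is.numeric(p) || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop(sprintf("`%s` must be non-negative and sum to 1 (got sum %.12g)",
                 what, sum(p)), call. = FALSE)
  if (is.null(names(p)) || any(!nzchar(names(p))))
    stop(sprintf("`%s` must be a named probability vector", what), call. = FALSE)
  invisible(p)
}

## Integer quotas from probabilities by largest remainder, summing to n.
## Deterministic: ties broken by category order.
quota_counts <- function(probs, n) {
  raw <- probs * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(probs))
}

## A vector of category labels with exact quota counts, shuffled.
quota_labels <- function(probs, n) {
  counts <- quota_counts(probs, n)
  sample(rep(names(counts), times = counts))
}

#' Names of the feature columns of a feature matrix
#'
#' @param features A feature matrix tibble (see [build_feature_matrix()]).
#' @return Character vector of columns named like `BM01_40`.
#' @export
feature_columns <- function(features) {
  grep("^BM[0-9]{2}_[0-9]+$", names(features), value = TRUE)
}
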