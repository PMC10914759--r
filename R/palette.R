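## The 48-function palette. IDs are stable and mirror the compiled VM
## (src/lgp.cpp); all functions are protected/total: division and
## reciprocal guard near-zero denominators, exp/sinh/cosh clamp their
## inputs, sqrt/log act on |x|, asin/acos clamp to [-1, 1], and every
## result is forced finite and clamped in magnitude.
PALETTE <- tibble::tibble(
  id = 1:48,
  name = c("add", "sub", "mul", "div", "min", "max", "pow", "mod", "hypot",
           "mean2", "absdiff", "gt", "lt", "eq", "and", "or", "xor",
           "gauss2", "atan2",
           "abs", "neg", "sign", "sqrt", "square", "cube", "exp", "log",
           "log1p", "sin", "cos", "tan", "tanh", "sinh", "cosh", "asin",
           "acos", "atan", "sigmoid", "relu", "floor", "ceil", "round",
           "recip", "not",
           "ifpos", "clip3", "fma", "mean3"),
  arity = c(rep(2L, 19), rep(1L, 25), rep(3L, 4)),
  ## Sampling weight when instructions are generated: smooth arithmetic /
  ## aggregation functions are favoured over hard nonlinearities, which
  ## mostly act as step functions on standardized features. Every function
  ## keeps positive weight and remains reachable.
  weight = c(4, 4, 2, 2, 2, 2, 1, 1, 2,
             4, 1, 1, 1, 1, 1, 1, 1,
             1, 1,
             1, 2, 1, 1, 1, 1, 1, 1,
             1, 1, 1, 1, 2, 1, 1, 1,
             1, 1, 2, 2, 1, 1, 1,
             1, 1,
             2, 1, 4, 4)
)

#' The instruction-function palette
#'
#' The palette of 48 mathematical and logical functions available to the
#' evolutionary process: arithmetic, comparison and boolean operators
#' (returning 0/1), trigonometric and hyperbolic functions, clamped
#' exponential/logarithm variants, sigmoid/relu, kernels, and ternary
#' forms (conditional, clip, fused multiply-add, three-way mean). All are
#' protected so program execution is a total function: no NaN or Inf can
#' escape.
#'
#' @return A tibble with columns `id`, `name`, `arity`.
#' @export
palette_functions <- function() PALETTE
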