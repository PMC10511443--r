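#' @useDynLib dualppg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats approx rnorm runif rbinom sd median quantile setNames cor
#' @importFrom utils head tail
NULL

# Derive a reproducible 31-bit substream seed from a master seed and a tag.
# Keeps every derived seed in [1, 2^31 - 2] so it is a valid R integer seed.
subSeed <- function(seed, tag) {
  s <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(tag))) {
    s <- (s * 31 + ch) %% 2147483647
  }
  as.integer(s %% 2147483646L + 1)
}

#' Evaluate an expression under a local RNG seed
#'
#' Seeds the RNG, evaluates `expr`, and restores the caller's RNG state, so
#' seeded draws never perturb surrounding randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Zero-phase IIR filtering with odd (point-symmetric) reflection padding at
# both ends, forward and backward passes. b, a are filter polynomials.
zeroPhaseFilter <- function(b, a, x) {
  n <- length(x)
  pad <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L) * 10L)
  if (pad < 1L) pad <- min(n - 1L, 1L)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  g <- sum(b) / sum(a)                    # DC gain (1 for low-pass designs)
  # filter the deviation from the edge value so the zero-state transient
  # acts on a signal that starts at zero
  run <- function(v) {
    as.numeric(signal::filter(b, a, v - v[1])) + g * v[1]
  }
  y <- run(xp)
  y <- rev(run(rev(y)))
  y[(pad + 1):(pad + n)]
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
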