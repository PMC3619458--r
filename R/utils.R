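# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`,
#' and restores the previous state so that seeded package functions do
#' not perturb the user's random stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Deterministic polynomial hash over the labels, folded with the master
#' seed modulo 2^31 - 1, giving independent named streams (per chain, per
#' generation, per language, ...) from one master seed.
#'
#' @param seed master integer seed.
#' @param ... labels (coerced to character) naming the stream.
#' @return an integer in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (part in list(...)) {
    for (b in utf8ToInt(paste0(as.character(part), "|"))) {
      h <- (h * 31 + b) %% m
    }
  }
  as.integer(h)
}

# 0 * log(0) = 0 convention used by all entropy computations
xlogx <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log(p[pos])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
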