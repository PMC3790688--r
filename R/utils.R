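# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the generator seeded at `seed`, then restores the caller's
#' RNG state, so seeded simulation calls do not perturb the session stream.
#' A `NULL` seed evaluates `code` under the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Spawn deterministic child seeds (< 2^31) from one master seed.
spawn_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max, n))
}

# Great-circle (geodesic) distance in radians between unit vectors.
# `a` is an n x 3 matrix, `b` a length-3 unit vector.
geodesic_dist <- function(a, b) {
  d <- as.vector(a %*% b)
  acos(pmin(1, pmax(-1, d)))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
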