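#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not perturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed
#'
#' Deterministic 32-bit-safe seed derivation for per-subject / per-run
#' generators, so a cohort is reproducible from one master seed.
#'
#' @param seed master seed.
#' @param ... one or more non-negative integer indices (subject, run, ...).
#' @return a single integer seed in [0, 2^31 - 2].
#' @keywords internal
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) s <- (s * 48271 + as.double(i) * 104729 + 7919) %% 2147483647
  as.integer(s)
}

#' Fisher-Z transform with clamping
#'
#' atanh of a correlation, with `r` clamped to +/-(1 - 1e-6) first so that
#' degenerate inputs (|r| = 1) give a large finite value rather than Inf.
#'
#' @param r correlation value(s) in [-1, 1] (NA allowed).
#' @return Fisher-Z value(s).
#' @export
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -(1 - 1e-6)), 1 - 1e-6))
}

# Pearson correlation of a vector against each column of a matrix.
# Returns NA for zero-variance pairs instead of warning.
cor_vec_mat <- function(x, Y) {
  x <- x - mean(x)
  sx <- sqrt(sum(x^2))
  Yc <- sweep(Y, 2L, colMeans(Y), "-")
  sy <- sqrt(colSums(Yc^2))
  num <- drop(crossprod(Yc, x))
  den <- sx * sy
  out <- rep(NA_real_, ncol(Y))
  ok <- den > 0
  out[ok] <- num[ok] / den[ok]
  out
}
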