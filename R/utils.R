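# Internal helpers: classed conditions, reproducible local RNG, log-sum-exp.

abort <- function(message, class) {
  stop(structure(
    class = c(class, "devtrans_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package internals never
#' disturb the caller's random number stream. `seed = NULL` uses the current
#' stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministic map (master, offset) -> seed strictly below 2^31, so pipeline
#' stages can be re-run in isolation with the seed the report records.
#' Arithmetic stays far below 2^53, hence exact in doubles.
#' @noRd
derive_seed <- function(master, offset) {
  m <- as.numeric(master) %% 1000003
  as.integer((m * 10007 + as.numeric(offset) * 9973 + 17) %% (2^31 - 2)) + 1L
}

# Row-wise log(sum(exp(m))) guarded against underflow; -Inf rows stay -Inf.
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  safe <- ifelse(is.finite(mx), mx, 0)
  safe + log(rowSums(exp(m - safe)))
}
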