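#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so callers' random streams are unaffected.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# derive a child seed from a master seed; keeps results < 2^31
derive_seed <- function(master, stream, index = 0L) {
  as.integer((as.numeric(master) * 7919 + stream * 104729 + index * 131) %%
               2147483647)
}

clip01 <- function(x, eps = 1e-7) pmin(pmax(x, eps), 1 - eps)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_binary <- function(x) all(x == 0 | x == 1)
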