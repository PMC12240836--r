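# Internal helpers: seeded RNG scopes and small shared utilities.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers never perturb the
#' caller's stream. Used to give each simulation sub-stage its own child
#' stream derived from the root seed.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed for sub-stage `k` of root seed `seed`.
# Kept below 2^31 - 1; a fixed odd multiplier decorrelates neighbouring roots.
childSeed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 69621) %% 2147483587)
}

# run-length segments of a vector: data.frame(start, end, value) in index space
indexRuns <- function(x) {
  r <- rle(as.vector(x))
  e <- cumsum(r$lengths)
  s <- e - r$lengths + 1L
  data.frame(start = s, end = e, value = r$values, stringsAsFactors = FALSE)
}

# stopifnot with a clearer message
assertThat <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
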