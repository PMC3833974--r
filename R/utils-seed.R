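#' Derive a reproducible substream seed from a master seed and a key
#'
#' Every stage of the pipeline draws its randomness from a named substream of
#' one master seed, so that stages are independently reproducible: rerunning a
#' single stage with the same master seed and key gives the same draws
#' regardless of what ran before it.
#'
#' The scheme hashes the key string into the 31-bit integer range with a
#' Fowler/Noll/Vo-style multiplicative mix, then folds in the master seed.
#' It is not cryptographic; it only needs to decorrelate named streams.
#'
#' @param master integer master seed.
#' @param key character scalar naming the substream (e.g. `"proj3"`).
#' @return an integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
#' @examples
#' substream_seed(42L, "genotypes")
substream_seed <- function(master, key) {
  stopifnot(length(master) == 1L, is.finite(master), is.character(key),
            length(key) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- (as.double(master) %% m + m) %% m
  for (b in utf8ToInt(key)) {
    # keep intermediate products < 2^53 so doubles stay exact
    h <- (h * 31 + b) %% m
    h <- (h * 2654435 + 1013904223) %% m
  }
  as.integer(h)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not disturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
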