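#' @useDynLib fedalz, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pnorm qnorm rnorm runif median predict setNames
#' @importFrom utils head
NULL

#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from one master seed. Sub-seeds for
#' independent random streams (volume noise, epoch shuffling, client
#' initialization, secret-sharing) are derived deterministically from the
#' master seed and a sequence of string/integer tokens, by mixing the token
#' bytes into the seed with multiply-add arithmetic modulo the Mersenne prime
#' 2^31 - 1. All intermediates stay below 2^53 so the arithmetic is exact in
#' double precision.
#'
#' @param seed Integer master seed.
#' @param ... Tokens (strings or integers) naming the stream, e.g.
#'   `derive_seed(1, "train", round, client)`.
#' @return An integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (tok in list(...)) {
    bytes <- if (is.character(tok)) utf8ToInt(tok) else {
      stopifnot(is.numeric(tok), tok == round(tok))
      utf8ToInt(paste0("#", format(tok, scientific = FALSE)))
    }
    for (b in bytes) h <- (h * 31 + b) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# largest-remainder (Hamilton) apportionment of `n` units to fractions `p`
largest_remainder <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-8, n >= 0)
  q <- n * p
  k <- floor(q)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(q - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(k)
}
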