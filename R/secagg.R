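#' Secure-aggregation configuration
#'
#' Additive secret sharing in the SPDZ style: computation over the integers
#' modulo a prime `Q`, with reals mapped to the field by fixed-point encoding
#' (scaling by `2^f` and rounding; negatives represented as `Q - |v|`). The
#' no-wrap-around condition `N * B * 2^f < Q / 2` guarantees that a sum of up
#' to `N` encoded values is decoded correctly.
#'
#' The default modulus is the Mersenne prime `2^31 - 1`: all share arithmetic
#' (values below `Q`, sums of up to `N` terms) then stays below `2^53` and is
#' exact in R's double-precision integers. With `f = 20` fractional bits and
#' magnitude bound `B = 64` the condition holds for up to 15 clients.
#'
#' @param Q Prime modulus.
#' @param f Fractional bits of the fixed-point encoding (`f >= 1`).
#' @param B Magnitude bound on encoded reals.
#' @param min_clients Smallest client count for which the protocol is run
#'   (3: with fewer, the other party's update is recoverable by subtraction).
#' @param n_max Largest client count the configuration must support; the
#'   overflow condition is checked for it at construction time.
#' @return A `fedalz_secagg_config`.
#' @export
secagg_config <- function(Q = 2147483647, f = 20, B = 64, min_clients = 3,
                          n_max = 8) {
  stopifnot(f >= 1, B > 0, min_clients >= 2, n_max >= min_clients)
  if (Q < 2 || !is_prime(Q)) stop("Q must be prime")
  cfg <- structure(list(Q = Q, f = f, B = B, min_clients = min_clients,
                        n_max = n_max),
                   class = "fedalz_secagg_config")
  check_no_overflow(cfg, n_max)
  cfg
}

is_prime <- function(q) {
  if (q < 2) return(FALSE)
  if (q %% 2 == 0) return(q == 2)
  d <- 3
  while (d * d <= q) {
    if (q %% d == 0) return(FALSE)
    d <- d + 2
  }
  TRUE
}

check_no_overflow <- function(cfg, n) {
  if (n * cfg$B * 2^cfg$f >= cfg$Q / 2) {
    stop(sprintf(
      "wrap-around risk: N*B*2^f = %.0f exceeds Q/2 = %.0f; reduce f or B or use a larger Q",
      n * cfg$B * 2^cfg$f, cfg$Q / 2))
  }
  invisible(TRUE)
}

#' Fixed-point encode / decode
#'
#' `fp_encode` maps reals to field elements `round(x * 2^f) mod Q` (negatives
#' as `Q - |.|`); `fp_decode` inverts via the signed representative in
#' `(-Q/2, Q/2]` divided by `2^f`. A round trip is exact to within
#' `2^-(f+1)` per coordinate.
#'
#' @param x Real vector with `max(abs(x)) <= B`.
#' @param cfg A [secagg_config()].
#' @return `fp_encode`: a `fedalz_fpvec` (integer-valued vector in `[0, Q)`
#'   plus the config); `fp_decode`: a real vector.
#' @export
fp_encode <- function(x, cfg) {
  bad <- which(abs(x) > cfg$B)
  if (length(bad)) {
    stop(sprintf("encoding range exceeded at coordinate %d: |%.6g| > B = %g",
                 bad[1], x[bad[1]], cfg$B))
  }
  v <- round(x * 2^cfg$f) %% cfg$Q
  structure(list(values = v, cfg = cfg), class = "fedalz_fpvec")
}

#' @rdname fp_encode
#' @param v A `fedalz_fpvec` or a raw vector of field elements.
#' @export
fp_decode <- function(v, cfg = NULL) {
  if (inherits(v, "fedalz_fpvec")) { cfg <- v$cfg; v <- v$values }
  stopifnot(!is.null(cfg), all(v >= 0), all(v < cfg$Q))
  signed <- ifelse(v > cfg$Q / 2, v - cfg$Q, v)
  signed / 2^cfg$f
}

# dedicated uniform field-element stream, isolated from the training RNG
draw_field <- function(n, Q) {
  if (n == 0) return(numeric(0))
  as.numeric(sample.int(Q, n, replace = TRUE)) - 1
}

#' Split a fixed-point vector into N additive shares
#'
#' The first `N - 1` shares are i.i.d. uniform on `[0, Q)`; the last is the
#' modular difference, so the shares sum to the secret mod `Q` while any
#' `N - 1` of them are jointly uniform and carry no information about it.
#'
#' @param v A `fedalz_fpvec`.
#' @param n_shares Number of shares `N >= 2`.
#' @param seed Optional seed for the share stream; `NULL` uses the current
#'   RNG state (honest randomness).
#' @return A `fedalz_shares`: matrix `length(v) x N`, column `j` being the
#'   share sent to client `j`, plus the config.
#' @export
make_shares <- function(v, n_shares, seed = NULL) {
  stopifnot(inherits(v, "fedalz_fpvec"))
  if (n_shares < 2) stop("need at least 2 shares to hide the secret")
  Q <- v$cfg$Q
  len <- length(v$values)
  draw <- function() {
    s <- matrix(0, len, n_shares)
    for (j in seq_len(n_shares - 1)) s[, j] <- draw_field(len, Q)
    s
  }
  s <- if (is.null(seed)) draw() else with_seed(seed, draw())
  partial <- if (n_shares > 2) rowSums(s[, seq_len(n_shares - 1), drop = FALSE])
             else s[, 1]
  s[, n_shares] <- (v$values - partial) %% Q
  structure(list(shares = s, cfg = v$cfg), class = "fedalz_shares")
}

#' Simulate the full share exchange among clients
#'
#' Each client splits its encoded vector into `N` shares and sends share `j`
#' to client `j`; each client `j` then sums the shares it received (its
#' partial sum) and reports it to the server; the server adds the `N` partial
#' sums mod `Q`. The returned transcript records exactly what each party
#' observes.
#'
#' @param clients List of `fedalz_fpvec`, one per client, equal lengths.
#' @param cfg A [secagg_config()].
#' @param seed Optional seed for the share streams.
#' @return A `fedalz_transcript`: list with `partials` (matrix, column `j` =
#'   partial sum reported by client `j` — the server's view), `total` (a
#'   `fedalz_fpvec`, the aggregate), `n_clients`.
#' @export
secure_exchange <- function(clients, cfg, seed = NULL) {
  n <- length(clients)
  if (n < cfg$min_clients) {
    stop("secure aggregation requires at least ", cfg$min_clients,
         " clients; with fewer, a single honest-but-curious party can recover",
         " another client's update")
  }
  len <- length(clients[[1]]$values)
  for (cl in clients) {
    if (length(cl$values) != len) stop("client vector length mismatch")
  }
  check_no_overflow(cfg, n)
  partials <- matrix(0, len, n)
  run <- function() {
    for (i in seq_len(n)) {
      sh <- make_shares(clients[[i]], n)
      partials <<- partials + sh$shares   # client j accumulates share alpha_j^i
    }
  }
  if (is.null(seed)) run() else with_seed(seed, run())
  partials <- partials %% cfg$Q
  total <- apply(partials, 1, sum) %% cfg$Q
  structure(list(partials = partials,
                 total = structure(list(values = total, cfg = cfg),
                                   class = "fedalz_fpvec"),
                 n_clients = n),
            class = "fedalz_transcript")
}

#' Secure multiparty sum of encoded vectors
#'
#' Runs the share exchange and returns the modular sum of the client vectors,
#' which equals the plaintext modular sum bit-exactly.
#'
#' @inheritParams secure_exchange
#' @return A `fedalz_fpvec` holding `(sum of inputs) mod Q`.
#' @export
secure_sum <- function(clients, cfg, seed = NULL) {
  secure_exchange(clients, cfg, seed)$total
}

#' Secure federated averaging
#'
#' Each client pre-scales its flattened model by its averaging weight
#' `w_i = n_i / sum(n_j)` (or `1/N`), fixed-point encodes it, and the weighted
#' average is obtained as a secure sum; the server decodes and unflattens.
#' The result deviates from the plaintext [fedavg_aggregate()] by at most
#' `N * 2^-(f+1)` per coordinate (one rounding per client).
#'
#' @param updates List of `fedalz_params` client models (at least
#'   `cfg$min_clients`).
#' @param n_samples Client sample counts.
#' @param cfg A [secagg_config()].
#' @param seed Optional seed for the share streams.
#' @param weighting `"by_size"` or `"uniform"`.
#' @return The aggregated `fedalz_params`.
#' @export
secure_fedavg <- function(updates, n_samples = rep(1L, length(updates)),
                          cfg = secagg_config(), seed = NULL,
                          weighting = c("by_size", "uniform")) {
  weighting <- match.arg(weighting)
  n <- length(updates)
  if (n < cfg$min_clients) {
    stop("secure aggregation requires at least ", cfg$min_clients, " clients")
  }
  w <- if (weighting == "by_size") n_samples / sum(n_samples) else rep(1 / n, n)
  flats <- lapply(updates, flatten_params)
  len <- unique(vapply(flats, length, 0L))
  if (length(len) != 1) stop("flattened model dimension mismatch")
  enc <- lapply(seq_len(n), function(i) fp_encode(w[i] * flats[[i]], cfg))
  tot <- secure_sum(enc, cfg, seed)
  out <- unflatten_params(fp_decode(tot), updates[[1]])
  attr(out, "loss") <- NULL
  attr(out, "opt_state") <- NULL
  out
}

#' The honest-but-curious server's view of one client
#'
#' Under the protocol the server observes, per client `j`, only the masked
#' partial-sum vector `sum_i alpha_j^i mod Q`, which is marginally uniform on
#' `[0, Q)` and statistically independent of any single client's update.
#'
#' @param transcript A `fedalz_transcript` from [secure_exchange()].
#' @param client_id Client index in `1..N`.
#' @return A `fedalz_fpvec` with that client's reported partial sum.
#' @export
adversary_view <- function(transcript, client_id) {
  stopifnot(inherits(transcript, "fedalz_transcript"))
  if (!(client_id %in% seq_len(transcript$n_clients))) {
    stop("no such client in the transcript: ", client_id)
  }
  structure(list(values = transcript$partials[, client_id],
                 cfg = transcript$total$cfg),
            class = "fedalz_fpvec")
}
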