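#' Simulate a stochastic neuron network
#'
#' Simulates the discrete-time dynamics: at every bin each neuron fires
#' independently with probability \eqn{\phi(v)}, where `v` is its
#' [membrane_potential()] given the network's recent history. All neurons
#' start silent; the first `burn_in` bins are discarded so that the recorded
#' sample is (up to ergodic forgetting) a draw from the stationary regime.
#'
#' The returned table has `n + K` rows (`K = network$memory`): `K` leading
#' bins are kept so that block estimators with memory `k <= K` have a full
#' history window for each of the `n` analysis bins.
#'
#' @param network A [network_spec()].
#' @param n Number of analysis bins (`n >= 1`).
#' @param burn_in Number of initial bins to discard (default 1000).
#' @param seed Integer seed; identical `(network, n, burn_in, seed)` give
#'   bit-identical output. `NULL` leaves the RNG state alone.
#' @param bin_size Bin duration in milliseconds, recorded as an attribute
#'   (the dynamics are per-bin; this is metadata).
#' @return A tibble with one 0/1 integer column per neuron and `n + K` rows,
#'   with attributes `memory`, `n` and `bin_size`.
#' @examples
#' trains <- simulate_network(two_neuron_network(w_xy = 10), n = 500, seed = 1)
#' colMeans(trains)
#' @export
simulate_network <- function(network, n, burn_in = 1000L, seed = NULL,
                             bin_size = 10) {
  stopifnot(inherits(network, "network_spec"))
  n <- as.integer(n); burn_in <- as.integer(burn_in)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (is.na(burn_in) || burn_in < 0L) stop("`burn_in` must be >= 0", call. = FALSE)
  K <- network$memory
  N <- length(network$neurons)
  total <- K + burn_in + n
  if (!is.null(seed)) set.seed(as.integer(seed))
  u <- matrix(runif(total * N), total, N)
  if (network$phi$family == "offset-logistic") {
    x <- sim_gl_logistic(u, network$weights, network$beta,
                         network$phi$offset, K)
  } else {
    x <- sim_gl_r(u, network)
  }
  x <- x[(total - (n + K) + 1L):total, , drop = FALSE]
  colnames(x) <- network$neurons
  out <- tibble::as_tibble(x)
  attr(out, "memory") <- K
  attr(out, "n") <- n
  attr(out, "bin_size") <- bin_size
  out
}

# Pure-R reference implementation of the same recursion; consumes the
# uniforms in the identical order as the compiled path.
sim_gl_r <- function(u, network) {
  K <- network$memory
  N <- length(network$neurons)
  total <- nrow(u)
  x <- matrix(0L, total, N)
  w <- network$weights
  for (t in seq.int(K + 1L, total)) {
    win <- x[(t - K):(t - 1L), , drop = FALSE]
    for (i in seq_len(N)) {
      pres <- lapply(seq_len(N), function(j) win[, j])
      v <- potential_from_window(win[, i], pres, w[, i], network$beta[i], K)
      p <- spiking_probability(network$phi, v)
      x[t, i] <- as.integer(u[t, i] < p)
    }
  }
  x
}
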