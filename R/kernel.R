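#' Exact joint transition kernel of a two-neuron network
#'
#' With memory bound `K`, the pair process is a Markov chain on joint
#' `K`-block states: the last `K` bins of both neurons determine the
#' distribution of the next joint symbol \eqn{(x_0, y_0)}. This enumerates
#' all \eqn{4^K} states and fills each row exactly from the membrane
#' potential formula and the spiking-rate function (the two neurons fire
#' conditionally independently, so each row is a product of two Bernoullis).
#' The result is the analytic oracle used to validate the simulator and the
#' plug-in estimator.
#'
#' @param network A two-neuron [network_spec()].
#' @return A `vlmc_kernel`: see [vlmc_kernel()] for the encoding.
#' @examples
#' ker <- exact_joint_kernel(two_neuron_network(w_xy = 0.375))
#' stationary_rate(ker, "y")
#' @export
exact_joint_kernel <- function(network) {
  stopifnot(inherits(network, "network_spec"))
  if (length(network$neurons) != 2L) {
    stop("exact enumeration supports exactly 2 neurons (state space is 4^K per pair)",
         call. = FALSE)
  }
  K <- network$memory
  ns <- 2^K
  w <- network$weights
  prob <- matrix(0, ns * ns, 4L)
  for (cx in 0:(ns - 1L)) {
    hx <- decode_history(cx, K)
    for (cy in 0:(ns - 1L)) {
      hy <- decode_history(cy, K)
      px <- spiking_probability(
        network$phi,
        potential_from_window(hx, list(hx, hy), w[, 1L], network$beta[1L], K))
      py <- spiking_probability(
        network$phi,
        potential_from_window(hy, list(hx, hy), w[, 2L], network$beta[2L], K))
      s <- cx * ns + cy + 1L
      prob[s, ] <- c((1 - px) * (1 - py), (1 - px) * py,
                     px * (1 - py), px * py)
    }
  }
  vlmc_kernel(prob, K, neurons = network$neurons)
}

#' Joint variable-length Markov kernel on k-block states
#'
#' Container for an explicit joint transition kernel of a binary pair
#' process with memory `k`. States are joint `k`-blocks encoded as
#' `cx * 2^k + cy + 1`, where each per-neuron history code has the *oldest*
#' bin in its least-significant bit and the most recent bin (`t - 1`) in bit
#' `k - 1`. Columns index the next joint symbol as `2 * x0 + y0 + 1`.
#'
#' @param prob Numeric matrix, `4^k` rows by 4 columns; each row a
#'   probability distribution over the next joint symbol.
#' @param k Memory length.
#' @param neurons Names of the two coordinates (default `c("x", "y")`).
#' @return An object of class `vlmc_kernel`.
#' @examples
#' # two independent Bernoulli(0.5) chains with k = 1:
#' vlmc_kernel(matrix(0.25, 4, 4), k = 1)
#' @export
vlmc_kernel <- function(prob, k, neurons = c("x", "y")) {
  k <- as.integer(k)
  stopifnot(k >= 1L, is.matrix(prob))
  if (nrow(prob) != 4^k || ncol(prob) != 4L) {
    stop(sprintf("`prob` must be a %d x 4 matrix for k = %d", 4^k, k),
         call. = FALSE)
  }
  if (any(prob < 0) || any(prob > 1)) {
    stop("kernel probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(rowSums(prob) - 1) > 1e-12)) {
    stop("kernel rows must sum to 1 (within 1e-12)", call. = FALSE)
  }
  structure(list(prob = prob, k = k, neurons = neurons),
            class = "vlmc_kernel")
}

#' @export
print.vlmc_kernel <- function(x, ...) {
  cat(sprintf("<vlmc_kernel> k = %d, %d joint block states, neurons: %s\n",
              x$k, nrow(x$prob), paste(x$neurons, collapse = ", ")))
  invisible(x)
}

decode_history <- function(code, k) {
  as.integer(intToBits(code))[seq_len(k)]
}

# Transition matrix of the induced chain on joint k-block states.
state_transition_matrix <- function(kernel) {
  k <- kernel$k
  ns <- 2^k
  m <- ns * ns
  P <- matrix(0, m, m)
  cx <- rep(0:(ns - 1L), each = ns)
  cy <- rep(0:(ns - 1L), times = ns)
  for (x0 in 0:1) {
    for (y0 in 0:1) {
      ncx <- cx %/% 2L + x0 * 2^(k - 1L)
      ncy <- cy %/% 2L + y0 * 2^(k - 1L)
      to <- ncx * ns + ncy + 1L
      pr <- kernel$prob[, 2L * x0 + y0 + 1L]
      P[cbind(seq_len(m), to)] <- P[cbind(seq_len(m), to)] + pr
    }
  }
  P
}

# Unique stationary law of the state chain. A finite chain has a unique
# stationary distribution iff it has exactly one closed communicating class;
# anything else errors.
stationary_distribution <- function(kernel) {
  P <- state_transition_matrix(kernel)
  m <- nrow(P)
  # transitive closure of the support graph (includes self-reachability)
  R <- (P > 0) | (diag(m) > 0)
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  # state i is recurrent iff every state it reaches reaches it back
  recurrent <- vapply(seq_len(m), function(i) all(!R[i, ] | R[, i]), TRUE)
  if (!any(recurrent)) {
    stop("kernel has no recurrent class", call. = FALSE)
  }
  n_classes <- nrow(unique(R[recurrent, , drop = FALSE]))
  if (n_classes > 1L) {
    stop("kernel induces a reducible state chain with no unique stationary law",
         call. = FALSE)
  }
  A <- rbind(t(diag(m) - P), rep(1, m))
  pi_hat <- qr.solve(A, c(rep(0, m), 1))
  pi_hat[pi_hat < 0 & pi_hat > -1e-12] <- 0
  if (any(pi_hat < 0) || abs(sum(pi_hat) - 1) > 1e-9) {
    stop("stationary solve failed to produce a probability vector", call. = FALSE)
  }
  resid <- max(abs(drop(pi_hat %*% P) - pi_hat))
  if (resid > 1e-10) {
    stop("stationary solve did not converge (residual ", format(resid), ")",
         call. = FALSE)
  }
  pi_hat
}

#' Exact stationary firing rate of a neuron
#'
#' Solves for the stationary distribution of the joint block-state chain
#' induced by a [vlmc_kernel()] and returns the marginal probability that
#' the chosen neuron spikes in a bin.
#'
#' @param kernel A `vlmc_kernel`.
#' @param neuron Neuron name or index (1 = first coordinate).
#' @return A probability.
#' @examples
#' ker <- exact_joint_kernel(two_neuron_network(w_xy = 0))
#' stationary_rate(ker, "x")  # 0.5 with the calibrated baseline
#' @export
stationary_rate <- function(kernel, neuron = 1L) {
  stopifnot(inherits(kernel, "vlmc_kernel"))
  idx <- if (is.character(neuron)) match(neuron, kernel$neurons) else as.integer(neuron)
  if (is.na(idx) || idx < 1L || idx > 2L) {
    stop("`neuron` must name one of the kernel's two coordinates", call. = FALSE)
  }
  pi_hat <- stationary_distribution(kernel)
  # P(next symbol of the neuron is 1), extended one step with the kernel
  col_sym <- if (idx == 1L) c(3L, 4L) else c(2L, 4L)  # columns with x0=1 / y0=1
  sum(pi_hat * rowSums(kernel$prob[, col_sym, drop = FALSE]))
}

#' Exact transfer entropy rate of a joint kernel
#'
#' For a pair process with memory `k` and explicit kernel, the transfer
#' entropy rate from source to target is the conditional mutual information
#' \deqn{T(X \to Y) = H(Y_0 \mid Y_{-k}^{-1}) - H(Y_0 \mid X_{-k}^{-1}, Y_{-k}^{-1}),}
#' computed here as finite sums under the exact stationary law of the block
#' chain (natural logarithms; nats). This is the analytic value the plug-in
#' estimator converges to.
#'
#' @param kernel A [vlmc_kernel()].
#' @param source,target Neuron names or indices; default direction is
#'   first -> second coordinate.
#' @return The transfer entropy rate in nats (non-negative).
#' @examples
#' ker <- exact_joint_kernel(two_neuron_network(w_xy = 10))
#' ter_exact(ker)                          # > 0: x drives y
#' ter_exact(ker, source = "y", target = "x")  # 0: no feedback
#' @export
ter_exact <- function(kernel, source = 1L, target = 2L) {
  stopifnot(inherits(kernel, "vlmc_kernel"))
  s_idx <- if (is.character(source)) match(source, kernel$neurons) else as.integer(source)
  t_idx <- if (is.character(target)) match(target, kernel$neurons) else as.integer(target)
  if (is.na(s_idx) || is.na(t_idx) || s_idx == t_idx ||
      !all(c(s_idx, t_idx) %in% 1:2)) {
    stop("`source` and `target` must name the two distinct coordinates",
         call. = FALSE)
  }
  k <- kernel$k
  ns <- 2^k
  pi_hat <- stationary_distribution(kernel)
  cx <- rep(0:(ns - 1L), each = ns)
  cy <- rep(0:(ns - 1L), times = ns)
  # P(target_0 = 1 | state): sum kernel columns where the target symbol is 1
  col_sym <- if (t_idx == 1L) c(3L, 4L) else c(2L, 4L)
  p1 <- rowSums(kernel$prob[, col_sym, drop = FALSE])
  tpast <- if (t_idx == 1L) cx else cy
  # H(T_0 | S_past, T_past): average Bernoulli entropy over states
  h_full <- sum(pi_hat * bernoulli_entropy(p1))
  # H(T_0 | T_past): mix over the source past within each target past
  w1 <- rowsum(pi_hat * p1, tpast)        # P(T_past, T_0 = 1)
  w <- rowsum(pi_hat, tpast)              # P(T_past)
  pos <- drop(w) > 0
  pcond <- drop(w1)[pos] / drop(w)[pos]
  h_own <- sum(drop(w)[pos] * bernoulli_entropy(pcond))
  max(h_own - h_full, 0)
}

bernoulli_entropy <- function(p) {
  xlx <- function(q) ifelse(q > 0, -q * log(q), 0)
  xlx(p) + xlx(1 - p)
}
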