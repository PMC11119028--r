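#' Stochastic neuron network specification
#'
#' Describes a discrete-time network of stochastic neurons with
#' variable-length memory. Each neuron `i` carries a spontaneous-activity
#' baseline \eqn{\beta_i} and synaptic weights \eqn{\omega_{j \to i}} from its
#' presynaptic neurons; a shared spiking-rate function \eqn{\phi} maps
#' membrane potential to spike probability, and `memory` is the bound `K` on
#' how far back any neuron's potential can reach (its last spike time is
#' truncated at `t - K`).
#'
#' @param weights Square numeric matrix; `weights[j, i]` is the synaptic
#'   weight \eqn{\omega_{j \to i}} of neuron `j` onto neuron `i`. Row/column
#'   names, if present, name the neurons (defaults `x`, `y`, `n3`, ...).
#' @param beta Numeric vector of baselines \eqn{\beta_i}, one per neuron, or
#'   a single value recycled to all neurons. Defaults to
#'   [calibrate_baseline()] of `phi`, which gives input-free neurons a 50\%
#'   stationary firing rate.
#' @param phi A [phi_spec()].
#' @param memory Positive integer memory bound `K`.
#' @return An object of class `network_spec`.
#' @examples
#' net <- two_neuron_network(w_xy = 10)
#' net
#' @export
network_spec <- function(weights, beta = NULL, phi = phi_spec(), memory = 3L) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (n < 1L || ncol(weights) != n || !is.numeric(weights) ||
      any(!is.finite(weights))) {
    stop("`weights` must be a finite square numeric matrix", call. = FALSE)
  }
  stopifnot(inherits(phi, "phi_spec"))
  memory <- as.integer(memory)
  if (length(memory) != 1L || is.na(memory) || memory < 1L) {
    stop("`memory` must be a positive integer", call. = FALSE)
  }
  if (is.null(beta)) beta <- calibrate_baseline(phi)
  beta <- rep_len(as.numeric(beta), n)
  if (any(!is.finite(beta))) stop("`beta` must be finite", call. = FALSE)
  nms <- rownames(weights)
  if (is.null(nms)) {
    nms <- if (n <= 2L) c("x", "y")[seq_len(n)] else
      c("x", "y", paste0("n", 3:n))[seq_len(n)]
  }
  dimnames(weights) <- list(nms, nms)
  names(beta) <- nms
  structure(list(weights = weights, beta = beta, phi = phi,
                 memory = memory, neurons = nms),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %d neurons, memory bound K = %d\n",
              length(x$neurons), x$memory))
  cat("weights (row = presynaptic j, column = postsynaptic i):\n")
  print(x$weights)
  cat("beta:", paste(sprintf("%s = %.4g", names(x$beta), x$beta),
                     collapse = ", "), "\n")
  print(x$phi)
  invisible(x)
}

#' Two-neuron network with a single directed connection
#'
#' Convenience constructor for the microcircuit used throughout the power
#' studies: a source neuron `x` and a target neuron `y` with weights
#' \eqn{\omega_{x \to y}} and \eqn{\omega_{y \to x}}.
#'
#' @param w_xy Synaptic weight from `x` onto `y`.
#' @param w_yx Synaptic weight from `y` onto `x` (default 0: no feedback).
#' @inheritParams network_spec
#' @return A `network_spec` with neurons named `x` and `y`.
#' @examples
#' two_neuron_network(w_xy = 0.375)
#' @export
two_neuron_network <- function(w_xy, w_yx = 0, beta = NULL, phi = phi_spec(),
                               memory = 3L) {
  w <- matrix(c(0, w_yx, w_xy, 0), 2, 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  network_spec(w, beta = beta, phi = phi, memory = memory)
}

#' Benchmark two-neuron coupling scenarios
#'
#' The four standard scenarios for validating the causality test, all with
#' \eqn{\omega_{y \to x} = 0} (so the `y -> x` direction is a true null):
#' strong excitatory (\eqn{\omega_{x \to y} = 10}), weak excitatory (0.375),
#' weak inhibitory (-0.375), and strong inhibitory (-10) coupling, with the
#' calibrated offset-logistic spiking-rate function and memory bound 3.
#'
#' @param scenario Integer 1-4.
#' @inheritParams network_spec
#' @return A `network_spec`.
#' @examples
#' scenario_network(2)
#' @export
scenario_network <- function(scenario, phi = phi_spec(), memory = 3L) {
  scenario <- as.integer(scenario)
  if (length(scenario) != 1L || is.na(scenario) || scenario < 1L || scenario > 4L) {
    stop("`scenario` must be 1, 2, 3 or 4", call. = FALSE)
  }
  w <- scenario_weights()[scenario]
  two_neuron_network(w_xy = w, w_yx = 0, phi = phi, memory = memory)
}

scenario_weights <- function() c(`1` = 10, `2` = 0.375, `3` = -0.375, `4` = -10)

#' Membrane potential of a stochastic neuron
#'
#' Computes the membrane potential just before bin `t` given the neuron's own
#' spike history and those of its presynaptic neurons. If the neuron spiked
#' at `t - 1` the potential is 0 (reset). Otherwise it is
#' \deqn{\beta + \frac{\sum_j \omega_j \sum_{s = L+1}^{t-1} x_s(j)}{2^{\,t-L-1}},}
#' where `L` is the neuron's last spike time before `t`, truncated so that
#' \eqn{L \ge t - K}: the synaptic input accumulated since the last spike,
#' geometrically leaked, on top of the spontaneous drive \eqn{\beta}.
#'
#' Histories are vectors ordered oldest to newest whose final element is bin
#' `t - 1`; only their last `K` entries are used.
#'
#' @param own 0/1 vector, the neuron's own history up to `t - 1`.
#' @param presyn List of 0/1 vectors (same length as `own`), one per
#'   presynaptic neuron; may be empty.
#' @param weights Numeric vector of synaptic weights, one per element of
#'   `presyn`.
#' @param beta Spontaneous-activity baseline \eqn{\beta}.
#' @param memory Memory bound `K`.
#' @return The membrane potential (a single number).
#' @examples
#' # input spike one bin after the neuron's own last spike, weight 10:
#' membrane_potential(own = c(0, 1, 0), presyn = list(c(0, 0, 1)),
#'                    weights = 10, beta = -2 * log(4), memory = 3)
#' @export
membrane_potential <- function(own, presyn = list(), weights = numeric(),
                               beta = 0, memory = 3L) {
  memory <- as.integer(memory)
  stopifnot(memory >= 1L, length(presyn) == length(weights))
  if (length(own) < memory ||
      any(vapply(presyn, length, 1L) != length(own))) {
    stop("histories must cover at least the `memory` bins before t and have equal length",
         call. = FALSE)
  }
  own <- check_binary(own, "own")
  presyn <- lapply(presyn, check_binary, what = "presyn")
  h_own <- tail(own, memory)
  h_pre <- lapply(presyn, tail, memory)
  potential_from_window(h_own, h_pre, weights, beta, memory)
}

# Potential from exactly the last K bins (oldest first). Shared by
# membrane_potential, the exact kernel and the pure-R simulator.
potential_from_window <- function(h_own, h_pre, weights, beta, K) {
  if (h_own[K] == 1) return(0)
  spikes <- which(h_own == 1L)
  # j indexes bins t-K..t-1; last own spike at j* -> L = t-K+j*-1, and with
  # no spike in the window L is truncated to t-K (same input range as j*=1)
  Lj <- if (length(spikes)) max(spikes) else 1L
  syn <- 0
  if (Lj < K && length(weights)) {
    idx <- seq.int(Lj + 1L, K)
    syn <- sum(vapply(seq_along(h_pre),
                      function(i) weights[i] * sum(h_pre[[i]][idx]), 0))
  }
  beta + syn / 2^(K - Lj)
}

check_binary <- function(v, what = "spike train") {
  if (is.logical(v)) v <- as.integer(v)
  if (!is.numeric(v) || anyNA(v) || any(v != 0 & v != 1)) {
    bad <- which(is.na(v) | (v != 0 & v != 1))[1]
    stop(sprintf("%s must contain only 0/1 symbols (offending position %d)",
                 what, bad), call. = FALSE)
  }
  as.integer(v)
}
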