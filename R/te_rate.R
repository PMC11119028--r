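#' Plug-in transfer entropy rate estimate
#'
#' Substitutes the empirical joint block distribution into the conditional
#' mutual information that defines the transfer entropy rate of a pair
#' process with memory `k`:
#' \deqn{\hat T = \hat H(Y_0 \mid Y_{-k}^{-1}) -
#'       \hat H(Y_0 \mid X_{-k}^{-1}, Y_{-k}^{-1}),}
#' evaluated as the four-term entropy combination
#' \eqn{\hat H(Y_{-k}^0) - \hat H(Y_{-k}^{-1}) - \hat H(X_{-k}^{-1}, Y_{-k}^0)
#' + \hat H(X_{-k}^{-1}, Y_{-k}^{-1})}. The estimate is a conditional mutual
#' information, hence non-negative up to floating-point cancellation; tiny
#' negative values are clipped to 0 in `value` (the raw difference is kept
#' in `raw`).
#'
#' @param counts A [count_blocks()] result.
#' @return An object of class `ter_estimate`: a list with `value` (nats,
#'   clipped at 0), `raw`, `k`, `n`, `source`, `target`.
#' @examples
#' trains <- simulate_network(two_neuron_network(w_xy = 10), n = 2000, seed = 1)
#' te_rate_plugin(count_blocks(trains, x, y, k = 3))
#' @export
te_rate_plugin <- function(counts) {
  stopifnot(inherits(counts, "block_counts"))
  k <- attr(counts, "k")
  past <- seq.int(-k, -1L)
  full <- seq.int(-k, 0L)
  raw <- block_entropy(counts, y_lags = full) -
    block_entropy(counts, y_lags = past) -
    block_entropy(counts, x_lags = past, y_lags = full) +
    block_entropy(counts, x_lags = past, y_lags = past)
  if (raw < -1e-9) {
    stop("plug-in transfer entropy rate is substantially negative; ",
         "this indicates corrupted counts", call. = FALSE)
  }
  structure(list(value = max(raw, 0), raw = raw, k = k, n = attr(counts, "n"),
                 source = attr(counts, "source"),
                 target = attr(counts, "target")),
            class = "ter_estimate")
}

#' Transfer entropy rate of a spike-train pair
#'
#' Data-frame front end: builds the block counts with [count_blocks()] and
#' returns the plug-in estimate for the `source -> target` direction.
#'
#' @inheritParams count_blocks
#' @return A `ter_estimate` (see [te_rate_plugin()]).
#' @examples
#' trains <- simulate_network(two_neuron_network(w_xy = 10), n = 2000, seed = 1)
#' te_rate(trains, x, y, k = 3)
#' te_rate(trains, y, x, k = 3)  # null direction: near 0
#' @export
te_rate <- function(data, source = "x", target = "y", k = 3L) {
  te_rate_plugin(count_blocks(data, {{ source }}, {{ target }}, k = k))
}

#' @export
print.ter_estimate <- function(x, ...) {
  cat(sprintf(
    "Plug-in transfer entropy rate %s -> %s: %.6g nats (k = %d, n = %d)\n",
    x$source, x$target, x$value, x$k, x$n))
  invisible(x)
}

#' @export
as.double.ter_estimate <- function(x, ...) x$value

#' @rdname te_rate_plugin
#' @param x A `ter_estimate`.
#' @param ... Unused.
#' @export
tidy.ter_estimate <- function(x, ...) {
  tibble::tibble(source = x$source, target = x$target, k = x$k, n = x$n,
                 te_rate = x$value)
}

#' Delete-a-block jackknife standard error for the plug-in estimate
#'
#' Splits the `n` sliding windows into `groups` contiguous blocks, recomputes
#' the plug-in estimate with each block left out, and returns the jackknife
#' standard error. Contiguous deletion respects the serial dependence of the
#' windows far better than a delete-one jackknife.
#'
#' @inheritParams count_blocks
#' @param groups Number of contiguous blocks (default 20).
#' @return A list with `estimate` (full-sample `ter_estimate` value), `se`,
#'   `groups`, and the leave-one-out `values`.
#' @examples
#' trains <- simulate_network(two_neuron_network(w_xy = 10), n = 4000, seed = 1)
#' te_rate_jackknife(trains, x, y, k = 3)$se
#' @export
te_rate_jackknife <- function(data, source = "x", target = "y", k = 3L,
                              groups = 20L) {
  x <- check_binary(dplyr::pull(data, {{ source }}), "source train")
  y <- check_binary(dplyr::pull(data, {{ target }}), "target train")
  k <- as.integer(k); groups <- as.integer(groups)
  n <- length(x) - k
  stopifnot(n >= groups, groups >= 2L)
  ca <- block_codes(x, k)
  cb <- block_codes(y, k)
  g <- ceiling(seq_len(n) * groups / n)
  theta_full <- te_rate_plugin(new_block_counts(ca, cb, k, n))$value
  vals <- vapply(seq_len(groups), function(gg) {
    keep <- g != gg
    te_rate_plugin(new_block_counts(ca[keep], cb[keep], k, sum(keep)))$value
  }, numeric(1))
  se <- sqrt((groups - 1) / groups * sum((vals - mean(vals))^2))
  list(estimate = theta_full, se = se, groups = groups, values = vals)
}
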