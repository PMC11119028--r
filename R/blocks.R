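#' Empirical joint block distribution of a spike-train pair
#'
#' Slides a window of `k + 1` bins over an aligned pair of binary trains and
#' tabulates the joint counts of the `(k+1)`-block pairs. A sample of length
#' `n + k` yields exactly `n` overlapping windows; the normalised counts are
#' the plug-in estimate of the joint block distribution, the ingredient of
#' the transfer-entropy-rate estimator and the likelihood-ratio statistic.
#'
#' @param data A data frame with one 0/1 column per neuron (e.g. the output
#'   of [simulate_network()] or [read_spike_trains()]).
#' @param source,target Columns holding the source and target trains
#'   (tidy-eval; defaults `x` and `y`).
#' @param k Memory length of the blocks (default 3). Validated against
#'   [admissible_memory()]: a `k` above the admissible bound for the sample
#'   size triggers a warning, not an error.
#' @return A tibble of class `block_counts` with columns `a_block` and
#'   `b_block` (source/target blocks as strings, oldest bin leftmost) and
#'   `count`, and attributes `k`, `n`, `source`, `target`.
#' @examples
#' trains <- simulate_network(two_neuron_network(w_xy = 10), n = 200, seed = 1)
#' count_blocks(trains, x, y, k = 2)
#' @export
count_blocks <- function(data, source = "x", target = "y", k = 3L) {
  x <- dplyr::pull(data, {{ source }})
  y <- dplyr::pull(data, {{ target }})
  src_name <- tidyselect_name(data, {{ source }}, "x")
  tgt_name <- tidyselect_name(data, {{ target }}, "y")
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("`k` must be a positive integer", call. = FALSE)
  if (length(x) != length(y)) {
    stop("source and target trains must have equal length", call. = FALSE)
  }
  n <- length(x) - k
  if (n < 1L) {
    stop(sprintf("need at least k + 1 = %d bins for one window", k + 1L),
         call. = FALSE)
  }
  x <- check_binary(x, "source train")
  y <- check_binary(y, "target train")
  adm <- if (n >= 8L) admissible_memory(n) else 0L
  if (k > adm) {
    warning(sprintf(paste0("k = %d exceeds the admissible memory bound %d ",
                           "for n = %d (k <= log(n)/2); estimates may be ",
                           "unreliable"), k, adm, n), call. = FALSE)
  }
  ca <- block_codes(x, k)
  cb <- block_codes(y, k)
  new_block_counts(ca, cb, k, n, src_name, tgt_name)
}

# sliding-window block codes: window i (1..n) covers bins i..i+k; bit m of
# the code is the symbol at offset m from the window's oldest bin
block_codes <- function(v, k) {
  n <- length(v) - k
  out <- integer(n)
  for (m in 0:k) out <- out + v[(1L + m):(n + m)] * 2L^m
  out
}

block_string <- function(code, width) {
  vapply(code, function(cd) {
    paste(as.integer(intToBits(cd))[seq_len(width)], collapse = "")
  }, character(1))
}

new_block_counts <- function(ca, cb, k, n, source = "x", target = "y") {
  tab <- dplyr::count(tibble::tibble(a = ca, b = cb), .data$a, .data$b,
                      name = "count")
  out <- tibble::tibble(
    a_block = block_string(tab$a, k + 1L),
    b_block = block_string(tab$b, k + 1L),
    count = as.integer(tab$count)
  )
  structure(out, class = c("block_counts", class(out)),
            k = k, n = n, source = source, target = target)
}

tidyselect_name <- function(data, col, default) {
  nm <- tryCatch(rlang::as_name(rlang::enquo(col)), error = function(e) NULL)
  if (is.null(nm) || !nzchar(nm)) default else nm
}

#' @export
print.block_counts <- function(x, ...) {
  cat(sprintf("Joint (k+1)-block counts: k = %d, n = %d windows, %s -> %s\n",
              attr(x, "k"), attr(x, "n"),
              attr(x, "source"), attr(x, "target")))
  NextMethod()
}

#' Marginal Shannon entropy of selected block coordinates
#'
#' Computes the entropy (in nats) of the marginal of the empirical block
#' distribution on a chosen subset of the `2(k + 1)` block coordinates,
#' with the convention \eqn{0 \log 0 = 0} (only observed blocks contribute).
#' Conditional entropies are differences of two such marginals; the
#' transfer-entropy-rate estimator is built from four of them.
#'
#' @param counts A [count_blocks()] result.
#' @param x_lags,y_lags Integer vectors of lags in `-k..0` selecting source
#'   and target coordinates (`0` is the window's most recent bin). Both
#'   empty selects nothing and gives entropy 0.
#' @return Entropy in nats.
#' @examples
#' trains <- simulate_network(two_neuron_network(w_xy = 0), n = 500, seed = 1)
#' bc <- count_blocks(trains, x, y, k = 2)
#' block_entropy(bc, y_lags = 0)          # ~ Bernoulli entropy of y
#' block_entropy(bc, y_lags = -2:0)       # 3-block entropy of y
#' @export
block_entropy <- function(counts, x_lags = integer(), y_lags = integer()) {
  stopifnot(inherits(counts, "block_counts"))
  if (nrow(counts) == 0L) stop("empty block counts", call. = FALSE)
  k <- attr(counts, "k")
  n <- attr(counts, "n")
  check_lags <- function(l) {
    l <- as.integer(l)
    if (anyNA(l) || any(l < -k | l > 0) || anyDuplicated(l)) {
      stop(sprintf("lags must be distinct integers in -%d..0", k), call. = FALSE)
    }
    sort(l)
  }
  x_lags <- check_lags(x_lags)
  y_lags <- check_lags(y_lags)
  if (!length(x_lags) && !length(y_lags)) return(0)
  key <- rep("", nrow(counts))
  if (length(x_lags)) {
    key <- paste0(key, substr_positions(counts$a_block, x_lags + k + 1L))
  }
  if (length(y_lags)) {
    key <- paste0(key, "|", substr_positions(counts$b_block, y_lags + k + 1L))
  }
  cnt <- rowsum(counts$count, key)
  entropy_nats(drop(cnt), n)
}

substr_positions <- function(s, pos) {
  if (length(pos) == 1L) return(substr(s, pos, pos))
  do.call(paste0, lapply(pos, function(p) substr(s, p, p)))
}

entropy_nats <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

#' Largest admissible block memory for a sample size
#'
#' The plug-in block estimator is consistent when the memory grows no faster
#' than \eqn{k(n) \le \log(n) / 2} (natural logarithm). This returns the
#' largest admissible integer `k` for a given number of windows `n`; callers
#' use it to validate a user-chosen `k`.
#'
#' @param n Effective sample size (number of windows), at least 8.
#' @return The largest admissible memory (a positive integer).
#' @examples
#' admissible_memory(5000)  # 4, so the default k = 3 is admissible
#' admissible_memory(100)   # 2
#' @export
admissible_memory <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer", call. = FALSE)
  k <- floor(log(n) / 2)
  if (k < 1L) {
    stop(sprintf("n = %d is too small for any admissible memory (need n >= 8)", n),
         call. = FALSE)
  }
  as.integer(k)
}
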