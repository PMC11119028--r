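#' Degrees of freedom of the causality test
#'
#' The likelihood-ratio statistic of the no-causal-influence test is
#' asymptotically chi-squared with \eqn{d = 2^k(2^k - 1)} degrees of
#' freedom for binary pair processes with memory `k` — the dimension gap
#' between the full transition model and its factorised null.
#'
#' @param k Memory length (positive integer).
#' @return The degrees of freedom \eqn{2^k(2^k - 1)}.
#' @examples
#' degrees_of_freedom(3)  # 56
#' @export
degrees_of_freedom <- function(k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  as.integer(2^k * (2^k - 1))
}

#' Likelihood-ratio statistic for no causal influence
#'
#' The test statistic is \eqn{\Delta_n = 2 n \hat T_n^{(k)}}: twice the
#' sample size times the plug-in transfer entropy rate. `lr_statistic()`
#' computes it through the plug-in estimator; [lr_statistic_direct()]
#' recomputes it as twice the gap between the maximised log-likelihoods of
#' the full and null transition models — the two agree exactly (up to
#' floating point), which is the identity that hands the likelihood-ratio
#' test its information-theoretic form.
#'
#' @param counts A [count_blocks()] result.
#' @return The statistic \eqn{\Delta_n \ge 0}.
#' @examples
#' trains <- simulate_network(two_neuron_network(w_xy = 10), n = 2000, seed = 1)
#' bc <- count_blocks(trains, x, y, k = 3)
#' lr_statistic(bc)
#' lr_statistic_direct(bc)
#' @export
lr_statistic <- function(counts) {
  stopifnot(inherits(counts, "block_counts"))
  2 * attr(counts, "n") * te_rate_plugin(counts)$value
}

#' Likelihood-ratio statistic from maximised log-likelihoods
#'
#' Independent route to the same statistic as [lr_statistic()]: plugs the
#' empirical conditional transition frequencies (the maximum-likelihood
#' transition matrices) into the log-likelihood of the sample, once for the
#' saturated model and once for the null factorisation in which the target's
#' next symbol is conditionally independent of the source's past given its
#' own past (the source is then conditioned on its own past and the target's
#' present and past). Returns twice the log-likelihood gap.
#'
#' @inheritParams lr_statistic
#' @return The statistic \eqn{\Delta_n \ge 0}.
#' @export
lr_statistic_direct <- function(counts) {
  stopifnot(inherits(counts, "block_counts"))
  k <- attr(counts, "k")
  cnt <- counts$count
  a_past <- substr(counts$a_block, 1L, k)
  b_past <- substr(counts$b_block, 1L, k)
  b_full <- counts$b_block
  lookup <- function(key) {
    tot <- rowsum(cnt, key)
    drop(tot)[key]
  }
  # saturated model: Q(a0, b0 | a_past, b_past) = N(a, b) / N(a_past, b_past)
  ll_full <- sum(cnt * log(cnt / lookup(paste(a_past, b_past))))
  # null, source factor: Qx(a0 | a_past, b_full) = N(a, b) / N(a_past, b_full)
  ll_x <- sum(cnt * log(cnt / lookup(paste(a_past, b_full))))
  # null, target factor: Qy(b0 | b_past) = N(b) / N(b_past), over the b-marginal
  nb <- drop(rowsum(cnt, b_full))
  nbp <- drop(rowsum(cnt, b_past))
  keys <- names(nb)
  ll_y <- sum(nb * log(nb / nbp[substr(keys, 1L, k)]))
  max(2 * (ll_full - (ll_x + ll_y)), 0)
}

#' Upper-tail chi-squared p-value of the causality statistic
#'
#' Maps an observed statistic \eqn{\delta_n} to its asymptotic p-value
#' \eqn{P(\chi^2(d) > \delta_n)} with `d = degrees_of_freedom(k)`.
#'
#' @param delta Observed statistic (non-negative).
#' @param k Memory length.
#' @return A p-value in `[0, 1]`, strictly decreasing in `delta`.
#' @examples
#' lr_p_value(51.08, k = 3)  # 0.6612
#' @export
lr_p_value <- function(delta, k) {
  if (!is.numeric(delta) || anyNA(delta) || any(delta < 0)) {
    stop("`delta` must be non-negative", call. = FALSE)
  }
  pchisq(delta, df = degrees_of_freedom(k), lower.tail = FALSE)
}

#' Likelihood-ratio test of no causal influence between spike trains
#'
#' Tests the null hypothesis that the target's next symbol is conditionally
#' independent of the source's past given the target's own past — i.e. that
#' the transfer entropy rate `source -> target` is zero — within the model
#' of jointly stationary ergodic binary chains with memory at most `k`.
#' The statistic \eqn{\Delta_n = 2 n \hat T_n^{(k)}} is referred to its
#' asymptotic chi-squared null distribution with [degrees_of_freedom()]
#' `(k)` degrees of freedom; the null is rejected when the upper-tail
#' p-value is at most `alpha`.
#'
#' The test is directional: run it once per ordered pair. Testing both
#' directions is two separate tests and no multiplicity correction is
#' applied. A warning (recorded in the result) is raised when `k` exceeds
#' the admissible memory for the sample size or when `n < 50 * 4^k`, below
#' which the chi-squared approximation is not trusted.
#'
#' @inheritParams count_blocks
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return An object of class `ter_test`: a list with `delta`, `df`,
#'   `p_value`, `alpha`, `reject`, `te_rate`, `k`, `n`, `source`, `target`,
#'   `warnings`. Has [tidy()], [glance()] and print methods.
#' @examples
#' trains <- simulate_network(two_neuron_network(w_xy = 10), n = 4000, seed = 1)
#' te_causality_test(trains, x, y, k = 3)
#' te_causality_test(trains, y, x, k = 3)  # true null direction
#' @export
te_causality_test <- function(data, source = "x", target = "y", k = 3L,
                              alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single number in (0, 1)", call. = FALSE)
  }
  warns <- character()
  counts <- withCallingHandlers(
    count_blocks(data, {{ source }}, {{ target }}, k = k),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  for (w in warns) warning(w, call. = FALSE)
  n <- attr(counts, "n")
  k <- attr(counts, "k")
  if (n < 50 * 4^k) {
    msg <- sprintf(paste0("n = %d is below the guard 50 * 4^k = %d; the ",
                          "chi-squared calibration of the test may be poor"),
                   n, 50L * 4L^k)
    warns <- c(warns, msg)
    warning(msg, call. = FALSE)
  }
  est <- te_rate_plugin(counts)
  delta <- 2 * n * est$value
  df <- degrees_of_freedom(k)
  p <- lr_p_value(delta, k)
  structure(list(delta = delta, df = df, p_value = p, alpha = alpha,
                 reject = p <= alpha, te_rate = est$value, k = k, n = n,
                 source = attr(counts, "source"),
                 target = attr(counts, "target"),
                 warnings = warns),
            class = "ter_test")
}

#' @export
print.ter_test <- function(x, ...) {
  cat("\n\tLikelihood-ratio test of no causal influence\n\n")
  cat(sprintf("direction: %s -> %s   (k = %d, n = %d)\n",
              x$source, x$target, x$k, x$n))
  cat(sprintf("Delta = %.4f, df = %d, p-value = %.4g\n",
              x$delta, x$df, x$p_value))
  cat(sprintf("plug-in transfer entropy rate: %.6g nats\n", x$te_rate))
  cat(sprintf("decision at alpha = %g: %s\n", x$alpha,
              if (x$reject) "reject (causal influence detected)"
              else "do not reject"))
  if (length(x$warnings)) {
    cat("warnings:\n")
    for (w in x$warnings) cat(" -", w, "\n")
  }
  cat("\n")
  invisible(x)
}

#' @rdname te_causality_test
#' @param x A `ter_test` object.
#' @param ... Unused.
#' @export
tidy.ter_test <- function(x, ...) {
  tibble::tibble(source = x$source, target = x$target, k = x$k, n = x$n,
                 te_rate = x$te_rate, statistic = x$delta, df = x$df,
                 p.value = x$p_value, alpha = x$alpha, reject = x$reject)
}

#' @rdname te_causality_test
#' @export
glance.ter_test <- function(x, ...) tidy(x)

#' Write a causality-test result as a JSON report
#'
#' @param result A [te_causality_test()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_test_report <- function(result, path) {
  stopifnot(inherits(result, "ter_test"))
  report <- list(direction = paste(result$source, "->", result$target),
                 k = result$k, n = result$n, delta = result$delta,
                 df = result$df, p_value = result$p_value,
                 alpha = result$alpha, reject = result$reject,
                 warnings = result$warnings)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
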