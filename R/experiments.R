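#' Specification of a Monte-Carlo power/size study
#'
#' Describes one coupling scenario of the two-neuron benchmark together with
#' the simulation grid: sample sizes, number of replicates, significance
#' levels, block memory and seeding. Replicate `r` at the `i`-th sample size
#' uses seed `base_seed + scenario * 1e6 + i * 1e4 + r`, recorded in the
#' output for auditability.
#'
#' @param scenario Scenario id 1-4 (see [scenario_network()]).
#' @param n Sample sizes (default `c(5000, 10000, 20000, 40000)`).
#' @param replicates Replicates per sample size (default 100).
#' @param alpha Significance levels (default `c(0.001, 0.01, 0.05, 0.10)`).
#' @param k Block memory (default 3); every `n` must satisfy
#'   `k <= log(n)/2`.
#' @param base_seed Integer base seed.
#' @param burn_in Discarded initial bins per simulation (default 1000).
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_spec(1, n = 5000, replicates = 10)
#' @export
scenario_spec <- function(scenario, n = c(5000L, 10000L, 20000L, 40000L),
                          replicates = 100L,
                          alpha = c(0.001, 0.01, 0.05, 0.10),
                          k = 3L, base_seed = 1L, burn_in = 1000L) {
  scenario <- as.integer(scenario)
  stopifnot(scenario %in% 1:4, length(n) >= 1L, all(n >= 1),
            replicates >= 1L, all(alpha > 0 & alpha < 1), k >= 1L)
  n <- as.integer(sort(unique(n)))
  bad <- n[k > floor(log(n) / 2)]
  if (length(bad)) {
    warning(sprintf("k = %d exceeds the admissible memory log(n)/2 for n = %s",
                    k, paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(scenario = scenario, w_xy = unname(scenario_weights()[scenario]),
                 w_yx = 0, n = n, replicates = as.integer(replicates),
                 alpha = sort(alpha), k = as.integer(k),
                 base_seed = as.integer(base_seed),
                 burn_in = as.integer(burn_in)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(paste0("<scenario_spec> scenario %d (w_xy = %g, w_yx = %g), ",
                     "k = %d\n  n: %s\n  alpha: %s\n  replicates: %d, ",
                     "burn-in: %d, base seed: %d\n"),
              x$scenario, x$w_xy, x$w_yx, x$k,
              paste(x$n, collapse = ", "), paste(x$alpha, collapse = ", "),
              x$replicates, x$burn_in, x$base_seed))
  invisible(x)
}

replicate_seed <- function(spec, n_index, r) {
  spec$base_seed + spec$scenario * 1000000L + n_index * 10000L + r
}

# Quiet per-replicate statistics for both directions (no admissibility
# warnings in the inner loop; the spec constructor validates once).
replicate_stats <- function(trains, k) {
  x <- trains$x
  y <- trains$y
  ca <- block_codes(x, k)
  cb <- block_codes(y, k)
  n <- length(ca)
  df <- degrees_of_freedom(k)
  out <- lapply(list(c("x", "y"), c("y", "x")), function(dir) {
    cnts <- if (dir[1] == "x") new_block_counts(ca, cb, k, n, "x", "y")
            else new_block_counts(cb, ca, k, n, "y", "x")
    est <- te_rate_plugin(cnts)
    delta <- 2 * n * est$value
    tibble::tibble(direction = paste0(dir[1], "->", dir[2]),
                   te_rate = est$value, delta = delta, df = df,
                   p_value = pchisq(delta, df, lower.tail = FALSE))
  })
  dplyr::bind_rows(out)
}

#' Run a Monte-Carlo power and size study
#'
#' For every sample size and replicate of the scenario, simulates the
#' two-neuron network, computes the likelihood-ratio statistic in both
#' directions, and tabulates rejection counts at each significance level.
#' The `x -> y` direction measures power (or size, when the scenario's
#' coupling is zero); `y -> x` is always a true null in the benchmark
#' scenarios and measures the empirical test size. Fully reproducible from
#' the spec's `base_seed`.
#'
#' @param spec A [scenario_spec()].
#' @param verbose Print progress per sample size.
#' @return An object of class `power_study`: a list with `spec`,
#'   `estimates` (one row per replicate x direction, with the seed used) and
#'   `rejections` (one row per direction x n x alpha). Has [tidy()] and
#'   [autoplot()] methods.
#' @examples
#' ps <- run_power_study(scenario_spec(1, n = 2000, replicates = 5,
#'                                     burn_in = 200))
#' tidy(ps)
#' @export
run_power_study <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  net <- scenario_network(spec$scenario, memory = max(spec$k, 3L))
  est <- vector("list", length(spec$n) * spec$replicates)
  idx <- 0L
  for (i in seq_along(spec$n)) {
    nn <- spec$n[i]
    if (verbose) message("scenario ", spec$scenario, ", n = ", nn)
    for (r in seq_len(spec$replicates)) {
      seed <- replicate_seed(spec, i, r)
      trains <- simulate_network(net, n = nn, burn_in = spec$burn_in,
                                 seed = seed)
      stats <- replicate_stats(trains, spec$k)
      stats$scenario <- spec$scenario
      stats$n <- nn
      stats$replicate <- r
      stats$seed <- seed
      idx <- idx + 1L
      est[[idx]] <- stats
    }
  }
  estimates <- dplyr::bind_rows(est)
  rejections <- tidyr::crossing(
    dplyr::distinct(estimates, .data$scenario, .data$direction, .data$n),
    alpha = spec$alpha)
  rejections <- dplyr::rowwise(rejections)
  rejections <- dplyr::mutate(
    rejections,
    rejected = sum(estimates$p_value[estimates$direction == .data$direction &
                                       estimates$n == .data$n] <= .data$alpha),
    replicates = spec$replicates)
  rejections <- dplyr::ungroup(rejections)
  structure(list(spec = spec, estimates = estimates, rejections = rejections),
            class = "power_study")
}

#' @export
print.power_study <- function(x, ...) {
  cat(sprintf("<power_study> scenario %d: %d replicates, %d sample sizes\n",
              x$spec$scenario, x$spec$replicates, length(x$spec$n)))
  print(power_table_wide(x))
  invisible(x)
}

#' @rdname run_power_study
#' @param x A `power_study`.
#' @param ... Unused.
#' @export
tidy.power_study <- function(x, ...) x$rejections

#' Rejection table in the classic wide layout
#'
#' One row per direction and sample size, one column per significance
#' level, holding rejection counts out of the study's replicates.
#'
#' @param study A [run_power_study()] result.
#' @return A tibble.
#' @export
power_table_wide <- function(study) {
  stopifnot(inherits(study, "power_study"))
  tab <- dplyr::mutate(study$rejections,
                       alpha = sprintf("alpha=%g%%", 100 * .data$alpha))
  tidyr::pivot_wider(
    dplyr::select(tab, "scenario", "direction", "n", "alpha", "rejected"),
    names_from = "alpha", values_from = "rejected")
}

#' Write a power study to disk
#'
#' Writes the wide rejection table as TSV and, optionally, the long-format
#' rejection table and per-replicate estimates as CSV.
#'
#' @param study A [run_power_study()] result.
#' @param path Path of the TSV table.
#' @param long_csv,estimates_csv Optional CSV paths.
#' @return `path`, invisibly.
#' @export
write_power_table <- function(study, path, long_csv = NULL,
                              estimates_csv = NULL) {
  utils::write.table(power_table_wide(study), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(long_csv)) {
    utils::write.csv(study$rejections, long_csv, row.names = FALSE)
  }
  if (!is.null(estimates_csv)) {
    utils::write.csv(study$estimates, estimates_csv, row.names = FALSE)
  }
  invisible(path)
}

#' Goodness-of-fit check of the null distribution of the statistic
#'
#' Collects the likelihood-ratio statistic over replicates for a direction
#' with zero coupling (a true null) and compares its empirical distribution
#' with the asymptotic chi-squared law: empirical mean and variance, a
#' histogram summary, and a two-sided Kolmogorov-Smirnov test against
#' \eqn{\chi^2(d)} with `d = degrees_of_freedom(k)`.
#'
#' @param spec A [scenario_spec()].
#' @param direction `"y->x"` (a true null in every benchmark scenario) or
#'   `"x->y"` (only valid when the scenario's coupling is zero).
#' @param n Sample size to use (default: the spec's largest).
#' @return An object of class `ter_null_check` with elements `delta`
#'   (replicate statistics), `df`, `n`, `replicates`, `mean`, `variance`,
#'   `ks_statistic`, `ks_p_value`, `reliable`, `histogram`. Has [glance()]
#'   and [autoplot()] methods.
#' @examples
#' nc <- null_distribution_check(
#'   scenario_spec(1, n = 2000, replicates = 5, burn_in = 200))
#' glance(nc)
#' @export
null_distribution_check <- function(spec, direction = "y->x", n = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  direction <- match.arg(direction, c("y->x", "x->y"))
  w <- if (direction == "y->x") spec$w_yx else spec$w_xy
  if (w != 0) {
    stop(sprintf("direction %s has nonzero coupling (w = %g): not a null check",
                 direction, w), call. = FALSE)
  }
  if (is.null(n)) n <- max(spec$n)
  n <- as.integer(n)
  i <- match(n, spec$n)
  if (is.na(i)) i <- length(spec$n) + 1L  # distinct seed stream for ad-hoc n
  net <- scenario_network(spec$scenario, memory = max(spec$k, 3L))
  delta <- vapply(seq_len(spec$replicates), function(r) {
    trains <- simulate_network(net, n = n, burn_in = spec$burn_in,
                               seed = replicate_seed(spec, i, r))
    st <- replicate_stats(trains, spec$k)
    st$delta[st$direction == direction]
  }, numeric(1))
  df <- degrees_of_freedom(spec$k)
  reliable <- spec$replicates >= 10L
  if (spec$replicates >= 2L) {
    ks <- suppressWarnings(ks.test(delta, "pchisq", df = df))
    ks_stat <- unname(ks$statistic)
    ks_p <- ks$p.value
  } else {
    ks_stat <- NA_real_
    ks_p <- NA_real_
  }
  hh <- graphics::hist(delta, plot = FALSE)
  structure(list(delta = delta, df = df, n = n, replicates = spec$replicates,
                 direction = direction, scenario = spec$scenario,
                 mean = mean(delta),
                 variance = if (length(delta) > 1L) var(delta) else NA_real_,
                 ks_statistic = ks_stat, ks_p_value = ks_p,
                 reliable = reliable,
                 histogram = tibble::tibble(
                   mid = hh$mids, count = hh$counts, density = hh$density)),
            class = "ter_null_check")
}

#' @export
print.ter_null_check <- function(x, ...) {
  cat(sprintf(paste0("<ter_null_check> scenario %d, direction %s, n = %d, ",
                     "%d replicates\n"),
              x$scenario, x$direction, x$n, x$replicates))
  cat(sprintf("mean Delta = %.2f (chi2 mean = %d), variance = %.2f (chi2 var = %d)\n",
              x$mean, x$df, x$variance, 2L * x$df))
  if (x$reliable) {
    cat(sprintf("KS vs chi2(%d): D = %.4f, p = %.4f\n",
                x$df, x$ks_statistic, x$ks_p_value))
  } else {
    cat("KS comparison unreliable: too few replicates\n")
  }
  invisible(x)
}

#' @rdname null_distribution_check
#' @param x A `ter_null_check`.
#' @param ... Unused.
#' @export
glance.ter_null_check <- function(x, ...) {
  tibble::tibble(scenario = x$scenario, direction = x$direction, n = x$n,
                 replicates = x$replicates, df = x$df, mean = x$mean,
                 variance = x$variance, ks_statistic = x$ks_statistic,
                 ks_p_value = x$ks_p_value, reliable = x$reliable)
}

#' Five-number summaries of the estimated transfer entropy rates
#'
#' Box-plot summaries (min, quartiles, max) of the per-replicate plug-in
#' transfer-entropy-rate estimates of a power study, per direction and
#' sample size. Under a true null the median of \eqn{2 n \hat T} sits near
#' the chi-squared median \eqn{\approx d}, so the null-direction medians
#' scale like \eqn{d / (2n)}; coupled directions sit well above.
#'
#' @param study A [run_power_study()] result.
#' @return A tibble with columns `scenario`, `direction`, `n`, `min`, `q1`,
#'   `median`, `q3`, `max`.
#' @export
ter_distribution_summary <- function(study) {
  stopifnot(inherits(study, "power_study"))
  dplyr::summarise(
    dplyr::group_by(study$estimates, .data$scenario, .data$direction, .data$n),
    min = min(.data$te_rate),
    q1 = quantile(.data$te_rate, 0.25, names = FALSE),
    median = quantile(.data$te_rate, 0.5, names = FALSE),
    q3 = quantile(.data$te_rate, 0.75, names = FALSE),
    max = max(.data$te_rate),
    .groups = "drop")
}
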