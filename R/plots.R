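#' Plot a power study
#'
#' `type = "power"` draws rejection rate against sample size, one line per
#' significance level, faceted by direction; the null direction should
#' hover near the nominal levels while the coupled direction climbs to 1.
#' `type = "ter"` draws box plots of the per-replicate transfer-entropy-rate
#' estimates per direction and sample size.
#'
#' @param object A [run_power_study()] result.
#' @param type `"power"` or `"ter"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_study <- function(object, type = c("power", "ter"), ...) {
  type <- match.arg(type)
  if (type == "power") {
    dat <- dplyr::mutate(object$rejections,
                         rate = .data$rejected / .data$replicates,
                         alpha = factor(.data$alpha))
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$n, y = .data$rate,
                                      colour = .data$alpha)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::facet_wrap(ggplot2::vars(.data$direction)) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "sample size n", y = "rejection rate",
                    colour = "level",
                    title = sprintf("Scenario %d: empirical power and size",
                                    object$spec$scenario))
  } else {
    ggplot2::ggplot(object$estimates,
                    ggplot2::aes(x = factor(.data$n), y = .data$te_rate,
                                 fill = .data$direction)) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(x = "sample size n",
                    y = "plug-in transfer entropy rate (nats)",
                    title = sprintf("Scenario %d: estimated TER by direction",
                                    object$spec$scenario))
  }
}

#' Plot a null-distribution check
#'
#' Histogram (on the density scale) of the replicate statistics with the
#' asymptotic chi-squared density overlaid.
#'
#' @param object A [null_distribution_check()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ter_null_check <- function(object, ...) {
  grid <- tibble::tibble(
    x = seq(max(min(object$delta) - 10, 0), max(object$delta) + 10,
            length.out = 400))
  grid$density <- stats::dchisq(grid$x, df = object$df)
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = tibble::tibble(delta = object$delta),
      ggplot2::aes(x = .data$delta, y = ggplot2::after_stat(density)),
      bins = max(10L, ceiling(sqrt(object$replicates))),
      fill = "grey70", colour = "grey40") +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$x, y = .data$density),
                       colour = "red") +
    ggplot2::labs(
      x = expression(Delta[n]), y = "density",
      title = sprintf("Null statistic vs chi-squared(%d), n = %d, %d replicates",
                      object$df, object$n, object$replicates))
}
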