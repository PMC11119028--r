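#' Spiking-rate function specification
#'
#' The spiking-rate function \eqn{\phi} maps a neuron's membrane potential to
#' its probability of firing in the next time bin. It must be non-decreasing
#' with range in \eqn{[0, 1]}. The default family is the *offset logistic*
#' \deqn{\phi(u) = \frac{1}{1 + e^{-(u + c)}},}
#' whose offset \eqn{c} sets the post-spike firing probability
#' \eqn{\phi(0) = 1/(1+e^{-c})}. The package default \eqn{c = \log 4} gives
#' \eqn{\phi(0) = 0.8}, which together with [calibrate_baseline()] reproduces
#' a 50\% stationary firing rate for an input-free neuron.
#'
#' @param family Either `"offset-logistic"` (default) or `"custom"`.
#' @param offset Offset \eqn{c} of the logistic family. Ignored for custom
#'   families.
#' @param fn For `family = "custom"`, a vectorised non-decreasing function
#'   from the reals to \eqn{[0, 1]}.
#' @return An object of class `phi_spec`.
#' @examples
#' phi <- phi_spec(offset = log(4))
#' spiking_probability(phi, 0)  # 0.8
#' @seealso [spiking_probability()], [calibrate_baseline()]
#' @export
phi_spec <- function(family = c("offset-logistic", "custom"), offset = log(4),
                     fn = NULL) {
  family <- match.arg(family)
  if (family == "offset-logistic") {
    stopifnot(is.numeric(offset), length(offset) == 1L, is.finite(offset))
    fn <- NULL
  } else {
    if (!is.function(fn)) {
      stop("a custom phi_spec requires `fn`, a function from potentials to [0, 1]",
           call. = FALSE)
    }
  }
  structure(list(family = family, offset = offset, fn = fn),
            class = "phi_spec")
}

#' @export
print.phi_spec <- function(x, ...) {
  if (x$family == "offset-logistic") {
    cat(sprintf("<phi_spec> offset-logistic, c = %.6g (phi(0) = %.4f)\n",
                x$offset, spiking_probability(x, 0)))
  } else {
    cat("<phi_spec> custom spiking-rate function\n")
  }
  invisible(x)
}

#' Evaluate the spiking-rate function
#'
#' Returns \eqn{\phi(v)}, the probability that a neuron with membrane
#' potential `potential` fires in the next bin.
#'
#' @param phi A [phi_spec()].
#' @param potential Numeric vector of finite membrane potentials.
#' @return Probabilities in \eqn{[0, 1]}, one per potential.
#' @examples
#' spiking_probability(phi_spec(offset = log(4)), c(0, -2 * log(4)))
#' @export
spiking_probability <- function(phi, potential) {
  stopifnot(inherits(phi, "phi_spec"))
  if (!is.numeric(potential) || anyNA(potential) || any(!is.finite(potential))) {
    stop("`potential` must be finite numeric", call. = FALSE)
  }
  if (phi$family == "offset-logistic") {
    p <- 1 / (1 + exp(-(potential + phi$offset)))
  } else {
    p <- phi$fn(potential)
    if (any(p < 0 | p > 1)) {
      stop("custom spiking-rate function returned values outside [0, 1]",
           call. = FALSE)
    }
  }
  p
}

#' Calibrate the spontaneous-activity baseline for a 50% firing rate
#'
#' An input-free neuron alternates between two spike probabilities:
#' \eqn{\phi(0)} in the bin after a spike (the potential is reset) and
#' \eqn{\phi(\beta)} otherwise. Its stationary firing rate \eqn{r} solves the
#' balance \eqn{r = \phi(0)\,r + \phi(\beta)\,(1 - r)}, which equals
#' \eqn{1/2} exactly when \eqn{\phi(0) + \phi(\beta) = 1}. This function
#' returns that \eqn{\beta}: in closed form \eqn{\beta = -2c} for the
#' offset-logistic family, by 1-D root finding otherwise.
#'
#' @param phi A [phi_spec()].
#' @param interval Search interval for the root when `phi` is custom.
#' @return The baseline \eqn{\beta} (a single number).
#' @examples
#' calibrate_baseline(phi_spec(offset = log(4)))  # -2 log 4
#' @export
calibrate_baseline <- function(phi, interval = c(-50, 50)) {
  stopifnot(inherits(phi, "phi_spec"))
  if (phi$family == "offset-logistic") {
    return(-2 * phi$offset)
  }
  target <- 1 - spiking_probability(phi, 0)
  f <- function(b) spiking_probability(phi, b) - target
  if (f(interval[1]) * f(interval[2]) > 0) {
    stop("cannot bracket a baseline with phi(0) + phi(beta) = 1 on the given interval",
         call. = FALSE)
  }
  uniroot(f, interval, tol = 1e-12)$root
}
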