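#' Success-count measure of a Bernoulli-valued sample
#'
#' For independent Bernoulli measurements with success probabilities
#' \eqn{\theta_1, \dots, \theta_n}, the total success count
#' \eqn{W = \sum_i Z_i} is distributed according to the convolution
#' \eqn{\nu = \mu_1 * \cdots * \mu_n}: the Poisson-binomial distribution.
#' \eqn{\nu} is not in general binomial (the \eqn{\mu_i} need not be
#' identical), but it is a finite categorical measure on \eqn{\{0,\dots,n\}}
#' and drives the whole conjugate analysis of a Bernoulli proportion.
#'
#' The pmf is computed by iterative convolution (dynamic programming), exact
#' to floating precision, in \eqn{O(n^2)} — appropriate up to desk scale
#' (\eqn{n \le 10^4}); beyond that a characteristic-function method would be
#' the natural swap-in.
#'
#' @param thetas success probabilities in \[0, 1\], or an `rvvm_sample` / list
#'   of measures all supported on \{0, 1\}.
#' @return An object of class `rvvm_nu`: list with `n` and `pmf` (length
#'   `n + 1`, for `W = 0..n`).  `n = 0` yields a point mass at 0.
#' @examples
#' nu <- success_count_distribution(c(0.9, 0.8))
#' nu$pmf              # 0.02 0.26 0.72
#' mean(nu)            # 1.7
#' variance(nu)        # 0.09 + 0.16
#' @export
success_count_distribution <- function(thetas) {
  th <- bernoulli_thetas(thetas)
  pmf <- 1
  for (t in th)
    pmf <- c(pmf * (1 - t), 0) + c(0, pmf * t)
  structure(list(n = length(th), pmf = pmf, thetas = th), class = "rvvm_nu")
}

## Extract per-record success probabilities, rejecting non-binary support.
bernoulli_thetas <- function(x) {
  if (is.numeric(x)) {
    if (any(is.na(x)) || any(x < 0) || any(x > 1))
      stop("success probabilities must lie in [0, 1]")
    return(as.numeric(x))
  }
  ms <- sample_measures(x)
  vapply(ms, function(m) {
    if (!all(m$support %in% c(0, 1)))
      stop("measure with support outside {0, 1}: ",
           "a Bernoulli target admits only binary measurements")
    p <- m$probs[match(1, m$support)]
    if (is.na(p)) 0 else p
  }, 0)
}

#' @export
print.rvvm_nu <- function(x, ...) {
  cat(sprintf("<success-count measure> n = %d, E(W) = %.6g, Var(W) = %.6g\n",
              x$n, mean(x), variance(x)))
  invisible(x)
}

#' @rdname success_count_distribution
#' @param x,object an `rvvm_nu`.
#' @param ... unused.
#' @export
mean.rvvm_nu <- function(x, ...) sum(seq(0, x$n) * x$pmf)

#' @rdname success_count_distribution
#' @export
variance.rvvm_nu <- function(object, ...) {
  k <- seq(0, object$n)
  max(0, sum(k^2 * object$pmf) - sum(k * object$pmf)^2)
}
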