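#' Simulation study: bias of the generalized mean and Bayes estimator
#'
#' For each sample size in `n_grid`, repeatedly generates a calibrated (or
#' deliberately miscalibrated) Bernoulli measurement protocol with true
#' success probability `theta0`, and records the error of the generalized
#' sample mean \eqn{\bar\rho(S)} and of the conjugate Bayes estimate.  Under
#' calibration both biases shrink with \eqn{n}; a confidence shift of
#' `miscal_shift` leaves the truths unchanged but displaces the reported
#' measures, producing a persistent bias of about
#' `miscal_shift * partial_frac`.
#'
#' Each unit is partially measured with probability `partial_frac`; partial
#' units draw a confidence from the mean-matched discrete distribution of
#' [confidence_weights()] (mean `theta0`), record Ber(confidence +
#' `miscal_shift`, clipped to \[0,1\]), and have their truth drawn as
#' Bernoulli(confidence); definitive units record their truth as a point
#' mass.
#'
#' @param n_grid sample sizes.
#' @param reps replications per cell (at least 1).
#' @param theta0 true success probability.
#' @param partial_frac fraction of nontrivial measurements.
#' @param miscal_shift additive confidence shift (0 = calibrated).
#' @param shape1,shape2 Beta prior for the Bayes estimate.
#' @param conf_grid,conf_concentration confidence distribution parameters.
#' @param seed integer seed.
#' @return Data frame per sample size: mean and Monte-Carlo standard error of
#'   the error of \eqn{\bar\rho(S)} (`bias_mean`, `se_mean`) and of the Bayes
#'   estimate (`bias_bayes`, `se_bayes`).
#' @export
run_wlln_study <- function(n_grid = c(50, 200, 800), reps = 200,
                           theta0 = 0.6, partial_frac = 0.3,
                           miscal_shift = 0, shape1 = 1, shape2 = 1,
                           conf_grid = seq(0.1, 0.9, by = 0.1),
                           conf_concentration = 4, seed = NULL) {
  if (reps < 1 || length(n_grid) == 0) stop("empty study grid")
  if (!is.null(seed)) set.seed(seed)
  w <- confidence_weights(theta0, conf_grid, conf_concentration)
  rows <- lapply(n_grid, function(n) {
    err_mean <- numeric(reps)
    err_bayes <- numeric(reps)
    for (r in seq_len(reps)) {
      partial <- stats::runif(n) < partial_frac
      conf <- numeric(n)
      conf[partial] <- sample(conf_grid, sum(partial), replace = TRUE,
                              prob = w)
      truth <- numeric(n)
      truth[partial] <- stats::rbinom(sum(partial), 1, conf[partial])
      truth[!partial] <- stats::rbinom(sum(!partial), 1, theta0)
      theta_rec <- ifelse(partial, pmin(1, pmax(0, conf + miscal_shift)),
                          truth)
      rho_bar <- mean(theta_rec)
      err_mean[r] <- rho_bar - theta0
      err_bayes[r] <- (shape1 + sum(theta_rec)) / (shape1 + shape2 + n) -
        theta0
    }
    data.frame(n = n,
               bias_mean = mean(err_mean),
               se_mean = stats::sd(err_mean) / sqrt(reps),
               bias_bayes = mean(err_bayes),
               se_bayes = stats::sd(err_bayes) / sqrt(reps))
  })
  do.call(rbind, rows)
}

#' Simulation study: posterior-sd behaviour as partial data accumulate
#'
#' Tracks the posterior standard deviation of the Bernoulli proportion as the
#' definitively measured subsample (size `m1`) grows, with the nontrivial
#' subsample size `m2` tied to `m1` by a rule: `"sqrt"` (`m2 = ceiling(sqrt(m1))`,
#' the vanishing-fraction regime), `"proportional"` (`m2 = prop * m1`, a fixed
#' fraction of maximally uncertain Ber(`confidence`) measurements), or
#' `"none"` (`m2 = 0`, the classical case, where the posterior sd equals the
#' single-component Beta sd).
#'
#' @param m1_grid definitively measured subsample sizes.
#' @param m2_rule how `m2` scales with `m1`.
#' @param prop proportionality constant for `m2_rule = "proportional"`.
#' @param theta0 true success probability of the definitive units.
#' @param confidence the (common) confidence of the nontrivial measurements.
#' @param reps replications per cell.
#' @param shape1,shape2 Beta prior.
#' @param seed integer seed.
#' @return Data frame per `m1`: `m2`, mean posterior sd (`post_sd`) and its
#'   Monte-Carlo standard error (`se`).
#' @export
run_consistency_study <- function(m1_grid = c(100, 400, 1600),
                                  m2_rule = c("sqrt", "proportional", "none"),
                                  prop = 1, theta0 = 0.5, confidence = 0.5,
                                  reps = 100, shape1 = 1, shape2 = 1,
                                  seed = NULL) {
  m2_rule <- match.arg(m2_rule)
  if (reps < 1 || length(m1_grid) == 0) stop("empty study grid")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(m1_grid, function(m1) {
    m2 <- switch(m2_rule,
                 sqrt = as.integer(ceiling(sqrt(m1))),
                 proportional = as.integer(round(prop * m1)),
                 none = 0L)
    sds <- numeric(reps)
    for (r in seq_len(reps)) {
      truths <- stats::rbinom(m1, 1, theta0)
      fit <- rvvm_binom(c(truths, rep(confidence, m2)),
                        shape1 = shape1, shape2 = shape2)
      sds[r] <- fit$sd
    }
    data.frame(m1 = m1, m2 = m2, post_sd = mean(sds),
               se = stats::sd(sds) / sqrt(reps))
  })
  do.call(rbind, rows)
}

#' Proportion-female estimates under the three bird protocols
#'
#' Recomputes, from the fixed 50-bird example of [bird_example()], the Bayes
#' estimate and posterior standard deviation of the proportion of females
#' under each sex measurement protocol: `rho1` (full truth), `rho2`
#' (definitively sexed subsample only) and `rho3` (point masses plus the
#' eight Bernoulli confidence measures).
#'
#' @param shape1,shape2 Beta prior shapes (the worked example uses
#'   Beta(15, 15)).
#' @param data a dataset with the [generate_birds()] layout; defaults to the
#'   fixed example.
#' @return Data frame with one row per protocol: `n`, `estimate`, `post_sd`.
#' @examples
#' bird_protocol_estimates(15, 15)
#' @export
bird_protocol_estimates <- function(shape1 = 15, shape2 = 15,
                                    data = bird_example()) {
  fits <- list(
    rho1 = rvvm_binom(data$sex.rho1, shape1, shape2),
    rho2 = rvvm_binom(data$sex.rho2[!is.na(data$sex.rho2)], shape1, shape2),
    rho3 = rvvm_binom(data$sex.rho3, shape1, shape2))
  data.frame(protocol = names(fits),
             n = vapply(fits, `[[`, 0L, "n"),
             estimate = vapply(fits, `[[`, 0, "mean"),
             post_sd = vapply(fits, `[[`, 0, "sd"),
             row.names = NULL)
}
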