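test_that("completion enumeration is exhaustive with product weights", {
  df <- data.frame(x = c(1, 2))
  df$y <- I(list(bernoulli_measure(0.9), bernoulli_measure(0.5)))
  comps <- enumerate_completions(df)
  expect_length(comps, 4L)
  w <- sort(vapply(comps, `[[`, 0, "weight"), decreasing = TRUE)
  expect_equal(w, c(0.45, 0.45, 0.05, 0.05))
  expect_equal(sum(w), 1, tolerance = 1e-10)

  # all-trivial data: a single completion of weight one
  df2 <- data.frame(x = 1:3)
  df2$y <- I(lapply(c(0, 1, 1), point_mass))
  comps2 <- enumerate_completions(df2)
  expect_length(comps2, 1L)
  expect_equal(comps2[[1]]$weight, 1)
  expect_equal(comps2[[1]]$data$y, c(0, 1, 1))

  # one categorical cell with three charged atoms
  df3 <- data.frame(x = 1)
  df3$y <- I(list(discrete_measure(0:3, c(0.2, 0.3, 0.5, 0))))
  expect_length(enumerate_completions(df3), 3L)

  # blow-up is rejected with a pointer to Monte-Carlo completion
  df4 <- data.frame(x = 1:20)
  df4$y <- I(rep(list(bernoulli_measure(0.5)), 20))
  expect_error(enumerate_completions(df4, limit = 1000), "mc")
})

test_that("sampled completions follow the product measure", {
  df <- data.frame(x = 1:3)
  df$y <- I(list(point_mass(1), bernoulli_measure(1), bernoulli_measure(0.3)))
  set.seed(8)
  reps <- 2000
  vals <- replicate(reps, sample_completion(df)$data$y[3])
  expect_equal(replicate(5, sample_completion(df)$data$y[1]), rep(1, 5))
  expect_equal(replicate(5, sample_completion(df)$data$y[2]), rep(1, 5))
  se <- sqrt(0.3 * 0.7 / reps)
  expect_lt(abs(mean(vals) - 0.3), 4 * se)
})

test_that("all-trivial pooled fit equals a single standard Bayesian fit", {
  birds <- bird_example()
  d <- birds[c("sex.rho1", "age", "weight")]
  ctrl <- list(chains = 2, iter = 1500, warmup = 1000)
  fit_pool <- rvvm_glm(sex.rho1 ~ age, d, family = "logistic",
                       mode = "exact", control = ctrl, seed = 101)
  expect_equal(fit_pool$n_completions, 1L)

  # independent route: the sampler run directly on the numeric data
  set.seed(202)
  X <- cbind("(Intercept)" = 1, age = d$age)
  direct <- rvvm:::bayes_glm_mcmc(X, d$sex.rho1, "logistic",
                                  list(intercept = c(0, 10),
                                       slope = c(0, 2.5), sigma_scale = 10),
                                  chains = 2, iter = 1500, warmup = 1000)
  for (j in 1:2) {
    se <- batch_se(fit_pool$draws[, j]) + batch_se(direct$draws[, j])
    expect_lt(abs(mean(fit_pool$draws[, j]) - mean(direct$draws[, j])),
              4 * se + 0.02)
  }
  # sanity against the maximum-likelihood fit (weak priors, n = 50)
  mle <- coef(glm(sex.rho1 ~ age, binomial, d))
  expect_lt(max(abs(coef(fit_pool) - mle)), 0.35)
})

test_that("posterior recovers generative coefficients from RVVM responses", {
  set.seed(55)
  n <- 80
  x <- rnorm(n)
  p <- plogis(0.5 + 1.2 * x)
  partial <- runif(n) < 0.3
  truth <- rbinom(n, 1, p)
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    # calibrated by construction: confidence equals the true success chance
    cells[[i]] <- if (partial[i]) bernoulli_measure(round(p[i], 2))
                  else point_mass(truth[i])
  }
  d <- data.frame(x = x)
  d$y <- I(cells)
  fit <- suppressWarnings(
    rvvm_glm(y ~ x, d, family = "logistic", mode = "mc", K = 25,
             control = list(chains = 2, iter = 500, warmup = 500), seed = 77))
  est <- coef(fit)
  psd <- apply(fit$draws, 2, sd)
  expect_lt(abs(est["(Intercept)"] - 0.5), 3 * psd["(Intercept)"])
  expect_lt(abs(est["x"] - 1.2), 3 * psd["x"])
})

test_that("exact and Monte-Carlo pooling agree on a small problem", {
  set.seed(66)
  d <- data.frame(x = c(-1, 0, 1, 2, -0.5, 0.5))
  d$y <- I(list(point_mass(0), bernoulli_measure(0.6), point_mass(1),
                bernoulli_measure(0.8), point_mass(0), bernoulli_measure(0.4)))
  ctrl <- list(chains = 2, iter = 400, warmup = 400)
  fe <- suppressWarnings(rvvm_glm(y ~ x, d, family = "logistic",
                                  mode = "exact", control = ctrl, seed = 1))
  fm <- suppressWarnings(rvvm_glm(y ~ x, d, family = "logistic", mode = "mc",
                                  K = 60, control = ctrl, seed = 2))
  for (j in c("(Intercept)", "x")) {
    se <- batch_se(fe$draws[, j]) + batch_se(fm$draws[, j])
    expect_lt(abs(mean(fe$draws[, j]) - mean(fm$draws[, j])), 4 * se + 0.1)
  }
})

test_that("partial-information fits keep juvenile males possible", {
  birds <- bird_example()
  comps <- enumerate_completions(birds["sex.rho3"])
  juv_partial_rows <- 43:50
  has_male <- vapply(comps, function(cmp)
    any(cmp$data$sex.rho3[juv_partial_rows] == 0), TRUE)
  # completions containing juvenile males carry substantial weight
  expect_gt(sum(vapply(comps[has_male], `[[`, 0, "weight")), 0.5)
  # whereas the definitively sexed juveniles are all female
  def_juv <- birds$age == 0 & !is.na(birds$sex.rho2)
  expect_true(all(birds$sex.rho2[def_juv] == 1))
})

test_that("pooled posteriors are at least as dispersed as full-truth fits", {
  birds <- bird_example()
  ctrl <- list(chains = 2, iter = 800, warmup = 800)
  f1 <- rvvm_glm(sex.rho1 ~ age, birds, family = "logistic", mode = "exact",
                 control = ctrl, seed = 11)
  f3 <- suppressWarnings(
    rvvm_glm(sex.rho3 ~ age, birds, family = "logistic", mode = "mc", K = 40,
             control = list(chains = 2, iter = 300, warmup = 400), seed = 12))
  sd1 <- apply(f1$draws, 2, sd)
  sd3 <- apply(f3$draws, 2, sd)
  expect_gt(sd3["age"], 0.85 * sd1["age"])
})

test_that("linear family and prediction methods work end to end", {
  birds <- bird_example()
  d <- birds[c("wing.chord", "age")]
  d$sexm <- birds$sex.rho3
  fit <- suppressWarnings(
    rvvm_glm(wing.chord ~ sexm + age, d, family = "linear", mode = "mc",
             K = 15, control = list(chains = 2, iter = 400, warmup = 400),
             seed = 31))
  expect_true("sigma" %in% colnames(fit$draws))
  expect_false("sigma" %in% names(coef(fit)))
  # fitted means: adults are larger-winged than juvenile males on average
  mu <- predict(fit, data.frame(sexm = c(0, 0), age = c(1, 0)),
                type = "response")
  expect_gt(mu[1], mu[2])
  expect_error(predict(fit, data.frame(sexm = 1, age = 1), type = "odds"),
               "logistic")
  s <- summary(fit)
  expect_true(all(c("estimate", "sd") %in% colnames(s$table)))
})
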