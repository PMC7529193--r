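test_that("constructors validate and canonicalize", {
  expect_error(point_mass(Inf), "finite")
  expect_error(point_mass(NA_real_), "finite")
  expect_error(bernoulli_measure(1.2), "probability")
  expect_error(bernoulli_measure(-0.1), "probability")
  expect_error(discrete_measure(c(0, 0), c(0.5, 0.5)), "distinct")
  expect_error(discrete_measure(0:1, c(0.5, 0.4)), "sum")

  # renormalization is tolerant of decimal rounding only
  m <- discrete_measure(0:2, c(0.3, 0.3, 0.4 + 5e-10))
  expect_equal(sum(m$probs), 1, tolerance = 1e-14)
  expect_error(discrete_measure(0:2, c(0.3, 0.3, 0.41)), "sum")

  # zero-probability atoms are dropped; degenerate Bernoullis collapse
  m <- discrete_measure(0:4, c(0, 0.5, 0.5, 0, 0))
  expect_equal(m$support, c(1, 2))
  expect_true(is_point_mass(bernoulli_measure(1)))
  expect_true(is_point_mass(bernoulli_measure(0)))
  expect_false(is_point_mass(bernoulli_measure(0.5)))

  # support comes out strictly increasing regardless of input order
  m <- discrete_measure(c(3, 1, 2), c(0.2, 0.5, 0.3))
  expect_equal(m$support, c(1, 2, 3))
  expect_equal(m$probs, c(0.5, 0.3, 0.2))
})

test_that("moments match closed forms", {
  expect_identical(mean(point_mass(7.5)), 7.5)
  expect_identical(mean(point_mass(3)), 3)
  expect_equal(mean(bernoulli_measure(0.7)), 0.7)
  expect_equal(mean(discrete_measure(0:4, c(0, 0.5, 0.5, 0, 0))), 1.5)

  expect_equal(variance(point_mass(5)), 0)
  expect_equal(variance(bernoulli_measure(0.4)), 0.24)
  expect_equal(variance(bernoulli_measure(0.5)), 0.25)
  expect_equal(variance(discrete_measure(0:2, c(0.25, 0.5, 0.25))), 0.5)
})

test_that("moments agree with Monte-Carlo sampling", {
  set.seed(11)
  for (m in list(bernoulli_measure(0.3),
                 discrete_measure(c(-1, 0, 2, 5), c(0.1, 0.4, 0.3, 0.2)))) {
    draws <- sample(m$support, 1e5, replace = TRUE, prob = m$probs)
    se_mean <- sd(draws) / sqrt(1e5)
    expect_lt(abs(mean(draws) - mean(m)), 4 * se_mean)
    se_var <- sd((draws - mean(draws))^2) / sqrt(1e5)
    expect_lt(abs(var(draws) - variance(m)), 4 * se_var)
  }
})

test_that("information content is the KL divergence from the point mass", {
  expect_equal(information_content(bernoulli_measure(0.9), 1), -log(0.9))
  expect_equal(information_content(point_mass(1), 1), 0)
  expect_equal(information_content(bernoulli_measure(0.5), 0), log(2))
  expect_error(information_content(bernoulli_measure(1), 0), "zero probability")
  expect_error(information_content(point_mass(2), 3), "zero probability")
  # always nonnegative, zero only at a point mass on the truth
  set.seed(4)
  for (i in 1:20) {
    p <- runif(1, 0.01, 0.99)
    expect_gt(information_content(bernoulli_measure(p), 1), 0)
  }
})

test_that("measure literals parse and round-trip", {
  expect_equal(parse_measure("ber:0.9"), bernoulli_measure(0.9))
  expect_equal(parse_measure("1"), point_mass(1))
  expect_equal(parse_measure("  -2.5 "), point_mass(-2.5))
  expect_equal(parse_measure("cat:0:0.0,1:0.5,2:0.5,3:0.0,4:0.0"),
               discrete_measure(0:4, c(0, 0.5, 0.5, 0, 0)))
  expect_error(parse_measure("ber:1.5"), "malformed")
  expect_error(parse_measure("cat:0:0.3,1:0.3"), "sum")
  expect_error(parse_measure("spam"), "malformed")

  expect_identical(format_measure(bernoulli_measure(0.9)), "ber:0.9")
  expect_identical(format_measure(point_mass(1)), "1")

  # parse . serialize is the identity on canonical literals
  set.seed(7)
  for (i in 1:50) {
    k <- sample(1:5, 1)
    support <- sort(sample(-10:10, k))
    probs <- round(as.numeric(rmultinom(1, 100, rep(1, k))) / 100, 10)
    m <- discrete_measure(support, probs)
    expect_equal(parse_measure(format_measure(m)), m)
  }
})
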