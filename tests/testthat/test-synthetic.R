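test_that("confidence distribution hits its target mean exactly", {
  for (m in c(0.3, 0.5, 0.75)) {
    w <- confidence_weights(m)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(sum(w * seq(0.1, 0.9, by = 0.1)), m, tolerance = 1e-9)
  }
  expect_error(confidence_weights(0.95), "between")
})

test_that("bird generator honours the stratum probabilities", {
  birds <- generate_birds(bird_sim_config(n_birds = 20000), seed = 41)
  juv <- birds$age == 0
  n_juv <- sum(juv); n_ad <- sum(!juv)
  expect_lt(abs(mean(birds$sex.rho1[juv]) - 0.75),
            3 * sqrt(0.75 * 0.25 / n_juv))
  expect_lt(abs(mean(birds$sex.rho1[!juv]) - 0.50),
            3 * sqrt(0.25 / n_ad))

  # protocol contracts: rho3 trivial exactly where rho2 observed
  nontrivial <- !vapply(birds$sex.rho3, is_point_mass, TRUE)
  expect_equal(nontrivial, is.na(birds$sex.rho2))
  definitive <- !nontrivial
  expect_equal(vapply(birds$sex.rho3[definitive], mean, 0),
               birds$sex.rho1[definitive])
  expect_true(all(birds$age[nontrivial] == 0))
})

test_that("identical seeds give byte-identical datasets", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_rvvm_csv(generate_birds(seed = 99), p1)
  write_rvvm_csv(generate_birds(seed = 99), p2)
  expect_identical(readLines(p1), readLines(p2))
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_rvvm_csv(generate_birds(seed = 100), p3)
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("degenerate configurations collapse to classical data", {
  birds <- generate_birds(bird_sim_config(n_birds = 200,
                                          juvenile_partial_prob = 0),
                          seed = 7)
  expect_false(anyNA(birds$sex.rho2))
  expect_true(all(vapply(birds$sex.rho3, is_point_mass, TRUE)))
})

test_that("the fixed bird example matches every published count", {
  birds <- bird_example()
  expect_equal(nrow(birds), 50L)
  expect_equal(sum(birds$age), 38)                       # adults
  expect_equal(sum(birds$sex.rho1[birds$age == 1]), 19)  # adult females
  definitive <- !is.na(birds$sex.rho2)
  expect_equal(sum(definitive), 42)
  expect_equal(sum(birds$sex.rho2, na.rm = TRUE), 23)
  def_juv <- definitive & birds$age == 0
  expect_equal(sum(def_juv), 4)
  expect_true(all(birds$sex.rho2[def_juv] == 1))

  # the eight partial confidences and their true sexes, rows 43-50
  lits <- vapply(birds$sex.rho3[43:50], format_measure, "")
  expect_equal(lits, paste0("ber:", c(0.9, 0.9, 0.8, 0.8, 0.7, 0.4, 0.3, 0.2)))
  expect_equal(birds$sex.rho1[43:50], c(1, 1, 1, 1, 1, 0, 0, 0))
  expect_equal(generalized_sum(birds$sex.rho3), 28)
  expect_identical(bird_example(), bird_example())  # deterministic
})

test_that("rating generator produces coherent categorical measures", {
  r <- generate_ratings(n_patients = 4, n_items = 17, seed = 13)
  expect_equal(nrow(r), 68L)
  expect_true(all(vapply(r$rho2, function(m)
    all(m$support %in% 0:4), TRUE)))
  # rho1 is the modal category of rho2
  modal <- vapply(r$rho2, function(m) m$support[which.max(m$probs)], 0)
  expect_gt(mean(modal == r$rho1), 0.9)

  # infinite concentration: the two protocols coincide
  r0 <- generate_ratings(n_patients = 3, n_items = 5, concentration = Inf,
                         seed = 13)
  expect_true(all(vapply(r0$rho2, is_point_mass, TRUE)))
  for (p in 1:3) {
    rows <- r0$patient == p
    expect_equal(generalized_sum(r0$rho2[rows]), sum(r0$rho1[rows]))
  }
  expect_error(generate_ratings(0), "at least 1")
})

test_that("the depressed-mood item fixture encodes the eight assessments", {
  h <- hamd_item1_example()
  expect_equal(nrow(h), 8L)
  expect_equal(h$rho1, c(1, 1, 2, 2, 1, 3, 2, 1))
  expect_equal(mean(h$rho2[[1]]), 1.5)
  expect_equal(mean(h$rho2[[2]]), 1)
  # certain and uncertain scores of "1" are distinguished by entropy
  expect_equal(variance(h$rho2[[2]]), 0)
  expect_gt(variance(h$rho2[[1]]), 0)
  # scoring: patient 6 leans more severe than the recorded category
  expect_gt(generalized_sum(h$rho2[6]), h$rho1[6])
})
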