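test_that("discoverability is v^c with validated inputs", {
  expect_equal(discoverability(1.0, 5), 1.0)
  expect_equal(discoverability(0.27, 1), 0.27)
  expect_equal(discoverability(0.27, 2), 0.0729)
  expect_equal(discoverability(0.5, disease_model(3)), 0.125)
  expect_error(discoverability(1.3, 2), "hit_rate")
  expect_error(discoverability(-0.1, 2), "hit_rate")
  expect_error(discoverability(0.5, 0.5), "complexity")
})

test_that("discoverability is monotone in v and decreasing in c below certainty", {
  set.seed(11)
  for (i in 1:50) {
    v <- sort(runif(2, 0, 1))
    c1 <- runif(1, 1, 6)
    expect_lte(discoverability(v[1], c1), discoverability(v[2], c1))
    if (v[2] < 1)
      expect_lt(discoverability(v[2], c1 + runif(1, 0.1, 3)),
                discoverability(v[2], c1))
  }
})

test_that("expected yield n v^c reproduces the worked trio-study figures", {
  expect_equal(round(expected_mechanisms(4, 0.27, 2), 2), 0.29)
  expect_equal(round(expected_mechanisms(16, 0.12, 2), 2), 0.23)
  expect_equal(expected_mechanisms(0, 0.5, 3), 0)
  expect_error(expected_mechanisms(-1, 0.5, 2), "non-negative")
})

test_that("mechanism count distribution matches exhaustive enumeration", {
  for (prm in list(c(3, 2, 0.3), c(2, 3, 0.27), c(4, 2, 0.9))) {
    md <- mechanism_distribution(prm[1], prm[3], prm[2])
    expect_equal(md$pmf, enumerate_mechanism_pmf(prm[1], prm[2], prm[3]),
                 tolerance = 1e-12)
  }
})

test_that("mechanism count distribution is a proper binomial with mean n v^c", {
  md <- mechanism_distribution(4, 0.27, 2)
  expect_true(all(md$pmf >= 0))
  expect_equal(sum(md$pmf), 1, tolerance = 1e-12)
  expect_equal(md$mean, sum(md$support * md$pmf), tolerance = 1e-12)
  expect_equal(md$mean, expected_mechanisms(4, 0.27, 2), tolerance = 1e-12)
  expect_equal(md$mean, 0.2916, tolerance = 1e-12)

  # tail by complement rule and by summation
  expect_equal(prob_at_least(md, 1), 1 - (1 - 0.0729)^4, tolerance = 1e-12)
  expect_equal(prob_at_least(md, 2), sum(md$pmf[3:5]), tolerance = 1e-12)
  expect_equal(prob_at_least(md, 0), 1)

  certain <- mechanism_distribution(1, 1.0, 1)
  expect_equal(certain$pmf, c(0, 1))
  expect_error(mechanism_distribution(2.5, 0.5, 2), "integer")
})

test_that("assay utility is v^c / P and scale-free for ranking", {
  expect_equal(assay_utility(assay("WES", 0.27, 4), disease_model(2)),
               0.018225)
  expect_equal(assay_utility(assay("chip", 0.12, 1), 2), 0.0144)
  expect_equal(assay_utility(assay("ideal", 1, 1), 1), 1)
  expect_error(assay("bad", 0.5, 0), "positive")

  # rescaling every price by a constant leaves utility ratios unchanged
  u1 <- assay_utility(assay("a", 0.3, 2), 2) /
    assay_utility(assay("b", 0.2, 1), 2)
  u2 <- assay_utility(assay("a", 0.3, 2 * 7.3), 2) /
    assay_utility(assay("b", 0.2, 1 * 7.3), 2)
  expect_equal(u1, u2, tolerance = 1e-12)
})

test_that("equivalent price ratio is (v2/v1)^c and reciprocal", {
  expect_equal(equivalent_price_ratio(0.3, 0.3, 4), 1.0)
  expect_equal(equivalent_price_ratio(0.27, 0.54, 2), 4.0)
  expect_equal(equivalent_price_ratio(0.1, 0.2, 3), 8.0)
  expect_error(equivalent_price_ratio(0, 0.5, 2), "positive")

  set.seed(21)
  for (i in 1:25) {
    v <- runif(2, 0.05, 1)
    cc <- runif(1, 1, 5)
    expect_equal(equivalent_price_ratio(v[1], v[2], cc) *
                   equivalent_price_ratio(v[2], v[1], cc),
                 1, tolerance = 1e-12)
  }
})

test_that("combining assays adds hit rates and prices, minus overlap", {
  combo <- combine_assays(list(assay("WES", 0.27, 4), assay("chip", 0.12, 1)))
  expect_equal(combo$hit_rate, 0.39)
  expect_equal(combo$price, 5)
  expect_equal(combo$name, "WES+chip")

  single <- combine_assays(list(assay("WES", 0.5, 4)))
  expect_equal(single$hit_rate, 0.5)
  expect_equal(single$price, 4)

  lapped <- combine_assays(list(assay("a", 0.5, 1), assay("b", 0.4, 1)),
                           overlap = 0.2)
  expect_equal(lapped$hit_rate, 0.7)

  expect_error(combine_assays(list(assay("a", 0.7, 1), assay("b", 0.6, 1))),
               "infeasible")
  expect_error(combine_assays(list()), "non-empty")
})
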