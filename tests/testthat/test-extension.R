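example2_scenario <- function() {
  extension_scenario(n = 4, hit_rate = 0.27, price_A = 4, price_B = 1,
                     complexity = 2, extra_hit_rate = 0.12)
}

test_that("scenario construction validates and combines hit rates", {
  sc <- example2_scenario()
  expect_equal(sc$augmented_hit_rate, 0.39)
  expect_equal(sc$budget, 4)  # defaults to the cost of strategy B

  direct <- extension_scenario(4, 0.27, 4, 1, 2, augmented_hit_rate = 0.39)
  expect_equal(direct$augmented_hit_rate, sc$augmented_hit_rate)

  expect_error(extension_scenario(4, 0.27, 4, 1, 2,
                                  augmented_hit_rate = 0.2), "lose coverage")
  expect_error(extension_scenario(4, 0.27, 4, 1, 2), "exactly one")
  expect_error(extension_scenario(4, 0.27, 4, 1, 2, augmented_hit_rate = 0.39,
                                  extra_hit_rate = 0.12), "exactly one")
  expect_error(extension_scenario(0, 0.27, 4, 1, 2,
                                  augmented_hit_rate = 0.39), "integer")
  expect_error(extension_scenario(4, 0.7, 4, 1, 2, extra_hit_rate = 0.6),
               "infeasible")
})

test_that("adding a fifth trio loses to re-assaying the existing four", {
  verdict <- extension_yields(example2_scenario())
  expect_equal(verdict$n_A, 5)
  expect_equal(round(verdict$yield_A, 3), 0.365)
  expect_equal(round(verdict$yield_B, 2), 0.61)
  expect_equal(verdict$yield_A, 0.3645, tolerance = 1e-12)
  expect_equal(verdict$yield_B, 0.6084, tolerance = 1e-12)
  expect_equal(verdict$favoured, "B")
  expect_equal(as.numeric(verdict$breakeven_delta), 0.27 * (sqrt(1.25) - 1),
               tolerance = 1e-12)
  expect_true(attr(verdict$breakeven_base_hit_rate, "infeasible"))
})

test_that("a redundant additional assay can only favour more subjects", {
  sc <- extension_scenario(4, 0.3, 2, 1, 2, augmented_hit_rate = 0.3,
                           budget = 4)
  verdict <- extension_yields(sc)
  expect_equal(verdict$yield_B, 4 * 0.3^2)  # the original study's yield
  expect_equal(verdict$favoured, "A")

  # budget too small to buy a case-unit or re-assay: flagged infeasible
  stuck <- extension_yields(extension_scenario(
    4, 0.3, 10, 2, 2, augmented_hit_rate = 0.35, budget = 1))
  expect_equal(stuck$favoured, "infeasible")
  expect_length(stuck$feasibility_notes, 2)

  # strategy B unaffordable but A affordable
  a_only <- extension_yields(extension_scenario(
    4, 0.3, 1, 2, 2, augmented_hit_rate = 0.9, budget = 2))
  expect_equal(a_only$favoured, "A")
})

test_that("the two strategies tie exactly on the equal-budget boundary", {
  set.seed(51)
  for (i in 1:25) {
    v <- runif(1, 0.1, 0.6)
    cc <- runif(1, 1, 5)
    p_A <- runif(1, 0.5, 5)
    p_B <- runif(1, 0.1, 2)
    v_B <- v * equivalence_hit_ratio(p_B, p_A, cc)
    if (v_B > 1) next
    n <- sample(2:20, 1)
    sc <- extension_scenario(n, v, p_A, p_B, cc, augmented_hit_rate = v_B,
                             budget = n * p_B)
    verdict <- extension_yields(sc, continuous_n = TRUE)
    expect_equal(verdict$yield_A, verdict$yield_B, tolerance = 1e-12)
    expect_equal(verdict$favoured, "equivalent")
  }
})

test_that("sample-size ratio to match re-assaying is (v_B/v)^c", {
  expect_equal(extension_sample_ratio(0.27, 0.27, 3), 1.0)
  expect_equal(extension_sample_ratio(0.27, 0.39, 2), (0.39 / 0.27)^2,
               tolerance = 1e-12)
  expect_equal(extension_sample_ratio(0.2, 0.4, 3), 8.0)
  expect_error(extension_sample_ratio(0, 0.4, 2), "positive")
})

test_that("equivalence hit ratio falls with complexity towards 1", {
  expect_equal(equivalence_hit_ratio(1, 4, 2), sqrt(1.25), tolerance = 1e-12)
  expect_equal(equivalence_hit_ratio(2, 2, 1), 2.0)
  expect_equal(equivalence_hit_ratio(1e-12, 4, 2), 1.0, tolerance = 1e-9)
  expect_equal(equivalence_hit_ratio(1, 4, Inf), 1.0)
  expect_error(equivalence_hit_ratio(0, 4, 2), "positive")

  ratios <- vapply(c(1, 2, 4, 8, 32), equivalence_hit_ratio,
                   numeric(1), price_B = 1, price_A = 4)
  expect_true(all(diff(ratios) < 0))
  expect_true(all(ratios > 1))
})

test_that("breakeven increment and required base hit rate invert each other", {
  delta <- min_extra_hit_rate(0.27, 1, 4, 2)
  expect_equal(round(as.numeric(delta), 3), 0.032)
  expect_false(attr(delta, "infeasible"))

  expect_equal(as.numeric(min_extra_hit_rate(0.4, 1e-12, 4, 2)), 0,
               tolerance = 1e-12)

  huge <- min_extra_hit_rate(0.5, 3, 1, 1)
  expect_equal(as.numeric(huge), 1.5)
  expect_true(attr(huge, "infeasible"))

  req <- required_base_hit_rate(0.12, 1, 4, 2)
  expect_equal(round(as.numeric(req), 2), 1.02)
  expect_true(attr(req, "infeasible"))
  expect_equal(as.numeric(required_base_hit_rate(0, 1, 4, 2)), 0)

  set.seed(61)
  for (i in 1:50) {
    v <- runif(1, 0.01, 0.99)
    cc <- runif(1, 1, 6)
    p_A <- runif(1, 0.1, 10)
    p_B <- runif(1, 0.1, 10)
    back <- required_base_hit_rate(as.numeric(
      min_extra_hit_rate(v, p_B, p_A, cc)), p_B, p_A, cc)
    expect_equal(as.numeric(back), v, tolerance = 1e-12)
  }
})

test_that("partition labels match the direct yield comparison everywhere", {
  pg <- partition_parameter_space(c(0.05, 2), c(0.8, 2.2),
                                  complexities = c(1, 2, 4),
                                  resolution = 17)
  for (i in seq_len(nrow(pg))) {
    expected <- if (pg$hit_ratio[i] < 1) "infeasible"
      else direct_favoured(pg$price_ratio[i], pg$hit_ratio[i],
                           pg$complexity[i])
    expect_identical(pg$label[i], expected)
  }
})

test_that("partition geometry: worked-example point, no-gain line, infinity", {
  pg <- partition_parameter_space(c(0.25, 2), c(1, 1.444444),
                                  complexities = c(2, Inf), resolution = 10)
  # the chip-genotyping extension point lies in strategy-B territory
  corner <- pg[pg$price_ratio == 0.25 &
                 abs(pg$hit_ratio - 1.444444) < 1e-9 & pg$complexity == 2, ]
  expect_equal(corner$label, "B")
  # v_B/v = 1 with a positive price buys nothing: strategy A for finite c
  expect_true(all(pg$label[pg$hit_ratio == 1 & pg$complexity == 2] == "A"))
  # at infinite complexity any true gain wins and the boundary is the line 1
  expect_true(all(pg$label[pg$hit_ratio > 1 & pg$complexity == Inf] == "B"))
  expect_true(all(pg$label[pg$hit_ratio == 1 & pg$complexity == Inf] ==
                    "equivalent"))
  bnd <- attr(pg, "boundary")
  expect_true(all(bnd$hit_ratio[bnd$complexity == Inf] == 1))

  expect_error(partition_parameter_space(c(2, 1), c(1, 2), 2), "increasing")
  expect_error(partition_parameter_space(c(1, 2), c(1, 2), 2,
                                         resolution = 1), "resolution")
  expect_error(partition_parameter_space(c(1, 2), c(1, 2), 0.5), "complexities")
})

test_that("verdicts on the boundary do not depend on the sample size", {
  for (n in c(2, 5, 40)) {
    v_B <- 0.3 * equivalence_hit_ratio(1, 4, 2)
    sc <- extension_scenario(n, 0.3, 4, 1, 2, augmented_hit_rate = v_B,
                             budget = n * 1)
    expect_equal(extension_yields(sc, continuous_n = TRUE)$favoured,
                 "equivalent")
  }
})
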