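test_that("the health impact function matches hand arithmetic", {
  expect_equal(attributable_cases(0, 0.011, 0.008, 1e6), 0)
  # 1e6 * 0.008 * (1 - exp(-0.011 * 0.17))
  expect_equal(attributable_cases(0.17, 0.011, 0.008, 1e6), 14.946021,
               tolerance = 1e-7)
  expect_error(attributable_cases(-0.1, 0.011, 0.008, 1e6), ">= 0")
  expect_error(attributable_cases(0.1, 0.011, 1.5, 1e6), "\\[0, 1\\]")
})

test_that("cases are bounded by baseline deaths and near-linear in beta*dC", {
  grid <- expand.grid(beta = c(1e-4, 0.006, 0.011, 0.015),
                      dc = c(0.01, 0.05, 0.17, 0.3, 0.6))
  rate <- 0.008
  pop <- 1e6
  cases <- attributable_cases(grid$dc, grid$beta, rate, pop)
  expect_true(all(cases >= 0 & cases <= rate * pop))
  linear <- rate * grid$beta * grid$dc * pop
  rel_err <- abs(cases - linear) / linear
  expect_true(all(rel_err <= grid$beta * grid$dc / 2))
})

test_that("cases increase in every positive argument", {
  base <- attributable_cases(0.2, 0.01, 0.008, 1e5)
  expect_gt(attributable_cases(0.3, 0.01, 0.008, 1e5), base)
  expect_gt(attributable_cases(0.2, 0.02, 0.008, 1e5), base)
  expect_gt(attributable_cases(0.2, 0.01, 0.009, 1e5), base)
  expect_gt(attributable_cases(0.2, 0.01, 0.008, 2e5), base)
})

test_that("impact_field is additive, null at zero field, and strict on ids", {
  cf <- default_crf_set()$expert_elicitation
  ut <- make_unit_table(c(0.17, 0.17))
  imp <- impact_field(ut$field, ut$pop, cf)
  expect_equal(sum(imp$cases), 2 * imp$cases[1])
  zero <- make_unit_table(c(0, 0))
  expect_equal(sum(impact_field(zero$field, zero$pop, cf)$cases), 0)
  broken <- ut$pop[1, ]
  expect_error(impact_field(ut$field, broken, cf), "u002")
})

test_that("doubling a small beta nearly doubles national cases", {
  ut <- make_unit_table(seq(0.05, 0.25, length.out = 20))
  c1 <- sum(impact_field(ut$field, ut$pop, crf("a", 0.005))$cases)
  c2 <- sum(impact_field(ut$field, ut$pop, crf("b", 0.010))$cases)
  expect_equal(c2 / c1, 2, tolerance = 0.01)
})

test_that("unit totals are independent of row order", {
  cf <- default_crf_set()$six_cities
  ut <- make_unit_table(seq(0.02, 0.3, length.out = 15))
  shuffle <- sample(15)
  imp1 <- impact_field(ut$field, ut$pop, cf)
  imp2 <- impact_field(ut$field[shuffle, ], ut$pop, cf)
  expect_equal(sum(imp1$cases), sum(imp2$cases), tolerance = 1e-12)
  agg <- aggregate_impacts(imp1, "national")
  expect_equal(agg$cases_central, sum(imp1$cases))
})

test_that("degenerate CRF distributions collapse the percentiles", {
  ut <- make_unit_table(c(0.1, 0.2))
  point <- crf("pt", 0.011)
  expect_message(
    res <- propagate_uncertainty(ut$field, ut$pop, point, n_draws = 200,
                                 seed = 1),
    "[Dd]egenerate")
  expect_equal(res$cases_p5, res$cases_central)
  expect_equal(res$cases_p95, res$cases_central)
  degen <- crf("zero_se", 0.011, beta_se = 0, distribution = "normal")
  expect_message(
    res2 <- propagate_uncertainty(ut$field, ut$pop, degen, n_draws = 200,
                                  seed = 1),
    "[Dd]egenerate")
  expect_equal(res2$cases_p5, res2$cases_p95)
})

test_that("normal-beta percentiles match the analytic near-linear oracle", {
  # narrow se keeps truncation negligible and the case mapping linear,
  # so percentiles scale as (beta +/- 1.645 se) / beta
  ut <- make_unit_table(seq(0.05, 0.25, length.out = 20))
  cf <- crf("narrow", beta = 0.011, beta_se = 0.002,
            distribution = "normal")
  res <- propagate_uncertainty(ut$field, ut$pop, cf, n_draws = 10000,
                               seed = 9)
  z <- qnorm(0.95)
  expected_p5 <- res$cases_central * (0.011 - z * 0.002) / 0.011
  expected_p95 <- res$cases_central * (0.011 + z * 0.002) / 0.011
  # Monte-Carlo error of an empirical quantile: 3 * asymptotic se
  mc_se <- function(p) {
    q <- qnorm(p, 0.011, 0.002)
    sqrt(p * (1 - p) / 10000) / dnorm(q, 0.011, 0.002) / 0.011 *
      res$cases_central
  }
  expect_lt(abs(res$cases_p5 - expected_p5), 3 * mc_se(0.05))
  expect_lt(abs(res$cases_p95 - expected_p95), 3 * mc_se(0.95))
  expect_true(res$cases_p5 <= res$cases_central &&
                res$cases_central <= res$cases_p95)
})

test_that("percentiles converge with the number of draws", {
  ut <- make_unit_table(seq(0.05, 0.25, length.out = 10))
  cf <- default_crf_set()$expert_elicitation
  r1 <- propagate_uncertainty(ut$field, ut$pop, cf, n_draws = 10000,
                              seed = 5)
  r2 <- propagate_uncertainty(ut$field, ut$pop, cf, n_draws = 100000,
                              seed = 6)
  expect_equal(r1$cases_p5, r2$cases_p5, tolerance = 0.02)
  expect_equal(r1$cases_p95, r2$cases_p95, tolerance = 0.02)
})

test_that("uncertainty propagation is bit-reproducible under a fixed seed", {
  ut <- make_unit_table(c(0.1, 0.2, 0.3))
  cf <- default_crf_set()$acs_cohort
  r1 <- propagate_uncertainty(ut$field, ut$pop, cf, n_draws = 500, seed = 8)
  r2 <- propagate_uncertainty(ut$field, ut$pop, cf, n_draws = 500, seed = 8)
  expect_identical(r1, r2)
})

test_that("CRF constructors validate their parameters", {
  expect_error(crf("bad", -0.01), ">= 0")
  expect_error(crf("bad", 0.01, beta_p5 = 0.02, beta_p95 = 0.03,
                   distribution = "normal"), "beta_p5 <= beta")
  expect_error(crf("bad", 0.01, distribution = "normal"),
               "needs `beta_se`")
  # se back-solved from the 5th-95th spread
  cf <- crf("ok", 0.011, beta_p5 = 0.003, beta_p95 = 0.02,
            distribution = "normal")
  expect_equal(cf$beta_se, (0.02 - 0.003) / (2 * qnorm(0.95)))
  expect_equal(length(default_crf_set()), 4)
  expect_equal(vapply(default_crf_set(), `[[`, numeric(1), "beta"),
               c(six_cities = 0.015, acs_cohort = 0.006,
                 acs_refined = 0.006, expert_elicitation = 0.011))
})
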