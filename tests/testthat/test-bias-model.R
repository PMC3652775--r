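test_that("identity data yields the identity fit", {
  fit <- fit_bias_model(make_identity_pairs())
  expect_lt(abs(fit$fixed_slope - 1), 1e-6)
  expect_lt(abs(fit$fixed_intercept), 1e-6)
  expect_true(all(abs(fit$region_slopes) < 1e-6))
  expect_lt(fit$residual_variance, 1e-6)
})

test_that("REML fit matches the grid-search profile-likelihood oracle", {
  pairs <- toy_pairs()
  fit <- fit_bias_model(pairs)
  oracle <- reml_grid_oracle(pairs)
  # agreement to 3 significant figures on every estimated quantity
  expect_equal(fit$fixed_intercept, oracle$beta[1], tolerance = 1e-3)
  expect_equal(fit$fixed_slope, oracle$beta[2], tolerance = 1e-3)
  expect_equal(unname(fit$region_slopes[names(oracle$u)]),
               unname(oracle$u), tolerance = 1e-3)
  expect_equal(fit$residual_variance, oracle$s2, tolerance = 1e-3)
})

test_that("REML fit agrees with an independent mixed-model implementation", {
  tr <- synthetic_truth(obs_noise_sd = 0.05)
  m <- generate_monitors(generate_field(tr, 200, seed = 41), tr, 90,
                         seed = 42)
  fit <- fit_bias_model(m)
  lf <- lme4::lmer(observed_value ~ model_value + (0 + model_value | region),
                   data = m, REML = TRUE)
  expect_equal(fit$fixed_intercept, unname(lme4::fixef(lf)[1]),
               tolerance = 1e-6)
  expect_equal(fit$fixed_slope, unname(lme4::fixef(lf)[2]),
               tolerance = 1e-6)
  u_lme4 <- lme4::ranef(lf)$region
  expect_equal(unname(fit$region_slopes[rownames(u_lme4)]),
               u_lme4[, 1], tolerance = 1e-5)
  expect_equal(unname(fit$standard_errors),
               unname(sqrt(diag(as.matrix(vcov(lf))))), tolerance = 1e-6)
})

test_that("fits are invariant to input row order", {
  pairs <- toy_pairs()
  shuffled <- pairs[c(7, 2, 11, 4, 9, 6, 1, 12, 3, 10, 5, 8), ]
  f1 <- fit_bias_model(pairs)
  f2 <- fit_bias_model(shuffled)
  expect_identical(f1$fixed_slope, f2$fixed_slope)
  expect_identical(f1$region_slopes, f2$region_slopes)
})

test_that("single-region input falls back to OLS with a warning", {
  pairs <- make_identity_pairs(6)
  eps <- c(0.003, -0.002, 0.001, -0.003, 0.002, -0.001)
  pairs$observed_value <- 0.01 + 2 * pairs$model_value + rep(eps, 3)
  one <- pairs[as.character(pairs$region) == "South", ]
  expect_warning(fit <- fit_bias_model(one), "OLS")
  expect_equal(fit$method, "OLS")
  ols <- lm(observed_value ~ model_value, data = one)
  expect_equal(fit$fixed_slope, unname(coef(ols)[2]), tolerance = 1e-8)
  expect_equal(unname(fit$region_slopes), 0)
})

test_that("degenerate designs are rejected", {
  pairs <- make_identity_pairs()
  pairs$model_value <- 0.05
  expect_error(fit_bias_model(pairs), "[Dd]egenerate")
  expect_error(fit_bias_model(make_identity_pairs(1)), "at least 3")
})

test_that("forcing the slope variance to zero recovers pooled OLS", {
  pairs <- toy_pairs()
  fit0 <- fit_bias_model(pairs, fix_lambda = 0)
  ols <- lm(observed_value ~ model_value, data = pairs)
  expect_equal(fit0$fixed_intercept, unname(coef(ols)[1]),
               tolerance = 1e-6)
  expect_equal(fit0$fixed_slope, unname(coef(ols)[2]), tolerance = 1e-6)
  eq <- suppressMessages(compose_adjustments(fit0))
  expect_true(all(abs(eq$slope - coef(ols)[2]) < 1e-6))
})

test_that("composed slopes shrink toward per-region OLS as data grow", {
  tr <- synthetic_truth(obs_noise_sd = 0.02)
  gap <- function(n_sites) {
    f <- generate_field(tr, 2 * n_sites, seed = 51)
    m <- generate_monitors(f, tr, n_sites, seed = 52)
    fit <- fit_bias_model(m)
    eq <- suppressMessages(compose_adjustments(fit))
    est <- setNames(eq$slope, as.character(eq$region))
    ols <- vapply(region_levels(), function(rg) {
      coef(lm(observed_value ~ model_value,
              data = m[as.character(m$region) == rg, ]))[["model_value"]]
    }, numeric(1))
    max(abs(est[region_levels()] - ols))
  }
  expect_lt(gap(600), gap(30) + 1e-9)
  expect_lt(gap(600), 0.01)
})

test_that("composition reproduces the published adjustment equations", {
  eq <- compose_adjustments(reference_bias_fit())
  expect_equal(eq$intercept, rep(0.01875, 3))
  expect_equal(eq$slope, c(3.016, 1.627, 1.04), tolerance = 1e-12)

  flat <- list(fixed_intercept = 0.1, fixed_slope = 2,
               region_slopes = c(MidwestEast = 0, South = 0, West = 0))
  expect_equal(compose_adjustments(flat)$slope, rep(2, 3))

  boundary <- list(fixed_intercept = 0, fixed_slope = 2,
                   region_slopes = c(MidwestEast = -2, South = 0, West = 0))
  expect_message(eqb <- compose_adjustments(boundary), "[Nn]on-positive")
  expect_equal(eqb$slope[eqb$region == "MidwestEast"], 0)

  partial <- list(fixed_intercept = 0, fixed_slope = 1,
                  region_slopes = c(South = 0.5))
  expect_warning(eqp <- compose_adjustments(partial), "zero random slope")
  expect_equal(eqp$slope[eqp$region == "West"], 1)
})

test_that("adjustment equations transform fields as published", {
  eq <- compose_adjustments(reference_bias_fit())
  ut <- make_unit_table(c(0.052, 0), state = "OH")
  adj <- apply_adjustment(ut$field, eq)
  expect_equal(adj$conc[1], 0.175582, tolerance = 1e-9)
  expect_equal(adj$conc[2], 0.01875)  # intercept floor at zero input
  expect_true(all(adj$stage == "adjusted"))
})

test_that("adjustment preserves within-region concentration order", {
  eq <- compose_adjustments(reference_bias_fit())
  tr <- synthetic_truth()
  f <- generate_field(tr, 300, seed = 61)
  adj <- apply_adjustment(f, eq)
  for (rg in region_levels()) {
    idx <- as.character(f$region) == rg
    expect_identical(order(f$conc[idx]), order(adj$conc[idx]))
  }
})

test_that("fields with unmapped regions are rejected by name", {
  eq <- compose_adjustments(reference_bias_fit())[1:2, ]
  ut <- make_unit_table(c(0.1, 0.2), state = "CA")  # West, dropped above
  expect_error(apply_adjustment(ut$field, eq), "West")
  expect_error(apply_adjustment(ut$field, eq), "u001")
})

test_that("a fitted model round-trips through disk exactly", {
  fit <- fit_bias_model(toy_pairs())
  path <- withr::local_tempfile(fileext = ".csv")
  write_bias_fit(fit, path)
  back <- read_bias_fit(path)
  expect_identical(back$fixed_intercept, fit$fixed_intercept)
  expect_identical(back$fixed_slope, fit$fixed_slope)
  expect_identical(back$region_slopes, fit$region_slopes)
  expect_identical(back$slope_variance, fit$slope_variance)
  expect_identical(back$residual_variance, fit$residual_variance)
  expect_identical(unname(back$standard_errors),
                   unname(fit$standard_errors))
  expect_identical(back$n_obs, fit$n_obs)
  expect_identical(back$method, fit$method)
})

test_that("tidy and glance summarise the fit", {
  fit <- fit_bias_model(toy_pairs())
  td <- tidy(fit)
  expect_equal(nrow(td), 5)
  expect_setequal(td$type, c("fixed", "random"))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 12L)
  expect_equal(gl$method, "REML")
})
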