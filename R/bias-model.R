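# Random-slope mixed model for air-quality model bias correction.
#
# Observed aromatic SOA at monitor i in region r:
#   obs_ri = b0 + (b1 + u_r) * model_ri + e_ri,
#   u_r ~ N(0, sigma_u^2), e_ri ~ N(0, sigma_e^2)
# i.e. a fixed intercept and slope with a random slope per region and no
# random intercept (the published fit reports region intercept effects of
# exactly 0). Estimation is REML: the restricted likelihood is profiled over
# the variance ratio lambda = sigma_u^2 / sigma_e^2 with a bounded scalar
# optimizer. Because the random-effects design is block diagonal with one
# rank-one block per region, V_r = I + lambda * x_r x_r', every quantity has
# a Sherman-Morrison closed form and the profile evaluation is O(n).

# sufficient statistics of the profiled restricted likelihood at a given
# lambda; X = [1, x], grouping g (character), response y
reml_profile <- function(lambda, x, y, g) {
  groups <- unique(g)
  A <- matrix(0, 2, 2)      # X' V^-1 X
  b <- numeric(2)           # X' V^-1 y
  yVy <- 0
  logdetV <- 0
  for (rg in groups) {
    idx <- g == rg
    xr <- x[idx]
    yr <- y[idx]
    Xr <- cbind(1, xr)
    Sr <- sum(xr^2)
    cr <- 1 + lambda * Sr
    Xx <- c(sum(xr), Sr)    # X_r' x_r
    A <- A + crossprod(Xr) - (lambda / cr) * tcrossprod(Xx)
    xy <- sum(xr * yr)
    b <- b + c(sum(yr), xy) - (lambda / cr) * Xx * xy
    yVy <- yVy + sum(yr^2) - (lambda / cr) * xy^2
    logdetV <- logdetV + log(cr)
  }
  beta <- solve(A, b)
  q <- yVy - 2 * sum(b * beta) + drop(t(beta) %*% A %*% beta)
  q <- max(q, 0)
  n <- length(y)
  sigma2_e <- q / (n - 2)
  # restricted log-likelihood up to an additive constant
  crit <- (n - 2) * log(max(sigma2_e, .Machine$double.xmin)) +
    logdetV + determinant(A, logarithm = TRUE)$modulus[1]
  list(crit = crit, beta = beta, sigma2_e = sigma2_e, A = A)
}

# BLUPs of the per-region slope deviations at the REML solution
reml_blups <- function(lambda, x, y, g, beta) {
  groups <- unique(g)
  u <- setNames(numeric(length(groups)), groups)
  for (rg in groups) {
    idx <- g == rg
    xr <- x[idx]
    resid <- y[idx] - beta[1] - beta[2] * xr
    cr <- 1 + lambda * sum(xr^2)
    u[rg] <- lambda * sum(xr * resid) / cr
  }
  u
}

#' Fit the random-slope bias-correction model
#'
#' Regresses observed aromatic-SOA concentrations on co-located model values
#' with a fixed intercept and slope and a REML-estimated random slope for
#' each region (random intercepts constrained to zero). Input rows are
#' canonicalized (sorted by site then month) before fitting so the result is
#' permutation-invariant. With a single region the model degenerates and the
#' fit falls back to ordinary least squares with zero random effects (a
#' warning is issued).
#'
#' @param pairs A tibble of monitor pairs with columns `region`,
#'   `model_value`, `observed_value` (and optionally `site_id`, `month` used
#'   for canonical ordering), as produced by [generate_monitors()].
#' @param reml_tol Convergence tolerance of the scalar profile optimization.
#' @param max_log_lambda Upper search bound on `log(lambda)` where `lambda`
#'   is the slope-variance to residual-variance ratio.
#' @param fix_lambda Optional non-negative value at which to fix the
#'   variance ratio instead of estimating it; `fix_lambda = 0` collapses the
#'   model to the pooled ordinary-least-squares line.
#'
#' @return An object of class `bias_fit`: a list with elements
#'   `fixed_intercept`, `fixed_slope`, `region_slopes` (named BLUPs),
#'   `slope_variance`, `residual_variance`, `standard_errors`, `n_obs`,
#'   `lambda`, `method`, and the canonicalized `data`.
#' @export
#' @examples
#' tr <- synthetic_truth(obs_noise_sd = 0.02)
#' mons <- generate_monitors(generate_field(tr, 300), tr, n_sites = 150)
#' fit <- fit_bias_model(mons)
#' fit
fit_bias_model <- function(pairs, reml_tol = 1e-8, max_log_lambda = 30,
                           fix_lambda = NULL) {
  pairs <- validate_pairs(pairs)
  x <- pairs$model_value
  y <- pairs$observed_value
  g <- as.character(pairs$region)
  groups <- unique(g)
  n <- length(y)

  if (any(vapply(groups, function(rg) sd(x[g == rg]) == 0, logical(1)))) {
    abort("Degenerate design: model values are constant within a region.")
  }

  if (length(groups) < 2) {
    warn("Only one region represented; falling back to pooled OLS with zero random effects.")
    ols <- lm(y ~ x)
    s <- summary(ols)
    return(new_bias_fit(
      beta = coef(ols),
      u = setNames(0, groups),
      sigma2_u = 0,
      sigma2_e = s$sigma^2,
      se = s$coefficients[, "Std. Error"],
      n_obs = n, lambda = 0, method = "OLS", data = pairs
    ))
  }

  if (!is.null(fix_lambda)) {
    if (fix_lambda < 0) abort("`fix_lambda` must be >= 0.")
    lambda <- fix_lambda
    best <- reml_profile(lambda, x, y, g)
  } else {
    obj <- function(ll) reml_profile(exp(ll), x, y, g)$crit
    opt <- optimize(obj, interval = c(-30, max_log_lambda), tol = reml_tol)
    lambda <- exp(opt$minimum)
    # variance components are floored at zero: keep the boundary fit if it
    # is at least as good as the interior optimum
    at0 <- reml_profile(0, x, y, g)
    best <- reml_profile(lambda, x, y, g)
    if (at0$crit <= best$crit) {
      lambda <- 0
      best <- at0
    }
  }
  beta <- best$beta
  u <- reml_blups(lambda, x, y, g, beta)
  se <- sqrt(diag(solve(best$A)) * best$sigma2_e)
  new_bias_fit(
    beta = beta,
    u = u,
    sigma2_u = lambda * best$sigma2_e,
    sigma2_e = best$sigma2_e,
    se = setNames(se, c("(Intercept)", "model_value")),
    n_obs = n, lambda = lambda, method = "REML", data = pairs
  )
}

validate_pairs <- function(pairs) {
  if (!is.data.frame(pairs)) abort("`pairs` must be a data frame.")
  needed <- c("region", "model_value", "observed_value")
  missing_cols <- setdiff(needed, names(pairs))
  if (length(missing_cols) > 0) {
    abort(paste0("`pairs` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  pairs <- as_tibble(pairs)
  if (nrow(pairs) < 3) abort("Need at least 3 monitor pairs.")
  if (any(!is.finite(pairs$model_value)) ||
      any(!is.finite(pairs$observed_value))) {
    abort("Model and observed values must be finite.")
  }
  if (any(pairs$model_value < 0) || any(pairs$observed_value < 0)) {
    abort("Model and observed values must be non-negative.")
  }
  bad_rg <- setdiff(unique(as.character(pairs$region)), region_levels())
  if (length(bad_rg) > 0) {
    abort(paste0("Unknown region(s): ", paste(bad_rg, collapse = ", ")))
  }
  per_region <- table(as.character(pairs$region))
  if (any(per_region < 3)) {
    abort("Each represented region needs at least 3 monitor pairs.")
  }
  # canonical ordering: permutation-invariant fits
  if (all(c("site_id", "month") %in% names(pairs))) {
    pairs <- arrange(pairs, .data$site_id, .data$month)
  } else {
    pairs <- arrange(pairs, as.character(.data$region), .data$model_value,
                     .data$observed_value)
  }
  pairs
}

new_bias_fit <- function(beta, u, sigma2_u, sigma2_e, se, n_obs, lambda,
                         method, data) {
  structure(
    list(
      fixed_intercept = unname(beta[1]),
      fixed_slope = unname(beta[2]),
      region_slopes = u,
      slope_variance = sigma2_u,
      residual_variance = sigma2_e,
      standard_errors = se,
      n_obs = n_obs,
      lambda = lambda,
      method = method,
      data = data
    ),
    class = "bias_fit"
  )
}

#' @export
print.bias_fit <- function(x, ...) {
  cat(sprintf("<bias_fit> %s, n = %d\n", x$method, x$n_obs))
  cat(sprintf("  fixed: intercept %.5g (se %.3g), slope %.5g (se %.3g)\n",
              x$fixed_intercept, x$standard_errors[1],
              x$fixed_slope, x$standard_errors[2]))
  cat("  random slope offsets:",
      paste(sprintf("%s %+.4g", names(x$region_slopes), x$region_slopes),
            collapse = ", "), "\n")
  cat(sprintf("  slope variance %.4g, residual variance %.4g\n",
              x$slope_variance, x$residual_variance))
  invisible(x)
}

#' Tidy a bias-correction model fit
#'
#' @param x A `bias_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per model term (fixed effects and per-region
#'   random slope offsets), columns `term`, `estimate`, `std_error`, `type`.
#' @export
tidy.bias_fit <- function(x, ...) {
  bind_rows(
    tibble(term = c("(Intercept)", "model_value"),
           estimate = c(x$fixed_intercept, x$fixed_slope),
           std_error = unname(x$standard_errors),
           type = "fixed"),
    tibble(term = paste0("slope_", names(x$region_slopes)),
           estimate = unname(x$region_slopes),
           std_error = NA_real_,
           type = "random")
  )
}

#' Glance at a bias-correction model fit
#'
#' @param x A `bias_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `n_obs`, `n_regions`, `method`,
#'   `slope_variance`, `residual_variance`, `lambda`.
#' @export
glance.bias_fit <- function(x, ...) {
  tibble(
    n_obs = x$n_obs,
    n_regions = length(x$region_slopes),
    method = x$method,
    slope_variance = x$slope_variance,
    residual_variance = x$residual_variance,
    lambda = x$lambda
  )
}

#' Compose per-region adjustment equations from a fitted bias model
#'
#' Each region's adjustment line has the fixed intercept and a slope equal to
#' the fixed slope plus that region's random-slope BLUP. Regions absent from
#' the fit receive a zero offset (with a warning); composed slopes that are
#' not positive are flagged with a message but kept.
#'
#' @param fit A `bias_fit`, or a list with elements `fixed_intercept`,
#'   `fixed_slope`, `region_slopes`.
#' @return A tibble with columns `region`, `intercept`, `slope`.
#' @export
#' @examples
#' fit <- list(fixed_intercept = 0.01875, fixed_slope = 1.896,
#'             region_slopes = c(MidwestEast = 1.12, South = -0.269,
#'                               West = -0.856))
#' compose_adjustments(fit)
compose_adjustments <- function(fit) {
  u <- fit$region_slopes
  missing_rg <- setdiff(region_levels(), names(u))
  if (length(missing_rg) > 0) {
    warn(paste0("Region(s) absent from fit get zero random slope: ",
                paste(missing_rg, collapse = ", ")))
    u[missing_rg] <- 0
  }
  eq <- tibble(
    region = factor(region_levels(), levels = region_levels()),
    intercept = fit$fixed_intercept,
    slope = fit$fixed_slope + unname(u[region_levels()])
  )
  nonpos <- eq$region[eq$slope <= 0]
  if (length(nonpos) > 0) {
    inform(paste0("Non-positive composed slope for region(s): ",
                  paste(nonpos, collapse = ", ")))
  }
  eq
}

#' Apply regional adjustment equations to a concentration field
#'
#' Replaces each unit's concentration by
#' `max(0, intercept + slope * concentration)` using its region's equation,
#' correcting the model's region-dependent underprediction. The returned
#' field carries `stage = "adjusted"`.
#'
#' @param field A concentration-field tibble (`unit_id`, `state`, `region`,
#'   `urban`, `conc`).
#' @param equations A tibble of adjustment equations from
#'   [compose_adjustments()].
#' @return The adjusted field tibble.
#' @export
#' @examples
#' eq <- compose_adjustments(list(fixed_intercept = 0.01875,
#'   fixed_slope = 1.896,
#'   region_slopes = c(MidwestEast = 1.12, South = -0.269, West = -0.856)))
#' field <- generate_field(synthetic_truth(), 49)
#' apply_adjustment(field, eq)
apply_adjustment <- function(field, equations) {
  unmapped <- setdiff(as.character(unique(field$region)),
                      as.character(equations$region))
  if (length(unmapped) > 0) {
    offenders <- field$unit_id[as.character(field$region) %in% unmapped]
    abort(paste0("No adjustment equation for region(s) ",
                 paste(unmapped, collapse = ", "), "; units affected: ",
                 paste(utils::head(offenders, 5), collapse = ", ")))
  }
  eq <- equations %>% mutate(region = as.character(.data$region))
  field %>%
    mutate(region_chr = as.character(.data$region)) %>%
    left_join(eq, by = c(region_chr = "region")) %>%
    mutate(conc = pmax(0, .data$intercept + .data$slope * .data$conc),
           stage = "adjusted") %>%
    select(-"region_chr", -"intercept", -"slope")
}

#' Serialize and restore a bias-correction fit
#'
#' `write_bias_fit()` writes the fitted parameters to a plain-text CSV
#' (`term,estimate,se`) with full double precision (17 significant digits)
#' so that `read_bias_fit()` round-trips every numeric field exactly.
#' The restored object carries the estimates, variances and sample size but
#' not the training data.
#'
#' @param fit A `bias_fit`.
#' @param path Output CSV path.
#' @return `write_bias_fit()` returns `path` invisibly; `read_bias_fit()`
#'   returns a `bias_fit`.
#' @export
write_bias_fit <- function(fit, path) {
  rows <- c(
    sprintf("(Intercept),%.17g,%.17g", fit$fixed_intercept,
            fit$standard_errors[1]),
    sprintf("model_value,%.17g,%.17g", fit$fixed_slope,
            fit$standard_errors[2]),
    sprintf("slope_%s,%.17g,", names(fit$region_slopes),
            fit$region_slopes),
    sprintf("slope_variance,%.17g,", fit$slope_variance),
    sprintf("residual_variance,%.17g,", fit$residual_variance),
    sprintf("lambda,%.17g,", fit$lambda),
    sprintf("n_obs,%d,", fit$n_obs),
    paste0("method,", fit$method, ",")
  )
  writeLines(c("term,estimate,se", rows), path)
  invisible(path)
}

#' @rdname write_bias_fit
#' @export
read_bias_fit <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  val <- setNames(d$estimate, d$term)
  se <- setNames(suppressWarnings(as.numeric(d$se)), d$term)
  slope_terms <- grep("^slope_(?!variance)", d$term, perl = TRUE,
                      value = TRUE)
  new_bias_fit(
    beta = as.numeric(val[c("(Intercept)", "model_value")]),
    u = setNames(as.numeric(val[slope_terms]),
                 sub("^slope_", "", slope_terms)),
    sigma2_u = as.numeric(val[["slope_variance"]]),
    sigma2_e = as.numeric(val[["residual_variance"]]),
    se = setNames(as.numeric(se[c("(Intercept)", "model_value")]),
                  c("(Intercept)", "model_value")),
    n_obs = as.integer(val[["n_obs"]]),
    lambda = as.numeric(val[["lambda"]]),
    method = unname(val[["method"]]),
    data = NULL
  )
}
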