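# Shared fixtures and independent oracles, all built in code.

# Monitor pairs where the observation equals the model exactly, balanced
# across the three regions.
make_identity_pairs <- function(n_per = 4) {
  x <- seq(0.02, 0.12, length.out = n_per)
  tibble::tibble(
    site_id = sprintf("s%02d", seq_len(3 * n_per)),
    month = "Jan",
    region = factor(rep(region_levels(), each = n_per),
                    levels = region_levels()),
    model_value = rep(x, 3),
    observed_value = rep(x, 3)
  )
}

# Deterministic 12-observation toy set (4 per region) with fixed inline
# "noise" so the REML solution is non-trivial but fully reproducible.
toy_pairs <- function() {
  x <- c(0.02, 0.05, 0.08, 0.11)
  slopes <- c(MidwestEast = 3.0, South = 1.6, West = 1.0)
  eps <- c(0.011, -0.007, 0.004, -0.012,
           -0.005, 0.009, -0.010, 0.006,
           0.008, -0.003, 0.012, -0.009)
  tibble::tibble(
    site_id = sprintf("s%02d", 1:12),
    month = "Jul",
    region = factor(rep(names(slopes), each = 4),
                    levels = region_levels()),
    model_value = rep(x, 3),
    observed_value = pmax(0, 0.02 + rep(slopes, each = 4) * rep(x, 3) + eps)
  )
}

# Brute-force profile-REML oracle: dense grid over the variance ratio,
# generic matrix algebra (explicit V, determinant(), solve()) — independent
# of the package's Sherman-Morrison fitting path.
reml_grid_oracle <- function(pairs, lambdas = c(0, exp(seq(-12, 12,
                                                           length.out = 4001)))) {
  pairs <- pairs[order(pairs$site_id, pairs$month), ]
  x <- pairs$model_value
  y <- pairs$observed_value
  g <- as.character(pairs$region)
  n <- length(y)
  X <- cbind(1, x)
  Z <- sapply(unique(g), function(rg) x * (g == rg))
  eval_one <- function(lam) {
    V <- diag(n) + lam * Z %*% t(Z)
    Vi <- solve(V)
    A <- t(X) %*% Vi %*% X
    beta <- solve(A, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    q <- drop(t(r) %*% Vi %*% r)
    s2 <- q / (n - 2)
    crit <- (n - 2) * log(s2) +
      determinant(V, logarithm = TRUE)$modulus[1] +
      determinant(A, logarithm = TRUE)$modulus[1]
    list(crit = crit, beta = unname(drop(beta)), s2 = s2,
         u = drop(lam * t(Z) %*% Vi %*% r))
  }
  fits <- lapply(lambdas, eval_one)
  best <- which.min(vapply(fits, `[[`, numeric(1), "crit"))
  c(fits[[best]], list(lambda = lambdas[best]))
}

# small aligned field + population pair for health-impact tests
make_unit_table <- function(conc, pop = 1e5, rate = 0.008,
                            urban = FALSE, state = "OH") {
  n <- length(conc)
  rmap <- region_map()
  state <- rep_len(state, n)
  list(
    field = tibble::tibble(
      unit_id = sprintf("u%03d", seq_len(n)),
      state = state,
      region = rmap$region[match(state, rmap$state)],
      urban = rep_len(urban, n),
      conc = conc,
      stage = "attributed"
    ),
    pop = tibble::tibble(
      unit_id = sprintf("u%03d", seq_len(n)),
      state = state,
      population = rep_len(pop, n),
      baseline_rate = rep_len(rate, n),
      urban = rep_len(urban, n)
    )
  )
}
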