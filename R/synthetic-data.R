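# Synthetic inputs for the aromatic-SOA burden pipeline: concentration
# fields standing in for gridded air-quality model output, monitor campaigns
# with known region-specific bias, an aromatic-VOC emissions inventory, and
# population/baseline-mortality tables. Generating parameters are recorded so
# downstream stages can be tested by parameter recovery.

#' Ground-truth parameters for the synthetic-data generators
#'
#' Bundles every generating parameter of the synthetic world: the fixed
#' intercept/slope and per-region slope offsets of the observation model
#' (observed = intercept + (slope + region offset) * modeled + noise), the
#' monitor noise level, and the log-normal concentration-field parameters.
#' Defaults reproduce the published bias structure: composed regional slopes
#' 3.016 / 1.627 / 1.04 for MidwestEast / South / West and an intercept of
#' 0.01875 ug/m3, with regional field means chosen so the national mean of
#' statewide averages is about 0.045 ug/m3 before adjustment.
#'
#' @param fixed_intercept Fixed intercept of the observation model, ug/m3.
#' @param fixed_slope Fixed (overall) slope, dimensionless.
#' @param region_slopes Named numeric of per-region slope offsets; must cover
#'   all three regions.
#' @param obs_noise_sd Monitor noise standard deviation in ugC/m3, or `NULL`
#'   to use 33% of each region's mean noiseless observation (the approximate
#'   error of tracer-based SOA estimates).
#' @param field_mean Named numeric of per-region mean concentrations, ug/m3.
#' @param field_sd Within-region concentration standard deviation, ug/m3.
#' @param model_scale Multiplier applied to field concentrations before they
#'   are used as "modeled" values in monitor pairs. The observed tracer data
#'   are in ug of carbon per m3 while model output is total organic mass; no
#'   published conversion exists, so the default is 1 (no rescaling) and the
#'   factor is exposed rather than silently fixed.
#' @param seed Default integer seed for generators built from this truth.
#'
#' @return An object of class `synthetic_truth` (a named list).
#' @export
#' @examples
#' synthetic_truth()
synthetic_truth <- function(fixed_intercept = 0.01875,
                            fixed_slope = 1.896,
                            region_slopes = c(MidwestEast = 1.12,
                                              South = -0.269,
                                              West = -0.856),
                            obs_noise_sd = NULL,
                            field_mean = c(MidwestEast = 0.060,
                                           South = 0.045,
                                           West = 0.025),
                            field_sd = 0.03,
                            model_scale = 1,
                            seed = 42L) {
  if (!is.null(obs_noise_sd) && obs_noise_sd < 0) {
    abort("`obs_noise_sd` must be >= 0.")
  }
  if (field_sd < 0) abort("`field_sd` must be >= 0.")
  missing_rg <- setdiff(region_levels(), names(region_slopes))
  if (length(missing_rg) > 0) {
    abort(paste0("`region_slopes` must name all regions; missing: ",
                 paste(missing_rg, collapse = ", ")))
  }
  missing_fm <- setdiff(region_levels(), names(field_mean))
  if (length(missing_fm) > 0) {
    abort(paste0("`field_mean` must name all regions; missing: ",
                 paste(missing_fm, collapse = ", ")))
  }
  if (any(field_mean <= 0)) abort("`field_mean` entries must be > 0.")
  structure(
    list(
      fixed_intercept = fixed_intercept,
      fixed_slope = fixed_slope,
      region_slopes = region_slopes[region_levels()],
      obs_noise_sd = obs_noise_sd,
      field_mean = field_mean[region_levels()],
      field_sd = field_sd,
      model_scale = model_scale,
      seed = as.integer(seed)
    ),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>\n")
  cat(sprintf("  observation model: obs = %.5g + (%.4g + u_region) * model + e\n",
              x$fixed_intercept, x$fixed_slope))
  cat("  region slope offsets:",
      paste(sprintf("%s %+.3g", names(x$region_slopes), x$region_slopes),
            collapse = ", "), "\n")
  cat(sprintf("  noise sd: %s | field mean: %s | field sd: %.3g | seed: %d\n",
              if (is.null(x$obs_noise_sd)) "auto (33% of regional mean)"
              else format(x$obs_noise_sd),
              paste(sprintf("%.3g", x$field_mean), collapse = "/"),
              x$field_sd, x$seed))
  invisible(x)
}

# deterministic round-robin allocation of units to states
allocate_states <- function(n_units, states = region_map()$state) {
  states[((seq_len(n_units) - 1L) %% length(states)) + 1L]
}

# run code with a temporary RNG state so generators do not disturb the
# caller's stream and are reproducible in isolation
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# log-normal draws with arithmetic mean m and sd s (s = 0 degenerates to m)
rlnorm_meansd <- function(n, m, s) {
  if (s == 0) return(rep(m, n))
  sdlog2 <- log(1 + (s / m)^2)
  rlnorm(n, meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Generate a synthetic concentration field
#'
#' Draws per-unit annual-average aromatic-SOA concentrations for "county
#' like" geographic units spread round-robin across the lower 48 states plus
#' DC. Concentrations are log-normal within each region (guaranteeing
#' positivity and the right skew seen in county-level data), with regional
#' means taken from `truth$field_mean` — or, when `state_targets` is given,
#' with state-specific means calibrated so each state's sample mean equals
#' its target exactly.
#'
#' @param truth A [synthetic_truth()] object.
#' @param n_units Number of geographic units (>= 1).
#' @param seed Integer seed; defaults to `truth$seed`.
#' @param state_targets Optional tibble with columns `state` and `mean_conc`
#'   (e.g. [state_concentration_table()]); restricts the field to those
#'   states and targets their means.
#' @param calibrate When `state_targets` is supplied, rescale each state's
#'   units so the state sample mean matches the target exactly (default
#'   `TRUE`).
#' @param urban_proportion Probability that a unit is flagged urban.
#'
#' @return A tibble with columns `unit_id`, `state`, `region`, `urban`,
#'   `conc` (ug/m3) and `stage` (`"raw"`).
#' @export
#' @examples
#' field <- generate_field(synthetic_truth(), n_units = 98)
#' dplyr::count(field, region)
generate_field <- function(truth, n_units, seed = truth$seed,
                           state_targets = NULL,
                           calibrate = !is.null(state_targets),
                           urban_proportion = 0.3) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (length(n_units) != 1 || is.na(n_units) || n_units < 1) {
    abort("`n_units` must be a single count >= 1.")
  }
  n_units <- as.integer(n_units)
  rmap <- region_map()
  states_pool <- rmap$state
  if (!is.null(state_targets)) {
    assert_known_states(state_targets$state)
    states_pool <- state_targets$state
  }
  field <- with_seed(seed, {
    st <- allocate_states(n_units, states_pool)
    rg <- rmap$region[match(st, rmap$state)]
    if (is.null(state_targets)) {
      m <- truth$field_mean[as.character(rg)]
    } else {
      m <- state_targets$mean_conc[match(st, state_targets$state)]
    }
    conc <- vapply(seq_len(n_units),
                   function(i) rlnorm_meansd(1, m[i], truth$field_sd),
                   numeric(1))
    urban <- runif(n_units) < urban_proportion
    tibble(
      unit_id = sprintf("unit_%05d", seq_len(n_units)),
      state = st,
      region = rg,
      urban = urban,
      conc = conc
    )
  })
  if (!is.null(state_targets) && calibrate) {
    field <- field %>%
      group_by(.data$state) %>%
      mutate(conc = .data$conc *
               state_targets$mean_conc[match(.data$state[1],
                                             state_targets$state)] /
               mean(.data$conc)) %>%
      ungroup()
  }
  field %>% mutate(stage = "raw")
}

#' Generate a synthetic monitor campaign
#'
#' Samples monitoring sites from a concentration field (stratified evenly
#' across the regions present) and produces paired model/observation values.
#' The "modeled" value is the unit's concentration times `truth$model_scale`;
#' the observation follows the truth's linear region-specific bias model with
#' additive Gaussian noise truncated at zero, emulating tracer-based ambient
#' measurements that exceed model output by region-dependent factors.
#'
#' @param field A field tibble from [generate_field()].
#' @param truth A [synthetic_truth()] object.
#' @param n_sites Number of monitor sites (>= 1).
#' @param seed Integer seed; defaults to `truth$seed + 1`.
#'
#' @return A tibble of monitor pairs with columns `site_id`, `month`,
#'   `region`, `model_value`, `observed_value` (both ugC/m3).
#' @export
#' @examples
#' tr <- synthetic_truth()
#' mons <- generate_monitors(generate_field(tr, 98), tr, n_sites = 30)
#' head(mons)
generate_monitors <- function(field, truth, n_sites,
                              seed = truth$seed + 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is.data.frame(field) || nrow(field) == 0) {
    abort("`field` must be a non-empty concentration field.")
  }
  if (length(n_sites) != 1 || is.na(n_sites) || n_sites < 1) {
    abort("`n_sites` must be a single count >= 1.")
  }
  n_sites <- as.integer(n_sites)
  regions <- sort(unique(as.character(field$region)))
  # near-equal allocation of sites across represented regions
  base <- n_sites %/% length(regions)
  alloc <- setNames(rep(base, length(regions)), regions)
  extra <- n_sites - base * length(regions)
  if (extra > 0) alloc[seq_len(extra)] <- alloc[seq_len(extra)] + 1L

  with_seed(seed, {
    pairs <- purrr::map(regions, function(rg) {
      k <- alloc[[rg]]
      if (k == 0) return(NULL)
      units <- field %>% filter(as.character(.data$region) == rg)
      idx <- sample.int(nrow(units), k, replace = k > nrow(units))
      model <- units$conc[idx] * truth$model_scale
      slope <- truth$fixed_slope + truth$region_slopes[[rg]]
      clean <- truth$fixed_intercept + slope * model
      nsd <- if (is.null(truth$obs_noise_sd)) 0.33 * mean(clean)
             else truth$obs_noise_sd
      tibble(
        region = factor(rg, levels = region_levels()),
        model_value = model,
        observed_value = pmax(0, clean + rnorm(k, 0, nsd))
      )
    })
    bind_rows(pairs) %>%
      mutate(
        site_id = sprintf("site_%04d", row_number()),
        month = month.abb[((row_number() - 1L) %% 12L) + 1L]
      ) %>%
      select("site_id", "month", "region", "model_value", "observed_value")
  })
}

# Published national inventory of single-ring aromatic VOC, tons/yr
default_inventory_entries <- function() {
  c(gasoline = 2491313, solvent_usage = 518334,
    diesel = 25436, other = 573679)
}

#' Generate an aromatic-VOC emissions inventory
#'
#' Returns the packaged national inventory of single-ring aromatic
#' hydrocarbon emissions by source category (tons/yr), totalling about 3.6
#' million tons/yr with a 69% gasoline share. Named `overrides` replace the
#' default tonnages; with `complete = FALSE` the inventory consists of the
#' overrides alone.
#'
#' @param overrides Optional named numeric of tonnages (tons/yr, >= 0).
#' @param complete If `TRUE` (default) start from the packaged defaults and
#'   replace overridden entries; if `FALSE` use only the overrides.
#'
#' @return A tibble with columns `source` and `tons_per_year`.
#' @export
#' @examples
#' generate_inventory()
#' generate_inventory(c(gasoline = 0))
generate_inventory <- function(overrides = NULL, complete = TRUE) {
  entries <- if (complete) default_inventory_entries() else numeric()
  if (!is.null(overrides)) {
    overrides <- unlist(overrides)
    if (any(overrides < 0)) abort("Inventory tonnages must be >= 0.")
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      abort("`overrides` must be a named numeric vector.")
    }
    entries[names(overrides)] <- overrides
  }
  if (length(entries) == 0) abort("Inventory has no entries.")
  tibble(source = names(entries), tons_per_year = unname(entries))
}

#' Configuration for the synthetic population generator
#'
#' @param pop_mean,pop_cv Mean and coefficient of variation of the log-normal
#'   unit population distribution (persons).
#' @param rate_mean,rate_sd Mean and sd of the baseline all-cause mortality
#'   rate, deaths per person-year; must keep rates in \[0, 1\]. `rate_sd = 0`
#'   gives every unit the same rate.
#' @param urban_proportion Probability a unit is flagged urban.
#' @param states,urban,unit_ids Optional vectors overriding the deterministic
#'   state allocation, the random urban flags, and the generated unit ids —
#'   used by the pipeline to keep population and field tables aligned.
#' @return A list of class `population_config`.
#' @export
population_config <- function(pop_mean = 60000, pop_cv = 1,
                              rate_mean = 0.008, rate_sd = 0,
                              urban_proportion = 0.3,
                              states = NULL, urban = NULL,
                              unit_ids = NULL) {
  if (rate_mean < 0 || rate_mean > 1) {
    abort("`rate_mean` must lie in [0, 1].")
  }
  if (rate_sd < 0) abort("`rate_sd` must be >= 0.")
  if (pop_mean <= 0 || pop_cv < 0) {
    abort("`pop_mean` must be > 0 and `pop_cv` >= 0.")
  }
  if (urban_proportion < 0 || urban_proportion > 1) {
    abort("`urban_proportion` must lie in [0, 1].")
  }
  structure(
    list(pop_mean = pop_mean, pop_cv = pop_cv, rate_mean = rate_mean,
         rate_sd = rate_sd, urban_proportion = urban_proportion,
         states = states, urban = urban, unit_ids = unit_ids),
    class = "population_config"
  )
}

#' Generate synthetic population and baseline-mortality records
#'
#' Draws per-unit populations (log-normal, rounded to whole persons) and
#' baseline all-cause mortality rates for the geographic units the pipeline
#' exposes. Rates are clamped to \[0, 1\]; populations are non-negative
#' integers. Deterministic under a fixed seed.
#'
#' @param n_units Number of geographic units (>= 1).
#' @param seed Integer seed.
#' @param config A [population_config()].
#'
#' @return A tibble with columns `unit_id`, `state`, `population`,
#'   `baseline_rate`, `urban`.
#' @export
#' @examples
#' generate_population(5, seed = 1)
generate_population <- function(n_units, seed,
                                config = population_config()) {
  stopifnot(inherits(config, "population_config"))
  if (length(n_units) != 1 || is.na(n_units) || n_units < 1) {
    abort("`n_units` must be a single count >= 1.")
  }
  n_units <- as.integer(n_units)
  with_seed(seed, {
    states <- config$states %||% allocate_states(n_units)
    assert_known_states(states)
    pop <- round(rlnorm_meansd(n_units, config$pop_mean,
                               config$pop_cv * config$pop_mean))
    rate <- if (config$rate_sd == 0) rep(config$rate_mean, n_units)
            else pmin(1, pmax(0, rnorm(n_units, config$rate_mean,
                                       config$rate_sd)))
    urban <- config$urban %||% (runif(n_units) < config$urban_proportion)
    tibble(
      unit_id = config$unit_ids %||% sprintf("unit_%05d", seq_len(n_units)),
      state = states,
      population = as.integer(pop),
      baseline_rate = rate,
      urban = urban
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
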