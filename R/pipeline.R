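# End-to-end orchestration: simulate -> fit-bias -> adjust -> attribute ->
# impact (per CRF) -> value, with per-stage CSV artifacts and a JSON run
# manifest so any report can be reconstructed from config + seed alone.

#' Published reference coefficients of the bias-correction model
#'
#' The reference random-slope fit of observed aromatic SOA on modeled
#' values: fixed intercept 0.01875 ug/m3, fixed slope 1.896, and region
#' random-slope offsets +1.12 (MidwestEast), -0.269 (South), -0.856 (West),
#' composing to regional adjustment slopes 3.016, 1.627 and 1.04.
#'
#' @return A list with `fixed_intercept`, `fixed_slope`, `region_slopes`,
#'   suitable for [compose_adjustments()].
#' @export
#' @examples
#' compose_adjustments(reference_bias_fit())
reference_bias_fit <- function() {
  list(
    fixed_intercept = 0.01875,
    fixed_slope = 1.896,
    region_slopes = c(MidwestEast = 1.12, South = -0.269, West = -0.856)
  )
}

#' Pipeline configuration
#'
#' @param seed Master integer seed; every stochastic stage derives its own
#'   stream from it.
#' @param n_units Number of geographic units in the synthetic field.
#' @param n_sites Number of monitor sites for the bias-model campaign.
#' @param truth A [synthetic_truth()]; its `seed` is overridden by `seed`.
#' @param mode Attribution mode, `"uniform"` or `"urban_rural"`.
#' @param urban_fraction Urban gasoline fraction in `urban_rural` mode.
#' @param crf_set Named list of [crf()] objects (default
#'   [default_crf_set()]).
#' @param valuation A [valuation_config()].
#' @param pop_config A [population_config()]; `states`, `urban` and
#'   `unit_ids` are filled from the generated field.
#' @param n_draws Monte-Carlo draws for CRF uncertainty propagation.
#' @param monitor_noise_sd Optional monitor noise sd override (ugC/m3).
#' @param gasoline_fraction Optional override of the gasoline-attributable
#'   fraction; by default it is computed from the generated inventory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 42L, n_units = 490L, n_sites = 120L,
                            truth = synthetic_truth(),
                            mode = "uniform", urban_fraction = 1,
                            crf_set = default_crf_set(),
                            valuation = valuation_config(),
                            pop_config = population_config(),
                            n_draws = 2000L,
                            monitor_noise_sd = NULL,
                            gasoline_fraction = NULL) {
  if (length(seed) != 1 || is.na(seed)) abort("`seed` must be an integer.")
  truth$seed <- as.integer(seed)
  if (!is.null(monitor_noise_sd)) truth$obs_noise_sd <- monitor_noise_sd
  structure(
    list(seed = as.integer(seed), n_units = as.integer(n_units),
         n_sites = as.integer(n_sites), truth = truth, mode = mode,
         urban_fraction = urban_fraction, crf_set = crf_set,
         valuation = valuation, pop_config = pop_config,
         n_draws = as.integer(n_draws),
         gasoline_fraction = gasoline_fraction),
    class = "pipeline_config"
  )
}

run_stage <- function(stage, code) {
  tryCatch(force(code), error = function(e) {
    abort(paste0("Pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full burden-estimation pipeline
#'
#' Executes every stage on synthetic inputs: generates the concentration
#' field, monitor campaign, inventory and population tables; fits the
#' random-slope bias model and adjusts the field; scales by the
#' gasoline-attributable fraction; computes premature mortality per CRF
#' with Monte-Carlo percentiles; and monetizes the results. When `out_dir`
#' is given, every stage artifact is written as a headered CSV plus a JSON
#' manifest; identical `config` and seed produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return Invisibly, a named list of all stage tibbles and the manifest.
#' @export
#' @examples
#' res <- run_pipeline(pipeline_config(seed = 7, n_units = 98,
#'                                     n_sites = 30, n_draws = 200))
#' res$national
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  truth <- config$truth

  field <- run_stage("simulate", generate_field(truth, config$n_units,
                                                seed = seed))
  monitors <- run_stage("simulate",
                        generate_monitors(field, truth, config$n_sites,
                                          seed = seed + 1L))
  inventory <- run_stage("simulate", generate_inventory())
  pc <- config$pop_config
  pc$states <- field$state
  pc$urban <- field$urban
  pc$unit_ids <- field$unit_id
  population <- run_stage("simulate",
                          generate_population(config$n_units,
                                              seed = seed + 2L,
                                              config = pc))

  fit <- run_stage("fit-bias", fit_bias_model(monitors))
  equations <- run_stage("fit-bias", compose_adjustments(fit))
  adjusted <- run_stage("adjust", apply_adjustment(field, equations))

  shares <- run_stage("attribute", source_shares(inventory))
  scenario <- attribution_scenario(
    mode = config$mode,
    gasoline_fraction = config$gasoline_fraction %||%
      gasoline_fraction(inventory),
    urban_fraction = config$urban_fraction
  )
  attributed <- run_stage("attribute", apply_attribution(adjusted, scenario))

  impacts <- run_stage("impact", purrr::map(config$crf_set, function(cf) {
    by_unit <- impact_field(attributed, population, cf)
    list(
      by_unit = by_unit,
      by_state = aggregate_impacts(by_unit, "state"),
      national = suppressMessages(
        propagate_uncertainty(attributed, population, cf,
                              n_draws = config$n_draws, seed = seed + 3L)
      )
    )
  }))
  by_state <- bind_rows(purrr::map(impacts, "by_state"))
  national <- bind_rows(purrr::map(impacts, "national"))

  state_report <- run_stage("value",
                            build_state_report(by_state, config$valuation))
  national_report <- run_stage("value", monetize(national, config$valuation))

  manifest <- list(
    package = "soaburden",
    version = as.character(packageVersion("soaburden")),
    seed = seed,
    n_units = config$n_units,
    n_sites = config$n_sites,
    mode = config$mode,
    gasoline_fraction = scenario$gasoline_fraction,
    n_draws = config$n_draws,
    rows = list(
      field = nrow(field), monitors = nrow(monitors),
      population = nrow(population), by_state = nrow(by_state),
      national = nrow(national)
    )
  )

  out <- list(field = field, monitors = monitors, inventory = inventory,
              population = population, fit = fit, equations = equations,
              adjusted = adjusted, shares = shares, attributed = attributed,
              by_state = by_state, national = national,
              state_report = state_report,
              national_report = national_report, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) readr::write_csv(x, file.path(out_dir, f))
    w(field, "field.csv")
    w(monitors, "monitors.csv")
    w(inventory, "inventory.csv")
    w(population, "population.csv")
    write_bias_fit(fit, file.path(out_dir, "bias_fit.csv"))
    w(equations, "adjustment_equations.csv")
    w(adjusted, "field_adjusted.csv")
    w(shares, "shares.csv")
    w(attributed, "field_attributed.csv")
    w(by_state, "impacts_by_state.csv")
    w(national, "impacts_national.csv")
    w(state_report, "social_cost_by_state.csv")
    w(national_report, "social_cost_national.csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(out)
}

#' Validate the packaged worked-example arithmetic
#'
#' Re-runs every closed-form worked example the package encodes — the
#' inventory share and total, the composed regional adjustment slopes, the
#' nationwide adjustment factor, the monetized national estimates, and the
#' share of the all-source PM2.5 mortality reference — and reports
#' pass/fail per check.
#'
#' @param inventory Inventory tibble (default the packaged one); pass a
#'   modified inventory to see the corresponding checks fail.
#' @return A tibble with columns `check`, `expected`, `actual`, `pass`,
#'   with attribute `all_pass`.
#' @export
#' @examples
#' validate_worked_examples()
validate_worked_examples <- function(inventory = generate_inventory()) {
  eq <- suppressMessages(compose_adjustments(reference_bias_fit()))
  slopes <- setNames(eq$slope, as.character(eq$region))
  vsl <- valuation_config()$vsl
  checks <- tibble(
    check = c(
      "gasoline share of aromatic VOC (%)",
      "inventory total (tons/yr)",
      "composed slope MidwestEast",
      "composed slope South",
      "composed slope West",
      "nationwide adjustment factor",
      "central social cost ($B)",
      "upper social cost ($B)",
      "lower social cost ($B)",
      "share of all-source PM2.5 mortality (%)"
    ),
    expected = c(69, 3608762, 3.016, 1.627, 1.04, 3.8, 28.2, 34.9, 13.6,
                 1.4),
    actual = c(
      round(percent_1dp(gasoline_fraction(inventory))),
      sum(inventory$tons_per_year),
      round(slopes[["MidwestEast"]], 3),
      round(slopes[["South"]], 3),
      round(slopes[["West"]], 3),
      ratio_1dp(0.17, 0.045),
      billions_1dp(3816 * vsl),
      billions_1dp(4714 * vsl),
      billions_1dp(1833 * vsl),
      percent_1dp(compare_to_reference(1833, 130000) / 100)
    )
  ) %>%
    mutate(pass = .data$expected == .data$actual)
  attr(checks, "all_pass") <- all(checks$pass)
  checks
}
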