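# Monetization of mortality estimates at the value of mortality risk and
# assembly of the report tables (national scenario summary, state rankings).

#' Valuation configuration
#'
#' @param vsl Value of mortality risk (historically "value of a statistical
#'   life") in dollars per expected death avoided; the regulatory default is
#'   $7.4M in 2006 dollars.
#' @param currency_year Label only; no inflation adjustment is performed.
#' @return A list of class `valuation_config`.
#' @export
valuation_config <- function(vsl = 7.4e6, currency_year = "2006") {
  if (!is.finite(vsl) || vsl <= 0) abort("`vsl` must be > 0.")
  structure(list(vsl = vsl, currency_year = currency_year),
            class = "valuation_config")
}

#' Monetize impact estimates
#'
#' Multiplies the central estimate and each percentile by the value of
#' mortality risk. Stored dollar values are unrounded; use
#' [billions_1dp()] / [millions_0dp()] for report formatting.
#'
#' @param estimates A tibble with `cases_central` and optionally `cases_p5`,
#'   `cases_p95` (e.g. from [aggregate_impacts()] or
#'   [propagate_uncertainty()]).
#' @param config A [valuation_config()].
#' @return `estimates` with added `dollars_central` (and `dollars_p5`,
#'   `dollars_p95` when percentiles are present) and a `currency_year`
#'   column.
#' @export
#' @examples
#' monetize(tibble::tibble(cases_central = 3816))
monetize <- function(estimates, config = valuation_config()) {
  stopifnot(inherits(config, "valuation_config"))
  out <- estimates %>%
    mutate(dollars_central = .data$cases_central * config$vsl)
  if ("cases_p5" %in% names(estimates)) {
    out <- out %>% mutate(dollars_p5 = .data$cases_p5 * config$vsl,
                          dollars_p95 = .data$cases_p95 * config$vsl)
  }
  out %>% mutate(currency_year = config$currency_year)
}

#' Report formatting helpers
#'
#' `billions_1dp()` renders dollars as billions rounded to one decimal
#' (`$28.2B`); `millions_0dp()` as whole millions; `percent_1dp()` as a
#' percentage with one decimal; `ratio_1dp()` rounds a ratio to one decimal
#' (used for the nationwide adjustment factor, e.g. 0.17/0.045 -> 3.8).
#'
#' @param dollars,x,numerator,denominator Numeric inputs.
#' @return Numeric values on the printed scale (not strings).
#' @export
#' @examples
#' billions_1dp(3816 * 7.4e6)  # 28.2
#' ratio_1dp(0.17, 0.045)      # 3.8
billions_1dp <- function(dollars) round(dollars / 1e9, 1)

#' @rdname billions_1dp
#' @export
millions_0dp <- function(dollars) round(dollars / 1e6, 0)

#' @rdname billions_1dp
#' @export
percent_1dp <- function(x) round(100 * x, 1)

#' @rdname billions_1dp
#' @export
ratio_1dp <- function(numerator, denominator) {
  round(numerator / denominator, 1)
}

#' Share of a reference mortality total
#'
#' Expresses attributable cases as a percentage of an independent reference
#' total — e.g. the roughly 130,000 annual U.S. premature mortalities
#' attributed to all-source PM2.5 exposure.
#'
#' @param cases Attributable cases.
#' @param reference_total Reference case count, > 0.
#' @return Percentage (0-100 scale), unrounded; round with
#'   [percent_1dp()] for reports.
#' @export
#' @examples
#' percent_1dp(compare_to_reference(1833, 130000) / 100)  # 1.4
compare_to_reference <- function(cases, reference_total) {
  if (!is.finite(reference_total) || reference_total <= 0) {
    abort("`reference_total` must be > 0.")
  }
  100 * cases / reference_total
}

#' Build a state-level social-cost report
#'
#' Monetizes state-aggregated impact estimates and ranks states by
#' descending central cases (ties broken alphabetically). Raw unrounded
#' dollars are kept alongside rounded report columns.
#'
#' @param estimates State-level estimates with columns `geography` and
#'   `cases_central` (optionally `cases_p5`/`cases_p95`).
#' @param config A [valuation_config()].
#' @return A tibble sorted by impact with added dollar columns and
#'   `dollars_central_millions` (rounded for display).
#' @export
build_state_report <- function(estimates, config = valuation_config()) {
  monetize(estimates, config) %>%
    arrange(desc(.data$cases_central), .data$geography) %>%
    mutate(rank = row_number(),
           dollars_central_millions = millions_0dp(.data$dollars_central))
}
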