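# Emissions-based source attribution: how much of the aromatic-VOC burden —
# and hence of the aromatic SOA field — comes from gasoline-powered vehicles.

#' Rank source categories by their share of aromatic VOC emissions
#'
#' @param inventory A tibble with columns `source` and `tons_per_year`
#'   (tons/yr, >= 0), e.g. from [generate_inventory()].
#' @return A tibble sorted by descending tonnage (ties broken by source
#'   label) with columns `source`, `tons_per_year`, `share`, `rank`. Shares
#'   sum to 1.
#' @export
#' @examples
#' source_shares(generate_inventory())
source_shares <- function(inventory) {
  if (!is.data.frame(inventory) ||
      !all(c("source", "tons_per_year") %in% names(inventory))) {
    abort("`inventory` needs columns `source` and `tons_per_year`.")
  }
  if (any(inventory$tons_per_year < 0)) {
    abort("Inventory tonnages must be >= 0.")
  }
  total <- sum(inventory$tons_per_year)
  if (total <= 0) abort("Inventory total must be > 0.")
  inventory %>%
    as_tibble() %>%
    mutate(share = .data$tons_per_year / total) %>%
    arrange(desc(.data$tons_per_year), .data$source) %>%
    mutate(rank = row_number())
}

#' Gasoline share of an emissions inventory
#'
#' @inheritParams source_shares
#' @param source Source label whose share to return (default `"gasoline"`).
#' @return The share as a plain number in \[0, 1\].
#' @export
#' @examples
#' gasoline_fraction()  # about 0.69
gasoline_fraction <- function(inventory = generate_inventory(),
                              source = "gasoline") {
  shares <- source_shares(inventory)
  hit <- shares$share[shares$source == source]
  if (length(hit) == 0) return(0)
  sum(hit)
}

#' Define a source-attribution scenario
#'
#' In `uniform` mode every unit's concentration is scaled by the gasoline
#' fraction. In `urban_rural` mode only rural units are scaled by the
#' gasoline fraction while urban units keep `urban_fraction` (default 1,
#' i.e. all urban aromatic SOA attributed to gasoline) — the sensitivity
#' case in which gasoline dominates urban aromatic emissions.
#'
#' @param mode `"uniform"` or `"urban_rural"`.
#' @param gasoline_fraction Fraction in \[0, 1\]; default computed from the
#'   packaged inventory (about 0.69).
#' @param urban_fraction Fraction applied to urban units in `urban_rural`
#'   mode.
#' @return A list of class `attribution_scenario`.
#' @export
attribution_scenario <- function(mode = c("uniform", "urban_rural"),
                                 gasoline_fraction =
                                   soaburden::gasoline_fraction(),
                                 urban_fraction = 1) {
  mode <- match.arg(mode)
  for (f in c(gasoline_fraction, urban_fraction)) {
    if (!is.finite(f) || f < 0 || f > 1) {
      abort("Attribution fractions must lie in [0, 1].")
    }
  }
  structure(
    list(mode = mode, gasoline_fraction = gasoline_fraction,
         urban_fraction = urban_fraction),
    class = "attribution_scenario"
  )
}

#' Scale a concentration field by its gasoline-attributable fraction
#'
#' @param field A concentration-field tibble with columns `unit_id`,
#'   `region`, `conc`, and `urban` (required in `urban_rural` mode).
#' @param scenario An [attribution_scenario()].
#' @return The field with `conc` scaled per scenario and
#'   `stage = "attributed"`.
#' @export
#' @examples
#' field <- generate_field(synthetic_truth(), 49)
#' apply_attribution(field, attribution_scenario("uniform"))
apply_attribution <- function(field, scenario = attribution_scenario()) {
  stopifnot(inherits(scenario, "attribution_scenario"))
  if (scenario$mode == "uniform") {
    out <- field %>% mutate(conc = .data$conc * scenario$gasoline_fraction)
  } else {
    if (!"urban" %in% names(field) || any(is.na(field$urban))) {
      offenders <- if ("urban" %in% names(field)) {
        field$unit_id[is.na(field$urban)]
      } else field$unit_id
      abort(paste0("urban_rural mode needs an urban flag on every unit; ",
                   "missing for: ",
                   paste(utils::head(offenders, 5), collapse = ", ")))
    }
    out <- field %>%
      mutate(conc = .data$conc * ifelse(.data$urban,
                                        scenario$urban_fraction,
                                        scenario$gasoline_fraction))
  }
  out %>% mutate(stage = "attributed")
}
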