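#' Census-based region assignments for the lower 48 states
#'
#' The bias-correction model groups monitor sites into three regions built
#' from the standard U.S. census divisions: the Northeast and Midwest merged
#' into a single `MidwestEast` region (where air-quality models underpredict
#' aromatic SOA most strongly), plus `South` and `West`. Every one of the
#' lower 48 states and the District of Columbia maps to exactly one region.
#'
#' @return A tibble with columns `state` (2-letter code) and `region`
#'   (factor with levels `MidwestEast`, `South`, `West`).
#' @export
#' @examples
#' region_map()
region_map <- function() {
  northeast <- c("CT", "ME", "MA", "NH", "NJ", "NY", "PA", "RI", "VT")
  midwest <- c("IL", "IN", "IA", "KS", "MI", "MN", "MO", "NE", "ND",
               "OH", "SD", "WI")
  south <- c("AL", "AR", "DC", "DE", "FL", "GA", "KY", "LA", "MD", "MS",
             "NC", "OK", "SC", "TN", "TX", "VA", "WV")
  west <- c("AZ", "CA", "CO", "ID", "MT", "NV", "NM", "OR", "UT", "WA",
            "WY")
  tibble(
    state = c(northeast, midwest, south, west),
    region = factor(
      c(rep("MidwestEast", length(northeast) + length(midwest)),
        rep("South", length(south)),
        rep("West", length(west))),
      levels = region_levels()
    )
  ) %>%
    arrange(.data$state)
}

#' @rdname region_map
#' @export
region_levels <- function() c("MidwestEast", "South", "West")

#' Reference statewide annual-average concentrations
#'
#' Published statewide annual averages of PM2.5 attributed to aromatic SOA
#' from gasoline (after bias adjustment and source attribution), in units of
#' ug/m3. They range from 0.23 (CT, RI) down to 0.03 (mountain-west states) and
#' serve as calibration targets for the statewide synthetic field mode.
#'
#' @return A tibble with columns `state`, `region`, and `mean_conc` (ug/m3).
#' @export
state_concentration_table <- function() {
  vals <- c(
    CT = 0.23, RI = 0.23, OH = 0.21, NY = 0.21, NJ = 0.20, IN = 0.20,
    MA = 0.19, NH = 0.18, IL = 0.17, PA = 0.17, MO = 0.17, MI = 0.16,
    SC = 0.16, NC = 0.16, GA = 0.16, VT = 0.15, IA = 0.15, WI = 0.15,
    ME = 0.14, KY = 0.14, DE = 0.14, TN = 0.14, AL = 0.14, WV = 0.13,
    VA = 0.13, MS = 0.13, KS = 0.12, DC = 0.12, MD = 0.12, AR = 0.11,
    MN = 0.11, NE = 0.11, OK = 0.09, LA = 0.09, SD = 0.09, TX = 0.08,
    ND = 0.08, FL = 0.08, NV = 0.05, AZ = 0.05, CA = 0.04, ID = 0.04,
    MT = 0.03, UT = 0.03, WY = 0.03, OR = 0.03, WA = 0.03, NM = 0.03,
    CO = 0.03
  )
  tibble(state = names(vals), mean_conc = unname(vals)) %>%
    left_join(region_map(), by = "state") %>%
    select("state", "region", "mean_conc")
}

# internal: validate a vector of state codes against the packaged map
assert_known_states <- function(states) {
  unknown <- setdiff(unique(states), region_map()$state)
  if (length(unknown) > 0) {
    abort(paste0("Unknown state code(s): ", paste(unknown, collapse = ", ")))
  }
  invisible(states)
}
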