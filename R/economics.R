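#' Annual gross income per field
#'
#' `sum over cycles of cycle yield x grain price(cycle label)`.
#'
#' @param survey A survey tibble.
#' @param prices A `price_set`; defaults to the calibrated packaged set.
#' @return A tibble `field_id`, `system`, `gross_income` ($/ha/yr).
#' @export
gross_income <- function(survey, prices = default_prices()) {
  missing <- setdiff(unique(survey$cycle_label), names(prices$grain_price))
  if (length(missing) > 0) {
    stop("no grain price for cycle label(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    field_id = survey$field_id,
    system = survey$system,
    income = survey$grain_yield * prices$grain_price[survey$cycle_label]
  ) |>
    dplyr::group_by(.data$field_id, .data$system) |>
    dplyr::summarise(gross_income = sum(.data$income), .groups = "drop")
}

#' Annual variable production cost per field
#'
#' `sum over cycles of sum(rate x unit price) + labor x labor price`.
#' Variable costs only; fixed costs (land, equipment ownership) are not
#' part of the accounting.
#'
#' @inheritParams gross_income
#' @return A tibble `field_id`, `system`, `production_cost` ($/ha/yr).
#' @export
production_cost <- function(survey, prices = default_prices()) {
  ann <- annual_rates(survey)
  pm <- c(prices$input_prices, labor = unname(prices$labor_price))
  bd <- breakdown_from_rates(ann, pm, "production_cost")
  bd[c("field_id", "system", "production_cost")]
}

#' Net economic return
#'
#' `net return = gross income - production cost`.
#'
#' @param gross,cost Gross income and production cost, $/ha/yr.
#' @return $/ha/yr.
#' @export
net_return <- function(gross, cost) {
  gross - cost
}

#' Benefit-to-cost ratio
#'
#' `gross income / production cost`; `cost` must be positive.
#'
#' @inheritParams net_return
#' @return Dimensionless ratio.
#' @export
benefit_cost <- function(gross, cost) {
  if (any(cost <= 0)) {
    stop("production cost must be > 0 to form the benefit-to-cost ratio",
         call. = FALSE)
  }
  gross / cost
}

#' Net profit-to-labor use ratio
#'
#' `net return / total labor input`; labor must be positive.
#'
#' @param net_return $/ha/yr.
#' @param labor h/ha/yr.
#' @return $/h.
#' @export
npl <- function(net_return, labor) {
  if (any(labor <= 0)) {
    stop("labor must be > 0 to form NPL", call. = FALSE)
  }
  net_return / labor
}

#' Eco-efficiency
#'
#' Net economic return per unit of environmental impact, reported per Mg
#' CO2e (the $/kg ratio times 1000).
#'
#' @param net_return $/ha/yr.
#' @param gwp kg CO2e/ha/yr (> 0).
#' @return $/Mg CO2e.
#' @export
eco_efficiency <- function(net_return, gwp) {
  if (any(gwp <= 0)) {
    stop("GWP must be > 0 to form eco-efficiency", call. = FALSE)
  }
  net_return / gwp * 1000
}

#' Input-use efficiencies per field
#'
#' Labor productivity (LP, kg grain per labor hour), partial factor
#' productivity of N fertilizer (PFP_N, kg grain per kg N) and
#' irrigation-water productivity (IWP, kg grain per m3), each formed from
#' annual totals. A zero denominator leaves the metric undefined (`NA`),
#' not zero.
#'
#' @param survey A survey tibble.
#' @return A tibble `field_id`, `system`, `lp`, `pfp_n`, `iwp`.
#' @export
input_efficiencies <- function(survey) {
  ann <- annual_rates(survey)
  grain_kg <- ann$annual_yield * 1000
  tibble::tibble(
    field_id = ann$field_id,
    system = ann$system,
    lp = ifelse(ann$labor > 0, grain_kg / ann$labor, NA_real_),
    pfp_n = ifelse(ann$n_rate > 0, grain_kg / ann$n_rate, NA_real_),
    iwp = ifelse(ann$irrigation > 0, grain_kg / ann$irrigation, NA_real_)
  )
}
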