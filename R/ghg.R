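#' Annual embodied greenhouse-gas emissions of agricultural inputs
#'
#' CO2-equivalent emitted in producing, packaging and transporting the
#' inputs applied to each field, summed over crop cycles:
#' `sum(rate x emission coefficient)`.
#'
#' @inheritParams energy_input
#' @return A tibble with one row per field: `field_id`, `system` and
#'   `embodied` (kg CO2e/ha/yr).
#' @export
embodied_ghg <- function(survey, coeffs = default_coefficients()) {
  ann <- annual_rates(survey)
  bd <- breakdown_from_rates(ann, coeffs$ghg_coefficients, "embodied")
  bd[c("field_id", "system", "embodied")]
}

#' Crop nitrogen uptake from grain yield
#'
#' Aboveground N uptake inferred from yield via the harvest index and
#' grain/straw N concentrations:
#' `dry yield x 1000 x (grain_n + straw_n x (1 - HI) / HI)` with
#' `dry yield = yield x (1 - grain_moisture)`.
#'
#' @param yield Grain yield, Mg/ha at the stated moisture.
#' @param coeffs A `coefficient_set`.
#' @return kg N/ha.
#' @export
crop_n_uptake <- function(yield, coeffs = default_coefficients()) {
  if (any(yield < 0)) {
    stop("yield must be >= 0", call. = FALSE)
  }
  hi <- coeffs$harvest_index
  dry <- yield * (1 - coeffs$grain_moisture)
  dry * 1000 * (coeffs$grain_n_conc + coeffs$straw_n_conc * (1 - hi) / hi)
}

#' Direct N2O emission from the nitrogen surplus
#'
#' The N surplus (applied N minus crop N uptake, kg N/ha) drives direct
#' N2O-N emission through either an exponential response
#' `a * exp(b * surplus)` (default) or a linear one
#' `max(0, a + b * surplus)`; the result is converted to N2O mass by
#' 44/28. A negative surplus is passed to the response function as is
#' unless `n2o_surplus_floor` is set in the coefficient set.
#'
#' @param n_surplus N surplus, kg N/ha (may be negative).
#' @param coeffs A `coefficient_set`.
#' @return kg N2O/ha.
#' @export
direct_n2o <- function(n_surplus, coeffs = default_coefficients()) {
  if (!is.null(coeffs$n2o_surplus_floor)) {
    n_surplus <- pmax(n_surplus, coeffs$n2o_surplus_floor)
  }
  n2o_n <- switch(coeffs$n2o_form,
    exponential = coeffs$n2o_a * exp(coeffs$n2o_b * n_surplus),
    linear = pmax(0, coeffs$n2o_a + coeffs$n2o_b * n_surplus)
  )
  n2o_n * 44 / 28
}

#' Total (direct + indirect) N2O emission
#'
#' Indirect N2O is taken as a fixed fraction of direct emission (default
#' 20%).
#'
#' @param direct Direct N2O, kg/ha (must be non-negative).
#' @param coeffs A `coefficient_set`.
#' @return kg N2O/ha.
#' @export
total_n2o <- function(direct, coeffs = default_coefficients()) {
  if (any(direct < 0)) {
    stop("direct N2O must be >= 0", call. = FALSE)
  }
  direct * (1 + coeffs$indirect_n2o_fraction)
}

#' CH4 emission of one rice crop cycle
#'
#' `daily emission factor x flooded duration x water-regime scaling x
#' organic-amendment scaling`. The default daily factor is 1.3 kg
#' CH4/ha/day for a continuously flooded cycle.
#'
#' @param duration Crop-cycle duration, days (> 0).
#' @param water_regime,organic_amendment Class names present in the
#'   coefficient set's `sf_water` / `sf_organic` maps.
#' @param coeffs A `coefficient_set`.
#' @return kg CH4/ha for the cycle.
#' @export
ch4_emission <- function(duration, water_regime, organic_amendment = "none",
                         coeffs = default_coefficients()) {
  if (any(duration <= 0)) {
    stop("duration must be > 0", call. = FALSE)
  }
  bad_w <- setdiff(unique(water_regime), names(coeffs$sf_water))
  if (length(bad_w) > 0) {
    stop("unknown water-regime class: ", paste(bad_w, collapse = ", "),
         call. = FALSE)
  }
  bad_o <- setdiff(unique(organic_amendment), names(coeffs$sf_organic))
  if (length(bad_o) > 0) {
    stop("unknown organic-amendment class: ", paste(bad_o, collapse = ", "),
         call. = FALSE)
  }
  coeffs$ch4_daily_ef * duration *
    coeffs$sf_water[water_regime] * coeffs$sf_organic[organic_amendment]
}

#' Global warming potential of the three gas components
#'
#' `GWP = embodied CO2e + gwp_ch4 x CH4 + gwp_n2o x N2O`, with the
#' 100-year factors 1:25:298 in the default set.
#'
#' @param embodied kg CO2e/ha.
#' @param ch4 kg CH4/ha.
#' @param n2o kg N2O/ha (total, direct + indirect).
#' @param coeffs A `coefficient_set`.
#' @return kg CO2e/ha.
#' @export
gwp <- function(embodied, ch4, n2o, coeffs = default_coefficients()) {
  if (any(embodied < 0) || any(ch4 < 0) || any(n2o < 0)) {
    stop("GWP components must be >= 0", call. = FALSE)
  }
  embodied + coeffs$gwp_ch4 * ch4 + coeffs$gwp_n2o * n2o
}

#' Yield-scaled global warming potential (GHG intensity)
#'
#' @param gwp kg CO2e/ha/yr.
#' @param annual_yield Mg/ha/yr (> 0).
#' @return kg CO2e per Mg grain.
#' @export
gwpi <- function(gwp, annual_yield) {
  if (any(annual_yield <= 0)) {
    stop("annual_yield must be > 0 to form GWPi", call. = FALSE)
  }
  gwp / annual_yield
}

# per-field annual CH4 and N2O gas totals (kg gas/ha/yr); N2O and CH4 are
# evaluated per crop cycle and summed, with the cycle N surplus formed
# from the cycle's applied N and yield-inferred uptake
ghg_gas_totals <- function(survey, coeffs) {
  n_in <- survey$n_rate + manure_n_rate(survey, coeffs)
  cyc <- tibble::tibble(
    field_id = survey$field_id,
    system = survey$system,
    ch4 = ch4_emission(survey$duration, survey$water_regime,
                       survey$organic_amendment, coeffs),
    n_surplus = n_in - crop_n_uptake(survey$grain_yield, coeffs)
  )
  cyc$n2o_direct <- direct_n2o(cyc$n_surplus, coeffs)
  cyc |>
    dplyr::group_by(.data$field_id, .data$system) |>
    dplyr::summarise(
      ch4 = sum(.data$ch4),
      n2o_direct = sum(.data$n2o_direct),
      n_surplus = sum(.data$n_surplus),
      .groups = "drop"
    ) |>
    dplyr::mutate(n2o_total = total_n2o(.data$n2o_direct, coeffs))
}

# manure N per cycle (kg N/ha); the survey may carry an optional manure_n
# column, otherwise zero
manure_n_rate <- function(survey, coeffs) {
  if ("manure_n" %in% names(survey)) survey$manure_n else 0
}

#' Per-field annual nitrogen budget
#'
#' @inheritParams energy_input
#' @return A tibble with one row per field: `n_input`, `n_uptake` and
#'   `n_surplus = n_input - n_uptake` (kg N/ha/yr; the surplus may be
#'   negative).
#' @export
n_budget <- function(survey, coeffs = default_coefficients()) {
  tibble::tibble(
    field_id = survey$field_id,
    system = survey$system,
    n_input = survey$n_rate + manure_n_rate(survey, coeffs),
    n_uptake = crop_n_uptake(survey$grain_yield, coeffs)
  ) |>
    dplyr::group_by(.data$field_id, .data$system) |>
    dplyr::summarise(
      n_input = sum(.data$n_input),
      n_uptake = sum(.data$n_uptake),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_surplus = .data$n_input - .data$n_uptake)
}

#' Per-field annual greenhouse-gas inventory
#'
#' Combines the three emission sources — embodied input emissions,
#' N-surplus driven N2O (direct + indirect) and flooded-paddy CH4 — into
#' the annual GWP and its yield-scaled intensity. N2O and CH4 are computed
#' per crop cycle and summed to annual values. Soil C sequestration,
#' non-growing-season fluxes and biological N2 fixation are outside the
#' inventory boundary.
#'
#' @inheritParams energy_input
#' @return A tibble with one row per field: `embodied` (kg CO2e),
#'   `n2o_direct`, `n2o_total` (kg N2O), `ch4` (kg CH4), `gwp`
#'   (kg CO2e/ha/yr) and `gwpi` (kg CO2e/Mg).
#' @export
ghg_inventory <- function(survey, coeffs = default_coefficients()) {
  emb <- embodied_ghg(survey, coeffs)
  gas <- ghg_gas_totals(survey, coeffs)
  ann <- annual_rates(survey)
  out <- emb |>
    dplyr::inner_join(gas[c("field_id", "n2o_direct", "n2o_total", "ch4")],
                      by = "field_id") |>
    dplyr::inner_join(ann[c("field_id", "annual_yield")], by = "field_id")
  out$gwp <- gwp(out$embodied, out$ch4, out$n2o_total, coeffs)
  out$gwpi <- gwpi(out$gwp, out$annual_yield)
  out[c("field_id", "system", "embodied", "n2o_direct", "n2o_total",
        "ch4", "gwp", "gwpi")]
}
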