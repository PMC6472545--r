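#' Per-field indicator table
#'
#' Runs the full accounting for every field: energy balance, GHG
#' inventory, economics and input-use efficiencies.
#'
#' @param survey A survey tibble.
#' @param coeffs A `coefficient_set`.
#' @param prices A `price_set`.
#' @return A tibble with one row per field: `field_id`, `system`,
#'   `annual_yield` (Mg/ha), `energy_input`, `energy_output`, `ney`
#'   (GJ/ha/yr), `ner`, `gwp` (kg CO2e/ha/yr), `gwpi` (kg CO2e/Mg),
#'   `gross_income`, `production_cost`, `net_return` ($/ha/yr),
#'   `benefit_cost`, `npl` ($/h), `eco_efficiency` ($/Mg CO2e), `lp`
#'   (kg/h), `pfp_n` (kg/kg), `iwp` (kg/m3).
#' @export
compute_indicators <- function(survey,
                               coeffs = default_coefficients(),
                               prices = default_prices()) {
  if (nrow(survey) == 0) {
    stop("no records in survey", call. = FALSE)
  }
  ann <- annual_rates(survey)
  en <- energy_input(survey, coeffs)
  gh <- ghg_inventory(survey, coeffs)
  gi <- gross_income(survey, prices)
  pc <- production_cost(survey, prices)
  ef <- input_efficiencies(survey)

  out <- ann[c("field_id", "system", "annual_yield", "labor")] |>
    dplyr::inner_join(en[c("field_id", "energy_input")], by = "field_id") |>
    dplyr::inner_join(gh[c("field_id", "gwp", "gwpi")], by = "field_id") |>
    dplyr::inner_join(gi[c("field_id", "gross_income")], by = "field_id") |>
    dplyr::inner_join(pc[c("field_id", "production_cost")], by = "field_id") |>
    dplyr::inner_join(ef[c("field_id", "lp", "pfp_n", "iwp")],
                      by = "field_id")
  out$energy_output <- energy_output(out$annual_yield, coeffs)
  out$ney <- net_energy_yield(out$energy_output, out$energy_input)
  out$ner <- net_energy_ratio(out$energy_output, out$energy_input)
  out$net_return <- net_return(out$gross_income, out$production_cost)
  out$benefit_cost <- benefit_cost(out$gross_income, out$production_cost)
  out$npl <- npl(out$net_return, out$labor)
  out$eco_efficiency <- eco_efficiency(out$net_return, out$gwp)
  out[c("field_id", "system", "annual_yield", "energy_input",
        "energy_output", "ney", "ner", "gwp", "gwpi", "gross_income",
        "production_cost", "net_return", "benefit_cost", "npl",
        "eco_efficiency", "lp", "pfp_n", "iwp")]
}

#' End-to-end analysis pipeline
#'
#' From a survey (tibble or CSV path) computes the per-field indicator
#' table, the per-system input/efficiency table, the six-statistic
#' distribution summaries with LSD letters, and the within-system and
#' pooled linear regressions (energy output ~ energy input,
#' annual yield ~ GWP, gross income ~ production cost). When `out_dir`
#' is given, each table is also written there as CSV
#' (`indicators.csv`, `input_table.csv`, `system_summary.csv`,
#' `regressions.csv`). Every summary number is recomputable from the
#' per-field indicator table. The pipeline is a pure function of the
#' survey and configuration.
#'
#' @param survey A survey tibble or a path to a survey CSV.
#' @param coeffs A `coefficient_set`.
#' @param prices A `price_set`.
#' @param out_dir Optional output directory for the report CSVs.
#' @param alpha Significance level of the LSD letters.
#' @return A list with elements `indicators`, `input_table`, `summary`,
#'   `regressions`, invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(survey,
                         coeffs = default_coefficients(),
                         prices = default_prices(),
                         out_dir = NULL,
                         alpha = 0.05) {
  if (is.character(survey)) {
    survey <- read_survey(survey)
  }
  if (nrow(survey) == 0) {
    stop("no records in survey", call. = FALSE)
  }

  ind <- with_stage("indicators", compute_indicators(survey, coeffs, prices))

  input_table <- with_stage("input_table", {
    ann <- annual_rates(survey)
    sh <- energy_shares(energy_input(survey, coeffs))
    mean_rates <- ann |>
      dplyr::group_by(.data$system) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(rate_columns()), mean),
                       .groups = "drop")
    mean_shares <- sh |>
      dplyr::group_by(.data$system) |>
      dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean),
                       .groups = "drop")
    effs <- ind |>
      dplyr::group_by(.data$system) |>
      dplyr::summarise(
        energy_input = mean(.data$energy_input),
        lp = mean(.data$lp, na.rm = TRUE),
        npl = mean(.data$npl),
        pfp_n = mean(.data$pfp_n, na.rm = TRUE),
        iwp = mean(.data$iwp, na.rm = TRUE),
        .groups = "drop"
      )
    list(rates = mean_rates, shares = mean_shares, efficiencies = effs)
  })

  summary_vars <- c("annual_yield", "energy_input", "energy_output", "ney",
                    "ner", "gwp", "gwpi", "production_cost", "net_return",
                    "benefit_cost", "eco_efficiency")
  smry <- with_stage("summary",
                     summarize_systems(ind, summary_vars, alpha = alpha))

  regressions <- with_stage("regressions", {
    reg_specs <- list(
      c(y = "energy_output", x = "energy_input"),
      c(y = "annual_yield", x = "gwp"),
      c(y = "gross_income", x = "production_cost")
    )
    res <- list()
    for (sp in reg_specs) {
      for (scope in c("MR", "DR", "RR", "pooled")) {
        sub <- if (scope == "pooled") ind else ind[ind$system == scope, ]
        fit <- fit_linear(sub[[sp[["x"]]]], sub[[sp[["y"]]]])
        fit$response <- sp[["y"]]
        fit$predictor <- sp[["x"]]
        fit$scope <- scope
        res[[length(res) + 1]] <- fit
      }
    }
    dplyr::bind_rows(res)[, c("response", "predictor", "scope", "slope",
                              "intercept", "r_squared", "slope_p_value",
                              "n")]
  })

  result <- list(indicators = ind, input_table = input_table,
                 summary = smry, regressions = regressions)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) {
      dir.create(out_dir, recursive = TRUE)
    }
    readr::write_csv(ind, file.path(out_dir, "indicators.csv"),
                     progress = FALSE)
    it <- dplyr::left_join(
      input_table$rates, input_table$efficiencies, by = "system",
      suffix = c("", "_eff")
    )
    readr::write_csv(it, file.path(out_dir, "input_table.csv"),
                     progress = FALSE)
    readr::write_csv(smry, file.path(out_dir, "system_summary.csv"),
                     progress = FALSE)
    readr::write_csv(regressions, file.path(out_dir, "regressions.csv"),
                     progress = FALSE)
    return(invisible(result))
  }
  result
}

# attach the stage name to any error raised inside a pipeline stage
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}
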