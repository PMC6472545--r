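#' Per-field annual fossil-energy input
#'
#' Sums `rate x energy equivalent` over all input categories and crop
#' cycles of each field. Includes human labor. Energy inputs cover the
#' fossil energy embodied in manufacturing, packaging and transporting
#' inputs plus fuel used directly for field operations and irrigation
#' pumping.
#'
#' @param survey A survey tibble (see [read_survey()]).
#' @param coeffs A `coefficient_set`; defaults to the calibrated packaged
#'   set.
#' @return A tibble with one row per field: `field_id`, `system`, one
#'   column per input category (GJ/ha/yr) and the total `energy_input`
#'   (GJ/ha/yr).
#' @export
energy_input <- function(survey, coeffs = default_coefficients()) {
  ann <- annual_rates(survey)
  breakdown_from_rates(ann, coeffs$energy_equivalents, "energy_input",
                       scale = 1 / 1000)   # MJ -> GJ
}

# shared rate-x-coefficient aggregation; errors name a category that has a
# non-zero rate but no coefficient
breakdown_from_rates <- function(ann, coef_map, total_name, scale = 1) {
  cats <- rate_columns()
  missing <- setdiff(cats, names(coef_map))
  if (length(missing) > 0) {
    nonzero <- vapply(missing, function(cc) any(ann[[cc]] != 0), logical(1))
    if (any(nonzero)) {
      stop("no coefficient for non-zero input category: ",
           paste(missing[nonzero], collapse = ", "), call. = FALSE)
    }
    cats <- setdiff(cats, missing)
  }
  out <- ann[c("field_id", "system")]
  for (cc in cats) {
    out[[cc]] <- ann[[cc]] * coef_map[[cc]] * scale
  }
  out[[total_name]] <- rowSums(as.matrix(out[cats]))
  tibble::as_tibble(out)
}

#' Category shares of total energy input
#'
#' @param breakdown Output of [energy_input()].
#' @return A tibble with the same rows, each category column expressed as
#'   a fraction of the field total (rows sum to 1; all-zero fields give
#'   zero shares).
#' @export
energy_shares <- function(breakdown) {
  cats <- intersect(rate_columns(), names(breakdown))
  out <- breakdown[c("field_id", "system")]
  tot <- breakdown$energy_input
  for (cc in cats) {
    out[[cc]] <- ifelse(tot > 0, breakdown[[cc]] / tot, 0)
  }
  out
}

#' Grain energy output
#'
#' @param annual_yield Annual grain yield, Mg/ha at 14% moisture.
#' @param coeffs A `coefficient_set` (uses `grain_energy_content`, MJ/kg).
#' @return Energy output, GJ/ha/yr.
#' @export
energy_output <- function(annual_yield, coeffs = default_coefficients()) {
  if (any(annual_yield < 0)) {
    stop("annual_yield must be >= 0", call. = FALSE)
  }
  annual_yield * coeffs$grain_energy_content   # Mg * MJ/kg = GJ/ha
}

#' Net energy yield
#'
#' `NEY = energy output - energy input` (GJ/ha/yr); may be negative.
#'
#' @param output,input Energy output and input, GJ/ha/yr.
#' @return GJ/ha/yr.
#' @export
net_energy_yield <- function(output, input) {
  output - input
}

#' Net energy ratio
#'
#' `NER = energy output / energy input` (dimensionless).
#'
#' @param output,input Energy output and input, GJ/ha/yr; `input` must be
#'   positive.
#' @return Dimensionless ratio.
#' @export
net_energy_ratio <- function(output, input) {
  if (any(input <= 0)) {
    stop("energy input must be > 0 to form NER", call. = FALSE)
  }
  output / input
}
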