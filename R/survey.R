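#' Read a per-field rice survey from a delimited text file
#'
#' A survey has one row per field-cycle: the cropping system (`MR`, `DR`,
#' `RR`), the cycle label (`MR`, `DR_early`, `DR_late`, `RR_main`,
#' `RR_ratoon`), grain yield (Mg/ha at 14% moisture) and the per-cycle
#' input rates. Rows are validated and grouped into field records by
#' `field_id`; a field must carry exactly the cycle set of its system.
#'
#' Required columns: `field_id`, `system`, `cycle_label`, `grain_yield`,
#' `n_rate`, `p_rate`, `k_rate`, `irrigation`, `seed`, `pesticide`,
#' `diesel`, `machinery`, `labor`. Optional columns filled with defaults
#' when absent: `plastic_film` (0 kg/ha), `electricity` (0 kWh/ha),
#' `duration` (days, per-cycle default), `water_regime` and
#' `organic_amendment` (per-cycle default classes).
#'
#' @param path Path to a CSV (or TSV) file with a header row.
#' @param schema Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(grain_yield = "yield_Mg_ha")`.
#' @return A validated survey tibble of class `rice_survey`.
#' @export
read_survey <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    stop("survey file not found: ", path, call. = FALSE)
  }
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  # base strtod parsing round-trips doubles written at 17 significant
  # digits exactly
  df <- utils::read.csv(path, sep = delim, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(df)) {
        stop("schema maps '", canon, "' to missing column '", schema[[canon]],
             "'", call. = FALSE)
      }
      names(df)[names(df) == schema[[canon]]] <- canon
    }
  }
  surv <- as_survey(df)
  message(dplyr::n_distinct(surv$field_id), " field records (",
          nrow(surv), " field-cycles) read from ", path)
  surv
}

#' Write a survey to CSV
#'
#' Numeric fields are written at full precision, so
#' `read_survey(write_survey(x, f))` round-trips exactly.
#'
#' @param survey A survey tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path) {
  out <- as.data.frame(survey)
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      # 17 significant digits guarantee exact double round-trip
      out[[col]] <- sprintf("%.17g", out[[col]])
    }
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Coerce and validate a data frame of field-cycle rows
#'
#' Fills optional columns with their defaults, checks every row against the
#' cycle invariants (non-negative quantities, positive yield and duration,
#' no seed on the ratoon crop) and every field against its system's cycle
#' set. Errors name the offending column or `field_id`.
#'
#' @param df A data frame with one row per field-cycle.
#' @return A survey tibble of class `rice_survey`.
#' @export
as_survey <- function(df) {
  required <- c("field_id", "system", "cycle_label", "grain_yield",
                "n_rate", "p_rate", "k_rate", "irrigation", "seed",
                "pesticide", "diesel", "machinery", "labor")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required survey column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  cyc <- reference_cycles()
  if (!"plastic_film" %in% names(df)) df$plastic_film <- 0
  if (!"electricity" %in% names(df)) df$electricity <- 0
  idx <- match(df$cycle_label, cyc$cycle_label)
  if (!"duration" %in% names(df)) df$duration <- cyc$duration[idx]
  if (!"water_regime" %in% names(df)) df$water_regime <- cyc$water_regime[idx]
  if (!"organic_amendment" %in% names(df)) {
    df$organic_amendment <- cyc$organic_amendment[idx]
  }
  validate_survey(df)
  class(df) <- c("rice_survey", class(df))
  df
}

#' @rdname as_survey
#' @param survey A survey data frame to check.
#' @return `survey`, invisibly, if valid; otherwise an error.
#' @export
validate_survey <- function(survey) {
  sets <- system_cycle_sets()
  bad_sys <- setdiff(unique(survey$system), names(sets))
  if (length(bad_sys) > 0) {
    stop("unknown cropping system(s): ", paste(bad_sys, collapse = ", "),
         call. = FALSE)
  }
  bad_cyc <- setdiff(unique(survey$cycle_label), unlist(sets))
  if (length(bad_cyc) > 0) {
    stop("unknown cycle label(s): ", paste(bad_cyc, collapse = ", "),
         call. = FALSE)
  }

  num_cols <- c("grain_yield", rate_columns(), "duration")
  for (col in num_cols) {
    v <- survey[[col]]
    if (!is.numeric(v)) {
      stop("survey column '", col, "' must be numeric", call. = FALSE)
    }
    bad <- !is.finite(v) | v < 0
    if (any(bad)) {
      stop("negative or non-finite '", col, "' for field_id ",
           paste(unique(survey$field_id[bad]), collapse = ", "),
           call. = FALSE)
    }
  }
  zero_yield <- survey$grain_yield <= 0
  if (any(zero_yield)) {
    stop("grain_yield must be > 0; violated for field_id ",
         paste(unique(survey$field_id[zero_yield]), collapse = ", "),
         call. = FALSE)
  }
  zero_dur <- survey$duration <= 0
  if (any(zero_dur)) {
    stop("duration must be > 0; violated for field_id ",
         paste(unique(survey$field_id[zero_dur]), collapse = ", "),
         call. = FALSE)
  }
  ratoon_seed <- survey$cycle_label == "RR_ratoon" & survey$seed != 0
  if (any(ratoon_seed)) {
    stop("RR_ratoon cycles must have seed = 0 (the ratoon crop is not ",
         "sown); violated for field_id ",
         paste(unique(survey$field_id[ratoon_seed]), collapse = ", "),
         call. = FALSE)
  }

  by_field <- split(survey, survey$field_id)
  for (fid in names(by_field)) {
    rec <- by_field[[fid]]
    sys <- unique(rec$system)
    if (length(sys) != 1) {
      stop("field_id ", fid, " is assigned to more than one system",
           call. = FALSE)
    }
    want <- sort(sets[[sys]])
    have <- sort(rec$cycle_label)
    if (!identical(want, have)) {
      stop("field_id ", fid, " (", sys, ") must have cycle set {",
           paste(want, collapse = ", "), "} but has {",
           paste(have, collapse = ", "), "}", call. = FALSE)
    }
  }
  invisible(survey)
}

#' Annual per-field input rates and yield
#'
#' Sums the per-cycle rates and grain yield of each field over its crop
#' cycles, giving annual (per calendar year) quantities.
#'
#' @param survey A survey tibble.
#' @return A tibble with one row per field: `field_id`, `system`,
#'   `annual_yield` (Mg/ha) and the annual input-rate columns.
#' @export
annual_rates <- function(survey) {
  survey |>
    dplyr::group_by(.data$field_id, .data$system) |>
    dplyr::summarise(
      annual_yield = sum(.data$grain_yield),
      dplyr::across(dplyr::all_of(rate_columns()), sum),
      .groups = "drop"
    )
}
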