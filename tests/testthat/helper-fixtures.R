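# hand-built minimal surveys used across tests

# one MR field and one RR field (3 rows), all quantities chosen round
tiny_survey_df <- function() {
  data.frame(
    field_id = c("F1", "F2", "F2"),
    system = c("MR", "RR", "RR"),
    cycle_label = c("MR", "RR_main", "RR_ratoon"),
    grain_yield = c(7.7, 7.5, 5.7),
    n_rate = c(226, 231, 111),
    p_rate = c(139, 72, 35),
    k_rate = c(197, 120, 58),
    irrigation = c(2423, 2226, 1068),
    seed = c(55, 26, 0),
    pesticide = c(3.3, 2.0, 1.0),
    diesel = c(63, 62, 30),
    machinery = c(1448, 1484, 712),
    labor = c(172, 420, 152),
    duration = c(120, 125, 60),
    water_regime = c("continuous", "continuous", "intermittent"),
    organic_amendment = c("none", "none", "none"),
    stringsAsFactors = FALSE
  )
}

tiny_survey <- function() as_survey(tiny_survey_df())

# a single-field MR survey with specified annual rates
mr_field <- function(rates, yield = 7.7, duration = 120,
                     water = "continuous", organic = "none") {
  defaults <- c(n_rate = 0, p_rate = 0, k_rate = 0, irrigation = 0,
                seed = 0, pesticide = 0, diesel = 0, machinery = 0,
                labor = 0)
  defaults[names(rates)] <- rates
  df <- data.frame(
    field_id = "M1", system = "MR", cycle_label = "MR",
    grain_yield = yield, duration = duration, water_regime = water,
    organic_amendment = organic, stringsAsFactors = FALSE
  )
  for (nm in names(defaults)) df[[nm]] <- defaults[[nm]]
  as_survey(df)
}
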