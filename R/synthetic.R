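#' Configuration for the synthetic farm-survey generator
#'
#' Encodes the study conditions the generator emulates: per-system mean
#' annual input rates and cycle yields, dispersion targets (coefficient of
#' variation of total energy input and of annual yield) and the
#' within-system r-squared of the energy output~input relationship.
#' Defaults are the published benchmark values (80 fields per system;
#' energy-input CVs 6/6/3%, yield CVs 5/4/4%, r-squared 0.46/0.27/0.56
#' for MR/DR/RR).
#'
#' @param n_fields Fields per cropping system.
#' @param means Per-system mean rates and yield
#'   ([reference_system_means()]).
#' @param cycles Per-cycle structure ([reference_cycles()]).
#' @param targets Dispersion and correlation targets
#'   ([reference_targets()]).
#' @param latent_loading Loading of the field-level management-intensity
#'   factor shared by all input categories (0 = independent inputs,
#'   1 = perfectly correlated). Default 0.7.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_fields = 80,
                             means = reference_system_means(),
                             cycles = reference_cycles(),
                             targets = reference_targets(),
                             latent_loading = 0.7) {
  if (n_fields < 2) {
    stop("n_fields must be >= 2", call. = FALSE)
  }
  if (latent_loading < 0 || latent_loading > 1) {
    stop("latent_loading must lie in [0, 1]", call. = FALSE)
  }
  if (any(targets$energy_input_cv <= 0) || any(targets$yield_cv <= 0)) {
    stop("CV targets must be > 0", call. = FALSE)
  }
  if (any(targets$output_input_r2 <= 0) || any(targets$output_input_r2 >= 1)) {
    stop("r-squared targets must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(n_fields = n_fields, means = means, cycles = cycles,
         targets = targets, latent_loading = latent_loading),
    class = "generator_config"
  )
}

#' Generate a synthetic farm survey
#'
#' Draws per-field annual input rates from truncated-normal distributions
#' around the per-system means, correlated through a single field-level
#' management-intensity factor, with the common relative spread chosen in
#' closed form so the total fossil-energy input hits the target CV. The
#' annual yield is then generated as linear in the field's energy input
#' plus Gaussian noise, with slope and noise variance solved from the
#' target yield CV and output~input r-squared. Annual quantities are split
#' across crop cycles in proportion to cycle duration, except seed (only
#' sown cycles) and labor (fixed establishment hours: transplanting 247
#' h/ha, direct seeding 28 h/ha, none for the ratoon crop, remainder by
#' duration). Deterministic given `seed`.
#'
#' @param n_fields Fields per system (overrides the config).
#' @param seed Integer seed; all randomness derives from it.
#' @param config A `generator_config`.
#' @param coeffs Coefficient set used to translate input rates into energy
#'   (the calibrated packaged set by default).
#' @return A validated survey tibble with `3 * n_fields` field records.
#' @export
generate_survey <- function(n_fields = NULL,
                            seed = 1L,
                            config = generator_config(),
                            coeffs = default_coefficients()) {
  if (!is.null(n_fields)) {
    config$n_fields <- n_fields
  }
  n <- config$n_fields
  lam <- config$latent_loading
  cats <- setdiff(rate_columns(), c("plastic_film", "electricity"))
  ee <- coeffs$energy_equivalents

  withr::with_seed(seed, {
    rows <- list()
    for (sys in c("MR", "DR", "RR")) {
      m <- config$means[config$means$system == sys, ]
      tg <- config$targets[config$targets$system == sys, ]
      sys_cyc <- config$cycles[config$cycles$system == sys, ]
      mu <- unlist(m[cats])

      # theoretical energy mean/shares at the system mean rates
      w <- mu * ee[cats] / 1000                 # GJ per category
      e_mean <- sum(w)
      sh <- w / e_mean
      # common relative spread so that total energy input has the target
      # CV under the equicorrelated (latent-factor) rate model
      cv_e <- tg$energy_input_cv / 100
      sigma_r <- cv_e / sqrt(lam^2 + (1 - lam^2) * sum(sh^2))

      z <- stats::rnorm(n)                      # management intensity
      rates <- matrix(0, n, length(cats), dimnames = list(NULL, cats))
      for (cc in cats) {
        repeat {
          eps <- stats::rnorm(n)
          val <- mu[[cc]] * (1 + sigma_r * (lam * z + sqrt(1 - lam^2) * eps))
          if (all(val > 0)) break               # truncation at zero
        }
        rates[, cc] <- val
      }
      e_field <- drop(rates %*% ee[cats]) / 1000

      # yield linear in energy input: slope and noise solved from the
      # yield CV and the output~input r-squared
      y_mean <- sum(sys_cyc$yield)
      sd_y <- tg$yield_cv / 100 * y_mean
      sd_e <- cv_e * e_mean
      slope <- sd_y * sqrt(tg$output_input_r2) / sd_e
      sd_noise <- sd_y * sqrt(1 - tg$output_input_r2)
      yield <- y_mean + slope * (e_field - e_mean) +
        stats::rnorm(n, 0, sd_noise)
      yield <- pmax(yield, 0.05 * y_mean)       # guard, never binds in practice

      cyc_frac <- sys_cyc$yield / sum(sys_cyc$yield)
      dur_frac <- sys_cyc$duration / sum(sys_cyc$duration)
      est <- c(direct_seeded = 28, transplanted = 247,
               ratoon = 0)[sys_cyc$establishment]
      labor_rem <- pmax(0, rates[, "labor"] - sum(est))
      for (ci in seq_len(nrow(sys_cyc))) {
        lab <- sys_cyc$cycle_label[ci]
        seed_frac <- split_fraction(lab, "seed", dur_frac[ci])
        labor_cyc <- est[ci] + labor_rem * dur_frac[ci]
        rows[[length(rows) + 1]] <- tibble::tibble(
          field_id = sprintf("%s_%03d", sys, seq_len(n)),
          system = sys,
          cycle_label = lab,
          grain_yield = yield * cyc_frac[ci],
          n_rate = rates[, "n_rate"] * dur_frac[ci],
          p_rate = rates[, "p_rate"] * dur_frac[ci],
          k_rate = rates[, "k_rate"] * dur_frac[ci],
          irrigation = rates[, "irrigation"] * dur_frac[ci],
          seed = rates[, "seed"] * seed_frac,
          pesticide = rates[, "pesticide"] * dur_frac[ci],
          diesel = rates[, "diesel"] * dur_frac[ci],
          machinery = rates[, "machinery"] * dur_frac[ci],
          plastic_film = 0,
          electricity = 0,
          labor = labor_cyc,
          duration = sys_cyc$duration[ci],
          water_regime = sys_cyc$water_regime[ci],
          organic_amendment = sys_cyc$organic_amendment[ci]
        )
      }
    }
    survey <- dplyr::bind_rows(rows) |>
      dplyr::arrange(.data$field_id, .data$cycle_label)
    as_survey(survey)
  })
}
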