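test_that("the generator yields 80 valid records per system, deterministically", {
  sv <- generate_survey(seed = 1)
  expect_equal(dplyr::n_distinct(sv$field_id), 240)
  counts <- table(unique(sv[c("field_id", "system")])$system)
  expect_equal(unname(counts[c("MR", "DR", "RR")]), c(80L, 80L, 80L),
               ignore_attr = TRUE)
  expect_silent(validate_survey(sv))

  sv2 <- generate_survey(seed = 1)
  expect_identical(sv, sv2)
  sv3 <- generate_survey(seed = 2)
  expect_false(identical(sv, sv3))
})

test_that("generated files round-trip byte-identically for the same seed", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_survey(generate_survey(n_fields = 10, seed = 4), f1)
  write_survey(generate_survey(n_fields = 10, seed = 4), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("per-system means and dispersion track the configured targets", {
  sv <- generate_survey(seed = 17)
  ind <- compute_indicators(sv)
  tg <- reference_targets()
  means <- reference_system_means()
  for (s in c("MR", "DR", "RR")) {
    sub <- ind[ind$system == s, ]
    t_s <- tg[tg$system == s, ]
    m_s <- means[means$system == s, ]
    # mean annual yield within 2 standard errors of the target
    se <- t_s$yield_cv / 100 * m_s$yield / sqrt(nrow(sub))
    expect_lt(abs(mean(sub$annual_yield) - m_s$yield), 2.5 * se)
    # energy-input CV within +-50% of the target at n = 80
    cv_hat <- 100 * sd(sub$energy_input) / mean(sub$energy_input)
    expect_gt(cv_hat, 0.5 * t_s$energy_input_cv)
    expect_lt(cv_hat, 1.5 * t_s$energy_input_cv)
  }
})

test_that("a large run reproduces the configured population values", {
  sv <- generate_survey(n_fields = 4000, seed = 23)
  ind <- compute_indicators(sv)
  rr <- ind[ind$system == "RR", ]
  expect_lt(abs(mean(rr$annual_yield) / 13.2 - 1), 0.005)

  tg <- reference_targets()
  for (s in c("MR", "DR", "RR")) {
    sub <- ind[ind$system == s, ]
    t_s <- tg[tg$system == s, ]
    cv_hat <- 100 * sd(sub$energy_input) / mean(sub$energy_input)
    expect_equal(cv_hat, t_s$energy_input_cv, tolerance = 0.05)
    r2_hat <- fit_linear(sub$energy_input, sub$energy_output)$r_squared
    expect_lt(abs(r2_hat - t_s$output_input_r2), 0.05)
  }
})

test_that("the output~input regression recovers the configured slope", {
  cfg <- generator_config()
  cs <- default_coefficients()
  sv <- generate_survey(n_fields = 500, seed = 29, config = cfg)
  ind <- compute_indicators(sv)
  tg <- reference_targets()
  means <- reference_system_means()
  for (s in c("MR", "DR", "RR")) {
    sub <- ind[ind$system == s, ]
    t_s <- tg[tg$system == s, ]
    m_s <- means[means$system == s, ]
    # configured population slope in output units
    sd_y <- t_s$yield_cv / 100 * m_s$yield
    sd_e <- t_s$energy_input_cv / 100 * t_s$energy_input
    slope_cfg <- cs$grain_energy_content * sd_y *
      sqrt(t_s$output_input_r2) / sd_e
    fit <- stats::lm(energy_output ~ energy_input, data = sub)
    est <- stats::coef(fit)["energy_input"]
    se <- summary(fit)$coefficients["energy_input", "Std. Error"]
    expect_lt(abs(est - slope_cfg), 2.5 * se)
  }
})

test_that("labor respects the establishment split", {
  sv <- generate_survey(n_fields = 30, seed = 37)
  # the un-sown ratoon cycle has no seed and no establishment labor base
  ratoon <- sv[sv$cycle_label == "RR_ratoon", ]
  expect_true(all(ratoon$seed == 0))
  main <- sv[sv$cycle_label == "RR_main", ]
  expect_true(all(main$labor >= 247))
  dr <- sv[sv$cycle_label %in% c("DR_early", "DR_late"), ]
  expect_true(all(dr$labor >= 247))
  mr <- sv[sv$cycle_label == "MR", ]
  expect_true(all(mr$labor >= 28))
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(n_fields = 1), "n_fields")
  expect_error(generator_config(latent_loading = 1.5), "latent_loading")
  tg <- reference_targets()
  tg$output_input_r2[1] <- 1.2
  expect_error(generator_config(targets = tg), "r-squared")
  tg2 <- reference_targets()
  tg2$energy_input_cv[2] <- 0
  expect_error(generator_config(targets = tg2), "CV")
})
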