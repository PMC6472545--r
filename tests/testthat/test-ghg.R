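test_that("crop N uptake follows the harvest-index partition", {
  cs <- default_coefficients()
  # 7.7 Mg at 14% moisture, HI 0.5, grain N 1.1%, straw N 0.7%:
  # 7.7 * 0.86 * 1000 * (0.011 + 0.007) = 119.196 kg N
  expect_equal(crop_n_uptake(7.7, cs), 119.196, tolerance = 1e-9)
  expect_equal(crop_n_uptake(0, cs), 0)
  y <- seq(1, 15, by = 0.5)
  expect_true(all(diff(crop_n_uptake(y, cs)) > 0))
  bad <- cs
  bad$harvest_index <- 1.2
  expect_error(validate_coefficient_set(bad), "harvest_index")
})

test_that("direct N2O evaluates the exponential surplus response", {
  cs <- default_coefficients()
  expect_equal(direct_n2o(0, cs), 0.54 * 44 / 28, tolerance = 1e-12)
  expect_equal(direct_n2o(100, cs), 0.54 * exp(0.63) * 44 / 28,
               tolerance = 1e-12)
  expect_equal(direct_n2o(100, cs), 1.593, tolerance = 1e-3)
  s <- seq(-50, 300, by = 10)
  expect_true(all(diff(direct_n2o(s, cs)) > 0))

  lin <- cs
  lin$n2o_form <- "linear"
  expect_equal(direct_n2o(10, lin), (0.54 + 0.063) * 44 / 28)
  expect_equal(direct_n2o(-1000, lin), 0)   # linear form floors at zero

  fl <- cs
  fl$n2o_surplus_floor <- 0
  expect_equal(direct_n2o(-50, fl), direct_n2o(0, cs))
})

test_that("total N2O adds the indirect fraction", {
  cs <- default_coefficients()
  expect_equal(total_n2o(1, cs), 1.2)
  expect_equal(total_n2o(0, cs), 0)
  none <- cs
  none$indirect_n2o_fraction <- 0
  expect_equal(total_n2o(0.7, none), 0.7)
  expect_error(total_n2o(-1, cs), ">= 0")
})

test_that("CH4 scales with duration and the regime classes", {
  cs <- default_coefficients()
  expect_equal(unname(ch4_emission(100, "continuous", "none", cs)), 130)
  expect_equal(unname(ch4_emission(100, "nonflooded", "none", cs)), 0)
  expect_equal(unname(ch4_emission(60, "intermittent", "none", cs)),
               1.3 * 60 * 0.52)
  expect_equal(unname(ch4_emission(105, "continuous", "straw", cs)),
               2 * 1.3 * 105)
  expect_error(ch4_emission(100, "swamp", "none", cs), "swamp")
  expect_error(ch4_emission(0, "continuous", "none", cs), "> 0")
})

test_that("GWP combines the three gases with the 1:25:298 factors", {
  cs <- default_coefficients()
  expect_equal(gwp(1000, 100, 1, cs), 1000 + 2500 + 298)
  expect_equal(gwp(0, 0, 0, cs), 0)
  plain <- cs
  plain$gwp_ch4 <- 1
  plain$gwp_n2o <- 1
  expect_equal(gwp(10, 20, 30, plain), 60)
  expect_error(gwp(-1, 0, 0, cs), ">= 0")
})

test_that("GWPi divides GWP by annual yield", {
  expect_equal(gwpi(7211, 7.7), 936.5, tolerance = 1e-3)
  expect_equal(gwpi(9783, 13.2), 741.1, tolerance = 1e-3)
  expect_equal(gwpi(0, 5), 0)
  expect_error(gwpi(100, 0), "> 0")
})

test_that("the inventory decomposition holds exactly per field", {
  cs <- default_coefficients()
  sv <- generate_survey(n_fields = 12, seed = 3)
  inv <- ghg_inventory(sv, cs)
  emb <- embodied_ghg(sv, cs)
  expect_equal(inv$gwp,
               emb$embodied[match(inv$field_id, emb$field_id)] +
                 cs$gwp_ch4 * inv$ch4 + cs$gwp_n2o * inv$n2o_total,
               tolerance = 1e-9)
  expect_equal(inv$n2o_total, 1.2 * inv$n2o_direct, tolerance = 1e-12)
  ann <- annual_rates(sv)
  expect_equal(inv$gwpi * ann$annual_yield[match(inv$field_id,
                                                 ann$field_id)],
               inv$gwp, tolerance = 1e-9)
})

test_that("annual CH4 and N2O are additive over cycles", {
  cs <- default_coefficients()
  sv <- tiny_survey()
  inv <- ghg_inventory(sv, cs)
  rr <- sv[sv$field_id == "F2", ]
  ch4_cycles <- ch4_emission(rr$duration, rr$water_regime,
                             rr$organic_amendment, cs)
  expect_equal(inv$ch4[inv$field_id == "F2"], sum(ch4_cycles),
               tolerance = 1e-12)
  n2o_cycles <- direct_n2o(rr$n_rate - crop_n_uptake(rr$grain_yield, cs), cs)
  expect_equal(inv$n2o_direct[inv$field_id == "F2"], sum(n2o_cycles),
               tolerance = 1e-12)
})

test_that("increasing the N rate weakly increases GWP", {
  cs <- default_coefficients()
  g <- vapply(seq(0, 400, by = 50), function(n) {
    ghg_inventory(mr_field(c(n_rate = n, diesel = 60)), cs)$gwp
  }, numeric(1))
  expect_true(all(diff(g) >= 0))
})

test_that("with unit scaling and no indirect N2O the inventory reduces to the bare sum", {
  cs <- default_coefficients()
  cs$indirect_n2o_fraction <- 0
  cs$sf_water[] <- 1
  cs$sf_organic[] <- 1
  sv <- mr_field(c(n_rate = 200, diesel = 60), duration = 100)
  inv <- ghg_inventory(sv, cs)
  expected_ch4 <- 1.3 * 100
  expected_n2o <- direct_n2o(200 - crop_n_uptake(7.7, cs), cs)
  expected_emb <- 200 * cs$ghg_coefficients[["n_rate"]] +
    60 * cs$ghg_coefficients[["diesel"]]
  expect_equal(inv$gwp,
               expected_emb + 25 * expected_ch4 + 298 * expected_n2o,
               tolerance = 1e-9)
})

test_that("the MR system at benchmark means lands on the published GWP and GWPi", {
  cs <- default_coefficients()
  ref <- reference_survey()
  inv <- ghg_inventory(ref, cs)
  mr <- inv[inv$system == "MR", ]
  expect_equal(mr$gwp, 7211, tolerance = 0.02)
  expect_equal(mr$gwpi, 936.5, tolerance = 0.02)
})

test_that("the N budget reports input, uptake and surplus per field", {
  cs <- default_coefficients()
  nb <- n_budget(tiny_survey(), cs)
  expect_equal(nb$n_surplus, nb$n_input - nb$n_uptake)
  f1 <- nb[nb$field_id == "F1", ]
  expect_equal(f1$n_input, 226)
  expect_equal(f1$n_uptake, 119.196, tolerance = 1e-9)
})
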