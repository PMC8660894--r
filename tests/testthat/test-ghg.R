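cfg <- default_config()

test_that("embodied emissions are the rate-weighted factor sum", {
  zero <- make_cycle(n_fertilizer = 0, p_fertilizer = 0, k_fertilizer = 0,
                     seed_rate = 0, manure_rate = 0)
  expect_equal(embodied_emissions(zero, cfg), 0)

  one <- make_cycle(n_fertilizer = 100, p_fertilizer = 0, k_fertilizer = 0,
                    seed_rate = 0)
  expect_equal(embodied_emissions(one, cfg),
               100 * cfg$embodied_ef$n_fertilizer)

  # linearity in each input holding the rest fixed
  base <- make_cycle()
  for (col in c("n_fertilizer", "p_fertilizer", "k_fertilizer",
                "seed_rate")) {
    up <- base; up[[col]] <- base[[col]] * 2
    delta <- embodied_emissions(up, cfg) - embodied_emissions(base, cfg)
    expect_equal(embodied_emissions(up, cfg) + delta,
                 {up2 <- base; up2[[col]] <- base[[col]] * 3
                  embodied_emissions(up2, cfg)}, tolerance = 1e-12)
  }

  cfg2 <- cfg
  cfg2$embodied_ef$seed <- NULL
  expect_error(embodied_emissions(base, cfg2), regexp = "seed",
               class = "rb_config_error")
})

test_that("fuel emissions sum operations against the diesel factor", {
  none <- make_cycle()
  expect_equal(fuel_emissions(none, cfg), 0)
  one <- make_cycle(operations = tibble::tibble(name = "tillage",
                                                fuel_l_ha = 10))
  expect_equal(fuel_emissions(one, cfg), 10 * cfg$fuel_ef)
  five <- make_cycle(operations = tibble::tibble(
    name = letters[1:5], fuel_l_ha = c(3, 7.5, 0, 12.25, 19)))
  expect_equal(fuel_emissions(five, cfg),
               (3 + 7.5 + 0 + 12.25 + 19) * cfg$fuel_ef, tolerance = 1e-12)
})

test_that("methane scaling follows the Tier-1 factor product", {
  cfg1 <- cfg
  cfg1$ch4$ef_baseline <- 1.3
  cfg1$ch4$sf_water$continuously_flooded <- 1
  cfg1$ch4$sf_preseason$nonflooded_short <- 1
  plain <- make_cycle(cultivation_days = 100)
  expect_equal(ch4_emissions(plain, cfg1), 130)

  # empty amendment list leaves the amendment factor at 1
  with_zero <- make_cycle(cultivation_days = 100,
                          amendments = tibble::tibble(type = "straw_long",
                                                      rate_t_ha = 0))
  expect_equal(ch4_emissions(with_zero, cfg1), ch4_emissions(plain, cfg1))

  # straw amendment against the hand-evaluated power expression
  straw <- make_cycle(cultivation_days = 100,
                      amendments = tibble::tibble(type = "straw_long",
                                                  rate_t_ha = 4))
  sfo <- (1 + 4 * cfg1$ch4$cfoa$straw_long)^cfg1$ch4$sfo_exponent
  expect_equal(ch4_emissions(straw, cfg1), 130 * sfo, tolerance = 1e-12)

  # zero exponent neutralizes any amendment load
  cfg0 <- cfg1
  cfg0$ch4$sfo_exponent <- 0
  expect_equal(ch4_emissions(straw, cfg0), 130)

  upland <- make_cycle(water_regime_class = "upland", ecosystem = "upland",
                       water_regime = "rainfed", irrigation = 0)
  expect_equal(ch4_emissions(upland, cfg), 0)

  odd <- make_cycle(water_regime_class = "midseason_aeration")
  expect_error(ch4_emissions(odd, cfg), class = "rb_config_error")
  odd2 <- make_cycle(preseason_class = "puddled")
  expect_error(ch4_emissions(odd2, cfg), class = "rb_config_error")
})

test_that("direct N2O is non-negative and non-decreasing in surplus", {
  cfg_flat <- cfg
  cfg_flat$n2o_direct_model$params <- c(0.7, 0)
  for (s in c(-100, 0, 50, 300)) {
    expect_equal(n2o_direct(s, cfg_flat), 0.7)
  }
  surpluses <- seq(-150, 250, by = 10)
  vals <- vapply(surpluses, n2o_direct, numeric(1), cfg = cfg)
  expect_true(all(vals >= 0))
  expect_true(all(diff(vals) >= 0))

  pw <- cfg
  pw$n2o_direct_model <- list(
    form = "piecewise_linear",
    params = list(knots = c(-50, 0, 100), values = c(0.1, 0.5, 3)))
  pw <- validate_config(pw)
  # at the knot both segments agree
  expect_equal(n2o_direct(0, pw), 0.5)
  expect_equal(n2o_direct(50, pw), 0.5 + 0.5 * (3 - 0.5), tolerance = 1e-12)
  expect_equal(n2o_direct(-25, pw), 0.1 + 0.5 * 0.4, tolerance = 1e-12)
  # constant extrapolation beyond the end knots
  expect_equal(n2o_direct(500, pw), 3)
  vals <- vapply(seq(-100, 200, 5), n2o_direct, numeric(1), cfg = pw)
  expect_true(all(diff(vals) >= 0))
})

test_that("unit masses convert at the configured GWP100 factors", {
  # 1 kg CH4 and nothing else -> 25 kg CO2-eq
  cfg_ch4 <- cfg
  cfg_ch4$n2o_direct_model$params <- c(0, 0)   # silence N2O
  cfg_ch4$ch4$ef_baseline <- 1 / 120           # 1 kg over the 120-day cycle
  cfg_ch4$ch4$sf_water$continuously_flooded <- 1
  cfg_ch4$ch4$sf_preseason$nonflooded_short <- 1
  cyc <- make_cycle(n_fertilizer = 0, p_fertilizer = 0, k_fertilizer = 0,
                    seed_rate = 0, manure_rate = 0, labor_hours = 0)
  out <- gwp_total(cyc, cfg_ch4, n_surplus = 0)
  expect_equal(out$ch4_mass, 1, tolerance = 1e-12)
  expect_equal(out$gwp_total, 25, tolerance = 1e-9)

  # 1 kg N2O (molecule) and nothing else -> 298 kg CO2-eq
  cfg_n2o <- cfg
  cfg_n2o$ch4$sf_water$continuously_flooded <- 0
  cfg_n2o$indirect_n2o_fraction <- 0
  cfg_n2o$n2o_direct_model$params <- c(28 / 44, 0)  # 1 kg N2O as N2O-N
  out <- gwp_total(cyc, cfg_n2o, n_surplus = 0)
  expect_equal(out$n2o_direct_mass * 44 / 28, 1, tolerance = 1e-12)
  expect_equal(out$gwp_total, 298, tolerance = 1e-9)

  # indirect N2O is the configured fraction of direct
  out <- gwp_total(make_cycle(), cfg, n_surplus = 80)
  expect_equal(out$n2o_indirect_mass, 0.2 * out$n2o_direct_mass,
               tolerance = 1e-12)
})

test_that("the emission breakdown matches the brute-force oracle", {
  cycles <- random_cycles(40, seed = 7)
  for (i in seq_len(nrow(cycles))) {
    cyc <- cycles[i, ]
    led <- n_balance(cyc, cfg)
    out <- gwp_total(cyc, cfg, led$n_surplus_for_n2o)
    expect_equal(out$gwp_total, oracle_gwp(cyc, cfg), tolerance = 1e-9)
    expect_equal(out$energy_input, oracle_energy(cyc, cfg),
                 tolerance = 1e-9)
    # additivity: total equals the converted component sum
    expect_equal(out$gwp_total,
                 out$co2_inputs + out$co2_fuel +
                   out$ch4_mass * cfg$gwp100$ch4 +
                   (out$n2o_direct_mass + out$n2o_indirect_mass) *
                   (44 / 28) * cfg$gwp100$n2o,
                 tolerance = 1e-9)
  }
})

test_that("GWP is invariant to line-item order", {
  pest <- tibble::tibble(class = c("herbicide", "insecticide", "fungicide"),
                         ai_name = c("herbin_a", "insectin_b", "fungin_a"),
                         ai_rate = c(0.3, 0.2, 0.4))
  ops <- tibble::tibble(name = c("tillage", "harvest", "pumping"),
                        fuel_l_ha = c(8, 15, 40))
  a <- make_cycle(pesticides = pest, operations = ops)
  b <- make_cycle(pesticides = pest[3:1, ], operations = ops[c(2, 3, 1), ])
  led <- n_balance(a, cfg)
  expect_equal(gwp_total(a, cfg, led$n_surplus_for_n2o)$gwp_total,
               gwp_total(b, cfg, led$n_surplus_for_n2o)$gwp_total,
               tolerance = 1e-12)
})

test_that("energy accounting is linear and handles the zero cycle", {
  zero <- make_cycle(yield_actual = 0, n_fertilizer = 0, p_fertilizer = 0,
                     k_fertilizer = 0, seed_rate = 0, manure_rate = 0,
                     labor_hours = 0)
  en <- energy_accounting(zero, cfg)
  expect_equal(en$energy_input, 0)
  expect_equal(en$net_energy_yield, 0)

  base <- make_cycle()
  dbl <- base
  for (col in c("n_fertilizer", "p_fertilizer", "k_fertilizer",
                "seed_rate", "manure_rate", "labor_hours")) {
    dbl[[col]] <- 2 * base[[col]]
  }
  dbl$field_operations <- lapply(base$field_operations, function(df) {
    df$fuel_l_ha <- 2 * df$fuel_l_ha; df})
  dbl$pesticide_applications <- lapply(base$pesticide_applications,
                                       function(df) {
    df$ai_rate <- 2 * df$ai_rate; df})
  expect_equal(energy_accounting(dbl, cfg)$energy_input,
               2 * energy_accounting(base, cfg)$energy_input,
               tolerance = 1e-12)
})
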