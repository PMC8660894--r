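cfg <- default_config()

# cohort with known per-crop closure and balance, one cycle per system:
# closure/balance pairs chosen around the selection boundaries
boundary_cohort <- function() {
  mk <- function(code, clos, bal) {
    # fertilizer chosen so the cycle's balance equals `bal` exactly, using
    # the same association order as the ledger arithmetic
    yp <- 10
    ya <- clos * yp
    rem <- (ya * 1000) * cfg$grain_n_conc +
      ((ya * 1000) * cfg$straw_grain_ratio * cfg$straw_n_conc) *
      cfg$straw_n_loss$removed
    make_cycle(system_code = code, yield_actual = ya, yield_potential = yp,
               n_fertilizer = bal + rem - cfg$bnf_lowland, manure_rate = 0,
               straw_management = "removed", harvested_area = 1e6,
               annual_area = 1e6)
  }
  dplyr::bind_rows(
    mk("AT60", 0.60, 50),   # exactly at the closure cutoff: excluded
    mk("BELOW", 0.59, 50),  # strictly below: selected
    mk("AT100", 0.70, 100), # exactly at the balance cutoff: excluded
    mk("HIGHN", 0.70, 101), # strictly above: selected
    mk("PLAIN", 0.70, 40))
}

test_that("selection boundaries are strict", {
  sys <- boundary_cohort()
  met <- system_metrics(sys, cfg)
  tg <- select_targets(met, cfg)
  expect_equal(tg$gap_systems, "BELOW")
  expect_equal(tg$nbal_systems, "HIGHN")
})

test_that("an empty selection makes both scenarios exact no-ops", {
  spec <- cohort_spec(n_systems = 6, seed = 21,
                      closure_range = c(0.75, 0.75))
  sys <- generate_cohort(spec, cfg)
  expect_equal(100 * sys$yield_actual / sys$yield_potential,
               rep(75, nrow(sys)), tolerance = 1e-12)
  # thresholds set so no system qualifies on either criterion
  cfg <- validate_config(utils::modifyList(
    unclass(default_config()), list(large_nbal_cutoff = 1e9)))
  sc <- run_scenarios(sys, cfg)
  expect_identical(sc$cap_n$scenario_production,
                   sc$cap_n$baseline_production)
  expect_identical(sc$cap_n$scenario_excess_n, sc$cap_n$baseline_excess_n)
  expect_identical(sc$fixed_ysnb$scenario_production,
                   sc$fixed_ysnb$baseline_production)
  expect_identical(sc$fixed_ysnb$scenario_excess_n,
                   sc$fixed_ysnb$baseline_excess_n)
})

test_that("gap cycles are raised to the exploitable ceiling", {
  one <- make_cycle(yield_actual = 5, yield_potential = 10,
                    harvested_area = 1e6, annual_area = 1e6)
  sc <- scenario_cap_n(one, cfg)
  # 0.75 x 10 Mg/ha on 1 Mha = 7.5 Mt from that system
  expect_equal(sc$scenario_production, 7.5, tolerance = 1e-12)
  expect_equal(sc$baseline_production, 5, tolerance = 1e-12)
})

test_that("fixed yield-scaled balance scales the balance with the yield", {
  yp <- 10
  ya <- 5  # closure 50%, selected
  # fertilizer such that ysNB is exactly 20 kg N/Mg at baseline
  rem <- ya * 1000 * (cfg$grain_n_conc + cfg$straw_grain_ratio *
                        cfg$straw_n_conc * cfg$straw_n_loss$removed)
  bal0 <- 20 * ya
  one <- make_cycle(yield_actual = ya, yield_potential = yp,
                    n_fertilizer = bal0 + rem - cfg$bnf_lowland,
                    manure_rate = 0, straw_management = "removed",
                    harvested_area = 1e6, annual_area = 1e6)
  sc <- scenario_fixed_ysnb(one, cfg)
  # new balance 20 x 7.5 = 150, excess 75 kg N/ha on 1 Mha = 0.075 Mt
  expect_equal(sc$scenario_excess_n, 0.075, tolerance = 1e-9)

  # ysNB of zero keeps the balance at zero after the yield increase
  zero <- make_cycle(yield_actual = ya, yield_potential = yp,
                     n_fertilizer = rem - cfg$bnf_lowland, manure_rate = 0,
                     straw_management = "removed", harvested_area = 1e6,
                     annual_area = 1e6)
  sc0 <- scenario_fixed_ysnb(zero, cfg)
  expect_equal(sc0$scenario_excess_n, 0, tolerance = 1e-12)
})

test_that("capping drives excess to zero in capped systems; the fixed-ysNB variant always dominates", {
  for (seed in c(1, 6)) {
    sys <- generate_cohort(global_cohort_spec(seed = seed), cfg)
    cycles <- assess_cycles(sys, cfg)
    met <- system_metrics(cycles)
    tg <- select_targets(met, cfg)
    cap <- scenario_cap_n(sys, cfg)
    fx <- scenario_fixed_ysnb(sys, cfg)

    # capped systems contribute no excess under the cap scenario
    capped <- cycles$system_code %in% tg$nbal_systems
    bal <- pmin(cycles$n_balance[capped], cfg$excess_n_threshold)
    expect_true(all(bal <= cfg$excess_n_threshold + 1e-12))

    # both scenarios raise the same yields: identical production
    expect_equal(cap$scenario_production, fx$scenario_production,
                 tolerance = 1e-12)
    expect_gte(cap$scenario_production, cap$baseline_production)

    # without a cap on gap systems, excess can only be larger
    expect_gte(fx$scenario_excess_n, cap$scenario_excess_n)
  }
})

test_that("scenario totals match a flat brute-force recomputation", {
  sys <- generate_cohort(global_cohort_spec(seed = 1), cfg)
  met <- system_metrics(sys, cfg)
  tg <- select_targets(met, cfg)
  cap <- scenario_cap_n(sys, cfg)
  fx <- scenario_fixed_ysnb(sys, cfg)

  prod_base <- prod_scen <- 0
  exc_base <- exc_cap <- exc_fx <- 0
  for (i in seq_len(nrow(sys))) {
    o <- oracle_nitrogen(sys[i, ], cfg)
    area <- sys$harvested_area[i]
    ya <- sys$yield_actual[i]
    in_gap <- sys$system_code[i] %in% tg$gap_systems
    in_nbal <- sys$system_code[i] %in% tg$nbal_systems
    ya_new <- if (in_gap) 0.75 * sys$yield_potential[i] else ya
    prod_base <- prod_base + ya * area
    prod_scen <- prod_scen + ya_new * area
    exc_base <- exc_base + max(0, o$balance - 75) * area
    bal_cap <- if (in_nbal) min(o$balance, 75) else o$balance
    exc_cap <- exc_cap + max(0, bal_cap - 75) * area
    bal_fx <- if (in_gap) (o$balance / ya) * ya_new else o$balance
    exc_fx <- exc_fx + max(0, bal_fx - 75) * area
  }
  expect_equal(cap$baseline_production, prod_base / 1e6, tolerance = 1e-9)
  expect_equal(cap$scenario_production, prod_scen / 1e6, tolerance = 1e-9)
  expect_equal(cap$baseline_excess_n, exc_base / 1e9, tolerance = 1e-9)
  expect_equal(cap$scenario_excess_n, exc_cap / 1e9, tolerance = 1e-9)
  expect_equal(fx$scenario_excess_n, exc_fx / 1e9, tolerance = 1e-9)
})

test_that("the optional cap on gap systems is honored", {
  yp <- 10; ya <- 4  # closure 40%: a gap system with a large balance kept < 100
  rem <- ya * 1000 * (cfg$grain_n_conc + cfg$straw_grain_ratio *
                        cfg$straw_n_conc * cfg$straw_n_loss$removed)
  one <- make_cycle(yield_actual = ya, yield_potential = yp,
                    n_fertilizer = 95 + rem - cfg$bnf_lowland,
                    manure_rate = 0, straw_management = "removed",
                    harvested_area = 1e6, annual_area = 1e6)
  default_run <- scenario_cap_n(one, cfg)
  expect_equal(default_run$scenario_excess_n,
               (95 - 75) * 1e6 / 1e9, tolerance = 1e-9)
  capped_run <- scenario_cap_n(one, cfg, cap_gap_systems = TRUE)
  expect_equal(capped_run$scenario_excess_n, 0, tolerance = 1e-12)
})

test_that("scenario results serialize to JSON and CSV", {
  sys <- generate_cohort(cohort_spec(n_systems = 5, seed = 3,
                                     n_large_gap = 2, n_large_nbal = 1), cfg)
  sc <- scenario_cap_n(sys, cfg)
  fj <- withr::local_tempfile(fileext = ".json")
  write_scenario(sc, fj)
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(back$scenario_production, sc$scenario_production,
               tolerance = 1e-12)
  expect_equal(sort(back$selected_gap_systems),
               sort(sc$selected_gap_systems))
  fc <- withr::local_tempfile(fileext = ".csv")
  write_scenario(sc, fc)
  expect_equal(utils::read.csv(fc)$baseline_excess_n, sc$baseline_excess_n,
               tolerance = 1e-9)
})
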