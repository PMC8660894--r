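# Hand-built cycle rows and brute-force oracles, kept independent of the
# package's own accounting code paths: every oracle below recomputes its
# quantity with flat loops over the raw fields.

make_cycle <- function(system_code = "TSTI1", cycle_index = 1L,
                       season = "single", climate_zone = "non_tropical",
                       water_regime = "irrigated", ecosystem = "lowland",
                       establishment = "transplanted",
                       mechanization = "intermediate", field_size = 5,
                       annual_area = 1000, yield_actual = 6,
                       yield_potential = 10, harvested_area = 1000,
                       n_fertilizer = 100, p_fertilizer = 40,
                       k_fertilizer = 40, manure_rate = 0,
                       manure_n_conc = 0.005, seed_rate = 40,
                       irrigation = 800, precipitation_in_season = 300,
                       labor_hours = 120, straw_management = "removed",
                       cultivation_days = 120,
                       water_regime_class = "continuously_flooded",
                       preseason_class = "nonflooded_short",
                       pesticides = NULL, operations = NULL,
                       amendments = NULL) {
  tibble::tibble(
    system_code = system_code, country = "TS", climate_zone = climate_zone,
    water_regime = water_regime, ecosystem = ecosystem,
    establishment = establishment, mechanization = mechanization,
    field_size = field_size, annual_area = annual_area,
    cycle_index = cycle_index, season = season,
    yield_actual = yield_actual, yield_potential = yield_potential,
    harvested_area = harvested_area, n_fertilizer = n_fertilizer,
    p_fertilizer = p_fertilizer, k_fertilizer = k_fertilizer,
    manure_rate = manure_rate, manure_n_conc = manure_n_conc,
    seed_rate = seed_rate, irrigation = irrigation,
    precipitation_in_season = precipitation_in_season,
    labor_hours = labor_hours, straw_management = straw_management,
    cultivation_days = cultivation_days,
    water_regime_class = water_regime_class,
    preseason_class = preseason_class, replicate_cycle = FALSE,
    pesticide_applications = list(
      pesticides %||% tibble::tibble(class = character(0),
                                     ai_name = character(0),
                                     ai_rate = numeric(0))),
    field_operations = list(
      operations %||% tibble::tibble(name = character(0),
                                     fuel_l_ha = numeric(0))),
    organic_amendments = list(
      amendments %||% tibble::tibble(type = character(0),
                                     rate_t_ha = numeric(0)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random cycle rows for property tests (independent of the cohort generator)
random_cycles <- function(n, seed = 99) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    yp <- runif(1, 4, 15)
    np <- sample(0:5, 1)
    make_cycle(
      system_code = sprintf("R%04d", i), annual_area = runif(1, 10, 1e6),
      yield_actual = runif(1, 0.2, 0.95) * yp, yield_potential = yp,
      harvested_area = runif(1, 10, 1e6),
      n_fertilizer = runif(1, 0, 250), p_fertilizer = runif(1, 0, 80),
      k_fertilizer = runif(1, 0, 100),
      manure_rate = sample(c(0, runif(1, 500, 9000)), 1),
      seed_rate = runif(1, 20, 150), irrigation = runif(1, 0, 1400),
      precipitation_in_season = runif(1, 50, 1400),
      labor_hours = runif(1, 5, 900),
      straw_management = sample(c("retained", "removed", "burned"), 1),
      cultivation_days = runif(1, 80, 180),
      water_regime_class = sample(c("continuously_flooded",
                                    "single_drainage", "multiple_drainage",
                                    "rainfed_regular"), 1),
      preseason_class = sample(c("nonflooded_short", "nonflooded_long",
                                 "flooded_pre"), 1),
      ecosystem = sample(c("lowland", "upland"), 1, prob = c(0.9, 0.1)),
      pesticides = if (np == 0) NULL else tibble::tibble(
        class = sample(c("insecticide", "herbicide", "fungicide"), np,
                       replace = TRUE),
        ai_name = sample(c("insectin_a", "herbin_a", "fungin_b"), np,
                         replace = TRUE),
        ai_rate = runif(np, 0.05, 0.8)),
      operations = tibble::tibble(
        name = c("tillage", "harvest"), fuel_l_ha = runif(2, 0, 25)),
      amendments = if (runif(1) < 0.5) tibble::tibble(
        type = "straw_long", rate_t_ha = runif(1, 0, 6)) else NULL
    )
  })
  dplyr::bind_rows(rows)
}

# ---- brute-force oracles ---------------------------------------------------

oracle_nitrogen <- function(cyc, cfg) {
  dm <- if (isTRUE(cfg$n_removal_dry_matter)) cfg$dm_fraction else 1
  bnf <- if (cyc$ecosystem == "upland") {
    cfg$bnf_lowland * cfg$bnf_upland_fraction
  } else cfg$bnf_lowland
  grain <- cyc$yield_actual * 1000 * dm * cfg$grain_n_conc
  straw_tot <- cyc$yield_actual * 1000 * dm * cfg$straw_grain_ratio *
    cfg$straw_n_conc
  straw_rem <- straw_tot * cfg$straw_n_loss[[cyc$straw_management]]
  n_in <- cyc$n_fertilizer + cyc$manure_rate * cyc$manure_n_conc + bnf
  bal <- n_in - grain - straw_rem
  list(n_input = n_in, balance = bal,
       surplus = n_in - grain - straw_tot,
       excess = max(0, bal - cfg$excess_n_threshold))
}

oracle_gwp <- function(cyc, cfg) {
  ef <- cfg$embodied_ef
  co2_in <- cyc$n_fertilizer * ef$n_fertilizer +
    cyc$p_fertilizer * ef$p_fertilizer +
    cyc$k_fertilizer * ef$k_fertilizer +
    cyc$seed_rate * ef$seed +
    sum(cyc$pesticide_applications[[1]]$ai_rate) * ef$pesticide +
    cyc$manure_rate * ef$manure
  fuel_l <- sum(cyc$field_operations[[1]]$fuel_l_ha)
  co2_fuel <- fuel_l * cfg$fuel_ef
  ch4 <- 0
  if (cyc$water_regime_class != "upland") {
    sfo <- 1
    oa <- cyc$organic_amendments[[1]]
    if (nrow(oa) > 0) {
      acc <- 0
      for (j in seq_len(nrow(oa))) {
        acc <- acc + oa$rate_t_ha[j] * cfg$ch4$cfoa[[oa$type[j]]]
      }
      sfo <- (1 + acc)^cfg$ch4$sfo_exponent
    }
    ch4 <- cfg$ch4$ef_baseline *
      cfg$ch4$sf_water[[cyc$water_regime_class]] *
      cfg$ch4$sf_preseason[[cyc$preseason_class]] * sfo *
      cyc$cultivation_days
  }
  surplus <- oracle_nitrogen(cyc, cfg)$surplus
  nd <- cfg$n2o_direct_model$params[[1]] *
    exp(cfg$n2o_direct_model$params[[2]] * surplus)
  ni <- cfg$indirect_n2o_fraction * nd
  co2_in + co2_fuel + ch4 * cfg$gwp100$ch4 +
    (nd + ni) * (44 / 28) * cfg$gwp100$n2o
}

oracle_energy <- function(cyc, cfg) {
  ee <- cfg$embodied_energy
  emb <- cyc$n_fertilizer * ee$n_fertilizer +
    cyc$p_fertilizer * ee$p_fertilizer +
    cyc$k_fertilizer * ee$k_fertilizer +
    cyc$seed_rate * ee$seed +
    sum(cyc$pesticide_applications[[1]]$ai_rate) * ee$pesticide +
    cyc$manure_rate * ee$manure
  emb + sum(cyc$field_operations[[1]]$fuel_l_ha) * cfg$fuel_energy +
    cyc$labor_hours * cfg$labor_energy
}

oracle_eiq <- function(cyc, cfg) {
  apps <- cyc$pesticide_applications[[1]]
  tot <- 0
  if (nrow(apps)) {
    for (j in seq_len(nrow(apps))) {
      q <- cfg$eiq_table[[apps$ai_name[j]]]
      if (!is.null(q)) tot <- tot + q * apps$ai_rate[j]
    }
  }
  tot
}

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
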