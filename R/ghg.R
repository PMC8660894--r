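as_cycle <- function(cycle) {
  if (is_tibble(cycle)) {
    if (nrow(cycle) != 1L) {
      rb_abort("per-cycle operations take exactly one cycle row",
               "rb_validation_error")
    }
    cycle <- as.list(cycle)
    for (lc in c("pesticide_applications", "field_operations",
                 "organic_amendments")) {
      if (lc %in% names(cycle)) cycle[[lc]] <- cycle[[lc]][[1]]
    }
  }
  cycle
}

# named vector of input rates, in the units of the embodied factor tables
input_rates <- function(cycle) {
  pest <- cycle$pesticide_applications
  c(n_fertilizer = cycle$n_fertilizer,
    p_fertilizer = cycle$p_fertilizer,
    k_fertilizer = cycle$k_fertilizer,
    seed = cycle$seed_rate,
    pesticide = if (nrow(pest)) sum(pest$ai_rate) else 0,
    manure = cycle$manure_rate)
}

lookup_factors <- function(rates, table, table_name) {
  missing <- setdiff(names(rates)[rates > 0], names(table))
  if (length(missing)) {
    rb_abort(sprintf("no %s factor for input(s): %s", table_name,
                     paste(missing, collapse = ", ")), "rb_config_error")
  }
  vapply(names(rates),
         function(nm) if (nm %in% names(table)) table[[nm]] else 0,
         numeric(1))
}

#' Embodied emissions of agricultural inputs
#'
#' CO2-equivalent emissions from the production, packaging and transport of
#' the inputs applied in one crop cycle (fertilizer N/P/K, seed, pesticide
#' active ingredient, manure), as sum of rate times embodied emission
#' factor.
#'
#' @param cycle one cycle row of an [rb_systems] table.
#' @param cfg an `rb_config` list.
#' @return kg CO2-eq per ha.
#' @export
embodied_emissions <- function(cycle, cfg) {
  cycle <- as_cycle(cycle)
  rates <- input_rates(cycle)
  sum(rates * lookup_factors(rates, cfg$embodied_ef, "embodied emission"))
}

#' Fuel emissions of field operations
#'
#' Diesel used by field operations (tillage, establishment, spraying,
#' harvest, irrigation pumping, ...) times the fuel emission factor.
#'
#' @inheritParams embodied_emissions
#' @return kg CO2-eq per ha.
#' @export
fuel_emissions <- function(cycle, cfg) {
  cycle <- as_cycle(cycle)
  ops <- cycle$field_operations
  if (nrow(ops) == 0) return(0)
  sum(ops$fuel_l_ha) * cfg$fuel_ef
}

#' Methane emissions of a rice crop cycle
#'
#' Tier-1 style scaling of a baseline daily emission factor by the in-season
#' water regime, the pre-season water status, and organic amendments:
#' daily EF = `ef_baseline * sf_water * sf_preseason * SFo` with
#' `SFo = (1 + sum(rate_i * CFOA_i))^exponent`, multiplied by the length of
#' the flooded cultivation period. Upland cycles emit no methane.
#'
#' @inheritParams embodied_emissions
#' @return kg CH4 per ha.
#' @export
ch4_emissions <- function(cycle, cfg) {
  cycle <- as_cycle(cycle)
  if (identical(cycle$water_regime_class, "upland")) return(0)
  sfw <- cfg$ch4$sf_water[[cycle$water_regime_class]]
  if (is.null(sfw)) {
    rb_abort(sprintf("unknown water_regime_class '%s' (not in ch4.sf_water)",
                     cycle$water_regime_class), "rb_config_error")
  }
  sfp <- cfg$ch4$sf_preseason[[cycle$preseason_class]]
  if (is.null(sfp)) {
    rb_abort(sprintf("unknown preseason_class '%s' (not in ch4.sf_preseason)",
                     cycle$preseason_class), "rb_config_error")
  }
  oa <- cycle$organic_amendments
  sfo <- 1
  if (nrow(oa)) {
    missing <- setdiff(oa$type, names(cfg$ch4$cfoa))
    if (length(missing)) {
      rb_abort(sprintf("unknown organic amendment type(s): %s",
                       paste(missing, collapse = ", ")), "rb_config_error")
    }
    cf <- vapply(oa$type, function(t) cfg$ch4$cfoa[[t]], numeric(1))
    sfo <- (1 + sum(oa$rate_t_ha * cf))^cfg$ch4$sfo_exponent
  }
  cfg$ch4$ef_baseline * sfw * sfp * sfo * cycle$cultivation_days
}

#' Direct soil nitrous-oxide emissions from nitrogen surplus
#'
#' Direct soil N2O (as N2O-N) as a non-decreasing function of the N surplus
#' of the crop cycle, with the functional form and parameters taken from the
#' configuration: `exponential` evaluates `a * exp(b * surplus)`;
#' `piecewise_linear` interpolates configured (knot, value) pairs with
#' constant extrapolation beyond the end knots.
#'
#' @param n_surplus N surplus, kg N per ha (may be negative).
#' @param cfg an `rb_config` list.
#' @return kg N2O-N per ha (never negative).
#' @export
n2o_direct <- function(n_surplus, cfg) {
  model <- cfg$n2o_direct_model
  if (model$form == "exponential") {
    a <- model$params[[1]]
    b <- model$params[[2]]
    return(a * exp(b * n_surplus))
  }
  if (model$form == "piecewise_linear") {
    k <- model$params$knots
    v <- model$params$values
    return(stats::approx(k, v, xout = n_surplus, rule = 2)$y)
  }
  rb_abort(sprintf("unsupported n2o_direct_model form '%s'", model$form),
           "rb_config_error")
}

#' Per-cycle emission breakdown and global warming potential
#'
#' Assembles the full CO2-equivalent account for one crop cycle: embodied
#' input emissions, fuel CO2, methane, and direct plus indirect N2O
#' (indirect taken as the configured fraction, 20% by default, of direct).
#' N2O masses are carried as N2O-N and converted to N2O molecules by 44/28
#' exactly once, at the CO2-eq conversion:
#' `gwp_total = co2_inputs + co2_fuel + ch4 * GWP_CH4 +
#'  (n2o_direct + n2o_indirect) * (44/28) * GWP_N2O`.
#'
#' @inheritParams embodied_emissions
#' @param n_surplus N surplus of this cycle, kg N per ha, as computed by
#'   [n_balance()]; drives the direct-N2O model.
#' @return a one-row tibble (`co2_inputs`, `co2_fuel`, `ch4_mass`,
#'   `n2o_direct_mass`, `n2o_indirect_mass`, `gwp_total`,
#'   `energy_input`, `net_energy_yield`).
#' @export
gwp_total <- function(cycle, cfg, n_surplus) {
  cycle <- as_cycle(cycle)
  co2_inputs <- embodied_emissions(cycle, cfg)
  co2_fuel <- fuel_emissions(cycle, cfg)
  ch4 <- ch4_emissions(cycle, cfg)
  nd <- n2o_direct(n_surplus, cfg)
  ni <- cfg$indirect_n2o_fraction * nd
  en <- energy_accounting(cycle, cfg)
  tibble(
    co2_inputs = co2_inputs,
    co2_fuel = co2_fuel,
    ch4_mass = ch4,
    n2o_direct_mass = nd,
    n2o_indirect_mass = ni,
    gwp_total = co2_inputs + co2_fuel + ch4 * cfg$gwp100$ch4 +
      (nd + ni) * (44 / 28) * cfg$gwp100$n2o,
    energy_input = en$energy_input,
    net_energy_yield = en$net_energy_yield
  )
}

#' Energy input and net energy yield of a crop cycle
#'
#' Energy input sums the embodied energy of agricultural inputs, the fuel
#' energy of field operations, and human labor energy. Energy output is the
#' grain energy of the harvested yield (on a dry-matter basis when
#' `cfg$energy_dry_matter` is set); net energy yield is output minus input.
#'
#' @inheritParams embodied_emissions
#' @return a list with `energy_input` and `net_energy_yield`, MJ per ha.
#' @export
energy_accounting <- function(cycle, cfg) {
  cycle <- as_cycle(cycle)
  rates <- input_rates(cycle)
  embodied <- sum(rates * lookup_factors(rates, cfg$embodied_energy,
                                         "embodied energy"))
  ops <- cycle$field_operations
  fuel <- if (nrow(ops)) sum(ops$fuel_l_ha) else 0
  energy_input <- embodied + fuel * cfg$fuel_energy +
    cycle$labor_hours * cfg$labor_energy
  dm <- if (isTRUE(cfg$energy_dry_matter)) cfg$dm_fraction else 1
  energy_output <- cycle$yield_actual * 1000 * dm * cfg$grain_energy
  list(energy_input = energy_input,
       net_energy_yield = energy_output - energy_input)
}
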