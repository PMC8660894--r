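#' Select scenario target systems
#'
#' Gap systems are those whose per-crop yield-gap closure is strictly below
#' the large-gap cutoff (60% of potential by default); large-N-balance
#' systems are those whose per-crop N balance is strictly above the cutoff
#' (100 kg N/ha/crop by default). A system at exactly the cutoff is
#' excluded. The two sets may overlap.
#'
#' @param metrics output of [system_metrics()].
#' @param cfg an `rb_config` list.
#' @return a list with character vectors `gap_systems` and `nbal_systems`.
#' @export
select_targets <- function(metrics, cfg) {
  wide <- metrics_wide(metrics, "per_crop")
  list(
    gap_systems = sort(wide$system_code[wide$closure <
                                          100 * cfg$large_gap_cutoff]),
    nbal_systems = sort(wide$system_code[wide$n_balance >
                                           cfg$large_nbal_cutoff])
  )
}

production_mt <- function(yields, areas) mt_from_mg(sum(yields * areas))

scenario_result <- function(base_prod, scen_prod, base_excess, scen_excess,
                            targets, mode) {
  structure(list(
    mode = mode,
    baseline_production = base_prod,
    scenario_production = scen_prod,
    delta_production = scen_prod - base_prod,
    delta_production_pct = 100 * (scen_prod - base_prod) / base_prod,
    baseline_excess_n = base_excess,
    scenario_excess_n = scen_excess,
    delta_excess_n = scen_excess - base_excess,
    delta_excess_n_pct = 100 * (scen_excess - base_excess) / base_excess,
    selected_gap_systems = targets$gap_systems,
    selected_nbal_systems = targets$nbal_systems
  ), class = "rb_scenario")
}

#' @export
print.rb_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s'\n", x$mode))
  cat(sprintf("  production: %.1f -> %.1f Mt (%+.1f Mt, %+.0f%%)\n",
              x$baseline_production, x$scenario_production,
              x$delta_production, x$delta_production_pct))
  cat(sprintf("  excess N:   %.2f -> %.2f Mt N (%+.2f Mt, %+.0f%%)\n",
              x$baseline_excess_n, x$scenario_excess_n, x$delta_excess_n,
              x$delta_excess_n_pct))
  cat(sprintf("  targets: %d large-gap, %d large-N-balance systems\n",
              length(x$selected_gap_systems),
              length(x$selected_nbal_systems)))
  invisible(x)
}

scenario_core <- function(systems, cfg, mode, cap_gap_systems = FALSE) {
  cycles <- assess_cycles(systems, cfg)
  metrics <- system_metrics(cycles)
  targets <- select_targets(metrics, cfg)
  in_gap <- cycles$system_code %in% targets$gap_systems
  in_nbal <- cycles$system_code %in% targets$nbal_systems

  base_prod <- production_mt(cycles$yield_actual, cycles$harvested_area)
  base_excess <- mt_from_kg(sum(pmax(0, cycles$n_balance -
                                       cfg$excess_n_threshold) *
                                  cycles$harvested_area))

  new_yield <- cycles$yield_actual
  new_yield[in_gap] <- cfg$closure_target * cycles$yield_potential[in_gap]
  new_bal <- cycles$n_balance

  if (mode == "cap_n") {
    capped <- in_nbal | (cap_gap_systems & in_gap)
    new_bal[capped] <- pmin(new_bal[capped], cfg$excess_n_threshold)
  } else if (mode == "fixed_ysnb") {
    ysnb <- cycles$yield_scaled_n_balance
    undef <- in_gap & (is.na(ysnb) | cycles$yield_actual <= 0)
    if (any(undef)) {
      warn(sprintf("%d gap cycle(s) with undefined yield-scaled N balance left at baseline",
                   sum(undef)), class = "rb_scenario_warning")
    }
    adj <- in_gap & !undef
    new_bal[adj] <- ysnb[adj] * new_yield[adj]
  } else {
    rb_abort(sprintf("unknown scenario mode '%s'", mode), "rb_config_error")
  }

  scen_prod <- production_mt(new_yield, cycles$harvested_area)
  scen_excess <- mt_from_kg(sum(pmax(0, new_bal - cfg$excess_n_threshold) *
                                  cycles$harvested_area))
  scenario_result(base_prod, scen_prod, base_excess, scen_excess, targets,
                  mode)
}

#' Yield-gap closure scenario with an N-balance cap
#'
#' Counterfactual in which (i) every crop cycle of a large-gap system is
#' raised to the exploitable ceiling (75% of its own cycle's yield
#' potential by default) and (ii) the N balance of every large-balance
#' system is reduced to the excess-N threshold (75 kg N/ha), driving its
#' excess N to zero. Harvested areas, cropping intensity and water regimes
#' are unchanged. Systems in both target sets receive both interventions.
#' By default the balances of gap-only systems stay at baseline;
#' `cap_gap_systems = TRUE` additionally applies the cap to them after the
#' yield increase.
#'
#' @param systems an [rb_systems] tibble.
#' @param cfg an `rb_config` list.
#' @param cap_gap_systems also cap the N balance of gap systems.
#' @return an `rb_scenario` result (production and excess-N totals in Mt,
#'   baseline vs scenario, plus the selected system codes).
#' @export
scenario_cap_n <- function(systems, cfg, cap_gap_systems = FALSE) {
  scenario_core(systems, cfg, "cap_n", cap_gap_systems = cap_gap_systems)
}

#' Yield-gap closure scenario at unchanged yield-scaled N balance
#'
#' Counterfactual in which the same large-gap systems are raised to the
#' exploitable ceiling while each affected cycle keeps its current
#' yield-scaled N balance, so its new balance is the baseline
#' kg N/Mg value times the new yield. Excess N is recomputed; other
#' systems are untouched (no cap is applied in this scenario).
#'
#' @inheritParams scenario_cap_n
#' @return an `rb_scenario` result.
#' @export
scenario_fixed_ysnb <- function(systems, cfg) {
  scenario_core(systems, cfg, "fixed_ysnb")
}

#' Run both scenarios
#'
#' @inheritParams scenario_cap_n
#' @return a list with elements `cap_n` and `fixed_ysnb`.
#' @export
run_scenarios <- function(systems, cfg, cap_gap_systems = FALSE) {
  list(cap_n = scenario_cap_n(systems, cfg,
                              cap_gap_systems = cap_gap_systems),
       fixed_ysnb = scenario_fixed_ysnb(systems, cfg))
}

#' Serialize a scenario result
#'
#' @param x an `rb_scenario` result.
#' @param path output `.json` or `.csv` path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  } else {
    flat <- unclass(x)
    flat$selected_gap_systems <- paste(flat$selected_gap_systems,
                                       collapse = ";")
    flat$selected_nbal_systems <- paste(flat$selected_nbal_systems,
                                        collapse = ";")
    utils::write.csv(as.data.frame(flat), path, row.names = FALSE)
  }
  invisible(path)
}
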