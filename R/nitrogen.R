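#' Nitrogen inputs of a crop cycle
#'
#' N enters the partial balance through synthetic fertilizer, manure
#' (rate times N concentration), and biological N fixation: a fixed
#' per-crop input for lowland rice (30 kg N/ha by default) reduced to a
#' configured fraction (10% by default) in upland rice.
#'
#' @inheritParams embodied_emissions
#' @return a list with `n_fertilizer`, `n_manure`, `n_bnf` (kg N per ha).
#' @export
n_input <- function(cycle, cfg) {
  cycle <- as_cycle(cycle)
  bnf <- if (identical(cycle$ecosystem, "upland")) {
    cfg$bnf_lowland * cfg$bnf_upland_fraction
  } else {
    cfg$bnf_lowland
  }
  list(n_fertilizer = cycle$n_fertilizer,
       n_manure = cycle$manure_rate * cycle$manure_n_conc,
       n_bnf = bnf)
}

#' Nitrogen removal of a crop cycle
#'
#' Grain removal is yield times grain N concentration (optionally on a
#' dry-matter basis, per config). Straw N leaving the field is yield times
#' the straw:grain ratio and straw N concentration, times the fraction of
#' straw N lost under the cycle's straw management — zero when straw is
#' retained, full when removed, and a configured fraction when burned.
#'
#' @inheritParams embodied_emissions
#' @return a list with `n_removal_grain`, `n_removal_straw` (kg N per ha)
#'   and `n_straw_total` (straw N at maturity, used by the surplus proxy).
#' @export
n_removal <- function(cycle, cfg) {
  cycle <- as_cycle(cycle)
  loss <- cfg$straw_n_loss[[cycle$straw_management]]
  if (is.null(loss)) {
    rb_abort(sprintf("unknown straw_management '%s'", cycle$straw_management),
             "rb_validation_error")
  }
  dm <- if (isTRUE(cfg$n_removal_dry_matter)) cfg$dm_fraction else 1
  grain_mass <- cycle$yield_actual * 1000 * dm  # kg
  grain <- grain_mass * cfg$grain_n_conc
  straw_total <- grain_mass * cfg$straw_grain_ratio * cfg$straw_n_conc
  list(n_removal_grain = grain,
       n_removal_straw = straw_total * loss,
       n_straw_total = straw_total)
}

#' Partial nitrogen balance ledger of a crop cycle
#'
#' Assembles the full per-cycle nitrogen ledger: inputs (fertilizer, manure,
#' biological fixation), removals (grain, and straw when it leaves the
#' field), the balance, the yield-scaled balance (kg N per Mg grain; `NA`
#' when yield is zero, never infinite), the N surplus feeding the direct-N2O
#' model (inputs minus aboveground N at maturity, i.e. grain plus total
#' straw N, under the default `aboveground_proxy` strategy), and excess N —
#' the part of the balance above the configured threshold (75 kg N/ha).
#' Leaching/denitrification losses are taken to offset N input from
#' irrigation water and deposition, so neither side carries them.
#'
#' @inheritParams embodied_emissions
#' @return a one-row tibble (`NitrogenLedger` fields).
#' @export
n_balance <- function(cycle, cfg) {
  cycle <- as_cycle(cycle)
  inp <- n_input(cycle, cfg)
  rem <- n_removal(cycle, cfg)
  total_in <- inp$n_fertilizer + inp$n_manure + inp$n_bnf
  bal <- total_in - rem$n_removal_grain - rem$n_removal_straw
  ysnb <- if (cycle$yield_actual > 0) bal / cycle$yield_actual else NA_real_
  surplus <- switch(
    cfg$surplus_strategy %||% "aboveground_proxy",
    aboveground_proxy = total_in - (rem$n_removal_grain + rem$n_straw_total),
    balance = bal,
    rb_abort(sprintf("unknown surplus_strategy '%s'", cfg$surplus_strategy),
             "rb_config_error")
  )
  tibble(
    n_fertilizer = inp$n_fertilizer,
    n_manure = inp$n_manure,
    n_bnf = inp$n_bnf,
    n_input_total = total_in,
    n_removal_grain = rem$n_removal_grain,
    n_removal_straw = rem$n_removal_straw,
    n_balance = bal,
    yield_scaled_n_balance = ysnb,
    n_surplus_for_n2o = surplus,
    excess_n = max(0, bal - cfg$excess_n_threshold)
  )
}

#' Total excess nitrogen across a cohort
#'
#' Sums per-cycle excess N (the part of the N balance above the threshold)
#' times harvested area over every cycle of every system, in Mt N per year.
#'
#' @param systems an [rb_systems] tibble.
#' @param cfg an `rb_config` list.
#' @param balance_override optional numeric vector, one value per cycle row,
#'   replacing the computed N balance (used by the scenario engine).
#' @return Mt N per year.
#' @export
total_excess_n <- function(systems, cfg, balance_override = NULL) {
  bal <- if (is.null(balance_override)) {
    vapply(seq_len(nrow(systems)),
           function(i) n_balance(systems[i, ], cfg)$n_balance, numeric(1))
  } else {
    stopifnot(length(balance_override) == nrow(systems))
    balance_override
  }
  excess <- pmax(0, bal - cfg$excess_n_threshold)
  mt_from_kg(sum(excess * systems$harvested_area))
}
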