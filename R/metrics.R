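#' Yield-gap closure
#'
#' Actual yield expressed as a percentage of yield potential. Normalizing by
#' the locally attainable ceiling makes farmer yields comparable across
#' climates and water regimes: 8 Mg/ha can be 80% of potential in one system
#' and barely half of it in another.
#'
#' @param yield_actual actual yield, Mg per ha.
#' @param yield_potential (water-limited) yield potential, Mg per ha; must
#'   be positive.
#' @return closure, percent of potential.
#' @export
closure <- function(yield_actual, yield_potential) {
  if (any(yield_potential <= 0)) {
    rb_abort("yield_potential must be > 0", "rb_validation_error")
  }
  100 * yield_actual / yield_potential
}

#' Area-weighted per-crop mean across cycles
#'
#' Where harvested area changes between crop cycles of a system, per-crop
#' values are weighted by the cycle's harvested area: `sum(w v) / sum(w)`.
#'
#' @param values per-cycle values.
#' @param areas per-cycle harvested areas (ha); total must be positive.
#' @return the weighted mean; identical to `values` for a single cycle.
#' @export
per_crop_mean <- function(values, areas) {
  if (length(values) != length(areas) || sum(areas) <= 0) {
    rb_abort("per_crop_mean needs matching values/areas with positive total area",
             "rb_validation_error")
  }
  sum(values * areas) / sum(areas)
}

#' Annual total across cycles
#'
#' Per-hectare quantities accumulate over the crop cycles grown within a
#' 12-month period, so the annual potential of double or triple rice exceeds
#' its per-crop potential.
#'
#' @param values per-cycle values.
#' @return their sum.
#' @export
annual_total <- function(values) sum(values)

#' Area-weighted mean across systems
#'
#' Cohort-level averages are weighted by each system's annual harvested
#' area.
#'
#' @param values one value per system.
#' @param areas annual harvested area per system (ha); total must be
#'   positive.
#' @return the weighted mean (always within the range of `values`).
#' @export
global_weighted_mean <- function(values, areas) {
  if (length(values) != length(areas) || sum(areas) <= 0) {
    rb_abort("global_weighted_mean needs matching values/areas with positive total area",
             "rb_validation_error")
  }
  sum(values * areas) / sum(areas)
}

#' Coefficient of variation
#'
#' @param series at least two values with positive mean.
#' @return 100 * sample SD / mean, percent.
#' @export
cv <- function(series) {
  if (length(series) < 2) {
    rb_abort("cv needs at least 2 values", "rb_validation_error")
  }
  m <- mean(series)
  if (m <= 0) rb_abort("cv needs a positive mean", "rb_validation_error")
  100 * stats::sd(series) / m
}

#' Per-cycle assessment table
#'
#' Runs every per-cycle accounting operation (nitrogen ledger, emission
#' breakdown and GWP, energy, pesticide pressure, water supply, yield-gap
#' closure) over each crop cycle of a cohort and binds the results to the
#' cycle rows. This is the long-format backbone from which system metrics,
#' the performance index, correlations, and scenarios are assembled.
#'
#' @param systems an [rb_systems] tibble.
#' @param cfg an `rb_config` list.
#' @return a tibble, one row per cycle, cycle descriptors plus computed
#'   quantities.
#' @export
assess_cycles <- function(systems, cfg) {
  rows <- lapply(seq_len(nrow(systems)), function(i) {
    cyc <- systems[i, ]
    led <- n_balance(cyc, cfg)
    emis <- gwp_total(cyc, cfg, led$n_surplus_for_n2o)
    pest <- pesticide_metrics(cyc, cfg)
    dplyr::bind_cols(
      cyc[, c("system_code", "cycle_index", "season", "climate_zone",
              "water_regime", "ecosystem", "mechanization",
              "harvested_area", "annual_area")],
      tibble(
        yield_actual = cyc$yield_actual,
        yield_potential = cyc$yield_potential,
        closure = closure(cyc$yield_actual, cyc$yield_potential),
        water_supply = cyc$irrigation + cyc$precipitation_in_season,
        labor = cyc$labor_hours,
        n_applications = pest$n_applications,
        ai_total = pest$ai_total,
        eiq = pest$eiq_field_use
      ),
      led, emis)
  })
  dplyr::bind_rows(rows)
}

metric_names <- function() {
  c("yield_actual", "yield_potential", "closure", "water_supply",
    "gwp", "energy_input", "net_energy_yield", "n_input", "n_balance",
    "n_applications", "eiq", "labor")
}

ys_metric_names <- function() {
  c("ys_gwp", "ys_energy", "ys_water", "ys_n_balance", "ys_n_applications",
    "ys_eiq", "ys_labor")
}

#' Per-system metrics on per-crop and annual bases
#'
#' Aggregates the per-cycle assessment to one value per (system, basis,
#' metric). The per-crop basis is the harvested-area-weighted mean across
#' the system's cycles; the annual basis is the sum. Yield-gap closure on
#' each basis is the ratio of aggregated actual to aggregated potential
#' yield. Yield-scaled metrics divide the basis value of the resource
#' metric by the basis yield, so yield-scaled value times yield always
#' reproduces the area-basis value.
#'
#' @param cycles output of [assess_cycles()] (or an [rb_systems] tibble,
#'   which is assessed first).
#' @param cfg an `rb_config` list, required when `cycles` is a systems
#'   table.
#' @return a tidy tibble: `system_code`, `climate_zone`, `water_regime`,
#'   `annual_area`, `basis`, `metric`, `value`.
#' @export
system_metrics <- function(cycles, cfg = NULL) {
  if (!"gwp_total" %in% names(cycles)) {
    if (is.null(cfg)) {
      rb_abort("cfg is required when passing a raw systems table",
               "rb_config_error")
    }
    cycles <- assess_cycles(cycles, cfg)
  }
  base_cols <- c(yield_actual = "yield_actual",
                 yield_potential = "yield_potential",
                 water_supply = "water_supply", gwp = "gwp_total",
                 energy_input = "energy_input",
                 net_energy_yield = "net_energy_yield",
                 n_input = "n_input_total", n_balance = "n_balance",
                 n_applications = "n_applications", eiq = "eiq",
                 labor = "labor")
  per_system <- function(g) {
    w <- g$harvested_area
    agg <- function(fun) {
      vapply(base_cols, function(cl) fun(g[[cl]]), numeric(1))
    }
    pc <- vapply(base_cols, function(cl) per_crop_mean(g[[cl]], w),
                 numeric(1))
    an <- agg(annual_total)
    mk <- function(v, basis) {
      v <- c(v, closure = unname(100 * v[["yield_actual"]] /
                                   v[["yield_potential"]]))
      y <- v[["yield_actual"]]
      ys <- c(ys_gwp = v[["gwp"]], ys_energy = v[["energy_input"]],
              ys_water = v[["water_supply"]],
              ys_n_balance = v[["n_balance"]],
              ys_n_applications = v[["n_applications"]],
              ys_eiq = v[["eiq"]], ys_labor = v[["labor"]])
      ys <- if (y > 0) ys / y else ys * NA_real_
      tibble(basis = basis, metric = names(c(v, ys)),
             value = unname(c(v, ys)))
    }
    out <- dplyr::bind_rows(mk(pc, "per_crop"), mk(an, "annual"))
    out$system_code <- g$system_code[1]
    out$climate_zone <- g$climate_zone[1]
    out$water_regime <- g$water_regime[1]
    out$annual_area <- g$annual_area[1]
    out
  }
  res <- dplyr::bind_rows(lapply(split(cycles, cycles$system_code),
                                 per_system))
  res <- res[, c("system_code", "climate_zone", "water_regime",
                 "annual_area", "basis", "metric", "value")]
  hi <- res$metric == "closure" & !is.na(res$value) & res$value > 100
  if (any(hi)) {
    warn(sprintf("closure above 100%% in %d system/basis combinations (kept unclipped)",
                 sum(hi)), class = "rb_closure_warning")
  }
  dplyr::arrange(res, .data$system_code, .data$basis, .data$metric)
}

#' Pivot a tidy metric table to wide form
#'
#' @param metrics output of [system_metrics()].
#' @param basis `"per_crop"` or `"annual"`.
#' @return one row per system, one column per metric.
#' @export
metrics_wide <- function(metrics, basis = "per_crop") {
  metrics |>
    dplyr::filter(.data$basis == !!basis) |>
    tidyr::pivot_wider(id_cols = c("system_code", "climate_zone",
                                   "water_regime", "annual_area"),
                       names_from = "metric", values_from = "value")
}

#' Write / read a tidy metric table
#'
#' Tidy CSV, one row per (system, basis, metric), deterministic row and
#' column order; values survive a round trip to at least 1e-9 relative.
#'
#' @param metrics output of [system_metrics()].
#' @param path output CSV path.
#' @return `path` invisibly (`write_metrics`); a tibble (`read_metrics`).
#' @export
write_metrics <- function(metrics, path) {
  cols <- c("system_code", "climate_zone", "water_regime", "annual_area",
            "basis", "metric", "value")
  out <- as.data.frame(metrics)[, cols, drop = FALSE]
  out <- out[order(out$system_code, out$basis, out$metric), , drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.csv(format(out, digits = 17, scientific = FALSE,
                          trim = TRUE), con, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$annual_area <- as.numeric(x$annual_area)
  x$value <- as.numeric(x$value)
  tibble::as_tibble(x)
}
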