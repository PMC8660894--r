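#' Pearson correlation with two-tailed significance
#'
#' Product-moment correlation between two per-system vectors, with the
#' two-tailed p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom. Correlations are computed over unweighted system
#' values — each cropping system counts once, regardless of its harvested
#' area.
#'
#' @param x,y numeric vectors of equal length (>= 3), non-zero variance.
#' @param exclude optional logical vector; `TRUE` rows are dropped before
#'   correlating (e.g. to repeat an analysis without one region).
#' @return a list: `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y, exclude = NULL) {
  if (!is.null(exclude)) {
    x <- x[!exclude]
    y <- y[!exclude]
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) {
    rb_abort("pearson needs at least 3 complete pairs", "rb_validation_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rb_abort("pearson needs non-zero variance in both vectors",
             "rb_validation_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n = length(x))
}

default_correlation_pairs <- function() {
  list(
    c("closure", "gwp"), c("closure", "ys_gwp"),
    c("closure", "water_supply"), c("closure", "ys_water"),
    c("closure", "n_applications"), c("closure", "ys_n_applications"),
    c("closure", "n_input"), c("closure", "n_balance"),
    c("closure", "ys_n_balance"),
    c("closure", "labor"), c("closure", "ys_labor"),
    c("energy_input", "gwp"),
    c("n_applications", "eiq")
  )
}

#' Correlation panel across systems
#'
#' Pearson correlations for the standard metric pairs of the assessment
#' (yield-gap closure against area and yield-scaled GWP, water supply,
#' pesticide applications, N input/balance, labor; energy input against
#' GWP; EIQ against applications), computed over per-system values on the
#' requested basis.
#'
#' @param metrics output of [system_metrics()].
#' @param basis `"per_crop"` (default) or `"annual"`.
#' @param pairs list of 2-vectors of metric names; defaults to the standard
#'   panel (pairs with metrics absent from the table are dropped).
#' @param exclude_systems character vector of system codes to leave out
#'   (labelled in the output).
#' @return a tibble: `metric_x`, `metric_y`, `basis`, `r`, `p_value`, `n`,
#'   `excluded`.
#' @export
correlation_panel <- function(metrics, basis = "per_crop", pairs = NULL,
                              exclude_systems = character(0)) {
  wide <- metrics_wide(metrics, basis)
  wide <- wide[!wide$system_code %in% exclude_systems, ]
  pairs <- pairs %||% Filter(
    function(p) all(p %in% names(wide)), default_correlation_pairs())
  rows <- lapply(pairs, function(p) {
    ct <- pearson(wide[[p[1]]], wide[[p[2]]])
    tibble(metric_x = p[1], metric_y = p[2], basis = basis,
           r = ct$r, p_value = ct$p_value, n = ct$n,
           excluded = paste(exclude_systems, collapse = ";"))
  })
  dplyr::bind_rows(rows)
}

#' Cohort summary table
#'
#' Mirrors the headline aggregates of the assessment: area-weighted global
#' means of yield potential, actual yield and closure on per-crop and
#' annual bases, the same contrasts split by climate zone (omitted for a
#' single-zone cohort), and the correlation panel on the per-crop basis.
#'
#' @param metrics output of [system_metrics()].
#' @param exclude_systems passed to [correlation_panel()].
#' @return a list: `global` (tibble), `by_zone` (tibble or NULL),
#'   `correlations` (tibble).
#' @export
results_table <- function(metrics, exclude_systems = character(0)) {
  summarise_group <- function(wide, label, basis) {
    tibble(
      group = label, basis = basis, n_systems = nrow(wide),
      yield_potential = global_weighted_mean(wide$yield_potential,
                                             wide$annual_area),
      yield_actual = global_weighted_mean(wide$yield_actual,
                                          wide$annual_area),
      closure = global_weighted_mean(wide$closure, wide$annual_area)
    )
  }
  global <- dplyr::bind_rows(lapply(c("per_crop", "annual"), function(b) {
    summarise_group(metrics_wide(metrics, b), "all", b)
  }))
  zones <- unique(metrics$climate_zone)
  by_zone <- NULL
  if (length(zones) > 1) {
    by_zone <- dplyr::bind_rows(lapply(c("per_crop", "annual"), function(b) {
      wide <- metrics_wide(metrics, b)
      dplyr::bind_rows(lapply(sort(zones), function(z) {
        summarise_group(wide[wide$climate_zone == z, ], z, b)
      }))
    }))
  }
  list(global = global, by_zone = by_zone,
       correlations = correlation_panel(metrics,
                                        exclude_systems = exclude_systems))
}
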