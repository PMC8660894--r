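performance_metric_map <- function() {
  # six index dimensions, all on the per-crop basis; lower raw value = better
  c(score_yield_gap = "gap_pct", score_gwp = "ys_gwp",
    score_water = "ys_water", score_pesticide = "ys_n_applications",
    score_n_balance = "ysnb_dev", score_labor = "ys_labor")
}

#' Normalized performance scores
#'
#' For each system the six dimensions of the overall performance index are
#' scored by dividing by the maximum value across the normalization cohort,
#' so every score lies in \[0, 1\] and at least one system attains 1 per
#' dimension. The dimensions are the yield gap (100 minus closure, closure
#' clipped at 100% for scoring only) and the yield-scaled global warming
#' potential, water supply, pesticide applications and labor; the N-balance
#' dimension is the absolute deviation of the yield-scaled N balance from
#' the target (8 kg N/Mg grain by default — a level that avoids both soil N
#' mining and large reactive losses), normalized by the cohort maximum
#' deviation. Lower scores are better on every dimension.
#'
#' @param metrics output of [system_metrics()].
#' @param cfg an `rb_config` list.
#' @param cohort `"all"` (default) normalizes across all systems;
#'   `"climate_zone"` normalizes within tropical / non-tropical subsets.
#' @return a tibble: `system_code`, `group` (climate zone), the six scores,
#'   and `overall_index`.
#' @export
normalize_scores <- function(metrics, cfg, cohort = c("all", "climate_zone")) {
  cohort <- match.arg(cohort)
  wide <- metrics_wide(metrics, "per_crop")
  if (nrow(wide) < 2) {
    rb_abort("normalize_scores needs at least 2 systems", "rb_validation_error")
  }
  wide$gap_pct <- 100 - pmin(wide$closure, 100)
  wide$ysnb_dev <- abs(wide$ys_n_balance - cfg$ysnb_target)
  map <- performance_metric_map()
  grp <- if (cohort == "all") rep("all", nrow(wide)) else wide$climate_zone
  scores <- wide[, c("system_code", "climate_zone")]
  names(scores)[2] <- "group"
  scores$group <- wide$climate_zone
  for (sc in names(map)) {
    raw <- wide[[map[[sc]]]]
    mx <- stats::ave(raw, grp, FUN = function(v) max(v, na.rm = TRUE))
    s <- ifelse(mx > 0, raw / mx, 0)
    if (any(mx <= 0)) {
      warn(sprintf("cohort maximum is 0 for %s; score set to 0 (degenerate)",
                   sc), class = "rb_score_warning")
    }
    scores[[sc]] <- s
  }
  scores$overall_index <- overall_index(scores, cfg)
  tibble::as_tibble(scores)
}

#' Overall performance index
#'
#' Averages the six scores with group-balanced weights so that the yield
#' gap, resource-use efficiency and labor carry similar influence: the four
#' resource scores (GWP, water, pesticides, N balance) are first averaged
#' into one block, then the index is the mean of the three blocks
#' `(yield gap + resource block + labor) / 3`. The weights are
#' configurable via `cfg$index_weights` (named: `yield_gap`, `resource`,
#' `labor`; they are normalized to sum to 1). Lower index = better overall
#' performance.
#'
#' @param scores a data frame holding the six score columns.
#' @param cfg an `rb_config` list.
#' @return numeric vector of index values in \[0, 1\].
#' @export
overall_index <- function(scores, cfg) {
  w <- cfg$index_weights %||% list(yield_gap = 1, resource = 1, labor = 1)
  w <- unlist(w[c("yield_gap", "resource", "labor")])
  w <- w / sum(w)
  resource <- rowMeans(cbind(scores$score_gwp, scores$score_water,
                             scores$score_pesticide, scores$score_n_balance))
  w[["yield_gap"]] * scores$score_yield_gap + w[["resource"]] * resource +
    w[["labor"]] * scores$score_labor
}

#' Export radar-chart data
#'
#' Writes the per-system scores in tidy form (`system_code`, `group`,
#' `metric`, `score`), ready for radar plotting, one row per system and
#' dimension.
#'
#' @param scores output of [normalize_scores()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
radar_export <- function(scores, path) {
  if (nrow(scores) == 0) {
    rb_abort("radar_export: empty score table", "rb_validation_error")
  }
  long <- tidyr::pivot_longer(
    scores[, c("system_code", "group", names(performance_metric_map()))],
    cols = dplyr::all_of(names(performance_metric_map())),
    names_to = "metric", values_to = "score")
  long <- dplyr::arrange(long, .data$system_code, .data$metric)
  utils::write.csv(format(as.data.frame(long), digits = 17,
                          scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE)
  invisible(path)
}
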