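#' Pesticide pressure metrics of a crop cycle
#'
#' Counts application events, totals active ingredient, and computes the
#' environmental-impact-quotient (EIQ) field-use rating — sum over events of
#' the active ingredient's EIQ times its rate — overall and split by
#' pesticide class (insecticide / herbicide / fungicide). An active
#' ingredient missing from the EIQ table still counts toward applications
#' and total a.i. but is excluded from the EIQ rating with a warning; given
#' the uncertainty of EIQ values the application count is the headline
#' metric and EIQ is secondary.
#'
#' @inheritParams embodied_emissions
#' @return a list: `n_applications`, `ai_total`, `eiq_field_use`, and
#'   `by_class` (tibble with the same three metrics per class).
#' @export
pesticide_metrics <- function(cycle, cfg) {
  cycle <- as_cycle(cycle)
  apps <- cycle$pesticide_applications
  classes <- c("insecticide", "herbicide", "fungicide")
  if (nrow(apps) == 0) {
    return(list(
      n_applications = 0L, ai_total = 0, eiq_field_use = 0,
      by_class = tibble(class = classes, n_applications = 0L,
                        ai_total = 0, eiq_field_use = 0)))
  }
  if (any(apps$ai_rate < 0)) {
    rb_abort("negative pesticide ai_rate", "rb_validation_error")
  }
  bad <- setdiff(unique(apps$ai_name[apps$ai_rate > 0]),
                 names(cfg$eiq_table))
  if (length(bad)) {
    warn(sprintf("no EIQ value for active ingredient(s): %s; excluded from EIQ rating",
                 paste(bad, collapse = ", ")), class = "rb_eiq_warning")
  }
  eiq_of <- function(ai) {
    vapply(ai, function(a) cfg$eiq_table[[a]] %||% 0, numeric(1))
  }
  apps$eiq <- eiq_of(apps$ai_name) * apps$ai_rate
  by_class <- apps |>
    dplyr::group_by(class = factor(.data$class, levels = classes)) |>
    dplyr::summarise(n_applications = dplyr::n(),
                     ai_total = sum(.data$ai_rate),
                     eiq_field_use = sum(.data$eiq), .groups = "drop") |>
    tidyr::complete(class, fill = list(n_applications = 0L, ai_total = 0,
                                       eiq_field_use = 0)) |>
    dplyr::mutate(class = as.character(class))
  list(n_applications = nrow(apps),
       ai_total = sum(apps$ai_rate),
       eiq_field_use = sum(apps$eiq),
       by_class = by_class)
}
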