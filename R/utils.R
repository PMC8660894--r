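#' @importFrom rlang abort warn %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble is_tibble
NULL

# Typed conditions used throughout: rb_schema_error, rb_integrity_error,
# rb_parse_error, rb_config_error, rb_validation_error.
rb_abort <- function(msg, class) {
  abort(msg, class = c(class, "rb_error"))
}

#' Convert a mass in kilograms to megatonnes
#'
#' 1 Mt = 1e9 kg. Used when summing per-hectare quantities (kg/ha) times
#' harvested area (ha) into cohort totals.
#'
#' @param kg mass in kilograms.
#' @return mass in megatonnes.
#' @export
mt_from_kg <- function(kg) kg / 1e9

#' Convert a mass in megatonnes to kilograms
#' @param mt mass in megatonnes.
#' @return mass in kilograms.
#' @export
kg_from_mt <- function(mt) mt * 1e9

# production helper: Mg (= yield Mg/ha x area ha) to Mt
mt_from_mg <- function(mg) mg / 1e6

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    rb_abort(sprintf("'%s' must be finite and >= 0", what),
             "rb_validation_error")
  }
  invisible(x)
}
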