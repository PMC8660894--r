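#' Default coefficient configuration
#'
#' Returns the packaged coefficient tables used by the accounting modules:
#' 100-year global-warming-potential factors, embodied emission and energy
#' factors for agricultural inputs, the Tier-1 style methane model (baseline
#' daily emission factor, water-regime and pre-season scaling factors,
#' organic-amendment conversion factors and exponent), the nitrogen-surplus
#' nitrous-oxide model, nitrogen-balance coefficients, the
#' environmental-impact-quotient (EIQ) table for the synthetic active
#' ingredients, and the thresholds used by the scenario engine.
#'
#' Key defaults: GWP100 of 25 (CH4) and 298 (N2O) relative to CO2 on a mass
#' basis; indirect N2O taken as 20% of direct; biological N fixation of
#' 30 kg N/ha/crop in lowland rice and 10% of that in upland rice; excess-N
#' threshold 75 kg N/ha; yield-scaled N-balance target 8 kg N/Mg grain;
#' scenario selection cutoffs of 60% yield-gap closure and 100 kg N/ha.
#' Embodied factors and crop N concentrations are documented typical values
#' for rice systems and are meant to be replaced by study-specific tables
#' via [read_config()].
#'
#' @return A list of class `rb_config`.
#' @export
default_config <- function() {
  cfg <- list(
    gwp100 = list(ch4 = 25, n2o = 298),
    # kg CO2-eq per unit of input (units: kg N, kg P2O5, kg K2O, kg seed,
    # kg a.i., kg fresh manure)
    embodied_ef = list(
      n_fertilizer = 4.96, p_fertilizer = 1.35, k_fertilizer = 0.58,
      seed = 0.90, pesticide = 18.0, manure = 0.01
    ),
    # MJ per unit of input, same units as embodied_ef
    embodied_energy = list(
      n_fertilizer = 65.0, p_fertilizer = 9.0, k_fertilizer = 6.8,
      seed = 20.0, pesticide = 300.0, manure = 0.30
    ),
    fuel_ef = 3.10,        # kg CO2-eq per L diesel (incl. upstream)
    fuel_energy = 40.0,    # MJ per L diesel
    labor_energy = 2.0,    # MJ per h of human labor
    grain_energy = 15.2,   # MJ per kg grain dry matter
    dm_fraction = 0.86,    # dry matter at 140 g H2O/kg standard moisture
    energy_dry_matter = TRUE,    # energy output on dry-matter basis
    n_removal_dry_matter = FALSE, # grain/straw N conc on standard-moisture mass
    ch4 = list(
      table_label = "IPCC-2019-refinement-style Tier 1 defaults",
      ef_baseline = 1.19,  # kg CH4/ha/day, continuously flooded, no amendment
      sf_water = list(
        continuously_flooded = 1.00, single_drainage = 0.71,
        multiple_drainage = 0.55, rainfed_regular = 0.54,
        rainfed_drought_prone = 0.16, upland = 0.0
      ),
      sf_preseason = list(
        nonflooded_short = 1.00, nonflooded_long = 0.89, flooded_pre = 2.41
      ),
      cfoa = list(
        straw_short = 1.00, straw_long = 0.19, compost = 0.17,
        farmyard_manure = 0.21, green_manure = 0.45
      ),
      sfo_exponent = 0.59
    ),
    # direct soil N2O from N surplus; exponential params are (a, b) in
    # N2O-N [kg/ha] = a * exp(b * surplus [kg N/ha])
    n2o_direct_model = list(form = "exponential", params = c(0.54, 0.0063)),
    indirect_n2o_fraction = 0.20,
    bnf_lowland = 30,          # kg N/ha/crop
    bnf_upland_fraction = 0.10,
    grain_n_conc = 0.0110,     # kg N per kg grain at standard moisture
    straw_grain_ratio = 1.0,   # straw dry mass : grain mass
    straw_n_conc = 0.0065,     # kg N per kg straw
    straw_n_loss = list(retained = 0.0, removed = 1.0, burned = 0.80),
    surplus_strategy = "aboveground_proxy",
    # EIQ per kg a.i. for the synthetic generator's fictional ingredients
    eiq_table = list(
      insectin_a = 32, insectin_b = 45, herbin_a = 20, herbin_b = 26,
      fungin_a = 38, fungin_b = 48
    ),
    excess_n_threshold = 75,   # kg N/ha
    ysnb_target = 8,           # kg N per Mg grain
    closure_target = 0.75,     # exploitable yield-gap ceiling (fraction of Yp)
    large_gap_cutoff = 0.60,   # closure fraction below which a gap is "large"
    large_nbal_cutoff = 100    # kg N/ha above which an N balance is "large"
  )
  cfg$provenance <- stats::setNames(
    as.list(rep("package default", length(config_tables()))), config_tables()
  )
  structure(cfg, class = "rb_config")
}

config_tables <- function() {
  c("gwp100", "embodied_ef", "embodied_energy", "fuel_ef", "fuel_energy",
    "labor_energy", "grain_energy", "dm_fraction", "energy_dry_matter",
    "n_removal_dry_matter", "ch4", "n2o_direct_model",
    "indirect_n2o_fraction", "bnf_lowland", "bnf_upland_fraction",
    "grain_n_conc", "straw_grain_ratio", "straw_n_conc", "straw_n_loss",
    "surplus_strategy", "eiq_table", "excess_n_threshold", "ysnb_target",
    "closure_target", "large_gap_cutoff", "large_nbal_cutoff")
}

#' Read a coefficient configuration file
#'
#' Reads a YAML or JSON coefficient file and merges it over the packaged
#' defaults: any table omitted from the file keeps its default value and the
#' per-table provenance records where each table came from. The file must
#' contain a `gwp100` table (the one block a study must state explicitly);
#' everything else is optional.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `rb_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    rb_abort(sprintf("config file not found: %s", path), "rb_config_error")
  }
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user$gwp100) || is.null(user$gwp100$ch4) ||
      is.null(user$gwp100$n2o)) {
    rb_abort("config file must define gwp100 (ch4 and n2o factors)",
             "rb_config_error")
  }
  cfg <- default_config()
  for (tab in intersect(names(user), config_tables())) {
    cfg[[tab]] <- modify_table(cfg[[tab]], user[[tab]])
    cfg$provenance[[tab]] <- sprintf("file:%s", path)
  }
  validate_config(cfg)
}

modify_table <- function(base, user) {
  if (!is.list(base) || !is.list(user)) return(user)
  for (nm in names(user)) base[[nm]] <- modify_table(base[[nm]], user[[nm]])
  base
}

#' Write a coefficient configuration to YAML
#'
#' @param cfg an `rb_config` list.
#' @param path output path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$provenance <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(path)
}

#' Validate a coefficient configuration
#'
#' Checks that every factor is finite and non-negative, that the methane
#' model tables are complete, and that the direct-N2O model form is known.
#'
#' @param cfg a config list.
#' @return `cfg`, with class `rb_config`, invisibly usable.
#' @export
validate_config <- function(cfg) {
  num_leaves <- function(x) {
    if (is.list(x)) return(unlist(lapply(x, num_leaves)))
    if (is.numeric(x)) return(x)
    numeric(0)
  }
  for (tab in c("gwp100", "embodied_ef", "embodied_energy", "fuel_ef",
                "fuel_energy", "labor_energy", "grain_energy", "ch4",
                "indirect_n2o_fraction", "bnf_lowland", "bnf_upland_fraction",
                "grain_n_conc", "straw_grain_ratio", "straw_n_conc",
                "straw_n_loss", "eiq_table", "excess_n_threshold",
                "ysnb_target", "closure_target", "large_gap_cutoff",
                "large_nbal_cutoff")) {
    vals <- num_leaves(cfg[[tab]])
    if (any(!is.finite(vals)) || any(vals < 0)) {
      rb_abort(sprintf("config table '%s' contains a negative or non-finite factor",
                       tab), "rb_config_error")
    }
  }
  form <- cfg$n2o_direct_model$form
  if (!form %in% c("exponential", "piecewise_linear")) {
    rb_abort(sprintf("unsupported n2o_direct_model form '%s'", form),
             "rb_config_error")
  }
  if (form == "piecewise_linear") {
    pm <- cfg$n2o_direct_model$params
    if (is.null(pm$knots) || is.null(pm$values) ||
        length(pm$knots) != length(pm$values) || length(pm$knots) < 2) {
      rb_abort("piecewise_linear model needs equal-length 'knots' and 'values' (>= 2)",
               "rb_config_error")
    }
    if (is.unsorted(pm$knots, strictly = TRUE) || is.unsorted(pm$values)) {
      rb_abort("piecewise_linear knots must be strictly increasing and values non-decreasing",
               "rb_config_error")
    }
    if (any(pm$values < 0)) {
      rb_abort("piecewise_linear values must be >= 0", "rb_config_error")
    }
  }
  structure(cfg, class = "rb_config")
}
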