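#' Synthetic-cohort generator specification
#'
#' Describes a seeded synthetic cohort of rice cropping systems with the
#' statistical structure the assessment assumes: per-crop yield potential
#' in a realistic range, yield-gap closure within a band, fertilizer N
#' rising linearly with closure (plus noise), mechanization-dependent labor
#' ranges, intensity-linked pesticide application counts, and log-uniform
#' harvested areas. Optional forced counts pin the number of large-gap
#' (closure below the cutoff) and large-N-balance (per-crop balance above
#' the cutoff) systems exactly, which the generator achieves by drawing
#' closures on the appropriate side of the cutoff and back-computing
#' fertilizer N from a target balance using the same coefficient tables the
#' assessment uses.
#'
#' @param n_systems number of cropping systems.
#' @param seed RNG seed; identical (spec, seed) yields a byte-identical
#'   dataset.
#' @param zone_mix fraction of tropical systems.
#' @param regime_mix fraction of irrigated systems.
#' @param intensity_probs sampling weights for 1/2/3 rice crops per year
#'   (triple rice only occurs in tropical systems).
#' @param yp_range per-crop yield potential range, Mg/ha.
#' @param closure_range yield-gap closure band (fraction of potential).
#' @param n_input_model list `(intercept, slope, sd)`: fertilizer N
#'   (kg N/ha) as a linear function of closure fraction plus Gaussian noise.
#' @param labor_model list of `c(min, max)` labor ranges (h/ha) by
#'   mechanization level.
#' @param area_model `c(min, max)` of the log10 harvested-area range (ha).
#' @param n_large_gap forced count of systems below the large-gap cutoff
#'   (`NULL` = unforced).
#' @param n_large_nbal forced count of systems above the large-N-balance
#'   cutoff (`NULL` = unforced).
#' @return a list of class `rb_cohort_spec`.
#' @export
cohort_spec <- function(n_systems = 32, seed = 1,
                        zone_mix = 0.5, regime_mix = 0.75,
                        intensity_probs = c(0.4, 0.4, 0.2),
                        yp_range = c(5.9, 14.8),
                        closure_range = c(0.20, 0.80),
                        n_input_model = list(intercept = 10, slope = 230,
                                             sd = 15),
                        labor_model = list(high = c(7, 40),
                                           intermediate = c(40, 300),
                                           low = c(300, 900)),
                        area_model = c(4.5, 6.8),
                        n_large_gap = NULL, n_large_nbal = NULL) {
  spec <- list(n_systems = n_systems, seed = seed, zone_mix = zone_mix,
               regime_mix = regime_mix,
               intensity_probs = intensity_probs / sum(intensity_probs),
               yp_range = yp_range, closure_range = closure_range,
               n_input_model = n_input_model, labor_model = labor_model,
               area_model = area_model, n_large_gap = n_large_gap,
               n_large_nbal = n_large_nbal)
  for (k in c("n_large_gap", "n_large_nbal")) {
    if (!is.null(spec[[k]]) && spec[[k]] > n_systems) {
      rb_abort(sprintf("%s (%d) exceeds n_systems (%d)", k, spec[[k]],
                       n_systems), "rb_validation_error")
    }
  }
  structure(spec, class = "rb_cohort_spec")
}

#' Reference 32-system cohort specification
#'
#' The preset used throughout the package's own analyses: 32 systems with
#' exactly 19 forced large-gap and 8 forced large-N-balance systems,
#' roughly half tropical, three-quarters irrigated, and intensity up to
#' triple rice in the tropics — the qualitative layout of published
#' multi-country rice farm-survey compilations.
#'
#' @param seed RNG seed.
#' @return an `rb_cohort_spec`.
#' @export
global_cohort_spec <- function(seed = 1) {
  cohort_spec(n_systems = 32, seed = seed, zone_mix = 0.53,
              regime_mix = 0.75, intensity_probs = c(0.40, 0.40, 0.20),
              n_large_gap = 19, n_large_nbal = 8)
}

region_codes <- function(n) {
  regions <- c("VN", "TH", "PH", "ID", "IN", "BA", "MY", "CN", "CC", "CS",
               "EG", "US", "UC", "AU", "UR", "BS", "BN", "NG", "ML", "TA",
               "MA", "BF", "KR", "JP", "ES", "IT", "PK", "LA", "KH", "NP",
               "SL", "GH", "CI", "SN", "MZ", "PE", "CO", "DO", "GY", "EC")
  regions[((seq_len(n) - 1) %% length(regions)) + 1]
}

#' Generate a synthetic cohort
#'
#' Draws a cohort of cropping systems from an [cohort_spec()]: system
#' descriptors, 1–3 crop cycles with yields tied to potential by the
#' system's closure draw, input rates, pesticide programs with fictional
#' active ingredients (covered by the packaged EIQ table), field
#' operations, water and straw management. The result passes
#' [validate_systems()] and is deterministic in the spec's seed.
#'
#' @param spec an `rb_cohort_spec`.
#' @param cfg coefficient config used to back-compute fertilizer targets;
#'   defaults to [default_config()]. Use the same config for generation and
#'   assessment so forced N-balance counts hold exactly.
#' @return a validated [rb_systems] tibble.
#' @export
generate_cohort <- function(spec, cfg = default_config()) {
  stopifnot(inherits(spec, "rb_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_systems
  cutoff <- cfg$large_gap_cutoff
  lo <- spec$closure_range[1]
  hi <- spec$closure_range[2]

  # climate zone, regime, ecosystem
  n_trop <- round(spec$zone_mix * n)
  zone <- sample(c(rep("tropical", n_trop),
                   rep("non_tropical", n - n_trop)))

  # closure draws, honoring a forced large-gap count
  if (is.null(spec$n_large_gap)) {
    cl <- stats::runif(n, lo, hi)
  } else {
    k <- spec$n_large_gap
    gap_hi <- min(hi, cutoff - 0.02)
    non_lo <- max(lo, cutoff + 0.02)
    if (k > 0 && gap_hi < lo) {
      rb_abort("closure_range incompatible with forced large-gap count",
               "rb_validation_error")
    }
    if (k < n && non_lo > hi) {
      rb_abort("closure_range incompatible with forced non-gap count",
               "rb_validation_error")
    }
    is_gap <- sample(rep(c(TRUE, FALSE), c(k, n - k)))
    cl <- ifelse(is_gap, stats::runif(n, lo, gap_hi),
                 stats::runif(n, non_lo, hi))
  }

  # water regime follows the gap: rainfed systems, exposed to water deficit,
  # sit mostly on the large-gap side, as in real cohorts
  p_rainfed <- ifelse(cl < cutoff,
                      pmin(1, 1.6 * (1 - spec$regime_mix)),
                      0.3 * (1 - spec$regime_mix))
  regime <- ifelse(stats::runif(n) < p_rainfed, "rainfed", "irrigated")
  eco <- rep("lowland", n)
  rf <- which(regime == "rainfed")
  if (length(rf)) eco[rf[1]] <- "upland"  # one rainfed upland system

  # intensity: triple rice only in the tropics
  intensity <- vapply(seq_len(n), function(i) {
    p <- spec$intensity_probs
    if (zone[i] != "tropical") p <- c(p[1] + p[3] / 2, p[2] + p[3] / 2, 0)
    if (eco[i] == "upland") return(1L)
    sample.int(3L, 1L, prob = p)
  }, integer(1))

  # mechanization follows closure (low-input systems are less mechanized)
  mech <- vapply(cl, function(c1) {
    if (c1 < 0.45) sample(c("low", "intermediate"), 1, prob = c(0.8, 0.2))
    else if (c1 < cutoff) sample(c("low", "intermediate"), 1,
                                 prob = c(0.4, 0.6))
    else sample(c("high", "intermediate"), 1, prob = c(0.65, 0.35))
  }, character(1))
  # guarantee every mechanization level appears
  for (lev in c("high", "intermediate", "low")) {
    if (!lev %in% mech) mech[sample.int(n, 1)] <- lev
  }
  estab <- vapply(mech, function(m) {
    switch(m, high = "direct_seeded",
           low = "transplanted",
           sample(c("transplanted", "direct_seeded"), 1))
  }, character(1))
  field_size <- vapply(mech, function(m) {
    switch(m, high = stats::runif(1, 40, 200),
           intermediate = stats::runif(1, 3, 40),
           low = stats::runif(1, 0.3, 3))
  }, numeric(1))

  # designated large-N-balance systems, preferring small-gap systems
  nbal_target <- rep(NA_real_, n)
  if (!is.null(spec$n_large_nbal) && spec$n_large_nbal > 0) {
    pool <- order(cl, decreasing = TRUE)
    chosen <- pool[seq_len(spec$n_large_nbal)]
    nbal_target[chosen] <- stats::runif(spec$n_large_nbal, 115, 180)
  }

  codes <- make.unique(paste0(
    region_codes(n), substr(toupper(regime), 1, 1),
    c("S", "D", "T")[intensity]), sep = "")
  codes <- gsub(".", "", codes, fixed = TRUE)

  straw_pool <- c("retained", "removed", "burned")
  ai_by_class <- list(insecticide = c("insectin_a", "insectin_b"),
                      herbicide = c("herbin_a", "herbin_b"),
                      fungicide = c("fungin_a", "fungin_b"))

  all_rows <- list()
  for (i in seq_len(n)) {
    ncyc <- intensity[i]
    seasons <- switch(ncyc, "single", c("wet", "dry"), c("wet", "dry", "dry"))
    # per-crop yield potential: tropical systems sit lower in the range
    yp_lo <- spec$yp_range[1]
    yp_hi <- spec$yp_range[2]
    yp_base <- if (zone[i] == "tropical") {
      stats::runif(1, yp_lo, yp_lo + 0.55 * (yp_hi - yp_lo))
    } else {
      stats::runif(1, yp_lo + 0.25 * (yp_hi - yp_lo), yp_hi)
    }
    if (eco[i] == "upland") yp_base <- stats::runif(1, yp_lo, yp_lo + 1.5)
    yp <- round(yp_base * stats::runif(ncyc, 0.92, 1.08), 2)
    yp <- pmin(pmax(yp, yp_lo), yp_hi)
    ya <- cl[i] * yp  # identical closure across cycles keeps forced counts exact

    footprint <- 10^stats::runif(1, spec$area_model[1], spec$area_model[2])
    areas <- footprint * stats::runif(ncyc, 0.85, 1.0)

    # mechanized systems mostly incorporate straw; manual systems remove it
    # for fodder or burn it
    straw <- sample(straw_pool, 1, prob = switch(mech[i],
      high = c(0.70, 0.15, 0.15), intermediate = c(0.40, 0.30, 0.30),
      low = c(0.15, 0.45, 0.40)))
    manure_rate <- if (stats::runif(1) < 0.3) stats::runif(1, 2000, 8000) else 0
    manure_n_conc <- 0.005
    wrc <- if (eco[i] == "upland") "upland"
    else if (regime[i] == "rainfed") {
      sample(c("rainfed_regular", "rainfed_drought_prone"), 1,
             prob = c(0.7, 0.3))
    } else {
      # reliable water supply (small-gap systems) favors continuous flooding
      p_cont <- 0.35 + 0.45 * cl[i]
      sample(c("continuously_flooded", "single_drainage",
               "multiple_drainage"), 1,
             prob = c(p_cont, 0.65 * (1 - p_cont), 0.35 * (1 - p_cont)))
    }
    # pre-season fields drain between crops in these cohorts; a flooded
    # pre-season (scaling factor > 2) is supported by the model but not
    # drawn by the generator
    psc <- sample(c("nonflooded_short", "nonflooded_long"), 1,
                  prob = c(0.7, 0.3))

    # nitrogen: removal from the same coefficients the assessment applies
    dm <- if (isTRUE(cfg$n_removal_dry_matter)) cfg$dm_fraction else 1
    removal <- ya * 1000 * dm *
      (cfg$grain_n_conc +
         cfg$straw_grain_ratio * cfg$straw_n_conc * cfg$straw_n_loss[[straw]])
    bnf <- if (eco[i] == "upland") cfg$bnf_lowland * cfg$bnf_upland_fraction
    else cfg$bnf_lowland
    manure_n <- manure_rate * manure_n_conc
    if (!is.na(nbal_target[i])) {
      n_fert <- pmax(0, nbal_target[i] + removal - bnf - manure_n)
    } else {
      m <- spec$n_input_model
      n_fert <- pmax(0, m$intercept + m$slope * cl[i] +
                       stats::rnorm(ncyc, 0, m$sd))
      if (!is.null(spec$n_large_nbal)) {
        # with a forced large-balance count, keep the other systems clear
        # of the cutoff (and, mostly, of the excess-N threshold)
        bal <- n_fert + bnf + manure_n - removal
        bal_pc <- sum(bal * areas) / sum(areas)
        if (bal_pc > 70) {
          n_fert <- pmax(0, n_fert - (bal_pc - stats::runif(1, 20, 65)))
        }
      }
    }

    lab_rng <- spec$labor_model[[mech[i]]]
    labor <- stats::runif(ncyc, lab_rng[1], lab_rng[2])

    n_apps <- pmin(9L, stats::rpois(ncyc, 1 + 8 * cl[i] *
                                      (0.55 + 0.2 * ncyc)))
    class_prob <- if (zone[i] == "tropical") c(0.45, 0.30, 0.25)
    else c(0.20, 0.60, 0.20)
    pest <- lapply(n_apps, function(k) {
      if (k == 0) return(empty_pesticides())
      clz <- sample(names(ai_by_class), k, replace = TRUE,
                    prob = class_prob)
      tibble(class = clz,
             ai_name = vapply(clz, function(cz) sample(ai_by_class[[cz]], 1),
                              character(1)),
             ai_rate = round(stats::runif(k, 0.15, 0.5), 3))
    })

    # water applied tracks the water regime: continuous flooding uses the
    # most, alternate wetting/drying the least
    irrig <- if (regime[i] == "irrigated") {
      switch(wrc,
             continuously_flooded = stats::runif(ncyc, 850, 1400),
             single_drainage = stats::runif(ncyc, 600, 1000),
             stats::runif(ncyc, 400, 750))
    } else rep(0, ncyc)
    precip <- vapply(seasons, function(s) {
      if (zone[i] == "tropical") {
        if (s == "dry") stats::runif(1, 150, 500) else stats::runif(1, 600, 1300)
      } else stats::runif(1, 150, 700)
    }, numeric(1))

    ops <- lapply(seq_len(ncyc), function(j) {
      base <- switch(mech[i],
        high = tibble(name = c("tillage", "establishment", "fertilizing",
                               "harvest"),
                      fuel_l_ha = c(stats::runif(1, 10, 16),
                                    stats::runif(1, 3, 6),
                                    stats::runif(1, 2, 4),
                                    stats::runif(1, 12, 20))),
        intermediate = tibble(name = c("tillage", "harvest"),
                              fuel_l_ha = c(stats::runif(1, 6, 10),
                                            stats::runif(1, 6, 12))),
        low = tibble(name = "tillage", fuel_l_ha = stats::runif(1, 2, 5)))
      if (regime[i] == "irrigated") {
        # pumping fuel scales with the water actually lifted
        base <- dplyr::bind_rows(base, tibble(
          name = "irrigation_pumping",
          fuel_l_ha = round(irrig[j] * stats::runif(1, 0.08, 0.12), 1)))
      }
      base
    })

    amend <- lapply(seq_len(ncyc), function(j) {
      out <- tibble(type = character(0), rate_t_ha = numeric(0))
      if (straw == "retained") {
        # the retained straw is the crop's own: dry mass from yield
        out <- dplyr::bind_rows(out, tibble(
          type = "straw_long",
          rate_t_ha = round(ya[j] * cfg$straw_grain_ratio * cfg$dm_fraction,
                            2)))
      }
      if (manure_rate > 0) {
        out <- dplyr::bind_rows(out, tibble(
          type = "farmyard_manure",
          rate_t_ha = round(manure_rate * 0.25 / 1000, 3)))
      }
      out
    })

    seed_rate <- if (estab[i] == "transplanted") stats::runif(ncyc, 30, 60)
    else stats::runif(ncyc, 80, 150)

    all_rows[[i]] <- tibble(
      system_code = codes[i], country = region_codes(n)[i],
      climate_zone = zone[i], water_regime = regime[i], ecosystem = eco[i],
      establishment = estab[i], mechanization = mech[i],
      field_size = round(field_size[i], 2),
      annual_area = round(sum(areas), 1),
      cycle_index = seq_len(ncyc), season = seasons,
      yield_actual = ya, yield_potential = yp,
      harvested_area = round(areas, 1),
      n_fertilizer = round(rep_len(n_fert, ncyc), 2),
      p_fertilizer = round(rep_len(n_fert, ncyc) * stats::runif(1, 0.3, 0.5), 2),
      k_fertilizer = round(rep_len(n_fert, ncyc) * stats::runif(1, 0.3, 0.6), 2),
      manure_rate = manure_rate, manure_n_conc = manure_n_conc,
      seed_rate = round(seed_rate, 1),
      irrigation = round(irrig, 0), precipitation_in_season = round(precip, 0),
      labor_hours = round(labor, 1), straw_management = straw,
      cultivation_days = round(90 + 4 * yp + stats::runif(ncyc, -8, 8)),
      water_regime_class = wrc, preseason_class = psc,
      replicate_cycle = FALSE,
      pesticide_applications = pest, field_operations = ops,
      organic_amendments = amend
    )
  }
  out <- dplyr::bind_rows(all_rows)
  # ensure every straw-management branch appears in the cohort
  missing_straw <- setdiff(straw_pool, unique(out$straw_management))
  if (length(missing_straw)) {
    # reassign low-closure unforced systems, whose balances sit far from
    # the large-balance cutoff, so forced counts are untouched
    pool <- codes[is.na(nbal_target)][order(cl[is.na(nbal_target)])]
    for (s in missing_straw) {
      code <- pool[1]
      pool <- pool[-1]
      rows <- out$system_code == code
      out$straw_management[rows] <- s
      if (s != "retained") {
        out$organic_amendments[rows] <- lapply(
          out$organic_amendments[rows],
          function(df) df[df$type != "straw_long", ])
      }
    }
  }
  suppressWarnings(validate_systems(out))
}
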