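#' @title Cropping-system tables
#'
#' @description
#' The package carries a cohort of rice cropping systems as a single tibble
#' of class `rb_systems`, one row per crop cycle, with the system-level
#' descriptors (code, country, climate zone, water regime, ecosystem,
#' establishment, mechanization, field size, annual harvested area) repeated
#' on each row — exactly the canonical CSV interchange layout. Three nested
#' attributes of a cycle (pesticide applications, field operations, organic
#' amendments) are list-columns of small tibbles; in the CSV they are
#' encoded as `;`-separated event strings (`class:ai_name:rate`,
#' `name:fuel_l_ha`, `type:rate_t_ha`).
#'
#' @name rb_systems
NULL

system_columns <- function() {
  c("system_code", "country", "climate_zone", "water_regime", "ecosystem",
    "establishment", "mechanization", "field_size", "annual_area")
}

cycle_numeric_columns <- function() {
  c("yield_actual", "yield_potential", "harvested_area", "n_fertilizer",
    "p_fertilizer", "k_fertilizer", "manure_rate", "manure_n_conc",
    "seed_rate", "irrigation", "precipitation_in_season", "labor_hours",
    "cultivation_days", "field_size", "annual_area")
}

canonical_columns <- function() {
  c("system_code", "country", "climate_zone", "water_regime", "ecosystem",
    "establishment", "mechanization", "field_size", "annual_area",
    "cycle_index", "season", "yield_actual", "yield_potential",
    "harvested_area", "n_fertilizer", "p_fertilizer", "k_fertilizer",
    "manure_rate", "manure_n_conc", "seed_rate", "irrigation",
    "precipitation_in_season", "labor_hours", "straw_management",
    "cultivation_days", "water_regime_class", "preseason_class",
    "replicate_cycle", "pesticide_applications", "field_operations",
    "organic_amendments")
}

enum_levels <- function() {
  list(
    season = c("wet", "dry", "single"),
    climate_zone = c("tropical", "non_tropical"),
    water_regime = c("irrigated", "rainfed"),
    ecosystem = c("lowland", "upland"),
    establishment = c("transplanted", "direct_seeded"),
    mechanization = c("high", "intermediate", "low"),
    straw_management = c("retained", "removed", "burned")
  )
}

# ---- event-string encoding -------------------------------------------------

encode_events <- function(lst, fields) {
  vapply(lst, function(df) {
    if (is.null(df) || nrow(df) == 0) return("")
    cols <- lapply(df[, fields, drop = FALSE], function(col) {
      if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
    })
    paste(do.call(paste, c(cols, sep = ":")), collapse = ";")
  }, character(1))
}

decode_events <- function(strings, fields, numeric_fields, what) {
  lapply(seq_along(strings), function(i) {
    s <- strings[[i]]
    empty <- tibble::as_tibble(stats::setNames(
      c(rep(list(character(0)), length(fields) - length(numeric_fields)),
        rep(list(numeric(0)), length(numeric_fields))),
      c(setdiff(fields, numeric_fields), numeric_fields)))[, fields]
    if (is.na(s) || !nzchar(s)) return(empty)
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) != length(fields)
    if (any(bad)) {
      rb_abort(sprintf("row %d: malformed %s event string '%s'", i, what, s),
               "rb_parse_error")
    }
    out <- stats::setNames(
      lapply(seq_along(fields), function(j) {
        vapply(parts, `[[`, character(1), j)
      }), fields)
    for (nf in numeric_fields) {
      v <- suppressWarnings(as.numeric(out[[nf]]))
      if (any(is.na(v))) {
        rb_abort(sprintf("row %d: non-numeric %s in %s event string '%s'",
                         i, nf, what, s), "rb_parse_error")
      }
      out[[nf]] <- v
    }
    tibble::as_tibble(out)
  })
}

empty_pesticides <- function() {
  tibble(class = character(0), ai_name = character(0), ai_rate = numeric(0))
}

# ---- validation ------------------------------------------------------------

#' Validate a cropping-system table
#'
#' Enforces the data contract: mandatory columns present; unique
#' (system_code, cycle_index) pairs; 1–3 cycles per system; all rates
#' finite and non-negative; harvested area strictly positive; cultivation
#' period within 60–220 days; enum fields drawn from their allowed levels.
#' Survey noise where actual yield exceeds yield potential is kept but
#' flagged with a warning, never silently accepted; irrigation reported for
#' a rainfed system is forced to zero with a warning.
#'
#' @param x a tibble, one row per crop cycle.
#' @return the validated table, classed `rb_systems`.
#' @export
validate_systems <- function(x) {
  x <- tibble::as_tibble(x)
  mandatory <- setdiff(canonical_columns(), "replicate_cycle")
  for (col in mandatory) {
    if (!col %in% names(x)) {
      rb_abort(sprintf("missing mandatory column '%s'", col),
               "rb_schema_error")
    }
  }
  key <- paste(x$system_code, x$cycle_index)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    rb_abort(sprintf("duplicate (system_code, cycle_index) pair: %s", dup),
             "rb_integrity_error")
  }
  for (col in setdiff(cycle_numeric_columns(), c("field_size", "annual_area"))) {
    if (!is.numeric(x[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(x[[col]]))) &
                     !is.na(x[[col]]))[1]
      rb_abort(sprintf("row %s: non-numeric value in '%s'",
                       bad %||% "?", col), "rb_parse_error")
    }
    check_nonneg(x[[col]], col)
  }
  if (any(x$harvested_area <= 0)) {
    rb_abort("harvested_area must be > 0", "rb_validation_error")
  }
  if (any(x$cultivation_days < 60 | x$cultivation_days > 220)) {
    rb_abort("cultivation_days must lie in [60, 220]", "rb_validation_error")
  }
  lv <- enum_levels()
  for (col in names(lv)) {
    bad <- setdiff(unique(x[[col]]), lv[[col]])
    if (length(bad)) {
      rb_abort(sprintf("unknown %s value(s): %s", col,
                       paste(bad, collapse = ", ")), "rb_validation_error")
    }
  }
  ncyc <- table(x$system_code)
  if (any(ncyc < 1 | ncyc > 3)) {
    rb_abort("each system must have 1-3 cycles", "rb_integrity_error")
  }
  over <- x$yield_actual > x$yield_potential
  if (any(over)) {
    warn(sprintf("%d cycle(s) report actual yield above yield potential (survey noise); kept as-is",
                 sum(over)), class = "rb_yield_warning")
  }
  wet_irr <- x$water_regime == "rainfed" & x$irrigation > 0
  if (any(wet_irr)) {
    warn(sprintf("irrigation > 0 on %d rainfed cycle(s); forced to 0",
                 sum(wet_irr)), class = "rb_irrigation_warning")
    x$irrigation[wet_irr] <- 0
  }
  for (lc in c("pesticide_applications", "field_operations",
               "organic_amendments")) {
    rates <- unlist(lapply(x[[lc]], function(df) {
      if (nrow(df) == 0) numeric(0) else df[[ncol(df)]]
    }))
    if (length(rates)) check_nonneg(rates, lc)
  }
  if (!"replicate_cycle" %in% names(x)) x$replicate_cycle <- FALSE
  class(x) <- unique(c("rb_systems", class(x)))
  x
}

# ---- read/write ------------------------------------------------------------

#' Read a cropping-system table
#'
#' Reads the canonical CSV interchange format (one row per crop cycle,
#' system descriptors repeated) or the nested JSON form (a list of systems,
#' each holding a `cycles` array). A `mapping` file (YAML, `external: canonical`
#' pairs) can rename external column headers into the canonical schema, so
#' third-party survey exports can be ingested without editing the file.
#'
#' Systems flagged `replicate_cycle` with a single reported cycle have that
#' cycle copied as cycle 2, for surveys that report one crop cycle of a
#' double-rice system and state that management and yield are identical in
#' both cycles.
#'
#' @param path path to a `.csv` or `.json` file.
#' @param mapping optional path to a YAML header-mapping file.
#' @return a validated `rb_systems` tibble.
#' @export
read_systems <- function(path, mapping = NULL) {
  if (!file.exists(path)) {
    rb_abort(sprintf("systems file not found: %s", path), "rb_schema_error")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    x <- tibble::as_tibble(tidyr::unnest(tibble::as_tibble(raw), "cycles"))
    event_schema <- list(
      pesticide_applications = list(fields = c("class", "ai_name", "ai_rate"),
                                    numeric = "ai_rate"),
      field_operations = list(fields = c("name", "fuel_l_ha"),
                              numeric = "fuel_l_ha"),
      organic_amendments = list(fields = c("type", "rate_t_ha"),
                                numeric = "rate_t_ha"))
    for (lc in names(event_schema)) {
      sch <- event_schema[[lc]]
      x[[lc]] <- lapply(x[[lc]], function(df) {
        df <- tibble::as_tibble(df)
        if (nrow(df) == 0 || !all(sch$fields %in% names(df))) {
          df <- tibble::as_tibble(stats::setNames(
            lapply(sch$fields,
                   function(f) if (f %in% sch$numeric) numeric(0)
                   else character(0)), sch$fields))
        }
        df[, sch$fields]
      })
    }
  } else {
    x <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, check.names = FALSE)
    x <- tibble::as_tibble(x)
    if (!is.null(mapping)) {
      mp <- yaml::read_yaml(mapping)
      hit <- names(x) %in% names(mp)
      names(x)[hit] <- unlist(mp[names(x)[hit]])
    }
    for (col in intersect(c(cycle_numeric_columns(), "cycle_index"),
                          names(x))) {
      v <- suppressWarnings(as.numeric(x[[col]]))
      bad <- which(is.na(v) & nzchar(x[[col]]) & !is.na(x[[col]]))
      if (length(bad)) {
        rb_abort(sprintf("row %d: non-numeric value '%s' in column '%s'",
                         bad[1], x[[col]][bad[1]], col), "rb_parse_error")
      }
      x[[col]] <- v
    }
    if ("replicate_cycle" %in% names(x)) {
      x$replicate_cycle <- toupper(x$replicate_cycle) %in% c("TRUE", "T", "1")
    }
    if ("pesticide_applications" %in% names(x)) {
      x$pesticide_applications <- decode_events(
        x$pesticide_applications, c("class", "ai_name", "ai_rate"),
        "ai_rate", "pesticide")
    }
    if ("field_operations" %in% names(x)) {
      x$field_operations <- decode_events(
        x$field_operations, c("name", "fuel_l_ha"), "fuel_l_ha", "operation")
    }
    if ("organic_amendments" %in% names(x)) {
      x$organic_amendments <- decode_events(
        x$organic_amendments, c("type", "rate_t_ha"), "rate_t_ha", "amendment")
    }
  }
  for (col in c("system_code", "cycle_index")) {
    if (!col %in% names(x)) {
      rb_abort(sprintf("missing mandatory column '%s'", col),
               "rb_schema_error")
    }
  }
  x <- replicate_flagged_cycles(x)
  x <- x[order(x$system_code, x$cycle_index), ]
  validate_systems(x)
}

replicate_flagged_cycles <- function(x) {
  if (!"replicate_cycle" %in% names(x)) return(x)
  codes <- unique(x$system_code[x$replicate_cycle %in% TRUE])
  for (code in codes) {
    rows <- which(x$system_code == code)
    if (length(rows) == 1L) {
      copy <- x[rows, ]
      copy$cycle_index <- copy$cycle_index + 1L
      x <- dplyr::bind_rows(x, copy)
    }
  }
  x
}

#' Write a cropping-system table
#'
#' Writes the canonical CSV (deterministic column order, event-string
#' encoding for the nested list-columns) or nested JSON, chosen by file
#' extension. `read_systems(write_systems(x))` reproduces `x`.
#'
#' @param x an `rb_systems` tibble.
#' @param path output path (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_systems <- function(x, path) {
  x <- tibble::as_tibble(x)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    syscols <- system_columns()
    nested <- lapply(split(x, x$system_code), function(g) {
      cyc <- g[, setdiff(names(g), syscols)]
      c(as.list(g[1, syscols]), list(cycles = cyc))
    })
    jsonlite::write_json(unname(nested), path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    return(invisible(path))
  }
  out <- x
  out$pesticide_applications <- encode_events(
    x$pesticide_applications, c("class", "ai_name", "ai_rate"))
  out$field_operations <- encode_events(
    x$field_operations, c("name", "fuel_l_ha"))
  out$organic_amendments <- encode_events(
    x$organic_amendments, c("type", "rate_t_ha"))
  cols <- c(intersect(canonical_columns(), names(out)),
            setdiff(names(out), canonical_columns()))
  out <- as.data.frame(out)[, cols]
  # replicated cycles are written once, with the flag set
  if ("replicate_cycle" %in% names(out)) {
    drop <- out$replicate_cycle & out$cycle_index > 1 &
      duplicated(out$system_code)
    out <- out[!drop, ]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' System-level descriptor table
#'
#' Collapses an `rb_systems` cycle table to one row per system, keeping the
#' system-level descriptor columns.
#'
#' @param x an `rb_systems` tibble.
#' @return a tibble with one row per system plus `n_cycles`.
#' @export
system_table <- function(x) {
  x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(system_columns()))) |>
    dplyr::summarise(n_cycles = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$system_code)
}
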