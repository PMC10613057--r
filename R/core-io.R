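#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble tribble
#' @importFrom generics tidy glance
#' @import dplyr
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Facility levels of the PHC network
#'
#' The three facility levels of a Kenyan-style primary health care (PHC)
#' network: dispensaries (level 2), health centers (level 3), and primary
#' (sub-county) hospitals (level 4). Every facility belongs to exactly one.
#'
#' @return Character vector of the three level names, in ascending order of
#'   care level.
#' @export
#' @examples
#' phc_levels()
phc_levels <- function() {
  c("dispensary", "health_center", "primary_hospital")
}

as_phc_level <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), phc_levels())
  if (length(bad) > 0) {
    abort(paste0(
      "Unknown facility level(s): ", paste(bad, collapse = ", "),
      ". Must be one of: ", paste(phc_levels(), collapse = ", ")
    ))
  }
  factor(x, levels = phc_levels())
}

#' Cost categories of a facility-year cost breakdown
#'
#' The four recurrent cost categories recorded per facility-year, all in
#' USD/year: clinical labor, drugs, medical supplies, and other indirect
#' costs (non-clinical personnel, utilities, operations).
#'
#' @return Character vector of the four cost-category column names.
#' @export
phc_cost_categories <- function() {
  c("clinical_labor", "drugs", "medical_supplies", "indirect")
}

facility_columns <- function() {
  c("facility_id", "sub_county", "level", "clinical_staff",
    "nonclinical_staff", "outpatient_visits", "inpatient_bed_days",
    phc_cost_categories())
}

#' Run configuration for the costing pipeline
#'
#' Bundles the analysis-wide settings: the outpatient/inpatient cost-weight
#' scheme, working days per year for caseload denominators, the share of
#' clinical staff time spent on necessary non-clinical work, the currency
#' exchange rate applied once at ingest, the sensitivity perturbation
#' specification, and reporting precision.
#'
#' @param weight_scheme Cost-weight scheme, see [weight_scheme()].
#' @param working_days_per_year Working days per clinical staff per year used
#'   as the caseload denominator. Default 264 (22 days x 12 months).
#' @param nonclinical_time_share Fraction of paid clinical time devoted to
#'   necessary non-clinical activities (administration, reporting, training).
#'   Must lie in `[0, 1)`. Default 0.30.
#' @param exchange_rate_kes_per_usd Kenyan shillings per US dollar, applied
#'   once when ingesting KES-denominated ledgers. Default 101.99.
#' @param perturbation_spec Sensitivity perturbations, see
#'   [sensitivity_spec()].
#' @param digits_per_capita Decimal places for reported per-capita USD values
#'   and ratios. Default 1.
#' @param digits_totals Decimal places for reported cost totals. Default 0.
#' @return A list of class `phc_config`.
#' @export
#' @examples
#' cfg <- phc_config()
#' cfg$nonclinical_time_share
phc_config <- function(weight_scheme = phccostgap::weight_scheme(),
                       working_days_per_year = 264,
                       nonclinical_time_share = 0.30,
                       exchange_rate_kes_per_usd = 101.99,
                       perturbation_spec = sensitivity_spec(),
                       digits_per_capita = 1,
                       digits_totals = 0) {
  stopifnot(working_days_per_year > 0)
  if (nonclinical_time_share < 0 || nonclinical_time_share >= 1) {
    abort("`nonclinical_time_share` must lie in [0, 1).")
  }
  if (exchange_rate_kes_per_usd <= 0) {
    abort("`exchange_rate_kes_per_usd` must be positive.")
  }
  structure(
    list(
      weight_scheme = weight_scheme,
      working_days_per_year = working_days_per_year,
      nonclinical_time_share = nonclinical_time_share,
      exchange_rate_kes_per_usd = exchange_rate_kes_per_usd,
      perturbation_spec = perturbation_spec,
      digits_per_capita = digits_per_capita,
      digits_totals = digits_totals
    ),
    class = "phc_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' Unrecognised keys are ignored with a warning; missing keys fall back to
#' the [phc_config()] defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `phc_config` list.
#' @export
read_phc_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(phc_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    warn(paste0("Ignoring unknown config key(s): ", paste(extra, collapse = ", ")))
  }
  args <- raw[intersect(names(raw), known)]
  if (!is.null(args$weight_scheme)) {
    ws <- args$weight_scheme
    args$weight_scheme <- weight_scheme(
      ip_weight = ws$ip_weight %||% 432,
      op_weights = unlist(ws$op_weights)
    )
  }
  if (!is.null(args$perturbation_spec)) {
    ps <- lapply(args$perturbation_spec, function(p) c(low = p[[1]], high = p[[2]]))
    args$perturbation_spec <- do.call(sensitivity_spec, ps)
  }
  do.call(phc_config, args)
}

#' Round half away from zero
#'
#' Commercial rounding as used in the reported tables (e.g. 1.568 -> 1.6,
#' 0.25 -> 0.3 at one decimal), as opposed to base R's round-half-to-even.
#' Halves are rounded away from zero.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(1.568, 1)   # 1.6
#' round_half_up(0.25, 1)    # 0.3 (base round() gives 0.2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by a few ulp so values that are exactly .5 in decimal but stored
  # fractionally below it (e.g. 0.25 * 10 = 2.4999...) still round up
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

validate_facilities <- function(facilities, context = "facility table") {
  facilities <- as_tibble(facilities)
  missing <- setdiff(facility_columns(), names(facilities))
  if (length(missing) > 0) {
    abort(paste0(
      "Missing required column(s) in ", context, ": ",
      paste(missing, collapse = ", ")
    ))
  }
  facilities$level <- as_phc_level(facilities$level)
  num_cols <- setdiff(facility_columns(), c("facility_id", "sub_county", "level"))
  if (nrow(facilities) == 0) {
    # header-only input: column types cannot be inferred from data
    for (col in num_cols) facilities[[col]] <- as.numeric(facilities[[col]])
  }
  for (col in num_cols) {
    v <- facilities[[col]]
    if (!is.numeric(v)) abort(paste0("Column `", col, "` must be numeric."))
    neg <- which(v < 0)
    if (length(neg) > 0) {
      abort(paste0(
        "Negative value in column `", col, "` at row ", neg[1],
        " of ", context, "."
      ))
    }
  }
  no_staff <- which(facilities$clinical_staff < 1 &
                      (facilities$outpatient_visits > 0 |
                         facilities$inpatient_bed_days > 0))
  if (length(no_staff) > 0) {
    abort(paste0(
      "Row ", no_staff[1], " of ", context,
      " reports service volume but no clinical staff."
    ))
  }
  zero_op <- facilities$facility_id[facilities$outpatient_visits == 0 &
                                      facility_total_cost(facilities) > 0]
  if (length(zero_op) > 0) {
    inform(paste0(
      "Facility(ies) with zero outpatient visits but positive cost ",
      "(carried in totals, contribute 0 to capture fractions): ",
      paste(zero_op, collapse = ", ")
    ))
  }
  facilities
}

#' Total recurrent cost of each facility
#'
#' Sum of the four cost categories (clinical labor, drugs, medical supplies,
#' indirect), per row.
#'
#' @param facilities Data frame with the four cost-category columns in USD.
#' @return Numeric vector of facility-year totals (USD).
#' @export
facility_total_cost <- function(facilities) {
  rowSums(as.matrix(as.data.frame(facilities)[, phc_cost_categories()]))
}

#' Read a facility cost-and-volume table
#'
#' Reads one row per sampled facility: identifiers, level, staffing, annual
#' service volumes, and the four recurrent cost categories in USD/year.
#' Unknown columns are dropped with a warning; missing required columns and
#' negative costs or volumes are hard errors.
#'
#' @param path Path to a CSV file with a header row naming all required
#'   columns (see [phc_cost_categories()] and the example file in
#'   `system.file("extdata", package = "phccostgap")`).
#' @param kes_columns Optional character vector of cost columns denominated
#'   in Kenyan shillings, converted to USD at `exchange_rate` on ingest.
#' @param exchange_rate KES per USD used for `kes_columns`. Default 101.99.
#' @return A tibble of facilities, one row each, validated.
#' @export
read_facility_table <- function(path, kes_columns = NULL,
                                exchange_rate = 101.99) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  extra <- setdiff(names(df), facility_columns())
  if (length(extra) > 0) {
    warn(paste0("Ignoring unknown column(s): ", paste(extra, collapse = ", ")))
    df <- df[, intersect(names(df), facility_columns()), drop = FALSE]
  }
  for (col in intersect(kes_columns, names(df))) {
    df[[col]] <- df[[col]] / exchange_rate
  }
  validate_facilities(df, context = basename(path))
}

#' Assemble a sub-county frame
#'
#' A sub-county frame holds everything the extrapolation stage needs for one
#' sub-county: its population, the sampled facilities, and the universe
#' outpatient totals per facility level from the routine health information
#' system (KHIS). If a level's universe total falls below the sampled total
#' (possible with noisy routine data), it is clamped up to the sampled total
#' with a warning so extrapolation never shrinks sampled costs.
#'
#' @param name Sub-county name.
#' @param county County name.
#' @param population Catchment population (> 0).
#' @param facilities Tibble of sampled facilities in this sub-county.
#' @param universe_op Named numeric vector or tibble (`level`, `universe_op`)
#'   of universe outpatient visits per level.
#' @return A list of class `phc_subcounty`.
#' @export
subcounty_frame <- function(name, county, population, facilities, universe_op) {
  if (!is.numeric(population) || population <= 0) {
    abort(paste0("Population of sub-county ", name, " must be > 0."))
  }
  facilities <- validate_facilities(facilities, context = paste0("sub-county ", name))
  if (is.data.frame(universe_op)) {
    uo <- stats::setNames(universe_op$universe_op, as.character(universe_op$level))
  } else {
    uo <- universe_op
  }
  full <- stats::setNames(rep(0, 3), phc_levels())
  full[names(uo)] <- uo
  sampled_op <- facilities |>
    group_by(level = .data$level) |>
    summarise(op = sum(.data$outpatient_visits), .groups = "drop")
  for (i in seq_len(nrow(sampled_op))) {
    lv <- as.character(sampled_op$level[i])
    if (full[[lv]] < sampled_op$op[i]) {
      warn(paste0(
        "Universe outpatient total for ", lv, " in ", name, " (", full[[lv]],
        ") is below the sampled total (", sampled_op$op[i],
        "); clamping to the sampled total (capture fraction 1)."
      ))
      full[[lv]] <- sampled_op$op[i]
    }
  }
  structure(
    list(name = name, county = county, population = population,
         facilities = facilities, universe_op = full),
    class = "phc_subcounty"
  )
}

#' @export
print.phc_subcounty <- function(x, ...) {
  cat("<phc_subcounty> ", x$name, " (", x$county, ")\n", sep = "")
  cat("  population:", format(x$population, big.mark = ","), "\n")
  cat("  sampled facilities:", nrow(x$facilities), "\n")
  cat("  universe outpatient visits:",
      paste(names(x$universe_op), format(x$universe_op, big.mark = ","),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read sub-county frames from three CSV files
#'
#' @param facility_path CSV of sampled facilities (see
#'   [read_facility_table()]).
#' @param universe_path CSV keyed by (`sub_county`, `level`) with a
#'   `universe_op` column of universe outpatient visits.
#' @param population_path CSV keyed by `sub_county` with `county` and
#'   `population` columns.
#' @return A list of `phc_subcounty` frames, ordered by sub-county name.
#' @export
read_subcounty_frames <- function(facility_path, universe_path, population_path) {
  facilities <- read_facility_table(facility_path)
  universe <- readr::read_csv(universe_path, show_col_types = FALSE, progress = FALSE)
  pops <- readr::read_csv(population_path, show_col_types = FALSE, progress = FALSE)
  for (col in c("sub_county", "level", "universe_op")) {
    if (!col %in% names(universe)) {
      abort(paste0("Universe file is missing required column: ", col))
    }
  }
  for (col in c("sub_county", "population")) {
    if (!col %in% names(pops)) {
      abort(paste0("Population file is missing required column: ", col))
    }
  }
  scs <- sort(unique(facilities$sub_county))
  missing_pop <- setdiff(scs, pops$sub_county)
  if (length(missing_pop) > 0) {
    abort(paste0(
      "Sub-county(ies) present in facilities but absent from population file: ",
      paste(missing_pop, collapse = ", ")
    ))
  }
  purrr::map(scs, function(sc) {
    prow <- pops[pops$sub_county == sc, ]
    urows <- universe[universe$sub_county == sc, c("level", "universe_op")]
    subcounty_frame(
      name = sc,
      county = if ("county" %in% names(prow)) prow$county[1] else NA_character_,
      population = prow$population[1],
      facilities = facilities[facilities$sub_county == sc, ],
      universe_op = urows
    )
  })
}

#' Write a stage result to CSV with reported (rounded) companions
#'
#' Writes any stage result (a data frame) with a deterministic column order:
#' unrounded numeric columns, each followed by a `<name>_reported` companion
#' rounded half away from zero at the configured precision — per-capita
#' values and ratios at `digits_per_capita`, totals at `digits_totals`.
#'
#' @param results Data frame of results; an empty frame writes a header-only
#'   file.
#' @param path Output CSV path.
#' @param config A [phc_config()]; controls reported precision.
#' @param per_capita_cols Columns rounded at per-capita precision; by default
#'   columns matching `_pc`, `per_capita`, `multiple`, `fraction`, or `rate`.
#' @return The augmented tibble, invisibly.
#' @export
write_results <- function(results, path, config = phc_config(),
                          per_capita_cols = NULL) {
  results <- as_tibble(results)
  num_cols <- names(results)[vapply(results, is.numeric, logical(1))]
  if (is.null(per_capita_cols)) {
    per_capita_cols <- grep("(_pc$|per_capita|multiple|fraction|rate|caseload)",
                            num_cols, value = TRUE)
  }
  out <- results
  for (col in num_cols) {
    digits <- if (col %in% per_capita_cols) config$digits_per_capita else config$digits_totals
    out[[paste0(col, "_reported")]] <- round_half_up(results[[col]], digits)
  }
  ord <- unlist(lapply(names(results), function(nm) {
    rep_nm <- paste0(nm, "_reported")
    c(nm, if (rep_nm %in% names(out)) rep_nm)
  }))
  out <- out[, ord, drop = FALSE]
  readr::write_csv(out, path, progress = FALSE)
  invisible(out)
}
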