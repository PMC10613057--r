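#' WHO-CHOICE outpatient/inpatient cost-weight scheme
#'
#' Relative cost weights used to convert inpatient bed-days into
#' outpatient-visit equivalents when allocating facility costs and computing
#' weighted caseloads. The defaults are the WHO-CHOICE ratios: an inpatient
#' day weighs 432 cost units at every level, against an outpatient visit at
#' 126 in primary hospitals, 111 in health centers, and 90 in dispensaries
#' (ratios 432:126, 432:111, 432:90).
#'
#' @param ip_weight Inpatient-day weight (same at all levels). Default 432.
#' @param op_weights Named numeric vector of outpatient-visit weights per
#'   facility level.
#' @return A list of class `phc_weights` with elements `ip_weight` and
#'   `op_weights`.
#' @export
#' @examples
#' ws <- weight_scheme()
#' ws$ip_weight / ws$op_weights["dispensary"]  # 4.8 OP-equivalents per bed-day
weight_scheme <- function(ip_weight = 432,
                          op_weights = c(dispensary = 90,
                                         health_center = 111,
                                         primary_hospital = 126)) {
  stopifnot(ip_weight > 0, all(op_weights > 0))
  missing <- setdiff(phc_levels(), names(op_weights))
  if (length(missing) > 0) {
    abort(paste0("`op_weights` missing level(s): ", paste(missing, collapse = ", ")))
  }
  if (any(ip_weight < op_weights)) {
    abort("`ip_weight` must be at least the outpatient weight at every level.")
  }
  structure(list(ip_weight = ip_weight, op_weights = op_weights[phc_levels()]),
            class = "phc_weights")
}

#' Weighted service volume in outpatient equivalents
#'
#' Converts a facility's annual service volume to outpatient-visit
#' equivalents: `op_visits + ip_days * ip_weight / op_weight[level]`. With
#' the default weights one inpatient bed-day counts as 432/126 ~ 3.43
#' outpatient visits in a hospital, 432/111 ~ 3.89 in a health center, and
#' 432/90 = 4.8 in a dispensary.
#'
#' @param op_visits Outpatient visits per year (vectorised).
#' @param ip_days Inpatient bed-days per year.
#' @param level Facility level(s), recycled against the volumes.
#' @param scheme A [weight_scheme()].
#' @return Numeric vector of outpatient-equivalent volumes per year.
#' @export
#' @examples
#' weighted_volume(9620, 666, "primary_hospital")  # 11903.43
weighted_volume <- function(op_visits, ip_days, level, scheme = weight_scheme()) {
  stopifnot(all(op_visits >= 0), all(ip_days >= 0))
  level <- as_phc_level(level)
  unname(op_visits + ip_days * scheme$ip_weight /
           scheme$op_weights[as.character(level)])
}

#' Allocate facility costs between outpatient and inpatient care
#'
#' Sums each facility's four recurrent cost categories and splits the total
#' between outpatient visits and inpatient bed-days in proportion to weighted
#' service volumes: the cost per outpatient equivalent is total cost divided
#' by weighted volume; outpatient cost is visits times that unit cost; the
#' inpatient cost is the remainder, so the two always reconstruct the total.
#' A facility with positive cost but zero weighted volume is flagged
#' `unallocatable`: its cost is carried but the unit cost is undefined (NA).
#'
#' @param facilities Data frame of facilities (one row each) with level,
#'   service volumes, and the four cost-category columns.
#' @param scheme A [weight_scheme()].
#' @return The input tibble with columns `total_cost`, `weighted_volume`,
#'   `cost_per_op_equivalent`, `op_cost`, `ip_cost`, and `unallocatable`
#'   appended.
#' @export
allocate_costs <- function(facilities, scheme = weight_scheme()) {
  facilities <- as_tibble(facilities)
  total <- facility_total_cost(facilities)
  wv <- weighted_volume(facilities$outpatient_visits,
                        facilities$inpatient_bed_days,
                        facilities$level, scheme)
  unit <- ifelse(wv > 0, total / wv, NA_real_)
  op_cost <- ifelse(wv > 0, facilities$outpatient_visits * unit,
                    ifelse(total > 0, NA_real_, 0))
  # the inpatient cost is the remainder so the two always sum to the total;
  # clamp the floating-point dust when all volume is outpatient
  ip_cost <- ifelse(wv > 0, pmax(total - op_cost, 0),
                    ifelse(total > 0, NA_real_, 0))
  op_cost <- ifelse(wv > 0, total - ip_cost, op_cost)
  flagged <- wv == 0 & total > 0
  if (any(flagged)) {
    warn(paste0(
      "Facility(ies) with positive cost but zero service volume are ",
      "unallocatable: ", paste(facilities$facility_id[flagged], collapse = ", ")
    ))
  }
  facilities |>
    mutate(total_cost = total,
           weighted_volume = wv,
           cost_per_op_equivalent = unit,
           op_cost = op_cost,
           ip_cost = ip_cost,
           unallocatable = flagged)
}

#' Daily caseloads per clinical staff
#'
#' Two productivity metrics per facility: outpatient visits per clinical
#' staff per working day, and weighted service volume (outpatient
#' equivalents) per clinical staff per working day. A facility with no
#' clinical staff yields NA and is flagged.
#'
#' @param facilities Data frame of facilities.
#' @param scheme A [weight_scheme()].
#' @param working_days Working days per year in the denominator (default
#'   264 = 22 days x 12 months).
#' @return The input tibble with `op_caseload` and `weighted_caseload`
#'   columns appended (services per clinical staff per day).
#' @export
#' @examples
#' kajiado <- tibble::tibble(
#'   facility_id = "h1", sub_county = "Kajiado East", level = "primary_hospital",
#'   clinical_staff = 119, nonclinical_staff = 50,
#'   outpatient_visits = 101672, inpatient_bed_days = 0,
#'   clinical_labor = 0, drugs = 0, medical_supplies = 0, indirect = 0
#' )
#' staff_caseloads(kajiado)$op_caseload  # 3.236 -> reported 3.2
staff_caseloads <- function(facilities, scheme = weight_scheme(),
                            working_days = 264) {
  stopifnot(working_days > 0)
  facilities <- as_tibble(facilities)
  no_staff <- facilities$clinical_staff < 1
  if (any(no_staff)) {
    warn(paste0("Facility(ies) with no clinical staff, caseload undefined: ",
                paste(facilities$facility_id[no_staff], collapse = ", ")))
  }
  denom <- ifelse(no_staff, NA_real_, facilities$clinical_staff * working_days)
  wv <- weighted_volume(facilities$outpatient_visits,
                        facilities$inpatient_bed_days,
                        facilities$level, scheme)
  facilities |>
    mutate(op_caseload = .data$outpatient_visits / denom,
           weighted_caseload = wv / denom)
}

#' Pooled overhead rate per facility level
#'
#' The overhead rate of a level is total indirect cost divided by the sum of
#' clinical labor, drug, medical supply, and indirect costs, pooled over all
#' sampled facilities at that level (a ratio of sums, not a mean of
#' per-facility ratios). It is the loading factor later applied to normative
#' direct costs.
#'
#' @param facilities Data frame of sampled facilities.
#' @param levels Level(s) to compute; defaults to all levels present.
#' @return Tibble with columns `level` and `overhead_rate` (fraction in
#'   `[0, 1)` whenever any non-indirect cost is positive).
#' @export
#' @examples
#' f <- tibble::tibble(
#'   facility_id = c("a", "b"), sub_county = "x",
#'   level = "dispensary", clinical_staff = 1, nonclinical_staff = 0,
#'   outpatient_visits = 10, inpatient_bed_days = 0,
#'   clinical_labor = c(60, 0), drugs = c(25, 0),
#'   medical_supplies = c(5, 0), indirect = c(10, 100)
#' )
#' pooled_overhead_rates(f)$overhead_rate  # 110/200 = 0.55, not mean(0.05, 1)
pooled_overhead_rates <- function(facilities, levels = NULL) {
  facilities <- as_tibble(facilities)
  present <- unique(as.character(facilities$level))
  levels <- levels %||% intersect(phc_levels(), present)
  missing <- setdiff(levels, present)
  if (length(missing) > 0) {
    abort(paste0("No facilities at level(s): ", paste(missing, collapse = ", ")))
  }
  out <- facilities |>
    filter(as.character(.data$level) %in% levels) |>
    mutate(total_cost = facility_total_cost(pick(everything()))) |>
    group_by(level = as.character(.data$level)) |>
    summarise(indirect_total = sum(.data$indirect),
              grand_total = sum(.data$total_cost),
              .groups = "drop")
  if (any(out$grand_total <= 0)) {
    bad <- out$level[out$grand_total <= 0]
    abort(paste0("No positive total cost at level(s): ",
                 paste(bad, collapse = ", ")))
  }
  out |>
    mutate(overhead_rate = .data$indirect_total / .data$grand_total) |>
    arrange(match(.data$level, phc_levels())) |>
    select("level", "overhead_rate")
}

#' Cost-category shares by facility level
#'
#' Pooled share of each recurrent cost category in total cost, by facility
#' level — the content of the usual stacked-bar cost-distribution figure.
#'
#' @param facilities Data frame of facilities.
#' @return Tibble with `level`, `category`, `cost`, and `share` columns.
#' @export
cost_category_shares <- function(facilities) {
  as_tibble(facilities) |>
    tidyr::pivot_longer(all_of(phc_cost_categories()),
                        names_to = "category", values_to = "cost") |>
    group_by(level = as.character(.data$level),
             category = factor(.data$category, levels = phc_cost_categories())) |>
    summarise(cost = sum(.data$cost), .groups = "drop_last") |>
    mutate(share = .data$cost / sum(.data$cost)) |>
    ungroup() |>
    arrange(match(.data$level, phc_levels()), .data$category)
}

#' Summary of facility characteristics by level and sub-county
#'
#' Means and ranges of staffing, service volumes, and daily caseloads per
#' clinical staff, grouped by sub-county and facility level — the standard
#' sample-characteristics table of a facility costing study. Caseload means
#' are means of per-facility ratios.
#'
#' @param facilities Data frame of facilities.
#' @param scheme A [weight_scheme()].
#' @param working_days Caseload denominator, see [staff_caseloads()].
#' @return Tibble with one row per (sub_county, level): facility count `n`,
#'   and mean/min/max of staff counts, volumes, and both caseloads.
#' @export
caseload_summary <- function(facilities, scheme = weight_scheme(),
                             working_days = 264) {
  staff_caseloads(facilities, scheme, working_days) |>
    group_by(.data$sub_county, level = as.character(.data$level)) |>
    summarise(
      n = n(),
      across(c("clinical_staff", "nonclinical_staff", "outpatient_visits",
               "inpatient_bed_days", "op_caseload", "weighted_caseload"),
             list(mean = mean, min = min, max = max)),
      .groups = "drop"
    ) |>
    arrange(.data$sub_county, match(.data$level, phc_levels()))
}
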