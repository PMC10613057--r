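resource_kinds <- function() c("drug", "diagnostic", "reagent", "human_resource")

#' Validate a standard treatment protocol (STP) catalog
#'
#' An STP catalog is two tables. The service master has one row per service:
#' `service_id`, `khis_group` (routine reporting group), `levels_offered`
#' (comma-separated facility levels), `encounters_per_episode` (>= 1),
#' `need_basis` (incidence, prevalence, or utilization_rate), and
#' `need_rate` (episodes per person-year). The resource lines table has one
#' row per ingredient: `service_id`, `kind` (drug, diagnostic, reagent, or
#' human_resource), `quantity` (units per encounter; minutes per encounter
#' for human resources), `cadre` (required iff human_resource), `unit_cost`
#' (USD per unit; USD per minute of salaried time for human resources), and
#' optional logical `per_episode` (line is costed once per episode instead
#' of once per encounter; default FALSE).
#'
#' @param services Service-master data frame.
#' @param lines Resource-lines data frame.
#' @return A list of class `stp_catalog` with validated `services` and
#'   `lines` tibbles (`levels_offered` parsed into a list column).
#' @export
stp_catalog <- function(services, lines) {
  services <- as_tibble(services)
  lines <- as_tibble(lines)
  req_s <- c("service_id", "khis_group", "levels_offered",
             "encounters_per_episode", "need_basis", "need_rate")
  req_l <- c("service_id", "kind", "quantity", "unit_cost")
  miss <- setdiff(req_s, names(services))
  if (length(miss) > 0) abort(paste0("Service master missing column(s): ",
                                     paste(miss, collapse = ", ")))
  miss <- setdiff(req_l, names(lines))
  if (length(miss) > 0) abort(paste0("Resource lines missing column(s): ",
                                     paste(miss, collapse = ", ")))
  if (anyDuplicated(services$service_id)) abort("Duplicate service_id in service master.")
  if (!is.list(services$levels_offered)) {
    services$levels_offered <- strsplit(as.character(services$levels_offered),
                                        "\\s*[,;]\\s*")
  }
  purrr::walk2(services$levels_offered, services$service_id, function(lv, id) {
    if (length(lv) == 0) abort(paste0("Service ", id, " offers no levels."))
    as_phc_level(lv)
  })
  if (any(services$encounters_per_episode < 1)) {
    abort("`encounters_per_episode` must be >= 1 for every service.")
  }
  if (any(services$need_rate < 0)) abort("`need_rate` must be >= 0.")
  bad_basis <- setdiff(unique(services$need_basis),
                       c("incidence", "prevalence", "utilization_rate"))
  if (length(bad_basis) > 0) {
    abort(paste0("Unknown need_basis: ", paste(bad_basis, collapse = ", ")))
  }
  bad_kind <- setdiff(unique(lines$kind), resource_kinds())
  if (length(bad_kind) > 0) {
    abort(paste0("Unknown resource kind(s): ", paste(bad_kind, collapse = ", ")))
  }
  if (any(lines$quantity < 0) || any(lines$unit_cost < 0)) {
    abort("Resource line quantities and unit costs must be >= 0.")
  }
  if (!"cadre" %in% names(lines)) lines$cadre <- NA_character_
  hr <- lines$kind == "human_resource"
  if (any(hr & (is.na(lines$cadre) | lines$cadre == ""))) {
    abort("Human-resource lines must name a cadre.")
  }
  if (any(!hr & !is.na(lines$cadre) & lines$cadre != "")) {
    abort("`cadre` is only meaningful for human_resource lines.")
  }
  if (!"per_episode" %in% names(lines)) lines$per_episode <- FALSE
  lines$per_episode <- as.logical(lines$per_episode)
  lines$per_episode[is.na(lines$per_episode)] <- FALSE
  orphan <- setdiff(lines$service_id, services$service_id)
  if (length(orphan) > 0) {
    abort(paste0("Resource lines reference unknown service(s): ",
                 paste(orphan, collapse = ", ")))
  }
  structure(list(services = services, lines = lines), class = "stp_catalog")
}

#' Read an STP catalog from two CSV files
#'
#' @param services_path CSV service master (see [stp_catalog()]).
#' @param lines_path CSV resource lines, one row per ingredient.
#' @return A validated `stp_catalog`.
#' @export
read_stp_catalog <- function(services_path, lines_path) {
  stp_catalog(
    readr::read_csv(services_path, show_col_types = FALSE, progress = FALSE),
    readr::read_csv(lines_path, show_col_types = FALSE, progress = FALSE)
  )
}

#' @export
print.stp_catalog <- function(x, ...) {
  cat("<stp_catalog> ", nrow(x$services), " services, ",
      nrow(x$lines), " resource lines, ",
      length(unique(x$services$khis_group)), " KHIS groups\n", sep = "")
  invisible(x)
}

#' Direct (pre-overhead) unit cost per service episode
#'
#' Ingredient costing of one episode of each service. Drug, diagnostic, and
#' reagent lines contribute `quantity x unit_cost` per encounter, scaled by
#' the service's encounters per episode (lines flagged `per_episode` are
#' costed once per episode). Human-resource lines contribute contact minutes
#' times the per-minute salary, grossed up by `1 / (1 - nonclinical_share)`
#' because a share of paid clinical time goes to necessary non-clinical
#' activities — at the default share 0.30, contact time is uplifted ~1.43x.
#' Non-labor lines are not uplifted.
#'
#' @param catalog An [stp_catalog()].
#' @param nonclinical_share Fraction of clinical staff time that is
#'   non-clinical, in `[0, 1)`. Default 0.30.
#' @return Tibble `service_id`, `hr_cost`, `nonhr_cost`, `direct_unit_cost`
#'   (USD per episode).
#' @export
#' @examples
#' cat1 <- stp_catalog(
#'   tibble::tibble(service_id = "s", khis_group = "g",
#'                  levels_offered = "dispensary",
#'                  encounters_per_episode = 2, need_basis = "incidence",
#'                  need_rate = 0.1),
#'   tibble::tibble(service_id = "s", kind = c("drug", "human_resource"),
#'                  quantity = c(1, 20), cadre = c(NA, "nurse"),
#'                  unit_cost = c(3, 0.10))
#' )
#' stp_direct_unit_cost(cat1)$direct_unit_cost  # 6 + 20*0.10*2/0.7 = 11.7143
stp_direct_unit_cost <- function(catalog, nonclinical_share = 0.30) {
  stopifnot(inherits(catalog, "stp_catalog"))
  if (nonclinical_share < 0 || nonclinical_share >= 1) {
    abort("`nonclinical_share` must lie in [0, 1).")
  }
  catalog$lines |>
    left_join(select(catalog$services, "service_id", "encounters_per_episode"),
              by = "service_id") |>
    mutate(
      scale = ifelse(.data$per_episode, 1, .data$encounters_per_episode),
      line_cost = .data$quantity * .data$unit_cost * .data$scale /
        ifelse(.data$kind == "human_resource", 1 - nonclinical_share, 1)
    ) |>
    group_by(.data$service_id) |>
    summarise(
      hr_cost = sum(.data$line_cost[.data$kind == "human_resource"]),
      nonhr_cost = sum(.data$line_cost[.data$kind != "human_resource"]),
      .groups = "drop"
    ) |>
    right_join(select(catalog$services, "service_id"), by = "service_id") |>
    mutate(across(c("hr_cost", "nonhr_cost"), ~tidyr::replace_na(.x, 0)),
           direct_unit_cost = .data$hr_cost + .data$nonhr_cost)
}

#' Load a direct cost with facility overhead
#'
#' The overhead rate `r` is defined as indirect cost over total cost, so the
#' loaded cost is `direct / (1 - r)`: the implied overhead added is
#' `direct * r / (1 - r)` and the indirect share of the loaded cost equals
#' `r` exactly. The multiplicative alternative `direct * (1 + r)` is
#' available for sensitivity comparisons.
#'
#' @param direct_cost Direct cost (USD), vectorised.
#' @param rate Overhead rate(s) in `[0, 1)`.
#' @param method `"grossing"` (default, `direct / (1 - r)`) or
#'   `"markup"` (`direct * (1 + r)`).
#' @return Loaded cost (USD).
#' @export
#' @examples
#' apply_overhead(8, 0.20)  # 10; indirect share of result = 2/10 = 0.20
apply_overhead <- function(direct_cost, rate, method = c("grossing", "markup")) {
  method <- match.arg(method)
  if (any(rate < 0) || any(rate >= 1)) abort("Overhead `rate` must lie in [0, 1).")
  switch(method,
         grossing = direct_cost / (1 - rate),
         markup = direct_cost * (1 + rate))
}

#' Population in need of a service
#'
#' Annual episodes needed at full (100%) coverage: population times the
#' service's need rate (incidence, prevalence, or utilization rate, in
#' episodes per person-year). Full coverage is the normative assumption —
#' the maximum expected service volume.
#'
#' @param population Catchment population (> 0).
#' @param need_rate Episodes per person-year, vectorised over services.
#' @return Episodes per year.
#' @export
#' @examples
#' population_in_need(100000, 0.05)  # 5000 episodes/year
population_in_need <- function(population, need_rate) {
  stopifnot(all(population > 0), all(need_rate >= 0))
  population * need_rate
}

#' Frequency-weighted cost per KHIS service group
#'
#' Routine reporting aggregates services into KHIS groups; the group's cost
#' per episode is the frequency-weighted mean of its member services' unit
#' costs, the weights being previous frequency of use.
#'
#' @param unit_costs Member unit costs (USD/episode).
#' @param frequencies Non-negative use frequencies, at least one positive.
#' @return Weighted mean cost (USD/episode).
#' @export
#' @examples
#' khis_group_cost(c(10, 20), c(300, 100))  # 12.5
khis_group_cost <- function(unit_costs, frequencies) {
  stopifnot(length(unit_costs) == length(frequencies), all(frequencies >= 0))
  if (sum(frequencies) == 0) abort("All member frequencies are zero.")
  sum(unit_costs * frequencies) / sum(frequencies)
}

#' Level-share matrix for normative costs
#'
#' How each KHIS group's episodes are apportioned across the facility levels
#' that offer its services. The default is uniform over each service's
#' offered levels; supply a data frame to override.
#'
#' @param catalog An [stp_catalog()].
#' @param shares Optional data frame (`service_id`, `level`, `share`);
#'   shares must sum to 1 over each service's offered levels.
#' @return Tibble `service_id`, `level`, `share`.
#' @export
level_shares <- function(catalog, shares = NULL) {
  stopifnot(inherits(catalog, "stp_catalog"))
  if (is.null(shares)) {
    shares <- catalog$services |>
      select("service_id", level = "levels_offered") |>
      tidyr::unnest_longer("level") |>
      group_by(.data$service_id) |>
      mutate(share = 1 / n()) |>
      ungroup()
  } else {
    shares <- as_tibble(shares)
    chk <- shares |>
      group_by(.data$service_id) |>
      summarise(s = sum(.data$share), .groups = "drop")
    if (any(abs(chk$s - 1) > 1e-9)) {
      abort(paste0("Level shares must sum to 1 per service; offending: ",
                   paste(chk$service_id[abs(chk$s - 1) > 1e-9], collapse = ", ")))
    }
  }
  shares
}

#' Normative cost of a sub-county at full coverage
#'
#' Bottom-up normative costing: for each service, the direct unit cost per
#' episode (ingredients plus uplifted clinical time) is loaded with the
#' level-specific overhead rate, weighted across the levels offering the
#' service, and multiplied by the population in need at 100% coverage; the
#' sum over services is the sub-county normative total, and dividing by
#' population gives the normative cost per capita (which is invariant to
#' population size when need rates are per person).
#'
#' @param catalog An [stp_catalog()].
#' @param population Sub-county population (> 0).
#' @param overheads Data frame (`level`, `overhead_rate`) from
#'   [pooled_overhead_rates()], covering every level any service uses.
#' @param shares Optional level-share override, see [level_shares()].
#' @param nonclinical_share Non-clinical time share, see
#'   [stp_direct_unit_cost()].
#' @param overhead_method Passed to [apply_overhead()].
#' @return An object of class `phc_normative`: per-service loaded unit costs
#'   by level, per-KHIS-group frequency-weighted costs, `normative_total`
#'   (USD/year) and `normative_pc` (USD/person/year).
#' @export
normative_subcounty <- function(catalog, population, overheads,
                                shares = NULL, nonclinical_share = 0.30,
                                overhead_method = "grossing") {
  stopifnot(inherits(catalog, "stp_catalog"), population > 0)
  if (nrow(catalog$services) == 0) abort("STP catalog is empty.")
  overheads <- as_tibble(overheads)
  shr <- level_shares(catalog, shares)
  used_levels <- unique(shr$level)
  missing_oh <- setdiff(used_levels, overheads$level)
  if (length(missing_oh) > 0) {
    abort(paste0("No overhead rate for level(s) in use: ",
                 paste(missing_oh, collapse = ", ")))
  }
  direct <- stp_direct_unit_cost(catalog, nonclinical_share)
  per_service_level <- shr |>
    left_join(direct, by = "service_id") |>
    left_join(overheads, by = "level") |>
    mutate(loaded_unit_cost = apply_overhead(.data$direct_unit_cost,
                                             .data$overhead_rate,
                                             method = overhead_method))
  per_service <- per_service_level |>
    group_by(.data$service_id) |>
    summarise(unit_cost = sum(.data$share * .data$loaded_unit_cost),
              .groups = "drop") |>
    left_join(select(catalog$services, "service_id", "khis_group", "need_rate"),
              by = "service_id") |>
    mutate(need = population_in_need(population, .data$need_rate),
           service_total = .data$need * .data$unit_cost)
  per_group <- per_service |>
    group_by(khis_group = .data$khis_group) |>
    summarise(group_unit_cost = if (sum(.data$need) > 0)
                khis_group_cost(.data$unit_cost, .data$need) else NA_real_,
              group_total = sum(.data$service_total),
              .groups = "drop")
  total <- sum(per_service$service_total)
  structure(
    list(per_service = per_service,
         per_service_level = per_service_level,
         per_group = per_group,
         population = population,
         normative_total = total,
         normative_pc = total / population),
    class = "phc_normative"
  )
}

#' @export
print.phc_normative <- function(x, ...) {
  cat("<phc_normative> ", nrow(x$per_service), " services, ",
      nrow(x$per_group), " KHIS groups\n", sep = "")
  cat("normative total: ",
      format(round_half_up(x$normative_total), big.mark = ","),
      " USD/year;  per capita: ",
      format(round_half_up(x$normative_pc, 1), nsmall = 1), " USD\n", sep = "")
  invisible(x)
}
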