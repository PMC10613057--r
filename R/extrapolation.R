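#' Extrapolate sampled costs to the facility universe at one level
#'
#' Proportional inflation of sampled costs by outpatient service capture:
#' the capture fraction is sampled outpatient visits over universe
#' outpatient visits (from routine KHIS-style aggregates), and the
#' extrapolated cost is the sampled cost divided by that fraction. This
#' assumes the sample is representative of the level's outpatient unit cost.
#' Capture fractions come from raw service counts, never from rounded
#' percentages.
#'
#' @param sample_cost Total sampled cost at the level (USD/year), vectorised.
#' @param sample_op Sampled outpatient visits at the level (> 0).
#' @param universe_op Universe outpatient visits at the level
#'   (>= `sample_op`).
#' @param level Optional level label(s) carried into the output.
#' @return Tibble with columns `level` (if given), `sample_cost`,
#'   `sample_op`, `universe_op`, `capture_fraction`, `extrapolated_cost`.
#' @export
#' @examples
#' extrapolate_level(100, 50, 200)  # capture 0.25, extrapolated 400
extrapolate_level <- function(sample_cost, sample_op, universe_op, level = NULL) {
  if (any(sample_op <= 0 & universe_op > 0)) {
    abort("Level unrepresented in sample: sample_op = 0 with positive universe_op.")
  }
  if (any(universe_op < sample_op)) {
    abort("`universe_op` must be >= `sample_op` (clamp at frame assembly).")
  }
  frac <- ifelse(sample_op > 0, sample_op / universe_op, NA_real_)
  out <- tibble(
    sample_cost = sample_cost,
    sample_op = sample_op,
    universe_op = universe_op,
    capture_fraction = frac,
    extrapolated_cost = ifelse(sample_op > 0, sample_cost / frac, sample_cost)
  )
  if (!is.null(level)) out <- bind_cols(tibble(level = level), out)
  out
}

level_sample_summary <- function(facilities) {
  as_tibble(facilities) |>
    mutate(total_cost = facility_total_cost(pick(everything()))) |>
    group_by(level = as.character(.data$level)) |>
    summarise(n = n(),
              sample_cost = sum(.data$total_cost),
              sample_op = sum(.data$outpatient_visits),
              .groups = "drop")
}

#' Whole-network cost of a sub-county
#'
#' The three-step scale-up for one sub-county: extrapolate sampled costs to
#' the universe per facility level using outpatient capture fractions, sum
#' the three levels to the network total, and divide by the sub-county
#' population for the actual cost per capita. A level absent from the sample
#' with zero universe volume contributes 0 (with a warning); a level absent
#' from the sample but present in the universe is an error.
#'
#' @param frame A [subcounty_frame()].
#' @return An object of class `phc_network_cost`: per-level extrapolations
#'   plus `network_total` (USD/year) and `actual_pc` (USD/person/year).
#'   Retrieve the per-level table with [tidy()] and the totals with
#'   [glance()].
#' @export
network_total <- function(frame) {
  stopifnot(inherits(frame, "phc_subcounty"))
  smp <- level_sample_summary(frame$facilities)
  absent <- setdiff(phc_levels(), smp$level)
  if (length(absent) > 0) {
    uo <- frame$universe_op[absent]
    if (any(uo > 0)) {
      abort(paste0("Level(s) unrepresented in the ", frame$name,
                   " sample but present in the universe: ",
                   paste(absent[uo > 0], collapse = ", ")))
    }
    warn(paste0("No sampled facilities at level(s) ",
                paste(absent, collapse = ", "), " in ", frame$name,
                "; contributing 0."))
    smp <- bind_rows(smp, tibble(level = absent, n = 0L,
                                 sample_cost = 0, sample_op = 0))
  }
  smp <- smp |> arrange(match(.data$level, phc_levels()))
  per_level <- extrapolate_level(
    smp$sample_cost, smp$sample_op,
    frame$universe_op[smp$level], level = smp$level
  ) |>
    mutate(n = smp$n, .after = "level")
  new_network_cost(frame$name, frame$county, per_level, frame$population)
}

new_network_cost <- function(name, county, per_level, population) {
  total <- sum(per_level$extrapolated_cost)
  structure(
    list(sub_county = name, county = county, per_level = per_level,
         network_total = total, population = population,
         actual_pc = total / population),
    class = "phc_network_cost"
  )
}

#' @export
print.phc_network_cost <- function(x, ...) {
  cat("<phc_network_cost> ", x$sub_county, "\n", sep = "")
  print(x$per_level)
  cat("network total: ", format(round_half_up(x$network_total), big.mark = ","),
      " USD;  per capita: ", format(round_half_up(x$actual_pc, 1), nsmall = 1),
      " USD (population ", format(x$population, big.mark = ","), ")\n", sep = "")
  invisible(x)
}

#' National roll-up of sampled facilities
#'
#' Pools every sampled facility across sub-counties into one national sample,
#' extrapolates per level against national universe outpatient totals, sums,
#' and divides by the national population. The sample is pooled (sums of
#' sampled costs and visits), not an average of sub-county per-capita values.
#'
#' @param frames List of [subcounty_frame()] objects.
#' @param national_universe_op Named numeric vector of national universe
#'   outpatient visits per level.
#' @param national_population National population (> 0). Not a built-in
#'   constant; it must come from the analysis configuration.
#' @param label Row label for the result. Default `"national"`.
#' @return A `phc_network_cost` for the pooled national sample.
#' @export
national_rollup <- function(frames, national_universe_op, national_population,
                            label = "national") {
  stopifnot(length(frames) > 0, national_population > 0)
  facilities <- purrr::map(frames, "facilities") |> purrr::list_rbind()
  pooled <- subcounty_frame(
    name = label, county = label, population = national_population,
    facilities = facilities, universe_op = national_universe_op
  )
  network_total(pooled)
}

#' Network costs for several sub-counties at once
#'
#' Applies [network_total()] to each frame and binds the per-sub-county
#' summaries into one tibble mirroring the usual network-cost summary table
#' (sample cost, capture fraction, extrapolated cost per level; network
#' total and per-capita per sub-county).
#'
#' @param frames List of [subcounty_frame()] objects.
#' @return Tibble with one row per (sub_county, level), carrying
#'   `network_total`, `population`, and `actual_pc` per sub-county.
#' @export
network_cost_table <- function(frames) {
  purrr::map(frames, function(fr) {
    nc <- network_total(fr)
    nc$per_level |>
      mutate(sub_county = nc$sub_county, county = nc$county, .before = 1) |>
      mutate(network_total = nc$network_total,
             population = nc$population,
             actual_pc = nc$actual_pc)
  }) |>
    purrr::list_rbind()
}
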