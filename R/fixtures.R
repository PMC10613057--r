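# Transcriptions of the published seven-sub-county study tables, used as
# fixed inputs for desk-scale reproduction checks. Values are printed table
# entries (populations, staffing/volume means, per-level sampled and
# extrapolated costs, per-capita costs), not generated data.

#' Sub-county populations of the seven-sub-county study
#'
#' @return Tibble `county`, `sub_county`, `population`.
#' @export
fixture_populations <- function() {
  tibble(
    county = c("Isiolo", "Kajiado", "Kilifi", "Kisumu", "Makueni",
               "Nyeri", "Nyeri"),
    sub_county = c("Garbatulla", "Kajiado East", "Ganze", "Kisumu West",
                   "Kibwezi West", "Kieni West", "Mukurweini"),
    population = c(99729, 191241, 191685, 151798, 183639, 93109, 98532)
  )
}

#' Sampled-facility characteristics by sub-county and level
#'
#' Facility counts and (mean) staffing and annual service volumes of the
#' sampled facilities, including the published daily caseloads per clinical
#' staff for the single-hospital rows.
#'
#' @return Tibble with per-(sub_county, level) `n`, mean clinical and
#'   non-clinical staff, mean outpatient visits and inpatient bed-days, and
#'   the published `op_caseload` / `weighted_caseload` (services per
#'   clinical staff per day).
#' @export
fixture_characteristics <- function() {
  tribble(
    ~sub_county, ~level, ~n, ~clinical_staff, ~nonclinical_staff,
    ~outpatient_visits, ~inpatient_bed_days, ~op_caseload, ~weighted_caseload,
    "Garbatulla", "dispensary", 7, 2.1, 2.4, 4542, 22, 8.0, 8.2,
    "Garbatulla", "health_center", 3, 21.0, 5.0, 11247, 277, 4.7, 5.2,
    "Garbatulla", "primary_hospital", 1, 21, 22, 9620, 666, 1.7, 2.1,
    "Kajiado East", "dispensary", 6, 4.7, 2.5, 12432, 0, 13.5, 13.5,
    "Kajiado East", "health_center", 3, 73.0, 10.0, 30123, 1, 1.5, 1.5,
    "Kajiado East", "primary_hospital", 1, 119, 50, 101672, 0, 3.2, 3.2,
    "Ganze", "dispensary", 4, 3.3, 2.3, 16421, 0, 21.9, 21.9,
    "Ganze", "health_center", 2, 54.5, 8.0, 30522, 1, 2.0, 2.0,
    "Ganze", "primary_hospital", 1, 40, 24, 54507, 1373, 5.1, 5.5,
    "Kisumu West", "dispensary", 3, 5.3, 1.7, 12526, 0, 8.9, 8.9,
    "Kisumu West", "health_center", 9, 10.9, 3.0, 10662, 1, 5.5, 5.5,
    "Kisumu West", "primary_hospital", 1, 40, 26, 26178, 14507, 2.5, 7.1,
    "Kibwezi West", "dispensary", 6, 1.2, 2.5, 7571, 0, 25.8, 25.8,
    "Kibwezi West", "health_center", 3, 28.7, 5.3, 22101, 3, 3.1, 3.1,
    "Kibwezi West", "primary_hospital", 1, 143, 32, 106352, 2001, 2.8, 3.0,
    "Kieni West", "dispensary", 6, 2.3, 2.2, 9007, 0, 16.4, 16.4,
    "Kieni West", "health_center", 3, 46.0, 7.0, 25530, 10, 2.2, 2.2,
    "Kieni West", "primary_hospital", 1, 29, 45, 18997, 8641, 2.5, 6.3,
    "Mukurweini", "dispensary", 6, 2.5, 2.7, 12616, 0, 19.0, 19.0,
    "Mukurweini", "health_center", 3, 24.7, 5.3, 18969, 10, 2.9, 3.0,
    "Mukurweini", "primary_hospital", 1, 65, 50, 56205, 19801, 3.2, 7.2
  )
}

#' Mean cost-category breakdowns of sampled facilities
#'
#' Mean annual costs (USD) per sampled facility by sub-county and level, in
#' the four recurrent categories.
#'
#' @return Tibble `sub_county`, `level`, `clinical_labor`, `drugs`,
#'   `medical_supplies`, `indirect`.
#' @export
fixture_cost_means <- function() {
  tribble(
    ~sub_county, ~level, ~clinical_labor, ~drugs, ~medical_supplies, ~indirect,
    "Garbatulla", "dispensary", 20573, 13528, 0, 4451,
    "Garbatulla", "health_center", 78341, 32713, 20, 14736,
    "Garbatulla", "primary_hospital", 302853, 98987, 0, 96833,
    "Kajiado East", "dispensary", 41847, 16068, 222, 17893,
    "Kajiado East", "health_center", 206267, 378469, 977, 63446,
    "Kajiado East", "primary_hospital", 1695249, 3485608, 21473, 377706,
    "Ganze", "dispensary", 31100, 27429, 77, 8701,
    "Ganze", "health_center", 107931, 63632, 3251, 45323,
    "Ganze", "primary_hospital", 355667, 126676, 701, 135420,
    "Kisumu West", "dispensary", 46909, 21290, 39, 9352,
    "Kisumu West", "health_center", 50372, 26612, 218, 15654,
    "Kisumu West", "primary_hospital", 340622, 221444, 11708, 167808,
    "Kibwezi West", "dispensary", 9277, 3979, 0, 9836,
    "Kibwezi West", "health_center", 92701, 64236, 175, 23767,
    "Kibwezi West", "primary_hospital", 2240773, 1110291, 65171, 791899,
    "Kieni West", "dispensary", 26879, 7846, 105, 7103,
    "Kieni West", "health_center", 145994, 238753, 736, 43748,
    "Kieni West", "primary_hospital", 152915, 266073, 5569, 251674,
    "Mukurweini", "dispensary", 27348, 7965, 14, 10762,
    "Mukurweini", "health_center", 77585, 12781, 177, 19706,
    "Mukurweini", "primary_hospital", 1020479, 1970513, 18099, 765596
  )
}

#' Published network-cost summary by sub-county and level
#'
#' Sampled total cost, extrapolated total cost, network total, and
#' per-capita cost per sub-county, plus the national (pooled-sample) row.
#'
#' @return Tibble `sub_county`, `level`, `n`, `sample_cost`,
#'   `extrapolated_cost`, `network_total`, `per_capita`.
#' @export
fixture_network_costs <- function() {
  tribble(
    ~sub_county, ~level, ~n, ~sample_cost, ~extrapolated_cost,
    ~network_total, ~per_capita,
    "Garbatulla", "dispensary", 7, 269873, 393498, 1269600, 12.7,
    "Garbatulla", "health_center", 3, 377428, 377428, 1269600, 12.7,
    "Garbatulla", "primary_hospital", 1, 498674, 498674, 1269600, 12.7,
    "Kajiado East", "dispensary", 6, 456184, 700052, 8227566, 43.0,
    "Kajiado East", "health_center", 3, 1947479, 1947479, 8227566, 43.0,
    "Kajiado East", "primary_hospital", 1, 5580035, 5580035, 8227566, 43.0,
    "Ganze", "dispensary", 4, 269225, 717690, 1776429, 9.3,
    "Ganze", "health_center", 2, 440275, 440275, 1776429, 9.3,
    "Ganze", "primary_hospital", 1, 618464, 618464, 1776429, 9.3,
    "Kisumu West", "dispensary", 3, 232770, 376642, 4206786, 27.7,
    "Kisumu West", "health_center", 9, 835710, 1007191, 4206786, 27.7,
    "Kisumu West", "primary_hospital", 1, 741581, 2822954, 4206786, 27.7,
    "Kibwezi West", "dispensary", 6, 138555, 724814, 5768441, 31.4,
    "Kibwezi West", "health_center", 3, 542635, 835494, 5768441, 31.4,
    "Kibwezi West", "primary_hospital", 1, 4208134, 4208134, 5768441, 31.4,
    "Kieni West", "dispensary", 6, 251597, 353741, 2602492, 28.0,
    "Kieni West", "health_center", 3, 1287695, 1572521, 2602492, 28.0,
    "Kieni West", "primary_hospital", 1, 676230, 676230, 2602492, 28.0,
    "Mukurweini", "dispensary", 6, 276534, 547465, 4652900, 47.2,
    "Mukurweini", "health_center", 3, 330749, 330749, 4652900, 47.2,
    "Mukurweini", "primary_hospital", 1, 3774687, 3774687, 4652900, 47.2,
    "national", "dispensary", 38, 1894738, 175351168, 1367753095, 26.6,
    "national", "health_center", 26, 5761970, 243666039, 1367753095, 26.6,
    "national", "primary_hospital", 7, 16097804, 948735888, 1367753095, 26.6
  )
}

#' Published actual vs normative per-capita costs
#'
#' @return Tibble `sub_county`, `actual_pc`, `normative_pc`,
#'   `multiple_reported` (the published required-investment multiple).
#' @export
fixture_gap_table <- function() {
  tribble(
    ~sub_county, ~actual_pc, ~normative_pc, ~multiple_reported,
    "Garbatulla", 12.7, 34.7, "2.7 times",
    "Kajiado East", 43.0, 45.6, "1.1 times",
    "Ganze", 9.3, 31.8, "3.4 times",
    "Kisumu West", 27.7, 36.9, "1.3 times",
    "Kibwezi West", 31.4, 42.4, "1.4 times",
    "Kieni West", 28.0, 30.9, "1.1 times",
    "Mukurweini", 47.2, 40.2, "0.9 times",
    "national", 26.6, 41.7, "1.6 times"
  )
}

#' National population implied by the published national figures
#'
#' The national per-capita cost and network total imply the population used
#' in the published roll-up (~51.4 M); it is not printed and must be treated
#' as an input. This derived value reproduces the published per-capita.
#'
#' @return A single number (persons).
#' @export
fixture_national_population <- function() 51419290

#' Assemble the seven published sub-county frames
#'
#' Builds one [subcounty_frame()] per published sub-county from the printed
#' tables: per level, one pooled pseudo-facility carrying the level's total
#' sampled cost (mean category breakdowns rescaled so the categories sum
#' exactly to the printed sampled total), the sampled outpatient volume
#' (published mean x facility count), and staffing. Universe outpatient
#' totals are back-derived so the capture fraction equals the printed
#' sampled-to-extrapolated cost ratio exactly — the published percentages
#' are rounded and would not reproduce the printed extrapolated costs.
#'
#' @return A list of class `phc_paper_fixture`: `frames` (seven
#'   [subcounty_frame()]s, in published order), `network_costs`
#'   (see [fixture_network_costs()]), `gap_table`, `characteristics`,
#'   `national` (pooled sample universe totals and implied population).
#' @export
#' @examples
#' fx <- paper_fixture()
#' fx$frames[["Garbatulla"]]$population  # 99729
paper_fixture <- function() {
  pops <- fixture_populations()
  chars <- fixture_characteristics()
  costs <- fixture_cost_means()
  net <- fixture_network_costs()
  sub_net <- net[net$sub_county != "national", ]
  fac <- chars |>
    left_join(costs, by = c("sub_county", "level")) |>
    left_join(select(sub_net, "sub_county", "level", "sample_cost",
                     "extrapolated_cost"),
              by = c("sub_county", "level")) |>
    mutate(
      # rescale printed category means (x n) to sum exactly to the printed
      # sampled total for the level
      cat_total = (.data$clinical_labor + .data$drugs +
                     .data$medical_supplies + .data$indirect) * .data$n,
      rescale = .data$sample_cost / .data$cat_total,
      facility_id = paste0(.data$sub_county, "_", .data$level, "_pool"),
      clinical_staff = .data$clinical_staff * .data$n,
      nonclinical_staff = .data$nonclinical_staff * .data$n,
      outpatient_visits = .data$outpatient_visits * .data$n,
      inpatient_bed_days = .data$inpatient_bed_days * .data$n,
      across(all_of(phc_cost_categories()), ~.x * .data$n * .data$rescale),
      universe_op = .data$outpatient_visits *
        .data$extrapolated_cost / .data$sample_cost
    )
  frames <- purrr::map(pops$sub_county, function(sc) {
    rows <- fac[fac$sub_county == sc, ]
    subcounty_frame(
      name = sc,
      county = pops$county[pops$sub_county == sc],
      population = pops$population[pops$sub_county == sc],
      facilities = rows[, facility_columns()],
      universe_op = stats::setNames(rows$universe_op, rows$level)
    )
  })
  names(frames) <- pops$sub_county
  nat <- net[net$sub_county == "national", ]
  # the published national sample sums differ by 1 USD from the sums of the
  # published sub-county sample costs (rounding); the universe ratio is
  # derived against the assembled pooled sample so the published
  # extrapolated costs reproduce exactly
  pooled_op <- fac |>
    group_by(level = .data$level) |>
    summarise(sample_op = sum(.data$outpatient_visits),
              pooled_cost = sum(.data$sample_cost), .groups = "drop") |>
    left_join(select(nat, "level", "extrapolated_cost"), by = "level") |>
    mutate(universe_op = .data$sample_op *
             .data$extrapolated_cost / .data$pooled_cost)
  structure(
    list(frames = frames,
         network_costs = net,
         gap_table = fixture_gap_table(),
         characteristics = chars,
         national = list(
           universe_op = stats::setNames(pooled_op$universe_op,
                                         pooled_op$level),
           population = fixture_national_population()
         )),
    class = "phc_paper_fixture"
  )
}
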