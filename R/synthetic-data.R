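#' Parameters of a synthetic PHC world
#'
#' Settings for [generate_world()]. Defaults emulate the statistical
#' structure of a Kenyan-style PHC costing study: three facility levels with
#' cost-category means anchored to the sampled-facility level means
#' (dispensary clinical labor ~27,400 USD/year, hospital ~872,700),
#' right-skewed (log-normal) cost dispersion, outpatient volumes spanning
#' the observed ranges, inpatient care essentially absent from dispensaries
#' (policy forbids it; a small violation rate is allowed), sampling weighted
#' by outpatient volume, and an STP catalog with drug/diagnostic/reagent and
#' clinical-time ingredients.
#'
#' @param seed Integer seed; the same seed reproduces the world
#'   bit-for-bit. Per-sub-county seeds are split from it deterministically,
#'   so adding a sub-county does not perturb the others.
#' @param n_subcounties Number of sub-counties.
#' @param facilities_per_level Named counts of universe facilities per level
#'   in each sub-county.
#' @param sample_fraction Named sampling fractions per level in `(0, 1]`
#'   (hospitals default to full sampling, as in sub-county designs with one
#'   referral hospital).
#' @param population_range Min/max sub-county population.
#' @param cost_category_means Per-level named list of mean annual costs for
#'   the four categories (USD).
#' @param cost_dispersion Log-scale standard deviation of multiplicative
#'   cost noise; 0 gives perfectly homogeneous unit costs per level.
#' @param op_volume_range,ip_volume_range Per-level min/max annual
#'   outpatient visits and inpatient bed-days.
#' @param staff_range Per-level min/max clinical staff.
#' @param dispensary_ip_violation_rate Probability a dispensary reports a
#'   small inpatient volume despite policy.
#' @param n_services Number of STPs in the synthetic catalog.
#' @param n_khis_groups Number of KHIS service groups.
#' @param need_rate_range Min/max episodes per person-year.
#' @param encounters_range Min/max encounters per episode.
#' @param unit_cost_ranges Named list of min/max unit costs per resource
#'   kind (USD per unit; USD per minute for human resources).
#' @param hr_minutes_range Min/max clinical minutes per encounter.
#' @param nonclinical_share Non-clinical time share used in the ground-truth
#'   normative computation.
#' @return A list of class `phc_world_params`.
#' @export
world_params <- function(
    seed = 1L,
    n_subcounties = 3,
    facilities_per_level = c(dispensary = 20, health_center = 8,
                             primary_hospital = 2),
    sample_fraction = c(dispensary = 0.35, health_center = 0.5,
                        primary_hospital = 1),
    population_range = c(90000, 200000),
    cost_category_means = list(
      dispensary = c(clinical_labor = 27400, drugs = 12700,
                     medical_supplies = 65, indirect = 9700),
      health_center = c(clinical_labor = 95000, drugs = 98000,
                        medical_supplies = 570, indirect = 28000),
      primary_hospital = c(clinical_labor = 872700, drugs = 1040000,
                           medical_supplies = 17500, indirect = 369600)
    ),
    cost_dispersion = 0.5,
    op_volume_range = list(dispensary = c(2400, 43000),
                           health_center = c(3400, 54500),
                           primary_hospital = c(9600, 106400)),
    ip_volume_range = list(dispensary = c(0, 0),
                           health_center = c(0, 400),
                           primary_hospital = c(600, 20000)),
    staff_range = list(dispensary = c(1, 17),
                       health_center = c(2, 92),
                       primary_hospital = c(21, 143)),
    dispensary_ip_violation_rate = 0.05,
    n_services = 12,
    n_khis_groups = 4,
    need_rate_range = c(0.01, 0.4),
    encounters_range = c(1, 4),
    unit_cost_ranges = list(drug = c(0.5, 10), diagnostic = c(0.5, 5),
                            reagent = c(0.2, 3),
                            human_resource = c(0.05, 0.25)),
    hr_minutes_range = c(5, 40),
    nonclinical_share = 0.30) {
  p <- as.list(environment())
  stopifnot(
    all(unlist(sample_fraction) > 0), all(unlist(sample_fraction) <= 1),
    all(population_range > 0), diff(population_range) >= 0,
    cost_dispersion >= 0, n_services >= 1
  )
  for (lv in phc_levels()) {
    if (any(facilities_per_level[lv] < 1)) {
      abort(paste0("Need at least one universe facility per level (", lv, ")."))
    }
  }
  structure(p, class = "phc_world_params")
}

# deterministic per-component seed split (31-bit, component 0 = catalog)
split_seed <- function(seed, component) {
  as.integer((as.numeric(seed) * 48271 + component * 7919) %% 2147483647)
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

generate_subcounty <- function(params, index) {
  set.seed(split_seed(params$seed, index))
  name <- sprintf("subcounty_%02d", index)
  population <- round(runif_range(1, params$population_range))
  fac <- purrr::map(phc_levels(), function(lv) {
    n <- params$facilities_per_level[[lv]]
    op <- round(runif_range(n, params$op_volume_range[[lv]]))
    ip <- round(runif_range(n, params$ip_volume_range[[lv]]))
    if (lv == "dispensary") {
      violate <- stats::runif(n) < params$dispensary_ip_violation_rate
      ip <- ifelse(violate, round(stats::runif(n, 1, 150)), 0)
    }
    means <- params$cost_category_means[[lv]]
    op_mid <- mean(params$op_volume_range[[lv]])
    sd <- params$cost_dispersion
    noise <- exp(stats::rnorm(n, -sd^2 / 2, sd))
    scale <- (op / op_mid) * noise
    tibble(
      facility_id = sprintf("%s_%s_%02d", name, lv, seq_len(n)),
      sub_county = name,
      level = lv,
      clinical_staff = round(runif_range(n, params$staff_range[[lv]])),
      nonclinical_staff = round(runif_range(n, params$staff_range[[lv]]) / 2),
      outpatient_visits = op,
      inpatient_bed_days = ip,
      clinical_labor = means[["clinical_labor"]] * scale,
      drugs = means[["drugs"]] * scale,
      medical_supplies = means[["medical_supplies"]] * scale,
      indirect = means[["indirect"]] * scale
    )
  }) |>
    purrr::list_rbind()
  # sample facilities per level with probability proportional to OP volume
  sampled_ids <- unlist(purrr::map(phc_levels(), function(lv) {
    rows <- fac[fac$level == lv, ]
    k <- max(1L, round(params$sample_fraction[[lv]] * nrow(rows)))
    sample(rows$facility_id, k, prob = rows$outpatient_visits)
  }))
  list(name = name, population = population, facilities = fac,
       sampled_ids = sampled_ids)
}

generate_catalog <- function(params) {
  set.seed(split_seed(params$seed, 0L))
  n <- params$n_services
  groups <- sprintf("group_%02d", seq_len(params$n_khis_groups))
  services <- tibble(
    service_id = sprintf("svc_%03d", seq_len(n)),
    khis_group = sample(groups, n, replace = TRUE),
    levels_offered = purrr::map(seq_len(n), function(i) {
      k <- sample(1:3, 1)
      sort(sample(phc_levels(), k))
    }),
    encounters_per_episode = runif_range(n, params$encounters_range),
    need_basis = sample(c("incidence", "prevalence", "utilization_rate"),
                        n, replace = TRUE),
    need_rate = runif_range(n, params$need_rate_range)
  )
  lines <- purrr::map(seq_len(n), function(i) {
    n_nonhr <- sample(1:3, 1)
    kinds <- sample(c("drug", "diagnostic", "reagent"), n_nonhr, replace = TRUE)
    nonhr <- tibble(
      service_id = services$service_id[i],
      kind = kinds,
      quantity = stats::runif(n_nonhr, 1, 5),
      cadre = NA_character_,
      unit_cost = vapply(kinds, function(k)
        runif_range(1, params$unit_cost_ranges[[k]]), numeric(1))
    )
    hr <- tibble(
      service_id = services$service_id[i],
      kind = "human_resource",
      quantity = runif_range(1, params$hr_minutes_range),
      cadre = sample(c("nurse", "clinical_officer", "medical_officer"), 1),
      unit_cost = runif_range(1, params$unit_cost_ranges$human_resource)
    )
    bind_rows(nonhr, hr)
  }) |>
    purrr::list_rbind()
  stp_catalog(services, lines)
}

# ground-truth normative per-capita by direct enumeration, independent of
# the pipeline's normative_subcounty()
truth_normative_pc <- function(catalog, overheads, nonclinical_share) {
  rates <- stats::setNames(overheads$overhead_rate, overheads$level)
  pc <- 0
  for (i in seq_len(nrow(catalog$services))) {
    svc <- catalog$services[i, ]
    ln <- catalog$lines[catalog$lines$service_id == svc$service_id, ]
    direct <- 0
    for (j in seq_len(nrow(ln))) {
      contrib <- ln$quantity[j] * ln$unit_cost[j] * svc$encounters_per_episode
      if (ln$kind[j] == "human_resource") contrib <- contrib / (1 - nonclinical_share)
      direct <- direct + contrib
    }
    lvls <- svc$levels_offered[[1]]
    loaded <- mean(direct / (1 - rates[lvls]))
    pc <- pc + svc$need_rate * loaded
  }
  unname(pc)
}

#' Generate a synthetic PHC world with known ground truth
#'
#' Builds a complete facility universe for each sub-county, an
#' outpatient-volume-weighted sample of it, and a synthetic STP catalog,
#' then computes the ground truth by brute-force enumeration over the whole
#' universe (never through the pipeline under test): the true universe cost
#' total and actual per-capita per sub-county, the true normative per-capita
#' (using overhead rates pooled over the full universe), and the true gap.
#'
#' @param params A [world_params()].
#' @return A list of class `phc_world`:
#'   `universe` and `sample` (lists of [subcounty_frame()]s, the sample
#'   sharing the universe's KHIS outpatient totals), `catalog` (an
#'   [stp_catalog()]), `universe_overheads` (level overhead rates pooled
#'   over the full universe), and `truth` (tibble per sub-county:
#'   `true_universe_total`, `true_actual_pc`, `true_normative_pc`,
#'   `true_gap`).
#' @export
#' @examples
#' w <- generate_world(world_params(seed = 7, n_subcounties = 2))
#' w$truth
generate_world <- function(params = world_params()) {
  stopifnot(inherits(params, "phc_world_params"))
  for (lv in phc_levels()) {
    k <- round(params$sample_fraction[[lv]] * params$facilities_per_level[[lv]])
    if (k > params$facilities_per_level[[lv]]) {
      abort("Sample larger than universe; reduce `sample_fraction`.")
    }
  }
  subs <- purrr::map(seq_len(params$n_subcounties),
                     ~generate_subcounty(params, .x))
  frames <- purrr::map(subs, function(s) {
    universe_op <- s$facilities |>
      group_by(level = as.character(.data$level)) |>
      summarise(op = sum(.data$outpatient_visits), .groups = "drop")
    uo <- stats::setNames(universe_op$op, universe_op$level)
    list(
      universe = subcounty_frame(s$name, county = "synthetic",
                                 population = s$population,
                                 facilities = s$facilities, universe_op = uo),
      sample = subcounty_frame(s$name, county = "synthetic",
                               population = s$population,
                               facilities = s$facilities[
                                 s$facilities$facility_id %in% s$sampled_ids, ],
                               universe_op = uo)
    )
  })
  universe <- purrr::map(frames, "universe")
  smp <- purrr::map(frames, "sample")
  catalog <- generate_catalog(params)
  all_universe_fac <- purrr::map(universe, "facilities") |> purrr::list_rbind()
  universe_overheads <- pooled_overhead_rates(all_universe_fac)
  norm_pc <- truth_normative_pc(catalog, universe_overheads,
                                params$nonclinical_share)
  truth <- purrr::map(universe, function(fr) {
    total <- sum(facility_total_cost(fr$facilities))
    tibble(
      sub_county = fr$name,
      population = fr$population,
      true_universe_total = total,
      true_actual_pc = total / fr$population,
      true_normative_pc = norm_pc,
      true_gap = norm_pc - total / fr$population
    )
  }) |>
    purrr::list_rbind()
  structure(
    list(params = params, universe = universe, sample = smp,
         catalog = catalog, universe_overheads = universe_overheads,
         truth = truth),
    class = "phc_world"
  )
}

#' @export
print.phc_world <- function(x, ...) {
  cat("<phc_world> seed ", x$params$seed, ": ", length(x$universe),
      " sub-counties, ",
      sum(purrr::map_int(x$universe, ~nrow(.x$facilities))),
      " universe facilities (",
      sum(purrr::map_int(x$sample, ~nrow(.x$facilities))), " sampled), ",
      nrow(x$catalog$services), " STPs\n", sep = "")
  print(x$truth)
  invisible(x)
}

#' Write a synthetic world to the CSV dialects the readers accept
#'
#' Emits `facilities.csv` (the sampled facilities), `universe.csv`,
#' `population.csv`, the STP catalog (`stp_services.csv`,
#' `stp_lines.csv`), and `truth.json`, so a full pipeline run can start
#' from files.
#'
#' @param world A [generate_world()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "phc_world"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fac <- purrr::map(world$sample, "facilities") |> purrr::list_rbind() |>
    mutate(level = as.character(.data$level))
  readr::write_csv(fac, file.path(dir, "facilities.csv"), progress = FALSE)
  uni <- purrr::map(world$sample, function(fr) {
    tibble(sub_county = fr$name, level = names(fr$universe_op),
           universe_op = unname(fr$universe_op))
  }) |> purrr::list_rbind()
  readr::write_csv(uni, file.path(dir, "universe.csv"), progress = FALSE)
  pops <- purrr::map(world$sample, function(fr) {
    tibble(sub_county = fr$name, county = fr$county, population = fr$population)
  }) |> purrr::list_rbind()
  readr::write_csv(pops, file.path(dir, "population.csv"), progress = FALSE)
  svc <- world$catalog$services |>
    mutate(levels_offered = purrr::map_chr(.data$levels_offered,
                                           paste, collapse = ","))
  readr::write_csv(svc, file.path(dir, "stp_services.csv"), progress = FALSE)
  readr::write_csv(world$catalog$lines, file.path(dir, "stp_lines.csv"),
                   progress = FALSE)
  jsonlite::write_json(world$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
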