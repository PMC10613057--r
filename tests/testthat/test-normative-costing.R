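tiny_catalog <- function(encounters = 2, need_rate = 0.1,
                         levels = "dispensary") {
  stp_catalog(
    tibble::tibble(service_id = "svc", khis_group = "grp",
                   levels_offered = levels,
                   encounters_per_episode = encounters,
                   need_basis = "incidence", need_rate = need_rate),
    tibble::tibble(service_id = "svc",
                   kind = c("drug", "human_resource"),
                   quantity = c(1, 20), cadre = c(NA, "nurse"),
                   unit_cost = c(3, 0.10))
  )
}

test_that("direct unit cost uplifts clinical time but not consumables", {
  # nurse 20 min at 0.10/min, 2 encounters, drugs 3.00/encounter, share 0.30
  d <- stp_direct_unit_cost(tiny_catalog(), nonclinical_share = 0.30)
  expect_equal(d$hr_cost, 20 * 0.10 * 2 / 0.7, tolerance = 1e-12)
  expect_equal(d$nonhr_cost, 6)
  expect_equal(d$direct_unit_cost, 11.7142857142857, tolerance = 1e-9)

  # share 0: the raw minutes cost
  d0 <- stp_direct_unit_cost(tiny_catalog(), nonclinical_share = 0)
  expect_equal(d0$hr_cost, 4)

  # uplift is inert without clinical-time lines
  onlydrug <- stp_catalog(
    tibble::tibble(service_id = "s", khis_group = "g",
                   levels_offered = "dispensary", encounters_per_episode = 1,
                   need_basis = "incidence", need_rate = 0),
    tibble::tibble(service_id = "s", kind = "drug", quantity = 1,
                   cadre = NA, unit_cost = 3)
  )
  expect_equal(stp_direct_unit_cost(onlydrug, 0.30)$direct_unit_cost, 3)
  expect_error(stp_direct_unit_cost(tiny_catalog(), 1), "\\[0, 1\\)")
})

test_that("per-episode lines are not scaled by encounters", {
  cat2 <- stp_catalog(
    tibble::tibble(service_id = "s", khis_group = "g",
                   levels_offered = "dispensary", encounters_per_episode = 4,
                   need_basis = "utilization_rate", need_rate = 0.1),
    tibble::tibble(service_id = "s", kind = c("drug", "drug"),
                   quantity = c(1, 1), cadre = NA, unit_cost = c(2, 2),
                   per_episode = c(FALSE, TRUE))
  )
  expect_equal(stp_direct_unit_cost(cat2)$direct_unit_cost, 2 * 4 + 2)
})

test_that("overhead loading makes the indirect share equal the rate", {
  expect_equal(apply_overhead(8, 0.20), 10)
  expect_equal(apply_overhead(5, 0), 5)
  set.seed(2)
  direct <- runif(50, 1, 100)
  r <- runif(50, 0, 0.9)
  loaded <- apply_overhead(direct, r)
  expect_equal(loaded - direct, direct * r / (1 - r), tolerance = 1e-12)
  expect_equal((loaded - direct) / loaded, r, tolerance = 1e-12)
  expect_true(all(loaded >= direct))
  expect_equal(apply_overhead(8, 0.25, method = "markup"), 10)
  expect_error(apply_overhead(8, 1), "\\[0, 1\\)")
})

test_that("population in need is linear in population at full coverage", {
  expect_equal(population_in_need(100000, 0.05), 5000)
  expect_equal(population_in_need(100000, 0), 0)
  rates <- c(0.1, 0.25, 0.4)
  expect_equal(sum(population_in_need(2e5, rates)),
               2 * sum(population_in_need(1e5, rates)))
})

test_that("KHIS group costs are frequency-weighted means", {
  expect_equal(khis_group_cost(c(10, 20), c(300, 100)), 12.5)
  expect_equal(khis_group_cost(42, 7), 42)
  expect_equal(khis_group_cost(c(10, 20, 30), c(1, 1, 1)), 20)
  expect_error(khis_group_cost(c(10, 20), c(0, 0)), "zero")
})

test_that("sub-county normative cost composes need, unit cost, and overhead", {
  cat1 <- stp_catalog(
    tibble::tibble(service_id = "s", khis_group = "g",
                   levels_offered = "dispensary", encounters_per_episode = 1,
                   need_basis = "incidence", need_rate = 0.2),
    tibble::tibble(service_id = "s", kind = "drug", quantity = 1,
                   cadre = NA, unit_cost = 8)
  )
  oh <- tibble::tibble(level = "dispensary", overhead_rate = 0.20)
  res <- normative_subcounty(cat1, 1000, oh)
  expect_equal(res$normative_total, 200 * 10)
  expect_equal(res$normative_pc, 2)

  # equal overheads across two offered levels collapse to the single-level cost
  cat2 <- tiny_catalog(levels = list(c("dispensary", "health_center")))
  oh2 <- tibble::tibble(level = c("dispensary", "health_center"),
                        overhead_rate = 0.2)
  res2 <- normative_subcounty(cat2, 1000, oh2)
  res1 <- normative_subcounty(tiny_catalog(), 1000, oh)
  expect_equal(res2$normative_pc, res1$normative_pc, tolerance = 1e-12)

  expect_error(normative_subcounty(tiny_catalog(), 1000,
                                   tibble::tibble(level = "health_center",
                                                  overhead_rate = 0.1)),
               "No overhead rate")
})

test_that("normative per-capita is invariant to population and monotone in inputs", {
  w <- generate_world(world_params(seed = 9, n_subcounties = 1))
  oh <- w$universe_overheads
  base <- normative_subcounty(w$catalog, 1e5, oh)
  double <- normative_subcounty(w$catalog, 2e5, oh)
  expect_equal(double$normative_total, 2 * base$normative_total,
               tolerance = 1e-12)
  expect_equal(double$normative_pc, base$normative_pc, tolerance = 1e-12)

  up_share <- normative_subcounty(w$catalog, 1e5, oh, nonclinical_share = 0.5)
  expect_gt(up_share$normative_pc, base$normative_pc)

  oh_up <- dplyr::mutate(oh, overhead_rate = pmin(overhead_rate + 0.1, 0.95))
  expect_gt(normative_subcounty(w$catalog, 1e5, oh_up)$normative_pc,
            base$normative_pc)

  cat_up <- w$catalog
  cat_up$lines$unit_cost <- cat_up$lines$unit_cost * 1.5
  expect_gt(normative_subcounty(cat_up, 1e5, oh)$normative_pc,
            base$normative_pc)

  cat_need <- w$catalog
  cat_need$services$need_rate <- cat_need$services$need_rate * 2
  expect_equal(normative_subcounty(cat_need, 1e5, oh)$normative_total,
               2 * base$normative_total, tolerance = 1e-9)
})

test_that("catalog validation rejects malformed inputs", {
  svc <- tibble::tibble(service_id = "s", khis_group = "g",
                        levels_offered = "dispensary",
                        encounters_per_episode = 1,
                        need_basis = "incidence", need_rate = 0.1)
  ln <- tibble::tibble(service_id = "s", kind = "drug", quantity = 1,
                       cadre = NA, unit_cost = 1)
  expect_s3_class(stp_catalog(svc, ln), "stp_catalog")
  expect_error(stp_catalog(dplyr::mutate(svc, encounters_per_episode = 0.5), ln),
               "encounters_per_episode")
  expect_error(stp_catalog(dplyr::mutate(svc, need_basis = "guess"), ln),
               "need_basis")
  expect_error(stp_catalog(svc, dplyr::mutate(ln, kind = "gadget")), "kind")
  expect_error(stp_catalog(svc, dplyr::mutate(ln, kind = "human_resource")),
               "cadre")
  expect_error(stp_catalog(svc, dplyr::mutate(ln, service_id = "other")),
               "unknown service")
})

test_that("the example STP files read and cost sensibly", {
  cat_ex <- read_stp_catalog(
    system.file("extdata", "stp_services_synthetic.csv", package = "phccostgap"),
    system.file("extdata", "stp_lines_synthetic.csv", package = "phccostgap")
  )
  d <- stp_direct_unit_cost(cat_ex, 0.30)
  mal <- d$direct_unit_cost[d$service_id == "malaria_uncomplicated"]
  # (0.9 + 0.5) consumables + 15 min x 0.12/min / 0.7, all x 1.5 encounters
  expect_equal(mal, 1.5 * (1.4 + 15 * 0.12 / 0.7), tolerance = 1e-9)
  anc <- d$direct_unit_cost[d$service_id == "anc_visit"]
  # diagnostic flagged per-episode is not scaled by the 4 encounters
  expect_equal(anc, 4 * (20 * 0.12 / 0.7 + 2 * 0.8) + 1.2, tolerance = 1e-9)
})
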