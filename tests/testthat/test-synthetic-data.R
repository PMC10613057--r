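test_that("the same seed reproduces the world bit-for-bit", {
  w1 <- generate_world(world_params(seed = 7, n_subcounties = 2))
  w2 <- generate_world(world_params(seed = 7, n_subcounties = 2))
  expect_identical(w1$truth, w2$truth)
  expect_identical(w1$sample[[1]]$facilities, w2$sample[[1]]$facilities)
  expect_identical(w1$catalog$lines, w2$catalog$lines)
  w3 <- generate_world(world_params(seed = 8, n_subcounties = 2))
  expect_false(identical(w1$truth, w3$truth))
})

test_that("adding a sub-county does not perturb existing ones", {
  w2 <- generate_world(world_params(seed = 3, n_subcounties = 2))
  w3 <- generate_world(world_params(seed = 3, n_subcounties = 3))
  expect_identical(w2$universe[[1]]$facilities, w3$universe[[1]]$facilities)
  expect_identical(w2$universe[[2]]$facilities, w3$universe[[2]]$facilities)
})

test_that("generated worlds respect the structural constraints", {
  w <- generate_world(world_params(seed = 10))
  for (fr in w$universe) {
    fac <- fr$facilities
    expect_true(all(fac$clinical_staff >= 1))
    expect_true(all(fac$outpatient_visits > 0))
    disp_ip <- fac$inpatient_bed_days[fac$level == "dispensary"]
    # policy: dispensaries provide (almost) no inpatient care
    expect_lte(mean(disp_ip > 0), 0.25)
    expect_true(all(disp_ip <= 150))
  }
  for (i in seq_along(w$sample)) {
    expect_true(all(w$sample[[i]]$facilities$facility_id %in%
                      w$universe[[i]]$facilities$facility_id))
    # KHIS totals equal the generated universe's outpatient sums
    expect_equal(w$sample[[i]]$universe_op, w$universe[[i]]$universe_op)
  }
  expect_error(generate_world(world_params(
    facilities_per_level = c(dispensary = 0, health_center = 1,
                             primary_hospital = 1))),
    "at least one")
})

test_that("ground truth is internally consistent by construction", {
  w <- generate_world(world_params(seed = 12, n_subcounties = 2))
  for (i in 1:2) {
    fr <- w$universe[[i]]
    expect_equal(w$truth$true_universe_total[i],
                 sum(facility_total_cost(fr$facilities)), tolerance = 1e-12)
    expect_equal(w$truth$true_actual_pc[i],
                 w$truth$true_universe_total[i] / fr$population,
                 tolerance = 1e-12)
    expect_equal(w$truth$true_gap[i],
                 w$truth$true_normative_pc[i] - w$truth$true_actual_pc[i],
                 tolerance = 1e-12)
  }
})

test_that("the pipeline normative per-capita recovers the generator's truth", {
  for (seed in c(2, 21, 77)) {
    w <- generate_world(world_params(seed = seed, n_subcounties = 1))
    res <- normative_subcounty(w$catalog, w$truth$population[1],
                               w$universe_overheads,
                               nonclinical_share = w$params$nonclinical_share)
    expect_equal(res$normative_pc, w$truth$true_normative_pc[1],
                 tolerance = 1e-9)
  }
})

test_that("extrapolated network totals recover the truth within 5% (median over 50 seeds)", {
  rel_err <- purrr::map(1:50, function(seed) {
    w <- generate_world(world_params(seed = seed, n_subcounties = 1))
    est <- network_total(w$sample[[1]])$network_total
    abs(est - w$truth$true_universe_total[1]) / w$truth$true_universe_total[1]
  }) |> unlist()
  expect_lt(median(rel_err), 0.05)
})

test_that("the estimated gap keeps the true sign on clearly gapped worlds", {
  signs <- purrr::map_lgl(1:40, function(seed) {
    w <- generate_world(world_params(seed = 1000 + seed, n_subcounties = 1))
    truth <- w$truth
    if (abs(truth$true_gap[1]) <= 0.2 * truth$true_actual_pc[1]) return(NA)
    actual_pc <- network_total(w$sample[[1]])$actual_pc
    oh <- pooled_overhead_rates(w$sample[[1]]$facilities)
    norm_pc <- normative_subcounty(w$catalog, truth$population[1], oh,
                                   nonclinical_share = w$params$nonclinical_share
    )$normative_pc
    sign(norm_pc - actual_pc) == sign(truth$true_gap[1])
  })
  signs <- signs[!is.na(signs)]
  expect_gt(length(signs), 5)
  expect_gte(mean(signs), 0.95)
})

test_that("a written world reads back through the standard readers", {
  w <- generate_world(world_params(seed = 14, n_subcounties = 2))
  dir <- withr::local_tempdir()
  write_world(w, dir)
  frames <- read_subcounty_frames(file.path(dir, "facilities.csv"),
                                  file.path(dir, "universe.csv"),
                                  file.path(dir, "population.csv"))
  expect_length(frames, 2)
  for (i in 1:2) {
    expect_equal(network_total(frames[[i]])$network_total,
                 network_total(w$sample[[i]])$network_total,
                 tolerance = 1e-9)
  }
  cat_back <- read_stp_catalog(file.path(dir, "stp_services.csv"),
                               file.path(dir, "stp_lines.csv"))
  expect_equal(stp_direct_unit_cost(cat_back)$direct_unit_cost,
               stp_direct_unit_cost(w$catalog)$direct_unit_cost,
               tolerance = 1e-9)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$true_universe_total, w$truth$true_universe_total,
               tolerance = 1e-9)
})

test_that("tidiers and plots summarise the result objects", {
  fx <- paper_fixture()
  nc <- network_total(fx$frames[["Ganze"]])
  expect_equal(nrow(tidy(nc)), 3)
  expect_equal(glance(nc)$actual_pc, nc$actual_pc)

  w <- generate_world(world_params(seed = 33, n_subcounties = 1))
  res <- normative_subcounty(w$catalog, 1e5, w$universe_overheads)
  expect_equal(glance(res)$normative_pc, res$normative_pc)
  expect_true(all(tidy(res)$unit_cost >= 0))

  tor <- one_way(actual_pc_model(fx$frames[["Ganze"]]), sensitivity_spec())
  expect_equal(nrow(tidy(tor)), 5)
  expect_s3_class(autoplot(tor), "ggplot")
  expect_s3_class(plot_cost_shares(fx$frames[["Ganze"]]$facilities), "ggplot")
  g <- resource_gap(fx$gap_table$actual_pc, fx$gap_table$normative_pc,
                    label = fx$gap_table$sub_county)
  expect_s3_class(plot_gap(g), "ggplot")
})
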