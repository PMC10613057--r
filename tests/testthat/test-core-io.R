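ext <- function(f) system.file("extdata", f, package = "phccostgap")

test_that("facility table reader round-trips the example file", {
  fac <- read_facility_table(ext("facilities.csv"))
  expect_equal(nrow(fac), 3)
  hosp <- fac[fac$level == "primary_hospital", ]
  expect_equal(hosp$clinical_staff, 21)
  expect_equal(hosp$outpatient_visits, 9620)
  expect_equal(hosp$inpatient_bed_days, 666)
  expect_equal(facility_total_cost(hosp), 302853 + 98987 + 0 + 96833)
})

test_that("reader handles header-only files, unknown columns, and bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(c("facility_id", "sub_county", "level", "clinical_staff",
                     "nonclinical_staff", "outpatient_visits",
                     "inpatient_bed_days", phc_cost_categories()),
                   collapse = ","), path)
  expect_equal(nrow(read_facility_table(path)), 0)

  fac <- random_facilities(3, seed = 11)
  fac$mystery <- "x"
  readr::write_csv(fac, path)
  expect_warning(out <- read_facility_table(path), "mystery")
  expect_false("mystery" %in% names(out))

  fac2 <- random_facilities(3, seed = 12)
  fac2$drugs[2] <- -5
  readr::write_csv(fac2, path)
  expect_error(read_facility_table(path), "row 2")

  fac3 <- random_facilities(3, seed = 13)[, -3]
  readr::write_csv(fac3, path)
  expect_error(read_facility_table(path), "level")
})

test_that("write then read reproduces every facility field", {
  fac <- random_facilities(25, seed = 42)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(fac, path)
  back <- read_facility_table(path)
  expect_identical(back$facility_id, fac$facility_id)
  expect_identical(as.character(back$level), fac$level)
  for (col in c("clinical_staff", "outpatient_visits", "inpatient_bed_days")) {
    expect_equal(back[[col]], fac[[col]], tolerance = 1e-12)
  }
  for (col in phc_cost_categories()) {
    expect_equal(back[[col]], fac[[col]], tolerance = 1e-9)
  }
})

test_that("sub-county frames assemble from the three input files", {
  frames <- read_subcounty_frames(ext("facilities.csv"), ext("universe.csv"),
                                  ext("population.csv"))
  expect_length(frames, 1)
  expect_equal(frames[[1]]$population, 99729)
  expect_equal(unname(frames[[1]]$universe_op["dispensary"]), 8800)
})

test_that("frame assembly warns and clamps when the sample exceeds the universe", {
  fac <- one_facility(op = 500)
  expect_warning(
    fr <- subcounty_frame("x", "y", 1000, fac, c(dispensary = 100)),
    "clamping"
  )
  expect_equal(unname(fr$universe_op["dispensary"]), 500)
})

test_that("two sub-counties in one file yield two frames, ordered by name", {
  fac <- random_facilities(6, seed = 3)
  fac$sub_county <- rep(c("beta", "alpha"), each = 3)
  paths <- replicate(3, withr::local_tempfile(fileext = ".csv",
                                              .local_envir = parent.frame()))
  readr::write_csv(fac, paths[1])
  uni <- expand.grid(sub_county = c("alpha", "beta"), level = phc_levels(),
                     stringsAsFactors = FALSE)
  uni$universe_op <- 1e6
  readr::write_csv(uni, paths[2])
  readr::write_csv(
    data.frame(sub_county = c("alpha", "beta"), county = "c",
               population = c(1000, 2000)),
    paths[3]
  )
  frames <- read_subcounty_frames(paths[1], paths[2], paths[3])
  expect_equal(purrr::map_chr(frames, "name"), c("alpha", "beta"))
  expect_equal(frames[[1]]$facilities$facility_id,
               fac$facility_id[fac$sub_county == "alpha"])
  expect_equal(frames[[2]]$population, 2000)
})

test_that("a sub-county missing from the population file is a hard error", {
  fac <- random_facilities(2, seed = 5)
  paths <- replicate(3, withr::local_tempfile(fileext = ".csv",
                                              .local_envir = parent.frame()))
  readr::write_csv(fac, paths[1])
  readr::write_csv(data.frame(sub_county = "testland", level = phc_levels(),
                              universe_op = 1e6), paths[2])
  readr::write_csv(data.frame(sub_county = "otherland", population = 1),
                   paths[3])
  expect_error(read_subcounty_frames(paths[1], paths[2], paths[3]), "testland")
})

test_that("round_half_up matches the reporting convention of the tables", {
  expect_equal(round_half_up(1.568, 1), 1.6)
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(12.7305, 1), 12.7)
  expect_equal(round_half_up(-0.85, 1), -0.9)
  expect_equal(round_half_up(1269600.4), 1269600)
})

test_that("write_results adds reported columns under the rounding convention", {
  g <- resource_gap(26.6, 41.7)
  path <- withr::local_tempfile(fileext = ".csv")
  out <- write_results(g, path)
  expect_equal(out$investment_multiple_reported, 1.6)
  expect_equal(out$gap_pc_reported, 15.1)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$investment_multiple, 41.7 / 26.6)

  empty <- resource_gap(numeric(0), numeric(0))
  out2 <- write_results(empty, path)
  expect_equal(nrow(out2), 0)
  expect_gt(length(readLines(path)), 0)
})

test_that("reported values equal unrounded values after half-up rounding on the published tables", {
  net <- fixture_network_costs()
  fx <- paper_fixture()
  for (sc in names(fx$frames)) {
    nc <- network_total(fx$frames[[sc]])
    expect_equal(round_half_up(nc$actual_pc, 1),
                 net$per_capita[net$sub_county == sc][1])
  }
  gaps <- fixture_gap_table()
  g <- resource_gap(gaps$actual_pc, gaps$normative_pc)
  expect_equal(g$multiple_reported, gaps$multiple_reported)
})

test_that("config reads from YAML and rejects invalid shares", {
  cfg <- read_phc_config(ext("config.yaml"))
  expect_equal(cfg$nonclinical_time_share, 0.30)
  expect_equal(cfg$exchange_rate_kes_per_usd, 101.99)
  expect_equal(cfg$working_days_per_year, 264)
  expect_error(phc_config(nonclinical_time_share = 1), "\\[0, 1\\)")
})
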