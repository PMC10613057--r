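# Random facility tables for property-style tests (not the full synthetic
# world; just well-formed rows).
random_facilities <- function(n, seed = 1) {
  set.seed(seed)
  levels <- sample(phc_levels(), n, replace = TRUE)
  tibble::tibble(
    facility_id = sprintf("fac_%04d", seq_len(n)),
    sub_county = "testland",
    level = levels,
    clinical_staff = sample(1:120, n, replace = TRUE),
    nonclinical_staff = sample(0:50, n, replace = TRUE),
    outpatient_visits = round(runif(n, 1000, 100000)),
    inpatient_bed_days = ifelse(levels == "dispensary", 0,
                                round(runif(n, 0, 15000))),
    clinical_labor = runif(n, 5e3, 2e6),
    drugs = runif(n, 1e3, 1e6),
    medical_supplies = runif(n, 0, 5e4),
    indirect = runif(n, 0, 5e5)
  )
}

one_facility <- function(level = "dispensary", op = 80, ip = 0,
                         costs = c(1000, 0, 0, 0), staff = 2) {
  tibble::tibble(
    facility_id = "f1", sub_county = "testland", level = level,
    clinical_staff = staff, nonclinical_staff = 1,
    outpatient_visits = op, inpatient_bed_days = ip,
    clinical_labor = costs[1], drugs = costs[2],
    medical_supplies = costs[3], indirect = costs[4]
  )
}
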