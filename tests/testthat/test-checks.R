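two_site_patients <- function(n_per_site = 4) {
  tibble::tibble(
    patient_id = sprintf("p%02d", seq_len(2 * n_per_site)),
    site_id = rep(c("s1", "s2"), each = n_per_site),
    birth_date = as.Date("2005-01-01"), sex = "female", race = "white",
    ethnicity = "non_hispanic", geocode_level = "block_group")
}

test_that("completeness trend counts patients with a record per active year", {
  p <- two_site_patients(4)[1:4, ]
  visits <- tibble::tibble(visit_id = sprintf("v%d", 1:4),
                           patient_id = p$patient_id,
                           date = as.Date("2015-06-01"),
                           visit_type = "outpatient",
                           provider_specialty = "none", in_person = TRUE)
  labs <- tibble::tibble(patient_id = c("p01", "p02", "p02"),
                         date = as.Date("2015-03-01"),
                         lab = "serum_creatinine", value = 1, unit = "mg/dL")
  ds <- make_dataset(p, visits = visits, labs = labs)
  out <- completeness_trend(ds, "lab:serum_creatinine")
  expect_equal(out$value, 0.5)  # 2 of 4 active patients
  expect_equal(out$denominator, 4)
  # duplicate records for a counted patient-year change nothing
  ds2 <- make_dataset(p, visits = visits,
                      labs = dplyr::bind_rows(labs, labs))
  expect_equal(completeness_trend(ds2, "lab:serum_creatinine")$value, 0.5)
  # all four with a record
  labs4 <- tibble::tibble(patient_id = p$patient_id,
                          date = as.Date("2015-03-01"),
                          lab = "serum_creatinine", value = 1, unit = "mg/dL")
  ds3 <- make_dataset(p, visits = visits, labs = labs4)
  expect_equal(completeness_trend(ds3, "lab:serum_creatinine")$value, 1.0)
})

test_that("same-day concordance is the fraction of systolic days with a diastolic", {
  p <- two_site_patients(1)[1, ]
  base <- as.Date("2015-01-01")
  vitals <- tibble::tibble(
    patient_id = "p01",
    date = base + c(0, 10, 20, 0, 10),
    measure = c(rep("systolic_bp", 3), rep("diastolic_bp", 2)),
    value = 100, unit = "mmHg")
  ds <- make_dataset(p, vitals = vitals)
  out <- same_day_concordance(ds)
  expect_equal(out$value, 2 / 3, tolerance = 1e-12)
  expect_equal(out$denominator, 3)
})

test_that("pair correlation is exact for linear relationships", {
  p <- two_site_patients(1)[1, ]
  base <- as.Date("2015-01-01")
  sys <- c(90, 100, 110, 120, 130)
  mk <- function(dia) make_dataset(p, vitals = tibble::tibble(
    patient_id = "p01", date = rep(base + 1:5, 2),
    measure = rep(c("systolic_bp", "diastolic_bp"), each = 5),
    value = c(sys, dia), unit = "mmHg"))
  expect_equal(pair_correlation(mk(0.5 * sys))$value, 1.0)
  expect_equal(pair_correlation(mk(-sys + 170))$value, -1.0)
  # below the minimum pair count: no row
  ds <- mk(0.5 * sys)
  ds$vitals <- ds$vitals[c(1, 6), ]
  expect_equal(nrow(pair_correlation(ds)), 0L)
})

test_that("unit-mapped proportion counts mapped units only", {
  p <- two_site_patients(1)[1, ]
  labs <- tibble::tibble(patient_id = "p01",
                         date = as.Date("2015-01-01") + 1:5,
                         lab = "urine_protein_quant", value = 10,
                         unit = c(rep("mg/dL", 4), "missing"))
  ds <- make_dataset(p, labs = labs)
  expect_equal(unit_mapped_proportion(ds, "urine_protein_quant")$value, 0.8)
  labs$unit <- "missing"
  expect_equal(unit_mapped_proportion(make_dataset(p, labs = labs),
                                      "urine_protein_quant")$value, 0)
  expect_equal(nrow(unit_mapped_proportion(make_dataset(p, labs = labs),
                                           "serum_cystatin_c")), 0L)
})

test_that("code utilization deduplicates patient-years and keeps zero rows", {
  cfg <- analysis_config()
  p <- two_site_patients(4)
  visits <- tibble::tibble(visit_id = sprintf("v%d", 1:8),
                           patient_id = p$patient_id,
                           date = as.Date("2015-06-01"),
                           visit_type = "outpatient",
                           provider_specialty = "none", in_person = TRUE)
  procs <- tibble::tibble(patient_id = rep("p01", 5),
                          date = as.Date("2015-02-01") + (0:4) * 30,
                          code = "90935", code_group = "chronic_dialysis")
  ds <- make_dataset(p, visits = visits, procs = procs)
  cohort <- tibble::tibble(patient_id = p$patient_id, site_id = p$site_id,
                           ced = as.Date("2015-01-01"))
  out <- code_utilization(ds, cohort, "chronic_dialysis", cfg)
  # 5 identical codes in one year contribute exactly 1 patient-year of 4
  expect_equal(out$value[out$site_id == "s1"], 0.25)
  # the other site has an explicit zero row
  expect_equal(out$value[out$site_id == "s2"], 0)
  # duplicating any procedure record changes nothing
  ds2 <- make_dataset(p, visits = visits,
                      procs = dplyr::bind_rows(procs, procs[3, ]))
  expect_equal(code_utilization(ds2, cohort, "chronic_dialysis", cfg), out)
  # a code below pooled prevalence is excluded: 1 of 8 patient-years = 12.5%
  # passes, so tighten via config
  cfg2 <- analysis_config(prevalence_min = 0.2)
  expect_equal(nrow(code_utilization(ds, cohort, "chronic_dialysis", cfg2)),
               0L)
})

test_that("geocode proportions partition each site", {
  p <- two_site_patients(5)
  p$geocode_level <- c(rep("block_group", 5),
                       c("tract", "tract", "tract", "zip5", "zip5"))
  ds <- make_dataset(p)
  out <- geocode_granularity(ds)
  s2 <- out[out$site_id == "s2", ]
  expect_equal(s2$value[s2$stratum == "tract"], 0.6)
  expect_equal(s2$value[s2$stratum == "zip5"], 0.4)
  expect_equal(s2$value[s2$stratum == "block_group"], 0)
  sums <- tapply(out$value, out$site_id, sum)
  expect_equal(as.numeric(sums), c(1, 1))
})

test_that("value distribution reports top mass and out-of-range fractions", {
  p <- two_site_patients(1)[1, ]
  vals <- c(rep(9999, 200), seq(1, 800, length.out = 800))
  labs <- tibble::tibble(patient_id = "p01",
                         date = as.Date("2015-01-01") + seq_along(vals),
                         lab = "urine_protein_quant", value = vals,
                         unit = "mg/dL")
  ds <- make_dataset(p, labs = labs)
  out <- value_distribution(ds, "lab:urine_protein_quant")
  expect_equal(out$value[out$stratum == "top_mass"], 0.2)
  expect_gte(out$value[out$stratum == "out_of_range"], 0.2)
  # all-distinct in-range values
  labs$value <- seq(1, 100, length.out = nrow(labs))
  out2 <- value_distribution(make_dataset(p, labs = labs),
                             "lab:urine_protein_quant")
  expect_equal(out2$value[out2$stratum == "top_mass"], 1 / nrow(labs))
  expect_equal(out2$value[out2$stratum == "out_of_range"], 0)
})

test_that("per-patient density doubles under full duplication", {
  ds <- generate_network(sim_config(n_sites = 2, patients_per_site = 60,
                                    seed = 41))
  before <- per_patient_density(ds, "vital:height")
  dup <- inject_anomaly(ds, anomaly_spec("duplicate_vitals", "site01",
                                         fraction = 1), seed = 1)$dataset
  after <- per_patient_density(dup, "vital:height")
  expect_equal(after$value[after$site_id == "site01"],
               2 * before$value[before$site_id == "site01"])
  expect_equal(after$value[after$site_id == "site02"],
               before$value[before$site_id == "site02"])
})

test_that("aggregate and pooled execution modes agree exactly", {
  ds <- generate_network(sim_config(n_sites = 4, patients_per_site = 120,
                                    seed = 42))
  for (round in c("DQ1", "DQ2")) {
    cat <- load_catalog(round)
    agg <- run_round(ds, "DQ1", catalog = cat)$results
    pooled <- run_round(ds, "DQ2", catalog = cat)$results
    j <- dplyr::full_join(agg, pooled, by = c("check_num", "site_id",
                                              "stratum"))
    expect_false(any(is.na(j$value.x) != is.na(j$value.y)))
    expect_true(all(j$value.x == j$value.y, na.rm = TRUE))
    expect_identical(j$value.x, j$value.y)
  }
})

test_that("aggregate-mode output carries site but never patient identifiers", {
  ds <- generate_network(sim_config(n_sites = 3, patients_per_site = 60,
                                    seed = 43))
  out <- run_round(ds, "DQ1")
  expect_named(out$results, c("check_num", "site_id", "stratum", "value",
                              "denominator"))
  expect_false(any(grepl("-p\\d{4}", out$results$stratum)))
  expect_true(all(out$results$site_id %in% ds$patients$site_id))
})

test_that("proportions from executors stay in [0, 1]", {
  ds <- generate_network(sim_config(n_sites = 3, patients_per_site = 60,
                                    seed = 44))
  prop_execs <- list(
    completeness_trend(ds, "lab:serum_creatinine"),
    same_day_concordance(ds),
    geocode_granularity(ds),
    unit_mapped_proportion(ds, "urine_protein_quant"))
  for (r in prop_execs) {
    expect_true(all(r$value >= 0 & r$value <= 1))
  }
})
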