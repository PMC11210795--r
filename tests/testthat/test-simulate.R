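test_that("generation is deterministic under a fixed seed", {
  a <- generate_network(sim_config(n_sites = 2, patients_per_site = 50,
                                   seed = 1))
  b <- generate_network(sim_config(n_sites = 2, patients_per_site = 50,
                                   seed = 1))
  for (d in c("patients", "visits", "vitals", "labs", "meds", "procs"))
    expect_identical(a[[d]], b[[d]], info = d)
  c_ <- generate_network(sim_config(n_sites = 2, patients_per_site = 50,
                                    seed = 2))
  expect_false(identical(a$vitals, c_$vitals))
})

test_that("CKD assignment follows the configured fraction binomially", {
  ds <- generate_network(sim_config(n_sites = 2, patients_per_site = 500,
                                    ckd_fraction = 0.5, seed = 8))
  # nephrology visits are the CKD marker in the generated data
  ckd <- unique(ds$visits$patient_id[ds$visits$provider_specialty ==
                                       "nephrology"])
  per_site <- table(sub("-.*", "", ckd))
  for (n in per_site) # 250 +/- 5 binomial SDs (~11)
    expect_lt(abs(n - 250), 5 * sqrt(500 * 0.25))
})

test_that("blood pressure correlation converges to its target", {
  ds <- generate_network(sim_config(n_sites = 2, patients_per_site = 600,
                                    bp_correlation = 0.6, seed = 12))
  v <- ds$vitals[ds$vitals$measure %in% c("systolic_bp", "diastolic_bp"), ]
  w <- tidyr::pivot_wider(v[, c("patient_id", "date", "measure", "value")],
                          names_from = "measure", values_from = "value",
                          values_fn = mean)
  w <- w[!is.na(w$systolic_bp) & !is.na(w$diastolic_bp), ]
  expect_gt(nrow(w), 10000)
  expect_lt(abs(cor(w$systolic_bp, w$diastolic_bp) - 0.6), 0.05)
})

test_that("generated values stay physiologically plausible", {
  ds <- generate_network(sim_config(n_sites = 1, patients_per_site = 200,
                                    seed = 14))
  h <- ds$vitals$value[ds$vitals$measure == "height"]
  expect_true(all(h > 60 & h < 220))
  up <- ds$labs$value[ds$labs$lab == "urine_protein_quant"]
  expect_true(all(up >= 0 & up <= 5000))
  expect_true(all(ds$labs$value > 0))
  expect_true(all(ds$labs$mapped_unit))
  # site span covers the study interval
  expect_equal(ds$site_span$first_year, 2009L)
  expect_equal(ds$site_span$last_year, 2021L)
})

test_that("anomaly injection changes only the targeted site and domain", {
  ds <- generate_network(sim_config(n_sites = 3, patients_per_site = 80,
                                    seed = 22))
  out <- inject_anomaly(ds, anomaly_spec("height_unit_error", "site02",
                                         fraction = 0.3), seed = 5)
  mod <- out$dataset
  expect_identical(mod$labs, ds$labs)
  expect_identical(mod$visits, ds$visits)
  expect_identical(mod$vitals[mod$vitals$site_id != "site02", ],
                   ds$vitals[ds$vitals$site_id != "site02", ])
  h0 <- ds$vitals$value[ds$vitals$site_id == "site02" &
                          ds$vitals$measure == "height"]
  h1 <- mod$vitals$value[mod$vitals$site_id == "site02" &
                           mod$vitals$measure == "height"]
  frac_changed <- mean(h1 != h0)
  expect_gt(frac_changed, 0.2)
  expect_lt(frac_changed, 0.4)
  expect_equal(sort(unique(round(h0[h1 != h0] / h1[h1 != h0], 6))), 2.54)
  expect_equal(out$registry$expected_dq_issue, "outlier values")
})

test_that("full duplication doubles every height row at the site", {
  ds <- generate_network(sim_config(n_sites = 2, patients_per_site = 50,
                                    seed = 23))
  out <- inject_anomaly(ds, anomaly_spec("duplicate_vitals", "site01",
                                         fraction = 1.0), seed = 5)
  n0 <- sum(ds$vitals$site_id == "site01" & ds$vitals$measure == "height")
  n1 <- sum(out$dataset$vitals$site_id == "site01" &
              out$dataset$vitals$measure == "height")
  expect_equal(n1, 2L * n0)
  counts <- table(paste(out$dataset$vitals$patient_id,
                        out$dataset$vitals$date,
                        out$dataset$vitals$value)[
    out$dataset$vitals$site_id == "site01" &
      out$dataset$vitals$measure == "height"])
  expect_true(all(counts %% 2 == 0))
})

test_that("urine-protein mass points hit the planted fraction", {
  ds <- generate_network(sim_config(n_sites = 2, patients_per_site = 200,
                                    seed = 24))
  out <- inject_anomaly(ds,
    anomaly_spec("qualitative_urine_protein_masses", "site01",
                 mass_points = c(60, 100, 150), fraction = 0.5), seed = 5)
  up <- out$dataset$labs
  up <- up$value[up$site_id == "site01" & up$lab == "urine_protein_quant"]
  expect_gte(mean(up %in% c(60, 100, 150)), 0.5)
})

test_that("missing-lab-year removes exactly the targeted site-year", {
  ds <- generate_network(sim_config(n_sites = 2, patients_per_site = 100,
                                    seed = 25))
  out <- inject_anomaly(ds, anomaly_spec("missing_lab_year", "site01",
                                         lab = "serum_creatinine",
                                         year = 2014), seed = 5)
  l <- out$dataset$labs
  yr <- as.integer(format(l$date, "%Y"))
  expect_equal(sum(l$site_id == "site01" & l$lab == "serum_creatinine" &
                     yr == 2014), 0L)
  expect_gt(sum(l$site_id == "site02" & l$lab == "serum_creatinine" &
                  yr == 2014), 0L)
  expect_gt(sum(l$site_id == "site01" & l$lab == "serum_creatinine" &
                  yr == 2013), 0L)
})

test_that("late data onset truncates the site span", {
  ds <- generate_network(sim_config(n_sites = 2, patients_per_site = 100,
                                    seed = 26))
  out <- inject_anomaly(ds, anomaly_spec("late_data_onset", "site01",
                                         cutoff_year = 2015), seed = 5)
  sp <- out$dataset$site_span
  expect_equal(sp$first_year[sp$site_id == "site01"], 2015L)
  expect_equal(sp$first_year[sp$site_id == "site02"], 2009L)
  expect_true(all(out$dataset$visits$date[
    out$dataset$visits$site_id == "site01"] >= as.Date("2015-01-01")))
})

test_that("plant expectations carry one row per plant", {
  ds <- generate_network(sim_config(n_sites = 11, patients_per_site = 30,
                                    seed = 27))
  pl <- inject_anomalies(ds, default_plants(ds), seed = 9)
  expect_equal(nrow(pl$registry), 11L)
  exp <- plant_expectations(pl$registry)
  expect_equal(nrow(exp), 11L)
  expect_true(all(exp$dq_issue %in% ehrdq:::DQ_ISSUES))
  drop_row <- exp[pl$registry$kind == "drop_specialty", ]
  expect_equal(drop_row$element, "specialty:nephrology")
  expect_equal(drop_row$dq_issue, "missingness")
  expect_equal(nrow(plant_expectations(pl$registry[0, ])), 0L)
  expect_error(inject_anomaly(ds, anomaly_spec("drop_specialty", "nowhere")),
               "unknown site")
})
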