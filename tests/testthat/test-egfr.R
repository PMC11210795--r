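test_that("bedside Schwartz closed form matches hand arithmetic", {
  expect_equal(compute_egfr(0.8, 120), 0.413 * 120 / 0.8)
  expect_equal(compute_egfr(0.8, 120), 61.95, tolerance = 1e-12)
  expect_equal(compute_egfr(0.413, 100), 100)
  expect_equal(compute_egfr(1.2, 140), 0.413 * 140 / 1.2, tolerance = 1e-12)
  expect_error(compute_egfr(0, 120), "implausible")
  expect_error(compute_egfr(0.8, -1), "implausible")
})

test_that("height linkage picks nearest-in-window with earlier-date ties", {
  cfg <- analysis_config()
  base <- as.Date("2015-01-01")
  labs <- tibble::tibble(patient_id = "p1", date = base + 100,
                         lab = "serum_creatinine", value = 1, unit = "mg/dL")
  heights <- tibble::tibble(date = base + c(5, 95), value = c(130, 140))
  out <- link_height(labs, heights, birth_date = "2005-01-01", config = cfg)
  expect_equal(out$height_used, 140)  # day 95 is nearer than day 5
  expect_equal(out$height_date, base + 95)

  # outside the 90-day window: no result
  labs2 <- labs; labs2$date <- base + 200
  expect_equal(nrow(link_height(labs2, heights[2, ],
                                birth_date = "2005-01-01", cfg)), 0L)

  # equidistant heights: the earlier one wins
  heights3 <- tibble::tibble(date = base + c(50, 150), value = c(120, 150))
  out3 <- link_height(labs, heights3, birth_date = "2005-01-01", cfg)
  expect_equal(out3$height_date, base + 50)
  expect_equal(out3$height_used, 120)

  # age window: a 25-year-old's creatinine yields nothing
  expect_equal(nrow(link_height(labs, heights, birth_date = "1989-01-01",
                                cfg)), 0L)
})

test_that("hand-traced patient survives all eleven attrition steps", {
  ds <- trace_patient_dataset()
  out <- apply_attrition(ds)
  expect_equal(out$report$retained, rep(1L, 11))
  expect_equal(nrow(out$cohort), 1L)
  expect_equal(out$cohort$ced, as.Date("2015-03-10"))
  e <- out$egfr
  expect_equal(sort(round(e$egfr, 2)), c(44, 45, 48.18))
})

test_that("an intervening normal eGFR excludes at step 7, not step 6", {
  ds <- trace_patient_dataset(insert_normal = TRUE)
  out <- apply_attrition(ds)
  retained <- out$report$retained
  expect_equal(retained[1:7], rep(1L, 7))  # steps 0-6
  expect_equal(retained[8:11], rep(0L, 4)) # steps 7-10
  expect_equal(nrow(out$cohort), 0L)
})

test_that("empty dataset yields all-zero attrition counts", {
  ds <- make_dataset(one_patient())
  out <- apply_attrition(ds)
  expect_equal(out$report$retained, rep(0L, 11))
  expect_equal(nrow(out$cohort), 0L)
})

test_that("attrition matches the brute-force oracle on random datasets", {
  cfg <- analysis_config()
  for (seed in 1:50) {
    ds <- random_small_dataset(seed)
    got <- apply_attrition(ds, cfg)
    want <- oracle_attrition(ds, cfg)
    expect_equal(as.data.frame(got$report[, c("site_id", "step", "retained")]),
                 want$report, ignore_attr = TRUE,
                 info = sprintf("seed %d", seed))
    expect_equal(as.data.frame(got$cohort), want$cohort, ignore_attr = TRUE,
                 info = sprintf("seed %d cohort", seed))
    # monotone non-increasing within site
    for (s in unique(got$report$site_id)) {
      r <- got$report$retained[got$report$site_id == s]
      expect_true(all(diff(r) <= 0), info = sprintf("seed %d site %s", seed, s))
    }
  }
})

test_that("threshold curve counts patients below thresholds and is monotone", {
  cohort <- tibble::tibble(patient_id = c("a", "b", "c", "d"), site_id = "s1",
                           ced = as.Date("2015-01-01"))
  egfr <- tibble::tibble(patient_id = c("a", "b", "c", "d"), site_id = "s1",
                         date = as.Date("2015-01-01"),
                         egfr = c(35, 48, 62, 85), scr = 1,
                         height_used = 140, height_date = as.Date("2015-01-01"))
  out <- egfr_threshold_curve(cohort, egfr, thresholds = c(40, 50, 60))
  expect_equal(out$proportion, c(0.25, 0.5, 0.5))

  one <- egfr_threshold_curve(cohort[2, ], egfr[2, ],
                              thresholds = c(40, 50, 60))
  expect_equal(one$proportion, c(0, 1, 1))

  ds <- generate_network(sim_config(n_sites = 2, patients_per_site = 150,
                                    seed = 31))
  att <- apply_attrition(ds)
  curve <- egfr_threshold_curve(att$cohort, att$egfr)
  for (s in unique(curve$site_id)) {
    pr <- curve$proportion[curve$site_id == s]
    expect_true(all(diff(pr) >= 0))
  }
  expect_equal(nrow(egfr_threshold_curve(cohort[0, ], egfr)), 0L)
})

test_that("trajectory medians bin by integer year offset from entry", {
  cohort <- tibble::tibble(patient_id = "a", site_id = "s1",
                           ced = as.Date("2015-06-01"))
  egfr <- tibble::tibble(patient_id = "a", site_id = "s1",
                         date = as.Date("2015-06-01") + c(-400, 0),
                         egfr = c(80, 48), scr = 1, height_used = 140,
                         height_date = as.Date("2015-01-01"))
  out <- egfr_trajectory_medians(cohort, egfr)
  expect_equal(out$offset, c(-2L, 0L))
  expect_equal(out$median_egfr, c(80, 48))

  same_day <- egfr[2, ]
  out2 <- egfr_trajectory_medians(cohort, same_day)
  expect_equal(out2$offset, 0L)
})

test_that("computed eGFR equals the generator's record-implied truth", {
  ds <- generate_network(sim_config(n_sites = 2, patients_per_site = 100,
                                    seed = 17))
  truth <- attr(ds, "egfr_truth")
  e <- compute_egfr_table(ds)
  m <- dplyr::inner_join(e, truth, by = c("patient_id", "date", "scr"),
                         relationship = "many-to-many")
  expect_gt(nrow(m), 1000)
  expect_equal(median(abs(m$egfr - m$egfr_truth)), 0)
})
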