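test_that("the prioritizer reproduces the published site summary row-for-row", {
  got <- assign_priority(table4_issues())
  expect_equal(got, c("urgent", "urgent", "high", "medium", "medium",
                      "medium", "medium", "medium", "medium", "medium",
                      "low", "low", "low"))
})

test_that("missing interior years yield missingness issues listing the years", {
  cat <- load_catalog("DQ2")
  cn <- cat$check_num[cat$variable == "lab:serum_creatinine" &
                        cat$executor == "completeness_trend"]
  trend <- tibble::tibble(
    check_num = cn, site_id = "s1",
    stratum = as.character(2010:2016),
    value = c(0.8, 0.7, 0.9, 0.8, 0, 0.85, 0.8),
    denominator = 100)
  iss <- detect_missing_years(trend, cat)
  expect_equal(nrow(iss), 1L)
  expect_equal(iss$dq_issue, "missingness")
  expect_equal(iss$info, "calendar years missing: 2014")
  expect_equal(iss$missing_kind, "interior")
  expect_equal(assign_priority(iss), "high")  # eligibility-tier lab

  # no zero years -> no issues
  trend$value[5] <- 0.5
  expect_equal(nrow(detect_missing_years(trend, cat)), 0L)
})

test_that("leading missing years at span start become a late-onset issue", {
  cat <- load_catalog("DQ2")
  cn <- cat$check_num[cat$variable == "visit:any" &
                        cat$executor == "completeness_trend"]
  trend <- tibble::tibble(
    check_num = cn, site_id = "s1",
    stratum = as.character(2009:2016),
    value = c(0, 0, 0, 0, 0, 0.4, 0.5, 0.5),
    denominator = 1000)
  iss <- detect_missing_years(trend, cat)
  expect_equal(nrow(iss), 1L)
  expect_equal(iss$element, "cohort_entry")
  expect_equal(iss$info,
               "calendar years missing: 2009, 2010, 2011, 2012, 2013")
  expect_equal(assign_priority(iss), "medium")
  expect_equal(strsplit(assign_theme(iss), ";")[[1]][2],
               "Variation in time of cohort entry")
})

test_that("total missingness of an eligibility element is urgent", {
  cat <- load_catalog("DQ2")
  cn <- cat$check_num[cat$variable == "specialty:nephrology"]
  trend <- tibble::tibble(check_num = cn, site_id = "s1",
                          stratum = as.character(2010:2015), value = 0,
                          denominator = 100)
  iss <- detect_missing_years(trend, cat)
  expect_equal(iss$missing_kind, "total")
  expect_equal(assign_priority(iss), "urgent")
})

test_that("leave-one-out z-scores with an SD floor find yearly spikes", {
  cat <- load_catalog("DQ2")
  cn <- cat$check_num[cat$variable == "visit:any" &
                        cat$executor == "yearly_count_trend"]
  mk <- function(v) tibble::tibble(check_num = cn, site_id = "s1",
                                   stratum = as.character(seq(2010, by = 1,
                                     length.out = length(v))),
                                   value = v, denominator = sum(v))
  # hand arithmetic: LOO mean 100, SD floored at 0.05*100 = 5, z = 200/5 = 40
  iss <- detect_spikes(mk(c(100, 100, 100, 100, 300)), cat)
  expect_equal(iss$dq_issue, "high spike")
  expect_match(iss$info, "2014")
  expect_equal(assign_priority(iss), "medium")
  expect_true(grepl("Implausible temporal trends", assign_theme(iss)))

  expect_equal(nrow(detect_spikes(mk(rep(100, 6)), cat)), 0L)

  low <- detect_spikes(mk(c(100, 100, 100, 100, 20)), cat)
  expect_equal(low$dq_issue, "low spike")
  # fewer than 4 years: no detection
  expect_equal(nrow(detect_spikes(mk(c(100, 300, 100)), cat)), 0L)
})

test_that("the Tukey fence flags the hand-computed outlier site", {
  vals <- tibble::tibble(site_id = sprintf("s%d", 1:5),
                         value = c(0.30, 0.32, 0.33, 0.35, 0.80))
  # type-7 quartiles: Q1 = 0.32, Q3 = 0.35, upper fence 0.395
  fl <- fence_outliers(vals, analysis_config())
  expect_equal(fl$site_id, "s5")
  expect_equal(fl$direction, "high")
  expect_equal(fl$fence_hi, 0.35 + 1.5 * (0.35 - 0.32), tolerance = 1e-12)
  # identical sites: nothing flagged; < 5 sites: nothing flagged
  expect_equal(nrow(fence_outliers(
    tibble::tibble(site_id = vals$site_id, value = 0.3),
    analysis_config())), 0L)
  expect_equal(nrow(fence_outliers(vals[1:4, ], analysis_config())), 0L)
})

test_that("fence agrees with brute-force quartile arithmetic on a grid", {
  cfg <- analysis_config(min_rel_dev = 0)  # pure fence for the oracle check
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(5:15, 1)
    v <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    vals <- tibble::tibble(site_id = sprintf("s%02d", seq_len(n)), value = v)
    got <- fence_outliers(vals, cfg)
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    lo <- q[1] - 1.5 * (q[2] - q[1]); hi <- q[2] + 1.5 * (q[2] - q[1])
    want <- vals$site_id[v < lo | v > hi]
    expect_setequal(got$site_id, want)
  }
})

test_that("value anomalies: mass points, defaulted 9999s, discordant BP", {
  cat <- load_catalog("DQ2")
  cn <- cat$check_num[cat$variable == "lab:urine_protein_quant" &
                        cat$executor == "value_distribution"]
  dist <- tibble::tibble(
    check_num = cn, site_id = "s1",
    stratum = c("top_mass", "out_of_range"),
    value = c(0.2, 0.2), denominator = 1000)
  iss <- detect_value_anomalies(dist, cat)
  expect_setequal(iss$dq_issue,
                  c("atypical numeric distribution", "outlier values"))
  # clean distribution: nothing
  dist$value <- c(0.01, 0)
  expect_equal(nrow(detect_value_anomalies(dist, cat)), 0L)
})

test_that("negative BP correlation is flagged discordant in a full round", {
  ds <- generate_network(sim_config(n_sites = 2, patients_per_site = 80,
                                    bp_correlation = -0.4, seed = 51))
  out <- dq_round(ds, "DQ2")
  disc <- out$issues[out$issues$dq_issue == "discordant values", ]
  expect_setequal(disc$site_id, c("site01", "site02"))
  expect_true(all(grepl("correlation", disc$info)))
})

test_that("issues validate against the issue vocabulary", {
  pl <- inject_anomalies(
    generate_network(sim_config(n_sites = 6, patients_per_site = 120,
                                seed = 52)),
    list(anomaly_spec("duplicate_vitals", "site01"),
         anomaly_spec("default_9999_labs", "site02")), seed = 5)
  out <- dq_round(pl$dataset, "DQ2")
  iss <- out$issues
  expect_true(all(iss$priority %in% ehrdq:::PRIORITIES))
  expect_true(all(iss$dq_issue %in% ehrdq:::DQ_ISSUES))
  expect_true(all(iss$status %in% ehrdq:::ISSUE_STATUSES))
  themes <- unlist(strsplit(iss$themes, ";"))
  expect_true(all(themes %in% ehrdq:::THEMES))
  expect_true(all(nchar(iss$info[iss$dq_issue == "missingness"]) > 0))
  expect_false(anyDuplicated(iss$issue_id) > 0)
})

test_that("theme lookup matches the published examples", {
  ex <- tibble::tibble(
    domain = c("laboratory tests", "anthropometrics", "utilization"),
    element = c("lab:serum_cystatin_c", "vital:height", "visit:any"),
    dq_issue = c("missingness", "high counts", "high spike"),
    missing_kind = c("interior", NA, NA))
  th <- assign_theme(ex)
  expect_true(grepl("Missingness of major variables", th[1]))
  expect_true(grepl("Duplication of values", th[2]))
  expect_true(grepl("Implausible temporal trends", th[3]))
})

test_that("round comparison resolves issues whose trigger disappears", {
  base <- generate_network(sim_config(n_sites = 6, patients_per_site = 120,
                                      seed = 53))
  planted <- inject_anomaly(base, anomaly_spec("missing_lab_year", "site01"),
                            seed = 3)$dataset
  before <- dq_round(planted, "DQ2")
  after <- run_round(base, "DQ2")  # the gap is fixed in round two
  cmp <- compare_rounds(before$issues, after)
  expect_equal(nrow(cmp), nrow(before$issues))
  key <- cmp$site_id == "site01" & cmp$element == "lab:serum_creatinine" &
    cmp$dq_issue == "missingness"
  expect_true(all(cmp$resolved[key]))
  expect_true(all(cmp$status[key] == "improvement"))

  # plant persists: not resolved
  cmp2 <- compare_rounds(before$issues, run_round(planted, "DQ2"))
  expect_false(any(cmp2$resolved[cmp2$site_id == "site01" &
                                   cmp2$element == "lab:serum_creatinine" &
                                   cmp2$dq_issue == "missingness"]))
})
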