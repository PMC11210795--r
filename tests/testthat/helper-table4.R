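# The 13 published site-summary issue tuples used to calibrate priorities.

table4_issues <- function() {
  tibble::tibble(
    domain = c("cohort definition", "anthropometrics", "laboratory tests",
               "cohort definition", "cohort entry", "laboratory tests",
               "anthropometrics", "anthropometrics", "blood_pressure",
               "blood_pressure", "laboratory tests", "medications",
               "medications"),
    element = c("attrition step 5", "height", "serum creatinine",
                "high serum creatinine cohort", "cohort entry",
                "quantitative urine protein measurement", "height", "weight",
                "diastolic", "systolic", "serum cystatin",
                "calcium channel blockers", "loop diuretics"),
    dq_issue = c("counts high", "values low", "missingness", "counts low",
                 "missingness", "missingness", "counts high", "counts high",
                 "counts high", "counts high", "missingness", "counts high",
                 "counts high"),
    info = c("see also domain: anthropometrics, element:height",
             "see also domain: cohort_definition, element:attrition_step_5",
             "calendar years missing: 2014", NA,
             "calendar years missing: 2009, 2010, 2011, 2012, 2013",
             "calendar years missing: 2014", NA, NA, NA, NA,
             "calendar years missing: 2014, 2015, 2018, 2019", NA, NA))
}

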