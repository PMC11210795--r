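# Brute-force attrition oracle: tests every patient against every criterion
# with explicit loops, independently of the package's vectorized pipeline.

oracle_attrition <- function(dataset, config = analysis_config()) {
  int <- config$study_interval
  k <- config$schwartz_k
  p <- dataset$patients
  res <- lapply(seq_len(nrow(p)), function(i) {
    pid <- p$patient_id[i]
    birth <- p$birth_date[i]
    v <- dataset$visits[dataset$visits$patient_id == pid, ]
    vy <- as.integer(format(v$date, "%Y"))
    l <- dataset$labs[dataset$labs$patient_id == pid &
                        dataset$labs$lab == "serum_creatinine", ]
    h <- dataset$vitals[dataset$vitals$patient_id == pid &
                          dataset$vitals$measure == "height" &
                          dataset$vitals$value > 0, ]
    pr <- dataset$procs[dataset$procs$patient_id == pid, ]

    s <- logical(11)
    s[1] <- any(vy >= int[1] & vy <= int[2])
    s[2] <- any(vy >= int[1] & vy <= int[2] & v$in_person)
    s[3] <- nrow(l) > 0
    age <- as.numeric(l$date - birth) / 365.25
    elig <- l[age >= config$age_min & age <= config$age_max, ]
    s[4] <- nrow(elig) > 0

    # compute eGFRs by exhaustive nearest-height search
    hdates <- sort(unique(h$date))
    hval <- vapply(hdates, function(d) min(h$value[h$date == d]), numeric(1))
    egfr <- data.frame(date = as.Date(character()), egfr = numeric())
    for (j in seq_len(nrow(elig))) {
      if (is.na(elig$value[j]) || elig$value[j] <= 0) next
      best <- NA; bestd <- Inf
      for (m in seq_along(hdates)) {
        dd <- abs(as.numeric(elig$date[j] - hdates[m]))
        better <- dd < bestd ||
          (dd == bestd && !is.na(best) && hdates[m] < hdates[best])
        if (better) { best <- m; bestd <- dd }
      }
      if (is.finite(bestd) && bestd <= config$height_window_days)
        egfr <- rbind(egfr, data.frame(date = elig$date[j],
                                       egfr = k * hval[best] / elig$value[j]))
    }
    s[5] <- nrow(egfr) > 0
    lows <- sort(unique(egfr$date[egfr$egfr >= config$egfr_low &
                                    egfr$egfr < config$egfr_high]))
    norms <- sort(unique(egfr$date[egfr$egfr >= config$egfr_high]))
    s[6] <- length(lows) > 0

    step6 <- FALSE; step7 <- FALSE; ced <- as.Date(NA)
    for (f in as.list(lows)) {
      addl <- lows[as.numeric(lows - f) >= config$gap_days]
      if (length(addl) >= 2) {
        step6 <- TRUE
        ok <- vapply(as.list(addl), function(a)
          !any(norms > f & norms < a), logical(1))
        if (sum(ok) >= 2) { step7 <- TRUE; ced <- f; break }
      }
    }
    s[7] <- step6; s[8] <- step7
    s[9] <- any(v$in_person & v$provider_specialty == "nephrology")
    if (step7) {
      s[10] <- !any(pr$code_group == "chronic_dialysis" & pr$date < ced)
      s[11] <- s[10] &&
        !any(pr$code_group == "kidney_transplant" & pr$date < ced)
    } else {
      s[10] <- FALSE; s[11] <- FALSE
    }
    # a patient counted at step k satisfies steps 0..k
    surv <- cumprod(s) == 1
    list(pid = pid, site = p$site_id[i], surv = surv, ced = ced)
  })
  all_sites <- sort(unique(p$site_id))
  report <- do.call(rbind, lapply(0:10, function(step) {
    data.frame(site_id = all_sites, step = step,
               retained = vapply(all_sites, function(s)
                 sum(vapply(res, function(r)
                   r$site == s && r$surv[step + 1], logical(1))),
                 integer(1)), row.names = NULL)
  }))
  report <- report[order(report$site_id, report$step), ]
  members <- Filter(function(r) r$surv[11], res)
  cohort <- data.frame(
    patient_id = vapply(members, `[[`, "", "pid"),
    site_id = vapply(members, `[[`, "", "site"),
    ced = as.Date(vapply(members, function(r) as.character(r$ced), "")))
  cohort <- cohort[order(cohort$site_id, cohort$patient_id), ]
  list(report = report, cohort = cohort)
}
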