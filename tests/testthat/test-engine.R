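test_that("annual-to-daily conversion and hazard-scale RR adjustment", {
  expect_equal(annual_prob_to_daily(0), 0)
  expect_equal(annual_prob_to_daily(1), 1)
  expect_equal(annual_prob_to_daily(0.014), 1 - 0.986^(1 / 365))
  expect_equal(annual_prob_to_daily(0.014), 3.8616e-5, tolerance = 1e-4)
  expect_true(all(diff(annual_prob_to_daily(seq(0, 1, 0.05))) > 0))
  expect_error(annual_prob_to_daily(1.1))
  expect_equal(rr_adjusted_daily_prob(0.3, 1), annual_prob_to_daily(0.3))
  expect_equal(rr_adjusted_daily_prob(0.3, 0), 0)
  expect_equal(rr_adjusted_daily_prob(0.014, 4.7),
               1 - exp(-4.7 * (-log(0.986)) / 365))
  expect_equal(rr_adjusted_daily_prob(0.014, 4.7), 1.815e-4, tolerance = 1e-3)
  expect_error(rr_adjusted_daily_prob(0.014, -1))
})

test_that("INR occupancy: baseline split, guided-dosing uplift, stable-dose rule", {
  p <- base_params
  expect_equal(inr_state_probs("sdw", 1, p),
               c(below = 0.36 * 0.54, in_range = 0.64, above = 0.36 * 0.46))
  g1 <- inr_state_probs("gtw", 1, p)
  expect_equal(unname(g1["in_range"]), 0.64 * 1.073)
  expect_equal(sum(g1), 1)
  expect_equal(inr_state_probs("gtw", 3, p), inr_state_probs("sdw", 1, p))
  expect_equal(inr_state_probs("sdw", 2, p), inr_state_probs("sdw", 1, p))
  expect_error(inr_state_probs("dab150", 1, p), "not INR-monitored")
  # additive-uplift variant
  pa <- base_params
  pa$flags$additive_ttr_uplift <- TRUE
  expect_equal(unname(inr_state_probs("gtw", 1, pa)["in_range"]), 0.64 + 0.073)
  # property: occupancy sums to 1 under random valid parameters
  set.seed(11)
  for (i in 1:20) {
    pr <- apply_overrides(p, list(ttr_sdw = runif(1, 0.3, 0.9),
                                  frac_below_of_out_of_range = runif(1),
                                  gtw_ttr_uplift = runif(1, 0, 0.3)))
    for (a in c("sdw", "gtw")) for (y in 1:2) {
      expect_equal(sum(inr_state_probs(a, y, pr)), 1)
    }
  }
})

test_that("daily hazards by state, arm and treatment status", {
  p <- base_params
  h <- daily_hazards("in_range", "sdw", "on_treatment", p)
  expect_equal(h$p_bleed_daily, annual_prob_to_daily(0.014))
  expect_equal(sum(h$lam_te_daily), -log(1 - 0.024) / 365)
  expect_equal(unname(h$p_te_by_subtype_daily["stroke"]),
               1 - exp(-0.525 * (-log(0.976)) / 365))
  # default (clinically coherent) assignment: above-range bleeds, below clots
  ha <- daily_hazards("above", "sdw", "on_treatment", p)
  hb <- daily_hazards("below", "sdw", "on_treatment", p)
  expect_equal(ha$p_bleed_daily, rr_adjusted_daily_prob(0.014, 4.7))
  expect_equal(hb$p_bleed_daily, annual_prob_to_daily(0.014))
  expect_equal(sum(hb$lam_te_daily), 3.5 * -log(1 - 0.024) / 365)
  expect_equal(sum(ha$lam_te_daily), 0.9 * -log(1 - 0.024) / 365)
  # literal printed labels swap the assignment
  pl <- base_params
  pl$flags$literal_rr_labels <- TRUE
  expect_equal(daily_hazards("below", "sdw", "on_treatment", pl)$p_bleed_daily,
               rr_adjusted_daily_prob(0.014, 4.7))
  expect_equal(sum(daily_hazards("above", "sdw", "on_treatment", pl)$lam_te_daily),
               3.5 * -log(1 - 0.024) / 365)
  # dabigatran references the SD-W time-weighted average
  hd <- daily_hazards("not_monitored", "dab150", "on_treatment", p)
  w <- inr_state_probs("sdw", 1, p)
  lam0 <- -log(1 - 0.024) / 365
  rr_avg <- unname(w["below"] * 3.5 + w["in_range"] + w["above"] * 0.9)
  split <- c(stroke = 0.525, mi = 0.125, pe = 0.30, dvt = 0.05)
  rr_dab <- c(stroke = 0.66, mi = 1.38, pe = 1.61, dvt = 1)
  expect_equal(unname(hd$lam_te_daily), unname(rr_dab * split * lam0 * rr_avg))
  # the split-weighted dabigatran multiplier exceeds 1 with these inputs,
  # so the total TE hazard is ABOVE the SD-W average (see methods vignette)
  expect_equal(sum(rr_dab * split), 1.052)
  expect_gt(sum(hd$lam_te_daily), rr_avg * lam0)
  # off treatment: no drug-related bleeds, subtherapeutic TE hazard
  hoff <- daily_hazards("below", "sdw", "off_permanent", p)
  expect_equal(hoff$p_bleed_daily, 0)
  expect_equal(sum(hoff$lam_te_daily), 3.5 * lam0)
  expect_error(daily_hazards("below", "dab150", "on_treatment", p))
  expect_error(daily_hazards("not_monitored", "sdw", "on_treatment", p))
})

test_that("bleed resolution matches the outcome tree", {
  p <- base_params
  s <- substream(7, 1, 0, 1, "bleed_subtype")
  n <- 200000
  ev <- resolve_bleed("sdw", s, p, day = 0, n = n)
  se <- function(q) 3 * sqrt(q * (1 - q) / n)
  expect_lt(abs(mean(ev$subtype == "ich") - 0.42), se(0.42))
  ich <- ev[ev$subtype == "ich", ]
  n_ich <- nrow(ich)
  se_i <- function(q) 3 * sqrt(q * (1 - q) / n_ich)
  expect_lt(abs(mean(ich$sequela == "none" & !ich$fatal) - 0.08), se_i(0.08))
  expect_lt(abs(mean(ich$sequela == "mild") - 0.16), se_i(0.16))
  expect_lt(abs(mean(ich$sequela == "severe") - 0.34), se_i(0.34))
  expect_lt(abs(mean(ich$fatal) - 0.42), se_i(0.42))
  # extracranial: 2% fatal, never a deficit
  gi <- ev[ev$subtype == "extracranial_gi", ]
  expect_lt(abs(mean(gi$fatal) - 0.02), 3 * sqrt(0.02 * 0.98 / nrow(gi)))
  expect_true(all(gi$sequela[!gi$fatal] == "none"))
  # fatal events die within 30 days of the event
  expect_true(all(ev$death_day[ev$fatal] - ev$day[ev$fatal] <= 30))
  expect_true(all(ev$death_day[ev$fatal] > ev$day[ev$fatal]))
  # dabigatran subtype split is the renormalized published one
  evd <- resolve_bleed("dab150", s, p, day = 0, n = n)
  expect_lt(abs(mean(evd$subtype == "ich") - 0.126 / 1.03),
            se(0.126 / 1.03))
})

test_that("thromboembolic resolution matches fatality and sequela tables", {
  p <- base_params
  s <- substream(8, 1, 0, 1, "te_outcome")
  n <- 200000
  se <- function(q, m) 3 * sqrt(q * (1 - q) / m)
  pe <- resolve_te("pe", s, p, n = n)
  expect_lt(abs(mean(pe$fatal) - 0.12), se(0.12, n))
  dvt <- resolve_te("dvt", s, p, n = n)
  expect_lt(abs(mean(dvt$fatal) - 0.06), se(0.06, n))
  expect_true(all(dvt$sequela[!dvt$fatal] == "none"))
  mi <- resolve_te("mi", s, p, n = n)
  expect_lt(abs(mean(mi$fatal) - 0.07), se(0.07, n))
  st <- resolve_te("stroke", s, p, n = n)
  expect_lt(abs(mean(st$fatal) - 0.195), se(0.195, n))
  surv <- st[!st$fatal, ]
  target <- c(severe = 0.402, mild = 0.425, none = 0.091) / 0.918
  for (lab in names(target)) {
    expect_lt(abs(mean(surv$sequela == lab) - target[[lab]]),
              se(target[[lab]], nrow(surv)))
  }
  # stroke deaths spread over three months
  expect_true(all(st$death_day[st$fatal] - st$day[st$fatal] <= 90))
  expect_error(resolve_te("appendicitis", s, p), "unknown TE subtype")
})

test_that("treatment status transitions and countdown", {
  p <- base_params
  on <- treatment_status("on_treatment")
  expect_equal(update_treatment_status(on, "ich", p)$state, "off_permanent")
  expect_equal(update_treatment_status(on, "subdural", p)$state, "off_permanent")
  gi <- update_treatment_status(on, "extracranial_gi", p)
  expect_equal(gi$state, "off_temporary")
  expect_equal(gi$days_remaining, 30L)
  expect_equal(update_treatment_status(on, "mi", p), on)
  offp <- treatment_status("off_permanent")
  expect_equal(update_treatment_status(offp, "extracranial_gi", p), offp)
  # countdown reverts to on_treatment after the stated days
  st <- gi
  for (i in 1:29) st <- tick_treatment_status(st)
  expect_equal(st$days_remaining, 1L)
  expect_equal(tick_treatment_status(st)$state, "on_treatment")
  expect_error(treatment_status("off_temporary", 0))
})

test_that("daily accrual: drug, monitoring, one-time items, discounting", {
  p <- base_params
  on <- treatment_status("on_treatment")
  hs <- list(utility = 0.95)
  a0 <- accrue_day(0, "gtw", hs, on, 1, p)
  expect_equal(a0$cost_today, 615 + 27.90 + 0.074 + 5 / 30)
  a0s <- accrue_day(0, "sdw", hs, on, 1, p)
  expect_equal(a0s$cost_today, 27.90 + 0.074 + 8.06 / 30)
  ad <- accrue_day(200, "dab150", hs, on, 1, p)
  expect_equal(ad$cost_today, 3.20)
  expect_equal(ad$discounted_cost, 3.20 * 1.03^(-200 / 365))
  expect_equal(ad$discounted_qaly_increment, 0.95 / 365 * 1.03^(-200 / 365))
  # later-year monitoring and sequela cost
  hs2 <- list(utility = 0.39, sequela = "severe", sequela_active = TRUE)
  a2 <- accrue_day(400, "sdw", hs2, on, 2, p)
  expect_equal(a2$cost_today, 0.074 + 4.03 / 30 + 6259 / 30)
  # off treatment: no drug or monitoring
  a3 <- accrue_day(400, "sdw", hs, treatment_status("off_permanent"), 2, p)
  expect_equal(a3$cost_today, 0)
  # zero discount leaves raw values
  p0 <- base_params
  p0$globals$discount_annual <- 0
  expect_equal(accrue_day(900, "dab150", hs, on, 3, p0)$discounted_cost, 3.20)
})

test_that("zero-risk trajectories equal the analytic sums", {
  co <- generate_cohort(2, 1, 5)
  for (arm in c("sdw", "gtw", "dab150")) {
    r <- run_arm(co, arm, zero_risk_params)
    cf <- closed_form_totals(arm, zero_risk_params)
    expect_equal(r$per_individual$cost, rep(cf$cost, 2), tolerance = 1e-12)
    expect_equal(r$per_individual$qaly, rep(cf$qaly, 2), tolerance = 1e-12)
    expect_true(all(r$per_individual$person_days == 1825))
    expect_true(all(r$per_individual$alive))
  }
})

test_that("trajectories are deterministic and respect the QALY bound", {
  p <- base_params
  t1 <- simulate_individual(3, "sdw", p, master_seed = 17, replicate_id = 2)
  t2 <- simulate_individual(3, "sdw", p, master_seed = 17, replicate_id = 2)
  expect_identical(t1, t2)
  co <- generate_cohort(2000, 1, 23)
  r <- run_arm(co, "gtw", p)
  ub <- 0.95 * sum(1.03^(-(0:1824) / 365)) / 365
  expect_true(all(r$per_individual$qaly <= ub + 1e-9))
  expect_true(all(r$per_individual$cost >= 0))
  expect_true(all(r$per_individual$person_days <= 1825))
  # fatal day-0 events cut person-time to the death window
  ev0 <- r$events[r$events$day == 0 & r$events$fatal, ]
  if (nrow(ev0) > 0) {
    pd <- r$per_individual$person_days[r$per_individual$id %in% ev0$individual]
    expect_true(all(pd <= 90))
  }
})

test_that("raising a hazard never delays the first event (shared streams)", {
  p_lo <- base_params
  p_hi <- apply_overrides(base_params, list(p_bleed_annual_inrange = 0.10))
  co <- generate_cohort(3000, 1, 31)
  a <- run_arm(co, "sdw", p_lo, horizon_days = 365)
  b <- run_arm(co, "sdw", p_hi, horizon_days = 365)
  f_lo <- first_event_days(a$events, 3000)
  f_hi <- first_event_days(b$events, 3000)
  expect_true(all(f_hi <= f_lo))
  expect_gt(sum(b$per_individual$n_bleed), sum(a$per_individual$n_bleed))
})

test_that("raising the discount rate never raises discounted totals", {
  p_hi <- base_params
  p_hi$globals$discount_annual <- 0.05
  co <- generate_cohort(500, 1, 37)
  for (arm in c("sdw", "dab150")) {
    a <- run_arm(co, arm, base_params, horizon_days = 730)
    b <- run_arm(co, arm, p_hi, horizon_days = 730)
    # identical event paths (discounting does not touch the streams)
    expect_identical(a$events, b$events)
    expect_true(all(b$per_individual$cost <= a$per_individual$cost + 1e-12))
    expect_true(all(b$per_individual$qaly <= a$per_individual$qaly + 1e-12))
  }
})

test_that("unit dabigatran RRs with shared streams reproduce SD-W event days", {
  p1 <- apply_overrides(base_params, c(unit_rr_overrides, list(
    bleed_split_dab_raw.intracranial = 0.42,
    bleed_split_dab_raw.extracranial = 0.58)))
  co <- generate_cohort(3000, 1, 11)
  a <- run_arm(co, "sdw", p1)
  b <- run_arm(co, "dab150", p1)
  # with splits equalized the whole event log coincides
  expect_identical(a$events, b$events)
  expect_identical(a$per_individual$person_days, b$per_individual$person_days)
  # with the published (different) bleed split, first-event days still match
  p2 <- apply_overrides(base_params, unit_rr_overrides)
  b2 <- run_arm(co, "dab150", p2)
  expect_identical(first_event_days(a$events, 3000),
                   first_event_days(b2$events, 3000))
})

test_that("event-rate bookkeeping", {
  expect_equal(events_per_100py(321, 3650000), 3.21)
  expect_equal(events_per_100py(0, 1000), 0)
  expect_equal(events_per_100py(181, 10000 * 365), 1.81)
  expect_error(events_per_100py(1, 0), "person-time")
})

test_that("run_arm with one individual equals simulate_individual", {
  co <- generate_cohort(1, 4, 99)
  r <- run_arm(co, "dab150", base_params)
  tr <- simulate_individual(0, "dab150", base_params, master_seed = 99,
                            replicate_id = 4)
  expect_equal(r$per_individual$cost, tr$discounted_cost)
  expect_equal(r$per_individual$qaly, tr$discounted_qalys)
  expect_equal(r$per_individual$person_days, tr$person_days)
})

test_that("replicate summaries are internally consistent and reproducible", {
  rs <- run_strategies(base_params, arms = c("sdw", "dab150"), n = 300,
                       n_replicates = 8, master_seed = 3, horizon_days = 180)
  rs2 <- run_strategies(base_params, arms = c("sdw", "dab150"), n = 300,
                        n_replicates = 8, master_seed = 3, horizon_days = 180)
  expect_identical(rs, rs2)
  sub <- rs$replicates[rs$replicates$arm == "sdw", ]
  expect_equal(rs$summary$se_cost[rs$summary$arm == "sdw"],
               stats::sd(sub$mean_cost) / sqrt(8))
  expect_equal(rs$summary$mean_cost[rs$summary$arm == "sdw"],
               mean(sub$mean_cost))
})
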