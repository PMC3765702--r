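# shared fixtures: built in code, no files

base_params <- default_parameter_set()

# parameter set with all event probabilities zeroed (closed-form world)
zero_risk_params <- apply_overrides(base_params, list(
  p_bleed_annual_inrange = 0, p_te_annual_inrange = 0))

# unit dabigatran relative risks (for common-random-numbers identities)
unit_rr_overrides <- list(rr_bleed_dab = 1, rr_te_dab.stroke_se = 1,
                          rr_te_dab.mi = 1, rr_te_dab.pe = 1,
                          rr_te_dab.dvt = 1)

# analytic per-patient discounted cost / QALY when nothing ever happens
closed_form_totals <- function(arm, params, horizon_days = NULL) {
  g <- params$globals
  H <- if (is.null(horizon_days)) g$horizon_days else horizon_days
  d <- 0:(H - 1)
  disc <- (1 + g$discount_annual)^(-d / 365)
  if (arm == "dab150") {
    drug <- params$cost_dab_daily
    mon <- 0
    day0 <- 0
    u <- params$utilities$no_event_dab
  } else {
    drug <- params$cost_warfarin_daily
    m1 <- if (arm == "sdw") params$cost_inr_month_sdw_y1 else params$cost_inr_month_gtw_y1
    mon <- ifelse(d < 365, m1, params$cost_inr_month_later) / 30
    day0 <- params$cost_lmwh_course +
      if (arm == "gtw") params$cost_genotyping else 0
    u <- params$utilities$no_event_warfarin
  }
  list(cost = day0 + sum((drug + mon) * disc),
       qaly = sum(u / 365 * disc))
}

# first event day per individual from a decoded event log (Inf if none)
first_event_days <- function(events, n) {
  out <- rep(Inf, n)
  if (nrow(events) > 0) {
    agg <- stats::aggregate(day ~ individual, data = events, FUN = min)
    out[agg$individual + 1L] <- agg$day
  }
  out
}
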