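#' Convert an annual event probability to a daily probability
#'
#' Uses the constant-hazard conversion `1 - (1 - p)^(1/365)`, the standard
#' transform for a model with daily cycles.
#'
#' @param p_annual Annual probability in \[0, 1\].
#' @return Daily probability; monotone in `p_annual`.
#' @export
#' @examples
#' annual_prob_to_daily(0.014)
annual_prob_to_daily <- function(p_annual) {
  if (any(!is.finite(p_annual)) || any(p_annual < 0) || any(p_annual > 1))
    stop("p_annual must be in [0, 1]")
  1 - (1 - p_annual)^(1 / 365)
}

#' Relative-risk-adjusted daily probability
#'
#' Applies a relative risk on the hazard (rate) scale:
#' `1 - exp(-rr * (-log(1 - p_annual)) / 365)`. This keeps the result a
#' valid probability for any `rr >= 0` and reduces to
#' [annual_prob_to_daily()] at `rr = 1`.
#'
#' @param p_annual Annual probability in \[0, 1).
#' @param rr Relative risk (>= 0).
#' @return Daily probability.
#' @export
#' @examples
#' rr_adjusted_daily_prob(0.014, 4.7)
rr_adjusted_daily_prob <- function(p_annual, rr) {
  if (any(!is.finite(p_annual)) || any(p_annual < 0) || any(p_annual >= 1))
    stop("p_annual must be in [0, 1)")
  if (any(!is.finite(rr)) || any(rr < 0)) stop("rr must be >= 0")
  1 - exp(-rr * (-log(1 - p_annual)) / 365)
}

arm_codes <- c(sdw = 1L, gtw = 2L, dab150 = 3L)

check_arm <- function(arm) {
  if (!(is.character(arm) && length(arm) == 1L && arm %in% names(arm_codes)))
    stop("arm must be one of ", paste(names(arm_codes), collapse = ", "))
  arm
}

#' INR state occupancy probabilities
#'
#' Daily probabilities of the INR being below (<2), within (2-3) or above
#' (>3) the therapeutic range for a warfarin arm in a given treatment year.
#' Year 1 under standard dosing uses the baseline TTR with the out-of-range
#' time split between below and above; year 1 under pharmacogenetic-guided
#' dosing applies the TTR uplift (relative multiplier by default, additive
#' percentage points behind `flags$additive_ttr_uplift`). From year 2 both
#' warfarin arms use the standard-dosing year-1 proportions (stable
#' maintenance dose).
#'
#' @param arm `"sdw"` or `"gtw"` (the dabigatran arm is not monitored and
#'   raises an error).
#' @param year_index Treatment year, 1-based.
#' @param params Parameter set.
#' @return Named numeric vector `c(below, in_range, above)` summing to 1.
#' @export
#' @examples
#' inr_state_probs("sdw", 1, default_parameter_set())
inr_state_probs <- function(arm, year_index, params) {
  check_arm(arm)
  if (arm == "dab150") stop("dabigatran arm is not INR-monitored")
  if (year_index < 1) stop("year_index must be >= 1")
  ttr <- params$ttr_sdw
  if (arm == "gtw" && year_index == 1) {
    ttr <- if (isTRUE(params$flags$additive_ttr_uplift))
      ttr + params$gtw_ttr_uplift
    else
      ttr * (1 + params$gtw_ttr_uplift)
    ttr <- min(max(ttr, 0), 1)
  }
  out <- 1 - ttr
  below <- out * params$frac_below_of_out_of_range
  c(below = below, in_range = ttr, above = out - below)
}

# Per-state relative risks under the default (clinically coherent) or the
# literal printed label assignment. States ordered below, in_range, above.
state_rrs <- function(params) {
  if (isTRUE(params$flags$literal_rr_labels)) {
    list(bleed = c(params$rr_bleed_out_of_range, 1, 1),
         te = c(params$rr_te_other_out_of_range, 1, params$rr_te_subtherapeutic))
  } else {
    list(bleed = c(1, 1, params$rr_bleed_out_of_range),
         te = c(params$rr_te_subtherapeutic, 1, params$rr_te_other_out_of_range))
  }
}

# ICH utilities honouring the literal_ich_utilities flag
# (printed ordering: no deficit 0.51, mild 0.75, severe 0.95)
ich_utilities <- function(params) {
  u <- params$utilities
  if (isTRUE(params$flags$literal_ich_utilities))
    c(none = u$ich_severe, mild = u$ich_mild, severe = u$ich_none)
  else
    c(none = u$ich_none, mild = u$ich_mild, severe = u$ich_severe)
}

te_subtypes <- c("stroke", "mi", "pe", "dvt")

#' Daily event hazards for a given INR state, arm and treatment status
#'
#' Warfarin arms: the major-bleed hazard is the in-range annual risk
#' converted to a daily probability and relative-risk-adjusted by INR
#' state; the thromboembolic hazard likewise, split across subtypes by the
#' fixed warfarin event-type distribution. Dabigatran (state
#' `"not_monitored"`): each hazard references the standard-warfarin
#' time-weighted average across INR states, multiplied by the
#' dabigatran-vs-warfarin relative risks (overall for bleeds,
#' subtype-specific for thromboembolism). Off treatment: the drug-related
#' bleed hazard is zero and the thromboembolic hazard equals the warfarin
#' below-range (subtherapeutic) hazard.
#'
#' @param inr_state One of `"below"`, `"in_range"`, `"above"`,
#'   `"not_monitored"`.
#' @param arm Arm name.
#' @param treatment_status `"on_treatment"`, `"off_temporary"` or
#'   `"off_permanent"`.
#' @param params Parameter set.
#' @return List with `p_bleed_daily`, `p_te_by_subtype_daily` (named, four
#'   subtypes), `p_te_total_daily`, and `lam_te_daily` (subtype hazards).
#' @export
daily_hazards <- function(inr_state, arm, treatment_status, params) {
  check_arm(arm)
  states <- c("below", "in_range", "above", "not_monitored")
  if (!(inr_state %in% states)) stop("unknown INR state: ", inr_state)
  if (arm == "dab150" && inr_state != "not_monitored")
    stop("dabigatran arm is never INR-monitored")
  if (arm != "dab150" && inr_state == "not_monitored" &&
      treatment_status == "on_treatment")
    stop("warfarin arms are always INR-monitored while on treatment")
  lam0_b <- -log(1 - params$p_bleed_annual_inrange) / 365
  lam0_t <- -log(1 - params$p_te_annual_inrange) / 365
  rrs <- state_rrs(params)
  split <- unlist(params$te_split_warfarin)[te_subtypes]
  if (treatment_status %in% c("off_temporary", "off_permanent")) {
    rr_below_te <- rrs$te[1]
    lam_te <- rr_below_te * lam0_t * split
    return(list(p_bleed_daily = 0,
                p_te_by_subtype_daily = 1 - exp(-lam_te),
                p_te_total_daily = 1 - exp(-sum(lam_te)),
                lam_te_daily = lam_te))
  }
  if (arm == "dab150") {
    w <- inr_state_probs("sdw", 1, params)
    lam_b <- params$rr_bleed_dab * (rrs$bleed * lam0_b)
    p_bleed <- sum(w * (1 - exp(-lam_b)))
    rr_dab <- unlist(params$rr_te_dab)[c("stroke_se", "mi", "pe", "dvt")]
    lam_bar <- sum(w * rrs$te) * lam0_t * split   # SD-W time-weighted subtype hazard
    lam_te <- rr_dab * lam_bar
    names(lam_te) <- te_subtypes
    return(list(p_bleed_daily = p_bleed,
                p_te_by_subtype_daily = 1 - exp(-lam_te),
                p_te_total_daily = 1 - exp(-sum(lam_te)),
                lam_te_daily = lam_te))
  }
  si <- match(inr_state, c("below", "in_range", "above"))
  lam_te <- rrs$te[si] * lam0_t * split
  list(p_bleed_daily = 1 - exp(-rrs$bleed[si] * lam0_b),
       p_te_by_subtype_daily = 1 - exp(-lam_te),
       p_te_total_daily = 1 - exp(-sum(lam_te)),
       lam_te_daily = lam_te)
}

# Normalized dabigatran bleed split (raw sums to 1.03 in the source table)
bleed_split <- function(arm, params) {
  if (arm == "dab150") {
    raw <- unlist(params$bleed_split_dab_raw)
    raw / sum(raw)
  } else {
    unlist(params$bleed_split_warfarin)
  }
}

# Normalized stroke-survivor sequela distribution (severe, mild, none).
# Printed outcome percentages sum to 111.3%; total death is kept at its
# printed 19.5% and survivor sequelae renormalized.
stroke_survivor_split <- function(params) {
  so <- params$stroke_outcomes
  v <- c(severe = so$severe, mild = so$mild, none = so$none)
  v / sum(v)
}

# Assemble the per-arm numeric tables consumed by the C++ daily-cycle engine.
build_engine_tables <- function(params, arm, horizon_days = NULL) {
  check_arm(arm)
  g <- params$globals
  H <- if (is.null(horizon_days)) g$horizon_days else horizon_days
  cuts <- function(w) c(w[1], w[1] + w[2])
  if (arm == "dab150") {
    # counterfactual INR state drawn with SD-W occupancy (shared uniform):
    # its time-average reproduces the RE-LY comparator's weighted hazard
    w1 <- inr_state_probs("sdw", 1, params)
    w2 <- inr_state_probs("sdw", 2, params)
  } else {
    w1 <- inr_state_probs(arm, 1, params)
    w2 <- inr_state_probs(arm, 2, params)
  }
  lam0_b <- -log(1 - params$p_bleed_annual_inrange) / 365
  lam0_t <- -log(1 - params$p_te_annual_inrange) / 365
  rrs <- state_rrs(params)
  split <- unlist(params$te_split_warfarin)[te_subtypes]
  if (arm == "dab150") {
    rr_dab <- unlist(params$rr_te_dab)[c("stroke_se", "mi", "pe", "dvt")]
    p_bleed_on <- 1 - exp(-params$rr_bleed_dab * rrs$bleed * lam0_b)
    lam_te_on <- t(vapply(1:3, function(s) rr_dab * rrs$te[s] * lam0_t * split,
                          numeric(4)))
  } else {
    p_bleed_on <- 1 - exp(-rrs$bleed * lam0_b)
    lam_te_on <- t(vapply(1:3, function(s) rrs$te[s] * lam0_t * split,
                          numeric(4)))
  }
  p_te_total_on <- 1 - exp(-rowSums(lam_te_on))
  lam_te_off <- rrs$te[1] * lam0_t * split
  bs <- bleed_split(arm, params)
  io <- params$ich_outcomes
  u_ich <- ich_utilities(params)
  u <- params$utilities
  ec <- params$event_costs
  drug_daily <- if (arm == "dab150") params$cost_dab_daily else params$cost_warfarin_daily
  monitor_y1 <- switch(arm, sdw = params$cost_inr_month_sdw_y1 / 30,
                       gtw = params$cost_inr_month_gtw_y1 / 30, dab150 = 0)
  monitor_later <- if (arm == "dab150") 0 else params$cost_inr_month_later / 30
  day0 <- switch(arm,
                 sdw = params$cost_lmwh_course,
                 gtw = params$cost_lmwh_course + params$cost_genotyping,
                 dab150 = 0)
  list(
    horizon = as.integer(H),
    disc_annual = g$discount_annual,
    inr_cut_y1 = cuts(w1), inr_cut_y2 = cuts(w2),
    p_bleed_on = p_bleed_on,
    p_te_total_on = p_te_total_on,
    lam_te_on = as.numeric(t(lam_te_on)),   # row-major state*4 + subtype
    p_te_total_off = 1 - exp(-sum(lam_te_off)),
    lam_te_off = as.numeric(lam_te_off),
    p_intracranial = as.numeric(bs["intracranial"]),
    ich_cum = cumsum(c(io$no_deficit, io$mild, io$severe)),
    p_death_extracranial = params$p_death_extracranial,
    stroke_death = c(params$stroke_outcomes$death_m1,
                     params$stroke_outcomes$death_m2,
                     params$stroke_outcomes$death_m3),
    stroke_seq_cum = cumsum(stroke_survivor_split(params)[c("severe", "mild")]),
    p_death_pe = params$p_death_pe,
    p_death_dvt = params$p_death_dvt,
    p_death_mi = params$p_death_mi,
    gi_off_days = as.integer(params$stop_after_gi_bleed_days),
    drug_daily = drug_daily,
    monitor_y1 = monitor_y1,
    monitor_later = monitor_later,
    day0_cost = day0,
    cost_ich = c(ec$ich_none, ec$ich_mild, ec$ich_severe, ec$ich_severe),
    cost_extracranial = ec$extracranial_bleed,
    cost_stroke = c(ec$stroke_none, ec$stroke_mild, ec$stroke_severe,
                    ec$stroke_severe),
    cost_mi = ec$mi, cost_pe = ec$pe, cost_dvt = ec$dvt,
    post_daily = c(0, params$post_event_monthly$mild / 30,
                   params$post_event_monthly$severe / 30),
    u_base = if (arm == "dab150") u$no_event_dab else u$no_event_warfarin,
    u_ich = as.numeric(u_ich),
    u_extracranial = u$extracranial,
    u_stroke = c(u$stroke_none, u$stroke_mild, u$stroke_severe),
    u_mi = u$mi, u_pe = u$pe, u_dvt = u$dvt
  )
}
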