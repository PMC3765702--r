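#' Simulate one individual's trajectory
#'
#' Runs the daily-cycle engine for a single virtual patient: each day an
#' INR state is drawn (warfarin arms; the dabigatran arm draws a
#' counterfactual standard-warfarin state so that its hazard averages to
#' the trial comparator), at most one major event may occur (bleed tested
#' first, thromboembolism conditional on no bleed), events are resolved
#' into subtype, outcome, sequela and possible death, treatment status and
#' costs/utilities are updated, and discounted cost and QALY accrue.
#'
#' @param individual A one-row data.frame with `id` (and `age_years`), or a
#'   bare integer id.
#' @param arm `"sdw"`, `"gtw"` or `"dab150"`.
#' @param params Parameter set.
#' @param master_seed,replicate_id Stream coordinates (must match the
#'   cohort the individual came from for common random numbers).
#' @param horizon_days Optional override of `params$globals$horizon_days`.
#' @return Object of class `afcua_trajectory`: list with `individual_id`,
#'   `events` (data.frame), `person_days`, `discounted_cost`,
#'   `discounted_qalys`, `alive_at_end`.
#' @export
simulate_individual <- function(individual, arm, params,
                                master_seed, replicate_id = 0,
                                horizon_days = NULL) {
  check_arm(arm)
  id <- if (is.data.frame(individual)) individual$id[1] else as.integer(individual)
  tb <- build_engine_tables(params, arm, horizon_days)
  res <- cpp_run_arm_ids(ids = id, arm_tag = arm_codes[[arm]],
                         master_seed = master_seed,
                         replicate_id = replicate_id, tb = tb)
  ev <- as.data.frame(res$events)
  structure(list(individual_id = id,
                 events = decode_events(ev),
                 person_days = res$person_days[1],
                 discounted_cost = res$cost[1],
                 discounted_qalys = res$qaly[1],
                 alive_at_end = res$alive[1]),
            class = "afcua_trajectory")
}

# run the C++ engine for arbitrary individual ids (the engine itself loops
# 0..n-1, so offset single-id runs through a 1-individual shim)
cpp_run_arm_ids <- function(ids, arm_tag, master_seed, replicate_id, tb) {
  if (length(ids) == 1L && ids == 0L) {
    return(cpp_run_arm(1L, arm_tag, master_seed, replicate_id, tb, TRUE))
  }
  # ids must be 0..n-1 for the vectorized path
  if (identical(as.integer(ids), seq_along(ids) - 1L)) {
    return(cpp_run_arm(length(ids), arm_tag, master_seed, replicate_id, tb, TRUE))
  }
  # arbitrary single id: simulate id+1 individuals, keep the last
  stopifnot(length(ids) == 1L)
  res <- cpp_run_arm(as.integer(ids) + 1L, arm_tag, master_seed,
                     replicate_id, tb, TRUE)
  keep <- as.integer(ids) + 1L
  ev <- as.data.frame(res$events)
  ev <- ev[ev$individual == ids, , drop = FALSE]
  list(cost = res$cost[keep], qaly = res$qaly[keep],
       person_days = res$person_days[keep], n_bleed = res$n_bleed[keep],
       n_te = res$n_te[keep], alive = res$alive[keep], events = ev)
}

subtype_labels <- c("ich", "extracranial_gi", "stroke", "mi", "pe", "dvt")
sequela_labels <- c("none", "mild", "severe", "not_applicable")

decode_events <- function(ev) {
  ev <- as.data.frame(ev)
  if (nrow(ev) == 0) {
    return(data.frame(individual = integer(), day = integer(),
                      category = character(), subtype = character(),
                      fatal = logical(), death_day = integer(),
                      sequela = character()))
  }
  data.frame(individual = ev$individual, day = ev$day,
             category = c("bleed", "thromboembolic")[ev$category],
             subtype = subtype_labels[ev$subtype],
             fatal = ev$fatal == 1,
             death_day = ifelse(ev$death_day < 0, NA_integer_, ev$death_day),
             sequela = sequela_labels[ev$sequela + 1L])
}

#' Simulate a whole cohort under one arm
#'
#' @param cohort An `afcua_cohort` from [generate_cohort()].
#' @param arm Arm name.
#' @param params Parameter set.
#' @param horizon_days Optional horizon override.
#' @param collect_events Keep the per-event log (default `TRUE`).
#' @return List with `per_individual` (data.frame: id, cost, qaly,
#'   person_days, n_bleed, n_te, alive), `events` (decoded data.frame), and
#'   `summary` (one-row data.frame of means and event rates).
#' @export
run_arm <- function(cohort, arm, params, horizon_days = NULL,
                    collect_events = TRUE) {
  check_arm(arm)
  stopifnot(inherits(cohort, "afcua_cohort"))
  n <- nrow(cohort$individuals)
  tb <- build_engine_tables(params, arm, horizon_days)
  res <- cpp_run_arm(n, arm_codes[[arm]], cohort$master_seed,
                     cohort$replicate_id, tb, collect_events)
  per <- data.frame(id = cohort$individuals$id, cost = res$cost,
                    qaly = res$qaly, person_days = res$person_days,
                    n_bleed = res$n_bleed, n_te = res$n_te,
                    alive = res$alive)
  pd <- sum(as.numeric(per$person_days))
  summ <- data.frame(
    arm = arm,
    mean_cost = mean(per$cost),
    mean_qaly = mean(per$qaly),
    bleeds_per_100py = events_per_100py(sum(per$n_bleed), pd),
    te_per_100py = events_per_100py(sum(per$n_te), pd),
    person_years = pd / 365,
    n_individuals = n)
  list(per_individual = per,
       events = if (collect_events) decode_events(res$events) else NULL,
       summary = summ)
}

#' Events per 100 person-years
#'
#' @param total_events Event count.
#' @param total_person_days Person-time denominator in days (> 0).
#' @return Rate per 100 person-years.
#' @export
#' @examples
#' events_per_100py(321, 3650000)  # 10,000 person-years -> 3.21
events_per_100py <- function(total_events, total_person_days) {
  if (total_person_days <= 0) stop("person-time must be > 0")
  total_events / (total_person_days / 365) * 100
}

#' Run all requested arms over replicated cohorts
#'
#' Each replicate generates a fresh virtual population which is reused by
#' every arm (the shared-population, common-random-numbers design); event
#' streams are likewise shared across arms so that between-arm differences
#' reflect the interventions, not sampling noise.
#'
#' @param params Parameter set.
#' @param arms Character vector of arms (default all three).
#' @param n Individuals per replicate (default
#'   `params$globals$cohort_size`).
#' @param n_replicates Number of replicate populations (default 1; the
#'   full design uses `params$globals$n_replicates`).
#' @param master_seed Master seed.
#' @param horizon_days Optional horizon override.
#' @return List with `summary` (one row per arm: means, Monte-Carlo
#'   standard errors, event rates) and `replicates` (one row per
#'   replicate x arm).
#' @export
run_strategies <- function(params, arms = c("sdw", "gtw", "dab150"),
                           n = NULL, n_replicates = 1, master_seed = 1,
                           horizon_days = NULL) {
  for (a in arms) check_arm(a)
  g <- params$globals
  if (is.null(n)) n <- g$cohort_size
  reps <- vector("list", n_replicates * length(arms))
  k <- 0L
  for (r in seq_len(n_replicates)) {
    cohort <- generate_cohort(n, replicate_id = r, master_seed = master_seed,
                              age_mean = g$age_mean, age_sd = g$age_sd)
    for (a in arms) {
      out <- run_arm(cohort, a, params, horizon_days, collect_events = FALSE)
      k <- k + 1L
      reps[[k]] <- cbind(replicate = r, out$summary,
                         total_bleeds = sum(out$per_individual$n_bleed),
                         total_te = sum(out$per_individual$n_te),
                         sd_cost = stats::sd(out$per_individual$cost),
                         sd_qaly = stats::sd(out$per_individual$qaly))
    }
  }
  repdf <- do.call(rbind, reps)
  summ <- do.call(rbind, lapply(arms, function(a) {
    sub <- repdf[repdf$arm == a, , drop = FALSE]
    pdays <- sum(sub$person_years) * 365
    if (n_replicates > 1) {
      se_cost <- stats::sd(sub$mean_cost) / sqrt(n_replicates)
      se_qaly <- stats::sd(sub$mean_qaly) / sqrt(n_replicates)
    } else {
      se_cost <- sub$sd_cost / sqrt(sub$n_individuals)
      se_qaly <- sub$sd_qaly / sqrt(sub$n_individuals)
    }
    data.frame(arm = a,
               mean_cost = mean(sub$mean_cost),
               mean_qaly = mean(sub$mean_qaly),
               se_cost = se_cost, se_qaly = se_qaly,
               bleeds_per_100py = events_per_100py(sum(sub$total_bleeds), pdays),
               te_per_100py = events_per_100py(sum(sub$total_te), pdays),
               n_individuals = n * n_replicates,
               n_replicates = n_replicates)
  }))
  rownames(summ) <- NULL
  list(summary = summ, replicates = repdf)
}

#' Resolve a major bleeding event
#'
#' Draws the bleed subtype from the arm's (normalized) intracranial /
#' extracranial split; intracranial events follow the outcome tree
#' (no deficit 8%, mild 16%, severe 34%, death in the first month 42%),
#' extracranial (gastrointestinal) events are fatal with probability 2%.
#' Fatal events get a death day uniform within 30 days of the event.
#'
#' @param arm Arm name.
#' @param stream An `afcua_stream` descriptor locating the individual's
#'   random substream (its purpose field is ignored; sibling purposes are
#'   derived).
#' @param params Parameter set.
#' @param day Event day (default 0).
#' @param n Number of draws (vectorized; successive draws use successive
#'   stream counters).
#' @return A data.frame of event records: `day`, `category`, `subtype`,
#'   `fatal`, `death_day`, `sequela`.
#' @export
resolve_bleed <- function(arm, stream, params, day = 0, n = 1) {
  check_arm(arm)
  stopifnot(inherits(stream, "afcua_stream"))
  u_at <- function(purpose) {
    cpp_stream_uniform(stream$master_seed, stream$replicate_id,
                       stream$individual_id, stream$arm_tag,
                       PURPOSES[[purpose]], day, seq_len(n) - 1)
  }
  us <- u_at("bleed_subtype")
  uo <- u_at("bleed_outcome")
  ud <- u_at("death_day")
  bs <- bleed_split(arm, params)
  ich <- us < bs[["intracranial"]]
  io <- params$ich_outcomes
  cum <- cumsum(c(io$no_deficit, io$mild, io$severe))
  oc <- findInterval(uo, cum)  # 0 none, 1 mild, 2 severe, 3 death
  fatal <- ifelse(ich, oc == 3L, uo < params$p_death_extracranial)
  sequela <- ifelse(fatal, "not_applicable",
                    ifelse(!ich, "none",
                           c("none", "mild", "severe")[pmin(oc, 2L) + 1L]))
  data.frame(day = day,
             category = "bleed",
             subtype = ifelse(ich, "ich", "extracranial_gi"),
             fatal = fatal,
             death_day = ifelse(fatal, day + 1L + floor(ud * 30), NA_integer_),
             sequela = sequela)
}

#' Resolve a major thromboembolic event
#'
#' Strokes die in months 1-3 with probabilities 8.3%/5.6%/5.6% (death day
#' uniform within the corresponding month); survivors draw a sequela from
#' the renormalized (severe, mild, none) distribution. MI, PE and DVT are
#' fatal with probabilities 7%, 12% and 6% and leave no lasting sequela.
#'
#' @param subtype `"stroke"`, `"mi"`, `"pe"` or `"dvt"`.
#' @inheritParams resolve_bleed
#' @return A data.frame of event records as in [resolve_bleed()].
#' @export
resolve_te <- function(subtype, stream, params, day = 0, n = 1) {
  if (!(subtype %in% te_subtypes)) stop("unknown TE subtype: ", subtype)
  stopifnot(inherits(stream, "afcua_stream"))
  u_at <- function(purpose) {
    cpp_stream_uniform(stream$master_seed, stream$replicate_id,
                       stream$individual_id, stream$arm_tag,
                       PURPOSES[[purpose]], day, seq_len(n) - 1)
  }
  uo <- u_at("te_outcome")
  ud <- u_at("death_day")
  if (subtype == "stroke") {
    sd3 <- c(params$stroke_outcomes$death_m1, params$stroke_outcomes$death_m2,
             params$stroke_outcomes$death_m3)
    pd <- sum(sd3)
    fatal <- uo < pd
    month <- findInterval(uo, cumsum(sd3)[1:2])  # 0, 1, 2
    death_day <- day + 1L + month * 30L + floor(ud * 30)
    v <- (uo - pd) / (1 - pd)
    sq <- stroke_survivor_split(params)
    cumseq <- cumsum(sq[c("severe", "mild")])
    sequela <- ifelse(fatal, "not_applicable",
                      ifelse(v < cumseq[1], "severe",
                             ifelse(v < cumseq[2], "mild", "none")))
  } else {
    pfat <- switch(subtype, mi = params$p_death_mi, pe = params$p_death_pe,
                   dvt = params$p_death_dvt)
    fatal <- uo < pfat
    death_day <- day + 1L + floor(ud * 30)
    sequela <- ifelse(fatal, "not_applicable", "none")
  }
  data.frame(day = day, category = "thromboembolic", subtype = subtype,
             fatal = fatal,
             death_day = ifelse(fatal, death_day, NA_integer_),
             sequela = sequela)
}

#' Update treatment status after an event
#'
#' Intracranial hemorrhage (including subdural) causes permanent
#' anticoagulant cessation; a gastrointestinal bleed a 30-day cessation;
#' any other event leaves the status unchanged. `off_permanent` is
#' absorbing. The temporary state counts down daily via
#' [tick_treatment_status()].
#'
#' @param status A status list from [treatment_status()].
#' @param event Event subtype (`"ich"`, `"subdural"`, `"extracranial_gi"`,
#'   `"stroke"`, `"mi"`, `"pe"`, `"dvt"`) or `"none"`.
#' @param params Parameter set (supplies the cessation length).
#' @return Updated status list.
#' @export
update_treatment_status <- function(status, event, params) {
  if (status$state == "off_permanent") return(status)
  if (event %in% c("ich", "subdural")) return(treatment_status("off_permanent"))
  if (event == "extracranial_gi")
    return(treatment_status("off_temporary",
                            days_remaining = params$stop_after_gi_bleed_days))
  status
}

#' @rdname update_treatment_status
#' @param state One of `"on_treatment"`, `"off_temporary"`,
#'   `"off_permanent"`.
#' @param days_remaining Days left off treatment (`off_temporary` only;
#'   must be positive).
#' @export
treatment_status <- function(state = "on_treatment", days_remaining = NULL) {
  if (!(state %in% c("on_treatment", "off_temporary", "off_permanent")))
    stop("unknown treatment state: ", state)
  if (state == "off_temporary") {
    if (is.null(days_remaining) || days_remaining <= 0)
      stop("off_temporary requires days_remaining > 0")
    return(list(state = state, days_remaining = as.integer(days_remaining)))
  }
  list(state = state, days_remaining = NULL)
}

#' @rdname update_treatment_status
#' @export
tick_treatment_status <- function(status) {
  if (status$state != "off_temporary") return(status)
  d <- status$days_remaining - 1L
  if (d <= 0L) treatment_status("on_treatment")
  else treatment_status("off_temporary", d)
}

#' Daily cost and utility accrual
#'
#' Computes one day's cost, utility, and their discounted contributions:
#' daily drug cost while on treatment, INR-monitoring cost spread as
#' monthly cost / 30 (warfarin arms; first-year rates differ by arm),
#' post-event monthly cost / 30 for an active mild or severe sequela,
#' one-time day-0 items (genotyping for the pharmacogenetic arm, a 5-day
#' low-molecular-weight-heparin bridging course for the warfarin arms), and
#' the current health-state utility. Both channels are discounted by
#' `(1 + discount_annual)^(-day/365)`; the QALY increment is
#' `utility/365 * discount`.
#'
#' @param day Day index (0-based).
#' @param arm Arm name.
#' @param health_status List with `utility` (current health-state utility)
#'   and optional `sequela` (`"none"`, `"mild"`, `"severe"`) and
#'   `sequela_active` (logical: 30 days have elapsed since the causing
#'   event).
#' @param treatment_status Status list from [treatment_status()].
#' @param year_index Treatment year (1-based).
#' @param params Parameter set.
#' @return List with `cost_today`, `utility_today`,
#'   `discounted_cost`, `discounted_qaly_increment`.
#' @export
accrue_day <- function(day, arm, health_status, treatment_status, year_index,
                       params) {
  check_arm(arm)
  on <- treatment_status$state == "on_treatment"
  cost <- 0
  if (day == 0) {
    if (arm != "dab150") cost <- cost + params$cost_lmwh_course
    if (arm == "gtw") cost <- cost + params$cost_genotyping
  }
  if (on) {
    cost <- cost + if (arm == "dab150") params$cost_dab_daily else params$cost_warfarin_daily
    if (arm != "dab150") {
      monthly <- if (year_index == 1) {
        if (arm == "sdw") params$cost_inr_month_sdw_y1 else params$cost_inr_month_gtw_y1
      } else params$cost_inr_month_later
      cost <- cost + monthly / 30
    }
  }
  seq_lab <- health_status$sequela
  if (!is.null(seq_lab) && isTRUE(health_status$sequela_active) &&
      seq_lab %in% c("mild", "severe")) {
    cost <- cost + params$post_event_monthly[[seq_lab]] / 30
  }
  u <- health_status$utility
  disc <- (1 + params$globals$discount_annual)^(-day / 365)
  list(cost_today = cost, utility_today = u,
       discounted_cost = cost * disc,
       discounted_qaly_increment = u / 365 * disc)
}
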