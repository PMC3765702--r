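#' One-way sensitivity scenario definitions
#'
#' The shipped scenario set varies one parameter at a time: the
#' pharmacogenetic arm's first-year TTR raised to 76.8% (a 20% relative
#' uplift), the dabigatran bleeding relative risk at both ends of its
#' interval (0.81, 1.07), the dabigatran stroke relative risk at both ends
#' (0.53, 0.82), genotyping cost at $100 and $1000, dabigatran day cost at
#' $1 and $5, and dabigatran no-event utility at 0.98. Each scenario is
#' also shipped as a JSON fixture under `inst/extdata/scenarios/`.
#'
#' @return Named list mapping scenario name to an override list (dotted
#'   field paths, see [apply_overrides()]).
#' @export
table_scenarios <- function() {
  list(
    ttr_gtw_768 = list(gtw_ttr_uplift = 0.20),
    rr_bleed_dab_081 = list(rr_bleed_dab = 0.81),
    rr_bleed_dab_107 = list(rr_bleed_dab = 1.07),
    rr_stroke_dab_082 = list(rr_te_dab.stroke_se = 0.82),
    rr_stroke_dab_053 = list(rr_te_dab.stroke_se = 0.53),
    cost_genotyping_100 = list(cost_genotyping = 100),
    cost_genotyping_1000 = list(cost_genotyping = 1000),
    cost_dab_daily_1 = list(cost_dab_daily = 1),
    cost_dab_daily_5 = list(cost_dab_daily = 5),
    utility_dab_098 = list(utilities.no_event_dab = 0.98)
  )
}

#' Run one-way sensitivity scenarios
#'
#' Applies each scenario's overrides and re-runs all three arms on the
#' identical cohorts and event streams as the base case (common random
#' numbers), so scenario deltas reflect the parameter change only. Each
#' scenario's results are summarized through the dominance frontier.
#'
#' @param base_params Baseline parameter set.
#' @param scenarios Named list of override lists (see [table_scenarios()]);
#'   an empty list yields an empty table.
#' @param sim_config List with `n` (individuals per replicate),
#'   `n_replicates`, `master_seed`, and optional `horizon_days`.
#' @return Data.frame with one row per scenario x arm: `scenario`, `arm`,
#'   `mean_cost`, `mean_qaly`, `status`, `comparator`, `delta_cost`,
#'   `delta_qaly`, `icur`.
#' @export
run_one_way <- function(base_params, scenarios,
                        sim_config = list(n = 2000, n_replicates = 1,
                                          master_seed = 1)) {
  stopifnot(is.list(scenarios))
  cols <- c("scenario", "arm", "mean_cost", "mean_qaly", "status",
            "comparator", "delta_cost", "delta_qaly", "icur")
  if (length(scenarios) == 0) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
    return(out)
  }
  if (is.null(names(scenarios)) || any(names(scenarios) == ""))
    stop("scenarios must be a named list")
  rows <- lapply(names(scenarios), function(nm) {
    p <- tryCatch(apply_overrides(base_params, scenarios[[nm]]),
                  error = function(e) stop("scenario '", nm, "': ",
                                           conditionMessage(e), call. = FALSE))
    rs <- run_strategies(p, n = sim_config$n,
                         n_replicates = sim_config$n_replicates,
                         master_seed = sim_config$master_seed,
                         horizon_days = sim_config$horizon_days)
    fr <- dominance_frontier(rs$summary)
    cbind(scenario = nm, as.data.frame(fr)[, c("arm", "mean_cost", "mean_qaly",
                                               "status", "comparator",
                                               "delta_cost", "delta_qaly",
                                               "icur")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Probabilistic sensitivity analysis
#'
#' Per iteration: draw a parameter set from the fitted distributions,
#' generate a fresh virtual population shared by the three arms, simulate,
#' and record per-arm mean cost and QALYs. Fully reproducible from
#' `master_seed`.
#'
#' @param base_params Baseline parameter set (distributions are fitted
#'   from [psa_registry()] ranges).
#' @param n_individuals Population size per iteration (the reference
#'   analysis uses `globals$psa_cohort_size` = 5000).
#' @param n_iterations Number of Monte Carlo iterations (reference: 1000).
#' @param master_seed Master seed.
#' @param arms Arms to simulate.
#' @param horizon_days Optional horizon override.
#' @return Data.frame with one row per iteration x arm: `iteration`,
#'   `arm`, `mean_cost`, `mean_qaly`.
#' @export
run_psa <- function(base_params, n_individuals, n_iterations, master_seed,
                    arms = c("sdw", "gtw", "dab150"), horizon_days = NULL) {
  stopifnot(n_individuals >= 1, n_iterations >= 1)
  fits <- fit_psa_distributions(base_params)
  g <- base_params$globals
  rows <- vector("list", n_iterations * length(arms))
  k <- 0L
  for (it in seq_len(n_iterations)) {
    draw_seed <- (master_seed + 715827881 * it) %% 2147483647
    p <- sample_psa_draw(base_params, draw_seed, fits)
    cohort <- generate_cohort(n_individuals, replicate_id = it,
                              master_seed = master_seed,
                              age_mean = g$age_mean, age_sd = g$age_sd)
    for (a in arms) {
      res <- run_arm(cohort, a, p, horizon_days, collect_events = FALSE)
      k <- k + 1L
      rows[[k]] <- data.frame(iteration = it, arm = a,
                              mean_cost = res$summary$mean_cost,
                              mean_qaly = res$summary$mean_qaly)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Threshold search: first-year TTR at which guided dosing is cost-effective
#'
#' Bisects the pharmacogenetic arm's first-year time-in-therapeutic-range
#' until its incremental cost-utility ratio against standard dosing
#' crosses the willingness-to-pay threshold. All bisection steps reuse
#' the same master seed (shared cohorts and event streams), so the
#' response is a deterministic, monotone function of TTR and Monte-Carlo
#' noise does not destabilize the bracket.
#'
#' @param base_params Baseline parameter set.
#' @param wtp_threshold Willingness-to-pay per QALY (default
#'   `globals$wtp_threshold`); `Inf` accepts the baseline immediately.
#' @param sim_config As in [run_one_way()].
#' @param tol Bracket tolerance on the TTR fraction (default 0.005).
#' @param upper Upper search bound for the TTR (default 0.95).
#' @param evaluator Optional function `ttr -> ICUR` replacing the built-in
#'   simulation-backed response (used for testing against a constructed
#'   monotone response).
#' @return List with `ttr` (threshold TTR fraction), `icur` (at `ttr`),
#'   `converged`, `bracket` (final `c(lo, hi)`), and `evaluations`.
#'   If the ICUR never crosses the threshold on the bracket,
#'   `converged = FALSE` and `ttr = NA` (no-threshold signal).
#' @export
find_ttr_threshold <- function(base_params, wtp_threshold = NULL,
                               sim_config = list(n = 2000, n_replicates = 1,
                                                 master_seed = 1),
                               tol = 0.005, upper = 0.95, evaluator = NULL) {
  if (is.null(wtp_threshold)) wtp_threshold <- base_params$globals$wtp_threshold
  base_ttr <- inr_state_probs("gtw", 1, base_params)[["in_range"]]
  if (is.infinite(wtp_threshold)) {
    return(list(ttr = base_ttr, icur = NA_real_, converged = TRUE,
                bracket = c(base_ttr, base_ttr), evaluations = 0L))
  }
  if (is.null(evaluator)) {
    # shared-stream ICUR of GT-W vs SD-W as a function of year-1 TTR
    sdw <- run_strategies(base_params, arms = "sdw", n = sim_config$n,
                          n_replicates = sim_config$n_replicates,
                          master_seed = sim_config$master_seed,
                          horizon_days = sim_config$horizon_days)$summary
    evaluator <- function(ttr) {
      uplift <- if (isTRUE(base_params$flags$additive_ttr_uplift))
        ttr - base_params$ttr_sdw else ttr / base_params$ttr_sdw - 1
      p <- apply_overrides(base_params, list(gtw_ttr_uplift = uplift))
      gtw <- run_strategies(p, arms = "gtw", n = sim_config$n,
                            n_replicates = sim_config$n_replicates,
                            master_seed = sim_config$master_seed,
                            horizon_days = sim_config$horizon_days)$summary
      icur(sdw$mean_cost, sdw$mean_qaly, gtw$mean_cost, gtw$mean_qaly,
           rounded = FALSE)
    }
  }
  nev <- 0L
  f <- function(t) { nev <<- nev + 1L; evaluator(t) }
  lo <- base_ttr
  hi <- upper
  f_lo <- f(lo)
  if (!is.na(f_lo) && f_lo <= wtp_threshold) {
    return(list(ttr = lo, icur = f_lo, converged = TRUE, bracket = c(lo, lo),
                evaluations = nev))
  }
  f_hi <- f(hi)
  if (is.na(f_hi) || f_hi > wtp_threshold) {
    return(list(ttr = NA_real_, icur = f_hi, converged = FALSE,
                bracket = c(lo, hi), evaluations = nev))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    if (!is.na(f_mid) && f_mid <= wtp_threshold) {
      hi <- mid
      f_hi <- f_mid
    } else {
      lo <- mid
    }
  }
  list(ttr = hi, icur = f_hi, converged = TRUE, bracket = c(lo, hi),
       evaluations = nev)
}
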