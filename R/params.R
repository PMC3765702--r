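#' Default model parameter set
#'
#' Returns the complete baseline parameter set of the anticoagulation
#' cost-utility model: INR time-in-range occupancy, annual event
#' probabilities and relative risks, event-type splits, outcome trees,
#' unit costs (2010-2011 CAD$), health-state utilities, and global
#' simulation settings (5-year horizon in daily cycles, 3% annual
#' discounting, willingness-to-pay threshold of $50,000/QALY).
#'
#' Three model arms are supported: `"sdw"` (standard warfarin dosing),
#' `"gtw"` (pharmacogenetic-guided warfarin dosing, CYP2C9/VKORC1) and
#' `"dab150"` (dabigatran 150 mg twice daily, no INR monitoring).
#'
#' Two printed-source inconsistencies are resolved by default and can be
#' restored via `flags`:
#' * `literal_rr_labels`: by default the bleeding relative risk 4.7 applies
#'   to the above-range INR state and the thromboembolic RR 3.5 to the
#'   below-range state (the clinically coherent assignment); the flag
#'   applies them as literally labelled in the source table.
#' * `literal_ich_utilities`: by default intracranial-hemorrhage utilities
#'   are ordered no-deficit 0.95 / mild 0.75 / severe 0.51, mirroring the
#'   stroke block; the flag restores the printed (inverted) ordering.
#' * `additive_ttr_uplift`: by default the pharmacogenetic TTR uplift of
#'   7.3% is a relative multiplier (0.64 * 1.073); the flag adds 7.3
#'   percentage points instead.
#'
#' @return A named list of class `afcua_params`. See
#'   [validate_params()] for the invariants enforced.
#' @export
#' @examples
#' p <- default_parameter_set()
#' p$cost_genotyping
#' sum(unlist(p$te_split_warfarin))
default_parameter_set <- function() {
  p <- list(
    # INR control
    ttr_sdw = 0.64,
    frac_below_of_out_of_range = 0.54,
    gtw_ttr_uplift = 0.073,
    # major bleeding
    p_bleed_annual_inrange = 0.014,
    rr_bleed_out_of_range = 4.7,
    rr_bleed_dab = 0.93,
    bleed_split_warfarin = list(intracranial = 0.42, extracranial = 0.58),
    bleed_split_dab_raw = list(intracranial = 0.126, extracranial = 0.904),
    # major thromboembolism
    p_te_annual_inrange = 0.024,
    rr_te_subtherapeutic = 3.5,
    rr_te_other_out_of_range = 0.9,
    rr_te_dab = list(stroke_se = 0.66, mi = 1.38, pe = 1.61, dvt = 1.0),
    te_split_warfarin = list(stroke = 0.525, mi = 0.125, pe = 0.30, dvt = 0.05),
    # event outcome trees
    ich_outcomes = list(no_deficit = 0.08, mild = 0.16, severe = 0.34,
                        death_first_month = 0.42),
    p_death_extracranial = 0.02,
    stroke_outcomes = list(death_m1 = 0.083, death_m2 = 0.056, death_m3 = 0.056,
                           severe = 0.402, mild = 0.425, none = 0.091),
    p_death_pe = 0.12,
    p_death_dvt = 0.06,
    p_death_mi = 0.07,
    # discontinuation rules (intracranial cessation is permanent)
    stop_after_gi_bleed_days = 30,
    # costs, CAD$
    cost_dab_daily = 3.20,
    cost_warfarin_daily = 0.074,
    cost_lmwh_course = 27.90,
    cost_inr_month_sdw_y1 = 8.06,
    cost_inr_month_gtw_y1 = 5.00,
    cost_inr_month_later = 4.03,
    cost_genotyping = 615,
    event_costs = list(stroke_none = 845, stroke_mild = 23772,
                       stroke_severe = 42620, ich_none = 1067,
                       ich_mild = 21218, ich_severe = 36451,
                       subdural = 31942, extracranial_bleed = 8146,
                       dvt = 2576, pe = 8799, mi = 7177),
    post_event_monthly = list(severe = 6259, mild = 1855),
    # health-state utilities
    utilities = list(no_event_warfarin = 0.95, no_event_dab = 0.95,
                     ich_none = 0.95, ich_mild = 0.75, ich_severe = 0.51,
                     extracranial = 0.80,
                     stroke_none = 0.95, stroke_mild = 0.75,
                     stroke_severe = 0.39,
                     mi = 0.84, pe = 0.76, dvt = 0.84),
    globals = list(horizon_days = 1825, discount_annual = 0.03,
                   cohort_size = 10000, n_replicates = 1000,
                   psa_cohort_size = 5000, psa_iterations = 1000,
                   wtp_threshold = 50000, age_mean = 64, age_sd = 8),
    flags = list(literal_rr_labels = FALSE, literal_ich_utilities = FALSE,
                 additive_ttr_uplift = FALSE, background_mortality = FALSE)
  )
  class(p) <- "afcua_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks every invariant of the model inputs: probabilities and utilities
#' in \[0, 1\], non-negative costs, the warfarin thromboembolic-event split
#' summing to 1, the intracranial-hemorrhage outcome tree summing to 1,
#' the (raw) dabigatran bleed split normalizable, and positive global
#' settings. Called on construction, after overrides, and on load.
#'
#' @param p A parameter set (named list as from [default_parameter_set()]).
#' @param tol Numeric tolerance for split sums (default `1e-9`).
#' @return `p`, invisibly, if valid; otherwise an error naming the first
#'   offending field.
#' @export
validate_params <- function(p, tol = 1e-9) {
  required <- names(default_parameter_fields())
  missing <- setdiff(required, names(p))
  if (length(missing) > 0L) {
    stop("parameter set is missing field(s): ", paste(missing, collapse = ", "))
  }
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop("field '", nm, "' must be a probability in [0,1], got ", format(x))
  }
  chk_pos <- function(x, nm, strict = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || (strict && x <= 0))
      stop("field '", nm, "' must be ", if (strict) "positive" else "non-negative",
           ", got ", format(x))
  }
  for (nm in c("ttr_sdw", "frac_below_of_out_of_range", "gtw_ttr_uplift",
               "p_bleed_annual_inrange", "p_te_annual_inrange",
               "p_death_extracranial", "p_death_pe", "p_death_dvt",
               "p_death_mi")) {
    chk_prob(p[[nm]], nm)
  }
  for (nm in c("rr_bleed_out_of_range", "rr_bleed_dab", "rr_te_subtherapeutic",
               "rr_te_other_out_of_range")) {
    chk_pos(p[[nm]], nm)
  }
  for (nm in names(p$rr_te_dab)) chk_pos(p$rr_te_dab[[nm]], paste0("rr_te_dab.", nm))
  for (nm in names(p$event_costs)) chk_pos(p$event_costs[[nm]], paste0("event_costs.", nm))
  for (nm in names(p$post_event_monthly)) {
    chk_pos(p$post_event_monthly[[nm]], paste0("post_event_monthly.", nm))
  }
  for (nm in c("cost_dab_daily", "cost_warfarin_daily", "cost_lmwh_course",
               "cost_inr_month_sdw_y1", "cost_inr_month_gtw_y1",
               "cost_inr_month_later", "cost_genotyping")) {
    chk_pos(p[[nm]], nm)
  }
  for (nm in names(p$utilities)) chk_prob(p$utilities[[nm]], paste0("utilities.", nm))
  for (nm in names(p$ich_outcomes)) chk_prob(p$ich_outcomes[[nm]], paste0("ich_outcomes.", nm))
  for (nm in names(p$stroke_outcomes)) {
    chk_prob(p$stroke_outcomes[[nm]], paste0("stroke_outcomes.", nm))
  }
  for (nm in names(p$te_split_warfarin)) {
    chk_prob(p$te_split_warfarin[[nm]], paste0("te_split_warfarin.", nm))
  }
  if (abs(sum(unlist(p$te_split_warfarin)) - 1) > tol)
    stop("te_split_warfarin must sum to 1")
  if (abs(sum(unlist(p$ich_outcomes)) - 1) > tol)
    stop("ich_outcomes must sum to 1")
  if (abs(sum(unlist(p$bleed_split_warfarin)) - 1) > tol)
    stop("bleed_split_warfarin must sum to 1")
  raw <- sum(unlist(p$bleed_split_dab_raw))
  if (raw <= 0) stop("bleed_split_dab_raw must have positive mass")
  sdeath <- p$stroke_outcomes$death_m1 + p$stroke_outcomes$death_m2 +
    p$stroke_outcomes$death_m3
  if (sdeath >= 1) stop("stroke_outcomes death probabilities must sum to < 1")
  g <- p$globals
  if (g$horizon_days < 1) stop("globals.horizon_days must be >= 1")
  if (g$discount_annual < 0) stop("globals.discount_annual must be >= 0")
  if (g$cohort_size < 1) stop("globals.cohort_size must be >= 1")
  if (g$age_sd < 0) stop("globals.age_sd must be >= 0")
  if (p$stop_after_gi_bleed_days < 0) stop("stop_after_gi_bleed_days must be >= 0")
  invisible(p)
}

# canonical field skeleton (names only), used for completeness checks
default_parameter_fields <- function() {
  list(ttr_sdw = NA, frac_below_of_out_of_range = NA, gtw_ttr_uplift = NA,
       p_bleed_annual_inrange = NA, rr_bleed_out_of_range = NA,
       rr_bleed_dab = NA, bleed_split_warfarin = NA, bleed_split_dab_raw = NA,
       p_te_annual_inrange = NA, rr_te_subtherapeutic = NA,
       rr_te_other_out_of_range = NA, rr_te_dab = NA, te_split_warfarin = NA,
       ich_outcomes = NA, p_death_extracranial = NA, stroke_outcomes = NA,
       p_death_pe = NA, p_death_dvt = NA, p_death_mi = NA,
       stop_after_gi_bleed_days = NA, cost_dab_daily = NA,
       cost_warfarin_daily = NA, cost_lmwh_course = NA,
       cost_inr_month_sdw_y1 = NA, cost_inr_month_gtw_y1 = NA,
       cost_inr_month_later = NA, cost_genotyping = NA, event_costs = NA,
       post_event_monthly = NA, utilities = NA, globals = NA, flags = NA)
}

#' Get or set a parameter by dotted path
#'
#' Fields are addressed by their name, with nested components separated by
#' dots, e.g. `"utilities.no_event_dab"` or `"rr_te_dab.stroke_se"`.
#'
#' @param p A parameter set.
#' @param path Dotted field path.
#' @param value Replacement value (for `param_set`).
#' @return `param_get` returns the value; `param_set` the modified set
#'   (not revalidated; callers revalidate).
#' @export
param_get <- function(p, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  x <- p
  for (k in keys) {
    if (!is.list(x) || !(k %in% names(x)))
      stop("unknown parameter path: '", path, "'")
    x <- x[[k]]
  }
  x
}

#' @rdname param_get
#' @export
param_set <- function(p, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  # verify the path exists before assigning
  param_get(p, path)
  p[[keys]] <- value
  p
}

#' Apply scenario overrides to a parameter set
#'
#' @param p A parameter set.
#' @param overrides Named list mapping dotted field paths to replacement
#'   values (see [param_get()]); an empty list returns `p` unchanged.
#' @return A new, revalidated parameter set.
#' @export
#' @examples
#' p <- apply_overrides(default_parameter_set(), list(rr_bleed_dab = 0.81))
#' p$rr_bleed_dab
apply_overrides <- function(p, overrides) {
  stopifnot(is.list(overrides))
  if (length(overrides) > 0L && is.null(names(overrides)))
    stop("overrides must be a named list of path = value")
  for (path in names(overrides)) {
    p <- param_set(p, path, overrides[[path]])
  }
  validate_params(p)
  p
}

#' Save / load a parameter set as JSON
#'
#' Serialization is lossless: `load_parameter_set(save_parameter_set(p, f))`
#' reproduces `p` exactly. Loading validates the set and fails with a named
#' error on missing fields or out-of-range values.
#'
#' @param p A parameter set.
#' @param path File path of the JSON configuration.
#' @return `load_parameter_set` returns the validated parameter set;
#'   `save_parameter_set` returns `path` invisibly.
#' @export
save_parameter_set <- function(p, path) {
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_parameter_set
#' @export
load_parameter_set <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  # read_json with simplifyVector collapses leaf lists to named vectors;
  # restore the canonical nested-list shape
  relist <- function(x) if (is.list(x)) lapply(x, relist) else as.list(x)
  for (nm in c("bleed_split_warfarin", "bleed_split_dab_raw", "rr_te_dab",
               "te_split_warfarin", "ich_outcomes", "stroke_outcomes",
               "event_costs", "post_event_monthly", "utilities", "globals",
               "flags")) {
    if (!is.null(p[[nm]]) && !is.list(p[[nm]])) p[[nm]] <- as.list(p[[nm]])
  }
  class(p) <- "afcua_params"
  validate_params(p)
  p
}

#' @export
print.afcua_params <- function(x, ...) {
  cat("<afcua_params>\n")
  cat("  arms: sdw (TTR ", sprintf("%.1f%%", 100 * x$ttr_sdw),
      "), gtw (uplift ", sprintf("%.1f%%", 100 * x$gtw_ttr_uplift),
      if (isTRUE(x$flags$additive_ttr_uplift)) " additive" else " relative",
      "), dab150\n", sep = "")
  cat("  horizon:", x$globals$horizon_days, "days; discount:",
      x$globals$discount_annual, "\n")
  cat("  cohort:", x$globals$cohort_size, "x", x$globals$n_replicates,
      "replicates; WTP threshold:", x$globals$wtp_threshold, "\n")
  invisible(x)
}

#' Table of parameters varied in sensitivity analyses
#'
#' One row per model input with a stated sensitivity range, giving the
#' dotted field path, range bounds and probabilistic-sensitivity
#' distribution family (`beta` for probabilities and utilities, `gamma`
#' for costs, `lognormal` for relative risks, `fixed` for quantities whose
#' printed range is unusable or absent). Event-type splits and outcome
#' trees are never sampled.
#'
#' @return A data.frame with columns `path`, `low`, `high`, `family`.
#' @export
psa_registry <- function() {
  reg <- rbind(
    data.frame(path = "ttr_sdw", low = 0.55, high = 0.69, family = "beta"),
    data.frame(path = "frac_below_of_out_of_range", low = 0.45, high = 0.60, family = "beta"),
    data.frame(path = "gtw_ttr_uplift", low = 0.00, high = 0.30, family = "beta"),
    data.frame(path = "p_bleed_annual_inrange", low = 0.009, high = 0.023, family = "beta"),
    data.frame(path = "p_te_annual_inrange", low = 0.012, high = 0.049, family = "beta"),
    data.frame(path = "rr_bleed_out_of_range", low = 3.57, high = 10, family = "lognormal"),
    data.frame(path = "rr_bleed_dab", low = 0.81, high = 1.07, family = "lognormal"),
    data.frame(path = "rr_te_subtherapeutic", low = 2.8, high = 44, family = "lognormal"),
    data.frame(path = "rr_te_other_out_of_range", low = 0.6, high = 1.3, family = "lognormal"),
    data.frame(path = "rr_te_dab.stroke_se", low = 0.53, high = 0.82, family = "lognormal"),
    data.frame(path = "rr_te_dab.mi", low = 1.00, high = 1.91, family = "lognormal"),
    data.frame(path = "rr_te_dab.pe", low = 0.76, high = 3.42, family = "lognormal"),
    data.frame(path = "cost_dab_daily", low = 1, high = 5, family = "gamma"),
    data.frame(path = "cost_warfarin_daily", low = 0.03, high = 0.10, family = "gamma"),
    data.frame(path = "cost_inr_month_sdw_y1", low = 5, high = 12, family = "gamma"),
    data.frame(path = "cost_inr_month_gtw_y1", low = 2, high = 8, family = "gamma"),
    data.frame(path = "cost_inr_month_later", low = 2, high = 6, family = "gamma"),
    data.frame(path = "cost_genotyping", low = 100, high = 1000, family = "gamma"),
    data.frame(path = "event_costs.stroke_none", low = 500, high = 1000, family = "gamma"),
    data.frame(path = "event_costs.stroke_mild", low = 15000, high = 40000, family = "gamma"),
    data.frame(path = "event_costs.stroke_severe", low = 30000, high = 60000, family = "gamma"),
    # printed range (25000-50000) cannot bracket the 1067 baseline: fixed
    data.frame(path = "event_costs.ich_none", low = NA_real_, high = NA_real_, family = "fixed"),
    data.frame(path = "event_costs.ich_mild", low = 15000, high = 25000, family = "gamma"),
    data.frame(path = "event_costs.ich_severe", low = 25000, high = 50000, family = "gamma"),
    data.frame(path = "event_costs.subdural", low = 20000, high = 45000, family = "gamma"),
    data.frame(path = "event_costs.extracranial_bleed", low = 5000, high = 12000, family = "gamma"),
    data.frame(path = "event_costs.dvt", low = 1500, high = 4000, family = "gamma"),
    data.frame(path = "event_costs.pe", low = 5000, high = 9000, family = "gamma"),
    data.frame(path = "event_costs.mi", low = 5000, high = 15000, family = "gamma"),
    data.frame(path = "post_event_monthly.severe", low = 3000, high = 10000, family = "gamma"),
    data.frame(path = "post_event_monthly.mild", low = 1000, high = 3000, family = "gamma"),
    data.frame(path = "utilities.no_event_warfarin", low = 0.95, high = 0.98, family = "beta"),
    data.frame(path = "utilities.no_event_dab", low = 0.95, high = 0.98, family = "beta"),
    data.frame(path = "utilities.ich_none", low = 0.90, high = 0.95, family = "beta"),
    data.frame(path = "utilities.ich_mild", low = 0.70, high = 0.90, family = "beta"),
    data.frame(path = "utilities.ich_severe", low = 0.15, high = 0.60, family = "beta"),
    data.frame(path = "utilities.extracranial", low = 0.75, high = 0.85, family = "beta"),
    data.frame(path = "utilities.stroke_none", low = 0.90, high = 0.95, family = "beta"),
    data.frame(path = "utilities.stroke_mild", low = 0.70, high = 0.90, family = "beta"),
    data.frame(path = "utilities.stroke_severe", low = 0.15, high = 0.50, family = "beta"),
    data.frame(path = "utilities.mi", low = 0.80, high = 0.90, family = "beta"),
    data.frame(path = "utilities.pe", low = 0.70, high = 0.90, family = "beta"),
    data.frame(path = "utilities.dvt", low = 0.80, high = 0.90, family = "beta")
  )
  rownames(reg) <- NULL
  reg
}
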