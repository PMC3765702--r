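#' Round to the nearest dollar, half away from zero
#'
#' Reported cost-utility ratios are printed as integers rounded half away
#' from zero (base `round()` rounds half to even); full precision is kept
#' internally everywhere.
#'
#' @param x Numeric.
#' @return Integer-valued numeric.
#' @export
round_dollar <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Raw cost/utility ratio
#'
#' @param mean_cost Mean discounted cost per patient (CAD$).
#' @param mean_qaly Mean discounted QALYs per patient (> 0).
#' @param rounded Round to the nearest dollar (default `TRUE`, matching
#'   reported tables).
#' @return Cost per QALY.
#' @export
#' @examples
#' raw_cu_ratio(7289, 3.5368)  # 2061
raw_cu_ratio <- function(mean_cost, mean_qaly, rounded = TRUE) {
  if (any(mean_qaly <= 0)) stop("mean_qaly must be > 0")
  r <- mean_cost / mean_qaly
  if (rounded) round_dollar(r) else r
}

#' Incremental cost-utility ratio
#'
#' `(alt_cost - ref_cost) / (alt_qaly - ref_qaly)`. Equal QALYs yield `NA`
#' with a warning (undefined ICUR), not an error.
#'
#' @param ref_cost,ref_qaly Reference strategy means.
#' @param alt_cost,alt_qaly Alternative strategy means.
#' @param rounded Round to the nearest dollar (default `TRUE`).
#' @return Incremental cost per QALY gained (sign preserved).
#' @export
#' @examples
#' icur(7289, 3.5368, 8494, 3.7897)  # 4765
icur <- function(ref_cost, ref_qaly, alt_cost, alt_qaly, rounded = TRUE) {
  dq <- alt_qaly - ref_qaly
  if (dq == 0) {
    warning("equal QALYs: ICUR undefined")
    return(NA_real_)
  }
  r <- (alt_cost - ref_cost) / dq
  if (rounded) round_dollar(r) else r
}

#' Net monetary benefit
#'
#' @param cost,qaly Strategy means.
#' @param threshold Willingness-to-pay per QALY (>= 0).
#' @return `threshold * qaly - cost`.
#' @export
nmb <- function(cost, qaly, threshold) {
  if (any(threshold < 0)) stop("threshold must be >= 0")
  threshold * qaly - cost
}

#' Incremental analysis with strict and extended dominance
#'
#' Sorts strategies by mean cost, marks strictly dominated strategies
#' (at least as costly and no more effective than some other strategy,
#' with at least one inequality strict), iteratively removes
#' extended-dominated strategies (whose ICUR against the previous frontier
#' strategy exceeds that of the next more effective, more expensive
#' alternative), and reports pairwise ICURs along the efficiency frontier.
#' Strategies with identical cost and QALY share the frontier.
#'
#' @param arm_summaries Data.frame with columns `arm`, `mean_cost`,
#'   `mean_qaly` (>= 2 rows), e.g. `run_strategies()$summary`.
#' @param rounded Round reported ICURs to the nearest dollar.
#' @return Data.frame of class `afcua_frontier`: one row per strategy with
#'   `arm`, `mean_cost`, `mean_qaly`, `status` (`on_frontier`,
#'   `strictly_dominated`, `extended_dominated`), `comparator`,
#'   `delta_cost`, `delta_qaly`, `icur`.
#' @export
#' @examples
#' base <- data.frame(arm = c("sdw", "gtw", "dab150"),
#'                    mean_cost = c(7289, 7749, 8494),
#'                    mean_qaly = c(3.5368, 3.5453, 3.7897))
#' dominance_frontier(base)
dominance_frontier <- function(arm_summaries, rounded = TRUE) {
  df <- as.data.frame(arm_summaries)
  stopifnot(all(c("arm", "mean_cost", "mean_qaly") %in% names(df)),
            nrow(df) >= 2)
  df <- df[order(df$mean_cost, df$mean_qaly), c("arm", "mean_cost", "mean_qaly")]
  n <- nrow(df)
  status <- rep("on_frontier", n)
  # strict dominance (ties share the frontier)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (df$mean_cost[j] <= df$mean_cost[i] &&
          df$mean_qaly[j] >= df$mean_qaly[i] &&
          (df$mean_cost[j] < df$mean_cost[i] ||
           df$mean_qaly[j] > df$mean_qaly[i])) {
        status[i] <- "strictly_dominated"
        break
      }
    }
  }
  # extended dominance: drop frontier candidates whose ICUR vs the previous
  # frontier strategy exceeds the ICUR of the next one
  repeat {
    idx <- which(status == "on_frontier")
    if (length(idx) < 3) break
    removed <- FALSE
    for (k in 2:(length(idx) - 1)) {
      a <- idx[k - 1]; b <- idx[k]; c <- idx[k + 1]
      r_ab <- (df$mean_cost[b] - df$mean_cost[a]) /
        (df$mean_qaly[b] - df$mean_qaly[a])
      r_bc <- (df$mean_cost[c] - df$mean_cost[b]) /
        (df$mean_qaly[c] - df$mean_qaly[b])
      if (is.finite(r_ab) && is.finite(r_bc) && r_ab > r_bc) {
        status[b] <- "extended_dominated"
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  comparator <- rep(NA_character_, n)
  delta_cost <- rep(NA_real_, n)
  delta_qaly <- rep(NA_real_, n)
  ic <- rep(NA_real_, n)
  idx <- which(status == "on_frontier")
  if (length(idx) >= 2) {
    for (k in 2:length(idx)) {
      b <- idx[k]; a <- idx[k - 1]
      comparator[b] <- df$arm[a]
      delta_cost[b] <- df$mean_cost[b] - df$mean_cost[a]
      delta_qaly[b] <- df$mean_qaly[b] - df$mean_qaly[a]
      if (delta_qaly[b] != 0) {
        r <- delta_cost[b] / delta_qaly[b]
        ic[b] <- if (rounded) round_dollar(r) else r
      }
    }
  }
  out <- cbind(df, status = status, comparator = comparator,
               delta_cost = delta_cost, delta_qaly = delta_qaly, icur = ic)
  rownames(out) <- NULL
  class(out) <- c("afcua_frontier", "data.frame")
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability that the
#' comparator strategy is cost-effective against the reference: the
#' fraction of probabilistic-sensitivity draws in which its net monetary
#' benefit is at least the reference's. Also reports the fraction of draws
#' in which the comparator strictly dominates (cheaper and more
#' effective).
#'
#' @param psa_draws Data.frame with one row per iteration x arm: columns
#'   `iteration`, `arm`, `mean_cost`, `mean_qaly` (as from [run_psa()]).
#' @param reference_arm,comparator_arm Arm names present in `psa_draws`.
#' @param thresholds Ascending willingness-to-pay grid (default 0 to
#'   100,000 by 2,500).
#' @return Data.frame with `threshold`, `probability_ce`, `p_dominant`.
#' @export
build_ceac <- function(psa_draws, reference_arm, comparator_arm,
                       thresholds = seq(0, 100000, by = 2500)) {
  df <- as.data.frame(psa_draws)
  stopifnot(all(c("iteration", "arm", "mean_cost", "mean_qaly") %in% names(df)))
  if (nrow(df) == 0) stop("psa_draws is empty")
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  ref <- df[df$arm == reference_arm, ]
  cmp <- df[df$arm == comparator_arm, ]
  if (nrow(ref) == 0 || nrow(cmp) == 0)
    stop("reference or comparator arm absent from psa_draws")
  m <- merge(ref, cmp, by = "iteration", suffixes = c("_ref", "_cmp"))
  if (nrow(m) == 0) stop("no common iterations between arms")
  dc <- m$mean_cost_cmp - m$mean_cost_ref
  dq <- m$mean_qaly_cmp - m$mean_qaly_ref
  p_dom <- mean(dc < 0 & dq > 0)
  out <- data.frame(
    threshold = thresholds,
    probability_ce = vapply(thresholds,
                            function(l) mean(l * dq - dc >= 0), numeric(1)),
    p_dominant = p_dom)
  out
}
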