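# substream purpose codes (keep in sync with src/engine.cpp)
PURPOSES <- c(age = 0L, inr = 1L, bleed_test = 2L, te_test = 3L,
              bleed_subtype = 4L, bleed_outcome = 5L, te_subtype = 6L,
              te_outcome = 7L, death_day = 8L)

AGE_TRUNC <- c(18, 100)

#' Generate a virtual atrial-fibrillation cohort
#'
#' Ages are drawn from a Normal(`age_mean`, `age_sd`) truncated to
#' \[18, 100\] by inverse-CDF transform of counter-based uniforms, so the
#' cohort is bit-identical for the same `(master_seed, replicate_id, n)`
#' regardless of execution order. Age is recorded for audit but drives no
#' hazard (the model has no age-dependent rates).
#'
#' @param n Cohort size (>= 1).
#' @param replicate_id Replicate index (each replicate is a fresh
#'   population; the same population is reused across all three arms).
#' @param master_seed Master seed for the whole experiment.
#' @param age_mean,age_sd Age distribution; defaults 64 and 8 years.
#' @return Object of class `afcua_cohort`: list with `replicate_id`,
#'   `master_seed`, and `individuals` (data.frame `id`, `age_years`).
#' @export
#' @examples
#' co <- generate_cohort(5, replicate_id = 1, master_seed = 42)
#' co$individuals
generate_cohort <- function(n, replicate_id, master_seed,
                            age_mean = 64, age_sd = 8) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  ids <- seq_len(n) - 1L
  if (age_sd == 0) {
    ages <- rep(age_mean, n)
  } else {
    u <- cpp_stream_uniform(master_seed, replicate_id, ids, 0L,
                            PURPOSES[["age"]], 0, 0)
    pl <- stats::pnorm(AGE_TRUNC[1], age_mean, age_sd)
    ph <- stats::pnorm(AGE_TRUNC[2], age_mean, age_sd)
    ages <- stats::qnorm(pl + u * (ph - pl), age_mean, age_sd)
  }
  structure(list(replicate_id = replicate_id, master_seed = master_seed,
                 individuals = data.frame(id = ids, age_years = ages)),
            class = "afcua_cohort")
}

#' @export
print.afcua_cohort <- function(x, ...) {
  cat("<afcua_cohort> n =", nrow(x$individuals),
      "replicate", x$replicate_id, "seed", x$master_seed, "\n")
  cat("  mean age:", round(mean(x$individuals$age_years), 2), "years\n")
  invisible(x)
}

#' Export / import a cohort as CSV
#'
#' @param cohort An `afcua_cohort`.
#' @param path CSV file path (columns `id`, `age_years`).
#' @param replicate_id,master_seed Provenance recorded on import.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   an `afcua_cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort$individuals, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path, replicate_id = NA, master_seed = NA) {
  df <- utils::read.csv(path)
  stopifnot(all(c("id", "age_years") %in% names(df)))
  structure(list(replicate_id = replicate_id, master_seed = master_seed,
                 individuals = df[, c("id", "age_years")]),
            class = "afcua_cohort")
}

#' Per-individual random substreams
#'
#' `substream()` returns a serializable descriptor of a counter-based
#' random stream identified by `(master_seed, replicate_id, individual_id,
#' arm_tag, purpose)`. `draw_uniform()` evaluates it at a `(day, index)`
#' counter: the same descriptor and counter always give the same uniform,
#' and streams for different individuals or purposes are statistically
#' independent. Event-occurrence purposes (`"inr"`, `"bleed_test"`,
#' `"te_test"`) use `arm_tag = 0` so they are shared across arms (common
#' random numbers); resolution purposes carry the arm tag.
#'
#' @param master_seed,replicate_id,individual_id Stream coordinates.
#' @param arm_tag 0 (shared) or an arm code 1-3 (`sdw`, `gtw`, `dab150`).
#' @param purpose One of `names(afcua_purposes())`.
#' @return `substream`: a list descriptor of class `afcua_stream`;
#'   `draw_uniform`: numeric vector of uniforms in (0, 1).
#' @export
#' @examples
#' s <- substream(42, 1, 7, 0, "bleed_test")
#' draw_uniform(s, day = 0:4)
substream <- function(master_seed, replicate_id, individual_id,
                      arm_tag = 0L, purpose = "bleed_test") {
  if (is.character(purpose)) {
    if (!purpose %in% names(PURPOSES)) stop("unknown purpose: ", purpose)
    purpose <- PURPOSES[[purpose]]
  }
  structure(list(master_seed = master_seed, replicate_id = replicate_id,
                 individual_id = individual_id, arm_tag = as.integer(arm_tag),
                 purpose = as.integer(purpose)),
            class = "afcua_stream")
}

#' @rdname substream
#' @param stream An `afcua_stream` descriptor.
#' @param day Day counter (vectorized).
#' @param idx Draw index within a day (vectorized).
#' @export
draw_uniform <- function(stream, day = 0, idx = 0) {
  stopifnot(inherits(stream, "afcua_stream"))
  cpp_stream_uniform(stream$master_seed, stream$replicate_id,
                     stream$individual_id, stream$arm_tag, stream$purpose,
                     day, idx)
}

#' @rdname substream
#' @export
afcua_purposes <- function() PURPOSES
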