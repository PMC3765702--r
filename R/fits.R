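#' Fit PSA sampling distributions from sensitivity ranges
#'
#' The one-way sensitivity ranges are interpreted as central 95% intervals.
#' Each two-parameter family is fitted under an exact mean constraint
#' (the fitted distribution's mean equals the baseline), with the remaining
#' degree of freedom chosen so the fitted 2.5%/97.5% quantiles match the
#' stated range as closely as possible (least squares on the two quantiles).
#'
#' `fit_beta_from_ci` parameterizes by concentration `k`: `alpha = m*k`,
#' `beta = (1-m)*k`, so the mean is `m` for every `k`; `k` is optimized.
#' `fit_gamma_from_ci` fixes `scale = mean/shape` and optimizes the shape.
#' `fit_lognormal_from_ci` uses the symmetric-CI closed form
#' `sigma = (log(high) - log(low)) / (2 * 1.96)` and then sets
#' `mu = log(mean) - sigma^2/2` to satisfy the mean constraint; when the
#' implied median `exp(mu)` differs from the geometric midpoint
#' `sqrt(low*high)` by more than 1% the result is flagged
#' `median_shifted = TRUE` (mean matching took precedence over centering).
#'
#' A degenerate range (`low == high == mean`) yields `family = "fixed"`:
#' sampling returns the mean always.
#'
#' @param mean Baseline value; becomes the fitted distribution mean.
#' @param low,high Lower and upper sensitivity bounds (central 95% interval).
#' @return A list with `family` and the shape parameters: beta
#'   (`alpha`, `beta`), gamma (`shape`, `scale`), lognormal (`mu`, `sigma`,
#'   `median_shifted`), or `family = "fixed"` with `value`.
#' @export
#' @examples
#' f <- fit_beta_from_ci(0.64, 0.55, 0.69)
#' f$alpha / (f$alpha + f$beta)  # == 0.64
fit_beta_from_ci <- function(mean, low, high) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop("beta fit requires 0 < mean < 1, got ", mean)
  if (low == high) {
    if (low != mean) stop("degenerate range must equal the mean")
    return(list(family = "fixed", value = mean))
  }
  if (mean < low || mean > high)
    stop("mean ", mean, " outside range [", low, ", ", high, "]")
  if (low < 0 || high > 1) stop("beta range must lie in [0, 1]")
  loss <- function(logk) {
    k <- exp(logk)
    a <- mean * k
    b <- (1 - mean) * k
    (stats::qbeta(0.025, a, b) - low)^2 + (stats::qbeta(0.975, a, b) - high)^2
  }
  opt <- stats::optimize(loss, c(log(1e-2), log(1e7)))
  k <- exp(opt$minimum)
  list(family = "beta", alpha = mean * k, beta = (1 - mean) * k)
}

#' @rdname fit_beta_from_ci
#' @export
fit_gamma_from_ci <- function(mean, low, high) {
  if (!is.finite(mean) || mean <= 0) stop("gamma fit requires mean > 0")
  if (low < 0 || high < low) stop("gamma fit requires 0 <= low <= high")
  if (low == high) {
    if (low != mean) stop("degenerate range must equal the mean")
    return(list(family = "fixed", value = mean))
  }
  if (mean < low || mean > high)
    stop("mean ", mean, " outside range [", low, ", ", high, "]")
  loss <- function(logshape) {
    sh <- exp(logshape)
    sc <- mean / sh
    (stats::qgamma(0.025, shape = sh, scale = sc) - low)^2 +
      (stats::qgamma(0.975, shape = sh, scale = sc) - high)^2
  }
  opt <- stats::optimize(loss, c(log(1e-2), log(1e7)))
  sh <- exp(opt$minimum)
  list(family = "gamma", shape = sh, scale = mean / sh)
}

#' @rdname fit_beta_from_ci
#' @export
fit_lognormal_from_ci <- function(mean, low, high) {
  if (!is.finite(mean) || mean <= 0 || low <= 0 || high <= 0)
    stop("lognormal fit requires positive mean, low, high")
  if (low == high) {
    if (low != mean) stop("degenerate range must equal the mean")
    return(list(family = "fixed", value = mean))
  }
  if (mean < low || mean > high)
    stop("mean ", mean, " outside range [", low, ", ", high, "]")
  sigma <- (log(high) - log(low)) / (2 * stats::qnorm(0.975))
  mu <- log(mean) - sigma^2 / 2
  median_shifted <-
    abs(mu - (log(low) + log(high)) / 2) > log(1.01)
  list(family = "lognormal", mu = mu, sigma = sigma,
       median_shifted = median_shifted)
}

#' Fit all PSA distributions for a parameter set
#'
#' @param p A parameter set.
#' @param registry Range/family table, by default [psa_registry()].
#' @return Named list (by dotted path) of fitted distributions; entries with
#'   `family = "fixed"` sample as constants.
#' @export
fit_psa_distributions <- function(p, registry = psa_registry()) {
  fits <- vector("list", nrow(registry))
  names(fits) <- registry$path
  for (i in seq_len(nrow(registry))) {
    path <- registry$path[i]
    m <- param_get(p, path)
    fam <- registry$family[i]
    if (fam == "fixed" || is.na(registry$low[i])) {
      fits[[i]] <- list(family = "fixed", value = m)
    } else if (fam == "beta") {
      fits[[i]] <- fit_beta_from_ci(m, registry$low[i], registry$high[i])
    } else if (fam == "gamma") {
      fits[[i]] <- fit_gamma_from_ci(m, registry$low[i], registry$high[i])
    } else if (fam == "lognormal") {
      fits[[i]] <- fit_lognormal_from_ci(m, registry$low[i], registry$high[i])
    } else {
      stop("unknown distribution family: ", fam)
    }
  }
  fits
}

#' Analytic mean of a fitted PSA distribution
#'
#' @param fit A fit from [fit_beta_from_ci()] and friends.
#' @return The distribution mean, in closed form.
#' @export
fitted_mean <- function(fit) {
  switch(fit$family,
    fixed = fit$value,
    beta = fit$alpha / (fit$alpha + fit$beta),
    gamma = fit$shape * fit$scale,
    lognormal = exp(fit$mu + fit$sigma^2 / 2),
    stop("unknown family ", fit$family)
  )
}

sample_fit <- function(fit, n = 1L) {
  switch(fit$family,
    fixed = rep(fit$value, n),
    beta = stats::rbeta(n, fit$alpha, fit$beta),
    gamma = stats::rgamma(n, shape = fit$shape, scale = fit$scale),
    lognormal = stats::rlnorm(n, meanlog = fit$mu, sdlog = fit$sigma),
    stop("unknown family ", fit$family)
  )
}

#' Draw one probabilistic-sensitivity parameter set
#'
#' Every parameter with a non-fixed fitted family is drawn independently
#' from its distribution; fixed parameters, event-type splits, outcome
#' trees and globals are left at baseline. Identical `seed` gives an
#' identical draw. Draws are made in registry order with a locally scoped
#' RNG, so the caller's RNG state is untouched.
#'
#' @param p Baseline parameter set.
#' @param seed Integer seed for this draw.
#' @param fits Fitted distributions, by default fitted on the fly from
#'   [psa_registry()]; pass precomputed fits when drawing repeatedly.
#' @return A new, validated parameter set.
#' @export
sample_psa_draw <- function(p, seed, fits = fit_psa_distributions(p)) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  out <- p
  for (path in names(fits)) {
    fit <- fits[[path]]
    if (fit$family == "fixed") next
    out <- param_set(out, path, sample_fit(fit, 1L))
  }
  validate_params(out)
  out
}
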