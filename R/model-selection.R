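#' Goodness-of-fit metrics
#'
#' Residual sum of squares, coefficient of determination and root-mean-square
#' error of modelled against observed rates:
#' `rss = sum((obs - mod)^2)`, `r2 = 1 - rss / sum((obs - mean(obs))^2)`,
#' `rmse = sqrt(rss / n)`.
#'
#' @param observed,modelled numeric vectors of equal length (>= 2).
#' @return A list with `rss`, `r2`, `rmse`.
#' @export
fit_metrics <- function(observed, modelled) {
  observed <- as.numeric(observed); modelled <- as.numeric(modelled)
  if (length(observed) != length(modelled)) stop("observed and modelled must have equal length")
  if (length(observed) < 2L) stop("need at least 2 observations")
  if (any(!is.finite(observed)) || any(!is.finite(modelled))) stop("non-finite values in inputs")
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) stop("observed values have zero variance; r2 is undefined")
  rss <- sum((observed - modelled)^2)
  list(rss = rss, r2 = 1 - rss / tss, rmse = sqrt(rss / length(observed)))
}

#' Akaike information criterion from a residual sum of squares
#'
#' Least-squares Gaussian form `AIC = n * log(rss / n) + 2 * p`, appropriate
#' for comparing nested decay models fitted to the same series. `p` counts the
#' pool parameters (3 for two-pool, 5 for three-pool); the measurement s.d. is
#' data-supplied, not estimated, so it does not enter `p`.
#'
#' @param rss residual sum of squares (> 0; `rss = 0` returns `-Inf` with a
#'   warning, flagging a degenerate exact fit).
#' @param n_obs number of observations (must exceed `n_params`).
#' @param n_params number of fitted parameters.
#' @return The AIC value.
#' @export
aic_rss <- function(rss, n_obs, n_params) {
  if (n_obs <= n_params) stop("n_obs must exceed n_params")
  if (rss < 0) stop("rss must be >= 0")
  if (rss == 0) {
    warning("rss is exactly 0: degenerate fit, AIC = -Inf")
    return(-Inf)
  }
  n_obs * log(rss / n_obs) + 2 * n_params
}

#' Compare two-pool and three-pool fits of one series
#'
#' Fits both models to the same series by [fit_decay_model()], evaluates each
#' at its maximum-likelihood point estimate (the single highest-log-likelihood
#' stored draw, the coherent choice for an RSS-based AIC) and reports
#' goodness-of-fit metrics and AIC per model. Residuals use the replicate-mean
#' observed rate at each time point (one curve per sample), so `n_obs` is the
#' number of time points. The lower-AIC model is selected; differences within
#' `|dAIC| <= 2` are reported as `"equivalent"` and resolved in favour of the
#' smaller model (parsimony).
#'
#' Both fits use the same `seed` via their own internal `set.seed()`, so the
#' result is invariant to the order in which models are fitted.
#'
#' @param series an [incubation_series()].
#' @param priors named list with elements `two_pool` and `three_pool`
#'   ([prior_box()] objects); defaults to [default_prior()] for each.
#' @param n_iter,n_burn,thin,step_fraction,seed,c_tot MCMC settings passed to
#'   [fit_decay_model()].
#' @return A data frame of class `model_comparison` with one row per model and
#'   columns `sample_id`, `model`, `n_obs`, `n_params`, `rss`, `r2`, `rmse`,
#'   `aic`, `selected`; attributes `delta_aic` (three-pool minus two-pool) and
#'   `decision` (`"two_pool"`, `"three_pool"` or `"equivalent"`).
#' @export
compare_models <- function(series,
                           priors = list(two_pool = default_prior("two_pool"),
                                         three_pool = default_prior("three_pool")),
                           n_iter = 50000, n_burn = 10000, thin = 10,
                           step_fraction = 0.05, seed = 1L, c_tot = 1000) {
  stopifnot(inherits(series, "incubation_series"))
  stopifnot(all(c("two_pool", "three_pool") %in% names(priors)))
  obs <- series$mean_rates
  one <- function(model) {
    ch <- fit_decay_model(series, model, priors[[model]], n_iter, n_burn,
                          thin, step_fraction, seed = seed, c_tot = c_tot)
    est <- ch$draws[which.max(ch$loglik), ]
    mod <- theta_flux(est, model, series$times, c_tot)
    m <- fit_metrics(obs, mod)
    p <- length(est)
    data.frame(sample_id = series$sample_id, model = model,
               n_obs = length(obs), n_params = p, rss = m$rss, r2 = m$r2,
               rmse = m$rmse, aic = aic_rss(m$rss, length(obs), p),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("two_pool"), one("three_pool"))
  delta <- out$aic[out$model == "three_pool"] - out$aic[out$model == "two_pool"]
  decision <- if (abs(delta) <= 2) "equivalent" else if (delta < 0) "three_pool" else "two_pool"
  chosen <- if (decision == "equivalent") "two_pool" else decision
  out$selected <- out$model == chosen
  attr(out, "delta_aic") <- delta
  attr(out, "decision") <- decision
  class(out) <- c("model_comparison", "data.frame")
  out
}
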