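#' Gaussian log-likelihood of a parameter set
#'
#' Heteroscedastic Gaussian log-likelihood (up to its additive normalisation
#' constant) of observed emission rates given decay-model parameters:
#' \deqn{\ell(\theta) = -\sum_t \sum_i \frac{[Z_i(t) - X(t)]^2}{2\sigma(t)^2}}
#' where \eqn{X(t)} is [flux_rate()] evaluated on the series schedule. The
#' constant is irrelevant to Metropolis-Hastings with data-supplied
#' \eqn{\sigma}, so it is omitted; the value is therefore always <= 0 and
#' equals 0 only for a perfect fit.
#'
#' @param params a [decay_params()] object.
#' @param series an [incubation_series()].
#' @return A single non-positive number.
#' @export
log_likelihood <- function(params, series) {
  validate_decay_params(params)
  stopifnot(inherits(series, "incubation_series"))
  x <- flux_rate(params, series$times)
  resid <- sweep(series$rates, 1L, x, "-")
  -sum(sweep(resid^2, 1L, 2 * series$sigma^2, "/"), na.rm = TRUE)
}

#' Propose a new parameter state
#'
#' Symmetric random-walk proposal used by [fit_decay_model()]: each component
#' jumps by a uniform draw of half-width `step_fraction * (upper - lower)` and
#' is reflected at the box boundaries; whole proposals violating the joint
#' constraints (`f1 + f2 <= 1`, rate ordering) are redrawn, which preserves
#' symmetry over the feasible region.
#'
#' @param theta named parameter vector inside `prior`.
#' @param prior a [prior_box()].
#' @param step_fraction jump half-width as a fraction of each prior range
#'   (> 0).
#' @return A named parameter vector inside the box.
#' @export
propose_params <- function(theta, prior, step_fraction = 0.05) {
  stopifnot(inherits(prior, "prior_box"))
  if (!is.numeric(step_fraction) || length(step_fraction) != 1L || step_fraction <= 0) {
    stop("step_fraction must be a single value > 0")
  }
  theta <- theta[names(prior$lower)]
  if (any(theta < prior$lower) || any(theta > prior$upper)) {
    stop("theta must lie inside the prior box")
  }
  out <- cpp_propose(as.numeric(theta), as.numeric(prior$lower),
                     as.numeric(prior$upper), step_fraction)
  stats::setNames(out, names(prior$lower))
}

#' Fit a decay model by Metropolis-Hastings MCMC
#'
#' Samples the posterior of the pool parameters under the uniform [prior_box()]
#' and the heteroscedastic Gaussian likelihood of [log_likelihood()]. Because
#' the prior is uniform and the proposal symmetric, a proposal is accepted with
#' probability `min(1, exp(l' - l))` where `l` is the log-likelihood. The chain
#' starts from the prior-box midpoint (deterministic, so a single-seed run is
#' fully reproducible), and post burn-in states are stored every `thin`
#' iterations together with their log-likelihoods.
#'
#' @param series an [incubation_series()].
#' @param model `"three_pool"` or `"two_pool"`.
#' @param prior a [prior_box()] for `model`; defaults to [default_prior()].
#' @param n_iter,n_burn,thin iteration count, burn-in length and thinning
#'   interval (defaults 50000, 10000, 10).
#' @param step_fraction proposal half-width as a fraction of each prior range.
#' @param seed integer RNG seed; recorded in the chain.
#' @param c_tot initial SOC content (mg C per g SOC).
#' @return An object of class `decay_chain`: `draws` (matrix, one row per
#'   stored state, columns named by parameter), `loglik`, `acceptance_rate`,
#'   the MCMC settings, `seed`, `model`, `prior`, `c_tot` and the `sample_id`.
#' @examples
#' prm <- decay_params(f1 = 0.01, f2 = 0.6, k1 = 0.02, k2 = 2e-4, k3 = 2e-6)
#' des <- cohort_design(schedule = default_schedule(), noise_cv = 0.05)
#' ser <- simulate_series(prm, des, seed = 1)
#' ch <- fit_decay_model(ser, "three_pool", n_iter = 2000, n_burn = 500, seed = 1)
#' summarize_posterior(ch)
#' @export
fit_decay_model <- function(series, model = c("three_pool", "two_pool"),
                            prior = default_prior(model),
                            n_iter = 50000, n_burn = 10000, thin = 10,
                            step_fraction = 0.05, seed = 1L, c_tot = 1000) {
  model <- match.arg(model)
  stopifnot(inherits(series, "incubation_series"), inherits(prior, "prior_box"))
  if (prior$model != model) stop("prior box is for model '", prior$model, "'")
  check_fit_eligible(series, model)
  if (!(n_iter > n_burn && n_burn >= 0)) stop("need n_iter > n_burn >= 0")
  if (thin < 1) stop("thin must be >= 1")
  if (step_fraction <= 0) stop("step_fraction must be > 0")

  set.seed(as.integer(seed))
  res <- cpp_mh(series$times, series$rates, series$sigma,
                as.numeric(prior$lower), as.numeric(prior$upper), c_tot,
                as.integer(n_iter), as.integer(n_burn), as.integer(thin),
                step_fraction)
  if (res$accept_post_burn == 0L) {
    stop("no proposals were accepted after burn-in; try a larger step_fraction or a wider prior")
  }
  draws <- res$draws
  colnames(draws) <- names(prior$lower)
  structure(
    list(draws = draws, loglik = as.numeric(res$loglik),
         acceptance_rate = res$acceptance_rate,
         n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
         thin = as.integer(thin), step_fraction = step_fraction,
         seed = as.integer(seed), model = model, prior = prior, c_tot = c_tot,
         sample_id = series$sample_id),
    class = "decay_chain")
}

#' @export
print.decay_chain <- function(x, ...) {
  cat(sprintf(
    "<decay_chain %s (%s): %d stored draws, acceptance %.1f%%, seed %d>\n",
    x$sample_id, x$model, nrow(x$draws), 100 * x$acceptance_rate, x$seed))
  invisible(x)
}

#' Summarise a posterior chain
#'
#' Per-parameter point estimates, 95% equal-tail intervals and a
#' "well-constrained" flag. A parameter counts as constrained when its marginal
#' histogram (`n_bins` bins spanning the prior range) has a clear interior
#' mode: the modal bin centre lies outside the outer 5% of the prior range on
#' either side, and the modal bin holds at least twice the count expected under
#' a uniform marginal. Constrained parameters are reported at the value they
#' take in the single highest-log-likelihood draw (a maximum-likelihood
#' estimate); unconstrained parameters fall back to the marginal mean.
#'
#' @param chain a `decay_chain` from [fit_decay_model()].
#' @param n_bins histogram bins per marginal (default 50).
#' @param min_draws minimum stored draws required (default 1000).
#' @return A data frame of class `posterior_summary` with columns `parameter`,
#'   `estimate`, `rule` (`"mle"` or `"mean"`), `q2.5`, `q97.5`, `constrained`.
#' @export
summarize_posterior <- function(chain, n_bins = 50L, min_draws = 1000L) {
  stopifnot(inherits(chain, "decay_chain"))
  n <- nrow(chain$draws)
  if (n < 1L) stop("empty chain")
  if (n < min_draws) {
    stop(sprintf("chain has %d stored draws; need >= %d for a stable summary", n, min_draws))
  }
  lo <- chain$prior$lower
  hi <- chain$prior$upper
  imle <- which.max(chain$loglik)
  rows <- lapply(colnames(chain$draws), function(p) {
    x <- chain$draws[, p]
    breaks <- seq(lo[[p]], hi[[p]], length.out = n_bins + 1L)
    counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                    all.inside = TRUE), nbins = n_bins)
    modal <- which.max(counts)
    centre <- (breaks[modal] + breaks[modal + 1L]) / 2
    edge_width <- 0.05 * (hi[[p]] - lo[[p]])
    interior <- centre > lo[[p]] + edge_width && centre < hi[[p]] - edge_width
    peaked <- counts[modal] >= 2 * n / n_bins
    constrained <- interior && peaked
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
    data.frame(parameter = p,
               estimate = if (constrained) chain$draws[imle, p] else mean(x),
               rule = if (constrained) "mle" else "mean",
               q2.5 = q[1], q97.5 = q[2], constrained = constrained,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Point-estimate parameter vector from a posterior summary
#'
#' @param summary a `posterior_summary` (or a `decay_chain`, which is
#'   summarised first).
#' @return A named numeric vector of per-parameter point estimates in prior
#'   order.
#' @export
point_estimates <- function(summary) {
  if (inherits(summary, "decay_chain")) summary <- summarize_posterior(summary)
  stats::setNames(summary$estimate, summary$parameter)
}

#' Gelman-Rubin convergence diagnostic across seeds
#'
#' Optional multi-seed diagnostic: refits the same series under several seeds
#' and computes the potential scale reduction factor per parameter
#' (between/within-chain variance ratio). Values below about 1.1 indicate
#' convergence.
#'
#' @param series an [incubation_series()].
#' @param model,prior,n_iter,n_burn,thin,step_fraction,c_tot passed to
#'   [fit_decay_model()].
#' @param seeds integer vector of seeds (default `1:3`).
#' @return Named numeric vector of split-free R-hat values per parameter.
#' @export
gelman_rubin <- function(series, model = c("three_pool", "two_pool"),
                         prior = default_prior(model), seeds = 1:3,
                         n_iter = 50000, n_burn = 10000, thin = 10,
                         step_fraction = 0.05, c_tot = 1000) {
  model <- match.arg(model)
  chains <- lapply(seeds, function(s) {
    fit_decay_model(series, model, prior, n_iter, n_burn, thin,
                    step_fraction, seed = s, c_tot = c_tot)$draws
  })
  m <- length(chains)
  n <- nrow(chains[[1L]])
  vapply(colnames(chains[[1L]]), function(p) {
    means <- vapply(chains, function(d) mean(d[, p]), numeric(1))
    vars <- vapply(chains, function(d) stats::var(d[, p]), numeric(1))
    W <- mean(vars)
    B <- n * stats::var(means)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

#' Write or read a chain as CSV
#'
#' One row per stored draw: `iteration`, the parameter columns and `loglik`.
#' Settings (seed, model, acceptance rate) travel in `#`-prefixed header
#' comments.
#'
#' @param chain a `decay_chain`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_chain_csv <- function(chain, path) {
  stopifnot(inherits(chain, "decay_chain"))
  hdr <- sprintf("# socpools chain: sample_id=%s model=%s seed=%d n_iter=%d n_burn=%d thin=%d step_fraction=%g acceptance_rate=%.6f",
                 chain$sample_id, chain$model, chain$seed, chain$n_iter,
                 chain$n_burn, chain$thin, chain$step_fraction,
                 chain$acceptance_rate)
  df <- data.frame(iteration = chain$n_burn + chain$thin * seq_len(nrow(chain$draws)),
                   chain$draws, loglik = chain$loglik, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chain_csv
#' @param path CSV path written by [write_chain_csv()].
#' @return For `read_chain_csv()`, a data frame of draws with a `loglik`
#'   column.
#' @export
read_chain_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
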