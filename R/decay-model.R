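#' Multi-pool first-order decay parameters
#'
#' Construct and validate the parameter set of a two- or three-pool first-order
#' soil organic carbon (SOC) decomposition model. In the three-pool model SOC is
#' partitioned into a fast, a slow and a passive fraction (`f1`, `f2`,
#' `1 - f1 - f2`), each decaying exponentially at its own first-order rate
#' (`k1 > k2 > k3`, per day). The two-pool model drops the passive pool: the
#' slow fraction is implied as `1 - f1` and only `k1 > k2` are needed.
#'
#' `c_tot` is the initial SOC content against which fluxes are normalised. The
#' default of 1000 mg C per g SOC expresses all model output per unit SOC;
#' absolute per-gram-soil quantities are obtained downstream by multiplying by
#' the measured SOC concentration, never by refitting.
#'
#' The rate ordering `k1 > k2 > k3 > 0` is enforced so that pool labels are
#' identifiable (no label switching during MCMC) and per-pool attribution is
#' well defined.
#'
#' @param f1 fast-pool fraction of SOC (dimensionless, >= 0).
#' @param f2 slow-pool fraction of SOC; omit (`NULL`) for the two-pool model,
#'   where the slow fraction is `1 - f1`.
#' @param k1,k2,k3 first-order decay rates of the fast, slow and passive pools
#'   (per day); omit `k3` for the two-pool model.
#' @param c_tot initial SOC content (mg C per g SOC), fixed at 1000 by default.
#' @return An object of class `decay_params`.
#' @examples
#' three_pool <- decay_params(f1 = 0.01, f2 = 0.6, k1 = 0.02, k2 = 2e-4, k3 = 2e-6)
#' two_pool <- decay_params(f1 = 0.01, k1 = 0.02, k2 = 2e-4)
#' flux_rate(three_pool, t = c(0, 10, 80))
#' @export
decay_params <- function(f1, f2 = NULL, k1, k2, k3 = NULL, c_tot = 1000) {
  if (is.null(f2) != is.null(k3)) {
    stop("supply both `f2` and `k3` (three-pool) or neither (two-pool)")
  }
  n_pools <- if (is.null(k3)) 2L else 3L
  x <- structure(
    list(n_pools = n_pools, f1 = as.numeric(f1),
         f2 = if (n_pools == 3L) as.numeric(f2) else NULL,
         k1 = as.numeric(k1), k2 = as.numeric(k2),
         k3 = if (n_pools == 3L) as.numeric(k3) else NULL,
         c_tot = as.numeric(c_tot)),
    class = "decay_params")
  validate_decay_params(x)
  x
}

#' Validate decay-model parameters
#'
#' Checks the invariants of a [decay_params()] object and stops with a message
#' naming the first violated constraint.
#'
#' @param params a `decay_params` object.
#' @return `params`, invisibly, when valid.
#' @export
validate_decay_params <- function(params) {
  stopifnot(inherits(params, "decay_params"))
  chk <- function(ok, what) if (!isTRUE(ok)) stop("invalid decay_params: ", what, call. = FALSE)
  chk(is.finite(params$f1) && params$f1 >= 0, "f1 must be >= 0")
  chk(is.finite(params$k1) && params$k1 > 0, "k1 must be > 0")
  chk(is.finite(params$k2) && params$k2 > 0, "k2 must be > 0")
  chk(params$k1 > params$k2, "rate ordering k1 > k2 violated")
  if (params$n_pools == 3L) {
    chk(is.finite(params$f2) && params$f2 >= 0, "f2 must be >= 0")
    chk(params$f1 + params$f2 <= 1, "f1 + f2 must be <= 1")
    chk(is.finite(params$k3) && params$k3 > 0, "k3 must be > 0")
    chk(params$k2 > params$k3, "rate ordering k2 > k3 violated")
  } else {
    chk(params$f1 <= 1, "f1 must be <= 1 in the two-pool model")
  }
  chk(is.finite(params$c_tot) && params$c_tot > 0, "c_tot must be > 0")
  invisible(params)
}

#' @export
print.decay_params <- function(x, ...) {
  cat(sprintf("<decay_params: %d-pool model, c_tot = %g mg C g^-1 SOC>\n",
              x$n_pools, x$c_tot))
  pp <- pool_pars(x)
  out <- data.frame(pool = names(pp$f), fraction = pp$f, k_per_day = pp$k,
                    row.names = NULL)
  print(out, ...)
  invisible(x)
}

# per-pool fraction and rate vectors; the residual fraction is implied
pool_pars <- function(params) {
  if (params$n_pools == 3L) {
    list(f = c(fast = params$f1, slow = params$f2,
               passive = 1 - params$f1 - params$f2),
         k = c(fast = params$k1, slow = params$k2, passive = params$k3))
  } else {
    list(f = c(fast = params$f1, slow = 1 - params$f1),
         k = c(fast = params$k1, slow = params$k2))
  }
}

#' Instantaneous CO2-C emission rate
#'
#' Evaluates the modelled CO2-C emission rate
#' \deqn{R(t) = C_{tot}\,[f_1 k_1 e^{-k_1 t} + f_2 k_2 e^{-k_2 t} +
#'   (1 - f_1 - f_2) k_3 e^{-k_3 t}]}
#' (or the two-term analogue for the two-pool model) at one or more times.
#'
#' @param params a [decay_params()] object.
#' @param t time since the start of flux measurement (days, >= 0); vectorised.
#' @return Emission rate(s), mg C per g SOC per day.
#' @export
flux_rate <- function(params, t) {
  validate_decay_params(params)
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  pp <- pool_pars(params)
  rowSums(per_pool_flux(pp, t)) * params$c_tot
}

# matrix length(t) x n_pools of f_i k_i exp(-k_i t) (per unit c_tot)
per_pool_flux <- function(pp, t) {
  m <- matrix(vapply(seq_along(pp$k),
                     function(i) pp$f[i] * pp$k[i] * exp(-pp$k[i] * t),
                     numeric(length(t))),
              nrow = length(t))
  colnames(m) <- names(pp$k)
  m
}

#' Cumulative CO2-C release
#'
#' Closed-form time integral of [flux_rate()]:
#' \deqn{C_{cum}(t) = C_{tot}\,[f_1 (1 - e^{-k_1 t}) + f_2 (1 - e^{-k_2 t}) +
#'   (1 - f_1 - f_2)(1 - e^{-k_3 t})].}
#' Non-decreasing in `t` and bounded above by `c_tot` (mass conservation).
#' Uses `expm1()` so very slow pools (`k3 t` near machine precision) are
#' integrated accurately.
#'
#' @inheritParams flux_rate
#' @return Cumulative release(s), mg C per g SOC.
#' @export
cumulative_release <- function(params, t) {
  validate_decay_params(params)
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  pp <- pool_pars(params)
  rowSums(per_pool_cum(pp, t)) * params$c_tot
}

# matrix length(t) x n_pools of f_i (1 - exp(-k_i t)) (per unit c_tot)
per_pool_cum <- function(pp, t) {
  m <- matrix(vapply(seq_along(pp$k),
                     function(i) pp$f[i] * (-expm1(-pp$k[i] * t)),
                     numeric(length(t))),
              nrow = length(t))
  colnames(m) <- names(pp$k)
  m
}

#' Per-pool contribution to cumulative release
#'
#' Splits the cumulative CO2-C release at a horizon into the shares originating
#' from the fast, slow and passive pools. The shares are the per-pool
#' cumulative terms divided by their sum, so they always add to one.
#'
#' @param params a [decay_params()] object.
#' @param t horizon (days, strictly > 0; the ratio is 0/0 at `t = 0`).
#' @return A list of class `pool_attribution` with elements `horizon` (days),
#'   `cum_total` (mg C per g SOC) and `frac_fast`, `frac_slow`, `frac_passive`
#'   (dimensionless; `frac_passive` is 0 for the two-pool model).
#' @export
pool_contributions <- function(params, t) {
  validate_decay_params(params)
  t <- as.numeric(t)
  if (length(t) != 1L || !is.finite(t) || t <= 0) {
    stop("t must be a single finite value > 0 (per-pool shares are undefined at t = 0)")
  }
  pp <- pool_pars(params)
  per_pool <- per_pool_cum(pp, t)[1L, ] * params$c_tot
  total <- sum(per_pool)
  frac <- per_pool / total
  structure(
    list(horizon = t, cum_total = total,
         frac_fast = unname(frac[["fast"]]),
         frac_slow = unname(frac[["slow"]]),
         frac_passive = if (params$n_pools == 3L) unname(frac[["passive"]]) else 0),
    class = "pool_attribution")
}

#' @export
print.pool_attribution <- function(x, ...) {
  cat(sprintf(
    "<pool_attribution at %g d: total %.4g mg C g^-1 SOC; fast %.1f%%, slow %.1f%%, passive %.1f%%>\n",
    x$horizon, x$cum_total, 100 * x$frac_fast, 100 * x$frac_slow,
    100 * x$frac_passive))
  invisible(x)
}

#' Per-pool mean residence times
#'
#' The mean residence time (MRT) of a first-order pool is the reciprocal of its
#' decay rate, `1 / k` (days); years use a 365-day year.
#'
#' @param params a [decay_params()] object.
#' @return A data frame with columns `pool`, `k_per_day`, `mrt_days`,
#'   `mrt_years`.
#' @export
turnover_times <- function(params) {
  validate_decay_params(params)
  pp <- pool_pars(params)
  data.frame(pool = names(pp$k), k_per_day = unname(pp$k),
             mrt_days = unname(1 / pp$k),
             mrt_years = unname(1 / pp$k / 365))
}
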