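# Canonical parameter sets used across tests.

# well-separated three-pool set used in the closed-form examples
theta_example <- function() {
  decay_params(f1 = 0.01, f2 = 0.60, k1 = 0.02, k2 = 2e-4, k3 = 2e-6)
}

# the recovery truth: fast pool 0.8% of SOC with MRT ~0.34 yr
theta_recovery <- function() {
  decay_params(f1 = 0.008, f2 = 0.55, k1 = 0.0081, k2 = 1.5e-4, k3 = 1e-6)
}

# random valid three-pool parameters drawn log-uniformly over wide ranges
random_params <- function(n = 1) {
  draws <- lapply(seq_len(n), function(i) {
    repeat {
      f1 <- stats::runif(1, 0, 0.05)
      f2 <- stats::runif(1, 0, 0.9)
      k1 <- exp(stats::runif(1, log(1e-3), log(1)))
      k2 <- exp(stats::runif(1, log(1e-5), log(1e-3)))
      k3 <- exp(stats::runif(1, log(1e-8), log(1e-5)))
      p <- tryCatch(decay_params(f1, f2, k1, k2, k3), error = function(e) NULL)
      if (!is.null(p)) return(p)
    }
  })
  if (n == 1) draws[[1]] else draws
}

# numerical quadrature of flux_rate, split at the pools' decay scales so the
# adaptive rule resolves the fast transient (independent oracle for
# cumulative_release)
quadrature_release <- function(params, t) {
  cuts <- sort(unique(pmin(c(0, 1 / params$k1, 10 / params$k1, 100 / params$k1,
                             1 / params$k2, 10 / params$k2, 1 / params$k3, t),
                           t)))
  total <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    total <- total + stats::integrate(function(u) flux_rate(params, u),
                                      cuts[i], cuts[i + 1L],
                                      rel.tol = 1e-10,
                                      subdivisions = 2000L)$value
  }
  total
}

# one small noisy series for fitter tests
example_series <- function(seed = 1, noise_cv = 0.05,
                           schedule = default_schedule(), replicates = 3) {
  des <- cohort_design(schedule = schedule, noise_cv = noise_cv,
                       replicates = replicates)
  simulate_series(theta_recovery(), des, seed = seed)
}
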