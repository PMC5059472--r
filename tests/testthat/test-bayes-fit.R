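# Metropolis-Hastings fitter: likelihood identities, proposal contract,
# determinism, flat-target sampling and posterior summarisation.

test_that("log_likelihood matches hand-computed values and scaling laws", {
  p <- theta_example()
  tt <- default_schedule()
  # perfect fit: Z == X gives exactly 0
  perfect <- incubation_series("s", tt, flux_rate(p, tt), sigma = rep(0.01, length(tt)))
  expect_identical(log_likelihood(p, perfect), 0)

  # one observation, Z=1, X=0.5, sigma=0.5 -> -(0.5)^2 / (2 * 0.25) = -0.5
  p1 <- decay_params(f1 = 1, f2 = 0, k1 = 5e-4, k2 = 2e-4, k3 = 1e-6)
  x1 <- flux_rate(p1, 1)
  one <- incubation_series("s", c(1, 2), c(x1 + 0.5, flux_rate(p1, 2)),
                           sigma = c(0.5, 0.5))
  expect_equal(log_likelihood(p1, one), -0.5, tolerance = 1e-12)

  # halving every sigma with residuals fixed multiplies the value by 4
  ser <- example_series(seed = 3)
  ll1 <- log_likelihood(p, ser)
  ser2 <- ser
  ser2$sigma <- ser$sigma / 2
  expect_equal(log_likelihood(p, ser2), 4 * ll1, tolerance = 1e-12)
  expect_lte(ll1, 0)
})

test_that("R and C++ likelihood paths agree on random inputs", {
  set.seed(11)
  for (i in 1:10) {
    p <- random_params()
    ser <- simulate_series(p, cohort_design(noise_cv = 0.1))
    theta <- c(p$f1, p$f2, p$k1, p$k2, p$k3)
    expect_equal(socpools:::cpp_loglik(theta, p$c_tot, ser$times, ser$rates,
                                       ser$sigma),
                 log_likelihood(p, ser), tolerance = 1e-12)
  }
})

test_that("propose_params respects the box, degenerates and is seed-stable", {
  prior <- default_prior("three_pool")
  theta <- (prior$lower + prior$upper) / 2

  # vanishing step: proposal collapses onto the current state
  tiny <- propose_params(theta, prior, step_fraction = 1e-12)
  expect_equal(unname(tiny), unname(theta), tolerance = 1e-9)

  # large jumps always land inside the box and satisfy the constraints
  set.seed(5)
  cur <- theta
  for (i in 1:500) {
    cur <- propose_params(cur, prior, step_fraction = 0.8)
    expect_true(all(cur >= prior$lower & cur <= prior$upper))
    expect_true(cur[["f1"]] + cur[["f2"]] <= 1)
    expect_true(cur[["k1"]] > cur[["k2"]] && cur[["k2"]] > cur[["k3"]])
  }

  # fixed seed reproduces the proposal sequence exactly
  seq1 <- {
    set.seed(9); replicate(20, propose_params(theta, prior, 0.1))
  }
  seq2 <- {
    set.seed(9); replicate(20, propose_params(theta, prior, 0.1))
  }
  expect_identical(seq1, seq2)

  expect_error(propose_params(theta, prior, step_fraction = 0), "step_fraction")
  expect_error(propose_params(prior$upper * 2, prior), "inside the prior")
})

test_that("fit_decay_model is bitwise reproducible given a seed", {
  ser <- example_series(seed = 2)
  ch1 <- fit_decay_model(ser, "three_pool", n_iter = 15000, n_burn = 3000,
                         thin = 10, seed = 7)
  ch2 <- fit_decay_model(ser, "three_pool", n_iter = 15000, n_burn = 3000,
                         thin = 10, seed = 7)
  expect_identical(ch1$draws, ch2$draws)
  expect_identical(ch1$loglik, ch2$loglik)
  expect_identical(ch1$acceptance_rate, ch2$acceptance_rate)
})

test_that("all stored draws satisfy the parameter invariants", {
  ser <- example_series(seed = 4)
  ch <- fit_decay_model(ser, "three_pool", n_iter = 20000, n_burn = 4000,
                        seed = 1)
  d <- ch$draws
  expect_true(all(d[, "f1"] >= 0 & d[, "f2"] >= 0))
  expect_true(all(d[, "f1"] + d[, "f2"] <= 1))
  expect_true(all(d[, "k1"] > d[, "k2"] & d[, "k2"] > d[, "k3"] & d[, "k3"] > 0))
  expect_true(all(d >= rep(ch$prior$lower, each = nrow(d)) &
                  d <= rep(ch$prior$upper, each = nrow(d))))
  expect_true(all(is.finite(ch$loglik)))
  expect_gt(ch$acceptance_rate, 0)
})

test_that("a flat likelihood reproduces the uniform prior", {
  # sigma so large the likelihood is constant: acceptance ~1 and every
  # marginal indistinguishable from uniform over its prior interval
  ser <- example_series(seed = 5)
  ser$sigma[] <- 1e6
  ch <- fit_decay_model(ser, "three_pool", n_iter = 110000, n_burn = 10000,
                        thin = 20, step_fraction = 0.5, seed = 2)
  expect_gt(ch$acceptance_rate, 0.99)
  prior <- ch$prior
  for (p in colnames(ch$draws)) {
    u <- (ch$draws[, p] - prior$lower[[p]]) / (prior$upper[[p]] - prior$lower[[p]])
    expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
    # chi-square goodness of fit, 20 bins
    counts <- tabulate(ceiling(u * 20), nbins = 20)
    expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  }
})

test_that("noiseless recovery: highest-likelihood draw lands on the truth", {
  truth <- theta_recovery()
  ser <- simulate_series(truth, cohort_design(noise_cv = 0), seed = 1)
  ch <- fit_decay_model(ser, "three_pool", n_iter = 100000, n_burn = 20000,
                        thin = 10, seed = 1)
  mle <- ch$draws[which.max(ch$loglik), ]
  expect_lt(abs(mle[["f1"]] - truth$f1) / truth$f1, 0.05)
  expect_lt(abs(mle[["k1"]] - truth$k1) / truth$k1, 0.05)

  # sharply peaked interior marginals are flagged constrained and summarised
  # by MLE; k1 sits at 0.8% of its wide prior range, inside the conservative
  # 5% edge zone, so the edge rule deliberately reports it unconstrained
  ps <- summarize_posterior(ch)
  expect_true(ps$constrained[ps$parameter == "f1"])
  expect_identical(ps$rule[ps$parameter == "f1"], "mle")
  expect_false(ps$constrained[ps$parameter == "k1"])
  expect_true(all(ps$rule[ps$constrained] == "mle"))
  expect_true(all(ps$estimate >= ps$q2.5 - 1e-12 & ps$estimate <= ps$q97.5 + 1e-12))
})

test_that("summarize_posterior falls back to the mean for flat marginals", {
  ser <- example_series(seed = 6)
  ser$sigma[] <- 1e6
  ch <- fit_decay_model(ser, "three_pool", n_iter = 60000, n_burn = 10000,
                        thin = 5, step_fraction = 0.5, seed = 3)
  ps <- summarize_posterior(ch)
  expect_true(all(!ps$constrained))
  expect_true(all(ps$rule == "mean"))
  prior <- ch$prior
  mid <- (prior$lower + prior$upper) / 2
  rng <- prior$upper - prior$lower
  expect_true(all(abs(ps$estimate - mid[ps$parameter]) < 0.1 * rng[ps$parameter]))
})

test_that("fitting inputs are validated", {
  ser <- example_series(seed = 1)
  expect_error(fit_decay_model(ser, "three_pool", n_iter = 100, n_burn = 200),
               "n_iter > n_burn")
  expect_error(fit_decay_model(ser, "three_pool", step_fraction = -1),
               "step_fraction")
  expect_error(fit_decay_model(ser, "three_pool",
                               prior = default_prior("two_pool")),
               "prior box is for model")
  short <- incubation_series("s", c(1, 3, 5, 7), c(1, 0.9, 0.8, 0.7),
                             sigma = rep(0.05, 4))
  expect_error(fit_decay_model(short, "three_pool"), ">= 6")
  ch <- fit_decay_model(ser, "three_pool", n_iter = 6000, n_burn = 1000, seed = 1)
  expect_error(summarize_posterior(ch), "stored draws")
})

test_that("chain CSV round trip preserves draws and log-likelihoods", {
  ser <- example_series(seed = 2)
  ch <- fit_decay_model(ser, "three_pool", n_iter = 21000, n_burn = 1000,
                        thin = 20, seed = 4)
  path <- tempfile(fileext = ".csv")
  write_chain_csv(ch, path)
  back <- read_chain_csv(path)
  expect_equal(as.matrix(back[, colnames(ch$draws)]), ch$draws,
               ignore_attr = TRUE)
  expect_equal(back$loglik, ch$loglik)
})

test_that("multi-seed Gelman-Rubin diagnostic is near one for a peaked posterior", {
  ser <- simulate_series(theta_recovery(), cohort_design(noise_cv = 0), seed = 2)
  rhat <- gelman_rubin(ser, "three_pool", seeds = 1:3, n_iter = 30000,
                       n_burn = 10000, thin = 10)
  expect_named(rhat, c("f1", "f2", "k1", "k2", "k3"))
  expect_true(all(is.finite(rhat)) && all(rhat > 0.8))
})
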