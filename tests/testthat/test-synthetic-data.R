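# Synthetic cohort generator: schedules, truth draws, noise model and the
# full cohort tables.

test_that("the canonical schedule follows the stated spacing rules", {
  s <- default_schedule()
  expect_length(s, 15)
  expect_equal(min(s), 1)
  expect_equal(max(s), 80)
  gaps <- diff(s)
  expect_true(all(gaps[s[-length(s)] < 7] <= 2))
  expect_true(all(gaps[s[-length(s)] >= 7] >= 5 & gaps[s[-length(s)] >= 7] <= 8))

  long <- extended_schedule(390)
  expect_equal(max(long), 390)
  expect_identical(long[1:15], s)
  expect_false(is.unsorted(long, strictly = TRUE))
})

test_that("draw_parameters yields valid, seed-stable, layer-shifted truths", {
  prior <- default_prior("three_pool")
  set.seed(41)
  for (i in 1:200) {
    p <- draw_parameters(prior, sample(c("active_layer", "permafrost"), 1))
    expect_s3_class(p, "decay_params") # constructor enforces all invariants
    th <- c(f1 = p$f1, f2 = p$f2, k1 = p$k1, k2 = p$k2, k3 = p$k3)
    expect_true(all(th >= prior$lower & th <= prior$upper))
  }

  expect_identical(draw_parameters(prior, "permafrost", seed = 5),
                   draw_parameters(prior, "permafrost", seed = 5))

  set.seed(42)
  f1_al <- replicate(1000, draw_parameters(prior, "active_layer")$f1)
  f1_pf <- replicate(1000, draw_parameters(prior, "permafrost")$f1)
  expect_gt(mean(f1_pf), mean(f1_al))
})

test_that("simulate_series implements the multiplicative noise model", {
  p <- theta_recovery()
  # noiseless limit: observations equal the closed-form flux exactly
  ser0 <- simulate_series(p, cohort_design(noise_cv = 0), seed = 1)
  expect_equal(ser0$rates[, 1], flux_rate(p, ser0$times), tolerance = 1e-12)
  expect_equal(ser0$rates[, 2], ser0$rates[, 3], tolerance = 1e-12)

  # determinism
  expect_identical(simulate_series(p, cohort_design(), seed = 9)$rates,
                   simulate_series(p, cohort_design(), seed = 9)$rates)

  # law of large numbers: replicate mean at each time approaches the truth
  des <- cohort_design(replicates = 10000, noise_cv = 0.05)
  big <- simulate_series(p, des, seed = 2)
  truth <- flux_rate(p, big$times)
  mc_se <- 0.05 * truth / sqrt(10000)
  expect_true(all(abs(big$mean_rates - truth) < 3 * mc_se))

  # sigma floor applies when noise is off
  expect_true("sigma_floored" %in% ser0$qc_flags)
  expect_true(all(ser0$sigma >= pmax(0.05 * ser0$mean_rates, 1e-4) - 1e-15))
})

test_that("simulate_headspace inverts the flux conversion", {
  p <- theta_example()
  des <- cohort_design(noise_cv = 0, replicates = 1)
  tmpl <- jar_template(moisture_frac = 0.25, ppm_start = 400)
  hs <- simulate_headspace(p, tmpl, des, seed = 1)
  back <- headspace_to_flux(hs)
  expect_equal(back$rate_ugC_gSOC_d, flux_rate(p, des$schedule) * 1000,
               tolerance = 1e-9)
  # a positive flux always raises the concentration above the
  # dilution-corrected start
  dry <- tmpl$soil_fresh_g * (1 - tmpl$moisture_frac)
  v <- tmpl$jar_ml - dry / 1.3
  expect_true(all(hs$ppm_end > tmpl$ppm_start * (v - 10) / v))
  expect_identical(simulate_headspace(p, tmpl, des, seed = 3),
                   simulate_headspace(p, tmpl, des, seed = 3))
})

test_that("make_cohort produces the designed layout and a truthful truth table", {
  co <- make_cohort(seed = 1)
  # 5 sites x 2 layers x 2 temperatures = 20 samples
  expect_equal(nrow(co$truth), 20)
  expect_equal(length(unique(co$flux$sample_id)), 20)
  # 30 replicate jar series per temperature (10 samples x 3 replicates)
  for (temp in c(-5, 5)) {
    sub <- co$flux[co$flux$temperature_C == temp, ]
    expect_equal(nrow(unique(sub[, c("sample_id", "replicate")])), 30)
    expect_equal(nrow(sub), 30 * length(default_schedule()))
  }
  # truth values live inside the prior box and honour the invariants
  prior <- default_prior("three_pool")
  for (i in seq_len(nrow(co$truth))) {
    tr <- co$truth[i, ]
    p <- decay_params(tr$f1, tr$f2, tr$k1, tr$k2, tr$k3)
    expect_true(all(c(tr$f1, tr$f2, tr$k1, tr$k2, tr$k3) >= prior$lower &
                    c(tr$f1, tr$f2, tr$k1, tr$k2, tr$k3) <= prior$upper))
  }
  # sub-zero samples carry the documented rate scaling relative to their
  # 5-degree sibling
  warm <- co$truth[co$truth$temperature_C == 5, ]
  cold <- co$truth[co$truth$temperature_C == -5, ]
  key <- function(d) paste(d$site, d$layer)
  cold <- cold[match(key(warm), key(cold)), ]
  expect_equal(cold$k1, warm$k1 * 0.25, tolerance = 1e-12)

  # the flux table round-trips into fit-ready series
  series <- build_series(co$flux)
  expect_length(series, 20)
  expect_s3_class(series[[1]], "incubation_series")
  expect_equal(series[[1]]$times, default_schedule())
})
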