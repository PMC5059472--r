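# Headspace-to-flux conversion, series assembly and observed cumulative
# release.

worked_record <- function(...) {
  rec <- list(sample_id = "s1", replicate = 1, day = 1, jar_ml = 250,
              soil_fresh_g = 20, moisture_frac = 0, soc_g_per_kg = 50,
              temperature_C = 5, pressure_kpa = 101.325, ppm_start = 0,
              ppm_end = 500, window_h = 48)
  utils::modifyList(rec, list(...))
}

test_that("the ideal-gas worked example converts to ~32.9 ug C g^-1 SOC d^-1", {
  fx <- headspace_to_flux(worked_record(), solids_density = Inf)
  # independent hand computation: n_air = PV/RT = 0.010953 mol;
  # 500 ppm * n_air * 12.011 g/mol = 65.78 ug C over 2 days in 1 g SOC
  n_air <- 101325 * 250e-6 / (8.31446 * 278.15)
  by_hand <- 500e-6 * n_air * 12.011 * 1e6 / (20 * 50 / 1000) / 2
  expect_equal(fx$rate_ugC_gSOC_d, by_hand, tolerance = 1e-12)
  expect_equal(fx$rate_ugC_gSOC_d, 32.89, tolerance = 1e-4)
  # dry-soil normalisation differs by the SOC concentration factor
  expect_equal(fx$rate_ugC_gSOC_d, fx$rate_ugC_gdw_d * 1000 / 50,
               tolerance = 1e-12)
})

test_that("flux conversion obeys its scaling laws", {
  base <- headspace_to_flux(worked_record())

  # zero concentration change -> zero rate
  zero <- headspace_to_flux(worked_record(ppm_end = 0))
  expect_equal(zero$rate_ugC_gSOC_d, 0)

  # doubling SOC halves the SOC-normalised rate, leaves the dry-soil rate
  dbl <- headspace_to_flux(worked_record(soc_g_per_kg = 100))
  expect_equal(dbl$rate_ugC_gSOC_d, base$rate_ugC_gSOC_d / 2, tolerance = 1e-12)
  expect_equal(dbl$rate_ugC_gdw_d, base$rate_ugC_gdw_d, tolerance = 1e-12)

  # linear in delta-ppm, inverse-linear in window length
  set.seed(21)
  for (i in 1:20) {
    rec <- worked_record(jar_ml = stats::runif(1, 150, 500),
                         soil_fresh_g = stats::runif(1, 10, 40),
                         moisture_frac = stats::runif(1, 0, 0.5),
                         ppm_start = stats::runif(1, 0, 200),
                         ppm_end = stats::runif(1, 300, 1200),
                         window_h = stats::runif(1, 12, 96),
                         temperature_C = stats::runif(1, -5, 25))
    f1 <- headspace_to_flux(rec)
    # scale the concentration increase by 3: rate scales by 3
    corr <- (rec$jar_ml - (rec$soil_fresh_g * (1 - rec$moisture_frac)) / 1.3)
    ppm0 <- rec$ppm_start * (corr - 10) / corr
    rec3 <- rec
    rec3$ppm_end <- ppm0 + 3 * (rec$ppm_end - ppm0)
    expect_equal(headspace_to_flux(rec3)$rate_ugC_gSOC_d,
                 3 * f1$rate_ugC_gSOC_d, tolerance = 1e-9)
    rec4 <- rec
    rec4$window_h <- rec$window_h * 2
    expect_equal(headspace_to_flux(rec4)$rate_ugC_gSOC_d,
                 f1$rate_ugC_gSOC_d / 2, tolerance = 1e-12)
  }

  # a concentration decrease is carried through negative and flagged
  neg <- headspace_to_flux(worked_record(ppm_start = 600, ppm_end = 400),
                           correct_dilution = FALSE)
  expect_lt(neg$rate_ugC_gSOC_d, 0)
  expect_equal(neg$qc_flags, "negative_flux")

  expect_error(headspace_to_flux(worked_record(jar_ml = -1)), "jar_ml")
  rec_bad <- worked_record()
  rec_bad$ppm_end <- NULL
  expect_error(headspace_to_flux(rec_bad), "ppm_end")
})

test_that("build_series assembles replicate matrices with the sigma floor", {
  flux <- data.frame(sample_id = "a", replicate = rep(1:3, each = 2),
                     site = "s", layer = "permafrost", temperature_C = 5,
                     day = rep(c(2, 4), 3),
                     rate_ugC_gSOC_d = c(1, 10, 2, 10, 3, 10))
  ser <- build_series(flux)[["a"]]
  expect_equal(ser$times, c(2, 4))
  # day 2 replicates (1,2,3) ug -> mean 0.002 mg, sd 0.001 mg (above floor)
  expect_equal(ser$mean_rates[1], 0.002)
  expect_equal(ser$sigma[1], 0.001)
  # identical replicates at day 4 -> floored at 5% of the mean, flagged
  expect_equal(ser$sigma[2], 0.05 * 0.01)
  expect_true("sigma_floored" %in% ser$qc_flags)

  # a missing replicate is tolerated and flagged
  ser2 <- build_series(flux[-1, ])[["a"]]
  expect_equal(ser2$mean_rates[1], 0.0025)
  expect_true(any(grepl("n_replicates=2", ser2$qc_flags)))

  # duplicate (replicate, day) rows are rejected
  expect_error(build_series(rbind(flux, flux[1, ])), "duplicate")
  expect_error(build_series(flux[, -1]), "sample_id")
})

test_that("observed_cumulative is trapezoidal with a leading rectangle", {
  # constant rate r over T days integrates to r * T
  ser <- incubation_series("c", c(2, 4, 6), rep(0.5, 3), sigma = rep(0.01, 3))
  expect_equal(observed_cumulative(ser), 0.5 * 6)

  # two points: leading rectangle + one trapezoid
  ser2 <- incubation_series("t", c(2, 5), c(0.4, 0.2), sigma = rep(0.01, 2))
  expect_equal(observed_cumulative(ser2), 0.4 * 2 + (0.4 + 0.2) / 2 * 3)

  # dense sampling of the closed-form flux reproduces cumulative_release
  p <- theta_example()
  tt <- seq(0.1, 80, by = 0.1)
  dense <- incubation_series("d", tt, flux_rate(p, tt),
                             sigma = rep(1e-3, length(tt)))
  expect_equal(observed_cumulative(dense), cumulative_release(p, 80),
               tolerance = 1e-3)
})

test_that("flux and headspace CSV round trips preserve the tables", {
  co <- make_cohort(cohort_design(n_sites = 1, temperatures = 5), seed = 3)
  dir <- tempfile()
  paths <- write_cohort(co, dir)
  flux_back <- read_flux_csv(paths[["flux"]])
  expect_equal(flux_back, co$flux, tolerance = 1e-12, ignore_attr = TRUE)
  head_back <- read_headspace_csv(paths[["headspace"]])
  expect_equal(head_back, co$headspace, tolerance = 1e-12, ignore_attr = TRUE)

  # missing required column is reported by name
  broken <- co$flux[, setdiff(names(co$flux), "day")]
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(broken, tmp, row.names = FALSE)
  expect_error(read_flux_csv(tmp), "day")
})
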