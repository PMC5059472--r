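#' Canonical 80-day measurement schedule
#'
#' The fixed measurement schedule the generator (and the recovery experiments)
#' use: every 2 days up to day 7, then every 5-8 days out to day 80.
#'
#' @return Integer vector of measurement days.
#' @export
default_schedule <- function() {
  c(1, 3, 5, 7, 13, 19, 26, 33, 40, 47, 54, 61, 68, 75, 80)
}

#' Extended long-incubation schedule
#'
#' The 80-day schedule continued at a 15-day spacing out to `total_days`
#' (default 390). Used for identifiability experiments on how incubation
#' length constrains the slow and passive pools.
#'
#' @param total_days last measurement day (> 80).
#' @param spacing spacing of the added measurements (days).
#' @return Integer vector of measurement days.
#' @export
extended_schedule <- function(total_days = 390, spacing = 15) {
  if (total_days <= 80) stop("total_days must exceed 80")
  c(default_schedule(), seq(80 + 10, total_days, by = spacing))
}

#' Synthetic-cohort design
#'
#' Describes the incubation cohort the generator emulates: by default 5 sites
#' x 2 soil layers (active layer, permafrost) x 3 replicate jars x 2
#' incubation temperatures (-5 and 5 degrees C) on the canonical 80-day
#' schedule, with multiplicative Gaussian measurement noise of coefficient of
#' variation `noise_cv`.
#'
#' @param n_sites number of sites (default 5).
#' @param layers soil layers (default active layer and permafrost).
#' @param replicates replicate jars per sample (default 3).
#' @param temperatures incubation temperatures, degrees C (default `c(-5, 5)`).
#' @param schedule measurement days (default [default_schedule()]).
#' @param noise_cv coefficient of variation of the multiplicative measurement
#'   noise (default 0.05).
#' @param sigma_floor absolute floor on the stored per-time s.d. (mg C g^-1
#'   SOC d^-1, default 1e-4).
#' @param cold_rate_scale factor applied to all decay rates for sub-zero
#'   incubation temperatures, emulating the temperature limitation of
#'   decomposition (default 0.25; no mechanistic temperature response is
#'   modelled).
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_sites = 5, layers = c("active_layer", "permafrost"),
                          replicates = 3, temperatures = c(-5, 5),
                          schedule = default_schedule(), noise_cv = 0.05,
                          sigma_floor = 1e-4, cold_rate_scale = 0.25) {
  if (replicates < 1) stop("replicates must be >= 1")
  if (is.unsorted(schedule, strictly = TRUE) || any(schedule <= 0)) {
    stop("schedule must be strictly increasing with days > 0")
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(list(n_sites = n_sites, layers = layers, replicates = replicates,
                 temperatures = temperatures, schedule = schedule,
                 noise_cv = noise_cv, sigma_floor = sigma_floor,
                 cold_rate_scale = cold_rate_scale),
            class = "cohort_design")
}

# Truth-generating ranges for the synthetic cohort, chosen once to match the
# reported pool structure of upland permafrost incubations: fast pool under 1%
# of SOC with a mean residence time near 0.34 yr (k1 ~ 1/124 d^-1), a slow
# pool of roughly half of SOC turning over in decades of incubation time, and
# a passive remainder. Permafrost draws get larger fast/slow pools than the
# active layer.
truth_ranges <- function(layer) {
  if (identical(layer, "permafrost")) {
    list(f1 = c(0.006, 0.016), f2 = c(0.50, 0.70))
  } else {
    list(f1 = c(0.003, 0.010), f2 = c(0.45, 0.60))
  }
}
TRUTH_K_RANGES <- list(k1 = c(0.005, 0.012), k2 = c(1e-4, 2.5e-4),
                       k3 = c(5e-7, 5e-6))

#' Draw a true parameter set for a synthetic sample
#'
#' Rejection-samples a three-pool truth uniformly over a layer-specific
#' sub-box of the prior (see Details), retrying until the joint constraints
#' (`f1 + f2 <= 1`, rate ordering) hold. Permafrost draws have larger fast-
#' and slow-pool fractions on average than active-layer draws.
#'
#' The sub-box, intersected with `prior`, spans `f1` in 0.3-1.6% of SOC,
#' `f2` in 45-70%, `k1` in 0.005-0.012 d^-1 (fast-pool MRT roughly 0.23-0.55
#' yr), `k2` in 1-2.5e-4 d^-1 and `k3` in 5e-7 to 5e-6 d^-1.
#'
#' @param prior a three-pool [prior_box()]; draws are truncated to it.
#' @param layer `"active_layer"` or `"permafrost"`.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (so cohort generation consumes one stream).
#' @param c_tot initial SOC content (mg C per g SOC).
#' @return A [decay_params()] object.
#' @export
draw_parameters <- function(prior = default_prior("three_pool"),
                            layer = c("active_layer", "permafrost"),
                            seed = NULL, c_tot = 1000) {
  layer <- match.arg(layer)
  if (prior$model != "three_pool") stop("draw_parameters needs a three-pool prior")
  if (!is.null(seed)) set.seed(as.integer(seed))
  rg <- c(truth_ranges(layer), TRUTH_K_RANGES)
  for (p in names(rg)) { # truncate to the prior box
    rg[[p]] <- c(max(rg[[p]][1], prior$lower[[p]]),
                 min(rg[[p]][2], prior$upper[[p]]))
    if (rg[[p]][1] >= rg[[p]][2]) {
      stop("prior box leaves no room for the '", p, "' truth range")
    }
  }
  for (i in seq_len(1000L)) {
    th <- vapply(rg, function(b) stats::runif(1, b[1], b[2]), numeric(1))
    ok <- tryCatch({
      theta_to_params(th, "three_pool", c_tot)
    }, error = function(e) NULL)
    if (!is.null(ok)) return(ok)
  }
  stop("could not draw a feasible parameter set after 1000 attempts; widen the prior")
}

#' Simulate an observed incubation series
#'
#' Generates replicate observations on the design schedule by inverting the
#' fitting model's noise assumption: `Z_i(t) = R(t) * (1 + e)` with
#' `e ~ Normal(0, noise_cv)`, independently per replicate and time. Negative
#' draws are truncated at zero (an aerobic jar cannot take up CO2) and the
#' series flagged `"truncated_zero"`. The stored per-time s.d. is the
#' replicate standard deviation under the usual floor rule.
#'
#' @param params the true [decay_params()].
#' @param design a [cohort_design()].
#' @param seed optional integer seed (`NULL` uses the current RNG stream).
#' @param sample_id,site,layer,temperature series metadata.
#' @return An [incubation_series()]; the generating `params` travel in
#'   `attr(, "truth")`.
#' @export
simulate_series <- function(params, design = cohort_design(), seed = NULL,
                            sample_id = "synthetic", site = NA_character_,
                            layer = NA_character_, temperature = NA_real_) {
  stopifnot(inherits(design, "cohort_design"))
  validate_decay_params(params)
  if (!is.null(seed)) set.seed(as.integer(seed))
  tt <- design$schedule
  truth <- flux_rate(params, tt)
  z <- matrix(truth, nrow = length(tt), ncol = design$replicates) *
    (1 + matrix(stats::rnorm(length(tt) * design$replicates, 0, design$noise_cv),
                nrow = length(tt)))
  truncated <- any(z < 0)
  z[z < 0] <- 0
  ser <- incubation_series(sample_id = sample_id, times = tt, rates = z,
                           site = site, layer = layer,
                           temperature = temperature,
                           sigma_floor_abs = design$sigma_floor)
  if (truncated) ser$qc_flags <- union(ser$qc_flags, "truncated_zero")
  attr(ser, "truth") <- params
  ser
}

#' Default jar template for headspace simulation
#'
#' @param jar_ml jar volume (mL). @param soil_fresh_g fresh soil mass (g).
#' @param moisture_frac water fraction of fresh mass.
#' @param soc_g_per_kg SOC concentration (g C per kg dry soil).
#' @param temperature_C incubation temperature. @param pressure_kpa ambient
#'   pressure. @param ppm_start headspace CO2 after flushing (ppm).
#' @param window_h accumulation window (hours).
#' @return A list usable as the `template` of [simulate_headspace()].
#' @export
jar_template <- function(jar_ml = 250, soil_fresh_g = 20, moisture_frac = 0.2,
                         soc_g_per_kg = 50, temperature_C = 5,
                         pressure_kpa = STANDARD_PRESSURE_KPA, ppm_start = 0,
                         window_h = 48) {
  list(jar_ml = jar_ml, soil_fresh_g = soil_fresh_g,
       moisture_frac = moisture_frac, soc_g_per_kg = soc_g_per_kg,
       temperature_C = temperature_C, pressure_kpa = pressure_kpa,
       ppm_start = ppm_start, window_h = window_h)
}

#' Simulate raw headspace records
#'
#' Inverts [headspace_to_flux()]: computes, for every schedule day and
#' replicate, the end-of-window CO2 concentration that the true flux would
#' produce in the template jar, perturbs it with multiplicative noise of
#' coefficient of variation `design$noise_cv` on the concentration increase,
#' and emits records in the headspace CSV dialect. A noiseless round trip
#' through [headspace_to_flux()] recovers the true rate exactly (to floating
#' point).
#'
#' @param params the true [decay_params()].
#' @param template a [jar_template()].
#' @param design a [cohort_design()].
#' @param seed optional integer seed.
#' @param sample_id,site,layer sample metadata.
#' @param solids_density,sample_gas_volume,correct_dilution conversion options
#'   mirrored from [headspace_to_flux()].
#' @return A data frame in the headspace CSV dialect.
#' @export
simulate_headspace <- function(params, template = jar_template(),
                               design = cohort_design(), seed = NULL,
                               sample_id = "synthetic", site = NA_character_,
                               layer = NA_character_,
                               solids_density = DEFAULT_SOLIDS_DENSITY,
                               sample_gas_volume = 10,
                               correct_dilution = TRUE) {
  validate_decay_params(params)
  if (!is.null(seed)) set.seed(as.integer(seed))
  tt <- design$schedule
  rate_soc_ug <- flux_rate(params, tt) * 1000 # mg -> ug C g^-1 SOC d^-1
  dry_g <- template$soil_fresh_g * (1 - template$moisture_frac)
  soc_g <- dry_g * template$soc_g_per_kg / 1000
  v_ml <- template$jar_ml - dry_g / solids_density
  n_air <- (template$pressure_kpa * 1000) * (v_ml * 1e-6) /
    (GAS_CONSTANT * (template$temperature_C + 273.15))
  ppm0 <- if (correct_dilution) {
    template$ppm_start * (v_ml - sample_gas_volume) / v_ml
  } else template$ppm_start
  window_d <- template$window_h / 24
  rows <- lapply(seq_len(design$replicates), function(r) {
    mass_ug <- rate_soc_ug * soc_g * window_d
    d_ppm <- mass_ug / (MOLAR_MASS_C * 1e6) / n_air * 1e6
    d_ppm <- d_ppm * (1 + stats::rnorm(length(tt), 0, design$noise_cv))
    data.frame(sample_id = sample_id, replicate = r, site = site,
               layer = layer, temperature_C = template$temperature_C,
               day = tt, jar_ml = template$jar_ml,
               soil_fresh_g = template$soil_fresh_g,
               moisture_frac = template$moisture_frac,
               soc_g_per_kg = template$soc_g_per_kg,
               pressure_kpa = template$pressure_kpa,
               ppm_start = template$ppm_start,
               ppm_end = pmax(ppm0 + d_ppm, 0), window_h = template$window_h,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a full synthetic incubation cohort
#'
#' Draws a true parameter set per sample (site x layer x temperature), then
#' simulates the flux-dialect table, the matching raw headspace table and the
#' truth table. With the default design this yields 10 samples per temperature
#' (5 sites x 2 layers), i.e. 30 replicate jar series per temperature. For
#' sub-zero temperatures all decay rates are scaled by
#' `design$cold_rate_scale` before simulation, and the scaled (effective)
#' rates are what the truth table records.
#'
#' @param design a [cohort_design()].
#' @param prior a three-pool [prior_box()] bounding the truths.
#' @param seed integer seed for the whole cohort.
#' @param template a [jar_template()] for the headspace table.
#' @return A list of class `synthetic_cohort` with data frames `flux`
#'   (flux dialect), `headspace` (headspace dialect), `truth` (`sample_id`,
#'   `site`, `layer`, `temperature_C`, `f1`, `f2`, `k1`, `k2`, `k3`) and the
#'   `design`.
#' @export
make_cohort <- function(design = cohort_design(),
                        prior = default_prior("three_pool"), seed = 1L,
                        template = jar_template()) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(as.integer(seed))
  flux <- list(); head <- list(); truth <- list()
  for (s in seq_len(design$n_sites)) {
    site <- sprintf("site%02d", s)
    for (layer in design$layers) {
      base <- draw_parameters(prior, layer)
      for (temp in design$temperatures) {
        scale <- if (temp < 0) design$cold_rate_scale else 1
        prm <- decay_params(f1 = base$f1, f2 = base$f2, k1 = base$k1 * scale,
                            k2 = base$k2 * scale, k3 = base$k3 * scale,
                            c_tot = base$c_tot)
        id <- sprintf("%s_%s_T%+d", site, abbreviate_layer(layer), as.integer(temp))
        ser <- simulate_series(prm, design, sample_id = id, site = site,
                               layer = layer, temperature = temp)
        flux[[id]] <- series_to_flux_rows(ser)
        tmpl <- template
        tmpl$temperature_C <- temp
        head[[id]] <- simulate_headspace(prm, tmpl, design, sample_id = id,
                                         site = site, layer = layer)
        truth[[id]] <- data.frame(sample_id = id, site = site, layer = layer,
                                  temperature_C = temp, f1 = prm$f1,
                                  f2 = prm$f2, k1 = prm$k1, k2 = prm$k2,
                                  k3 = prm$k3, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(flux = do.call(rbind, c(flux, make.row.names = FALSE)),
                 headspace = do.call(rbind, c(head, make.row.names = FALSE)),
                 truth = do.call(rbind, c(truth, make.row.names = FALSE)),
                 design = design),
            class = "synthetic_cohort")
}

abbreviate_layer <- function(layer) {
  c(active_layer = "AL", permafrost = "PF")[[layer]]
}

# one flux-dialect row per replicate x day
series_to_flux_rows <- function(series) {
  reps <- seq_len(ncol(series$rates))
  do.call(rbind, lapply(reps, function(r) {
    data.frame(sample_id = series$sample_id, replicate = r,
               site = series$site, layer = series$layer,
               temperature_C = series$temperature, day = series$times,
               rate_ugC_gSOC_d = series$rates[, r] * 1000,
               stringsAsFactors = FALSE)
  }))
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `flux.csv`, `headspace.csv` and `truth.csv` into `dir`.
#'
#' @param cohort a `synthetic_cohort` from [make_cohort()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(flux = file.path(dir, "flux.csv"),
             headspace = file.path(dir, "headspace.csv"),
             truth = file.path(dir, "truth.csv"))
  utils::write.csv(cohort$flux, paths[["flux"]], row.names = FALSE)
  utils::write.csv(cohort$headspace, paths[["headspace"]], row.names = FALSE)
  utils::write.csv(cohort$truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}
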