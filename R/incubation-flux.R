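# Physical constants used throughout the flux conversion. Kept in one place so
# unit round trips are bit-stable.
GAS_CONSTANT <- 8.31446      # J mol^-1 K^-1
MOLAR_MASS_C <- 12.011       # g mol^-1
STANDARD_PRESSURE_KPA <- 101.325
DEFAULT_SOLIDS_DENSITY <- 1.3 # g cm^-3, assumed soil solids bulk density

#' Convert jar-headspace CO2 concentration changes to flux rates
#'
#' Ideal-gas conversion of a sealed-jar headspace measurement window into a
#' CO2-C release rate. The effective headspace volume is the jar volume minus
#' the soil volume (dry mass / `solids_density`; set `solids_density = Inf` to
#' ignore the correction). Moles of headspace air are `P V / (R T)`; the CO2
#' increase over the window, in ppm of that air, gives the carbon mass via the
#' molar mass of C. Rates are expressed per gram dry soil and, via the SOC
#' concentration, per gram SOC, both per day.
#'
#' When `correct_dilution` is `TRUE` the stored starting concentration is
#' multiplied by `(V - sample_gas_volume) / V`, accounting for the withdrawn
#' headspace aliquot being replaced with CO2-free air before the window
#' starts.
#'
#' A concentration decrease yields a negative rate, carried through and
#' flagged `"negative_flux"`.
#'
#' @param records a data frame in the headspace CSV dialect (see
#'   [read_headspace_csv()]) or a single-record list with fields `sample_id`,
#'   `replicate`, `day`, `jar_ml`, `soil_fresh_g`, `moisture_frac` (water as a
#'   fraction of fresh mass), `soc_g_per_kg`, `temperature_C`, `pressure_kpa`,
#'   `ppm_start`, `ppm_end`, `window_h`.
#' @param solids_density assumed soil solids bulk density (g cm^-3, default
#'   1.3) used for the headspace-volume correction.
#' @param sample_gas_volume withdrawn/refilled headspace aliquot (mL, default
#'   10).
#' @param correct_dilution apply the withdrawal/refill dilution correction to
#'   `ppm_start` (default `TRUE`).
#' @return A data frame (one row per record) with `sample_id`, `replicate`,
#'   `day`, `rate_ugC_gdw_d` (ug C per g dry soil per day), `rate_ugC_gSOC_d`
#'   (ug C per g SOC per day) and `qc_flags`.
#' @examples
#' rec <- list(sample_id = "s1", replicate = 1, day = 1, jar_ml = 250,
#'             soil_fresh_g = 20, moisture_frac = 0, soc_g_per_kg = 50,
#'             temperature_C = 5, pressure_kpa = 101.325,
#'             ppm_start = 0, ppm_end = 500, window_h = 48)
#' headspace_to_flux(rec, solids_density = Inf) # ~32.9 ug C g^-1 SOC d^-1
#' @export
headspace_to_flux <- function(records, solids_density = DEFAULT_SOLIDS_DENSITY,
                              sample_gas_volume = 10,
                              correct_dilution = TRUE) {
  if (!is.data.frame(records)) records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("sample_id", "replicate", "day", "jar_ml", "soil_fresh_g",
            "moisture_frac", "soc_g_per_kg", "temperature_C", "pressure_kpa",
            "ppm_start", "ppm_end", "window_h")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing headspace column(s): ", paste(miss, collapse = ", "))
  with(records, {
    if (any(jar_ml <= 0)) stop("jar_ml must be > 0")
    if (any(soil_fresh_g <= 0)) stop("soil_fresh_g must be > 0")
    if (any(moisture_frac < 0 | moisture_frac >= 1)) stop("moisture_frac must be in [0, 1)")
    if (any(window_h <= 0)) stop("window_h must be > 0")
    if (any(ppm_start < 0 | ppm_end < 0)) stop("ppm values must be >= 0")
    if (any(soc_g_per_kg <= 0)) stop("soc_g_per_kg must be > 0 for SOC normalisation")
  })

  dry_g <- records$soil_fresh_g * (1 - records$moisture_frac)
  soil_ml <- dry_g / solids_density        # 1 cm^3 = 1 mL
  v_ml <- records$jar_ml - soil_ml
  if (any(v_ml <= 0)) stop("effective headspace volume is <= 0; check jar_ml/soil mass")
  n_air <- (records$pressure_kpa * 1000) * (v_ml * 1e-6) /
    (GAS_CONSTANT * (records$temperature_C + 273.15))
  ppm0 <- if (correct_dilution) {
    records$ppm_start * (v_ml - sample_gas_volume) / v_ml
  } else records$ppm_start
  d_ppm <- records$ppm_end - ppm0
  mass_ug <- d_ppm * 1e-6 * n_air * MOLAR_MASS_C * 1e6
  window_d <- records$window_h / 24
  rate_dw <- mass_ug / dry_g / window_d
  rate_soc <- rate_dw * 1000 / records$soc_g_per_kg
  flags <- ifelse(d_ppm < 0, "negative_flux", "")
  data.frame(sample_id = records$sample_id, replicate = records$replicate,
             day = records$day, rate_ugC_gdw_d = rate_dw,
             rate_ugC_gSOC_d = rate_soc, qc_flags = flags,
             stringsAsFactors = FALSE)
}

#' Read incubation CSV inputs
#'
#' `read_headspace_csv()` reads the raw headspace dialect (columns
#' `sample_id, replicate, site, layer, temperature_C, day, jar_ml,
#' soil_fresh_g, moisture_frac, soc_g_per_kg, pressure_kpa, ppm_start,
#' ppm_end, window_h`); `read_flux_csv()` reads the pre-computed flux dialect
#' (`sample_id, replicate, site, layer, temperature_C, day,
#' rate_ugC_gSOC_d`). Both are UTF-8 CSVs with a header row; `#` lines are
#' treated as comments. Missing required columns raise an error naming the
#' column.
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_flux_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "replicate", "site", "layer", "temperature_C", "day",
            "rate_ugC_gSOC_d")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("flux CSV is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_flux_csv
#' @export
read_headspace_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "replicate", "site", "layer", "temperature_C", "day",
            "jar_ml", "soil_fresh_g", "moisture_frac", "soc_g_per_kg",
            "pressure_kpa", "ppm_start", "ppm_end", "window_h")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("headspace CSV is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Assemble incubation series from a flux table
#'
#' Groups flux-dialect rows by `sample_id`, pivots replicates into columns and
#' builds one [incubation_series()] per sample with the replicate-mean rate and
#' the floored replicate standard deviation at each day. Rates are converted
#' from ug to the model's mg C per g SOC per day. Missing replicate
#' measurements are tolerated (the series is flagged); duplicate
#' `(replicate, day)` rows are an error.
#'
#' @param flux a flux-dialect data frame (see [read_flux_csv()]).
#' @param sigma_floor_cv,sigma_floor_abs floor rule for the per-time s.d.
#'   (fraction of the replicate mean, and absolute floor in mg C g^-1 SOC
#'   d^-1).
#' @return A named list of `incubation_series`, one per `sample_id`.
#' @export
build_series <- function(flux, sigma_floor_cv = 0.05, sigma_floor_abs = 1e-4) {
  need <- c("sample_id", "replicate", "day", "rate_ugC_gSOC_d")
  miss <- setdiff(need, names(flux))
  if (length(miss)) stop("flux table is missing column(s): ", paste(miss, collapse = ", "))
  out <- lapply(split(flux, flux$sample_id), function(g) {
    if (anyDuplicated(g[, c("replicate", "day")])) {
      stop("duplicate (replicate, day) rows for sample ", g$sample_id[1L])
    }
    days <- sort(unique(g$day))
    reps <- sort(unique(g$replicate))
    m <- matrix(NA_real_, nrow = length(days), ncol = length(reps),
                dimnames = list(NULL, paste0("rep", reps)))
    m[cbind(match(g$day, days), match(g$replicate, reps))] <- g$rate_ugC_gSOC_d
    incubation_series(
      sample_id = g$sample_id[1L], times = days, rates = m / 1000,
      site = if ("site" %in% names(g)) g$site[1L] else NA_character_,
      layer = if ("layer" %in% names(g)) g$layer[1L] else NA_character_,
      temperature = if ("temperature_C" %in% names(g)) g$temperature_C[1L] else NA_real_,
      sigma_floor_cv = sigma_floor_cv, sigma_floor_abs = sigma_floor_abs)
  })
  out[order(names(out))]
}

#' Observed cumulative release over the measured window
#'
#' Trapezoidal integration of the replicate-mean rates from time zero to the
#' last measurement day. The interval before the first measurement is filled
#' with a rectangle at the first observed rate (the flux before the first
#' sample is unobserved; holding it constant is the conservative convention for
#' a declining flux).
#'
#' @param series an [incubation_series()].
#' @return Cumulative observed release, mg C per g SOC.
#' @export
observed_cumulative <- function(series) {
  stopifnot(inherits(series, "incubation_series"))
  t <- series$times
  r <- series$mean_rates
  lead <- r[1L] * t[1L]
  if (length(t) < 2L) return(lead)
  lead + sum(diff(t) * (utils::head(r, -1L) + utils::tail(r, -1L)) / 2)
}
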