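#' Observed incubation flux time series
#'
#' Container for one soil sample's CO2-C emission-rate observations
#' \eqn{Z_i(t)}: a strictly increasing measurement schedule, a matrix of
#' replicate rates and a per-time measurement standard deviation
#' \eqn{\sigma(t)} used by the Gaussian likelihood.
#'
#' When `sigma` is not supplied it is computed as the standard deviation across
#' replicates at each time, floored at
#' `max(sigma_floor_cv * |replicate mean|, sigma_floor_abs)`. The floor keeps
#' the likelihood usable when replicates coincide (or only one replicate
#' exists); times where the floor engaged are flagged `"sigma_floored"`.
#'
#' @param sample_id sample identifier.
#' @param times measurement days (strictly increasing, all > 0); day 0 is the
#'   start of flux measurement, after any pre-equilibration.
#' @param rates observed rates, mg C per g SOC per day: a numeric vector (one
#'   replicate) or a `length(times) x n_replicates` matrix; `NA` marks a
#'   missing replicate measurement.
#' @param sigma optional per-time measurement s.d. (same units, all > 0).
#' @param site,layer,temperature optional metadata (`layer` is
#'   `"active_layer"` or `"permafrost"`).
#' @param sigma_floor_cv,sigma_floor_abs floor rule constants (relative and
#'   absolute, defaults 0.05 and 1e-4 mg C g^-1 SOC d^-1).
#' @return An object of class `incubation_series` with elements `sample_id`,
#'   `site`, `layer`, `temperature`, `times`, `rates` (matrix), `mean_rates`,
#'   `sigma` and `qc_flags`.
#' @export
incubation_series <- function(sample_id, times, rates, sigma = NULL,
                              site = NA_character_, layer = NA_character_,
                              temperature = NA_real_,
                              sigma_floor_cv = 0.05, sigma_floor_abs = 1e-4) {
  times <- as.numeric(times)
  if (length(times) < 2L) stop("an incubation series needs at least 2 time points")
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("times must be finite and > 0 (day 0 is the start of measurement)")
  }
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (is.vector(rates)) rates <- matrix(as.numeric(rates), ncol = 1L)
  rates <- as.matrix(rates)
  storage.mode(rates) <- "double"
  if (nrow(rates) != length(times)) {
    stop("rates must have one row per time point")
  }
  if (any(rowSums(!is.na(rates)) < 1L)) stop("every time point needs at least one replicate rate")

  qc <- character(0)
  mean_rates <- rowMeans(rates, na.rm = TRUE)
  if (is.null(sigma)) {
    raw_sd <- apply(rates, 1L, stats::sd, na.rm = TRUE)
    raw_sd[!is.finite(raw_sd)] <- 0 # single replicate
    floorv <- pmax(sigma_floor_cv * abs(mean_rates), sigma_floor_abs)
    sigma <- pmax(raw_sd, floorv)
    if (any(raw_sd < floorv)) qc <- c(qc, "sigma_floored")
  } else {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(times)) stop("sigma must have one value per time point")
    if (any(!is.finite(sigma)) || any(sigma <= 0)) {
      stop("sigma must be finite and > 0 everywhere (apply a floor upstream)")
    }
  }
  n_rep <- rowSums(!is.na(rates))
  if (any(n_rep < ncol(rates))) {
    qc <- c(qc, paste0("n_replicates=", min(n_rep)))
  }
  structure(
    list(sample_id = sample_id, site = site, layer = layer,
         temperature = temperature, times = times, rates = rates,
         mean_rates = mean_rates, sigma = sigma, qc_flags = qc),
    class = "incubation_series")
}

#' @export
print.incubation_series <- function(x, ...) {
  cat(sprintf(
    "<incubation_series %s: %d time points (day %g-%g), %d replicate column(s)%s>\n",
    x$sample_id, length(x$times), min(x$times), max(x$times), ncol(x$rates),
    if (length(x$qc_flags)) paste0("; flags: ", paste(x$qc_flags, collapse = ",")) else ""))
  invisible(x)
}

# minimum distinct time points for a p-parameter fit (p + 1 rule)
check_fit_eligible <- function(series, model) {
  need <- if (model == "three_pool") 6L else 4L
  if (length(unique(series$times)) < need) {
    stop(sprintf("series '%s' has %d distinct time points; a %s fit needs >= %d",
                 series$sample_id, length(unique(series$times)), model, need))
  }
  invisible(TRUE)
}
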