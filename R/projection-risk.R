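#' Effective incubation days for a seasonal-thaw projection
#'
#' Converts a calendar projection horizon into effective incubation days under
#' the assumption that soils decompose only while thawed:
#' `years * months * 30` (30-day months, so 85 years at 4 thawed months per
#' year gives exactly 10,200 days).
#'
#' @param calendar_years projection length in calendar years (>= 0).
#' @param thawed_months_per_year thawed months per year (0-12).
#' @return Effective incubation days.
#' @examples
#' thawed_days(85, 4) # 10200
#' @export
thawed_days <- function(calendar_years, thawed_months_per_year = 4) {
  if (any(calendar_years < 0) || any(thawed_months_per_year < 0)) {
    stop("inputs must be >= 0")
  }
  if (any(thawed_months_per_year > 12)) stop("thawed_months_per_year cannot exceed 12")
  calendar_years * thawed_months_per_year * 30
}

#' Cumulative release and pool attribution at a horizon
#'
#' Wraps [cumulative_release()] (as a fraction of `c_tot`) and
#' [pool_contributions()] at a single projection horizon.
#'
#' @param params a [decay_params()] object.
#' @param horizon projection horizon in effective incubation days (> 0).
#' @return A list of class `horizon_report` with `horizon_days`,
#'   `cum_fraction_of_soc` and `attribution` (a `pool_attribution`).
#' @examples
#' prm <- decay_params(f1 = 0.01, f2 = 0.6, k1 = 0.02, k2 = 2e-4, k3 = 2e-6)
#' horizon_report(prm, thawed_days(85, 4))
#' @export
horizon_report <- function(params, horizon) {
  if (length(horizon) != 1L || !is.finite(horizon) || horizon <= 0) {
    stop("horizon must be a single value > 0")
  }
  att <- pool_contributions(params, horizon)
  structure(
    list(horizon_days = horizon,
         cum_fraction_of_soc = att$cum_total / params$c_tot,
         attribution = att),
    class = "horizon_report")
}

#' @export
print.horizon_report <- function(x, ...) {
  cat(sprintf("<horizon_report at %g d: %.2f%% of SOC released>\n",
              x$horizon_days, 100 * x$cum_fraction_of_soc))
  print(x$attribution)
  invisible(x)
}

#' Regional permafrost warming-risk arithmetic
#'
#' Upscales a laboratory-derived cumulative release fraction to a regional
#' carbon stock: `stock (Pg C) x 1000 x decline_fraction x release_fraction`,
#' rounded to the nearest integer Tg C (half away from zero). `decline` may be
#' a vector (for example the low/high areal-decline bounds of an emissions
#' scenario), giving one released-carbon value per element.
#'
#' @param stock_pg regional permafrost SOC stock, Pg C (>= 0).
#' @param decline projected areal permafrost decline fraction(s) in \[0, 1\].
#' @param release cumulative CO2-C release fraction over the horizon, in
#'   \[0, 1\]; either supplied directly or computed upstream as a mean of
#'   [horizon_report()] `cum_fraction_of_soc` over fitted samples.
#' @param label optional scenario label.
#' @return A data frame with columns `label`, `decline`, `release` and `tg_c`
#'   (released carbon, Tg C, integer).
#' @examples
#' regional_risk(1.29, decline = c(0.19, 0.25), release = 0.454, label = "RCP4.5")
#' @export
regional_risk <- function(stock_pg, decline, release, label = NA_character_) {
  if (length(stock_pg) != 1L || stock_pg < 0) stop("stock_pg must be a single value >= 0")
  if (any(decline < 0 | decline > 1)) stop("decline fractions must be in [0, 1]")
  if (length(release) != 1L || release < 0 || release > 1) {
    stop("release must be a single fraction in [0, 1]")
  }
  tg <- stock_pg * 1000 * decline * release
  data.frame(label = label, decline = decline, release = release,
             tg_c = round_half_away(tg), stringsAsFactors = FALSE)
}

# round() halves to even; risk totals round half away from zero
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
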