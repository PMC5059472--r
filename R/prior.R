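#' Uniform prior box for decay-model parameters
#'
#' A box of independent uniform priors, one interval per parameter of the
#' decay model: `(f1, f2, k1, k2, k3)` for the three-pool model, `(f1, k1, k2)`
#' for the two-pool model. The default rate bands are contiguous and
#' non-overlapping so that the fast/slow/passive timescale separation (days to
#' months, years, millennia) is encoded in the prior and the rate ordering
#' `k1 > k2 > k3` holds automatically; site-specific widening (for example a
#' longer slow/passive turnover for low-emission soils) is done through the
#' `lower`/`upper` overrides.
#'
#' Defaults (three-pool): `f1` in \[0, 0.05\], `f2` in \[0, 0.95\], `k1` in
#' \[1e-3, 1\] per day, `k2` in \[1e-5, 1e-3\], `k3` in \[1e-8, 1e-5\]. The
#' two-pool box drops `f2` and `k3`.
#'
#' @param model `"three_pool"` or `"two_pool"`.
#' @param lower,upper named numeric vectors overriding individual bounds, e.g.
#'   `upper = c(k2 = 5e-3)`.
#' @return An object of class `prior_box`: a list with numeric vectors `lower`
#'   and `upper` (named by parameter) and the `model` string.
#' @examples
#' default_prior("three_pool")
#' default_prior("two_pool", upper = c(k1 = 0.5))
#' @export
default_prior <- function(model = c("three_pool", "two_pool"),
                          lower = NULL, upper = NULL) {
  model <- match.arg(model)
  lo <- c(f1 = 0, f2 = 0, k1 = 1e-3, k2 = 1e-5, k3 = 1e-8)
  hi <- c(f1 = 0.05, f2 = 0.95, k1 = 1, k2 = 1e-3, k3 = 1e-5)
  if (model == "two_pool") {
    lo <- lo[c("f1", "k1", "k2")]
    hi <- hi[c("f1", "k1", "k2")]
  }
  prior_box(lower = modify_named(lo, lower),
            upper = modify_named(hi, upper), model = model)
}

modify_named <- function(base, override) {
  if (is.null(override)) return(base)
  bad <- setdiff(names(override), names(base))
  if (length(bad)) stop("unknown prior parameter(s): ", paste(bad, collapse = ", "))
  base[names(override)] <- override
  base
}

#' Construct a prior box from explicit bounds
#'
#' @param lower,upper named numeric vectors of bounds, in the parameter order
#'   `(f1, f2, k1, k2, k3)` (three-pool) or `(f1, k1, k2)` (two-pool).
#' @param model `"three_pool"` or `"two_pool"`; inferred from the parameter
#'   names when `NULL`.
#' @return A `prior_box` object.
#' @export
prior_box <- function(lower, upper, model = NULL) {
  if (is.null(model)) {
    model <- if ("k3" %in% names(lower)) "three_pool" else "two_pool"
  }
  want <- param_names(model)
  if (!setequal(names(lower), want) || !setequal(names(upper), want)) {
    stop("prior bounds must be named exactly: ", paste(want, collapse = ", "))
  }
  lower <- lower[want]; upper <- upper[want]
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper)) {
    stop("prior box requires finite lower < upper for every parameter")
  }
  x <- structure(list(lower = lower, upper = upper, model = model),
                 class = "prior_box")
  # the sampler starts from the midpoint, so require a feasible midpoint
  mid <- (lower + upper) / 2
  theta_to_params(mid, model) # errors if infeasible
  x
}

param_names <- function(model) {
  if (model == "three_pool") c("f1", "f2", "k1", "k2", "k3") else c("f1", "k1", "k2")
}

# theta vector (prior order) -> validated decay_params
theta_to_params <- function(theta, model, c_tot = 1000) {
  if (model == "three_pool") {
    decay_params(f1 = theta[["f1"]], f2 = theta[["f2"]], k1 = theta[["k1"]],
                 k2 = theta[["k2"]], k3 = theta[["k3"]], c_tot = c_tot)
  } else {
    decay_params(f1 = theta[["f1"]], k1 = theta[["k1"]], k2 = theta[["k2"]],
                 c_tot = c_tot)
  }
}

# flux at times for a raw theta vector, without enforcing the ordering
# invariants (used to evaluate mixed per-parameter point estimates)
theta_flux <- function(theta, model, t, c_tot = 1000) {
  if (model == "three_pool") {
    f <- c(theta[["f1"]], theta[["f2"]], 1 - theta[["f1"]] - theta[["f2"]])
    k <- c(theta[["k1"]], theta[["k2"]], theta[["k3"]])
  } else {
    f <- c(theta[["f1"]], 1 - theta[["f1"]])
    k <- c(theta[["k1"]], theta[["k2"]])
  }
  c_tot * rowSums(matrix(vapply(seq_along(k),
                                function(i) f[i] * k[i] * exp(-k[i] * t),
                                numeric(length(t))),
                         nrow = length(t)))
}

#' @export
print.prior_box <- function(x, ...) {
  cat(sprintf("<prior_box: %s>\n", x$model))
  print(data.frame(parameter = names(x$lower), lower = unname(x$lower),
                   upper = unname(x$upper)), ...)
  invisible(x)
}
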