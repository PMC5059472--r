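#include <Rcpp.h>
using namespace Rcpp;

// Parameter vectors are ordered (f1, f2, k1, k2, k3) for the three-pool model
// and (f1, k1, k2) for the two-pool model; the slow (two-pool) or passive
// (three-pool) fraction is implied by mass balance.

static inline double reflect_into(double x, double lo, double hi) {
  const double w = hi - lo;
  if (w <= 0.0) return lo;
  // proposal jumps are at most a few box widths, so iterate
  for (int i = 0; i < 1000 && (x < lo || x > hi); ++i) {
    if (x < lo) x = 2.0 * lo - x;
    if (x > hi) x = 2.0 * hi - x;
  }
  if (x < lo) x = lo;
  if (x > hi) x = hi;
  return x;
}

static bool feasible_theta(const double* th, int npar) {
  if (npar == 5) {
    double f1 = th[0], f2 = th[1], k1 = th[2], k2 = th[3], k3 = th[4];
    return f1 >= 0.0 && f2 >= 0.0 && (f1 + f2) <= 1.0 &&
           k1 > k2 && k2 > k3 && k3 > 0.0;
  }
  double f1 = th[0], k1 = th[1], k2 = th[2];
  return f1 >= 0.0 && f1 <= 1.0 && k1 > k2 && k2 > 0.0;
}

static double loglik_theta(const double* th, int npar, double c_tot,
                           const NumericVector& times,
                           const NumericMatrix& rates,
                           const NumericVector& sigma) {
  const int T = times.size();
  const int R = rates.ncol();
  double f[3], k[3];
  int np;
  if (npar == 5) {
    np = 3;
    f[0] = th[0]; f[1] = th[1]; f[2] = 1.0 - th[0] - th[1];
    k[0] = th[2]; k[1] = th[3]; k[2] = th[4];
  } else {
    np = 2;
    f[0] = th[0]; f[1] = 1.0 - th[0];
    k[0] = th[1]; k[1] = th[2];
  }
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    double x = 0.0;
    for (int p = 0; p < np; ++p) x += f[p] * k[p] * std::exp(-k[p] * times[t]);
    x *= c_tot;
    const double s2 = 2.0 * sigma[t] * sigma[t];
    for (int r = 0; r < R; ++r) {
      const double z = rates(t, r);
      if (!ISNAN(z)) {
        const double d = z - x;
        ll -= d * d / s2;
      }
    }
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_loglik(NumericVector theta, double c_tot, NumericVector times,
                  NumericMatrix rates, NumericVector sigma) {
  return loglik_theta(theta.begin(), theta.size(), c_tot, times, rates, sigma);
}

// Symmetric component-wise uniform jump, reflected at the box boundaries.
// Proposals violating the joint constraints (f1 + f2 <= 1, k ordering) are
// redrawn whole, which preserves proposal symmetry over the feasible region.
// [[Rcpp::export]]
NumericVector cpp_propose(NumericVector theta, NumericVector lo,
                          NumericVector hi, double step_fraction,
                          int max_tries = 10000) {
  const int npar = theta.size();
  NumericVector prop(npar);
  for (int tries = 0; tries < max_tries; ++tries) {
    for (int j = 0; j < npar; ++j) {
      const double w = step_fraction * (hi[j] - lo[j]);
      const double x = theta[j] + R::runif(-w, w);
      prop[j] = reflect_into(x, lo[j], hi[j]);
    }
    if (feasible_theta(prop.begin(), npar)) return prop;
  }
  // pathological box: stay put rather than emit an infeasible state
  return clone(theta);
}

// One iteration is a sweep over the components: each parameter in turn gets a
// reflected uniform jump (the other components held fixed) and its own
// accept/reject step. Component-wise updates keep the acceptance rate usable
// when the posterior is much narrower than the prior box in some directions,
// which is the normal situation for the fast-pool rate under a wide prior.
// [[Rcpp::export]]
List cpp_mh(NumericVector times, NumericMatrix rates, NumericVector sigma,
            NumericVector lo, NumericVector hi, double c_tot,
            int n_iter, int n_burn, int thin, double step_fraction) {
  const int npar = lo.size();
  NumericVector theta(npar), prop(npar);
  for (int j = 0; j < npar; ++j) theta[j] = 0.5 * (lo[j] + hi[j]);
  if (!feasible_theta(theta.begin(), npar))
    stop("prior box midpoint is infeasible; supply a box whose midpoint satisfies the parameter constraints");

  double ll = loglik_theta(theta.begin(), npar, c_tot, times, rates, sigma);
  const int n_keep = (n_iter - n_burn) / thin;
  NumericMatrix draws(n_keep, npar);
  NumericVector kept_ll(n_keep);
  long accept_total = 0, accept_post = 0;
  int stored = 0;

  for (int i = 1; i <= n_iter; ++i) {
    for (int j = 0; j < npar; ++j) {
      for (int k = 0; k < npar; ++k) prop[k] = theta[k];
      const double w = step_fraction * (hi[j] - lo[j]);
      bool ok = false;
      for (int tries = 0; tries < 10000 && !ok; ++tries) {
        prop[j] = reflect_into(theta[j] + R::runif(-w, w), lo[j], hi[j]);
        ok = feasible_theta(prop.begin(), npar);
      }
      if (!ok) continue; // pathological box: leave component unchanged
      const double llp = loglik_theta(prop.begin(), npar, c_tot, times, rates, sigma);
      bool accept = llp >= ll;
      if (!accept && R::runif(0.0, 1.0) < std::exp(llp - ll)) accept = true;
      if (accept) {
        theta[j] = prop[j];
        ll = llp;
        ++accept_total;
        if (i > n_burn) ++accept_post;
      }
    }
    if (i > n_burn && ((i - n_burn) % thin == 0) && stored < n_keep) {
      for (int j = 0; j < npar; ++j) draws(stored, j) = theta[j];
      kept_ll[stored] = ll;
      ++stored;
    }
  }

  return List::create(_["draws"] = draws,
                      _["loglik"] = kept_ll,
                      _["acceptance_rate"] =
                        (double)accept_total / ((double)n_iter * npar),
                      _["accept_post_burn"] = (double)accept_post);
}
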