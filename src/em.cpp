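// EM for the normal-inverse-chi-square hierarchical model, on per-group
// sufficient statistics (n, mean, centered sum of squares). Hot path of
// genome-wide scanning: one alternative and one null fit per position.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double ml_group(double n, double xb, double ss,
                              double mu0, double k0, double nu0,
                              double t20) {
  double kn = k0 + n, nun = nu0 + n;
  double Sn = nu0 * t20 + ss + (k0 * n / kn) * (xb - mu0) * (xb - mu0);
  return -n / 2.0 * std::log(M_PI) + 0.5 * (std::log(k0) - std::log(kn)) +
         R::lgammafn(nun / 2.0) - R::lgammafn(nu0 / 2.0) +
         (nu0 / 2.0) * std::log(nu0 * t20) - (nun / 2.0) * std::log(Sn);
}

static inline double ml_free(double n, double ss, double mu0_unused,
                             double nu0, double t20) {
  // native mean profiled at its sample mean: deviation term is zero
  double nun = nu0 + n;
  return -n / 2.0 * std::log(2.0 * M_PI) +
         (nu0 / 2.0) * std::log(nu0 * t20 / 2.0) - R::lgammafn(nu0 / 2.0) +
         R::lgammafn(nun / 2.0) -
         (nun / 2.0) * std::log((ss + nu0 * t20) / 2.0);
}

static double obs_loglik(const NumericMatrix& gs, const NumericVector& ns,
                         double mu0, double k0, double nu0, double t20) {
  double ll = 0.0;
  for (int i = 0; i < gs.nrow(); ++i)
    ll += ml_group(gs(i, 0), gs(i, 1), gs(i, 2), mu0, k0, nu0, t20);
  if (ns.size() == 3) ll += ml_free(ns[0], ns[2], mu0, nu0, t20);
  return ll;
}

// [[Rcpp::export(name = ".em_fit_cpp")]]
List em_fit_cpp(NumericMatrix gs, NumericVector ns, NumericVector init,
                double tol, int max_iter, bool keep_trace) {
  int m = gs.nrow();
  bool has_native = ns.size() == 3;
  double mu0 = init[0], k0 = init[1], nu0 = init[2], t20 = init[3];
  double ll = obs_loglik(gs, ns, mu0, k0, nu0, t20);
  std::vector<double> trace;
  if (keep_trace) trace.push_back(ll);
  bool converged = false;
  int iter = 0;
  while (iter < max_iter) {
    ++iter;
    // E-step
    double sE1 = 0, sEmu = 0, sEmu2 = 0;
    double aE1 = 0, aElog = 0;  // over all variance draws
    for (int i = 0; i < m; ++i) {
      double n = gs(i, 0), xb = gs(i, 1), ss = gs(i, 2);
      double kn = k0 + n, nun = nu0 + n;
      double mun = (k0 * mu0 + n * xb) / kn;
      double Sn = nu0 * t20 + ss + (k0 * n / kn) * (xb - mu0) * (xb - mu0);
      double E1 = nun / Sn;
      double Elog = std::log(Sn / 2.0) - R::digamma(nun / 2.0);
      sE1 += E1;
      sEmu += mun * E1;
      sEmu2 += mun * mun * E1 + 1.0 / kn;
      aE1 += E1;
      aElog += Elog;
    }
    int nvar = m;
    if (has_native) {
      double SnN = nu0 * t20 + ns[2];
      aE1 += (nu0 + ns[0]) / SnN;
      aElog += std::log(SnN / 2.0) - R::digamma((nu0 + ns[0]) / 2.0);
      ++nvar;
    }
    // M-step
    double mu0n = mu0, k0n = k0;
    if (m > 0) {
      mu0n = sEmu / sE1;
      double denom = sEmu2 - 2.0 * mu0n * sEmu + mu0n * mu0n * sE1;
      k0n = m / denom;
      if (k0n < 1e-8) k0n = 1e-8;
      if (k0n > 1e8) k0n = 1e8;
    }
    double A = aElog / nvar, B = aE1 / nvar;
    double rhs = A + std::log(B);
    // solve log(nu/2) - digamma(nu/2) = rhs, bisection on log nu in [-4, 8]
    auto h = [rhs](double lognu) {
      double nu = std::exp(lognu);
      return std::log(nu / 2.0) - R::digamma(nu / 2.0) - rhs;
    };
    double nu0n;
    if (h(8.0) > 0) nu0n = std::exp(8.0);
    else if (h(-4.0) < 0) nu0n = std::exp(-4.0);
    else {
      double lo = -4.0, hi = 8.0;
      for (int b = 0; b < 60 && hi - lo > 1e-10; ++b) {
        double mid = 0.5 * (lo + hi);
        if (h(mid) > 0) lo = mid; else hi = mid;
      }
      nu0n = std::exp(0.5 * (lo + hi));
    }
    double t20n = 1.0 / B;
    if (t20n < 1e-12) t20n = 1e-12;
    double ll_new = obs_loglik(gs, ns, mu0n, k0n, nu0n, t20n);
    if (keep_trace) trace.push_back(ll_new);
    bool done = std::fabs(ll_new - ll) < tol * (std::fabs(ll) + 1.0);
    if (ll_new >= ll - 1e-12) {
      mu0 = mu0n; k0 = k0n; nu0 = nu0n; t20 = t20n; ll = ll_new;
    }
    if (done) { converged = true; break; }
  }
  return List::create(
    _["hyper"] = NumericVector::create(mu0, k0, nu0, t20),
    _["loglik"] = ll, _["n_iter"] = iter, _["converged"] = converged,
    _["trace"] = keep_trace ? wrap(trace) : R_NilValue);
}

// negative marginal loglik and its gradient in the optimization
// parameterization (mu0, log kappa0, log nu0, log tau20); ns empty or the
// native (n, mean, ss) with the mean profiled at the sample mean
// [[Rcpp::export(name = ".negll_cpp")]]
double negll_cpp(NumericVector par, NumericMatrix gs, NumericVector ns) {
  double mu0 = par[0], k0 = std::exp(par[1]), nu0 = std::exp(par[2]),
         t20 = std::exp(par[3]);
  return -obs_loglik(gs, ns, mu0, k0, nu0, t20);
}

// [[Rcpp::export(name = ".negll_grad_cpp")]]
NumericVector negll_grad_cpp(NumericVector par, NumericMatrix gs,
                             NumericVector ns) {
  double mu0 = par[0], k0 = std::exp(par[1]), nu0 = std::exp(par[2]),
         t20 = std::exp(par[3]);
  double g_mu0 = 0, g_k0 = 0, g_nu0 = 0, g_t20 = 0;
  for (int i = 0; i < gs.nrow(); ++i) {
    double n = gs(i, 0), xb = gs(i, 1), ss = gs(i, 2);
    double kn = k0 + n, nun = nu0 + n, D = xb - mu0;
    double Sn = nu0 * t20 + ss + (k0 * n / kn) * D * D;
    g_mu0 += nun * k0 * n * D / (Sn * kn);
    g_k0 += 0.5 / k0 - 0.5 / kn -
            (nun / 2.0) * (n * n / (kn * kn)) * D * D / Sn;
    g_nu0 += 0.5 * R::digamma(nun / 2.0) - 0.5 * R::digamma(nu0 / 2.0) +
             0.5 * std::log(nu0 * t20) + 0.5 -
             0.5 * std::log(Sn) - (nun / 2.0) * t20 / Sn;
    g_t20 += (nu0 / 2.0) / t20 - (nun / 2.0) * nu0 / Sn;
  }
  if (ns.size() == 3) {
    double n = ns[0], ss = ns[2];
    double nun = nu0 + n, T = ss + nu0 * t20;
    g_nu0 += 0.5 * std::log(nu0 * t20 / 2.0) + 0.5 -
             0.5 * R::digamma(nu0 / 2.0) + 0.5 * R::digamma(nun / 2.0) -
             0.5 * std::log(T / 2.0) - (nun / 2.0) * t20 / T;
    g_t20 += (nu0 / 2.0) / t20 - (nun / 2.0) * nu0 / T;
  }
  // chain rule to the log-parameterization, then negate
  return NumericVector::create(-g_mu0, -g_k0 * k0, -g_nu0 * nu0,
                               -g_t20 * t20);
}
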