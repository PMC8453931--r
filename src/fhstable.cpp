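// Core numerical machinery: positive-stable density/sampler, symmetric-stable
// sampler, and the MCMC kernels for the stable-random-effects area model.
// All randomness flows through R's RNG stream (RNGScope), so chains are
// bit-reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Gauss-Legendre nodes/weights on [0, 1], cached per order.
// ---------------------------------------------------------------------------

static void gauss_legendre01(int n, std::vector<double>& x, std::vector<double>& w) {
  static std::map<int, std::pair<std::vector<double>, std::vector<double> > > cache;
  std::map<int, std::pair<std::vector<double>, std::vector<double> > >::iterator it =
      cache.find(n);
  if (it != cache.end()) { x = it->second.first; w = it->second.second; return; }
  // Newton iteration on Legendre roots over [-1, 1], then map to [0, 1].
  x.assign(n, 0.0); w.assign(n, 0.0);
  int m = (n + 1) / 2;
  for (int i = 0; i < m; ++i) {
    double z = std::cos(M_PI * (i + 0.75) / (n + 0.5));
    double pp = 0.0;
    for (int iter = 0; iter < 100; ++iter) {
      double p1 = 1.0, p2 = 0.0;
      for (int j = 0; j < n; ++j) {
        double p3 = p2; p2 = p1;
        p1 = ((2.0 * j + 1.0) * z * p2 - j * p3) / (j + 1.0);
      }
      pp = n * (z * p1 - p2) / (z * z - 1.0);
      double z1 = z;
      z = z1 - p1 / pp;
      if (std::fabs(z - z1) < 1e-15) break;
    }
    double xm = 0.5, xl = 0.5;           // map [-1,1] -> [0,1]
    x[i] = xm - xl * z;
    x[n - 1 - i] = xm + xl * z;
    w[i] = 2.0 * xl / ((1.0 - z * z) * pp * pp);
    w[n - 1 - i] = w[i];
  }
  cache[n] = std::make_pair(x, w);
}

// ---------------------------------------------------------------------------
// Positive stable law, standardized so that E exp(-t P) = exp(-t^a), 0 < a < 1.
// This is S(a, 1, cos(pi a / 2)^{1/a}, 0) in the 1-parameterization, i.e. the
// mixing law of the normal scale mixture underlying the symmetric stable law.
// ---------------------------------------------------------------------------

// log of the Zolotarev auxiliary function A(u), u in (0, pi):
//   A(u) = sin(a u)^{a/(1-a)} sin((1-a) u) sin(u)^{-1/(1-a)}
static inline double logA_zol(double u, double a, double s) {
  return s * std::log(std::sin(a * u)) + std::log(std::sin((1.0 - a) * u))
       - (1.0 + s) * std::log(std::sin(u));
}

// integrand exponent g(u) = log A(u) - A(u) x^{-s}, computed in log space
static inline double g_zol(double u, double a, double s, double lnh) {
  double la = logA_zol(u, a, s);
  double r = la - std::exp(la + lnh);
  if (!std::isfinite(r)) return -std::numeric_limits<double>::infinity();
  return r;
}

// bisection for a monotone scalar function; increasing = true when f goes
// from negative to positive over (lo, hi)
template <class F>
static double bisect(F f, double lo, double hi, bool increasing, int iter = 52) {
  for (int k = 0; k < iter; ++k) {
    double mid = 0.5 * (lo + hi);
    if ((f(mid) < 0.0) == increasing) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

static const double U_EPS = 1e-12;

// log-density of the standardized positive stable law via the single-integral
// representation, with the quadrature split at the integrand's mode
static double postable_logpdf_one(double x, double a, int nq) {
  if (!(x > 0.0)) return -std::numeric_limits<double>::infinity();
  double s = a / (1.0 - a);
  double lnh = -s * std::log(x);           // h = x^{-s}
  double lnA0 = s * std::log(a) + std::log(1.0 - a);   // lim_{u->0} log A(u)
  double target = -lnh;                    // log A at the mode solves A h = 1

  double ustar, gmax;
  if (target <= lnA0) {                    // integrand decreasing on (0, pi)
    ustar = 0.0;
    gmax = g_zol(U_EPS, a, s, lnh);
  } else {
    ustar = bisect([&](double u) { return logA_zol(u, a, s) - target; },
                   U_EPS, M_PI - U_EPS, true);
    gmax = g_zol(ustar, a, s, lnh);
  }
  const double drop = 60.0;                // exp(-60) ~ 9e-27 relative cutoff
  double ulo = 0.0, uhi = M_PI;
  // cutoff brackets need no precision: 36 halvings locate them amply
  if (ustar > 0.0 && g_zol(U_EPS, a, s, lnh) < gmax - drop)
    ulo = bisect([&](double u) { return g_zol(u, a, s, lnh) - (gmax - drop); },
                 U_EPS, ustar, true, 36);
  if (g_zol(M_PI - U_EPS, a, s, lnh) < gmax - drop)
    uhi = bisect([&](double u) { return g_zol(u, a, s, lnh) - (gmax - drop); },
                 std::max(ustar, U_EPS), M_PI - U_EPS, false, 36);

  std::vector<double> qx, qw;
  gauss_legendre01(nq, qx, qw);

  // evaluate g on all nodes first and normalize by the node maximum, so the
  // exponentials can never overflow even when g varies by thousands
  std::vector<double> gv; gv.reserve(2 * nq);
  std::vector<double> wv; wv.reserve(2 * nq);
  double lo1 = ulo, hi1 = std::max(ustar, ulo), lo2 = std::max(ustar, ulo), hi2 = uhi;
  for (int p = 0; p < 2; ++p) {
    double aa = (p == 0) ? lo1 : lo2, bb = (p == 0) ? hi1 : hi2;
    if (bb <= aa) continue;
    for (int j = 0; j < nq; ++j) {
      double u = aa + (bb - aa) * qx[j];
      gv.push_back(g_zol(u, a, s, lnh));
      wv.push_back((bb - aa) * qw[j]);
    }
  }
  double gm = -std::numeric_limits<double>::infinity();
  for (size_t j = 0; j < gv.size(); ++j) if (gv[j] > gm) gm = gv[j];
  if (!std::isfinite(gm)) return -std::numeric_limits<double>::infinity();
  double I = 0.0;
  for (size_t j = 0; j < gv.size(); ++j) I += wv[j] * std::exp(gv[j] - gm);
  return std::log(s / M_PI) - (1.0 + s) * std::log(x) + gm + std::log(I);
}

// [[Rcpp::export]]
NumericVector cpp_dpostable_log(NumericVector x, double alpha_half, int n_quad) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = postable_logpdf_one(x[i], alpha_half, n_quad);
  return out;
}

// Kanter's representation: P = (A(U)/E)^{(1-a)/a}, U ~ U(0, pi), E ~ Exp(1)
static inline double rpostable_one(double a) {
  double s = a / (1.0 - a);
  double u = M_PI * unif_rand();
  double e = exp_rand();
  return std::exp((logA_zol(u, a, s) - std::log(e)) / s);
}

// [[Rcpp::export]]
NumericVector cpp_rpostable(int n, double alpha_half) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpostable_one(alpha_half);
  return out;
}

// ---------------------------------------------------------------------------
// Symmetric alpha-stable sampler (Chambers-Mallows-Stuck), 1-parameterization:
// characteristic function exp(-|gamma w|^alpha). At alpha = 2 this is the
// Gaussian with variance 2 gamma^2, drawn directly.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_rsas(int n, double alpha, double gamma1) {
  NumericVector out(n);
  if (alpha == 2.0) {
    double sd = gamma1 * std::sqrt(2.0);
    for (int i = 0; i < n; ++i) out[i] = sd * norm_rand();
    return out;
  }
  bool cauchy = std::fabs(alpha - 1.0) < 1e-12;
  for (int i = 0; i < n; ++i) {
    double u = M_PI * (unif_rand() - 0.5);
    if (cauchy) { out[i] = gamma1 * std::tan(u); continue; }
    double e = exp_rand();
    double x = std::sin(alpha * u) / std::pow(std::cos(u), 1.0 / alpha)
             * std::pow(std::cos(u - alpha * u) / e, (1.0 - alpha) / alpha);
    out[i] = gamma1 * x;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Single conditional updates of the Gibbs sweep. These are the same routines
// the full samplers call, so the R-level wrappers exercise the identical code
// path used inside the chains.
// ---------------------------------------------------------------------------

static arma::vec update_beta_impl(const arma::vec& y, const arma::mat& X,
                                  const arma::vec& psi, const arma::vec& v,
                                  const arma::vec& mu_beta,
                                  const arma::mat& Sigma_beta_inv) {
  arma::mat Xw = X;
  Xw.each_col() %= (1.0 / psi);                     // rows scaled by 1/psi_i
  arma::mat Q = X.t() * Xw + Sigma_beta_inv;        // posterior precision
  arma::vec rhs = Xw.t() * (y - v) + Sigma_beta_inv * mu_beta;
  arma::mat R;
  if (!arma::chol(R, Q))
    stop("singular precision matrix in the beta update: check that the design matrix has full column rank and that the sampling variances are positive");
  arma::vec mu = arma::solve(Q, rhs);
  int p = X.n_cols;
  arma::vec z(p);
  for (int j = 0; j < p; ++j) z[j] = norm_rand();
  return mu + arma::solve(arma::trimatu(R), z);
}

// [[Rcpp::export]]
arma::vec cpp_update_beta(const arma::vec& y, const arma::mat& X,
                          const arma::vec& psi, const arma::vec& v,
                          const arma::vec& mu_beta,
                          const arma::mat& Sigma_beta_inv) {
  return update_beta_impl(y, X, psi, v, mu_beta, Sigma_beta_inv);
}

static arma::vec update_v_impl(const arma::vec& resid, const arma::vec& psi,
                               const arma::vec& lam, double gam) {
  int m = resid.n_elem;
  arma::vec v(m);
  for (int i = 0; i < m; ++i) {
    double lg = lam[i] * gam;
    double del = lg / (lg + psi[i]);
    v[i] = del * resid[i] + std::sqrt(del * psi[i]) * norm_rand();
  }
  return v;
}

// [[Rcpp::export]]
arma::vec cpp_update_v(const arma::vec& resid, const arma::vec& psi,
                       const arma::vec& lam, double gam) {
  return update_v_impl(resid, psi, lam, gam);
}

static double update_gamma_impl(const arma::vec& v, const arma::vec& lam,
                                double a_ig, double b_ig) {
  int m = v.n_elem;
  double rate = b_ig;
  for (int i = 0; i < m; ++i) rate += v[i] * v[i] / (2.0 * lam[i]);
  double shape = 0.5 * m + a_ig;
  double gi = R::rgamma(shape, 1.0 / rate);         // gamma^{-1} draw
  return 1.0 / gi;
}

// [[Rcpp::export]]
double cpp_update_gamma(const arma::vec& v, const arma::vec& lam,
                        double a_ig, double b_ig) {
  return update_gamma_impl(v, lam, a_ig, b_ig);
}

// exact rejection draw from pi(lambda | v, gamma, alpha) using the
// positive-stable prior as proposal and the likelihood bound
// N(v | 0, lambda gamma) <= (2 pi v^2)^{-1/2} exp(-1/2)
static double draw_lambda_one(double v, double gam, double a_half,
                              int max_attempts, int nq,
                              int& attempts, int& fallbacks) {
  if (std::fabs(v) < 1e-8) {   // flat likelihood limit: prior draw is exact
    attempts += 1;
    return rpostable_one(a_half);
  }
  double log_bound = -0.5 * std::log(2.0 * M_PI * v * v) - 0.5;
  for (int k = 0; k < max_attempts; ++k) {
    double lam = rpostable_one(a_half);
    double loglik = -0.5 * std::log(2.0 * M_PI * lam * gam)
                  - v * v / (2.0 * lam * gam);
    double logu = std::log(unif_rand()) + log_bound;
    ++attempts;
    if (logu < loglik) return lam;
  }
  // bounded-runtime fallback: inverse-CDF draw on a log-spaced grid of the
  // target N(v | 0, lambda gamma) f_{alpha/2}(lambda)
  ++fallbacks;
  const int ng = 512;
  double c = std::max(v * v / gam, 1.0);
  double llo = std::log(c) - 25.0, lhi = std::log(c) + 35.0;
  std::vector<double> lg(ng), lt(ng);
  double mx = -std::numeric_limits<double>::infinity();
  for (int j = 0; j < ng; ++j) {
    lg[j] = llo + (lhi - llo) * (j + 0.5) / ng;
    double lam = std::exp(lg[j]);
    lt[j] = -0.5 * std::log(2.0 * M_PI * lam * gam) - v * v / (2.0 * lam * gam)
          + postable_logpdf_one(lam, a_half, nq) + lg[j];  // + log-Jacobian
    if (lt[j] > mx) mx = lt[j];
  }
  double tot = 0.0;
  for (int j = 0; j < ng; ++j) { lt[j] = std::exp(lt[j] - mx); tot += lt[j]; }
  double u = unif_rand() * tot, acc = 0.0;
  for (int j = 0; j < ng; ++j) { acc += lt[j]; if (u <= acc) return std::exp(lg[j]); }
  return std::exp(lg[ng - 1]);
}

// [[Rcpp::export]]
List cpp_update_lambda(const arma::vec& v, double gam, double alpha,
                       int max_attempts, int n_quad) {
  int m = v.n_elem;
  double a_half = std::min(alpha, 2.0 - 1e-6) / 2.0;
  arma::vec lam(m);
  IntegerVector att(m);
  int fallbacks = 0;
  for (int i = 0; i < m; ++i) {
    int ai = 0;
    lam[i] = draw_lambda_one(v[i], gam, a_half, max_attempts, n_quad, ai, fallbacks);
    att[i] = ai;
  }
  return List::create(_["lambda"] = lam, _["attempts"] = att,
                      _["fallbacks"] = fallbacks);
}

static double loglik_lambda(const arma::vec& lam, double alpha, int nq) {
  double a_half = std::min(alpha, 2.0 - 1e-6) / 2.0;
  double ll = 0.0;
  for (size_t i = 0; i < lam.n_elem; ++i)
    ll += postable_logpdf_one(lam[i], a_half, nq);
  return ll;
}

// Metropolis-Hastings step for the tail index: uniform random-walk proposal
// centered at the current value; proposals outside (0, 2] rejected outright.
// cur_loglik = sum_i log f_{alpha/2}(lambda_i) at the current alpha (pass NA
// to recompute). Returns the new alpha, accept flag, and its log-likelihood.
static void update_alpha_impl(const arma::vec& lam, double& alpha,
                              double halfwidth, int nq,
                              double& cur_ll, bool& accepted) {
  if (!std::isfinite(cur_ll)) cur_ll = loglik_lambda(lam, alpha, nq);
  double prop = alpha + halfwidth * (2.0 * unif_rand() - 1.0);
  accepted = false;
  if (prop <= 0.0 || prop > 2.0) return;
  double prop_ll = loglik_lambda(lam, prop, nq);
  if (std::log(unif_rand()) < prop_ll - cur_ll) {
    alpha = prop;
    cur_ll = prop_ll;
    accepted = true;
  }
}

// [[Rcpp::export]]
List cpp_update_alpha(const arma::vec& lam, double alpha, double halfwidth,
                      int n_quad, double cur_loglik) {
  double a = alpha, ll = cur_loglik;
  bool acc;
  update_alpha_impl(lam, a, halfwidth, n_quad, ll, acc);
  return List::create(_["alpha"] = a, _["accepted"] = acc, _["loglik"] = ll);
}

// ---------------------------------------------------------------------------
// Full MCMC for the stable-random-effects model. Sweep order:
// beta -> v -> gamma -> lambda -> alpha (alpha skipped when fixed).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_fhas_mcmc(const arma::vec& y, const arma::mat& X, const arma::vec& psi,
                   const arma::vec& mu_beta, const arma::mat& Sigma_beta_inv,
                   double a_ig, double b_ig,
                   arma::vec beta, arma::vec v, double gam, double alpha,
                   arma::vec lam,
                   bool alpha_is_fixed, double halfwidth,
                   int iterations, int burn_in, int thin,
                   int max_attempts, int n_quad, bool store_lambda) {
  int m = y.n_elem, p = X.n_cols;
  int n_keep = (iterations - burn_in) / thin;
  arma::mat beta_s(n_keep, p), v_s(n_keep, m), theta_s(n_keep, m);
  arma::vec gamma_s(n_keep), alpha_s(n_keep);
  arma::mat lam_s(store_lambda ? n_keep : 0, store_lambda ? m : 0);

  int alpha_props = 0, alpha_acc = 0, fallbacks = 0;
  double total_attempts = 0.0;
  int max_att_seen = 0;
  double cur_ll = NA_REAL;
  int keep = 0;

  for (int it = 0; it < iterations; ++it) {
    beta = update_beta_impl(y, X, psi, v, mu_beta, Sigma_beta_inv);
    arma::vec xb = X * beta;
    v = update_v_impl(y - xb, psi, lam, gam);
    gam = update_gamma_impl(v, lam, a_ig, b_ig);

    double a_half = std::min(alpha, 2.0 - 1e-6) / 2.0;
    for (int i = 0; i < m; ++i) {
      int ai = 0;
      lam[i] = draw_lambda_one(v[i], gam, a_half, max_attempts, n_quad,
                               ai, fallbacks);
      total_attempts += ai;
      if (ai > max_att_seen) max_att_seen = ai;
    }

    if (!alpha_is_fixed) {
      cur_ll = loglik_lambda(lam, alpha, n_quad);  // lambda changed
      bool acc;
      update_alpha_impl(lam, alpha, halfwidth, n_quad, cur_ll, acc);
      ++alpha_props;
      if (acc) ++alpha_acc;
    }

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      beta_s.row(keep) = beta.t();
      v_s.row(keep) = v.t();
      theta_s.row(keep) = (xb + v).t();
      gamma_s[keep] = gam;
      alpha_s[keep] = alpha;
      if (store_lambda) lam_s.row(keep) = lam.t();
      ++keep;
    }
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["beta"] = beta_s, _["v"] = v_s, _["theta"] = theta_s,
    _["gamma"] = gamma_s, _["alpha"] = alpha_s,
    _["lambda"] = lam_s,
    _["alpha_proposals"] = alpha_props, _["alpha_accepts"] = alpha_acc,
    _["lambda_attempts_mean"] = total_attempts / (double(iterations) * m),
    _["lambda_attempts_max"] = max_att_seen,
    _["lambda_fallbacks"] = fallbacks);
}
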