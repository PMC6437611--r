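#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Conway-Maxwell-Poisson series machinery.
//
// Unnormalised mass at k is exp(k*loglambda - nu*lgamma(k+1)). All series are
// summed with online rescaling against the running maximum so that large
// loglambda (needed for near-deterministic reporting, nu >> 1) cannot
// overflow. Summation stops once terms fall 1e-12 below the modal term.
// ---------------------------------------------------------------------------

static const int CMP_KMAX = 200000;
static const double CMP_LOGTOL = 27.7; // exp(-27.7) < 1e-12

struct CmpMoments {
  double logZ;
  double mean;
  double var;
};

static double log_term(int k, double loglambda, double nu) {
  return k * loglambda - nu * R::lgammafn((double)k + 1.0);
}

static CmpMoments cmp_series(double loglambda, double nu, int kmin,
                             bool soft = false) {
  if (nu < 0.0)
    stop("CMP series does not converge for nu < 0");
  if (nu == 0.0 && loglambda >= 0.0)
    stop("CMP series does not converge for nu = 0 with lambda >= 1");
  double logmax = R_NegInf, s0 = 0.0, s1 = 0.0, s2 = 0.0;
  double prev = R_NegInf;
  for (int k = kmin; k <= CMP_KMAX; ++k) {
    double lt = log_term(k, loglambda, nu);
    if (lt > logmax) {
      double c = std::exp(logmax - lt);
      s0 *= c; s1 *= c; s2 *= c;
      logmax = lt;
    }
    double t = std::exp(lt - logmax);
    s0 += t;
    s1 += t * k;
    s2 += t * (double)k * (double)k;
    if (lt < logmax - CMP_LOGTOL && lt < prev) break;
    prev = lt;
    if (k == CMP_KMAX) {
      if (soft) { // signal "mean beyond reach" to the root-solver
        CmpMoments m; m.logZ = R_PosInf; m.mean = R_PosInf; m.var = R_PosInf;
        return m;
      }
      stop("CMP series did not converge within term limit");
    }
  }
  CmpMoments m;
  m.logZ = logmax + std::log(s0);
  m.mean = s1 / s0;
  m.var = s2 / s0 - (s1 / s0) * (s1 / s0);
  return m;
}

// Solve loglambda so that the CMP mean (over support k >= kmin) equals mu.
// Newton in loglambda (d mean / d loglambda = variance, an exponential-family
// identity) with a bisection safeguard; tolerance 1e-10 relative on the mean.
static double cmp_loglambda_from_mean(double mu, double nu, int kmin) {
  if (!(mu > (double)kmin) && !(kmin == 0 && mu > 0.0))
    stop("target CMP mean is below the attainable minimum for this support");
  // asymptotic init lambda ~ (mu + (nu-1)/(2 nu))^nu, floored for small nu
  double madj = std::max(mu + (nu - 1.0) / (2.0 * std::max(nu, 1e-8)),
                         std::max(0.5 * mu, 0.05));
  double x = nu > 0 ? nu * std::log(madj) : std::log(mu / (1.0 + mu));
  double lo = R_NegInf, hi = R_PosInf;
  double tol = 1e-10 * std::max(1.0, mu);
  for (int it = 0; it < 300; ++it) {
    CmpMoments m = cmp_series(x, nu, kmin, true);
    double step;
    if (!R_finite(m.mean)) { // divergent trial value: mean far too large
      if (hi == R_PosInf || x < hi) hi = x;
      step = -0.5;
    } else {
      double f = m.mean - mu;
      if (std::fabs(f) < tol) return x;
      if (f < 0) { if (lo == R_NegInf || x > lo) lo = x; }
      else { if (hi == R_PosInf || x < hi) hi = x; }
      step = -f / std::max(m.var, 1e-12);
    }
    if (step > 5.0) step = 5.0;
    if (step < -5.0) step = -5.0;
    // force a bracket when the Newton step is too timid to reach one
    if (hi == R_PosInf && step > 0 && step < 0.25) step = 0.25;
    if (lo == R_NegInf && step < 0 && step > -0.25) step = -0.25;
    double xn = x + step;
    if (xn <= lo || xn >= hi) {
      if (lo > R_NegInf && hi < R_PosInf) xn = 0.5 * (lo + hi);
      else if (hi < R_PosInf) xn = hi - 0.5;
      else xn = lo + 0.5;
    }
    x = xn;
  }
  return x; // best effort; callers verify via round-trip tests
}

// [[Rcpp::export]]
NumericVector cpp_cmp_logpmf(IntegerVector x, double lambda, double nu, bool truncated) {
  double ll = std::log(lambda);
  int kmin = truncated ? 1 : 0;
  CmpMoments m = cmp_series(ll, nu, kmin);
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (x[i] == NA_INTEGER) { out[i] = NA_REAL; continue; }
    if (x[i] < kmin) { out[i] = R_NegInf; continue; }
    out[i] = log_term(x[i], ll, nu) - m.logZ;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_cmp_moments(double lambda, double nu, bool truncated) {
  CmpMoments m = cmp_series(std::log(lambda), nu, truncated ? 1 : 0);
  return NumericVector::create(m.mean, m.var, m.logZ);
}

// [[Rcpp::export]]
double cpp_cmp_lambda_from_mean(double mu, double nu, bool truncated) {
  return std::exp(cmp_loglambda_from_mean(mu, nu, truncated ? 1 : 0));
}

// cdf table over k = kmin..kend capturing all but <1e-12 of the mass
static std::vector<double> cmp_cdf_table(double loglambda, double nu, int kmin, int &kmin_out) {
  CmpMoments m = cmp_series(loglambda, nu, kmin);
  std::vector<double> cdf;
  double acc = 0.0;
  double prev = R_NegInf, logmax = R_NegInf;
  for (int k = kmin; k <= CMP_KMAX; ++k) {
    double lt = log_term(k, loglambda, nu);
    acc += std::exp(lt - m.logZ);
    cdf.push_back(acc);
    if (lt > logmax) logmax = lt;
    if (lt < logmax - CMP_LOGTOL && lt < prev && acc > 1.0 - 1e-12) break;
    prev = lt;
  }
  cdf.back() = 1.0;
  kmin_out = kmin;
  return cdf;
}

static int sample_cdf(const std::vector<double> &cdf, int kmin) {
  double uu = unif_rand();
  int idx = (int)(std::lower_bound(cdf.begin(), cdf.end(), uu) - cdf.begin());
  if (idx >= (int)cdf.size()) idx = (int)cdf.size() - 1;
  return kmin + idx;
}

// [[Rcpp::export]]
IntegerVector cpp_rcmp(int n, double lambda, double nu, bool truncated) {
  int kmin;
  std::vector<double> cdf = cmp_cdf_table(std::log(lambda), nu, truncated ? 1 : 0, kmin);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sample_cdf(cdf, kmin);
  return out;
}

// ---------------------------------------------------------------------------
// Successive sampling (PPS without replacement) ordered log-likelihood:
//   sum_k [ log u_(k) - log( W + sum_{j>=k} u_(j) ) ]
// where W is the total visibility of unsampled units.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_ss_loglik(NumericVector u, double W) {
  int n = u.size();
  double tail = W, ll = 0.0;
  for (int k = n - 1; k >= 0; --k) {
    tail += u[k];
    if (tail <= 0.0) stop("zero denominator in successive sampling likelihood");
    ll += std::log(u[k]) - std::log(tail);
  }
  return ll;
}

// ---------------------------------------------------------------------------
// Metropolis-within-Gibbs sampler for imputed-visibility SS-PSE.
//
// Latent state: visibilities u_1..u_n (enrollment order), the total
// visibility W of the unsampled units, superpopulation parameters theta,
// reporting parameters (tau, rho), and N. The ordered-selection likelihood
// depends on the unsampled units only through W, whose conditional law given
// (N, theta) is the (N - n)-fold convolution of the superpopulation
// distribution. That density is evaluated by the saddlepoint (exponentially
// tilted) approximation, which is accurate far into the tails -- essential
// here because the likelihood tilts W many standard deviations below its
// mean; for the fixed small-support "table" family the convolution is
// enumerated exactly instead. W mixes by a local random walk, and moves that
// change its conditional law (theta, N) transport W to the same quantile of
// a moment-matched gamma, so acceptance stays high across the N grid. The
// label term N!/(N-n)! from observing an unlabelled value sequence is
// carried in the N-move ratio.
// ---------------------------------------------------------------------------

struct Moments3 {
  double mean, var, m3; // central third moment
};

struct Superpop {
  int family; // 0 cmp, 1 negbinom, 2 table
  double th1; // cmp: loglambda; negbinom: mu
  double th2; // cmp: nu;        negbinom: sigma
  std::vector<double> table_logp; // family 2
  double logZ;    // cmp normaliser over k >= 1 / negbinom log(1 - p0)
  Moments3 mom;   // zero-truncated moments
  std::vector<double> logp; // pmf table over support 1..K (mass to <1e-14)
};

static bool superpop_refresh(Superpop &sp) {
  double s0 = 0, s1 = 0, s2 = 0, s3 = 0;
  std::vector<double> lp;
  if (sp.family == 0) {
    if (sp.th2 < 1e-2 || sp.th2 > 1e3) return false;
    if (sp.th1 / sp.th2 > 11.0) return false; // series term-limit guard
    double logmax = R_NegInf, prev = R_NegInf;
    std::vector<double> lt_all;
    for (int k = 1; k <= CMP_KMAX; ++k) {
      double lt = log_term(k, sp.th1, sp.th2);
      lt_all.push_back(lt);
      if (lt > logmax) {
        double c = std::exp(logmax - lt);
        s0 *= c; s1 *= c; s2 *= c; s3 *= c;
        logmax = lt;
      }
      double t = std::exp(lt - logmax);
      double kk = (double)k;
      s0 += t; s1 += t * kk; s2 += t * kk * kk; s3 += t * kk * kk * kk;
      if (lt < logmax - 32.5 && lt < prev) break; // mass below ~1e-14
      prev = lt;
      if (k == CMP_KMAX) return false;
    }
    sp.logZ = logmax + std::log(s0);
    lp.resize(lt_all.size());
    for (size_t k = 0; k < lt_all.size(); ++k) lp[k] = lt_all[k] - sp.logZ;
  } else if (sp.family == 1) {
    double mu = sp.th1, sig = sp.th2;
    if (!(sig * sig > mu * 1.0001) || mu <= 1.0 || mu > 5e4) return false;
    double size = mu * mu / (sig * sig - mu);
    double p0 = R::dnbinom_mu(0.0, size, mu, 0);
    if (p0 >= 1.0 - 1e-14) return false;
    double l1p = std::log1p(-p0);
    for (int k = 1; k <= CMP_KMAX; ++k) {
      double lt = R::dnbinom_mu((double)k, size, mu, 1) - l1p;
      lp.push_back(lt);
      double t = std::exp(lt);
      double kk = (double)k;
      s0 += t; s1 += t * kk; s2 += t * kk * kk; s3 += t * kk * kk * kk;
      if (kk > mu && lt < std::log(1e-14)) break;
      if (k == CMP_KMAX) return false;
    }
    sp.logZ = l1p;
  } else {
    lp = sp.table_logp;
    for (size_t k = 0; k < lp.size(); ++k) {
      double t = std::exp(lp[k]);
      double kk = (double)(k + 1);
      s0 += t; s1 += t * kk; s2 += t * kk * kk; s3 += t * kk * kk * kk;
    }
  }
  double m1 = s1 / s0, m2 = s2 / s0, m3r = s3 / s0;
  sp.mom.mean = m1;
  sp.mom.var = m2 - m1 * m1;
  sp.mom.m3 = m3r - 3.0 * m1 * m2 + 2.0 * m1 * m1 * m1;
  sp.logp.swap(lp);
  // a point-mass table distribution is legitimate (validation scenarios)
  return sp.family == 2 ? sp.mom.var >= 0.0 : sp.mom.var >= 1e-12;
}

static double superpop_logpmf(const Superpop &sp, int u,
                              const std::vector<double> &lfact) {
  if (u < 1) return R_NegInf;
  if (sp.family == 0) {
    return u * sp.th1 - sp.th2 * lfact[u] - sp.logZ;
  } else if (sp.family == 1) {
    double size = sp.th1 * sp.th1 / (sp.th2 * sp.th2 - sp.th1);
    return R::dnbinom_mu((double)u, size, sp.th1, 1) - sp.logZ;
  } else {
    if (u > (int)sp.table_logp.size()) return R_NegInf;
    return sp.table_logp[u - 1];
  }
}

// ---- saddlepoint machinery for W = sum of m iid superpopulation draws ----
//
// K(t) = log E[exp(tX)] over the pmf table; solve K'(t) = w/m by Newton,
// then log f(w) = m K(t) - t w - 0.5 log(2 pi m K''(t)).

struct Cumulants { double K, K1, K2; };

static Cumulants cumulants_at(const Superpop &sp, double t) {
  double mx = R_NegInf;
  int Ksz = (int)sp.logp.size();
  for (int k = 0; k < Ksz; ++k)
    mx = std::max(mx, sp.logp[k] + t * (k + 1));
  double s0 = 0, s1 = 0, s2 = 0;
  for (int k = 0; k < Ksz; ++k) {
    double x = (double)(k + 1);
    double e = std::exp(sp.logp[k] + t * x - mx);
    s0 += e; s1 += e * x; s2 += e * x * x;
  }
  Cumulants c;
  c.K = mx + std::log(s0);
  c.K1 = s1 / s0;
  c.K2 = s2 / s0 - c.K1 * c.K1;
  return c;
}

// log saddlepoint density of W at w (continuous approximation of the sum);
// t_warm carries the solved tilt across nearby calls. The tilt equation
// K'(t) = w/m is solved by bracketed Newton (K' is strictly increasing), so
// convergence is guaranteed; an unconverged tilt would *overestimate* the
// density (Legendre duality) and must never be returned.
static double logf_W_saddle(const Superpop &sp, int m, double w,
                            double &t_warm) {
  int Ksz = (int)sp.logp.size();
  double xbar = w / m;
  if (xbar <= 1.0 + 1e-6 || xbar >= (double)Ksz - 1e-6) return R_NegInf;
  double t = (R_finite(t_warm) && std::fabs(t_warm) < 40.0) ? t_warm : 0.0;
  double lo = R_NegInf, hi = R_PosInf;
  Cumulants c = cumulants_at(sp, t);
  bool ok = false;
  for (int it = 0; it < 300; ++it) {
    double f = c.K1 - xbar;
    if (std::fabs(f) < 1e-8 * std::max(1.0, xbar)) { ok = true; break; }
    if (f < 0) { if (lo == R_NegInf || t > lo) lo = t; }
    else { if (hi == R_PosInf || t < hi) hi = t; }
    double step = -f / std::max(c.K2, 1e-300);
    if (step > 3.0) step = 3.0;
    if (step < -3.0) step = -3.0;
    double tn = t + step;
    if (tn <= lo || tn >= hi) {
      if (lo > R_NegInf && hi < R_PosInf) tn = 0.5 * (lo + hi);
      else if (hi < R_PosInf) tn = hi - 1.0;
      else tn = lo + 1.0;
    }
    if (tn < -80.0 || tn > 80.0) return R_NegInf; // numerically degenerate
    t = tn;
    c = cumulants_at(sp, t);
  }
  if (!ok) return R_NegInf;
  t_warm = t;
  return m * c.K - t * w - 0.5 * std::log(2.0 * M_PI * m * c.K2);
}

// [[Rcpp::export]]
NumericVector cpp_logf_W_saddle_cmp(double lambda, double nu, int m, double w,
                                    double t_init = NA_REAL) {
  Superpop sp; sp.family = 0; sp.th1 = std::log(lambda); sp.th2 = nu;
  if (!superpop_refresh(sp)) stop("bad params");
  double t = t_init;
  double lf = logf_W_saddle(sp, m, w, t);
  return NumericVector::create(lf, t);
}

// matched-gamma quantile transport of W between two (m, theta) laws
struct GammaApprox { double alpha, rate, shift; bool ok; };

static GammaApprox gamma_of(const Superpop &sp, int m) {
  GammaApprox g;
  double M = m * sp.mom.mean, V = m * sp.mom.var, C = m * sp.mom.m3;
  double skew = C / std::pow(std::max(V, 1e-12), 1.5);
  if (skew < 1e-4) skew = 1e-4; // near-normal limit still uses a wide gamma
  g.alpha = 4.0 / (skew * skew);
  g.rate = std::sqrt(g.alpha / V);
  g.shift = M - g.alpha / g.rate;
  g.ok = R_finite(g.alpha) && g.alpha > 0 && g.rate > 0;
  return g;
}

// exact convolution pmf of W for the table family, cached per m
struct TableConv {
  std::vector<std::vector<double>> logpmf_by_m; // index m, value at W = w
  void ensure(const Superpop &sp, int m) {
    if ((int)logpmf_by_m.size() > m && !logpmf_by_m[m].empty()) return;
    int K = (int)sp.table_logp.size();
    if ((int)logpmf_by_m.size() <= m) logpmf_by_m.resize(m + 1);
    std::vector<double> p(K);
    for (int k = 0; k < K; ++k) p[k] = std::exp(sp.table_logp[k]);
    std::vector<double> conv(1, 1.0); // m = 0: point mass at 0
    logpmf_by_m[0] = std::vector<double>(1, 0.0);
    for (int r = 1; r <= m; ++r) {
      std::vector<double> nxt(conv.size() + K, 0.0);
      for (size_t sidx = 0; sidx < conv.size(); ++sidx) {
        if (conv[sidx] == 0.0) continue;
        for (int k = 0; k < K; ++k) nxt[sidx + k + 1] += conv[sidx] * p[k];
      }
      conv.swap(nxt);
      if (logpmf_by_m[r].empty()) {
        logpmf_by_m[r].resize(conv.size());
        for (size_t sidx = 0; sidx < conv.size(); ++sidx)
          logpmf_by_m[r][sidx] =
            conv[sidx] > 1e-300 ? std::log(conv[sidx]) : R_NegInf;
      }
    }
  }
  double logpmf(int m, double w) const {
    int wi = (int)std::lround(w);
    if (wi < 0 || wi >= (int)logpmf_by_m[m].size()) return R_NegInf;
    return logpmf_by_m[m][wi];
  }
  // inverse-cdf draw
  double draw(int m) const {
    if (m == 0) return 0.0;
    const std::vector<double> &lp = logpmf_by_m[m];
    double uu = unif_rand(), acc = 0.0;
    for (size_t w = 0; w < lp.size(); ++w) {
      if (R_finite(lp[w])) acc += std::exp(lp[w]);
      if (acc >= uu) return (double)w;
    }
    return (double)(lp.size() - 1);
  }
};

// Reporting model cache: CMP with mean tau*u, dispersion nu_meas = 1/rho.
struct MeasCache {
  double tau, nu;
  std::vector<double> loglam;
  std::vector<double> logZ;
  std::vector<char> have;
  std::vector<double> warm; // warm starts across parameter moves
  void reset(double tau_, double nu_, int umax) {
    tau = tau_; nu = nu_;
    if ((int)loglam.size() != umax + 1) {
      loglam.assign(umax + 1, 0.0);
      logZ.assign(umax + 1, 0.0);
      have.assign(umax + 1, 0);
      warm.assign(umax + 1, NA_REAL);
    } else {
      std::fill(have.begin(), have.end(), 0);
    }
  }
  void ensure(int u) {
    if (have[u]) return;
    double mu = tau * (double)u;
    double x = NA_REAL;
    if (R_finite(warm[u])) {
      // warm-started Newton in soft mode; any divergence or non-convergence
      // falls back to the bracketed cold solve
      x = warm[u];
      double cap = 2.0 * std::max(nu, 0.05); // modal size moves <= e^2 per step
      bool ok = false;
      for (int it = 0; it < 30; ++it) {
        CmpMoments m = cmp_series(x, nu, 0, true);
        if (!R_finite(m.mean)) break;
        double f = m.mean - mu;
        if (std::fabs(f) < 1e-9 * std::max(1.0, mu)) { ok = true; break; }
        double step = -f / std::max(m.var, 1e-12);
        if (step > cap) step = cap;
        if (step < -cap) step = -cap;
        x += step;
      }
      if (!ok) x = NA_REAL;
    }
    if (!R_finite(x)) x = cmp_loglambda_from_mean(mu, nu, 0);
    warm[u] = x;
    loglam[u] = x;
    CmpMoments m = cmp_series(x, nu, 0, true);
    if (!R_finite(m.mean)) stop("reporting-model series failed to converge");
    logZ[u] = m.logZ;
    have[u] = 1;
  }
  double logpmf(int d, int u, const std::vector<double> &lfact) {
    ensure(u);
    return d * loglam[u] - nu * lfact[d] - logZ[u];
  }
};

// [[Rcpp::export]]
List cpp_sspse_mcmc(IntegerVector d, bool impute, int family,
                    NumericVector table_probs,
                    bool fix_theta, double th1_init, double th2_init,
                    bool fix_meas, double tau_init, double rho_init,
                    NumericVector logprior, NumericVector prior_cdf,
                    NumericVector hyper, // m_mu s_mu s_sigma m_tau s_tau s_rho
                    int burnin, int samples, int thin,
                    NumericVector prop_scales, // N theta meas u W
                    int u_max, bool store_u) {
  int n = d.size();
  int ngrid = logprior.size();
  int maxN = n + ngrid - 1;

  // --- observed degrees ---
  std::vector<char> obs(n);
  int dmax = 1;
  double dsum = 0; int nobs = 0;
  for (int i = 0; i < n; ++i) {
    obs[i] = d[i] != NA_INTEGER;
    if (obs[i]) { dmax = std::max(dmax, d[i]); dsum += d[i]; nobs++; }
  }
  if (u_max < dmax) u_max = dmax;
  std::vector<double> lfact(u_max + 1);
  for (size_t k = 0; k < lfact.size(); ++k)
    lfact[k] = R::lgammafn((double)k + 1.0);

  // --- initial state ---
  std::vector<int> u(n);
  double dbar = nobs > 0 ? std::max(dsum / std::max(nobs, 1), 1.0) : 2.0;
  for (int i = 0; i < n; ++i)
    u[i] = obs[i] ? std::max(d[i], 1)
                  : (int)std::max(1.0, std::floor(dbar + 0.5));

  Superpop sp;
  sp.family = family;
  sp.th1 = th1_init; sp.th2 = th2_init;
  if (family == 2) {
    sp.table_logp.resize(table_probs.size());
    for (int k = 0; k < table_probs.size(); ++k)
      sp.table_logp[k] = table_probs[k] > 0 ? std::log(table_probs[k])
                                            : R_NegInf;
    fix_theta = true;
  }
  if (!superpop_refresh(sp))
    stop("invalid initial superpopulation parameters");
  bool exactW = (family == 2);
  TableConv tconv;
  if (exactW) tconv.ensure(sp, maxN - n);

  bool use_meas = impute && !fix_meas && nobs > 0;
  double tau = tau_init, rho = rho_init;
  MeasCache mc, mcp;
  if (impute && nobs > 0) mc.reset(tau, 1.0 / rho, u_max);

  int N = n + (int)(std::lower_bound(prior_cdf.begin(), prior_cdf.end(), 0.5)
                    - prior_cdf.begin());
  if (N > maxN) N = maxN;

  // suffix sums of u in enrollment order
  std::vector<double> Tsuf(n);
  auto rebuild_tsuf = [&]() {
    double acc = 0;
    for (int k = n - 1; k >= 0; --k) { acc += u[k]; Tsuf[k] = acc; }
  };
  rebuild_tsuf();

  double W;
  double t_warm = NA_REAL, t_warm_p = NA_REAL;
  if (exactW) {
    W = tconv.draw(N - n);
  } else {
    // start W near its conditional mode: one fixed-point pass on the
    // exponential tilt c = sum_k 1/(W + T_k), W = m K'(-c)
    int m = N - n;
    W = m * sp.mom.mean;
    for (int pass = 0; pass < 8 && m > 0; ++pass) {
      double c = 0.0;
      for (int k = 0; k < n; ++k) c += 1.0 / (W + Tsuf[k]);
      double Wn = m * cumulants_at(sp, -c).K1;
      if (std::fabs(Wn - W) < 1e-6 * std::max(1.0, W)) { W = Wn; break; }
      W = Wn;
    }
    if (m > 0 && W <= m) W = m + 1.0;
  }
  auto logf_W = [&](const Superpop &s, int m, double w, double &warm) {
    if (m == 0) return w == 0.0 ? 0.0 : R_NegInf;
    if (exactW) return tconv.logpmf(m, w);
    return logf_W_saddle(s, m, w, warm);
  };
  auto denomsum_at = [&](double w) {
    double sum = 0;
    for (int k = 0; k < n; ++k) sum += std::log(w + Tsuf[k]);
    return sum;
  };
  double denomsum = denomsum_at(W);
  double logfW = logf_W(sp, N - n, W, t_warm);

  double sc_N = prop_scales[0], sc_th = prop_scales[1];
  double sc_me = prop_scales[2], sc_u = prop_scales[3];
  double sc_W = prop_scales[4] * std::sqrt(std::max((N - n) * sp.mom.var, 1.0));
  double m_mu = hyper[0], s_mu = hyper[1], s_sig = hyper[2];
  double m_tau = hyper[3], s_tau = hyper[4], s_rho = hyper[5];

  auto hyper_theta = [&](const Superpop &s) {
    double sdv = std::sqrt(std::max(s.mom.var, 1e-12));
    double lp = R::dnorm4(std::log(s.mom.mean), m_mu, s_mu, 1);
    lp += -0.5 * (sdv * sdv) / (s_sig * s_sig) + std::log(sdv);
    return lp;
  };
  auto hyper_meas = [&](double tau_, double rho_) {
    double lp = R::dnorm4(std::log(tau_), m_tau, s_tau, 1);
    lp += -0.5 * (rho_ * rho_) / (s_rho * s_rho) + std::log(rho_);
    return lp;
  };

  double meas_total = 0.0;
  if (impute && nobs > 0)
    for (int i = 0; i < n; ++i)
      if (obs[i]) meas_total += mc.logpmf(d[i], u[i], lfact);

  int nsweep = burnin + samples * thin;
  IntegerVector N_out(samples);
  NumericVector mu_out(samples), sig_out(samples), tau_out(samples),
    rho_out(samples), W_out(samples);
  NumericVector u_mean(n), u_m2(n);
  IntegerMatrix u_draws(store_u ? samples : 0, store_u ? n : 0);

  long acc_u = 0, att_u = 0, acc_me = 0, att_me = 0;
  long acc_th = 0, att_th = 0, acc_N = 0, att_N = 0, acc_W = 0, att_W = 0;
  long w_acc_u = 0, w_att_u = 0, w_acc_me = 0, w_att_me = 0;
  long w_acc_th = 0, w_att_th = 0, w_acc_N = 0, w_att_N = 0;
  long w_acc_W = 0, w_att_W = 0;
  int rec = 0;

  for (int it = 1; it <= nsweep; ++it) {
    // ---- block 1: visibilities ----
    if (impute) {
      for (int i = 0; i < n; ++i) {
        int delta = (int)std::lround(norm_rand() * sc_u);
        if (delta == 0) continue;
        int up = u[i] + delta;
        att_u++; w_att_u++;
        if (up < 1 || up > u_max) continue;
        double logr = superpop_logpmf(sp, up, lfact)
                    - superpop_logpmf(sp, u[i], lfact);
        if (!R_finite(logr)) continue;
        double dm = 0.0;
        if (obs[i]) {
          dm = mc.logpmf(d[i], up, lfact) - mc.logpmf(d[i], u[i], lfact);
          logr += dm;
        }
        logr += std::log((double)up) - std::log((double)u[i]);
        // denominators for k <= i shift by delta
        double prod = 1.0, lacc = 0.0;
        for (int k = 0; k <= i; ++k) {
          prod *= (W + Tsuf[k]) / (W + Tsuf[k] + delta);
          if (prod < 1e-250 || prod > 1e250) {
            lacc += std::log(prod); prod = 1.0;
          }
        }
        lacc += std::log(prod);
        logr += lacc;
        if (R_finite(logr) && (logr >= 0 || unif_rand() < std::exp(logr))) {
          for (int k = 0; k <= i; ++k) Tsuf[k] += delta;
          denomsum -= lacc;
          meas_total += dm;
          u[i] = up;
          acc_u++; w_acc_u++;
        }
      }
    }

    // ---- block 2: reporting parameters (tau, rho) ----
    if (use_meas) {
      att_me++; w_att_me++;
      double ltau = std::log(tau) + norm_rand() * sc_me;
      double lrho = std::log(rho) + norm_rand() * sc_me;
      double taup = std::exp(ltau), rhop = std::exp(lrho);
      if (taup > 0.02 && taup < 50.0 && rhop > 1e-3 && rhop < 10.0) {
        mcp.reset(taup, 1.0 / rhop, u_max);
        double tot = 0.0;
        for (int i = 0; i < n; ++i)
          if (obs[i]) tot += mcp.logpmf(d[i], u[i], lfact);
        double logr = tot - meas_total
                    + hyper_meas(taup, rhop) - hyper_meas(tau, rho);
        if (R_finite(logr) && (logr >= 0 || unif_rand() < std::exp(logr))) {
          tau = taup; rho = rhop;
          std::swap(mc, mcp);
          meas_total = tot;
          acc_me++; w_acc_me++;
        }
      }
    }

    // ---- block 3: superpopulation parameters (gamma-transport of W) ----
    if (!fix_theta) {
      att_th++; w_att_th++;
      Superpop spp = sp;
      if (family == 0) {
        // symmetric walk in (loglambda/nu, log nu): the first coordinate
        // tracks the log modal size, so the pair is near-orthogonal
        double y1 = sp.th1 / sp.th2 + norm_rand() * sc_th;
        double y2 = std::log(sp.th2) + norm_rand() * sc_th;
        spp.th2 = std::exp(y2);
        spp.th1 = y1 * spp.th2;
      } else {
        spp.th1 = std::exp(std::log(sp.th1) + norm_rand() * sc_th);
        spp.th2 = std::exp(std::log(sp.th2) + norm_rand() * sc_th);
      }
      if (superpop_refresh(spp)) {
        int m = N - n;
        double Wp = W, jac = 0.0;
        bool okW = true;
        if (m > 0) {
          // scale W with the superpopulation mean so the tilt carries over
          double ratio = spp.mom.mean / sp.mom.mean;
          Wp = W * ratio;
          jac = std::log(ratio);
          okW = R_finite(Wp) && Wp > m;
        }
        if (okW) {
          double lsp = 0.0, lspp = 0.0;
          for (int i = 0; i < n; ++i) {
            lsp += superpop_logpmf(sp, u[i], lfact);
            lspp += superpop_logpmf(spp, u[i], lfact);
          }
          double dsp = denomsum_at(Wp);
          double lfWp = logf_W(spp, m, Wp, t_warm_p);
          double logr = (lspp - lsp) + (hyper_theta(spp) - hyper_theta(sp))
                      + (lfWp - logfW) + (denomsum - dsp) + jac;
          if (R_finite(logr) && (logr >= 0 || unif_rand() < std::exp(logr))) {
            sp = spp;
            W = Wp; denomsum = dsp; logfW = lfWp; t_warm = t_warm_p;
            acc_th++; w_acc_th++;
          }
        }
      }
    }

    // ---- block 4: local random walk on W ----
    if (!exactW && N > n) {
      att_W++; w_att_W++;
      double Wp = W + norm_rand() * sc_W;
      if (Wp > (double)(N - n)) {
        double dsp = denomsum_at(Wp);
        double lfWp = logf_W(sp, N - n, Wp, t_warm_p);
        double logr = (lfWp - logfW) + (denomsum - dsp);
        if (R_finite(logr) && (logr >= 0 || unif_rand() < std::exp(logr))) {
          W = Wp; denomsum = dsp; logfW = lfWp; t_warm = t_warm_p;
          acc_W++; w_acc_W++;
        }
      }
    } else if (exactW && N > n) {
      // exact-convolution family: independence refresh from f(W | N)
      att_W++; w_att_W++;
      double Wp = tconv.draw(N - n);
      double dsp = denomsum_at(Wp);
      double logr = denomsum - dsp; // f terms cancel (proposal = prior law)
      if (logr >= 0 || unif_rand() < std::exp(logr)) {
        W = Wp; denomsum = dsp; logfW = logf_W(sp, N - n, W, t_warm);
        acc_W++; w_acc_W++;
      }
    }

    // ---- block 5: population size N (gamma-transport of W) ----
    {
      att_N++; w_att_N++;
      bool indep = (it % 5 == 0);
      int Np;
      if (indep) {
        double uu = unif_rand();
        Np = n + (int)(std::lower_bound(prior_cdf.begin(), prior_cdf.end(), uu)
                       - prior_cdf.begin());
        if (Np > maxN) Np = maxN;
      } else {
        Np = N + (int)std::lround(norm_rand() * sc_N);
      }
      if (Np >= n && Np <= maxN && Np != N) {
        int m0 = N - n, m1 = Np - n;
        double Wp = 0.0, jac = 0.0;
        bool okW = true;
        if (exactW) {
          Wp = tconv.draw(m1); // independence proposal from f(W | Np)
          // f terms cancel against the proposal on both sides
        } else if (m0 == 0 && m1 > 0) {
          GammaApprox g1 = gamma_of(sp, m1);
          double pq = std::log(unif_rand());
          Wp = g1.shift + R::qgamma(pq, g1.alpha, 1.0 / g1.rate, 1, 1);
          jac = -R::dgamma(Wp - g1.shift, g1.alpha, 1.0 / g1.rate, 1);
          okW = R_finite(Wp) && Wp > m1;
        } else if (m1 == 0) {
          GammaApprox g0 = gamma_of(sp, m0);
          Wp = 0.0;
          jac = R::dgamma(W - g0.shift, g0.alpha, 1.0 / g0.rate, 1);
          okW = W > g0.shift;
        } else {
          // proportional transport W' = W * m1 / m0 preserves the
          // per-unsampled-unit mean, i.e. the exponential tilt of W, so
          // acceptance is governed by the informative likelihood terms
          Wp = W * (double)m1 / (double)m0;
          jac = std::log((double)m1 / (double)m0);
          okW = Wp > m1;
        }
        if (okW) {
          double dsp = denomsum_at(Wp);
          double lfWp = exactW ? 0.0 : logf_W(sp, m1, Wp, t_warm_p);
          double lfW0 = exactW ? 0.0 : logfW;
          double logr = (R::lgammafn(Np + 1.0) - R::lgammafn(Np - n + 1.0))
                      - (R::lgammafn(N + 1.0) - R::lgammafn(N - n + 1.0))
                      + (lfWp - lfW0) + (denomsum - dsp) + jac;
          if (!indep) logr += logprior[Np - n] - logprior[N - n];
          if (R_finite(logr) && (logr >= 0 || unif_rand() < std::exp(logr))) {
            N = Np; W = Wp; denomsum = dsp;
            if (!exactW) { logfW = lfWp; t_warm = t_warm_p; }
            else logfW = logf_W(sp, N - n, W, t_warm);
            acc_N++; w_acc_N++;
          }
        }
      }
    }

    // ---- adaptation during burn-in only ----
    if (it <= burnin && it % 50 == 0) {
      if (w_att_u > 0) {
        double r = (double)w_acc_u / w_att_u;
        sc_u = std::min(std::max(sc_u * std::exp(0.8 * (r - 0.40)), 0.4),
                        1000.0);
      }
      if (w_att_me > 0) {
        double r = (double)w_acc_me / w_att_me;
        sc_me = std::min(std::max(sc_me * std::exp(0.8 * (r - 0.30)), 1e-3),
                         3.0);
      }
      if (w_att_th > 0) {
        double r = (double)w_acc_th / w_att_th;
        sc_th = std::min(std::max(sc_th * std::exp(0.8 * (r - 0.30)), 1e-3),
                         3.0);
      }
      if (w_att_W > 0) {
        double r = (double)w_acc_W / w_att_W;
        sc_W = std::max(sc_W * std::exp(0.8 * (r - 0.35)), 1.0);
      }
      if (w_att_N > 0) {
        double r = (double)w_acc_N / w_att_N;
        sc_N = std::min(std::max(sc_N * std::exp(0.8 * (r - 0.25)), 1.0),
                        (double)ngrid);
      }
      w_acc_u = w_att_u = w_acc_me = w_att_me = 0;
      w_acc_th = w_att_th = w_acc_N = w_att_N = 0;
      w_acc_W = w_att_W = 0;
    }

    // ---- periodic exact recomputation to kill numerical drift ----
    if (it % 500 == 0) {
      rebuild_tsuf();
      denomsum = denomsum_at(W);
      if (impute && nobs > 0) {
        meas_total = 0.0;
        for (int i = 0; i < n; ++i)
          if (obs[i]) meas_total += mc.logpmf(d[i], u[i], lfact);
      }
    }

    // ---- record ----
    if (it > burnin && (it - burnin) % thin == 0) {
      N_out[rec] = N;
      mu_out[rec] = sp.mom.mean;
      sig_out[rec] = std::sqrt(std::max(sp.mom.var, 0.0));
      tau_out[rec] = tau;
      rho_out[rec] = rho;
      W_out[rec] = W;
      for (int i = 0; i < n; ++i) {
        u_mean[i] += u[i];
        u_m2[i] += (double)u[i] * (double)u[i];
        if (store_u) u_draws(rec, i) = u[i];
      }
      rec++;
    }
  }

  for (int i = 0; i < n; ++i) {
    u_mean[i] /= samples;
    u_m2[i] = std::sqrt(std::max(u_m2[i] / samples - u_mean[i] * u_mean[i],
                                 0.0));
  }

  return List::create(
    _["N"] = N_out, _["mu"] = mu_out, _["sigma"] = sig_out,
    _["tau"] = tau_out, _["rho"] = rho_out, _["W"] = W_out,
    _["u_mean"] = u_mean, _["u_sd"] = u_m2,
    _["u_draws"] = u_draws,
    _["accept"] = NumericVector::create(
      _["u"] = att_u > 0 ? (double)acc_u / att_u : NA_REAL,
      _["meas"] = att_me > 0 ? (double)acc_me / att_me : NA_REAL,
      _["theta"] = att_th > 0 ? (double)acc_th / att_th : NA_REAL,
      _["W"] = att_W > 0 ? (double)acc_W / att_W : NA_REAL,
      _["N"] = att_N > 0 ? (double)acc_N / att_N : NA_REAL),
    _["scales"] = NumericVector::create(sc_N, sc_th, sc_me, sc_u, sc_W));
}
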