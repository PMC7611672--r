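// Ex-Gaussian race likelihood with trigger/go-failure mixtures.
// Compiled because the DE-MCMC sampler evaluates per-participant dataset
// log-likelihoods for every chain at every iteration.

#include <Rcpp.h>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();
static const double LOG_SQRT_2PI = 0.9189385332046727;

// log Phi(z): erfc-based (machine precision) with an asymptotic branch for
// the far left tail where erfc underflows. Much faster than R::pnorm in
// the sampler's inner loop.
static inline double log_phi(double z) {
  if (z < -37.0) {
    double z2 = z * z;
    return -0.5 * z2 - LOG_SQRT_2PI - std::log(-z) +
           std::log1p(-1.0 / z2 + 3.0 / (z2 * z2));
  }
  return std::log(0.5 * std::erfc(-z * M_SQRT1_2));
}

// log pdf of ex-Gaussian (Gaussian mu/sigma convolved with Exp mean tau),
// evaluated in log space for stability at small tau.
static inline double exg_logpdf(double t, double mu, double sigma, double tau) {
  double z = (t - mu) / sigma - sigma / tau;
  double k = (mu - t) / tau + 0.5 * sigma * sigma / (tau * tau);
  return -std::log(tau) + k + log_phi(z);
}

// log survival: S(t) = Phi(-(t-mu)/sigma) + exp(k) * Phi((t-mu)/sigma - sigma/tau)
// both terms positive -> log-sum-exp, no cancellation.
static inline double exg_logsf(double t, double mu, double sigma, double tau) {
  double z1 = (t - mu) / sigma;
  double a = log_phi(-z1);
  double k = (mu - t) / tau + 0.5 * sigma * sigma / (tau * tau);
  double b = k + log_phi(z1 - sigma / tau);
  double m = std::max(a, b);
  if (m == NEG_INF) return NEG_INF;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

static inline double exg_logcdf(double t, double mu, double sigma, double tau) {
  double ls = exg_logsf(t, mu, sigma, tau);
  if (ls >= 0.0) return NEG_INF;           // S == 1 to machine precision
  return std::log1p(-std::exp(ls));
}

// Gauss-Legendre nodes/weights on [-1, 1] for the three quadrature panels
// (20 points over the Gaussian bulk, 16 over the main exponential decay,
// 8 over the far tail); layout validated against adaptive quadrature.
static const int GL_NQ = 44;
static const double GLA_X[20] = {
  -0.9931285991850950, -0.9639719272779138, -0.9122344282513259,
  -0.8391169718222188, -0.7463319064601508, -0.6360536807265150,
  -0.5108670019508271, -0.3737060887154195, -0.2277858511416451,
  -0.0765265211334973, 0.0765265211334973, 0.2277858511416451,
  0.3737060887154195, 0.5108670019508271, 0.6360536807265150,
  0.7463319064601508, 0.8391169718222188, 0.9122344282513259,
  0.9639719272779138, 0.9931285991850950};
static const double GLA_W[20] = {
  0.0176140071391509, 0.0406014298003864, 0.0626720483341088,
  0.0832767415767047, 0.1019301198172407, 0.1181945319615186,
  0.1316886384491769, 0.1420961093183824, 0.1491729864726042,
  0.1527533871307263, 0.1527533871307263, 0.1491729864726042,
  0.1420961093183824, 0.1316886384491769, 0.1181945319615186,
  0.1019301198172407, 0.0832767415767047, 0.0626720483341088,
  0.0406014298003864, 0.0176140071391509};
static const double GLB_X[16] = {
  -0.9894009349916499, -0.9445750230732326, -0.8656312023878318,
  -0.7554044083550030, -0.6178762444026438, -0.4580167776572274,
  -0.2816035507792589, -0.0950125098376374, 0.0950125098376374,
  0.2816035507792589, 0.4580167776572274, 0.6178762444026438,
  0.7554044083550030, 0.8656312023878318, 0.9445750230732326,
  0.9894009349916499};
static const double GLB_W[16] = {
  0.0271524594117542, 0.0622535239386475, 0.0951585116824926,
  0.1246289712555341, 0.1495959888165767, 0.1691565193950026,
  0.1826034150449236, 0.1894506104550686, 0.1894506104550686,
  0.1826034150449236, 0.1691565193950026, 0.1495959888165767,
  0.1246289712555341, 0.0951585116824926, 0.0622535239386475,
  0.0271524594117542};
static const double GLC_X[8] = {
  -0.9602898564975362, -0.7966664774136267, -0.5255324099163290,
  -0.1834346424956498, 0.1834346424956498, 0.5255324099163290,
  0.7966664774136267, 0.9602898564975362};
static const double GLC_W[8] = {
  0.1012285362903771, 0.2223810344533744, 0.3137066458778869,
  0.3626837833783617, 0.3626837833783617, 0.3137066458778869,
  0.2223810344533744, 0.1012285362903771};

// quadrature nodes for the inhibition integral, with the stop finish-time
// density pre-evaluated (it does not depend on the SSD)
struct StopQuad {
  double u[GL_NQ];
  double wf[GL_NQ];  // weight * f_stop(u)
};

static void stop_quad_init(StopQuad &q, const double *st) {
  double lo = st[0] - 6.0 * st[1];
  if (lo < 0.0) lo = 0.0;
  double p1 = st[0] + 6.0 * st[1];
  if (p1 <= lo) p1 = lo + 6.0 * st[1];
  double p2 = p1 + 12.0 * st[2];
  double p3 = p1 + 60.0 * st[2];
  const double *px[3] = {GLA_X, GLB_X, GLC_X};
  const double *pw[3] = {GLA_W, GLB_W, GLC_W};
  const int pn[3] = {20, 16, 8};
  const double edges[4] = {lo, p1, p2, p3};
  int k = 0;
  for (int pan = 0; pan < 3; ++pan) {
    double a = edges[pan], b = edges[pan + 1];
    double c = 0.5 * (a + b), h = 0.5 * (b - a);
    for (int j = 0; j < pn[pan]; ++j) {
      q.u[k] = c + h * px[pan][j];
      q.wf[k] = h * pw[pan][j] *
        std::exp(exg_logpdf(q.u[k], st[0], st[1], st[2]));
      ++k;
    }
  }
}

// P(stop wins the race | stop triggered) at delay d. Nodes are ascending
// in u and the go survivals are decreasing in t, so once a node's
// contribution is negligible relative to the accumulated mass the
// remaining tail can be dropped.
static double p_inhibit_quad(const StopQuad &q, double d, const double *gm,
                             const double *gx) {
  double total = 0.0;
  for (int k = 0; k < GL_NQ; ++k) {
    if (q.wf[k] == 0.0) continue;
    double t = d + q.u[k];
    double ls = exg_logsf(t, gm[0], gm[1], gm[2]) +
                exg_logsf(t, gx[0], gx[1], gx[2]);
    double contrib = q.wf[k] * std::exp(ls);
    total += contrib;
    if (contrib < 1e-17 && total > 1e-12 && k > 20) break;
  }
  if (total > 1.0) total = 1.0;
  if (total < 0.0) total = 0.0;
  return total;
}

static double p_inhibit(double d, const double *st, const double *gm,
                        const double *gx) {
  StopQuad q;
  stop_quad_init(q, st);
  return p_inhibit_quad(q, d, gm, gx);
}

// ---- exported scalar/vector wrappers -------------------------------------

// [[Rcpp::export]]
NumericVector exg_logpdf_cpp(NumericVector t, NumericVector mu,
                             NumericVector sigma, NumericVector tau) {
  R_xlen_t n = std::max(std::max(t.size(), mu.size()),
                        std::max(sigma.size(), tau.size()));
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = exg_logpdf(t[i % t.size()], mu[i % mu.size()],
                        sigma[i % sigma.size()], tau[i % tau.size()]);
  return out;
}

// [[Rcpp::export]]
NumericVector exg_logsf_cpp(NumericVector t, NumericVector mu,
                            NumericVector sigma, NumericVector tau) {
  R_xlen_t n = std::max(std::max(t.size(), mu.size()),
                        std::max(sigma.size(), tau.size()));
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = exg_logsf(t[i % t.size()], mu[i % mu.size()],
                       sigma[i % sigma.size()], tau[i % tau.size()]);
  return out;
}

// [[Rcpp::export]]
NumericVector exg_logcdf_cpp(NumericVector t, NumericVector mu,
                             NumericVector sigma, NumericVector tau) {
  R_xlen_t n = std::max(std::max(t.size(), mu.size()),
                        std::max(sigma.size(), tau.size()));
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = exg_logcdf(t[i % t.size()], mu[i % mu.size()],
                        sigma[i % sigma.size()], tau[i % tau.size()]);
  return out;
}

// [[Rcpp::export]]
NumericVector inhibit_prob_cpp(NumericVector d, NumericVector stop_par,
                               NumericVector gm_par, NumericVector gx_par) {
  const double *st = REAL(stop_par), *gm = REAL(gm_par), *gx = REAL(gx_par);
  NumericVector out(d.size());
  for (R_xlen_t i = 0; i < d.size(); ++i)
    out[i] = p_inhibit(d[i], st, gm, gx);
  return out;
}

// ---- dataset log-likelihood, one row of `par` per chain ------------------
//
// par columns (natural scale):
//   0 mu_stop 1 sigma_stop 2 tau_stop
//   3 mu_gm   4 sigma_gm   5 tau_gm      (go runner matching the stimulus)
//   6 mu_gx   7 sigma_gx   8 tau_gx      (mismatching go runner)
//   9 p_tf   10 p_gf
// data: go responded (rt, match), count of go omissions, signal-respond
// (rt, ssd, match), inhibited stop/no-go ssds.

// go-trial component only: depends on the two go runners and p_gf
// [[Rcpp::export]]
NumericVector race_loglik_go_cpp(NumericMatrix par,
                                 NumericVector go_rt, IntegerVector go_match,
                                 int n_go_omit) {
  int nch = par.nrow();
  NumericVector out(nch);
  for (int c = 0; c < nch; ++c) {
    double gm[3] = {par(c, 3), par(c, 4), par(c, 5)};
    double gx[3] = {par(c, 6), par(c, 7), par(c, 8)};
    double pgf = par(c, 10);
    if (!(gm[1] > 0 && gm[2] > 0 && gx[1] > 0 && gx[2] > 0 &&
          pgf >= 0 && pgf <= 1)) { out[c] = NEG_INF; continue; }
    double ll = 0.0;
    double log1m_pgf = std::log1p(-pgf);
    for (R_xlen_t i = 0; i < go_rt.size(); ++i) {
      double t = go_rt[i];
      const double *fst = go_match[i] ? gm : gx;
      const double *oth = go_match[i] ? gx : gm;
      ll += log1m_pgf + exg_logpdf(t, fst[0], fst[1], fst[2]) +
            exg_logsf(t, oth[0], oth[1], oth[2]);
      if (ll == NEG_INF) break;
    }
    if (n_go_omit > 0 && ll > NEG_INF) {
      if (pgf <= 0.0) ll = NEG_INF;
      else ll += n_go_omit * std::log(pgf);
    }
    out[c] = ll;
  }
  return out;
}

// product of the two go survivals, S_match(t) * S_mismatch(t)
static inline double go_surv_prod(double t, const double *gm,
                                  const double *gx) {
  return std::exp(exg_logsf(t, gm[0], gm[1], gm[2]) +
                  exg_logsf(t, gx[0], gx[1], gx[2]));
}

// sampler fast path for many inhibited SSDs: tabulate the go-survival
// product on a uniform grid once per chain and evaluate the inhibition
// integral with Catmull-Rom interpolation at the quadrature nodes
// (interpolation error ~1e-7, far below the Monte-Carlo tolerances the
// likelihood is validated against)
struct GoSurvGrid {
  double t0, h;
  int n;
  std::vector<double> g;
};

static void go_grid_init(GoSurvGrid &gr, double tmin, double tmax,
                         const double *gm, const double *gx) {
  const int n = 128;
  if (tmax <= tmin) tmax = tmin + 1e-3;
  gr.t0 = tmin;
  gr.h = (tmax - tmin) / (n - 1);
  gr.n = n;
  gr.g.resize(n);
  for (int i = 0; i < n; ++i) {
    gr.g[i] = go_surv_prod(tmin + i * gr.h, gm, gx);
  }
}

static inline double go_grid_eval(const GoSurvGrid &gr, double t) {
  double x = (t - gr.t0) / gr.h;
  int i = (int)std::floor(x);
  if (i < 1) i = 1;
  if (i > gr.n - 3) i = gr.n - 3;
  double u = x - i;
  const double *g = gr.g.data();
  double a = g[i - 1], b = g[i], c = g[i + 1], d = g[i + 2];
  double val = b + 0.5 * u * (c - a +
      u * (2.0 * a - 5.0 * b + 4.0 * c - d +
           u * (3.0 * (b - c) + d - a)));
  return val < 0.0 ? 0.0 : val;
}

// stop/no-go component: signal-respond and inhibited trials (all params)
// [[Rcpp::export]]
NumericVector race_loglik_sig_cpp(NumericMatrix par,
                                  NumericVector sr_rt, NumericVector sr_ssd,
                                  IntegerVector sr_match,
                                  NumericVector inh_ssd) {
  int nch = par.nrow();
  NumericVector out(nch);
  for (int c = 0; c < nch; ++c) {
    double st[3] = {par(c, 0), par(c, 1), par(c, 2)};
    double gm[3] = {par(c, 3), par(c, 4), par(c, 5)};
    double gx[3] = {par(c, 6), par(c, 7), par(c, 8)};
    double ptf = par(c, 9), pgf = par(c, 10);
    if (!(st[1] > 0 && st[2] > 0 && gm[1] > 0 && gm[2] > 0 &&
          gx[1] > 0 && gx[2] > 0 && ptf >= 0 && ptf <= 1 &&
          pgf >= 0 && pgf <= 1)) { out[c] = NEG_INF; continue; }
    double ll = 0.0;
    double log1m_pgf = std::log1p(-pgf);
    for (R_xlen_t i = 0; i < sr_rt.size(); ++i) {
      double t = sr_rt[i], d = sr_ssd[i];
      const double *fst = sr_match[i] ? gm : gx;
      const double *oth = sr_match[i] ? gx : gm;
      double surv_stop = std::exp(exg_logsf(t - d, st[0], st[1], st[2]));
      double cens = ptf + (1.0 - ptf) * surv_stop;
      if (cens <= 0.0) { ll = NEG_INF; break; }
      ll += log1m_pgf + exg_logpdf(t, fst[0], fst[1], fst[2]) +
            exg_logsf(t, oth[0], oth[1], oth[2]) + std::log(cens);
      if (ll == NEG_INF) break;
    }
    if (ll > NEG_INF && inh_ssd.size() > 0) {
      std::vector<double> ud;
      std::vector<int> cnt;
      double dmin = inh_ssd[0], dmax = inh_ssd[0];
      for (R_xlen_t i = 0; i < inh_ssd.size(); ++i) {
        if (inh_ssd[i] < dmin) dmin = inh_ssd[i];
        if (inh_ssd[i] > dmax) dmax = inh_ssd[i];
        bool found = false;
        for (size_t j = 0; j < ud.size(); ++j) {
          if (ud[j] == inh_ssd[i]) { ++cnt[j]; found = true; break; }
        }
        if (!found) { ud.push_back(inh_ssd[i]); cnt.push_back(1); }
      }
      StopQuad q;
      stop_quad_init(q, st);
      bool use_grid = ud.size() > 3;
      GoSurvGrid gr;
      if (use_grid) {
        go_grid_init(gr, dmin + q.u[0], dmax + q.u[GL_NQ - 1], gm, gx);
      }
      for (size_t j = 0; j < ud.size(); ++j) {
        double pi;
        if (use_grid) {
          double total = 0.0;
          for (int k = 0; k < GL_NQ; ++k) {
            if (q.wf[k] == 0.0) continue;
            double contrib = q.wf[k] * go_grid_eval(gr, ud[j] + q.u[k]);
            total += contrib;
            if (contrib < 1e-17 && total > 1e-12 && k > 20) break;
          }
          pi = total > 1.0 ? 1.0 : (total < 0.0 ? 0.0 : total);
        } else {
          pi = p_inhibit_quad(q, ud[j], gm, gx);
        }
        double p = pgf + (1.0 - pgf) * (1.0 - ptf) * pi;
        if (p <= 0.0) { ll = NEG_INF; break; }
        ll += cnt[j] * std::log(p);
      }
    }
    out[c] = ll;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector race_loglik_chains_cpp(NumericMatrix par,
                                     NumericVector go_rt, IntegerVector go_match,
                                     int n_go_omit,
                                     NumericVector sr_rt, NumericVector sr_ssd,
                                     IntegerVector sr_match,
                                     NumericVector inh_ssd) {
  int nch = par.nrow();
  NumericVector out(nch);
  for (int c = 0; c < nch; ++c) {
    double st[3] = {par(c, 0), par(c, 1), par(c, 2)};
    double gm[3] = {par(c, 3), par(c, 4), par(c, 5)};
    double gx[3] = {par(c, 6), par(c, 7), par(c, 8)};
    double ptf = par(c, 9), pgf = par(c, 10);
    bool bad = !(st[1] > 0 && st[2] > 0 && gm[1] > 0 && gm[2] > 0 &&
                 gx[1] > 0 && gx[2] > 0 && ptf >= 0 && ptf <= 1 &&
                 pgf >= 0 && pgf <= 1);
    if (bad) { out[c] = NEG_INF; continue; }
    double ll = 0.0;
    double log1m_pgf = std::log1p(-pgf);

    // go trials with a response
    for (R_xlen_t i = 0; i < go_rt.size(); ++i) {
      double t = go_rt[i];
      const double *fst = go_match[i] ? gm : gx;
      const double *oth = go_match[i] ? gx : gm;
      ll += log1m_pgf + exg_logpdf(t, fst[0], fst[1], fst[2]) +
            exg_logsf(t, oth[0], oth[1], oth[2]);
      if (ll == NEG_INF) break;
    }
    // go omissions
    if (n_go_omit > 0) {
      if (pgf <= 0.0) ll = NEG_INF;
      else ll += n_go_omit * std::log(pgf);
    }
    // signal-respond trials (stop/no-go with a response)
    if (ll > NEG_INF) {
      for (R_xlen_t i = 0; i < sr_rt.size(); ++i) {
        double t = sr_rt[i], d = sr_ssd[i];
        const double *fst = sr_match[i] ? gm : gx;
        const double *oth = sr_match[i] ? gx : gm;
        double surv_stop = std::exp(exg_logsf(t - d, st[0], st[1], st[2]));
        double cens = ptf + (1.0 - ptf) * surv_stop;
        if (cens <= 0.0) { ll = NEG_INF; break; }
        ll += log1m_pgf + exg_logpdf(t, fst[0], fst[1], fst[2]) +
              exg_logsf(t, oth[0], oth[1], oth[2]) + std::log(cens);
        if (ll == NEG_INF) break;
      }
    }
    // inhibited stop/no-go trials: SSDs sit on the staircase lattice, so
    // deduplicate before integrating
    if (ll > NEG_INF && inh_ssd.size() > 0) {
      std::vector<double> ud;
      std::vector<int> cnt;
      for (R_xlen_t i = 0; i < inh_ssd.size(); ++i) {
        bool found = false;
        for (size_t j = 0; j < ud.size(); ++j) {
          if (ud[j] == inh_ssd[i]) { ++cnt[j]; found = true; break; }
        }
        if (!found) { ud.push_back(inh_ssd[i]); cnt.push_back(1); }
      }
      StopQuad q;
      stop_quad_init(q, st);
      for (size_t j = 0; j < ud.size(); ++j) {
        double pi = p_inhibit_quad(q, ud[j], gm, gx);
        double p = pgf + (1.0 - pgf) * (1.0 - ptf) * pi;
        if (p <= 0.0) { ll = NEG_INF; break; }
        ll += cnt[j] * std::log(p);
      }
    }
    out[c] = ll;
  }
  return out;
}
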