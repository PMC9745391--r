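// Slice-within-Gibbs MCMC for the two-species N-mixture co-abundance model.
//
// Latent state is kept explicit: integer abundances N[i][j] (updated by
// categorical enumeration up to the truncation bound K) and, when the
// overdispersion random effect is on, one epsilon per species x unit x
// observed occasion. All continuous parameters are updated by Neal (2003)
// slice sampling with stepping-out and shrinkage, which needs no tuning
// and leaves the stationary law exactly the posterior. Randomness comes
// from R's RNG, so set.seed() on the R side makes chains reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// guard against exp overflow in linear predictors; beyond this the
// likelihood is effectively zero anyway
static inline double safe_exp(double x) {
  return (x > 500.0) ? R_PosInf : std::exp(x);
}

struct Model {
  int J, O, L, C, K;
  bool izip, binom, odre;
  double eps_p, coef_sd, sd_upper;
  // data
  std::vector<int> n;        // [2][J][O], -1 when masked
  std::vector<int> Z;        // [2][J] effective zero informant (all 1 if poisson)
  std::vector<double> X;     // [J][C]
  std::vector<int> li;       // [J], 0-based landscape index
  std::vector<double> eff;   // [J]
  // state
  double a0[2];
  std::vector<double> acov;  // [2][C]
  std::vector<double> land;  // [2][L]
  double sigl[2], delta, b0[2], b1[2], tau[2];
  std::vector<int> N;        // [2][J]
  std::vector<double> eps;   // [2][J][O]
  // caches
  std::vector<double> eta;   // [2][J] abundance linear predictor w/o delta term
  std::vector<double> lgfact;// lgamma(m+1), m = 0..K+1

  inline int idn(int i, int j, int k) const { return (i * J + j) * O + k; }
  inline int idj(int i, int j) const { return i * J + j; }

  void refresh_eta(int i) {
    for (int j = 0; j < J; ++j) {
      double e = a0[i] + land[i * L + li[j]];
      for (int c = 0; c < C; ++c) e += acov[i * C + c] * X[j * C + c];
      eta[idj(i, j)] = e;
    }
  }

  inline double clamp_p(double p) const {
    if (p < eps_p) return eps_p;
    if (p > 1.0 - eps_p) return 1.0 - eps_p;
    return p;
  }

  // log detection density of count x given abundance t and linear pred lp
  inline double ldet(int x, int t, double lp) const {
    if (binom) {
      if (x > t) return NEG_INF;
      double p = clamp_p(1.0 / (1.0 + std::exp(-lp)));
      return lgfact[t] - lgfact[t - x] - lgfact[x] +
             x * std::log(p) + (t - x) * std::log1p(-p);
    }
    double rate = t * safe_exp(lp);
    if (rate <= 0.0) return (x == 0) ? 0.0 : NEG_INF;
    if (!R_FINITE(rate)) return NEG_INF;
    return x * std::log(rate) - rate - lgfact[x];
  }

  inline double lp_det(int i, int j, int k) const {
    return b0[i] + b1[i] * eff[j] + (odre ? eps[idn(i, j, k)] : 0.0);
  }
};

// Neal (2003) slice sampler for a scalar with bounded support.
template <typename F>
static double slice_sample(F&& logf, double x0, double w, double lower,
                           double upper, int max_steps = 30) {
  double f0 = logf(x0);
  if (!R_FINITE(f0)) return x0;  // stuck start; caller guards against this
  double y = f0 - exp_rand();
  double u = unif_rand() * w;
  double lo = x0 - u, hi = lo + w;
  int jj = (int)std::floor(unif_rand() * max_steps);
  int kk = max_steps - 1 - jj;
  while (jj-- > 0 && lo > lower && logf(lo) > y) lo -= w;
  while (kk-- > 0 && hi < upper && logf(hi) > y) hi += w;
  if (lo < lower) lo = lower;
  if (hi > upper) hi = upper;
  for (int it = 0; it < 100; ++it) {
    double x1 = lo + unif_rand() * (hi - lo);
    if (logf(x1) >= y) return x1;
    if (x1 < x0) lo = x1; else hi = x1;
  }
  return x0;
}

// categorical draw from log-weights lw[0..m-1]; returns index
static int sample_cat(const std::vector<double>& lw) {
  double mx = NEG_INF;
  for (double v : lw) if (v > mx) mx = v;
  if (!R_FINITE(mx)) return 0;
  double tot = 0.0;
  std::vector<double> wts(lw.size());
  for (size_t q = 0; q < lw.size(); ++q) {
    wts[q] = std::exp(lw[q] - mx);
    tot += wts[q];
  }
  double u = unif_rand() * tot, acc = 0.0;
  for (size_t q = 0; q < lw.size(); ++q) {
    acc += wts[q];
    if (u <= acc) return (int)q;
  }
  return (int)lw.size() - 1;
}

// ---- Gibbs updates -------------------------------------------------------

// update latent abundance for species i at all units; the detection
// contribution is decomposed so the inner loop over candidate t touches
// only the lgamma table, no transcendentals
static void update_N(Model& M, int i) {
  std::vector<double> lw;
  std::vector<int> ns;
  std::vector<double> logp, log1mp, lrate;
  for (int j = 0; j < M.J; ++j) {
    if (M.Z[M.idj(i, j)] == 0) { M.N[M.idj(i, j)] = 0; continue; }
    ns.clear(); logp.clear(); log1mp.clear(); lrate.clear();
    int lo = 0;
    bool anypos = false;
    for (int k = 0; k < M.O; ++k) {
      int x = M.n[M.idn(i, j, k)];
      if (x < 0) continue;
      if (x > 0) anypos = true;
      if (M.binom && x > lo) lo = x;
      ns.push_back(x);
      double lp = M.lp_det(i, j, k);
      if (M.binom) {
        double p = M.clamp_p(1.0 / (1.0 + std::exp(-lp)));
        logp.push_back(std::log(p));
        log1mp.push_back(std::log1p(-p));
      } else {
        lrate.push_back(lp);
      }
    }
    if (!M.binom && anypos && lo < 1) lo = 1;
    double lam = safe_exp(M.eta[M.idj(i, j)] +
                          (i == 1 ? M.delta * M.N[M.idj(0, j)] : 0.0));
    bool sub_term = (i == 0) && (M.Z[M.idj(1, j)] == 1);
    int N2 = M.N[M.idj(1, j)];
    double eta2 = M.eta[M.idj(1, j)];
    double llam = R_FINITE(lam) ? std::log(lam) : 0.0;
    // t-independent detection pieces
    double c0 = 0.0, S1 = 0.0, Sn = 0.0, Sr = 0.0;
    int nobs = (int)ns.size();
    for (int q = 0; q < nobs; ++q) {
      if (M.binom) {
        c0 += ns[q] * logp[q] - ns[q] * log1mp[q] - M.lgfact[ns[q]];
        S1 += log1mp[q];
      } else {
        double r = safe_exp(lrate[q]);
        c0 += ns[q] * lrate[q] - M.lgfact[ns[q]];
        Sn += ns[q];
        Sr += R_FINITE(r) ? r : 1e300;
      }
    }
    lw.assign(M.K - lo + 1, 0.0);
    for (int t = lo; t <= M.K; ++t) {
      double v = R_FINITE(lam) ? (t * llam - lam - M.lgfact[t]) : NEG_INF;
      if (R_FINITE(v)) {
        if (M.binom) {
          double s2 = 0.0;
          for (int q = 0; q < nobs; ++q) s2 += M.lgfact[t - ns[q]];
          v += nobs * M.lgfact[t] - s2 + t * S1 + c0;
        } else {
          if (t == 0) {
            v += (Sn > 0) ? NEG_INF : 0.0;
          } else {
            v += Sn * std::log((double)t) - t * Sr + c0;
          }
        }
      }
      if (sub_term && R_FINITE(v)) {
        double e2 = eta2 + M.delta * t;
        double lam2 = safe_exp(e2);
        v += R_FINITE(lam2) ? (N2 * e2 - lam2) : NEG_INF;
      }
      lw[t - lo] = v;
    }
    M.N[M.idj(i, j)] = lo + sample_cat(lw);
  }
}

// joint multiplicative rescaling of (tau_i, all eps_i..) -- the
// non-centered move that breaks the funnel coupling between the ODRE SD
// and its effects. Proposal tau' = c tau, eps' = c eps with
// log c ~ N(0, s^2); the prior and Jacobian terms collapse to log c, so
// the acceptance probability is exp(log c + sum of likelihood deltas).
static void update_tau_scale(Model& M, int i, double s = 0.4) {
  double c = std::exp(s * norm_rand());
  double taun = M.tau[i] * c;
  if (taun <= 0.0 || taun >= M.sd_upper) return;
  double d = std::log(c);
  for (int j = 0; j < M.J && R_FINITE(d); ++j) {
    int t = M.N[M.idj(i, j)];
    for (int k = 0; k < M.O; ++k) {
      int x = M.n[M.idn(i, j, k)];
      if (x < 0) continue;
      double lp0 = M.b0[i] + M.b1[i] * M.eff[j];
      double e = M.eps[M.idn(i, j, k)];
      d += M.ldet(x, t, lp0 + c * e) - M.ldet(x, t, lp0 + e);
    }
  }
  if (R_FINITE(d) && std::log(unif_rand()) < d) {
    M.tau[i] = taun;
    for (int j = 0; j < M.J; ++j)
      for (int k = 0; k < M.O; ++k) M.eps[M.idn(i, j, k)] *= c;
  }
}

// same rescaling move for (sigma_land_i, landscape intercepts)
static void update_sigl_scale(Model& M, int i, double s = 0.4) {
  double c = std::exp(s * norm_rand());
  double sn = M.sigl[i] * c;
  if (sn <= 0.0 || sn >= M.sd_upper) return;
  double d = std::log(c);
  for (int j = 0; j < M.J && R_FINITE(d); ++j) {
    if (M.Z[M.idj(i, j)] == 0) continue;
    double l0 = M.land[i * M.L + M.li[j]];
    double eta0 = M.eta[M.idj(i, j)] +
                  (i == 1 ? M.delta * M.N[M.idj(0, j)] : 0.0);
    double eta1 = eta0 + (c - 1.0) * l0;
    double lam0 = safe_exp(eta0), lam1 = safe_exp(eta1);
    if (!R_FINITE(lam1)) { d = NEG_INF; break; }
    d += M.N[M.idj(i, j)] * (eta1 - eta0) - lam1 + lam0;
  }
  if (R_FINITE(d) && std::log(unif_rand()) < d) {
    M.sigl[i] = sn;
    for (int l = 0; l < M.L; ++l) M.land[i * M.L + l] *= c;
    M.refresh_eta(i);
  }
}

// Poisson pseudo-likelihood of N given abundance params, as a function of
// one coefficient x with per-unit multiplier g_j and offset rest_j
static double abund_cond(const Model& M, int i, const std::vector<double>& rest,
                         const std::vector<double>& g, double x,
                         double prior_sd) {
  double ll = -0.5 * x * x / (prior_sd * prior_sd);
  for (int j = 0; j < M.J; ++j) {
    if (M.Z[M.idj(i, j)] == 0) continue;
    double e = rest[j] + x * g[j];
    double lam = safe_exp(e);
    if (!R_FINITE(lam)) return NEG_INF;
    ll += M.N[M.idj(i, j)] * e - lam;
  }
  return ll;
}

static void update_abundance_params(Model& M, int i) {
  std::vector<double> rest(M.J), g(M.J);
  // intercept
  for (int j = 0; j < M.J; ++j) {
    rest[j] = M.eta[M.idj(i, j)] - M.a0[i] +
              (i == 1 ? M.delta * M.N[M.idj(0, j)] : 0.0);
    g[j] = 1.0;
  }
  M.a0[i] = slice_sample([&](double x) {
    return abund_cond(M, i, rest, g, x, M.coef_sd);
  }, M.a0[i], 1.0, -50.0, 50.0);
  M.refresh_eta(i);
  // covariate effects
  for (int c = 0; c < M.C; ++c) {
    for (int j = 0; j < M.J; ++j) {
      rest[j] = M.eta[M.idj(i, j)] - M.acov[i * M.C + c] * M.X[j * M.C + c] +
                (i == 1 ? M.delta * M.N[M.idj(0, j)] : 0.0);
      g[j] = M.X[j * M.C + c];
    }
    M.acov[i * M.C + c] = slice_sample([&](double x) {
      return abund_cond(M, i, rest, g, x, M.coef_sd);
    }, M.acov[i * M.C + c], 1.0, -50.0, 50.0);
    M.refresh_eta(i);
  }
  // landscape random intercepts (prior sd = sigl[i])
  for (int l = 0; l < M.L; ++l) {
    for (int j = 0; j < M.J; ++j) {
      g[j] = (M.li[j] == l) ? 1.0 : 0.0;
      rest[j] = M.eta[M.idj(i, j)] - M.land[i * M.L + l] * g[j] +
                (i == 1 ? M.delta * M.N[M.idj(0, j)] : 0.0);
    }
    M.land[i * M.L + l] = slice_sample([&](double x) {
      return abund_cond(M, i, rest, g, x, M.sigl[i]);
    }, M.land[i * M.L + l], 1.0, -50.0, 50.0);
    M.refresh_eta(i);
  }
  // landscape SD, Uniform(0, sd_upper) prior
  {
    double sse = 0.0;
    for (int l = 0; l < M.L; ++l) {
      double v = M.land[i * M.L + l];
      sse += v * v;
    }
    int m = M.L;
    M.sigl[i] = slice_sample([&](double s) {
      if (s <= 0.0 || s >= M.sd_upper) return NEG_INF;
      return -m * std::log(s) - 0.5 * sse / (s * s);
    }, M.sigl[i], 0.5, 1e-12, M.sd_upper);
  }
}

static void update_delta(Model& M) {
  std::vector<double> rest(M.J), g(M.J);
  for (int j = 0; j < M.J; ++j) {
    rest[j] = M.eta[M.idj(1, j)];
    g[j] = (double)M.N[M.idj(0, j)];
  }
  M.delta = slice_sample([&](double x) {
    return abund_cond(M, 1, rest, g, x, M.coef_sd);
  }, M.delta, 0.5, -50.0, 50.0);
}

static void update_detection_params(Model& M, int i) {
  // collect observed cells once
  std::vector<int> js, ks, ns;
  for (int j = 0; j < M.J; ++j)
    for (int k = 0; k < M.O; ++k) {
      int x = M.n[M.idn(i, j, k)];
      if (x >= 0) { js.push_back(j); ks.push_back(k); ns.push_back(x); }
    }
  auto det_cond = [&](double b0x, double b1x) {
    double ll = -0.5 * (b0x * b0x + b1x * b1x) / (M.coef_sd * M.coef_sd);
    for (size_t q = 0; q < js.size(); ++q) {
      double lp = b0x + b1x * M.eff[js[q]] +
                  (M.odre ? M.eps[M.idn(i, js[q], ks[q])] : 0.0);
      double v = M.ldet(ns[q], M.N[M.idj(i, js[q])], lp);
      if (!R_FINITE(v)) return NEG_INF;
      ll += v;
    }
    return ll;
  };
  M.b0[i] = slice_sample([&](double x) { return det_cond(x, M.b1[i]); },
                         M.b0[i], 1.0, -50.0, 50.0);
  M.b1[i] = slice_sample([&](double x) { return det_cond(M.b0[i], x); },
                         M.b1[i], 1.0, -50.0, 50.0);
  if (M.odre) {
    // epsilon per observed cell
    double t2 = M.tau[i] * M.tau[i];
    for (size_t q = 0; q < js.size(); ++q) {
      int j = js[q], k = ks[q], x = ns[q];
      double lp0 = M.b0[i] + M.b1[i] * M.eff[j];
      int t = M.N[M.idj(i, j)];
      int id = M.idn(i, j, k);
      M.eps[id] = slice_sample([&](double e) {
        return -0.5 * e * e / t2 + M.ldet(x, t, lp0 + e);
      }, M.eps[id], 1.0, -40.0, 40.0);
    }
    // tau, Uniform(0, sd_upper) prior
    double sse = 0.0;
    for (size_t q = 0; q < js.size(); ++q) {
      double e = M.eps[M.idn(i, js[q], ks[q])];
      sse += e * e;
    }
    int m = (int)js.size();
    M.tau[i] = slice_sample([&](double s) {
      if (s <= 0.0 || s >= M.sd_upper) return NEG_INF;
      return -m * std::log(s) - 0.5 * sse / (s * s);
    }, M.tau[i], 0.3, 1e-12, M.sd_upper);
  }
}

// ---- driver --------------------------------------------------------------

// [[Rcpp::export(name = ".run_chain")]]
List run_chain(IntegerVector n_arr, IntegerVector dims, IntegerMatrix Z,
               NumericMatrix X, IntegerVector li, NumericVector eff,
               List spec, List init, int n_iter, int n_burn, int thin,
               bool monitor_latent) {
  Model M;
  M.J = dims[1]; M.O = dims[2];
  M.C = X.ncol(); M.L = 0;
  for (int j = 0; j < M.J; ++j) if (li[j] > M.L) M.L = li[j];
  M.K = as<int>(spec["K"]);
  M.izip = as<bool>(spec["izip"]);
  M.binom = as<bool>(spec["binom"]);
  M.odre = as<bool>(spec["odre"]);
  M.eps_p = as<double>(spec["eps_p"]);
  M.coef_sd = as<double>(spec["coef_sd"]);
  M.sd_upper = as<double>(spec["sd_upper"]);

  M.n.assign(n_arr.begin(), n_arr.end());  // already flattened [2][J][O]
  M.Z.resize(2 * M.J);
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < M.J; ++j)
      M.Z[M.idj(i, j)] = M.izip ? Z(i, j) : 1;
  M.X.resize(M.J * M.C);
  for (int j = 0; j < M.J; ++j)
    for (int c = 0; c < M.C; ++c) M.X[j * M.C + c] = X(j, c);
  M.li.resize(M.J);
  for (int j = 0; j < M.J; ++j) M.li[j] = li[j] - 1;
  M.eff.assign(eff.begin(), eff.end());
  M.lgfact.resize(M.K + 2);
  for (int m = 0; m <= M.K + 1; ++m) M.lgfact[m] = std::lgamma(m + 1.0);

  // initial state
  NumericVector i_a0 = init["alpha0"], i_sigl = init["sigma_land"],
                i_b0 = init["beta0"], i_b1 = init["beta1"],
                i_tau = init["tau"];
  NumericMatrix i_acov = init["alpha"], i_land = init["land"];
  IntegerMatrix i_N = init["N"];
  for (int i = 0; i < 2; ++i) {
    M.a0[i] = i_a0[i]; M.sigl[i] = i_sigl[i];
    M.b0[i] = i_b0[i]; M.b1[i] = i_b1[i]; M.tau[i] = i_tau[i];
  }
  M.acov.resize(2 * M.C);
  for (int i = 0; i < 2; ++i)
    for (int c = 0; c < M.C; ++c) M.acov[i * M.C + c] = i_acov(i, c);
  M.land.resize(2 * M.L);
  for (int i = 0; i < 2; ++i)
    for (int l = 0; l < M.L; ++l) M.land[i * M.L + l] = i_land(i, l);
  M.delta = as<double>(init["delta"]);
  M.N.resize(2 * M.J);
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < M.J; ++j) M.N[M.idj(i, j)] = i_N(i, j);
  M.eps.assign(2 * M.J * M.O, 0.0);
  M.eta.resize(2 * M.J);
  M.refresh_eta(0); M.refresh_eta(1);

  int n_top = 2 + 2 * M.C + 2 * M.L + 2 + 1 + 2 + 2 + (M.odre ? 2 : 0);
  int n_lat = monitor_latent ? (2 * M.J + (M.odre ? 2 * M.J * M.O : 0)) : 0;
  int n_save = (n_iter - n_burn) / thin;
  NumericMatrix draws(n_save, n_top + n_lat);

  GetRNGstate();
  int row = 0;
  for (int it = 1; it <= n_iter; ++it) {
    update_N(M, 0);
    update_N(M, 1);
    update_abundance_params(M, 0);
    update_abundance_params(M, 1);
    update_sigl_scale(M, 0);
    update_sigl_scale(M, 1);
    update_delta(M);
    update_detection_params(M, 0);
    update_detection_params(M, 1);
    if (M.odre) { update_tau_scale(M, 0); update_tau_scale(M, 1); }
    if (it > n_burn && ((it - n_burn) % thin == 0) && row < n_save) {
      int c = 0;
      for (int i = 0; i < 2; ++i) draws(row, c++) = M.a0[i];
      for (int i = 0; i < 2; ++i)
        for (int cc = 0; cc < M.C; ++cc) draws(row, c++) = M.acov[i * M.C + cc];
      for (int i = 0; i < 2; ++i)
        for (int l = 0; l < M.L; ++l) draws(row, c++) = M.land[i * M.L + l];
      for (int i = 0; i < 2; ++i) draws(row, c++) = M.sigl[i];
      draws(row, c++) = M.delta;
      for (int i = 0; i < 2; ++i) draws(row, c++) = M.b0[i];
      for (int i = 0; i < 2; ++i) draws(row, c++) = M.b1[i];
      if (M.odre) for (int i = 0; i < 2; ++i) draws(row, c++) = M.tau[i];
      if (monitor_latent) {
        for (int i = 0; i < 2; ++i)
          for (int j = 0; j < M.J; ++j) draws(row, c++) = M.N[M.idj(i, j)];
        if (M.odre)
          for (int q = 0; q < 2 * M.J * M.O; ++q) draws(row, c++) = M.eps[q];
      }
      ++row;
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();
  return List::create(_["draws"] = draws, _["n_top"] = n_top,
                      _["L"] = M.L);
}
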