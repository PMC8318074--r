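#include <Rcpp.h>
using namespace Rcpp;

// 11-node Gauss-Legendre rule on [-1, 1]; used to integrate the trial
// density over the uniform starting-point range z +/- sz/2.
static const double GL_X[11] = {
  -0.97822865814605620, -0.88706259976809454, -0.73015200557404891,
  -0.51909612920681214, -0.26954315595234446,  0.0,
   0.26954315595234490,  0.51909612920681159,  0.73015200557404913,
   0.88706259976809509,  0.97822865814605697};
static const double GL_W[11] = {
  0.055668567116170103, 0.125580369464904557, 0.186290210927737010,
  0.233193764591989872, 0.262804544510246929, 0.272925086777901393,
  0.262804544510245319, 0.233193764591991148, 0.186290210927734484,
  0.125580369464904057, 0.055668567116173344};

// Defective density of absorption at the LOWER boundary at decision time t,
// for a Wiener process with diffusion coefficient 1, boundary separation a,
// drift v and relative starting point w in (0,1).  Series representation
// with the standard small-time / large-time switch; eps is the truncation
// tolerance of the infinite sums.
static double wfpt_lower(double t, double a, double v, double w, double eps) {
  if (!(t > 0.0) || !R_finite(t)) return 0.0;
  double tt = t / (a * a);

  double kl, ks;
  if (M_PI * tt * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * eps) / (M_PI * M_PI * tt));
    double fl = 1.0 / (M_PI * std::sqrt(tt));
    if (kl < fl) kl = fl;
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }
  double tmp = 2.0 * std::sqrt(2.0 * M_PI * tt) * eps;
  if (tmp < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt * std::log(tmp));
    double fs = std::sqrt(tt) + 1.0;
    if (ks < fs) ks = fs;
  } else {
    ks = 2.0;
  }

  double p = 0.0;
  if (ks < kl) { // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = -(int)std::floor((K - 1) / 2.0);
    int hi = (int)std::ceil((K - 1) / 2.0);
    for (int k = lo; k <= hi; ++k) {
      double wk = w + 2.0 * k;
      p += wk * std::exp(-wk * wk / (2.0 * tt));
    }
    p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {       // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k)
      p += k * std::exp(-0.5 * k * k * M_PI * M_PI * tt) *
           std::sin(k * M_PI * w);
    p *= M_PI;
  }

  double dens = p * std::exp(-v * a * w - 0.5 * v * v * t) / (a * a);
  return dens > 0.0 ? dens : 0.0;
}

// Density at either boundary, integrating over the uniform starting-point
// range when sz > 0.  The upper boundary is obtained by reflection:
// (v, w) -> (-v, 1 - w).
static double wfpt_dens(double t, bool upper_bound, double a, double v,
                        double z, double sz, double eps) {
  double vv = upper_bound ? -v : v;
  double w0 = upper_bound ? 1.0 - z : z;
  if (sz <= 0.0) return wfpt_lower(t, a, vv, w0, eps);
  double s = 0.0;
  for (int i = 0; i < 11; ++i) {
    double w = w0 + 0.5 * sz * GL_X[i];
    s += GL_W[i] * wfpt_lower(t, a, vv, w, eps);
  }
  return 0.5 * s; // GL weights sum to 2
}

// [[Rcpp::export]]
NumericVector wfpt_density_cpp(NumericVector t_dec, LogicalVector upper,
                               double a, double v, double z, double sz,
                               double eps) {
  int n = t_dec.size();
  bool rec = (upper.size() == 1);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    bool up = rec ? (bool)upper[0] : (bool)upper[i];
    out[i] = wfpt_dens(t_dec[i], up, a, v, z, sz, eps);
  }
  return out;
}

// Sum of trial log-likelihoods for one subject.  upper[i] codes the choice
// (1 = desirable-state judgment, the upper boundary), desir[i] the true
// state (1 = desirable).  Drift magnitude is b0 + b1 * desir when has_bias,
// else b0; its sign points toward the correct boundary.
static double subject_ll(const double *lrt, const int *upper, const int *desir,
                         int n, double a, double t0, double z, double sz,
                         double b0, double b1, bool has_bias, double eps) {
  if (!(a > 0.0) || !(z - 0.5 * sz > 0.0) || !(z + 0.5 * sz < 1.0))
    return R_NegInf;
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double t = lrt[i] - t0;
    if (!(t > 0.0)) return R_NegInf;
    double vmag = has_bias ? (b0 + b1 * desir[i]) : b0;
    double veff = desir[i] ? vmag : -vmag;
    double d = wfpt_dens(t, upper[i] != 0, a, veff, z, sz, eps);
    if (!(d > 0.0)) return R_NegInf;
    ll += std::log(d);
  }
  return ll;
}

// [[Rcpp::export]]
double ddm_loglik_cpp(NumericVector log_rt, IntegerVector upper,
                      IntegerVector desir, double a, double t0, double z,
                      double sz, double b0, double b1, bool has_bias,
                      double eps) {
  return subject_ll(REAL(log_rt), INTEGER(upper), INTEGER(desir),
                    log_rt.size(), a, t0, z, sz, b0, b1, has_bias, eps);
}

// Euler-Maruyama first-passage simulation with Brownian-bridge crossing
// correction between steps (makes the discretization bias O(dt) rather
// than O(sqrt(dt))).  Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
List simulate_fp_cpp(int n, double a, double v, double z, double sz,
                     double dt, double t_max) {
  if (dt <= 0.0) stop("step size `dt` must be positive");
  NumericVector times(n);
  IntegerVector bound(n); // 1 = upper, 0 = lower
  double sdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double w = z + (sz > 0.0 ? sz * (unif_rand() - 0.5) : 0.0);
    double x = a * w;
    double t = 0.0;
    int b = -1;
    while (t < t_max) {
      double xn = x + v * dt + sdt * norm_rand();
      t += dt;
      if (xn >= a) { b = 1; break; }
      if (xn <= 0.0) { b = 0; break; }
      // bridge probabilities of an unobserved crossing within the step
      double pu = std::exp(-2.0 * (a - x) * (a - xn) / dt);
      double pl = std::exp(-2.0 * x * xn / dt);
      double u = unif_rand();
      if (u < pu) { b = 1; break; }
      if (u < pu + pl) { b = 0; break; }
      x = xn;
    }
    if (b < 0) b = (x >= 0.5 * a) ? 1 : 0; // censored at t_max (rare)
    times[i] = t;
    bound[i] = b;
  }
  return List::create(_["decision_time"] = times, _["boundary"] = bound);
}

struct SubjData {
  std::vector<double> lrt;
  std::vector<int> upper, desir;
};

// Hierarchical Metropolis-within-Gibbs sampler.
//
// Subject-level parameters on sampling scales, in column order:
//   log(a), t0, [logit(z) if free_z], b0, [b1 if has_bias]
// Each has a group-level normal (mu, sig); mu has a flat prior on
// [lo, hi], sig a half-normal(0, sig_tau) prior.  sz is a single
// group-level scalar with a flat prior on [0, sz_max].
// [[Rcpp::export]]
NumericMatrix hddm_mcmc_cpp(List log_rt, List upper, List desir,
                            bool free_z, bool has_bias,
                            int n_samples, int n_burn, int thin,
                            NumericVector mu_init, NumericVector sig_init,
                            NumericMatrix theta_init, double sz_init,
                            NumericVector lo, NumericVector hi,
                            double sig_tau, double sz_max, double eps) {
  int S = log_rt.size();
  int np = mu_init.size();
  int idx_lz = free_z ? 2 : -1;

  std::vector<SubjData> dat(S);
  for (int s = 0; s < S; ++s) {
    NumericVector r = log_rt[s];
    IntegerVector u = upper[s], d = desir[s];
    dat[s].lrt.assign(r.begin(), r.end());
    dat[s].upper.assign(u.begin(), u.end());
    dat[s].desir.assign(d.begin(), d.end());
  }

  std::vector<double> mu(mu_init.begin(), mu_init.end());
  std::vector<double> sig(sig_init.begin(), sig_init.end());
  std::vector<std::vector<double>> th(S, std::vector<double>(np));
  for (int s = 0; s < S; ++s)
    for (int p = 0; p < np; ++p) th[s][p] = theta_init(s, p);
  double sz = sz_init;

  auto nat_ll = [&](int s, const std::vector<double> &t, double szv) {
    double a = std::exp(t[0]);
    double t0 = t[1];
    double z = free_z ? 1.0 / (1.0 + std::exp(-t[idx_lz])) : 0.5;
    int ib0 = free_z ? 3 : 2;
    double b0 = t[ib0];
    double b1 = has_bias ? t[ib0 + 1] : 0.0;
    return subject_ll(dat[s].lrt.data(), dat[s].upper.data(),
                      dat[s].desir.data(), (int)dat[s].lrt.size(), a, t0, z,
                      szv, b0, b1, has_bias, eps);
  };

  std::vector<double> ll(S);
  for (int s = 0; s < S; ++s) {
    ll[s] = nat_ll(s, th[s], sz);
    if (!R_finite(ll[s]))
      stop("non-finite log-likelihood at initial values (subject %d)", s + 1);
  }

  std::vector<double> step(np, 0.15), step_sig(np, 0.3);
  double step_sz = 0.05;
  std::vector<double> acc(np, 0.0), att(np, 0.0), acc_sig(np, 0.0),
      att_sig(np, 0.0);
  double acc_sz = 0.0, att_sz = 0.0;

  int n_keep = (n_samples - n_burn + thin - 1) / thin;
  int ncol = 2 * np + 1 + S * np + 1; // mu, sig, sz, theta, deviance
  NumericMatrix out(n_keep, ncol);
  int row = 0;

  for (int iter = 0; iter < n_samples; ++iter) {
    // subject-level parameters
    for (int s = 0; s < S; ++s) {
      for (int p = 0; p < np; ++p) {
        att[p] += 1.0;
        double cur = th[s][p];
        double prop = cur + step[p] * norm_rand();
        if (prop < lo[p] || prop > hi[p]) continue;
        std::vector<double> tp = th[s];
        tp[p] = prop;
        double llp = nat_ll(s, tp, sz);
        if (!R_finite(llp)) continue;
        double dprior = R::dnorm(prop, mu[p], sig[p], 1) -
                        R::dnorm(cur, mu[p], sig[p], 1);
        if (std::log(unif_rand()) < llp - ll[s] + dprior) {
          th[s][p] = prop;
          ll[s] = llp;
          acc[p] += 1.0;
        }
      }
    }
    // group means: conjugate given flat prior (rejection for range)
    for (int p = 0; p < np; ++p) {
      double m = 0.0;
      for (int s = 0; s < S; ++s) m += th[s][p];
      m /= S;
      double sd = sig[p] / std::sqrt((double)S);
      for (int tries = 0; tries < 100; ++tries) {
        double prop = m + sd * norm_rand();
        if (prop >= lo[p] && prop <= hi[p]) { mu[p] = prop; break; }
      }
    }
    // group spreads: random walk on log scale, half-normal prior
    for (int p = 0; p < np; ++p) {
      att_sig[p] += 1.0;
      double cur = sig[p];
      double prop = cur * std::exp(step_sig[p] * norm_rand());
      double lp_cur = 0.0, lp_prop = 0.0;
      for (int s = 0; s < S; ++s) {
        lp_cur += R::dnorm(th[s][p], mu[p], cur, 1);
        lp_prop += R::dnorm(th[s][p], mu[p], prop, 1);
      }
      lp_cur += -0.5 * cur * cur / (sig_tau * sig_tau) + std::log(cur);
      lp_prop += -0.5 * prop * prop / (sig_tau * sig_tau) + std::log(prop);
      if (std::log(unif_rand()) < lp_prop - lp_cur) {
        sig[p] = prop;
        acc_sig[p] += 1.0;
      }
    }
    // group-level sz: full-data Metropolis step; an occasional draw from
    // the flat prior helps traverse this weakly identified parameter
    {
      bool indep = unif_rand() < 0.25;
      if (!indep) att_sz += 1.0;
      double prop = indep ? sz_max * unif_rand()
                          : sz + step_sz * norm_rand();
      if (prop >= 0.0 && prop <= sz_max) {
        std::vector<double> llp(S);
        double d = 0.0;
        bool ok = true;
        for (int s = 0; s < S; ++s) {
          llp[s] = nat_ll(s, th[s], prop);
          if (!R_finite(llp[s])) { ok = false; break; }
          d += llp[s] - ll[s];
        }
        if (ok && std::log(unif_rand()) < d) {
          sz = prop;
          ll = llp;
          if (!indep) acc_sz += 1.0;
        }
      }
    }
    // step-size adaptation during burn-in
    if (iter < n_burn && (iter + 1) % 50 == 0) {
      for (int p = 0; p < np; ++p) {
        if (att[p] > 0) step[p] *= std::exp(acc[p] / att[p] - 0.35);
        if (att_sig[p] > 0)
          step_sig[p] *= std::exp(acc_sig[p] / att_sig[p] - 0.35);
        acc[p] = att[p] = acc_sig[p] = att_sig[p] = 0.0;
      }
      if (att_sz > 0) step_sz *= std::exp(acc_sz / att_sz - 0.35);
      acc_sz = att_sz = 0.0;
    }
    // record
    if (iter >= n_burn && (iter - n_burn) % thin == 0) {
      int c = 0;
      for (int p = 0; p < np; ++p) out(row, c++) = mu[p];
      for (int p = 0; p < np; ++p) out(row, c++) = sig[p];
      out(row, c++) = sz;
      for (int s = 0; s < S; ++s)
        for (int p = 0; p < np; ++p) out(row, c++) = th[s][p];
      double dev = 0.0;
      for (int s = 0; s < S; ++s) dev += ll[s];
      out(row, c++) = -2.0 * dev;
      ++row;
    }
    if ((iter + 1) % 200 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
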