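// Computational kernels for the t-likelihood models: unconstrained log
// posterior, adaptive random-walk Metropolis sampler, and the tensor-grid
// quadrature oracle. All randomness comes from R's RNG so set.seed() in R
// controls every draw.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---- likelihood -----------------------------------------------------------

// joint log likelihood of both groups given common parameters; per-theta
// normalization constants are hoisted out of the observation loops
static double loglik_groups(const NumericVector& y1, const NumericVector& y2,
                            double mu, double sigma, double delta, double rho,
                            double nu, bool t_lik) {
  const int n1 = y1.size(), n2 = y2.size();
  const double md = delta * sigma;
  const double mu1 = mu - md / 2.0, mu2 = mu + md / 2.0;
  const double s1 = sigma * std::sqrt(2.0 * (1.0 - rho));
  const double s2 = sigma * std::sqrt(2.0 * rho);
  double ll;
  if (t_lik) {
    // scale shrunk so the t distribution's SD equals sigma_g
    const double shrink2 = (nu - 2.0) / nu;
    const double t1sq = s1 * s1 * shrink2, t2sq = s2 * s2 * shrink2;
    const double lnorm = R::lgammafn((nu + 1.0) / 2.0) - R::lgammafn(nu / 2.0)
                       - 0.5 * std::log(nu * M_PI);
    const double c = (nu + 1.0) / 2.0;
    double s = 0.0;
    for (int i = 0; i < n1; ++i) {
      const double d = y1[i] - mu1;
      s += std::log1p(d * d / (nu * t1sq));
    }
    for (int i = 0; i < n2; ++i) {
      const double d = y2[i] - mu2;
      s += std::log1p(d * d / (nu * t2sq));
    }
    ll = (n1 + n2) * lnorm - 0.5 * n1 * std::log(t1sq)
       - 0.5 * n2 * std::log(t2sq) - c * s;
  } else {
    double q1 = 0.0, q2 = 0.0;
    for (int i = 0; i < n1; ++i) {
      const double d = y1[i] - mu1;
      q1 += d * d;
    }
    for (int i = 0; i < n2; ++i) {
      const double d = y2[i] - mu2;
      q2 += d * d;
    }
    ll = -0.5 * (n1 + n2) * std::log(2.0 * M_PI)
       - n1 * std::log(s1) - n2 * std::log(s2)
       - 0.5 * q1 / (s1 * s1) - 0.5 * q2 / (s2 * s2);
  }
  return ll;
}

// ---- unconstrained log posterior ------------------------------------------

struct ModelFlags {
  bool effect, unequal, t_lik;
  double fix_nu;  // > 2 fixes nu (not sampled); <= 0 means nu is free
};

struct PriorPars {
  double d_loc, d_scale, d_lo, d_hi, r_a, r_b, nu_shift, nu_scale;
};

// z layout: mu, log sigma, [delta], [logit rho], [log(nu - shift)]
static double log_post_z(const double* z, const NumericVector& y1,
                         const NumericVector& y2, const ModelFlags& fl,
                         const PriorPars& pp) {
  int j = 0;
  const double mu = z[j++];
  const double sigma = std::exp(z[j++]);
  double delta = 0.0, rho = 0.5, nu = R_PosInf;
  double lp = 0.0;  // Jeffreys 1/sigma prior cancels with the log-sigma Jacobian
  if (fl.effect) {
    delta = z[j++];
    if (delta < pp.d_lo || delta > pp.d_hi) return R_NegInf;
    lp += R::dcauchy(delta, pp.d_loc, pp.d_scale, 1);
  }
  if (fl.unequal) {
    const double lr = z[j++];
    rho = 1.0 / (1.0 + std::exp(-lr));
    lp += R::dbeta(rho, pp.r_a, pp.r_b, 1) + std::log(rho * (1.0 - rho));
  }
  if (fl.t_lik) {
    if (fl.fix_nu > 2.0) {
      nu = fl.fix_nu;
    } else {
      const double lnu = z[j++];
      nu = pp.nu_shift + std::exp(lnu);
      lp += R::dexp(nu - pp.nu_shift, pp.nu_scale, 1) + lnu;
    }
  }
  if (!R_finite(lp)) return R_NegInf;
  return lp + loglik_groups(y1, y2, mu, sigma, delta, rho, nu, fl.t_lik);
}

static ModelFlags make_flags(List flags) {
  ModelFlags fl;
  fl.effect = as<bool>(flags["effect"]);
  fl.unequal = as<bool>(flags["unequal"]);
  fl.t_lik = as<bool>(flags["t_lik"]);
  fl.fix_nu = as<double>(flags["fix_nu"]);
  return fl;
}

static PriorPars make_priors(List pr) {
  PriorPars pp;
  pp.d_loc = as<double>(pr["delta_location"]);
  pp.d_scale = as<double>(pr["delta_scale"]);
  pp.d_lo = as<double>(pr["delta_lo"]);
  pp.d_hi = as<double>(pr["delta_hi"]);
  pp.r_a = as<double>(pr["rho_a"]);
  pp.r_b = as<double>(pr["rho_b"]);
  pp.nu_shift = as<double>(pr["nu_shift"]);
  pp.nu_scale = as<double>(pr["nu_scale"]);
  return pp;
}

// [[Rcpp::export]]
NumericVector cpp_log_post(NumericMatrix z, NumericVector y1, NumericVector y2,
                           List flags, List prior_pars) {
  const ModelFlags fl = make_flags(flags);
  const PriorPars pp = make_priors(prior_pars);
  const int n = z.nrow(), d = z.ncol();
  NumericVector out(n);
  std::vector<double> row(d);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < d; ++k) row[k] = z(i, k);
    out[i] = log_post_z(row.data(), y1, y2, fl, pp);
  }
  return out;
}

// ---- adaptive random-walk Metropolis --------------------------------------

// lower-triangular Cholesky of a small covariance matrix (jittered if needed)
static void chol_small(const std::vector<double>& S, int d,
                       std::vector<double>& L) {
  std::vector<double> A(S);
  for (int i = 0; i < d; ++i) A[i * d + i] += 1e-10;
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * d + j];
      for (int k = 0; k < j; ++k) s -= L[i * d + k] * L[j * d + k];
      if (i == j) {
        L[i * d + i] = std::sqrt(std::max(s, 1e-12));
      } else {
        L[i * d + j] = s / L[j * d + j];
      }
    }
    for (int j = i + 1; j < d; ++j) L[i * d + j] = 0.0;
  }
}

// one chain; returns kept draws (rows) in unconstrained space plus the
// post-warmup acceptance rate
// [[Rcpp::export]]
List cpp_mh_chain(NumericVector y1, NumericVector y2, List flags,
                  List prior_pars, NumericVector init, int n_warmup,
                  int n_keep, int thin) {
  const ModelFlags fl = make_flags(flags);
  const PriorPars pp = make_priors(prior_pars);
  const int d = init.size();
  RNGScope scope;

  std::vector<double> z(init.begin(), init.end());
  double lp = log_post_z(z.data(), y1, y2, fl, pp);
  if (!R_finite(lp)) stop("initial value has zero posterior density");

  // running moments for the adaptive covariance
  std::vector<double> mean(z), cov(d * d, 0.0), L(d * d, 0.0);
  for (int i = 0; i < d; ++i) cov[i * d + i] = 0.01;
  chol_small(cov, d, L);
  double log_lambda = 0.0;
  const double target = 0.30;

  std::vector<double> prop(d), eps(d);
  NumericMatrix draws(n_keep, d);
  int kept = 0, acc_count = 0, post_iters = 0;
  const int n_total = n_warmup + n_keep * thin;

  for (int iter = 1; iter <= n_total; ++iter) {
    const double lambda = std::exp(log_lambda) * 2.38 / std::sqrt((double)d);
    for (int k = 0; k < d; ++k) eps[k] = norm_rand();
    for (int i = 0; i < d; ++i) {
      double s = 0.0;
      for (int k = 0; k <= i; ++k) s += L[i * d + k] * eps[k];
      prop[i] = z[i] + lambda * s;
    }
    const double lp_prop = log_post_z(prop.data(), y1, y2, fl, pp);
    const double alpha = R_finite(lp_prop)
        ? std::min(1.0, std::exp(lp_prop - lp)) : 0.0;
    bool accepted = false;
    if (alpha > 0.0 && unif_rand() < alpha) {
      z = prop;
      lp = lp_prop;
      accepted = true;
    }
    if (iter <= n_warmup) {
      // Robbins-Monro scale adaptation + running covariance update
      const double gamma = 1.0 / std::pow((double)iter, 0.6);
      log_lambda += gamma * (alpha - target);
      const double w = 1.0 / (iter + 1.0);
      std::vector<double> dz(d);
      for (int i = 0; i < d; ++i) dz[i] = z[i] - mean[i];
      for (int i = 0; i < d; ++i) mean[i] += w * dz[i];
      for (int i = 0; i < d; ++i)
        for (int j = 0; j < d; ++j)
          cov[i * d + j] = (1.0 - w) * (cov[i * d + j] + w * dz[i] * dz[j]);
      if (iter >= 50 && iter % 25 == 0) chol_small(cov, d, L);
    } else {
      ++post_iters;
      if (accepted) ++acc_count;
      if ((iter - n_warmup) % thin == 0 && kept < n_keep) {
        for (int i = 0; i < d; ++i) draws(kept, i) = z[i];
        ++kept;
      }
    }
  }
  return List::create(_["draws"] = draws,
                      _["accept_rate"] = post_iters > 0
                          ? (double)acc_count / post_iters : NA_REAL,
                      _["kept"] = kept);
}

// ---- tensor-grid oracle ---------------------------------------------------

// streaming log-sum-exp over the full tensor grid; each dimension carries
// per-node log weights (quadrature weight plus any importance correction
// for the improper nuisance prior)
// [[Rcpp::export]]
double cpp_oracle_lse(NumericVector y1, NumericVector y2,
                      NumericVector mu_nodes, NumericVector mu_lw,
                      NumericVector sig_nodes, NumericVector sig_lw,
                      NumericVector delta_nodes, NumericVector delta_lw,
                      NumericVector rho_nodes, NumericVector rho_lw,
                      NumericVector nu_nodes, NumericVector nu_lw,
                      bool t_lik) {
  const int Gm = mu_nodes.size(), Gs = sig_nodes.size();
  const int Gd = delta_nodes.size(), Gr = rho_nodes.size(), Gn = nu_nodes.size();
  double M = R_NegInf, S = 0.0;
  for (int in = 0; in < Gn; ++in) {
    const double nu = nu_nodes[in];
    for (int ir = 0; ir < Gr; ++ir) {
      const double rho = rho_nodes[ir];
      const double lw3 = nu_lw[in] + rho_lw[ir];
      for (int id = 0; id < Gd; ++id) {
        const double delta = delta_nodes[id];
        const double lw2 = lw3 + delta_lw[id];
        for (int is = 0; is < Gs; ++is) {
          const double sigma = sig_nodes[is];
          const double lw1 = lw2 + sig_lw[is];
          for (int im = 0; im < Gm; ++im) {
            const double f = loglik_groups(y1, y2, mu_nodes[im], sigma, delta,
                                           rho, nu, t_lik)
                           + mu_lw[im] + lw1;
            if (!R_finite(f)) continue;  // overflowed far-tail nodes add zero mass
            if (f > M) {
              S = S * std::exp(M - f) + 1.0;
              M = f;
            } else {
              S += std::exp(f - M);
            }
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return M + std::log(S);
}
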