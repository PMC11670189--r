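// Joint log-posterior and analytic gradient for the hierarchical outcome
// models, on the unconstrained scale used by the Hamiltonian sampler.
//
// Parameterization (per predictor stack), all non-centered:
//   alpha                          ~ Normal(0, alpha_sd)
//   beta[k,] = a_k * L(l_k) z_k    z ~ Normal(0,1), squared-exp corr over age
//   gamma    = a_g * L(l_g) z_g    GP over birth-order categories
//   eps      = a_e * L(l_e) z_e    GP over calendar years
//   kappa    = s_k * z_k           iid mother random effects
//   eta      = s_f * z_f           iid father random effects
//   amplitudes / sigmas / lambda sampled on log scale, half-Normal priors
//   lengthscales sampled on log scale, log-Normal priors
//
// Unknown-sex children enter through a child-level two-component mixture
// over male in {0,1} with weight pm (male fraction among sexed children).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double GP_JITTER = 1e-6;

// squared-exponential correlation over integer level index, plus jitter;
// Toeplitz: only n distinct values, so n (not n^2) exp evaluations
static arma::mat gp_corr(int n, double l) {
  arma::vec v(n);
  for (int d = 0; d < n; ++d)
    v(d) = std::exp(-0.5 * d * d / (l * l));
  arma::mat C(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j) {
      C(i, j) = v(i - j);
      C(j, i) = v(i - j);
    }
  C.diag() += GP_JITTER;
  return C;
}

// dC/d(log l), excluding the constant jitter
static arma::mat gp_corr_dlogl(int n, double l) {
  arma::vec v(n);
  for (int d = 0; d < n; ++d) {
    double d2l2 = double(d) * d / (l * l);
    v(d) = std::exp(-0.5 * d2l2) * d2l2;
  }
  arma::mat D(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j) {
      D(i, j) = v(i - j);
      D(j, i) = v(i - j);
    }
  return D;
}

// directional derivative of the lower Cholesky factor applied to a vector:
// dL * z with dL = L * Phi(L^-1 dC L^-T), Phi = lower triangle, half diagonal
static arma::vec chol_deriv_apply(const arma::mat& L, const arma::mat& dC,
                                  const arma::vec& z) {
  arma::mat T1 = arma::solve(arma::trimatl(L), dC);
  arma::mat T = arma::solve(arma::trimatl(L), T1.t()).t();
  arma::mat phi = arma::trimatl(T);
  phi.diag() *= 0.5;
  return L * (phi * z);
}

static double lse1p(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// numerical guard: regions the sampler may probe during warmup where the GP
// correlation matrix is not factorizable are reported as zero density
struct bad_region {};

static arma::mat safe_chol(const arma::mat& C) {
  arma::mat L;
  if (!arma::chol(L, C, "lower")) throw bad_region();
  return L;
}

static double bounded_exp(double u) {
  double v = std::exp(u);
  if (!std::isfinite(v) || v > 1e3 || v < 1e-3) throw bad_region();
  return v;
}

struct StackDims {
  int K, A, G, Y, M, F;
  int size() const { return 1 + K * A + 2 * K + G + 2 + Y + 2 + M + 1 + F + 1; }
};

struct Stack {
  double alpha;
  arma::mat beta;           // K x A (natural scale)
  arma::vec gam, eps, kap, eta;
  // saved pieces for the chain rule
  std::vector<arma::mat> Lb;
  arma::vec ab, lb;         // per-effect amplitude / lengthscale
  arma::mat Lg, Le;
  double ag, lg, ae, le, sk, sf;
  // raw innovations
  arma::mat zb;             // A x K
  arma::vec zg, ze, zk, zf;
};

static Stack unpack_stack(const arma::vec& par, int off, const StackDims& d) {
  Stack s;
  int p = off;
  s.alpha = par(p); p += 1;
  s.zb = arma::mat(&par(p), d.A, d.K);
  p += d.K * d.A;
  s.ab = arma::exp(par.subvec(p, p + d.K - 1)); p += d.K;
  s.lb.set_size(d.K);
  for (int k = 0; k < d.K; ++k) s.lb(k) = bounded_exp(par(p + k));
  p += d.K;
  s.beta.set_size(d.K, d.A);
  s.Lb.resize(d.K);
  for (int k = 0; k < d.K; ++k) {
    s.Lb[k] = safe_chol(gp_corr(d.A, s.lb(k)));
    s.beta.row(k) = (s.ab(k) * (s.Lb[k] * s.zb.col(k))).t();
  }
  s.zg = par.subvec(p, p + d.G - 1); p += d.G;
  s.ag = std::exp(par(p)); p += 1;
  s.lg = bounded_exp(par(p)); p += 1;
  s.Lg = safe_chol(gp_corr(d.G, s.lg));
  s.gam = s.ag * (s.Lg * s.zg);
  s.ze = par.subvec(p, p + d.Y - 1); p += d.Y;
  s.ae = std::exp(par(p)); p += 1;
  s.le = bounded_exp(par(p)); p += 1;
  s.Le = safe_chol(gp_corr(d.Y, s.le));
  s.eps = s.ae * (s.Le * s.ze);
  if (d.M > 0) { s.zk = par.subvec(p, p + d.M - 1); } else s.zk.set_size(0);
  p += d.M;
  s.sk = std::exp(par(p)); p += 1;
  s.kap = s.sk * s.zk;
  if (d.F > 0) { s.zf = par.subvec(p, p + d.F - 1); } else s.zf.set_size(0);
  p += d.F;
  s.sf = std::exp(par(p)); p += 1;
  s.eta = s.sf * s.zf;
  return s;
}

// natural-scale gradient accumulators for one stack
struct StackGrad {
  double g_alpha = 0.0;
  arma::mat g_beta;   // K x A
  arma::vec g_gam, g_eps, g_kap, g_eta;
  StackGrad(const StackDims& d) {
    g_beta.zeros(d.K, d.A);
    g_gam.zeros(d.G); g_eps.zeros(d.Y);
    g_kap.zeros(std::max(d.M, 1)); g_eta.zeros(std::max(d.F, 1));
  }
};

// chain natural-scale gradients back to the unconstrained vector, add the
// prior, and return the prior log-density of this stack
static double chain_stack(const arma::vec& par, int off, const StackDims& d,
                          const Stack& s, const StackGrad& g, arma::vec& grad,
                          double alpha_sd, double amp_sd, double sigma_sd,
                          double ls_meanlog, double ls_sdlog) {
  double lp = 0.0;
  int p = off;
  // alpha
  grad(p) += g.g_alpha - s.alpha / (alpha_sd * alpha_sd);
  lp += -0.5 * s.alpha * s.alpha / (alpha_sd * alpha_sd);
  p += 1;
  // z_beta
  for (int k = 0; k < d.K; ++k) {
    arma::vec gb = g.g_beta.row(k).t();
    arma::vec gz = s.ab(k) * (s.Lb[k].t() * gb);
    for (int a = 0; a < d.A; ++a) {
      grad(p + k * d.A + a) += gz(a) - s.zb(a, k);
      lp += -0.5 * s.zb(a, k) * s.zb(a, k);
    }
  }
  p += d.K * d.A;
  // log-amplitudes
  for (int k = 0; k < d.K; ++k) {
    double a = s.ab(k);
    grad(p + k) += arma::dot(s.beta.row(k), g.g_beta.row(k))
      - a * a / (amp_sd * amp_sd) + 1.0;
    lp += -0.5 * a * a / (amp_sd * amp_sd) + std::log(a);
  }
  p += d.K;
  // log-lengthscales
  for (int k = 0; k < d.K; ++k) {
    double u = par(p + k);
    arma::vec db = s.ab(k) *
      chol_deriv_apply(s.Lb[k], gp_corr_dlogl(d.A, s.lb(k)), s.zb.col(k));
    grad(p + k) += arma::dot(g.g_beta.row(k).t(), db)
      - (u - ls_meanlog) / (ls_sdlog * ls_sdlog);
    lp += -0.5 * std::pow((u - ls_meanlog) / ls_sdlog, 2);
  }
  p += d.K;
  // gamma GP
  {
    arma::vec gz = s.ag * (s.Lg.t() * g.g_gam);
    for (int i = 0; i < d.G; ++i) {
      grad(p + i) += gz(i) - s.zg(i);
      lp += -0.5 * s.zg(i) * s.zg(i);
    }
    p += d.G;
    grad(p) += arma::dot(s.gam, g.g_gam) - s.ag * s.ag / (amp_sd * amp_sd) + 1.0;
    lp += -0.5 * s.ag * s.ag / (amp_sd * amp_sd) + std::log(s.ag);
    p += 1;
    double u = par(p);
    grad(p) += s.ag * arma::dot(g.g_gam,
      chol_deriv_apply(s.Lg, gp_corr_dlogl(d.G, s.lg), s.zg))
      - (u - ls_meanlog) / (ls_sdlog * ls_sdlog);
    lp += -0.5 * std::pow((u - ls_meanlog) / ls_sdlog, 2);
    p += 1;
  }
  // eps GP
  {
    arma::vec gz = s.ae * (s.Le.t() * g.g_eps);
    for (int i = 0; i < d.Y; ++i) {
      grad(p + i) += gz(i) - s.ze(i);
      lp += -0.5 * s.ze(i) * s.ze(i);
    }
    p += d.Y;
    grad(p) += arma::dot(s.eps, g.g_eps) - s.ae * s.ae / (amp_sd * amp_sd) + 1.0;
    lp += -0.5 * s.ae * s.ae / (amp_sd * amp_sd) + std::log(s.ae);
    p += 1;
    double u = par(p);
    grad(p) += s.ae * arma::dot(g.g_eps,
      chol_deriv_apply(s.Le, gp_corr_dlogl(d.Y, s.le), s.ze))
      - (u - ls_meanlog) / (ls_sdlog * ls_sdlog);
    lp += -0.5 * std::pow((u - ls_meanlog) / ls_sdlog, 2);
    p += 1;
  }
  // kappa
  for (int i = 0; i < d.M; ++i) {
    grad(p + i) += s.sk * g.g_kap(i) - s.zk(i);
    lp += -0.5 * s.zk(i) * s.zk(i);
  }
  p += d.M;
  {
    double dot = (d.M > 0) ? arma::dot(s.kap, g.g_kap.head(d.M)) : 0.0;
    grad(p) += dot - s.sk * s.sk / (sigma_sd * sigma_sd) + 1.0;
    lp += -0.5 * s.sk * s.sk / (sigma_sd * sigma_sd) + std::log(s.sk);
    p += 1;
  }
  // eta
  for (int i = 0; i < d.F; ++i) {
    grad(p + i) += s.sf * g.g_eta(i) - s.zf(i);
    lp += -0.5 * s.zf(i) * s.zf(i);
  }
  p += d.F;
  {
    double dot = (d.F > 0) ? arma::dot(s.eta, g.g_eta.head(d.F)) : 0.0;
    grad(p) += dot - s.sf * s.sf / (sigma_sd * sigma_sd) + 1.0;
    lp += -0.5 * s.sf * s.sf / (sigma_sd * sigma_sd) + std::log(s.sf);
    p += 1;
  }
  return lp;
}

// parsed model data, cacheable behind an external pointer
struct CppModel {
  int type;
  arma::mat X;
  arma::vec y;
  arma::ivec age, bo, yr, mid, fid, unknown, uchild;
  int nu, male_col;
  double pm;
  double alpha_sd, amp_sd, sigma_sd, lambda_sd, ls_meanlog, ls_sdlog;
  StackDims d;
  int n, nstack, npar;
  // sparse view of X (most covariates are 0/1 indicators)
  std::vector<int> xr_ptr, xr_col;
  std::vector<double> xr_val;
};

// linear predictor for all rows under one stack; male column already zeroed
// for unknown-sex rows, whose M=1 branch adds beta[male_k, age]
static arma::vec stack_theta(const Stack& s, const CppModel& mod) {
  int n = mod.n;
  arma::vec th(n);
  for (int i = 0; i < n; ++i) {
    double t = s.alpha + s.gam(mod.bo(i) - 1) + s.eps(mod.yr(i) - 1);
    if (mod.mid(i) > 0) t += s.kap(mod.mid(i) - 1);
    if (mod.fid(i) > 0) t += s.eta(mod.fid(i) - 1);
    int a = mod.age(i) - 1;
    for (int p = mod.xr_ptr[i]; p < mod.xr_ptr[i + 1]; ++p)
      t += mod.xr_val[p] * s.beta(mod.xr_col[p], a);
    th(i) = t;
  }
  return th;
}

// scatter one row's effective residual into the natural-scale accumulators
static inline void accum_row(StackGrad& g, const CppModel& mod, int i,
                             double r) {
  int a = mod.age(i) - 1;
  g.g_alpha += r;
  g.g_gam(mod.bo(i) - 1) += r;
  g.g_eps(mod.yr(i) - 1) += r;
  if (mod.mid(i) > 0) g.g_kap(mod.mid(i) - 1) += r;
  if (mod.fid(i) > 0) g.g_eta(mod.fid(i) - 1) += r;
  for (int p = mod.xr_ptr[i]; p < mod.xr_ptr[i + 1]; ++p)
    g.g_beta(mod.xr_col[p], a) += mod.xr_val[p] * r;
}



static CppModel parse_model(List data) {
  CppModel m;
  m.type = as<int>(data["type"]);
  m.X = as<arma::mat>(data["X"]);
  m.y = as<arma::vec>(data["y"]);
  m.age = as<arma::ivec>(data["age"]);
  m.bo = as<arma::ivec>(data["bo"]);
  m.yr = as<arma::ivec>(data["yr"]);
  m.mid = as<arma::ivec>(data["mid"]);
  m.fid = as<arma::ivec>(data["fid"]);
  m.unknown = as<arma::ivec>(data["unknown"]);
  m.uchild = as<arma::ivec>(data["uchild"]);
  m.nu = as<int>(data["nu"]);
  m.pm = as<double>(data["pm"]);
  m.male_col = as<int>(data["male_col"]);
  List prior = data["prior"];
  m.alpha_sd = as<double>(prior["alpha_sd"]);
  m.amp_sd = as<double>(prior["amp_sd"]);
  m.sigma_sd = as<double>(prior["sigma_sd"]);
  m.lambda_sd = as<double>(prior["lambda_sd"]);
  m.ls_meanlog = as<double>(prior["ls_meanlog"]);
  m.ls_sdlog = as<double>(prior["ls_sdlog"]);
  m.d.K = m.X.n_cols; m.d.A = as<int>(data["A"]); m.d.G = as<int>(data["G"]);
  m.d.Y = as<int>(data["Yn"]); m.d.M = as<int>(data["M"]);
  m.d.F = as<int>(data["Fn"]);
  m.n = m.X.n_rows;
  m.nstack = (m.type == 3) ? 2 : 1;
  m.npar = m.nstack * m.d.size() + ((m.type == 2) ? 1 : 0);
  m.xr_ptr.resize(m.n + 1);
  m.xr_ptr[0] = 0;
  for (int i = 0; i < m.n; ++i) {
    for (int k = 0; k < (int)m.X.n_cols; ++k) {
      double x = m.X(i, k);
      if (x != 0.0) { m.xr_col.push_back(k); m.xr_val.push_back(x); }
    }
    m.xr_ptr[i + 1] = (int)m.xr_col.size();
  }
  return m;
}

static List compute_lp_grad(const arma::vec& par, const CppModel& mod) {

  const int type = mod.type;
  const arma::mat& X = mod.X;
  const arma::vec& y = mod.y;
  const arma::ivec& age = mod.age;
  const arma::ivec& bo = mod.bo;
  const arma::ivec& yr = mod.yr;
  const arma::ivec& mid = mod.mid;
  const arma::ivec& fid = mod.fid;
  const arma::ivec& unknown = mod.unknown;
  const arma::ivec& uchild = mod.uchild;
  const int nu = mod.nu, male_col = mod.male_col;
  const double pm = mod.pm;
  const double alpha_sd = mod.alpha_sd, amp_sd = mod.amp_sd,
    sigma_sd = mod.sigma_sd, lambda_sd = mod.lambda_sd,
    ls_meanlog = mod.ls_meanlog, ls_sdlog = mod.ls_sdlog;
  const StackDims& d = mod.d;
  const int n = mod.n, npar = mod.npar;
  if ((int)par.n_elem != npar)
    stop("parameter vector has length %d, expected %d", par.n_elem, npar);

  try {
  Stack s1 = unpack_stack(par, 0, d);
  Stack s2; // zip rate stack
  if (type == 3) s2 = unpack_stack(par, d.size(), d);
  double lambda = (type == 2) ? std::exp(par(npar - 1)) : 1.0;

  arma::vec th1 = stack_theta(s1, mod);
  arma::vec th2;
  if (type == 3) th2 = stack_theta(s2, mod);

  StackGrad g1(d), g2(d);
  double ll = 0.0, g_loglambda = 0.0;
  const double LOG2PI = std::log(2.0 * M_PI);
  int mk = male_col - 1; // 0-based male row in beta, or -1

  // per-branch row values for unknown-sex children
  arma::vec l0(n, arma::fill::zeros), l1(n, arma::fill::zeros);
  arma::vec r0a(n, arma::fill::zeros), r1a(n, arma::fill::zeros);
  arma::vec r0b(n, arma::fill::zeros), r1b(n, arma::fill::zeros);
  arma::vec dl0(n, arma::fill::zeros), dl1(n, arma::fill::zeros); // dloglambda
  arma::vec Lg0(std::max(nu, 1), arma::fill::zeros),
            Lg1(std::max(nu, 1), arma::fill::zeros);

  // row log-lik and residuals for given theta (and eta-pred for zip)
  auto row_eval = [&](int i, double t1, double t2, double& out_ll,
                      double& r_a, double& r_b, double& dlam) {
    if (type == 1) {            // Bernoulli(logistic(theta))
      double p = 1.0 / (1.0 + std::exp(-t1));
      out_ll = (y(i) == 1.0) ? -lse1p(-t1) : -lse1p(t1);
      r_a = y(i) - p;
      r_b = 0.0; dlam = 0.0;
    } else if (type == 2) {     // Normal(theta, lambda) on log outcome
      double z = (y(i) - t1) / lambda;
      out_ll = -std::log(lambda) - 0.5 * z * z - 0.5 * LOG2PI;
      r_a = z / lambda;
      r_b = 0.0;
      dlam = -1.0 + z * z;
    } else {                    // ZIP(logistic(theta), exp(eta))
      double p = 1.0 / (1.0 + std::exp(-t1));
      double mu = std::exp(t2);
      dlam = 0.0;
      if (y(i) == 0.0) {
        double lp0 = -lse1p(-t1);            // log p
        double lq0 = -lse1p(t1);             // log(1-p)
        double la = lp0, lb2 = lq0 - mu;
        double m = std::max(la, lb2);
        double den_log = m + std::log(std::exp(la - m) + std::exp(lb2 - m));
        out_ll = den_log;
        double den = std::exp(den_log);
        double em = std::exp(-mu);
        r_a = p * (1.0 - p) * (1.0 - em) / den;
        r_b = -(1.0 - p) * em * mu / den;
      } else {
        out_ll = -lse1p(t1) + y(i) * t2 - mu - std::lgamma(y(i) + 1.0);
        r_a = -p;
        r_b = y(i) - mu;
      }
    }
  };

  for (int i = 0; i < n; ++i) {
    double t1 = th1(i), t2 = (type == 3) ? th2(i) : 0.0;
    if (unknown(i) == 0) {
      double lli, ra, rb, dlam;
      row_eval(i, t1, t2, lli, ra, rb, dlam);
      ll += lli;
      accum_row(g1, mod, i, ra);
      if (type == 3) accum_row(g2, mod, i, rb);
      g_loglambda += dlam;
    } else {
      int a = age(i) - 1;
      double t1m = t1 + ((mk >= 0) ? s1.beta(mk, a) : 0.0);
      double t2m = (type == 3) ? t2 + ((mk >= 0) ? s2.beta(mk, a) : 0.0) : 0.0;
      row_eval(i, t1, t2, l0(i), r0a(i), r0b(i), dl0(i));
      row_eval(i, t1m, t2m, l1(i), r1a(i), r1b(i), dl1(i));
      int c = uchild(i) - 1;
      Lg0(c) += l0(i);
      Lg1(c) += l1(i);
    }
  }

  arma::vec w(std::max(nu, 1), arma::fill::zeros);
  if (nu > 0) {
    double lpm = std::log(pm), lqm = std::log1p(-pm);
    for (int c = 0; c < nu; ++c) {
      double la = lpm + Lg1(c), lb2 = lqm + Lg0(c);
      double m = std::max(la, lb2);
      double lse = m + std::log(std::exp(la - m) + std::exp(lb2 - m));
      ll += lse;
      w(c) = std::exp(la - lse);
    }
    for (int i = 0; i < n; ++i) {
      if (unknown(i) == 0) continue;
      double wc = w(uchild(i) - 1);
      double ra = wc * r1a(i) + (1.0 - wc) * r0a(i);
      accum_row(g1, mod, i, ra);
      if (mk >= 0) g1.g_beta(mk, age(i) - 1) += wc * r1a(i);
      if (type == 3) {
        double rb = wc * r1b(i) + (1.0 - wc) * r0b(i);
        accum_row(g2, mod, i, rb);
        if (mk >= 0) g2.g_beta(mk, age(i) - 1) += wc * r1b(i);
      }
      g_loglambda += wc * dl1(i) + (1.0 - wc) * dl0(i);
    }
  }

  arma::vec grad(npar, arma::fill::zeros);
  double lp = ll;
  lp += chain_stack(par, 0, d, s1, g1, grad, alpha_sd, amp_sd, sigma_sd,
                    ls_meanlog, ls_sdlog);
  if (type == 3)
    lp += chain_stack(par, d.size(), d, s2, g2, grad, alpha_sd, amp_sd,
                      sigma_sd, ls_meanlog, ls_sdlog);
  if (type == 2) {
    // half-Normal(lambda_sd) prior on lambda, sampled as log(lambda)
    lp += -0.5 * lambda * lambda / (lambda_sd * lambda_sd) + std::log(lambda);
    grad(npar - 1) += g_loglambda
      - lambda * lambda / (lambda_sd * lambda_sd) + 1.0;
  }

  return List::create(_["value"] = lp,
                      _["grad"] = NumericVector(grad.begin(), grad.end()));
  } catch (const bad_region&) {
    return List::create(_["value"] = R_NegInf,
                        _["grad"] = NumericVector(par.n_elem));
  }
}

// [[Rcpp::export]]
List fam_lp_grad_cpp(NumericVector par_, List data) {
  arma::vec par(par_.begin(), par_.size());
  return compute_lp_grad(par, parse_model(data));
}

// [[Rcpp::export]]
SEXP fam_model_ptr_cpp(List data) {
  XPtr<CppModel> p(new CppModel(parse_model(data)), true);
  return p;
}

// [[Rcpp::export]]
List fam_lp_grad_ptr_cpp(NumericVector par_, SEXP ptr) {
  XPtr<CppModel> p(ptr);
  if (!p)
    stop("model data pointer has expired (e.g. the model object was "
         "serialized); rebuild it with assemble_model()");
  arma::vec par(par_.begin(), par_.size());
  return compute_lp_grad(par, *p);
}

// natural-scale parameters implied by an unconstrained vector (one stack)
// [[Rcpp::export]]
List fam_unpack_stack_cpp(NumericVector par_, List data, int stack) {
  arma::vec par(par_.begin(), par_.size());
  StackDims d;
  arma::mat X = as<arma::mat>(data["X"]);
  d.K = X.n_cols; d.A = as<int>(data["A"]); d.G = as<int>(data["G"]);
  d.Y = as<int>(data["Yn"]); d.M = as<int>(data["M"]); d.F = as<int>(data["Fn"]);
  Stack s = unpack_stack(par, (stack - 1) * d.size(), d);
  return List::create(_["alpha"] = s.alpha, _["beta"] = s.beta,
                      _["gamma"] = s.gam, _["eps"] = s.eps,
                      _["kappa"] = s.kap, _["eta"] = s.eta,
                      _["amp_beta"] = s.ab, _["ls_beta"] = s.lb,
                      _["amp_gamma"] = s.ag, _["ls_gamma"] = s.lg,
                      _["amp_eps"] = s.ae, _["ls_eps"] = s.le,
                      _["sigma_kappa"] = s.sk, _["sigma_eta"] = s.sf);
}
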