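// Hamiltonian Monte Carlo core for the BYM2 space-time Poisson model.
// Works on the unconstrained scale (log sigma, logit rho) with analytic
// gradients; island areas' structured effects are frozen at zero by a
// coordinate mask. All randomness comes from R's RNG so seeding on the R
// side makes runs fully reproducible.
//
// Metric: warmup starts from the diagonal local curvature, then switches to
// a dense metric assembled from the model's Gauss-Newton Hessian (Poisson
// weights + ICAR precision + soft sum-to-zero + priors) at the end of the
// first warmup phase. The dense metric is what makes the near-Gaussian but
// strongly correlated eta/nu geometry cheap to traverse.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Model {
  NumericVector y, E, tvec, s_area, comp_soft_sd;
  NumericMatrix X;
  IntegerVector area, e1, e2, comp;
  LogicalVector island;
  double beta_sd, sigma_scale, rho_a, rho_b;
  int n_obs, n_area, p, n_comp, n_edge;
  // parameter layout offsets (0-based): beta0=0, beta=1..p, beta3=p+1,
  // log_sigma=p+2, logit_rho=p+3, eta=p+4.., nu=p+4+n..
  int i_b3, i_ls, i_lr, i_eta, i_nu, dim;
};

Model make_model(const List& data) {
  Model m;
  m.y = data["y"]; m.E = data["E"]; m.tvec = data["tvec"];
  m.X = as<NumericMatrix>(data["X"]);
  m.area = data["area"]; m.e1 = data["e1"]; m.e2 = data["e2"];
  m.comp = data["comp"]; m.s_area = data["s_area"];
  m.island = data["island"]; m.comp_soft_sd = data["comp_soft_sd"];
  m.beta_sd = data["beta_sd"]; m.sigma_scale = data["sigma_scale"];
  m.rho_a = data["rho_a"]; m.rho_b = data["rho_b"];
  m.n_obs = m.y.size(); m.n_area = as<int>(data["n_area"]);
  m.p = as<int>(data["p"]);
  m.n_comp = m.comp_soft_sd.size();
  m.n_edge = m.e1.size();
  m.i_b3 = m.p + 1; m.i_ls = m.p + 2; m.i_lr = m.p + 3;
  m.i_eta = m.p + 4; m.i_nu = m.p + 4 + m.n_area;
  m.dim = m.p + 4 + 2 * m.n_area;
  return m;
}

const double LOG2PI = std::log(2.0 * M_PI);

inline double dnorm_log(double x, double sd) {
  return -0.5 * LOG2PI - std::log(sd) - 0.5 * (x / sd) * (x / sd);
}

// Log posterior on the unconstrained scale (Jacobians included) and its
// gradient. Island eta coordinates get zero gradient.
double lp_grad(const Model& m, const std::vector<double>& z,
               std::vector<double>& g) {
  std::fill(g.begin(), g.end(), 0.0);
  const double b0 = z[0], b3 = z[m.i_b3], ls = z[m.i_ls], lr = z[m.i_lr];
  const double sigma = std::exp(ls);
  const double rho = 1.0 / (1.0 + std::exp(-lr));
  const double sr1 = std::sqrt(1.0 - rho);
  double lp = 0.0;

  std::vector<double> a(m.n_area), kappa(m.n_area), gkap(m.n_area, 0.0);
  for (int i = 0; i < m.n_area; ++i) {
    a[i] = m.island[i] ? 0.0 : std::sqrt(rho / m.s_area[i]);
    kappa[i] = a[i] * z[m.i_eta + i] + sr1 * z[m.i_nu + i];
  }

  // Poisson likelihood
  for (int k = 0; k < m.n_obs; ++k) {
    double mu = b0 + b3 * m.tvec[k] + sigma * kappa[m.area[k]];
    for (int j = 0; j < m.p; ++j) mu += m.X(k, j) * z[1 + j];
    const double lam = m.E[k] * std::exp(mu);
    lp += m.y[k] * (std::log(m.E[k]) + mu) - lam - std::lgamma(m.y[k] + 1.0);
    const double r = m.y[k] - lam;
    g[0] += r;
    g[m.i_b3] += r * m.tvec[k];
    for (int j = 0; j < m.p; ++j) g[1 + j] += r * m.X(k, j);
    gkap[m.area[k]] += r;
  }

  // random-effect gradients from the likelihood
  double dlp_dsigma = 0.0, dlr = 0.0;
  for (int i = 0; i < m.n_area; ++i) {
    const double gs = sigma * gkap[i];
    dlp_dsigma += gkap[i] * kappa[i];
    g[m.i_eta + i] += gs * a[i];
    g[m.i_nu + i] += gs * sr1;
    // d kappa / d logit_rho, written in a form stable at the boundaries:
    // rho(1-rho) * [eta/(2 sqrt(rho s)) - nu/(2 sqrt(1-rho))]
    double dk = -rho * sr1 * z[m.i_nu + i] / 2.0;
    if (!m.island[i])
      dk += (1.0 - rho) * std::sqrt(rho) * z[m.i_eta + i] /
            (2.0 * std::sqrt(m.s_area[i]));
    dlr += gs * dk;
  }

  // ICAR pairwise-difference prior on eta
  for (int k = 0; k < m.n_edge; ++k) {
    const double d = z[m.i_eta + m.e1[k]] - z[m.i_eta + m.e2[k]];
    lp -= 0.5 * d * d;
    g[m.i_eta + m.e1[k]] -= d;
    g[m.i_eta + m.e2[k]] += d;
  }
  // soft sum-to-zero per non-island component
  std::vector<double> csum(m.n_comp, 0.0);
  std::vector<int> csize(m.n_comp, 0);
  for (int i = 0; i < m.n_area; ++i)
    if (!m.island[i]) { csum[m.comp[i]] += z[m.i_eta + i]; csize[m.comp[i]]++; }
  for (int c = 0; c < m.n_comp; ++c) {
    if (csize[c] == 0) continue;
    const double sd = m.comp_soft_sd[c];
    lp += dnorm_log(csum[c], sd);
    const double gc = -csum[c] / (sd * sd);
    for (int i = 0; i < m.n_area; ++i)
      if (!m.island[i] && m.comp[i] == c) g[m.i_eta + i] += gc;
  }

  // standard-normal prior on nu
  for (int i = 0; i < m.n_area; ++i) {
    lp += dnorm_log(z[m.i_nu + i], 1.0);
    g[m.i_nu + i] -= z[m.i_nu + i];
  }

  // fixed-effect priors
  lp += dnorm_log(b0, m.beta_sd);
  g[0] -= b0 / (m.beta_sd * m.beta_sd);
  lp += dnorm_log(b3, m.beta_sd);
  g[m.i_b3] -= b3 / (m.beta_sd * m.beta_sd);
  for (int j = 0; j < m.p; ++j) {
    lp += dnorm_log(z[1 + j], m.beta_sd);
    g[1 + j] -= z[1 + j] / (m.beta_sd * m.beta_sd);
  }

  // sigma ~ half-normal, on log scale (Jacobian ls)
  lp += std::log(2.0) + dnorm_log(sigma, m.sigma_scale) + ls;
  dlp_dsigma += -sigma / (m.sigma_scale * m.sigma_scale);
  g[m.i_ls] = dlp_dsigma * sigma + 1.0;

  // rho ~ Beta(a, b), on logit scale (Jacobian log(rho(1-rho)))
  lp += R::dbeta(rho, m.rho_a, m.rho_b, 1) + std::log(rho) + std::log(1.0 - rho);
  dlr += (m.rho_a - 1.0) * (1.0 - rho) - (m.rho_b - 1.0) * rho;
  dlr += 1.0 - 2.0 * rho;
  g[m.i_lr] = dlr;

  // freeze island eta coordinates
  for (int i = 0; i < m.n_area; ++i)
    if (m.island[i]) g[m.i_eta + i] = 0.0;
  return lp;
}

// In-place Cholesky of a row-major symmetric PD matrix; returns false on
// failure. Only the lower triangle of the result is referenced afterwards.
bool cholesky(std::vector<double>& A, int n) {
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * n + j];
      for (int k = 0; k < j; ++k) s -= A[i * n + k] * A[j * n + k];
      if (i == j) {
        if (s <= 0.0) return false;
        A[i * n + i] = std::sqrt(s);
      } else {
        A[i * n + j] = s / A[j * n + j];
      }
    }
  }
  return true;
}

struct Hmc {
  const Model& m;
  std::vector<bool> fixed;       // coordinates that never move
  std::vector<double> mass;      // diagonal metric (phase 1)
  bool dense = false;
  std::vector<double> L;         // Cholesky factor of the dense metric
  std::vector<double> Minv;      // inverse of the dense metric

  explicit Hmc(const Model& mm) : m(mm), fixed(mm.dim, false),
                                  mass(mm.dim, 1.0) {
    for (int i = 0; i < m.n_area; ++i)
      if (m.island[i]) fixed[m.i_eta + i] = true;
  }

  // velocity v = M^{-1} p
  void velocity(const std::vector<double>& p, std::vector<double>& v) const {
    const int d = m.dim;
    if (!dense) {
      for (int i = 0; i < d; ++i) v[i] = fixed[i] ? 0.0 : p[i] / mass[i];
      return;
    }
    for (int i = 0; i < d; ++i) {
      double s = 0.0;
      const double* row = &Minv[(size_t)i * d];
      for (int j = 0; j < d; ++j) s += row[j] * p[j];
      v[i] = fixed[i] ? 0.0 : s;
    }
  }

  double kinetic(const std::vector<double>& p) const {
    std::vector<double> v(m.dim);
    velocity(p, v);
    double k = 0.0;
    for (int i = 0; i < m.dim; ++i) k += p[i] * v[i];
    return 0.5 * k;
  }

  void sample_momentum(std::vector<double>& p) const {
    const int d = m.dim;
    if (!dense) {
      for (int i = 0; i < d; ++i)
        p[i] = fixed[i] ? 0.0 : norm_rand() * std::sqrt(mass[i]);
      return;
    }
    std::vector<double> e(d);
    for (int i = 0; i < d; ++i) e[i] = fixed[i] ? 0.0 : norm_rand();
    for (int i = d - 1; i >= 0; --i) {
      double s = 0.0;
      const double* row = &L[(size_t)i * d];
      for (int j = 0; j <= i; ++j) s += row[j] * e[j];
      p[i] = fixed[i] ? 0.0 : s;
    }
  }

  // One leapfrog trajectory; returns lp at the end point.
  double leapfrog(std::vector<double>& z, std::vector<double>& p,
                  std::vector<double>& g, double eps, int Lsteps) const {
    std::vector<double> v(m.dim);
    double lp = 0.0;
    for (int step = 0; step < Lsteps; ++step) {
      for (int i = 0; i < m.dim; ++i)
        if (!fixed[i]) p[i] += 0.5 * eps * g[i];
      velocity(p, v);
      for (int i = 0; i < m.dim; ++i)
        if (!fixed[i]) z[i] += eps * v[i];
      lp = lp_grad(m, z, g);
      for (int i = 0; i < m.dim; ++i)
        if (!fixed[i]) p[i] += 0.5 * eps * g[i];
      if (!std::isfinite(lp)) return lp;
    }
    return lp;
  }

  double reasonable_eps(const std::vector<double>& z0, double lp0) const {
    double eps = 0.1;
    std::vector<double> z, p(m.dim), g0(m.dim), g;
    lp_grad(m, z0, g0);
    sample_momentum(p);
    const double h0 = -lp0 + kinetic(p);
    z = z0; g = g0;
    std::vector<double> pw = p;
    double lp1 = leapfrog(z, pw, g, eps, 1);
    double h1 = std::isfinite(lp1) ? -lp1 + kinetic(pw) : INFINITY;
    double accept = std::exp(h0 - h1);
    const bool up = accept > 0.5;
    for (int it = 0; it < 50; ++it) {
      eps *= up ? 2.0 : 0.5;
      z = z0; g = g0; pw = p;
      lp1 = leapfrog(z, pw, g, eps, 1);
      h1 = std::isfinite(lp1) ? -lp1 + kinetic(pw) : INFINITY;
      accept = std::exp(h0 - h1);
      if (up ? (accept <= 0.5) : (accept >= 0.5)) break;
    }
    return eps;
  }

  // Dense metric: Gauss-Newton Hessian of the posterior at z over ALL
  // coordinates — mu is smooth in every unconstrained coordinate including
  // log sigma and logit rho, so their likelihood-induced correlation with
  // the latent fields lands in the metric too — plus the ICAR precision,
  // the soft sum-to-zero blocks and the prior curvatures.
  void build_dense_metric(const std::vector<double>& z) {
    const int d = m.dim;
    const double sigma = std::exp(z[m.i_ls]);
    const double rho = 1.0 / (1.0 + std::exp(-z[m.i_lr]));
    const double sr1 = std::sqrt(1.0 - rho);
    std::vector<double> H((size_t)d * d, 0.0);

    std::vector<double> a(m.n_area);
    for (int i = 0; i < m.n_area; ++i)
      a[i] = m.island[i] ? 0.0 : std::sqrt(rho / m.s_area[i]);

    // likelihood term: sum_k lam_k u_k u_k^T with u = dmu/dz (sparse)
    std::vector<int> idx(m.p + 6);
    std::vector<double> u(m.p + 6);
    for (int k = 0; k < m.n_obs; ++k) {
      const int i = m.area[k];
      const double kap = a[i] * z[m.i_eta + i] + sr1 * z[m.i_nu + i];
      double mu = z[0] + z[m.i_b3] * m.tvec[k] + sigma * kap;
      for (int j = 0; j < m.p; ++j) mu += m.X(k, j) * z[1 + j];
      const double lam = m.E[k] * std::exp(mu);
      // d kappa / d logit_rho in boundary-stable form
      double dk = -rho * sr1 * z[m.i_nu + i] / 2.0;
      if (!m.island[i])
        dk += (1.0 - rho) * std::sqrt(rho) * z[m.i_eta + i] /
              (2.0 * std::sqrt(m.s_area[i]));
      int nz = 0;
      idx[nz] = 0; u[nz++] = 1.0;
      for (int j = 0; j < m.p; ++j) { idx[nz] = 1 + j; u[nz++] = m.X(k, j); }
      idx[nz] = m.i_b3; u[nz++] = m.tvec[k];
      idx[nz] = m.i_eta + i; u[nz++] = sigma * a[i];
      idx[nz] = m.i_nu + i; u[nz++] = sigma * sr1;
      idx[nz] = m.i_ls; u[nz++] = sigma * kap;
      idx[nz] = m.i_lr; u[nz++] = sigma * dk;
      for (int r = 0; r < nz; ++r)
        for (int c = 0; c < nz; ++c)
          H[(size_t)idx[r] * d + idx[c]] += lam * u[r] * u[c];
    }

    // ICAR precision on eta
    for (int k = 0; k < m.n_edge; ++k) {
      const int i = m.i_eta + m.e1[k], j = m.i_eta + m.e2[k];
      H[(size_t)i * d + i] += 1.0;
      H[(size_t)j * d + j] += 1.0;
      H[(size_t)i * d + j] -= 1.0;
      H[(size_t)j * d + i] -= 1.0;
    }
    // soft sum-to-zero blocks
    for (int c = 0; c < m.n_comp; ++c) {
      const double w = 1.0 / (m.comp_soft_sd[c] * m.comp_soft_sd[c]);
      for (int i = 0; i < m.n_area; ++i) {
        if (m.island[i] || m.comp[i] != c) continue;
        for (int j = 0; j < m.n_area; ++j) {
          if (m.island[j] || m.comp[j] != c) continue;
          H[(size_t)(m.i_eta + i) * d + (m.i_eta + j)] += w;
        }
      }
    }
    // priors
    const double wb = 1.0 / (m.beta_sd * m.beta_sd);
    H[0] += wb;
    H[(size_t)m.i_b3 * d + m.i_b3] += wb;
    for (int j = 0; j < m.p; ++j) H[(size_t)(1 + j) * d + (1 + j)] += wb;
    for (int i = 0; i < m.n_area; ++i)
      H[(size_t)(m.i_nu + i) * d + (m.i_nu + i)] += 1.0;

    // prior curvature of log sigma (half-normal through the exp transform)
    // and logit rho (Beta plus Jacobian), with a small positive floor so
    // both stay comfortably in the PD cone
    H[(size_t)m.i_ls * d + m.i_ls] +=
        2.0 * sigma * sigma / (m.sigma_scale * m.sigma_scale) + 0.1;
    H[(size_t)m.i_lr * d + m.i_lr] +=
        (m.rho_a + m.rho_b) * rho * (1.0 - rho) + 0.1;

    // frozen coordinates: identity rows/columns
    for (int i = 0; i < d; ++i) {
      if (!fixed[i]) continue;
      for (int j = 0; j < d; ++j) {
        H[(size_t)i * d + j] = 0.0;
        H[(size_t)j * d + i] = 0.0;
      }
      H[(size_t)i * d + i] = 1.0;
    }

    // factor and invert; fall back to the diagonal metric on failure
    std::vector<double> C = H;
    if (!cholesky(C, d)) {
      dense = false;
      for (int i = 0; i < d; ++i) {
        const double hd = H[(size_t)i * d + i];
        mass[i] = (std::isfinite(hd) && hd > 1e-2) ? hd : 1.0;
      }
      return;
    }
    // Minv = L^{-T} L^{-1} via triangular solves of unit vectors
    Minv.assign((size_t)d * d, 0.0);
    std::vector<double> col(d);
    for (int rhs = 0; rhs < d; ++rhs) {
      // forward solve L x = e_rhs
      for (int i = 0; i < d; ++i) {
        double s = (i == rhs) ? 1.0 : 0.0;
        for (int k = 0; k < i; ++k) s -= C[(size_t)i * d + k] * col[k];
        col[i] = s / C[(size_t)i * d + i];
      }
      // backward solve L^T y = x
      for (int i = d - 1; i >= 0; --i) {
        double s = col[i];
        for (int k = i + 1; k < d; ++k) s -= C[(size_t)k * d + i] * col[k];
        col[i] = s / C[(size_t)i * d + i];
      }
      for (int i = 0; i < d; ++i) Minv[(size_t)i * d + rhs] = col[i];
    }
    L = C;
    dense = true;
  }

  void diag_curvature_metric(const std::vector<double>& at) {
    std::vector<double> zp, gp(m.dim), gm(m.dim);
    const double h = 1e-4;
    for (int i = 0; i < m.dim; ++i) {
      if (fixed[i]) { mass[i] = 1.0; continue; }
      zp = at; zp[i] += h; lp_grad(m, zp, gp);
      zp[i] -= 2 * h; lp_grad(m, zp, gm);
      double curv = -(gp[i] - gm[i]) / (2 * h);
      mass[i] = (std::isfinite(curv) && curv > 1e-2) ? curv : 1.0;
    }
    dense = false;
  }
};

}  // namespace

// [[Rcpp::export]]
double hmc_lp(List data, NumericVector z) {
  Model m = make_model(data);
  std::vector<double> zz(z.begin(), z.end()), g(m.dim);
  return lp_grad(m, zz, g);
}

// [[Rcpp::export]]
NumericVector hmc_grad(List data, NumericVector z) {
  Model m = make_model(data);
  std::vector<double> zz(z.begin(), z.end()), g(m.dim);
  lp_grad(m, zz, g);
  return NumericVector(g.begin(), g.end());
}

// [[Rcpp::export]]
List hmc_run(List data, NumericVector init, int iter_warmup,
             int iter_sampling, double target_accept, double path_length,
             int max_leapfrog, bool use_dense = true) {
  RNGScope scope;
  Model m = make_model(data);
  Hmc hmc(m);
  std::vector<double> z(init.begin(), init.end());
  std::vector<double> g(m.dim), p(m.dim);
  double lp = lp_grad(m, z, g);
  if (!std::isfinite(lp)) stop("initial point has non-finite density");

  hmc.diag_curvature_metric(z);

  // dual-averaging state
  const double da_gamma = 0.05, da_t0 = 10.0, da_kappa = 0.75;
  double eps = hmc.reasonable_eps(z, lp);
  double mu = std::log(10.0 * eps), log_eps = std::log(eps),
         log_eps_bar = 0.0, hbar = 0.0;
  int da_iter = 0;

  const int phase1 = iter_warmup / 2;

  // Interweaved scale moves: the marginal posteriors of rho and sigma are
  // far wider than their conditionals given the latent fields (moving
  // either requires the whole field to rebalance), which throttles any
  // fixed-metric HMC. A Metropolis proposal on logit rho (resp. log sigma)
  // combined with the deterministic field rescaling that keeps the linear
  // predictor exactly invariant makes the likelihood cancel, so the move
  // walks the ridge at prior-plus-Jacobian cost only.
  int n_free_eta = 0;
  for (int i = 0; i < m.n_area; ++i) if (!m.island[i]) ++n_free_eta;
  double tau_r = 0.5, tau_s = 0.5;
  long mv_iter = 0, mv_acc_r = 0, mv_acc_s = 0;
  auto scale_moves = [&](bool adapt) {
    ++mv_iter;
    bool moved = false;
    // rho move: eta *= sqrt(rho/rho'), nu *= sqrt((1-rho)/(1-rho'))
    {
      const double lr = z[m.i_lr], lr2 = lr + tau_r * norm_rand();
      const double rho = 1.0 / (1.0 + std::exp(-lr));
      const double rho2 = 1.0 / (1.0 + std::exp(-lr2));
      const double ce = std::sqrt(rho / rho2);
      const double cn = std::sqrt((1.0 - rho) / (1.0 - rho2));
      std::vector<double> z2 = z;
      z2[m.i_lr] = lr2;
      for (int i = 0; i < m.n_area; ++i) {
        if (!m.island[i]) z2[m.i_eta + i] *= ce;
        z2[m.i_nu + i] *= cn;
      }
      std::vector<double> gtmp(m.dim);
      const double lp2 = lp_grad(m, z2, gtmp);
      const double delta = lp2 - lp + n_free_eta * std::log(ce) +
                           m.n_area * std::log(cn);
      const double alpha = std::isfinite(lp2)
                               ? std::min(1.0, std::exp(delta)) : 0.0;
      if (unif_rand() < alpha) {
        z = z2; g = gtmp; lp = lp2; moved = true; ++mv_acc_r;
      }
      if (adapt)
        tau_r = std::exp(std::log(tau_r) +
                         (alpha - 0.44) / std::sqrt((double)mv_iter));
    }
    // sigma move: eta and nu *= sigma/sigma'
    {
      const double ls = z[m.i_ls], ls2 = ls + tau_s * norm_rand();
      const double r = std::exp(ls - ls2);
      std::vector<double> z2 = z;
      z2[m.i_ls] = ls2;
      for (int i = 0; i < m.n_area; ++i) {
        if (!m.island[i]) z2[m.i_eta + i] *= r;
        z2[m.i_nu + i] *= r;
      }
      std::vector<double> gtmp(m.dim);
      const double lp2 = lp_grad(m, z2, gtmp);
      const double delta = lp2 - lp + (n_free_eta + m.n_area) * (ls - ls2);
      const double alpha = std::isfinite(lp2)
                               ? std::min(1.0, std::exp(delta)) : 0.0;
      if (unif_rand() < alpha) {
        z = z2; g = gtmp; lp = lp2; moved = true; ++mv_acc_s;
      }
      if (adapt)
        tau_s = std::exp(std::log(tau_s) +
                         (alpha - 0.44) / std::sqrt((double)mv_iter));
    }
    return moved;
  };

  auto one_iter = [&](double step, bool adapt, double plen, int* divergent) {
    std::vector<double> z1 = z, g1 = g;
    hmc.sample_momentum(p);
    const double h0 = -lp + hmc.kinetic(p);
    int L = (int)std::lround(plen / step);
    if (L < 1) L = 1;
    if (L > max_leapfrog) L = max_leapfrog;
    // jitter path length to avoid resonance
    if (L > 1) L = L / 2 + (int)std::floor(unif_rand() * (L - L / 2 + 1));
    double lp1 = hmc.leapfrog(z1, p, g1, step, L);
    double h1 = std::isfinite(lp1) ? -lp1 + hmc.kinetic(p) : INFINITY;
    double alpha = std::exp(std::min(0.0, h0 - h1));
    if (!std::isfinite(h1)) alpha = 0.0;
    if (divergent && (h1 - h0) > 1000.0) ++(*divergent);
    if (unif_rand() < alpha) { z = z1; g = g1; lp = lp1; }
    if (adapt) {
      ++da_iter;
      const double w = 1.0 / (da_iter + da_t0);
      hbar = (1.0 - w) * hbar + w * (target_accept - alpha);
      log_eps = mu - std::sqrt((double)da_iter) / da_gamma * hbar;
      const double wt = std::pow((double)da_iter, -da_kappa);
      log_eps_bar = wt * log_eps + (1.0 - wt) * log_eps_bar;
    }
    return alpha;
  };

  // warmup phase 1: diagonal curvature metric, moderate trajectories,
  // reach the typical set and adapt the step size
  const double plen1 = std::min(path_length, 8.0);
  for (int it = 0; it < phase1; ++it) {
    one_iter(std::exp(log_eps), true, plen1, nullptr);
    for (int sw = 0; sw < 50; ++sw) scale_moves(true);
  }

  // switch to the dense Gauss-Newton metric at the current state
  if (use_dense) hmc.build_dense_metric(z);
  else hmc.diag_curvature_metric(z);

  // warmup phase 2: re-adapt the step size under the new metric
  eps = hmc.reasonable_eps(z, lp);
  mu = std::log(10.0 * eps);
  log_eps = std::log(eps);
  log_eps_bar = 0.0; hbar = 0.0; da_iter = 0;
  for (int it = phase1; it < iter_warmup; ++it) {
    one_iter(std::exp(log_eps), true, path_length, nullptr);
    for (int sw = 0; sw < 50; ++sw) scale_moves(true);
  }

  const double eps_final = std::exp(log_eps_bar);
  int divergences = 0;
  double accept_sum = 0.0;
  NumericMatrix draws(iter_sampling, m.dim);
  for (int it = 0; it < iter_sampling; ++it) {
    accept_sum += one_iter(eps_final, false, path_length, &divergences);
    for (int sw = 0; sw < 50; ++sw) scale_moves(false);
    for (int i = 0; i < m.dim; ++i) draws(it, i) = z[i];
    if (it % 64 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["draws"] = draws,
    _["step_size"] = eps_final,
    _["accept_rate"] = accept_sum / iter_sampling,
    _["divergences"] = divergences,
    _["dense_metric"] = hmc.dense,
    _["scale_move"] = NumericVector::create(
        _["tau_rho"] = tau_r, _["tau_sigma"] = tau_s,
        _["acc_rho"] = (double)mv_acc_r / mv_iter,
        _["acc_sigma"] = (double)mv_acc_s / mv_iter));
}
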