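// Blocked Gibbs sampler for the single-exposure structural model with a
// marginalized latent confounder:
//
//   X | Z ~ N(omega_X + Z alpha [+ psi_XW W],            tau_X^2)
//   Y | X,Z ~ N(omega_Y + theta X + Z beta [+ psi_YW W + psi_YXW WX]
//               + rho (X - E[X|Z]),                      s^2)
//
// with tau_X^2 = delta_X^2 + sigma_X^2, tau_Y^2 = delta_Y^2 + sigma_Y^2,
// lambda = delta_X delta_Y, rho = lambda / tau_X^2, s^2 = tau_Y^2 - rho lambda.
//
// Blocks:
//  (1) (omega_X, alpha, psi_XW): Gaussian, using both equations;
//  (2) alpha hyperparameters (mu_alpha flat, sigma_alpha flat on SD scale);
//  (3) (omega_Y, theta, beta, psi_YW, psi_YXW): Gaussian;
//  (4) shrinkage locals (horseshoe or Laplace via inverse-gamma /
//      inverse-Gaussian parameter expansion of the half-Cauchy scales);
//  (5) (delta_X, delta_Y, sigma_X, sigma_Y): two alternating adaptive
//      Metropolis kernels on (delta_X, delta_Y, log sigma_X, log sigma_Y) —
//      a plain one at fixed coefficients, and a compensated one that also
//      shifts (theta, omega_Y, beta, psi_YW) along the observational-
//      equivalence direction theta' = theta - d_rho, beta' = beta +
//      d_rho alpha, which only the shrinkage prior constrains — plus a
//      likelihood-invariant rescaling of (delta_X, delta_Y) at fixed
//      (tau_X^2, tau_Y^2, lambda) and a joint sign flip.
//
// Everything reduces to Gram-matrix algebra after one O(n p^2) precompute,
// so a sweep costs O(p^3) independent of n.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const int HORSESHOE = 0, LAPLACE = 1, POINT_ZERO = 2;

static double rinvgamma(double shape, double scale) {
  if (shape == 1.0) return scale / R::exp_rand();
  return scale / R::rgamma(shape, 1.0);
}

static double rinvgauss(double mu, double lambda) {
  double z = R::norm_rand(), z2 = z * z;
  double x = mu + (mu * mu * z2) / (2.0 * lambda) -
             (mu / (2.0 * lambda)) *
                 std::sqrt(4.0 * mu * lambda * z2 + mu * mu * z2 * z2);
  if (x <= 0 || !std::isfinite(x)) x = 1e-12;
  if (R::unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

static arma::vec mvn_prec(const arma::mat &P, const arma::vec &b) {
  arma::mat Pj = P;
  Pj.diag() += 1e-10 * (1.0 + arma::max(P.diag()));
  arma::mat R = arma::chol(Pj); // upper: Pj = R' R
  arma::vec m = arma::solve(arma::trimatu(R),
                            arma::solve(arma::trimatl(R.t()), b));
  arma::vec z(b.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = R::norm_rand();
  return m + arma::solve(arma::trimatu(R), z);
}

struct SuffStats { double SAA, SBB, SAB; };

// bivariate-normal residual log-likelihood given sufficient statistics
static double biv_loglik(double n, double tx2, double ty2, double lam,
                         const SuffStats &S) {
  double det = tx2 * ty2 - lam * lam;
  if (det <= 0) return -INFINITY;
  return -0.5 * n * std::log(det) -
         0.5 * (ty2 * S.SAA - 2.0 * lam * S.SAB + tx2 * S.SBB) / det;
}

// [[Rcpp::export]]
List gibbs_single_cpp(const arma::vec &x, const arma::vec &y,
                      const arma::mat &Wx, const arma::mat &Wy,
                      const arma::uvec &alpha_idx, int wxw_idx,
                      int theta_idx, const arma::uvec &beta_idx,
                      int yw_idx, int yxw_idx,
                      int prior_type, bool alpha_hier, double alpha_sd_fixed,
                      double u_tau_x2, double theta_lower, double theta_upper,
                      int n_warmup, int n_keep, int thin,
                      List init, int n_sigma_mh, bool ridge) {
  const int n = x.n_elem, px = Wx.n_cols, py = Wy.n_cols;
  const int J = alpha_idx.n_elem;
  const int Jb = beta_idx.n_elem;

  // Gram precomputation
  arma::mat Gxx = Wx.t() * Wx, Gyy = Wy.t() * Wy, Gxy = Wx.t() * Wy;
  arma::vec hx = Wx.t() * x, hy = Wx.t() * y;
  arma::vec gy = Wy.t() * y, gx = Wy.t() * x;
  double xx = arma::dot(x, x), yy = arma::dot(y, y), xy = arma::dot(x, y);

  // state
  arma::vec a = as<arma::vec>(init["a"]);
  arma::vec g = as<arma::vec>(init["g"]);
  double delta_x = init["delta_x"], delta_y = init["delta_y"];
  double sigma_x = init["sigma_x"], sigma_y = init["sigma_y"];
  double mu_alpha = init["mu_alpha"], sigma_alpha = init["sigma_alpha"];
  arma::vec eta2(std::max(Jb, 1), arma::fill::ones); // horseshoe locals^2/gamma^2
  arma::vec nu(std::max(Jb, 1), arma::fill::ones);
  double gamma2 = 1.0, xi = 1.0;     // horseshoe global
  arma::vec vlap(std::max(Jb, 1), arma::fill::ones); // laplace local variances
  double tau2_lap = 1.0, zeta = 1.0;

  // adaptation state
  arma::vec mh_sc = {0.02, 0.02, 0.10, 0.10};
  double mh_logstep = 0.0, comp_logstep = 0.0;
  long mh_tries = 0, mh_acc = 0;

  const int n_total = n_warmup + n_keep * thin;
  const int n_par = 12 + 2 * J +
                    (prior_type == HORSESHOE ? (1 + 2 * Jb) : 0) +
                    (prior_type == LAPLACE ? 1 : 0) +
                    (wxw_idx >= 0 ? 1 : 0) + (yw_idx >= 0 ? 1 : 0) +
                    (yxw_idx >= 0 ? 1 : 0);
  arma::mat draws(n_keep, n_par);
  int keep_row = 0;

  auto beta_prec = [&](int j) {
    if (prior_type == HORSESHOE) return 1.0 / (gamma2 * eta2(j));
    return 1.0 / vlap(j); // laplace
  };
  auto log_prior_beta = [&](const arma::vec &b) {
    double lp = 0.0;
    for (int j = 0; j < Jb; ++j) lp += -0.5 * b(j) * b(j) * beta_prec(j);
    return lp;
  };

  for (int it = 0; it < n_total; ++it) {
    double tx2 = delta_x * delta_x + sigma_x * sigma_x;
    double ty2 = delta_y * delta_y + sigma_y * sigma_y;
    double lam = delta_x * delta_y;
    double rho = lam / tx2, s2 = ty2 - lam * lam / tx2;

    // ---- (1) X-equation coefficients (both equations inform them) ----
    {
      double cx = 1.0 / tx2 + rho * rho / s2;
      arma::mat P = cx * Gxx;
      arma::vec b = hx / tx2 - (rho / s2) * (hy - Gxy * g - rho * hx);
      for (int j = 0; j < J; ++j) {
        double prec = alpha_hier ? 1.0 / (sigma_alpha * sigma_alpha)
                                 : 1.0 / (alpha_sd_fixed * alpha_sd_fixed);
        P(alpha_idx(j), alpha_idx(j)) += prec;
        b(alpha_idx(j)) += prec * (alpha_hier ? mu_alpha : 0.0);
      }
      a = mvn_prec(P, b);
    }

    // ---- (2) alpha hyperparameters ----
    if (alpha_hier && J >= 2) {
      double abar = 0.0;
      for (int j = 0; j < J; ++j) abar += a(alpha_idx(j));
      abar /= J;
      mu_alpha = abar + R::norm_rand() * sigma_alpha / std::sqrt((double)J);
      double S = 0.0;
      for (int j = 0; j < J; ++j) {
        double d = a(alpha_idx(j)) - mu_alpha;
        S += d * d;
      }
      sigma_alpha = std::sqrt(rinvgamma(0.5 * (J - 1), 0.5 * S));
      if (sigma_alpha < 1e-6) sigma_alpha = 1e-6;
    }

    // ---- (3) Y-equation coefficients ----
    {
      arma::mat P = Gyy / s2;
      arma::vec WyA = gx - Gxy.t() * a; // Wy' (x - Wx a)
      arma::vec b = (gy - rho * WyA) / s2;
      for (int j = 0; j < Jb; ++j) P(beta_idx(j), beta_idx(j)) += beta_prec(j);
      bool bounded = std::isfinite(theta_lower) || std::isfinite(theta_upper);
      arma::vec gprop = mvn_prec(P, b);
      if (bounded) {
        int tries = 0;
        while ((gprop(theta_idx) < theta_lower ||
                gprop(theta_idx) > theta_upper) && ++tries < 100)
          gprop = mvn_prec(P, b);
        if (gprop(theta_idx) >= theta_lower && gprop(theta_idx) <= theta_upper)
          g = gprop;
      } else {
        g = gprop;
      }
    }

    // ---- (4) shrinkage hierarchy ----
    if (prior_type == HORSESHOE && Jb > 0) {
      double sb = 0.0;
      for (int j = 0; j < Jb; ++j) {
        double bj = g(beta_idx(j));
        eta2(j) = rinvgamma(1.0, 1.0 / nu(j) + bj * bj / (2.0 * gamma2));
        nu(j) = rinvgamma(1.0, 1.0 + 1.0 / eta2(j));
        sb += bj * bj / eta2(j);
      }
      gamma2 = rinvgamma(0.5 * (Jb + 1.0), 1.0 / xi + 0.5 * sb);
      xi = rinvgamma(1.0, 1.0 + 1.0 / gamma2);
    } else if (prior_type == LAPLACE && Jb > 0) {
      double sv = 0.0;
      for (int j = 0; j < Jb; ++j) {
        double bj = g(beta_idx(j));
        double ab = std::max(std::fabs(bj), 1e-8);
        double inv = rinvgauss(1.0 / (std::sqrt(tau2_lap) * ab), 1.0 / tau2_lap);
        vlap(j) = 1.0 / std::max(inv, 1e-12);
        sv += vlap(j);
      }
      tau2_lap = rinvgamma(Jb + 0.5, 1.0 / zeta + 0.5 * sv);
      zeta = rinvgamma(1.0, 1.0 + 1.0 / tau2_lap);
    }

    // ---- residual sufficient statistics ----
    SuffStats S;
    S.SAA = xx - 2.0 * arma::dot(a, hx) + arma::as_scalar(a.t() * Gxx * a);
    S.SBB = yy - 2.0 * arma::dot(g, gy) + arma::as_scalar(g.t() * Gyy * g);
    S.SAB = xy - arma::dot(a, hy) - arma::dot(g, gx) +
            arma::as_scalar(a.t() * Gxy * g);

    // ---- (5) covariance block: plain and compensated Metropolis ----
    // Two alternating kernels on (delta_X, delta_Y, log sigma_X, log
    // sigma_Y). The plain kernel moves the error covariance at fixed
    // coefficients (lambda is likelihood-identified through the residual
    // cross-product). The compensated kernel additionally shifts the
    // Y-equation coefficients along the observational-equivalence direction
    // (theta -> theta - d_rho, omega_Y -> omega_Y + d_rho omega_X,
    //  beta -> beta + d_rho alpha, psi_YW -> psi_YW + d_rho psi_XW), so the
    // conditional mean is preserved wherever coefficients exist — the
    // direction that only the beta-shrinkage prior constrains. Acceptance
    // uses the exact bivariate likelihood via sufficient statistics, the
    // flat-prior Jacobians, and the shrinkage-prior ratio for beta.
    {
      // compensation direction in g-space and its Gram products
      arma::vec comp(py, arma::fill::zeros);
      comp(theta_idx) = -1.0;
      comp(0) = a(0);
      for (int j = 0; j < Jb; ++j) comp(beta_idx(j)) = a(alpha_idx(j));
      if (yw_idx >= 0 && wxw_idx >= 0) comp(yw_idx) = a(wxw_idx);
      arma::vec Gyyc = Gyy * comp;
      double cww = arma::dot(comp, Gyyc);
      double cu = arma::dot(comp, gy) - arma::dot(Gyyc, g);
      arma::vec WyA = gx - Gxy.t() * a;
      double cv = arma::dot(comp, WyA);
      // beta-prior cross terms for the shifted beta
      double pba = 0, paa = 0;
      for (int j = 0; j < Jb; ++j) {
        double pr = beta_prec(j), bj = g(beta_idx(j)), al = a(alpha_idx(j));
        pba += pr * bj * al; paa += pr * al * al;
      }
      double rho_base = rho, theta_base = g(theta_idx);
      // posterior for state (q, t): t = rho(q) - rho_base, g_t = g + t comp
      auto logpost = [&](const arma::vec &q, bool use_comp,
                         double &t_out) -> double {
        double tx2q = q(0) * q(0) + std::exp(2 * q(2));
        double ty2q = q(1) * q(1) + std::exp(2 * q(3));
        double lamq = q(0) * q(1);
        if (std::isfinite(u_tau_x2) && tx2q > u_tau_x2) return -INFINITY;
        double t = use_comp ? lamq / tx2q - rho_base : 0.0;
        t_out = t;
        double thq = theta_base - t;
        if ((std::isfinite(theta_lower) && thq < theta_lower) ||
            (std::isfinite(theta_upper) && thq > theta_upper))
          return -INFINITY;
        SuffStats St;
        St.SAA = S.SAA;
        St.SBB = S.SBB - 2.0 * t * cu + t * t * cww;
        St.SAB = S.SAB - t * cv;
        return biv_loglik(n, tx2q, ty2q, lamq, St) + q(2) + q(3) -
               0.5 * (2.0 * t * pba + t * t * paa);
      };
      arma::vec q = {delta_x, delta_y, std::log(sigma_x), std::log(sigma_y)};
      double t_cur = 0, t_prop = 0;
      // plain kernel (t stays 0)
      double cur = logpost(q, false, t_prop);
      for (int m = 0; m < n_sigma_mh; ++m) {
        arma::vec qp = q;
        double step = std::exp(mh_logstep);
        for (int k = 0; k < 4; ++k) qp(k) += step * mh_sc(k) * R::norm_rand();
        double lp = logpost(qp, false, t_prop);
        double apr = std::isfinite(lp) ? std::min(1.0, std::exp(lp - cur)) : 0.0;
        ++mh_tries;
        if (R::unif_rand() < apr) { q = qp; cur = lp; ++mh_acc; }
        if (it < n_warmup)
          mh_logstep += (apr - 0.3) / std::pow(1.0 + it, 0.6);
      }
      // compensated kernel
      if (ridge) {
        rho_base = q(0) * q(1) / (q(0) * q(0) + std::exp(2 * q(2)));
        cur = logpost(q, true, t_cur); // t_cur = 0 at the fresh base
        for (int m = 0; m < n_sigma_mh; ++m) {
          arma::vec qp = q;
          double step = std::exp(comp_logstep);
          for (int k = 0; k < 4; ++k)
            qp(k) += step * mh_sc(k) * R::norm_rand();
          double lp = logpost(qp, true, t_prop);
          double apr = std::isfinite(lp) ? std::min(1.0, std::exp(lp - cur))
                                         : 0.0;
          if (R::unif_rand() < apr) { q = qp; cur = lp; t_cur = t_prop; }
          if (it < n_warmup)
            comp_logstep += (apr - 0.3) / std::pow(1.0 + it, 0.6);
        }
        if (t_cur != 0.0) g += t_cur * comp;
      }
      delta_x = q(0); delta_y = q(1);
      sigma_x = std::exp(q(2)); sigma_y = std::exp(q(3));
      tx2 = delta_x * delta_x + sigma_x * sigma_x;
      ty2 = delta_y * delta_y + sigma_y * sigma_y;
      lam = delta_x * delta_y;
      rho = lam / tx2; s2 = ty2 - lam * lam / tx2;

      // likelihood-invariant fiber move: (delta_x, delta_y) -> (c dx, dy/c)
      // holding (tau_x^2, tau_y^2, lambda); flat priors, Jacobian
      // (sigma_x sigma_y)/(sigma_x' sigma_y')
      if (std::fabs(delta_x) > 1e-12 && std::fabs(delta_y) > 1e-12) {
        double c = std::exp(0.3 * R::norm_rand());
        double dxp = c * delta_x, dyp = delta_y / c;
        double sx2p = tx2 - dxp * dxp, sy2p = ty2 - dyp * dyp;
        if (sx2p > 0 && sy2p > 0) {
          double la = std::log(sigma_x * sigma_y) -
                      0.5 * std::log(sx2p * sy2p);
          if (std::log(R::unif_rand()) < la) {
            delta_x = dxp; delta_y = dyp;
            sigma_x = std::sqrt(sx2p); sigma_y = std::sqrt(sy2p);
          }
        }
        // joint sign flip (exactly symmetric, always accepted)
        if (R::unif_rand() < 0.5) { delta_x = -delta_x; delta_y = -delta_y; }
      }
    }

    // ---- record ----
    if (it >= n_warmup && ((it - n_warmup) % thin == 0)) {
      double tx = std::sqrt(delta_x * delta_x + sigma_x * sigma_x);
      double ty = std::sqrt(delta_y * delta_y + sigma_y * sigma_y);
      int c = 0;
      arma::rowvec row(n_par);
      row(c++) = g(theta_idx);
      row(c++) = a(0);
      row(c++) = g(0);
      row(c++) = delta_x; row(c++) = delta_y;
      row(c++) = sigma_x; row(c++) = sigma_y;
      row(c++) = tx; row(c++) = ty;
      row(c++) = delta_x * delta_y;
      row(c++) = mu_alpha; row(c++) = sigma_alpha;
      for (int j = 0; j < J; ++j) row(c++) = a(alpha_idx(j));
      for (int j = 0; j < J; ++j)
        row(c++) = (j < Jb) ? g(beta_idx(j)) : 0.0;
      if (prior_type == HORSESHOE) {
        row(c++) = std::sqrt(gamma2);
        for (int j = 0; j < Jb; ++j) row(c++) = std::sqrt(gamma2 * eta2(j));
        for (int j = 0; j < Jb; ++j) row(c++) = 1.0 / (1.0 + gamma2 * eta2(j));
      } else if (prior_type == LAPLACE) {
        row(c++) = std::sqrt(tau2_lap);
      }
      if (wxw_idx >= 0) row(c++) = a(wxw_idx);
      if (yw_idx >= 0) row(c++) = g(yw_idx);
      if (yxw_idx >= 0) row(c++) = g(yxw_idx);
      draws.row(keep_row++) = row;
    }
  }

  return List::create(
      _["draws"] = draws,
      _["accept_sigma"] = mh_tries ? (double)mh_acc / mh_tries : NA_REAL);
}
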