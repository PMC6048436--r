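// Metropolis-within-Gibbs sampler for the Pool-Seq hierarchical model.
//
// Observation layer: ref reads r_ij ~ Binomial(c_ij, y_ij / n_i) with
// latent pool allele counts y_ij ~ Binomial(n_i, g(alpha_ij)); population
// frequencies alpha_j ~ N(pi_j 1 + delta_j beta_j z, pi_j(1-pi_j) Omega)
// with the censored link g(a) = min(max(a, 0), 1), so alpha is unbounded
// and frequencies pinned at 0/1 carry their full Gaussian tail (the same
// clipping the generative model applies); pi_j ~ Beta(a, b).
// Omega gets a conjugate inverse-Wishart update on the standardized
// residuals; (delta_j, beta_j) get exact Gibbs draws (the conditional of
// beta under a uniform(-B, B) prior is a truncated Gaussian, and the
// marginal over it is available in closed form); P ~ Beta conjugate.
//
// All randomness flows through R's RNG so set.seed() governs the run.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double ALPHA_LO = 1e-5;
static const double PI_LO = 1e-4;

static inline double reflect(double x, double lo, double hi) {
  while (x < lo || x > hi) {
    if (x < lo) x = 2.0 * lo - x;
    else x = 2.0 * hi - x;
  }
  return x;
}

// log Binomial(r | c, q) ratio helper: r*log(q) with 0*log(0) = 0
static inline double xlogy(double x, double y) {
  if (x == 0.0) return 0.0;
  return x * std::log(y);
}

// Truncated normal draw on [lo, hi] via inverse CDF (R RNG)
static inline double rtruncnorm(double m, double s, double lo, double hi) {
  double plo = R::pnorm(lo, m, s, 1, 0);
  double phi = R::pnorm(hi, m, s, 1, 0);
  double u = plo + unif_rand() * (phi - plo);
  u = std::min(std::max(u, 1e-15), 1.0 - 1e-15);
  return R::qnorm(u, m, s, 1, 0);
}

// [[Rcpp::export(name = ".gea_mcmc")]]
List gea_mcmc(const arma::imat& ref, const arma::imat& cov,
              const arma::ivec& pool_size,
              const arma::mat& omega_init,
              bool estimate_omega,
              bool aux, const arma::vec& z, double beta_bound,
              double pi_a, double pi_b,
              int npilot, int pilot_length, int burnin,
              int nsamp, int thin,
              bool accumulate_cross) {
  const int n = ref.n_rows, J = ref.n_cols;
  RNGScope scope;

  // --- state ---
  arma::mat alpha(n, J), e(n, J);
  arma::vec pi(n);
  arma::imat y(n, J);
  arma::ivec delta(n, arma::fill::zeros);
  arma::vec beta(n, arma::fill::zeros);
  double P = 0.01;

  for (int j = 0; j < n; ++j) {
    double s = 0.0;
    for (int i = 0; i < J; ++i) {
      double c = cov(j, i), r = ref(j, i);
      double f = c > 0 ? (r + 0.5) / (c + 1.0) : 0.5;
      alpha(j, i) = std::min(std::max(f, 1e-3), 1.0 - 1e-3);
      int ni = pool_size(i);
      int yy = (int) std::lround(ni * alpha(j, i));
      if (r > 0 && yy < 1) yy = 1;
      if (r < c && yy > ni - 1) yy = ni - 1;
      y(j, i) = std::min(std::max(yy, 0), ni);
      s += alpha(j, i);
    }
    pi(j) = std::min(std::max(s / J, PI_LO), 1.0 - PI_LO);
  }

  // per-population lookup tables over pool count values
  std::vector<arma::vec> lch(J), lgy(J), lg1y(J);
  for (int i = 0; i < J; ++i) {
    int ni = pool_size(i);
    lch[i].set_size(ni + 1); lgy[i].set_size(ni + 1); lg1y[i].set_size(ni + 1);
    for (int yv = 0; yv <= ni; ++yv) {
      lch[i](yv) = R::lchoose(ni, yv);
      lgy[i](yv) = yv > 0 ? std::log((double) yv / ni) : R_NegInf;
      lg1y[i](yv) = yv < ni ? std::log(1.0 - (double) yv / ni) : R_NegInf;
    }
  }

  arma::mat Omega = omega_init, Lambda = arma::inv_sympd(Omega);
  arma::vec lam1 = Lambda * arma::ones(J);
  arma::vec zlam(J, arma::fill::zeros);
  double zLz = 0.0;
  if (aux) { zlam = Lambda * z; zLz = arma::dot(z, zlam); }

  // proposal widths and acceptance counters (pilot tuning)
  arma::vec sig_a(n, arma::fill::value(0.05)), sig_p(n, arma::fill::value(0.05));
  arma::vec acc_a(n, arma::fill::zeros), att_a(n, arma::fill::zeros);
  arma::vec acc_p(n, arma::fill::zeros), att_p(n, arma::fill::zeros);

  // accumulators
  arma::vec pi_sum(n, arma::fill::zeros), xtx_sum(n, arma::fill::zeros);
  arma::mat alpha_sum(n, J, arma::fill::zeros);
  arma::vec delta_sum(n, arma::fill::zeros), db_sum(n, arma::fill::zeros);
  arma::mat omega_sum(J, J, arma::fill::zeros);
  double P_sum = 0.0;
  arma::cube cross;
  if (accumulate_cross) cross = arma::cube(J, J, n, arma::fill::zeros);

  auto sweep_once = [&](bool tune) {
    for (int j = 0; j < n; ++j) {
      double pj = pi(j), v = pj * (1.0 - pj);
      double db = aux ? delta(j) * beta(j) : 0.0;
      // residual e_j = alpha - pi - db * z, and w = Lambda * e
      arma::rowvec ej = alpha.row(j) - pj;
      if (aux && db != 0.0) ej -= db * z.t();
      arma::vec w = Lambda * ej.t();

      // latent pool counts (censored link: g(a) clamps into [0, 1])
      for (int rep = 0; rep < 2; ++rep)
      for (int i = 0; i < J; ++i) {
        int ni = pool_size(i), yy = y(j, i);
        int yp = yy + (unif_rand() < 0.5 ? -1 : 1);
        if (yp < 0 || yp > ni) continue;
        double a = std::min(std::max(alpha(j, i), 0.0), 1.0);
        double r = ref(j, i), c = cov(j, i);
        double la = std::log(a), l1a = std::log(1.0 - a);
        // log target at a pool count value (combinatorial + both layers)
        auto logt = [&](int yv) {
          double lt = lch[i](yv);
          if (yv > 0) lt += yv * la;
          if (yv < ni) lt += (ni - yv) * l1a;
          if (r > 0) lt += r * lgy[i](yv);
          if (c - r > 0) lt += (c - r) * lg1y[i](yv);
          return lt;
        };
        double lnew = logt(yp), lold = logt(yy);
        if (lnew == R_NegInf) continue;
        double lr = (lold == R_NegInf) ? R_PosInf : lnew - lold;
        if (lr >= 0.0 || unif_rand() < std::exp(lr)) y(j, i) = yp;
      }

      // population frequencies, component-wise, unbounded with censored
      // binomial likelihood
      for (int i = 0; i < J; ++i) {
        double a = alpha(j, i);
        double ap = a + sig_a(j) * norm_rand();
        double d = ap - a;
        int yy = y(j, i), ni = pool_size(i);
        double ga = std::min(std::max(a, 0.0), 1.0);
        double gp = std::min(std::max(ap, 0.0), 1.0);
        double lr = xlogy(yy, gp) + xlogy(ni - yy, 1.0 - gp)
                  - xlogy(yy, ga) - xlogy(ni - yy, 1.0 - ga)
                  - 0.5 / v * (2.0 * d * w(i) + d * d * Lambda(i, i));
        if (std::isnan(lr)) lr = R_NegInf;
        if (tune) att_a(j) += 1.0;
        if (lr >= 0.0 || unif_rand() < std::exp(lr)) {
          alpha(j, i) = ap;
          ej(i) += d;
          w += d * Lambda.col(i);
          if (tune) acc_a(j) += 1.0;
        }
      }

      // across-population frequency pi_j
      {
        double q = arma::dot(ej, w.t());
        double pp = reflect(pj + sig_p(j) * norm_rand(), PI_LO, 1.0 - PI_LO);
        double d = pp - pj, vp = pp * (1.0 - pp);
        // mean shifts by d for every population
        double oe = arma::dot(lam1, ej.t());
        double o11 = arma::accu(lam1);
        double qp = q - 2.0 * d * oe + d * d * o11;
        double lr = -0.5 * qp / vp - 0.5 * J * std::log(vp)
                  + 0.5 * q / v + 0.5 * J * std::log(v)
                  + (pi_a - 1.0) * std::log(pp / pj)
                  + (pi_b - 1.0) * std::log((1.0 - pp) / (1.0 - pj));
        if (tune) att_p(j) += 1.0;
        if (lr >= 0.0 || unif_rand() < std::exp(lr)) {
          pi(j) = pp; pj = pp; v = vp;
          ej -= d;
          w -= d * lam1;
          if (tune) acc_p(j) += 1.0;
        }
      }

      // spike-and-slab covariate term
      if (aux) {
        arma::vec e0 = ej.t() + db * z;          // residual without the term
        arma::vec w0 = w + db * zlam;
        double A = zLz / v;
        double b_lin = arma::dot(z, w0) / v;
        double m = b_lin / A, s = 1.0 / std::sqrt(A);
        double plo = R::pnorm(-beta_bound, m, s, 1, 0);
        double phi = R::pnorm(beta_bound, m, s, 1, 0);
        double mass = std::max(phi - plo, 1e-300);
        double logM1M0 = 0.5 * b_lin * b_lin / A
                       + std::log(mass) + std::log(s) + 0.5 * std::log(2.0 * M_PI)
                       - std::log(2.0 * beta_bound);
        double logodds = std::log(P / (1.0 - P)) + logM1M0;
        double p1 = 1.0 / (1.0 + std::exp(-logodds));
        int dnew = unif_rand() < p1 ? 1 : 0;
        double bnew = 0.0;
        if (dnew == 1) bnew = rtruncnorm(m, s, -beta_bound, beta_bound);
        delta(j) = dnew; beta(j) = bnew;
      }
    }

    if (estimate_omega) {
      arma::mat Astd = alpha;
      Astd.each_col() -= pi;
      Astd.each_col() /= arma::sqrt(pi % (1.0 - pi));
      arma::mat Psi = arma::eye(J, J) + Astd.t() * Astd;
      double nu = J + 2.0 + n;
      // Omega ~ InvWishart(Psi, nu): draw Lambda ~ Wishart(Psi^-1, nu)
      arma::mat Cl = arma::chol(arma::inv_sympd(Psi), "lower");
      arma::mat A(J, J, arma::fill::zeros);
      for (int i = 0; i < J; ++i) {
        A(i, i) = std::sqrt(R::rchisq(nu - i));
        for (int k = 0; k < i; ++k) A(i, k) = norm_rand();
      }
      arma::mat CA = Cl * A;
      Lambda = CA * CA.t();
      Omega = arma::inv_sympd(Lambda);
      lam1 = Lambda * arma::ones(J);
      if (aux) { zlam = Lambda * z; zLz = arma::dot(z, zlam); }
    }

    if (aux) {
      double sd = arma::accu(delta);
      P = R::rbeta(1.0 + sd, 1.0 + n - sd);
      P = std::min(std::max(P, 1e-8), 1.0 - 1e-8);
    }
  };

  // pilot runs: adapt proposal widths to a 25-45% acceptance window
  for (int p = 0; p < npilot; ++p) {
    for (int it = 0; it < pilot_length; ++it) sweep_once(true);
    for (int j = 0; j < n; ++j) {
      if (att_a(j) > 0) {
        double r = acc_a(j) / att_a(j);
        if (r < 0.25) sig_a(j) *= 0.8;
        else if (r > 0.45) sig_a(j) *= 1.25;
        sig_a(j) = std::min(std::max(sig_a(j), 1e-3), 1.0);
      }
      if (att_p(j) > 0) {
        double r = acc_p(j) / att_p(j);
        if (r < 0.25) sig_p(j) *= 0.8;
        else if (r > 0.45) sig_p(j) *= 1.25;
        sig_p(j) = std::min(std::max(sig_p(j), 1e-3), 1.0);
      }
      acc_a(j) = att_a(j) = acc_p(j) = att_p(j) = 0.0;
    }
  }

  for (int it = 0; it < burnin; ++it) sweep_once(false);

  acc_a.zeros(); att_a.zeros(); acc_p.zeros(); att_p.zeros();
  for (int s = 0; s < nsamp; ++s) {
    for (int t = 0; t < thin; ++t) sweep_once(true);
    pi_sum += pi;
    alpha_sum += alpha;
    omega_sum += Omega;
    P_sum += P;
    arma::mat Astd = alpha;
    Astd.each_col() -= pi;
    Astd.each_col() /= arma::sqrt(pi % (1.0 - pi));
    for (int j = 0; j < n; ++j) {
      arma::rowvec aj = Astd.row(j);
      xtx_sum(j) += arma::as_scalar(aj * Lambda * aj.t());
      if (accumulate_cross) cross.slice(j) += aj.t() * aj;
    }
    if (aux) {
      delta_sum += arma::conv_to<arma::vec>::from(delta);
      db_sum += arma::conv_to<arma::vec>::from(delta) % beta;
    }
    if (s % 50 == 0) Rcpp::checkUserInterrupt();
  }

  double S = (double) nsamp;
  List out = List::create(
    _["pi"] = pi_sum / S,
    _["alpha"] = alpha_sum / S,
    _["omega"] = omega_sum / S,
    _["xtx"] = xtx_sum / S,
    _["pip"] = delta_sum / S,
    _["beta_hat"] = db_sum / S,
    _["p_mean"] = P_sum / S,
    _["n_samples"] = nsamp,
    _["acc_alpha"] = arma::accu(acc_a) / std::max(arma::accu(att_a), 1.0),
    _["acc_pi"] = arma::accu(acc_p) / std::max(arma::accu(att_p), 1.0),
    _["sig_alpha"] = sig_a, _["sig_pi"] = sig_p);
  if (accumulate_cross) out["cross"] = cross / S;
  return out;
}
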