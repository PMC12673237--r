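// MCMC for the Gaussian double-hierarchical (location-scale) model:
//   y_j ~ N(mu_j, sigma_j^2)
//   mu_j    = x_j' beta  + alpha_{id(j)}
//   log s_j = x_j' gamma + omega_{id(j)}
//   (alpha_i, omega_i) ~ BVN(0, {sigma_a^2, rho sigma_a sigma_o; ., sigma_o^2})
// Sampler: conjugate Gibbs for beta and alpha; adaptive random-walk
// Metropolis for omega (per individual), gamma (joint), and the
// hyperparameters on transformed scales; plus joint scaling moves on
// (alpha, sigma_a) and (omega, sigma_o) that break the funnel between
// the random effects and their scales. Adaptation runs during burn-in
// only. Uses R's RNG, so chains are reproducible via set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LS_MIN = -10.0, LS_MAX = 5.0, ZR_MAX = 7.0;

// log density of half-t(df, scale) evaluated at s = exp(ls), including
// the log|ds/dls| = ls Jacobian of the log transform
static inline double lhalft_ls(double ls, double df, double scale) {
  double s = std::exp(ls);
  return -0.5 * (df + 1.0) * std::log1p((s / scale) * (s / scale) / df) + ls;
}

// log of the bivariate-normal portion of the joint density (alpha, omega
// pairs given hyperparameters), constants in q dropped where harmless
static inline double lbvn(double Saa, double Sao, double Soo, int q,
                          double sa, double so, double rho) {
  double om2 = 1.0 - rho * rho;
  double quad = Saa / (sa * sa) - 2.0 * rho * Sao / (sa * so) + Soo / (so * so);
  return -q * std::log(sa * so) - 0.5 * q * std::log(om2) - 0.5 * quad / om2;
}

// Zg: per-individual values of the design columns listed in gcols
// (columns constant within individuals, e.g. intercept and site).
// Translation moves shift such a fixed effect and the individual effects
// in opposition, leaving the likelihood invariant; they sample the slow
// fixed-effect/random-effect trade-off direction directly.

// [[Rcpp::export]]
List dhglm_chain(const arma::vec& y, const arma::mat& X,
                 const arma::uvec& id, int q,
                 int n_iter, int n_burn, int thin,
                 List init, List prior,
                 const arma::mat& Zg, const arma::uvec& gcols) {
  const int N = y.n_elem, p = X.n_cols;
  const double beta_sd = prior["beta_sd"], gamma_sd = prior["gamma_sd"];
  const double sdf = prior["sigma_df"], ssc = prior["sigma_scale"];

  arma::vec beta = init["beta"], gamma = init["gamma"];
  arma::vec alpha = init["alpha"], omega = init["omega"];
  double ls_a = init["ls_a"], ls_o = init["ls_o"], zr = init["zr"];

  arma::vec n_i(q, arma::fill::zeros);
  for (int j = 0; j < N; ++j) n_i(id(j)) += 1.0;

  // adaptive proposal state
  arma::vec ls_om(q); ls_om.fill(std::log(0.3));
  double ls_sa = std::log(0.2), ls_so = std::log(0.2);
  arma::vec mg(p, arma::fill::zeros);            // gamma running mean/cov
  arma::mat Cg(p, p, arma::fill::zeros), Lg = arma::eye(p, p) * 0.02;
  double ls_g = 0.0; int cg = 0;
  arma::vec ls_tb(gcols.n_elem), ls_tg(gcols.n_elem);  // translation moves
  ls_tb.fill(std::log(0.1)); ls_tg.fill(std::log(0.1));
  arma::vec mh(3, arma::fill::zeros);            // hyper running mean/cov
  arma::mat Ch(3, 3, arma::fill::zeros), Lh = arma::eye(3, 3) * 0.05;
  double ls_h = 0.0; int ch = 0;

  const int n_keep = (n_iter - n_burn) / thin;
  const int npar = 2 * p + 3 + 2 * q;
  arma::mat out(n_keep, npar);
  int kept = 0;
  double acc_om = 0, acc_g = 0, acc_h = 0, acc_sa = 0, acc_so = 0, n_om = 0;

  for (int it = 1; it <= n_iter; ++it) {
    const bool adapting = it <= n_burn;
    const double gain = 1.0 / std::pow(10.0 + it, 0.6);
    double sa = std::exp(ls_a), so = std::exp(ls_o), rho = std::tanh(zr);

    // --- cached dispersion quantities
    arma::vec eta_g = X * gamma;
    arma::vec lsd = eta_g + omega.elem(id);
    arma::vec w = arma::exp(-2.0 * lsd);

    // --- beta: Gaussian full conditional
    {
      arma::vec r0 = y - alpha.elem(id);
      arma::mat Xw = X.each_col() % w;
      arma::mat A = X.t() * Xw;
      A.diag() += 1.0 / (beta_sd * beta_sd);
      arma::vec b = X.t() * (w % r0);
      arma::mat L = arma::chol(A, "lower");
      arma::vec mu = arma::solve(A, b, arma::solve_opts::likely_sympd);
      arma::vec z(p);
      for (int k = 0; k < p; ++k) z(k) = R::norm_rand();
      beta = mu + arma::solve(arma::trimatu(L.t()), z);
    }
    arma::vec r = y - X * beta;

    // --- alpha: per-individual Gaussian full conditional
    {
      arma::vec S(q, arma::fill::zeros), T(q, arma::fill::zeros);
      for (int j = 0; j < N; ++j) {
        S(id(j)) += w(j);
        T(id(j)) += w(j) * r(j);
      }
      double va = std::max(sa * sa * (1.0 - rho * rho), 1e-12);
      for (int i = 0; i < q; ++i) {
        double m = (so > 1e-12) ? rho * (sa / so) * omega(i) : 0.0;
        double prec = 1.0 / va + S(i);
        double mean = (m / va + T(i)) / prec;
        alpha(i) = mean + R::norm_rand() / std::sqrt(prec);
      }
    }
    arma::vec u = r - alpha.elem(id);

    // --- omega: adaptive per-individual random-walk Metropolis.
    // With t_i = sum_j u_j^2 exp(-2 x_j'gamma) over individual i's rows,
    // the data part of the conditional is -n_i w - 0.5 exp(-2w) t_i.
    {
      arma::vec t_i(q, arma::fill::zeros);
      arma::vec e0 = arma::exp(-2.0 * eta_g);
      for (int j = 0; j < N; ++j) t_i(id(j)) += u(j) * u(j) * e0(j);
      double vo = std::max(so * so * (1.0 - rho * rho), 1e-12);
      for (int i = 0; i < q; ++i) {
        double mo = (sa > 1e-12) ? rho * (so / sa) * alpha(i) : 0.0;
        double cur = omega(i);
        double prop = cur + std::exp(ls_om(i)) * R::norm_rand();
        double lp_cur = -n_i(i) * cur - 0.5 * std::exp(-2.0 * cur) * t_i(i)
          - 0.5 * (cur - mo) * (cur - mo) / vo;
        double lp_prop = -n_i(i) * prop - 0.5 * std::exp(-2.0 * prop) * t_i(i)
          - 0.5 * (prop - mo) * (prop - mo) / vo;
        bool acc = std::log(R::unif_rand()) < lp_prop - lp_cur;
        if (acc) omega(i) = prop;
        n_om += 1; acc_om += acc;
        if (adapting) ls_om(i) += gain * ((acc ? 1.0 : 0.0) - 0.44);
      }
    }

    // --- gamma: joint adaptive random-walk Metropolis
    {
      arma::vec v0 = u % u % arma::exp(-2.0 * omega.elem(id));
      arma::vec eg = X * gamma;
      double f_cur = -arma::accu(eg) - 0.5 * arma::dot(v0, arma::exp(-2.0 * eg))
        - 0.5 * arma::dot(gamma, gamma) / (gamma_sd * gamma_sd);
      arma::vec z(p);
      for (int k = 0; k < p; ++k) z(k) = R::norm_rand();
      arma::vec gp = gamma + std::exp(ls_g) * (Lg * z);
      arma::vec egp = X * gp;
      double f_prop = -arma::accu(egp)
        - 0.5 * arma::dot(v0, arma::exp(-2.0 * egp))
        - 0.5 * arma::dot(gp, gp) / (gamma_sd * gamma_sd);
      bool acc = std::log(R::unif_rand()) < f_prop - f_cur;
      if (acc) gamma = gp;
      acc_g += acc;
      if (adapting) {
        ls_g += gain * ((acc ? 1.0 : 0.0) - 0.28);
        ++cg;
        arma::vec d = gamma - mg;
        mg += d / cg;
        Cg += d * (gamma - mg).t();
        if (cg > 4 * p && it % 100 == 0) {
          arma::mat S = Cg / (cg - 1) + arma::eye(p, p) * 1e-9;
          arma::mat Ltry;
          if (arma::chol(Ltry, S, "lower")) Lg = Ltry * (2.38 / std::sqrt(p));
        }
      }
    }

    eta_g = X * gamma;  // refresh after the gamma move

    // --- scaling move on (alpha, sigma_a): alpha' = alpha e^d, ls_a' = ls_a + d.
    // The BVN prior term and the transform Jacobian cancel exactly, so the
    // ratio is data likelihood (mean model) plus the sigma_a hyperprior.
    {
      double d = std::exp(ls_sa) * R::norm_rand();
      double ls_new = ls_a + d;
      if (ls_new > LS_MIN && ls_new < LS_MAX) {
        double ed = std::exp(d);
        arma::vec w2 = arma::exp(-2.0 * (eta_g + omega.elem(id)));
        arma::vec res_new = r - ed * alpha.elem(id);
        arma::vec res_old = r - alpha.elem(id);
        double dll = -0.5 * arma::dot(w2, res_new % res_new)
          + 0.5 * arma::dot(w2, res_old % res_old)
          + lhalft_ls(ls_new, sdf, ssc) - lhalft_ls(ls_a, sdf, ssc);
        bool acc = std::log(R::unif_rand()) < dll;
        if (acc) { alpha *= ed; ls_a = ls_new; sa = std::exp(ls_a); }
        acc_sa += acc;
        if (adapting) ls_sa += gain * ((acc ? 1.0 : 0.0) - 0.44);
      }
      u = r - alpha.elem(id);
    }

    // --- scaling move on (omega, sigma_o), same cancellation
    {
      double d = std::exp(ls_so) * R::norm_rand();
      double ls_new = ls_o + d;
      if (ls_new > LS_MIN && ls_new < LS_MAX) {
        double ed = std::exp(d);
        arma::vec lsd_old = eta_g + omega.elem(id);
        arma::vec lsd_new = eta_g + ed * omega.elem(id);
        double dll = -arma::accu(lsd_new) + arma::accu(lsd_old)
          - 0.5 * arma::dot(u % u, arma::exp(-2.0 * lsd_new))
          + 0.5 * arma::dot(u % u, arma::exp(-2.0 * lsd_old))
          + lhalft_ls(ls_new, sdf, ssc) - lhalft_ls(ls_o, sdf, ssc);
        bool acc = std::log(R::unif_rand()) < dll;
        if (acc) { omega *= ed; ls_o = ls_new; so = std::exp(ls_o); }
        acc_so += acc;
        if (adapting) ls_so += gain * ((acc ? 1.0 : 0.0) - 0.44);
      }
    }

    // --- translation moves on between-individual fixed effects:
    // beta_k += d, alpha_i -= d z_i (likelihood-invariant), and the
    // analogue for gamma_k with omega. Only the Gaussian priors change.
    {
      double sa_c = std::exp(ls_a), so_c = std::exp(ls_o);
      double rho_c = std::tanh(zr);
      for (arma::uword m = 0; m < gcols.n_elem; ++m) {
        const arma::vec& zi = Zg.col(m);
        // beta side
        {
          double d = std::exp(ls_tb(m)) * R::norm_rand();
          arma::vec an = alpha - d * zi;
          double f_cur = lbvn(arma::dot(alpha, alpha), arma::dot(alpha, omega),
                              arma::dot(omega, omega), q, sa_c, so_c, rho_c)
            - 0.5 * beta(gcols(m)) * beta(gcols(m)) / (beta_sd * beta_sd);
          double bn = beta(gcols(m)) + d;
          double f_prop = lbvn(arma::dot(an, an), arma::dot(an, omega),
                               arma::dot(omega, omega), q, sa_c, so_c, rho_c)
            - 0.5 * bn * bn / (beta_sd * beta_sd);
          bool acc = std::log(R::unif_rand()) < f_prop - f_cur;
          if (acc) { beta(gcols(m)) = bn; alpha = an; }
          if (adapting) ls_tb(m) += gain * ((acc ? 1.0 : 0.0) - 0.44);
        }
        // gamma side
        {
          double d = std::exp(ls_tg(m)) * R::norm_rand();
          arma::vec on = omega - d * zi;
          double f_cur = lbvn(arma::dot(alpha, alpha), arma::dot(alpha, omega),
                              arma::dot(omega, omega), q, sa_c, so_c, rho_c)
            - 0.5 * gamma(gcols(m)) * gamma(gcols(m)) / (gamma_sd * gamma_sd);
          double gn = gamma(gcols(m)) + d;
          double f_prop = lbvn(arma::dot(alpha, alpha), arma::dot(alpha, on),
                               arma::dot(on, on), q, sa_c, so_c, rho_c)
            - 0.5 * gn * gn / (gamma_sd * gamma_sd);
          bool acc = std::log(R::unif_rand()) < f_prop - f_cur;
          if (acc) { gamma(gcols(m)) = gn; omega = on; }
          if (adapting) ls_tg(m) += gain * ((acc ? 1.0 : 0.0) - 0.44);
        }
      }
      if (gcols.n_elem > 0) { r = y - X * beta; u = r - alpha.elem(id); }
    }

    // --- hyperparameters (ls_a, ls_o, atanh rho): joint adaptive MH
    {
      double Saa = arma::dot(alpha, alpha), Soo = arma::dot(omega, omega);
      double Sao = arma::dot(alpha, omega);
      arma::vec th = {ls_a, ls_o, zr};
      double rho_c = std::tanh(th(2));
      double f_cur = lbvn(Saa, Sao, Soo, q, std::exp(th(0)), std::exp(th(1)), rho_c)
        + lhalft_ls(th(0), sdf, ssc) + lhalft_ls(th(1), sdf, ssc)
        + std::log(1.0 - rho_c * rho_c);
      arma::vec z(3);
      for (int k = 0; k < 3; ++k) z(k) = R::norm_rand();
      arma::vec tp = th + std::exp(ls_h) * (Lh * z);
      if (tp(0) > LS_MIN && tp(0) < LS_MAX && tp(1) > LS_MIN &&
          tp(1) < LS_MAX && std::abs(tp(2)) < ZR_MAX) {
        double rho_p = std::tanh(tp(2));
        double f_prop = lbvn(Saa, Sao, Soo, q, std::exp(tp(0)), std::exp(tp(1)), rho_p)
          + lhalft_ls(tp(0), sdf, ssc) + lhalft_ls(tp(1), sdf, ssc)
          + std::log(1.0 - rho_p * rho_p);
        bool acc = std::log(R::unif_rand()) < f_prop - f_cur;
        if (acc) { ls_a = tp(0); ls_o = tp(1); zr = tp(2); }
        acc_h += acc;
        if (adapting) ls_h += gain * ((acc ? 1.0 : 0.0) - 0.28);
      }
      if (adapting) {
        ++ch;
        arma::vec cur = {ls_a, ls_o, zr};
        arma::vec dlt = cur - mh;
        mh += dlt / ch;
        Ch += dlt * (cur - mh).t();
        if (ch > 20 && it % 100 == 0) {
          arma::mat S = Ch / (ch - 1) + arma::eye(3, 3) * 1e-9;
          arma::mat Ltry;
          if (arma::chol(Ltry, S, "lower")) Lh = Ltry * (2.38 / std::sqrt(3.0));
        }
      }
    }

    // --- store
    if (it > n_burn && (it - n_burn) % thin == 0 && kept < n_keep) {
      int c = 0;
      for (int k = 0; k < p; ++k) out(kept, c++) = beta(k);
      for (int k = 0; k < p; ++k) out(kept, c++) = gamma(k);
      out(kept, c++) = std::exp(ls_a);
      out(kept, c++) = std::exp(ls_o);
      out(kept, c++) = std::tanh(zr);
      for (int i = 0; i < q; ++i) out(kept, c++) = alpha(i);
      for (int i = 0; i < q; ++i) out(kept, c++) = omega(i);
      ++kept;
    }
  }

  return List::create(
    _["draws"] = out,
    _["accept"] = NumericVector::create(
      _["omega"] = acc_om / std::max(n_om, 1.0),
      _["gamma"] = acc_g / n_iter, _["hyper"] = acc_h / n_iter,
      _["scale_alpha"] = acc_sa / n_iter, _["scale_omega"] = acc_so / n_iter));
}
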