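// Gibbs sampling engine for multi-class Bayesian Alphabet whole-genome
// regression.  Single-site updates with class-specific prior kernels:
//   0 = RR-BLUP   (common normal, class covariance G)
//   1 = BayesA    (locus-specific covariance G_l)
//   2 = BayesB    (inclusion indicators + locus-specific G_l)
//   3 = BayesCPi  (inclusion indicators + class covariance G)
//   4 = Bayesian LASSO (double-exponential / multivariate Laplace via
//                       exponential scale mixture of normals)
// All randomness flows through R's RNG so chains are reproducible with
// set.seed() and bit-identical across equivalent model reductions.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

// ---------------------------------------------------------------------------
// scalar distribution samplers (R RNG)

// Inverse Gaussian(mu, lambda), Michael-Schucany-Haas.
static double r_invgauss(double mu, double lambda) {
  double z = norm_rand();
  double y = z * z;
  double x = mu + 0.5 * mu * mu * y / lambda -
             0.5 * (mu / lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// Generalized inverse Gaussian, density f(x) ~ x^(lam-1) exp(-omega(x+1/x)/2),
// lam >= 0, omega > 0.  Devroye (2014) rejection algorithm.
static double gig_psi(double x, double alpha, double lam) {
  return -alpha * (std::cosh(x) - 1.0) - lam * (std::exp(x) - x - 1.0);
}
static double gig_dpsi(double x, double alpha, double lam) {
  return -alpha * std::sinh(x) - lam * (std::exp(x) - 1.0);
}
static double rgig_two_param(double lam, double omega) {
  double alpha = std::sqrt(omega * omega + lam * lam) - lam;
  double t = 1.0, s = 1.0;
  double v = -gig_psi(1.0, alpha, lam);
  if (v > 2.0) {
    t = std::sqrt(2.0 / (alpha + lam));
  } else if (v < 0.5) {
    t = std::log(4.0 / (alpha + 2.0 * lam));
  }
  v = -gig_psi(-1.0, alpha, lam);
  if (v > 2.0) {
    s = std::sqrt(4.0 / (alpha * std::cosh(1.0) + lam));
  } else if (v < 0.5) {
    double term = std::log(1.0 + 1.0 / alpha +
                           std::sqrt(1.0 / (alpha * alpha) + 2.0 / alpha));
    s = (lam > 0.0) ? std::min(1.0 / lam, term) : term;
  }
  double eta = -gig_psi(t, alpha, lam);
  double zeta = -gig_dpsi(t, alpha, lam);
  double theta = -gig_psi(-s, alpha, lam);
  double xi = gig_dpsi(-s, alpha, lam);
  double p = 1.0 / xi, r = 1.0 / zeta;
  double td = t - r * eta, sd = s - p * theta;
  double q = td + sd;
  double X = 0.0;
  for (int tries = 0; tries < 10000; ++tries) {
    double U = unif_rand(), V = unif_rand(), W = unif_rand();
    if (U < q / (p + q + r)) {
      X = -sd + q * V;
    } else if (U < (q + r) / (p + q + r)) {
      X = td - r * std::log(V);
    } else {
      X = -sd + p * std::log(V);
    }
    double env;
    if (X >= -sd && X <= td) env = 1.0;
    else if (X > td) env = std::exp(-eta - zeta * (X - t));
    else env = std::exp(-theta + xi * (X + s));
    if (W * env <= std::exp(gig_psi(X, alpha, lam))) break;
  }
  return (lam / omega + std::sqrt(1.0 + lam * lam / (omega * omega))) * std::exp(X);
}

// GIG(p, chi, psi): f(x) ~ x^(p-1) exp(-(chi/x + psi*x)/2).
static double rgig_scalar(double p, double chi, double psi) {
  if (chi < 1e-12) chi = 1e-12;
  if (p >= 0.5 && std::fabs(p - 0.5) < 1e-12) {
    // reciprocal inverse Gaussian shortcut: 1/X ~ IG(sqrt(psi/chi), psi) ... use
    // general identity below instead to keep one code path for p = 1/2 too.
  }
  if (p < 0.0) return 1.0 / rgig_scalar(-p, psi, chi);
  double omega = std::sqrt(chi * psi);
  double scale = std::sqrt(chi / psi);
  return scale * rgig_two_param(p, omega);
}

// Wishart(df, I) via Bartlett; lower-triangular factor times transpose.
static mat rwishart_identity(uword t, double df) {
  mat A(t, t, arma::fill::zeros);
  for (uword i = 0; i < t; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - (double)i));
    for (uword j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  return A * A.t();
}

// Inverse Wishart(S, df): draw W ~ Wishart(df, S^{-1}), return W^{-1}.
static mat r_invwishart(const mat& S, double df) {
  mat L = arma::chol(arma::inv_sympd(arma::symmatu(S)), "lower");
  mat W = L * rwishart_identity(S.n_rows, df) * L.t();
  return arma::inv_sympd(arma::symmatu(W));
}

// Scaled inverse chi-square: nu * S / chisq(nu); prior mean nu*S/(nu-2).
static double r_scinvchisq(double nu, double S) {
  return nu * S / R::rchisq(nu);
}

// N(mean, Prec^{-1}) given upper Cholesky factor U of the precision (U'U = Prec).
static vec rmvnorm_prec_chol(const vec& mean, const mat& U) {
  vec z(mean.n_elem);
  for (uword i = 0; i < z.n_elem; ++i) z(i) = norm_rand();
  return mean + arma::solve(arma::trimatu(U), z);
}

static vec rdirichlet(const vec& shape) {
  vec g(shape.n_elem);
  for (uword i = 0; i < g.n_elem; ++i) g(i) = R::rgamma(shape(i), 1.0);
  double s = arma::accu(g);
  if (s <= 0.0) { g.fill(1.0); s = (double)g.n_elem; }
  return g / s;
}

// Cholesky with diagonal jitter-and-retry for marginally non-PD matrices.
static bool chol_jitter(mat& U, const mat& A, int& n_jitter) {
  mat S = arma::symmatu(A);
  if (arma::chol(U, S)) return true;
  double eps = 1e-8 * std::max(1.0, arma::trace(S) / S.n_rows);
  for (int k = 0; k < 5; ++k) {
    S.diag() += eps;
    ++n_jitter;
    if (arma::chol(U, S)) return true;
    eps *= 10.0;
  }
  return false;
}

// ---------------------------------------------------------------------------
// inclusion-label machinery (shared by the sampler and the exported kernel)

// Log weight of each inclusion label for one locus, with the effect vector
// beta integrated out analytically:
//   Lambda_k = xtx * (D_k R^{-1} D_k) + G^{-1},  mu_k = Lambda_k^{-1} D_k R^{-1} r
//   log w_k  = log Pi_k - 1/2 log|Lambda_k| + 1/2 mu_k' Lambda_k mu_k
// (terms common to all labels drop out).  Also returns mu_k and the upper
// Cholesky factor of Lambda_k for the subsequent draw of beta.
static void label_log_weights(double xtx, const vec& r, const mat& Rinv,
                              const mat& Ginv, const vec& pi,
                              const arma::imat& labels, vec& logw,
                              std::vector<vec>& mus, std::vector<mat>& chols,
                              int& n_jitter) {
  uword z = labels.n_rows, t = labels.n_cols;
  vec Rr = Rinv * r;
  for (uword k = 0; k < z; ++k) {
    vec d = arma::conv_to<vec>::from(labels.row(k).t());
    mat Lambda = xtx * (Rinv % (d * d.t())) + Ginv;
    mat U;
    if (!chol_jitter(U, Lambda, n_jitter))
      stop("singular conditional precision in inclusion-label update");
    vec b = d % Rr;
    // mu = Lambda^{-1} b via the Cholesky factor
    vec mu_k = arma::solve(arma::trimatu(U),
                           arma::solve(arma::trimatl(U.t()), b));
    double logdet = 2.0 * arma::accu(arma::log(U.diag()));
    double quad = arma::dot(b, mu_k);
    logw(k) = (pi(k) > 0.0 ? std::log(pi(k)) : -arma::datum::inf)
              - 0.5 * logdet + 0.5 * quad;
    mus[k] = mu_k;
    chols[k] = U;
    (void)t;
  }
}

// [[Rcpp::export(name = ".label_probs_cpp")]]
arma::vec label_probs_cpp(double xtx, const arma::vec& r, const arma::mat& Rinv,
                          const arma::mat& Ginv, const arma::vec& pi,
                          const arma::imat& labels) {
  uword z = labels.n_rows;
  vec logw(z);
  std::vector<vec> mus(z);
  std::vector<mat> chols(z);
  int n_jitter = 0;
  label_log_weights(xtx, r, Rinv, Ginv, pi, labels, logw, mus, chols, n_jitter);
  vec w = arma::exp(logw - logw.max());
  return w / arma::accu(w);
}

// [[Rcpp::export(name = ".riwish_cpp")]]
arma::mat riwish_cpp(const arma::mat& S, double df) {
  if (df <= (double)S.n_rows - 1.0) stop("inverse-Wishart df too small");
  return r_invwishart(S, df);
}

// [[Rcpp::export(name = ".rscinvchisq_cpp")]]
double rscinvchisq_cpp(double df, double scale) { return r_scinvchisq(df, scale); }

// [[Rcpp::export(name = ".rgig_cpp")]]
double rgig_cpp(double p, double chi, double psi) { return rgig_scalar(p, chi, psi); }

// [[Rcpp::export(name = ".rinvgauss_cpp")]]
double rinvgauss_cpp(double mu, double lambda) { return r_invgauss(mu, lambda); }

// ---------------------------------------------------------------------------
// main sampler

// [[Rcpp::export(name = ".mc_gibbs_cpp")]]
List mc_gibbs_cpp(const arma::mat& X, const arma::mat& Y,
                  const arma::ivec& entry_marker, const arma::ivec& entry_class,
                  const List& class_params, const arma::mat& S_e, double nu_e,
                  const arma::imat& labels, int n_iter, int burn_in, int thin,
                  bool update_mu, bool update_residual, bool update_variances,
                  bool save_effects, int verbose) {
  const uword n = Y.n_rows, t = Y.n_cols, me = entry_marker.n_elem;
  const uword g = class_params.size();
  const uword z = labels.n_rows;

  // unpack class parameters
  std::vector<int> kernel(g);
  std::vector<mat> Sb(g), lapSinv(g);
  std::vector<double> nub(g), lambda(g);
  std::vector<vec> pi(g);
  std::vector<bool> pi_fixed(g);
  for (uword c = 0; c < g; ++c) {
    List cp = class_params[c];
    kernel[c] = as<int>(cp["kernel"]);
    Sb[c] = as<mat>(cp["S_beta"]);
    nub[c] = as<double>(cp["nu_beta"]);
    pi[c] = as<vec>(cp["pi"]);
    pi_fixed[c] = as<bool>(cp["pi_fixed"]);
    lambda[c] = as<double>(cp["lambda"]);
    mat lapS = as<mat>(cp["laplace_scale"]);
    lapSinv[c] = arma::inv_sympd(arma::symmatu(lapS));
  }

  // precompute x'x per marker
  const uword m = X.n_cols;
  vec xtx(m);
  for (uword j = 0; j < m; ++j) xtx(j) = arma::dot(X.col(j), X.col(j));

  // state
  vec mu = arma::conv_to<vec>::from(arma::mean(Y, 0).t());
  if (!update_mu) mu.zeros();
  mat E = Y;
  E.each_row() -= mu.t();
  mat beta(me, t, arma::fill::zeros), alpha(me, t, arma::fill::zeros);
  arma::imat delta(me, t, arma::fill::ones);
  arma::ivec delta_label(me);
  delta_label.fill((int)z - 1);  // all-ones label
  std::vector<mat> Gclass(g);    // kernels 0,3
  arma::cube Glocus(t, t, me);   // kernels 1,2
  vec vlasso(me, arma::fill::ones);
  for (uword c = 0; c < g; ++c) {
    mat Gm = (t == 1) ? mat(1, 1, arma::fill::value(nub[c] * Sb[c](0, 0) / (nub[c] - 2.0)))
                      : Sb[c] / (nub[c] - (double)t - 1.0);
    Gclass[c] = Gm;
  }
  for (uword e = 0; e < me; ++e) Glocus.slice(e) = Gclass[entry_class(e)];
  mat Rres = (t == 1) ? mat(1, 1, arma::fill::value(nu_e * S_e(0, 0) / (nu_e - 2.0)))
                      : S_e / (nu_e - (double)t - 1.0);
  mat Rinv = arma::inv_sympd(arma::symmatu(Rres));
  int n_jitter = 0;

  // accumulators
  int n_keep = n_iter - burn_in;
  if (n_keep <= 0) stop("burn_in must be smaller than the chain length");
  int n_samp = (n_keep + thin - 1) / thin;
  mat sum_alpha(me, t, arma::fill::zeros);
  vec sum_mu(t, arma::fill::zeros);
  mat sum_R(t, t, arma::fill::zeros);
  std::vector<mat> sum_G(g, mat(t, t, arma::fill::zeros));
  std::vector<vec> sum_pi(g, vec(z, arma::fill::zeros));
  arma::cube sum_Glocus(t, t, me, arma::fill::zeros);
  mat samp_Vg(n_samp, t * t), samp_R(n_samp, t * t), samp_h2(n_samp, t);
  mat samp_mu(n_samp, t), samp_pi(n_samp, g * z), samp_G(n_samp, g * t * t);
  mat samp_alpha(save_effects ? n_samp : 0, save_effects ? me * t : 0);
  int kept = 0, isamp = 0;

  std::vector<vec> mus(z);
  std::vector<mat> chols(z);
  vec logw(z);
  std::vector<mat> Gcinv(g);

  for (int iter = 1; iter <= n_iter; ++iter) {
    // --- overall mean, flat prior: mu | E, R ~ N(mu + colMeans(E), R/n)
    if (update_mu) {
      vec mhat = arma::conv_to<vec>::from(arma::mean(E, 0).t());
      mat U;
      if (!chol_jitter(U, Rres / (double)n, n_jitter))
        stop("non-positive-definite residual covariance in mean update");
      vec zdraw(t);
      for (uword i = 0; i < t; ++i) zdraw(i) = norm_rand();
      vec dmu = mhat + U.t() * zdraw;
      mu += dmu;
      E.each_row() -= dmu.t();
    }

    // per-class covariance inverses for kernels 0 and 3
    for (uword c = 0; c < g; ++c) {
      if (kernel[c] == 0 || kernel[c] == 3)
        Gcinv[c] = arma::inv_sympd(arma::symmatu(Gclass[c]));
    }

    // --- marker effects, single site, classes in declared order
    for (uword e = 0; e < me; ++e) {
      uword c = (uword)entry_class(e);
      uword j = (uword)entry_marker(e);
      int ker = kernel[c];
      vec a_old = alpha.row(e).t();
      vec r = E.t() * X.col(j) + xtx(j) * a_old;
      mat Ginv;
      if (ker == 0 || ker == 3) Ginv = Gcinv[c];
      else if (ker == 1 || ker == 2) Ginv = arma::inv_sympd(arma::symmatu(Glocus.slice(e)));
      else Ginv = lapSinv[c] / vlasso(e);

      vec a_new(t);
      if (ker == 2 || ker == 3) {
        label_log_weights(xtx(j), r, Rinv, Ginv, pi[c], labels, logw, mus, chols,
                          n_jitter);
        vec w = arma::exp(logw - logw.max());
        w /= arma::accu(w);
        double u = unif_rand(), acc = 0.0;
        uword k = z - 1;
        for (uword kk = 0; kk < z; ++kk) { acc += w(kk); if (u <= acc) { k = kk; break; } }
        vec b = rmvnorm_prec_chol(mus[k], chols[k]);
        beta.row(e) = b.t();
        for (uword s = 0; s < t; ++s) delta(e, s) = labels(k, s);
        delta_label(e) = (int)k;
        a_new = arma::conv_to<vec>::from(labels.row(k).t()) % b;
      } else {
        mat Lambda = xtx(j) * Rinv + Ginv;
        mat U;
        if (!chol_jitter(U, Lambda, n_jitter))
          stop("singular conditional precision at locus " + std::to_string(j + 1));
        vec b0 = Rinv * r;
        vec mean = arma::solve(arma::trimatu(U),
                               arma::solve(arma::trimatl(U.t()), b0));
        vec b = rmvnorm_prec_chol(mean, U);
        beta.row(e) = b.t();
        delta.row(e).ones();
        delta_label(e) = (int)z - 1;
        a_new = b;
      }
      alpha.row(e) = a_new.t();
      vec da = a_new - a_old;
      if (arma::any(da != 0.0)) E -= X.col(j) * da.t();
    }

    // --- variance components and Pi
    if (update_variances) {
      for (uword c = 0; c < g; ++c) {
        int ker = kernel[c];
        if (ker == 0 || ker == 3) {
          mat SS = Sb[c];
          double cnt = 0.0;
          double ssq = 0.0;
          for (uword e = 0; e < me; ++e) {
            if ((uword)entry_class(e) != c) continue;
            if (ker == 3 && arma::accu(delta.row(e)) == 0) continue;
            if (t == 1) ssq += beta(e, 0) * beta(e, 0);
            else SS += beta.row(e).t() * beta.row(e);
            cnt += 1.0;
          }
          if (t == 1) {
            double s2 = (nub[c] * Sb[c](0, 0) + ssq) / R::rchisq(nub[c] + cnt);
            Gclass[c](0, 0) = s2;
          } else {
            Gclass[c] = r_invwishart(SS, nub[c] + cnt);
          }
        } else if (ker == 1 || ker == 2) {
          for (uword e = 0; e < me; ++e) {
            if ((uword)entry_class(e) != c) continue;
            bool inc = (ker == 1) || arma::accu(delta.row(e)) > 0;
            if (t == 1) {
              double num = nub[c] * Sb[c](0, 0) + (inc ? beta(e, 0) * beta(e, 0) : 0.0);
              Glocus.slice(e)(0, 0) = num / R::rchisq(nub[c] + (inc ? 1.0 : 0.0));
            } else {
              mat SS = Sb[c];
              if (inc) SS += beta.row(e).t() * beta.row(e);
              Glocus.slice(e) = r_invwishart(SS, nub[c] + (inc ? 1.0 : 0.0));
            }
          }
        } else {  // Bayesian LASSO mixing scales
          for (uword e = 0; e < me; ++e) {
            if ((uword)entry_class(e) != c) continue;
            vec b = beta.row(e).t();
            double a = arma::as_scalar(b.t() * lapSinv[c] * b);
            double lam2 = lambda[c] * lambda[c];
            if (t == 1) {
              // 1/v ~ IG(sqrt(lam^2/a), lam^2)
              double av = std::max(a, 1e-12);
              double inv_v = r_invgauss(std::sqrt(lam2 / av), lam2);
              vlasso(e) = 1.0 / std::max(inv_v, 1e-12);
            } else {
              vlasso(e) = rgig_scalar(1.0 - 0.5 * (double)t, a, lam2);
            }
          }
        }
        // Pi | delta ~ Dirichlet(1 + label counts), uniform prior
        if ((ker == 2 || ker == 3) && !pi_fixed[c]) {
          vec shape(z, arma::fill::ones);
          for (uword e = 0; e < me; ++e)
            if ((uword)entry_class(e) == c) shape(delta_label(e)) += 1.0;
          pi[c] = rdirichlet(shape);
        }
      }
    }

    // --- residual covariance
    if (update_residual) {
      if (t == 1) {
        double ssq = arma::accu(E % E);
        Rres(0, 0) = (nu_e * S_e(0, 0) + ssq) / R::rchisq(nu_e + (double)n);
      } else {
        Rres = r_invwishart(S_e + E.t() * E, nu_e + (double)n);
      }
      Rinv = arma::inv_sympd(arma::symmatu(Rres));
    }

    if (!E.is_finite())
      stop("NaN/Inf in residuals at iteration " + std::to_string(iter));

    // periodic exact refresh of the residual bookkeeping
    if (iter % 500 == 0) {
      mat fit(n, t, arma::fill::zeros);
      for (uword e = 0; e < me; ++e)
        fit += X.col((uword)entry_marker(e)) * alpha.row(e);
      E = Y - fit;
      E.each_row() -= mu.t();
    }

    // --- accumulate
    if (iter > burn_in) {
      sum_alpha += alpha;
      sum_mu += mu;
      sum_R += Rres;
      for (uword c = 0; c < g; ++c) { sum_G[c] += Gclass[c]; sum_pi[c] += pi[c]; }
      sum_Glocus += Glocus;
      ++kept;
      if ((iter - burn_in - 1) % thin == 0 && isamp < n_samp) {
        mat gmat = Y - E;
        gmat.each_row() -= mu.t();
        mat Vg = (n > 1) ? mat(arma::cov(gmat)) : mat(t, t, arma::fill::zeros);
        samp_Vg.row(isamp) = arma::vectorise(Vg).t();
        samp_R.row(isamp) = arma::vectorise(Rres).t();
        for (uword s = 0; s < t; ++s)
          samp_h2(isamp, s) = Vg(s, s) / (Vg(s, s) + Rres(s, s));
        samp_mu.row(isamp) = mu.t();
        for (uword c = 0; c < g; ++c) {
          samp_pi.row(isamp).subvec(c * z, (c + 1) * z - 1) = pi[c].t();
          mat Gc;
          if (kernel[c] == 0 || kernel[c] == 3) Gc = Gclass[c];
          else if (kernel[c] == 4) {
            double vbar = 0.0; int cnt = 0;
            for (uword e = 0; e < me; ++e)
              if ((uword)entry_class(e) == c) { vbar += vlasso(e); ++cnt; }
            Gc = (vbar / std::max(cnt, 1)) * arma::inv_sympd(lapSinv[c]);
          } else {
            Gc = mat(t, t, arma::fill::zeros); int cnt = 0;
            for (uword e = 0; e < me; ++e)
              if ((uword)entry_class(e) == c) { Gc += Glocus.slice(e); ++cnt; }
            Gc /= std::max(cnt, 1);
          }
          samp_G.row(isamp).subvec(c * t * t, (c + 1) * t * t - 1) =
            arma::vectorise(Gc).t();
        }
        if (save_effects) samp_alpha.row(isamp) = arma::vectorise(alpha).t();
        ++isamp;
      }
    }
    if (verbose > 0 && iter % verbose == 0) {
      Rcpp::Rcout << "iter " << iter << "/" << n_iter
                  << " resvar[1] = " << Rres(0, 0) << std::endl;
    }
    if (iter % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  // exact residual recomputation for the bookkeeping invariant
  mat fit(n, t, arma::fill::zeros);
  for (uword e = 0; e < me; ++e)
    fit += X.col((uword)entry_marker(e)) * alpha.row(e);
  mat Eexact = Y - fit;
  Eexact.each_row() -= mu.t();
  double drift = arma::abs(E - Eexact).max();

  mat mean_Glocus(me, t * t);
  for (uword e = 0; e < me; ++e)
    mean_Glocus.row(e) = arma::vectorise(sum_Glocus.slice(e) / (double)kept).t();
  List mean_G(g), mean_pi(g);
  for (uword c = 0; c < g; ++c) {
    mean_G[c] = sum_G[c] / (double)kept;
    mean_pi[c] = sum_pi[c] / (double)kept;
  }

  return List::create(
    _["mean_alpha"] = sum_alpha / (double)kept,
    _["mean_mu"] = sum_mu / (double)kept,
    _["mean_R"] = sum_R / (double)kept,
    _["mean_class_cov"] = mean_G,
    _["mean_pi"] = mean_pi,
    _["mean_locus_cov"] = mean_Glocus,
    _["samples"] = List::create(
      _["Vg"] = samp_Vg.rows(0, isamp - 1), _["R"] = samp_R.rows(0, isamp - 1),
      _["h2"] = samp_h2.rows(0, isamp - 1), _["mu"] = samp_mu.rows(0, isamp - 1),
      _["pi"] = samp_pi.rows(0, isamp - 1), _["class_cov"] = samp_G.rows(0, isamp - 1),
      _["alpha"] = save_effects ? samp_alpha.rows(0, isamp - 1) : mat(0, 0)),
    _["final"] = List::create(
      _["alpha"] = alpha, _["beta"] = beta, _["delta"] = delta, _["mu"] = mu,
      _["R"] = Rres, _["residuals"] = E, _["vlasso"] = vlasso),
    _["resid_drift"] = drift,
    _["n_jitter"] = n_jitter,
    _["n_kept"] = kept);
}
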