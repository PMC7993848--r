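// Blocked Gibbs sampler for truncated stick-breaking Dirichlet-process
// mixture profile regression. Cluster labels are updated either from the
// exposure likelihood times the response likelihood (supervised) or from
// the exposure likelihood alone (unsupervised / cut feedback, in which the
// cluster health effects are still refreshed given current memberships).
// Per-exposure binary switches (variable selection) decide whether a
// mixture component's cluster mean is cluster-specific or fixed at the
// common value 0 of the standardized exposures.
//
// All randomness goes through R's RNG (set.seed determinism).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

arma::mat rwish_bartlett(const arma::mat& S, double df) {
  const arma::uword p = S.n_rows;
  arma::mat L = arma::chol(S, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (arma::uword i = 0; i < p; ++i) A(i, i) = std::sqrt(R::rchisq(df - i));
  for (arma::uword i = 1; i < p; ++i)
    for (arma::uword j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  arma::mat LA = L * A;
  return LA * LA.t();
}

arma::vec rmvnorm_prec(const arma::vec& lin, const arma::mat& prec) {
  // draw from N(prec^{-1} lin, prec^{-1})
  arma::mat U = arma::chol(prec);
  arma::vec mean = arma::solve(arma::trimatu(U),
                    arma::solve(arma::trimatl(U.t()), lin));
  arma::vec z(lin.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = R::norm_rand();
  return mean + arma::solve(arma::trimatu(U), z);
}

// log N(x_i | m, Sigma) for all rows, via a lower-Cholesky of Sigma
arma::vec mvn_logdens_rows(const arma::mat& X, const arma::vec& m,
                           const arma::mat& Lchol) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  double logdet = 0.0;
  for (arma::uword j = 0; j < p; ++j) logdet += std::log(Lchol(j, j));
  arma::mat D = X.t();
  D.each_col() -= m;
  arma::mat Z = arma::solve(arma::trimatl(Lchol), D);
  arma::vec q = arma::sum(Z % Z, 0).t();
  return -0.5 * q - logdet - 0.5 * p * std::log(2.0 * M_PI);
}

} // namespace

// [[Rcpp::export]]
List profile_mcmc_cpp(const arma::mat& X, const arma::vec& y,
                      const arma::mat& W, int C, bool supervised,
                      bool varsel, const List& priors,
                      int n_burn, int n_keep, int thin) {
  const arma::uword n = X.n_rows, p = X.n_cols, q = W.n_cols;
  if (n_keep <= 0) stop("n_keep must be positive");
  if (thin < 1) thin = 1;
  if (C < 2) stop("truncation level C must be at least 2");

  const arma::vec nu0 = priors["nu0"];
  const arma::mat Lambda0 = priors["Lambda0"];
  const arma::mat R0 = priors["R0"];
  const double r0 = priors["r0"];
  const double a_alpha = priors["a_alpha"], b_alpha = priors["b_alpha"];
  const double s_theta2 = priors["s_theta2"];
  const double gvar = priors["gamma_var"];
  const double a_sig = priors["a_sig"], b_sig = priors["b_sig"];
  if (r0 < p) stop("Wishart degrees of freedom must be >= p");

  const arma::mat Lambda0inv = arma::inv_sympd(Lambda0);
  const arma::mat R0inv = arma::inv_sympd(R0);
  arma::mat WtW;
  if (q > 0) WtW = W.t() * W;

  RNGScope scope;

  // --- state ---
  arma::ivec z(n);
  int kinit = std::min(C, 5);
  for (arma::uword i = 0; i < n; ++i)
    z(i) = (int)std::floor(R::unif_rand() * kinit);
  arma::vec V(C, arma::fill::value(0.5)); V(C - 1) = 1.0;
  arma::vec psi(C);
  arma::mat mu(p, C);
  std::vector<arma::mat> Sigma(C), Lch(C);
  for (int c = 0; c < C; ++c) {
    // seed cluster means at random exposure profiles (k-means-style start)
    arma::uword i0 = (arma::uword)std::floor(R::unif_rand() * n);
    mu.col(c) = X.row(i0).t();
    Sigma[c] = arma::eye(p, p);
    Lch[c] = arma::eye(p, p);
  }
  arma::vec theta(C, arma::fill::zeros);
  arma::vec gamma(q, arma::fill::zeros);
  double sigma2 = std::max(arma::var(y), 1e-8), alpha = 1.0, omega = 0.5;
  arma::uvec g(p, arma::fill::ones); // selection switches
  if (!varsel) g.fill(1);

  auto masked_mean = [&](int c) {
    arma::vec m = mu.col(c);
    for (arma::uword j = 0; j < p; ++j) if (g(j) == 0) m(j) = 0.0;
    return m;
  };

  const int n_iter = n_burn + n_keep * thin;
  arma::imat z_out(n_keep, n);
  arma::mat theta_out(n_keep, C), g_out(n_keep, p);
  arma::mat gamma_out(n_keep, std::max<arma::uword>(q, 1));
  arma::vec sigma2_out(n_keep), alpha_out(n_keep);
  arma::ivec nocc_out(n_keep);
  int kept = 0, ridge_repairs = 0;

  for (int it = 0; it < n_iter; ++it) {
    // stick weights from current V
    double acc = 0.0;
    for (int c = 0; c < C; ++c) {
      psi(c) = std::exp(std::log(std::max(V(c), 1e-300)) + acc);
      acc += std::log(std::max(1.0 - V(c), 1e-300));
    }

    // --- label update ---
    arma::vec wg = (q > 0) ? arma::vec(W * gamma) : arma::vec(n, arma::fill::zeros);
    arma::mat logw(n, C);
    for (int c = 0; c < C; ++c) {
      arma::vec lx = mvn_logdens_rows(X, masked_mean(c), Lch[c]);
      logw.col(c) = std::log(std::max(psi(c), 1e-300)) + lx;
      if (supervised) {
        arma::vec resid = y - wg - theta(c);
        logw.col(c) += -0.5 * arma::square(resid) / sigma2 -
                       0.5 * std::log(2.0 * M_PI * sigma2);
      }
    }
    for (arma::uword i = 0; i < n; ++i) {
      int best = 0;
      double bv = -std::numeric_limits<double>::infinity();
      for (int c = 0; c < C; ++c) {
        double gv = logw(i, c) - std::log(-std::log(R::unif_rand()));
        if (gv > bv) { bv = gv; best = c; }
      }
      z(i) = best;
    }

    arma::ivec nc(C, arma::fill::zeros);
    for (arma::uword i = 0; i < n; ++i) nc(z(i))++;

    // --- stick variables and concentration ---
    double logsum = 0.0;
    int tail = n;
    for (int c = 0; c < C - 1; ++c) {
      tail -= nc(c);
      V(c) = R::rbeta(1.0 + nc(c), alpha + tail);
      V(c) = std::min(std::max(V(c), 1e-12), 1.0 - 1e-12);
      logsum += std::log(1.0 - V(c));
    }
    V(C - 1) = 1.0;
    alpha = R::rgamma(a_alpha + C - 1, 1.0 / (b_alpha - logsum));

    // --- cluster exposure parameters ---
    for (int c = 0; c < C; ++c) {
      arma::uvec members = arma::find(z == c);
      const int m = (int)members.n_elem;
      if (m == 0) {
        mu.col(c) = nu0 + arma::chol(Lambda0, "lower") *
                    arma::vec(p, arma::fill::none).imbue([]() { return R::norm_rand(); });
        arma::mat Si = rwish_bartlett(R0, r0);
        Sigma[c] = arma::inv_sympd(Si);
      } else {
        arma::mat Xc = X.rows(members);
        arma::mat Siginv = arma::inv_sympd(Sigma[c]);
        arma::mat Dg = arma::eye(p, p);
        for (arma::uword j = 0; j < p; ++j) if (g(j) == 0) Dg(j, j) = 0.0;
        arma::mat M = Dg * Siginv * Dg;
        arma::vec sumx = arma::sum(Xc, 0).t();
        arma::mat prec = Lambda0inv + m * M;
        arma::vec lin = Lambda0inv * nu0 + Dg * Siginv * sumx;
        mu.col(c) = rmvnorm_prec(lin, prec);
        arma::vec mc = masked_mean(c);
        arma::mat D = Xc.t();
        D.each_col() -= mc;
        arma::mat Sc = D * D.t();
        arma::mat scale = arma::inv_sympd(R0inv + Sc);
        arma::mat Si = rwish_bartlett(scale, r0 + m);
        Sigma[c] = arma::inv_sympd(Si);
      }
      arma::mat L;
      if (!arma::chol(L, Sigma[c], "lower")) {
        Sigma[c].diag() += 1e-8;
        ++ridge_repairs;
        if (!arma::chol(L, Sigma[c], "lower"))
          stop("singular cluster covariance after ridge repair");
      }
      Lch[c] = L;
    }

    // --- variable selection switches ---
    if (varsel) {
      for (arma::uword j = 0; j < p; ++j) {
        double ll[2] = {0.0, 0.0};
        for (int s = 0; s < 2; ++s) {
          g(j) = (arma::uword)s;
          for (int c = 0; c < C; ++c) {
            arma::uvec members = arma::find(z == c);
            if (members.n_elem == 0) continue;
            arma::vec lx = mvn_logdens_rows(X.rows(members), masked_mean(c), Lch[c]);
            ll[s] += arma::accu(lx);
          }
        }
        double lo = std::log(omega) - std::log1p(-omega) + ll[1] - ll[0];
        double pr = 1.0 / (1.0 + std::exp(-lo));
        g(j) = (R::unif_rand() < pr) ? 1 : 0;
      }
      int ng = (int)arma::accu(g);
      omega = R::rbeta(1.0 + ng, 1.0 + (double)(p - ng));
      omega = std::min(std::max(omega, 1e-12), 1.0 - 1e-12);
    }

    // --- response side: theta, gamma, sigma2 ---
    for (int c = 0; c < C; ++c) {
      arma::uvec members = arma::find(z == c);
      const int m = (int)members.n_elem;
      if (m == 0) {
        theta(c) = R::norm_rand() * std::sqrt(s_theta2);
      } else {
        double ssum = arma::accu(y.elem(members) - wg.elem(members));
        double prec = m / sigma2 + 1.0 / s_theta2;
        theta(c) = (ssum / sigma2) / prec + R::norm_rand() / std::sqrt(prec);
      }
    }
    arma::vec thz(n);
    for (arma::uword i = 0; i < n; ++i) thz(i) = theta(z(i));
    if (q > 0) {
      arma::mat A = WtW / sigma2;
      A.diag() += 1.0 / gvar;
      gamma = rmvnorm_prec(W.t() * (y - thz) / sigma2, A);
      wg = W * gamma;
    }
    arma::vec resid = y - thz - wg;
    sigma2 = 1.0 / R::rgamma(a_sig + 0.5 * n,
                             1.0 / (b_sig + 0.5 * arma::dot(resid, resid)));

    if (it >= n_burn && ((it - n_burn) % thin == 0) && kept < n_keep) {
      for (arma::uword i = 0; i < n; ++i) z_out(kept, i) = z(i) + 1;
      theta_out.row(kept) = theta.t();
      for (arma::uword j = 0; j < p; ++j) g_out(kept, j) = (double)g(j);
      if (q > 0) gamma_out.row(kept) = gamma.t();
      sigma2_out(kept) = sigma2;
      alpha_out(kept) = alpha;
      nocc_out(kept) = (int)arma::accu(nc > 0);
      ++kept;
    }
  }

  return List::create(
    _["z"] = z_out, _["theta"] = theta_out, _["g"] = g_out,
    _["gamma"] = (q > 0) ? gamma_out : arma::mat(n_keep, 0),
    _["sigma2"] = sigma2_out, _["alpha"] = alpha_out,
    _["n_occupied"] = nocc_out, _["ridge_repairs"] = ridge_repairs);
}

// Co-membership probability matrix S (mean over iterations of the n x n
// same-cluster indicator) and, per iteration, the squared distance of its
// score matrix from S. Returns S, the distances, and the 1-based index of
// the minimizing iteration (earliest wins ties).
// [[Rcpp::export]]
List dahl_scores_cpp(const arma::imat& zdraws) {
  const arma::uword T = zdraws.n_rows, n = zdraws.n_cols;
  arma::mat S(n, n, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t) {
    for (arma::uword i = 0; i < n; ++i) {
      const int zi = zdraws(t, i);
      for (arma::uword j = i; j < n; ++j) {
        if (zdraws(t, j) == zi) S(i, j) += 1.0;
      }
    }
  }
  S /= (double)T;
  S = arma::symmatu(S);
  const double sumS2 = arma::accu(S % S);
  arma::vec dist(T);
  for (arma::uword t = 0; t < T; ++t) {
    double d = sumS2;
    for (arma::uword i = 0; i < n; ++i) {
      const int zi = zdraws(t, i);
      d += (1.0 - 2.0 * S(i, i));
      for (arma::uword j = i + 1; j < n; ++j) {
        if (zdraws(t, j) == zi) d += 2.0 * (1.0 - 2.0 * S(i, j));
      }
    }
    dist(t) = d;
  }
  arma::uword best = dist.index_min();
  return List::create(_["S"] = S, _["dist"] = dist,
                      _["best"] = (int)(best + 1));
}
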