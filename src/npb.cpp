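// Marginal (Polya-urn) Gibbs sampler for Dirichlet-process shrinkage
// regression: each regression coefficient belongs either to an exact zero
// atom or to a cluster sharing one normal-base value. Two independent DP
// blocks (main effects, pairwise interactions) share only the error
// variance and the covariate coefficients.
//
// All randomness goes through R's RNG so set.seed() fully determines runs.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct DPBlock {
  std::vector<arma::uword> cols;  // columns of X in this block
  std::vector<int> lab;           // -1 = zero atom, else cluster index
  std::vector<double> val;        // cluster shared values
  std::vector<int> csize;         // cluster sizes
  double mu, phi2, pi0, alpha;
  // hyperprior parameters
  double a_alpha, b_alpha, a_pi, b_pi, sigma_mu2, a_phi, b_phi;
  bool fix_mu = false, fix_phi2 = false, fix_pi0 = false, fix_alpha = false;
  int nzero() const {
    int n0 = 0;
    for (int l : lab) if (l < 0) ++n0;
    return n0;
  }
};

int sample_log_weights(const std::vector<double>& lw) {
  // Gumbel-max categorical draw from unnormalized log weights
  int best = 0;
  double bestv = -std::numeric_limits<double>::infinity();
  for (size_t k = 0; k < lw.size(); ++k) {
    double g = lw[k] - std::log(-std::log(R::unif_rand()));
    if (g > bestv) { bestv = g; best = (int)k; }
  }
  return best;
}

void drop_cluster(DPBlock& b, int k) {
  int last = (int)b.val.size() - 1;
  if (k != last) {
    b.val[k] = b.val[last];
    b.csize[k] = b.csize[last];
    for (int& l : b.lab) if (l == last) l = k;
  }
  b.val.pop_back();
  b.csize.pop_back();
}

double update_alpha_ew(double alpha, int k, int nitems, double a, double b) {
  // Escobar-West auxiliary update for the DP concentration
  if (nitems <= 0) return R::rgamma(a, 1.0 / b);
  if (k < 1) k = 1;
  double eta = R::rbeta(alpha + 1.0, (double)nitems);
  double denom = b - std::log(eta);
  double odds = (a + k - 1.0) / ((double)nitems * denom);
  double shape = (R::unif_rand() < odds / (1.0 + odds)) ? (a + k) : (a + k - 1.0);
  if (shape <= 0) shape = a;
  return R::rgamma(shape, 1.0 / denom);
}

} // namespace

// [[Rcpp::export]]
List npb_mcmc_cpp(const arma::vec& y, const arma::mat& X,
                  const arma::ivec& block_id, const arma::mat& W,
                  const List& priors, const List& fix,
                  int n_burn, int n_keep, int thin) {
  const arma::uword n = y.n_elem, P = X.n_cols, q = W.n_cols;
  if (n_keep <= 0) stop("n_keep must be positive");
  if (thin < 1) thin = 1;

  // Pre-computations
  arma::vec colnorm2(P);
  for (arma::uword j = 0; j < P; ++j) colnorm2(j) = arma::dot(X.col(j), X.col(j));
  arma::mat WtW;
  if (q > 0) WtW = W.t() * W;

  const double a_sig = priors["a_sig"], b_sig = priors["b_sig"];
  const double gvar = priors["gamma_var"];

  // Two blocks (main = 1, interaction = 2); absent blocks stay empty
  std::vector<DPBlock> blocks(2);
  for (int b = 0; b < 2; ++b) {
    DPBlock& B = blocks[b];
    List pb = priors[b == 0 ? "main" : "interaction"];
    B.a_alpha = pb["a_alpha"]; B.b_alpha = pb["b_alpha"];
    B.a_pi = pb["a_pi"]; B.b_pi = pb["b_pi"];
    B.sigma_mu2 = pb["sigma_mu2"];
    B.a_phi = pb["a_phi"]; B.b_phi = pb["b_phi"];
    B.mu = 0.0; B.phi2 = 1.0; B.pi0 = 0.5; B.alpha = 1.0;
    if (fix.containsElementNamed("mu")) { B.mu = fix["mu"]; B.fix_mu = true; }
    if (fix.containsElementNamed("phi2")) { B.phi2 = fix["phi2"]; B.fix_phi2 = true; }
    if (fix.containsElementNamed("pi0")) { B.pi0 = fix["pi0"]; B.fix_pi0 = true; }
    if (fix.containsElementNamed("alpha")) { B.alpha = fix["alpha"]; B.fix_alpha = true; }
  }
  for (arma::uword j = 0; j < P; ++j) {
    blocks[block_id(j) - 1].cols.push_back(j);
    blocks[block_id(j) - 1].lab.push_back(-1); // start everything at zero
  }

  bool fix_sigma2 = fix.containsElementNamed("sigma2");
  double sigma2 = fix_sigma2 ? (double)fix["sigma2"]
                             : std::max(arma::var(y), 1e-8);
  arma::vec beta(P, arma::fill::zeros);
  arma::vec gamma(q, arma::fill::zeros);
  arma::vec r = y; // residual y - X beta - W gamma

  const int n_iter = n_burn + n_keep * thin;
  arma::mat beta_out(n_keep, P);
  arma::imat lab_out(n_keep, P);
  arma::mat gamma_out(n_keep, std::max<arma::uword>(q, 1));
  arma::vec sigma2_out(n_keep);
  arma::mat hyper_out(n_keep, 8); // mu/phi2/pi0/alpha per block
  int kept = 0;

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    for (int b = 0; b < 2; ++b) {
      DPBlock& B = blocks[b];
      const size_t Pb = B.cols.size();
      if (Pb == 0) continue;

      // (1) reassign each coefficient: zero atom / existing cluster / new
      for (size_t jj = 0; jj < Pb; ++jj) {
        arma::uword j = B.cols[jj];
        if (beta(j) != 0.0) r += X.col(j) * beta(j);
        int old = B.lab[jj];
        if (old >= 0) {
          if (--B.csize[old] == 0) drop_cluster(B, old);
          B.lab[jj] = -1;
        }
        const double s = arma::dot(X.col(j), r);
        const double q2 = colnorm2(j);
        const int K = (int)B.val.size();
        const int n0 = B.nzero() - 1; // excluding j itself
        std::vector<double> lw(K + 2);
        lw[0] = std::log((double)n0 + B.alpha * B.pi0); // zero atom, lik const
        for (int k = 0; k < K; ++k) {
          double v = B.val[k];
          lw[1 + k] = std::log((double)B.csize[k]) +
                      (s * v - 0.5 * q2 * v * v) / sigma2;
        }
        const double phit2 = 1.0 / (q2 / sigma2 + 1.0 / B.phi2);
        const double mut = phit2 * (s / sigma2 + B.mu / B.phi2);
        lw[K + 1] = std::log(B.alpha * (1.0 - B.pi0)) +
                    0.5 * std::log(phit2 / B.phi2) +
                    0.5 * (mut * mut / phit2 - B.mu * B.mu / B.phi2);
        int pick = sample_log_weights(lw);
        if (pick == 0) {
          beta(j) = 0.0; // exact zero
        } else if (pick <= K) {
          int k = pick - 1;
          B.lab[jj] = k;
          ++B.csize[k];
          beta(j) = B.val[k];
          r -= X.col(j) * beta(j);
        } else {
          double v = mut + std::sqrt(phit2) * R::norm_rand();
          B.lab[jj] = (int)B.val.size();
          B.val.push_back(v);
          B.csize.push_back(1);
          beta(j) = v;
          r -= X.col(j) * v;
        }
      }

      // (2) refresh each cluster's shared value (conjugate normal)
      for (int k = 0; k < (int)B.val.size(); ++k) {
        arma::vec Svec(n, arma::fill::zeros);
        for (size_t jj = 0; jj < Pb; ++jj) {
          if (B.lab[jj] == k) Svec += X.col(B.cols[jj]);
        }
        const double SS = arma::dot(Svec, Svec);
        const double old = B.val[k];
        const double Sr = arma::dot(Svec, r) + SS * old;
        const double prec = SS / sigma2 + 1.0 / B.phi2;
        const double mean = (Sr / sigma2 + B.mu / B.phi2) / prec;
        const double v = mean + R::norm_rand() / std::sqrt(prec);
        B.val[k] = v;
        r += Svec * (old - v);
        for (size_t jj = 0; jj < Pb; ++jj) {
          if (B.lab[jj] == k) beta(B.cols[jj]) = v;
        }
      }

      // (3) block hyperparameters
      const int K = (int)B.val.size();
      if (!B.fix_mu) {
        double sum = 0.0;
        for (double v : B.val) sum += v;
        double prec = K / B.phi2 + 1.0 / B.sigma_mu2;
        B.mu = sum / B.phi2 / prec + R::norm_rand() / std::sqrt(prec);
      }
      if (!B.fix_phi2) {
        double ss = 0.0;
        for (double v : B.val) ss += (v - B.mu) * (v - B.mu);
        B.phi2 = 1.0 / R::rgamma(B.a_phi + 0.5 * K, 1.0 / (B.b_phi + 0.5 * ss));
      }
      if (!B.fix_pi0) {
        int n0 = B.nzero();
        B.pi0 = R::rbeta(B.a_pi + n0, B.b_pi + (double)(Pb - n0));
      }
      if (!B.fix_alpha) {
        int kocc = K + (B.nzero() > 0 ? 1 : 0);
        B.alpha = update_alpha_ew(B.alpha, kocc, (int)Pb, B.a_alpha, B.b_alpha);
      }
    }

    // covariate coefficients (conjugate multivariate normal)
    if (q > 0) {
      arma::vec rw = r + W * gamma;
      arma::mat A = WtW / sigma2;
      A.diag() += 1.0 / gvar;
      arma::mat U = arma::chol(A);
      arma::vec mean = arma::solve(arma::trimatu(U),
                       arma::solve(arma::trimatl(U.t()), W.t() * rw / sigma2));
      arma::vec z(q);
      for (arma::uword i = 0; i < q; ++i) z(i) = R::norm_rand();
      gamma = mean + arma::solve(arma::trimatu(U), z);
      r = rw - W * gamma;
    }

    if (!fix_sigma2) {
      double rss = arma::dot(r, r);
      sigma2 = 1.0 / R::rgamma(a_sig + 0.5 * n, 1.0 / (b_sig + 0.5 * rss));
      if (!std::isfinite(sigma2) || sigma2 <= 0) stop("non-finite error variance draw");
    }

    if (it >= n_burn && ((it - n_burn) % thin == 0) && kept < n_keep) {
      beta_out.row(kept) = beta.t();
      for (arma::uword j = 0; j < P; ++j) {
        const DPBlock& B = blocks[block_id(j) - 1];
        size_t jj = 0;
        while (B.cols[jj] != j) ++jj;
        lab_out(kept, j) = B.lab[jj];
      }
      if (q > 0) gamma_out.row(kept) = gamma.t();
      sigma2_out(kept) = sigma2;
      for (int b = 0; b < 2; ++b) {
        hyper_out(kept, 4 * b + 0) = blocks[b].mu;
        hyper_out(kept, 4 * b + 1) = blocks[b].phi2;
        hyper_out(kept, 4 * b + 2) = blocks[b].pi0;
        hyper_out(kept, 4 * b + 3) = blocks[b].alpha;
      }
      ++kept;
    }
  }

  return List::create(
    _["beta"] = beta_out, _["labels"] = lab_out,
    _["gamma"] = (q > 0) ? gamma_out : arma::mat(n_keep, 0),
    _["sigma2"] = sigma2_out, _["hyper"] = hyper_out);
}
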