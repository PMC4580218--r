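// EM core for the binomial admixture model.
//
// Genotypes are alt-allele dosages g_ij in {0,1,2}; missing entries are
// encoded as any negative value (the R wrapper passes -1 for NA and for
// entries masked out during cross-validation).  The per-entry likelihood is
// Binomial(2, p_ij) with p_ij = sum_k q_ik f_kj (constant binomial
// coefficient dropped throughout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double clampp(double p, double delta) {
  if (p < delta) return delta;
  if (p > 1.0 - delta) return 1.0 - delta;
  return p;
}

// Log-likelihood at fixed (Q, F); missing entries skipped.
// [[Rcpp::export(name = ".admix_loglik_cpp")]]
double admix_loglik_cpp(const arma::mat& G, const arma::mat& Q,
                        const arma::mat& F, double delta) {
  const arma::uword n = G.n_rows, m = G.n_cols, K = Q.n_cols;
  double ll = 0.0;
  for (arma::uword j = 0; j < m; ++j) {
    for (arma::uword i = 0; i < n; ++i) {
      const double g = G(i, j);
      if (g < 0) continue;
      double p = 0.0;
      for (arma::uword k = 0; k < K; ++k) p += Q(i, k) * F(k, j);
      p = clampp(p, delta);
      ll += g * std::log(p) + (2.0 - g) * std::log(1.0 - p);
    }
  }
  return ll;
}

// One full EM pass from (Q, F); returns updated matrices and the
// log-likelihood evaluated at the *input* parameters (so the caller sees a
// provably non-decreasing sequence).  fixed[i] != 0 pins row i of Q
// (supervised samples: their ancestry is known and never updated).
// [[Rcpp::export(name = ".admix_em_cpp")]]
List admix_em_cpp(const arma::mat& G, arma::mat Q, arma::mat F,
                  const arma::ivec& fixed, double delta,
                  int max_iter, double tol) {
  const arma::uword n = G.n_rows, m = G.n_cols, K = Q.n_cols;

  // per-sample number of observed loci (for the Q normalizer 2 * m_i)
  arma::vec mobs(n, arma::fill::zeros);
  for (arma::uword j = 0; j < m; ++j)
    for (arma::uword i = 0; i < n; ++i)
      if (G(i, j) >= 0) mobs(i) += 1.0;

  arma::mat Qnum(n, K), A(K, m), B(K, m);
  std::vector<double> llpath;
  llpath.reserve(max_iter);
  double ll_prev = -std::numeric_limits<double>::infinity();
  bool converged = false;
  int iter = 0;

  std::vector<double> w1(K), w0(K);
  for (iter = 0; iter < max_iter; ++iter) {
    Qnum.zeros(); A.zeros(); B.zeros();
    double ll = 0.0;
    for (arma::uword j = 0; j < m; ++j) {
      for (arma::uword i = 0; i < n; ++i) {
        const double g = G(i, j);
        if (g < 0) continue;
        double p = 0.0;
        for (arma::uword k = 0; k < K; ++k) p += Q(i, k) * F(k, j);
        p = clampp(p, delta);
        ll += g * std::log(p) + (2.0 - g) * std::log(1.0 - p);
        const double ip = 1.0 / p, iq = 1.0 / (1.0 - p);
        for (arma::uword k = 0; k < K; ++k) {
          const double a = g * Q(i, k) * F(k, j) * ip;
          const double b = (2.0 - g) * Q(i, k) * (1.0 - F(k, j)) * iq;
          Qnum(i, k) += a + b;
          A(k, j) += a;
          B(k, j) += b;
        }
      }
    }
    llpath.push_back(ll);
    if (iter > 0) {
      const double rel = std::fabs(ll - ll_prev) /
        std::max(1.0, std::fabs(ll_prev));
      if (rel < tol) { converged = true; break; }
    }
    ll_prev = ll;

    // M-step: Q rows (unpinned) and F
    for (arma::uword i = 0; i < n; ++i) {
      if (fixed(i) != 0) continue;
      const double denom = 2.0 * mobs(i);
      double s = 0.0;
      for (arma::uword k = 0; k < K; ++k) { Q(i, k) = Qnum(i, k) / denom; s += Q(i, k); }
      // renormalize against clamp-induced drift
      for (arma::uword k = 0; k < K; ++k) Q(i, k) /= s;
    }
    for (arma::uword j = 0; j < m; ++j)
      for (arma::uword k = 0; k < K; ++k) {
        const double denom = A(k, j) + B(k, j);
        double f = denom > 0 ? A(k, j) / denom : 0.5;
        F(k, j) = clampp(f, delta);
      }
  }

  const double ll_final = admix_loglik_cpp(G, Q, F, delta);
  return List::create(_["Q"] = Q, _["F"] = F,
                      _["loglik"] = ll_final,
                      _["loglik_path"] = NumericVector(llpath.begin(), llpath.end()),
                      _["n_iter"] = (int)llpath.size(),
                      _["converged"] = converged);
}

// Per-sample ancestry-support selection.  A founder whose true contribution
// to a sample is zero sits on the simplex boundary, where its ML estimate is
// positive with probability ~1/2; comparing nested supports by raw
// likelihood can therefore never remove it.  For each unpinned sample the
// components below `thresh` are dropped, a short per-sample EM refit on the
// restricted support (F fixed) is run, and the restricted model is kept iff
// it wins on BIC: 2 * (ll_full - ll_restricted) <= n_dropped * log(m_i).
// [[Rcpp::export(name = ".admix_refine_q_cpp")]]
arma::mat admix_refine_q_cpp(const arma::mat& G, const arma::mat& Q,
                             const arma::mat& F, const arma::ivec& fixed,
                             double thresh, int iters, double delta) {
  const arma::uword n = G.n_rows, m = G.n_cols, K = Q.n_cols;
  arma::mat out = Q;
  arma::vec q(K), qr(K), num(K);
  for (arma::uword i = 0; i < n; ++i) {
    if (fixed(i) != 0) continue;
    q = Q.row(i).t();
    if (q.min() >= thresh) continue;
    // current per-sample loglik
    auto samp_ll = [&](const arma::vec& qq) {
      double ll = 0.0;
      for (arma::uword j = 0; j < m; ++j) {
        const double g = G(i, j);
        if (g < 0) continue;
        double p = clampp(arma::dot(qq, F.col(j)), delta);
        ll += g * std::log(p) + (2.0 - g) * std::log(1.0 - p);
      }
      return ll;
    };
    const double ll_cur = samp_ll(q);
    // restricted support: zero the small components, renormalize
    qr = q;
    int n_dropped = 0;
    for (arma::uword k = 0; k < K; ++k)
      if (qr(k) < thresh) { if (qr(k) > 0) ++n_dropped; qr(k) = 0.0; }
    const double s0 = arma::accu(qr);
    if (s0 <= 0 || n_dropped == 0) continue;
    qr /= s0;
    // short EM on the restricted support (zeros are EM-invariant)
    for (int it = 0; it < iters; ++it) {
      num.zeros();
      double mobs = 0.0;
      for (arma::uword j = 0; j < m; ++j) {
        const double g = G(i, j);
        if (g < 0) continue;
        mobs += 1.0;
        double p = clampp(arma::dot(qr, F.col(j)), delta);
        for (arma::uword k = 0; k < K; ++k) {
          if (qr(k) == 0.0) continue;
          num(k) += g * qr(k) * F(k, j) / p +
            (2.0 - g) * qr(k) * (1.0 - F(k, j)) / (1.0 - p);
        }
      }
      qr = num / (2.0 * mobs);
      qr /= arma::accu(qr);
    }
    double mobs = 0.0;
    for (arma::uword j = 0; j < m; ++j) if (G(i, j) >= 0) mobs += 1.0;
    if (2.0 * (ll_cur - samp_ll(qr)) <= n_dropped * std::log(mobs))
      out.row(i) = qr.t();
  }
  return out;
}

// Expected dosage 2 * p_ij for a set of entries (row, col), 0-based.
// [[Rcpp::export(name = ".admix_expected_dosage_cpp")]]
arma::vec admix_expected_dosage_cpp(const arma::mat& Q, const arma::mat& F,
                                    const arma::uvec& rows,
                                    const arma::uvec& cols) {
  arma::vec out(rows.n_elem);
  const arma::uword K = Q.n_cols;
  for (arma::uword t = 0; t < rows.n_elem; ++t) {
    double p = 0.0;
    for (arma::uword k = 0; k < K; ++k) p += Q(rows(t), k) * F(k, cols(t));
    out(t) = 2.0 * p;
  }
  return out;
}
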