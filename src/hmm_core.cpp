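// Log-domain inference core for the multi-sequence Gaussian HMM.
// Sequences are stacked row-wise; `lengths` gives per-patient lengths.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double logsumexp(const arma::rowvec &v) {
  double m = v.max();
  if (!std::isfinite(m)) return m;
  return m + std::log(arma::sum(arma::exp(v - m)));
}

// Multivariate normal log-densities: n x S matrix.
// [[Rcpp::export]]
arma::mat cpp_gauss_logdens(const arma::mat &X, const arma::mat &means,
                            const arma::cube &covs) {
  const arma::uword n = X.n_rows, K = X.n_cols, S = means.n_rows;
  arma::mat out(n, S);
  const double c0 = -0.5 * (double)K * std::log(2.0 * M_PI);
  for (arma::uword s = 0; s < S; ++s) {
    arma::mat L = arma::chol(covs.slice(s), "lower");
    double logdet = arma::sum(arma::log(L.diag()));
    arma::mat D = X.each_row() - means.row(s);       // n x K
    arma::mat Z = arma::solve(arma::trimatl(L), D.t());  // K x n
    out.col(s) = (c0 - logdet - 0.5 * arma::sum(arma::square(Z), 0).t());
  }
  return out;
}

// Forward-backward over stacked sequences.
// Returns total log-likelihood, posterior state probabilities (gamma),
// summed expected transition counts (xi), and the sum of first-visit gammas.
// [[Rcpp::export]]
List cpp_forward_backward(const arma::mat &logB, const arma::vec &logpi,
                          const arma::mat &logA, const arma::ivec &lengths) {
  const arma::uword S = logB.n_cols;
  arma::mat gamma(logB.n_rows, S, arma::fill::zeros);
  arma::mat xi(S, S, arma::fill::zeros);
  arma::vec gamma1(S, arma::fill::zeros);
  double total = 0.0;

  arma::uword off = 0;
  for (arma::uword q = 0; q < (arma::uword)lengths.n_elem; ++q) {
    const arma::uword T = (arma::uword)lengths(q);
    if (T == 0) continue;
    arma::mat alpha(T, S), beta(T, S);
    alpha.row(0) = logpi.t() + logB.row(off);
    for (arma::uword t = 1; t < T; ++t) {
      for (arma::uword s = 0; s < S; ++s) {
        arma::rowvec prev = alpha.row(t - 1) + logA.col(s).t();
        alpha(t, s) = logsumexp(prev) + logB(off + t, s);
      }
    }
    double ll = logsumexp(alpha.row(T - 1));
    total += ll;

    beta.row(T - 1).zeros();
    for (arma::uword t = T - 1; t-- > 0;) {
      for (arma::uword s = 0; s < S; ++s) {
        arma::rowvec nxt = logA.row(s) + logB.row(off + t + 1) + beta.row(t + 1);
        beta(t, s) = logsumexp(nxt);
      }
    }
    for (arma::uword t = 0; t < T; ++t) {
      arma::rowvec g = alpha.row(t) + beta.row(t) - ll;
      gamma.row(off + t) = arma::exp(g);
    }
    gamma1 += gamma.row(off).t();
    for (arma::uword t = 0; t + 1 < T; ++t) {
      for (arma::uword r = 0; r < S; ++r)
        for (arma::uword s = 0; s < S; ++s)
          xi(r, s) += std::exp(alpha(t, r) + logA(r, s) +
                               logB(off + t + 1, s) + beta(t + 1, s) - ll);
    }
    off += T;
  }
  return List::create(_["loglik"] = total, _["gamma"] = gamma,
                      _["xi"] = xi, _["gamma_first"] = gamma1);
}

// Forward log-likelihood only.
// [[Rcpp::export]]
double cpp_hmm_loglik(const arma::mat &logB, const arma::vec &logpi,
                      const arma::mat &logA, const arma::ivec &lengths) {
  const arma::uword S = logB.n_cols;
  double total = 0.0;
  arma::uword off = 0;
  for (arma::uword q = 0; q < (arma::uword)lengths.n_elem; ++q) {
    const arma::uword T = (arma::uword)lengths(q);
    if (T == 0) continue;
    arma::rowvec alpha = logpi.t() + logB.row(off);
    for (arma::uword t = 1; t < T; ++t) {
      arma::rowvec nxt(S);
      for (arma::uword s = 0; s < S; ++s)
        nxt(s) = logsumexp(alpha + logA.col(s).t()) + logB(off + t, s);
      alpha = nxt;
    }
    total += logsumexp(alpha);
    off += T;
  }
  return total;
}

// Viterbi decoding; ties broken toward the lowest state index.
// [[Rcpp::export]]
IntegerVector cpp_viterbi(const arma::mat &logB, const arma::vec &logpi,
                          const arma::mat &logA, const arma::ivec &lengths) {
  const arma::uword S = logB.n_cols;
  IntegerVector path(logB.n_rows);
  arma::uword off = 0;
  for (arma::uword q = 0; q < (arma::uword)lengths.n_elem; ++q) {
    const arma::uword T = (arma::uword)lengths(q);
    if (T == 0) continue;
    arma::mat delta(T, S);
    arma::umat psi(T, S, arma::fill::zeros);
    delta.row(0) = logpi.t() + logB.row(off);
    for (arma::uword t = 1; t < T; ++t) {
      for (arma::uword s = 0; s < S; ++s) {
        arma::vec cand = delta.row(t - 1).t() + logA.col(s);
        arma::uword best = 0;
        double bv = cand(0);
        for (arma::uword r = 1; r < S; ++r)
          if (cand(r) > bv + 1e-15) { bv = cand(r); best = r; }
        delta(t, s) = bv + logB(off + t, s);
        psi(t, s) = best;
      }
    }
    arma::uword best = 0;
    double bv = delta(T - 1, 0);
    for (arma::uword s = 1; s < S; ++s)
      if (delta(T - 1, s) > bv + 1e-15) { bv = delta(T - 1, s); best = s; }
    path[off + T - 1] = (int)best + 1;
    for (arma::uword t = T - 1; t-- > 0;) {
      best = psi(t + 1, best);
      path[off + t] = (int)best + 1;
    }
    off += T;
  }
  return path;
}
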