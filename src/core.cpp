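// Hot loops for the HMM machinery and synthetic-label generation.
// All samplers draw through R's RNG so set.seed() governs reproducibility.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Scaled forward pass. logobs is T x K (log emission densities), trans is a
// row-stochastic K x K matrix, init a length-K simplex. Returns the scaled
// forward messages (rows sum to 1) and the total log-likelihood.
static double forward_pass(const arma::mat& logobs, const arma::mat& trans,
                           const arma::vec& init, arma::mat& alpha) {
  const arma::uword T = logobs.n_rows, K = logobs.n_cols;
  alpha.set_size(T, K);
  double loglik = 0.0;
  arma::rowvec a(K);
  for (arma::uword t = 0; t < T; ++t) {
    arma::rowvec lo = logobs.row(t);
    double m = lo.max();
    arma::rowvec b = arma::exp(lo - m);
    if (t == 0) {
      a = init.t() % b;
    } else {
      a = (alpha.row(t - 1) * trans) % b;
    }
    double s = arma::accu(a);
    if (!(s > 0.0) || !std::isfinite(s)) {
      // numerical underflow: fall back to the emission-only distribution
      a = b / arma::accu(b);
      s = 1e-300;
    }
    alpha.row(t) = a / s;
    loglik += std::log(s) + m;
  }
  return loglik;
}

// [[Rcpp::export]]
double cpp_forward_loglik(const arma::mat& logobs, const arma::mat& trans,
                          const arma::vec& init) {
  arma::mat alpha;
  return forward_pass(logobs, trans, init, alpha);
}

static int sample_categorical(const arma::rowvec& p) {
  double u = unif_rand() * arma::accu(p);
  double c = 0.0;
  for (arma::uword k = 0; k < p.n_elem; ++k) {
    c += p(k);
    if (u <= c) return (int)k;
  }
  return (int)p.n_elem - 1;
}

// Forward-filter backward-sample: one posterior draw of the state sequence.
// Returns 0-based states, length T.
// [[Rcpp::export]]
IntegerVector cpp_ffbs(const arma::mat& logobs, const arma::mat& trans,
                       const arma::vec& init) {
  const arma::uword T = logobs.n_rows, K = logobs.n_cols;
  arma::mat alpha;
  forward_pass(logobs, trans, init, alpha);
  IntegerVector z(T);
  z[T - 1] = sample_categorical(alpha.row(T - 1));
  for (arma::uword t = T - 1; t-- > 0;) {
    arma::rowvec p = alpha.row(t) % trans.col((arma::uword)z[t + 1]).t();
    double s = arma::accu(p);
    if (!(s > 0.0)) p = alpha.row(t); // degenerate column: ignore transition
    z[t] = sample_categorical(p);
  }
  return z;
}

// Posterior state marginals by forward-backward. Rows sum to 1.
// [[Rcpp::export]]
arma::mat cpp_fb_posterior(const arma::mat& logobs, const arma::mat& trans,
                           const arma::vec& init) {
  const arma::uword T = logobs.n_rows, K = logobs.n_cols;
  arma::mat alpha;
  forward_pass(logobs, trans, init, alpha);
  arma::mat post(T, K);
  arma::rowvec beta(K, arma::fill::ones);
  post.row(T - 1) = alpha.row(T - 1);
  for (arma::uword t = T - 1; t-- > 0;) {
    arma::rowvec lo = logobs.row(t + 1);
    double m = lo.max();
    arma::rowvec b = arma::exp(lo - m) % beta;
    beta = (trans * b.t()).t();
    beta /= arma::accu(beta) > 0 ? arma::accu(beta) : 1.0;
    arma::rowvec g = alpha.row(t) % beta;
    double s = arma::accu(g);
    if (s > 0) post.row(t) = g / s; else post.row(t) = alpha.row(t);
  }
  return post;
}

// Sample a Markov chain of length T (0-based states) from row-stochastic
// trans and initial simplex init.
// [[Rcpp::export]]
IntegerVector cpp_sample_markov(int T, const arma::mat& trans,
                                const arma::vec& init) {
  IntegerVector z(T);
  z[0] = sample_categorical(init.t());
  for (int t = 1; t < T; ++t) {
    z[t] = sample_categorical(trans.row((arma::uword)z[t - 1]));
  }
  return z;
}

// 4-connected component labelling of a logical mask (BFS). Returns an
// integer matrix: 0 = background, components numbered from 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
        for (int d = 0; d < 4; ++d) {
          int ni = ci + di[d], nj = cj + dj[d];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  }
  return lab;
}
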