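// Hot loops of the partialized-connectivity machinery: cross-spectral matrix
// formation, ridge-regularized inversion and pair extraction, plus the
// trial-shuffled permutation null which repeats them per iteration.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Partial coupling values for the requested pairs at every frequency slice.
// A: (trials*tapers) x sources x freqs complex cube (unit-normalized already
// for the PLV variant). pairs: 0-based index pairs. Values clipped to [0,1].
static arma::mat partial_values_core(const arma::cx_cube& A,
                                     const arma::umat& pairs,
                                     const bool imaginary,
                                     const double ridge_scale) {
  const arma::uword n_rows = A.n_rows;
  const arma::uword n_f = A.n_slices;
  const arma::uword n_pairs = pairs.n_rows;
  arma::mat out(n_pairs, n_f);
  for (arma::uword f = 0; f < n_f; ++f) {
    const arma::cx_mat& X = A.slice(f);
    arma::cx_mat C = (X.t() * X) / static_cast<double>(n_rows);
    double ridge = ridge_scale * arma::mean(arma::real(C.diag()));
    C.diag() += ridge;
    arma::cx_mat P;
    if (!arma::inv(P, C)) {
      stop("cross-spectral matrix singular after ridge (frequency slice %d)",
           (int)(f + 1));
    }
    arma::vec d = arma::real(P.diag());
    for (arma::uword k = 0; k < n_pairs; ++k) {
      const arma::uword i = pairs(k, 0), j = pairs(k, 1);
      std::complex<double> K = -P(i, j) / std::sqrt(d(i) * d(j));
      double v = imaginary ? std::abs(K.imag()) : std::abs(K);
      out(k, f) = std::min(std::max(v, 0.0), 1.0);
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_partial_values")]]
arma::mat cpp_partial_values(const arma::cx_cube& A, const arma::umat& pairs,
                             const bool imaginary, const double ridge_scale) {
  return partial_values_core(A, pairs, imaginary, ridge_scale);
}

// Trial-shuffled null: perms is (n_trials x (n_src * n_iter)), 1-based trial
// permutations, one column per (iteration, source) with source fastest.
// Returns pairs x freqs x iterations.
// [[Rcpp::export(name = ".cpp_shuffle_null")]]
arma::cube cpp_shuffle_null(const arma::cx_cube& A, const arma::umat& pairs,
                            const bool imaginary, const double ridge_scale,
                            const arma::umat& perms, const int n_trials,
                            const int n_tapers) {
  const arma::uword n_src = A.n_cols;
  const arma::uword n_rows = A.n_rows;
  const arma::uword n_iter = perms.n_cols / n_src;
  arma::cube out(pairs.n_rows, A.n_slices, n_iter);
  arma::cx_cube A_sh(n_rows, n_src, A.n_slices);
  arma::uvec rows(n_rows);
  for (arma::uword it = 0; it < n_iter; ++it) {
    for (arma::uword s = 0; s < n_src; ++s) {
      const arma::uvec perm = perms.col(it * n_src + s);
      for (int tr = 0; tr < n_trials; ++tr) {
        for (int k = 0; k < n_tapers; ++k) {
          rows(tr * n_tapers + k) = (perm(tr) - 1) * n_tapers + k;
        }
      }
      for (arma::uword f = 0; f < A.n_slices; ++f) {
        const arma::cx_vec src_col = A.slice(f).col(s);
        A_sh.slice(f).col(s) = src_col.elem(rows);
      }
    }
    out.slice(it) = partial_values_core(A_sh, pairs, imaginary, ridge_scale);
  }
  return out;
}
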