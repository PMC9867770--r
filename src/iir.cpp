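#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Direct-form II transposed IIR filter, column-wise over a multichannel
// matrix, with explicit initial/final state. The streaming one-sample step
// and the batch causal filter both call this kernel, so their outputs are
// bit-identical by construction.
//
// b, a: coefficient vectors (a[0] == 1 after normalization in R).
// x: T x C signal matrix. zi: (max(nb,na)-1) x C state matrix.
// [[Rcpp::export]]
Rcpp::List cpp_iir_filter(const arma::vec& b, const arma::vec& a,
                          const arma::mat& x, const arma::mat& z0) {
  const arma::uword n = std::max(b.n_elem, a.n_elem);
  arma::vec bb(n, arma::fill::zeros), aa(n, arma::fill::zeros);
  bb.head(b.n_elem) = b;
  aa.head(a.n_elem) = a;
  const arma::uword T = x.n_rows, C = x.n_cols, ns = n - 1;
  if (z0.n_rows != ns || z0.n_cols != C)
    Rcpp::stop("state matrix has wrong shape");
  arma::mat y(T, C);
  arma::mat z = z0;
  for (arma::uword c = 0; c < C; ++c) {
    for (arma::uword t = 0; t < T; ++t) {
      const double xn = x(t, c);
      const double yn = bb[0] * xn + z(0, c);
      for (arma::uword k = 0; k < ns; ++k) {
        const double znext = (k + 1 < ns) ? z(k + 1, c) : 0.0;
        z(k, c) = bb[k + 1] * xn + znext - aa[k + 1] * yn;
      }
      y(t, c) = yn;
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("zf") = z);
}
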