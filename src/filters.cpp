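// Zero-phase (forward-backward) IIR filtering, direct form I.
// Mirrors the usual filtfilt construction: zero-pad the tail, filter,
// reverse, filter again, reverse, trim.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

static arma::vec iir_filter(const arma::vec& b, const arma::vec& a, const arma::vec& x) {
  const arma::uword n = x.n_elem, nb = b.n_elem, na = a.n_elem;
  arma::vec y(n, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    double acc = 0.0;
    for (arma::uword k = 0; k < nb && k <= i; ++k) acc += b[k] * x[i - k];
    for (arma::uword k = 1; k < na && k <= i; ++k) acc -= a[k] * y[i - k];
    y[i] = acc / a[0];
  }
  return y;
}

// [[Rcpp::export]]
arma::vec iir_filtfilt_cpp(const arma::vec& b, const arma::vec& a, const arma::vec& x) {
  const arma::uword n = x.n_elem;
  const arma::uword pad = 2 * std::max(a.n_elem, b.n_elem);
  arma::vec xp(n + pad, arma::fill::zeros);
  xp.head(n) = x;
  arma::vec f = iir_filter(b, a, xp);
  f = arma::reverse(f);
  f = iir_filter(b, a, f);
  f = arma::reverse(f);
  return f.head(n);
}
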