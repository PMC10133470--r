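// Batched matrix multiply over cube slices: the workhorse behind the
// transformer attention, temporal re-weighting and graph-attention
// aggregation.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// [[Rcpp::export]]
arma::cube bmm_cpp(const arma::cube& A, const arma::cube& B) {
  if (A.n_slices != B.n_slices || A.n_cols != B.n_rows)
    Rcpp::stop("bmm_cpp: conformability failure");
  arma::cube C(A.n_rows, B.n_cols, A.n_slices);
  for (arma::uword i = 0; i < A.n_slices; ++i)
    C.slice(i) = A.slice(i) * B.slice(i);
  return C;
}
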