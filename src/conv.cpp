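// Valid (unpadded, stride-1) 2-D convolution via im2col + GEMM.
// Layout matches the R side: x (C_in, H, W, M) column-major flattened,
// w (C_in, kh, kw, C_out), outputs (C_out, Ho, Wo, M).
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::mat im2col(const arma::vec& x, int cin, int H, int W, int M,
                        int kh, int kw, int Ho, int Wo) {
  arma::mat cols(cin * kh * kw, Ho * Wo * M);
  for (int m = 0; m < M; ++m)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int col = i + Ho * (j + Wo * m);
        double* dst = cols.colptr(col);
        for (int dj = 0; dj < kw; ++dj)
          for (int di = 0; di < kh; ++di) {
            const double* src = x.memptr() + cin * ((i + di) + H * ((j + dj) + W * m));
            std::copy(src, src + cin, dst + cin * (di + kh * dj));
          }
      }
  return cols;
}

// [[Rcpp::export]]
List conv2d_fwd_cpp(const NumericVector& x, const IntegerVector& xdim,
                    const NumericVector& w, const IntegerVector& wdim,
                    const NumericVector& bias) {
  const int cin = xdim[0], H = xdim[1], W = xdim[2], M = xdim[3];
  const int kh = wdim[1], kw = wdim[2], cout = wdim[3];
  const int Ho = H - kh + 1, Wo = W - kw + 1;
  const arma::vec xv(const_cast<double*>(x.begin()), x.size(), false);
  arma::mat cols = im2col(xv, cin, H, W, M, kh, kw, Ho, Wo);
  arma::mat wm(const_cast<double*>(w.begin()), cin * kh * kw, cout, false);
  arma::mat om = cols.t() * wm;              // (Ho*Wo*M, cout)
  om.each_row() += arma::rowvec(const_cast<double*>(bias.begin()), cout, false);
  // rearrange to (cout, Ho, Wo, M)
  NumericVector out(cout * Ho * Wo * M);
  double* op = out.begin();
  for (int c = 0; c < cout; ++c) {
    const double* colc = om.colptr(c);
    for (int r = 0; r < Ho * Wo * M; ++r) op[c + (R_xlen_t)cout * r] = colc[r];
  }
  out.attr("dim") = IntegerVector::create(cout, Ho, Wo, M);
  return List::create(_["out"] = out, _["cols"] = wrap(cols));
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(const NumericVector& dout, const arma::mat& cols,
                    const NumericVector& w, const IntegerVector& wdim,
                    const IntegerVector& xdim) {
  const int cin = xdim[0], H = xdim[1], W = xdim[2], M = xdim[3];
  const int kh = wdim[1], kw = wdim[2], cout = wdim[3];
  const int Ho = H - kh + 1, Wo = W - kw + 1;
  const int P = Ho * Wo * M;
  // dout (cout, Ho, Wo, M) -> (P, cout)
  arma::mat dom(P, cout);
  const double* dp = dout.begin();
  for (int c = 0; c < cout; ++c) {
    double* colc = dom.colptr(c);
    for (int r = 0; r < P; ++r) colc[r] = dp[c + (R_xlen_t)cout * r];
  }
  arma::rowvec db = arma::sum(dom, 0);
  arma::mat dwm = cols * dom;                // (cin*kh*kw, cout)
  arma::mat wm(const_cast<double*>(w.begin()), cin * kh * kw, cout, false);
  arma::mat dcols = wm * dom.t();            // (cin*kh*kw, P)
  // col2im scatter-add
  arma::vec dx(cin * H * W * (R_xlen_t)M, arma::fill::zeros);
  for (int m = 0; m < M; ++m)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int col = i + Ho * (j + Wo * m);
        const double* src = dcols.colptr(col);
        for (int dj = 0; dj < kw; ++dj)
          for (int di = 0; di < kh; ++di) {
            double* dst = dx.memptr() + cin * ((i + di) + H * ((j + dj) + W * m));
            const double* s = src + cin * (di + kh * dj);
            for (int c = 0; c < cin; ++c) dst[c] += s[c];
          }
      }
  NumericVector dxv = wrap(dx);
  dxv.attr("dim") = xdim;
  NumericVector dwv = wrap(arma::vectorise(dwm));
  dwv.attr("dim") = wdim;
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = wrap(arma::vec(db.t())));
}
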