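// im2col / col2im cores for the trainable network profile. The convolution
// itself is a BLAS matrix product on the R side; these kernels only
// rearrange memory. Inputs are H x W x C arrays in column-major layout;
// columns of the patch matrix are ordered (dr fastest, then dc, then
// channel), matching the column-major flattening of a kh x kw x Cin x Cout
// weight array.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static std::vector<double> pad_image(const NumericVector& x, int h, int w,
                                     int c, int pad, int& hp, int& wp) {
  hp = h + 2 * pad;
  wp = w + 2 * pad;
  std::vector<double> xp((size_t)hp * wp * c, 0.0);
  for (int ch = 0; ch < c; ++ch) {
    for (int j = 0; j < w; ++j) {
      const double* src = &x[(size_t)ch * h * w + (size_t)j * h];
      double* dst = &xp[(size_t)ch * hp * wp + (size_t)(j + pad) * hp + pad];
      std::copy(src, src + h, dst);
    }
  }
  return xp;
}

// patch matrix: (ho*wo) x (k*k*cin)
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, IntegerVector xdim, int k, int pad) {
  const int h = xdim[0], wd = xdim[1], cin = xdim[2];
  int hp, wp;
  std::vector<double> xp = pad_image(x, h, wd, cin, pad, hp, wp);
  const int ho = hp - k + 1, wo = wp - k + 1;
  NumericMatrix out(ho * wo, k * k * cin);
  int col = 0;
  for (int ci = 0; ci < cin; ++ci) {
    const double* xp0 = xp.data() + (size_t)ci * hp * wp;
    for (int dc = 0; dc < k; ++dc) {
      for (int dr = 0; dr < k; ++dr, ++col) {
        double* dst = &out[(size_t)col * ho * wo];
        for (int j = 0; j < wo; ++j) {
          const double* src = xp0 + (size_t)(j + dc) * hp + dr;
          std::copy(src, src + ho, dst + (size_t)j * ho);
        }
      }
    }
  }
  return out;
}

// scatter-add the patch-matrix gradient back onto the (padded) input grid
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix dxcol, IntegerVector xdim, int k, int pad) {
  const int h = xdim[0], wd = xdim[1], cin = xdim[2];
  const int hp = h + 2 * pad, wp = wd + 2 * pad;
  const int ho = hp - k + 1, wo = wp - k + 1;
  std::vector<double> dxp((size_t)hp * wp * cin, 0.0);
  int col = 0;
  for (int ci = 0; ci < cin; ++ci) {
    double* dxp0 = dxp.data() + (size_t)ci * hp * wp;
    for (int dc = 0; dc < k; ++dc) {
      for (int dr = 0; dr < k; ++dr, ++col) {
        const double* src = &dxcol[(size_t)col * ho * wo];
        for (int j = 0; j < wo; ++j) {
          double* __restrict dst = dxp0 + (size_t)(j + dc) * hp + dr;
          const double* __restrict s = src + (size_t)j * ho;
          for (int i = 0; i < ho; ++i) dst[i] += s[i];
        }
      }
    }
  }
  NumericVector dx((size_t)h * wd * cin);
  for (int ci = 0; ci < cin; ++ci) {
    for (int j = 0; j < wd; ++j) {
      const double* src = &dxp[(size_t)ci * hp * wp + (size_t)(j + pad) * hp + pad];
      double* dst = &dx[(size_t)ci * h * wd + (size_t)j * h];
      std::copy(src, src + h, dst);
    }
  }
  dx.attr("dim") = IntegerVector::create(h, wd, cin);
  return dx;
}
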