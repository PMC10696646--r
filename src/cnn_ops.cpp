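// Low-level tensor ops for the 2D CNNs: same-padded convolution via im2col +
// BLAS matmul, and 2x2/stride-2 max pooling with argmax caching for backprop.
// Tensors are column-major R arrays with dim (H, W, C, N).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Dims4 {
  int h, w, c, n;
};

Dims4 dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (h, w, c, n)");
  return Dims4{d[0], d[1], d[2], d[3]};
}

inline double at4(const double* p, const Dims4& d, int i, int j, int c, int s) {
  return p[i + d.h * (j + d.w * (c + (long)d.c * s))];
}

inline double& at4(double* p, const Dims4& d, int i, int j, int c, int s) {
  return p[i + d.h * (j + d.w * (c + (long)d.c * s))];
}

// im2col for one sample with TensorFlow-style "same" padding:
// pad_before = (k - 1) / 2 (floor), pad_after = k - 1 - pad_before.
// cols is (kh*kw*cin) x (h*w), column index = i + h*j (output position).
void im2col_same(const double* x, const Dims4& d, int s, int kh, int kw,
                 arma::mat& cols) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int j = 0; j < d.w; ++j) {
    for (int i = 0; i < d.h; ++i) {
      const int col = i + d.h * j;
      double* dst = cols.colptr(col);
      int row = 0;
      for (int c = 0; c < d.c; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          const int jj = j - pw + kj;
          for (int ki = 0; ki < kh; ++ki, ++row) {
            const int ii = i - ph + ki;
            dst[row] = (ii >= 0 && ii < d.h && jj >= 0 && jj < d.w)
                           ? at4(x, d, ii, jj, c, s)
                           : 0.0;
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col_same
void col2im_same(const arma::mat& cols, double* x, const Dims4& d, int s,
                 int kh, int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int j = 0; j < d.w; ++j) {
    for (int i = 0; i < d.h; ++i) {
      const int col = i + d.h * j;
      const double* src = cols.colptr(col);
      int row = 0;
      for (int c = 0; c < d.c; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          const int jj = j - pw + kj;
          for (int ki = 0; ki < kh; ++ki, ++row) {
            const int ii = i - ph + ki;
            if (ii >= 0 && ii < d.h && jj >= 0 && jj < d.w)
              at4(x, d, ii, jj, c, s) += src[row];
          }
        }
      }
    }
  }
}

}  // namespace

// W: (kh*kw*cin) x cout matrix; b: cout. Output (H, W, cout, N), same padding.
// [[Rcpp::export(name = ".cnn_conv_forward")]]
NumericVector cnn_conv_forward(NumericVector x, NumericMatrix w,
                               NumericVector b, int kh, int kw) {
  Dims4 d = dims4(x);
  const int cout = w.ncol();
  if ((int)w.nrow() != kh * kw * d.c) stop("weight shape mismatch");
  NumericVector out((R_xlen_t)d.h * d.w * cout * d.n);
  out.attr("dim") = IntegerVector::create(d.h, d.w, cout, d.n);
  arma::mat Wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat cols(kh * kw * d.c, d.h * d.w);
  for (int s = 0; s < d.n; ++s) {
    im2col_same(x.begin(), d, s, kh, kw, cols);
    arma::mat o = Wm.t() * cols;  // cout x (h*w)
    o.each_col() += arma::vec(b.begin(), cout, false);
    // o(c, i + h*j) -> out[i, j, c, s]
    double* op = out.begin();
    Dims4 od{d.h, d.w, cout, d.n};
    for (int c = 0; c < cout; ++c)
      for (int j = 0; j < d.w; ++j)
        for (int i = 0; i < d.h; ++i)
          at4(op, od, i, j, c, s) = o(c, i + d.h * j);
  }
  return out;
}

// [[Rcpp::export(name = ".cnn_conv_backward")]]
List cnn_conv_backward(NumericVector x, NumericMatrix w, NumericVector dout,
                       int kh, int kw) {
  Dims4 d = dims4(x);
  const int cout = w.ncol();
  Dims4 od{d.h, d.w, cout, d.n};
  arma::mat Wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat dW(w.nrow(), cout, arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  NumericVector dx((R_xlen_t)d.h * d.w * d.c * d.n);
  dx.attr("dim") = IntegerVector::create(d.h, d.w, d.c, d.n);
  arma::mat cols(kh * kw * d.c, d.h * d.w);
  arma::mat dom(cout, d.h * d.w);
  for (int s = 0; s < d.n; ++s) {
    const double* dp = dout.begin();
    for (int c = 0; c < cout; ++c)
      for (int j = 0; j < d.w; ++j)
        for (int i = 0; i < d.h; ++i)
          dom(c, i + d.h * j) = at4(dp, od, i, j, c, s);
    im2col_same(x.begin(), d, s, kh, kw, cols);
    dW += cols * dom.t();
    db += arma::sum(dom, 1);
    arma::mat dcols = Wm * dom;  // (kh*kw*cin) x (h*w)
    col2im_same(dcols, dx.begin(), d, s, kh, kw);
  }
  return List::create(_["dx"] = dx, _["dw"] = wrap(dW), _["db"] = wrap(db));
}

// 2x2 max pool, stride 2, valid. Returns pooled output and 1-based argmax
// linear indices into the input array (for backward).
// [[Rcpp::export(name = ".cnn_maxpool_forward")]]
List cnn_maxpool_forward(NumericVector x) {
  Dims4 d = dims4(x);
  const int oh = d.h / 2, ow = d.w / 2;
  NumericVector out((R_xlen_t)oh * ow * d.c * d.n);
  out.attr("dim") = IntegerVector::create(oh, ow, d.c, d.n);
  IntegerVector amax((R_xlen_t)oh * ow * d.c * d.n);
  amax.attr("dim") = IntegerVector::create(oh, ow, d.c, d.n);
  Dims4 od{oh, ow, d.c, d.n};
  const double* xp = x.begin();
  for (int s = 0; s < d.n; ++s)
    for (int c = 0; c < d.c; ++c)
      for (int j = 0; j < ow; ++j)
        for (int i = 0; i < oh; ++i) {
          double best = -std::numeric_limits<double>::infinity();
          long bidx = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              const int ii = 2 * i + di, jj = 2 * j + dj;
              const long idx = ii + (long)d.h * (jj + (long)d.w * (c + (long)d.c * s));
              if (xp[idx] > best) { best = xp[idx]; bidx = idx; }
            }
          at4(out.begin(), od, i, j, c, s) = best;
          amax[i + (long)oh * (j + (long)ow * (c + (long)d.c * s))] = (int)(bidx + 1);
        }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".cnn_maxpool_backward")]]
NumericVector cnn_maxpool_backward(NumericVector dout, IntegerVector argmax,
                                   IntegerVector in_dim) {
  NumericVector dx((R_xlen_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3]);
  dx.attr("dim") = in_dim;
  const int m = dout.size();
  for (int k = 0; k < m; ++k) dx[argmax[k] - 1] += dout[k];
  return dx;
}
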