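// Compiled primitives: LFSR maximum-length sequences and the convolution /
// max-pooling layers (forward + backward) used by the echo-spectrogram CNN.
// Layout convention for feature maps: column-major R arrays with
// dim = c(H, W, C, N) (height, width, channels, batch).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Fibonacci LFSR over GF(2). taps are 1-based bit positions of the feedback
// polynomial (the register has `order` bits); the output bit is the last bit.
// Returns the +/-1 mapped sequence of length 2^order - 1 (bit 1 -> +1).
// [[Rcpp::export(name = ".lfsr_sequence")]]
NumericVector lfsr_sequence(int order, IntegerVector taps) {
  if (order < 2 || order > 24) stop("order must be in 2..24");
  const long len = (1L << order) - 1L;
  std::vector<int> reg(order, 1);  // all-ones start state
  NumericVector out(len);
  for (long i = 0; i < len; ++i) {
    int outbit = reg[order - 1];
    out[i] = outbit ? 1.0 : -1.0;
    int fb = 0;
    for (int t = 0; t < taps.size(); ++t) fb ^= reg[taps[t] - 1];
    for (int j = order - 1; j > 0; --j) reg[j] = reg[j - 1];
    reg[0] = fb;
  }
  return out;
}

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C,
                             int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// im2col for one sample (valid convolution, stride 1).
// cols: (kh*kw*C) x (Ho*Wo), column p = output position (i + j*Ho).
static void im2col(const double* x, int H, int W, int C, int kh, int kw,
                   arma::mat& cols) {
  int Ho = H - kh + 1, Wo = W - kw + 1;
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < kw; ++dj)
      for (int di = 0; di < kh; ++di) {
        int r = di + kh * (dj + kw * c);
        for (int j = 0; j < Wo; ++j) {
          const double* src = x + (std::size_t)H * (W * c + j + dj) + di;
          double* dst = cols.colptr(j * Ho) + r;
          for (int i = 0; i < Ho; ++i) *(dst + (std::size_t)i * cols.n_rows) =
            src[i];
        }
      }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("input channel mismatch");
  int Ho = H - kh + 1, Wo = W - kw + 1;
  if (Ho < 1 || Wo < 1) stop("input smaller than kernel");
  const std::size_t P = (std::size_t)Ho * Wo, K = (std::size_t)kh * kw * Cin;
  arma::mat Wm(w.begin(), K, Cout, false);
  arma::vec bv(b.begin(), Cout, false);
  NumericVector y(Rcpp::no_init(P * Cout * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  // one im2col over the whole batch, one gemm
  arma::mat cols(K, P * N);
  for (int n = 0; n < N; ++n) {
    arma::mat sub(cols.colptr(P * n), K, P, false, true);
    im2col(x.begin() + (std::size_t)H * W * C * n, H, W, C, kh, kw, sub);
  }
  arma::mat out = cols.t() * Wm;               // (P*N) x Cout
  // out(p + P*n, c) -> y[p + P*(c + Cout*n)]
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c) {
      const double* src = out.colptr(c) + P * n;
      double* dst = y.begin() + P * ((std::size_t)Cout * n + c);
      double bc = bv(c);
      for (std::size_t p = 0; p < P; ++p) dst[p] = src[p] + bc;
    }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = H - kh + 1, Wo = W - kw + 1;
  const std::size_t P = (std::size_t)Ho * Wo, K = (std::size_t)kh * kw * Cin;
  arma::mat Wm(w.begin(), K, Cout, false);
  NumericVector dx(x.size()); dx.attr("dim") = x.attr("dim");
  NumericVector dw(w.size()); dw.attr("dim") = w.attr("dim");
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), K, Cout, false);
  arma::vec dbv(db.begin(), Cout, false);
  arma::mat cols(K, P * N);
  arma::mat dYm(P * N, Cout);                  // rows: p + P*n
  for (int n = 0; n < N; ++n) {
    arma::mat sub(cols.colptr(P * n), K, P, false, true);
    im2col(x.begin() + (std::size_t)H * W * C * n, H, W, C, kh, kw, sub);
    const double* dyp = dy.begin() + P * Cout * n;
    for (int c = 0; c < Cout; ++c) {
      double* dst = dYm.colptr(c) + P * n;
      const double* src = dyp + P * c;
      for (std::size_t p = 0; p < P; ++p) dst[p] = src[p];
    }
  }
  dWm = cols * dYm;                            // K x Cout
  dbv = arma::sum(dYm, 0).t();
  arma::mat dcols = Wm * dYm.t();              // K x (P*N)
  for (int n = 0; n < N; ++n) {
    double* dxp = dx.begin() + (std::size_t)H * W * C * n;
    for (int c = 0; c < C; ++c)
      for (int dj = 0; dj < kw; ++dj)
        for (int di = 0; di < kh; ++di) {
          int r = di + kh * (dj + kw * c);
          for (int j = 0; j < Wo; ++j) {
            double* dst = dxp + (std::size_t)H * (W * c + j + dj) + di;
            const double* src = dcols.colptr(P * n + (std::size_t)j * Ho) + r;
            for (int i = 0; i < Ho; ++i)
              dst[i] += *(src + (std::size_t)i * K);
          }
        }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, int k, int stride) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  int Ho = (H - k) / stride + 1, Wo = (W - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("input smaller than pooling kernel");
  NumericVector y(Rcpp::no_init((std::size_t)Ho * Wo * C * N));
  IntegerVector idx(Rcpp::no_init((std::size_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + (std::size_t)H * W * C * n;
    double* yp = y.begin() + (std::size_t)Ho * Wo * C * n;
    int* ip = idx.begin() + (std::size_t)Ho * Wo * C * n;
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          double best = -std::numeric_limits<double>::infinity();
          long bidx = 0;
          for (int dj = 0; dj < k; ++dj)
            for (int di = 0; di < k; ++di) {
              long off = (std::size_t)H * (W * c + j * stride + dj) +
                i * stride + di;
              if (xp[off] > best) { best = xp[off]; bidx = off; }
            }
          long p = (std::size_t)Ho * Wo * c + (std::size_t)j * Ho + i;
          yp[p] = best; ip[p] = (int)bidx;
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector dy, IntegerVector idx,
                          IntegerVector xdim) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector dx((std::size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  IntegerVector yd = dy.attr("dim");
  std::size_t per = (std::size_t)yd[0] * yd[1] * yd[2];
  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + per * n;
    const int* ip = idx.begin() + per * n;
    double* dxp = dx.begin() + (std::size_t)H * W * C * n;
    for (std::size_t p = 0; p < per; ++p) dxp[ip[p]] += dyp[p];
  }
  return dx;
}
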