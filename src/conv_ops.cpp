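#include <Rcpp.h>
using namespace Rcpp;

// Image tensors are H x W x C x N arrays (R column-major). im2col unrolls
// sliding kh x kw windows into a (oh*ow*N) x (kh*kw*C) matrix whose rows are
// ordered fastest along output height, then output width, then sample, and
// whose columns are ordered fastest along kernel row, kernel column, then
// input channel. Out-of-bounds taps (zero padding) contribute zeros.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad) {
  const int oh = (H + 2 * pad - kh) / stride + 1;
  const int ow = (W + 2 * pad - kw) / stride + 1;
  NumericMatrix out(oh * ow * N, kh * kw * C);
  const double* xp = x.begin();
  for (int ccol = 0; ccol < kh * kw * C; ++ccol) {
    const int ki = ccol % kh;
    const int kj = (ccol / kh) % kw;
    const int c  = ccol / (kh * kw);
    double* col = &out(0, ccol);
    int r = 0;
    for (int n = 0; n < N; ++n) {
      const double* base = xp + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < ow; ++wo) {
        const int wi = wo * stride - pad + kj;
        const bool wok = (wi >= 0 && wi < W);
        for (int ho = 0; ho < oh; ++ho, ++r) {
          const int hi = ho * stride - pad + ki;
          col[r] = (wok && hi >= 0 && hi < H) ? base[hi + (size_t)H * wi] : 0.0;
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add column gradients back onto the input grid.

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad) {
  const int oh = (H + 2 * pad - kh) / stride + 1;
  const int ow = (W + 2 * pad - kw) / stride + 1;
  NumericVector dx((size_t)H * W * C * N);
  double* dxp = dx.begin();
  for (int ccol = 0; ccol < kh * kw * C; ++ccol) {
    const int ki = ccol % kh;
    const int kj = (ccol / kh) % kw;
    const int c  = ccol / (kh * kw);
    const double* col = &cols(0, ccol);
    int r = 0;
    for (int n = 0; n < N; ++n) {
      double* base = dxp + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < ow; ++wo) {
        const int wi = wo * stride - pad + kj;
        const bool wok = (wi >= 0 && wi < W);
        for (int ho = 0; ho < oh; ++ho, ++r) {
          const int hi = ho * stride - pad + ki;
          if (wok && hi >= 0 && hi < H) base[hi + (size_t)H * wi] += col[r];
        }
      }
    }
  }
  return dx;
}

// Max pooling with window clipping at padded borders (padding never wins the
// max). Returns pooled values plus 0-based argmax indices into the input for
// the backward scatter.

// [[Rcpp::export]]
List maxpool_cpp(NumericVector x, int H, int W, int C, int N,
                 int k, int stride, int pad) {
  const int oh = (H + 2 * pad - k) / stride + 1;
  const int ow = (W + 2 * pad - k) / stride + 1;
  NumericVector out((size_t)oh * ow * C * N);
  IntegerVector arg((size_t)oh * ow * C * N);
  const double* xp = x.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < ow; ++wo) {
        for (int ho = 0; ho < oh; ++ho, ++o) {
          double best = R_NegInf;
          size_t besti = 0;
          for (int kj = 0; kj < k; ++kj) {
            const int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int hi = ho * stride - pad + ki;
              if (hi < 0 || hi >= H) continue;
              const size_t idx = off + hi + (size_t)H * wi;
              if (xp[idx] > best) { best = xp[idx]; besti = idx; }
            }
          }
          out[o] = best;
          arg[o] = (int)besti;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(oh, ow, C, N);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bw_cpp(NumericVector grad, IntegerVector argmax, int len) {
  NumericVector dx(len);
  for (R_xlen_t i = 0; i < grad.size(); ++i) dx[argmax[i]] += grad[i];
  return dx;
}

// Box (mean) filter with replicated edges, separable two-pass implementation.

// [[Rcpp::export]]
NumericMatrix meanfilt_cpp(NumericMatrix x, int k) {
  const int H = x.nrow(), W = x.ncol(), r = k / 2;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j) {           // vertical pass
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int di = -r; di <= r; ++di) {
        int ii = i + di;
        if (ii < 0) ii = 0; else if (ii >= H) ii = H - 1;
        s += x(ii, j);
      }
      tmp(i, j) = s / k;
    }
  }
  for (int j = 0; j < W; ++j) {           // horizontal pass
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int dj = -r; dj <= r; ++dj) {
        int jj = j + dj;
        if (jj < 0) jj = 0; else if (jj >= W) jj = W - 1;
        s += tmp(i, jj);
      }
      out(i, j) = s / k;
    }
  }
  return out;
}

// Median filter with replicated edges (nth_element over the k*k window).

// [[Rcpp::export]]
NumericMatrix medfilt_cpp(NumericMatrix x, int k) {
  const int H = x.nrow(), W = x.ncol(), r = k / 2, n = k * k;
  NumericMatrix out(H, W);
  std::vector<double> win(n);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int m = 0;
      for (int dj = -r; dj <= r; ++dj) {
        int jj = j + dj;
        if (jj < 0) jj = 0; else if (jj >= W) jj = W - 1;
        for (int di = -r; di <= r; ++di) {
          int ii = i + di;
          if (ii < 0) ii = 0; else if (ii >= H) ii = H - 1;
          win[m++] = x(ii, jj);
        }
      }
      std::nth_element(win.begin(), win.begin() + n / 2, win.end());
      out(i, j) = win[n / 2];
    }
  }
  return out;
}
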