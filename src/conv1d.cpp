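// Compiled kernels for the dilated convolutional classifier.
//
// Activations for a batch of N length-L spectra are stored column-major as a
// C x (L*N) matrix. A convolution with kernel size k and dilation d sums, over
// kernel offsets s = (j - (k-1)/2) * d, the product W_j times the activation
// shifted by s within each sample (zero padding at sample edges). Each offset
// is computed as one full-width GEMM followed by per-sample shifted
// accumulation, which keeps BLAS calls large and the shift bookkeeping at
// memcpy speed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".conv1dFwd")]]
arma::mat conv1d_fwd(const arma::cube& W, const arma::vec& b,
                     const arma::mat& x, int dil, int L, int N) {
  const int k = W.n_slices;
  const int half = (k - 1) / 2;
  arma::mat out(W.n_rows, x.n_cols, arma::fill::zeros);
  arma::mat tmp;
  for (int j = 0; j < k; ++j) {
    const int s = (j - half) * dil;
    tmp = W.slice(j) * x;  // one GEMM over the whole batch
    const int t0 = std::max(0, -s);
    const int t1 = std::min(L - 1, L - 1 - s);
    if (t0 > t1) continue;
    for (int n = 0; n < N; ++n) {
      const arma::uword o0 = (arma::uword)n * L + t0;
      out.cols(o0, o0 + (t1 - t0)) += tmp.cols(o0 + s, o0 + s + (t1 - t0));
    }
  }
  out.each_col() += b;
  return out;
}

// [[Rcpp::export(name = ".conv1dBwd")]]
Rcpp::List conv1d_bwd(const arma::cube& W, const arma::mat& x,
                      const arma::mat& dout, int dil, int L, int N) {
  const int k = W.n_slices;
  const int half = (k - 1) / 2;
  arma::cube dW(W.n_rows, W.n_cols, k);
  arma::mat dx(x.n_rows, x.n_cols, arma::fill::zeros);
  arma::mat xs(x.n_rows, x.n_cols);
  arma::mat tmp;
  for (int j = 0; j < k; ++j) {
    const int s = (j - half) * dil;
    const int t0 = std::max(0, -s);
    const int t1 = std::min(L - 1, L - 1 - s);
    if (t0 > t1) {
      dW.slice(j).zeros();
      continue;
    }
    // xs = x shifted by s within each sample, zero-padded
    xs.zeros();
    for (int n = 0; n < N; ++n) {
      const arma::uword o0 = (arma::uword)n * L + t0;
      xs.cols(o0, o0 + (t1 - t0)) = x.cols(o0 + s, o0 + s + (t1 - t0));
    }
    dW.slice(j) = dout * xs.t();                 // GEMM, K = L*N
    tmp = W.slice(j).t() * dout;                 // GEMM over the whole batch
    for (int n = 0; n < N; ++n) {
      const arma::uword o0 = (arma::uword)n * L + t0;
      dx.cols(o0 + s, o0 + s + (t1 - t0)) += tmp.cols(o0, o0 + (t1 - t0));
    }
  }
  arma::vec db = arma::sum(dout, 1);
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dx") = dx);
}

// Leaky ReLU (slope 0.01) and its gradient applied to an upstream gradient.

// [[Rcpp::export(name = ".lreluCpp")]]
arma::mat lrelu(const arma::mat& x) {
  arma::mat y = x;
  y.transform([](double v) { return v > 0 ? v : 0.01 * v; });
  return y;
}

// [[Rcpp::export(name = ".dlreluMulCpp")]]
arma::mat dlrelu_mul(const arma::mat& dy, const arma::mat& pre) {
  arma::mat out(dy.n_rows, dy.n_cols);
  const double* p = pre.memptr();
  const double* d = dy.memptr();
  double* o = out.memptr();
  const arma::uword n = dy.n_elem;
  for (arma::uword i = 0; i < n; ++i) o[i] = d[i] * (p[i] > 0 ? 1.0 : 0.01);
  return out;
}

// Max pool with kernel = stride = P along L; returns pooled values and the
// within-window argmax (1-based) for the backward scatter.

// [[Rcpp::export(name = ".poolFwdCpp")]]
Rcpp::List pool_fwd(const arma::mat& x, int P, int L, int N) {
  const int C = x.n_rows;
  const int Lp = L / P;
  arma::mat y(C, (arma::uword)Lp * N);
  arma::imat arg(C, (arma::uword)Lp * N);
  for (int n = 0; n < N; ++n) {
    for (int p = 0; p < Lp; ++p) {
      const arma::uword base = (arma::uword)n * L + (arma::uword)p * P;
      const arma::uword oc = (arma::uword)n * Lp + p;
      for (int c = 0; c < C; ++c) {
        double best = x(c, base);
        int bw = 0;
        for (int w = 1; w < P; ++w) {
          const double v = x(c, base + w);
          if (v > best) { best = v; bw = w; }
        }
        y(c, oc) = best;
        arg(c, oc) = bw + 1;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("arg") = arg,
                            Rcpp::Named("Lp") = Lp);
}

// [[Rcpp::export(name = ".poolBwdCpp")]]
arma::mat pool_bwd(const arma::imat& arg, const arma::mat& dy, int P, int L,
                   int N) {
  const int C = dy.n_rows;
  const int Lp = L / P;
  arma::mat dx(C, (arma::uword)L * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    for (int p = 0; p < Lp; ++p) {
      const arma::uword base = (arma::uword)n * L + (arma::uword)p * P;
      const arma::uword oc = (arma::uword)n * Lp + p;
      for (int c = 0; c < C; ++c) {
        dx(c, base + arg(c, oc) - 1) = dy(c, oc);
      }
    }
  }
  return dx;
}
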