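// Low-level tensor primitives for the encoder/decoder networks.
//
// Activation layout convention ("NHWB matrix form"): a batch of B images of
// size H x W with C channels is a dense matrix with (B*H*W) rows and C
// columns, row index r = h + H*(w + W*b) (0-based). Keeping activations 2-D
// lets every convolution run as one BLAS GEMM on the im2col patch matrix and
// avoids array permutes in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Gather K x K patches (stride 1) into a patch matrix so that
// conv(X, W) == im2col(X) * Wmat with Wmat (KH*KW*C) x K filters,
// patch feature index f = kh + KH*(kw + KW*c). Zero padding `pad` on all
// sides; output spatial size OH = H + 2*pad - KH + 1 (same for W).
// [[Rcpp::export(name = ".cpp_im2col")]]
arma::mat cpp_im2col(const arma::mat& X, int H, int W, int B,
                     int KH, int KW, int pad) {
  const int C = X.n_cols;
  const int OH = H + 2 * pad - KH + 1;
  const int OW = W + 2 * pad - KW + 1;
  arma::mat P(static_cast<size_t>(B) * OH * OW,
              static_cast<size_t>(KH) * KW * C, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      for (int kw = 0; kw < KW; ++kw) {
        for (int kh = 0; kh < KH; ++kh) {
          const size_t f = kh + KH * (kw + KW * c);
          for (int ow = 0; ow < OW; ++ow) {
            const int w = ow + kw - pad;
            if (w < 0 || w >= W) continue;
            for (int oh = 0; oh < OH; ++oh) {
              const int h = oh + kh - pad;
              if (h < 0 || h >= H) continue;
              P(oh + static_cast<size_t>(OH) * (ow + static_cast<size_t>(OW) * b), f) =
                X(h + static_cast<size_t>(H) * (w + static_cast<size_t>(W) * b), c);
            }
          }
        }
      }
    }
  }
  return P;
}

// Adjoint of im2col: scatter-add patch gradients back onto the input grid.
// [[Rcpp::export(name = ".cpp_col2im")]]
arma::mat cpp_col2im(const arma::mat& dP, int H, int W, int C, int B,
                     int KH, int KW, int pad) {
  const int OH = H + 2 * pad - KH + 1;
  const int OW = W + 2 * pad - KW + 1;
  arma::mat dX(static_cast<size_t>(B) * H * W, C, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      for (int kw = 0; kw < KW; ++kw) {
        for (int kh = 0; kh < KH; ++kh) {
          const size_t f = kh + KH * (kw + KW * c);
          for (int ow = 0; ow < OW; ++ow) {
            const int w = ow + kw - pad;
            if (w < 0 || w >= W) continue;
            for (int oh = 0; oh < OH; ++oh) {
              const int h = oh + kh - pad;
              if (h < 0 || h >= H) continue;
              dX(h + static_cast<size_t>(H) * (w + static_cast<size_t>(W) * b), c) +=
                dP(oh + static_cast<size_t>(OH) * (ow + static_cast<size_t>(OW) * b), f);
            }
          }
        }
      }
    }
  }
  return dX;
}

// Fused stride-1 same/valid convolution + bias + ReLU: returns the patch
// matrix (kept for the weight-gradient GEMM) and the rectified activation.
// [[Rcpp::export(name = ".cpp_conv_relu_fw")]]
List cpp_conv_relu_fw(const arma::mat& X, const arma::mat& W,
                      const arma::vec& b, int H, int Wd, int B,
                      int KH, int KW, int pad) {
  arma::mat P = cpp_im2col(X, H, Wd, B, KH, KW, pad);
  arma::mat A = P * W;
  A.each_row() += b.t();
  A.transform([](double v) { return v > 0 ? v : 0.0; });
  return List::create(_["A"] = A, _["P"] = P);
}

// Backward of the fused conv block. dA is the gradient w.r.t. the rectified
// output; A the cached activation (A > 0 marks the active units).
// [[Rcpp::export(name = ".cpp_conv_relu_bw")]]
List cpp_conv_relu_bw(const arma::mat& P, const arma::mat& W,
                      const arma::mat& A, const arma::mat& dA,
                      int H, int Wd, int Cin, int B, int KH, int KW,
                      int pad) {
  arma::mat dZ = dA;
  for (size_t i = 0; i < dZ.n_elem; ++i) if (A(i) <= 0) dZ(i) = 0;
  arma::mat dW = P.t() * dZ;
  arma::vec db = arma::sum(dZ, 0).t();
  arma::mat dX = cpp_col2im(dZ * W.t(), H, Wd, Cin, B, KH, KW, pad);
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}

// 2x2 max pooling, stride 2 (H and W must be even). Returns the pooled
// activation matrix and, per (row, channel), the 1-based source row index of
// the argmax for the backward scatter.
// [[Rcpp::export(name = ".cpp_maxpool2_fw")]]
List cpp_maxpool2_fw(const arma::mat& X, int H, int W, int B) {
  const int C = X.n_cols;
  const int OH = H / 2, OW = W / 2;
  arma::mat out(static_cast<size_t>(B) * OH * OW, C);
  arma::umat idx(static_cast<size_t>(B) * OH * OW, C);
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      for (int ow = 0; ow < OW; ++ow) {
        for (int oh = 0; oh < OH; ++oh) {
          const size_t r = oh + static_cast<size_t>(OH) * (ow + static_cast<size_t>(OW) * b);
          const size_t s00 = (2 * oh)     + static_cast<size_t>(H) * ((2 * ow)     + static_cast<size_t>(W) * b);
          const size_t s10 = s00 + 1;
          const size_t s01 = s00 + H;
          const size_t s11 = s00 + H + 1;
          double best = X(s00, c); size_t bi = s00;
          if (X(s10, c) > best) { best = X(s10, c); bi = s10; }
          if (X(s01, c) > best) { best = X(s01, c); bi = s01; }
          if (X(s11, c) > best) { best = X(s11, c); bi = s11; }
          out(r, c) = best;
          idx(r, c) = bi + 1;  // 1-based for R
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bw")]]
arma::mat cpp_maxpool2_bw(const arma::mat& dOut, const arma::umat& idx,
                          int H, int W, int B) {
  const int C = dOut.n_cols;
  arma::mat dX(static_cast<size_t>(B) * H * W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (size_t r = 0; r < dOut.n_rows; ++r)
      dX(idx(r, c) - 1, c) += dOut(r, c);
  return dX;
}

static inline arma::mat sigm(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// Batched single-direction LSTM over T steps.
// X: cube B x E x T (inputs per step); h0, c0: B x H initial states;
// Wx: E x 4H, Wh: H x 4H, b: length 4H; gate block order [i f g o].
// Returns hidden states Hs (B x H x T) plus the caches needed for BPTT.
// [[Rcpp::export(name = ".cpp_lstm_fw")]]
List cpp_lstm_fw(const arma::cube& X, const arma::mat& h0, const arma::mat& c0,
                 const arma::mat& Wx, const arma::mat& Wh, const arma::vec& b) {
  const int B = X.n_rows, T = X.n_slices;
  const int Hn = h0.n_cols;
  arma::cube Hs(B, Hn, T), Cs(B, Hn, T), G(B, 4 * Hn, T), TanhC(B, Hn, T);
  arma::mat h = h0, c = c0;
  arma::rowvec br = b.t();
  for (int t = 0; t < T; ++t) {
    arma::mat A = X.slice(t) * Wx + h * Wh;
    A.each_row() += br;
    arma::mat i = sigm(A.cols(0, Hn - 1));
    arma::mat f = sigm(A.cols(Hn, 2 * Hn - 1));
    arma::mat g = arma::tanh(A.cols(2 * Hn, 3 * Hn - 1));
    arma::mat o = sigm(A.cols(3 * Hn, 4 * Hn - 1));
    c = f % c + i % g;
    arma::mat tc = arma::tanh(c);
    h = o % tc;
    G.slice(t) = arma::join_rows(i, f, g, o);
    Cs.slice(t) = c;
    TanhC.slice(t) = tc;
    Hs.slice(t) = h;
  }
  return List::create(_["H"] = Hs, _["C"] = Cs, _["G"] = G, _["TanhC"] = TanhC);
}

// BPTT for cpp_lstm_fw. dH: gradient w.r.t. every hidden output (B x H x T).
// Returns gradients for inputs, weights and the initial states (dh0/dc0 feed
// the latent-code projection of the decoder).
// [[Rcpp::export(name = ".cpp_lstm_bw")]]
List cpp_lstm_bw(const arma::cube& X, const arma::mat& h0, const arma::mat& c0,
                 const arma::mat& Wx, const arma::mat& Wh,
                 const arma::cube& Hs, const arma::cube& Cs,
                 const arma::cube& G, const arma::cube& TanhC,
                 const arma::cube& dH) {
  const int B = X.n_rows, E = X.n_cols, T = X.n_slices;
  const int Hn = h0.n_cols;
  arma::cube dX(B, E, T, arma::fill::zeros);
  arma::mat dWx(E, 4 * Hn, arma::fill::zeros), dWh(Hn, 4 * Hn, arma::fill::zeros);
  arma::rowvec db(4 * Hn, arma::fill::zeros);
  arma::mat dh_next(B, Hn, arma::fill::zeros), dc_next(B, Hn, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    arma::mat i = G.slice(t).cols(0, Hn - 1);
    arma::mat f = G.slice(t).cols(Hn, 2 * Hn - 1);
    arma::mat g = G.slice(t).cols(2 * Hn, 3 * Hn - 1);
    arma::mat o = G.slice(t).cols(3 * Hn, 4 * Hn - 1);
    const arma::mat& tc = TanhC.slice(t);
    arma::mat cprev = (t == 0) ? c0 : Cs.slice(t - 1);
    arma::mat hprev = (t == 0) ? h0 : Hs.slice(t - 1);

    arma::mat dh = dH.slice(t) + dh_next;
    arma::mat dc = dc_next + dh % o % (1.0 - tc % tc);
    arma::mat da_o = (dh % tc) % o % (1.0 - o);
    arma::mat da_i = (dc % g) % i % (1.0 - i);
    arma::mat da_g = (dc % i) % (1.0 - g % g);
    arma::mat da_f = (dc % cprev) % f % (1.0 - f);
    arma::mat dA = arma::join_rows(da_i, da_f, da_g, da_o);

    dX.slice(t) = dA * Wx.t();
    dh_next = dA * Wh.t();
    dc_next = dc % f;
    dWx += X.slice(t).t() * dA;
    dWh += hprev.t() * dA;
    db += arma::sum(dA, 0);
  }
  return List::create(_["dX"] = dX, _["dWx"] = dWx, _["dWh"] = dWh,
                      _["db"] = db.t(), _["dh0"] = dh_next, _["dc0"] = dc_next);
}
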