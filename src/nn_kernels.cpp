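// Dense kernels for the sequence regressors: 1-D convolution, multi-head
// self-attention and LSTM recurrence, each with an analytic backward pass.
//
// Layout convention: a batch of sequences is an arma::cube with dims
// (L, C, B) -- slice b is the L x C matrix of sequence b -- except the LSTM,
// which takes (B, C, T) so each time step is a contiguous B x C matrix.
// All dense projections are batched into single large GEMMs over matrices
// stacked across the batch ((B*L) x C); only the attention score products
// and the LSTM recurrence run per sequence / per step.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_len(int L, int k, int stride, int dil, int padL, int padR) {
  return (L + padL + padR - ((k - 1) * dil + 1)) / stride + 1;
}

// Stack cube slices vertically: (L, C, B) -> (B*L, C), block b = slice b.
static arma::mat stack_cube(const arma::cube& x) {
  const int L = x.n_rows, C = x.n_cols, B = x.n_slices;
  arma::mat out(B * L, C);
  for (int b = 0; b < B; ++b) out.rows(b * L, b * L + L - 1) = x.slice(b);
  return out;
}

static arma::cube unstack_mat(const arma::mat& m, int L, int B) {
  arma::cube out(L, m.n_cols, B);
  for (int b = 0; b < B; ++b) out.slice(b) = m.rows(b * L, b * L + L - 1);
  return out;
}

// Batched im2col: rows = (b, t), cols = (tap j, channel c) as j*Cin + c,
// matching the weight matrix row order.
static arma::mat im2col_all(const arma::cube& x, int k, int stride, int dil,
                            int padL, int Lout) {
  const int L = x.n_rows, Cin = x.n_cols, B = x.n_slices;
  arma::mat col(B * Lout, k * Cin, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const arma::mat& xs = x.slice(b);
    for (int j = 0; j < k; ++j) {
      for (int t = 0; t < Lout; ++t) {
        int p = t * stride + j * dil - padL;
        if (p >= 0 && p < L)
          col(b * Lout + t, arma::span(j * Cin, j * Cin + Cin - 1)) = xs.row(p);
      }
    }
  }
  return col;
}

// [[Rcpp::export(name = ".conv1d_fwd")]]
arma::cube conv1d_fwd(const arma::cube& x, const arma::mat& W,
                      const arma::vec& b, int k, int stride, int dil,
                      int padL, int padR) {
  const int L = x.n_rows, B = x.n_slices;
  const int Lout = out_len(L, k, stride, dil, padL, padR);
  arma::mat col = im2col_all(x, k, stride, dil, padL, Lout);
  arma::mat y = col * W;
  y.each_row() += b.t();
  return unstack_mat(y, Lout, B);
}

// [[Rcpp::export(name = ".conv1d_bwd")]]
List conv1d_bwd(const arma::cube& x, const arma::mat& W, const arma::cube& dY,
                int k, int stride, int dil, int padL, int padR) {
  const int L = x.n_rows, Cin = x.n_cols, B = x.n_slices;
  const int Lout = dY.n_rows;
  arma::mat col = im2col_all(x, k, stride, dil, padL, Lout);
  arma::mat dYs = stack_cube(dY);
  arma::mat dW = col.t() * dYs;
  arma::vec db = arma::sum(dYs, 0).t();
  arma::mat dcol = dYs * W.t();                  // (B*Lout) x (k*Cin)
  arma::cube dx(L, Cin, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    arma::mat& dxs = dx.slice(b);
    for (int j = 0; j < k; ++j) {
      for (int t = 0; t < Lout; ++t) {
        int p = t * stride + j * dil - padL;
        if (p >= 0 && p < L)
          dxs.row(p) += dcol(b * Lout + t, arma::span(j * Cin, j * Cin + Cin - 1));
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

static inline arma::mat softmax_rows(arma::mat S) {
  S.each_col() -= arma::max(S, 1);
  S = arma::exp(S);
  S.each_col() /= arma::sum(S, 1);
  return S;
}

// Multi-head self-attention. Wq/Wk/Wv: C x (N*w); Wm: (N*w) x C. Softmax
// logits are scaled by 1/sqrt(scale_d); the FIT convention sets scale_d to
// the block channel width C. Q/K/V are returned stacked ((B*L) x N*w) and
// handed back to the backward pass.
// [[Rcpp::export(name = ".mha_fwd")]]
List mha_fwd(const arma::cube& x, const arma::mat& Wq, const arma::vec& bq,
             const arma::mat& Wk, const arma::vec& bk, const arma::mat& Wv,
             const arma::vec& bv, const arma::mat& Wm, const arma::vec& bm,
             int heads, double scale_d) {
  const int L = x.n_rows, B = x.n_slices, P = Wq.n_cols;
  const int w = P / heads;
  const double inv = 1.0 / std::sqrt(scale_d);
  arma::mat X = stack_cube(x);
  arma::mat Q = X * Wq; Q.each_row() += bq.t();
  arma::mat K = X * Wk; K.each_row() += bk.t();
  arma::mat V = X * Wv; V.each_row() += bv.t();
  arma::mat H(B * L, P);
  for (int b = 0; b < B; ++b) {
    arma::span rs(b * L, b * L + L - 1);
    for (int h = 0; h < heads; ++h) {
      arma::span cs(h * w, h * w + w - 1);
      arma::mat S = softmax_rows(Q(rs, cs) * K(rs, cs).t() * inv);
      H(rs, cs) = S * V(rs, cs);
    }
  }
  arma::mat out = H * Wm;
  out.each_row() += bm.t();
  return List::create(_["out"] = unstack_mat(out, L, B),
                      _["Q"] = Q, _["K"] = K, _["V"] = V);
}

// [[Rcpp::export(name = ".mha_bwd")]]
List mha_bwd(const arma::cube& x, const arma::mat& Wq, const arma::mat& Wk,
             const arma::mat& Wv, const arma::mat& Wm, const arma::mat& Q,
             const arma::mat& K, const arma::mat& V, const arma::cube& dOut,
             int heads, double scale_d) {
  const int L = x.n_rows, B = x.n_slices, P = Wq.n_cols;
  const int w = P / heads;
  const double inv = 1.0 / std::sqrt(scale_d);
  arma::mat X = stack_cube(x);
  arma::mat dO = stack_cube(dOut);
  arma::mat dH = dO * Wm.t();
  arma::mat H(B * L, P), dQ(B * L, P), dK(B * L, P), dV(B * L, P);
  for (int b = 0; b < B; ++b) {
    arma::span rs(b * L, b * L + L - 1);
    for (int h = 0; h < heads; ++h) {
      arma::span cs(h * w, h * w + w - 1);
      const auto Qi = Q(rs, cs);
      const auto Ki = K(rs, cs);
      const auto Vi = V(rs, cs);
      arma::mat S = softmax_rows(Qi * Ki.t() * inv);
      H(rs, cs) = S * Vi;
      const auto dHi = dH(rs, cs);
      arma::mat dS = dHi * Vi.t();
      dV(rs, cs) = S.t() * dHi;
      arma::vec rowsum = arma::sum(dS % S, 1);   // before mutating dS
      dS.each_col() -= rowsum;
      dS %= S;                                   // now dS = dSraw
      dQ(rs, cs) = dS * Ki * inv;
      dK(rs, cs) = dS.t() * Qi * inv;
    }
  }
  arma::mat dx = dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
  return List::create(
      _["dx"] = unstack_mat(dx, L, B),
      _["dWq"] = X.t() * dQ, _["dbq"] = arma::sum(dQ, 0).t(),
      _["dWk"] = X.t() * dK, _["dbk"] = arma::sum(dK, 0).t(),
      _["dWv"] = X.t() * dV, _["dbv"] = arma::sum(dV, 0).t(),
      _["dWm"] = H.t() * dO, _["dbm"] = arma::sum(dO, 0).t());
}

// [[Rcpp::export(name = ".stack3")]]
arma::mat stack3(const arma::cube& x) { return stack_cube(x); }

// [[Rcpp::export(name = ".unstack3")]]
arma::cube unstack3(const arma::mat& m, int L, int B) {
  return unstack_mat(m, L, B);
}

// Add a row vector to every row of a matrix (bias broadcast).
// [[Rcpp::export(name = ".addrow")]]
arma::mat addrow(arma::mat m, const arma::vec& v) {
  m.each_row() += v.t();
  return m;
}

// Fused X %*% W + bias (one conversion of the small input instead of a
// round trip of the large product).
// [[Rcpp::export(name = ".linbias")]]
arma::mat linbias(const arma::mat& X, const arma::mat& W, const arma::vec& b) {
  arma::mat y = X * W;
  y.each_row() += b.t();
  return y;
}

// GELU, tanh form: 0.5 x (1 + tanh(sqrt(2/pi) (x + 0.044715 x^3))).
// The forward pass returns the tanh term so the backward pass is free of
// transcendental calls.
static const double GELU_S = 0.7978845608028654;
static const double GELU_A = 0.044715;

// [[Rcpp::export(name = ".gelu_fwd")]]
List gelu_fwd(NumericVector x) {
  NumericVector y(x.size()), th(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = x[i];
    double t = std::tanh(GELU_S * (v + GELU_A * v * v * v));
    th[i] = t;
    y[i] = 0.5 * v * (1.0 + t);
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["th"] = th);
}

// [[Rcpp::export(name = ".gelu_bwd")]]
NumericVector gelu_bwd(NumericVector x, NumericVector th, NumericVector dy) {
  NumericVector dx(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = x[i], t = th[i];
    double d = 0.5 * (1.0 + t) +
      0.5 * v * (1.0 - t * t) * GELU_S * (1.0 + 3.0 * GELU_A * v * v);
    dx[i] = dy[i] * d;
  }
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// Batch norm over (position, batch) per channel of an (L, C, B) cube.
// [[Rcpp::export(name = ".bn_fwd")]]
List bn_fwd_cpp(const arma::cube& x, const arma::vec& gamma,
                const arma::vec& beta, const arma::vec& rmean,
                const arma::vec& rvar, bool training, double momentum,
                double eps) {
  const int L = x.n_rows, C = x.n_cols, B = x.n_slices;
  arma::vec mu(C), v(C);
  if (training) {
    mu.zeros(); v.zeros();
    for (int b = 0; b < B; ++b) {
      mu += arma::sum(x.slice(b), 0).t();
      v += arma::sum(arma::square(x.slice(b)), 0).t();
    }
    mu /= double(L) * B;
    v = v / (double(L) * B) - arma::square(mu);
    v = arma::clamp(v, 0.0, arma::datum::inf);
  } else {
    mu = rmean; v = rvar;
  }
  arma::vec invsd = 1.0 / arma::sqrt(v + eps);
  arma::cube xhat(L, C, B), y(L, C, B);
  for (int b = 0; b < B; ++b) {
    arma::mat xh = x.slice(b);
    xh.each_row() -= mu.t();
    xh.each_row() %= invsd.t();
    xhat.slice(b) = xh;
    xh.each_row() %= gamma.t();
    xh.each_row() += beta.t();
    y.slice(b) = xh;
  }
  arma::vec new_rmean = rmean, new_rvar = rvar;
  if (training) {
    new_rmean = (1.0 - momentum) * rmean + momentum * mu;
    new_rvar = (1.0 - momentum) * rvar + momentum * v;
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invsd"] = invsd,
                      _["rmean"] = new_rmean, _["rvar"] = new_rvar);
}

// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd_cpp(const arma::cube& xhat, const arma::vec& invsd,
                const arma::vec& gamma, const arma::cube& dy) {
  const int L = dy.n_rows, C = dy.n_cols, B = dy.n_slices;
  const double M = double(L) * B;
  arma::vec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    dgamma += arma::sum(dy.slice(b) % xhat.slice(b), 0).t();
    dbeta += arma::sum(dy.slice(b), 0).t();
  }
  // dxhat = dy * gamma; fold the per-channel sums into one pass
  arma::vec s1 = dbeta % gamma;          // sum of dxhat per channel
  arma::vec s2 = dgamma % gamma;         // sum of dxhat * xhat per channel
  arma::cube dx(L, C, B);
  arma::rowvec scale = (invsd / M).t();
  for (int b = 0; b < B; ++b) {
    arma::mat t = M * dy.slice(b);
    t.each_row() %= gamma.t();
    t.each_row() -= s1.t();
    t -= xhat.slice(b).each_row() % s2.t();
    t.each_row() %= scale;
    dx.slice(b) = t;
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Layer norm over the channel axis of an (L, C, B) cube.
// [[Rcpp::export(name = ".ln_fwd")]]
List ln_fwd(const arma::cube& x, const arma::vec& gamma, const arma::vec& beta,
            double eps) {
  const int L = x.n_rows, C = x.n_cols, B = x.n_slices;
  arma::cube xhat(L, C, B), y(L, C, B);
  arma::mat invsd(L, B);
  for (int b = 0; b < B; ++b) {
    const arma::mat& xs = x.slice(b);
    arma::vec mu = arma::mean(xs, 1);
    arma::vec v = arma::mean(arma::square(xs), 1) - arma::square(mu);
    arma::vec is = 1.0 / arma::sqrt(arma::clamp(v, 0.0, arma::datum::inf) + eps);
    invsd.col(b) = is;
    arma::mat xh = xs;
    xh.each_col() -= mu;
    xh.each_col() %= is;
    xhat.slice(b) = xh;
    xh.each_row() %= gamma.t();
    xh.each_row() += beta.t();
    y.slice(b) = xh;
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invsd"] = invsd);
}

// [[Rcpp::export(name = ".ln_bwd")]]
List ln_bwd(const arma::cube& xhat, const arma::mat& invsd,
            const arma::vec& gamma, const arma::cube& dy) {
  const int L = dy.n_rows, C = dy.n_cols, B = dy.n_slices;
  arma::cube dx(L, C, B);
  arma::vec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const arma::mat& dys = dy.slice(b);
    const arma::mat& xh = xhat.slice(b);
    dgamma += arma::sum(dys % xh, 0).t();
    dbeta += arma::sum(dys, 0).t();
    arma::mat dxh = dys;
    dxh.each_row() %= gamma.t();
    arma::vec s1 = arma::sum(dxh, 1);
    arma::vec s2 = arma::sum(dxh % xh, 1);
    arma::mat out = double(C) * dxh;
    out.each_col() -= s1;
    out -= xh.each_col() % s2;
    out.each_col() %= invsd.col(b) / double(C);
    dx.slice(b) = out;
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Single LSTM layer over a (B, Cin, T) cube. Gate order [i, f, g, o].
// Returns the full hidden state sequence (B, h, T) plus caches for BPTT.
// [[Rcpp::export(name = ".lstm_fwd")]]
List lstm_fwd(const arma::cube& x, const arma::mat& Wx, const arma::mat& Wh,
              const arma::vec& b) {
  const int B = x.n_rows, T = x.n_slices, hidden = Wh.n_rows;
  arma::cube Hc(B, hidden, T), Cc(B, hidden, T), Ic(B, hidden, T),
             Fc(B, hidden, T), Gc(B, hidden, T), Oc(B, hidden, T);
  arma::mat XW = stack_cube(x) * Wx;             // (T*B) x 4h, block t = step t
  XW.each_row() += b.t();
  arma::mat h(B, hidden, arma::fill::zeros), c(B, hidden, arma::fill::zeros);
  arma::span si(0, hidden - 1), sf(hidden, 2 * hidden - 1),
             sg(2 * hidden, 3 * hidden - 1), so(3 * hidden, 4 * hidden - 1);
  for (int t = 0; t < T; ++t) {
    arma::mat A = XW.rows(t * B, t * B + B - 1) + h * Wh;
    arma::mat i = 1.0 / (1.0 + arma::exp(-A.cols(si)));
    arma::mat f = 1.0 / (1.0 + arma::exp(-A.cols(sf)));
    arma::mat g = arma::tanh(A.cols(sg));
    arma::mat o = 1.0 / (1.0 + arma::exp(-A.cols(so)));
    c = f % c + i % g;
    h = o % arma::tanh(c);
    Ic.slice(t) = i; Fc.slice(t) = f; Gc.slice(t) = g; Oc.slice(t) = o;
    Cc.slice(t) = c; Hc.slice(t) = h;
  }
  return List::create(_["H"] = Hc, _["C"] = Cc, _["I"] = Ic, _["F"] = Fc,
                      _["G"] = Gc, _["O"] = Oc);
}

// [[Rcpp::export(name = ".lstm_bwd")]]
List lstm_bwd(const arma::cube& x, const arma::mat& Wx, const arma::mat& Wh,
              const arma::cube& Hc, const arma::cube& Cc, const arma::cube& Ic,
              const arma::cube& Fc, const arma::cube& Gc, const arma::cube& Oc,
              const arma::cube& dH) {
  const int B = x.n_rows, Cin = x.n_cols, T = x.n_slices, hidden = Wh.n_rows;
  arma::mat dA_all(T * B, 4 * hidden);
  arma::mat dWh(hidden, 4 * hidden, arma::fill::zeros);
  arma::mat dh_carry(B, hidden, arma::fill::zeros),
            dc_carry(B, hidden, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    const arma::mat &i = Ic.slice(t), &f = Fc.slice(t), &g = Gc.slice(t),
                    &o = Oc.slice(t), &c = Cc.slice(t);
    arma::mat tc = arma::tanh(c);
    arma::mat dh = dH.slice(t) + dh_carry;
    arma::mat dc = dh % o % (1.0 - tc % tc) + dc_carry;
    arma::mat cprev = (t > 0) ? arma::mat(Cc.slice(t - 1))
                              : arma::mat(B, hidden, arma::fill::zeros);
    arma::mat dA(B, 4 * hidden);
    dA.cols(0, hidden - 1)              = dc % g % i % (1.0 - i);
    dA.cols(hidden, 2 * hidden - 1)     = dc % cprev % f % (1.0 - f);
    dA.cols(2 * hidden, 3 * hidden - 1) = dc % i % (1.0 - g % g);
    dA.cols(3 * hidden, 4 * hidden - 1) = dh % tc % o % (1.0 - o);
    dA_all.rows(t * B, t * B + B - 1) = dA;
    if (t > 0) dWh += Hc.slice(t - 1).t() * dA;
    dh_carry = dA * Wh.t();
    dc_carry = dc % f;
  }
  arma::mat dWx = stack_cube(x).t() * dA_all;
  arma::vec db = arma::sum(dA_all, 0).t();
  arma::mat dXs = dA_all * Wx.t();               // (T*B) x Cin
  arma::cube dx(B, Cin, T);
  for (int t = 0; t < T; ++t) dx.slice(t) = dXs.rows(t * B, t * B + B - 1);
  return List::create(_["dx"] = dx, _["dWx"] = dWx, _["dWh"] = dWh,
                      _["db"] = db);
}
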