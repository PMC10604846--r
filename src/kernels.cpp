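// Low-level compute kernels for the hybrid gait network.
//
// Tensor layout convention (column-major, matching R arrays):
//   skeleton feature maps  X[c, t, v, b]  dims (C, T, V, B)
//   LSTM sequences         X[d, t, b]     dims (D, T, B)
// All kernels implement both the forward pass and the exact reverse-mode
// gradients; the R side composes them into full models.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat view_mat(const NumericVector& x, int nrow, int ncol,
                          int offset) {
  return arma::mat(const_cast<double*>(x.begin()) + offset, nrow, ncol,
                   false, true);
}

// ---------------------------------------------------------------------------
// Graph convolution over partition subsets:
//   Y[co,t,v,b] = sum_k sum_u sum_ci  A_k[u,v] * X[ci,t,u,b] * W_k[ci,co]
// A: (V, V, K), W: (Cin, Cout, K)
// [[Rcpp::export]]
NumericVector gconv_forward(NumericVector X, NumericVector A,
                            NumericVector W) {
  IntegerVector dx = X.attr("dim");
  int Cin = dx[0], T = dx[1], V = dx[2], B = dx[3];
  IntegerVector dw = W.attr("dim");
  int Cout = dw[1], K = dw[2];
  NumericVector Y(Cout * T * V * B);
  Y.attr("dim") = IntegerVector::create(Cout, T, V, B);
  for (int b = 0; b < B; ++b) {
    arma::mat Xm = view_mat(X, Cin, T * V, b * Cin * T * V);
    arma::mat Ym = view_mat(Y, Cout, T * V, b * Cout * T * V);
    for (int k = 0; k < K; ++k) {
      arma::mat Wk = view_mat(W, Cin, Cout, k * Cin * Cout);
      arma::mat Ak = view_mat(A, V, V, k * V * V);
      arma::mat Z = Wk.t() * Xm;                       // (Cout, T*V)
      arma::mat Zr(Z.memptr(), Cout * T, V, false);    // (Cout*T, V)
      arma::mat Yr(Ym.memptr(), Cout * T, V, false);
      Yr += Zr * Ak;
    }
  }
  return Y;
}

// [[Rcpp::export]]
List gconv_backward(NumericVector X, NumericVector A, NumericVector W,
                    NumericVector dY) {
  IntegerVector dx = X.attr("dim");
  int Cin = dx[0], T = dx[1], V = dx[2], B = dx[3];
  IntegerVector dw = W.attr("dim");
  int Cout = dw[1], K = dw[2];
  NumericVector dX(Cin * T * V * B);
  dX.attr("dim") = dx;
  NumericVector dW(Cin * Cout * K);
  dW.attr("dim") = IntegerVector::create(Cin, Cout, K);
  for (int b = 0; b < B; ++b) {
    arma::mat Xm = view_mat(X, Cin, T * V, b * Cin * T * V);
    arma::mat dXm = view_mat(dX, Cin, T * V, b * Cin * T * V);
    arma::mat dYm = view_mat(dY, Cout, T * V, b * Cout * T * V);
    arma::mat dYr(dYm.memptr(), Cout * T, V, false);
    for (int k = 0; k < K; ++k) {
      arma::mat Wk = view_mat(W, Cin, Cout, k * Cin * Cout);
      arma::mat Ak = view_mat(A, V, V, k * V * V);
      arma::mat dWk = view_mat(dW, Cin, Cout, k * Cin * Cout);
      arma::mat dZr = dYr * Ak.t();                    // (Cout*T, V)
      arma::mat dZ(dZr.memptr(), Cout, T * V, false);
      dXm += Wk * dZ;
      dWk += Xm * dZ.t();
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW);
}

// ---------------------------------------------------------------------------
// Temporal convolution (per joint, across frames, mixing channels):
//   Y[co,to,v,b] = bias[co] +
//     sum_tau sum_ci W[ci,co,tau] * X[ci, stride*to + tau - pad, v, b]
// Zero padding outside [0, T). W: (Cin, Cout, Gamma).
// Gathers the zero-padded input columns feeding one kernel tap into a
// dense matrix so each tap costs one GEMM.
static arma::mat tconv_gather(const NumericVector& X, int Cin, int T,
                              int VB, int To, int stride, int tau,
                              int pad) {
  arma::mat Xg(Cin, (size_t)To * VB, arma::fill::zeros);
  const double* xp = X.begin();
  for (int vb = 0; vb < VB; ++vb) {
    for (int to = 0; to < To; ++to) {
      int ti = stride * to + tau - pad;
      if (ti >= 0 && ti < T)
        std::memcpy(Xg.colptr((size_t)vb * To + to),
                    xp + ((size_t)vb * T + ti) * Cin,
                    Cin * sizeof(double));
    }
  }
  return Xg;
}

// [[Rcpp::export]]
NumericVector tconv_forward(NumericVector X, NumericVector W,
                            NumericVector bias, int stride) {
  IntegerVector dx = X.attr("dim");
  int Cin = dx[0], T = dx[1], V = dx[2], B = dx[3];
  IntegerVector dw = W.attr("dim");
  int Cout = dw[1], G = dw[2];
  int pad = (G - 1) / 2;
  int To = (T + 2 * pad - G) / stride + 1;
  int VB = V * B;
  NumericVector Y(Cout * (size_t)To * VB);
  Y.attr("dim") = IntegerVector::create(Cout, To, V, B);
  arma::mat Ym(Y.begin(), Cout, (size_t)To * VB, false, true);
  arma::vec bv(const_cast<double*>(bias.begin()), Cout, false, true);
  Ym.each_col() = bv;
  for (int tau = 0; tau < G; ++tau) {
    arma::mat Wt = view_mat(W, Cin, Cout, tau * Cin * Cout);
    Ym += Wt.t() * tconv_gather(X, Cin, T, VB, To, stride, tau, pad);
  }
  return Y;
}

// [[Rcpp::export]]
List tconv_backward(NumericVector X, NumericVector W, NumericVector dY,
                    int stride) {
  IntegerVector dx = X.attr("dim");
  int Cin = dx[0], T = dx[1], V = dx[2], B = dx[3];
  IntegerVector dw = W.attr("dim");
  int Cout = dw[1], G = dw[2];
  int pad = (G - 1) / 2;
  int To = (T + 2 * pad - G) / stride + 1;
  int VB = V * B;
  NumericVector dX(Cin * (size_t)T * VB);
  dX.attr("dim") = dx;
  NumericVector dW(Cin * Cout * G);
  dW.attr("dim") = IntegerVector::create(Cin, Cout, G);
  NumericVector db(Cout);
  arma::mat dYm(const_cast<double*>(dY.begin()), Cout, (size_t)To * VB,
                false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  dbv = arma::sum(dYm, 1);
  double* dxp = dX.begin();
  for (int tau = 0; tau < G; ++tau) {
    arma::mat Wt = view_mat(W, Cin, Cout, tau * Cin * Cout);
    arma::mat dWt = view_mat(dW, Cin, Cout, tau * Cin * Cout);
    arma::mat Xg = tconv_gather(X, Cin, T, VB, To, stride, tau, pad);
    dWt += Xg * dYm.t();
    arma::mat dXg = Wt * dYm;                   // (Cin, To*VB)
    for (int vb = 0; vb < VB; ++vb) {           // scatter-add, unpadded
      for (int to = 0; to < To; ++to) {
        int ti = stride * to + tau - pad;
        if (ti >= 0 && ti < T) {
          double* dst = dxp + ((size_t)vb * T + ti) * Cin;
          const double* src = dXg.colptr((size_t)vb * To + to);
          for (int c = 0; c < Cin; ++c) dst[c] += src[c];
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// ---------------------------------------------------------------------------
// Batch normalization over the first array dimension (channels); the
// remaining dimensions are the normalization population.
// [[Rcpp::export]]
List bn_train_forward(NumericVector X, int C, NumericVector g,
                      NumericVector b, double eps) {
  size_t n = X.size() / C;
  arma::mat Xm(const_cast<double*>(X.begin()), C, n, false, true);
  arma::vec mu = arma::mean(Xm, 1);
  arma::mat Xc = Xm.each_col() - mu;
  arma::vec v = arma::mean(arma::square(Xc), 1);
  arma::vec istd = 1.0 / arma::sqrt(v + eps);
  NumericVector Xhat(X.size()), Y(X.size());
  Xhat.attr("dim") = X.attr("dim");
  Y.attr("dim") = X.attr("dim");
  arma::mat Xh(Xhat.begin(), C, n, false, true);
  arma::mat Ym(Y.begin(), C, n, false, true);
  Xh = Xc.each_col() % istd;
  arma::vec gv(const_cast<double*>(g.begin()), C, false, true);
  arma::vec bv(const_cast<double*>(b.begin()), C, false, true);
  Ym = (Xh.each_col() % gv);
  Ym.each_col() += bv;
  return List::create(_["y"] = Y, _["xhat"] = Xhat,
                      _["istd"] = NumericVector(istd.begin(), istd.end()),
                      _["mu"] = NumericVector(mu.begin(), mu.end()),
                      _["var"] = NumericVector(v.begin(), v.end()));
}

// [[Rcpp::export]]
NumericVector bn_eval_forward(NumericVector X, int C, NumericVector g,
                              NumericVector b, NumericVector mean,
                              NumericVector var, double eps) {
  size_t n = X.size() / C;
  arma::mat Xm(const_cast<double*>(X.begin()), C, n, false, true);
  NumericVector Y(X.size());
  Y.attr("dim") = X.attr("dim");
  arma::mat Ym(Y.begin(), C, n, false, true);
  arma::vec mu(const_cast<double*>(mean.begin()), C, false, true);
  arma::vec v(const_cast<double*>(var.begin()), C, false, true);
  arma::vec gv(const_cast<double*>(g.begin()), C, false, true);
  arma::vec bv(const_cast<double*>(b.begin()), C, false, true);
  arma::vec scale = gv / arma::sqrt(v + eps);
  arma::vec shift = bv - mu % scale;
  Ym = (Xm.each_col() % scale);
  Ym.each_col() += shift;
  return Y;
}

// [[Rcpp::export]]
List bn_backward_cpp(NumericVector dY, NumericVector Xhat,
                     NumericVector istd, NumericVector g) {
  int C = g.size();
  size_t n = dY.size() / C;
  arma::mat dYm(const_cast<double*>(dY.begin()), C, n, false, true);
  arma::mat Xh(const_cast<double*>(Xhat.begin()), C, n, false, true);
  arma::vec dg = arma::sum(dYm % Xh, 1);
  arma::vec db = arma::sum(dYm, 1);
  NumericVector dX(dY.size());
  dX.attr("dim") = dY.attr("dim");
  arma::mat dXm(dX.begin(), C, n, false, true);
  arma::vec gv(const_cast<double*>(g.begin()), C, false, true);
  arma::vec iv(const_cast<double*>(istd.begin()), C, false, true);
  arma::vec coef = gv % iv / (double)n;
  dXm = dYm * (double)n;
  dXm.each_col() -= db;
  dXm -= Xh.each_col() % dg;
  dXm.each_col() %= coef;
  return List::create(_["dx"] = dX,
                      _["dg"] = NumericVector(dg.begin(), dg.end()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// y = max(x, 0)
// [[Rcpp::export]]
NumericVector relu_forward(NumericVector X) {
  NumericVector Y(clone(X));
  double* p = Y.begin();
  for (R_xlen_t i = 0; i < Y.size(); ++i) if (p[i] < 0) p[i] = 0;
  return Y;
}

// dx = dy * (ref > 0)
// [[Rcpp::export]]
NumericVector relu_backward(NumericVector dY, NumericVector ref) {
  NumericVector dX(clone(dY));
  double* p = dX.begin();
  const double* r = ref.begin();
  for (R_xlen_t i = 0; i < dX.size(); ++i) if (r[i] <= 0) p[i] = 0;
  return dX;
}

// ---------------------------------------------------------------------------
// Single LSTM layer, batched over B. Gate order within the stacked 4H
// dimension: input i, forget f, candidate g, output o.
//   i,f,o = sigmoid(Wx X_t + Wh h_{t-1} + b),  g = tanh(...)
//   c_t = f . c_{t-1} + i . g ;  h_t = o . tanh(c_t)
// X: (D, T, B); Wx: (4H, D); Wh: (4H, H); b: 4H.
// [[Rcpp::export]]
List lstm_forward(NumericVector X, NumericMatrix Wx, NumericMatrix Wh,
                  NumericVector b) {
  IntegerVector dx = X.attr("dim");
  int D = dx[0], T = dx[1], B = dx[2];
  int H = Wh.ncol();
  arma::mat Wxm(Wx.begin(), 4 * H, D, false, true);
  arma::mat Whm(Wh.begin(), 4 * H, H, false, true);
  arma::vec bv(b.begin(), 4 * H, false, true);

  NumericVector Hout(H * T * B), Cout_(H * T * B), Gates(4 * H * T * B);
  Hout.attr("dim") = IntegerVector::create(H, T, B);
  Cout_.attr("dim") = IntegerVector::create(H, T, B);
  Gates.attr("dim") = IntegerVector::create(4 * H, T, B);

  arma::mat h(H, B, arma::fill::zeros), c(H, B, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    arma::mat Xt(B, D);
    for (int bb = 0; bb < B; ++bb)
      Xt.row(bb) = arma::rowvec(const_cast<double*>(X.begin()) +
                                (bb * T + t) * D, D, false);
    arma::mat Z = Wxm * Xt.t() + Whm * h;    // (4H, B)
    Z.each_col() += bv;
    arma::mat ig = 1.0 / (1.0 + arma::exp(-Z.rows(0, H - 1)));
    arma::mat fg = 1.0 / (1.0 + arma::exp(-Z.rows(H, 2 * H - 1)));
    arma::mat gg = arma::tanh(Z.rows(2 * H, 3 * H - 1));
    arma::mat og = 1.0 / (1.0 + arma::exp(-Z.rows(3 * H, 4 * H - 1)));
    c = fg % c + ig % gg;
    h = og % arma::tanh(c);
    for (int bb = 0; bb < B; ++bb) {
      std::memcpy(Hout.begin() + (bb * T + t) * H, h.colptr(bb),
                  H * sizeof(double));
      std::memcpy(Cout_.begin() + (bb * T + t) * H, c.colptr(bb),
                  H * sizeof(double));
      double* gp = Gates.begin() + (bb * T + t) * 4 * H;
      std::memcpy(gp, ig.colptr(bb), H * sizeof(double));
      std::memcpy(gp + H, fg.colptr(bb), H * sizeof(double));
      std::memcpy(gp + 2 * H, gg.colptr(bb), H * sizeof(double));
      std::memcpy(gp + 3 * H, og.colptr(bb), H * sizeof(double));
    }
  }
  return List::create(_["H"] = Hout, _["C"] = Cout_, _["gates"] = Gates);
}

// dH: (H, T, B) gradient w.r.t. every hidden state (zeros where unused).
// [[Rcpp::export]]
List lstm_backward(NumericVector X, NumericMatrix Wx, NumericMatrix Wh,
                   NumericVector Hout, NumericVector Cout_,
                   NumericVector Gates, NumericVector dH) {
  IntegerVector dx = X.attr("dim");
  int D = dx[0], T = dx[1], B = dx[2];
  int H = Wh.ncol();
  arma::mat Wxm(Wx.begin(), 4 * H, D, false, true);
  arma::mat Whm(Wh.begin(), 4 * H, H, false, true);

  NumericVector dX(D * T * B);
  dX.attr("dim") = dx;
  arma::mat dWx(4 * H, D, arma::fill::zeros);
  arma::mat dWh(4 * H, H, arma::fill::zeros);
  arma::vec db(4 * H, arma::fill::zeros);

  arma::mat dh_next(H, B, arma::fill::zeros), dc(H, B, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    arma::mat ig(H, B), fg(H, B), gg(H, B), og(H, B), ct(H, B),
        cprev(H, B), hprev(H, B), dht(H, B), Xt(D, B);
    for (int bb = 0; bb < B; ++bb) {
      const double* gp = Gates.begin() + (bb * T + t) * 4 * H;
      std::memcpy(ig.colptr(bb), gp, H * sizeof(double));
      std::memcpy(fg.colptr(bb), gp + H, H * sizeof(double));
      std::memcpy(gg.colptr(bb), gp + 2 * H, H * sizeof(double));
      std::memcpy(og.colptr(bb), gp + 3 * H, H * sizeof(double));
      std::memcpy(ct.colptr(bb), Cout_.begin() + (bb * T + t) * H,
                  H * sizeof(double));
      std::memcpy(dht.colptr(bb), dH.begin() + (bb * T + t) * H,
                  H * sizeof(double));
      std::memcpy(Xt.colptr(bb), X.begin() + (bb * T + t) * D,
                  D * sizeof(double));
      if (t > 0) {
        std::memcpy(cprev.colptr(bb), Cout_.begin() + (bb * T + t - 1) * H,
                    H * sizeof(double));
        std::memcpy(hprev.colptr(bb), Hout.begin() + (bb * T + t - 1) * H,
                    H * sizeof(double));
      }
    }
    if (t == 0) { cprev.zeros(); hprev.zeros(); }
    arma::mat dh = dht + dh_next;
    arma::mat tc = arma::tanh(ct);
    arma::mat dct = dc + dh % og % (1.0 - tc % tc);
    arma::mat di = dct % gg % ig % (1.0 - ig);
    arma::mat df = dct % cprev % fg % (1.0 - fg);
    arma::mat dg = dct % ig % (1.0 - gg % gg);
    arma::mat do_ = dh % tc % og % (1.0 - og);
    arma::mat dZ = arma::join_cols(arma::join_cols(di, df),
                                   arma::join_cols(dg, do_)); // (4H, B)
    dWx += dZ * Xt.t();
    dWh += dZ * hprev.t();
    db += arma::sum(dZ, 1);
    arma::mat dXt = Wxm.t() * dZ;                       // (D, B)
    for (int bb = 0; bb < B; ++bb)
      std::memcpy(dX.begin() + (bb * T + t) * D, dXt.colptr(bb),
                  D * sizeof(double));
    dh_next = Whm.t() * dZ;
    dc = dct % fg;
  }
  return List::create(_["dX"] = dX, _["dWx"] = dWx, _["dWh"] = dWh,
                      _["db"] = db);
}
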