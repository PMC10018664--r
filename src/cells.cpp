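// Recurrent-cell kernels: batched forward passes and backpropagation through
// time for simple RNN, GRU and LSTM cells, plus a 1-D convolution + max-pool
// feature stage. Sequences are arma::cubes laid out (batch, features, time);
// slice t is the batch matrix at timestep t.
//
// Gate activations are fixed logistic sigmoids; the tunable "hidden"
// activation applies to the cell candidate (and, for LSTM, the cell-state
// output transform), matching the usual Keras-style cell definitions.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// activation ids (keep in sync with R/activations.R):
// 0 linear, 1 sigmoid, 2 relu, 3 selu, 4 elu, 5 softsign, 6 tanh,
// 7 softmax (row-wise over units), 8 softplus, 9 hard_sigmoid, 10 swish

static const double SELU_SCALE = 1.0507009873554805;
static const double SELU_ALPHA = 1.6732632423543772;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

static mat act_apply(const mat& x, int id) {
  switch (id) {
  case 0: return x;
  case 1: return sigm(x);
  case 2: return clamp(x, 0.0, datum::inf);
  case 3: {
    mat y = x;
    y.transform([](double v) {
      return v > 0 ? SELU_SCALE * v : SELU_SCALE * SELU_ALPHA * (std::exp(v) - 1.0);
    });
    return y;
  }
  case 4: {
    mat y = x;
    y.transform([](double v) { return v > 0 ? v : std::exp(v) - 1.0; });
    return y;
  }
  case 5: return x / (1.0 + abs(x));
  case 6: return tanh(x);
  case 7: {
    mat z = x;
    z.each_col() -= max(x, 1);
    z = exp(z);
    z.each_col() /= sum(z, 1);
    return z;
  }
  case 8: {
    // numerically stable log(1 + exp(x))
    mat y = x;
    y.transform([](double v) {
      return v > 30 ? v : (v < -30 ? std::exp(v) : std::log1p(std::exp(v)));
    });
    return y;
  }
  case 9: return clamp(0.2 * x + 0.5, 0.0, 1.0);
  case 10: return x % sigm(x);
  default: Rcpp::stop("unknown activation id");
  }
}

// gradient wrt pre-activation: dX given upstream dY, pre-activation P and
// output Y (softmax needs the full row of Y).
static mat act_dpre(const mat& dY, const mat& P, const mat& Y, int id) {
  switch (id) {
  case 0: return dY;
  case 1: return dY % Y % (1.0 - Y);
  case 2: return dY % conv_to<mat>::from(P > 0);
  case 3: {
    mat d = P;
    d.transform([](double v) {
      return v > 0 ? SELU_SCALE : SELU_SCALE * SELU_ALPHA * std::exp(v);
    });
    return dY % d;
  }
  case 4: {
    mat d = P;
    d.transform([](double v) { return v > 0 ? 1.0 : std::exp(v); });
    return dY % d;
  }
  case 5: {
    mat d = 1.0 / square(1.0 + abs(P));
    return dY % d;
  }
  case 6: return dY % (1.0 - square(Y));
  case 7: {
    mat s = sum(dY % Y, 1);
    mat d = dY;
    d.each_col() -= s;
    return Y % d;
  }
  case 8: return dY % sigm(P);
  case 9: {
    mat d = conv_to<mat>::from((P > -2.5) % (P < 2.5)) * 0.2;
    return dY % d;
  }
  case 10: {
    mat s = sigm(P);
    return dY % (s % (1.0 + P % (1.0 - s)));
  }
  default: Rcpp::stop("unknown activation id");
  }
}

// exposed for R-side layers (dense heads) so R and C++ share one definition
// [[Rcpp::export(name = ".act_apply")]]
arma::mat act_apply_export(const arma::mat& x, int id) { return act_apply(x, id); }

// [[Rcpp::export(name = ".act_dpre")]]
arma::mat act_dpre_export(const arma::mat& dY, const arma::mat& P,
                          const arma::mat& Y, int id) {
  return act_dpre(dY, P, Y, id);
}

// ---------------------------------------------------------------- simple RNN

// [[Rcpp::export(name = ".rnn_forward")]]
Rcpp::List rnn_forward(const arma::cube& X, const arma::mat& W,
                       const arma::mat& U, const arma::rowvec& b,
                       const arma::mat& h0, int act) {
  const uword B = X.n_rows, T = X.n_slices, H = W.n_cols;
  cube Hs(B, H, T), Ps(B, H, T);
  mat h = h0;
  for (uword t = 0; t < T; ++t) {
    mat p = X.slice(t) * W + h * U;
    p.each_row() += b;
    h = act_apply(p, act);
    Ps.slice(t) = p;
    Hs.slice(t) = h;
  }
  return Rcpp::List::create(Rcpp::Named("H") = Hs, Rcpp::Named("P") = Ps);
}

// [[Rcpp::export(name = ".rnn_backward")]]
Rcpp::List rnn_backward(const arma::cube& X, const arma::mat& W,
                        const arma::mat& U, const arma::mat& h0,
                        const arma::cube& Hs, const arma::cube& Ps,
                        const arma::cube& dH, int act) {
  const uword B = X.n_rows, F = X.n_cols, T = X.n_slices, H = W.n_cols;
  cube dX(B, F, T, fill::zeros);
  mat dW(F, H, fill::zeros), dU(H, H, fill::zeros);
  rowvec db(H, fill::zeros);
  mat dh(B, H, fill::zeros);
  for (uword t = T; t-- > 0;) {
    dh += dH.slice(t);
    mat dp = act_dpre(dh, Ps.slice(t), Hs.slice(t), act);
    const mat& h_prev = (t == 0) ? h0 : Hs.slice(t - 1);
    dX.slice(t) = dp * W.t();
    dW += X.slice(t).t() * dp;
    dU += h_prev.t() * dp;
    db += sum(dp, 0);
    dh = dp * U.t();
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("dU") = dU, Rcpp::Named("db") = db);
}

// ----------------------------------------------------------------------- GRU
// weights concatenated column-wise [update z | reset r | candidate c]

// [[Rcpp::export(name = ".gru_forward")]]
Rcpp::List gru_forward(const arma::cube& X, const arma::mat& W,
                       const arma::mat& U, const arma::rowvec& b,
                       const arma::mat& h0, int act) {
  const uword B = X.n_rows, T = X.n_slices, H = W.n_cols / 3;
  cube Hs(B, H, T), Z(B, H, T), R(B, H, T), C(B, H, T), Pc(B, H, T);
  mat h = h0;
  const mat Wz = W.cols(0, H - 1), Wr = W.cols(H, 2 * H - 1), Wc = W.cols(2 * H, 3 * H - 1);
  const mat Uz = U.cols(0, H - 1), Ur = U.cols(H, 2 * H - 1), Uc = U.cols(2 * H, 3 * H - 1);
  const rowvec bz = b.cols(0, H - 1), br = b.cols(H, 2 * H - 1), bc = b.cols(2 * H, 3 * H - 1);
  for (uword t = 0; t < T; ++t) {
    const mat& x = X.slice(t);
    mat pz = x * Wz + h * Uz; pz.each_row() += bz;
    mat pr = x * Wr + h * Ur; pr.each_row() += br;
    mat z = sigm(pz), r = sigm(pr);
    mat pc = x * Wc + (r % h) * Uc; pc.each_row() += bc;
    mat c = act_apply(pc, act);
    mat hn = z % h + (1.0 - z) % c;
    Z.slice(t) = z; R.slice(t) = r; C.slice(t) = c; Pc.slice(t) = pc;
    Hs.slice(t) = hn;
    h = hn;
  }
  return Rcpp::List::create(Rcpp::Named("H") = Hs, Rcpp::Named("Z") = Z,
                            Rcpp::Named("R") = R, Rcpp::Named("C") = C,
                            Rcpp::Named("Pc") = Pc);
}

// [[Rcpp::export(name = ".gru_backward")]]
Rcpp::List gru_backward(const arma::cube& X, const arma::mat& W,
                        const arma::mat& U, const arma::mat& h0,
                        const arma::cube& Hs, const arma::cube& Z,
                        const arma::cube& R, const arma::cube& C,
                        const arma::cube& Pc, const arma::cube& dH, int act) {
  const uword B = X.n_rows, F = X.n_cols, T = X.n_slices, H = Z.n_cols;
  const mat Wz = W.cols(0, H - 1), Wr = W.cols(H, 2 * H - 1), Wc = W.cols(2 * H, 3 * H - 1);
  const mat Uz = U.cols(0, H - 1), Ur = U.cols(H, 2 * H - 1), Uc = U.cols(2 * H, 3 * H - 1);
  cube dX(B, F, T, fill::zeros);
  mat dW(F, 3 * H, fill::zeros), dU(H, 3 * H, fill::zeros);
  rowvec db(3 * H, fill::zeros);
  mat dh(B, H, fill::zeros);
  for (uword t = T; t-- > 0;) {
    dh += dH.slice(t);
    const mat& h_prev = (t == 0) ? h0 : Hs.slice(t - 1);
    const mat& z = Z.slice(t); const mat& r = R.slice(t); const mat& c = C.slice(t);
    mat dz = dh % (h_prev - c);
    mat dc = dh % (1.0 - z);
    mat dh_prev = dh % z;
    mat dpc = act_dpre(dc, Pc.slice(t), c, act);
    mat drh = dpc * Uc.t();
    mat dr = drh % h_prev;
    dh_prev += drh % r;
    mat dpz = dz % z % (1.0 - z);
    mat dpr = dr % r % (1.0 - r);
    dX.slice(t) = dpc * Wc.t() + dpz * Wz.t() + dpr * Wr.t();
    dh_prev += dpz * Uz.t() + dpr * Ur.t();
    const mat& x = X.slice(t);
    dW.cols(0, H - 1) += x.t() * dpz;
    dW.cols(H, 2 * H - 1) += x.t() * dpr;
    dW.cols(2 * H, 3 * H - 1) += x.t() * dpc;
    dU.cols(0, H - 1) += h_prev.t() * dpz;
    dU.cols(H, 2 * H - 1) += h_prev.t() * dpr;
    dU.cols(2 * H, 3 * H - 1) += (r % h_prev).t() * dpc;
    db.cols(0, H - 1) += sum(dpz, 0);
    db.cols(H, 2 * H - 1) += sum(dpr, 0);
    db.cols(2 * H, 3 * H - 1) += sum(dpc, 0);
    dh = dh_prev;
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("dU") = dU, Rcpp::Named("db") = db);
}

// ---------------------------------------------------------------------- LSTM
// weights concatenated [input i | forget f | candidate g | output o]

// [[Rcpp::export(name = ".lstm_forward")]]
Rcpp::List lstm_forward(const arma::cube& X, const arma::mat& W,
                        const arma::mat& U, const arma::rowvec& b,
                        const arma::mat& h0, const arma::mat& c0, int act) {
  const uword B = X.n_rows, T = X.n_slices, H = W.n_cols / 4;
  cube Hs(B, H, T), I(B, H, T), Fg(B, H, T), G(B, H, T), O(B, H, T),
       Cs(B, H, T), Pg(B, H, T), Hc(B, H, T);
  mat h = h0, c = c0;
  for (uword t = 0; t < T; ++t) {
    mat p = X.slice(t) * W + h * U;
    p.each_row() += b;
    mat i = sigm(p.cols(0, H - 1));
    mat f = sigm(p.cols(H, 2 * H - 1));
    mat pg = p.cols(2 * H, 3 * H - 1);
    mat g = act_apply(pg, act);
    mat o = sigm(p.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    mat hc = act_apply(c, act);
    h = o % hc;
    I.slice(t) = i; Fg.slice(t) = f; G.slice(t) = g; O.slice(t) = o;
    Cs.slice(t) = c; Pg.slice(t) = pg; Hc.slice(t) = hc; Hs.slice(t) = h;
  }
  return Rcpp::List::create(Rcpp::Named("H") = Hs, Rcpp::Named("I") = I,
                            Rcpp::Named("F") = Fg, Rcpp::Named("G") = G,
                            Rcpp::Named("O") = O, Rcpp::Named("Cs") = Cs,
                            Rcpp::Named("Pg") = Pg, Rcpp::Named("Hc") = Hc);
}

// [[Rcpp::export(name = ".lstm_backward")]]
Rcpp::List lstm_backward(const arma::cube& X, const arma::mat& W,
                         const arma::mat& U, const arma::mat& h0,
                         const arma::mat& c0, const arma::cube& Hs,
                         const arma::cube& I, const arma::cube& Fg,
                         const arma::cube& G, const arma::cube& O,
                         const arma::cube& Cs, const arma::cube& Pg,
                         const arma::cube& Hc, const arma::cube& dH, int act) {
  const uword B = X.n_rows, F = X.n_cols, T = X.n_slices, H = I.n_cols;
  cube dX(B, F, T, fill::zeros);
  mat dW(F, 4 * H, fill::zeros), dU(H, 4 * H, fill::zeros);
  rowvec db(4 * H, fill::zeros);
  mat dh(B, H, fill::zeros), dc(B, H, fill::zeros);
  for (uword t = T; t-- > 0;) {
    dh += dH.slice(t);
    const mat& c_prev = (t == 0) ? c0 : Cs.slice(t - 1);
    const mat& h_prev = (t == 0) ? h0 : Hs.slice(t - 1);
    const mat& i = I.slice(t); const mat& f = Fg.slice(t);
    const mat& g = G.slice(t); const mat& o = O.slice(t);
    mat dmo = dh % Hc.slice(t);
    dc += act_dpre(dh % o, Cs.slice(t), Hc.slice(t), act);
    mat di = dc % g, dg = dc % i, df = dc % c_prev;
    mat dc_prev = dc % f;
    mat dpi = di % i % (1.0 - i);
    mat dpf = df % f % (1.0 - f);
    mat dpg = act_dpre(dg, Pg.slice(t), g, act);
    mat dpo = dmo % o % (1.0 - o);
    mat D(B, 4 * H);
    D.cols(0, H - 1) = dpi;
    D.cols(H, 2 * H - 1) = dpf;
    D.cols(2 * H, 3 * H - 1) = dpg;
    D.cols(3 * H, 4 * H - 1) = dpo;
    dX.slice(t) = D * W.t();
    dW += X.slice(t).t() * D;
    dU += h_prev.t() * D;
    db += sum(D, 0);
    dh = D * U.t();
    dc = dc_prev;
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("dU") = dU, Rcpp::Named("db") = db);
}

// -------------------------------------------------- Conv1D (valid) + maxpool
// kernel K: cube (F_in, F_out, kernel_width); pool: width-2 stride-2 max.

// [[Rcpp::export(name = ".conv1d_forward")]]
Rcpp::List conv1d_forward(const arma::cube& X, const arma::cube& K,
                          const arma::rowvec& b, int act) {
  const uword B = X.n_rows, T = X.n_slices;
  const uword Fo = K.n_cols, Kw = K.n_slices;
  if (T < Kw) Rcpp::stop("input window too short for convolution kernel");
  const uword Tc = T - Kw + 1;
  cube P(B, Fo, Tc, fill::zeros), Y(B, Fo, Tc);
  for (uword t = 0; t < Tc; ++t) {
    mat p(B, Fo, fill::zeros);
    for (uword k = 0; k < Kw; ++k) p += X.slice(t + k) * K.slice(k);
    p.each_row() += b;
    P.slice(t) = p;
    Y.slice(t) = act_apply(p, act);
  }
  const uword Tp = Tc / 2;
  if (Tp < 1) Rcpp::stop("input window too short for pooling after convolution");
  cube Out(B, Fo, Tp);
  ucube Amax(B, Fo, Tp); // 0 or 1: which of the pooled pair was the max
  for (uword t = 0; t < Tp; ++t) {
    const mat& a = Y.slice(2 * t);
    const mat& b2 = Y.slice(2 * t + 1);
    umat pick = b2 > a;
    Out.slice(t) = a % conv_to<mat>::from(1 - pick) + b2 % conv_to<mat>::from(pick);
    Amax.slice(t) = pick;
  }
  return Rcpp::List::create(Rcpp::Named("Out") = Out, Rcpp::Named("P") = P,
                            Rcpp::Named("Y") = Y, Rcpp::Named("Amax") = Amax);
}

// [[Rcpp::export(name = ".conv1d_backward")]]
Rcpp::List conv1d_backward(const arma::cube& X, const arma::cube& K,
                           const arma::cube& P, const arma::cube& Y,
                           const arma::ucube& Amax, const arma::cube& dOut,
                           int act) {
  const uword B = X.n_rows, F = X.n_cols, T = X.n_slices;
  const uword Fo = K.n_cols, Kw = K.n_slices, Tc = P.n_slices, Tp = dOut.n_slices;
  cube dY(B, Fo, Tc, fill::zeros);
  for (uword t = 0; t < Tp; ++t) {
    mat pick = conv_to<mat>::from(Amax.slice(t));
    dY.slice(2 * t) += dOut.slice(t) % (1.0 - pick);
    dY.slice(2 * t + 1) += dOut.slice(t) % pick;
  }
  cube dX(B, F, T, fill::zeros), dK(F, Fo, Kw, fill::zeros);
  rowvec db(Fo, fill::zeros);
  for (uword t = 0; t < Tc; ++t) {
    mat dp = act_dpre(dY.slice(t), P.slice(t), Y.slice(t), act);
    db += sum(dp, 0);
    for (uword k = 0; k < Kw; ++k) {
      dX.slice(t + k) += dp * K.slice(k).t();
      dK.slice(k) += X.slice(t + k).t() * dp;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dK") = dK,
                            Rcpp::Named("db") = db);
}

// ------------------------------------------------------------- whole-network
// Single-call training step and prediction: the full layer stack, head and
// loss evaluated in C++ so BPTT caches never cross the R boundary. Layer
// layout integers: type 0 = unidirectional cell, 1 = bidirectional cell,
// 2 = conv stage; cell 0 = rnn, 1 = gru, 2 = lstm. Head type 0 = vector
// dense, 1 = encoder-decoder. Loss 0 = MSE, 1 = MAE, 2 = Huber, 3 = LogCosh.

struct CellCache {
  cube H;
  std::vector<cube> ex; // rnn: {P}; gru: {Z,R,C,Pc}; lstm: {I,F,G,O,Cs,Pg,Hc}
};

static void cell_fwd(int cell, const cube& X, const mat& W, const mat& U,
                     const rowvec& b, int act, CellCache& cc) {
  const uword B = X.n_rows, T = X.n_slices;
  if (cell == 0) { // simple RNN
    const uword H = W.n_cols;
    cc.H.set_size(B, H, T);
    cc.ex.assign(1, cube(B, H, T));
    mat h(B, H, fill::zeros);
    for (uword t = 0; t < T; ++t) {
      mat p = X.slice(t) * W + h * U;
      p.each_row() += b;
      h = act_apply(p, act);
      cc.ex[0].slice(t) = p;
      cc.H.slice(t) = h;
    }
  } else if (cell == 1) { // GRU
    const uword H = W.n_cols / 3;
    cc.H.set_size(B, H, T);
    cc.ex.assign(4, cube(B, H, T));
    mat h(B, H, fill::zeros);
    const mat Wz = W.cols(0, H - 1), Wr = W.cols(H, 2 * H - 1), Wc = W.cols(2 * H, 3 * H - 1);
    const mat Uz = U.cols(0, H - 1), Ur = U.cols(H, 2 * H - 1), Uc = U.cols(2 * H, 3 * H - 1);
    const rowvec bz = b.cols(0, H - 1), br = b.cols(H, 2 * H - 1), bc = b.cols(2 * H, 3 * H - 1);
    for (uword t = 0; t < T; ++t) {
      const mat& x = X.slice(t);
      mat pz = x * Wz + h * Uz; pz.each_row() += bz;
      mat pr = x * Wr + h * Ur; pr.each_row() += br;
      mat z = sigm(pz), r = sigm(pr);
      mat pc = x * Wc + (r % h) * Uc; pc.each_row() += bc;
      mat c = act_apply(pc, act);
      h = z % h + (1.0 - z) % c;
      cc.ex[0].slice(t) = z; cc.ex[1].slice(t) = r;
      cc.ex[2].slice(t) = c; cc.ex[3].slice(t) = pc;
      cc.H.slice(t) = h;
    }
  } else { // LSTM
    const uword H = W.n_cols / 4;
    cc.H.set_size(B, H, T);
    cc.ex.assign(7, cube(B, H, T));
    mat h(B, H, fill::zeros), c(B, H, fill::zeros);
    for (uword t = 0; t < T; ++t) {
      mat p = X.slice(t) * W + h * U;
      p.each_row() += b;
      mat i = sigm(p.cols(0, H - 1));
      mat f = sigm(p.cols(H, 2 * H - 1));
      mat pg = p.cols(2 * H, 3 * H - 1);
      mat g = act_apply(pg, act);
      mat o = sigm(p.cols(3 * H, 4 * H - 1));
      c = f % c + i % g;
      mat hc = act_apply(c, act);
      h = o % hc;
      cc.ex[0].slice(t) = i; cc.ex[1].slice(t) = f; cc.ex[2].slice(t) = g;
      cc.ex[3].slice(t) = o; cc.ex[4].slice(t) = c; cc.ex[5].slice(t) = pg;
      cc.ex[6].slice(t) = hc;
      cc.H.slice(t) = h;
    }
  }
}

struct CellGrads { cube dX; mat dW, dU; rowvec db; };

static void cell_bwd(int cell, const cube& X, const mat& W, const mat& U,
                     int act, const CellCache& cc, const cube& dH,
                     CellGrads& out) {
  const uword B = X.n_rows, F = X.n_cols, T = X.n_slices;
  out.dX.zeros(B, F, T);
  if (cell == 0) {
    const uword H = W.n_cols;
    out.dW.zeros(F, H); out.dU.zeros(H, H); out.db.zeros(H);
    mat dh(B, H, fill::zeros);
    const mat h0(B, H, fill::zeros);
    for (uword t = T; t-- > 0;) {
      dh += dH.slice(t);
      mat dp = act_dpre(dh, cc.ex[0].slice(t), cc.H.slice(t), act);
      const mat& h_prev = (t == 0) ? h0 : cc.H.slice(t - 1);
      out.dX.slice(t) = dp * W.t();
      out.dW += X.slice(t).t() * dp;
      out.dU += h_prev.t() * dp;
      out.db += sum(dp, 0);
      dh = dp * U.t();
    }
  } else if (cell == 1) {
    const uword H = W.n_cols / 3;
    out.dW.zeros(F, 3 * H); out.dU.zeros(H, 3 * H); out.db.zeros(3 * H);
    const mat Wz = W.cols(0, H - 1), Wr = W.cols(H, 2 * H - 1), Wc = W.cols(2 * H, 3 * H - 1);
    const mat Uz = U.cols(0, H - 1), Ur = U.cols(H, 2 * H - 1), Uc = U.cols(2 * H, 3 * H - 1);
    mat dh(B, H, fill::zeros);
    const mat h0(B, H, fill::zeros);
    for (uword t = T; t-- > 0;) {
      dh += dH.slice(t);
      const mat& h_prev = (t == 0) ? h0 : cc.H.slice(t - 1);
      const mat& z = cc.ex[0].slice(t); const mat& r = cc.ex[1].slice(t);
      const mat& c = cc.ex[2].slice(t);
      mat dz = dh % (h_prev - c);
      mat dc = dh % (1.0 - z);
      mat dh_prev = dh % z;
      mat dpc = act_dpre(dc, cc.ex[3].slice(t), c, act);
      mat drh = dpc * Uc.t();
      mat dr = drh % h_prev;
      dh_prev += drh % r;
      mat dpz = dz % z % (1.0 - z);
      mat dpr = dr % r % (1.0 - r);
      out.dX.slice(t) = dpc * Wc.t() + dpz * Wz.t() + dpr * Wr.t();
      dh_prev += dpz * Uz.t() + dpr * Ur.t();
      const mat& x = X.slice(t);
      out.dW.cols(0, H - 1) += x.t() * dpz;
      out.dW.cols(H, 2 * H - 1) += x.t() * dpr;
      out.dW.cols(2 * H, 3 * H - 1) += x.t() * dpc;
      out.dU.cols(0, H - 1) += h_prev.t() * dpz;
      out.dU.cols(H, 2 * H - 1) += h_prev.t() * dpr;
      out.dU.cols(2 * H, 3 * H - 1) += (r % h_prev).t() * dpc;
      out.db.cols(0, H - 1) += sum(dpz, 0);
      out.db.cols(H, 2 * H - 1) += sum(dpr, 0);
      out.db.cols(2 * H, 3 * H - 1) += sum(dpc, 0);
      dh = dh_prev;
    }
  } else {
    const uword H = W.n_cols / 4;
    out.dW.zeros(F, 4 * H); out.dU.zeros(H, 4 * H); out.db.zeros(4 * H);
    mat dh(B, H, fill::zeros), dc(B, H, fill::zeros);
    const mat zero(B, H, fill::zeros);
    for (uword t = T; t-- > 0;) {
      dh += dH.slice(t);
      const mat& c_prev = (t == 0) ? zero : cc.ex[4].slice(t - 1);
      const mat& h_prev = (t == 0) ? zero : cc.H.slice(t - 1);
      const mat& i = cc.ex[0].slice(t); const mat& f = cc.ex[1].slice(t);
      const mat& g = cc.ex[2].slice(t); const mat& o = cc.ex[3].slice(t);
      mat dmo = dh % cc.ex[6].slice(t);
      dc += act_dpre(dh % o, cc.ex[4].slice(t), cc.ex[6].slice(t), act);
      mat di = dc % g, dg = dc % i, df = dc % c_prev;
      mat dc_prev = dc % f;
      mat dpi = di % i % (1.0 - i);
      mat dpf = df % f % (1.0 - f);
      mat dpg = act_dpre(dg, cc.ex[5].slice(t), g, act);
      mat dpo = dmo % o % (1.0 - o);
      mat D(B, 4 * H);
      D.cols(0, H - 1) = dpi;
      D.cols(H, 2 * H - 1) = dpf;
      D.cols(2 * H, 3 * H - 1) = dpg;
      D.cols(3 * H, 4 * H - 1) = dpo;
      out.dX.slice(t) = D * W.t();
      out.dW += X.slice(t).t() * D;
      out.dU += h_prev.t() * D;
      out.db += sum(D, 0);
      dh = D * U.t();
      dc = dc_prev;
    }
  }
}

static cube rev_time(const cube& X) {
  cube Y(X.n_rows, X.n_cols, X.n_slices);
  for (uword t = 0; t < X.n_slices; ++t) Y.slice(t) = X.slice(X.n_slices - 1 - t);
  return Y;
}

struct LayerCache {
  cube X;                 // layer input
  CellCache cc, cc_bwd;   // cc_bwd used by bidirectional layers
  cube convP, convY, convOut;
  ucube convAmax;
};

struct NetSpec {
  std::vector<int> ltype, cell;
  int act, htype, out_act, loss, O;
};

static NetSpec parse_spec(const Rcpp::List& sp) {
  NetSpec ns;
  ns.ltype = Rcpp::as<std::vector<int>>(sp["ltype"]);
  ns.cell = Rcpp::as<std::vector<int>>(sp["cell"]);
  ns.act = Rcpp::as<int>(sp["act"]);
  ns.htype = Rcpp::as<int>(sp["htype"]);
  ns.out_act = Rcpp::as<int>(sp["out_act"]);
  ns.loss = Rcpp::as<int>(sp["loss"]);
  ns.O = Rcpp::as<int>(sp["O"]);
  return ns;
}

// forward through the layer stack; fills caches, returns the head vector
static mat stack_forward(const NetSpec& ns, const Rcpp::List& params,
                         const cube& X, std::vector<LayerCache>& caches) {
  const uword L = ns.ltype.size();
  caches.resize(L);
  cube A = X;
  mat head_vec;
  for (uword l = 0; l < L; ++l) {
    std::string nm = "L" + std::to_string(l + 1);
    caches[l].X = A;
    if (ns.ltype[l] == 2) { // conv + pool
      cube K = Rcpp::as<cube>(params[nm + ".K"]);
      rowvec cb = Rcpp::as<rowvec>(params[nm + ".cb"]);
      const uword B = A.n_rows, T = A.n_slices, Fo = K.n_cols, Kw = K.n_slices;
      if (T < Kw + 1) Rcpp::stop("input window too short for the conv stage");
      const uword Tc = T - Kw + 1, Tp = Tc / 2;
      cube P(B, Fo, Tc), Y(B, Fo, Tc);
      for (uword t = 0; t < Tc; ++t) {
        mat p(B, Fo, fill::zeros);
        for (uword k = 0; k < Kw; ++k) p += A.slice(t + k) * K.slice(k);
        p.each_row() += cb;
        P.slice(t) = p;
        Y.slice(t) = act_apply(p, ns.act);
      }
      cube Out(B, Fo, Tp);
      ucube Amax(B, Fo, Tp);
      for (uword t = 0; t < Tp; ++t) {
        umat pick = Y.slice(2 * t + 1) > Y.slice(2 * t);
        Out.slice(t) = Y.slice(2 * t) % conv_to<mat>::from(1 - pick) +
                       Y.slice(2 * t + 1) % conv_to<mat>::from(pick);
        Amax.slice(t) = pick;
      }
      caches[l].convP = P; caches[l].convY = Y;
      caches[l].convOut = Out; caches[l].convAmax = Amax;
      A = Out;
    } else if (ns.ltype[l] == 1) { // bidirectional
      mat W = Rcpp::as<mat>(params[nm + ".fwd.W"]);
      mat U = Rcpp::as<mat>(params[nm + ".fwd.U"]);
      rowvec b = Rcpp::as<rowvec>(params[nm + ".fwd.b"]);
      cell_fwd(ns.cell[l], A, W, U, b, ns.act, caches[l].cc);
      cube Ar = rev_time(A);
      mat Wb = Rcpp::as<mat>(params[nm + ".bwd.W"]);
      mat Ub = Rcpp::as<mat>(params[nm + ".bwd.U"]);
      rowvec bb = Rcpp::as<rowvec>(params[nm + ".bwd.b"]);
      cell_fwd(ns.cell[l], Ar, Wb, Ub, bb, ns.act, caches[l].cc_bwd);
      const uword B = A.n_rows, T = A.n_slices, H = caches[l].cc.H.n_cols;
      cube out(B, 2 * H, T);
      for (uword t = 0; t < T; ++t) {
        out.slice(t).cols(0, H - 1) = caches[l].cc.H.slice(t);
        out.slice(t).cols(H, 2 * H - 1) = caches[l].cc_bwd.H.slice(T - 1 - t);
      }
      head_vec = join_rows(caches[l].cc.H.slice(T - 1),
                           caches[l].cc_bwd.H.slice(T - 1));
      A = out;
    } else { // unidirectional cell
      mat W = Rcpp::as<mat>(params[nm + ".W"]);
      mat U = Rcpp::as<mat>(params[nm + ".U"]);
      rowvec b = Rcpp::as<rowvec>(params[nm + ".b"]);
      cell_fwd(ns.cell[l], A, W, U, b, ns.act, caches[l].cc);
      head_vec = caches[l].cc.H.slice(A.n_slices - 1);
      A = caches[l].cc.H;
    }
  }
  return head_vec;
}

struct HeadCache { mat P, Y, head_vec; CellCache dec; cube Xdec; };

static void head_forward(const NetSpec& ns, const Rcpp::List& params,
                         const mat& head_vec, HeadCache& hc) {
  const uword B = head_vec.n_rows, O = (uword)ns.O;
  hc.head_vec = head_vec;
  mat headW = Rcpp::as<mat>(params["head.W"]);
  rowvec headb = Rcpp::as<rowvec>(params["head.b"]);
  if (ns.htype == 0) {
    hc.P = head_vec * headW;
    hc.P.each_row() += headb;
  } else {
    hc.Xdec.set_size(B, head_vec.n_cols, O);
    for (uword o = 0; o < O; ++o) hc.Xdec.slice(o) = head_vec;
    mat dW = Rcpp::as<mat>(params["dec.W"]);
    mat dU = Rcpp::as<mat>(params["dec.U"]);
    rowvec db = Rcpp::as<rowvec>(params["dec.b"]);
    cell_fwd(ns.cell.back(), hc.Xdec, dW, dU, db, ns.act, hc.dec);
    hc.P.set_size(B, O);
    for (uword o = 0; o < O; ++o)
      hc.P.col(o) = hc.dec.H.slice(o) * headW + as_scalar(headb(0)) * ones(B);
  }
  hc.Y = act_apply(hc.P, ns.out_act);
}

// [[Rcpp::export(name = ".net_predict")]]
arma::mat net_predict(const arma::cube& X, const Rcpp::List& params,
                      const Rcpp::List& spec) {
  NetSpec ns = parse_spec(spec);
  std::vector<LayerCache> caches;
  mat head_vec = stack_forward(ns, params, X, caches);
  HeadCache hc;
  head_forward(ns, params, head_vec, hc);
  return hc.Y;
}

static double loss_value(const mat& Y, const mat& Yt, int loss) {
  mat d = Y - Yt;
  switch (loss) {
  case 0: return accu(square(d)) / d.n_elem;
  case 1: return accu(abs(d)) / d.n_elem;
  case 2: {
    mat a = abs(d);
    mat v = a;
    v.transform([](double x) { return x <= 1 ? 0.5 * x * x : x - 0.5; });
    return accu(v) / d.n_elem;
  }
  default: {
    mat a = abs(d);
    return accu(a + log1p(exp(-2.0 * a)) - std::log(2.0)) / d.n_elem;
  }
  }
}

static mat loss_grad(const mat& Y, const mat& Yt, int loss) {
  mat d = Y - Yt;
  mat g;
  switch (loss) {
  case 0: g = 2.0 * d; break;
  case 1: g = sign(d); break;
  case 2: g = clamp(d, -1.0, 1.0); break;
  default: g = tanh(d); break;
  }
  return g / d.n_elem;
}

// [[Rcpp::export(name = ".net_step")]]
Rcpp::List net_step(const arma::cube& X, const arma::mat& Yt,
                    const Rcpp::List& params, const Rcpp::List& spec) {
  NetSpec ns = parse_spec(spec);
  std::vector<LayerCache> caches;
  mat head_vec = stack_forward(ns, params, X, caches);
  HeadCache hc;
  head_forward(ns, params, head_vec, hc);
  double lo = loss_value(hc.Y, Yt, ns.loss);
  Rcpp::List grads;
  if (!std::isfinite(lo))
    return Rcpp::List::create(Rcpp::Named("loss") = lo,
                              Rcpp::Named("grads") = grads);

  mat dP = act_dpre(loss_grad(hc.Y, Yt, ns.loss), hc.P, hc.Y, ns.out_act);
  const uword B = dP.n_rows, O = dP.n_cols;
  mat headW = Rcpp::as<mat>(params["head.W"]);
  mat d_head;
  if (ns.htype == 0) {
    grads["head.W"] = hc.head_vec.t() * dP;
    grads["head.b"] = rowvec(sum(dP, 0));
    d_head = dP * headW.t();
  } else {
    const uword H = hc.dec.H.n_cols;
    mat dW(H, 1, fill::zeros);
    cube dHdec(B, H, O, fill::zeros);
    for (uword o = 0; o < O; ++o) {
      dW += hc.dec.H.slice(o).t() * dP.col(o);
      dHdec.slice(o) = dP.col(o) * headW.t();
    }
    grads["head.W"] = dW;
    grads["head.b"] = accu(dP);
    CellGrads cg;
    mat decW = Rcpp::as<mat>(params["dec.W"]);
    mat decU = Rcpp::as<mat>(params["dec.U"]);
    cell_bwd(ns.cell.back(), hc.Xdec, decW, decU, ns.act, hc.dec, dHdec, cg);
    grads["dec.W"] = cg.dW;
    grads["dec.U"] = cg.dU;
    grads["dec.b"] = cg.db;
    d_head = sum(cg.dX, 2); // context fed at every decoder step
  }

  const uword L = ns.ltype.size();
  cube dOut;
  { // zero gradient wrt the final layer's output sequence
    const LayerCache& lc = caches[L - 1];
    if (ns.ltype[L - 1] == 1) {
      dOut.zeros(lc.cc.H.n_rows, 2 * lc.cc.H.n_cols, lc.cc.H.n_slices);
    } else {
      dOut.zeros(lc.cc.H.n_rows, lc.cc.H.n_cols, lc.cc.H.n_slices);
    }
  }
  for (uword li = L; li-- > 0;) {
    std::string nm = "L" + std::to_string(li + 1);
    LayerCache& lc = caches[li];
    bool is_last = (li == L - 1);
    if (ns.ltype[li] == 2) {
      cube K = Rcpp::as<cube>(params[nm + ".K"]);
      const uword F = lc.X.n_cols, T = lc.X.n_slices;
      const uword Fo = K.n_cols, Kw = K.n_slices, Tc = lc.convP.n_slices,
                  Tp = dOut.n_slices;
      cube dY(dOut.n_rows, Fo, Tc, fill::zeros);
      for (uword t = 0; t < Tp; ++t) {
        mat pick = conv_to<mat>::from(lc.convAmax.slice(t));
        dY.slice(2 * t) += dOut.slice(t) % (1.0 - pick);
        dY.slice(2 * t + 1) += dOut.slice(t) % pick;
      }
      cube dX(dOut.n_rows, F, T, fill::zeros), dK(F, Fo, Kw, fill::zeros);
      rowvec db(Fo, fill::zeros);
      for (uword t = 0; t < Tc; ++t) {
        mat dp = act_dpre(dY.slice(t), lc.convP.slice(t), lc.convY.slice(t), ns.act);
        db += sum(dp, 0);
        for (uword k = 0; k < Kw; ++k) {
          dX.slice(t + k) += dp * K.slice(k).t();
          dK.slice(k) += lc.X.slice(t + k).t() * dp;
        }
      }
      grads[nm + ".K"] = dK;
      grads[nm + ".cb"] = db;
      dOut = dX;
    } else if (ns.ltype[li] == 1) {
      const uword H = lc.cc.H.n_cols, T = lc.X.n_slices;
      cube dF(dOut.n_rows, H, T), dG(dOut.n_rows, H, T);
      for (uword t = 0; t < T; ++t) {
        dF.slice(t) = dOut.slice(t).cols(0, H - 1);
        dG.slice(t) = dOut.slice(T - 1 - t).cols(H, 2 * H - 1);
      }
      if (is_last) {
        dF.slice(T - 1) += d_head.cols(0, H - 1);
        dG.slice(T - 1) += d_head.cols(H, 2 * H - 1);
      }
      CellGrads rf, rb;
      cell_bwd(ns.cell[li], lc.X, Rcpp::as<mat>(params[nm + ".fwd.W"]),
               Rcpp::as<mat>(params[nm + ".fwd.U"]), ns.act, lc.cc, dF, rf);
      cube Xr = rev_time(lc.X);
      cell_bwd(ns.cell[li], Xr, Rcpp::as<mat>(params[nm + ".bwd.W"]),
               Rcpp::as<mat>(params[nm + ".bwd.U"]), ns.act, lc.cc_bwd, dG, rb);
      grads[nm + ".fwd.W"] = rf.dW; grads[nm + ".fwd.U"] = rf.dU;
      grads[nm + ".fwd.b"] = rf.db;
      grads[nm + ".bwd.W"] = rb.dW; grads[nm + ".bwd.U"] = rb.dU;
      grads[nm + ".bwd.b"] = rb.db;
      dOut = rf.dX + rev_time(rb.dX);
    } else {
      if (is_last) dOut.slice(lc.X.n_slices - 1) += d_head;
      CellGrads cg;
      cell_bwd(ns.cell[li], lc.X, Rcpp::as<mat>(params[nm + ".W"]),
               Rcpp::as<mat>(params[nm + ".U"]), ns.act, lc.cc, dOut, cg);
      grads[nm + ".W"] = cg.dW; grads[nm + ".U"] = cg.dU;
      grads[nm + ".b"] = cg.db;
      dOut = cg.dX;
    }
  }
  return Rcpp::List::create(Rcpp::Named("loss") = lo,
                            Rcpp::Named("grads") = grads,
                            Rcpp::Named("Y") = hc.Y);
}
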