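// Batched forward / backward pass of the BiLSTM multi-attention network.
//
// Layout conventions
//   - The input array X arrives from R with dim (B, L, 20), column-major,
//     so it is viewed as a (B*L) x 20 matrix whose row index is i + t*B
//     (record i, position t).  C, Hcat, T, scores and attention reuse the
//     same row indexing.
//   - The backward LSTM direction runs over reversed, left-aligned copies
//     of each sequence so that padding never precedes real residues; the
//     index map revsrc[] (an involution on valid rows) converts between
//     the two layouts.
//   - LSTM gate order inside the 4D-wide blocks: input, forget, cell
//     candidate, output.  Initial hidden and cell states of both
//     directions are learned affine maps of the scalar group flag.
//
// The pure-R layer functions in R/net_ops.R define the semantics; this
// file must agree with them to numerical precision (tested), and adds the
// analytic gradients used for training.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double EPS = 1e-12;

struct DirParams {
  mat Wx, Wh;
  vec b, wh0, bh0, wc0, bc0;
};

struct Params {
  mat W1; vec b1;
  DirParams f, b;
  mat Wa; vec ba; mat Va;
  mat W2; vec b2; mat W3; vec b3;
};

static mat getm(const Rcpp::List& L, const char* n) {
  return Rcpp::as<mat>(L[n]);
}
static vec getv(const Rcpp::List& L, const char* n) {
  return Rcpp::as<vec>(L[n]);
}

static Params read_params(const Rcpp::List& pl) {
  Params p;
  p.W1 = getm(pl, "W1"); p.b1 = getv(pl, "b1");
  p.f = {getm(pl, "Wx_f"), getm(pl, "Wh_f"), getv(pl, "b_f"),
         getv(pl, "wh0_f"), getv(pl, "bh0_f"), getv(pl, "wc0_f"), getv(pl, "bc0_f")};
  p.b = {getm(pl, "Wx_b"), getm(pl, "Wh_b"), getv(pl, "b_b"),
         getv(pl, "wh0_b"), getv(pl, "bh0_b"), getv(pl, "wc0_b"), getv(pl, "bc0_b")};
  p.Wa = getm(pl, "Wa"); p.ba = getv(pl, "ba"); p.Va = getm(pl, "Va");
  p.W2 = getm(pl, "W2"); p.b2 = getv(pl, "b2");
  p.W3 = getm(pl, "W3"); p.b3 = getv(pl, "b3");
  return p;
}

static mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct LstmCache {
  cube I, Fg, G, O, Tc, Cc, Hs;  // gates, tanh(c), cell state, hidden state
  mat h0, c0;
};

// One LSTM direction over the whole batch; Cmat is (B*L) x F, Hout is
// (B*L) x D.  States at t >= len(i) evolve over padding but are masked by
// the caller and receive zero gradient.
static void lstm_forward(const mat& Cmat, const DirParams& dp, const vec& g,
                         int B, int L, int D, LstmCache& cc, mat& Hout,
                         bool keep_cache) {
  mat h = g * dp.wh0.t();  h.each_row() += dp.bh0.t();
  mat c = g * dp.wc0.t();  c.each_row() += dp.bc0.t();
  if (keep_cache) {
    cc.I.set_size(B, D, L); cc.Fg.set_size(B, D, L); cc.G.set_size(B, D, L);
    cc.O.set_size(B, D, L); cc.Tc.set_size(B, D, L); cc.Cc.set_size(B, D, L);
    cc.Hs.set_size(B, D, L);
    cc.h0 = h; cc.c0 = c;
  }
  for (int t = 0; t < L; ++t) {
    mat Z = Cmat.rows(t * B, t * B + B - 1) * dp.Wx + h * dp.Wh;
    Z.each_row() += dp.b.t();
    mat gi = sigmoid(Z.cols(0, D - 1));
    mat gf = sigmoid(Z.cols(D, 2 * D - 1));
    mat gg = tanh(Z.cols(2 * D, 3 * D - 1));
    mat go = sigmoid(Z.cols(3 * D, 4 * D - 1));
    c = gf % c + gi % gg;
    mat tc = tanh(c);
    h = go % tc;
    Hout.rows(t * B, t * B + B - 1) = h;
    if (keep_cache) {
      cc.I.slice(t) = gi; cc.Fg.slice(t) = gf; cc.G.slice(t) = gg;
      cc.O.slice(t) = go; cc.Tc.slice(t) = tc; cc.Cc.slice(t) = c;
      cc.Hs.slice(t) = h;
    }
  }
}

struct DirGrads {
  mat dWx, dWh;
  vec db, dwh0, dbh0, dwc0, dbc0;
};

static void lstm_backward(const mat& Cmat, const DirParams& dp,
                          const LstmCache& cc, const mat& dH, const vec& g,
                          int B, int L, int D, DirGrads& gr, mat& dCmat) {
  gr.dWx.zeros(dp.Wx.n_rows, dp.Wx.n_cols);
  gr.dWh.zeros(dp.Wh.n_rows, dp.Wh.n_cols);
  gr.db.zeros(4 * D);
  mat dh_next(B, D, fill::zeros), dc_next(B, D, fill::zeros);
  for (int t = L - 1; t >= 0; --t) {
    mat dh = dH.rows(t * B, t * B + B - 1) + dh_next;
    const mat& gi = cc.I.slice(t); const mat& gf = cc.Fg.slice(t);
    const mat& gg = cc.G.slice(t); const mat& go = cc.O.slice(t);
    const mat& tc = cc.Tc.slice(t);
    mat dgo = dh % tc;
    mat dc = dh % go % (1.0 - tc % tc) + dc_next;
    mat cprev = (t > 0) ? cc.Cc.slice(t - 1) : cc.c0;
    mat dgi = dc % gg, dgg = dc % gi, dgf = dc % cprev;
    dc_next = dc % gf;
    mat dZ(B, 4 * D);
    dZ.cols(0, D - 1)         = dgi % gi % (1.0 - gi);
    dZ.cols(D, 2 * D - 1)     = dgf % gf % (1.0 - gf);
    dZ.cols(2 * D, 3 * D - 1) = dgg % (1.0 - gg % gg);
    dZ.cols(3 * D, 4 * D - 1) = dgo % go % (1.0 - go);
    mat Ct = Cmat.rows(t * B, t * B + B - 1);
    gr.dWx += Ct.t() * dZ;
    mat hprev = (t > 0) ? cc.Hs.slice(t - 1) : cc.h0;
    gr.dWh += hprev.t() * dZ;
    gr.db += sum(dZ, 0).t();
    dCmat.rows(t * B, t * B + B - 1) += dZ * dp.Wx.t();
    dh_next = dZ * dp.Wh.t();
  }
  gr.dwh0 = dh_next.t() * g;
  gr.dbh0 = sum(dh_next, 0).t();
  gr.dwc0 = dc_next.t() * g;
  gr.dbc0 = sum(dc_next, 0).t();
}

// Full forward pass; fills everything backward() needs.
struct ForwardState {
  int B, L, F, D, A, K, S;
  uvec revsrc;            // row i+t*B -> reversed-layout source row; B*L = invalid
  mat Cpre, Cd;           // pre-activation features; post relu+dropout
  mat Crev;               // reversed layout of Cd
  LstmCache cf, cb;
  mat Hd;                 // concatenated, masked, dropped hidden states (B*L x 2D)
  mat Tpre_tanh;          // tanh(Hd*Wa + ba)
  mat Amat;               // attention (B*L x K)
  mat E, Upre, U;         // context (B x K*2D), summary pre/post
  mat P;                  // class probabilities (B x 5)
  mat M1, M2, M3;         // dropout masks (scaled); empty when not training
};

static void forward_pass(const Params& p, const mat& Xm,
                         const Rcpp::IntegerVector& lengths, const vec& g,
                         double dropout, unsigned int seed, bool training,
                         ForwardState& st) {
  const int B = g.n_elem, L = Xm.n_rows / B;
  const int F = p.W1.n_cols, D = p.f.Wh.n_rows;
  const int A = p.Wa.n_cols, K = p.Va.n_cols, S = p.W2.n_cols;
  st.B = B; st.L = L; st.F = F; st.D = D; st.A = A; st.K = K; st.S = S;

  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  auto make_mask = [&](int nr, int nc) {
    mat m(nr, nc);
    double keep = 1.0 - dropout;
    for (int j = 0; j < nc; ++j)       // column-major fill, deterministic
      for (int i = 0; i < nr; ++i)
        m(i, j) = (unif(rng) < keep) ? 1.0 / keep : 0.0;
    return m;
  };
  bool drop = training && dropout > 0;

  st.Cpre = Xm * p.W1;
  st.Cpre.each_row() += p.b1.t();
  st.Cd = clamp(st.Cpre, 0.0, datum::inf);
  if (drop) { st.M1 = make_mask(B * L, F); st.Cd %= st.M1; }

  // reversed, left-aligned layout
  st.revsrc.set_size(B * L);
  st.revsrc.fill(B * L);
  for (int i = 0; i < B; ++i) {
    int len = lengths[i];
    for (int t = 0; t < len; ++t)
      st.revsrc[i + t * B] = i + (len - 1 - t) * B;
  }
  st.Crev.zeros(B * L, F);
  for (int r = 0; r < B * L; ++r)
    if (st.revsrc[r] < (unsigned)(B * L)) st.Crev.row(r) = st.Cd.row(st.revsrc[r]);

  mat Hf(B * L, D), Hbrev(B * L, D);
  lstm_forward(st.Cd, p.f, g, B, L, D, st.cf, Hf, training);
  lstm_forward(st.Crev, p.b, g, B, L, D, st.cb, Hbrev, training);

  st.Hd.zeros(B * L, 2 * D);
  for (int r = 0; r < B * L; ++r) {
    if (st.revsrc[r] >= (unsigned)(B * L)) continue;  // padding stays zero
    st.Hd(r, span(0, D - 1)) = Hf.row(r);
    st.Hd(r, span(D, 2 * D - 1)) = Hbrev.row(st.revsrc[r]);
  }
  if (drop) { st.M2 = make_mask(B * L, 2 * D); st.Hd %= st.M2; }

  st.Tpre_tanh = tanh(st.Hd * p.Wa + repmat(p.ba.t(), B * L, 1));
  mat Sc = st.Tpre_tanh * p.Va;           // B*L x K
  st.Amat.zeros(B * L, K);
  for (int i = 0; i < B; ++i) {
    int len = lengths[i];
    for (int k = 0; k < K; ++k) {
      double mx = -datum::inf;
      for (int t = 0; t < len; ++t) mx = std::max(mx, Sc(i + t * B, k));
      double tot = 0;
      for (int t = 0; t < len; ++t) {
        double e = std::exp(Sc(i + t * B, k) - mx);
        st.Amat(i + t * B, k) = e;
        tot += e;
      }
      for (int t = 0; t < len; ++t) st.Amat(i + t * B, k) /= tot;
    }
  }

  st.E.set_size(B, K * 2 * D);
  for (int i = 0; i < B; ++i) {
    int len = lengths[i];
    uvec idx(len);
    for (int t = 0; t < len; ++t) idx[t] = i + t * B;
    mat Ai = st.Amat.rows(idx);           // len x K
    mat Hi = st.Hd.rows(idx);             // len x 2D
    mat Ei = Ai.t() * Hi;                 // K x 2D, row k = head k
    st.E.row(i) = vectorise(Ei.t()).t();  // head-major flatten
  }

  st.Upre = st.E * p.W2;
  st.Upre.each_row() += p.b2.t();
  st.U = clamp(st.Upre, 0.0, datum::inf);
  if (drop) { st.M3 = make_mask(B, S); st.U %= st.M3; }

  mat Ylin = st.U * p.W3;
  Ylin.each_row() += p.b3.t();
  st.P.set_size(B, 5);
  for (int i = 0; i < B; ++i) {
    rowvec r = Ylin.row(i);
    r -= r.max();
    rowvec e = exp(r);
    st.P.row(i) = e / accu(e);
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_forward(Rcpp::List params, Rcpp::NumericVector X,
                       Rcpp::IntegerVector lengths, Rcpp::NumericVector group) {
  Params p = read_params(params);
  Rcpp::IntegerVector dims = X.attr("dim");
  int B = dims[0], L = dims[1];
  mat Xm(X.begin(), B * L, 20, false);
  vec g(group.begin(), B);
  ForwardState st;
  forward_pass(p, Xm, lengths, g, 0.0, 0u, false, st);
  Rcpp::NumericVector Aout(B * st.K * L);
  for (int i = 0; i < B; ++i)
    for (int k = 0; k < st.K; ++k)
      for (int t = 0; t < L; ++t)
        Aout[i + (size_t)B * (k + (size_t)st.K * t)] = st.Amat(i + t * B, k);
  Aout.attr("dim") = Rcpp::IntegerVector::create(B, st.K, L);
  return Rcpp::List::create(Rcpp::Named("class_probs") = st.P,
                            Rcpp::Named("attention") = Aout);
}

// [[Rcpp::export]]
Rcpp::List cpp_train_step(Rcpp::List params, Rcpp::NumericVector X,
                          Rcpp::IntegerVector lengths, Rcpp::NumericVector group,
                          Rcpp::IntegerVector class_targets,  // 0-based
                          Rcpp::IntegerVector cs_targets,     // 0-based, -1 = none
                          double dropout, int dropout_seed) {
  Params p = read_params(params);
  Rcpp::IntegerVector dims = X.attr("dim");
  int B = dims[0], L = dims[1];
  mat Xm(X.begin(), B * L, 20, false);
  vec g(group.begin(), B);
  for (int i = 0; i < B; ++i)
    if (cs_targets[i] >= lengths[i])
      Rcpp::stop("cleavage-site target beyond sequence end (record %d)", i + 1);
  ForwardState st;
  forward_pass(p, Xm, lengths, g, dropout, (unsigned)dropout_seed, true, st);
  const int D = st.D, K = st.K;

  // ---- loss -------------------------------------------------------------
  double lc = 0;
  for (int i = 0; i < B; ++i)
    lc += -std::log(std::max(st.P(i, class_targets[i]), EPS));
  lc /= B;
  std::vector<int> pos;
  for (int i = 0; i < B; ++i) if (cs_targets[i] >= 0) pos.push_back(i);
  int npos = pos.size();
  double lcs = 0;
  for (int i : pos) {
    int head = class_targets[i] - 1;    // classes 2..5 -> heads 0..3
    lcs += -std::log(std::max(st.Amat(i + cs_targets[i] * B, head), EPS));
  }
  if (npos > 0) lcs /= npos;
  double wc = (npos > 0) ? 0.5 : 1.0;
  double loss = (npos > 0) ? 0.5 * (lc + lcs) : lc;

  // ---- output layer -----------------------------------------------------
  mat dYlin = st.P;
  for (int i = 0; i < B; ++i) dYlin(i, class_targets[i]) -= 1.0;
  dYlin *= wc / B;
  mat dW3 = st.U.t() * dYlin;
  vec db3 = sum(dYlin, 0).t();
  mat dU = dYlin * p.W3.t();
  if (!st.M3.is_empty()) dU %= st.M3;
  dU %= conv_to<mat>::from(st.Upre > 0);
  mat dW2 = st.E.t() * dU;
  vec db2 = sum(dU, 0).t();
  mat dE = dU * p.W2.t();

  // ---- context and attention --------------------------------------------
  mat dAmat(B * L, K, fill::zeros);
  mat dHd(B * L, 2 * D, fill::zeros);
  for (int i = 0; i < B; ++i) {
    int len = lengths[i];
    uvec idx(len);
    for (int t = 0; t < len; ++t) idx[t] = i + t * B;
    vec v = dE.row(i).t();
    mat dEi = mat(v.memptr(), 2 * D, K).t();   // K x 2D, head-major
    mat Ai = st.Amat.rows(idx);
    mat Hi = st.Hd.rows(idx);
    dAmat.rows(idx) += Hi * dEi.t();
    dHd.rows(idx) += Ai * dEi;
  }
  for (int i : pos) {
    int head = class_targets[i] - 1;
    int r = i + cs_targets[i] * B;
    dAmat(r, head) += -(0.5 / npos) / std::max(st.Amat(r, head), EPS);
  }
  // softmax jacobian per (record, head)
  mat dSc(B * L, K, fill::zeros);
  for (int i = 0; i < B; ++i) {
    int len = lengths[i];
    for (int k = 0; k < K; ++k) {
      double s = 0;
      for (int t = 0; t < len; ++t)
        s += st.Amat(i + t * B, k) * dAmat(i + t * B, k);
      for (int t = 0; t < len; ++t) {
        int r = i + t * B;
        dSc(r, k) = st.Amat(r, k) * (dAmat(r, k) - s);
      }
    }
  }
  mat dVa = st.Tpre_tanh.t() * dSc;
  mat dT = dSc * p.Va.t();
  mat dTpre = dT % (1.0 - st.Tpre_tanh % st.Tpre_tanh);
  mat dWa = st.Hd.t() * dTpre;
  vec dba = sum(dTpre, 0).t();
  dHd += dTpre * p.Wa.t();

  if (!st.M2.is_empty()) dHd %= st.M2;
  for (int r = 0; r < B * L; ++r)                 // padding carries no gradient
    if (st.revsrc[r] >= (unsigned)(B * L)) dHd.row(r).zeros();

  mat dHf = dHd.cols(0, D - 1);
  mat dHbrev(B * L, D, fill::zeros);
  for (int r = 0; r < B * L; ++r)
    if (st.revsrc[r] < (unsigned)(B * L))
      dHbrev.row(st.revsrc[r]) = dHd(r, span(D, 2 * D - 1));

  DirGrads gf_, gb_;
  mat dCd(B * L, st.F, fill::zeros), dCrev(B * L, st.F, fill::zeros);
  lstm_backward(st.Cd, p.f, st.cf, dHf, g, B, L, D, gf_, dCd);
  lstm_backward(st.Crev, p.b, st.cb, dHbrev, g, B, L, D, gb_, dCrev);
  for (int r = 0; r < B * L; ++r)
    if (st.revsrc[r] < (unsigned)(B * L)) dCd.row(st.revsrc[r]) += dCrev.row(r);

  if (!st.M1.is_empty()) dCd %= st.M1;
  dCd %= conv_to<mat>::from(st.Cpre > 0);
  mat dW1 = Xm.t() * dCd;
  vec db1 = sum(dCd, 0).t();

  Rcpp::List grads = Rcpp::List::create(
    Rcpp::Named("W1") = dW1, Rcpp::Named("b1") = db1,
    Rcpp::Named("Wx_f") = gf_.dWx, Rcpp::Named("Wh_f") = gf_.dWh,
    Rcpp::Named("b_f") = gf_.db,
    Rcpp::Named("wh0_f") = gf_.dwh0, Rcpp::Named("bh0_f") = gf_.dbh0,
    Rcpp::Named("wc0_f") = gf_.dwc0, Rcpp::Named("bc0_f") = gf_.dbc0,
    Rcpp::Named("Wx_b") = gb_.dWx, Rcpp::Named("Wh_b") = gb_.dWh,
    Rcpp::Named("b_b") = gb_.db,
    Rcpp::Named("wh0_b") = gb_.dwh0, Rcpp::Named("bh0_b") = gb_.dbh0,
    Rcpp::Named("wc0_b") = gb_.dwc0, Rcpp::Named("bc0_b") = gb_.dbc0,
    Rcpp::Named("Wa") = dWa, Rcpp::Named("ba") = dba, Rcpp::Named("Va") = dVa,
    Rcpp::Named("W2") = dW2, Rcpp::Named("b2") = db2,
    Rcpp::Named("W3") = dW3, Rcpp::Named("b3") = db3);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("class_loss") = lc,
                            Rcpp::Named("cs_loss") = (npos > 0) ? lcs : NA_REAL,
                            Rcpp::Named("grads") = grads);
}
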