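// Mask-aware hierarchical attention recurrent network.
//
// Forward and analytic backward passes for the full architecture:
//   1. per-period variable-level recurrence (GRU or LSTM) over the V
//      variables of each real period, each scalar value lifted by a learned
//      per-variable embedding (value * E_v + b_v);
//   2. additive attention over the per-variable outputs, masked-softmaxed
//      over the value mask, giving alpha and the period context;
//   3. bidirectional recurrence over the period contexts with
//      state-pass-through at padded periods (so padding is exactly inert);
//   4. additive attention over the bidirectional outputs, masked-softmaxed
//      over the period mask, giving beta and the patient summary;
//   5. concatenation with static features, optional ReLU dense layer,
//      sigmoid output.
//
// Masked recurrent steps use skip semantics (state passes through
// unchanged), which makes the padding-invariance and missing-invariance
// contracts exact rather than approximate.
//
// Real periods are packed into rows (patient, period) so padded periods
// cost nothing in the inner recurrence.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// masked softmax over the columns of S (one distribution per row);
// all-masked rows yield an all-zero distribution
static mat masked_softmax_rows(const mat& S, const mat& M) {
  mat out(size(S), fill::zeros);
  for (uword r = 0; r < S.n_rows; ++r) {
    double mx = -datum::inf;
    for (uword c = 0; c < S.n_cols; ++c)
      if (M(r, c) > 0.5 && S(r, c) > mx) mx = S(r, c);
    if (!std::isfinite(mx)) continue;           // all masked
    double tot = 0.0;
    for (uword c = 0; c < S.n_cols; ++c) {
      if (M(r, c) > 0.5) {
        double e = std::exp(S(r, c) - mx);
        out(r, c) = e; tot += e;
      }
    }
    out.row(r) /= tot;
  }
  return out;
}

struct GruParams {
  mat Wx, Wh_rz, Wh_h; rowvec b;  // b = [b_r, b_z, b_h]
};
struct LstmParams {
  mat Wx, Wh; rowvec b;           // gate order i, f, o, g
};
struct AttParams {
  mat W; rowvec b; vec v;
};

static GruParams gru_params(const Rcpp::List& p, const std::string& pre) {
  GruParams g;
  g.Wx = Rcpp::as<mat>(p[pre + "_Wx"]);
  g.Wh_rz = Rcpp::as<mat>(p[pre + "_Wh_rz"]);
  g.Wh_h = Rcpp::as<mat>(p[pre + "_Wh_h"]);
  g.b = Rcpp::as<rowvec>(p[pre + "_b"]);
  return g;
}
static LstmParams lstm_params(const Rcpp::List& p, const std::string& pre) {
  LstmParams l;
  l.Wx = Rcpp::as<mat>(p[pre + "_Wx"]);
  l.Wh = Rcpp::as<mat>(p[pre + "_Wh"]);
  l.b = Rcpp::as<rowvec>(p[pre + "_b"]);
  return l;
}
static AttParams att_params(const Rcpp::List& p, const std::string& pre) {
  AttParams a;
  a.W = Rcpp::as<mat>(p[pre + "_W"]);
  a.b = Rcpp::as<rowvec>(p[pre + "_b"]);
  a.v = Rcpp::as<vec>(p[pre + "_v"]);
  return a;
}

// ---------------------------------------------------------------------------
// inner (variable-level) encoder over packed rows
// ---------------------------------------------------------------------------

struct InnerCache {
  cube H;                  // state after each variable step   [R x U x V]
  cube r, z, hh;           // GRU gates                        [R x U x V]
  cube gi, gf, go, gg, C;  // LSTM gates and cell states       [R x U x V]
  mat S;                   // raw attention scores             [R x V]
  mat alpha;               // attention weights                [R x V]
  mat ctx;                 // period contexts                  [R x U]
  mat xg, mg;              // gathered values / value masks    [R x V]
};

// gather packed rows from the (B, T, V) tensors
static void gather_rows(const cube& X, const cube& Mv,
                        const uvec& rb, const uvec& rt,
                        mat& xg, mat& mg) {
  const uword R = rb.n_elem, V = X.n_slices;
  xg.set_size(R, V); mg.set_size(R, V);
  for (uword v = 0; v < V; ++v) {
    const mat& Xs = X.slice(v);
    const mat& Ms = Mv.slice(v);
    for (uword r = 0; r < R; ++r) {
      xg(r, v) = Xs(rb(r), rt(r));
      mg(r, v) = Ms(rb(r), rt(r));
    }
  }
}

static void inner_forward(const Rcpp::List& p, int rnn_type,
                          const cube& X, const cube& Mv,
                          const uvec& rb, const uvec& rt,
                          bool keep_gates, InnerCache& cc) {
  const mat embW = Rcpp::as<mat>(p["emb_W"]);
  const mat embB = Rcpp::as<mat>(p["emb_b"]);
  const AttParams att = att_params(p, "in_att");
  const uword V = X.n_slices, R = rb.n_elem;

  gather_rows(X, Mv, rb, rt, cc.xg, cc.mg);
  // value masking: zero inputs at unrecorded positions (defensive; the
  // tensor contract already zeroes them)
  cc.xg %= cc.mg;

  if (rnn_type == 0) {
    const GruParams g = gru_params(p, "in");
    const uword U = g.Wh_h.n_rows;
    // fold the scalar embedding through Wx:  e_v Wx = x * Px.row(v) + Qx.row(v)
    const mat Px = embW * g.Wx;   // V x 3U
    const mat Qx = embB * g.Wx;
    cc.H.set_size(R, U, V);
    if (keep_gates) { cc.r.set_size(R, U, V); cc.z.set_size(R, U, V);
                      cc.hh.set_size(R, U, V); }
    mat Hprev(R, U, fill::zeros);
    for (uword v = 0; v < V; ++v) {
      const vec xv = cc.xg.col(v);
      const vec mv = cc.mg.col(v);
      mat Arz = xv * Px(v, span(0, 2 * U - 1)) + Hprev * g.Wh_rz;
      Arz.each_row() += Qx(v, span(0, 2 * U - 1)) + g.b.cols(0, 2 * U - 1);
      mat r = sigm(Arz.cols(0, U - 1));
      mat z = sigm(Arz.cols(U, 2 * U - 1));
      mat rh = r % Hprev;
      mat Ah = xv * Px(v, span(2 * U, 3 * U - 1)) + rh * g.Wh_h;
      Ah.each_row() += Qx(v, span(2 * U, 3 * U - 1)) + g.b.cols(2 * U, 3 * U - 1);
      mat hh = tanh(Ah);
      mat Hnew = Hprev + z % (hh - Hprev);
      mat H = Hprev + mat(Hnew - Hprev).each_col() % mv;
      cc.H.slice(v) = H;
      if (keep_gates) { cc.r.slice(v) = r; cc.z.slice(v) = z;
                        cc.hh.slice(v) = hh; }
      Hprev = std::move(H);
    }
  } else {
    const LstmParams l = lstm_params(p, "in");
    const uword U = l.Wh.n_rows;
    const mat Px = embW * l.Wx;   // V x 4U
    const mat Qx = embB * l.Wx;
    cc.H.set_size(R, U, V);
    cc.C.set_size(R, U, V);
    if (keep_gates) { cc.gi.set_size(R, U, V); cc.gf.set_size(R, U, V);
                      cc.go.set_size(R, U, V); cc.gg.set_size(R, U, V); }
    mat Hprev(R, U, fill::zeros), Cprev(R, U, fill::zeros);
    for (uword v = 0; v < V; ++v) {
      const vec xv = cc.xg.col(v);
      const vec mv = cc.mg.col(v);
      mat A = xv * Px.row(v) + Hprev * l.Wh;
      A.each_row() += Qx.row(v) + l.b;
      mat gi = sigm(A.cols(0, U - 1));
      mat gf = sigm(A.cols(U, 2 * U - 1));
      mat go = sigm(A.cols(2 * U, 3 * U - 1));
      mat gg = tanh(A.cols(3 * U, 4 * U - 1));
      mat Cnew = gf % Cprev + gi % gg;
      mat Hnew = go % tanh(Cnew);
      mat C = Cprev + mat(Cnew - Cprev).each_col() % mv;
      mat H = Hprev + mat(Hnew - Hprev).each_col() % mv;
      cc.H.slice(v) = H; cc.C.slice(v) = C;
      if (keep_gates) { cc.gi.slice(v) = gi; cc.gf.slice(v) = gf;
                        cc.go.slice(v) = go; cc.gg.slice(v) = gg; }
      Hprev = std::move(H); Cprev = std::move(C);
    }
  }

  // variable-level additive attention over the per-step outputs
  const uword U = cc.H.n_cols;
  cc.S.set_size(R, V);
  for (uword v = 0; v < V; ++v) {
    mat u = tanh(cc.H.slice(v) * att.W + repmat(att.b, R, 1));
    cc.S.col(v) = u * att.v;
  }
  cc.alpha = masked_softmax_rows(cc.S, cc.mg);
  cc.ctx.zeros(R, U);
  for (uword v = 0; v < V; ++v)
    cc.ctx += cc.H.slice(v).each_col() % cc.alpha.col(v);
}

// backward through the inner encoder; dctx is the gradient at the period
// contexts. Returns parameter gradients into `g` (accumulated).
static void inner_backward(const Rcpp::List& p, int rnn_type,
                           const InnerCache& cc, const mat& dctx,
                           Rcpp::List& g) {
  const mat embW = Rcpp::as<mat>(p["emb_W"]);
  const mat embB = Rcpp::as<mat>(p["emb_b"]);
  const AttParams att = att_params(p, "in_att");
  const uword R = cc.xg.n_rows, V = cc.xg.n_cols, U = cc.H.n_cols;
  const uword A = att.W.n_cols;

  // ---- attention backward ----
  mat dalpha(R, V, fill::zeros);
  cube dH(R, U, V, fill::zeros);
  for (uword v = 0; v < V; ++v) {
    dalpha.col(v) = sum(dctx % cc.H.slice(v), 1);
    dH.slice(v) = dctx.each_col() % cc.alpha.col(v);
  }
  vec rowdot = sum(cc.alpha % dalpha, 1);
  mat dS = cc.alpha % dalpha - cc.alpha.each_col() % rowdot;

  mat dattW(size(att.W), fill::zeros);
  rowvec dattb(A, fill::zeros);
  vec dattv(A, fill::zeros);
  for (uword v = 0; v < V; ++v) {
    mat u = tanh(cc.H.slice(v) * att.W + repmat(att.b, R, 1));
    mat du = dS.col(v) * att.v.t();          // R x A
    dattv += u.t() * dS.col(v);
    mat da = du % (1.0 - u % u);
    dattW += cc.H.slice(v).t() * da;
    dattb += sum(da, 0);
    dH.slice(v) += da * att.W.t();
  }
  g["in_att_W"] = Rcpp::as<mat>(g["in_att_W"]) + dattW;
  g["in_att_b"] = Rcpp::as<rowvec>(g["in_att_b"]) + dattb;
  g["in_att_v"] = Rcpp::as<vec>(g["in_att_v"]) + dattv;

  // ---- recurrence backward ----
  if (rnn_type == 0) {
    const GruParams gr = gru_params(p, "in");
    const mat Px = embW * gr.Wx;
    mat dPx(size(Px), fill::zeros), dQx(size(Px), fill::zeros);
    mat dWh_rz(size(gr.Wh_rz), fill::zeros), dWh_h(size(gr.Wh_h), fill::zeros);
    rowvec db(3 * U, fill::zeros);
    mat dHc(R, U, fill::zeros);  // running gradient at the hidden state
    for (sword v = V - 1; v >= 0; --v) {
      dHc += dH.slice(v);
      const vec mv = cc.mg.col(v);
      const mat Hprev = (v == 0) ? mat(R, U, fill::zeros)
                                 : mat(cc.H.slice(v - 1));
      const mat& r = cc.r.slice(v);
      const mat& z = cc.z.slice(v);
      const mat& hh = cc.hh.slice(v);
      mat dEff = dHc.each_col() % mv;          // into the computed branch
      mat dPass = dHc.each_col() % (1.0 - mv); // skip path
      mat dz = dEff % (hh - Hprev);
      mat dhh = dEff % z;
      mat dHprev = dPass + dEff % (1.0 - z);
      mat dAh = dhh % (1.0 - hh % hh);
      mat drh = dAh * gr.Wh_h.t();
      mat dr = drh % Hprev;
      dHprev += drh % r;
      mat dArz = join_rows(dr % r % (1.0 - r), dz % z % (1.0 - z));
      dHprev += dArz * gr.Wh_rz.t();
      dWh_h += (r % Hprev).t() * dAh;
      dWh_rz += Hprev.t() * dArz;
      db.cols(0, 2 * U - 1) += sum(dArz, 0);
      db.cols(2 * U, 3 * U - 1) += sum(dAh, 0);
      const vec xv = cc.xg.col(v);
      mat dAall = join_rows(dArz, dAh);        // R x 3U
      dPx.row(v) += xv.t() * dAall;
      dQx.row(v) += sum(dAall, 0);
      dHc = std::move(dHprev);
    }
    g["in_Wx"] = Rcpp::as<mat>(g["in_Wx"]) + embW.t() * dPx + embB.t() * dQx;
    g["emb_W"] = Rcpp::as<mat>(g["emb_W"]) + dPx * gr.Wx.t();
    g["emb_b"] = Rcpp::as<mat>(g["emb_b"]) + dQx * gr.Wx.t();
    g["in_Wh_rz"] = Rcpp::as<mat>(g["in_Wh_rz"]) + dWh_rz;
    g["in_Wh_h"] = Rcpp::as<mat>(g["in_Wh_h"]) + dWh_h;
    g["in_b"] = Rcpp::as<rowvec>(g["in_b"]) + db;
  } else {
    const LstmParams l = lstm_params(p, "in");
    const mat Px = embW * l.Wx;
    mat dPx(size(Px), fill::zeros), dQx(size(Px), fill::zeros);
    mat dWh(size(l.Wh), fill::zeros);
    rowvec db(4 * U, fill::zeros);
    mat dHc(R, U, fill::zeros), dCc(R, U, fill::zeros);
    for (sword v = V - 1; v >= 0; --v) {
      dHc += dH.slice(v);
      const vec mv = cc.mg.col(v);
      const mat Hprev = (v == 0) ? mat(R, U, fill::zeros)
                                 : mat(cc.H.slice(v - 1));
      const mat Cprev = (v == 0) ? mat(R, U, fill::zeros)
                                 : mat(cc.C.slice(v - 1));
      const mat& gi = cc.gi.slice(v);
      const mat& gf = cc.gf.slice(v);
      const mat& go = cc.go.slice(v);
      const mat& gg = cc.gg.slice(v);
      mat Cnew = gf % Cprev + gi % gg;
      mat tc = tanh(Cnew);
      mat dhEff = dHc.each_col() % mv;
      mat dhPass = dHc.each_col() % (1.0 - mv);
      mat dcEff = dCc.each_col() % mv;
      mat dcPass = dCc.each_col() % (1.0 - mv);
      mat dgo = dhEff % tc;
      mat dC = dcEff + dhEff % go % (1.0 - tc % tc);
      mat dgi = dC % gg;
      mat dgf = dC % Cprev;
      mat dgg = dC % gi;
      mat dCprev = dcPass + dC % gf;
      mat dA = join_rows(join_rows(dgi % gi % (1.0 - gi),
                                   dgf % gf % (1.0 - gf)),
                         join_rows(dgo % go % (1.0 - go),
                                   dgg % (1.0 - gg % gg)));
      mat dHprev = dhPass + dA * l.Wh.t();
      dWh += Hprev.t() * dA;
      db += sum(dA, 0);
      const vec xv = cc.xg.col(v);
      dPx.row(v) += xv.t() * dA;
      dQx.row(v) += sum(dA, 0);
      dHc = std::move(dHprev);
      dCc = std::move(dCprev);
    }
    g["in_Wx"] = Rcpp::as<mat>(g["in_Wx"]) + embW.t() * dPx + embB.t() * dQx;
    g["emb_W"] = Rcpp::as<mat>(g["emb_W"]) + dPx * l.Wx.t();
    g["emb_b"] = Rcpp::as<mat>(g["emb_b"]) + dQx * l.Wx.t();
    g["in_Wh"] = Rcpp::as<mat>(g["in_Wh"]) + dWh;
    g["in_b"] = Rcpp::as<rowvec>(g["in_b"]) + db;
  }
}

// ---------------------------------------------------------------------------
// time-level recurrence (one direction) over contexts  [B x U x T]
// ---------------------------------------------------------------------------

struct TimeCache {
  cube H;               // [B x U x T] states in step order
  cube r, z, hh;        // GRU
  cube gi, gf, go, gg, C;  // LSTM
};

// dir = +1 processes slices 0..T-1, dir = -1 processes T-1..0;
// H.slice(t) always holds the state at calendar slot t.
static void time_forward(const GruParams* gr, const LstmParams* ls,
                         const cube& Ctx, const mat& m, int dir,
                         bool keep_gates, TimeCache& tc) {
  const uword B = Ctx.n_rows, T = Ctx.n_slices;
  const uword U = gr ? gr->Wh_h.n_rows : ls->Wh.n_rows;
  tc.H.set_size(B, U, T);
  if (gr) {
    if (keep_gates) { tc.r.set_size(B, U, T); tc.z.set_size(B, U, T);
                      tc.hh.set_size(B, U, T); }
    mat Hprev(B, U, fill::zeros);
    for (uword s = 0; s < T; ++s) {
      uword t = (dir > 0) ? s : (T - 1 - s);
      const mat xt = Ctx.slice(t);
      const vec mv = m.col(t);
      mat Arz = xt * gr->Wx.cols(0, 2 * U - 1) + Hprev * gr->Wh_rz;
      Arz.each_row() += gr->b.cols(0, 2 * U - 1);
      mat r = sigm(Arz.cols(0, U - 1));
      mat z = sigm(Arz.cols(U, 2 * U - 1));
      mat Ah = xt * gr->Wx.cols(2 * U, 3 * U - 1) + (r % Hprev) * gr->Wh_h;
      Ah.each_row() += gr->b.cols(2 * U, 3 * U - 1);
      mat hh = tanh(Ah);
      mat Hnew = Hprev + z % (hh - Hprev);
      mat H = Hprev + mat(Hnew - Hprev).each_col() % mv;
      tc.H.slice(t) = H;
      if (keep_gates) { tc.r.slice(t) = r; tc.z.slice(t) = z;
                        tc.hh.slice(t) = hh; }
      Hprev = std::move(H);
    }
  } else {
    if (keep_gates) { tc.gi.set_size(B, U, T); tc.gf.set_size(B, U, T);
                      tc.go.set_size(B, U, T); tc.gg.set_size(B, U, T); }
    tc.C.set_size(B, U, T);
    mat Hprev(B, U, fill::zeros), Cprev(B, U, fill::zeros);
    for (uword s = 0; s < T; ++s) {
      uword t = (dir > 0) ? s : (T - 1 - s);
      const mat xt = Ctx.slice(t);
      const vec mv = m.col(t);
      mat A = xt * ls->Wx + Hprev * ls->Wh;
      A.each_row() += ls->b;
      mat gi = sigm(A.cols(0, U - 1));
      mat gf = sigm(A.cols(U, 2 * U - 1));
      mat go = sigm(A.cols(2 * U, 3 * U - 1));
      mat gg = tanh(A.cols(3 * U, 4 * U - 1));
      mat Cnew = gf % Cprev + gi % gg;
      mat Hnew = go % tanh(Cnew);
      mat C = Cprev + mat(Cnew - Cprev).each_col() % mv;
      mat H = Hprev + mat(Hnew - Hprev).each_col() % mv;
      tc.H.slice(t) = H; tc.C.slice(t) = C;
      if (keep_gates) { tc.gi.slice(t) = gi; tc.gf.slice(t) = gf;
                        tc.go.slice(t) = go; tc.gg.slice(t) = gg; }
      Hprev = std::move(H); Cprev = std::move(C);
    }
  }
}

// backward for one direction; dHout holds gradients at H.slice(t);
// dCtx accumulates input-context gradients; parameter grads accumulate in
// the provided matrices.
static void time_backward(const GruParams* gr, const LstmParams* ls,
                          const cube& Ctx, const mat& m, int dir,
                          const TimeCache& tc, const cube& dHout,
                          cube& dCtx,
                          mat& dWx, mat& dWh_rz, mat& dWh_h, mat& dWh,
                          rowvec& db) {
  const uword B = Ctx.n_rows, T = Ctx.n_slices;
  const uword U = tc.H.n_cols;
  mat dHc(B, U, fill::zeros), dCc(B, U, fill::zeros);
  for (uword s = 0; s < T; ++s) {
    // reverse of processing order
    uword t = (dir > 0) ? (T - 1 - s) : s;
    bool first = (dir > 0) ? (t == 0) : (t == T - 1);
    uword tprev = (dir > 0) ? t - 1 : t + 1;
    dHc += dHout.slice(t);
    const vec mv = m.col(t);
    const mat Hprev = first ? mat(B, U, fill::zeros) : mat(tc.H.slice(tprev));
    const mat xt = Ctx.slice(t);
    if (gr) {
      const mat& r = tc.r.slice(t);
      const mat& z = tc.z.slice(t);
      const mat& hh = tc.hh.slice(t);
      mat dEff = dHc.each_col() % mv;
      mat dPass = dHc.each_col() % (1.0 - mv);
      mat dz = dEff % (hh - Hprev);
      mat dhh = dEff % z;
      mat dHprev = dPass + dEff % (1.0 - z);
      mat dAh = dhh % (1.0 - hh % hh);
      mat drh = dAh * gr->Wh_h.t();
      mat dr = drh % Hprev;
      dHprev += drh % r;
      mat dArz = join_rows(dr % r % (1.0 - r), dz % z % (1.0 - z));
      dHprev += dArz * gr->Wh_rz.t();
      dWh_h += (r % Hprev).t() * dAh;
      dWh_rz += Hprev.t() * dArz;
      mat dAall = join_rows(dArz, dAh);
      db += sum(dAall, 0);
      dWx += xt.t() * dAall;
      dCtx.slice(t) += dAall * gr->Wx.t();
      dHc = std::move(dHprev);
    } else {
      const mat& gi = tc.gi.slice(t);
      const mat& gf = tc.gf.slice(t);
      const mat& go = tc.go.slice(t);
      const mat& gg = tc.gg.slice(t);
      const mat Cprev = first ? mat(B, U, fill::zeros)
                              : mat(tc.C.slice(tprev));
      mat Cnew = gf % Cprev + gi % gg;
      mat tcn = tanh(Cnew);
      mat dhEff = dHc.each_col() % mv;
      mat dhPass = dHc.each_col() % (1.0 - mv);
      mat dcEff = dCc.each_col() % mv;
      mat dcPass = dCc.each_col() % (1.0 - mv);
      mat dgo = dhEff % tcn;
      mat dC = dcEff + dhEff % go % (1.0 - tcn % tcn);
      mat dgi = dC % gg;
      mat dgf = dC % Cprev;
      mat dgg = dC % gi;
      mat dCprev = dcPass + dC % gf;
      mat dA = join_rows(join_rows(dgi % gi % (1.0 - gi),
                                   dgf % gf % (1.0 - gf)),
                         join_rows(dgo % go % (1.0 - go),
                                   dgg % (1.0 - gg % gg)));
      mat dHprev = dhPass + dA * ls->Wh.t();
      dWh += Hprev.t() * dA;
      db += sum(dA, 0);
      dWx += xt.t() * dA;
      dCtx.slice(t) += dA * ls->Wx.t();
      dHc = std::move(dHprev);
      dCc = std::move(dCprev);
    }
  }
}

// ---------------------------------------------------------------------------
// full forward (+ optional backward)
// ---------------------------------------------------------------------------

static Rcpp::List zero_like(const Rcpp::List& p) {
  Rcpp::List g = Rcpp::clone(p);
  Rcpp::CharacterVector nm = p.names();
  for (int i = 0; i < p.size(); ++i) {
    std::string n = Rcpp::as<std::string>(nm[i]);
    SEXP e = p[n];
    if (Rf_isMatrix(e)) {
      mat z(size(Rcpp::as<mat>(e)), fill::zeros);
      g[n] = z;
    } else {
      vec z(Rcpp::as<vec>(e).n_elem, fill::zeros);
      g[n] = z;
    }
  }
  return g;
}

// [[Rcpp::export]]
Rcpp::List cpp_forward(Rcpp::List params,
                       arma::cube X, arma::cube Mv, arma::mat m,
                       arma::mat S, int rnn_type, int dense,
                       bool want_attention, bool want_grad,
                       Rcpp::Nullable<Rcpp::NumericVector> y_ = R_NilValue) {
  const uword B = X.n_rows, T = X.n_cols, V = X.n_slices;

  // pack real periods
  std::vector<uword> rbv, rtv;
  for (uword t = 0; t < T; ++t)
    for (uword b = 0; b < B; ++b)
      if (m(b, t) > 0.5) { rbv.push_back(b); rtv.push_back(t); }
  uvec rb = conv_to<uvec>::from(rbv), rt = conv_to<uvec>::from(rtv);
  const uword R = rb.n_elem;

  InnerCache cc;
  inner_forward(params, rnn_type, X, Mv, rb, rt, want_grad, cc);
  const uword U = cc.H.n_cols;

  // scatter contexts into calendar slots (padded slots stay zero)
  cube Ctx(B, U, T, fill::zeros);
  for (uword r = 0; r < R; ++r)
    Ctx.slice(rt(r)).row(rb(r)) = cc.ctx.row(r);

  // bidirectional time recurrence
  GruParams gf, gb; LstmParams lf, lb;
  TimeCache tf, tb;
  if (rnn_type == 0) {
    gf = gru_params(params, "tf"); gb = gru_params(params, "tb");
    time_forward(&gf, nullptr, Ctx, m, +1, want_grad, tf);
    time_forward(&gb, nullptr, Ctx, m, -1, want_grad, tb);
  } else {
    lf = lstm_params(params, "tf"); lb = lstm_params(params, "tb");
    time_forward(nullptr, &lf, Ctx, m, +1, want_grad, tf);
    time_forward(nullptr, &lb, Ctx, m, -1, want_grad, tb);
  }

  // time-level attention on [H_fwd ; H_bwd]
  const AttParams oatt = att_params(params, "out_att");
  const uword A = oatt.W.n_cols;
  mat So(B, T);
  for (uword t = 0; t < T; ++t) {
    mat G = join_rows(tf.H.slice(t), tb.H.slice(t));
    mat u = tanh(G * oatt.W + repmat(oatt.b, B, 1));
    So.col(t) = u * oatt.v;
  }
  mat beta = masked_softmax_rows(So, m);
  mat Z(B, 2 * U, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat G = join_rows(tf.H.slice(t), tb.H.slice(t));
    Z += G.each_col() % beta.col(t);
  }

  // head
  mat Zs = join_rows(Z, S);
  const vec head_w = Rcpp::as<vec>(params["head_w"]);
  const double head_b = Rcpp::as<vec>(params["head_b"])(0);
  mat D; vec logits;
  if (dense) {
    const mat dW = Rcpp::as<mat>(params["dense_W"]);
    const rowvec dbias = Rcpp::as<rowvec>(params["dense_b"]);
    D = Zs * dW;
    D.each_row() += dbias;
    D = clamp(D, 0.0, datum::inf);      // ReLU
    logits = D * head_w + head_b;
  } else {
    logits = Zs * head_w + head_b;
  }
  vec pr = 1.0 / (1.0 + exp(-logits));

  Rcpp::List out;
  out["p"] = pr;

  if (want_attention) {
    cube alpha(B, T, V, fill::zeros);
    for (uword v = 0; v < V; ++v)
      for (uword r = 0; r < R; ++r)
        alpha(rb(r), rt(r), v) = cc.alpha(r, v);
    out["alpha"] = alpha;
    out["beta"] = beta;
  }

  if (!want_grad) return out;

  // ---- loss and backward ----
  vec y = Rcpp::as<vec>(y_.get());
  const double eps = 1e-12;
  double loss = -mean(y % log(pr + eps) + (1.0 - y) % log(1.0 - pr + eps));
  vec dlogit = (pr - y) / (double)B;

  Rcpp::List g = zero_like(params);

  mat dZs;
  if (dense) {
    const mat dW = Rcpp::as<mat>(params["dense_W"]);
    mat dD = dlogit * head_w.t();
    dD %= conv_to<mat>::from(D > 0.0);
    g["head_w"] = Rcpp::as<vec>(g["head_w"]) + D.t() * dlogit;
    g["head_b"] = vec{accu(dlogit)};
    g["dense_W"] = Rcpp::as<mat>(g["dense_W"]) + Zs.t() * dD;
    g["dense_b"] = Rcpp::as<rowvec>(g["dense_b"]) + sum(dD, 0);
    dZs = dD * dW.t();
  } else {
    g["head_w"] = Rcpp::as<vec>(g["head_w"]) + Zs.t() * dlogit;
    g["head_b"] = vec{accu(dlogit)};
    dZs = dlogit * head_w.t();
  }
  mat dZ = dZs.cols(0, 2 * U - 1);

  // time-attention backward
  mat dbeta(B, T, fill::zeros);
  cube dG(B, 2 * U, T, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat G = join_rows(tf.H.slice(t), tb.H.slice(t));
    dbeta.col(t) = sum(dZ % G, 1);
    dG.slice(t) = dZ.each_col() % beta.col(t);
  }
  vec rowdot = sum(beta % dbeta, 1);
  mat dSo = beta % dbeta - beta.each_col() % rowdot;
  mat doattW(size(oatt.W), fill::zeros);
  rowvec doattb(A, fill::zeros);
  vec doattv(A, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat G = join_rows(tf.H.slice(t), tb.H.slice(t));
    mat u = tanh(G * oatt.W + repmat(oatt.b, B, 1));
    mat du = dSo.col(t) * oatt.v.t();
    doattv += u.t() * dSo.col(t);
    mat da = du % (1.0 - u % u);
    doattW += G.t() * da;
    doattb += sum(da, 0);
    dG.slice(t) += da * oatt.W.t();
  }
  g["out_att_W"] = Rcpp::as<mat>(g["out_att_W"]) + doattW;
  g["out_att_b"] = Rcpp::as<rowvec>(g["out_att_b"]) + doattb;
  g["out_att_v"] = Rcpp::as<vec>(g["out_att_v"]) + doattv;

  // split dG into the two directions
  cube dHf(B, U, T), dHb(B, U, T);
  for (uword t = 0; t < T; ++t) {
    dHf.slice(t) = dG.slice(t).cols(0, U - 1);
    dHb.slice(t) = dG.slice(t).cols(U, 2 * U - 1);
  }

  cube dCtx(B, U, T, fill::zeros);
  if (rnn_type == 0) {
    mat dWx_f(size(gf.Wx), fill::zeros), dWhrz_f(size(gf.Wh_rz), fill::zeros),
        dWhh_f(size(gf.Wh_h), fill::zeros), dummy;
    rowvec db_f(3 * U, fill::zeros);
    time_backward(&gf, nullptr, Ctx, m, +1, tf, dHf, dCtx,
                  dWx_f, dWhrz_f, dWhh_f, dummy, db_f);
    g["tf_Wx"] = Rcpp::as<mat>(g["tf_Wx"]) + dWx_f;
    g["tf_Wh_rz"] = Rcpp::as<mat>(g["tf_Wh_rz"]) + dWhrz_f;
    g["tf_Wh_h"] = Rcpp::as<mat>(g["tf_Wh_h"]) + dWhh_f;
    g["tf_b"] = Rcpp::as<rowvec>(g["tf_b"]) + db_f;
    mat dWx_b(size(gb.Wx), fill::zeros), dWhrz_b(size(gb.Wh_rz), fill::zeros),
        dWhh_b(size(gb.Wh_h), fill::zeros);
    rowvec db_b(3 * U, fill::zeros);
    time_backward(&gb, nullptr, Ctx, m, -1, tb, dHb, dCtx,
                  dWx_b, dWhrz_b, dWhh_b, dummy, db_b);
    g["tb_Wx"] = Rcpp::as<mat>(g["tb_Wx"]) + dWx_b;
    g["tb_Wh_rz"] = Rcpp::as<mat>(g["tb_Wh_rz"]) + dWhrz_b;
    g["tb_Wh_h"] = Rcpp::as<mat>(g["tb_Wh_h"]) + dWhh_b;
    g["tb_b"] = Rcpp::as<rowvec>(g["tb_b"]) + db_b;
  } else {
    mat dWx_f(size(lf.Wx), fill::zeros), dWh_f(size(lf.Wh), fill::zeros),
        dummy1, dummy2;
    rowvec db_f(4 * U, fill::zeros);
    time_backward(nullptr, &lf, Ctx, m, +1, tf, dHf, dCtx,
                  dWx_f, dummy1, dummy2, dWh_f, db_f);
    g["tf_Wx"] = Rcpp::as<mat>(g["tf_Wx"]) + dWx_f;
    g["tf_Wh"] = Rcpp::as<mat>(g["tf_Wh"]) + dWh_f;
    g["tf_b"] = Rcpp::as<rowvec>(g["tf_b"]) + db_f;
    mat dWx_b(size(lb.Wx), fill::zeros), dWh_b(size(lb.Wh), fill::zeros);
    rowvec db_b(4 * U, fill::zeros);
    time_backward(nullptr, &lb, Ctx, m, -1, tb, dHb, dCtx,
                  dWx_b, dummy1, dummy2, dWh_b, db_b);
    g["tb_Wx"] = Rcpp::as<mat>(g["tb_Wx"]) + dWx_b;
    g["tb_Wh"] = Rcpp::as<mat>(g["tb_Wh"]) + dWh_b;
    g["tb_b"] = Rcpp::as<rowvec>(g["tb_b"]) + db_b;
  }

  // gather context gradients back to packed rows and run inner backward
  mat dctx(R, U);
  for (uword r = 0; r < R; ++r)
    dctx.row(r) = dCtx.slice(rt(r)).row(rb(r));
  inner_backward(params, rnn_type, cc, dctx, g);

  out["loss"] = loss;
  out["grads"] = g;
  return out;
}

// variable-level encoder exposed on its own: contexts and alpha for a batch
// [[Rcpp::export]]
Rcpp::List cpp_encode_period(Rcpp::List params, arma::cube X, arma::cube Mv,
                             arma::mat m, int rnn_type) {
  const uword B = X.n_rows, T = X.n_cols, V = X.n_slices;
  std::vector<uword> rbv, rtv;
  for (uword t = 0; t < T; ++t)
    for (uword b = 0; b < B; ++b)
      if (m(b, t) > 0.5) { rbv.push_back(b); rtv.push_back(t); }
  uvec rb = conv_to<uvec>::from(rbv), rt = conv_to<uvec>::from(rtv);
  InnerCache cc;
  inner_forward(params, rnn_type, X, Mv, rb, rt, false, cc);
  const uword U = cc.H.n_cols;
  cube Ctx(B, T, U, fill::zeros);       // R-friendly [B, T, U] layout
  cube alpha(B, T, V, fill::zeros);
  for (uword r = 0; r < rb.n_elem; ++r) {
    for (uword u = 0; u < U; ++u) Ctx(rb(r), rt(r), u) = cc.ctx(r, u);
    for (uword v = 0; v < V; ++v) alpha(rb(r), rt(r), v) = cc.alpha(r, v);
  }
  return Rcpp::List::create(Rcpp::Named("contexts") = Ctx,
                            Rcpp::Named("alpha") = alpha);
}

// time-level encoder exposed on its own: summary and beta from contexts
// given as [B, T, U]
// [[Rcpp::export]]
Rcpp::List cpp_encode_sequence(Rcpp::List params, arma::cube contexts,
                               arma::mat m, int rnn_type) {
  const uword B = contexts.n_rows, T = contexts.n_cols,
              U = contexts.n_slices;
  cube Ctx(B, U, T);
  for (uword t = 0; t < T; ++t)
    for (uword u = 0; u < U; ++u)
      Ctx.slice(t).col(u) = contexts.slice(u).col(t);
  TimeCache tf, tb;
  GruParams gf, gb; LstmParams lf, lb;
  if (rnn_type == 0) {
    gf = gru_params(params, "tf"); gb = gru_params(params, "tb");
    time_forward(&gf, nullptr, Ctx, m, +1, false, tf);
    time_forward(&gb, nullptr, Ctx, m, -1, false, tb);
  } else {
    lf = lstm_params(params, "tf"); lb = lstm_params(params, "tb");
    time_forward(nullptr, &lf, Ctx, m, +1, false, tf);
    time_forward(nullptr, &lb, Ctx, m, -1, false, tb);
  }
  const AttParams oatt = att_params(params, "out_att");
  mat So(B, T);
  for (uword t = 0; t < T; ++t) {
    mat G = join_rows(tf.H.slice(t), tb.H.slice(t));
    mat u = tanh(G * oatt.W + repmat(oatt.b, B, 1));
    So.col(t) = u * oatt.v;
  }
  mat beta = masked_softmax_rows(So, m);
  mat Z(B, 2 * U, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat G = join_rows(tf.H.slice(t), tb.H.slice(t));
    Z += G.each_col() % beta.col(t);
  }
  return Rcpp::List::create(Rcpp::Named("summary") = Z,
                            Rcpp::Named("beta") = beta);
}
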