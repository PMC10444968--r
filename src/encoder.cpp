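// Fused transformer-encoder training steps (forward + backward) for the
// peptide:TCR model, mirroring the reference R implementation in
// R/nn.R one-to-one. The R path remains the readable reference; tests
// assert numerical agreement between the two backends.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

static const double LN_EPS = 1e-5;
static const double CLAMP = 30.0;

struct LnCache {
  mat xhat;
  vec inv;
};

static mat ln_fwd(const mat &X, const rowvec &g, const rowvec &b,
                  LnCache &cache) {
  vec mu = arma::mean(X, 1);
  mat xc = X.each_col() - mu;
  vec v = arma::mean(arma::square(xc), 1);
  cache.inv = 1.0 / arma::sqrt(v + LN_EPS);
  cache.xhat = xc.each_col() % cache.inv;
  mat y = cache.xhat.each_row() % g;
  y.each_row() += b;
  return y;
}

static mat ln_bwd(const mat &dY, const LnCache &cache, const rowvec &g,
                  rowvec &dg, rowvec &db) {
  dg = arma::sum(dY % cache.xhat, 0);
  db = arma::sum(dY, 0);
  mat dxhat = dY.each_row() % g;
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % cache.xhat, 1);
  mat dX = dxhat.each_col() - m1;
  dX -= cache.xhat.each_col() % m2;
  dX.each_col() %= cache.inv;
  return dX;
}

static mat softmax_rows(mat S) {
  S.clamp(-CLAMP, CLAMP);
  mat E = arma::exp(S);
  E.each_col() /= arma::sum(E, 1);
  return E;
}

struct BlockCache {
  mat Xin, Q, K, V, C, X1, Hpre, H;
  LnCache ln1, ln2;
  std::vector<std::vector<mat>> P; // [b][head]
};

struct Batch {
  int B, Lmax, D;
  arma::ivec ids, typ, pos; // length B*Lmax, 0-based token ids
  arma::ivec lens;
  arma::uvec cls_rows;
};

struct Params {
  mat tok_emb, pos_emb, typ_emb;
  rowvec emb_g, emb_b;
  struct Block {
    mat Wq, Wk, Wv, Wo, W1, W2;
    rowvec bq, bk, bv, bo, b1, b2, ln1_g, ln1_b, ln2_g, ln2_b;
  };
  std::vector<Block> blocks;
  mat mlm_W, cls_W;
  rowvec mlm_b, cls_b;
};

static rowvec as_rowvec(SEXP x) {
  NumericVector v(x);
  return rowvec(v.begin(), v.size());
}

static Params unpack_params(const List &p, int n_blocks) {
  Params out;
  out.tok_emb = as<mat>(p["tok_emb"]);
  out.pos_emb = as<mat>(p["pos_emb"]);
  out.typ_emb = as<mat>(p["typ_emb"]);
  out.emb_g = as_rowvec(p["emb_g"]);
  out.emb_b = as_rowvec(p["emb_b"]);
  out.blocks.resize(n_blocks);
  for (int i = 0; i < n_blocks; ++i) {
    std::string pre = "b" + std::to_string(i + 1) + ".";
    Params::Block &bl = out.blocks[i];
    bl.Wq = as<mat>(p[pre + "Wq"]); bl.bq = as_rowvec(p[pre + "bq"]);
    bl.Wk = as<mat>(p[pre + "Wk"]); bl.bk = as_rowvec(p[pre + "bk"]);
    bl.Wv = as<mat>(p[pre + "Wv"]); bl.bv = as_rowvec(p[pre + "bv"]);
    bl.Wo = as<mat>(p[pre + "Wo"]); bl.bo = as_rowvec(p[pre + "bo"]);
    bl.ln1_g = as_rowvec(p[pre + "ln1_g"]);
    bl.ln1_b = as_rowvec(p[pre + "ln1_b"]);
    bl.W1 = as<mat>(p[pre + "W1"]); bl.b1 = as_rowvec(p[pre + "b1"]);
    bl.W2 = as<mat>(p[pre + "W2"]); bl.b2 = as_rowvec(p[pre + "b2"]);
    bl.ln2_g = as_rowvec(p[pre + "ln2_g"]);
    bl.ln2_b = as_rowvec(p[pre + "ln2_b"]);
  }
  out.mlm_W = as<mat>(p["mlm_W"]); out.mlm_b = as_rowvec(p["mlm_b"]);
  out.cls_W = as<mat>(p["cls_W"]); out.cls_b = as_rowvec(p["cls_b"]);
  return out;
}

static Batch unpack_batch(const List &pb, int D) {
  Batch b;
  b.B = as<int>(pb["B"]);
  b.Lmax = as<int>(pb["Lmax"]);
  b.D = D;
  IntegerVector ids = pb["ids_vec"], typ = pb["typ_vec"], pos = pb["pos_vec"],
                lens = pb["lens"];
  b.ids = arma::conv_to<arma::ivec>::from(
      std::vector<int>(ids.begin(), ids.end()));
  b.typ = arma::conv_to<arma::ivec>::from(
      std::vector<int>(typ.begin(), typ.end()));
  b.pos = arma::conv_to<arma::ivec>::from(
      std::vector<int>(pos.begin(), pos.end()));
  b.lens = arma::conv_to<arma::ivec>::from(
      std::vector<int>(lens.begin(), lens.end()));
  b.cls_rows.set_size(b.B);
  for (int i = 0; i < b.B; ++i) b.cls_rows[i] = (arma::uword)i * b.Lmax;
  return b;
}

// dropout mask via the R RNG (keeps set.seed semantics); p <= 0 -> empty
static mat dropout_mask(int n, int d, double p) {
  mat m;
  if (p <= 0) return m;
  m.set_size(n, d);
  // column-major fill to match R's matrix(runif(n*d), n, d)
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < n; ++i)
      m(i, j) = (R::runif(0.0, 1.0) >= p) ? 1.0 / (1.0 - p) : 0.0;
  return m;
}

struct ForwardCache {
  mat X0y; // after embedding LN (before dropout)
  LnCache ln0;
  mat m0;
  std::vector<BlockCache> blocks;
  std::vector<mat> mo, mf;
  mat X; // final
};

static void encoder_forward(const Params &P, const Batch &bt, int n_heads,
                            double dropout, ForwardCache &fc) {
  const int N = bt.B * bt.Lmax, D = bt.D;
  const int d = D / n_heads;
  const double scale = 1.0 / std::sqrt((double)d);

  mat X0(N, D);
  for (int r = 0; r < N; ++r) {
    X0.row(r) = P.tok_emb.row(bt.ids[r]) + P.pos_emb.row(bt.pos[r] - 1) +
                P.typ_emb.row(bt.typ[r] - 1);
  }
  mat X = ln_fwd(X0, P.emb_g, P.emb_b, fc.ln0);
  fc.m0 = dropout_mask(N, D, dropout);
  if (!fc.m0.is_empty()) X %= fc.m0;

  int nb = (int)P.blocks.size();
  fc.blocks.resize(nb);
  fc.mo.resize(nb);
  fc.mf.resize(nb);
  for (int i = 0; i < nb; ++i) {
    const Params::Block &bl = P.blocks[i];
    BlockCache &ca = fc.blocks[i];
    ca.Xin = X;
    ca.Q = X * bl.Wq; ca.Q.each_row() += bl.bq;
    ca.K = X * bl.Wk; ca.K.each_row() += bl.bk;
    ca.V = X * bl.Wv; ca.V.each_row() += bl.bv;
    ca.C.zeros(N, D);
    ca.P.assign(bt.B, std::vector<mat>(n_heads));
    for (int b = 0; b < bt.B; ++b) {
      int r0 = b * bt.Lmax, len = bt.lens[b];
      for (int hd = 0; hd < n_heads; ++hd) {
        int c0 = hd * d;
        mat Qb = ca.Q.submat(r0, c0, r0 + len - 1, c0 + d - 1);
        mat Kb = ca.K.submat(r0, c0, r0 + len - 1, c0 + d - 1);
        mat Vb = ca.V.submat(r0, c0, r0 + len - 1, c0 + d - 1);
        mat Pm = softmax_rows(Qb * Kb.t() * scale);
        ca.C.submat(r0, c0, r0 + len - 1, c0 + d - 1) = Pm * Vb;
        ca.P[b][hd] = std::move(Pm);
      }
    }
    mat O = ca.C * bl.Wo;
    O.each_row() += bl.bo;
    fc.mo[i] = dropout_mask(N, D, dropout);
    if (!fc.mo[i].is_empty()) O %= fc.mo[i];
    mat X1 = ln_fwd(ca.Xin + O, bl.ln1_g, bl.ln1_b, ca.ln1);
    ca.X1 = X1;
    ca.Hpre = X1 * bl.W1;
    ca.Hpre.each_row() += bl.b1;
    ca.H = ca.Hpre % (ca.Hpre > 0);
    mat F = ca.H * bl.W2;
    F.each_row() += bl.b2;
    fc.mf[i] = dropout_mask(N, (int)F.n_cols, dropout);
    if (!fc.mf[i].is_empty()) F %= fc.mf[i];
    X = ln_fwd(X1 + F, bl.ln2_g, bl.ln2_b, ca.ln2);
  }
  fc.X = std::move(X);
}

static void encoder_backward(mat dX, const Params &P, const Batch &bt,
                             int n_heads, const ForwardCache &fc, List &g) {
  const int N = bt.B * bt.Lmax, D = bt.D;
  const int d = D / n_heads;
  const double scale = 1.0 / std::sqrt((double)d);
  int nb = (int)P.blocks.size();

  for (int i = nb - 1; i >= 0; --i) {
    const Params::Block &bl = P.blocks[i];
    const BlockCache &ca = fc.blocks[i];
    std::string pre = "b" + std::to_string(i + 1) + ".";

    rowvec dg2, db2v;
    mat dsum2 = ln_bwd(dX, ca.ln2, bl.ln2_g, dg2, db2v);
    g[pre + "ln2_g"] = NumericVector(dg2.begin(), dg2.end());
    g[pre + "ln2_b"] = NumericVector(db2v.begin(), db2v.end());
    mat dF = fc.mf[i].is_empty() ? dsum2 : dsum2 % fc.mf[i];
    rowvec db2 = arma::sum(dF, 0);
    g[pre + "b2"] = NumericVector(db2.begin(), db2.end());
    g[pre + "W2"] = wrap(mat(ca.H.t() * dF));
    mat dH = dF * bl.W2.t();
    mat dHpre = dH % (ca.Hpre > 0);
    rowvec db1 = arma::sum(dHpre, 0);
    g[pre + "b1"] = NumericVector(db1.begin(), db1.end());
    g[pre + "W1"] = wrap(mat(ca.X1.t() * dHpre));
    mat dX1 = dsum2 + dHpre * bl.W1.t();

    rowvec dg1, db1v;
    mat dsum1 = ln_bwd(dX1, ca.ln1, bl.ln1_g, dg1, db1v);
    g[pre + "ln1_g"] = NumericVector(dg1.begin(), dg1.end());
    g[pre + "ln1_b"] = NumericVector(db1v.begin(), db1v.end());
    mat dO = fc.mo[i].is_empty() ? dsum1 : dsum1 % fc.mo[i];
    rowvec dbo = arma::sum(dO, 0);
    g[pre + "bo"] = NumericVector(dbo.begin(), dbo.end());
    g[pre + "Wo"] = wrap(mat(ca.C.t() * dO));
    mat dC = dO * bl.Wo.t();

    mat dQ(N, D, arma::fill::zeros), dK(N, D, arma::fill::zeros),
        dV(N, D, arma::fill::zeros);
    for (int b = 0; b < bt.B; ++b) {
      int r0 = b * bt.Lmax, len = bt.lens[b];
      for (int hd = 0; hd < n_heads; ++hd) {
        int c0 = hd * d;
        const mat &Pm = ca.P[b][hd];
        mat dCbh = dC.submat(r0, c0, r0 + len - 1, c0 + d - 1);
        mat Vb = ca.V.submat(r0, c0, r0 + len - 1, c0 + d - 1);
        mat dP = dCbh * Vb.t();
        dV.submat(r0, c0, r0 + len - 1, c0 + d - 1) = Pm.t() * dCbh;
        vec rs = arma::sum(dP % Pm, 1);
        mat dS = (Pm % (dP.each_col() - rs)) * scale;
        dQ.submat(r0, c0, r0 + len - 1, c0 + d - 1) =
            dS * ca.K.submat(r0, c0, r0 + len - 1, c0 + d - 1);
        dK.submat(r0, c0, r0 + len - 1, c0 + d - 1) =
            dS.t() * ca.Q.submat(r0, c0, r0 + len - 1, c0 + d - 1);
      }
    }
    rowvec dbq = arma::sum(dQ, 0), dbk = arma::sum(dK, 0),
           dbv = arma::sum(dV, 0);
    g[pre + "bq"] = NumericVector(dbq.begin(), dbq.end());
    g[pre + "Wq"] = wrap(mat(ca.Xin.t() * dQ));
    g[pre + "bk"] = NumericVector(dbk.begin(), dbk.end());
    g[pre + "Wk"] = wrap(mat(ca.Xin.t() * dK));
    g[pre + "bv"] = NumericVector(dbv.begin(), dbv.end());
    g[pre + "Wv"] = wrap(mat(ca.Xin.t() * dV));
    dX = dsum1 + dQ * bl.Wq.t() + dK * bl.Wk.t() + dV * bl.Wv.t();
  }

  if (!fc.m0.is_empty()) dX %= fc.m0;
  rowvec dg0, db0;
  mat dX0 = ln_bwd(dX, fc.ln0, P.emb_g, dg0, db0);
  g["emb_g"] = NumericVector(dg0.begin(), dg0.end());
  g["emb_b"] = NumericVector(db0.begin(), db0.end());

  mat dtok(P.tok_emb.n_rows, D, arma::fill::zeros);
  mat dpos(P.pos_emb.n_rows, D, arma::fill::zeros);
  mat dtyp(P.typ_emb.n_rows, D, arma::fill::zeros);
  for (int r = 0; r < N; ++r) {
    dtok.row(bt.ids[r]) += dX0.row(r);
    dpos.row(bt.pos[r] - 1) += dX0.row(r);
    dtyp.row(bt.typ[r] - 1) += dX0.row(r);
  }
  g["tok_emb"] = wrap(dtok);
  g["pos_emb"] = wrap(dpos);
  g["typ_emb"] = wrap(dtyp);
}

// forward only: final per-token states as one (B*Lmax) x D matrix
// [[Rcpp::export]]
NumericMatrix cpp_encoder_forward(List params, List pb, int n_blocks,
                                  int n_heads, double dropout) {
  Params P = unpack_params(params, n_blocks);
  Batch bt = unpack_batch(pb, (int)P.tok_emb.n_cols);
  ForwardCache fc;
  encoder_forward(P, bt, n_heads, dropout, fc);
  return wrap(fc.X);
}

// fused masked-LM step: loss + gradients
// targets/flags are aligned with the flattened (B*Lmax) layout
// [[Rcpp::export]]
List cpp_mlm_step(List params, List pb, int n_blocks, int n_heads,
                  double dropout, IntegerVector target_vec,
                  LogicalVector flag_vec) {
  Params P = unpack_params(params, n_blocks);
  Batch bt = unpack_batch(pb, (int)P.tok_emb.n_cols);
  ForwardCache fc;
  encoder_forward(P, bt, n_heads, dropout, fc);

  std::vector<arma::uword> mrows;
  for (int r = 0; r < (int)flag_vec.size(); ++r)
    if (flag_vec[r]) mrows.push_back(r);
  if (mrows.empty()) {
    return List::create(_["loss"] = 0.0, _["grads"] = R_NilValue);
  }
  arma::uvec mr(mrows);
  mat Xm = fc.X.rows(mr);
  mat logits = Xm * P.mlm_W;
  logits.each_row() += P.mlm_b;
  vec mx = arma::max(logits, 1);
  mat Z = logits.each_col() - mx;
  mat E = arma::exp(Z);
  vec se = arma::sum(E, 1);
  const int n = (int)mr.n_elem;
  double loss = 0.0;
  mat dlogits = E.each_col() / se; // softmax
  for (int k = 0; k < n; ++k) {
    int tgt = target_vec[mr[k]];
    loss -= Z(k, tgt) - std::log(se[k]);
    dlogits(k, tgt) -= 1.0;
  }
  loss /= n;
  dlogits /= n;

  List g;
  rowvec dmb = arma::sum(dlogits, 0);
  g["mlm_b"] = NumericVector(dmb.begin(), dmb.end());
  g["mlm_W"] = wrap(mat(Xm.t() * dlogits));
  mat dX(fc.X.n_rows, fc.X.n_cols, arma::fill::zeros);
  dX.rows(mr) = dlogits * P.mlm_W.t();
  encoder_backward(std::move(dX), P, bt, n_heads, fc, g);
  return List::create(_["loss"] = loss, _["grads"] = g);
}

// fused focal-loss classification step: loss + gradients + probabilities
// [[Rcpp::export]]
List cpp_cls_step(List params, List pb, int n_blocks, int n_heads,
                  double dropout, IntegerVector y, double gamma,
                  double alpha) {
  Params P = unpack_params(params, n_blocks);
  Batch bt = unpack_batch(pb, (int)P.tok_emb.n_cols);
  ForwardCache fc;
  encoder_forward(P, bt, n_heads, dropout, fc);

  mat Xc = fc.X.rows(bt.cls_rows);
  mat logits = Xc * P.cls_W;
  logits.each_row() += P.cls_b;
  vec mx = arma::max(logits, 1);
  mat Z = logits.each_col() - mx;
  mat E = arma::exp(Z);
  vec se = arma::sum(E, 1);
  mat p = E.each_col() / se;
  const int n = bt.B;
  vec pbind = p.col(1);

  double loss = 0.0;
  mat dlogits(n, 2, arma::fill::zeros);
  for (int k = 0; k < n; ++k) {
    double pt = (y[k] == 1) ? pbind[k] : 1.0 - pbind[k];
    pt = std::min(std::max(pt, 1e-12), 1.0 - 1e-12);
    double at = (y[k] == 1) ? alpha : 1.0 - alpha;
    loss += -at * std::pow(1.0 - pt, gamma) * std::log(pt);
    double dfl_dpt;
    if (gamma == 0.0) {
      dfl_dpt = -at / pt;
    } else {
      dfl_dpt = at * (gamma * std::pow(1.0 - pt, gamma - 1.0) * std::log(pt) -
                      std::pow(1.0 - pt, gamma) / pt);
    }
    int truth = (y[k] == 1) ? 1 : 0;
    for (int c = 0; c < 2; ++c) {
      double onehot = (c == truth) ? 1.0 : 0.0;
      dlogits(k, c) = dfl_dpt * pt * (onehot - p(k, c)) / n;
    }
  }
  loss /= n;

  List g;
  rowvec dcb = arma::sum(dlogits, 0);
  g["cls_b"] = NumericVector(dcb.begin(), dcb.end());
  g["cls_W"] = wrap(mat(Xc.t() * dlogits));
  mat dX(fc.X.n_rows, fc.X.n_cols, arma::fill::zeros);
  dX.rows(bt.cls_rows) = dlogits * P.cls_W.t();
  encoder_backward(std::move(dX), P, bt, n_heads, fc, g);
  return List::create(_["loss"] = loss, _["grads"] = g,
                      _["p"] = NumericVector(pbind.begin(), pbind.end()));
}
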