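// Transformer core for the two-stage budding detector: a masked auto-encoder
// vision transformer (stage 1) and a lightweight temporal transformer
// (stage 2), with hand-derived backward passes. All randomness (weight init,
// masking, batch order) lives on the R side; every function here is a
// deterministic map from parameters + inputs to outputs/gradients.
//
// Batch layout: token matrices are stacked row-blocks, X is (B*n) x D with
// sample b occupying rows [b*n, (b+1)*n). Linear/LayerNorm/MLP operate on the
// stacked matrix; attention loops over per-sample blocks.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
// single-precision core: deep-learning arithmetic is fp32 throughout, with
// loss accumulation in double; inputs/outputs cross to R as doubles
typedef arma::fmat mat;
typedef arma::fcube cube;
typedef arma::frowvec rowvec;
typedef arma::fvec vec;
using arma::umat;
using arma::uvec;

static const float LN_EPS = 1e-5f;

// ---------------------------------------------------------------------------
// elementwise GELU (exact, erf form)

static mat gelu_fwd(const mat& x, mat& cdf) {
  cdf = 0.5f * (1.0f + arma::erf(x / std::sqrt(2.0f)));
  return x % cdf;
}

static mat gelu_bwd(const mat& x, const mat& cdf, const mat& dy) {
  mat pdf = arma::exp(-0.5f * arma::square(x)) /
    std::sqrt(2.0f * (float)M_PI);
  return dy % (cdf + x % pdf);
}

// ---------------------------------------------------------------------------
// row-wise LayerNorm

struct LNCache {
  mat xhat;        // normalized input
  vec inv_sigma;   // 1/sqrt(var + eps) per row
};

static mat ln_fwd(const mat& X, const rowvec& g, const rowvec& b, LNCache& c) {
  vec mu = arma::mean(X, 1);
  mat Xc = X.each_col() - mu;
  vec var = arma::mean(arma::square(Xc), 1);
  c.inv_sigma = 1.0f / arma::sqrt(var + LN_EPS);
  c.xhat = Xc.each_col() % c.inv_sigma;
  mat Y = c.xhat.each_row() % g;
  Y.each_row() += b;
  return Y;
}

static mat ln_bwd(const mat& dY, const LNCache& c, const rowvec& g,
                  rowvec& dg, rowvec& db) {
  dg += arma::sum(dY % c.xhat, 0);
  db += arma::sum(dY, 0);
  mat dxhat = dY.each_row() % g;
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % c.xhat, 1);
  mat dX = dxhat;
  dX.each_col() -= m1;
  dX -= c.xhat.each_col() % m2;
  dX.each_col() %= c.inv_sigma;
  return dX;
}

// ---------------------------------------------------------------------------
// pre-LN transformer block (MHA + GELU MLP, residual connections)

struct BlockW {
  mat Wq, Wk, Wv, Wo, W1, W2;
  mat Wqkv;        // join_rows(Wq, Wk, Wv), built once per call
  rowvec bq, bk, bv, bo, b1, b2, g1, be1, g2, be2;
  rowvec bqkv;
};

struct BlockG {
  mat Wq, Wk, Wv, Wo, W1, W2;
  rowvec bq, bk, bv, bo, b1, b2, g1, be1, g2, be2;
  void init(const BlockW& w) {
    Wq.zeros(arma::size(w.Wq)); Wk.zeros(arma::size(w.Wk));
    Wv.zeros(arma::size(w.Wv)); Wo.zeros(arma::size(w.Wo));
    W1.zeros(arma::size(w.W1)); W2.zeros(arma::size(w.W2));
    bq.zeros(arma::size(w.bq)); bk.zeros(arma::size(w.bk));
    bv.zeros(arma::size(w.bv)); bo.zeros(arma::size(w.bo));
    b1.zeros(arma::size(w.b1)); b2.zeros(arma::size(w.b2));
    g1.zeros(arma::size(w.g1)); be1.zeros(arma::size(w.be1));
    g2.zeros(arma::size(w.g2)); be2.zeros(arma::size(w.be2));
  }
};

struct BlockC {
  mat Xin;          // block input
  LNCache ln1;
  mat X1;           // LN1 output
  mat Q, K, V;      // projections (stacked)
  cube A;           // attention weights, n x n x (B*heads)
  mat O;            // concatenated head outputs (input to Wo)
  mat X2;           // after attention residual
  LNCache ln2;
  mat X3;           // LN2 output
  mat H;            // MLP pre-activation
  mat Cdf;          // gaussian CDF at H (cached for backward)
  mat Act;          // gelu(H)
};

static BlockW get_block(const List& p, const std::string& pre) {
  BlockW w;
  w.Wq = as<mat>(p[pre + "_Wq"]); w.bq = as<rowvec>(p[pre + "_bq"]);
  w.Wk = as<mat>(p[pre + "_Wk"]); w.bk = as<rowvec>(p[pre + "_bk"]);
  w.Wv = as<mat>(p[pre + "_Wv"]); w.bv = as<rowvec>(p[pre + "_bv"]);
  w.Wo = as<mat>(p[pre + "_Wo"]); w.bo = as<rowvec>(p[pre + "_bo"]);
  w.W1 = as<mat>(p[pre + "_W1"]); w.b1 = as<rowvec>(p[pre + "_b1"]);
  w.W2 = as<mat>(p[pre + "_W2"]); w.b2 = as<rowvec>(p[pre + "_b2"]);
  w.g1 = as<rowvec>(p[pre + "_ln1g"]); w.be1 = as<rowvec>(p[pre + "_ln1b"]);
  w.g2 = as<rowvec>(p[pre + "_ln2g"]); w.be2 = as<rowvec>(p[pre + "_ln2b"]);
  w.Wqkv = arma::join_rows(arma::join_rows(w.Wq, w.Wk), w.Wv);
  w.bqkv = arma::join_rows(arma::join_rows(w.bq, w.bk), w.bv);
  return w;
}

static void put_block(List& g, const std::string& pre, const BlockG& gr) {
  g[pre + "_Wq"] = gr.Wq; g[pre + "_bq"] = gr.bq;
  g[pre + "_Wk"] = gr.Wk; g[pre + "_bk"] = gr.bk;
  g[pre + "_Wv"] = gr.Wv; g[pre + "_bv"] = gr.bv;
  g[pre + "_Wo"] = gr.Wo; g[pre + "_bo"] = gr.bo;
  g[pre + "_W1"] = gr.W1; g[pre + "_b1"] = gr.b1;
  g[pre + "_W2"] = gr.W2; g[pre + "_b2"] = gr.b2;
  g[pre + "_ln1g"] = gr.g1; g[pre + "_ln1b"] = gr.be1;
  g[pre + "_ln2g"] = gr.g2; g[pre + "_ln2b"] = gr.be2;
}

static mat block_fwd(const mat& X, const BlockW& w, int B, int n, int heads,
                     BlockC& c) {
  const int D = X.n_cols;
  const int dh = D / heads;
  const float scale = 1.0f / std::sqrt((float)dh);
  c.Xin = X;
  c.X1 = ln_fwd(X, w.g1, w.be1, c.ln1);
  mat QKV = c.X1 * w.Wqkv;
  QKV.each_row() += w.bqkv;
  c.Q = QKV.cols(0, D - 1);
  c.K = QKV.cols(D, 2 * D - 1);
  c.V = QKV.cols(2 * D, 3 * D - 1);
  c.A.set_size(n, n, B * heads);
  c.O.set_size(X.n_rows, D);
  for (int b = 0; b < B; ++b) {
    const arma::span rs(b * n, b * n + n - 1);
    for (int h = 0; h < heads; ++h) {
      const arma::span cs(h * dh, h * dh + dh - 1);
      mat S = c.Q(rs, cs) * c.K(rs, cs).t() * scale;
      S.each_col() -= arma::max(S, 1);
      mat A = arma::exp(S);
      A.each_col() /= arma::sum(A, 1);
      c.A.slice(b * heads + h) = A;
      c.O(rs, cs) = A * c.V(rs, cs);
    }
  }
  mat attn = c.O * w.Wo;
  attn.each_row() += w.bo;
  c.X2 = X + attn;
  c.X3 = ln_fwd(c.X2, w.g2, w.be2, c.ln2);
  c.H = c.X3 * w.W1; c.H.each_row() += w.b1;
  c.Act = gelu_fwd(c.H, c.Cdf);
  mat out = c.Act * w.W2;
  out.each_row() += w.b2;
  return c.X2 + out;
}

static mat block_bwd(const mat& dY, const BlockW& w, const BlockC& c,
                     BlockG& g, int B, int n, int heads) {
  const int D = c.Xin.n_cols;
  const int dh = D / heads;
  const float scale = 1.0f / std::sqrt((float)dh);
  // MLP branch
  g.b2 += arma::sum(dY, 0);
  g.W2 += c.Act.t() * dY;
  mat dAct = dY * w.W2.t();
  mat dH = gelu_bwd(c.H, c.Cdf, dAct);
  g.b1 += arma::sum(dH, 0);
  g.W1 += c.X3.t() * dH;
  mat dX3 = dH * w.W1.t();
  mat dX2 = dY + ln_bwd(dX3, c.ln2, w.g2, g.g2, g.be2);
  // attention branch
  mat dattn = dX2;
  g.bo += arma::sum(dattn, 0);
  g.Wo += c.O.t() * dattn;
  mat dO = dattn * w.Wo.t();
  mat dQ(arma::size(c.Q), arma::fill::zeros);
  mat dK(arma::size(c.K), arma::fill::zeros);
  mat dV(arma::size(c.V), arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const arma::span rs(b * n, b * n + n - 1);
    for (int h = 0; h < heads; ++h) {
      const arma::span cs(h * dh, h * dh + dh - 1);
      const mat& A = c.A.slice(b * heads + h);
      mat dOh = dO(rs, cs);
      mat dA = dOh * c.V(rs, cs).t();
      dV(rs, cs) += A.t() * dOh;
      vec rowdot = arma::sum(dA % A, 1);
      mat dS = A % (dA.each_col() - rowdot);
      dS *= scale;
      dQ(rs, cs) += dS * c.K(rs, cs);
      dK(rs, cs) += dS.t() * c.Q(rs, cs);
    }
  }
  mat dQKV = arma::join_rows(arma::join_rows(dQ, dK), dV);
  mat dWqkv = c.X1.t() * dQKV;
  const int Dm = c.Xin.n_cols;
  g.Wq += dWqkv.cols(0, Dm - 1);
  g.Wk += dWqkv.cols(Dm, 2 * Dm - 1);
  g.Wv += dWqkv.cols(2 * Dm, 3 * Dm - 1);
  g.bq += arma::sum(dQ, 0);
  g.bk += arma::sum(dK, 0);
  g.bv += arma::sum(dV, 0);
  mat dX1 = dQKV * w.Wqkv.t();
  return dX2 + ln_bwd(dX1, c.ln1, w.g1, g.g1, g.be1);
}

// ---------------------------------------------------------------------------
// MAE: encoder over visible tokens + CLS, decoder over the full grid with
// mask tokens, loss on masked (or all) patches.

struct EncState {
  std::vector<BlockW> w;
  rowvec lng, lnb;
};

static EncState get_stack(const List& p, const std::string& tag, int depth) {
  EncState s;
  for (int i = 0; i < depth; ++i)
    s.w.push_back(get_block(p, tag + std::to_string(i)));
  s.lng = as<rowvec>(p[tag + "_lng"]);
  s.lnb = as<rowvec>(p[tag + "_lnb"]);
  return s;
}

// run blocks + final LN
static mat stack_fwd(const mat& X0, const EncState& s, int B, int n, int heads,
                     std::vector<BlockC>& caches, LNCache& lnf) {
  mat X = X0;
  caches.resize(s.w.size());
  for (size_t i = 0; i < s.w.size(); ++i)
    X = block_fwd(X, s.w[i], B, n, heads, caches[i]);
  return ln_fwd(X, s.lng, s.lnb, lnf);
}

static mat stack_bwd(const mat& dY, const EncState& s,
                     std::vector<BlockC>& caches, LNCache& lnf,
                     std::vector<BlockG>& g, rowvec& dlng, rowvec& dlnb,
                     int B, int n, int heads) {
  mat dX = ln_bwd(dY, lnf, s.lng, dlng, dlnb);
  for (int i = (int)s.w.size() - 1; i >= 0; --i)
    dX = block_bwd(dX, s.w[i], caches[i], g[i], B, n, heads);
  return dX;
}

// Build encoder token matrix: row 0 of each block = CLS + pos[0], then
// visible patches (linear embed + pos by original index).
static mat build_enc_tokens(const cube& Xp, const umat& keep, const mat& peW,
                            const rowvec& peb, const mat& cls, const mat& pos) {
  const int B = Xp.n_slices;
  const int nv = keep.n_rows;
  const int n = nv + 1;
  const int D = peW.n_cols;
  mat T(B * n, D);
  for (int b = 0; b < B; ++b) {
    T.row(b * n) = cls.row(0) + pos.row(0);
    for (int j = 0; j < nv; ++j) {
      const int pidx = keep(j, b);
      T.row(b * n + j + 1) =
        Xp.slice(b).row(pidx) * peW + peb + pos.row(pidx + 1);
    }
  }
  return T;
}

// [[Rcpp::export]]
List cpp_mae_batch(List params, const arma::fcube& Xp, const arma::umat& keep,
                   int enc_depth, int dec_depth, int enc_heads, int dec_heads,
                   bool loss_on_all, bool want_grad, bool want_recon) {
  const int B = Xp.n_slices;
  const int P = Xp.n_rows;
  const int pp = Xp.n_cols;
  const int nv = keep.n_rows;
  const int n = nv + 1;     // encoder tokens incl. CLS
  const int n2 = P + 1;     // decoder tokens incl. CLS

  mat peW = as<mat>(params["pe_W"]);
  rowvec peb = as<rowvec>(params["pe_b"]);
  mat cls = as<mat>(params["cls"]);
  mat pos = as<mat>(params["pos"]);
  EncState enc = get_stack(params, "e", enc_depth);
  mat dinW = as<mat>(params["d_in_W"]);
  rowvec dinb = as<rowvec>(params["d_in_b"]);
  mat mtok = as<mat>(params["mask_tok"]);
  mat dpos = as<mat>(params["dpos"]);
  EncState dec = get_stack(params, "d", dec_depth);
  mat outW = as<mat>(params["out_W"]);
  rowvec outb = as<rowvec>(params["out_b"]);
  const int Dd = dinW.n_cols;

  // ---- forward: encoder
  mat T0 = build_enc_tokens(Xp, keep, peW, peb, cls, pos);
  std::vector<BlockC> ec;
  LNCache elnf;
  mat Y = stack_fwd(T0, enc, B, n, enc_heads, ec, elnf);

  // ---- decoder input
  mat Z = Y * dinW;              // (B*n) x Dd
  Z.each_row() += dinb;
  mat D0(B * n2, Dd);
  std::vector<std::vector<char>> is_masked(B, std::vector<char>(P, 1));
  for (int b = 0; b < B; ++b) {
    D0.row(b * n2) = Z.row(b * n) + dpos.row(0);
    for (int j = 0; j < nv; ++j) is_masked[b][keep(j, b)] = 0;
    for (int i = 0; i < P; ++i)
      if (is_masked[b][i]) D0.row(b * n2 + i + 1) = mtok.row(0) + dpos.row(i + 1);
    for (int j = 0; j < nv; ++j) {
      const int pidx = keep(j, b);
      D0.row(b * n2 + pidx + 1) = Z.row(b * n + j + 1) + dpos.row(pidx + 1);
    }
  }
  std::vector<BlockC> dc;
  LNCache dlnf;
  mat Yd = stack_fwd(D0, dec, B, n2, dec_heads, dc, dlnf);

  // ---- prediction head on patch rows
  mat recon(B * P, pp);
  for (int b = 0; b < B; ++b)
    recon.rows(b * P, b * P + P - 1) =
      Yd.rows(b * n2 + 1, b * n2 + P) * outW;
  recon.each_row() += outb;

  // ---- loss
  double loss = 0.0;
  mat dRecon(arma::size(recon), arma::fill::zeros);
  const int n_mask_per = loss_on_all ? P : (P - nv);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < P; ++i) {
      if (!loss_on_all && !is_masked[b][i]) continue;
      rowvec diff = recon.row(b * P + i) - Xp.slice(b).row(i);
      loss += (double)arma::dot(diff, diff) / (n_mask_per * pp);
      dRecon.row(b * P + i) = 2.0f * diff / (float)(n_mask_per * pp * B);
    }
  }
  loss /= B;

  List out = List::create(Named("loss") = loss);
  if (want_recon) {
    cube rc(P, pp, B);
    for (int b = 0; b < B; ++b) rc.slice(b) = recon.rows(b * P, b * P + P - 1);
    out["recon"] = rc;
  }
  if (!want_grad) return out;

  // ---- backward
  List g;  // named gradient list
  mat doutW(arma::size(outW), arma::fill::zeros);
  rowvec doutb = arma::sum(dRecon, 0);
  mat dYd(arma::size(Yd), arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    mat dR = dRecon.rows(b * P, b * P + P - 1);
    doutW += Yd.rows(b * n2 + 1, b * n2 + P).t() * dR;
    dYd.rows(b * n2 + 1, b * n2 + P) = dR * outW.t();
  }
  std::vector<BlockG> dg(dec_depth);
  for (int i = 0; i < dec_depth; ++i) dg[i].init(dec.w[i]);
  rowvec d_dlng(Dd, arma::fill::zeros), d_dlnb(Dd, arma::fill::zeros);
  mat dD0 = stack_bwd(dYd, dec, dc, dlnf, dg, d_dlng, d_dlnb, B, n2, dec_heads);

  mat dmtok(1, Dd, arma::fill::zeros);
  mat ddpos(arma::size(dpos), arma::fill::zeros);
  mat dZ(arma::size(Z), arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    dZ.row(b * n) = dD0.row(b * n2);
    ddpos.row(0) += dD0.row(b * n2);
    for (int i = 0; i < P; ++i) {
      ddpos.row(i + 1) += dD0.row(b * n2 + i + 1);
      if (is_masked[b][i]) dmtok.row(0) += dD0.row(b * n2 + i + 1);
    }
    for (int j = 0; j < nv; ++j) {
      const int pidx = keep(j, b);
      dZ.row(b * n + j + 1) = dD0.row(b * n2 + pidx + 1);
    }
  }
  mat ddinW = Y.t() * dZ;
  rowvec ddinb = arma::sum(dZ, 0);
  mat dY_enc = dZ * dinW.t();

  std::vector<BlockG> eg(enc_depth);
  for (int i = 0; i < enc_depth; ++i) eg[i].init(enc.w[i]);
  const int D = peW.n_cols;
  rowvec d_elng(D, arma::fill::zeros), d_elnb(D, arma::fill::zeros);
  mat dT0 = stack_bwd(dY_enc, enc, ec, elnf, eg, d_elng, d_elnb, B, n, enc_heads);

  mat dcls(1, D, arma::fill::zeros);
  mat dposm(arma::size(pos), arma::fill::zeros);
  mat dpeW(arma::size(peW), arma::fill::zeros);
  rowvec dpeb(D, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    dcls.row(0) += dT0.row(b * n);
    dposm.row(0) += dT0.row(b * n);
    for (int j = 0; j < nv; ++j) {
      const int pidx = keep(j, b);
      rowvec dt = dT0.row(b * n + j + 1);
      dposm.row(pidx + 1) += dt;
      dpeW += Xp.slice(b).row(pidx).t() * dt;
      dpeb += dt;
    }
  }

  g["pe_W"] = dpeW; g["pe_b"] = dpeb; g["cls"] = dcls; g["pos"] = dposm;
  for (int i = 0; i < enc_depth; ++i) put_block(g, "e" + std::to_string(i), eg[i]);
  g["e_lng"] = d_elng; g["e_lnb"] = d_elnb;
  g["d_in_W"] = ddinW; g["d_in_b"] = ddinb;
  g["mask_tok"] = dmtok; g["dpos"] = ddpos;
  for (int i = 0; i < dec_depth; ++i) put_block(g, "d" + std::to_string(i), dg[i]);
  g["d_lng"] = d_dlng; g["d_lnb"] = d_dlnb;
  g["out_W"] = doutW; g["out_b"] = doutb;
  out["grads"] = g;
  return out;
}

// Encoder-only forward over an arbitrary kept-token set (no masking when
// keep lists every patch). Returns all token latents after the final LN.
// [[Rcpp::export]]
arma::fcube cpp_encode(List params, const arma::fcube& Xp, const arma::umat& keep,
                      int enc_depth, int enc_heads) {
  const int B = Xp.n_slices;
  const int nv = keep.n_rows;
  const int n = nv + 1;
  mat peW = as<mat>(params["pe_W"]);
  rowvec peb = as<rowvec>(params["pe_b"]);
  mat cls = as<mat>(params["cls"]);
  mat pos = as<mat>(params["pos"]);
  EncState enc = get_stack(params, "e", enc_depth);
  mat T0 = build_enc_tokens(Xp, keep, peW, peb, cls, pos);
  std::vector<BlockC> ec;
  LNCache lnf;
  mat Y = stack_fwd(T0, enc, B, n, enc_heads, ec, lnf);
  cube out(n, Y.n_cols, B);
  for (int b = 0; b < B; ++b) out.slice(b) = Y.rows(b * n, b * n + n - 1);
  return out;
}

// Vector-Jacobian product of the CLS output w.r.t. encoder parameters:
// recomputes the full-visibility forward pass and backpropagates a gradient
// supplied for each sample's CLS latent (used when fine-tuning the encoder
// under the stage-2 objective).
// [[Rcpp::export]]
List cpp_encode_cls_vjp(List params, const arma::fcube& Xp, const arma::fmat& Gcls,
                        int enc_depth, int enc_heads) {
  const int B = Xp.n_slices;
  const int P = Xp.n_rows;
  const int n = P + 1;
  mat peW = as<mat>(params["pe_W"]);
  rowvec peb = as<rowvec>(params["pe_b"]);
  mat cls = as<mat>(params["cls"]);
  mat pos = as<mat>(params["pos"]);
  EncState enc = get_stack(params, "e", enc_depth);
  umat keep(P, B);
  for (int b = 0; b < B; ++b)
    for (int i = 0; i < P; ++i) keep(i, b) = i;
  mat T0 = build_enc_tokens(Xp, keep, peW, peb, cls, pos);
  std::vector<BlockC> ec;
  LNCache lnf;
  mat Y = stack_fwd(T0, enc, B, n, enc_heads, ec, lnf);
  mat dY(arma::size(Y), arma::fill::zeros);
  for (int b = 0; b < B; ++b) dY.row(b * n) = Gcls.row(b);
  std::vector<BlockG> eg(enc_depth);
  for (int i = 0; i < enc_depth; ++i) eg[i].init(enc.w[i]);
  const int D = peW.n_cols;
  rowvec dlng(D, arma::fill::zeros), dlnb(D, arma::fill::zeros);
  mat dT0 = stack_bwd(dY, enc, ec, lnf, eg, dlng, dlnb, B, n, enc_heads);
  mat dcls(1, D, arma::fill::zeros);
  mat dposm(arma::size(pos), arma::fill::zeros);
  mat dpeW(arma::size(peW), arma::fill::zeros);
  rowvec dpeb(D, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    dcls.row(0) += dT0.row(b * n);
    dposm.row(0) += dT0.row(b * n);
    for (int i = 0; i < P; ++i) {
      rowvec dt = dT0.row(b * n + i + 1);
      dposm.row(i + 1) += dt;
      dpeW += Xp.slice(b).row(i).t() * dt;
      dpeb += dt;
    }
  }
  List g;
  g["pe_W"] = dpeW; g["pe_b"] = dpeb; g["cls"] = dcls; g["pos"] = dposm;
  for (int i = 0; i < enc_depth; ++i) put_block(g, "e" + std::to_string(i), eg[i]);
  g["e_lng"] = dlng; g["e_lnb"] = dlnb;
  return g;
}

// ---------------------------------------------------------------------------
// Temporal transformer over 11 frame embeddings; two-way softmax on the
// center-slot output. labels: 0/1 per sample, or -1 to skip the loss.

// [[Rcpp::export]]
List cpp_temporal_batch(List params, const arma::fcube& E, const arma::fmat& postab,
                        const arma::ivec& labels, int depth, int heads,
                        bool want_grad, bool want_dE) {
  const int n = E.n_rows;        // window length (11)
  const int B = E.n_slices;
  const int center = (n - 1) / 2;
  mat inW = as<mat>(params["t_in_W"]);
  rowvec inb = as<rowvec>(params["t_in_b"]);
  EncState st = get_stack(params, "t", depth);
  mat hW = as<mat>(params["head_W"]);
  rowvec hb = as<rowvec>(params["head_b"]);
  const int Td = inW.n_cols;

  mat T0(B * n, Td);
  for (int b = 0; b < B; ++b) {
    mat tok = E.slice(b) * inW;
    tok.each_row() += inb;
    tok += postab;
    T0.rows(b * n, b * n + n - 1) = tok;
  }
  std::vector<BlockC> cc;
  LNCache lnf;
  mat Y = stack_fwd(T0, st, B, n, heads, cc, lnf);
  mat logits(B, 2);
  for (int b = 0; b < B; ++b)
    logits.row(b) = Y.row(b * n + center) * hW + hb;
  mat probs = logits;
  probs.each_col() -= arma::max(probs, 1);
  probs = arma::exp(probs);
  probs.each_col() /= arma::sum(probs, 1);

  double loss = 0.0;
  int n_lab = 0;
  mat dlogits(B, 2, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    if (labels(b) < 0) continue;
    ++n_lab;
    loss += -std::log(std::max((double)probs(b, labels(b)), 1e-12));
    dlogits.row(b) = probs.row(b);
    dlogits(b, labels(b)) -= 1.0f;
  }
  if (n_lab > 0) { loss /= n_lab; dlogits /= (float)n_lab; }

  List out = List::create(Named("probs") = probs, Named("loss") = loss);
  if (!want_grad && !want_dE) return out;

  mat dhW(arma::size(hW), arma::fill::zeros);
  rowvec dhb = arma::sum(dlogits, 0);
  mat dY(arma::size(Y), arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    dhW += Y.row(b * n + center).t() * dlogits.row(b);
    dY.row(b * n + center) = dlogits.row(b) * hW.t();
  }
  std::vector<BlockG> tg(depth);
  for (int i = 0; i < depth; ++i) tg[i].init(st.w[i]);
  rowvec dlng(Td, arma::fill::zeros), dlnb(Td, arma::fill::zeros);
  mat dT0 = stack_bwd(dY, st, cc, lnf, tg, dlng, dlnb, B, n, heads);

  mat dinW(arma::size(inW), arma::fill::zeros);
  rowvec dinb = arma::sum(dT0, 0);
  cube dE;
  if (want_dE) dE.set_size(n, E.n_cols, B);
  for (int b = 0; b < B; ++b) {
    mat dtok = dT0.rows(b * n, b * n + n - 1);
    dinW += E.slice(b).t() * dtok;
    if (want_dE) dE.slice(b) = dtok * inW.t();
  }
  if (want_grad) {
    List g;
    g["t_in_W"] = dinW; g["t_in_b"] = dinb;
    for (int i = 0; i < depth; ++i) put_block(g, "t" + std::to_string(i), tg[i]);
    g["t_lng"] = dlng; g["t_lnb"] = dlnb;
    g["head_W"] = dhW; g["head_b"] = dhb;
    out["grads"] = g;
  }
  if (want_dE) out["dE"] = dE;
  return out;
}
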