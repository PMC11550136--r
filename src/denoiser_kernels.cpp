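// Compiled kernels for the transformer denoiser: forward and backward
// passes over sequence-major activation matrices (row r = (n-1)*L + l).
// Mirrors the reference R implementation (denoiser_fwd_ref) exactly;
// correctness is pinned by equivalence and central-difference tests.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::rowvec;
using arma::vec;

static const double LN_EPS = 1e-5;

struct LnCache {
  mat Y, xhat;
  vec inv;
};

static void layernorm_fwd_c(const mat& X, const rowvec& g, const rowvec& b,
                            LnCache& c) {
  vec mu = arma::mean(X, 1);
  mat xc = X.each_col() - mu;
  vec v = arma::mean(xc % xc, 1);
  c.inv = 1.0 / arma::sqrt(v + LN_EPS);
  c.xhat = xc.each_col() % c.inv;
  c.Y = c.xhat.each_row() % g;
  c.Y.each_row() += b;
}

static mat layernorm_bwd_c(const LnCache& c, const rowvec& g, const mat& dY,
                           rowvec& dg, rowvec& db) {
  mat dxh = dY.each_row() % g;
  dg = arma::sum(dY % c.xhat, 0);
  db = arma::sum(dY, 0);
  vec m1 = arma::mean(dxh, 1);
  vec m2 = arma::mean(dxh % c.xhat, 1);
  mat dX = dxh;
  dX.each_col() -= m1;
  dX -= c.xhat.each_col() % m2;
  dX.each_col() %= c.inv;
  return dX;
}

static void softmax_rows_inplace(mat& S) {
  vec mx = arma::max(S, 1);
  S.each_col() -= mx;
  S = arma::exp(S);
  vec sm = arma::sum(S, 1);
  S.each_col() /= sm;
}

// block-local multi-head attention; blocks are contiguous row ranges of
// length B. A (attention weights) cached as a cube slice per block*head.
// rel is a heads x (2B-1) learned relative-position bias: logit (i,j)
// gains rel(h, j-i+B-1).
static void attention_fwd_c(const mat& X, const mat& Wq, const mat& Wk,
                            const mat& Wv, const mat& Wo, const mat& rel,
                            int heads, int B,
                            mat& Q, mat& K, mat& V, mat& O, cube& A,
                            mat& Y, bool keep_A) {
  const int R = X.n_rows, d = X.n_cols;
  const int dh = d / heads, nblk = R / B;
  const double scale = 1.0 / std::sqrt((double)dh);
  Q = X * Wq;
  K = X * Wk;
  V = X * Wv;
  O.set_size(R, d);
  if (keep_A) A.set_size(B, B, nblk * heads);
  for (int bi = 0; bi < nblk; ++bi) {
    const int i0 = bi * B, i1 = i0 + B - 1;
    for (int h = 0; h < heads; ++h) {
      const int c0 = h * dh, c1 = c0 + dh - 1;
      mat S = Q.submat(i0, c0, i1, c1) * K.submat(i0, c0, i1, c1).t() * scale;
      for (int i = 0; i < B; ++i) {
        S.row(i) += rel.submat(h, B - 1 - i, h, 2 * B - 2 - i);
      }
      softmax_rows_inplace(S);
      O.submat(i0, c0, i1, c1) = S * V.submat(i0, c0, i1, c1);
      if (keep_A) A.slice(bi * heads + h) = S;
    }
  }
  Y = O * Wo;
}

static mat attention_bwd_c(const mat& X, const mat& Wq, const mat& Wk,
                           const mat& Wv, const mat& Wo, int heads, int B,
                           const mat& Q, const mat& K, const mat& V,
                           const mat& O, const cube& A, const mat& dY,
                           mat& dWq, mat& dWk, mat& dWv, mat& dWo,
                           mat& drel) {
  const int R = X.n_rows, d = X.n_cols;
  const int dh = d / heads, nblk = R / B;
  const double scale = 1.0 / std::sqrt((double)dh);
  mat dO = dY * Wo.t();
  dWo = O.t() * dY;
  mat dQ(R, d), dK(R, d), dV(R, d);
  for (int bi = 0; bi < nblk; ++bi) {
    const int i0 = bi * B, i1 = i0 + B - 1;
    for (int h = 0; h < heads; ++h) {
      const int c0 = h * dh, c1 = c0 + dh - 1;
      const mat& Ah = A.slice(bi * heads + h);
      mat dOb = dO.submat(i0, c0, i1, c1);
      mat dA = dOb * V.submat(i0, c0, i1, c1).t();
      dV.submat(i0, c0, i1, c1) = Ah.t() * dOb;
      // softmax backward: dS = A % (dA - rowsum(A % dA)); the relative
      // bias enters the logits additively, so drel collects dS by offset
      vec rs = arma::sum(Ah % dA, 1);
      mat dSraw = Ah % (dA.each_col() - rs);
      for (int i = 0; i < B; ++i) {
        drel.submat(h, B - 1 - i, h, 2 * B - 2 - i) += dSraw.row(i);
      }
      mat dS = dSraw * scale;
      dQ.submat(i0, c0, i1, c1) = dS * K.submat(i0, c0, i1, c1);
      dK.submat(i0, c0, i1, c1) = dS.t() * Q.submat(i0, c0, i1, c1);
    }
  }
  dWq = X.t() * dQ;
  dWk = X.t() * dK;
  dWv = X.t() * dV;
  return dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
}

static std::string pnm(int l, const char* suffix) {
  return "L" + std::to_string(l + 1) + "." + suffix;
}

// convolutional token embedding: W_emb is (4*k) x d for an odd kernel k;
// position l sees the one-hot window l-(k-1)/2 .. l+(k-1)/2 (zero-padded)
static mat conv_embed_fwd(const mat& xtm_sm, const mat& W_emb, int N, int L) {
  const int k = W_emb.n_rows / 4;
  const int half = (k - 1) / 2;
  const int d = W_emb.n_cols;
  mat H(N * L, d, arma::fill::zeros);
  for (int o = -half; o <= half; ++o) {
    const mat Wo = W_emb.rows((o + half) * 4, (o + half) * 4 + 3);
    // rows l of sequence n read input rows l+o (where valid)
    for (int n = 0; n < N; ++n) {
      const int lo = std::max(0, -o), hi = std::min(L - 1, L - 1 - o);
      if (lo > hi) continue;
      H.rows(n * L + lo, n * L + hi) +=
        xtm_sm.rows(n * L + lo + o, n * L + hi + o) * Wo;
    }
  }
  return H;
}

static mat conv_embed_bwd(const mat& xtm_sm, const mat& dH, int krows,
                          int N, int L) {
  const int k = krows / 4;
  const int half = (k - 1) / 2;
  mat dW(krows, dH.n_cols, arma::fill::zeros);
  for (int o = -half; o <= half; ++o) {
    for (int n = 0; n < N; ++n) {
      const int lo = std::max(0, -o), hi = std::min(L - 1, L - 1 - o);
      if (lo > hi) continue;
      dW.rows((o + half) * 4, (o + half) * 4 + 3) +=
        xtm_sm.rows(n * L + lo + o, n * L + hi + o).t() *
        dH.rows(n * L + lo, n * L + hi);
    }
  }
  return dW;
}

// [[Rcpp::export(name = ".cpp_denoiser_fwd")]]
List cpp_denoiser_fwd(List params, const arma::mat& xtm_sm,
                      const arma::mat& t_emb, const arma::ivec& tv,
                      int N, int L, int layers, int heads, int B,
                      bool keep_cache) {
  mat W_emb = as<mat>(params["W_emb"]);
  mat P_pos = as<mat>(params["P_pos"]);
  const int d = W_emb.n_cols;

  mat W_t = as<mat>(params["W_t"]);
  rowvec b_t = as<rowvec>(params["b_t"]);

  mat H = conv_embed_fwd(xtm_sm, W_emb, N, L);
  mat TEraw(N * L, d);
  for (int n = 0; n < N; ++n) {
    H.rows(n * L, n * L + L - 1) += P_pos;
    TEraw.rows(n * L, n * L + L - 1).each_row() = t_emb.row(tv[n] - 1);
  }
  mat TErows = TEraw * W_t;
  TErows.each_row() += b_t;

  List caches(layers);
  for (int l = 0; l < layers; ++l) {
    rowvec g1 = as<rowvec>(params[pnm(l, "ln1.g")]);
    rowvec b1 = as<rowvec>(params[pnm(l, "ln1.b")]);
    rowvec g2 = as<rowvec>(params[pnm(l, "ln2.g")]);
    rowvec b2 = as<rowvec>(params[pnm(l, "ln2.b")]);
    mat Wq = as<mat>(params[pnm(l, "Wq")]);
    mat Wk = as<mat>(params[pnm(l, "Wk")]);
    mat Wv = as<mat>(params[pnm(l, "Wv")]);
    mat Wo = as<mat>(params[pnm(l, "Wo")]);
    mat W1 = as<mat>(params[pnm(l, "W1")]);
    rowvec bb1 = as<rowvec>(params[pnm(l, "b1")]);
    mat W2 = as<mat>(params[pnm(l, "W2")]);
    rowvec bb2 = as<rowvec>(params[pnm(l, "b2")]);

    H += TErows;
    LnCache ln1;
    layernorm_fwd_c(H, g1, b1, ln1);
    mat Q, K, V, O, attY;
    cube A;
    mat relb = as<mat>(params[pnm(l, "rel")]);
    attention_fwd_c(ln1.Y, Wq, Wk, Wv, Wo, relb, heads, B, Q, K, V, O, A,
                    attY, keep_cache);
    mat H2 = H + attY;
    LnCache ln2;
    layernorm_fwd_c(H2, g2, b2, ln2);
    mat Z1 = ln2.Y * W1;
    Z1.each_row() += bb1;
    mat A1 = Z1;
    A1.transform([](double x) { return x > 0.0 ? x : 0.0; });
    mat F2 = A1 * W2;
    F2.each_row() += bb2;

    if (keep_cache) {
      caches[l] = List::create(
        _["Hin"] = H, _["ln1Y"] = ln1.Y, _["ln1xhat"] = ln1.xhat,
        _["ln1inv"] = ln1.inv, _["Q"] = Q, _["K"] = K, _["V"] = V,
        _["O"] = O, _["A"] = A, _["ln2Y"] = ln2.Y,
        _["ln2xhat"] = ln2.xhat, _["ln2inv"] = ln2.inv, _["Z1"] = Z1,
        _["A1"] = A1);
    }
    H = H2 + F2;
  }

  rowvec gf = as<rowvec>(params["lnf.g"]);
  rowvec bf = as<rowvec>(params["lnf.b"]);
  LnCache lnf;
  layernorm_fwd_c(H, gf, bf, lnf);
  mat W_out = as<mat>(params["W_out"]);
  rowvec b_out = as<rowvec>(params["b_out"]);
  mat logits = lnf.Y * W_out;
  logits.each_row() += b_out;
  mat probs = logits;
  softmax_rows_inplace(probs);

  List out = List::create(_["logits"] = logits, _["probs"] = probs);
  if (keep_cache) {
    out["cache"] = List::create(
      _["layers"] = caches, _["lnfY"] = lnf.Y, _["lnfxhat"] = lnf.xhat,
      _["lnfinv"] = lnf.inv, _["xtm"] = xtm_sm, _["TEraw"] = TEraw);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_denoiser_bwd")]]
List cpp_denoiser_bwd(List params, List cache, const arma::mat& dlogits_sm,
                      int N, int L, int layers, int heads, int B) {
  List g;
  mat W_out = as<mat>(params["W_out"]);
  rowvec gf = as<rowvec>(params["lnf.g"]);

  mat lnfY = as<mat>(cache["lnfY"]);
  LnCache lnf;
  lnf.xhat = as<mat>(cache["lnfxhat"]);
  lnf.inv = as<vec>(cache["lnfinv"]);

  g["W_out"] = lnfY.t() * dlogits_sm;
  g["b_out"] = arma::sum(dlogits_sm, 0);
  mat dlnfY = dlogits_sm * W_out.t();
  rowvec dgf, dbf;
  mat dH = layernorm_bwd_c(lnf, gf, dlnfY, dgf, dbf);
  g["lnf.g"] = dgf;
  g["lnf.b"] = dbf;

  List caches = cache["layers"];
  mat dTE;
  for (int l = layers - 1; l >= 0; --l) {
    List cl = caches[l];
    rowvec g1 = as<rowvec>(params[pnm(l, "ln1.g")]);
    rowvec g2 = as<rowvec>(params[pnm(l, "ln2.g")]);
    mat Wq = as<mat>(params[pnm(l, "Wq")]);
    mat Wk = as<mat>(params[pnm(l, "Wk")]);
    mat Wv = as<mat>(params[pnm(l, "Wv")]);
    mat Wo = as<mat>(params[pnm(l, "Wo")]);
    mat W1 = as<mat>(params[pnm(l, "W1")]);
    mat W2 = as<mat>(params[pnm(l, "W2")]);

    mat A1 = as<mat>(cl["A1"]);
    mat Z1 = as<mat>(cl["Z1"]);
    mat ln2Y = as<mat>(cl["ln2Y"]);

    // FFN branch
    g[pnm(l, "W2")] = A1.t() * dH;
    g[pnm(l, "b2")] = arma::sum(dH, 0);
    mat dZ1 = dH * W2.t();
    dZ1 %= arma::conv_to<mat>::from(Z1 > 0.0);
    g[pnm(l, "W1")] = ln2Y.t() * dZ1;
    g[pnm(l, "b1")] = arma::sum(dZ1, 0);
    mat dln2Y = dZ1 * W1.t();

    LnCache ln2;
    ln2.xhat = as<mat>(cl["ln2xhat"]);
    ln2.inv = as<vec>(cl["ln2inv"]);
    rowvec dg2, db2;
    mat dH2 = dH + layernorm_bwd_c(ln2, g2, dln2Y, dg2, db2);
    g[pnm(l, "ln2.g")] = dg2;
    g[pnm(l, "ln2.b")] = db2;

    // attention branch
    mat ln1Y = as<mat>(cl["ln1Y"]);
    mat Q = as<mat>(cl["Q"]);
    mat K = as<mat>(cl["K"]);
    mat V = as<mat>(cl["V"]);
    mat O = as<mat>(cl["O"]);
    cube A = as<cube>(cl["A"]);
    mat dWq, dWk, dWv, dWo;
    mat drel(heads, 2 * B - 1, arma::fill::zeros);
    mat dln1Y = attention_bwd_c(ln1Y, Wq, Wk, Wv, Wo, heads, B, Q, K, V, O,
                                A, dH2, dWq, dWk, dWv, dWo, drel);
    g[pnm(l, "Wq")] = dWq;
    g[pnm(l, "Wk")] = dWk;
    g[pnm(l, "Wv")] = dWv;
    g[pnm(l, "Wo")] = dWo;
    g[pnm(l, "rel")] = drel;

    LnCache ln1;
    ln1.xhat = as<mat>(cl["ln1xhat"]);
    ln1.inv = as<vec>(cl["ln1inv"]);
    rowvec dg1, db1;
    dH = dH2 + layernorm_bwd_c(ln1, g1, dln1Y, dg1, db1);
    g[pnm(l, "ln1.g")] = dg1;
    g[pnm(l, "ln1.b")] = db1;
    // the projected time embedding enters every layer input
    if (dTE.n_elem == 0) dTE = dH; else dTE += dH;
  }

  mat xtm = as<mat>(cache["xtm"]);
  mat TEraw = as<mat>(cache["TEraw"]);
  g["W_t"] = TEraw.t() * dTE;
  g["b_t"] = arma::sum(dTE, 0);
  g["W_emb"] = conv_embed_bwd(xtm, dH, as<mat>(params["W_emb"]).n_rows, N, L);
  mat dP(L, as<mat>(params["P_pos"]).n_cols, arma::fill::zeros);
  for (int n = 0; n < N; ++n) dP += dH.rows(n * L, n * L + L - 1);
  g["P_pos"] = dP;
  return g;
}
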