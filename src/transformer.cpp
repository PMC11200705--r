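// Transformer encoder classifier: forward pass and hand-written
// backpropagation. Post-norm blocks:
//   x  -> x + Dropout(MHA(x))  -> LayerNorm
//      -> . + Dropout(FF(.))   -> LayerNorm
// preceded by a learned linear embedding plus fixed sinusoidal positional
// encoding, followed by flattening over (time, model) and a fully connected
// softmax classifier.
//
// The whole batch is processed as one (B*L) x d matrix (rows of sample s
// occupy the block [s*L, (s+1)*L)), so projections, feed-forward and layer
// normalization are single BLAS calls; only the attention products are
// per sample and head. Dropout draws come from R's RNG (unif_rand), so
// results are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

static const double LN_EPS = 1e-5;

struct BlockP {
  mat Wq, Wk, Wv, Wo, W1, W2;
  rowvec bq, bk, bv, bo, b1, b2, g1, be1, g2, be2;
};

static mat getm(const List& p, const std::string& nm) { return as<mat>(p[nm]); }
static rowvec getv(const List& p, const std::string& nm) { return as<rowvec>(p[nm]); }

// row-wise layer norm over the feature dimension; caches xhat and 1/sd
static mat layernorm_fwd(const mat& X, const rowvec& g, const rowvec& b,
                         mat& xhat, vec& inv_std) {
  vec mu = arma::mean(X, 1);
  mat c = X.each_col() - mu;
  vec v = arma::mean(c % c, 1);
  inv_std = 1.0 / arma::sqrt(v + LN_EPS);
  xhat = c.each_col() % inv_std;
  mat Y = xhat.each_row() % g;
  Y.each_row() += b;
  return Y;
}

static mat layernorm_bwd(const mat& dY, const rowvec& g, const mat& xhat,
                         const vec& inv_std, rowvec& dg, rowvec& db) {
  dg += arma::sum(dY % xhat, 0);
  db += arma::sum(dY, 0);
  mat dxh = dY.each_row() % g;
  vec m1 = arma::mean(dxh, 1);
  vec m2 = arma::mean(dxh % xhat, 1);
  mat dX = dxh.each_col() - m1;
  dX -= xhat.each_col() % m2;
  dX.each_col() %= inv_std;
  return dX;
}

static void softmax_rows(mat& S) {
  vec mx = arma::max(S, 1);
  S.each_col() -= mx;
  S = arma::exp(S);
  vec tot = arma::sum(S, 1);
  S.each_col() /= tot;
}

// dropout masks come from a fast xorshift generator whose seed is drawn
// once per call from R's RNG, so results stay reproducible under set.seed()
// without paying the Mersenne-Twister cost per element
static inline double xs_unif(uint64_t& s) {
  s ^= s << 13; s ^= s >> 7; s ^= s << 17;
  return (double)(s >> 11) * (1.0 / 9007199254740992.0);
}

// dropout mask with entries 0 or 1/(1-p)
static mat dropout_mask(int nr, int nc, double p, uint64_t& state) {
  mat M(nr, nc);
  const double scale = 1.0 / (1.0 - p);
  double* ptr = M.memptr();
  const size_t n = (size_t)nr * nc;
  for (size_t i = 0; i < n; ++i) ptr[i] = (xs_unif(state) < p) ? 0.0 : scale;
  return M;
}

struct BlockCache {
  mat Xin, Q, K, V, O, M1, Z1, F1, M2, Y1, xhat1, xhat2;
  vec inv1, inv2;
  std::vector<mat> A; // attention weights, indexed s * n_heads + h
};

// [[Rcpp::export(name = ".tf_pass")]]
List tf_pass(List params, const arma::cube& X, IntegerVector y, List cfg,
             bool training, bool compute_grad) {
  const int L = X.n_rows, C = X.n_cols, B = X.n_slices;
  const int d = as<int>(cfg["d_model"]);
  const int n_blocks = as<int>(cfg["n_blocks"]);
  const int n_heads = as<int>(cfg["n_heads"]);
  const int ncls = as<int>(cfg["n_classes"]);
  const double p_drop = training ? as<double>(cfg["dropout"]) : 0.0;
  if (d % n_heads != 0) stop("d_model must be divisible by n_heads");
  const int dh = d / n_heads;
  const double scale = 1.0 / std::sqrt((double)dh);
  const int BL = B * L;

  mat W_emb = getm(params, "W_emb");
  rowvec b_emb = getv(params, "b_emb");
  mat PE = getm(params, "pe");
  mat W_fc = getm(params, "W_fc");
  rowvec b_fc = getv(params, "b_fc");
  if ((int)W_emb.n_rows != C || (int)W_emb.n_cols != d)
    stop("embedding weight shape does not match input channels / d_model");
  if ((int)PE.n_rows != L)
    stop("input length %d does not match configured sequence length %d",
         L, (int)PE.n_rows);
  if ((int)W_fc.n_rows != L * d)
    stop("FC weight shape does not match flattened width");

  std::vector<BlockP> bp(n_blocks);
  for (int i = 0; i < n_blocks; ++i) {
    std::string s = "_" + std::to_string(i + 1);
    BlockP& b = bp[i];
    b.Wq = getm(params, "Wq" + s); b.bq = getv(params, "bq" + s);
    b.Wk = getm(params, "Wk" + s); b.bk = getv(params, "bk" + s);
    b.Wv = getm(params, "Wv" + s); b.bv = getv(params, "bv" + s);
    b.Wo = getm(params, "Wo" + s); b.bo = getv(params, "bo" + s);
    b.g1 = getv(params, "g1" + s); b.be1 = getv(params, "be1" + s);
    b.W1 = getm(params, "W1" + s); b.b1 = getv(params, "b1f" + s);
    b.W2 = getm(params, "W2" + s); b.b2 = getv(params, "b2f" + s);
    b.g2 = getv(params, "g2" + s); b.be2 = getv(params, "be2" + s);
  }

  const bool has_y = y.size() > 0;
  if (compute_grad && !has_y) stop("labels required to compute gradients");
  if (has_y && y.size() != B) stop("label length must match batch size");

  uint64_t rng_state = 1;
  if (p_drop > 0)
    rng_state = (uint64_t)(unif_rand() * 9007199254740992.0) | 1u;

  // stack input slices into one (B*L) x C matrix
  mat Xall(BL, C);
  for (int s = 0; s < B; ++s)
    Xall.rows(s * L, (s + 1) * L - 1) =
        mat(const_cast<double*>(X.slice_memptr(s)), L, C, false, true);

  // ---- forward ----
  mat H = Xall * W_emb;
  H.each_row() += b_emb;
  for (int s = 0; s < B; ++s) H.rows(s * L, (s + 1) * L - 1) += PE;

  std::vector<BlockCache> cache(n_blocks);
  for (int i = 0; i < n_blocks; ++i) {
    BlockP& b = bp[i];
    BlockCache& cc = cache[i];
    cc.Xin = H;
    cc.Q = H * b.Wq; cc.Q.each_row() += b.bq;
    cc.K = H * b.Wk; cc.K.each_row() += b.bk;
    cc.V = H * b.Wv; cc.V.each_row() += b.bv;
    cc.O.set_size(BL, d);
    if (compute_grad) cc.A.resize((size_t)B * n_heads);
    for (int s = 0; s < B; ++s) {
      const arma::span rows(s * L, (s + 1) * L - 1);
      for (int h = 0; h < n_heads; ++h) {
        const arma::span sp(h * dh, (h + 1) * dh - 1);
        mat S = cc.Q(rows, sp) * cc.K(rows, sp).t() * scale;
        softmax_rows(S);
        cc.O(rows, sp) = S * cc.V(rows, sp);
        if (compute_grad) cc.A[(size_t)s * n_heads + h] = std::move(S);
      }
    }
    mat M = cc.O * b.Wo;
    M.each_row() += b.bo;
    if (p_drop > 0) { cc.M1 = dropout_mask(BL, d, p_drop, rng_state); M %= cc.M1; }
    mat R1 = cc.Xin + M;
    cc.Y1 = layernorm_fwd(R1, b.g1, b.be1, cc.xhat1, cc.inv1);
    cc.Z1 = cc.Y1 * b.W1;
    cc.Z1.each_row() += b.b1;
    cc.F1 = arma::clamp(cc.Z1, 0.0, arma::datum::inf);
    mat F2 = cc.F1 * b.W2;
    F2.each_row() += b.b2;
    if (p_drop > 0) { cc.M2 = dropout_mask(BL, d, p_drop, rng_state); F2 %= cc.M2; }
    mat R2 = cc.Y1 + F2;
    H = layernorm_fwd(R2, b.g2, b.be2, cc.xhat2, cc.inv2);
    if (!compute_grad && i < n_blocks - 1) cache[i] = BlockCache();
  }

  // flatten (column-major per sample: time index fastest) and classify
  mat F(B, L * d);
  for (int s = 0; s < B; ++s)
    F.row(s) = arma::vectorise(H.rows(s * L, (s + 1) * L - 1)).t();
  mat logits = F * W_fc;
  logits.each_row() += b_fc;
  mat probs = logits;
  softmax_rows(probs);

  double loss = NA_REAL;
  if (has_y) {
    loss = 0.0;
    for (int s = 0; s < B; ++s) {
      int cls = y[s];
      if (cls < 0 || cls >= ncls) stop("label out of range");
      loss += -std::log(std::max(probs(s, cls), 1e-300));
    }
    loss /= B;
  }

  List out = List::create(_["probs"] = probs, _["loss"] = loss,
                          _["flat_width"] = L * d);
  if (!compute_grad) return out;

  // ---- backward ----
  mat dz = probs;
  for (int s = 0; s < B; ++s) dz(s, y[s]) -= 1.0;
  dz /= (double)B;
  mat dW_fc = F.t() * dz;
  rowvec db_fc = arma::sum(dz, 0);
  mat dF = dz * W_fc.t();
  mat dH(BL, d);
  for (int s = 0; s < B; ++s)
    dH.rows(s * L, (s + 1) * L - 1) = arma::reshape(dF.row(s).t(), L, d);

  List gr;
  for (int i = n_blocks - 1; i >= 0; --i) {
    BlockP& b = bp[i];
    BlockCache& cc = cache[i];
    rowvec dg2(d, arma::fill::zeros), dbe2(d, arma::fill::zeros);
    mat dR2 = layernorm_bwd(dH, b.g2, cc.xhat2, cc.inv2, dg2, dbe2);
    mat dY1 = dR2;
    mat dF2 = (p_drop > 0) ? mat(dR2 % cc.M2) : dR2;
    mat dW2 = cc.F1.t() * dF2;
    rowvec db2 = arma::sum(dF2, 0);
    mat dF1 = dF2 * b.W2.t();
    mat dZ1 = dF1;
    {
      double* dz1 = dZ1.memptr();
      const double* z1 = cc.Z1.memptr();
      const size_t n = dZ1.n_elem;
      for (size_t k = 0; k < n; ++k) if (z1[k] <= 0) dz1[k] = 0.0;
    }
    mat dW1 = cc.Y1.t() * dZ1;
    rowvec db1 = arma::sum(dZ1, 0);
    dY1 += dZ1 * b.W1.t();
    rowvec dg1(d, arma::fill::zeros), dbe1(d, arma::fill::zeros);
    mat dR1 = layernorm_bwd(dY1, b.g1, cc.xhat1, cc.inv1, dg1, dbe1);
    mat dM = (p_drop > 0) ? mat(dR1 % cc.M1) : dR1;
    mat dWo = cc.O.t() * dM;
    rowvec dbo = arma::sum(dM, 0);
    mat dO = dM * b.Wo.t();
    mat dQ(BL, d), dK(BL, d), dV(BL, d);
    for (int s = 0; s < B; ++s) {
      const arma::span rows(s * L, (s + 1) * L - 1);
      for (int h = 0; h < n_heads; ++h) {
        const arma::span sp(h * dh, (h + 1) * dh - 1);
        const mat& A = cc.A[(size_t)s * n_heads + h];
        mat dOh = dO(rows, sp);
        mat dA = dOh * cc.V(rows, sp).t();
        dV(rows, sp) = A.t() * dOh;
        vec rs = arma::sum(dA % A, 1);
        mat dS = A % (dA.each_col() - rs);
        dQ(rows, sp) = dS * cc.K(rows, sp) * scale;
        dK(rows, sp) = dS.t() * cc.Q(rows, sp) * scale;
      }
    }
    std::string sfx = "_" + std::to_string(i + 1);
    gr["Wq" + sfx] = mat(cc.Xin.t() * dQ); gr["bq" + sfx] = rowvec(arma::sum(dQ, 0));
    gr["Wk" + sfx] = mat(cc.Xin.t() * dK); gr["bk" + sfx] = rowvec(arma::sum(dK, 0));
    gr["Wv" + sfx] = mat(cc.Xin.t() * dV); gr["bv" + sfx] = rowvec(arma::sum(dV, 0));
    gr["Wo" + sfx] = dWo; gr["bo" + sfx] = dbo;
    gr["g1" + sfx] = dg1; gr["be1" + sfx] = dbe1;
    gr["W1" + sfx] = dW1; gr["b1f" + sfx] = db1;
    gr["W2" + sfx] = dW2; gr["b2f" + sfx] = db2;
    gr["g2" + sfx] = dg2; gr["be2" + sfx] = dbe2;
    mat dXin = dR1 + dQ * b.Wq.t() + dK * b.Wk.t() + dV * b.Wv.t();
    dH = dXin;
    cache[i] = BlockCache(); // release
  }
  gr["W_emb"] = mat(Xall.t() * dH);
  gr["b_emb"] = rowvec(arma::sum(dH, 0));
  gr["W_fc"] = dW_fc;
  gr["b_fc"] = db_fc;
  out["grads"] = gr;
  return out;
}
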