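// Transformer encoder forward/backward.
//
// Sequences are stacked row-wise into (sum of lengths) x dim matrices so the
// projection and feed-forward GEMMs run over the whole mini-batch at once;
// only the n x n attention softmax is computed per sequence and head.
// Padding positions are dropped before stacking (right-padding only), which
// realises mask-aware attention exactly: a padded key can never receive
// probability mass, and real positions are unchanged.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LN_EPS = 1e-5;

struct LayerCache {
  arma::mat X, Q, K, V, O;      // block input, projections, concat heads
  std::vector<std::vector<arma::mat>> P;  // softmax matrices [seq][head]
  arma::mat xhat1, Y1, H, G, xhat2;
  arma::vec invstd1, invstd2;
};

struct EncCache {
  std::vector<int> tok, pos;    // stacked 0-based token ids / positions
  std::vector<int> starts, lens;  // 0-based row starts, true lengths
  int n_heads = 0, vocab_size = 0, max_len = 0, ff_dim = 0, dim = 0,
      n_layers = 0;
  std::vector<LayerCache> layers;
};

static arma::mat ln_forward(const arma::mat& R, const arma::vec& g,
                            const arma::vec& b, arma::mat& xhat,
                            arma::vec& invstd) {
  arma::vec mu = arma::mean(R, 1);
  arma::mat C = R.each_col() - mu;
  arma::vec v = arma::mean(arma::square(C), 1);
  invstd = 1.0 / arma::sqrt(v + LN_EPS);
  xhat = C.each_col() % invstd;
  arma::mat Y = xhat.each_row() % g.t();
  Y.each_row() += b.t();
  return Y;
}

static arma::mat ln_backward(const arma::mat& dY, const arma::mat& xhat,
                             const arma::vec& invstd, const arma::vec& g,
                             arma::vec& dg, arma::vec& db) {
  dg = arma::sum(dY % xhat, 0).t();
  db = arma::sum(dY, 0).t();
  arma::mat dxhat = dY.each_row() % g.t();
  arma::vec m1 = arma::mean(dxhat, 1);
  arma::vec m2 = arma::mean(dxhat % xhat, 1);
  arma::mat dR = dxhat.each_col() - m1;
  dR -= xhat.each_col() % m2;
  dR.each_col() %= invstd;
  return dR;
}

static const double GELU_C = 0.7978845608028654;  // sqrt(2/pi)
static const double GELU_A = 0.044715;

static arma::mat gelu(const arma::mat& x) {
  arma::mat x2 = arma::square(x);
  arma::mat u = GELU_C * (x + GELU_A * (x2 % x));
  return 0.5 * x % (1.0 + arma::tanh(u));
}

static arma::mat dgelu(const arma::mat& x) {
  arma::mat x2 = arma::square(x);
  arma::mat u = GELU_C * (x + GELU_A * (x2 % x));
  arma::mat t = arma::tanh(u);
  return 0.5 * (1.0 + t) +
         0.5 * x % (1.0 - arma::square(t)) %
             (GELU_C * (1.0 + 3.0 * GELU_A * x2));
}

static arma::vec get_vec(const List& lp, const char* nm) {
  return as<arma::vec>(lp[nm]);
}
static arma::mat get_mat(const List& lp, const char* nm) {
  return as<arma::mat>(lp[nm]);
}

// [[Rcpp::export]]
List cpp_enc_forward(List params, IntegerMatrix ids, IntegerVector lens,
                     int n_heads, bool keep_cache) {
  arma::mat tok_emb = as<arma::mat>(params["tok_emb"]);
  arma::mat pos_emb = as<arma::mat>(params["pos_emb"]);
  List layers = params["layers"];
  const int L = layers.size();
  const int d = tok_emb.n_cols;
  const int n_seq = ids.nrow();
  if (d % n_heads != 0) stop("dim not divisible by n_heads");
  const int dk = d / n_heads;
  const double scale = 1.0 / std::sqrt((double)dk);

  EncCache* cache = new EncCache();
  cache->n_heads = n_heads;
  cache->vocab_size = tok_emb.n_rows;
  cache->max_len = pos_emb.n_rows;
  cache->dim = d;
  cache->n_layers = L;

  int N = 0;
  cache->starts.resize(n_seq);
  cache->lens.resize(n_seq);
  for (int s = 0; s < n_seq; ++s) {
    cache->starts[s] = N;
    cache->lens[s] = lens[s];
    N += lens[s];
  }
  cache->tok.resize(N);
  cache->pos.resize(N);
  arma::mat X(N, d);
  for (int s = 0; s < n_seq; ++s) {
    for (int t = 0; t < lens[s]; ++t) {
      int r = cache->starts[s] + t;
      int id = ids(s, t);
      if (id < 0 || id >= (int)tok_emb.n_rows) {
        delete cache;
        stop("token id outside the vocabulary");
      }
      cache->tok[r] = id;
      cache->pos[r] = t;
      X.row(r) = tok_emb.row(id) + pos_emb.row(t);
    }
  }

  List outputs(L + 1);
  outputs[0] = wrap(X);
  cache->layers.resize(L);

  for (int l = 0; l < L; ++l) {
    List lp = layers[l];
    LayerCache& lc = cache->layers[l];
    arma::mat Wq = get_mat(lp, "Wq"), Wk = get_mat(lp, "Wk"),
              Wv = get_mat(lp, "Wv"), Wo = get_mat(lp, "Wo");
    arma::vec bq = get_vec(lp, "bq"), bk = get_vec(lp, "bk"),
              bv = get_vec(lp, "bv"), bo = get_vec(lp, "bo");
    arma::mat Q = X * Wq; Q.each_row() += bq.t();
    arma::mat K = X * Wk; K.each_row() += bk.t();
    arma::mat V = X * Wv; V.each_row() += bv.t();
    arma::mat O(N, d);
    if (keep_cache) lc.P.resize(n_seq);
    for (int s = 0; s < n_seq; ++s) {
      int r0 = cache->starts[s], n = cache->lens[s];
      if (keep_cache) lc.P[s].resize(n_heads);
      for (int h = 0; h < n_heads; ++h) {
        int c0 = h * dk, c1 = (h + 1) * dk - 1;
        arma::mat Qh = Q.submat(r0, c0, r0 + n - 1, c1);
        arma::mat Kh = K.submat(r0, c0, r0 + n - 1, c1);
        arma::mat S = scale * (Qh * Kh.t());
        S.each_col() -= arma::max(S, 1);
        arma::mat P = arma::exp(S);
        P.each_col() /= arma::sum(P, 1);
        O.submat(r0, c0, r0 + n - 1, c1) =
            P * V.submat(r0, c0, r0 + n - 1, c1);
        if (keep_cache) lc.P[s][h] = P;
      }
    }
    arma::mat A = O * Wo; A.each_row() += bo.t();
    arma::mat R1 = X + A;
    arma::mat Y1 = ln_forward(R1, get_vec(lp, "ln1_g"), get_vec(lp, "ln1_b"),
                              lc.xhat1, lc.invstd1);
    arma::mat W1 = get_mat(lp, "W1"), W2 = get_mat(lp, "W2");
    arma::vec b1 = get_vec(lp, "b1"), b2 = get_vec(lp, "b2");
    if (l == 0) cache->ff_dim = W1.n_cols;
    arma::mat H = Y1 * W1; H.each_row() += b1.t();
    arma::mat G = gelu(H);
    arma::mat FF = G * W2; FF.each_row() += b2.t();
    arma::mat R2 = Y1 + FF;
    arma::mat Y2 = ln_forward(R2, get_vec(lp, "ln2_g"), get_vec(lp, "ln2_b"),
                              lc.xhat2, lc.invstd2);
    if (keep_cache) {
      lc.X = std::move(X); lc.Q = std::move(Q); lc.K = std::move(K);
      lc.V = std::move(V); lc.O = std::move(O);
      lc.Y1 = std::move(Y1); lc.H = std::move(H); lc.G = std::move(G);
    } else {
      lc.P.clear();
      lc.xhat1.reset(); lc.xhat2.reset();
      lc.invstd1.reset(); lc.invstd2.reset();
    }
    X = std::move(Y2);
    outputs[l + 1] = wrap(X);
  }

  IntegerVector starts(n_seq);
  for (int s = 0; s < n_seq; ++s) starts[s] = cache->starts[s] + 1;  // 1-based

  List res = List::create(Named("outputs") = outputs,
                          Named("starts") = starts);
  if (keep_cache) {
    XPtr<EncCache> xp(cache, true);
    res["cache"] = xp;
  } else {
    delete cache;
    res["cache"] = R_NilValue;
  }
  return res;
}

// [[Rcpp::export]]
List cpp_enc_backward(SEXP cache_xp, List params, List grad_outputs) {
  XPtr<EncCache> xp(cache_xp);
  EncCache* cache = xp.get();
  if (cache == nullptr || cache->n_layers == 0)
    stop("invalid or expired encoder cache");
  List layers = params["layers"];
  const int L = cache->n_layers;
  const int d = cache->dim;
  const int n_heads = cache->n_heads;
  const int dk = d / n_heads;
  const double scale = 1.0 / std::sqrt((double)dk);
  const int n_seq = cache->starts.size();
  const int N = cache->tok.size();
  if ((int)grad_outputs.size() != L + 1)
    stop("grad_outputs must have n_layers + 1 elements");

  auto grad_at = [&](int k) -> arma::mat {
    RObject g = grad_outputs[k];
    if (g.isNULL()) return arma::mat();
    arma::mat m = as<arma::mat>(g);
    if (m.n_elem == 0) return arma::mat();
    if ((int)m.n_rows != N || (int)m.n_cols != d)
      stop("gradient shape mismatch");
    return m;
  };

  arma::mat carry = grad_at(L);
  if (carry.n_elem == 0) carry = arma::zeros(N, d);

  List layer_grads(L);
  for (int l = L - 1; l >= 0; --l) {
    List lp = layers[l];
    LayerCache& lc = cache->layers[l];
    arma::mat W1 = get_mat(lp, "W1"), W2 = get_mat(lp, "W2");
    arma::mat Wq = get_mat(lp, "Wq"), Wk = get_mat(lp, "Wk"),
              Wv = get_mat(lp, "Wv"), Wo = get_mat(lp, "Wo");

    arma::vec dg2, db2l;
    arma::mat dR2 = ln_backward(carry, lc.xhat2, lc.invstd2,
                                get_vec(lp, "ln2_g"), dg2, db2l);
    // R2 = Y1 + G*W2 + b2
    arma::mat dG = dR2 * W2.t();
    arma::mat dW2 = lc.G.t() * dR2;
    arma::vec db2 = arma::sum(dR2, 0).t();
    arma::mat dH = dG % dgelu(lc.H);
    arma::mat dW1 = lc.Y1.t() * dH;
    arma::vec db1 = arma::sum(dH, 0).t();
    arma::mat dY1 = dR2 + dH * W1.t();

    arma::vec dg1, db1l;
    arma::mat dR1 = ln_backward(dY1, lc.xhat1, lc.invstd1,
                                get_vec(lp, "ln1_g"), dg1, db1l);
    // R1 = X + O*Wo + bo
    arma::mat dO = dR1 * Wo.t();
    arma::mat dWo = lc.O.t() * dR1;
    arma::vec dbo = arma::sum(dR1, 0).t();

    arma::mat dQ(N, d, arma::fill::zeros), dK(N, d, arma::fill::zeros),
        dV(N, d, arma::fill::zeros);
    for (int s = 0; s < n_seq; ++s) {
      int r0 = cache->starts[s], n = cache->lens[s];
      for (int h = 0; h < n_heads; ++h) {
        int c0 = h * dk, c1 = (h + 1) * dk - 1;
        const arma::mat& P = lc.P[s][h];
        arma::mat dOh = dO.submat(r0, c0, r0 + n - 1, c1);
        arma::mat Vh = lc.V.submat(r0, c0, r0 + n - 1, c1);
        arma::mat Qh = lc.Q.submat(r0, c0, r0 + n - 1, c1);
        arma::mat Kh = lc.K.submat(r0, c0, r0 + n - 1, c1);
        arma::mat dP = dOh * Vh.t();
        dV.submat(r0, c0, r0 + n - 1, c1) = P.t() * dOh;
        arma::vec rs = arma::sum(dP % P, 1);
        arma::mat dS = P % (dP.each_col() - rs);
        dQ.submat(r0, c0, r0 + n - 1, c1) = scale * (dS * Kh);
        dK.submat(r0, c0, r0 + n - 1, c1) = scale * (dS.t() * Qh);
      }
    }
    arma::mat dWq = lc.X.t() * dQ;
    arma::mat dWk = lc.X.t() * dK;
    arma::mat dWv = lc.X.t() * dV;
    arma::vec dbq = arma::sum(dQ, 0).t();
    arma::vec dbk = arma::sum(dK, 0).t();
    arma::vec dbv = arma::sum(dV, 0).t();

    arma::mat dX = dR1 + dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();

    layer_grads[l] = List::create(
        Named("Wq") = dWq, Named("bq") = dbq, Named("Wk") = dWk,
        Named("bk") = dbk, Named("Wv") = dWv, Named("bv") = dbv,
        Named("Wo") = dWo, Named("bo") = dbo, Named("ln1_g") = dg1,
        Named("ln1_b") = db1l, Named("W1") = dW1, Named("b1") = db1,
        Named("W2") = dW2, Named("b2") = db2, Named("ln2_g") = dg2,
        Named("ln2_b") = db2l);

    carry = dX;
    arma::mat inj = grad_at(l);
    if (inj.n_elem > 0) carry += inj;
  }

  arma::mat d_tok = arma::zeros(cache->vocab_size, d);
  arma::mat d_pos = arma::zeros(cache->max_len, d);
  for (int r = 0; r < N; ++r) {
    d_tok.row(cache->tok[r]) += carry.row(r);
    d_pos.row(cache->pos[r]) += carry.row(r);
  }

  return List::create(Named("tok_emb") = d_tok, Named("pos_emb") = d_pos,
                      Named("layers") = layer_grads);
}
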