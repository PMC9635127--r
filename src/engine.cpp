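// Numerical engine: forward pass, backpropagation and Adam updates for the
// conv + transformer + pooled-head classifier. All randomness (weight init,
// shuffling, dropout masks) is drawn on the R side; everything here is
// deterministic, so seeded runs are bit-reproducible on one platform.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;

// ---------------------------------------------------------------- conversions

static mat as_mat(SEXP x) {
  Rcpp::NumericMatrix M(x);
  return mat(M.begin(), M.nrow(), M.ncol());
}

static vec as_col(SEXP x) {
  Rcpp::NumericVector v(x);
  return vec(v.begin(), v.size());
}

static cube as_cube(SEXP x) {
  Rcpp::NumericVector v(x);
  Rcpp::IntegerVector d = v.attr("dim");
  return cube(v.begin(), d[0], d[1], d[2]);
}

static Rcpp::NumericVector cube_to_r(const cube& c) {
  Rcpp::NumericVector v(c.begin(), c.end());
  v.attr("dim") = Rcpp::IntegerVector::create(c.n_rows, c.n_cols, c.n_slices);
  return v;
}

// ------------------------------------------------------------- model weights

struct ConvW { cube W; vec b; vec g; vec be; };

struct TxW {
  mat Wq, Wk, Wv, Wo;
  vec ln1g, ln1b;
  mat W1; vec b1; mat W2; vec b2;
  vec ln2g, ln2b;
};

struct HeadW { mat W1; vec b1; mat W2; vec b2; bool two; };

struct Model {
  std::vector<ConvW> conv;
  bool use_tx;
  TxW tx;
  HeadW head;
};

static Model model_from_list(const List& w) {
  Model m;
  for (int b = 1;; ++b) {
    std::string nm = "conv" + std::to_string(b) + "_W";
    if (!w.containsElementNamed(nm.c_str())) break;
    std::string p = "conv" + std::to_string(b);
    ConvW cb;
    cb.W = as_cube(w[p + "_W"]);
    cb.b = as_col(w[p + "_b"]);
    cb.g = as_col(w[p + "_g"]);
    cb.be = as_col(w[p + "_beta"]);
    m.conv.push_back(cb);
  }
  m.use_tx = w.containsElementNamed("tx_Wq");
  if (m.use_tx) {
    m.tx.Wq = as_mat(w["tx_Wq"]);   m.tx.Wk = as_mat(w["tx_Wk"]);
    m.tx.Wv = as_mat(w["tx_Wv"]);   m.tx.Wo = as_mat(w["tx_Wo"]);
    m.tx.ln1g = as_col(w["tx_ln1_g"]); m.tx.ln1b = as_col(w["tx_ln1_b"]);
    m.tx.W1 = as_mat(w["tx_ffn_W1"]);  m.tx.b1 = as_col(w["tx_ffn_b1"]);
    m.tx.W2 = as_mat(w["tx_ffn_W2"]);  m.tx.b2 = as_col(w["tx_ffn_b2"]);
    m.tx.ln2g = as_col(w["tx_ln2_g"]); m.tx.ln2b = as_col(w["tx_ln2_b"]);
  }
  m.head.W1 = as_mat(w["fc1_W"]);
  m.head.b1 = as_col(w["fc1_b"]);
  m.head.two = w.containsElementNamed("fc2_W");
  if (m.head.two) {
    m.head.W2 = as_mat(w["fc2_W"]);
    m.head.b2 = as_col(w["fc2_b"]);
  }
  return m;
}

static List model_to_list(const Model& m) {
  List out;
  for (size_t b = 0; b < m.conv.size(); ++b) {
    std::string p = "conv" + std::to_string(b + 1);
    out[p + "_W"] = cube_to_r(m.conv[b].W);
    out[p + "_b"] = Rcpp::wrap(m.conv[b].b);
    out[p + "_g"] = Rcpp::wrap(m.conv[b].g);
    out[p + "_beta"] = Rcpp::wrap(m.conv[b].be);
  }
  if (m.use_tx) {
    out["tx_Wq"] = Rcpp::wrap(m.tx.Wq);   out["tx_Wk"] = Rcpp::wrap(m.tx.Wk);
    out["tx_Wv"] = Rcpp::wrap(m.tx.Wv);   out["tx_Wo"] = Rcpp::wrap(m.tx.Wo);
    out["tx_ln1_g"] = Rcpp::wrap(m.tx.ln1g); out["tx_ln1_b"] = Rcpp::wrap(m.tx.ln1b);
    out["tx_ffn_W1"] = Rcpp::wrap(m.tx.W1);  out["tx_ffn_b1"] = Rcpp::wrap(m.tx.b1);
    out["tx_ffn_W2"] = Rcpp::wrap(m.tx.W2);  out["tx_ffn_b2"] = Rcpp::wrap(m.tx.b2);
    out["tx_ln2_g"] = Rcpp::wrap(m.tx.ln2g); out["tx_ln2_b"] = Rcpp::wrap(m.tx.ln2b);
  }
  out["fc1_W"] = Rcpp::wrap(m.head.W1);
  out["fc1_b"] = Rcpp::wrap(m.head.b1);
  if (m.head.two) {
    out["fc2_W"] = Rcpp::wrap(m.head.W2);
    out["fc2_b"] = Rcpp::wrap(m.head.b2);
  }
  return out;
}

// Flat views over every trainable array, in a fixed structural order shared by
// weights, gradients and Adam moments.
static void spans(Model& m, std::vector<std::pair<double*, uword>>& out) {
  for (auto& cb : m.conv) {
    out.push_back({cb.W.memptr(), cb.W.n_elem});
    out.push_back({cb.b.memptr(), cb.b.n_elem});
    out.push_back({cb.g.memptr(), cb.g.n_elem});
    out.push_back({cb.be.memptr(), cb.be.n_elem});
  }
  if (m.use_tx) {
    out.push_back({m.tx.Wq.memptr(), m.tx.Wq.n_elem});
    out.push_back({m.tx.Wk.memptr(), m.tx.Wk.n_elem});
    out.push_back({m.tx.Wv.memptr(), m.tx.Wv.n_elem});
    out.push_back({m.tx.Wo.memptr(), m.tx.Wo.n_elem});
    out.push_back({m.tx.ln1g.memptr(), m.tx.ln1g.n_elem});
    out.push_back({m.tx.ln1b.memptr(), m.tx.ln1b.n_elem});
    out.push_back({m.tx.W1.memptr(), m.tx.W1.n_elem});
    out.push_back({m.tx.b1.memptr(), m.tx.b1.n_elem});
    out.push_back({m.tx.W2.memptr(), m.tx.W2.n_elem});
    out.push_back({m.tx.b2.memptr(), m.tx.b2.n_elem});
    out.push_back({m.tx.ln2g.memptr(), m.tx.ln2g.n_elem});
    out.push_back({m.tx.ln2b.memptr(), m.tx.ln2b.n_elem});
  }
  out.push_back({m.head.W1.memptr(), m.head.W1.n_elem});
  out.push_back({m.head.b1.memptr(), m.head.b1.n_elem});
  if (m.head.two) {
    out.push_back({m.head.W2.memptr(), m.head.W2.n_elem});
    out.push_back({m.head.b2.memptr(), m.head.b2.n_elem});
  }
}

static Model zeros_like(const Model& m) {
  Model z = m;
  std::vector<std::pair<double*, uword>> sp;
  spans(z, sp);
  for (auto& s : sp) std::memset(s.first, 0, s.second * sizeof(double));
  return z;
}

// ------------------------------------------------------------ layer norm

struct LNCache { mat xhat; vec sigma; };

// Position-wise: each row of X is normalized over its channels with the
// population (biased) variance, then scaled/shifted per channel.
static mat ln_forward(const mat& X, const vec& g, const vec& b, double eps,
                      LNCache& c) {
  vec mu = mean(X, 1);
  mat Xc = X.each_col() - mu;
  vec v = mean(square(Xc), 1);
  c.sigma = sqrt(v + eps);
  c.xhat = Xc.each_col() / c.sigma;
  mat Y = c.xhat;
  Y.each_row() %= g.t();
  Y.each_row() += b.t();
  return Y;
}

static mat ln_backward(const mat& dY, const LNCache& c, const vec& g,
                       vec& dg, vec& db) {
  dg += sum(dY % c.xhat, 0).t();
  db += sum(dY, 0).t();
  mat G = dY;
  G.each_row() %= g.t();
  vec mg = mean(G, 1);
  vec mgx = mean(G % c.xhat, 1);
  mat dX = G;
  dX.each_col() -= mg;
  dX -= c.xhat.each_col() % mgx;
  dX.each_col() /= c.sigma;
  return dX;
}

// ------------------------------------------------------------ conv block

struct ConvCache { mat Xpad; LNCache ln; mat rmask; int Lin; int Lout; };

// 1-D conv (stride 1, zero same-padding) -> layer norm -> ReLU ->
// non-overlapping average pooling (floor length division).
static mat conv_block_fwd(const mat& X, const ConvW& w, double eps, int pool,
                          ConvCache& c) {
  const int L = X.n_rows, K = w.W.n_slices;
  const int Cin = w.W.n_cols, Cout = w.W.n_rows;
  if ((int)X.n_cols != Cin)
    Rcpp::stop("conv block expects %d input channels, got %d", Cin, (int)X.n_cols);
  if (L < pool)
    Rcpp::stop("feature map of length %d is shorter than the pooling kernel %d", L, pool);
  const int pl = (K - 1) / 2;
  c.Lin = L;
  c.Xpad.zeros(L + K - 1, Cin);
  c.Xpad.rows(pl, pl + L - 1) = X;
  mat Y(L, Cout);
  Y.each_row() = w.b.t();
  for (int k = 0; k < K; ++k)
    Y += c.Xpad.rows(k, k + L - 1) * w.W.slice(k).t();
  mat Yn = ln_forward(Y, w.g, w.be, eps, c.ln);
  c.rmask = conv_to<mat>::from(Yn > 0);
  Yn %= c.rmask;
  const int Lout = L / pool;
  c.Lout = Lout;
  mat P(Lout, Cout);
  for (int j = 0; j < Lout; ++j)
    P.row(j) = mean(Yn.rows(j * pool, j * pool + pool - 1), 0);
  return P;
}

static mat conv_block_bwd(const mat& dP, const ConvW& w, ConvW& g,
                          const ConvCache& c, int pool, bool need_dx) {
  const int L = c.Lin, K = w.W.n_slices;
  const int Cin = w.W.n_cols, Cout = w.W.n_rows;
  mat dY(L, Cout, fill::zeros);
  for (int j = 0; j < c.Lout; ++j) {
    rowvec r = dP.row(j) / pool;
    for (int t = 0; t < pool; ++t) dY.row(j * pool + t) += r;
  }
  dY %= c.rmask;
  mat dC = ln_backward(dY, c.ln, w.g, g.g, g.be);
  g.b += sum(dC, 0).t();
  mat dXpad;
  if (need_dx) dXpad.zeros(c.Xpad.n_rows, Cin);
  for (int k = 0; k < K; ++k) {
    g.W.slice(k) += dC.t() * c.Xpad.rows(k, k + L - 1);
    if (need_dx) dXpad.rows(k, k + L - 1) += dC * w.W.slice(k);
  }
  if (!need_dx) return mat();
  const int pl = (K - 1) / 2;
  return dXpad.rows(pl, pl + L - 1);
}

// ------------------------------------------------------------ attention

static mat softmax_rows(mat S) {
  vec mx = max(S, 1);
  S.each_col() -= mx;
  mat E = exp(S);
  vec sm = sum(E, 1);
  E.each_col() /= sm;
  return E;
}

struct TxCache {
  mat Z, H, Mid, F1;
  cube Q, K, V, A;
  LNCache ln1, ln2;
  mat fmask;
};

// Single post-norm encoder layer: Mid = LN(Z + MultiHead(Z));
// Output = LN(Mid + FFN(Mid)). Scaled dot-product attention uses the
// per-head width d/h in the softmax scale.
static mat encoder_fwd(const mat& Z, const TxW& w, int h, double eps,
                       TxCache& c) {
  const int l = Z.n_rows, d = Z.n_cols, dh = d / h;
  const double s = std::sqrt((double)dh);
  c.Z = Z;
  c.Q.set_size(l, dh, h); c.K.set_size(l, dh, h); c.V.set_size(l, dh, h);
  c.A.set_size(l, l, h);
  c.H.set_size(l, d);
  for (int i = 0; i < h; ++i) {
    const uword a = i * dh, b = (i + 1) * dh - 1;
    mat Qi = Z * w.Wq.cols(a, b);
    mat Ki = Z * w.Wk.cols(a, b);
    mat Vi = Z * w.Wv.cols(a, b);
    mat Ai = softmax_rows(Qi * Ki.t() / s);
    c.Q.slice(i) = Qi; c.K.slice(i) = Ki; c.V.slice(i) = Vi; c.A.slice(i) = Ai;
    c.H.cols(a, b) = Ai * Vi;
  }
  mat O = c.H * w.Wo;
  c.Mid = ln_forward(Z + O, w.ln1g, w.ln1b, eps, c.ln1);
  mat F1 = c.Mid * w.W1;
  F1.each_row() += w.b1.t();
  c.fmask = conv_to<mat>::from(F1 > 0);
  F1 %= c.fmask;
  c.F1 = F1;
  mat F = F1 * w.W2;
  F.each_row() += w.b2.t();
  return ln_forward(c.Mid + F, w.ln2g, w.ln2b, eps, c.ln2);
}

static mat encoder_bwd(const mat& dOut, const TxW& w, TxW& g,
                       const TxCache& c, int h) {
  const int d = c.Z.n_cols, dh = d / h;
  const double s = std::sqrt((double)dh);
  mat dOutin = ln_backward(dOut, c.ln2, w.ln2g, g.ln2g, g.ln2b);
  mat dMid = dOutin;                       // residual branch
  g.b2 += sum(dOutin, 0).t();
  g.W2 += c.F1.t() * dOutin;
  mat dF1 = dOutin * w.W2.t();
  dF1 %= c.fmask;
  g.b1 += sum(dF1, 0).t();
  g.W1 += c.Mid.t() * dF1;
  dMid += dF1 * w.W1.t();
  mat dMidin = ln_backward(dMid, c.ln1, w.ln1g, g.ln1g, g.ln1b);
  mat dZ = dMidin;                         // residual branch
  g.Wo += c.H.t() * dMidin;
  mat dH = dMidin * w.Wo.t();
  for (int i = 0; i < h; ++i) {
    const uword a = i * dh, b = (i + 1) * dh - 1;
    mat dHi = dH.cols(a, b);
    const mat& Ai = c.A.slice(i);
    mat dAi = dHi * c.V.slice(i).t();
    mat dVi = Ai.t() * dHi;
    vec rs = sum(dAi % Ai, 1);
    mat dS = Ai % (dAi.each_col() - rs);
    dS /= s;
    mat dQi = dS * c.K.slice(i);
    mat dKi = dS.t() * c.Q.slice(i);
    g.Wq.cols(a, b) += c.Z.t() * dQi;
    g.Wk.cols(a, b) += c.Z.t() * dKi;
    g.Wv.cols(a, b) += c.Z.t() * dVi;
    dZ += dQi * w.Wq.cols(a, b).t();
    dZ += dKi * w.Wk.cols(a, b).t();
    dZ += dVi * w.Wv.cols(a, b).t();
  }
  return dZ;
}

// ------------------------------------------------------------ full model

struct Caches {
  std::vector<ConvCache> conv;
  TxCache tx;
  int gap_rows;
  rowvec v, a1, rd;
  double p;
};

static double model_fwd(const mat& X, const Model& m, int h, double eps,
                        int pool, const rowvec& mask, Caches& c) {
  mat cur = X;
  c.conv.resize(m.conv.size());
  for (size_t b = 0; b < m.conv.size(); ++b)
    cur = conv_block_fwd(cur, m.conv[b], eps, pool, c.conv[b]);
  if (m.use_tx) cur = encoder_fwd(cur, m.tx, h, eps, c.tx);
  c.gap_rows = cur.n_rows;
  c.v = mean(cur, 0);
  double z;
  if (m.head.two) {
    c.a1 = c.v * m.head.W1 + m.head.b1.t();
    rowvec r = c.a1;
    r.transform([](double x) { return x > 0.0 ? x : 0.0; });
    c.rd = mask.n_elem ? rowvec(r % mask) : r;
    z = dot(c.rd, m.head.W2.col(0)) + m.head.b2(0);
  } else {
    z = dot(c.v, m.head.W1.col(0)) + m.head.b1(0);
  }
  c.p = 1.0 / (1.0 + std::exp(-z));
  return c.p;
}

// Returns the weighted BCE loss and accumulates gradients into g.
static double model_bwd(double y, double wp, double wn, const Model& m,
                        Model& g, Caches& c, const rowvec& mask, int h,
                        int pool) {
  const double p = std::min(std::max(c.p, 1e-12), 1.0 - 1e-12);
  const double loss = -(wp * y * std::log(p) + wn * (1.0 - y) * std::log1p(-p));
  const double dz = -wp * y * (1.0 - p) + wn * (1.0 - y) * p;
  rowvec dv;
  if (m.head.two) {
    g.head.W2.col(0) += (dz * c.rd).t();
    g.head.b2(0) += dz;
    rowvec drd = dz * m.head.W2.col(0).t();
    if (mask.n_elem) drd %= mask;
    for (uword i = 0; i < drd.n_elem; ++i) if (c.a1(i) <= 0.0) drd(i) = 0.0;
    g.head.W1 += c.v.t() * drd;
    g.head.b1 += drd.t();
    dv = drd * m.head.W1.t();
  } else {
    g.head.W1.col(0) += (dz * c.v).t();
    g.head.b1(0) += dz;
    dv = dz * m.head.W1.col(0).t();
  }
  mat dOut = repmat(dv / c.gap_rows, c.gap_rows, 1);
  if (m.use_tx) dOut = encoder_bwd(dOut, m.tx, g.tx, c.tx, h);
  for (int b = (int)m.conv.size() - 1; b >= 0; --b)
    dOut = conv_block_bwd(dOut, m.conv[b], g.conv[b], c.conv[b], pool, b > 0);
  return loss;
}

// ------------------------------------------------------------ exports

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_layer_norm(Rcpp::NumericMatrix X, Rcpp::NumericVector g,
                                   Rcpp::NumericVector b, double eps) {
  LNCache c;
  mat Y = ln_forward(as_mat(X), as_col(g), as_col(b), eps, c);
  return Rcpp::wrap(Y);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_conv_block(Rcpp::NumericMatrix X, Rcpp::NumericVector W,
                                   Rcpp::NumericVector b, Rcpp::NumericVector g,
                                   Rcpp::NumericVector beta, double eps, int pool) {
  ConvW w;
  w.W = as_cube(W); w.b = as_col(b); w.g = as_col(g); w.be = as_col(beta);
  ConvCache c;
  mat P = conv_block_fwd(as_mat(X), w, eps, pool, c);
  return Rcpp::wrap(P);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_sdpa(Rcpp::NumericMatrix Q, Rcpp::NumericMatrix K,
                             Rcpp::NumericMatrix V) {
  mat q = as_mat(Q), k = as_mat(K), v = as_mat(V);
  const double s = std::sqrt((double)q.n_cols);
  mat A = softmax_rows(q * k.t() / s);
  mat out = A * v;
  return Rcpp::wrap(out);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_mha(Rcpp::NumericMatrix Z, Rcpp::NumericMatrix Wq,
                            Rcpp::NumericMatrix Wk, Rcpp::NumericMatrix Wv,
                            Rcpp::NumericMatrix Wo, int h) {
  mat z = as_mat(Z), wq = as_mat(Wq), wk = as_mat(Wk), wv = as_mat(Wv),
      wo = as_mat(Wo);
  const int d = z.n_cols, dh = d / h;
  const double s = std::sqrt((double)dh);
  mat H(z.n_rows, d);
  for (int i = 0; i < h; ++i) {
    const uword a = i * dh, b = (i + 1) * dh - 1;
    mat Qi = z * wq.cols(a, b), Ki = z * wk.cols(a, b), Vi = z * wv.cols(a, b);
    H.cols(a, b) = softmax_rows(Qi * Ki.t() / s) * Vi;
  }
  mat out = H * wo;
  return Rcpp::wrap(out);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_encoder(Rcpp::NumericMatrix Z, List txw, int h,
                                double eps) {
  TxW w;
  w.Wq = as_mat(txw["tx_Wq"]);   w.Wk = as_mat(txw["tx_Wk"]);
  w.Wv = as_mat(txw["tx_Wv"]);   w.Wo = as_mat(txw["tx_Wo"]);
  w.ln1g = as_col(txw["tx_ln1_g"]); w.ln1b = as_col(txw["tx_ln1_b"]);
  w.W1 = as_mat(txw["tx_ffn_W1"]);  w.b1 = as_col(txw["tx_ffn_b1"]);
  w.W2 = as_mat(txw["tx_ffn_W2"]);  w.b2 = as_col(txw["tx_ffn_b2"]);
  w.ln2g = as_col(txw["tx_ln2_g"]); w.ln2b = as_col(txw["tx_ln2_b"]);
  TxCache c;
  mat out = encoder_fwd(as_mat(Z), w, h, eps, c);
  return Rcpp::wrap(out);
}

// [[Rcpp::export]]
double cpp_forward(List wlist, Rcpp::NumericMatrix X, int h, double eps,
                   int pool, Rcpp::NumericVector mask) {
  Model m = model_from_list(wlist);
  Caches c;
  rowvec mk(mask.begin(), mask.size());
  return model_fwd(as_mat(X), m, h, eps, pool, mk, c);
}

// [[Rcpp::export]]
List cpp_loss_grad(List wlist, Rcpp::NumericMatrix X, double y, double wp,
                   double wn, int h, double eps, int pool,
                   Rcpp::NumericVector mask) {
  Model m = model_from_list(wlist);
  Model g = zeros_like(m);
  Caches c;
  rowvec mk(mask.begin(), mask.size());
  double p = model_fwd(as_mat(X), m, h, eps, pool, mk, c);
  double loss = model_bwd(y, wp, wn, m, g, c, mk, h, pool);
  return List::create(Rcpp::Named("p") = p, Rcpp::Named("loss") = loss,
                      Rcpp::Named("grads") = model_to_list(g));
}

static void adam_update(Model& w, Model& g, Model& m1, Model& m2, int t,
                        double lr, double b1, double b2, double eps) {
  std::vector<std::pair<double*, uword>> sw, sg, sm, sv;
  spans(w, sw); spans(g, sg); spans(m1, sm); spans(m2, sv);
  const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  for (size_t i = 0; i < sw.size(); ++i) {
    double* pw = sw[i].first;
    double* pg = sg[i].first;
    double* pm = sm[i].first;
    double* pv = sv[i].first;
    for (uword j = 0; j < sw[i].second; ++j) {
      pm[j] = b1 * pm[j] + (1.0 - b1) * pg[j];
      pv[j] = b2 * pv[j] + (1.0 - b2) * pg[j] * pg[j];
      pw[j] -= lr * (pm[j] / c1) / (std::sqrt(pv[j] / c2) + eps);
    }
  }
}

// One epoch: samples are visited in `order` (1-based), per-sample gradients
// are summed in groups of `accum` (final partial group still updates), and
// one Adam step is applied per group. masks has one row per visited sample
// (already inverted-dropout scaled); a 0-row matrix disables dropout.
// [[Rcpp::export]]
List cpp_train_epoch(List wlist, List mlist, List vlist, int t, List xs,
                     Rcpp::NumericVector ys, Rcpp::IntegerVector order,
                     Rcpp::NumericMatrix masks, double lr, int accum,
                     double wp, double wn, int h, double eps, int pool,
                     double beta1, double beta2, double adam_eps) {
  Model w = model_from_list(wlist);
  Model m1 = model_from_list(mlist);
  Model m2 = model_from_list(vlist);
  Model g = zeros_like(w);
  const int n = order.size();
  const bool use_mask = masks.nrow() > 0;
  double loss_sum = 0.0;
  int in_group = 0;
  for (int i = 0; i < n; ++i) {
    const int idx = order[i] - 1;
    mat X = as_mat(xs[idx]);
    rowvec mk;
    if (use_mask) {
      Rcpp::NumericMatrix::Row r = masks(i, Rcpp::_);
      mk = rowvec(masks.ncol());
      for (int j = 0; j < masks.ncol(); ++j) mk(j) = r[j];
    }
    Caches c;
    model_fwd(X, w, h, eps, pool, mk, c);
    loss_sum += model_bwd(ys[idx], wp, wn, w, g, c, mk, h, pool);
    ++in_group;
    if (in_group == accum || i == n - 1) {
      ++t;
      adam_update(w, g, m1, m2, t, lr, beta1, beta2, adam_eps);
      g = zeros_like(w);
      in_group = 0;
    }
  }
  return List::create(
      Rcpp::Named("weights") = model_to_list(w),
      Rcpp::Named("m") = model_to_list(m1),
      Rcpp::Named("v") = model_to_list(m2),
      Rcpp::Named("t") = t,
      Rcpp::Named("loss_sum") = loss_sum);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_predict(List wlist, List xs, int h, double eps,
                                int pool) {
  Model m = model_from_list(wlist);
  const int n = xs.size();
  Rcpp::NumericVector out(n);
  rowvec mk;
  for (int i = 0; i < n; ++i) {
    Caches c;
    out[i] = model_fwd(as_mat(xs[i]), m, h, eps, pool, mk, c);
  }
  return out;
}
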