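// Multitask LSTM network: two stacked LSTM layers scanning a 701-sample
// normalized voltage sequence, feeding (flattened hidden sequence) two fully
// connected heads -- a linear translation head producing the adult trace and
// a sigmoid classification head producing the drugged probability.
//
// Forward pass and reverse-mode (backprop-through-time) gradients of the
// joint loss J = mean(CrossEntropy) + mean(MSE) are implemented here for a
// mini-batch; inverted dropout (masks scaled by 1/(1-p) at train time) is
// applied to LSTM layer outputs and FC hidden activations.
//
// Parameter vector layout (flat, column-major within blocks):
//   W1 (4H x (1+H)), b1 (4H)                      LSTM layer 1 [f;i;s;o]
//   W2 (4H x 2H),    b2 (4H)                      LSTM layer 2 (if 2 layers)
//   Wt1 (TH x T*H),  bt1 (TH)                     translation hidden (ReLU)
//   Wt2 (T x TH),    bt2 (T)                      translation output (linear)
//   Wc1 (CH x T*H),  bc1 (CH)                     classification hidden (ReLU)
//   Wc2 (1 x CH),    bc2 (1)                      classification output (sigmoid)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>
using namespace arma;

namespace {

struct Dims {
  int T, H, TH, CH, layers;
  bool has_class() const { return CH > 0; }
  uword n_params() const {
    uword n = 4u * H * (1 + H) + 4u * H;                 // layer 1
    if (layers == 2) n += 4u * H * (2 * H) + 4u * H;     // layer 2
    n += (uword)TH * ((uword)T * H) + TH;                // trans hidden
    n += (uword)T * TH + T;                              // trans out
    if (has_class()) {
      n += (uword)CH * ((uword)T * H) + CH;              // class hidden
      n += (uword)CH + 1;                                // class out
    }
    return n;
  }
};

// sequential views into the flat parameter vector (zero-copy)
struct ParamView {
  double* p;
  uword off = 0, total;
  ParamView(double* ptr, uword n) : p(ptr), total(n) {}
  mat M(uword r, uword c) {
    mat m(p + off, r, c, false, true);
    off += r * c;
    return m;
  }
  vec V(uword n) {
    vec v(p + off, n, false, true);
    off += n;
    return v;
  }
  void done() const {
    if (off != total) Rcpp::stop("parameter vector length mismatch: used %d of %d",
                                 (int)off, (int)total);
  }
};

inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct MaskGen {
  std::mt19937_64 eng;
  std::uniform_real_distribution<double> unif;
  double p, scale;
  bool active;
  MaskGen(uint64_t seed, double p_, bool training)
    : eng(seed), unif(0.0, 1.0), p(p_), scale(p_ < 1.0 ? 1.0 / (1.0 - p_) : 0.0),
      active(training && p_ > 0.0) {}
  // inverted-dropout mask (entries 0 or 1/(1-p))
  mat operator()(uword r, uword c) {
    mat m(r, c);
    if (!active) { m.fill(1.0); return m; }
    for (uword j = 0; j < c; ++j)
      for (uword i = 0; i < r; ++i)
        m(i, j) = (unif(eng) < p) ? 0.0 : scale;
    return m;
  }
};

struct LSTMLayerCache {
  cube f, i, s, o, c, tanhc, h;
  void init(uword H, uword B, uword T) {
    f.set_size(H, B, T); i.set_size(H, B, T); s.set_size(H, B, T);
    o.set_size(H, B, T); c.set_size(H, B, T); tanhc.set_size(H, B, T);
    h.set_size(H, B, T);
  }
};

// one LSTM layer scan; X_t supplied by a callable returning (in x B)
template <typename InputAt>
void lstm_forward(const mat& W, const vec& b, uword H, uword B, uword T,
                  InputAt input_at, uword in_dim, LSTMLayerCache& cc) {
  cc.init(H, B, T);
  mat h(H, B, fill::zeros), c(H, B, fill::zeros);
  const mat Wx = W.cols(0, in_dim - 1);
  const mat Wh = W.cols(in_dim, in_dim + H - 1);
  for (uword t = 0; t < T; ++t) {
    mat G = Wx * input_at(t) + Wh * h;
    G.each_col() += b;
    mat f = sigm(G.rows(0, H - 1));
    mat i = sigm(G.rows(H, 2 * H - 1));
    mat s = tanh(G.rows(2 * H, 3 * H - 1));
    mat o = sigm(G.rows(3 * H, 4 * H - 1));
    c = f % c + i % s;
    mat tc = tanh(c);
    h = o % tc;
    cc.f.slice(t) = f; cc.i.slice(t) = i; cc.s.slice(t) = s; cc.o.slice(t) = o;
    cc.c.slice(t) = c; cc.tanhc.slice(t) = tc; cc.h.slice(t) = h;
  }
}

} // namespace

// Full forward pass (optionally with caches for the backward pass).
// X: T x B inputs; Y: T x B targets (translation); labels: B (0/1) or empty.
// Returns gradients when want_grad.
// [[Rcpp::export(name = ".net_eval_cpp")]]
Rcpp::List net_eval_cpp(const arma::mat& X,
                        Rcpp::NumericVector params,
                        int T, int H, int TH, int CH, int layers,
                        double dropout, bool training, uint64_t seed,
                        Rcpp::Nullable<Rcpp::NumericMatrix> Y_ = R_NilValue,
                        Rcpp::Nullable<Rcpp::NumericVector> labels_ = R_NilValue,
                        bool want_grad = false) {
  if (layers != 1 && layers != 2) Rcpp::stop("layers must be 1 or 2");
  Dims d{T, H, TH, CH, layers};
  if ((uword)params.size() != d.n_params())
    Rcpp::stop("parameter vector has length %d; expected %d",
               (int)params.size(), (int)d.n_params());
  if ((int)X.n_rows != T)
    Rcpp::stop("input sequence length %d does not match network window %d",
               (int)X.n_rows, T);
  if (!X.is_finite()) Rcpp::stop("non-finite values in network input");
  const uword B = X.n_cols;

  ParamView pv(params.begin(), d.n_params());
  mat W1 = pv.M(4 * H, 1 + H);       vec b1 = pv.V(4 * H);
  mat W2, b2m; vec b2;
  if (layers == 2) { W2 = pv.M(4 * H, 2 * H); b2 = pv.V(4 * H); }
  mat Wt1 = pv.M(TH, (uword)T * H);  vec bt1 = pv.V(TH);
  mat Wt2 = pv.M(T, TH);             vec bt2 = pv.V(T);
  mat Wc1, Wc2; vec bc1, bc2;
  if (d.has_class()) {
    Wc1 = pv.M(CH, (uword)T * H); bc1 = pv.V(CH);
    Wc2 = pv.M(1, CH);            bc2 = pv.V(1);
  }
  pv.done();

  MaskGen mg(seed, dropout, training);

  // ---- forward ----
  LSTMLayerCache L1, L2;
  lstm_forward(W1, b1, H, B, T,
               [&](uword t) { return X.row(t); }, 1, L1);
  cube mask1;
  cube x2;  // layer-2 inputs after dropout (kept for backward)
  if (layers == 2) {
    mask1.set_size(H, B, T);
    x2.set_size(H, B, T);
    for (uword t = 0; t < T; ++t) {
      mask1.slice(t) = mg(H, B);
      x2.slice(t) = L1.h.slice(t) % mask1.slice(t);
    }
    lstm_forward(W2, b2, H, B, T,
                 [&](uword t) { return x2.slice(t); }, H, L2);
  }
  const LSTMLayerCache& Ltop = (layers == 2) ? L2 : L1;

  // flatten hidden sequence: rows (t*H + j), with dropout
  mat A0((uword)T * H, B);
  for (uword t = 0; t < T; ++t)
    A0.rows(t * H, t * H + H - 1) = Ltop.h.slice(t);
  mat mask0 = mg((uword)T * H, B);
  A0 %= mask0;

  // translation head
  mat Z1 = Wt1 * A0; Z1.each_col() += bt1;
  mat R1 = clamp(Z1, 0.0, datum::inf);     // ReLU
  mat maskt = mg(TH, B);
  mat A1 = R1 % maskt;
  mat Yhat = Wt2 * A1; Yhat.each_col() += bt2;

  // classification head
  rowvec prob;
  mat Zc, Rc, Ac, maskc;
  if (d.has_class()) {
    Zc = Wc1 * A0; Zc.each_col() += bc1;
    Rc = clamp(Zc, 0.0, datum::inf);
    maskc = mg(CH, B);
    Ac = Rc % maskc;
    rowvec z = Wc2 * Ac + bc2(0);
    prob = 1.0 / (1.0 + exp(-z));
  }
  if (!Yhat.is_finite())
    Rcpp::stop("non-finite activations in translation head");

  Rcpp::List out = Rcpp::List::create(
    Rcpp::_["yhat"] = Yhat,
    Rcpp::_["prob"] = d.has_class() ? Rcpp::wrap(prob) : R_NilValue);

  const bool have_y = Y_.isNotNull();
  if (!have_y && !want_grad) return out;

  // ---- losses ----
  double mse = NA_REAL, ce = NA_REAL;
  mat Y;
  rowvec labels;
  const double delta = 1e-7;
  if (have_y) {
    Y = Rcpp::as<mat>(Y_.get());
    if (Y.n_rows != (uword)T || Y.n_cols != B) Rcpp::stop("target shape mismatch");
    mse = accu(square(Yhat - Y)) / ((double)T * B);
  }
  if (d.has_class() && labels_.isNotNull()) {
    labels = Rcpp::as<rowvec>(Rcpp::NumericVector(labels_.get()));
    if (labels.n_elem != B) Rcpp::stop("label length mismatch");
    rowvec pc = clamp(prob, delta, 1.0 - delta);
    ce = accu(-(labels % log(pc) + (1.0 - labels) % log(1.0 - pc))) / (double)B;
  }
  double J = (std::isnan(mse) ? 0.0 : mse) + (std::isnan(ce) ? 0.0 : ce);
  out["mse"] = mse; out["ce"] = ce; out["loss"] = J;
  if (!want_grad) return out;
  if (!have_y) Rcpp::stop("gradients require targets");

  // ---- backward ----
  mat gW1(4 * H, 1 + H, fill::zeros);      vec gb1(4 * H, fill::zeros);
  mat gW2; vec gb2;
  if (layers == 2) { gW2.zeros(4 * H, 2 * H); gb2.zeros(4 * H); }
  mat gWt1(TH, (uword)T * H, fill::zeros); vec gbt1(TH, fill::zeros);
  mat gWt2(T, TH, fill::zeros);            vec gbt2(T, fill::zeros);
  mat gWc1, gWc2; vec gbc1, gbc2;
  if (d.has_class()) {
    gWc1.zeros(CH, (uword)T * H); gbc1.zeros(CH);
    gWc2.zeros(1, CH);            gbc2.zeros(1);
  }

  // translation head backward
  mat dYhat = (2.0 / ((double)T * B)) * (Yhat - Y);
  gWt2 += dYhat * A1.t();
  gbt2 += sum(dYhat, 1);
  mat dA1 = Wt2.t() * dYhat;
  mat dZ1 = (dA1 % maskt) % conv_to<mat>::from(Z1 > 0.0);
  gWt1 += dZ1 * A0.t();
  gbt1 += sum(dZ1, 1);
  mat dA0 = Wt1.t() * dZ1;

  // classification head backward
  if (d.has_class() && labels.n_elem == B) {
    // d(CE)/dz with the clipped probability in the CE but the exact
    // sigmoid derivative, so the finite-difference oracle matches
    rowvec pc = clamp(prob, delta, 1.0 - delta);
    rowvec dCEdp = (pc - labels) / (pc % (1.0 - pc)) / (double)B;
    rowvec dz = dCEdp % (prob % (1.0 - prob));
    gWc2 += dz * Ac.t();
    gbc2(0) += accu(dz);
    mat dAc = Wc2.t() * dz;
    mat dZc = (dAc % maskc) % conv_to<mat>::from(Zc > 0.0);
    gWc1 += dZc * A0.t();
    gbc1 += sum(dZc, 1);
    dA0 += Wc1.t() * dZc;
  }

  dA0 %= mask0;

  // BPTT through the top layer, then (if present) layer 1
  auto bptt = [&](const LSTMLayerCache& cc, const mat& W, mat& gW, vec& gb,
                  uword in_dim,
                  std::function<mat(uword)> input_at,
                  std::function<void(uword, const mat&)> add_dx,
                  std::function<mat(uword)> dh_ext) {
    const mat Wx = W.cols(0, in_dim - 1);
    const mat Wh = W.cols(in_dim, in_dim + H - 1);
    mat gWx(size(Wx), fill::zeros), gWh(size(Wh), fill::zeros);
    vec gbl(4 * H, fill::zeros);
    mat dh_rec(H, B, fill::zeros), dc(H, B, fill::zeros);
    for (sword t = T - 1; t >= 0; --t) {
      mat dh = dh_ext(t) + dh_rec;
      const mat& f = cc.f.slice(t); const mat& i = cc.i.slice(t);
      const mat& s = cc.s.slice(t); const mat& o = cc.o.slice(t);
      const mat& tc = cc.tanhc.slice(t);
      mat dzo = (dh % tc) % o % (1.0 - o);
      dc += (dh % o) % (1.0 - square(tc));
      mat cprev = (t == 0) ? mat(H, B, fill::zeros) : cc.c.slice(t - 1);
      mat dzf = (dc % cprev) % f % (1.0 - f);
      mat dzi = (dc % s) % i % (1.0 - i);
      mat dzs = (dc % i) % (1.0 - square(s));
      mat dG = join_cols(dzf, dzi, dzs, dzo);
      mat xin = input_at(t);
      gWx += dG * xin.t();
      mat hprev = (t == 0) ? mat(H, B, fill::zeros)
                           : cc.h.slice(t - 1);
      gWh += dG * hprev.t();
      gbl += sum(dG, 1);
      add_dx(t, Wx.t() * dG);
      dh_rec = Wh.t() * dG;
      dc %= f;
    }
    gW.cols(0, in_dim - 1) += gWx;
    gW.cols(in_dim, in_dim + H - 1) += gWh;
    gb += gbl;
  };

  cube dh1(H, B, T, fill::zeros); // gradient wrt layer-1 outputs
  if (layers == 2) {
    bptt(L2, W2, gW2, gb2, H,
         [&](uword t) { return x2.slice(t); },
         [&](uword t, const mat& dx) { dh1.slice(t) += dx % mask1.slice(t); },
         [&](uword t) { return dA0.rows(t * H, t * H + H - 1); });
    bptt(L1, W1, gW1, gb1, 1,
         [&](uword t) { return mat(X.row(t)); },
         [&](uword, const mat&) {},
         [&](uword t) { return dh1.slice(t); });
  } else {
    bptt(L1, W1, gW1, gb1, 1,
         [&](uword t) { return mat(X.row(t)); },
         [&](uword, const mat&) {},
         [&](uword t) { return dA0.rows(t * H, t * H + H - 1); });
  }

  // serialize gradient blocks in parameter order
  Rcpp::NumericVector grad_out((R_xlen_t)d.n_params());
  double* gp = grad_out.begin();
  auto putM = [&gp](const mat& m) { std::copy(m.begin(), m.end(), gp); gp += m.n_elem; };
  auto putV = [&gp](const vec& v) { std::copy(v.begin(), v.end(), gp); gp += v.n_elem; };
  putM(gW1); putV(gb1);
  if (layers == 2) { putM(gW2); putV(gb2); }
  putM(gWt1); putV(gbt1); putM(gWt2); putV(gbt2);
  if (d.has_class()) { putM(gWc1); putV(gbc1); putM(gWc2); putV(gbc2); }
  out["grad"] = grad_out;
  return out;
}

// In-place fused ADAM step used by the training loop's hot path; the R-level
// adam_update() implements the identical update functionally.
// [[Rcpp::export(name = ".adam_step_cpp")]]
void adam_step_cpp(Rcpp::NumericVector theta, Rcpp::NumericVector grad,
                   Rcpp::NumericVector m, Rcpp::NumericVector v, int t,
                   double alpha, double beta1, double beta2, double eps) {
  const R_xlen_t n = theta.size();
  if (grad.size() != n || m.size() != n || v.size() != n)
    Rcpp::stop("ADAM buffers must match the parameter length");
  const double c1 = 1.0 - std::pow(beta1, t);
  const double c2 = 1.0 - std::pow(beta2, t);
  double* th = theta.begin(); double* g = grad.begin();
  double* mm = m.begin(); double* vv = v.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = g[i];
    if (!std::isfinite(gi)) Rcpp::stop("non-finite gradient at index %ld", (long)(i + 1));
    mm[i] = (1.0 - beta1) * gi + beta1 * mm[i];
    vv[i] = (1.0 - beta2) * gi * gi + beta2 * vv[i];
    const double mhat = mm[i] / c1;
    const double vhat = vv[i] / c2;
    th[i] -= alpha * mhat / (std::sqrt(vhat) + eps);
  }
}

// Expose the dropout mask stream so its statistics can be validated.
// [[Rcpp::export(name = ".dropout_mask_cpp")]]
arma::mat dropout_mask_cpp(int r, int c, double p, uint64_t seed) {
  MaskGen mg(seed, p, true);
  return mg(r, c);
}
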