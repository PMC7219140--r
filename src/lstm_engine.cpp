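// Stacked (optionally bidirectional) LSTM sequence regressor.
//
// Forward pass implements the standard gated recurrence
//   i = sigmoid(W_i x + V_i h_prev + b_i)      (input gate)
//   f = sigmoid(W_f x + V_f h_prev + b_f)      (forget gate)
//   o = sigmoid(W_o x + V_o h_prev + b_o)      (output gate)
//   c = f . c_prev + i . tanh(W_c x + V_c h_prev + b_c)
//   h = o . tanh(c)
// for every layer and direction; in a bidirectional stack each layer above
// the first consumes the concatenated forward/backward hidden sequences of
// the layer below. A linear readout maps the top-layer states at the
// prediction position(s) to one value. Training is full backprop through
// time with Adam, minibatched; all matrices carry a batch of windows in
// their columns so each timestep is a handful of BLAS-3 calls.
//
// Gate blocks are packed row-wise in the order [i; f; o; c] inside W
// (4H x D), V (4H x H) and b (4H).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;

static inline mat sigm(const mat &x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct LayerDir {
  mat W, V;
  vec b;
};

struct Params {
  int H = 0, L = 0, D = 0;
  bool bi = false;
  std::vector<LayerDir> fwd, bwd; // one per layer
  vec w_out;                      // H (uni) or 2H (bi: [fwd; bwd])
  double b_out = 0.0;
};

struct DirCache {
  // all H x B, indexed by sequence position s
  std::vector<mat> i, f, o, g, cprev, tc, h, hprev;
  void init(int T) {
    i.assign(T, mat()); f.assign(T, mat()); o.assign(T, mat());
    g.assign(T, mat()); cprev.assign(T, mat()); tc.assign(T, mat());
    h.assign(T, mat()); hprev.assign(T, mat());
  }
};

static Params params_from_list(const List &pl) {
  Params p;
  p.H = as<int>(pl["hidden"]);
  p.L = as<int>(pl["depth"]);
  p.D = as<int>(pl["input_dim"]);
  p.bi = as<bool>(pl["bidirectional"]);
  List layers = pl["layers"];
  for (int l = 0; l < p.L; ++l) {
    List lay = layers[l];
    List fw = lay["fwd"];
    LayerDir d;
    d.W = as<mat>(fw["W"]); d.V = as<mat>(fw["V"]); d.b = as<vec>(fw["b"]);
    p.fwd.push_back(d);
    if (p.bi) {
      List bw = lay["bwd"];
      LayerDir e;
      e.W = as<mat>(bw["W"]); e.V = as<mat>(bw["V"]); e.b = as<vec>(bw["b"]);
      p.bwd.push_back(e);
    }
  }
  List ro = pl["readout"];
  p.w_out = as<vec>(ro["w"]);
  p.b_out = as<double>(ro["b"]);
  return p;
}

static List params_to_list(const Params &p) {
  List layers(p.L);
  for (int l = 0; l < p.L; ++l) {
    List lay = List::create(
        _["fwd"] = List::create(_["W"] = p.fwd[l].W, _["V"] = p.fwd[l].V,
                                _["b"] = p.fwd[l].b));
    if (p.bi)
      lay["bwd"] = List::create(_["W"] = p.bwd[l].W, _["V"] = p.bwd[l].V,
                                _["b"] = p.bwd[l].b);
    layers[l] = lay;
  }
  return List::create(
      _["hidden"] = p.H, _["depth"] = p.L, _["input_dim"] = p.D,
      _["bidirectional"] = p.bi, _["layers"] = layers,
      _["readout"] = List::create(_["w"] = p.w_out, _["b"] = p.b_out));
}

// Run one direction of one layer over the input sequence.
static void run_dir(const LayerDir &p, const std::vector<mat> &in,
                    bool backward, DirCache &K) {
  const int T = (int)in.size();
  const int H = (int)p.V.n_rows / 4;
  const int B = (int)in[0].n_cols;
  K.init(T);
  mat h(H, B, arma::fill::zeros), c(H, B, arma::fill::zeros);
  for (int step = 0; step < T; ++step) {
    const int s = backward ? T - 1 - step : step;
    K.hprev[s] = h;
    mat a = p.W * in[s] + p.V * h;
    a.each_col() += p.b;
    mat ig = sigm(a.rows(0, H - 1));
    mat fg = sigm(a.rows(H, 2 * H - 1));
    mat og = sigm(a.rows(2 * H, 3 * H - 1));
    mat gg = arma::tanh(a.rows(3 * H, 4 * H - 1));
    K.cprev[s] = c;
    c = fg % c + ig % gg;
    mat tc = arma::tanh(c);
    h = og % tc;
    K.i[s] = ig; K.f[s] = fg; K.o[s] = og; K.g[s] = gg;
    K.tc[s] = tc; K.h[s] = h;
  }
}

// BPTT through one direction of one layer. dh_inj[s] may be empty (no
// injected gradient at that position). din accumulates input gradients.
static void back_dir(const LayerDir &p, const std::vector<mat> &in,
                     bool backward, const DirCache &K,
                     const std::vector<mat> &dh_inj, LayerDir &g,
                     std::vector<mat> &din) {
  const int T = (int)in.size();
  const int H = (int)p.V.n_rows / 4;
  const int B = (int)in[0].n_cols;
  g.W.zeros(p.W.n_rows, p.W.n_cols);
  g.V.zeros(p.V.n_rows, p.V.n_cols);
  g.b.zeros(p.b.n_elem);
  mat dh_c(H, B, arma::fill::zeros), dc_c(H, B, arma::fill::zeros);
  mat da(4 * H, B);
  for (int step = T - 1; step >= 0; --step) {
    const int s = backward ? T - 1 - step : step;
    mat dh = dh_c;
    if (dh_inj[s].n_elem > 0) dh += dh_inj[s];
    mat dog = dh % K.tc[s];
    mat dc = dh % K.o[s] % (1.0 - arma::square(K.tc[s])) + dc_c;
    dc_c = dc % K.f[s];
    da.rows(0, H - 1) = (dc % K.g[s]) % K.i[s] % (1.0 - K.i[s]);
    da.rows(H, 2 * H - 1) = (dc % K.cprev[s]) % K.f[s] % (1.0 - K.f[s]);
    da.rows(2 * H, 3 * H - 1) = dog % K.o[s] % (1.0 - K.o[s]);
    da.rows(3 * H, 4 * H - 1) = (dc % K.i[s]) % (1.0 - arma::square(K.g[s]));
    g.W += da * in[s].t();
    g.V += da * K.hprev[s].t();
    g.b += arma::sum(da, 1);
    dh_c = p.V.t() * da;
    din[s] += p.W.t() * da;
  }
}

struct StackCache {
  std::vector<std::vector<mat>> inputs;  // per layer, per position
  std::vector<DirCache> fwd, bwd;        // per layer
};

// Full forward pass; returns predictions for the batch.
static vec stack_forward(const Params &p, const cube &X, int p_f, int p_b,
                         StackCache *K) {
  const int T = (int)X.n_cols;
  const int B = (int)X.n_slices;
  std::vector<mat> in(T);
  for (int s = 0; s < T; ++s) {
    in[s] = mat(X.n_rows, B);
    for (int b = 0; b < B; ++b) in[s].col(b) = X.slice(b).col(s);
  }
  std::vector<DirCache> fc(p.L), bc(p.L);
  std::vector<std::vector<mat>> inputs;
  for (int l = 0; l < p.L; ++l) {
    inputs.push_back(in);
    run_dir(p.fwd[l], in, false, fc[l]);
    if (p.bi) run_dir(p.bwd[l], in, true, bc[l]);
    if (l + 1 < p.L) {
      std::vector<mat> nxt(T);
      for (int s = 0; s < T; ++s)
        nxt[s] = p.bi ? arma::join_cols(fc[l].h[s], bc[l].h[s]) : fc[l].h[s];
      in = nxt;
    }
  }
  const int H = p.H;
  vec pred(B);
  mat top = fc[p.L - 1].h[p_f];
  if (p.bi) {
    mat topb = bc[p.L - 1].h[p_b];
    pred = top.t() * p.w_out.subvec(0, H - 1) +
           topb.t() * p.w_out.subvec(H, 2 * H - 1);
  } else {
    pred = top.t() * p.w_out;
  }
  pred += p.b_out;
  if (K) {
    K->inputs = std::move(inputs);
    K->fwd = std::move(fc);
    K->bwd = std::move(bc);
  }
  return pred;
}

// Gradient of mean squared error over the batch w.r.t. all parameters.
static double stack_backward(const Params &p, const StackCache &K,
                             const vec &pred, const vec &y, int p_f, int p_b,
                             Params &g) {
  const int T = (int)K.inputs[0].size();
  const int B = (int)pred.n_elem;
  const int H = p.H;
  vec resid = pred - y;
  double loss = arma::dot(resid, resid) / B;
  arma::rowvec dpred = (2.0 / B) * resid.t(); // 1 x B

  g.H = p.H; g.L = p.L; g.D = p.D; g.bi = p.bi;
  g.fwd.assign(p.L, LayerDir());
  if (p.bi) g.bwd.assign(p.L, LayerDir());
  g.w_out.zeros(p.w_out.n_elem);
  g.b_out = arma::accu(dpred);

  mat topf = K.fwd[p.L - 1].h[p_f];
  g.w_out.subvec(0, H - 1) = topf * dpred.t();
  if (p.bi) {
    mat topb = K.bwd[p.L - 1].h[p_b];
    g.w_out.subvec(H, 2 * H - 1) = topb * dpred.t();
  }

  // dh injections for the top layer come from the readout only.
  std::vector<mat> dinj_f(T), dinj_b(T);
  dinj_f[p_f] = p.w_out.subvec(0, H - 1) * dpred;
  if (p.bi) dinj_b[p_b] = p.w_out.subvec(H, 2 * H - 1) * dpred;

  for (int l = p.L - 1; l >= 0; --l) {
    const int Din = (int)p.fwd[l].W.n_cols;
    std::vector<mat> din(T);
    for (int s = 0; s < T; ++s) din[s] = mat(Din, B, arma::fill::zeros);
    back_dir(p.fwd[l], K.inputs[l], false, K.fwd[l], dinj_f, g.fwd[l], din);
    if (p.bi)
      back_dir(p.bwd[l], K.inputs[l], true, K.bwd[l], dinj_b, g.bwd[l], din);
    if (l > 0) {
      // split input gradient into dh for the layer below's directions
      for (int s = 0; s < T; ++s) {
        if (p.bi) {
          dinj_f[s] = din[s].rows(0, H - 1);
          dinj_b[s] = din[s].rows(H, 2 * H - 1);
        } else {
          dinj_f[s] = din[s];
        }
      }
    }
  }
  return loss;
}

// [[Rcpp::export]]
arma::vec cpp_lstm_predict(List params, arma::cube X, int p_f, int p_b) {
  Params p = params_from_list(params);
  return stack_forward(p, X, p_f - 1, p_b - 1, nullptr);
}

// [[Rcpp::export]]
List cpp_lstm_grad(List params, arma::cube X, arma::vec y, int p_f, int p_b) {
  Params p = params_from_list(params);
  StackCache K;
  vec pred = stack_forward(p, X, p_f - 1, p_b - 1, &K);
  Params g;
  double loss = stack_backward(p, K, pred, y, p_f - 1, p_b - 1, g);
  return List::create(_["loss"] = loss, _["grad"] = params_to_list(g));
}

struct Adam {
  std::vector<mat> mW, vW, mV, vV;
  std::vector<vec> mb, vb;
  vec mw, vw;
  double mb0 = 0, vb0 = 0;
  long t = 0;
  void init(const Params &p) {
    int n = p.L * (p.bi ? 2 : 1);
    mW.resize(n); vW.resize(n); mV.resize(n); vV.resize(n);
    mb.resize(n); vb.resize(n);
    int k = 0;
    for (int l = 0; l < p.L; ++l) {
      const LayerDir &d = p.fwd[l];
      mW[k].zeros(d.W.n_rows, d.W.n_cols); vW[k].zeros(d.W.n_rows, d.W.n_cols);
      mV[k].zeros(d.V.n_rows, d.V.n_cols); vV[k].zeros(d.V.n_rows, d.V.n_cols);
      mb[k].zeros(d.b.n_elem); vb[k].zeros(d.b.n_elem);
      ++k;
      if (p.bi) {
        const LayerDir &e = p.bwd[l];
        mW[k].zeros(e.W.n_rows, e.W.n_cols); vW[k].zeros(e.W.n_rows, e.W.n_cols);
        mV[k].zeros(e.V.n_rows, e.V.n_cols); vV[k].zeros(e.V.n_rows, e.V.n_cols);
        mb[k].zeros(e.b.n_elem); vb[k].zeros(e.b.n_elem);
        ++k;
      }
    }
    mw.zeros(p.w_out.n_elem);
    vw.zeros(p.w_out.n_elem);
  }
  template <typename T>
  void upd(T &x, const T &gx, T &m, T &v, double lr, double b1, double b2,
           double c1, double c2) {
    m = b1 * m + (1 - b1) * gx;
    v = b2 * v + (1 - b2) * (gx % gx);
    x -= lr * (m / c1) / (arma::sqrt(v / c2) + 1e-8);
  }
  void step(Params &p, const Params &g, double lr) {
    ++t;
    const double b1 = 0.9, b2 = 0.999;
    const double c1 = 1 - std::pow(b1, (double)t);
    const double c2 = 1 - std::pow(b2, (double)t);
    int k = 0;
    for (int l = 0; l < p.L; ++l) {
      upd(p.fwd[l].W, g.fwd[l].W, mW[k], vW[k], lr, b1, b2, c1, c2);
      upd(p.fwd[l].V, g.fwd[l].V, mV[k], vV[k], lr, b1, b2, c1, c2);
      upd(p.fwd[l].b, g.fwd[l].b, mb[k], vb[k], lr, b1, b2, c1, c2);
      ++k;
      if (p.bi) {
        upd(p.bwd[l].W, g.bwd[l].W, mW[k], vW[k], lr, b1, b2, c1, c2);
        upd(p.bwd[l].V, g.bwd[l].V, mV[k], vV[k], lr, b1, b2, c1, c2);
        upd(p.bwd[l].b, g.bwd[l].b, mb[k], vb[k], lr, b1, b2, c1, c2);
        ++k;
      }
    }
    upd(p.w_out, g.w_out, mw, vw, lr, b1, b2, c1, c2);
    mb0 = b1 * mb0 + (1 - b1) * g.b_out;
    vb0 = b2 * vb0 + (1 - b2) * g.b_out * g.b_out;
    p.b_out -= lr * (mb0 / c1) / (std::sqrt(vb0 / c2) + 1e-8);
  }
};

// Decoupled (AdamW-style) weight decay on the weight matrices only.
static void decay_weights(Params &p, double lr, double wd) {
  if (wd <= 0) return;
  const double f = lr * wd;
  for (int l = 0; l < p.L; ++l) {
    p.fwd[l].W -= f * p.fwd[l].W;
    p.fwd[l].V -= f * p.fwd[l].V;
    if (p.bi) {
      p.bwd[l].W -= f * p.bwd[l].W;
      p.bwd[l].V -= f * p.bwd[l].V;
    }
  }
}

// [[Rcpp::export]]
List cpp_lstm_train(List params, arma::cube X, arma::vec y, arma::cube Xv,
                    arma::vec yv, int epochs, double lr, int batch_size,
                    int p_f, int p_b, int seed, double weight_decay,
                    int patience) {
  Params p = params_from_list(params);
  const int B = (int)X.n_slices;
  const bool has_val = Xv.n_slices > 0;
  if (batch_size <= 0 || batch_size > B) batch_size = B;
  Adam opt;
  opt.init(p);
  std::mt19937 rng((unsigned)seed);
  std::vector<int> idx(B);
  for (int i = 0; i < B; ++i) idx[i] = i;
  vec epoch_loss(epochs, arma::fill::value(arma::datum::nan));
  vec val_loss(epochs, arma::fill::value(arma::datum::nan));
  Params best = p;
  double best_val = arma::datum::inf;
  int best_epoch = 0, since_best = 0, ran = 0;
  // plateau schedule: halve the learning rate after 4 stale epochs,
  // never stop before min_epochs
  const int min_epochs = std::min(8, epochs);
  const int lr_patience = 4;
  const double lr_min = 1e-3;
  double cur_lr = lr;
  for (int e = 0; e < epochs; ++e) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double tot = 0;
    int nb = 0;
    for (int start = 0; start < B; start += batch_size) {
      int end = std::min(start + batch_size, B);
      int bs = end - start;
      cube Xb(X.n_rows, X.n_cols, bs);
      vec yb(bs);
      for (int i = 0; i < bs; ++i) {
        Xb.slice(i) = X.slice(idx[start + i]);
        yb(i) = y(idx[start + i]);
      }
      StackCache K;
      vec pred = stack_forward(p, Xb, p_f - 1, p_b - 1, &K);
      Params g;
      tot += stack_backward(p, K, pred, yb, p_f - 1, p_b - 1, g);
      ++nb;
      opt.step(p, g, cur_lr);
      decay_weights(p, cur_lr, weight_decay);
    }
    epoch_loss(e) = tot / std::max(nb, 1);
    ran = e + 1;
    if (has_val) {
      vec pv = stack_forward(p, Xv, p_f - 1, p_b - 1, nullptr);
      vec rv = pv - yv;
      val_loss(e) = arma::dot(rv, rv) / rv.n_elem;
      if (val_loss(e) < best_val - 1e-9) {
        best_val = val_loss(e);
        best = p;
        best_epoch = e + 1;
        since_best = 0;
      } else {
        ++since_best;
        if (since_best % lr_patience == 0 && cur_lr > lr_min) {
          cur_lr = std::max(lr_min, cur_lr * 0.5);
        }
        if (since_best >= patience && patience > 0 && e + 1 >= min_epochs) {
          break;
        }
      }
    } else {
      best = p;
      best_epoch = e + 1;
    }
  }
  return List::create(_["params"] = params_to_list(best),
                      _["loss"] = epoch_loss.head(ran),
                      _["val_loss"] = val_loss.head(ran),
                      _["best_epoch"] = best_epoch);
}
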