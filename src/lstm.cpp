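#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

// Compact multi-head LSTM classifier: two LSTM layers, one tanh dense layer,
// K softmax heads on the final timestep's hidden state. Trained with BPTT,
// Adam, global-norm gradient clipping, masked categorical cross-entropy
// (target 0 = sample excluded from that head's loss), early stopping on
// validation support-weighted F1. All randomness comes from std::mt19937
// seeded explicitly, so runs are reproducible across sessions.
//
// Performance notes: the input projection X_t * Wx of every timestep is one
// large GEMM over the stacked (B*T) x F batch; per-timestep work is limited
// to the recurrent h * Wh product and elementwise gate math, with all caches
// preallocated per batch.

using arma::mat;
using arma::cube;
using arma::uword;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct Net {
  std::vector<mat> p;           // parameter tensors, fixed order
  int F, H1, H2, D;
  std::vector<int> heads;

  static const int L1WX = 0, L1WH = 1, L1B = 2, L2WX = 3, L2WH = 4, L2B = 5,
                   DW = 6, DB = 7, HEAD0 = 8;

  void init(int F_, int H1_, int H2_, int D_, std::vector<int> heads_,
            unsigned seed) {
    F = F_; H1 = H1_; H2 = H2_; D = D_; heads = heads_;
    std::mt19937 gen(seed);
    auto glorot = [&](int r, int c) {
      double lim = std::sqrt(6.0 / (r + c));
      std::uniform_real_distribution<double> u(-lim, lim);
      mat m(r, c);
      for (uword j = 0; j < m.n_cols; ++j)
        for (uword i = 0; i < m.n_rows; ++i) m(i, j) = u(gen);
      return m;
    };
    p.clear();
    p.push_back(glorot(F, 4 * H1));
    p.push_back(glorot(H1, 4 * H1));
    mat b1(1, 4 * H1, arma::fill::zeros);
    b1.cols(H1, 2 * H1 - 1).fill(1.0);     // forget-gate bias 1
    p.push_back(b1);
    p.push_back(glorot(H1, 4 * H2));
    p.push_back(glorot(H2, 4 * H2));
    mat b2(1, 4 * H2, arma::fill::zeros);
    b2.cols(H2, 2 * H2 - 1).fill(1.0);
    p.push_back(b2);
    p.push_back(glorot(H2, D));
    p.push_back(mat(1, D, arma::fill::zeros));
    for (int k : heads) {
      p.push_back(glorot(D, k));
      p.push_back(mat(1, k, arma::fill::zeros));
    }
  }

  void from_list(const Rcpp::List& w) {
    p.clear();
    for (int i = 0; i < w.size(); ++i)
      p.push_back(Rcpp::as<mat>(w[i]));
    F = p[L1WX].n_rows; H1 = p[L1WH].n_rows; H2 = p[L2WH].n_rows;
    D = p[DW].n_cols;
    heads.clear();
    for (size_t i = HEAD0; i < p.size(); i += 2)
      heads.push_back(p[i].n_cols);
  }

  Rcpp::List to_list() const {
    Rcpp::List out(p.size());
    Rcpp::CharacterVector nm(p.size());
    const char* base[] = {"l1_Wx", "l1_Wh", "l1_b", "l2_Wx", "l2_Wh", "l2_b",
                          "dense_W", "dense_b"};
    for (size_t i = 0; i < p.size(); ++i) {
      out[i] = Rcpp::wrap(p[i]);
      if (i < 8) nm[i] = base[i];
      else nm[i] = std::string((((i - 8) % 2 == 0) ? "head" : "head_b")) +
                   std::to_string((i - 8) / 2 + 1);
    }
    out.attr("names") = nm;
    return out;
  }
};

// Per-layer forward cache over one batch: gate activations and states as
// B x H x T cubes (slice t = timestep t).
struct LayerCache {
  cube I, Fg, G, O, C, TC, Hs;
  void alloc(uword B, uword H, uword T) {
    I.set_size(B, H, T); Fg.set_size(B, H, T); G.set_size(B, H, T);
    O.set_size(B, H, T); C.set_size(B, H, T); TC.set_size(B, H, T);
    Hs.set_size(B, H, T);
  }
};

// Forward one LSTM layer. Xcat is the stacked input (rows t*B..t*B+B-1 =
// timestep t), (B*T) x Fin. Fills the cache and returns h_T.
static mat lstm_forward_layer(const mat& Xcat, uword B, uword T,
                              const mat& Wx, const mat& Wh, const mat& b,
                              LayerCache& cc) {
  const uword H = Wh.n_rows;
  cc.alloc(B, H, T);
  mat Acat = Xcat * Wx;                       // one large GEMM
  Acat.each_row() += b.row(0);
  mat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat A = Acat.rows(t * B, t * B + B - 1) + h * Wh;
    cc.I.slice(t) = sigmoid(A.cols(0, H - 1));
    cc.Fg.slice(t) = sigmoid(A.cols(H, 2 * H - 1));
    cc.G.slice(t) = arma::tanh(A.cols(2 * H, 3 * H - 1));
    cc.O.slice(t) = sigmoid(A.cols(3 * H, 4 * H - 1));
    c = cc.Fg.slice(t) % c + cc.I.slice(t) % cc.G.slice(t);
    cc.C.slice(t) = c;
    cc.TC.slice(t) = arma::tanh(c);
    h = cc.O.slice(t) % cc.TC.slice(t);
    cc.Hs.slice(t) = h;
  }
  return h;
}

// BPTT through one layer. dh_ext: external gradient per timestep stacked as
// (B*T) x H (may have zero rows when only dh_last applies). Returns the
// stacked input gradient when want_dx.
static mat lstm_backward_layer(const mat& Xcat, uword B, uword T,
                               const LayerCache& cc, const mat& Wx,
                               const mat& Wh, const mat* dh_ext_cat,
                               const mat* dh_last, bool want_dx,
                               mat& dWx, mat& dWh, mat& db) {
  const uword H = Wh.n_rows;
  mat dAcat(B * T, 4 * H);
  mat dh(B, H, arma::fill::zeros), dc(B, H, arma::fill::zeros);
  if (dh_last) dh += *dh_last;
  for (uword t = T; t-- > 0;) {
    mat dht = dh;
    if (dh_ext_cat) dht += dh_ext_cat->rows(t * B, t * B + B - 1);
    const mat& tc = cc.TC.slice(t);
    mat dO = dht % tc;
    dc += dht % cc.O.slice(t) % (1.0 - tc % tc);
    mat dI = dc % cc.G.slice(t);
    mat dG = dc % cc.I.slice(t);
    mat dF(B, H, arma::fill::zeros);
    if (t > 0) dF = dc % cc.C.slice(t - 1);
    dc = dc % cc.Fg.slice(t);
    mat dA(B, 4 * H);
    dA.cols(0, H - 1) = dI % cc.I.slice(t) % (1.0 - cc.I.slice(t));
    dA.cols(H, 2 * H - 1) = dF % cc.Fg.slice(t) % (1.0 - cc.Fg.slice(t));
    dA.cols(2 * H, 3 * H - 1) = dG % (1.0 - cc.G.slice(t) % cc.G.slice(t));
    dA.cols(3 * H, 4 * H - 1) = dO % cc.O.slice(t) % (1.0 - cc.O.slice(t));
    dAcat.rows(t * B, t * B + B - 1) = dA;
    if (t > 0) dWh += cc.Hs.slice(t - 1).t() * dA;
    dh = dA * Wh.t();
  }
  dWx += Xcat.t() * dAcat;                    // one large GEMM
  db += arma::sum(dAcat, 0);
  if (want_dx) return dAcat * Wx.t();         // one large GEMM
  return mat();
}

// Stack selected windows of the (W x F x N) cube as a (B*T) x F matrix with
// rows t*B + b = timestep t of window idx[b].
static mat gather_batch(const cube& X, const std::vector<int>& idx) {
  const uword T = X.n_rows, F = X.n_cols, B = idx.size();
  mat Xcat(B * T, F);
  for (uword b = 0; b < B; ++b) {
    const mat& sl = X.slice(idx[b]);
    for (uword t = 0; t < T; ++t) Xcat.row(t * B + b) = sl.row(t);
  }
  return Xcat;
}

static mat softmax_rows(mat z) {
  z.each_col() -= arma::max(z, 1);
  z = arma::exp(z);
  z.each_col() /= arma::sum(z, 1);
  return z;
}

// Hidden-state sequence of layer 1 stacked as (B*T) x H1 (input to layer 2).
static mat stack_states(const cube& Hs) {
  const uword B = Hs.n_rows, H = Hs.n_cols, T = Hs.n_slices;
  mat out(B * T, H);
  for (uword t = 0; t < T; ++t) out.rows(t * B, t * B + B - 1) = Hs.slice(t);
  return out;
}

// Full forward on a stacked batch; returns head probabilities.
static std::vector<mat> net_forward(const Net& net, const mat& Xcat, uword B,
                                    uword T, LayerCache& c1, LayerCache& c2,
                                    mat* dsave, mat* h2Tsave, mat* h1save) {
  lstm_forward_layer(Xcat, B, T, net.p[Net::L1WX], net.p[Net::L1WH],
                     net.p[Net::L1B], c1);
  mat H1cat = stack_states(c1.Hs);
  mat h2T = lstm_forward_layer(H1cat, B, T, net.p[Net::L2WX], net.p[Net::L2WH],
                               net.p[Net::L2B], c2);
  mat d = arma::tanh(h2T * net.p[Net::DW] +
                     arma::repmat(net.p[Net::DB], B, 1));
  if (dsave) *dsave = d;
  if (h2Tsave) *h2Tsave = h2T;
  if (h1save) *h1save = std::move(H1cat);
  std::vector<mat> probs;
  for (size_t k = 0; k < net.heads.size(); ++k)
    probs.push_back(softmax_rows(d * net.p[Net::HEAD0 + 2 * k] +
        arma::repmat(net.p[Net::HEAD0 + 2 * k + 1], B, 1)));
  return probs;
}

// Support-weighted F1 per head (masked samples ignored), averaged over heads
// that have at least one labeled sample.
static double weighted_f1(const arma::imat& Y,
                          const std::vector<arma::ivec>& pred,
                          const std::vector<int>& heads) {
  double acc = 0; int used = 0;
  for (size_t k = 0; k < heads.size(); ++k) {
    const int C = heads[k];
    arma::vec tp(C, arma::fill::zeros), fp(C, arma::fill::zeros),
        fn(C, arma::fill::zeros), sup(C, arma::fill::zeros);
    int n = 0;
    for (uword i = 0; i < Y.n_rows; ++i) {
      int y = Y(i, k);
      if (y == 0) continue;
      ++n;
      int yh = pred[k][i];
      sup[y - 1] += 1;
      if (yh == y) tp[y - 1] += 1;
      else { fp[yh - 1] += 1; fn[y - 1] += 1; }
    }
    if (n == 0) continue;
    double wf1 = 0;
    for (int c = 0; c < C; ++c) {
      double pr = (tp[c] + fp[c] > 0) ? tp[c] / (tp[c] + fp[c]) : 0;
      double re = (tp[c] + fn[c] > 0) ? tp[c] / (tp[c] + fn[c]) : 0;
      double f1 = (pr + re > 0) ? 2 * pr * re / (pr + re) : 0;
      wf1 += sup[c] / n * f1;
    }
    acc += wf1; ++used;
  }
  return used ? acc / used : 0.0;
}

// Argmax with lowest-index preference on exact ties.
static arma::ivec argmax_rows(const mat& P) {
  arma::ivec out(P.n_rows);
  for (uword i = 0; i < P.n_rows; ++i) {
    uword best = 0;
    for (uword j = 1; j < P.n_cols; ++j)
      if (P(i, j) > P(i, best)) best = j;
    out[i] = best + 1;
  }
  return out;
}

static std::vector<arma::ivec> predict_classes(const Net& net, const cube& X,
                                               int chunk = 512) {
  const int N = X.n_slices, T = X.n_rows;
  std::vector<arma::ivec> pred(net.heads.size(), arma::ivec(N));
  LayerCache c1, c2;
  for (int s = 0; s < N; s += chunk) {
    int e = std::min(N, s + chunk);
    std::vector<int> idx(e - s);
    for (int i = s; i < e; ++i) idx[i - s] = i;
    mat Xcat = gather_batch(X, idx);
    std::vector<mat> probs = net_forward(net, Xcat, e - s, T, c1, c2,
                                         nullptr, nullptr, nullptr);
    for (size_t k = 0; k < probs.size(); ++k) {
      arma::ivec am = argmax_rows(probs[k]);
      for (int i = s; i < e; ++i) pred[k][i] = am[i - s];
    }
  }
  return pred;
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_train(const arma::cube& X, const arma::imat& Y,
                          const arma::cube& Xval, const arma::imat& Yval,
                          Rcpp::IntegerVector head_sizes,
                          int units1, int units2, int dense_units,
                          double lr, int batch_size, int max_epochs,
                          int patience, double clip, int seed) {
  const int N = X.n_slices, F = X.n_cols, T = X.n_rows;
  std::vector<int> heads(head_sizes.begin(), head_sizes.end());
  const int K = heads.size();
  if ((int)Y.n_cols != K) Rcpp::stop("Y must have one column per head");
  if ((int)Y.n_rows != N) Rcpp::stop("Y rows must match window count");
  if (Xval.n_slices == 0) Rcpp::stop("validation set must be non-empty");

  Net net;
  net.init(F, units1, units2, dense_units, heads, (unsigned)seed);

  // Adam state
  std::vector<mat> m(net.p.size()), v(net.p.size());
  for (size_t i = 0; i < net.p.size(); ++i) {
    m[i].zeros(net.p[i].n_rows, net.p[i].n_cols);
    v[i].zeros(net.p[i].n_rows, net.p[i].n_cols);
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  std::mt19937 gen((unsigned)seed + 1u);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  std::vector<double> hist_loss, hist_f1;
  double best_f1 = -1;
  int best_epoch = -1, wait = 0;
  std::vector<mat> best_p = net.p;
  LayerCache c1, c2;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), gen);
    double ep_loss = 0; int nb = 0;
    for (int s = 0; s < N; s += batch_size) {
      int e = std::min(N, s + batch_size);
      std::vector<int> idx(order.begin() + s, order.begin() + e);
      const int B = idx.size();
      mat Xcat = gather_batch(X, idx);
      mat d, h2T, H1cat;
      std::vector<mat> probs = net_forward(net, Xcat, B, T, c1, c2,
                                           &d, &h2T, &H1cat);

      // masked cross-entropy and logit gradients
      double loss = 0;
      int labeled = 0;
      mat dd(B, net.D, arma::fill::zeros);
      std::vector<mat> gHead(K), gHeadB(K);
      for (int k = 0; k < K; ++k) {
        mat dL = probs[k];
        int nk = 0;
        for (int bi = 0; bi < B; ++bi) {
          int y = Y(idx[bi], k);
          if (y == 0) { dL.row(bi).zeros(); continue; }
          ++nk;
          loss += -std::log(std::max(probs[k](bi, y - 1), 1e-12));
          dL(bi, y - 1) -= 1.0;
        }
        labeled += nk;
        if (nk > 0) dL /= nk; else dL.zeros();
        gHead[k] = d.t() * dL;
        gHeadB[k] = arma::sum(dL, 0);
        dd += dL * net.p[Net::HEAD0 + 2 * k].t();
      }
      if (labeled) loss /= labeled;

      mat dz = dd % (1.0 - d % d);
      mat gDW = h2T.t() * dz;
      mat gDB = arma::sum(dz, 0);
      mat dh2T = dz * net.p[Net::DW].t();

      mat g1Wx(net.F, 4 * net.H1, arma::fill::zeros),
          g1Wh(net.H1, 4 * net.H1, arma::fill::zeros),
          g1b(1, 4 * net.H1, arma::fill::zeros),
          g2Wx(net.H1, 4 * net.H2, arma::fill::zeros),
          g2Wh(net.H2, 4 * net.H2, arma::fill::zeros),
          g2b(1, 4 * net.H2, arma::fill::zeros);
      // layer 2 gets gradient only at the final timestep
      mat dH1cat = lstm_backward_layer(H1cat, B, T, c2, net.p[Net::L2WX],
                                       net.p[Net::L2WH], nullptr, &dh2T,
                                       true, g2Wx, g2Wh, g2b);
      lstm_backward_layer(Xcat, B, T, c1, net.p[Net::L1WX], net.p[Net::L1WH],
                          &dH1cat, nullptr, false, g1Wx, g1Wh, g1b);

      std::vector<mat> grads{g1Wx, g1Wh, g1b, g2Wx, g2Wh, g2b, gDW, gDB};
      for (int k = 0; k < K; ++k) {
        grads.push_back(gHead[k]);
        grads.push_back(gHeadB[k]);
      }

      // global-norm clip
      double gn = 0;
      for (auto& g : grads) gn += arma::accu(g % g);
      gn = std::sqrt(gn);
      if (clip > 0 && gn > clip)
        for (auto& g : grads) g *= clip / gn;

      ++step;
      double corr = lr * std::sqrt(1 - std::pow(b2, step)) /
                    (1 - std::pow(b1, step));
      for (size_t i = 0; i < net.p.size(); ++i) {
        m[i] = b1 * m[i] + (1 - b1) * grads[i];
        v[i] = b2 * v[i] + (1 - b2) * (grads[i] % grads[i]);
        net.p[i] -= corr * m[i] / (arma::sqrt(v[i]) + eps);
      }
      ep_loss += loss; ++nb;
    }
    ep_loss /= std::max(nb, 1);

    std::vector<arma::ivec> vp = predict_classes(net, Xval);
    double f1 = weighted_f1(Yval, vp, heads);
    hist_loss.push_back(ep_loss);
    hist_f1.push_back(f1);
    if (f1 > best_f1 + 1e-9) {
      best_f1 = f1; best_epoch = epoch; best_p = net.p; wait = 0;
    } else if (++wait >= patience) break;
    Rcpp::checkUserInterrupt();
  }
  net.p = best_p;
  return Rcpp::List::create(
      Rcpp::Named("weights") = net.to_list(),
      Rcpp::Named("history") = Rcpp::DataFrame::create(
          Rcpp::Named("epoch") = Rcpp::seq(1, (int)hist_loss.size()),
          Rcpp::Named("train_loss") = hist_loss,
          Rcpp::Named("val_weighted_f1") = hist_f1),
      Rcpp::Named("best_epoch") = best_epoch + 1,
      Rcpp::Named("best_val_f1") = best_f1);
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_predict(const Rcpp::List& weights, const arma::cube& X) {
  Net net;
  net.from_list(weights);
  const int N = X.n_slices, T = X.n_rows;
  std::vector<mat> out;
  for (int k : net.heads) out.push_back(mat(N, k));
  const int chunk = 512;
  LayerCache c1, c2;
  for (int s = 0; s < N; s += chunk) {
    int e = std::min(N, s + chunk);
    std::vector<int> idx(e - s);
    for (int i = s; i < e; ++i) idx[i - s] = i;
    mat Xcat = gather_batch(X, idx);
    std::vector<mat> probs = net_forward(net, Xcat, e - s, T, c1, c2,
                                         nullptr, nullptr, nullptr);
    for (size_t k = 0; k < probs.size(); ++k)
      out[k].rows(s, e - 1) = probs[k];
  }
  Rcpp::List res(out.size());
  for (size_t k = 0; k < out.size(); ++k) res[k] = Rcpp::wrap(out[k]);
  return res;
}
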