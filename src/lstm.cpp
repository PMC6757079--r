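// Gated recurrent (LSTM) binary sequence classifier trained by
// backpropagation through time with Adam updates.  One forward/backward
// pass processes all trials of a (mini-)batch simultaneously: the input is
// an n x E x T cube whose slice t is the batch matrix of window vectors at
// time step t.  The final hidden state of the top layer feeds a single
// sigmoid readout; the loss is class-weighted binary cross-entropy.
//
// All randomness (weight init, batch shuffling) comes from one std::mt19937_64
// seeded from R, so identical calls are bit-reproducible.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Layer {
  mat Wx;   // E_l x 4H
  mat Wh;   // H x 4H
  rowvec b; // 4H
};

struct Net {
  std::vector<Layer> layers;
  vec w_out;    // H
  double b_out;
  int H;
};

inline mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

Net init_net(int E, int H, int n_layers, std::mt19937_64& rng) {
  Net net;
  net.H = H;
  for (int l = 0; l < n_layers; ++l) {
    int in = (l == 0) ? E : H;
    double a_x = 1.0 / std::sqrt((double)in);
    double a_h = 1.0 / std::sqrt((double)H);
    std::uniform_real_distribution<double> ux(-a_x, a_x), uh(-a_h, a_h);
    Layer ly;
    ly.Wx.set_size(in, 4 * H);
    ly.Wh.set_size(H, 4 * H);
    ly.b.zeros(4 * H);
    for (uword i = 0; i < ly.Wx.n_elem; ++i) ly.Wx(i) = ux(rng);
    for (uword i = 0; i < ly.Wh.n_elem; ++i) ly.Wh(i) = uh(rng);
    // forget-gate bias starts at 1 so memory persists early in training
    ly.b.subvec(H, 2 * H - 1).fill(1.0);
    net.layers.push_back(ly);
  }
  std::uniform_real_distribution<double> uo(-1.0 / std::sqrt((double)H),
                                            1.0 / std::sqrt((double)H));
  net.w_out.set_size(H);
  for (int i = 0; i < H; ++i) net.w_out(i) = uo(rng);
  net.b_out = 0.0;
  return net;
}

// Per-layer, per-step activations kept for BPTT.
struct Tape {
  std::vector<std::vector<mat>> i, f, g, o, c, h; // [layer][t], each n x H
};

// Forward pass over the whole sequence; returns scores, fills tape if given.
vec forward(const Net& net, const cube& X, const uvec& rows, Tape* tape) {
  int T = X.n_slices, H = net.H, L = net.layers.size();
  int n = rows.n_elem;
  std::vector<mat> h(L), c(L);
  for (int l = 0; l < L; ++l) { h[l].zeros(n, H); c[l].zeros(n, H); }
  if (tape) {
    tape->i.assign(L, {}); tape->f.assign(L, {}); tape->g.assign(L, {});
    tape->o.assign(L, {}); tape->c.assign(L, {}); tape->h.assign(L, {});
  }
  for (int t = 0; t < T; ++t) {
    mat input = X.slice(t).rows(rows);
    for (int l = 0; l < L; ++l) {
      const Layer& ly = net.layers[l];
      mat z = input * ly.Wx + h[l] * ly.Wh;
      z.each_row() += ly.b;
      mat ig = sigm(z.cols(0, H - 1));
      mat fg = sigm(z.cols(H, 2 * H - 1));
      mat gg = tanh(z.cols(2 * H, 3 * H - 1));
      mat og = sigm(z.cols(3 * H, 4 * H - 1));
      c[l] = fg % c[l] + ig % gg;
      h[l] = og % tanh(c[l]);
      if (tape) {
        tape->i[l].push_back(ig); tape->f[l].push_back(fg);
        tape->g[l].push_back(gg); tape->o[l].push_back(og);
        tape->c[l].push_back(c[l]); tape->h[l].push_back(h[l]);
      }
      input = h[l];
    }
  }
  return sigm(h[L - 1] * net.w_out + net.b_out);
}

double wbce(const vec& p, const vec& y, const vec& wgt) {
  vec pc = clamp(p, 1e-12, 1.0 - 1e-12);
  return accu(wgt % (-y % log(pc) - (1.0 - y) % log(1.0 - pc))) / accu(wgt);
}

struct Grads {
  std::vector<Layer> layers;
  vec w_out;
  double b_out;
};

Grads backward(const Net& net, const cube& X, const uvec& rows,
               const vec& y, const vec& wgt, const Tape& tape,
               const vec& p) {
  int T = X.n_slices, H = net.H, L = net.layers.size();
  int n = rows.n_elem;
  Grads gr;
  gr.layers.resize(L);
  for (int l = 0; l < L; ++l) {
    gr.layers[l].Wx.zeros(size(net.layers[l].Wx));
    gr.layers[l].Wh.zeros(size(net.layers[l].Wh));
    gr.layers[l].b.zeros(4 * H);
  }
  // d loss / d score-logit for the sigmoid + weighted BCE readout
  vec dlogit = wgt % (p - y) / accu(wgt);
  gr.w_out = tape.h[L - 1][T - 1].t() * dlogit;
  gr.b_out = accu(dlogit);
  // dh[l], dc[l]: gradients flowing into h_t, c_t of each layer
  std::vector<mat> dh(L), dc(L);
  for (int l = 0; l < L; ++l) { dh[l].zeros(n, H); dc[l].zeros(n, H); }
  dh[L - 1] = dlogit * net.w_out.t();
  // dX accumulated per time step from layer 1 down (into lower layer's dh)
  std::vector<mat> dz(L);
  for (int t = T - 1; t >= 0; --t) {
    for (int l = L - 1; l >= 0; --l) {
      const Layer& ly = net.layers[l];
      const mat& ig = tape.i[l][t]; const mat& fg = tape.f[l][t];
      const mat& gg = tape.g[l][t]; const mat& og = tape.o[l][t];
      const mat& ct = tape.c[l][t];
      mat tanh_c = tanh(ct);
      mat dct = dc[l] + dh[l] % og % (1.0 - square(tanh_c));
      mat c_prev = (t == 0) ? mat(n, H, fill::zeros) : tape.c[l][t - 1];
      mat di = dct % gg % ig % (1.0 - ig);
      mat df = dct % c_prev % fg % (1.0 - fg);
      mat dg = dct % ig % (1.0 - square(gg));
      mat do_ = dh[l] % tanh_c % og % (1.0 - og);
      mat dzl(n, 4 * H);
      dzl.cols(0, H - 1) = di;
      dzl.cols(H, 2 * H - 1) = df;
      dzl.cols(2 * H, 3 * H - 1) = dg;
      dzl.cols(3 * H, 4 * H - 1) = do_;
      mat input = (l == 0) ? mat(X.slice(t).rows(rows)) : tape.h[l - 1][t];
      mat h_prev = (t == 0) ? mat(n, H, fill::zeros) : tape.h[l][t - 1];
      gr.layers[l].Wx += input.t() * dzl;
      gr.layers[l].Wh += h_prev.t() * dzl;
      gr.layers[l].b += sum(dzl, 0);
      // propagate to previous time step of this layer
      dh[l] = dzl * ly.Wh.t();
      dc[l] = dct % fg;
      // propagate to the layer below (its h at this same t)
      if (l > 0) dh[l - 1] += dzl * ly.Wx.t();
    }
  }
  return gr;
}

// flatten-order iteration over all trainable parameters
template <typename F>
void for_params(Net& net, Grads& gr, F fun) {
  for (size_t l = 0; l < net.layers.size(); ++l) {
    fun(net.layers[l].Wx, gr.layers[l].Wx);
    fun(net.layers[l].Wh, gr.layers[l].Wh);
  }
}

} // namespace

// [[Rcpp::export]]
Rcpp::List lstm_fit_cpp(const arma::cube& X, const arma::vec& y,
                        const arma::vec& wgt,
                        const arma::cube& Xval, const arma::vec& yval,
                        const arma::vec& wval,
                        int hidden, int n_layers, double lr, int max_epochs,
                        int batch_size, int patience, double seed) {
  int n = X.n_rows, E = X.n_cols;
  std::mt19937_64 rng((uint64_t)seed);
  Net net = init_net(E, hidden, n_layers, rng);

  // Adam state, one pair of moment buffers per parameter block
  std::vector<mat> mWx(n_layers), vWx(n_layers), mWh(n_layers), vWh(n_layers);
  std::vector<rowvec> mb(n_layers), vb(n_layers);
  for (int l = 0; l < n_layers; ++l) {
    mWx[l].zeros(size(net.layers[l].Wx)); vWx[l].zeros(size(net.layers[l].Wx));
    mWh[l].zeros(size(net.layers[l].Wh)); vWh[l].zeros(size(net.layers[l].Wh));
    mb[l].zeros(4 * hidden); vb[l].zeros(4 * hidden);
  }
  vec mw(hidden, fill::zeros), vw(hidden, fill::zeros);
  double mbo = 0, vbo = 0;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  bool has_val = Xval.n_rows > 0;
  double best_monitor = datum::inf;
  int bad_epochs = 0, epochs_run = 0;
  Net best = net;
  std::vector<double> loss_hist, val_hist;

  std::vector<uword> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  int bs = (batch_size <= 0 || batch_size > n) ? n : batch_size;

  uvec all_rows = regspace<uvec>(0, n - 1);
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    if (bs < n) std::shuffle(order.begin(), order.end(), rng);
    for (int start = 0; start < n; start += bs) {
      int stop = std::min(start + bs, n) - 1;
      uvec rows(stop - start + 1);
      for (int i = start; i <= stop; ++i) rows(i - start) = order[i];
      Tape tape;
      vec p = forward(net, X, rows, &tape);
      Grads gr = backward(net, X, rows, y.elem(rows), wgt.elem(rows), tape, p);
      // global-norm gradient clipping at 5
      double gnorm2 = dot(gr.w_out, gr.w_out) + gr.b_out * gr.b_out;
      for (int l = 0; l < n_layers; ++l)
        gnorm2 += accu(square(gr.layers[l].Wx)) +
                  accu(square(gr.layers[l].Wh)) +
                  accu(square(gr.layers[l].b));
      double clip = std::sqrt(gnorm2) > 5.0 ? 5.0 / std::sqrt(gnorm2) : 1.0;
      ++step;
      double c1 = 1.0 - std::pow(b1, (double)step);
      double c2 = 1.0 - std::pow(b2, (double)step);
      auto adam = [&](auto& par, auto& g, auto& m, auto& v) {
        g *= clip;
        m = b1 * m + (1 - b1) * g;
        v = b2 * v + (1 - b2) * (g % g);
        par -= lr * (m / c1) / (sqrt(v / c2) + eps);
      };
      for (int l = 0; l < n_layers; ++l) {
        adam(net.layers[l].Wx, gr.layers[l].Wx, mWx[l], vWx[l]);
        adam(net.layers[l].Wh, gr.layers[l].Wh, mWh[l], vWh[l]);
        adam(net.layers[l].b, gr.layers[l].b, mb[l], vb[l]);
      }
      adam(net.w_out, gr.w_out, mw, vw);
      gr.b_out *= clip;
      mbo = b1 * mbo + (1 - b1) * gr.b_out;
      vbo = b2 * vbo + (1 - b2) * gr.b_out * gr.b_out;
      net.b_out -= lr * (mbo / c1) / (std::sqrt(vbo / c2) + eps);
    }
    epochs_run = epoch + 1;
    vec p_all = forward(net, X, all_rows, nullptr);
    double train_loss = wbce(p_all, y, wgt);
    loss_hist.push_back(train_loss);
    double monitor = train_loss;
    if (has_val) {
      uvec vrows = regspace<uvec>(0, Xval.n_rows - 1);
      vec pv = forward(net, Xval, vrows, nullptr);
      monitor = wbce(pv, yval, wval);
      val_hist.push_back(monitor);
    }
    if (monitor < best_monitor - 1e-6) {
      best_monitor = monitor;
      best = net;
      bad_epochs = 0;
    } else if (++bad_epochs >= patience) {
      break;
    }
  }

  Rcpp::List layers(n_layers);
  for (int l = 0; l < n_layers; ++l)
    layers[l] = Rcpp::List::create(
      Rcpp::Named("Wx") = best.layers[l].Wx,
      Rcpp::Named("Wh") = best.layers[l].Wh,
      Rcpp::Named("b") = best.layers[l].b);
  return Rcpp::List::create(
    Rcpp::Named("layers") = layers,
    Rcpp::Named("w_out") = best.w_out,
    Rcpp::Named("b_out") = best.b_out,
    Rcpp::Named("hidden") = hidden,
    Rcpp::Named("epochs_run") = epochs_run,
    Rcpp::Named("final_loss") = loss_hist.empty() ? NA_REAL : loss_hist.back(),
    Rcpp::Named("loss_history") = loss_hist,
    Rcpp::Named("val_history") = val_hist,
    Rcpp::Named("best_monitor") = best_monitor);
}

// [[Rcpp::export]]
arma::vec lstm_predict_cpp(const Rcpp::List& params, const arma::cube& X) {
  Rcpp::List layers = params["layers"];
  Net net;
  net.H = Rcpp::as<int>(params["hidden"]);
  for (int l = 0; l < layers.size(); ++l) {
    Rcpp::List ly = layers[l];
    Layer out;
    out.Wx = Rcpp::as<mat>(ly["Wx"]);
    out.Wh = Rcpp::as<mat>(ly["Wh"]);
    out.b = Rcpp::as<rowvec>(ly["b"]);
    net.layers.push_back(out);
  }
  net.w_out = Rcpp::as<vec>(params["w_out"]);
  net.b_out = Rcpp::as<double>(params["b_out"]);
  uvec rows = regspace<uvec>(0, X.n_rows - 1);
  return forward(net, X, rows, nullptr);
}
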