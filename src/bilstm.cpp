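// Stacked bidirectional LSTM sequence-to-sequence model.
//
// Layout: layer 1 = bidirectional LSTM (H units per direction, sum-merged),
// optional inverted dropout, layer 2 = bidirectional LSTM (C_out units per
// direction, sum-merged) emitting the full output sequence. Forward pass,
// backpropagation through time and the Adam optimizer are implemented here.
//
// The code is templated on the element type: training runs in single
// precision (the standard for this model class; twice the BLAS throughput
// and half the memory traffic), while the exported forward/gradient entry
// points run in double precision so gradients can be verified against
// finite differences to ~1e-10.
//
// Cubes are laid out (channels, batch, time): slice t is a channels x batch
// matrix, so each timestep update is a GEMM over the whole mini-batch, and
// the input projection / input-side gradients collapse into single GEMMs
// over the flattened (channels, batch*time) view.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

template <typename T> struct CellT {
  Mat<T> W;  // 4H x D input weights (gate order i, f, o, g)
  Mat<T> U;  // 4H x H recurrent weights
  Col<T> b;  // 4H
};

template <typename T> struct CacheT {
  // per-gate activation caches, kept as separate contiguous cubes so the
  // elementwise backward arithmetic runs on contiguous memory
  Cube<T> Gi, Gf, Go, Gg;  // H x B x T activated gates
  Cube<T> C;               // H x B x T cell states
  Cube<T> WX;              // 4H x B x T input projection (forward scratch)
  Cube<T> DZ;              // 4H x B x T pre-activation grads (backward)
};

template <typename T> struct NetT {
  CellT<T> l1f, l1b, l2f, l2b;
};

template <typename T>
static CellT<T> cell_from_list(const Rcpp::List& l) {
  CellT<T> c;
  c.W = conv_to<Mat<T>>::from(Rcpp::as<mat>(l["W"]));
  c.U = conv_to<Mat<T>>::from(Rcpp::as<mat>(l["U"]));
  c.b = conv_to<Col<T>>::from(Rcpp::as<vec>(l["b"]));
  return c;
}

template <typename T>
static Rcpp::List cell_to_list(const CellT<T>& c) {
  return Rcpp::List::create(
      Rcpp::Named("W") = conv_to<mat>::from(c.W),
      Rcpp::Named("U") = conv_to<mat>::from(c.U),
      Rcpp::Named("b") = conv_to<vec>::from(c.b));
}

template <typename T>
static NetT<T> net_from_list(const Rcpp::List& w) {
  NetT<T> n;
  n.l1f = cell_from_list<T>(w["l1f"]);
  n.l1b = cell_from_list<T>(w["l1b"]);
  n.l2f = cell_from_list<T>(w["l2f"]);
  n.l2b = cell_from_list<T>(w["l2b"]);
  return n;
}

template <typename T>
static Rcpp::List net_to_list(const NetT<T>& n) {
  return Rcpp::List::create(Rcpp::Named("l1f") = cell_to_list(n.l1f),
                            Rcpp::Named("l1b") = cell_to_list(n.l1b),
                            Rcpp::Named("l2f") = cell_to_list(n.l2f),
                            Rcpp::Named("l2b") = cell_to_list(n.l2b));
}

// flat (rows, B*T) view over a cube's contiguous memory
template <typename T>
static Mat<T> flat_view(const Cube<T>& X) {
  return Mat<T>(const_cast<T*>(X.memptr()), X.n_rows,
                X.n_cols * X.n_slices, false, true);
}

// dir = +1 processes t = 0..T-1, dir = -1 processes t = T-1..0
template <typename T>
static void cell_forward(const CellT<T>& cl, const Cube<T>& X, int dir,
                         CacheT<T>* ca, Cube<T>& Hout, Cube<T>& WXbuf) {
  const uword Tn = X.n_slices, B = X.n_cols, H = cl.U.n_cols;
  if (ca) {
    ca->Gi.set_size(H, B, Tn); ca->Gf.set_size(H, B, Tn);
    ca->Go.set_size(H, B, Tn); ca->Gg.set_size(H, B, Tn);
    ca->C.set_size(H, B, Tn);
  }
  Hout.set_size(H, B, Tn);
  WXbuf.set_size(4 * H, B, Tn);
  {
    Mat<T> wxf = flat_view(WXbuf);
    wxf = cl.W * flat_view(X);
  }
  Mat<T> h(H, B, fill::zeros), c(H, B, fill::zeros), a(4 * H, B);
  Mat<T> gi(H, B), gf(H, B), go(H, B), gg(H, B);
  for (uword k = 0; k < Tn; ++k) {
    uword t = dir > 0 ? k : Tn - 1 - k;
    a = WXbuf.slice(t) + cl.U * h;
    a.each_col() += cl.b;
    gi = a.rows(0, H - 1);
    gf = a.rows(H, 2 * H - 1);
    go = a.rows(2 * H, 3 * H - 1);
    gg = a.rows(3 * H, 4 * H - 1);
    gi = T(1) / (T(1) + exp(-gi));
    gf = T(1) / (T(1) + exp(-gf));
    go = T(1) / (T(1) + exp(-go));
    gg = tanh(gg);
    c = gf % c + gi % gg;
    h = go % tanh(c);
    if (ca) {
      ca->Gi.slice(t) = gi; ca->Gf.slice(t) = gf;
      ca->Go.slice(t) = go; ca->Gg.slice(t) = gg;
      ca->C.slice(t) = c;
    }
    Hout.slice(t) = h;
  }
}

template <typename T>
static void cell_backward(const CellT<T>& cl, const Cube<T>& X, int dir,
                          CacheT<T>& ca, const Cube<T>& Hout,
                          const Cube<T>& dH, CellT<T>& g, Cube<T>& dX) {
  const uword Tn = X.n_slices, B = X.n_cols, H = cl.U.n_cols;
  g.U.zeros(cl.U.n_rows, cl.U.n_cols);
  ca.DZ.set_size(4 * H, B, Tn);
  Mat<T> dh_rec(H, B, fill::zeros), dc(H, B, fill::zeros);
  Mat<T> tc(H, B), dh(H, B);
  const Mat<T> zeroHB(H, B, fill::zeros);
  for (uword k = Tn; k-- > 0;) {
    uword t = dir > 0 ? k : Tn - 1 - k;
    const Mat<T>& gi = ca.Gi.slice(t);
    const Mat<T>& gf = ca.Gf.slice(t);
    const Mat<T>& go = ca.Go.slice(t);
    const Mat<T>& gg = ca.Gg.slice(t);
    tc = tanh(ca.C.slice(t));
    dh = dH.slice(t) + dh_rec;
    dc += dh % go % (T(1) - tc % tc);
    uword tp = dir > 0 ? t - 1 : t + 1;
    const Mat<T>& cprev = (k > 0) ? ca.C.slice(tp) : zeroHB;
    const Mat<T>& hprev = (k > 0) ? Hout.slice(tp) : zeroHB;
    Mat<T>& dz = ca.DZ.slice(t);
    dz.rows(0, H - 1) = (dc % gg) % gi % (T(1) - gi);
    dz.rows(H, 2 * H - 1) = (dc % cprev) % gf % (T(1) - gf);
    dz.rows(2 * H, 3 * H - 1) = (dh % tc) % go % (T(1) - go);
    dz.rows(3 * H, 4 * H - 1) = (dc % gi) % (T(1) - gg % gg);
    g.U += dz * hprev.t();
    dh_rec = cl.U.t() * dz;
    dc = dc % gf;
  }
  Mat<T> dzf = flat_view(ca.DZ);
  g.W = dzf * flat_view(X).t();
  g.b = sum(dzf, 1);
  Mat<T> dxf = flat_view(dX);
  dxf += cl.W.t() * dzf;
}

// workspace reused across batches to avoid reallocating ~100 MB per step
template <typename T> struct WorkT {
  CacheT<T> c1f, c1b, c2f, c2b;
  // separate input-projection buffers per layer so sizes stay stable
  Cube<T> h1f, h1b, O1, mask, h2f, h2b, Yhat, dY, dO1, dX, wx1, wx2;
};

template <typename T>
static void net_forward(const NetT<T>& net, const Cube<T>& X, double dropout,
                        bool training, std::mt19937_64* rng, bool keep,
                        WorkT<T>& w) {
  cell_forward(net.l1f, X, +1, keep ? &w.c1f : nullptr, w.h1f, w.wx1);
  cell_forward(net.l1b, X, -1, keep ? &w.c1b : nullptr, w.h1b, w.wx1);
  w.O1 = w.h1f + w.h1b;
  if (training && dropout > 0.0) {
    w.mask.set_size(w.O1.n_rows, w.O1.n_cols, w.O1.n_slices);
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    T scale = T(1.0 / (1.0 - dropout));
    for (uword i = 0; i < w.mask.n_elem; ++i)
      w.mask(i) = unif(*rng) < dropout ? T(0) : scale;
    w.O1 %= w.mask;
  } else {
    w.mask.set_size(0, 0, 0);
  }
  cell_forward(net.l2f, w.O1, +1, keep ? &w.c2f : nullptr, w.h2f, w.wx2);
  cell_forward(net.l2b, w.O1, -1, keep ? &w.c2b : nullptr, w.h2b, w.wx2);
  w.Yhat = w.h2f + w.h2b;
}

// mean squared error over all elements; equals the batch mean of the
// per-sequence flattened MSEs since all sequences share one shape
template <typename T>
static double net_loss_grad(const NetT<T>& net, const Cube<T>& X,
                            const Cube<T>& Y, double dropout,
                            std::mt19937_64* rng, NetT<T>& grad,
                            WorkT<T>& w) {
  net_forward(net, X, dropout, true, rng, true, w);
  double loss = double(accu(square(w.Yhat - Y))) / double(Y.n_elem);
  w.dY = (w.Yhat - Y) * T(2.0 / double(Y.n_elem));
  w.dO1.set_size(w.O1.n_rows, w.O1.n_cols, w.O1.n_slices);
  w.dO1.zeros();
  cell_backward(net.l2f, w.O1, +1, w.c2f, w.h2f, w.dY, grad.l2f, w.dO1);
  cell_backward(net.l2b, w.O1, -1, w.c2b, w.h2b, w.dY, grad.l2b, w.dO1);
  if (w.mask.n_elem > 0) w.dO1 %= w.mask;
  w.dX.set_size(X.n_rows, X.n_cols, X.n_slices);
  w.dX.zeros();
  cell_backward(net.l1f, X, +1, w.c1f, w.h1f, w.dO1, grad.l1f, w.dX);
  cell_backward(net.l1b, X, -1, w.c1b, w.h1b, w.dO1, grad.l1b, w.dX);
  return loss;
}

// [[Rcpp::export]]
arma::cube cpp_bilstm_forward(Rcpp::List weights, arma::cube X,
                              double dropout = 0.0, bool training = false,
                              int seed = 1) {
  NetT<double> net = net_from_list<double>(weights);
  std::mt19937_64 rng(seed);
  WorkT<double> w;
  Cube<double> Xc(X);
  net_forward(net, Xc, dropout, training, &rng, false, w);
  return w.Yhat;
}

// [[Rcpp::export]]
Rcpp::List cpp_bilstm_loss_grad(Rcpp::List weights, arma::cube X,
                                arma::cube Y, double dropout = 0.0,
                                int seed = 1) {
  NetT<double> net = net_from_list<double>(weights);
  NetT<double> grad;
  std::mt19937_64 rng(seed);
  WorkT<double> w;
  double loss = net_loss_grad<double>(net, X, Y, dropout, &rng, grad, w);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = net_to_list(grad));
}

template <typename T> struct AdamT {
  NetT<T> m, v;
  long t = 0;
  void init(const NetT<T>& n) {
    auto z = [](CellT<T>& c, const CellT<T>& ref) {
      c.W.zeros(ref.W.n_rows, ref.W.n_cols);
      c.U.zeros(ref.U.n_rows, ref.U.n_cols);
      c.b.zeros(ref.b.n_elem);
    };
    z(m.l1f, n.l1f); z(m.l1b, n.l1b); z(m.l2f, n.l2f); z(m.l2b, n.l2b);
    z(v.l1f, n.l1f); z(v.l1b, n.l1b); z(v.l2f, n.l2f); z(v.l2b, n.l2b);
  }
};

template <typename T, typename M>
static void adam_update(M& w, const M& g, M& m, M& v, T lr, T b1, T b2,
                        T eps, T bc1, T bc2) {
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * square(g);
  w -= lr * (m / bc1) / (sqrt(v / bc2) + eps);
}

template <typename T>
static void adam_step(NetT<T>& net, const NetT<T>& grad, AdamT<T>& st,
                      double lr0) {
  const T b1 = T(0.9), b2 = T(0.999), eps = T(1e-7), lr = T(lr0);
  st.t += 1;
  T bc1 = 1 - std::pow(b1, T(st.t));
  T bc2 = 1 - std::pow(b2, T(st.t));
  CellT<T>* ws[4] = { &net.l1f, &net.l1b, &net.l2f, &net.l2b };
  const CellT<T>* gs[4] = { &grad.l1f, &grad.l1b, &grad.l2f, &grad.l2b };
  CellT<T>* ms[4] = { &st.m.l1f, &st.m.l1b, &st.m.l2f, &st.m.l2b };
  CellT<T>* vs[4] = { &st.v.l1f, &st.v.l1b, &st.v.l2f, &st.v.l2b };
  for (int i = 0; i < 4; ++i) {
    adam_update(ws[i]->W, gs[i]->W, ms[i]->W, vs[i]->W, lr, b1, b2, eps, bc1, bc2);
    adam_update(ws[i]->U, gs[i]->U, ms[i]->U, vs[i]->U, lr, b1, b2, eps, bc1, bc2);
    adam_update(ws[i]->b, gs[i]->b, ms[i]->b, vs[i]->b, lr, b1, b2, eps, bc1, bc2);
  }
}

template <typename T>
static void gather_cols(const Cube<T>& X, const std::vector<uword>& idx,
                        Cube<T>& out) {
  out.set_size(X.n_rows, idx.size(), X.n_slices);
  for (uword t = 0; t < X.n_slices; ++t) {
    const Mat<T>& s = X.slice(t);
    Mat<T>& o = out.slice(t);
    for (uword j = 0; j < idx.size(); ++j) o.col(j) = s.col(idx[j]);
  }
}

template <typename T>
static double eval_loss(const NetT<T>& net, const Cube<T>& X,
                        const Cube<T>& Y, WorkT<T>& w, Cube<T>& xb,
                        Cube<T>& yb, uword chunk = 256) {
  double se = 0.0;
  const uword N = X.n_cols;
  for (uword lo = 0; lo < N; lo += chunk) {
    uword hi = std::min(N, lo + chunk);
    std::vector<uword> idx;
    for (uword j = lo; j < hi; ++j) idx.push_back(j);
    gather_cols(X, idx, xb);
    gather_cols(Y, idx, yb);
    net_forward(net, xb, 0.0, false, nullptr, false, w);
    se += double(accu(square(w.Yhat - yb)));
  }
  return se / double(Y.n_elem);
}

// [[Rcpp::export]]
Rcpp::List cpp_bilstm_train(Rcpp::List weights, arma::cube X, arma::cube Y,
                            arma::cube Xval, arma::cube Yval,
                            double lr, int batch_size, int max_epochs,
                            int patience, double dropout, int seed,
                            bool verbose = false, double lr_decay = 1.0) {
  typedef float real;
  NetT<real> net = net_from_list<real>(weights);
  Cube<real> Xf = conv_to<Cube<real>>::from(X);
  Cube<real> Yf = conv_to<Cube<real>>::from(Y);
  Cube<real> Xv = conv_to<Cube<real>>::from(Xval);
  Cube<real> Yv = conv_to<Cube<real>>::from(Yval);
  AdamT<real> st;
  st.init(net);
  std::mt19937_64 rng(seed);
  const uword N = Xf.n_cols;
  std::vector<uword> perm(N);
  for (uword i = 0; i < N; ++i) perm[i] = i;

  std::vector<double> hist_train, hist_val;
  NetT<real> best = net, grad;
  WorkT<real> w;
  Cube<real> xb, yb;
  double best_val = datum::inf;
  int best_epoch = -1, since_best = 0;

  double lr_now = lr;
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    if (epoch > 0) lr_now *= lr_decay;
    std::shuffle(perm.begin(), perm.end(), rng);
    double tr_loss = 0.0;
    int n_batches = 0;
    for (uword lo = 0; lo < N; lo += batch_size) {
      uword hi = std::min(N, lo + uword(batch_size));
      std::vector<uword> idx(perm.begin() + lo, perm.begin() + hi);
      gather_cols(Xf, idx, xb);
      gather_cols(Yf, idx, yb);
      double loss = net_loss_grad<real>(net, xb, yb, dropout, &rng, grad, w);
      if (!std::isfinite(loss))
        Rcpp::stop("training diverged: non-finite loss at epoch %d",
                   epoch + 1);
      adam_step(net, grad, st, lr_now);
      tr_loss += loss;
      n_batches += 1;
    }
    tr_loss /= std::max(1, n_batches);
    double val_loss = Xv.n_cols > 0 ?
        eval_loss(net, Xv, Yv, w, xb, yb) : tr_loss;
    hist_train.push_back(tr_loss);
    hist_val.push_back(val_loss);
    if (val_loss < best_val) {
      best_val = val_loss;
      best = net;
      best_epoch = epoch;
      since_best = 0;
    } else {
      since_best += 1;
      if (since_best >= patience) break;
    }
    if (verbose)
      Rcpp::Rcout << "epoch " << epoch + 1 << " train " << tr_loss
                  << " val " << val_loss << std::endl;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = net_to_list(best),
      Rcpp::Named("final_weights") = net_to_list(net),
      Rcpp::Named("train_loss") = hist_train,
      Rcpp::Named("val_loss") = hist_val,
      Rcpp::Named("best_epoch") = best_epoch + 1,
      Rcpp::Named("best_val_loss") = best_val);
}
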