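// Compact CNN for 128x128x3 insect crops: four same-padded conv+ReLU+maxpool
// blocks, one hidden dense layer with dropout, softmax output. Feature maps
// are stored as (S*S) x C single-precision matrices (row r = y*S + x), so a
// convolution is one im2col followed by a BLAS sgemm.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::umat;

template <typename M>
static void relu_inplace(M& Z) {
  float* p = Z.memptr();
  const arma::uword n = Z.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    if (p[i] < 0.f) p[i] = 0.f;
  }
}

// im2col with 'same' zero padding; column block order (channel, dy, dx).
static void im2col(const fmat& X, int S, int k, fmat& out) {
  const int p = (k - 1) / 2;
  const int C = X.n_cols;
  out.set_size(S * S, (arma::uword)k * k * C);
  for (int c = 0; c < C; ++c) {
    const float* xc = X.colptr(c);
    for (int dy = -p; dy <= p; ++dy) {
      for (int dx = -p; dx <= p; ++dx) {
        float* oc = out.colptr((arma::uword)c * k * k + (dy + p) * k + (dx + p));
        for (int y = 0; y < S; ++y) {
          const int yy = y + dy;
          if (yy < 0 || yy >= S) {
            std::fill(oc + (size_t)y * S, oc + (size_t)(y + 1) * S, 0.f);
            continue;
          }
          for (int x = 0; x < S; ++x) {
            const int xx = x + dx;
            oc[(size_t)y * S + x] = (xx >= 0 && xx < S) ? xc[(size_t)yy * S + xx] : 0.f;
          }
        }
      }
    }
  }
}

// Adjoint of im2col: scatter-add patch-gradient columns back onto the input.
static void col2im(const fmat& dcol, int S, int k, int C, fmat& dX) {
  const int p = (k - 1) / 2;
  dX.zeros(S * S, C);
  for (int c = 0; c < C; ++c) {
    float* xc = dX.colptr(c);
    for (int dy = -p; dy <= p; ++dy) {
      for (int dx = -p; dx <= p; ++dx) {
        const float* oc = dcol.colptr((arma::uword)c * k * k + (dy + p) * k + (dx + p));
        for (int y = 0; y < S; ++y) {
          const int yy = y + dy;
          if (yy < 0 || yy >= S) continue;
          for (int x = 0; x < S; ++x) {
            const int xx = x + dx;
            if (xx >= 0 && xx < S) xc[(size_t)yy * S + xx] += oc[(size_t)y * S + x];
          }
        }
      }
    }
  }
}

static fmat maxpool(const fmat& A, int S, umat& idx) {
  const int C = A.n_cols;
  const int P = S / 2;
  fmat out(P * P, C);
  idx.set_size(P * P, C);
  for (int c = 0; c < C; ++c) {
    const float* a = A.colptr(c);
    float* o = out.colptr(c);
    arma::uword* id = idx.colptr(c);
    for (int py = 0; py < P; ++py) {
      for (int px = 0; px < P; ++px) {
        const int y = 2 * py, x = 2 * px;
        int best = y * S + x;
        float bv = a[best];
        const int cand[3] = { y * S + x + 1, (y + 1) * S + x, (y + 1) * S + x + 1 };
        for (int t = 0; t < 3; ++t) {
          if (a[cand[t]] > bv) { bv = a[cand[t]]; best = cand[t]; }
        }
        o[(size_t)py * P + px] = bv;
        id[(size_t)py * P + px] = best;
      }
    }
  }
  return out;
}

static void maxpool_backward(const fmat& dOut, const umat& idx, int S, fmat& dA) {
  const int C = dOut.n_cols;
  dA.zeros(S * S, C);
  for (int c = 0; c < C; ++c) {
    const float* d = dOut.colptr(c);
    const arma::uword* id = idx.colptr(c);
    float* a = dA.colptr(c);
    const arma::uword n = dOut.n_rows;
    for (arma::uword i = 0; i < n; ++i) a[id[i]] += d[i];
  }
}

struct Net {
  int k1, k4, d1, d4, fc, ncls;
  fmat W1, W2, W3, W4, W5, W6;
  fvec b1, b2, b3, b4, b5, b6;
};

static fmat as_fmat(SEXP s) {
  NumericMatrix m(s);
  fmat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i)
      out(i, j) = (float)m(i, j);
  return out;
}

static fvec as_fvec(SEXP s) {
  NumericVector v(s);
  fvec out(v.size());
  for (int i = 0; i < v.size(); ++i) out(i) = (float)v[i];
  return out;
}

static Net net_from_r(const List& weights, const List& spec) {
  Net net;
  net.k1 = as<int>(spec["kernel_first"]);
  net.k4 = as<int>(spec["kernel_last"]);
  net.d1 = as<int>(spec["depth_first"]);
  net.d4 = as<int>(spec["depth_last"]);
  net.fc = as<int>(spec["fc_size"]);
  net.ncls = as<int>(spec["n_classes"]);
  net.W1 = as_fmat(weights["W1"]); net.b1 = as_fvec(weights["b1"]);
  net.W2 = as_fmat(weights["W2"]); net.b2 = as_fvec(weights["b2"]);
  net.W3 = as_fmat(weights["W3"]); net.b3 = as_fvec(weights["b3"]);
  net.W4 = as_fmat(weights["W4"]); net.b4 = as_fvec(weights["b4"]);
  net.W5 = as_fmat(weights["W5"]); net.b5 = as_fvec(weights["b5"]);
  net.W6 = as_fmat(weights["W6"]); net.b6 = as_fvec(weights["b6"]);
  return net;
}

static List net_to_r(const Net& net) {
  auto mat = [](const fmat& m) {
    NumericMatrix out(m.n_rows, m.n_cols);
    for (arma::uword j = 0; j < m.n_cols; ++j)
      for (arma::uword i = 0; i < m.n_rows; ++i)
        out(i, j) = m(i, j);
    return out;
  };
  auto vec = [](const fvec& v) {
    NumericVector out(v.n_elem);
    for (arma::uword i = 0; i < v.n_elem; ++i) out[i] = v(i);
    return out;
  };
  return List::create(
    _["W1"] = mat(net.W1), _["b1"] = vec(net.b1),
    _["W2"] = mat(net.W2), _["b2"] = vec(net.b2),
    _["W3"] = mat(net.W3), _["b3"] = vec(net.b3),
    _["W4"] = mat(net.W4), _["b4"] = vec(net.b4),
    _["W5"] = mat(net.W5), _["b5"] = vec(net.b5),
    _["W6"] = mat(net.W6), _["b6"] = vec(net.b6));
}

// Load one uint8 image (S*S*3 raw bytes, x fastest then y then channel) into
// a (S*S) x 3 float matrix scaled to [0, 1].
static void load_image(const RawVector& img, int S, fmat& X0) {
  const int n = S * S;
  X0.set_size(n, 3);
  const Rbyte* p = img.begin();
  for (int c = 0; c < 3; ++c) {
    float* xc = X0.colptr(c);
    const Rbyte* src = p + (size_t)c * n;
    for (int i = 0; i < n; ++i) xc[i] = src[i] / 255.f;
  }
}

struct Cache {
  fmat X0, col1, A1, X1, col2, A2, X2, col3, A3, X3, col4, A4, X4;
  umat i1, i2, i3, i4;
  fvec f, h_relu, mask, probs;
};

static const int SZ0 = 128, SZ1 = 64, SZ2 = 32, SZ3 = 16, SZ4 = 8;

static void forward(const Net& net, Cache& cc, bool train, double dropout,
                    std::mt19937& rng) {
  im2col(cc.X0, SZ0, net.k1, cc.col1);
  cc.A1 = cc.col1 * net.W1; cc.A1.each_row() += net.b1.t(); relu_inplace(cc.A1);
  cc.X1 = maxpool(cc.A1, SZ0, cc.i1);

  im2col(cc.X1, SZ1, 3, cc.col2);
  cc.A2 = cc.col2 * net.W2; cc.A2.each_row() += net.b2.t(); relu_inplace(cc.A2);
  cc.X2 = maxpool(cc.A2, SZ1, cc.i2);

  im2col(cc.X2, SZ2, 3, cc.col3);
  cc.A3 = cc.col3 * net.W3; cc.A3.each_row() += net.b3.t(); relu_inplace(cc.A3);
  cc.X3 = maxpool(cc.A3, SZ2, cc.i3);

  im2col(cc.X3, SZ3, net.k4, cc.col4);
  cc.A4 = cc.col4 * net.W4; cc.A4.each_row() += net.b4.t(); relu_inplace(cc.A4);
  cc.X4 = maxpool(cc.A4, SZ3, cc.i4);

  cc.f = arma::vectorise(cc.X4);
  fvec h = net.W5.t() * cc.f + net.b5;
  relu_inplace(h);
  if (train && dropout > 0) {
    const float keep = 1.f - (float)dropout;
    std::bernoulli_distribution bern(keep);
    cc.mask.set_size(h.n_elem);
    for (arma::uword i = 0; i < h.n_elem; ++i)
      cc.mask(i) = bern(rng) ? 1.f / keep : 0.f;
    h %= cc.mask;
  } else {
    cc.mask.reset();
  }
  // h is the activation seen by the output layer (post-dropout in training);
  // its sign doubles as the ReLU mask wherever the dropout mask is nonzero.
  cc.h_relu = h;
  fvec o = net.W6.t() * h + net.b6;
  o -= o.max();
  fvec e = arma::exp(o);
  cc.probs = e / arma::accu(e);
}

struct Grads {
  fmat W1, W2, W3, W4, W5, W6;
  fvec b1, b2, b3, b4, b5, b6;
  void zero_like(const Net& n) {
    W1.zeros(arma::size(n.W1)); W2.zeros(arma::size(n.W2));
    W3.zeros(arma::size(n.W3)); W4.zeros(arma::size(n.W4));
    W5.zeros(arma::size(n.W5)); W6.zeros(arma::size(n.W6));
    b1.zeros(arma::size(n.b1)); b2.zeros(arma::size(n.b2));
    b3.zeros(arma::size(n.b3)); b4.zeros(arma::size(n.b4));
    b5.zeros(arma::size(n.b5)); b6.zeros(arma::size(n.b6));
  }
};

static void backward(const Net& net, Cache& cc, int label, Grads& g) {
  fvec dout = cc.probs;
  dout(label) -= 1.f;

  g.W6 += cc.h_relu * dout.t();
  g.b6 += dout;
  fvec dh = net.W6 * dout;
  if (cc.mask.n_elem) dh %= cc.mask;
  for (arma::uword i = 0; i < dh.n_elem; ++i)
    if (cc.h_relu(i) <= 0.f) dh(i) = 0.f;

  g.W5 += cc.f * dh.t();
  g.b5 += dh;
  fvec df = net.W5 * dh;
  fmat dX4(df.memptr(), SZ4 * SZ4, net.d4, false);

  fmat dA, dcol, dX;
  // layer 4
  maxpool_backward(dX4, cc.i4, SZ3, dA);
  dA.elem(arma::find(cc.A4 <= 0.f)).zeros();
  g.W4 += cc.col4.t() * dA;
  g.b4 += arma::sum(dA, 0).t();
  dcol = dA * net.W4.t();
  col2im(dcol, SZ3, net.k4, 64, dX);
  // layer 3
  maxpool_backward(dX, cc.i3, SZ2, dA);
  dA.elem(arma::find(cc.A3 <= 0.f)).zeros();
  g.W3 += cc.col3.t() * dA;
  g.b3 += arma::sum(dA, 0).t();
  dcol = dA * net.W3.t();
  col2im(dcol, SZ2, 3, 64, dX);
  // layer 2
  maxpool_backward(dX, cc.i2, SZ1, dA);
  dA.elem(arma::find(cc.A2 <= 0.f)).zeros();
  g.W2 += cc.col2.t() * dA;
  g.b2 += arma::sum(dA, 0).t();
  dcol = dA * net.W2.t();
  col2im(dcol, SZ1, 3, net.d1, dX);
  // layer 1 (no input gradient needed)
  maxpool_backward(dX, cc.i1, SZ0, dA);
  dA.elem(arma::find(cc.A1 <= 0.f)).zeros();
  g.W1 += cc.col1.t() * dA;
  g.b1 += arma::sum(dA, 0).t();
}

struct AdamState {
  fmat mW1, vW1, mW2, vW2, mW3, vW3, mW4, vW4, mW5, vW5, mW6, vW6;
  fvec mb1, vb1, mb2, vb2, mb3, vb3, mb4, vb4, mb5, vb5, mb6, vb6;
  long t = 0;
  void init(const Net& n) {
    mW1.zeros(arma::size(n.W1)); vW1.zeros(arma::size(n.W1));
    mW2.zeros(arma::size(n.W2)); vW2.zeros(arma::size(n.W2));
    mW3.zeros(arma::size(n.W3)); vW3.zeros(arma::size(n.W3));
    mW4.zeros(arma::size(n.W4)); vW4.zeros(arma::size(n.W4));
    mW5.zeros(arma::size(n.W5)); vW5.zeros(arma::size(n.W5));
    mW6.zeros(arma::size(n.W6)); vW6.zeros(arma::size(n.W6));
    mb1.zeros(arma::size(n.b1)); vb1.zeros(arma::size(n.b1));
    mb2.zeros(arma::size(n.b2)); vb2.zeros(arma::size(n.b2));
    mb3.zeros(arma::size(n.b3)); vb3.zeros(arma::size(n.b3));
    mb4.zeros(arma::size(n.b4)); vb4.zeros(arma::size(n.b4));
    mb5.zeros(arma::size(n.b5)); vb5.zeros(arma::size(n.b5));
    mb6.zeros(arma::size(n.b6)); vb6.zeros(arma::size(n.b6));
  }
};

template <typename T>
static void adam_update(T& w, const T& grad, T& m, T& v, float lr, long t) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  m = b1 * m + (1.f - b1) * grad;
  v = b2 * v + (1.f - b2) * (grad % grad);
  const float c1 = 1.f - std::pow(b1, (float)t);
  const float c2 = 1.f - std::pow(b2, (float)t);
  w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
}

template <typename T>
static void sgd_update(T& w, const T& grad, T& m, float lr) {
  m = 0.9f * m + grad;  // classical momentum
  w -= lr * m;
}

// [[Rcpp::export]]
List cnn_train_cpp(List images, IntegerVector labels, List weights, List spec,
                   int epochs, int batch_size, std::string optimizer,
                   double lr, double dropout, int seed, bool verbose) {
  const int n = images.size();
  if (n == 0) stop("no training images");
  if (labels.size() != n) stop("labels/images length mismatch");
  Net net = net_from_r(weights, spec);
  const int S = SZ0;
  {
    RawVector first(images[0]);
    if ((int)first.size() != S * S * 3)
      stop("images must be %dx%dx3 uint8 rasters", S, S);
  }
  std::mt19937 rng((unsigned)seed);
  AdamState st;
  st.init(net);
  Grads g;
  Cache cc;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  const bool adam = (optimizer == "adam");
  NumericVector ep_loss(epochs), ep_acc(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0;
    int correct = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int stop_i = std::min(start + batch_size, n);
      const int bs = stop_i - start;
      g.zero_like(net);
      for (int b = start; b < stop_i; ++b) {
        const int i = order[b];
        RawVector img(images[i]);
        load_image(img, S, cc.X0);
        forward(net, cc, true, dropout, rng);
        const int y = labels[i];
        loss_sum += -std::log(std::max(1e-12f, cc.probs(y)));
        if (cc.probs.index_max() == (arma::uword)y) ++correct;
        backward(net, cc, y, g);
      }
      const float scale = 1.f / bs;
      g.W1 *= scale; g.W2 *= scale; g.W3 *= scale; g.W4 *= scale;
      g.W5 *= scale; g.W6 *= scale;
      g.b1 *= scale; g.b2 *= scale; g.b3 *= scale; g.b4 *= scale;
      g.b5 *= scale; g.b6 *= scale;
      if (adam) {
        ++st.t;
        adam_update(net.W1, g.W1, st.mW1, st.vW1, (float)lr, st.t);
        adam_update(net.W2, g.W2, st.mW2, st.vW2, (float)lr, st.t);
        adam_update(net.W3, g.W3, st.mW3, st.vW3, (float)lr, st.t);
        adam_update(net.W4, g.W4, st.mW4, st.vW4, (float)lr, st.t);
        adam_update(net.W5, g.W5, st.mW5, st.vW5, (float)lr, st.t);
        adam_update(net.W6, g.W6, st.mW6, st.vW6, (float)lr, st.t);
        adam_update(net.b1, g.b1, st.mb1, st.vb1, (float)lr, st.t);
        adam_update(net.b2, g.b2, st.mb2, st.vb2, (float)lr, st.t);
        adam_update(net.b3, g.b3, st.mb3, st.vb3, (float)lr, st.t);
        adam_update(net.b4, g.b4, st.mb4, st.vb4, (float)lr, st.t);
        adam_update(net.b5, g.b5, st.mb5, st.vb5, (float)lr, st.t);
        adam_update(net.b6, g.b6, st.mb6, st.vb6, (float)lr, st.t);
      } else {
        sgd_update(net.W1, g.W1, st.mW1, (float)lr);
        sgd_update(net.W2, g.W2, st.mW2, (float)lr);
        sgd_update(net.W3, g.W3, st.mW3, (float)lr);
        sgd_update(net.W4, g.W4, st.mW4, (float)lr);
        sgd_update(net.W5, g.W5, st.mW5, (float)lr);
        sgd_update(net.W6, g.W6, st.mW6, (float)lr);
        sgd_update(net.b1, g.b1, st.mb1, (float)lr);
        sgd_update(net.b2, g.b2, st.mb2, (float)lr);
        sgd_update(net.b3, g.b3, st.mb3, (float)lr);
        sgd_update(net.b4, g.b4, st.mb4, (float)lr);
        sgd_update(net.b5, g.b5, st.mb5, (float)lr);
        sgd_update(net.b6, g.b6, st.mb6, (float)lr);
      }
      Rcpp::checkUserInterrupt();
    }
    ep_loss[ep] = loss_sum / n;
    ep_acc[ep] = (double)correct / n;
    if (verbose) {
      Rcout << "epoch " << (ep + 1) << "/" << epochs
            << " loss " << ep_loss[ep] << " acc " << ep_acc[ep] << "\n";
    }
  }
  return List::create(_["weights"] = net_to_r(net),
                      _["loss"] = ep_loss,
                      _["accuracy"] = ep_acc);
}

// [[Rcpp::export]]
NumericMatrix cnn_predict_cpp(List images, List weights, List spec) {
  const int n = images.size();
  Net net = net_from_r(weights, spec);
  NumericMatrix out(n, net.ncls);
  Cache cc;
  std::mt19937 rng(0);
  for (int i = 0; i < n; ++i) {
    RawVector img(images[i]);
    if ((int)img.size() != SZ0 * SZ0 * 3)
      stop("images must be %dx%dx3 uint8 rasters", SZ0, SZ0);
    load_image(img, SZ0, cc.X0);
    forward(net, cc, false, 0.0, rng);
    for (int c = 0; c < net.ncls; ++c) out(i, c) = cc.probs(c);
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
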