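// Minimal CNN engine for small patch classifiers.
//
// Sequential nets over square grayscale patches: valid (unpadded)
// convolution via im2col + sgemm, ReLU, max-pooling, dense, inverted
// dropout and a terminal 2-class softmax with cross-entropy loss, trained
// by SGD with momentum. Single precision throughout; all randomness
// (shuffling, dropout) is drawn from R's RNG so set.seed() on the R side
// fixes a run exactly.
//
// Activation layout: one column per sample, features flattened
// column-major as (h fastest, then w, then channel).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

enum LayerKind { CONV, RELU, MAXPOOL, DENSE, DROPOUT, SOFTMAX };

struct Layer {
  LayerKind kind;
  int kh = 0, kw = 0, sh = 1, sw = 1; // conv / maxpool geometry
  int filters = 0, units = 0;
  double rate = 0.0;                  // dropout
  // input/output geometry, filled by shape propagation
  int in_h = 0, in_w = 0, in_c = 0;
  int out_h = 0, out_w = 0, out_c = 0;
  bool flat_in = false;
  // parameters and SGD velocity
  fmat W, b, vW, vb;
  // caches for backward
  fmat P;       // conv: im2col matrix
  fmat A_in;    // dense: input activation
  fmat mask;    // relu / dropout mask
  umat argmax;  // maxpool: winning source index per output cell
};

static std::vector<Layer> parse_layers(const Rcpp::List& spec, int h, int w, int c) {
  std::vector<Layer> net;
  bool flat = false;
  for (int i = 0; i < spec.size(); ++i) {
    Rcpp::List ls = spec[i];
    std::string kind = Rcpp::as<std::string>(ls["kind"]);
    Layer L;
    L.in_h = h; L.in_w = w; L.in_c = c; L.flat_in = flat;
    if (kind == "conv" || kind == "maxpool") {
      if (flat) Rcpp::stop("layer %d (%s): input already flattened", i + 1, kind.c_str());
      Rcpp::IntegerVector k = ls["kernel"], s = ls["stride"];
      L.kh = k[0]; L.kw = k[1]; L.sh = s[0]; L.sw = s[1];
      L.out_h = (h - L.kh) / L.sh + 1;
      L.out_w = (w - L.kw) / L.sw + 1;
      if (L.out_h < 1 || L.out_w < 1)
        Rcpp::stop("layer %d (%s): spatial dimension collapses", i + 1, kind.c_str());
      if (kind == "conv") {
        L.kind = CONV;
        L.filters = Rcpp::as<int>(ls["filters"]);
        L.out_c = L.filters;
      } else {
        L.kind = MAXPOOL;
        L.out_c = c;
      }
      h = L.out_h; w = L.out_w; c = L.out_c;
    } else if (kind == "dense") {
      L.kind = DENSE;
      L.units = Rcpp::as<int>(ls["units"]);
      L.out_h = 1; L.out_w = 1; L.out_c = L.units;
      h = 1; w = 1; c = L.units; flat = true;
    } else if (kind == "relu") {
      L.kind = RELU; L.out_h = h; L.out_w = w; L.out_c = c;
    } else if (kind == "dropout") {
      L.kind = DROPOUT; L.rate = Rcpp::as<double>(ls["rate"]);
      L.out_h = h; L.out_w = w; L.out_c = c;
    } else if (kind == "softmax") {
      L.kind = SOFTMAX; L.out_h = h; L.out_w = w; L.out_c = c;
    } else {
      Rcpp::stop("unknown layer kind: %s", kind.c_str());
    }
    net.push_back(L);
  }
  return net;
}

static void load_weights(std::vector<Layer>& net, const Rcpp::List& weights) {
  if ((int)weights.size() != (int)net.size())
    Rcpp::stop("weights list length does not match layer count");
  for (size_t i = 0; i < net.size(); ++i) {
    Layer& L = net[i];
    if (L.kind != CONV && L.kind != DENSE) continue;
    Rcpp::List wl = weights[i];
    L.W = conv_to<fmat>::from(Rcpp::as<mat>(wl["W"]));
    L.b = conv_to<fmat>::from(Rcpp::as<mat>(wl["b"]));
    int rows_exp = (L.kind == CONV) ? L.kh * L.kw * L.in_c : L.in_h * L.in_w * L.in_c;
    int cols_exp = (L.kind == CONV) ? L.filters : L.units;
    if ((int)L.W.n_rows != rows_exp || (int)L.W.n_cols != cols_exp)
      Rcpp::stop("layer %d: weight matrix is %dx%d, expected %dx%d",
                 (int)i + 1, (int)L.W.n_rows, (int)L.W.n_cols, rows_exp, cols_exp);
    L.vW.zeros(L.W.n_rows, L.W.n_cols);
    L.vb.zeros(L.b.n_rows, L.b.n_cols);
  }
}

// im2col gather: P is (oh*ow*nb) x (kh*kw*c)
static void im2col(const fmat& A, const Layer& L, int nb, fmat& P) {
  const int H = L.in_h, W = L.in_w, C = L.in_c;
  const int oh = L.out_h, ow = L.out_w;
  P.set_size((uword)oh * ow * nb, (uword)L.kh * L.kw * C);
  for (int cc = 0; cc < C; ++cc)
    for (int dx = 0; dx < L.kw; ++dx)
      for (int dy = 0; dy < L.kh; ++dy) {
        const uword col = dy + dx * L.kh + (uword)cc * L.kh * L.kw;
        float* pcol = P.colptr(col);
        for (int n = 0; n < nb; ++n) {
          const float* a = A.colptr(n) + (uword)cc * H * W;
          for (int jo = 0; jo < ow; ++jo) {
            const float* src = a + (uword)(jo * L.sw + dx) * H + dy;
            float* dst = pcol + (uword)n * oh * ow + (uword)jo * oh;
            for (int io = 0; io < oh; ++io) dst[io] = src[io * L.sh];
          }
        }
      }
}

// scatter-add of dP back onto the input activation gradient
static void col2im(const fmat& dP, const Layer& L, int nb, fmat& dA) {
  const int H = L.in_h, W = L.in_w, C = L.in_c;
  const int oh = L.out_h, ow = L.out_w;
  dA.zeros((uword)H * W * C, nb);
  for (int cc = 0; cc < C; ++cc)
    for (int dx = 0; dx < L.kw; ++dx)
      for (int dy = 0; dy < L.kh; ++dy) {
        const uword col = dy + dx * L.kh + (uword)cc * L.kh * L.kw;
        const float* pcol = dP.colptr(col);
        for (int n = 0; n < nb; ++n) {
          float* a = dA.colptr(n) + (uword)cc * H * W;
          for (int jo = 0; jo < ow; ++jo) {
            float* dst = a + (uword)(jo * L.sw + dx) * H + dy;
            const float* src = pcol + (uword)n * oh * ow + (uword)jo * oh;
            for (int io = 0; io < oh; ++io) dst[io * L.sh] += src[io];
          }
        }
      }
}

// permute conv gemm output (oh*ow*nb x F) into activation layout (oh*ow*F x nb)
static void gemm_to_act(const fmat& Y, const fvec& bias, int oh, int ow, int F,
                        int nb, fmat& A) {
  A.set_size((uword)oh * ow * F, nb);
  const uword S = (uword)oh * ow;
  for (int f = 0; f < F; ++f) {
    const float* y = Y.colptr(f);
    const float bf = bias[f];
    for (int n = 0; n < nb; ++n) {
      float* dst = A.colptr(n) + (uword)f * S;
      const float* src = y + (uword)n * S;
      for (uword r = 0; r < S; ++r) dst[r] = src[r] + bf;
    }
  }
}

static void act_to_gemm(const fmat& dA, int oh, int ow, int F, int nb, fmat& dY) {
  dY.set_size((uword)oh * ow * nb, F);
  const uword S = (uword)oh * ow;
  for (int f = 0; f < F; ++f) {
    float* y = dY.colptr(f);
    for (int n = 0; n < nb; ++n) {
      const float* src = dA.colptr(n) + (uword)f * S;
      float* dst = y + (uword)n * S;
      for (uword r = 0; r < S; ++r) dst[r] = src[r];
    }
  }
}

// forward one batch; train=true caches for backward and applies dropout
static fmat forward(std::vector<Layer>& net, const fmat& X, bool train) {
  fmat A = X;
  const int nb = X.n_cols;
  for (Layer& L : net) {
    switch (L.kind) {
    case CONV: {
      im2col(A, L, nb, L.P);
      fmat Y = L.P * L.W;
      gemm_to_act(Y, L.b.col(0), L.out_h, L.out_w, L.filters, nb, A);
      if (!train) L.P.reset();
      break;
    }
    case RELU: {
      A.transform([](float v) { return v > 0.0f ? v : 0.0f; });
      if (train) L.mask = conv_to<fmat>::from(A > 0.0f);
      break;
    }
    case MAXPOOL: {
      const int H = L.in_h, C = L.in_c, oh = L.out_h, ow = L.out_w;
      fmat Out((uword)oh * ow * C, nb);
      if (train) L.argmax.set_size((uword)oh * ow * C, nb);
      for (int n = 0; n < nb; ++n) {
        const float* a = A.colptr(n);
        float* o = Out.colptr(n);
        for (int cc = 0; cc < C; ++cc) {
          const uword coff = (uword)cc * L.in_h * L.in_w;
          for (int jo = 0; jo < ow; ++jo)
            for (int io = 0; io < oh; ++io) {
              float best = -std::numeric_limits<float>::infinity();
              uword besti = 0;
              for (int dx = 0; dx < L.kw; ++dx)
                for (int dy = 0; dy < L.kh; ++dy) {
                  uword src = coff + (uword)(jo * L.sw + dx) * H + io * L.sh + dy;
                  if (a[src] > best) { best = a[src]; besti = src; }
                }
              uword out = (uword)cc * oh * ow + (uword)jo * oh + io;
              o[out] = best;
              if (train) L.argmax(out, n) = besti;
            }
        }
      }
      A = std::move(Out);
      break;
    }
    case DENSE: {
      if (train) L.A_in = A;
      A = L.W.t() * A;
      A.each_col() += L.b.col(0);
      break;
    }
    case DROPOUT: {
      if (train) {
        const float keep = 1.0f - (float)L.rate;
        L.mask.set_size(A.n_rows, A.n_cols);
        // column-major draw order: fixed by R's RNG state
        for (uword j = 0; j < A.n_cols; ++j)
          for (uword i = 0; i < A.n_rows; ++i)
            L.mask(i, j) = (unif_rand() >= L.rate) ? 1.0f / keep : 0.0f;
        A %= L.mask;
      }
      break;
    }
    case SOFTMAX: {
      A.each_row() -= max(A, 0);
      A = exp(A);
      A.each_row() /= sum(A, 0);
      break;
    }
    }
  }
  return A; // class probabilities, n_classes x nb
}

// backward from softmax cross-entropy; fills per-layer dW/db into grads
static void backward(std::vector<Layer>& net, const fmat& probs,
                     const Rcpp::IntegerVector& yb,
                     std::vector<fmat>& dW, std::vector<fmat>& db) {
  const int nb = probs.n_cols;
  fmat dA = probs;
  for (int n = 0; n < nb; ++n) dA(yb[n], n) -= 1.0f;
  dA /= (float)nb;                       // mean cross-entropy
  for (int i = (int)net.size() - 1; i >= 0; --i) {
    Layer& L = net[i];
    switch (L.kind) {
    case SOFTMAX:
      break;                             // fused with the loss above
    case DENSE: {
      dW[i] = L.A_in * dA.t();
      db[i] = sum(dA, 1);
      dA = L.W * dA;
      break;
    }
    case DROPOUT:
      if (L.mask.n_elem) dA %= L.mask;
      break;
    case RELU:
      dA %= L.mask;
      break;
    case MAXPOOL: {
      fmat dIn((uword)L.in_h * L.in_w * L.in_c, nb, fill::zeros);
      for (int n = 0; n < nb; ++n) {
        float* d = dIn.colptr(n);
        const float* g = dA.colptr(n);
        for (uword r = 0; r < dA.n_rows; ++r) d[L.argmax(r, n)] += g[r];
      }
      dA = std::move(dIn);
      break;
    }
    case CONV: {
      fmat dY;
      act_to_gemm(dA, L.out_h, L.out_w, L.filters, nb, dY);
      dW[i] = L.P.t() * dY;
      db[i] = sum(dY, 0).t();
      if (i > 0) {                       // no input gradient needed at layer 1
        fmat dP = dY * L.W.t();
        col2im(dP, L, nb, dA);
      }
      break;
    }
    }
  }
}

static double batch_loss(const fmat& probs, const Rcpp::IntegerVector& yb) {
  double loss = 0.0;
  for (int n = 0; n < (int)probs.n_cols; ++n)
    loss -= std::log(std::max(probs(yb[n], n), 1e-12f));
  return loss / probs.n_cols;
}

static double batch_acc(const fmat& probs, const Rcpp::IntegerVector& yb) {
  int ok = 0;
  for (int n = 0; n < (int)probs.n_cols; ++n) {
    int pred = probs(1, n) >= 0.5f ? 1 : 0; // tie -> positive class
    if (pred == yb[n]) ++ok;
  }
  return (double)ok / probs.n_cols;
}

static Rcpp::List export_weights(const std::vector<Layer>& net) {
  Rcpp::List out(net.size());
  for (size_t i = 0; i < net.size(); ++i) {
    const Layer& L = net[i];
    if (L.kind == CONV || L.kind == DENSE)
      out[i] = Rcpp::List::create(
        Rcpp::Named("W") = conv_to<mat>::from(L.W),
        Rcpp::Named("b") = conv_to<mat>::from(L.b));
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_cnn_train")]]
Rcpp::List cpp_cnn_train(Rcpp::List layers, Rcpp::List weights,
                         Rcpp::NumericMatrix x, Rcpp::IntegerVector dims,
                         Rcpp::IntegerVector y, double learning_rate,
                         double momentum, int epochs, int batch_size) {
  std::vector<Layer> net = parse_layers(layers, dims[0], dims[1], dims[2]);
  load_weights(net, weights);
  const int N = x.ncol();
  if (N != y.size()) Rcpp::stop("x and y disagree on sample count");
  if ((int)x.nrow() != dims[0] * dims[1] * dims[2])
    Rcpp::stop("x rows (%d) do not match input dims", (int)x.nrow());
  fmat X = conv_to<fmat>::from(Rcpp::as<mat>(x));

  std::vector<fmat> dW(net.size()), db(net.size());
  std::vector<double> h_loss, h_acc;
  std::vector<int> h_epoch;
  std::vector<int> perm(N);
  for (int e = 0; e < epochs; ++e) {
    // seeded reshuffle each epoch (Fisher-Yates on R's RNG)
    for (int i = 0; i < N; ++i) perm[i] = i;
    for (int i = N - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    for (int start = 0; start < N; start += batch_size) {
      const int nb = std::min(batch_size, N - start);
      fmat Xb(X.n_rows, nb);
      Rcpp::IntegerVector yb(nb);
      for (int k = 0; k < nb; ++k) {
        Xb.col(k) = X.col(perm[start + k]);
        yb[k] = y[perm[start + k]];
      }
      fmat probs = forward(net, Xb, true);
      const double loss = batch_loss(probs, yb);
      if (!std::isfinite(loss))
        Rcpp::stop("non-finite training loss at epoch %d", e + 1);
      h_loss.push_back(loss);
      h_acc.push_back(batch_acc(probs, yb));
      h_epoch.push_back(e + 1);
      backward(net, probs, yb, dW, db);
      for (size_t i = 0; i < net.size(); ++i) {
        Layer& L = net[i];
        if (L.kind != CONV && L.kind != DENSE) continue;
        L.vW = (float)momentum * L.vW - (float)learning_rate * dW[i];
        L.vb = (float)momentum * L.vb - (float)learning_rate * db[i];
        L.W += L.vW;
        L.b += L.vb;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("weights") = export_weights(net),
    Rcpp::Named("history") = Rcpp::DataFrame::create(
      Rcpp::Named("iteration") = Rcpp::seq_len((int)h_loss.size()),
      Rcpp::Named("epoch") = h_epoch,
      Rcpp::Named("loss") = h_loss,
      Rcpp::Named("accuracy") = h_acc));
}

// [[Rcpp::export(name = ".cpp_cnn_predict")]]
Rcpp::NumericMatrix cpp_cnn_predict(Rcpp::List layers, Rcpp::List weights,
                                    Rcpp::NumericMatrix x,
                                    Rcpp::IntegerVector dims,
                                    int chunk = 512) {
  std::vector<Layer> net = parse_layers(layers, dims[0], dims[1], dims[2]);
  load_weights(net, weights);
  const int N = x.ncol();
  fmat X = conv_to<fmat>::from(Rcpp::as<mat>(x));
  Rcpp::NumericMatrix out(N, 2);
  for (int start = 0; start < N; start += chunk) {
    const int nb = std::min(chunk, N - start);
    fmat probs = forward(net, X.cols(start, start + nb - 1), false);
    for (int k = 0; k < nb; ++k) {
      out(start + k, 0) = probs(0, k);
      out(start + k, 1) = probs(1, k);
    }
  }
  return out;
}

// Loss and exact gradients for one batch in eval mode (no dropout): used by
// the finite-difference gradient tests.
// [[Rcpp::export(name = ".cpp_cnn_loss_grad")]]
Rcpp::List cpp_cnn_loss_grad(Rcpp::List layers, Rcpp::List weights,
                             Rcpp::NumericMatrix x, Rcpp::IntegerVector dims,
                             Rcpp::IntegerVector y) {
  std::vector<Layer> net = parse_layers(layers, dims[0], dims[1], dims[2]);
  load_weights(net, weights);
  fmat X = conv_to<fmat>::from(Rcpp::as<mat>(x));
  // cache-enabled forward but with dropout disabled (rate 0 -> unit mask)
  for (Layer& L : net) if (L.kind == DROPOUT) L.rate = 0.0;
  fmat probs = forward(net, X, true);
  std::vector<fmat> dW(net.size()), db(net.size());
  Rcpp::IntegerVector yb = y;
  backward(net, probs, yb, dW, db);
  Rcpp::List grads(net.size());
  for (size_t i = 0; i < net.size(); ++i)
    if (net[i].kind == CONV || net[i].kind == DENSE)
      grads[i] = Rcpp::List::create(
        Rcpp::Named("W") = conv_to<mat>::from(dW[i]),
        Rcpp::Named("b") = conv_to<mat>::from(db[i]));
  return Rcpp::List::create(
    Rcpp::Named("loss") = batch_loss(probs, yb),
    Rcpp::Named("grads") = grads);
}
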