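// Small CNN classifier for 64x64 particle crops: three 3x3 conv + 2x2
// max-pool blocks, one hidden dense layer, 2-way softmax. Single-precision
// im2col + GEMM so that 30-epoch training on a few thousand crops is a
// matter of minutes on one CPU core. All randomness from an explicit seed.

#include "imageops.h"
#include <random>

using namespace arma;

namespace {

struct Net {
  fmat W1, W2, W3, W4, W5;
  fvec b1, b2, b3, b4, b5;
  int F1, F2, F3, Hd;
};

struct AdamState {
  fmat mW, vW;
  fvec mb, vb;
  void init(const fmat& W, const fvec& b) {
    mW = zeros<fmat>(W.n_rows, W.n_cols); vW = mW;
    mb = zeros<fvec>(b.n_elem); vb = mb;
  }
};

void adam_step(fmat& W, fvec& b, const fmat& dW, const fvec& db,
               AdamState& st, double lr, int t) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
  const float c1 = 1.0f - std::pow(b1, (float)t);
  const float c2 = 1.0f - std::pow(b2, (float)t);
  st.mW = b1 * st.mW + (1 - b1) * dW;
  st.vW = b2 * st.vW + (1 - b2) * square(dW);
  W -= (float)lr * (st.mW / c1) / (sqrt(st.vW / c2) + eps);
  st.mb = b1 * st.mb + (1 - b1) * db;
  st.vb = b2 * st.vb + (1 - b2) * square(db);
  b -= (float)lr * (st.mb / c1) / (sqrt(st.vb / c2) + eps);
}

// activations stored channel-major: A is (C, H*W*B), pixel column index
// = s*H*W + x*H + y. im2col with 3x3 kernel, zero 'same' padding.
fmat im2col3(const fmat& A, int C, int H, int W, int B) {
  fmat Col(9 * C, A.n_cols, fill::zeros);
  int k = 0;
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy, ++k) {
      const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
      const int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
      if (y1 <= y0) continue;
      for (int s = 0; s < B; ++s) {
        for (int x = x0; x < x1; ++x) {
          const int tc = s * H * W + x * H + y0;
          const int sc = s * H * W + (x + dx) * H + (y0 + dy);
          Col.submat(k * C, tc, (k + 1) * C - 1, tc + (y1 - y0) - 1) =
              A.cols(sc, sc + (y1 - y0) - 1);
        }
      }
    }
  }
  return Col;
}

void col2im3_add(const fmat& dCol, fmat& dA, int C, int H, int W, int B) {
  int k = 0;
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy, ++k) {
      const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
      const int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
      if (y1 <= y0) continue;
      for (int s = 0; s < B; ++s) {
        for (int x = x0; x < x1; ++x) {
          const int tc = s * H * W + x * H + y0;
          const int sc = s * H * W + (x + dx) * H + (y0 + dy);
          dA.cols(sc, sc + (y1 - y0) - 1) +=
              dCol.submat(k * C, tc, (k + 1) * C - 1, tc + (y1 - y0) - 1);
        }
      }
    }
  }
}

// 2x2 max pool; arg records the winning source pixel column per (channel,
// output column) for the backward scatter.
void maxpool2(const fmat& Z, int C, int H, int W, int B,
              fmat& out, umat& arg) {
  const int OH = H / 2, OW = W / 2;
  out.set_size(C, OH * OW * B);
  arg.set_size(C, OH * OW * B);
  for (int s = 0; s < B; ++s) {
    for (int xo = 0; xo < OW; ++xo) {
      for (int yo = 0; yo < OH; ++yo) {
        const int oc = s * OH * OW + xo * OH + yo;
        const int base = s * H * W;
        const int cand[4] = {base + (2 * xo) * H + 2 * yo,
                             base + (2 * xo) * H + 2 * yo + 1,
                             base + (2 * xo + 1) * H + 2 * yo,
                             base + (2 * xo + 1) * H + 2 * yo + 1};
        const float* p0 = Z.colptr(cand[0]);
        const float* p1 = Z.colptr(cand[1]);
        const float* p2 = Z.colptr(cand[2]);
        const float* p3 = Z.colptr(cand[3]);
        float* po = out.colptr(oc);
        uword* pa = arg.colptr(oc);
        for (int c = 0; c < C; ++c) {
          float best = p0[c]; uword bi = cand[0];
          if (p1[c] > best) { best = p1[c]; bi = cand[1]; }
          if (p2[c] > best) { best = p2[c]; bi = cand[2]; }
          if (p3[c] > best) { best = p3[c]; bi = cand[3]; }
          po[c] = best; pa[c] = bi;
        }
      }
    }
  }
}

void maxpool2_back(const fmat& dOut, const umat& arg, fmat& dZ) {
  for (uword oc = 0; oc < dOut.n_cols; ++oc) {
    const float* pd = dOut.colptr(oc);
    const uword* pa = arg.colptr(oc);
    for (uword c = 0; c < dOut.n_rows; ++c) dZ(c, pa[c]) += pd[c];
  }
}

struct Cache {
  fmat Col1, Col2, Col3;   // im2col inputs per conv layer
  fmat A1, A2, A3;         // post-relu conv activations (pre-pool)
  fmat P1, P2, P3;         // pooled activations
  umat G1, G2, G3;         // pool argmax
  fmat Flat, H4;           // dense input, hidden activation
  fmat P;                  // softmax output (2 x B)
};

// X: 4096 x B standardized crops (one column per crop)
void forward(const Net& net, const fmat& X, Cache& cc, bool keep) {
  const int B = X.n_cols;
  fmat A0(1, 64 * 64 * B);
  // crop column (x*64+y ordering) matches pixel-column layout directly
  std::memcpy(A0.memptr(), X.memptr(), sizeof(float) * X.n_elem);

  cc.Col1 = im2col3(A0, 1, 64, 64, B);
  cc.A1 = net.W1 * cc.Col1; cc.A1.each_col() += net.b1;
  cc.A1.transform([](float v) { return v > 0 ? v : 0; });
  maxpool2(cc.A1, net.F1, 64, 64, B, cc.P1, cc.G1);

  cc.Col2 = im2col3(cc.P1, net.F1, 32, 32, B);
  cc.A2 = net.W2 * cc.Col2; cc.A2.each_col() += net.b2;
  cc.A2.transform([](float v) { return v > 0 ? v : 0; });
  maxpool2(cc.A2, net.F2, 32, 32, B, cc.P2, cc.G2);

  cc.Col3 = im2col3(cc.P2, net.F2, 16, 16, B);
  cc.A3 = net.W3 * cc.Col3; cc.A3.each_col() += net.b3;
  cc.A3.transform([](float v) { return v > 0 ? v : 0; });
  maxpool2(cc.A3, net.F3, 16, 16, B, cc.P3, cc.G3);

  // flatten (F3, 64*B) -> (F3*64, B), sample-contiguous
  cc.Flat = reshape(cc.P3, net.F3 * 64, B);
  cc.H4 = net.W4 * cc.Flat; cc.H4.each_col() += net.b4;
  cc.H4.transform([](float v) { return v > 0 ? v : 0; });

  fmat Z5 = net.W5 * cc.H4; Z5.each_col() += net.b5;
  Z5.each_row() -= max(Z5, 0);
  cc.P = exp(Z5);
  cc.P.each_row() /= sum(cc.P, 0);

  if (!keep) { cc.Col1.reset(); cc.Col2.reset(); cc.Col3.reset(); }
}

struct Grads {
  fmat dW1, dW2, dW3, dW4, dW5;
  fvec db1, db2, db3, db4, db5;
};

void backward(const Net& net, const Cache& cc, const fmat& Y, Grads& g) {
  const int B = cc.P.n_cols;
  fmat dZ5 = (cc.P - Y) / (float)B;
  g.dW5 = dZ5 * cc.H4.t(); g.db5 = sum(dZ5, 1);

  fmat dH4 = net.W5.t() * dZ5;
  dH4 %= conv_to<fmat>::from(cc.H4 > 0);
  g.dW4 = dH4 * cc.Flat.t(); g.db4 = sum(dH4, 1);

  fmat dFlat = net.W4.t() * dH4;
  fmat dP3 = reshape(dFlat, net.F3, 64 * B);

  fmat dA3(net.F3, 16 * 16 * B, fill::zeros);
  maxpool2_back(dP3, cc.G3, dA3);
  dA3 %= conv_to<fmat>::from(cc.A3 > 0);
  g.dW3 = dA3 * cc.Col3.t(); g.db3 = sum(dA3, 1);
  fmat dCol3 = net.W3.t() * dA3;
  fmat dP2(net.F2, 16 * 16 * B, fill::zeros);
  col2im3_add(dCol3, dP2, net.F2, 16, 16, B);

  fmat dA2(net.F2, 32 * 32 * B, fill::zeros);
  maxpool2_back(dP2, cc.G2, dA2);
  dA2 %= conv_to<fmat>::from(cc.A2 > 0);
  g.dW2 = dA2 * cc.Col2.t(); g.db2 = sum(dA2, 1);
  fmat dCol2 = net.W2.t() * dA2;
  fmat dP1(net.F1, 32 * 32 * B, fill::zeros);
  col2im3_add(dCol2, dP1, net.F1, 32, 32, B);

  fmat dA1(net.F1, 64 * 64 * B, fill::zeros);
  maxpool2_back(dP1, cc.G1, dA1);
  dA1 %= conv_to<fmat>::from(cc.A1 > 0);
  g.dW1 = dA1 * cc.Col1.t(); g.db1 = sum(dA1, 1);
}

Net net_from_list(const Rcpp::List& wl) {
  Net n;
  n.W1 = conv_to<fmat>::from(Rcpp::as<mat>(wl["W1"]));
  n.W2 = conv_to<fmat>::from(Rcpp::as<mat>(wl["W2"]));
  n.W3 = conv_to<fmat>::from(Rcpp::as<mat>(wl["W3"]));
  n.W4 = conv_to<fmat>::from(Rcpp::as<mat>(wl["W4"]));
  n.W5 = conv_to<fmat>::from(Rcpp::as<mat>(wl["W5"]));
  n.b1 = conv_to<fvec>::from(Rcpp::as<vec>(wl["b1"]));
  n.b2 = conv_to<fvec>::from(Rcpp::as<vec>(wl["b2"]));
  n.b3 = conv_to<fvec>::from(Rcpp::as<vec>(wl["b3"]));
  n.b4 = conv_to<fvec>::from(Rcpp::as<vec>(wl["b4"]));
  n.b5 = conv_to<fvec>::from(Rcpp::as<vec>(wl["b5"]));
  n.F1 = n.W1.n_rows; n.F2 = n.W2.n_rows; n.F3 = n.W3.n_rows;
  n.Hd = n.W4.n_rows;
  return n;
}

Rcpp::List net_to_list(const Net& n) {
  return Rcpp::List::create(
      Rcpp::Named("W1") = conv_to<mat>::from(n.W1),
      Rcpp::Named("b1") = conv_to<vec>::from(n.b1),
      Rcpp::Named("W2") = conv_to<mat>::from(n.W2),
      Rcpp::Named("b2") = conv_to<vec>::from(n.b2),
      Rcpp::Named("W3") = conv_to<mat>::from(n.W3),
      Rcpp::Named("b3") = conv_to<vec>::from(n.b3),
      Rcpp::Named("W4") = conv_to<mat>::from(n.W4),
      Rcpp::Named("b4") = conv_to<vec>::from(n.b4),
      Rcpp::Named("W5") = conv_to<mat>::from(n.W5),
      Rcpp::Named("b5") = conv_to<vec>::from(n.b5));
}

// rotation in [-max_angle, max_angle], then horizontal / vertical flip each
// with probability 0.5; operates on one 4096-vector crop
vec augment_one(const vec& crop, std::mt19937& rng, double max_angle) {
  std::uniform_real_distribution<double> ang(-max_angle, max_angle);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  mat img(64, 64);
  // column index = x*64 + y -> img(y, x); vec is already in that order
  std::memcpy(img.memptr(), crop.memptr(), sizeof(double) * 4096);
  mat out = rotate_reflect(img, ang(rng));
  if (unif(rng) < 0.5) out = fliplr(out);  // horizontal flip (x)
  if (unif(rng) < 0.5) out = flipud(out);  // vertical flip (y)
  vec v(4096);
  std::memcpy(v.memptr(), out.memptr(), sizeof(double) * 4096);
  return v;
}

double eval_set(const Net& net, const fmat& X, const ivec& y,
                double& acc_out) {
  const int n = X.n_cols, bs = 64;
  double loss = 0; int correct = 0;
  Cache cc;
  for (int i0 = 0; i0 < n; i0 += bs) {
    int i1 = std::min(n, i0 + bs);
    forward(net, X.cols(i0, i1 - 1), cc, false);
    for (int j = i0; j < i1; ++j) {
      float p = cc.P(y(j), j - i0);
      loss += -std::log(std::max(p, 1e-12f));
      int pred = cc.P(1, j - i0) >= cc.P(0, j - i0) ? 1 : 0;
      if (pred == y(j)) ++correct;
    }
  }
  acc_out = (double)correct / n;
  return loss / n;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_cnn_init")]]
Rcpp::List cpp_cnn_init(int f1, int f2, int f3, int hidden, int seed) {
  std::mt19937 rng(seed);
  auto he = [&](int rows, int cols, int fan_in) {
    std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / fan_in));
    mat W(rows, cols);
    for (uword j = 0; j < W.n_cols; ++j)
      for (uword i = 0; i < W.n_rows; ++i) W(i, j) = nd(rng);
    return W;
  };
  Net n;
  n.W1 = conv_to<fmat>::from(he(f1, 9, 9));
  n.W2 = conv_to<fmat>::from(he(f2, 9 * f1, 9 * f1));
  n.W3 = conv_to<fmat>::from(he(f3, 9 * f2, 9 * f2));
  n.W4 = conv_to<fmat>::from(he(hidden, f3 * 64, f3 * 64));
  n.W5 = conv_to<fmat>::from(he(2, hidden, hidden));
  n.b1 = zeros<fvec>(f1); n.b2 = zeros<fvec>(f2); n.b3 = zeros<fvec>(f3);
  n.b4 = zeros<fvec>(hidden); n.b5 = zeros<fvec>(2);
  return net_to_list(n);
}

// [[Rcpp::export(name = ".cpp_cnn_predict")]]
arma::mat cpp_cnn_predict(const Rcpp::List& weights, const arma::mat& X) {
  Net net = net_from_list(weights);
  const int n = X.n_cols, bs = 64;
  mat out(n, 2);
  Cache cc;
  for (int i0 = 0; i0 < n; i0 += bs) {
    int i1 = std::min(n, i0 + bs);
    fmat Xb = conv_to<fmat>::from(X.cols(i0, i1 - 1));
    forward(net, Xb, cc, false);
    out.rows(i0, i1 - 1) = conv_to<mat>::from(cc.P.t());
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_augment")]]
arma::mat cpp_augment(const arma::mat& X, int seed, double max_angle) {
  std::mt19937 rng(seed);
  mat out(X.n_rows, X.n_cols);
  for (uword i = 0; i < X.n_cols; ++i)
    out.col(i) = augment_one(X.col(i), rng, max_angle);
  return out;
}

// [[Rcpp::export(name = ".cpp_cnn_train")]]
Rcpp::List cpp_cnn_train(const Rcpp::List& weights,
                         const arma::mat& Xtr, const arma::ivec& ytr,
                         const arma::mat& Xval, const arma::ivec& yval,
                         int epochs, int batch, double lr, int seed,
                         bool augment, double max_angle) {
  Net net = net_from_list(weights);
  const int n = Xtr.n_cols;
  fmat Xv = conv_to<fmat>::from(Xval);

  AdamState a1, a2, a3, a4, a5;
  a1.init(net.W1, net.b1); a2.init(net.W2, net.b2); a3.init(net.W3, net.b3);
  a4.init(net.W4, net.b4); a5.init(net.W5, net.b5);

  std::mt19937 rng(seed);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  mat hist(epochs, 4);  // train_loss, train_acc, val_loss, val_acc
  Cache cc; Grads g;
  int t = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0; int ep_correct = 0;
    for (int i0 = 0; i0 < n; i0 += batch) {
      const int i1 = std::min(n, i0 + batch), B = i1 - i0;
      fmat Xb(4096, B);
      fmat Y(2, B, fill::zeros);
      ivec yb(B);
      for (int j = 0; j < B; ++j) {
        vec col = Xtr.col(idx[i0 + j]);
        if (augment) col = augment_one(col, rng, max_angle);
        Xb.col(j) = conv_to<fvec>::from(col);
        yb(j) = ytr(idx[i0 + j]);
        Y(yb(j), j) = 1.0f;
      }
      forward(net, Xb, cc, true);
      for (int j = 0; j < B; ++j) {
        ep_loss += -std::log(std::max(cc.P(yb(j), j), 1e-12f));
        if ((cc.P(1, j) >= cc.P(0, j) ? 1 : 0) == yb(j)) ++ep_correct;
      }
      backward(net, cc, Y, g);
      ++t;
      adam_step(net.W1, net.b1, g.dW1, g.db1, a1, lr, t);
      adam_step(net.W2, net.b2, g.dW2, g.db2, a2, lr, t);
      adam_step(net.W3, net.b3, g.dW3, g.db3, a3, lr, t);
      adam_step(net.W4, net.b4, g.dW4, g.db4, a4, lr, t);
      adam_step(net.W5, net.b5, g.dW5, g.db5, a5, lr, t);
    }
    hist(ep, 0) = ep_loss / n;
    hist(ep, 1) = (double)ep_correct / n;
    double vacc = NA_REAL, vloss = NA_REAL;
    if (Xv.n_cols > 0) {
      ivec yv = yval;
      vloss = eval_set(net, Xv, yv, vacc);
    }
    hist(ep, 2) = vloss;
    hist(ep, 3) = vacc;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("weights") = net_to_list(net),
                            Rcpp::Named("history") = hist);
}
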