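// A small 1D-convolutional regressor trained with Adam on mean-squared error.
// Architecture (fixed topology, configurable filter counts): three stride-1
// same-padded conv layers with ELU activations, one dropout layer after the
// conv stack, dense layers of 256 and 128 units (ELU), and a linear scalar
// output.  Implemented with im2col + GEMM so a whole mini-batch is one matrix
// product per layer; the im2col shift is done on the full batch at once with
// the sample-boundary rows zeroed afterwards.  All randomness (shuffling,
// dropout) comes from a local mt19937 so training is reproducible from a
// seed in a single thread.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// the network trains in single precision (standard for small-net SGD and
// about twice the GEMM throughput); weights cross the R boundary as doubles
static fmat as_f(const arma::mat &m) { return conv_to<fmat>::from(m); }
static frowvec as_fr(const arma::rowvec &v) { return conv_to<frowvec>::from(v); }

static inline fmat elu(const fmat &x) {
  fmat y = x;
  y.transform([](float v) { return v > 0 ? v : std::expm1(v); });
  return y;
}

// derivative of ELU in terms of the activation output a (alpha = 1)
static inline fmat elu_grad(const fmat &a) {
  fmat g = a;
  g.transform([](float v) { return v > 0 ? 1.0f : v + 1.0f; });
  return g;
}

// im2col for a batch laid out as (B*L x C): row b*L+p holds channels of
// position p of sample b.  Output (B*L x K*C), zero padding, K odd.
// One shifted block copy per tap, then the rows that crossed a sample
// boundary are zeroed.
static fmat im2col(const fmat &A, uword B, uword L, uword K) {
  const uword C = A.n_cols, N = B * L;
  const int half = (int)K / 2;
  fmat col(N, K * C, fill::zeros);
  for (uword k = 0; k < K; ++k) {
    int off = (int)k - half;  // col row r reads A row r+off
    uword r0 = (uword)std::max(0, -off), r1 = N - (uword)std::max(0, off);
    col.submat(r0, k * C, r1 - 1, k * C + C - 1) =
        A.rows(r0 + off, r1 - 1 + off);
    if (off < 0)       // first |off| rows of every sample read the previous one
      for (uword b = 1; b < B; ++b)
        col.submat(b * L, k * C, b * L - off - 1, k * C + C - 1).zeros();
    else if (off > 0)  // last |off| rows of every sample read the next one
      for (uword b = 0; b + 1 < B; ++b)
        col.submat(b * L + L - off, k * C, b * L + L - 1, k * C + C - 1).zeros();
  }
  return col;
}

// adjoint of im2col: dA[r+off] += dcol[r] within each sample
static fmat col2im(const fmat &dcol, uword B, uword L, uword K, uword C) {
  const uword N = B * L;
  const int half = (int)K / 2;
  fmat dA(N, C, fill::zeros);
  for (uword k = 0; k < K; ++k) {
    int off = (int)k - half;
    uword r0 = (uword)std::max(0, -off), r1 = N - (uword)std::max(0, off);
    fmat slice = dcol.submat(r0, k * C, r1 - 1, k * C + C - 1);
    // zero contributions that would cross a sample boundary
    if (off < 0) {
      for (uword b = 1; b < B; ++b)
        slice.rows(b * L - r0, b * L - r0 - off - 1).zeros();
    } else if (off > 0) {
      for (uword b = 0; b + 1 < B; ++b)
        slice.rows(b * L + L - off - r0, b * L + L - 1 - r0).zeros();
    }
    dA.rows(r0 + off, r1 - 1 + off) += slice;
  }
  return dA;
}

struct AdamState {
  std::vector<fmat> m, v;
  float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  long t = 0;
  void init(const std::vector<fmat *> &ws) {
    for (auto *w : ws) {
      m.push_back(zeros<fmat>(w->n_rows, w->n_cols));
      v.push_back(zeros<fmat>(w->n_rows, w->n_cols));
    }
  }
  // single fused pass per tensor: update m, v and the weights without
  // temporaries (the elementwise sqrt/div work dominates small-batch cost)
  void step(std::vector<fmat *> &ws, const std::vector<fmat> &gs, float lr) {
    ++t;
    float c1 = 1.0f - std::pow(b1, (float)t), c2 = 1.0f - std::pow(b2, (float)t);
    float sc2 = std::sqrt(c2), lr_t = lr * sc2 / c1, eps_t = eps * sc2;
    for (size_t i = 0; i < ws.size(); ++i) {
      float *mp = m[i].memptr(), *vp = v[i].memptr(), *wp = ws[i]->memptr();
      const float *gp = gs[i].memptr();
      const uword n = m[i].n_elem;
      for (uword j = 0; j < n; ++j) {
        mp[j] = b1 * mp[j] + (1 - b1) * gp[j];
        vp[j] = b2 * vp[j] + (1 - b2) * gp[j] * gp[j];
        wp[j] -= lr_t * mp[j] / (std::sqrt(vp[j]) + eps_t);
      }
    }
  }
};

struct Net {
  uword L, K;
  fmat W1, W2, W3, D1, D2, D3;
  frowvec b1, b2, b3, d1, d2, d3;

  static Net from_list(const Rcpp::List &w) {
    Net n;
    n.L = Rcpp::as<uword>(w["L"]);
    n.K = Rcpp::as<uword>(w["K"]);
    n.W1 = as_f(Rcpp::as<mat>(w["W1"])); n.b1 = as_fr(Rcpp::as<rowvec>(w["b1"]));
    n.W2 = as_f(Rcpp::as<mat>(w["W2"])); n.b2 = as_fr(Rcpp::as<rowvec>(w["b2"]));
    n.W3 = as_f(Rcpp::as<mat>(w["W3"])); n.b3 = as_fr(Rcpp::as<rowvec>(w["b3"]));
    n.D1 = as_f(Rcpp::as<mat>(w["D1"])); n.d1 = as_fr(Rcpp::as<rowvec>(w["d1"]));
    n.D2 = as_f(Rcpp::as<mat>(w["D2"])); n.d2 = as_fr(Rcpp::as<rowvec>(w["d2"]));
    n.D3 = as_f(Rcpp::as<mat>(w["D3"])); n.d3 = as_fr(Rcpp::as<rowvec>(w["d3"]));
    return n;
  }
  Rcpp::List to_list() const {
    return Rcpp::List::create(
        Rcpp::Named("L") = (int)L, Rcpp::Named("K") = (int)K,
        Rcpp::Named("W1") = conv_to<mat>::from(W1),
        Rcpp::Named("b1") = conv_to<rowvec>::from(b1),
        Rcpp::Named("W2") = conv_to<mat>::from(W2),
        Rcpp::Named("b2") = conv_to<rowvec>::from(b2),
        Rcpp::Named("W3") = conv_to<mat>::from(W3),
        Rcpp::Named("b3") = conv_to<rowvec>::from(b3),
        Rcpp::Named("D1") = conv_to<mat>::from(D1),
        Rcpp::Named("d1") = conv_to<rowvec>::from(d1),
        Rcpp::Named("D2") = conv_to<mat>::from(D2),
        Rcpp::Named("d2") = conv_to<rowvec>::from(d2),
        Rcpp::Named("D3") = conv_to<mat>::from(D3),
        Rcpp::Named("d3") = conv_to<rowvec>::from(d3));
  }
};

struct Cache {
  fmat X0, col1, col2, col3, A1, A2, A3, A3d, mask, Fl, H1, H2;
};

// Forward pass over a (B x L) batch; caches intermediates for backprop.
// A3 is the pre-dropout conv-stack output, A3d the (possibly) dropped one.
static fvec forward(const Net &net, const fmat &X, bool training,
                    double dropout, std::mt19937 *rng, Cache &c) {
  const uword B = X.n_rows, L = net.L, K = net.K;
  c.X0 = reshape(X.t(), B * L, 1);
  c.col1 = im2col(c.X0, B, L, K);
  fmat Z1 = c.col1 * net.W1; Z1.each_row() += net.b1;
  c.A1 = elu(Z1);
  c.col2 = im2col(c.A1, B, L, K);
  fmat Z2 = c.col2 * net.W2; Z2.each_row() += net.b2;
  c.A2 = elu(Z2);
  c.col3 = im2col(c.A2, B, L, K);
  fmat Z3 = c.col3 * net.W3; Z3.each_row() += net.b3;
  c.A3 = elu(Z3);
  if (training && dropout > 0) {
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    c.mask.set_size(c.A3.n_rows, c.A3.n_cols);
    for (uword j = 0; j < c.mask.n_cols; ++j)
      for (uword i = 0; i < c.mask.n_rows; ++i)
        c.mask(i, j) = unif(*rng) < dropout ? 0.0f : 1.0f / (1.0f - dropout);
    c.A3d = c.A3 % c.mask;
  } else {
    c.A3d = c.A3;
  }
  const uword C3 = net.W3.n_cols;
  c.Fl = reshape(c.A3d.t(), L * C3, B).t();  // per-sample position-major
  fmat Z4 = c.Fl * net.D1; Z4.each_row() += net.d1;
  c.H1 = elu(Z4);
  fmat Z5 = c.H1 * net.D2; Z5.each_row() += net.d2;
  c.H2 = elu(Z5);
  return vectorise(c.H2 * net.D3) + net.d3(0);
}

// [[Rcpp::export]]
arma::vec cnn_predict_cpp(const Rcpp::List &weights, const arma::mat &X) {
  Net net = Net::from_list(weights);
  Cache c;
  return conv_to<vec>::from(forward(net, as_f(X), false, 0.0, nullptr, c));
}

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(const Rcpp::List &weights, const arma::mat &X,
                         const arma::vec &y, int epochs, int batch_size,
                         double lr, double dropout, int seed) {
  Net net = Net::from_list(weights);
  const fmat Xf = as_f(X);
  const fvec yf = conv_to<fvec>::from(y);
  const uword n = Xf.n_rows, L = net.L, K = net.K;
  const uword C3 = net.W3.n_cols;
  std::mt19937 rng((unsigned)seed);

  fmat B1(net.b1), B2(net.b2), B3(net.b3),
       Dd1(net.d1), Dd2(net.d2), Dd3(net.d3);
  std::vector<fmat *> params = {&net.W1, &B1, &net.W2, &B2, &net.W3, &B3,
                                &net.D1, &Dd1, &net.D2, &Dd2, &net.D3, &Dd3};
  AdamState adam;
  adam.init(params);

  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;
  vec loss_hist(epochs, fill::zeros);
  Cache c;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0;
    uword nb = 0;
    for (uword start = 0; start < n; start += batch_size) {
      uword stop = std::min(n, start + (uword)batch_size);
      uword B = stop - start;
      fmat Xb(B, Xf.n_cols);
      fvec yb(B);
      for (uword i = 0; i < B; ++i) {
        Xb.row(i) = Xf.row(idx[start + i]);
        yb(i) = yf(idx[start + i]);
      }
      net.b1 = B1; net.b2 = B2; net.b3 = B3;
      net.d1 = Dd1; net.d2 = Dd2; net.d3 = Dd3;
      fvec yhat = forward(net, Xb, true, dropout, &rng, c);
      fvec r = yhat - yb;
      ep_loss += (double)dot(r, r) / B;
      ++nb;

      // ---- backward ----
      fvec dy = 2.0f * r / (float)B;
      fmat dD3 = c.H2.t() * dy;
      frowvec dd3(1); dd3(0) = accu(dy);
      fmat dH2 = (dy * net.D3.t()) % elu_grad(c.H2);
      fmat dD2 = c.H1.t() * dH2;
      frowvec dd2 = sum(dH2, 0);
      fmat dH1 = (dH2 * net.D2.t()) % elu_grad(c.H1);
      fmat dD1 = c.Fl.t() * dH1;
      frowvec dd1 = sum(dH1, 0);
      fmat dFl = dH1 * net.D1.t();
      fmat dA3d = reshape(dFl.t(), C3, B * L).t();
      if (dropout > 0) dA3d %= c.mask;        // through dropout
      fmat gz3 = dA3d % elu_grad(c.A3);       // pre-dropout activation
      fmat dW3 = c.col3.t() * gz3;
      frowvec db3 = sum(gz3, 0);
      fmat dA2 = col2im(gz3 * net.W3.t(), B, L, K, net.W2.n_cols);
      fmat gz2 = dA2 % elu_grad(c.A2);
      fmat dW2 = c.col2.t() * gz2;
      frowvec db2 = sum(gz2, 0);
      fmat dA1 = col2im(gz2 * net.W2.t(), B, L, K, net.W1.n_cols);
      fmat gz1 = dA1 % elu_grad(c.A1);
      fmat dW1 = c.col1.t() * gz1;
      frowvec db1 = sum(gz1, 0);

      std::vector<fmat> grads = {dW1, fmat(db1), dW2, fmat(db2),
                                 dW3, fmat(db3), dD1, fmat(dd1),
                                 dD2, fmat(dd2), dD3, fmat(dd3)};
      adam.step(params, grads, (float)lr);
    }
    loss_hist(ep) = ep_loss / nb;
    if (!std::isfinite(loss_hist(ep)))
      Rcpp::stop("training diverged (non-finite loss) at epoch %d", ep + 1);
    if (ep % 50 == 0) Rcpp::checkUserInterrupt();
  }
  net.b1 = B1; net.b2 = B2; net.b3 = B3;
  net.d1 = Dd1; net.d2 = Dd2; net.d3 = Dd3;
  return Rcpp::List::create(Rcpp::Named("weights") = net.to_list(),
                            Rcpp::Named("loss") = loss_hist);
}
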