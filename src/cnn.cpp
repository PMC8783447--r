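// Compact CNN engine for 50x50 single-channel patch classification.
//
// Fixed topology (both networks in the package use it, differing only in
// filter counts and output size):
//   input 50x50x1 (zero-centered upstream)
//   conv1 3x3 'same' (f1) -> BN -> ReLU -> maxpool 2x2 stride 2   (-> 25x25)
//   conv2 3x3 'same' (f2) -> BN -> ReLU -> maxpool 2x2 stride 2   (-> 12x12)
//   conv3 3x3 'same' (f3) -> BN -> ReLU
//   fully connected (nc) -> softmax
// Training: SGD with momentum, optional L2 decay, cross-entropy or MSE loss
// on the softmax output. Single-threaded and deterministic for fixed
// initial weights and batch order.
//
// Activations for a batch are held as cubes of shape (H, W, C*B) with
// slice index b*C + c, so each convolution is a single im2col + one large
// GEMM over the whole batch and batch normalization reduces over strided
// slice sets.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double BN_EPS = 1e-5;

// batched im2col for 3x3 'same' convolution: output (9C) x (H*W*B),
// column block b holds sample b's columns, column j = x*H + y.
static arma::mat im2col3_batch(const arma::cube& in, int C, int B) {
  const int H = in.n_rows, W = in.n_cols;
  arma::mat col(9 * C, (arma::uword)H * W * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    arma::uword col0 = (arma::uword)b * H * W;
    for (int c = 0; c < C; ++c) {
      const arma::mat& sl = in.slice((arma::uword)b * C + c);
      for (int dx = -1; dx <= 1; ++dx) {
        for (int dy = -1; dy <= 1; ++dy) {
          int row = c * 9 + (dx + 1) * 3 + (dy + 1);
          int xlo = std::max(0, -dx), xhi = std::min(W, W - dx);
          int ylo = std::max(0, -dy), yhi = std::min(H, H - dy);
          for (int x = xlo; x < xhi; ++x) {
            const double* src = sl.colptr(x + dx);
            // column index col0 + x*H + y; consecutive y are consecutive
            // columns, i.e. strides of n_rows in memory
            double* dst = col.colptr(col0 + (arma::uword)x * H) + row;
            for (int y = ylo; y < yhi; ++y)
              dst[(arma::uword)y * col.n_rows] = src[y + dy];
          }
        }
      }
    }
  }
  return col;
}

// scatter-add of a (9C) x (H*W*B) gradient back to input layout
static void col2im3_batch(const arma::mat& dcol, arma::cube& dout, int C,
                          int B) {
  const int H = dout.n_rows, W = dout.n_cols;
  dout.zeros();
  for (int b = 0; b < B; ++b) {
    arma::uword col0 = (arma::uword)b * H * W;
    for (int c = 0; c < C; ++c) {
      arma::mat& sl = dout.slice((arma::uword)b * C + c);
      for (int dx = -1; dx <= 1; ++dx) {
        for (int dy = -1; dy <= 1; ++dy) {
          int row = c * 9 + (dx + 1) * 3 + (dy + 1);
          int xlo = std::max(0, -dx), xhi = std::min(W, W - dx);
          int ylo = std::max(0, -dy), yhi = std::min(H, H - dy);
          for (int x = xlo; x < xhi; ++x) {
            double* dst = sl.colptr(x + dx);
            const double* src = dcol.colptr(col0 + (arma::uword)x * H) + row;
            for (int y = ylo; y < yhi; ++y)
              dst[y + dy] += src[(arma::uword)y * dcol.n_rows];
          }
        }
      }
    }
  }
}

// Y (K x HW*B) -> activation cube (H, W, K*B)
static arma::cube unstack(const arma::mat& Y, int H, int W, int K, int B) {
  arma::cube out(H, W, (arma::uword)K * B);
  for (int b = 0; b < B; ++b)
    for (int k = 0; k < K; ++k) {
      arma::rowvec r = Y.row(k).subvec((arma::uword)b * H * W,
                                       (arma::uword)(b + 1) * H * W - 1);
      out.slice((arma::uword)b * K + k) = arma::reshape(r, H, W);
    }
  return out;
}

// activation cube (H, W, K*B) -> (K x HW*B)
static arma::mat restack(const arma::cube& A, int K, int B) {
  const int H = A.n_rows, W = A.n_cols;
  arma::mat Y(K, (arma::uword)H * W * B);
  for (int b = 0; b < B; ++b)
    for (int k = 0; k < K; ++k) {
      Y.row(k).subvec((arma::uword)b * H * W,
                      (arma::uword)(b + 1) * H * W - 1) =
        arma::vectorise(A.slice((arma::uword)b * K + k)).t();
    }
  return Y;
}

static arma::cube maxpool_batch(const arma::cube& in, arma::ucube& idx) {
  const int H = in.n_rows / 2, W = in.n_cols / 2, S = in.n_slices;
  arma::cube out(H, W, S);
  idx.set_size(H, W, S);
  for (int s = 0; s < S; ++s)
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        double best = -arma::datum::inf;
        int bi = 0;
        for (int dx = 0; dx < 2; ++dx)
          for (int dy = 0; dy < 2; ++dy) {
            double v = in(2 * y + dy, 2 * x + dx, s);
            if (v > best) { best = v; bi = dx * 2 + dy; }
          }
        out(y, x, s) = best;
        idx(y, x, s) = bi;
      }
  return out;
}

static arma::cube maxpool_back_batch(const arma::cube& dout,
                                     const arma::ucube& idx, int Hin,
                                     int Win) {
  const int H = dout.n_rows, W = dout.n_cols, S = dout.n_slices;
  arma::cube din(Hin, Win, S, arma::fill::zeros);
  for (int s = 0; s < S; ++s)
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        int bi = (int)idx(y, x, s);
        din(2 * y + bi % 2, 2 * x + bi / 2, s) = dout(y, x, s);
      }
  return din;
}

struct BNCache {
  arma::vec mu, invstd;
  arma::cube xhat;
};

// batch norm over batch x spatial per channel; acts has slices b*C + c
static void bn_forward_train(arma::cube& acts, int C, int B,
                             const arma::vec& g, const arma::vec& bt,
                             arma::vec& rmu, arma::vec& rvar, double bn_mom,
                             BNCache& cache) {
  double m = (double)B * acts.n_rows * acts.n_cols;
  cache.mu.set_size(C); cache.invstd.set_size(C);
  cache.xhat.copy_size(acts);
  for (int c = 0; c < C; ++c) {
    double s = 0;
    for (int b = 0; b < B; ++b)
      s += arma::accu(acts.slice((arma::uword)b * C + c));
    double mu = s / m;
    double v = 0;
    for (int b = 0; b < B; ++b) {
      arma::mat d = acts.slice((arma::uword)b * C + c) - mu;
      v += arma::accu(d % d);
    }
    v /= m;
    double invstd = 1.0 / std::sqrt(v + BN_EPS);
    cache.mu(c) = mu; cache.invstd(c) = invstd;
    rmu(c) = (1 - bn_mom) * rmu(c) + bn_mom * mu;
    rvar(c) = (1 - bn_mom) * rvar(c) + bn_mom * v;
    for (int b = 0; b < B; ++b) {
      arma::uword sl = (arma::uword)b * C + c;
      cache.xhat.slice(sl) = (acts.slice(sl) - mu) * invstd;
      acts.slice(sl) = g(c) * cache.xhat.slice(sl) + bt(c);
    }
  }
}

static void bn_forward_infer(arma::cube& acts, int C, int B,
                             const arma::vec& g, const arma::vec& bt,
                             const arma::vec& rmu, const arma::vec& rvar) {
  for (int c = 0; c < C; ++c) {
    double invstd = 1.0 / std::sqrt(rvar(c) + BN_EPS);
    for (int b = 0; b < B; ++b) {
      arma::uword sl = (arma::uword)b * C + c;
      acts.slice(sl) = g(c) * (acts.slice(sl) - rmu(c)) * invstd + bt(c);
    }
  }
}

static void bn_backward(arma::cube& dacts, int C, int B,
                        const BNCache& cache, const arma::vec& g,
                        arma::vec& dg, arma::vec& dbt) {
  double m = (double)B * dacts.n_rows * dacts.n_cols;
  for (int c = 0; c < C; ++c) {
    double sum_dy = 0, sum_dy_xh = 0;
    for (int b = 0; b < B; ++b) {
      arma::uword sl = (arma::uword)b * C + c;
      sum_dy += arma::accu(dacts.slice(sl));
      sum_dy_xh += arma::accu(dacts.slice(sl) % cache.xhat.slice(sl));
    }
    dg(c) += sum_dy_xh;
    dbt(c) += sum_dy;
    double invstd = cache.invstd(c), gc = g(c);
    for (int b = 0; b < B; ++b) {
      arma::uword sl = (arma::uword)b * C + c;
      dacts.slice(sl) = gc * invstd *
        (dacts.slice(sl) - sum_dy / m -
         cache.xhat.slice(sl) * (sum_dy_xh / m));
    }
  }
}

static void relu_fwd(arma::cube& a) {
  a.transform([](double v) { return v > 0 ? v : 0; });
}

static void relu_bwd(arma::cube& d, const arma::cube& a_post) {
  for (arma::uword i = 0; i < d.n_elem; ++i)
    if (a_post(i) <= 0) d(i) = 0;
}

// crop 25x25 slices to 24x24 (max pool on an odd size drops the last
// row/col, matching the 50 -> 25 -> 12 spatial path)
static arma::cube crop_batch(const arma::cube& in, int n) {
  arma::cube out(n, n, in.n_slices);
  for (arma::uword s = 0; s < in.n_slices; ++s)
    out.slice(s) = in.slice(s).submat(0, 0, n - 1, n - 1);
  return out;
}

static arma::mat softmax_cols(arma::mat z) {
  for (arma::uword j = 0; j < z.n_cols; ++j) {
    arma::vec col = z.col(j);
    col -= col.max();
    col = arma::exp(col);
    z.col(j) = col / arma::accu(col);
  }
  return z;
}

// flatten conv3 activations (12, 12, f3*B) to (144*f3) x B, channel-major
// per sample (index = c*144 + x*12 + y)
static arma::mat flatten_batch(const arma::cube& A, int C, int B) {
  arma::mat out(144 * (arma::uword)C, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      out.col(b).subvec((arma::uword)c * 144, (arma::uword)(c + 1) * 144 - 1) =
        arma::vectorise(A.slice((arma::uword)b * C + c));
  return out;
}

static arma::cube unflatten_batch(const arma::mat& V, int C, int B) {
  arma::cube out(12, 12, (arma::uword)C * B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      arma::vec v = V.col(b).subvec((arma::uword)c * 144,
                                    (arma::uword)(c + 1) * 144 - 1);
      out.slice((arma::uword)b * C + c) = arma::reshape(v, 12, 12);
    }
  return out;
}

// inference forward pass for a batch (running BN statistics)
// [[Rcpp::export(name = ".cpp_cnn_predict")]]
arma::mat cpp_cnn_predict(const arma::cube& X, const List& params) {
  arma::mat W1 = params["W1"], W2 = params["W2"], W3 = params["W3"],
            Wfc = params["Wfc"];
  arma::vec b1 = params["b1"], b2 = params["b2"], b3 = params["b3"],
            bfc = params["bfc"];
  arma::vec g1 = params["g1"], g2 = params["g2"], g3 = params["g3"];
  arma::vec t1 = params["beta1"], t2 = params["beta2"], t3 = params["beta3"];
  arma::vec rm1 = params["rm1"], rm2 = params["rm2"], rm3 = params["rm3"];
  arma::vec rv1 = params["rv1"], rv2 = params["rv2"], rv3 = params["rv3"];
  const int B = X.n_slices, nc = Wfc.n_rows;
  const int f1 = W1.n_rows, f2 = W2.n_rows, f3 = W3.n_rows;
  // process in chunks to bound memory on large validation sets
  const int chunk = 256;
  arma::mat probs(nc, B);
  arma::ucube pi;
  for (int start = 0; start < B; start += chunk) {
    int nb = std::min(chunk, B - start);
    arma::cube x(50, 50, nb);
    for (int b = 0; b < nb; ++b) x.slice(b) = X.slice(start + b);
    arma::mat col1 = im2col3_batch(x, 1, nb);
    arma::mat Y1 = W1 * col1;
    Y1.each_col() += b1;
    arma::cube a1 = unstack(Y1, 50, 50, f1, nb);
    bn_forward_infer(a1, f1, nb, g1, t1, rm1, rv1);
    relu_fwd(a1);
    arma::cube p1 = maxpool_batch(a1, pi);
    arma::mat col2 = im2col3_batch(p1, f1, nb);
    arma::mat Y2 = W2 * col2;
    Y2.each_col() += b2;
    arma::cube a2 = unstack(Y2, 25, 25, f2, nb);
    bn_forward_infer(a2, f2, nb, g2, t2, rm2, rv2);
    relu_fwd(a2);
    arma::cube p2 = maxpool_batch(crop_batch(a2, 24), pi);
    arma::mat col3 = im2col3_batch(p2, f2, nb);
    arma::mat Y3 = W3 * col3;
    Y3.each_col() += b3;
    arma::cube a3 = unstack(Y3, 12, 12, f3, nb);
    bn_forward_infer(a3, f3, nb, g3, t3, rm3, rv3);
    relu_fwd(a3);
    arma::mat flat = flatten_batch(a3, f3, nb);
    arma::mat logits = Wfc * flat;
    logits.each_col() += bfc;
    probs.cols(start, start + nb - 1) = softmax_cols(logits);
  }
  return probs;
}

// one SGDM step on a mini-batch; returns updated parameter/velocity lists
// plus the batch loss and accuracy. y is 0-based class index.
// [[Rcpp::export(name = ".cpp_cnn_train_batch")]]
List cpp_cnn_train_batch(const arma::cube& X, const arma::ivec& y,
                         List params, List vel, double lr, double momentum,
                         double l2, double bn_mom, int loss_type) {
  arma::mat W1 = params["W1"], W2 = params["W2"], W3 = params["W3"],
            Wfc = params["Wfc"];
  arma::vec b1 = params["b1"], b2 = params["b2"], b3 = params["b3"],
            bfc = params["bfc"];
  arma::vec g1 = params["g1"], g2 = params["g2"], g3 = params["g3"];
  arma::vec t1 = params["beta1"], t2 = params["beta2"], t3 = params["beta3"];
  arma::vec rm1 = params["rm1"], rm2 = params["rm2"], rm3 = params["rm3"];
  arma::vec rv1 = params["rv1"], rv2 = params["rv2"], rv3 = params["rv3"];

  const int B = X.n_slices, nc = Wfc.n_rows;
  const int f1 = W1.n_rows, f2 = W2.n_rows, f3 = W3.n_rows;

  // ---- forward ----
  arma::cube x(50, 50, B);
  for (int b = 0; b < B; ++b) x.slice(b) = X.slice(b);
  arma::mat col1 = im2col3_batch(x, 1, B);
  arma::mat Y1 = W1 * col1;
  Y1.each_col() += b1;
  arma::cube a1 = unstack(Y1, 50, 50, f1, B);
  BNCache c1, c2, c3;
  bn_forward_train(a1, f1, B, g1, t1, rm1, rv1, bn_mom, c1);
  relu_fwd(a1);
  arma::ucube pi1, pi2;
  arma::cube p1 = maxpool_batch(a1, pi1);
  arma::mat col2 = im2col3_batch(p1, f1, B);
  arma::mat Y2 = W2 * col2;
  Y2.each_col() += b2;
  arma::cube a2 = unstack(Y2, 25, 25, f2, B);
  bn_forward_train(a2, f2, B, g2, t2, rm2, rv2, bn_mom, c2);
  relu_fwd(a2);
  arma::cube p2 = maxpool_batch(crop_batch(a2, 24), pi2);
  arma::mat col3 = im2col3_batch(p2, f2, B);
  arma::mat Y3 = W3 * col3;
  Y3.each_col() += b3;
  arma::cube a3 = unstack(Y3, 12, 12, f3, B);
  bn_forward_train(a3, f3, B, g3, t3, rm3, rv3, bn_mom, c3);
  relu_fwd(a3);
  arma::mat flat = flatten_batch(a3, f3, B);
  arma::mat logits = Wfc * flat;
  logits.each_col() += bfc;
  arma::mat probs = softmax_cols(logits);

  // ---- loss + dlogits ----
  double loss = 0;
  int correct = 0;
  arma::mat dz(nc, B);
  for (int b = 0; b < B; ++b) {
    arma::vec p = probs.col(b);
    arma::vec t(nc, arma::fill::zeros);
    t((arma::uword)y(b)) = 1.0;
    arma::uword pred;
    p.max(pred);
    if ((int)pred == (int)y(b)) ++correct;
    if (loss_type == 0) { // cross-entropy
      loss += -std::log(std::max(p(y(b)), 1e-12));
      dz.col(b) = (p - t) / B;
    } else { // MSE on softmax outputs
      arma::vec d = p - t;
      loss += arma::dot(d, d) / nc;
      arma::vec dLdp = 2.0 * d / nc;
      dz.col(b) = (p % dLdp - p * arma::dot(p, dLdp)) / B;
    }
  }
  loss /= B;
  double acc = (double)correct / B;

  // ---- backward ----
  arma::mat dWfc = dz * flat.t();
  arma::vec dbfc = arma::sum(dz, 1);
  arma::cube d3 = unflatten_batch(Wfc.t() * dz, f3, B);
  relu_bwd(d3, a3);
  arma::vec dg3(f3, arma::fill::zeros), dt3(f3, arma::fill::zeros);
  bn_backward(d3, f3, B, c3, g3, dg3, dt3);
  arma::mat dY3 = restack(d3, f3, B);
  arma::mat dW3 = dY3 * col3.t();
  arma::vec db3 = arma::sum(dY3, 1);
  arma::cube dp2(12, 12, (arma::uword)f2 * B);
  col2im3_batch(W3.t() * dY3, dp2, f2, B);
  arma::cube da2crop = maxpool_back_batch(dp2, pi2, 24, 24);
  arma::cube da2(25, 25, (arma::uword)f2 * B, arma::fill::zeros);
  for (arma::uword s = 0; s < da2.n_slices; ++s)
    da2.slice(s).submat(0, 0, 23, 23) = da2crop.slice(s);
  relu_bwd(da2, a2);
  arma::vec dg2(f2, arma::fill::zeros), dt2(f2, arma::fill::zeros);
  bn_backward(da2, f2, B, c2, g2, dg2, dt2);
  arma::mat dY2 = restack(da2, f2, B);
  arma::mat dW2 = dY2 * col2.t();
  arma::vec db2 = arma::sum(dY2, 1);
  arma::cube dp1(25, 25, (arma::uword)f1 * B);
  col2im3_batch(W2.t() * dY2, dp1, f1, B);
  arma::cube da1 = maxpool_back_batch(dp1, pi1, 50, 50);
  relu_bwd(da1, a1);
  arma::vec dg1(f1, arma::fill::zeros), dt1(f1, arma::fill::zeros);
  bn_backward(da1, f1, B, c1, g1, dg1, dt1);
  arma::mat dY1 = restack(da1, f1, B);
  arma::mat dW1 = dY1 * col1.t();
  arma::vec db1 = arma::sum(dY1, 1);

  // ---- SGDM update: v <- m*v - lr*(g + l2*w); w <- w + v ----
  auto upd = [&](arma::mat& Wm, arma::mat& V, const arma::mat& G) {
    V = momentum * V - lr * (G + l2 * Wm);
    Wm += V;
  };
  auto updv = [&](arma::vec& w, arma::vec& V, const arma::vec& G) {
    V = momentum * V - lr * G;
    w += V;
  };
  arma::mat vW1 = vel["W1"], vW2 = vel["W2"], vW3 = vel["W3"],
            vWfc = vel["Wfc"];
  arma::vec vb1 = vel["b1"], vb2 = vel["b2"], vb3 = vel["b3"],
            vbfc = vel["bfc"];
  arma::vec vg1 = vel["g1"], vg2 = vel["g2"], vg3 = vel["g3"];
  arma::vec vt1 = vel["beta1"], vt2 = vel["beta2"], vt3 = vel["beta3"];
  upd(W1, vW1, dW1); upd(W2, vW2, dW2);
  upd(W3, vW3, dW3); upd(Wfc, vWfc, dWfc);
  updv(b1, vb1, db1); updv(b2, vb2, db2); updv(b3, vb3, db3);
  updv(bfc, vbfc, dbfc);
  updv(g1, vg1, dg1); updv(g2, vg2, dg2); updv(g3, vg3, dg3);
  updv(t1, vt1, dt1); updv(t2, vt2, dt2); updv(t3, vt3, dt3);

  List np = List::create(
    _["W1"] = W1, _["b1"] = b1, _["g1"] = g1, _["beta1"] = t1,
    _["rm1"] = rm1, _["rv1"] = rv1,
    _["W2"] = W2, _["b2"] = b2, _["g2"] = g2, _["beta2"] = t2,
    _["rm2"] = rm2, _["rv2"] = rv2,
    _["W3"] = W3, _["b3"] = b3, _["g3"] = g3, _["beta3"] = t3,
    _["rm3"] = rm3, _["rv3"] = rv3,
    _["Wfc"] = Wfc, _["bfc"] = bfc);
  List nv = List::create(
    _["W1"] = vW1, _["b1"] = vb1, _["g1"] = vg1, _["beta1"] = vt1,
    _["W2"] = vW2, _["b2"] = vb2, _["g2"] = vg2, _["beta2"] = vt2,
    _["W3"] = vW3, _["b3"] = vb3, _["g3"] = vg3, _["beta3"] = vt3,
    _["Wfc"] = vWfc, _["bfc"] = vbfc);
  return List::create(_["params"] = np, _["vel"] = nv, _["loss"] = loss,
                      _["acc"] = acc);
}

// Finalize batch-norm statistics: one forward pass over the full training
// set with the trained weights, normalizing each chunk by its own batch
// statistics (as during training) while accumulating the per-channel mean
// of the chunk means and variances. Running statistics collected during
// SGD lag the weights they are used with; inference uses these finalized
// population statistics instead.
// [[Rcpp::export(name = ".cpp_cnn_finalize_bn")]]
List cpp_cnn_finalize_bn(const arma::cube& X, List params, int chunk) {
  arma::mat W1 = params["W1"], W2 = params["W2"], W3 = params["W3"];
  arma::vec b1 = params["b1"], b2 = params["b2"], b3 = params["b3"];
  arma::vec g1 = params["g1"], g2 = params["g2"], g3 = params["g3"];
  arma::vec t1 = params["beta1"], t2 = params["beta2"], t3 = params["beta3"];
  const int B = X.n_slices;
  const int f1 = W1.n_rows, f2 = W2.n_rows, f3 = W3.n_rows;
  arma::vec m1(f1, arma::fill::zeros), v1(f1, arma::fill::zeros);
  arma::vec m2(f2, arma::fill::zeros), v2(f2, arma::fill::zeros);
  arma::vec m3(f3, arma::fill::zeros), v3(f3, arma::fill::zeros);
  int nchunks = 0;
  arma::ucube pi;
  for (int start = 0; start < B; start += chunk) {
    int nb = std::min(chunk, B - start);
    if (nb < 2) break; // batch statistics need more than one sample
    ++nchunks;
    arma::cube x(50, 50, nb);
    for (int b = 0; b < nb; ++b) x.slice(b) = X.slice(start + b);
    arma::vec rm(f1, arma::fill::zeros), rv(f1, arma::fill::ones);
    BNCache c;
    arma::mat Y1 = W1 * im2col3_batch(x, 1, nb);
    Y1.each_col() += b1;
    arma::cube a1 = unstack(Y1, 50, 50, f1, nb);
    bn_forward_train(a1, f1, nb, g1, t1, rm, rv, 1.0, c);
    m1 += rm; v1 += rv;
    relu_fwd(a1);
    arma::cube p1 = maxpool_batch(a1, pi);
    rm.zeros(f2); rv.ones(f2);
    arma::mat Y2 = W2 * im2col3_batch(p1, f1, nb);
    Y2.each_col() += b2;
    arma::cube a2 = unstack(Y2, 25, 25, f2, nb);
    bn_forward_train(a2, f2, nb, g2, t2, rm, rv, 1.0, c);
    m2 += rm; v2 += rv;
    relu_fwd(a2);
    arma::cube p2 = maxpool_batch(crop_batch(a2, 24), pi);
    rm.zeros(f3); rv.ones(f3);
    arma::mat Y3 = W3 * im2col3_batch(p2, f2, nb);
    Y3.each_col() += b3;
    arma::cube a3 = unstack(Y3, 12, 12, f3, nb);
    bn_forward_train(a3, f3, nb, g3, t3, rm, rv, 1.0, c);
    m3 += rm; v3 += rv;
  }
  if (nchunks > 0) {
    m1 /= nchunks; v1 /= nchunks;
    m2 /= nchunks; v2 /= nchunks;
    m3 /= nchunks; v3 /= nchunks;
    params["rm1"] = m1; params["rv1"] = v1;
    params["rm2"] = m2; params["rv2"] = v2;
    params["rm3"] = m3; params["rv3"] = v3;
  }
  return params;
}
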