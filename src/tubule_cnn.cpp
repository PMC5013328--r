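// Patch-level convolutional classifier: forward pass, cross-entropy
// gradients, and 8-connected component labelling for the nuclei detector.
//
// Layout conventions (shared with the R side):
//  - a batch of patches arrives as an R array (N, H, W, C), column-major;
//  - each conv block is valid convolution (stride 1) -> ReLU -> max pool
//    (non-overlapping, floor division; trailing rows/cols are dropped);
//  - conv weights are (K*K*C_in) x C_out matrices where the row index is
//    kr + kc*K + ch*K*K; biases are length C_out;
//  - the final feature map (Hp x Wp x C) is flattened column-major slice
//    by slice, then two fully connected layers end in a 2-way softmax.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Arch {
  std::vector<int> filt, kern, pool;
  int fc1 = 0, fc2 = 0;
};

Arch parse_arch(const IntegerMatrix& conv, const IntegerVector& fc) {
  Arch a;
  for (int i = 0; i < conv.nrow(); ++i) {
    a.filt.push_back(conv(i, 0));
    a.kern.push_back(conv(i, 1));
    a.pool.push_back(conv(i, 2));
  }
  if (fc.size() != 2) stop("exactly two fully connected widths expected");
  a.fc1 = fc[0];
  a.fc2 = fc[1];
  return a;
}

// extract sample n of an (N,H,W,C) array into a cube (H,W,C)
arma::cube sample_cube(const double* x, int n, int N, int H, int W, int C,
                       double scale) {
  arma::cube out(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        out(h, w, c) = x[n + (std::size_t)N * (h + (std::size_t)H * (w + (std::size_t)W * c))] / scale;
  return out;
}

void im2col(const arma::cube& x, int K, arma::mat& P) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H - K + 1, Wo = W - K + 1;
  P.set_size((std::size_t)Ho * Wo, (std::size_t)K * K * C);
  for (int ch = 0; ch < C; ++ch)
    for (int kc = 0; kc < K; ++kc)
      for (int kr = 0; kr < K; ++kr) {
        const std::size_t f = kr + (std::size_t)K * kc + (std::size_t)K * K * ch;
        for (int c = 0; c < Wo; ++c)
          for (int r = 0; r < Ho; ++r)
            P(r + (std::size_t)Ho * c, f) = x(r + kr, c + kc, ch);
      }
}

struct BlockCache {
  arma::mat P;       // im2col matrix
  arma::mat Z;       // pre-ReLU conv output, (Hc*Wc) x Cout
  arma::umat argmax; // (Hp*Wp) x Cout linear indices into the Hc*Wc plane
  int Hin = 0, Win = 0, Cin = 0, Hc = 0, Wc = 0, Hp = 0, Wp = 0, K = 0, pool = 0;
};

// one conv block forward; returns pooled activations as a cube
arma::cube block_forward(const arma::cube& x, const arma::mat& W,
                         const arma::vec& b, int K, int pool, BlockCache* cache) {
  const int Hin = x.n_rows, Win = x.n_cols, Cin = x.n_slices;
  const int Hc = Hin - K + 1, Wc = Win - K + 1;
  if (Hc < pool || Wc < pool) stop("feature map smaller than pool window");
  arma::mat P;
  im2col(x, K, P);
  arma::mat Z = P * W;             // (Hc*Wc) x Cout
  Z.each_row() += b.t();
  const int Cout = Z.n_cols;
  const int Hp = Hc / pool, Wp = Wc / pool;
  arma::cube out(Hp, Wp, Cout);
  arma::umat argmax;
  if (cache) argmax.set_size((std::size_t)Hp * Wp, Cout);
  for (int ch = 0; ch < Cout; ++ch) {
    for (int pc = 0; pc < Wp; ++pc)
      for (int pr = 0; pr < Hp; ++pr) {
        double best = -arma::datum::inf;
        std::size_t besti = 0;
        for (int dc = 0; dc < pool; ++dc)
          for (int dr = 0; dr < pool; ++dr) {
            const std::size_t idx = (pr * pool + dr) + (std::size_t)Hc * (pc * pool + dc);
            const double v = Z(idx, ch);
            if (v > best) { best = v; besti = idx; }
          }
        const double rect = best > 0.0 ? best : 0.0;  // ReLU commutes with max pool
        out(pr, pc, ch) = rect;
        if (cache) argmax(pr + (std::size_t)Hp * pc, ch) = besti;
      }
  }
  if (cache) {
    cache->P = std::move(P);
    cache->Z = std::move(Z);
    cache->argmax = std::move(argmax);
    cache->Hin = Hin; cache->Win = Win; cache->Cin = Cin;
    cache->Hc = Hc; cache->Wc = Wc; cache->Hp = Hp; cache->Wp = Wp;
    cache->K = K; cache->pool = pool;
  }
  return out;
}

arma::vec softmax2(const arma::vec& z) {
  const double m = z.max();
  arma::vec e = arma::exp(z - m);
  return e / arma::accu(e);
}

arma::vec flatten_cube(const arma::cube& x) {
  return arma::vectorise(x);
}

struct FCCache {
  arma::vec f, z1, a1, z2, p;
};

arma::vec fc_forward(const arma::cube& last, const arma::mat& W1, const arma::vec& b1,
                     const arma::mat& W2, const arma::vec& b2, FCCache* cache) {
  arma::vec f = flatten_cube(last);
  if (f.n_elem != W1.n_rows) stop("flattened feature length does not match fc weights");
  arma::vec z1 = W1.t() * f + b1;
  arma::vec a1 = arma::clamp(z1, 0.0, arma::datum::inf);
  arma::vec z2 = W2.t() * a1 + b2;
  arma::vec p = softmax2(z2);
  if (cache) { cache->f = f; cache->z1 = z1; cache->a1 = a1; cache->z2 = z2; cache->p = p; }
  return p;
}

} // namespace

// Forward pass over a batch. x: (N,H,W,C) array, values divided by `scale`
// before entering the network. Returns an N x 2 matrix of class
// probabilities (columns: non-tubule, tubule).
// [[Rcpp::export]]
NumericMatrix cpp_cnn_forward(NumericVector x, List weights,
                              IntegerMatrix conv, IntegerVector fc,
                              double scale = 255.0) {
  IntegerVector dims = x.attr("dim");
  if (dims.size() != 4) stop("patch array must have dim (N, H, W, C)");
  const int N = dims[0], H = dims[1], W = dims[2], C = dims[3];
  Arch a = parse_arch(conv, fc);
  const int nb = (int)a.filt.size();

  std::vector<arma::mat> Wc(nb);
  std::vector<arma::vec> bc(nb);
  for (int i = 0; i < nb; ++i) {
    Wc[i] = as<arma::mat>(weights[2 * i]);
    bc[i] = as<arma::vec>(weights[2 * i + 1]);
  }
  arma::mat W1 = as<arma::mat>(weights[2 * nb]);
  arma::vec b1 = as<arma::vec>(weights[2 * nb + 1]);
  arma::mat W2 = as<arma::mat>(weights[2 * nb + 2]);
  arma::vec b2 = as<arma::vec>(weights[2 * nb + 3]);

  NumericMatrix out(N, 2);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    arma::cube act = sample_cube(xp, n, N, H, W, C, scale);
    for (int i = 0; i < nb; ++i)
      act = block_forward(act, Wc[i], bc[i], a.kern[i], a.pool[i], nullptr);
    arma::vec p = fc_forward(act, W1, b1, W2, b2, nullptr);
    out(n, 0) = p[0];
    out(n, 1) = p[1];
  }
  return out;
}

// Weighted mean cross-entropy loss and its gradients over a batch.
// y: integer class labels, 0 = non-tubule, 1 = tubule.
// w: per-sample loss weights (all 1 for the unweighted mean).
// [[Rcpp::export]]
List cpp_cnn_loss_grad(NumericVector x, IntegerVector y, List weights,
                       IntegerMatrix conv, IntegerVector fc,
                       NumericVector w, double scale = 255.0) {
  IntegerVector dims = x.attr("dim");
  if (dims.size() != 4) stop("patch array must have dim (N, H, W, C)");
  const int N = dims[0], H = dims[1], W = dims[2], C = dims[3];
  if (y.size() != N) stop("labels and patches differ in length");
  if (w.size() != N) stop("weights and patches differ in length");
  Arch a = parse_arch(conv, fc);
  const int nb = (int)a.filt.size();

  std::vector<arma::mat> Wc(nb);
  std::vector<arma::vec> bc(nb);
  for (int i = 0; i < nb; ++i) {
    Wc[i] = as<arma::mat>(weights[2 * i]);
    bc[i] = as<arma::vec>(weights[2 * i + 1]);
  }
  arma::mat W1 = as<arma::mat>(weights[2 * nb]);
  arma::vec b1 = as<arma::vec>(weights[2 * nb + 1]);
  arma::mat W2 = as<arma::mat>(weights[2 * nb + 2]);
  arma::vec b2 = as<arma::vec>(weights[2 * nb + 3]);

  std::vector<arma::mat> dWc(nb);
  std::vector<arma::vec> dbc(nb);
  for (int i = 0; i < nb; ++i) {
    dWc[i].zeros(Wc[i].n_rows, Wc[i].n_cols);
    dbc[i].zeros(bc[i].n_elem);
  }
  arma::mat dW1(W1.n_rows, W1.n_cols, arma::fill::zeros);
  arma::vec db1(b1.n_elem, arma::fill::zeros);
  arma::mat dW2(W2.n_rows, W2.n_cols, arma::fill::zeros);
  arma::vec db2(b2.n_elem, arma::fill::zeros);

  double loss = 0.0;
  const double* xp = x.begin();
  std::vector<BlockCache> caches(nb);

  for (int n = 0; n < N; ++n) {
    arma::cube act = sample_cube(xp, n, N, H, W, C, scale);
    for (int i = 0; i < nb; ++i)
      act = block_forward(act, Wc[i], bc[i], a.kern[i], a.pool[i], &caches[i]);
    FCCache fcc;
    arma::vec p = fc_forward(act, W1, b1, W2, b2, &fcc);
    const int cls = y[n];
    if (cls < 0 || cls > 1) stop("labels must be 0 or 1");
    loss += -w[n] * std::log(std::max(p[cls], 1e-12));

    // fully connected backward
    arma::vec dz2 = fcc.p;
    dz2[cls] -= 1.0;
    dz2 *= w[n];
    dW2 += fcc.a1 * dz2.t();
    db2 += dz2;
    arma::vec da1 = W2 * dz2;
    arma::vec dz1 = da1 % arma::conv_to<arma::vec>::from(fcc.z1 > 0);
    dW1 += fcc.f * dz1.t();
    db1 += dz1;
    arma::vec df = W1 * dz1;

    // conv blocks backward
    // df corresponds to the flattened pooled output of the last block
    arma::vec dflat = df;
    for (int i = nb - 1; i >= 0; --i) {
      BlockCache& ck = caches[i];
      const int Cout = ck.Z.n_cols;
      const std::size_t npool = (std::size_t)ck.Hp * ck.Wp;
      // gradient w.r.t. the (post-ReLU) conv plane, routed through argmax
      arma::mat dZ(ck.Z.n_rows, Cout, arma::fill::zeros);
      for (int ch = 0; ch < Cout; ++ch)
        for (std::size_t pp = 0; pp < npool; ++pp) {
          const double g = dflat[pp + npool * ch];
          if (g != 0.0) dZ(ck.argmax(pp, ch), ch) += g;
        }
      // ReLU mask on the winning pre-activations
      dZ %= arma::conv_to<arma::mat>::from(ck.Z > 0);
      dWc[i] += ck.P.t() * dZ;
      dbc[i] += arma::sum(dZ, 0).t();
      if (i > 0) {
        arma::mat dP = dZ * Wc[i].t();  // (Hc*Wc) x (K*K*Cin)
        const int K = ck.K;
        arma::cube dX(ck.Hin, ck.Win, ck.Cin, arma::fill::zeros);
        for (int ch = 0; ch < ck.Cin; ++ch)
          for (int kc = 0; kc < K; ++kc)
            for (int kr = 0; kr < K; ++kr) {
              const std::size_t f = kr + (std::size_t)K * kc + (std::size_t)K * K * ch;
              for (int c = 0; c < ck.Wc; ++c)
                for (int r = 0; r < ck.Hc; ++r)
                  dX(r + kr, c + kc, ch) += dP(r + (std::size_t)ck.Hc * c, f);
            }
        dflat = arma::vectorise(dX);
      }
    }
  }

  const double nN = (double)N;
  List grads(2 * nb + 4);
  for (int i = 0; i < nb; ++i) {
    grads[2 * i] = wrap(dWc[i] / nN);
    grads[2 * i + 1] = wrap(dbc[i] / nN);
  }
  grads[2 * nb] = wrap(dW1 / nN);
  grads[2 * nb + 1] = wrap(db1 / nN);
  grads[2 * nb + 2] = wrap(dW2 / nN);
  grads[2 * nb + 3] = wrap(db2 / nN);
  return List::create(_["loss"] = loss / nN, _["grads"] = grads);
}

// 8-connected component labelling of a binary matrix (non-zero = foreground).
// Returns an integer matrix of component labels, 0 for background.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components8(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        const int rr = stack.back().first, cc = stack.back().second;
        stack.pop_back();
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            const int nr = rr + dr, nc = cc + dc;
            if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
            if (mask(nr, nc) != 0 && lab(nr, nc) == 0) {
              lab(nr, nc) = next;
              stack.push_back(std::make_pair(nr, nc));
            }
          }
      }
    }
  return lab;
}
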