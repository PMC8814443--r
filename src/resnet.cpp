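// Residual-network feature extractor: forward, backward and SGD training.
//
// Activations are stored channels x positions (C x N*H*W), position index
// p = b*H*W + j*H + i with i the fastest-varying (column-major image
// flattening, matching R's as.vector on a 64x64 matrix). Convolutions are
// im2col + single-precision GEMM. Batch normalization is per-channel
// (per-row) over all positions in the batch.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;

static const float BN_EPS = 1e-5f;

// ---------------------------------------------------------------- im2col

// 3x3 kernel, pad 1, arbitrary stride. Col is (9*C) x (N*oH*oW); the row
// block for kernel offset (di, dj) (each in 0..2) starts at (dj*3+di)*C.
static void im2col3(const fmat& X, int N, int H, int W, int stride,
                    fmat& Col, int& oH, int& oW) {
  const int C = X.n_rows;
  oH = (H + 2 - 3) / stride + 1;
  oW = (W + 2 - 3) / stride + 1;
  Col.zeros(9 * C, (size_t)N * oH * oW);
  for (int b = 0; b < N; b++) {
    const size_t ibase = (size_t)b * H * W, obase = (size_t)b * oH * oW;
    for (int dj = 0; dj < 3; dj++) {
      for (int di = 0; di < 3; di++) {
        const int roff = (dj * 3 + di) * C;
        for (int oj = 0; oj < oW; oj++) {
          const int jj = oj * stride - 1 + dj;
          if (jj < 0 || jj >= W) continue;
          // valid oi range: 0 <= oi*stride - 1 + di < H
          int oi0 = 0;
          while (oi0 * stride - 1 + di < 0) oi0++;
          int oi1 = oH - 1;
          while (oi1 * stride - 1 + di >= H) oi1--;
          for (int oi = oi0; oi <= oi1; oi++) {
            const int ii = oi * stride - 1 + di;
            std::memcpy(Col.colptr(obase + (size_t)oj * oH + oi) + roff,
                        X.colptr(ibase + (size_t)jj * H + ii),
                        C * sizeof(float));
          }
        }
      }
    }
  }
}

// scatter-add of dCol back onto dX (C x N*H*W)
static void col2im3(const fmat& dCol, int N, int H, int W, int stride,
                    int C, fmat& dX) {
  const int oH = (H + 2 - 3) / stride + 1, oW = (W + 2 - 3) / stride + 1;
  dX.zeros(C, (size_t)N * H * W);
  for (int b = 0; b < N; b++) {
    const size_t ibase = (size_t)b * H * W, obase = (size_t)b * oH * oW;
    for (int dj = 0; dj < 3; dj++) {
      for (int di = 0; di < 3; di++) {
        const int roff = (dj * 3 + di) * C;
        for (int oj = 0; oj < oW; oj++) {
          const int jj = oj * stride - 1 + dj;
          if (jj < 0 || jj >= W) continue;
          int oi0 = 0;
          while (oi0 * stride - 1 + di < 0) oi0++;
          int oi1 = oH - 1;
          while (oi1 * stride - 1 + di >= H) oi1--;
          for (int oi = oi0; oi <= oi1; oi++) {
            const int ii = oi * stride - 1 + di;
            float* dst = dX.colptr(ibase + (size_t)jj * H + ii);
            const float* src = dCol.colptr(obase + (size_t)oj * oH + oi) + roff;
            for (int c = 0; c < C; c++) dst[c] += src[c];
          }
        }
      }
    }
  }
}

// 1x1 convolution with stride (projection shortcut): column subsampling
static void subsample_cols(const fmat& X, int N, int H, int W, int stride,
                           fmat& S, int& oH, int& oW) {
  oH = (H + stride - 1) / stride;
  oW = (W + stride - 1) / stride;
  S.set_size(X.n_rows, (size_t)N * oH * oW);
  for (int b = 0; b < N; b++)
    for (int oj = 0; oj < oW; oj++)
      for (int oi = 0; oi < oH; oi++)
        S.col((size_t)b * oH * oW + (size_t)oj * oH + oi) =
          X.col((size_t)b * H * W + (size_t)(oj * stride) * H + oi * stride);
}

static void subsample_cols_back(const fmat& dS, int N, int H, int W,
                                int stride, fmat& dX) {
  const int oH = (H + stride - 1) / stride, oW = (W + stride - 1) / stride;
  dX.zeros(dS.n_rows, (size_t)N * H * W);
  for (int b = 0; b < N; b++)
    for (int oj = 0; oj < oW; oj++)
      for (int oi = 0; oi < oH; oi++)
        dX.col((size_t)b * H * W + (size_t)(oj * stride) * H + oi * stride) =
          dS.col((size_t)b * oH * oW + (size_t)oj * oH + oi);
}

// ---------------------------------------------------------------- batchnorm

struct BNParam { fvec gamma, beta, rmean, rvar; };
struct BNCache { fvec invstd; fmat xhat; };

static fmat bn_infer(const fmat& X, const BNParam& p) {
  fvec invstd = 1.0f / sqrt(p.rvar + BN_EPS);
  fmat Y = X.each_col() - p.rmean;
  Y.each_col() %= invstd % p.gamma;
  Y.each_col() += p.beta;
  return Y;
}

static fmat bn_train(const fmat& X, BNParam& p, BNCache& c, float mom) {
  const float P = (float)X.n_cols;
  fvec mu = mean(X, 1);
  fmat Xc = X.each_col() - mu;
  fvec v = mean(square(Xc), 1);  // biased
  c.invstd = 1.0f / sqrt(v + BN_EPS);
  c.xhat = Xc.each_col() % c.invstd;
  p.rmean = (1.0f - mom) * p.rmean + mom * mu;
  p.rvar = (1.0f - mom) * p.rvar + mom * v;
  (void)P;
  fmat Y = c.xhat.each_col() % p.gamma;
  Y.each_col() += p.beta;
  return Y;
}

static fmat bn_backward(const fmat& dY, const BNParam& p, const BNCache& c,
                        fvec& dgamma, fvec& dbeta) {
  const float P = (float)dY.n_cols;
  dbeta = sum(dY, 1);
  dgamma = sum(dY % c.xhat, 1);
  fmat dxhat = dY.each_col() % p.gamma;
  fvec s1 = sum(dxhat, 1);
  fvec s2 = sum(dxhat % c.xhat, 1);
  fmat dX = P * dxhat;
  dX.each_col() -= s1;
  dX -= c.xhat.each_col() % s2;
  dX.each_col() %= c.invstd / P;
  return dX;
}

// ---------------------------------------------------------------- network

struct Block {
  int in_ch, out_ch, stride;
  bool proj;
  fmat W1, W2, Wp;      // (9*Cin x C), (9*C x C), (Cin x C)
  BNParam bn1, bn2, bnp;
};

struct Net {
  fmat stemW;           // 9*in_ch x stem_filters
  BNParam stemBN;
  std::vector<Block> blocks;
  fmat fcW;             // feat_dim x n_classes
  fvec fcB;
  int in_ch, input_size;
};

static BNParam bn_from_list(const List& l, const std::string& pre) {
  BNParam p;
  p.gamma = Rcpp::as<fvec>(l[pre + "gamma"]);
  p.beta = Rcpp::as<fvec>(l[pre + "beta"]);
  p.rmean = Rcpp::as<fvec>(l[pre + "rmean"]);
  p.rvar = Rcpp::as<fvec>(l[pre + "rvar"]);
  return p;
}

static Net parse_net(const List& params) {
  Net net;
  List stem = params["stem"];
  net.stemW = Rcpp::as<fmat>(stem["W"]);
  net.stemBN = bn_from_list(stem, "");
  net.in_ch = Rcpp::as<int>(params["in_ch"]);
  net.input_size = Rcpp::as<int>(params["input_size"]);
  List blocks = params["blocks"];
  for (int i = 0; i < blocks.size(); i++) {
    List bl = blocks[i];
    Block b;
    b.in_ch = Rcpp::as<int>(bl["in_ch"]);
    b.out_ch = Rcpp::as<int>(bl["out_ch"]);
    b.stride = Rcpp::as<int>(bl["stride"]);
    b.proj = Rcpp::as<bool>(bl["proj"]);
    b.W1 = Rcpp::as<fmat>(bl["W1"]);
    b.bn1 = bn_from_list(bl, "bn1_");
    b.W2 = Rcpp::as<fmat>(bl["W2"]);
    b.bn2 = bn_from_list(bl, "bn2_");
    if (b.proj) {
      b.Wp = Rcpp::as<fmat>(bl["Wp"]);
      b.bnp = bn_from_list(bl, "bnp_");
    }
    net.blocks.push_back(b);
  }
  List fc = params["fc"];
  net.fcW = Rcpp::as<fmat>(fc["W"]);
  net.fcB = Rcpp::as<fvec>(fc["b"]);
  return net;
}

static void bn_to_list(const BNParam& p, List& l, const std::string& pre) {
  l[pre + "gamma"] = Rcpp::wrap(p.gamma);
  l[pre + "beta"] = Rcpp::wrap(p.beta);
  l[pre + "rmean"] = Rcpp::wrap(p.rmean);
  l[pre + "rvar"] = Rcpp::wrap(p.rvar);
}

static List net_to_list(const Net& net, const List& proto) {
  List out = Rcpp::clone(proto);
  List stem = out["stem"];
  stem["W"] = Rcpp::wrap(net.stemW);
  bn_to_list(net.stemBN, stem, "");
  out["stem"] = stem;
  List blocks = out["blocks"];
  for (size_t i = 0; i < net.blocks.size(); i++) {
    List bl = blocks[i];
    const Block& b = net.blocks[i];
    bl["W1"] = Rcpp::wrap(b.W1);
    bn_to_list(b.bn1, bl, "bn1_");
    bl["W2"] = Rcpp::wrap(b.W2);
    bn_to_list(b.bn2, bl, "bn2_");
    if (b.proj) {
      bl["Wp"] = Rcpp::wrap(b.Wp);
      bn_to_list(b.bnp, bl, "bnp_");
    }
    blocks[i] = bl;
  }
  out["blocks"] = blocks;
  List fc = out["fc"];
  fc["W"] = Rcpp::wrap(net.fcW);
  fc["b"] = Rcpp::wrap(net.fcB);
  out["fc"] = fc;
  return out;
}

// forward in inference mode; returns pooled features (feat_dim x N)
static fmat forward_features(const Net& net, const fmat& X0, int N) {
  int H = net.input_size, W = net.input_size, oH, oW;
  fmat Col;
  im2col3(X0, N, H, W, 2, Col, oH, oW);
  fmat A = net.stemW.t() * Col;
  A = bn_infer(A, net.stemBN);
  A.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  H = oH; W = oW;
  for (const Block& b : net.blocks) {
    fmat Sc;
    if (b.proj) {
      int sH, sW;
      fmat Sub;
      subsample_cols(A, N, H, W, b.stride, Sub, sH, sW);
      Sc = bn_infer(b.Wp.t() * Sub, b.bnp);
    } else if (b.stride > 1) {
      int sH, sW;
      subsample_cols(A, N, H, W, b.stride, Sc, sH, sW);
    } else {
      Sc = A;
    }
    im2col3(A, N, H, W, b.stride, Col, oH, oW);
    fmat Y = bn_infer(b.W1.t() * Col, b.bn1);
    Y.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    H = oH; W = oW;
    im2col3(Y, N, H, W, 1, Col, oH, oW);
    Y = bn_infer(b.W2.t() * Col, b.bn2);
    Y += Sc;
    Y.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    A = Y;
  }
  // global average pool
  const int C = A.n_rows, HW = H * W;
  fmat P(C, N);
  for (int b = 0; b < N; b++)
    P.col(b) = mean(A.cols((size_t)b * HW, (size_t)(b + 1) * HW - 1), 1);
  return P;
}

// [[Rcpp::export]]
arma::mat cpp_resnet_features(List params, arma::mat x, int n) {
  Net net = parse_net(params);
  fmat X0 = conv_to<fmat>::from(x);  // in_ch x (n * H * W)
  fmat P = forward_features(net, X0, n);
  return conv_to<mat>::from(P);
}

// [[Rcpp::export]]
arma::mat cpp_resnet_logits(List params, arma::mat x, int n) {
  Net net = parse_net(params);
  fmat X0 = conv_to<fmat>::from(x);
  fmat P = forward_features(net, X0, n);
  fmat L = net.fcW.t() * P;
  L.each_col() += net.fcB;
  return conv_to<mat>::from(L);
}

// ------------------------------------------------------------- training

struct BlockCache {
  fmat X, R1;        // block input; post-relu conv1 output
  fmat Out;          // block output (for relu mask)
  BNCache c1, c2, cp;
  int H, W;          // input spatial size
};

static fmat forward_train(Net& net, const fmat& X0, int N, float bn_mom,
                          fmat& stemIn, BNCache& stemC, fmat& stemOut,
                          std::vector<BlockCache>& caches,
                          int& Hout, int& Wout) {
  int H = net.input_size, W = net.input_size, oH, oW;
  fmat Col;
  stemIn = X0;
  im2col3(X0, N, H, W, 2, Col, oH, oW);
  fmat A = bn_train(net.stemW.t() * Col, net.stemBN, stemC, bn_mom);
  A.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  stemOut = A;
  H = oH; W = oW;
  caches.resize(net.blocks.size());
  for (size_t bi = 0; bi < net.blocks.size(); bi++) {
    Block& b = net.blocks[bi];
    BlockCache& cc = caches[bi];
    cc.X = A; cc.H = H; cc.W = W;
    fmat Sc;
    if (b.proj) {
      int sH, sW;
      fmat Sub;
      subsample_cols(A, N, H, W, b.stride, Sub, sH, sW);
      Sc = bn_train(b.Wp.t() * Sub, b.bnp, cc.cp, bn_mom);
    } else if (b.stride > 1) {
      int sH, sW;
      subsample_cols(A, N, H, W, b.stride, Sc, sH, sW);
    } else {
      Sc = A;
    }
    im2col3(A, N, H, W, b.stride, Col, oH, oW);
    fmat Y = bn_train(b.W1.t() * Col, b.bn1, cc.c1, bn_mom);
    Y.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    cc.R1 = Y;
    H = oH; W = oW;
    im2col3(Y, N, H, W, 1, Col, oH, oW);
    Y = bn_train(b.W2.t() * Col, b.bn2, cc.c2, bn_mom);
    Y += Sc;
    Y.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    cc.Out = Y;
    A = Y;
  }
  Hout = H; Wout = W;
  return A;
}

struct Grads {
  fmat stemW; fvec stem_g, stem_b;
  struct BG { fmat W1, W2, Wp; fvec g1, b1, g2, b2, gp, bp; };
  std::vector<BG> blocks;
  fmat fcW; fvec fcB;
};

// conv backward helper: input act Xin (C x P_in) at spatial (H, W),
// weights Wm (9C x F), upstream dY (F x P_out). Accumulates dW, returns dX.
static fmat conv_backward(const fmat& Xin, int N, int H, int W, int stride,
                          const fmat& Wm, const fmat& dY, fmat& dW) {
  fmat Col;
  int oH, oW;
  im2col3(Xin, N, H, W, stride, Col, oH, oW);
  dW = Col * dY.t();
  fmat dCol = Wm * dY;
  fmat dX;
  col2im3(dCol, N, H, W, stride, (int)Xin.n_rows, dX);
  return dX;
}

static void backward(Net& net, int N, const fmat& stemIn,
                     const BNCache& stemC, const fmat& stemOut,
                     std::vector<BlockCache>& caches,
                     int Hlast, int Wlast, const fmat& dPool,
                     Grads& g) {
  // dPool: C x N gradient at pooled features
  const int C = dPool.n_rows, HW = Hlast * Wlast;
  fmat dA(C, (size_t)N * HW);
  for (int b = 0; b < N; b++)
    dA.cols((size_t)b * HW, (size_t)(b + 1) * HW - 1) =
      repmat(dPool.col(b) / (float)HW, 1, HW);
  g.blocks.resize(net.blocks.size());
  for (int bi = (int)net.blocks.size() - 1; bi >= 0; bi--) {
    Block& b = net.blocks[bi];
    BlockCache& cc = caches[bi];
    Grads::BG& bg = g.blocks[bi];
    dA %= conv_to<fmat>::from(cc.Out > 0.0f);
    // main branch: bn2 <- conv2 <- relu <- bn1 <- conv1
    fmat dY2 = bn_backward(dA, b.bn2, cc.c2, bg.g2, bg.b2);
    int H1 = cc.H / b.stride + (cc.H % b.stride ? 1 : 0);
    int W1 = cc.W / b.stride + (cc.W % b.stride ? 1 : 0);
    fmat dR1 = conv_backward(cc.R1, N, H1, W1, 1, b.W2, dY2, bg.W2);
    dR1 %= conv_to<fmat>::from(cc.R1 > 0.0f);
    fmat dY1 = bn_backward(dR1, b.bn1, cc.c1, bg.g1, bg.b1);
    fmat dX = conv_backward(cc.X, N, cc.H, cc.W, b.stride, b.W1, dY1, bg.W1);
    // shortcut branch (dA is also the gradient at the shortcut output)
    if (b.proj) {
      fmat dSc = bn_backward(dA, b.bnp, cc.cp, bg.gp, bg.bp);
      int sH, sW;
      fmat Sub;
      subsample_cols(cc.X, N, cc.H, cc.W, b.stride, Sub, sH, sW);
      bg.Wp = Sub * dSc.t();
      fmat dSub = b.Wp * dSc;
      fmat dXs;
      subsample_cols_back(dSub, N, cc.H, cc.W, b.stride, dXs);
      dX += dXs;
    } else if (b.stride > 1) {
      fmat dXs;
      subsample_cols_back(dA, N, cc.H, cc.W, b.stride, dXs);
      dX += dXs;
    } else {
      dX += dA;
    }
    dA = dX;
  }
  dA %= conv_to<fmat>::from(stemOut > 0.0f);
  fmat dY0 = bn_backward(dA, net.stemBN, stemC, g.stem_g, g.stem_b);
  fmat dummy;
  conv_backward(stemIn, N, net.input_size, net.input_size, 2, net.stemW,
                dY0, g.stemW);
}

// [[Rcpp::export]]
List cpp_resnet_train(List params, arma::mat images, arma::ivec labels,
                      int epochs, int batch, arma::vec lr_per_epoch,
                      double momentum, double bn_momentum,
                      double weight_decay, int seed) {
  Net net = parse_net(params);
  const int N = images.n_cols;  // images: (H*W) x N, single channel
  const int HW = images.n_rows;
  const int K = net.fcW.n_cols;
  fmat imgs = conv_to<fmat>::from(images);
  std::mt19937 rng((unsigned)seed);
  std::vector<int> order(N);
  for (int i = 0; i < N; i++) order[i] = i;
  // momentum buffers
  Net vel = net;
  auto zero_bn = [](BNParam& p) { p.gamma.zeros(); p.beta.zeros();
                                  p.rmean.zeros(); p.rvar.zeros(); };
  vel.stemW.zeros(); zero_bn(vel.stemBN);
  for (Block& b : vel.blocks) {
    b.W1.zeros(); b.W2.zeros(); zero_bn(b.bn1); zero_bn(b.bn2);
    if (b.proj) { b.Wp.zeros(); zero_bn(b.bnp); }
  }
  vel.fcW.zeros(); vel.fcB.zeros();
  std::vector<double> loss_hist, acc_hist;
  const float mom = (float)momentum, wd = (float)weight_decay;
  for (int ep = 0; ep < epochs; ep++) {
    std::shuffle(order.begin(), order.end(), rng);
    const float lr = (float)lr_per_epoch[std::min<int>(ep, lr_per_epoch.n_elem - 1)];
    double ep_loss = 0.0; int ep_correct = 0, ep_n = 0;
    for (int start = 0; start < N; start += batch) {
      const int B = std::min(batch, N - start);
      fmat X0(1, (size_t)B * HW);
      ivec yb(B);
      for (int b = 0; b < B; b++) {
        X0.cols((size_t)b * HW, (size_t)(b + 1) * HW - 1) =
          imgs.col(order[start + b]).t();
        yb[b] = labels[order[start + b]];
      }
      fmat stemIn, stemOut;
      BNCache stemC;
      std::vector<BlockCache> caches;
      int Hl, Wl;
      fmat A = forward_train(net, X0, B, (float)bn_momentum, stemIn, stemC,
                             stemOut, caches, Hl, Wl);
      const int C = A.n_rows, HWl = Hl * Wl;
      fmat P(C, B);
      for (int b = 0; b < B; b++)
        P.col(b) = mean(A.cols((size_t)b * HWl, (size_t)(b + 1) * HWl - 1), 1);
      fmat L = net.fcW.t() * P;
      L.each_col() += net.fcB;
      // softmax cross-entropy
      fmat Sm = L;
      for (int b = 0; b < B; b++) {
        fvec col = Sm.col(b);
        col -= col.max();
        col = exp(col);
        col /= accu(col);
        Sm.col(b) = col;
        ep_loss += -std::log(std::max(1e-12f, col[yb[b]]));
        if ((int)col.index_max() == yb[b]) ep_correct++;
        ep_n++;
      }
      fmat dL = Sm;
      for (int b = 0; b < B; b++) dL(yb[b], b) -= 1.0f;
      dL /= (float)B;
      fmat dfcW = P * dL.t();
      fvec dfcB = sum(dL, 1);
      fmat dP = net.fcW * dL;
      Grads g;
      backward(net, B, stemIn, stemC, stemOut, caches, Hl, Wl, dP, g);
      // SGD with momentum (weight decay on conv/fc weights only)
      auto upd = [&](fmat& W, fmat& V, const fmat& G, bool decay) {
        V = mom * V + G + (decay ? wd * W : fmat(zeros<fmat>(W.n_rows, W.n_cols)));
        W -= lr * V;
      };
      auto updv = [&](fvec& w, fvec& v, const fvec& gr) {
        v = mom * v + gr;
        w -= lr * v;
      };
      upd(net.stemW, vel.stemW, g.stemW, true);
      updv(net.stemBN.gamma, vel.stemBN.gamma, g.stem_g);
      updv(net.stemBN.beta, vel.stemBN.beta, g.stem_b);
      for (size_t bi = 0; bi < net.blocks.size(); bi++) {
        Block& b = net.blocks[bi];
        Block& v = vel.blocks[bi];
        Grads::BG& bg = g.blocks[bi];
        upd(b.W1, v.W1, bg.W1, true);
        updv(b.bn1.gamma, v.bn1.gamma, bg.g1);
        updv(b.bn1.beta, v.bn1.beta, bg.b1);
        upd(b.W2, v.W2, bg.W2, true);
        updv(b.bn2.gamma, v.bn2.gamma, bg.g2);
        updv(b.bn2.beta, v.bn2.beta, bg.b2);
        if (b.proj) {
          upd(b.Wp, v.Wp, bg.Wp, true);
          updv(b.bnp.gamma, v.bnp.gamma, bg.gp);
          updv(b.bnp.beta, v.bnp.beta, bg.bp);
        }
      }
      upd(net.fcW, vel.fcW, dfcW, true);
      updv(net.fcB, vel.fcB, dfcB);
    }
    loss_hist.push_back(ep_loss / std::max(1, ep_n));
    acc_hist.push_back((double)ep_correct / std::max(1, ep_n));
  }
  return List::create(
    Rcpp::Named("params") = net_to_list(net, params),
    Rcpp::Named("loss") = loss_hist,
    Rcpp::Named("train_acc") = acc_hist);
}
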