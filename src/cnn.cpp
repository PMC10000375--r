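// Minimal CNN engine for the random-subspace ensemble: 3x3/s1/p1
// convolutions via im2col + GEMM, ReLU, 2x2/s2 max-pooling, fully connected
// layers, softmax cross-entropy, Adam.  Single precision; all randomness
// from an explicit std::mt19937 seed.
//
// Spatial activations are stored planar as fmat (H*W*B, C): column c holds
// plane c of every image in the batch (row index b*H*W + h*W + w), so
// im2col reduces to contiguous row copies per image row.  Dense activations
// are fmat (U, B).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

enum LayerKind { CONV = 0, RELU = 1, POOL = 2, FC = 3, SOFTMAX = 4 };

struct Layer {
  int kind = 0;
  int filters = 0;   // conv
  int units = 0;     // fc
  int inH = 0, inW = 0, inC = 0;
  int outH = 0, outW = 0, outC = 0;
  int inFlat = 0;
  bool flatten = false;   // fc consuming a spatial input
  bool dense = false;     // layer operates on (U, B) activations
};

struct Net {
  std::vector<Layer> layers;
  std::vector<fmat> W;
  std::vector<fvec> b;
  int inH, inW, inC, M;
};

static std::vector<Layer> parseArch(const List& arch, int inH, int inW,
                                    int inC) {
  List ls = arch["layers"];
  std::vector<Layer> layers;
  int h = inH, w = inW, c = inC, flat = -1;
  for (int i = 0; i < ls.size(); ++i) {
    List l = ls[i];
    std::string kind = as<std::string>(l["kind"]);
    Layer L;
    L.inH = h; L.inW = w; L.inC = c;
    L.dense = flat >= 0;
    if (kind == "conv") {
      L.kind = CONV;
      L.filters = as<int>(l["filters"]);
      L.outH = h; L.outW = w; L.outC = L.filters;  // 3x3, s1, p1
      c = L.filters;
    } else if (kind == "relu") {
      L.kind = RELU;
      L.outH = h; L.outW = w; L.outC = c;
      L.inFlat = flat;
    } else if (kind == "maxpool") {
      L.kind = POOL;
      L.outH = h / 2; L.outW = w / 2; L.outC = c;
      h /= 2; w /= 2;
    } else if (kind == "fc") {
      L.kind = FC;
      L.units = as<int>(l["units"]);
      if (flat < 0) { L.flatten = true; L.inFlat = h * w * c; }
      else L.inFlat = flat;
      flat = L.units;
    } else if (kind == "softmax") {
      L.kind = SOFTMAX;
      L.inFlat = flat;
      L.dense = true;
    } else {
      stop("unknown layer kind");
    }
    layers.push_back(L);
  }
  return layers;
}

static Net buildNet(const List& arch, const IntegerVector& inputShape,
                    const List& weights) {
  Net net;
  net.inH = inputShape[0]; net.inW = inputShape[1]; net.inC = inputShape[2];
  net.layers = parseArch(arch, net.inH, net.inW, net.inC);
  net.W.resize(net.layers.size());
  net.b.resize(net.layers.size());
  int wi = 0;
  for (size_t i = 0; i < net.layers.size(); ++i) {
    Layer& L = net.layers[i];
    if (L.kind == CONV || L.kind == FC) {
      if (wi >= weights.size()) stop("weights list too short");
      List p = weights[wi++];
      NumericMatrix Wm = p["W"];
      NumericVector bv = p["b"];
      fmat Wf(Wm.nrow(), Wm.ncol());
      for (int cc = 0; cc < Wm.ncol(); ++cc)
        for (int rr = 0; rr < Wm.nrow(); ++rr)
          Wf(rr, cc) = (float)Wm(rr, cc);
      net.W[i] = Wf;
      fvec bf(bv.size());
      for (int k = 0; k < bv.size(); ++k) bf(k) = (float)bv[k];
      net.b[i] = bf;
    }
  }
  net.M = net.layers.back().inFlat;
  return net;
}

// weight column layout for conv: c * 9 + (kr * 3 + kc)

static void im2col3(const fmat& A, int H, int W, int C, int B, fmat& K) {
  size_t HW = (size_t)H * W;
  K.set_size(HW * B, (size_t)C * 9);
  for (int c = 0; c < C; ++c) {
    const float* src0 = A.colptr(c);
    for (int kr = 0; kr < 3; ++kr) {
      int dr = kr - 1;
      for (int kc = 0; kc < 3; ++kc) {
        int dc = kc - 1;
        float* dst0 = K.colptr((size_t)c * 9 + kr * 3 + kc);
        for (int bb = 0; bb < B; ++bb) {
          const float* src = src0 + (size_t)bb * HW;
          float* dst = dst0 + (size_t)bb * HW;
          for (int h = 0; h < H; ++h) {
            float* drow = dst + (size_t)h * W;
            int hh = h + dr;
            if (hh < 0 || hh >= H) {
              std::memset(drow, 0, sizeof(float) * W);
              continue;
            }
            const float* srow = src + (size_t)hh * W;
            int lo = std::max(0, -dc), hi = std::min(W, W - dc);
            if (lo > 0) drow[0] = 0.0f;
            if (hi < W) drow[W - 1] = 0.0f;
            std::memcpy(drow + lo, srow + lo + dc, sizeof(float) * (hi - lo));
          }
        }
      }
    }
  }
}

static void col2im3(const fmat& dK, int H, int W, int C, int B, fmat& dA) {
  size_t HW = (size_t)H * W;
  dA.zeros(HW * B, C);
  for (int c = 0; c < C; ++c) {
    float* dst0 = dA.colptr(c);
    for (int kr = 0; kr < 3; ++kr) {
      int dr = kr - 1;
      for (int kc = 0; kc < 3; ++kc) {
        int dc = kc - 1;
        const float* src0 = dK.colptr((size_t)c * 9 + kr * 3 + kc);
        for (int bb = 0; bb < B; ++bb) {
          float* dst = dst0 + (size_t)bb * HW;
          const float* src = src0 + (size_t)bb * HW;
          for (int h = 0; h < H; ++h) {
            int hh = h + dr;
            if (hh < 0 || hh >= H) continue;
            const float* srow = src + (size_t)h * W;
            float* drow = dst + (size_t)hh * W;
            int lo = std::max(0, -dc), hi = std::min(W, W - dc);
            for (int w = lo; w < hi; ++w) drow[w + dc] += srow[w];
          }
        }
      }
    }
  }
}

struct Cache {
  std::vector<fmat> input;         // input activation per layer
  std::vector<fmat> colmat;        // im2col matrices for conv layers
  std::vector<arma::uvec> argmax;  // pool argmax (row index in input)
};

// forward pass; A0 is (HW*B, C).  Returns class probabilities (M, B).
static fmat forward(const Net& net, const fmat& A0, int B, Cache* cache) {
  fmat A = A0;
  if (cache) {
    cache->input.resize(net.layers.size());
    cache->colmat.resize(net.layers.size());
    cache->argmax.resize(net.layers.size());
  }
  for (size_t i = 0; i < net.layers.size(); ++i) {
    const Layer& L = net.layers[i];
    if (L.kind == CONV) {
      fmat K;
      im2col3(A, L.inH, L.inW, L.inC, B, K);
      A = K * net.W[i].t();
      A.each_row() += net.b[i].t();
      if (cache) cache->colmat[i] = std::move(K);
    } else if (L.kind == RELU) {
      if (cache) cache->input[i] = A;
      A.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    } else if (L.kind == POOL) {
      int H = L.inH, W = L.inW, C = L.inC;
      int oH = L.outH, oW = L.outW;
      size_t HW = (size_t)H * W, oHW = (size_t)oH * oW;
      fmat out(oHW * B, C);
      arma::uvec arg;
      if (cache) arg.set_size(oHW * B * C);
      for (int c = 0; c < C; ++c) {
        const float* src = A.colptr(c);
        float* dst = out.colptr(c);
        for (int bb = 0; bb < B; ++bb) {
          for (int oh = 0; oh < oH; ++oh) {
            const float* r0 = src + (size_t)bb * HW + (size_t)(2 * oh) * W;
            const float* r1 = r0 + W;
            float* drow = dst + (size_t)bb * oHW + (size_t)oh * oW;
            for (int ow = 0; ow < oW; ++ow) {
              int base = 2 * ow;
              float v = r0[base]; int k = 0;
              if (r0[base + 1] > v) { v = r0[base + 1]; k = 1; }
              if (r1[base] > v) { v = r1[base]; k = 2; }
              if (r1[base + 1] > v) { v = r1[base + 1]; k = 3; }
              drow[ow] = v;
              if (cache) {
                size_t srcRow = (size_t)bb * HW + (size_t)(2 * oh + k / 2) * W
                                + base + (k % 2);
                arg((size_t)c * oHW * B + (size_t)bb * oHW
                    + (size_t)oh * oW + ow) = srcRow;
              }
            }
          }
        }
      }
      A = std::move(out);
      if (cache) cache->argmax[i] = std::move(arg);
    } else if (L.kind == FC) {
      fmat X;
      if (L.flatten) {
        size_t HW = (size_t)L.inH * L.inW;
        int C = L.inC;
        X.set_size((size_t)HW * C, B);
        for (int bb = 0; bb < B; ++bb) {
          float* xc = X.colptr(bb);
          for (int c = 0; c < C; ++c) {
            std::memcpy(xc + (size_t)c * HW, A.colptr(c) + (size_t)bb * HW,
                        sizeof(float) * HW);
          }
        }
      } else {
        X = std::move(A);
      }
      if (cache) cache->input[i] = X;
      A = net.W[i] * X;
      A.each_col() += net.b[i];
    } else if (L.kind == SOFTMAX) {
      for (int bb = 0; bb < B; ++bb) {
        fvec col = A.col(bb);
        col -= col.max();
        col = arma::exp(col);
        A.col(bb) = col / arma::accu(col);
      }
    }
  }
  return A;
}

// backward from softmax-CE; labels 0-based
static void backward(const Net& net, const Cache& cache, const fmat& probs,
                     const std::vector<int>& yb, int B,
                     std::vector<fmat>& dW, std::vector<fvec>& db) {
  dW.assign(net.layers.size(), fmat());
  db.assign(net.layers.size(), fvec());
  fmat dA = probs;
  for (int bb = 0; bb < B; ++bb) dA(yb[bb], bb) -= 1.0f;
  dA /= (float)B;
  for (int i = (int)net.layers.size() - 1; i >= 0; --i) {
    const Layer& L = net.layers[i];
    if (L.kind == SOFTMAX) {
      continue;  // fused with the cross-entropy gradient above
    } else if (L.kind == FC) {
      const fmat& X = cache.input[i];
      dW[i] = dA * X.t();
      db[i] = arma::sum(dA, 1);
      fmat dX = net.W[i].t() * dA;
      if (L.flatten) {
        size_t HW = (size_t)L.inH * L.inW;
        int C = L.inC;
        fmat dSp((size_t)HW * B, C);
        for (int bb = 0; bb < B; ++bb) {
          const float* xc = dX.colptr(bb);
          for (int c = 0; c < C; ++c) {
            std::memcpy(dSp.colptr(c) + (size_t)bb * HW,
                        xc + (size_t)c * HW, sizeof(float) * HW);
          }
        }
        dA = std::move(dSp);
      } else {
        dA = std::move(dX);
      }
    } else if (L.kind == RELU) {
      const fmat& X = cache.input[i];
      const float* xp = X.memptr();
      float* dp = dA.memptr();
      size_t n = dA.n_elem;
      for (size_t k = 0; k < n; ++k) if (xp[k] <= 0.0f) dp[k] = 0.0f;
    } else if (L.kind == POOL) {
      const arma::uvec& arg = cache.argmax[i];
      int C = L.inC;
      size_t HW = (size_t)L.inH * L.inW;
      size_t oHW = (size_t)L.outH * L.outW;
      fmat dIn(HW * B, C, arma::fill::zeros);
      for (int c = 0; c < C; ++c) {
        const float* src = dA.colptr(c);
        float* dst = dIn.colptr(c);
        const arma::uword* ap = arg.memptr() + (size_t)c * oHW * B;
        for (size_t k = 0; k < oHW * B; ++k) dst[ap[k]] += src[k];
      }
      dA = std::move(dIn);
    } else if (L.kind == CONV) {
      const fmat& K = cache.colmat[i];
      dW[i] = (K.t() * dA).t();     // (Cout, C*9)
      db[i] = arma::sum(dA, 0).t();
      if (i == 0) continue;         // no gradient needed below the input
      fmat dK = dA * net.W[i];
      fmat dIn;
      col2im3(dK, L.inH, L.inW, L.inC, B, dIn);
      dA = std::move(dIn);
    }
  }
}

// Convert R array (H, W, C, N) slices to planar (HW*B, C)
static fmat batchToActivation(const double* xd, int H, int W, int C,
                              const std::vector<int>& idx) {
  int B = idx.size();
  size_t HW = (size_t)H * W;
  fmat A(HW * B, C);
  for (int bb = 0; bb < B; ++bb) {
    size_t base = (size_t)idx[bb] * HW * C;
    for (int c = 0; c < C; ++c) {
      float* dst = A.colptr(c) + (size_t)bb * HW;
      const double* src = xd + base + (size_t)c * HW;
      for (int h = 0; h < H; ++h) {
        for (int w = 0; w < W; ++w) {
          dst[(size_t)h * W + w] = (float)src[(size_t)w * H + h];
        }
      }
    }
  }
  return A;
}

// Gather a batch (row blocks) from a pre-converted dataset (HW*N, C).
static fmat gatherBatch(const fmat& all, size_t HW, int C,
                        const std::vector<int>& idx) {
  int B = idx.size();
  fmat A(HW * B, C);
  for (int c = 0; c < C; ++c) {
    float* dst = A.colptr(c);
    const float* src = all.colptr(c);
    for (int bb = 0; bb < B; ++bb) {
      std::memcpy(dst + (size_t)bb * HW, src + (size_t)idx[bb] * HW,
                  sizeof(float) * HW);
    }
  }
  return A;
}

static fmat datasetToPlanar(const NumericVector& x, int H, int W, int C,
                            int N) {
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  return batchToActivation(x.begin(), H, W, C, idx);
}

static List weightsToR(const Net& net) {
  List out;
  for (size_t i = 0; i < net.layers.size(); ++i) {
    if (net.layers[i].kind == CONV || net.layers[i].kind == FC) {
      NumericMatrix Wm(net.W[i].n_rows, net.W[i].n_cols);
      for (size_t cc = 0; cc < net.W[i].n_cols; ++cc)
        for (size_t rr = 0; rr < net.W[i].n_rows; ++rr)
          Wm(rr, cc) = net.W[i](rr, cc);
      NumericVector bv(net.b[i].n_elem);
      for (size_t k = 0; k < net.b[i].n_elem; ++k) bv[k] = net.b[i](k);
      out.push_back(List::create(Named("W") = Wm, Named("b") = bv));
    }
  }
  return out;
}

static void checkDims(const NumericVector& x, const Net& net, int* H, int* W,
                      int* C, int* N) {
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 4) stop("input must be a 4-D array (H, W, C, N)");
  *H = xd[0]; *W = xd[1]; *C = xd[2]; *N = xd[3];
  if (*H != net.inH || *W != net.inW || *C != net.inC)
    stop("input array does not match architecture input shape");
}

// [[Rcpp::export(name = ".cnnInit")]]
List cnnInit(List arch, IntegerVector inputShape, int seed) {
  std::vector<Layer> layers =
      parseArch(arch, inputShape[0], inputShape[1], inputShape[2]);
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<float> norm(0.0f, 1.0f);
  List out;
  for (size_t i = 0; i < layers.size(); ++i) {
    const Layer& L = layers[i];
    int rows = 0, cols = 0;
    if (L.kind == CONV) { rows = L.filters; cols = L.inC * 9; }
    else if (L.kind == FC) { rows = L.units; cols = L.inFlat; }
    else continue;
    float sd = std::sqrt(2.0f / (float)cols);   // He initialization
    NumericMatrix Wm(rows, cols);
    for (int cc = 0; cc < cols; ++cc)
      for (int rr = 0; rr < rows; ++rr)
        Wm(rr, cc) = sd * norm(rng);
    NumericVector bv(rows);  // zeros
    out.push_back(List::create(Named("W") = Wm, Named("b") = bv));
  }
  return out;
}

// [[Rcpp::export(name = ".cnnTrain")]]
List cnnTrain(NumericVector x, IntegerVector y, List arch,
              IntegerVector inputShape, List weights, int epochs,
              int batchSize, double lr, int seed) {
  Net net = buildNet(arch, inputShape, weights);
  int H, W, C, N;
  checkDims(x, net, &H, &W, &C, &N);
  size_t HW = (size_t)H * W;
  fmat all = datasetToPlanar(x, H, W, C, N);
  std::mt19937 rng((unsigned)seed);

  std::vector<fmat> mW(net.layers.size()), vW(net.layers.size());
  std::vector<fvec> mb(net.layers.size()), vb(net.layers.size());
  for (size_t i = 0; i < net.layers.size(); ++i) {
    if (!net.W[i].is_empty()) {
      mW[i].zeros(net.W[i].n_rows, net.W[i].n_cols);
      vW[i].zeros(net.W[i].n_rows, net.W[i].n_cols);
      mb[i].zeros(net.b[i].n_elem);
      vb[i].zeros(net.b[i].n_elem);
    }
  }
  const float b1 = 0.9f, b2 = 0.999f, epsA = 1e-8f;
  long step = 0;
  std::vector<int> perm(N);
  for (int i = 0; i < N; ++i) perm[i] = i;
  NumericVector lossHistory(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(perm.begin(), perm.end(), rng);
    double epochLoss = 0.0; long seen = 0;
    for (int start = 0; start < N; start += batchSize) {
      int B = std::min(batchSize, N - start);
      std::vector<int> idx(perm.begin() + start, perm.begin() + start + B);
      fmat A0 = gatherBatch(all, HW, C, idx);
      Cache cache;
      fmat probs = forward(net, A0, B, &cache);
      std::vector<int> yb(B);
      double loss = 0.0;
      for (int bb = 0; bb < B; ++bb) {
        yb[bb] = y[idx[bb]] - 1;
        loss += -std::log(std::max(probs(yb[bb], bb), 1e-12f));
      }
      if (!std::isfinite(loss))
        stop("non-finite training loss at epoch %d", ep + 1);
      epochLoss += loss; seen += B;
      std::vector<fmat> dW; std::vector<fvec> db;
      backward(net, cache, probs, yb, B, dW, db);
      ++step;
      float corr = std::sqrt(1.0f - std::pow(b2, (float)step)) /
                   (1.0f - std::pow(b1, (float)step));
      for (size_t i = 0; i < net.layers.size(); ++i) {
        if (net.W[i].is_empty()) continue;
        mW[i] = b1 * mW[i] + (1.0f - b1) * dW[i];
        vW[i] = b2 * vW[i] + (1.0f - b2) * arma::square(dW[i]);
        net.W[i] -= (float)lr * corr * mW[i] / (arma::sqrt(vW[i]) + epsA);
        mb[i] = b1 * mb[i] + (1.0f - b1) * db[i];
        vb[i] = b2 * vb[i] + (1.0f - b2) * arma::square(db[i]);
        net.b[i] -= (float)lr * corr * mb[i] / (arma::sqrt(vb[i]) + epsA);
      }
    }
    lossHistory[ep] = epochLoss / seen;
    Rcpp::checkUserInterrupt();
  }
  return List::create(Named("weights") = weightsToR(net),
                      Named("loss") = lossHistory);
}

// [[Rcpp::export(name = ".cnnPredict")]]
NumericMatrix cnnPredict(NumericVector x, List arch, IntegerVector inputShape,
                         List weights, int batchSize) {
  Net net = buildNet(arch, inputShape, weights);
  int H, W, C, N;
  checkDims(x, net, &H, &W, &C, &N);
  NumericMatrix out(N, net.M);
  for (int start = 0; start < N; start += batchSize) {
    int B = std::min(batchSize, N - start);
    std::vector<int> idx(B);
    for (int i = 0; i < B; ++i) idx[i] = start + i;
    fmat A0 = batchToActivation(x.begin(), H, W, C, idx);
    fmat probs = forward(net, A0, B, nullptr);
    for (int bb = 0; bb < B; ++bb)
      for (int m = 0; m < net.M; ++m) out(start + bb, m) = probs(m, bb);
  }
  return out;
}

// [[Rcpp::export(name = ".cnnLoss")]]
double cnnLoss(NumericVector x, IntegerVector y, List arch,
               IntegerVector inputShape, List weights) {
  Net net = buildNet(arch, inputShape, weights);
  int H, W, C, N;
  checkDims(x, net, &H, &W, &C, &N);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  fmat A0 = batchToActivation(x.begin(), H, W, C, idx);
  fmat probs = forward(net, A0, N, nullptr);
  double loss = 0.0;
  for (int bb = 0; bb < N; ++bb)
    loss += -std::log(std::max(probs(y[bb] - 1, bb), 1e-12f));
  return loss / N;
}

// [[Rcpp::export(name = ".cnnGrad")]]
List cnnGrad(NumericVector x, IntegerVector y, List arch,
             IntegerVector inputShape, List weights) {
  Net net = buildNet(arch, inputShape, weights);
  int H, W, C, N;
  checkDims(x, net, &H, &W, &C, &N);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  fmat A0 = batchToActivation(x.begin(), H, W, C, idx);
  Cache cache;
  fmat probs = forward(net, A0, N, &cache);
  std::vector<int> yb(N);
  for (int i = 0; i < N; ++i) yb[i] = y[i] - 1;
  std::vector<fmat> dW; std::vector<fvec> db;
  backward(net, cache, probs, yb, N, dW, db);
  List out;
  for (size_t i = 0; i < net.layers.size(); ++i) {
    if (net.W[i].is_empty()) continue;
    NumericMatrix Wm(dW[i].n_rows, dW[i].n_cols);
    for (size_t cc = 0; cc < dW[i].n_cols; ++cc)
      for (size_t rr = 0; rr < dW[i].n_rows; ++rr)
        Wm(rr, cc) = dW[i](rr, cc);
    NumericVector bv(db[i].n_elem);
    for (size_t k = 0; k < db[i].n_elem; ++k) bv[k] = db[i](k);
    out.push_back(List::create(Named("W") = Wm, Named("b") = bv));
  }
  return out;
}
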