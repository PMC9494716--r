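// Full forward/backward pass of the U-Net in one call, to keep all
// intermediates in C++.  The parameter list is flat, in construction
// order: encoder stages (conv_counts[s] convolutions each, then 2x2
// stride-2 max pooling, the last stage pooling by `bf`), two bottleneck
// convolutions, decoder stages from deepest to shallowest (upsample,
// channel-halving convolution, concatenation with the encoder skip, two
// convolutions), and a 1x1 classification head.  ReLU follows every
// convolution except the head.  The loss is mean per-pixel
// cross-entropy minus log of the soft Jaccard index averaged over
// foreground classes present in the truth.
#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Conv {
  mat W;    // (k*k*cin) x cout
  vec b;
  int k;
};

mat im2col3(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int half = (k - 1) / 2;
  mat A(H * W, k * k * C);
  for (int ch = 0; ch < C; ++ch)
    for (int dc = -half; dc <= half; ++dc)
      for (int dr = -half; dr <= half; ++dr) {
        const int col = (dr + half) + k * (dc + half) + k * k * ch;
        double* out = A.colptr(col);
        for (int c = 0; c < W; ++c) {
          const int cc = c + dc;
          if (cc < 0 || cc >= W) {
            std::fill(out + c * H, out + (c + 1) * H, 0.0);
            continue;
          }
          const double* src = x.slice_colptr(ch, cc);
          for (int r = 0; r < H; ++r) {
            const int rr = r + dr;
            out[c * H + r] = (rr < 0 || rr >= H) ? 0.0 : src[rr];
          }
        }
      }
  return A;
}

cube col2im3(const mat& dA, const int H, const int W, const int C,
             const int k) {
  const int half = (k - 1) / 2;
  cube dx(H, W, C, fill::zeros);
  for (int ch = 0; ch < C; ++ch)
    for (int dc = -half; dc <= half; ++dc)
      for (int dr = -half; dr <= half; ++dr) {
        const int col = (dr + half) + k * (dc + half) + k * k * ch;
        const double* g = dA.colptr(col);
        for (int c = 0; c < W; ++c) {
          const int cc = c + dc;
          if (cc < 0 || cc >= W) continue;
          double* dst = dx.slice_colptr(ch, cc);
          for (int r = 0; r < H; ++r) {
            const int rr = r + dr;
            if (rr >= 0 && rr < H) dst[rr] += g[c * H + r];
          }
        }
      }
  return dx;
}

struct ConvCache {
  mat A;      // im2col of the input
  cube y;     // post-ReLU output (raw logits for the head)
  int H, W, Cin;
};

cube conv_relu(const Conv& cv, const cube& x, ConvCache& cc,
               const bool relu) {
  const int H = x.n_rows, W = x.n_cols;
  cc.H = H; cc.W = W; cc.Cin = x.n_slices;
  cc.A = (cv.k == 1)
    ? mat(const_cast<double*>(x.memptr()), H * W, x.n_slices)
    : im2col3(x, cv.k);
  mat Y = cc.A * cv.W;
  Y.each_row() += cv.b.t();
  if (relu) Y.for_each([](double& v) { if (v < 0.0) v = 0.0; });
  cc.y = cube(Y.memptr(), H, W, cv.W.n_cols);
  return cc.y;
}

cube conv_relu_bwd(const Conv& cv, const ConvCache& cc, cube dy,
                   mat& dW, vec& db, const bool relu) {
  if (relu) {
    const double* yp = cc.y.memptr();
    double* dp = dy.memptr();
    for (uword i = 0; i < dy.n_elem; ++i)
      if (yp[i] <= 0.0) dp[i] = 0.0;
  }
  mat dY(dy.memptr(), cc.H * cc.W, dy.n_slices, false);
  dW = cc.A.t() * dY;
  db = sum(dY, 0).t();
  mat dA = dY * cv.W.t();
  return (cv.k == 1) ? cube(dA.memptr(), cc.H, cc.W, cc.Cin)
                     : col2im3(dA, cc.H, cc.W, cc.Cin, cv.k);
}

void pool2(const cube& x, cube& y, std::vector<int>& idx) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int h = H / 2, w = W / 2;
  y.set_size(h, w, C);
  idx.resize((size_t)h * w * C);
  size_t p = 0;
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < w; ++c)
      for (int r = 0; r < h; ++r) {
        double best = -datum::inf; int bi = 0;
        for (int dc = 0; dc < 2; ++dc)
          for (int dr = 0; dr < 2; ++dr) {
            const int rr = 2 * r + dr, cc2 = 2 * c + dc;
            const double v = x(rr, cc2, ch);
            if (v > best) { best = v; bi = rr + H * cc2 + H * W * ch; }
          }
        y(r, c, ch) = best;
        idx[p++] = bi;
      }
}

cube unpool2(const std::vector<int>& idx, const cube& dy,
             const int H, const int W) {
  cube dx(H, W, dy.n_slices, fill::zeros);
  const double* g = dy.memptr();
  double* d = dx.memptr();
  for (size_t i = 0; i < idx.size(); ++i) d[idx[i]] += g[i];
  return dx;
}

cube up_nn(const cube& x, const int f) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(H * f, W * f, C);
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < W * f; ++c)
      for (int r = 0; r < H * f; ++r)
        y(r, c, ch) = x(r / f, c / f, ch);
  return y;
}

cube up_nn_bwd(const cube& dy, const int f) {
  const int H = dy.n_rows / f, W = dy.n_cols / f, C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int ch = 0; ch < C; ++ch)
    for (int c = 0; c < W * f; ++c)
      for (int r = 0; r < H * f; ++r)
        dx(r / f, c / f, ch) += dy(r, c, ch);
  return dx;
}

std::vector<Conv> read_params(const Rcpp::List& params) {
  std::vector<Conv> out;
  for (int i = 0; i < params.size(); ++i) {
    Rcpp::List p = params[i];
    Conv cv;
    cv.W = Rcpp::as<mat>(p["W"]);
    cv.b = Rcpp::as<vec>(p["b"]);
    cv.k = Rcpp::as<int>(p["k"]);
    out.push_back(cv);
  }
  return out;
}

// shared forward; caches filled only when `train`
struct Net {
  std::vector<Conv> L;
  Rcpp::IntegerVector conv_counts;
  int depth, bf;
};

cube forward(const Net& net, const cube& x0, bool train,
             std::vector<ConvCache>& cc,
             std::vector<std::vector<std::vector<int>>>& pool_idx,
             std::vector<std::vector<std::pair<int,int>>>& pool_dims,
             std::vector<cube>& skips) {
  cube x = x0;
  ConvCache scratch;
  int li = 0;
  cc.resize(net.L.size());
  pool_idx.assign(net.depth, {});
  pool_dims.assign(net.depth, {});
  skips.assign(net.depth, cube());
  for (int s = 0; s < net.depth; ++s) {
    for (int j = 0; j < net.conv_counts[s]; ++j, ++li)
      x = conv_relu(net.L[li], x, train ? cc[li] : scratch, true);
    skips[s] = x;
    int f = (s == net.depth - 1) ? net.bf : 2;
    while (f > 1) {
      cube y; std::vector<int> idx;
      pool2(x, y, idx);
      pool_idx[s].push_back(std::move(idx));
      pool_dims[s].push_back({(int)x.n_rows, (int)x.n_cols});
      x = y;
      f /= 2;
    }
  }
  x = conv_relu(net.L[li], x, train ? cc[li] : scratch, true); ++li;
  x = conv_relu(net.L[li], x, train ? cc[li] : scratch, true); ++li;
  for (int s = net.depth - 1; s >= 0; --s) {
    int f = (s == net.depth - 1) ? net.bf : 2;
    cube u = up_nn(x, f);
    cube y = conv_relu(net.L[li], u, train ? cc[li] : scratch, true); ++li;
    cube z(y.n_rows, y.n_cols, y.n_slices + skips[s].n_slices);
    z.slices(0, y.n_slices - 1) = y;
    z.slices(y.n_slices, z.n_slices - 1) = skips[s];
    x = conv_relu(net.L[li], z, train ? cc[li] : scratch, true); ++li;
    x = conv_relu(net.L[li], x, train ? cc[li] : scratch, true); ++li;
  }
  return conv_relu(net.L[li], x, train ? cc[li] : scratch, false);
}

Net make_net(const Rcpp::List& params, const Rcpp::IntegerVector& conv_counts,
             const int depth, const int bf) {
  Net net;
  net.L = read_params(params);
  net.conv_counts = conv_counts;
  net.depth = depth;
  net.bf = bf;
  return net;
}

}  // namespace

// [[Rcpp::export(name = ".unet_infer")]]
arma::cube unet_infer(const Rcpp::List& params,
                      const Rcpp::IntegerVector& conv_counts,
                      const int depth, const int bf,
                      const arma::cube& x) {
  Net net = make_net(params, conv_counts, depth, bf);
  std::vector<ConvCache> cc;
  std::vector<std::vector<std::vector<int>>> pi;
  std::vector<std::vector<std::pair<int,int>>> pd;
  std::vector<cube> sk;
  return forward(net, x, false, cc, pi, pd, sk);
}

// [[Rcpp::export(name = ".unet_grad")]]
Rcpp::List unet_grad(const Rcpp::List& params,
                     const Rcpp::IntegerVector& conv_counts,
                     const int depth, const int bf,
                     const arma::cube& x,
                     const arma::imat& truth,  // 0-based classes
                     const double eps,
                     const bool include_background) {
  Net net = make_net(params, conv_counts, depth, bf);
  std::vector<ConvCache> cc;
  std::vector<std::vector<std::vector<int>>> pool_idx;
  std::vector<std::vector<std::pair<int,int>>> pool_dims;
  std::vector<cube> skips;
  cube logits = forward(net, x, true, cc, pool_idx, pool_dims, skips);

  const int H = logits.n_rows, W = logits.n_cols, K = logits.n_slices;
  const int n = H * W;
  // softmax
  mat P(n, K);
  {
    mat Z(logits.memptr(), n, K, false);
    for (int i = 0; i < n; ++i) {
      double m = Z(i, 0);
      for (int k = 1; k < K; ++k) m = std::max(m, Z(i, k));
      double s = 0.0;
      for (int k = 0; k < K; ++k) { P(i, k) = std::exp(Z(i, k) - m); s += P(i, k); }
      for (int k = 0; k < K; ++k) P(i, k) /= s;
    }
  }
  // cross-entropy and its softmax-shortcut gradient
  std::vector<int> t(n);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) t[r + c * H] = truth(r, c);
  double Hloss = 0.0;
  mat dZ(n, K, fill::zeros);
  for (int i = 0; i < n; ++i) {
    const double pt = std::max(P(i, t[i]), 1e-12);
    Hloss -= std::log(pt);
    for (int k = 0; k < K; ++k)
      dZ(i, k) = (P(i, k) - (k == t[i] ? 1.0 : 0.0)) / n;
  }
  Hloss /= n;
  // soft Jaccard over foreground classes present in the truth
  std::vector<int> cls;
  {
    std::vector<int> cnt(K, 0);
    for (int i = 0; i < n; ++i) ++cnt[t[i]];
    for (int k = include_background ? 0 : 1; k < K; ++k)
      if (cnt[k] > 0) cls.push_back(k);
  }
  double J = 1.0;
  if (!cls.empty()) {
    std::vector<double> S(cls.size(), 0.0), D(cls.size(), 0.0);
    for (size_t j = 0; j < cls.size(); ++j) {
      const int k = cls[j];
      double sp = 0.0, sy = 0.0, si = 0.0;
      for (int i = 0; i < n; ++i) {
        sp += P(i, k);
        if (t[i] == k) { sy += 1.0; si += P(i, k); }
      }
      S[j] = si;
      D[j] = sp + sy - si;
    }
    J = 0.0;
    for (size_t j = 0; j < cls.size(); ++j) J += (S[j] + eps) / (D[j] + eps);
    J /= cls.size();
    // chain -log(J) through p and the softmax
    mat G(n, K, fill::zeros);
    for (size_t j = 0; j < cls.size(); ++j) {
      const int k = cls[j];
      const double de = D[j] + eps, se = S[j] + eps;
      const double scale = -1.0 / (J * cls.size());
      for (int i = 0; i < n; ++i) {
        const double yi = (t[i] == k) ? 1.0 : 0.0;
        G(i, k) = scale * (yi * de - se * (1.0 - yi)) / (de * de);
      }
    }
    vec gp = sum(G % P, 1);
    dZ += P % (G.each_col() - gp);
  }
  const double L = Hloss - std::log(J);

  // backward
  cube dx(dZ.memptr(), H, W, K);
  const int nl = net.L.size();
  Rcpp::List gW(nl), gb(nl);
  int li = nl - 1;
  {
    mat dW; vec db;
    dx = conv_relu_bwd(net.L[li], cc[li], dx, dW, db, false);
    gW[li] = dW; gb[li] = db; --li;
  }
  std::vector<cube> dskip(depth);
  for (int s = 0; s < depth; ++s) {
    // decoder stages were appended for s = depth-1 .. 0; walking the
    // layer list backwards visits s = 0 first
    mat dW; vec db;
    dx = conv_relu_bwd(net.L[li], cc[li], dx, dW, db, true);
    gW[li] = dW; gb[li] = db; --li;
    cube dz = conv_relu_bwd(net.L[li], cc[li], dx, dW, db, true);
    gW[li] = dW; gb[li] = db; --li;
    const int ws = net.L[li].W.n_cols;  // dec s up: cout = widths[s]
    cube dy = dz.slices(0, ws - 1);
    dskip[s] = dz.slices(ws, dz.n_slices - 1);
    cube du = conv_relu_bwd(net.L[li], cc[li], dy, dW, db, true);
    gW[li] = dW; gb[li] = db; --li;
    const int f = (s == depth - 1) ? bf : 2;
    dx = up_nn_bwd(du, f);
  }
  {
    mat dW; vec db;
    dx = conv_relu_bwd(net.L[li], cc[li], dx, dW, db, true);
    gW[li] = dW; gb[li] = db; --li;
    dx = conv_relu_bwd(net.L[li], cc[li], dx, dW, db, true);
    gW[li] = dW; gb[li] = db; --li;
  }
  for (int s = depth - 1; s >= 0; --s) {
    for (int q = (int)pool_idx[s].size() - 1; q >= 0; --q)
      dx = unpool2(pool_idx[s][q], dx, pool_dims[s][q].first,
                   pool_dims[s][q].second);
    dx += dskip[s];
    for (int j = conv_counts[s] - 1; j >= 0; --j, --li) {
      mat dW; vec db;
      dx = conv_relu_bwd(net.L[li], cc[li], dx, dW, db, true);
      gW[li] = dW; gb[li] = db;
    }
  }
  return Rcpp::List::create(Rcpp::Named("L") = L,
                            Rcpp::Named("H") = Hloss,
                            Rcpp::Named("J") = J,
                            Rcpp::Named("dW") = gW,
                            Rcpp::Named("db") = gb);
}
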