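// Two-channel VGG-style regression CNN: 13 conv layers (3x3, pad 1) in
// five blocks with 2x2 max-pooling, three fully connected layers (last one
// 128 units = the perceptive features) and a linear 5-unit head regressing
// the quantified BI-RADS descriptor codes. Single precision, im2col+GEMM,
// Adam. All randomness comes from R's RNG so set.seed() governs init,
// shuffling and dropout.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

struct Arch {
  int S;                     // input side, divisible by 32
  int Cin;                   // input channels (2)
  std::vector<int> widths;   // 13 conv output widths
  std::vector<int> fc;       // 3 fc widths, last = feature dim
  int out_dim;               // regression head width (5)
};

static Arch parse_arch(const List& arch) {
  Arch a;
  a.S = as<int>(arch["input_side"]);
  a.Cin = as<int>(arch["in_channels"]);
  a.widths = as<std::vector<int>>(arch["conv_widths"]);
  a.fc = as<std::vector<int>>(arch["fc_sizes"]);
  a.out_dim = as<int>(arch["output_dim"]);
  if (a.widths.size() != 13) stop("need 13 conv widths");
  if (a.fc.size() != 3) stop("need 3 fc sizes");
  if (a.S % 32 != 0) stop("input side must be divisible by 32");
  return a;
}

// pooling happens after conv layers 2, 4, 7, 10, 13 (1-based)
static const bool POOL_AFTER[13] = {false,true,false,true,false,false,true,
                                    false,false,true,false,false,true};

struct Net {
  std::vector<fmat> Wc, bc;  // conv: (Cout x 9*Cin), (Cout x 1)
  std::vector<fmat> Wf, bf;  // fc
  fmat Wh, bh;               // head
};

static Net net_from_list(const List& w) {
  Net n;
  for (int l = 0; l < 13; ++l) {
    n.Wc.push_back(arma::conv_to<fmat>::from(as<arma::mat>(w["Wc" + std::to_string(l + 1)])));
    n.bc.push_back(arma::conv_to<fmat>::from(as<arma::mat>(w["bc" + std::to_string(l + 1)])));
  }
  for (int l = 0; l < 3; ++l) {
    n.Wf.push_back(arma::conv_to<fmat>::from(as<arma::mat>(w["Wf" + std::to_string(l + 1)])));
    n.bf.push_back(arma::conv_to<fmat>::from(as<arma::mat>(w["bf" + std::to_string(l + 1)])));
  }
  n.Wh = arma::conv_to<fmat>::from(as<arma::mat>(w["Wh"]));
  n.bh = arma::conv_to<fmat>::from(as<arma::mat>(w["bh"]));
  return n;
}

static List net_to_list(const Net& n) {
  List w;
  for (int l = 0; l < 13; ++l) {
    w["Wc" + std::to_string(l + 1)] = arma::conv_to<arma::mat>::from(n.Wc[l]);
    w["bc" + std::to_string(l + 1)] = arma::conv_to<arma::mat>::from(n.bc[l]);
  }
  for (int l = 0; l < 3; ++l) {
    w["Wf" + std::to_string(l + 1)] = arma::conv_to<arma::mat>::from(n.Wf[l]);
    w["bf" + std::to_string(l + 1)] = arma::conv_to<arma::mat>::from(n.bf[l]);
  }
  w["Wh"] = arma::conv_to<arma::mat>::from(n.Wh);
  w["bh"] = arma::conv_to<arma::mat>::from(n.bh);
  return w;
}

// ---- layer primitives ------------------------------------------------

// Activations are fmat (C, H*W*B) with pixel p = j*H + i, samples stacked.
// im2col row layout: row = roff * C + c (channel blocks contiguous, so each
// kernel-offset block copies as one memcpy per pixel).
static void im2col_fm(const fmat& A, int H, int W, int B, fmat& cols) {
  const int C = A.n_rows;
  cols.set_size(9 * C, (arma::uword)H * W * B);
  for (int b = 0; b < B; ++b) {
    const arma::uword base = (arma::uword)b * H * W;
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        const int roff = ky * 3 + kx;
        for (int j = 0; j < W; ++j) {
          const int jj = j + kx - 1;
          const bool jin = (jj >= 0 && jj < W);
          for (int i = 0; i < H; ++i) {
            const int ii = i + ky - 1;
            const arma::uword col = base + (arma::uword)j * H + i;
            float* dst = cols.colptr(col) + (arma::uword)roff * C;
            if (jin && ii >= 0 && ii < H) {
              const float* src = A.colptr(base + (arma::uword)jj * H + ii);
              std::memcpy(dst, src, C * sizeof(float));
            } else {
              std::memset(dst, 0, C * sizeof(float));
            }
          }
        }
      }
  }
}

static void col2im_fm(const fmat& dcols, int H, int W, int B, fmat& dA) {
  const int C = dcols.n_rows / 9;
  dA.zeros(C, (arma::uword)H * W * B);
  for (int b = 0; b < B; ++b) {
    const arma::uword base = (arma::uword)b * H * W;
    for (int ky = 0; ky < 3; ++ky)
      for (int kx = 0; kx < 3; ++kx) {
        const int roff = ky * 3 + kx;
        for (int j = 0; j < W; ++j) {
          const int jj = j + kx - 1;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int ii = i + ky - 1;
            if (ii < 0 || ii >= H) continue;
            const arma::uword col = base + (arma::uword)j * H + i;
            const float* src = dcols.colptr(col) + (arma::uword)roff * C;
            float* dst = dA.colptr(base + (arma::uword)jj * H + ii);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
  }
}

static fmat maxpool(const fmat& A, int H, int W, int B, arma::umat& argidx) {
  const int C = A.n_rows, H2 = H / 2, W2 = W / 2;
  fmat out(C, (arma::uword)H2 * W2 * B);
  argidx.set_size(C, (arma::uword)H2 * W2 * B);
  for (int b = 0; b < B; ++b) {
    const arma::uword base = (arma::uword)b * H * W;
    const arma::uword obase = (arma::uword)b * H2 * W2;
    for (int j2 = 0; j2 < W2; ++j2)
      for (int i2 = 0; i2 < H2; ++i2) {
        const arma::uword oc = obase + (arma::uword)j2 * H2 + i2;
        const arma::uword p[4] = {
          base + (arma::uword)(2 * j2) * H + 2 * i2,
          base + (arma::uword)(2 * j2) * H + 2 * i2 + 1,
          base + (arma::uword)(2 * j2 + 1) * H + 2 * i2,
          base + (arma::uword)(2 * j2 + 1) * H + 2 * i2 + 1};
        for (int c = 0; c < C; ++c) {
          float best = A(c, p[0]); arma::uword bi = p[0];
          for (int k = 1; k < 4; ++k)
            if (A(c, p[k]) > best) { best = A(c, p[k]); bi = p[k]; }
          out(c, oc) = best; argidx(c, oc) = bi;
        }
      }
  }
  return out;
}

static void maxpool_back(const fmat& dout, const arma::umat& argidx,
                         int C, arma::uword ncol_in, fmat& dA) {
  dA.zeros(C, ncol_in);
  for (arma::uword oc = 0; oc < dout.n_cols; ++oc)
    for (int c = 0; c < C; ++c) dA(c, argidx(c, oc)) += dout(c, oc);
}

// ---- forward / backward ----------------------------------------------

struct FwdCache {
  std::vector<fmat> conv_cols;   // im2col inputs per conv layer
  std::vector<fmat> conv_act;    // post-ReLU (pre-pool) activations
  std::vector<arma::umat> pool_arg;
  std::vector<int> Hs;           // spatial side at each conv layer input
  fmat fc_in;                    // flattened conv output (D x B)
  std::vector<fmat> fc_act;      // post-ReLU (post-dropout) fc activations
  std::vector<fmat> drop_mask;   // dropout masks for fc1, fc2
  fmat feats;                    // fc3 activations (features)
  fmat head;                     // head output
};

static void forward(const Net& net, const Arch& a, const fmat& X0, int B,
                    bool training, double dropout, FwdCache& cc) {
  fmat A = X0;                  // (Cin, S*S*B)
  int H = a.S;
  cc.conv_cols.clear(); cc.conv_act.clear(); cc.pool_arg.clear(); cc.Hs.clear();
  cc.fc_act.clear(); cc.drop_mask.clear();
  for (int l = 0; l < 13; ++l) {
    cc.Hs.push_back(H);
    fmat cols;
    im2col_fm(A, H, H, B, cols);
    fmat Z = net.Wc[l] * cols;
    Z.each_col() += net.bc[l].col(0);
    Z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    if (training) cc.conv_cols.push_back(std::move(cols));
    if (POOL_AFTER[l]) {
      arma::umat arg;
      fmat P = maxpool(Z, H, H, B, arg);
      if (training) { cc.conv_act.push_back(std::move(Z)); cc.pool_arg.push_back(std::move(arg)); }
      A = std::move(P);
      H /= 2;
    } else {
      if (training) { cc.conv_act.push_back(Z); cc.pool_arg.push_back(arma::umat()); }
      A = std::move(Z);
    }
  }
  // flatten: per sample, vectorise the (C x HW) block column-major
  const int C = a.widths[12];
  const int HW = H * H;
  const int D = C * HW;
  cc.fc_in.set_size(D, B);
  for (int b = 0; b < B; ++b) {
    const fmat blk = A.cols((arma::uword)b * HW, (arma::uword)(b + 1) * HW - 1);
    cc.fc_in.col(b) = arma::vectorise(blk);
  }
  fmat F = cc.fc_in;
  for (int l = 0; l < 3; ++l) {
    F = net.Wf[l] * F;
    F.each_col() += net.bf[l].col(0);
    F.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    if (l < 2) {                      // dropout after fc1, fc2 only
      if (training && dropout > 0) {
        fmat mask(F.n_rows, F.n_cols);
        const float keep = 1.0f - (float)dropout;
        for (arma::uword k = 0; k < mask.n_elem; ++k)
          mask(k) = (R::unif_rand() < keep) ? 1.0f / keep : 0.0f;
        F %= mask;
        cc.drop_mask.push_back(std::move(mask));
      } else {
        cc.drop_mask.push_back(fmat());
      }
    }
    cc.fc_act.push_back(F);
  }
  cc.feats = cc.fc_act[2];
  cc.head = net.Wh * cc.feats;
  cc.head.each_col() += net.bh.col(0);
}

struct Grads {
  std::vector<fmat> Wc, bc, Wf, bf;
  fmat Wh, bh;
};

static void backward(const Net& net, const Arch& a, const fmat& Y, int B,
                     FwdCache& cc, Grads& g) {
  g.Wc.assign(13, fmat()); g.bc.assign(13, fmat());
  g.Wf.assign(3, fmat()); g.bf.assign(3, fmat());
  // MSE loss: mean over samples of mean over out_dim
  fmat dH = (cc.head - Y) * (2.0f / (float)(a.out_dim * B));
  g.Wh = dH * cc.feats.t();
  g.bh = arma::sum(dH, 1);
  fmat dF = net.Wh.t() * dH;
  for (int l = 2; l >= 0; --l) {
    dF %= arma::conv_to<fmat>::from(cc.fc_act[l] > 0);
    // note: fc_act already includes dropout scaling; relu mask on the
    // post-dropout activation equals the pre-dropout mask where kept
    const fmat& in = (l == 0) ? cc.fc_in : cc.fc_act[l - 1];
    g.Wf[l] = dF * in.t();
    g.bf[l] = arma::sum(dF, 1);
    if (l > 0) {
      dF = net.Wf[l].t() * dF;
      if (cc.drop_mask[l - 1].n_elem > 0) dF %= cc.drop_mask[l - 1];
    }
  }
  fmat dIn = net.Wf[0].t() * dF;
  // unflatten
  const int C = a.widths[12];
  const int Hlast = cc.Hs[12] / (POOL_AFTER[12] ? 2 : 1);
  const int HW = Hlast * Hlast;
  fmat dA(C, (arma::uword)HW * B);
  for (int b = 0; b < B; ++b)
    dA.cols((arma::uword)b * HW, (arma::uword)(b + 1) * HW - 1) =
      arma::reshape(dIn.col(b), C, HW);
  for (int l = 12; l >= 0; --l) {
    const int H = cc.Hs[l];
    if (POOL_AFTER[l]) {
      fmat dZ;
      maxpool_back(dA, cc.pool_arg[l], cc.conv_act[l].n_rows,
                   cc.conv_act[l].n_cols, dZ);
      dA = std::move(dZ);
    }
    {
      const float* act = cc.conv_act[l].memptr();
      float* gd = dA.memptr();
      for (arma::uword k = 0; k < dA.n_elem; ++k)
        if (act[k] <= 0.0f) gd[k] = 0.0f;
    }
    g.Wc[l] = dA * cc.conv_cols[l].t();
    g.bc[l] = arma::sum(dA, 1);
    if (l > 0) {
      fmat dcols = net.Wc[l].t() * dA;
      col2im_fm(dcols, H, H, B, dA);
    }
  }
}

// ---- Adam -------------------------------------------------------------

struct Adam {
  std::vector<fmat> m, v;
  long t = 0;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  void init(const std::vector<fmat*>& params) {
    for (auto* p : params) {
      m.push_back(fmat(p->n_rows, p->n_cols, arma::fill::zeros));
      v.push_back(fmat(p->n_rows, p->n_cols, arma::fill::zeros));
    }
  }
  void step(std::vector<fmat*>& params, std::vector<fmat*>& grads, double lr) {
    ++t;
    const double bc1 = 1.0 - std::pow(b1, (double)t);
    const double bc2 = 1.0 - std::pow(b2, (double)t);
    for (size_t k = 0; k < params.size(); ++k) {
      fmat& g = *grads[k];
      m[k] = (float)b1 * m[k] + (float)(1 - b1) * g;
      v[k] = (float)b2 * v[k] + (float)(1 - b2) * (g % g);
      fmat mh = m[k] / (float)bc1;
      fmat vh = v[k] / (float)bc2;
      *params[k] -= (float)lr * (mh / (arma::sqrt(vh) + (float)eps));
    }
  }
};

static std::vector<fmat*> param_ptrs(Net& n) {
  std::vector<fmat*> p;
  for (auto& W : n.Wc) p.push_back(&W);
  for (auto& b : n.bc) p.push_back(&b);
  for (auto& W : n.Wf) p.push_back(&W);
  for (auto& b : n.bf) p.push_back(&b);
  p.push_back(&n.Wh); p.push_back(&n.bh);
  return p;
}

static std::vector<fmat*> grad_ptrs(Grads& g) {
  std::vector<fmat*> p;
  for (auto& W : g.Wc) p.push_back(&W);
  for (auto& b : g.bc) p.push_back(&b);
  for (auto& W : g.Wf) p.push_back(&W);
  for (auto& b : g.bf) p.push_back(&b);
  p.push_back(&g.Wh); p.push_back(&g.bh);
  return p;
}

// ---- batch assembly ---------------------------------------------------

// X: numeric array (S, S, Cin, n) column-major from R
static fmat make_batch(const NumericVector& X, const Arch& a,
                       const std::vector<int>& idx) {
  const int SS = a.S * a.S;
  const int per = SS * a.Cin;
  fmat A(a.Cin, (arma::uword)SS * idx.size());
  const double* xp = X.begin();
  for (size_t b = 0; b < idx.size(); ++b) {
    const double* base = xp + (arma::uword)per * idx[b];
    for (int c = 0; c < a.Cin; ++c)
      for (int p = 0; p < SS; ++p)
        A(c, (arma::uword)b * SS + p) = (float)base[c * SS + p];
  }
  return A;
}

static double eval_mse(const Net& net, const Arch& a, const NumericVector& X,
                       const NumericMatrix& Y, int batch) {
  const int n = Y.nrow();
  double se = 0.0;
  FwdCache cc;
  for (int s = 0; s < n; s += batch) {
    const int e = std::min(n, s + batch);
    std::vector<int> idx;
    for (int i = s; i < e; ++i) idx.push_back(i);
    fmat Xb = make_batch(X, a, idx);
    forward(net, a, Xb, (int)idx.size(), false, 0.0, cc);
    for (size_t b = 0; b < idx.size(); ++b)
      for (int k = 0; k < a.out_dim; ++k) {
        const double d = cc.head(k, b) - Y(idx[b], k);
        se += d * d;
      }
  }
  return se / ((double)n * a.out_dim);
}

// ---- exported functions ----------------------------------------------

// [[Rcpp::export]]
List cpp_cnn_init(List arch, std::string scheme) {
  Arch a = parse_arch(arch);
  Net n;
  int cin = a.Cin;
  for (int l = 0; l < 13; ++l) {
    const int fan_in = 9 * cin;
    const double sd = (scheme == "paper_normal") ? 1.0 : std::sqrt(2.0 / fan_in);
    fmat W(a.widths[l], fan_in);
    for (arma::uword k = 0; k < W.n_elem; ++k) W(k) = (float)(R::norm_rand() * sd);
    n.Wc.push_back(W);
    n.bc.push_back(fmat(a.widths[l], 1, arma::fill::zeros));
    cin = a.widths[l];
  }
  int d = a.widths[12] * (a.S / 32) * (a.S / 32);
  for (int l = 0; l < 3; ++l) {
    const double sd = (scheme == "paper_normal") ? 1.0 : std::sqrt(2.0 / d);
    fmat W(a.fc[l], d);
    for (arma::uword k = 0; k < W.n_elem; ++k) W(k) = (float)(R::norm_rand() * sd);
    n.Wf.push_back(W);
    n.bf.push_back(fmat(a.fc[l], 1, arma::fill::zeros));
    d = a.fc[l];
  }
  const double sdh = (scheme == "paper_normal") ? 1.0 : std::sqrt(1.0 / d);
  fmat Wh(a.out_dim, d);
  for (arma::uword k = 0; k < Wh.n_elem; ++k) Wh(k) = (float)(R::norm_rand() * sdh);
  n.Wh = Wh;
  n.bh = fmat(a.out_dim, 1, arma::fill::zeros);
  return net_to_list(n);
}

// [[Rcpp::export]]
List cpp_cnn_train(NumericVector X, NumericMatrix Y, List weights, List arch,
                   NumericVector lr_per_epoch, int batch_size, double dropout,
                   Nullable<NumericVector> Xval, Nullable<NumericMatrix> Yval) {
  Arch a = parse_arch(arch);
  Net net = net_from_list(weights);
  const int n = Y.nrow();
  const int epochs = lr_per_epoch.size();
  Adam opt;
  {
    auto ps = param_ptrs(net);
    opt.init(ps);
  }
  NumericVector tr_mse(epochs), va_mse(epochs, NA_REAL);
  const bool has_val = Xval.isNotNull() && Yval.isNotNull();
  NumericVector Xv; NumericMatrix Yv;
  if (has_val) { Xv = Xval.get(); Yv = Yval.get(); }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  FwdCache cc; Grads g;
  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double se = 0.0;
    const double lr = lr_per_epoch[ep];
    for (int s = 0; s < n; s += batch_size) {
      const int e = std::min(n, s + batch_size);
      std::vector<int> idx(order.begin() + s, order.begin() + e);
      const int B = (int)idx.size();
      fmat Xb = make_batch(X, a, idx);
      fmat Yb(a.out_dim, B);
      for (int b = 0; b < B; ++b)
        for (int k = 0; k < a.out_dim; ++k) Yb(k, b) = (float)Y(idx[b], k);
      forward(net, a, Xb, B, true, dropout, cc);
      const fmat diff = cc.head - Yb;
      const double batch_se = arma::accu(arma::conv_to<arma::mat>::from(diff % diff));
      if (!std::isfinite(batch_se))
        stop("divergence error: non-finite loss at epoch %d", ep + 1);
      se += batch_se;
      backward(net, a, Yb, B, cc, g);
      auto ps = param_ptrs(net);
      auto gs = grad_ptrs(g);
      opt.step(ps, gs, lr);
    }
    tr_mse[ep] = se / ((double)n * a.out_dim);
    if (has_val) va_mse[ep] = eval_mse(net, a, Xv, Yv, batch_size);
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = net_to_list(net),
                      _["train_mse"] = tr_mse,
                      _["val_mse"] = va_mse,
                      _["lr"] = lr_per_epoch);
}

// [[Rcpp::export]]
List cpp_cnn_forward(NumericVector X, int n, List weights, List arch) {
  Arch a = parse_arch(arch);
  Net net = net_from_list(weights);
  const int batch = 16;
  NumericMatrix feats(n, a.fc[2]), head(n, a.out_dim);
  FwdCache cc;
  for (int s = 0; s < n; s += batch) {
    const int e = std::min(n, s + batch);
    std::vector<int> idx;
    for (int i = s; i < e; ++i) idx.push_back(i);
    fmat Xb = make_batch(X, a, idx);
    forward(net, a, Xb, (int)idx.size(), false, 0.0, cc);
    for (size_t b = 0; b < idx.size(); ++b) {
      for (int k = 0; k < a.fc[2]; ++k) feats(idx[b], k) = cc.feats(k, b);
      for (int k = 0; k < a.out_dim; ++k) head(idx[b], k) = cc.head(k, b);
    }
  }
  return List::create(_["features"] = feats, _["head"] = head);
}
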