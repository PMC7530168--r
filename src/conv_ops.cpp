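// Convolution primitives for the connectome CNN.
//
// The frozen backbone forward pass runs in single precision (the standard
// numeric type of convolutional networks) via im2col + SGEMM; the small
// trainable layers get double-precision im2col/col2im/maxpool primitives and
// are assembled in R on top of BLAS matrix products.
//
// Activation layout convention (shared with the R code): a batch activation
// is a (B*H*W) x C matrix; rows are grouped by sample, within a sample
// column-major spatial order (row index fastest).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// single-sample im2col for a 3x3 same-padding kernel: (H*W) x (9*C)
static fmat im2col3_f(const fmat& x, const int H, const int W) {
  const int C = x.n_cols, Hp = H + 2, Wp = W + 2;
  fmat xp(Hp * Wp, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const float* src = x.colptr(c);
    float* dst = xp.colptr(c);
    for (int j = 0; j < W; ++j)
      std::memcpy(dst + (j + 1) * Hp + 1, src + j * H, H * sizeof(float));
  }
  fmat out(H * W, 9 * C);
  int k = 0;
  for (int dj = -1; dj <= 1; ++dj)
    for (int di = -1; di <= 1; ++di, ++k)
      for (int c = 0; c < C; ++c) {
        const float* src = xp.colptr(c);
        float* dst = out.colptr(k * C + c);
        for (int j = 0; j < W; ++j)
          std::memcpy(dst + j * H, src + (j + 1 + dj) * Hp + 1 + di,
                      H * sizeof(float));
      }
  return out;
}

static fmat maxpool2_f(const fmat& x, const int H, const int W) {
  const int C = x.n_cols, Ho = H / 2, Wo = W / 2;
  fmat out(Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const float* src = x.colptr(c);
    float* dst = out.colptr(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const float* a = src + (2 * j) * H + 2 * i;
        const float* b = src + (2 * j + 1) * H + 2 * i;
        dst[j * Ho + i] = std::max(std::max(a[0], a[1]),
                                   std::max(b[0], b[1]));
      }
  }
  return out;
}

// Frozen backbone forward for a batch of inputs.
// input: (H0*W0) x C0 x B cube; Ws[l]: (9*Cin) x Cout; pool_after: 1-based
// conv-layer indices followed by 2x2/stride-2 max pooling.
// Returns a (Hf*Wf*Cf) x B matrix of flattened feature maps (column-major
// spatial within channel blocks, i.e. columns of the final (Hf*Wf) x Cf
// activation stacked).
// [[Rcpp::export]]
arma::mat backbone_forward_batch(const arma::cube& input, Rcpp::List Ws,
                                 Rcpp::List bs,
                                 Rcpp::IntegerVector pool_after,
                                 const int H0, const int W0) {
  const int L = Ws.size(), B = input.n_slices;
  std::vector<fmat> W(L);
  std::vector<frowvec> bias(L);
  for (int l = 0; l < L; ++l) {
    W[l] = conv_to<fmat>::from(Rcpp::as<arma::mat>(Ws[l]));
    bias[l] = conv_to<frowvec>::from(Rcpp::as<arma::vec>(bs[l]));
  }
  std::set<int> pools(pool_after.begin(), pool_after.end());
  mat out;
  for (int s = 0; s < B; ++s) {
    fmat x = conv_to<fmat>::from(input.slice(s));
    int H = H0, Wd = W0;
    for (int l = 0; l < L; ++l) {
      fmat z = im2col3_f(x, H, Wd) * W[l];
      z.each_row() += bias[l];
      z.transform([](float v) { return v > 0.f ? v : 0.f; });
      x = std::move(z);
      if (pools.count(l + 1)) { x = maxpool2_f(x, H, Wd); H /= 2; Wd /= 2; }
    }
    if (s == 0) out.set_size(x.n_elem, B);
    out.col(s) = conv_to<vec>::from(vectorise(x));
  }
  return out;
}

// ---- double-precision primitives for the trainable layers ----

// batched im2col, 3x3 same padding: X is (B*H*W) x C -> (B*H*W) x (9*C)
// [[Rcpp::export]]
arma::mat im2col3_batch(const arma::mat& X, const int B, const int H,
                        const int W) {
  const int C = X.n_cols, HW = H * W, Hp = H + 2, Wp = W + 2;
  mat out(B * HW, 9 * C);
  mat xp(Hp * Wp, C);
  for (int s = 0; s < B; ++s) {
    xp.zeros();
    for (int c = 0; c < C; ++c) {
      const double* src = X.colptr(c) + s * HW;
      double* dst = xp.colptr(c);
      for (int j = 0; j < W; ++j)
        std::memcpy(dst + (j + 1) * Hp + 1, src + j * H, H * sizeof(double));
    }
    int k = 0;
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di, ++k)
        for (int c = 0; c < C; ++c) {
          const double* src = xp.colptr(c);
          double* dst = out.colptr(k * C + c) + s * HW;
          for (int j = 0; j < W; ++j)
            std::memcpy(dst + j * H, src + (j + 1 + dj) * Hp + 1 + di,
                        H * sizeof(double));
        }
  }
  return out;
}

// adjoint of im2col3_batch: scatter-add G (B*H*W) x (9*C) back to
// (B*H*W) x C
// [[Rcpp::export]]
arma::mat col2im3_batch(const arma::mat& G, const int B, const int H,
                        const int W) {
  const int C = G.n_cols / 9, HW = H * W, Hp = H + 2, Wp = W + 2;
  mat out(B * HW, C, fill::zeros);
  mat acc(Hp * Wp, C);
  for (int s = 0; s < B; ++s) {
    acc.zeros();
    int k = 0;
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di, ++k)
        for (int c = 0; c < C; ++c) {
          const double* src = G.colptr(k * C + c) + s * HW;
          double* dst = acc.colptr(c);
          for (int j = 0; j < W; ++j) {
            double* d = dst + (j + 1 + dj) * Hp + 1 + di;
            const double* g = src + j * H;
            for (int i = 0; i < H; ++i) d[i] += g[i];
          }
        }
    for (int c = 0; c < C; ++c) {
      const double* src = acc.colptr(c);
      double* dst = out.colptr(c) + s * HW;
      for (int j = 0; j < W; ++j)
        std::memcpy(dst + j * H, src + (j + 1) * Hp + 1, H * sizeof(double));
    }
  }
  return out;
}

// batched 2x2 stride-2 max pooling; returns pooled values and 1-based argmax
// row indices into the input matrix
// [[Rcpp::export]]
Rcpp::List maxpool2_batch(const arma::mat& X, const int B, const int H,
                          const int W) {
  const int C = X.n_cols, Ho = H / 2, Wo = W / 2, HW = H * W,
            HWo = Ho * Wo;
  mat out(B * HWo, C);
  imat arg(B * HWo, C);
  for (int c = 0; c < C; ++c)
    for (int s = 0; s < B; ++s) {
      const double* src = X.colptr(c) + s * HW;
      double* dst = out.colptr(c) + s * HWo;
      sword* am = arg.colptr(c) + s * HWo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          int base = (2 * j) * H + 2 * i;
          int cand[4] = {base, base + 1, base + H, base + H + 1};
          int best = cand[0];
          for (int t = 1; t < 4; ++t)
            if (src[cand[t]] > src[best]) best = cand[t];
          dst[j * Ho + i] = src[best];
          am[j * Ho + i] = s * HW + best + 1;  // 1-based row in X
        }
    }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("argmax") = arg);
}

// backward of maxpool2_batch: route dOut rows to argmax positions
// [[Rcpp::export]]
arma::mat maxpool2_backward(const arma::mat& dOut, const arma::imat& argmax,
                            const int n_in_rows) {
  mat dX(n_in_rows, dOut.n_cols, fill::zeros);
  for (uword c = 0; c < dOut.n_cols; ++c) {
    const double* g = dOut.colptr(c);
    const sword* am = argmax.colptr(c);
    double* d = dX.colptr(c);
    for (uword r = 0; r < dOut.n_rows; ++r) d[am[r] - 1] += g[r];
  }
  return dX;
}

// in-place Adam parameter update with bias-correction constants
// c1 = 1/(1-beta1^t), c2 = 1/(1-beta2^t); operates directly on the R
// arrays (callers own them exclusively; snapshots are deep-copied)
// [[Rcpp::export]]
void adam_update(Rcpp::NumericVector param, Rcpp::NumericVector m,
                 Rcpp::NumericVector v, Rcpp::NumericVector g,
                 const double lr, const double beta1, const double beta2,
                 const double c1, const double c2, const double eps,
                 const double wd) {
  const R_xlen_t n = param.size();
  double* p = param.begin();
  double* mm = m.begin();
  double* vv = v.begin();
  const double* gg = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = gg[i] + wd * p[i];  // L2 penalty folded in
    mm[i] = beta1 * mm[i] + (1 - beta1) * gi;
    vv[i] = beta2 * vv[i] + (1 - beta2) * gi * gi;
    p[i] -= lr * (mm[i] * c1) / (std::sqrt(vv[i] * c2) + eps);
  }
}
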