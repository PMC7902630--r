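// Minimal 2D conv-net kernels for slice-wise segmentation networks.
// Tensors are R double arrays in (H, W, C, N) layout; conv weights (k, k, Cin, Cout).
// Internally float32: GEMM via Armadillo (im2col), which dominates training cost.
#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
// Large im2col buffers are allocated and released once per layer call; keep
// them on the heap free lists instead of returning pages to the kernel.
__attribute__((constructor)) static void cascadeseg_tune_malloc() {
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
}
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Persistent per-layer scratch buffers: the im2col matrix, GEMM output and
// input-gradient scratch of every layer live in slots that are reused across
// training steps, so the steady state performs no large allocations.
// Single-threaded by design.
static std::vector<arma::fmat> g_pool, g_ybuf, g_xbuf;

static arma::fmat &slot_of(std::vector<arma::fmat> &v, int slot) {
  if (slot < 0) stop("invalid buffer slot");
  if ((size_t)slot >= v.size()) v.resize(slot + 1);
  return v[slot];
}
static arma::fmat &pool_buf(int slot) { return slot_of(g_pool, slot); }
static arma::fmat &y_buf(int slot) { return slot_of(g_ybuf, slot); }
static arma::fmat &x_buf(int slot) { return slot_of(g_xbuf, slot); }

// [[Rcpp::export]]
void nn_release_buffers() {
  for (auto *v : {&g_pool, &g_ybuf, &g_xbuf}) {
    v->clear();
    v->shrink_to_fit();
  }
}

static inline void get_dim4(const NumericVector &x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d (H, W, C, N) array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// im2col for "same" zero padding, odd kernel k (1 or 3 in practice).
// Rows: h + H*(w + W*n); cols: dh + k*(dw + k*c)  -- matches (k,k,Cin,Cout) weight layout.
static void im2col_same(arma::fmat &M, const double *x, int H, int W, int C,
                        int N, int k) {
  const int pad = (k - 1) / 2;
  const arma::uword HW = (arma::uword)H * W;
  M.set_size((arma::uword)H * W * N, (arma::uword)k * k * C);
  if (k > 1) M.zeros();
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const arma::uword col = dh + k * (dw + k * c);
        for (int n = 0; n < N; ++n) {
          const double *xs = x + ((arma::uword)n * C + c) * HW;
          float *Mc = M.colptr(col) + (arma::uword)n * HW;
          for (int w = 0; w < W; ++w) {
            const int wi = w + dw - pad;
            if (wi < 0 || wi >= W) continue;
            const int h0 = std::max(0, pad - dh), h1 = std::min(H, H + pad - dh);
            const double *src = xs + (arma::uword)wi * H;
            float *dst = Mc + (arma::uword)w * H;
            for (int h = h0; h < h1; ++h) dst[h] = (float)src[h + dh - pad];
          }
        }
      }
    }
  }
}

// Forward convolution; the im2col matrix is kept in the pool slot so the
// backward pass (or the next inference batch of the same shape) reuses it.
// [[Rcpp::export]]
NumericVector nn_conv2d_fw_pool(NumericVector x, NumericVector w,
                                NumericVector b, int slot) {
  int xd[4], wd[4];
  get_dim4(x, xd); get_dim4(w, wd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], F = wd[3];
  if (wd[2] != C) stop("conv2d: weight Cin does not match input channels");
  arma::fmat &M = pool_buf(slot);
  im2col_same(M, REAL(x), H, W, C, N, k);
  arma::fmat Wm((arma::uword)k * k * C, F);
  { const double *wp = REAL(w); for (arma::uword i = 0; i < Wm.n_elem; ++i) Wm(i) = (float)wp[i]; }
  arma::fmat &Y = y_buf(slot);
  Y.set_size(M.n_rows, F);
  Y = M * Wm;
  const arma::uword HW = (arma::uword)H * W;
  NumericVector out((R_xlen_t)HW * F * N);
  out.attr("dim") = IntegerVector::create(H, W, F, N);
  double *op = REAL(out);
  const double *bp = REAL(b);
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f) {
      const float *yc = Y.colptr(f) + (arma::uword)n * HW;
      double *oc = op + ((arma::uword)n * F + f) * HW;
      const double bf = bp[f];
      for (arma::uword i = 0; i < HW; ++i) oc[i] = (double)yc[i] + bf;
    }
  return out;
}

// Backward convolution from the pooled im2col matrix of the forward pass.
// The slot buffer is overwritten with the column gradient (it is consumed).
// With need_dx = false only the weight/bias gradients are computed.
// [[Rcpp::export]]
List nn_conv2d_bw_pool(int slot, NumericVector w, NumericVector dy,
                       IntegerVector xdim, bool need_dx = true) {
  arma::fmat &M = pool_buf(slot);
  int wd[4], yd[4];
  get_dim4(w, wd); get_dim4(dy, yd);
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int k = wd[0], F = wd[3], pad = (k - 1) / 2;
  const arma::uword HW = (arma::uword)H * W;
  if (M.n_rows != HW * (arma::uword)N || M.n_cols != (arma::uword)k * k * C)
    stop("conv2d backward: pooled im2col buffer does not match this layer");
  arma::fmat &dY = y_buf(slot);
  dY.set_size((arma::uword)HW * N, F);
  { const double *dp = REAL(dy);
    for (int n = 0; n < N; ++n)
      for (int f = 0; f < F; ++f) {
        float *dc = dY.colptr(f) + (arma::uword)n * HW;
        const double *sc = dp + ((arma::uword)n * F + f) * HW;
        for (arma::uword i = 0; i < HW; ++i) dc[i] = (float)sc[i];
      } }
  arma::fmat Wm((arma::uword)k * k * C, F);
  { const double *wp = REAL(w); for (arma::uword i = 0; i < Wm.n_elem; ++i) Wm(i) = (float)wp[i]; }
  arma::fmat dWm = M.t() * dY;           // (kkC x F)
  NumericVector dwv((R_xlen_t)k * k * C * F), db(F);
  dwv.attr("dim") = IntegerVector::create(k, k, C, F);
  { double *p = REAL(dwv); for (arma::uword i = 0; i < dWm.n_elem; ++i) p[i] = (double)dWm(i); }
  for (int f = 0; f < F; ++f) db[f] = (double)arma::accu(dY.col(f));
  if (!need_dx)
    return List::create(_["dx"] = R_NilValue, _["dw"] = dwv, _["db"] = db);
  arma::fmat &dM = M;                    // overwrite the slot in place
  dM = dY * Wm.t();                      // (HWN x kkC)
  // col2im accumulate into pooled scratch, laid out like the (H,W,C,N) input
  arma::fmat &dxb = x_buf(slot);
  dxb.set_size(HW * (arma::uword)C * N, 1);
  dxb.zeros();
  float *dxf = dxb.memptr();
  for (int c = 0; c < C; ++c)
    for (int dw = 0; dw < k; ++dw)
      for (int dh = 0; dh < k; ++dh) {
        const arma::uword col = dh + k * (dw + k * c);
        for (int n = 0; n < N; ++n) {
          const float *Mc = dM.colptr(col) + (arma::uword)n * HW;
          float *dxs = dxf + ((size_t)n * C + c) * HW;
          for (int w2 = 0; w2 < W; ++w2) {
            const int wi = w2 + dw - pad;
            if (wi < 0 || wi >= W) continue;
            const int h0 = std::max(0, pad - dh), h1 = std::min(H, H + pad - dh);
            const float *src = Mc + (arma::uword)w2 * H;
            float *dst = dxs + (size_t)wi * H;
            for (int h = h0; h < h1; ++h) dst[h + dh - pad] += src[h];
          }
        }
      }
  NumericVector dx((R_xlen_t)HW * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  { double *p = REAL(dx); const size_t nn = (size_t)HW * C * N;
    for (size_t i = 0; i < nn; ++i) p[i] = (double)dxf[i]; }
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = db);
}

// [[Rcpp::export]]
List nn_maxpool2_fw(NumericVector x) {
  int xd[4]; get_dim4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial dims must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  const double *xp = REAL(x); double *yp = REAL(y);
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = ((R_xlen_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          R_xlen_t i00 = base + (R_xlen_t)(2 * w) * H + 2 * h;
          R_xlen_t cand[4] = {i00, i00 + 1, i00 + H, i00 + H + 1};
          R_xlen_t best = cand[0];
          for (int t = 1; t < 4; ++t) if (xp[cand[t]] > xp[best]) best = cand[t];
          yp[o] = xp[best]; idx[o] = (int)best; ++o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool2_bw(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  double *p = REAL(dx); const double *d = REAL(dy);
  for (R_xlen_t i = 0; i < idx.size(); ++i) p[idx[i]] += d[i];
  return dx;
}

// Transposed convolution, kernel 2, stride 2: y(2h+a, 2w+b, f, n) += x(h,w,c,n) w(a,b,c,f).
// Realised as GEMM (HWN x C) x (C x 4F) plus a scatter of the 2x2 cells.
// Xmat rows r = h + H*(w + W*n); W4 column q = a + 2*b + 4*f.
static void upconv_xmat(arma::fmat &X, const double *xp, int H, int W, int C, int N) {
  const arma::uword HW = (arma::uword)H * W;
  X.set_size(HW * N, C);
  for (int c = 0; c < C; ++c) {
    float *col = X.colptr(c);
    for (int n = 0; n < N; ++n) {
      const double *xs = xp + ((R_xlen_t)n * C + c) * HW;
      float *dst = col + (arma::uword)n * HW;
      for (arma::uword i = 0; i < HW; ++i) dst[i] = (float)xs[i];
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_upconv2_fw(NumericVector x, NumericVector w, NumericVector b,
                            int slot) {
  int xd[4], wd[4]; get_dim4(x, xd); get_dim4(w, wd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3], F = wd[3];
  if (wd[2] != C) stop("upconv2: weight Cin mismatch");
  const int Ho = 2 * H, Wo = 2 * W;
  arma::fmat &X = pool_buf(slot);
  upconv_xmat(X, REAL(x), H, W, C, N);
  arma::fmat W4(C, 4 * F);
  { const double *wp = REAL(w);  // (a,b,c,f): a + 2b + 4c + 4C f
    for (int f = 0; f < F; ++f)
      for (int c = 0; c < C; ++c)
        for (int q = 0; q < 4; ++q)
          W4(c, q + 4 * f) = (float)wp[q + 4 * c + 4 * (R_xlen_t)C * f]; }
  arma::fmat &Y4 = y_buf(slot);
  Y4.set_size(X.n_rows, (arma::uword)4 * F);
  Y4 = X * W4;                                  // (HWN x 4F)
  NumericVector y((R_xlen_t)Ho * Wo * F * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  double *yp = REAL(y);
  const double *bp = REAL(b);
  const arma::uword HW = (arma::uword)H * W;
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f) {
      double *ys = yp + ((R_xlen_t)n * F + f) * Ho * Wo;
      const float *c00 = Y4.colptr(0 + 4 * f) + (arma::uword)n * HW;
      const float *c10 = Y4.colptr(1 + 4 * f) + (arma::uword)n * HW;
      const float *c01 = Y4.colptr(2 + 4 * f) + (arma::uword)n * HW;
      const float *c11 = Y4.colptr(3 + 4 * f) + (arma::uword)n * HW;
      const double bf = bp[f];
      for (int w2 = 0; w2 < W; ++w2) {
        double *y0 = ys + (R_xlen_t)(2 * w2) * Ho;
        double *y1 = y0 + Ho;
        const arma::uword off = (arma::uword)w2 * H;
        for (int h = 0; h < H; ++h) {
          y0[2 * h]     = bf + (double)c00[off + h];
          y0[2 * h + 1] = bf + (double)c10[off + h];
          y1[2 * h]     = bf + (double)c01[off + h];
          y1[2 * h + 1] = bf + (double)c11[off + h];
        }
      }
    }
  return y;
}

// Backward transposed convolution from the pooled input matrix of the
// forward pass (the Y4 slot is overwritten with the gathered gradient).
// [[Rcpp::export]]
List nn_upconv2_bw(int slot, NumericVector w, NumericVector dy,
                   IntegerVector xdim) {
  int wd[4]; get_dim4(w, wd);
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3], F = wd[3];
  const int Ho = 2 * H;
  const arma::uword HW = (arma::uword)H * W;
  arma::fmat &X = pool_buf(slot);
  if (X.n_rows != HW * (arma::uword)N || X.n_cols != (arma::uword)C)
    stop("upconv2 backward: pooled input buffer does not match this layer");
  // gather dy into (HWN x 4F)
  arma::fmat &dY4 = y_buf(slot);
  dY4.set_size(HW * N, (arma::uword)4 * F);
  const double *dp = REAL(dy);
  NumericVector db(F);
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f) {
      const double *ds = dp + ((R_xlen_t)n * F + f) * Ho * 2 * W;
      float *c00 = dY4.colptr(0 + 4 * f) + (arma::uword)n * HW;
      float *c10 = dY4.colptr(1 + 4 * f) + (arma::uword)n * HW;
      float *c01 = dY4.colptr(2 + 4 * f) + (arma::uword)n * HW;
      float *c11 = dY4.colptr(3 + 4 * f) + (arma::uword)n * HW;
      double acc = 0;
      for (int w2 = 0; w2 < W; ++w2) {
        const double *d0 = ds + (R_xlen_t)(2 * w2) * Ho;
        const double *d1 = d0 + Ho;
        const arma::uword off = (arma::uword)w2 * H;
        for (int h = 0; h < H; ++h) {
          c00[off + h] = (float)d0[2 * h];
          c10[off + h] = (float)d0[2 * h + 1];
          c01[off + h] = (float)d1[2 * h];
          c11[off + h] = (float)d1[2 * h + 1];
          acc += d0[2 * h] + d0[2 * h + 1] + d1[2 * h] + d1[2 * h + 1];
        }
      }
      db[f] += acc;
    }
  arma::fmat dW4 = X.t() * dY4;                 // (C x 4F)
  arma::fmat W4(C, 4 * F);
  { const double *wp = REAL(w);
    for (int f = 0; f < F; ++f)
      for (int c = 0; c < C; ++c)
        for (int q = 0; q < 4; ++q)
          W4(c, q + 4 * f) = (float)wp[q + 4 * c + 4 * (R_xlen_t)C * f]; }
  arma::fmat &dX = x_buf(slot);
  dX.set_size(HW * N, (arma::uword)C);
  dX = dY4 * W4.t();                            // (HWN x C)
  NumericVector dx((R_xlen_t)HW * C * N), dwv((R_xlen_t)4 * C * F);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  dwv.attr("dim") = IntegerVector::create(2, 2, C, F);
  double *dxp = REAL(dx);
  for (int c = 0; c < C; ++c) {
    const float *col = dX.colptr(c);
    for (int n = 0; n < N; ++n) {
      double *dst = dxp + ((R_xlen_t)n * C + c) * HW;
      const float *src = col + (arma::uword)n * HW;
      for (arma::uword i = 0; i < HW; ++i) dst[i] = (double)src[i];
    }
  }
  { double *p = REAL(dwv);
    for (int f = 0; f < F; ++f)
      for (int c = 0; c < C; ++c)
        for (int q = 0; q < 4; ++q)
          p[q + 4 * c + 4 * (R_xlen_t)C * f] = (double)dW4(c, q + 4 * f); }
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = db);
}
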