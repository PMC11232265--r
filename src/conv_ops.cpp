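// Convolution primitives for the fusion network.
//
// All convolutions are stride-1 with symmetric zero padding, implemented as
// im2col + GEMM in single precision (the network is trained in float32, the
// convention for CNN autoencoders of this size). Layouts follow R's
// column-major order: activations are H x W x C (x B) arrays, kernels are
// kh x kw x Cin x Cout arrays, so no permutation is needed at the boundary.
// A whole minibatch is processed per call: patch rows of all samples are
// stacked into one matrix so each layer costs a single large GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct ActDims { int H, W, C, B; };

static ActDims act_dims(const NumericVector& a, const char* what) {
  SEXP ds = a.attr("dim");
  if (Rf_isNull(ds)) stop("%s must be a 3-d or 4-d array", what);
  IntegerVector d(ds);
  if (d.size() == 3) return ActDims{d[0], d[1], d[2], 1};
  if (d.size() == 4) return ActDims{d[0], d[1], d[2], d[3]};
  stop("%s must be a 3-d or 4-d array", what);
}

// Fill rows [b*H*W, (b+1)*H*W) of the stacked patch matrix K from one
// sample; column d = ikh + kh*(ikw + kw*c) holds the input plane c
// shifted by (ikh - pad, ikw - pad), zero outside the image. Writes every
// entry of its rows, so K need not be pre-zeroed. `cstride` is the float
// distance between consecutive channel planes of the sample.
static void im2col_strided(arma::fmat& K, const float* x, size_t cstride,
                           size_t row0, int H, int W, int C,
                           int kh, int kw, int pad) {
  for (int c = 0; c < C; ++c) {
    const float* plane = x + (size_t)c * cstride;
    for (int ikw = 0; ikw < kw; ++ikw) {
      for (int ikh = 0; ikh < kh; ++ikh) {
        const int d = ikh + kh * (ikw + kw * c);
        float* col = K.colptr(d) + row0;
        const int di = ikh - pad, dj = ikw - pad;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          float* dst = col + (size_t)j * H;
          if (sj < 0 || sj >= W) {
            std::fill(dst, dst + H, 0.0f);
            continue;
          }
          const float* src = plane + (size_t)sj * H;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int i = 0; i < i0; ++i) dst[i] = 0.0f;
          for (int i = i0; i < i1; ++i) dst[i] = src[i + di];
          for (int i = i1; i < H; ++i) dst[i] = 0.0f;
        }
      }
    }
  }
}

static void im2col_into(arma::fmat& K, const float* x, size_t row0,
                        int H, int W, int C, int kh, int kw, int pad) {
  im2col_strided(K, x, (size_t)H * W, row0, H, W, C, kh, kw, pad);
}

// Adjoint of im2col: scatter-add one sample's patch-gradient rows back
// onto its input gradient (same strided layout as im2col_strided).
static void col2im_strided(const arma::fmat& G, float* gx, size_t cstride,
                           size_t row0, int H, int W, int C,
                           int kh, int kw, int pad) {
  for (int c = 0; c < C; ++c) {
    float* plane = gx + (size_t)c * cstride;
    for (int ikw = 0; ikw < kw; ++ikw) {
      for (int ikh = 0; ikh < kh; ++ikh) {
        const int d = ikh + kh * (ikw + kw * c);
        const float* col = G.colptr(d) + row0;
        const int di = ikh - pad, dj = ikw - pad;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          float* dst = plane + (size_t)sj * H;
          const float* src = col + (size_t)j * H;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i) dst[i + di] += src[i];
        }
      }
    }
  }
}

static void col2im_from(const arma::fmat& G, float* gx, size_t row0,
                        int H, int W, int C, int kh, int kw, int pad) {
  col2im_strided(G, gx, (size_t)H * W, row0, H, W, C, kh, kw, pad);
}

// Non-static entry points for the whole-network fast path (net_fast.cpp).
void net_im2col(arma::fmat& K, const float* x, size_t cstride, size_t row0,
                int H, int W, int C, int kh, int kw, int pad) {
  im2col_strided(K, x, cstride, row0, H, W, C, kh, kw, pad);
}
void net_col2im(const arma::fmat& G, float* gx, size_t cstride, size_t row0,
                int H, int W, int C, int kh, int kw, int pad) {
  col2im_strided(G, gx, cstride, row0, H, W, C, kh, kw, pad);
}

static arma::fvec to_f(const NumericVector& a) {
  arma::fvec v(a.size());
  std::copy(a.begin(), a.end(), v.begin());
  return v;
}

// Forward pass. When `keep_patches` is true the stacked patch matrix is
// returned alongside the output (as an external pointer) so the backward
// pass can reuse it instead of rebuilding; the training loop uses this.
// [[Rcpp::export]]
SEXP cpp_conv2d(NumericVector x, NumericVector w, NumericVector b,
                int pad, bool relu, bool keep_patches = false) {
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("kernel must be a 4-d array (kh, kw, in, out)");
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  ActDims xd = act_dims(x, "input");
  if (xd.C != cin) stop("input channel count does not match kernel");
  if (xd.H < kh || xd.W < kw) stop("input smaller than kernel");
  const size_t HW = (size_t)xd.H * xd.W, D = (size_t)kh * kw * cin;

  arma::fvec xf = to_f(x);
  arma::fmat Wm(D, (arma::uword)cout);
  std::copy(w.begin(), w.end(), Wm.begin());
  arma::fmat* K = new arma::fmat(HW * xd.B, D, arma::fill::none);
  for (int bb = 0; bb < xd.B; ++bb)
    im2col_into(*K, xf.memptr() + HW * cin * bb, HW * bb,
                xd.H, xd.W, cin, kh, kw, pad);
  arma::fmat out = (*K) * Wm;                    // (HW*B) x Cout
  for (int oc = 0; oc < cout; ++oc) out.col(oc) += (float)b[oc];
  if (relu) out.transform([](float v) { return v > 0.0f ? v : 0.0f; });

  NumericVector res(HW * cout * (size_t)xd.B);
  for (int bb = 0; bb < xd.B; ++bb)
    for (int oc = 0; oc < cout; ++oc) {
      const float* src = out.colptr(oc) + HW * bb;
      double* dst = res.begin() + HW * (oc + (size_t)cout * bb);
      for (size_t t = 0; t < HW; ++t) dst[t] = src[t];
    }
  if (xd.B == 1 && Rf_length(x.attr("dim")) == 3)
    res.attr("dim") = IntegerVector::create(xd.H, xd.W, cout);
  else
    res.attr("dim") = IntegerVector::create(xd.H, xd.W, cout, xd.B);
  if (!keep_patches) {
    delete K;
    return res;
  }
  XPtr<arma::fmat> kptr(K, true);
  return List::create(_["out"] = res, _["patches"] = kptr);
}

// Gradients of one conv layer. When `relu` is true, `out` must be the
// stored forward output; the incoming gradient is masked by out > 0
// before the linear-conv adjoint. `patches`, when non-NULL, is the
// external pointer returned by the forward call (the patch matrix is
// then reused instead of rebuilt). `need_gx` can be false for the first
// layer, whose input gradient nobody consumes.
// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gout,
                    NumericVector out, int pad, bool relu,
                    SEXP patches = R_NilValue, bool need_gx = true) {
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  ActDims xd = act_dims(x, "input");
  ActDims gd = act_dims(gout, "gradient");
  if (gd.C != cout || gd.H != xd.H || gd.W != xd.W || gd.B != xd.B)
    stop("gradient shape does not match layer output");
  const size_t HW = (size_t)xd.H * xd.W, D = (size_t)kh * kw * cin;

  arma::fmat Wm(D, (arma::uword)cout);
  std::copy(w.begin(), w.end(), Wm.begin());

  // Stacked output-gradient matrix (HW*B) x Cout, ReLU-masked.
  arma::fmat Gm(HW * xd.B, (arma::uword)cout, arma::fill::none);
  for (int bb = 0; bb < xd.B; ++bb)
    for (int oc = 0; oc < cout; ++oc) {
      const double* src = gout.begin() + HW * (oc + (size_t)cout * bb);
      float* dst = Gm.colptr(oc) + HW * bb;
      if (relu) {
        const double* o = out.begin() + HW * (oc + (size_t)cout * bb);
        for (size_t t = 0; t < HW; ++t)
          dst[t] = o[t] > 0.0 ? (float)src[t] : 0.0f;
      } else {
        for (size_t t = 0; t < HW; ++t) dst[t] = (float)src[t];
      }
    }

  arma::fmat* K = nullptr;
  bool own_k = false;
  if (patches != R_NilValue) {
    XPtr<arma::fmat> kp(patches);
    K = kp.get();
  }
  if (K == nullptr || K->n_rows != HW * xd.B || K->n_cols != D) {
    K = new arma::fmat(HW * xd.B, D, arma::fill::none);
    own_k = true;
    arma::fvec xf = to_f(x);
    for (int bb = 0; bb < xd.B; ++bb)
      im2col_into(*K, xf.memptr() + HW * cin * bb, HW * bb,
                  xd.H, xd.W, cin, kh, kw, pad);
  }
  arma::fmat gW = K->t() * Gm;                   // D x Cout (summed over B)
  if (own_k) delete K;
  arma::frowvec gB = arma::sum(Gm, 0);

  NumericVector gw(gW.n_elem);
  std::copy(gW.begin(), gW.end(), gw.begin());
  gw.attr("dim") = wd;
  NumericVector gb(cout);
  std::copy(gB.begin(), gB.end(), gb.begin());

  if (!need_gx)
    return List::create(_["gx"] = R_NilValue, _["gw"] = gw, _["gb"] = gb);

  arma::fmat Gcol = Gm * Wm.t();                 // (HW*B) x D
  arma::fvec gxf(HW * cin * (size_t)xd.B, arma::fill::zeros);
  for (int bb = 0; bb < xd.B; ++bb)
    col2im_from(Gcol, gxf.memptr() + HW * cin * bb, HW * bb,
                xd.H, xd.W, cin, kh, kw, pad);
  NumericVector gx(gxf.n_elem);
  std::copy(gxf.begin(), gxf.end(), gx.begin());
  if (Rf_length(x.attr("dim")) == 3)
    gx.attr("dim") = IntegerVector::create(xd.H, xd.W, cin);
  else
    gx.attr("dim") = IntegerVector::create(xd.H, xd.W, cin, xd.B);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable 2-d correlation with a symmetric 1-d kernel (double precision:
// used by the SSIM loss, its analytic adjoint, metrics and the phantom
// renderer, where exact gradients matter more than speed).
//   valid: output (H-m+1) x (W-m+1), y(i,j) = sum_{t,u} k[t] k[u] x(i+t, j+u)
//   full:  the adjoint of valid (zero-padded full correlation)
//   same_reflect: same-size output with mirrored edges
// [[Rcpp::export]]
NumericMatrix cpp_sepfilter2(NumericMatrix x, NumericVector k, std::string mode) {
  const int H = x.nrow(), W = x.ncol(), m = k.size();
  const double* kp = k.begin();
  if (mode == "valid") {
    if (H < m || W < m) stop("image smaller than filter window");
    const int Hv = H - m + 1, Wv = W - m + 1;
    NumericMatrix tmp(Hv, W), out(Hv, Wv);
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < Hv; ++i) {
        double s = 0; for (int t = 0; t < m; ++t) s += kp[t] * x(i + t, j);
        tmp(i, j) = s;
      }
    for (int j = 0; j < Wv; ++j)
      for (int i = 0; i < Hv; ++i) {
        double s = 0; for (int t = 0; t < m; ++t) s += kp[t] * tmp(i, j + t);
        out(i, j) = s;
      }
    return out;
  } else if (mode == "full") {
    const int Hf = H + m - 1, Wf = W + m - 1;
    NumericMatrix tmp(Hf, W), out(Hf, Wf);
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < Hf; ++i) {
        double s = 0;
        const int t0 = std::max(0, i - H + 1), t1 = std::min(m - 1, i);
        for (int t = t0; t <= t1; ++t) s += kp[t] * x(i - t, j);
        tmp(i, j) = s;
      }
    for (int j = 0; j < Wf; ++j)
      for (int i = 0; i < Hf; ++i) {
        double s = 0;
        const int t0 = std::max(0, j - W + 1), t1 = std::min(m - 1, j);
        for (int t = t0; t <= t1; ++t) s += kp[t] * tmp(i, j - t);
        out(i, j) = s;
      }
    return out;
  } else if (mode == "same_reflect") {
    const int off = m / 2;
    NumericMatrix tmp(H, W), out(H, W);
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double s = 0;
        for (int t = 0; t < m; ++t) s += kp[t] * x(reflect_idx(i + t - off, H), j);
        tmp(i, j) = s;
      }
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double s = 0;
        for (int t = 0; t < m; ++t) s += kp[t] * tmp(i, reflect_idx(j + t - off, W));
        out(i, j) = s;
      }
    return out;
  }
  stop("unknown filter mode '%s'", mode.c_str());
}
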