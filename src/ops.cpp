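#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Feature maps are stored as npix x C matrices, npix = H*W, pixel linear
// index = row + col*H (0-based, column-major, matching R matrices).

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& x, int H, int W, int k) {
  int C = x.ncol(), npix = H * W, pad = k / 2, kk = k * k;
  NumericMatrix out(npix, kk * C);
  for (int c = 0; c < C; ++c) {
    const double* px = &x(0, c);
    for (int dx = -pad; dx <= pad; ++dx) {
      for (int dy = -pad; dy <= pad; ++dy) {
        int oc = c * kk + (dy + pad) + (dx + pad) * k;
        double* po = &out(0, oc);
        for (int col = 0; col < W; ++col) {
          int sc = col + dx;
          if (sc < 0 || sc >= W) continue;
          int r0 = dy < 0 ? -dy : 0;
          int r1 = dy > 0 ? H - dy : H;
          const double* src = px + sc * H + dy;
          double* dst = po + col * H;
          for (int r = r0; r < r1; ++r) dst[r] = src[r];
        }
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add patch gradients back to pixel grid.
// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& d, int H, int W, int k, int C) {
  int npix = H * W, pad = k / 2, kk = k * k;
  NumericMatrix out(npix, C);
  for (int c = 0; c < C; ++c) {
    double* po = &out(0, c);
    for (int dx = -pad; dx <= pad; ++dx) {
      for (int dy = -pad; dy <= pad; ++dy) {
        int oc = c * kk + (dy + pad) + (dx + pad) * k;
        const double* pd = &d(0, oc);
        for (int col = 0; col < W; ++col) {
          int sc = col + dx;
          if (sc < 0 || sc >= W) continue;
          int r0 = dy < 0 ? -dy : 0;
          int r1 = dy > 0 ? H - dy : H;
          double* dst = po + sc * H + dy;
          const double* src = pd + col * H;
          for (int r = r0; r < r1; ++r) dst[r] += src[r];
        }
      }
    }
  }
  return out;
}

// 2x2 stride-2 max pooling. Returns pooled values and 1-based argmax row
// indices into the input matrix (per channel column).
// [[Rcpp::export]]
List cpp_maxpool2(const NumericMatrix& x, int H, int W) {
  int C = x.ncol(), Ho = H / 2, Wo = W / 2, npo = Ho * Wo;
  NumericMatrix out(npo, C);
  IntegerMatrix amax(npo, C);
  for (int c = 0; c < C; ++c) {
    const double* px = &x(0, c);
    for (int co = 0; co < Wo; ++co) {
      for (int ro = 0; ro < Ho; ++ro) {
        int idx[4] = {2 * ro + 2 * co * H,       2 * ro + 1 + 2 * co * H,
                      2 * ro + (2 * co + 1) * H, 2 * ro + 1 + (2 * co + 1) * H};
        int best = idx[0];
        double bv = px[idx[0]];
        for (int j = 1; j < 4; ++j)
          if (px[idx[j]] > bv) { bv = px[idx[j]]; best = idx[j]; }
        out(ro + co * Ho, c) = bv;
        amax(ro + co * Ho, c) = best + 1;
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool2_backward(const NumericMatrix& dout,
                                    const IntegerMatrix& amax, int npix) {
  int C = dout.ncol(), npo = dout.nrow();
  NumericMatrix dx(npix, C);
  for (int c = 0; c < C; ++c)
    for (int i = 0; i < npo; ++i)
      dx(amax(i, c) - 1, c) += dout(i, c);
  return dx;
}

// Bilinear interpolation weights for 2x resize, half-pixel-centre mapping:
// source position p = (j + 0.5)/2 - 0.5, clamped at the borders.
static void up2_weights(int n_out, int n_in, std::vector<int>& i0,
                        std::vector<int>& i1, std::vector<double>& w1) {
  i0.resize(n_out); i1.resize(n_out); w1.resize(n_out);
  for (int j = 0; j < n_out; ++j) {
    double p = (j + 0.5) / 2.0 - 0.5;
    if (p < 0) p = 0;
    if (p > n_in - 1) p = n_in - 1;
    int a = (int)std::floor(p);
    int b = a + 1 < n_in ? a + 1 : a;
    i0[j] = a; i1[j] = b; w1[j] = p - a;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_upsample2(const NumericMatrix& x, int H, int W) {
  int C = x.ncol(), Ho = 2 * H, Wo = 2 * W;
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> rw, cw;
  up2_weights(Ho, H, r0, r1, rw);
  up2_weights(Wo, W, c0, c1, cw);
  NumericMatrix out(Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const double* px = &x(0, c);
    double* po = &out(0, c);
    for (int co = 0; co < Wo; ++co) {
      int ca = c0[co] * H, cb = c1[co] * H;
      double wc = cw[co];
      for (int ro = 0; ro < Ho; ++ro) {
        double wr = rw[ro];
        double v00 = px[r0[ro] + ca], v10 = px[r1[ro] + ca];
        double v01 = px[r0[ro] + cb], v11 = px[r1[ro] + cb];
        po[ro + co * Ho] = (1 - wr) * (1 - wc) * v00 + wr * (1 - wc) * v10 +
                           (1 - wr) * wc * v01 + wr * wc * v11;
      }
    }
  }
  return out;
}

// Adjoint of cpp_upsample2 (gradient w.r.t. the low-resolution input).
// [[Rcpp::export]]
NumericMatrix cpp_upsample2_backward(const NumericMatrix& dout, int H, int W) {
  int C = dout.ncol(), Ho = 2 * H, Wo = 2 * W;
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> rw, cw;
  up2_weights(Ho, H, r0, r1, rw);
  up2_weights(Wo, W, c0, c1, cw);
  NumericMatrix dx(H * W, C);
  for (int c = 0; c < C; ++c) {
    const double* pd = &dout(0, c);
    double* px = &dx(0, c);
    for (int co = 0; co < Wo; ++co) {
      int ca = c0[co] * H, cb = c1[co] * H;
      double wc = cw[co];
      for (int ro = 0; ro < Ho; ++ro) {
        double wr = rw[ro], g = pd[ro + co * Ho];
        px[r0[ro] + ca] += (1 - wr) * (1 - wc) * g;
        px[r1[ro] + ca] += wr * (1 - wc) * g;
        px[r0[ro] + cb] += (1 - wr) * wc * g;
        px[r1[ro] + cb] += wr * wc * g;
      }
    }
  }
  return dx;
}

// Connected-component labelling of a binary mask (H x W, 0/1).
// eight = true: 8-connectivity; false: 4-connectivity. Labels are assigned
// in raster scan order of component discovery (1, 2, ...).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask, bool eight) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nn = eight ? 8 : 4;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * H);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % H, pc = p / H;
        for (int j = 0; j < nn; ++j) {
          int qr = pr + dr8[j], qc = pc + dc8[j];
          if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
          if (mask(qr, qc) != 0 && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(qr + qc * H);
          }
        }
      }
    }
  }
  return lab;
}

// Fill interior holes: background (4-connectivity) not reachable from the
// image border becomes foreground.
// [[Rcpp::export]]
IntegerMatrix cpp_fill_holes(const IntegerMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix reach(H, W);
  std::vector<int> stack;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if ((r == 0 || r == H - 1 || c == 0 || c == W - 1) &&
          mask(r, c) == 0 && reach(r, c) == 0) {
        reach(r, c) = 1;
        stack.push_back(r + c * H);
        while (!stack.empty()) {
          int p = stack.back(); stack.pop_back();
          int pr = p % H, pc = p / H;
          const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
          for (int j = 0; j < 4; ++j) {
            int qr = pr + dr[j], qc = pc + dc[j];
            if (qr < 0 || qr >= H || qc < 0 || qc >= W) continue;
            if (mask(qr, qc) == 0 && reach(qr, qc) == 0) {
              reach(qr, qc) = 1;
              stack.push_back(qr + qc * H);
            }
          }
        }
      }
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      out(r, c) = (mask(r, c) != 0 || reach(r, c) == 0) ? 1 : 0;
  return out;
}

// ---- training fast paths -------------------------------------------------

// Add per-channel bias in place (x is always a freshly allocated GEMM
// result when called).
// [[Rcpp::export]]
NumericMatrix cpp_addbias(NumericMatrix x, const NumericVector& b) {
  int n = x.nrow(), C = x.ncol();
  for (int c = 0; c < C; ++c) {
    double* p = &x(0, c);
    double bc = b[c];
    for (int i = 0; i < n; ++i) p[i] += bc;
  }
  return x;
}

// Batch-norm forward, training mode: per-channel standardisation over all
// pixels, returning the normalised map, the output, and the batch moments.
// [[Rcpp::export]]
List cpp_bn_fwd_train(const NumericMatrix& x, const NumericVector& gamma,
                      const NumericVector& beta, double eps) {
  int n = x.nrow(), C = x.ncol();
  NumericMatrix out(n, C), xhat(n, C);
  NumericVector mean(C), var(C), invstd(C);
  for (int c = 0; c < C; ++c) {
    const double* p = &x(0, c);
    double s = 0, s2 = 0;
    for (int i = 0; i < n; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    double mu = s / n, v = s2 / n - mu * mu;
    if (v < 0) v = 0;
    double is = 1.0 / std::sqrt(v + eps);
    mean[c] = mu; var[c] = v; invstd[c] = is;
    double g = gamma[c], b = beta[c];
    double* ph = &xhat(0, c);
    double* po = &out(0, c);
    for (int i = 0; i < n; ++i) {
      double h = (p[i] - mu) * is;
      ph[i] = h;
      po[i] = g * h + b;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat,
                      _["invstd"] = invstd, _["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
NumericMatrix cpp_bn_fwd_eval(const NumericMatrix& x,
                              const NumericVector& gamma,
                              const NumericVector& beta,
                              const NumericVector& rmean,
                              const NumericVector& rvar, double eps) {
  int n = x.nrow(), C = x.ncol();
  NumericMatrix out(n, C);
  for (int c = 0; c < C; ++c) {
    double is = 1.0 / std::sqrt(rvar[c] + eps);
    double g = gamma[c] * is, b = beta[c] - rmean[c] * g;
    const double* p = &x(0, c);
    double* po = &out(0, c);
    for (int i = 0; i < n; ++i) po[i] = g * p[i] + b;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_bn_bwd(const NumericMatrix& dout, const NumericMatrix& xhat,
                const NumericVector& invstd, const NumericVector& gamma) {
  int n = dout.nrow(), C = dout.ncol();
  NumericMatrix dx(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* pd = &dout(0, c);
    const double* ph = &xhat(0, c);
    double sg = 0, sb = 0;
    for (int i = 0; i < n; ++i) { sg += pd[i] * ph[i]; sb += pd[i]; }
    dgamma[c] = sg; dbeta[c] = sb;
    double g = gamma[c], is = invstd[c];
    double m1 = sb / n, m2 = sg / n;
    double* px = &dx(0, c);
    for (int i = 0; i < n; ++i)
      px[i] = (pd[i] - m1 - ph[i] * m2) * g * is;
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericMatrix cpp_relu(const NumericMatrix& x) {
  int n = x.nrow() * x.ncol();
  NumericMatrix out(x.nrow(), x.ncol());
  const double* p = x.begin();
  double* po = out.begin();
  for (int i = 0; i < n; ++i) po[i] = p[i] > 0 ? p[i] : 0;
  return out;
}

// dout *= (act > 0), in place (dout is owned by the backward pass).
// [[Rcpp::export]]
NumericMatrix cpp_relu_bwd(NumericMatrix dout, const NumericMatrix& act) {
  int n = dout.nrow() * dout.ncol();
  double* pd = dout.begin();
  const double* pa = act.begin();
  for (int i = 0; i < n; ++i) if (pa[i] <= 0) pd[i] = 0;
  return dout;
}

// Per-channel scaling out = x * s[col].
// [[Rcpp::export]]
NumericMatrix cpp_colscale(const NumericMatrix& x, const NumericVector& s) {
  int n = x.nrow(), C = x.ncol();
  NumericMatrix out(n, C);
  for (int c = 0; c < C; ++c) {
    const double* p = &x(0, c);
    double* po = &out(0, c);
    double sc = s[c];
    for (int i = 0; i < n; ++i) po[i] = p[i] * sc;
  }
  return out;
}
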