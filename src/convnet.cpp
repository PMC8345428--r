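// Compiled kernels for the padded-VGG16 fully convolutional segmenter.
//
// Layout conventions (match R arrays, column-major):
//   activations   : arma::cube  H x W x C      (dim = c(H, W, C) in R)
//   conv weights  : arma::mat   (kh*kw*inC) x outC, patch index i + kh*j + kh*kw*c
//   deconv weights: arma::cube  kh x kw x (outC*inC), slice = oc + outC*ic
//
// Convolutions use stride 1 with symmetric zero padding; im2col buffers are
// processed in row strips so a full-width forward pass stays within a few
// hundred MB regardless of feature-map size.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// cap on im2col strip buffer, in doubles (~320 MB)
static const double kBufDoubles = 4.0e7;

static void im2col_strip(const arma::cube& x, arma::mat& M, int r0, int nr,
                         int kh, int kw, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int outW = W + 2 * pad - kw + 1;
  M.zeros();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int col = i + kh * j + kh * kw * c;
        double* Mcol = M.colptr(col);
        for (int ow = 0; ow < outW; ++ow) {
          const int xc = ow + j - pad;
          if (xc < 0 || xc >= W) continue;
          const int rlo = std::max(r0, pad - i);
          const int rhi = std::min(r0 + nr, H + pad - i);
          if (rhi <= rlo) continue;
          const double* src = &x(rlo + i - pad, xc, c);
          double* dst = Mcol + (size_t)ow * nr + (rlo - r0);
          std::memcpy(dst, src, (size_t)(rhi - rlo) * sizeof(double));
        }
      }
    }
  }
}

// scatter-add transpose of im2col_strip
static void col2im_strip(arma::cube& dx, const arma::mat& dM, int r0, int nr,
                         int kh, int kw, int pad) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  const int outW = W + 2 * pad - kw + 1;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int col = i + kh * j + kh * kw * c;
        const double* Mcol = dM.colptr(col);
        for (int ow = 0; ow < outW; ++ow) {
          const int xc = ow + j - pad;
          if (xc < 0 || xc >= W) continue;
          const int rlo = std::max(r0, pad - i);
          const int rhi = std::min(r0 + nr, H + pad - i);
          if (rhi <= rlo) continue;
          const double* src = Mcol + (size_t)ow * nr + (rlo - r0);
          double* dst = &dx(rlo + i - pad, xc, c);
          for (int t = 0; t < rhi - rlo; ++t) dst[t] += src[t];
        }
      }
    }
  }
}

// direct shifted-plane convolution: profitable when channel counts are
// small and the feature maps large (im2col materialization dominates there)
static bool use_direct(int kh, int kw, int C, int outC) {
  return kh == 3 && kw == 3 && C * outC <= 1024;
}

static arma::cube pad_zero(const arma::cube& x, int pad) {
  if (pad == 0) return x;
  arma::cube xp(x.n_rows + 2 * pad, x.n_cols + 2 * pad, x.n_slices,
                arma::fill::zeros);
  xp.subcube(pad, pad, 0, pad + x.n_rows - 1, pad + x.n_cols - 1,
             x.n_slices - 1) = x;
  return xp;
}

static arma::cube conv_direct_forward(const arma::cube& x, const arma::mat& w,
                                      const arma::vec& b, int kh, int kw,
                                      int pad, bool relu) {
  const arma::cube xp = pad_zero(x, pad);
  const int outH = xp.n_rows - kh + 1, outW = xp.n_cols - kw + 1;
  const int C = x.n_slices, outC = w.n_cols;
  arma::cube y(outH, outW, outC);
  for (int oc = 0; oc < outC; ++oc) {
    arma::mat& yp = y.slice(oc);
    yp.fill(b(oc));
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i)
          yp += w(i + kh * j + kh * kw * c, oc) *
                xp.slice(c).submat(i, j, i + outH - 1, j + outW - 1);
    if (relu) yp.for_each([](double& v) { if (v < 0) v = 0; });
  }
  return y;
}

static List conv_direct_backward(const arma::cube& x, const arma::mat& w,
                                 const arma::cube& dy, int kh, int kw,
                                 int pad) {
  const arma::cube xp = pad_zero(x, pad);
  const int outH = dy.n_rows, outW = dy.n_cols;
  const int C = x.n_slices, outC = dy.n_slices;
  arma::cube dxp(xp.n_rows, xp.n_cols, C, arma::fill::zeros);
  arma::mat dW(w.n_rows, outC, arma::fill::zeros);
  arma::vec db(outC);
  for (int oc = 0; oc < outC; ++oc) {
    const arma::mat& g = dy.slice(oc);
    db(oc) = arma::accu(g);
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i) {
          const int col = i + kh * j + kh * kw * c;
          dW(col, oc) = arma::accu(
              xp.slice(c).submat(i, j, i + outH - 1, j + outW - 1) % g);
          dxp.slice(c).submat(i, j, i + outH - 1, j + outW - 1) +=
              w(col, oc) * g;
        }
  }
  arma::cube dx = (pad == 0) ? dxp
      : arma::cube(dxp.subcube(pad, pad, 0, pad + x.n_rows - 1,
                               pad + x.n_cols - 1, C - 1));
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
arma::cube conv_forward_cpp(const arma::cube& x, const arma::mat& w,
                            const arma::vec& b, int kh, int kw, int pad,
                            bool relu) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if ((int)w.n_rows != kh * kw * C)
    stop("conv weight rows (%d) do not match kh*kw*inC (%d)",
         (int)w.n_rows, kh * kw * C);
  const int outH = H + 2 * pad - kh + 1;
  const int outW = W + 2 * pad - kw + 1;
  if (outH < 1 || outW < 1) stop("convolution output size is non-positive");
  const int outC = w.n_cols;
  if (use_direct(kh, kw, C, outC))
    return conv_direct_forward(x, w, b, kh, kw, pad, relu);
  arma::cube y(outH, outW, outC);
  const int strip = std::max(1, (int)(kBufDoubles / ((double)outW * w.n_rows)));
  for (int r0 = 0; r0 < outH; r0 += strip) {
    const int nr = std::min(strip, outH - r0);
    arma::mat M((size_t)nr * outW, w.n_rows);
    im2col_strip(x, M, r0, nr, kh, kw, pad);
    arma::mat Y = M * w;
    Y.each_row() += b.t();
    if (relu) Y.for_each([](double& v) { if (v < 0) v = 0; });
    for (int oc = 0; oc < outC; ++oc) {
      arma::mat Yc(Y.colptr(oc), nr, outW, false, true);
      y.slice(oc).rows(r0, r0 + nr - 1) = Yc;
    }
  }
  return y;
}

// dy must already carry the ReLU mask when the forward pass fused a ReLU
// [[Rcpp::export]]
List conv_backward_cpp(const arma::cube& x, const arma::mat& w,
                       const arma::cube& dy, int kh, int kw, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int outH = dy.n_rows, outW = dy.n_cols, outC = dy.n_slices;
  if (use_direct(kh, kw, C, outC))
    return conv_direct_backward(x, w, dy, kh, kw, pad);
  arma::cube dx(H, W, C, arma::fill::zeros);
  arma::mat dW(w.n_rows, outC, arma::fill::zeros);
  arma::vec db(outC);
  for (int oc = 0; oc < outC; ++oc) db(oc) = arma::accu(dy.slice(oc));
  const int strip = std::max(1, (int)(kBufDoubles / ((double)outW * w.n_rows)));
  for (int r0 = 0; r0 < outH; r0 += strip) {
    const int nr = std::min(strip, outH - r0);
    arma::mat M((size_t)nr * outW, w.n_rows);
    im2col_strip(x, M, r0, nr, kh, kw, pad);
    arma::mat G((size_t)nr * outW, outC);
    for (int oc = 0; oc < outC; ++oc) {
      arma::mat Gc(G.colptr(oc), nr, outW, false, true);
      Gc = dy.slice(oc).rows(r0, r0 + nr - 1);
    }
    dW += M.t() * G;
    arma::mat dM = G * w.t();
    col2im_strip(dx, dM, r0, nr, kh, kw, pad);
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2 max pooling, stride 2, ceil mode (odd trailing row/col pools alone)
// [[Rcpp::export]]
List maxpool_forward_cpp(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int outH = (H + 1) / 2, outW = (W + 1) / 2;
  arma::cube y(outH, outW, C);
  IntegerVector idx((R_xlen_t)outH * outW * C);
  R_xlen_t e = 0;
  for (int c = 0; c < C; ++c) {
    for (int ow = 0; ow < outW; ++ow) {
      const int w0 = 2 * ow, w1 = std::min(W - 1, 2 * ow + 1);
      for (int oh = 0; oh < outH; ++oh) {
        const int h0 = 2 * oh, h1 = std::min(H - 1, 2 * oh + 1);
        double best = x(h0, w0, c);
        R_xlen_t bi = h0 + (R_xlen_t)H * w0 + (R_xlen_t)H * W * c;
        for (int ww = w0; ww <= w1; ++ww)
          for (int hh = h0; hh <= h1; ++hh) {
            const double v = x(hh, ww, c);
            if (v > best) {
              best = v;
              bi = hh + (R_xlen_t)H * ww + (R_xlen_t)H * W * c;
            }
          }
        y(oh, ow, c) = best;
        idx[e++] = (int)bi;
      }
    }
  }
  // e runs (oh, ow, c) fastest-to-slowest == column-major order of y
  idx.attr("dim") = IntegerVector::create(outH, outW, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube maxpool_backward_cpp(const IntegerVector& idx, const arma::cube& dy,
                                int H, int W) {
  const int C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  const double* g = dy.memptr();
  double* d = dx.memptr();
  const R_xlen_t n = idx.size();
  for (R_xlen_t e = 0; e < n; ++e) d[idx[e]] += g[e];
  return dx;
}

// transposed convolution, stride s, no output padding
// [[Rcpp::export]]
arma::cube deconv_forward_cpp(const arma::cube& x, const arma::cube& w,
                              const arma::vec& b, int stride, int outC) {
  const int H = x.n_rows, W = x.n_cols, inC = x.n_slices;
  const int kh = w.n_rows, kw = w.n_cols;
  if ((int)w.n_slices != outC * inC)
    stop("deconv weight slices do not match outC*inC");
  const int outH = (H - 1) * stride + kh;
  const int outW = (W - 1) * stride + kw;
  arma::cube y(outH, outW, outC, arma::fill::zeros);
  for (int ic = 0; ic < inC; ++ic) {
    for (int oc = 0; oc < outC; ++oc) {
      const arma::mat& ws = w.slice(oc + outC * ic);
      for (int wj = 0; wj < W; ++wj)
        for (int hi = 0; hi < H; ++hi) {
          const double v = x(hi, wj, ic);
          if (v != 0.0)
            y.slice(oc).submat(hi * stride, wj * stride,
                               hi * stride + kh - 1, wj * stride + kw - 1) +=
                v * ws;
        }
    }
  }
  for (int oc = 0; oc < outC; ++oc) y.slice(oc) += b(oc);
  return y;
}

// [[Rcpp::export]]
List deconv_backward_cpp(const arma::cube& x, const arma::cube& w,
                         const arma::cube& dy, int stride, int outC) {
  const int H = x.n_rows, W = x.n_cols, inC = x.n_slices;
  const int kh = w.n_rows, kw = w.n_cols;
  arma::cube dx(H, W, inC, arma::fill::zeros);
  arma::cube dW(kh, kw, outC * inC, arma::fill::zeros);
  arma::vec db(outC);
  for (int oc = 0; oc < outC; ++oc) db(oc) = arma::accu(dy.slice(oc));
  for (int ic = 0; ic < inC; ++ic) {
    for (int oc = 0; oc < outC; ++oc) {
      const arma::mat& ws = w.slice(oc + outC * ic);
      arma::mat& dws = dW.slice(oc + outC * ic);
      for (int wj = 0; wj < W; ++wj)
        for (int hi = 0; hi < H; ++hi) {
          const arma::mat sub = dy.slice(oc).submat(
              hi * stride, wj * stride, hi * stride + kh - 1,
              wj * stride + kw - 1);
          dx(hi, wj, ic) += arma::accu(sub % ws);
          dws += x(hi, wj, ic) * sub;
        }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// box-mean downsampling by integer factor; partial edge blocks average the
// pixels they actually cover
// [[Rcpp::export]]
arma::cube box_downsample_cpp(const arma::cube& x, int f) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int outH = (H + f - 1) / f, outW = (W + f - 1) / f;
  arma::cube y(outH, outW, C);
  for (int c = 0; c < C; ++c)
    for (int ow = 0; ow < outW; ++ow) {
      const int w0 = ow * f, w1 = std::min(W, w0 + f);
      for (int oh = 0; oh < outH; ++oh) {
        const int h0 = oh * f, h1 = std::min(H, h0 + f);
        double s = 0;
        for (int ww = w0; ww < w1; ++ww)
          for (int hh = h0; hh < h1; ++hh) s += x(hh, ww, c);
        y(oh, ow, c) = s / ((w1 - w0) * (h1 - h0));
      }
    }
  return y;
}

// streamed binary confusion counts for one block pair (labels as matrices)
// [[Rcpp::export]]
IntegerVector confusion_block_cpp(const IntegerMatrix& pred,
                                  const IntegerMatrix& truth, int positive) {
  if (pred.nrow() != truth.nrow() || pred.ncol() != truth.ncol())
    stop("prediction and truth blocks differ in size");
  long tp = 0, fp = 0, fn = 0, tn = 0;
  const R_xlen_t n = pred.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const bool p = pred[i] == positive, t = truth[i] == positive;
    if (p && t) ++tp;
    else if (p) ++fp;
    else if (t) ++fn;
    else ++tn;
  }
  return IntegerVector::create(_["tp"] = (int)tp, _["fp"] = (int)fp,
                               _["fn"] = (int)fn, _["tn"] = (int)tn);
}
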